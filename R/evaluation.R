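#' Correct-answer sets
#'
#' `build_estimation_answer_set()` applies the estimation-benchmark filters
#' to ClinVar records: review status of two or more stars (multi-submitter
#' agreement), a definite Pathogenic or Benign assertion (Likely_pathogenic,
#' Likely_benign and VUS are excluded), and missense consequence — the
#' variant class that is hardest to call and therefore the evaluation target.
#'
#' `build_explanation_answer_set()` is the looser set used to train the
#' explanation model, where more data matters more than label purity:
#' Likely_* calls are mapped to their parent label, every single-nucleotide
#' consequence is admitted, and the majority class is downsampled to parity.
#'
#' @param clinvar ClinVar records ([load_clinvar()] result or tibble).
#' @param seed seed for the parity downsampling.
#' @return tibble of labeled variants: `key, gene, chrom, consequence,
#'   label, stars`.
#' @export
build_estimation_answer_set <- function(clinvar) {
  cv <- as_records(clinvar)
  keep <- cv$review_stars >= 2 &
    cv$clinical_significance %in% c("Pathogenic", "Benign") &
    cv$consequence == "missense_variant"
  cv <- cv[keep, , drop = FALSE]
  out <- tibble::tibble(
    key = canonical_variant_key(cv$chrom, cv$pos, cv$ref, cv$alt),
    gene = cv$gene,
    chrom = sub("^chr", "", as.character(cv$chrom)),
    consequence = cv$consequence,
    label = ifelse(cv$clinical_significance == "Pathogenic",
                   "pathogenic", "benign"),
    stars = as.integer(cv$review_stars)
  )
  out[!duplicated(out$key), ]
}

#' @rdname build_estimation_answer_set
#' @export
build_explanation_answer_set <- function(clinvar, seed = 1L) {
  cv <- as_records(clinvar)
  snv <- nchar(cv$ref) == 1 & nchar(cv$alt) == 1
  keep <- snv & cv$clinical_significance %in%
    c("Pathogenic", "Likely_pathogenic", "Benign", "Likely_benign")
  cv <- cv[keep, , drop = FALSE]
  out <- tibble::tibble(
    key = canonical_variant_key(cv$chrom, cv$pos, cv$ref, cv$alt),
    gene = cv$gene,
    chrom = sub("^chr", "", as.character(cv$chrom)),
    consequence = cv$consequence,
    label = ifelse(cv$clinical_significance %in%
                     c("Pathogenic", "Likely_pathogenic"),
                   "pathogenic", "benign"),
    stars = as.integer(cv$review_stars)
  )
  out <- out[!duplicated(out$key), ]
  balance_classes(out, seed)
}

#' Balance class sizes by downsampling the majority class
#'
#' Uniform, seed-reproducible downsampling of the majority class (without
#' replacement) to the minority count; the minority class is preserved in
#' full. When benign variants are the majority this removes only benign
#' variants.
#'
#' @param variants labeled-variant tibble with a `label` column.
#' @param seed RNG seed.
#' @return tibble with equal class counts, in original row order.
#' @export
balance_classes <- function(variants, seed = 1L) {
  tab <- table(variants$label)
  if (length(tab) < 2 || any(tab == 0)) {
    stop_kgx("both classes must be present", "kgx_validation_error")
  }
  if (tab[1] == tab[2]) return(variants)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  maj_idx <- which(variants$label == majority)
  keep_maj <- with_seed(seed, sample(maj_idx, min(tab)))
  variants[sort(c(which(variants$label == minority), keep_maj)), ]
}

#' Chromosome-disjoint fold assignment
#'
#' Partitions chromosomes into `k` folds so that training and test folds
#' never share a chromosome (variants of one gene — and a fortiori one
#' chromosome — never straddle the split, preventing same-gene leakage).
#' Chromosomes are packed greedily, largest variant count first into the
#' currently lightest fold, which keeps fold sizes balanced.
#'
#' @param variants labeled-variant tibble with `key` and `chrom` columns.
#' @param k number of folds.
#' @param seed kept for interface symmetry; the assignment is deterministic.
#' @return tibble `key, chrom, fold` with folds in `0:(k-1)`.
#' @export
chromosome_folds <- function(variants, k = 5L, seed = 1L) {
  chroms <- table(variants$chrom)
  if (length(chroms) < k) {
    stop_kgx(sprintf("need at least %d chromosomes, got %d", k, length(chroms)),
             "kgx_validation_error")
  }
  ord <- order(-as.integer(chroms), names(chroms))
  load <- numeric(k)
  fold_of <- integer(length(chroms))
  names(fold_of) <- names(chroms)[ord]
  for (i in seq_along(ord)) {
    f <- which.min(load)
    fold_of[i] <- f - 1L
    load[f] <- load[f] + as.integer(chroms[ord[i]])
  }
  tibble::tibble(
    key = variants$key, chrom = variants$chrom,
    fold = unname(fold_of[variants$chrom])
  )
}

rank_auc <- function(scores, labels) {
  y <- labels == "pathogenic"
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop_kgx("AUC undefined with a single class", "kgx_validation_error")
  }
  r <- rank(scores) # midranks handle ties
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics
#'
#' Accuracy, precision, recall and F1 at the given threshold with
#' "pathogenic" as the positive class, plus AUC via the Mann-Whitney rank
#' statistic (midranks correct for ties) and the ROC curve.
#'
#' @param scores numeric pathogenicity scores.
#' @param labels `"pathogenic"` / `"benign"`, same length (both present).
#' @param threshold decision threshold, default 0.5.
#' @return a `kgx_metrics` list: `accuracy, precision, recall, f1, auc`,
#'   `roc` (tibble of fpr/tpr sorted by threshold), and the confusion counts.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels), length(scores) >= 2)
  pred <- ifelse(scores >= threshold, "pathogenic", "benign")
  y <- labels == "pathogenic"
  tp <- sum(pred == "pathogenic" & y)
  fp <- sum(pred == "pathogenic" & !y)
  fn <- sum(pred == "benign" & y)
  tn <- sum(pred == "benign" & !y)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  th <- sort(unique(scores), decreasing = TRUE)
  roc <- tibble::tibble(
    threshold = c(Inf, th),
    tpr = c(0, vapply(th, function(t) sum(scores >= t & y) / sum(y), numeric(1))),
    fpr = c(0, vapply(th, function(t) sum(scores >= t & !y) / sum(!y), numeric(1)))
  )
  structure(list(
    accuracy = (tp + tn) / length(scores),
    precision = precision, recall = recall, f1 = f1,
    auc = rank_auc(scores, labels),
    roc = roc,
    confusion = c(tp = tp, fp = fp, fn = fn, tn = tn)
  ), class = "kgx_metrics")
}

#' @export
print.kgx_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f  AUC %.3f\n",
    x$accuracy, x$precision, x$recall, x$f1, x$auc
  ))
  invisible(x)
}

metrics_row <- function(m) {
  tibble::tibble(accuracy = m$accuracy, precision = m$precision,
                 recall = m$recall, f1 = m$f1, auc = m$auc)
}

#' Chromosome-disjoint cross-validation
#'
#' Runs the full train/score loop over the fold assignment: for each fold,
#' trains the chosen model on all out-of-fold variants and scores the
#' in-fold variants, then averages the per-fold metrics. Before every fold
#' the chromosome sets of the training and test variants are intersected;
#' any overlap is a hard error (leakage guard). Optionally sweeps the
#' model's capacity parameter (epochs for the graph classifier, depth for
#' the baselines) and reports the best mean performance, mirroring the
#' epoch/depth-sweep protocol.
#'
#' @param dataset a list with `kg` (the knowledge graph), `index`
#'   ([variant_index()]) and `answers` (labeled-variant tibble); see
#'   [assemble_dataset()].
#' @param folds fold assignment from [chromosome_folds()].
#' @param model `"graph"`, `"tree"` or `"forest"`.
#' @param param capacity parameter (epochs or depth); `NULL` for defaults.
#' @param sweep optional vector of capacity values; when given, every value
#'   is cross-validated and the best mean accuracy is reported.
#' @param config a [classifier_config()] (graph model only).
#' @param flatten_cfg a [flatten_config()] (baselines only).
#' @param threshold decision threshold for metrics.
#' @param seed RNG seed for backend training.
#' @return a `kgx_cv_report`: `per_fold` (tibble with a fold column),
#'   `mean` (one-row tibble), `scores` (tibble of key/score/label/fold),
#'   `model`, and `sweep` (tibble of param vs mean accuracy, or `NULL`).
#' @export
cross_validate <- function(dataset, folds, model = c("graph", "tree", "forest"),
                           param = NULL, sweep = NULL,
                           config = classifier_config(),
                           flatten_cfg = flatten_config(),
                           threshold = 0.5, seed = 1L) {
  model <- match.arg(model)
  answers <- dataset$answers
  fold_of <- folds$fold[match(answers$key, folds$key)]
  if (any(is.na(fold_of))) {
    stop_kgx("every answer-set variant needs a fold", "kgx_validation_error")
  }
  # a chromosome must never span folds
  span <- tapply(fold_of, answers$chrom, function(f) length(unique(f)))
  if (any(span > 1)) {
    stop_kgx("chromosome split across folds: leakage", "kgx_leakage_error")
  }

  # feature subgraphs may be precomputed once and shared across model runs
  fgs <- dataset$fgs %||% lapply(answers$key, build_feature_graph,
                                 kg = dataset$kg, mode = "estimation",
                                 index = dataset$index)
  # embeddings do not depend on the capacity parameter: compute once
  X <- if (model == "graph") {
    cfg0 <- config
    cfg0$seed <- as.integer(seed)
    embed_graphs(fgs, cfg0)
  } else {
    flatten_graphs(fgs, flatten_cfg)
  }
  y <- factor(answers$label, levels = c("benign", "pathogenic"))

  run_once <- function(p) {
    per <- list(); sc_all <- list()
    for (f in sort(unique(fold_of))) {
      tr <- fold_of != f; te <- !tr
      if (length(intersect(unique(answers$chrom[tr]),
                           unique(answers$chrom[te])))) {
        stop_kgx("train and test folds share a chromosome", "kgx_leakage_error")
      }
      if (model == "graph") {
        epochs <- if (!is.null(p)) as.integer(p) else config$epochs
        fit <- fit_logistic(
          X[tr, , drop = FALSE], y[tr], config$lambda / sqrt(epochs)
        )
        s <- as.numeric(predict(fit, X[te, , drop = FALSE], type = "response"))
      } else {
        depth <- if (!is.null(p)) as.integer(p) else if (model == "tree") 9L else 0L
        b <- if (model == "tree") {
          fit_tree(X[tr, , drop = FALSE], answers$label[tr], depth, seed)
        } else {
          fit_forest(X[tr, , drop = FALSE], answers$label[tr], depth, seed)
        }
        s <- predict_baseline(b, X[te, , drop = FALSE])
      }
      m_f <- compute_metrics(s, answers$label[te], threshold)
      per[[length(per) + 1L]] <- cbind(tibble::tibble(fold = f), metrics_row(m_f))
      sc_all[[length(sc_all) + 1L]] <- tibble::tibble(
        key = answers$key[te], score = s, label = answers$label[te], fold = f
      )
    }
    per <- do.call(rbind, per)
    list(per_fold = per,
         mean = tibble::as_tibble(lapply(per[, -1], mean)),
         scores = do.call(rbind, sc_all))
  }

  sweep_tbl <- NULL
  if (!is.null(sweep)) {
    res <- lapply(sweep, function(p) run_once(p))
    acc <- vapply(res, function(r) r$mean$accuracy, numeric(1))
    sweep_tbl <- tibble::tibble(param = sweep, mean_accuracy = acc)
    best <- res[[which.max(acc)]]
  } else {
    best <- run_once(param)
  }
  structure(c(best, list(model = model, sweep = sweep_tbl)),
            class = "kgx_cv_report")
}

#' @export
print.kgx_cv_report <- function(x, ...) {
  cat(sprintf("<kgx_cv_report> model=%s, %d fold(s)\n", x$model,
              nrow(x$per_fold)))
  cat(sprintf(
    "mean: accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f  AUC %.3f\n",
    x$mean$accuracy, x$mean$precision, x$mean$recall, x$mean$f1, x$mean$auc
  ))
  invisible(x)
}

#' Bundle a simulated (or loaded) dataset for cross-validation
#'
#' Assembles the knowledge graph, position index and estimation answer set
#' from annotation tables, the shape [cross_validate()] consumes.
#'
#' @param clinvar,cosmic,dbnsfp,dbscsnv record tables or loader results.
#' @param variants optional variant universe tibble.
#' @param balance_seed seed for class balancing; `NULL` skips balancing.
#' @return list with `kg`, `index`, `answers`.
#' @export
assemble_dataset <- function(clinvar, cosmic = NULL, dbnsfp = NULL,
                             dbscsnv = NULL, variants = NULL,
                             balance_seed = 1L) {
  kg <- records_to_kg(clinvar, cosmic, dbnsfp, dbscsnv, variants)
  parts <- Filter(Negate(is.null), list(clinvar, cosmic, dbnsfp, dbscsnv,
                                        variants))
  index <- do.call(variant_index, parts)
  answers <- build_estimation_answer_set(clinvar)
  if (!is.null(balance_seed)) answers <- balance_classes(answers, balance_seed)
  list(kg = kg, index = index, answers = answers)
}
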