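#' COSMIC sample-count aggregation
#'
#' Carries the COSMIC sample count forward by its order of magnitude,
#' aggregating it into a small integer bin: 1 sample is bin 0; `1 < n <= 10`
#' is 1; `10 < n <= 100` is 2; `100 < n <= 1000` is 3; `1000 < n <= 10000`
#' is 4; everything above 10,000 is 5. Equivalently,
#' `min(ceiling(log10(n)), 5)`.
#'
#' @param n integer vector of sample counts, all `>= 1`.
#' @return integer vector of bins in `0:5`.
#' @export
#' @examples
#' bin_sample_count(c(1, 10, 11, 100, 10001))
bin_sample_count <- function(n) {
  if (any(is.na(n)) || any(n < 1)) {
    stop_kgx("sample counts must be >= 1", "kgx_validation_error")
  }
  thresholds <- c(1, 10, 100, 1000, 10000)
  vapply(n, function(k) sum(k > thresholds), numeric(1))
}

#' Default distance bins for neighbor aggregation
#'
#' Upper edges (inclusive) of the distance bins used when tallying
#' neighboring variants: 1-10, 11-25, 26-50, 51-100 bases. Distance 0
#' (same base, different allele) falls in the first bin. Configurable via
#' [flatten_config()]; set 100 per-base bins by passing `1:100`.
#' @export
DEFAULT_DISTANCE_BINS <- c(10L, 25L, 50L, 100L)

distance_bin <- function(d, bins = DEFAULT_DISTANCE_BINS) {
  if (any(d < 0) || any(d > max(bins))) {
    stop_kgx("neighbor distance outside the binned range", "kgx_validation_error")
  }
  findInterval(d, bins, left.open = TRUE) + 1L
}

DEFAULT_CONSEQUENCES <- c(
  "missense_variant", "synonymous_variant", "stop_gained",
  "splice_region_variant"
)

#' Flattening configuration
#'
#' Fixed schema parameters for converting feature subgraphs into the
#' fixed-length vectors consumed by the decision-tree and random-forest
#' baselines. The schema length depends only on this config, never on the
#' data, so vectors are comparable across variants.
#'
#' @param distance_bins inclusive upper bin edges for neighbor distances.
#' @param publishers closed ClinVar publisher vocabulary (unknown labels are
#'   tallied as `"Other"`).
#' @param consequences closed consequence vocabulary (others tallied as
#'   `"other"`).
#' @param algorithms dbNSFP algorithms expected on the target.
#' @param sentinel value encoding a missing numeric feature.
#' @return a `kgx_flatten_config`.
#' @export
flatten_config <- function(distance_bins = DEFAULT_DISTANCE_BINS,
                           publishers = DEFAULT_PUBLISHERS,
                           consequences = DEFAULT_CONSEQUENCES,
                           algorithms = ESTIMATION_ALGORITHMS,
                           sentinel = -1) {
  structure(list(
    distance_bins = as.integer(distance_bins),
    publishers = publishers,
    consequences = consequences,
    algorithms = algorithms,
    sentinel = sentinel
  ), class = "kgx_flatten_config")
}

canon_consequence <- function(x, vocab) {
  x[is.na(x) | !x %in% vocab] <- "other"
  x
}

canon_publisher <- function(x, vocab) {
  x[is.na(x) | !x %in% vocab] <- "Other"
  x
}

#' Tabulate publications as features
#'
#' ClinVar-linked publications carry a publisher label and are tabulated per
#' publisher; COSMIC publications carry none and are simply totaled.
#'
#' @param clinvar_pubs character vector of publisher labels, one per ClinVar
#'   publication (possibly empty).
#' @param cosmic_pubs character vector of COSMIC publication ids.
#' @param publishers publisher vocabulary.
#' @return named numeric vector: one `clinvar_pubs_<publisher>` count per
#'   vocabulary label plus `cosmic_pubs_total`.
#' @export
aggregate_publications <- function(clinvar_pubs = character(),
                                   cosmic_pubs = character(),
                                   publishers = DEFAULT_PUBLISHERS) {
  pub <- canon_publisher(clinvar_pubs, publishers)
  counts <- table(factor(pub, levels = publishers))
  out <- c(as.numeric(counts), length(cosmic_pubs))
  names(out) <- c(paste0("clinvar_pubs_", publishers), "cosmic_pubs_total")
  out
}

#' Tally neighboring variants into distance bins
#'
#' Neighbor annotations are summed within distance bins (proximity matters,
#' so counts are kept per distance stratum). Includes the two ClinVar
#' combination features: consequence crossed with clinical significance, and
#' consequence crossed with review status (collapsed to >= 2 stars or not)
#' and clinical significance.
#'
#' @param neighbors tibble with `key`, `distance` (from [neighbors_within()]).
#' @param annotations tibble with one row per neighbor annotation record:
#'   columns `key`, `source` (`"clinvar"`/`"cosmic"`), `consequence`,
#'   `clinical_significance`, `review_stars`, `n_pubs`.
#' @param config a [flatten_config()].
#' @return named numeric feature vector with a fixed, data-independent schema.
#' @export
aggregate_neighbors <- function(neighbors, annotations = NULL,
                                config = flatten_config()) {
  bins <- config$distance_bins
  nb <- length(bins)
  sig_levels <- CLINICAL_SIGNIFICANCE
  cons_levels <- c(config$consequences, "other")
  stars_levels <- c("hi", "lo")

  per_bin_names <- function(b) {
    c(
      sprintf("nbin%d_n_variants", b),
      sprintf("nbin%d_clinvar_n", b),
      sprintf("nbin%d_cosmic_n", b),
      sprintf("nbin%d_clinvar_pubs", b),
      sprintf("nbin%d_cosmic_pubs", b),
      as.vector(outer(cons_levels, sig_levels,
                      function(co, s) sprintf("nbin%d_cs_%s_%s", b, co, s))),
      as.vector(outer(
        as.vector(outer(cons_levels, stars_levels, paste, sep = "_")),
        sig_levels,
        function(cr, s) sprintf("nbin%d_csr_%s_%s", b, cr, s)
      ))
    )
  }
  nm <- unlist(lapply(seq_len(nb), per_bin_names))
  out <- setNames(numeric(length(nm)), nm)
  if (is.null(neighbors) || nrow(neighbors) == 0) return(out)

  bidx <- distance_bin(neighbors$distance, bins)
  for (b in unique(bidx)) {
    out[sprintf("nbin%d_n_variants", b)] <- sum(bidx == b)
  }
  if (!is.null(annotations) && nrow(annotations)) {
    ann <- annotations[annotations$key %in% neighbors$key, , drop = FALSE]
    if (!nrow(ann)) return(out)
    ab <- distance_bin(neighbors$distance[match(ann$key, neighbors$key)], bins)
    for (i in seq_len(nrow(ann))) {
      b <- ab[i]
      if (ann$source[i] == "clinvar") {
        out[sprintf("nbin%d_clinvar_n", b)] <-
          out[sprintf("nbin%d_clinvar_n", b)] + 1
        out[sprintf("nbin%d_clinvar_pubs", b)] <-
          out[sprintf("nbin%d_clinvar_pubs", b)] + (ann$n_pubs[i] %||% 0)
        co <- canon_consequence(ann$consequence[i], config$consequences)
        s <- ann$clinical_significance[i]
        if (s %in% sig_levels) {
          k1 <- sprintf("nbin%d_cs_%s_%s", b, co, s)
          out[k1] <- out[k1] + 1
          st <- if (!is.na(ann$review_stars[i]) && ann$review_stars[i] >= 2) "hi" else "lo"
          k2 <- sprintf("nbin%d_csr_%s_%s_%s", b, co, st, s)
          out[k2] <- out[k2] + 1
        }
      } else if (ann$source[i] == "cosmic") {
        out[sprintf("nbin%d_cosmic_n", b)] <-
          out[sprintf("nbin%d_cosmic_n", b)] + 1
        out[sprintf("nbin%d_cosmic_pubs", b)] <-
          out[sprintf("nbin%d_cosmic_pubs", b)] + (ann$n_pubs[i] %||% 0)
      }
    }
  }
  out
}

# one row per (record, predicate) with literal values resolved
fg_literals <- function(fg) {
  ed <- fg$edges
  nv <- fg$nodes$value; names(nv) <- fg$nodes$node_id
  data.table::data.table(
    subject = ed$subject, predicate = ed$predicate,
    object = ed$object, value = unname(nv[ed$object])
  )
}

# per-record summary table of a feature graph: rec, rec_type, hub
fg_records <- function(fg) {
  rec <- fg$edges[fg$edges$predicate == "describes_variant", ]
  nt <- fg$nodes$node_type; names(nt) <- fg$nodes$node_id
  data.table::data.table(
    rec = rec$subject, hub = rec$object, rec_type = unname(nt[rec$subject])
  )
}

#' Flatten a feature subgraph into a fixed-length vector
#'
#' Deterministic, schema-stable conversion of an estimation-mode feature
#' subgraph into the feature array used by the baselines: the target's dbNSFP
#' scores and COSMIC registration status / sample-count bin, publication
#' tallies ([aggregate_publications()]) and binned neighbor tallies
#' ([aggregate_neighbors()]). Missing numeric features encode as the
#' sentinel (default -1). The vector length depends only on the config.
#'
#' @param fg a `kgx_feature_graph` in estimation mode.
#' @param config a [flatten_config()].
#' @return named numeric vector matching [flatten_schema()].
#' @export
flatten <- function(fg, config = flatten_config()) {
  if (!inherits(fg, "kgx_feature_graph") || fg$mode != "estimation") {
    stop_kgx("flatten expects an estimation-mode feature graph", "kgx_mode_error")
  }
  recs <- fg_records(fg)
  lits <- fg_literals(fg)
  tgt <- recs[recs$hub == fg$target_hub, ]

  # target dbNSFP scores
  sc <- setNames(rep(config$sentinel, length(config$algorithms)),
                 paste0("dbnsfp_", config$algorithms))
  db_rec <- tgt$rec[tgt$rec_type == "dbnsfp_record"]
  if (length(db_rec)) {
    sl <- lits[lits$subject %in% db_rec & startsWith(lits$predicate, "score:"), ]
    alg <- sub("^score:", "", sl$predicate)
    keep <- alg %in% config$algorithms
    sc[paste0("dbnsfp_", alg[keep])] <- as.numeric(sl$value[keep])
  }

  # target COSMIC
  cm_rec <- tgt$rec[tgt$rec_type == "cosmic_record"]
  cosmic_registered <- as.numeric(length(cm_rec) > 0)
  cosmic_bin <- config$sentinel
  cosmic_pubs <- character()
  if (length(cm_rec)) {
    n <- as.numeric(lits$value[lits$subject %in% cm_rec &
                                 lits$predicate == "sample_count"])
    if (length(n)) cosmic_bin <- bin_sample_count(max(n))
    cosmic_pubs <- lits$object[lits$subject %in% cm_rec &
                                 lits$predicate == "has_publication"]
  }
  # target ClinVar publications are excluded in estimation mode by
  # construction; the publisher tally is still part of the fixed schema
  pubs <- aggregate_publications(character(), cosmic_pubs, config$publishers)

  nb_ann <- neighbor_annotations(fg, recs, lits)
  nbf <- aggregate_neighbors(fg$neighbor_links, nb_ann, config)

  c(sc,
    cosmic_registered = cosmic_registered,
    cosmic_sample_bin = cosmic_bin,
    pubs,
    nbf)
}

neighbor_annotations <- function(fg, recs = fg_records(fg), lits = fg_literals(fg)) {
  nbl <- fg$neighbor_links
  nb <- recs[recs$hub %in% nbl$hub & recs$rec_type %in%
               c("clinvar_record", "cosmic_record"), ]
  if (!nrow(nb)) {
    return(tibble::tibble(
      key = character(), source = character(), consequence = character(),
      clinical_significance = character(), review_stars = numeric(),
      n_pubs = numeric()
    ))
  }
  key <- nbl$key[match(nb$hub, nbl$hub)]
  getlit <- function(rec, pred) {
    v <- lits$value[lits$subject == rec & lits$predicate == pred]
    if (length(v)) v[1] else NA_character_
  }
  tibble::tibble(
    key = key,
    source = sub("_record$", "", nb$rec_type),
    consequence = vapply(nb$rec, getlit, character(1), "consequence"),
    clinical_significance = vapply(nb$rec, getlit, character(1),
                                   "clinical_significance"),
    review_stars = suppressWarnings(as.numeric(
      vapply(nb$rec, getlit, character(1), "review_stars")
    )),
    n_pubs = vapply(nb$rec, function(r) {
      sum(lits$subject == r & lits$predicate == "has_publication")
    }, numeric(1))
  )
}

#' Feature-vector schema
#'
#' @param config a [flatten_config()].
#' @return character vector of feature names, in vector order.
#' @export
flatten_schema <- function(config = flatten_config()) {
  empty <- structure(list(
    target = "schema", mode = "estimation", target_hub = "variant:schema",
    nodes = data.table::data.table(node_id = "variant:schema",
                                   node_type = "variant_hub",
                                   value = NA_character_, source_db = "hub"),
    edges = data.table::data.table(subject = character(),
                                   predicate = character(),
                                   object = character()),
    neighbor_links = data.table::setnames(
      data.table::data.table(k = character(), distance = integer(),
                             hub = character()),
      "k", "key"
    )
  ), class = "kgx_feature_graph")
  names(flatten(empty, config))
}

#' Flatten many feature graphs
#'
#' @param fgs list of estimation-mode `kgx_feature_graph`s.
#' @param config a [flatten_config()].
#' @return numeric matrix, one row per graph, columns = [flatten_schema()].
#' @export
flatten_graphs <- function(fgs, config = flatten_config()) {
  schema <- flatten_schema(config)
  X <- t(vapply(fgs, function(g) flatten(g, config)[schema],
                numeric(length(schema))))
  colnames(X) <- schema
  X
}

check_baseline_input <- function(vectors, labels) {
  labels <- as.character(labels)
  if (nrow(vectors) != length(labels)) {
    stop_kgx("vectors and labels disagree in length", "kgx_training_error")
  }
  if (length(unique(labels)) < 2) {
    stop_kgx("both classes must be present", "kgx_training_error")
  }
  factor(labels, levels = c("benign", "pathogenic"))
}

#' Decision-tree and random-forest baselines
#'
#' White-box and black-box baselines trained on flattened feature vectors.
#' `fit_tree` wraps [rpart::rpart()] (`cp = 0`, depth honored via
#' `maxdepth`); `fit_forest` wraps [ranger::ranger()] probability forests
#' with `max.depth`. Predictions are class probabilities for "pathogenic" in
#' `[0, 1]` and are reproducible for a fixed seed.
#'
#' @param vectors numeric matrix from [flatten_graphs()].
#' @param labels `"pathogenic"` / `"benign"` per row.
#' @param max_depth maximum tree depth.
#' @param seed RNG seed.
#' @param num_trees forest size.
#' @return a `kgx_baseline` model.
#' @export
fit_tree <- function(vectors, labels, max_depth = 9L, seed = 1L) {
  y <- check_baseline_input(vectors, labels)
  df <- data.frame(vectors, check.names = TRUE)
  df$.y <- y
  fit <- with_seed(seed, rpart::rpart(
    .y ~ ., data = df, method = "class",
    control = rpart::rpart.control(
      maxdepth = min(max_depth, 30L), cp = 0, xval = 0, minsplit = 4
    )
  ))
  structure(list(type = "tree", fit = fit, colnames = colnames(df)),
            class = "kgx_baseline")
}

#' @rdname fit_tree
#' @export
fit_forest <- function(vectors, labels, max_depth = 0L, seed = 1L,
                       num_trees = 300L) {
  y <- check_baseline_input(vectors, labels)
  df <- data.frame(vectors, check.names = TRUE)
  fit <- ranger::ranger(
    x = df, y = y, probability = TRUE, num.trees = num_trees,
    max.depth = max_depth, seed = seed, num.threads = 1
  )
  structure(list(type = "forest", fit = fit, colnames = colnames(df)),
            class = "kgx_baseline")
}

#' Score flattened vectors with a baseline model
#'
#' @param model a `kgx_baseline`.
#' @param vectors numeric matrix with the training schema.
#' @return numeric vector of pathogenic probabilities.
#' @export
predict_baseline <- function(model, vectors) {
  df <- data.frame(vectors, check.names = TRUE)
  if (model$type == "tree") {
    as.numeric(predict(model$fit, df, type = "prob")[, "pathogenic"])
  } else {
    as.numeric(predict(model$fit, data = df,
                       num.threads = 1)$predictions[, "pathogenic"])
  }
}
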