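#' Classifier configuration
#'
#' Configuration for the pluggable graph classifier. Two reference backends
#' implement the train / predict / attribute contract:
#'
#' * `"graph_kernel_logistic"` (default): each feature subgraph is flattened
#'   into a fixed-length vector by hashing per-edge tokens (node types,
#'   predicates, categorical literal values) into `dim` buckets, accumulating
#'   numeric literal payloads; a ridge-penalized logistic regression
#'   ([glmnet::glmnet()]) is fit on top. Fully deterministic.
#' * `"gnn"`: a small randomized message-passing network (echo-state style:
#'   fixed random projection weights drawn from `seed`, `rounds` rounds of
#'   neighborhood averaging with `tanh` nonlinearity) with a logistic readout
#'   over mean-pooled node states.
#'
#' `epochs` is the capacity knob swept in the evaluation protocol: for the
#' logistic backend it relaxes the ridge penalty as
#' `lambda / sqrt(epochs)`, so larger values mean a less regularized
#' (longer-trained) model.
#'
#' @param backend one of `"graph_kernel_logistic"`, `"gnn"`.
#' @param dim number of hash buckets for the graph feature vector.
#' @param lambda base ridge penalty.
#' @param epochs integer >= 1, capacity parameter.
#' @param rounds message-passing rounds (gnn backend).
#' @param state_dim node state dimension (gnn backend).
#' @param seed integer seed for any backend randomness.
#' @param decision_threshold score threshold for [classify_score()]; scores
#'   at or above it are pathogenic.
#' @return a `kgx_classifier_config` list.
#' @export
classifier_config <- function(backend = c("graph_kernel_logistic", "gnn"),
                              dim = 512L, lambda = 0.02, epochs = 10L,
                              rounds = 2L, state_dim = 32L, seed = 1L,
                              decision_threshold = 0.5) {
  backend <- match.arg(backend)
  stopifnot(epochs >= 1, dim >= 16, lambda > 0)
  structure(list(
    backend = backend, dim = as.integer(dim), lambda = lambda,
    epochs = as.integer(epochs), rounds = as.integer(rounds),
    state_dim = as.integer(state_dim), seed = as.integer(seed),
    decision_threshold = decision_threshold
  ), class = "kgx_classifier_config")
}

NUMERIC_PREDICATES <- c(
  "review_stars", "n_submissions", "last_update_year", "sample_count",
  "ada_score", "rf_score"
)
CATEGORICAL_PREDICATES <- c(
  "clinical_significance", "consequence", "publisher"
)

# Per-edge feature map: token (hashed to a bucket) and numeric value.
# The graph-level feature vector is the sum over unmasked edges, which is
# what makes LIME edge masking consistent with training features.
edge_features <- function(fg) {
  ed <- fg$edges
  n <- nrow(ed)
  if (!n) {
    return(data.table::data.table(token = character(), val = numeric()))
  }
  nd <- fg$nodes
  ntype <- nd$node_type; names(ntype) <- nd$node_id
  nval <- nd$value; names(nval) <- nd$node_id

  # role: does this edge describe the target variant or a neighbor?
  rec_edges <- ed[ed$predicate == "describes_variant", ]
  rec_hub <- rec_edges$object; names(rec_hub) <- rec_edges$subject
  owner <- ed$subject
  is_pub <- !is.na(ntype[owner]) & ntype[owner] == "publication"
  # publication ids are "<record>/pub/<pmid>"
  owner[is_pub] <- sub("/pub/.*$", "", owner[is_pub])
  owner_hub <- rec_hub[owner]
  owner_hub[is.na(owner_hub)] <- ed$subject[is.na(owner_hub)] # hub-subject edges
  role <- ifelse(owner_hub == fg$target_hub, "t", "n")

  subj_type <- unname(ntype[ed$subject])
  pred <- ed$predicate
  objv <- unname(nval[ed$object])

  token <- character(n); val <- rep(1, n)
  num <- pred %in% NUMERIC_PREDICATES
  if (any(num)) {
    token[num] <- paste(role[num], subj_type[num], pred[num], sep = ":")
    x <- suppressWarnings(as.numeric(objv[num]))
    x[is.na(x)] <- 0
    p <- pred[num]
    x[p == "review_stars"] <- x[p == "review_stars"] / 4
    x[p == "n_submissions"] <- log1p(x[p == "n_submissions"])
    x[p == "last_update_year"] <- (x[p == "last_update_year"] - 2000) / 20
    x[p == "sample_count"] <- log10(pmax(x[p == "sample_count"], 1)) / 5
    val[num] <- x
  }
  cat_ <- pred %in% CATEGORICAL_PREDICATES
  token[cat_] <- paste(role[cat_], subj_type[cat_], pred[cat_], objv[cat_], sep = ":")
  sc <- startsWith(pred, "score:")
  if (any(sc)) {
    token[sc] <- paste(role[sc], pred[sc], sep = ":")
    x <- suppressWarnings(as.numeric(objv[sc]))
    x[is.na(x)] <- 0
    val[sc] <- x
  }
  rest <- !num & !cat_ & !sc
  token[rest] <- paste(role[rest], subj_type[rest], pred[rest], sep = ":")
  # neighbor links carry their distance, coarsened into bins
  nbl <- ed$predicate == "neighbor"
  if (any(nbl) && nrow(fg$neighbor_links)) {
    d <- fg$neighbor_links$distance[match(ed$object[nbl], fg$neighbor_links$hub)]
    token[nbl] <- paste0("neighbor:bin", distance_bin(d))
  }
  data.table::data.table(token = token, val = val)
}

.bucket_cache <- new.env(parent = emptyenv())

tokens_to_buckets <- function(tokens, dim) {
  ck <- paste0("d", dim)
  cache <- .bucket_cache[[ck]]
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .bucket_cache[[ck]] <- cache
  }
  out <- integer(length(tokens))
  for (i in seq_along(tokens)) {
    b <- cache[[tokens[i]]]
    if (is.null(b)) {
      b <- hash_bucket(tokens[i], dim)
      cache[[tokens[i]]] <- b
    }
    out[i] <- b
  }
  out
}

graph_vector <- function(fg, dim) {
  ef <- edge_features(fg)
  v <- numeric(dim)
  if (nrow(ef)) {
    b <- tokens_to_buckets(ef$token, dim)
    for (i in seq_along(b)) v[b[i]] <- v[b[i]] + ef$val[i]
  }
  v
}

#' Train the graph classifier
#'
#' Trains a pathogenicity classifier on a list of feature subgraphs. All
#' graphs must share one mode (estimation or explanation); the fitted model
#' is tagged with that mode and refuses to score graphs built in the other
#' mode. Deterministic for a fixed config seed.
#'
#' @param graphs list of `kgx_feature_graph` (from [build_feature_graph()]).
#' @param labels vector of `"pathogenic"` / `"benign"`, same length.
#' @param config a [classifier_config()].
#' @return a `kgx_model`.
#' @export
train_classifier <- function(graphs, labels, config = classifier_config()) {
  stopifnot(inherits(config, "kgx_classifier_config"))
  labels <- as.character(labels)
  if (length(graphs) != length(labels) || length(graphs) < 2) {
    stop_kgx("need >= 2 graphs with one label each", "kgx_training_error")
  }
  if (!all(labels %in% c("pathogenic", "benign"))) {
    stop_kgx("labels must be 'pathogenic' or 'benign'", "kgx_training_error")
  }
  if (length(unique(labels)) < 2) {
    stop_kgx("both classes must be present in training data", "kgx_training_error")
  }
  mode <- graphs[[1]]$mode
  y <- factor(labels, levels = c("benign", "pathogenic"))
  X <- embed_graphs(graphs, config)
  fit <- fit_logistic(X, y, config$lambda / sqrt(config$epochs))
  structure(list(
    backend = config$backend, fit = fit, mode = mode, config = config
  ), class = "kgx_model")
}

# ridge logistic fit; glmnet's small-class advisory warning is muffled
# (tiny inputs are legitimate here, e.g. the two-graph smoke case)
fit_logistic <- function(X, y, lambda) {
  withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8|dangerous ground", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

embed_graphs <- function(graphs, config) {
  if (config$backend == "graph_kernel_logistic") {
    X <- t(vapply(graphs, graph_vector, numeric(config$dim), dim = config$dim))
  } else {
    X <- t(vapply(graphs, gnn_embed, numeric(2L * config$state_dim),
                  config = config))
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

# randomized message passing: fixed random projections per seed
gnn_weights <- function(config) {
  d <- config$state_dim
  with_seed(config$seed, lapply(seq_len(config$rounds), function(k) {
    matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d)
  }))
}

gnn_embed <- function(fg, config) {
  d <- config$state_dim
  nd <- fg$nodes
  n <- nrow(nd)
  if (!n) return(numeric(2L * d))
  # categorical literals keep their value in the token; numeric payloads are
  # folded into the initial amplitude instead
  val <- nd$value
  val[is.na(val) | nd$node_type == "dbnsfp_score"] <- ""
  val[!is.na(suppressWarnings(as.numeric(nd$value)))] <- ""
  tok <- paste(nd$node_type, val)
  b <- tokens_to_buckets(tok, d)
  h <- matrix(0, n, d)
  numv <- suppressWarnings(as.numeric(nd$value))
  amp <- ifelse(is.na(numv), 1, 1 + numv)
  for (i in seq_len(n)) h[i, b[i]] <- amp[i]
  si <- match(fg$edges$subject, nd$node_id)
  oi <- match(fg$edges$object, nd$node_id)
  W <- gnn_weights(config)
  deg <- pmax(tabulate(c(si, oi), n), 1)
  for (k in seq_len(config$rounds)) {
    m <- matrix(0, n, d)
    if (length(si)) {
      for (e in seq_along(si)) {
        m[si[e], ] <- m[si[e], ] + h[oi[e], ]
        m[oi[e], ] <- m[oi[e], ] + h[si[e], ]
      }
    }
    h <- tanh((h + m / deg) %*% W[[k]])
  }
  ti <- match(fg$target_hub, nd$node_id)
  c(colMeans(h), h[ti, ])
}

#' Score a variant feature subgraph
#'
#' @param model a `kgx_model` from [train_classifier()].
#' @param fg a `kgx_feature_graph` built in the same mode the model was
#'   trained in (mode mismatch is an error).
#' @return pathogenicity score in `[0, 1]`; at or above the decision
#'   threshold (default 0.5) is interpreted as pathogenic.
#' @export
predict_score <- function(model, fg) {
  stopifnot(inherits(model, "kgx_model"))
  if (inherits(fg, "kgx_feature_graph")) fg <- list(fg)
  modes <- vapply(fg, `[[`, character(1), "mode")
  if (any(modes != model$mode)) {
    stop_kgx(sprintf("model was trained in %s mode but graph is %s mode",
                     model$mode, modes[modes != model$mode][1]),
             "kgx_mode_error")
  }
  X <- embed_graphs(fg, model$config)
  as.numeric(predict(model$fit, X, type = "response"))
}

score_matrix <- function(model, X) {
  as.numeric(predict(model$fit, X, type = "response"))
}

#' Classify a pathogenicity score
#'
#' A score of `threshold` (default 0.5) or more is interpreted as pathogenic,
#' less as benign.
#'
#' @param score numeric vector in `[0, 1]`.
#' @param threshold decision threshold.
#' @return character vector `"pathogenic"` / `"benign"`.
#' @export
#' @examples
#' classify_score(c(0.5, 0.499, 1.0))
classify_score <- function(score, threshold = 0.5) {
  if (any(is.na(score)) || any(score < 0 | score > 1)) {
    stop_kgx("scores must lie in [0, 1]", "kgx_validation_error")
  }
  ifelse(score >= threshold, "pathogenic", "benign")
}

#' Perturbation-based edge attribution
#'
#' LIME-style local surrogate: the feature subgraph is perturbed by random
#' edge masking, each masked graph is re-scored by the model, and a linear
#' surrogate of the score as a function of edge presence is fit. The fitted
#' weight of each edge is its contribution; positive pushes the score toward
#' pathogenic.
#'
#' When all `2^E` masks fit within `n_perturbations` the full factorial is
#' enumerated and the surrogate is the exact least-squares fit; otherwise
#' `n_perturbations` uniform random masks are drawn under `seed` and a small
#' ridge penalty (`1e-3`) stabilizes the fit.
#'
#' @param model a trained `kgx_model`.
#' @param fg the feature subgraph to explain.
#' @param n_perturbations number of masks (default 256).
#' @param seed RNG seed for mask sampling.
#' @return tibble with the edge columns and a `contribution` column; zero
#'   rows for an edgeless graph.
#' @export
edge_contributions <- function(model, fg, n_perturbations = 256L, seed = 1L) {
  E <- nrow(fg$edges)
  out <- tibble::as_tibble(fg$edges)
  if (E == 0) {
    out$contribution <- numeric()
    return(out)
  }
  exhaustive <- E <= 20 && 2^E <= n_perturbations
  if (exhaustive) {
    M <- as.matrix(expand.grid(rep(list(c(0, 1)), E)))
    ridge <- 0
  } else {
    M <- with_seed(seed, matrix(
      stats::rbinom(n_perturbations * E, 1, 0.5), n_perturbations, E
    ))
    ridge <- 1e-3
  }
  y <- score_masked(model, fg, M)
  Z <- cbind(1, M)
  A <- crossprod(Z) + diag(c(0, rep(ridge, E)))
  beta <- solve(A, crossprod(Z, y))
  out$contribution <- as.numeric(beta[-1])
  out
}

score_masked <- function(model, fg, M) {
  cfg <- model$config
  if (cfg$backend == "graph_kernel_logistic") {
    ef <- edge_features(fg)
    b <- tokens_to_buckets(ef$token, cfg$dim)
    Phi <- matrix(0, nrow(ef), cfg$dim)
    for (i in seq_along(b)) Phi[i, b[i]] <- Phi[i, b[i]] + ef$val[i]
    X <- M %*% Phi
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    score_matrix(model, X)
  } else {
    apply(M, 1, function(m) {
      sub <- fg
      sub$edges <- fg$edges[as.logical(m), ]
      predict_score(model, sub)
    })
  }
}

#' Node contributions from edge contributions
#'
#' Converts per-edge attributions to per-node attributions: a node inherits
#' the signed value of the maximum-magnitude contribution among its incident
#' edges (`method = "max"`, the default, which preserves the single-edge
#' node-equals-edge identity and avoids double counting); `"sum"` and
#' `"mean"` are selectable alternatives. Nodes with no incident contributing
#' edge get 0.
#'
#' @param edge_contribs result of [edge_contributions()].
#' @param fg the feature subgraph.
#' @param method aggregation over incident edges.
#' @return named numeric vector over all nodes of `fg`.
#' @export
node_contributions <- function(edge_contribs, fg, method = c("max", "sum", "mean")) {
  method <- match.arg(method)
  ids <- fg$nodes$node_id
  out <- setNames(numeric(length(ids)), ids)
  if (!nrow(edge_contribs)) return(out)
  inc <- rbind(
    data.frame(node = edge_contribs$subject, c = edge_contribs$contribution),
    data.frame(node = edge_contribs$object, c = edge_contribs$contribution)
  )
  inc <- inc[inc$node %in% ids, ]
  agg <- switch(method,
    max = function(v) v[which.max(abs(v))],
    sum = sum,
    mean = mean
  )
  got <- tapply(inc$c, inc$node, agg)
  out[names(got)] <- as.numeric(got)
  out
}

#' Save / load a trained model
#'
#' Single-file archive holding the backend id, fitted parameters, training
#' configuration and feature-mode tag.
#'
#' @param model a `kgx_model`.
#' @param path file path.
#' @return `load_model`: the restored `kgx_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "kgx_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "kgx_model"))
  m
}

#' @export
print.kgx_model <- function(x, ...) {
  cat(sprintf("<kgx_model> backend=%s mode=%s epochs=%d\n",
              x$backend, x$mode, x$config$epochs))
  invisible(x)
}
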