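#' Run one pipeline stage
#'
#' Single programmatic entry point wiring the modules into the end-to-end
#' pipeline; the `inst/cli/kgxplain.R` script is a thin command-line wrapper
#' around it. Every stage writes its artifacts plus a `provenance.json`
#' (inputs with md5 hashes, seeds, package version) into `out_dir`, so any
#' artifact directory is rerunnable from its own metadata.
#'
#' Commands and their config fields:
#'
#' * `simulate`: `sim` (a [sim_config()] or its argument list) -> the four
#'   annotation TSVs plus `truth.tsv`.
#' * `build-kg`: `data_dir` (TSVs from `simulate`) -> `nodes.tsv`,
#'   `edges.tsv`, `graph.nt`.
#' * `train`: `data_dir`, `mode` (`estimation`/`explanation`), optional
#'   `classifier` ([classifier_config()]), `seed` -> `model.rds`. The
#'   explanation model applies the ClinVar half-masking plan
#'   ([make_mask_plan()]) to its training variants.
#' * `predict`: `data_dir`, `model` (path), `variants` (keys; default all
#'   estimation answers) -> `predictions.tsv` with score and class.
#' * `explain`: `data_dir`, `model` (path; must be explanation mode —
#'   an estimation-mode model is refused), `variants`, optional
#'   `explainer_config` (YAML path), `top_n` -> one `explanation_<key>.txt`
#'   + `.tsv` per variant.
#' * `evaluate`: `data_dir`, `model_kind` (`graph`/`tree`/`forest`),
#'   `folds`, `seed`, optional `sweep` -> `metrics.tsv`, `roc.tsv`,
#'   `sweep.tsv`.
#'
#' @param command one of `simulate`, `build-kg`, `train`, `predict`,
#'   `explain`, `evaluate`.
#' @param config named list (or path to a YAML file) with the fields above.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list of the artifacts written.
#' @export
run_pipeline <- function(command = c("simulate", "build-kg", "train",
                                     "predict", "explain", "evaluate"),
                         config = list(), out_dir = ".") {
  command <- match.arg(command)
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  result <- switch(command,
    "simulate" = {
      sc <- config$sim %||% list()
      if (!inherits(sc, "kgx_sim_config")) {
        if (is.null(sc$seed)) sc$seed <- seed
        sc <- do.call(sim_config, sc)
      }
      sim <- simulate_variants(sc)
      write_simulation(sim, out_dir)
      list(files = c("clinvar.tsv", "cosmic.tsv", "dbnsfp.tsv",
                     "dbscsnv.tsv", "truth.tsv"))
    },
    "build-kg" = {
      d <- load_data_dir(config$data_dir)
      kg <- records_to_kg(d$clinvar, d$cosmic, d$dbnsfp, d$dbscsnv, d$variants)
      kg_write_tsv(kg, out_dir)
      n <- write_ntriples(kg, file.path(out_dir, "graph.nt"))
      list(files = c("nodes.tsv", "edges.tsv", "graph.nt"), triples = n)
    },
    "train" = {
      d <- load_data_dir(config$data_dir)
      mode <- config$mode %||% "estimation"
      cfg <- config$classifier %||% classifier_config(seed = seed)
      ds <- assemble_dataset(d$clinvar, d$cosmic, d$dbnsfp, d$dbscsnv,
                             d$variants)
      if (mode == "estimation") {
        fgs <- lapply(ds$answers$key, build_feature_graph, kg = ds$kg,
                      mode = "estimation", index = ds$index)
        labels <- ds$answers$label
      } else {
        ans <- build_explanation_answer_set(d$clinvar, seed)
        plan <- make_mask_plan(ans$key, seed)
        fgs <- Map(function(k, m) {
          build_feature_graph(k, ds$kg, "explanation", ds$index,
                              drop_target_clinvar = (m == "drop_clinvar"))
        }, ans$key, plan$mask)
        labels <- ans$label
      }
      model <- train_classifier(fgs, labels, cfg)
      save_model(model, file.path(out_dir, "model.rds"))
      list(files = "model.rds", mode = mode, n_train = length(fgs))
    },
    "predict" = {
      d <- load_data_dir(config$data_dir)
      model <- load_model(config$model)
      ds <- assemble_dataset(d$clinvar, d$cosmic, d$dbnsfp, d$dbscsnv,
                             d$variants, balance_seed = NULL)
      keys <- config$variants %||% ds$answers$key
      fgs <- lapply(keys, build_feature_graph, kg = ds$kg, mode = model$mode,
                    index = ds$index)
      s <- predict_score(model, fgs)
      out <- tibble::tibble(key = keys, score = s, class = classify_score(s))
      data.table::fwrite(out, file.path(out_dir, "predictions.tsv"), sep = "\t")
      list(files = "predictions.tsv", n = length(keys))
    },
    "explain" = {
      d <- load_data_dir(config$data_dir)
      model <- load_model(config$model)
      if (model$mode != "explanation") {
        stop_kgx("explain requires an explanation-mode model; refusing an estimation-mode model",
                 "kgx_mode_error")
      }
      ds <- assemble_dataset(d$clinvar, d$cosmic, d$dbnsfp, d$dbscsnv,
                             d$variants, balance_seed = NULL)
      ex_cfg <- if (!is.null(config$explainer_config)) {
        load_explainer_config(config$explainer_config)
      } else {
        list(impacts = x_impacts(), rules = x_rules())
      }
      files <- character()
      for (k in config$variants) {
        ex <- explain_variant(model, k, ds$kg, ds$index,
                              rules = ex_cfg$rules, impacts = ex_cfg$impacts,
                              top_n = config$top_n %||% 10L, seed = seed)
        f <- file.path(out_dir, sprintf("explanation_%s.txt", gsub("[:>]", "_", k)))
        write_explanation(ex, f)
        files <- c(files, basename(f))
      }
      list(files = files)
    },
    "evaluate" = {
      d <- load_data_dir(config$data_dir)
      ds <- assemble_dataset(d$clinvar, d$cosmic, d$dbnsfp, d$dbscsnv,
                             d$variants, balance_seed = seed)
      folds <- chromosome_folds(ds$answers, config$folds %||% 5L, seed)
      rep <- cross_validate(
        ds, folds, model = config$model_kind %||% "graph",
        sweep = config$sweep, seed = seed,
        config = config$classifier %||% classifier_config(seed = seed)
      )
      data.table::fwrite(
        rbind(rep$per_fold, cbind(tibble::tibble(fold = NA_integer_), rep$mean)),
        file.path(out_dir, "metrics.tsv"), sep = "\t"
      )
      data.table::fwrite(
        do.call(rbind, lapply(split(rep$scores, rep$scores$fold), function(s) {
          r <- compute_metrics(s$score, s$label)$roc
          cbind(tibble::tibble(fold = s$fold[1]), r)
        })),
        file.path(out_dir, "roc.tsv"), sep = "\t"
      )
      if (!is.null(rep$sweep)) {
        data.table::fwrite(rep$sweep, file.path(out_dir, "sweep.tsv"), sep = "\t")
      }
      list(files = c("metrics.tsv", "roc.tsv"),
           mean = as.list(rep$mean))
    }
  )

  prov <- list(
    command = command, seed = seed,
    package_version = as.character(utils::packageVersion("kgxplain")),
    inputs = input_hashes(config),
    config = config_for_provenance(config),
    written = result$files
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}

load_data_dir <- function(dir) {
  if (is.null(dir) || !dir.exists(dir)) {
    stop_kgx("config$data_dir must name an existing directory", "kgx_validation_error")
  }
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop_kgx(paste("missing input:", p), "kgx_validation_error")
    p
  }
  variants <- NULL
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf)) {
    tr <- data.table::fread(tf, sep = "\t")
    pk <- parse_variant_key(tr$key)
    variants <- tibble::tibble(chrom = pk$chrom, pos = pk$pos, ref = pk$ref,
                               alt = pk$alt, gene = NA_character_,
                               consequence = NA_character_)
  }
  list(
    clinvar = load_clinvar(need("clinvar.tsv")),
    cosmic = load_cosmic(need("cosmic.tsv")),
    dbnsfp = load_dbnsfp(need("dbnsfp.tsv")),
    dbscsnv = load_dbscsnv(need("dbscsnv.tsv")),
    variants = variants
  )
}

input_hashes <- function(config) {
  paths <- character()
  if (!is.null(config$data_dir) && dir.exists(config$data_dir)) {
    paths <- list.files(config$data_dir, pattern = "\\.tsv$", full.names = TRUE)
  }
  if (!is.null(config$model) && file.exists(config$model)) {
    paths <- c(paths, config$model)
  }
  if (!length(paths)) return(list())
  h <- tools::md5sum(paths)
  as.list(setNames(unname(h), basename(paths)))
}

config_for_provenance <- function(config) {
  lapply(config, function(x) {
    if (inherits(x, "kgx_sim_config") || inherits(x, "kgx_classifier_config")) {
      x <- unclass(x)
      if (!is.null(x$coverage)) x$coverage <- as.list(x$coverage)
    }
    x
  })
}
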