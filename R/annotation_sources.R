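#' dbNSFP algorithm registry
#'
#' Pathogenicity-prediction and conservation scores are stored as rank-style
#' scores in `[0, 1]`, higher meaning more damaging. The *estimation* set is
#' the restricted whitelist allowed on the target variant when training the
#' estimation model: it contains only algorithms that are not themselves
#' trained on ClinVar labels, guarding against type-1 circularity (ensemble
#' scores such as REVEL or MetaLR encode the very labels being predicted).
#' The remaining algorithms, and the dbscSNV splice scores, are available to
#' the explanation model only.
#'
#' @format Character vectors of algorithm names.
#' @name dbnsfp_algorithms
#' @export
ESTIMATION_ALGORITHMS <- c(
  "SIFT", "LRT", "PROVEAN", "phyloP100way_vertebrate", "GERP++_RS",
  "SiPhy_29way_logOdds"
)

#' @rdname dbnsfp_algorithms
#' @export
EXPLANATION_ALGORITHMS <- c(
  "CADD", "DANN", "FATHMM", "M-CAP", "MetaLR", "MetaSVM", "MutPred",
  "MutationTaster", "Polyphen2_HDIV", "Polyphen2_HVAR", "REVEL",
  "fathmm-MKL_coding", "phastCons100way_vertebrate"
)

#' @rdname dbnsfp_algorithms
#' @export
CONSERVATION_ALGORITHMS <- c(
  "phyloP100way_vertebrate", "GERP++_RS", "SiPhy_29way_logOdds",
  "phastCons100way_vertebrate"
)

CLINICAL_SIGNIFICANCE <- c(
  "Pathogenic", "Likely_pathogenic", "Benign", "Likely_benign", "VUS"
)

#' Default ClinVar publisher vocabulary
#'
#' Closed vocabulary of publisher labels for ClinVar-linked publications,
#' used for the per-publisher publication tabulation of the flattened
#' baseline features. Configurable; any publisher outside the vocabulary is
#' tallied under `"Other"`.
#' @export
DEFAULT_PUBLISHERS <- c("Elsevier", "Springer", "Wiley", "PubMedCentral", "Other")

key_cols <- c("chrom", "pos", "ref", "alt")

read_annotation_tsv <- function(source, required) {
  dt <- data.table::fread(source, sep = "\t", header = TRUE, na.strings = "",
                          colClasses = list(character = "chrom"))
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    stop_kgx(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
             "kgx_schema_error")
  }
  dt
}

finish_load <- function(dt, reasons, source_name) {
  ok <- is.na(reasons)
  res <- list(
    records = tibble::as_tibble(dt[ok]),
    rejected = tibble::tibble(row = which(!ok), reason = reasons[!ok]),
    source = source_name
  )
  class(res) <- "kgx_load"
  res
}

#' @export
print.kgx_load <- function(x, ...) {
  cat(sprintf("<kgx_load:%s> %d record(s), %d rejected\n",
              x$source, nrow(x$records), nrow(x$rejected)))
  if (nrow(x$rejected)) {
    for (i in seq_len(min(5, nrow(x$rejected)))) {
      cat(sprintf("  row %d: %s\n", x$rejected$row[i], x$rejected$reason[i]))
    }
  }
  invisible(x)
}

#' Extract the records tibble from a loader result
#' @param x a `kgx_load` or a records tibble/data.frame.
#' @return a tibble of records.
#' @export
as_records <- function(x) {
  if (inherits(x, "kgx_load")) x$records else tibble::as_tibble(x)
}

validate_keys <- function(dt) {
  reasons <- rep(NA_character_, nrow(dt))
  bad_pos <- is.na(dt$pos) | dt$pos < 1 | dt$pos != floor(dt$pos)
  reasons[bad_pos] <- "pos must be an integer >= 1"
  bad_allele <- !grepl("^[ACGTacgt]+$", dt$ref) | !grepl("^[ACGTacgt]+$", dt$alt)
  reasons[is.na(reasons) & bad_allele] <- "ref/alt must be ACGT strings"
  reasons
}

#' Load simplified annotation tables
#'
#' Readers for the four tab-separated annotation schemas. All share the
#' variant key columns `chrom, pos, ref, alt`. Every input row yields exactly
#' one record or a rejection with a reason; rejected rows are reported in the
#' result and by `print()`.
#'
#' * `clinvar.tsv`: `gene, consequence, clinical_significance` (one of
#'   Pathogenic, Likely_pathogenic, Benign, Likely_benign, VUS),
#'   `review_stars` (0-4), `last_update_year`, `n_submissions` (>= 1), and
#'   `publications` as `pmid:publisher` pairs joined by `|` (may be empty).
#' * `cosmic.tsv`: `gene, protein_change` (HGVS-p-like, `*` allowed),
#'   `sample_count` (>= 1), `publications` as pmids joined by `|`.
#' * `dbnsfp.tsv`: one column per algorithm, each a score in `[0, 1]`
#'   (missing scores empty).
#' * `dbscsnv.tsv`: `ada_score, rf_score` in `[0, 1]`.
#'
#' @param source path to a TSV file (or anything [data.table::fread()]
#'   accepts as `input`).
#' @return a `kgx_load` list with elements `records` (tibble), `rejected`
#'   (tibble of row/reason) and `source`.
#' @export
load_clinvar <- function(source) {
  dt <- read_annotation_tsv(source, c(
    key_cols, "gene", "consequence", "clinical_significance", "review_stars",
    "last_update_year", "n_submissions", "publications"
  ))
  reasons <- validate_keys(dt)
  if (nrow(dt)) {
    bad <- !dt$clinical_significance %in% CLINICAL_SIGNIFICANCE
    reasons[is.na(reasons) & bad] <- "unknown clinical_significance"
    bad <- is.na(dt$review_stars) | dt$review_stars < 0 | dt$review_stars > 4
    reasons[is.na(reasons) & bad] <- "review_stars outside [0, 4]"
    bad <- is.na(dt$n_submissions) | dt$n_submissions < 1
    reasons[is.na(reasons) & bad] <- "n_submissions must be >= 1"
  }
  dt$publications[is.na(dt$publications)] <- ""
  finish_load(dt, reasons, "clinvar")
}

#' @rdname load_clinvar
#' @export
load_cosmic <- function(source) {
  dt <- read_annotation_tsv(source, c(
    key_cols, "gene", "protein_change", "sample_count", "publications"
  ))
  reasons <- validate_keys(dt)
  if (nrow(dt)) {
    bad <- is.na(dt$sample_count) | dt$sample_count < 1
    reasons[is.na(reasons) & bad] <- "sample_count must be >= 1"
  }
  dt$publications[is.na(dt$publications)] <- ""
  finish_load(dt, reasons, "cosmic")
}

#' @rdname load_clinvar
#' @export
load_dbnsfp <- function(source) {
  dt <- read_annotation_tsv(source, key_cols)
  algos <- setdiff(names(dt), key_cols)
  reasons <- validate_keys(dt)
  if (nrow(dt)) {
    for (a in algos) {
      v <- dt[[a]]
      bad <- !is.na(v) & (v < 0 | v > 1)
      reasons[is.na(reasons) & bad] <- sprintf("score '%s' outside [0, 1]", a)
    }
  }
  finish_load(dt, reasons, "dbnsfp")
}

#' @rdname load_clinvar
#' @export
load_dbscsnv <- function(source) {
  dt <- read_annotation_tsv(source, c(key_cols, "ada_score", "rf_score"))
  reasons <- validate_keys(dt)
  if (nrow(dt)) {
    for (a in c("ada_score", "rf_score")) {
      v <- dt[[a]]
      bad <- !is.na(v) & (v < 0 | v > 1)
      reasons[is.na(reasons) & bad] <- sprintf("%s outside [0, 1]", a)
    }
  }
  finish_load(dt, reasons, "dbscsnv")
}

# split "pmid:publisher|pmid:publisher" -> data.table(pmid, publisher)
split_clinvar_pubs <- function(pubs) {
  lapply(pubs, function(p) {
    if (is.na(p) || !nzchar(p)) {
      return(data.table::data.table(pmid = character(), publisher = character()))
    }
    parts <- strsplit(strsplit(p, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.table::data.table(
      pmid = vapply(parts, `[`, character(1), 1),
      publisher = vapply(parts, function(x) if (length(x) > 1) x[2] else "Other",
                         character(1))
    )
  })
}

split_cosmic_pubs <- function(pubs) {
  lapply(pubs, function(p) {
    if (is.na(p) || !nzchar(p)) character() else strsplit(p, "|", fixed = TRUE)[[1]]
  })
}

node_dt <- function(node_id, node_type, value = NA_character_, source_db) {
  data.table::data.table(
    node_id = node_id, node_type = node_type,
    value = as.character(value), source_db = source_db
  )
}

edge_dt <- function(subject, predicate, object) {
  data.table::data.table(subject = subject, predicate = predicate, object = object)
}

literal_children <- function(rec_id, fields, db) {
  # one literal child node per (record, field); values already character
  keep <- !is.na(unlist(fields, use.names = FALSE))
  f <- names(fields)
  out_n <- list(); out_e <- list()
  for (j in seq_along(fields)) {
    v <- fields[[j]]
    ok <- !is.na(v)
    if (!any(ok)) next
    lid <- paste0(rec_id[ok], "/", f[j])
    out_n[[j]] <- node_dt(lid, "literal_value", v[ok], "none")
    out_e[[j]] <- edge_dt(rec_id[ok], f[j], lid)
  }
  list(nodes = data.table::rbindlist(out_n), edges = data.table::rbindlist(out_e))
}

#' Assemble the annotation knowledge graph
#'
#' Converts validated annotation records into a single knowledge graph: one
#' record node per input record with literal child nodes for each field,
#' every record node attached to its variant hub, gene hubs attached to
#' variant hubs. Records about the same variant from different sources share
#' one hub, which is what lets the downstream feature subgraphs join the
#' databases. Deterministic for a fixed input order.
#'
#' @param clinvar,cosmic,dbnsfp,dbscsnv loader results ([load_clinvar()] and
#'   friends) or record tibbles; any may be `NULL`.
#' @param variants optional tibble (`chrom, pos, ref, alt, gene, consequence`)
#'   declaring the variant universe; adds a consequence literal on each
#'   variant hub so that unannotated variants still carry their variant type.
#' @return a `kgx_graph`.
#' @export
records_to_kg <- function(clinvar = NULL, cosmic = NULL, dbnsfp = NULL,
                          dbscsnv = NULL, variants = NULL) {
  nodes <- list(); edges <- list()
  add <- function(x) {
    nodes[[length(nodes) + 1L]] <<- x$nodes
    edges[[length(edges) + 1L]] <<- x$edges
  }
  hub_nodes <- function(keys, genes = NULL) {
    vh <- paste0("variant:", keys)
    out <- list(nodes = node_dt(vh, "variant_hub", NA, "hub"),
                edges = edge_dt(character(), character(), character()))
    if (!is.null(genes)) {
      ok <- !is.na(genes) & nzchar(genes)
      if (any(ok)) {
        gh <- paste0("gene:", genes[ok])
        out$nodes <- rbind(out$nodes, node_dt(gh, "gene_hub", NA, "hub"))
        out$edges <- edge_dt(vh[ok], "in_gene", gh)
      }
    }
    out
  }

  if (!is.null(variants)) {
    v <- as_records(variants)
    keys <- canonical_variant_key(v$chrom, v$pos, v$ref, v$alt)
    add(hub_nodes(keys, if ("gene" %in% names(v)) v$gene))
    if ("consequence" %in% names(v) && any(!is.na(v$consequence))) {
      ok <- !is.na(v$consequence)
      lid <- paste0("variant:", keys[ok], "/consequence")
      add(list(
        nodes = node_dt(lid, "literal_value", v$consequence[ok], "none"),
        edges = edge_dt(paste0("variant:", keys[ok]), "consequence", lid)
      ))
    }
  }

  cv <- if (!is.null(clinvar)) as_records(clinvar) else NULL
  if (!is.null(cv) && nrow(cv)) {
    keys <- canonical_variant_key(cv$chrom, cv$pos, cv$ref, cv$alt)
    rid <- sprintf("clinvar:%s#%d", keys, seq_len(nrow(cv)))
    add(hub_nodes(keys, cv$gene))
    add(list(nodes = node_dt(rid, "clinvar_record", NA, "clinvar"),
             edges = edge_dt(rid, "describes_variant", paste0("variant:", keys))))
    add(literal_children(rid, list(
      clinical_significance = cv$clinical_significance,
      review_stars = as.character(cv$review_stars),
      last_update_year = as.character(cv$last_update_year),
      n_submissions = as.character(cv$n_submissions),
      consequence = cv$consequence
    ), "clinvar"))
    pubs <- split_clinvar_pubs(cv$publications)
    np <- vapply(pubs, nrow, integer(1))
    if (any(np > 0)) {
      pub <- data.table::rbindlist(pubs)
      owner <- rep(rid, np)
      pid <- paste0(owner, "/pub/", pub$pmid)
      add(list(nodes = node_dt(pid, "publication", pub$pmid, "clinvar"),
               edges = edge_dt(owner, "has_publication", pid)))
      lid <- paste0(pid, "/publisher")
      add(list(nodes = node_dt(lid, "literal_value", pub$publisher, "none"),
               edges = edge_dt(pid, "publisher", lid)))
    }
  }

  co <- if (!is.null(cosmic)) as_records(cosmic) else NULL
  if (!is.null(co) && nrow(co)) {
    keys <- canonical_variant_key(co$chrom, co$pos, co$ref, co$alt)
    rid <- sprintf("cosmic:%s#%d", keys, seq_len(nrow(co)))
    add(hub_nodes(keys, co$gene))
    add(list(nodes = node_dt(rid, "cosmic_record", NA, "cosmic"),
             edges = edge_dt(rid, "describes_variant", paste0("variant:", keys))))
    add(literal_children(rid, list(
      protein_change = co$protein_change,
      sample_count = as.character(co$sample_count)
    ), "cosmic"))
    pubs <- split_cosmic_pubs(co$publications)
    np <- lengths(pubs)
    if (any(np > 0)) {
      owner <- rep(rid, np)
      pmid <- unlist(pubs, use.names = FALSE)
      pid <- paste0(owner, "/pub/", pmid)
      add(list(nodes = node_dt(pid, "publication", pmid, "cosmic"),
               edges = edge_dt(owner, "has_publication", pid)))
    }
  }

  db <- if (!is.null(dbnsfp)) as_records(dbnsfp) else NULL
  if (!is.null(db) && nrow(db)) {
    keys <- canonical_variant_key(db$chrom, db$pos, db$ref, db$alt)
    rid <- paste0("dbnsfp:", keys)
    add(hub_nodes(keys))
    add(list(nodes = node_dt(rid, "dbnsfp_record", NA, "dbnsfp"),
             edges = edge_dt(rid, "describes_variant", paste0("variant:", keys))))
    for (a in setdiff(names(db), key_cols)) {
      v <- db[[a]]
      ok <- !is.na(v)
      if (!any(ok)) next
      sid <- paste0(rid[ok], "/score/", a)
      add(list(
        nodes = node_dt(sid, "dbnsfp_score", format_payload(v[ok]), "dbnsfp"),
        edges = edge_dt(rid[ok], paste0("score:", a), sid)
      ))
    }
  }

  ds <- if (!is.null(dbscsnv)) as_records(dbscsnv) else NULL
  if (!is.null(ds) && nrow(ds)) {
    keys <- canonical_variant_key(ds$chrom, ds$pos, ds$ref, ds$alt)
    rid <- paste0("dbscsnv:", keys)
    add(hub_nodes(keys))
    add(list(nodes = node_dt(rid, "dbscsnv_record", NA, "dbscsnv"),
             edges = edge_dt(rid, "describes_variant", paste0("variant:", keys))))
    add(literal_children(rid, list(
      ada_score = format_payload(ds$ada_score),
      rf_score = format_payload(ds$rf_score)
    ), "dbscsnv"))
  }

  g <- kg_new()
  nd <- unique(data.table::rbindlist(nodes))
  if (anyDuplicated(nd$node_id)) {
    stop_kgx("conflicting node definitions for the same node_id",
             "kgx_integrity_error")
  }
  g$nodes <- nd
  g$edges <- unique(data.table::rbindlist(edges))
  rebuild_hub_index(g)
  g
}
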