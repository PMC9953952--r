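#' Variant position index
#'
#' Builds the per-chromosome position index of all known variants, used for
#' the 100-base neighbor expansion. Any number of record tables (or loader
#' results) sharing the key columns `chrom, pos, ref, alt` can be combined;
#' the union of their variants is indexed.
#'
#' @param ... record tibbles or `kgx_load` results.
#' @return a data.table with columns `key, chrom, pos`, sorted by
#'   chromosome and position.
#' @export
variant_index <- function(...) {
  parts <- lapply(list(...), function(x) {
    r <- as_records(x)
    dt <- data.table::data.table(
      k = canonical_variant_key(r$chrom, r$pos, r$ref, r$alt),
      chrom = sub("^chr", "", as.character(r$chrom)),
      pos = as.integer(r$pos)
    )
    data.table::setnames(dt, "k", "key")
  })
  idx <- unique(data.table::rbindlist(parts))
  data.table::setkeyv(idx, c("chrom", "pos"))
  idx[]
}

#' Neighboring variants within a window
#'
#' Returns all known variants on the same chromosome whose position lies
#' within `window` bases of the target (inclusive; distance 100 counts),
#' sorted by ascending distance. The target itself is excluded, but a variant
#' at the same position with a different allele is a neighbor at distance 0.
#' For insertions/deletions the leftmost reference position is used.
#'
#' @param target canonical variant key.
#' @param index a [variant_index()].
#' @param window window size in bases (default 100).
#' @return tibble with columns `key`, `distance`.
#' @export
neighbors_within <- function(target, index, window = 100L) {
  i <- match(target, index$key)
  if (is.na(i)) stop_kgx(sprintf("target '%s' not in index", target),
                         "kgx_lookup_error")
  tc <- index$chrom[i]; tp <- index$pos[i]
  hit <- index[index$chrom == tc & abs(index$pos - tp) <= window &
                 index$key != target, ]
  d <- abs(hit$pos - tp)
  o <- order(d, hit$key)
  tibble::tibble(key = hit$key[o], distance = as.integer(d[o]))
}

#' ClinVar half-masking plan for explanation training
#'
#' When training the explanation model, exactly half (floor) of the training
#' variants have their own ClinVar records withheld, so that the model also
#' learns to explain variants that are absent from ClinVar rather than
#' parroting the recorded significance.
#'
#' @param variants character vector of variant keys (>= 2).
#' @param seed integer seed; the plan is reproducible.
#' @return tibble with columns `key`, `mask` (`"keep_clinvar"` or
#'   `"drop_clinvar"`).
#' @export
make_mask_plan <- function(variants, seed) {
  if (is.data.frame(variants)) variants <- variants$key
  n <- length(variants)
  if (n < 2) stop_kgx("need at least 2 variants", "kgx_validation_error")
  drop <- with_seed(seed, sample(n, floor(n / 2)))
  tibble::tibble(
    key = variants,
    mask = ifelse(seq_len(n) %in% drop, "drop_clinvar", "keep_clinvar")
  )
}

# adjacency cache: environments mapping subject -> edge row indices and
# hub -> record rows, built once per graph and reused across subgraph builds
kg_cache <- function(kg) {
  if (is.null(kg$.cache)) {
    ed <- kg$edges
    out_idx <- new.env(parent = emptyenv(), hash = TRUE)
    sp <- split(seq_len(nrow(ed)), ed$subject)
    for (s in names(sp)) assign(s, sp[[s]], envir = out_idx)
    rec <- ed[ed$predicate == "describes_variant", ]
    ntype <- kg$nodes$node_type
    names(ntype) <- kg$nodes$node_id
    rec_idx <- new.env(parent = emptyenv(), hash = TRUE)
    rp <- split(seq_len(nrow(rec)), rec$object)
    for (h in names(rp)) assign(h, rp[[h]], envir = rec_idx)
    node_row <- new.env(parent = emptyenv(), hash = TRUE)
    kg$.cache <- list(
      edges = ed,
      records = data.table::data.table(rec = rec$subject, hub = rec$object,
                                       rec_type = unname(ntype[rec$subject])),
      out_idx = out_idx, rec_idx = rec_idx, node_type = ntype
    )
  }
  kg$.cache
}

env_rows <- function(env, keys) {
  if (!length(keys)) return(integer())
  out <- unlist(lapply(keys, function(k) env[[k]]), use.names = FALSE)
  if (is.null(out)) integer() else out
}

#' Build the per-variant feature subgraph
#'
#' Extracts the subgraph fed to the classifier for one target variant, in
#' *estimation* or *explanation* mode, including the annotation records of all
#' neighboring variants within `window` bases and explicit neighbor links
#' carrying the base-pair distance.
#'
#' Mode controls the target's own features only (neighbor ClinVar/COSMIC
#' records are legitimate estimation features in both modes):
#'
#' * `estimation`: the target's ClinVar and dbscSNV records are excluded
#'   (label leakage and splice-only evidence), and its dbNSFP scores are
#'   restricted to the non-circular [ESTIMATION_ALGORITHMS].
#' * `explanation`: all target records are included (unless
#'   `drop_target_clinvar`, used by the half-masking scheme of
#'   [make_mask_plan()]).
#'
#' @param target canonical variant key, present in the graph's hub index.
#' @param kg the integrated `kgx_graph`.
#' @param mode `"estimation"` or `"explanation"`.
#' @param index a [variant_index()] covering the variant universe.
#' @param drop_target_clinvar drop the target's ClinVar records even in
#'   explanation mode.
#' @param window neighbor window in bases.
#' @return a `kgx_feature_graph`: list with `target`, `mode`, `nodes`,
#'   `edges`, `neighbor_links` (key, distance, hub).
#' @export
build_feature_graph <- function(target, kg, mode = c("estimation", "explanation"),
                                index, drop_target_clinvar = FALSE,
                                window = 100L) {
  mode <- match.arg(mode)
  hub <- kg$hub_index[[hub_index_key(target, "variant")]]
  if (is.null(hub)) stop_kgx(sprintf("unknown target '%s'", target),
                             "kgx_lookup_error")
  cache <- kg_cache(kg)
  ed <- cache$edges
  rbh <- cache$records

  # index vectors are computed outside `[` on purpose: data.table's i-scope
  # would resolve names like `hub` to columns of the table being subset
  ti <- env_rows(cache$rec_idx, hub)
  target_recs <- rbh[ti, ]
  drop_types <- if (mode == "estimation" || drop_target_clinvar) "clinvar_record" else character()
  if (mode == "estimation") drop_types <- c(drop_types, "dbscsnv_record")
  target_recs <- target_recs[!target_recs$rec_type %in% drop_types, ]

  nb <- neighbors_within(target, index, window)
  nb_hub <- paste0("variant:", nb$key)
  ni <- env_rows(cache$rec_idx, nb_hub)
  nb_recs <- rbh[ni, ]
  nb_recs <- nb_recs[nb_recs$rec_type %in% c("clinvar_record", "cosmic_record"), ]

  recs <- rbind(target_recs, nb_recs)
  # record -> child edges, plus one more hop (publications -> publisher)
  l1i <- env_rows(cache$out_idx, recs$rec)
  lvl1 <- ed[l1i, ]
  if (mode == "estimation" && nrow(lvl1)) {
    tgt_dbnsfp <- target_recs$rec[target_recs$rec_type == "dbnsfp_record"]
    allowed <- paste0("score:", ESTIMATION_ALGORITHMS)
    bad <- lvl1$subject %in% tgt_dbnsfp & startsWith(lvl1$predicate, "score:") &
      !lvl1$predicate %in% allowed
    lvl1 <- lvl1[!bad, ]
  }
  kids <- setdiff(lvl1$object, c(hub, nb_hub))
  l2i <- env_rows(cache$out_idx, kids)
  lvl2 <- ed[l2i, ]

  hi <- env_rows(cache$out_idx, c(hub, nb_hub))
  hub_edges <- ed[hi, ]
  hub_edges <- hub_edges[hub_edges$predicate %in% c("in_gene", "consequence"), ]

  nb_present <- vapply(nb$key, function(kk) {
    !is.null(kg$hub_index[[hub_index_key(kk, "variant")]])
  }, logical(1), USE.NAMES = FALSE)
  nbl <- data.table::setnames(data.table::data.table(
    k = nb$key, distance = nb$distance, hub = nb_hub
  ), "k", "key")[nb_present, ]
  nb_edges <- if (nrow(nbl)) {
    edge_dt(hub, "neighbor", nbl$hub)
  } else {
    edge_dt(character(), character(), character())
  }

  edges <- unique(rbind(
    lvl1[, c("subject", "predicate", "object")],
    lvl2[, c("subject", "predicate", "object")],
    hub_edges[, c("subject", "predicate", "object")],
    nb_edges
  ))
  node_ids <- unique(c(hub, nbl$hub, edges$subject, edges$object))
  nodes <- kg$nodes[kg$nodes$node_id %in% node_ids, ]

  structure(list(
    target = target, mode = mode, target_hub = hub,
    nodes = nodes, edges = edges, neighbor_links = nbl
  ), class = "kgx_feature_graph")
}

#' @export
print.kgx_feature_graph <- function(x, ...) {
  cat(sprintf("<kgx_feature_graph:%s> target %s: %d nodes, %d edges, %d neighbor(s)\n",
              x$mode, x$target, nrow(x$nodes), nrow(x$edges), nrow(x$neighbor_links)))
  invisible(x)
}

#' Serialize a feature graph to TSV
#'
#' Same two-file nodes/edges dialect as [kg_write_tsv()], plus a `meta.tsv`
#' carrying the target key and mode tag, and the neighbor links with their
#' distances.
#'
#' @param fg a `kgx_feature_graph`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
fg_write_tsv <- function(fg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(fg$nodes, file.path(dir, "nodes.tsv"), sep = "\t")
  data.table::fwrite(fg$edges, file.path(dir, "edges.tsv"), sep = "\t")
  data.table::fwrite(fg$neighbor_links, file.path(dir, "neighbor_links.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(target = fg$target, mode = fg$mode),
    file.path(dir, "meta.tsv"), sep = "\t"
  )
  invisible(dir)
}
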