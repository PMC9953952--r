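#' Annotation knowledge graphs
#'
#' A `kgx_graph` is a typed directed multigraph with per-database provenance,
#' the container that integrates ClinVar-, COSMIC-, dbNSFP- and dbscSNV-style
#' annotation records. Every annotation record node is attached to a canonical
#' *hub node* for its variant (and gene hubs are attached to variant hubs), so
#' that records about the same variant from different databases join through a
#' single node. Triples (subject, predicate, object) are stored with set
#' semantics: re-adding an existing triple is a no-op.
#'
#' The object has reference semantics (it is an environment, like a database
#' handle): `get_or_create_hub()` and `attach_record()` modify it in place.
#'
#' @param x a `kgx_graph`.
#' @name kgx_graph
NULL

NODE_TYPES <- c(
  "variant_hub", "gene_hub", "clinvar_record", "cosmic_record",
  "dbnsfp_record", "dbnsfp_score", "dbscsnv_record", "publication",
  "literal_value"
)
SOURCE_DBS <- c("clinvar", "cosmic", "dbnsfp", "dbscsnv", "hub", "none")

#' Create an empty knowledge graph
#'
#' @return an empty `kgx_graph`.
#' @export
#' @examples
#' kg <- kg_new()
#' kg_n_nodes(kg)
kg_new <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- data.table::data.table(
    node_id = character(), node_type = character(),
    value = character(), source_db = character()
  )
  g$edges <- data.table::data.table(
    subject = character(), predicate = character(), object = character()
  )
  g$hub_index <- new.env(parent = emptyenv())
  class(g) <- "kgx_graph"
  g
}

#' @rdname kgx_graph
#' @export
kg_n_nodes <- function(x) nrow(x$nodes)

#' @rdname kgx_graph
#' @export
kg_n_edges <- function(x) nrow(x$edges)

#' @rdname kgx_graph
#' @export
kg_nodes <- function(x) data.table::copy(x$nodes)

#' @rdname kgx_graph
#' @export
kg_edges <- function(x) data.table::copy(x$edges)

#' @export
print.kgx_graph <- function(x, ...) {
  hubs <- sum(x$nodes$source_db == "hub")
  cat(sprintf(
    "<kgx_graph> %d nodes (%d hubs), %d triples\n",
    kg_n_nodes(x), hubs, kg_n_edges(x)
  ))
  invisible(x)
}

#' Canonical variant key
#'
#' Builds the canonical string key `"chrom:pos:ref>alt"` under which a variant
#' is indexed across all annotation sources. Positions are 1-based and fully
#' closed (the ClinVar/VCF convention); chromosome labels are stored without a
#' `"chr"` prefix and alleles are normalized to uppercase.
#'
#' @param chrom chromosome label (e.g. `"17"`, `"X"`; a leading `"chr"` is
#'   stripped).
#' @param pos 1-based integer position, `>= 1`.
#' @param ref,alt nonempty `ACGT` allele strings (case-insensitive).
#' @return character vector of keys.
#' @export
#' @examples
#' canonical_variant_key("17", 7579472, "G", "C")
canonical_variant_key <- function(chrom, pos, ref, alt) {
  chrom <- sub("^chr", "", as.character(chrom))
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(is.na(pos)) || any(pos < 1) || any(pos != floor(pos))) {
    stop_kgx("pos must be an integer >= 1", "kgx_validation_error")
  }
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt))) {
    stop_kgx("ref/alt must be nonempty ACGT strings", "kgx_validation_error")
  }
  sprintf("%s:%d:%s>%s", chrom, as.integer(pos), ref, alt)
}

# parse "chrom:pos:ref>alt" back into its fields
parse_variant_key <- function(key) {
  m <- regmatches(key, regexec("^([^:]+):([0-9]+):([ACGT]+)>([ACGT]+)$", key))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop_kgx("malformed variant key", "kgx_validation_error")
  data.table::setnames(data.table::data.table(
    k = key,
    chrom = vapply(m, `[`, character(1), 2),
    pos = as.integer(vapply(m, `[`, character(1), 3)),
    ref = vapply(m, `[`, character(1), 4),
    alt = vapply(m, `[`, character(1), 5)
  ), "k", "key")
}

hub_index_key <- function(key, kind) paste0(kind, "|", key)

#' Add a node to a knowledge graph
#'
#' Low-level constructor used by [records_to_kg()]. Adding an existing
#' `node_id` with identical fields is a no-op; with conflicting fields it is
#' an error.
#'
#' @param graph a `kgx_graph`.
#' @param node_id unique node identifier.
#' @param node_type one of the registered ontology class labels.
#' @param value optional scalar payload (stored as character).
#' @param source_db provenance tag.
#' @return `node_id`, invisibly.
#' @export
kg_add_node <- function(graph, node_id, node_type,
                        value = NA_character_, source_db = "none") {
  stopifnot(inherits(graph, "kgx_graph"))
  if (!node_type %in% NODE_TYPES) {
    stop_kgx(sprintf("unknown node_type '%s'", node_type), "kgx_validation_error")
  }
  if (!source_db %in% SOURCE_DBS) {
    stop_kgx(sprintf("unknown source_db '%s'", source_db), "kgx_validation_error")
  }
  i <- match(node_id, graph$nodes$node_id)
  if (!is.na(i)) {
    old <- graph$nodes[i]
    if (old$node_type != node_type || old$source_db != source_db ||
        !identical(old$value, as.character(value))) {
      stop_kgx(sprintf("node '%s' already exists with different fields", node_id),
               "kgx_integrity_error")
    }
    return(invisible(node_id))
  }
  graph$nodes <- rbind(graph$nodes, data.table::data.table(
    node_id = node_id, node_type = node_type,
    value = as.character(value), source_db = source_db
  ))
  invisible(node_id)
}

kg_add_edges <- function(graph, subject, predicate, object) {
  new <- data.table::data.table(
    subject = subject, predicate = predicate, object = object
  )
  all <- unique(rbind(graph$edges, new))
  graph$edges <- all
  graph$.cache <- NULL
  invisible(graph)
}

#' Get or create a hub node
#'
#' Returns the canonical hub node for a variant key or gene symbol, creating
#' it if absent. Idempotent: a second call with the same key returns the same
#' node id and adds nothing.
#'
#' @param graph a `kgx_graph` (modified in place).
#' @param key canonical variant key (see [canonical_variant_key()]) or gene
#'   symbol.
#' @param kind `"variant"` or `"gene"`.
#' @return the hub `node_id`.
#' @export
get_or_create_hub <- function(graph, key, kind = c("variant", "gene")) {
  kind <- match.arg(kind)
  ik <- hub_index_key(key, kind)
  hit <- graph$hub_index[[ik]]
  if (!is.null(hit)) return(hit)
  node_id <- paste0(kind, ":", key)
  kg_add_node(graph, node_id,
              node_type = paste0(kind, "_hub"), source_db = "hub")
  assign(ik, node_id, envir = graph$hub_index)
  node_id
}

#' Attach a record node to its hub
#'
#' Adds the triple `(record, predicate, hub)`. A record may be attached to at
#' most one variant hub and one gene hub; attempting to re-attach it to a
#' different hub of the same kind is an integrity error. Re-adding the same
#' triple is a no-op.
#'
#' @param graph a `kgx_graph` (modified in place).
#' @param record_node node id of an annotation record already in the graph.
#' @param hub node id of an existing hub node.
#' @param predicate edge label, default `"describes_variant"`.
#' @return invisibly, the graph.
#' @export
attach_record <- function(graph, record_node, hub,
                          predicate = "describes_variant") {
  j <- match(hub, graph$nodes$node_id)
  if (is.na(j) || graph$nodes$source_db[j] != "hub") {
    stop_kgx("hub node not found", "kgx_lookup_error")
  }
  if (is.na(match(record_node, graph$nodes$node_id))) {
    stop_kgx("record node not found", "kgx_lookup_error")
  }
  hub_kind <- graph$nodes$node_type[j]
  e <- graph$edges[graph$edges$subject == record_node, ]
  if (nrow(e)) {
    tgt_types <- graph$nodes$node_type[match(e$object, graph$nodes$node_id)]
    prior <- e$object[tgt_types == hub_kind]
    if (length(prior) && any(prior != hub)) {
      stop_kgx(sprintf(
        "record '%s' is already attached to a different %s", record_node, hub_kind
      ), "kgx_integrity_error")
    }
  }
  kg_add_edges(graph, record_node, predicate, hub)
  invisible(graph)
}

#' Reachable subgraph of a node
#'
#' Closure of nodes reachable from `start`. Edges are followed in their stored
#' direction, except when the frontier node is a hub: hubs are crossed
#' ignoring direction (record -> hub -> record), so that records about
#' neighboring variants, which sit on the far side of their hub, are reached.
#' This is the subgraph of everything directly or indirectly referenced by a
#' variant, used as the explanation subgraph.
#'
#' @param graph a `kgx_graph`.
#' @param start node id; included in the result.
#' @return a new `kgx_graph` restricted to the reachable closure.
#' @export
reachable_subgraph <- function(graph, start) {
  if (is.na(match(start, graph$nodes$node_id))) {
    stop_kgx(sprintf("unknown start node '%s'", start), "kgx_lookup_error")
  }
  ed <- graph$edges
  is_hub <- graph$nodes$source_db == "hub"
  hub_ids <- graph$nodes$node_id[is_hub]
  seen <- start
  frontier <- start
  while (length(frontier)) {
    out <- ed$object[ed$subject %in% frontier]
    hub_frontier <- intersect(frontier, hub_ids)
    inn <- if (length(hub_frontier)) ed$subject[ed$object %in% hub_frontier] else character()
    nxt <- setdiff(unique(c(out, inn)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sub <- kg_new()
  sub$nodes <- graph$nodes[graph$nodes$node_id %in% seen]
  sub$edges <- ed[ed$subject %in% seen & ed$object %in% seen]
  for (ik in ls(graph$hub_index)) {
    id <- graph$hub_index[[ik]]
    if (id %in% seen) assign(ik, id, envir = sub$hub_index)
  }
  sub
}

#' Write / read a knowledge graph as two TSV files
#'
#' `nodes.tsv` holds `node_id, node_type, value, source_db`; `edges.tsv` holds
#' `subject, predicate, object`.
#'
#' @param graph a `kgx_graph`.
#' @param dir directory (created if needed).
#' @return `kg_write_tsv`: invisibly, the directory; `kg_read_tsv`: a
#'   `kgx_graph`.
#' @export
kg_write_tsv <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(graph$nodes, file.path(dir, "nodes.tsv"), sep = "\t")
  data.table::fwrite(graph$edges, file.path(dir, "edges.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname kg_write_tsv
#' @export
kg_read_tsv <- function(dir) {
  g <- kg_new()
  g$nodes <- data.table::fread(
    file.path(dir, "nodes.tsv"),
    sep = "\t", colClasses = "character", na.strings = ""
  )
  g$edges <- data.table::fread(
    file.path(dir, "edges.tsv"),
    sep = "\t", colClasses = "character", na.strings = ""
  )
  rebuild_hub_index(g)
  g
}

rebuild_hub_index <- function(g) {
  hubs <- g$nodes[g$nodes$source_db == "hub", ]
  if (nrow(hubs)) {
    kind <- sub("_hub$", "", hubs$node_type)
    key <- substring(hubs$node_id, nchar(kind) + 2L)
    for (i in seq_len(nrow(hubs))) {
      assign(hub_index_key(key[i], kind[i]), hubs$node_id[i], envir = g$hub_index)
    }
  }
  invisible(g)
}
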