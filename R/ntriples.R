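#' N-Triples serialization
#'
#' A `kgx_graph` serializes to RDF-style N-Triples, one `(subject, predicate,
#' object)` triple per line. Non-literal nodes become IRIs under the project
#' namespace `urn:kgx:` carrying the node id, type, provenance and payload as
#' percent-encoded query fields, so a round trip preserves every node payload
#' exactly. Leaf nodes of type `literal_value` serialize as plain RDF string
#' literals; on read they are re-created with ids synthesized from
#' `subject/predicate`, which reproduces the original graph up to isomorphism
#' provided each literal node has exactly one incoming edge (the convention
#' used by [records_to_kg()]).
#'
#' Isolated nodes do not appear in any triple and are therefore not preserved;
#' serialize graphs with isolated nodes via [kg_write_tsv()] instead.
#'
#' @param graph a `kgx_graph`.
#' @param path file path to write to / read from.
#' @return `write_ntriples`: the number of triples written (equal to the edge
#'   multiset size). `read_ntriples`: a `kgx_graph`.
#' @export
write_ntriples <- function(graph, path) {
  nd <- graph$nodes
  ed <- graph$edges
  iri_of <- function(ids) {
    i <- match(ids, nd$node_id)
    v <- nd$value[i]
    q <- paste0(
      "id=", enc(ids), "&t=", enc(nd$node_type[i]), "&db=", enc(nd$source_db[i]),
      ifelse(is.na(v), "", paste0("&v=", enc(v)))
    )
    paste0("<urn:kgx:n?", q, ">")
  }
  term_of <- function(ids) {
    i <- match(ids, nd$node_id)
    lit <- nd$node_type[i] == "literal_value"
    out <- character(length(ids))
    if (any(!lit)) out[!lit] <- iri_of(ids[!lit])
    if (any(lit)) {
      out[lit] <- paste0("\"", escape_lit(ifelse(
        is.na(nd$value[i][lit]), "", nd$value[i][lit]
      )), "\"")
    }
    out
  }
  lines <- if (nrow(ed)) {
    paste(iri_of(ed$subject), paste0("<urn:kgx:p:", enc(ed$predicate), ">"),
          term_of(ed$object), ".")
  } else {
    character()
  }
  writeLines(lines, path)
  invisible(length(lines))
}

enc <- function(x) {
  vapply(x, URLencode, character(1), reserved = TRUE, USE.NAMES = FALSE)
}

escape_lit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_lit <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

decode_iri <- function(iri) {
  # urn:kgx:n?id=...&t=...&db=...[&v=...]
  q <- sub("^urn:kgx:n\\?", "", iri)
  parts <- strsplit(q, "&", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- list()
  for (p in kv) out[[p[1]]] <- URLdecode(if (length(p) > 1) p[2] else "")
  out
}

#' @rdname write_ntriples
#' @export
read_ntriples <- function(path) {
  lines <- readLines(path)
  g <- kg_new()
  pat <- paste0(
    "^<(urn:kgx:n\\?[^>]*)> <urn:kgx:p:([^>]*)> ",
    "(?:<(urn:kgx:n\\?[^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\") \\.\\s*$"
  )
  keep <- nzchar(trimws(lines))
  nodes <- new.env(parent = emptyenv())
  subs <- character(); preds <- character(); objs <- character()
  ensure_node <- function(info) {
    if (is.null(nodes[[info$id]])) {
      nodes[[info$id]] <- list(
        node_type = info$t, source_db = info$db,
        value = if (is.null(info$v)) NA_character_ else info$v
      )
    }
    info$id
  }
  for (ln in which(keep)) {
    m <- regmatches(lines[ln], regexec(pat, lines[ln], perl = TRUE))[[1]]
    if (!length(m)) {
      stop_kgx(sprintf("malformed N-Triples line %d", ln), "kgx_parse_error")
    }
    s <- decode_iri(m[2])
    pred <- URLdecode(m[3])
    sid <- ensure_node(s)
    if (nzchar(m[4])) {
      oid <- ensure_node(decode_iri(m[4]))
    } else {
      oid <- paste0(sid, "/", pred)
      k <- 1L
      while (!is.null(nodes[[oid]])) {
        k <- k + 1L
        oid <- paste0(sid, "/", pred, "#", k)
      }
      nodes[[oid]] <- list(
        node_type = "literal_value", source_db = "none",
        value = unescape_lit(m[5])
      )
    }
    subs <- c(subs, sid); preds <- c(preds, pred); objs <- c(objs, oid)
  }
  ids <- ls(nodes)
  if (length(ids)) {
    g$nodes <- data.table::data.table(
      node_id = ids,
      node_type = vapply(ids, function(i) nodes[[i]]$node_type, character(1)),
      value = vapply(ids, function(i) nodes[[i]]$value, character(1)),
      source_db = vapply(ids, function(i) nodes[[i]]$source_db, character(1))
    )
  }
  if (length(subs)) {
    g$edges <- unique(data.table::data.table(
      subject = subs, predicate = preds, object = objs
    ))
  }
  rebuild_hub_index(g)
  g
}
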