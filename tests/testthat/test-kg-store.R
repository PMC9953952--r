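test_that("canonical variant keys are normalized, deterministic and validated", {
  expect_identical(canonical_variant_key("17", 7579472, "G", "C"),
                   "17:7579472:G>C")
  expect_identical(canonical_variant_key("chr17", 7579472, "g", "c"),
                   "17:7579472:G>C")
  expect_identical(canonical_variant_key("17", 7579472, "G", "C"),
                   canonical_variant_key("17", 7579472, "G", "C"))
  expect_error(canonical_variant_key("17", 0, "G", "C"),
               class = "kgx_validation_error")
  expect_error(canonical_variant_key("17", 10, "G", "N"),
               class = "kgx_validation_error")
  expect_error(canonical_variant_key("17", 10, "", "C"),
               class = "kgx_validation_error")
})

test_that("hub creation is idempotent and keyed", {
  kg <- kg_new()
  h1 <- get_or_create_hub(kg, "17:100:G>C", "variant")
  n1 <- kg_n_nodes(kg)
  h2 <- get_or_create_hub(kg, "17:100:G>C", "variant")
  expect_identical(h1, h2)
  expect_identical(kg_n_nodes(kg), n1)
  h3 <- get_or_create_hub(kg, "17:200:A>T", "variant")
  g1 <- get_or_create_hub(kg, "TP53", "gene")
  expect_length(unique(c(h1, h3, g1)), 3L)
  expect_true(all(kg_nodes(kg)$source_db == "hub"))
})

test_that("attach_record adds one edge, dedupes, and guards the one-hub invariant", {
  kg <- kg_new()
  h <- get_or_create_hub(kg, "17:100:G>C", "variant")
  h2 <- get_or_create_hub(kg, "17:200:A>T", "variant")
  kg_add_node(kg, "clinvar:r1", "clinvar_record", source_db = "clinvar")
  attach_record(kg, "clinvar:r1", h)
  expect_identical(kg_n_edges(kg), 1L)
  attach_record(kg, "clinvar:r1", h) # idempotent
  expect_identical(kg_n_edges(kg), 1L)
  expect_error(attach_record(kg, "clinvar:r1", h2),
               class = "kgx_integrity_error")
  expect_error(attach_record(kg, "clinvar:r1", "nope"),
               class = "kgx_lookup_error")
})

test_that("reachable_subgraph follows direction except across hubs", {
  kg <- kg_new()
  kg_add_node(kg, "a", "literal_value")
  expect_identical(kg_n_nodes(reachable_subgraph(kg, "a")), 1L)
  expect_error(reachable_subgraph(kg, "zz"), class = "kgx_lookup_error")

  # chain a -> b -> c
  kg_add_node(kg, "b", "literal_value"); kg_add_node(kg, "c", "literal_value")
  kg$edges <- data.table::data.table(subject = c("a", "b"),
                                     predicate = "p", object = c("b", "c"))
  expect_setequal(kg_nodes(reachable_subgraph(kg, "a"))$node_id,
                  c("a", "b", "c"))
  expect_setequal(kg_nodes(reachable_subgraph(kg, "b"))$node_id, c("b", "c"))

  # star of k records pointing at one hub: all reachable from the hub by
  # crossing it against edge direction; oracle = brute-force closure
  k <- 7
  kg2 <- kg_new()
  h <- get_or_create_hub(kg2, "1:5:A>T", "variant")
  for (i in seq_len(k)) {
    kg_add_node(kg2, paste0("r", i), "clinvar_record", source_db = "clinvar")
    attach_record(kg2, paste0("r", i), h)
  }
  got <- kg_nodes(reachable_subgraph(kg2, h))$node_id
  expect_length(got, k + 1L)
  # brute force: repeatedly expand out-edges + in-edges-at-hubs
  closure <- h
  repeat {
    ed <- kg_edges(kg2)
    nxt <- union(ed$object[ed$subject %in% closure],
                 ed$subject[ed$object %in% intersect(closure, h)])
    if (all(nxt %in% closure)) break
    closure <- union(closure, nxt)
  }
  expect_setequal(got, closure)
})

test_that("reachable sets are monotone under edge addition", {
  base <- small_sim(seed = 11)
  # two different genes, so part of the graph is unreachable from the start
  kg <- records_to_kg(base$clinvar[1:5, ],
                      variants = base$variants[c(1:5, 30:34), ])
  start <- paste0("variant:", base$variants$key[1])
  before <- kg_nodes(reachable_subgraph(kg, start))$node_id
  # add an edge from a reachable node to a previously unreachable one
  outside <- setdiff(kg_nodes(kg)$node_id, before)[1]
  expect_false(is.na(outside))
  kgxplain:::kg_add_edges(kg, before[1], "extra", outside)
  after <- kg_nodes(reachable_subgraph(kg, start))$node_id
  expect_true(all(before %in% after))
})

test_that("N-Triples round trip preserves nodes, edges and payloads", {
  empty <- kg_new()
  path <- withr::local_tempfile(fileext = ".nt")
  expect_identical(write_ntriples(empty, path), 0L)
  expect_identical(length(readLines(path)), 0L)

  kg <- kg_new()
  h <- get_or_create_hub(kg, "1:5:A>T", "variant")
  kg_add_node(kg, "clinvar:r1", "clinvar_record", source_db = "clinvar")
  attach_record(kg, "clinvar:r1", h)
  kg_add_node(kg, "clinvar:r1/review_stars", "literal_value", value = "3")
  kgxplain:::kg_add_edges(kg, "clinvar:r1", "review_stars",
                          "clinvar:r1/review_stars")
  kg_add_node(kg, "gene:TP53", "gene_hub", source_db = "hub")
  kgxplain:::kg_add_edges(kg, h, "in_gene", "gene:TP53")
  n <- write_ntriples(kg, path)
  expect_identical(n, 3L)
  expect_identical(length(readLines(path)), 3L)
  rt <- read_ntriples(path)
  expect_setequal(kg_nodes(rt)$node_id, kg_nodes(kg)$node_id)
  expect_identical(
    data.table::setorderv(kg_edges(rt), c("subject", "predicate", "object")),
    data.table::setorderv(kg_edges(kg), c("subject", "predicate", "object"))
  )

  # a realistic several-hundred-edge graph round-trips exactly
  sim <- small_sim(seed = 9)
  big <- records_to_kg(sim$clinvar, sim$cosmic, sim$dbnsfp, sim$dbscsnv,
                       sim$variants)
  n2 <- write_ntriples(big, path)
  expect_identical(n2, kg_n_edges(big))
  expect_gt(n2, 500L)
  rt2 <- read_ntriples(path)
  expect_identical(kg_n_nodes(rt2), kg_n_nodes(big))
  expect_identical(kg_n_edges(rt2), kg_n_edges(big))
  ord <- function(g) {
    nd <- kg_nodes(g)
    nd[order(nd$node_id), c("node_id", "node_type", "value", "source_db")]
  }
  expect_equal(as.data.frame(ord(rt2)), as.data.frame(ord(big)))
})

test_that("malformed N-Triples lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".nt")
  writeLines(c(
    "<urn:kgx:n?id=a&t=variant_hub&db=hub> <urn:kgx:p:x> \"ok\" .",
    "this is not a triple"
  ), path)
  expect_error(read_ntriples(path), "line 2", class = "kgx_parse_error")
})

test_that("two-file TSV serialization round-trips including the hub index", {
  sim <- small_sim(seed = 12)
  kg <- records_to_kg(sim$clinvar[1:20, ], variants = sim$variants[1:30, ])
  dir <- withr::local_tempdir()
  kg_write_tsv(kg, dir)
  rt <- kg_read_tsv(dir)
  expect_identical(kg_n_nodes(rt), kg_n_nodes(kg))
  expect_identical(kg_n_edges(rt), kg_n_edges(kg))
  key <- sim$variants$key[1]
  expect_identical(get_or_create_hub(rt, key, "variant"),
                   get_or_create_hub(kg, key, "variant"))
})
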