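# Shared fixture builders. Everything is generated in code at test time.

clinvar_row <- function(chrom = "17", pos = 10000L, ref = "G", alt = "A",
                        gene = "MYO7A", consequence = "missense_variant",
                        clinical_significance = "Pathogenic",
                        review_stars = 3L, last_update_year = 2019L,
                        n_submissions = 3L, publications = "") {
  tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    consequence = consequence, clinical_significance = clinical_significance,
    review_stars = review_stars, last_update_year = last_update_year,
    n_submissions = n_submissions, publications = publications
  )
}

cosmic_row <- function(chrom = "17", pos = 10000L, ref = "G", alt = "A",
                       gene = "MYO7A", protein_change = "p.R1861*",
                       sample_count = 5L, publications = "") {
  tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    protein_change = protein_change, sample_count = sample_count,
    publications = publications
  )
}

dbnsfp_row <- function(chrom = "17", pos = 10000L, ref = "G", alt = "A",
                       scores = c(SIFT = 0.9)) {
  out <- tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
  for (a in names(scores)) out[[a]] <- scores[[a]]
  out
}

variants_row <- function(chrom = "17", pos = 10000L, ref = "G", alt = "A",
                         gene = "MYO7A", consequence = "missense_variant") {
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 gene = gene, consequence = consequence)
}

write_tsv_tmp <- function(df, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  data.table::fwrite(df, path, sep = "\t")
  path
}

# explanation-mode feature graph straight from record tibbles
fixture_fg <- function(clinvar = NULL, cosmic = NULL, dbnsfp = NULL,
                       dbscsnv = NULL, variants, target_pos = 10000L,
                       target = canonical_variant_key("17", target_pos, "G", "A"),
                       mode = "explanation") {
  kg <- records_to_kg(clinvar, cosmic, dbnsfp, dbscsnv, variants)
  parts <- Filter(Negate(is.null), list(clinvar, cosmic, dbnsfp, dbscsnv,
                                        variants))
  idx <- do.call(variant_index, parts)
  build_feature_graph(target, kg, mode, idx)
}

# minimal hand-built feature graph for classifier tests: `spec` is a list of
# c(predicate, value) literal children attached to one record on the target
toy_fg <- function(spec, target = "1:100:A>G", rec_type = "clinvar_record") {
  hub <- paste0("variant:", target)
  rec <- paste0("rec:", target)
  nodes <- data.table::data.table(
    node_id = c(hub, rec), node_type = c("variant_hub", rec_type),
    value = NA_character_, source_db = c("hub", sub("_record", "", rec_type))
  )
  edges <- data.table::data.table(subject = rec, predicate = "describes_variant",
                                  object = hub)
  for (i in seq_along(spec)) {
    pred <- spec[[i]][1]; val <- spec[[i]][2]
    lid <- paste0(rec, "/", pred, "#", i)
    nodes <- rbind(nodes, data.table::data.table(
      node_id = lid, node_type = "literal_value", value = val,
      source_db = "none"
    ))
    edges <- rbind(edges, data.table::data.table(
      subject = rec, predicate = pred, object = lid
    ))
  }
  structure(list(
    target = target, mode = "estimation", target_hub = hub,
    nodes = nodes, edges = edges,
    neighbor_links = data.table::setnames(
      data.table::data.table(k = character(), distance = integer(),
                             hub = character()), "k", "key")
  ), class = "kgx_feature_graph")
}

small_sim <- function(seed = 3, ...) {
  simulate_variants(sim_config(
    seed = seed, n_chromosomes = 6, genes_per_chromosome = 2,
    variants_per_gene = 25, ...
  ))
}

# cached small explanation model shared across explainer tests
explainer_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      ds <- sim_dataset(sim)
      ans <- build_explanation_answer_set(sim$clinvar, 1)
      plan <- make_mask_plan(ans$key, 1)
      fgs <- Map(function(k, m) {
        build_feature_graph(k, ds$kg, "explanation", ds$index,
                            drop_target_clinvar = (m == "drop_clinvar"))
      }, ans$key, plan$mask)
      model <- train_classifier(fgs, ans$label, classifier_config(seed = 1))
      cache <<- list(sim = sim, ds = ds, answers = ans, model = model)
    }
    cache
  }
})

all_pred <- setdiff(c(ESTIMATION_ALGORITHMS, EXPLANATION_ALGORITHMS),
                    CONSERVATION_ALGORITHMS)

golden_cases <- function() {
  target_vt <- variants_row() # 17:10000:G>A missense in MYO7A
  list(
    list(
      rule = "Neighboring variants in ClinVar",
      fg = {
        nb <- do.call(rbind, lapply(1:14, function(i) {
          clinvar_row(pos = 10000L + i, ref = "C", alt = "T",
                      clinical_significance = if (i <= 3) "Pathogenic" else "VUS")
        }))
        vt <- rbind(target_vt, do.call(rbind, lapply(1:14, function(i) {
          variants_row(pos = 10000L + i, ref = "C", alt = "T")
        })))
        fixture_fg(clinvar = nb, variants = vt)
      },
      expected = "Fourteen neighboring variants are \u201cmissense variant\u201d, three of which are registered as \u201cPathogenic\u201d in ClinVar."
    ),
    list(
      rule = "Outstanding algorithms in dbNSFP",
      fg = fixture_fg(
        dbnsfp = dbnsfp_row(scores = c(
          phyloP100way_vertebrate = 0.97, SiPhy_29way_logOdds = 0.88,
          SIFT = 0.72, PROVEAN = 0.71, LRT = 0.63
        )),
        variants = target_vt
      ),
      expected = "This variant has dbNSFP algorithms: phyloP100way_vertebrate is high (0.97), SiPhy_29way_logOdds is high (0.88), SIFT is high (0.72), PROVEAN is high (0.71), and LRT is moderate (0.63)."
    ),
    list(
      rule = "Average of algorithms in dbNSFP",
      fg = fixture_fg(
        dbnsfp = dbnsfp_row(scores = c(
          setNames(rep(0.84, 14), all_pred[1:14]),
          setNames(rep(0.79, 4), CONSERVATION_ALGORITHMS)
        )),
        variants = target_vt
      ),
      expected = "This variant has an average score of 0.84 for 14 prediction algorithms, and 0.79 for 4 conservation algorithms from dbNSFP."
    ),
    list(
      rule = "Same amino acid variants",
      fg = fixture_fg(
        clinvar = clinvar_row(alt = "T", clinical_significance = "VUS"),
        variants = rbind(target_vt, variants_row(alt = "T"))
      ),
      expected = "Neighboring variants in the same base are registered as \"VUS\" in ClinVar."
    ),
    list(
      rule = "Neighboring variant papers",
      fg = {
        pubs <- function(ids) paste(sprintf("%d:Wiley", ids), collapse = "|")
        nb <- do.call(rbind, lapply(1:8, function(i) {
          ids <- if (i < 8) (i * 10 + 1):(i * 10 + 3) else 901:905 # 21 + 5
          clinvar_row(pos = 10000L + i, ref = "C", alt = "T",
                      publications = pubs(ids))
        }))
        vt <- rbind(target_vt, do.call(rbind, lapply(1:8, function(i) {
          variants_row(pos = 10000L + i, ref = "C", alt = "T")
        })))
        fixture_fg(clinvar = nb, variants = vt)
      },
      expected = "Eight neighboring variants are reported in twenty-six papers."
    ),
    list(
      rule = "Variants in COSMIC",
      fg = fixture_fg(
        cosmic = cosmic_row(pos = 10040L, ref = "C", alt = "T",
                            protein_change = "p.R1861*"),
        variants = rbind(target_vt,
                         variants_row(pos = 10040L, ref = "C", alt = "T"))
      ),
      expected = "A neighboring variant, p.R1861*, is registered in COSMIC."
    ),
    list(
      rule = "Variants in dbNSFP",
      fg = fixture_fg(dbnsfp = dbnsfp_row(scores = c(SIFT = 0.88)),
                      variants = target_vt),
      expected = "This variant has a score of 0.88 according to the SIFT algorithm of dbNSFP."
    ),
    list(
      rule = "Variants reference",
      fg = fixture_fg(clinvar = clinvar_row(publications = "28492532:Wiley"),
                      variants = target_vt),
      expected = "This variant is explained in https://pubmed.ncbi.nlm.nih.gov/28492532/ (accessed on 2 December 2022)."
    ),
    list(
      rule = "Variants in ClinVar",
      fg = fixture_fg(clinvar = clinvar_row(clinical_significance = "Pathogenic",
                                            review_stars = 3L,
                                            n_submissions = 3L),
                      variants = target_vt),
      expected = "This variant is considered pathogenic with 3 stars in ClinVar, and the report has 3 submissions."
    ),
    list(
      rule = "Variants type",
      fg = fixture_fg(variants = target_vt),
      expected = "This variant is a missense variant."
    )
  )
}

flat_fixture_fg <- function(n_neighbors = 1L) {
  # documented flattening fixture: target with SIFT 0.9, a COSMIC record of
  # 100 samples and 2 papers, plus pathogenic missense ClinVar neighbors at
  # 5-base spacing with 2 stars and one paper each
  target_vt <- variants_row()
  parts <- list(variants_row())
  cv <- NULL
  if (n_neighbors > 0) {
    cv <- do.call(rbind, lapply(seq_len(n_neighbors), function(i) {
      clinvar_row(pos = 10000L + i, ref = "C", alt = "T",
                  clinical_significance = "Pathogenic", review_stars = 2L,
                  publications = sprintf("%d:Wiley", i))
    }))
    parts <- c(parts, lapply(seq_len(n_neighbors), function(i) {
      variants_row(pos = 10000L + i, ref = "C", alt = "T")
    }))
  }
  fixture_fg(
    clinvar = cv,
    cosmic = cosmic_row(sample_count = 100L, publications = "11|22"),
    dbnsfp = dbnsfp_row(scores = c(SIFT = 0.9)),
    variants = do.call(rbind, parts),
    mode = "estimation"
  )
}
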