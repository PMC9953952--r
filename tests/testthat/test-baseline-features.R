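test_that("COSMIC sample-count binning follows the printed aggregation rules", {
  expect_identical(bin_sample_count(1), 0)
  expect_identical(bin_sample_count(2), 1)
  expect_identical(bin_sample_count(10), 1)
  expect_identical(bin_sample_count(11), 2)
  expect_identical(bin_sample_count(100), 2)
  expect_identical(bin_sample_count(1000), 3)
  expect_identical(bin_sample_count(10000), 4)
  expect_identical(bin_sample_count(10001), 5)
  expect_identical(bin_sample_count(1e9), 5)
  expect_error(bin_sample_count(0), class = "kgx_validation_error")
})

test_that("binning equals ceiling(log10(n)) clipped to [0, 5]", {
  n <- c(1:100000, 10^(1:9), 10^(1:9) + 1)
  closed_form <- pmin(ceiling(log10(n)), 5)
  expect_identical(bin_sample_count(n), closed_form)
})

test_that("publications tabulate per ClinVar publisher and total for COSMIC", {
  zero <- aggregate_publications()
  expect_true(all(zero == 0))
  got <- aggregate_publications(c("Wiley", "Wiley", "Springer"),
                                c("p1", "p2", "p3"))
  expect_identical(unname(got["clinvar_pubs_Wiley"]), 2)
  expect_identical(unname(got["clinvar_pubs_Springer"]), 1)
  expect_identical(unname(got["clinvar_pubs_Elsevier"]), 0)
  expect_identical(unname(got["cosmic_pubs_total"]), 3)
  # unknown publishers fall into the closed vocabulary's Other bucket
  got2 <- aggregate_publications(c("NoSuchHouse"))
  expect_identical(unname(got2["clinvar_pubs_Other"]), 1)
})

test_that("neighbor tallies land in the right distance bins and add up", {
  empty <- aggregate_neighbors(tibble::tibble(key = character(),
                                              distance = integer()))
  expect_true(all(empty == 0))

  nb <- tibble::tibble(key = c("a", "b"), distance = c(5L, 80L))
  ann <- tibble::tibble(
    key = c("a", "b"), source = "clinvar",
    consequence = "missense_variant", clinical_significance = "Pathogenic",
    review_stars = c(3, 1), n_pubs = c(2, 0)
  )
  got <- aggregate_neighbors(nb, ann)
  expect_identical(unname(got["nbin1_n_variants"]), 1)
  expect_identical(unname(got["nbin4_n_variants"]), 1)
  expect_identical(unname(got["nbin1_cs_missense_variant_Pathogenic"]), 1)
  expect_identical(unname(got["nbin4_cs_missense_variant_Pathogenic"]), 1)
  # review-status cross splits on the two-star boundary
  expect_identical(unname(got["nbin1_csr_missense_variant_hi_Pathogenic"]), 1)
  expect_identical(unname(got["nbin4_csr_missense_variant_lo_Pathogenic"]), 1)
  expect_identical(unname(got["nbin1_clinvar_pubs"]), 2)

  # two neighbors in one bin accumulate
  nb2 <- tibble::tibble(key = c("a", "b"), distance = c(3L, 7L))
  got2 <- aggregate_neighbors(nb2, ann)
  expect_identical(unname(got2["nbin1_cs_missense_variant_Pathogenic"]), 2)
  expect_error(
    aggregate_neighbors(tibble::tibble(key = "a", distance = 101L)),
    class = "kgx_validation_error"
  )
})


test_that("flatten matches the hand-computed reference on the documented fixture", {
  v <- flatten(flat_fixture_fg(1L))
  expect_identical(unname(v["dbnsfp_SIFT"]), 0.9)
  expect_identical(unname(v["dbnsfp_LRT"]), -1)          # missing -> sentinel
  expect_identical(unname(v["cosmic_registered"]), 1)
  expect_identical(unname(v["cosmic_sample_bin"]), 2)    # 100 samples -> 2
  expect_identical(unname(v["cosmic_pubs_total"]), 2)
  expect_identical(unname(v["clinvar_pubs_Wiley"]), 0)   # target ClinVar masked
  expect_identical(unname(v["nbin1_n_variants"]), 1)
  expect_identical(unname(v["nbin1_clinvar_n"]), 1)
  expect_identical(unname(v["nbin1_cs_missense_variant_Pathogenic"]), 1)
  expect_identical(unname(v["nbin1_csr_missense_variant_hi_Pathogenic"]), 1)
  expect_identical(unname(v["nbin1_clinvar_pubs"]), 1)
  expect_identical(unname(v["nbin2_n_variants"]), 0)
})

test_that("vector length is invariant to neighbor and record counts", {
  schema <- flatten_schema()
  v0 <- flatten(flat_fixture_fg(0L))
  v50 <- flatten(flat_fixture_fg(50L))
  expect_identical(length(v0), length(schema))
  expect_identical(length(v50), length(schema))
  expect_identical(names(v0), names(v50))
  # neighbors sit at distances 1..50: 10 in bin 1-10, 15 in 11-25, 25 in 26-50
  expect_identical(unname(v50["nbin1_n_variants"]), 10)
  expect_identical(unname(v50["nbin3_n_variants"]), 25)
  # an empty target flattens to the all-sentinel/zero vector of full length
  bare <- fixture_fg(variants = variants_row(), mode = "estimation")
  vb <- flatten(bare)
  expect_identical(length(vb), length(schema))
  expect_true(all(vb[startsWith(names(vb), "nbin")] == 0))
  expect_true(all(vb[startsWith(names(vb), "dbnsfp_")] == -1))
  expect_error(flatten(fixture_fg(variants = variants_row())),
               class = "kgx_mode_error") # explanation mode refused
})

test_that("flatten is invariant to input record order", {
  cv <- rbind(
    clinvar_row(pos = 10004L, ref = "C", alt = "T",
                clinical_significance = "Pathogenic"),
    clinvar_row(pos = 10090L, ref = "C", alt = "T",
                clinical_significance = "Benign")
  )
  vt <- rbind(variants_row(),
              variants_row(pos = 10004L, ref = "C", alt = "T"),
              variants_row(pos = 10090L, ref = "C", alt = "T"))
  f1 <- flatten(fixture_fg(clinvar = cv, variants = vt, mode = "estimation"))
  f2 <- flatten(fixture_fg(clinvar = cv[2:1, ], variants = vt[c(3, 1, 2), ],
                           mode = "estimation"))
  expect_identical(f1, f2)
})

test_that("tree and forest baselines honor depth, seeds and class checks", {
  X <- rbind(matrix(0, 20, 3), matrix(1, 20, 3))
  colnames(X) <- c("a", "b", "c")
  y <- rep(c("benign", "pathogenic"), each = 20)
  tr <- fit_tree(X, y, max_depth = 1, seed = 1)
  expect_identical(unname(predict_baseline(tr, X) >= 0.5), y == "pathogenic")
  fo <- fit_forest(X, y, max_depth = 2, seed = 1)
  expect_true(all(abs(predict_baseline(fo, X) - (y == "pathogenic")) < 0.4))
  fo2 <- fit_forest(X, y, max_depth = 2, seed = 1)
  expect_identical(predict_baseline(fo, X), predict_baseline(fo2, X))
  expect_error(fit_tree(X, rep("benign", 40)), class = "kgx_training_error")
  expect_error(fit_forest(X, rep("pathogenic", 40)),
               class = "kgx_training_error")
})
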