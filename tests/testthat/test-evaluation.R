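test_that("the estimation answer set applies the star/significance/missense filters", {
  cv <- rbind(
    clinvar_row(pos = 1L, review_stars = 1L),                          # 1 star
    clinvar_row(pos = 2L, clinical_significance = "VUS"),              # VUS
    clinvar_row(pos = 3L),                                             # keep
    clinvar_row(pos = 4L, clinical_significance = "Likely_pathogenic"),
    clinvar_row(pos = 5L, clinical_significance = "Benign"),           # keep
    clinvar_row(pos = 6L, consequence = "synonymous_variant")          # not missense
  )
  ans <- build_estimation_answer_set(cv)
  expect_identical(sort(ans$key),
                   sort(canonical_variant_key("17", c(3, 5), "G", "A")))
  expect_setequal(ans$label, c("pathogenic", "benign"))
})

test_that("the explanation answer set admits likely labels and all SNVs, balanced", {
  cv <- rbind(
    clinvar_row(pos = 1L, clinical_significance = "Likely_pathogenic",
                review_stars = 0L),
    clinvar_row(pos = 2L, clinical_significance = "Benign",
                consequence = "synonymous_variant"),
    clinvar_row(pos = 3L, clinical_significance = "Pathogenic"),
    clinvar_row(pos = 4L, clinical_significance = "Likely_benign"),
    clinvar_row(pos = 5L, clinical_significance = "Pathogenic"),
    clinvar_row(pos = 6L, clinical_significance = "VUS"),
    clinvar_row(pos = 7L, ref = "GA", alt = "G") # not an SNV
  )
  ans <- build_explanation_answer_set(cv, seed = 1)
  expect_identical(sum(ans$label == "pathogenic"),
                   sum(ans$label == "benign"))
  expect_true(canonical_variant_key("17", 1, "G", "A") %in% ans$key ||
                sum(ans$label == "pathogenic") == 2) # likely mapped to parent
  expect_false(canonical_variant_key("17", 6, "G", "A") %in% ans$key)
  expect_false("17:7:GA>G" %in% ans$key)
  expect_true(canonical_variant_key("17", 2, "G", "A") %in% ans$key)
})

test_that("class balancing downsamples only the majority class, reproducibly", {
  v <- tibble::tibble(
    key = sprintf("1:%d:A>G", 1:30), chrom = "1",
    label = rep(c("pathogenic", "benign"), c(10, 20))
  )
  b <- balance_classes(v, seed = 4)
  expect_identical(unname(table(b$label)["pathogenic"]), 10L)
  expect_identical(unname(table(b$label)["benign"]), 10L)
  expect_true(all(v$key[v$label == "pathogenic"] %in% b$key))
  expect_identical(balance_classes(v, seed = 4), b)
  expect_identical(balance_classes(b, seed = 9), b) # already balanced
  expect_error(balance_classes(v[v$label == "benign", ]),
               class = "kgx_validation_error")
})

test_that("chromosome folds never split a chromosome and stay balanced", {
  v5 <- tibble::tibble(key = sprintf("%d:1:A>G", 1:5),
                       chrom = as.character(1:5), label = "benign")
  f5 <- chromosome_folds(v5, k = 5)
  expect_setequal(f5$fold, 0:4)
  expect_identical(anyDuplicated(f5$fold), 0L)

  expect_error(chromosome_folds(v5[1, ], k = 5), class = "kgx_validation_error")

  # skewed chromosome sizes: partition-checking oracle
  sizes <- kgxplain:::with_seed(8, sample(5:120, 22, replace = TRUE))
  v22 <- do.call(rbind, lapply(1:22, function(c_) {
    tibble::tibble(key = sprintf("%d:%d:A>G", c_, seq_len(sizes[c_])),
                   chrom = as.character(c_), label = "benign")
  }))
  f22 <- chromosome_folds(v22, k = 5)
  per_chrom <- tapply(f22$fold, f22$chrom, function(x) length(unique(x)))
  expect_true(all(per_chrom == 1L))
  fold_sizes <- table(f22$fold)
  expect_lte(max(fold_sizes) / min(fold_sizes), 2)
})

test_that("compute_metrics matches hand-computed and brute-force references", {
  perfect <- compute_metrics(c(0.9, 0.8, 0.3, 0.1),
                             c("pathogenic", "pathogenic", "benign", "benign"))
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$auc, 1)
  expect_identical(perfect$precision, 1)
  expect_identical(perfect$recall, 1)
  expect_identical(perfect$f1, 1)

  # interleaved labels: 3 of 4 positive/negative pairs concordant
  mixed <- compute_metrics(c(0.9, 0.8, 0.3, 0.1),
                           c("pathogenic", "benign", "pathogenic", "benign"))
  expect_identical(mixed$auc, 0.75)

  flipped <- compute_metrics(c(0.1, 0.2, 0.8, 0.9),
                             c("pathogenic", "pathogenic", "benign", "benign"))
  expect_identical(flipped$accuracy, 0)
  expect_identical(flipped$auc, 0)

  expect_error(compute_metrics(c(0.4, 0.6), c("benign", "benign")),
               class = "kgx_validation_error")

  # brute-force all-pairs AUC (ties count half) on random scores with ties
  brute_auc <- function(s, y) {
    pos <- s[y == "pathogenic"]; neg <- s[y == "benign"]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  for (seed in 1:5) {
    n <- 400
    s <- kgxplain:::with_seed(seed, round(runif(n), 2)) # many ties
    y <- kgxplain:::with_seed(seed + 100,
                              sample(c("pathogenic", "benign"), n, TRUE))
    m <- compute_metrics(s, y)
    expect_equal(m$auc, brute_auc(s, y), tolerance = 1e-12)
  }
})

test_that("metric rank statistic agrees with an established ROC implementation", {
  s <- kgxplain:::with_seed(3, runif(300))
  y <- kgxplain:::with_seed(4, sample(c("pathogenic", "benign"), 300, TRUE))
  ours <- compute_metrics(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = s, levels = c("benign", "pathogenic"),
    direction = "<", quiet = TRUE
  )))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("cross-validation is fold-disjoint, averaged correctly, and leak-proof", {
  sim <- small_sim(seed = 31)
  ds <- sim_dataset(sim)
  folds <- chromosome_folds(ds$answers, k = 5)
  rep <- cross_validate(ds, folds, model = "tree", seed = 1)
  expect_identical(nrow(rep$per_fold), 5L)
  for (col in c("accuracy", "precision", "recall", "f1", "auc")) {
    expect_equal(rep$mean[[col]], mean(rep$per_fold[[col]]), tolerance = 1e-12)
  }
  # every variant is scored exactly once, in its own fold
  expect_setequal(rep$scores$key, ds$answers$key)
  got_fold <- folds$fold[match(rep$scores$key, folds$key)]
  expect_identical(rep$scores$fold, got_fold)

  # deterministic rerun
  rep2 <- cross_validate(ds, folds, model = "tree", seed = 1)
  expect_identical(rep$mean, rep2$mean)

  # deliberate leakage: a chromosome assigned to two folds is a hard error
  bad <- folds
  i <- which(bad$chrom == bad$chrom[1])
  bad$fold[i[1]] <- (bad$fold[i[1]] + 1L) %% 5L
  expect_error(cross_validate(ds, bad, model = "tree"),
               class = "kgx_leakage_error")
})

test_that("the epoch/depth sweep reports the best mean accuracy", {
  sim <- small_sim(seed = 32)
  ds <- sim_dataset(sim)
  folds <- chromosome_folds(ds$answers, k = 5)
  rep <- cross_validate(ds, folds, model = "tree", sweep = c(1, 5, 9))
  expect_identical(nrow(rep$sweep), 3L)
  expect_identical(rep$mean$accuracy, max(rep$sweep$mean_accuracy))
})
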