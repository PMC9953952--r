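# training graphs with a single discriminative annotation
separable_pair <- function() {
  list(
    path = toy_fg(list(c("clinical_significance", "Pathogenic")),
                  target = "1:100:A>G"),
    benign = toy_fg(list(c("clinical_significance", "Benign")),
                    target = "1:200:A>G")
  )
}

test_that("training on trivially separable graphs classifies both correctly", {
  p <- separable_pair()
  graphs <- c(rep(list(p$path), 5), rep(list(p$benign), 5))
  labels <- rep(c("pathogenic", "benign"), each = 5)
  m <- train_classifier(graphs, labels, classifier_config(seed = 1))
  s <- predict_score(m, list(p$path, p$benign))
  expect_identical(classify_score(s), c("pathogenic", "benign"))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("training is deterministic for a fixed seed and validates input", {
  p <- separable_pair()
  graphs <- c(rep(list(p$path), 3), rep(list(p$benign), 3))
  labels <- rep(c("pathogenic", "benign"), each = 3)
  m1 <- train_classifier(graphs, labels, classifier_config(seed = 5))
  m2 <- train_classifier(graphs, labels, classifier_config(seed = 5))
  expect_identical(predict_score(m1, graphs), predict_score(m2, graphs))

  expect_error(train_classifier(graphs, rep("pathogenic", 6)),
               class = "kgx_training_error")
  expect_error(train_classifier(graphs[1], "pathogenic"),
               class = "kgx_training_error")
  expect_error(train_classifier(graphs, c(labels[-1], "weird")),
               class = "kgx_training_error")
})

test_that("a memorized pathogenic graph scores at or above threshold", {
  p <- separable_pair()
  graphs <- c(rep(list(p$path), 10), rep(list(p$benign), 10))
  labels <- rep(c("pathogenic", "benign"), each = 10)
  m <- train_classifier(graphs, labels,
                        classifier_config(seed = 1, epochs = 100))
  expect_gte(predict_score(m, p$path), 0.5)
  # hub-only degenerate graph scores without crashing
  empty <- toy_fg(list(), target = "1:999:A>G")
  empty$edges <- empty$edges[0, ]
  s <- predict_score(m, empty)
  expect_true(s >= 0 && s <= 1)
})

test_that("mode mismatch between model and graph is refused", {
  p <- separable_pair()
  graphs <- c(rep(list(p$path), 3), rep(list(p$benign), 3))
  m <- train_classifier(graphs, rep(c("pathogenic", "benign"), each = 3))
  g2 <- p$path
  g2$mode <- "explanation"
  expect_error(predict_score(m, g2), class = "kgx_mode_error")
})

test_that("classification threshold is exactly 0.5", {
  expect_identical(classify_score(0.5), "pathogenic")
  expect_identical(classify_score(0.499), "benign")
  expect_identical(classify_score(1.0), "pathogenic")
  expect_identical(classify_score(0), "benign")
  expect_error(classify_score(1.2), class = "kgx_validation_error")
  expect_error(classify_score(-0.1), class = "kgx_validation_error")
})

test_that("graph classifier recovers a planted signal on synthetic data", {
  sim <- simulate_variants(sim_config(
    seed = 17, n_chromosomes = 5, genes_per_chromosome = 2,
    variants_per_gene = 40
  ))
  ds <- sim_dataset(sim)
  fgs <- lapply(ds$answers$key, build_feature_graph, kg = ds$kg,
                mode = "estimation", index = ds$index)
  expect_gte(length(fgs), 100)
  m <- train_classifier(fgs, ds$answers$label, classifier_config(seed = 1))
  s <- predict_score(m, fgs)
  auc <- kgxplain:::rank_auc(s, ds$answers$label)
  expect_gte(auc, 0.9) # training AUC on planted signal
})

test_that("exhaustive edge attribution equals the difference-of-means surrogate", {
  p <- separable_pair()
  graphs <- c(rep(list(p$path), 5), rep(list(p$benign), 5))
  labels <- rep(c("pathogenic", "benign"), each = 5)
  m <- train_classifier(graphs, labels, classifier_config(seed = 1))

  g <- toy_fg(list(
    c("clinical_significance", "Pathogenic"),
    c("consequence", "missense_variant"),
    c("consequence", "stop_gained"),
    c("publisher", "Wiley")
  ))
  ec <- edge_contributions(m, g, n_perturbations = 2^nrow(g$edges), seed = 1)
  E <- nrow(g$edges)
  # independent oracle: full factorial is balanced and orthogonal, so each
  # OLS weight equals mean(score | edge on) - mean(score | edge off)
  M <- as.matrix(expand.grid(rep(list(c(0, 1)), E)))
  y <- kgxplain:::score_masked(m, g, M)
  oracle <- vapply(seq_len(E), function(e) {
    mean(y[M[, e] == 1]) - mean(y[M[, e] == 0])
  }, numeric(1))
  expect_lt(max(abs(ec$contribution - oracle)), 1e-6)

  # a single-edge graph attributes the full score swing to that edge
  g1 <- toy_fg(list(c("clinical_significance", "Pathogenic")))
  ec1 <- edge_contributions(m, g1, n_perturbations = 4, seed = 1)
  # masking describes_variant does not change features; the significance edge
  # carries the whole effect
  sig_edge <- ec1$contribution[ec1$predicate == "clinical_significance"]
  g1_empty <- g1; g1_empty$edges <- g1$edges[0, ]
  swing <- predict_score(m, g1) - predict_score(m, g1_empty)
  expect_lt(abs(sig_edge - swing), 1e-6)

  # zero-edge graph: empty attribution map
  g0 <- g1_empty
  expect_identical(nrow(edge_contributions(m, g0)), 0L)
})

test_that("attribution of a score-invariant edge is (near) zero", {
  p <- separable_pair()
  graphs <- c(rep(list(p$path), 5), rep(list(p$benign), 5))
  m <- train_classifier(graphs, rep(c("pathogenic", "benign"), each = 5),
                        classifier_config(seed = 1))
  # the describes_variant edge token never occurs with nonzero weight in a
  # model trained only on significance tokens; oracle confirms invariance
  g <- toy_fg(list(c("clinical_significance", "Pathogenic")))
  ec <- edge_contributions(m, g, n_perturbations = 4, seed = 1)
  null_edge <- ec$contribution[ec$predicate == "describes_variant"]
  expect_lt(abs(null_edge), 1e-8)
})

test_that("sampled attribution is deterministic per seed", {
  p <- separable_pair()
  graphs <- c(rep(list(p$path), 5), rep(list(p$benign), 5))
  m <- train_classifier(graphs, rep(c("pathogenic", "benign"), each = 5),
                        classifier_config(seed = 1))
  g <- toy_fg(lapply(1:30, function(i) c("consequence", paste0("c", i))))
  e1 <- edge_contributions(m, g, n_perturbations = 64, seed = 9)
  e2 <- edge_contributions(m, g, n_perturbations = 64, seed = 9)
  expect_identical(e1, e2)
})

test_that("node contributions use the signed max-magnitude rule", {
  g <- toy_fg(list(c("consequence", "x")))
  # single edge c = 0.3: both endpoints get 0.3
  ec <- tibble::as_tibble(g$edges)
  ec$contribution <- c(0, 0.3)
  nc <- node_contributions(ec, g)
  lit <- g$nodes$node_id[g$nodes$node_type == "literal_value"]
  rec <- unique(ec$subject[ec$contribution == 0.3])
  expect_identical(unname(nc[lit]), 0.3)
  expect_identical(unname(nc[rec]), 0.3)

  # node incident to {+0.3, -0.5} gets -0.5
  g2 <- toy_fg(list(c("consequence", "x"), c("consequence", "y")))
  ec2 <- tibble::as_tibble(g2$edges)
  ec2$contribution <- c(0, 0.3, -0.5)
  nc2 <- node_contributions(ec2, g2)
  rec2 <- ec2$subject[2]
  expect_identical(unname(nc2[rec2]), -0.5)

  # isolated node gets 0
  g3 <- g2
  g3$nodes <- rbind(g3$nodes, data.table::data.table(
    node_id = "lonely", node_type = "literal_value", value = "v",
    source_db = "none"
  ))
  nc3 <- node_contributions(ec2, g3)
  expect_identical(unname(nc3["lonely"]), 0)
  # alternative aggregations are selectable
  expect_identical(unname(node_contributions(ec2, g2, "sum")[rec2]),
                   0.3 - 0.5)
})

test_that("the randomized message-passing backend is deterministic and learns", {
  p <- separable_pair()
  graphs <- c(rep(list(p$path), 6), rep(list(p$benign), 6))
  labels <- rep(c("pathogenic", "benign"), each = 6)
  cfg <- classifier_config(backend = "gnn", seed = 4)
  m1 <- train_classifier(graphs, labels, cfg)
  m2 <- train_classifier(graphs, labels, cfg)
  expect_identical(predict_score(m1, graphs), predict_score(m2, graphs))
  s <- predict_score(m1, list(p$path, p$benign))
  expect_gt(s[1], s[2])
})

test_that("models survive a save/load round trip", {
  p <- separable_pair()
  graphs <- c(rep(list(p$path), 3), rep(list(p$benign), 3))
  m <- train_classifier(graphs, rep(c("pathogenic", "benign"), each = 3))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict_score(m2, graphs), predict_score(m, graphs))
})
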