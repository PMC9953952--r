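#' Simulation configuration
#'
#' Parameters of the synthetic variant/annotation generator. The generator
#' plants a tunable pathogenicity signal with the statistical structure the
#' feature set assumes: class-separated dbNSFP scores, spatial clustering of
#' pathogenic variants (so the 100-base neighborhood is informative), and
#' COSMIC sample counts correlated with pathogenicity. With
#' `score_separation = 0` and `hotspot_clustering = 0` every feature is
#' uninformative by construction (the global negative control).
#'
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chromosome genes per chromosome.
#' @param variants_per_gene variants per gene.
#' @param pathogenic_fraction marginal probability a variant is pathogenic;
#'   preserved exactly in expectation under clustering.
#' @param hotspot_clustering in `[0, 1]`: probability boost that a variant
#'   within 100 bases of a pathogenic predecessor is itself pathogenic
#'   (and symmetric damping after a benign one, keeping the marginal fixed).
#' @param score_separation difference of class-conditional mean dbNSFP
#'   scores (beta-distributed in `[0, 1]`); also scales the COSMIC
#'   sample-count class shift.
#' @param annotation_noise probability that a ClinVar significance
#'   contradicts the true label.
#' @param coverage named per-source probabilities a variant carries a record.
#' @param clump_prob probability of a short (<= 60 base) gap to the next
#'   variant, which is what creates 100-base neighborhoods.
#' @param seed mandatory integer seed; the whole dataset is reproducible.
#' @return a `kgx_sim_config`.
#' @export
sim_config <- function(n_chromosomes = 10L, genes_per_chromosome = 5L,
                       variants_per_gene = 40L, pathogenic_fraction = 0.5,
                       hotspot_clustering = 0.5, score_separation = 0.3,
                       annotation_noise = 0.05,
                       coverage = c(clinvar = 0.9, cosmic = 0.6,
                                    dbnsfp = 0.95, dbscsnv = 0.3),
                       clump_prob = 0.5, seed) {
  if (missing(seed)) stop_kgx("seed is mandatory", "kgx_validation_error")
  stopifnot(
    pathogenic_fraction > 0, pathogenic_fraction < 1,
    hotspot_clustering >= 0, hotspot_clustering <= 1,
    score_separation >= 0, all(coverage >= 0), all(coverage <= 1)
  )
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    variants_per_gene = as.integer(variants_per_gene),
    pathogenic_fraction = pathogenic_fraction,
    hotspot_clustering = hotspot_clustering,
    score_separation = score_separation,
    annotation_noise = annotation_noise,
    coverage = coverage, clump_prob = clump_prob,
    seed = as.integer(seed)
  ), class = "kgx_sim_config")
}

BASES <- c("A", "C", "G", "T")
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "L", "K", "M", "F",
         "P", "S", "T", "W", "Y", "V")

rbeta_mean <- function(n, mean, precision = 8) {
  mean <- pmin(pmax(mean, 0.05), 0.95)
  round(rbeta(n, mean * precision, (1 - mean) * precision), 4)
}

#' Generate a synthetic variant set with annotation tables
#'
#' Produces a variant list with true labels plus the four annotation tables
#' in exactly the schemas the loaders expect. Pathogenicity labels are drawn
#' along each gene in position order with hotspot clustering; dbNSFP (and
#' dbscSNV) scores are beta-distributed with class-dependent means; ClinVar
#' significance equals the true label up to the annotation-noise rate, with
#' categorical stars, submission counts and publisher-tagged publications;
#' COSMIC sample counts are log-uniform with a class shift proportional to
#' the score separation. Gene loci are spaced 10^6 bases apart, with
#' clumped intra-gene gaps so that many variants have neighbors within 100
#' bases. Fully reproducible per seed.
#'
#' @param config a [sim_config()].
#' @return a `kgx_sim` list: `config`, `variants` (with `true_label`),
#'   `clinvar`, `cosmic`, `dbnsfp`, `dbscsnv` tibbles.
#' @export
simulate_variants <- function(config) {
  stopifnot(inherits(config, "kgx_sim_config"))
  with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(cfg) {
  rows <- list()
  p0 <- cfg$pathogenic_fraction
  cl <- cfg$hotspot_clustering
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- as.character(ci)
    for (gi in seq_len(cfg$genes_per_chromosome)) {
      gene <- sprintf("GENE%d_%d", ci, gi)
      m <- cfg$variants_per_gene
      gaps <- ifelse(runif(m) < cfg$clump_prob,
                     sample(0:60, m, replace = TRUE),
                     sample(150:600, m, replace = TRUE))
      pos <- (gi - 1L) * 1000000L + 1000L + cumsum(pmax(gaps, 0L))
      if (max(pos) - min(pos) >= 1000000L) {
        stop_kgx("variants denser than the per-gene coordinate space",
                 "kgx_validation_error")
      }
      ref <- sample(BASES, m, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
      # same-base second alleles at a low rate, to exercise distance 0
      dup <- runif(m) < 0.03
      if (any(dup)) {
        di <- which(dup)
        pos[di] <- pos[pmax(di - 1L, 1L)]
        ref[di] <- ref[pmax(di - 1L, 1L)]
        for (j in di) alt[j] <- sample(setdiff(BASES, c(ref[j], alt[j])), 1)
      }
      consequence <- sample(
        c("missense_variant", "synonymous_variant", "stop_gained",
          "splice_region_variant"),
        m, replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05)
      )
      lab <- logical(m)
      for (i in seq_len(m)) {
        p <- p0
        if (i > 1 && pos[i] - pos[i - 1] <= 100) {
          p <- if (lab[i - 1]) p0 + cl * (1 - p0) else p0 * (1 - cl)
        }
        lab[i] <- runif(1) < p
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
        consequence = consequence, true_label = ifelse(lab, "pathogenic", "benign")
      )
    }
  }
  v <- do.call(rbind, rows)
  v <- v[!duplicated(canonical_variant_key(v$chrom, v$pos, v$ref, v$alt)), ]
  v$key <- canonical_variant_key(v$chrom, v$pos, v$ref, v$alt)
  n <- nrow(v)
  path <- v$true_label == "pathogenic"
  sep <- cfg$score_separation
  cov <- cfg$coverage

  # ClinVar
  has_cv <- runif(n) < cov[["clinvar"]]
  noise <- runif(n) < cfg$annotation_noise
  asserted_path <- xor(path, noise)
  certainty <- sample(c("definite", "likely", "vus"), n, replace = TRUE,
                      prob = c(0.7, 0.2, 0.1))
  significance <- ifelse(
    certainty == "vus", "VUS",
    ifelse(asserted_path,
           ifelse(certainty == "definite", "Pathogenic", "Likely_pathogenic"),
           ifelse(certainty == "definite", "Benign", "Likely_benign"))
  )
  stars <- sample(0:4, n, replace = TRUE, prob = c(0.10, 0.15, 0.45, 0.20, 0.10))
  n_pub <- stats::rpois(n, 0.8)
  pubs <- vapply(n_pub, function(k) {
    if (k == 0) return("")
    paste(sprintf("%d:%s", sample(10000000:99999999, k),
                  sample(DEFAULT_PUBLISHERS[1:4], k, replace = TRUE)),
          collapse = "|")
  }, character(1))
  clinvar <- tibble::tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, gene = v$gene,
    consequence = v$consequence, clinical_significance = significance,
    review_stars = stars,
    last_update_year = sample(2005:2020, n, replace = TRUE),
    n_submissions = 1L + stats::rpois(n, 2),
    publications = pubs
  )[has_cv, ]

  # COSMIC: log-uniform sample counts, class shift scaled by separation
  has_co <- runif(n) < cov[["cosmic"]]
  expo <- runif(n, 0, 2) + ifelse(path, 4 * sep * runif(n), 0)
  resid <- (v$pos %% 500L) + 1L
  cosmic <- tibble::tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, gene = v$gene,
    protein_change = sprintf("p.%s%d%s", sample(AA1, n, replace = TRUE),
                             resid, sample(c(AA1, "*"), n, replace = TRUE)),
    sample_count = pmax(1L, as.integer(round(10^expo))),
    publications = vapply(stats::rpois(n, 0.5), function(k) {
      if (k == 0) "" else paste(sample(10000000:99999999, k), collapse = "|")
    }, character(1))
  )[has_co, ]

  # dbNSFP: beta scores, pathogenic mean = benign mean + separation
  has_db <- runif(n) < cov[["dbnsfp"]]
  algos <- c(ESTIMATION_ALGORITHMS, EXPLANATION_ALGORITHMS)
  dbnsfp <- tibble::tibble(chrom = v$chrom, pos = v$pos, ref = v$ref,
                           alt = v$alt)
  for (a in algos) {
    dbnsfp[[a]] <- rbeta_mean(n, ifelse(path, 0.40 + sep, 0.40))
  }
  dbnsfp <- dbnsfp[has_db, ]

  has_ds <- runif(n) < cov[["dbscsnv"]]
  dbscsnv <- tibble::tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    ada_score = rbeta_mean(n, ifelse(path, 0.40 + sep, 0.40)),
    rf_score = rbeta_mean(n, ifelse(path, 0.40 + sep, 0.40))
  )[has_ds, ]

  structure(list(
    config = cfg,
    variants = v[, c("key", "chrom", "pos", "ref", "alt", "gene",
                     "consequence", "true_label")],
    clinvar = clinvar, cosmic = cosmic, dbnsfp = dbnsfp, dbscsnv = dbscsnv
  ), class = "kgx_sim")
}

#' @export
print.kgx_sim <- function(x, ...) {
  cat(sprintf(
    "<kgx_sim> %d variants (%d pathogenic); clinvar %d, cosmic %d, dbnsfp %d, dbscsnv %d records\n",
    nrow(x$variants), sum(x$variants$true_label == "pathogenic"),
    nrow(x$clinvar), nrow(x$cosmic), nrow(x$dbnsfp), nrow(x$dbscsnv)
  ))
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Writes `clinvar.tsv`, `cosmic.tsv`, `dbnsfp.tsv`, `dbscsnv.tsv`,
#' `truth.tsv` (key and true label) and `provenance.json` (config and seed).
#' Byte-identical for identical configs.
#'
#' @param sim a `kgx_sim`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in c("clinvar", "cosmic", "dbnsfp", "dbscsnv")) {
    data.table::fwrite(sim[[f]], file.path(dir, paste0(f, ".tsv")), sep = "\t")
  }
  data.table::fwrite(sim$variants[, c("key", "true_label")],
                     file.path(dir, "truth.tsv"), sep = "\t")
  cfg <- unclass(sim$config)
  cfg$coverage <- as.list(cfg$coverage)
  jsonlite::write_json(cfg, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Realized planted-signal summary
#'
#' Reports the class separation actually realized in a simulated dataset:
#' the mean dbNSFP score gap between classes (over the estimation
#' algorithms), the concordance of true labels between neighbor pairs within
#' 100 bases, and per-source annotation coverage.
#'
#' @param sim a `kgx_sim`.
#' @return list with `score_gap`, `neighbor_concordance`, `coverage`.
#' @export
planted_signal_report <- function(sim) {
  v <- sim$variants
  db <- sim$dbnsfp
  gap <- NA_real_
  if (nrow(db)) {
    keys <- canonical_variant_key(db$chrom, db$pos, db$ref, db$alt)
    lab <- v$true_label[match(keys, v$key)]
    sc <- rowMeans(as.matrix(db[, ESTIMATION_ALGORITHMS]))
    gap <- mean(sc[lab == "pathogenic"]) - mean(sc[lab == "benign"])
  }
  dt <- data.table::as.data.table(v)
  data.table::setorderv(dt, c("chrom", "pos"))
  same <- dt$chrom[-1] == dt$chrom[-nrow(dt)] &
    dt$pos[-1] - dt$pos[-nrow(dt)] <= 100
  conc <- if (any(same)) {
    mean((dt$true_label[-1] == dt$true_label[-nrow(dt)])[same])
  } else NA_real_
  nv <- nrow(v)
  list(
    score_gap = gap,
    neighbor_concordance = conc,
    coverage = c(
      clinvar = nrow(sim$clinvar) / nv, cosmic = nrow(sim$cosmic) / nv,
      dbnsfp = nrow(sim$dbnsfp) / nv, dbscsnv = nrow(sim$dbscsnv) / nv
    )
  )
}

#' Assemble a simulated dataset for cross-validation
#'
#' Convenience wrapper: [records_to_kg()] + [variant_index()] +
#' [build_estimation_answer_set()] + [balance_classes()] on a `kgx_sim`.
#'
#' @param sim a `kgx_sim`.
#' @param balance_seed seed for class balancing (`NULL` to skip).
#' @return list with `kg`, `index`, `answers` (see [cross_validate()]).
#' @export
sim_dataset <- function(sim, balance_seed = 1L) {
  assemble_dataset(sim$clinvar, sim$cosmic, sim$dbnsfp, sim$dbscsnv,
                   variants = sim$variants, balance_seed = balance_seed)
}
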