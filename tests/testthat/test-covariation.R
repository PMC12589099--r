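make_mats <- function(n = 10, x = NULL, y = NULL) {
  x <- x %||% seq_len(n)
  p <- matrix(x, ncol = 1, dimnames = list(paste0("s", seq_along(x)), "P1"))
  m <- matrix(y, ncol = 1, dimnames = list(paste0("s", seq_along(y)), "M1"))
  list(p = p, m = m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Pearson records match identity, anti-linearity and a hand case", {
  d <- make_mats(x = 1:10, y = 1:10)
  rec <- correlate_all(d$p, d$m, min_obs = 3)
  expect_equal(rec$r, 1, tolerance = 1e-12)
  expect_gt(rec$p, 0)                     # clamped to a representable value

  d2 <- make_mats(x = 1:10, y = -2 * (1:10) + 3)
  expect_equal(correlate_all(d2$p, d2$m, min_obs = 3)$r, -1, tolerance = 1e-12)

  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  d3 <- make_mats(x = x, y = y)
  rec3 <- correlate_all(d3$p, d3$m, min_obs = 3)
  expect_equal(rec3$r, pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(rec3$r, 10 / sqrt(10 * 14.8), tolerance = 1e-12)
  # p matches the correlation t-test
  expect_equal(rec3$p, cor.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("pairwise-complete handling matches cor.test on masked data", {
  set.seed(5)
  p <- matrix(rnorm(200), 40, 5, dimnames = list(paste0("s", 1:40),
                                                 paste0("P", 1:5)))
  m <- matrix(rnorm(120), 40, 3, dimnames = list(paste0("s", 1:40),
                                                 paste0("M", 1:3)))
  p[sample(200, 25)] <- NA
  m[sample(120, 15)] <- NA
  rec <- correlate_all(p, m, min_obs = 5)
  for (i in sample(nrow(rec), 6)) {
    x <- p[, rec$protein_id[i]]; y <- m[, rec$metabolite_id[i]]
    ok <- !is.na(x) & !is.na(y)
    ct <- cor.test(x[ok], y[ok])
    expect_equal(rec$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(rec$p[i], ct$p.value, tolerance = 1e-10)
    expect_equal(rec$n_obs[i], sum(ok))
  }
})

test_that("r is invariant under affine rescaling of either feature", {
  set.seed(8)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  d1 <- make_mats(x = x, y = y)
  d2 <- make_mats(x = 3 * x - 7, y = -2 * y + 1)
  r1 <- correlate_all(d1$p, d1$m, min_obs = 3)$r
  r2 <- correlate_all(d2$p, d2$m, min_obs = 3)$r
  expect_equal(abs(r1), abs(r2), tolerance = 1e-12)
})

test_that("pairs below min_obs or with zero variance are omitted", {
  p <- matrix(c(1:8, rep(5, 8)), 8, 2,
              dimnames = list(paste0("s", 1:8), c("P1", "Pconst")))
  m <- matrix(c(1:5, NA, NA, NA), 8, 1,
              dimnames = list(paste0("s", 1:8), "M1"))
  rec <- suppressMessages(correlate_all(p, m, min_obs = 6))
  expect_equal(nrow(rec), 0)
  rec2 <- suppressMessages(correlate_all(p, m, min_obs = 5))
  expect_equal(rec2$protein_id, "P1")   # constant feature dropped
})

test_that("BH adjustment equals the step-up oracle", {
  one <- data.frame(tissue = "t", protein_id = "P", metabolite_id = "M",
                    n_obs = 10L, r = .5, p = 0.03, p_adj = NA_real_,
                    significant = NA, sign_class = NA_character_)
  expect_equal(adjust_bh(one)$p_adj, 0.03)

  recs <- data.frame(tissue = "t", protein_id = paste0("P", 1:4),
                     metabolite_id = "M", n_obs = 10L, r = 1,
                     p = c(.01, .02, .03, .04), p_adj = NA_real_,
                     significant = NA, sign_class = NA_character_)
  expect_equal(adjust_bh(recs)$p_adj, rep(0.04, 4))

  tied <- recs; tied$p <- rep(0.02, 4)
  expect_equal(adjust_bh(tied)$p_adj, rep(0.02, 4))

  set.seed(1)
  for (i in 1:25) {
    p <- runif(sample(1:400, 1))^sample(1:3, 1)
    rr <- data.frame(tissue = "t", protein_id = seq_along(p),
                     metabolite_id = "M", n_obs = 10L, r = 1, p = p,
                     p_adj = NA_real_, significant = NA,
                     sign_class = NA_character_)
    expect_equal(adjust_bh(rr)$p_adj, bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("per-tissue and pooled BH families differ as documented", {
  recs <- data.frame(tissue = rep(c("a", "b"), each = 3),
                     protein_id = paste0("P", 1:6), metabolite_id = "M",
                     n_obs = 10L, r = 1,
                     p = c(.01, .2, .9, .001, .002, .003),
                     p_adj = NA_real_, significant = NA,
                     sign_class = NA_character_)
  per <- adjust_bh(recs, family = "per_tissue")
  pooled <- adjust_bh(recs, family = "pooled")
  expect_equal(per$p_adj[1:3], bh_oracle(c(.01, .2, .9)))
  expect_equal(pooled$p_adj, bh_oracle(recs$p))
})

test_that("cooperativity counting de-duplicates pairs across tissues", {
  recs <- data.frame(
    tissue = c("a", "b", "a", "b"),
    protein_id = c("P1", "P1", "P2", "P3"),
    metabolite_id = c("M1", "M1", "M1", "M1"),
    n_obs = 10L, r = c(.9, .8, -.7, .6),
    p = 1e-6, p_adj = 1e-5, significant = TRUE,
    sign_class = c("co-operative", "co-operative", "antagonistic",
                   "co-operative"))
  s <- classify_cooperativity(recs)
  expect_equal(s$pooled$n_significant_unique_pairs, 3)
  expect_equal(s$pooled$n_cooperative, 3)
  expect_equal(s$pooled$n_antagonistic, 1)
  expect_equal(s$per_tissue$n_cooperative[s$per_tissue$tissue == "a"], 1)

  none <- recs; none$significant <- FALSE; none$sign_class <- "none"
  s0 <- classify_cooperativity(none)
  expect_equal(s0$pooled$n_significant_unique_pairs, 0)
  expect_equal(s0$pooled$n_cooperative, 0)
})

test_that("false-positive control holds on an all-null cohort", {
  cfg <- cohort_config(n_individuals = 60, n_proteins = 120,
                       n_metabolites = 40, n_latent_factors = 5,
                       planted = lapply(1:40, function(i) planted_null(i, i)),
                       missing_rate = 0, seed = 23, tissue_labels = "liver")
  sim <- simulate_cohort(cfg)
  recs <- adjust_bh(correlate_all(sim$proteins$liver, sim$metabolites$liver,
                                  min_obs = 20, tissue = "liver"))
  n <- nrow(recs)
  expect_lte(mean(recs$significant), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("planted edges are recovered as significant with the right sign", {
  hits <- 0; signs <- 0; nseed <- 40
  for (s in seq_len(nseed)) {
    cfg <- cohort_config(n_individuals = 150, n_proteins = 30,
                         n_metabolites = 3,
                         planted = list(planted_enzyme(1, 1, -1)),
                         noise_sd_protein = 0.3, noise_sd_metabolite = 0.3,
                         missing_rate = 0, seed = 100 + s,
                         tissue_labels = "liver")
    sim <- simulate_cohort(cfg)
    recs <- adjust_bh(correlate_all(sim$proteins$liver,
                                    sim$metabolites$liver,
                                    min_obs = 20, tissue = "liver"))
    rec <- recs[recs$protein_id == "P0001" & recs$metabolite_id == "M001", ]
    hits <- hits + rec$significant
    signs <- signs + (rec$sign_class == "antagonistic")
  }
  expect_gte(hits / nseed, 0.95)
  expect_gte(signs / nseed, 0.95)
})

test_that("contaminant flagging removes signature features and their clones", {
  set.seed(4)
  n <- 40
  base <- matrix(rnorm(n * 30, sd = .3), n, 30,
                 dimnames = list(NULL, sprintf("P%02d", 1:30)))
  contam <- rnorm(n, sd = 3)                # large shared variance block
  base[, "P01"] <- contam + rnorm(n, sd = .05)
  base[, "P02"] <- base[, "P01"]            # exact clone, dragged along
  qc <- flag_contaminant_proteins(base, signature = "P01",
                                  loading_quantile = 0.05)
  expect_true("P01" %in% qc$removed_feature_ids)
  expect_true("P02" %in% qc$removed_feature_ids)
  expect_equal(unname(qc$removal_reason[["P01"]]), "signature_overlap")
  expect_equal(unname(qc$removal_reason[["P02"]]), "correlated_with_removed")

  # PC1 top set agrees with a dense eigendecomposition oracle
  cc <- scale(base, scale = FALSE)
  ev <- eigen(crossprod(cc) / (n - 1))$vectors[, 1]
  names(ev) <- colnames(base)
  top_oracle <- names(sort(abs(ev), decreasing = TRUE))[1:2]
  top_pkg <- names(sort(abs(qc$pc1_loading), decreasing = TRUE))[1:2]
  expect_setequal(top_oracle, top_pkg)

  expect_warning(
    qc2 <- flag_contaminant_proteins(base, signature = "absent"),
    "absent")
  expect_length(qc2$removed_feature_ids, 0)
})

test_that("feature CV follows the population formula, with back-transform", {
  expect_equal(unname(feature_cv(cbind(f = c(2, 2, 2)))), 0)
  expect_equal(unname(feature_cv(cbind(f = c(1, 2, 3)))),
               sqrt(2 / 3) / 2, tolerance = 1e-12)
  expect_equal(unname(feature_cv(cbind(f = c(0, 1)), linearize = TRUE)),
               0.5 / 1.5, tolerance = 1e-12)
  expect_error(feature_cv(cbind(f = c(-1, 2))), "positive")
})
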