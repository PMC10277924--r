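test_that("harmonization aligns, flips, and drops records correctly", {
  ex <- data.frame(variant = c("v1", "v2", "v3", "v4"),
                   effect_allele = c("A", "A", "A", "C"),
                   other_allele = c("G", "G", "T", "T"),
                   beta = c(0.5, 0.3, 0.2, 0.1), se = rep(0.05, 4))
  ou <- data.frame(variant = c("v1", "v2", "v3", "v4"),
                   effect_allele = c("G", "A", "A", "C"),
                   other_allele = c("A", "G", "T", "A"),
                   beta = c(-0.2, 0.1, 0.4, 0.2), se = rep(0.06, 4))
  h <- harmonize(ex, ou)
  # v1: swapped alleles -> outcome beta flips to +0.2 on the A/G convention
  expect_equal(h$beta_outcome[h$variant == "v1"], 0.2)
  expect_equal(h$effect_allele[h$variant == "v1"], "A")
  # v2 already aligned: untouched
  expect_equal(h$beta_outcome[h$variant == "v2"], 0.1)
  # v3 palindromic (A/T): dropped
  expect_false("v3" %in% h$variant)
  # v4 allele mismatch (C/T vs C/A): dropped
  expect_false("v4" %in% h$variant)
  dropped <- attr(h, "dropped")
  expect_setequal(dropped$reason[dropped$variant == "v3"], "palindromic")
  expect_setequal(dropped$reason[dropped$variant == "v4"], "allele_mismatch")
  # re-harmonizing harmonized data is the identity
  ex2 <- data.frame(variant = h$variant, effect_allele = h$effect_allele,
                    other_allele = h$other_allele, beta = h$beta_exposure,
                    se = h$se_exposure)
  ou2 <- data.frame(variant = h$variant, effect_allele = h$effect_allele,
                    other_allele = h$other_allele, beta = h$beta_outcome,
                    se = h$se_outcome)
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$beta_outcome, h$beta_outcome)
  expect_equal(h2$beta_exposure, h$beta_exposure)
})

test_that("IVW matches the hand-computed two-instrument example and the Wald ratio", {
  iv2 <- data.frame(beta_exposure = c(0.5, 0.5), se_exposure = c(0.01, 0.01),
                    beta_outcome = c(0.1, 0.1), se_outcome = c(0.1, 0.1))
  res <- mr_ivw(iv2)
  expect_equal(res$estimate, 0.2, tolerance = 1e-12)
  expect_equal(res$se, 1 / sqrt(50), tolerance = 1e-12)
  # single IV reduces to the Wald ratio
  iv1 <- iv2[1, ]
  res1 <- mr_ivw(iv1)
  expect_equal(res1$estimate, 0.1 / 0.5)
  expect_equal(res1$se, 0.1 / 0.5)
  expect_identical(res1$method, "wald")
  # J identical copies equal the single-IV Wald ratio
  ivJ <- iv2[rep(1, 5), ]
  expect_equal(mr_ivw(ivJ)$estimate, res1$estimate, tolerance = 1e-12)
})

test_that("IVW recovers a planted causal effect with nominal CI coverage", {
  theta <- 0.163
  bx <- c(0.05, 0.04, 0.06, 0.05, 0.045, 0.055)   # 6 strong instruments
  est <- numeric(300); cover <- logical(300)
  for (s in 1:300) {
    iv <- iv_scenario(bx, theta, se_x = 5e-4, se_y = 0.003, seed = 3000 + s)
    r <- mr_ivw(iv)
    est[s] <- r$estimate
    cover[s] <- r$ci[1] <= theta && theta <= r$ci[2]
  }
  expect_lt(abs(mean(est) - theta), 3 * sd(est) / sqrt(300))
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("null causal effect gives nominal CI coverage of zero", {
  cover <- vapply(1:300, function(s) {
    iv <- iv_scenario(c(0.05, 0.06, 0.04, 0.05), theta = 0,
                      se_x = 5e-4, se_y = 0.004, seed = 4000 + s)
    r <- mr_ivw(iv)
    r$ci[1] <= 0 && 0 <= r$ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.95 * 0.05 / 300))
  expect_lt(mean(cover), 0.95 + 3 * sqrt(0.95 * 0.05 / 300))
})

test_that("Egger regression matches closed-form WLS and detects pleiotropy", {
  # three equally weighted points on an exact line: by = 0.5 bx - 0.05
  iv3 <- data.frame(beta_exposure = c(0.2, 0.4, 0.6),
                    se_exposure = rep(0.01, 3),
                    beta_outcome = c(0.05, 0.15, 0.25),
                    se_outcome = rep(0.1, 3))
  res <- mr_egger(iv3)
  expect_equal(res$estimate, 0.5, tolerance = 1e-10)
  expect_equal(res$intercept, -0.05, tolerance = 1e-10)
  expect_error(mr_egger(iv3[1:2, ]), "at least 3")
  # collinear points through the origin: zero intercept, exact slope
  iv0 <- data.frame(beta_exposure = c(0.1, 0.2, 0.3),
                    se_exposure = rep(0.01, 3),
                    beta_outcome = c(0.03, 0.06, 0.09),
                    se_outcome = rep(0.1, 3))
  r0 <- mr_egger(iv0)
  expect_equal(r0$estimate, 0.3, tolerance = 1e-10)
  expect_equal(r0$intercept, 0, tolerance = 1e-12)
  # planted directional pleiotropy +0.05 with 20 strong IVs
  set.seed(111)
  iv20 <- iv_scenario(runif(20, 0.03, 0.10), theta = 0.2,
                      se_x = 5e-4, se_y = 0.002, pleiotropy = 0.05,
                      seed = 112)
  rp <- mr_egger(iv20)
  expect_lt(abs(rp$intercept - 0.05), 0.01)
  expect_lt(rp$intercept_p, 0.05)
})

test_that("Egger orientation flips exposure-outcome pairs jointly", {
  set.seed(113)
  iv <- iv_scenario(c(0.05, -0.04, 0.06, -0.05, 0.045), theta = 0.3,
                    se_x = 5e-4, se_y = 0.002, seed = 114)
  r <- mr_egger(iv)
  iv_flipped <- iv
  iv_flipped$beta_exposure <- -iv$beta_exposure
  iv_flipped$beta_outcome <- -iv$beta_outcome
  expect_equal(mr_egger(iv_flipped)$estimate, r$estimate, tolerance = 1e-12)
})

test_that("the PRESSO global test is calibrated, flags outliers, and is seed-deterministic", {
  # calibration: data generated exactly under the no-pleiotropy model
  ps <- vapply(1:60, function(s) {
    iv <- iv_scenario(runif(8, 0.03, 0.08), theta = 0.2,
                      se_x = 0.002, se_y = 0.02, seed = 5000 + s)
    mr_presso(iv, n_sim = 300, seed = 6000 + s)$global_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  # a displaced instrument is detected and flagged
  set.seed(115)
  iv <- iv_scenario(runif(10, 0.03, 0.08), theta = 0.2,
                    se_x = 0.002, se_y = 0.02, seed = 116)
  iv$beta_outcome[4] <- iv$beta_outcome[4] + 10 * iv$se_outcome[4]
  r <- mr_presso(iv, n_sim = 500, seed = 117)
  expect_lt(r$global_p, 0.05)
  expect_true(r$outliers[4])
  # determinism under a fixed seed
  r2 <- mr_presso(iv, n_sim = 500, seed = 117)
  expect_identical(r$global_p, r2$global_p)
  expect_error(mr_presso(iv[1:3, ], n_sim = 100, seed = 1), "at least 4")
})

test_that("the IV cascade rules act on constructed candidates", {
  # two candidates in strong LD: the better joint-ranked one is kept
  set.seed(119)
  n <- 300
  anchor <- rbinom(n, 2, 0.3)
  noisy <- ifelse(runif(n) < 0.95, anchor, rbinom(n, 2, 0.3))
  dos <- cbind(vA = anchor, vB = noisy)
  coords <- data.frame(gene = "gX", chrom = "chr1", start = 5e6, end = 5.02e6,
                       strand = "+")
  expr <- matrix(0.8 * anchor + rnorm(n), 1, n, dimnames = list("gX", NULL))
  vi <- data.frame(variant = c("vA", "vB"), chrom = "chr1",
                   pos = c(5.005e6, 5.01e6))
  eq <- map_cis_eqtls(expr, dos, coords, vi)
  mkstats <- function(beta, p) {
    data.frame(variant = c("vA", "vB"), chrom = "chr1",
               pos = c(5.005e6, 5.01e6),
               effect_allele = "A", other_allele = "G",
               beta = beta, se = 0.005, p = p)
  }
  exposure <- mkstats(c(0.05, 0.048), c(1e-20, 1e-18))
  outcome <- mkstats(c(0.008, 0.008), c(0.5, 0.5))
  iv <- select_ivs("gX", eq, exposure, outcome, dos, coords)
  expect_false(iv$failed)
  expect_equal(nrow(iv$ivs), 1)
  expect_equal(iv$ivs$variant, "vA")   # better eQTL and GWAS ranks
  # region whose best exposure hit misses genome-wide significance: excluded
  weak <- mkstats(c(0.01, 0.01), c(1e-6, 1e-6))
  iv2 <- select_ivs("gX", eq, weak, outcome, dos, coords)
  expect_true(iv2$failed)
  expect_equal(iv2$audit$candidate_regions, 0)
  # exposure hit contaminated by an outcome hit: excluded
  contaminated <- mkstats(c(0.05, 0.05), c(1e-20, 1e-20))
  out_hit <- mkstats(c(0.05, 0.05), c(1e-12, 1e-12))
  iv3 <- select_ivs("gX", eq, contaminated, out_hit, dos, coords)
  expect_true(iv3$failed)
  # failure state refuses estimation
  expect_error(mr_ivw(iv3), "failure state")
})
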