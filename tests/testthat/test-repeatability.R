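test_that("consistency ICC is 1 for identical and for offset columns", {
  set.seed(1)
  a <- rnorm(10)
  expect_equal(as.numeric(icc_consistency(cbind(a, a))), 1)
  # a constant session offset is a systematic difference: not penalised
  expect_equal(as.numeric(icc_consistency(cbind(a, a + 5))), 1)
  # the absolute-agreement variant does penalise it
  expect_lt(as.numeric(icc_consistency(cbind(a, a + 5), type = "agreement")), 1)
})

test_that("consistency ICC converges to the variance-component ratio", {
  set.seed(2)
  S <- 5000
  u <- rnorm(S, 0, 1)
  y <- cbind(u + rnorm(S), u + rnorm(S))   # sigma_u^2 = sigma_e^2 -> ICC 0.5
  expect_lt(abs(as.numeric(icc_consistency(y)) - 0.5), 0.03)
})

test_that("consistency ICC agrees with the aov mean-squares oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    S <- 8 + seed; k <- 2 + seed %% 3
    x <- matrix(rnorm(S * k), S, k) + rnorm(S)
    expect_equal(as.numeric(icc_consistency(x)), oracle_icc_aov(x),
                 tolerance = 1e-10, label = paste("seed", seed))
  }
})

test_that("rows with missing values are dropped and counted", {
  set.seed(3)
  x <- matrix(rnorm(20), 10, 2)
  x[3, 1] <- NA; x[7, 2] <- NA
  est <- icc_consistency(x)
  expect_identical(attr(est, "n_dropped"), 2L)
  expect_identical(attr(est, "n_subjects"), 8L)
  expect_equal(as.numeric(est), as.numeric(icc_consistency(x[-c(3, 7), ])))
})

test_that("zero total variance yields an undefined estimate with a diagnostic", {
  est <- icc_consistency(matrix(1, 5, 2))
  expect_true(is.na(est))
  expect_match(attr(est, "message"), "variance")
})

test_that("vectorised ICC field matches the scalar estimator voxel by voxel", {
  set.seed(4)
  a <- array(rnorm(50 * 12 * 3), c(50, 12, 3))
  f <- icc_field(a)
  for (v in c(1, 17, 50))
    expect_equal(f[v], as.numeric(icc_consistency(a[v, , ])),
                 tolerance = 1e-12)
})

test_that("mode of ICC is the centre of the fullest of 80 bins", {
  # point mass at 0.5 lies in bin [0.5, 0.5125): centre 0.50625
  expect_equal(mode_of_icc(rep(0.5, 100)), 0.50625)
  # values <= 0 are excluded
  expect_equal(mode_of_icc(c(rep(0.5, 10), rep(-0.3, 500), rep(0, 50))),
               0.50625)
  # bimodal with more mass near 0.8
  expect_equal(mode_of_icc(c(rep(0.2, 40), rep(0.8, 60))),
               mode_of_icc(rep(0.8, 5)))
  # no positive values: undefined
  expect_true(is.na(mode_of_icc(c(-0.1, 0))))
  # ICC = 1 falls in the last bin
  expect_equal(mode_of_icc(rep(1, 5)), 1 - 0.0125 / 2)
})

test_that("voxelwise mode recovers a planted ICC level from simulated volumes", {
  set.seed(5)
  nvox <- 4000; S <- 40
  # sigma_u^2 = 1.5, sigma_e^2 = 1 -> true ICC 0.6
  u <- matrix(rnorm(nvox * S, 0, sqrt(1.5)), nvox, S)
  a <- array(NA_real_, c(nvox, S, 2))
  for (t in 1:2) a[, , t] <- u + matrix(rnorm(nvox * S), nvox, S)
  res <- voxelwise_icc_mode(a)
  expect_lt(abs(res$mode - 0.6), 0.05)
  expect_gt(res$n_positive, nvox * 0.9)
})

test_that("collapsing reports ICC 1 at every level for duplicated columns", {
  sim <- make_session_scores(n_subjects = 8, sigma_e = 0, sigma_session = 0,
                             items = expand.grid(ic = c("IC1", "IC2"),
                                                 basemap = c("A", "B"),
                                                 metric = "I",
                                                 stringsAsFactors = FALSE),
                             seed = 6)
  for (lvl in c("per_item", "per_basemap", "global")) {
    est <- collapse_and_estimate(sim$scores, level = lvl, flavour = "within")
    expect_true(all(abs(est$icc - 1) < 1e-9), label = lvl)
  }
})

test_that("pooled ICC lies strictly between the per-item extremes", {
  set.seed(7)
  S <- 60
  u <- rnorm(S)
  # item 1: perfectly consistent; item 2: pure noise
  df <- rbind(
    data.frame(subject = rep(1:S, 2), session = rep(2:3, each = S),
               ic = "IC1", basemap = "A", metric = "I",
               value = c(u, u)),
    data.frame(subject = rep(1:S, 2), session = rep(2:3, each = S),
               ic = "IC2", basemap = "A", metric = "I",
               value = rnorm(2 * S)))
  per_item <- collapse_and_estimate(df, "per_item", "within")
  pooled <- collapse_and_estimate(df, "per_basemap", "within")
  expect_gt(pooled$icc, min(per_item$icc))
  expect_lt(pooled$icc, max(per_item$icc))
})

test_that("collapsing is pure aggregation: per-item estimates are unchanged", {
  sim <- make_session_scores(n_subjects = 10, sigma_u = 1, sigma_e = 1,
                             items = expand.grid(ic = paste0("IC", 1:3),
                                                 basemap = c("A", "B"),
                                                 metric = "I",
                                                 stringsAsFactors = FALSE),
                             seed = 8)
  before <- collapse_and_estimate(sim$scores, "per_item", "within")
  invisible(collapse_and_estimate(sim$scores, "global", "within"))
  after <- collapse_and_estimate(sim$scores, "per_item", "within")
  expect_identical(before, after)
})

test_that("between-session ICC stacks the baseline-vs-later pairings", {
  sim <- make_session_scores(n_subjects = 200, n_sessions = 3,
                             sigma_u = 1, sigma_day = 1, sigma_e = 0.5,
                             seed = 9)
  est_w <- collapse_and_estimate(sim$scores, "per_item", "within")
  est_b <- collapse_and_estimate(sim$scores, "per_item", "between")
  expect_equal(est_w$icc, sim$true_icc_within, tolerance = 0.08)
  expect_equal(est_b$icc, sim$true_icc_between, tolerance = 0.08)
  expect_gt(est_w$icc, est_b$icc)
  # between uses twice the rows (two stacked pairings)
  expect_equal(est_b$n_rows, 2L * est_w$n_rows)
})

test_that("undefined score cells are dropped pairwise with the count surfaced", {
  sim <- make_session_scores(n_subjects = 10, seed = 10)
  sc <- sim$scores
  sc$value[sc$subject == 3 & sc$session == 2] <- NA
  est <- collapse_and_estimate(sc, "per_item", "within")
  expect_identical(est$n_dropped, 1L)
  expect_gt(est$undefined_fraction, 0)
})

test_that("top-k agreement counts shared top base maps deterministically", {
  a <- c(A = 0.9, B = 0.8, C = 0.7, D = 0.1, E = 0.0)
  expect_identical(topk_agreement(a, a, k = 3), 3L)
  b <- c(A = 0.0, B = 0.0, C = 0.1, D = 0.9, E = 0.8)
  expect_identical(topk_agreement(a, b, k = 2), 0L)
  # tie at rank k: lowest index wins in both rankings
  tie <- c(A = 0.5, B = 0.5, C = 0.5, D = 0.1, E = 0.1)
  expect_identical(topk_agreement(tie, tie, k = 2), 2L)
  expect_error(topk_agreement(a, b, k = 6), "k")
  # correspondence mapping translates name spaces
  b2 <- c(x = 0.9, y = 0.8, z = 0, w = 0, v = 0)
  mp <- c(x = "A", y = "B", z = "C", w = "D", v = "E")
  expect_identical(topk_agreement(a, b2, k = 2, mapping = mp), 2L)
})

test_that("mean top-k agreement of random rankings matches k^2/K", {
  set.seed(11)
  K <- 10L; k <- 3L
  agree <- replicate(1500, topk_agreement(
    setNames(runif(K), paste0("c", 1:K)),
    setNames(runif(K), paste0("c", 1:K)), k = k))
  # E[|topA n topB|] = k^2/K for independent uniform rankings
  expect_equal(mean(agree), k^2 / K, tolerance = 0.06)
})
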