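test_that("a map identical to one disjoint base map scores perfect overlap", {
  at <- tiny_atlas(seed = 4, K = 3L)
  s <- atlas_summary(at)
  expect_identical(s$n_labelled, s$n_binary)  # disjoint fixture
  v <- array(0, at$geometry$shape)
  v[at$binary[, , , 1]] <- 5
  la <- label_activation(stat_map(v, at$geometry), at)
  sp <- spatial_metrics(la, at)
  expect_equal(sp$icn$I[1], 1)
  expect_equal(sp$icn$J[1], 1)
  expect_equal(sp$icn$SQ[1], 1)
  expect_equal(sp$icn$OL[1], 1)
  expect_equal(sp$icn$IR[1], 1)
  expect_equal(sp$icn$I[2:3], c(0, 0))
  # labelled counts only come from voxels labelled 1
  expect_identical(la$n_label, la$n_binary)
})

test_that("empty activation gives zero counts and undefined ratios", {
  at <- tiny_atlas(seed = 4, K = 3L)
  v <- array(0, at$geometry$shape)
  la <- label_activation(stat_map(v, at$geometry), at)
  expect_identical(la$n_binary, c(0L, 0L, 0L))
  sp <- spatial_metrics(la, at)
  expect_equal(sp$icn$I, c(0, 0, 0))
  expect_true(all(is.na(sp$icn$IR)))   # no active ICN voxel: undefined
  expect_true(all(is.na(sp$icn$OL)))   # empty map: undefined
})

test_that("spatial metrics reproduce the arithmetic example |A|=10, |ICN|=20, inter=5", {
  # grid engineered so that counts are exactly as stated
  z <- array(0, c(30, 1, 1, 1))
  z[1:20, 1, 1, 1] <- 10                      # ICN_1: 20 voxels
  at <- build_atlas(zmap_set(z), 3)
  v <- array(0, c(30, 1, 1))
  v[16:25, 1, 1] <- 5                         # activation: 10 voxels, 5 inside
  la <- label_activation(stat_map(v, at$geometry), at)
  sp <- spatial_metrics(la, at)
  expect_equal(sp$icn$I[1], 0.25)
  expect_equal(sp$icn$OL[1], 0.5)
  expect_equal(sp$icn$J[1], 0.2)
  expect_equal(sp$icn$SQ[1], 1 / 3)
  expect_equal(sp$icn$SQ[1], 2 * sp$icn$J[1] / (1 + sp$icn$J[1]))
})

test_that("I_T is the size-weighted mean of the per-component involvements", {
  z <- array(0, c(40, 1, 1, 2))
  z[1:10, 1, 1, 1] <- 10                      # ICN_1: 10 voxels
  z[11:40, 1, 1, 2] <- 10                     # ICN_2: 30 voxels
  at <- build_atlas(zmap_set(z), 3)
  v <- array(0, c(40, 1, 1))
  v[c(1, 11:13), 1, 1] <- 5                   # intersections 1 and 3
  sp <- spatial_metrics(label_activation(stat_map(v, at$geometry), at), at)
  expect_equal(sp$icn$I, c(0.1, 0.1))
  expect_equal(unname(sp$global["I_T"]), 4 / 40)
})

test_that("two-voxel normalised mean activation follows the hand evaluation", {
  z <- array(0, c(6, 1, 1, 1))
  z[1:2, 1, 1, 1] <- 10
  at <- build_atlas(zmap_set(z), 3)
  lo <- 4; hi <- 9; delta <- 1.5
  v <- array(NA_real_, c(6, 1, 1))
  v[1, 1, 1] <- lo + delta; v[2, 1, 1] <- hi
  v[3, 1, 1] <- lo                            # outside the ICN, sets the min
  la <- label_activation(stat_map(v, at$geometry), at)
  av <- activation_metrics(la, at)
  numer <- (delta + (hi - lo)) / (hi - lo)
  expect_equal(av$icn$MA_N[1], numer / 2)
})

test_that("all active voxels at the map maximum give MA_N = RA_N = 1", {
  z <- array(0, c(5, 1, 1, 1)); z[1:3, 1, 1, 1] <- 10
  at <- build_atlas(zmap_set(z), 3)
  v <- array(NA_real_, c(5, 1, 1))
  v[1:3, 1, 1] <- 8; v[5, 1, 1] <- 2          # min set outside the ICN
  av <- activation_metrics(label_activation(stat_map(v, at$geometry), at), at)
  expect_equal(av$icn$MA_N[1], 1)
  expect_equal(av$icn$RA_N[1], 1)
})

test_that("every metric matches the per-voxel accumulation oracle on random cases", {
  for (seed in 1:20) {
    K <- 2L + (seed %% 3L)
    shape <- c(8L, 8L, 8L)
    zm <- random_zmaps(shape, K, seed = seed + 100)
    at <- build_atlas(zm, 3)
    if (any(component_sizes <- atlas_summary(at)$n_binary == 0)) next
    v <- random_values(shape, seed = seed)
    m <- stat_map(v, at$geometry)
    la <- label_activation(m, at)
    sp <- spatial_metrics(la, at)
    av <- activation_metrics(la, at)
    oc <- oracle_engagement(v, at)
    for (col in c("I", "IR", "OL", "SQ", "J"))
      expect_equal(sp$icn[[col]], oc$icn[[col]], tolerance = 1e-12,
                   label = paste("seed", seed, col))
    for (col in c("MA", "MA_N", "RA_N", "IR_M", "I_M", "r"))
      expect_equal(av$icn[[col]], oc$icn[[col]], tolerance = 1e-12,
                   label = paste("seed", seed, col))
    expect_equal(unname(sp$global["I_T"]), unname(oc$global["I_T"]),
                 tolerance = 1e-12)
    expect_equal(av$global[c("MA", "MA_N", "I_T_M")],
                 oc$global[c("MA", "MA_N", "I_T_M")], tolerance = 1e-12)
  }
})

test_that("metric identities and bounds hold across random fixtures", {
  for (seed in 21:35) {
    at <- tiny_atlas(seed = seed, K = 3L)
    af <- make_activation_fixture(at, runif(3), n_distractors = 10, seed = seed)
    tab <- engage(af$map, at)
    with(tab$icn, {
      expect_equal(SQ, 2 * J / (1 + J), tolerance = 1e-12)
      expect_true(all(I >= 0 & I <= 1))
      expect_true(all(OL >= 0 & OL <= 1, na.rm = TRUE))
      expect_true(all(J >= 0 & J <= 1))
      expect_true(all(SQ >= 0 & SQ <= 1))
      expect_true(all(MA_N >= 0 & MA_N <= 1, na.rm = TRUE))
      if (any(!is.na(IR))) expect_equal(sum(IR), 1, tolerance = 1e-12)
      if (any(!is.na(RA_N))) expect_equal(sum(RA_N), 1, tolerance = 1e-12)
    })
    it <- unname(tab$global["I_T"])
    expect_true(min(tab$icn$I) - 1e-12 <= it && it <= max(tab$icn$I) + 1e-12)
  }
})

test_that("growing the activation never decreases involvement", {
  at <- tiny_atlas(seed = 50, K = 3L)
  af1 <- make_activation_fixture(at, c(0.3, 0.3, 0.3), seed = 1)
  v2 <- af1$map$values
  extra <- which(v2 == 0 & as.vector(at$binary[, , , 1]))[1:5]
  v2[extra] <- 6
  t1 <- engage(af1$map, at)
  t2 <- engage(stat_map(v2, at$geometry), at)
  expect_true(all(t2$icn$I >= t1$icn$I - 1e-12))
  expect_true(t2$global["I_T"] >= t1$global["I_T"])
})

test_that("I-family metrics are invariant under rescaling of the statistic", {
  at <- tiny_atlas(seed = 60, K = 3L)
  af <- make_activation_fixture(at, c(0.4, 0.6, 0.2), seed = 3)
  t1 <- engage(af$map, at, input_threshold = 3)
  v2 <- af$map$values * 2          # affine rescale keeps active set (thr 3 < 2*5)
  t2 <- engage(stat_map(v2, at$geometry), at, input_threshold = 3)
  for (col in c("I", "IR", "OL", "SQ", "J"))
    expect_equal(t2$icn[[col]], t1$icn[[col]], tolerance = 1e-12)
  # MA_N with self-derived bounds is shift/scale covariant too
  expect_equal(t2$icn$MA_N, t1$icn$MA_N, tolerance = 1e-12)
})

test_that("engage equals the stagewise composition and respects thresholds", {
  at <- tiny_atlas(seed = 70, K = 3L)
  af <- make_activation_fixture(at, c(0.5, 0.5, 0.5), n_distractors = 15,
                                seed = 4)
  tab <- engage(af$map, at, input_threshold = 3)
  thr <- threshold_map(af$map, 3)
  la <- label_activation(thr, at, raw_values = af$map$values)
  sp <- spatial_metrics(la, at); av <- activation_metrics(la, at)
  expect_equal(tab$icn$I, sp$icn$I)
  expect_equal(tab$icn$MA_N, av$icn$MA_N)
  # unthresholded run covers at least the thresholded run's counts
  tab_raw <- engage(af$map, at, input_threshold = NULL)
  expect_true(all(tab_raw$icn$I >= tab$icn$I - 1e-12))
})

test_that("shared session bounds change MA_N but not I", {
  at <- tiny_atlas(seed = 80, K = 3L)
  af <- make_activation_fixture(at, c(0.5, 0.4, 0.3), seed = 5)
  t_own <- engage(af$map, at)
  t_shared <- engage(af$map, at, bounds = c(0, 20))
  expect_equal(t_shared$icn$I, t_own$icn$I)
  expect_false(isTRUE(all.equal(t_shared$icn$MA_N, t_own$icn$MA_N)))
})

test_that("undefined cells are explicit NA markers, never zero", {
  at <- tiny_atlas(seed = 90, K = 3L)
  af <- make_activation_fixture(at, c(0.5, 0, 0), seed = 6)
  tab <- engage(af$map, at)
  expect_true(is.na(tab$icn$MA_N[2]))   # no active voxel in component 2
  expect_true(is.na(tab$icn$MA[3]))
  tidy <- as.data.frame(tab)
  expect_false(any(tidy$defined[is.na(tidy$value)]))
})

test_that("geometry mismatch is a hard error pointing at resampling", {
  at <- tiny_atlas(seed = 95, K = 2L)
  wrong <- stat_map(array(1, c(4, 4, 4)))
  expect_error(label_activation(wrong, at), "resample_to_atlas")
})

test_that("a constant map cannot be normalised and says so", {
  at <- tiny_atlas(seed = 96, K = 2L)
  v <- array(5, at$geometry$shape)
  la <- label_activation(stat_map(v, at$geometry), at)
  expect_error(activation_metrics(la, at), "normalise|bounds")
  # explicit bounds rescue it
  av <- activation_metrics(la, at, bounds = c(0, 10))
  expect_equal(av$icn$MA_N, c(0.5, 0.5))
})

test_that("bounds that fail to bracket warn and clip into [0, 1]", {
  at <- tiny_atlas(seed = 97, K = 2L)
  af <- make_activation_fixture(at, c(1, 1), amplitude = 5, seed = 7)
  expect_warning(tab <- engage(af$map, at, bounds = c(0, 4)), "clip")
  expect_true(all(tab$icn$MA_N <= 1, na.rm = TRUE))
})

test_that("label-based counting is available and never exceeds binary counting", {
  zm <- random_zmaps(c(8L, 8L, 8L), 3L, seed = 7)
  at <- build_atlas(zm, 3)
  v <- random_values(c(8L, 8L, 8L), seed = 7)
  la <- label_activation(stat_map(v, at$geometry), at)
  expect_true(all(la$n_label <= la$n_binary))
  expect_true(sum(la$n_label) <= la$n_active)
})
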