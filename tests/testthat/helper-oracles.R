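# Independent brute-force oracles. These deliberately use per-voxel loops
# and naive accumulation, never the package's vectorised paths.

# threshold-then-argmax labelling, one voxel at a time
oracle_label_atlas <- function(z, threshold) {
  d <- dim(z)
  labels <- array(NA_integer_, d[1:3])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    zs <- z[i, j, k, ]
    zs[is.na(zs)] <- -Inf
    supra <- which(zs > threshold)
    if (length(supra))
      labels[i, j, k] <- supra[which.max(zs[supra])]
  }
  labels
}

# full engagement metric family by naive per-voxel accumulation
oracle_engagement <- function(values, atlas, bounds = NULL) {
  d <- dim(values)
  K <- dim(atlas$z)[4]
  active <- !is.na(values) & values != 0
  n_act <- sum(active)
  inter <- integer(K); stat_sum <- numeric(K); size <- integer(K)
  lo <- if (is.null(bounds)) min(values, na.rm = TRUE) else bounds[1]
  hi <- if (is.null(bounds)) max(values, na.rm = TRUE) else bounds[2]
  nnum <- numeric(K)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    for (c in seq_len(K)) {
      b <- atlas$binary[i, j, k, c]
      if (b) size[c] <- size[c] + 1L
      if (b && active[i, j, k]) {
        inter[c] <- inter[c] + 1L
        stat_sum[c] <- stat_sum[c] + values[i, j, k]
        nv <- (values[i, j, k] - lo) / (hi - lo)
        nnum[c] <- nnum[c] + min(max(nv, 0), 1)
      }
    }
  }
  I <- inter / size
  IR <- if (sum(inter) > 0) inter / sum(inter) else rep(NA_real_, K)
  OL <- if (n_act > 0) inter / n_act else rep(NA_real_, K)
  SQ <- 2 * inter / (n_act + size)
  J <- inter / (n_act + size - inter)
  MA <- ifelse(inter > 0, stat_sum / inter, NA_real_)
  MA_N <- ifelse(inter > 0, nnum / inter, NA_real_)
  RA_N <- if (sum(nnum) > 0) nnum / sum(nnum) else rep(NA_real_, K)
  s <- sum(MA_N, na.rm = TRUE)
  IR_M <- if (s > 0) MA_N / s else rep(NA_real_, K)
  I_M <- nnum / size
  domain <- apply(atlas$binary, 1:3, any)
  r <- sapply(seq_len(K), function(c) {
    ok <- domain & !is.na(values)
    x <- values[ok]; y <- atlas$z[, , , c][ok]
    if (sum(ok) < 3 || sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  })
  list(icn = data.frame(I = I, IR = IR, OL = OL, SQ = SQ, J = J, MA = MA,
                        MA_N = MA_N, RA_N = RA_N, IR_M = IR_M, I_M = I_M,
                        r = r),
       global = c(I_T = sum(inter) / sum(size),
                  MA = if (sum(inter) > 0) sum(stat_sum) / sum(inter) else NA_real_,
                  MA_N = if (sum(inter) > 0) sum(nnum) / sum(inter) else NA_real_,
                  I_T_M = sum(nnum) / sum(size)))
}

# consistency ICC through the two-way ANOVA mean squares of stats::aov
oracle_icc_aov <- function(x) {
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(seq_len(nrow(x)), ncol(x))),
                   sess = factor(rep(seq_len(ncol(x)), each = nrow(x))))
  ms <- summary(stats::aov(y ~ subj + sess, data = df))[[1]][, "Mean Sq"]
  MS_R <- ms[1]; MS_E <- ms[3]
  (MS_R - MS_E) / (MS_R + (ncol(x) - 1) * MS_E)
}

# random zmap_set on a small grid
random_zmaps <- function(shape = c(6L, 6L, 6L), K = 4L, seed = 1L,
                         scale = 4) {
  set.seed(seed)
  z <- array(stats::rnorm(prod(shape) * K, mean = 1, sd = scale),
             c(shape, K))
  zmap_set(z)
}

# random activation values (with NA holes and zeros) on a grid
random_values <- function(shape, seed = 1L, p_active = 0.3, p_na = 0.1) {
  set.seed(seed)
  M <- prod(shape)
  v <- numeric(M)
  act <- stats::runif(M) < p_active
  v[act] <- stats::runif(sum(act), 3, 10)
  v[stats::runif(M) < p_na & !act] <- NA_real_
  array(v, shape)
}

# small ready-made atlas for metric tests
tiny_atlas <- function(seed = 1L, K = 3L, shape = c(8L, 8L, 8L)) {
  fx <- make_atlas_fixture(shape = shape, K = K, radius = 1.8, seed = seed)
  build_atlas(fx$zmaps, 3)
}
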