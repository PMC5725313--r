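#' Synthetic atlas fixture with known ground truth
#'
#' Generates K component Z maps as constant-amplitude blobs (spheres) on a
#' small grid, with a bounded sub-threshold noise floor, and returns the
#' ground-truth winner-take-all labelling computed from the construction
#' itself (blob membership and amplitude ordering), not from the atlas
#' builder. Component amplitudes are distinct and separated by more than
#' twice the noise half-width, and all exceed the threshold by a safe
#' margin, so the truth is exact by construction.
#'
#' By default blob centres are drawn so that blobs are disjoint when
#' possible; set \code{overlap = TRUE} to force pairwise overlaps (overlap
#' voxels belong, in truth, to the higher-amplitude component). Optional
#' separable Gaussian smoothing produces softer maps; ground truth is then
#' only reported for the unsmoothed construction and \code{truth} is
#' \code{NULL}.
#'
#' @param shape grid dimensions (default 12^3).
#' @param K number of components.
#' @param radius blob radius in voxels (scalar or per-component). For
#'   disjoint placement (the default, K <= 8) each component occupies one
#'   octant of the grid, so the radius must fit inside an octant.
#' @param threshold atlas threshold the truth is computed against.
#' @param overlap force pairwise blob overlap (default FALSE: centres are
#'   spread to avoid it where the grid allows).
#' @param noise_sd half-width of the uniform sub-threshold background
#'   noise.
#' @param smooth_fwhm Gaussian smoothing FWHM in voxels (0 = none).
#' @param affine voxel-to-world transform.
#' @param seed integer seed; the same seed reproduces the fixture exactly.
#' @return List: \code{zmaps} (a \code{\link{zmap_set}}), \code{truth}
#'   (ground-truth label array with \code{NA} background, or \code{NULL}
#'   if smoothed), \code{sizes} (true per-component labelled sizes),
#'   \code{binary_sizes} (true per-component supra-threshold sizes).
#' @export
make_atlas_fixture <- function(shape = c(12L, 12L, 12L), K = 4L, radius = 2,
                               threshold = 3, overlap = FALSE,
                               noise_sd = 0.2, smooth_fwhm = 0,
                               affine = diag(4), seed = 1L) {
  shape <- as.integer(shape)
  radius <- rep_len(radius, K)
  if (any(2 * radius + 1 > min(shape)))
    stop("component radius too large for the grid", call. = FALSE)
  set.seed(seed)
  amplitudes <- threshold + 1 + seq_len(K)          # distinct, gap 1 > 2*noise
  centers <- matrix(NA_real_, K, 3)
  if (!overlap && K <= 8L) {
    # disjoint by construction: one grid octant per component, jittered.
    # Octant centres are half-grid apart; jitter slack shrinks with radius
    # so that the worst-case centre separation still exceeds the sum of
    # the two largest radii.
    half <- floor(min(shape) / 2)
    slack <- pmax(0, half / 2 - radius - 0.5)
    rs <- sort(radius + slack, decreasing = TRUE)
    if (K >= 2L && rs[1] + rs[2] >= half)
      stop("component radius too large for disjoint placement on this grid",
           call. = FALSE)
    oct <- as.matrix(expand.grid(0:1, 0:1, 0:1))[sample(8L, K), , drop = FALSE]
    halves <- floor(shape / 2)
    for (i in seq_len(K)) {
      lo <- oct[i, ] * halves + 1
      mid <- lo + (halves - 1) / 2
      centers[i, ] <- mid + stats::runif(3, -1, 1) * slack[i]
    }
  } else {
    for (i in seq_len(K)) {
      for (attempt in seq_len(500)) {
        c_i <- sapply(1:3, function(ax)
          stats::runif(1, 1 + radius[i], shape[ax] - radius[i]))
        if (overlap || i == 1L) break
        d <- sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                             matrix(c_i, i - 1, 3, byrow = TRUE))^2))
        if (all(d > radius[i] + radius[seq_len(i - 1)] + 1)) break
      }
      centers[i, ] <- c_i
    }
    if (overlap && K >= 2L)               # drag every centre toward the first
      for (i in 2:K) centers[i, ] <- (centers[i, ] + centers[1, ]) / 2
  }

  idx <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                               z = seq_len(shape[3])))
  z <- array(0, c(shape, K))
  inside <- matrix(FALSE, nrow(idx), K)
  for (i in seq_len(K)) {
    d2 <- rowSums((idx - matrix(centers[i, ], nrow(idx), 3, byrow = TRUE))^2)
    inside[, i] <- d2 <= radius[i]^2
    zi <- ifelse(inside[, i], amplitudes[i], 0) +
      stats::runif(nrow(idx), -noise_sd, noise_sd)
    z[, , , i] <- array(zi, shape)
  }
  truth <- NULL; sizes <- NULL
  if (smooth_fwhm > 0) {
    for (i in seq_len(K)) z[, , , i] <- gaussian_smooth_3d(z[, , , i], smooth_fwhm)
  } else {
    amp <- inside %*% diag(amplitudes, K)
    amp[!inside] <- -Inf
    lab <- max.col(amp, ties.method = "first")
    lab[rowSums(inside) == 0L] <- NA_integer_
    truth <- array(as.integer(lab), shape)
    sizes <- tabulate(lab[!is.na(lab)], nbins = K)
  }
  zm <- zmap_set(z, geometry = grid_geometry(shape, affine),
                 provenance = sprintf("synthetic blob atlas (seed %d)", seed))
  list(zmaps = zm, truth = truth, sizes = sizes,
       binary_sizes = if (is.null(truth)) NULL else as.integer(colSums(inside)),
       centers = centers, amplitudes = amplitudes)
}

# separable Gaussian smoothing; FWHM in voxels
gaussian_smooth_3d <- function(vol, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(v, axis) {
    d <- dim(v)
    perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    vp <- aperm(v, perm)
    dp <- dim(vp)
    m <- matrix(vp, dp[1], dp[2] * dp[3])
    n <- dp[1]
    out <- matrix(0, n, ncol(m))
    for (off in -half:half) {
      src <- pmin(pmax(seq_len(n) + off, 1L), n)    # edge replication
      out <- out + k[off + half + 1L] * m[src, , drop = FALSE]
    }
    aperm(array(out, dp), order(perm))
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}

#' Synthetic activation map with exact requested involvement
#'
#' Builds a statistical map activating, for each base map i, exactly
#' \code{floor(target_I[i] * |ICN_i|)} voxels sampled without replacement
#' from the component's binary mask, so the involvement I_i recovered by
#' the engagement pipeline equals the floor-quantised request exactly
#' (guaranteed when the atlas' binary masks are disjoint, as in the default
#' \code{\link{make_atlas_fixture}} geometry; the achieved overlaps are
#' reported in all cases). Active voxels carry \code{amplitude} plus a
#' positive jitter, so they survive the conventional Z > 3 input
#' threshold; the background is zero. Optional distractor voxels outside
#' every component can be added.
#'
#' @param atlas a \code{label_atlas}.
#' @param target_I numeric vector in [0, 1], one requested involvement per
#'   base map.
#' @param amplitude statistic value of active voxels (default 5).
#' @param n_distractors active voxels to place outside all components.
#' @param seed integer seed.
#' @return List: \code{map} (a \code{\link{stat_map}}), \code{achieved_I}
#'   (per-component overlap counts divided by component sizes) and
#'   \code{n_selected}.
#' @export
make_activation_fixture <- function(atlas, target_I, amplitude = 5,
                                    n_distractors = 0L, seed = 1L) {
  stopifnot(inherits(atlas, "label_atlas"))
  K <- length(atlas$component_names)
  target_I <- rep_len(target_I, K)
  if (any(target_I < 0 | target_I > 1))
    stop("'target_I' must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  M <- prod(atlas$geometry$shape)
  bin <- matrix(atlas$binary, M, K)
  v <- numeric(M)
  active <- logical(M)
  for (i in seq_len(K)) {
    vox <- which(bin[, i])
    n_take <- floor(target_I[i] * length(vox))
    if (n_take > 0) {
      take <- if (n_take == length(vox)) vox else sample(vox, n_take)
      active[take] <- TRUE
    }
  }
  if (n_distractors > 0L) {
    outside <- which(rowSums(bin) == 0L & !active)
    if (length(outside))
      active[sample(outside, min(n_distractors, length(outside)))] <- TRUE
  }
  v[active] <- amplitude + stats::runif(sum(active))
  map <- stat_map(array(v, atlas$geometry$shape), atlas$geometry,
                  stat_kind = "Z")
  achieved <- colSums(bin & active) / colSums(bin)
  list(map = map, achieved_I = achieved, n_selected = sum(active))
}

#' Synthetic multi-session score set with known ICC
#'
#' Simulates a tidy subject x session x item score table under the
#' crossed random-effects model
#' \deqn{y_{st} = u_s + d_{s,day(t)} + b_t + e_{st}} with independent
#' zero-mean normal subject effects u (variance \code{sigma_u^2}),
#' subject-by-day effects d (variance \code{sigma_day^2}; sessions listed
#' in \code{same_day} share one day, the rest another), fixed-per-session
#' offsets b drawn with variance \code{sigma_session^2}, and residuals e
#' (variance \code{sigma_e^2}). Session offsets b are exactly the
#' systematic differences the consistency ICC is designed not to penalise.
#'
#' The true consistency ICC is recorded per comparison: for a same-day
#' session pair \eqn{(sigma_u^2 + sigma_day^2) / (sigma_u^2 + sigma_day^2 +
#' sigma_e^2)}; for a cross-day pair \eqn{sigma_u^2 / (sigma_u^2 +
#' sigma_day^2 + sigma_e^2)}. With \code{sigma_day = 0} both collapse to
#' the classic \eqn{sigma_u^2 / (sigma_u^2 + sigma_e^2)}.
#'
#' @param n_subjects subjects (default 25).
#' @param n_sessions scanning sessions (default 3).
#' @param items data frame of item labels (columns ic, basemap, metric) or
#'   \code{NULL} for a single item.
#' @param sigma_u subject effect SD.
#' @param sigma_day subject-by-day effect SD (default 0).
#' @param sigma_session session offset SD.
#' @param sigma_e residual SD.
#' @param same_day sessions sharing the second day (default 2 and 3,
#'   mirroring a baseline scan followed by two same-day scans).
#' @param seed integer seed.
#' @return List: \code{scores} (tidy data frame: subject, session, ic,
#'   basemap, metric, value), \code{true_icc_within},
#'   \code{true_icc_between}, and the variance components.
#' @export
make_session_scores <- function(n_subjects = 25L, n_sessions = 3L,
                                items = NULL, sigma_u = 1, sigma_day = 0,
                                sigma_session = 0.5, sigma_e = 1,
                                same_day = c(2L, 3L), seed = 1L) {
  if (any(c(sigma_u, sigma_day, sigma_session, sigma_e) < 0))
    stop("variance components must be non-negative")
  set.seed(seed)
  if (is.null(items))
    items <- data.frame(ic = "IC1", basemap = "ICN1", metric = "I",
                        stringsAsFactors = FALSE)
  day <- ifelse(seq_len(n_sessions) %in% same_day, 2L, 1L)
  out <- vector("list", nrow(items))
  for (it in seq_len(nrow(items))) {
    u <- stats::rnorm(n_subjects, 0, sigma_u)
    d <- matrix(stats::rnorm(n_subjects * 2L, 0, sigma_day), n_subjects, 2L)
    b <- stats::rnorm(n_sessions, 0, sigma_session)
    e <- matrix(stats::rnorm(n_subjects * n_sessions, 0, sigma_e),
                n_subjects, n_sessions)
    y <- outer(u, rep(1, n_sessions)) + d[, day] +
      outer(rep(1, n_subjects), b) + e
    out[[it]] <- data.frame(subject = rep(seq_len(n_subjects), n_sessions),
                            session = rep(seq_len(n_sessions),
                                          each = n_subjects),
                            ic = items$ic[it], basemap = items$basemap[it],
                            metric = items$metric[it],
                            value = as.vector(y), stringsAsFactors = FALSE)
  }
  tot_w <- sigma_u^2 + sigma_day^2 + sigma_e^2
  list(scores = do.call(rbind, out),
       true_icc_within = (sigma_u^2 + sigma_day^2) / tot_w,
       true_icc_between = sigma_u^2 / tot_w,
       sigma = c(u = sigma_u, day = sigma_day, session = sigma_session,
                 e = sigma_e))
}

#' Synthetic metric matrix with planted factor structure
#'
#' Builds an observations x metrics matrix from two orthogonal latent
#' factors plus one independent (pure-uniqueness) column: the first
#' \code{n_f1} columns load on factor 1, the next \code{n_f2} on factor 2,
#' the last column is independent noise. Used to verify that the two-stage
#' reduction recovers one representative per factor plus the unique
#' column.
#'
#' @param n observations (default 2000).
#' @param n_f1,n_f2 columns loading on each factor (defaults 5 and 5; one
#'   more unique column gives the standard 11).
#' @param loading common loading strength (default 0.9).
#' @param seed integer seed.
#' @return List: \code{x} (the matrix, metric names m1..), \code{truth}
#'   (list: factor1/factor2 column names, unique column name),
#'   \code{loadings} (the planted loading matrix).
#' @export
make_metric_matrix_fixture <- function(n = 2000L, n_f1 = 5L, n_f2 = 5L,
                                       loading = 0.9, seed = 1L) {
  set.seed(seed)
  p <- n_f1 + n_f2 + 1L
  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
  L <- matrix(0, p, 2)
  # graded loadings so each factor has a unique strongest representative
  L[seq_len(n_f1), 1] <- loading - 0.06 * (seq_len(n_f1) - 1L)
  L[n_f1 + seq_len(n_f2), 2] <- loading - 0.06 * (seq_len(n_f2) - 1L)
  x <- cbind(f1, f2) %*% t(L)
  uniq_sd <- sqrt(pmax(1 - rowSums(L^2), 0.05))
  x <- x + matrix(stats::rnorm(n * p), n, p) %*% diag(uniq_sd, p)
  colnames(x) <- paste0("m", seq_len(p))
  list(x = x,
       truth = list(factor1 = colnames(x)[seq_len(n_f1)],
                    factor2 = colnames(x)[n_f1 + seq_len(n_f2)],
                    unique = colnames(x)[p]),
       loadings = L)
}
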