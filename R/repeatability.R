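#' Two-way consistency intra-class correlation
#'
#' Estimates the ICC of a subjects-by-sessions score matrix with the
#' two-way mixed, consistency-type formula (the Shrout-Fleiss ICC(3,1)
#' class): \deqn{ICC = (MS_R - MS_E) / (MS_R + (k - 1) MS_E)} where MS_R is
#' the between-subject mean square, MS_E the residual mean square of the
#' two-way (subject + session) decomposition, and k the number of sessions.
#' Session main effects are removed before the residual is formed, so a
#' constant offset between sessions is not penalised; the estimate can be
#' negative when subjects barely differ. The absolute-agreement variant
#' (ICC(A,1)), which does penalise session offsets, is available for
#' sensitivity analysis via \code{type = "agreement"}.
#'
#' Rows containing any missing value are dropped; the count is attached as
#' attribute \code{n_dropped}.
#'
#' @param x numeric matrix, subjects in rows, sessions/raters in columns.
#' @param type "consistency" (default) or "agreement".
#' @return Numeric ICC in [-1, 1], with attributes \code{n_subjects} and
#'   \code{n_dropped}. \code{NA} (with a message attribute) when the total
#'   variance is zero.
#' @export
icc_consistency <- function(x, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  S <- nrow(x); k <- ncol(x)
  if (S < 2L || k < 2L)
    stop("need at least 2 subjects and 2 sessions after dropping ",
         "incomplete rows", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  SS_rows <- k * sum((row_m - grand)^2)
  SS_cols <- S * sum((col_m - grand)^2)
  SS_tot <- sum((x - grand)^2)
  SS_err <- SS_tot - SS_rows - SS_cols
  # catastrophic-cancellation guard: exact consistency must give ICC = 1
  if (SS_err < 1e-10 * SS_tot) SS_err <- 0
  MS_R <- SS_rows / (S - 1)
  MS_C <- SS_cols / (k - 1)
  MS_E <- SS_err / ((S - 1) * (k - 1))
  if (SS_tot < .Machine$double.eps * length(x)) {
    out <- NA_real_
    attr(out, "message") <- "zero total variance: ICC undefined"
    attr(out, "n_subjects") <- S
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  denom_extra <- if (type == "agreement") (k / S) * (MS_C - MS_E) else 0
  out <- (MS_R - MS_E) / (MS_R + (k - 1) * MS_E + denom_extra)
  attr(out, "n_subjects") <- S
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Voxel-wise ICC field
#'
#' Computes the consistency ICC independently at every voxel/item of a
#' (units x subjects x sessions) array, vectorised over units.
#'
#' @param a numeric array with dimensions (n_units, n_subjects,
#'   n_sessions); units are typically voxels.
#' @param type as in \code{\link{icc_consistency}}.
#' @return Numeric vector of n_units ICC values (\code{NA} where the total
#'   variance is zero or data are missing).
#' @export
icc_field <- function(a, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  stopifnot(length(dim(a)) == 3L)
  n <- dim(a)[1]; S <- dim(a)[2]; k <- dim(a)[3]
  m <- matrix(a, n, S * k)
  grand <- rowMeans(m)
  # row means per subject: n x S; column (session) means: n x k
  subj_m <- sapply(seq_len(S), function(s) rowMeans(a[, s, , drop = FALSE]))
  sess_m <- sapply(seq_len(k), function(t) rowMeans(a[, , t, drop = FALSE]))
  if (n == 1L) { subj_m <- matrix(subj_m, 1); sess_m <- matrix(sess_m, 1) }
  SS_rows <- k * rowSums((subj_m - grand)^2)
  SS_cols <- S * rowSums((sess_m - grand)^2)
  SS_tot <- rowSums((m - grand)^2)
  SS_err <- pmax(SS_tot - SS_rows - SS_cols, 0)
  SS_err[SS_err < 1e-10 * SS_tot] <- 0
  MS_R <- SS_rows / (S - 1)
  MS_C <- SS_cols / (k - 1)
  MS_E <- SS_err / ((S - 1) * (k - 1))
  denom_extra <- if (type == "agreement") (k / S) * (MS_C - MS_E) else 0
  out <- (MS_R - MS_E) / (MS_R + (k - 1) * MS_E + denom_extra)
  out[SS_tot < .Machine$double.eps * S * k] <- NA_real_
  out
}

#' Mode of a voxel-wise ICC distribution
#'
#' Summarises a field of voxel-wise ICC values by the mode of an 80-bin
#' histogram spanning [0, 1]: values less than or equal to zero are
#' discarded, the remaining values are binned into 80 equal left-closed
#' bins, and the centre of the fullest bin is returned. Ties between bins
#' go to the lower bin (deterministic).
#'
#' @param icc numeric vector of voxel-wise ICC values.
#' @param n_bins number of histogram bins on [0, 1] (default 80).
#' @return The mode bin's centre, or \code{NA} if no positive values
#'   remain.
#' @export
mode_of_icc <- function(icc, n_bins = 80L) {
  v <- icc[!is.na(icc) & icc > 0]
  if (!length(v)) {
    out <- NA_real_
    attr(out, "message") <- "no positive ICC values: mode undefined"
    return(out)
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  b <- which.max(counts)
  (breaks[b] + breaks[b + 1L]) / 2
}

#' Mode-of-ICC repeatability of co-registered score volumes
#'
#' Convenience wrapper: computes the per-voxel consistency ICC of a
#' (subjects x sessions) collection of volumes and summarises it with the
#' 80-bin histogram mode.
#'
#' @param maps 5-D numeric array (x, y, z, subject, session), or a
#'   (voxels, subject, session) array.
#' @param type ICC variant, see \code{\link{icc_consistency}}.
#' @param mask optional logical volume restricting the voxels considered.
#' @return List with \code{mode} (the histogram mode), \code{icc} (the
#'   voxel-wise ICC field) and \code{n_positive}.
#' @export
voxelwise_icc_mode <- function(maps, type = "consistency", mask = NULL) {
  d <- dim(maps)
  if (length(d) == 5L) {
    a <- array(maps, c(prod(d[1:3]), d[4], d[5]))
    if (!is.null(mask)) a <- a[as.vector(mask), , , drop = FALSE]
  } else if (length(d) == 3L) {
    a <- maps
  } else stop("'maps' must be (x,y,z,subject,session) or (voxel,subject,session)")
  icc <- icc_field(a, type = type)
  list(mode = mode_of_icc(icc), icc = icc,
       n_positive = sum(icc > 0, na.rm = TRUE))
}

#' Session design for repeatability analysis
#'
#' Declares which session pairs form the within-session comparison (same
#' day, e.g. scans 2 and 3 acquired 45 minutes apart) and which form the
#' between-session comparison (baseline vs each later scan, stacked).
#'
#' @param within integer vector of the two same-day sessions.
#' @param between list of integer pairs, each baseline-vs-later.
#' @return A list of class \code{session_design}.
#' @export
session_design <- function(within = c(2L, 3L),
                           between = list(c(1L, 2L), c(1L, 3L))) {
  structure(list(within = as.integer(within),
                 between = lapply(between, as.integer)),
            class = "session_design")
}

#' Collapse a session score set and estimate ICC at a pooling level
#'
#' Takes a tidy score table (one row per subject x session x item, where an
#' item is an (IC, base map, metric) triple) and estimates within- or
#' between-session consistency ICC at one of three pooling levels:
#' \describe{
#'   \item{per_item}{one ICC per (IC, base map, metric): rows are subjects.}
#'   \item{per_basemap}{pooled across ICs: rows are subject x IC pairs, one
#'     ICC per (base map, metric).}
#'   \item{global}{pooled across ICs and base maps: one ICC per metric.}
#' }
#' Within-session uses the same-day session pair as the two columns;
#' between-session stacks the (baseline, later) pairings as extra rows of a
#' two-column matrix. Rows with undefined scores are dropped pairwise and
#' counted. Pooling is pure aggregation: it never alters the per-item
#' scores it summarises.
#'
#' @param scores data frame with columns \code{subject}, \code{session},
#'   \code{ic}, \code{basemap}, \code{metric}, \code{value}.
#' @param level "per_item", "per_basemap" or "global".
#' @param flavour "within" or "between".
#' @param design a \code{\link{session_design}}.
#' @param type ICC variant, see \code{\link{icc_consistency}}.
#' @return Data frame of ICC estimates with columns ic, basemap, metric
#'   (NA where collapsed over), icc, flavour, level, n_rows, n_dropped,
#'   undefined_fraction.
#' @export
collapse_and_estimate <- function(scores,
                                  level = c("per_item", "per_basemap", "global"),
                                  flavour = c("within", "between"),
                                  design = session_design(),
                                  type = "consistency") {
  level <- match.arg(level)
  flavour <- match.arg(flavour)
  need <- c("subject", "session", "ic", "basemap", "metric", "value")
  if (!all(need %in% names(scores)))
    stop("'scores' must have columns ", paste(need, collapse = ", "))
  group_cols <- switch(level,
                       per_item = c("ic", "basemap", "metric"),
                       per_basemap = c("basemap", "metric"),
                       global = "metric")
  unit_cols <- switch(level,
                      per_item = "subject",
                      per_basemap = c("subject", "ic"),
                      global = c("subject", "ic", "basemap"))
  pairs <- if (flavour == "within") list(design$within) else design$between
  key <- interaction(scores[group_cols], drop = TRUE, sep = "\r")
  out <- lapply(split(scores, key), function(df) {
    unit <- interaction(df[unit_cols], drop = TRUE, sep = "\r")
    mats <- lapply(pairs, function(p) {
      a <- df$value[match(paste(levels(unit), p[1]),
                          paste(unit, df$session))]
      b <- df$value[match(paste(levels(unit), p[2]),
                          paste(unit, df$session))]
      cbind(a, b)
    })
    m <- do.call(rbind, mats)
    complete <- stats::complete.cases(m)
    res <- data.frame(ic = if ("ic" %in% group_cols) df$ic[1] else NA,
                      basemap = if ("basemap" %in% group_cols) df$basemap[1] else NA,
                      metric = df$metric[1],
                      icc = NA_real_, flavour = flavour, level = level,
                      n_rows = sum(complete), n_dropped = sum(!complete),
                      undefined_fraction = mean(!complete),
                      stringsAsFactors = FALSE)
    if (sum(complete) >= 2L) {
      est <- try(icc_consistency(m, type = type), silent = TRUE)
      if (!inherits(est, "try-error")) res$icc <- as.numeric(est)
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Top-k agreement between two engagement rankings
#'
#' Counts how many base maps appear in the top-k of both rankings: do the
#' highest engagement values pertain to the same base maps in both tables?
#' Ties at rank k are broken deterministically by lowest index. With a
#' correspondence mapping, the second ranking's base maps are translated to
#' the first's name space before comparison (identity when both use the
#' same atlas).
#'
#' @param a,b named numeric vectors of one metric's values per base map,
#'   or \code{engagement_table}s together with \code{metric}.
#' @param k size of the top set (default 3).
#' @param mapping optional named character vector translating names of
#'   \code{b} to names of \code{a}.
#' @param metric metric column to extract when tables are passed.
#' @return Integer in 0..k: the number of shared top-k base maps.
#' @export
topk_agreement <- function(a, b, k = 3L, mapping = NULL, metric = "I") {
  if (inherits(a, "engagement_table")) a <- stats::setNames(a$icn[[metric]], a$icn$component)
  if (inherits(b, "engagement_table")) b <- stats::setNames(b$icn[[metric]], b$icn$component)
  if (!is.null(mapping)) names(b) <- unname(mapping[names(b)])
  if (k > length(a) || k > length(b))
    stop("'k' exceeds the number of base maps", call. = FALSE)
  top <- function(v) {
    v[is.na(v)] <- -Inf
    names(v)[order(-v, seq_along(v))[seq_len(k)]]
  }
  length(intersect(top(a), top(b)))
}
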