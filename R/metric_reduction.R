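#' Prepare a metric matrix for factoring
#'
#' Rows are observations (input map x ICN pairs), columns the ICN-specific
#' metrics. Rows containing undefined cells are dropped (count logged in
#' the result) and columns standardised to zero mean / unit variance.
#'
#' @param x numeric matrix or data frame of metric values.
#' @return List with \code{z} (standardised matrix), \code{n_dropped},
#'   \code{means}, \code{sds}.
#' @keywords internal
prepare_metric_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  if (nrow(x) <= ncol(x))
    stop("need more observations than metrics after dropping undefined rows",
         call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant metric column(s) cannot be standardised: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  z <- scale(x)
  list(z = z, n_dropped = n_dropped,
       means = attr(z, "scaled:center"), sds = attr(z, "scaled:scale"))
}

# principal-axis factoring on a correlation matrix, followed by varimax.
# Sign convention: each factor's largest-magnitude loading is positive.
paf_varimax <- function(R, n_factors, max_iter = 200, tol = 1e-7) {
  p <- ncol(R)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv) || min(eigen(R, symmetric = TRUE,
                                only.values = TRUE)$values) < 1e-10) {
    cors <- which(abs(R) > 0.999 & upper.tri(R), arr.ind = TRUE)
    pairs <- apply(cors, 1, function(idx)
      paste(colnames(R)[idx[1]], colnames(R)[idx[2]], sep = " ~ "))
    stop("singular correlation matrix; collinear columns: ",
         if (length(pairs)) paste(pairs, collapse = "; ") else "(unidentified)",
         call. = FALSE)
  }
  h2 <- 1 - 1 / diag(inv)            # initial communalities: SMC
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(n_factors)], 0)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(ev), n_factors)
    h2_new <- pmin(rowSums(L^2), 1)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  if (n_factors > 1L) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- unclass(rot$loadings)
  }
  for (j in seq_len(ncol(L)))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  expl <- colSums(L^2) / p
  ord <- order(-expl)
  L <- L[, ord, drop = FALSE]
  expl <- expl[ord]
  dimnames(L) <- list(colnames(R), paste0("F", seq_len(n_factors)))
  list(loadings = L, uniqueness = stats::setNames(1 - rowSums(L^2), colnames(R)),
       explained = stats::setNames(expl, colnames(L)))
}

efa_stage <- function(z, n_factors) {
  R <- stats::cor(z)
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  pca_share <- (pca$sdev^2) / sum(pca$sdev^2)
  fa <- paf_varimax(R, n_factors)
  c(fa, list(pca_share = pca_share))
}

#' Two-stage metric-set reduction by factor analysis
#'
#' Identifies a parsimonious subset of the ICN-specific engagement metrics.
#' Stage 1 runs a PCA and an exploratory factor analysis (principal-axis
#' extraction, varimax rotation) on all metrics and retains
#' \code{n_keep_stage1} of them: the strongest loaders on the two factors
#' with the highest explained variance, the highest-uniqueness metric, and
#' the remaining best loaders. Stage 2 repeats the analysis on the
#' survivors and selects \code{n_final} metrics: the top loader on each of
#' the two factors plus the survivor with the highest uniqueness.
#'
#' @param mm numeric matrix or data frame, observations x metrics (11
#'   ICN-specific metrics in the standard workflow). Rows with undefined
#'   cells are dropped.
#' @param n_factors number of latent factors (default 2).
#' @param n_keep_stage1 metrics retained after stage 1 (default 5).
#' @param n_final metrics selected at stage 2 (default 3).
#' @return An object of class \code{reduction_report}: per-stage loadings,
#'   uniqueness and explained-variance shares; \code{selection} (the final
#'   metric names) and \code{rationale} codes (\code{high_loading_factor1},
#'   \code{high_loading_factor2}, \code{high_uniqueness}).
#' @export
reduce_metrics <- function(mm, n_factors = 2L, n_keep_stage1 = 5L,
                           n_final = 3L) {
  prep <- prepare_metric_matrix(mm)
  z <- prep$z
  if (n_keep_stage1 < n_final)
    stop("'n_keep_stage1' must be at least 'n_final'")
  s1 <- efa_stage(z, n_factors)
  L1 <- s1$loadings
  metrics <- rownames(L1)

  pick_stage1 <- function() {
    picked <- character(0)
    add <- function(nm) if (!nm %in% picked) picked <<- c(picked, nm)
    add(metrics[which.max(abs(L1[, 1]))])
    if (ncol(L1) >= 2L) add(metrics[which.max(abs(L1[, 2]))])
    add(names(which.max(s1$uniqueness)))
    strength <- apply(abs(L1), 1, max)
    for (nm in metrics[order(-strength)]) {
      if (length(picked) >= n_keep_stage1) break
      add(nm)
    }
    picked[seq_len(min(n_keep_stage1, length(picked)))]
  }
  keep <- pick_stage1()

  s2 <- efa_stage(z[, keep, drop = FALSE], n_factors)
  L2 <- s2$loadings
  sel <- character(0); why <- character(0)
  take <- function(nm, code) {
    if (!nm %in% sel) { sel <<- c(sel, nm); why <<- c(why, code) }
  }
  take(keep[which.max(abs(L2[, 1]))], "high_loading_factor1")
  if (ncol(L2) >= 2L) {
    cand <- keep[order(-abs(L2[, 2]))]
    cand <- cand[!cand %in% sel]
    if (length(cand)) take(cand[1], "high_loading_factor2")
  }
  uniq_cand <- names(sort(s2$uniqueness, decreasing = TRUE))
  uniq_cand <- uniq_cand[!uniq_cand %in% sel]
  if (length(uniq_cand) && length(sel) < n_final)
    take(uniq_cand[1], "high_uniqueness")
  # fill, if n_final exceeds the three canonical picks
  strength2 <- apply(abs(L2), 1, max)
  for (nm in keep[order(-strength2)]) {
    if (length(sel) >= n_final) break
    take(nm, "high_loading")
  }
  structure(list(stage1 = s1, stage2 = s2, retained_stage1 = keep,
                 selection = sel[seq_len(min(n_final, length(sel)))],
                 rationale = stats::setNames(why[seq_len(min(n_final, length(sel)))],
                                             sel[seq_len(min(n_final, length(sel)))]),
                 n_dropped_rows = prep$n_dropped),
            class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat("<reduction_report>\n stage 1 retained:",
      paste(x$retained_stage1, collapse = ", "), "\n",
      "final selection:",
      paste(sprintf("%s (%s)", x$selection, x$rationale), collapse = ", "),
      "\n explained variance (stage 2):",
      paste(signif(x$stage2$explained, 3), collapse = ", "), "\n")
  invisible(x)
}
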