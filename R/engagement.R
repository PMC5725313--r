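#' Label an input map's active voxels against an atlas
#'
#' Transfers the atlas labels onto the input map's active voxels: the
#' labelled activation volume carries, at each active voxel, the label of
#' the corresponding base-map voxel (and \code{NA} elsewhere). A voxel is
#' active when it holds a non-missing, non-zero value; for a thresholded
#' map these are exactly the surviving voxels.
#'
#' Two intersection counts are accumulated per component: against the
#' (possibly overlapping) binary base maps, which is how the engagement
#' metric definitions are written, and against the mutually exclusive
#' winner-take-all labels. \code{\link{spatial_metrics}} selects between
#' them.
#'
#' @param map a \code{\link{stat_map}} already on the atlas grid (use
#'   \code{\link{resample_to_atlas}} first; a geometry mismatch is an
#'   error, never a silent resample).
#' @param atlas a \code{label_atlas}.
#' @param raw_values optional 3-D array of the unthresholded statistic on
#'   the same grid, used for the spatial-correlation metric and for the
#'   default normalisation bounds. Defaults to the map's own values.
#' @return An object of class \code{labelled_activation}: labelled volume
#'   \code{L}, per-component counts and statistic sums, the activation size
#'   and the map-wide normalisation bounds.
#' @export
label_activation <- function(map, atlas, raw_values = NULL) {
  stopifnot(inherits(map, "stat_map"), inherits(atlas, "label_atlas"))
  if (!same_geometry(map$geometry, atlas$geometry))
    stop("input map is not on the atlas grid; run resample_to_atlas() first",
         call. = FALSE)
  if (is.null(raw_values)) raw_values <- map$values
  v <- map$values
  active <- !is.na(v) & v != 0
  K <- length(atlas$component_names)
  M <- prod(atlas$geometry$shape)
  bin <- matrix(atlas$binary, M, K)
  act <- as.vector(active)
  vv <- as.vector(v); vv[!act] <- 0
  n_binary <- colSums(bin & act)
  lab <- as.vector(atlas$labels)
  n_label <- tabulate(lab[act & !is.na(lab)], nbins = K)
  stat_sum <- as.vector(crossprod(bin, vv * act))
  L <- atlas$labels
  L[!active] <- NA_integer_
  rng <- if (any(!is.na(map$values))) range(map$values, na.rm = TRUE) else c(NA_real_, NA_real_)
  structure(list(L = L, active = active,
                 n_active = sum(act),
                 n_binary = as.integer(n_binary),
                 n_label = as.integer(n_label),
                 stat_sum = stat_sum,
                 bounds = rng,
                 raw_values = raw_values,
                 component_names = atlas$component_names),
            class = "labelled_activation")
}

#' @export
print.labelled_activation <- function(x, ...) {
  cat("<labelled_activation> ", x$n_active, " active voxels; per-component",
      " overlap: ", paste(x$n_binary, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Spatial (extent/overlap) engagement metrics
#'
#' Computes the purely spatial metric family for each base map i, writing
#' A for the set of active input voxels and ICN_i for the component's
#' binary base map:
#' \describe{
#'   \item{I_i}{spatial involvement, |A n ICN_i| / |ICN_i| -- the activated
#'     fraction of the component.}
#'   \item{IR_i}{relative spatial involvement,
#'     |A n ICN_i| / sum_j |A n ICN_j|; sums to 1 over components.}
#'   \item{OL_i}{overlap with the activation, |A n ICN_i| / |A|.}
#'   \item{SQ_i}{Sorensen-Dice coefficient, 2|A n ICN_i|/(|A| + |ICN_i|).}
#'   \item{J_i}{Jaccard index, |A n ICN_i| / |A u ICN_i|.}
#' }
#' plus the global total involvement
#' I_T = sum_i |A n ICN_i| / sum_i |ICN_i|, the base-map-size-weighted mean
#' of the I_i. Undefined cells (IR with no active component voxel, OL with
#' an empty map) are \code{NA}, never silently zero.
#'
#' @param la a \code{\link{labelled_activation}}.
#' @param atlas the \code{label_atlas} used to produce it.
#' @param counts "binary" (default; intersections against the binary base
#'   maps, as the metric definitions are written) or "labels" (against the
#'   mutually exclusive winner-take-all labels).
#' @return A list with \code{icn} (data frame: component, I, IR, OL, SQ, J)
#'   and \code{global} (named numeric: I_T).
#' @export
spatial_metrics <- function(la, atlas, counts = c("binary", "labels")) {
  counts <- match.arg(counts)
  stopifnot(inherits(la, "labelled_activation"))
  sizes <- component_sizes(atlas, counts)
  if (any(sizes == 0))
    stop("atlas integrity: zero-volume base map(s): ",
         paste(atlas$component_names[sizes == 0], collapse = ", "),
         call. = FALSE)
  inter <- if (counts == "binary") la$n_binary else la$n_label
  n_act <- la$n_active
  I <- inter / sizes
  IR <- if (sum(inter) > 0) inter / sum(inter) else rep(NA_real_, length(inter))
  OL <- if (n_act > 0) inter / n_act else rep(NA_real_, length(inter))
  SQ <- 2 * inter / (n_act + sizes)
  J <- inter / (n_act + sizes - inter)
  list(icn = data.frame(component = la$component_names,
                        I = I, IR = IR, OL = OL, SQ = SQ, J = J,
                        stringsAsFactors = FALSE),
       global = c(I_T = sum(inter) / sum(sizes)))
}

component_sizes <- function(atlas, counts = "binary") {
  K <- length(atlas$component_names)
  if (counts == "binary") {
    colSums(matrix(atlas$binary, prod(atlas$geometry$shape), K))
  } else {
    lab <- atlas$labels
    tabulate(lab[!is.na(lab)], nbins = K)
  }
}

#' Activation-strength, density and correlation engagement metrics
#'
#' Computes the statistic-weighted metric family. Voxel values are first
#' normalised to [0, 1] as (v - min)/(max - min) using the map-wide bounds
#' (or explicitly supplied ones, e.g. bounds matched across the maps of a
#' scanning session). Writing nnum_i for the sum of normalised values over
#' the active voxels of ICN_i and n_i = |A n ICN_i|:
#' \describe{
#'   \item{MA_i}{mean raw activation, sum of the statistic over active
#'     ICN_i voxels divided by n_i; undefined when n_i = 0.}
#'   \item{MA_N,i}{normalised mean activation, nnum_i / n_i; undefined when
#'     n_i = 0.}
#'   \item{RA_N,i}{normalised relative activation, nnum_i / sum_j nnum_j;
#'     sums to 1 when the denominator is positive.}
#'   \item{IR_i^M}{relative normalised mean activation,
#'     MA_N,i / sum over defined j of MA_N,j.}
#'   \item{I_i^M}{normalised mean activation density, nnum_i / |ICN_i|.}
#'   \item{r_i}{Pearson correlation between the unthresholded input values
#'     and the component's unmasked prototype Z, over the voxels belonging
#'     to any base map (the atlas domain).}
#' }
#' Globals pool the sums over all components: MA = sum stat / sum n_i,
#' MA_N = sum nnum / sum n_i, I_T^M = sum nnum / sum |ICN_i|.
#'
#' @param la a \code{\link{labelled_activation}}.
#' @param atlas the \code{label_atlas} used to produce it.
#' @param bounds optional fixed \code{c(min, max)} normalisation bounds.
#'   Defaults to the input map's own min/max. Bounds that do not bracket
#'   the data give a warning and values clipped to [0, 1]; a constant map
#'   (max = min) is an error.
#' @param counts as in \code{\link{spatial_metrics}}; determines
#'   \code{|ICN_i|} for the density metric.
#' @return A list with \code{icn} (data frame: component, MA, MA_N, RA_N,
#'   IR_M, I_M, r) and \code{global} (named numeric: MA, MA_N, I_T_M), plus
#'   the bounds used.
#' @export
activation_metrics <- function(la, atlas, bounds = NULL,
                               counts = c("binary", "labels")) {
  counts <- match.arg(counts)
  stopifnot(inherits(la, "labelled_activation"))
  if (is.null(bounds)) bounds <- la$bounds
  if (anyNA(bounds) || length(bounds) != 2L)
    stop("normalisation bounds unavailable: the input map holds no values",
         call. = FALSE)
  lo <- bounds[1]; hi <- bounds[2]
  if (hi <= lo)
    stop("cannot normalise: max <= min of the statistic (constant map?); ",
         "supply explicit 'bounds'", call. = FALSE)
  v <- la$raw_values
  active <- la$active
  va <- ifelse(active, v, NA_real_)
  if (any(va < lo - 1e-12 | va > hi + 1e-12, na.rm = TRUE))
    warning("normalisation bounds do not bracket the data; values clipped to [0, 1]")
  norm <- pmin(pmax((va - lo) / (hi - lo), 0), 1)
  norm[!active | is.na(norm)] <- 0

  K <- length(la$component_names)
  M <- length(active)
  bin <- matrix(atlas$binary, M, K)
  n_i <- la$n_binary
  nnum <- as.vector(crossprod(bin, as.vector(norm)))
  sizes <- component_sizes(atlas, counts)

  MA <- ifelse(n_i > 0, la$stat_sum / n_i, NA_real_)
  MA_N <- ifelse(n_i > 0, nnum / n_i, NA_real_)
  RA_N <- if (sum(nnum) > 0) nnum / sum(nnum) else rep(NA_real_, K)
  denom_irm <- sum(MA_N, na.rm = TRUE)
  IR_M <- if (denom_irm > 0) MA_N / denom_irm else rep(NA_real_, K)
  I_M <- nnum / sizes

  # correlation over the atlas domain (any component's binary mask),
  # unthresholded input vs unmasked prototype Z
  domain <- rowSums(bin) > 0
  rv <- as.vector(la$raw_values)
  r <- vapply(seq_len(K), function(i) {
    zi <- as.vector(atlas$z[, , , i])
    ok <- domain & !is.na(rv) & !is.na(zi)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(rv[ok]) == 0 || stats::sd(zi[ok]) == 0) return(NA_real_)
    stats::cor(rv[ok], zi[ok])
  }, numeric(1))

  glob <- c(MA = if (sum(n_i) > 0) sum(la$stat_sum) / sum(n_i) else NA_real_,
            MA_N = if (sum(n_i) > 0) sum(nnum) / sum(n_i) else NA_real_,
            I_T_M = sum(nnum) / sum(sizes))
  list(icn = data.frame(component = la$component_names,
                        MA = MA, MA_N = MA_N, RA_N = RA_N,
                        IR_M = IR_M, I_M = I_M, r = r,
                        stringsAsFactors = FALSE),
       global = glob, bounds = c(lo, hi))
}

#' Quantify ICN engagement of a statistical map (full pipeline)
#'
#' End-to-end composition: load (if given a path), resample onto the atlas
#' grid, apply significance and cluster-extent thresholding (skipped when
#' \code{input_threshold} is \code{NULL}, the unthresholded mode), label the
#' active voxels, and compute all eleven ICN-specific plus four global
#' engagement metrics. Deterministic: identical inputs give identical
#' tables.
#'
#' @param map a \code{\link{stat_map}} or a path to a NIfTI/Analyze volume.
#' @param atlas a \code{label_atlas} or a path to a saved atlas directory.
#' @param input_threshold statistic threshold for the input map (strict
#'   \code{>}), or \code{NULL} to atlase the raw map. Default 3.
#' @param cluster_k minimum cluster extent in voxels (26-connectivity).
#' @param bounds optional fixed normalisation bounds \code{c(min, max)}.
#' @param counts intersection semantics, see \code{\link{spatial_metrics}}.
#' @param resample_method interpolation for grid reconciliation.
#' @param stat_kind statistic type hint when \code{map} is a path.
#' @param tail "positive" or "negative" (sign-flip for deactivation maps).
#' @return An object of class \code{engagement_table}: \code{$icn} one row
#'   per base map with the 11 ICN-specific metrics, \code{$global} the 4
#'   global metrics, \code{$meta} run metadata (atlas, thresholds, bounds).
#' @export
engage <- function(map, atlas, input_threshold = 3, cluster_k = 0,
                   bounds = NULL, counts = c("binary", "labels"),
                   resample_method = "trilinear", stat_kind = "unknown",
                   tail = "positive") {
  counts <- match.arg(counts)
  if (is.character(atlas)) atlas <- load_atlas(atlas)
  input_id <- NA_character_
  if (is.character(map)) { input_id <- map; map <- load_stat_map(map, stat_kind) }
  map <- resample_to_atlas(map, atlas$geometry, method = resample_method)
  raw <- map$values
  if (identical(tail, "negative")) raw <- -raw
  thr_map <- if (is.null(input_threshold)) {
    if (identical(tail, "negative"))
      stat_map(raw, map$geometry, map$stat_kind)
    else map
  } else {
    threshold_map(map, input_threshold, cluster_k = cluster_k, tail = tail)
  }
  la <- label_activation(thr_map, atlas, raw_values = raw)
  sp <- spatial_metrics(la, atlas, counts = counts)
  av <- activation_metrics(la, atlas, bounds = bounds, counts = counts)
  icn <- cbind(sp$icn,
               av$icn[match(sp$icn$component, av$icn$component),
                      c("MA", "MA_N", "RA_N", "IR_M", "I_M", "r")],
               artefact = atlas$artefact_flags)
  rownames(icn) <- NULL
  structure(list(icn = icn,
                 global = c(sp$global, av$global),
                 meta = list(atlas = atlas$provenance,
                             atlas_threshold = atlas$threshold,
                             input_threshold = input_threshold,
                             cluster_k = cluster_k,
                             counts = counts,
                             bounds = av$bounds,
                             tail = tail,
                             input = input_id,
                             n_active = la$n_active)),
            class = "engagement_table")
}

#' @export
print.engagement_table <- function(x, digits = 3, ...) {
  cat("<engagement_table> atlas '", x$meta$atlas, "', ",
      nrow(x$icn), " base maps, ", x$meta$n_active,
      " active voxels\n", sep = "")
  print(cbind(x$icn[1], round(x$icn[, !vapply(x$icn, is.character, TRUE) &
                                      names(x$icn) != "artefact"], digits)))
  cat("global: ", paste(names(x$global), round(x$global, digits),
                        sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Tidy long-format view of an engagement table
#'
#' @param x an \code{engagement_table}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return Data frame with columns basemap, metric, value, defined; global
#'   metrics carry basemap "(global)". Undefined cells keep \code{NA} with
#'   \code{defined = FALSE}.
#' @export
as.data.frame.engagement_table <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  metric_cols <- setdiff(names(x$icn), c("component", "artefact"))
  long <- do.call(rbind, lapply(metric_cols, function(m)
    data.frame(basemap = x$icn$component, metric = m, value = x$icn[[m]],
               stringsAsFactors = FALSE)))
  glob <- data.frame(basemap = "(global)", metric = names(x$global),
                     value = unname(x$global), stringsAsFactors = FALSE)
  out <- rbind(long, glob)
  out$defined <- !is.na(out$value)
  rownames(out) <- NULL
  out
}

#' Write an engagement table as tidy CSV
#'
#' @param x an \code{engagement_table} (or list of them; tables are
#'   concatenated with a \code{map} column).
#' @param path output CSV file.
#' @param map_ids optional identifiers when \code{x} is a list.
#' @return \code{path}, invisibly.
#' @export
write_engagement_csv <- function(x, path, map_ids = NULL) {
  if (inherits(x, "engagement_table")) x <- list(x)
  if (is.null(map_ids))
    map_ids <- vapply(seq_along(x), function(i) {
      id <- x[[i]]$meta$input
      if (is.na(id)) paste0("map", i) else id
    }, character(1))
  rows <- do.call(rbind, lapply(seq_along(x), function(i)
    cbind(map = map_ids[i], as.data.frame(x[[i]]))))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
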