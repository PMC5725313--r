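#' Statistical map container
#'
#' One input statistical volume (SPM{T}, SPM{F}, Z map, or arbitrary
#' statistic) on a defined grid. \code{NA} marks voxels carrying no value
#' (outside the brain, or removed by thresholding).
#'
#' @param values 3-D numeric array.
#' @param geometry a \code{\link{grid_geometry}}; defaults to an identity
#'   affine on the array grid.
#' @param stat_kind one of "T", "F", "Z", "unknown".
#' @param thresholded logical; has significance thresholding been applied?
#' @param threshold_value the applied threshold, or \code{NULL}.
#' @return An object of class \code{stat_map}.
#' @export
stat_map <- function(values, geometry = NULL, stat_kind = "unknown",
                     thresholded = FALSE, threshold_value = NULL) {
  if (length(dim(values)) != 3L) stop("'values' must be a 3-D array")
  storage.mode(values) <- "double"
  if (is.null(geometry)) geometry <- grid_geometry(dim(values))
  if (!identical(as.integer(dim(values)), geometry$shape))
    stop_geometry("values do not match the stated grid shape")
  stat_kind <- match.arg(stat_kind, c("T", "F", "Z", "unknown"))
  structure(list(geometry = geometry, values = values, stat_kind = stat_kind,
                 thresholded = isTRUE(thresholded),
                 threshold_value = threshold_value),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", paste(x$geometry$shape, collapse = " x "),
      " grid, kind ", x$stat_kind,
      if (x$thresholded) sprintf(", thresholded at %g", x$threshold_value),
      ", ", sum(!is.na(x$values)), " voxels with values\n", sep = "")
  invisible(x)
}

#' Load a statistical map from a NIfTI/Analyze volume
#'
#' @param path a \code{.nii}, \code{.nii.gz} or Analyze \code{.hdr/.img}
#'   file.
#' @param stat_kind hint for the statistic type; kept as metadata only.
#' @param volume for 4-D inputs, the 1-based volume index to extract.
#'   4-D input without an explicit index is an error.
#' @return A \code{\link{stat_map}} with geometry taken from the header and
#'   values preserved.
#' @export
load_stat_map <- function(path, stat_kind = "unknown", volume = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    extra <- d[-(1:3)]
    if (prod(extra) > 1L && is.null(volume))
      stop("input is 4-D (", prod(extra), " volumes); pass 'volume' to ",
           "select which one to atlase", call. = FALSE)
    v <- if (is.null(volume)) 1L else as.integer(volume)
    if (v < 1L || v > prod(extra)) stop("'volume' out of range")
    arr <- array(as.double(img), c(prod(d[1:3]), prod(extra)))[, v]
    values <- array(arr, d[1:3])
  } else {
    values <- array(as.double(img), d[1:3])
  }
  stat_map(values, geometry_from_nifti(img), stat_kind = stat_kind)
}

#' Write a statistical map as NIfTI
#'
#' @param map a \code{stat_map}.
#' @param path output file (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
save_stat_map <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  img <- RNifti::`sform<-`(img, structure(map$geometry$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Resample a statistical map onto an atlas grid
#'
#' Carries the input map onto the target grid in world space: each target
#' voxel centre is mapped through the two affines to a continuous source
#' voxel coordinate and the value interpolated there. Trilinear is the
#' default for continuous statistic volumes; use nearest for label or mask
#' volumes. A target voxel whose interpolation stencil falls outside the
#' source field of view, or touches any \code{NA} source voxel (under
#' trilinear), is \code{NA}: missingness is never smoothed into numbers.
#'
#' If the map is already on the target grid it is returned unchanged.
#'
#' @param map a \code{\link{stat_map}}.
#' @param target a \code{\link{grid_geometry}} (e.g. \code{atlas$geometry}).
#' @param method "trilinear" or "nearest".
#' @return A \code{stat_map} on the target geometry.
#' @export
resample_to_atlas <- function(map, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (inherits(target, "label_atlas")) target <- target$geometry
  stopifnot(inherits(map, "stat_map"), inherits(target, "grid_geometry"))
  if (same_geometry(map$geometry, target)) return(map)

  sh <- target$shape
  ijk <- as.matrix(expand.grid(i = 0:(sh[1] - 1L), j = 0:(sh[2] - 1L),
                               k = 0:(sh[3] - 1L)))
  src <- world_to_voxel(map$geometry, voxel_to_world(target, ijk))
  sdim <- map$geometry$shape
  vals <- map$values

  inside_count <- sum(src[, 1] > -0.5 & src[, 1] < sdim[1] - 0.5 &
                      src[, 2] > -0.5 & src[, 2] < sdim[2] - 0.5 &
                      src[, 3] > -0.5 & src[, 3] < sdim[3] - 0.5)
  if (inside_count == 0L)
    stop("no spatial overlap between the input map and the target grid",
         call. = FALSE)

  if (method == "nearest") {
    idx <- ceiling(src - 0.5)    # half-way ties go to the lower voxel index
    ok <- idx[, 1] >= 0 & idx[, 1] < sdim[1] &
          idx[, 2] >= 0 & idx[, 2] < sdim[2] &
          idx[, 3] >= 0 & idx[, 3] < sdim[3]
    out <- rep(NA_real_, nrow(idx))
    lin <- idx[ok, 1] + sdim[1] * (idx[ok, 2] + sdim[2] * idx[ok, 3]) + 1
    out[ok] <- vals[lin]
  } else {
    f <- floor(src)
    w <- src - f
    ok <- f[, 1] >= 0 & f[, 1] + 1 <= sdim[1] - 1 &
          f[, 2] >= 0 & f[, 2] + 1 <= sdim[2] - 1 &
          f[, 3] >= 0 & f[, 3] + 1 <= sdim[3] - 1
    # voxels whose source position is exactly on the grid boundary face
    # still interpolate if the fraction is zero there
    exact_hi <- function(ax) f[, ax] == sdim[ax] - 1 & w[, ax] == 0
    for (ax in 1:3) {
      hit <- !ok & exact_hi(ax)
      if (any(hit)) { f[hit, ax] <- f[hit, ax] - 1; w[hit, ax] <- 1 }
    }
    ok <- f[, 1] >= 0 & f[, 1] + 1 <= sdim[1] - 1 &
          f[, 2] >= 0 & f[, 2] + 1 <= sdim[2] - 1 &
          f[, 3] >= 0 & f[, 3] + 1 <= sdim[3] - 1
    out <- rep(NA_real_, nrow(src))
    if (any(ok)) {
      fo <- f[ok, , drop = FALSE]; wo <- w[ok, , drop = FALSE]
      acc <- numeric(sum(ok))
      bad <- logical(sum(ok))
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        lin <- (fo[, 1] + dx) + sdim[1] * ((fo[, 2] + dy) +
                 sdim[2] * (fo[, 3] + dz)) + 1
        v <- vals[lin]
        wt <- (if (dx) wo[, 1] else 1 - wo[, 1]) *
              (if (dy) wo[, 2] else 1 - wo[, 2]) *
              (if (dz) wo[, 3] else 1 - wo[, 3])
        bad <- bad | is.na(v)
        v[is.na(v)] <- 0
        acc <- acc + wt * v
      }
      acc[bad] <- NA_real_
      out[ok] <- acc
    }
  }
  stat_map(array(out, sh), target, stat_kind = map$stat_kind,
           thresholded = map$thresholded,
           threshold_value = map$threshold_value)
}

#' Apply significance and cluster-extent thresholding
#'
#' Retains voxels whose value strictly exceeds the threshold; everything
#' else becomes \code{NA}. With \code{cluster_k > 0}, surviving voxels are
#' grouped into 26-connected components and components with fewer than
#' \code{cluster_k} voxels are removed (the SPM cluster-extent convention).
#' For deactivation maps set \code{tail = "negative"}: the map's sign is
#' flipped before thresholding.
#'
#' Thresholding is idempotent and monotone in the threshold.
#'
#' @param map a \code{\link{stat_map}}.
#' @param threshold numeric statistic threshold (strict \code{>}).
#' @param cluster_k minimum surviving cluster size in voxels (0 = none).
#' @param tail "positive" (default) or "negative".
#' @return A thresholded \code{stat_map}.
#' @export
threshold_map <- function(map, threshold, cluster_k = 0, tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  stopifnot(inherits(map, "stat_map"))
  if (!is.numeric(cluster_k) || length(cluster_k) != 1L || cluster_k < 0)
    stop("'cluster_k' must be a non-negative integer", call. = FALSE)
  v <- map$values
  if (tail == "negative") v <- -v
  keep <- !is.na(v) & v > threshold
  v[!keep] <- NA_real_
  if (cluster_k > 0 && any(keep)) {
    comp <- connected_components(keep)
    sizes <- tabulate(comp[keep])
    drop <- which(sizes < cluster_k)
    if (length(drop)) v[comp %in% drop] <- NA_real_
  }
  stat_map(v, map$geometry, stat_kind = map$stat_kind, thresholded = TRUE,
           threshold_value = threshold)
}

# 26-connectivity connected-component labelling of a 3-D logical mask.
# Returns an integer array: 0 outside the mask, component id inside.
connected_components <- function(mask) {
  d <- dim(mask)
  comp <- array(0L, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lin_off <- offs[, 1] + d[1] * (offs[, 2] + d[2] * offs[, 3])
  idx_all <- which(mask)
  next_id <- 0L
  for (start in idx_all) {
    if (comp[start] != 0L) next
    next_id <- next_id + 1L
    queue <- start
    comp[start] <- next_id
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      nb_i <- ci[1] + offs[, 1]; nb_j <- ci[2] + offs[, 2]; nb_k <- ci[3] + offs[, 3]
      ok <- nb_i >= 1 & nb_i <= d[1] & nb_j >= 1 & nb_j <= d[2] &
            nb_k >= 1 & nb_k <= d[3]
      nb <- cur + lin_off[ok]
      nb <- nb[mask[nb] & comp[nb] == 0L]
      if (length(nb)) {
        comp[nb] <- next_id
        queue <- c(queue, nb)
      }
    }
  }
  comp
}
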