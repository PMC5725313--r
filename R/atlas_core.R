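#' Set of ICN prototype Z-score maps
#'
#' Container for the K co-registered component Z-score volumes from which a
#' base atlas is built. Each volume is the Gaussianised statistical map of
#' one ICA component (an intrinsic connectivity network prototype, or an
#' artefact component).
#'
#' @param z either a 4-D numeric array (x, y, z, component) or a list of K
#'   3-D arrays sharing one grid.
#' @param component_names character vector of K unique names. Defaults to
#'   \code{ICN1..ICNK}.
#' @param geometry a \code{\link{grid_geometry}}; defaults to an identity
#'   affine on the array grid.
#' @param artefact_flags logical vector of K flags marking noise/artefact
#'   components (e.g. 2 of 20 in the d=20 BrainMap decomposition). Flagged
#'   components are built into the atlas like any other; the flag is carried
#'   through to reports.
#' @param provenance free-text atlas name/reference.
#' @return An object of class \code{zmap_set}.
#' @export
zmap_set <- function(z, component_names = NULL, geometry = NULL,
                     artefact_flags = NULL, provenance = "") {
  if (is.list(z)) {
    dims <- unique(lapply(z, dim))
    if (length(dims) != 1L)
      stop_geometry("component volumes have differing dimensions")
    z <- array(unlist(z, use.names = FALSE), c(dims[[1]], length(z)))
  }
  if (length(dim(z)) != 4L) stop("'z' must be a 4-D array or list of 3-D arrays")
  storage.mode(z) <- "double"
  K <- dim(z)[4]
  if (K < 1L) stop("at least one component volume is required")
  if (is.null(component_names)) component_names <- paste0("ICN", seq_len(K))
  component_names <- as.character(component_names)
  if (length(component_names) != K || anyDuplicated(component_names))
    stop("'component_names' must be ", K, " unique names")
  if (is.null(artefact_flags)) artefact_flags <- rep(FALSE, K)
  artefact_flags <- as.logical(artefact_flags)
  if (length(artefact_flags) != K || anyNA(artefact_flags))
    stop("'artefact_flags' must be ", K, " non-missing logicals")
  if (is.null(geometry)) geometry <- grid_geometry(dim(z)[1:3])
  if (!identical(as.integer(dim(z)[1:3]), geometry$shape))
    stop_geometry("Z volumes do not match the stated grid shape")
  structure(list(geometry = geometry, z = z,
                 component_names = component_names,
                 artefact_flags = artefact_flags,
                 provenance = as.character(provenance)[1]),
            class = "zmap_set")
}

#' @export
print.zmap_set <- function(x, ...) {
  cat("<zmap_set> ", dim(x$z)[4], " components on ",
      paste(x$geometry$shape, collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' Build a winner-take-all ICN base atlas
#'
#' Thresholds each prototype Z map at \code{threshold} (strictly greater
#' than) and assigns every voxel the label of the component with the highest
#' supra-threshold Z there, so that any given voxel belongs to at most one
#' component. Voxels where no component exceeds the threshold are unlabelled
#' (\code{NA}). Binary per-component masks (Z > threshold) are kept
#' alongside; these may overlap across components, unlike the labels.
#'
#' Exact ties in the supra-threshold Z are resolved deterministically in
#' favour of the lowest component index; ties have measure zero on real
#' Z maps but the rule makes synthetic runs reproducible. A Z exactly equal
#' to the threshold is excluded.
#'
#' @param zmaps a \code{\link{zmap_set}}.
#' @param threshold numeric atlas threshold T on the prototype Z scores;
#'   default 3, the conventional base-map threshold.
#' @return An object of class \code{label_atlas} with fields
#'   \code{geometry}, \code{labels} (3-D integer array, \code{NA} where
#'   unlabelled), \code{z} (the full 4-D prototype Z stack), \code{binary}
#'   (4-D logical), \code{threshold}, \code{component_names},
#'   \code{artefact_flags}, \code{provenance}.
#' @seealso \code{\link{atlas_masked_z}} for the thresholded Z volumes,
#'   \code{\link{atlas_summary}}, \code{\link{save_atlas}}.
#' @export
build_atlas <- function(zmaps, threshold = 3) {
  if (!inherits(zmaps, "zmap_set")) stop("'zmaps' must be a zmap_set")
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite number")
  dims <- dim(zmaps$z)
  M <- prod(dims[1:3]); K <- dims[4]
  zm <- matrix(zmaps$z, M, K)
  supra <- !is.na(zm) & zm > threshold
  zneg <- zm
  zneg[!supra] <- -Inf
  lab <- max.col(zneg, ties.method = "first")
  lab[!matrixStats_any(supra)] <- NA_integer_
  labels <- array(as.integer(lab), dims[1:3])
  binary <- array(supra, dims)
  if (all(is.na(lab)))
    warning("no voxel exceeds the atlas threshold: atlas is empty")
  structure(list(geometry = zmaps$geometry, labels = labels, z = zmaps$z,
                 binary = binary, threshold = threshold,
                 component_names = zmaps$component_names,
                 artefact_flags = zmaps$artefact_flags,
                 provenance = zmaps$provenance),
            class = "label_atlas")
}

# rowwise any() for a logical matrix, without extra dependencies
matrixStats_any <- function(m) rowSums(m) > 0L

#' @export
print.label_atlas <- function(x, ...) {
  n_lab <- sum(!is.na(x$labels))
  cat("<label_atlas> ", length(x$component_names), " base maps, T = ",
      x$threshold, ", ", n_lab, "/", prod(x$geometry$shape),
      " voxels labelled\n", sep = "")
  invisible(x)
}

#' Thresholded (masked) prototype Z volumes of an atlas
#'
#' Returns the per-component Z volumes with sub-threshold voxels set to
#' \code{NA}: the masked base maps from which the winner-take-all labels are
#' derived.
#'
#' @param atlas a \code{label_atlas}.
#' @return 4-D numeric array matching \code{atlas$z}.
#' @export
atlas_masked_z <- function(atlas) {
  zm <- atlas$z
  zm[!atlas$binary] <- NA_real_
  zm
}

#' Per-component summary of a label atlas
#'
#' @param atlas a \code{label_atlas}.
#' @return A data frame with one row per base map: labelled voxel count
#'   (mutually exclusive), binary-mask voxel count (may overlap), fraction
#'   of the grid covered by the binary mask, and the artefact flag. The
#'   labelled counts sum to the number of labelled voxels.
#' @export
atlas_summary <- function(atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  K <- length(atlas$component_names)
  M <- prod(atlas$geometry$shape)
  lab <- atlas$labels
  n_label <- tabulate(lab[!is.na(lab)], nbins = K)
  n_binary <- colSums(matrix(atlas$binary, M, K))
  data.frame(component = atlas$component_names,
             artefact = atlas$artefact_flags,
             n_labelled = as.integer(n_label),
             n_binary = as.integer(n_binary),
             frac_grid = n_binary / M,
             stringsAsFactors = FALSE)
}

#' Persist a label atlas to a directory
#'
#' Writes three files: \code{labels.nii.gz} (integer label volume, 0 for
#' unlabelled voxels), \code{zstack.nii.gz} (4-D prototype Z stack) and
#' \code{meta.json} (schema-versioned sidecar holding component names,
#' threshold, artefact flags, provenance and the affine).
#'
#' @param atlas a \code{label_atlas}.
#' @param path directory to create/write into.
#' @return \code{path}, invisibly.
#' @export
save_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "label_atlas"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  lab <- atlas$labels
  lab[is.na(lab)] <- 0L
  lab_img <- RNifti::asNifti(array(as.double(lab), dim(lab)))
  lab_img <- RNifti::`sform<-`(lab_img, structure(atlas$geometry$affine, code = 2L))
  RNifti::writeNifti(lab_img, file.path(path, "labels.nii.gz"),
                     datatype = "int32")
  z_img <- RNifti::asNifti(atlas$z)
  z_img <- RNifti::`sform<-`(z_img, structure(atlas$geometry$affine, code = 2L))
  RNifti::writeNifti(z_img, file.path(path, "zstack.nii.gz"),
                     datatype = "double")
  meta <- list(icn_atlas_schema = 1L,
               component_names = atlas$component_names,
               artefact_flags = atlas$artefact_flags,
               threshold = atlas$threshold,
               missing_label = 0L,
               provenance = atlas$provenance,
               affine = atlas$geometry$affine)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a label atlas saved by \code{save_atlas}
#'
#' @param path atlas directory.
#' @return A \code{label_atlas}. Labels, names, threshold and affine round
#'   trip exactly; Z volumes to stored floating precision.
#' @export
load_atlas <- function(path) {
  need <- c("labels.nii.gz", "zstack.nii.gz", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("not a valid atlas directory: missing ",
         paste(missing, collapse = ", "), call. = FALSE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  for (field in c("component_names", "threshold", "affine"))
    if (is.null(meta[[field]]))
      stop("atlas metadata is missing field '", field, "'", call. = FALSE)
  lab_img <- RNifti::readNifti(file.path(path, "labels.nii.gz"))
  z_img <- RNifti::readNifti(file.path(path, "zstack.nii.gz"))
  affine <- matrix(unlist(meta$affine), 4, 4)
  geometry <- grid_geometry(dim(lab_img)[1:3], affine)
  labels <- array(as.integer(lab_img), dim(lab_img)[1:3])
  miss <- if (is.null(meta$missing_label)) 0L else as.integer(meta$missing_label)
  labels[labels == miss] <- NA_integer_
  z <- array(as.double(z_img), dim(z_img))
  if (length(dim(z)) == 3L) z <- array(z, c(dim(z), 1L))
  threshold <- as.numeric(meta$threshold)
  flags <- if (is.null(meta$artefact_flags))
    rep(FALSE, length(meta$component_names)) else as.logical(meta$artefact_flags)
  binary <- !is.na(z) & z > threshold
  structure(list(geometry = geometry, labels = labels, z = z,
                 binary = array(binary, dim(z)), threshold = threshold,
                 component_names = as.character(meta$component_names),
                 artefact_flags = flags,
                 provenance = if (is.null(meta$provenance)) "" else meta$provenance),
            class = "label_atlas")
}
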