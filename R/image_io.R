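# Gray-matter map and parcellation I/O, smoothing and regional extraction.

#' Construct a gray-matter map object
#'
#' A \code{gm_map} holds one subject's 3D gray-matter value image (modulated
#' tissue fraction, unitless and non-negative) together with the 4x4
#' voxel-to-world affine (RAS mm; voxel indices are 0-based).
#'
#' @param values 3D numeric array of gray-matter values.
#' @param affine 4x4 voxel-to-mm transform.
#' @param subject_id Subject identifier.
#' @param space_tag Label for the coordinate space (e.g. \code{"MNI"}).
#' @return An object of class \code{gm_map}.
#' @export
gm_map <- function(values, affine = diag(4), subject_id = "subject",
                   space_tag = "MNI") {
  if (length(dim(values)) != 3L)
    stopf("expected 3D volume, got %dD", length(dim(values)))
  if (!all(is.finite(values)))
    stopf("gray-matter map contains %d non-finite voxels",
          sum(!is.finite(values)))
  if (any(values < 0))
    stopf("gray-matter map contains %d negative voxels; clip before construction",
          sum(values < 0))
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(subject_id = subject_id, values = values,
                 affine = unname(affine), space_tag = space_tag),
            class = "gm_map")
}

#' @export
print.gm_map <- function(x, ...) {
  cat(sprintf("<gm_map> subject '%s', grid %s, space %s\n", x$subject_id,
              paste(dim(x$values), collapse = "x"), x$space_tag))
  invisible(x)
}

#' Construct an atlas parcellation object
#'
#' @param labels 3D integer array of region labels; 0 is background.
#' @param regions Data frame with columns \code{region_id} (unique positive
#'   integers) and \code{region_name}.
#' @param affine 4x4 voxel-to-mm transform.
#' @return An object of class \code{atlas_parcellation}.
#' @export
atlas_parcellation <- function(labels, regions, affine = diag(4)) {
  if (length(dim(labels)) != 3L)
    stopf("expected 3D label volume, got %dD", length(dim(labels)))
  storage.mode(labels) <- "integer"
  stopifnot(is.data.frame(regions),
            all(c("region_id", "region_name") %in% names(regions)))
  if (anyDuplicated(regions$region_id))
    stopf("duplicate region ids in region table")
  if (any(regions$region_id <= 0))
    stopf("region ids must be positive integers")
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0L]
  missing <- setdiff(present, regions$region_id)
  if (length(missing))
    stopf("labels present in volume but absent from region table: %s",
          paste(missing, collapse = ", "))
  empty <- setdiff(regions$region_id, present)
  if (length(empty))
    stopf("regions with no voxels: %s", paste(empty, collapse = ", "))
  structure(list(labels = labels,
                 regions = regions[order(regions$region_id), , drop = FALSE],
                 affine = unname(affine)),
            class = "atlas_parcellation")
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  cat(sprintf("<atlas_parcellation> %d regions, grid %s\n",
              nrow(x$regions), paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Packaged 90-region AAL cerebrum region table
#'
#' Region ids 1-90 with the standard Automated Anatomical Labeling names for
#' the 90 cortical and subcortical cerebrum regions.
#'
#' @return Data frame with columns \code{region_id}, \code{region_name}.
#' @export
aal90_regions <- function() {
  path <- system.file("extdata", "aal90_regions.tsv", package = "imcn",
                      mustWork = TRUE)
  read_tsv(path)
}

#' Read a gray-matter map from a NIfTI-1 file
#'
#' Negative voxels (which can arise from interpolation during spatial
#' normalisation) are clipped to zero, with the count reported as a warning;
#' densities are non-negative by definition.
#'
#' @param path Path to a 3D \code{.nii}/\code{.nii.gz} file.
#' @param subject_id Subject identifier; defaults to the file name.
#' @param space_tag Coordinate-space label stored on the object.
#' @return A \code{\link{gm_map}}.
#' @export
load_gm_map <- function(path, subject_id = NULL, space_tag = "MNI") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] == 1L) dim(img) <- dm[1:3]
  if (length(dim(img)) != 3L)
    stopf("expected 3D volume, got %dD: %s", length(dm), path)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  if (!all(is.finite(vals)))
    stopf("%d non-finite voxels in %s", sum(!is.finite(vals)), path)
  n_neg <- sum(vals < 0)
  if (n_neg > 0) {
    warnf("clipped %d negative voxels to 0 in %s", n_neg, path)
    vals[vals < 0] <- 0
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  gm_map(vals, aff, subject_id = subject_id, space_tag = space_tag)
}

#' Write a gray-matter map to a NIfTI-1 file
#'
#' Values are stored as float64 so that a write-then-read round trip is
#' value-identical.
#'
#' @param map A \code{\link{gm_map}}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return The path, invisibly.
#' @export
write_gm_map <- function(map, path) {
  stopifnot(inherits(map, "gm_map"))
  img <- RNifti::asNifti(map$values, datatype = "double")
  img <- set_affine(img, map$affine)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an atlas parcellation from NIfTI plus a region table
#'
#' @param label_path Path to the integer-labelled NIfTI volume (0 = background).
#' @param region_table_path Path to a TSV with columns \code{region_id},
#'   \code{region_name}; when \code{NULL} and labels span 1-90 the packaged
#'   AAL-90 table is used, otherwise names \code{R001}, ... are generated.
#' @return An \code{\link{atlas_parcellation}}.
#' @export
load_atlas <- function(label_path, region_table_path = NULL) {
  if (!file.exists(label_path)) stopf("file not found: %s", label_path)
  img <- RNifti::readNifti(label_path)
  if (length(dim(img)) != 3L)
    stopf("expected 3D label volume, got %dD", length(dim(img)))
  labels <- as.array(img)
  attributes(labels) <- list(dim = dim(labels))
  labels <- round(labels)
  storage.mode(labels) <- "integer"
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0L]
  if (!is.null(region_table_path)) {
    regions <- read_tsv(region_table_path)
  } else if (length(ids) == 90L && all(ids == 1:90)) {
    regions <- aal90_regions()
  } else {
    regions <- data.frame(region_id = ids,
                          region_name = sprintf("R%03d", ids))
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  atlas_parcellation(labels, regions, aff)
}

#' Write an atlas parcellation
#'
#' @param atlas An \code{\link{atlas_parcellation}}.
#' @param label_path Output NIfTI path for the label volume.
#' @param region_table_path Optional output TSV path for the region table.
#' @return \code{label_path}, invisibly.
#' @export
write_atlas <- function(atlas, label_path, region_table_path = NULL) {
  stopifnot(inherits(atlas, "atlas_parcellation"))
  img <- RNifti::asNifti(atlas$labels, datatype = "int32")
  img <- set_affine(img, atlas$affine)
  RNifti::writeNifti(img, label_path)
  if (!is.null(region_table_path))
    write_tsv(atlas$regions, region_table_path)
  invisible(label_path)
}

# Voxel edge lengths (mm) along each array axis, from the affine.
voxel_sizes <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

# 1D zero-padded Gaussian convolution along the first axis of a matrix,
# implemented as multiplication with a banded kernel matrix.
gaussian_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  radius <- min(n - 1L, as.integer(ceiling(6 * sigma)))
  k <- dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (d in seq(-radius, radius))
    K[cbind(pmax(1, 1 - d):pmin(n, n - d) + d, pmax(1, 1 - d):pmin(n, n - d))] <-
      k[d + radius + 1L]
  K
}

#' Gaussian-smooth a gray-matter map
#'
#' Separable Gaussian filter with per-axis standard deviation
#' \code{fwhm_mm / (2 sqrt(2 log 2)) / voxel_size_mm}, zero-padded at the
#' volume boundary. The discrete kernel is normalised to unit mass, so the
#' total image sum is conserved for structure away from the boundary.
#'
#' @param map A \code{\link{gm_map}}.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm (the
#'   conventional VBM setting is 8 mm). \code{0} returns the input unchanged.
#' @return A smoothed \code{\link{gm_map}}.
#' @export
smooth_gm_map <- function(map, fwhm_mm) {
  stopifnot(inherits(map, "gm_map"))
  if (fwhm_mm < 0) stopf("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(map)
  vs <- voxel_sizes(map$affine)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  a <- map$values
  dm <- dim(a)
  for (axis in 1:3) {
    K <- gaussian_kernel_matrix(dm[axis], sigma_vox[axis])
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dmp <- dim(m)
    m <- K %*% matrix(m, nrow = dmp[1])
    dim(m) <- dmp
    a <- aperm(m, order(perm))
  }
  out <- map
  out$values <- a
  out
}

#' Resample an atlas onto a map's voxel grid
#'
#' Nearest-neighbour resampling through both affines; label volumes must
#' never be interpolated continuously. Map voxels falling outside the atlas
#' grid receive the background label 0.
#'
#' @param atlas An \code{\link{atlas_parcellation}}.
#' @param map A \code{\link{gm_map}} defining the target grid.
#' @return An \code{\link{atlas_parcellation}} on the map grid.
#' @export
resample_atlas <- function(atlas, map) {
  stopifnot(inherits(atlas, "atlas_parcellation"), inherits(map, "gm_map"))
  dm <- dim(map$values)
  idx <- as.matrix(expand.grid(i = 0:(dm[1] - 1L), j = 0:(dm[2] - 1L),
                               k = 0:(dm[3] - 1L)))
  world <- map$affine %*% rbind(t(idx), 1)
  src <- solve(atlas$affine) %*% world
  src <- round(t(src[1:3, , drop = FALSE]))
  da <- dim(atlas$labels)
  ok <- src[, 1] >= 0 & src[, 1] < da[1] &
        src[, 2] >= 0 & src[, 2] < da[2] &
        src[, 3] >= 0 & src[, 3] < da[3]
  lab <- integer(nrow(idx))
  lab[ok] <- atlas$labels[src[ok, , drop = FALSE] + 1L]
  labels <- array(lab, dim = dm)
  atlas_parcellation(labels, atlas$regions, map$affine)
}

#' Extract per-region voxel value samples
#'
#' Returns, for each atlas region, the vector of map values at the voxels
#' carrying that label, ordered by ascending flattened (column-major) voxel
#' index. These per-region samples are the raw material for the kernel
#' density estimates underlying the covariance network.
#'
#' @param map A \code{\link{gm_map}}.
#' @param atlas An \code{\link{atlas_parcellation}} on the same grid.
#' @return An object of class \code{regional_samples}: list with
#'   \code{subject_id} and \code{samples}, a list named by region id.
#' @export
extract_regional_samples <- function(map, atlas) {
  stopifnot(inherits(map, "gm_map"), inherits(atlas, "atlas_parcellation"))
  if (!identical(dim(map$values), dim(atlas$labels)))
    stopf("grid mismatch: map %s vs atlas %s (resample the atlas first)",
          paste(dim(map$values), collapse = "x"),
          paste(dim(atlas$labels), collapse = "x"))
  if (nrow(atlas$regions) == 0L) stopf("atlas has zero regions")
  lab <- as.vector(atlas$labels)
  vals <- as.vector(map$values)
  inside <- lab != 0L
  samples <- split(vals[inside], factor(lab[inside],
                                        levels = atlas$regions$region_id))
  names(samples) <- as.character(atlas$regions$region_id)
  structure(list(subject_id = map$subject_id, samples = samples,
                 region_ids = atlas$regions$region_id),
            class = "regional_samples")
}

#' Per-subject regional mean GMV table
#'
#' @param samples_list List of \code{regional_samples}, one per subject.
#' @return Data frame: first column \code{subject_id}, then one column per
#'   region (atlas region-id order) named \code{region_<id>}.
#' @export
region_mean_table <- function(samples_list) {
  stopifnot(length(samples_list) >= 1L,
            all(vapply(samples_list, inherits, TRUE, "regional_samples")))
  ids0 <- samples_list[[1]]$region_ids
  for (s in samples_list)
    if (!identical(s$region_ids, ids0))
      stopf("inconsistent region sets across subjects (subject '%s')",
            s$subject_id)
  means <- t(vapply(samples_list,
                    function(s) vapply(s$samples, mean, numeric(1)),
                    numeric(length(ids0))))
  out <- data.frame(subject_id = vapply(samples_list, `[[`, "", "subject_id"),
                    means, check.names = FALSE)
  names(out) <- c("subject_id", sprintf("region_%d", ids0))
  rownames(out) <- NULL
  out
}
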