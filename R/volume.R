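#' Construct a volume map
#'
#' A `volume_map` is the carrier of all per-subject and statistical images in
#' the pipeline: a 3D scalar lattice together with its voxel geometry, tissue
#' class and semantic kind. Voxel coordinates are 0-based lattice indices;
#' positions in mm are `origin + index * voxel_size`.
#'
#' @param values 3D numeric array of voxel values. Must be finite;
#'   modulated/rescaled maps must additionally be non-negative.
#' @param voxel_size voxel edge length in mm, scalar or length-3.
#' @param origin mm offset of voxel (0,0,0).
#' @param tissue tissue class of the map.
#' @param kind semantic kind of the map. `"modulated"` maps carry absolute
#'   local tissue volume (value x voxel volume); `"rescaled"` maps have been
#'   divided by the subject's total tissue volume.
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(values, voxel_size = 4, origin = c(0, 0, 0),
                       tissue = c("none", "GM", "WM", "CSF"),
                       kind = c("modulated", "rescaled", "template", "mask",
                                "stat")) {
  tissue <- match.arg(tissue)
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  if (!all(is.finite(values)))
    stop("volume contains non-finite voxel values", call. = FALSE)
  if (kind %in% c("modulated", "rescaled") && any(values < 0))
    stop(sprintf("%s maps must be non-negative", kind), call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0),
            length(origin) == 3L)
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), tissue = tissue, kind = kind),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_map> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, tissue=%s, kind=%s\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$tissue, x$kind))
  invisible(x)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path path to a NIfTI file (.nii or .nii.gz).
#' @param tissue,kind metadata tags to attach (NIfTI has no standard slot for
#'   them).
#' @return A [volume_map].
#' @export
read_volume <- function(path, tissue = "none", kind = "modulated") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D data", call. = FALSE)
  vox <- RNifti::pixdim(img)[1:3]
  vals <- array(as.numeric(img), dim = d)
  if (!all(is.finite(vals)))
    stop("volume contains non-finite voxel values", call. = FALSE)
  orig <- -RNifti::origin(img)[1:3] * vox  # informational only
  volume_map(vals, voxel_size = vox, origin = orig, tissue = tissue,
             kind = kind)
}

#' Write a volume map to a NIfTI-1 file
#'
#' Value data are written as float32 (or uint8 for mask kind), so a
#' write/read round trip preserves values to float32 precision and the voxel
#' geometry exactly.
#'
#' @param vol a [volume_map].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_map"))
  datatype <- if (vol$kind == "mask") "uint8" else "float"
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Build the analysis mask from a template map
#'
#' Voxels enter the analysis where the template, rescaled to a partial volume
#' estimate in `[0, 1]` by its maximum, exceeds `pve_threshold`. With the
#' default 0.25 this restricts group comparisons to the tissue segment of the
#' template and avoids edge effects between tissue classes.
#'
#' @param template a [volume_map]; typically the voxel-wise mean of all
#'   subjects' modulated maps in the analysis (study-specific template
#'   analogue).
#' @param pve_threshold partial-volume-estimate threshold in (0, 1).
#' @return An object of class `analysis_mask` with elements `values`
#'   (logical array), `pve_threshold`, `n_voxels`, `voxel_size`.
#' @export
make_analysis_mask <- function(template, pve_threshold = 0.25) {
  stopifnot(inherits(template, "volume_map"))
  if (pve_threshold <= 0 || pve_threshold >= 1)
    stop("'pve_threshold' must be in (0, 1)", call. = FALSE)
  mx <- max(template$values)
  if (mx <= 0)
    stop("template has no positive voxels; cannot form a mask", call. = FALSE)
  # templates already on the PVE scale (max <= 1) are used as-is; larger
  # scales (e.g. raw modulated means) are normalized by their maximum
  m <- template$values / max(mx, 1) > pve_threshold
  if (!any(m))
    stop("degenerate analysis mask: no voxel exceeds the PVE threshold",
         call. = FALSE)
  structure(list(values = m, pve_threshold = pve_threshold,
                 n_voxels = sum(m), voxel_size = template$voxel_size),
            class = "analysis_mask")
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf("<analysis_mask> %d in-mask voxels (PVE > %.3g) of %s\n",
              x$n_voxels, x$pve_threshold,
              paste(dim(x$values), collapse = " x ")))
  invisible(x)
}

#' Total tissue volume of a modulated map
#'
#' Sums the partial volume estimates over the lattice and multiplies by the
#' voxel volume, i.e. the integral of the modulated map, reported in cm^3.
#'
#' @param vol a non-negative [volume_map].
#' @return total tissue volume in cm^3.
#' @export
total_tissue_volume <- function(vol) {
  stopifnot(inherits(vol, "volume_map"))
  if (any(vol$values < 0))
    stop("negative voxel values: not a modulated tissue map", call. = FALSE)
  sum(vol$values) * prod(vol$voxel_size) / 1000
}

#' Rescale a modulated map by a total tissue volume
#'
#' Divides every voxel by the subject's total tissue volume of the same
#' class, yielding a map of relative tissue volume. Rescaling is
#' tissue-specific (not by total brain volume) so that tissue-specific local
#' variation is preserved.
#'
#' @param vol a [volume_map] of kind `"modulated"`.
#' @param total total tissue volume in cm^3 (must be > 0); typically
#'   [total_tissue_volume] of the same subject's map.
#' @return A [volume_map] of kind `"rescaled"`.
#' @export
rescale_map <- function(vol, total) {
  stopifnot(inherits(vol, "volume_map"))
  if (!is.numeric(total) || length(total) != 1L || total <= 0)
    stop("'total' must be a single positive volume in cm^3", call. = FALSE)
  out <- vol
  out$values <- vol$values / total
  out$kind <- "rescaled"
  out
}

# -- Gaussian smoothing ------------------------------------------------------

gaussian_kernel_1d <- function(fwhm_vox) {
  if (fwhm_vox <= 0) return(1)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# arr: 3D array; fwhm_vox: per-axis FWHM in voxel units
smooth_field <- function(arr, fwhm_vox, boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  d <- dim(arr)
  if (length(fwhm_vox) == 1L) fwhm_vox <- rep(fwhm_vox, 3L)
  k <- lapply(fwhm_vox, gaussian_kernel_1d)
  if (all(lengths(k) == 1L)) return(arr)
  out <- conv3d_sep(as.numeric(arr), as.integer(d), k[[1]], k[[2]], k[[3]],
                    boundary = if (boundary == "periodic") 1L else 0L)
  array(out, dim = d)
}

#' Smooth a volume map with a Gaussian kernel
#'
#' Separable Gaussian convolution with `sigma = FWHM / (2 sqrt(2 ln 2))` per
#' axis (in voxel units). Half-sample symmetric (reflective) boundary
#' handling conserves the integrated tissue volume and keeps near-edge
#' smoothness stationary; `fwhm_mm = 0` is the identity.
#'
#' @param vol a [volume_map].
#' @param fwhm_mm full width at half maximum of the kernel in mm (scalar or
#'   per-axis).
#' @return The smoothed [volume_map].
#' @export
gaussian_smooth <- function(vol, fwhm_mm = 4) {
  stopifnot(inherits(vol, "volume_map"))
  if (any(fwhm_mm < 0)) stop("'fwhm_mm' must be >= 0", call. = FALSE)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  out <- vol
  out$values <- smooth_field(vol$values, fwhm_mm / vol$voxel_size)
  out
}
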