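#' Stack of per-subject volume maps
#'
#' A `map_stack` stores one tissue class for a whole cohort as a voxels x
#' subjects matrix plus the shared lattice geometry. It is the unit the
#' mass-univariate GLM operates on; individual subjects can be pulled out as
#' [volume_map] objects with [get_subject_volume()].
#'
#' @param data numeric matrix, voxels (column-major lattice order) x subjects.
#' @param dims 3D lattice dimensions.
#' @param voxel_size voxel edge length(s) in mm.
#' @param tissue tissue class.
#' @param subject_ids character vector of subject identifiers.
#' @param kind `"modulated"` or `"rescaled"`.
#' @return An object of class `map_stack`.
#' @export
map_stack <- function(data, dims, voxel_size = 4, tissue = "GM",
                      subject_ids = colnames(data), kind = "modulated") {
  dims <- as.integer(dims)
  stopifnot(is.matrix(data), length(dims) == 3L, nrow(data) == prod(dims))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(ncol(data)))
  structure(list(data = data, dims = dims,
                 voxel_size = as.numeric(voxel_size), tissue = tissue,
                 subject_ids = subject_ids, kind = kind),
            class = "map_stack")
}

#' @export
print.map_stack <- function(x, ...) {
  cat(sprintf("<map_stack> %s, %d subjects on %s lattice (%s)\n", x$tissue,
              ncol(x$data), paste(x$dims, collapse = " x "), x$kind))
  invisible(x)
}

#' Extract one subject's map from a stack
#'
#' @param stack a [map_stack].
#' @param i subject index or id.
#' @return A [volume_map].
#' @export
get_subject_volume <- function(stack, i) {
  stopifnot(inherits(stack, "map_stack"))
  if (is.character(i)) i <- match(i, stack$subject_ids)
  volume_map(array(stack$data[, i], dim = stack$dims),
             voxel_size = stack$voxel_size, tissue = stack$tissue,
             kind = stack$kind)
}

#' Combine volume maps into a stack
#'
#' @param vols list of [volume_map]s with identical geometry.
#' @param subject_ids optional ids.
#' @return A [map_stack].
#' @export
stack_volumes <- function(vols, subject_ids = NULL) {
  stopifnot(length(vols) >= 1L, all(vapply(vols, inherits, TRUE, "volume_map")))
  d <- dim(vols[[1]]$values)
  data <- vapply(vols, function(v) {
    if (!identical(dim(v$values), d)) stop("geometry mismatch", call. = FALSE)
    as.numeric(v$values)
  }, numeric(prod(d)))
  map_stack(data, d, voxel_size = vols[[1]]$voxel_size,
            tissue = vols[[1]]$tissue, subject_ids = subject_ids,
            kind = vols[[1]]$kind)
}

#' Integrated tissue volumes of a stack
#'
#' @param stack a [map_stack] of modulated maps.
#' @return numeric vector of per-subject total tissue volumes in cm^3.
#' @export
stack_totals <- function(stack) {
  stopifnot(inherits(stack, "map_stack"))
  colSums(stack$data) * prod(stack$voxel_size) / 1000
}

#' Rescale every subject in a stack by its total tissue volume
#'
#' @param stack a [map_stack] of modulated maps.
#' @param totals per-subject totals in cm^3; computed with [stack_totals()]
#'   when omitted.
#' @return A [map_stack] of kind `"rescaled"`.
#' @export
rescale_stack <- function(stack, totals = NULL) {
  stopifnot(inherits(stack, "map_stack"))
  if (is.null(totals)) totals <- stack_totals(stack)
  stopifnot(length(totals) == ncol(stack$data), all(totals > 0))
  out <- stack
  out$data <- sweep(stack$data, 2L, totals, "/")
  out$kind <- "rescaled"
  out
}

#' Mean template of a stack
#'
#' Voxel-wise mean of all subjects' maps, the study-specific template
#' analogue used to derive the analysis mask.
#'
#' @param stack a [map_stack].
#' @return A [volume_map] of kind `"template"`.
#' @export
stack_template <- function(stack) {
  stopifnot(inherits(stack, "map_stack"))
  volume_map(array(rowMeans(stack$data), dim = stack$dims),
             voxel_size = stack$voxel_size, tissue = stack$tissue,
             kind = "template")
}
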