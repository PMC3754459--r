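#' The voxel-level threshold ladder
#'
#' The 500 equally spaced voxel-level probabilities `p_k = k * 1e-4`,
#' k = 1..500, spanning P = 0.0001 up to P = 0.05 — the unique uniform grid
#' matching both endpoints and the count. Overlap is traced along the whole
#' ladder to show whether it is consistent and stable rather than an
#' artefact of one threshold.
#'
#' @param n number of rungs.
#' @param step probability step between rungs.
#' @return Increasing vector of voxel-level probabilities.
#' @export
threshold_ladder <- function(n = 500L, step = 1e-4) {
  seq_len(n) * step
}

#' Gaussianize a t map by probability matching
#'
#' Monotone conversion `z = qnorm(pt(t, df))`, computed tail-wise in log
#' space for numerical stability. Voxel ranking by t equals ranking by z.
#'
#' @param stat a [t_contrast()] map.
#' @return 3D array of z values (NA outside the mask).
#' @export
gaussianize_t <- function(stat) {
  stopifnot(inherits(stat, "stat_map"))
  t <- stat$t
  z <- array(NA_real_, dim = dim(t))
  lo <- !is.na(t) & t <= 0
  hi <- !is.na(t) & t > 0
  z[lo] <- qnorm(pt(t[lo], stat$df, log.p = TRUE), log.p = TRUE)
  z[hi] <- -qnorm(pt(-t[hi], stat$df, log.p = TRUE), log.p = TRUE)
  z
}

#' Conjunction (logical AND) of two suprathreshold masks
#'
#' @param a,b [threshold_statmap()] masks with identical geometry and
#'   forming threshold.
#' @return A `supra_mask` of the voxel-wise AND; commutative.
#' @export
conjunction_mask <- function(a, b) {
  stopifnot(inherits(a, "supra_mask"), inherits(b, "supra_mask"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("geometry mismatch between masks", call. = FALSE)
  v <- a$values & b$values
  structure(list(values = v, voxel_p = a$voxel_p, height = a$height,
                 df = a$df, label = paste(a$label, "AND", b$label),
                 voxel_size = a$voxel_size, n_voxels = sum(v)),
            class = "supra_mask")
}

#' Overlap of two suprathreshold masks as a percentage
#'
#' `100 |A AND B| / |denominator map|`. In the pipeline's conjunction
#' analyses map A is the diagnosis-effect map and is the default
#' denominator; `"B"` and the symmetric `"mean"` (average of the two sizes)
#' are also available since "proportion of the suprathreshold voxels for
#' each map" admits either reading.
#'
#' @param a,b [threshold_statmap()] masks.
#' @param denominator `"A"`, `"B"` or `"mean"`.
#' @return percentage in `[0, 100]`, or `NA` (flagged via attribute
#'   `"undefined"`) when the denominator mask is empty.
#' @export
overlap_percent <- function(a, b, denominator = c("A", "B", "mean")) {
  denominator <- match.arg(denominator)
  conj <- conjunction_mask(a, b)
  den <- switch(denominator, A = a$n_voxels, B = b$n_voxels,
                mean = (a$n_voxels + b$n_voxels) / 2)
  if (den == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * conj$n_voxels / den
}

# counts of values strictly above each threshold; thresholds ascending
count_above <- function(x, thresholds_ascending) {
  idx <- findInterval(x, thresholds_ascending)
  tab <- tabulate(idx, nbins = length(thresholds_ascending))
  rev(cumsum(rev(tab)))
}

# per-ladder overlap of one ordered pair of z vectors (in-mask values);
# denominator is the first (diagnosis) member
pair_overlap_counts <- function(z_dx, z_other, ladder) {
  u <- qnorm(1 - ladder)              # descending in the ladder order
  ord <- order(u)                     # ascending thresholds for counting
  back <- order(ord)                  # map counts back to ladder order
  u_asc <- u[ord]
  n_dx <- count_above(z_dx, u_asc)[back]
  n_other <- count_above(z_other, u_asc)[back]
  n_int <- count_above(pmin(z_dx, z_other), u_asc)[back]
  list(n_dx = n_dx, n_other = n_other, n_int = n_int,
       pct = ifelse(n_dx > 0, 100 * n_int / n_dx, NA_real_),
       pct_other = ifelse(n_other > 0, 100 * n_int / n_other, NA_real_),
       pct_mean = ifelse(n_dx + n_other > 0,
                         100 * n_int / ((n_dx + n_other) / 2), NA_real_))
}

#' Directional conjunction overlap along the threshold ladder
#'
#' Evaluates, at every ladder threshold, the two direction-matched
#' conjunction pairs between a diagnosis-effect comparison and the control
#' sex-difference comparison, and averages the two overlap percentages:
#' \describe{
#'   \item{masculinized}{`(dx_pos AND sex_pos)` and `(dx_neg AND sex_neg)` —
#'     the diagnosis effect points the same way as typical sexual
#'     dimorphism (extreme-male-brain direction).}
#'   \item{feminized}{`(dx_pos AND sex_neg)` and `(dx_neg AND sex_pos)` —
#'     the diagnosis effect points against typical dimorphism
#'     (gender-incoherence direction).}
#' }
#' Each conjunction is converted to a percentage of the diagnosis map's
#' suprathreshold voxels (see [overlap_percent()]); maps are compared on the
#' Gaussian scale so that t maps with different degrees of freedom share
#' voxel-level probability semantics. Thresholds where a denominator is
#' empty are flagged and excluded from the average.
#'
#' @param dx_pos,dx_neg t maps of the diagnosis comparison (positive /
#'   negative direction; typically `t_contrast(fit, "group")` and its
#'   negation).
#' @param sex_pos,sex_neg t maps of the control sex-difference comparison.
#' @param mode `"masculinized"` or `"feminized"`.
#' @param ladder voxel-level probabilities, see [threshold_ladder()].
#' @return A data.frame of class `overlap_result`: per threshold the pair
#'   counts, per-pair percentages (of the diagnosis map, of the other map,
#'   and symmetric mean), the averaged `percent`, and `n_undefined`.
#' @export
directional_overlap <- function(dx_pos, dx_neg, sex_pos, sex_neg,
                                mode = c("masculinized", "feminized"),
                                ladder = threshold_ladder()) {
  mode <- match.arg(mode)
  maps <- list(dx_pos, dx_neg, sex_pos, sex_neg)
  stopifnot(all(vapply(maps, inherits, TRUE, "stat_map")))
  mvals <- dx_pos$mask$values
  for (m in maps)
    if (!identical(dim(m$t), dim(mvals)))
      stop("stat maps must share a common analysis mask", call. = FALSE)
  vox <- which(mvals)
  z <- lapply(maps, function(m) gaussianize_t(m)[vox])
  names(z) <- c("dx_pos", "dx_neg", "sex_pos", "sex_neg")
  pairs <- if (mode == "masculinized")
    list(c("dx_pos", "sex_pos"), c("dx_neg", "sex_neg"))
  else
    list(c("dx_pos", "sex_neg"), c("dx_neg", "sex_pos"))
  p1 <- pair_overlap_counts(z[[pairs[[1]][1]]], z[[pairs[[1]][2]]], ladder)
  p2 <- pair_overlap_counts(z[[pairs[[2]][1]]], z[[pairs[[2]][2]]], ladder)
  both <- cbind(p1$pct, p2$pct)
  percent <- rowMeans(both, na.rm = TRUE)
  percent[is.nan(percent)] <- NA_real_
  out <- data.frame(p = ladder,
                    n_dx1 = p1$n_dx, n_sex1 = p1$n_other, n_int1 = p1$n_int,
                    pct1 = p1$pct,
                    n_dx2 = p2$n_dx, n_sex2 = p2$n_other, n_int2 = p2$n_int,
                    pct2 = p2$pct,
                    percent = percent,
                    percent_of_other = rowMeans(cbind(p1$pct_other,
                                                      p2$pct_other),
                                                na.rm = TRUE),
                    percent_mean_denom = rowMeans(cbind(p1$pct_mean,
                                                        p2$pct_mean),
                                                  na.rm = TRUE),
                    n_undefined = is.na(p1$pct) + is.na(p2$pct))
  attr(out, "mode") <- mode
  attr(out, "pairs") <- pairs
  class(out) <- c("overlap_result", "data.frame")
  out
}

#' Monte Carlo null distribution of random overlap
#'
#' Per iteration, two pairs of independent Gaussian random fields are
#' generated (mirroring the two direction-pairs of the observed statistic):
#' the first member of each pair is smoothed to the smoothness of the
#' diagnosis map and the second to that of the sex-difference map. Fields
#' are generated as white noise convolved with the matching Gaussian kernel
#' under periodic boundary conditions (exactly stationary), standardized to
#' zero mean and unit variance within the analysis mask, thresholded at
#' `qnorm(1 - p_k)` for every ladder value, and the overlap percentage is
#' computed with the same denominator convention as the observed statistic
#' and averaged across the two pairs.
#'
#' @param smoothness_a smoothness of the diagnosis map: a
#'   [estimate_smoothness()] object or per-axis FWHM in voxels.
#' @param smoothness_b smoothness of the sex-difference map.
#' @param mask an [make_analysis_mask()] object or logical array.
#' @param ladder voxel-level probabilities.
#' @param n_iterations number of Monte Carlo iterations (>= 100).
#' @param seed optional integer seed.
#' @return An object of class `null_overlap`: per-threshold `mean`, `q005`
#'   and `q995` percentiles, the raw `samples` matrix (iterations x
#'   thresholds, NA where both pair denominators were empty), and metadata.
#' @export
simulate_null_overlap <- function(smoothness_a, smoothness_b, mask,
                                  ladder = threshold_ladder(),
                                  n_iterations = 5000L, seed = NULL) {
  if (n_iterations < 100L)
    stop("'n_iterations' must be >= 100", call. = FALSE)
  fw_a <- if (inherits(smoothness_a, "smoothness_estimate"))
    smoothness_a$fwhm else as.numeric(smoothness_a)
  fw_b <- if (inherits(smoothness_b, "smoothness_estimate"))
    smoothness_b$fwhm else as.numeric(smoothness_b)
  fw_a <- rep(ifelse(is.na(fw_a), 1, fw_a), length.out = 3)
  fw_b <- rep(ifelse(is.na(fw_b), 1, fw_b), length.out = 3)
  if (any(c(fw_a, fw_b) < 0.5))
    warning("field FWHM < 0.5 voxel: lattice discreteness breaks the ",
            "calibration of the Monte Carlo null")
  mvals <- if (inherits(mask, "analysis_mask")) mask$values else mask
  d <- dim(mvals)
  vox <- which(mvals)
  if (!is.null(seed)) set.seed(seed)
  ka <- lapply(fw_a, gaussian_kernel_1d)
  kb <- lapply(fw_b, gaussian_kernel_1d)
  u <- qnorm(1 - ladder)
  ord <- order(u); back <- order(ord); u_asc <- u[ord]
  raw <- null_overlap_block(as.integer(n_iterations), as.integer(d),
                            ka[[1]], ka[[2]], ka[[3]],
                            kb[[1]], kb[[2]], kb[[3]],
                            as.integer(vox), u_asc)
  samples <- raw[, back, drop = FALSE]
  structure(list(ladder = ladder, samples = samples,
                 mean = colMeans(samples, na.rm = TRUE),
                 q005 = apply(samples, 2L, stats::quantile, probs = 0.005,
                              na.rm = TRUE, names = FALSE),
                 q995 = apply(samples, 2L, stats::quantile, probs = 0.995,
                              na.rm = TRUE, names = FALSE),
                 n_iterations = as.integer(n_iterations),
                 fwhm_a = fw_a, fwhm_b = fw_b, seed = seed),
            class = "null_overlap")
}

#' @export
print.null_overlap <- function(x, ...) {
  cat(sprintf("<null_overlap> %d iterations over %d thresholds; mean overlap %.2f%% at p = %g\n",
              x$n_iterations, length(x$ladder),
              x$mean[which.min(abs(x$ladder - 0.025))], 0.025))
  invisible(x)
}

#' Empirical p-value of an observed overlap against the Monte Carlo null
#'
#' `p = #(null >= observed) / n_iterations` at each requested threshold. A
#' low p (e.g. < 0.001) means the observed overlap does not occur by
#' chance; a high p (e.g. > 0.999) flags a significant non-overlap (or
#' non-random maps). An observed overlap above every null sample gives
#' p = 0, to be reported as "< 1/n_iterations".
#'
#' @param observed observed averaged overlap percentage(s), one per
#'   requested threshold.
#' @param null a [simulate_null_overlap()] object.
#' @param threshold_index ladder indices the observations refer to
#'   (default: the whole ladder).
#' @return numeric vector of empirical p-values (`NA` where the observed
#'   value is undefined).
#' @export
empirical_overlap_p <- function(observed, null,
                                threshold_index = seq_along(null$ladder)) {
  stopifnot(inherits(null, "null_overlap"),
            length(observed) == length(threshold_index))
  vapply(seq_along(observed), function(j) {
    if (is.na(observed[j])) return(NA_real_)
    s <- null$samples[, threshold_index[j]]
    s <- s[!is.na(s)]
    if (length(s) == 0L) return(NA_real_)
    sum(s >= observed[j]) / null$n_iterations
  }, 0)
}

#' Assemble an overlap curve
#'
#' Joins the observed directional overlap, the Monte Carlo null band and the
#' per-threshold empirical p into one table. Empirical p-values of zero are
#' floored at `1 / (n_iterations + 1)` (the resolution of the simulation);
#' per the null's interpretation, `non_random` flags p < 0.001 and
#' `non_overlap` flags p > 0.999.
#'
#' @param observed a [directional_overlap()] result.
#' @param null a [simulate_null_overlap()] result on the same ladder.
#' @return A data.frame of class `overlap_curve` with columns `p`,
#'   `observed`, `null_mean`, `null_p005`, `null_p995`, `empirical_p`,
#'   `non_random`, `non_overlap`, `n_undefined`.
#' @export
overlap_curve <- function(observed, null) {
  stopifnot(inherits(observed, "overlap_result"),
            inherits(null, "null_overlap"),
            isTRUE(all.equal(observed$p, null$ladder)))
  raw <- empirical_overlap_p(observed$percent, null)
  p <- pmax(raw, 1 / (null$n_iterations + 1))
  p[is.na(raw)] <- NA_real_
  out <- data.frame(p = observed$p, observed = observed$percent,
                    null_mean = null$mean, null_p005 = null$q005,
                    null_p995 = null$q995, empirical_p = p,
                    non_random = !is.na(p) & p < 0.001,
                    non_overlap = !is.na(p) & p > 0.999,
                    n_undefined = observed$n_undefined)
  attr(out, "mode") <- attr(observed, "mode")
  attr(out, "n_iterations") <- null$n_iterations
  class(out) <- c("overlap_curve", "data.frame")
  out
}
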