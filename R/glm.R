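#' Build a voxel-wise GLM design from a cohort table
#'
#' Constructs the subjects x predictors design matrix used by
#' [fit_mass_univariate()]. Factors are sum-to-zero coded (sex: M = +1,
#' F = -1; diagnosis: autism = +1, control = -1; centre: `contr.sum`
#' dummies), age is mean-centred, and the sex x diagnosis interaction is the
#' product column. Factors with a single observed level are dropped from the
#' design (with a message), so the same constructor serves the 2 x 2
#' factorial model and the planned two-group comparisons.
#'
#' @param cohort data.frame with columns `sex`, `diagnosis`, `age`, `centre`.
#' @param include_interaction add the sex x diagnosis product column (only
#'   when both factors vary).
#' @param include_age add mean-centred age as a nuisance covariate.
#' @param include_centre add sum-coded centre dummies (multicentre designs).
#' @return An object of class `glm_design`: list with `X` (design matrix),
#'   `labels`, `contrasts` (named unit contrast vectors), `error_df`.
#' @export
build_design <- function(cohort, include_interaction = TRUE,
                         include_age = TRUE, include_centre = FALSE) {
  n <- nrow(cohort)
  X <- matrix(1, n, 1)
  labels <- "intercept"
  sex_col <- dx_col <- NULL
  if (length(unique(cohort$sex)) > 1L) {
    sex_col <- ifelse(cohort$sex == "M", 1, -1)
    X <- cbind(X, sex_col); labels <- c(labels, "sex")
  }
  if (length(unique(cohort$diagnosis)) > 1L) {
    dx_col <- ifelse(cohort$diagnosis == "autism", 1, -1)
    X <- cbind(X, dx_col); labels <- c(labels, "diagnosis")
  }
  if (is.null(sex_col) && is.null(dx_col))
    stop("design error: neither sex nor diagnosis varies in the cohort",
         call. = FALSE)
  if (include_interaction && !is.null(sex_col) && !is.null(dx_col)) {
    X <- cbind(X, sex_col * dx_col); labels <- c(labels, "sex:diagnosis")
  }
  if (include_age) {
    X <- cbind(X, cohort$age - mean(cohort$age)); labels <- c(labels, "age")
  }
  if (include_centre) {
    centres <- factor(cohort$centre)
    if (nlevels(centres) > 1L) {
      C <- contr.sum(nlevels(centres))[as.integer(centres), , drop = FALSE]
      X <- cbind(X, C)
      labels <- c(labels, paste0("centre", seq_len(ncol(C))))
    } else {
      message("single centre: centre dummies dropped from the design")
    }
  }
  colnames(X) <- labels
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- labels[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design error: rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  error_df <- n - qrX$rank
  if (error_df < 1L) stop("design error: no error degrees of freedom",
                          call. = FALSE)
  contrasts <- lapply(seq_along(labels), function(j) {
    v <- numeric(length(labels)); v[j] <- 1; v
  })
  names(contrasts) <- labels
  if (xor(is.null(sex_col), is.null(dx_col)))
    contrasts$group <- contrasts[[if (is.null(sex_col)) "diagnosis" else
      "sex"]]
  if ("sex:diagnosis" %in% labels)
    contrasts$interaction <- contrasts[["sex:diagnosis"]]
  structure(list(X = X, labels = labels, contrasts = contrasts,
                 error_df = error_df, qr = qrX),
            class = "glm_design")
}

#' Fit the mass-univariate GLM
#'
#' Ordinary least squares at every in-mask voxel with a common design.
#' Residual variance uses the design's error degrees of freedom. Voxels
#' whose residual variance is (numerically) zero are flagged and excluded
#' from inference; their count is recorded.
#'
#' @param stack a [map_stack] (typically rescaled) aligned with the design's
#'   cohort rows.
#' @param design a [build_design()] object.
#' @param mask an [make_analysis_mask()] object on the same lattice.
#' @return An object of class `vbm_fit` with per-voxel betas, residual
#'   variance, residuals (for smoothness estimation), `(X'X)^-1`, error df
#'   and bookkeeping.
#' @export
fit_mass_univariate <- function(stack, design, mask) {
  stopifnot(inherits(stack, "map_stack"), inherits(design, "glm_design"),
            inherits(mask, "analysis_mask"))
  if (!identical(as.integer(dim(mask$values)), stack$dims))
    stop("mask geometry does not match the map stack", call. = FALSE)
  if (nrow(design$X) != ncol(stack$data))
    stop("design rows do not match the number of subjects", call. = FALSE)
  vox <- which(mask$values)
  Y <- t(stack$data[vox, , drop = FALSE])        # subjects x voxels
  qrX <- design$qr
  betas <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  rss <- colSums(res^2)
  df <- design$error_df
  sigma2 <- rss / df
  scale_ref <- mean(colSums(Y^2))
  flagged <- sigma2 <= scale_ref * 1e-24
  XtXinv <- solve(crossprod(design$X))
  structure(list(betas = betas, sigma2 = sigma2, residuals = res,
                 XtXinv = XtXinv, df = df, voxels = vox,
                 flagged = flagged, n_flagged = sum(flagged),
                 design = design, dims = stack$dims,
                 voxel_size = stack$voxel_size, mask = mask,
                 tissue = stack$tissue),
            class = "vbm_fit")
}

#' @export
print.vbm_fit <- function(x, ...) {
  cat(sprintf("<vbm_fit> %d voxels, %d predictors, error df = %d (%d flagged)\n",
              length(x$voxels), ncol(x$design$X), x$df, x$n_flagged))
  invisible(x)
}

#' Compute a t-contrast statistical map
#'
#' `t = c'beta / sqrt(sigma^2 c'(X'X)^-1 c)` at every unflagged in-mask
#' voxel; negating the contrast negates the map. Contrasts can be given by
#' name (as labelled in the design) or as a numeric vector.
#'
#' @param fit a [fit_mass_univariate()] object.
#' @param contrast contrast vector of length = number of predictors, or a
#'   name in `fit$design$contrasts`.
#' @param label optional label stored on the map.
#' @return An object of class `stat_map`: `t` (3D array, `NA` outside the
#'   mask and at flagged voxels), `df`, `label`, `mask`, `voxel_size`, and a
#'   `smoothness` slot filled by [estimate_smoothness()].
#' @export
t_contrast <- function(fit, contrast, label = NULL) {
  stopifnot(inherits(fit, "vbm_fit"))
  if (is.character(contrast)) {
    if (is.null(label)) label <- contrast
    contrast <- fit$design$contrasts[[contrast]]
    if (is.null(contrast)) stop("unknown contrast name", call. = FALSE)
  }
  if (length(contrast) != ncol(fit$design$X))
    stop("contrast length does not match the number of predictors",
         call. = FALSE)
  cvar <- drop(t(contrast) %*% fit$XtXinv %*% contrast)
  if (cvar <= 0) stop("non-estimable contrast", call. = FALSE)
  tval <- drop(contrast %*% fit$betas) / sqrt(fit$sigma2 * cvar)
  tval[fit$flagged] <- NA_real_
  arr <- array(NA_real_, dim = fit$dims)
  arr[fit$voxels] <- tval
  structure(list(t = arr, df = fit$df,
                 label = if (is.null(label)) "contrast" else label,
                 mask = fit$mask, voxel_size = fit$voxel_size,
                 smoothness = estimate_smoothness(fit)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> '%s', df = %d, t in [%.2f, %.2f], FWHM = %s voxels\n",
              x$label, x$df, min(x$t, na.rm = TRUE), max(x$t, na.rm = TRUE),
              paste(sprintf("%.2f", x$smoothness$fwhm), collapse = "/")))
  invisible(x)
}

# adjacent in-mask voxel pairs along each axis; list of 2-column index
# matrices into `vox` (linear order of in-mask voxels)
mask_axis_pairs <- function(mask_values) {
  d <- dim(mask_values)
  vox <- which(mask_values)
  pos <- integer(prod(d))
  pos[vox] <- seq_along(vox)
  co <- arrayInd(vox, d)
  strides <- c(1L, d[1], d[1] * d[2])
  lapply(1:3, function(a) {
    ok <- co[, a] < d[a]
    nb <- vox[ok] + strides[a]
    sel <- pos[nb] > 0L
    cbind(pos[vox[ok]][sel], pos[nb][sel])
  })
}

smoothness_from_images <- function(V, mask_values, n_images_effective) {
  # V: images x in-mask voxels, standardized to unit mean square per voxel
  pairs <- mask_axis_pairs(mask_values)
  lam <- fwhm <- rep(NA_real_, 3L)
  for (a in 1:3) {
    pr <- pairs[[a]]
    if (nrow(pr) == 0L) {
      warning("mask too thin along axis ", a,
              "; axis dropped from smoothness estimate")
      next
    }
    dsq <- (V[, pr[, 2], drop = FALSE] - V[, pr[, 1], drop = FALSE])^2
    lam[a] <- mean(dsq, na.rm = TRUE)
    fwhm[a] <- sqrt(4 * log(2) / lam[a])
  }
  fw <- ifelse(is.na(fwhm), 1, fwhm)  # dropped axes contribute unit width
  structure(list(fwhm = fwhm, lambda = lam,
                 resel_count = sum(mask_values) / prod(fw),
                 n_voxels = sum(mask_values),
                 n_images = n_images_effective),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness_estimate> FWHM = %s voxels, %.1f resels over %d voxels\n",
              paste(sprintf("%.2f", x$fwhm), collapse = "/"),
              x$resel_count, x$n_voxels))
  invisible(x)
}

#' Estimate the spatial smoothness of a fitted model's residual fields
#'
#' Residual images are standardized voxel-wise to unit mean square (which
#' absorbs the loss of error degrees of freedom), then the per-axis
#' derivative variance `lambda_d` is estimated as the mean squared forward
#' difference between adjacent in-mask voxels, averaged over residual
#' images. `fwhm_d = sqrt(4 ln 2 / lambda_d)` in voxel units, and the search
#' region's resel count is `in-mask voxels / prod(fwhm)` (stationary
#' assumption). Axes along which the mask admits no adjacent pairs are
#' dropped with a warning.
#'
#' @param fit a [fit_mass_univariate()] object (>= 2 residual images).
#' @return An object of class `smoothness_estimate` with `fwhm` (per-axis
#'   voxels), `resel_count` and bookkeeping.
#' @export
estimate_smoothness <- function(fit) {
  stopifnot(inherits(fit, "vbm_fit"))
  n <- nrow(fit$residuals)
  if (n < 2L) stop("need at least 2 residual images", call. = FALSE)
  msq <- colMeans(fit$residuals^2)
  V <- sweep(fit$residuals, 2L, sqrt(msq), "/")
  V[, fit$flagged] <- NA_real_
  m <- array(FALSE, dim = fit$dims)
  m[fit$voxels] <- TRUE
  smoothness_from_images(V, m, n_images_effective = fit$df)
}

#' Estimate smoothness of a set of mean-zero fields
#'
#' Direct analogue of [estimate_smoothness()] for raw simulated fields
#' rather than model residuals (used as the estimator oracle and by the
#' Monte Carlo calibration checks).
#'
#' @param data voxels x images matrix.
#' @param dims lattice dimensions.
#' @param mask optional logical array; defaults to all voxels.
#' @return A `smoothness_estimate`.
#' @export
estimate_field_smoothness <- function(data, dims, mask = NULL) {
  stopifnot(is.matrix(data), nrow(data) == prod(dims))
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  m <- if (inherits(mask, "analysis_mask")) mask$values else mask
  V <- t(data[which(m), , drop = FALSE])
  msq <- colMeans(V^2)
  V <- sweep(V, 2L, sqrt(msq), "/")
  smoothness_from_images(V, m, n_images_effective = ncol(data))
}

# local resels-per-voxel lattice from standardized residuals (used by the
# non-stationary cluster-extent option)
resels_per_voxel <- function(fit) {
  msq <- colMeans(fit$residuals^2)
  V <- sweep(fit$residuals, 2L, sqrt(msq), "/")
  m <- array(FALSE, dim = fit$dims)
  m[fit$voxels] <- TRUE
  pairs <- mask_axis_pairs(m)
  nmask <- length(fit$voxels)
  lam_loc <- matrix(NA_real_, nmask, 3L)
  for (a in 1:3) {
    pr <- pairs[[a]]
    if (nrow(pr) == 0L) next
    dsq <- colMeans((V[, pr[, 2], drop = FALSE] -
                       V[, pr[, 1], drop = FALSE])^2)
    acc <- cnt <- numeric(nmask)
    for (side in 1:2) {
      idx <- pr[, side]
      acc <- acc + unname(tapply(dsq, factor(idx, levels = seq_len(nmask)),
                                 sum, default = 0))
      cnt <- cnt + tabulate(idx, nbins = nmask)
    }
    lam_loc[, a] <- ifelse(cnt > 0, acc / cnt, NA_real_)
  }
  glob <- colMeans(lam_loc, na.rm = TRUE)
  for (a in 1:3) lam_loc[is.na(lam_loc[, a]), a] <-
    if (is.finite(glob[a])) glob[a] else 4 * log(2)
  # resel density = prod_a sqrt(lambda_a / (4 ln 2)) = 1 / prod_a fwhm_a
  rpv <- apply(sqrt(pmax(lam_loc, 0) / (4 * log(2))), 1L, prod)
  arr <- array(NA_real_, dim = fit$dims)
  arr[fit$voxels] <- rpv
  arr
}
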