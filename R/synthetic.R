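#' Define a spherical effect region
#'
#' @param centre voxel coordinates of the sphere centre (0-based lattice
#'   indices, length 3).
#' @param radius_mm sphere radius in mm (> 0).
#' @param amplitude signed effect amplitude in map volume units (for
#'   `age_slope` fields: volume units per year of age).
#' @return A list describing the region.
#' @export
effect_region <- function(centre, radius_mm, amplitude) {
  stopifnot(length(centre) == 3L, radius_mm > 0, is.finite(amplitude))
  list(centre = as.numeric(centre), radius_mm = as.numeric(radius_mm),
       amplitude = as.numeric(amplitude))
}

#' Define a ground-truth effect field
#'
#' An effect field plants a known group-difference pattern into the
#' synthetic cohort. The `factor` decides which subjects receive it:
#' \describe{
#'   \item{sex}{added to all male subjects (MC and MA).}
#'   \item{diagnosis_in_males}{added to males with autism (MA).}
#'   \item{diagnosis_in_females}{added to females with autism (FA).}
#'   \item{interaction}{added with sign +1 to MA and -1 to FA, i.e. a pure
#'     sex-by-diagnosis crossover with no average diagnosis main effect.}
#'   \item{age_slope}{added to every subject scaled by (age - midpoint of
#'     the age range); amplitude is per year.}
#' }
#'
#' @param factor one of `"sex"`, `"diagnosis_in_males"`,
#'   `"diagnosis_in_females"`, `"interaction"`, `"age_slope"`.
#' @param regions a single [effect_region] or a list of them.
#' @param tissue tissue class the field applies to.
#' @return A list of class `effect_field`.
#' @export
effect_field <- function(factor, regions, tissue = "GM") {
  factor <- match.arg(factor, c("sex", "diagnosis_in_males",
                                "diagnosis_in_females", "interaction",
                                "age_slope"))
  if (!is.null(regions$centre)) regions <- list(regions)
  stopifnot(length(regions) >= 1L)
  structure(list(factor = factor, regions = regions, tissue = tissue),
            class = "effect_field")
}

#' Scenario configuration for the synthetic cohort generator
#'
#' Describes a four-group (male/female x autism/control) VBM study whose
#' modulated tissue maps are generated with known ground truth. Defaults
#' emulate the preprocessed inputs of the study design the pipeline targets:
#' a 40 x 48 x 40 lattice of 4 mm isotropic voxels, n = 30 per group,
#' DARTEL-modulated maps smoothed to an effective field smoothness of 8 mm
#' (2 voxels) FWHM, and group mean total volumes calibrated to published
#' participant characteristics (grey matter 914/940/824/845 cm^3 for
#' MC/MA/FC/FA; white matter 510/513/448/465 cm^3).
#'
#' @param grid_dims voxels per axis (all >= 8).
#' @param voxel_size voxel edge in mm.
#' @param n_per_group subjects per group (>= 2).
#' @param tissues tissue classes to generate, subset of `c("GM", "WM")`.
#' @param subject_noise_sd marginal (post-smoothing) standard deviation of
#'   the subject-level voxel noise, in map volume units.
#' @param noise_fwhm_mm spatial smoothness (FWHM) of the subject noise, mm.
#' @param effect_fields list of [effect_field]s; at most one per
#'   (factor, tissue) pair.
#' @param smooth_effects logical; smooth planted spheres with the noise
#'   kernel (default) so effects are spatially smooth like real VBM effects.
#' @param baseline_total_cm3 named per-tissue target integral of the
#'   baseline template, cm^3.
#' @param support_frac ellipsoid semi-axes of the baseline support as a
#'   fraction of the grid dimensions.
#' @param baseline_value_scale multiplies the flat baseline amplitude
#'   implied by `baseline_total_cm3` (kept at 1 in practice).
#' @param group_scale named list per tissue of multiplicative global scale
#'   factors for the four groups, emulating global volume differences
#'   (females smaller); removed exactly by tissue-specific rescaling.
#' @param subject_scale_cv coefficient of variation of the per-subject
#'   global scale jitter (drives the between-subject SD of total volumes).
#' @param age_range uniform age range in years.
#' @param centres character vector of centre labels; subjects are assigned
#'   round-robin within group.
#' @param csf_cells named list `mean`/`sd` of per-group CSF totals (cm^3),
#'   simulated at the table level only (no CSF maps are generated).
#' @param digit_ratio per-hand, per-group means and SDs of the 2D:4D digit
#'   ratio plus the coupling slope passed to [generate_digit_ratios()].
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(grid_dims = c(40L, 48L, 40L),
                            voxel_size = 4,
                            n_per_group = 30L,
                            tissues = "GM",
                            subject_noise_sd = 0.1,
                            noise_fwhm_mm = 8,
                            effect_fields = list(),
                            smooth_effects = TRUE,
                            baseline_total_cm3 = c(GM = 914, WM = 510),
                            support_frac = 0.4,
                            baseline_value_scale = 1,
                            group_scale = list(
                              GM = c(MC = 1, MA = 940 / 914,
                                     FC = 824 / 914, FA = 845 / 914),
                              WM = c(MC = 1, MA = 513 / 510,
                                     FC = 448 / 510, FA = 465 / 510)),
                            subject_scale_cv = 0.085,
                            age_range = c(18, 49),
                            centres = "CAM",
                            csf_cells = list(
                              mean = c(MC = 270, MA = 264, FC = 236, FA = 227),
                              sd = c(MC = 59, MA = 63, FC = 53, FA = 45)),
                            digit_ratio = list(
                              left = list(mean = c(MC = 0.947, MA = 0.947,
                                                   FC = 0.975, FA = 0.967),
                                          sd = c(MC = 0.030, MA = 0.030,
                                                 FC = 0.0287, FA = 0.0322)),
                              right = list(mean = c(MC = 0.950, MA = 0.950,
                                                    FC = 0.972, FA = 0.971),
                                           sd = c(MC = 0.030, MA = 0.030,
                                                  FC = 0.0293, FA = 0.0256)),
                              coupling = c(MC = 0, MA = 0, FC = 0, FA = 0)),
                            seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 8L))
    stop("'grid_dims' must be three integers, all >= 8", call. = FALSE)
  if (n_per_group < 2L)
    stop("'n_per_group' must be >= 2", call. = FALSE)
  if (noise_fwhm_mm < 0) stop("'noise_fwhm_mm' must be >= 0", call. = FALSE)
  stopifnot(all(tissues %in% c("GM", "WM")), subject_noise_sd >= 0,
            support_frac > 0, support_frac <= 0.5, length(age_range) == 2L)
  if (length(effect_fields) > 0L) {
    if (inherits(effect_fields, "effect_field"))
      effect_fields <- list(effect_fields)
    stopifnot(all(vapply(effect_fields, inherits, TRUE, "effect_field")))
    key <- vapply(effect_fields,
                  function(f) paste(f$factor, f$tissue), "")
    if (anyDuplicated(key))
      stop("configuration error: factor '", key[duplicated(key)][1],
           "' is assigned by more than one effect field", call. = FALSE)
    for (f in effect_fields)
      for (r in f$regions)
        if (any(r$centre < 0) || any(r$centre > grid_dims - 1L))
          stop("effect region centre lies outside the grid", call. = FALSE)
  }
  structure(list(grid_dims = grid_dims, voxel_size = voxel_size,
                 n_per_group = as.integer(n_per_group), tissues = tissues,
                 subject_noise_sd = subject_noise_sd,
                 noise_fwhm_mm = noise_fwhm_mm,
                 effect_fields = effect_fields,
                 smooth_effects = isTRUE(smooth_effects),
                 baseline_total_cm3 = baseline_total_cm3,
                 support_frac = support_frac,
                 baseline_value_scale = baseline_value_scale,
                 group_scale = group_scale,
                 subject_scale_cv = subject_scale_cv,
                 age_range = as.numeric(age_range), centres = centres,
                 csf_cells = csf_cells, digit_ratio = digit_ratio,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Read a scenario configuration from a YAML file
#'
#' Fields follow the arguments of [scenario_config()]; effect fields are
#' given as a list with `factor`, `tissue` and `regions` (each region
#' `centre`, `radius_mm`, `amplitude`).
#'
#' @param path path to a YAML file.
#' @return A [scenario_config()].
#' @export
scenario_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read scenario files",
         call. = FALSE)
  spec <- yaml::read_yaml(path)
  if (!is.null(spec$effect_fields))
    spec$effect_fields <- lapply(spec$effect_fields, function(f) {
      effect_field(f$factor,
                   lapply(f$regions, function(r)
                     effect_region(r$centre, r$radius_mm, r$amplitude)),
                   tissue = if (is.null(f$tissue)) "GM" else f$tissue)
    })
  do.call(scenario_config, spec)
}

# sphere of TRUE voxels around a 0-based centre, radius in mm
sphere_mask <- function(dims, voxel_size, centre, radius_mm) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 1) - centre[a]) *
                 voxel_size[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  array(d2 <= radius_mm^2, dim = dims)
}

# ellipsoidal baseline support
baseline_support <- function(config) {
  d <- config$grid_dims
  semi <- config$support_frac * d
  centre <- (d - 1) / 2
  ax <- lapply(1:3, function(a)
    (((seq_len(d[a]) - 1) - centre[a]) / semi[a])^2)
  array(outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+") <= 1, dim = d)
}

# flat baseline template whose integral is the target total
baseline_template <- function(config, tissue) {
  supp <- baseline_support(config)
  vox_cm3 <- prod(rep(config$voxel_size, length.out = 3)) / 1000
  target <- config$baseline_total_cm3[[tissue]]
  amp <- config$baseline_value_scale * target / (sum(supp) * vox_cm3)
  list(values = supp * amp, support = supp)
}

#' Ground-truth region masks of a scenario
#'
#' Boolean masks of every planted effect field, reconstructed from the
#' configuration alone (no randomness involved). Masks are the exact
#' unsmoothed spheres, keyed `"<factor>.<tissue>"`; the baseline support is
#' included as `"support.<tissue>"`.
#'
#' @param config a [scenario_config()].
#' @return Named list of logical arrays.
#' @export
ground_truth_masks <- function(config) {
  d <- config$grid_dims
  out <- list()
  for (tissue in config$tissues)
    out[[paste0("support.", tissue)]] <- baseline_support(config)
  for (f in config$effect_fields) {
    m <- array(FALSE, dim = d)
    for (r in f$regions)
      m <- m | sphere_mask(d, config$voxel_size, r$centre, r$radius_mm)
    out[[paste0(f$factor, ".", f$tissue)]] <- m
  }
  out
}

# variance shrinkage of unit-variance white noise under the separable kernel
kernel_variance_factor <- function(fwhm_vox) {
  prod(vapply(fwhm_vox, function(f) sum(gaussian_kernel_1d(f)^2), 0))
}

# stationary smooth noise: white noise on a grid padded by ~3 FWHM per side,
# smoothed, cropped, so edge voxels keep the same marginal smoothness
smooth_noise_field <- function(dims, fwhm_vox, marginal_sd) {
  if (marginal_sd == 0) return(array(0, dim = dims))
  if (all(fwhm_vox <= 0))
    return(array(rnorm(prod(dims), sd = marginal_sd), dim = dims))
  pad <- as.integer(ceiling(3 * fwhm_vox))
  dp <- dims + 2L * pad
  white_sd <- marginal_sd / sqrt(kernel_variance_factor(fwhm_vox))
  x <- array(rnorm(prod(dp), sd = white_sd), dim = dp)
  x <- smooth_field(x, fwhm_vox)
  x[pad[1] + seq_len(dims[1]), pad[2] + seq_len(dims[2]),
    pad[3] + seq_len(dims[3]), drop = FALSE]
}

#' Generate a synthetic four-group VBM cohort
#'
#' Each subject's modulated map is `baseline + applicable effect fields +
#' smoothed Gaussian noise`, multiplied by the group's global scale and a
#' per-subject scale jitter, and clipped at zero (clip events are counted).
#' Noise is white Gaussian smoothed to `noise_fwhm_mm` on a padded grid and
#' restricted to the baseline support, so in-brain voxels have stationary
#' smoothness and marginal SD `subject_noise_sd`. The covariate table is
#' derived from the generated maps (integrated totals) plus simulated ages,
#' CSF totals and digit ratios. Fully reproducible from `config$seed`.
#'
#' @param config a [scenario_config()].
#' @return A list of class `vbm_cohort` with elements `cohort` (data.frame:
#'   id, sex, diagnosis, group, age, centre, totals, digit ratios), `maps`
#'   (named list of [map_stack] per tissue), `ground_truth` (see
#'   [ground_truth_masks()]), `n_clipped` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_per_group
  groups <- c("MC", "MA", "FC", "FA")
  group <- factor(rep(groups, each = n), levels = groups)
  sex <- factor(ifelse(group %in% c("MC", "MA"), "M", "F"),
                levels = c("M", "F"))
  diagnosis <- factor(ifelse(group %in% c("MA", "FA"), "autism", "control"),
                      levels = c("control", "autism"))
  ntot <- 4L * n
  cohort <- data.frame(
    id = sprintf("S%03d", seq_len(ntot)),
    sex = sex, diagnosis = diagnosis, group = group,
    age = runif(ntot, config$age_range[1], config$age_range[2]),
    centre = factor(rep(rep_len(config$centres, n), 4L)),
    stringsAsFactors = FALSE)

  age_mid <- mean(config$age_range)
  get_scale <- function(tissue) {
    scl <- config$group_scale[[tissue]]
    if (is.null(scl)) c(MC = 1, MA = 1, FC = 1, FA = 1) else scl
  }
  fwhm_vox <- config$noise_fwhm_mm / rep(config$voxel_size, length.out = 3)
  gt <- ground_truth_masks(config)
  subj_scale <- 1 + config$subject_scale_cv * rnorm(ntot)

  maps <- list()
  n_clipped <- 0L
  d <- config$grid_dims
  for (tissue in config$tissues) {
    base <- baseline_template(config, tissue)
    supp <- base$support
    fields <- Filter(function(f) f$tissue == tissue, config$effect_fields)
    eff <- lapply(fields, function(f) {
      e <- array(0, dim = d)
      for (r in f$regions)
        e <- e + r$amplitude *
          sphere_mask(d, config$voxel_size, r$centre, r$radius_mm)
      if (config$smooth_effects) e <- smooth_field(e, fwhm_vox)
      e
    })
    names(eff) <- vapply(fields, `[[`, "", "factor")
    scl <- get_scale(tissue)
    data <- matrix(0, nrow = prod(d), ncol = ntot)
    for (i in seq_len(ntot)) {
      g <- as.character(group[i])
      m <- base$values
      if (!is.null(eff$sex) && sex[i] == "M") m <- m + eff$sex
      if (!is.null(eff$diagnosis_in_males) && g == "MA")
        m <- m + eff$diagnosis_in_males
      if (!is.null(eff$diagnosis_in_females) && g == "FA")
        m <- m + eff$diagnosis_in_females
      if (!is.null(eff$interaction)) {
        if (g == "MA") m <- m + eff$interaction
        if (g == "FA") m <- m - eff$interaction
      }
      if (!is.null(eff$age_slope))
        m <- m + (cohort$age[i] - age_mid) * eff$age_slope
      noise <- smooth_noise_field(d, fwhm_vox, config$subject_noise_sd)
      m <- (m + noise * supp) * scl[[g]] * subj_scale[i]
      neg <- m < 0
      if (any(neg)) {
        n_clipped <- n_clipped + sum(neg)
        m[neg] <- 0
      }
      data[, i] <- m
    }
    maps[[tissue]] <- map_stack(data, d, voxel_size = config$voxel_size,
                                tissue = tissue, subject_ids = cohort$id)
  }

  for (tissue in config$tissues)
    cohort[[paste0("total_", tissue)]] <- stack_totals(maps[[tissue]])
  for (tissue in setdiff(c("GM", "WM"), config$tissues))
    cohort[[paste0("total_", tissue)]] <-
      config$baseline_total_cm3[[tissue]] *
      unname(get_scale(tissue)[as.character(group)]) * subj_scale
  cohort$total_CSF <- pmax(0, config$csf_cells$mean[as.character(group)] +
                             config$csf_cells$sd[as.character(group)] *
                             rnorm(ntot))

  dr <- config$digit_ratio
  region_volumes <- NULL
  if (!is.null(dr$region) && any(dr$coupling != 0)) {
    rt <- if (is.null(dr$region_tissue)) config$tissues[1] else
      dr$region_tissue
    rmask <- gt[[paste0(dr$region, ".", rt)]]
    if (is.null(rmask))
      stop("configuration error: digit-ratio region '", dr$region,
           "' has no ground-truth mask", call. = FALSE)
    rel <- sweep(maps[[rt]]$data, 2L, stack_totals(maps[[rt]]), "/")
    region_volumes <- colMeans(rel[as.logical(rmask), , drop = FALSE])
  }
  cohort <- generate_digit_ratios(cohort, region_volumes = region_volumes,
                                  coupling = dr$coupling,
                                  group_means = dr$left$mean,
                                  noise_sd = dr$left$sd, hand = "left")
  cohort <- generate_digit_ratios(cohort, region_volumes = NULL,
                                  coupling = 0,
                                  group_means = dr$right$mean,
                                  noise_sd = dr$right$sd, hand = "right")

  structure(list(cohort = cohort, maps = maps, ground_truth = gt,
                 n_clipped = n_clipped, config = config),
            class = "vbm_cohort")
}

#' @export
print.vbm_cohort <- function(x, ...) {
  cat(sprintf("<vbm_cohort> %d subjects (%s), tissues: %s, %d clipped voxels\n",
              nrow(x$cohort),
              paste(table(x$cohort$group), collapse = "/"),
              paste(names(x$maps), collapse = ", "), x$n_clipped))
  invisible(x)
}

#' Write a generated cohort to disk
#'
#' One NIfTI-1 volume per subject per tissue (4 mm isotropic by default),
#' the covariate table as TSV with header, and the ground-truth masks as
#' uint8 NIfTI volumes.
#'
#' @param cohort_obj a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort_obj, dir) {
  stopifnot(inherits(cohort_obj, "vbm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (tissue in names(cohort_obj$maps)) {
    stack <- cohort_obj$maps[[tissue]]
    for (i in seq_along(stack$subject_ids)) {
      p <- file.path(dir, sprintf("%s_%s.nii.gz", stack$subject_ids[i],
                                  tissue))
      write_volume(get_subject_volume(stack, i), p)
      paths <- c(paths, p)
    }
  }
  for (nm in names(cohort_obj$ground_truth)) {
    p <- file.path(dir, sprintf("groundtruth_%s.nii.gz", nm))
    gt <- volume_map(cohort_obj$ground_truth[[nm]] * 1,
                     voxel_size = cohort_obj$config$voxel_size,
                     kind = "mask")
    write_volume(gt, p)
    paths <- c(paths, p)
  }
  tsv <- file.path(dir, "cohort.tsv")
  write.table(cohort_obj$cohort, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, tsv))
}

#' Fill 2D:4D digit ratios into a cohort table
#'
#' Each subject's ratio is the group mean plus `coupling` times the
#' within-group standardized region volume plus Gaussian noise. A coupling
#' slope of 0 gives zero correlation between ratio and volume in
#' expectation; with positive coupling and zero noise the within-group
#' correlation is exactly 1. Generated ratios are truncated to the
#' physiologically plausible interval (0.7, 1.2).
#'
#' @param cohort data.frame with columns `id` and `group`.
#' @param region_volumes per-subject scalar volumes aligned with the cohort
#'   rows (e.g. mean relative volume of an overlap region); `NULL` disables
#'   the coupling term.
#' @param coupling slope in ratio units per SD of region volume; scalar or
#'   named per group.
#' @param group_means named per-group mean ratios.
#' @param noise_sd residual SD; scalar or named per group.
#' @param hand which hand's column (`ratio_2d4d_left`/`_right`) to fill.
#' @param seed optional seed (set it when calling outside
#'   [generate_cohort()], which manages the RNG stream itself).
#' @return The cohort table with the ratio column filled.
#' @export
generate_digit_ratios <- function(cohort, region_volumes = NULL,
                                  coupling = 0,
                                  group_means = c(MC = 0.947, MA = 0.947,
                                                  FC = 0.975, FA = 0.967),
                                  noise_sd = 0.03,
                                  hand = c("left", "right"),
                                  seed = NULL) {
  hand <- match.arg(hand)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(region_volumes) && length(region_volumes) != nrow(cohort))
    stop("alignment error: 'region_volumes' does not match the cohort rows",
         call. = FALSE)
  g <- as.character(cohort$group)
  pick <- function(x) if (length(x) == 1L) rep(x, nrow(cohort)) else
    unname(x[g])
  mu <- pick(group_means)
  sdv <- pick(noise_sd)
  slope <- pick(coupling)
  ratio <- mu + sdv * rnorm(nrow(cohort))
  if (!is.null(region_volumes)) {
    zs <- rep(0, nrow(cohort))
    for (grp in unique(g)) {
      idx <- g == grp
      v <- region_volumes[idx]
      s <- sd(v)
      if (s == 0 && any(slope[idx] != 0))
        stop("constant region volume in group ", grp,
             ": coupling undefined", call. = FALSE)
      if (s > 0) zs[idx] <- (v - mean(v)) / s
    }
    ratio <- ratio + slope * zs
  }
  cohort[[paste0("ratio_2d4d_", hand)]] <- pmin(pmax(ratio, 0.7), 1.2)
  cohort
}
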