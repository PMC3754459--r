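# shared fixtures, built in code

# all-true analysis mask on a given lattice
full_mask <- function(dims, voxel_size = 4) {
  tpl <- volume_map(array(1, dim = dims), voxel_size = voxel_size,
                    kind = "template")
  make_analysis_mask(tpl)
}

# minimal cohort table for design/GLM tests (no maps involved)
toy_cohort <- function(n_per_group = 30, groups = c("MC", "MA", "FC", "FA"),
                       centres = "A", seed = 1) {
  set.seed(seed)
  g <- rep(groups, each = n_per_group)
  data.frame(
    id = sprintf("S%03d", seq_along(g)),
    sex = factor(ifelse(g %in% c("MC", "MA"), "M", "F"),
                 levels = c("M", "F")),
    diagnosis = factor(ifelse(g %in% c("MA", "FA"), "autism", "control"),
                       levels = c("control", "autism")),
    group = factor(g, levels = unique(g)),
    age = runif(length(g), 18, 49),
    centre = factor(rep_len(centres, length(g))))
}

# wrap a plain t-value array as a stat_map (for overlap/cluster unit tests)
toy_stat_map <- function(t_array, df = 1000, mask = NULL, label = "toy",
                         fwhm = c(2, 2, 2), voxel_size = 4) {
  if (is.null(mask)) mask <- full_mask(dim(t_array), voxel_size)
  sm <- structure(list(fwhm = fwhm, lambda = 4 * log(2) / fwhm^2,
                       resel_count = mask$n_voxels / prod(fwhm),
                       n_voxels = mask$n_voxels, n_images = NA),
                  class = "smoothness_estimate")
  structure(list(t = t_array, df = df, label = label, mask = mask,
                 voxel_size = rep(voxel_size, 3), smoothness = sm),
            class = "stat_map")
}

# small fast scenario for generator/GLM tests
small_config <- function(seed = 1, n_per_group = 8,
                         grid_dims = c(16, 16, 16), ...) {
  scenario_config(grid_dims = grid_dims, n_per_group = n_per_group,
                  group_scale = NULL, seed = seed, ...)
}

# planted female-masculinization scenario: female diagnosis regions inside
# the control sex-dimorphism regions (matched directions), an independent
# male diagnosis region elsewhere
masc_config <- function(seed = 1) {
  scenario_config(
    effect_fields = list(
      effect_field("sex", list(
        effect_region(c(13, 24, 20), 20, 0.15),
        effect_region(c(27, 24, 20), 20, -0.15))),
      effect_field("diagnosis_in_females", list(
        effect_region(c(13, 24, 20), 12, 0.12),
        effect_region(c(27, 24, 20), 12, -0.12))),
      effect_field("diagnosis_in_males",
        effect_region(c(20, 24, 32), 12, 0.12))),
    seed = seed)
}

# independent-placement scenario: diagnosis regions disjoint from the
# dimorphism region
independent_config <- function(seed = 1) {
  scenario_config(
    effect_fields = list(
      effect_field("sex", effect_region(c(13, 24, 20), 12, 0.12)),
      effect_field("diagnosis_in_females",
                   effect_region(c(27, 24, 20), 12, 0.12)),
      effect_field("diagnosis_in_males",
                   effect_region(c(20, 24, 32), 12, 0.12))),
    seed = seed)
}

# observed-vs-null overlap curve between the diagnosis effect in females
# (from cohort_dx) and the control sex difference from an INDEPENDENT
# cohort (cohort_sex), so the two map families share no subjects
disjoint_overlap_curve <- function(cohort_dx, cohort_sex, n_iterations = 500,
                                   seed = 1, ladder = threshold_ladder()) {
  prep_dx <- vbmoverlap:::prepare_tissue_analysis(cohort_dx, "GM")
  prep_sex <- vbmoverlap:::prepare_tissue_analysis(cohort_sex, "GM",
                                                   mask = prep_dx$mask)
  dxf <- vbmoverlap:::fit_group_contrast(
    prep_dx$stack, cohort_dx$cohort, which(cohort_dx$cohort$sex == "F"),
    prep_dx$mask, "diagnosis", label_pos = "FA>FC", label_neg = "FC>FA")
  sx <- vbmoverlap:::fit_group_contrast(
    prep_sex$stack, cohort_sex$cohort,
    which(cohort_sex$cohort$diagnosis == "control"),
    prep_dx$mask, "sex", label_pos = "MC>FC", label_neg = "FC>MC")
  obs <- directional_overlap(dxf$pos, dxf$neg, sx$pos, sx$neg,
                             mode = "masculinized", ladder = ladder)
  null <- simulate_null_overlap(dxf$pos$smoothness, sx$pos$smoothness,
                                prep_dx$mask, ladder = ladder,
                                n_iterations = n_iterations, seed = seed)
  overlap_curve(obs, null)
}

# brute-force flood fill, the independent oracle for extract_clusters
flood_fill_components <- function(mask_arr, connectivity) {
  d <- dim(mask_arr)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  off <- switch(as.character(connectivity),
                "6" = off[rowSums(abs(off)) == 1, ],
                "18" = off[rowSums(abs(off)) <= 2, ],
                "26" = off)
  lab <- array(0L, dim = d)
  nxt <- 0L
  for (start in which(mask_arr)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, d)
      for (k in seq_len(nrow(off))) {
        nb <- co + off[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        nl <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask_arr[nl] && lab[nl] == 0L) {
          lab[nl] <- nxt
          queue <- c(queue, nl)
        }
      }
    }
  }
  lab
}
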