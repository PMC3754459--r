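test_that("same config and seed reproduce the cohort bit for bit", {
  cfg <- small_config(seed = 9, n_per_group = 4)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$maps$GM$data, b$maps$GM$data)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$ground_truth, b$ground_truth)
  # ground truth reproducible from the config alone, without generation
  expect_identical(ground_truth_masks(cfg), a$ground_truth)
})

test_that("scenario configuration rejects invalid setups", {
  expect_error(scenario_config(grid_dims = c(6, 16, 16)), ">= 8")
  expect_error(scenario_config(n_per_group = 1), ">= 2")
  expect_error(scenario_config(noise_fwhm_mm = -1), ">= 0")
  dup <- list(effect_field("sex", effect_region(c(8, 8, 8), 8, 1)),
              effect_field("sex", effect_region(c(20, 20, 20), 8, 1)))
  expect_error(scenario_config(effect_fields = dup, grid_dims = rep(32, 3)),
               "configuration error")
  out <- effect_field("sex", effect_region(c(50, 8, 8), 8, 1))
  expect_error(scenario_config(effect_fields = list(out),
                               grid_dims = rep(16, 3)), "outside")
})

test_that("table totals equal the integrated map volumes and maps are non-negative", {
  cc <- generate_cohort(small_config(seed = 2, n_per_group = 5))
  expect_true(all(cc$maps$GM$data >= 0))
  expect_equal(cc$cohort$total_GM, stack_totals(cc$maps$GM),
               tolerance = 1e-6)
  expect_equal(cc$cohort$total_GM,
               vapply(seq_len(20), function(i)
                 total_tissue_volume(get_subject_volume(cc$maps$GM, i)), 0),
               tolerance = 1e-6)
})

test_that("negative excursions are clipped at zero and logged", {
  cfg <- small_config(seed = 4, n_per_group = 3,
                      effect_fields = list(
                        effect_field("sex",
                                     effect_region(c(8, 8, 8), 12, -100))))
  cc <- generate_cohort(cfg)
  expect_gt(cc$n_clipped, 0)
  expect_true(all(cc$maps$GM$data >= 0))
})

test_that("zero-effect cohorts give null voxel-wise t statistics", {
  # one central in-support voxel per replicate cohort, two-sample t MC vs FC
  tstats <- vapply(1:80, function(s) {
    cc <- generate_cohort(small_config(seed = 1000 + s, n_per_group = 8,
                                       grid_dims = c(12, 12, 12)))
    y <- cc$maps$GM$data[6 + 5 * 12 + 5 * 144, ]
    g <- cc$cohort$group
    two_sample_t(y[g == "MC"], y[g == "FC"])$t
  }, 0)
  ks <- stats::ks.test(tstats, function(q) pt(q, df = 14))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted sex effect is recovered with the power the oracle predicts", {
  # oracle: 20-replicate direct simulation of this configuration gives mean
  # within-blob suprathreshold fraction 0.68 (range 0.55-0.85) at P < 0.001
  pw <- vapply(1:3, function(s) {
    cfg <- scenario_config(
      effect_fields = list(effect_field("sex",
        effect_region(c(20, 24, 20), 12, 1.5 * 0.1))),
      group_scale = NULL, seed = 100 + s)
    cc <- generate_cohort(cfg)
    prep <- vbmoverlap:::prepare_tissue_analysis(cc, "GM")
    sx <- vbmoverlap:::fit_group_contrast(
      prep$stack, cc$cohort, which(cc$cohort$diagnosis == "control"),
      prep$mask, "sex", label_pos = "M>F", label_neg = "F>M")
    gt <- cc$ground_truth[["sex.GM"]]
    mean(sx$pos$t[gt] > qt(0.999, sx$pos$df), na.rm = TRUE)
  }, 0)
  expect_gt(mean(pw), 0.55)
})

test_that("digit ratios: null coupling, exact coupling, and group means", {
  cohort <- toy_cohort(30)
  # slope 0: null within-group correlation (SD ~ 1/sqrt(29)); direct
  # simulation puts |r| < 0.25 in ~82% of seeds
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    vols <- rnorm(nrow(cohort))
    out <- generate_digit_ratios(cohort, vols, coupling = 0,
                                 seed = s + 5000)
    r <- cor(out$ratio_2d4d_left[cohort$group == "FC"],
             vols[cohort$group == "FC"])
    abs(r) < 0.25
  }, TRUE)
  expect_gte(mean(hits), 0.7)
  # zero noise, positive slope: correlation exactly 1 within group
  set.seed(1)
  vols <- rnorm(nrow(cohort))
  out <- generate_digit_ratios(cohort, vols, coupling = 0.01,
                               noise_sd = 0, seed = 2)
  idx <- cohort$group == "FA"
  expect_equal(cor(out$ratio_2d4d_left[idx], vols[idx]), 1)
  # published group means: pooled t close to 1 in expectation across seeds
  tbar <- mean(vapply(1:200, function(s) {
    out <- generate_digit_ratios(cohort, NULL, seed = s,
                                 group_means = c(MC = 0.947, MA = 0.947,
                                                 FC = 0.975, FA = 0.967),
                                 noise_sd = c(MC = 0.03, MA = 0.03,
                                              FC = 0.0287, FA = 0.0322))
    fa <- out$ratio_2d4d_left[cohort$group == "FA"]
    fc <- out$ratio_2d4d_left[cohort$group == "FC"]
    two_sample_t(fc, fa)$t
  }, 0))
  expect_equal(tbar, 1.016, tolerance = 0.25)
  # alignment error
  expect_error(generate_digit_ratios(cohort, region_volumes = 1:3,
                                     coupling = 1),
               "alignment")
})

test_that("a cohort written to disk reads back consistently", {
  cc <- generate_cohort(small_config(seed = 8, n_per_group = 2,
                                     grid_dims = c(12, 12, 12)))
  dir <- file.path(tempdir(), "cohort_out")
  paths <- write_cohort(cc, dir)
  tsv <- read.table(file.path(dir, "cohort.tsv"), header = TRUE,
                    sep = "\t")
  expect_equal(nrow(tsv), 8)
  v <- read_volume(file.path(dir, "S001_GM.nii.gz"), tissue = "GM")
  expect_equal(as.numeric(v$values),
               as.numeric(get_subject_volume(cc$maps$GM, 1)$values),
               tolerance = 1e-6)
  gt <- read_volume(file.path(dir, "groundtruth_support.GM.nii.gz"),
                    kind = "mask")
  expect_equal(gt$values > 0, cc$ground_truth[["support.GM"]])
})

test_that("scenario YAML round trip preserves the configuration", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "grid_dims: [16, 16, 16]",
    "n_per_group: 4",
    "subject_noise_sd: 0.1",
    "noise_fwhm_mm: 8",
    "seed: 3",
    "effect_fields:",
    "  - factor: sex",
    "    tissue: GM",
    "    regions:",
    "      - centre: [8, 8, 8]",
    "        radius_mm: 10",
    "        amplitude: 0.15"), path)
  cfg <- scenario_from_yaml(path)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$grid_dims, rep(16L, 3))
  expect_equal(cfg$effect_fields[[1]]$factor, "sex")
  expect_equal(cfg$effect_fields[[1]]$regions[[1]]$radius_mm, 10)
  ref <- scenario_config(grid_dims = c(16, 16, 16), n_per_group = 4,
                         seed = 3, effect_fields = list(
                           effect_field("sex",
                                        effect_region(c(8, 8, 8), 10,
                                                      0.15))))
  expect_identical(generate_cohort(cfg)$maps$GM$data,
                   generate_cohort(ref)$maps$GM$data)
})

test_that("ratios stay in the physiological range and respect group sizes", {
  cc <- generate_cohort(small_config(seed = 12, n_per_group = 6))
  expect_true(all(cc$cohort$ratio_2d4d_left > 0.7 &
                    cc$cohort$ratio_2d4d_left < 1.2))
  expect_equal(as.integer(table(cc$cohort$group)), rep(6L, 4))
  expect_true(all(cc$cohort$age >= 18 & cc$cohort$age <= 49))
})
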