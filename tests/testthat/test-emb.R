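# end-to-end study-logic tests on the synthetic cohort; Monte Carlo nulls
# are run at reduced iteration counts here (the acceptance suite runs the
# decision-scale versions)

test_that("zero-effect scenario: S1 fails and the prediction is not testable", {
  cc <- generate_cohort(scenario_config(seed = 61))
  v <- run_question2(cc, n_iterations = 150, seed = 62)
  expect_false(v$S1_holds)
  expect_true(is.na(v$S2_holds))
  expect_true(is.na(v$S3_holds))
  expect_match(v$decision, "not testable")
})

test_that("planted female masculinization is recovered end to end", {
  cc <- generate_cohort(masc_config(63))
  v <- run_question2(cc, n_iterations = 300, seed = 64)
  expect_true(v$S1_holds)
  # S3: overlap far above the null at every rung at or below p = 0.025
  sel <- v$curves$S3$p <= 0.025
  expect_true(all(v$curves$S3$observed[sel] >
                    v$curves$S3$null_p995[sel], na.rm = TRUE))
  expect_true(all(v$curves$S3$empirical_p[sel] < 0.01, na.rm = TRUE))
  expect_gt(v$curves$S3$observed[250], 20)
  # S2 (independent male regions) never reaches the S3 overlap level
  expect_gt(min(v$curves$S3$observed[sel] - v$curves$S2$observed[sel],
                na.rm = TRUE), 0)
  expect_false(overlap_consistent(v$curves$S2, alpha = 1 / 301))
})

test_that("overlap voxels coincide with the planted interaction regions", {
  cc <- generate_cohort(masc_config(65))
  prep <- vbmoverlap:::prepare_tissue_analysis(cc, "GM")
  dxf <- vbmoverlap:::fit_group_contrast(
    prep$stack, cc$cohort, which(cc$cohort$sex == "F"), prep$mask,
    "diagnosis", label_pos = "FA>FC", label_neg = "FC>FA")
  sx <- vbmoverlap:::fit_group_contrast(
    prep$stack, cc$cohort, which(cc$cohort$diagnosis == "control"),
    prep$mask, "sex", label_pos = "MC>FC", label_neg = "FC>MC")
  cj1 <- conjunction_mask(threshold_statmap(dxf$pos, 0.025),
                          threshold_statmap(sx$pos, 0.025))
  cj2 <- conjunction_mask(threshold_statmap(dxf$neg, 0.025),
                          threshold_statmap(sx$neg, 0.025))
  overlap_vox <- cj1$values | cj2$values
  gt <- cc$ground_truth[["diagnosis_in_females.GM"]]
  jaccard <- sum(overlap_vox & gt) / sum(overlap_vox | gt)
  expect_gte(jaccard, 0.3)
})

test_that("direction swap: a feminized male diagnosis field is detected only in feminized mode", {
  cfg <- scenario_config(
    effect_fields = list(
      effect_field("sex", effect_region(c(20, 24, 20), 16, 0.15)),
      effect_field("diagnosis_in_males",
                   effect_region(c(20, 24, 20), 16, -0.15))),
    seed = 67)
  cc <- generate_cohort(cfg)
  vf <- run_question2(cc, mode = "feminized", n_iterations = 300, seed = 68)
  vm <- run_question2(cc, mode = "masculinized", n_iterations = 300,
                      seed = 68)
  sel <- vf$curves$S2$p <= 0.025
  expect_true(all(vf$curves$S2$empirical_p[sel] < 0.01, na.rm = TRUE))
  expect_gt(vf$curves$S2$observed[250], vm$curves$S2$observed[250])
  expect_false(all(vm$curves$S2$empirical_p[sel] < 0.01, na.rm = TRUE))
})

test_that("question 1 recovers a planted crossover interaction and flags shared diagnosis maps", {
  cfg <- scenario_config(
    effect_fields = list(
      effect_field("interaction", effect_region(c(20, 24, 20), 16, 0.1)),
      effect_field("diagnosis_in_males",
                   effect_region(c(13, 24, 32), 12, 0.12)),
      effect_field("diagnosis_in_females",
                   effect_region(c(13, 24, 32), 12, 0.12))),
    seed = 71)
  cc <- generate_cohort(cfg)
  q1 <- run_question1(cc, n_iterations = 200, seed = 72)
  ret <- rbind(q1$clusters$interaction$pos[q1$clusters$interaction$pos$retained, ],
               q1$clusters$interaction$neg[q1$clusters$interaction$neg$retained, ])
  expect_gte(nrow(ret), 1)
  # the retained interaction clusters cover >= 50% of the planted region
  vox <- c(unlist(attr(q1$clusters$interaction$pos, "voxels")[
    q1$clusters$interaction$pos$retained]),
    unlist(attr(q1$clusters$interaction$neg, "voxels")[
      q1$clusters$interaction$neg$retained]))
  gt <- which(cc$ground_truth[["interaction.GM"]])
  expect_gte(mean(gt %in% vox), 0.5)
  # identical diagnosis fields in both sexes: DxF/DxM overlap above the
  # null band at the reference rung
  expect_gt(q1$dx_overlap$observed[250], q1$dx_overlap$null_p995[250])
})

test_that("no planted interaction: factorial inference stays silent", {
  nret <- vapply(1:5, function(s) {
    cc <- generate_cohort(scenario_config(seed = 900 + s))
    prep <- vbmoverlap:::prepare_tissue_analysis(cc, "GM")
    fit <- fit_mass_univariate(prep$stack, build_design(cc$cohort),
                               prep$mask)
    cvec <- fit$design$contrasts$interaction
    sum(cluster_inference(t_contrast(fit, cvec), 0.025)$retained) +
      sum(cluster_inference(t_contrast(fit, -cvec), 0.025)$retained)
  }, 0)
  expect_gte(mean(nret == 0), 0.8)
})

test_that("report bundles are deterministic, consistent, and validate input", {
  cc <- generate_cohort(masc_config(75))
  v1 <- run_question2(cc, n_iterations = 150, seed = 76)
  v2 <- run_question2(cc, n_iterations = 150, seed = 76)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  p1 <- write_report(v1, d1)
  p2 <- write_report(v2, d2)
  for (k in seq_along(p1))
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  # booleans in the JSON equal those recomputed from the stored curves
  js <- jsonlite::read_json(file.path(d1, "verdict.json"))
  s3_tsv <- read.table(file.path(d1, "curve_S3.tsv"), header = TRUE,
                       sep = "\t")
  recomputed <- overlap_consistent(s3_tsv,
                                   alpha = js$thresholds$overlap_alpha,
                                   p_max = js$thresholds$consistency_p_max,
                                   frac = js$thresholds$consistency_frac)
  if (isTRUE(js$S1_holds)) {
    expect_identical(js$S3_holds, recomputed)
  }
  # missing curve names the stage
  broken <- v1
  broken$curves$S2 <- NULL
  expect_error(write_report(broken, file.path(tempdir(), "rep3")),
               "missing overlap curve.*S2")
})
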