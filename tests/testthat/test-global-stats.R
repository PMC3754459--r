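# printed participant-characteristics cells used throughout (cm^3)
gm_means <- c(MC = 914, MA = 940, FC = 824, FA = 845)
gm_sds <- c(MC = 78, MA = 105, FC = 81, FA = 72)
csf_means <- c(MC = 270, MA = 264, FC = 236, FA = 227)
csf_sds <- c(MC = 59, MA = 63, FC = 53, FA = 45)

test_that("cell-stats ANOVA reproduces the published sex main effects", {
  gm <- anova_from_cell_stats(gm_means, gm_sds, 30)
  sexF <- gm$F[gm$effect == "sex"]
  expect_equal(gm$df2[1], 116)
  expect_equal(sexF, 35.623, tolerance = 0.02)
  expect_equal(gm$partial_eta_sq[gm$effect == "sex"], 0.235,
               tolerance = 0.02)
  csf <- anova_from_cell_stats(csf_means, csf_sds, 30)
  csfF <- csf$F[csf$effect == "sex"]
  expect_gt(csfF, 12.3 - 0.05)
  expect_lt(csfF, 12.5)
  # degenerate and invalid inputs
  same <- anova_from_cell_stats(c(MC = 5, MA = 5, FC = 5, FA = 5),
                                c(MC = 1, MA = 1, FC = 1, FA = 1), 10)
  expect_true(all(same$F == 0))
  expect_error(anova_from_cell_stats(gm_means, gm_sds, c(30, 28)),
               "balanced")
})

test_that("raw-data type-III ANOVA agrees with the closed form on matched moments", {
  # construct raw data whose cell moments match the printed cells exactly
  set.seed(41)
  n <- 30
  cohort <- toy_cohort(n)
  exact_cell <- function(m, s, n) {
    z <- scale(rnorm(n))            # mean 0, sd 1 exactly
    m + s * as.numeric(z)
  }
  y <- unlist(lapply(c("MC", "MA", "FC", "FA"), function(g)
    exact_cell(gm_means[g], gm_sds[g], n)))
  raw <- two_way_anova(y, cohort)
  closed <- anova_from_cell_stats(gm_means, gm_sds, n)
  expect_equal(raw$F, closed$F, tolerance = 1e-8)
  expect_equal(raw$partial_eta_sq, closed$partial_eta_sq, tolerance = 1e-8)
  # balanced cells with equal means: all F ~ 0
  flat <- two_way_anova(unlist(lapply(1:4, function(i)
    exact_cell(5, 1, n))), cohort)
  expect_true(all(flat$F < 1e-12))
  tiny <- cohort[c(1, 31, 61, 91), ]
  expect_error(two_way_anova(rnorm(4), tiny), "at least 2")
})

test_that("sex F reduces to the pooled t^2 when diagnosis has no effect", {
  m <- c(MC = 10, MA = 10, FC = 8, FA = 8)
  s <- c(MC = 2, MA = 2, FC = 2, FA = 2)
  n <- 12
  F_sex <- anova_from_cell_stats(m, s, n)$F[1]
  t_eq <- two_sample_t(mean1 = 10, sd1 = 2, n1 = 2 * n,
                       mean2 = 8, sd2 = 2, n2 = 2 * n)
  expect_equal(F_sex, t_eq$t^2, tolerance = 1e-10)
})

test_that("Pillai MANOVA matches a hand-built H/E eigen oracle and is bounded", {
  set.seed(43)
  n <- 15
  cohort <- toy_cohort(n)
  Y <- matrix(rnorm(60 * 3), 60, 3)
  Y[cohort$sex == "M", 1] <- Y[cohort$sex == "M", 1] + 1.5
  res <- manova_pillai(Y, cohort)
  expect_equal(res$effect, c("sex", "diagnosis", "sex:diagnosis"))
  expect_equal(res$df1, rep(3, 3))
  expect_equal(res$df2, rep(54, 3))
  # oracle: balanced design, H_sex from the sex-marginal mean difference,
  # E from within-cell crossproducts
  cells <- split(seq_len(60), cohort$group)
  cellmeans <- lapply(cells, function(i) colMeans(Y[i, , drop = FALSE]))
  E <- Reduce(`+`, lapply(cells, function(i)
    crossprod(sweep(Y[i, , drop = FALSE], 2, colMeans(Y[i, , drop = FALSE])))))
  dM <- (cellmeans$MC + cellmeans$MA) / 2
  dF <- (cellmeans$FC + cellmeans$FA) / 2
  dvec <- dM - dF
  H <- (60 / 4) * tcrossprod(dvec)
  V_oracle <- sum(diag(H %*% solve(H + E))) # Pillai = tr(H (H+E)^-1), rank 1
  expect_equal(res$pillai[1], V_oracle, tolerance = 1e-8)
  expect_true(all(res$pillai >= 0 & res$pillai <= 1)) # min(#DV, df_h) = 1
  # permuted responses: V near 0 and p roughly uniform
  ps <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    manova_pillai(Y[sample(60), ], cohort)$p[1]
  }, 0)
  expect_gt(mean(ps > 0.05), 0.8)
  expect_error(manova_pillai(Y[, 1, drop = FALSE], cohort))
})

test_that("two-sample t reproduces the published digit-ratio comparison", {
  res <- two_sample_t(mean1 = 0.967, sd1 = 0.0322, n1 = 30,
                      mean2 = 0.975, sd2 = 0.0287, n2 = 30)
  expect_equal(res$df, 58)
  expect_equal(abs(res$t), 1.010, tolerance = 0.01)
  expect_equal(res$p, 0.317, tolerance = 0.02)
  # conventions and identities
  same <- two_sample_t(mean1 = 3, sd1 = 0, n1 = 5, mean2 = 3, sd2 = 0,
                       n2 = 5)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  pw <- two_sample_t(mean1 = 1, sd1 = 2, n1 = 20, mean2 = 0, sd2 = 2,
                     n2 = 20, pooled = TRUE)
  wl <- two_sample_t(mean1 = 1, sd1 = 2, n1 = 20, mean2 = 0, sd2 = 2,
                     n2 = 20, pooled = FALSE)
  expect_equal(pw$t, wl$t)
  expect_equal(pw$df, wl$df)
  set.seed(2)
  x <- rnorm(10); y <- rnorm(12)
  raw <- two_sample_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(raw$t, unname(ref$statistic))
  expect_equal(raw$p, ref$p.value)
})

test_that("digit-ratio analysis: published example, exact cases, null calibration", {
  expect_equal(correlation_p(0.38, 30), 0.039, tolerance = 0.02)
  set.seed(47)
  n <- 30
  group <- rep(c("FC", "FA"), each = n)
  ratio <- rnorm(2 * n, 0.97, 0.03)
  vol <- numeric(2 * n)
  vol[1:n] <- 2 * ratio[1:n]                     # collinear in group FC
  vol[(n + 1):(2 * n)] <- rnorm(n)
  res <- digit_ratio_analysis(vol, ratio, group)
  expect_equal(res$per_group$r[res$per_group$group == "FC"], 1)
  # p from r and n matches cor.test
  ct <- cor.test(vol[group == "FA"], ratio[group == "FA"])
  expect_equal(res$per_group$p[res$per_group$group == "FA"],
               correlation_p(res$per_group$r[res$per_group$group == "FA"],
                             n))
  expect_equal(res$per_group$p[res$per_group$group == "FA"], ct$p.value,
               tolerance = 1e-10)
  # constant ratio in one group is flagged
  ratio2 <- ratio; ratio2[1:n] <- 0.97
  res2 <- digit_ratio_analysis(vol, ratio2, group)
  expect_true(is.na(res2$per_group$r[res2$per_group$group == "FC"]))
  expect_match(res2$per_group$flag[res2$per_group$group == "FC"],
               "undefined")
  # equal slopes in both groups: interaction p roughly uniform
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    r <- rnorm(2 * n, 0.97, 0.03)
    v <- 5 * r + rnorm(2 * n, 0, 0.1)
    digit_ratio_analysis(v, r, group)$interaction$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(digit_ratio_analysis(vol, ratio, rep("A", 2 * n)),
               "two levels")
})
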