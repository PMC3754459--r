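#' Two-way factorial ANOVA on a per-subject scalar
#'
#' Type-III sums of squares with sum-to-zero factor coding (sex x diagnosis),
#' matching the post-hoc ANOVAs run on absolute global tissue volumes.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param y per-subject response (e.g. total grey matter volume in cm^3).
#' @param cohort data.frame with factors `sex` and `diagnosis`.
#' @return data.frame with one row per effect (`sex`, `diagnosis`,
#'   `sex:diagnosis`): `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
two_way_anova <- function(y, cohort) {
  stopifnot(length(y) == nrow(cohort))
  d <- data.frame(y = y, sex = factor(cohort$sex),
                  diagnosis = factor(cohort$diagnosis))
  if (any(table(d$sex, d$diagnosis) < 2L))
    stop("every sex x diagnosis cell needs at least 2 subjects",
         call. = FALSE)
  fit <- lm(y ~ sex * diagnosis, data = d,
            contrasts = list(sex = "contr.sum", diagnosis = "contr.sum"))
  aov3 <- car::Anova(fit, type = 3)
  keep <- c("sex", "diagnosis", "sex:diagnosis")
  ss <- aov3[keep, "Sum Sq"]
  ss_err <- aov3["Residuals", "Sum Sq"]
  df_err <- aov3["Residuals", "Df"]
  data.frame(effect = keep,
             F = aov3[keep, "F value"],
             df1 = aov3[keep, "Df"],
             df2 = df_err,
             p = aov3[keep, "Pr(>F)"],
             partial_eta_sq = ss / (ss + ss_err),
             row.names = NULL)
}

#' Closed-form 2 x 2 ANOVA from printed cell summaries
#'
#' Reconstructs the balanced two-way ANOVA from the four cells' means, SDs
#' and common n (as printed in a participant-characteristics table):
#' `MSE` is the mean of the cell variances; for each effect,
#' `SS = 2n * sum over marginal means of (marginal - grand)^2` (main
#' effects) or `n * sum over cells of the interaction residual^2`;
#' `F = SS / MSE` on df (1, 4n - 4).
#'
#' @param means,sds named numeric vectors for cells `MC`, `MA`, `FC`, `FA`.
#' @param n common cell size (the design is balanced; unequal n is an
#'   error).
#' @return data.frame with rows `sex`, `diagnosis`, `sex:diagnosis`: `F`,
#'   `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
anova_from_cell_stats <- function(means, sds, n) {
  cells <- c("MC", "MA", "FC", "FA")
  if (!all(cells %in% names(means)) || !all(cells %in% names(sds)))
    stop("'means' and 'sds' must be named MC, MA, FC, FA", call. = FALSE)
  if (length(n) != 1L || n < 2L)
    stop("unequal or invalid cell sizes: the design is balanced",
         call. = FALSE)
  if (any(sds < 0)) stop("SDs must be non-negative", call. = FALSE)
  m <- means[cells]
  grand <- mean(m)
  marg_sex <- c(M = mean(m[c("MC", "MA")]), F = mean(m[c("FC", "FA")]))
  marg_dx <- c(control = mean(m[c("MC", "FC")]),
               autism = mean(m[c("MA", "FA")]))
  ss_sex <- 2 * n * sum((marg_sex - grand)^2)
  ss_dx <- 2 * n * sum((marg_dx - grand)^2)
  inter_resid <- m - marg_sex[c("M", "M", "F", "F")] -
    marg_dx[c("control", "autism", "control", "autism")] + grand
  ss_int <- n * sum(inter_resid^2)
  mse <- mean(sds[cells]^2)
  df2 <- 4 * n - 4
  ss <- c(ss_sex, ss_dx, ss_int)
  Fv <- ss / mse
  data.frame(effect = c("sex", "diagnosis", "sex:diagnosis"),
             F = Fv, df1 = 1, df2 = df2,
             p = pf(Fv, 1, df2, lower.tail = FALSE),
             partial_eta_sq = ss / (ss + mse * df2),
             row.names = NULL)
}

#' Two-way MANOVA with Pillai's trace
#'
#' Multivariate ANOVA over several dependent variables (e.g. absolute total
#' grey matter, white matter and CSF volumes) with sex and diagnosis as
#' fixed factors: `V = sum theta_i / (1 + theta_i)` over the eigenvalues of
#' `H E^-1`, with the standard F approximation.
#'
#' @param Y matrix or data.frame of dependent variables (subjects x DVs,
#'   >= 2 columns).
#' @param cohort data.frame with factors `sex` and `diagnosis`.
#' @return data.frame with one row per effect: `pillai`, `approx_F`, `df1`,
#'   `df2`, `p`.
#' @export
manova_pillai <- function(Y, cohort) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(cohort), ncol(Y) >= 2L)
  d <- data.frame(sex = factor(cohort$sex),
                  diagnosis = factor(cohort$diagnosis))
  if (nrow(Y) - 4L <= ncol(Y))
    stop("error degrees of freedom must exceed the number of DVs",
         call. = FALSE)
  fit <- manova(Y ~ sex * diagnosis, data = d,
                contrasts = list(sex = "contr.sum",
                                 diagnosis = "contr.sum"))
  s <- summary(fit, test = "Pillai")$stats
  keep <- c("sex", "diagnosis", "sex:diagnosis")
  data.frame(effect = keep,
             pillai = s[keep, "Pillai"],
             approx_F = s[keep, "approx F"],
             df1 = s[keep, "num Df"],
             df2 = s[keep, "den Df"],
             p = s[keep, "Pr(>F)"],
             row.names = NULL)
}

#' Two-sample t-test from raw data or printed summaries
#'
#' Pooled (equal-variance) or Welch t-test; the summary-input mode accepts
#' means, SDs and group sizes as printed in a table. With zero variance in
#' both groups and equal means, t = 0 and p = 1 by convention.
#'
#' @param x,y raw per-group observations (leave `NULL` when using summary
#'   input).
#' @param mean1,sd1,n1,mean2,sd2,n2 summary statistics of the two groups.
#' @param pooled use the pooled-variance test (default); `FALSE` gives
#'   Welch with Satterthwaite df.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(x = NULL, y = NULL, mean1 = NULL, sd1 = NULL,
                         n1 = NULL, mean2 = NULL, sd2 = NULL, n2 = NULL,
                         pooled = TRUE) {
  if (!is.null(x) || !is.null(y)) {
    stopifnot(length(x) >= 2L, length(y) >= 2L)
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2L, n2 >= 2L, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  if (pooled) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Digit-ratio correlation and group-interaction regression
#'
#' Pearson correlation between a region's (relative) volume and the 2D:4D
#' digit ratio within each of two groups, with the two-sided p from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)`, plus the moderation test from the
#' linear model `volume ~ group + ratio + group:ratio` (group sum-coded,
#' ratio mean-centred): the interaction beta and its p-value quantify the
#' group difference between the correlations.
#'
#' @param volumes per-subject region volumes.
#' @param ratios per-subject 2D:4D ratios.
#' @param group two-level factor (or coercible) aligned with the rows.
#' @return list of class `digit_ratio_analysis`: `per_group` data.frame
#'   (`group`, `r`, `n`, `p`, `flag`), and `interaction` (`beta`, `se`,
#'   `t`, `p`).
#' @export
digit_ratio_analysis <- function(volumes, ratios, group) {
  stopifnot(length(volumes) == length(ratios),
            length(volumes) == length(group))
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("'group' must have exactly two levels", call. = FALSE)
  ok <- stats::complete.cases(volumes, ratios, group)
  volumes <- volumes[ok]; ratios <- ratios[ok]; group <- droplevels(group[ok])
  per_group <- do.call(rbind, lapply(levels(group), function(g) {
    idx <- group == g
    n <- sum(idx)
    if (sd(ratios[idx]) == 0 || sd(volumes[idx]) == 0)
      return(data.frame(group = g, r = NA_real_, n = n, p = NA_real_,
                        flag = "constant input: correlation undefined"))
    ct <- cor.test(volumes[idx], ratios[idx], method = "pearson")
    data.frame(group = g, r = unname(ct$estimate), n = n,
               p = ct$p.value, flag = "")
  }))
  g_sum <- ifelse(group == levels(group)[1], 1, -1)
  ratio_c <- ratios - mean(ratios)
  fit <- lm(volumes ~ g_sum + ratio_c + g_sum:ratio_c)
  cf <- summary(fit)$coefficients
  if (!"g_sum:ratio_c" %in% rownames(cf))   # rank-deficient (constant ratio)
    inter <- rep(NA_real_, 4)
  else
    inter <- cf["g_sum:ratio_c", ]
  structure(list(per_group = per_group,
                 interaction = list(beta = unname(inter[1]),
                                    se = unname(inter[2]),
                                    t = unname(inter[3]),
                                    p = unname(inter[4]))),
            class = "digit_ratio_analysis")
}

#' Two-sided p-value of a Pearson correlation from r and n
#'
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom.
#'
#' @param r Pearson correlation.
#' @param n sample size.
#' @return two-sided p-value.
#' @export
correlation_p <- function(r, n) {
  stopifnot(abs(r) <= 1, n > 2)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t), n - 2)
}
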