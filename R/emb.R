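# shared preprocessing: tissue-specific rescaling + analysis mask from the
# cohort's mean modulated map (study-specific template analogue)
prepare_tissue_analysis <- function(cohort_obj, tissue, pve_threshold = 0.25,
                                    mask = NULL) {
  stopifnot(inherits(cohort_obj, "vbm_cohort"))
  stack <- cohort_obj$maps[[tissue]]
  if (is.null(stack)) stop("no maps for tissue ", tissue, call. = FALSE)
  if (is.null(mask))
    mask <- make_analysis_mask(stack_template(stack),
                               pve_threshold = pve_threshold)
  list(stack = rescale_stack(stack), mask = mask,
       cohort = cohort_obj$cohort)
}

# two-group voxel-wise comparison returning both one-sided t maps
fit_group_contrast <- function(stack, cohort, rows, mask, contrast_name,
                               include_age = TRUE, include_centre = FALSE,
                               label_pos, label_neg) {
  sub <- cohort[rows, , drop = FALSE]
  substack <- stack
  substack$data <- stack$data[, rows, drop = FALSE]
  substack$subject_ids <- stack$subject_ids[rows]
  design <- build_design(sub, include_interaction = FALSE,
                         include_age = include_age,
                         include_centre = include_centre)
  fit <- fit_mass_univariate(substack, design, mask)
  cvec <- design$contrasts[[contrast_name]]
  list(fit = fit,
       pos = t_contrast(fit, cvec, label = label_pos),
       neg = t_contrast(fit, -cvec, label = label_neg))
}

#' Question 1: is the neuroanatomy of autism different in males and females?
#'
#' Fits the 2 x 2 factorial GLM (sex, diagnosis, their interaction, age as
#' nuisance covariate) voxel-wise, reports cluster-level FDR-controlled
#' interaction and main-effect clusters (both one-sided contrasts at the
#' cluster-forming threshold), and measures the spatial similarity of the
#' diagnosis effect in females (DxF: FA vs FC) and in males (DxM: MA vs MC)
#' as a same-direction conjunction overlap curve against the Monte Carlo
#' null.
#'
#' @param cohort_obj a [generate_cohort()] object (or compatible list).
#' @param tissue tissue class to analyse.
#' @param voxel_p cluster-forming voxel-level threshold (applied to each
#'   one-sided contrast).
#' @param q cluster-wise FDR level.
#' @param connectivity cluster connectivity.
#' @param ladder overlap threshold ladder.
#' @param n_iterations Monte Carlo iterations for the overlap null.
#' @param pve_threshold analysis-mask PVE threshold.
#' @param seed seed for the Monte Carlo null.
#' @return A list of class `question1_result`: cluster tables per contrast,
#'   the DxF/DxM `overlap_curve`, and the parameters used.
#' @export
run_question1 <- function(cohort_obj, tissue = "GM", voxel_p = 0.025,
                          q = 0.05, connectivity = 18L,
                          ladder = threshold_ladder(),
                          n_iterations = 1000L, pve_threshold = 0.25,
                          seed = NULL) {
  prep <- prepare_tissue_analysis(cohort_obj, tissue, pve_threshold)
  cohort <- prep$cohort
  design <- build_design(cohort, include_interaction = TRUE,
                         include_age = TRUE)
  fit <- fit_mass_univariate(prep$stack, design, prep$mask)
  one_sided <- function(name, lab) {
    cvec <- design$contrasts[[name]]
    list(pos = cluster_inference(t_contrast(fit, cvec,
                                            label = paste0(lab, "+")),
                                 voxel_p = voxel_p, q = q,
                                 connectivity = connectivity),
         neg = cluster_inference(t_contrast(fit, -cvec,
                                            label = paste0(lab, "-")),
                                 voxel_p = voxel_p, q = q,
                                 connectivity = connectivity))
  }
  clusters <- list(interaction = one_sided("interaction", "sexXdx"),
                   sex = one_sided("sex", "MgtF"),
                   diagnosis = one_sided("diagnosis", "AgtC"))
  dxf <- fit_group_contrast(prep$stack, cohort, which(cohort$sex == "F"),
                            prep$mask, "diagnosis",
                            label_pos = "FA>FC", label_neg = "FC>FA")
  dxm <- fit_group_contrast(prep$stack, cohort, which(cohort$sex == "M"),
                            prep$mask, "diagnosis",
                            label_pos = "MA>MC", label_neg = "MC>MA")
  obs <- directional_overlap(dxf$pos, dxf$neg, dxm$pos, dxm$neg,
                             mode = "masculinized", ladder = ladder)
  null <- simulate_null_overlap(dxf$pos$smoothness, dxm$pos$smoothness,
                                prep$mask, ladder = ladder,
                                n_iterations = n_iterations, seed = seed)
  structure(list(tissue = tissue, clusters = clusters,
                 dx_overlap = overlap_curve(obs, null),
                 params = list(voxel_p = voxel_p, q = q,
                               connectivity = connectivity,
                               n_iterations = n_iterations,
                               pve_threshold = pve_threshold, seed = seed)),
            class = "question1_result")
}

#' Consistency rule for "substantial overlap irrespective of threshold"
#'
#' An overlap curve counts as consistently non-random when its empirical p
#' is below `alpha` at at least `frac` of the defined ladder rungs at or
#' below `p_max`. This operationalizes a verdict that must hold across the
#' threshold ladder rather than at one cherry-picked threshold.
#'
#' @param curve an [overlap_curve()] (or any data.frame with columns `p`
#'   and `empirical_p`).
#' @param alpha empirical p cut-off.
#' @param p_max only ladder rungs at or below this voxel-level probability
#'   enter the rule.
#' @param frac required fraction of qualifying rungs.
#' @return logical.
#' @export
overlap_consistent <- function(curve, alpha = 0.001, p_max = 0.025,
                               frac = 0.9) {
  sel <- curve$p <= p_max & !is.na(curve$empirical_p)
  if (!any(sel)) return(FALSE)
  mean(curve$empirical_p[sel] < alpha) >= frac
}

#' Question 2: does the neuroanatomy fit the extreme-male-brain (or
#' gender-incoherence) prediction?
#'
#' Evaluates the prerequisite/requisite logic on one tissue class:
#' \describe{
#'   \item{S1}{significant sexual dimorphism in controls — cluster-level
#'     FDR-retained clusters in the MC vs FC comparison (either direction).}
#'   \item{S2}{the male diagnosis map (MA vs MC) overlaps the control
#'     sex-difference map non-randomly in the direction set by `mode`.}
#'   \item{S3}{same for the female diagnosis map (FA vs FC).}
#' }
#' `mode = "masculinized"` tests the extreme-male-brain direction
#' (diagnosis effect aligned with typical dimorphism);
#' `mode = "feminized"` tests the gender-incoherence direction. S2/S3 hold
#' when the overlap's empirical p is below 0.001 consistently across the
#' ladder (at >= 90% of rungs at or below p = 0.025). If S1 fails, S2/S3
#' are marked not evaluable (NA), and the prediction is not testable.
#'
#' @inheritParams run_question1
#' @param mode conjunction direction, `"masculinized"` or `"feminized"`.
#' @param male_cohort optional separate (e.g. larger multicentre) male
#'   cohort, a `vbm_cohort` containing MA/MC subjects on the same lattice;
#'   centre factors are added to its design when it has more than one
#'   centre.
#' @param n_iterations Monte Carlo iterations for each overlap null.
#' @return An object of class `emb_verdict`.
#' @export
run_question2 <- function(cohort_obj, tissue = "GM",
                          mode = c("masculinized", "feminized"),
                          male_cohort = NULL, voxel_p = 0.025, q = 0.05,
                          connectivity = 18L, ladder = threshold_ladder(),
                          n_iterations = 5000L, pve_threshold = 0.25,
                          seed = NULL) {
  mode <- match.arg(mode)
  prep <- prepare_tissue_analysis(cohort_obj, tissue, pve_threshold)
  cohort <- prep$cohort

  ctrl <- which(cohort$diagnosis == "control")
  sexmaps <- fit_group_contrast(prep$stack, cohort, ctrl, prep$mask, "sex",
                                label_pos = "MC>FC", label_neg = "FC>MC")
  s1 <- list(pos = cluster_inference(sexmaps$pos, voxel_p = voxel_p, q = q,
                                     connectivity = connectivity),
             neg = cluster_inference(sexmaps$neg, voxel_p = voxel_p, q = q,
                                     connectivity = connectivity))
  S1_holds <- any(s1$pos$retained) || any(s1$neg$retained)

  if (is.null(male_cohort)) {
    dxm <- fit_group_contrast(prep$stack, cohort,
                              which(cohort$sex == "M"), prep$mask,
                              "diagnosis",
                              label_pos = "MA>MC", label_neg = "MC>MA")
  } else {
    mprep <- prepare_tissue_analysis(male_cohort, tissue, pve_threshold,
                                     mask = prep$mask)
    mc <- mprep$cohort
    dxm <- fit_group_contrast(mprep$stack, mc, seq_len(nrow(mc)),
                              prep$mask, "diagnosis",
                              include_centre =
                                length(unique(mc$centre)) > 1L,
                              label_pos = "MA>MC(L)",
                              label_neg = "MC>MA(L)")
  }
  dxf <- fit_group_contrast(prep$stack, cohort,
                            which(cohort$sex == "F"), prep$mask,
                            "diagnosis",
                            label_pos = "FA>FC", label_neg = "FC>FA")

  make_curve <- function(dx, store_pairs = FALSE) {
    obs <- directional_overlap(dx$pos, dx$neg, sexmaps$pos, sexmaps$neg,
                               mode = mode, ladder = ladder)
    null <- simulate_null_overlap(dx$pos$smoothness, sexmaps$pos$smoothness,
                                  prep$mask, ladder = ladder,
                                  n_iterations = n_iterations, seed = seed)
    curve <- overlap_curve(obs, null)
    curve$pct1 <- obs$pct1
    curve$pct2 <- obs$pct2
    curve
  }
  s2_curve <- make_curve(dxm)
  s3_curve <- make_curve(dxf)

  if (S1_holds) {
    S2_holds <- overlap_consistent(s2_curve)
    S3_holds <- overlap_consistent(s3_curve)
    decision <- sprintf(
      "S1 holds; %s prediction %s in males (S2 %s) and %s in females (S3 %s).",
      mode,
      if (S2_holds) "confirmed" else "not confirmed",
      if (S2_holds) "true" else "false",
      if (S3_holds) "confirmed" else "not confirmed",
      if (S3_holds) "true" else "false")
  } else {
    S2_holds <- NA
    S3_holds <- NA
    decision <- paste("S1 fails: no significant sexual dimorphism in",
                      "controls; S2/S3 not evaluable - prediction not",
                      "testable.")
  }

  structure(list(tissue = tissue, mode = mode,
                 S1_holds = S1_holds, S2_holds = S2_holds,
                 S3_holds = S3_holds,
                 s1_clusters = s1,
                 curves = list(S2 = s2_curve, S3 = s3_curve),
                 thresholds = list(voxel_p = voxel_p, q = q,
                                   overlap_alpha = 0.001,
                                   consistency_frac = 0.9,
                                   consistency_p_max = 0.025,
                                   connectivity = connectivity,
                                   pve_threshold = pve_threshold),
                 n_iterations = n_iterations, seed = seed,
                 decision = decision),
            class = "emb_verdict")
}

#' @export
print.emb_verdict <- function(x, ...) {
  cat(sprintf("<emb_verdict> tissue %s, mode %s\n  S1 = %s, S2 = %s, S3 = %s\n  %s\n",
              x$tissue, x$mode, x$S1_holds, x$S2_holds, x$S3_holds,
              x$decision))
  invisible(x)
}

#' Write a machine-readable report bundle
#'
#' Writes `verdict.json` (booleans, thresholds, seed and iteration counts)
#' plus TSV tables for every overlap curve and cluster table. Output is
#' deterministic: two runs with the same seeds produce byte-identical
#' files.
#'
#' @param verdict an [run_question2()] `emb_verdict` (or a
#'   [run_question1()] result).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(verdict, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  write_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (inherits(verdict, "emb_verdict")) {
    for (nm in c("S2", "S3")) {
      if (is.null(verdict$curves[[nm]]))
        stop("report error: missing overlap curve for stage ", nm,
             call. = FALSE)
      write_tsv(verdict$curves[[nm]], sprintf("curve_%s.tsv", nm))
    }
    write_tsv(verdict$s1_clusters$pos, "clusters_S1_pos.tsv")
    write_tsv(verdict$s1_clusters$neg, "clusters_S1_neg.tsv")
    json <- list(tissue = verdict$tissue, mode = verdict$mode,
                 S1_holds = verdict$S1_holds,
                 S2_holds = verdict$S2_holds,
                 S3_holds = verdict$S3_holds,
                 thresholds = verdict$thresholds,
                 n_iterations = verdict$n_iterations,
                 seed = verdict$seed, decision = verdict$decision)
  } else if (inherits(verdict, "question1_result")) {
    if (is.null(verdict$dx_overlap))
      stop("report error: missing overlap curve for stage dx_overlap",
           call. = FALSE)
    write_tsv(verdict$dx_overlap, "curve_DxF_DxM.tsv")
    for (eff in names(verdict$clusters))
      for (side in c("pos", "neg"))
        write_tsv(verdict$clusters[[eff]][[side]],
                  sprintf("clusters_%s_%s.tsv", eff, side))
    json <- list(tissue = verdict$tissue, params = verdict$params,
                 n_retained_interaction =
                   sum(verdict$clusters$interaction$pos$retained) +
                   sum(verdict$clusters$interaction$neg$retained))
  } else stop("unsupported report object", call. = FALSE)
  jp <- file.path(out_dir, "verdict.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- c(paths, jp)
  invisible(paths)
}
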