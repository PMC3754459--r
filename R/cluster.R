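#' Threshold a statistical map
#'
#' One-sided thresholding: a voxel is suprathreshold iff
#' `t > qt(1 - voxel_p, df)`. Tightening `voxel_p` yields nested masks.
#'
#' @param stat a [t_contrast()] map.
#' @param voxel_p voxel-level forming probability in (0, 0.5].
#' @return An object of class `supra_mask`: logical array `values` tagged
#'   with `voxel_p`, the realizing `height`, `df` and the source `label`.
#' @export
threshold_statmap <- function(stat, voxel_p) {
  stopifnot(inherits(stat, "stat_map"))
  if (is.null(stat$df)) stop("stat map has no degrees of freedom",
                             call. = FALSE)
  if (voxel_p <= 0 || voxel_p > 0.5)
    stop("'voxel_p' must be in (0, 0.5]", call. = FALSE)
  height <- qt(1 - voxel_p, df = stat$df)
  v <- stat$t > height
  v[is.na(v)] <- FALSE
  structure(list(values = v, voxel_p = voxel_p, height = height,
                 df = stat$df, label = stat$label,
                 voxel_size = stat$voxel_size, n_voxels = sum(v)),
            class = "supra_mask")
}

#' @export
print.supra_mask <- function(x, ...) {
  cat(sprintf("<supra_mask> '%s': %d voxels above t = %.3f (p < %g)\n",
              x$label, x$n_voxels, x$height, x$voxel_p))
  invisible(x)
}

conn_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)))
  g <- g[keep, ]
  # half set: lexicographically positive offsets (each pair visited once)
  g[g$dz > 0 | (g$dz == 0 & (g$dy > 0 | (g$dy == 0 & g$dx > 0))), ]
}

#' Extract connected clusters from a suprathreshold mask
#'
#' Partitions the suprathreshold voxels into maximal connected components
#' under the declared connectivity (default 18: faces and edges). Clusters
#' are sorted by extent, descending. When the source statistical map is
#' supplied, each cluster's peak is the maximum-t voxel (ties broken by the
#' lowest linear index).
#'
#' @param mask a [threshold_statmap()] result.
#' @param connectivity 6, 18 or 26.
#' @param stat optional [t_contrast()] map for peak statistics.
#' @return A data.frame (one row per cluster) with `cluster`, `k_e` (extent
#'   in voxels), `peak_t`, 0-based `peak_x/y/z` voxel indices and mm
#'   coordinates; the voxel index sets are attached as attribute `"voxels"`.
#' @export
extract_clusters <- function(mask, connectivity = 18L, stat = NULL) {
  stopifnot(inherits(mask, "supra_mask"))
  d <- dim(mask$values)
  ids <- which(mask$values)
  empty <- data.frame(cluster = integer(), k_e = integer(),
                      peak_t = numeric(), peak_x = integer(),
                      peak_y = integer(), peak_z = integer(),
                      peak_x_mm = numeric(), peak_y_mm = numeric(),
                      peak_z_mm = numeric())
  if (length(ids) == 0L) {
    attr(empty, "voxels") <- list()
    return(empty)
  }
  off <- conn_offsets(as.integer(connectivity))
  pos <- integer(prod(d))
  pos[ids] <- seq_along(ids)
  co <- arrayInd(ids, d)
  edges <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    dx <- off$dx[k]; dy <- off$dy[k]; dz <- off$dz[k]
    ok <- co[, 1] + dx >= 1L & co[, 1] + dx <= d[1] &
      co[, 2] + dy >= 1L & co[, 2] + dy <= d[2] &
      co[, 3] + dz >= 1L & co[, 3] + dz <= d[3]
    nb <- ids[ok] + dx + dy * d[1] + dz * d[1] * d[2]
    sel <- pos[nb] > 0L
    edges[[k]] <- rbind(pos[ids[ok]][sel], pos[nb][sel])
  }
  e <- do.call(cbind, edges)
  g <- igraph::make_graph(as.vector(e), n = length(ids), directed = FALSE)
  memb <- igraph::components(g)$membership
  vox_by_cluster <- split(ids, memb)
  sizes <- lengths(vox_by_cluster)
  ord <- order(-sizes, vapply(vox_by_cluster, min, 0))
  vox_by_cluster <- vox_by_cluster[ord]
  names(vox_by_cluster) <- NULL
  peak <- lapply(vox_by_cluster, function(v) {
    if (is.null(stat)) return(list(t = NA_real_, idx = v[1]))
    tv <- stat$t[v]
    best <- which(tv == max(tv))
    list(t = max(tv), idx = min(v[best]))
  })
  pk_idx <- vapply(peak, function(p) p$idx, 0)
  pk_co <- arrayInd(pk_idx, d) - 1L          # 0-based voxel indices
  vs <- rep(mask$voxel_size, length.out = 3)
  out <- data.frame(cluster = seq_along(vox_by_cluster),
                    k_e = as.integer(sizes[ord]),
                    peak_t = vapply(peak, function(p) p$t, 0),
                    peak_x = pk_co[, 1], peak_y = pk_co[, 2],
                    peak_z = pk_co[, 3],
                    peak_x_mm = pk_co[, 1] * vs[1],
                    peak_y_mm = pk_co[, 2] * vs[2],
                    peak_z_mm = pk_co[, 3] * vs[3])
  attr(out, "voxels") <- vox_by_cluster
  out
}

#' Expected-cluster-size quantities under stationary Gaussian random field
#' theory
#'
#' At Gaussian height threshold `u`, the expected suprathreshold volume is
#' `E[N] = V (1 - Phi(u))`, the expected number of clusters is
#' `E[m] = R rho3(u)` with the 3D EC density
#' `rho3(u) = (4 ln 2)^{3/2} (2 pi)^{-2} (u^2 - 1) exp(-u^2 / 2)`
#' (lower-dimensional EC terms are omitted; the 3D resel term dominates for
#' the mask sizes targeted here), and the mean cluster size is
#' `nbar = E[N] / E[m]`.
#'
#' @param u Gaussian height threshold (> 1; the EC density is non-positive
#'   otherwise).
#' @param smoothness a [estimate_smoothness()] object.
#' @param n_mask_voxels search-region size in voxels.
#' @return list with `EN`, `Em`, `nbar`.
#' @keywords internal
grf_cluster_moments <- function(u, smoothness, n_mask_voxels) {
  if (u <= 1)
    stop("inference error: Gaussian threshold u <= 1; use a stricter ",
         "cluster-forming threshold", call. = FALSE)
  rho3 <- (4 * log(2))^1.5 * (2 * pi)^(-2) * (u^2 - 1) * exp(-u^2 / 2)
  EN <- n_mask_voxels * pnorm(u, lower.tail = FALSE)
  Em <- smoothness$resel_count * rho3
  list(EN = EN, Em = Em, nbar = EN / Em)
}

#' Uncorrected GRF cluster-extent p-value
#'
#' The cluster-size distribution is modelled as
#' `P(extent >= k) = exp(-beta k^{2/3})` with
#' `beta = (Gamma(5/2) / nbar)^{2/3}`, so that the implied mean extent
#' matches `nbar` from [grf_cluster_moments()]. `k = 0` gives p = 1; p is
#' strictly decreasing in `k` and, at fixed `k`, increasing with smoothness
#' (larger mean cluster size).
#'
#' @param k_e cluster extent(s) in voxels (resels x prod(fwhm) for the
#'   non-stationary variant).
#' @param u Gaussian height threshold corresponding to the forming
#'   probability (`qnorm(1 - voxel_p)`).
#' @param smoothness a [estimate_smoothness()] object.
#' @param n_mask_voxels search-region size in voxels.
#' @return vector of uncorrected cluster p-values.
#' @export
cluster_p_uncorrected <- function(k_e, u, smoothness, n_mask_voxels) {
  mom <- grf_cluster_moments(u, smoothness, n_mask_voxels)
  beta <- (gamma(2.5) / mom$nbar)^(2 / 3)
  exp(-beta * pmax(k_e, 0)^(2 / 3))
}

#' Cluster-wise topological FDR
#'
#' Benjamini-Hochberg step-up over the uncorrected cluster p-values of one
#' contrast's map; `q_fdr` is the BH-adjusted p and a cluster is retained
#' iff `q_fdr < q`.
#'
#' @param clusters data.frame with a `p_uncorrected` column.
#' @param q FDR level.
#' @return The data.frame with `q_fdr` and logical `retained` appended.
#' @export
topological_fdr <- function(clusters, q = 0.05) {
  if (nrow(clusters) == 0L) {
    clusters$q_fdr <- numeric(0)
    clusters$retained <- logical(0)
    return(clusters)
  }
  if (is.null(clusters$p_uncorrected) || anyNA(clusters$p_uncorrected))
    stop("p_uncorrected must be set on all clusters", call. = FALSE)
  clusters$q_fdr <- p.adjust(clusters$p_uncorrected, method = "BH")
  clusters$retained <- clusters$q_fdr < q
  clusters
}

#' Full cluster-level inference on a statistical map
#'
#' Thresholds the map at the cluster-forming `voxel_p`, extracts connected
#' clusters, assigns each an uncorrected GRF extent p-value (after
#' gaussianizing the threshold by probability matching,
#' `u = qnorm(1 - voxel_p)`), and controls the cluster-wise topological FDR
#' at level `q`. With `nonstationary = TRUE` cluster extents are first
#' converted to resels through a local resels-per-voxel lattice estimated
#' from the fit's residuals, then referred to the same size distribution on
#' the resel scale (default is the stationary analysis).
#'
#' @param stat a [t_contrast()] map.
#' @param voxel_p cluster-forming voxel-level probability.
#' @param q cluster-wise FDR level.
#' @param connectivity cluster connectivity (6, 18, 26).
#' @param nonstationary use resel-rescaled cluster extents.
#' @param fit required when `nonstationary = TRUE` (source of the local
#'   smoothness lattice).
#' @return Cluster table (see [extract_clusters()]) with `extent_resels`,
#'   `p_uncorrected`, `q_fdr` and `retained` columns; suprathreshold mask in
#'   attribute `"supra_mask"`.
#' @export
cluster_inference <- function(stat, voxel_p = 0.025, q = 0.05,
                              connectivity = 18L, nonstationary = FALSE,
                              fit = NULL) {
  supra <- threshold_statmap(stat, voxel_p)
  cl <- extract_clusters(supra, connectivity = connectivity, stat = stat)
  sm <- stat$smoothness
  nvox <- stat$mask$n_voxels
  u <- qnorm(1 - voxel_p)
  fw <- ifelse(is.na(sm$fwhm), 1, sm$fwhm)
  if (nrow(cl) > 0L) {
    vox_sets <- attr(cl, "voxels")
    if (nonstationary) {
      if (is.null(fit)) stop("'fit' is required for the non-stationary ",
                             "extent correction", call. = FALSE)
      rpv <- resels_per_voxel(fit)
      cl$extent_resels <- vapply(vox_sets, function(v) sum(rpv[v]), 0)
      k_eff <- cl$extent_resels * prod(fw)
    } else {
      cl$extent_resels <- cl$k_e / prod(fw)
      k_eff <- cl$k_e
    }
    cl$p_uncorrected <- cluster_p_uncorrected(k_eff, u, sm, nvox)
    cl <- topological_fdr(cl, q = q)
    attr(cl, "voxels") <- vox_sets
  } else {
    cl$extent_resels <- numeric(0)
    cl$p_uncorrected <- numeric(0)
    cl <- topological_fdr(cl, q = q)
    attr(cl, "voxels") <- list()
  }
  attr(cl, "supra_mask") <- supra
  attr(cl, "voxel_p") <- voxel_p
  attr(cl, "q") <- q
  cl
}
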