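# Banded 1D Gaussian smoothing matrix with edge renormalisation; fwhm = 0
# gives the identity, so smoothing is exactly invertible to "no smoothing".
smooth_matrix_1d <- function(n, fwhm, voxel_mm) {
  if (fwhm <= 0) return(diag(n))
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1L, ceiling(3 * sigma))
  M <- outer(seq_len(n), seq_len(n),
             function(i, j) ifelse(abs(i - j) <= half,
                                   exp(-(i - j)^2 / (2 * sigma^2)), 0))
  M / rowSums(M)
}

#' Smooth a 3D volume with a separable Gaussian kernel
#'
#' @param vol 3D numeric array.
#' @param fwhm full-width at half-maximum of the kernel (mm).
#' @param voxel_mm isotropic voxel size (mm).
#' @return smoothed array of the same dimensions.
#' @export
smooth_volume <- function(vol, fwhm, voxel_mm = 2.2) {
  stopifnot(length(dim(vol)) == 3)
  if (fwhm <= 0) return(vol)
  d <- dim(vol)
  M1 <- smooth_matrix_1d(d[1], fwhm, voxel_mm)
  M2 <- smooth_matrix_1d(d[2], fwhm, voxel_mm)
  M3 <- smooth_matrix_1d(d[3], fwhm, voxel_mm)
  a <- array(M1 %*% matrix(vol, d[1], d[2] * d[3]), d)
  a <- aperm(array(M2 %*% matrix(aperm(a, c(2, 1, 3)), d[2], d[1] * d[3]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  a <- aperm(array(M3 %*% matrix(aperm(a, c(3, 1, 2)), d[3], d[1] * d[2]),
                   c(d[3], d[1], d[2])), c(2, 3, 1))
  a
}

#' Second-level one-sample group inference
#'
#' Smooths each participant's contrast map with a Gaussian kernel, then tests
#' each voxel's mean against zero with a one-sample t-test and converts t to
#' z preserving two-sided tail probability. Voxels with zero across-subject
#' variance and nonzero mean get a capped statistic.
#'
#' @param maps list of per-participant 3D arrays (or plain numeric vectors)
#'   sharing geometry.
#' @param fwhm smoothing kernel FWHM (mm); 0 disables smoothing.
#' @param voxel_mm isotropic voxel size (mm).
#' @return object of class `group_contrast`: `mean`, `sd`, `t`, `z`, `df`,
#'   `n`, `dims`, and `subject_maps` (the smoothed maps as an n x voxels
#'   matrix, reused by [conjunction()]).
#' @export
second_level <- function(maps, fwhm = 8, voxel_mm = 2.2) {
  stopifnot(length(maps) >= 3)
  dims <- if (is.array(maps[[1]])) dim(maps[[1]]) else NULL
  if (!is.null(dims))
    stopifnot(all(vapply(maps, function(m) identical(dim(m), dims), TRUE)))
  sm <- lapply(maps, function(m) {
    if (!is.null(dims) && length(dims) == 3 && fwhm > 0)
      smooth_volume(m, fwhm, voxel_mm) else m
  })
  X <- do.call(rbind, lapply(sm, as.vector))
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  t_stat <- ifelse(sdv > 0, mu / (sdv / sqrt(n)),
                   ifelse(mu == 0, 0, sign(mu) * T_CAP))
  z <- t_to_z(t_stat, n - 1)
  structure(list(mean = as_volume(mu, dims), sd = as_volume(sdv, dims),
                 t = as_volume(t_stat, dims), z = as_volume(z, dims),
                 df = n - 1, n = n, dims = dims, subject_maps = X),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("group_contrast: n = %d, df = %d, max |z| = %.2f\n",
              x$n, x$df, max(abs(x$z))))
  invisible(x)
}

# 3D connected-component labelling by flood fill.
# connectivity: "face" (6 neighbours), "edge" (18), "corner" (26).
label_clusters <- function(mask, connectivity = "face") {
  stopifnot(length(dim(mask)) == 3)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  dist <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- switch(connectivity,
                 face = offs[dist == 1, ],
                 edge = offs[dist <= 2, ],
                 corner = offs)
  d <- dim(mask)
  labels <- array(0L, d)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      co <- arrayInd(v, d)
      nx <- co[1] + offs$dx; ny <- co[2] + offs$dy; nz <- co[3] + offs$dz
      ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
      if (!any(ok)) next
      lin <- nx[ok] + (ny[ok] - 1L) * d[1] + (nz[ok] - 1L) * d[1] * d[2]
      lin <- lin[mask[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- cur
        stack <- c(stack, lin)
      }
    }
  }
  labels
}

#' Threshold a group map by voxelwise FDR plus cluster extent
#'
#' Benjamini-Hochberg control at level `q` over two-sided p-values of the
#' in-mask z map, followed by removal of significant clusters smaller than
#' `min_extent` voxels under the chosen connectivity. At the study's 2.2 mm
#' isotropic resolution a 5-voxel extent corresponds to 53.24 mm^3.
#'
#' @param group a [second_level()] result.
#' @param q FDR level in (0, 1).
#' @param min_extent minimum surviving cluster size (voxels).
#' @param mask optional logical array restricting the analysis.
#' @param connectivity `"face"`, `"edge"` or `"corner"`.
#' @return object of class `thresholded_map`: `z_map`, `significant`
#'   (logical array), `p_adjusted`, `q`, `min_extent`, `connectivity`,
#'   `cluster_labels`, `min_cluster_volume_mm3`.
#' @export
threshold_map <- function(group, q = 0.05, min_extent = 5, mask = NULL,
                          connectivity = c("face", "edge", "corner"),
                          voxel_mm = 2.2) {
  connectivity <- match.arg(connectivity)
  stopifnot(q > 0, q < 1)
  z <- group$z
  dims <- if (is.array(z)) dim(z) else NULL
  zv <- as.vector(z)
  in_mask <- if (is.null(mask)) rep(TRUE, length(zv)) else as.vector(mask)
  if (!any(in_mask)) stop("empty analysis mask", call. = FALSE)
  p <- 2 * stats::pnorm(-abs(zv))
  p_adj <- rep(NA_real_, length(zv))
  p_adj[in_mask] <- stats::p.adjust(p[in_mask], method = "BH")
  sig <- !is.na(p_adj) & p_adj <= q
  labels <- NULL
  if (!is.null(dims) && length(dims) == 3) {
    sig_arr <- array(sig, dims)
    labels <- label_clusters(sig_arr, connectivity)
    if (min_extent > 1 && any(sig)) {
      sizes <- tabulate(labels[labels > 0L])
      small <- which(sizes < min_extent)
      sig_arr[labels %in% small] <- FALSE
      labels[labels %in% small] <- 0L
      sig <- as.vector(sig_arr)
    }
  }
  structure(list(z_map = z, significant = as_volume(sig, dims),
                 p_adjusted = as_volume(p_adj, dims), q = q,
                 min_extent = min_extent, connectivity = connectivity,
                 cluster_labels = labels,
                 min_cluster_volume_mm3 = min_extent * voxel_mm^3),
            class = "thresholded_map")
}

#' @export
print.thresholded_map <- function(x, ...) {
  cat(sprintf("thresholded_map: q = %g, extent >= %d (%s connectivity): %d significant voxel(s)\n",
              x$q, x$min_extent, x$connectivity, sum(x$significant)))
  invisible(x)
}

#' Min-statistic conjunction with a sign-flip permutation null
#'
#' The conjunction mask is the intersection of the significant sets of the
#' thresholded input contrasts. In addition, the minimum group z statistic
#' across contrasts is tested voxelwise against a permutation null built by
#' randomly sign-flipping each participant's maps (the same flips applied to
#' every contrast, valid under a symmetric null), using the max-over-voxels
#' distribution of the min statistic, at threshold p < 0.05. The
#' `perm_significant` component carries that test's outcome.
#'
#' @param thresholded list of [threshold_map()] results (>= 2 contrasts).
#' @param participant_maps list with one element per contrast, each an
#'   n_participants x voxels matrix of (smoothed) contrast maps — e.g. the
#'   `subject_maps` of the [second_level()] fits.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed integer seed for the flips.
#' @param alpha permutation threshold.
#' @return object of class `conjunction_result`: `conjunction_mask`,
#'   `min_stat_map`, `perm_significant`, `perm_p`, `null_max`,
#'   `n_permutations`, `p_threshold`.
#' @export
conjunction <- function(thresholded, participant_maps, n_perm = 10000,
                        seed = 1L, alpha = 0.05) {
  stopifnot(length(thresholded) >= 2,
            length(participant_maps) == length(thresholded))
  if (n_perm < 100)
    stop("n_perm < 100 gives an unstable permutation null; refusing",
         call. = FALSE)
  dims <- if (is.array(thresholded[[1]]$significant))
    dim(thresholded[[1]]$significant) else NULL
  inter <- Reduce(`&`, lapply(thresholded, function(t) as.vector(t$significant)))
  Xs <- lapply(participant_maps, as.matrix)
  n <- nrow(Xs[[1]])
  V <- ncol(Xs[[1]])
  stopifnot(all(vapply(Xs, function(X) all(dim(X) == c(n, V)), TRUE)))
  # the min statistic and its permutation null are computed on the t scale
  # (t -> z is strictly monotone at shared df, so p-values are unchanged)
  # and converted to z only for the returned maps
  group_t <- function(m, ss) {
    sd2 <- (ss - n * m^2) / (n - 1)
    ifelse(sd2 > 0, m / sqrt(sd2 / n), ifelse(m == 0, 0, sign(m) * T_CAP))
  }
  ss_list <- lapply(Xs, function(X) colSums(X^2))
  obs_t <- mapply(function(X, ss) group_t(colMeans(X), ss), Xs, ss_list)
  min_t <- do.call(pmin, as.data.frame(obs_t))
  null_max_t <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    tmin <- NULL
    for (ci in seq_along(Xs)) {
      M <- (S %*% Xs[[ci]]) / n
      sd2 <- sweep(-n * M^2, 2, ss_list[[ci]], `+`) / (n - 1)
      tc <- ifelse(sd2 > 0, M / sqrt(sd2 / n),
                   ifelse(M == 0, 0, sign(M) * T_CAP))
      tmin <- if (is.null(tmin)) tc else pmin(tmin, tc)
    }
    apply(tmin, 1, max)
  })
  perm_p <- vapply(min_t, function(s) (1 + sum(null_max_t >= s)) /
                     (n_perm + 1), numeric(1))
  perm_sig <- perm_p < alpha
  min_stat <- t_to_z(min_t, n - 1)
  null_max <- t_to_z(null_max_t, n - 1)
  structure(list(conjunction_mask = as_volume(inter, dims),
                 min_stat_map = as_volume(min_stat, dims),
                 perm_significant = as_volume(perm_sig, dims),
                 perm_p = as_volume(perm_p, dims),
                 null_max = null_max, n_permutations = n_perm,
                 p_threshold = alpha),
            class = "conjunction_result")
}

#' @export
print.conjunction_result <- function(x, ...) {
  cat(sprintf("conjunction_result: %d voxel(s) in all contrasts; %d pass the %d-permutation min-statistic test (p < %g)\n",
              sum(x$conjunction_mask), sum(x$perm_significant),
              x$n_permutations, x$p_threshold))
  invisible(x)
}

#' Quantify overlap of a thresholded map with a network parcellation
#'
#' Fractions of significant voxels falling in each of the seven network
#' labels (1-7) of an integer-labelled parcellation volume, plus the fraction
#' outside any network (`unassigned`, label 0). Fractions sum to 1 whenever
#' the significant set is non-empty.
#'
#' @param thresholded a [threshold_map()] result (or logical array).
#' @param parcellation integer array of the same geometry with labels 0-7.
#' @param network_names optional character vector of length 7.
#' @return named numeric vector of 8 fractions (7 networks + unassigned).
#' @export
network_overlap <- function(thresholded, parcellation,
                            network_names = c("visual", "somatomotor",
                                              "dorsal_attention",
                                              "ventral_attention", "limbic",
                                              "frontoparietal", "default")) {
  sig <- if (inherits(thresholded, "thresholded_map"))
    thresholded$significant else thresholded
  stopifnot(length(sig) == length(parcellation))
  lab <- as.vector(parcellation)[as.vector(sig)]
  out <- stats::setNames(numeric(8), c(network_names, "unassigned"))
  if (length(lab) == 0) {
    warning("empty significant set: all-zero proportions")
    return(out)
  }
  for (k in 1:7) out[k] <- mean(lab == k)
  out["unassigned"] <- mean(!(lab %in% 1:7))
  out
}
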