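#' Group PCA of subject rSPMZs with split-half resampling z-scores
#'
#' Spatial principal components of the subject-by-voxel stack are the
#' multivariate patterns explaining the most between-subject variance.
#' Their voxel values are z-scored by split-half resampling: on each
#' iteration the subjects are split into random halves, each half's PCA is
#' computed, each half's components are matched to the full-stack
#' reference components by maximal absolute Pearson correlation and
#' sign-aligned, and the matched pair is converted to a z map with the
#' same signal/noise construction as the single-subject rSPMZ. The final z
#' map of a component is the mean over iterations. Components are
#' sign-flipped so the mean subject loading is positive.
#'
#' @param maps Subject maps: a matrix subjects x voxels, or a list of
#'   equal-length numeric vectors.
#' @param n_components Components to return (default 2).
#' @param n_iter Resampling iterations (default 100).
#' @param seed Integer seed for the resampling streams.
#' @return List of class `group_components`; each element has
#'   `component_index`, `z` (voxel z map), `variance_explained`, and
#'   `reference` (the full-stack loading pattern). The per-iteration z
#'   maps are attached as the `iterations` attribute for audit.
#' @export
group_pca_zscore <- function(maps, n_components = 2, n_iter = 100,
                             seed = 1L) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  n <- nrow(maps)
  if (n < 4) stop("at least 4 subjects are required")
  if (n_iter < 2) stop("n_iter must be >= 2")
  n_components <- min(n_components, n - 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # uncentered SVD: the first spatial component is then the dominant
  # pattern *common* to subjects, not merely the main axis of
  # between-subject variation
  spatial_pcs <- function(S, k) {
    sv <- svd(S)
    k <- min(k, sum(sv$d > max(sv$d) * 1e-10))
    V <- sv$v[, seq_len(k), drop = FALSE]
    scores <- S %*% V
    # flip so the mean subject loading is positive
    for (j in seq_len(k)) if (mean(scores[, j]) < 0) {
      V[, j] <- -V[, j]; scores[, j] <- -scores[, j]
    }
    list(V = V, varexp = sv$d^2 / sum(sv$d^2), scores = scores)
  }

  ref <- spatial_pcs(maps, n_components)
  k <- ncol(ref$V)
  zs <- array(0, c(n_iter, k, ncol(maps)))
  half1_n <- floor(n / 2)
  for (it in seq_len(n_iter)) {
    perm <- sample(n)
    h1 <- maps[perm[seq_len(half1_n)], , drop = FALSE]
    h2 <- maps[perm[(half1_n + 1):n], , drop = FALSE]
    p1 <- spatial_pcs(h1, k)
    p2 <- spatial_pcs(h2, k)
    for (j in seq_len(k)) {
      m1 <- match_component(ref$V[, j], p1$V)
      m2 <- match_component(ref$V[, j], p2$V)
      rz <- compute_rspmz(m1, m2)
      zs[it, j, ] <- rz$z
    }
  }
  comps <- lapply(seq_len(k), function(j)
    list(component_index = j, z = colMeans(zs[, j, , drop = FALSE], dims = 1),
         variance_explained = ref$varexp[j], reference = ref$V[, j]))
  comps <- lapply(comps, function(cm) {
    cm$z <- as.vector(cm$z); cm
  })
  structure(comps, class = "group_components",
            iterations = zs)
}

# Pick the candidate column with maximal |correlation| to the reference,
# sign-aligned to it.
match_component <- function(ref, candidates) {
  cr <- as.vector(cor(ref, candidates))
  j <- which.max(abs(cr))
  candidates[, j] * sign(cr[j])
}

#' Benjamini-Hochberg FDR threshold for a z map
#'
#' Two-sided normal p-values, step-up procedure over in-mask voxels.
#'
#' @param z Voxel z values (vector; NA allowed outside the analysis).
#' @param q FDR level in (0, 1), default 0.05.
#' @return Logical vector: `TRUE` where the voxel survives.
#' @export
fdr_threshold <- function(z, q = 0.05) {
  stopifnot(q > 0, q < 1)
  out <- rep(FALSE, length(z))
  ok <- which(is.finite(z))
  if (length(ok) == 0) return(out)
  p <- 2 * pnorm(-abs(z[ok]))
  out[ok] <- p.adjust(p, method = "BH") <= q
  out
}

#' Conjunction mask and mean map of two thresholded analyses
#'
#' @param maskA,maskB Logical vectors/arrays on a shared grid.
#' @param mapA,mapB Matching voxel maps.
#' @return List: `common` (logical AND), `mean_map` (elementwise average
#'   inside the conjunction, NA outside).
#' @export
conjunction_mean <- function(maskA, maskB, mapA, mapB) {
  if (length(maskA) != length(maskB) || length(mapA) != length(mapB) ||
      length(maskA) != length(mapA))
    stop("grid mismatch between masks/maps")
  common <- maskA & maskB
  mean_map <- (mapA + mapB) / 2
  mean_map[!common] <- NA
  list(common = common, mean_map = mean_map)
}

#' Extract suprathreshold clusters and their peaks
#'
#' Labels connected components of the mask (positive- and negative-valued
#' voxels clustered separately, since activation and deactivation are
#' reported apart), drops components smaller than `min_cluster`, and
#' reports each cluster's size, peak |value| voxel (ties resolve to the
#' smallest linear index) and peak coordinates in voxel indices and mm.
#'
#' @param map 3D numeric array of voxel values.
#' @param mask 3D logical array of suprathreshold voxels.
#' @param min_cluster Minimum cluster extent in voxels (default 20).
#' @param connectivity 26 (default; faces+edges+corners), 18 or 6.
#' @param voxdim Voxel dimensions in mm for the mm coordinates (0-based
#'   scaling affine).
#' @return Data frame of class `cluster_table`: `cluster_id`, `sign`,
#'   `size`, `peak_value`, `i`, `j`, `k`, `x_mm`, `y_mm`, `z_mm`, sorted
#'   by |peak value| descending.
#' @export
extract_clusters <- function(map, mask, min_cluster = 20,
                             connectivity = c(26, 18, 6),
                             voxdim = c(3, 3, 4.5)) {
  connectivity <- match.arg(as.character(connectivity[1]),
                            c("26", "18", "6"))
  connectivity <- as.integer(connectivity)
  stopifnot(identical(dim(map), dim(mask)), min_cluster >= 1)
  rows <- list()
  for (sgn in c(1, -1)) {
    m <- mask & (sign(map) == sgn)
    lab <- label_components(m, connectivity)
    if (max(lab) == 0) next
    for (id in seq_len(max(lab))) {
      vox <- which(lab == id)
      if (length(vox) < min_cluster) next
      pk <- vox[which.max(abs(map[vox]))]   # which.max: first = smallest index
      ijk <- arrayInd(pk, dim(map))
      rows[[length(rows) + 1]] <-
        data.frame(sign = sgn, size = length(vox), peak_value = map[pk],
                   i = ijk[1], j = ijk[2], k = ijk[3],
                   x_mm = (ijk[1] - 1) * voxdim[1],
                   y_mm = (ijk[2] - 1) * voxdim[2],
                   z_mm = (ijk[3] - 1) * voxdim[3])
    }
  }
  if (length(rows) == 0) {
    tab <- data.frame(cluster_id = integer(0), sign = numeric(0),
                      size = integer(0), peak_value = numeric(0),
                      i = integer(0), j = integer(0), k = integer(0),
                      x_mm = numeric(0), y_mm = numeric(0),
                      z_mm = numeric(0))
  } else {
    tab <- do.call(rbind, rows)
    tab <- tab[order(-abs(tab$peak_value)), ]
    tab <- cbind(cluster_id = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
  }
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

# Connected-component labeling by breadth-first flood fill.
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  todo <- which(mask)
  for (v in todo) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- v; lab[v] <- cur
    while (length(queue) > 0) {
      head_v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(head_v, d)
      nb <- sweep(offs, 2, as.integer(ijk), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin) > 0) {
        lab[lin] <- cur
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

#' Jaccard overlap of two binary masks
#'
#' Intersection over union; defined as 0 (with a `both_empty` attribute)
#' when both masks are empty.
#'
#' @param maskA,maskB Logical vectors/arrays on a shared grid.
#' @return Fraction in \[0, 1\].
#' @export
jaccard_index <- function(maskA, maskB) {
  if (length(maskA) != length(maskB)) stop("grid mismatch between masks")
  uni <- sum(maskA | maskB)
  if (uni == 0) return(structure(0, both_empty = TRUE))
  sum(maskA & maskB) / uni
}
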