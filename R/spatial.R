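# neighbour offsets for 6/18/26-connectivity on a 3-D grid
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26)) {
    stopf("connectivity must be 6, 18 or 26")
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  g[keep, , drop = FALSE]
}

#' Threshold a group F-map and extract clusters
#'
#' Voxels with `|signed F| >= f_crit` (strict inequality available via
#' `strict`) form the suprathreshold mask; connected components under the
#' chosen connectivity are labeled and components smaller than
#' `min_extent` voxels are discarded.
#'
#' @param fmap a [group_f_test()] object (signed or not; thresholding
#'   uses the absolute value).
#' @param f_crit critical F value (> 0).
#' @param min_extent minimum cluster size in voxels (>= 1; the
#'   conventional default is 100).
#' @param connectivity 6, 18 or 26 (default 18, the common SPM
#'   convention).
#' @param strict use `>` instead of the default `>=` at the threshold.
#' @return an object of class `cluster_set`: list with the labeled 3-D
#'   `labels` array (0 = background, cluster ids contiguous from 1,
#'   ordered by decreasing size), per-cluster `size`, `peak_F`,
#'   `peak_mm`, `centroid_mm`, `sign` (majority sign of signed F), and
#'   the thresholding parameters.
#' @export
threshold_and_cluster <- function(fmap, f_crit, min_extent = 100,
                                  connectivity = 18, strict = FALSE) {
  if (f_crit <= 0) stopf("f_crit must be positive")
  if (min_extent < 1) stopf("min_extent must be >= 1")
  Fv <- fmap$signed_F %||% fmap$F
  mask <- if (strict) abs(Fv) > f_crit else abs(Fv) >= f_crit
  shape <- dim(mask)
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, shape)
  comp_of <- integer(0)
  next_id <- 0L
  todo <- which(mask)
  coords <- arrayInd(todo, shape)
  inmask <- array(FALSE, shape)
  inmask[todo] <- TRUE
  for (v in seq_along(todo)) {
    if (labels[todo[v]] != 0L) next
    next_id <- next_id + 1L
    queue <- matrix(coords[v, ], 1)
    labels[todo[v]] <- next_id
    while (nrow(queue)) {
      nb <- queue[rep(seq_len(nrow(queue)), each = nrow(offs)), ,
                  drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), nrow(queue)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1) * shape[1] +
        (nb[, 3] - 1) * shape[1] * shape[2]
      new <- !duplicated(lin) & inmask[lin] & labels[lin] == 0L
      lin <- lin[new]
      labels[lin] <- next_id
      queue <- nb[new, , drop = FALSE]
    }
  }
  sizes <- tabulate(labels[labels > 0L], nbins = next_id)
  keep <- which(sizes >= min_extent)
  # relabel surviving clusters 1..K by decreasing size
  keep <- keep[order(-sizes[keep])]
  relabel <- integer(next_id)
  relabel[keep] <- seq_along(keep)
  pos <- which(labels > 0L)
  labels[pos] <- relabel[labels[pos]]
  K <- length(keep)
  info <- lapply(seq_len(K), function(k) {
    vox <- which(labels == k)
    ijk <- arrayInd(vox, shape)
    f <- abs(Fv[vox])
    pk <- which.max(f)
    mm <- function(ij) {
      drop(fmap$affine %*% c(ij - 1, 1))[1:3]
    }
    list(size = length(vox), peak_F = f[pk], peak_mm = mm(ijk[pk, ]),
         centroid_mm = mm(colMeans(ijk)),
         sign = if (is.null(fmap$signed_F)) 1 else
           as.integer(sign(sum(sign(fmap$signed_F[vox])) + 0.5)))
  })
  structure(list(labels = labels, n_clusters = K,
                 size = vapply(info, `[[`, 0, "size"),
                 peak_F = vapply(info, `[[`, 0, "peak_F"),
                 peak_mm = t(vapply(info, `[[`, numeric(3), "peak_mm")),
                 centroid_mm = t(vapply(info, `[[`, numeric(3),
                                        "centroid_mm")),
                 sign = vapply(info, `[[`, 0, "sign"),
                 f_crit = f_crit, min_extent = min_extent,
                 connectivity = connectivity, strict = strict),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set> %d cluster(s) at |F| %s %.3g, extent >= %d, %d-connectivity\n",
    x$n_clusters, if (x$strict) ">" else ">=", x$f_crit, x$min_extent,
    x$connectivity))
  invisible(x)
}

#' Spatial summary statistics of suprathreshold voxels
#'
#' Volume (surviving voxel count times the voxel volume from the image
#' geometry), mean, median and maximum |F| over the voxels of all
#' surviving clusters. An empty cluster set reports zero volume and
#' absent (NA) statistics.
#'
#' @param fmap the [group_f_test()] map the clusters were derived from.
#' @param clusters a [threshold_and_cluster()] object.
#' @return an object of class `spatial_stats`: list with `volume_mm3`,
#'   `mean_F`, `median_F`, `max_F`, `n_voxels`, `n_clusters`,
#'   `threshold`.
#' @export
summarize_clusters <- function(fmap, clusters) {
  if (!identical(dim(clusters$labels), fmap$grid_shape)) {
    stopf("clusters were not derived from this map")
  }
  vox <- which(clusters$labels > 0L)
  Fv <- abs((fmap$signed_F %||% fmap$F)[vox])
  vol_vox <- prod(fmap$voxel_size)
  structure(list(
    volume_mm3 = length(vox) * vol_vox,
    mean_F = if (length(vox)) mean(Fv) else NA_real_,
    median_F = if (length(vox)) stats::median(Fv) else NA_real_,
    max_F = if (length(vox)) max(Fv) else NA_real_,
    n_voxels = length(vox), n_clusters = clusters$n_clusters,
    threshold = clusters$f_crit), class = "spatial_stats")
}

#' @export
print.spatial_stats <- function(x, ...) {
  cat(sprintf(
    "<spatial_stats> %d voxels / %g mm^3 in %d cluster(s); mean F %.2f, median %.2f, max %.2f (|F| >= %.3g)\n",
    x$n_voxels, x$volume_mm3, x$n_clusters, x$mean_F, x$median_F,
    x$max_F, x$threshold))
  invisible(x)
}
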