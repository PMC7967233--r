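# Region merging: group the FMM regions into clusters with deterministic
# k-means on seed coordinates, pick the cluster that is surely nodule
# (bright and central), and grow over the cluster adjacency graph with a
# mean-intensity criterion. Also hosts the end-to-end `segment()` pipeline.

#' Initial k-means centroids from the seed-grid rules
#'
#' Reuses the seed-grid generator with lattice pitch `cluster_density`, so
#' cluster centroids obey the same delete/shift/keep gradient rules and stay
#' away from object boundaries. The number of surviving centroids fixes k.
#'
#' @param grad a `gradient_field`.
#' @param mask optional logical lung mask.
#' @param cluster_density lattice pitch in px (>= 3, default 7). Lowering it
#'   yields more, smaller clusters (finer merging decisions).
#' @return Integer matrix of centroid (row, col) positions.
#' @export
init_centroids <- function(grad, mask = NULL, cluster_density = 7) {
  if (cluster_density < 3) stop("`cluster_density` must be >= 3", call. = FALSE)
  sg <- tryCatch(generate_seed_grid(grad, mask, seed_distance = cluster_density),
                 error = function(e) stop("no valid cluster centroids: ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(sg$seeds) == 1L)
    warning("single cluster centroid: merging degenerates to one cluster")
  sg$seeds
}

# Deterministic Lloyd k-means on 2D points with fixed initial centers.
# Ties in assignment go to the lower cluster id; clusters left empty at
# convergence are dropped and ids reindexed.
lloyd_kmeans <- function(pts, centers, iter_max = 100, tol = 1e-4) {
  k <- nrow(centers)
  ctr <- matrix(as.numeric(centers), k, 2)
  assign_pts <- function(ctr) {
    d2 <- outer(pts[, 1], ctr[, 1], "-")^2 + outer(pts[, 2], ctr[, 2], "-")^2
    max.col(-d2, ties.method = "first")
  }
  cl <- assign_pts(ctr)
  for (it in seq_len(iter_max)) {
    new_ctr <- ctr
    for (j in seq_len(k)) {
      m <- cl == j
      if (any(m)) new_ctr[j, ] <- colMeans(pts[m, , drop = FALSE])
    }
    shift <- max(abs(new_ctr - ctr))
    ctr <- new_ctr
    cl_new <- assign_pts(ctr)
    done <- identical(cl_new, cl) || shift < tol
    cl <- cl_new
    if (done) break
  }
  nonempty <- sort(unique(cl))
  list(cluster = match(cl, nonempty), centers = ctr[nonempty, , drop = FALSE])
}

#' Cluster FMM regions with deterministic k-means
#'
#' Regions are clustered via their seed coordinates only (seeds packed
#' closely together lie in the same uniform area); intensity plays no role
#' here, it is the merging criterion. k-means is initialized at the given
#' centroids rather than randomly, so the clustering is repeatable. Every
#' region is assigned wholly to its seed's cluster.
#'
#' @param part an [fmm_partition()] result (must carry `mean_intensity`,
#'   i.e. be built with `img`).
#' @param centroids integer matrix of initial centroid positions (from
#'   [init_centroids()]).
#' @return An object of class `cluster_set`: `cluster_of_region` (integer
#'   vector indexed by region label), `stats` (per-cluster mean intensity
#'   over member pixels, pixel centroid, member pixel count), `adjacency`
#'   (2-column matrix of 4-adjacent cluster pairs, i < j), and the cluster
#'   label image `labels`.
#' @export
cluster_regions <- function(part, centroids) {
  stopifnot(inherits(part, "fmm_partition"))
  if (is.null(part$region_stats$mean_intensity))
    stop("fmm_partition must be computed with `img` to carry intensities",
         call. = FALSE)
  if (nrow(centroids) < 1L) stop("at least one centroid is required", call. = FALSE)
  pts <- cbind(part$region_stats$seed_row, part$region_stats$seed_col)
  km <- lloyd_kmeans(pts, centroids)
  cl_of_reg <- km$cluster
  k <- nrow(km$centers)

  labs <- part$labels
  cl_img <- matrix(0L, nrow(labs), ncol(labs))
  sel <- labs > 0L
  cl_img[sel] <- cl_of_reg[labs[sel]]

  idx <- which(cl_img > 0L, arr.ind = TRUE)
  cid <- cl_img[cl_img > 0L]
  intens <- rep(NA_real_, length(cid))
  n_pix <- tabulate(cid, nbins = k)
  stats <- data.frame(cluster = seq_len(k),
                      pixel_count = n_pix,
                      centroid_row = as.vector(rowsum(idx[, 1] + 0, cid)[, 1]) / n_pix,
                      centroid_col = as.vector(rowsum(idx[, 2] + 0, cid)[, 1]) / n_pix)
  w <- part$region_stats
  sums <- rowsum(w$mean_intensity * w$pixel_count, cl_of_reg)
  cnts <- rowsum(w$pixel_count + 0, cl_of_reg)
  stats$mean_intensity <- as.vector(sums / cnts)[match(seq_len(k),
                                                       as.integer(rownames(sums)))]

  # 4-connectivity adjacency of the cluster label image
  pairs <- rbind(
    cbind(as.vector(cl_img[-nrow(cl_img), ]), as.vector(cl_img[-1, ])),
    cbind(as.vector(cl_img[, -ncol(cl_img)]), as.vector(cl_img[, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) > 0L) {
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  structure(list(cluster_of_region = cl_of_reg, stats = stats,
                 adjacency = pairs, labels = cl_img),
            class = "cluster_set")
}

#' Select the start cluster for merging
#'
#' The merge must begin from a cluster that surely belongs to the nodule.
#' Crops are nodule-centered and nodules are usually bright, so the cluster
#' maximizing mean intensity over centroid distance to the image center
#' (plus one pixel, guarding the centroid-at-center singularity) is chosen.
#' This combined criterion also handles cavitary nodules, where the central
#' cluster is dark cavity rather than nodule tissue.
#'
#' @param clusters a `cluster_set`.
#' @param image_shape integer (nrow, ncol) of the crop.
#' @return The winning cluster id (ties to the lower id).
#' @export
select_start_cluster <- function(clusters, image_shape) {
  stopifnot(inherits(clusters, "cluster_set"))
  ctr <- (image_shape[1:2] + 1) / 2
  s <- clusters$stats
  d <- sqrt((s$centroid_row - ctr[1])^2 + (s$centroid_col - ctr[2])^2)
  ratio <- s$mean_intensity / (d + 1)
  s$cluster[which.max(ratio)]
}

#' Merge clusters into the segmentation mask
#'
#' Breadth-first growth over the cluster adjacency graph starting from the
#' start cluster. A frontier neighbor j, discovered from accepted cluster i,
#' is accepted iff `|mean_i - mean_j| < mean_threshold` — pairwise cluster
#' means, not a running mean of the growing blob, so a gentle intensity
#' gradient can be traversed step by step. The mask is the union of all
#' accepted clusters' pixels (whole clusters only).
#'
#' @param clusters a `cluster_set`.
#' @param start the start cluster id.
#' @param mean_threshold maximum absolute mean-intensity difference for a
#'   merge, in (0, 1); default 0.15.
#' @return An object of class `fmm_mask`: logical `mask`, the accepted
#'   `merged_cluster_ids`, and a `trace` data frame recording every
#'   accept/reject decision (from, to, difference, accepted).
#' @export
merge_clusters <- function(clusters, start, mean_threshold = 0.15) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (!(mean_threshold > 0 && mean_threshold < 1))
    stop("`mean_threshold` must be in (0, 1)", call. = FALSE)
  if (!start %in% clusters$stats$cluster) stop("invalid start cluster", call. = FALSE)
  means <- clusters$stats$mean_intensity
  adj <- clusters$adjacency
  neighbors <- function(i) {
    sort(c(adj[adj[, 1] == i, 2], adj[adj[, 2] == i, 1]))
  }
  accepted <- start
  visited <- start
  queue <- start
  trace <- list()
  while (length(queue) > 0L) {
    i <- queue[1]
    queue <- queue[-1]
    for (j in neighbors(i)) {
      if (j %in% visited) next
      visited <- c(visited, j)
      diff <- abs(means[i] - means[j])
      ok <- diff < mean_threshold
      trace[[length(trace) + 1L]] <- data.frame(from = i, to = j,
                                                difference = diff, accepted = ok)
      if (ok) {
        accepted <- c(accepted, j)
        queue <- c(queue, j)
      }
    }
  }
  mask <- matrix(clusters$labels %in% accepted,
                 nrow(clusters$labels), ncol(clusters$labels))
  structure(list(mask = mask, merged_cluster_ids = sort(accepted),
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(from = integer(), to = integer(),
                              difference = numeric(), accepted = logical())),
            class = "fmm_mask")
}

#' Default segmentation parameters
#'
#' @return Named list of all pipeline parameters with their defaults:
#'   `sigma` (Gaussian scale before the gradient, px), `tau` (speed
#'   exponent), `alpha`/`beta` (seed rules), `seed_distance` (seed lattice
#'   pitch, px), `cluster_density` (centroid lattice pitch, px),
#'   `mean_threshold` (merge criterion), and the `diffusion` denoising
#'   settings (`kappa`, `iters`, `dt`).
#' @export
fmm_params <- function() {
  list(sigma = 1, tau = -2, alpha = 1, beta = 2, seed_distance = 3,
       cluster_density = 7, mean_threshold = 0.15,
       diffusion = list(kappa = 0.05, iters = 10, dt = 0.15))
}

#' Segment a nodule crop end to end
#'
#' Composes the full pipeline: anisotropic-diffusion denoising, pleural
#' padding, Gaussian-smoothed gradient, exponential speed image, seed grid,
#' multi-label fast marching, k-means region clustering, start-cluster
#' selection and mean-intensity merging. The result is restricted to the
#' lung mask by construction (pixels outside it are never part of the
#' marching domain). Fully deterministic: identical inputs and parameters
#' produce identical masks.
#'
#' @param img a [nodule_image].
#' @param params parameter list as from [fmm_params()]; individual entries
#'   may be overridden via `...`.
#' @param ... named overrides of entries in `params`, e.g.
#'   `mean_threshold = 0.2`.
#' @return An object of class `fmm_segmentation`: the final logical `mask`
#'   plus all intermediates (`denoised`, `gradient`, `speed`, `seed_grid`,
#'   `partition`, `clusters`, `start_cluster`, `merge`) and the parameters.
#' @export
segment <- function(img, params = fmm_params(), ...) {
  stopifnot(inherits(img, "nodule_image"))
  dots <- list(...)
  params[names(dots)] <- dots
  den <- denoise(img, kappa = params$diffusion$kappa,
                 iters = params$diffusion$iters, dt = params$diffusion$dt)
  padded <- pad_pleura(den, img$lung_mask)
  grad <- gradient_magnitude(padded, sigma = params$sigma, mask = img$lung_mask)
  speed <- speed_from_gradient(grad, tau = params$tau)
  seeds <- generate_seed_grid(grad, img$lung_mask,
                              seed_distance = params$seed_distance,
                              alpha = params$alpha, beta = params$beta)
  part <- fmm_partition(speed, seeds, domain = img$lung_mask, img = img)
  centroids <- init_centroids(grad, img$lung_mask,
                              cluster_density = params$cluster_density)
  clusters <- cluster_regions(part, centroids)
  start <- select_start_cluster(clusters, dim(img$intensity))
  merged <- merge_clusters(clusters, start, mean_threshold = params$mean_threshold)
  if (!any(merged$mask))
    warning("empty segmentation mask; returning the start cluster only")
  structure(list(mask = merged$mask, denoised = den, gradient = grad,
                 speed = speed, seed_grid = seeds, partition = part,
                 clusters = clusters, start_cluster = start, merge = merged,
                 params = params),
            class = "fmm_segmentation")
}

#' @export
print.fmm_segmentation <- function(x, ...) {
  cat(sprintf(
    "<fmm_segmentation> %d x %d px | %d seeds -> %d clusters | start %d | mask %d px\n",
    nrow(x$mask), ncol(x$mask), nrow(x$seed_grid$seeds),
    nrow(x$clusters$stats), x$start_cluster, sum(x$mask)))
  invisible(x)
}
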