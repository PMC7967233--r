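# Shared fixture: a solid disk crop with a known two-level structure.
disk_image <- function(side = 42, radius = 10, fg = 0.65, bg = 0.15,
                       noise = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(bg, side, side)
  m[disk_mask(side, radius)] <- fg
  m <- fmmseg:::gaussian_blur(m, 0.8)
  if (noise > 0) m <- m + matrix(rnorm(side^2, sd = noise), side, side)
  nodule_image(pmin(pmax(m, 0), 1), 0.5)
}

test_that("centroid initialization inherits the seed-grid rules", {
  gf <- gradient_magnitude(matrix(0.5, 21, 21))
  ctr <- init_centroids(gf, cluster_density = 7)
  expect_equal(nrow(ctr), 9L)   # full 3x3 lattice survives on zero gradient

  # centroid sitting on a strong edge is deleted
  im <- matrix(0.2, 21, 21); im[, 11:21] <- 0.8
  gf2 <- gradient_magnitude(im, 1)
  ctr2 <- init_centroids(gf2, cluster_density = 7)
  expect_false(any(abs(ctr2[, 2] - 10.5) < 2))
  expect_error(init_centroids(gf, cluster_density = 2), ">= 3")
})

test_that("higher cluster density gives no more clusters", {
  img <- disk_image(noise = 0.02)
  den <- denoise(img)
  gf <- gradient_magnitude(den, 1)
  counts <- vapply(c(5, 7, 9), function(d) nrow(init_centroids(gf, cluster_density = d)),
                   numeric(1))
  expect_true(!is.unsorted(rev(counts)))
})

segment_fixture <- function(...) {
  img <- disk_image(...)
  sg <- segment(img)
  list(img = img, sg = sg)
}

test_that("k-means region clustering is deterministic and distance-driven", {
  img <- disk_image(noise = 0.02)
  sg <- segment(img)
  part <- sg$partition
  # k = 1: every region in one cluster, mean = global mean of the domain
  one <- cluster_regions(part, matrix(c(21L, 21L), 1))
  expect_equal(length(unique(one$cluster_of_region)), 1L)
  expect_equal(one$stats$mean_intensity, mean(img$intensity), tolerance = 1e-12)
  expect_equal(one$stats$pixel_count, 42L * 42L)

  # identical rerun -> identical assignment
  two_a <- cluster_regions(part, init_centroids(sg$gradient))
  two_b <- cluster_regions(part, init_centroids(sg$gradient))
  expect_identical(two_a$cluster_of_region, two_b$cluster_of_region)

  # adjacency is irreflexive, symmetric-by-construction (i < j) and only
  # links clusters that truly share a 4-connected boundary
  adj <- sg$clusters$adjacency
  expect_true(all(adj[, 1] < adj[, 2]))
  labs <- sg$clusters$labels
  for (k in seq_len(min(5, nrow(adj)))) {
    i <- adj[k, 1]; j <- adj[k, 2]
    vert <- (labs[-1, ] == i & labs[-nrow(labs), ] == j) |
      (labs[-1, ] == j & labs[-nrow(labs), ] == i)
    horiz <- (labs[, -1] == i & labs[, -ncol(labs)] == j) |
      (labs[, -1] == j & labs[, -ncol(labs)] == i)
    expect_true(any(vert) || any(horiz))
  }
})

test_that("two separated seed groups recover the optimal 2-means split", {
  # regions whose seeds form two tight distant groups
  sp <- matrix(1, 24, 24)
  seeds <- rbind(c(4L, 4L), c(4L, 7L), c(7L, 5L),
                 c(20L, 19L), c(18L, 21L), c(21L, 21L))
  part <- fmm_partition(sp, seeds, img = matrix(0.5, 24, 24))
  cl <- cluster_regions(part, rbind(c(5L, 5L), c(20L, 20L)))
  got <- cl$cluster_of_region
  oracle <- best_two_means(seeds)
  expect_true(identical(got, oracle) || identical(got, 3L - oracle))
})

test_that("start cluster balances brightness and centrality", {
  img <- disk_image()
  sg <- segment(img)
  st <- sg$clusters$stats
  ctr <- (dim(img$intensity) + 1) / 2
  d <- sqrt((st$centroid_row - ctr[1])^2 + (st$centroid_col - ctr[2])^2)
  expect_equal(select_start_cluster(sg$clusters, dim(img$intensity)),
               st$cluster[which.max(st$mean_intensity / (d + 1))])
  # the winner on a centered bright disk contains the image center region
  win <- sg$start_cluster
  expect_gt(st$mean_intensity[st$cluster == win], 0.5)

  # cavitary-style fixture: enumerate ratios over all clusters and check argmax
  cav <- make_phantom_case(synth_config("cavitary", "isolated", 10, Inf, seed = 2))
  sgc <- segment(cav$image)
  stc <- sgc$clusters$stats
  ctrc <- (dim(cav$image$intensity) + 1) / 2
  dc <- sqrt((stc$centroid_row - ctrc[1])^2 + (stc$centroid_col - ctrc[2])^2)
  expect_equal(sgc$start_cluster, stc$cluster[which.max(stc$mean_intensity / (dc + 1))])
  # the start cluster is ring tissue, not the dark cavity
  expect_gt(stc$mean_intensity[stc$cluster == sgc$start_cluster], 0.4)
})

test_that("merging follows the pairwise mean-intensity rule", {
  # hand-built cluster set: chain A(0.8) - B(0.7) - C(0.6), plus D(0.45) off B
  fake <- structure(list(
    cluster_of_region = 1:4,
    stats = data.frame(cluster = 1:4, pixel_count = c(4L, 4L, 4L, 4L),
                       centroid_row = c(2, 2, 2, 5), centroid_col = c(2, 5, 8, 5),
                       mean_intensity = c(0.8, 0.7, 0.6, 0.45)),
    adjacency = rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L)),
    labels = matrix(0L, 6, 12)
  ), class = "cluster_set")
  fake$labels <- matrix(0L, 6, 12)
  fake$labels[1:4, 1:4] <- 1L; fake$labels[1:4, 5:8] <- 2L
  fake$labels[1:4, 9:12] <- 3L; fake$labels[5:6, 5:8] <- 4L

  m <- merge_clusters(fake, start = 1L, mean_threshold = 0.15)
  # A-B diff 0.1 accepted, B-C diff 0.1 accepted even though |A-C| = 0.2;
  # B-D diff 0.25 rejected
  expect_setequal(m$merged_cluster_ids, 1:3)
  expect_true(all(m$mask[fake$labels %in% 1:3]))
  expect_false(any(m$mask[fake$labels == 4L]))
  tr <- m$trace
  expect_equal(tr$accepted[tr$to == 4], FALSE)
  expect_equal(nrow(tr), 3L)

  # diff 0.25 from the start: only the start cluster remains
  fake2 <- fake
  fake2$stats$mean_intensity <- c(0.70, 0.45, 0.44, 0.44)
  m2 <- merge_clusters(fake2, start = 1L, mean_threshold = 0.15)
  expect_equal(m2$merged_cluster_ids, 1L)

  # diff 0.09 on a two-cluster pair merges both
  fake3 <- fake
  fake3$stats$mean_intensity <- c(0.70, 0.61, 0.10, 0.10)
  m3 <- merge_clusters(fake3, start = 1L, mean_threshold = 0.15)
  expect_true(all(c(1L, 2L) %in% m3$merged_cluster_ids))
  expect_error(merge_clusters(fake, 1L, mean_threshold = 0), "mean_threshold")
})

test_that("raising the merge threshold never shrinks the mask", {
  for (s in 1:4) {
    cs <- make_phantom_case(synth_config("solid-irregular", "isolated", 10, 99,
                                         seed = 40 + s))
    lo <- segment(cs$image, mean_threshold = 0.10)
    hi <- segment(cs$image, mean_threshold = 0.20)
    expect_true(all(hi$mask[lo$mask]))
  }
})

test_that("end-to-end segmentation is accurate and deterministic", {
  cs <- make_phantom_case(synth_config("solid-round", "isolated", 10, 197, seed = 5))
  a <- segment(cs$image)
  b <- segment(cs$image)
  expect_identical(a$mask, b$mask)
  expect_gt(dice(a$mask, cs$ground_truth), 0.95)
  # mask is a union of whole clusters
  labs <- a$clusters$labels
  for (k in a$merge$merged_cluster_ids)
    expect_true(all(a$mask[labs == k]))
  expect_false(any(a$mask[!(labs %in% a$merge$merged_cluster_ids)]))

  # juxtapleural: the mask cannot leave the lung mask
  cj <- make_phantom_case(synth_config("solid-round", "juxtapleural", 10, 197, seed = 6))
  sj <- segment(cj$image)
  expect_false(any(sj$mask[!cj$image$lung_mask]))
})
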