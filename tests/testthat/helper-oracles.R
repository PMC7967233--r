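# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the package's own code paths.

# Shortest arrival times by Dijkstra on the 8-connected pixel graph with
# edge cost = step length * (1/F_u + 1/F_v) / 2, minimized over all seeds.
dijkstra_times <- function(F, seeds) {
  nr <- nrow(F); nc <- ncol(F)
  id <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    step <- sqrt(dr^2 + dc^2)
    for (c in seq_len(nc)) {
      c2 <- c + dc
      if (c2 < 1 || c2 > nc) next
      r <- seq_len(nr); r2 <- r + dr
      ok <- r2 >= 1 & r2 <= nr
      from <- c(from, id(r[ok], c))
      to <- c(to, id(r2[ok], c2))
      w <- c(w, step * (1 / F[cbind(r[ok], c)] + 1 / F[cbind(r2[ok], c2)]) / 2)
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE,
    vertices = data.frame(name = seq_len(nr * nc)))
  src <- as.character(id(seeds[, 1], seeds[, 2]))
  D <- igraph::distances(g, v = src, weights = igraph::E(g)$weight)
  d <- apply(D, 2, min)
  matrix(d[order(as.integer(colnames(D)))], nr, nc)
}

# Exhaustive evaluation of the keep/shift/delete seed rules on a gradient
# matrix; mirrors the stated rules with plain loops.
naive_seed_rules <- function(G, domain, seed_distance, alpha, beta) {
  nr <- nrow(G); nc <- ncol(G)
  lm <- function(r, c) {
    vals <- c()
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && domain[rr, cc])
        vals <- c(vals, G[rr, cc])
    }
    mean(vals)
  }
  total <- mean(G[domain])
  start <- (seed_distance + 1L) %/% 2L
  out <- NULL
  decisions <- NULL
  for (r in seq.int(start, nr, by = seed_distance)) {
    for (c in seq.int(start, nc, by = seed_distance)) {
      if (!domain[r, c]) next
      l <- lm(r, c)
      if (l > beta * total) {
        decisions <- rbind(decisions, data.frame(row = r, col = c, rule = "delete"))
        next
      }
      if (l < alpha * total) {
        out <- rbind(out, c(r, c))
        decisions <- rbind(decisions, data.frame(row = r, col = c, rule = "keep"))
        next
      }
      best <- c(r, c); bestv <- l
      # raster-order scan of the 3x3 candidates, self first (wins ties)
      for (rr in (r - 1):(r + 1)) for (cc in (c - 1):(c + 1)) {
        if (rr == r && cc == c) next
        if (rr < 1 || rr > nr || cc < 1 || cc > nc || !domain[rr, cc]) next
        v <- lm(rr, cc)
        if (v < bestv) { bestv <- v; best <- c(rr, cc) }
      }
      out <- rbind(out, best)
      decisions <- rbind(decisions, data.frame(row = r, col = c, rule = "shift"))
    }
  }
  out <- unique(out)
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  list(seeds = out, decisions = decisions, total = total, local_mean = lm)
}

# Brute-force diameters: long axis from all pairwise distances between mask
# pixels; short axis from all nearly-perpendicular chords.
naive_diameters <- function(mask, spacing = 1) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) == 1L) return(list(long = 0, short = 0))
  D <- as.matrix(dist(pix))
  long <- max(D)
  ij <- which(D == long, arr.ind = TRUE)[1, ]
  u <- (pix[ij[2], ] - pix[ij[1], ]) / long
  v <- c(-u[2], u[1])
  short <- 0
  n <- nrow(pix)
  for (i in seq_len(n - 1)) {
    dd <- sweep(pix[(i + 1):n, , drop = FALSE], 2, pix[i, ])
    du <- abs(dd %*% u); dv <- abs(dd %*% v)
    cand <- dv[du <= 0.5]
    if (length(cand)) short <- max(short, max(cand))
  }
  list(long = long * spacing, short = short * spacing)
}

# Optimal 2-means on a tiny point set by exhaustive partition search.
best_two_means <- function(pts) {
  n <- nrow(pts)
  best <- NULL; bestcost <- Inf
  for (code in 1:(2^(n - 1) - 1)) {   # fix point 1 in group 1, skip empties
    grp <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    cost <- 0
    for (g in 1:2) {
      m <- grp == g
      ctr <- colMeans(pts[m, , drop = FALSE])
      cost <- cost + sum(sweep(pts[m, , drop = FALSE], 2, ctr)^2)
    }
    if (cost < bestcost) { bestcost <- cost; best <- grp }
  }
  best
}

disk_mask <- function(side, radius, ctr = (side + 1) / 2) {
  rr <- row(matrix(0, side, side)); cc <- col(matrix(0, side, side))
  (rr - ctr)^2 + (cc - ctr)^2 <= radius^2
}
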