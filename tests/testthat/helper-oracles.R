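# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# crossing-number point-in-polygon; TRUE strictly inside
oracle_inside <- function(p, poly) {
  n <- nrow(poly)
  cross <- 0L
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    if ((a[1] > p[1]) != (b[1] > p[1])) {
      xint <- a[2] + (p[1] - a[1]) / (b[1] - a[1]) * (b[2] - a[2])
      if (p[2] < xint) cross <- cross + 1L
    }
  }
  cross %% 2L == 1L
}

# exact distance from point to closed polygon boundary
oracle_dist_to_boundary <- function(p, poly) {
  n <- nrow(poly)
  best <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}

# brute-force DBSCAN pieces: core flags and the partition of core points
oracle_dbscan_cores <- function(points, eps, min_pts) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  core <- rowSums(d <= eps) >= min_pts
  # connected components of the core-core eps graph
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      nb <- which(core & d[j, ] <= eps & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  list(core = core, comp = comp, d = d)
}

# brute-force Delaunay: all triples with an empty circumcircle
oracle_delaunay <- function(points, tol = 1e-9) {
  n <- nrow(points)
  tris <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- points[i, ]; b <- points[j, ]; c <- points[k, ]
    d2 <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d2) < tol) next
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) + sum(c^2) * (a[2] - b[2])) / d2
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) + sum(c^2) * (b[1] - a[1])) / d2
    r2 <- sum((a - c(ux, uy))^2)
    empty <- TRUE
    for (m in seq_len(n)) {
      if (m %in% c(i, j, k)) next
      if (sum((points[m, ] - c(ux, uy))^2) < r2 - tol) { empty <- FALSE; break }
    }
    if (empty) tris[[length(tris) + 1L]] <- sort(c(i, j, k))
  }
  tris
}

# slow GLCM with explicit loops
oracle_glcm_stats <- function(q, pixels, off, levels) {
  member <- matrix(FALSE, nrow(q), ncol(q))
  member[pixels] <- TRUE
  counts <- matrix(0, levels, levels)
  for (t in seq_len(nrow(pixels))) {
    r2 <- pixels[t, 1] + off[1]; c2 <- pixels[t, 2] + off[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q) && member[r2, c2]) {
      gi <- q[pixels[t, 1], pixels[t, 2]] + 1L
      gj <- q[r2, c2] + 1L
      counts[gi, gj] <- counts[gi, gj] + 1
      counts[gj, gi] <- counts[gj, gi] + 1
    }
  }
  if (sum(counts) == 0) return(NULL)
  P <- counts / sum(counts)
  ii <- matrix(0:(levels - 1L), levels, levels); jj <- t(ii)
  c(contrast = sum(P * (ii - jj)^2), dissimilarity = sum(P * abs(ii - jj)),
    asm = sum(P^2), energy = sqrt(sum(P^2)))
}

# disk mask fixture
disk_mask <- function(dim, center, radius_px) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  m <- matrix(0L, dim[1], dim[2])
  m[(rows - center[1])^2 + (cols - center[2])^2 <= radius_px^2] <- 1L
  m
}

# star-convex portal mask with optional Gaussian bumps; radii in px
polar_mask <- function(dim, center, R_px, bump_theta = numeric(0),
                       bump_sigma = numeric(0), bump_h_px = numeric(0),
                       n_grid = 1440L) {
  theta <- seq(0, 2 * pi, length.out = n_grid + 1L)[-(n_grid + 1L)]
  r <- rep(R_px, n_grid)
  for (j in seq_along(bump_theta)) {
    d <- ((theta - bump_theta[j] + pi) %% (2 * pi)) - pi
    r <- r + bump_h_px[j] * exp(-0.5 * (d / bump_sigma[j])^2)
  }
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  th <- atan2(-(rows - center[1]), cols - center[2])
  pos <- (th %% (2 * pi)) / (2 * pi) * n_grid
  i0 <- (as.integer(floor(pos)) %% n_grid) + 1L
  i1 <- (i0 %% n_grid) + 1L
  fr <- pos - floor(pos)
  rb <- r[i0] * (1 - fr) + r[i1] * fr
  m <- matrix(0L, dim[1], dim[2])
  m[(rows - center[1])^2 + (cols - center[2])^2 <= rb^2] <- 1L
  m
}
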