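# Shared oracles and small fixtures for the test suite.

# Exhaustive O(n^3) convex-hull area oracle: a point is a hull vertex iff
# it lies strictly inside no triangle of other points; vertices are then
# ordered by angle around the centroid and the shoelace formula applied.
brute_hull_area <- function(points) {
  pts <- unique(points)
  n <- nrow(pts)
  if (n < 3) return(0)
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 >= -1e-12 && s2 >= -1e-12 && s3 >= -1e-12) ||
      (s1 <= 1e-12 && s2 <= 1e-12 && s3 <= 1e-12)
  }
  is_vertex <- rep(TRUE, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    combos <- utils::combn(others, 3)
    for (cidx in seq_len(ncol(combos))) {
      tri <- combos[, cidx]
      if (in_triangle(pts[i, ], pts[tri[1], ], pts[tri[2], ], pts[tri[3], ])) {
        # interior unless it is itself one of the triangle's corners
        if (!any(vapply(tri, function(j)
          all(abs(pts[j, ] - pts[i, ]) < 1e-12), logical(1)))) {
          is_vertex[i] <- FALSE
          break
        }
      }
    }
  }
  v <- pts[is_vertex, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]; m <- nrow(v)
  abs(0.5 * sum(x * y[c(2:m, 1)] - x[c(2:m, 1)] * y))
}

# Grid-integration oracle for the intersection area of two 1-SD ellipses.
grid_overlap_area <- function(ellipse_a, ellipse_b, n_grid = 500) {
  inside <- function(e, x, y) {
    A <- solve(e$cov)
    dx <- x - e$centroid[1]; dy <- y - e$centroid[2]
    A[1, 1] * dx^2 + 2 * A[1, 2] * dx * dy + A[2, 2] * dy^2 <= 1
  }
  lim <- function(e) {
    r <- sqrt(max(eigen(e$cov, symmetric = TRUE)$values))
    c(e$centroid - r, e$centroid + r)
  }
  la <- lim(ellipse_a); lb <- lim(ellipse_b)
  x0 <- max(la[1], lb[1]); y0 <- max(la[2], lb[2])
  x1 <- min(la[3], lb[3]); y1 <- min(la[4], lb[4])
  if (x1 <= x0 || y1 <= y0) return(0)
  xs <- seq(x0, x1, length.out = n_grid)
  ys <- seq(y0, y1, length.out = n_grid)
  cell <- diff(xs[1:2]) * diff(ys[1:2])
  X <- rep(xs, times = n_grid)
  Y <- rep(ys, each = n_grid)
  sum(inside(ellipse_a, X, Y) & inside(ellipse_b, X, Y)) * cell
}

# Minimal valid sample table: one source taxon plus consumer taxa with
# given per-replicate d15N/d13C values at one site.
toy_samples <- function(site = "reefA",
                        consumers = list(baseline_clam = cbind(d13C = c(-16, -16.2, -15.8),
                                                               d15N = c(4, 4, 4))),
                        categories = NULL) {
  rows <- list(data.frame(
    sample_id = paste0(site, "_POM_", 1:3), site = site, taxon = "POM",
    role = "source", trophic_category = "none",
    d13C = c(-21, -20.5, -21.5), d15N = c(1.4, 1.6, 1.5),
    stringsAsFactors = FALSE))
  for (tx in names(consumers)) {
    m <- consumers[[tx]]
    cat_ <- if (!is.null(categories) && tx %in% names(categories))
      categories[[tx]] else "omnivore"
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = paste0(site, "_", tx, "_", seq_len(nrow(m))),
      site = site, taxon = tx, role = "consumer", trophic_category = cat_,
      d13C = m[, "d13C"], d15N = m[, "d15N"], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
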