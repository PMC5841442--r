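#' @title Isotopic-niche geometry
#' @description
#' Metrics describing the spread of a group of points in delta-13C /
#' delta-15N biplot space: the nitrogen and carbon ranges (NR, CR), the
#' convex-hull total area (TA), the standard ellipse area (SEA, the 1-SD
#' bivariate ellipse containing about 40% of the data for a bivariate
#' normal), its small-sample correction SEAc = SEA (n-1)/(n-2), a
#' Bayesian posterior for SEA, and between-group ellipse overlaps.
#' Point sets are two-column matrices or data frames with delta-13C in
#' the first column and delta-15N in the second (columns `d13C`, `d15N`
#' are picked up by name when present).
#' @name niche_geometry
NULL

as_points <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("d13C", "d15N") %in% names(points)))
      points <- points[c("d13C", "d15N")]
    points <- as.matrix(points)
  }
  if (!is.matrix(points) || ncol(points) != 2 || !is.numeric(points))
    stop_domain("points must be a numeric two-column matrix (d13C, d15N)")
  unname(points)
}

#' Isotopic ranges (NR, CR)
#'
#' NR is the delta-15N range (max - min), a proxy for food-chain length;
#' CR is the delta-13C range, a proxy for basal carbon-source diversity.
#'
#' @param points two-column matrix/data frame (d13C, d15N); >= 2 rows.
#' @return named vector `c(NR =, CR =)` in permil.
#' @export
layman_ranges <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 2) stop_domain(">= 2 points are required for NR/CR")
  c(NR = diff(range(points[, 2])), CR = diff(range(points[, 1])))
}

# shoelace signed area of a polygon given as an n x 2 matrix
polygon_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  0.5 * sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
}

#' Convex-hull total area (TA)
#'
#' Area of the polygon through the most extreme points of the group
#' (the convex hull), via hull construction and the shoelace formula.
#' Collinear input gives 0.
#'
#' @param points two-column matrix/data frame; >= 3 rows.
#' @return area in squared permil.
#' @export
convex_hull_area <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 3) stop_domain(">= 3 points are required for a hull area")
  h <- grDevices::chull(points)
  if (length(h) < 3) return(0)
  abs(polygon_area(points[h, , drop = FALSE]))
}

#' Standard ellipse of a bivariate point set
#'
#' The 1-SD ellipse of the sample covariance (n - 1 denominator):
#' `SEA = pi * sqrt(lambda1 * lambda2)` over the covariance eigenvalues,
#' i.e. `pi * sqrt(det(cov))`. For a bivariate normal this ellipse
#' contains `1 - exp(-1/2)` (about 39.3%) of the probability mass.
#'
#' @param points two-column matrix/data frame; >= 3 non-collinear rows.
#' @return list `centroid`, `cov`, `SEA`.
#' @export
standard_ellipse <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 3) stop_domain(">= 3 points are required for an ellipse")
  S <- stats::cov(points)
  d <- det(S)
  if (!is.finite(d) || d <= .Machine$double.eps * max(diag(S))^2)
    stop_domain("degenerate ellipse: singular covariance (collinear points)")
  list(centroid = colMeans(points), cov = S, SEA = pi * sqrt(d))
}

#' Small-sample corrected standard ellipse area
#'
#' `SEAc = SEA * (n - 1) / (n - 2)`; the correction removes the downward
#' bias of the sample ellipse area for small groups.
#'
#' @param sea standard ellipse area.
#' @param n number of points behind it (>= 3).
#' @return SEAc.
#' @export
seac <- function(sea, n) {
  if (n <= 2) stop_domain("SEAc undefined for n <= 2")
  sea * (n - 1) / (n - 2)
}

#' Bayesian posterior of the standard ellipse area
#'
#' Conjugate normal--inverse-Wishart posterior for the covariance with a
#' vague prior (by default: inverse-Wishart with `nu0 = 3` degrees of
#' freedom — dimension + 1 — and scale `0.01 * I`; prior mean weight
#' `kappa0 = 1e-3` at the origin). Each posterior covariance draw is
#' mapped to its ellipse area `pi * sqrt(det(Sigma))`.
#'
#' @param points two-column matrix/data frame; >= 3 non-collinear rows.
#' @param n_draws number of posterior draws (>= 1).
#' @param seed RNG seed; draws are reproducible for a given seed.
#' @param nu0,psi0,kappa0,mu0 prior degrees of freedom, scale matrix,
#'   mean weight, and mean.
#' @return numeric vector of SEA draws (squared permil).
#' @export
bayesian_sea <- function(points, n_draws = 10000, seed = NULL,
                         nu0 = 3, psi0 = diag(2) * 0.01,
                         kappa0 = 1e-3, mu0 = c(0, 0)) {
  points <- as_points(points)
  standard_ellipse(points) # validates non-degeneracy
  if (n_draws < 1) stop_domain("n_draws must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(points)
  xbar <- colMeans(points)
  S <- crossprod(sweep(points, 2, xbar))
  dev <- xbar - mu0
  psi_n <- psi0 + S + (kappa0 * n / (kappa0 + n)) * tcrossprod(dev)
  nu_n <- nu0 + n
  # Sigma ~ IW(nu_n, psi_n): draw W ~ Wishart(nu_n, psi_n^-1), Sigma = W^-1,
  # so det(Sigma) = 1/det(W) and SEA = pi / sqrt(det(W)).
  W <- stats::rWishart(n_draws, nu_n, solve(psi_n))
  detW <- W[1, 1, ] * W[2, 2, ] - W[1, 2, ] * W[2, 1, ]
  pi / sqrt(detW)
}

# polygonise a covariance ellipse (1-SD boundary), counter-clockwise
ellipse_polygon <- function(centroid, cov, n_vertices = 512) {
  e <- eigen(cov, symmetric = TRUE)
  if (any(e$values <= 0)) stop_domain("degenerate ellipse: singular covariance")
  M <- e$vectors %*% diag(sqrt(e$values))
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  xy <- cbind(cos(t), sin(t)) %*% t(M)
  xy <- sweep(xy, 2, centroid, "+")
  if (polygon_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  xy
}

# Sutherland-Hodgman clipping of a polygon by a convex CCW clip polygon
clip_convex <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (is.null(out) || nrow(out) == 0) return(out)
    a <- clip[i, ]; b <- clip[if (i == n) 1 else i + 1, ]
    # inside = left of directed edge a->b
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    m <- nrow(inp)
    s <- (b[1] - a[1]) * (inp[, 2] - a[2]) - (b[2] - a[2]) * (inp[, 1] - a[1])
    res <- matrix(numeric(0), ncol = 2)
    for (j in seq_len(m)) {
      k <- if (j == m) 1 else j + 1
      p <- inp[j, ]; q <- inp[k, ]
      if (s[j] >= 0) res <- rbind(res, p)
      if ((s[j] >= 0) != (s[k] >= 0)) {
        t <- s[j] / (s[j] - s[k])
        res <- rbind(res, p + t * (q - p))
      }
    }
    out <- res
  }
  out
}

#' Area overlap of two covariance ellipses
#'
#' Intersects the two ellipse boundaries by dense polygonal approximation
#' (default 512 vertices each) and convex polygon clipping; robust and
#' oracle-checkable against grid integration. To compare SEAc ellipses,
#' scale each covariance by its group's `(n - 1)/(n - 2)` first (see
#' `scale` / [seac_ellipse()]).
#'
#' @param ellipse_a,ellipse_b lists with `centroid` and `cov` (as from
#'   [standard_ellipse()]).
#' @param n_vertices boundary vertices per ellipse.
#' @return list `overlap_area`, `area_a`, `area_b`, `pct_of_a`,
#'   `pct_of_b` (raw percentages; round with [round_half_up()] for
#'   integer reporting).
#' @export
ellipse_overlap <- function(ellipse_a, ellipse_b, n_vertices = 512) {
  pa <- ellipse_polygon(ellipse_a$centroid, ellipse_a$cov, n_vertices)
  pb <- ellipse_polygon(ellipse_b$centroid, ellipse_b$cov, n_vertices)
  inter <- clip_convex(pa, pb)
  ov <- if (is.null(inter) || nrow(inter) < 3) 0 else abs(polygon_area(inter))
  aa <- abs(polygon_area(pa)); ab <- abs(polygon_area(pb))
  list(overlap_area = ov, area_a = aa, area_b = ab,
       pct_of_a = 100 * ov / aa, pct_of_b = 100 * ov / ab)
}

#' Scale an ellipse to its SEAc area
#'
#' Multiplies the covariance by `(n - 1)/(n - 2)` so the 1-SD ellipse
#' area equals SEAc; used before between-group overlap comparisons.
#'
#' @param ellipse list with `centroid`, `cov`.
#' @param n group size (>= 3).
#' @return ellipse list with scaled covariance.
#' @export
seac_ellipse <- function(ellipse, n) {
  if (n <= 2) stop_domain("SEAc undefined for n <= 2")
  list(centroid = ellipse$centroid, cov = ellipse$cov * (n - 1) / (n - 2))
}

#' Niche metrics per trophic category and site
#'
#' Computes NR, CR, TA, SEA and SEAc for every (trophic category, site)
#' group of consumers. At the default `species_means` level each point is
#' one taxon's mean (delta-13C, delta-15N), so `n` is a taxon count, not
#' a replicate count; `individuals` uses every replicate as a point.
#'
#' @param samples validated sample table.
#' @param level `"species_means"` or `"individuals"`.
#' @param n_draws if > 0, also attach Bayesian SEA posterior draws.
#' @param seed seed for the Bayesian draws.
#' @return data frame with one row per group: `site, trophic_category,
#'   n, NR, CR, TA, SEA, SEAc` plus list-columns `ellipse` and `sea_b`.
#' @export
category_metrics <- function(samples, level = c("species_means", "individuals"),
                             n_draws = 0, seed = NULL) {
  level <- match.arg(level)
  samples <- validate_samples(samples)
  cons <- samples[samples$role == "consumer", , drop = FALSE]
  groups <- unique(cons[c("site", "trophic_category")])
  groups <- groups[order(groups$site, groups$trophic_category), , drop = FALSE]
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    s <- groups$site[i]; cat_ <- groups$trophic_category[i]
    g <- cons[cons$site == s & cons$trophic_category == cat_, , drop = FALSE]
    pts <- if (level == "species_means") {
      cbind(d13C = tapply(g$d13C, g$taxon, mean),
            d15N = tapply(g$d15N, g$taxon, mean))
    } else as.matrix(g[c("d13C", "d15N")])
    if (nrow(pts) < 3)
      stop_domain("category '", cat_, "' at site '", s,
                  "' has < 3 points at level ", level)
    rng <- layman_ranges(pts)
    ell <- standard_ellipse(pts)
    row <- data.frame(site = s, trophic_category = cat_, n = nrow(pts),
                      NR = unname(rng["NR"]), CR = unname(rng["CR"]),
                      TA = convex_hull_area(pts), SEA = ell$SEA,
                      SEAc = seac(ell$SEA, nrow(pts)),
                      stringsAsFactors = FALSE)
    row$ellipse <- list(ell[c("centroid", "cov")])
    row$sea_b <- list(if (n_draws > 0)
      bayesian_sea(pts, n_draws,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, i))
      else NULL)
    rows[[i]] <- row
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("niche_metrics", "data.frame")
  res
}

#' Between-site SEAc overlap per trophic category
#'
#' For every trophic category present at both sites, scales each site's
#' standard ellipse to its SEAc area and computes the intersection area
#' and the percentage of each site's SEAc it represents (integer
#' percentages use round-half-up).
#'
#' @param metrics result of [category_metrics()] covering two sites.
#' @param n_vertices boundary vertices per ellipse.
#' @return data frame: `trophic_category, site_a, site_b, seac_a, seac_b,
#'   overlap_area, pct_of_a, pct_of_b, pct_of_a_int, pct_of_b_int`.
#' @export
overlap_between_sites <- function(metrics, n_vertices = 512) {
  sites <- sort(unique(metrics$site))
  if (length(sites) != 2) stop_domain("exactly two sites are required")
  cats <- intersect(metrics$trophic_category[metrics$site == sites[1]],
                    metrics$trophic_category[metrics$site == sites[2]])
  rows <- lapply(cats, function(cat_) {
    a <- metrics[metrics$site == sites[1] & metrics$trophic_category == cat_, ]
    b <- metrics[metrics$site == sites[2] & metrics$trophic_category == cat_, ]
    ov <- ellipse_overlap(seac_ellipse(a$ellipse[[1]], a$n),
                          seac_ellipse(b$ellipse[[1]], b$n), n_vertices)
    data.frame(trophic_category = cat_, site_a = sites[1], site_b = sites[2],
               seac_a = a$SEAc, seac_b = b$SEAc,
               overlap_area = ov$overlap_area,
               pct_of_a = ov$pct_of_a, pct_of_b = ov$pct_of_b,
               pct_of_a_int = round_half_up(ov$pct_of_a),
               pct_of_b_int = round_half_up(ov$pct_of_b),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
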