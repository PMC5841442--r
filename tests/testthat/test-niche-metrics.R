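test_that("isotopic ranges and the round-half-up convention are exact", {
  pts <- cbind(d13C = c(-16.31, -13.51, -15.0), d15N = c(8, 12.88, 10))
  r <- layman_ranges(pts)
  expect_equal(unname(r["CR"]), 2.80)
  expect_equal(unname(r["NR"]), 4.88)
  expect_error(layman_ranges(pts[1, , drop = FALSE]), ">= 2")
  expect_identical(round_half_up(c(0.5, 1.5, 2.5, -0.5, 87.5, 46.49)),
                   c(1, 2, 3, -1, 88, 46))
})

test_that("convex hull area matches simple shapes and the exhaustive oracle", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(convex_hull_area(sq), 1)
  # interior points cannot change the hull
  expect_equal(convex_hull_area(rbind(sq, c(0.5, 0.5), c(0.2, 0.7))), 1)
  # collinear input has zero area
  expect_equal(convex_hull_area(cbind(1:5, 2 * (1:5))), 0)
  expect_error(convex_hull_area(sq[1:2, ]), ">= 3")
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(4:12, 1)
    pts <- cbind(stats::rnorm(n), stats::rnorm(n))
    expect_equal(convex_hull_area(pts), brute_hull_area(pts),
                 tolerance = 1e-10)
  }
})

test_that("the standard ellipse is exact on known covariances and invariant", {
  pts <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  e <- standard_ellipse(pts)
  expect_equal(e$centroid, c(0, 0))
  expect_equal(e$cov, diag(c(2 / 3, 2 / 3)), ignore_attr = TRUE)
  expect_equal(e$SEA, pi * 2 / 3)
  expect_equal(seac(e$SEA, 4), e$SEA * 3 / 2)
  expect_error(seac(e$SEA, 2), "n <= 2")
  expect_error(standard_ellipse(cbind(1:5, 2 * (1:5))), "degenerate")
  # rotation and translation invariance of the area
  set.seed(7)
  pts <- cbind(stats::rnorm(40, sd = 2), stats::rnorm(40))
  sea0 <- standard_ellipse(pts)$SEA
  for (theta in c(0.3, 1.1, 2.7)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    moved <- sweep(pts %*% R, 2, c(12.3, -45.6), "+")
    expect_equal(standard_ellipse(moved)$SEA, sea0, tolerance = 1e-9)
  }
  # SEAc equals SEA (n-1)/(n-2) exactly
  expect_identical(seac(sea0, 40), sea0 * 39 / 38)
})

test_that("the Bayesian SEA posterior is seeded and concentrates near SEA", {
  set.seed(11)
  pts <- MASS::mvrnorm(60, c(-15, 8), matrix(c(1.2, 0.3, 0.3, 0.8), 2))
  d1 <- bayesian_sea(pts, 2000, seed = 5)
  d2 <- bayesian_sea(pts, 2000, seed = 5)
  expect_identical(d1, d2)
  expect_true(all(d1 > 0))
  sea <- standard_ellipse(pts)$SEA
  # with n = 60 the posterior median sits close to the sample SEA
  expect_equal(stats::median(d1), sea, tolerance = 0.15)
  expect_error(bayesian_sea(pts, 0), "n_draws")
})

test_that("ellipse overlap matches grid integration and its edge cases", {
  ea <- list(centroid = c(0, 0), cov = matrix(c(2, 0.6, 0.6, 1), 2))
  eb <- list(centroid = c(1.1, 0.4), cov = matrix(c(1, -0.2, -0.2, 1.5), 2))
  ov <- ellipse_overlap(ea, eb)
  expect_equal(ov$area_a, pi * sqrt(det(ea$cov)), tolerance = 1e-3)
  expect_equal(ov$area_b, pi * sqrt(det(eb$cov)), tolerance = 1e-3)
  expect_equal(ov$overlap_area, grid_overlap_area(ea, eb, 800),
               tolerance = 0.005)
  # identical ellipses overlap fully
  self <- ellipse_overlap(ea, ea)
  expect_equal(self$overlap_area, self$area_a, tolerance = 1e-9)
  expect_equal(self$pct_of_a, 100, tolerance = 1e-6)
  # distant ellipses do not overlap at all
  far <- list(centroid = c(50, 50), cov = diag(2))
  expect_equal(ellipse_overlap(ea, far)$overlap_area, 0)
  # one ellipse nested in the other: overlap equals the smaller area
  small <- list(centroid = c(0, 0), cov = 0.05 * diag(2))
  nest <- ellipse_overlap(ea, small)
  expect_equal(nest$overlap_area, nest$area_b, tolerance = 1e-6)
  expect_equal(nest$pct_of_b, 100, tolerance = 1e-4)
})

test_that("category metrics count taxa at the species-means level", {
  mk <- function(site, shift) toy_samples(site, consumers = list(
    baseline_clam = cbind(d13C = c(-16, -16.2, -15.8), d15N = c(4, 4.2, 3.9)),
    h1 = cbind(d13C = c(-15, -15.5) + shift, d15N = c(5, 5.2)),
    h2 = cbind(d13C = c(-14, -14.2) + shift, d15N = c(6, 6.3)),
    h3 = cbind(d13C = c(-13.2, -13.4) + shift, d15N = c(5.4, 5.8)),
    h4 = cbind(d13C = c(-16.5, -16.1) + shift, d15N = c(6.6, 6.2))),
    categories = list(h1 = "herbivore", h2 = "herbivore",
                      h3 = "herbivore", h4 = "herbivore"))
  s <- rbind(mk("reefA", 0), mk("reefB", 1.2))
  # omnivores have a single taxon -> species-means level must refuse
  expect_error(category_metrics(s), "omnivore")
  herb <- s[s$trophic_category != "omnivore" | s$role == "source", ]
  m <- category_metrics(herb, n_draws = 500, seed = 3)
  expect_equal(nrow(m), 2)
  expect_equal(m$n, c(4, 4)) # 4 taxa, not 8 replicates
  a <- m[m$site == "reefA", ]
  means <- cbind(tapply(herb$d13C[herb$site == "reefA" & herb$role == "consumer"],
                        herb$taxon[herb$site == "reefA" & herb$role == "consumer"],
                        mean),
                 tapply(herb$d15N[herb$site == "reefA" & herb$role == "consumer"],
                        herb$taxon[herb$site == "reefA" & herb$role == "consumer"],
                        mean))
  expect_equal(a$SEA, standard_ellipse(means)$SEA)
  expect_equal(a$SEAc, seac(a$SEA, 4))
  expect_equal(length(m$sea_b[[1]]), 500)
  # individuals level uses every replicate
  mi <- category_metrics(herb, level = "individuals")
  expect_equal(mi$n, c(8, 8))
  ov <- overlap_between_sites(m)
  expect_equal(ov$trophic_category, "herbivore")
  expect_equal(ov$pct_of_a_int, round_half_up(ov$pct_of_a))
  expect_true(ov$overlap_area <= min(ov$seac_a, ov$seac_b) + 1e-9)
})
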