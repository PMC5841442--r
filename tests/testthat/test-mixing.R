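three_sources <- function() {
  source_spec(c("POM", "turf_epiphytes", "macroalgae"),
              mean_d13C = c(-21, -17.5, -12), sd_d13C = c(0.6, 0.8, 0.8),
              mean_d15N = c(1.0, 2.85, 1.4), sd_d15N = c(0.25, 0.35, 0.35),
              n = 10)
}

# Simulated consumers with the sample mean and SD pinned to the model's
# true moments, so recovery checks isolate sampler bias from the
# sampling luck of one finite data draw (the likelihood depends on the
# data only through those moments).
simulate_consumers <- function(p, n, sources = three_sources(),
                               tef_ = tef(), seed = 99) {
  set.seed(seed)
  mC <- sum(p * sources$mean_d13C) + tef_$mean["d13C"]
  mN <- sum(p * sources$mean_d15N) + tef_$mean["d15N"]
  vC <- sum(p^2 * (sources$sd_d13C^2 + tef_$sd["d13C"]^2))
  vN <- sum(p^2 * (sources$sd_d15N^2 + tef_$sd["d15N"]^2))
  y <- cbind(d13C = stats::rnorm(n), d15N = stats::rnorm(n))
  y <- scale(y) # exact zero mean, unit SD
  cbind(d13C = y[, 1] * sqrt(vC) + mC, d15N = y[, 2] * sqrt(vN) + mN)
}

test_that("the sampler recovers known proportions and is seed-deterministic", {
  p_true <- c(0.6, 0.3, 0.1)
  y <- simulate_consumers(p_true, 30)
  prob <- mixing_problem(y, three_sources())
  fit <- fit_mixing(prob, iterations = 30000, burnin = 6000, thin = 6,
                    seed = 123)
  est <- colMeans(fit$p)
  expect_lt(max(abs(est - p_true)), 0.10)
  expect_true(all(abs(rowSums(fit$p) - 1) < 1e-12))
  expect_identical(colnames(fit$p),
                   c("POM", "turf_epiphytes", "macroalgae"))
  fit2 <- fit_mixing(prob, iterations = 30000, burnin = 6000, thin = 6,
                     seed = 123)
  expect_identical(fit$p, fit2$p)
  expect_identical(fit$sigma, fit2$sigma)
})

test_that("prior-only marginals approach the uniform 1/K and K = 1 degenerates", {
  prob <- mixing_problem(cbind(-15, 8), three_sources())
  fit <- fit_mixing(prob, iterations = 30000, burnin = 5000, thin = 5,
                    seed = 7, prior_only = TRUE)
  expect_lt(max(abs(colMeans(fit$p) - 1 / 3)), 0.03)
  one <- source_spec("POM", -21, 0.6, 1.0, 0.25)
  fit1 <- fit_mixing(mixing_problem(cbind(-20.6, 4.4), one),
                     iterations = 2000, burnin = 500, thin = 1, seed = 1)
  expect_true(all(fit1$p[, 1] == 1))
})

test_that("posterior summaries are nested credibility intervals", {
  y <- simulate_consumers(c(0.5, 0.3, 0.2), 20, seed = 4)
  fit <- fit_mixing(mixing_problem(y, three_sources()),
                    iterations = 12000, burnin = 2000, thin = 5, seed = 2)
  sm <- summarize_posterior(fit, levels = c(50, 75, 95))
  expect_identical(sm$source, c("POM", "turf_epiphytes", "macroalgae"))
  expect_true(all(sm$lo_95 <= sm$lo_75 & sm$lo_75 <= sm$lo_50))
  expect_true(all(sm$hi_50 <= sm$hi_75 & sm$hi_75 <= sm$hi_95))
  expect_true(all(sm$lo_50 <= sm$mean & sm$mean <= sm$hi_50 |
                    sm$lo_95 <= sm$mean & sm$mean <= sm$hi_95))
  short <- fit
  short$p <- fit$p[1:50, , drop = FALSE]
  expect_error(summarize_posterior(short), "too few")
})

test_that("independent chains mix: Gelman-Rubin below 1.05 on a seeded problem", {
  y <- simulate_consumers(c(0.6, 0.3, 0.1), 30, seed = 21)
  prob <- mixing_problem(y, three_sources())
  chains <- lapply(c(101, 202, 303, 404), function(sd)
    fit_mixing(prob, iterations = 12000, burnin = 3000, thin = 3,
               seed = sd)$p)
  psrf <- gelman_rubin(chains)
  expect_true(all(psrf < 1.05))
  # chains from different posteriors must be flagged as discordant
  other <- fit_mixing(mixing_problem(
    simulate_consumers(c(0.1, 0.2, 0.7), 30, seed = 22), three_sources()),
    iterations = 12000, burnin = 3000, thin = 3, seed = 505)$p
  expect_true(any(gelman_rubin(list(chains[[1]], other)) > 1.2))
  expect_error(gelman_rubin(chains[1]), ">= 2")
})

test_that("per-category fits are site-symmetric on identical data", {
  base <- toy_samples("reefA", consumers = list(
    baseline_clam = cbind(d13C = c(-16, -16.2, -15.8), d15N = c(4, 4.2, 3.9)),
    h1 = cbind(d13C = c(-15, -15.5, -14.6), d15N = c(5, 5.2, 5.4)),
    h2 = cbind(d13C = c(-14, -14.2, -13.8), d15N = c(6, 6.3, 6.1))),
    categories = list(h1 = "herbivore", h2 = "herbivore"))
  twin <- base
  twin$site <- "reefB"
  twin$sample_id <- paste0(twin$sample_id, "_twin")
  s <- rbind(base, twin)
  expect_warning(
    fits <- fit_by_category(s, three_sources(), seed = 17,
                            iterations = 4000, burnin = 1000, thin = 2),
    "skipped")
  # no carnivores anywhere: both sites' carnivore groups are skipped
  expect_setequal(attr(fits, "skipped"),
                  c("reefA|carnivore", "reefB|carnivore"))
  expect_identical(summarize_posterior(fits[["reefA|herbivore"]]),
                   summarize_posterior(fits[["reefB|herbivore"]]))
  expect_identical(summarize_posterior(fits[["reefA|omnivore"]]),
                   summarize_posterior(fits[["reefB|omnivore"]]))
})

test_that("problem construction rejects invalid inputs", {
  expect_error(mixing_problem(cbind(1, 2)[0, , drop = FALSE], three_sources()),
               ">= 1 consumer")
  dup <- three_sources()
  dup$source[2] <- "POM"
  expect_error(mixing_problem(cbind(-15, 8), dup), "unique")
  prob <- mixing_problem(cbind(-15, 8), three_sources())
  expect_error(fit_mixing(prob, iterations = 100, burnin = 200), "chain config")
})
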