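test_that("scenario validation enforces the ground-truth invariants", {
  sc <- default_scenario()
  bad <- sc$consumers
  bad$diet[[1]] <- c(POM = 0.7, turf_epiphytes = 0.7)
  expect_error(reef_scenario(sc$sources, bad, baseline_taxon = "baseline_clam"),
               "simplex")
  bad <- sc$consumers
  bad$tp[bad$taxon == "baseline_clam"] <- 2.4
  expect_error(reef_scenario(sc$sources, bad, baseline_taxon = "baseline_clam"),
               "baseline")
  bad <- sc$consumers
  bad$n_reps[3] <- 2
  expect_error(reef_scenario(sc$sources, bad, baseline_taxon = "baseline_clam"),
               ">= 3")
  expect_error(reef_scenario(sc$sources, sc$consumers,
                             baseline_taxon = "no_such_taxon"), "absent")
})

test_that("generation is seed-deterministic and respects the schema", {
  sc <- default_scenario()
  d1 <- generate_dataset(sc, seed = 31)
  d2 <- generate_dataset(sc, seed = 31)
  d3 <- generate_dataset(sc, seed = 32)
  expect_identical(d1$samples, d2$samples)
  expect_false(identical(d1$samples$d15N, d3$samples$d15N))
  expect_s3_class(d1, "study_dataset")
  s <- validate_samples(d1$samples)
  expect_setequal(unique(s$site), c("coral", "degraded"))
  # 6 sources x 5 reps and 36 consumer taxa per site
  expect_equal(sum(s$role == "source" & s$site == "coral"), 30)
  expect_equal(length(unique(s$taxon[s$role == "consumer"])), 36)
  expect_equal(length(d1$transects), 16)
})

test_that("noise-free additive generation equals the analytic forward model", {
  sc <- default_scenario(noise_free = TRUE)
  cons <- generate_consumers(sc, seed = 1)
  for (i in c(1, 20, 45, 70)) {
    row <- sc$consumers[i, ]
    mo <- isonicheweb:::consumer_moments(sc, row)
    got <- cons[cons$site == row$site & cons$taxon == row$taxon, ]
    expect_equal(got$d13C, rep(mo$mean["d13C"], row$n_reps),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(got$d15N, rep(mo$mean["d15N"], row$n_reps),
                 ignore_attr = TRUE, tolerance = 1e-12)
    # additive mode: (TP - 1) enrichment steps above the diet mixture
    src <- sc$sources[sc$sources$site == row$site, ]
    p <- row$diet[[1]]
    mixN <- sum(p * src$mean_d15N[match(names(p), src$source)])
    expect_equal(unname(mo$mean["d15N"]),
                 mixN + (row$tp - 1) * 3.4, tolerance = 1e-12)
  }
})

test_that("the scaled generator mode is inverted exactly by the TP estimator", {
  sc <- default_scenario(noise_free = TRUE, d15N_mode = "scaled")
  ds <- generate_dataset(sc, seed = 1)
  est <- estimate_species_tp(ds$samples, "baseline_clam")
  truth <- sc$consumers
  for (s in c("coral", "degraded")) {
    e <- est[est$site == s, ]
    tr <- truth[truth$site == s, ]
    m <- match(e$taxon, tr$taxon)
    expect_lt(max(abs(e$tp_mean - tr$tp[m])), 1e-9)
  }
})

test_that("noisy consumer spread matches the propagated variance", {
  sc <- default_scenario()
  row <- sc$consumers[sc$consumers$taxon == "carn_12" &
                        sc$consumers$site == "coral", ]
  mo <- isonicheweb:::consumer_moments(sc, row)
  # empirical SD of the generated replicates over many seeds approaches
  # the propagated SD
  sims <- unlist(lapply(1:60, function(sd_) {
    cons <- generate_consumers(sc, seed = sd_)
    cons$d15N[cons$site == "coral" & cons$taxon == "carn_12"]
  }))
  expect_equal(stats::sd(sims), unname(mo$sd["d15N"]), tolerance = 0.15)
  expect_equal(mean(sims), unname(mo$mean["d15N"]), tolerance = 0.05)
  v_manual <- sum(row$diet[[1]]^2 *
                    (sc$sources$sd_d15N[sc$sources$site == "coral"][
                      match(names(row$diet[[1]]),
                            sc$sources$source[sc$sources$site == "coral"])]^2 +
                       sc$tef$sd["d15N"]^2 * (row$tp - 1))) +
    sc$residual_sd["d15N"]^2
  expect_equal(unname(mo$sd["d15N"]), sqrt(unname(v_manual)))
})

test_that("surveys honour the benthic truth and the rugosity floor", {
  sc <- default_scenario(noise_free = TRUE)
  trs <- generate_survey(sc, seed = 2)
  expect_equal(length(trs), 16)
  rug <- vapply(trs, rugosity, 0)
  expect_true(all(rug >= 1))
  coral_rug <- rug[vapply(trs, `[[`, "", "site") == "coral"]
  expect_equal(unname(coral_rug), rep(1.92, 8))
  # multinomial cover concentrates near the true fractions
  sc2 <- default_scenario()
  trs2 <- generate_survey(sc2, seed = 3)
  coral_trs <- Filter(function(tr) tr$site == "coral", trs2)
  cover <- rowMeans(vapply(coral_trs, function(tr)
    percent_cover(tr, names(sc2$benthic$coral$cover)),
    numeric(5)))
  expect_equal(unname(cover["coral"]), 50, tolerance = 0.15)
  sc_nb <- mixing_scenario()
  expect_error(generate_survey(sc_nb), "benthic")
})

test_that("the mixing companion scenario keeps every consumer one step up", {
  sc <- mixing_scenario()
  expect_true(all(sc$consumers$tp == 2))
  expect_setequal(unique(sc$sources$source),
                  c("POM", "turf_epiphytes", "macroalgae"))
  g <- default_source_grouping()
  expect_setequal(unique(unname(g)),
                  c("POM", "turf_epiphytes", "macroalgae"))
  expect_equal(sum(unname(g) == "macroalgae"), 4)
})
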