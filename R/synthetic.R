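#' @title Synthetic two-reef scenario
#' @description
#' A scenario holds the ground truth for a simulated two-site study:
#' per-site basal-source isotope distributions, per-consumer-taxon true
#' trophic positions and diet (source-proportion) vectors, trophic
#' enrichment factors, residual SDs, benthic-cover and rugosity truths,
#' and an RNG seed. The default emulates the design the analysis is
#' meant for: a coral-dominated site with a narrow basal delta-13C
#' spread whose consumers are fuelled mainly by turf + epiphytes, and a
#' degraded macroalgal site with a wide delta-13C spread whose
#' carnivores lean on particulate organic matter (POM), with a
#' designated baseline bivalve at trophic position 2.
#' @name reef_scenario
NULL

#' Construct and validate a reef scenario
#'
#' @param sources data frame: `site, source, mean_d13C, sd_d13C,
#'   mean_d15N, sd_d15N` (true source distributions per site).
#' @param consumers data frame: `site, taxon, trophic_category, tp,
#'   n_reps` plus a list-column `diet` of named proportion vectors over
#'   that site's sources.
#' @param tef [tef()] object.
#' @param residual_sd named `c(d13C =, d15N =)` residual SDs (permil).
#' @param baseline_taxon taxon generated at TP 2 anchoring estimation.
#' @param benthic per site: list with `cover` (named simplex of true
#'   cover fractions), `rugosity` (true index >= 1), `rugosity_sdlog`
#'   (lognormal chain-noise SD), `n_transects`, `points_per_transect`,
#'   `linear_length`.
#' @param d15N_mode `"additive"`: consumer delta-15N sits `(TP - 1)`
#'   TEF steps above its source mixture; `"scaled"`: delta-15N follows
#'   the saturating trophic-position curve anchored at the baseline
#'   taxon, so the scaled estimator inverts the generator exactly.
#' @param params scaling constants used by `"scaled"` mode.
#' @param n_source_reps replicates generated per source per site.
#' @param seed default RNG seed for the generators.
#' @return object of class `"reef_scenario"`.
#' @export
reef_scenario <- function(sources, consumers, tef = isonicheweb::tef(),
                          residual_sd = c(d13C = 0.3, d15N = 0.3),
                          baseline_taxon, benthic = NULL,
                          d15N_mode = c("additive", "scaled"),
                          params = scaling_constants(),
                          n_source_reps = 5, seed = 1) {
  d15N_mode <- match.arg(d15N_mode)
  if (any(consumers$n_reps < 3))
    stop_domain("replicate counts must be >= 3")
  for (i in seq_len(nrow(consumers))) {
    p <- consumers$diet[[i]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
      stop_domain("diet of ", consumers$taxon[i],
                  " is not on the simplex (must sum to 1)")
    site_src <- sources$source[sources$site == consumers$site[i]]
    if (!all(names(p) %in% site_src))
      stop_domain("diet of ", consumers$taxon[i],
                  " references unknown sources")
  }
  base_rows <- consumers[consumers$taxon == baseline_taxon, , drop = FALSE]
  if (nrow(base_rows) == 0)
    stop_domain("baseline taxon absent from consumers")
  if (any(base_rows$tp != 2))
    stop_domain("true TP of the baseline taxon must be 2")
  if (!is.null(benthic)) {
    for (s in names(benthic)) {
      bc <- benthic[[s]]
      if (abs(sum(bc$cover) - 1) > 1e-9 || any(bc$cover < 0))
        stop_domain("cover fractions at ", s, " are not on the simplex")
      if (bc$rugosity < 1) stop_domain("true rugosity must be >= 1")
    }
  }
  structure(list(sources = sources, consumers = consumers, tef = tef,
                 residual_sd = residual_sd, baseline_taxon = baseline_taxon,
                 benthic = benthic, d15N_mode = d15N_mode, params = params,
                 n_source_reps = n_source_reps, seed = seed),
            class = "reef_scenario")
}

# deterministic diet profiles: category profile tilted per taxon
tilt_diet <- function(profile, tilt) {
  p <- profile * exp(tilt)
  p / sum(p)
}

#' Default packaged two-reef scenario
#'
#' Two sites sharing 36 consumer taxa (12 per trophic category,
#' including the baseline clam among omnivores) over 6 basal sources.
#' The `"coral"` site compresses the source delta-13C spread and feeds
#' all categories mainly on turf + epiphytes (herbivores ~60%,
#' omnivores ~80%, carnivores ~85% on average); the `"degraded"` site
#' widens the delta-13C spread, feeds herbivores and omnivores evenly,
#' and weights carnivores toward POM (~70%). True trophic positions run
#' from 2.0 (herbivores, baseline) to 4.0 (top carnivores).
#'
#' @param seed scenario RNG seed.
#' @param noise_free zero out all SDs (source, TEF, residual, survey
#'   noise) to obtain the deterministic forward model.
#' @param d15N_mode passed to [reef_scenario()].
#' @return a [reef_scenario()].
#' @export
default_scenario <- function(seed = 1, noise_free = FALSE,
                             d15N_mode = "additive") {
  src_names <- c("POM", "turf_epiphytes", "Dictyota", "Caulerpa",
                 "Halimeda", "Amphiroa")
  sd0 <- function(x) if (noise_free) 0 * x else x
  mk_sources <- function(site, enrich) {
    # POM (water column) and algal turf keep the same signature at both
    # sites; the erect macroalgae are more d13C-enriched on the degraded
    # reef, widening its basal carbon range
    d13C <- c(-21, -17.5, -14.5, -13, -11.5, -8.8) +
      c(0, 0, enrich, enrich, enrich, enrich)
    data.frame(site = site, source = src_names,
               mean_d13C = d13C,
               sd_d13C = sd0(c(0.8, 1.0, 0.8, 0.8, 0.8, 0.6)),
               mean_d15N = c(1.5, 2.0, 1.8, 2.2, 1.6, 2.5),
               sd_d15N = sd0(rep(0.4, 6)), stringsAsFactors = FALSE)
  }
  sources <- rbind(mk_sources("coral", 0), mk_sources("degraded", 1.5))
  profiles <- list(
    coral = list(
      herbivore = c(POM = 0.04, turf_epiphytes = 0.60, Dictyota = 0.12,
                    Caulerpa = 0.10, Halimeda = 0.08, Amphiroa = 0.06),
      omnivore = c(POM = 0.05, turf_epiphytes = 0.80, Dictyota = 0.05,
                   Caulerpa = 0.04, Halimeda = 0.03, Amphiroa = 0.03),
      carnivore = c(POM = 0.05, turf_epiphytes = 0.85, Dictyota = 0.03,
                    Caulerpa = 0.03, Halimeda = 0.02, Amphiroa = 0.02)),
    degraded = list(
      herbivore = c(POM = 0.15, turf_epiphytes = 0.20, Dictyota = 0.20,
                    Caulerpa = 0.15, Halimeda = 0.15, Amphiroa = 0.15),
      omnivore = c(POM = 0.20, turf_epiphytes = 0.20, Dictyota = 0.15,
                   Caulerpa = 0.15, Halimeda = 0.15, Amphiroa = 0.15),
      carnivore = c(POM = 0.70, turf_epiphytes = 0.20, Dictyota = 0.03,
                    Caulerpa = 0.03, Halimeda = 0.02, Amphiroa = 0.02)))
  tp_of <- list(herbivore = seq(2.0, 2.6, length.out = 12),
                omnivore = seq(2.2, 3.2, length.out = 12),
                carnivore = seq(2.9, 4.0, length.out = 12))
  rows <- list()
  for (site in c("coral", "degraded")) {
    for (cat_ in names(tp_of)) {
      for (i in 1:12) {
        taxon <- sprintf("%s_%02d", substr(cat_, 1, 4), i)
        tp <- tp_of[[cat_]][i]
        if (cat_ == "omnivore" && i == 1) { taxon <- "baseline_clam"; tp <- 2 }
        # fixed per-taxon diet tilt, identical at both sites (species keep
        # their dietary identity across reefs); herbivores and omnivores
        # are more specialised than carnivores. The degraded site's wider
        # mixture range then emerges from its wider source spacing and
        # flatter base diets, not from site-specific preferences.
        tilt_scale <- c(herbivore = 1.0, omnivore = 1.6, carnivore = 0.6)[cat_]
        tilt <- tilt_scale * sin(seq_len(6) * i)
        rows[[length(rows) + 1]] <- data.frame(
          site = site, taxon = taxon, trophic_category = cat_,
          tp = tp, n_reps = 3 + (i %% 3), stringsAsFactors = FALSE)
        rows[[length(rows)]]$diet <-
          list(tilt_diet(profiles[[site]][[cat_]], tilt))
      }
    }
  }
  consumers <- do.call(rbind, rows)
  benthic <- list(
    coral = list(cover = c(coral = 0.50, turf = 0.24, fleshy_macroalgae = 0.12,
                           calcareous_macroalgae = 0.06, other = 0.08),
                 rugosity = 1.92,
                 rugosity_sdlog = if (noise_free) 0 else 0.08,
                 n_transects = 8, points_per_transect = 100,
                 linear_length = 10),
    degraded = list(cover = c(coral = 0.07, turf = 0.23, fleshy_macroalgae = 0.40,
                              calcareous_macroalgae = 0.22, other = 0.08),
                    rugosity = 1.42,
                    rugosity_sdlog = if (noise_free) 0 else 0.08,
                    n_transects = 8, points_per_transect = 100,
                    linear_length = 10))
  reef_scenario(
    sources = sources, consumers = consumers,
    tef = if (noise_free) tef(sd_d13C = 0, sd_d15N = 0) else tef(),
    residual_sd = if (noise_free) c(d13C = 0, d15N = 0)
                  else c(d13C = 0.3, d15N = 0.3),
    baseline_taxon = "baseline_clam", benthic = benthic,
    d15N_mode = d15N_mode, seed = seed)
}

#' Two-reef scenario tailored to source-contribution estimation
#'
#' A companion to [default_scenario()] for exercising the mixing model:
#' three pooled end members per site (POM, turf + epiphytes,
#' macroalgae) with well-separated signatures on both isotopes, and
#' consumer categories generated exactly one trophic enrichment step
#' above their assimilated source mixture (every true TP is 2) — the
#' convention the single-step mixing model assumes, so the true
#' proportions are recoverable. Diets mirror the intended study
#' contrast: at the `"coral"` site turf + epiphytes contribute about
#' 60% / 80% / 85% for herbivores / omnivores / carnivores; at the
#' `"degraded"` site herbivores and omnivores feed evenly while
#' carnivores draw ~70% from POM.
#'
#' @param seed scenario RNG seed.
#' @param noise_free zero all SDs for the deterministic forward model.
#' @param n_taxa consumer taxa per category per site.
#' @return a [reef_scenario()].
#' @export
mixing_scenario <- function(seed = 1, noise_free = FALSE, n_taxa = 12) {
  src_names <- c("POM", "turf_epiphytes", "macroalgae")
  sd0 <- function(x) if (noise_free) 0 * x else x
  # turf + epiphytes sits well off the POM--macroalgae axis in d15N
  # (detritus-enriched turf), keeping the mixing polygon well conditioned
  mk <- function(site) data.frame(
    site = site, source = src_names,
    mean_d13C = c(-21, -17.5, -12),
    sd_d13C = sd0(c(0.6, 0.8, 0.8)),
    mean_d15N = c(1.0, 2.85, 1.4),
    sd_d15N = sd0(c(0.25, 0.35, 0.35)), stringsAsFactors = FALSE)
  diets <- list(
    coral = list(
      herbivore = c(POM = 0.11, turf_epiphytes = 0.60, macroalgae = 0.29),
      omnivore = c(POM = 0.10, turf_epiphytes = 0.80, macroalgae = 0.10),
      carnivore = c(POM = 0.07, turf_epiphytes = 0.85, macroalgae = 0.08)),
    degraded = list(
      herbivore = c(POM = 1, turf_epiphytes = 1, macroalgae = 1) / 3,
      omnivore = c(POM = 1, turf_epiphytes = 1, macroalgae = 1) / 3,
      carnivore = c(POM = 0.70, turf_epiphytes = 0.20, macroalgae = 0.10)))
  rows <- list()
  for (site in c("coral", "degraded")) {
    for (cat_ in names(diets[[site]])) {
      for (i in seq_len(n_taxa)) {
        taxon <- sprintf("mix_%s_%02d", substr(cat_, 1, 4), i)
        if (cat_ == "omnivore" && i == 1) taxon <- "baseline_clam"
        rows[[length(rows) + 1]] <- data.frame(
          site = site, taxon = taxon, trophic_category = cat_,
          tp = 2, n_reps = 4, stringsAsFactors = FALSE)
        rows[[length(rows)]]$diet <- list(diets[[site]][[cat_]])
      }
    }
  }
  reef_scenario(
    sources = rbind(mk("coral"), mk("degraded")),
    consumers = do.call(rbind, rows),
    tef = if (noise_free) tef(sd_d13C = 0, sd_d15N = 0) else tef(),
    residual_sd = if (noise_free) c(d13C = 0, d15N = 0)
                  else c(d13C = 0.2, d15N = 0.2),
    baseline_taxon = "baseline_clam", seed = seed)
}

#' Default pooling of synthetic source taxa into mixing end members
#'
#' Pools the four macroalgal taxa of [default_scenario()] into one
#' `"macroalgae"` end member, leaving POM and turf + epiphytes as their
#' own end members — the three-source structure the mixing model is
#' typically run with.
#'
#' @return named character vector suitable for [pool_sources()].
#' @export
default_source_grouping <- function() {
  c(POM = "POM", turf_epiphytes = "turf_epiphytes",
    Dictyota = "macroalgae", Caulerpa = "macroalgae",
    Halimeda = "macroalgae", Amphiroa = "macroalgae")
}

scenario_source_row <- function(scenario, site, source) {
  s <- scenario$sources
  s[s$site == site & s$source == source, , drop = FALSE]
}

# expected (noise-free) consumer delta values and the noise SDs
consumer_moments <- function(scenario, row) {
  src <- scenario$sources[scenario$sources$site == row$site, , drop = FALSE]
  p <- row$diet[[1]]
  src <- src[match(names(p), src$source), , drop = FALSE]
  lam <- scenario$tef$mean; tau <- scenario$tef$sd
  tp <- row$tp
  mixC <- sum(p * src$mean_d13C)
  mixN <- sum(p * src$mean_d15N)
  mC <- mixC + (tp - 1) * lam["d13C"]
  if (scenario$d15N_mode == "additive") {
    mN <- mixN + (tp - 1) * lam["d15N"]
  } else {
    # anchor at the baseline taxon's expected value (its mixture + one step),
    # then follow the saturating curve so the scaled estimator inverts exactly
    base_row <- scenario$consumers[
      scenario$consumers$taxon == scenario$baseline_taxon &
        scenario$consumers$site == row$site, , drop = FALSE][1, ]
    pb <- base_row$diet[[1]]
    srcb <- scenario$sources[scenario$sources$site == row$site, , drop = FALSE]
    srcb <- srcb[match(names(pb), srcb$source), , drop = FALSE]
    baseN <- sum(pb * srcb$mean_d15N) + lam["d15N"]
    pr <- scenario$params
    mN <- pr$d15N_lim - (pr$d15N_lim - baseN) *
      exp(-pr$k * (tp - pr$tp_base))
  }
  vC <- sum(p^2 * (src$sd_d13C^2 + tau["d13C"]^2 * (tp - 1))) +
    scenario$residual_sd["d13C"]^2
  vN <- sum(p^2 * (src$sd_d15N^2 + tau["d15N"]^2 * (tp - 1))) +
    scenario$residual_sd["d15N"]^2
  list(mean = c(d13C = unname(mC), d15N = unname(mN)),
       sd = c(d13C = sqrt(unname(vC)), d15N = sqrt(unname(vN))))
}

#' Generate basal-source samples from a scenario
#'
#' Per site and source, `n_source_reps` replicate delta values are drawn
#' from the scenario's normal source distributions. Seeded and
#' reproducible.
#'
#' @param scenario a [reef_scenario()].
#' @param seed overrides the scenario seed.
#' @return validated [isotope_samples] data frame of `role = "source"`
#'   rows.
#' @export
generate_sources <- function(scenario, seed = scenario$seed) {
  if (scenario$n_source_reps <= 0)
    stop_domain("n_source_reps must be positive")
  set.seed(derive_seed(seed, 1))
  rows <- lapply(seq_len(nrow(scenario$sources)), function(i) {
    r <- scenario$sources[i, ]
    k <- scenario$n_source_reps
    data.frame(
      sample_id = sprintf("%s_%s_%02d", r$site, r$source, seq_len(k)),
      site = r$site, taxon = r$source, role = "source",
      trophic_category = "none",
      d13C = stats::rnorm(k, r$mean_d13C, r$sd_d13C),
      d15N = stats::rnorm(k, r$mean_d15N, r$sd_d15N),
      stringsAsFactors = FALSE)
  })
  validate_samples(do.call(rbind, rows))
}

#' Generate consumer samples from a scenario
#'
#' Each consumer replicate's expected value is the diet-weighted source
#' mixture plus `(TP - 1)` TEF steps for delta-13C, and either the same
#' additive form or the saturating trophic-position curve for delta-15N
#' (see [reef_scenario()]'s `d15N_mode`). Noise is independent normal
#' per isotope with variance
#' `sum_k p_k^2 (omega_k^2 + tau^2 (TP - 1)) + residual^2`.
#'
#' @param scenario a [reef_scenario()].
#' @param seed overrides the scenario seed.
#' @return validated [isotope_samples] data frame of consumer rows.
#' @export
generate_consumers <- function(scenario, seed = scenario$seed) {
  set.seed(derive_seed(seed, 2))
  rows <- lapply(seq_len(nrow(scenario$consumers)), function(i) {
    r <- scenario$consumers[i, ]
    mo <- consumer_moments(scenario, r)
    k <- r$n_reps
    data.frame(
      sample_id = sprintf("%s_%s_%02d", r$site, r$taxon, seq_len(k)),
      site = r$site, taxon = r$taxon, role = "consumer",
      trophic_category = r$trophic_category,
      d13C = stats::rnorm(k, mo$mean["d13C"], mo$sd["d13C"]),
      d15N = stats::rnorm(k, mo$mean["d15N"], mo$sd["d15N"]),
      stringsAsFactors = FALSE)
  })
  validate_samples(do.call(rbind, rows))
}

#' Generate benthic survey transects from a scenario
#'
#' Point components are multinomial draws from the site's true cover
#' fractions; chain lengths are `linear_length * rugosity * lognormal
#' noise`, floored at the linear length so the rugosity invariant holds.
#'
#' @param scenario a [reef_scenario()] with a `benthic` block.
#' @param seed overrides the scenario seed.
#' @return list of [survey_transect] objects.
#' @export
generate_survey <- function(scenario, seed = scenario$seed) {
  if (is.null(scenario$benthic)) stop_domain("scenario has no benthic block")
  set.seed(derive_seed(seed, 3))
  out <- list()
  for (s in names(scenario$benthic)) {
    bc <- scenario$benthic[[s]]
    for (t in seq_len(bc$n_transects)) {
      comps <- sample(names(bc$cover), bc$points_per_transect,
                      replace = TRUE, prob = bc$cover)
      noise <- if (bc$rugosity_sdlog > 0)
        exp(stats::rnorm(1, 0, bc$rugosity_sdlog)) else 1
      chain <- bc$linear_length * max(1, bc$rugosity * noise)
      out[[length(out) + 1]] <- survey_transect(
        s, sprintf("%s_T%02d", s, t), comps, chain, bc$linear_length)
    }
  }
  out
}

#' Generate a complete study dataset from a scenario
#'
#' @param scenario a [reef_scenario()].
#' @param seed overrides the scenario seed.
#' @return a [study_dataset()] with sources, consumers and (when the
#'   scenario has a benthic block) survey transects.
#' @export
generate_dataset <- function(scenario, seed = scenario$seed) {
  samples <- rbind(generate_sources(scenario, seed),
                   generate_consumers(scenario, seed))
  transects <- if (is.null(scenario$benthic)) list()
               else generate_survey(scenario, seed)
  study_dataset(samples, scenario$baseline_taxon, transects)
}
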