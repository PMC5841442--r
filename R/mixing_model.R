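#' @title Bayesian stable-isotope mixing model
#' @description
#' Estimates the dietary proportions of basal carbon sources from
#' consumer delta-13C / delta-15N values, in the SIAR family. For source
#' k with per-isotope means `mu_jk` and SDs `omega_jk`, trophic
#' enrichment factor means `lambda_j` and SDs `tau_j`, proportions `p`
#' on the simplex and residual SDs `sigma_j`, each consumer observation
#' of isotope j is modelled as
#' `Normal( sum_k p_k (mu_jk + lambda_j), sum_k p_k^2 (omega_jk^2 + tau_j^2) + sigma_j^2 )`.
#' The prior is Dirichlet(alpha) on `p` (uniform by default) and
#' half-normal(0, 5 permil) on each residual SD. Sampling is
#' Metropolis-within-Gibbs: a random-walk block update on the additive
#' log-ratio transform of `p` (with the exact Jacobian), then per-isotope
#' updates of `log sigma_j`, with proposal scales adapted during burn-in
#' only.
#' @name mixing_model
NULL

#' Define a mixing problem
#'
#' @param consumers two-column matrix/data frame of consumer
#'   (d13C, d15N) observations; >= 1 row.
#' @param sources [source_spec] data frame with >= 2 rows (a single
#'   source is allowed and yields the degenerate p = 1 posterior).
#' @param tef [tef()] trophic enrichment factors, applied as exactly one
#'   trophic step for every consumer.
#' @param prior_alpha Dirichlet concentration (scalar or length-K).
#' @param residual include the residual error term sigma_j (recommended;
#'   prevents zero-variance degeneracy on sparse groups).
#' @return object of class `"mixing_problem"`.
#' @export
mixing_problem <- function(consumers, sources, tef = isonicheweb::tef(),
                           prior_alpha = 1, residual = TRUE) {
  y <- as_points(consumers)
  if (nrow(y) < 1) stop_domain(">= 1 consumer observation is required")
  if (anyDuplicated(sources$source)) stop_domain("source labels must be unique")
  K <- nrow(sources)
  if (K < 1) stop_domain(">= 1 source is required")
  alpha <- rep_len(prior_alpha, K)
  structure(list(
    y = y, n = nrow(y),
    ybar = colMeans(y),
    ss = colSums(sweep(y, 2, colMeans(y))^2),
    mu = cbind(d13C = sources$mean_d13C, d15N = sources$mean_d15N),
    omega2 = cbind(d13C = sources$sd_d13C^2, d15N = sources$sd_d15N^2),
    lambda = tef$mean, tau2 = tef$sd^2,
    labels = sources$source, K = K, alpha = alpha,
    residual = residual
  ), class = "mixing_problem")
}

softmax_alr <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0)))
  e / sum(e)
}

#' Fit the mixing model by MCMC
#'
#' @param problem a [mixing_problem()].
#' @param iterations total MCMC iterations (default 1e5).
#' @param burnin iterations discarded (and used for proposal adaptation).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed RNG seed for reproducibility.
#' @param prior_only if TRUE the likelihood is switched off and the
#'   sampler explores the prior (marginal proportion means tend to 1/K).
#' @param sigma_prior_sd scale of the half-normal prior on residual SDs
#'   (permil).
#' @return object of class `"mixing_posterior"`: `p` (retained draws x K
#'   matrix, columns named by source), `sigma` (draws x 2), `acceptance`
#'   (post-adaptation rates for the proportion block and each sigma),
#'   `seed`, `config`. A diagnostics warning is recorded in
#'   `$diagnostics` if a post-adaptation acceptance rate falls outside
#'   (0.05, 0.95).
#' @export
fit_mixing <- function(problem, iterations = 100000, burnin = 10000,
                       thin = 10, seed = NULL, prior_only = FALSE,
                       sigma_prior_sd = 5) {
  if (!inherits(problem, "mixing_problem")) stop_domain("not a mixing_problem")
  if (iterations <= burnin || thin < 1 || burnin < 0)
    stop_domain("invalid chain config: need iterations > burnin >= 0, thin >= 1")
  if (!is.null(seed)) set.seed(seed)
  K <- problem$K
  n <- problem$n
  ybar <- problem$ybar; ss <- problem$ss
  mu <- problem$mu; omega2 <- problem$omega2
  lambda <- problem$lambda; tau2 <- problem$tau2
  alpha <- problem$alpha
  use_sigma <- problem$residual
  s2prior <- 2 * sigma_prior_sd^2

  loglik <- function(p, sig2) {
    if (prior_only) return(0)
    m <- drop(crossprod(mu, p)) + lambda
    v <- drop(crossprod(omega2 + rep(tau2, each = K), p^2)) + sig2
    sum(-n / 2 * log(2 * pi * v) - (ss + n * (ybar - m)^2) / (2 * v))
  }
  logpost <- function(z, u) {
    p <- softmax_alr(z)
    sig2 <- if (use_sigma) exp(2 * u) else c(0, 0)
    # Dirichlet prior + alr Jacobian collapse to sum(alpha * log p)
    lp <- sum(alpha * log(p))
    if (use_sigma) lp <- lp + sum(-exp(2 * u) / s2prior + u)
    lp + loglik(p, sig2)
  }

  z <- rep(0, max(K - 1, 0))
  u <- c(0, 0) # log sigma, start at 1 permil
  retained <- floor((iterations - burnin) / thin)
  P <- matrix(NA_real_, retained, K, dimnames = list(NULL, problem$labels))
  SIG <- matrix(NA_real_, retained, 2, dimnames = list(NULL, c("d13C", "d15N")))
  sz <- 0.5; su <- c(0.5, 0.5)
  acc_z <- 0; try_z <- 0; acc_u <- c(0, 0); try_u <- c(0, 0)
  win_az <- 0; win_tz <- 0; win_au <- c(0, 0); win_tu <- c(0, 0)
  cur <- logpost(z, u)
  kept <- 0
  for (it in seq_len(iterations)) {
    adapting <- it <= burnin
    if (K > 1) {
      zp <- z + stats::rnorm(K - 1, 0, sz)
      lp <- logpost(zp, u)
      if (log(stats::runif(1)) < lp - cur) { z <- zp; cur <- lp
        if (adapting) win_az <- win_az + 1 else acc_z <- acc_z + 1 }
      if (adapting) win_tz <- win_tz + 1 else try_z <- try_z + 1
    }
    if (use_sigma) {
      for (j in 1:2) {
        up <- u; up[j] <- u[j] + stats::rnorm(1, 0, su[j])
        lp <- logpost(z, up)
        if (log(stats::runif(1)) < lp - cur) { u <- up; cur <- lp
          if (adapting) win_au[j] <- win_au[j] + 1 else acc_u[j] <- acc_u[j] + 1 }
        if (adapting) win_tu[j] <- win_tu[j] + 1 else try_u[j] <- try_u[j] + 1
      }
    }
    if (adapting && it %% 100 == 0) {
      if (win_tz > 0) sz <- sz * exp(win_az / win_tz - 0.3)
      for (j in 1:2) if (win_tu[j] > 0)
        su[j] <- su[j] * exp(win_au[j] / win_tu[j] - 0.3)
      win_az <- 0; win_tz <- 0; win_au[] <- 0; win_tu[] <- 0
    }
    if (!adapting && (it - burnin) %% thin == 0 && kept < retained) {
      kept <- kept + 1
      P[kept, ] <- softmax_alr(z)
      SIG[kept, ] <- if (use_sigma) exp(u) else c(0, 0)
    }
  }
  acc <- c(proportions = if (try_z > 0) acc_z / try_z else NA_real_,
           sigma_d13C = if (try_u[1] > 0) acc_u[1] / try_u[1] else NA_real_,
           sigma_d15N = if (try_u[2] > 0) acc_u[2] / try_u[2] else NA_real_)
  diag_msg <- character(0)
  bad <- !is.na(acc) & (acc <= 0.05 | acc >= 0.95)
  if (any(bad))
    diag_msg <- paste("post-adaptation acceptance rate outside (0.05, 0.95):",
                      paste(names(acc)[bad], collapse = ", "))
  structure(list(p = P, sigma = SIG, acceptance = acc,
                 diagnostics = diag_msg, seed = seed,
                 config = list(iterations = iterations, burnin = burnin,
                               thin = thin, prior_only = prior_only)),
            class = "mixing_posterior")
}

#' @export
print.mixing_posterior <- function(x, ...) {
  cat("Mixing posterior:", nrow(x$p), "retained draws over",
      ncol(x$p), "source(s)\n")
  cat("posterior means:",
      paste(sprintf("%s = %.3f", colnames(x$p), colMeans(x$p)),
            collapse = ", "), "\n")
  if (length(x$diagnostics)) cat("diagnostics:", x$diagnostics, "\n")
  invisible(x)
}

#' Summarise a mixing posterior
#'
#' Posterior mean and central (equal-tailed) credibility intervals per
#' source at the requested levels; intervals at increasing levels are
#' nested by construction.
#'
#' @param posterior a [fit_mixing()] result (>= 100 retained draws).
#' @param levels credibility levels in percent.
#' @return data frame: `source, mean` plus `lo_<level>`/`hi_<level>`
#'   columns.
#' @export
summarize_posterior <- function(posterior, levels = c(50, 75, 95)) {
  P <- posterior$p
  if (nrow(P) < 100) stop_domain("too few retained draws (< 100) to summarise")
  out <- data.frame(source = colnames(P), mean = colMeans(P),
                    stringsAsFactors = FALSE)
  for (lv in sort(levels)) {
    a <- (1 - lv / 100) / 2
    q <- apply(P, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    out[[paste0("lo_", lv)]] <- q[1, ]
    out[[paste0("hi_", lv)]] <- q[2, ]
  }
  rownames(out) <- NULL
  out
}

#' Fit the mixing model per trophic category and site
#'
#' Runs an independent fit for each (trophic category, site) group of
#' consumers against that site's source table. Consumer observations are
#' taxon means by default, matching the biplot convention.
#'
#' @param samples validated sample table.
#' @param sources either a single [source_spec] table (used for every
#'   site) or a named list of tables keyed by site.
#' @param tef [tef()] object.
#' @param level `"species_means"` or `"individuals"`.
#' @param seed master seed; each group's chain gets a derived seed.
#' @param ... chain configuration passed to [fit_mixing()].
#' @return named list (`"<site>|<category>"`) of `mixing_posterior`
#'   objects; empty groups are skipped with a warning and listed in the
#'   `"skipped"` attribute.
#' @export
fit_by_category <- function(samples, sources, tef = isonicheweb::tef(),
                            level = c("species_means", "individuals"),
                            seed = NULL, ...) {
  level <- match.arg(level)
  samples <- validate_samples(samples)
  cons <- samples[samples$role == "consumer", , drop = FALSE]
  sites <- sort(unique(cons$site))
  cats <- c("herbivore", "omnivore", "carnivore")
  fits <- list()
  skipped <- character(0)
  for (s in sites) {
    src <- if (is.data.frame(sources)) sources else sources[[s]]
    if (is.null(src)) stop_domain("no source table for site ", s)
    for (cat_ in cats) {
      # seed depends on the category only, so identical data at two
      # sites yield identical chains under the same master seed
      idx <- match(cat_, cats)
      g <- cons[cons$site == s & cons$trophic_category == cat_, , drop = FALSE]
      if (nrow(g) == 0) { skipped <- c(skipped, paste(s, cat_, sep = "|")); next }
      pts <- if (level == "species_means") {
        cbind(d13C = tapply(g$d13C, g$taxon, mean),
              d15N = tapply(g$d15N, g$taxon, mean))
      } else as.matrix(g[c("d13C", "d15N")])
      prob <- mixing_problem(pts, src, tef)
      fits[[paste(s, cat_, sep = "|")]] <-
        fit_mixing(prob, seed = if (is.null(seed)) NULL
                   else derive_seed(seed, idx), ...)
    }
  }
  if (length(skipped))
    warning("skipped empty group(s): ", paste(skipped, collapse = ", "),
            call. = FALSE)
  attr(fits, "skipped") <- skipped
  fits
}

#' Gelman--Rubin potential scale reduction factor
#'
#' Split-free PSRF across independent chains for each parameter column;
#' values near 1 indicate between-chain agreement.
#'
#' @param chains list of >= 2 draw matrices with identical columns.
#' @return named vector of PSRF values, one per column.
#' @export
gelman_rubin <- function(chains) {
  m <- length(chains)
  if (m < 2) stop_domain(">= 2 chains are required")
  n <- nrow(chains[[1]])
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    draws <- vapply(chains, function(ch) ch[, j], numeric(n))
    means <- colMeans(draws)
    W <- mean(apply(draws, 2, stats::var))
    B <- n * stats::var(means)
    vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
    sqrt(vhat / W)
  }, numeric(1)) |> stats::setNames(colnames(chains[[1]]))
}
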