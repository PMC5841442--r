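#' Percent cover of benthic components on a transect
#'
#' Line-point intercept reduction: each component's cover is 100 times
#' its share of intercept points. When a reference `components` vector
#' is supplied, components not seen on the transect are reported as 0
#' and labels outside the list are grouped under `"other"`.
#'
#' @param transect a [survey_transect()].
#' @param components optional character vector of reporting components.
#' @return named numeric vector of percentages (sums to 100).
#' @export
percent_cover <- function(transect, components = NULL) {
  pts <- transect$point_components
  if (length(pts) == 0) stop_domain("empty transect")
  if (is.null(components)) {
    tab <- table(pts)
    out <- 100 * as.numeric(tab) / length(pts)
    names(out) <- names(tab)
  } else {
    lab <- ifelse(pts %in% components, pts, "other")
    levels_ <- unique(c(components, if (any(lab == "other")) "other"))
    tab <- table(factor(lab, levels = levels_))
    out <- 100 * as.numeric(tab) / length(pts)
    names(out) <- levels_
  }
  out
}

#' Rugosity index of a transect
#'
#' Ratio of the moulded chain length to the straight-line transect
#' length; 1 for a perfectly flat surface, larger for more
#' architecturally complex reef.
#'
#' @param transect a [survey_transect()].
#' @return rugosity index (>= 1 by the transect invariants).
#' @export
rugosity <- function(transect) {
  transect$chain_length / transect$linear_length
}

#' Per-site cover summaries
#'
#' Per site and component: the per-transect percentages, their mean and
#' a 95% t-interval half-width (t-quantile with df = n - 1).
#'
#' @param transects list of [survey_transect()] objects.
#' @param components optional reporting component list (see
#'   [percent_cover()]).
#' @param conf_level confidence level.
#' @return data frame `site, component, n_transects, mean_pct, ci_pct`
#'   with the per-transect values in list-column `pct`.
#' @export
cover_summary <- function(transects, components = NULL, conf_level = 0.95) {
  sites <- unique(vapply(transects, `[[`, "", "site"))
  if (is.null(components)) {
    components <- sort(unique(unlist(
      lapply(transects, `[[`, "point_components"))))
  } else if (!"other" %in% components) {
    # labels outside the reporting list are grouped under "other"
    components <- c(components, "other")
  }
  rows <- list()
  for (s in sites) {
    trs <- Filter(function(tr) tr$site == s, transects)
    # percent_cover may append "other"; index against the fixed levels
    mat <- vapply(trs, function(tr) {
      pc <- percent_cover(tr, components)
      pc[components]
    }, numeric(length(components)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(components))
    for (i in seq_along(components)) {
      v <- mat[i, ]
      n <- length(v)
      half <- if (n > 1) stats::qt(1 - (1 - conf_level) / 2, n - 1) *
        stats::sd(v) / sqrt(n) else NA_real_
      row <- data.frame(site = s, component = components[i], n_transects = n,
                        mean_pct = mean(v), ci_pct = half,
                        stringsAsFactors = FALSE)
      row$pct <- list(v)
      rows[[length(rows) + 1]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Between-site comparison of transect-level values
#'
#' Pooled-variance Student's t (df = nA + nB - 2) with per-site means
#' and 95% t-interval half-widths; used for percent cover of a
#' component or for the rugosity index.
#'
#' @param values_a,values_b per-transect values at each site (>= 2 each).
#' @param conf_level confidence level for the per-site intervals.
#' @return list `mean_a, ci_a, mean_b, ci_b, t, df, p`.
#' @export
compare_sites <- function(values_a, values_b, conf_level = 0.95) {
  tt <- pooled_t_test(values_a, values_b, conf_level)
  list(mean_a = tt$mean_x, ci_a = tt$ci_x,
       mean_b = tt$mean_y, ci_b = tt$ci_y,
       t = tt$t, df = tt$df, p = tt$p)
}

#' Full benthic survey report for two sites
#'
#' Per-component cover summaries and between-site pooled t tests, plus
#' the rugosity comparison. A `macroalgae` aggregate (the sum of erect
#' fleshy and calcareous groups, excluding turf) is added when those
#' component labels are present.
#'
#' @param transects list of [survey_transect()] objects covering two
#'   sites.
#' @param components optional reporting component list.
#' @param macroalgae_components labels summed into the macroalgae
#'   aggregate.
#' @return list `cover` (data frame from [cover_summary()]),
#'   `cover_tests` (per-component data frame), `rugosity` (per-site
#'   values + test), `macroalgae` (per-site mean cover of the
#'   aggregate, or NULL).
#' @export
survey_report <- function(transects, components = NULL,
                          macroalgae_components =
                            c("fleshy_macroalgae", "calcareous_macroalgae")) {
  sites <- sort(unique(vapply(transects, `[[`, "", "site")))
  if (length(sites) != 2) stop_domain("exactly two sites are required")
  cov <- cover_summary(transects, components)
  comps <- unique(cov$component)
  tests <- lapply(comps, function(cmp) {
    a <- cov$pct[cov$site == sites[1] & cov$component == cmp][[1]]
    b <- cov$pct[cov$site == sites[2] & cov$component == cmp][[1]]
    cs <- compare_sites(a, b)
    data.frame(component = cmp, mean_a = cs$mean_a, mean_b = cs$mean_b,
               t = cs$t, df = cs$df, p = cs$p, stringsAsFactors = FALSE)
  })
  rug_a <- vapply(Filter(function(tr) tr$site == sites[1], transects),
                  rugosity, 0)
  rug_b <- vapply(Filter(function(tr) tr$site == sites[2], transects),
                  rugosity, 0)
  macro <- NULL
  present <- intersect(macroalgae_components, comps)
  if (length(present)) {
    agg <- function(site) {
      trs <- Filter(function(tr) tr$site == site, transects)
      vapply(trs, function(tr) {
        pc <- percent_cover(tr, comps)
        sum(pc[present])
      }, 0)
    }
    ma <- agg(sites[1]); mb <- agg(sites[2])
    macro <- list(mean = stats::setNames(c(mean(ma), mean(mb)), sites),
                  test = compare_sites(ma, mb))
  }
  list(cover = cov,
       cover_tests = { d <- do.call(rbind, tests); rownames(d) <- NULL; d },
       rugosity = list(values = stats::setNames(list(rug_a, rug_b), sites),
                       test = compare_sites(rug_a, rug_b)),
       macroalgae = macro,
       sites = sites)
}
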