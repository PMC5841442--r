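#' @title Isotope sample tables
#' @description
#' An isotope sample table is a plain data frame with one row per measured
#' specimen and the fixed column schema
#' `sample_id, site, taxon, role, trophic_category, d13C, d15N`.
#' `d13C` is the per-mil deviation from VPDB, `d15N` the per-mil deviation
#' from atmospheric N2. `role` is `"source"` (basal carbon source) or
#' `"consumer"`; `trophic_category` is `"herbivore"`, `"omnivore"` or
#' `"carnivore"` for consumers and `"none"` for sources (and only for
#' sources).
#' @name isotope_samples
NULL

SAMPLE_COLUMNS <- c("sample_id", "site", "taxon", "role",
                    "trophic_category", "d13C", "d15N")
ROLES <- c("source", "consumer")
TROPHIC_CATEGORIES <- c("herbivore", "omnivore", "carnivore", "none")

#' Validate an isotope sample table
#'
#' Checks the fixed schema and the row-level invariants: finite isotope
#' values, known `role` and `trophic_category` levels, and
#' `trophic_category == "none"` exactly for `role == "source"`.
#'
#' @param samples data frame with the [isotope_samples] schema.
#' @return the validated data frame (invisibly usable in pipelines).
#' @export
validate_samples <- function(samples) {
  if (!is.data.frame(samples)) stop_domain("samples must be a data frame")
  missing <- setdiff(SAMPLE_COLUMNS, names(samples))
  if (length(missing))
    stop_domain("missing required column(s): ", paste(missing, collapse = ", "))
  samples <- samples[SAMPLE_COLUMNS]
  for (col in c("d13C", "d15N")) {
    v <- samples[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_domain("non-numeric ", col, " value at row ", bad %||% 1)
    }
    if (any(!is.finite(v)))
      stop_domain("non-finite ", col, " value at row ", which(!is.finite(v))[1])
  }
  if (!all(samples$role %in% ROLES))
    stop_domain("role must be one of: ", paste(ROLES, collapse = ", "))
  if (!all(samples$trophic_category %in% TROPHIC_CATEGORIES))
    stop_domain("trophic_category must be one of: ",
                paste(TROPHIC_CATEGORIES, collapse = ", "))
  bad <- xor(samples$role == "source", samples$trophic_category == "none")
  if (any(bad))
    stop_domain("trophic_category must be 'none' iff role is 'source' (row ",
                which(bad)[1], ")")
  samples
}

#' Read an isotope sample table from CSV
#'
#' @param path path to a CSV file with the [isotope_samples] schema.
#' @return validated data frame of samples, rows in file order.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(SAMPLE_COLUMNS, names(df))
  if (length(missing))
    stop_domain("missing required column(s): ", paste(missing, collapse = ", "))
  for (col in c("d13C", "d15N")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !all(is.na(df[[col]]) == is.na(v)))
      stop_domain("non-numeric ", col, " value at row ",
                  which(is.na(v) & !is.na(df[[col]]))[1])
    df[[col]] <- v
  }
  validate_samples(df)
}

#' Write an isotope sample table to CSV
#'
#' Isotope values are serialised with 4 decimal places (mass-spectrometer
#' precision is ~0.02 permil, so the round trip is lossless at reporting
#' precision); writing, re-reading and writing again is byte-identical.
#'
#' @param samples validated sample data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  samples <- validate_samples(samples)
  out <- samples
  out$d13C <- formatC(samples$d13C, format = "f", digits = 4)
  out$d15N <- formatC(samples$d15N, format = "f", digits = 4)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_domain("cannot write to path: ", path)
  invisible(path)
}

#' Trophic enrichment factor
#'
#' The mean +/- SD isotopic shift per trophic step applied in the mixing
#' model. Defaults are the widely used single-step values of 0.40 +/- 1.30
#' permil for carbon and 3.40 +/- 1.00 permil for nitrogen.
#'
#' @param mean_d13C,sd_d13C carbon shift mean and SD (permil).
#' @param mean_d15N,sd_d15N nitrogen shift mean and SD (permil).
#' @return object of class `"tef"`.
#' @export
tef <- function(mean_d13C = 0.40, sd_d13C = 1.30,
                mean_d15N = 3.40, sd_d15N = 1.00) {
  if (sd_d13C < 0 || sd_d15N < 0) stop_domain("TEF SDs must be >= 0")
  structure(list(mean = c(d13C = mean_d13C, d15N = mean_d15N),
                 sd = c(d13C = sd_d13C, d15N = sd_d15N)),
            class = "tef")
}

#' @export
print.tef <- function(x, ...) {
  cat(sprintf("Trophic enrichment factor: d13C %.2f +/- %.2f, d15N %.2f +/- %.2f permil/step\n",
              x$mean["d13C"], x$sd["d13C"], x$mean["d15N"], x$sd["d15N"]))
  invisible(x)
}

#' Construct a basal-source specification table
#'
#' @param source character vector of source labels.
#' @param mean_d13C,sd_d13C,mean_d15N,sd_d15N numeric vectors (permil).
#' @param n sample counts behind each summary (NA if unknown).
#' @return data frame of class `"source_spec"`, one row per source.
#' @export
source_spec <- function(source, mean_d13C, sd_d13C, mean_d15N, sd_d15N,
                        n = NA_integer_) {
  if (anyDuplicated(source)) stop_domain("source labels must be unique")
  if (any(c(sd_d13C, sd_d15N) < 0)) stop_domain("source SDs must be >= 0")
  structure(data.frame(source = source, n = n,
                       mean_d13C = mean_d13C, sd_d13C = sd_d13C,
                       mean_d15N = mean_d15N, sd_d15N = sd_d15N,
                       stringsAsFactors = FALSE),
            class = c("source_spec", "data.frame"))
}

#' Pool basal-source samples into source summaries
#'
#' Groups source samples by a taxon -> pooled-label map and computes the
#' per-isotope mean and sample SD (n - 1 denominator) over *all* member
#' samples of each group (pooled, not a mean of per-taxon means). This is
#' how, e.g., turf algae and epiphytes are combined into one
#' "turf + epiphytes" end member.
#'
#' @param samples validated sample table; every mapped taxon must have
#'   `role == "source"`.
#' @param grouping named character vector: names are taxa, values are the
#'   pooled source labels.
#' @param sd_override optional named list (by pooled label) of
#'   `c(d13C =, d15N =)` SDs, required for any group with a single sample.
#' @return [source_spec] data frame, one row per pooled label (in first
#'   appearance order), with pooled sample counts.
#' @export
pool_sources <- function(samples, grouping, sd_override = NULL) {
  samples <- validate_samples(samples)
  sel <- samples[samples$taxon %in% names(grouping), , drop = FALSE]
  if (any(sel$role != "source"))
    stop_domain("grouped taxa must all have role = 'source': ",
                paste(unique(sel$taxon[sel$role != "source"]), collapse = ", "))
  labels <- unname(grouping[sel$taxon])
  out <- lapply(unique(unname(grouping)), function(lab) {
    g <- sel[labels == lab, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    ov <- sd_override[[lab]]
    if (nrow(g) < 2 && is.null(ov))
      stop_domain("group '", lab, "' has < 2 samples; supply sd_override")
    data.frame(source = lab, n = nrow(g),
               mean_d13C = mean(g$d13C),
               sd_d13C = if (!is.null(ov)) unname(ov["d13C"]) else stats::sd(g$d13C),
               mean_d15N = mean(g$d15N),
               sd_d15N = if (!is.null(ov)) unname(ov["d15N"]) else stats::sd(g$d15N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("source_spec", "data.frame"))
}

#' Benthic survey transects
#'
#' A transect records the ordered benthic component intercepted at each
#' point of a line-point survey, plus the moulded chain length and the
#' straight-line length used for the rugosity index.
#'
#' @param site site label.
#' @param transect_id transect identifier.
#' @param point_components character vector, one component label per
#'   intercept point.
#' @param chain_length,linear_length metres; `chain_length >= linear_length > 0`.
#' @return object of class `"survey_transect"`.
#' @export
survey_transect <- function(site, transect_id, point_components,
                            chain_length, linear_length) {
  if (length(point_components) == 0)
    stop_domain("point_components must be non-empty")
  if (!(linear_length > 0)) stop_domain("linear_length must be > 0")
  if (chain_length < linear_length)
    stop_domain("chain_length must be >= linear_length")
  structure(list(site = site, transect_id = transect_id,
                 point_components = as.character(point_components),
                 chain_length = chain_length, linear_length = linear_length),
            class = "survey_transect")
}

#' Read survey transects from the two-file CSV layout
#'
#' `points_path`: columns `site, transect_id, point_index, component`;
#' `chains_path`: columns `site, transect_id, chain_length, linear_length`.
#'
#' @param points_path,chains_path CSV paths.
#' @return list of [survey_transect] objects.
#' @export
read_transects <- function(points_path, chains_path) {
  pts <- utils::read.csv(points_path, stringsAsFactors = FALSE)
  ch <- utils::read.csv(chains_path, stringsAsFactors = FALSE)
  need_p <- c("site", "transect_id", "point_index", "component")
  need_c <- c("site", "transect_id", "chain_length", "linear_length")
  if (length(setdiff(need_p, names(pts))))
    stop_domain("points file missing column(s): ",
                paste(setdiff(need_p, names(pts)), collapse = ", "))
  if (length(setdiff(need_c, names(ch))))
    stop_domain("chains file missing column(s): ",
                paste(setdiff(need_c, names(ch)), collapse = ", "))
  keys <- unique(pts[c("site", "transect_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    s <- keys$site[i]; id <- keys$transect_id[i]
    p <- pts[pts$site == s & pts$transect_id == id, , drop = FALSE]
    p <- p[order(p$point_index), , drop = FALSE]
    cc <- ch[ch$site == s & ch$transect_id == id, , drop = FALSE]
    if (nrow(cc) != 1)
      stop_domain("chain record missing or duplicated for transect ", id,
                  " at ", s)
    survey_transect(s, id, p$component, cc$chain_length, cc$linear_length)
  })
}

#' Write survey transects to the two-file CSV layout
#'
#' @param transects list of [survey_transect] objects.
#' @param points_path,chains_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_transects <- function(transects, points_path, chains_path) {
  pts <- do.call(rbind, lapply(transects, function(tr) {
    data.frame(site = tr$site, transect_id = tr$transect_id,
               point_index = seq_along(tr$point_components),
               component = tr$point_components, stringsAsFactors = FALSE)
  }))
  ch <- do.call(rbind, lapply(transects, function(tr) {
    data.frame(site = tr$site, transect_id = tr$transect_id,
               chain_length = tr$chain_length, linear_length = tr$linear_length,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(pts, points_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(ch, chains_path, row.names = FALSE, quote = FALSE)
  invisible(c(points_path, chains_path))
}

#' Bundle samples, transects and study metadata
#'
#' Validates that the baseline taxon is present among consumers at every
#' site and that every consumer taxon carries a trophic category.
#'
#' @param samples validated sample table.
#' @param baseline_taxon label of the trophic-level-2 baseline consumer
#'   (a filter-feeding bivalve in the intended design).
#' @param transects optional list of [survey_transect] objects.
#' @return object of class `"study_dataset"` with elements `samples`,
#'   `transects`, `baseline_taxon`, `category_map`.
#' @export
study_dataset <- function(samples, baseline_taxon, transects = list()) {
  samples <- validate_samples(samples)
  cons <- samples[samples$role == "consumer", , drop = FALSE]
  for (s in unique(samples$site)) {
    if (!any(cons$site == s & cons$taxon == baseline_taxon))
      stop_domain("baseline taxon '", baseline_taxon,
                  "' absent among consumers at site ", s)
  }
  cmap <- tapply(cons$trophic_category, cons$taxon, function(x) unique(x)[1])
  structure(list(samples = samples, transects = transects,
                 baseline_taxon = baseline_taxon,
                 category_map = cmap),
            class = "study_dataset")
}
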