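#' Meta-transcript abundance per million diatom reads
#'
#' `1e6 * metaT_sum / diatom_total`: the total meta-transcriptome occurrence
#' of a gene family expressed per million reconciled diatom reads.
#'
#' @param metaT_sum Summed meta-transcriptome counts (>= 0).
#' @param diatom_total Total diatom meta-transcriptome counts (> 0).
#' @return Normalised abundance (vectorised).
#' @export
per_million_diatom <- function(metaT_sum, diatom_total) {
  if (any(diatom_total <= 0)) {
    stop("diatom_total must be positive", call. = FALSE)
  }
  if (any(metaT_sum < 0)) stop("metaT_sum must be nonnegative", call. = FALSE)
  1e6 * metaT_sum / diatom_total
}

#' Log-ratio of meta-transcriptome to meta-genome abundance
#'
#' `log10(1 + metaT) - log10(1 + metaG)`; the unit offset admits stations
#' with zero meta-genome counts. This proxies the per-gene expression level.
#'
#' @param metaT,metaG Nonnegative abundances (vectorised).
#' @return Log10 expression ratio.
#' @export
log_expression_ratio <- function(metaT, metaG) {
  if (any(metaT < 0) || any(metaG < 0)) {
    stop("metaT and metaG must be nonnegative", call. = FALSE)
  }
  log10(1 + metaT) - log10(1 + metaG)
}

#' Harmonize plankton size-fraction labels
#'
#' The Arctic stations were sampled with a 5 um lower filter where other
#' stations used 3 um; the two are treated as equivalent, so raw `"3-20"`
#' and `"5-20"` labels both map to `"3/5-20"`. All other labels from the
#' controlled vocabulary pass through unchanged and no record is lost.
#'
#' @param records Tibble with a `size_fraction` column.
#' @return The same tibble with harmonized `size_fraction`.
#' @export
reconcile_fractions <- function(records) {
  known <- c("0.8-2000", "0.8-5", "3/5-20", "20-180", "180-2000",
             "3-20", "5-20")
  bad <- setdiff(unique(records$size_fraction), known)
  if (length(bad) > 0L) {
    stop("unknown size-fraction labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(records, size_fraction = dplyr::if_else(
    .data$size_fraction %in% c("3-20", "5-20"), "3/5-20", .data$size_fraction
  ))
}

correlation_row <- function(method, tails, direction, n,
                            r = NA_real_, p = NA_real_, undefined = FALSE) {
  tibble::tibble(
    method = method, r = r, r_squared = r^2, p_value = p,
    tails = tails, direction = direction, n = as.integer(n),
    undefined = undefined
  )
}

#' Correlate per-station abundances with an environmental variable
#'
#' Pearson or Spearman correlation with significance from the regression
#' F-statistic `F = r^2 (n-2) / (1 - r^2)` on (1, n-2) df. One-tailed tests
#' take the upper tail in the declared direction (equivalently the one-sided
#' t-test on `t = r sqrt((n-2)/(1-r^2))`); the direction is always explicit,
#' never inferred from the data. Spearman replaces both variables by average
#' ranks (ties averaged) and applies the same machinery (t-approximation).
#' Pairs with missing values are dropped pairwise.
#'
#' @param values Per-station response values (e.g. normalised abundances).
#' @param env_values Per-station environmental variable, same length.
#' @param method `"pearson"` or `"spearman"`.
#' @param tails `"one"` or `"two"`.
#' @param direction Hypothesized sign for one-tailed tests, `"positive"` or
#'   `"negative"`; ignored for two-tailed.
#' @return One-row tibble: `method`, `r`, `r_squared`, `p_value`, `tails`,
#'   `direction`, `n`, `undefined`. Constant input yields an `undefined`
#'   flagged row rather than an error.
#' @export
correlate_env <- function(values, env_values,
                          method = c("pearson", "spearman"),
                          tails = c("one", "two"),
                          direction = c("positive", "negative")) {
  method <- match.arg(method)
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  ok <- stats::complete.cases(values, env_values)
  x <- values[ok]; y <- env_values[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(correlation_row(method, tails, direction, n, undefined = TRUE))
  }
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p_two <- 0
  } else {
    f <- r^2 * (n - 2) / (1 - r^2)
    p_two <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  if (tails == "two") {
    p <- p_two
  } else {
    sign_match <- if (direction == "positive") r >= 0 else r <= 0
    p <- if (r == 0) 0.5 else if (sign_match) p_two / 2 else 1 - p_two / 2
  }
  correlation_row(method, tails, direction, n, r = r, p = p)
}

#' Classify a genome bin's plastid-glycolysis pathway completeness
#'
#' @param has_cpEnolase,has_cpPGAM Logical vectors.
#' @return Character vector: `"both"`, `"one"`, or `"neither"`.
#' @export
classify_pathway <- function(has_cpEnolase, has_cpPGAM) {
  dplyr::case_when(
    has_cpEnolase & has_cpPGAM ~ "both",
    has_cpEnolase | has_cpPGAM ~ "one",
    .default = "neither"
  )
}

#' Association between genome-bin coverage and absolute latitude
#'
#' Pearson correlation of per-station mean mapped vertical coverage (an
#' abundance proxy) against absolute station latitude, with a two-tailed
#' t-test on `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param coverages Per-station coverages.
#' @param latitudes Per-station latitudes in degrees (sign is dropped).
#' @return One-row correlation tibble as from [correlate_env()].
#' @export
mag_latitude_association <- function(coverages, latitudes) {
  correlate_env(coverages, abs(latitudes), method = "pearson", tails = "two")
}

#' Normalise a station abundance table
#'
#' Harmonizes size fractions, then adds the per-million-diatom-reads metaT
#' normalisation and the metaT/metaG log expression ratio per record.
#' Stations with nonpositive diatom totals are dropped from the per-million
#' normalisation with a warning (the log ratio is still computed).
#'
#' @param abundances Tibble with `meta_gene_id`, `station_id`, `depth_layer`,
#'   `size_fraction`, `metaT`, `metaG`, `diatom_total_metaT`.
#' @param stations Optional station metadata tibble keyed by `station_id`,
#'   `depth_layer`, `size_fraction`; when given it is joined on.
#' @return Tibble with added `metaT_per_million_diatom` and
#'   `log_expression_ratio` columns.
#' @export
normalize_abundances <- function(abundances, stations = NULL) {
  out <- reconcile_fractions(abundances)
  bad <- out$diatom_total_metaT <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with nonpositive diatom totals excluded ",
            "from per-million normalisation", call. = FALSE)
  }
  out <- dplyr::mutate(
    out,
    metaT_per_million_diatom = dplyr::if_else(
      .data$diatom_total_metaT > 0,
      1e6 * .data$metaT / .data$diatom_total_metaT, NA_real_
    ),
    log_expression_ratio = log_expression_ratio(.data$metaT, .data$metaG)
  )
  if (!is.null(stations)) {
    stations <- reconcile_fractions(stations)
    out <- dplyr::left_join(
      out, stations, by = c("station_id", "depth_layer", "size_fraction")
    )
  }
  out
}
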