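#' Genes differentially expressed in both of two comparisons
#'
#' A gene is shared when it passes fold-change > `fc_threshold` and
#' p-value < `p_threshold` (both strict) with the requested direction in
#' BOTH comparison tables. Genes present in only one table are excluded and
#' counted in the returned audit attribute.
#'
#' @param compA,compB Tibbles with `gene_id`, `fold_change` (> 0),
#'   `p_value`, `direction` (`"up"`/`"down"`).
#' @param fc_threshold Fold-change cutoff (default 2, strict).
#' @param p_threshold P-value cutoff (default 0.05, strict).
#' @param direction Direction required in both comparisons.
#' @return Sorted character vector of shared gene ids, with attribute
#'   `n_unmatched` counting genes found in only one table.
#' @export
shared_degs <- function(compA, compB, fc_threshold = 2, p_threshold = 0.05,
                        direction = c("up", "down")) {
  direction <- match.arg(direction)
  passes <- function(d) {
    d$gene_id[d$fold_change > fc_threshold & d$p_value < p_threshold &
                d$direction == direction]
  }
  unmatched <- length(union(compA$gene_id, compB$gene_id)) -
    length(intersect(compA$gene_id, compB$gene_id))
  out <- sort(intersect(passes(compA), passes(compB)))
  attr(out, "n_unmatched") <- unmatched
  out
}

#' Chi-squared enrichment test on a 2x2 contingency table
#'
#' Compares the focal proportion `k1/n1` against the background proportion
#' `k2/n2` with a 1-df chi-squared test without continuity correction. The
#' two-tailed p is the chi-squared upper tail; the one-tailed p is the
#' upper-tail normal probability of `z = sign(k1/n1 - k2/n2) * sqrt(chi2)`,
#' so a table with zero deviation returns 0.5. Tails are always explicit.
#'
#' @param k1,n1 Focal set successes and size.
#' @param k2,n2 Background successes and size.
#' @param tails `"one"` or `"two"`.
#' @return One-row tibble: `k1`, `n1`, `k2`, `n2`, `statistic`, `tails`,
#'   `p_value`.
#' @export
chi2_enrichment <- function(k1, n1, k2, n2, tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 > 0, n2 > 0)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero-margin contingency table", call. = FALSE)
  }
  chi2 <- unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic
  ))
  p <- if (tails == "two") {
    stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    z <- sign(k1 / n1 - k2 / n2) * sqrt(chi2)
    stats::pnorm(z, lower.tail = FALSE)
  }
  tibble::tibble(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                 statistic = chi2, tails = tails, p_value = p)
}

#' Enrichment of predicted chloroplast-targeted proteins in a DEG set
#'
#' Counts chloroplast-predicted genes in the DEG set against the full
#' detected background (which, following the printed denominators, includes
#' the DEG genes; pass `disjoint_background = TRUE` to subtract them).
#' Genes without an annotation row count as non-chloroplast.
#'
#' @param deg_set Character vector of DEG gene ids (subset of
#'   `detected_background`).
#' @param annotations Tibble with `gene_id` and `chloroplast_predicted`.
#' @param detected_background Character vector of all genes detected in the
#'   expression data.
#' @param tails Passed to [chi2_enrichment()].
#' @param disjoint_background Remove DEG genes from the background counts.
#' @return One-row tibble from [chi2_enrichment()].
#' @export
localization_enrichment <- function(deg_set, annotations, detected_background,
                                    tails = c("one", "two"),
                                    disjoint_background = FALSE) {
  tails <- match.arg(tails)
  if (!all(deg_set %in% detected_background)) {
    stop("deg_set must be a subset of detected_background", call. = FALSE)
  }
  is_cp <- stats::setNames(annotations$chloroplast_predicted,
                           annotations$gene_id)
  cp_of <- function(g) {
    v <- unname(is_cp[g])
    v[is.na(v)] <- FALSE
    v
  }
  bg <- if (disjoint_background) setdiff(detected_background, deg_set)
        else detected_background
  chi2_enrichment(
    k1 = sum(cp_of(deg_set)), n1 = length(deg_set),
    k2 = sum(cp_of(bg)), n2 = length(bg), tails = tails
  )
}

#' Per-term GO enrichment of a DEG set
#'
#' One [chi2_enrichment()] per GO term attached to the background; raw
#' p-values are reported without multiple-testing correction so users can
#' apply their own. Terms absent from the background are skipped with a
#' warning.
#'
#' @param deg_set Character vector of DEG gene ids.
#' @param go_map Tibble with `gene_id`, `go_id` (one row per assignment).
#' @param background Character vector of background gene ids.
#' @param tails Passed to [chi2_enrichment()].
#' @return Tibble with one row per tested term: `go_id` plus the
#'   [chi2_enrichment()] columns.
#' @export
go_enrichment <- function(deg_set, go_map, background,
                          tails = c("one", "two")) {
  tails <- match.arg(tails)
  go_map <- dplyr::filter(go_map, .data$gene_id %in% background)
  terms <- sort(unique(go_map$go_id))
  requested <- unique(go_map$go_id)
  skipped <- setdiff(requested, terms)
  if (length(skipped) > 0L) {
    warning("GO terms absent from background skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(terms, function(term) {
    members <- go_map$gene_id[go_map$go_id == term]
    dplyr::bind_cols(
      tibble::tibble(go_id = term),
      chi2_enrichment(
        k1 = sum(deg_set %in% members), n1 = length(deg_set),
        k2 = sum(background %in% members), n2 = length(background),
        tails = tails
      )
    )
  })
}

#' Two-group one-way ANOVA from printed summary statistics
#'
#' Classical pooled-variance one-way ANOVA for two groups, computable from
#' group sizes, means and SDs alone; `F` equals the squared pooled-variance
#' two-sample t statistic on (1, n1+n2-2) df, with a two-sided p. By
#' default the SDs are taken as sample SDs (n-1 divisor, matching `sd()`
#' and a raw-data `aov`); `sd_type = "population"` treats them as
#' population SDs (n divisor), the convention some spreadsheet summaries
#' print.
#'
#' @param n1,mean1,sd1 First group summary (n >= 2, sd >= 0).
#' @param n2,mean2,sd2 Second group summary.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return One-row tibble: `F`, `df1`, `df2`, `p_value`, `degenerate`.
#' @export
anova_two_group_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                                    sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df2 <- n1 + n2 - 2
  ss_within <- if (sd_type == "sample") {
    (n1 - 1) * sd1^2 + (n2 - 1) * sd2^2
  } else {
    n1 * sd1^2 + n2 * sd2^2
  }
  pooled <- ss_within / df2
  delta <- mean1 - mean2
  if (pooled == 0) {
    degenerate <- delta != 0
    return(tibble::tibble(
      F = if (degenerate) Inf else 0, df1 = 1L, df2 = df2,
      p_value = if (degenerate) 0 else 1, degenerate = degenerate
    ))
  }
  f <- delta^2 / (pooled * (1 / n1 + 1 / n2))
  tibble::tibble(F = f, df1 = 1L, df2 = as.integer(df2),
                 p_value = stats::pf(f, 1, df2, lower.tail = FALSE),
                 degenerate = FALSE)
}
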