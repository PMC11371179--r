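#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

#' Read a predictor-call table
#'
#' Normalised TSV schema: `seq_id`, `variant` (`complete`/`met_trimmed`),
#' `predictor`, `call` (`plastid`/`mitochondrion`/`secretory`/`other`),
#' `score` (required for MitoFates rows).
#'
#' @param path TSV path with header.
#' @return Tibble of predictor calls.
#' @export
read_predictor_calls <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    seq_id = "c", variant = "c", predictor = "c", call = "c", score = "d"
  ), progress = FALSE)
  mf <- out$predictor == "MitoFates"
  if (any(mf & is.na(out$score))) {
    stop("MitoFates rows must carry a score", call. = FALSE)
  }
  dup <- duplicated(out[, c("seq_id", "variant", "predictor")])
  if (any(dup)) {
    stop("duplicate (seq_id, variant, predictor) rows in ", path,
         call. = FALSE)
  }
  out
}

#' Read a tip-labeling table
#'
#' @param path TSV with columns `tip_id`, `category`.
#' @return Tibble.
#' @export
read_tip_labels <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(tip_id = "c", category = "c"),
                  progress = FALSE)
}

#' Read an e-value table into a named vector
#'
#' @param path TSV with columns `id`, `evalue`.
#' @return Named numeric vector.
#' @export
read_evalues <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(id = "c", evalue = "d"),
                         progress = FALSE)
  stats::setNames(tab$evalue, tab$id)
}

#' Read a growth-curve table
#'
#' @param path TSV with columns `line_id`, `condition`, `time_days`,
#'   `cells_per_ml`.
#' @return Tibble.
#' @export
read_growth_curves <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    line_id = "c", condition = "c", time_days = "d", cells_per_ml = "d"
  ), progress = FALSE)
}

#' Read a fluorometry trace table
#'
#' @param path TSV with columns `line_id`, `step`, `E`, `F0`, `FM`, `Fs`,
#'   `FM_prime`.
#' @return Tibble.
#' @export
read_fluorometry <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    line_id = "c", step = "i", E = "d", F0 = "d", FM = "d", Fs = "d",
    FM_prime = "d"
  ), progress = FALSE)
}

#' Read a protein FASTA into a tibble
#'
#' @param path FASTA path.
#' @return Tibble with `seq_id` and `sequence`.
#' @export
read_fasta_tbl <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    return(tibble::tibble(seq_id = sub("\\s.*$", "", names(ss)),
                          sequence = as.character(ss)))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[idx]))
  ends <- c(idx[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(i) {
    paste(lines[seq.int(idx[i] + 1L, ends[i])], collapse = "")
  }, character(1))
  tibble::tibble(seq_id = ids, sequence = seqs)
}
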