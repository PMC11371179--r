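#' Parse an hmmscan `--domtblout` table
#'
#' Reads the per-domain table written by `hmmscan --domtblout` into a tidy
#' tibble of domain hits. In hmmscan output the *target* is the Pfam model and
#' the *query* is the protein, so `model_name` comes from column 1 and
#' `seq_id` from column 4. All coordinates are kept 1-based inclusive, as
#' HMMER writes them.
#'
#' @param path Path to a `--domtblout` file. Lines starting with `#` are
#'   comments and are skipped.
#' @return A tibble with one row per domain hit and columns `seq_id`,
#'   `model_name`, `model_length`, `hmm_from`, `hmm_to`, `ali_from`,
#'   `ali_to`, `i_evalue`.
#' @export
parse_domtblout <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble::tibble(
      seq_id = character(), model_name = character(),
      model_length = integer(), hmm_from = integer(), hmm_to = integer(),
      ali_from = integer(), ali_to = integer(), i_evalue = double()
    ))
  }
  rows <- purrr::map(idx, function(i) {
    f <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(f) < 22) {
      stop("malformed domtblout row at line ", i, ": expected >= 22 fields, got ",
           length(f), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(f[c(3, 13, 16, 17, 18, 19)]))
    if (anyNA(num)) {
      stop("malformed domtblout row at line ", i, ": non-numeric field",
           call. = FALSE)
    }
    tibble::tibble(
      seq_id = f[4], model_name = f[1],
      model_length = as.integer(num[1]),
      hmm_from = as.integer(num[3]), hmm_to = as.integer(num[4]),
      ali_from = as.integer(num[5]), ali_to = as.integer(num[6]),
      i_evalue = num[2], line = i
    )
  })
  hits <- dplyr::bind_rows(rows)
  bad <- hits$hmm_from > hits$hmm_to | hits$hmm_from < 1L |
    hits$hmm_to > hits$model_length | hits$ali_from > hits$ali_to |
    hits$ali_from < 1L | hits$i_evalue < 0
  if (any(bad)) {
    stop("invalid domain coordinates at line ",
         paste(hits$line[bad], collapse = ", "), call. = FALSE)
  }
  dplyr::select(hits, -"line")
}

#' Read a BLAST tabular (`-outfmt 6`) hit table
#'
#' Standard 12-column layout: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore.
#'
#' @param path Path to a tab-separated outfmt-6 file (no header).
#' @return Tibble with the 12 standard columns.
#' @export
read_blast6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  out <- readr::read_tsv(path, col_names = cols,
                         col_types = "ccdiiiiiiidd", progress = FALSE)
  if (any(out$bitscore < 0) || any(out$evalue < 0)) {
    stop("negative bitscore or e-value in ", path, call. = FALSE)
  }
  out
}

# Union length of a set of 1-based inclusive integer intervals.
interval_union_length <- function(from, to) {
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]
  total <- 0L; cur_from <- from[1L]; cur_to <- to[1L]
  for (i in seq_along(from)[-1L]) {
    if (from[i] <= cur_to + 1L) {
      cur_to <- max(cur_to, to[i])
    } else {
      total <- total + (cur_to - cur_from + 1L)
      cur_from <- from[i]; cur_to <- to[i]
    }
  }
  total + (cur_to - cur_from + 1L)
}

#' Fraction of an HMM model covered by domain hits
#'
#' Coverage is the union of the `[hmm_from, hmm_to]` model-coordinate
#' intervals (inclusive) divided by the model length; overlapping envelopes
#' are merged, never summed.
#'
#' @param hits Tibble of domain hits for one (sequence, model) pair, as from
#'   [parse_domtblout()].
#' @param model_length Model length in match states; taken from `hits` when
#'   omitted.
#' @return Coverage fraction in \[0, 1\]; 0 for an empty hit set.
#' @export
domain_coverage <- function(hits, model_length = NULL) {
  if (is.null(hits) || nrow(hits) == 0L) return(0)
  if (is.null(model_length)) model_length <- hits$model_length[[1L]]
  stopifnot(model_length >= 1)
  interval_union_length(hits$hmm_from, hits$hmm_to) / model_length
}

#' Domain-completeness gate for an enolase or PGAM candidate
#'
#' Enolase candidates must cover more than 90% of both the Enolase_N and
#' Enolase_C models; PGAM candidates more than 50% of His_Phos. Thresholds
#' are strict: a coverage exactly at the threshold fails. A model with no
#' hits counts as coverage 0.
#'
#' @param coverages Named numeric vector or list mapping model name to
#'   coverage fraction.
#' @param family One of `"enolase"`, `"pgam1"`, `"pgam2"`.
#' @return Logical scalar.
#' @export
family_completeness <- function(coverages, family = c("enolase", "pgam1", "pgam2")) {
  family <- match.arg(family)
  cov_of <- function(m) {
    v <- coverages[[m]]
    if (is.null(v) || is.na(v)) 0 else v
  }
  if (family == "enolase") {
    cov_of("Enolase_N") > 0.90 && cov_of("Enolase_C") > 0.90
  } else {
    cov_of("His_Phos") > 0.50
  }
}

#' Room for a plastid-targeting presequence upstream of the domain
#'
#' A plastid presequence needs more than 20 residues before the conserved
#' domain starts; sequences whose earliest domain alignment begins within the
#' first 20 aa are treated as lacking a credible targeting sequence.
#'
#' @param hits Tibble of domain hits (the family's models) for one sequence.
#' @return `TRUE` if the earliest `ali_from` is > 20 (1-based), else `FALSE`.
#' @export
presequence_room <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) {
    stop("cannot assess presequence room without domain hits", call. = FALSE)
  }
  min(hits$ali_from) > 20L
}

#' Trim a protein to its first encoded N-terminal methionine
#'
#' Returns the suffix starting at the first methionine at position >= 2 (a
#' leading Met is the existing start, so trimming there would be vacuous), or
#' `NA_character_` when the sequence has no such Met.
#'
#' @param sequence Amino-acid string.
#' @return Trimmed sequence or `NA_character_`.
#' @export
trim_to_first_met <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  pos <- regexpr("M", substring(sequence, 2L), fixed = TRUE)
  if (pos < 0L) return(NA_character_)
  substring(sequence, pos + 1L)
}

qualifying_plastid_predictors <- function(lineage_class) {
  switch(lineage_class,
    primary_plastid = c("TargetP", "PredAlgo"),
    secondary_plastid = c("HECTAR", "ASAFind"),
    character()
  )
}

#' Lineage-aware consensus subcellular localization
#'
#' A protein is called plastid-targeted when any qualifying predictor for its
#' lineage (TargetP or PredAlgo for primary plastids; HECTAR or ASAFind for
#' secondary plastids) returns a plastid call on either the complete or the
#' Met-trimmed variant. Otherwise it is called mitochondrial when HECTAR
#' returns mitochondrion or MitoFates scores >= 0.35 on either variant; else
#' `other`. Plastid takes precedence over mitochondrion; prokaryotes are
#' always `other`. WoLFPSORT calls are accepted in input but never drive the
#' consensus.
#'
#' @param calls Tibble of predictor calls for one sequence, with columns
#'   `variant` (`complete`/`met_trimmed`), `predictor`, `call`
#'   (`plastid`/`mitochondrion`/`secretory`/`other`) and `score`
#'   (required for MitoFates).
#' @param lineage_class One of `primary_plastid`, `secondary_plastid`,
#'   `non_photosynthetic`, `prokaryote`.
#' @param mitofates_threshold MitoFates presequence-probability gate
#'   (default 0.35, inclusive).
#' @return List with `consensus` and an `evidence` tibble of the calls that
#'   fired.
#' @export
consensus_localization <- function(calls, lineage_class,
                                   mitofates_threshold = 0.35) {
  lineage_class <- match.arg(
    lineage_class,
    c("primary_plastid", "secondary_plastid", "non_photosynthetic", "prokaryote")
  )
  empty_ev <- tibble::tibble(predictor = character(), variant = character(),
                             call = character())
  if (lineage_class == "prokaryote" || is.null(calls) || nrow(calls) == 0L) {
    return(list(consensus = "other", evidence = empty_ev))
  }
  calls <- dplyr::arrange(calls, .data$predictor, .data$variant)
  qual <- qualifying_plastid_predictors(lineage_class)
  pla <- dplyr::filter(calls, .data$predictor %in% qual, .data$call == "plastid")
  if (nrow(pla) > 0L) {
    return(list(consensus = "plastid",
                evidence = dplyr::select(pla, "predictor", "variant", "call")))
  }
  mito_hectar <- dplyr::filter(calls, .data$predictor == "HECTAR",
                               .data$call == "mitochondrion")
  mito_mf <- dplyr::filter(calls, .data$predictor == "MitoFates",
                           !is.na(.data$score),
                           .data$score >= mitofates_threshold)
  mito <- dplyr::bind_rows(mito_hectar, mito_mf)
  if (nrow(mito) > 0L) {
    return(list(consensus = "mitochondrion",
                evidence = dplyr::select(mito, "predictor", "variant", "call")))
  }
  list(consensus = "other", evidence = empty_ev)
}

#' Reciprocal best-hit retention
#'
#' For each query the best hit is the row with maximal bitscore, ties broken
#' by minimal e-value then lexicographically smallest subject id (the
#' original analyses relied on `-max_target_seqs 1`, whose tie behaviour is
#' undefined; this rule is deterministic). A query is retained iff its best
#' hit falls in `target_set`.
#'
#' @param rows Tibble of BLAST rows (`qseqid`, `sseqid`, `evalue`,
#'   `bitscore`).
#' @param target_set Character vector of subject ids counting as the
#'   homologous set.
#' @return Character vector of retained query ids.
#' @export
reciprocal_best_hit <- function(rows, target_set) {
  if (is.null(rows) || nrow(rows) == 0L) return(character())
  best <- rows |>
    dplyr::group_by(.data$qseqid) |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$evalue, .data$sseqid,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = 1L) |>
    dplyr::ungroup()
  sort(best$qseqid[best$sseqid %in% target_set])
}

#' Screen candidate proteins for plastid localization
#'
#' Composes the gates in order: domain completeness (family-specific
#' coverage thresholds), presequence room (earliest domain alignment > 20 aa
#' into the sequence), then lineage-aware targeting-predictor consensus.
#' When either structural gate fails the consensus is forced to `other`
#' regardless of predictor calls.
#'
#' @param records Tibble of proteins: `seq_id`, `sequence`, `lineage_class`.
#' @param hits Tibble of domain hits as from [parse_domtblout()].
#' @param calls Tibble of predictor calls (`seq_id`, `variant`, `predictor`,
#'   `call`, `score`).
#' @param family Protein family being screened (`enolase`, `pgam1`,
#'   `pgam2`).
#' @return Tibble with one verdict row per protein: `seq_id`, `family`,
#'   `domain_complete`, `presequence_room`, `consensus`, `evidence`
#'   (collapsed `predictor:variant:call` string).
#' @export
screen_proteins <- function(records, hits, calls,
                            family = c("enolase", "pgam1", "pgam2")) {
  family <- match.arg(family)
  fam_models <- if (family == "enolase") c("Enolase_N", "Enolase_C") else "His_Phos"
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    h <- dplyr::filter(hits, .data$seq_id == rec$seq_id,
                       .data$model_name %in% fam_models)
    if (nrow(h) == 0L) {
      stop("no family domain hits for ", rec$seq_id,
           ": family undeterminable", call. = FALSE)
    }
    covs <- h |>
      dplyr::group_by(.data$model_name) |>
      dplyr::summarise(cov = domain_coverage(dplyr::pick(dplyr::everything())),
                       .groups = "drop")
    cov_map <- stats::setNames(as.list(covs$cov), covs$model_name)
    complete <- family_completeness(cov_map, family)
    room <- presequence_room(h)
    cl <- dplyr::filter(calls, .data$seq_id == rec$seq_id)
    cons <- consensus_localization(cl, rec$lineage_class)
    if (!complete || !room) {
      cons <- list(consensus = "other",
                   evidence = cons$evidence[0, ])
    }
    tibble::tibble(
      seq_id = rec$seq_id, family = family,
      domain_complete = complete, presequence_room = room,
      consensus = cons$consensus,
      evidence = paste(cons$evidence$predictor, cons$evidence$variant,
                       cons$evidence$call, sep = ":", collapse = ";")
    )
  })
}

#' Write localization verdicts to TSV
#'
#' @param verdicts Tibble from [screen_proteins()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  readr::write_tsv(verdicts, path)
  invisible(path)
}
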