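random_clade <- function(n, prefix, edge_rate) {
  if (n == 1L) {
    return(sprintf("%s_1:%.6f", prefix, stats::rexp(1, edge_rate)))
  }
  cl <- ape::rtree(n, br = function(k) stats::rexp(k, edge_rate))
  cl$tip.label <- sprintf("%s_%d", prefix, seq_len(n))
  sub(";$", "", ape::write.tree(cl))
}

clade_edge_children <- function(tree, clade_tips) {
  mrca <- ape::getMRCA(tree, clade_tips)
  if (is.null(mrca)) mrca <- which(tree$tip.label == clade_tips[1L])
  desc <- phangorn::Descendants(tree, mrca, type = "all")
  if (mrca <= ape::Ntip(tree)) desc <- mrca  # single-tip clade: its own edge
  intersect(tree$edge[, 2], desc)
}

#' Simulate a labeled reference tree with grafted environmental tips
#'
#' Builds two reference clades (diatom plastid-targeted references and other
#' references) with random topologies and exponential branch lengths, joined
#' by two long stem edges, then grafts each environmental tip onto an edge
#' strictly inside the diatom clade with probability `1 - p_misplaced`,
#' otherwise inside the other-reference clade. Because placement is by
#' grafting, the retention truth is exact: a tip grafted inside the diatom
#' clade must be retained by the monophyly filter and one grafted elsewhere
#' must not. The long stems (relative to the exponential clade edges)
#' guarantee the tree diameter midpoint falls on a stem edge, so midpoint
#' rooting keeps both reference clades intact.
#'
#' @param n_diatom_refs,n_other_refs Reference tip counts (>= 1).
#' @param n_env Environmental tip count (>= 1).
#' @param p_misplaced Probability an environmental tip is grafted outside
#'   the diatom clade.
#' @param seed Integer seed.
#' @param stem_length Length of each stem edge joining the two reference
#'   clades (default 10).
#' @param edge_rate Rate of the exponential clade edge lengths (default 5,
#'   i.e. mean 0.2).
#' @return List with `tree` (`ape::phylo`), `labels` (tibble `tip_id`,
#'   `category`) and `truth` (tibble `tip_id`, `placed_in`,
#'   `retained_truth`).
#' @export
simulate_labeled_tree <- function(n_diatom_refs = 6, n_other_refs = 6,
                                  n_env = 10, p_misplaced = 0, seed = 1,
                                  stem_length = 10, edge_rate = 5) {
  stopifnot(n_diatom_refs >= 1, n_other_refs >= 1, n_env >= 1,
            p_misplaced >= 0, p_misplaced <= 1)
  set.seed(seed)
  txt <- sprintf("(%s:%.1f,%s:%.1f);",
                 random_clade(n_diatom_refs, "dia", edge_rate), stem_length,
                 random_clade(n_other_refs, "oth", edge_rate), stem_length)
  tree <- ape::read.tree(text = txt)
  dia_tips <- sprintf("dia_%d", seq_len(n_diatom_refs))
  oth_tips <- sprintf("oth_%d", seq_len(n_other_refs))
  placed <- character(n_env)
  for (j in seq_len(n_env)) {
    in_diatom <- stats::runif(1) >= p_misplaced
    placed[j] <- if (in_diatom) "diatom" else "other"
    clade_tips <- if (in_diatom) dia_tips else oth_tips
    children <- clade_edge_children(tree, clade_tips)
    child <- if (length(children) == 1L) children else sample(children, 1L)
    elen <- tree$edge.length[tree$edge[, 2] == child]
    tree <- phytools::bind.tip(
      tree, sprintf("env_%d", j),
      edge.length = stats::rexp(1, edge_rate) + 0.01,
      where = child, position = stats::runif(1, 0, elen)
    )
  }
  env_tips <- sprintf("env_%d", seq_len(n_env))
  labels <- tibble::tibble(
    tip_id = c(dia_tips, oth_tips, env_tips),
    category = c(rep("diatom_plastid_ref", n_diatom_refs),
                 rep("other_ref", n_other_refs),
                 rep("environmental", n_env))
  )
  truth <- tibble::tibble(tip_id = env_tips, placed_in = placed,
                          retained_truth = placed == "diatom")
  list(tree = tree, labels = labels, truth = truth)
}

#' Simulate localization-screen inputs with known truth
#'
#' Generates candidate proteins of one family across ground-truth
#' localization classes, together with internally consistent domain-hit
#' tables and sequences: `plastid` and `mitochondrion` proteins carry
#' complete domains starting after residue 20; `no_room` proteins have
#' plastid predictor support but a domain starting inside the first 20 aa;
#' `incomplete` proteins fail the family coverage gate; `cytosolic`
#' proteins are structurally sound but draw no targeting calls.
#'
#' @param n_per_class Named integer vector over classes `plastid`,
#'   `mitochondrion`, `cytosolic`, `no_room`, `incomplete`.
#' @param family `"enolase"`, `"pgam1"` or `"pgam2"`.
#' @param lineage_class Lineage used for every simulated protein.
#' @param seed Integer seed.
#' @return List with `records`, `hits`, `truth` tibbles (predictor calls
#'   come from [simulate_predictor_table()]).
#' @export
simulate_protein_set <- function(n_per_class = c(plastid = 4, mitochondrion = 2,
                                                 cytosolic = 2, no_room = 2,
                                                 incomplete = 2),
                                 family = c("enolase", "pgam1", "pgam2"),
                                 lineage_class = "secondary_plastid",
                                 seed = 1) {
  family <- match.arg(family)
  set.seed(seed)
  models <- if (family == "enolase") {
    tibble::tibble(model_name = c("Enolase_N", "Enolase_C"),
                   model_length = c(130L, 296L))
  } else {
    tibble::tibble(model_name = "His_Phos", model_length = 176L)
  }
  classes <- rep(names(n_per_class), n_per_class)
  aa <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]]  # no M: Met placed on purpose
  recs <- list(); hits <- list()
  for (i in seq_along(classes)) {
    cls <- classes[i]
    id <- sprintf("seq_%02d_%s", i, cls)
    ali_from <- if (cls == "no_room") sample(1:20, 1) else sample(30:60, 1)
    h <- models
    h$seq_id <- id
    # model span: full for all but the 'incomplete' class
    frac <- if (cls == "incomplete") 0.40 else 1.00
    h$hmm_from <- 1L
    h$hmm_to <- pmax(1L, as.integer(floor(frac * h$model_length)))
    span <- h$hmm_to - h$hmm_from
    # successive domains occupy successive stretches of the sequence
    h$ali_from <- ali_from + cumsum(c(0L, utils::head(span + 6L, -1L)))
    h$ali_to <- h$ali_from + span
    h$i_evalue <- 10^stats::runif(nrow(h), -60, -20)
    seq_len_total <- max(h$ali_to) + 30L
    body <- sample(aa, seq_len_total, replace = TRUE)
    body[c(1L, 25L)] <- "M"  # start Met plus an internal Met for trimming
    recs[[i]] <- tibble::tibble(
      seq_id = id, sequence = paste(body, collapse = ""),
      lineage_class = lineage_class, true_localization = switch(
        cls, plastid = "plastid", mitochondrion = "mitochondrion", "other"
      ),
      class = cls
    )
    hits[[i]] <- h
  }
  records <- dplyr::bind_rows(recs)
  list(
    records = dplyr::select(records, "seq_id", "sequence", "lineage_class"),
    hits = dplyr::select(dplyr::bind_rows(hits), "seq_id", "model_name",
                         "model_length", "hmm_from", "hmm_to", "ali_from",
                         "ali_to", "i_evalue"),
    truth = dplyr::select(records, "seq_id", "class", "true_localization",
                          "lineage_class")
  )
}

#' Simulate targeting-predictor call tables with stated error rates
#'
#' Emits one call per (sequence, predictor, variant) conditioned on the true
#' localization. Plastid-qualifying predictors for the sequence's lineage
#' call `plastid` on truly plastid proteins with probability `sensitivity`,
#' and on non-plastid proteins with probability `1 - specificity`. HECTAR
#' additionally calls `mitochondrion` on truly mitochondrial proteins with
#' probability `sensitivity`. MitoFates emits a presequence probability
#' score drawn above its 0.35 threshold with probability `sensitivity` for
#' mitochondrial proteins and below it with probability `specificity`
#' otherwise. WoLFPSORT calls are emitted for realism but never used by the
#' consensus.
#'
#' @param truth Tibble with `seq_id`, `true_localization`, `lineage_class`.
#' @param sensitivity,specificity Per-call error rates in \[0, 1\], applied
#'   to every predictor.
#' @param seed Integer seed.
#' @return Tibble of predictor calls (`seq_id`, `variant`, `predictor`,
#'   `call`, `score`).
#' @export
simulate_predictor_table <- function(truth, sensitivity = 1, specificity = 1,
                                     seed = 1) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  set.seed(seed)
  variants <- c("complete", "met_trimmed")
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    plastid_tools <- qualifying_plastid_predictors(tr$lineage_class)
    purrr::map_dfr(variants, function(v) {
      rows <- list()
      for (tool in plastid_tools) {
        if (tr$true_localization == "plastid") {
          call <- if (stats::runif(1) < sensitivity) "plastid" else "other"
        } else if (tool == "HECTAR" && tr$true_localization == "mitochondrion") {
          call <- if (stats::runif(1) < sensitivity) "mitochondrion" else "other"
        } else {
          call <- if (stats::runif(1) < specificity) "other" else "plastid"
        }
        rows[[tool]] <- tibble::tibble(predictor = tool, call = call,
                                       score = NA_real_)
      }
      mf_high <- if (tr$true_localization == "mitochondrion") {
        stats::runif(1) < sensitivity
      } else {
        stats::runif(1) >= specificity
      }
      rows[["MitoFates"]] <- tibble::tibble(
        predictor = "MitoFates",
        call = if (mf_high) "mitochondrion" else "other",
        score = if (mf_high) stats::runif(1, 0.35, 1) else stats::runif(1, 0, 0.34)
      )
      rows[["WoLFPSORT"]] <- tibble::tibble(
        predictor = "WoLFPSORT",
        call = sample(c("plastid", "mitochondrion", "secretory", "other"), 1),
        score = NA_real_
      )
      dplyr::mutate(dplyr::bind_rows(rows), seq_id = tr$seq_id, variant = v,
                    .before = 1)
    })
  })
}

#' Simulate station metadata and meta-gene abundances
#'
#' Latitudes are uniform over `lat_range`; meta-genome counts are negative
#' binomial around `baseline_metaG` (Poisson in the large-`dispersion`
#' limit); meta-transcriptome counts are negative binomial around
#' `metaG * 10^(effect_beta * |latitude|/90 + noise)` with lognormal noise of
#' SD `noise_sd` (log10 units), emulating higher expression of the gene
#' family toward the poles without a commensurate gene-abundance increase.
#' Temperature decreases and day length increases with absolute latitude.
#'
#' @param n_stations Station count (>= 6).
#' @param lat_range Latitude range in degrees.
#' @param effect_beta Latitude effect on log10 metaT/metaG (0 = null).
#' @param dispersion Negative-binomial size parameter (> 0).
#' @param baseline_metaG Mean meta-genome count per station.
#' @param noise_sd SD of the station-level lognormal expression noise
#'   (log10 units).
#' @param diatom_total Total diatom metaT reads per station.
#' @param seed Integer seed.
#' @return List with `stations`, `abundances` and `truth` tibbles.
#' @export
simulate_station_abundances <- function(n_stations = 40,
                                        lat_range = c(-80, 80),
                                        effect_beta = 1, dispersion = 2,
                                        baseline_metaG = 50, noise_sd = 0.2,
                                        diatom_total = 1e6, seed = 1) {
  stopifnot(n_stations >= 6, dispersion > 0, baseline_metaG > 0)
  set.seed(seed)
  lat <- stats::runif(n_stations, lat_range[1], lat_range[2])
  station_id <- sprintf("TARA_%03d", seq_len(n_stations))
  metaG <- stats::rnbinom(n_stations, size = dispersion, mu = baseline_metaG)
  mu_t <- metaG * 10^(effect_beta * abs(lat) / 90 +
                        stats::rnorm(n_stations, 0, noise_sd))
  metaT <- ifelse(mu_t > 0,
                  stats::rnbinom(n_stations, size = dispersion, mu = mu_t), 0)
  stations <- tibble::tibble(
    station_id = station_id, latitude = lat, depth_layer = "SRF",
    size_fraction = "0.8-2000",
    temperature = 28 - 0.3 * abs(lat) + stats::rnorm(n_stations, 0, 1.5),
    day_length = 12 + 6 * abs(lat) / 90 + stats::rnorm(n_stations, 0, 0.5)
  )
  abundances <- tibble::tibble(
    meta_gene_id = "cpEnolase_meta", station_id = station_id,
    depth_layer = "SRF", size_fraction = "0.8-2000",
    metaT = as.numeric(metaT), metaG = as.numeric(metaG),
    diatom_total_metaT = diatom_total
  )
  truth <- tibble::tibble(
    meta_gene_id = "cpEnolase_meta", effect_beta = effect_beta,
    dispersion = dispersion, baseline_metaG = baseline_metaG,
    noise_sd = noise_sd
  )
  list(stations = stations, abundances = abundances, truth = truth)
}

#' Simulate a logistic growth curve
#'
#' Density follows `N(t) = K / (1 + (K/N0 - 1) 2^(-rate t))`, the logistic
#' trajectory whose early slope on the log2 scale equals `rate` divisions
#' per day, with multiplicative lognormal noise of coefficient of variation
#' `cv`; observations are capped at the carrying capacity.
#'
#' @param times Sampling times in days (default daily over two weeks).
#' @param N0 Inoculation density, cells/mL.
#' @param rate Division rate, divisions/day (> 0).
#' @param K Carrying capacity, cells/mL (> N0); `Inf` gives a pure
#'   exponential.
#' @param cv Lognormal noise CV (0 = noiseless).
#' @param seed Integer seed.
#' @param line_id,condition Labels carried into the output.
#' @return List with `curve` (tibble `line_id`, `condition`, `time_days`,
#'   `cells_per_ml`) and `truth` (generating parameters).
#' @export
simulate_growth <- function(times = 0:14, N0 = 1e4, rate = 1, K = 2e7,
                            cv = 0.05, seed = 1, line_id = "line_1",
                            condition = "19C_LD") {
  stopifnot(rate > 0, K > N0, N0 > 0, cv >= 0)
  set.seed(seed)
  mean_n <- if (is.infinite(K)) {
    N0 * 2^(rate * times)
  } else {
    K / (1 + (K / N0 - 1) * 2^(-rate * times))
  }
  obs <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    pmin(mean_n * stats::rlnorm(length(times), -sdlog^2 / 2, sdlog), K)
  } else {
    mean_n
  }
  list(
    curve = tibble::tibble(line_id = line_id, condition = condition,
                           time_days = times, cells_per_ml = obs),
    truth = tibble::tibble(line_id = line_id, rate = rate, N0 = N0, K = K,
                           cv = cv)
  )
}

#' Simulate a steady-state light-curve fluorometry trace
#'
#' The irradiance protocol is an initial 35 umol photons m-2 s-1 step
#' followed by six increasing steps to 750 (intermediate values
#' configurable). rETR and NPQ follow the saturation and sigmoid models;
#' the fluorescence steps are back-computed so the derived parameters
#' reproduce the generating curves exactly at zero noise:
#' `FM' = FM / (1 + NPQ(E))` and `Fs = FM' (1 - rETR(E)/E)`. Gaussian noise
#' of SD `noise_sd` (fluorescence units) is added to `Fs` and `FM'`.
#'
#' @param E_grid Irradiance steps.
#' @param retr_m,alpha Generating rETR saturation parameters.
#' @param npq_m,e50,n_sig Generating NPQ sigmoid parameters.
#' @param f0,fm Dark-step fluorescence levels (FM > F0 > 0).
#' @param noise_sd Gaussian fluorescence noise SD (0 = noiseless).
#' @param seed Integer seed.
#' @param line_id Label carried into the output.
#' @return List with `trace` (fluorometry tibble) and `truth`.
#' @export
simulate_light_curve <- function(E_grid = c(35, 100, 170, 250, 340, 450, 750),
                                 retr_m = 60, alpha = 0.3, npq_m = 2,
                                 e50 = 200, n_sig = 2, f0 = 150, fm = 430,
                                 noise_sd = 0, seed = 1, line_id = "line_1") {
  stopifnot(retr_m > 0, alpha > 0, npq_m >= 0, e50 > 0, n_sig > 0,
            fm > f0, f0 > 0, noise_sd >= 0)
  set.seed(seed)
  retr <- retr_model(E_grid, retr_m, alpha)
  phi <- retr / E_grid
  stopifnot(all(phi < 1))
  npq <- npq_model(E_grid, npq_m, e50, n_sig)
  fm_prime <- fm / (1 + npq)
  fs <- fm_prime * (1 - phi)
  if (noise_sd > 0) {
    fm_prime <- fm_prime + stats::rnorm(length(E_grid), 0, noise_sd)
    fs <- fs + stats::rnorm(length(E_grid), 0, noise_sd)
    fm_prime <- pmax(fm_prime, 1e-6)
    fs <- pmin(pmax(fs, 1e-6), fm_prime)
  }
  list(
    trace = tibble::tibble(
      line_id = line_id, step = seq_along(E_grid), E = E_grid,
      F0 = f0, FM = fm, Fs = fs, FM_prime = fm_prime
    ),
    truth = tibble::tibble(line_id = line_id, retr_m = retr_m, alpha = alpha,
                           E_K = retr_m / alpha, npq_m = npq_m, e50 = e50,
                           n_sig = n_sig, noise_sd = noise_sd)
  )
}

#' Simulate paired differential-expression tables with a known shared set
#'
#' Builds two knockout-versus-control comparison tables over a common gene
#' universe in which a designated subset is upregulated (fold-change > 2,
#' p < 0.05) in both comparisons, and chloroplast-targeting annotations in
#' which the shared set is enriched at a configurable rate over the
#' background.
#'
#' @param n_genes Background gene count.
#' @param n_shared_up Genes upregulated in both comparisons.
#' @param cp_rate_shared,cp_rate_background Chloroplast-predicted rates in
#'   the shared set and the rest of the background.
#' @param seed Integer seed.
#' @return List with `compA`, `compB`, `annotations`, `truth`.
#' @export
simulate_deg_tables <- function(n_genes = 500, n_shared_up = 40,
                                cp_rate_shared = 0.4,
                                cp_rate_background = 0.1, seed = 1) {
  stopifnot(n_shared_up < n_genes)
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  shared <- sort(sample(genes, n_shared_up))
  make_comp <- function() {
    up <- genes %in% shared
    tibble::tibble(
      gene_id = genes,
      fold_change = ifelse(up, stats::runif(n_genes, 2.5, 8),
                           stats::runif(n_genes, 0.5, 1.8)),
      p_value = ifelse(up, stats::runif(n_genes, 1e-6, 0.01),
                       stats::runif(n_genes, 0.2, 1)),
      direction = ifelse(up, "up", sample(c("up", "down"), n_genes, TRUE))
    )
  }
  annotations <- tibble::tibble(
    gene_id = genes,
    chloroplast_predicted = ifelse(
      genes %in% shared,
      stats::runif(n_genes) < cp_rate_shared,
      stats::runif(n_genes) < cp_rate_background
    )
  )
  list(compA = make_comp(), compB = make_comp(),
       annotations = annotations,
       truth = tibble::tibble(gene_id = shared))
}

#' Write domain hits in hmmscan `--domtblout` layout
#'
#' Produces a syntactically valid `--domtblout` file (comment header,
#' whitespace-aligned columns, one row per domain) that round-trips through
#' [parse_domtblout()].
#'
#' @param hits Tibble with `seq_id`, `model_name`, `model_length`,
#'   `hmm_from`, `hmm_to`, `ali_from`, `ali_to`, `i_evalue`.
#' @param path Output path.
#' @param qlen Optional per-row query sequence lengths (defaults to
#'   `ali_to + 30`).
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path, qlen = NULL) {
  if (is.null(qlen)) qlen <- hits$ali_to + 30L
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    paste(
      h$model_name, "-", h$model_length, h$seq_id, "-", qlen[i],
      format(h$i_evalue, scientific = TRUE, digits = 2), "100.0", "0.1",
      "1", "1",
      format(h$i_evalue, scientific = TRUE, digits = 2),
      format(h$i_evalue, scientific = TRUE, digits = 2),
      "99.0", "0.1", h$hmm_from, h$hmm_to, h$ali_from, h$ali_to,
      max(1L, h$ali_from - 2L), h$ali_to + 2L, "0.95", "synthetic fixture",
      sep = " "
    )
  }, character(1))
  header <- c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  )
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}

#' Write BLAST hits in tabular `-outfmt 6` layout
#'
#' @param rows Tibble with at least `qseqid`, `sseqid`, `evalue`,
#'   `bitscore`; the remaining standard columns are filled with plausible
#'   values when absent.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast6 <- function(rows, path) {
  defaults <- tibble::tibble(
    pident = 85.0, length = 300L, mismatch = 40L, gapopen = 2L,
    qstart = 1L, qend = 300L, sstart = 1L, send = 300L
  )
  for (col in names(defaults)) {
    if (!col %in% names(rows)) rows[[col]] <- defaults[[col]]
  }
  out <- rows[, c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

write_fasta <- function(sequences, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  } else {
    writeLines(paste0(">", names(sequences), "\n", unname(sequences)), path)
  }
  invisible(path)
}

#' Generate a complete ground-truthed demo workspace
#'
#' Writes seeded fixtures for every pipeline stage into `dir`, in the
#' formats the stages consume: protein FASTA, hmmscan domtblout, predictor
#' and lineage TSVs for the localization screen; newick tree, labeling,
#' e-value and BLAST tables for the environmental sieve; station and
#' abundance TSVs; growth and fluorometry TSVs; per-stage truth tables; and
#' a run manifest (JSON) echoing the seed and parameters.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param p_misplaced Misplacement probability for environmental tips.
#' @param sensitivity,specificity Predictor error rates.
#' @param effect_beta Latitude effect for the abundance simulation.
#' @param growth_cv Growth-curve noise CV.
#' @param lc_noise_sd Fluorometry noise SD.
#' @return Invisibly, a named list of all generated objects.
#' @export
simulate_workspace <- function(dir, seed = 1, p_misplaced = 0,
                               sensitivity = 1, specificity = 1,
                               effect_beta = 1, growth_cv = 0.05,
                               lc_noise_sd = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)

  prot <- simulate_protein_set(seed = seed)
  calls <- simulate_predictor_table(prot$truth, sensitivity, specificity,
                                    seed = seed + 1L)
  write_fasta(stats::setNames(prot$records$sequence, prot$records$seq_id),
              fp("proteins.fasta"))
  write_domtblout(prot$hits, fp("proteins.domtblout"))
  readr::write_tsv(calls, fp("predictor_calls.tsv"))
  readr::write_tsv(prot$records[, c("seq_id", "lineage_class")],
                   fp("lineage_map.tsv"))
  readr::write_tsv(prot$truth, fp("truth_localization.tsv"))

  sim_tree <- simulate_labeled_tree(p_misplaced = p_misplaced,
                                    seed = seed + 2L)
  ape::write.tree(sim_tree$tree, fp("tree.nwk"))
  readr::write_tsv(sim_tree$labels, fp("tip_labels.tsv"))
  readr::write_tsv(sim_tree$truth, fp("truth_retention.tsv"))
  env_ids <- sim_tree$truth$tip_id
  evalues <- tibble::tibble(id = env_ids, evalue = 10^stats::runif(
    length(env_ids), -60, -15
  ))
  readr::write_tsv(evalues, fp("evalues.tsv"))
  genome_rows <- tibble::tibble(
    qseqid = env_ids, sseqid = "Phatr3_J41515",
    evalue = 1e-50, bitscore = 300
  )
  write_blast6(genome_rows, fp("blast_genome.tsv"))
  align_rows <- tibble::tibble(
    qseqid = env_ids, sseqid = "dia_1", evalue = 1e-45, bitscore = 280
  )
  write_blast6(align_rows, fp("blast_alignment.tsv"))

  abund <- simulate_station_abundances(effect_beta = effect_beta,
                                       seed = seed + 3L)
  readr::write_tsv(abund$stations, fp("stations.tsv"))
  readr::write_tsv(abund$abundances, fp("abundances.tsv"))
  readr::write_tsv(abund$truth, fp("truth_abundance.tsv"))

  growth <- simulate_growth(cv = growth_cv, seed = seed + 4L)
  readr::write_tsv(growth$curve, fp("growth.tsv"))
  readr::write_tsv(growth$truth, fp("truth_growth.tsv"))

  lc <- simulate_light_curve(noise_sd = lc_noise_sd, seed = seed + 5L)
  readr::write_tsv(lc$trace, fp("fluorometry.tsv"))
  readr::write_tsv(lc$truth, fp("truth_lightcurve.tsv"))

  degs <- simulate_deg_tables(seed = seed + 6L)
  readr::write_tsv(degs$compA, fp("deg_A.tsv"))
  readr::write_tsv(degs$compB, fp("deg_B.tsv"))
  readr::write_tsv(degs$annotations, fp("annotations.tsv"))
  readr::write_tsv(degs$truth, fp("truth_shared_degs.tsv"))

  manifest <- list(
    seed = seed, p_misplaced = p_misplaced, sensitivity = sensitivity,
    specificity = specificity, effect_beta = effect_beta,
    growth_cv = growth_cv, lc_noise_sd = lc_noise_sd,
    files = list.files(dir)
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(proteins = prot, calls = calls, tree = sim_tree,
                 abundance = abund, growth = growth, light_curve = lc,
                 degs = degs))
}
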