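#' Keep candidate ids passing the homology-search e-value gate
#'
#' @param evalues Named numeric vector (names are candidate ids) of HMM
#'   search e-values.
#' @param threshold Inclusive retention threshold (default `1e-10`).
#' @return Character vector of retained ids.
#' @export
prefilter_evalue <- function(evalues, threshold = 1e-10) {
  stopifnot(is.numeric(evalues), !is.null(names(evalues)), all(evalues >= 0))
  sort(names(evalues)[evalues <= threshold])
}

# Edge length between two adjacent nodes, either orientation.
edge_length_between <- function(tree, a, b) {
  i <- which((tree$edge[, 1] == a & tree$edge[, 2] == b) |
               (tree$edge[, 1] == b & tree$edge[, 2] == a))
  if (length(i) != 1L) stop("nodes ", a, " and ", b, " are not adjacent")
  tree$edge.length[i]
}

#' Root a tree at the midpoint of its diameter
#'
#' Places the root halfway along the longest tip-to-tip path, so the two
#' diameter endpoints are equidistant from the root; this also minimises the
#' maximum root-to-tip distance. Ties for the diameter are broken by the
#' lexicographically smallest (sorted) tip-label pair, so rooting is
#' deterministic. If the midpoint falls exactly on an internal node, that
#' node becomes the root (a basal multifurcation is retained rather than
#' inserting a zero-length edge).
#'
#' @param tree An `ape::phylo` tree with branch lengths (rooted or
#'   unrooted).
#' @return A rooted `ape::phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0)) {
    stop("tree must have finite nonnegative branch lengths", call. = FALSE)
  }
  if (all(tree$edge.length == 0)) {
    stop("all branch lengths are zero: midpoint undefined", call. = FALSE)
  }
  ntip <- ape::Ntip(tree)
  stopifnot(ntip >= 2L)
  if (ntip == 2L) {
    d <- sum(tree$edge.length)
    tree$edge.length <- rep(d / 2, length(tree$edge.length))
    return(tree)
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  dmat <- ape::cophenetic.phylo(tree)
  diam <- max(dmat)
  cand <- which(dmat == diam, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  labs <- rownames(dmat)
  pair_key <- vapply(seq_len(nrow(cand)), function(i) {
    p <- sort(c(labs[cand[i, 1]], labs[cand[i, 2]]))
    paste(p, collapse = "\r")
  }, character(1))
  best <- cand[order(pair_key)[1L], ]
  t1 <- which(tree$tip.label == sort(c(labs[best[1]], labs[best[2]]))[1])
  t2 <- which(tree$tip.label == sort(c(labs[best[1]], labs[best[2]]))[2])
  path <- ape::nodepath(tree, t1, t2)
  target <- diam / 2
  eps <- 1e-12 * max(1, diam)
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    a <- path[k]; b <- path[k + 1L]
    len <- edge_length_between(tree, a, b)
    if (cum + len >= target - eps) {
      x <- target - cum  # distance from a along this edge
      if (x <= eps && a > ntip) {
        out <- ape::root(tree, node = a, resolve.root = FALSE)
      } else if (len - x <= eps && b > ntip) {
        out <- ape::root(tree, node = b, resolve.root = FALSE)
      } else {
        # identify parent -> child orientation of edge (a, b)
        if (any(tree$edge[, 1] == a & tree$edge[, 2] == b)) {
          child <- b; from_parent <- x
        } else {
          child <- a; from_parent <- len - x
        }
        out <- phytools::reroot(tree, child, position = from_parent)
      }
      return(ape::collapse.singles(out))
    }
    cum <- cum + len
  }
  stop("internal error: midpoint not located on diameter path")
}

#' Root a tree on the edge separating an outgroup from the ingroup
#'
#' @param tree An `ape::phylo` tree.
#' @param outgroup_tips Character vector of outgroup tip labels.
#' @return Rooted tree, with the root on the edge inducing the
#'   outgroup/ingroup bipartition. Errors when no edge induces that
#'   bipartition (outgroup not monophyletic in the unrooted sense).
#' @export
outgroup_root <- function(tree, outgroup_tips) {
  stopifnot(inherits(tree, "phylo"))
  missing_tips <- setdiff(outgroup_tips, tree$tip.label)
  if (length(missing_tips) > 0L) {
    stop("outgroup tips not in tree: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  }
  if (ape::is.rooted(tree) && ape::Ntip(tree) > 2L) tree <- ape::unroot(tree)
  if (!ape::is.monophyletic(tree, outgroup_tips)) {
    stop("outgroup does not induce a bipartition of the tree: ",
         paste(outgroup_tips, collapse = ", "), call. = FALSE)
  }
  ape::root(tree, outgroup = outgroup_tips, resolve.root = TRUE)
}

check_labels <- function(tree, labels) {
  stopifnot(all(c("tip_id", "category") %in% names(labels)))
  bad_cat <- setdiff(unique(labels$category),
                     c("diatom_plastid_ref", "other_ref", "environmental"))
  if (length(bad_cat) > 0L) {
    stop("unknown tip categories: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  unlabeled <- setdiff(tree$tip.label, labels$tip_id)
  if (length(unlabeled) > 0L) {
    stop("unlabeled tips: ", paste(unlabeled, collapse = ", "), call. = FALSE)
  }
  cats <- stats::setNames(labels$category, labels$tip_id)[tree$tip.label]
  if (sum(cats == "diatom_plastid_ref") < 1L || sum(cats == "other_ref") < 1L) {
    stop("need at least one diatom_plastid_ref and one other_ref tip",
         call. = FALSE)
  }
  cats
}

#' Retain environmental tips monophyletic with diatom plastid references
#'
#' For each environmental tip the tree is walked rootward to the smallest
#' ancestral clade containing at least one reference tip (of any category);
#' the tip is retained iff every reference tip in that anchor clade is a
#' diatom plastid-targeted reference. This is the topological reading of
#' "positions closer to diatom plastid-targeted proteins than to any
#' non-diatom or non-plastid sequence" on a midpoint-rooted tree; a
#' patristic-distance mode is available for sensitivity analysis (retain iff
#' the nearest reference by path length is a diatom plastid reference).
#'
#' @param tree A rooted `ape::phylo` tree.
#' @param labels Tibble with `tip_id` and `category` (one of
#'   `diatom_plastid_ref`, `other_ref`, `environmental`) covering every tip.
#' @param mode `"topology"` (default) or `"patristic"`.
#' @return Tibble with one row per environmental tip: `tip_id`, `retained`,
#'   `anchor_clade_size`, `anchor_ref_categories`.
#' @export
retain_env_tips <- function(tree, labels, mode = c("topology", "patristic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  cats <- check_labels(tree, labels)
  env_idx <- which(cats == "environmental")
  ref_idx <- which(cats != "environmental")
  if (mode == "patristic") {
    dmat <- ape::cophenetic.phylo(tree)
    return(purrr::map_dfr(env_idx, function(t) {
      d <- dmat[tree$tip.label[t], tree$tip.label[ref_idx]]
      nearest <- ref_idx[which(d == min(d))]
      near_cats <- sort(unique(unname(cats[nearest])))
      tibble::tibble(
        tip_id = tree$tip.label[t],
        retained = identical(near_cats, "diatom_plastid_ref"),
        anchor_clade_size = NA_integer_,
        anchor_ref_categories = paste(near_cats, collapse = ";")
      )
    }))
  }
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ape::Ntip(tree) + 1L
  desc <- phangorn::Descendants(tree, type = "tips")
  purrr::map_dfr(env_idx, function(t) {
    node <- parent_of[t]
    repeat {
      tips_in <- desc[[node]]
      refs_in <- intersect(tips_in, ref_idx)
      if (length(refs_in) > 0L || node == root) break
      node <- parent_of[node]
    }
    ref_cats <- sort(unique(unname(cats[refs_in])))
    tibble::tibble(
      tip_id = tree$tip.label[t],
      retained = identical(ref_cats, "diatom_plastid_ref"),
      anchor_clade_size = length(tips_in),
      anchor_ref_categories = paste(ref_cats, collapse = ";")
    )
  })
}

#' Run the full environmental meta-gene sieve
#'
#' Pipeline order: (1) homology-search e-value gate; (2) reciprocal best hit
#' against the reference genome, keeping queries whose best hit is an
#' enolase/PGAM gene; (3) reciprocal best hit against the curated alignment,
#' keeping queries whose best hit is a diatom plastid-targeted isoform;
#' (4) midpoint rooting and monophyletic retention on the tree.
#'
#' @param evalues Named numeric vector of candidate e-values.
#' @param blast_to_genome,blast_to_alignment BLAST outfmt-6 tibbles
#'   (queries are candidates).
#' @param genome_targets,alignment_targets Subject-id sets defining a
#'   qualifying best hit at each stage.
#' @param tree `ape::phylo` containing reference tips and the candidate
#'   environmental tips (rooted internally by [midpoint_root()]).
#' @param labels Tip labeling tibble as for [retain_env_tips()].
#' @param threshold E-value gate (default `1e-10`).
#' @param mode Retention mode passed to [retain_env_tips()].
#' @return List with `retained` (character vector) and `audit` (per-candidate
#'   tibble of stage survivals).
#' @export
run_sieve <- function(evalues, blast_to_genome, genome_targets,
                      blast_to_alignment, alignment_targets,
                      tree, labels, threshold = 1e-10,
                      mode = c("topology", "patristic")) {
  mode <- match.arg(mode)
  ids <- sort(names(evalues))
  if (length(ids) == 0L) {
    return(list(retained = character(),
                audit = tibble::tibble(id = character())))
  }
  s1 <- prefilter_evalue(evalues, threshold)
  s2 <- intersect(s1, reciprocal_best_hit(blast_to_genome, genome_targets))
  s3 <- intersect(s2, reciprocal_best_hit(blast_to_alignment, alignment_targets))
  audit <- tibble::tibble(
    id = ids,
    pass_evalue = ids %in% s1,
    pass_genome_rbh = ids %in% s2,
    pass_alignment_rbh = ids %in% s3
  )
  if (length(s3) == 0L) {
    audit$retained <- FALSE
    return(list(retained = character(), audit = audit))
  }
  missing_tips <- setdiff(s3, tree$tip.label)
  if (length(missing_tips) > 0L) {
    stop("sieve survivors missing from tree: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  rooted <- if (ape::is.rooted(tree)) tree else midpoint_root(tree)
  res <- retain_env_tips(rooted, labels, mode = mode)
  kept <- res$tip_id[res$retained]
  audit$retained <- audit$id %in% intersect(s3, kept)
  list(retained = sort(intersect(s3, kept)), audit = audit)
}
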