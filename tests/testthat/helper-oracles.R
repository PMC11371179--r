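# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: coverage by integer enumeration, midpoint by
# exhaustive edge placement, clade retention by explicit clade enumeration,
# ANOVA by aov() on raw data.

brute_coverage <- function(hmm_from, hmm_to, model_length) {
  covered <- logical(model_length)
  for (i in seq_along(hmm_from)) {
    covered[seq.int(hmm_from[i], hmm_to[i])] <- TRUE
  }
  sum(covered) / model_length
}

# Minimum over every possible root placement (any point on any edge) of the
# maximum root-to-tip distance, by closed-form minimisation per edge.
brute_min_eccentricity <- function(tree) {
  ntip <- ape::Ntip(tree)
  D <- ape::dist.nodes(tree)
  best <- Inf
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    L <- tree$edge.length[e]
    tips <- seq_len(ntip)
    child_side <- abs(D[tips, p] - (D[tips, ch] + L)) < 1e-9
    A <- max(D[tips[child_side], ch])
    B <- if (any(!child_side)) max(D[tips[!child_side], p]) else -Inf
    x <- min(max((B + L - A) / 2, 0), L)
    best <- min(best, max(A + x, B + L - x))
  }
  best
}

max_root_to_tip <- function(rooted) {
  ntip <- ape::Ntip(rooted)
  D <- ape::dist.nodes(rooted)
  max(D[ntip + 1L, seq_len(ntip)])
}

# Tip sets per node by direct recursion over the edge matrix (independent of
# phangorn).
node_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- max(tree$edge)
  sets <- vector("list", nnode)
  for (t in seq_len(ntip)) sets[[t]] <- t
  # process children before parents: order edges by child descending works
  # for ape's cladewise numbering only sometimes; iterate to fixpoint instead
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (!is.null(sets[[ch]])) {
        merged <- sort(union(sets[[p]], sets[[ch]]))
        if (!identical(merged, sets[[p]])) {
          sets[[p]] <- merged
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sets
}

# Brute-force retention: enumerate every clade, take the smallest
# reference-containing clade covering the tip, check purity.
brute_retention <- function(tree, labels) {
  cats <- stats::setNames(labels$category, labels$tip_id)[tree$tip.label]
  sets <- node_tip_sets(tree)
  ref_idx <- which(cats != "environmental")
  vapply(which(cats == "environmental"), function(t) {
    sizes <- vapply(sets, length, integer(1))
    containing <- which(vapply(seq_along(sets), function(n) {
      t %in% sets[[n]] && length(intersect(sets[[n]], ref_idx)) > 0
    }, logical(1)))
    anchor <- containing[which.min(sizes[containing])]
    refs <- intersect(sets[[anchor]], ref_idx)
    all(cats[refs] == "diatom_plastid_ref")
  }, logical(1))
}

# Random rooted tree with a valid labeling for the retention filter.
random_labeled_tree <- function(ntips) {
  tree <- ape::rtree(ntips)
  cats <- sample(c("diatom_plastid_ref", "other_ref", "environmental"),
                 ntips, replace = TRUE)
  # force at least one of each required category
  cats[sample(ntips, 3)] <- c("diatom_plastid_ref", "other_ref",
                              "environmental")
  list(tree = tree,
       labels = tibble::tibble(tip_id = tree$tip.label, category = cats))
}

anova_raw_oracle <- function(y1, y2) {
  y <- c(y1, y2)
  g <- factor(rep(c("a", "b"), c(length(y1), length(y2))))
  summary(stats::aov(y ~ g))[[1]][["Pr(>F)"]][1]
}
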