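#' Neighbour-joining tree from a K2P distance matrix
#'
#' Standard neighbour-joining agglomeration (via [ape::nj()]) with
#' negative branch-length estimates clamped to zero.  All pairwise
#' distances must be defined; saturated pairs make a distance matrix
#' unusable for tree building and are reported by name.
#'
#' @param dm a [distance_matrix()] result with at least 3 specimens.
#' @return An unrooted `phylo` tree whose tip labels are the specimen ids,
#'   with a `species` attribute (named character vector keyed by tip
#'   label).
#' @examples
#' tr <- nj_tree(distance_matrix(worked_fixture()))
#' @export
nj_tree <- function(dm) {
  stopifnot(inherits(dm, "k2p_dist"))
  n <- length(dm$ids)
  if (n < 3L) stop("input error: need at least 3 specimens for NJ")
  undef <- which(!dm$defined & upper.tri(dm$defined), arr.ind = TRUE)
  if (nrow(undef) > 0L) {
    pairs <- apply(undef, 1L, function(ij)
      paste(dm$ids[ij[1]], dm$ids[ij[2]], sep = " / "))
    stop("matrix error: undefined distance for pair(s): ",
         paste(utils::head(pairs, 5L), collapse = "; "),
         if (length(pairs) > 5L) " ...")
  }
  tr <- ape::nj(stats::as.dist(dm$values))
  tr$edge.length <- pmax(tr$edge.length, 0)
  attr(tr, "species") <- stats::setNames(dm$species, dm$ids)
  tr
}

#' Bootstrap NJ majority-rule consensus tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P distance
#' matrix and NJ tree per pseudo-replicate, and returns the 50%
#' majority-rule consensus with each retained bipartition's support (the
#' percentage of replicates containing it) stored in the node labels.
#' Replicates in which some pair becomes saturated (undefined distance)
#' are dropped and counted; a warning is attached when more than 10% are
#' dropped.
#'
#' @param aln a [labelled_alignment()].
#' @param replicates number of bootstrap pseudo-replicates (>= 1); 1000 is
#'   the conventional choice, smaller values are useful for exploration.
#' @param seed integer seed controlling the resampling; recorded on the
#'   result.
#' @return A `phylo` consensus tree with `node.label` support percentages
#'   and attributes `species`, `replicates`, `n_dropped`, `seed`,
#'   `split_support` (data frame of all observed bipartition supports) and
#'   `dropped_warning`.
#' @export
bootstrap_consensus <- function(aln, replicates = 1000, seed = NULL) {
  stopifnot(inherits(aln, "labelled_alignment"), replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(aln$seqs)
  trees <- vector("list", replicates)
  dropped <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- aln
    boot$seqs <- aln$seqs[, cols, drop = FALSE]
    dmb <- distance_matrix(boot)
    if (!all(dmb$defined)) {
      dropped <- dropped + 1L
      next
    }
    trees[[r]] <- nj_tree(dmb)
  }
  trees <- trees[!vapply(trees, is.null, TRUE)]
  n_used <- length(trees)
  if (n_used == 0L)
    stop("matrix error: every bootstrap replicate had undefined distances")
  class(trees) <- "multiPhylo"

  # bipartition frequencies across replicates, keyed canonically
  tab <- new.env(parent = emptyenv())
  for (tr in trees) {
    sp <- phylo_splits(tr)
    for (k in unique(sp$keys))
      assign(k, (if (exists(k, tab)) get(k, tab) else 0L) + 1L, tab)
  }
  keys <- ls(tab)
  freq <- vapply(keys, function(k) get(k, tab), 1L)
  support_pct <- 100 * freq / n_used

  cns <- ape::consensus(trees, p = 0.5)
  cns_sp <- phylo_splits(cns)
  # assign supports to consensus internal nodes by matching bipartitions
  parts <- ape::prop.part(cns)
  labs <- attr(parts, "labels")
  ntip <- length(labs)
  node_lab <- character(length(parts))
  for (i in seq_along(parts)) {
    clade <- labs[parts[[i]]]
    if (length(clade) >= ntip) { node_lab[i] <- ""; next }  # root
    k <- split_key(clade, labs)
    m <- match(k, keys)
    node_lab[i] <- if (!is.na(m)) sprintf("%.1f", support_pct[m]) else ""
  }
  cns$node.label <- node_lab
  attr(cns, "species") <- stats::setNames(aln$species, aln$specimen)
  attr(cns, "replicates") <- replicates
  attr(cns, "n_used") <- n_used
  attr(cns, "n_dropped") <- dropped
  attr(cns, "seed") <- seed
  attr(cns, "split_support") <- data.frame(split = keys,
                                           support = support_pct,
                                           row.names = NULL,
                                           stringsAsFactors = FALSE)
  attr(cns, "dropped_warning") <- dropped > 0.1 * replicates
  if (dropped > 0.1 * replicates)
    warning(dropped, " of ", replicates,
            " bootstrap replicates dropped (saturated distances)")
  cns
}

#' Per-species monophyly resolution from a supported tree
#'
#' A species is *resolved* when the unrooted bipartition separating
#' exactly its specimens from all others is present in the tree with
#' bootstrap support strictly above `cutoff` (default 60%).  The unrooted
#' bipartition criterion needs no outgroup.  Species with fewer than two
#' specimens cannot be tested for monophyly and are excluded (listed
#' separately); a species comprising all but one specimen corresponds to
#' a trivial bipartition, always present with full support.
#'
#' @param tree a `phylo` with support values in `node.label`, e.g. from
#'   [bootstrap_consensus()].
#' @param species named character vector mapping tip labels to species;
#'   defaults to the tree's `species` attribute.
#' @param cutoff support percentage that must be exceeded (default 60).
#' @return A list of class `resolution_report` with `per_species` (data
#'   frame `species`, `n`, `resolved`, `support`), `n_species_scored`,
#'   `n_resolved`, `pct_resolved`, `support_cutoff`, `excluded`
#'   (singleton species) and `n_individuals_resolved` (individuals
#'   belonging to resolved species).
#' @export
resolution_score <- function(tree, species = attr(tree, "species"),
                             cutoff = 60) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(species))
    stop("input error: no species labels supplied or attached to the tree")
  if (is.null(tree$node.label) || !any(nzchar(tree$node.label)))
    stop("input error: tree carries no support values")
  tips <- tree$tip.label
  if (!all(tips %in% names(species)))
    stop("scoring error: species label missing for tip(s): ",
         paste(setdiff(tips, names(species)), collapse = ", "))
  species <- species[tips]
  # prefer the full replicate-level split table when present (consensus
  # trees only retain majority splits)
  st <- attr(tree, "split_support")
  if (is.null(st)) {
    sp <- phylo_splits(tree)
    st <- data.frame(split = sp$keys, support = sp$support,
                     stringsAsFactors = FALSE)
  }
  counts <- table(species)
  multi <- names(counts)[counts >= 2L]
  rows <- lapply(multi, function(s) {
    members <- tips[species == s]
    if (length(members) >= length(tips) - 1L) {
      sup <- 100  # trivial bipartition, present in every tree
    } else {
      m <- match(split_key(members, tips), st$split)
      sup <- if (is.na(m)) 0 else st$support[m]
    }
    data.frame(species = s, n = length(members),
               resolved = !is.na(sup) && sup > cutoff,
               support = sup, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  structure(list(
    per_species = per,
    n_species_scored = nrow(per),
    n_resolved = sum(per$resolved),
    pct_resolved = if (nrow(per)) 100 * mean(per$resolved) else NA_real_,
    support_cutoff = cutoff,
    excluded = names(counts)[counts < 2L],
    n_individuals_resolved = sum(per$n[per$resolved])
  ), class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf(
    "Monophyly resolution (> %g%% support): %d / %d species (%.1f%%), %d individuals\n",
    x$support_cutoff, x$n_resolved, x$n_species_scored, x$pct_resolved,
    x$n_individuals_resolved))
  if (length(x$excluded))
    cat("  excluded singleton species:",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

# phyDat conversion: gaps, N and ambiguity codes become missing/ambiguous
aln_to_phydat <- function(aln) {
  phangorn::phyDat(aln$seqs, type = "DNA")
}

#' Fitch parsimony score of a tree on an alignment
#'
#' Sums the Fitch small-parsimony length over characters (gaps and
#' ambiguity codes treated as missing) and derives the consistency index
#' CI = (minimum conceivable length) / (tree length), the retention index
#' RI, and the rescaled consistency index RC = CI * RI.  Multifurcating
#' topologies are scored on an arbitrary binary resolution.  On an
#' invariant alignment the tree length is 0 and CI/RI/RC are flagged
#' undefined.
#'
#' @param tree a `phylo` over the alignment's specimens.
#' @param aln a [labelled_alignment()].
#' @return A list of class `parsimony_score` with `tree_length`,
#'   `n_characters`, `n_informative`, `ci`, `ri`, `rc`, `defined`.
#' @examples
#' aln <- worked_fixture()
#' fitch_score(nj_tree(distance_matrix(aln)), aln)
#' @export
fitch_score <- function(tree, aln) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "labelled_alignment"))
  if (!setequal(tree$tip.label, aln$specimen))
    stop("input error: tree tips and alignment specimens differ")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  dat <- aln_to_phydat(aln)
  len <- phangorn::fitch(tree, dat)
  st <- alignment_stats(aln)
  if (len == 0) {
    ci <- ri <- rc <- NA_real_
    defined <- FALSE
  } else {
    ci <- phangorn::CI(tree, dat)
    ri <- phangorn::RI(tree, dat)
    rc <- ci * ri
    defined <- TRUE
  }
  structure(list(tree_length = as.integer(len),
                 n_characters = ncol(aln$seqs),
                 n_informative = st$n_parsimony_informative,
                 ci = ci, ri = ri, rc = rc, defined = defined),
            class = "parsimony_score")
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat(sprintf("Parsimony: length %d over %d characters (%d informative)\n",
              x$tree_length, x$n_characters, x$n_informative))
  if (x$defined) {
    cat(sprintf("  CI %.4f  RI %.4f  RC %.4f\n", x$ci, x$ri, x$rc))
  } else cat("  CI/RI/RC undefined (tree length 0)\n")
  invisible(x)
}

#' Heuristic maximum-parsimony search
#'
#' Builds `n_starts` random stepwise-addition starting trees and
#' hill-climbs each by tree rearrangement (nearest-neighbour interchange
#' by default, subtree pruning and regrafting optionally) until no
#' improvement, returning the best tree found and its
#' [fitch_score()].  Deterministic under a fixed seed.
#'
#' @param aln a [labelled_alignment()] with at least 4 sequences.
#' @param n_starts number of random-addition starting trees (default 10).
#' @param seed integer seed; recorded on the result.
#' @param rearrangements `"NNI"` (default) or `"SPR"`.
#' @return A list of class `mp_result` with `tree` (best `phylo`),
#'   `score` (a `parsimony_score`), `n_starts`, `seed`.
#' @export
mp_search <- function(aln, n_starts = 10, seed = NULL,
                      rearrangements = c("NNI", "SPR")) {
  stopifnot(inherits(aln, "labelled_alignment"))
  rearrangements <- match.arg(rearrangements)
  if (nrow(aln$seqs) < 4L) stop("input error: need at least 4 specimens")
  if (!is.null(seed)) set.seed(seed)
  dat <- aln_to_phydat(aln)
  best <- NULL
  best_len <- Inf
  for (i in seq_len(n_starts)) {
    start <- phangorn::random.addition(dat)
    tr <- suppressMessages(
      phangorn::optim.parsimony(start, dat, method = "fitch",
                                rearrangements = rearrangements,
                                trace = 0))
    len <- phangorn::fitch(tr, dat)
    if (len < best_len) {
      best_len <- len
      best <- tr
    }
  }
  attr(best, "species") <- stats::setNames(aln$species, aln$specimen)
  structure(list(tree = best, score = fitch_score(best, aln),
                 n_starts = n_starts, seed = seed,
                 rearrangements = rearrangements),
            class = "mp_result")
}

#' @export
print.mp_result <- function(x, ...) {
  cat(sprintf("Maximum-parsimony search (%d random-addition starts, %s)\n",
              x$n_starts, x$rearrangements))
  print(x$score)
  invisible(x)
}

#' Write a tree as Newick with supports as internal node labels
#'
#' @param tree a `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
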