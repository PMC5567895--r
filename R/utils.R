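# internal helpers shared across modules

# map a character matrix/vector of bases to integer codes
# A=1, C=2, G=3, T=4; gaps, N and IUPAC ambiguity -> NA (treated as missing)
encode_bases <- function(x) {
  out <- match(x, c("A", "C", "G", "T"))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# pairwise site-pattern counts over all sequence pairs via indicator
# cross-products; code is an n x L integer matrix from encode_bases()
# returns n x n matrices: n_compared, ts (transitions), tv (transversions)
pair_counts <- function(code) {
  n <- nrow(code)
  L <- ncol(code)
  I <- lapply(1:4, function(b) {
    m <- matrix(0, n, L)
    m[which(code == b)] <- 1
    m
  })
  ok <- I[[1]] + I[[2]] + I[[3]] + I[[4]]
  n_comp <- ok %*% t(ok)
  same <- Reduce(`+`, lapply(I, function(m) m %*% t(m)))
  ts <- I[[1]] %*% t(I[[3]]) + I[[3]] %*% t(I[[1]]) +
    I[[2]] %*% t(I[[4]]) + I[[4]] %*% t(I[[2]])
  tv <- n_comp - same - ts
  list(n_compared = n_comp, ts = ts, tv = tv)
}

# canonical key for the bipartition separating `tips` from the rest of
# `all_tips`: the side not containing the reference (first, sorted) tip,
# sorted and collapsed.  Both sides of a split map to the same key.
split_key <- function(tips, all_tips) {
  ref <- sort(all_tips)[1L]
  side <- if (ref %in% tips) setdiff(all_tips, tips) else tips
  paste(sort(side), collapse = "\r")
}

# all non-trivial bipartitions of a phylo tree as canonical keys, with the
# support parsed from node labels (NA when absent); drops the root "split"
phylo_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)   # clades indexed by node number order
  labs <- attr(parts, "labels")
  nn <- length(parts)
  support <- rep(NA_real_, nn)
  if (!is.null(tree$node.label) && length(tree$node.label) == nn) {
    support <- suppressWarnings(as.numeric(tree$node.label))
  }
  keys <- character(0)
  sup <- numeric(0)
  for (i in seq_len(nn)) {
    clade <- labs[parts[[i]]]
    if (length(clade) <= 1L || length(clade) >= ntip - 1L) next
    keys <- c(keys, split_key(clade, labs))
    sup <- c(sup, support[i])
  }
  # the basal-most non-root node can duplicate the root split on rooted
  # shapes; keep the maximum support for duplicated keys
  if (anyDuplicated(keys)) {
    agg <- tapply(sup, keys, function(v) if (all(is.na(v))) NA_real_
                  else max(v, na.rm = TRUE))
    keys <- names(agg)
    sup <- as.numeric(agg)
  }
  list(keys = keys, support = sup, labels = labs)
}

# standard error of the mean (NA for fewer than 2 values)
se_mean <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

fmt_pct <- function(x) sprintf("%.2f", x)
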