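# Independent brute-force oracles and fixture builders shared by the
# tests.  These re-derive every quantity from first principles (explicit
# per-site / per-pair loops), deliberately avoiding the package's own
# vectorised implementations.

PURINES <- c("A", "G")
BASES <- c("A", "C", "G", "T")

# K2P by explicit site loop
oracle_k2p <- function(a, b) {
  n <- ts <- tv <- 0L
  for (i in seq_along(a)) {
    x <- a[i]; y <- b[i]
    if (x %in% BASES && y %in% BASES) {
      n <- n + 1L
      if (x != y) {
        if ((x %in% PURINES) == (y %in% PURINES)) ts <- ts + 1L
        else tv <- tv + 1L
      }
    }
  }
  if (n == 0L) return(list(P = NA, Q = NA, n = 0L, d = NA, defined = FALSE))
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(list(P = P, Q = Q, n = n, d = NA,
                                      defined = FALSE))
  list(P = P, Q = Q, n = n, d = -0.5 * log(w1) - 0.25 * log(w2),
       defined = TRUE)
}

# per-column recount of variable / parsimony-informative sites
oracle_site_counts <- function(mat) {
  nv <- np <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% BASES]
    tab <- table(col)
    if (length(tab) >= 2L) {
      nv <- nv + 1L
      if (sum(tab >= 2L) >= 2L) np <- np + 1L
    }
  }
  list(variable = nv, informative = np)
}

# random alignment with optional gaps / ambiguity, as a character matrix
random_alignment <- function(n, L, gap_prob = 0.05, amb_prob = 0.02) {
  pool <- BASES
  m <- matrix(sample(pool, n * L, replace = TRUE), n, L)
  if (gap_prob > 0)
    m[sample(length(m), round(gap_prob * length(m)))] <- "-"
  if (amb_prob > 0)
    m[sample(length(m), round(amb_prob * length(m)))] <-
      sample(c("N", "R", "Y", "W"), round(amb_prob * length(m)),
             replace = TRUE)
  m
}

random_labelled <- function(n_species = 3, per = 3, L = 40, ...) {
  n <- n_species * per
  labelled_alignment(
    random_alignment(n, L, ...),
    specimen = sprintf("q%02d", seq_len(n)),
    species = rep(sprintf("Sp_%02d", seq_len(n_species)), each = per))
}

# build a k2p_dist object directly from a distance matrix + labels
make_dm <- function(values, species, ids = NULL) {
  n <- nrow(values)
  if (is.null(ids)) ids <- sprintf("t%02d", seq_len(n))
  dimnames(values) <- list(ids, ids)
  defined <- !is.na(values)
  structure(list(ids = ids, species = species, values = values,
                 defined = defined,
                 n_compared = matrix(1L, n, n),
                 p_transition = values, q_transversion = values * 0),
            class = "k2p_dist")
}

# random symmetric distance matrix with zero diagonal
random_dm <- function(n_species = 3, per = 3, scale = 0.1) {
  n <- n_species * per
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- round(runif(n * (n - 1) / 2, 0, scale), 4)
  v <- v + t(v)
  make_dm(v, rep(sprintf("Sp_%02d", seq_len(n_species)), each = per))
}

# naive per-query classifier (BM / BCM / ASB) by explicit loops
oracle_classify <- function(dm, qi, method, threshold = Inf, tol = 1e-12) {
  d <- dm$values[qi, ]
  d[qi] <- NA
  cand <- which(!is.na(d) & d <= threshold + tol)
  if (length(cand) == 0L) return("no_match")
  if (method %in% c("BM", "BCM")) {
    dmin <- min(d[cand])
    best <- cand[d[cand] <= dmin + tol]
    hit <- dm$species[best] == dm$species[qi]
    if (all(hit)) "correct" else if (any(hit)) "ambiguous" else "incorrect"
  } else {
    con <- cand[dm$species[cand] == dm$species[qi]]
    het <- cand[dm$species[cand] != dm$species[qi]]
    if (length(con) == 0L) return("incorrect")
    if (length(het) == 0L) return("correct")
    if (max(d[con]) < min(d[het]) - tol) "correct"
    else if (min(d[het]) < max(d[con]) - tol) "incorrect"
    else "ambiguous"
  }
}

# Fitch small-parsimony length by exhaustive enumeration over internal
# node states (gap-free alignments; feasible for <= 6 taxa)
oracle_fitch <- function(tree, mat) {
  tree <- ape::multi2di(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- 0L
  tip_ix <- match(tree$tip.label, rownames(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[tip_ix, j]
    obs <- unique(col[col %in% BASES])
    if (length(obs) <= 1L) next
    grid <- expand.grid(rep(list(obs), nnode), stringsAsFactors = FALSE)
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      states <- c(col, unlist(grid[g, ]))
      cost <- 0L
      for (e in seq_len(nrow(tree$edge))) {
        p <- states[tree$edge[e, 1]]
        c0 <- states[tree$edge[e, 2]]
        if (c0 %in% BASES && p != c0) cost <- cost + 1L
      }
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

# does the unrooted bipartition {tips} | rest occur in the tree?
# independent edge-walk implementation
oracle_has_split <- function(tree, tips) {
  all_tips <- tree$tip.label
  ntip <- length(all_tips)
  desc <- function(node) {
    if (node <= ntip) return(all_tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    cl <- desc(node)
    if (setequal(cl, tips) || setequal(setdiff(all_tips, cl), tips))
      return(TRUE)
  }
  setequal(tips, all_tips)
}

# linear-interpolated percentile by the explicit order-statistic formula
oracle_percentile <- function(x, coverage) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * coverage / 100 + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# minimal divergence_summary stub carrying only an intra list
mk_summary_cl <- function(intra) {
  structure(list(intra_all = intra, intra_available = length(intra) > 0),
            class = "divergence_summary")
}

# path to a study alignment, were it supplied by the user
study_alignment_path <- function(name) {
  system.file("extdata", "study_alignments", paste0(name, ".fasta"),
              package = "barcodeval")
}
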