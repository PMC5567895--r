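#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K2P (Kimura 1980) distance with pairwise deletion: only
#' sites where both sequences carry an unambiguous base (`A`, `C`, `G` or
#' `T`) are compared.  With `P` the proportion of compared sites differing
#' by a transition (A<->G, C<->T) and `Q` the proportion differing by a
#' transversion,
#' \deqn{d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).}
#' The distance is undefined (saturated) when `1 - 2P - Q <= 0`, when
#' `1 - 2Q <= 0`, or when no site is comparable; this is reported via the
#' `defined` flag, not as an error.
#'
#' @param a,b equal-length aligned sequences: character vectors of single
#'   characters or single strings.
#' @return A list of class `k2p_result` with elements `p_transition`,
#'   `q_transversion`, `n_compared`, `distance`, `defined`.
#' @examples
#' k2p(strrep("A", 100), paste0(strrep("G", 10), strrep("A", 90)))
#' @export
k2p <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1L]]
  if (length(a) != length(b))
    stop("input error: sequences differ in length (", length(a), " vs ",
         length(b), ")")
  ca <- encode_bases(toupper(a))
  cb <- encode_bases(toupper(b))
  ok <- !is.na(ca) & !is.na(cb)
  n <- sum(ok)
  if (n == 0L) {
    return(structure(list(p_transition = NA_real_, q_transversion = NA_real_,
                          n_compared = 0L, distance = NA_real_,
                          defined = FALSE), class = "k2p_result"))
  }
  ca <- ca[ok]; cb <- cb[ok]
  diffs <- ca != cb
  # transitions: both purine (A,G -> codes 1,3) or both pyrimidine (2,4)
  ts <- sum(diffs & (ca %% 2L == cb %% 2L))
  tv <- sum(diffs) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- w1 > 0 && w2 > 0
  d <- if (defined) -0.5 * log(w1) - 0.25 * log(w2) else NA_real_
  structure(list(p_transition = P, q_transversion = Q, n_compared = n,
                 distance = d, defined = defined), class = "k2p_result")
}

#' @export
print.k2p_result <- function(x, ...) {
  cat("K2P distance: ",
      if (x$defined) sprintf("%.6f", x$distance) else "undefined (saturated)",
      sprintf("  [P=%.4f Q=%.4f over %d sites]\n",
              x$p_transition, x$q_transversion, x$n_compared), sep = "")
  invisible(x)
}

#' K2P distance matrix for a labelled alignment
#'
#' Evaluates [k2p()] for every unordered pair of sequences (pairwise
#' deletion per pair).  Saturated or incomparable pairs are recorded as
#' undefined in the mask and carry `NA` distances; they are excluded from
#' downstream summaries rather than clamped.
#'
#' @param aln a [labelled_alignment()].
#' @return An object of class `k2p_dist`: a list with `ids`, `species`,
#'   `values` (symmetric numeric matrix, zero diagonal, `NA` where
#'   undefined), `defined` (symmetric logical matrix), `n_compared`,
#'   `p_transition` and `q_transversion` matrices.
#' @examples
#' dm <- distance_matrix(worked_fixture())
#' @export
distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "labelled_alignment"))
  code <- encode_bases(aln$seqs)
  pc <- pair_counts(code)
  n <- nrow(code)
  P <- ifelse(pc$n_compared > 0, pc$ts / pc$n_compared, NA_real_)
  Q <- ifelse(pc$n_compared > 0, pc$tv / pc$n_compared, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- !is.na(P) & w1 > 0 & w2 > 0
  d <- matrix(NA_real_, n, n)
  d[defined] <- -0.5 * log(w1[defined]) - 0.25 * log(w2[defined])
  diag(d) <- 0
  diag(defined) <- TRUE
  dimnames(d) <- dimnames(defined) <- list(aln$specimen, aln$specimen)
  structure(list(ids = aln$specimen, species = aln$species, values = d,
                 defined = defined, n_compared = pc$n_compared,
                 p_transition = P, q_transversion = Q),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- length(x$ids)
  undef <- sum(!x$defined[upper.tri(x$defined)])
  cat("K2P distance matrix: ", n, " specimens, ",
      length(unique(x$species)), " species",
      if (undef > 0) paste0(", ", undef, " undefined pair(s)"), "\n",
      sep = "")
  invisible(x)
}

#' Intra- and inter-specific divergence summary
#'
#' Splits all defined pairwise distances into conspecific (intra-specific)
#' and heterospecific (inter-specific) sets and summarises each with its
#' range and mean with standard error.  Per species with at least two
#' members it also reports `theta` (mean conspecific distance) and the
#' coalescent depth (maximum conspecific distance).  Species represented
#' by a single specimen contribute nothing to the intra-specific
#' statistics and are listed separately.
#'
#' @param dm a [distance_matrix()] result.
#' @return An object of class `divergence_summary`: a list with
#'   `intra_all`, `inter_all` (numeric vectors of defined distances),
#'   `range_intra`, `range_inter`, `mean_intra`, `se_intra`, `mean_inter`,
#'   `se_inter`, `theta` (named per-species means), `coalescent_depth`
#'   (named per-species maxima), `singletons`, `n_undefined_pairs`.
#' @export
summarize_divergence <- function(dm) {
  stopifnot(inherits(dm, "k2p_dist"))
  n <- length(dm$ids)
  ut <- upper.tri(dm$values)
  same <- outer(dm$species, dm$species, `==`)
  intra <- dm$values[ut & same & dm$defined]
  inter <- dm$values[ut & !same & dm$defined]
  counts <- table(dm$species)
  multi <- names(counts)[counts >= 2L]
  theta <- cd <- stats::setNames(rep(NA_real_, length(multi)), multi)
  for (sp in multi) {
    ix <- which(dm$species == sp)
    vals <- dm$values[ix, ix][upper.tri(matrix(0, length(ix), length(ix)))]
    vals <- vals[!is.na(vals)]
    if (length(vals)) {
      theta[sp] <- mean(vals)
      cd[sp] <- max(vals)
    }
  }
  structure(list(
    intra_all = intra, inter_all = inter,
    range_intra = if (length(intra)) range(intra) else c(NA_real_, NA_real_),
    range_inter = if (length(inter)) range(inter) else c(NA_real_, NA_real_),
    mean_intra = if (length(intra)) mean(intra) else NA_real_,
    se_intra = se_mean(intra),
    mean_inter = if (length(inter)) mean(inter) else NA_real_,
    se_inter = se_mean(inter),
    theta = theta, coalescent_depth = cd,
    singletons = names(counts)[counts == 1L],
    n_undefined_pairs = sum(!dm$defined[ut]),
    intra_available = length(intra) > 0
  ), class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("Divergence summary (K2P, pairwise deletion)\n")
  if (x$intra_available) {
    cat(sprintf("  intra-specific: n=%d  range %.4f-%.4f  mean %.4f +/- %.4f\n",
                length(x$intra_all), x$range_intra[1], x$range_intra[2],
                x$mean_intra, x$se_intra))
  } else cat("  intra-specific: unavailable (no species with >= 2 members)\n")
  if (length(x$inter_all)) {
    cat(sprintf("  inter-specific: n=%d  range %.4f-%.4f  mean %.4f +/- %.4f\n",
                length(x$inter_all), x$range_inter[1], x$range_inter[2],
                x$mean_inter, x$se_inter))
  }
  if (length(x$singletons))
    cat("  singleton species:", paste(x$singletons, collapse = ", "), "\n")
  if (x$n_undefined_pairs > 0)
    cat("  undefined (saturated) pairs excluded:", x$n_undefined_pairs, "\n")
  invisible(x)
}

#' Write a distance matrix as TSV
#'
#' Writes either a square matrix (header row/column of specimen ids) or a
#' long-format table (`id1`, `id2`, `species1`, `species2`, `distance`,
#' `defined`) of the upper triangle.
#'
#' @param dm a [distance_matrix()] result.
#' @param path output path.
#' @param format `"square"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dm, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    utils::write.table(dm$values, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else {
    ij <- which(upper.tri(dm$values), arr.ind = TRUE)
    long <- data.frame(id1 = dm$ids[ij[, 1]], id2 = dm$ids[ij[, 2]],
                       species1 = dm$species[ij[, 1]],
                       species2 = dm$species[ij[, 2]],
                       distance = dm$values[ij],
                       defined = dm$defined[ij], stringsAsFactors = FALSE)
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
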