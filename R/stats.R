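#' Per-locus sequence characteristics
#'
#' Summarises an alignment the way barcode surveys tabulate their loci:
#' number of sequences, ungapped length range, aligned length, variable and
#' parsimony-informative site counts, mean GC content and the
#' transition/transversion (Ts/Tv) ratio.
#'
#' Site-state counting ignores gaps, `N` and IUPAC ambiguity codes: a
#' *variable* site has at least two distinct unambiguous bases; a
#' *parsimony-informative* site has at least two distinct unambiguous bases
#' each carried by at least two sequences.  Mean GC is computed over
#' unambiguous bases only.  The Ts/Tv ratio is the total number of
#' transition pairs divided by the total number of transversion pairs,
#' summed over all sequence pairs and sites (pairwise deletion); it is `NA`
#' (flagged undefined) when no transversion is observed.
#'
#' @param aln a [labelled_alignment()].
#' @return An object of class `alignment_stats`: a list with elements
#'   `locus`, `n_sequences`, `min_len`, `max_len` (ungapped bp, `-`
#'   removed), `aligned_length`, `n_variable_sites`, `pct_variable`,
#'   `n_parsimony_informative`, `mean_gc`, `ts_tv_ratio`,
#'   `ts_tv_defined`.
#' @examples
#' aln <- worked_fixture()
#' alignment_stats(aln)
#' @export
alignment_stats <- function(aln) {
  stopifnot(inherits(aln, "labelled_alignment"))
  m <- aln$seqs
  code <- encode_bases(m)          # 1..4 for A,C,G,T else NA
  n_var <- 0L
  n_pi <- 0L
  for (j in seq_len(ncol(code))) {
    tab <- tabulate(code[, j], nbins = 4L)
    states <- sum(tab > 0L)
    if (states >= 2L) {
      n_var <- n_var + 1L
      if (sum(tab >= 2L) >= 2L) n_pi <- n_pi + 1L
    }
  }
  ungapped <- nrow(m) - 0L
  lens <- apply(m, 1L, function(s) sum(s != "-"))
  gc <- sum(code == 2L | code == 3L, na.rm = TRUE) / sum(!is.na(code))
  pc <- pair_counts(code)
  ts <- sum(pc$ts[upper.tri(pc$ts)])
  tv <- sum(pc$tv[upper.tri(pc$tv)])
  structure(list(
    locus = aln$locus,
    n_sequences = nrow(m),
    min_len = min(lens), max_len = max(lens),
    aligned_length = ncol(m),
    n_variable_sites = n_var,
    pct_variable = 100 * n_var / ncol(m),
    n_parsimony_informative = n_pi,
    mean_gc = gc,
    ts_tv_ratio = if (tv > 0) ts / tv else NA_real_,
    ts_tv_defined = tv > 0
  ), class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat("Alignment statistics for '", x$locus, "'\n", sep = "")
  cat(sprintf("  sequences:               %d\n", x$n_sequences))
  cat(sprintf("  ungapped length (bp):    %d-%d\n", x$min_len, x$max_len))
  cat(sprintf("  aligned length (bp):     %d\n", x$aligned_length))
  cat(sprintf("  variable sites:          %d (%.2f%%)\n",
              x$n_variable_sites, x$pct_variable))
  cat(sprintf("  parsimony informative:   %d\n", x$n_parsimony_informative))
  cat(sprintf("  mean GC content:         %.4f\n", x$mean_gc))
  cat(sprintf("  Ts/Tv ratio:             %s\n",
              if (x$ts_tv_defined) sprintf("%.4f", x$ts_tv_ratio)
              else "undefined (no transversions)"))
  invisible(x)
}

#' Tabulate alignment statistics for several alignments
#'
#' @param alns list of [labelled_alignment()] objects.
#' @return data frame with one row per alignment, columns mirroring
#'   [alignment_stats()].
#' @export
stats_table <- function(alns) {
  rows <- lapply(alns, function(a) {
    s <- alignment_stats(a)
    data.frame(locus = s$locus, n = s$n_sequences,
               min_len = s$min_len, max_len = s$max_len,
               aligned_length = s$aligned_length,
               n_variable = s$n_variable_sites,
               pct_variable = s$pct_variable,
               n_parsimony_informative = s$n_parsimony_informative,
               mean_gc = s$mean_gc, ts_tv = s$ts_tv_ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concatenate loci over shared specimens
#'
#' Joins two or more single-locus alignments into one multilocus alignment,
#' keeping only rows present in every input.  With `join = "specimen"`
#' rows are matched by specimen id.  With `join = "species"` one
#' representative per species per locus is picked (the lexicographically
#' first specimen id) and rows are matched by species, which mimics
#' building a per-species reference concatenation when specimen sets
#' differ between loci.
#'
#' @param alns list of [labelled_alignment()] objects (at least 2).
#' @param join `"specimen"` (default) or `"species"`.
#' @param locus name for the result; default joins input names with `+`.
#' @return A [labelled_alignment()] whose `aligned_length` is the sum of
#'   the input lengths and whose `partitions` table records the locus
#'   boundaries (1-based, inclusive).
#' @examples
#' sim <- simulate_barcodes(sim_spec(n_species = 4, individuals = 3,
#'                                   seed = 1))
#' cat12 <- concatenate_alignments(sim[1:2])
#' @export
concatenate_alignments <- function(alns, join = c("specimen", "species"),
                                   locus = NULL) {
  join <- match.arg(join)
  if (length(alns) < 2L) stop("concatenation error: need at least 2 alignments")
  stopifnot(all(vapply(alns, inherits, TRUE, "labelled_alignment")))
  if (is.null(locus))
    locus <- paste(vapply(alns, `[[`, "", "locus"), collapse = "+")

  if (join == "species") {
    alns <- lapply(alns, function(a) {
      keep <- vapply(split(seq_along(a$specimen), a$species),
                     function(ix) ix[order(a$specimen[ix])][1L], 1L)
      labelled_alignment(a$seqs[keep, , drop = FALSE],
                         specimen = a$species[keep],
                         species = a$species[keep], locus = a$locus)
    })
  }
  key <- function(a) a$specimen
  shared <- Reduce(intersect, lapply(alns, key))
  if (length(shared) == 0L)
    stop("concatenation error: no ", join, " shared by all alignments")
  dup <- unlist(lapply(alns, function(a) a$specimen[duplicated(a$specimen)]))
  if (length(dup))
    stop("ambiguity error: duplicate specimen match for: ",
         paste(unique(dup), collapse = ", "))
  shared <- sort(shared)
  blocks <- lapply(alns, function(a) a$seqs[match(shared, a$specimen), ,
                                            drop = FALSE])
  lens <- vapply(blocks, ncol, 1L)
  ends <- cumsum(lens)
  parts <- data.frame(locus = vapply(alns, `[[`, "", "locus"),
                      start = c(1L, utils::head(ends, -1L) + 1L),
                      end = ends, stringsAsFactors = FALSE)
  species <- alns[[1L]]$species[match(shared, alns[[1L]]$specimen)]
  labelled_alignment(do.call(cbind, blocks), specimen = shared,
                     species = species, locus = locus, partitions = parts)
}
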