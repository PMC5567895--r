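# TaxonDNA-style identification: Best Match, Best Close Match,
# All Species Barcodes.  Ties on distance are detected with an absolute
# tolerance of 1e-12.

TIE_TOL <- 1e-12

verdict_from_best <- function(best_species, query_species) {
  hits <- best_species == query_species
  if (all(hits)) "correct" else if (any(hits)) "ambiguous" else "incorrect"
}

#' Best Match identification of one query
#'
#' Identifies a query specimen by its closest sequence(s) in the reference
#' alignment (the query itself excluded).  The verdict is `correct` when
#' every equally-best match is conspecific with the query, `incorrect`
#' when none is, and `ambiguous` when equally good matches span species.
#' A query with no defined distance to any candidate is `no_match`.
#'
#' @param dm a [distance_matrix()] result.
#' @param query specimen id (or row index) of the query.
#' @return A list of class `match_verdict` with `query_id`, `species`,
#'   `method`, `verdict`, `best_ids`, `best_distance`.
#' @export
best_match <- function(dm, query) {
  bcm_engine(dm, query, threshold = Inf, method = "BM")
}

#' Best Close Match identification of one query
#'
#' As [best_match()], but candidate matches are restricted to distances
#' at most `threshold` (the intra-species variability criterion).  When no
#' candidate lies within the threshold the query is `no_match`
#' (unidentified).
#'
#' @inheritParams best_match
#' @param threshold distance threshold (substitutions/site); the
#'   conventional default is 0.03, and [percentile_threshold()] derives a
#'   data-driven alternative.
#' @return A `match_verdict`, as for [best_match()].
#' @export
best_close_match <- function(dm, query, threshold = 0.03) {
  stopifnot(threshold >= 0)
  bcm_engine(dm, query, threshold = threshold, method = "BCM")
}

bcm_engine <- function(dm, query, threshold, method) {
  stopifnot(inherits(dm, "k2p_dist"))
  qi <- if (is.character(query)) match(query, dm$ids) else as.integer(query)
  if (is.na(qi) || qi < 1L || qi > length(dm$ids))
    stop("input error: unknown query '", query, "'")
  d <- dm$values[qi, ]
  d[qi] <- NA_real_
  ok <- which(!is.na(d) & d <= threshold + TIE_TOL)
  if (!length(ok)) {
    return(structure(list(query_id = dm$ids[qi], species = dm$species[qi],
                          method = method, verdict = "no_match",
                          best_ids = character(0),
                          best_distance = NA_real_),
                     class = "match_verdict"))
  }
  dmin <- min(d[ok])
  best <- ok[d[ok] <= dmin + TIE_TOL]
  structure(list(query_id = dm$ids[qi], species = dm$species[qi],
                 method = method,
                 verdict = verdict_from_best(dm$species[best],
                                             dm$species[qi]),
                 best_ids = dm$ids[best], best_distance = dmin),
            class = "match_verdict")
}

#' All Species Barcodes identification of one query
#'
#' The strictest TaxonDNA criterion: within the threshold, the query is
#' `correct` only if *every* conspecific sequence lies strictly closer
#' than every heterospecific sequence; `incorrect` when some
#' heterospecific is strictly closer than some conspecific; `ambiguous`
#' when the closest heterospecific ties the farthest conspecific (within
#' 1e-12).  A query whose species has no other representative within the
#' threshold cannot be `correct`.  No candidate within the threshold gives
#' `no_match`.
#'
#' @inheritParams best_close_match
#' @return A `match_verdict`; `best_ids` holds the nearest candidate(s).
#' @export
all_species_barcodes <- function(dm, query, threshold = 0.03) {
  stopifnot(inherits(dm, "k2p_dist"), threshold >= 0)
  qi <- if (is.character(query)) match(query, dm$ids) else as.integer(query)
  if (is.na(qi) || qi < 1L || qi > length(dm$ids))
    stop("input error: unknown query '", query, "'")
  d <- dm$values[qi, ]
  d[qi] <- NA_real_
  ok <- which(!is.na(d) & d <= threshold + TIE_TOL)
  if (!length(ok)) {
    return(structure(list(query_id = dm$ids[qi], species = dm$species[qi],
                          method = "ASB", verdict = "no_match",
                          best_ids = character(0),
                          best_distance = NA_real_),
                     class = "match_verdict"))
  }
  dmin <- min(d[ok])
  best <- ok[d[ok] <= dmin + TIE_TOL]
  con <- ok[dm$species[ok] == dm$species[qi]]
  het <- ok[dm$species[ok] != dm$species[qi]]
  verdict <- if (!length(con)) {
    "incorrect"
  } else if (!length(het)) {
    "correct"
  } else {
    worst_con <- max(d[con])
    best_het <- min(d[het])
    if (worst_con < best_het - TIE_TOL) "correct"
    else if (best_het < worst_con - TIE_TOL) "incorrect"
    else "ambiguous"
  }
  structure(list(query_id = dm$ids[qi], species = dm$species[qi],
                 method = "ASB", verdict = verdict,
                 best_ids = dm$ids[best], best_distance = dmin),
            class = "match_verdict")
}

#' @export
print.match_verdict <- function(x, ...) {
  cat(sprintf("%s: %s -> %s", x$method, x$query_id, x$verdict))
  if (length(x$best_ids))
    cat(sprintf("  (best: %s at %.4f)", paste(x$best_ids, collapse = ","),
                x$best_distance))
  cat("\n")
  invisible(x)
}

#' Percentile-derived identification threshold
#'
#' Returns the distance below which `coverage` percent of all
#' intra-specific pairwise distances fall, using the linearly interpolated
#' sample percentile (R's default quantile definition, type 7).  The
#' conventional choice is the 95th percentile of the pairwise summary.
#'
#' @param summary a [summarize_divergence()] result with a non-empty
#'   intra-specific distance set.
#' @param coverage percent of intra-specific distances to cover
#'   (default 95).
#' @return A single distance value.
#' @export
percentile_threshold <- function(summary, coverage = 95) {
  stopifnot(inherits(summary, "divergence_summary"))
  if (!length(summary$intra_all))
    stop("threshold error: no intra-specific distances available")
  stats::quantile(summary$intra_all, coverage / 100, type = 7,
                  names = FALSE)
}

#' Dataset-level identification success rates
#'
#' Applies [best_match()], [best_close_match()] or
#' [all_species_barcodes()] to every specimen as query and aggregates the
#' verdicts into percentages.  With `fold_no_match = TRUE` unidentified
#' queries are folded into the incorrect column so that correct +
#' ambiguous + incorrect sums to 100, the three-column convention of
#' published success-rate tables.
#'
#' @param dm a [distance_matrix()] result.
#' @param method `"BM"`, `"BCM"` or `"ASB"`.
#' @param threshold distance threshold for BCM/ASB (ignored by BM); either
#'   a number or `"auto95"` for the [percentile_threshold()] at 95%.
#' @param fold_no_match fold `no_match` into `incorrect`?  Default `TRUE`.
#' @return A list of class `match_report` with `method`, `threshold`,
#'   `n_queries`, `pct_correct`, `pct_ambiguous`, `pct_incorrect`,
#'   `pct_no_match`, `verdicts` (per-query data frame) and
#'   `fold_no_match`.
#' @examples
#' classify_dataset(distance_matrix(worked_fixture()), "BCM",
#'                  threshold = 0.2)
#' @export
classify_dataset <- function(dm, method = c("BCM", "BM", "ASB"),
                             threshold = 0.03, fold_no_match = TRUE) {
  method <- match.arg(method)
  if (identical(threshold, "auto95"))
    threshold <- percentile_threshold(summarize_divergence(dm), 95)
  fn <- switch(method,
               BM = function(q) best_match(dm, q),
               BCM = function(q) best_close_match(dm, q, threshold),
               ASB = function(q) all_species_barcodes(dm, q, threshold))
  vs <- lapply(seq_along(dm$ids), fn)
  verdicts <- data.frame(
    query_id = vapply(vs, `[[`, "", "query_id"),
    species = vapply(vs, `[[`, "", "species"),
    method = method,
    verdict = vapply(vs, `[[`, "", "verdict"),
    best_distance = vapply(vs, `[[`, 0, "best_distance"),
    best_ids = vapply(vs, function(v) paste(v$best_ids, collapse = ","), ""),
    stringsAsFactors = FALSE)
  v <- verdicts$verdict
  if (fold_no_match) v[v == "no_match"] <- "incorrect"
  n <- length(v)
  pct <- function(k) 100 * sum(v == k) / n
  structure(list(method = method,
                 threshold = if (method == "BM") NA_real_ else threshold,
                 n_queries = n,
                 pct_correct = pct("correct"),
                 pct_ambiguous = pct("ambiguous"),
                 pct_incorrect = pct("incorrect"),
                 pct_no_match = pct("no_match"),
                 fold_no_match = fold_no_match,
                 verdicts = verdicts),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("%s identification over %d queries", x$method, x$n_queries))
  if (!is.na(x$threshold)) cat(sprintf(" (threshold %.4g)", x$threshold))
  cat("\n")
  cat(sprintf("  correct   %6.2f%%\n", x$pct_correct))
  cat(sprintf("  ambiguous %6.2f%%\n", x$pct_ambiguous))
  cat(sprintf("  incorrect %6.2f%%%s\n", x$pct_incorrect,
              if (x$fold_no_match) "  (no_match folded in)" else ""))
  if (!x$fold_no_match)
    cat(sprintf("  no match  %6.2f%%\n", x$pct_no_match))
  invisible(x)
}

#' Write per-query verdicts and the summary row as TSV
#'
#' @param report a [classify_dataset()] result.
#' @param verdict_path,summary_path output paths (either may be `NULL`).
#' @return invisibly, `NULL`.
#' @export
write_match_report <- function(report, verdict_path = NULL,
                               summary_path = NULL) {
  if (!is.null(verdict_path))
    utils::write.table(report$verdicts, verdict_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    row <- data.frame(method = report$method, threshold = report$threshold,
                      n = report$n_queries, correct = report$pct_correct,
                      ambiguous = report$pct_ambiguous,
                      incorrect = report$pct_incorrect,
                      no_match = report$pct_no_match)
    utils::write.table(row, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
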