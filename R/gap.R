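#' Global barcoding-gap histogram
#'
#' Bins the intra- and inter-specific distance distributions into
#' half-open intervals `[k*w, (k+1)*w)` (default bin width 0.005) and
#' looks for a *global* barcoding gap: a maximal run of bins, strictly
#' between the occupied intra-specific range and the occupied
#' inter-specific range, containing no distance of either kind.  When the
#' two distributions overlap no global gap exists; the fraction of
#' inter-specific mass above the maximum intra-specific distance is then
#' the informative quantity and is always reported.
#'
#' @param summary a [summarize_divergence()] result.
#' @param bin_width histogram bin width in distance units (default 0.005).
#' @return A list of class `global_gap` with elements `bin_width`,
#'   `histogram` (data frame `bin_start`, `intra_pct`, `inter_pct`;
#'   percentages of each pair class, each summing to 100 when the class is
#'   non-empty), `gap` (`c(gap_start, gap_end)` bin starts of the empty
#'   run, or `NULL`), `pct_inter_above_max_intra`.
#' @export
global_gap <- function(summary, bin_width = 0.005) {
  stopifnot(inherits(summary, "divergence_summary"))
  if (!length(summary$inter_all))
    stop("input error: no defined inter-specific distances")
  intra <- summary$intra_all
  inter <- summary$inter_all
  bin_of <- function(d) floor(d / bin_width + 1e-9)
  nb <- max(bin_of(c(intra, inter))) + 1L
  hist_of <- function(d) {
    cnt <- tabulate(bin_of(d) + 1L, nbins = nb)
    if (length(d)) 100 * cnt / length(d) else rep(0, nb)
  }
  hi <- hist_of(intra)
  he <- hist_of(inter)
  gap <- NULL
  if (length(intra)) {
    last_intra <- max(bin_of(intra))
    first_inter <- min(bin_of(inter))
    if (first_inter > last_intra + 1L) {
      empty <- seq.int(last_intra + 1L, first_inter - 1L)
      empty <- empty[hi[empty + 1L] == 0 & he[empty + 1L] == 0]
      if (length(empty))
        gap <- c(gap_start = min(empty) * bin_width,
                 gap_end = max(empty) * bin_width)
    }
  }
  pct_above <- if (length(intra))
    100 * mean(inter > max(intra)) else NA_real_
  structure(list(
    bin_width = bin_width,
    histogram = data.frame(bin_start = (seq_len(nb) - 1L) * bin_width,
                           intra_pct = hi, inter_pct = he),
    gap = gap,
    pct_inter_above_max_intra = pct_above
  ), class = "global_gap")
}

#' Per-species local barcoding gap (max-intra vs nearest neighbour)
#'
#' For each species, contrasts the maximum defined conspecific distance
#' (`max_intra`) with the nearest-neighbour distance (`nn`): the minimum
#' defined distance from any member to any non-conspecific specimen.  A
#' species shows a local gap — it lies "above the 1:1 line" of the NN
#' dot plot — iff `nn > max_intra` strictly; ties count as no gap.
#' Singleton species have no conspecific distance; they are recorded with
#' `max_intra = 0` and flagged, and are excluded from the percentage
#' unless `include_singletons = TRUE`.
#'
#' @param dm a [distance_matrix()] result with at least 2 species.
#' @param include_singletons include singleton species (as `max_intra = 0`)
#'   in `pct_above_line`?  Default `FALSE`.
#' @return A list of class `local_gap` with elements `per_species` (data
#'   frame `species`, `n`, `max_intra`, `nn`, `above_line`, `singleton`),
#'   `n_above_line`, `n_scored`, `pct_above_line`, `excluded` (species
#'   with no defined distance to any non-conspecific).
#' @export
local_gap <- function(dm, include_singletons = FALSE) {
  stopifnot(inherits(dm, "k2p_dist"))
  sp <- unique(dm$species)
  if (length(sp) < 2L) stop("input error: need at least 2 species")
  rows <- list()
  excluded <- character(0)
  for (s in sp) {
    ix <- which(dm$species == s)
    ox <- which(dm$species != s)
    inter <- dm$values[ix, ox, drop = FALSE]
    inter <- inter[!is.na(inter)]
    if (!length(inter)) {
      excluded <- c(excluded, s)
      next
    }
    nn <- min(inter)
    singleton <- length(ix) < 2L
    if (singleton) {
      mi <- 0
    } else {
      vals <- dm$values[ix, ix][upper.tri(matrix(0, length(ix), length(ix)))]
      vals <- vals[!is.na(vals)]
      mi <- if (length(vals)) max(vals) else NA_real_
    }
    rows[[s]] <- data.frame(species = s, n = length(ix), max_intra = mi,
                            nn = nn, above_line = !is.na(mi) && nn > mi,
                            singleton = singleton, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  scored <- if (include_singletons) per else per[!per$singleton, , drop = FALSE]
  scored <- scored[!is.na(scored$max_intra), , drop = FALSE]
  structure(list(
    per_species = per,
    n_above_line = sum(scored$above_line),
    n_scored = nrow(scored),
    pct_above_line = if (nrow(scored)) 100 * mean(scored$above_line)
                     else NA_real_,
    include_singletons = include_singletons,
    excluded = excluded
  ), class = "local_gap")
}

#' Combined barcoding-gap report
#'
#' Runs [global_gap()] and [local_gap()] on one dataset and bundles the
#' results.
#'
#' @param dm a [distance_matrix()] result.
#' @inheritParams global_gap
#' @inheritParams local_gap
#' @return A list of class `gap_report` with elements `global` and
#'   `local`.
#' @examples
#' gap_analysis(distance_matrix(worked_fixture()))
#' @export
gap_analysis <- function(dm, bin_width = 0.005, include_singletons = FALSE) {
  summ <- summarize_divergence(dm)
  structure(list(global = global_gap(summ, bin_width = bin_width),
                 local = local_gap(dm, include_singletons)),
            class = "gap_report")
}

#' @export
print.global_gap <- function(x, ...) {
  cat("Global barcoding gap (bin width ", x$bin_width, ")\n", sep = "")
  if (is.null(x$gap)) {
    cat("  no global gap: intra- and inter-specific distributions",
        "overlap or touch\n")
  } else {
    cat(sprintf("  empty run of bins from %.3f to %.3f\n",
                x$gap[1], x$gap[2]))
  }
  if (!is.na(x$pct_inter_above_max_intra))
    cat(sprintf("  %.1f%% of inter-specific pairs exceed the maximum",
                x$pct_inter_above_max_intra), "intra-specific distance\n")
  invisible(x)
}

#' @export
print.local_gap <- function(x, ...) {
  cat(sprintf(
    "Local barcoding gap: %d / %d species above the 1:1 line (%.1f%%)\n",
    x$n_above_line, x$n_scored, x$pct_above_line))
  if (length(x$excluded))
    cat("  excluded (no defined inter distance):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.gap_report <- function(x, ...) {
  print(x$global)
  print(x$local)
  invisible(x)
}

#' Write gap-report tables as TSV
#'
#' @param report a [gap_analysis()] result.
#' @param hist_path,species_path output paths for the histogram and the
#'   per-species table (either may be `NULL` to skip).
#' @return invisibly, `NULL`.
#' @export
write_gap_report <- function(report, hist_path = NULL, species_path = NULL) {
  if (!is.null(hist_path))
    utils::write.table(report$global$histogram, hist_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(species_path))
    utils::write.table(report$local$per_species, species_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
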