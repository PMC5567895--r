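#' Evaluate one barcode dataset end to end
#'
#' The package's central fitting-style entry point: given one
#' species-labelled alignment (a single locus or a concatenation), runs
#' the full evaluation chain — sequence characteristics, K2P distance
#' matrix, divergence summary, global and local barcoding-gap analysis,
#' Best Match / Best Close Match / All Species Barcodes identification,
#' and (optionally) NJ bootstrap monophyly resolution and a heuristic
#' maximum-parsimony score — and returns the bundle as a classed object
#' with `print`, `summary` and `plot` methods.
#'
#' @param aln a [labelled_alignment()].
#' @param bcm_threshold distance threshold for BCM/ASB: a number
#'   (default 0.03, the conventional 3% criterion) or `"auto95"` for the
#'   95th percentile of intra-specific distances.
#' @param bin_width gap-histogram bin width (default 0.005).
#' @param bootstrap number of NJ bootstrap replicates (default 100); 0
#'   skips tree building.
#' @param support_cutoff bootstrap percentage a species clade must exceed
#'   to count as resolved (default 60).
#' @param mp also run a maximum-parsimony search?  Default `FALSE`.
#' @param mp_starts random-addition starts for the MP search.
#' @param fold_no_match fold unidentified queries into the incorrect
#'   column (three-column table convention)?  Default `TRUE`.
#' @param include_singletons include singleton species in the local-gap
#'   percentage?  Default `FALSE`.
#' @param seed integer seed for the stochastic stages (bootstrap, MP).
#' @return An object of class `barcode_eval`: a list with elements
#'   `locus`, `stats`, `dm`, `divergence`, `gap`, `match` (list with
#'   `BM`, `BCM`, `ASB`), `threshold`, `tree`, `resolution`, `mp`,
#'   `seed`, `notes` (character vector of per-stage diagnostics).
#' @examples
#' ev <- barcode_eval(worked_fixture(), bootstrap = 20, seed = 1)
#' ev
#' @export
barcode_eval <- function(aln, bcm_threshold = 0.03, bin_width = 0.005,
                         bootstrap = 100, support_cutoff = 60,
                         mp = FALSE, mp_starts = 5,
                         fold_no_match = TRUE, include_singletons = FALSE,
                         seed = NULL) {
  stopifnot(inherits(aln, "labelled_alignment"))
  notes <- character(0)
  st <- alignment_stats(aln)
  dm <- distance_matrix(aln)
  dv <- summarize_divergence(dm)
  thr <- if (identical(bcm_threshold, "auto95")) {
    t95 <- percentile_threshold(dv, 95)
    notes <- c(notes, sprintf("auto95 threshold = %.6f", t95))
    t95
  } else bcm_threshold
  gap <- tryCatch(
    gap_analysis(dm, bin_width = bin_width,
                 include_singletons = include_singletons),
    error = function(e) {
      notes <<- c(notes, paste("gap stage:", conditionMessage(e)))
      NULL
    })
  match <- list(
    BM = classify_dataset(dm, "BM", fold_no_match = fold_no_match),
    BCM = classify_dataset(dm, "BCM", threshold = thr,
                           fold_no_match = fold_no_match),
    ASB = classify_dataset(dm, "ASB", threshold = thr,
                           fold_no_match = fold_no_match))
  tree <- resolution <- NULL
  if (bootstrap > 0) {
    tree <- tryCatch(
      withCallingHandlers(
        bootstrap_consensus(aln, replicates = bootstrap, seed = seed),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        notes <<- c(notes, paste("tree stage:", conditionMessage(e)))
        NULL
      })
    if (!is.null(tree))
      resolution <- resolution_score(tree, cutoff = support_cutoff)
  }
  mp_res <- NULL
  if (mp) {
    mp_res <- tryCatch(
      mp_search(aln, n_starts = mp_starts,
                seed = if (is.null(seed)) NULL else seed + 1L),
      error = function(e) {
        notes <<- c(notes, paste("MP stage:", conditionMessage(e)))
        NULL
      })
  }
  structure(list(locus = aln$locus, n = nrow(aln$seqs), stats = st,
                 dm = dm, divergence = dv, gap = gap, match = match,
                 threshold = thr, tree = tree, resolution = resolution,
                 mp = mp_res, seed = seed, notes = notes),
            class = "barcode_eval")
}

#' @export
print.barcode_eval <- function(x, ...) {
  cat("Barcode evaluation of '", x$locus, "' (", x$n, " sequences, ",
      length(unique(x$dm$species)), " species)\n", sep = "")
  cat(sprintf("  variable sites: %d / %d\n",
              x$stats$n_variable_sites, x$stats$aligned_length))
  if (x$divergence$intra_available)
    cat(sprintf("  mean intra %.4f +/- %.4f, mean inter %.4f +/- %.4f\n",
                x$divergence$mean_intra, x$divergence$se_intra,
                x$divergence$mean_inter, x$divergence$se_inter))
  if (!is.null(x$gap))
    cat(sprintf("  local gap: %.1f%% of species above the 1:1 line\n",
                x$gap$local$pct_above_line))
  cat(sprintf("  BCM correct: %.2f%% (threshold %.4g)\n",
              x$match$BCM$pct_correct, x$threshold))
  if (!is.null(x$resolution))
    cat(sprintf("  NJ resolution: %.1f%% of species (> %g%% support)\n",
                x$resolution$pct_resolved, x$resolution$support_cutoff))
  if (!is.null(x$mp))
    cat(sprintf("  MP length %d (CI %.4f)\n", x$mp$score$tree_length,
                x$mp$score$ci))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @export
summary.barcode_eval <- function(object, ...) {
  print(object$stats)
  print(object$divergence)
  if (!is.null(object$gap)) print(object$gap)
  for (m in object$match) print(m)
  if (!is.null(object$resolution)) print(object$resolution)
  if (!is.null(object$mp)) print(object$mp)
  invisible(object)
}

#' Plot a barcode evaluation
#'
#' Two base-graphics panels: the intra/inter distance histogram (the
#' global barcoding gap view) and the per-species nearest-neighbour vs
#' maximum-intra dot plot with the 1:1 line (the local gap view).
#'
#' @param x a [barcode_eval()] result.
#' @param ... passed on to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.barcode_eval <- function(x, ...) {
  if (is.null(x$gap)) {
    warning("no gap report to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  h <- x$gap$global$histogram
  graphics::barplot(t(as.matrix(h[, c("intra_pct", "inter_pct")])),
                    beside = TRUE, names.arg = format(h$bin_start),
                    col = c("grey30", "grey75"), border = NA,
                    xlab = "K2P distance (bin start)", ylab = "% of pairs",
                    main = paste("Distance distributions:", x$locus), ...)
  graphics::legend("topright", legend = c("intra", "inter"),
                   fill = c("grey30", "grey75"), bty = "n")
  per <- x$gap$local$per_species
  lim <- range(c(per$max_intra, per$nn), na.rm = TRUE)
  graphics::plot(per$max_intra, per$nn, xlim = lim, ylim = lim,
                 xlab = "maximum intra-specific distance",
                 ylab = "nearest-neighbour distance",
                 main = "Local barcoding gap", pch = 19)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Evaluate several loci and their concatenations
#'
#' Orchestrates [barcode_eval()] over single loci and declared
#' combinations (built with [concatenate_alignments()]), and assembles
#' the standard result tables: sequence characteristics, divergence,
#' identification success and tree-based resolution, one row per dataset.
#' Optionally writes every table (TSV) and tree (Newick) under an output
#' directory.
#'
#' @param loci named list of [labelled_alignment()]s or FASTA paths.
#' @param combinations list of character vectors of locus names to
#'   concatenate, e.g. `list(c("a", "b"), c("a", "b", "c"))`.
#' @param join matching rule for concatenation, `"specimen"` or
#'   `"species"`.
#' @param output_dir optional directory for TSV/Newick outputs.
#' @param seed integer master seed; dataset-level seeds are derived from
#'   it.
#' @param ... further arguments passed to [barcode_eval()].
#' @return An object of class `barcode_eval_set`: list with `evals`
#'   (named list of `barcode_eval` or error messages), `stats`,
#'   `divergence`, `identification`, `resolution` tables, and `log`.
#' @export
run_evaluation <- function(loci, combinations = list(),
                           join = c("specimen", "species"),
                           output_dir = NULL, seed = NULL, ...) {
  join <- match.arg(join)
  loci <- lapply(loci, function(x)
    if (inherits(x, "labelled_alignment")) x else read_alignment(x))
  if (is.null(names(loci)) || any(!nzchar(names(loci))))
    names(loci) <- vapply(loci, `[[`, "", "locus")
  datasets <- loci
  for (cmb in combinations) {
    if (!all(cmb %in% names(loci)))
      stop("config error: combination references unknown locus: ",
           paste(setdiff(cmb, names(loci)), collapse = ", "))
    nm <- paste(cmb, collapse = "+")
    datasets[[nm]] <- concatenate_alignments(loci[cmb], join = join,
                                             locus = nm)
  }
  log <- character(0)
  evals <- list()
  for (i in seq_along(datasets)) {
    nm <- names(datasets)[i]
    ds_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    evals[[nm]] <- tryCatch(
      barcode_eval(datasets[[i]], seed = ds_seed, ...),
      error = function(e) {
        log <<- c(log, paste0(nm, ": ", conditionMessage(e)))
        conditionMessage(e)
      })
    if (inherits(evals[[nm]], "barcode_eval")) {
      log <- c(log, sprintf("%s: n=%d, seed=%s", nm,
                            nrow(datasets[[i]]$seqs),
                            if (is.null(ds_seed)) "NULL" else ds_seed))
      log <- c(log, paste0(nm, ": ", evals[[nm]]$notes))
    }
  }
  ok <- vapply(evals, inherits, TRUE, "barcode_eval")
  tab <- function(f) {
    rows <- lapply(names(evals)[ok], function(nm) f(nm, evals[[nm]]))
    do.call(rbind, rows)
  }
  stats <- tab(function(nm, e) {
    s <- e$stats
    data.frame(dataset = nm, n = s$n_sequences, min_len = s$min_len,
               max_len = s$max_len, aligned_length = s$aligned_length,
               n_variable = s$n_variable_sites,
               pct_variable = s$pct_variable,
               n_parsimony_informative = s$n_parsimony_informative,
               mean_gc = s$mean_gc, ts_tv = s$ts_tv_ratio,
               stringsAsFactors = FALSE)
  })
  divergence <- tab(function(nm, e) {
    d <- e$divergence
    data.frame(dataset = nm,
               min_intra = d$range_intra[1], max_intra = d$range_intra[2],
               min_inter = d$range_inter[1], max_inter = d$range_inter[2],
               mean_intra = d$mean_intra, se_intra = d$se_intra,
               mean_inter = d$mean_inter, se_inter = d$se_inter,
               n_undefined = d$n_undefined_pairs, stringsAsFactors = FALSE)
  })
  identification <- tab(function(nm, e) {
    do.call(rbind, lapply(e$match, function(m)
      data.frame(dataset = nm, method = m$method,
                 threshold = m$threshold, correct = m$pct_correct,
                 ambiguous = m$pct_ambiguous, incorrect = m$pct_incorrect,
                 no_match = m$pct_no_match, stringsAsFactors = FALSE)))
  })
  resolution <- tab(function(nm, e) {
    if (is.null(e$resolution)) return(NULL)
    r <- e$resolution
    data.frame(dataset = nm, n_species_scored = r$n_species_scored,
               n_resolved = r$n_resolved, pct_resolved = r$pct_resolved,
               n_individuals_resolved = r$n_individuals_resolved,
               mp_length = if (is.null(e$mp)) NA_integer_
                           else e$mp$score$tree_length,
               stringsAsFactors = FALSE)
  })
  out <- structure(list(evals = evals, stats = stats,
                        divergence = divergence,
                        identification = identification,
                        resolution = resolution, log = log, seed = seed),
                   class = "barcode_eval_set")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) if (!is.null(df))
      utils::write.table(df, file.path(output_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(stats, "stats.tsv")
    wt(divergence, "summary.tsv")
    wt(identification, "classify.tsv")
    wt(resolution, "resolution.tsv")
    for (nm in names(evals)[ok]) {
      if (!is.null(evals[[nm]]$tree))
        write_tree(evals[[nm]]$tree,
                   file.path(output_dir, paste0(gsub("[^A-Za-z0-9_+-]", "_",
                                                     nm), ".nwk")))
    }
    writeLines(log, file.path(output_dir, "run.log"))
  }
  out
}

#' @export
print.barcode_eval_set <- function(x, ...) {
  cat("Barcode evaluation set:", length(x$evals), "datasets\n")
  ok <- vapply(x$evals, inherits, TRUE, "barcode_eval")
  if (any(!ok))
    cat("  failed:", paste(names(x$evals)[!ok], collapse = ", "), "\n")
  bcm <- x$identification[x$identification$method == "BCM", ]
  for (i in seq_len(nrow(bcm))) {
    res <- x$resolution[x$resolution$dataset == bcm$dataset[i], ]
    cat(sprintf("  %-28s BCM correct %6.2f%%%s\n", bcm$dataset[i],
                bcm$correct[i],
                if (nrow(res)) sprintf(", NJ resolution %5.1f%%",
                                       res$pct_resolved[1]) else ""))
  }
  invisible(x)
}
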