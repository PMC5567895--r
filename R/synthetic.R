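#' Specification for a simulated species-complex barcode dataset
#'
#' Describes a multi-species, multi-locus sampling design with controlled
#' intra- and inter-specific divergence, mirroring a typical barcode
#' reference library for a taxonomically complex genus: a few dozen
#' species, 3-5 individuals each, and loci of 500-700 bp whose
#' substitution rates differ (a conserved plastid coding gene, a fast
#' plastid gene, and a fast nuclear spacer carrying small indels).
#'
#' Sequences evolve under a Kimura two-type (transition/transversion)
#' substitution process along a Yule species tree rescaled so that the
#' mean tip-to-tip path length equals `inter_scale`; individuals within a
#' species radiate from the species sequence as a star genealogy with
#' pendant depth `intra_scale / 2`, making the expected conspecific
#' distance equal `intra_scale`.  Branch lengths are in expected
#' substitutions/site, so K2P estimates recover them directly.
#'
#' @param n_species number of species (default 41).
#' @param individuals individuals per species: a single count, a range to
#'   sample per species uniformly (default `3:5`), or a vector of length
#'   `n_species`.
#' @param loci data frame with columns `name`, `length` (bp >= 50),
#'   `rate` (locus-specific rate multiplier) and `indels` (logical);
#'   defaults to a conserved 636 bp locus (rate 0.08), a fast 598 bp
#'   locus (rate 1) and a fast 605 bp nuclear-style locus (rate 1.05)
#'   with indels.
#' @param inter_scale expected K2P distance between *sister* species at
#'   rate 1 (default 0.08).  The species tree enforces this as a floor:
#'   every between-species path is at least `inter_scale`, recent sister
#'   pairs sit near it, and the deepest pairs reach about
#'   `2 * inter_scale`.
#' @param intra_scale expected conspecific K2P distance at rate 1
#'   (default 0.004); must be smaller than `inter_scale`.
#' @param kappa transition/transversion rate ratio (default 2).
#' @param base_freqs equilibrium base frequencies (A, C, G, T), summing
#'   to 1.  The default is uniform, matching the equal-composition
#'   assumption of the K2P estimator so closed-form recovery holds;
#'   unequal frequencies give an HKY-type process under which K2P
#'   recovery is only approximate.
#' @param indel_rate per-site probability of starting a 1-4 bp shared gap
#'   run on indel-bearing loci (default 0.01).
#' @param seed integer seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_species = 41, individuals = 3:5,
                     loci = NULL, inter_scale = 0.08, intra_scale = 0.004,
                     kappa = 2,
                     base_freqs = rep(0.25, 4),
                     indel_rate = 0.01, seed = NULL) {
  if (is.null(loci)) {
    loci <- data.frame(
      name = c("plastid_slow", "plastid_fast", "nuclear_its"),
      length = c(636L, 598L, 605L),
      rate = c(0.08, 1, 1.05),
      indels = c(FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE)
  }
  stopifnot(n_species >= 2, all(loci$length >= 50), kappa > 0,
            all(c(inter_scale, intra_scale) >= 0))
  if (intra_scale >= inter_scale)
    stop("spec error: intra_scale must be smaller than inter_scale")
  if (abs(sum(base_freqs) - 1) > 1e-9)
    stop("spec error: base_freqs must sum to 1")
  structure(list(n_species = n_species, individuals = individuals,
                 loci = loci, inter_scale = inter_scale,
                 intra_scale = intra_scale, kappa = kappa,
                 base_freqs = base_freqs, indel_rate = indel_rate,
                 seed = seed),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "Simulation spec: %d species, %s individuals/species, %d loci\n",
    x$n_species, paste(range(x$individuals), collapse = "-"),
    nrow(x$loci)))
  cat(sprintf("  inter_scale %.4g, intra_scale %.4g, kappa %.2g\n",
              x$inter_scale, x$intra_scale, x$kappa))
  invisible(x)
}

#' Simulate species-labelled barcode alignments
#'
#' Generates one [labelled_alignment()] per locus under a [sim_spec()]:
#' a Yule species tree is drawn, rescaled to height `inter_scale / 2`,
#' and every species stem is lengthened by `inter_scale / 2` (so the
#' expected sister-species K2P distance is `inter_scale` and deeper pairs
#' range up to about twice that); star-shaped within-species tips of
#' depth `intra_scale / 2` are grafted on; each locus then evolves along
#' this genealogy (edge lengths times the locus rate multiplier) under a
#' two-rate transition/transversion process.  Branch lengths are in
#' expected substitutions/site: the `species_tree` attribute's cophenetic
#' paths (plus `intra_scale`) are the closed-form expectations that
#' realized K2P distances recover.  Indel-bearing loci receive
#' shared whole-column gap runs of 1-4 bp in all individuals of a random
#' species.  Specimen ids are `sp<k>_ind<j>`; species labels are
#' `Sim_species<k>`.
#'
#' @param spec a [sim_spec()].
#' @return A named list of [labelled_alignment()]s (one per locus) with
#'   attributes `species_tree` (Newick, rate-1 scale), `spec` and `seed`.
#'   Same seed, same output, byte for byte.
#' @examples
#' sim <- simulate_barcodes(sim_spec(n_species = 5, individuals = 3,
#'                                   seed = 42))
#' @export
simulate_barcodes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  S <- spec$n_species
  n_ind <- if (length(spec$individuals) == S && S > 1) {
    spec$individuals
  } else if (length(spec$individuals) == 1L) {
    rep(spec$individuals, S)
  } else {
    sample(spec$individuals, S, replace = TRUE)
  }

  sp_tree <- ape::rphylo(S, birth = 1, death = 0)
  sp_tree$tip.label <- sprintf("SP%04d", seq_len(S))
  # Yule tree rescaled to height inter_scale / 2 gives the between-species
  # structure; lengthening every species stem by inter_scale / 2 puts a
  # floor of inter_scale on between-species paths, so sister species sit
  # near inter_scale and no pair saturates
  height <- max(ape::node.depth.edgelength(sp_tree)[seq_len(S)])
  sp_tree$edge.length <- sp_tree$edge.length * (spec$inter_scale / 2) / height
  tip_edges <- sp_tree$edge[, 2] <= S
  sp_tree$edge.length[tip_edges] <-
    sp_tree$edge.length[tip_edges] + spec$inter_scale / 2

  # graft a star of individuals (pendant depth intra_scale / 2) onto each
  # species tip by rewriting the Newick string
  h <- spec$intra_scale / 2
  nwk <- ape::write.tree(sp_tree)
  for (k in seq_len(S)) {
    inds <- paste(sprintf("sp%d_ind%d:%.10f", k, seq_len(n_ind[k]), h),
                  collapse = ",")
    nwk <- sub(sprintf("SP%04d:", k), sprintf("(%s):", inds), nwk,
               fixed = TRUE)
  }
  full <- ape::read.tree(text = nwk)

  Q <- c(1, spec$kappa, 1, 1, spec$kappa, 1)  # AC AG AT CG CT GT
  species_of <- sub("_ind\\d+$", "", full$tip.label)
  species_lab <- sprintf("Sim_species%02d",
                         as.integer(sub("^sp", "", species_of)))
  out <- list()
  for (i in seq_len(nrow(spec$loci))) {
    lt <- full
    lt$edge.length <- lt$edge.length * spec$loci$rate[i]
    sq <- phangorn::simSeq(lt, l = spec$loci$length[i], Q = Q,
                           bf = spec$base_freqs, type = "DNA")
    m <- toupper(as.character(sq))
    m <- m[full$tip.label, , drop = FALSE]
    if (isTRUE(spec$loci$indels[i]) && spec$indel_rate > 0) {
      L <- ncol(m)
      starts <- which(stats::runif(L) < spec$indel_rate)
      for (s0 in starts) {
        w <- sample.int(4L, 1L)
        cols <- s0:min(L, s0 + w - 1L)
        gap_sp <- sample(unique(species_of), 1L)
        m[species_of == gap_sp, cols] <- "-"
      }
    }
    out[[spec$loci$name[i]]] <- labelled_alignment(
      m, specimen = full$tip.label, species = species_lab,
      locus = spec$loci$name[i])
  }
  attr(out, "species_tree") <- ape::write.tree(sp_tree)
  attr(out, "spec") <- spec
  attr(out, "seed") <- spec$seed
  out
}

#' A small deterministic worked example alignment
#'
#' Returns a hand-constructed 4-species x 3-individual alignment of
#' 120 bp whose substitutions are placed at known columns, so that every
#' pipeline stage (K2P matrix, gap report, identification verdicts, NJ
#' topology, Fitch length) can be verified by hand.  Species differ by
#' disjoint blocks of transitions/transversions; each non-reference
#' individual carries one private transition.  Expected outputs computed
#' independently of this package ship in `inst/extdata/`.
#'
#' Pair difference counts by construction (120 comparable sites each):
#' conspecific pairs differ by 1 or 2 transitions; species blocks (all
#' mutually disjoint columns) give Alpha_one vs Alpha_two 10 transitions,
#' Alpha_one vs Beta_three 8+4 (ts+tv), Alpha_one vs Beta_four 10+6,
#' Alpha_two vs Beta_three 10+4, Alpha_two vs Beta_four 12+6,
#' Beta_three vs Beta_four 10+10, plus the individuals' private
#' transitions.
#'
#' @return A [labelled_alignment()] named `fixture`.
#' @export
worked_fixture <- function() {
  base <- rep(c("A", "C", "G", "T"), 30)
  ts_of <- c(A = "G", C = "T", G = "A", T = "C")
  tv_of <- c(A = "C", C = "G", G = "T", T = "A")
  tv2_of <- c(A = "T", C = "A", G = "C", T = "G")
  species_block <- list(
    Alpha_one = list(ts = 41:44, tv = integer(0)),
    Alpha_two = list(ts = 1:6, tv = integer(0)),
    Beta_three = list(ts = 11:14, tv = 15:18),
    Beta_four = list(ts = 21:26, tv = 27:32)
  )
  seqs <- list()
  specimen <- species <- character(0)
  k <- 0L
  for (sp in names(species_block)) {
    k <- k + 1L
    blk <- species_block[[sp]]
    s <- base
    s[blk$ts] <- ts_of[s[blk$ts]]
    half <- blk$tv[seq_len(floor(length(blk$tv) / 2))]
    rest <- setdiff(blk$tv, half)
    s[half] <- tv_of[s[half]]
    s[rest] <- tv2_of[s[rest]]
    for (j in 1:3) {
      si <- s
      if (j > 1L) {
        col <- 100L + (k - 1L) * 4L + (j - 1L)
        si[col] <- ts_of[si[col]]
      }
      id <- sprintf("sp%d_ind%d", k, j)
      seqs[[id]] <- si
      specimen <- c(specimen, id)
      species <- c(species, sp)
    }
  }
  labelled_alignment(do.call(rbind, seqs), specimen = specimen,
                     species = species, locus = "fixture")
}
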