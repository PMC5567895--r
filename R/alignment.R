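#' Species-labelled multiple sequence alignment
#'
#' The central container of the package: an aligned set of DNA sequences,
#' each carrying a specimen identifier and a binomial species label.  All
#' downstream stages (distances, gap analysis, identification, trees)
#' consume this object.
#'
#' @param seqs character matrix of single characters (rows = sequences,
#'   columns = alignment sites) over `A,C,G,T,-,N` and IUPAC ambiguity
#'   codes, or a character vector of equal-length sequence strings.
#' @param specimen character vector of unique specimen identifiers.
#' @param species character vector of species labels, parallel to
#'   `specimen`; must be non-empty strings.
#' @param locus name of the locus (or concatenation) the alignment covers.
#' @param partitions optional data frame with columns `locus`, `start`,
#'   `end` (1-based, inclusive) recording locus boundaries of a
#'   concatenated alignment.  Defaults to a single partition spanning the
#'   whole alignment.
#'
#' @return An object of class `labelled_alignment`: a list with elements
#'   `locus`, `specimen`, `species`, `seqs` (character matrix with specimen
#'   row names) and `partitions`.
#' @export
labelled_alignment <- function(seqs, specimen, species, locus = "locus",
                               partitions = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- which(lens != lens[1L])[1L]
      stop("alignment error: sequence ", bad, " ('", specimen[bad],
           "') has length ", lens[bad], ", expected ", lens[1L])
    }
    seqs <- do.call(rbind, strsplit(seqs, ""))
  }
  seqs <- toupper(seqs)
  seqs[seqs == "U"] <- "T"
  seqs[seqs == "?"] <- "N"
  n <- nrow(seqs)
  if (is.null(n) || n < 2L) stop("alignment error: need at least 2 sequences")
  if (ncol(seqs) < 1L) stop("alignment error: aligned length must be positive")
  specimen <- as.character(specimen)
  species <- as.character(species)
  if (length(specimen) != n || length(species) != n)
    stop("labelling error: specimen/species labels do not match row count")
  if (anyDuplicated(specimen))
    stop("labelling error: duplicated specimen ids: ",
         paste(unique(specimen[duplicated(specimen)]), collapse = ", "))
  if (any(!nzchar(species)) || anyNA(species))
    stop("labelling error: empty species label for specimen(s): ",
         paste(specimen[!nzchar(species) | is.na(species)], collapse = ", "))
  rownames(seqs) <- specimen
  if (is.null(partitions)) {
    partitions <- data.frame(locus = locus, start = 1L, end = ncol(seqs),
                             stringsAsFactors = FALSE)
  }
  structure(
    list(locus = locus, specimen = specimen, species = species,
         seqs = seqs, partitions = partitions),
    class = "labelled_alignment")
}

#' @export
print.labelled_alignment <- function(x, ...) {
  cat("Labelled alignment '", x$locus, "': ", nrow(x$seqs), " sequences x ",
      ncol(x$seqs), " sites, ", length(unique(x$species)), " species\n",
      sep = "")
  if (nrow(x$partitions) > 1L) {
    cat("Partitions:\n")
    print(x$partitions, row.names = FALSE)
  }
  invisible(x)
}

#' Number of aligned sites
#' @param aln a [labelled_alignment()].
#' @return integer alignment length in bp.
#' @export
aligned_length <- function(aln) ncol(aln$seqs)

# default header rule: species = last two underscore- or pipe-separated
# tokens joined as Genus_species; specimen id = full header
default_header_rule <- function(header) {
  tokens <- strsplit(header, "[_|]")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) < 2L)
    stop("labelling error: cannot parse species from header '", header, "'")
  k <- length(tokens)
  list(specimen = header,
       species = paste(tokens[k - 1L], tokens[k], sep = "_"))
}

#' Read a species-labelled alignment from an aligned FASTA file
#'
#' Sequences are upper-cased and `U` is mapped to `T`.  Species labels are
#' parsed from the FASTA headers: by default the last two underscore- or
#' pipe-separated tokens form the binomial (`Genus_species`) and the full
#' header is kept as the specimen id.
#'
#' @param path path to an aligned multi-FASTA file (gap character `-`).
#' @param header_rule either a function mapping one header string to
#'   `list(specimen =, species =)`, or the string `"default"`.
#' @param locus locus name; defaults to the file name without extension.
#' @return A [labelled_alignment()].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">Tarj1|Terminalia_arjuna", "ACGTACGTAA",
#'              ">Tarj2|Terminalia_arjuna", "ACGTACGTAT"), f)
#' aln <- read_alignment(f)
#' @export
read_alignment <- function(path, header_rule = "default", locus = NULL) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  if (is.null(locus))
    locus <- sub("\\.[^.]*$", "", basename(path))
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                       set.attributes = FALSE),
    error = function(e) stop("input error: cannot read FASTA from ", path,
                             " (", conditionMessage(e), ")"))
  if (length(recs) == 0L) stop("input error: no FASTA records in ", path)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("alignment error: record '", names(recs)[bad], "' has length ",
         lens[bad], " but first record has ", lens[1L])
  }
  mat <- toupper(do.call(rbind, recs))
  if (identical(header_rule, "default")) header_rule <- default_header_rule
  parsed <- lapply(names(recs), header_rule)
  labelled_alignment(mat,
                     specimen = vapply(parsed, `[[`, "", "specimen"),
                     species = vapply(parsed, `[[`, "", "species"),
                     locus = locus)
}

#' Write a labelled alignment to FASTA
#'
#' Headers are written as `specimen|species` unless the specimen id already
#' ends with the species label (as produced by the default header rule), in
#' which case the specimen id alone is written, making
#' `read_alignment(write_alignment(x))` an identity on sequences and labels.
#'
#' @param aln a [labelled_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  hdr <- ifelse(endsWith(aln$specimen, aln$species),
                aln$specimen,
                paste0(aln$specimen, "|", aln$species))
  seqs <- apply(aln$seqs, 1L, paste, collapse = "")
  writeLines(paste0(">", hdr, "\n", seqs), path)
  invisible(path)
}

#' Write the partition table of a (concatenated) alignment
#'
#' @param aln a [labelled_alignment()].
#' @param path output TSV path with columns `locus`, `start`, `end`
#'   (1-based, inclusive).
#' @return `path`, invisibly.
#' @export
write_partitions <- function(aln, path) {
  utils::write.table(aln$partitions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
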