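#' Read an in-frame codon alignment from FASTA
#'
#' Tokenizes each sequence into codon triplets.  Triplets consisting only of
#' `A/C/G/T` must be sense codons; an in-frame stop codon is an error (the
#' message names the taxon and the 1-based codon column).  Any triplet
#' containing a gap (`-`) or an ambiguity character is treated as fully
#' missing data: the likelihood marginalizes over all sense codons at that
#' position.
#'
#' @param path Path to a FASTA file of equal-length, in-frame sequences.
#' @param code A [genetic_code()] object.
#' @return A `codon_alignment`: list with `taxa`, `triplets` (character
#'   matrix, taxa by codon columns), `states` (integer matrix, 1-based sense
#'   codon index, 0 = missing), `n_sites`, and `code`.
#' @export
read_codon_fasta <- function(path, code = genetic_code()) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  taxa <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  codon_alignment(seqs, taxa, code)
}

#' Build a codon alignment from character sequences
#'
#' @param seqs Character vector of nucleotide sequences (equal length,
#'   multiple of 3).
#' @param taxa Taxon names (unique).
#' @param code A [genetic_code()] object.
#' @export
codon_alignment <- function(seqs, taxa = names(seqs), code = genetic_code()) {
  if (is.null(taxa)) stop("taxon names are required")
  if (anyDuplicated(taxa))
    stop("duplicate taxon names: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("sequence lengths differ: ", paste(range(lens), collapse = " vs "))
  if (lens[1] %% 3 != 0)
    stop("alignment length ", lens[1], " is not a multiple of 3")
  n_sites <- unname(lens[1]) %/% 3L
  ntaxa <- length(seqs)
  starts <- 3L * (seq_len(n_sites) - 1L) + 1L
  triplets <- matrix("", ntaxa, n_sites, dimnames = list(taxa, NULL))
  for (i in seq_len(ntaxa))
    triplets[i, ] <- substring(seqs[i], starts, starts + 2L)
  states <- matrix(match(triplets, code$codons, nomatch = 0L), ntaxa, n_sites,
                   dimnames = list(taxa, NULL))
  # resolved ACGT triplets that are not sense codons are in-frame stops
  clean <- !grepl("[^ACGT]", triplets)
  bad <- which(states == 0L & clean, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("in-frame stop codon '", triplets[bad[1, 1], bad[1, 2]],
         "' in taxon '", taxa[bad[1, 1]], "' at codon column ", bad[1, 2])
  }
  structure(list(taxa = taxa, triplets = triplets, states = states,
                 n_sites = n_sites, code = code),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$taxa), "taxa x", x$n_sites,
      "codon columns;", sum(x$states == 0L), "missing codons\n")
  invisible(x)
}

#' Write a codon alignment to FASTA, optionally masking codons
#'
#' Masked codons are written as `---`; everything else round-trips
#' byte-identically up to line wrapping.
#'
#' @param alignment A `codon_alignment`.
#' @param path Output file path.
#' @param mask Optional two-column structure of (taxon, 1-based codon column)
#'   pairs to replace with gaps: either a data.frame with columns
#'   `taxon`/`site` or a [mask_decision] object (its masked pairs, plus any
#'   fully masked columns, are applied).
#' @return The output path, invisibly.
#' @export
write_masked_fasta <- function(alignment, path, mask = NULL) {
  trip <- alignment$triplets
  if (!is.null(mask)) {
    mp <- mask_pairs(mask, alignment)
    trip[mp] <- "---"
  }
  seqs <- apply(trip, 1, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- alignment$taxa
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

# normalize a mask specification into a 2-column index matrix (row, col)
mask_pairs <- function(mask, alignment) {
  if (inherits(mask, "mask_decision")) {
    df <- mask$masked_codons
    cols <- which(mask$column_masked)
    if (length(cols) > 0)
      df <- rbind(df[, c("taxon", "site")],
                  expand.grid(taxon = alignment$taxa, site = cols,
                              stringsAsFactors = FALSE))
  } else {
    df <- as.data.frame(mask)
    names(df)[1:2] <- c("taxon", "site")
  }
  if (nrow(df) == 0) return(cbind(integer(0), integer(0)))
  ri <- match(df$taxon, alignment$taxa)
  if (anyNA(ri))
    stop("mask references unknown taxa: ",
         paste(unique(df$taxon[is.na(ri)]), collapse = ", "))
  ci <- as.integer(df$site)
  if (any(ci < 1 | ci > alignment$n_sites))
    stop("mask references codon columns outside 1..", alignment$n_sites)
  cbind(ri, ci)
}

# alignment recast as nucleotide states (1..4, 0 = missing) for the GTR phase
nucleotide_states <- function(alignment) {
  nt <- alignment$code$nt
  trip <- alignment$triplets
  ntaxa <- nrow(trip)
  out <- matrix(0L, ntaxa, 3L * ncol(trip))
  for (k in 1:3) {
    chars <- substr(trip, k, k)
    out[, seq(k, ncol(out), by = 3L)] <-
      matrix(match(chars, nt, nomatch = 0L), ntaxa)
  }
  out
}

# collapse identical columns; returns list(states = taxa x patterns, w)
compress_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(states = states[, u, drop = FALSE],
       w = as.numeric(tabulate(idx, nbins = sum(u))),
       index = idx)
}
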