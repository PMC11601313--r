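#' Genetic code tables for codon models
#'
#' Builds the lookup structures the codon machinery needs: the ordered list
#' of sense (non-stop) codons, the codon-to-amino-acid map, and the table of
#' single-nucleotide codon neighbors annotated with the changed position,
#' the nucleotide exchangeability index, and a synonymous flag.  Instantaneous
#' multi-nucleotide changes are excluded by construction, which is what the
#' MG94 family of models assumes.
#'
#' @param code_id Genetic code identifier passed to
#'   [Biostrings::getGeneticCode()]; the default `"1"` is the standard
#'   (universal) code, the only one exercised by the test suite.
#' @return An object of class `genetic_code`: a list with elements
#'   `codons` (sense codons, ordered), `aa` (amino acid per sense codon),
#'   `stops`, `neighbors` (integer matrix with columns `from`, `to`,
#'   `theta_idx`, `pos`, `target_nt`, `syn`), and `nt` (`A`,`C`,`G`,`T`).
#' @export
genetic_code <- function(code_id = "1") {
  cache_key <- paste0("gc_", code_id)
  if (!is.null(.bustede_cache[[cache_key]])) return(.bustede_cache[[cache_key]])
  nt <- c("A", "C", "G", "T")
  tab <- Biostrings::getGeneticCode(code_id)
  all_codons <- as.vector(outer(outer(nt, nt, paste0), nt,
                                function(a, b) paste0(a, b)))
  all_codons <- sort(names(tab))  # canonical alphabetical order
  aa_all <- tab[all_codons]
  stops <- all_codons[aa_all == "*"]
  codons <- all_codons[aa_all != "*"]
  aa <- aa_all[codons]
  n <- length(codons)

  # unordered nucleotide pair index: AC=1 AG=2 AT=3 CG=4 CT=5 GT=6
  pair_idx <- matrix(0L, 4, 4, dimnames = list(nt, nt))
  pairs <- c("AC", "AG", "AT", "CG", "CT", "GT")
  for (i in seq_along(pairs)) {
    a <- substr(pairs[i], 1, 1); b <- substr(pairs[i], 2, 2)
    pair_idx[a, b] <- i; pair_idx[b, a] <- i
  }

  cmat <- do.call(rbind, strsplit(codons, ""))
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- NULL
    for (k in 1:3) {
      for (j in nt[nt != cmat[i, k]]) {
        tgt <- cmat[i, ]; tgt[k] <- j
        tgt_c <- paste(tgt, collapse = "")
        jj <- match(tgt_c, codons)
        if (is.na(jj)) next  # change into a stop codon: not a sense state
        rows <- rbind(rows, c(i, jj, pair_idx[cmat[i, k], j], k,
                              match(j, nt),
                              as.integer(aa[i] == aa[jj])))
      }
    }
    nb[[i]] <- rows
  }
  nb <- do.call(rbind, nb)
  colnames(nb) <- c("from", "to", "theta_idx", "pos", "target_nt", "syn")
  storage.mode(nb) <- "integer"
  gc <- structure(
    list(codons = codons, aa = aa, stops = stops, neighbors = nb, nt = nt,
         code_id = code_id),
    class = "genetic_code")
  .bustede_cache[[cache_key]] <- gc
  gc
}

.bustede_cache <- new.env(parent = emptyenv())

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code", x$code_id, "-", length(x$codons), "sense codons,",
      length(x$stops), "stop codons,", nrow(x$neighbors),
      "single-nucleotide neighbor pairs\n")
  invisible(x)
}
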