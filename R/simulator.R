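#' Specification of a parametric codon-alignment simulation
#'
#' Bundles the generating tree, model parameters, and size/seed.  The truth
#' parameters must satisfy every model constraint (checked on construction).
#'
#' @param tree An `ape::phylo` with branch lengths (nucleotide
#'   substitutions/site) and tip labels, or a `phylogeny`.
#' @param theta Named 6-vector of exchangeabilities (`AG` = 1).
#' @param pi34 3x4 position-specific nucleotide frequencies.
#' @param dist Rate distributions (`omega`, `alpha` lists).
#' @param n_sites Number of codon columns.
#' @param seed Mandatory RNG seed; identical specs give byte-identical
#'   output.
#' @param hyper A [model_hyper()] describing the constraint set of `dist`.
#' @param code A [genetic_code()].
#' @export
simulation_spec <- function(tree, theta, pi34, dist, n_sites, seed,
                            hyper = model_hyper(
                              n_omega = length(dist$omega$rates),
                              m_alpha = length(dist$alpha$rates),
                              error_sink = FALSE),
                            code = genetic_code()) {
  if (inherits(tree, "phylogeny")) tree <- tree$phy
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0), n_sites >= 1, !missing(seed))
  # same unrooted-branch convention as the likelihood (one omega draw per
  # branch of the unrooted tree)
  if (ape::Ntip(tree) >= 3) {
    tree <- ape::collapse.singles(tree)
    if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  }
  validate_distributions(dist, hyper)
  structure(list(tree = tree, theta = theta, pi = pi34, dist = dist,
                 n_sites = as.integer(n_sites), seed = seed, hyper = hyper,
                 code = code),
            class = "simulation_spec")
}

#' Simulate a codon alignment under the branch-site mixture model
#'
#' Per site a synonymous rate class is drawn; per (branch, site) an omega
#' class is drawn independently; the root codon is drawn from the stationary
#' distribution and evolved down the tree by sampling rows of the
#' class-specific transition matrices.  One RNG stream is consumed in a
#' fixed order (site alpha classes, root codons, then branches in preorder
#' with children ordered by their smallest descendant label), so a seed
#' fully determines the output.
#'
#' @param spec A [simulation_spec()].
#' @return List with `alignment` (a `codon_alignment`), and `truth`: the
#'   per-site alpha classes, the (branch x site) omega class draws with
#'   branch labels, and the generating spec.
#' @export
simulate_alignment <- function(spec) {
  code <- spec$code
  freq <- codon_stationary_frequencies(spec$pi, code)
  om <- spec$dist$omega
  al <- spec$dist$alpha
  N <- length(om$rates)
  M <- length(al$rates)
  ns <- spec$n_sites
  scale <- rate_scale(code, spec$theta, spec$pi, freq,
                      sum(om$rates * om$weights))
  eigs <- class_eigs(code, spec$theta, spec$pi, freq, om$rates)

  phy <- ape::reorder.phylo(spec$tree, "postorder")
  edge <- phy$edge
  elen <- phy$edge.length
  ntip <- length(phy$tip.label)
  ord <- preorder_edges(phy)

  # cumulative transition rows per (omega class, alpha class, branch)
  trans_cum <- function(k, m, e) {
    eg <- eigs[[k]]
    x <- al$rates[m] * elen[e] * scale
    P <- eg$U %*% (exp(drop(eg$lam) * x) * eg$Uinv)
    P[P < 0] <- 0
    P <- P / rowSums(P)
    t(apply(P, 1, cumsum))
  }

  with_local_seed(spec$seed, {
    alpha_class <- sample.int(M, ns, replace = TRUE, prob = al$weights)
    root <- edge[nrow(edge), 1]  # postorder: root is the last parent
    node_state <- matrix(0L, max(edge), ns)
    node_state[root, ] <- sample.int(length(freq), ns, replace = TRUE,
                                     prob = freq)
    omega_class <- matrix(0L, nrow(edge), ns)
    for (e in ord) {
      pa <- edge[e, 1]; ch <- edge[e, 2]
      k <- sample.int(N, ns, replace = TRUE, prob = om$weights)
      omega_class[e, ] <- k
      u <- stats::runif(ns)
      st <- integer(ns)
      for (m in seq_len(M)) {
        for (kk in unique(k[alpha_class == m])) {
          idx <- which(alpha_class == m & k == kk)
          cs <- trans_cum(kk, m, e)
          st[idx] <- rowSums(u[idx] > cs[node_state[pa, idx], , drop = FALSE]) + 1L
        }
      }
      node_state[ch, ] <- st
    }
    seqs <- apply(node_state[seq_len(ntip), , drop = FALSE], 1,
                  function(s) paste(code$codons[s], collapse = ""))
    aln <- codon_alignment(seqs, phy$tip.label, code)
    rownames(omega_class) <- ifelse(edge[, 2] <= ntip,
                                    phy$tip.label[edge[, 2]],
                                    paste0("Node", edge[, 2]))
    list(alignment = aln,
         truth = list(alpha_class = alpha_class, omega_class = omega_class,
                      spec = spec, tree = phy))
  })
}

# preorder edge indices (parents before children), children visited in
# order of their smallest descendant tip label
preorder_edges <- function(phy) {
  edge <- phy$edge
  ntip <- length(phy$tip.label)
  nnode <- max(edge)
  lab <- character(nnode)
  lab[seq_len(ntip)] <- phy$tip.label
  for (e in seq_len(nrow(edge))) {  # postorder: children resolved first
    pa <- edge[e, 1]; ch <- edge[e, 2]
    lab[pa] <- if (lab[pa] == "") lab[ch] else min(lab[pa], lab[ch])
  }
  root <- edge[nrow(edge), 1]
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  out <- integer(0)
  stack <- list(root)
  while (length(stack) > 0) {
    nd <- stack[[1]]; stack <- stack[-1]
    es <- kids[[as.character(nd)]]
    if (is.null(es)) next
    es <- es[order(lab[edge[es, 2]])]
    out <- c(out, es)
    stack <- c(as.list(edge[es, 2]), stack)
  }
  out
}

#' Overwrite a segment of one taxon with non-homologous codons
#'
#' Emulates a local mis-alignment: the chosen taxon's codons in the segment
#' are replaced either by uniform random sense codons (`mode = "random"`) or
#' by a one-nucleotide frameshifted copy of its own sequence with any
#' resulting stop/incomplete codons resampled (`mode = "frameshift"`).
#' This is deliberately test-oriented functionality: the generating model
#' itself is error-free.
#'
#' @param alignment A `codon_alignment`.
#' @param taxon Taxon to corrupt.
#' @param start First codon column of the segment (1-based).
#' @param length Segment length in codons (0 = no-op).
#' @param seed RNG seed.
#' @param mode `"random"` or `"frameshift"`.
#' @return List with the corrupted `alignment` and `truth_mask` (data.frame
#'   of taxon/site pairs that were overwritten).
#' @export
inject_error_segment <- function(alignment, taxon, start, length, seed,
                                 mode = c("random", "frameshift")) {
  mode <- match.arg(mode)
  stopifnot(taxon %in% alignment$taxa, start >= 1,
            start + length - 1 <= alignment$n_sites, length >= 0)
  if (length == 0)
    return(list(alignment = alignment,
                truth_mask = data.frame(taxon = character(0),
                                        site = integer(0))))
  code <- alignment$code
  row <- match(taxon, alignment$taxa)
  sites <- seq(start, start + length - 1)
  with_local_seed(seed, {
    if (mode == "random") {
      new <- code$codons[sample.int(length(code$codons), length,
                                    replace = TRUE)]
    } else {
      nt <- paste(alignment$triplets[row, sites], collapse = "")
      shifted <- substr(paste0(substring(nt, 2), "A"), 1, 3 * length)
      new <- substring(shifted, 3 * seq_len(length) - 2, 3 * seq_len(length))
      bad <- !(new %in% code$codons)
      if (any(bad))
        new[bad] <- code$codons[sample.int(length(code$codons), sum(bad),
                                           replace = TRUE)]
    }
    trip <- alignment$triplets
    trip[row, sites] <- new
    seqs <- apply(trip, 1, paste, collapse = "")
    list(alignment = codon_alignment(seqs, alignment$taxa, code),
         truth_mask = data.frame(taxon = taxon, site = sites,
                                 stringsAsFactors = FALSE))
  })
}

#' Write a simulated data set to FASTA / Newick / TSV truth tables
#'
#' @param sim Output of [simulate_alignment()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named vector of the written paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  nw <- file.path(dir, paste0(prefix, ".nwk"))
  tt <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_masked_fasta(sim$alignment, fa)
  ape::write.tree(sim$truth$tree, nw)
  truth <- data.frame(branch = rep(rownames(sim$truth$omega_class),
                                   ncol(sim$truth$omega_class)),
                      site = rep(seq_len(ncol(sim$truth$omega_class)),
                                 each = nrow(sim$truth$omega_class)),
                      omega_class = as.vector(sim$truth$omega_class))
  utils::write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  c(fasta = fa, newick = nw, truth = tt)
}
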