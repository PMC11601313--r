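#' Read a Newick tree and match it to an alignment
#'
#' The tree is treated as unrooted for likelihood purposes (the substitution
#' model is reversible, so the likelihood is invariant to root placement);
#' an internal node serves as the computational root.  Missing branch lengths
#' are initialized to a small positive default (0.1 substitutions/site) and
#' are re-estimated during model fitting.
#'
#' @param path Path to a Newick file (or a Newick string).
#' @param alignment A `codon_alignment` whose taxa must match the tree's
#'   leaf labels exactly.
#' @return A `phylogeny`: list with the `ape::phylo` tree (postorder), the
#'   postorder `edge` matrix, branch lengths `elen`, `ntip`, `tip_rows`
#'   (alignment row per tip number), and per-edge leaf `splits`.
#' @export
read_newick <- function(path, alignment) {
  phy <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(phy)) stop("could not parse Newick input")
  phylogeny(phy, alignment)
}

#' Build the internal phylogeny representation from an `ape` tree
#'
#' @param phy An `ape::phylo` object.
#' @param alignment A `codon_alignment` with matching taxa.
#' @rdname read_newick
#' @export
phylogeny <- function(phy, alignment) {
  extra <- setdiff(phy$tip.label, alignment$taxa)
  missing <- setdiff(alignment$taxa, phy$tip.label)
  if (length(extra) || length(missing))
    stop("tree/alignment label mismatch;",
         if (length(extra)) paste0(" only in tree: ", paste(extra, collapse = ", ")),
         if (length(missing)) paste0(" only in alignment: ",
                                     paste(missing, collapse = ", ")))
  if (is.null(phy$edge.length)) {
    phy$edge.length <- rep(0.1, nrow(phy$edge))
  }
  phy$edge.length[is.na(phy$edge.length)] <- 0.1
  if (any(phy$edge.length < 0))
    stop("negative branch length in input tree")
  # the mixture draws omega independently per branch, so the branch
  # structure is part of the model: collapse degree-2 nodes and unroot so
  # that rooted and unrooted encodings of the same tree are equivalent
  if (ape::Ntip(phy) >= 3) {
    phy <- ape::collapse.singles(phy)
    if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  }
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  edge <- phy$edge
  storage.mode(edge) <- "integer"
  # leaves below each edge's child (computational-root side excluded)
  nnode <- max(edge)
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (e in seq_len(nrow(edge))) {
    pa <- edge[e, 1]; ch <- edge[e, 2]
    below[[pa]] <- c(below[[pa]], below[[ch]])
  }
  splits <- lapply(seq_len(nrow(edge)), function(e) {
    inside <- sort(below[[edge[e, 2]]])
    list(inside = phy$tip.label[inside],
         outside = phy$tip.label[sort(setdiff(seq_len(ntip), inside))])
  })
  structure(list(phy = phy, edge = edge, elen = phy$edge.length,
                 ntip = ntip,
                 tip_rows = match(phy$tip.label, alignment$taxa),
                 splits = splits, taxa = alignment$taxa),
            class = "phylogeny")
}

#' @export
print.phylogeny <- function(x, ...) {
  cat("Phylogeny:", x$ntip, "leaves,", nrow(x$edge), "branches, tree length",
      format(sum(x$elen), digits = 4), "subs/site\n")
  invisible(x)
}

# tip states reordered to tree tip numbering, pattern-compressed
tree_patterns <- function(tree, states) {
  compress_patterns(states[tree$tip_rows, , drop = FALSE])
}

# branch label for reports: tip name for terminal branches, "Node<k>" otherwise
branch_labels <- function(tree) {
  ch <- tree$edge[, 2]
  ifelse(ch <= tree$ntip, tree$phy$tip.label[ch], paste0("Node", ch))
}
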