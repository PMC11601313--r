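#' Assemble a branch-site mixture model state
#'
#' Bundles everything the likelihood engine needs: alignment patterns mapped
#' onto the tree, nucleotide-level parameters, stationary frequencies, branch
#' lengths, and the two rate distributions.
#'
#' @param alignment A `codon_alignment`.
#' @param tree A `phylogeny` (see [read_newick()]).
#' @param theta Named 6-vector of exchangeabilities (AC, AG, AT, CG, CT, GT),
#'   `theta["AG"] == 1`.
#' @param pi34 3x4 position-specific nucleotide frequencies.
#' @param dist List with `omega` and `alpha` distributions
#'   (`list(rates, weights)` each).
#' @param hyper A [model_hyper()] object.
#' @param elen Branch lengths (defaults to the tree's).
#' @param scale_omega Reference mean omega for the branch-length
#'   normalization (see [rate_scale()]).  Defaults to the mean of the
#'   omega distribution; model fits freeze it at the single-class
#'   (phase-3) estimate so that adding small-weight/extreme-rate classes
#'   does not silently rescale every branch.
#' @return A `busted_model` list.
#' @export
busted_model <- function(alignment, tree, theta, pi34, dist, hyper,
                         elen = tree$elen, scale_omega = NULL) {
  validate_distributions(dist, hyper)
  freq <- codon_stationary_frequencies(pi34, alignment$code)
  pat <- tree_patterns(tree, alignment$states)
  structure(list(alignment = alignment, tree = tree, theta = theta,
                 pi = pi34, freq = freq, dist = dist, hyper = hyper,
                 elen = elen, patterns = pat,
                 scale_omega = scale_omega),
            class = "busted_model")
}

# eigendecompositions + branch-length scale for the current parameters
engine_parts <- function(model) {
  om <- model$dist$omega
  eigs <- class_eigs(model$alignment$code, model$theta, model$pi,
                     model$freq, om$rates)
  ref <- model$scale_omega %||% sum(om$rates * om$weights)
  scale <- rate_scale(model$alignment$code, model$theta, model$pi,
                      model$freq, ref)
  list(eigs = eigs, scale = scale)
}

#' Log-likelihood of a codon alignment under the branch-site mixture
#'
#' Felsenstein pruning on per-branch marginal transition matrices: because
#' omega is drawn independently per (branch, site), mixing the per-class
#' transition matrices within each branch is exact.  Site patterns are
#' compressed; partial likelihoods are rescaled per node to prevent
#' underflow.
#'
#' @param model A [busted_model()].
#' @param per_site Also return per-site log-likelihood contributions.
#' @return The log-likelihood (scalar), or a list with `loglik` and
#'   `site_loglik` (length `n_sites`) when `per_site = TRUE`.
#' @export
log_likelihood <- function(model, per_site = FALSE) {
  ep <- engine_parts(model)
  res <- cpp_mix_loglik(ep$eigs, model$dist$omega$weights,
                        model$dist$alpha$rates, model$dist$alpha$weights,
                        model$tree$edge, model$elen, ep$scale,
                        model$patterns$states, model$patterns$w,
                        as.numeric(model$freq), per_site)
  if (!per_site) return(res$loglik)
  sl <- res$sitelog
  lq <- log(model$dist$alpha$weights)
  persite <- apply(sl, 1, function(v) {
    mx <- max(lq + v); mx + log(sum(exp(lq + v - mx)))
  })
  list(loglik = res$loglik, site_loglik = persite[model$patterns$index])
}

#' Per-site likelihoods for one synonymous-rate class
#'
#' Mostly a testing/inspection surface: the pruning likelihood of each codon
#' column conditional on the site's alpha class, before mixing over classes.
#'
#' @param model A [busted_model()].
#' @return Matrix `n_sites` x `m_alpha` of per-site log-likelihoods.
#' @export
site_likelihoods <- function(model) {
  ep <- engine_parts(model)
  res <- cpp_mix_loglik(ep$eigs, model$dist$omega$weights,
                        model$dist$alpha$rates, model$dist$alpha$weights,
                        model$tree$edge, model$elen, ep$scale,
                        model$patterns$states, model$patterns$w,
                        as.numeric(model$freq), TRUE)
  res$sitelog[model$patterns$index, , drop = FALSE]
}
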