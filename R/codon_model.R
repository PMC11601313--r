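#' Position-specific nucleotide frequencies, corrected for absent stop codons
#'
#' Implements the stop-codon-corrected F3x4 estimator: it solves for the
#' 3x4 table of position-specific nucleotide frequencies whose implied
#' stop-excluded codon distribution reproduces the observed position
#' marginals.  Raw counted frequencies are biased because stop codons never
#' appear in coding sequence, so the nucleotides they contain are
#' under-represented at the corresponding positions.  If the solver fails to
#' converge, raw counts with a 0.5 pseudocount are returned with a warning.
#'
#' @param alignment A `codon_alignment`.
#' @param pseudocount Pseudocount added to nucleotide counts (default 0.5);
#'   guards degenerate alignments where some nucleotide is never observed.
#' @return A 3x4 matrix (rows = codon positions, columns = A,C,G,T), each
#'   row summing to 1.
#' @export
corrected_position_frequencies <- function(alignment, pseudocount = 0.5) {
  code <- alignment$code
  obs <- observed_position_marginals(alignment, pseudocount)
  fit <- try(solve_cf3x4(obs, code), silent = TRUE)
  if (inherits(fit, "try-error") || fit$objective > 1e-8) {
    warning("corrected-F3x4 solver did not converge; using raw position frequencies")
    return(obs)
  }
  fit$pi
}

# observed per-position nucleotide marginals over resolved codons
observed_position_marginals <- function(alignment, pseudocount = 0.5) {
  code <- alignment$code
  st <- alignment$states
  resolved <- st[st > 0L]
  if (length(resolved) == 0) stop("alignment has no resolved codons")
  cmat <- do.call(rbind, strsplit(code$codons, ""))
  counts <- matrix(pseudocount, 3, 4, dimnames = list(NULL, code$nt))
  tab <- tabulate(resolved, nbins = length(code$codons))
  for (k in 1:3) {
    idx <- match(cmat[, k], code$nt)
    for (j in 1:4) counts[k, j] <- counts[k, j] + sum(tab[idx == j])
  }
  sweep(counts, 1, rowSums(counts), "/")
}

# marginals of the stop-excluded codon distribution implied by pi
implied_position_marginals <- function(pi34, code) {
  f <- codon_stationary_frequencies(pi34, code)
  cmat <- do.call(rbind, strsplit(code$codons, ""))
  out <- matrix(0, 3, 4, dimnames = list(NULL, code$nt))
  for (k in 1:3) {
    idx <- match(cmat[, k], code$nt)
    for (j in 1:4) out[k, j] <- sum(f[idx == j])
  }
  out
}

# least-squares solve for pi matching observed stop-excluded marginals
solve_cf3x4 <- function(obs, code) {
  to_pi <- function(x) {
    m <- rbind(c(x[1:3], 0), c(x[4:6], 0), c(x[7:9], 0))
    e <- exp(m - apply(m, 1, max))
    sweep(e, 1, rowSums(e), "/")
  }
  objfn <- function(x) {
    d <- implied_position_marginals(to_pi(x), code) - obs
    sum(d^2)
  }
  start <- as.vector(t(log(obs[, 1:3] / obs[, 4])))
  opt <- stats::nlminb(start, objfn,
                       control = list(iter.max = 500, abs.tol = 1e-16,
                                      rel.tol = 1e-14, x.tol = 1e-12))
  pi <- to_pi(opt$par)
  colnames(pi) <- code$nt
  list(pi = pi, objective = opt$objective)
}

#' Stationary codon frequencies induced by position-specific frequencies
#'
#' `freq(c)` is proportional to the product of the position frequencies of
#' the codon's three nucleotides, renormalized over sense codons.
#'
#' @param pi34 3x4 matrix of position-specific nucleotide frequencies.
#' @param code A [genetic_code()] object.
#' @return Named numeric vector over sense codons, summing to 1.
#' @export
codon_stationary_frequencies <- function(pi34, code = genetic_code()) {
  cmat <- do.call(rbind, strsplit(code$codons, ""))
  f <- pi34[1, match(cmat[, 1], code$nt)] *
       pi34[2, match(cmat[, 2], code$nt)] *
       pi34[3, match(cmat[, 3], code$nt)]
  tot <- sum(f)
  if (!is.finite(tot) || tot <= 0)
    stop("position frequencies place no mass on sense codons")
  stats::setNames(f / tot, code$codons)
}

#' MG94xREV instantaneous rate matrix
#'
#' Off-diagonal entries are `alpha * theta_ij * pi_jk` for one-nucleotide
#' synonymous changes and `alpha * omega * theta_ij * pi_jk` for
#' one-nucleotide non-synonymous changes (source nucleotide i to target j at
#' codon position k); multi-nucleotide changes have rate 0.  The diagonal
#' makes rows sum to zero.  The matrix is unscaled: branch-length
#' normalization is a model-level constant, see [rate_scale()].
#'
#' @param code A [genetic_code()] object.
#' @param theta Named numeric of 6 nucleotide exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT, with `theta["AG"] == 1`.
#' @param pi34 3x4 position-specific frequency matrix.
#' @param alpha Synonymous rate multiplier (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @return A 61x61 generator matrix over sense codons.
#' @export
build_rate_matrix <- function(code, theta, pi34, alpha = 1, omega = 1) {
  stopifnot(alpha > 0, omega >= 0)
  Q <- cpp_build_mg94(code$neighbors, as.numeric(theta), pi34, omega)
  dimnames(Q) <- list(code$codons, code$codons)
  alpha * Q
}

#' Branch-length normalization constant
#'
#' Branch lengths are expected nucleotide-level substitutions per site.  One
#' constant per model is computed from the weighted-mean generator (expected
#' omega over its distribution, alpha = 1): the codon-level expected rate is
#' divided by 3 so that a branch of length t accumulates `3 t` expected codon
#' substitutions under the mean process.
#'
#' @param code,theta,pi34 As in [build_rate_matrix()].
#' @param freq Stationary codon frequencies.
#' @param mean_omega Expectation of the omega distribution.
#' @return Scalar multiplier applied to `Q * t` before exponentiation.
#' @export
rate_scale <- function(code, theta, pi34, freq, mean_omega) {
  Q <- build_rate_matrix(code, theta, pi34, alpha = 1, omega = mean_omega)
  rho <- -sum(freq * diag(Q))
  3 / rho
}

# eigendecompositions of the per-omega-class generators (alpha = 1)
class_eigs <- function(code, theta, pi34, freq, omegas) {
  lapply(omegas, function(w) {
    Q <- cpp_build_mg94(code$neighbors, as.numeric(theta), pi34, w)
    cpp_eig_rev(Q, freq)
  })
}

# nucleotide GTR generator, normalized to one expected substitution per unit t
gtr_matrix <- function(theta, pi_nt) {
  Q <- matrix(0, 4, 4, dimnames = list(names(pi_nt), names(pi_nt)))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ord <- c("AC", "AG", "AT", "CG", "CT", "GT")
  for (i in seq_len(6)) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    Q[a, b] <- theta[ord[i]] * pi_nt[b]
    Q[b, a] <- theta[ord[i]] * pi_nt[a]
  }
  diag(Q) <- -rowSums(Q)
  rho <- -sum(pi_nt * diag(Q))
  Q / rho
}
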