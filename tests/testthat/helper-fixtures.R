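# Shared fixtures: small trees, parameter sets, and independent oracles.
# Oracles deliberately avoid the package's computational path: transition
# matrices come from Matrix::expm and likelihoods from explicit enumeration
# of ancestral states and per-branch omega-class assignments.

fix_theta <- function() {
  stats::setNames(c(0.6, 1, 0.4, 0.9, 1.4, 0.8),
                  c("AC", "AG", "AT", "CG", "CT", "GT"))
}

fix_pi <- function() {
  matrix(c(0.30, 0.20, 0.28, 0.22,
           0.25, 0.25, 0.25, 0.25,
           0.35, 0.15, 0.20, 0.30), 3, 4, byrow = TRUE,
         dimnames = list(NULL, c("A", "C", "G", "T")))
}

# unit-mean alpha distribution
fix_alpha <- function(rates = c(0.5, 1, 2), weights = c(0.3, 0.4, 0.3)) {
  list(rates = rates / sum(rates * weights), weights = weights)
}

# no-selection omega profile (largest class at 1)
fix_omega_null <- function() {
  list(rates = c(0.1, 0.6, 1.0), weights = c(0.6, 0.3, 0.1))
}

# strong-selection profile: omega_3 = 5 carrying 5% weight
fix_omega_sel <- function() {
  list(rates = c(0.1, 0.6, 5.0), weights = c(0.6, 0.35, 0.05))
}

fix_tree8 <- function() {
  ape::read.tree(text = paste0(
    "((A:0.08,B:0.1):0.05,((C:0.12,D:0.07):0.04,",
    "(E:0.1,(F:0.09,(G:0.05,H:0.11):0.06):0.03):0.05):0.04);"))
}

fix_tree16 <- function(short_tip = NULL, short_len = 0.01) {
  tr <- withr::with_seed(1, ape::rtree(16, br = function(n) stats::runif(n, 0.02, 0.15)))
  tr$tip.label <- paste0("t", 1:16)
  if (!is.null(short_tip)) {
    term <- match(match(short_tip, tr$tip.label), tr$edge[, 2])
    tr$edge.length[term] <- short_len
  }
  tr
}

fix_sim <- function(tree, omega, n_sites, seed, alpha = fix_alpha()) {
  dist <- list(omega = omega, alpha = alpha)
  simulate_alignment(simulation_spec(tree, fix_theta(), fix_pi(), dist,
                                     n_sites = n_sites, seed = seed))
}

# reduced-effort optimizer settings for test-scale fits
fix_opts <- function(seed = 1, ...) {
  args <- list(K = 16, P = 2, seed = seed, nm_maxit = 40, maxit_dist = 120,
               rounds = 2, bl_passes = 1, phase3_rounds = 1)
  args[names(list(...))] <- list(...)
  do.call(fit_options, args)
}

# a fit-shaped object at chosen (true) parameters, for filter tests
pseudo_fit <- function(alignment, tree, dist, hyper = model_hyper(),
                       theta = fix_theta(), pi34 = fix_pi(),
                       elen = tree$elen, scale_omega = NULL) {
  structure(list(alignment = alignment, tree = tree, theta = theta,
                 pi = pi34, freq = codon_stationary_frequencies(pi34, alignment$code),
                 dist = dist, hyper = hyper, elen = elen,
                 scale_omega = scale_omega,
                 loglik = NA_real_, omega0 = scale_omega,
                 fingerprint = bustede:::data_fingerprint(alignment, tree)),
            class = "busted_fit")
}

# ---- independent likelihood oracle -----------------------------------------

# transition matrix via Matrix::expm (independent of the eigen route)
oracle_P <- function(theta, pi34, omega, x, code = genetic_code()) {
  Q <- build_rate_matrix(code, theta, pi34, 1, omega)
  as.matrix(Matrix::expm(Q * x))
}

# brute-force mixture log-likelihood: enumerate ancestral states and all
# per-branch omega assignments; alpha mixed per site
oracle_loglik <- function(alignment, phy, theta, pi34, dist,
                          scale_omega = NULL, per_site = FALSE) {
  code <- alignment$code
  freq <- codon_stationary_frequencies(pi34, code)
  ref <- if (is.null(scale_omega))
    sum(dist$omega$rates * dist$omega$weights) else scale_omega
  sc <- rate_scale(code, theta, pi34, freq, ref)
  edge <- phy$edge
  elen <- phy$elen
  nE <- nrow(edge)
  ntip <- phy$ntip
  N <- length(dist$omega$rates)
  M <- length(dist$alpha$rates)
  states <- alignment$states[phy$tip_rows, , drop = FALSE]
  internals <- sort(unique(edge[, 1]))
  root <- edge[nE, 1]
  assignments <- as.matrix(expand.grid(rep(list(seq_len(N)), nE)))
  site_lik <- matrix(0, alignment$n_sites, M)
  for (m in seq_len(M)) {
    am <- dist$alpha$rates[m]
    for (a in seq_len(nrow(assignments))) {
      ks <- assignments[a, ]
      pw <- prod(dist$omega$weights[ks])
      Ps <- lapply(seq_len(nE), function(e)
        oracle_P(theta, pi34, dist$omega$rates[ks[e]], am * elen[e] * sc, code))
      grid <- as.matrix(expand.grid(rep(list(seq_len(61)), length(internals))))
      colnames(grid) <- internals
      for (s in seq_len(alignment$n_sites)) {
        term <- freq[grid[, as.character(root)]]
        for (e in seq_len(nE)) {
          pa <- grid[, as.character(edge[e, 1])]
          ch <- edge[e, 2]
          if (ch <= ntip) {
            st <- states[ch, s]
            term <- term * (if (st == 0L) 1 else Ps[[e]][cbind(pa, st)])
          } else {
            term <- term * Ps[[e]][cbind(pa, grid[, as.character(ch)])]
          }
        }
        site_lik[s, m] <- site_lik[s, m] + pw * sum(term)
      }
    }
  }
  persite <- log(as.vector(site_lik %*% dist$alpha$weights))
  if (per_site) persite else sum(persite)
}

# random feasible distribution for oracle comparisons (2 omega classes,
# up to 2 alpha classes keeps the enumeration small)
oracle_random_dist <- function(n_omega = 2, m_alpha = 2) {
  w <- c(stats::runif(n_omega - 1, 0, 1), stats::runif(1, 1, 3))
  w <- sort(w)
  p <- stats::runif(n_omega, 0.2, 1)
  a <- sort(stats::runif(m_alpha, 0.2, 2))
  q <- stats::runif(m_alpha, 0.2, 1)
  q <- q / sum(q)
  list(omega = list(rates = w, weights = p / sum(p)),
       alpha = list(rates = a / sum(a * q), weights = q))
}

rand_pi <- function() {
  m <- matrix(stats::rexp(12) + 0.2, 3, 4)
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  m
}

rand_theta <- function() {
  th <- stats::setNames(exp(stats::runif(6, -1, 1)),
                        c("AC", "AG", "AT", "CG", "CT", "GT"))
  th["AG"] <- 1
  th
}

write_fasta_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
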