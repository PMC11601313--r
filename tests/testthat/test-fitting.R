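test_that("GTR phase agrees with phangorn and degenerates sensibly", {
  aln <- codon_alignment(c(A = "ATGAAACCCGGG", B = "ATGAGACCAGGA",
                           C = "CTGAAACACGGT", D = "ATGCAACCCGGC"))
  phy <- read_newick("((A:0.1,B:0.2):0.05,(C:0.15,D:0.08):0.1);", aln)
  # engine evaluation at fixed parameters equals an independent GTR
  # implementation (phangorn) on the same data
  nts <- bustede:::nucleotide_states(aln)
  pat <- bustede:::compress_patterns(nts[phy$tip_rows, , drop = FALSE])
  pi_nt <- stats::setNames(c(0.3, 0.25, 0.25, 0.2), c("A", "C", "G", "T"))
  theta <- stats::setNames(c(0.5, 1, 0.3, 0.8, 1.5, 0.7),
                           c("AC", "AG", "AT", "CG", "CT", "GT"))
  eig <- bustede:::cpp_eig_rev(bustede:::gtr_matrix(theta, pi_nt), pi_nt)
  ll_mine <- bustede:::cpp_mix_loglik(list(eig), 1, 1, 1, phy$edge, phy$elen,
                                      1, pat$states, pat$w, pi_nt,
                                      FALSE)$loglik
  chars <- matrix(c("A", "C", "G", "T")[ifelse(nts == 0, NA, nts)],
                  nrow = nrow(nts), dimnames = list(aln$taxa, NULL))
  fit_ph <- phangorn::pml(phy$phy, phangorn::phyDat(chars, type = "DNA"),
                          bf = pi_nt, Q = unname(theta), k = 1)
  expect_equal(ll_mine, as.numeric(stats::logLik(fit_ph)), tolerance = 1e-6)

  # the fitted phase-1 likelihood cannot be worse than phangorn's joint
  # optimum by more than optimizer slack
  p1 <- fit_phase1_gtr(aln, phy, fix_opts())
  opt_ph <- phangorn::optim.pml(fit_ph, optQ = TRUE, optEdge = TRUE,
                                control = phangorn::pml.control(
                                  epsilon = 1e-8, maxit = 50, trace = 0))
  expect_gt(p1$loglik, as.numeric(stats::logLik(opt_ph)) - 0.1)
  expect_identical(unname(p1$theta["AG"]), 1)

  # identical sequences collapse every branch length to ~0
  same <- codon_alignment(c(A = "ATGAAACCC", B = "ATGAAACCC",
                            C = "ATGAAACCC"))
  phy_s <- read_newick("(A:0.1,B:0.2,C:0.1);", same)
  p1s <- fit_phase1_gtr(same, phy_s, fix_opts())
  expect_lt(max(p1s$elen), 1e-6)
})

test_that("GTR recovers equal exchangeabilities from JC-like data", {
  # simulate with all thetas equal, uniform frequencies, omega = 1:
  # every nucleotide exchangeability should come back near 1 (n = 3000 nt)
  tr <- ape::read.tree(text = "((A:0.2,B:0.25):0.1,(C:0.15,D:0.3):0.1);")
  pi_u <- matrix(0.25, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  th1 <- stats::setNames(rep(1, 6), c("AC", "AG", "AT", "CG", "CT", "GT"))
  dist <- list(omega = list(rates = 1, weights = 1),
               alpha = list(rates = 1, weights = 1))
  spec <- simulation_spec(tr, th1, pi_u, dist, n_sites = 1000, seed = 5,
                          hyper = model_hyper(1, 1, error_sink = FALSE))
  sim <- simulate_alignment(spec)
  phy <- phylogeny(sim$truth$tree, sim$alignment)
  p1 <- fit_phase1_gtr(sim$alignment, phy, fix_opts())
  expect_true(all(p1$theta > 0.75 & p1$theta < 1.35))
})

test_that("single-class codon phases recover the mean omega", {
  tr <- fix_tree8()
  hy1 <- model_hyper(1, 1, error_sink = FALSE)
  for (tru in c(1, 0.1)) {
    dist <- list(omega = list(rates = tru, weights = 1),
                 alpha = list(rates = 1, weights = 1))
    sim <- simulate_alignment(simulation_spec(tr, fix_theta(), fix_pi(),
                                              dist, n_sites = 500,
                                              seed = 40 + tru * 10,
                                              hyper = hy1))
    phy <- phylogeny(sim$truth$tree, sim$alignment)
    p1 <- fit_phase1_gtr(sim$alignment, phy, fix_opts())
    p23 <- fit_phase2_3_mg94(sim$alignment, phy, p1, fix_opts())
    if (tru == 1) expect_true(p23$omega0 > 0.8 && p23$omega0 < 1.25)
    if (tru == 0.1) expect_lt(p23$omega0, 0.3)
    # the joint refinement never loses likelihood over the mean-only phase
    expect_gte(p23$loglik, p23$loglik2 - 1e-6)
  }
})

test_that("simplex screening obeys its contracts", {
  # the stopping threshold is max(0.5, 1e-4 |logL|)
  expect_identical(simplex_stop_tol(-2000), 0.5)
  expect_identical(simplex_stop_tol(-8e4), 8)

  hy <- model_hyper()
  starts <- propose_starts(12, 0.4, hy, seed = 2)
  # a deterministic concave toy objective over the packed vector
  objective <- function(u) -sum((u - 0.1)^2)
  scr <- screen_and_polish(starts, objective, hy, -2000,
                           fix_opts(P = 12, nm_maxit = 25))
  # with P = K screening is a pure ordering: the polished optimum cannot be
  # worse than any unpolished start
  expect_gte(scr$loglik, max(scr$scores))
  scr2 <- screen_and_polish(starts, objective, hy, -2000,
                            fix_opts(P = 3, nm_maxit = 25))
  expect_gte(scr2$loglik, max(scr2$scores))
  expect_error(screen_and_polish(starts, function(u) -Inf, hy, -2000,
                                 fix_opts()),
               "non-finite")
})

test_that("full fits nest correctly and AICc is internally consistent", {
  sim <- fix_sim(fix_tree8(), fix_omega_null(), n_sites = 120, seed = 77)
  phy <- phylogeny(sim$truth$tree, sim$alignment)
  opts <- fix_opts(K = 8, maxit_dist = 60, rounds = 1, nm_maxit = 20)
  p123 <- bustede:::fit_phases123(sim$alignment, phy, opts)
  s_alt <- fit_busted(sim$alignment, phy,
                      model_hyper(3, 3, error_sink = FALSE), opts,
                      phase123 = p123)
  s_null <- fit_null_from_alt(s_alt, opts)
  s_alt <- ensure_nesting(s_alt, s_null, opts)
  # nesting: alternative cannot fit worse than its null
  expect_gte(s_alt$loglik, s_null$loglik - 1e-6)
  expect_equal(s_null$n_params, s_alt$n_params - 1)
  # AICc consistent with the stored log-likelihood and parameter count
  expect_equal(s_alt$aicc,
               aicc(s_alt$loglik, s_alt$n_params,
                    length(sim$alignment$taxa) * sim$alignment$n_sites),
               tolerance = 1e-12)
  ledger <- s_alt$param_ledger
  expect_identical(sum(ledger), s_alt$n_params)
  expect_identical(unname(ledger["theta"]), 5L)
  expect_identical(unname(ledger["frequencies"]), 9L)
  expect_identical(unname(ledger["branch_lengths"]), nrow(phy$edge))

  # BUSTED-E adds exactly two free parameters over BUSTED-S
  e_alt <- fit_busted(sim$alignment, phy, model_hyper(), opts,
                      phase123 = p123, warm_fit = s_alt)
  expect_equal(e_alt$n_params, s_alt$n_params + 2)
  expect_gte(e_alt$loglik, s_alt$loglik - 0.11)
})

test_that("fits are bit-reproducible for a fixed seed", {
  sim <- fix_sim(fix_tree8(), fix_omega_null(), n_sites = 80, seed = 12)
  phy <- phylogeny(sim$truth$tree, sim$alignment)
  opts <- fix_opts(K = 6, maxit_dist = 40, rounds = 1, nm_maxit = 15, seed = 4)
  f1 <- fit_busted(sim$alignment, phy, model_hyper(), opts)
  f2 <- fit_busted(sim$alignment, phy, model_hyper(), opts)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$dist, f2$dist)
  expect_identical(f1$elen, f2$elen)
})
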