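test_that("empirical Bayes factors follow the posterior/prior odds forms", {
  # posterior equal to prior gives no evidence either way
  expect_equal(ebf_error(0.01, 0.01), 1, tolerance = 1e-12)
  expect_equal(ebf_selection(0.2, 0.1, 0.2, 0.1), 1, tolerance = 1e-12)
  # worked example: posterior 0.5 against a 1% prior
  expect_equal(ebf_error(0.5, 0.01), 1 / (0.01 / 0.99), tolerance = 1e-12)
  expect_equal(ebf_error(0.5, 0.01), 99, tolerance = 1e-12)
  # posterior -> 1 diverges; the reporting cap bounds it
  expect_identical(ebf_error(1, 0.01), Inf)
  expect_identical(ebf_error(1, 0.01, cap = 1e6), 1e6)
  # sentinels: no error class instantiated
  expect_true(is.na(ebf_error(0.5, 0)))
  expect_true(is.na(ebf_selection(0.5, 0.2, 0, 0.1)))
  # error preferred with zero selection posterior
  expect_identical(ebf_selection(0.3, 0, 0.005, 0.1), Inf)
  # hand-computed odds ratio
  expect_equal(ebf_selection(0.3, 0.2, 0.005, 0.1),
               (0.3 / 0.2) / (0.005 / 0.1), tolerance = 1e-12)
})

test_that("conditional class probabilities are coherent posteriors", {
  sim <- fix_sim(fix_tree8(), fix_omega_null(), n_sites = 40, seed = 3)
  phy <- phylogeny(sim$truth$tree, sim$alignment)
  dist <- list(omega = list(rates = c(0.1, 0.6, 1.5, 150),
                            weights = c(0.55, 0.3, 0.145, 0.005)),
               alpha = fix_alpha())
  fit <- pseudo_fit(sim$alignment, phy, dist, scale_omega = 0.5)
  cond <- conditional_class_probabilities(fit)
  tot <- apply(cond$posterior, c(1, 2), sum)
  expect_lt(max(abs(tot - 1)), 1e-9)
  # mixing the forced likelihoods by the priors recovers the site
  # likelihood on every branch: posterior-weighted consistency
  m <- busted_model(sim$alignment, phy, fix_theta(), fix_pi(), dist,
                    model_hyper(), scale_omega = 0.5)
  site_ll <- log_likelihood(m, per_site = TRUE)$site_loglik
  for (e in c(1, 5, nrow(phy$edge))) {
    mixed <- vapply(seq_len(sim$alignment$n_sites), function(s) {
      v <- cond$cond_loglik[e, s, ]
      mx <- max(v)
      mx + log(sum(dist$omega$weights * exp(v - mx)))
    }, numeric(1))
    expect_equal(mixed, site_ll, tolerance = 1e-8)
  }
})

test_that("a zero-length branch is uninformative about its omega class", {
  tr <- fix_tree8()
  tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")] <- 0
  sim <- fix_sim(tr, fix_omega_null(), n_sites = 25, seed = 8)
  phy <- phylogeny(sim$truth$tree, sim$alignment)
  dist <- list(omega = list(rates = c(0.1, 0.6, 1.5, 150),
                            weights = c(0.55, 0.3, 0.145, 0.005)),
               alpha = fix_alpha())
  fit <- pseudo_fit(sim$alignment, phy, dist, elen = phy$elen,
                    scale_omega = 0.5)
  cond <- conditional_class_probabilities(fit)
  eA <- which(bustede:::branch_labels(phy) == "A")
  for (k in 1:4)
    expect_equal(unname(cond$posterior[eA, , k]),
                 rep(dist$omega$weights[k], sim$alignment$n_sites),
                 tolerance = 1e-9)
  expect_equal(unname(ebf_error(cond$posterior[eA, 1, 4],
                                dist$omega$weights[4])), 1, tolerance = 1e-7)
})

test_that("conditional probabilities match a brute-force Bayes computation", {
  aln <- codon_alignment(c(A = "ATGAAACAT", B = "ATGAGGCGT",
                           C = "CTAAAACAT"))
  phy <- read_newick("(A:0.15,B:0.3,C:0.2);", aln)
  dist <- list(omega = list(rates = c(0.2, 2.5), weights = c(0.8, 0.2)),
               alpha = fix_alpha(c(0.6, 1.6), c(0.5, 0.5)))
  hy <- model_hyper(n_omega = 2, m_alpha = 2, error_sink = FALSE)
  fit <- pseudo_fit(aln, phy, dist, hyper = hy, scale_omega = 0.6)
  cond <- conditional_class_probabilities(fit)
  # oracle: per branch and class, enumerate all other branches' classes
  code <- aln$code
  freq <- codon_stationary_frequencies(fix_pi(), code)
  sc <- rate_scale(code, fix_theta(), fix_pi(), freq, 0.6)
  states <- aln$states[phy$tip_rows, , drop = FALSE]
  for (e in 1:3) {
    for (s in 1:3) {
      condlik <- numeric(2)
      for (k in 1:2) {
        tot <- 0
        for (m in 1:2) {
          am <- dist$alpha$rates[m]
          others <- as.matrix(expand.grid(1:2, 1:2))
          for (o in seq_len(nrow(others))) {
            ks <- integer(3)
            ks[e] <- k
            ks[-e] <- others[o, ]
            pr <- prod(dist$omega$weights[ks[-e]])
            lik <- 0
            for (r in 1:61) {
              pp <- freq[r]
              for (b in 1:3) {
                P <- oracle_P(fix_theta(), fix_pi(), dist$omega$rates[ks[b]],
                              am * phy$elen[b] * sc, code)
                tip <- phy$edge[b, 2]
                pp <- pp * P[r, states[tip, s]]
              }
              lik <- lik + pp
            }
            tot <- tot + dist$alpha$weights[m] * pr * lik
          }
        }
        condlik[k] <- tot
      }
      post <- dist$omega$weights * condlik
      post <- post / sum(post)
      expect_equal(unname(cond$posterior[e, s, ]), unname(post),
                   tolerance = 1e-8)
    }
  }
})

# hand-made conditional structure to exercise the decision rules exactly
fake_cond <- function(post_err, post_sel, prior, nb, ns) {
  N <- length(prior)
  post <- array(0, dim = c(nb, ns, N))
  post[, , N] <- post_err
  post[, , N - 1] <- post_sel
  rest <- (1 - post_err - post_sel) / (N - 2)
  for (k in seq_len(N - 2)) post[, , k] <- rest
  list(posterior = post, cond_loglik = array(0, dim = c(nb, ns, N)),
       prior = prior)
}

test_that("mask decisions apply inclusive thresholds and the column rule", {
  aln <- codon_alignment(c(A = "ATGAAACATCGT", B = "ATGAAGCGTCGA",
                           C = "ATAACACATCGG", D = "CTGAAACACCGT",
                           E = "ATGAAACATCGC"))
  phy <- read_newick("((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05,E:0.1);", aln)
  dist <- list(omega = list(rates = c(0.1, 0.5, 1.5, 150),
                            weights = c(0.6, 0.29, 0.1, 0.01)),
               alpha = fix_alpha())
  fit <- pseudo_fit(aln, phy, dist, scale_omega = 0.5)
  prior <- dist$omega$weights
  nb <- nrow(phy$edge)
  ns <- aln$n_sites
  lab <- bustede:::branch_labels(phy)

  # posterior chosen so that EBF_e and EBF_s land essentially on the
  # cutoffs for taxon A at site 2; the thresholds are inclusive, so
  # setting the cutoffs to the achieved values must still mask
  post_err_eq <- (100 * (0.01 / 0.99)) / (1 + 100 * (0.01 / 0.99))
  post_sel_eq <- post_err_eq / (20 * 0.01 / prior[3])
  cond <- fake_cond(1e-6, 0.1, prior, nb, ns)
  cond$posterior[lab == "A", 2, 4] <- post_err_eq
  cond$posterior[lab == "A", 2, 3] <- post_sel_eq
  mask <- decide_masks(fit, filter_config(), cond = cond)
  achieved <- filter_config(C1 = mask$ebf_error[lab == "A", 2],
                            C2 = mask$ebf_selection[lab == "A", 2])
  expect_equal(achieved$C1, 100, tolerance = 1e-9)
  expect_equal(achieved$C2, 20, tolerance = 1e-9)
  mask <- decide_masks(fit, achieved, cond = cond)
  expect_identical(mask$masked_codons,
                   data.frame(taxon = "A", site = 2L,
                              stringsAsFactors = FALSE))

  # EBF_e just below C1 never masks, however extreme EBF_s is
  cond2 <- fake_cond(1e-6, 0.1, prior, nb, ns)
  cond2$posterior[lab == "A", 2, 4] <- post_err_eq * 0.98
  cond2$posterior[lab == "A", 2, 3] <- 1e-9
  mask2 <- decide_masks(fit, filter_config(), cond = cond2)
  expect_identical(nrow(mask2$masked_codons), 0L)

  # internal branch: the smaller split's observed codons are masked, and
  # once 3 of 5 observed codons (0.6 > 0.4) are masked the column goes
  eint <- which(lab %in% paste0("Node", 7:9) &
                  lengths(lapply(phy$splits, `[[`, "inside")) == 2)[1]
  cond3 <- fake_cond(1e-6, 1e-4, prior, nb, ns)
  cond3$posterior[eint, 3, 4] <- 0.9
  cond3$posterior[eint, 3, 3] <- 1e-6
  cond3$posterior[lab == "E", 3, 4] <- 0.9
  cond3$posterior[lab == "E", 3, 3] <- 1e-6
  mask3 <- decide_masks(fit, filter_config(), cond = cond3)
  expect_true(mask3$column_masked[3])
  expect_true(all(mask3$masked[, 3]))

  # masking is monotone in the cutoffs
  mask_tight <- decide_masks(fit, filter_config(C1 = 1e5, C2 = 1e4),
                             cond = cond3)
  expect_lte(nrow(mask_tight$masked_codons), nrow(mask3$masked_codons))
})

test_that("an uninstantiated error class masks nothing", {
  sim <- fix_sim(fix_tree8(), fix_omega_null(), n_sites = 30, seed = 14)
  phy <- phylogeny(sim$truth$tree, sim$alignment)
  dist <- list(omega = list(rates = c(0.1, 0.6, 1.5, 150),
                            weights = c(0.55, 0.3, 0.15, 0) +
                              c(0, 0, 0, 1e-12)),
               alpha = fix_alpha())
  dist$omega$weights <- dist$omega$weights / sum(dist$omega$weights)
  fit <- pseudo_fit(sim$alignment, phy, dist, scale_omega = 0.5)
  mask <- decide_masks(fit)
  expect_identical(nrow(mask$masked_codons), 0L)
  expect_true(all(is.na(mask$ebf_error)))
})
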