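#' Options controlling the multi-phase maximum-likelihood fit
#'
#' The fitting procedure mirrors the staged BUSTED strategy: a nucleotide
#' GTR fit, a single-class MG94 fit of the mean dN/dS, joint refinement,
#' Latin-hypercube proposals of the rate distributions with means pinned to
#' the single-class estimates, Nelder-Mead screening of the best proposals,
#' and a final joint optimization.
#'
#' @param K Latin-hypercube sample count (default 250).
#' @param P Starts retained for simplex polishing (default 5).
#' @param seed RNG seed for the proposals; fits are otherwise deterministic.
#' @param nm_maxit Iteration cap for each screening simplex run.
#' @param maxit_dist Iteration cap for the distribution block in the final
#'   optimization.
#' @param rounds Maximum coordinate-block rounds in the final optimization.
#' @param bl_passes Branch-length optimization passes per round.
#' @param phase3_rounds Block rounds in the joint MG94 refinement.
#' @param tol Relative log-likelihood improvement below which a block round
#'   loop stops.
#' @param optimize_blens Re-estimate branch lengths (phases 3 and 7).
#' @param nm_reltol Relative convergence tolerance of the Nelder-Mead
#'   blocks (smaller = longer polishing).
#' @param probes Run the error-sink basin probes during the full
#'   optimization (see the phase-7 documentation); disabling them saves
#'   time when the data are known to be free of error-like segments.
#' @export
fit_options <- function(K = 250, P = 5, seed = 1, nm_maxit = 200,
                        maxit_dist = 400, rounds = 3, bl_passes = 2,
                        phase3_rounds = 2, tol = 1e-6,
                        optimize_blens = TRUE, nm_reltol = 1e-9,
                        probes = TRUE) {
  stopifnot(K >= P, P >= 1)
  structure(list(K = K, P = P, seed = seed, nm_maxit = nm_maxit,
                 maxit_dist = maxit_dist, rounds = rounds,
                 bl_passes = bl_passes, phase3_rounds = phase3_rounds,
                 tol = tol, optimize_blens = optimize_blens,
                 nm_reltol = nm_reltol, probes = probes),
            class = "fit_options")
}

# ---- phase 1: nucleotide GTR -----------------------------------------------

#' Phase 1: nucleotide-level GTR fit
#'
#' Reads the alignment as nucleotide columns (gaps/ambiguities missing) and
#' fits GTR exchangeabilities (normalized to `theta_AG = 1`) plus branch
#' lengths; empirical base frequencies are used.  Supplies starting branch
#' lengths and nucleotide biases for the codon phases.
#'
#' @param alignment A `codon_alignment`.
#' @param tree A `phylogeny`.
#' @param options A [fit_options()].
#' @return List with `theta`, `elen`, `pi_nt`, `loglik`.
#' @export
fit_phase1_gtr <- function(alignment, tree, options = fit_options()) {
  nts <- nucleotide_states(alignment)
  pat <- compress_patterns(nts[tree$tip_rows, , drop = FALSE])
  counts <- tabulate(nts[nts > 0L], nbins = 4) + 0.5
  pi_nt <- stats::setNames(counts / sum(counts), alignment$code$nt)
  theta <- stats::setNames(rep(1, 6), c("AC", "AG", "AT", "CG", "CT", "GT"))
  elen <- pmax(tree$elen, 1e-8)

  ll_at <- function(theta, elen) {
    eig <- cpp_eig_rev(gtr_matrix(theta, pi_nt), pi_nt)
    cpp_mix_loglik(list(eig), 1, 1, 1, tree$edge, elen, 1,
                   pat$states, pat$w, pi_nt, FALSE)$loglik
  }
  cur <- ll_at(theta, elen)
  for (round in 1:4) {
    prev <- cur
    opt <- stats::nlminb(log(theta[-2]), function(lt) {
      th <- theta; th[-2] <- exp(clamp(lt, -20, 20))
      -ll_at(th, elen)
    }, control = list(iter.max = 100, rel.tol = 1e-10))
    theta[-2] <- exp(clamp(opt$par, -20, 20))
    eig <- cpp_eig_rev(gtr_matrix(theta, pi_nt), pi_nt)
    bl <- cpp_optimize_blens(list(eig), 1, 1, 1, tree$edge, elen, 1,
                             pat$states, pat$w, pi_nt, 1e-9, 20)
    if (bl$loglik >= -opt$objective) elen <- as.numeric(bl$elen)
    cur <- ll_at(theta, elen)
    if (cur - prev < max(1e-6, options$tol * abs(cur))) break
  }
  list(theta = theta, elen = elen, pi_nt = pi_nt, loglik = cur)
}

# ---- phases 2-3: single-class MG94 -----------------------------------------

#' Phases 2-3: mean-dN/dS MG94xREV fit
#'
#' Phase 2 estimates the single mean `omega0` with everything else held at
#' the GTR estimates; phase 3 jointly refines `omega0`, the nucleotide
#' biases, and the branch lengths under the full single-class codon model.
#'
#' @param alignment,tree,options As in [fit_phase1_gtr()].
#' @param phase1 Output of [fit_phase1_gtr()].
#' @return List with `theta`, `elen`, `omega0`, `pi`, `freq`, `loglik`
#'   (phase-3 value) and `loglik2` (phase-2 value).
#' @export
fit_phase2_3_mg94 <- function(alignment, tree, phase1,
                              options = fit_options()) {
  code <- alignment$code
  pi34 <- corrected_position_frequencies(alignment)
  freq <- codon_stationary_frequencies(pi34, code)
  pat <- tree_patterns(tree, alignment$states)
  theta <- phase1$theta
  elen <- phase1$elen

  ll_at <- function(theta, w0, elen) {
    eig <- class_eigs(code, theta, pi34, freq, w0)
    sc <- rate_scale(code, theta, pi34, freq, w0)
    cpp_mix_loglik(eig, 1, 1, 1, tree$edge, elen, sc,
                   pat$states, pat$w, as.numeric(freq), FALSE)$loglik
  }
  # phase 2: mean omega only
  o2 <- stats::optimize(function(lw) -ll_at(theta, exp(lw), elen),
                        lower = log(1e-4), upper = log(20), tol = 1e-7)
  w0 <- exp(o2$minimum)
  loglik2 <- -o2$objective
  # phase 3: joint refinement in blocks
  cur <- loglik2
  for (round in seq_len(options$phase3_rounds)) {
    prev <- cur
    opt <- stats::nlminb(c(log(theta[-2]), log(w0)), function(par) {
      th <- theta; th[-2] <- exp(clamp(par[1:5], -20, 20))
      -ll_at(th, exp(clamp(par[6], -12, 5)), elen)
    }, control = list(iter.max = 100, rel.tol = 1e-9))
    theta[-2] <- exp(clamp(opt$par[1:5], -20, 20))
    w0 <- exp(clamp(opt$par[6], -12, 5))
    cur <- -opt$objective
    if (options$optimize_blens) {
      eig <- class_eigs(code, theta, pi34, freq, w0)
      sc <- rate_scale(code, theta, pi34, freq, w0)
      bl <- cpp_optimize_blens(eig, 1, 1, 1, tree$edge, elen, sc,
                               pat$states, pat$w, as.numeric(freq), 1e-9, 20)
      if (bl$loglik >= cur) {
        elen <- as.numeric(bl$elen)
        cur <- bl$loglik
      }
    }
    if (cur - prev < max(1e-6, options$tol * abs(cur))) break
  }
  list(theta = theta, elen = elen, omega0 = w0, pi = pi34, freq = freq,
       loglik = cur, loglik2 = loglik2)
}

# ---- phases 4-6: proposals, screening, simplex polish ----------------------

# objective factory: loglik as a function of the packed distribution vector,
# with nucleotide parameters and branch lengths held fixed.  The
# branch-length normalization is referenced to `ref_omega` (the phase-3
# single-class mean), one constant per fit: were it recomputed from the
# current mixture mean, adding a tiny-weight extreme-omega class would
# rescale every branch and distort the likelihood surface.
make_dist_objective <- function(code, theta, pi34, freq, tree, pat, hyper,
                                elen, ref_omega) {
  sc <- rate_scale(code, theta, pi34, freq, ref_omega)
  function(u) {
    dist <- unpack_dist(u, hyper)
    om <- dist$omega
    eigs <- class_eigs(code, theta, pi34, freq, om$rates)
    cpp_mix_loglik(eigs, om$weights, dist$alpha$rates, dist$alpha$weights,
                   tree$edge, elen, sc, pat$states, pat$w,
                   as.numeric(freq), FALSE)$loglik
  }
}

#' Phases 5-6: screen proposed starts and polish the best by Nelder-Mead
#'
#' Evaluates the likelihood at every proposed distribution, keeps the top
#' `P`, and runs a bounded Nelder-Mead simplex from each, stopping when an
#' iteration fails to improve the log-likelihood by at least
#' `max(0.5, 1e-4 |logL(phase 3)|)`.  Returns the best polished start.
#'
#' @param starts List of distribution draws (see [propose_starts()]).
#' @param objective Function mapping a packed distribution vector to a
#'   log-likelihood (see the internal objective factory).
#' @param hyper A [model_hyper()].
#' @param loglik3 Phase-3 log-likelihood, used by the stopping rule.
#' @param options A [fit_options()].
#' @return List with the winning `dist`, its `loglik`, and the screening
#'   scores.
#' @export
screen_and_polish <- function(starts, objective, hyper, loglik3,
                              options = fit_options()) {
  us <- lapply(starts, pack_dist, hyper = hyper)
  scores <- vapply(us, function(u) tryCatch(objective(u), error = function(e) -Inf),
                   numeric(1))
  if (all(!is.finite(scores)))
    stop("all proposed starts have non-finite likelihood")
  keep <- order(scores, decreasing = TRUE)[seq_len(min(options$P, length(us)))]
  stop_tol <- simplex_stop_tol(loglik3)
  best_u <- us[[keep[1]]]
  best_ll <- scores[keep[1]]
  for (i in keep) {
    if (!is.finite(scores[i])) next
    o <- stats::optim(us[[i]], function(u) -objective(u),
                      method = "Nelder-Mead",
                      control = list(maxit = options$nm_maxit,
                                     reltol = stop_tol / (abs(loglik3) + 1)))
    if (-o$value > best_ll) {
      best_ll <- -o$value
      best_u <- o$par
    }
  }
  list(dist = unpack_dist(best_u, hyper), loglik = best_ll, scores = scores)
}

#' Stopping threshold for the screening simplex
#'
#' An iteration must improve the log-likelihood by at least
#' `max(0.5, 1e-4 |logL|)` to continue.
#'
#' @param loglik3 Phase-3 log-likelihood (negative).
#' @export
simplex_stop_tol <- function(loglik3) max(0.5, 1e-4 * abs(loglik3))

# ---- phase 7: full joint optimization --------------------------------------

#' Phase 7: full joint optimization from the best start
#'
#' Coordinate-block ascent over (rate distributions | nucleotide biases |
#' branch lengths), Nelder-Mead for the distribution block and a
#' quasi-Newton step for the biases, iterated until the round improvement
#' falls below tolerance.  All ordering, bound, and error-sink constraints
#' are maintained by the parameterization and asserted on exit.
#'
#' @param start_dist Starting distributions (`omega`, `alpha`).
#' @param ctx Fit context: list with `code`, `theta`, `pi`, `freq`, `tree`,
#'   `pat`, `elen`.
#' @param hyper A [model_hyper()].
#' @param options A [fit_options()].
#' @return List with `loglik`, `dist`, `theta`, `elen`, and a `phases` log.
#' @export
fit_full <- function(start_dist, ctx, hyper, options = fit_options()) {
  theta <- ctx$theta
  elen <- ctx$elen
  u <- pack_dist(start_dist, hyper)
  obj <- function(u, th, el) {
    make_dist_objective(ctx$code, th, ctx$pi, ctx$freq, ctx$tree, ctx$pat,
                        hyper, el, ctx$ref_omega)(u)
  }
  cur <- obj(u, theta, elen)
  trace <- c(start = cur)
  for (round in seq_len(options$rounds)) {
    prev <- cur
    o <- stats::optim(u, function(v) -obj(v, theta, elen),
                      method = "Nelder-Mead",
                      control = list(maxit = options$maxit_dist,
                                     reltol = options$nm_reltol %||% 1e-9))
    if (-o$value >= cur) {
      u <- o$par
      cur <- -o$value
    }
    if (round == 1 && hyper$error_sink &&
        hyper$variant == "alternative" && isTRUE(options$probes %||% TRUE)) {
      # basin probes: the error-sink likelihood surface is multimodal
      # because error-like codons can instead be absorbed by the unbounded
      # selection class (the model is label-degenerate when that class
      # saturates).  Polish up to two extra candidates and keep the best:
      # (a) the incumbent with the sink loaded to its cap; (b) when the
      # fitted "selection" rate is itself in error territory (>= E/2), the
      # relabeling that assigns that mass to the sink, accepted within a
      # 0.1 log-likelihood tie tolerance.
      for (pr in list(sink_probe(unpack_dist(u, hyper), hyper),
                      swap_probe(unpack_dist(u, hyper), hyper))) {
        if (is.null(pr)) next
        op <- stats::optim(pack_dist(pr$dist, hyper),
                           function(v) -obj(v, theta, elen),
                           method = "Nelder-Mead",
                           control = list(maxit = max(150, 2 * options$maxit_dist),
                                          reltol = options$nm_reltol %||% 1e-9))
        if (-op$value > cur - pr$tol) {
          u <- op$par
          cur <- -op$value
        }
      }
    }
    ot <- stats::nlminb(log(theta[-2]), function(lt) {
      th <- theta; th[-2] <- exp(clamp(lt, -20, 20))
      -obj(u, th, elen)
    }, control = list(iter.max = 40, rel.tol = 1e-8))
    if (-ot$objective >= cur) {
      theta[-2] <- exp(clamp(ot$par, -20, 20))
      cur <- -ot$objective
    }
    if (options$optimize_blens) {
      dist <- unpack_dist(u, hyper)
      eigs <- class_eigs(ctx$code, theta, ctx$pi, ctx$freq, dist$omega$rates)
      sc <- rate_scale(ctx$code, theta, ctx$pi, ctx$freq, ctx$ref_omega)
      for (pass in seq_len(options$bl_passes)) {
        bl <- cpp_optimize_blens(eigs, dist$omega$weights, dist$alpha$rates,
                                 dist$alpha$weights, ctx$tree$edge, elen, sc,
                                 ctx$pat$states, ctx$pat$w,
                                 as.numeric(ctx$freq), 1e-9, 20)
        if (bl$loglik >= cur) {
          elen <- as.numeric(bl$elen)
          cur <- bl$loglik
        } else break
      }
    }
    trace <- c(trace, cur)
    if (cur - prev < max(1e-8, options$tol * abs(cur))) break
  }
  if (hyper$error_sink) {
    # boundary snap: when the error class carries no likelihood support,
    # report its weight as (numerically) zero rather than leaving simplex
    # residue; accepted only within a negligible 0.01 logL tie
    dz <- unpack_dist(u, hyper)
    N <- hyper$n_omega
    if (dz$omega$weights[N] > 1e-12) {
      wb <- dz$omega$weights[-N] / sum(dz$omega$weights[-N])
      dz$omega$weights <- c(wb * (1 - 1e-13), 1e-13)
      uz <- pack_dist(dz, hyper)
      llz <- obj(uz, theta, elen)
      if (llz >= cur - 0.01) {
        u <- uz
        cur <- llz
      }
    }
  }
  dist <- unpack_dist(u, hyper)
  validate_distributions(dist, hyper)
  list(loglik = cur, dist = dist, theta = theta, elen = elen, phases = trace)
}

# candidate that reallocates selection-class weight to the error sink (up to
# its cap); NULL when the sink is already loaded or there is nothing to move
sink_probe <- function(dist, hyper) {
  N <- hyper$n_omega
  nb <- n_bio_classes(hyper)
  om <- dist$omega
  cap <- hyper$p_e_max
  if (om$weights[N] >= 0.9 * cap) return(NULL)
  p4 <- 0.95 * cap
  take <- p4 - om$weights[N]
  w <- om$weights
  if (w[nb] <= take + 1e-6) return(NULL)
  w[nb] <- w[nb] - take
  w[N] <- p4
  r <- om$rates
  r[N] <- max(r[N], 3 * hyper$E)
  list(dist = list(omega = list(rates = r, weights = w), alpha = dist$alpha),
       tol = 0)
}

# relabeling candidate for the degenerate case where the "selection" class
# has wandered into error territory (rate >= E/2): demote it to the sink
# (subject to the weight cap) and return the selection class to the
# neutral boundary.  Accepted within a small likelihood tie tolerance,
# because at saturation the two labelings fit identically.
swap_probe <- function(dist, hyper) {
  if (hyper$variant != "alternative") return(NULL)
  N <- hyper$n_omega
  nb <- n_bio_classes(hyper)
  om <- dist$omega
  if (om$rates[nb] < hyper$E / 2) return(NULL)
  cap <- hyper$p_e_max
  w <- om$weights
  move <- min(w[nb], 0.95 * cap - w[N])
  if (move <= 0) return(NULL)
  w[nb] <- w[nb] - move
  w[N] <- w[N] + move
  r <- om$rates
  r[N] <- max(r[N], r[nb], hyper$E)
  r[nb] <- 1.2
  list(dist = list(omega = list(rates = r, weights = w), alpha = dist$alpha),
       tol = 0.1)
}

# ---- full pipeline ----------------------------------------------------------

#' Fit a BUSTED-family model by the staged procedure
#'
#' Runs all phases: GTR, single-class MG94, Latin-hypercube proposals with
#' means pinned to the single-class estimate, screening, simplex polish, and
#' the full joint optimization.  When `warm_fit` (a fit of a nested model,
#' e.g. plain BUSTED-S when fitting BUSTED-E) is given, its solution seeds
#' half of the proposal set, with error-sink parameters drawn randomly.
#'
#' @param alignment A `codon_alignment`.
#' @param tree A `phylogeny`.
#' @param hyper A [model_hyper()].
#' @param options A [fit_options()].
#' @param phase123 Optional precomputed phase 1-3 results (shared across
#'   model variants fitted to the same data).
#' @param warm_fit Optional `busted_fit` whose solution seeds the starts.
#' @return A `busted_fit`: log-likelihood, all parameter estimates, free
#'   parameter ledger, AICc, and the per-phase log-likelihood trail.
#' @export
fit_busted <- function(alignment, tree, hyper = model_hyper(),
                       options = fit_options(), phase123 = NULL,
                       warm_fit = NULL) {
  if (is.null(phase123)) phase123 <- fit_phases123(alignment, tree, options)
  p3 <- phase123$p23
  ctx <- list(code = alignment$code, theta = p3$theta, pi = p3$pi,
              freq = p3$freq, tree = tree,
              pat = tree_patterns(tree, alignment$states), elen = p3$elen,
              ref_omega = p3$omega0)
  starts <- propose_starts(options$K, p3$omega0, hyper, seed = options$seed)
  if (!is.null(warm_fit)) {
    n_warm <- max(1, floor(length(starts) / 2))
    warm <- with_local_seed(options$seed + 1L,
      replicate(n_warm, adapt_dist(warm_fit$dist, hyper), simplify = FALSE))
    starts[seq_len(n_warm)] <- warm
    ctx$theta <- warm_fit$theta
    ctx$elen <- warm_fit$elen
  }
  objective <- make_dist_objective(ctx$code, ctx$theta, ctx$pi, ctx$freq,
                                   tree, ctx$pat, hyper, ctx$elen,
                                   ctx$ref_omega)
  scr <- screen_and_polish(starts, objective, hyper, p3$loglik, options)
  full <- fit_full(scr$dist, ctx, hyper, options)
  new_busted_fit(alignment, tree, hyper, options, phase123, scr, full)
}

#' Fit the matched null model, warm-started from an alternative fit
#'
#' Constrains the selection class to omega = 1 and re-optimizes all free
#' parameters starting from the alternative's solution (the standard nested
#' warm start for the EDS likelihood-ratio test).
#'
#' @param alt_fit A `busted_fit` with `variant = "alternative"`.
#' @param options A [fit_options()]; defaults to the alternative's.
#' @return A `busted_fit` with `variant = "null"`.
#' @export
fit_null_from_alt <- function(alt_fit, options = alt_fit$options) {
  h <- alt_fit$hyper
  stopifnot(h$variant == "alternative")
  hyper0 <- model_hyper(h$n_omega, h$m_alpha, h$error_sink, h$E, h$p_e_max,
                        variant = "null")
  start <- adapt_dist(alt_fit$dist, hyper0)
  ctx <- list(code = alt_fit$alignment$code, theta = alt_fit$theta,
              pi = alt_fit$pi, freq = alt_fit$freq, tree = alt_fit$tree,
              pat = tree_patterns(alt_fit$tree, alt_fit$alignment$states),
              elen = alt_fit$elen, ref_omega = alt_fit$scale_omega)
  full <- fit_full(start, ctx, hyper0, options)
  scr <- list(scores = full$loglik, loglik = full$phases[["start"]])
  phase123 <- list(p1 = list(loglik = alt_fit$phases$gtr),
                   p23 = list(theta = alt_fit$theta, pi = alt_fit$pi,
                              elen = alt_fit$elen,
                              omega0 = alt_fit$omega0,
                              loglik = alt_fit$phases$mg94_joint,
                              loglik2 = alt_fit$phases$mg94_mean))
  new_busted_fit(alt_fit$alignment, alt_fit$tree, hyper0, options, phase123,
                 scr, full)
}

#' Restore the alternative/null nesting after warm-started refits
#'
#' Nested maximum-likelihood fits satisfy `logL(alt) >= logL(null)` at their
#' optima, but a null fit warm-started from the alternative occasionally
#' polishes shared parameters past it.  When that happens the alternative is
#' re-optimized starting from the null's solution (feasible for the
#' alternative, selection class at its boundary), restoring the inequality.
#'
#' @param alt,null Matched alternative and null `busted_fit`s.
#' @param options A [fit_options()].
#' @return The (possibly improved) alternative fit.
#' @export
ensure_nesting <- function(alt, null, options = alt$options) {
  if (alt$loglik >= null$loglik - 1e-6) return(alt)
  start <- adapt_dist(null$dist, alt$hyper)
  ctx <- list(code = alt$alignment$code, theta = null$theta, pi = alt$pi,
              freq = alt$freq, tree = alt$tree,
              pat = tree_patterns(alt$tree, alt$alignment$states),
              elen = null$elen, ref_omega = alt$scale_omega)
  full <- fit_full(start, ctx, alt$hyper, options)
  if (full$loglik <= alt$loglik) return(alt)
  phase123 <- list(p1 = list(loglik = alt$phases$gtr),
                   p23 = list(theta = alt$theta, pi = alt$pi,
                              elen = alt$elen, omega0 = alt$omega0,
                              loglik = alt$phases$mg94_joint,
                              loglik2 = alt$phases$mg94_mean))
  scr <- list(scores = alt$loglik, loglik = alt$loglik)
  new_busted_fit(alt$alignment, alt$tree, alt$hyper, options, phase123, scr,
                 full)
}

# carry a fitted distribution into a different variant's constraint set:
# used both to seed BUSTED-E from BUSTED-S (random error-sink draw) and to
# seed a null fit from its alternative (selection class pinned to 1)
adapt_dist <- function(dist, hyper) {
  om <- dist$omega
  nb_have <- length(om$rates)
  nb_want <- n_bio_classes(hyper)
  sink_have <- nb_have > nb_want ||
    (nb_have == hyper$n_omega && hyper$error_sink &&
       om$rates[nb_have] >= hyper$E)
  if (hyper$error_sink && !sink_have) {
    w4 <- hyper$E * (1 + 9 * stats::runif(1))
    p4 <- stats::runif(1) * hyper$p_e_max
    om <- list(rates = c(om$rates, w4),
               weights = c(om$weights * (1 - p4), p4))
  }
  if (!hyper$error_sink && length(om$rates) > nb_want) {
    keep <- seq_len(nb_want)
    om <- list(rates = om$rates[keep],
               weights = om$weights[keep] / sum(om$weights[keep]))
  }
  if (hyper$variant == "null") om$rates[nb_want] <- 1
  om$rates[nb_want] <- max(om$rates[nb_want], 1)
  if (nb_want >= 2) om$rates[nb_want - 1] <- min(om$rates[nb_want - 1], 1)
  list(omega = om, alpha = dist$alpha)
}

# phases 1-3, bundled so several model variants can share them
fit_phases123 <- function(alignment, tree, options = fit_options()) {
  p1 <- fit_phase1_gtr(alignment, tree, options)
  p23 <- fit_phase2_3_mg94(alignment, tree, p1, options)
  list(p1 = p1, p23 = p23)
}

new_busted_fit <- function(alignment, tree, hyper, options, phase123, scr,
                           full) {
  B <- nrow(tree$edge)
  ledger <- c(theta = 5L, frequencies = 9L, branch_lengths = B,
              alpha_dist = 2L * (hyper$m_alpha - 1L),
              omega_dist = as.integer(sum(n_free_omega(hyper))))
  k <- sum(ledger)
  n <- length(alignment$taxa) * alignment$n_sites
  fit <- structure(list(
    loglik = full$loglik,
    theta = full$theta, pi = phase123$p23$pi,
    freq = codon_stationary_frequencies(phase123$p23$pi, alignment$code),
    elen = full$elen, dist = full$dist, hyper = hyper,
    n_params = k, param_ledger = ledger, n_obs = n,
    aicc = aicc(full$loglik, k, n),
    phases = list(gtr = phase123$p1$loglik,
                  mg94_mean = phase123$p23$loglik2,
                  mg94_joint = phase123$p23$loglik,
                  screened = max(scr$scores),
                  polished = scr$loglik,
                  full = full$phases),
    omega0 = phase123$p23$omega0,
    scale_omega = phase123$p23$omega0,
    options = options,
    alignment = alignment, tree = tree,
    fingerprint = data_fingerprint(alignment, tree)),
    class = "busted_fit")
  # the label-swap probe may accept a tie within 0.1 logL; everything else
  # in phase 7 is monotone
  stopifnot(fit$loglik >= scr$loglik - 0.5)
  fit
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)` with `n` the number of characters
#' (sequences times codon sites).
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

data_fingerprint <- function(alignment, tree) {
  paste(length(alignment$taxa), alignment$n_sites,
        sum(alignment$states), paste(sort(alignment$taxa), collapse = "|"),
        signif(sum(tree$elen), 8), sep = ":")
}

#' @export
print.busted_fit <- function(x, ...) {
  h <- x$hyper
  cat("BUSTED", if (h$error_sink) "-E" else "-S",
      " fit (", h$variant, "): logL = ", format(x$loglik, digits = 10),
      ", k = ", x$n_params, ", AICc = ", format(x$aicc, digits = 10), "\n",
      sep = "")
  om <- x$dist$omega
  cat("  omega: ",
      paste(sprintf("%.4g (w=%.4g)", om$rates, om$weights), collapse = ", "),
      "\n", sep = "")
  al <- x$dist$alpha
  cat("  alpha: ",
      paste(sprintf("%.4g (w=%.4g)", al$rates, al$weights), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# rebuild the model state embedded in a fit (for filtering / refitting)
fit_model <- function(fit) {
  busted_model(fit$alignment, fit$tree, fit$theta, fit$pi, fit$dist,
               fit$hyper, fit$elen, scale_omega = fit$scale_omega)
}
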