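#' Filtering thresholds for error masking
#'
#' @param C1 Empirical-Bayes-factor cutoff for error-class membership
#'   (default 100, inclusive).
#' @param C2 Cutoff for preferring the error class over the selection class
#'   (default 20, inclusive).
#' @param C3 If strictly more than this fraction of a site's observed codons
#'   is masked, the whole column is masked (default 0.4).
#' @export
filter_config <- function(C1 = 100, C2 = 20, C3 = 0.4) {
  stopifnot(C1 > 1, C2 > 1, C3 > 0, C3 <= 1)
  structure(list(C1 = C1, C2 = C2, C3 = C3), class = "filter_config")
}

#' Conditional omega-class probabilities per (branch, site)
#'
#' For each branch and site, the site likelihood is recomputed with that
#' branch's omega forced to each class in turn (all other branches keep the
#' mixture, all other estimates fixed at their ML values); weighting the
#' conditional likelihoods by the class prior and normalizing gives
#' empirical Bayes posterior probabilities.  The computation costs about
#' `N` full-alignment likelihood passes via an inside-outside recursion.
#'
#' @param fit A converged `busted_fit` (typically BUSTED-E alternative).
#' @return List with `posterior` and `cond_loglik`, both arrays of dimension
#'   (branches, sites, omega classes), and `prior` (the fitted weights).
#' @export
conditional_class_probabilities <- function(fit) {
  model <- fit_model(fit)
  ep <- engine_parts(model)
  fl <- cpp_forced_logliks(ep$eigs, model$dist$omega$weights,
                           model$dist$alpha$rates, model$dist$alpha$weights,
                           model$tree$edge, model$elen, ep$scale,
                           model$patterns$states, model$patterns$w,
                           as.numeric(model$freq))
  # expand patterns back to sites
  fl <- fl[, model$patterns$index, , drop = FALSE]
  prior <- model$dist$omega$weights
  N <- length(prior)
  post <- fl
  for (k in seq_len(N)) post[, , k] <- log(prior[k]) + fl[, , k]
  mx <- apply(post, c(1, 2), max)
  for (k in seq_len(N)) post[, , k] <- exp(post[, , k] - mx)
  tot <- apply(post, c(1, 2), sum)
  degenerate <- !is.finite(tot) | tot <= 0
  for (k in seq_len(N)) {
    pk <- post[, , k] / tot
    pk[degenerate] <- 1 / N
    post[, , k] <- pk
  }
  if (any(degenerate))
    warning(sum(degenerate), " degenerate (branch, site) pairs; uniform posterior used")
  dimnames(post) <- list(branch_labels(model$tree), NULL, NULL)
  list(posterior = post, cond_loglik = fl, prior = prior)
}

#' Empirical Bayes factor for error-class membership
#'
#' Ratio of posterior to prior odds of the error class against all other
#' classes: `[post_N / (1 - post_N)] / [p_N / (1 - p_N)]`.
#'
#' @param posterior Posterior probability of the error class (vectorized).
#' @param prior Prior (fitted) weight of the error class.
#' @param cap Reporting cap for infinite factors (default 1e6); threshold
#'   comparisons use the uncapped value.
#' @return The Bayes factor; `NA` (a "no error class" sentinel) when the
#'   prior weight is 0, in which case nothing is ever masked.
#' @export
ebf_error <- function(posterior, prior, cap = Inf) {
  if (prior <= 0) return(rep(NA_real_, length(posterior)))
  if (prior >= 1) stop("error-class prior must be < 1")
  po <- posterior / (1 - posterior)  # Inf at posterior = 1
  pmin(po / (prior / (1 - prior)), cap)
}

#' Empirical Bayes factor for error versus selection class
#'
#' `[post_N / post_{N-1}] / [p_N / p_{N-1}]`: evidence that the error class
#' is preferred to the (non-error) selection class.
#'
#' @param post_err,post_sel Posterior probabilities of the error and
#'   selection classes.
#' @param prior_err,prior_sel Their prior (fitted) weights.
#' @param cap Reporting cap (default uncapped).
#' @return The Bayes factor; `NA` when a prior is 0; `Inf` when the
#'   selection posterior is 0 but the error posterior is positive.
#' @export
ebf_selection <- function(post_err, post_sel, prior_err, prior_sel,
                          cap = Inf) {
  if (prior_err <= 0 || prior_sel <= 0)
    return(rep(NA_real_, length(post_err)))
  out <- (post_err / post_sel) / (prior_err / prior_sel)
  out[post_sel == 0 & post_err > 0] <- Inf
  out[post_sel == 0 & post_err == 0] <- NA_real_
  pmin(out, cap)
}

#' Decide which codons to mask as error-like
#'
#' A (branch, site) pair is flagged when both `EBF_e >= C1` and
#' `EBF_s >= C2`.  For a terminal branch the corresponding observed codon is
#' masked; for an internal branch every observed codon in the smaller of the
#' two leaf sets the branch separates is masked (ties broken toward the
#' split not containing the computational root).  If strictly more than `C3`
#' of a site's observed codons end up masked, the entire column is masked.
#'
#' @param fit A converged BUSTED-E `busted_fit`.
#' @param config A [filter_config()].
#' @param cond Optionally, a precomputed result of
#'   [conditional_class_probabilities()].
#' @return A `mask_decision`: per-(branch, site) table of posteriors, EBFs
#'   and decisions (`report`), the masked codon list (`masked_codons`),
#'   per-site masked fractions, and the `column_masked` flags.
#' @export
decide_masks <- function(fit, config = filter_config(), cond = NULL) {
  stopifnot(fit$hyper$error_sink)
  if (is.null(cond)) cond <- conditional_class_probabilities(fit)
  tree <- fit$tree
  aln <- fit$alignment
  N <- fit$hyper$n_omega
  nb <- nrow(tree$edge)
  ns <- aln$n_sites
  post <- cond$posterior
  prior <- cond$prior
  # a numerically-zero sink weight (< 1e-8) means the error class is not
  # instantiated: empirical Bayes factors against a vanishing prior are
  # meaningless, so nothing is masked (the "no-error-class" sentinel)
  prior_err <- if (prior[N] < 1e-8) 0 else prior[N]
  ebf_e <- matrix(ebf_error(as.vector(post[, , N]), prior_err), nb, ns)
  ebf_s <- matrix(ebf_selection(as.vector(post[, , N]),
                                as.vector(post[, , N - 1]),
                                prior_err, prior[N - 1]), nb, ns)
  hit <- !is.na(ebf_e) & ebf_e >= config$C1 &
         !is.na(ebf_s) & ebf_s >= config$C2
  hit[is.na(hit)] <- FALSE

  observed <- aln$states > 0L
  rownames(observed) <- aln$taxa
  masked <- matrix(FALSE, length(aln$taxa), ns,
                   dimnames = list(aln$taxa, NULL))
  labels <- branch_labels(tree)
  is_leaf <- tree$edge[, 2] <= tree$ntip
  rule <- matrix("", nb, ns)
  for (e in which(rowSums(hit) > 0)) {
    sites <- which(hit[e, ])
    if (is_leaf[e]) {
      tx <- tree$phy$tip.label[tree$edge[e, 2]]
      sel <- observed[tx, sites]
      masked[tx, sites[sel]] <- TRUE
      rule[e, sites] <- "leaf"
    } else {
      sp <- tree$splits[[e]]
      # smaller split; ties go to the child side (away from the root)
      grp <- if (length(sp$inside) <= length(sp$outside)) sp$inside else sp$outside
      side <- if (length(sp$inside) <= length(sp$outside)) "inside" else "outside"
      for (s in sites) {
        obs_tx <- grp[observed[grp, s]]
        masked[obs_tx, s] <- TRUE
      }
      rule[e, sites] <- paste0("internal-", side)
    }
  }
  n_obs <- pmax(colSums(observed), 1L)
  frac <- colSums(masked) / n_obs
  column_masked <- frac > config$C3 & colSums(masked) > 0
  for (s in which(column_masked)) masked[observed[, s], s] <- TRUE

  mi <- which(masked, arr.ind = TRUE)
  masked_codons <- data.frame(taxon = aln$taxa[mi[, 1]],
                              site = as.integer(mi[, 2]),
                              stringsAsFactors = FALSE)
  rep_idx <- which(hit | ebf_e >= 1, arr.ind = TRUE)
  report <- data.frame(
    branch = labels[rep_idx[, 1]],
    site = as.integer(rep_idx[, 2]),
    post_error = post[, , N][rep_idx],
    post_selection = post[, , N - 1][rep_idx],
    ebf_error = pmin(ebf_e[rep_idx], 1e6),
    ebf_selection = pmin(ebf_s[rep_idx], 1e6),
    flagged = hit[rep_idx],
    rule = rule[rep_idx],
    stringsAsFactors = FALSE)
  report <- report[order(report$site, report$branch), , drop = FALSE]
  structure(list(report = report, masked_codons = masked_codons,
                 masked = masked, flagged = hit,
                 ebf_error = ebf_e, ebf_selection = ebf_s,
                 masked_fraction = frac, column_masked = column_masked,
                 config = config, prior = prior),
            class = "mask_decision")
}

#' @export
print.mask_decision <- function(x, ...) {
  cat("Mask decision:", nrow(x$masked_codons), "codons masked (",
      sum(x$column_masked), "whole columns);",
      sum(x$flagged), "(branch, site) pairs flagged\n")
  invisible(x)
}

#' Write the per-(branch, site) filter report as TSV
#'
#' @param mask A `mask_decision`.
#' @param path Output path.
#' @export
write_filter_report <- function(mask, path) {
  utils::write.table(mask$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
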