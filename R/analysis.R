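#' Full error-aware selection analysis of one alignment
#'
#' Fits BUSTED-S and BUSTED-E (alternative and null variants, phases 1-3
#' shared, BUSTED-E warm-started from BUSTED-S), runs the EDS
#' likelihood-ratio tests under both models, the BUSTED-E vs BUSTED-S test,
#' AICc model averaging, and the empirical-Bayes error filter.
#'
#' @param alignment A `codon_alignment` (or a FASTA path).
#' @param tree A `phylogeny` (or a Newick path/string).
#' @param options A [fit_options()].
#' @param hyper_e A [model_hyper()] for the error-sink model.
#' @param filter A [filter_config()].
#' @param fit_busted_s Also fit the plain model and model-average (default
#'   TRUE).
#' @return A `busted_analysis`: fits, tests, model average, mask decision.
#' @export
busted_analysis <- function(alignment, tree, options = fit_options(),
                            hyper_e = model_hyper(),
                            filter = filter_config(),
                            fit_busted_s = TRUE) {
  if (is.character(alignment)) alignment <- read_codon_fasta(alignment)
  if (is.character(tree) || inherits(tree, "phylo"))
    tree <- if (inherits(tree, "phylo")) phylogeny(tree, alignment)
            else read_newick(tree, alignment)
  p123 <- fit_phases123(alignment, tree, options)
  hyper_s <- model_hyper(n_bio_classes(hyper_e), hyper_e$m_alpha,
                         error_sink = FALSE)
  out <- list(alignment = alignment, tree = tree, options = options)

  if (fit_busted_s) {
    s_alt <- fit_busted(alignment, tree, hyper_s, options, phase123 = p123)
    s_null <- fit_null_from_alt(s_alt, options)
    s_alt <- ensure_nesting(s_alt, s_null, options)
    out$fits$busted_s <- list(alt = s_alt, null = s_null)
    out$tests$eds_s <- eds_test(s_alt, s_null)
  }
  e_alt <- fit_busted(alignment, tree, hyper_e, options, phase123 = p123,
                      warm_fit = if (fit_busted_s) s_alt else NULL)
  e_null <- fit_null_from_alt(e_alt, options)
  e_alt <- ensure_nesting(e_alt, e_null, options)
  out$fits$busted_e <- list(alt = e_alt, null = e_null)
  out$tests$eds_e <- eds_test(e_alt, e_null)
  if (fit_busted_s) {
    out$tests$model_test <- error_model_test(s_alt, e_alt)
    out$model_average <- model_average(
      list(s_alt, e_alt),
      c(out$tests$eds_s$p_value, out$tests$eds_e$p_value))
  }
  if (hyper_e$error_sink) out$mask <- decide_masks(e_alt, filter)
  structure(out, class = "busted_analysis")
}

#' @export
print.busted_analysis <- function(x, ...) {
  cat("Error-aware selection analysis:", length(x$alignment$taxa), "taxa x",
      x$alignment$n_sites, "codons\n")
  if (!is.null(x$fits$busted_s)) print(x$fits$busted_s$alt)
  print(x$fits$busted_e$alt)
  if (!is.null(x$tests$eds_s)) print(x$tests$eds_s)
  print(x$tests$eds_e)
  if (!is.null(x$tests$model_test)) print(x$tests$model_test)
  if (!is.null(x$model_average)) print(x$model_average)
  if (!is.null(x$mask)) print(x$mask)
  invisible(x)
}

fit_json <- function(fit) {
  list(log_likelihood = fit$loglik,
       n_params = fit$n_params,
       param_ledger = as.list(fit$param_ledger),
       aicc = fit$aicc,
       omega = fit$dist$omega,
       alpha = fit$dist$alpha,
       theta = as.list(fit$theta),
       tree_length = sum(fit$elen),
       mean_omega0 = fit$omega0,
       phase_log = fit$phases)
}

test_json <- function(tst) {
  list(lrt = tst$lrt, p_value = tst$p_value, p_raw_chi2 = tst$p_raw,
       df = tst$df, test = tst$test,
       note = paste("conservative chi-squared with 2 df; the",
                    "boundary-aware mixture distribution would be less",
                    "conservative"))
}

#' Serialize an analysis to the machine-readable JSON document
#'
#' @param analysis A `busted_analysis`.
#' @param path Output JSON path; when NULL the list is returned instead.
#' @param masked_fasta Optional path to also write the masked alignment.
#' @export
analysis_json <- function(analysis, path = NULL, masked_fasta = NULL) {
  doc <- list(schema = "bustede/1.0",
              data = list(n_taxa = length(analysis$alignment$taxa),
                          n_codons = analysis$alignment$n_sites,
                          taxa = analysis$alignment$taxa),
              config = list(options = unclass(analysis$options),
                            filter = if (!is.null(analysis$mask))
                              unclass(analysis$mask$config)))
  doc$fits <- lapply(analysis$fits, function(pair)
    list(alternative = fit_json(pair$alt), null = fit_json(pair$null)))
  doc$tests <- lapply(analysis$tests, test_json)
  if (!is.null(analysis$model_average))
    doc$model_average <- list(aicc = as.list(analysis$model_average$aicc),
                              weights = as.list(analysis$model_average$weights),
                              p_values = as.list(analysis$model_average$ps),
                              p_ma = analysis$model_average$p_ma)
  if (!is.null(analysis$mask)) {
    doc$filter <- list(n_masked_codons = nrow(analysis$mask$masked_codons),
                       n_masked_columns = sum(analysis$mask$column_masked),
                       masked = analysis$mask$masked_codons)
    if (!is.null(masked_fasta)) {
      write_masked_fasta(analysis$alignment, masked_fasta, analysis$mask)
      doc$filter$masked_fasta <- masked_fasta
    }
  }
  if (is.null(path)) return(doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Batch analysis over several alignments with a summary table
#'
#' @param alignments List of `codon_alignment`s or FASTA paths.
#' @param trees Matched list of trees (Newick paths or `phylo`).
#' @param ... Passed to [busted_analysis()].
#' @return List with per-alignment `analyses` and a `summary` data.frame
#'   (p-values, model-averaged p, BH q-values, error weight, masked count).
#' @export
busted_batch <- function(alignments, trees, ...) {
  stopifnot(length(alignments) == length(trees))
  analyses <- Map(function(a, t) busted_analysis(a, t, ...),
                  alignments, trees)
  summary <- do.call(rbind, lapply(analyses, function(x) {
    e <- x$fits$busted_e$alt
    data.frame(p_busted_s = x$tests$eds_s$p_value %||% NA_real_,
               p_busted_e = x$tests$eds_e$p_value,
               p_ma = x$model_average$p_ma %||% NA_real_,
               error_weight = e$dist$omega$weights[e$hyper$n_omega],
               n_masked = nrow(x$mask$masked_codons))
  }))
  summary$q_ma <- bh_qvalues(summary$p_ma)
  list(analyses = analyses, summary = summary)
}
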