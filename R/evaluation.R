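# Model accuracy over the full sequence landscape: R^2 between true and
# predicted log binding probabilities, both strands combined.

#' Convert a motif frequency matrix to an additive energy matrix
#'
#' Inverts the Boltzmann relationship between site frequency and binding
#' energy at low occupancy: `e(b, j) = ln(f_max(j) / f(b, j))`, with
#' pseudocounted frequencies so that unobserved bases get a large but
#' finite penalty.  The preferred base of each column gets energy 0, the
#' consensus gauge of [energy_matrix()].
#'
#' @param model a `motif_model`.
#' @param pseudocount added to every count before forming frequencies
#'   (default 0.5); with 0, any zero count is an error.
#' @param mu chemical potential stored on the result.
#' @return an [energy_matrix()].
#' @export
pwm_to_energy <- function(model, pseudocount = 0.5, mu = -0.5) {
  stopifnot(inherits(model, "motif_model"), pseudocount >= 0)
  f <- (model$counts + pseudocount) /
    (rowSums(model$counts) + 4 * pseudocount)
  if (any(f == 0))
    stop("zero frequency at pseudocount 0; use a positive pseudocount")
  e <- log(apply(f, 1L, max) / f)
  energy_matrix(e, model_id = paste0(model$mode, "_pwm"), mu = mu)
}

#' Log probability of binding in either orientation
#'
#' `ln(occ(E_fwd) + occ(E_rev))` where `E_fwd` is the energy of the
#' sequence and `E_rev` that of its reverse complement under the same
#' matrix; `combine = "max"` uses the larger of the two occupancies
#' instead of their sum.  Invariant under reverse complementation of the
#' sequence.
#'
#' @param matrix an [energy_matrix()].
#' @param sequence character vector of sequences of the matrix width.
#' @param mu chemical potential; defaults to the matrix's stored value.
#' @param combine `"sum"` (default) or `"max"`.
#' @return numeric vector of log probabilities.
#' @export
log_occupancy_both_strands <- function(matrix, sequence, mu = NULL,
                                       combine = c("sum", "max")) {
  stopifnot(inherits(matrix, "energy_matrix"))
  combine <- match.arg(combine)
  mu <- mu %||% matrix$mu
  codes <- seq_to_codes(sequence, width = matrix$width,
                        context = "log_occupancy_both_strands")
  log_occupancy_codes(matrix, codes, mu, combine)
}

#' @noRd
log_occupancy_codes <- function(matrix, codes, mu, combine) {
  e_fwd <- energies_of_codes(matrix, codes)
  e_rev <- energies_of_codes(reverse_complement_matrix(matrix), codes)
  p_fwd <- occupancy(e_fwd, mu)
  p_rev <- occupancy(e_rev, mu)
  if (combine == "sum") log(p_fwd + p_rev) else log(pmax(p_fwd, p_rev))
}

#' Landscape accuracy of a discovered motif
#'
#' Converts the motif to an energy matrix, computes the predicted log
#' binding probability (both strands combined) for every possible L-mer,
#' and compares with the true model's values by the squared Pearson
#' correlation.  R^2 is invariant to affine transforms of either vector,
#' so gauge shifts of the energy matrices do not affect it.
#'
#' @param true_matrix the generating [energy_matrix()].
#' @param model a `motif_model` of the same width.
#' @param mu chemical potential (defaults to the true matrix's value, the
#'   sampling operating point).
#' @param combine `"sum"` (default) or `"max"` over the two orientations.
#' @param pseudocount passed to [pwm_to_energy()].
#' @return a `landscape_evaluation`: list with `model_id`, `mode`,
#'   `combine_rule`, `r_squared`, and the two value vectors `truth` and
#'   `predicted` (length 4^L, lexicographic sequence order).
#' @export
evaluate_model <- function(true_matrix, model, mu = NULL,
                           combine = c("sum", "max"), pseudocount = 0.5) {
  stopifnot(inherits(true_matrix, "energy_matrix"),
            inherits(model, "motif_model"))
  if (true_matrix$width != model$width)
    stop("width mismatch: true matrix is ", true_matrix$width,
         ", model is ", model$width)
  combine <- match.arg(combine)
  mu <- mu %||% true_matrix$mu
  fitted <- pwm_to_energy(model, pseudocount = pseudocount, mu = mu)
  codes <- enumerate_codes(true_matrix$width)
  truth <- log_occupancy_codes(true_matrix, codes, mu, combine)
  predicted <- log_occupancy_codes(fitted, codes, mu, combine)
  structure(
    list(model_id = true_matrix$model_id, mode = model$mode,
         combine_rule = combine,
         r_squared = stats::cor(truth, predicted)^2,
         truth = truth, predicted = predicted),
    class = "landscape_evaluation"
  )
}

#' @export
print.landscape_evaluation <- function(x, ...) {
  cat("<landscape_evaluation> ", x$model_id, " / ", x$mode, " (",
      x$combine_rule, "): R^2 = ", round(x$r_squared, 3), " over ",
      length(x$truth), " sequences\n", sep = "")
  invisible(x)
}

#' Replicate the study's summary tables for a set of samples
#'
#' For each sample, runs the three discovery modes, scores the asymmetric
#' and symmetric models' significance, selects the winning model by
#' `-ln(E-value)`, and evaluates landscape accuracy of all three models.
#' The output mirrors the study layout: an information-content block
#' (True / Asym / Sym), a `-ln(E-value)` block (Asym / Sym), and an R^2
#' block (Control / Asym / Sym), one column per dataset, with the winning
#' mode per dataset recorded.
#'
#' @param samples named list of `site_sample`s (names are dataset ids).
#' @param true_matrices named list of the generating [energy_matrix()]s,
#'   with matching names.
#' @param config a [discovery_config()].
#' @param bin_width significance lattice resolution in bits.
#' @param combine orientation-combining rule for R^2.
#' @return a `symmetry_report`: list of data.frames `information`,
#'   `minus_ln_evalue`, `r_squared` (rows as above, one column per
#'   dataset), plus `verdicts` (named character) and `details`.
#' @export
replicate_tables <- function(samples, true_matrices,
                             config = discovery_config(),
                             bin_width = 0.005,
                             combine = c("sum", "max")) {
  combine <- match.arg(combine)
  stopifnot(is.list(samples), is.list(true_matrices))
  ids <- names(samples)
  if (length(samples) == 0L) {
    empty <- data.frame(row.names = character())
    return(structure(list(information = empty, minus_ln_evalue = empty,
                          r_squared = empty, verdicts = character(),
                          details = list()),
                     class = "symmetry_report"))
  }
  if (is.null(ids) || any(!nzchar(ids))) stop("samples must be named")
  missing <- setdiff(ids, names(true_matrices))
  if (length(missing))
    stop("no true matrix for dataset(s): ", paste(missing, collapse = ", "))

  cols <- lapply(ids, function(id) {
    analyze_one_dataset(samples[[id]], true_matrices[[id]], config,
                        bin_width, combine)
  })
  names(cols) <- ids
  block <- function(field, rows) {
    as.data.frame(lapply(cols, function(cc) cc[[field]][rows]),
                  row.names = rows, check.names = FALSE)
  }
  structure(
    list(
      information = block("information", c("True", "Asym", "Sym")),
      minus_ln_evalue = block("minus_ln_evalue", c("Asym", "Sym")),
      r_squared = block("r_squared", c("Control", "Asym", "Sym")),
      verdicts = vapply(cols, function(cc) cc$verdict, ""),
      details = cols
    ),
    class = "symmetry_report"
  )
}

#' @noRd
analyze_one_dataset <- function(sample, true_matrix, config, bin_width,
                                combine) {
  m_fix <- discover_fixed(sample, config)
  m_asym <- discover_asymmetric(sample, config)
  m_sym <- discover_symmetric(sample, config)
  r_asym <- evalue_report(m_asym, config, bin_width)
  r_sym <- evalue_report(m_sym, config, bin_width)
  sel <- select_model(r_asym, r_sym)
  list(
    information = c(
      True = true_information(true_matrix, background = config$background),
      Asym = information_content(m_asym, config$background),
      Sym = information_content(m_sym, config$background)
    ),
    minus_ln_evalue = c(Asym = r_asym$minus_ln_evalue,
                        Sym = r_sym$minus_ln_evalue),
    r_squared = c(
      Control = evaluate_model(true_matrix, m_fix, combine = combine)$r_squared,
      Asym = evaluate_model(true_matrix, m_asym, combine = combine)$r_squared,
      Sym = evaluate_model(true_matrix, m_sym, combine = combine)$r_squared
    ),
    verdict = sel$verdict,
    margin = sel$margin,
    reports = list(asymmetric = r_asym, symmetric = r_sym),
    models = list(fixed = m_fix, asymmetric = m_asym, symmetric = m_sym)
  )
}

#' @export
print.symmetry_report <- function(x, digits = 2, ...) {
  if (!nrow(x$information)) {
    cat("<symmetry_report> (empty)\n")
    return(invisible(x))
  }
  cat("Information content (bits)\n")
  print(round(x$information, digits))
  cat("\n-ln(E-value)\n")
  print(round(x$minus_ln_evalue, 0))
  cat("\nR^2, predicted vs true log binding probability\n")
  print(round(x$r_squared, digits))
  cat("\nSelected model per dataset:\n")
  print(x$verdicts)
  invisible(x)
}

#' Write a symmetry report as TSV
#'
#' One block per statistic, separated by comment lines naming the block.
#'
#' @param report a [replicate_tables()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "symmetry_report"))
  con <- file(path, "w")
  on.exit(close(con))
  blocks <- list("information_bits" = report$information,
                 "minus_ln_evalue" = report$minus_ln_evalue,
                 "r_squared" = report$r_squared)
  for (nm in names(blocks)) {
    writeLines(paste0("# ", nm), con)
    df <- blocks[[nm]]
    writeLines(paste(c("row", colnames(df)), collapse = "\t"), con)
    for (r in rownames(df))
      writeLines(paste(c(r, format(unlist(df[r, ]), digits = 10,
                                   trim = TRUE)), collapse = "\t"), con)
  }
  writeLines("# verdict", con)
  writeLines(paste(c("row", names(report$verdicts)), collapse = "\t"), con)
  writeLines(paste(c("Verdict", unname(report$verdicts)), collapse = "\t"),
             con)
  invisible(path)
}
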