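# Significance of motif information content.
#
# The null model: each alignment column is n letters drawn i.i.d. from the
# background composition.  The information content of a column is the KL
# divergence of its empirical composition from the background (bits), so its
# exact distribution over the multinomial count lattice can be computed by
# dynamic programming, binned on a fine lattice, entirely in log space —
# p-values of magnitude exp(-1500) are routine here and underflow any direct
# representation.  The total-information null for an L-column motif is the
# L-fold convolution of the column distribution.

# cache of column/total distributions, keyed by (n, background, bin width)
.sig_cache <- new.env(parent = emptyenv())

#' Null distribution of single-column information content
#'
#' Distribution of `I_col = sum_b (n_b/n) log2(n_b / (n p_b))` where
#' `(n_A..n_T) ~ Multinomial(n, background)`, computed exactly by dynamic
#' programming over bases and binned to multiples of `bin_width` bits.
#'
#' @param n letters per column.
#' @param background per-base probabilities.
#' @param bin_width lattice resolution in bits (default 0.005).
#' @return a `column_logdist`: list with `log_prob` (log probability per
#'   bin), `min_bin` (index of the first bin; bin value = index *
#'   `bin_width`), `bin_width`, `n`, `background`.  The probability mass
#'   sums to 1 within 1e-9.
#' @export
column_score_distribution <- function(n, background = rep(0.25, 4),
                                      bin_width = 0.005) {
  n <- as.integer(n)
  stopifnot(n >= 1L, bin_width > 0, length(background) == 4L,
            all(background > 0), abs(sum(background) - 1) < 1e-9)
  key <- paste0("col:", n, ":", bin_width, ":",
                paste(format(background, digits = 12), collapse = ","))
  if (!is.null(.sig_cache[[key]])) return(.sig_cache[[key]])
  # the DP refuses oversized lattices itself; translate to friendly advice
  lp <- tryCatch(
    cpp_column_info_logdist(n, log(background), bin_width),
    error = function(e)
      stop("column distribution lattice too large for n = ", n,
           "; increase bin_width (", conditionMessage(e), ")")
  )
  out <- structure(
    list(log_prob = as.numeric(lp), min_bin = attr(lp, "min_bin"),
         bin_width = bin_width, n = n, background = background),
    class = "column_logdist"
  )
  total <- logsumexp(out$log_prob)
  if (abs(total) > 1e-9)
    stop("internal error: column distribution mass off by ", format(total))
  .sig_cache[[key]] <- out
  out
}

# L-fold convolution of the column distribution, cached
#' @noRd
total_info_logdist <- function(n, width, background, bin_width) {
  key <- paste0("tot:", n, ":", width, ":", bin_width, ":",
                paste(format(background, digits = 12), collapse = ","))
  if (!is.null(.sig_cache[[key]])) return(.sig_cache[[key]])
  col <- column_score_distribution(n, background, bin_width)
  lp <- col$log_prob
  mb <- col$min_bin
  if (width > 1L) {
    for (i in seq_len(width - 1L)) {
      lp <- cpp_logconv(lp, col$log_prob)
      mb <- mb + col$min_bin
    }
  }
  out <- list(log_prob = lp, min_bin = mb, bin_width = bin_width)
  .sig_cache[[key]] <- out
  out
}

#' Log p-value of an observed motif information content
#'
#' `ln P(I_total >= i_obs)` under the null of L independent columns of n
#' background-distributed letters.  Monotone nonincreasing in `i_obs`;
#' exactly 0 (p = 1) at `i_obs = 0` since information is nonnegative.
#'
#' @param i_obs observed information in bits.
#' @param n letters per column.
#' @param width number of columns L.
#' @param background per-base probabilities.
#' @param bin_width lattice resolution in bits.
#' @return natural-log p-value (<= 0).
#' @export
log_pvalue_information <- function(i_obs, n, width,
                                   background = rep(0.25, 4),
                                   bin_width = 0.005) {
  max_info <- width * max(log2(1 / background))
  if (i_obs > max_info + 1e-9)
    stop("i_obs = ", format(i_obs), " exceeds the maximum attainable ",
         format(max_info), " bits for width ", width)
  tot <- total_info_logdist(n, width, background, bin_width)
  thr <- as.integer(round(i_obs / bin_width))
  if (thr <= tot$min_bin || i_obs <= 0) return(0)
  keep <- seq_along(tot$log_prob) + tot$min_bin - 1L >= thr
  min(logsumexp(tot$log_prob[keep]), 0)
}

#' Null distribution of a symmetric motif's information content
#'
#' A reverse-complement-symmetric PWM built from N random sequences does
#' not have L independent columns: column j and column L+1-j hold the same
#' data (each site counted in both orientations), so the matrix has
#' floor(L/2) independent columns of 2N letters, each contributing its
#' information twice, plus — for odd L — a centre column whose
#' complement-paired counts are equivalent to a two-letter column
#' (A/T vs C/G) of N letters.  `log_pvalue_symmetric()` computes
#' `ln P(I_total >= i_obs)` under that constrained null.  The background
#' must be complement-palindromic (p_A = p_T, p_C = p_G).
#'
#' @param i_obs observed information of the symmetric model, bits.
#' @param n_sites number of input sites N (the symmetric model's
#'   effective sample is 2N).
#' @param width motif width L.
#' @param background per-base probabilities.
#' @param bin_width lattice resolution in bits.
#' @return natural-log p-value (<= 0).
#' @export
log_pvalue_symmetric <- function(i_obs, n_sites, width,
                                 background = rep(0.25, 4),
                                 bin_width = 0.005) {
  if (abs(background[1L] - background[4L]) > 1e-9 ||
      abs(background[2L] - background[3L]) > 1e-9)
    stop("symmetric null requires a complement-palindromic background")
  if (i_obs <= 0) return(0)
  key <- paste0("sym:", n_sites, ":", width, ":", bin_width, ":",
                paste(format(background, digits = 12), collapse = ","))
  tot <- .sig_cache[[key]]
  if (is.null(tot)) {
    npairs <- width %/% 2L
    col <- column_score_distribution(2L * n_sites, background, bin_width)
    # a pair of mirrored columns contributes its information twice:
    # stretch the bin lattice by a factor of 2
    dbl <- rep(-Inf, 2L * (length(col$log_prob) - 1L) + 1L)
    dbl[seq_along(col$log_prob) * 2L - 1L] <- col$log_prob
    lp <- dbl
    mb <- 2L * col$min_bin
    if (npairs > 1L) {
      for (i in seq_len(npairs - 1L)) {
        lp <- cpp_logconv(lp, dbl)
        mb <- mb + 2L * col$min_bin
      }
    }
    if (width %% 2L == 1L) {
      bg2 <- c(background[1L] + background[4L],
               background[2L] + background[3L])
      ctr <- cpp_column_info_logdist(n_sites, log(bg2), bin_width)
      lp <- cpp_logconv(lp, as.numeric(ctr))
      mb <- mb + attr(ctr, "min_bin")
    }
    tot <- list(log_prob = lp, min_bin = mb, bin_width = bin_width)
    .sig_cache[[key]] <- tot
  }
  thr <- as.integer(round(i_obs / bin_width))
  if (thr <= tot$min_bin) return(0)
  keep <- seq_along(tot$log_prob) + tot$min_bin - 1L >= thr
  min(logsumexp(tot$log_prob[keep]), 0)
}

#' Significance report for a discovered motif
#'
#' Combines the information-content tail p-value with the log number of
#' possible alignments of the input data.  The asymmetric
#' (orientation-free) mode could have aligned its N sites in 2^N ways, so
#' `n_alignments_log = N ln 2`; the fixed and symmetric modes admit a
#' single alignment (the symmetric model uses both orientations of every
#' site simultaneously), so their correction is 0.  The fixed and
#' asymmetric p-values use the L-independent-column null at n = N
#' ([log_pvalue_information()]); the symmetric p-value uses the
#' symmetry-constrained null ([log_pvalue_symmetric()]), which accounts
#' for the mirrored columns holding the same doubled data rather than
#' treating them as independent.  The reported statistic is
#' `-ln(E-value) = -(ln p + n_alignments_log)`: larger means more
#' significant.
#'
#' @param model a `motif_model` from [discover_fixed()],
#'   [discover_asymmetric()] or [discover_symmetric()].
#' @param config a [discovery_config()] (supplies the background).
#' @param bin_width lattice resolution in bits.
#' @return a `significance_report`: list with `mode`, `information_bits`,
#'   `log_pvalue`, `n_alignments_log`, `minus_ln_evalue`, `n_sites`,
#'   `width`.
#' @export
evalue_report <- function(model, config = discovery_config(),
                          bin_width = 0.005) {
  stopifnot(inherits(model, "motif_model"))
  i_obs <- information_content(model, config$background)
  n_col <- model$effective_n
  n_sites <- if (model$mode == "symmetric") n_col %/% 2L else n_col
  corr <- if (model$mode == "asymmetric") n_sites * log(2) else 0
  lp <- if (model$mode == "symmetric") {
    log_pvalue_symmetric(i_obs, n_sites, model$width,
                         config$background, bin_width)
  } else {
    log_pvalue_information(i_obs, n_col, model$width,
                           config$background, bin_width)
  }
  structure(
    list(mode = model$mode, information_bits = i_obs, log_pvalue = lp,
         n_alignments_log = corr, minus_ln_evalue = -(lp + corr),
         n_sites = n_sites, width = model$width),
    class = "significance_report"
  )
}

#' @export
print.significance_report <- function(x, ...) {
  cat("<significance_report> mode ", x$mode, ": I = ",
      round(x$information_bits, 3), " bits, ln p = ",
      round(x$log_pvalue, 1), ", -ln E = ", round(x$minus_ln_evalue, 1),
      "\n", sep = "")
  invisible(x)
}

#' Choose between the asymmetric and symmetric motif model
#'
#' The decision rule of the study: the mode with the larger `-ln(E-value)`
#' wins.  Because the asymmetric E-value is charged for its 2^N possible
#' alignments, a symmetric motif is selected even when the asymmetric model
#' shows higher raw information content.  As an advisory secondary
#' criterion the free-parameter counts of the two models are reported
#' (3 per free column: 3L asymmetric vs 3 * ceiling(L/2) symmetric).
#'
#' @param report_asym,report_sym [evalue_report()]s for the two modes run
#'   on the same sample.
#' @return list with `verdict` ("asymmetric" or "symmetric"), `margin`
#'   (difference of `-ln E` in favour of the verdict) and
#'   `free_parameters`.
#' @export
select_model <- function(report_asym, report_sym) {
  stopifnot(inherits(report_asym, "significance_report"),
            inherits(report_sym, "significance_report"),
            report_asym$mode == "asymmetric",
            report_sym$mode == "symmetric")
  if (report_asym$width != report_sym$width)
    stop("reports have different widths")
  L <- report_asym$width
  diff <- report_sym$minus_ln_evalue - report_asym$minus_ln_evalue
  list(
    verdict = if (diff > 0) "symmetric" else "asymmetric",
    margin = abs(diff),
    free_parameters = c(asymmetric = 3L * L,
                        symmetric = 3L * as.integer(ceiling(L / 2)))
  )
}
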