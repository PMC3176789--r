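#' Motif discovery configuration
#'
#' @param pseudocount added to each count when forming frequencies; the
#'   default 0 keeps counted frequencies (and hence information content)
#'   pure.  Use a positive value (0.5 is conventional) when frequencies must
#'   be strictly positive, e.g. for energy conversion.
#' @param restarts number of seeded restarts of the orientation search.
#' @param max_iterations maximum coordinate-ascent sweeps per restart.
#' @param seed RNG seed for the restart initializations.
#' @param background per-base background probabilities (must sum to 1).
#' @return a `discovery_config` list.
#' @export
discovery_config <- function(pseudocount = 0, restarts = 20L,
                             max_iterations = 100L, seed = 1L,
                             background = rep(0.25, 4)) {
  stopifnot(pseudocount >= 0, restarts >= 1L, max_iterations >= 1L,
            length(background) == 4L, abs(sum(background) - 1) < 1e-9,
            all(background > 0))
  structure(list(pseudocount = pseudocount, restarts = as.integer(restarts),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), background = background),
            class = "discovery_config")
}

#' Build a position weight matrix from oriented sites
#'
#' Tallies each site in its designated orientation ("forward", "reverse",
#' or "both" — in which case each site contributes once in each orientation
#' and the effective sample size is doubled).  Frequencies are
#' `(count + pseudocount) / (column total + 4 * pseudocount)`.
#'
#' @param sites character vector of equal-length ACGT sequences.
#' @param orientations character vector, one of "forward"/"reverse" per
#'   site, or the single string "both" applying to all sites.
#' @param config a [discovery_config()].
#' @param mode label stored on the model ("fixed", "asymmetric",
#'   "symmetric").
#' @return a `motif_model`: list with `mode`, `width`, `counts` (L x 4),
#'   `frequencies` (L x 4, rows summing to 1), `orientations`,
#'   `effective_n` and `provenance`.
#' @export
build_pwm <- function(sites, orientations = "forward",
                      config = discovery_config(), mode = "fixed") {
  codes <- seq_to_codes(sites, context = "build_pwm")
  n <- nrow(codes)
  L <- ncol(codes)
  both <- identical(orientations, "both")
  if (!both) {
    if (length(orientations) == 1L)
      orientations <- rep(orientations, n)
    if (length(orientations) != n)
      stop("need one orientation per site (", n, "), got ",
           length(orientations))
    if (!all(orientations %in% c("forward", "reverse")))
      stop("orientations must be 'forward', 'reverse', or the single 'both'")
    flip <- orientations == "reverse"
    codes[flip, ] <- revcomp_codes(codes[flip, , drop = FALSE])
    counts <- count_codes(codes)
    effective_n <- n
  } else {
    counts <- count_codes(codes) + count_codes(revcomp_codes(codes))
    orientations <- rep("both", n)
    effective_n <- 2L * n
  }
  new_motif_model(mode, counts, orientations, effective_n, config)
}

#' @noRd
count_codes <- function(codes) {
  L <- ncol(codes)
  t(vapply(seq_len(L), function(j) tabulate(codes[, j], nbins = 4L),
           numeric(4L)))
}

#' @noRd
new_motif_model <- function(mode, counts, orientations, effective_n, config,
                            provenance = list()) {
  colnames(counts) <- DNA_BASES
  freq <- (counts + config$pseudocount) /
    (rowSums(counts) + 4 * config$pseudocount)
  structure(
    list(mode = mode, width = nrow(counts), counts = counts,
         frequencies = freq, orientations = orientations,
         effective_n = as.integer(effective_n),
         pseudocount = config$pseudocount,
         provenance = provenance),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> mode ", x$mode, ", width ", x$width,
      ", effective_n ", x$effective_n, ", information ",
      round(information_content(x), 3), " bits\n", sep = "")
  invisible(x)
}

#' Information content of a motif model
#'
#' `I = sum_j sum_b f(b, j) * log2(f(b, j) / background_b)` in bits, with
#' the convention 0 * log 0 = 0.  Nonnegative for a uniform background.
#'
#' @param model a [build_pwm()] / `discover_*` result.
#' @param background per-base background probabilities.
#' @return information in bits.
#' @export
information_content <- function(model, background = rep(0.25, 4)) {
  stopifnot(inherits(model, "motif_model"))
  info_of_frequencies(model$frequencies, background)
}

#' @noRd
info_of_frequencies <- function(freq, background = rep(0.25, 4)) {
  bg <- matrix(background, nrow = nrow(freq), ncol = 4L, byrow = TRUE)
  pos <- freq > 0
  sum(freq[pos] * log2(freq[pos] / bg[pos]))
}

#' Motif discovery with known site orientations (control mode)
#'
#' Every site is taken in its recorded (forward) orientation, so the only
#' discrepancy from the true motif is sampling noise.  Deterministic.
#'
#' @param sample a [sample_sites()] result (or any `site_sample`).
#' @param config a [discovery_config()].
#' @return a `motif_model` with mode `"fixed"`.
#' @export
discover_fixed <- function(sample, config = discovery_config()) {
  stopifnot(inherits(sample, "site_sample"))
  build_pwm(sample$sites, "forward", config, mode = "fixed")
}

#' Symmetric motif discovery
#'
#' Assumes the motif is reverse-complement symmetric: every site contributes
#' in both orientations, doubling the effective sample size, and the
#' resulting frequency matrix satisfies `f(b, j) = f(complement(b), L+1-j)`
#' exactly — including the central column of odd widths.  Deterministic, no
#' search.
#'
#' @inheritParams discover_fixed
#' @return a `motif_model` with mode `"symmetric"`.
#' @export
discover_symmetric <- function(sample, config = discovery_config()) {
  stopifnot(inherits(sample, "site_sample"))
  build_pwm(sample$sites, "both", config, mode = "symmetric")
}

#' Asymmetric (orientation-free) motif discovery
#'
#' Each site may enter the alignment in either orientation; the assignment
#' is chosen to maximize the information content of the resulting matrix.
#' For up to 12 sites the 2^N assignments are searched exhaustively
#' (`method = "auto"`); beyond that a seeded multi-restart coordinate
#' ascent is used: sweeps flip one site's orientation whenever the flip
#' strictly increases the information, until a full sweep makes no flip or
#' `max_iterations` sweeps elapse.  Equal-information flips are rejected.
#' The best restart is returned, canonicalized so that the majority of
#' orientations is "forward" (ties broken toward the lexicographically
#' smaller consensus).  Deterministic given `config$seed`.
#'
#' @inheritParams discover_fixed
#' @param method `"auto"` (exhaustive for N <= 12, ascent otherwise),
#'   `"ascent"`, or `"exhaustive"`.
#' @return a `motif_model` with mode `"asymmetric"`; `$provenance` records
#'   the search method, restart information and any convergence warning.
#' @export
discover_asymmetric <- function(sample, config = discovery_config(),
                                method = c("auto", "ascent", "exhaustive")) {
  stopifnot(inherits(sample, "site_sample"))
  method <- match.arg(method)
  n <- length(sample$sites)
  if (method == "auto") method <- if (n <= 12L) "exhaustive" else "ascent"
  codes <- seq_to_codes(sample$sites, width = sample$width)
  res <- if (method == "exhaustive") orient_exhaustive(codes)
         else orient_ascent(codes, config)
  model <- build_pwm(sample$sites,
                     ifelse(res$forward, "forward", "reverse"),
                     config, mode = "asymmetric")
  model$provenance <- c(res$provenance, list(method = method))
  canonicalize_orientation(model, sample$sites)
}

# exhaustive search over all 2^N orientation assignments (N <= 12)
#' @noRd
orient_exhaustive <- function(codes) {
  n <- nrow(codes)
  L <- ncol(codes)
  if (n > 12L) stop("exhaustive orientation search limited to 12 sites")
  rev_codes <- revcomp_codes(codes)
  base <- count_codes(codes)                      # all-forward counts
  # per-site count delta when flipped, flattened L x 4 column-major
  D <- t(vapply(seq_len(n), function(i) {
    d <- matrix(0, L, 4L)
    d[cbind(seq_len(L), rev_codes[i, ])] <- d[cbind(seq_len(L), rev_codes[i, ])] + 1
    d[cbind(seq_len(L), codes[i, ])] <- d[cbind(seq_len(L), codes[i, ])] - 1
    as.vector(d)
  }, numeric(L * 4L)))
  flips <- as.matrix(expand.grid(rep(list(c(0, 1)), n),
                                 KEEP.OUT.ATTRS = FALSE))
  cnt <- flips %*% D
  cnt <- sweep(cnt, 2L, as.vector(base), `+`)
  f <- cnt / n
  pos <- f > 0
  terms <- matrix(0, nrow(f), ncol(f))
  terms[pos] <- f[pos] * log2(4 * f[pos])
  info <- rowSums(terms)
  best <- which.max(info)  # first maximum: deterministic tie-break
  list(forward = unname(flips[best, ] == 0),
       provenance = list(information = info[best], converged = TRUE))
}

# multi-restart coordinate ascent on orientation assignments
#' @noRd
orient_ascent <- function(codes, config) {
  n <- nrow(codes)
  L <- ncol(codes)
  rev_codes <- revcomp_codes(codes)
  # flat indices into the L x 4 count matrix (column-major):
  # cell (position j, base b) lives at (b - 1) * L + j
  idx_f <- sweep((codes - 1L) * L, 2L, seq_len(L), `+`)
  idx_r <- sweep((rev_codes - 1L) * L, 2L, seq_len(L), `+`)
  # information lookup per count value: g[c + 1] = (c/n) log2(4 c / n)
  k <- 0:n
  g <- c(0, (k[-1] / n) * log2(4 * k[-1] / n))

  inits <- with_local_seed(config$seed, {
    c(list(rep(TRUE, n)),
      replicate(config$restarts - 1L,
                stats::runif(n) < 0.5, simplify = FALSE))
  })

  best <- NULL
  all_converged <- TRUE
  for (init in inits) {
    fwd <- init
    counts <- matrix(0, L, 4L)
    for (i in seq_len(n)) {
      ix <- if (fwd[i]) idx_f[i, ] else idx_r[i, ]
      counts[ix] <- counts[ix] + 1
    }
    info <- sum(g[counts + 1L])
    converged <- FALSE
    for (sweep_no in seq_len(config$max_iterations)) {
      flipped <- FALSE
      for (i in seq_len(n)) {
        from <- if (fwd[i]) idx_f[i, ] else idx_r[i, ]
        to <- if (fwd[i]) idx_r[i, ] else idx_f[i, ]
        keep <- from != to
        if (!any(keep)) next
        fr <- from[keep]
        tt <- to[keep]
        delta <- sum(g[counts[tt] + 2L] - g[counts[tt] + 1L] +
                     g[counts[fr]] - g[counts[fr] + 1L])
        if (delta > 1e-12) {
          counts[fr] <- counts[fr] - 1
          counts[tt] <- counts[tt] + 1
          fwd[i] <- !fwd[i]
          info <- info + delta
          flipped <- TRUE
        }
      }
      if (!flipped) {
        converged <- TRUE
        break
      }
    }
    all_converged <- all_converged && converged
    if (is.null(best) || info > best$information + 1e-12)
      best <- list(forward = fwd, information = info, converged = converged)
  }
  prov <- list(information = best$information, converged = all_converged)
  if (!all_converged) {
    warning("orientation search did not converge within ",
            config$max_iterations, " sweeps in at least one restart")
    prov$warning <- "non-convergence in at least one restart"
  }
  list(forward = best$forward, provenance = prov)
}

# report the model in the canonical global orientation: majority forward,
# ties broken toward the lexicographically smaller consensus string
#' @noRd
canonicalize_orientation <- function(model, sites) {
  ori <- model$orientations
  n_fwd <- sum(ori == "forward")
  n <- length(ori)
  flip <- if (n_fwd * 2L == n) {
    cons <- function(counts) paste(DNA_BASES[apply(counts, 1L, which.max)],
                                   collapse = "")
    flipped_counts <- model$counts[model$width:1, 4:1, drop = FALSE]
    cons(flipped_counts) < cons(model$counts)
  } else n_fwd * 2L < n
  if (!flip) return(model)
  model$counts <- model$counts[model$width:1, 4:1, drop = FALSE]
  colnames(model$counts) <- DNA_BASES
  model$frequencies <- model$frequencies[model$width:1, 4:1, drop = FALSE]
  colnames(model$frequencies) <- DNA_BASES
  model$orientations <- ifelse(ori == "forward", "reverse", "forward")
  model
}

#' Read / write a motif model in TSV form
#'
#' Counts in the energy-matrix TSV dialect with extra `# mode`,
#' `# effective_n` and `# pseudocount` headers.
#'
#' @param model a `motif_model`.
#' @param path file path.
#' @return `read_motif_model()` returns a `motif_model`;
#'   `write_motif_model()` returns `path` invisibly.
#' @export
write_motif_model <- function(model, path) {
  stopifnot(inherits(model, "motif_model"))
  lines <- c(
    paste0("# mode: ", model$mode),
    paste0("# effective_n: ", model$effective_n),
    paste0("# pseudocount: ", format(model$pseudocount, digits = 15)),
    paste(c("pos", DNA_BASES), collapse = "\t"),
    vapply(seq_len(model$width), function(j) {
      paste(c(j, format(model$counts[j, ], digits = 15, trim = TRUE)),
            collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_motif_model
#' @export
read_motif_model <- function(path) {
  lines <- readLines(path)
  meta <- parse_hash_meta(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- utils::read.table(text = paste(body, collapse = "\n"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  counts <- as.matrix(df[order(df$pos), DNA_BASES])
  rownames(counts) <- NULL
  cfg <- discovery_config(pseudocount = as.numeric(meta$pseudocount %||% 0))
  new_motif_model(meta$mode %||% "fixed", counts,
                  orientations = "unknown",
                  effective_n = as.integer(meta$effective_n %||%
                                             round(sum(counts[1L, ]))),
                  config = cfg,
                  provenance = list(source = basename(path)))
}
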