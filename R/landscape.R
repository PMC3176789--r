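#' Fermi-Dirac binding occupancy
#'
#' Probability that a site of energy E (kT) is bound at chemical potential
#' `mu`: `1 / (1 + exp(E - mu))`.  Strictly decreasing in energy; saturates
#' to exactly 1 and 0 at the infinite limits.  At the study operating point
#' (consensus energy 0, mu = -0.5) the consensus is bound with probability
#' 0.38.
#'
#' @param energy numeric vector of binding energies (kT).
#' @param mu chemical potential (kT), related to protein concentration.
#' @return numeric vector of probabilities in (0, 1).
#' @export
occupancy <- function(energy, mu = -0.5) {
  stopifnot(is.finite(mu))
  1 / (1 + exp(energy - mu))
}

#' Enumerate the full sequence landscape of an energy matrix
#'
#' Builds one record per possible L-mer (4^L in total; 4096 for L = 6,
#' 16384 for L = 7): its binding energy, its Fermi-Dirac occupancy at `mu`,
#' and its normalized sampling probability pi = occupancy / sum(occupancy).
#' This is the categorical distribution from which binding-site samples are
#' drawn, and the ground truth against which discovered motifs are judged.
#'
#' @param matrix an [energy_matrix()]; width at most 12.
#' @param mu chemical potential; defaults to the matrix's stored `mu`.
#' @return a `landscape`: a data.frame with columns `sequence`, `energy`,
#'   `occupancy`, `prob`, in lexicographic sequence order, with attributes
#'   `width`, `model_id`, `mu` and the integer code matrix (`codes`).
#' @export
enumerate_landscape <- function(matrix, mu = NULL) {
  stopifnot(inherits(matrix, "energy_matrix"))
  if (matrix$width > 12L)
    stop("refusing to enumerate 4^", matrix$width,
         " sequences; width must be <= 12")
  if (anyNA(matrix$energies))
    stop("matrix has undetermined entries; cannot enumerate its landscape")
  mu <- mu %||% matrix$mu
  codes <- enumerate_codes(matrix$width)
  energy <- energies_of_codes(matrix, codes)
  p <- occupancy(energy, mu)
  out <- data.frame(sequence = codes_to_seq(codes), energy = energy,
                    occupancy = p, prob = p / sum(p),
                    stringsAsFactors = FALSE)
  attr(out, "width") <- matrix$width
  attr(out, "model_id") <- matrix$model_id
  attr(out, "mu") <- mu
  attr(out, "codes") <- codes
  class(out) <- c("landscape", "data.frame")
  out
}

#' Per-position base probabilities of a landscape
#'
#' The marginal probability of each base at each position under the
#' sampling distribution pi — the "true motif" frequency matrix that an
#' ideal discovery run would recover.
#'
#' @param landscape a [enumerate_landscape()] result.
#' @return L x 4 matrix of probabilities (columns A, C, G, T), rows summing
#'   to 1.
#' @export
landscape_marginals <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  codes <- attr(landscape, "codes")
  L <- attr(landscape, "width")
  f <- vapply(seq_len(L), function(j) {
    vapply(1:4, function(b) sum(landscape$prob[codes[, j] == b]), 0)
  }, numeric(4))
  t(matrix(f, nrow = 4L, dimnames = list(DNA_BASES, NULL)))
}

#' True information content of a binding site model
#'
#' Information content (bits) of the landscape marginal frequencies against
#' a uniform background — the information an infinitely large, correctly
#' aligned sample would converge to.
#'
#' @param matrix an [energy_matrix()].
#' @param mu chemical potential; defaults to the matrix's stored value.
#' @param background per-base background probabilities.
#' @return information in bits.
#' @export
true_information <- function(matrix, mu = NULL, background = rep(0.25, 4)) {
  f <- landscape_marginals(enumerate_landscape(matrix, mu = mu))
  info_of_frequencies(f, background)
}

#' Sampling configuration for binding-site draws
#'
#' @param n_sites number of sites to draw (study default 500).
#' @param mu chemical potential of the occupancy model (study default -0.5).
#' @param seed integer RNG seed; recorded in the sample's provenance.
#' @param replacement draw with replacement (default) or without.
#' @return a `sample_config` list.
#' @export
sample_config <- function(n_sites = 500L, mu = -0.5, seed = 1L,
                          replacement = TRUE) {
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 1L, is.finite(mu), is.finite(seed))
  structure(list(n_sites = n_sites, mu = mu, seed = as.integer(seed),
                 replacement = isTRUE(replacement)),
            class = "sample_config")
}

#' Draw a seeded random sample of binding sites from a landscape
#'
#' Sites are drawn i.i.d. (with replacement by default) from the categorical
#' distribution pi of the landscape; each record carries the site's true
#' binding energy.  Identical (landscape, config) always yields the
#' identical sample; the global RNG state is left untouched.
#'
#' @param landscape a [enumerate_landscape()] result, built at the same `mu`
#'   as `config$mu`.
#' @param config a [sample_config()].
#' @return a `site_sample`: list with `model_id`, `width`, `sites`
#'   (character), `energies` (numeric), `config`, and `generator` (package
#'   version string).
#' @export
sample_sites <- function(landscape, config = sample_config()) {
  stopifnot(inherits(landscape, "landscape"), inherits(config, "sample_config"))
  n_seq <- nrow(landscape)
  if (!config$replacement) {
    eligible <- sum(landscape$prob > 1e-12)
    if (config$n_sites > eligible)
      stop("cannot draw ", config$n_sites, " sites without replacement: only ",
           eligible, " sequences have non-negligible probability")
  }
  idx <- with_local_seed(config$seed,
    sample.int(n_seq, config$n_sites, replace = config$replacement,
               prob = landscape$prob))
  structure(
    list(model_id = attr(landscape, "model_id"),
         width = attr(landscape, "width"),
         sites = landscape$sequence[idx],
         energies = landscape$energy[idx],
         config = config,
         generator = paste0("motifsym ",
                            as.character(utils::packageVersion("motifsym")))),
    class = "site_sample"
  )
}

#' @export
print.site_sample <- function(x, ...) {
  cat("<site_sample> ", x$model_id, ": ", length(x$sites), " sites of width ",
      x$width, " (mu = ", x$config$mu, ", seed = ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write / read a binding-site sample as TSV
#'
#' The dialect is a plain table of sampled sites with their true binding
#' energies: `#`-prefixed header lines carrying `model_id`, `mu`, `seed`
#' and `n`, then a `site<TAB>energy` header and one row per site.  The
#' reader also ingests third-party site/energy tables of a different
#' column layout via `site_col` / `energy_col` and `header`.
#'
#' @param sample a [sample_sites()] result.
#' @param path file path.
#' @param site_col,energy_col column indices for the reader.
#' @param header does the file carry a (non-`#`) header line?
#' @return `read_sample()` returns a `site_sample`; `write_sample()` returns
#'   `path` invisibly.
#' @export
write_sample <- function(sample, path) {
  stopifnot(inherits(sample, "site_sample"))
  lines <- c(
    paste0("# model_id: ", sample$model_id),
    paste0("# mu: ", format(sample$config$mu, digits = 15)),
    paste0("# seed: ", sample$config$seed),
    paste0("# n: ", length(sample$sites)),
    "site\tenergy",
    paste(sample$sites, format(sample$energies, digits = 15, trim = TRUE),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sample
#' @export
read_sample <- function(path, site_col = 1L, energy_col = 2L, header = TRUE) {
  lines <- readLines(path)
  meta <- parse_hash_meta(lines)
  keep <- !grepl("^#", lines) & nzchar(lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (header && length(body)) {
    body <- body[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(body)) stop("sample file '", path, "' has no data rows")
  fields <- strsplit(body, "\t", fixed = TRUE)
  need <- max(site_col, energy_col)
  short <- which(lengths(fields) < need)
  if (length(short))
    stop("malformed line ", lineno[short[1L]], " in '", path,
         "': fewer than ", need, " fields")
  sites <- toupper(vapply(fields, `[[`, "", site_col))
  energies <- suppressWarnings(
    as.numeric(vapply(fields, `[[`, "", energy_col)))
  if (anyNA(energies))
    stop("malformed line ", lineno[which(is.na(energies))[1L]], " in '", path,
         "': energy is not numeric")
  widths <- nchar(sites)
  if (length(unique(widths)) != 1L)
    stop("malformed line ", lineno[which(widths != widths[1L])[1L]],
         " in '", path, "': site length ", widths[widths != widths[1L]][1L],
         " differs from ", widths[1L])
  seq_to_codes(sites, context = path)  # validates the alphabet
  cfg <- sample_config(
    n_sites = length(sites),
    mu = as.numeric(meta$mu %||% -0.5),
    seed = as.integer(meta$seed %||% 0L)
  )
  structure(
    list(model_id = meta$model_id %||% "sample", width = widths[1L],
         sites = sites, energies = energies, config = cfg,
         generator = paste0("read from ", basename(path))),
    class = "site_sample"
  )
}

#' Export a site sample as FASTA
#'
#' Record ids are `<model_id>_site<NNN>`; lines wrap at 60 columns.
#'
#' @param sample a [sample_sites()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sites_fasta <- function(sample, path) {
  stopifnot(inherits(sample, "site_sample"))
  ids <- sprintf("%s_site%03d", sample$model_id, seq_along(sample$sites))
  write_fasta(stats::setNames(sample$sites, ids), path)
}
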