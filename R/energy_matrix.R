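#' Additive binding-energy matrices
#'
#' An `energy_matrix` stores the additive per-position, per-base binding
#' energies of a transcription factor, in kT units, with the conventional
#' gauge that the preferred base of every position has energy 0 and the
#' consensus sequence therefore has total energy 0.  Higher energies mean
#' weaker binding.  Rows are positions (1..L), columns are the bases
#' A, C, G, T.
#'
#' @param energies numeric L x 4 matrix of nonnegative energies (kT); each
#'   row must contain a 0 (its preferred base).  `NA` entries mark
#'   undetermined values (only produced by [fit_energy_matrix()]).
#' @param model_id short label, e.g. `"M7S-1"`.
#' @param mu chemical potential associated with the model (kT), used as the
#'   default operating point for occupancy computations.
#' @return an object of class `energy_matrix`: a list with elements
#'   `model_id`, `width`, `energies` (L x 4 matrix with column names
#'   A, C, G, T) and `mu`.
#' @seealso [site_energy()], [enumerate_landscape()], [mnt_models()]
#' @export
energy_matrix <- function(energies, model_id = "matrix", mu = -0.5) {
  energies <- as.matrix(energies)
  if (ncol(energies) != 4L)
    stop("energies must have 4 columns (A, C, G, T)")
  if (nrow(energies) < 1L || nrow(energies) > 12L)
    stop("matrix width must be between 1 and 12")
  storage.mode(energies) <- "double"
  colnames(energies) <- DNA_BASES
  rownames(energies) <- NULL
  obs <- !is.na(energies)
  if (any(energies[obs] < 0))
    stop("energies must be nonnegative (consensus gauge)")
  rowmin <- apply(energies, 1L, function(e) min(e, na.rm = TRUE))
  if (any(abs(rowmin) > 1e-9))
    stop("every position must have a base with energy 0 (row ",
         which(abs(rowmin) > 1e-9)[1L], " has minimum ",
         format(max(abs(rowmin))), ")")
  if (!is.finite(mu)) stop("mu must be finite")
  structure(
    list(model_id = as.character(model_id), width = nrow(energies),
         energies = energies, mu = mu),
    class = "energy_matrix"
  )
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat("<energy_matrix> ", x$model_id, ": width ", x$width,
      ", mu = ", x$mu, ", consensus ", consensus_sequence(x), "\n", sep = "")
  m <- round(x$energies, 3)
  rownames(m) <- paste0("pos", seq_len(x$width))
  print(m)
  invisible(x)
}

#' Consensus (minimum-energy) sequence of an energy matrix
#'
#' Ties are broken toward the alphabetically first base.
#'
#' @param matrix an [energy_matrix()].
#' @return single character string of length `matrix$width`.
#' @export
consensus_sequence <- function(matrix) {
  stopifnot(inherits(matrix, "energy_matrix"))
  paste(DNA_BASES[apply(matrix$energies, 1L, which.min)], collapse = "")
}

#' Binding energy of a sequence under an additive energy matrix
#'
#' Sums the per-position energies of the bases in `sequence`; the consensus
#' sequence scores exactly 0.
#'
#' @param matrix an [energy_matrix()].
#' @param sequence character vector of ACGT sequences, each of length
#'   `matrix$width`.
#' @return numeric vector of energies in kT.
#' @export
site_energy <- function(matrix, sequence) {
  stopifnot(inherits(matrix, "energy_matrix"))
  codes <- seq_to_codes(sequence, width = matrix$width, context = "site_energy")
  energies_of_codes(matrix, codes)
}

#' @noRd
energies_of_codes <- function(matrix, codes) {
  L <- matrix$width
  e <- matrix$energies[cbind(rep(seq_len(L), each = nrow(codes)),
                             as.vector(codes))]
  rowSums(matrix(e, nrow = nrow(codes), ncol = L))
}

#' Reverse complement of an energy matrix
#'
#' The energy of base b at position j in the result equals the input energy
#' of complement(b) at position L+1-j, so that for every sequence s,
#' `site_energy(reverse_complement_matrix(m), s) == site_energy(m,
#' reverse_complement(s))`.  Applying the operation twice returns the input.
#'
#' @param matrix an [energy_matrix()].
#' @return an [energy_matrix()].
#' @export
reverse_complement_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "energy_matrix"))
  e <- matrix$energies[matrix$width:1, 4:1, drop = FALSE]
  colnames(e) <- DNA_BASES
  out <- matrix
  out$energies <- e
  out
}

#' Classify the reverse-complement symmetry of an energy matrix
#'
#' A matrix is `even_symmetric` when it equals its own reverse complement
#' (only possible for even widths in a strict sense, though the test is the
#' equality itself); `odd_symmetric` when every position pair (j, L+1-j)
#' except the central position of an odd-width matrix is complement-mirrored,
#' with the central column unconstrained; otherwise `asymmetric`.
#'
#' @param matrix an [energy_matrix()].
#' @param tol numeric tolerance for entry equality.
#' @return one of `"even_symmetric"`, `"odd_symmetric"`, `"asymmetric"`.
#' @export
classify_symmetry <- function(matrix, tol = 1e-8) {
  stopifnot(inherits(matrix, "energy_matrix"))
  e <- matrix$energies
  rc <- reverse_complement_matrix(matrix)$energies
  same <- function(a, b) {
    ok <- !(is.na(a) | is.na(b))
    all(is.na(a) == is.na(b)) && all(abs(a[ok] - b[ok]) < tol)
  }
  if (same(e, rc)) return("even_symmetric")
  L <- matrix$width
  if (L %% 2L == 1L) {
    centre <- (L + 1L) %/% 2L
    if (same(e[-centre, , drop = FALSE], rc[-centre, , drop = FALSE]))
      return("odd_symmetric")
  }
  "asymmetric"
}

#' Derive a variant of an energy matrix by a position swap or deletion
#'
#' These are the elementary transforms relating the asymmetric and symmetric
#' members of a model family: swapping two columns (e.g. positions 5 and 6
#' of a 7-long matrix turns consensus GTGGACC into the symmetric GTGGCAC)
#' and deleting the central column (turning a 7-long odd-symmetric matrix
#' into a 6-long even-symmetric one).
#'
#' @param matrix an [energy_matrix()].
#' @param swap integer vector `c(j, k)`: exchange entire columns j and k.
#' @param delete integer position to remove (width decreases by 1).
#'   Exactly one of `swap` and `delete` must be given.
#' @param model_id label for the derived matrix; defaults to the input label
#'   with a suffix describing the transform.
#' @return an [energy_matrix()].
#' @export
make_variant <- function(matrix, swap = NULL, delete = NULL, model_id = NULL) {
  stopifnot(inherits(matrix, "energy_matrix"))
  if (is.null(swap) == is.null(delete))
    stop("give exactly one of `swap` or `delete`")
  e <- matrix$energies
  L <- matrix$width
  if (!is.null(swap)) {
    swap <- as.integer(swap)
    if (length(swap) != 2L || any(swap < 1L | swap > L))
      stop("swap positions must be two positions in 1..", L)
    e[swap, ] <- e[rev(swap), ]
    id <- model_id %||% paste0(matrix$model_id, "_swap", swap[1L], swap[2L])
  } else {
    delete <- as.integer(delete)
    if (length(delete) != 1L || delete < 1L || delete > L)
      stop("delete position must be a single position in 1..", L)
    e <- e[-delete, , drop = FALSE]
    id <- model_id %||% paste0(matrix$model_id, "_del", delete)
  }
  energy_matrix(e, model_id = id, mu = matrix$mu)
}

#' Expand a degenerate IUPAC consensus into its concrete sequences
#'
#' Uses the 15-letter IUPAC nucleotide code (DNA only; `U` is rejected).
#' The classic example is the HincII recognition site GTYRAC, which expands
#' to four sites, two of them reverse-complement palindromes.
#'
#' @param iupac single IUPAC string.
#' @return character vector of all matching ACGT sequences, in lexicographic
#'   order; its length is the product of the per-position degeneracies.
#' @export
expand_degenerate <- function(iupac) {
  stopifnot(is.character(iupac), length(iupac) == 1L)
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1L]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- !(chars %in% names(map)) | chars == "U"
  if (any(bad))
    stop("unknown IUPAC character '", chars[which(bad)[1L]],
         "' at position ", which(bad)[1L])
  opts <- lapply(chars, function(ch) strsplit(map[[ch]], "", fixed = TRUE)[[1L]])
  g <- expand.grid(rev(opts), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  sort(do.call(paste0, rev(g)))
}

#' Is a sequence a reverse-complement palindrome?
#'
#' TRUE iff the sequence equals its own reverse complement; always FALSE for
#' odd lengths.
#'
#' @param sequence character vector of ACGT sequences.
#' @return logical vector.
#' @export
is_reverse_palindrome <- function(sequence) {
  out <- sequence == reverse_complement(sequence)
  out[nchar(sequence) %% 2L == 1L] <- FALSE
  out
}
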