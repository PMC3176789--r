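# shared low-level helpers: base coding, reverse complement, seeded RNG

DNA_BASES <- c("A", "C", "G", "T")

# integer codes 1..4 = A,C,G,T; complement is 5 - code
comp_code <- function(code) 5L - code

#' @noRd
seq_to_codes <- function(sites, width = NULL, context = "sequence") {
  if (length(sites) == 0L) stop(context, ": no sequences given")
  L <- nchar(sites[1L])
  if (!all(nchar(sites) == L)) {
    bad <- which(nchar(sites) != L)[1L]
    stop(context, ": sequence ", bad, " has length ", nchar(sites[bad]),
         ", expected ", L)
  }
  if (!is.null(width) && L != width) {
    stop(context, ": sequences have length ", L, ", expected ", width)
  }
  chars <- strsplit(sites, "", fixed = TRUE)
  m <- matrix(match(unlist(chars), DNA_BASES),
              nrow = length(sites), ncol = L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(context, ": non-ACGT character '",
         substr(sites[bad[1L]], bad[2L], bad[2L]),
         "' in sequence ", bad[1L], " at position ", bad[2L])
  }
  m
}

#' @noRd
codes_to_seq <- function(codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  chars <- matrix(DNA_BASES[codes], nrow = nrow(codes))
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

#' @noRd
revcomp_codes <- function(codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  (5L - codes)[, ncol(codes):1, drop = FALSE]
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of ACGT sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  codes_to_seq(revcomp_codes(seq_to_codes(x)))
}

# all 4^L sequences as a code matrix, rows in lexicographic sequence order
#' @noRd
enumerate_codes <- function(width) {
  stopifnot(width >= 1L, width <= 12L)
  g <- expand.grid(rep(list(1:4), width), KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)[, width:1, drop = FALSE]
}

# lexicographic index (1-based) of each row of a code matrix
#' @noRd
codes_to_index <- function(codes) {
  L <- ncol(codes)
  idx <- rep(1, nrow(codes))
  for (j in seq_len(L)) idx <- idx + (codes[, j] - 1) * 4^(L - j)
  as.integer(idx)
}

#' @noRd
logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# evaluate expr with a temporary RNG seed, restoring global RNG state
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib motifsym, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
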