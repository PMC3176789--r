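#' Reconstruct an additive energy matrix from sites and energies
#'
#' Solves the additive model E(site) = sum_j e(j, base_j) by least squares
#' over one-hot position/base indicators, then fixes the gauge by shifting
#' every position's energies so that the smallest observed entry is 0 (the
#' consensus convention).  When the input energies are exactly additive —
#' as for records written by [sample_sites()] / [write_sample()] — the
#' generating matrix is recovered exactly up to that gauge, and every input
#' energy is reproduced to numerical tolerance.
#'
#' Position/base combinations never observed in `sites` cannot be estimated;
#' they are returned as `NA` and listed in the `undetermined` attribute of
#' the result.
#'
#' @param sites character vector of equal-length ACGT sequences.
#' @param energies numeric vector of binding energies (kT), one per site.
#' @param tol maximum absolute residual tolerated before the energies are
#'   declared non-additive.
#' @param model_id label for the fitted matrix.
#' @param mu chemical potential stored with the result.
#' @return an [energy_matrix()]; entries that could not be determined are
#'   `NA`, and `attr(, "undetermined")` holds their (position, base) pairs.
#' @export
fit_energy_matrix <- function(sites, energies, tol = 1e-6,
                              model_id = "fitted", mu = -0.5) {
  if (length(sites) != length(energies))
    stop("sites and energies differ in length (", length(sites), " vs ",
         length(energies), ")")
  codes <- seq_to_codes(sites, context = "fit_energy_matrix")
  L <- ncol(codes)
  n <- nrow(codes)

  # one-hot design over the 4L (position, base) cells
  cell <- (rep(seq_len(L), each = n) - 1L) * 4L + as.vector(codes)
  X <- matrix(0, nrow = n, ncol = 4L * L)
  X[cbind(rep(seq_len(n), times = L), cell)] <- 1
  observed <- colSums(X) > 0

  beta <- rep(NA_real_, 4L * L)
  Xo <- X[, observed, drop = FALSE]
  beta[observed] <- as.vector(MASS::ginv(Xo) %*% energies)

  fitted <- as.vector(Xo %*% beta[observed])
  max_resid <- max(abs(fitted - energies))
  if (max_resid > tol)
    stop("energies are not additive: max residual ", format(max_resid),
         " exceeds tolerance ", format(tol))

  e <- matrix(beta, nrow = L, ncol = 4L, byrow = TRUE,
              dimnames = list(NULL, DNA_BASES))
  shift <- apply(e, 1L, function(row) min(row, na.rm = TRUE))
  e <- sweep(e, 1L, shift)
  e[!is.na(e) & abs(e) < 1e-9] <- 0  # clean numerical dust at the gauge
  und <- which(is.na(e), arr.ind = TRUE)
  colnames(und) <- c("position", "base")
  out <- energy_matrix(e, model_id = model_id, mu = mu)
  attr(out, "undetermined") <- und
  attr(out, "max_residual") <- max_resid
  out
}
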