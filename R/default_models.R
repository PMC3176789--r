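#' Built-in Mnt-like binding site models
#'
#' Eight additive energy matrices patterned on the Mnt repressor half-site
#' (consensus GTGGACC): four 7-long models — asymmetric `M7A-1`/`M7A-2` and
#' their symmetrized counterparts `M7S-1`/`M7S-2` (positions 5 and 6
#' exchanged, giving the odd-symmetric consensus GTGGCAC with an
#' unconstrained central base) — and four 6-long models obtained by deleting
#' the central position: asymmetric `M6A-1`/`M6A-2` (consensus GTGACC) and
#' even-symmetric `M6S-1`/`M6S-2` (consensus GTGCAC).
#'
#' The numeric energies are the package's own defaults, chosen so that the
#' landscape-true information content at the default chemical potential
#' (mu = -0.5) sits at the realistic scale of roughly 3.1-3.3 bits while
#' the worst base of most positions carries a strong penalty (~5.5 kT), as
#' protein-DNA binding data typically show.  The "-1" and "-2" members of
#' each family share the same energies in the outer positions but differ in
#' which bases carry them (changing the rank order at position 2 from
#' T,G > C,A to T,A > C,G, which makes the "-1" models more nearly
#' symmetric) and in the specificity of the central position of the 7-long
#' matrices, which is much weaker in the "-2" models.  They are an
#' approximation of the experimentally derived Mnt parameters, not a
#' reproduction of them; arbitrary matrices can be loaded with
#' [read_energy_matrix()] or reconstructed from site/energy records with
#' [fit_energy_matrix()].
#'
#' @param id optional single model id; if omitted, all eight are returned.
#' @param mu chemical potential stored with the models.
#' @return for `mnt_models()`, a named list of [energy_matrix()] objects;
#'   for `mnt_model(id)`, a single [energy_matrix()].
#' @examples
#' consensus_sequence(mnt_model("M7S-1"))  # "GTGGCAC"
#' classify_symmetry(mnt_model("M6S-2"))   # "even_symmetric"
#' @export
mnt_models <- function(mu = -0.5) {
  # half-site columns (A, C, G, T), kT; mirrored to build the symmetric 7-mer
  c1  <- c(1.80, 2.20, 0.00, 1.15)  # G preferred
  c2  <- c(5.50, 1.35, 0.80, 0.00)  # T preferred, ranks T,G > C,A ("-1")
  c2b <- c(0.80, 1.35, 5.50, 0.00)  # T preferred, ranks T,A > C,G ("-2")
  c3  <- c(0.62, 5.50, 0.00, 1.05)  # G preferred
  c4  <- c(1.10, 0.15, 0.00, 1.10)  # centre, S = G/C, sharper ("-1")
  c4b <- c(0.50, 0.10, 0.00, 0.50)  # centre, S = G/C, weaker  ("-2")
  mirror <- function(col) col[4:1]
  m7s <- function(cc2, cc4)
    rbind(c1, cc2, c3, cc4, mirror(c3), mirror(cc2), mirror(c1))
  s1 <- energy_matrix(m7s(c2, c4),  "M7S-1", mu)
  s2 <- energy_matrix(m7s(c2b, c4b), "M7S-2", mu)
  a1 <- make_variant(s1, swap = c(5, 6), model_id = "M7A-1")
  a2 <- make_variant(s2, swap = c(5, 6), model_id = "M7A-2")
  out <- list(
    `M7A-1` = a1,
    `M7A-2` = a2,
    `M7S-1` = s1,
    `M7S-2` = s2,
    `M6A-1` = make_variant(a1, delete = 4, model_id = "M6A-1"),
    `M6A-2` = make_variant(a2, delete = 4, model_id = "M6A-2"),
    `M6S-1` = make_variant(s1, delete = 4, model_id = "M6S-1"),
    `M6S-2` = make_variant(s2, delete = 4, model_id = "M6S-2")
  )
  out
}

#' @rdname mnt_models
#' @export
mnt_model <- function(id, mu = -0.5) {
  models <- mnt_models(mu = mu)
  if (!id %in% names(models))
    stop("unknown model id '", id, "'; available: ",
         paste(names(models), collapse = ", "))
  models[[id]]
}

#' Read / write an energy matrix in TSV form
#'
#' The dialect is a header line `pos<TAB>A<TAB>C<TAB>G<TAB>T` followed by one
#' row per position; `#`-prefixed comment lines before the header carry
#' `model_id` and `mu` as `# key: value`.
#'
#' @param path file path.
#' @param matrix an [energy_matrix()] (for writing).
#' @return `read_energy_matrix()` returns an [energy_matrix()];
#'   `write_energy_matrix()` returns `path` invisibly.
#' @export
read_energy_matrix <- function(path) {
  lines <- readLines(path)
  meta <- parse_hash_meta(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2L) stop("matrix file '", path, "' has no data rows")
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  missing <- setdiff(c("pos", DNA_BASES), header)
  if (length(missing))
    stop("matrix file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  df <- utils::read.table(text = paste(body, collapse = "\n"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  df <- df[order(df$pos), , drop = FALSE]
  energy_matrix(as.matrix(df[, DNA_BASES]),
                model_id = meta$model_id %||% "matrix",
                mu = as.numeric(meta$mu %||% -0.5))
}

#' @rdname read_energy_matrix
#' @export
write_energy_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "energy_matrix"))
  lines <- c(
    paste0("# model_id: ", matrix$model_id),
    paste0("# mu: ", format(matrix$mu, digits = 15)),
    paste(c("pos", DNA_BASES), collapse = "\t"),
    vapply(seq_len(matrix$width), function(j) {
      paste(c(j, format(matrix$energies[j, ], digits = 15, trim = TRUE)),
            collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @noRd
parse_hash_meta <- function(lines) {
  h <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in h) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) out[[m[2L]]] <- trimws(m[3L])
  }
  out
}
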