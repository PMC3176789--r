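test_that("site_energy sums per-position contributions and validates input", {
  toy <- toy_matrix()
  expect_equal(site_energy(toy, "CT"), 1.0)
  expect_equal(site_energy(toy, "AT"), 0.0)
  expect_equal(site_energy(toy, c("GT", "TA", "CG")), c(2.0, 3.2, 1.6))
  for (m in mnt_models())
    expect_identical(site_energy(m, consensus_sequence(m)), 0)
  expect_error(site_energy(toy, "ACG"), "length")
  expect_error(site_energy(toy, "AX"), "position 2")
})

test_that("sampled site energies round-trip through site_energy exactly", {
  m <- mnt_model("M7A-2")
  smp <- make_sample("M7A-2", n = 200, seed = 3)
  expect_identical(site_energy(m, smp$sites), smp$energies)
})

test_that("reverse_complement_matrix is an involution that mirrors energies", {
  toy <- toy_matrix()
  rc <- reverse_complement_matrix(toy)
  # brute force over all 16 dinucleotides
  for (s in all_kmers(2)) {
    expect_equal(site_energy(rc, s), site_energy(toy, reverse_complement(s)))
  }
  for (m in mnt_models()) {
    back <- reverse_complement_matrix(reverse_complement_matrix(m))
    expect_equal(back$energies, m$energies)
  }
  m6s <- mnt_model("M6S-1")
  expect_equal(reverse_complement_matrix(m6s)$energies, m6s$energies)
})

test_that("classify_symmetry distinguishes even, odd and asymmetric models", {
  expect_identical(classify_symmetry(mnt_model("M6S-1")), "even_symmetric")
  expect_identical(classify_symmetry(mnt_model("M6S-2")), "even_symmetric")
  expect_identical(classify_symmetry(mnt_model("M7S-1")), "odd_symmetric")
  expect_identical(classify_symmetry(mnt_model("M7S-2")), "odd_symmetric")
  for (id in c("M7A-1", "M7A-2", "M6A-1", "M6A-2"))
    expect_identical(classify_symmetry(mnt_model(id)), "asymmetric")
  expect_identical(classify_symmetry(toy_matrix()), "asymmetric")
})

test_that("swapping positions 5 and 6 converts the asymmetric 7-mers to symmetric", {
  for (k in 1:2) {
    asym <- mnt_model(paste0("M7A-", k))
    expect_identical(consensus_sequence(asym), "GTGGACC")
    swapped <- make_variant(asym, swap = c(5, 6))
    expect_identical(consensus_sequence(swapped), "GTGGCAC")
    expect_identical(classify_symmetry(swapped), "odd_symmetric")
    expect_equal(swapped$energies, mnt_model(paste0("M7S-", k))$energies)
  }
  m <- mnt_model("M7A-1")
  expect_equal(make_variant(m, swap = c(3, 3))$energies, m$energies)
  expect_error(make_variant(m, swap = c(0, 5)), "1..7")
  expect_error(make_variant(m, delete = 9), "1..7")
  expect_error(make_variant(m, swap = c(1, 2), delete = 3), "exactly one")
})

test_that("deleting the centre column preserves the additive decomposition", {
  m7 <- mnt_model("M7S-1")
  m6 <- make_variant(m7, delete = 4)
  expect_identical(m6$width, 6L)
  # energy of any 6-mer equals the 7-mer energy with base X inserted at
  # position 4, minus the column-4 energy of X: brute force over 4^6 x 4
  kmers <- all_kmers(6)
  e6 <- site_energy(m6, kmers)
  for (b in 1:4) {
    X <- c("A", "C", "G", "T")[b]
    ins <- paste0(substr(kmers, 1, 3), X, substr(kmers, 4, 6))
    expect_equal(site_energy(m7, ins) - m7$energies[4, b], e6)
  }
})

test_that("expand_degenerate enumerates IUPAC patterns (HincII example)", {
  hincii <- expand_degenerate("GTYRAC")
  expect_setequal(hincii, c("GTTAAC", "GTCGAC", "GTCAAC", "GTTGAC"))
  expect_length(hincii, 4L)
  expect_identical(sum(is_reverse_palindrome(hincii)), 2L)
  expect_identical(expand_degenerate("ACGT"), "ACGT")
  expect_length(expand_degenerate("NN"), 16L)
  expect_error(expand_degenerate("GTXAAC"), "position 3")
  expect_error(expand_degenerate("GU"), "position 2")
  # size equals the product of per-symbol degeneracies; all match the pattern
  degeneracy <- c(N = 4, B = 3, D = 3, H = 3, V = 3, R = 2, Y = 2, S = 2,
                  W = 2, K = 2, M = 2, A = 1, C = 1, G = 1, T = 1)
  set.seed(42)
  matches_pattern <- function(s, pat) {
    all(mapply(function(base, code)
      grepl(base, Biostrings::IUPAC_CODE_MAP[[code]], fixed = TRUE),
      strsplit(s, "")[[1L]], strsplit(pat, "")[[1L]]))
  }
  for (i in 1:10) {
    pat <- paste(sample(names(degeneracy), 5, TRUE), collapse = "")
    got <- expand_degenerate(pat)
    expect_length(got, prod(degeneracy[strsplit(pat, "")[[1L]]]))
    expect_identical(anyDuplicated(got), 0L)
    expect_true(all(vapply(got, matches_pattern, TRUE, pat = pat)))
  }
})

test_that("is_reverse_palindrome detects reverse-complement palindromes", {
  expect_true(is_reverse_palindrome("GTTAAC"))
  expect_true(is_reverse_palindrome("GTCGAC"))
  expect_false(is_reverse_palindrome("GTCAAC"))
  expect_false(is_reverse_palindrome("GTTGAC"))
  expect_false(any(is_reverse_palindrome(all_kmers(3))))
})

test_that("fit_energy_matrix recovers a generating matrix from site records", {
  m <- mnt_model("M6A-1")
  smp <- make_sample("M6A-1", n = 500, seed = 8)
  fit <- fit_energy_matrix(smp$sites, smp$energies, model_id = "refit")
  expect_lt(attr(fit, "max_residual"), 1e-9)
  # every observed cell matches the generator; fitted energies reproduce
  # every stored energy
  obs <- !is.na(fit$energies)
  expect_equal(fit$energies[obs], m$energies[obs], tolerance = 1e-7)
  expect_equal(site_energy(fit, smp$sites), smp$energies, tolerance = 1e-7)
})

test_that("fit_energy_matrix solves small exact designs and flags gaps", {
  toy <- toy_matrix()
  sites <- c("AA", "CT", "GC", "TG", "AT", "CA", "GT", "TC")
  fit <- fit_energy_matrix(sites, site_energy(toy, sites))
  expect_equal(fit$energies, toy$energies, tolerance = 1e-9)
  expect_identical(nrow(attr(fit, "undetermined")), 0L)

  # all-identical sites: observed (consensus) cells 0, the rest undetermined
  same <- fit_energy_matrix(rep("GT", 5), rep(0, 5))
  expect_identical(unname(same$energies[1, "G"]), 0)
  expect_identical(unname(same$energies[2, "T"]), 0)
  expect_identical(sum(is.na(same$energies)), 6L)
  expect_identical(nrow(attr(same, "undetermined")), 6L)

  expect_error(fit_energy_matrix(c("AA", "AC", "CA", "CC"), c(0, 1, 1, 5)),
               "residual")
})

test_that("energy matrices survive a TSV round trip", {
  m <- mnt_model("M7S-2")
  path <- withr_local_tempfile()
  write_energy_matrix(m, path)
  back <- read_energy_matrix(path)
  expect_equal(back$energies, m$energies)
  expect_identical(back$model_id, m$model_id)
  expect_identical(back$mu, m$mu)
  bad <- sub("\tT$", "", readLines(path))
  writeLines(bad, path)
  expect_error(read_energy_matrix(path), "T")
})
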