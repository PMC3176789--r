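test_that("single-letter columns are fully conserved under a uniform background", {
  d <- column_score_distribution(1)
  mass <- exp(d$log_prob)
  expect_equal(sum(mass), 1, tolerance = 1e-12)
  peak <- (which.max(d$log_prob) + d$min_bin - 1L) * d$bin_width
  expect_equal(peak, 2)  # one letter: 2 bits, probability 1
  expect_equal(max(mass), 1, tolerance = 1e-12)
})

test_that("two-letter column distribution matches the 16-outcome enumeration", {
  d <- column_score_distribution(2)
  bits <- (seq_along(d$log_prob) + d$min_bin - 1L) * d$bin_width
  mass <- exp(d$log_prob)
  expect_equal(sum(mass[abs(bits - 2) < 1e-9]), 0.25, tolerance = 1e-12)
  expect_equal(sum(mass[abs(bits - 1) < 1e-9]), 0.75, tolerance = 1e-12)
})

test_that("the DP equals exhaustive enumeration for small columns", {
  for (case in list(list(n = 3, bg = rep(0.25, 4)),
                    list(n = 5, bg = rep(0.25, 4)),
                    list(n = 6, bg = rep(0.25, 4)),
                    list(n = 5, bg = c(0.4, 0.1, 0.1, 0.4)),
                    list(n = 4, bg = c(0.1, 0.2, 0.3, 0.4)))) {
    d <- column_score_distribution(case$n, case$bg)
    oracle <- enum_column_dist(case$n, case$bg)
    got <- rep(0, length(oracle$bin))
    bins <- seq_along(d$log_prob) + d$min_bin - 1L
    for (i in seq_along(oracle$bin)) {
      hit <- bins == oracle$bin[i]
      if (any(hit)) got[i] <- exp(d$log_prob[hit])
    }
    expect_lt(max(abs(got - oracle$prob)), 1e-12)
    expect_equal(sum(exp(d$log_prob)), 1, tolerance = 1e-12)
  }
})

test_that("the DP matches exact partition enumeration at the study depth", {
  # independent exact oracle at n = 500 (uniform background)
  d <- column_score_distribution(500)
  oracle <- partition_column_dist(500)
  bins <- seq_along(d$log_prob) + d$min_bin - 1L
  common <- intersect(bins, oracle$bin)
  expect_gt(length(common), 100)
  dp_lp <- d$log_prob[match(common, bins)]
  or_lp <- oracle$log_prob[match(common, oracle$bin)]
  expect_lt(max(abs(dp_lp - or_lp)), 1e-8)
  # no mass outside the common support
  expect_equal(sum(exp(dp_lp)), 1, tolerance = 1e-9)
})

test_that("log_pvalue_information reproduces small-case anchors", {
  expect_identical(log_pvalue_information(0, 10, 7), 0)
  expect_equal(log_pvalue_information(2, 2, 1), log(0.25), tolerance = 1e-9)
  # fully conserved motif: p = (4 (1/4)^n)^L
  expect_equal(log_pvalue_information(4, 3, 2),
               2 * log(4 * 0.25^3), tolerance = 1e-9)
  expect_equal(log_pvalue_information(6, 4, 3),
               3 * log(4 * 0.25^4), tolerance = 1e-9)
  expect_error(log_pvalue_information(15, 10, 7), "exceeds")
})

test_that("log_pvalue_information is monotone in the observed information", {
  lp <- vapply(seq(0, 6, by = 0.5), log_pvalue_information,
               0, n = 50, width = 3)
  expect_true(all(diff(lp) <= 0))
  expect_true(all(lp <= 0))
})

test_that("the p-value is stable under lattice refinement at study depth", {
  lp1 <- log_pvalue_information(3.9, 500, 7, bin_width = 0.005)
  lp2 <- log_pvalue_information(3.9, 500, 7, bin_width = 0.0025)
  expect_lt(abs(lp1 - lp2) / abs(lp1), 0.005)
  expect_lt(lp1, -1000)  # extreme significance, finite in log space
})

test_that("the symmetric null matches direct simulation of random alignments", {
  for (case in list(c(N = 25, L = 2, i = 0.30),
                    c(N = 20, L = 3, i = 0.55))) {
    N <- case[["N"]]; L <- case[["L"]]; i0 <- case[["i"]]
    nsim <- 20000
    ivals <- with(list(), {
      set.seed(99)
      replicate(nsim, {
        cd <- matrix(sample.int(4L, N * L, TRUE), N, L)
        cs <- t(vapply(seq_len(L), function(j) tabulate(cd[, j], 4L),
                       numeric(4L)))
        sym <- cs + cs[L:1, 4:1]
        f <- sym / (2 * N)
        sum(ifelse(f > 0, f * log2(4 * f), 0))
      })
    })
    emp <- mean(ivals >= i0)
    model <- exp(log_pvalue_symmetric(i0, N, L))
    se <- sqrt(emp * (1 - emp) / nsim)
    expect_lt(abs(emp - model), 4 * se + 1e-4)
  }
})

test_that("evalue_report applies the alignment-count correction per mode", {
  smp <- make_sample("M7S-1", n = 500, seed = 1)
  asym <- evalue_report(discover_asymmetric(smp))
  sym <- evalue_report(discover_symmetric(smp))
  fixed <- evalue_report(discover_fixed(smp))
  expect_equal(asym$n_alignments_log, 500 * log(2))
  expect_equal(asym$n_alignments_log, 346.57, tolerance = 1e-3)
  expect_identical(sym$n_alignments_log, 0)
  expect_identical(fixed$n_alignments_log, 0)
  expect_equal(asym$minus_ln_evalue,
               -asym$log_pvalue - 500 * log(2))
  expect_lte(asym$minus_ln_evalue, -asym$log_pvalue)
  expect_true(all(is.finite(c(asym$minus_ln_evalue, sym$minus_ln_evalue,
                              fixed$minus_ln_evalue))))
})

test_that("a single-site asymmetric report pays exactly ln 2", {
  smp <- structure(list(model_id = "one", width = 6L, sites = "GTCAAC",
                        energies = 0, config = sample_config(n_sites = 1)),
                   class = "site_sample")
  r <- evalue_report(discover_asymmetric(smp))
  expect_equal(r$minus_ln_evalue, -r$log_pvalue - log(2))
})

test_that("select_model picks the larger -lnE and reports free parameters", {
  mk <- function(mode, mlnE, width = 7L)
    structure(list(mode = mode, information_bits = 3, log_pvalue = -mlnE,
                   n_alignments_log = 0, minus_ln_evalue = mlnE,
                   n_sites = 500L, width = width),
              class = "significance_report")
  sel <- select_model(mk("asymmetric", 10), mk("symmetric", 12))
  expect_identical(sel$verdict, "symmetric")
  expect_equal(sel$margin, 2)
  expect_identical(sel$free_parameters,
                   c(asymmetric = 21L, symmetric = 12L))
  sel2 <- select_model(mk("asymmetric", 15), mk("symmetric", 12))
  expect_identical(sel2$verdict, "asymmetric")
  expect_error(select_model(mk("symmetric", 1), mk("symmetric", 2)))
})
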