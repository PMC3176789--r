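# Independent oracles and small fixtures, all built in code.

# the 2-wide toy matrix: column 1 (A:0, C:1, G:2, T:3),
# column 2 (T:0, A:0.2, C:0.4, G:0.6)
toy_matrix <- function() {
  energy_matrix(rbind(c(0, 1, 2, 3), c(0.2, 0.4, 0.6, 0)),
                model_id = "toy2")
}

all_kmers <- function(L) {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), L),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  do.call(paste0, rev(g))
}

# exhaustive single-column information distribution: enumerate every count
# composition of n letters over 4 bases, weight by the multinomial pmf
enum_column_dist <- function(n, background = rep(0.25, 4),
                             bin_width = 0.005) {
  g <- expand.grid(a = 0:n, c = 0:n, g = 0:n)
  g <- g[g$a + g$c + g$g <= n, ]
  g$t <- n - g$a - g$c - g$g
  counts <- as.matrix(g[, c("a", "c", "g", "t")])
  # bin per-base score terms on the lattice, matching the DP's convention
  bins <- apply(counts, 1L, function(k) {
    f <- k / n
    t <- ifelse(f > 0, f * log2(f / background), 0)
    sum(round(t / bin_width))
  })
  prob <- apply(counts, 1L, function(k) stats::dmultinom(k, prob = background))
  agg <- tapply(prob, bins, sum)
  idx <- as.integer(names(agg))
  list(bin = idx, prob = as.numeric(agg))
}

# exact column distribution at large n for the uniform background, by
# enumerating unordered partitions of n into at most 4 parts
partition_column_dist <- function(n, bin_width = 0.005) {
  rows <- vector("list", 2048)
  nr <- 0
  for (a in seq.int(ceiling(n / 4), n)) {
    for (b in seq.int(0, min(a, n - a))) {
      r <- n - a - b
      cmax <- min(b, r)
      cmin <- ceiling(r / 2)
      if (cmin > cmax) next
      cs <- cmin:cmax
      nr <- nr + 1
      rows[[nr]] <- cbind(a, b, cs, r - cs)
    }
  }
  counts <- do.call(rbind, rows[seq_len(nr)])
  # multiplicity: distinct assignments of the 4 count values to 4 bases
  multip <- apply(counts, 1L, function(k) {
    tab <- table(k)
    factorial(4) / prod(factorial(tab))
  })
  lprob <- lgamma(n + 1) - rowSums(lgamma(counts + 1)) + n * log(0.25) +
    log(multip)
  f <- counts / n
  bins <- rowSums(round(ifelse(f > 0, f * log2(4 * f), 0) / bin_width))
  agg <- tapply(lprob, bins, function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  })
  list(bin = as.integer(names(agg)), log_prob = as.numeric(agg))
}

# independent exhaustive orientation search: best information content over
# all 2^N orientation assignments, computed directly from strings
oracle_best_orientation_info <- function(sites) {
  n <- length(sites)
  L <- nchar(sites[1L])
  rc <- reverse_complement(sites)
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    pick <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0, rc, sites)
    mat <- do.call(rbind, strsplit(pick, "", fixed = TRUE))
    info <- sum(vapply(seq_len(L), function(j) {
      f <- tabulate(match(mat[, j], c("A", "C", "G", "T")), 4L) / n
      sum(ifelse(f > 0, f * log2(4 * f), 0))
    }, 0))
    if (info > best) best <- info
  }
  best
}

# draw a sample from a built-in model
make_sample <- function(id, n = 500, seed = 1, mu = -0.5) {
  land <- enumerate_landscape(mnt_model(id), mu = mu)
  sample_sites(land, sample_config(n_sites = n, mu = mu, seed = seed))
}

# random motif-like site set: sites near a shared consensus
make_motif_sites <- function(n, L, seed, mut_rate = 0.25) {
  set.seed(seed)
  cons <- sample(c("A", "C", "G", "T"), L, TRUE)
  vapply(seq_len(n), function(i) {
    s <- cons
    mut <- stats::runif(L) < mut_rate
    s[mut] <- sample(c("A", "C", "G", "T"), sum(mut), TRUE)
    paste(s, collapse = "")
  }, "")
}

withr_local_tempfile <- function(ext = ".tsv") tempfile(fileext = ext)
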