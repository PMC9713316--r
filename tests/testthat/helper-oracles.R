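# Independent oracles and small fixture builders shared across the suite.

# Naive Bray-Curtis, written directly from the definition.
naive_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Brute-force PERMANOVA pieces: plain double loops, no shared code with the
# package implementation.
brute_ss_total <- function(d, n) {
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) s <- s + d[i, j]^2
  s / n
}

brute_ss_within <- function(d, groups) {
  s <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    part <- 0
    for (a in seq_len(length(idx) - 1)) {
      for (b in (a + 1):length(idx)) part <- part + d[idx[a], idx[b]]^2
    }
    s <- s + part / length(idx)
  }
  s
}

brute_pseudo_f <- function(d, groups) {
  n <- nrow(d)
  a <- length(unique(groups))
  sst <- brute_ss_total(d, n)
  ssw <- brute_ss_within(d, groups)
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# Exhaustive enumeration of distinct label arrangements (independent
# recursion over positions).
brute_label_arrangements <- function(groups) {
  res <- list()
  build <- function(acc, pool) {
    if (!length(pool)) {
      res[[length(res) + 1]] <<- acc
      return(invisible())
    }
    for (lab in unique(pool)) {
      build(c(acc, lab), pool[-which(pool == lab)[1]])
    }
  }
  build(character(0), sort(groups))
  res
}

brute_exhaustive_p <- function(d, groups) {
  f_obs <- brute_pseudo_f(d, groups)
  arr <- brute_label_arrangements(groups)
  fs <- vapply(arr, function(g) brute_pseudo_f(d, g), numeric(1))
  mean(fs >= f_obs - 1e-12 * max(1, abs(f_obs)))
}

# Random valid dissimilarity matrix from points in R^p (metric, no ties
# w.p. 1).
random_euclidean_dist <- function(n, p = 3, seed = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(n * p), n, p)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  distance_matrix(m)
}

# Random normalized profile over k taxa.
random_profile <- function(k, taxa = paste0("t", seq_len(k))) {
  x <- rgamma(k, shape = 1)
  stats::setNames(x / sum(x), taxa)
}

# Small study config used where full default depth is unnecessary.
small_study_config <- function(seed = 1L, ...) {
  study_config(
    platforms = list(illumina = platform_model(5e4, 0.002),
                     ont = platform_model(1e4, 0.02)),
    seed = seed, ...)
}

# The worked toy example: equal-proportion 5-genus mock community, one
# off-target genus observed at 0.1.
toy_profiles <- function() {
  mock <- c("Bacillus", "Escherichia", "Lactococcus", "Pseudomonas",
            "Staphylococcus")
  list(
    observed = stats::setNames(c(0.1, 0.3, 0.2, 0.2, 0.1, 0.1),
                               c(mock, "Acinetobacter")),
    expected = stats::setNames(rep(0.2, 5), mock),
    mock = mock)
}
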