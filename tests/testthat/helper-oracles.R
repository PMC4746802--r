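# Independent oracles used across the suite. These deliberately do not
# share code with the package: the KS oracle is a plain loop over j, the
# BH oracle is the textbook step-up recursion, and the hypergeometric
# oracle is a choose()-sum (with a full subset enumeration for small
# cases). Keep them dumb.

ks_oracle <- function(ranks, n) {
  V <- sort(ranks)
  t <- length(V)
  # work on the common denominator t*n so exact ties stay exact
  a_num <- -Inf
  b_num <- -Inf
  for (j in seq_len(t)) {
    a_num <- max(a_num, j * n - V[j] * t)
    b_num <- max(b_num, V[j] * t - (j - 1) * n)
  }
  if (a_num > b_num) a_num / (t * n) else -b_num / (t * n)
}

# exact permutation p-value: proportion of all size-t subsets of 1..n
# whose KS score strictly exceeds the observed value
exact_perm_p <- function(observed_value, n, t) {
  subsets <- utils::combn(n, t)
  greater <- 0L
  for (i in seq_len(ncol(subsets))) {
    if (ks_oracle(subsets[, i], n) > observed_value) greater <- greater + 1L
  }
  greater / ncol(subsets)
}

# textbook BH step-up, computed on the sorted vector then unsorted
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, ps[i] * m / i)
    adj[i] <- min(running_min, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# upper-tail hypergeometric by direct summation of counts
hyper_oracle <- function(N, K, n_sig, k_hit) {
  if (k_hit <= 0L) return(1)
  total <- choose(N, n_sig)
  upper <- min(K, n_sig)
  if (k_hit > upper) return(0)
  s <- 0
  for (i in k_hit:upper) {
    s <- s + choose(K, i) * choose(N - K, n_sig - i)
  }
  s / total
}

# brute-force upper tail by enumerating every size-n_sig draw
hyper_enum <- function(N, K, n_sig, k_hit) {
  draws <- utils::combn(N, n_sig)
  hits <- colSums(draws <= K)   # treat compounds 1..K as the therapies
  mean(hits >= k_hit)
}

# small clean fixture instance: genes g1..gn ranked in index order
toy_instance <- function(n) {
  ranked_instance(paste0("g", seq_len(n)), scores = seq_len(n) / (n + 1))
}
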