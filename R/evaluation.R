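#' Hypergeometric enrichment of known therapies among significant hits
#'
#' Given a database of `N` compounds of which `K` are known therapies for
#' the disease under study, and a screen calling `n_sig` compounds
#' significant of which `k_hit` are known therapies, tests whether known
#' therapies are over-represented among the significant calls:
#' `p_hyper = P(X >= k_hit)` for `X ~ Hypergeometric(N, K, n_sig)`
#' (upper tail only). Also reports the expected hit count under the null,
#' `mu = n_sig * K / N`.
#'
#' @param N Database compound count.
#' @param K Known-therapy count within the database.
#' @param n_sig Number of compounds called significant.
#' @param k_hit Known therapies among the significant compounds.
#' @return A list of class `enrichment_check` with fields `N`, `K`,
#'   `n_sig`, `k_hit`, `p_hyper`, `mu`.
#' @export
hypergeometric_enrichment <- function(N, K, n_sig, k_hit) {
  N <- as.integer(N); K <- as.integer(K)
  n_sig <- as.integer(n_sig); k_hit <- as.integer(k_hit)
  if (anyNA(c(N, K, n_sig, k_hit))) stop("counts must be integers", call. = FALSE)
  if (N < 0L || K < 0L || n_sig < 0L || k_hit < 0L) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (K > N) stop("K must not exceed N", call. = FALSE)
  if (n_sig > N) stop("n_sig must not exceed N", call. = FALSE)
  if (k_hit > min(K, n_sig)) {
    stop("k_hit must not exceed min(K, n_sig)", call. = FALSE)
  }
  p <- stats::phyper(k_hit - 1L, K, N - K, n_sig, lower.tail = FALSE)
  structure(
    list(N = N, K = K, n_sig = n_sig, k_hit = k_hit,
         p_hyper = p, mu = n_sig * K / N),
    class = "enrichment_check"
  )
}

#' @export
print.enrichment_check <- function(x, ...) {
  cat(sprintf(
    "enrichment_check: %d/%d known therapies among %d significant of %d compounds\n",
    x$k_hit, x$K, x$n_sig, x$N))
  cat(sprintf("  expected hits mu = %.4g, upper-tail hypergeometric p = %.4g\n",
              x$mu, x$p_hyper))
  invisible(x)
}

#' Percentile rank of requested compounds in a screening result
#'
#' The percentile of a compound in the deterministically sorted result
#' table (ascending p, ties by descending KS then compound identifier):
#' `100 * rank / total`, rank 1-based. Small percentiles mean strong
#' candidates.
#'
#' @param results A `repo_results` data frame from [repo()] (already in
#'   its deterministic sort order).
#' @param compound_ids Character vector of compound identifiers to look
#'   up; every one must be present.
#' @return Named numeric vector of percentiles, in `compound_ids` order.
#' @export
percentile_rank <- function(results, compound_ids) {
  stopifnot(inherits(results, "data.frame"))
  compound_ids <- as.character(compound_ids)
  idx <- match(compound_ids, results$compound_id)
  if (anyNA(idx)) {
    stop(sprintf("compound not in results: '%s'",
                 compound_ids[which(is.na(idx))[1L]]), call. = FALSE)
  }
  stats::setNames(100 * idx / nrow(results), compound_ids)
}
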