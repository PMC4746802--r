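# Signed KS statistic from sorted 1-based signature positions V in an
# instance of n genes:
#   a = max_j [ j/t - V(j)/n ],  b = max_j [ V(j)/n - (j-1)/t ]
#   KS = a if a > b, else -b   (tie a == b gives -b)
# a >= 0 always (j = t term is 1 - V(t)/n >= 0) and b > 0 always
# (j = 1 term is V(1)/n > 0).
# Every term is a rational with denominator t*n, so the max and the a/b
# comparison are done on integer numerators: float rounding would
# otherwise mis-resolve exact ties (e.g. 1 - 7/10 vs 3/10).
.ks_core <- function(V, n) {
  t <- length(V)
  j <- seq_len(t)
  a_num <- max(j * n - V * t)
  b_num <- max(V * t - (j - 1) * n)
  d <- t * n
  list(a = a_num / d, b = b_num / d,
       value = if (a_num > b_num) a_num / d else -b_num / d)
}

.ks_stat <- function(V, n) {
  t <- length(V)
  j <- seq_len(t)
  a_num <- max(j * n - V * t)
  b_num <- max(V * t - (j - 1) * n)
  if (a_num > b_num) a_num / (t * n) else -b_num / (t * n)
}

#' Signed Kolmogorov-Smirnov enrichment score of a signature in an instance
#'
#' Compares the observed ranks of a signature's genes inside the ranked
#' instance against the uniform expectation. Let `n` be the instance size,
#' `t` the signature size and `V` the sorted 1-based positions of the
#' signature genes. Then
#' \deqn{a = \max_j (j/t - V(j)/n), \quad b = \max_j (V(j)/n - (j-1)/t)}
#' and `KS = a` if `a > b`, else `KS = -b` (an exact tie yields `-b`).
#' Signatures concentrated at top ranks score highly positive; unenriched
#' or inversely enriched signatures score near zero or negative. The
#' statistic depends only on rank positions, never on gene labels or the
#' underlying scores.
#'
#' @param instance A duplicate-free [ranked_instance()].
#' @param signature_genes Character vector of signature genes; must all be
#'   present in the instance (restrict the database first).
#' @return An object of class `ks_score`: list with `value`, `a`, `b`,
#'   `t`, `n`.
#' @export
ks_score <- function(instance, signature_genes) {
  stopifnot(inherits(instance, "ranked_instance"))
  signature_genes <- unique(as.character(signature_genes))
  if (length(signature_genes) == 0L) {
    stop("empty signature", call. = FALSE)
  }
  pos <- match(signature_genes, instance$genes)
  if (anyNA(pos)) {
    stop(sprintf("signature gene not in instance: '%s'",
                 signature_genes[which(is.na(pos))[1L]]), call. = FALSE)
  }
  V <- sort.int(pos)
  ks <- .ks_core(V, instance$n)
  structure(
    list(value = ks$value, a = ks$a, b = ks$b,
         t = length(V), n = instance$n),
    class = "ks_score"
  )
}

#' @export
print.ks_score <- function(x, ...) {
  cat(sprintf("ks_score: %.6g (a = %.6g, b = %.6g, t = %d, n = %d)\n",
              x$value, x$a, x$b, x$t, x$n))
  invisible(x)
}

# Deterministic per-length substream seed, kept inside 32-bit integer
# range. Each signature length draws its null from its own substream so
# results do not depend on the order lengths are processed.
.substream_seed <- function(seed, len) {
  v <- (as.numeric(seed) %% 2147483647) * 7919 + as.numeric(len) * 104729
  as.integer(v %% 2147483647)
}

# Evaluate expr with a temporarily seeded RNG, restoring global state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Length-stratified bootstrap null distributions of the KS score
#'
#' The signed KS statistic has no convenient closed-form null, so
#' significance is assessed empirically: for each unique signature length
#' \eqn{\ell}, draw `B` gene subsets of size \eqn{\ell} uniformly without
#' replacement from the instance and score each with the KS statistic.
#' One null is built per unique length and shared by every signature of
#' that length. Fully reproducible given `seed`; each length uses an
#' independently derived substream so results are order-independent.
#'
#' @param instance A duplicate-free [ranked_instance()].
#' @param lengths Integer vector of signature lengths (duplicates
#'   collapsed); each must lie in `[1, n]`.
#' @param B Number of resamples per length (default 10000).
#' @param seed Integer RNG seed (mandatory).
#' @return Named list (by length) of `ks_null` objects, each with fields
#'   `length`, `scores` (length `B`), `B` and `seed` (the derived
#'   substream seed).
#' @export
bootstrap_null <- function(instance, lengths, B = 10000L, seed) {
  stopifnot(inherits(instance, "ranked_instance"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be >= 1", call. = FALSE)
  lengths <- sort(unique(as.integer(lengths)))
  n <- instance$n
  if (any(lengths < 1L)) stop("signature length must be >= 1", call. = FALSE)
  if (any(lengths > n)) {
    stop(sprintf("signature length %d exceeds instance size %d",
                 max(lengths), n), call. = FALSE)
  }
  out <- lapply(lengths, function(len) {
    sub <- .substream_seed(seed, len)
    scores <- .with_seed(sub, {
      vapply(seq_len(B),
             function(i) .ks_stat(sort.int(sample.int(n, len)), n),
             numeric(1L))
    })
    structure(list(length = len, scores = scores, B = B, seed = sub),
              class = "ks_null")
  })
  stats::setNames(out, as.character(lengths))
}

#' @export
print.ks_null <- function(x, ...) {
  cat(sprintf("ks_null: length %d, B = %d resamples, seed %d\n",
              x$length, x$B, x$seed))
  invisible(x)
}

#' Empirical bootstrap p-value for an observed KS score
#'
#' The p-value is the proportion of resampled KS scores that strictly
#' exceed the observed score (one-sided: only top-rank enrichment is
#' tested; inversely enriched signatures get p near 1). With
#' `add_one = TRUE` the standard never-zero estimator
#' `(count + 1) / (B + 1)` is used instead.
#'
#' @param observed A [ks_score()] object.
#' @param null A `ks_null` from [bootstrap_null()] with
#'   `null$length == observed$t`.
#' @param add_one Use the add-one estimator (default `FALSE`).
#' @return A p-value in `[0, 1]`.
#' @export
empirical_p <- function(observed, null, add_one = FALSE) {
  stopifnot(inherits(observed, "ks_score"), inherits(null, "ks_null"))
  if (null$length != observed$t) {
    stop(sprintf("null length %d does not match signature overlap %d",
                 null$length, observed$t), call. = FALSE)
  }
  cnt <- sum(null$scores > observed$value)
  if (add_one) (cnt + 1) / (null$B + 1) else cnt / null$B
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the expected false-discovery
#' proportion across all scored compounds, clipped to 1, returned in
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0L))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Score a full signature database against a ranked instance
#'
#' The end-to-end driver: restrict the database to the instance, compute
#' each signature's signed KS enrichment score, build one bootstrap null
#' per unique overlap size, assign empirical p-values, FDR-adjust across
#' all signatures, and return results sorted by ascending p (ties broken
#' by descending KS, then compound identifier). Removed signatures are
#' reported via message, never silently dropped: result rows plus dropped
#' signatures always account for every database compound.
#'
#' @param instance A duplicate-free [ranked_instance()].
#' @param db A [signature_db()].
#' @param B Bootstrap resamples per unique length (default 10000).
#' @param seed Integer RNG seed (mandatory).
#' @param min_overlap Minimum instance overlap to score a signature
#'   (default 1).
#' @param add_one Use add-one p-value estimator (default `FALSE`).
#' @return A data frame of class `repo_results` with columns
#'   `compound_id`, `compound_name`, `t`, `ks`, `p_value`, `fdr`; run
#'   parameters and the dropped-signature count are attached as the
#'   `"meta"` attribute.
#' @export
repo <- function(instance, db, B = 10000L, seed, min_overlap = 1L,
                 add_one = FALSE) {
  stopifnot(inherits(instance, "ranked_instance"), inherits(db, "signature_db"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  rdb <- restrict_to_instance(db, instance, min_overlap = min_overlap)
  ids <- names(rdb$sets)
  pos_of <- stats::setNames(seq_len(instance$n), instance$genes)
  ks_obj <- lapply(rdb$sets, function(g) {
    V <- sort.int(unname(pos_of[g]))
    ks <- .ks_core(V, instance$n)
    structure(list(value = ks$value, a = ks$a, b = ks$b, t = length(V),
                   n = instance$n),
              class = "ks_score")
  })
  t <- vapply(ks_obj, `[[`, integer(1L), "t")
  nulls <- bootstrap_null(instance, unique(t), B = B, seed = seed)
  p <- vapply(seq_along(ks_obj), function(i) {
    empirical_p(ks_obj[[i]], nulls[[as.character(t[i])]], add_one = add_one)
  }, numeric(1L))
  q <- fdr_adjust(p)
  res <- data.frame(
    compound_id = ids,
    compound_name = if (is.null(rdb$display)) ids else {
      nm <- unname(rdb$display[ids]); nm[is.na(nm)] <- ids[is.na(nm)]; nm
    },
    t = unname(t),
    ks = vapply(ks_obj, `[[`, numeric(1L), "value"),
    p_value = p,
    fdr = q,
    stringsAsFactors = FALSE
  )
  ord <- order(res$p_value, -res$ks, res$compound_id, method = "radix")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "meta") <- list(
    B = as.integer(B), seed = as.integer(seed),
    min_overlap = as.integer(min_overlap), add_one = add_one,
    n_input = n_compounds(db),
    n_dropped = attr(rdb, "n_dropped"),
    instance_n = instance$n
  )
  class(res) <- c("repo_results", "data.frame")
  res
}

#' Write a compound-screening result table and its metadata sidecar
#'
#' Writes a TSV with header
#' `compound_id  compound_name  t  ks  p_value  fdr` (floats at 6
#' significant digits) plus a JSON sidecar (`<path>.meta.json`) recording
#' the run parameters, dropped-signature count and MD5 digests of the
#' input files, so any run is reconstructible from its sidecar alone.
#'
#' @param results A `repo_results` data frame from [repo()].
#' @param path Output TSV path.
#' @param inputs Optional named character vector of input file paths to
#'   digest (e.g. `c(instance = ..., db = ...)`).
#' @return `path`, invisibly.
#' @export
write_repo_results <- function(results, path, inputs = NULL) {
  stopifnot(inherits(results, "repo_results"))
  out <- as.data.frame(results)
  for (col in c("ks", "p_value", "fdr")) {
    out[[col]] <- formatC(out[[col]], digits = 6, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- attr(results, "meta")
  if (!is.null(inputs)) {
    digests <- tools::md5sum(inputs)
    meta$input_digests <- as.list(stats::setNames(unname(digests),
                                                  names(inputs)))
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a result table written by [write_repo_results()]
#'
#' @param path Path to the result TSV.
#' @return A `repo_results` data frame (metadata sidecar, if present,
#'   attached as the `"meta"` attribute).
#' @export
read_repo_results <- function(path) {
  res <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(compound_id = "character",
                                          compound_name = "character"))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    attr(res, "meta") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  class(res) <- c("repo_results", "data.frame")
  res
}
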