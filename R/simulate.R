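#' Generate a synthetic ranked instance
#'
#' Produces `n` synthetic gene identifiers (`G000001`, `G000002`, ...) in
#' a seeded random order with pseudo-scores increasing along the ranking
#' (p-value-like: rank 1 carries the smallest score). Only the rank
#' structure matters to the KS method, so no expression values are
#' simulated.
#'
#' @param n Number of genes (>= 1).
#' @param seed Integer RNG seed.
#' @return A [ranked_instance()] with scores.
#' @export
make_instance <- function(n, seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  .with_seed(.substream_seed(seed, 1L), {
    ids <- sprintf("G%06d", sample.int(n))
    scores <- sort(stats::runif(n))
    ranked_instance(ids, scores)
  })
}

#' Plant an enriched signature at controlled rank positions
#'
#' Draws `t` signature ranks without replacement with weights
#' proportional to the Beta(1, `concentration`) density evaluated at the
#' rank midpoints `(i - 0.5)/n`. `concentration = 1` recovers the uniform
#' null exactly; large values concentrate the signature near rank 1,
#' emulating a compound whose interacting genes are highly differentially
#' expressed. A single interpretable strength knob with the null as a
#' special case.
#'
#' @param instance A [ranked_instance()].
#' @param t Signature size (1 <= t <= n).
#' @param concentration Positive real; enrichment strength.
#' @param seed Integer RNG seed.
#' @return A list with `genes` (character, the signature) and `ranks`
#'   (sorted 1-based positions in the instance).
#' @export
plant_signature <- function(instance, t, concentration = 1, seed) {
  stopifnot(inherits(instance, "ranked_instance"))
  t <- as.integer(t)
  n <- instance$n
  if (is.na(t) || t < 1L) stop("t must be >= 1", call. = FALSE)
  if (t > n) stop("t must not exceed instance size", call. = FALSE)
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be > 0", call. = FALSE)
  }
  .with_seed(.substream_seed(seed, 2L), {
    w <- stats::dbeta((seq_len(n) - 0.5) / n, 1, concentration)
    ranks <- sort.int(sample.int(n, t, prob = w))
    list(genes = instance$genes[ranks], ranks = ranks)
  })
}

#' Generate a null signature database over an instance
#'
#' `m` signatures of uniformly random instance genes, with lengths drawn
#' uniformly (with replacement) from `length_pool`; a constant length is
#' a pool of size one, and repeating values in the pool weights them, so
#' any discrete length law can be expressed. Every generated gene set is
#' a subset of the instance, so [restrict_to_instance()] is the identity
#' on the result.
#'
#' @param instance A [ranked_instance()].
#' @param m Number of signatures (>= 1).
#' @param length_pool Integer vector of candidate signature lengths; all
#'   must lie in `[1, n]`.
#' @param seed Integer RNG seed.
#' @param prefix Compound-identifier prefix (default `"null"`).
#' @return A [signature_db()].
#' @export
make_null_db <- function(instance, m, length_pool = 5:50, seed,
                         prefix = "null") {
  stopifnot(inherits(instance, "ranked_instance"))
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1", call. = FALSE)
  length_pool <- as.integer(length_pool)
  n <- instance$n
  if (any(is.na(length_pool)) || any(length_pool < 1L) ||
      any(length_pool > n)) {
    stop(sprintf("length_pool must lie in [1, %d]", n), call. = FALSE)
  }
  .with_seed(.substream_seed(seed, 3L), {
    lens <- length_pool[sample.int(length(length_pool), m, replace = TRUE)]
    sets <- lapply(lens, function(len) instance$genes[sample.int(n, len)])
    names(sets) <- sprintf("%s_%04d", prefix, seq_len(m))
    signature_db(sets, source = "synthetic:null")
  })
}

#' Simulate a full compound screen with planted ground truth
#'
#' Builds a synthetic instance plus a signature database containing
#' `planted` enriched signatures (via [plant_signature()]) among
#' `m - planted` uniformly random ones, and optionally writes the ranked
#' list, the GMT and a JSON ground-truth manifest to `out_dir` so the
#' command-line and library paths share test inputs.
#'
#' @param n Instance size (default 2000 genes).
#' @param m Total signature count (default 100).
#' @param planted Number of enriched signatures (default 1; must not
#'   exceed `m`).
#' @param concentration Enrichment strength for planted signatures
#'   (default 50; see [plant_signature()]).
#' @param t_planted Planted signature size (default 20).
#' @param length_pool Length pool for the null signatures
#'   (default `5:50`).
#' @param seed Integer RNG seed.
#' @param out_dir Optional directory to write `instance.tsv`,
#'   `signatures.gmt` and `manifest.json` into (created if needed).
#' @return A list with `instance`, `db`, `planted_ids` and (when written)
#'   `paths`.
#' @export
simulate_screen <- function(n = 2000L, m = 100L, planted = 1L,
                            concentration = 50, t_planted = 20L,
                            length_pool = 5:50, seed, out_dir = NULL) {
  planted <- as.integer(planted)
  m <- as.integer(m)
  if (is.na(planted) || planted < 0L) stop("planted must be >= 0", call. = FALSE)
  if (planted > m) stop("planted must not exceed m", call. = FALSE)
  instance <- make_instance(n, seed)
  sets <- list()
  planted_ids <- character(0L)
  if (planted > 0L) {
    planted_ids <- sprintf("planted_%03d", seq_len(planted))
    sets <- lapply(seq_len(planted), function(i) {
      plant_signature(instance, t_planted, concentration,
                      seed = .substream_seed(seed, 100L + i))$genes
    })
    names(sets) <- planted_ids
  }
  if (m - planted > 0L) {
    null_db <- make_null_db(instance, m - planted, length_pool, seed)
    sets <- c(sets, null_db$sets)
  }
  db <- signature_db(sets, source = "synthetic:screen")
  out <- list(instance = instance, db = db, planted_ids = planted_ids)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      instance = file.path(out_dir, "instance.tsv"),
      db = file.path(out_dir, "signatures.gmt"),
      manifest = file.path(out_dir, "manifest.json")
    )
    write_ranked_list(instance, paths$instance)
    write_gmt(db, paths$db)
    jsonlite::write_json(
      list(n = instance$n, m = m, planted = planted_ids,
           concentration = concentration, t_planted = as.integer(t_planted),
           seed = as.integer(seed)),
      paths$manifest, auto_unbox = TRUE, pretty = TRUE)
    out$paths <- paths
  }
  out
}
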