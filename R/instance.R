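#' Construct a ranked instance
#'
#' A ranked instance is the complete ordered gene list from one case/control
#' expression study: every gene, ordered by strength of differential
#' expression (rank 1 = most differentially expressed). It is the query
#' object scored against a signature database.
#'
#' @param genes Character vector of gene identifiers, in rank order.
#' @param scores Optional numeric vector of ranking scores parallel to
#'   `genes` (dimensionless; by convention smaller = more differentially
#'   expressed, as for p-values).
#' @param .allow_duplicates Internal: permit duplicate identifiers in the
#'   not-yet-collapsed stages of the ingest pipeline.
#' @return An object of class `ranked_instance` with fields `genes`,
#'   `scores` (or `NULL`) and `n`.
#' @seealso [read_ranked_list()], [collapse_duplicates()]
#' @export
ranked_instance <- function(genes, scores = NULL, .allow_duplicates = FALSE) {
  genes <- as.character(genes)
  if (length(genes) < 1L) {
    stop("empty instance", call. = FALSE)
  }
  if (!.allow_duplicates && anyDuplicated(genes)) {
    stop("duplicate gene identifiers in instance; run collapse_duplicates() first",
         call. = FALSE)
  }
  if (!is.null(scores)) {
    scores <- as.numeric(scores)
    if (length(scores) != length(genes)) {
      stop("genes and scores must have equal length", call. = FALSE)
    }
  }
  structure(
    list(genes = genes, scores = scores, n = length(genes)),
    class = "ranked_instance"
  )
}

#' @export
print.ranked_instance <- function(x, ...) {
  cat(sprintf("ranked_instance: %d genes\n", x$n))
  k <- min(5L, x$n)
  head_ids <- paste(x$genes[seq_len(k)], collapse = ", ")
  cat(sprintf("  top ranks: %s%s\n", head_ids, if (x$n > k) ", ..." else ""))
  cat(sprintf("  scores: %s\n", if (is.null(x$scores)) "absent" else "present"))
  invisible(x)
}

#' @export
as.data.frame.ranked_instance <- function(x, ...) {
  df <- data.frame(gene_id = x$genes, stringsAsFactors = FALSE)
  if (!is.null(x$scores)) df$score <- x$scores
  df
}

#' Read a ranked gene list from a delimited file
#'
#' Accepts the two-column output of differential-expression tools such as
#' GEO2R (gene identifier, ranking score) or a one-column pre-ordered list.
#' With a score column, rows are sorted ascending by score (smaller = more
#' differentially expressed; see `descending`), stably so that ties keep
#' file order. Without one, file order is the ranking.
#'
#' The returned instance may still contain duplicate identifiers (e.g. one
#' row per microarray probe); pass it through [map_to_entrez()] and
#' [collapse_duplicates()] before scoring, or use [prepare_instance()].
#'
#' @param path Path to a delimited text file with 1 or 2 columns.
#' @param has_header Logical; does the first line name the columns?
#' @param delimiter Field separator (default tab).
#' @param descending Logical; if `TRUE`, larger scores rank first
#'   (for effect-size-like scores such as |t|).
#' @return A [ranked_instance()] (duplicates permitted at this stage).
#' @export
read_ranked_list <- function(path, has_header = FALSE, delimiter = "\t",
                             descending = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("ranked-list file not found: %s", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.delim(path, header = has_header, sep = delimiter,
                      colClasses = "character", stringsAsFactors = FALSE,
                      quote = "", comment.char = ""),
    error = function(e) stop("empty instance", call. = FALSE)
  )
  if (nrow(df) == 0L) stop("empty instance", call. = FALSE)
  if (ncol(df) < 1L || ncol(df) > 2L) {
    stop(sprintf("expected 1 or 2 columns, found %d", ncol(df)), call. = FALSE)
  }
  genes <- trimws(df[[1L]])
  if (ncol(df) == 1L) {
    return(ranked_instance(genes, .allow_duplicates = TRUE))
  }
  raw_scores <- trimws(df[[2L]])
  scores <- suppressWarnings(as.numeric(raw_scores))
  if (anyNA(scores)) {
    i <- which(is.na(scores))[1L]
    stop(sprintf("non-numeric score at row %d: '%s'",
                 i + as.integer(has_header), raw_scores[i]), call. = FALSE)
  }
  ord <- order(scores, decreasing = descending, method = "radix")
  ranked_instance(genes[ord], scores[ord], .allow_duplicates = TRUE)
}

#' Write a ranked instance to a delimited file
#'
#' Inverse of [read_ranked_list()]: writes `gene_id` (and `score` when
#' present) as tab-separated text without a header, in rank order.
#'
#' @param instance A [ranked_instance()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(instance, path) {
  stopifnot(inherits(instance, "ranked_instance"))
  df <- as.data.frame(instance)
  if (!is.null(instance$scores)) {
    df$score <- format(df$score, digits = 15, scientific = FALSE, trim = TRUE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an alias-to-identifier mapping table
#'
#' Two-column delimited text, `alias<TAB>target_id`, no header required.
#' Each alias must map to exactly one target; exact duplicate rows are
#' tolerated, conflicting ones are an error.
#'
#' @param path Path to the mapping file.
#' @param delimiter Field separator (default tab).
#' @param has_header Logical; skip a header line?
#' @return A named character vector: `names()` are aliases, values targets.
#' @export
read_alias_map <- function(path, delimiter = "\t", has_header = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("alias map file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = has_header, sep = delimiter,
                          colClasses = "character", stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("alias map must have two columns", call. = FALSE)
  alias <- trimws(df[[1L]])
  target <- trimws(df[[2L]])
  dup <- duplicated(paste0(alias, "\r", target))
  alias <- alias[!dup]; target <- target[!dup]
  if (anyDuplicated(alias)) {
    bad <- alias[duplicated(alias)][1L]
    stop(sprintf("alias '%s' maps to more than one target", bad), call. = FALSE)
  }
  if (length(alias) == 0L) stop("empty alias map", call. = FALSE)
  stats::setNames(target, alias)
}

#' Map instance gene aliases to a common identifier system
#'
#' Translates each identifier through a many-to-one alias map (typically
#' alias -> Entrez Gene ID, so that instance and signature database share
#' one identifier system). Aliases absent from the map are dropped and
#' counted in a message; input order is preserved.
#'
#' @param instance A [ranked_instance()] (duplicates permitted).
#' @param mapping Named character vector as from [read_alias_map()].
#' @return A [ranked_instance()] over the mapped identifiers (duplicates
#'   permitted: distinct aliases may share a target).
#' @export
map_to_entrez <- function(instance, mapping) {
  stopifnot(inherits(instance, "ranked_instance"))
  if (length(mapping) == 0L) stop("empty alias map", call. = FALSE)
  if (is.null(names(mapping))) stop("alias map must be named", call. = FALSE)
  hit <- instance$genes %in% names(mapping)
  n_dropped <- sum(!hit)
  if (!any(hit)) stop("no genes mapped", call. = FALSE)
  if (n_dropped > 0L) {
    message(sprintf("map_to_entrez: dropped %d unmapped alias%s of %d",
                    n_dropped, if (n_dropped == 1L) "" else "es", instance$n))
  }
  ranked_instance(
    unname(mapping[instance$genes[hit]]),
    if (is.null(instance$scores)) NULL else instance$scores[hit],
    .allow_duplicates = TRUE
  )
}

#' Collapse duplicate identifiers to their best-ranked occurrence
#'
#' Microarray inputs map many probes to one gene; after identifier mapping
#' a gene can therefore occur several times. Each identifier is reduced to
#' its best-ranked occurrence (smallest score when scores are present,
#' otherwise earliest position), and retained entries keep their rank
#' order. Idempotent on already-clean input.
#'
#' @param instance A [ranked_instance()] possibly containing duplicates.
#' @return A duplicate-free [ranked_instance()].
#' @export
collapse_duplicates <- function(instance) {
  stopifnot(inherits(instance, "ranked_instance"))
  g <- instance$genes
  s <- instance$scores
  if (is.null(s)) {
    keep <- !duplicated(g)
    return(ranked_instance(g[keep], NULL))
  }
  # best occurrence per gene = smallest score, earliest position on ties;
  # walking in (score, position) order and keeping first sightings yields
  # the winners already in rank order
  ord <- order(s, seq_along(s), method = "radix")
  keep <- ord[!duplicated(g[ord])]
  ranked_instance(g[keep], s[keep])
}

#' Read, map and collapse an instance in one call
#'
#' Convenience wrapper for the full ingest pipeline:
#' [read_ranked_list()] then optionally [map_to_entrez()] then
#' [collapse_duplicates()].
#'
#' @inheritParams read_ranked_list
#' @param mapping_path Optional path to an alias-map file
#'   (see [read_alias_map()]).
#' @return A duplicate-free [ranked_instance()].
#' @export
prepare_instance <- function(path, mapping_path = NULL, has_header = FALSE,
                             delimiter = "\t", descending = FALSE) {
  inst <- read_ranked_list(path, has_header = has_header,
                           delimiter = delimiter, descending = descending)
  if (!is.null(mapping_path)) {
    inst <- map_to_entrez(inst, read_alias_map(mapping_path))
  }
  collapse_duplicates(inst)
}
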