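#' Construct a compound-gene signature database
#'
#' A signature is an unordered, directionless set of genes known to
#' interact with one compound; a signature database is a collection of
#' them, the unit scored against a ranked instance.
#'
#' @param sets Named list of character vectors; names are compound
#'   identifiers (unique), elements are gene-identifier sets. Duplicate
#'   genes within a set are removed silently.
#' @param display Optional named character vector of human-readable
#'   compound names, indexed by compound identifier.
#' @param source Provenance string (e.g. file path or "CTD dump v...").
#' @param t Optional named integer vector of per-signature overlap sizes;
#'   set by [restrict_to_instance()], `NULL` before restriction.
#' @return An object of class `signature_db`.
#' @export
signature_db <- function(sets, display = NULL, source = "user", t = NULL) {
  if (!is.list(sets) || length(sets) == 0L) {
    stop("signature database is empty", call. = FALSE)
  }
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every signature needs a compound identifier", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate compound identifier: '%s'",
                 ids[duplicated(ids)][1L]), call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    stop("signature with empty gene set", call. = FALSE)
  }
  if (!is.null(display)) display <- display[ids]
  structure(
    list(sets = sets, display = display, source = source, t = t),
    class = "signature_db"
  )
}

#' @export
print.signature_db <- function(x, ...) {
  cat(sprintf("signature_db: %d compounds, %d unique genes (source: %s)\n",
              n_compounds(x), n_genes(x), x$source))
  if (!is.null(x$t)) {
    cat(sprintf("  restricted to instance; overlap t in [%d, %d]\n",
                min(x$t), max(x$t)))
  }
  invisible(x)
}

#' Number of compounds in a signature database
#' @param db A [signature_db()].
#' @return Integer count.
#' @export
n_compounds <- function(db) length(db$sets)

#' Number of unique genes across all signatures
#' @param db A [signature_db()].
#' @return Integer count.
#' @export
n_genes <- function(db) length(unique(unlist(db$sets, use.names = FALSE)))

#' Read a GMT gene-set file as a signature database
#'
#' Broad-style GMT: one signature per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The name field is taken
#' as the compound identifier, the description as the display name.
#' Duplicate genes within a line are deduplicated with a warning;
#' duplicate signature names are an error.
#'
#' @param path Path to a GMT file (gzip-transparent).
#' @return A [signature_db()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("GMT file not found: %s", path), call. = FALSE)
  }
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("signature database is empty", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields",
                 short[1L]), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate compound identifier in GMT: '%s'",
                 ids[duplicated(ids)][1L]), call. = FALSE)
  }
  desc <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- vapply(sets, function(g) length(g) - length(unique(g)), integer(1L))
  if (any(ndup > 0L)) {
    warning(sprintf("deduplicated genes within %d signature(s): %s",
                    sum(ndup > 0L),
                    paste(ids[ndup > 0L][seq_len(min(3L, sum(ndup > 0L)))],
                          collapse = ", ")),
            call. = FALSE)
  }
  signature_db(stats::setNames(sets, ids),
               display = stats::setNames(desc, ids),
               source = path)
}

#' Write a signature database as a GMT file
#'
#' Genes within each signature are written in a stable sorted order so
#' identical databases always produce byte-identical files;
#' `read_gmt(write_gmt(db))` reproduces the compound-to-gene-set mapping
#' exactly.
#'
#' @param db A [signature_db()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "signature_db"))
  if (n_compounds(db) == 0L) stop("signature database is empty", call. = FALSE)
  ids <- names(db$sets)
  desc <- if (is.null(db$display)) rep(db$source, length(ids)) else db$display
  desc[is.na(desc) | !nzchar(desc)] <- "na"
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], desc[i], sort(db$sets[[i]], method = "radix")),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a raw CTD chemical-gene interaction dump to a signature database
#'
#' The Comparative Toxicogenomics Database distributes expert-curated,
#' literature-supported chemical-gene interactions as a tab-delimited dump
#' with a `#` comment header block. This converter keeps rows matching the
#' requested organism (default human, taxon 9606) and, when
#' `require_evidence`, having a nonempty PubMed field, then groups kept
#' rows by chemical into signatures over the union of their gene
#' identifiers. Interaction directionality is deliberately ignored: the
#' method scores interaction membership only, so databases without (or
#' with conflicting) regulatory direction remain usable. Gene forms for
#' gene products (transcripts, proteins, peptides) are retained.
#'
#' Columns are resolved by header names (`ChemicalName`, `ChemicalID`,
#' `GeneID`, `OrganismID`, `PubMedIDs`); the header line may be a plain
#' first row or live inside the comment block, as in the public
#' `chem_gene_ixns` files. The MeSH `ChemicalID` is used as the compound
#' identifier and `ChemicalName` kept as display name.
#'
#' @param path Path to the dump (gzip-transparent).
#' @param organism_id Taxon identifier to keep (string or number;
#'   default `"9606"`).
#' @param require_evidence Keep only rows with a nonempty PubMed field
#'   (default `TRUE`).
#' @return A [signature_db()].
#' @export
convert_ctd <- function(path, organism_id = "9606", require_evidence = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("CTD file not found: %s", path), call. = FALSE)
  }
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  is_comment <- startsWith(lines, "#")
  required <- c("ChemicalName", "ChemicalID", "GeneID", "OrganismID",
                "PubMedIDs")
  header_line <- NULL
  data_lines <- lines[!is_comment]
  if (length(data_lines) > 0L &&
      all(c("ChemicalID", "GeneID") %in%
          strsplit(data_lines[1L], "\t", fixed = TRUE)[[1L]])) {
    header_line <- data_lines[1L]
    data_lines <- data_lines[-1L]
  } else {
    # public dumps carry the field list inside the comment block
    cand <- grep("ChemicalName", lines[is_comment], value = TRUE)
    if (length(cand) > 0L) {
      header_line <- sub("^#\\s*", "", cand[length(cand)])
    }
  }
  if (is.null(header_line)) {
    stop("required column 'ChemicalName' absent: no header found", call. = FALSE)
  }
  cols <- strsplit(header_line, "\t", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(required, cols)
  if (length(missing_cols) > 0L) {
    stop(sprintf("required column '%s' absent from CTD file",
                 missing_cols[1L]), call. = FALSE)
  }
  if (length(data_lines) == 0L) {
    stop("no interaction rows survive filtering", call. = FALSE)
  }
  df <- utils::read.delim(text = data_lines, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < length(cols)) {
    # ragged trailing fields; pad names to observed width
    cols <- cols[seq_len(ncol(df))]
  }
  names(df)[seq_along(cols)] <- cols
  keep <- df[["OrganismID"]] == as.character(organism_id)
  if (require_evidence) {
    keep <- keep & nzchar(trimws(df[["PubMedIDs"]]))
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no interaction rows survive filtering", call. = FALSE)
  }
  sets <- split(df[["GeneID"]], df[["ChemicalID"]])
  sets <- lapply(sets, unique)
  disp <- df[["ChemicalName"]][!duplicated(df[["ChemicalID"]])]
  names(disp) <- df[["ChemicalID"]][!duplicated(df[["ChemicalID"]])]
  message(sprintf(
    "convert_ctd: kept %d rows -> %d compounds, %d unique genes",
    nrow(df), length(sets), length(unique(df[["GeneID"]]))))
  signature_db(sets, display = disp,
               source = sprintf("CTD:%s", path))
}

#' Restrict a signature database to the genes of an instance
#'
#' Intersects every signature with the instance gene universe and records
#' the overlap size `t`; signatures overlapping fewer than `min_overlap`
#' genes are removed and counted in a message (never silently). All
#' instance genes participate regardless of significance, so that even
#' short signatures retain overlap. Idempotent.
#'
#' @param db A [signature_db()].
#' @param instance A duplicate-free [ranked_instance()].
#' @param min_overlap Minimum overlap size to keep a signature
#'   (default 1).
#' @return A restricted [signature_db()] with `t` set; the number of
#'   removed signatures is available as `attr(, "n_dropped")`.
#' @export
restrict_to_instance <- function(db, instance, min_overlap = 1L) {
  stopifnot(inherits(db, "signature_db"), inherits(instance, "ranked_instance"))
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)
  if (anyDuplicated(instance$genes)) {
    stop("instance contains duplicates; run collapse_duplicates() first",
         call. = FALSE)
  }
  sets <- lapply(db$sets, function(g) g[g %in% instance$genes])
  t <- lengths(sets)
  keep <- t >= min_overlap
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no signature overlaps instance", call. = FALSE)
  if (n_dropped > 0L) {
    message(sprintf(
      "restrict_to_instance: removed %d of %d signatures with overlap < %d",
      n_dropped, length(keep), min_overlap))
  }
  out <- signature_db(sets[keep],
                      display = if (is.null(db$display)) NULL else
                        db$display[names(sets)[keep]],
                      source = db$source,
                      t = t[keep])
  attr(out, "n_dropped") <- n_dropped
  out
}
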