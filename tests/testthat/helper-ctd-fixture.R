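# Small synthetic CTD-style dump built from an explicit row table, so
# tests can filter/group the rows independently of convert_ctd().
make_ctd_rows <- function(seed = 11) {
  set.seed(seed)
  chems <- sprintf("D%03d", 1:8)
  do.call(rbind, lapply(1:50, function(i) {
    ci <- sample(8, 1)
    data.frame(
      ChemicalName = paste0("chem", substr(chems[ci], 2, 4)),
      ChemicalID = chems[ci],
      GeneSymbol = paste0("SYM", sample(30, 1)),
      GeneID = as.character(sample(30, 1)),
      Organism = "x",
      OrganismID = sample(c("9606", "10090"), 1, prob = c(0.7, 0.3)),
      Interaction = "increases expression",
      InteractionActions = "increases^expression",
      PubMedIDs = sample(c("123456", ""), 1, prob = c(0.8, 0.2)),
      GeneForms = sample(c("gene", "protein", "mRNA"), 1),
      stringsAsFactors = FALSE
    )
  }))
}

write_ctd_dump <- function(rows, header_in_comments = FALSE) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  cols <- names(rows)
  body <- apply(rows, 1, paste, collapse = "\t")
  if (header_in_comments) {
    lines <- c("# chemical-gene interactions (synthetic fixture)",
               "# Fields:",
               paste0("# ", paste(cols, collapse = "\t")),
               body)
  } else {
    lines <- c("# synthetic fixture", paste(cols, collapse = "\t"), body)
  }
  writeLines(lines, path)
  path
}
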