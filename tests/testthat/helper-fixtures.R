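# Shared helpers: tiny in-code fixtures for IO and filtering tests.

tiny_counts <- function(marker = "rbcL") {
  m <- matrix(c(10L, 0L, 5L, 5L), 2, 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"),
                              c("Fabaceae;Robinia;Robinia_pseudoacacia",
                                "Rosaceae;Prunus")))
  count_table(m, marker)
}

write_hit_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

hit_line <- function(otu, lineage, bitscore, extra = NULL) {
  fields <- c(otu, "acc1", "99.1", "500", "2", "0", "1", "500", "1", "500",
              "1e-120", as.character(bitscore), lineage, extra)
  paste(fields, collapse = "\t")
}

# Minimal hit-table data frame for assign_taxon tests.
hits_df <- function(lineages, bitscores, read_count = 1) {
  if (length(lineages) == 0L) {
    return(nestbarcode:::empty_hit_table())
  }
  labels <- lapply(lineages, parse_taxon)
  df <- data.frame(otu_id = "otu1", subject = "acc", pident = 99,
                   bitscore = bitscores, lineage = lineages,
                   stringsAsFactors = FALSE)
  cbind(df, nestbarcode:::taxa_frame(labels)[c("family", "genus", "species")],
        read_count = read_count)
}
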