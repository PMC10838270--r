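#' Bundled seven-mixture bark mock-community reference table
#'
#' The package ships the published reference table of seven artificial bark
#' mixtures assembled from nine woody species (one per family), together
#' with the read proportions each mixture yielded for the rbcL and trnL
#' markers and their median (two-marker) consensus. Values are stored as
#' printed (three decimals); cells printed with a `(0)` removal mark carry
#' `removed = TRUE`. Taxa identified to different ranks by the two markers
#' (e.g. family Fabaceae by trnL where rbcL resolves Robinia pseudoacacia)
#' are aligned on their consensus label, so the three proportion tables
#' share identical axes: 7 samples by 9 consensus taxa. Cells for taxa not
#' part of a mixture's design are `NA`.
#'
#' @return A list with elements:
#' \describe{
#'   \item{design}{[mixture_design()] of true proportions, 31 cells.}
#'   \item{rbcl, trnl, median}{[proportion_table()]s as printed.}
#'   \item{labels}{Data frame recording, per (sample, consensus taxon), the
#'     marker-specific identifications as printed (`trnl_id`, `rbcl_id`,
#'     `median_id`), e.g. `"Fabaceae"`, `"Anacardiaceae"`, `"Prunus mume"`.}
#' }
#' @examples
#' fx <- load_table1_fixture()
#' fx$median$values["PC1", "Robinia pseudoacacia"]  # 0.886
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_bark_mixtures.tsv",
                      package = "nestbarcode", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)

  design_labels <- lapply(df$design_taxon, parse_taxon)
  dd <- taxa_frame(design_labels)
  design <- suppressWarnings(mixture_design(data.frame(
    sample = df$sample, family = dd$family, genus = dd$genus,
    species = dd$species, true = df$true_proportion,
    stringsAsFactors = FALSE
  )))

  cons_labels <- lapply(unique(df$consensus_taxon), parse_taxon)
  cons_names <- vapply(cons_labels, function(t) t$name, character(1))
  samples <- unique(df$sample)

  build <- function(value_col, removed_col, marker) {
    v <- matrix(NA_real_, length(samples), length(cons_names),
                dimnames = list(samples, cons_names))
    r <- matrix(FALSE, length(samples), length(cons_names),
                dimnames = list(samples, cons_names))
    idx <- cbind(match(df$sample, samples),
                 match(df$consensus_taxon, unique(df$consensus_taxon)))
    v[idx] <- df[[value_col]]
    r[idx] <- df[[removed_col]] == 1
    proportion_table(v, marker, removed = r, taxa = cons_labels)
  }

  list(
    design = design,
    rbcl = build("rbcl_proportion", "rbcl_removed", "rbcL"),
    trnl = build("trnl_proportion", "trnl_removed", "trnL"),
    median = build("median_proportion", "median_removed", "median"),
    labels = df[c("sample", "consensus_taxon", "trnl_id", "rbcl_id",
                  "median_id")]
  )
}
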