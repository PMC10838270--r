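#' Read a per-marker count table from TSV
#'
#' Expects a tab-separated file whose header row names the taxa (either bare
#' names or `Family;Genus;Genus_species` lineages, see [parse_taxon()]) and
#' whose first column holds sample ids.
#'
#' @param path File path.
#' @param marker `"rbcL"` or `"trnL"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, marker = c("rbcL", "trnL")) {
  marker <- match.arg(marker)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop(sprintf("%s: need a sample column plus at least one taxon column",
                 path), call. = FALSE)
  }
  samples <- as.character(df[[1]])
  dup <- samples[duplicated(samples)]
  if (length(dup)) {
    stop(sprintf("%s: duplicate sample id(s): %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) {
    stop(sprintf("%s: non-numeric count cells", path), call. = FALSE)
  }
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s: negative count at sample '%s', taxon '%s'", path,
                 samples[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  rownames(m) <- samples
  taxa <- lapply(colnames(m), function(nm) {
    tryCatch(parse_taxon(nm), error = function(e) {
      stop(sprintf("%s: malformed taxon header '%s'", path, nm),
           call. = FALSE)
    })
  })
  colnames(m) <- vapply(taxa, function(t) t$name, character(1))
  count_table(m, marker, taxa)
}

#' Write a count table to TSV
#'
#' Column headers are full lineage strings so that reading the file back
#' reproduces the taxa exactly.
#'
#' @param x A `count_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  hdr <- vapply(x$taxa, taxon_string, character(1))
  df <- data.frame(sample = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample", hdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a proportion table
#'
#' Proportion tables are stored as TSV with the same layout as count tables;
#' removed cells are written as `value(0)` (the removal-flag convention used
#' in printed mock-community tables) and absent cells as `NA`. Values are
#' written with full precision so a write/read round trip reproduces them to
#' better than 1e-12.
#'
#' @param x A `proportion_table`.
#' @param path File path.
#' @param marker `"rbcL"` or `"trnL"`.
#' @return `read_proportion_table` returns a [proportion_table()];
#'   `write_proportion_table` returns `path` invisibly.
#' @export
write_proportion_table <- function(x, path) {
  stopifnot(inherits(x, "proportion_table"))
  cells <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values))
  cells[x$removed & !is.na(x$values)] <-
    paste0(cells[x$removed & !is.na(x$values)], "(0)")
  cells[is.na(x$values)] <- "NA"
  df <- data.frame(sample = rownames(x$values), cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample", vapply(x$taxa, taxon_string, character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proportion_table
#' @export
read_proportion_table <- function(path, marker = c("rbcL", "trnL", "median")) {
  marker <- match.arg(marker)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  samples <- df[[1]]
  cells <- as.matrix(df[-1])
  removed <- grepl("\\(0\\)$", cells)
  vals <- suppressWarnings(as.numeric(sub("\\(0\\)$", "", cells)))
  values <- matrix(vals, nrow = nrow(cells))
  removed <- matrix(removed, nrow = nrow(cells))
  rownames(values) <- samples
  taxa <- lapply(colnames(cells), parse_taxon)
  colnames(values) <- vapply(taxa, function(t) t$name, character(1))
  proportion_table(values, marker, removed = removed, taxa = taxa)
}

#' Read a BLAST tabular hit table
#'
#' Parses a headerless tab-separated file in the BLAST `outfmt 6` dialect:
#' the standard 12 columns (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`) followed by a required 13th
#' column holding the subject lineage (`Family;Genus;Genus_species`) and an
#' optional 14th column with the read count of the query OTU. When the 14th
#' column is absent, a `;size=N` annotation on the query id (usearch
#' convention) is honoured, and otherwise each OTU counts one read.
#'
#' @param path File path; an empty file yields an empty hit table.
#' @return An object of class `hit_table`: a data frame with columns
#'   `otu_id`, `subject`, `pident`, `bitscore`, `lineage`, `family`,
#'   `genus`, `species` and `read_count`, grouped by OTU and sorted by
#'   descending bit score within each OTU.
#' @export
read_hit_table <- function(path) {
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    return(empty_hit_table())
  }
  if (ncol(raw) < 13L) {
    stop(sprintf(
      "%s: expected >= 13 tab-separated columns (outfmt 6 + lineage); got %d",
      path, ncol(raw)), call. = FALSE)
  }
  bitscore <- suppressWarnings(as.numeric(raw[[12]]))
  if (any(is.na(bitscore)) || any(bitscore <= 0)) {
    stop(sprintf("%s: missing or non-positive bit scores in column 12", path),
         call. = FALSE)
  }
  otu_id <- as.character(raw[[1]])
  read_count <- if (ncol(raw) >= 14L) {
    suppressWarnings(as.numeric(raw[[14]]))
  } else if (any(grepl(";size=", otu_id, fixed = TRUE))) {
    as.numeric(sub("^.*;size=(\\d+).*$", "\\1", otu_id))
  } else {
    rep(1, nrow(raw))
  }
  if (any(is.na(read_count)) || any(read_count < 0)) {
    stop(sprintf("%s: invalid OTU read counts", path), call. = FALSE)
  }
  otu_id <- sub(";size=\\d+", "", otu_id)
  labels <- lapply(as.character(raw[[13]]), parse_taxon)
  df <- data.frame(
    otu_id = otu_id,
    subject = as.character(raw[[2]]),
    pident = suppressWarnings(as.numeric(raw[[3]])),
    bitscore = bitscore,
    lineage = as.character(raw[[13]]),
    taxa_frame(labels)[c("family", "genus", "species")],
    read_count = read_count,
    stringsAsFactors = FALSE
  )
  df <- df[order(match(df$otu_id, unique(df$otu_id)), -df$bitscore), ]
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  df
}

empty_hit_table <- function() {
  df <- data.frame(otu_id = character(), subject = character(),
                   pident = numeric(), bitscore = numeric(),
                   lineage = character(), family = character(),
                   genus = character(), species = character(),
                   read_count = numeric(), stringsAsFactors = FALSE)
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Read a plant checklist
#'
#' One accepted species name per line; blank lines and lines starting with
#' `#` are ignored; runs of whitespace are collapsed. The genus index is
#' derived from the first word of each binomial.
#'
#' @param path File path.
#' @return An object of class `checklist` with elements `species` (character
#'   vector of accepted binomials) and `genera`.
#' @export
read_checklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(gsub("[ \t]+", " ", lines))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    stop(sprintf("%s: checklist is empty", path), call. = FALSE)
  }
  checklist(lines)
}

#' Build a checklist from species names
#'
#' @param species Character vector of accepted species binomials.
#' @return A `checklist` object.
#' @export
checklist <- function(species) {
  species <- unique(trimws(gsub("[ \t]+", " ", species)))
  species <- species[nzchar(species)]
  if (!length(species)) stop("checklist: no species names", call. = FALSE)
  structure(
    list(species = species,
         genera = unique(vapply(strsplit(species, " "), `[`, character(1), 1))),
    class = "checklist"
  )
}

#' @export
print.checklist <- function(x, ...) {
  cat(sprintf("<checklist> %d species in %d genera\n",
              length(x$species), length(x$genera)))
  invisible(x)
}
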