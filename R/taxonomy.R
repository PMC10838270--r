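#' Assign a taxon to one OTU by top-bit-score consensus
#'
#' Considers only the hits tied for the maximum bit score (ties are judged
#' after rounding scores to one decimal, the precision BLAST reports, so
#' floating-point noise cannot inflate the rank). The OTU is assigned to
#' species rank when those hits name a single species, to genus rank when
#' they name several species of one genus, to family rank when they span
#' several genera of one family, and is left unassigned (`NULL`) when they
#' span more than one family.
#'
#' @param hits A `hit_table` (or compatible data frame) holding the hits of
#'   a single OTU: columns `bitscore`, `family`, `genus`, `species`.
#' @return A [taxon_label()], or `NULL` when the OTU cannot be assigned at
#'   family rank.
#' @export
assign_taxon <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) {
    stop("assign_taxon: empty hit list", call. = FALSE)
  }
  score <- round(hits$bitscore, 1)
  top <- hits[score == max(score), c("family", "genus", "species"),
              drop = FALSE]
  top <- unique(top)
  if (length(unique(top$family)) > 1L) return(NULL)
  fam <- top$family[1]
  genera <- unique(top$genus[nzchar(top$genus)])
  if (length(genera) != 1L || any(!nzchar(top$genus))) {
    return(taxon_label(fam))
  }
  species <- unique(top$species[nzchar(top$species)])
  if (length(species) == 1L && all(nzchar(top$species))) {
    return(taxon_label(fam, genera, species))
  }
  taxon_label(fam, genera)
}

#' Demote species-rank labels absent from a checklist
#'
#' Species-level assignments whose binomial does not appear in the regional
#' checklist of accepted plant names are demoted to genus rank; genus- and
#' family-rank labels pass through unchanged.
#'
#' @param label A [taxon_label()].
#' @param checklist A [checklist()].
#' @return A `taxon_label`.
#' @export
demote_by_checklist <- function(label, checklist) {
  stopifnot(inherits(label, "taxon_label"), inherits(checklist, "checklist"))
  if (label$rank == "species" && !(label$species %in% checklist$species)) {
    return(taxon_label(label$family, label$genus))
  }
  label
}

#' Consensus of the two markers' labels for the same taxon
#'
#' When the two labels are lineage-compatible (see [taxa_compatible()]) the
#' more specific one is kept, so a family-rank call by one marker adopts the
#' other marker's species identification. Incompatible labels within one
#' family fall back to the family; labels from different families yield no
#' consensus (`NULL`).
#'
#' @param label_rbcl,label_trnl [taxon_label()]s.
#' @return A `taxon_label` or `NULL`. The operation is commutative.
#' @export
consensus_label <- function(label_rbcl, label_trnl) {
  a <- label_rbcl
  b <- label_trnl
  stopifnot(inherits(a, "taxon_label"), inherits(b, "taxon_label"))
  if (taxa_compatible(a, b)) {
    return(if (rank_level(a$rank) >= rank_level(b$rank)) a else b)
  }
  if (a$family == b$family) return(taxon_label(a$family))
  NULL
}

#' Aggregate assigned OTU reads into a per-sample count table
#'
#' Runs [assign_taxon()] (and optionally [demote_by_checklist()]) on each
#' OTU of each sample's hit table and sums the OTU read counts that share a
#' final label. Unassigned OTUs (top ties spanning families) are dropped
#' from the table but logged with their counts in the `unassigned`
#' attribute, so totals remain auditable; counts of assigned OTUs are
#' conserved exactly.
#'
#' @param hit_tables Named list of `hit_table`s, one per sample (names are
#'   the sample ids), all for the same marker.
#' @param checklist Optional [checklist()] used to demote species-rank
#'   labels before aggregation.
#' @param marker `"rbcL"` or `"trnL"`.
#' @return A [count_table()] with one column per distinct final label, and
#'   attribute `unassigned`: a data frame of dropped (sample, otu_id, reads).
#' @export
aggregate_counts <- function(hit_tables, checklist = NULL,
                             marker = c("rbcL", "trnL")) {
  marker <- match.arg(marker)
  stopifnot(is.list(hit_tables), !is.null(names(hit_tables)),
            all(nzchar(names(hit_tables))))
  labels <- list()       # name -> taxon_label
  cells <- list()        # list of (sample, name, reads)
  unassigned <- data.frame(sample = character(), otu_id = character(),
                           reads = numeric(), stringsAsFactors = FALSE)
  for (s in names(hit_tables)) {
    ht <- hit_tables[[s]]
    if (is.null(ht) || nrow(ht) == 0L) next
    for (otu in unique(ht$otu_id)) {
      rows <- ht[ht$otu_id == otu, , drop = FALSE]
      lab <- assign_taxon(rows)
      if (!is.null(lab) && !is.null(checklist)) {
        lab <- demote_by_checklist(lab, checklist)
      }
      reads <- rows$read_count[1]
      if (is.null(lab)) {
        unassigned <- rbind(unassigned, data.frame(
          sample = s, otu_id = otu, reads = reads, stringsAsFactors = FALSE))
        next
      }
      key <- paste(lab$family, lab$name, sep = "\r")
      labels[[key]] <- lab
      cells[[length(cells) + 1L]] <- list(sample = s, key = key,
                                          reads = reads)
    }
  }
  samples <- names(hit_tables)
  keys <- names(labels)
  m <- matrix(0, length(samples), length(keys),
              dimnames = list(samples, vapply(labels, function(l) l$name,
                                              character(1))))
  for (cell in cells) {
    j <- match(cell$key, keys)
    m[cell$sample, j] <- m[cell$sample, j] + cell$reads
  }
  out <- count_table(m, marker, taxa = unname(labels))
  attr(out, "unassigned") <- unassigned
  out
}
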