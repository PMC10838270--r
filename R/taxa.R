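#' Taxon labels
#'
#' A taxon label is a plant name resolved to one of three ranks: species,
#' genus or family, together with its lineage (family >= genus >= species).
#' Metabarcoding assignments frequently stop above species rank, so a label
#' carries exactly as much lineage as the evidence supports: a family-rank
#' label has an empty genus and species, a genus-rank label an empty species.
#'
#' @param family Family name (always required).
#' @param genus Genus name; empty string for a family-rank label.
#' @param species Species binomial (e.g. `"Robinia pseudoacacia"`); empty
#'   string unless the label is resolved to species rank.
#' @return An object of class `taxon_label` with fields `name` (the most
#'   specific available name), `rank`, `family`, `genus` and `species`.
#' @examples
#' taxon_label("Fabaceae", "Robinia", "Robinia pseudoacacia")
#' taxon_label("Rosaceae", "Prunus")
#' taxon_label("Fabaceae")
#' @export
taxon_label <- function(family, genus = "", species = "") {
  stopifnot(is.character(family), length(family) == 1L)
  family <- trimws(family)
  genus <- trimws(genus)
  species <- trimws(species)
  if (!nzchar(family)) {
    stop("taxon_label: 'family' must be non-empty", call. = FALSE)
  }
  if (nzchar(species) && !nzchar(genus)) {
    stop("taxon_label: species-rank label requires a genus", call. = FALSE)
  }
  rank <- if (nzchar(species)) "species" else if (nzchar(genus)) "genus" else "family"
  name <- switch(rank, species = species, genus = genus, family = family)
  structure(
    list(name = name, rank = rank, family = family, genus = genus,
         species = species),
    class = "taxon_label"
  )
}

#' @export
print.taxon_label <- function(x, ...) {
  cat(sprintf("<taxon_label> %s [%s] (%s)\n", x$name, x$rank,
              paste(Filter(nzchar, c(x$family, x$genus, x$species)),
                    collapse = " > ")))
  invisible(x)
}

#' @export
format.taxon_label <- function(x, ...) x$name

rank_level <- function(rank) {
  match(rank, c("family", "genus", "species"))
}

#' Lineage compatibility of two taxon labels
#'
#' Two labels are compatible when one's lineage is a prefix of the other's:
#' the families agree, the genera agree where both are defined, and the
#' species agree where both are defined. `"Fabaceae"` (family) is compatible
#' with `"Robinia pseudoacacia"`; `"Prunus mume"` and `"Prunus salicina"`
#' are not (both define a species and the species differ).
#'
#' @param a,b `taxon_label` objects.
#' @return Logical scalar.
#' @export
taxa_compatible <- function(a, b) {
  stopifnot(inherits(a, "taxon_label"), inherits(b, "taxon_label"))
  if (a$family != b$family) return(FALSE)
  if (nzchar(a$genus) && nzchar(b$genus) && a$genus != b$genus) return(FALSE)
  if (nzchar(a$species) && nzchar(b$species) && a$species != b$species) {
    return(FALSE)
  }
  TRUE
}

#' Parse a taxon string into a label
#'
#' Accepts either a full lineage `"Family;Genus;Genus_species"` (a trailing
#' field may be omitted to express a coarser rank; underscores in the species
#' field are read as spaces) or a bare name. A bare binomial is read as a
#' species; a bare single word ending in "aceae" as a family; any other
#' single word as a genus. When the family is not given it falls back to the
#' genus name as a placeholder so that labels parsed from the same source
#' still match each other; supply full lineages whenever family-level
#' comparisons matter.
#'
#' @param x Character scalar.
#' @return A `taxon_label`.
#' @examples
#' parse_taxon("Fabaceae;Robinia;Robinia_pseudoacacia")
#' parse_taxon("Rosaceae;Prunus")
#' parse_taxon("Prunus mume")
#' @export
parse_taxon <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (!nzchar(x)) stop("parse_taxon: empty taxon string", call. = FALSE)
  if (grepl(";", x, fixed = TRUE)) {
    parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    if (length(parts) > 3L || any(!nzchar(parts))) {
      stop(sprintf("parse_taxon: malformed lineage '%s'", x), call. = FALSE)
    }
    fam <- parts[1]
    gen <- if (length(parts) >= 2L) parts[2] else ""
    sp <- if (length(parts) == 3L) gsub("_", " ", parts[3], fixed = TRUE) else ""
    if (nzchar(sp) && !grepl(" ", sp, fixed = TRUE)) {
      sp <- paste(gen, sp)
    }
    return(taxon_label(fam, gen, sp))
  }
  words <- strsplit(gsub("_", " ", x, fixed = TRUE), "[ ]+")[[1]]
  if (length(words) >= 2L) {
    return(taxon_label(words[1], words[1], paste(words[1:2], collapse = " ")))
  }
  if (grepl("aceae$", x)) return(taxon_label(x))
  taxon_label(x, x)
}

#' Serialize a taxon label as a lineage string
#'
#' Inverse of [parse_taxon()] for labels carrying full lineage information.
#'
#' @param label A `taxon_label`.
#' @return `"Family;Genus;Genus_species"` truncated at the label's rank.
#' @export
taxon_string <- function(label) {
  stopifnot(inherits(label, "taxon_label"))
  parts <- c(label$family, label$genus,
             gsub(" ", "_", label$species, fixed = TRUE))
  paste(parts[nzchar(parts)], collapse = ";")
}

# Internal: data.frame representation of a list of labels, one row per label.
taxa_frame <- function(labels) {
  if (length(labels) == 0L) {
    return(data.frame(name = character(), rank = character(),
                      family = character(), genus = character(),
                      species = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(labels, function(l) {
    data.frame(name = l$name, rank = l$rank, family = l$family,
               genus = l$genus, species = l$species, stringsAsFactors = FALSE)
  }))
}

# Internal: rebuild labels from a taxa frame.
frame_taxa <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    taxon_label(df$family[i], df$genus[i], df$species[i])
  })
}
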