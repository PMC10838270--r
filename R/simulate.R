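# Nine woody species, one per family, used as the default mock-community
# palette (the same palette as the bundled reference table).
default_mock_taxa <- function() {
  lapply(c(
    "Fabaceae;Robinia;Robinia_pseudoacacia",
    "Rosaceae;Prunus;Prunus_salicina",
    "Pinaceae;Pinus;Pinus_koreanus",
    "Salicaceae;Populus;Populus_tomentiglandulosa",
    "Anacardiaceae;Rhus;Rhus_chinensis",
    "Rutaceae;Zanthoxylum;Zanthoxylum_schinifolium",
    "Lauraceae;Lindera;Lindera_obtusiloba",
    "Simaroubaceae;Ailanthus;Ailanthus_altissima",
    "Paulowniaceae;Paulownia;Paulownia_tomentosa"
  ), parse_taxon)
}

# Airborne-pollen style background genera shared by real samples and the
# negative control.
background_pool_taxa <- function(n) {
  pool <- c("Fagaceae;Quercus", "Betulaceae;Alnus", "Solanaceae;Solanum",
            "Ebenaceae;Diospyros", "Fabaceae;Glycine", "Salicaceae;Salix",
            "Moraceae;Morus", "Ulmaceae;Ulmus", "Platanaceae;Platanus",
            "Poaceae;Setaria", "Juglandaceae;Juglans", "Oleaceae;Fraxinus")
  if (n > length(pool)) {
    extra <- sprintf("Synfam%02d;Syngen%02d", seq_len(n - length(pool)),
                     seq_len(n - length(pool)))
    pool <- c(pool, extra)
  }
  lapply(pool[seq_len(n)], parse_taxon)
}

#' Simulation parameters
#'
#' Bundles the knobs of the synthetic mock-community and nest-study
#' generators. Defaults mirror the reference study design: seven mixtures
#' of nine woody taxa, 1e5 reads per sample and marker, log-normal
#' per-(taxon, marker) amplification bias with sigma 0.5, a shared airborne
#' contamination pool of 10 taxa contributing an expected 0.2% of reads
#' (observed false-positive proportions in such experiments sit below
#' 0.0025), and negative-control depths of 0 (rbcL) and 3098 (trnL) reads.
#' The nest study covers 13 nests: 5 P. rothneyi at ANU, 3 P. rothneyi and
#' 5 P. mandarinus at Imha, with a small (8 genera) flora pool at the
#' semi-urban ANU site and a large (20 genera) pool at the forested Imha
#' site.
#'
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @param n_taxa,n_mixtures Mock design size.
#' @param depth Sequencing depth per sample and marker.
#' @param bias_sigma Standard deviation of the log-normal per-(taxon,
#'   marker) amplification factor; 0 disables marker bias.
#' @param contam_rate Expected contaminant read fraction per sample.
#' @param contam_pool_size Number of background (contaminant) taxa.
#' @param nc_depth Named vector, negative-control reads per marker.
#' @param genus_tie_rate,family_tie_rate Probability that a taxon's
#'   reference hits tie at genus (two congeneric species) or family rank
#'   (two genera of the family) for a given marker.
#' @param design `"dirichlet"` (random proportions, every taxon in at least
#'   three mixtures) or `"table1"` (the bundled reference design).
#' @param nest List of nest-study settings: `n_nests` (named
#'   `species.locality` counts), `pool_size` (genera per locality),
#'   `preference_weight` (weight of the species' plant preference vs the
#'   local flora), `depth`, `area_range` (per-locality vegetation-area
#'   ranges, m^2 within the 100 m foraging radius), `flora_survey_n`
#'   (individuals counted per landscape survey).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed,
                       n_taxa = 9, n_mixtures = 7, depth = 1e5,
                       bias_sigma = 0.5, contam_rate = 0.002,
                       contam_pool_size = 10,
                       nc_depth = c(rbcL = 0, trnL = 3098),
                       genus_tie_rate = 0.4, family_tie_rate = 0.1,
                       design = c("dirichlet", "table1"),
                       nest = list()) {
  if (missing(seed)) stop("sim_params: a seed is mandatory", call. = FALSE)
  design <- match.arg(design)
  stopifnot(contam_rate >= 0, contam_rate <= 1, depth >= 1,
            bias_sigma >= 0, genus_tie_rate >= 0, family_tie_rate >= 0,
            genus_tie_rate + family_tie_rate <= 1)
  nest_defaults <- list(
    n_nests = c(rothneyi.ANU = 5, rothneyi.Imha = 3,
                mandarinus.Imha = 5, mandarinus.ANU = 0),
    pool_size = c(ANU = 8, Imha = 20),
    preference_weight = 0.5,
    depth = 2e4,
    area_range = list(ANU = c(4000, 15000), Imha = c(12000, 31416)),
    flora_survey_n = 400
  )
  nest <- utils::modifyList(nest_defaults, nest)
  structure(list(seed = as.integer(seed), n_taxa = n_taxa,
                 n_mixtures = n_mixtures, depth = depth,
                 bias_sigma = bias_sigma, contam_rate = contam_rate,
                 contam_pool_size = contam_pool_size, nc_depth = nc_depth,
                 genus_tie_rate = genus_tie_rate,
                 family_tie_rate = family_tie_rate,
                 design = design, nest = nest),
            class = "sim_params")
}

# Run fn with the RNG seeded from params, restoring global RNG state after.
with_sim_rng <- function(params, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(params$seed)
  fn()
}

rdirichlet1 <- function(n) {
  g <- stats::rgamma(n, 1, 1)
  g / sum(g)
}

#' Simulate a two-marker mock-community experiment
#'
#' Draws a mixture design (or uses the bundled reference design), distorts
#' each mixture's true proportions by per-(taxon, marker) log-normal
#' amplification factors, samples reads by multinomial draws at the
#' configured depth, adds contaminant reads from a shared background pool,
#' and samples the negative controls from the same pool. Matching BLAST-style
#' hit tables are generated so that the taxonomy module reproduces the
#' intended per-marker labels, including genus- and family-rank top-score
#' ties at the configured rates.
#'
#' @param params A [sim_params()] object.
#' @return A list with `design` ([mixture_design()]), `rbcl`/`trnl`
#'   ([count_table()]s keyed by true taxon, contaminant columns included),
#'   `nc_rbcl`/`nc_trnl` (one-sample negative-control count tables),
#'   `hits` (per marker, a named list of `hit_table`s per sample), `bias`
#'   (the amplification factors), `contam_pool` (background taxa and their
#'   proportions; taxa overlapping the design are flagged in the
#'   `overlaps_design` column) and `intended_rank` (the rank each taxon's
#'   hits support per marker).
#' @export
generate_mock_experiment <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_sim_rng(params, function() generate_mock_(params))
}

generate_mock_ <- function(params) {
  markers <- c("rbcL", "trnL")
  if (params$design == "table1") {
    fx <- load_table1_fixture()
    design <- fx$design
    taxa <- frame_taxa(unique(as.data.frame(
      design)[c("family", "genus", "species")]))
  } else {
    taxa <- if (params$n_taxa == 9) default_mock_taxa() else {
      lapply(sprintf("Simfam%02d;Simgen%02d;Simgen%02d_sp", 1:params$n_taxa,
                     1:params$n_taxa, 1:params$n_taxa), parse_taxon)
    }
    design <- random_design(taxa, params$n_mixtures)
  }
  samples <- design_samples(design)
  taxa_names <- vapply(taxa, function(t) t$species, character(1))

  bias <- matrix(stats::rlnorm(length(taxa) * 2, 0, params$bias_sigma),
                 length(taxa), 2, dimnames = list(taxa_names, markers))

  pool <- background_pool_taxa(params$contam_pool_size)
  pool_names <- vapply(pool, function(t) t$name, character(1))
  pool_p <- rdirichlet1(length(pool))
  overlaps <- vapply(pool, function(pt) {
    any(vapply(taxa, function(dt) taxa_compatible(pt, dt), logical(1)))
  }, logical(1))

  # rank supported by each (taxon, marker)'s reference hits, fixed across
  # samples as it is a property of the reference database
  draw_rank <- function() {
    u <- stats::runif(1)
    if (u < params$family_tie_rate) "family"
    else if (u < params$family_tie_rate + params$genus_tie_rate) "genus"
    else "species"
  }
  intended <- matrix(vapply(seq_len(length(taxa) * 2), function(i)
    draw_rank(), character(1)), length(taxa), 2,
    dimnames = list(taxa_names, markers))

  counts <- list()
  hits <- list()
  for (mk in markers) {
    m <- matrix(0, length(samples), length(taxa) + length(pool),
                dimnames = list(samples, c(taxa_names, pool_names)))
    mk_hits <- list()
    for (s in samples) {
      des <- design[design$sample == s, , drop = FALSE]
      idx <- match(des$species, taxa_names)
      p <- des$true * bias[idx, mk]
      p <- p / sum(p)
      reads <- as.vector(stats::rmultinom(1, params$depth, p))
      m[s, idx] <- reads
      n_contam <- stats::rbinom(1, params$depth, params$contam_rate)
      contam <- if (n_contam > 0) {
        as.vector(stats::rmultinom(1, n_contam, pool_p))
      } else rep(0L, length(pool))
      m[s, length(taxa) + seq_along(pool)] <-
        m[s, length(taxa) + seq_along(pool)] + contam
      mk_hits[[s]] <- build_hit_table(
        s, mk, taxa[idx], reads, intended[idx, mk], pool, contam)
    }
    counts[[mk]] <- count_table(m, mk, taxa = c(taxa, pool))
    hits[[mk]] <- mk_hits
  }

  nc <- lapply(markers, function(mk) {
    depth <- params$nc_depth[[mk]]
    v <- if (depth > 0) as.vector(stats::rmultinom(1, depth, pool_p)) else
      rep(0L, length(pool))
    count_table(matrix(v, 1, dimnames = list("NC", pool_names)), mk,
                taxa = pool)
  })
  names(nc) <- markers

  list(design = design, rbcl = counts$rbcL, trnl = counts$trnL,
       nc_rbcl = nc$rbcL, nc_trnl = nc$trnL, hits = hits, bias = bias,
       contam_pool = data.frame(taxon = pool_names, proportion = pool_p,
                                overlaps_design = overlaps,
                                stringsAsFactors = FALSE),
       intended_rank = intended)
}

# Random design: every taxon in at least three mixtures, every mixture with
# at least two taxa, Dirichlet(1) proportions within each mixture.
random_design <- function(taxa, n_mixtures) {
  n <- length(taxa)
  member <- matrix(FALSE, n_mixtures, n)
  for (j in seq_len(n)) {
    member[sample.int(n_mixtures, min(3, n_mixtures)), j] <- TRUE
  }
  for (i in seq_len(n_mixtures)) {
    while (sum(member[i, ]) < 2L) {
      member[i, sample.int(n, 1)] <- TRUE
    }
  }
  rows <- lapply(seq_len(n_mixtures), function(i) {
    idx <- which(member[i, ])
    p <- rdirichlet1(length(idx))
    tf <- taxa_frame(taxa[idx])
    data.frame(sample = sprintf("PC%d", i), family = tf$family,
               genus = tf$genus, species = tf$species, true = p,
               stringsAsFactors = FALSE)
  })
  mixture_design(do.call(rbind, rows))
}

# One OTU per present taxon; hits encode the intended assignment rank via
# top-bit-score ties, plus a lower-scoring decoy hit.
build_hit_table <- function(sample, marker, taxa, reads, ranks, pool,
                            contam) {
  rows <- list()
  add <- function(otu, lineage, score, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      otu_id = otu, subject = paste0("acc_", length(rows) + 1L),
      pident = 99.0, length = 450L, mismatch = 2L, gapopen = 0L,
      qstart = 1L, qend = 450L, sstart = 1L, send = 450L,
      evalue = 1e-120, bitscore = score, lineage = lineage,
      read_count = n, stringsAsFactors = FALSE)
  }
  k <- 0L
  for (i in seq_along(taxa)) {
    if (reads[i] <= 0) next
    k <- k + 1L
    otu <- sprintf("%s_%s_otu%03d", sample, marker, k)
    t <- taxa[[i]]
    full <- taxon_string(t)
    if (ranks[i] == "species") {
      add(otu, full, 900.0, reads[i])
    } else if (ranks[i] == "genus") {
      add(otu, full, 900.0, reads[i])
      add(otu, sprintf("%s;%s;%s_simsib", t$family, t$genus, t$genus),
          900.0, reads[i])
    } else {
      add(otu, full, 900.0, reads[i])
      add(otu, sprintf("%s;Simgenus_%s", t$family, t$genus), 900.0, reads[i])
    }
    add(otu, full, 850.0, reads[i])
  }
  for (j in seq_along(pool)) {
    if (contam[j] <= 0) next
    k <- k + 1L
    otu <- sprintf("%s_%s_otu%03d", sample, marker, k)
    pt <- pool[[j]]
    gen <- if (nzchar(pt$genus)) pt$genus else pt$family
    add(otu, sprintf("%s;%s;%s_bg1", pt$family, gen, gen), 880.0, contam[j])
    add(otu, sprintf("%s;%s;%s_bg2", pt$family, gen, gen), 880.0, contam[j])
  }
  if (!length(rows)) return(empty_hit_table())
  df <- do.call(rbind, rows)
  labels <- lapply(df$lineage, parse_taxon)
  df <- cbind(df[c("otu_id", "subject", "pident", "bitscore", "lineage")],
              taxa_frame(labels)[c("family", "genus", "species")],
              df["read_count"])
  df <- df[order(match(df$otu_id, unique(df$otu_id)), -df$bitscore), ]
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Simulate a two-species, two-locality nest study
#'
#' Each nest's true plant composition is a convex mixture of its wasp
#' species' plant-preference vector (weight `preference_weight`) and a
#' nest-specific draw from its locality's flora pool. Localities differ in
#' pool size, and each nest samples a number of locally available genera
#' proportional to its vegetation area, so nests in richer, larger-area
#' localities accumulate more taxa - the diversity-area relationship the
#' community statistics are meant to recover is built in. Read counts are
#' multinomial at the configured depth; a genus-level landscape flora
#' survey is generated per nest from the locality pool.
#'
#' @param params A [sim_params()] object (the `nest` block is used).
#' @return A list with `counts` (a genus-level [count_table()], nests in
#'   rows), `metadata` (data frame: `nest_id`, `wasp_species`, `locality`,
#'   `vegetation_area`), `flora` (nest-by-genus landscape survey counts)
#'   and `truth` (the true composition matrix).
#' @export
generate_nest_study <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_sim_rng(params, function() generate_nests_(params))
}

generate_nests_ <- function(params) {
  np <- params$nest
  master <- background_pool_taxa(max(np$pool_size, 12))
  master_names <- vapply(master, function(t) t$name, character(1))
  # both wasp species prefer Quercus and Robinia-like hosts; give each a
  # distinct preference profile over the first few master genera
  pref <- list(
    rothneyi = stats::setNames(rep(0, length(master)), master_names),
    mandarinus = stats::setNames(rep(0, length(master)), master_names)
  )
  pref$rothneyi[1:6] <- c(0.30, 0.10, 0.05, 0.10, 0.05, 0.40)[1:6]
  pref$mandarinus[1:6] <- c(0.35, 0.05, 0.15, 0.05, 0.10, 0.30)[1:6]
  pref <- lapply(pref, function(p) p / sum(p))

  pools <- lapply(names(np$pool_size), function(loc) {
    master_names[seq_len(min(np$pool_size[[loc]], length(master)))]
  })
  names(pools) <- names(np$pool_size)

  rows <- list()
  meta <- list()
  flora <- list()
  for (grp in names(np$n_nests)) {
    n <- np$n_nests[[grp]]
    if (n == 0) next
    parts <- strsplit(grp, ".", fixed = TRUE)[[1]]
    species <- parts[1]
    loc <- parts[2]
    for (i in seq_len(n)) {
      id <- sprintf("%s_%s_%02d", toupper(substr(species, 1, 2)), loc, i)
      area <- stats::runif(1, np$area_range[[loc]][1],
                           np$area_range[[loc]][2])
      pool <- pools[[loc]]
      k <- max(3L, round(length(pool) * area / max(np$area_range[[loc]])))
      avail <- unique(c(master_names[1], sample(pool, min(k, length(pool)))))
      flora_p <- stats::setNames(rep(0, length(master)), master_names)
      flora_p[avail] <- rdirichlet1(length(avail))
      p <- np$preference_weight * pref[[species]] +
        (1 - np$preference_weight) * flora_p
      p <- p / sum(p)
      rows[[id]] <- as.vector(stats::rmultinom(1, np$depth, p))
      meta[[id]] <- data.frame(nest_id = id, wasp_species = species,
                               locality = loc, vegetation_area = area,
                               stringsAsFactors = FALSE)
      loc_p <- stats::setNames(rep(0, length(master)), master_names)
      loc_p[pool] <- rdirichlet1(length(pool))
      flora[[id]] <- as.vector(stats::rmultinom(1, np$flora_survey_n, loc_p))
    }
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), master_names)
  fl <- do.call(rbind, flora)
  dimnames(fl) <- list(names(flora), master_names)
  truth <- m / rowSums(m)
  list(counts = count_table(m, "rbcL", taxa = master),
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       flora = fl, truth = truth)
}
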