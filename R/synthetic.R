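# Self-contained synthetic world generator and the independent brute-force
# expansion oracle used to cross-check the pipeline. The oracle deliberately
# shares no code with the expansion module: plain loops over vectors.

#' Specification for a synthetic metaweb world
#'
#' Defaults describe a small but structurally complete world: a three-level
#' taxonomy under a handful of families, interaction records emitted at
#' mixed taxonomic ranks with known ground truth, habitat/stratum
#' associations over a subset of the nine habitat classes and eleven strata,
#' and clustered occurrence points over rectangular habitat patches. Planted
#' "true" habitats receive many more points than `min_count_retain` at the
#' synthetic scale while stray points stay well below it, with a small
#' deliberately ambiguous band (see `p_stray`).
#'
#' @param n_families,genera_per_family,species_per_genus Taxonomy shape.
#' @param n_guilds Number of basal feeding-guild nodes (>= 0).
#' @param n_records Number of interaction records to emit.
#' @param p_coarse_record Proportion of records coarsened to genus or family
#'   rank on one side.
#' @param n_habitats,n_strata Sizes of the habitat (<= 9) and stratum
#'   (<= 11) vocabularies in play.
#' @param points_per_species Occurrence points planted per species per true
#'   habitat.
#' @param p_stray Probability a species also gets a small stray point
#'   cluster (about a tenth of `points_per_species`) in a non-habitat.
#' @param p_missing_assoc Fraction of species whose checklist associations
#'   are blanked to exercise genus/family inference.
#' @param seed Integer seed; the whole world is deterministic under it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_families = 3L, genera_per_family = 2L,
                           species_per_genus = 3L, n_guilds = 2L,
                           n_records = 40L, p_coarse_record = 0.4,
                           n_habitats = 4L, n_strata = 3L,
                           points_per_species = 60L, p_stray = 0.3,
                           p_missing_assoc = 0.15, seed = 1L) {
  stopifnot(n_families >= 1, genera_per_family >= 1, species_per_genus >= 1,
            n_guilds >= 0, n_records >= 1,
            p_coarse_record >= 0, p_coarse_record <= 1,
            n_habitats >= 1, n_habitats <= 9,
            n_strata >= 1, n_strata <= 11,
            points_per_species >= 1, p_missing_assoc >= 0,
            p_missing_assoc <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic world for the whole pipeline
#'
#' Builds a checklist (families, genera, species, guilds), mixed-rank
#' interaction records, diet-range and guild-map tables, special cases,
#' occurrence points over rectangular habitat patches, and the ground-truth
#' species-level link set computed by the independent [oracle_expand()]
#' (never by the expansion module itself). Names follow the collision-free
#' scheme `Fam{i}` / `Gen{i}.{j}` / `Gen{i}.{j} sp{i}.{j}.{k}`.
#'
#' The returned `checklist` may have association gaps (see
#' `p_missing_assoc`); `checklist_full` carries every planted association
#' and is what the ground truth is computed against.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `checklist`, `checklist_full`, `records`, `diet_ranges`,
#'   `guild_map`, `special_cases`, `points`, `patches`, `habitats`,
#'   `strata`, `ground_truth` (tibble of `(Source_Name, Target_Name,
#'   Inference)` triples from the oracle).
#' @export
generate_world <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  habitats <- metaweb_habitats()[seq_len(spec$n_habitats)]
  strata <- metaweb_strata()[seq_len(spec$n_strata)]

  fams <- paste0("Fam", seq_len(spec$n_families))
  taxa <- list()
  for (i in seq_len(spec$n_families)) {
    taxa[[length(taxa) + 1L]] <- tibble::tibble(
      Taxon = fams[i], Rank = "Family", Kingdom = "Animalia",
      Phylum = "Arthropoda", Class = "Insecta", Order = "Ordo1",
      Family = fams[i], Genus = NA_character_, Species = NA_character_)
    for (j in seq_len(spec$genera_per_family)) {
      gen <- paste0("Gen", i, ".", j)
      taxa[[length(taxa) + 1L]] <- tibble::tibble(
        Taxon = gen, Rank = "Genus", Kingdom = "Animalia",
        Phylum = "Arthropoda", Class = "Insecta", Order = "Ordo1",
        Family = fams[i], Genus = gen, Species = NA_character_)
      for (k in seq_len(spec$species_per_genus)) {
        ep <- paste0("sp", i, ".", j, ".", k)
        taxa[[length(taxa) + 1L]] <- tibble::tibble(
          Taxon = paste(gen, ep), Rank = "Species", Kingdom = "Animalia",
          Phylum = "Arthropoda", Class = "Insecta", Order = "Ordo1",
          Family = fams[i], Genus = gen, Species = ep)
      }
    }
  }
  guilds <- if (spec$n_guilds > 0L) {
    paste0("Guild", seq_len(spec$n_guilds))
  } else character(0)
  for (g in guilds) {
    taxa[[length(taxa) + 1L]] <- tibble::tibble(
      Taxon = g, Rank = "Guild", Kingdom = "Resources",
      Phylum = NA_character_, Class = NA_character_, Order = NA_character_,
      Family = NA_character_, Genus = NA_character_,
      Species = NA_character_)
  }
  checklist <- dplyr::bind_rows(taxa)

  sp_names <- checklist$Taxon[checklist$Rank == "Species"]
  n_sp <- length(sp_names)
  # planted associations: 1-2 habitats, 1-2 strata per species
  planted_hab <- purrr::map(seq_len(n_sp), function(i) {
    sort(sample(habitats, sample(1:min(2, length(habitats)), 1)))
  })
  planted_zone <- purrr::map(seq_len(n_sp), function(i) {
    sort(sample(strata, sample(1:min(2, length(strata)), 1)))
  })
  full <- checklist
  full$Habitat <- purrr::map(full$Taxon, function(t) {
    i <- match(t, sp_names)
    if (is.na(i)) character(0) else planted_hab[[i]]
  })
  full$Zone <- purrr::map(full$Taxon, function(t) {
    i <- match(t, sp_names)
    if (is.na(i)) character(0) else planted_zone[[i]]
  })
  full <- as_checklist(full, metaweb_vocab(habitats = metaweb_habitats(),
                                           strata = metaweb_strata()))
  # blank a fraction of species to exercise inference
  gap_sp <- sp_names[runif(n_sp) < spec$p_missing_assoc]
  checklist <- full
  gap_rows <- checklist$Taxon %in% gap_sp
  checklist$Habitat[gap_rows] <- list(character(0))
  checklist$Zone[gap_rows] <- list(character(0))

  # diet ranges: first family is a generalist predator family; one
  # polylectic species; one basal guild-feeding family (when guilds exist)
  dr <- list(tibble::tibble(Taxon = fams[1], Range = "Predator",
                            Citation = list(901L), Rank = "Family"))
  poly_sp <- sp_names[[n_sp]]
  dr[[2]] <- tibble::tibble(Taxon = poly_sp, Range = "Polylectic",
                            Citation = list(902L), Rank = "Species")
  guild_map <- tibble::tibble(Taxon = character(0), Guild = character(0))
  if (spec$n_guilds > 0L && spec$n_families >= 2L) {
    dr[[3]] <- tibble::tibble(Taxon = fams[2], Range = "Basal",
                              Citation = list(903L), Rank = "Family")
    guild_map <- tibble::tibble(Taxon = fams[2], Guild = guilds[[1]])
  }
  diet_ranges <- as_diet_ranges(dplyr::bind_rows(dr))

  # interaction records at mixed ranks
  rows <- list()
  seen <- character(0)
  genera <- checklist$Taxon[checklist$Rank == "Genus"]
  tries <- 0L
  while (length(rows) < spec$n_records && tries < spec$n_records * 50L) {
    tries <- tries + 1L
    src <- sample(sp_names, 1)
    tgt <- sample(setdiff(sp_names, src), 1)
    src_rank <- "Species"
    tgt_rank <- "Species"
    if (runif(1) < spec$p_coarse_record) {
      src_fam <- full$Family[match(src, full$Taxon)]
      choice <- sample(c("genus_target", "genus_source", "family_target"), 1)
      if (choice == "genus_target") {
        tgt <- full$Genus[match(tgt, full$Taxon)]
        tgt_rank <- "Genus"
      } else if (choice == "genus_source") {
        src <- full$Genus[match(src, full$Taxon)]
        src_rank <- "Genus"
      } else {
        # family-level resource; only sometimes from an eligible consumer,
        # so ineligible coarse records (retained) are also exercised
        tgt <- full$Family[match(tgt, full$Taxon)]
        tgt_rank <- "Family"
      }
    }
    key <- paste(src, tgt, sep = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    stages <- list(character(0), "Young", "Adult", c("Young", "Adult"))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      Source_Name = src, Target_Name = tgt,
      Source_Rank = src_rank, Target_Rank = tgt_rank,
      Source_Life_Stage = stages[sample(4, 1)],
      Target_Life_Stage = stages[sample(4, 1)],
      Citation = list(sort(sample(1:30, sample(1:2, 1)))),
      Interaction_Type = sample(c("Predation", "Herbivory", NA), 1))
  }
  records <- as_interactions(dplyr::bind_rows(rows))

  # special cases: last species inherits the first species' diet
  special_cases <- as_special_cases(tibble::tibble(
    Taxon = sp_names[[n_sp]], Inference_Taxon = sp_names[[1]],
    Citation = list(904L), Case = "Missing diets"))

  # occurrence points over one rectangular patch per habitat, laid on a row
  patches <- tibble::tibble(
    habitat = habitats,
    xmin = (seq_along(habitats) - 1) * 10,
    ymin = 0,
    xmax = (seq_along(habitats) - 1) * 10 + 8,
    ymax = 8)
  pts <- list()
  for (i in seq_len(n_sp)) {
    for (h in planted_hab[[i]]) {
      p <- patches[patches$habitat == h, , drop = FALSE]
      n_pts <- spec$points_per_species
      pts[[length(pts) + 1L]] <- tibble::tibble(
        species = sp_names[[i]],
        x = runif(n_pts, p$xmin, p$xmax),
        y = runif(n_pts, p$ymin, p$ymax))
    }
    if (runif(1) < spec$p_stray) {
      other <- setdiff(habitats, planted_hab[[i]])
      if (length(other) > 0L) {
        h <- sample(other, 1)
        p <- patches[patches$habitat == h, , drop = FALSE]
        n_pts <- max(1L, spec$points_per_species %/% 10L)
        pts[[length(pts) + 1L]] <- tibble::tibble(
          species = sp_names[[i]],
          x = runif(n_pts, p$xmin, p$xmax),
          y = runif(n_pts, p$ymin, p$ymax))
      }
    }
  }
  points <- dplyr::bind_rows(pts)

  ground_truth <- oracle_expand(records, full, diet_ranges, guild_map)

  list(checklist = checklist, checklist_full = full, records = records,
       diet_ranges = diet_ranges, guild_map = guild_map,
       special_cases = special_cases, points = points, patches = patches,
       habitats = habitats, strata = strata, ground_truth = ground_truth)
}

#' Brute-force expansion oracle
#'
#' Independent re-implementation of the expansion rules as explicit loops,
#' used only to cross-check [expand_metaweb()] on small instances. Returns
#' the deduplicated set of `(Source_Name, Target_Name, Inference)` triples
#' (empirical beats inferred on a collision, matching the assembly rule).
#'
#' @param records Interaction tibble.
#' @param checklist Checklist tibble with `Habitat`/`Zone` list columns.
#' @param diet_ranges Diet-range tibble (or `NULL`).
#' @param guild_map Family-to-guild map (or `NULL`).
#' @return Tibble of triples, sorted; `Inference` is `NA` for empirical.
#' @export
oracle_expand <- function(records, checklist, diet_ranges = NULL,
                          guild_map = NULL) {
  n <- nrow(records)
  srcs <- character(0); tgts <- character(0); infs <- character(0)
  cl_taxon <- checklist$Taxon
  cl_rank <- checklist$Rank
  cl_genus <- checklist$Genus
  cl_family <- checklist$Family
  cl_hab <- checklist$Habitat
  cl_zone <- checklist$Zone
  pred_fams <- character(0); poly_sp <- character(0)
  if (!is.null(diet_ranges)) {
    for (i in seq_len(nrow(diet_ranges))) {
      if (diet_ranges$Range[[i]] == "Predator" &&
          diet_ranges$Rank[[i]] == "Family") {
        pred_fams <- c(pred_fams, diet_ranges$Taxon[[i]])
      }
      if (diet_ranges$Range[[i]] == "Polylectic") {
        poly_sp <- c(poly_sp, diet_ranges$Taxon[[i]])
      }
    }
  }
  sp_of_genus <- function(g) {
    out <- character(0)
    for (t in seq_along(cl_taxon)) {
      if (cl_rank[[t]] == "Species" && !is.na(cl_genus[[t]]) &&
          cl_genus[[t]] == g) out <- c(out, cl_taxon[[t]])
    }
    out
  }
  sp_of_family <- function(f) {
    out <- character(0)
    for (t in seq_along(cl_taxon)) {
      if (cl_rank[[t]] == "Species" && !is.na(cl_family[[t]]) &&
          cl_family[[t]] == f) out <- c(out, cl_taxon[[t]])
    }
    out
  }
  share <- function(a, b) {
    ia <- match(a, cl_taxon); ib <- match(b, cl_taxon)
    length(intersect(cl_hab[[ia]], cl_hab[[ib]])) > 0 &&
      length(intersect(cl_zone[[ia]], cl_zone[[ib]])) > 0
  }
  add <- function(s, t, inf) {
    srcs <<- c(srcs, s); tgts <<- c(tgts, t); infs <<- c(infs, inf)
  }
  for (i in seq_len(n)) {
    s <- records$Source_Name[[i]]; t <- records$Target_Name[[i]]
    sr <- records$Source_Rank[[i]]; tr <- records$Target_Rank[[i]]
    inf <- records$Inference[[i]]
    if (sr == "Species" && tr == "Genus") {
      members <- sp_of_genus(t)
      if (length(members) == 0) add(s, t, inf)
      else for (m in members) add(s, m, "Source_Species_Target_Genus")
    } else if (sr == "Genus" && tr == "Species") {
      members <- sp_of_genus(s)
      if (length(members) == 0) add(s, t, inf)
      else for (m in members) add(m, t, "Source_Genus_Target_Species")
    } else if (sr == "Species" && tr == "Family") {
      fam_s <- cl_family[[match(s, cl_taxon)]]
      eligible <- (!is.na(fam_s) && fam_s %in% pred_fams) || s %in% poly_sp
      if (!eligible) {
        add(s, t, inf)
      } else {
        members <- sp_of_family(t)
        kept <- character(0)
        for (m in members) if (share(s, m)) kept <- c(kept, m)
        if (length(kept) == 0) add(s, t, inf)
        else for (m in kept) add(s, m, "Source_Species_Target_Family")
      }
    } else {
      add(s, t, inf)
    }
  }
  if (!is.null(diet_ranges) && !is.null(guild_map) && nrow(guild_map) > 0) {
    for (i in seq_len(nrow(diet_ranges))) {
      if (diet_ranges$Range[[i]] != "Basal") next
      fam <- diet_ranges$Taxon[[i]]
      for (j in seq_len(nrow(guild_map))) {
        if (guild_map$Taxon[[j]] != fam) next
        members <- if (diet_ranges$Rank[[i]] == "Species") fam else
          sp_of_family(fam)
        for (m in members) {
          add(m, guild_map$Guild[[j]], "Source_Family_Target_Guild")
        }
      }
    }
  }
  # dedupe: empirical (NA inference) wins, else first in sorted tag order
  key <- paste(srcs, tgts, sep = "\r")
  out_s <- character(0); out_t <- character(0); out_i <- character(0)
  for (k in unique(key)) {
    hit <- which(key == k)
    tags <- infs[hit]
    if (any(is.na(tags))) {
      pick <- NA_character_
    } else {
      pick <- sort(tags)[[1]]
    }
    out_s <- c(out_s, srcs[[hit[[1]]]])
    out_t <- c(out_t, tgts[[hit[[1]]]])
    out_i <- c(out_i, pick)
  }
  out <- tibble::tibble(Source_Name = out_s, Target_Name = out_t,
                        Inference = out_i)
  dplyr::arrange(out, .data$Source_Name, .data$Target_Name)
}
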