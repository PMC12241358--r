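# Taxonomy-based inference of species-level interactions: genus expansion
# (link 1), habitat/stratum-trimmed family expansion for generalist predator
# families and polylectic pollinators (link 2), feeding-guild links (link 3),
# nested-redundancy detection and provenance-merging assembly.

coarse_ranks <- function() {
  c("Genus", "Family", "Order", "Class", "Phylum", "Kingdom")
}

#' Expansion configuration
#'
#' Defaults mirror the construction rules: taxonomic inference is restricted
#' to the genus level except for generalist predator families and explicitly
#' polylectic pollinator species; family-level inferences are trimmed by
#' shared habitat and shared vertical stratum; a coarse record that expands
#' to at least one species-level record is dropped, otherwise retained.
#'
#' @param allow_family_expansion_for Which consumers may have family-level
#'   resources expanded: any of `"PredatorFamilies"`, `"PolylecticSpecies"`.
#' @param require_shared_habitat,require_shared_stratum Trim family-expanded
#'   records whose consumer and resource share no habitat / no stratum.
#' @param drop_expanded_coarse_record Drop the coarse record once it has
#'   produced at least one species-level record.
#' @return A list of class `expansion_config`.
#' @export
expansion_config <- function(allow_family_expansion_for =
                               c("PredatorFamilies", "PolylecticSpecies"),
                             require_shared_habitat = TRUE,
                             require_shared_stratum = TRUE,
                             drop_expanded_coarse_record = TRUE) {
  allow <- match.arg(allow_family_expansion_for,
                     c("PredatorFamilies", "PolylecticSpecies"),
                     several.ok = TRUE)
  structure(list(
    allow_family_expansion_for = allow,
    require_shared_habitat = isTRUE(require_shared_habitat),
    require_shared_stratum = isTRUE(require_shared_stratum),
    drop_expanded_coarse_record = isTRUE(drop_expanded_coarse_record)
  ), class = "expansion_config")
}

# checklist lookup helpers -----------------------------------------------

species_rows <- function(checklist) {
  checklist[checklist$Rank == "Species", , drop = FALSE]
}

species_in_group <- function(checklist, group_name, group_col) {
  sp <- species_rows(checklist)
  sp$Taxon[!is.na(sp[[group_col]]) & sp[[group_col]] == group_name]
}

taxon_sets <- function(checklist, names, col) {
  i <- match(names, checklist$Taxon)
  if (anyNA(i)) {
    stop("Name(s) not in checklist: ",
         paste(head(unique(names[is.na(i)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  checklist[[col]][i]
}

check_resolved <- function(records, checklist) {
  unresolved <- setdiff(unique(c(records$Source_Name, records$Target_Name)),
                        checklist$Taxon)
  if (length(unresolved) > 0L) {
    stop("Interaction name(s) not in checklist: ",
         paste(head(unresolved, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# build expanded copies of record row i with new endpoint names
expand_row <- function(records, i, side = c("target", "source"),
                       members, tag) {
  side <- match.arg(side)
  n <- length(members)
  out <- records[rep(i, n), , drop = FALSE]
  if (side == "target") {
    out$Target_Name <- members
    out$Target_Rank <- "Species"
  } else {
    out$Source_Name <- members
    out$Source_Rank <- "Species"
  }
  out$Inference <- tag
  out$ID_og <- records$ID_og[[i]]
  out$ID <- paste(out$Source_Name, "-", out$Target_Name)
  out
}

#' Expand genus-level interaction records to species level (link 1)
#'
#' Records whose resource is given at genus rank (consumer at species rank)
#' are replaced by one species-species record per checklist species in that
#' genus, tagged `Source_Species_Target_Genus`; the mirrored case (genus
#' consumer, species resource) is expanded the same way with the tag
#' `Source_Genus_Target_Species`. Genera with no checklist species leave the
#' coarse record untouched, so no information is lost. Citations, life
#' stages and interaction type are copied verbatim; `ID_og` keeps the
#' original pair.
#'
#' @param records Interaction tibble (see [as_interactions()]).
#' @param checklist Checklist tibble.
#' @param config An [expansion_config()].
#' @return The full record tibble with eligible rows expanded. The attribute
#'   `"expansion"` carries bookkeeping counts (`n_coarse_expanded`,
#'   `n_coarse_retained`, `n_new`).
#' @export
expand_genus_links <- function(records, checklist,
                               config = expansion_config()) {
  check_resolved(records, checklist)
  tgt <- records$Source_Rank == "Species" & records$Target_Rank == "Genus"
  src <- records$Source_Rank == "Genus" & records$Target_Rank == "Species"
  keep <- vector("list", nrow(records))
  n_expanded <- 0L
  n_retained <- 0L
  n_new <- 0L
  for (i in seq_len(nrow(records))) {
    if (tgt[i] || src[i]) {
      side <- if (tgt[i]) "target" else "source"
      genus <- if (tgt[i]) records$Target_Name[[i]] else
        records$Source_Name[[i]]
      members <- species_in_group(checklist, genus, "Genus")
      if (length(members) == 0L) {
        keep[[i]] <- records[i, , drop = FALSE]
        n_retained <- n_retained + 1L
      } else {
        tag <- if (tgt[i]) "Source_Species_Target_Genus" else
          "Source_Genus_Target_Species"
        new <- expand_row(records, i, side, members, tag)
        n_new <- n_new + nrow(new)
        if (config$drop_expanded_coarse_record) {
          keep[[i]] <- new
          n_expanded <- n_expanded + 1L
        } else {
          keep[[i]] <- dplyr::bind_rows(records[i, , drop = FALSE], new)
        }
      }
    } else {
      keep[[i]] <- records[i, , drop = FALSE]
    }
  }
  out <- dplyr::bind_rows(keep)
  attr(out, "expansion") <- list(n_coarse_expanded = n_expanded,
                                 n_coarse_retained = n_retained,
                                 n_new = n_new)
  out
}

shares_habitat_stratum <- function(checklist, a, b, config) {
  hab_a <- taxon_sets(checklist, a, "Habitat")
  hab_b <- taxon_sets(checklist, b, "Habitat")
  zon_a <- taxon_sets(checklist, a, "Zone")
  zon_b <- taxon_sets(checklist, b, "Zone")
  ok <- rep(TRUE, length(a))
  if (config$require_shared_habitat) {
    ok <- ok & purrr::map2_lgl(hab_a, hab_b,
                               ~ length(intersect(.x, .y)) > 0L)
  }
  if (config$require_shared_stratum) {
    ok <- ok & purrr::map2_lgl(zon_a, zon_b,
                               ~ length(intersect(.x, .y)) > 0L)
  }
  ok
}

#' Expand family-level resource records for eligible consumers (link 2)
#'
#' Records with a species-rank consumer and a family-rank resource are
#' expanded to all checklist species of the family, but only when the
#' consumer is licensed: its family is listed with diet range `Predator`
#' (generalist predator family) or the consumer itself is listed
#' `Polylectic` (pollinator with documented broad floral diet). Expanded
#' records in which consumer and resource share no habitat or no vertical
#' stratum are then removed. Family records of non-eligible consumers are
#' retained at coarse resolution, untouched; an eligible record whose
#' expansion is entirely trimmed away is likewise retained.
#'
#' @inheritParams expand_genus_links
#' @param diet_ranges Diet-range tibble (see [as_diet_ranges()]).
#' @return As [expand_genus_links()]; expanded rows carry the tag
#'   `Source_Species_Target_Family`.
#' @export
expand_family_links <- function(records, checklist, diet_ranges,
                                config = expansion_config()) {
  check_resolved(records, checklist)
  diet_ranges <- as_diet_ranges(diet_ranges)
  predator_families <- if ("PredatorFamilies" %in%
                           config$allow_family_expansion_for) {
    diet_ranges$Taxon[diet_ranges$Range == "Predator" &
                      diet_ranges$Rank == "Family"]
  } else character(0)
  polylectic_species <- if ("PolylecticSpecies" %in%
                            config$allow_family_expansion_for) {
    diet_ranges$Taxon[diet_ranges$Range == "Polylectic"]
  } else character(0)

  cand <- records$Source_Rank == "Species" & records$Target_Rank == "Family"
  src_family <- rep(NA_character_, nrow(records))
  if (any(cand)) {
    src_family[cand] <- checklist$Family[
      match(records$Source_Name[cand], checklist$Taxon)]
  }
  eligible <- cand & ((!is.na(src_family) & src_family %in% predator_families) |
                        records$Source_Name %in% polylectic_species)

  keep <- vector("list", nrow(records))
  n_expanded <- 0L
  n_retained <- 0L
  n_new <- 0L
  for (i in seq_len(nrow(records))) {
    if (!eligible[i]) {
      keep[[i]] <- records[i, , drop = FALSE]
      next
    }
    members <- species_in_group(checklist, records$Target_Name[[i]], "Family")
    if (length(members) > 0L) {
      ok <- shares_habitat_stratum(
        checklist, rep(records$Source_Name[[i]], length(members)),
        members, config)
      members <- members[ok]
    }
    if (length(members) == 0L) {
      keep[[i]] <- records[i, , drop = FALSE]
      n_retained <- n_retained + 1L
    } else {
      new <- expand_row(records, i, "target", members,
                        "Source_Species_Target_Family")
      n_new <- n_new + nrow(new)
      if (config$drop_expanded_coarse_record) {
        keep[[i]] <- new
        n_expanded <- n_expanded + 1L
      } else {
        keep[[i]] <- dplyr::bind_rows(records[i, , drop = FALSE], new)
      }
    }
  }
  out <- dplyr::bind_rows(keep)
  attr(out, "expansion") <- list(n_coarse_expanded = n_expanded,
                                 n_coarse_retained = n_retained,
                                 n_new = n_new)
  out
}

#' Create feeding-guild links for guild-consumer families (link 3)
#'
#' For families documented as generalist feeders on a basal feeding guild
#' (diet range `Basal`), connect every checklist species of the family to
#' the guild node(s) named in `guild_map`. This keeps guild-feeding
#' information at species resolution without aggregating the family.
#'
#' @param guild_consumers Diet-range tibble; only rows with
#'   `Range == "Basal"` are used. Each names a family (or a single species)
#'   and carries the documenting citation(s).
#' @param checklist Checklist tibble; guild nodes must be present with rank
#'   `Guild`.
#' @param guild_map Data frame mapping `Taxon` (the consumer family) to
#'   `Guild` (the resource guild node name); one row per pair.
#' @return New interaction records tagged `Source_Family_Target_Guild`, one
#'   per species x guild; `ID_og` records the family-guild pair.
#' @export
expand_guild_links <- function(guild_consumers, checklist, guild_map) {
  guild_consumers <- as_diet_ranges(guild_consumers)
  basal <- guild_consumers[guild_consumers$Range == "Basal", , drop = FALSE]
  guild_map <- tibble::as_tibble(guild_map)
  if (nrow(basal) == 0L || nrow(guild_map) == 0L) {
    return(as_interactions(tibble::tibble(
      Source_Name = character(0), Target_Name = character(0),
      Source_Rank = character(0), Target_Rank = character(0))))
  }
  stopifnot(all(c("Taxon", "Guild") %in% names(guild_map)))
  guild_nodes <- checklist$Taxon[checklist$Rank == "Guild"]
  bad <- setdiff(unique(guild_map$Guild), guild_nodes)
  if (length(bad) > 0L) {
    stop("Guild name(s) absent from checklist guild nodes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(basal))) {
    fam <- basal$Taxon[[i]]
    guilds <- guild_map$Guild[guild_map$Taxon == fam]
    if (length(guilds) == 0L) next
    members <- if (basal$Rank[[i]] == "Species") fam else
      species_in_group(checklist, fam, "Family")
    if (length(members) == 0L) next
    grid <- tidyr::expand_grid(Source_Name = members, Target_Name = guilds)
    grid$Source_Rank <- "Species"
    grid$Target_Rank <- "Guild"
    grid$Inference <- "Source_Family_Target_Guild"
    grid$Citation <- rep(list(basal$Citation[[i]]), nrow(grid))
    grid$ID_og <- paste(fam, "-", grid$Target_Name)
    rows[[length(rows) + 1L]] <- grid
  }
  if (length(rows) == 0L) {
    return(as_interactions(tibble::tibble(
      Source_Name = character(0), Target_Name = character(0),
      Source_Rank = character(0), Target_Rank = character(0))))
  }
  as_interactions(dplyr::bind_rows(rows))
}

#' Find hierarchically nested redundant records
#'
#' A coarse-rank record (at least one endpoint above species rank) is
#' redundant when its (consumer, resource) pair is hierarchically covered by
#' at least one species-species record: the fine endpoints match and the
#' coarse endpoint contains the covering species (e.g. genus A eating
#' species C is covered by species B eating C when B is within A).
#'
#' @inheritParams expand_genus_links
#' @return A tibble with one row per (coarse record, covering record) pair:
#'   columns `coarse_id`, `covering_id` (interaction `ID` strings).
#' @export
find_nested_redundancies <- function(records, checklist) {
  check_resolved(records, checklist)
  sp_idx <- match(records$Source_Name, checklist$Taxon)
  tg_idx <- match(records$Target_Name, checklist$Taxon)
  anc_cols <- c(Species = NA, Genus = "Genus", Family = "Family",
                Order = "Order", Class = "Class", Phylum = "Phylum",
                Kingdom = "Kingdom")
  # all rank-generalisations of a species name (itself + ancestors)
  generalise <- function(name) {
    i <- match(name, checklist$Taxon)
    if (checklist$Rank[[i]] != "Species") return(name)
    anc <- unlist(checklist[i, c("Genus", "Family", "Order", "Class",
                                 "Phylum", "Kingdom")], use.names = FALSE)
    unique(c(name, anc[!is.na(anc)]))
  }
  is_coarse <- checklist$Rank[sp_idx] %in% coarse_ranks() |
    checklist$Rank[tg_idx] %in% coarse_ranks()
  is_fine <- checklist$Rank[sp_idx] == "Species" &
    checklist$Rank[tg_idx] == "Species"
  if (!any(is_coarse) || !any(is_fine)) {
    return(tibble::tibble(coarse_id = character(0),
                          covering_id = character(0)))
  }
  gen <- purrr::map_dfr(which(is_fine), function(i) {
    tidyr::expand_grid(src = generalise(records$Source_Name[[i]]),
                       tgt = generalise(records$Target_Name[[i]]),
                       covering_id = records$ID[[i]])
  })
  coarse <- tibble::tibble(src = records$Source_Name[is_coarse],
                           tgt = records$Target_Name[is_coarse],
                           coarse_id = records$ID[is_coarse])
  out <- dplyr::inner_join(coarse, gen, by = c("src", "tgt"),
                           relationship = "many-to-many")
  dplyr::distinct(dplyr::arrange(out[, c("coarse_id", "covering_id")],
                                 .data$coarse_id, .data$covering_id))
}

#' Assemble a metaweb from empirical and inferred records
#'
#' Deduplicates on the (consumer, resource) pair. When an empirical record
#' collides with inferred ones, the empirical record wins (its inference
#' stays empirical, i.e. `NA`; its interaction type and life stages are
#' kept) and the citation sets are merged. Collisions among inferred records
#' merge citations and keep the first record in a deterministic
#' (tag, original-pair) order. Conflicting interaction types are resolved in
#' favour of the kept record and reported via a message.
#'
#' @param empirical,inferred Interaction tibbles.
#' @param checklist Checklist tibble; all endpoints must resolve.
#' @return A list: `web` (a [metaweb()]) and `n_merged` (records removed by
#'   deduplication).
#' @export
assemble_metaweb <- function(empirical, inferred, checklist) {
  all_rec <- dplyr::bind_rows(empirical, inferred)
  check_resolved(all_rec, checklist)
  if (nrow(all_rec) == 0L) {
    return(list(web = metaweb(checklist, all_rec), n_merged = 0L))
  }
  all_rec$.emp <- is.na(all_rec$Inference)
  # deterministic keep-order: empirical first, then by tag and original pair
  all_rec <- dplyr::arrange(
    all_rec, .data$Source_Name, .data$Target_Name,
    dplyr::desc(.data$.emp), .data$Inference, .data$ID_og)
  grp <- dplyr::group_by(all_rec, .data$Source_Name, .data$Target_Name)
  n_type_conflicts <- sum(dplyr::summarise(
    grp, n = dplyr::n_distinct(.data$Interaction_Type[
      !is.na(.data$Interaction_Type)]), .groups = "drop")$n > 1L)
  merged <- dplyr::summarise(
    grp,
    Source_Rank = .data$Source_Rank[[1L]],
    Target_Rank = .data$Target_Rank[[1L]],
    Source_Life_Stage = list(.data$Source_Life_Stage[[1L]]),
    Target_Life_Stage = list(.data$Target_Life_Stage[[1L]]),
    Citation = list(mw_set_int(unlist(.data$Citation))),
    Inference = .data$Inference[[1L]],
    Interaction_Type = .data$Interaction_Type[[1L]],
    ID = .data$ID[[1L]],
    ID_og = .data$ID_og[[1L]],
    .groups = "drop"
  )
  if (n_type_conflicts > 0L) {
    rlang::inform(paste0(n_type_conflicts,
      " merged pair(s) had conflicting interaction types;",
      " the retained record's type was kept."))
  }
  merged <- merged[interaction_cols()]
  list(web = metaweb(checklist, merged),
       n_merged = nrow(all_rec) - nrow(merged))
}

#' Run the full taxonomy-based expansion and assemble the metaweb
#'
#' Applies, in order: genus expansion (link 1), feeding-guild links from the
#' diet-range table (link 3), family expansion with habitat/stratum trimming
#' (link 2, which requires associations to be present on the checklist), and
#' assembly with provenance merging.
#'
#' @inheritParams expand_family_links
#' @param guild_map Family-to-guild map for [expand_guild_links()]; `NULL`
#'   to skip link 3.
#' @return A list: `web` (the assembled [metaweb()]) and `report`, a one-row
#'   tibble of bookkeeping counts that reconcile exactly:
#'   `n_input = n_fine_passthrough + n_coarse_expanded + n_retained_coarse`
#'   and `nrow(web) = n_input - n_coarse_expanded + n_expanded_link1 +
#'   n_expanded_link2 + n_expanded_link3 - n_redundant_removed`.
#' @export
expand_metaweb <- function(records, checklist, diet_ranges = NULL,
                           guild_map = NULL, config = expansion_config()) {
  records <- as_interactions(records)
  n_input <- nrow(records)
  n_emp_sp <- sum(records$Source_Rank == "Species" &
                  records$Target_Rank == "Species" &
                  is.na(records$Inference))
  coarse_in <- records$Source_Rank %in% coarse_ranks() |
    records$Target_Rank %in% coarse_ranks()

  step1 <- expand_genus_links(records, checklist, config)
  c1 <- attr(step1, "expansion")

  link3 <- if (!is.null(diet_ranges) && !is.null(guild_map)) {
    expand_guild_links(diet_ranges, checklist, guild_map)
  } else {
    step1[0, , drop = FALSE]
  }

  step2 <- if (!is.null(diet_ranges)) {
    expand_family_links(step1, checklist, diet_ranges, config)
  } else {
    out <- step1
    attr(out, "expansion") <- list(n_coarse_expanded = 0L,
                                   n_coarse_retained = 0L, n_new = 0L)
    out
  }
  c2 <- attr(step2, "expansion")

  asm <- assemble_metaweb(step2, link3, checklist)
  final <- asm$web$interactions
  n_retained_coarse <- sum(final$Source_Rank %in% coarse_ranks() |
                           final$Target_Rank %in% coarse_ranks())
  report <- tibble::tibble(
    n_input = n_input,
    n_empirical_species_level = n_emp_sp,
    n_coarse_input = sum(coarse_in),
    n_coarse_expanded = c1$n_coarse_expanded + c2$n_coarse_expanded,
    n_expanded_link1 = c1$n_new,
    n_expanded_link2 = c2$n_new,
    n_expanded_link3 = nrow(link3),
    n_retained_coarse = n_retained_coarse,
    n_redundant_removed = asm$n_merged,
    n_final = nrow(final)
  )
  list(web = asm$web, report = report)
}
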