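# End-to-end pipeline: ingest -> habitat/stratum association inference ->
# taxonomic expansion -> assembly -> diagnostics -> optional special cases.

#' Pipeline configuration
#'
#' Inputs may be in-memory data frames or file paths (paths are read with
#' the schema readers). Only `checklist` and `records` are required.
#'
#' @param checklist Checklist table or CSV path.
#' @param records Raw interaction table or CSV path.
#' @param diet_ranges,guild_map,special_cases Optional tables or paths.
#' @param points,patches Optional occurrence points and habitat patches for
#'   map-derived habitat counts (see [intersect_occurrences()]); a
#'   precomputed `habitat_counts` table may be given instead.
#' @param habitat_counts Optional `(species, habitat, count)` table.
#' @param literature Optional `(species, habitat)` literature associations.
#' @param true_basal,true_apex Taxon sets for [detect_improper_positions()].
#' @param vocab Vocabulary list from [metaweb_vocab()].
#' @param expansion An [expansion_config()].
#' @param association An [association_config()].
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed is used by any downstream sampling).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(checklist, records, diet_ranges = NULL,
                            guild_map = NULL, special_cases = NULL,
                            points = NULL, patches = NULL,
                            habitat_counts = NULL, literature = NULL,
                            true_basal = character(0),
                            true_apex = character(0),
                            vocab = metaweb_vocab(),
                            expansion = expansion_config(),
                            association = association_config(),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

maybe_read <- function(x, reader, ...) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

merge_associations <- function(checklist, assoc, column, flag_column) {
  i <- match(assoc$species, checklist$Taxon)
  for (k in seq_along(i)) {
    if (length(checklist[[column]][[i[[k]]]]) == 0L) {
      checklist[[column]][[i[[k]]]] <- assoc$labels[[k]]
      if (!is.na(assoc$inference[[k]]) &&
          assoc$inference[[k]] != "unresolved") {
        checklist[[flag_column]][[i[[k]]]] <- assoc$inference[[k]]
      }
    }
  }
  checklist
}

#' Run the metaweb construction pipeline
#'
#' Stage order: ingest; habitat association filtering from occurrence
#' counts (when points/patches or a count table are supplied) and
#' genus-then-family inference of missing habitat and stratum associations
#' (so every species has associations before trimming); taxonomic expansion
#' (genus links, guild links, then habitat/stratum-trimmed family links) and
#' assembly; gap diagnostics; optional special-case application followed by
#' re-diagnosis. The run manifest records the configuration, seed and
#' per-stage counts, which reconcile exactly (see [expand_metaweb()]).
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_result`: `web` (the final
#'   [metaweb()]), `checklist` (with inferred associations), `report`
#'   (expansion bookkeeping), `gaps` (pre-correction [detect_improper_positions()]
#'   report), `gaps_after` (post-special-case report, or `NULL`),
#'   `added_special` (records added by special cases), `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  checklist <- maybe_read(cfg$checklist, read_checklist, vocab = cfg$vocab)
  checklist <- as_checklist(checklist, vocab = cfg$vocab)
  records <- as_interactions(maybe_read(cfg$records, read_interactions))
  diet_ranges <- maybe_read(cfg$diet_ranges, read_diet_ranges)
  if (!is.null(diet_ranges)) diet_ranges <- as_diet_ranges(diet_ranges)
  special_cases <- maybe_read(cfg$special_cases, read_special_cases)

  # stage: habitat associations from occurrence data
  counts <- cfg$habitat_counts
  if (is.null(counts) && !is.null(cfg$points) && !is.null(cfg$patches)) {
    counts <- intersect_occurrences(cfg$points, cfg$patches)
  }
  n_map_assoc <- 0L
  if (!is.null(counts)) {
    filtered <- filter_habitat_associations(counts, cfg$literature,
                                            cfg$association)
    keep <- !filtered$needs_inference &
      filtered$species %in% checklist$Taxon
    filt <- filtered[keep, , drop = FALSE]
    filt$labels <- filt$habitats
    filt$inference <- NA_character_
    checklist <- merge_associations(checklist, filt, "Habitat",
                                    "Hab_Inference")
    n_map_assoc <- sum(keep)
  }

  # stage: genus-then-family inference of missing associations
  sp <- species_rows(checklist)
  hab_assoc <- tibble::tibble(species = sp$Taxon, labels = sp$Habitat)
  hab_assoc <- suppressWarnings(
    infer_missing_associations(hab_assoc, checklist))
  checklist <- merge_associations(checklist, hab_assoc, "Habitat",
                                  "Hab_Inference")
  zone_assoc <- tibble::tibble(species = sp$Taxon, labels = sp$Zone)
  zone_assoc <- suppressWarnings(
    infer_missing_associations(zone_assoc, checklist))
  checklist <- merge_associations(checklist, zone_assoc, "Zone",
                                  "Zone_Inference")

  # stage: expansion and assembly
  exp <- expand_metaweb(records, checklist, diet_ranges, cfg$guild_map,
                        cfg$expansion)

  # stage: diagnostics
  gaps <- detect_improper_positions(exp$web, cfg$true_basal, cfg$true_apex)

  # stage: special cases (optional), then re-diagnosis
  web <- exp$web
  added <- web$interactions[0, , drop = FALSE]
  gaps_after <- NULL
  if (!is.null(special_cases) && nrow(special_cases) > 0L) {
    sc <- apply_special_cases(web, special_cases, checklist)
    web <- sc$web
    added <- sc$added
    gaps_after <- detect_improper_positions(web, cfg$true_basal,
                                            cfg$true_apex)
  }

  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("metawebr")),
    n_taxa = nrow(checklist),
    n_species = nrow(sp),
    n_map_associations = n_map_assoc,
    n_habitat_inferred = sum(!is.na(hab_assoc$inference) &
                               hab_assoc$inference != "unresolved"),
    n_stratum_inferred = sum(!is.na(zone_assoc$inference) &
                               zone_assoc$inference != "unresolved"),
    expansion = as.list(exp$report),
    gaps = as.list(gaps$counts),
    n_special_added = nrow(added),
    association_config = unclass(cfg$association),
    expansion_config = unclass(cfg$expansion)
  )
  structure(list(web = web, checklist = checklist, report = exp$report,
                 gaps = gaps, gaps_after = gaps_after,
                 added_special = added, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$web)
  print(x$gaps)
  invisible(x)
}
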