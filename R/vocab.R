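# Controlled vocabularies: habitat classes, vertical strata, taxonomic ranks,
# life stages, plant life forms and the feeding-type translation table.

#' Default habitat class vocabulary
#'
#' The nine top-level classes of the Swiss habitat typology used to describe
#' broad habitat associations. Any downstream filter only requires that the
#' checklist and occurrence tables use a consistent closed vocabulary, so the
#' labels can be replaced wholesale via [metaweb_vocab()].
#'
#' @return Character vector of nine habitat class names.
#' @export
#' @examples
#' metaweb_habitats()
metaweb_habitats <- function() {
  c(
    "Waters",
    "Shores and wetlands",
    "Glaciers, rock and scree",
    "Grassland",
    "Fringes and scrub",
    "Forest",
    "Ruderal",
    "Crops and plantations",
    "Buildings"
  )
}

#' Default vertical stratum vocabulary
#'
#' Eleven positions a species can occupy within a habitat. "in vegetation"
#' is kept distinct from "on vegetation" to separate endophagous species
#' (unavailable to surface feeders) from free-living ones.
#'
#' @return Character vector of eleven stratum labels.
#' @export
metaweb_strata <- function() {
  c(
    "on ground or in leaf litter",
    "on vegetation",
    "in ground",
    "in water",
    "on host",
    "in dwellings",
    "in air",
    "in host nest",
    "in vegetation",
    "on fungi",
    "in caves"
  )
}

#' Taxonomic rank vocabulary
#'
#' Ranks recognised in checklists and interaction tables. `Guild` marks
#' non-taxonomic basal resource nodes (Fungi, Detritus, POM, ...) so that
#' they are never targeted by taxonomic expansion.
#'
#' @return Character vector of rank labels.
#' @export
metaweb_ranks <- function() {
  c("Species", "Genus", "Family", "Order", "Class", "Phylum", "Kingdom",
    "Guild")
}

#' Life stage vocabulary
#' @return Character vector: Egg, Young, Adult (in life order).
#' @export
metaweb_life_stages <- function() c("Egg", "Young", "Adult")

#' Bundle habitat and stratum vocabularies
#'
#' @param habitats Character vector of allowed habitat class labels.
#' @param strata Character vector of allowed stratum labels.
#' @return A list with elements `habitats` and `strata`.
#' @export
metaweb_vocab <- function(habitats = metaweb_habitats(),
                          strata = metaweb_strata()) {
  stopifnot(is.character(habitats), is.character(strata),
            !anyDuplicated(habitats), !anyDuplicated(strata))
  list(habitats = habitats, strata = strata)
}

#' Default life-stage synonym map
#'
#' Maps raw life-stage labels to the three canonical stages. All larval
#' stages collapse onto "Young"; "Adult" refers to the imaginal stage for
#' insects. The map is a named character vector (names = lower-case raw
#' labels) and can be extended or replaced in [normalize_life_stage()].
#'
#' @return Named character vector mapping raw labels to canonical stages.
#' @export
life_stage_synonyms <- function() {
  c(
    egg = "Egg", eggs = "Egg", ova = "Egg",
    young = "Young", larva = "Young", larvae = "Young", nymph = "Young",
    nymphs = "Young", caterpillar = "Young", juvenile = "Young",
    tadpole = "Young", pupa = "Young", instar = "Young",
    adult = "Adult", adults = "Adult", imago = "Adult", imagines = "Adult"
  )
}

#' Default Raunkiaer life-form vocabulary
#' @return Character vector of recognised plant life forms.
#' @export
raunkiaer_life_forms <- function() {
  c("phanerophyte", "chamaephyte", "hemicryptophyte", "geophyte",
    "therophyte", "helophyte", "hydrophyte", "pleustophyte", "epiphyte")
}

#' Freshwater feeding-type translation table
#'
#' Translation of the ten freshwater macroinvertebrate feeding-type classes
#' (Moog classification) into basal feeding guilds, plus the interaction
#' type implied where the class is animal-directed. "other feeding type"
#' translates to no guild and is discarded at ingest.
#'
#' @return A tibble with columns `feeding_type`, `guilds` (list column of
#'   character vectors) and `interaction_type` (`NA` where unspecified).
#' @export
#' @examples
#' moog_translation()
moog_translation <- function() {
  tibble::tibble(
    feeding_type = c(
      "grazers/scrapers", "miners", "xylophagous", "shredders",
      "gatherers/collectors", "active filter feeders",
      "passive filter feeders", "predators", "parasites",
      "other feeding type"
    ),
    guilds = list(
      c("Algae", "Detritus", "POM"),
      c("Algae", "Plantae"),
      "Detritus",
      c("Plantae", "POM", "Detritus"),
      "POM",
      c("POM", "Microprey"),
      c("POM", "Microprey"),
      "Animalia",
      "Animalia",
      character(0)
    ),
    interaction_type = c(NA, NA, NA, NA, NA, NA, NA,
                         "Predation", "Parasitism", NA)
  )
}

#' Translate a freshwater feeding-type class into feeding guilds
#'
#' @param feeding_type A single feeding-type label (case-insensitive).
#' @param table Translation table as produced by [moog_translation()].
#' @return A list with `guilds` (character vector, possibly empty meaning
#'   the class carries no usable diet information and is discarded) and
#'   `interaction_type` (`NA` unless the class implies one).
#' @export
#' @examples
#' translate_moog_feeding_type("shredders")
#' translate_moog_feeding_type("parasites")
translate_moog_feeding_type <- function(feeding_type,
                                        table = moog_translation()) {
  stopifnot(is.character(feeding_type), length(feeding_type) == 1L)
  key <- tolower(trimws(feeding_type))
  i <- match(key, table$feeding_type)
  if (is.na(i)) {
    stop("Unknown feeding-type class: '", feeding_type, "'", call. = FALSE)
  }
  list(guilds = table$guilds[[i]],
       interaction_type = table$interaction_type[[i]])
}

#' Normalise a raw life-stage label to the canonical stage set
#'
#' Raw labels may be composite ("Egg, Young and Adult"); components are
#' split on commas, slashes, ampersands and the word "and", then mapped
#' through the synonym table. Unmapped components are dropped with a
#' warning; a label with no mappable component returns `NA` (missing),
#' the lenient behaviour expected during bulk ingest.
#'
#' @param raw_label Single character label, or `NA`.
#' @param synonyms Named character vector as [life_stage_synonyms()].
#' @return Character vector of canonical stages in life order (subset of
#'   Egg, Young, Adult), or `NA_character_` when nothing maps.
#' @export
#' @examples
#' normalize_life_stage("larva")
#' normalize_life_stage("Egg, Young and Adult")
normalize_life_stage <- function(raw_label, synonyms = life_stage_synonyms()) {
  if (length(raw_label) != 1L) {
    stop("normalize_life_stage() takes a single label", call. = FALSE)
  }
  if (is.na(raw_label) || !nzchar(trimws(raw_label))) {
    return(NA_character_)
  }
  parts <- strsplit(raw_label, "\\s*(,|/|&|\\band\\b)\\s*")[[1]]
  parts <- tolower(trimws(parts))
  parts <- parts[nzchar(parts)]
  canon <- metaweb_life_stages()
  mapped <- character(0)
  for (p in parts) {
    hit <- if (p %in% tolower(canon)) {
      canon[match(p, tolower(canon))]
    } else {
      unname(synonyms[p])
    }
    if (is.null(hit) || is.na(hit)) {
      warning("Unmapped life-stage label component: '", p, "'", call. = FALSE)
    } else {
      mapped <- c(mapped, hit)
    }
  }
  if (length(mapped) == 0L) return(NA_character_)
  canon[canon %in% mapped]
}

#' Map a Raunkiaer plant life form to vertical strata
#'
#' Hydrophytes and pleustophytes live "in water"; epiphytes "on vegetation";
#' all other life forms occupy the three terrestrial plant strata so that
#' animals classified "on vegetation" can be matched against vegetation.
#'
#' @param life_form Single life-form label (case-insensitive), from
#'   [raunkiaer_life_forms()].
#' @return Character vector of stratum labels.
#' @export
#' @examples
#' map_raunkiaer_to_strata("hydrophyte")
#' map_raunkiaer_to_strata("hemicryptophyte")
map_raunkiaer_to_strata <- function(life_form) {
  stopifnot(is.character(life_form), length(life_form) == 1L)
  lf <- tolower(trimws(life_form))
  if (!lf %in% raunkiaer_life_forms()) {
    stop("Unknown Raunkiaer life form: '", life_form, "'", call. = FALSE)
  }
  if (lf %in% c("hydrophyte", "pleustophyte")) {
    "in water"
  } else if (lf == "epiphyte") {
    "on vegetation"
  } else {
    c("on ground or in leaf litter", "in ground", "on vegetation")
  }
}
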