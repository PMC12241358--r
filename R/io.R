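# Schema-faithful readers/writers for the deposited table formats and the
# in-memory metaweb container. Set-valued cells (habitats, strata, citations,
# life stages) are list columns in memory and delimiter-joined strings on
# disk; both empty string and "NA" parse as missing.

# ---- set helpers -----------------------------------------------------------

mw_split <- function(cell, delim = ";") {
  if (length(cell) != 1L || is.na(cell) || !nzchar(trimws(cell)) ||
      identical(trimws(cell), "NA")) {
    return(character(0))
  }
  parts <- trimws(strsplit(cell, delim, fixed = TRUE)[[1]])
  parts[nzchar(parts) & parts != "NA"]
}

mw_join <- function(x, delim = "; ") {
  if (length(x) == 0L || all(is.na(x))) return(NA_character_)
  paste(x, collapse = delim)
}

mw_set_chr <- function(x) {
  x <- as.character(x)
  sort(unique(x[!is.na(x) & nzchar(x)]))
}

mw_set_int <- function(x) {
  x <- suppressWarnings(as.integer(x))
  sort(unique(x[!is.na(x)]))
}

# life stages keep life order, not alphabetical
mw_set_stage <- function(x) {
  canon <- metaweb_life_stages()
  canon[canon %in% x]
}

mw_chr <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (!nzchar(x) | x == "NA")] <- NA_character_
  x
}

checklist_cols <- function() {
  c("Taxon", "Rank", "Kingdom", "Phylum", "Class", "Order", "Family",
    "Genus", "Species", "Habitat", "Zone", "Count", "Hab_Citation",
    "Hab_Inference", "Zone_Citation", "Zone_Inference")
}

interaction_cols <- function() {
  c("Source_Name", "Target_Name", "Source_Rank", "Target_Rank",
    "Source_Life_Stage", "Target_Life_Stage", "Citation", "Inference",
    "Interaction_Type", "ID", "ID_og")
}

# ---- checklist -------------------------------------------------------------

#' Coerce a data frame to a canonical taxa checklist
#'
#' Validates the checklist schema: required columns, closed rank vocabulary,
#' habitat/stratum labels within `vocab`, unique taxon names, species rows
#' carrying genus and epithet, and guild rows carrying no taxonomy below
#' kingdom. String-valued multi-label cells are split on `delim` into list
#' columns; already-list columns are normalised to sorted sets.
#'
#' @param df Data frame with the checklist columns (`Taxon`, `Rank`,
#'   `Kingdom` ... `Species`, `Habitat`, `Zone`, `Count`, `Hab_Citation`,
#'   `Hab_Inference`, `Zone_Citation`, `Zone_Inference`). Missing
#'   set/provenance columns are created empty.
#' @param vocab Vocabulary list from [metaweb_vocab()].
#' @param delim Within-cell delimiter for multi-valued string cells.
#' @return A tibble, one row per taxon, with `Habitat`, `Zone`,
#'   `Hab_Citation`, `Zone_Citation` as list columns.
#' @export
as_checklist <- function(df, vocab = metaweb_vocab(), delim = ";") {
  df <- tibble::as_tibble(df)
  required <- c("Taxon", "Rank")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("Checklist is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  optional_chr <- c("Kingdom", "Phylum", "Class", "Order", "Family",
                    "Genus", "Species", "Hab_Inference", "Zone_Inference")
  for (col in optional_chr) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]] <- mw_chr(df[[col]])
  }
  if (!"Count" %in% names(df)) df$Count <- NA_integer_
  df$Count <- suppressWarnings(as.integer(df$Count))
  if (any(!is.na(df$Count) & df$Count < 0L)) {
    stop("Occurrence counts must be nonnegative", call. = FALSE)
  }

  to_set <- function(col, setter) {
    if (!col %in% names(df)) {
      return(purrr::map(seq_len(nrow(df)), ~ setter(character(0))))
    }
    x <- df[[col]]
    if (is.list(x)) {
      purrr::map(x, setter)
    } else {
      purrr::map(as.character(x), ~ setter(mw_split(.x, delim)))
    }
  }
  df$Habitat <- to_set("Habitat", mw_set_chr)
  df$Zone <- to_set("Zone", mw_set_chr)
  df$Hab_Citation <- to_set("Hab_Citation", mw_set_int)
  df$Zone_Citation <- to_set("Zone_Citation", mw_set_int)

  df$Taxon <- mw_chr(df$Taxon)
  if (any(is.na(df$Taxon))) stop("Empty taxon name in checklist", call. = FALSE)
  dup <- unique(df$Taxon[duplicated(df$Taxon)])
  if (length(dup) > 0L) {
    stop("Duplicate taxa in checklist: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_rank <- setdiff(unique(df$Rank), metaweb_ranks())
  if (length(bad_rank) > 0L) {
    stop("Unknown rank(s): ", paste(bad_rank, collapse = ", "), call. = FALSE)
  }
  bad_hab <- setdiff(unique(unlist(df$Habitat)), vocab$habitats)
  if (length(bad_hab) > 0L) {
    stop("Habitat label(s) outside vocabulary: ",
         paste(bad_hab, collapse = ", "), call. = FALSE)
  }
  bad_zone <- setdiff(unique(unlist(df$Zone)), vocab$strata)
  if (length(bad_zone) > 0L) {
    stop("Stratum label(s) outside vocabulary: ",
         paste(bad_zone, collapse = ", "), call. = FALSE)
  }
  sp <- df$Rank == "Species"
  if (any(sp & (is.na(df$Genus) | is.na(df$Species)))) {
    stop("Species-rank rows must carry Genus and species epithet",
         call. = FALSE)
  }
  gld <- df$Rank == "Guild"
  if (any(gld & !(is.na(df$Family) & is.na(df$Genus) & is.na(df$Species)))) {
    stop("Guild rows must carry no taxonomy below kingdom", call. = FALSE)
  }
  df[checklist_cols()]
}

#' Read a taxa checklist CSV
#'
#' @param path Path to a CSV with the checklist column headers.
#' @inheritParams as_checklist
#' @return A canonical checklist tibble (see [as_checklist()]).
#' @export
read_checklist <- function(path, vocab = metaweb_vocab(), delim = ";") {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = character(0), progress = FALSE)
  as_checklist(df, vocab = vocab, delim = delim)
}

# ---- interactions ----------------------------------------------------------

#' Coerce a data frame to a canonical interaction table
#'
#' Directed consumer-to-resource records. `Source` is always the consumer
#' and `Target` the resource. `ID` is recomputed as
#' `"Source_Name - Target_Name"`; `ID_og` (the pre-expansion pair) defaults
#' to `ID` for empirical rows (`Inference` missing).
#'
#' @param df Data frame with at least `Source_Name`, `Target_Name`,
#'   `Source_Rank`, `Target_Rank`. Life stage and citation columns may be
#'   delimiter-joined strings or list columns.
#' @param delim Within-cell delimiter for multi-valued string cells.
#' @return A tibble with `Source_Life_Stage`, `Target_Life_Stage`,
#'   `Citation` as list columns and `Inference` `NA` for empirical rows.
#' @export
as_interactions <- function(df, delim = ";") {
  df <- tibble::as_tibble(df)
  required <- c("Source_Name", "Target_Name", "Source_Rank", "Target_Rank")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("Interaction table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("Source_Name", "Target_Name", "Source_Rank", "Target_Rank")) {
    df[[col]] <- mw_chr(df[[col]])
  }
  if (any(is.na(df$Source_Name)) || any(is.na(df$Target_Name))) {
    stop("Empty source or target name in interaction table", call. = FALSE)
  }
  bad_rank <- setdiff(unique(c(df$Source_Rank, df$Target_Rank)),
                      metaweb_ranks())
  if (length(bad_rank) > 0L) {
    stop("Unknown rank(s) in interaction table: ",
         paste(bad_rank, collapse = ", "), call. = FALSE)
  }
  for (col in c("Inference", "Interaction_Type")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]] <- mw_chr(df[[col]])
  }
  to_set <- function(col, setter) {
    if (!col %in% names(df)) {
      return(purrr::map(seq_len(nrow(df)), ~ setter(character(0))))
    }
    x <- df[[col]]
    if (is.list(x)) purrr::map(x, setter)
    else purrr::map(as.character(x), ~ setter(mw_split(.x, delim)))
  }
  df$Source_Life_Stage <- to_set("Source_Life_Stage", mw_set_stage)
  df$Target_Life_Stage <- to_set("Target_Life_Stage", mw_set_stage)
  df$Citation <- to_set("Citation", mw_set_int)

  df$ID <- paste(df$Source_Name, "-", df$Target_Name)
  if (!"ID_og" %in% names(df)) df$ID_og <- NA_character_
  df$ID_og <- mw_chr(df$ID_og)
  empirical <- is.na(df$Inference)
  df$ID_og[empirical] <- df$ID[empirical]
  df$ID_og[is.na(df$ID_og)] <- df$ID[is.na(df$ID_og)]
  df[interaction_cols()]
}

#' Read an interaction records CSV
#'
#' @param path Path to a CSV with the interaction column headers (the
#'   `Inference`, `ID` and `ID_og` columns are optional for raw records).
#' @inheritParams as_interactions
#' @return A canonical interaction tibble (see [as_interactions()]).
#' @export
read_interactions <- function(path, delim = ";") {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = character(0), progress = FALSE)
  as_interactions(df, delim = delim)
}

# ---- auxiliary tables ------------------------------------------------------

#' Coerce/read the diet-range table
#'
#' One row per taxon whose diet breadth licenses expansion: `Range` is
#' `Predator` (generalist predator family), `Basal` (family feeding on a
#' basal guild) or `Polylectic` (pollinator species with documented broad
#' floral diet; species rank only).
#'
#' @param df Data frame with columns `Taxon`, `Range`, `Citation`, `Rank`.
#' @param delim Within-cell delimiter.
#' @return Tibble with `Citation` as an integer list column.
#' @export
as_diet_ranges <- function(df, delim = ";") {
  df <- tibble::as_tibble(df)
  miss <- setdiff(c("Taxon", "Range", "Rank"), names(df))
  if (length(miss) > 0L) {
    stop("Diet-range table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$Taxon <- mw_chr(df$Taxon)
  df$Range <- mw_chr(df$Range)
  df$Rank <- mw_chr(df$Rank)
  bad <- setdiff(unique(df$Range), c("Basal", "Predator", "Polylectic"))
  if (length(bad) > 0L) {
    stop("Unknown diet range value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$Range == "Polylectic" & df$Rank != "Species")) {
    stop("Polylectic entries must be at species rank", call. = FALSE)
  }
  if (any(df$Range %in% c("Predator", "Basal") &
          !df$Rank %in% c("Family", "Species"))) {
    stop("Predator/Basal entries must be at family or species rank",
         call. = FALSE)
  }
  if (!"Citation" %in% names(df)) df$Citation <- list(integer(0))
  x <- df$Citation
  df$Citation <- if (is.list(x)) purrr::map(x, mw_set_int) else
    purrr::map(as.character(x), ~ mw_set_int(mw_split(.x, delim)))
  df[c("Taxon", "Range", "Citation", "Rank")]
}

#' @rdname as_diet_ranges
#' @param path Path to a diet-range CSV.
#' @export
read_diet_ranges <- function(path, delim = ";") {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = character(0), progress = FALSE)
  as_diet_ranges(df, delim = delim)
}

#' Coerce/read the special-cases table
#'
#' Species whose missing diets or predators are filled from an ecologically
#' similar donor species. `Case` is `"Missing diets"` or
#' `"Missing predators"` (the compact forms `MissingDiets` /
#' `MissingPredators` are also accepted).
#'
#' @param df Data frame with columns `Taxon`, `Inference_Taxon`, `Citation`,
#'   `Case`.
#' @param delim Within-cell delimiter.
#' @return Tibble with normalised `Case` labels.
#' @export
as_special_cases <- function(df, delim = ";") {
  df <- tibble::as_tibble(df)
  miss <- setdiff(c("Taxon", "Inference_Taxon", "Case"), names(df))
  if (length(miss) > 0L) {
    stop("Special-cases table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$Taxon <- mw_chr(df$Taxon)
  df$Inference_Taxon <- mw_chr(df$Inference_Taxon)
  norm <- c("missing diets" = "Missing diets",
            "missingdiets" = "Missing diets",
            "missing predators" = "Missing predators",
            "missingpredators" = "Missing predators")
  key <- tolower(trimws(df$Case))
  if (any(!key %in% names(norm))) {
    stop("Unknown special case value(s): ",
         paste(unique(df$Case[!key %in% names(norm)]), collapse = ", "),
         call. = FALSE)
  }
  df$Case <- unname(norm[key])
  if (any(df$Taxon == df$Inference_Taxon)) {
    stop("Special case cannot use the taxon itself as the donor",
         call. = FALSE)
  }
  if (!"Citation" %in% names(df)) df$Citation <- list(integer(0))
  x <- df$Citation
  df$Citation <- if (is.list(x)) purrr::map(x, mw_set_int) else
    purrr::map(as.character(x), ~ mw_set_int(mw_split(.x, delim)))
  df[c("Taxon", "Inference_Taxon", "Citation", "Case")]
}

#' @rdname as_special_cases
#' @param path Path to a special-cases CSV.
#' @export
read_special_cases <- function(path, delim = ";") {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = character(0), progress = FALSE)
  as_special_cases(df, delim = delim)
}

#' Coerce/read the reference meta-dataset
#'
#' @param df Data frame with at least `Citation` (unique integer ID) and
#'   `Data_Type` (`Digital` or `Analogue`); other descriptive columns are
#'   passed through.
#' @return Tibble with integer `Citation`.
#' @export
as_references <- function(df) {
  df <- tibble::as_tibble(df)
  miss <- setdiff(c("Citation", "Data_Type"), names(df))
  if (length(miss) > 0L) {
    stop("Reference table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$Citation <- suppressWarnings(as.integer(df$Citation))
  if (any(is.na(df$Citation)) || anyDuplicated(df$Citation)) {
    stop("Citation IDs must be unique integers", call. = FALSE)
  }
  bad <- setdiff(unique(df$Data_Type), c("Digital", "Analogue"))
  if (length(bad) > 0L) {
    stop("Data_Type must be Digital or Analogue; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname as_references
#' @param path Path to a reference meta-dataset CSV.
#' @export
read_references <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = c("", "NA"), progress = FALSE)
  as_references(df)
}

#' Coerce/read the metaweb-summary comparison table
#'
#' One row per published metaweb: `Name`, `Richness` (species count),
#' `Mean_Total_Degree`, `SD_Total_Degree`, `Network_Type` (`bitrophic` or
#' `multitrophic`) and `Ecosystem`.
#'
#' @param df Data frame with those columns.
#' @return Validated tibble.
#' @export
as_metaweb_summaries <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("Name", "Richness", "Mean_Total_Degree", "SD_Total_Degree",
            "Network_Type")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("Summary table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"Ecosystem" %in% names(df)) df$Ecosystem <- NA_character_
  df$Richness <- as.numeric(df$Richness)
  df$Mean_Total_Degree <- as.numeric(df$Mean_Total_Degree)
  df$SD_Total_Degree <- as.numeric(df$SD_Total_Degree)
  if (any(df$Richness < 1) || any(df$SD_Total_Degree < 0, na.rm = TRUE)) {
    stop("Richness must be >= 1 and degree SD >= 0", call. = FALSE)
  }
  bad <- setdiff(unique(df$Network_Type), c("bitrophic", "multitrophic"))
  if (length(bad) > 0L) {
    stop("Network_Type must be bitrophic or multitrophic; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname as_metaweb_summaries
#' @param path Path to a summary CSV.
#' @export
read_metaweb_summaries <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = c("", "NA"), progress = FALSE)
  as_metaweb_summaries(df)
}

# ---- metaweb container -----------------------------------------------------

#' Construct a metaweb
#'
#' A metaweb bundles a taxa checklist with an interaction table under
#' referential integrity: every interaction endpoint resolves to exactly one
#' checklist row and each (consumer, resource) pair appears once.
#'
#' @param taxa Checklist tibble (see [as_checklist()]).
#' @param interactions Interaction tibble (see [as_interactions()]).
#' @return An object of class `metaweb`: a list with elements `taxa` and
#'   `interactions`.
#' @export
metaweb <- function(taxa, interactions) {
  web <- structure(list(taxa = tibble::as_tibble(taxa),
                        interactions = tibble::as_tibble(interactions)),
                   class = "metaweb")
  validate_metaweb(web)
  web
}

#' Validate metaweb invariants
#'
#' Checks referential integrity (all interaction endpoints resolve against
#' the checklist), pair uniqueness, non-empty names and the
#' `ID == "Source_Name - Target_Name"` identity.
#'
#' @param web A `metaweb`.
#' @return `web`, invisibly; errors on any violation.
#' @export
validate_metaweb <- function(web) {
  stopifnot(inherits(web, "metaweb"))
  taxa <- web$taxa
  ints <- web$interactions
  if (anyDuplicated(taxa$Taxon)) {
    stop("Duplicate taxa in metaweb checklist", call. = FALSE)
  }
  unresolved <- setdiff(unique(c(ints$Source_Name, ints$Target_Name)),
                        taxa$Taxon)
  if (length(unresolved) > 0L) {
    stop("Interaction name(s) not in checklist: ",
         paste(head(unresolved, 5L), collapse = ", "), call. = FALSE)
  }
  pair <- paste(ints$Source_Name, ints$Target_Name, sep = "\r")
  if (anyDuplicated(pair)) {
    stop("Duplicate (consumer, resource) pairs in metaweb", call. = FALSE)
  }
  bad_id <- ints$ID != paste(ints$Source_Name, "-", ints$Target_Name)
  if (any(bad_id)) {
    stop("Interaction ID must equal 'Source_Name - Target_Name'",
         call. = FALSE)
  }
  invisible(web)
}

#' @export
print.metaweb <- function(x, ...) {
  n_sp <- sum(x$taxa$Rank == "Species")
  cat("<metaweb> ", nrow(x$taxa), " taxa (", n_sp, " species), ",
      nrow(x$interactions), " interactions\n", sep = "")
  invisible(x)
}

#' One-row summary of a metaweb
#'
#' @param x A `metaweb`.
#' @param ... Unused.
#' @return A tibble with taxon, species, link and species-species link
#'   counts plus directed connectance (links / richness^2).
#' @exportS3Method generics::glance
glance.metaweb <- function(x, ...) {
  sp <- x$taxa$Taxon[x$taxa$Rank == "Species"]
  ints <- x$interactions
  ss <- sum(ints$Source_Name %in% sp & ints$Target_Name %in% sp)
  tibble::tibble(
    n_taxa = nrow(x$taxa),
    n_species = length(sp),
    n_links = nrow(ints),
    n_species_links = ss,
    connectance = nrow(ints) / nrow(x$taxa)^2
  )
}

# ---- metaweb writer/reader -------------------------------------------------

flatten_checklist <- function(taxa, delim = "; ") {
  taxa$Habitat <- purrr::map_chr(taxa$Habitat, mw_join, delim = delim)
  taxa$Zone <- purrr::map_chr(taxa$Zone, mw_join, delim = delim)
  taxa$Hab_Citation <- purrr::map_chr(taxa$Hab_Citation, mw_join,
                                      delim = delim)
  taxa$Zone_Citation <- purrr::map_chr(taxa$Zone_Citation, mw_join,
                                       delim = delim)
  taxa
}

flatten_interactions <- function(ints, delim = "; ") {
  ints$Source_Life_Stage <- purrr::map_chr(ints$Source_Life_Stage, mw_join,
                                           delim = delim)
  ints$Target_Life_Stage <- purrr::map_chr(ints$Target_Life_Stage, mw_join,
                                           delim = delim)
  ints$Citation <- purrr::map_chr(ints$Citation, mw_join, delim = delim)
  ints
}

#' Write a metaweb to a directory as two CSV files
#'
#' Writes `interactions.csv` and `checklist.csv` with the deposited column
#' layouts. Refuses to write a web that violates the metaweb invariants.
#' Set-valued cells are joined with `"; "`; missing values are written as
#' `NA`. [read_metaweb()] round-trips the result field-for-field.
#'
#' @param web A `metaweb`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metaweb <- function(web, dir) {
  validate_metaweb(web)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(flatten_checklist(web$taxa),
                   file.path(dir, "checklist.csv"), na = "NA")
  readr::write_csv(flatten_interactions(web$interactions),
                   file.path(dir, "interactions.csv"), na = "NA")
  invisible(dir)
}

#' Read a metaweb written by [write_metaweb()]
#'
#' @param dir Directory holding `checklist.csv` and `interactions.csv`.
#' @param vocab Vocabulary list from [metaweb_vocab()].
#' @return A `metaweb`.
#' @export
read_metaweb <- function(dir, vocab = metaweb_vocab()) {
  taxa <- read_checklist(file.path(dir, "checklist.csv"), vocab = vocab)
  ints <- read_interactions(file.path(dir, "interactions.csv"))
  metaweb(taxa, ints)
}
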