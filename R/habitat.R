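# Habitat and vertical-stratum association pipeline: occurrence-count
# intersection, threshold filters with a generalist/specialist split, and
# median-share inference for species without data.

#' Association filter configuration
#'
#' @param min_count_retain Minimum occurrence count for a map-derived
#'   habitat association to enter the candidate set (default 100).
#' @param generalist_threshold Number of candidate habitat associations at
#'   or above which a species is a habitat generalist (default 3).
#' @param specialist_min_count Minimum count for a specialist's map-derived
#'   association to be retained (default 5).
#' @param generalist_median_strict Generalists keep map-derived habitats
#'   with counts strictly above the median of their candidate counts
#'   (default `TRUE`); set `FALSE` for at-or-above.
#' @return A list of class `association_config`.
#' @export
association_config <- function(min_count_retain = 100L,
                               generalist_threshold = 3L,
                               specialist_min_count = 5L,
                               generalist_median_strict = TRUE) {
  stopifnot(min_count_retain >= 0, generalist_threshold >= 0,
            specialist_min_count >= 0)
  structure(list(
    min_count_retain = as.integer(min_count_retain),
    generalist_threshold = as.integer(generalist_threshold),
    specialist_min_count = as.integer(specialist_min_count),
    generalist_median_strict = isTRUE(generalist_median_strict)
  ), class = "association_config")
}

#' Count species occurrences per habitat from points and patches
#'
#' Intersects occurrence points with axis-aligned rectangular habitat
#' patches (the toy stand-in for a polygonal habitat map; patch borders are
#' inclusive). A point inside any patch of a habitat counts once towards
#' that habitat; a point inside overlapping patches of different habitats
#' increments each of them. Points outside all patches are ignored.
#'
#' @param points Data frame with columns `species`, `x`, `y`.
#' @param patches Data frame with columns `habitat`, `xmin`, `ymin`,
#'   `xmax`, `ymax`.
#' @return A tibble `(species, habitat, count)` with unique
#'   (species, habitat) rows, sorted.
#' @export
intersect_occurrences <- function(points, patches) {
  points <- tibble::as_tibble(points)
  patches <- tibble::as_tibble(patches)
  stopifnot(all(c("species", "x", "y") %in% names(points)),
            all(c("habitat", "xmin", "ymin", "xmax", "ymax") %in%
                  names(patches)))
  empty <- tibble::tibble(species = character(0), habitat = character(0),
                          count = integer(0))
  if (nrow(points) == 0L || nrow(patches) == 0L) return(empty)
  points$.pt <- seq_len(nrow(points))
  hits <- purrr::map_dfr(seq_len(nrow(patches)), function(j) {
    inside <- points$x >= patches$xmin[[j]] & points$x <= patches$xmax[[j]] &
      points$y >= patches$ymin[[j]] & points$y <= patches$ymax[[j]]
    tibble::tibble(.pt = points$.pt[inside],
                   species = points$species[inside],
                   habitat = patches$habitat[[j]])
  })
  if (nrow(hits) == 0L) return(empty)
  hits <- dplyr::distinct(hits, .data$.pt, .data$species, .data$habitat)
  out <- dplyr::count(hits, .data$species, .data$habitat, name = "count")
  out$count <- as.integer(out$count)
  dplyr::arrange(out, .data$species, .data$habitat)
}

#' Filter habitat associations by occurrence-count thresholds
#'
#' Composes the retention rules in order. Per species the candidate set is
#' the union of map-derived habitats with at least `min_count_retain`
#' occurrences and all literature-documented habitats (which are exempt
#' from every count threshold). Species with `generalist_threshold` or more
#' candidates are habitat generalists; they keep only map-derived candidates
#' with counts above the median of the candidate counts (literature-only
#' candidates enter the median with count 0). Specialists keep map-derived
#' candidates with at least `specialist_min_count` occurrences. Species
#' ending with an empty set are flagged for taxonomic inference.
#'
#' @param counts Tibble `(species, habitat, count)` as produced by
#'   [intersect_occurrences()] or read from a count table.
#' @param literature Optional data frame `(species, habitat)` of
#'   literature-documented associations.
#' @param config An [association_config()].
#' @return A tibble with one row per species: `species`, `habitats` (list
#'   column), `label` (`"generalist"`/`"specialist"`), `needs_inference`.
#' @export
filter_habitat_associations <- function(counts, literature = NULL,
                                        config = association_config()) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("species", "habitat", "count") %in% names(counts)))
  if (anyDuplicated(paste(counts$species, counts$habitat, sep = "\r"))) {
    stop("(species, habitat) must be unique in the count table",
         call. = FALSE)
  }
  if (any(counts$count < 0)) stop("Counts must be nonnegative", call. = FALSE)
  if (is.null(literature)) {
    literature <- tibble::tibble(species = character(0),
                                 habitat = character(0))
  }
  literature <- dplyr::distinct(tibble::as_tibble(literature),
                                .data$species, .data$habitat)
  all_species <- sort(unique(c(counts$species, literature$species)))
  out <- purrr::map_dfr(all_species, function(sp) {
    cnt <- counts[counts$species == sp, , drop = FALSE]
    lit <- literature$habitat[literature$species == sp]
    map_cand <- cnt$habitat[cnt$count >= config$min_count_retain]
    cand <- sort(union(map_cand, lit))
    label <- if (length(cand) >= config$generalist_threshold) {
      "generalist"
    } else {
      "specialist"
    }
    cand_counts <- cnt$count[match(cand, cnt$habitat)]
    cand_counts[is.na(cand_counts)] <- 0L
    if (label == "generalist") {
      med <- stats::median(cand_counts)
      keep_map <- if (config$generalist_median_strict) {
        map_cand[cnt$count[match(map_cand, cnt$habitat)] > med]
      } else {
        map_cand[cnt$count[match(map_cand, cnt$habitat)] >= med]
      }
    } else {
      keep_map <- map_cand[cnt$count[match(map_cand, cnt$habitat)] >=
                             config$specialist_min_count]
    }
    final <- sort(union(keep_map, lit))
    tibble::tibble(species = sp, habitats = list(final), label = label,
                   needs_inference = length(final) == 0L)
  })
  out
}

#' Infer missing associations from congeners or confamilials
#'
#' For each species with an empty association set, pools the association
#' sets of informed species in the same genus (then, failing that, the same
#' family): each label's share is the number of informed group members
#' carrying it, and labels whose share is at or above the median share over
#' the labels present in the group are assigned. Works identically for
#' habitat classes and for vertical strata.
#'
#' @param assocs Tibble `(species, labels)` where `labels` is a list column
#'   of character vectors; species with empty sets are the inference
#'   targets, the rest are donors.
#' @param checklist Checklist tibble used to group species by genus/family.
#' @param levels Inference levels to try, in order (default genus then
#'   family).
#' @return `assocs` with empty sets filled where possible, plus an
#'   `inference` column: `NA` for empirical rows, `"Genus"` or `"Family"`
#'   for inferred ones, and `"unresolved"` where no informed relative exists
#'   at either level (also reported via a warning).
#' @export
infer_missing_associations <- function(assocs, checklist,
                                       levels = c("genus", "family")) {
  assocs <- tibble::as_tibble(assocs)
  stopifnot(all(c("species", "labels") %in% names(assocs)))
  levels <- match.arg(levels, c("genus", "family"), several.ok = TRUE)
  sp <- species_rows(checklist)
  idx <- match(assocs$species, sp$Taxon)
  if (anyNA(idx)) {
    stop("Species not in checklist: ",
         paste(head(assocs$species[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  grp_cols <- c(genus = "Genus", family = "Family")
  informed <- lengths(assocs$labels) > 0L
  out_labels <- assocs$labels
  inference <- rep(NA_character_, nrow(assocs))
  for (i in which(!informed)) {
    done <- FALSE
    for (lv in levels) {
      grp_val <- sp[[grp_cols[[lv]]]][idx[[i]]]
      if (is.na(grp_val)) next
      donors <- which(informed &
                        sp[[grp_cols[[lv]]]][idx] == grp_val &
                        assocs$species != assocs$species[[i]])
      if (length(donors) == 0L) next
      shares <- table(unlist(assocs$labels[donors]))
      keep <- names(shares)[shares >= stats::median(as.numeric(shares))]
      out_labels[[i]] <- sort(keep)
      inference[[i]] <- if (lv == "genus") "Genus" else "Family"
      done <- TRUE
      break
    }
    if (!done) inference[[i]] <- "unresolved"
  }
  n_unres <- sum(inference == "unresolved", na.rm = TRUE)
  if (n_unres > 0L) {
    warning(n_unres, " species could not be inferred at any level",
            call. = FALSE)
  }
  assocs$labels <- out_labels
  assocs$inference <- inference
  assocs
}
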