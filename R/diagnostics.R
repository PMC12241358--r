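# Trophic-chain truncation diagnostics and gap-filling inferences.

#' Detect improper basal/apex positions and obligate cannibals
#'
#' Compares the taxa that appear basal or apex in the web against declared
#' true basal taxa (plants, basal feeding guilds) and true apex taxa (apex
#' predators and their parasites). A taxon never appearing as a consumer is
#' missing diet information (improper basal position) unless it is truly
#' basal; a taxon never appearing as a resource is missing predator
#' information (improper apex position) unless truly apex. Taxa whose only
#' records are self-loops are reported as obligate cannibals. Records are
#' consumer-to-resource throughout, so "no outgoing energy flow" corresponds
#' to never appearing as a resource here.
#'
#' @param web A [metaweb()].
#' @param true_basal,true_apex Character vectors of taxa declared truly
#'   basal/apex; must be present in the web's checklist.
#' @return A `gap_report`: list with `improper_apex`, `improper_basal`,
#'   `obligate_cannibals` (sorted character vectors) and `counts` (one-row
#'   tibble with the three set sizes and `n_taxa`).
#' @export
detect_improper_positions <- function(web, true_basal = character(0),
                                      true_apex = character(0)) {
  validate_metaweb(web)
  taxa <- web$taxa$Taxon
  missing_decl <- setdiff(c(true_basal, true_apex), taxa)
  if (length(missing_decl) > 0L) {
    stop("Declared taxa absent from the web: ",
         paste(head(missing_decl, 5L), collapse = ", "), call. = FALSE)
  }
  ints <- web$interactions
  consumers <- unique(ints$Source_Name)
  resources <- unique(ints$Target_Name)
  improper_basal <- sort(setdiff(setdiff(taxa, consumers), true_basal))
  improper_apex <- sort(setdiff(setdiff(taxa, resources), true_apex))
  self <- ints$Source_Name == ints$Target_Name
  non_self_involved <- unique(c(ints$Source_Name[!self],
                                ints$Target_Name[!self]))
  cannibals <- sort(setdiff(unique(ints$Source_Name[self]),
                            non_self_involved))
  structure(list(
    improper_apex = improper_apex,
    improper_basal = improper_basal,
    obligate_cannibals = cannibals,
    counts = tibble::tibble(
      n_taxa = length(taxa),
      n_improper_apex = length(improper_apex),
      n_improper_basal = length(improper_basal),
      n_obligate_cannibals = length(cannibals)
    )
  ), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report> ", x$counts$n_improper_apex, " improper apex, ",
      x$counts$n_improper_basal, " improper basal, ",
      x$counts$n_obligate_cannibals, " obligate cannibals (of ",
      x$counts$n_taxa, " taxa)\n", sep = "")
  invisible(x)
}

#' Tidy a gap report into (species, gap_type) rows
#'
#' @param x A `gap_report`.
#' @param ... Unused.
#' @return A tibble with columns `species` and `gap_type` (one of
#'   `improper_apex`, `improper_basal`, `obligate_cannibal`).
#' @exportS3Method generics::tidy
tidy.gap_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(species = x$improper_apex, gap_type = "improper_apex"),
    tibble::tibble(species = x$improper_basal, gap_type = "improper_basal"),
    tibble::tibble(species = x$obligate_cannibals,
                   gap_type = "obligate_cannibal")
  )
}

#' @exportS3Method generics::glance
glance.gap_report <- function(x, ...) x$counts

#' Write a gap report as CSV plus a JSON count summary
#'
#' @param x A `gap_report`.
#' @param csv_path,json_path Output paths; `NULL` to skip either.
#' @return `x`, invisibly.
#' @export
write_gap_report <- function(x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "gap_report"))
  if (!is.null(csv_path)) readr::write_csv(tidy(x), csv_path, na = "NA")
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(x$counts), json_path, auto_unbox = TRUE)
  }
  invisible(x)
}

special_case_tag <- function() "special_case"

#' Fill diet/predator gaps from ecologically similar donor species
#'
#' For a `"Missing diets"` case, the donor's consumer-side records are
#' copied to the gap species (it inherits the donor's diet); for
#' `"Missing predators"`, the donor's resource-side records are copied (it
#' inherits the donor's predators). Copies are tagged `special_case`, carry
#' the union of the donor record's citations and the case's citation, keep
#' the donor record's life stages and interaction type, and set `ID_og` to
#' the donor pair for traceability. Pairs already present in the web are
#' not duplicated, so the operation is idempotent; a donor without relevant
#' records yields a warning and no additions.
#'
#' @param web A [metaweb()].
#' @param cases Special-cases tibble (see [as_special_cases()]).
#' @param checklist Checklist used to resolve ranks; defaults to the web's.
#' @return A list: `web` (updated metaweb) and `added` (the new records).
#' @export
apply_special_cases <- function(web, cases, checklist = web$taxa) {
  validate_metaweb(web)
  cases <- as_special_cases(cases)
  ints <- web$interactions
  additions <- list()
  for (i in seq_len(nrow(cases))) {
    gap <- cases$Taxon[[i]]
    donor <- cases$Inference_Taxon[[i]]
    if (!all(c(gap, donor) %in% checklist$Taxon)) {
      stop("Special-case taxa not in checklist: ", gap, " / ", donor,
           call. = FALSE)
    }
    gap_rank <- checklist$Rank[match(gap, checklist$Taxon)]
    if (cases$Case[[i]] == "Missing diets") {
      src <- ints[ints$Source_Name == donor, , drop = FALSE]
      if (nrow(src) == 0L) {
        warning("Donor '", donor, "' has no diet records; case skipped",
                call. = FALSE)
        next
      }
      new <- src
      new$Source_Name <- gap
      new$Source_Rank <- gap_rank
    } else {
      src <- ints[ints$Target_Name == donor, , drop = FALSE]
      if (nrow(src) == 0L) {
        warning("Donor '", donor, "' has no predator records; case skipped",
                call. = FALSE)
        next
      }
      new <- src
      new$Target_Name <- gap
      new$Target_Rank <- gap_rank
    }
    new$Inference <- special_case_tag()
    new$ID_og <- src$ID
    new$ID <- paste(new$Source_Name, "-", new$Target_Name)
    new$Citation <- purrr::map(src$Citation,
                               ~ mw_set_int(c(.x, cases$Citation[[i]])))
    additions[[length(additions) + 1L]] <- new
  }
  added <- dplyr::bind_rows(additions)
  if (nrow(added) > 0L) {
    existing <- paste(ints$Source_Name, ints$Target_Name, sep = "\r")
    key <- paste(added$Source_Name, added$Target_Name, sep = "\r")
    added <- added[!key %in% existing & !duplicated(key), , drop = FALSE]
  }
  list(web = metaweb(web$taxa, dplyr::bind_rows(ints, added)), added = added)
}

#' Connect generalist consumers to every species of a prey family
#'
#' Implements broad gap-filling statements such as "hedgehogs feed on
#' diplopods": each named consumer is linked to every checklist species of
#' the prey family, optionally trimmed to pairs that share at least one
#' habitat and one vertical stratum. Existing pairs are not duplicated.
#'
#' @param web A [metaweb()].
#' @param prey_family Family name whose species become resources.
#' @param consumer_taxa Character vector of consumer taxon names.
#' @param checklist Checklist used for membership and associations;
#'   defaults to the web's.
#' @param trim_by_cooccurrence Drop pairs sharing no habitat or no stratum.
#' @param citation Citation ID(s) documenting the broad statement.
#' @return A list: `web` (updated metaweb) and `added` (the new records,
#'   tagged `special_case`).
#' @export
connect_family_to_generalist_consumers <- function(web, prey_family,
                                                   consumer_taxa,
                                                   checklist = web$taxa,
                                                   trim_by_cooccurrence = TRUE,
                                                   citation = integer(0)) {
  validate_metaweb(web)
  missing_names <- setdiff(consumer_taxa, checklist$Taxon)
  if (length(missing_names) > 0L) {
    stop("Consumer taxa not in checklist: ",
         paste(missing_names, collapse = ", "), call. = FALSE)
  }
  members <- species_in_group(checklist, prey_family, "Family")
  empty <- web$interactions[0, , drop = FALSE]
  if (length(members) == 0L || length(consumer_taxa) == 0L) {
    return(list(web = web, added = empty))
  }
  grid <- tidyr::expand_grid(Source_Name = sort(unique(consumer_taxa)),
                             Target_Name = members)
  if (trim_by_cooccurrence) {
    cfg <- expansion_config()
    ok <- shares_habitat_stratum(checklist, grid$Source_Name,
                                 grid$Target_Name, cfg)
    grid <- grid[ok, , drop = FALSE]
  }
  if (nrow(grid) == 0L) return(list(web = web, added = empty))
  grid$Source_Rank <- checklist$Rank[match(grid$Source_Name,
                                           checklist$Taxon)]
  grid$Target_Rank <- "Species"
  grid$Inference <- special_case_tag()
  grid$Citation <- rep(list(mw_set_int(citation)), nrow(grid))
  grid$ID_og <- paste(grid$Source_Name, "-", prey_family)
  added <- as_interactions(grid)
  added$ID_og <- paste(added$Source_Name, "-", prey_family)
  ints <- web$interactions
  existing <- paste(ints$Source_Name, ints$Target_Name, sep = "\r")
  key <- paste(added$Source_Name, added$Target_Name, sep = "\r")
  added <- added[!key %in% existing, , drop = FALSE]
  list(web = metaweb(web$taxa, dplyr::bind_rows(ints, added)), added = added)
}

#' Rank consumers by how many members of a focal group they consume
#'
#' Used to pick donors when inferring missing predators for a group (e.g.
#' the fish predators most commonly shared by caddisflies). Ties are broken
#' lexicographically by consumer name.
#'
#' @param web A [metaweb()].
#' @param focal_group Character vector of focal resource taxa.
#' @param k Number of top consumers to return (default all).
#' @return A tibble `(consumer, n_shared)` sorted by descending
#'   `n_shared`, then name.
#' @export
most_shared_consumers <- function(web, focal_group, k = Inf) {
  validate_metaweb(web)
  stopifnot(length(focal_group) > 0L)
  ints <- web$interactions
  hits <- ints[ints$Target_Name %in% focal_group &
                 ints$Source_Name != ints$Target_Name, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble::tibble(consumer = character(0), n_shared = integer(0)))
  }
  out <- dplyr::count(
    dplyr::distinct(hits, .data$Source_Name, .data$Target_Name),
    .data$Source_Name, name = "n_shared")
  out <- dplyr::arrange(out, dplyr::desc(.data$n_shared), .data$Source_Name)
  names(out)[1] <- "consumer"
  out$n_shared <- as.integer(out$n_shared)
  head(out, if (is.finite(k)) k else nrow(out))
}
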