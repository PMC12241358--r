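# Taxonomic expansion rules: genus links, trimmed family links, guild
# links, nested redundancies and assembly.

test_that("genus-level records expand to all checklist congeners", {
  cl <- tiny_checklist()
  # resource at genus rank: one record per species of GenB
  recs <- tiny_records(list(rec("GenA a1", "GenB", tgt_rank = "Genus")))
  out <- expand_genus_links(recs, cl)
  expect_setequal(out$Target_Name, c("GenB b1", "GenB b2"))
  expect_true(all(out$Inference == "Source_Species_Target_Genus"))
  expect_true(all(out$ID_og == "GenA a1 - GenB"))
  expect_true(all(out$ID == paste(out$Source_Name, "-", out$Target_Name)))

  # mirrored coarse consumer
  recs2 <- tiny_records(list(rec("GenA", "GenB b1", src_rank = "Genus")))
  out2 <- expand_genus_links(recs2, cl)
  expect_setequal(out2$Source_Name, c("GenA a1", "GenA a2"))
  expect_true(all(out2$Inference == "Source_Genus_Target_Species"))

  # genus with no checklist species is retained untouched
  cl2 <- dplyr::bind_rows(cl, as_checklist(tibble::tibble(
    Taxon = "GenC", Rank = "Genus", Family = "FamA", Genus = "GenC")))
  recs3 <- tiny_records(list(rec("GenA a1", "GenC", tgt_rank = "Genus")))
  out3 <- expand_genus_links(recs3, cl2)
  expect_equal(out3$Target_Name, "GenC")
  expect_true(is.na(out3$Inference))
})

test_that("family expansion is gated and trimmed by habitat and stratum", {
  cl <- tiny_checklist()
  preds <- as_diet_ranges(tibble::tibble(
    Taxon = "FamA", Range = "Predator", Citation = "9", Rank = "Family"))
  # consumer a1 lives in Forest / on vegetation; FamB = {b1 same, b2 Waters}
  recs <- tiny_records(list(rec("GenA a1", "FamB", tgt_rank = "Family")))
  out <- expand_family_links(recs, cl, preds)
  expect_equal(out$Target_Name, "GenB b1")
  expect_equal(out$Inference, "Source_Species_Target_Family")

  # ineligible consumer: record retained coarse, untouched
  preds_b <- as_diet_ranges(tibble::tibble(
    Taxon = "FamB", Range = "Predator", Citation = "9", Rank = "Family"))
  out2 <- expand_family_links(recs, cl, preds_b)
  expect_equal(out2$Target_Name, "FamB")
  expect_true(is.na(out2$Inference))

  # polylectic species expands a family-rank floral resource
  poly <- as_diet_ranges(tibble::tibble(
    Taxon = "GenA a1", Range = "Polylectic", Citation = "9",
    Rank = "Species"))
  out3 <- expand_family_links(recs, cl, poly)
  expect_equal(out3$Target_Name, "GenB b1")

  # trimming off keeps the whole family
  cfg <- expansion_config(require_shared_habitat = FALSE,
                          require_shared_stratum = FALSE)
  out4 <- expand_family_links(recs, cl, preds, cfg)
  expect_setequal(out4$Target_Name, c("GenB b1", "GenB b2"))
})

test_that("guild links connect every family member to its guilds", {
  cl <- tiny_checklist()
  basal <- as_diet_ranges(tibble::tibble(
    Taxon = "FamB", Range = "Basal", Citation = "7", Rank = "Family"))
  gm <- tibble::tibble(Taxon = "FamB", Guild = "Fungi")
  out <- expand_guild_links(basal, cl, gm)
  expect_setequal(out$Source_Name, c("GenB b1", "GenB b2"))
  expect_true(all(out$Target_Name == "Fungi"))
  expect_true(all(out$Inference == "Source_Family_Target_Guild"))
  expect_true(all(out$Target_Rank == "Guild"))
  expect_equal(out$Citation, list(7L, 7L))

  # empty guild map -> empty output
  expect_equal(nrow(expand_guild_links(basal, cl, gm[0, ])), 0L)
  # unknown guild node -> integrity error
  expect_error(expand_guild_links(basal, cl,
                                  tibble::tibble(Taxon = "FamB",
                                                 Guild = "Slime")),
               "Slime")
  # counting identity over random family structures
  set.seed(21)
  w <- generate_world(synthetic_spec(n_families = 5, seed = 21))
  fams <- unique(w$checklist_full$Family[!is.na(w$checklist_full$Family)])
  dr <- as_diet_ranges(tibble::tibble(Taxon = fams, Range = "Basal",
                                      Citation = "1", Rank = "Family"))
  gm2 <- tibble::tibble(Taxon = rep(fams, times = seq_along(fams) %% 2 + 1),
                        Guild = "Guild1")
  gm2 <- dplyr::distinct(gm2)
  out2 <- expand_guild_links(dr, w$checklist_full, gm2)
  sizes <- table(w$checklist_full$Family[
    w$checklist_full$Rank == "Species"])
  expected <- sum(sizes[unique(gm2$Taxon)])
  expect_equal(nrow(out2), as.integer(expected))
})

test_that("nested redundancies match a quadratic brute-force scan", {
  cl <- tiny_checklist()
  recs <- tiny_records(list(
    rec("GenA", "GenB b1", src_rank = "Genus"),
    rec("GenA a1", "GenB b1")))
  nested <- find_nested_redundancies(recs, cl)
  expect_equal(nested$coarse_id, "GenA - GenB b1")
  expect_equal(nested$covering_id, "GenA a1 - GenB b1")

  # disjoint genera -> empty
  recs2 <- tiny_records(list(
    rec("GenA", "GenB b1", src_rank = "Genus"),
    rec("GenB b2", "GenA a1")))
  expect_equal(nrow(find_nested_redundancies(recs2, cl)), 0L)

  # random records vs an O(n^2) oracle over record pairs
  for (s in 1:5) {
    w <- generate_world(synthetic_spec(n_records = 20,
                                       p_coarse_record = 0.6, seed = s))
    recs3 <- w$records
    cl3 <- w$checklist_full
    contains <- function(coarse, species) {
      i <- match(coarse, cl3$Taxon); j <- match(species, cl3$Taxon)
      if (cl3$Rank[[i]] == "Species") return(coarse == species)
      col <- cl3$Rank[[i]]
      col_val <- switch(col, Genus = cl3$Genus[[j]],
                        Family = cl3$Family[[j]], Order = cl3$Order[[j]],
                        NA_character_)
      !is.na(col_val) && col_val == coarse
    }
    expected <- list()
    for (a in seq_len(nrow(recs3))) {
      ra <- recs3[a, ]
      coarse_a <- !(ra$Source_Rank == "Species" &&
                      ra$Target_Rank == "Species") &&
        !(ra$Source_Rank %in% "Guild" || ra$Target_Rank %in% "Guild")
      if (!coarse_a) next
      for (b in seq_len(nrow(recs3))) {
        rb <- recs3[b, ]
        if (!(rb$Source_Rank == "Species" && rb$Target_Rank == "Species")) next
        if (contains(ra$Source_Name, rb$Source_Name) &&
            contains(ra$Target_Name, rb$Target_Name)) {
          expected[[length(expected) + 1L]] <-
            tibble::tibble(coarse_id = ra$ID, covering_id = rb$ID)
        }
      }
    }
    expected <- if (length(expected)) {
      dplyr::arrange(dplyr::bind_rows(expected), coarse_id, covering_id)
    } else {
      tibble::tibble(coarse_id = character(0), covering_id = character(0))
    }
    got <- find_nested_redundancies(recs3, cl3)
    expect_equal(as.data.frame(got), as.data.frame(expected))
  }
})

test_that("assembly dedups with empirical priority and merges citations", {
  cl <- tiny_checklist()
  emp <- tiny_records(list(
    rec("GenA a1", "GenB b1", citation = list(12L),
        Interaction_Type = "Predation")))
  inf <- tiny_records(list(
    rec("GenA a1", "GenB b1", citation = list(88L),
        inference = "Source_Species_Target_Genus",
        Interaction_Type = "Herbivory", ID_og = "GenA a1 - GenB"),
    rec("GenA a2", "GenB b2", citation = list(3L),
        inference = "Source_Species_Target_Genus",
        ID_og = "GenA a2 - GenB")))
  out <- suppressMessages(assemble_metaweb(emp, inf, cl))
  ints <- out$web$interactions
  expect_equal(nrow(ints), 2L)
  merged <- ints[ints$ID == "GenA a1 - GenB b1", ]
  expect_true(is.na(merged$Inference))           # empirical wins
  expect_equal(merged$Citation[[1]], c(12L, 88L)) # citations merged
  expect_equal(merged$Interaction_Type, "Predation")
  expect_equal(merged$ID_og, "GenA a1 - GenB b1")
  expect_equal(out$n_merged, 1L)

  # disjoint sets: simple union; assembling again changes nothing
  again <- assemble_metaweb(ints, ints[0, ], cl)
  expect_equal(as.data.frame(again$web$interactions), as.data.frame(ints))
})

test_that("full expansion matches the brute-force oracle on random worlds", {
  for (s in 1:25) {
    w <- generate_world(synthetic_spec(
      n_families = 3, genera_per_family = 2, species_per_genus = 3,
      n_records = 30, p_coarse_record = 0.5, seed = 100 + s))
    res <- expand_quiet(w$records, w$checklist_full, w$diet_ranges,
                        w$guild_map)
    expect_identical(triples(res$web$interactions),
                     as.data.frame(w$ground_truth))
  }
})

test_that("expansion is idempotent and conserves provenance", {
  w <- generate_world(synthetic_spec(seed = 33))
  r1 <- expand_quiet(w$records, w$checklist_full, w$diet_ranges, w$guild_map)
  r2 <- expand_quiet(r1$web$interactions, w$checklist_full, w$diet_ranges,
                     w$guild_map)
  expect_equal(as.data.frame(r2$web$interactions),
               as.data.frame(r1$web$interactions))

  # every output citation appears in some input record or diet entry
  in_cites <- unique(c(unlist(w$records$Citation),
                       unlist(w$diet_ranges$Citation)))
  expect_true(all(unlist(r1$web$interactions$Citation) %in% in_cites))

  # every empirical species-species input record survives unchanged
  emp <- w$records[w$records$Source_Rank == "Species" &
                     w$records$Target_Rank == "Species" &
                     is.na(w$records$Inference), ]
  out_ids <- r1$web$interactions$ID[is.na(r1$web$interactions$Inference)]
  expect_true(all(emp$ID %in% out_ids))

  # no self-invented pairs: every ID_og traces to an input or a guild entry
  valid_og <- c(w$records$ID_og,
                paste(w$guild_map$Taxon, "-", w$guild_map$Guild))
  expect_true(all(r1$web$interactions$ID_og %in% valid_og))
})

test_that("family-expanded records always share habitat and stratum", {
  for (s in c(2, 12)) {
    w <- generate_world(synthetic_spec(n_records = 60,
                                       p_coarse_record = 0.6, seed = s))
    res <- expand_quiet(w$records, w$checklist_full, w$diet_ranges,
                        w$guild_map)
    ints <- res$web$interactions
    fam <- ints[!is.na(ints$Inference) &
                  ints$Inference == "Source_Species_Target_Family", ]
    if (nrow(fam) == 0L) next
    cl <- w$checklist_full
    hab <- function(x) cl$Habitat[[match(x, cl$Taxon)]]
    zon <- function(x) cl$Zone[[match(x, cl$Taxon)]]
    for (i in seq_len(nrow(fam))) {
      expect_gte(length(intersect(hab(fam$Source_Name[[i]]),
                                  hab(fam$Target_Name[[i]]))), 1L)
      expect_gte(length(intersect(zon(fam$Source_Name[[i]]),
                                  zon(fam$Target_Name[[i]]))), 1L)
    }
  }
})
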