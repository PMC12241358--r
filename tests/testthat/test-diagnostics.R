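# Trophic-chain truncation diagnostics and special-case gap filling.

chain_web <- function(drop_bird = FALSE) {
  cl <- as_checklist(tibble::tibble(
    Taxon = c("Planta viridis", "Herbivora parva", "Avis major"),
    Rank = "Species",
    Family = c("FamP", "FamH", "FamA"),
    Genus = c("Planta", "Herbivora", "Avis"),
    Species = c("viridis", "parva", "major")))
  rows <- list(rec("Herbivora parva", "Planta viridis"))
  if (!drop_bird) rows <- c(rows, list(rec("Avis major", "Herbivora parva")))
  metaweb(cl, tiny_records(rows))
}

test_that("improper positions and obligate cannibals follow the definitions", {
  web <- chain_web()
  rep0 <- detect_improper_positions(web, true_basal = "Planta viridis",
                                    true_apex = "Avis major")
  expect_equal(rep0$improper_apex, character(0))
  expect_equal(rep0$improper_basal, character(0))
  expect_equal(rep0$obligate_cannibals, character(0))

  # removing the bird's record leaves the herbivore improperly apex,
  # and the bird (recordless) both improper basal and apex
  web2 <- chain_web(drop_bird = TRUE)
  rep2 <- detect_improper_positions(web2, true_basal = "Planta viridis",
                                    true_apex = character(0))
  expect_true("Herbivora parva" %in% rep2$improper_apex)
  expect_setequal(rep2$improper_basal, "Avis major")

  # a species whose only record is a self-loop is an obligate cannibal
  cl <- web$taxa
  selfy <- metaweb(cl, tiny_records(list(
    rec("Herbivora parva", "Herbivora parva"),
    rec("Avis major", "Planta viridis"))))
  rep3 <- detect_improper_positions(selfy)
  expect_equal(rep3$obligate_cannibals, "Herbivora parva")

  # declared taxa must exist
  expect_error(detect_improper_positions(web, true_basal = "Nemo nihil"),
               "absent")
})

test_that("diagnostics equal a brute-force edge-list pass on random webs", {
  for (s in 1:10) {
    web <- random_web(n_nodes = sample(20:100, 1), n_edges = 150, seed = s)
    taxa <- web$taxa$Taxon
    tb <- sample(taxa, 5)
    ta <- sample(taxa, 5)
    got <- detect_improper_positions(web, tb, ta)
    # brute force over the edge list
    ints <- web$interactions
    is_consumer <- vapply(taxa, function(t) any(ints$Source_Name == t),
                          logical(1))
    is_resource <- vapply(taxa, function(t) any(ints$Target_Name == t),
                          logical(1))
    exp_basal <- sort(setdiff(taxa[!is_consumer], tb))
    exp_apex <- sort(setdiff(taxa[!is_resource], ta))
    cann <- character(0)
    for (t in taxa) {
      mine <- ints[ints$Source_Name == t | ints$Target_Name == t, ]
      if (nrow(mine) > 0L &&
          all(mine$Source_Name == t & mine$Target_Name == t)) {
        cann <- c(cann, t)
      }
    }
    expect_equal(got$improper_basal, exp_basal)
    expect_equal(got$improper_apex, exp_apex)
    expect_equal(got$obligate_cannibals, sort(cann))
  }
})

test_that("gap reports tidy and serialise", {
  web <- chain_web(drop_bird = TRUE)
  rep0 <- detect_improper_positions(web)
  td <- tidy(rep0)
  expect_true(all(c("species", "gap_type") %in% names(td)))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_gap_report(rep0, csv, js)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), nrow(td))
  counts <- jsonlite::read_json(js)
  expect_equal(counts$n_taxa, 3L)
})

test_that("special cases copy donor diets/predators with provenance", {
  cl <- as_checklist(tibble::tibble(
    Taxon = c("Anguis fragilis", "Anguis vernonensis", "Limax cinereus",
              "Lumbricus terrestris"),
    Rank = "Species",
    Family = c("Anguidae", "Anguidae", "Limacidae", "Lumbricidae"),
    Genus = c("Anguis", "Anguis", "Limax", "Lumbricus"),
    Species = c("fragilis", "vernonensis", "cinereus", "terrestris")))
  web <- metaweb(cl, tiny_records(list(
    rec("Anguis fragilis", "Limax cinereus", citation = list(5L)),
    rec("Anguis fragilis", "Lumbricus terrestris", citation = list(6L)))))
  cases <- tibble::tibble(Taxon = "Anguis vernonensis",
                          Inference_Taxon = "Anguis fragilis",
                          Citation = "508", Case = "Missing diets")
  out <- apply_special_cases(web, cases)
  expect_equal(nrow(out$added), 2L)
  expect_setequal(out$added$Target_Name,
                  c("Limax cinereus", "Lumbricus terrestris"))
  expect_true(all(out$added$Inference == "special_case"))
  expect_true(all(vapply(out$added$Citation, function(x) 508L %in% x,
                         logical(1))))
  # applying twice adds nothing
  out2 <- apply_special_cases(out$web, cases)
  expect_equal(nrow(out2$added), 0L)
  # donor without resource-side records warns and is a no-op
  # (Anguis fragilis is never a resource in this web)
  cases2 <- tibble::tibble(Taxon = "Limax cinereus",
                           Inference_Taxon = "Anguis fragilis",
                           Citation = "1", Case = "Missing predators")
  expect_warning(out3 <- apply_special_cases(web, cases2), "no predator")
  expect_equal(nrow(out3$added), 0L)
})

test_that("generalist consumers connect to a prey family, trimmed", {
  cl <- as_checklist(tibble::tibble(
    Taxon = c("Erinaceus europaeus", "Diplo d1", "Diplo d2"),
    Rank = "Species",
    Family = c("Erinaceidae", "Julidae", "Julidae"),
    Genus = c("Erinaceus", "Diplo", "Diplo"),
    Species = c("europaeus", "d1", "d2"),
    Habitat = list("Forest", "Forest", "Waters"),
    Zone = list("on ground or in leaf litter",
                "on ground or in leaf litter", "in water")))
  web <- metaweb(cl, tiny_records(list(rec("Diplo d1", "Diplo d2"))))
  out <- connect_family_to_generalist_consumers(
    web, "Julidae", "Erinaceus europaeus", citation = 77L)
  expect_equal(out$added$Target_Name, "Diplo d1")
  expect_equal(out$added$Inference, "special_case")
  # trimming off keeps both, habitat/stratum overlap notwithstanding
  out2 <- connect_family_to_generalist_consumers(
    web, "Julidae", "Erinaceus europaeus", trim_by_cooccurrence = FALSE)
  expect_setequal(out2$added$Target_Name, c("Diplo d1", "Diplo d2"))
  # empty family -> nothing
  out3 <- connect_family_to_generalist_consumers(
    web, "Nullidae", "Erinaceus europaeus")
  expect_equal(nrow(out3$added), 0L)
})

test_that("most_shared_consumers ranks by coverage with lexicographic ties", {
  cl <- as_checklist(tibble::tibble(
    Taxon = c("Piscis unus", "Piscis duo", "Trich t1", "Trich t2",
              "Trich t3"),
    Rank = "Species",
    Family = c("Percidae", "Percidae", "Limnephilidae", "Limnephilidae",
               "Limnephilidae"),
    Genus = c("Piscis", "Piscis", "Trich", "Trich", "Trich"),
    Species = c("unus", "duo", "t1", "t2", "t3")))
  web <- metaweb(cl, tiny_records(list(
    rec("Piscis unus", "Trich t1"), rec("Piscis unus", "Trich t2"),
    rec("Piscis unus", "Trich t3"), rec("Piscis duo", "Trich t1"))))
  focal <- c("Trich t1", "Trich t2", "Trich t3")
  out <- most_shared_consumers(web, focal)
  expect_equal(out$consumer, c("Piscis unus", "Piscis duo"))
  expect_equal(out$n_shared, c(3L, 1L))
  expect_equal(nrow(most_shared_consumers(web, focal, k = 1)), 1L)
  # k larger than candidates returns all
  expect_equal(nrow(most_shared_consumers(web, focal, k = 10)), 2L)
  # no consumers -> empty
  expect_equal(nrow(most_shared_consumers(web, "Piscis duo")), 0L)
})
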