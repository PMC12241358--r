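# Occurrence intersection, habitat-association filters and median-share
# inference for data-poor species.

test_that("point-in-patch counts match a brute-force double loop", {
  patches <- tibble::tibble(
    habitat = c("Forest", "Waters", "Forest"),
    xmin = c(0, 10, 4), ymin = c(0, 0, 0),
    xmax = c(5, 15, 8), ymax = c(5, 5, 5))
  # one point in one patch
  pts <- tibble::tibble(species = "s1", x = 1, y = 1)
  expect_equal(intersect_occurrences(pts, patches),
               tibble::tibble(species = "s1", habitat = "Forest",
                              count = 1L))
  # zero points
  expect_equal(nrow(intersect_occurrences(pts[0, ], patches)), 0L)

  # 200 random points vs O(n*m) oracle (incl. overlapping Forest patches)
  set.seed(9)
  pts2 <- tibble::tibble(species = sample(c("s1", "s2"), 200, TRUE),
                         x = runif(200, -2, 18), y = runif(200, -2, 7))
  got <- intersect_occurrences(pts2, patches)
  counts <- list()
  for (i in seq_len(nrow(pts2))) {
    hit_habs <- character(0)
    for (j in seq_len(nrow(patches))) {
      if (pts2$x[i] >= patches$xmin[j] && pts2$x[i] <= patches$xmax[j] &&
          pts2$y[i] >= patches$ymin[j] && pts2$y[i] <= patches$ymax[j]) {
        hit_habs <- union(hit_habs, patches$habitat[j])
      }
    }
    for (h in hit_habs) {
      key <- paste(pts2$species[i], h)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  exp_tbl <- tibble::tibble(
    species = sub(" .*", "", names(counts)),
    habitat = sub("^\\S+ ", "", names(counts)),
    count = as.integer(unlist(counts)))
  exp_tbl <- dplyr::arrange(exp_tbl, species, habitat)
  expect_equal(as.data.frame(got), as.data.frame(exp_tbl))
})

test_that("habitat filters reproduce the worked generalist example", {
  counts <- tibble::tibble(
    species = "gen", habitat = c("A", "B", "C", "D"),
    count = c(200L, 150L, 120L, 110L))
  out <- filter_habitat_associations(counts)
  expect_equal(out$label, "generalist")
  # median(200,150,120,110) = 135; strictly above keeps A and B
  expect_equal(out$habitats[[1]], c("A", "B"))
})

test_that("habitat filters reproduce the worked specialist example", {
  counts <- tibble::tibble(species = "spc",
                           habitat = c("Forest", "Waters"),
                           count = c(150L, 4L))
  lit <- tibble::tibble(species = "spc", habitat = "Grassland")
  out <- filter_habitat_associations(counts, lit)
  expect_equal(out$label, "specialist")   # Waters fails the 100 rule; 2 < 3
  expect_equal(out$habitats[[1]], c("Forest", "Grassland"))
  expect_false(out$needs_inference)

  # no counts, no literature -> flagged empty
  out2 <- filter_habitat_associations(
    tibble::tibble(species = "x", habitat = "Forest", count = 0L))
  expect_true(out2$needs_inference)
  expect_equal(out2$habitats[[1]], character(0))
})

test_that("literature associations survive every filter; 100-rule is monotone", {
  set.seed(14)
  habs <- paste0("H", 1:6)
  for (rep_i in 1:20) {
    n <- sample(3:6, 1)
    counts <- tibble::tibble(species = "s",
                             habitat = sample(habs, n),
                             count = as.integer(sample(0:400, n)))
    lit <- tibble::tibble(species = "s", habitat = sample(habs, 2))
    out <- filter_habitat_associations(counts, lit)
    expect_true(all(lit$habitat %in% out$habitats[[1]]))

    # raising a sub-threshold count to the threshold only adds candidates
    low <- which(counts$count < 100L)
    if (length(low) > 0L) {
      before <- out$habitats[[1]]
      counts2 <- counts
      counts2$count[low[1]] <- 100L
      out2 <- filter_habitat_associations(counts2, lit)
      cand_before <- union(counts$habitat[counts$count >= 100], lit$habitat)
      cand_after <- union(counts2$habitat[counts2$count >= 100], lit$habitat)
      expect_true(all(cand_before %in% cand_after))
    }
  }

  # permutation invariance of row order
  counts <- tibble::tibble(species = rep(c("a", "b"), each = 3),
                           habitat = rep(paste0("H", 1:3), 2),
                           count = c(200L, 120L, 3L, 500L, 99L, 101L))
  out1 <- filter_habitat_associations(counts)
  out2 <- filter_habitat_associations(counts[sample(nrow(counts)), ])
  expect_equal(out1, out2)
})

test_that("median-share inference follows the genus-then-family rule", {
  cl <- as_checklist(tibble::tibble(
    Taxon = c("G f1", "G f2", "G f3", "G f4", "H h1", "H h2"),
    Rank = "Species",
    Family = c("FamG", "FamG", "FamG", "FamG", "FamH", "FamH"),
    Genus = c("G", "G", "G", "G", "H", "H"),
    Species = c("f1", "f2", "f3", "f4", "h1", "h2")))
  assocs <- tibble::tibble(
    species = c("G f1", "G f2", "G f3", "G f4"),
    labels = list("Forest", c("Forest", "Grassland"), "Forest",
                  character(0)))
  out <- infer_missing_associations(assocs, cl)
  # shares: Forest 3, Grassland 1; median 2 -> Forest only
  expect_equal(out$labels[[4]], "Forest")
  expect_equal(out$inference[[4]], "Genus")

  # single informed congener: median of one
  assocs2 <- tibble::tibble(species = c("H h1", "H h2"),
                            labels = list("Waters", character(0)))
  out2 <- infer_missing_associations(assocs2, cl)
  expect_equal(out2$labels[[2]], "Waters")

  # genus empty, family informed -> family-level flag
  cl2 <- dplyr::bind_rows(cl, as_checklist(tibble::tibble(
    Taxon = "K k1", Rank = "Species", Family = "FamG", Genus = "K",
    Species = "k1")))
  assocs3 <- tibble::tibble(
    species = c("G f1", "G f2", "K k1"),
    labels = list("Forest", "Forest", character(0)))
  out3 <- infer_missing_associations(assocs3, cl2)
  expect_equal(out3$labels[[3]], "Forest")
  expect_equal(out3$inference[[3]], "Family")

  # identical informed sets return exactly that set
  assocs4 <- tibble::tibble(
    species = c("G f1", "G f2", "G f3", "G f4"),
    labels = list(c("A", "B"), c("A", "B"), c("A", "B"), character(0)))
  out4 <- infer_missing_associations(assocs4, cl)
  expect_equal(out4$labels[[4]], c("A", "B"))

  # nobody informed at either level -> unresolved with warning
  assocs5 <- tibble::tibble(species = c("H h1", "H h2"),
                            labels = list(character(0), character(0)))
  expect_warning(out5 <- infer_missing_associations(assocs5, cl),
                 "could not be inferred")
  expect_equal(out5$inference, c("unresolved", "unresolved"))
})

test_that("Raunkiaer life forms map onto strata", {
  expect_equal(map_raunkiaer_to_strata("hydrophyte"), "in water")
  expect_equal(map_raunkiaer_to_strata("pleustophyte"), "in water")
  expect_equal(map_raunkiaer_to_strata("epiphyte"), "on vegetation")
  expect_setequal(map_raunkiaer_to_strata("hemicryptophyte"),
                  c("on ground or in leaf litter", "in ground",
                    "on vegetation"))
  expect_error(map_raunkiaer_to_strata("astronaut"), "astronaut")
})
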