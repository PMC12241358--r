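# Fixtures built in code: tiny checklists, record tables and webs used
# across the test files.

# checklist rows from compact specs: list(name = list(rank, family, genus,
# habitats, strata))
tiny_checklist <- function(vocab = metaweb_vocab()) {
  as_checklist(tibble::tibble(
    Taxon = c("FamA", "GenA", "GenA a1", "GenA a2",
              "FamB", "GenB", "GenB b1", "GenB b2",
              "Fungi"),
    Rank = c("Family", "Genus", "Species", "Species",
             "Family", "Genus", "Species", "Species",
             "Guild"),
    Kingdom = c(rep("Animalia", 8), "Resources"),
    Family = c("FamA", "FamA", "FamA", "FamA",
               "FamB", "FamB", "FamB", "FamB", NA),
    Genus = c(NA, "GenA", "GenA", "GenA", NA, "GenB", "GenB", "GenB", NA),
    Species = c(NA, NA, "a1", "a2", NA, NA, "b1", "b2", NA),
    Habitat = list(character(0), character(0), "Forest", "Waters",
                   character(0), character(0), "Forest", "Waters",
                   character(0)),
    Zone = list(character(0), character(0), "on vegetation", "in water",
                character(0), character(0), "on vegetation", "in water",
                character(0))
  ), vocab = vocab)
}

tiny_records <- function(rows) {
  as_interactions(dplyr::bind_rows(rows))
}

rec <- function(src, tgt, src_rank = "Species", tgt_rank = "Species",
                citation = list(1L), inference = NA_character_, ...) {
  tibble::tibble(Source_Name = src, Target_Name = tgt,
                 Source_Rank = src_rank, Target_Rank = tgt_rank,
                 Citation = citation, Inference = inference, ...)
}

expand_quiet <- function(...) suppressMessages(expand_metaweb(...))

triples <- function(ints) {
  out <- ints[, c("Source_Name", "Target_Name", "Inference")]
  as.data.frame(dplyr::arrange(out, Source_Name, Target_Name))
}

# random web over n named nodes for diagnostics tests
random_web <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nm <- sprintf("Gen%02d sp%02d", seq_len(n_nodes), seq_len(n_nodes))
  taxa <- as_checklist(tibble::tibble(
    Taxon = nm, Rank = "Species", Kingdom = "Animalia",
    Family = "FamX", Genus = sprintf("Gen%02d", seq_len(n_nodes)),
    Species = sprintf("sp%02d", seq_len(n_nodes))))
  src <- sample(nm, n_edges, replace = TRUE)
  tgt <- sample(nm, n_edges, replace = TRUE)
  keep <- !duplicated(paste(src, tgt))
  ints <- as_interactions(tibble::tibble(
    Source_Name = src[keep], Target_Name = tgt[keep],
    Source_Rank = "Species", Target_Rank = "Species"))
  metaweb(taxa, ints)
}
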