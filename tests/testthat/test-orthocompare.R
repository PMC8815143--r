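test_that("direction summaries apply the mixed-direction exclusion", {
  ogs <- orthogroup_set(
    data.frame(og_id = c("OG1", "OG1", "OG1", "OG1"),
               species = c("At", "Os", "Hv", "Hv"),
               gene_id = c("Atg1", "Osg1", "Hvg1", "Hvg2")),
    species = c("At", "Os", "Hv"))
  calls <- data.frame(
    species = c("At", "Os", "Hv", "Hv"),
    treatment = "UV",
    gene_id = c("Atg1", "Osg1", "Hvg1", "Hvg2"),
    direction = c("up", "up", "up", "down"),
    log2fc = c(2, 3, 2, -2), qval = 0.01)
  s <- summarize_directions(ogs, calls)
  st <- setNames(s$state, s$species)
  expect_equal(unname(st[c("At", "Os", "Hv")]),
               c("up", "up", "mixed_excluded"))
  # exclusion does not leak into the other species' classification
  cl <- classify_responses(s)
  at <- cl[cl$species == "At", ]
  expect_equal(at$conserved_with, "Os")
  expect_equal(at$opposite_with, "")
  hv <- cl[cl$species == "Hv", ]
  expect_equal(hv$conserved_with, "")
  expect_equal(hv$opposite_with, "")
})

test_that("genes outside any orthogroup are reported as unassigned", {
  ogs <- orthogroup_set(data.frame(og_id = "OG1", species = "At",
                                   gene_id = "Atg1"),
                        species = c("At", "Os", "Hv"))
  calls <- data.frame(species = c("At", "At"), treatment = "UV",
                      gene_id = c("Atg1", "At_orphan"),
                      direction = "up", log2fc = 2, qval = 0.01)
  s <- summarize_directions(ogs, calls)
  expect_equal(attr(s, "unassigned")$gene_id, "At_orphan")
  expect_false("At_orphan" %in% unlist(strsplit(s$genes, ",")))
})

test_that("classification matches the definition on all 64 state triples", {
  states <- c("up", "down", "absent", "mixed_excluded")
  flip <- c(up = "down", down = "up")
  roster <- c("At", "Os", "Hv")
  for (a in states) {
    for (b in states) {
      for (c in states) {
        combo <- c(a, b, c)
        cl <- classify_responses(states_summary(combo))
        for (i in seq_along(roster)) {
          row <- cl[cl$species == roster[[i]], ]
          if (!combo[[i]] %in% c("up", "down")) {
            expect_equal(row$conserved_with, "")
            expect_equal(row$opposite_with, "")
            next
          }
          others <- setdiff(seq_along(roster), i)
          exp_cons <- roster[others][combo[others] == combo[[i]]]
          exp_opp <- roster[others][combo[others] == flip[[combo[[i]]]]]
          expect_equal(row$conserved_with,
                       paste(exp_cons, collapse = ","))
          expect_equal(row$opposite_with, paste(exp_opp, collapse = ","))
        }
      }
    }
  }
})

test_that("opposite relations are symmetric and disjoint from conserved", {
  set.seed(17)
  d <- synthetic_design(seed = 17, n_orthogroups = 120)
  ogs <- generate_orthogroups(d)
  deg <- generate_deg_tables(d, ogs)
  calls <- bind_calls(lapply(deg$tables, call_degs))
  cl <- classify_responses(summarize_directions(ogs, calls))
  for (r in seq_len(nrow(cl))) {
    cw <- strsplit(cl$conserved_with[[r]], ",")[[1]]
    ow <- strsplit(cl$opposite_with[[r]], ",")[[1]]
    expect_length(intersect(cw, ow), 0)
    for (o in ow) {
      mate <- cl[cl$og_id == cl$og_id[[r]] &
                   cl$treatment == cl$treatment[[r]] & cl$species == o, ]
      expect_true(grepl(cl$species[[r]], mate$opposite_with))
    }
  }
  # mixed-excluded species never contribute genes to any tally
  mixed <- cl[cl$state == "mixed_excluded", ]
  expect_true(all(mixed$n_conserved == 0 & mixed$n_opposite == 0))
})

test_that("k-of-n filters keep and drop orthogroups at the boundary", {
  roster <- c("At", "Os", "Hv")
  treatments <- c("3AT", "AA", "ABA", "MV", "SA", "UV")
  mk <- function(t, states) states_summary(states, treatment = t)
  rows <- do.call(rbind, lapply(treatments, function(t) {
    if (t %in% c("3AT", "SA", "UV")) {
      mk(t, c("up", "up", "up"))
    } else {
      mk(t, c("absent", "absent", "absent"))
    }
  }))
  attr(rows, "species") <- roster
  attr(rows, "treatments") <- treatments
  class(rows) <- c("direction_summary", "data.frame")
  cl <- classify_responses(rows)
  expect_equal(multi_treatment_filter(cl, 3, "common_all_species",
                                      direction = "up")$og_ids, "OG1")
  expect_length(multi_treatment_filter(cl, 4, "common_all_species")$og_ids, 0)
  expect_error(multi_treatment_filter(cl, 9, "common_all_species"), "between")
})

test_that("same-pair opposite filtering is stricter than any-pair", {
  roster <- c("At", "Os", "Hv")
  treatments <- c("T1", "T2")
  # T1: At vs Os opposite; T2: At vs Hv opposite -> any-pair k=2 keeps,
  # same-pair k=2 drops
  rows <- rbind(
    states_summary(c("up", "down", "absent"), treatment = "T1"),
    states_summary(c("up", "absent", "down"), treatment = "T2"))
  attr(rows, "species") <- roster
  attr(rows, "treatments") <- treatments
  class(rows) <- c("direction_summary", "data.frame")
  cl <- classify_responses(rows)
  expect_equal(multi_treatment_filter(cl, 2, "opposite_any_pair")$og_ids,
               "OG1")
  expect_length(
    multi_treatment_filter(cl, 2, "opposite_any_pair",
                           same_pair = TRUE)$og_ids, 0)
  expect_equal(
    multi_treatment_filter(cl, 1, "opposite_any_pair",
                           same_pair = TRUE)$og_ids, "OG1")
})

test_that("count tallies are category-additive and percentage-consistent", {
  d <- synthetic_design(seed = 23, n_orthogroups = 150)
  ogs <- generate_orthogroups(d)
  deg <- generate_deg_tables(d, ogs)
  calls <- bind_calls(lapply(deg$tables, call_degs))
  cl <- classify_responses(summarize_directions(ogs, calls))
  counts <- summarize_counts(cl, calls)
  # total = with_both + each single-species category, per relation
  for (sp in c("At", "Os", "Hv")) {
    for (t in unique(counts$treatment)) {
      for (rel in c("conserved", "opposite")) {
        cc <- counts[counts$species == sp & counts$treatment == t &
                       counts$relation == rel, ]
        expect_equal(cc$n_genes[cc$category == "total"],
                     sum(cc$n_genes[cc$category != "total"]))
      }
    }
  }
  expect_true(all(counts$pct[counts$deg_total > 0] <= 100))
  # strict mode never increases the conserved tally
  strict <- summarize_counts(cl, calls, strict = TRUE)
  cons <- counts$relation == "conserved"
  expect_true(all(strict$n_genes[cons] <= counts$n_genes[cons]))
})
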