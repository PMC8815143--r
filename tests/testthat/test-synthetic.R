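test_that("designs validate their probability inputs", {
  expect_error(synthetic_design(class_fractions = c(conserved_all = 1)),
               "named")
  bad <- c(conserved_all = 0.5, conserved_pair = 0.2, opposite_pair = 0.2,
           species_specific = 0.2, mixed_within_species = 0, null = 0)
  expect_error(synthetic_design(class_fractions = bad), "sum to 1")
  expect_error(synthetic_design(paralog_prob = 1.2), "paralog_prob")
  expect_error(synthetic_design(n_orthogroups = 0), "n_orthogroups")
  # mixed class needs paralogs; its mass folds into species_specific at 0
  d <- synthetic_design(paralog_prob = 0)
  expect_equal(unname(d$class_fractions[["mixed_within_species"]]), 0)
  expect_equal(sum(d$class_fractions), 1)
})

test_that("orthogroup generation is deterministic and structured", {
  d <- synthetic_design(seed = 7, n_orthogroups = 50)
  a <- generate_orthogroups(d)
  b <- generate_orthogroups(d)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # every gene in exactly one OG, species encoded in the id
  expect_false(anyDuplicated(a$gene_id) > 0)
  expect_true(all(startsWith(a$gene_id, a$species)))

  d1 <- synthetic_design(seed = 1, n_orthogroups = 1, paralog_prob = 0)
  one <- generate_orthogroups(d1)
  expect_equal(nrow(one), 3)
  expect_equal(sort(unique(one$species)), sort(c("At", "Os", "Hv")))
})

test_that("paralog frequency matches the closed-form Bernoulli rate", {
  fr <- c(conserved_all = 0.2, conserved_pair = 0.2, opposite_pair = 0.2,
          species_specific = 0.2, mixed_within_species = 0, null = 0.2)
  d <- synthetic_design(seed = 19, n_orthogroups = 500, paralog_prob = 0.3,
                        class_fractions = fr)
  ogs <- generate_orthogroups(d)
  per_og <- tapply(ogs$gene_id,
                   list(ogs$og_id, ogs$species), length)
  frac_multi <- mean(apply(per_og, 1, function(x) any(x >= 2)))
  p <- 1 - 0.7^3
  ci <- 2.576 * sqrt(p * (1 - p) / 500)
  expect_gt(frac_multi, p - ci)
  expect_lt(frac_multi, p + ci)
})

test_that("planted truth labels partition OGs with the expected class mix", {
  d <- synthetic_design(seed = 31, n_orthogroups = 500)
  ogs <- generate_orthogroups(d)
  deg <- generate_deg_tables(d, ogs)
  truth <- deg$truth
  # one truth row per OG x treatment
  expect_equal(nrow(truth), 500 * 6)
  expect_false(anyDuplicated(truth[, c("og_id", "treatment")]) > 0)
  # per-OG class counts within 3 sd of the design fractions
  og_class <- attr(ogs, "class_labels")
  for (cls in names(d$class_fractions)) {
    expected <- 500 * d$class_fractions[[cls]]
    sd3 <- 3 * sqrt(500 * d$class_fractions[[cls]] *
                      (1 - d$class_fractions[[cls]]))
    expect_lte(abs(sum(og_class == cls) - expected), max(sd3, 1))
  }
})

test_that("noise-free data reconstruct every planted class exactly", {
  d <- synthetic_design(seed = 13, n_orthogroups = 200, noise_sd = 0,
                        effect_size = 3)
  ogs <- generate_orthogroups(d)
  deg <- generate_deg_tables(d, ogs)
  # construction check: all planted log2fc at +-3, DE qvals below 0.05
  for (tab in deg$tables) {
    de <- tab$qval < 0.05
    expect_true(all(abs(tab$log2fc[de]) == 3))
    expect_true(all(abs(tab$log2fc[!de]) < 1))
  }
  calls <- bind_calls(lapply(deg$tables, call_degs))
  pred <- predict_og_class(summarize_directions(ogs, calls,
                                                treatments = d$treatments))
  m <- merge(pred, deg$truth, by = c("og_id", "treatment"))
  expect_equal(nrow(m), 200 * 6)
  expect_true(all(m$predicted_class == m$class))
})

test_that("opposite pairs place opposing signs in exactly two species", {
  d <- synthetic_design(seed = 47, n_orthogroups = 150, noise_sd = 0)
  ogs <- generate_orthogroups(d)
  deg <- generate_deg_tables(d, ogs)
  opp <- deg$truth[deg$truth$class == "opposite_pair", ]
  expect_gt(nrow(opp), 0)
  calls <- bind_calls(lapply(deg$tables, call_degs))
  for (r in sample(seq_len(nrow(opp)), min(25, nrow(opp)))) {
    genes <- ogs[ogs$og_id == opp$og_id[[r]], ]
    cc <- calls[calls$gene_id %in% genes$gene_id &
                  calls$treatment == opp$treatment[[r]], ]
    sp_sign <- tapply(sign(cc$log2fc), cc$species, unique)
    expect_length(sp_sign, 2)
    expect_equal(as.vector(sort(unname(unlist(sp_sign)))), c(-1, 1))
  }
})

test_that("promoter generation plants motifs at the designed rates", {
  d <- synthetic_design(seed = 3, n_orthogroups = 40, promoter_len = 200,
                        motif_rate_target = 1, motif_rate_background = 0)
  ogs <- generate_orthogroups(d)
  targets <- ogs$gene_id[seq_len(30)]
  p <- generate_promoters(d, ogs, target_genes = targets)
  hits <- scan_motif("CTTGNNNNNCAMG", p$promoters)
  expect_true(all(hits$has_motif[hits$gene_id %in% targets]))
  expect_true(all(p$planted[targets]))
  expect_true(all(!p$planted[setdiff(names(p$planted), targets)]))
  # determinism: byte-identical FASTA for the same design
  d2 <- synthetic_design(seed = 8, n_orthogroups = 10, promoter_len = 100)
  o2 <- generate_orthogroups(d2)
  t1 <- tempfile(); t2 <- tempfile()
  generate_promoters(d2, o2, dir = t1)
  generate_promoters(d2, o2, dir = t2)
  expect_identical(readLines(file.path(t1, "genome.fa")),
                   readLines(file.path(t2, "genome.fa")))
  expect_identical(readLines(file.path(t1, "genes.gff3")),
                   readLines(file.path(t2, "genes.gff3")))
  unlink(c(t1, t2), recursive = TRUE)
  # pattern longer than the promoter is a configuration error
  dshort <- synthetic_design(promoter_len = 10)
  expect_error(generate_promoters(dshort, ogs), "shorter")
})

test_that("background match frequency follows the degeneracy closed form", {
  # per-window single-strand match probability 2048/4^13; both strands give
  # 2 (L - 12) 2048/4^13 expected matches per promoter with no planting
  d <- synthetic_design(seed = 29, n_orthogroups = 120, promoter_len = 2000,
                        motif_rate_target = 0, motif_rate_background = 0)
  ogs <- generate_orthogroups(d)
  p <- generate_promoters(d, ogs)
  hits <- scan_motif("CTTGNNNNNCAMG", p$promoters)
  n_windows <- 2 * (2000 - 12) * nrow(hits)
  pw <- 2048 / 4^13
  total <- sum(hits$n_total)
  ci <- 2.576 * sqrt(n_windows * pw * (1 - pw))
  expect_lte(abs(total - n_windows * pw), ci + 1)
})

test_that("promoters written to disk round-trip through the extractor", {
  d <- synthetic_design(seed = 5, n_orthogroups = 25, promoter_len = 300)
  ogs <- generate_orthogroups(d)
  dir <- tempfile()
  p <- generate_promoters(d, ogs, target_genes = ogs$gene_id[1:10],
                          dir = dir)
  ext <- extract_promoters(p$fasta, p$gff3, length = 300)
  m <- match(p$promoters$gene_id, ext$gene_id)
  expect_false(anyNA(m))
  expect_identical(ext$sequence[m], p$promoters$sequence)
  unlink(dir, recursive = TRUE)
})

test_that("dataset writing round-trips orthogroups and DEG tables", {
  d <- synthetic_design(seed = 2, n_orthogroups = 30, promoter_len = 100)
  dir <- tempfile()
  ds <- write_synthetic_dataset(d, dir)
  back <- read_orthogroups(ds$paths$orthogroups)
  expect_equal(back$og_id, ds$orthogroups$og_id)
  expect_equal(back$species, ds$orthogroups$species)
  expect_equal(back$gene_id, ds$orthogroups$gene_id)
  nm <- names(ds$paths$deg)[[1]]
  sp_tr <- strsplit(nm, ".", fixed = TRUE)[[1]]
  st <- read_stat_table(ds$paths$deg[[nm]], sp_tr[[1]], sp_tr[[2]])
  expect_equal(st$log2fc, ds$deg$tables[[nm]]$log2fc)
  expect_equal(st$gene_id, ds$deg$tables[[nm]]$gene_id)
  expect_true(file.exists(ds$paths$fasta))
  unlink(dir, recursive = TRUE)
})
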