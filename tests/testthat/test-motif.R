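MDM <- "CTTGNNNNNCAMG"

test_that("motif patterns validate IUPAC codes and count degeneracy", {
  p <- motif_pattern(MDM)
  expect_equal(p$length, 13)
  expect_equal(p$degeneracy, 4^5 * 2)   # five N positions, one M
  expect_error(motif_pattern("CTTGX"), "X")
  expect_equal(revcomp_iupac(MDM), "CKTGNNNNNCAAG")
  expect_equal(revcomp_iupac("ACGT"), "ACGT")
})

test_that("scanning matches the degenerate code sets exactly", {
  # M is matched by A ...
  expect_equal(scan_motif(MDM, c(g = "CTTGACGTACAAG"))$n_forward, 1L)
  # ... but not by T
  expect_equal(scan_motif(MDM, c(g = "CTTGACGTACATG"))$n_total, 0L)
  # reverse-complement instance is found on the reverse strand only
  h <- scan_motif(MDM, c(g = "CGTGAAAAACAAG"))
  expect_equal(h$n_forward, 0L)
  expect_equal(h$n_reverse, 1L)
  expect_equal(scan_motif(MDM, c(g = "CGTGAAAAACAAG"),
                          strands = "forward")$n_total, 0L)
  # genomic N is matched only by pattern position N
  expect_equal(scan_motif(MDM, c(g = "CTTGANNNACAAG"))$n_forward, 1L)
  expect_equal(scan_motif(MDM, c(g = "NTTGAAAAACAAG"))$n_forward, 0L)
  # overlapping matches are all counted
  expect_equal(scan_motif("AA", c(g = "AAAA"),
                          strands = "forward")$n_forward, 3L)
  # promoters shorter than the pattern are excluded from scanning
  expect_true(is.na(scan_motif(MDM, c(g = "CTTG"))$has_motif))
})

test_that("every concrete realisation of the MDM is a forward hit", {
  pat <- motif_pattern(MDM)
  ns <- expand.grid(rep(list(c("A", "C", "G", "T")), 5),
                    stringsAsFactors = FALSE)
  words <- apply(ns, 1, function(n) {
    c(paste0("CTTG", paste(n, collapse = ""), "CAAG"),
      paste0("CTTG", paste(n, collapse = ""), "CACG"))
  })
  words <- as.vector(words)
  expect_length(words, pat$degeneracy)
  hits <- scan_motif(MDM, setNames(words, seq_along(words)),
                     strands = "forward")
  expect_true(all(hits$n_forward == 1L))
})

test_that("scanner agrees with the per-offset oracle on random sequences", {
  # oracle self-check against the literal double loop first
  set.seed(301)
  for (i in 1:25) {
    s <- random_dna(40)
    expect_equal(oracle_count_forward(s, MDM),
                 oracle_count_forward_loop(s, MDM))
  }
  patterns <- c(MDM, "CAMG", "RYSWKM", "TTNNGG", "ACGTN", "BDHV")
  seqs <- vapply(1:150, function(i) random_dna(400), "")
  for (pat in patterns) {
    hits <- scan_motif(pat, setNames(seqs, seq_along(seqs)))
    ora_f <- vapply(seqs, oracle_count_forward, 0L, iupac = pat)
    ora_r <- vapply(seqs, oracle_count_reverse, 0L, iupac = pat)
    expect_equal(hits$n_forward, unname(ora_f))
    expect_equal(hits$n_reverse, unname(ora_r))
  }
})

test_that("promoter extraction follows the coordinate conventions", {
  # plus-strand gene: first CDS base at 301 -> promoter is 101..300;
  # minus-strand gene: translation start at 200 -> revcomp of 201..400
  contig <- random_dna(600)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", contig), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t301\t420\t.\t+\t.\tID=gplus",
    "chr1\tt\tmRNA\t301\t420\t.\t+\t.\tID=gplus.t1;Parent=gplus",
    "chr1\tt\tCDS\t301\t420\t.\t+\t0\tID=c1;Parent=gplus.t1",
    "chr1\tt\tgene\t100\t200\t.\t-\t.\tID=gminus",
    "chr1\tt\tmRNA\t100\t200\t.\t-\t.\tID=gminus.t1;Parent=gminus",
    "chr1\tt\tCDS\t100\t200\t.\t-\t0\tID=c2;Parent=gminus.t1"), gff)
  prom <- extract_promoters(fa, gff, length = 200)
  expect_equal(prom$sequence[prom$gene_id == "gplus"],
               substr(contig, 101, 300))
  expect_equal(prom$sequence[prom$gene_id == "gminus"],
               oracle_revcomp(substr(contig, 201, 400)))
  expect_false(any(prom$truncated))
  # truncation at the contig start is flagged
  short <- extract_promoters(fa, gff, length = 400)
  expect_true(short$truncated[short$gene_id == "gplus"])
  expect_equal(short$length[short$gene_id == "gplus"], 300L)
})

test_that("the longest-CDS transcript is the representative", {
  contig <- random_dna(500)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", contig), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t200\t400\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t200\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tt\tCDS\t250\t400\t.\t+\t0\tID=c1;Parent=g1.t1",
    "chr1\tt\tmRNA\t200\t400\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\tt\tCDS\t200\t400\t.\t+\t0\tID=c2;Parent=g1.t2"), gff)
  prom <- extract_promoters(fa, gff, length = 100)
  # g1.t2 has the longer CDS, so the anchor is position 200
  expect_equal(prom$sequence, substr(contig, 100, 199))
})

test_that("motif enrichment reproduces the textbook 2x2 chi-square", {
  bg <- paste0("g", 1:10000)
  motif_genes <- paste0("g", 1:1000)
  deg <- c(paste0("g", 1:30), paste0("g", 5001:5070))  # 30 of 100 with motif
  hits <- data.frame(gene_id = bg, has_motif = bg %in% motif_genes)
  r <- mdm_enrichment(deg, bg, hits)
  tab <- matrix(c(30, 70, 970, 8930), nrow = 2)
  expect_equal(r$statistic, chisq_formula(tab), tolerance = 1e-12)
  expect_equal(r$k, 30)
  expect_equal(r$direction, "over")
  # equal proportions give statistic 0, p 1
  deg0 <- c(paste0("g", 1:10), paste0("g", 2001:2090))
  r0 <- mdm_enrichment(deg0, bg, hits)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  expect_error(mdm_enrichment(character(), bg, hits), "empty")
  nohit <- data.frame(gene_id = bg, has_motif = FALSE)
  expect_error(mdm_enrichment(deg, bg, nohit), "motif-bearing")
})

test_that("adding motif-bearing DEGs never weakens an over-representation", {
  bg <- paste0("g", 1:2000)
  motif_genes <- paste0("g", 1:300)
  hits <- data.frame(gene_id = bg, has_motif = bg %in% motif_genes)
  deg <- c(paste0("g", 1:60), paste0("g", 1001:1140))
  p_prev <- mdm_enrichment(deg, bg, hits)$p_value
  for (extra in paste0("g", 61:70)) {
    deg <- c(deg, extra)
    r <- mdm_enrichment(deg, bg, hits)
    expect_true(r$direction == "over")
    expect_lte(r$p_value, p_prev + 1e-12)
    p_prev <- r$p_value
  }
})

test_that("MDS candidate filtering applies every leg of the chain", {
  treatments <- c("3AT", "AA", "ABA", "MV", "SA", "UV")
  mk_calls <- function(gene, de_in) {
    do.call(rbind, lapply(de_in, function(t) {
      data.frame(species = "At", treatment = t, gene_id = gene,
                 direction = "up", log2fc = 2, qval = 0.01)
    }))
  }
  calls <- rbind(mk_calls("g_ok", c("AA", "3AT", "UV")),
                 mk_calls("g_aa_only", "AA"),
                 mk_calls("g_nonet", treatments),
                 mk_calls("g_nomotif", c("AA", "3AT", "UV")))
  # make every treatment present in the calls table
  calls <- rbind(calls, mk_calls("filler", treatments))
  hits <- data.frame(gene_id = c("g_ok", "g_aa_only", "g_nonet", "filler"),
                     has_motif = TRUE)
  network <- c("g_ok", "g_aa_only", "g_nomotif")
  out <- mds_candidates(network, hits, calls)
  expect_equal(out$gene_id, "g_ok")
  expect_equal(out$n_treatments, 3L)
  expect_equal(out[["UV"]], 2)
  expect_true(is.na(out[["SA"]]))
  # output is always inside network-and-motif genes
  expect_true(all(out$gene_id %in% intersect(network, hits$gene_id)))
  expect_error(mds_candidates(network, hits,
                              calls[calls$treatment != "AA", ]), "AA")
})
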