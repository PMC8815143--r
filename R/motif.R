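IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Build a degenerate IUPAC motif pattern
#'
#' @param iupac Pattern string over the IUPAC nucleotide alphabet, e.g. the
#'   mitochondrial dysfunction motif `"CTTGNNNNNCAMG"`.
#' @return A `motif_pattern`: list with the pattern string, per-position
#'   allowed-base sets, pattern length and degenerate word count (the product
#'   of the per-position set sizes; 4^5 x 2 = 2048 for the MDM).
#' @export
motif_pattern <- function(iupac) {
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "", fixed = TRUE)[[1L]]
  if (!length(chars)) stop("motif pattern must have length >= 1")
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC character(s) in pattern '", iupac, "': ",
         paste(unique(bad), collapse = ", "))
  }
  sets <- IUPAC_SETS[chars]
  structure(list(iupac = iupac, sets = sets, length = length(chars),
                 degeneracy = prod(lengths(sets))),
            class = "motif_pattern")
}

#' Reverse complement of an IUPAC pattern string
#'
#' @param iupac IUPAC pattern string.
#' @return The reverse-complemented pattern string (degenerate codes are
#'   complemented code-wise, e.g. M <-> K).
#' @export
revcomp_iupac <- function(iupac) {
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(IUPAC_COMPLEMENT))
  if (length(bad)) {
    stop("invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  }
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

# Regex character class per IUPAC code. A genomic N is never matched by a
# degenerate code except pattern position N itself.
.iupac_class <- function(code) {
  set <- IUPAC_SETS[[code]]
  if (code == "N") set <- c(set, "N")
  if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
}

.iupac_regex <- function(iupac) {
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1L]]
  paste(vapply(chars, .iupac_class, ""), collapse = "")
}

# Overlapping match start positions of an IUPAC pattern in one sequence.
.scan_one <- function(seq, regex) {
  hits <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1L]]
  if (hits[[1L]] == -1L) integer() else as.integer(hits)
}

#' Scan promoters for a degenerate motif with zero mismatches
#'
#' A window matches when every position's base lies in the pattern's allowed
#' set; matching is exact (no mismatches, no indels) and overlapping matches
#' are all counted. In `strands = "both"` mode the reverse strand is scanned
#' as well (implemented by scanning the reverse-complemented pattern on the
#' forward sequence); all positions are reported in forward promoter
#' coordinates (1-based start of the matching window).
#'
#' @param pattern A `motif_pattern` or IUPAC string.
#' @param promoters A `promoter_set` data.frame (see [extract_promoters()]) or
#'   a named character vector of sequences.
#' @param strands `"both"` (default) or `"forward"`.
#' @return A `motif_hits` data.frame with one row per promoter: `gene_id`,
#'   `n_forward`, `n_reverse`, `n_total`, `has_motif`, and comma-separated
#'   `positions_fwd` / `positions_rev`. Promoters shorter than the pattern are
#'   excluded from scanning: their counts are `NA` and `has_motif` is `NA`.
#' @export
scan_motif <- function(pattern, promoters, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (is.character(pattern)) pattern <- motif_pattern(pattern)
  if (is.character(promoters)) {
    promoters <- data.frame(gene_id = names(promoters),
                            sequence = unname(promoters))
  }
  seqs <- toupper(promoters$sequence)
  ok <- nchar(seqs) >= pattern$length
  fwd_re <- .iupac_regex(pattern$iupac)
  rev_re <- .iupac_regex(revcomp_iupac(pattern$iupac))

  n_fwd <- n_rev <- rep(NA_integer_, length(seqs))
  pos_fwd <- pos_rev <- rep(NA_character_, length(seqs))
  fwd_hits <- lapply(seqs[ok], .scan_one, regex = fwd_re)
  n_fwd[ok] <- lengths(fwd_hits)
  pos_fwd[ok] <- vapply(fwd_hits, paste, "", collapse = ",")
  if (strands == "both") {
    rev_hits <- lapply(seqs[ok], .scan_one, regex = rev_re)
    n_rev[ok] <- lengths(rev_hits)
    pos_rev[ok] <- vapply(rev_hits, paste, "", collapse = ",")
  } else {
    n_rev[ok] <- 0L
    pos_rev[ok] <- ""
  }
  out <- data.frame(gene_id = promoters$gene_id,
                    n_forward = n_fwd, n_reverse = n_rev,
                    n_total = n_fwd + n_rev,
                    has_motif = (n_fwd + n_rev) >= 1L,
                    positions_fwd = pos_fwd, positions_rev = pos_rev)
  structure(out, pattern = pattern$iupac, strands = strands,
            class = c("motif_hits", "data.frame"))
}

#' Extract promoter sequences upstream of the translation start
#'
#' Reads a genome FASTA and GFF3 gene models, picks one representative
#' transcript per gene (the mRNA with the longest summed CDS, ties broken by
#' lexicographically smallest transcript id), and cuts the region immediately
#' upstream of the translation start site (first CDS base): for a plus-strand
#' gene with first CDS base at 1-based position p, positions `p-length .. p-1`
#' of the contig; for a minus-strand gene with translation start at its
#' rightmost CDS base q, the reverse complement of `q+1 .. q+length`.
#' Promoters are truncated at contig ends and flagged.
#'
#' @param fasta Path to the genome FASTA.
#' @param gff3 Path to GFF3 gene models containing gene/mRNA/CDS features.
#' @param length Promoter length in bases upstream of the translation start
#'   (default 2000).
#' @return A `promoter_set` data.frame: `gene_id`, `sequence` (promoter in
#'   5'->3' orientation of the gene), `length`, `truncated`. Genes without CDS
#'   features are skipped with a warning.
#' @export
extract_promoters <- function(fasta, gff3, length = 2000) {
  stopifnot(length >= 1)
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  feats <- rtracklayer::import(gff3)
  meta <- S4Vectors::mcols(feats)
  is_cds <- as.character(meta$type) == "CDS"
  is_mrna <- as.character(meta$type) == "mRNA"
  genes <- feats[as.character(meta$type) == "gene"]
  gene_ids <- as.character(S4Vectors::mcols(genes)$ID)

  mrna <- feats[is_mrna]
  mrna_id <- as.character(S4Vectors::mcols(mrna)$ID)
  mrna_parent <- vapply(S4Vectors::mcols(mrna)$Parent,
                        function(p) as.character(p)[[1L]], "")
  cds <- feats[is_cds]
  cds_parent <- vapply(S4Vectors::mcols(cds)$Parent,
                       function(p) as.character(p)[[1L]], "")

  rows <- lapply(gene_ids, function(g) {
    tx <- mrna_id[mrna_parent == g]
    if (!base::length(tx)) tx <- g   # CDS may hang directly off the gene
    cds_len <- vapply(tx, function(t) {
      sum(BiocGenerics::width(cds[cds_parent == t]))
    }, 0)
    if (all(cds_len == 0)) {
      warning("gene ", g, " has no CDS feature; skipped")
      return(NULL)
    }
    best <- sort(tx[cds_len == max(cds_len)])[[1L]]
    bc <- cds[cds_parent == best]
    contig <- as.character(GenomicRanges::seqnames(bc))[[1L]]
    if (!contig %in% names(genome)) {
      stop("contig ", contig, " referenced by ", g, " absent from FASTA")
    }
    clen <- base::length(genome[[contig]])
    strand <- as.character(BiocGenerics::strand(bc))[[1L]]
    if (strand == "-") {
      q <- max(BiocGenerics::end(bc))
      from <- q + 1L
      to <- min(clen, q + length)
      if (to < from) return(data.frame(gene_id = g, sequence = "",
                                       length = 0L, truncated = TRUE))
      s <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[contig]], from, to))
    } else {
      p <- min(BiocGenerics::start(bc))
      from <- max(1L, p - length)
      to <- p - 1L
      if (to < from) return(data.frame(gene_id = g, sequence = "",
                                       length = 0L, truncated = TRUE))
      s <- Biostrings::subseq(genome[[contig]], from, to)
    }
    seq <- as.character(s)
    data.frame(gene_id = g, sequence = seq, length = nchar(seq),
               truncated = nchar(seq) < length)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), sequence = character(),
                      length = integer(), truncated = logical())
  }
  rownames(out) <- NULL
  structure(out, promoter_length = length,
            anchor = "translation_start",
            class = c("promoter_set", "data.frame"))
}

#' Motif presence enrichment in a DEG set (2x2 chi-square)
#'
#' Tests whether motif-bearing promoters are over-represented among a DEG set
#' relative to the remaining expressed-gene background, using a 2x2 chi-square
#' on motif presence/absence (1 df, no continuity correction by default).
#'
#' @param deg_genes Character vector of DE gene ids (must be a subset of
#'   `background_genes`).
#' @param background_genes Character vector: the expressed-gene universe.
#' @param hits A `motif_hits` table covering the background (genes absent from
#'   the table, or excluded from scanning, are dropped from the universe).
#' @param yates Apply Yates continuity correction (default `FALSE`).
#' @return One-row `enrichment_result` data.frame: counts `k` (motif+ in
#'   set), `n` (set size), `K` (motif+ in background), `N` (background size),
#'   proportions, chi-square `statistic`, `p_value` and `direction`
#'   (`"over"`/`"under"`).
#' @export
mdm_enrichment <- function(deg_genes, background_genes, hits, yates = FALSE) {
  scanned <- hits$gene_id[!is.na(hits$has_motif)]
  background_genes <- unique(intersect(background_genes, scanned))
  deg_genes <- unique(deg_genes)
  if (!all(deg_genes %in% background_genes)) {
    stop("deg_genes must be a subset of the (scanned) background")
  }
  if (!length(deg_genes)) stop("empty DEG set: chi-square test undefined")
  motif_pos <- hits$gene_id[!is.na(hits$has_motif) & hits$has_motif]
  K <- sum(background_genes %in% motif_pos)
  if (K == 0L) {
    stop("no motif-bearing gene in the background: chi-square test undefined")
  }
  N <- length(background_genes)
  n <- length(deg_genes)
  k <- sum(deg_genes %in% motif_pos)
  pat <- attr(hits, "pattern")
  .chisq_2x2_result(k, n, K, N, yates = yates,
                    label = if (is.null(pat)) NA_character_ else pat)
}

# Shared 2x2 chi-square machinery: set of size n with k positives inside a
# universe of size N with K positives. Compares the set against the REMAINING
# background (n vs N - n).
.chisq_2x2_result <- function(k, n, K, N, yates = FALSE, label = NA_character_) {
  tab <- matrix(c(k, n - k, K - k, (N - n) - (K - k)), nrow = 2L)
  if (any(tab < 0)) stop("inconsistent 2x2 counts")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  prop_set <- k / n
  prop_bg <- (K - k) / (N - n)
  out <- data.frame(label = label, k = k, n = n, K = K, N = N,
                    prop_set = prop_set, prop_background = prop_bg,
                    statistic = unname(ht$statistic),
                    p_value = unname(ht$p.value),
                    direction = if (prop_set >= prop_bg) "over" else "under")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Filter mitochondrial dysfunction stimulon (MDS) candidate genes
#'
#' A gene is an MDS candidate when it (1) belongs to the supplied regulatory
#' network gene list, (2) carries the motif in its promoter, (3) is
#' differentially expressed following both required treatments (default AA and
#' 3AT), and (4) is responsive in at least one further treatment, i.e. DE in
#' at least `min_treatments` of the treatment panel. Direction is
#' unrestricted.
#'
#' @param network_genes Character vector of regulatory-network member genes.
#' @param hits A `motif_hits` table.
#' @param calls A `deg_calls` data.frame covering all treatments for the
#'   relevant species.
#' @param required_treatments Treatments in which the gene must be DE
#'   (default `c("AA", "3AT")`); set `require_all = FALSE` to demand only one
#'   of them.
#' @param min_treatments Minimum total number of treatments with a DE call
#'   (default 3).
#' @param require_all Logical; all required treatments (`TRUE`, default) or
#'   at least one of them.
#' @return data.frame of candidates: `gene_id`, `n_treatments`, plus one
#'   log2fc column per treatment (`NA` where the gene is not DE), ready for
#'   heatmap export.
#' @export
mds_candidates <- function(network_genes, hits, calls,
                           required_treatments = c("AA", "3AT"),
                           min_treatments = 3, require_all = TRUE) {
  treatments <- sort(unique(calls$treatment))
  missing_t <- setdiff(required_treatments, treatments)
  if (length(missing_t)) {
    stop("calls lack required treatment(s): ",
         paste(missing_t, collapse = ", "))
  }
  motif_pos <- hits$gene_id[!is.na(hits$has_motif) & hits$has_motif]
  cand <- intersect(network_genes, motif_pos)
  if (!length(cand)) return(.empty_mds(treatments))
  cc <- calls[calls$gene_id %in% cand, , drop = FALSE]
  de_in <- function(g, t) any(cc$gene_id == g & cc$treatment == t)
  keep <- vapply(cand, function(g) {
    req <- vapply(required_treatments, de_in, NA, g = g)
    n_de <- length(unique(cc$treatment[cc$gene_id == g]))
    (if (require_all) all(req) else any(req)) && n_de >= min_treatments
  }, NA)
  cand <- cand[keep]
  if (!length(cand)) return(.empty_mds(treatments))
  prof <- vapply(treatments, function(t) {
    v <- rep(NA_real_, length(cand))
    m <- match(cand, cc$gene_id[cc$treatment == t])
    v[!is.na(m)] <- cc$log2fc[cc$treatment == t][m[!is.na(m)]]
    v
  }, numeric(length(cand)))
  prof <- matrix(prof, nrow = length(cand),
                 dimnames = list(NULL, treatments))
  out <- data.frame(gene_id = cand,
                    n_treatments = unname(vapply(cand, function(g) {
                      length(unique(cc$treatment[cc$gene_id == g]))
                    }, 0L)),
                    check.names = FALSE)
  rownames(out) <- NULL
  cbind(out, as.data.frame(prof, check.names = FALSE))
}

.empty_mds <- function(treatments) {
  out <- data.frame(gene_id = character(), n_treatments = integer(),
                    check.names = FALSE)
  for (t in treatments) out[[t]] <- numeric()
  out
}
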