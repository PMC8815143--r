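#' Design object for the synthetic three-species stress-response dataset
#'
#' Fixes every tunable of the generator: the species and treatment rosters,
#' the number of orthogroups, the probability of within-species paralogs, the
#' mixture of planted orthogroup response classes, the planted effect size
#' and noise on the log2 fold-change scale, per-promoter motif-planting
#' rates and the promoter length. The same design (including `seed`) always
#' regenerates byte-identical outputs.
#'
#' @param seed Integer random seed.
#' @param n_orthogroups Number of orthogroups (>= 1).
#' @param species Ordered species labels (default `c("At", "Os", "Hv")`).
#' @param treatments Ordered treatment labels (default the six-stress panel
#'   `c("3AT", "AA", "ABA", "MV", "SA", "UV")`).
#' @param paralog_prob Probability in \[0, 1\] that a species contributes a
#'   second gene to an orthogroup.
#' @param class_fractions Named probabilities over the planted classes
#'   `conserved_all`, `conserved_pair`, `opposite_pair`, `species_specific`,
#'   `mixed_within_species`, `null`; must be >= 0 and sum to 1 (tolerance
#'   1e-9). When `paralog_prob` is 0 the mixed class cannot be realised (it
#'   needs two paralogs) and its mass is folded into `species_specific`.
#' @param effect_size Mean |log2 fold-change| of planted DE genes.
#' @param noise_sd Standard deviation of log2 fold-change noise.
#' @param motif_rate_background,motif_rate_target Per-promoter probabilities
#'   of planting one exact motif instance in non-target / target promoters.
#' @param promoter_len Promoter length in bases (default 2000).
#' @return A validated `synthetic_design` list.
#' @export
synthetic_design <- function(seed = 1L,
                             n_orthogroups = 500L,
                             species = c("At", "Os", "Hv"),
                             treatments = c("3AT", "AA", "ABA", "MV", "SA",
                                            "UV"),
                             paralog_prob = 0.3,
                             class_fractions = c(conserved_all = 0.15,
                                                 conserved_pair = 0.15,
                                                 opposite_pair = 0.15,
                                                 species_specific = 0.20,
                                                 mixed_within_species = 0.05,
                                                 null = 0.30),
                             effect_size = 3,
                             noise_sd = 0.2,
                             motif_rate_background = 0.05,
                             motif_rate_target = 0.15,
                             promoter_len = 2000L) {
  classes <- c("conserved_all", "conserved_pair", "opposite_pair",
               "species_specific", "mixed_within_species", "null")
  if (!setequal(names(class_fractions), classes)) {
    stop("class_fractions must be named: ", paste(classes, collapse = ", "))
  }
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0)) stop("class_fractions must be >= 0")
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1 (got ", sum(class_fractions), ")")
  }
  if (n_orthogroups < 1L) stop("n_orthogroups must be >= 1")
  if (paralog_prob < 0 || paralog_prob > 1) {
    stop("paralog_prob must be in [0, 1]")
  }
  for (p in c(motif_rate_background, motif_rate_target)) {
    if (p < 0 || p > 1) stop("motif rates must be in [0, 1]")
  }
  if (anyDuplicated(species) || anyDuplicated(treatments)) {
    stop("species and treatment labels must be unique")
  }
  if (length(species) < 2L) stop("need at least two species")
  if (paralog_prob == 0 && class_fractions[["mixed_within_species"]] > 0) {
    class_fractions[["species_specific"]] <-
      class_fractions[["species_specific"]] +
      class_fractions[["mixed_within_species"]]
    class_fractions[["mixed_within_species"]] <- 0
  }
  structure(list(seed = as.integer(seed), n_orthogroups = as.integer(n_orthogroups),
                 species = species, treatments = treatments,
                 paralog_prob = paralog_prob,
                 class_fractions = class_fractions,
                 effect_size = effect_size, noise_sd = noise_sd,
                 motif_rate_background = motif_rate_background,
                 motif_rate_target = motif_rate_target,
                 promoter_len = as.integer(promoter_len)),
            class = "synthetic_design")
}

#' Generate orthogroups with planted response classes
#'
#' Every orthogroup receives one gene per species plus, with probability
#' `paralog_prob`, a second (paralog) gene, and is assigned a planted response
#' class drawn from `class_fractions`. Orthogroups planted as
#' `mixed_within_species` are guaranteed two paralogs in their designated
#' species. Gene identifiers encode the species prefix
#' (`<species>_OG<k>_g<j>`).
#'
#' @param design A `synthetic_design`.
#' @return An `orthogroup_set` (long data.frame) with extra attributes
#'   `class_labels` (named character: planted class per orthogroup) and
#'   `mixed_species` (designated species for mixed orthogroups, `NA`
#'   otherwise).
#' @export
generate_orthogroups <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  n <- design$n_orthogroups
  sp <- design$species
  og_ids <- sprintf("OG%06d", seq_len(n))
  og_class <- sample(names(design$class_fractions), n, replace = TRUE,
                     prob = design$class_fractions)
  names(og_class) <- og_ids

  extra <- matrix(stats::rbinom(n * length(sp), 1L, design$paralog_prob),
                  nrow = n, dimnames = list(og_ids, sp))
  mixed_sp <- rep(NA_character_, n)
  names(mixed_sp) <- og_ids
  is_mixed <- og_class == "mixed_within_species"
  if (any(is_mixed)) {
    mixed_sp[is_mixed] <- sample(sp, sum(is_mixed), replace = TRUE)
    extra[cbind(which(is_mixed), match(mixed_sp[is_mixed], sp))] <- 1L
  }

  rows <- vector("list", n * length(sp))
  idx <- 0L
  for (i in seq_len(n)) {
    for (j in seq_along(sp)) {
      k <- 1L + extra[i, j]
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        og_id = og_ids[[i]], species = sp[[j]],
        gene_id = sprintf("%s_OG%06d_g%d", sp[[j]], i, seq_len(k)))
    }
  }
  tab <- do.call(rbind, rows)
  out <- orthogroup_set(tab, species = sp)
  attr(out, "class_labels") <- og_class
  attr(out, "mixed_species") <- mixed_sp
  out
}

# Truncated normal on (-1, 1): null-gene fold-change noise, guaranteed to sit
# below the DEG fold-change threshold.
.rnorm_trunc1 <- function(n, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  lo <- stats::pnorm(-1, 0, sd)
  hi <- stats::pnorm(1, 0, sd)
  stats::qnorm(stats::runif(n, lo, hi), 0, sd)
}

#' Generate per-(species, treatment) DE statistic tables with truth labels
#'
#' Plants the orthogroup classes drawn by [generate_orthogroups()] into DE
#' statistics. Each non-null orthogroup is active in a uniformly drawn subset
#' of treatments (1 to all); in an active treatment its designated species
#' carry q-values from Uniform(0, 0.05) and log2 fold-changes of
#' `sign * effect_size + Normal(0, noise_sd)`, with signs set by the class
#' (shared for conserved, opposing for opposite pairs, one up / one down
#' paralog for the mixed class). All other gene/treatment combinations are
#' null: q-value from Uniform(0.05, 1) and log2 fold-change from a Normal
#' truncated to |log2FC| < 1.
#'
#' @param design The `synthetic_design` used for [generate_orthogroups()].
#' @param orthogroups The matching `orthogroup_set`.
#' @return List with `tables` (named list `"<species>.<treatment>"` of
#'   `stat_table`s covering every gene of the species) and `truth` (data.frame
#'   `og_id`, `treatment`, `class` — the planted class in active treatments,
#'   `"null"` otherwise — plus designated `species` and `direction`).
#' @export
generate_deg_tables <- function(design, orthogroups) {
  stopifnot(inherits(design, "synthetic_design"))
  og_class <- attr(orthogroups, "class_labels")
  mixed_sp <- attr(orthogroups, "mixed_species")
  if (is.null(og_class)) {
    stop("orthogroups must come from generate_orthogroups() on this design")
  }
  set.seed(design$seed + 1L)
  sp <- design$species
  tr <- design$treatments
  og_ids <- names(og_class)
  n_tr <- length(tr)

  # planted sign per (gene, treatment); 0 = null
  genes <- orthogroups$gene_id
  sign_mat <- matrix(0, nrow = length(genes), ncol = n_tr,
                     dimnames = list(genes, tr))
  truth <- vector("list", length(og_ids))
  for (i in seq_along(og_ids)) {
    og <- og_ids[[i]]
    cls <- og_class[[og]]
    truth_row <- data.frame(og_id = og, treatment = tr, class = "null",
                            species = NA_character_,
                            direction = NA_character_)
    if (cls != "null") {
      n_active <- sample.int(n_tr, 1L)
      active <- sort(sample.int(n_tr, n_active))
      members <- orthogroups[orthogroups$og_id == og, , drop = FALSE]
      designated <- switch(cls,
        conserved_all = sp,
        conserved_pair = sort(sample(sp, 2L)),
        opposite_pair = sample(sp, 2L),   # order carries the sign split
        species_specific = sample(sp, 1L),
        mixed_within_species = mixed_sp[[og]])
      for (t in active) {
        d <- sample(c(1, -1), 1L)
        if (cls == "mixed_within_species") {
          g <- members$gene_id[members$species == designated]
          sign_mat[g[[1L]], t] <- 1
          sign_mat[g[[2L]], t] <- -1
          dir_label <- "mixed"
        } else if (cls == "opposite_pair") {
          g1 <- members$gene_id[members$species == designated[[1L]]]
          g2 <- members$gene_id[members$species == designated[[2L]]]
          sign_mat[g1, t] <- d
          sign_mat[g2, t] <- -d
          dir_label <- if (d > 0) "up" else "down"
        } else {
          g <- members$gene_id[members$species %in% designated]
          sign_mat[g, t] <- d
          dir_label <- if (d > 0) "up" else "down"
        }
        truth_row$class[[t]] <- cls
        truth_row$direction[[t]] <- dir_label
      }
      truth_row$species <- paste(designated, collapse = ",")
    }
    truth[[i]] <- truth_row
  }
  truth <- do.call(rbind, truth)

  tables <- list()
  for (s in sp) {
    s_genes <- orthogroups$gene_id[orthogroups$species == s]
    for (t in tr) {
      sg <- sign_mat[s_genes, t]
      de <- sg != 0
      qval <- numeric(length(s_genes))
      lfc <- numeric(length(s_genes))
      qval[de] <- stats::runif(sum(de), 0, 0.05)
      lfc[de] <- sg[de] * design$effect_size +
        stats::rnorm(sum(de), 0, design$noise_sd)
      qval[!de] <- stats::runif(sum(!de), 0.05, 1)
      lfc[!de] <- .rnorm_trunc1(sum(!de), design$noise_sd)
      tables[[paste(s, t, sep = ".")]] <-
        stat_table(data.frame(gene_id = s_genes, log2fc = lfc, qval = qval),
                   species = s, treatment = t)
    }
  }
  list(tables = tables, truth = truth)
}

# Realise one concrete instance of a degenerate pattern.
.realize_motif <- function(pattern) {
  paste(vapply(pattern$sets, function(s) {
    if (length(s) == 1L) s else sample(s, 1L)
  }, ""), collapse = "")
}

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate promoters with planted motifs (and optionally a genome on disk)
#'
#' Every gene receives an iid uniform A/C/G/T promoter of `promoter_len`
#' bases. With probability `motif_rate_target` (genes in `target_genes`) or
#' `motif_rate_background` (all others), one exact instance of the degenerate
#' pattern — degenerate positions drawn uniformly from their allowed sets —
#' overwrites the promoter at a uniform random offset; chance matches of the
#' pattern may add more occurrences. When `dir` is given, a genome FASTA (one
#' contig per gene, promoter plus a short CDS, half the genes on the minus
#' strand) and matching GFF3 gene models are written such that
#' [extract_promoters()] reproduces the in-memory sequences exactly.
#'
#' @param design A `synthetic_design` (`promoter_len` must be >= the pattern
#'   length).
#' @param orthogroups The `orthogroup_set` whose genes receive promoters.
#' @param target_genes Character vector (subset of the orthogroup genes)
#'   planted at the target rate.
#' @param pattern IUPAC string or `motif_pattern` to plant (default the MDM,
#'   `"CTTGNNNNNCAMG"`).
#' @param dir Output directory for `genome.fa` / `genes.gff3`, or `NULL`
#'   (default) for in-memory promoters only.
#' @return List with `promoters` (a `promoter_set`), `planted` (named logical:
#'   was an instance planted), `fasta` and `gff3` (paths or `NA`).
#' @export
generate_promoters <- function(design, orthogroups, target_genes = character(),
                               pattern = "CTTGNNNNNCAMG", dir = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  if (is.character(pattern)) pattern <- motif_pattern(pattern)
  L <- design$promoter_len
  if (L < pattern$length) {
    stop("promoter_len (", L, ") is shorter than the pattern (",
         pattern$length, ")")
  }
  genes <- orthogroups$gene_id
  bad <- setdiff(target_genes, genes)
  if (length(bad)) {
    stop("target gene(s) not in the orthogroup set: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  set.seed(design$seed + 2L)
  rate <- ifelse(genes %in% target_genes, design$motif_rate_target,
                 design$motif_rate_background)
  planted <- stats::runif(length(genes)) < rate
  seqs <- vapply(seq_along(genes), function(i) {
    s <- .random_seq(L)
    if (planted[[i]]) {
      inst <- .realize_motif(pattern)
      off <- sample.int(L - pattern$length + 1L, 1L)
      substr(s, off, off + pattern$length - 1L) <- inst
    }
    s
  }, "")
  names(planted) <- genes
  promoters <- structure(
    data.frame(gene_id = genes, sequence = seqs, length = nchar(seqs),
               truncated = FALSE),
    promoter_length = L, anchor = "translation_start",
    class = c("promoter_set", "data.frame"))

  fasta <- gff3 <- NA_character_
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    cds_len <- 60L
    strand <- rep_len(c("+", "-"), length(genes))
    contigs <- character(length(genes))
    gff <- character()
    rc <- function(s) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    for (i in seq_along(genes)) {
      cds <- paste0("ATG", .random_seq(cds_len - 6L), "TGA")
      contig_id <- paste0("ctg_", genes[[i]])
      if (strand[[i]] == "+") {
        contigs[[i]] <- paste0(seqs[[i]], cds)
        c1 <- L + 1L
        c2 <- L + cds_len
      } else {
        contigs[[i]] <- paste0(rc(cds), rc(seqs[[i]]))
        c1 <- 1L
        c2 <- cds_len
      }
      tid <- paste0(genes[[i]], ".t1")
      gff <- c(gff, paste(
        c(paste(contig_id, "synth", "gene", c1, c2, ".", strand[[i]], ".",
                paste0("ID=", genes[[i]]), sep = "\t"),
          paste(contig_id, "synth", "mRNA", c1, c2, ".", strand[[i]], ".",
                paste0("ID=", tid, ";Parent=", genes[[i]]), sep = "\t"),
          paste(contig_id, "synth", "CDS", c1, c2, ".", strand[[i]], "0",
                paste0("ID=", tid, ".cds;Parent=", tid), sep = "\t"))))
    }
    genome <- Biostrings::DNAStringSet(contigs)
    names(genome) <- paste0("ctg_", genes)
    fasta <- file.path(dir, "genome.fa")
    gff3 <- file.path(dir, "genes.gff3")
    Biostrings::writeXStringSet(genome, fasta)
    writeLines(c("##gff-version 3", gff), gff3)
  }
  list(promoters = promoters, planted = planted, fasta = fasta, gff3 = gff3)
}

#' Write a complete synthetic dataset to disk
#'
#' Materialises one synthetic study: `Orthogroups.tsv` (OrthoFinder v2
#' dialect), one DE statistic TSV per (species, treatment)
#' (`deg_<species>_<treatment>.tsv`), the planted truth labels
#' (`truth_labels.tsv`), the genome FASTA and GFF3 with planted promoter
#' motifs, and `network.txt` — the regulatory-network stand-in, defined as
#' the motif-target genes (genes of orthogroups active in the AA-like
#' treatment given by `target_treatment`).
#'
#' @param design A `synthetic_design`.
#' @param dir Output directory (created if needed).
#' @param target_treatment Treatment whose responsive genes are planted at the
#'   target motif rate and written as the network list (default `"AA"`).
#' @param pattern IUPAC pattern to plant (default `"CTTGNNNNNCAMG"`).
#' @return Invisibly, a list with the generated in-memory objects
#'   (`orthogroups`, `deg`, `promoters`, `planted`) and all file paths.
#' @export
write_synthetic_dataset <- function(design, dir, target_treatment = "AA",
                                    pattern = "CTTGNNNNNCAMG") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ogs <- generate_orthogroups(design)
  deg <- generate_deg_tables(design, ogs)
  active <- deg$truth[deg$truth$treatment == target_treatment &
                        deg$truth$class != "null", , drop = FALSE]
  target_genes <- character()
  for (i in seq_len(nrow(active))) {
    des <- strsplit(active$species[[i]], ",", fixed = TRUE)[[1L]]
    target_genes <- c(target_genes,
                      ogs$gene_id[ogs$og_id == active$og_id[[i]] &
                                    ogs$species %in% des])
  }
  target_genes <- unique(target_genes)
  prom <- generate_promoters(design, ogs, target_genes = target_genes,
                             pattern = pattern, dir = dir)

  og_path <- file.path(dir, "Orthogroups.tsv")
  write_orthogroups(ogs, og_path)
  deg_paths <- character()
  for (nm in names(deg$tables)) {
    p <- file.path(dir, paste0("deg_", sub("\\.", "_", nm), ".tsv"))
    write_tsv(deg$tables[[nm]][, c("gene_id", "log2fc", "qval")], p)
    deg_paths[[nm]] <- p
  }
  truth_path <- file.path(dir, "truth_labels.tsv")
  write_tsv(deg$truth, truth_path)
  network_path <- file.path(dir, "network.txt")
  writeLines(target_genes, network_path)
  invisible(list(orthogroups = ogs, deg = deg, promoters = prom$promoters,
                 planted = prom$planted, target_genes = target_genes,
                 paths = list(orthogroups = og_path, deg = deg_paths,
                              truth = truth_path, network = network_path,
                              fasta = prom$fasta, gff3 = prom$gff3)))
}

#' Predict the planted class of each (orthogroup, treatment) cell
#'
#' Reduces a [summarize_directions()] table back to the synthetic generator's
#' class vocabulary so recovered classes can be compared against planted
#' truth labels: any up+down split across species is `opposite_pair`; all
#' species sharing a direction is `conserved_all`; a shared direction in
#' exactly two species is `conserved_pair`; a single responsive species is
#' `species_specific`; a mixed-excluded species with no other response is
#' `mixed_within_species`; otherwise `null`.
#'
#' @param summaries A `direction_summary`.
#' @return data.frame `og_id`, `treatment`, `predicted_class`.
#' @export
predict_og_class <- function(summaries) {
  roster <- attr(summaries, "species")
  n_sp <- length(roster)
  arr <- .state_wide(summaries)
  og_ids <- dimnames(arr)[[1L]]
  treatments <- dimnames(arr)[[3L]]
  grid <- expand.grid(og_id = og_ids, treatment = treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pred <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    st <- arr[grid$og_id[[r]], , grid$treatment[[r]]]
    u <- sum(st == "up")
    d <- sum(st == "down")
    m <- sum(st == "mixed_excluded")
    pred[[r]] <- if (u >= 1 && d >= 1) "opposite_pair"
    else if (u == n_sp || d == n_sp) "conserved_all"
    else if (u == 2 || d == 2) "conserved_pair"
    else if (u + d == 1) "species_specific"
    else if (m >= 1) "mixed_within_species"
    else "null"
  }
  data.frame(og_id = grid$og_id, treatment = grid$treatment,
             predicted_class = pred)
}
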