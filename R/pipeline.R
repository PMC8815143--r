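#' Round half away from zero to the nearest integer
#'
#' Display rounding for human-readable percentage columns (machine outputs
#' keep one decimal): 0.5 rounds up, unlike base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector (`NA` preserved).
#' @export
round_half_up <- function(x) {
  ifelse(is.na(x), NA_real_, sign(x) * floor(abs(x) + 0.5))
}

#' Percentage of a count pair in machine and display form
#'
#' @param numerator,denominator Non-negative counts.
#' @return One-row data.frame: `numerator`, `denominator`, `pct` (one
#'   decimal), `pct_display` (integer, round half up). A zero denominator
#'   yields `NA` percentages.
#' @export
report_percentages <- function(numerator, denominator) {
  pct <- if (denominator > 0) 100 * numerator / denominator else NA_real_
  data.frame(numerator = numerator, denominator = denominator,
             pct = round(pct, 1L), pct_display = round_half_up(pct))
}

#' Export a log2 fold-change heatmap matrix for an orthogroup set
#'
#' Builds the gene x (species.treatment) matrix used for conserved/opposite
#' response heatmaps: one row per gene of every orthogroup in the set (row
#' names `og_id:gene_id`), columns ordered species-major / treatment-minor
#' per the rosters, entries holding the DEG log2 fold-change and `NA` where
#' the gene was not called for that treatment (a gene is only ever non-`NA`
#' in its own species' columns).
#'
#' @param og_set Character vector of orthogroup ids, or the result of
#'   [multi_treatment_filter()].
#' @param calls A `deg_calls` data.frame.
#' @param orthogroups The `orthogroup_set` giving orthogroup membership.
#' @param species,treatments Column rosters; default the orthogroup roster
#'   and the sorted treatments present in `calls`.
#' @return Numeric matrix (possibly 0-row) with dimnames.
#' @export
export_heatmap_matrix <- function(og_set, calls, orthogroups,
                                  species = NULL, treatments = NULL) {
  if (is.list(og_set) && !is.null(og_set$og_ids)) og_set <- og_set$og_ids
  if (is.null(species)) species <- attr(orthogroups, "species")
  if (is.null(treatments)) treatments <- sort(unique(calls$treatment))
  cols <- as.vector(t(outer(species, treatments, paste, sep = ".")))
  members <- orthogroups[orthogroups$og_id %in% og_set, , drop = FALSE]
  m <- matrix(NA_real_, nrow = nrow(members), ncol = length(cols),
              dimnames = list(paste(members$og_id, members$gene_id,
                                    sep = ":"), cols))
  if (!nrow(members)) return(m)
  hit <- calls[calls$gene_id %in% members$gene_id, , drop = FALSE]
  if (nrow(hit)) {
    ri <- match(hit$gene_id, members$gene_id)
    ci <- match(paste(hit$species, hit$treatment, sep = "."), cols)
    keep <- !is.na(ci)
    m[cbind(ri[keep], ci[keep])] <- hit$log2fc[keep]
  }
  m
}

#' Build and validate a pipeline configuration
#'
#' @param orthogroups Path to the orthogroup table.
#' @param deg_tables Named character vector of DE statistic TSV paths, names
#'   `"<species>.<treatment>"`.
#' @param out_dir Output directory (created by [run_pipeline()]).
#' @param species,treatments Rosters; defaults derived from `deg_tables`
#'   names (species in first-appearance order, treatments sorted).
#' @param fasta,gff3 Optional genome FASTA / GFF3 for promoter extraction.
#' @param network Optional path to the regulatory-network gene list used by
#'   the MDS candidate filter.
#' @param lfc_threshold,fdr_threshold DEG thresholds (defaults 1 and 0.05).
#' @param pattern IUPAC promoter motif (default the MDM `"CTTGNNNNNCAMG"`).
#' @param promoter_length Promoter length in bases (default 2000).
#' @param strands `"both"` or `"forward"` for the motif scan.
#' @param alpha Significance threshold used in reports (default 0.05).
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(orthogroups, deg_tables, out_dir,
                            species = NULL, treatments = NULL,
                            fasta = NULL, gff3 = NULL, network = NULL,
                            lfc_threshold = 1, fdr_threshold = 0.05,
                            pattern = "CTTGNNNNNCAMG",
                            promoter_length = 2000,
                            strands = c("both", "forward"),
                            alpha = 0.05, seed = 1L) {
  strands <- match.arg(strands)
  if (is.null(orthogroups)) stop("config field 'orthogroups' is required")
  if (is.null(deg_tables) || !length(deg_tables)) {
    stop("config field 'deg_tables' is required")
  }
  parts <- strsplit(names(deg_tables), ".", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("deg_tables names must be '<species>.<treatment>'")
  }
  sp <- vapply(parts, `[[`, "", 1L)
  tr <- vapply(parts, `[[`, "", 2L)
  if (is.null(species)) species <- unique(sp)
  if (is.null(treatments)) treatments <- sort(unique(tr))
  if (anyDuplicated(species) || anyDuplicated(treatments)) {
    stop("species and treatment labels must be unique")
  }
  for (p in c(orthogroups, unname(deg_tables), fasta, gff3, network)) {
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  }
  structure(list(orthogroups = orthogroups, deg_tables = deg_tables,
                 out_dir = out_dir, species = species,
                 treatments = treatments, fasta = fasta, gff3 = gff3,
                 network = network, lfc_threshold = lfc_threshold,
                 fdr_threshold = fdr_threshold, pattern = pattern,
                 promoter_length = promoter_length, strands = strands,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key = value file
#'
#' Plain-text format: optional `[section]` headers, `key = value` lines,
#' `#` comments. DE tables are given as `deg.<species>.<treatment> = path`;
#' every other key matches a [pipeline_config()] argument (`species` and
#' `treatments` as comma-separated lists).
#'
#' @param path Config file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !grepl("^\\[.*\\]$", lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) {
    stop("malformed config line ", bad[[1L]], ": '", lines[[bad[[1L]]]], "'")
  }
  keys <- trimws(vapply(kv, `[[`, "", 2L))
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  named <- stats::setNames(vals, keys)
  is_deg <- startsWith(keys, "deg.")
  deg_tables <- stats::setNames(vals[is_deg], sub("^deg\\.", "", keys[is_deg]))
  getv <- function(k, default = NULL) {
    if (k %in% keys) unname(named[[k]]) else default
  }
  split_csv <- function(x) if (is.null(x)) NULL else trimws(strsplit(x, ",")[[1L]])
  pipeline_config(
    orthogroups = getv("orthogroups"),
    deg_tables = deg_tables,
    out_dir = if (!is.null(out_dir)) out_dir else getv("out_dir", "results"),
    species = split_csv(getv("species")),
    treatments = split_csv(getv("treatments")),
    fasta = getv("fasta"), gff3 = getv("gff3"), network = getv("network"),
    lfc_threshold = as.numeric(getv("lfc_threshold", "1")),
    fdr_threshold = as.numeric(getv("fdr_threshold", "0.05")),
    pattern = getv("pattern", "CTTGNNNNNCAMG"),
    promoter_length = as.numeric(getv("promoter_length", "2000")),
    strands = getv("strands", "both"),
    alpha = as.numeric(getv("alpha", "0.05")),
    seed = as.integer(getv("seed", "1")))
}

#' Run the full cross-species comparison pipeline
#'
#' Stages: read inputs, call DEGs, per-species treatment summaries
#' (treatment-specific sets and pairwise-overlap matrices), orthogroup
#' direction summaries with mixed-direction exclusion, conserved/opposite
#' classification and tallies, k-of-n multi-treatment filters (common in >= 3
#' treatments across all species; up-regulated in >= 4; opposite pair in
#' >= 4), and — when a genome and gene models are configured — promoter
#' extraction, motif scanning, per-(species, treatment) motif enrichment and
#' the MDS candidate filter. All result tables are written as TSV under
#' `out_dir` together with a manifest recording the seed, a config hash and
#' per-stage row counts.
#'
#' @param config A `pipeline_config` (or path to a config file).
#' @return Invisibly, a list of the in-memory stage results (`calls`,
#'   `summaries`, `classes`, `counts`, `filters`, `hits`, `enrichment`,
#'   `mds`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list()
  note <- function(stage, rows) {
    message("[", stage, "] ", rows, " rows")
    manifest[[length(manifest) + 1L]] <<- data.frame(stage = stage,
                                                     rows = rows)
  }

  ogs <- read_orthogroups(config$orthogroups, species = config$species)
  note("read_orthogroups", nrow(ogs))
  stats_tabs <- lapply(names(config$deg_tables), function(nm) {
    p <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    read_stat_table(config$deg_tables[[nm]], species = p[[1L]],
                    treatment = p[[2L]])
  })
  expressed <- lapply(split(
    unlist(lapply(stats_tabs, `[[`, "gene_id")),
    unlist(lapply(stats_tabs, `[[`, "species"))), unique)

  calls <- bind_calls(lapply(stats_tabs, call_degs,
                             lfc_threshold = config$lfc_threshold,
                             fdr_threshold = config$fdr_threshold))
  note("call_degs", nrow(calls))
  write_tsv(calls, file.path(out, "deg_calls.tsv"))

  spec <- treatment_specific(calls)
  write_tsv(spec, file.path(out, "treatment_specific.tsv"))
  note("treatment_specific", nrow(spec))
  overlaps <- pairwise_overlap(calls, treatments = config$treatments)
  for (s in names(overlaps)) {
    write_tsv(overlaps[[s]], file.path(out, paste0("overlap_", s, ".tsv")),
              rownames_as = "treatment")
  }

  summaries <- summarize_directions(ogs, calls,
                                    treatments = config$treatments)
  note("summarize_directions", nrow(summaries))
  write_tsv(as.data.frame(summaries),
            file.path(out, "direction_summary.tsv"))
  unassigned <- attr(summaries, "unassigned")
  write_tsv(unassigned, file.path(out, "unassigned_degs.tsv"))

  classes <- classify_responses(summaries)
  note("classify_responses", nrow(classes))
  write_tsv(as.data.frame(classes), file.path(out, "response_classes.tsv"))
  counts <- summarize_counts(classes, calls)
  write_tsv(counts, file.path(out, "response_counts.tsv"))
  note("summarize_counts", nrow(counts))

  filters <- list(
    common_k3 = multi_treatment_filter(classes, k = 3,
                                       scope = "common_all_species"),
    common_up_k4 = multi_treatment_filter(classes, k = 4,
                                          scope = "common_all_species",
                                          direction = "up"),
    opposite_k4 = multi_treatment_filter(classes, k = 4,
                                         scope = "opposite_any_pair"))
  for (nm in names(filters)) {
    f <- filters[[nm]]
    write_tsv(data.frame(og_id = f$og_ids,
                         n_qualifying = unname(f$n_qualifying)),
              file.path(out, paste0("ogs_", nm, ".tsv")))
    hm <- export_heatmap_matrix(f, calls, ogs, species = config$species,
                                treatments = config$treatments)
    write_tsv(hm, file.path(out, paste0("heatmap_", nm, ".tsv")),
              rownames_as = "og_gene")
    note(paste0("filter_", nm), length(f$og_ids))
  }

  hits <- NULL
  enrichment <- NULL
  mds <- NULL
  if (!is.null(config$fasta) && !is.null(config$gff3)) {
    promoters <- extract_promoters(config$fasta, config$gff3,
                                   length = config$promoter_length)
    note("extract_promoters", nrow(promoters))
    hits <- scan_motif(config$pattern, promoters, strands = config$strands)
    write_tsv(as.data.frame(hits), file.path(out, "motif_hits.tsv"))
    note("scan_motif", sum(hits$has_motif, na.rm = TRUE))
    enr <- list()
    for (s in config$species) {
      for (t in config$treatments) {
        deg <- unique(calls$gene_id[calls$species == s &
                                      calls$treatment == t])
        bg <- intersect(expressed[[s]], hits$gene_id[!is.na(hits$has_motif)])
        deg <- intersect(deg, bg)
        if (!length(deg)) next
        r <- mdm_enrichment(deg, bg, hits)
        r$species <- s
        r$treatment <- t
        enr[[paste(s, t)]] <- r
      }
    }
    enrichment <- do.call(rbind, enr)
    if (!is.null(enrichment)) {
      write_tsv(enrichment, file.path(out, "motif_enrichment.tsv"))
      note("mdm_enrichment", nrow(enrichment))
    }
    if (!is.null(config$network) &&
        all(c("AA", "3AT") %in% config$treatments)) {
      network <- read_gene_list(config$network)
      mds <- lapply(config$species, function(s) {
        mds_candidates(network, hits,
                       calls[calls$species == s, , drop = FALSE])
      })
      names(mds) <- config$species
      mds_tab <- do.call(rbind, lapply(config$species, function(s) {
        x <- mds[[s]]
        if (nrow(x)) cbind(data.frame(species = s), x) else NULL
      }))
      if (is.null(mds_tab)) mds_tab <- data.frame()
      write_tsv(mds_tab, file.path(out, "mds_candidates.tsv"))
      note("mds_candidates", if (nrow(mds_tab)) nrow(mds_tab) else 0L)
    }
  }

  manifest <- do.call(rbind, manifest)
  cfg_file <- tempfile()
  dput(unclass(config), file = cfg_file)
  manifest <- rbind(
    data.frame(stage = c("seed", "config_md5"),
               rows = c(config$seed, unname(tools::md5sum(cfg_file)))),
    data.frame(stage = manifest$stage, rows = as.character(manifest$rows)))
  unlink(cfg_file)
  write_tsv(manifest, file.path(out, "manifest.tsv"))

  invisible(list(calls = calls, summaries = summaries, classes = classes,
                 counts = counts, filters = filters, overlaps = overlaps,
                 treatment_specific = spec, hits = hits,
                 enrichment = enrichment, mds = mds, manifest = manifest))
}
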