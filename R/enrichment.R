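#' Hypergeometric over-representation of labels in a gene set
#'
#' For each label (e.g. a transcription-factor family) with K carriers in the
#' background universe of size N, tests whether the gene set of size n holds
#' more carriers (k) than expected under sampling without replacement:
#' one-sided upper-tail p = P[X >= k], X ~ Hypergeom(N, K, n).
#' Under-representation is reported as the lower tail P[X <= k].
#'
#' @param gene_set Character vector of genes (subset of `background`).
#' @param label_map data.frame with columns `gene_id`, `label` (e.g. from
#'   [read_annotation_map()]).
#' @param background Character vector: the expressed-gene universe.
#' @return `enrichment_result` data.frame, one row per label present in the
#'   background: counts `k`, `n`, `K`, `N`, `p_over`, `p_under`, `p_value`
#'   (the over-representation tail), BH-adjusted columns `p_over_bh` /
#'   `p_under_bh`, and `direction`. Labels with no carrier in the background
#'   are skipped with a message.
#' @export
hypergeom_enrichment <- function(gene_set, label_map, background) {
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% background)) {
    stop("gene_set must be a subset of the background")
  }
  N <- length(background)
  n <- length(gene_set)
  labels <- unique(label_map$label)
  rows <- lapply(labels, function(lab) {
    carriers <- unique(label_map$gene_id[label_map$label == lab])
    K <- sum(background %in% carriers)
    if (K == 0L) {
      message("label '", lab, "' absent from background; skipped")
      return(NULL)
    }
    k <- sum(gene_set %in% carriers)
    p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_under <- stats::phyper(k, K, N - K, n)
    data.frame(label = lab, k = k, n = n, K = K, N = N,
               p_over = p_over, p_under = p_under,
               direction = if (k / n >= K / N) "over" else "under")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(label = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_over = numeric(),
                      p_under = numeric(), direction = character())
  }
  out$p_value <- out$p_over
  out$p_over_bh <- stats::p.adjust(out$p_over, method = "BH")
  out$p_under_bh <- stats::p.adjust(out$p_under, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Fisher exact over-representation of categories in a gene set
#'
#' Fisher's exact test on the 2x2 table (in set & in category, in set & not,
#' out of set & in category, out & not), one category at a time. This is the
#' statistic used by category over-representation tools on functional bins.
#'
#' @param gene_set Character vector of genes (subset of `background`).
#' @param category_map data.frame with columns `gene_id`, `label`; a gene may
#'   carry several category labels.
#' @param background Character vector: the expressed-gene universe.
#' @param alternative `"greater"` (over-representation, default), `"less"`,
#'   or `"two.sided"`.
#' @return `enrichment_result` data.frame, one row per category present in
#'   the background, with counts, `p_value`, BH column and `direction`. Empty
#'   categories are skipped.
#' @export
fisher_ora <- function(gene_set, category_map, background,
                       alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% background)) {
    stop("gene_set must be a subset of the background")
  }
  N <- length(background)
  n <- length(gene_set)
  labels <- unique(category_map$label)
  rows <- lapply(labels, function(lab) {
    carriers <- unique(category_map$gene_id[category_map$label == lab])
    K <- sum(background %in% carriers)
    if (K == 0L) {
      message("category '", lab, "' absent from background; skipped")
      return(NULL)
    }
    k <- sum(gene_set %in% carriers)
    tab <- matrix(c(k, n - k, K - k, (N - n) - (K - k)), nrow = 2L)
    p <- stats::fisher.test(tab, alternative = alternative)$p.value
    data.frame(label = lab, k = k, n = n, K = K, N = N, p_value = p,
               direction = if (k / n >= K / N) "over" else "under")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(label = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      direction = character())
  }
  out$p_value_bh <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Chi-square enrichment of a binary gene property in a set
#'
#' 2x2 chi-square (1 df, no continuity correction by default) of a binary
#' property (e.g. producing a cell-to-cell mobile mRNA) in a gene set versus
#' the remaining background. Reports the set and background percentages
#' alongside the test.
#'
#' @param gene_set Character vector of genes (subset of `background`).
#' @param property_genes Character vector of genes carrying the property.
#' @param background Character vector: the universe over which the property is
#'   defined.
#' @param yates Apply Yates continuity correction (default `FALSE`).
#' @return One-row `enrichment_result` with counts, percentages (`pct_set`,
#'   `pct_background`, and integer `pct_set_display` rounded half up),
#'   chi-square `statistic`, `p_value` and `direction`.
#' @export
property_enrichment_chisq <- function(gene_set, property_genes, background,
                                      yates = FALSE) {
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (!length(gene_set)) stop("empty gene set: chi-square test undefined")
  if (!all(gene_set %in% background)) {
    stop("gene_set must be a subset of the background")
  }
  K <- sum(background %in% property_genes)
  if (K == 0L) stop("property absent from background: test undefined")
  N <- length(background)
  n <- length(gene_set)
  k <- sum(gene_set %in% property_genes)
  out <- .chisq_2x2_result(k, n, K, N, yates = yates, label = "property")
  out$pct_set <- round(100 * k / n, 1L)
  out$pct_background <- round(100 * K / N, 1L)
  out$pct_set_display <- round_half_up(100 * k / n)
  out
}

#' Detect families enriched in opposite directions between species
#'
#' Flags every (family, treatment, species pair) where a family is
#' significantly over-represented in the up-regulated gene set of one species
#' and in the down-regulated set of another species for the same treatment
#' (or vice versa).
#'
#' @param enrichments data.frame with columns `species`, `treatment`,
#'   `direction` (`"up"`/`"down"`: the DEG direction of the tested set),
#'   `label` (family) and `p_value` (over-representation p).
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @return data.frame of flagged tuples: `label`, `treatment`, `species_up`,
#'   `species_down`, `p_up`, `p_down` (one row per ordered up/down species
#'   pair).
#' @export
opposite_family_detection <- function(enrichments, alpha = 0.05) {
  sig <- enrichments[enrichments$p_value < alpha, , drop = FALSE]
  up <- sig[sig$direction == "up", , drop = FALSE]
  dn <- sig[sig$direction == "down", , drop = FALSE]
  if (!nrow(up) || !nrow(dn)) {
    return(data.frame(label = character(), treatment = character(),
                      species_up = character(), species_down = character(),
                      p_up = numeric(), p_down = numeric()))
  }
  hit <- merge(up[, c("label", "treatment", "species", "p_value")],
               dn[, c("label", "treatment", "species", "p_value")],
               by = c("label", "treatment"), suffixes = c("_up", "_down"))
  hit <- hit[hit$species_up != hit$species_down, , drop = FALSE]
  names(hit)[names(hit) == "p_value_up"] <- "p_up"
  names(hit)[names(hit) == "p_value_down"] <- "p_down"
  out <- hit[order(hit$label, hit$treatment, hit$species_up), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
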