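#' Call differentially expressed genes from a statistic table
#'
#' A gene is called differentially expressed when its FDR-adjusted p-value is
#' strictly below `fdr_threshold` and its absolute log2 fold-change passes
#' `lfc_threshold`. The fold-change comparator defaults to `>=`; a strict `>`
#' comparator is available because figure legends and methods sections of
#' published studies differ on the edge case.
#'
#' @param stats A `stat_table` (see [read_stat_table()]), or a data.frame with
#'   columns `species`, `treatment`, `gene_id`, `log2fc`, `qval` possibly
#'   covering several species/treatments.
#' @param lfc_threshold Minimum absolute log2 fold-change (default 1).
#' @param fdr_threshold FDR cut-off, strict (default 0.05).
#' @param lfc_comparator `">="` (default) or `">"`.
#' @return A `deg_calls` data.frame with columns `species`, `treatment`,
#'   `gene_id`, `direction` (`"up"`/`"down"`), `log2fc`, `qval`; one row per
#'   called gene.
#' @export
call_degs <- function(stats, lfc_threshold = 1, fdr_threshold = 0.05,
                      lfc_comparator = c(">=", ">")) {
  lfc_comparator <- match.arg(lfc_comparator)
  stopifnot(lfc_threshold > 0, fdr_threshold > 0)
  pass_lfc <- if (lfc_comparator == ">=") {
    abs(stats$log2fc) >= lfc_threshold
  } else {
    abs(stats$log2fc) > lfc_threshold
  }
  keep <- pass_lfc & stats$qval < fdr_threshold
  out <- data.frame(species = stats$species[keep],
                    treatment = stats$treatment[keep],
                    gene_id = stats$gene_id[keep],
                    direction = ifelse(stats$log2fc[keep] > 0, "up", "down"),
                    log2fc = stats$log2fc[keep],
                    qval = stats$qval[keep])
  rownames(out) <- NULL
  class(out) <- c("deg_calls", "data.frame")
  out
}

#' Combine per-table DEG calls
#'
#' @param ... `deg_calls` data.frames (or a single list of them).
#' @return A single `deg_calls` data.frame.
#' @export
bind_calls <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !is.data.frame(xs[[1L]])) {
    xs <- xs[[1L]]
  }
  out <- do.call(rbind, lapply(xs, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("deg_calls", "data.frame")
  out
}

#' Treatment-specific DEGs within each species
#'
#' A gene is specific to treatment t in a species when it is called for t and
#' for no other treatment in that species, regardless of direction.
#'
#' @param calls A `deg_calls` data.frame covering >= 2 treatments.
#' @return data.frame with columns `species`, `treatment`, `gene_id` listing
#'   the treatment-specific genes.
#' @export
treatment_specific <- function(calls) {
  if (length(unique(calls$treatment)) < 2L) {
    stop("treatment_specific() needs calls for at least two treatments")
  }
  u <- unique(calls[, c("species", "gene_id", "treatment")])
  n_treat <- stats::ave(seq_len(nrow(u)),
                        paste(u$species, u$gene_id, sep = "\r"),
                        FUN = length)
  out <- u[n_treat == 1L, c("species", "treatment", "gene_id")]
  rownames(out) <- NULL
  out
}

#' Pairwise treatment-overlap matrices of DEG counts
#'
#' For each species, counts genes called in both members of every treatment
#' pair, irrespective of direction. The diagonal holds the per-treatment DEG
#' count.
#'
#' @param calls A `deg_calls` data.frame.
#' @param treatments Ordered treatment roster; defaults to the treatments
#'   present, sorted.
#' @param direction `"any"` (default) counts overlaps irrespective of
#'   direction; `"up"` / `"down"` restrict to calls of that direction.
#' @return Named list (one entry per species) of symmetric integer matrices
#'   with treatment dimnames.
#' @export
pairwise_overlap <- function(calls, treatments = NULL,
                             direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  if (direction != "any") {
    calls <- calls[calls$direction == direction, , drop = FALSE]
  }
  if (is.null(treatments)) treatments <- sort(unique(calls$treatment))
  if (length(treatments) < 2L) {
    stop("pairwise_overlap() needs at least two treatments")
  }
  lapply(split(calls, calls$species), function(sp) {
    sets <- lapply(treatments, function(t) unique(sp$gene_id[sp$treatment == t]))
    names(sets) <- treatments
    m <- matrix(0L, length(treatments), length(treatments),
                dimnames = list(treatments, treatments))
    for (i in seq_along(treatments)) {
      for (j in seq_along(treatments)) {
        m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
      }
    }
    m
  })
}
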