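#' Summarise DEG directions per orthogroup, species and treatment
#'
#' For every (orthogroup, species, treatment) cell the member genes' DEG calls
#' are reduced to one of four states: `up` (at least one DE gene, all DE genes
#' up), `down` (all DE genes down), `mixed_excluded` (the species contributes
#' both up- and down-regulated genes to the orthogroup for that treatment, so
#' its genes are excluded from classification for that treatment), or `absent`
#' (no DE gene).
#'
#' @param orthogroups An `orthogroup_set` (see [read_orthogroups()]).
#' @param calls A `deg_calls` data.frame.
#' @param treatments Ordered treatment roster; defaults to treatments present
#'   in `calls`, sorted.
#' @return A `direction_summary` data.frame with one row per (orthogroup,
#'   species, treatment): columns `og_id`, `species`, `treatment`, `state`,
#'   `n_up`, `n_down`, `genes` (comma-separated DE gene ids contributing to
#'   the cell). DEG calls whose gene belongs to no orthogroup are returned in
#'   the `unassigned` attribute.
#' @export
summarize_directions <- function(orthogroups, calls, treatments = NULL) {
  roster <- attr(orthogroups, "species")
  if (is.null(treatments)) treatments <- sort(unique(calls$treatment))
  og_ids <- unique(orthogroups$og_id)

  idx <- match(calls$gene_id, orthogroups$gene_id)
  unassigned <- calls[is.na(idx), , drop = FALSE]
  assigned <- calls[!is.na(idx), , drop = FALSE]
  assigned$og_id <- orthogroups$og_id[idx[!is.na(idx)]]

  fo <- factor(assigned$og_id, levels = og_ids)
  fs <- factor(assigned$species, levels = roster)
  ft <- factor(assigned$treatment, levels = treatments)
  up_arr <- table(fo[assigned$direction == "up"],
                  fs[assigned$direction == "up"],
                  ft[assigned$direction == "up"])
  down_arr <- table(fo[assigned$direction == "down"],
                    fs[assigned$direction == "down"],
                    ft[assigned$direction == "down"])

  grid <- expand.grid(og_id = og_ids, species = roster,
                      treatment = treatments, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  n_up <- as.integer(up_arr)[seq_len(nrow(grid))]
  n_down <- as.integer(down_arr)[seq_len(nrow(grid))]
  state <- ifelse(n_up > 0 & n_down > 0, "mixed_excluded",
                  ifelse(n_up > 0, "up",
                         ifelse(n_down > 0, "down", "absent")))
  key <- paste(assigned$og_id, assigned$species, assigned$treatment,
               sep = "\r")
  gene_by_cell <- vapply(split(assigned$gene_id, key), paste, "",
                         collapse = ",")
  gkey <- paste(grid$og_id, grid$species, grid$treatment, sep = "\r")
  genes <- unname(gene_by_cell[gkey])
  genes[is.na(genes)] <- ""

  out <- data.frame(og_id = grid$og_id, species = grid$species,
                    treatment = grid$treatment, state = state,
                    n_up = n_up, n_down = n_down, genes = genes)
  structure(out, species = roster, treatments = treatments,
            unassigned = unassigned,
            class = c("direction_summary", "data.frame"))
}

# Wide per-(og, treatment) state matrix: rows og x treatment grid, one column
# of states per species, in roster order. Shared by classify and the filters.
.state_wide <- function(summaries) {
  roster <- attr(summaries, "species")
  treatments <- attr(summaries, "treatments")
  if (is.null(roster)) roster <- unique(summaries$species)
  if (is.null(treatments)) treatments <- unique(summaries$treatment)
  og_ids <- unique(summaries$og_id)
  arr <- array(NA_character_,
               dim = c(length(og_ids), length(roster), length(treatments)),
               dimnames = list(og_ids, roster, treatments))
  arr[cbind(match(summaries$og_id, og_ids),
            match(summaries$species, roster),
            match(summaries$treatment, treatments))] <- summaries$state
  arr[is.na(arr)] <- "absent"
  arr
}

#' Classify conserved and opposite responses per orthogroup
#'
#' For each focal (orthogroup, species, treatment) with a non-excluded `up` or
#' `down` state, records which other species share the direction
#' (`conserved_with`) and which show the opposing direction (`opposite_with`).
#' Species whose state is `absent` or `mixed_excluded` appear in neither set,
#' so the mixed-direction exclusion propagates into the classification.
#'
#' @param summaries A `direction_summary` from [summarize_directions()].
#' @return A `response_class` data.frame: one row per focal (orthogroup,
#'   species, treatment) cell (all states retained, so downstream tallies can
#'   see exclusions), with comma-separated `conserved_with` / `opposite_with`
#'   species sets, their sizes, the focal `state`, contributing `genes` and
#'   `n_genes`.
#' @export
classify_responses <- function(summaries) {
  roster <- attr(summaries, "species")
  treatments <- attr(summaries, "treatments")
  if (is.null(roster)) roster <- unique(summaries$species)
  if (is.null(treatments)) treatments <- unique(summaries$treatment)
  arr <- .state_wide(summaries)
  og_ids <- dimnames(arr)[[1L]]

  oi <- match(summaries$og_id, og_ids)
  ti <- match(summaries$treatment, treatments)
  focal <- summaries$state
  flip <- c(up = "down", down = "up")

  cons <- opp <- matrix(FALSE, nrow(summaries), length(roster),
                        dimnames = list(NULL, roster))
  directional <- focal %in% c("up", "down")
  for (o in roster) {
    other_state <- arr[cbind(oi, match(o, roster), ti)]
    same_sp <- summaries$species == o
    cons[, o] <- directional & !same_sp & other_state == focal
    opp[, o] <- directional & !same_sp &
      other_state == unname(flip[focal])
  }
  collapse <- function(m) {
    apply(m, 1L, function(r) paste(roster[r], collapse = ","))
  }
  out <- data.frame(og_id = summaries$og_id, species = summaries$species,
                    treatment = summaries$treatment, state = focal,
                    conserved_with = collapse(cons),
                    opposite_with = collapse(opp),
                    n_conserved = rowSums(cons), n_opposite = rowSums(opp),
                    genes = summaries$genes,
                    n_genes = ifelse(nzchar(summaries$genes),
                                     lengths(strsplit(summaries$genes, ",",
                                                      fixed = TRUE)), 0L))
  structure(out, species = roster, treatments = treatments,
            class = c("response_class", "data.frame"))
}

#' Multi-treatment (k-of-n) orthogroup filters
#'
#' `scope = "common_all_species"` keeps an orthogroup when, in at least `k`
#' treatments, every species in the roster has the same non-excluded
#' direction (with `direction = "up"` or `"down"` additionally pinning that
#' shared direction). `scope = "opposite_any_pair"` keeps an orthogroup when
#' at least `k` treatments contain at least one species pair with opposing
#' directions; with `same_pair = TRUE` a single species pair must be opposite
#' in >= `k` treatments.
#'
#' @param classes A `response_class` from [classify_responses()].
#' @param k Minimum number of qualifying treatments (1 <= k <= n treatments).
#' @param scope `"common_all_species"` or `"opposite_any_pair"`.
#' @param direction `"any"` (default), `"up"` or `"down"`; used by the common
#'   scope only.
#' @param same_pair Logical; strict variant of the opposite scope (see above).
#' @return List with elements `og_ids` (kept orthogroups),
#'   `n_qualifying` (named integer: qualifying-treatment count per kept OG),
#'   `genes` (data.frame `og_id`, `species`, `treatment`, `gene_id` of the DE
#'   genes contributing in qualifying treatments) and the filter settings.
#' @export
multi_treatment_filter <- function(classes, k,
                                   scope = c("common_all_species",
                                             "opposite_any_pair"),
                                   direction = c("any", "up", "down"),
                                   same_pair = FALSE) {
  scope <- match.arg(scope)
  direction <- match.arg(direction)
  roster <- attr(classes, "species")
  treatments <- attr(classes, "treatments")
  if (is.null(roster)) roster <- unique(classes$species)
  if (is.null(treatments)) treatments <- unique(classes$treatment)
  if (k < 1L || k > length(treatments)) {
    stop("k must be between 1 and the number of treatments (",
         length(treatments), ")")
  }
  arr <- .state_wide(classes)
  og_ids <- dimnames(arr)[[1L]]
  n_og <- length(og_ids)
  n_t <- length(treatments)

  # qual[og, treatment]: does the treatment qualify for this OG?
  if (scope == "common_all_species") {
    qual <- matrix(FALSE, n_og, n_t, dimnames = list(og_ids, treatments))
    for (t in seq_len(n_t)) {
      st <- arr[, , t, drop = FALSE]
      dim(st) <- c(n_og, length(roster))
      all_dir <- rowSums(st == "up") == length(roster) |
        rowSums(st == "down") == length(roster)
      if (direction != "any") {
        all_dir <- rowSums(st == direction) == length(roster)
      }
      qual[, t] <- all_dir
    }
    keep <- rowSums(qual) >= k
  } else {
    pairs <- utils::combn(roster, 2L, simplify = FALSE)
    # per-pair qualification, then collapse per the same_pair flag
    pair_qual <- array(FALSE, dim = c(n_og, n_t, length(pairs)))
    for (p in seq_along(pairs)) {
      a <- match(pairs[[p]][1L], roster)
      b <- match(pairs[[p]][2L], roster)
      for (t in seq_len(n_t)) {
        sa <- arr[, a, t]
        sb <- arr[, b, t]
        pair_qual[, t, p] <- (sa == "up" & sb == "down") |
          (sa == "down" & sb == "up")
      }
    }
    if (same_pair) {
      per_pair_counts <- apply(pair_qual, c(1L, 3L), sum)
      keep <- apply(per_pair_counts, 1L, max) >= k
      qual <- apply(pair_qual, c(1L, 2L), any)
    } else {
      qual <- apply(pair_qual, c(1L, 2L), any)
      keep <- rowSums(qual) >= k
    }
    dimnames(qual) <- list(og_ids, treatments)
  }

  kept <- og_ids[keep]
  genes <- classes[classes$og_id %in% kept &
                     classes$state %in% c("up", "down") &
                     nzchar(classes$genes), , drop = FALSE]
  if (nrow(genes)) {
    tqual <- qual[cbind(match(genes$og_id, og_ids),
                        match(genes$treatment, treatments))]
    genes <- genes[tqual, , drop = FALSE]
    if (scope == "opposite_any_pair" && nrow(genes)) {
      genes <- genes[genes$n_opposite > 0, , drop = FALSE]
    }
  }
  gene_tab <- if (nrow(genes)) {
    do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      data.frame(og_id = genes$og_id[[i]], species = genes$species[[i]],
                 treatment = genes$treatment[[i]],
                 gene_id = strsplit(genes$genes[[i]], ",", fixed = TRUE)[[1L]])
    }))
  } else {
    data.frame(og_id = character(), species = character(),
               treatment = character(), gene_id = character())
  }
  list(scope = scope, k = k, direction = direction, same_pair = same_pair,
       og_ids = kept,
       n_qualifying = stats::setNames(rowSums(qual)[keep], kept),
       genes = gene_tab)
}

#' Per-species, per-treatment conserved/opposite gene tallies
#'
#' Projects the orthogroup-level classification onto genes and tallies, for
#' each species and treatment, how many DE genes were conserved with both
#' other species, with each single other species only, or in total, and
#' likewise for opposite responses. Percentages are relative to the species'
#' DEG total for that treatment.
#'
#' By default a gene conserved with one species and opposite with the other
#' counts in both tallies; `strict = TRUE` assigns such genes to the opposite
#' tally only.
#'
#' @param classes A `response_class` from [classify_responses()].
#' @param calls The `deg_calls` used to build the summaries (supplies DEG
#'   totals for the percentage denominators).
#' @param strict Logical; see above. Default `FALSE`.
#' @return Long data.frame with columns `species`, `treatment`, `relation`
#'   (`"conserved"`/`"opposite"`), `category` (`"with_both"`,
#'   `"with_<sp>_only"`, `"total"`), `n_genes`, `deg_total`, `pct` (one
#'   decimal) and `pct_display` (integer, round half up).
#' @export
summarize_counts <- function(classes, calls, strict = FALSE) {
  roster <- attr(classes, "species")
  treatments <- attr(classes, "treatments")
  if (is.null(roster)) roster <- unique(classes$species)
  if (is.null(treatments)) treatments <- unique(classes$treatment)

  deg_total <- function(sp, t) {
    length(unique(calls$gene_id[calls$species == sp & calls$treatment == t]))
  }
  rows <- list()
  for (sp in roster) {
    others <- setdiff(roster, sp)
    for (t in treatments) {
      cc <- classes[classes$species == sp & classes$treatment == t &
                      classes$state %in% c("up", "down"), , drop = FALSE]
      has_cons <- cc$n_conserved > 0
      has_opp <- cc$n_opposite > 0
      cons_rows <- if (strict) has_cons & !has_opp else has_cons
      den <- deg_total(sp, t)
      cw <- strsplit(cc$conserved_with, ",", fixed = TRUE)
      ow <- strsplit(cc$opposite_with, ",", fixed = TRUE)
      n_cons_both <- sum(cc$n_genes[cons_rows & lengths(cw) == 2L])
      n_cons_only <- vapply(others, function(o) {
        sum(cc$n_genes[cons_rows & lengths(cw) == 1L &
                         vapply(cw, function(x) identical(x, o), NA)])
      }, 0)
      n_cons_tot <- sum(cc$n_genes[cons_rows])
      n_opp_both <- sum(cc$n_genes[has_opp & lengths(ow) == 2L])
      n_opp_only <- vapply(others, function(o) {
        sum(cc$n_genes[has_opp & lengths(ow) == 1L &
                         vapply(ow, function(x) identical(x, o), NA)])
      }, 0)
      n_opp_tot <- sum(cc$n_genes[has_opp])
      cats <- data.frame(
        species = sp, treatment = t,
        relation = rep(c("conserved", "opposite"),
                       each = length(others) + 2L),
        category = rep(c("with_both", paste0("with_", others, "_only"),
                         "total"), 2L),
        n_genes = c(n_cons_both, n_cons_only, n_cons_tot,
                    n_opp_both, n_opp_only, n_opp_tot),
        deg_total = den)
      rows[[length(rows) + 1L]] <- cats
    }
  }
  out <- do.call(rbind, rows)
  pct <- ifelse(out$deg_total > 0, 100 * out$n_genes / out$deg_total, NA_real_)
  out$pct <- round(pct, 1L)
  out$pct_display <- round_half_up(pct)
  rownames(out) <- NULL
  out
}
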