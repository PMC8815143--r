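#' Read an OrthoFinder-style orthogroup table
#'
#' Parses the `Orthogroups.tsv` dialect written by OrthoFinder v2: a
#' tab-separated table whose first column holds orthogroup identifiers and
#' whose remaining columns hold, per species, the member genes of each
#' orthogroup separated by `", "`. Empty cells mean the species has no gene in
#' that orthogroup.
#'
#' @param path Path to the tab-separated orthogroup file.
#' @param id_column Expected name of the first header cell (default
#'   `"Orthogroup"`).
#' @param species Optional character vector restricting/validating the species
#'   columns. If supplied, a header species not in this roster is an error.
#' @param strip_regex Optional regular expression removed from every gene
#'   identifier (e.g. `"\\.\\d+$"` to drop transcript suffixes). Default
#'   `NULL`: identifiers are kept verbatim.
#'
#' @return An `orthogroup_set`: a data.frame in long form with columns
#'   `og_id`, `species`, `gene_id` (one row per gene) and an attribute
#'   `species` giving the ordered species roster (all header species, including
#'   those with no genes anywhere).
#' @export
read_orthogroups <- function(path, id_column = "Orthogroup", species = NULL,
                             strip_regex = NULL) {
  if (!file.exists(path)) stop("orthogroup file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("orthogroup file is empty: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (header[[1L]] != id_column) {
    stop("first header cell of ", path, " is '", header[[1L]],
         "', expected '", id_column, "'")
  }
  roster <- header[-1L]
  if (!is.null(species)) {
    unknown <- setdiff(roster, species)
    if (length(unknown)) {
      stop("unknown species column(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
    roster <- species[species %in% roster]
  }
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    cells <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    length(cells) <- length(header)         # right-pad missing trailing cells
    cells[is.na(cells)] <- ""
    og <- cells[[1L]]
    out <- lapply(seq_along(roster), function(j) {
      cell <- trimws(cells[[j + 1L]])
      if (!nzchar(cell)) return(NULL)
      genes <- trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
      genes <- genes[nzchar(genes)]
      if (!length(genes)) return(NULL)
      data.frame(og_id = og, species = roster[[j]], gene_id = genes)
    })
    do.call(rbind, out)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(og_id = character(), species = character(),
                      gene_id = character())
  }
  if (!is.null(strip_regex)) tab$gene_id <- sub(strip_regex, "", tab$gene_id)
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup)) {
    stop("gene(s) assigned to more than one orthogroup in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  orthogroup_set(tab, species = roster)
}

#' Construct an orthogroup set from a long gene table
#'
#' @param tab data.frame with columns `og_id`, `species`, `gene_id`.
#' @param species Ordered species roster; defaults to the species present.
#' @return An `orthogroup_set` data.frame (long form) with a `species`
#'   attribute.
#' @export
orthogroup_set <- function(tab, species = NULL) {
  stopifnot(all(c("og_id", "species", "gene_id") %in% names(tab)))
  if (is.null(species)) species <- unique(tab$species)
  bad <- setdiff(unique(tab$species), species)
  if (length(bad)) {
    stop("species not in declared roster: ", paste(bad, collapse = ", "))
  }
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup)) {
    stop("gene(s) assigned to more than one orthogroup: ",
         paste(unique(dup), collapse = ", "))
  }
  tab <- tab[, c("og_id", "species", "gene_id")]
  rownames(tab) <- NULL
  structure(tab, species = species, class = c("orthogroup_set", "data.frame"))
}

#' Write an orthogroup set in OrthoFinder v2 dialect
#'
#' @param ogs An `orthogroup_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(ogs, path) {
  roster <- attr(ogs, "species")
  og_ids <- unique(ogs$og_id)
  header <- paste(c("Orthogroup", roster), collapse = "\t")
  cell <- function(og, sp) {
    g <- ogs$gene_id[ogs$og_id == og & ogs$species == sp]
    paste(g, collapse = ", ")
  }
  body <- vapply(og_ids, function(og) {
    paste(c(og, vapply(roster, cell, "", og = og)), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a per-(species, treatment) differential-expression statistic table
#'
#' Reads a TSV of per-gene test output (gene identifier, log2 fold-change
#' versus mock, FDR-adjusted p-value). Missing q-values are conservatively
#' treated as 1 (not significant); malformed numeric fields are an error that
#' names the offending row.
#'
#' @param path TSV path with a single header line.
#' @param species,treatment Labels attached to every row of the result.
#' @param columns Named character vector mapping the canonical names
#'   `gene_id`, `log2fc`, `qval` to the header names used in the file.
#' @return A `stat_table` data.frame with columns `species`, `treatment`,
#'   `gene_id`, `log2fc`, `qval`.
#' @export
read_stat_table <- function(path, species, treatment,
                            columns = c(gene_id = "gene_id",
                                        log2fc = "log2fc", qval = "qval")) {
  if (!file.exists(path)) stop("stat table not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols)) {
    stop("stat table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  gene_id <- raw[[columns[["gene_id"]]]]
  lfc_chr <- raw[[columns[["log2fc"]]]]
  q_chr <- raw[[columns[["qval"]]]]
  log2fc <- suppressWarnings(as.numeric(lfc_chr))
  bad <- which(is.na(log2fc) & !(is.na(lfc_chr) | lfc_chr %in% c("NA", "")))
  if (length(bad)) {
    stop("non-numeric log2fc in ", path, " at data row ", bad[[1L]],
         ": '", lfc_chr[[bad[[1L]]]], "'")
  }
  if (anyNA(log2fc) || any(!is.finite(log2fc))) {
    i <- which(is.na(log2fc) | !is.finite(log2fc))[[1L]]
    stop("missing or non-finite log2fc in ", path, " at data row ", i,
         " (gene ", gene_id[[i]], ")")
  }
  qna <- is.na(q_chr) | q_chr %in% c("NA", "")
  qval <- suppressWarnings(as.numeric(q_chr))
  bad <- which(is.na(qval) & !qna)
  if (length(bad)) {
    stop("non-numeric qval in ", path, " at data row ", bad[[1L]],
         ": '", q_chr[[bad[[1L]]]], "'")
  }
  qval[qna] <- 1.0
  if (any(qval < 0 | qval > 1)) {
    i <- which(qval < 0 | qval > 1)[[1L]]
    stop("qval outside [0, 1] in ", path, " at data row ", i,
         " (gene ", gene_id[[i]], ")")
  }
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) {
    stop("duplicated gene id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  stat_table(data.frame(gene_id = gene_id, log2fc = log2fc, qval = qval),
             species = species, treatment = treatment)
}

#' Construct a stat table from in-memory vectors
#'
#' @param tab data.frame with columns `gene_id`, `log2fc`, `qval`.
#' @param species,treatment Labels attached to every row.
#' @return A `stat_table` data.frame.
#' @export
stat_table <- function(tab, species, treatment) {
  stopifnot(all(c("gene_id", "log2fc", "qval") %in% names(tab)))
  out <- data.frame(species = species, treatment = treatment,
                    gene_id = tab$gene_id, log2fc = tab$log2fc,
                    qval = tab$qval)
  if (anyDuplicated(out$gene_id)) {
    stop("duplicated gene id(s): ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  }
  stopifnot(all(is.finite(out$log2fc)), all(out$qval >= 0 & out$qval <= 1))
  class(out) <- c("stat_table", "data.frame")
  out
}

#' Read a one-gene-per-line list
#'
#' @param path Text file with one gene identifier per line (blank lines
#'   ignored). An empty file yields an empty set with a warning.
#' @return Character vector of unique gene identifiers, order preserved.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x)]
  if (!length(x)) {
    warning("gene list ", path, " is empty")
    return(character())
  }
  unique(x)
}

#' Read a two-column gene annotation map
#'
#' Reads a headerless (or headered, see `header`) two-column TSV of
#' `gene_id<TAB>label`. For `kind = "tf_family"` a gene may carry at most one
#' family label; for `kind = "category"` multiple labels per gene are allowed.
#' `kind = "binary_property"` and `kind = "network_membership"` accept either
#' a one-column gene list or a two-column file whose second column is ignored.
#'
#' @param path TSV path.
#' @param kind One of `"tf_family"`, `"category"`, `"binary_property"`,
#'   `"network_membership"`.
#' @param header Logical; does the file carry a header line? Default `FALSE`.
#' @return For labelled kinds, a data.frame with columns `gene_id`, `label`
#'   (deduplicated); for binary kinds a character vector of gene identifiers.
#'   Carries attribute `kind`.
#' @export
read_annotation_map <- function(path, kind = c("tf_family", "category",
                                               "binary_property",
                                               "network_membership"),
                                header = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("annotation file ", path, " is empty")
    if (kind %in% c("binary_property", "network_membership")) {
      return(structure(character(), kind = kind))
    }
    return(structure(data.frame(gene_id = character(), label = character()),
                     kind = kind))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  gene_id <- trimws(vapply(parts, `[[`, "", 1L))
  if (any(!nzchar(gene_id))) {
    stop("empty gene id in ", path, " at line ",
         which(!nzchar(gene_id))[[1L]])
  }
  if (kind %in% c("binary_property", "network_membership")) {
    return(structure(unique(gene_id), kind = kind))
  }
  label <- trimws(vapply(parts, function(p) {
    if (length(p) < 2L) NA_character_ else p[[2L]]
  }, ""))
  if (anyNA(label)) {
    stop("missing label column in ", path, " at line ",
         which(is.na(label))[[1L]])
  }
  map <- unique(data.frame(gene_id = gene_id, label = label))
  if (kind == "tf_family" && anyDuplicated(map$gene_id)) {
    dup <- unique(map$gene_id[duplicated(map$gene_id)])
    stop("gene(s) with more than one TF family in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  structure(map, kind = kind)
}

#' Write a data.frame as a diffable TSV
#'
#' Single header line, tab separators, no quoting, no row names; `NA` is
#' written literally so downstream plotting tools can pick it up.
#'
#' @param x data.frame (or matrix with a leading id column when
#'   `rownames_as` is given).
#' @param path Output path.
#' @param rownames_as If non-`NULL` and `x` is a matrix, the column name under
#'   which row names are emitted.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, rownames_as = NULL) {
  if (is.matrix(x)) {
    df <- as.data.frame(x, check.names = FALSE)
    if (!is.null(rownames_as)) {
      rn <- if (is.null(rownames(x))) character(nrow(x)) else rownames(x)
      id <- data.frame(x = rn)
      names(id) <- rownames_as
      df <- cbind(id, df)
    }
    x <- df
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
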