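#' Read a count matrix from delimited text
#'
#' Reads a TSV/CSV count table with one header row and one id column and
#' returns it in the canonical gene x sample orientation. The orientation of
#' the file must be stated explicitly; nothing is auto-detected, because a
#' silently transposed matrix is one of the classic ways an expression
#' analysis goes wrong.
#'
#' @param path Path to a delimited text file. The delimiter is inferred from
#'   the extension (`.csv` = comma, anything else = tab) unless `sep` is given.
#' @param orientation Either `"samples_by_genes"` (samples in rows, the layout
#'   used for patient-level survival tables) or `"genes_by_samples"`.
#' @param sep Field separator; overrides the extension-based default.
#' @return An integer matrix, genes in rows and samples in columns, with
#'   unique row and column names.
#' @export
read_counts <- function(path, orientation = c("genes_by_samples", "samples_by_genes"),
                        sep = NULL) {
  orientation <- match.arg(orientation)
  df <- read_delim_table(path, sep)
  ids <- as.character(df[[1L]])
  body <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(body) <- "double"
  rownames(body) <- ids
  if (orientation == "samples_by_genes") body <- t(body)
  as_count_matrix(body, context = path)
}

#' Write a count matrix to delimited text
#'
#' @param counts Count matrix (genes x samples).
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @param orientation Layout to write, as in [read_counts()].
#' @export
write_counts <- function(counts, path,
                         orientation = c("genes_by_samples", "samples_by_genes")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "samples_by_genes") t(counts) else counts
  id_name <- if (orientation == "samples_by_genes") "sample" else "gene"
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Validate and coerce a numeric matrix into the canonical count matrix.
as_count_matrix <- function(m, context = "counts") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must carry gene and sample identifiers", call. = FALSE)
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  if (nrow(m) < 1L || ncol(m) < 2L)
    stop("need at least 1 gene and 2 samples", call. = FALSE)
  bad <- which(!is.finite(m) | m < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf("invalid count %s at gene '%s', sample '%s' in %s",
                 format(m[bad[1L]]), rownames(m)[i[1L]], colnames(m)[i[2L]],
                 context), call. = FALSE)
  }
  rounded <- round(m)
  off <- which(abs(m - rounded) > 1e-9)
  if (length(off)) {
    i <- arrayInd(off[1L], dim(m))
    stop(sprintf("non-integer count %s at gene '%s', sample '%s' in %s",
                 format(m[off[1L]]), rownames(m)[i[1L]], colnames(m)[i[2L]],
                 context), call. = FALSE)
  }
  storage.mode(rounded) <- "integer"
  rounded
}

#' Read a per-sample survival table
#'
#' Loads time-to-event and event status for each sample. Rows whose time is
#' missing, zero or negative, or whose status is missing, are dropped and
#' counted; a zero-length follow-up carries no information for the Cox
#' partial likelihood, so it is treated like an invalid negative time.
#' Status may be coded 0/1 (1 = death/event, 0 = right-censored) or as the
#' strings "alive"/"dead" (case-insensitive), which are mapped to 0/1.
#'
#' @param path Path to a delimited text file with a sample id column.
#' @param time_col,status_col Column names holding follow-up time and status.
#' @param id_col Column name of the sample id; defaults to the first column.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return A data frame with columns `sample`, `time`, `status`, carrying the
#'   number of dropped rows in `attr(, "n_dropped")`.
#' @export
read_survival <- function(path, time_col = "time", status_col = "status",
                          id_col = NULL, sep = NULL) {
  df <- read_delim_table(path, sep)
  if (is.null(id_col)) id_col <- names(df)[1L]
  for (col in c(id_col, time_col, status_col))
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", path, call. = FALSE)
  out <- data.frame(sample = as.character(df[[id_col]]),
                    time   = suppressWarnings(as.numeric(df[[time_col]])),
                    status = map_status(df[[status_col]]),
                    stringsAsFactors = FALSE)
  keep <- !is.na(out$time) & out$time > 0 & !is.na(out$status)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) dropped (non-positive or missing time/status)")
  out <- out[keep, , drop = FALSE]
  if (anyDuplicated(out$sample))
    stop("duplicate sample ids in survival table: ",
         paste(unique(out$sample[duplicated(out$sample)]), collapse = ", "),
         call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a survival table
#' @param surv Data frame as returned by [read_survival()].
#' @param path Output path.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv[, c("sample", "time", "status")], path,
                     sep = sep_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

map_status <- function(x) {
  if (is.numeric(x)) {
    bad <- x[!is.na(x) & !x %in% c(0, 1)]
    if (length(bad))
      stop("status values outside {0,1}: ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    return(as.integer(x))
  }
  s <- tolower(trimws(as.character(x)))
  out <- ifelse(s %in% c("0", "alive"), 0L,
                ifelse(s %in% c("1", "dead"), 1L, NA_integer_))
  unknown <- unique(s[!is.na(x) & is.na(out) & s != ""])
  if (length(unknown))
    stop("unrecognized status values: ", paste(unknown, collapse = ", "),
         " (expected 0/1 or alive/dead)", call. = FALSE)
  out
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-delimited gene-set exchange format: one set per line, with
#' the set name, a description, then the member gene ids. Duplicate members
#' within a set are dropped with a warning; sets are kept in file order.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of member gene ids, with the
#'   per-set descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields", call. = FALSE)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop("GMT parse error at line ", i, ": empty member list", call. = FALSE)
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[1L], "' dropped", call. = FALSE)
      members <- unique(members)
    }
    nms[i] <- f[1L]; descs[i] <- f[2L]; sets[[i]] <- members
  }
  if (anyDuplicated(nms))
    stop("duplicate set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(sets) <- nms
  names(descs) <- nms
  attr(sets, "description") <- descs
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors (see [read_gmt()]).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "description")
  if (is.null(descs)) descs <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict counts and sample metadata to their common samples
#'
#' Intersects the sample ids of a count matrix with those of a survival table
#' or condition-label table and returns both restricted to the intersection
#' in a single canonical order (the order of appearance in the count matrix).
#'
#' @param counts Count (or expression) matrix, samples in columns.
#' @param meta Data frame with a `sample` column (survival or conditions).
#' @return A list with elements `counts` and `meta`, sample order identical,
#'   plus `n_common`, the intersection size.
#' @export
align_samples <- function(counts, meta) {
  stopifnot(is.matrix(counts), "sample" %in% names(meta))
  common <- intersect(colnames(counts), meta$sample)
  if (length(common) == 0L)
    stop("no samples in common between counts and metadata", call. = FALSE)
  counts <- counts[, common, drop = FALSE]
  meta <- meta[match(common, meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  list(counts = counts, meta = meta, n_common = length(common))
}

#' Read condition labels for the fold-change mode
#'
#' @param path Delimited text with a sample id column and a condition column.
#' @param condition_col Name of the two-level condition column.
#' @param reference Reference level; defaults to the first level in sort order.
#' @param id_col Sample id column name; defaults to the first column.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return Data frame with columns `sample` and `group` (factor, reference
#'   level first).
#' @export
read_conditions <- function(path, condition_col = "condition",
                            reference = NULL, id_col = NULL, sep = NULL) {
  df <- read_delim_table(path, sep)
  if (is.null(id_col)) id_col <- names(df)[1L]
  if (!condition_col %in% names(df))
    stop("column '", condition_col, "' not found in ", path, call. = FALSE)
  make_conditions(as.character(df[[id_col]]),
                  as.character(df[[condition_col]]), reference)
}

make_conditions <- function(sample, group, reference = NULL) {
  lev <- sort(unique(group))
  if (length(lev) != 2L)
    stop("condition must have exactly two levels, found: ",
         paste(lev, collapse = ", "), call. = FALSE)
  if (!is.null(reference)) {
    if (!reference %in% lev)
      stop("reference level '", reference, "' not among levels", call. = FALSE)
    lev <- c(reference, setdiff(lev, reference))
  }
  g <- factor(group, levels = lev)
  if (any(table(g) < 2L))
    stop("each condition level needs at least 2 samples", call. = FALSE)
  data.frame(sample = sample, group = g, stringsAsFactors = FALSE)
}

#' Write enrichment results to a TSV file
#'
#' One row per pathway with columns `pathway`, `pval`, `padj`, `es`, `nes`,
#' `size` and `leading_edge` (member gene ids joined by commas), sorted by
#' ascending p-value with ties broken by pathway name. Numeric columns keep
#' at least 6 significant digits.
#'
#' @param results An enrichment result data frame from [run_enrichment()].
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  if (nrow(df)) {
    df <- df[order(df$pval, df$pathway), , drop = FALSE]
    le <- vapply(df$leading_edge, paste, character(1), collapse = ",")
    out <- data.frame(pathway = df$pathway,
                      pval = signif(df$pval, 10),
                      padj = signif(df$padj, 10),
                      es = signif(df$es, 10),
                      nes = signif(df$nes, 10),
                      size = df$size,
                      leading_edge = le,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(pathway = character(), pval = numeric(),
                      padj = numeric(), es = numeric(), nes = numeric(),
                      size = integer(), leading_edge = character())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an enrichment results TSV
#' @param path Path written by [write_results()].
#' @return Enrichment result data frame with `leading_edge` as a list column.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(leading_edge = "character"))
  df$leading_edge <- lapply(strsplit(df$leading_edge, ",", fixed = TRUE),
                            function(x) x[nzchar(x)])
  class(df) <- c("enrichment_result", "data.frame")
  df
}

read_delim_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- sep_for(path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}
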