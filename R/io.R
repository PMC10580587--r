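# Readers and writers for the pipeline's plain-text formats:
# expression matrices (TSV / GCT 1.2), GMT gene sets, sample annotations,
# and tab-separated result tables.

#' Read a log2 expression matrix from TSV or GCT 1.2
#'
#' TSV layout: a header line whose first field names the gene-id column and whose
#' remaining fields are sample ids, followed by one line per gene. GCT 1.2 layout:
#' a `#1.2` version line, a `<n genes> <tab> <n samples>` line, then a
#' `Name <tab> Description <tab> <samples...>` table.
#'
#' Values are assumed to be on the log2 scale already; set `log2_transform = TRUE`
#' to apply `log2(x + 1)` to raw-scale input. Rows containing missing values are
#' dropped (count reported via [message()]); duplicated gene ids are collapsed by
#' keeping the row with the highest mean expression (also reported).
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"gct"`.
#' @param log2_transform Apply `log2(x + 1)` after reading? Default `FALSE`.
#' @return Numeric matrix, genes in rows (unique rownames), samples in columns
#'   (unique colnames), no missing values.
#' @seealso [write_expression()], [read_gmt()], [read_annotation()]
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "TP53\t5.1\t6.2", "VIM\t7.0\t7.5"), f)
#' read_expression(f)
#' @export
read_expression <- function(path, format = c("tsv", "gct"), log2_transform = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_acetyl("io_error", sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (format == "gct") {
    if (length(lines) < 3L || !identical(trimws(lines[[1L]]), "#1.2"))
      stop_acetyl("format_error", "not a GCT 1.2 file: first line must be '#1.2'")
    dims <- suppressWarnings(as.integer(strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop_acetyl("format_error", "GCT line 2 must give '<rows>\t<columns>'")
    body <- lines[-(1:2)]
    id_cols <- 2L
  } else {
    if (length(lines) < 2L)
      stop_acetyl("format_error", "expression TSV needs a header line and at least one gene row")
    body <- lines
    id_cols <- 1L
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) <= id_cols)
    stop_acetyl("format_error", "malformed header: no sample columns found")
  sample_ids <- header[-seq_len(id_cols)]
  if (anyDuplicated(sample_ids) || any(!nzchar(sample_ids)))
    stop_acetyl("format_error", "malformed header: sample ids must be unique and non-empty")
  rows <- fields[-1L]
  nf <- lengths(rows)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    stop_acetyl("parse_error", sprintf("row %d has %d fields, expected %d",
                                       bad, nf[bad], length(header)))
  }
  gene_ids <- vapply(rows, `[[`, character(1L), 1L)
  raw <- vapply(rows, function(f) f[-seq_len(id_cols)], character(length(sample_ids)))
  raw <- matrix(raw, nrow = length(sample_ids))   # samples x genes, character
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & !(trimws(raw) %in% c("", "NA", "NaN", "na")), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_acetyl("parse_error",
                sprintf("non-numeric value '%s' at gene row %d, sample column %d",
                        raw[bad[1L, 1L], bad[1L, 2L]], bad[1L, 2L], bad[1L, 1L]))
  x <- t(vals)
  dimnames(x) <- list(gene_ids, sample_ids)

  drop <- rowSums(is.na(x)) > 0L
  if (any(drop)) {
    message(sprintf("read_expression: dropped %d row(s) with missing values", sum(drop)))
    x <- x[!drop, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop_acetyl("format_error", "no complete gene rows after filtering")
  if (anyDuplicated(rownames(x))) {
    n_before <- nrow(x)
    means <- rowMeans(x)
    keep <- order(-means)                       # highest-mean row wins
    x <- x[keep, , drop = FALSE]
    x <- x[!duplicated(rownames(x)), , drop = FALSE]
    x <- x[order(match(rownames(x), gene_ids)), , drop = FALSE]
    message(sprintf("read_expression: collapsed %d duplicated gene id(s) by highest mean",
                    n_before - nrow(x)))
  }
  if (log2_transform) x <- log2(x + 1)
  x
}

#' Write an expression matrix to TSV or GCT 1.2
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  body <- apply(format(x, digits = 15, trim = TRUE, scientific = FALSE), 1L,
                paste, collapse = "\t")
  if (format == "gct") {
    writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(x)), collapse = "\t"), con)
    writeLines(paste(rownames(x), "na", body, sep = "\t"), con)
  } else {
    writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
    writeLines(paste(rownames(x), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name <tab> description <tab> member1 <tab> member2 ...`.
#' Duplicate members within a line are removed; empty member fields are ignored.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per set, file order preserved),
#'   with a named `"description"` attribute; class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_acetyl("io_error", sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", sum(keep))
  nms <- desc <- character(sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- fields[[i]]
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(f) < 3L || length(members) == 0L)
      stop_acetyl("parse_error",
                  sprintf("GMT line %d: need name, description and at least one member", i))
    j <- j + 1L
    nms[j] <- f[[1L]]
    desc[j] <- f[[2L]]
    sets[[j]] <- members
  }
  names(sets) <- nms
  structure(sets, description = setNames(desc, nms),
            class = c("gene_set_collection", "list"))
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors; an optional named `"description"`
#'   attribute supplies the second GMT column (default `"na"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# Build + validate a sample annotation data.frame; shared by the reader and
# the synthetic generator. `state` is the two-group label: normal stage ->
# "normal", cancer stage -> "cancer", CIN grades -> NA (excluded from the
# two-group comparison but retained for scoring/correlation).
make_annotation <- function(sample_id, stage, state = NULL) {
  stage <- as.character(stage)
  bad <- setdiff(unique(stage), STAGE_LEVELS)
  if (length(bad))
    stop_acetyl("format_error",
                sprintf("unknown stage label(s): %s (allowed: %s)",
                        paste(bad, collapse = ", "), paste(STAGE_LEVELS, collapse = ", ")))
  if (anyDuplicated(sample_id))
    stop_acetyl("format_error", "duplicated sample ids in annotation")
  derived <- ifelse(stage == "normal", "normal",
                    ifelse(stage == "cancer", "cancer", NA_character_))
  if (is.null(state)) {
    state <- derived
  } else {
    state <- as.character(state)
    badst <- setdiff(stats::na.omit(unique(state)), c("normal", "cancer"))
    if (length(badst))
      stop_acetyl("format_error",
                  sprintf("unknown state label(s): %s", paste(badst, collapse = ", ")))
  }
  data.frame(sample_id = as.character(sample_id),
             stage = factor(stage, levels = STAGE_LEVELS),
             state = state,
             stringsAsFactors = FALSE)
}

#' Read a sample annotation table
#'
#' Two- or three-column TSV with header: `sample_id`, `stage` (one of
#' `normal`, `CIN1`, `CIN2`, `CIN3`, `cancer`) and optionally `state`
#' (`normal`/`cancer`). When `state` is absent it is derived from `stage`
#' (CIN grades get `NA` and are excluded from two-group comparisons).
#'
#' @param path Path to the TSV file.
#' @param expr Optional expression matrix; if given, every annotated sample must
#'   be one of its columns.
#' @return `data.frame` with columns `sample_id`, `stage` (ordered factor),
#'   `state`.
#' @export
read_annotation <- function(path, expr = NULL) {
  if (!file.exists(path)) stop_acetyl("io_error", sprintf("file not found: %s", path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop_acetyl("format_error", "annotation needs at least sample_id and stage columns")
  ann <- make_annotation(tab[[1L]], tab[[2L]],
                         state = if (ncol(tab) >= 3L) tab[[3L]] else NULL)
  if (!is.null(expr)) {
    missing <- setdiff(ann$sample_id, colnames(expr))
    if (length(missing))
      stop_acetyl("alignment_error",
                  sprintf("annotated sample(s) absent from expression matrix: %s",
                          paste(missing, collapse = ", ")))
  }
  ann
}

#' Write a result table as TSV
#'
#' Plain tab-separated text with a header line; numeric columns keep 15
#' significant digits so the pipeline's own tables round-trip through
#' [read_results_table()].
#'
#' @param records A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- tryCatch(
    write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"),
    error = function(e) stop_acetyl("io_error", conditionMessage(e)))
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#'
#' @param path Path to the TSV file.
#' @return `data.frame`.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop_acetyl("io_error", sprintf("file not found: %s", path))
  read.delim(path, stringsAsFactors = FALSE)
}
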