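#' Read and write expression matrices
#'
#' TSV with the gene symbol in the first column (header `gene`) and one
#' column per sample. Duplicate gene or sample IDs and non-numeric cells
#' are rejected rather than coerced.
#'
#' @param path File path.
#' @return `read_expression_tsv` returns a numeric genes x samples
#'   matrix; `write_expression_tsv` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs gene + sample columns", call. = FALSE)
  genes <- normalize_symbols(df[[1L]])
  samples <- colnames(df)[-1L]
  if (anyDuplicated(genes)) {
    stop(sprintf("duplicate gene row(s): %s",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop(sprintf("duplicate sample column(s): %s",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")),
         call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop(sprintf("non-numeric expression value at gene %s, sample %s",
                   genes[bad], samples[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(genes, samples)
  m
}

#' @param matrix Numeric genes x samples matrix.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(matrix, path) {
  matrix <- validate_expression_matrix(matrix)
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write clinical survival tables
#'
#' TSV with columns `sample`, `time`, `event` and optionally `group` plus
#' any further annotation columns (e.g. receptor status).
#'
#' @param path File path.
#' @return `read_clinical_tsv` returns a validated survival table.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(df))) {
    stop("clinical TSV needs columns sample, time, event", call. = FALSE)
  }
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample IDs in clinical table", call. = FALSE)
  }
  validate_survival_table(df, need_group = FALSE)
}

#' @param table Survival table.
#' @rdname read_clinical_tsv
#' @export
write_clinical_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read ChIP-seq peaks (ENCODE narrowPeak or BED6/BED3)
#'
#' narrowPeak (10 columns) carries the summit as an offset from `start`
#' in column 10; an offset of -1 (summit not called) falls back to the
#' interval midpoint. 6- or 3-column BED files are read with midpoint
#' summits. Coordinates stay 0-based half-open throughout. Malformed
#' lines are rejected with their line number.
#'
#' @param path File path.
#' @return A [peak_set()].
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty peak file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ncols <- nf[1L]
  if (!ncols %in% c(3L, 6L, 10L)) {
    stop(sprintf("line 1: expected 3, 6 or 10 tab-separated columns, got %d",
                 ncols), call. = FALSE)
  }
  bad <- which(nf != ncols)
  if (length(bad)) {
    stop(sprintf("line %d: expected %d columns, got %d",
                 bad[1L], ncols, nf[bad[1L]]), call. = FALSE)
  }
  get_col <- function(i) vapply(fields, `[[`, character(1), i)
  num_col <- function(i, what) {
    v <- suppressWarnings(as.numeric(get_col(i)))
    if (anyNA(v)) {
      stop(sprintf("line %d: non-numeric %s", which(is.na(v))[1L], what),
           call. = FALSE)
    }
    v
  }
  chrom <- get_col(1L)
  start <- num_col(2L, "start")
  end <- num_col(3L, "end")
  name <- if (ncols >= 4L) get_col(4L) else NA_character_
  score <- if (ncols >= 5L) suppressWarnings(as.numeric(get_col(5L))) else NA_real_
  summit <- start + floor((end - start) / 2)
  if (ncols == 10L) {
    off <- num_col(10L, "summit offset")
    has_summit <- off >= 0
    summit[has_summit] <- start[has_summit] + off[has_summit]
    out_of_range <- has_summit & (summit < start | summit >= end)
    if (any(out_of_range)) {
      stop(sprintf("line %d: summit offset outside interval",
                   which(out_of_range)[1L]), call. = FALSE)
    }
  }
  peak_set(chrom, start, end, summit = summit, score = score, name = name)
}

#' @param peaks A `peak_set`.
#' @param path Output path.
#' @rdname read_narrowpeak
#' @export
write_narrowpeak <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  df <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = ifelse(is.na(peaks$name), ".", peaks$name),
    score = ifelse(is.na(peaks$score), 0, peaks$score),
    strand = ".", signal = 0, p = -1, q = -1,
    peak = peaks$summit - peaks$start
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3 region file
#'
#' @param path File path.
#' @return A [region_set()].
#' @export
read_bed_regions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty BED file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("line %d: fewer than 3 columns", bad[1L]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("line %d: non-numeric coordinate",
                 which(is.na(start) | is.na(end))[1L]), call. = FALSE)
  }
  region_set(chrom, start, end)
}

#' Read and write dose matrices (CSV)
#'
#' CSV layout: first row holds the doses of drug B (first cell empty or a
#' label), first column the doses of drug A; both grids include 0; cells
#' are percent inhibition.
#'
#' @param path File path.
#' @return `read_dose_matrix_csv` returns a [dose_matrix()].
#' @export
read_dose_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  doses_a <- suppressWarnings(as.numeric(df[[1L]]))
  doses_b <- suppressWarnings(as.numeric(colnames(df)[-1L]))
  if (anyNA(doses_a) || anyNA(doses_b)) {
    stop("non-numeric dose labels in matrix CSV", call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    stop("non-numeric inhibition cell in matrix CSV", call. = FALSE)
  }
  dose_matrix(doses_a, doses_b, vals)
}

#' @param matrix A `dose_matrix`.
#' @rdname read_dose_matrix_csv
#' @export
write_dose_matrix_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "dose_matrix"))
  df <- data.frame(dose_a = matrix$doses_a, matrix$inhibition,
                   check.names = FALSE)
  colnames(df) <- c("dose_a", matrix$doses_b)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write score/label tables
#'
#' Two-column TSVs mapping sample IDs to a score or a group label.
#'
#' @param path File path.
#' @return Named vector (scores: numeric; labels: character).
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("scores TSV needs sample + score columns", call. = FALSE)
  if (anyDuplicated(df[[1L]])) stop("duplicate sample IDs", call. = FALSE)
  if (!is.numeric(df[[2L]])) stop("non-numeric score column", call. = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}

#' @param x Named vector to write.
#' @param value_name Header for the value column.
#' @rdname read_scores_tsv
#' @export
write_scores_tsv <- function(x, path, value_name = "score") {
  df <- data.frame(sample = names(x), value = unname(as.vector(x)))
  colnames(df)[2L] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
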