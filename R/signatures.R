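#' Gene signatures
#'
#' A `gene_signature` is a named, ordered set of unique uppercase gene
#' symbols together with per-gene provenance notes recording which curation
#' rule admitted each gene.
#'
#' @param name Signature name.
#' @param genes Character vector of gene symbols; uppercased, whitespace
#'   stripped, duplicates removed (first occurrence kept).
#' @param provenance Optional character vector, one note per gene after
#'   deduplication, or a single note recycled to all genes.
#' @return An object of class `gene_signature`: a list with elements
#'   `name`, `genes` and `provenance`.
#' @examples
#' gene_signature("toy", c("hes1", "MYC", "HES1"))
#' @export
gene_signature <- function(name, genes, provenance = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  genes <- normalize_symbols(genes)
  if (any(!nzchar(genes))) stop("empty gene symbol in signature", call. = FALSE)
  keep <- !duplicated(genes)
  genes <- genes[keep]
  if (is.null(provenance)) {
    provenance <- rep_len(NA_character_, length(genes))
  } else if (length(provenance) == 1L) {
    provenance <- rep_len(as.character(provenance), length(genes))
  } else {
    provenance <- as.character(provenance)[keep]
  }
  structure(
    list(name = name, genes = genes, provenance = provenance),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature '%s': %d genes\n", x$name, length(x$genes)))
  shown <- utils::head(x$genes, 8L)
  cat("  ", paste(shown, collapse = ", "),
      if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Select differentially regulated genes by thresholds
#'
#' Filters a differential-expression table to the genes passing a log2
#' fold-change threshold and (optionally) an adjusted-p cutoff. The
#' fold-change threshold is applied to `|log2fc|` after direction
#' filtering; thresholds are inclusive (`>=` / `<=`).
#'
#' @param table Data frame with columns `gene`, `log2fc` and optionally
#'   `padj`. One row per gene; duplicates are rejected.
#' @param lfc_min Minimum absolute log2 fold change (>= 0).
#' @param padj_max Adjusted-p cutoff, or `NULL` to filter on fold change
#'   only (the washout tables carry no stated adjusted-p filter).
#' @param direction One of `"up"`, `"down"`, `"both"`.
#' @return Character vector of gene symbols (uppercased, input order).
#' @examples
#' de <- data.frame(gene = c("G1", "G2", "G3"),
#'                  log2fc = c(1.5, 0.5, 2.0),
#'                  padj = c(0.01, 0.001, 0.2))
#' select_regulated_genes(de, lfc_min = 1, padj_max = 0.05)
#' @export
select_regulated_genes <- function(table, lfc_min = 1, padj_max = NULL,
                                   direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  table <- validate_de_table(table, require_padj = !is.null(padj_max))
  stopifnot_scalar_number(lfc_min, "lfc_min")
  if (lfc_min < 0) stop("`lfc_min` must be >= 0", call. = FALSE)
  keep <- switch(direction,
    up   = table$log2fc >= lfc_min,
    down = table$log2fc <= -lfc_min,
    both = abs(table$log2fc) >= lfc_min
  )
  if (!is.null(padj_max)) {
    stopifnot_scalar_number(padj_max, "padj_max")
    keep <- keep & table$padj <= padj_max
  }
  table$gene[keep]
}

validate_de_table <- function(table, require_padj = FALSE) {
  if (!is.data.frame(table)) stop("`table` must be a data frame", call. = FALSE)
  if (!all(c("gene", "log2fc") %in% names(table))) {
    stop("`table` needs columns `gene` and `log2fc`", call. = FALSE)
  }
  table$gene <- normalize_symbols(table$gene)
  if (any(!nzchar(table$gene))) stop("empty gene symbol in DE table", call. = FALSE)
  dup <- table$gene[duplicated(table$gene)]
  if (length(dup)) {
    stop(sprintf("duplicate gene(s) in DE table: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(table$log2fc)) stop("`log2fc` must be numeric", call. = FALSE)
  if (require_padj) {
    if (!"padj" %in% names(table) || anyNA(table$padj)) {
      stop("adjusted-p filtering requested but `padj` is absent or has missing values",
           call. = FALSE)
    }
    if (any(table$padj < 0 | table$padj > 1)) {
      stop("`padj` values must lie in [0, 1]", call. = FALSE)
    }
  }
  table
}

#' Curate a signature from washout, gain-of-function and canonical sets
#'
#' Combines gene sets following the three-step curation rule: the union of
#' the washout (signal-withdrawal) sets is intersected with the
#' gain-of-function set, and the result merged with a canonical collection
#' of manually curated targets. Symbols are uppercased, deduplicated and
#' sorted lexicographically; the provenance slot records the admitting rule
#' per gene.
#'
#' @param washout_sets List of character vectors (at least one).
#' @param gof_set Character vector of gain-of-function regulated genes.
#' @param canonical Character vector of canonical targets.
#' @param name Signature name.
#' @return A [gene_signature].
#' @examples
#' curate_signature(list(c("A", "B"), c("B", "C")),
#'                  gof_set = c("B", "C", "D"), canonical = "E")
#' @export
curate_signature <- function(washout_sets, gof_set, canonical,
                             name = "curated") {
  if (!is.list(washout_sets) || length(washout_sets) == 0L) {
    stop("`washout_sets` must be a non-empty list of gene sets", call. = FALSE)
  }
  washout <- unique(normalize_symbols(unlist(washout_sets, use.names = FALSE)))
  washout <- washout[nzchar(washout)]
  gof <- unique(normalize_symbols(gof_set))
  canonical <- unique(normalize_symbols(canonical))
  canonical <- canonical[nzchar(canonical)]
  core <- intersect(washout, gof)
  genes <- sort(union(core, canonical))
  prov <- ifelse(genes %in% core & genes %in% canonical, "washout&gof+canonical",
          ifelse(genes %in% core, "washout&gof", "canonical"))
  gene_signature(name, genes, prov)
}

#' Load a packaged signature by name
#'
#' The package ships the 77-gene TNBC NOTCH activity signature as
#' `"TNBC_NOTCH_77"`.
#'
#' @param name Registered signature name.
#' @return A [gene_signature].
#' @examples
#' sig <- load_packaged_signature("TNBC_NOTCH_77")
#' length(sig)
#' @export
load_packaged_signature <- function(name = "TNBC_NOTCH_77") {
  available <- c("TNBC_NOTCH_77")
  if (!name %in% available) {
    stop(sprintf("unknown packaged signature '%s'; available: %s",
                 name, paste(available, collapse = ", ")), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".txt"), package = "tnbcnotch",
                      mustWork = TRUE)
  sig <- read_signature(path, name = name)
  if (name == "TNBC_NOTCH_77" && length(sig$genes) != 77L) {
    stop("packaged TNBC_NOTCH_77 is corrupt: expected 77 genes", call. = FALSE)
  }
  sig
}

#' Read / write signature files
#'
#' Signature files carry one symbol per line; lines starting with `#` are
#' provenance header notes and are preserved on round trip.
#'
#' @param path File path.
#' @param name Signature name; defaults to the file name without extension.
#' @return `read_signature` returns a [gene_signature];
#'   `write_signature` returns `path` invisibly.
#' @export
read_signature <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  body <- trimws(lines[!startsWith(lines, "#")])
  body <- body[nzchar(body)]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  sig <- gene_signature(name, body)
  attr(sig, "header") <- header
  sig
}

#' @param sig A [gene_signature].
#' @rdname read_signature
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  header <- attr(sig, "header")
  if (is.null(header)) {
    header <- sprintf("# signature: %s", sig$name)
    notes <- !is.na(sig$provenance)
    if (any(notes)) {
      header <- c(header, sprintf("# %s: %s", sig$genes[notes],
                                  sig$provenance[notes]))
    }
  }
  writeLines(c(header, sig$genes), path)
  invisible(path)
}
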