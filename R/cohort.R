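# Expression cohort container and file I/O.

STAGES <- c("I", "II", "III", "IV")
ALL_STAGES <- c(STAGES, "unknown")
GROUPS <- c("tumor", "normal")

#' Construct an expression cohort
#'
#' An expression cohort bundles a nonnegative gene-by-sample matrix of
#' normalized expression values (RSEM-style normalized abundance estimates,
#' as in TCGA level-3 RNA-seq data) with optional per-sample annotations:
#' a group label (`"tumor"` or `"normal"`) and a tumor stage (`"I"`--`"IV"`
#' or `"unknown"`). Staging applies to tumors only, so every normal sample
#' carries stage `"unknown"`.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty dimnames; all entries must be finite and nonnegative.
#' @param annotations Optional data.frame with columns `sample_id`, `group`
#'   and `stage`, one row per sample of `values`.
#' @return An object of class `expression_cohort`: a list with elements
#'   `genes`, `samples`, `values` and `annotations` (NULL until attached).
#' @seealso [read_expression()], [read_annotations()], [restrict_to_panel()]
#' @export
expression_cohort <- function(values, annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("'values' must have gene rownames and sample colnames")
  genes <- trimws(genes)
  samples <- trimws(samples)
  if (any(genes == "")) stop("empty gene symbol in row names")
  if (any(samples == "")) stop("empty sample id in column names")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene symbol(s): ", paste(dup, collapse = ", "))
  dup <- unique(samples[duplicated(samples)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite expression value for gene '", genes[bad[1L, 1L]],
         "', sample '", samples[bad[1L, 2L]], "'")
  bad <- which(values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative expression value for gene '", genes[bad[1L, 1L]],
         "', sample '", samples[bad[1L, 2L]], "'")
  dimnames(values) <- list(genes, samples)
  x <- structure(list(genes = genes, samples = samples, values = values,
                      annotations = NULL),
                 class = "expression_cohort")
  if (!is.null(annotations)) x <- set_annotations(x, annotations)
  x
}

# Attach a validated, sample-ordered annotation table to a cohort.
set_annotations <- function(cohort, annotations) {
  req <- c("sample_id", "group", "stage")
  if (!is.data.frame(annotations) || !all(req %in% names(annotations)))
    stop("annotations need columns: ", paste(req, collapse = ", "))
  ann <- data.frame(sample_id = trimws(as.character(annotations$sample_id)),
                    group = normalize_group(annotations$group),
                    stage = normalize_stage(annotations$stage),
                    stringsAsFactors = FALSE)
  extra <- setdiff(ann$sample_id, cohort$samples)
  if (length(extra)) {
    warning("ignoring annotation rows for unknown sample(s): ",
            paste(extra, collapse = ", "))
    ann <- ann[!ann$sample_id %in% extra, , drop = FALSE]
  }
  missing <- setdiff(cohort$samples, ann$sample_id)
  if (length(missing))
    stop("missing annotation for sample(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate annotation row(s) for sample(s): ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  ann <- ann[match(cohort$samples, ann$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  bad <- ann$sample_id[ann$group == "normal" & ann$stage != "unknown"]
  if (length(bad))
    stop("normal sample(s) must have stage 'unknown': ",
         paste(bad, collapse = ", "))
  cohort$annotations <- ann
  cohort
}

normalize_group <- function(x) {
  g <- tolower(trimws(as.character(x)))
  bad <- unique(g[!g %in% GROUPS])
  if (length(bad))
    stop("unrecognized group token(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(GROUPS, collapse = ", "), ")")
  g
}

# Stage vocabulary: I--IV plus "unknown", case-insensitive; sub-stages such
# as "IIa"/"IIIB" collapse to their Roman-numeral prefix.
normalize_stage <- function(x) {
  s <- toupper(trimws(as.character(x)))
  s[is.na(x) | s == "" | s == "NA"] <- "UNKNOWN"
  s <- sub("^(IV|III|II|I)[A-C]$", "\\1", s)
  out <- ifelse(s == "UNKNOWN", "unknown", s)
  bad <- unique(out[!out %in% ALL_STAGES])
  if (length(bad))
    stop("unrecognized stage token(s): ", paste(bad, collapse = ", "),
         " (allowed: I, II, III, IV, unknown)")
  out
}

# Sample-id accessors; screening and network construction use these splits.
tumor_samples <- function(cohort) {
  ann <- need_annotations(cohort)
  ann$sample_id[ann$group == "tumor"]
}

normal_samples <- function(cohort) {
  ann <- need_annotations(cohort)
  ann$sample_id[ann$group == "normal"]
}

need_annotations <- function(cohort) {
  if (is.null(cohort$annotations))
    stop("cohort has no sample annotations; call read_annotations() first")
  cohort$annotations
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' The expected layout is one header row whose first field is `gene` and
#' remaining fields are sample ids, followed by one row per gene with the
#' gene symbol in the first column and nonnegative numeric values in the
#' rest. Malformed headers, non-numeric cells, duplicated symbols and
#' negative values are reported with the offending row/column named.
#'
#' @param path Path to a tab-separated expression file.
#' @return An [expression_cohort()] with empty annotations, preserving the
#'   file's gene and sample order.
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L)
    stop("expression file needs a 'gene' column plus at least one sample column")
  if (tolower(trimws(names(raw)[1L])) != "gene")
    stop("malformed header: first column must be 'gene', found '",
         names(raw)[1L], "'")
  genes <- trimws(raw[[1L]])
  samples <- trimws(names(raw)[-1L])
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop("non-numeric value '", col[bad[1L]], "' for gene '",
           genes[bad[1L]], "' in column '", samples[j], "'")
    vals[, j] <- num
  }
  expression_cohort(vals)
}

#' Write an expression cohort's matrix to TSV
#'
#' Inverse of [read_expression()]: the written file round-trips to an
#' identical cohort (same gene/sample order, values to full double
#' precision).
#'
#' @param cohort An [expression_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(cohort, path) {
  df <- data.frame(gene = cohort$genes, cohort$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample annotations and attach them to a cohort
#'
#' The annotation file is a TSV with header `sample_id`, `group`, `stage`.
#' Group tokens are `tumor`/`normal` (case-insensitive); stage tokens are
#' `I`--`IV` or `unknown` (case-insensitive, sub-stages like `IIa`
#' collapsing to `II`). Annotated samples absent from the matrix are
#' ignored with a warning; matrix samples without an annotation are an
#' error, as is a normal sample with a known stage.
#'
#' @param path Path to the annotation TSV.
#' @param cohort The [expression_cohort()] the annotations describe.
#' @return The cohort with annotations attached.
#' @export
read_annotations <- function(path, cohort) {
  ann <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  set_annotations(cohort, ann)
}

#' Write a cohort's annotation table to TSV
#' @param cohort An annotated [expression_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(cohort, path) {
  ann <- need_annotations(cohort)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene panel from a plain-text file
#'
#' One gene symbol per line; `#` starts a comment and blank lines are
#' skipped. This is the format of plasma-proteome gene lists: the set of
#' genes whose protein products are detectable in blood plasma.
#'
#' @param path Path to the panel file.
#' @return Character vector of unique gene symbols, in file order.
#' @export
read_gene_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  symbols <- lines[lines != ""]
  if (!length(symbols)) stop("gene panel file contains no symbols")
  dup <- unique(symbols[duplicated(symbols)])
  if (length(dup))
    stop("duplicate panel symbol(s): ", paste(dup, collapse = ", "))
  symbols
}

#' Restrict a cohort to a gene panel
#'
#' Intersects the cohort's genes with a panel of symbols (case-sensitive
#' match after whitespace trimming, no alias resolution), mirroring the
#' mapping of a plasma-proteome gene list onto an expression data set.
#' The operation is idempotent.
#'
#' @param cohort An [expression_cohort()].
#' @param panel Character vector of gene symbols (e.g. from
#'   [read_gene_panel()]).
#' @return A list with elements `cohort` (restricted to the intersection,
#'   original gene order preserved) and `unmapped` (panel symbols absent
#'   from the cohort).
#' @export
restrict_to_panel <- function(cohort, panel) {
  panel <- trimws(as.character(panel))
  panel <- panel[panel != ""]
  if (!length(panel)) stop("empty gene panel")
  keep <- cohort$genes %in% panel
  if (!any(keep))
    stop("no panel symbol maps to the cohort's genes")
  out <- expression_cohort(cohort$values[keep, , drop = FALSE])
  if (!is.null(cohort$annotations))
    out <- set_annotations(out, cohort$annotations)
  list(cohort = out, unmapped = setdiff(panel, cohort$genes))
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("expression_cohort:", length(x$genes), "genes x",
      length(x$samples), "samples\n")
  if (is.null(x$annotations)) {
    cat("  annotations: none\n")
  } else {
    grp <- table(x$annotations$group)
    cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
        "\n")
    st <- table(factor(x$annotations$stage[x$annotations$group == "tumor"],
                       levels = ALL_STAGES))
    cat("  tumor stages:",
        paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  }
  invisible(x)
}
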