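# Tumor-vs-normal rank-based screening and stage-pattern classification.

PATTERNS <- c("leading_up", "leading_down", "stage_specific",
              "progressive_up", "progressive_down", "not_significant")

#' Mann-Whitney U test for one gene
#'
#' Two-sample rank test of the first (tumor) group against the second
#' (normal) group. The reported U is the tumor-group statistic with midrank
#' tie handling. The p-value is exact when the smaller group has at most 8
#' observations and the pooled values are tie-free, and otherwise uses the
#' normal approximation with tie and continuity corrections. A pooled
#' sample with zero variance (all values identical) is fully tied and
#' returns the central U with p = 1.
#'
#' @param tumor_values,normal_values Numeric vectors, each of length >= 2.
#' @return A list with elements `u` (tumor-group U) and `p` (two-sided
#'   p-value).
#' @export
mann_whitney_u <- function(tumor_values, normal_values) {
  n1 <- length(tumor_values)
  n2 <- length(normal_values)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  pooled <- c(tumor_values, normal_values)
  if (!all(is.finite(pooled))) stop("non-finite expression values")
  if (max(pooled) == min(pooled))
    return(list(u = n1 * n2 / 2, p = 1))
  exact <- min(n1, n2) <= 8L && !anyDuplicated(pooled)
  ht <- suppressWarnings(stats::wilcox.test(tumor_values, normal_values,
                                            exact = exact, correct = TRUE))
  p <- ht$p.value
  if (!is.finite(p)) p <- 1  # degenerate rank variance
  list(u = unname(ht$statistic), p = min(p, 1))
}

# Direction of deregulation at level alpha: median comparison, falling back
# on the U statistic when the medians tie.
de_direction <- function(u, p, med_tumor, med_normal, n1, n2, alpha) {
  if (!(p < alpha)) return("none")
  if (med_tumor > med_normal) return("up")
  if (med_tumor < med_normal) return("down")
  if (u > n1 * n2 / 2) "up" else if (u < n1 * n2 / 2) "down" else "none"
}

#' Screen a cohort for tumor-vs-normal differential expression
#'
#' Runs [mann_whitney_u()] per gene (all tumors against all normals), adds
#' per-stage p-values (tumors of one stage against all normals, for stages
#' with at least two tumors), a Benjamini-Hochberg q-value column (reported
#' for information; the raw p at `alpha` drives all labels), the direction
#' of deregulation, and -- unless `classify = FALSE` -- the stage-pattern
#' label from [classify_patterns()].
#'
#' @param cohort An annotated [expression_cohort()] with >= 2 tumors and
#'   >= 2 normals.
#' @param config A [pipeline_config()].
#' @param classify Assign pattern labels (default TRUE).
#' @return A `differential_table`: data.frame sorted by ascending p with
#'   columns `gene`, `u`, `p`, `q`, `direction`, `p_stage_I`..`p_stage_IV`
#'   (and `pattern` when classified), plus attributes `alpha` and
#'   `stage_counts`.
#' @export
screen_cohort <- function(cohort, config = pipeline_config(),
                          classify = TRUE) {
  validate_config(config)
  ann <- need_annotations(cohort)
  tids <- tumor_samples(cohort)
  nids <- normal_samples(cohort)
  if (length(nids) < 2L) stop("screen needs at least 2 normal samples")
  if (length(tids) < 2L) stop("screen needs at least 2 tumor samples")
  tv <- cohort$values[, tids, drop = FALSE]
  nv <- cohort$values[, nids, drop = FALSE]
  tumor_stage <- ann$stage[match(tids, ann$sample_id)]
  stage_counts <- table(factor(tumor_stage, levels = ALL_STAGES))
  stage_ok <- STAGES[stage_counts[STAGES] >= 2L]
  skipped <- setdiff(STAGES, stage_ok)
  if (length(skipped))
    warning("stage(s) with < 2 tumors skipped in per-stage tests: ",
            paste(skipped, collapse = ", "))

  ng <- length(cohort$genes)
  u <- p <- numeric(ng)
  direction <- character(ng)
  psl <- matrix(NA_real_, ng, 4L,
                dimnames = list(NULL, paste0("p_stage_", STAGES)))
  n1 <- length(tids); n2 <- length(nids)
  for (g in seq_len(ng)) {
    tvg <- tv[g, ]; nvg <- nv[g, ]
    mw <- mann_whitney_u(tvg, nvg)
    u[g] <- mw$u; p[g] <- mw$p
    direction[g] <- de_direction(mw$u, mw$p, stats::median(tvg),
                                 stats::median(nvg), n1, n2, config$alpha)
    for (st in stage_ok) {
      sel <- tumor_stage == st
      psl[g, paste0("p_stage_", st)] <- mann_whitney_u(tvg[sel], nvg)$p
    }
  }
  tab <- data.frame(gene = cohort$genes, u = u, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    direction = direction, psl,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "alpha") <- config$alpha
  attr(tab, "stage_counts") <- stage_counts
  attr(tab, "n_tumor") <- n1
  attr(tab, "n_normal") <- n2
  class(tab) <- c("differential_table", "data.frame")
  if (classify) tab <- classify_patterns(cohort, tab, config)
  tab
}

#' Leading deregulated genes
#'
#' The k smallest-p genes among those significant (p < alpha) with the
#' requested direction, in ascending p order -- the "leading" up- or
#' downregulated genes of the screen. If fewer than k genes qualify, all
#' qualifying genes are returned with a warning.
#'
#' @param table A `differential_table` from [screen_cohort()].
#' @param direction `"up"` or `"down"`.
#' @param k Number of genes (default: the table's `top_k` would be the
#'   config's; here 5).
#' @return Character vector of gene symbols.
#' @export
leading_genes <- function(table, direction = c("up", "down"), k = 5L) {
  direction <- match.arg(direction)
  if (!nrow(table)) stop("empty differential table")
  alpha <- attr(table, "alpha")
  qual <- table$gene[table$direction == direction & table$p < alpha]
  if (length(qual) < k)
    warning("only ", length(qual), " significant ", direction,
            "-regulated genes (requested ", k, ")")
  utils::head(qual, k)
}

#' Stage-specific deregulated genes
#'
#' A gene is stage-specifically upregulated at stage s when tumors of stage
#' s have significantly higher expression than tumors of all other known
#' stages (Mann-Whitney p < alpha with higher focal-stage median);
#' downregulation mirrors the criterion. Tumors with unrecorded stage are
#' excluded from both sides; stages with fewer than two tumors (or with a
#' complement of fewer than two) are skipped with a warning.
#'
#' @param cohort An annotated [expression_cohort()].
#' @param table A `differential_table` (used for the gene order; the test
#'   here compares tumor stages, not tumor vs normal).
#' @param config A [pipeline_config()].
#' @return A list with elements `up` and `down`, each a named list mapping
#'   stage to the character vector of flagged genes, plus a
#'   `stage_specific_p` attribute (gene x stage matrix of p-values for the
#'   focal-vs-other-stages test).
#' @export
stage_specific_genes <- function(cohort, table, config = pipeline_config()) {
  ann <- need_annotations(cohort)
  tids <- tumor_samples(cohort)
  tumor_stage <- ann$stage[match(tids, ann$sample_id)]
  known <- tumor_stage %in% STAGES
  tv <- cohort$values[, tids, drop = FALSE]
  if (!any(known)) {
    warning("no tumors with known stage; stage-specific lists are empty")
    empty <- stats::setNames(vector("list", 0L), character())
    return(list(up = empty, down = empty))
  }
  genes <- table$gene
  up <- list(); down <- list()
  pmat <- matrix(NA_real_, length(genes), length(STAGES),
                 dimnames = list(genes, STAGES))
  for (st in STAGES) {
    focal <- known & tumor_stage == st
    other <- known & tumor_stage != st
    if (sum(focal) < 2L || sum(other) < 2L) {
      warning("stage ", st, " skipped in stage-specific testing (< 2 tumors ",
              "on one side)")
      next
    }
    ups <- character(); downs <- character()
    for (g in genes) {
      fv <- tv[g, focal]; ov <- tv[g, other]
      mw <- mann_whitney_u(fv, ov)
      pmat[g, st] <- mw$p
      if (mw$p < config$alpha) {
        mf <- stats::median(fv); mo <- stats::median(ov)
        if (mf > mo) ups <- c(ups, g) else if (mf < mo) downs <- c(downs, g)
      }
    }
    up[[st]] <- ups
    down[[st]] <- downs
  }
  out <- list(up = up, down = down)
  attr(out, "stage_specific_p") <- pmat
  out
}

#' Jonckheere-style ordered trend test across tumor stages
#'
#' Sum of pairwise Mann-Whitney U statistics over ordered stage pairs
#' (counting ties as 1/2), compared with its null mean and variance by
#' normal approximation with continuity correction. One-sided.
#'
#' @param values Numeric vector of expression values.
#' @param stages Character vector of stage labels (`I`..`IV`) parallel to
#'   `values`; other labels are dropped.
#' @param alternative `"increasing"` or `"decreasing"`.
#' @return A list with elements `statistic` (the U sum) and `p`.
#' @export
jonckheere_trend <- function(values, stages,
                             alternative = c("increasing", "decreasing")) {
  alternative <- match.arg(alternative)
  keep <- stages %in% STAGES
  values <- values[keep]
  stages <- factor(stages[keep], levels = STAGES)
  counts <- table(stages)
  present <- names(counts)[counts > 0L]
  if (length(present) < 2L) stop("trend test needs >= 2 distinct stages")
  jt <- 0
  for (i in seq_len(length(present) - 1L)) {
    xi <- values[stages == present[i]]
    for (j in (i + 1L):length(present)) {
      xj <- values[stages == present[j]]
      cmp <- outer(xi, xj, "<")
      ties <- outer(xi, xj, "==")
      jt <- jt + sum(cmp) + sum(ties) / 2
    }
  }
  ns <- as.numeric(counts[present])
  N <- sum(ns)
  mean_jt <- (N^2 - sum(ns^2)) / 4
  var_jt <- (N^2 * (2 * N + 3) - sum(ns^2 * (2 * ns + 3))) / 72
  if (var_jt <= 0) return(list(statistic = jt, p = 1))
  cc <- 0.5
  z <- if (alternative == "increasing")
    (jt - mean_jt - cc) / sqrt(var_jt)
  else
    (jt - mean_jt + cc) / sqrt(var_jt)
  p <- if (alternative == "increasing")
    stats::pnorm(z, lower.tail = FALSE)
  else
    stats::pnorm(z, lower.tail = TRUE)
  list(statistic = jt, p = p)
}

#' Progressively deregulated genes
#'
#' A gene is progressively upregulated when (a) its overall tumor-vs-normal
#' p is below alpha with direction up, (b) its stage medians are
#' nondecreasing from I to IV over stages with at least two tumors, and
#' (c) the one-sided [jonckheere_trend()] p across known-stage tumors is
#' below alpha. Progressive downregulation mirrors all three conditions.
#'
#' @inheritParams stage_specific_genes
#' @return A list with character-vector elements `up` and `down`.
#' @export
progressive_genes <- function(cohort, table, config = pipeline_config()) {
  ann <- need_annotations(cohort)
  tids <- tumor_samples(cohort)
  tumor_stage <- ann$stage[match(tids, ann$sample_id)]
  known <- tumor_stage %in% STAGES
  counts <- table(factor(tumor_stage[known], levels = STAGES))
  used_stages <- STAGES[counts >= 2L]
  if (length(used_stages) < 2L) {
    warning("fewer than two stages with >= 2 tumors; no progressive calls")
    return(list(up = character(), down = character()))
  }
  tv <- cohort$values[, tids, drop = FALSE]
  alpha <- config$alpha
  flag <- function(direction) {
    cand <- table$gene[table$direction == direction & table$p < alpha]
    alt <- if (direction == "up") "increasing" else "decreasing"
    cmp <- if (direction == "up") `<=` else `>=`
    out <- character()
    for (g in cand) {
      med <- vapply(used_stages, function(st)
        stats::median(tv[g, known & tumor_stage == st]), 0)
      if (all(cmp(med[-length(med)], med[-1L])) &&
          jonckheere_trend(tv[g, known], tumor_stage[known], alt)$p < alpha)
        out <- c(out, g)
    }
    out
  }
  list(up = flag("up"), down = flag("down"))
}

#' Assign stage-pattern labels to a differential table
#'
#' Each gene receives one label. Assignment precedence (highest last, so it
#' overrides): stage-specific flags, then progressive flags, then the
#' top-`top_k` leading up/down genes; everything else is
#' `"not_significant"` (genes significant overall but matching no pattern
#' keep that fallback label -- their `p`/`direction` columns carry the
#' significance).
#'
#' @inheritParams stage_specific_genes
#' @return The table with a `pattern` column added/replaced.
#' @export
classify_patterns <- function(cohort, table, config = pipeline_config()) {
  pattern <- rep("not_significant", nrow(table))
  names(pattern) <- table$gene
  ss <- stage_specific_genes(cohort, table, config)
  ss_genes <- unique(c(unlist(ss$up, use.names = FALSE),
                       unlist(ss$down, use.names = FALSE)))
  pattern[ss_genes] <- "stage_specific"
  pg <- progressive_genes(cohort, table, config)
  pattern[pg$up] <- "progressive_up"
  pattern[pg$down] <- "progressive_down"
  lu <- suppressWarnings(leading_genes(table, "up", config$top_k))
  ld <- suppressWarnings(leading_genes(table, "down", config$top_k))
  pattern[lu] <- "leading_up"
  pattern[ld] <- "leading_down"
  table$pattern <- unname(pattern)
  table
}

#' Write a differential table to TSV
#' @param table A `differential_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.differential_table <- function(x, n = 10L, ...) {
  cat("differential_table:", nrow(x), "genes screened at alpha =",
      attr(x, "alpha"), "\n")
  cat("  significant:", sum(x$p < attr(x, "alpha")), "| up:",
      sum(x$direction == "up"), "| down:", sum(x$direction == "down"), "\n")
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' @export
summary.differential_table <- function(object, ...) {
  alpha <- attr(object, "alpha")
  out <- list(n_genes = nrow(object),
              alpha = alpha,
              n_significant = sum(object$p < alpha),
              n_up = sum(object$direction == "up"),
              n_down = sum(object$direction == "down"),
              patterns = if ("pattern" %in% names(object))
                table(factor(object$pattern, levels = PATTERNS)) else NULL,
              stage_counts = attr(object, "stage_counts"))
  class(out) <- "summary.differential_table"
  out
}

#' @export
print.summary.differential_table <- function(x, ...) {
  cat("Screened", x$n_genes, "genes at alpha =", x$alpha, "\n")
  cat("Significant:", x$n_significant, "(up", x$n_up, ", down", x$n_down,
      ")\n")
  if (!is.null(x$patterns)) {
    cat("Patterns:\n")
    print(x$patterns)
  }
  invisible(x)
}
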