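# Closeness centrality, the RCC gene-importance statistic and its paired
# Wilcoxon contrast between normal- and tumor-group networks.

#' Component-scaled closeness centrality of a weighted network layer
#'
#' Closeness is the inverse of the average shortest-path distance from a
#' node to the other nodes it can reach, scaled by the Wasserman-Faust
#' component factor: for node v reaching m nodes (itself included) in an
#' n-node network, `closeness(v) = ((m - 1) / sum of distances) *
#' ((m - 1) / (n - 1))`, so small disconnected components are penalized
#' while the within-component value keeps the "inverse average distance"
#' meaning. Isolated nodes score 0. Edge traversal lengths default to
#' 1/weight; for the dissimilarity layer, whose weights are themselves
#' distances, `distance_mode = "direct"` uses the weight as the length.
#'
#' @param layer A `network_layer` (from [build_dual_network()]).
#' @param distance_mode `"inverse"` (default) or `"direct"`; `"direct"` is
#'   honoured only for dissimilarity layers.
#' @return Named numeric vector of closeness scores (>= 0), one per gene.
#' @export
closeness_centrality <- function(layer, distance_mode = c("inverse",
                                                          "direct")) {
  distance_mode <- match.arg(distance_mode)
  w <- layer$weights
  n <- nrow(w)
  if (n == 1L) return(stats::setNames(0, layer$genes))
  len <- w
  if (distance_mode == "inverse" || layer$kind != "dissimilarity") {
    len[w > 0] <- 1 / w[w > 0]
  }
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  score <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    reach <- is.finite(dv)
    m <- sum(reach) + 1L
    if (m <= 1L) return(0)
    tot <- sum(dv[reach])
    if (tot <= 0) return(0)
    ((m - 1) / tot) * ((m - 1) / (n - 1))
  }, 0)
  stats::setNames(score, layer$genes)
}

#' Ratio of closeness centralities (RCC) across the four networks
#'
#' For every gene, closeness is computed in the similarity and
#' dissimilarity layers of the normal-group and tumor-group network pairs;
#' the RCC gene-importance statistic is the similarity/dissimilarity
#' closeness ratio per group: `RCC_N = CN_sim / CN_dis` and
#' `RCC_P = CT_sim / CT_dis`. Genes with a zero denominator in either
#' group are marked undefined (never imputed).
#'
#' @param normal_pair,tumor_pair `dual_network_pair`s over an identical
#'   gene set for the normal and tumor groups.
#' @param distance_mode Passed to [closeness_centrality()].
#' @return An `rcc_table` data.frame with columns `gene`, `cn_sim`,
#'   `cn_dis`, `ct_sim`, `ct_dis`, `rcc_n`, `rcc_p`, `log2_rcc_n`,
#'   `log2_rcc_p`, `defined`.
#' @export
rcc_table <- function(normal_pair, tumor_pair,
                      distance_mode = c("inverse", "direct")) {
  distance_mode <- match.arg(distance_mode)
  genes <- normal_pair$similarity$genes
  if (!identical(genes, tumor_pair$similarity$genes))
    stop("normal and tumor networks must share an identical gene set")
  cn_sim <- closeness_centrality(normal_pair$similarity, distance_mode)
  cn_dis <- closeness_centrality(normal_pair$dissimilarity, distance_mode)
  ct_sim <- closeness_centrality(tumor_pair$similarity, distance_mode)
  ct_dis <- closeness_centrality(tumor_pair$dissimilarity, distance_mode)
  defined <- cn_dis > 0 & ct_dis > 0
  rcc_n <- ifelse(cn_dis > 0, cn_sim / cn_dis, NA_real_)
  rcc_p <- ifelse(ct_dis > 0, ct_sim / ct_dis, NA_real_)
  tab <- data.frame(gene = genes, cn_sim = unname(cn_sim),
                    cn_dis = unname(cn_dis), ct_sim = unname(ct_sim),
                    ct_dis = unname(ct_dis), rcc_n = unname(rcc_n),
                    rcc_p = unname(rcc_p),
                    log2_rcc_n = log2(unname(rcc_n)),
                    log2_rcc_p = log2(unname(rcc_p)),
                    defined = unname(defined), stringsAsFactors = FALSE)
  class(tab) <- c("rcc_table", "data.frame")
  tab
}

#' Paired Wilcoxon signed-rank test of log2(RCC)
#'
#' Tests, across genes, whether log2(RCC) differs between the normal and
#' tumor networks. Pairs with a non-finite entry are dropped (undefined
#' RCC), zero differences are dropped per the standard Wilcoxon
#' convention, the p-value is exact for up to 25 tie-free differences and
#' otherwise uses the normal approximation with tie and continuity
#' corrections; two-sided.
#'
#' @param log2_rcc_normal,log2_rcc_tumor Paired numeric vectors (e.g. the
#'   `log2_rcc_n` / `log2_rcc_p` columns of an [rcc_table()] restricted to
#'   candidate biomarkers).
#' @return An `rcc_test` list: `w` (sum of positive ranks of normal minus
#'   tumor), `p`, `n_pairs` (used), `n_dropped` (zero or undefined).
#' @export
wilcoxon_paired <- function(log2_rcc_normal, log2_rcc_tumor) {
  if (length(log2_rcc_normal) != length(log2_rcc_tumor))
    stop("paired vectors must have equal length")
  d <- log2_rcc_normal - log2_rcc_tumor
  usable <- is.finite(d)
  d <- d[usable]
  nonzero <- d != 0
  n_dropped <- sum(!usable) + sum(!nonzero)
  d <- d[nonzero]
  if (length(d) < 3L)
    stop("untestable: fewer than 3 usable non-zero paired differences")
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  p <- ht$p.value
  if (!is.finite(p)) p <- 1
  structure(list(w = unname(ht$statistic), p = min(p, 1),
                 n_pairs = length(d), n_dropped = n_dropped),
            class = "rcc_test")
}

#' @export
print.rcc_test <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank test on log2(RCC):\n")
  cat("  W =", x$w, "| p =", signif(x$p, 4), "| pairs used:", x$n_pairs,
      "| dropped:", x$n_dropped, "\n")
  invisible(x)
}

#' Joint soft power for a between-group RCC contrast
#'
#' Contrasting log2(RCC) between two groups requires the same soft power
#' in both: with group-wise powers, a difference in the chosen beta shifts
#' log2(RCC) for every gene and the paired contrast measures the power
#' difference instead of network rewiring. This selector evaluates the
#' similarity-transform scale-free fit per group at every power of the
#' grid and picks the smallest power at which both groups reach the
#' threshold, falling back on the argmax of the per-power minimum (with a
#' warning).
#'
#' In addition, only *admissible* powers are considered: a power is
#' admissible when, in both groups, both the similarity and the
#' dissimilarity layer keep at least half of their nodes non-isolated
#' after hard thresholding. Beyond that range the dissimilarity network
#' loses its edges, closeness degenerates to zero and the closeness ratio
#' is undefined for most genes, so such powers cannot support an RCC
#' analysis regardless of their fit index.
#'
#' @param r_normal,r_tumor [pearson_matrix()] results for the two groups.
#' @param config A [pipeline_config()].
#' @return A `soft_power_fit` whose `r2` is the per-power minimum of the
#'   two groups' signed fit indices (NA for inadmissible powers).
#' @export
select_joint_soft_power <- function(r_normal, r_tumor,
                                    config = pipeline_config()) {
  validate_config(config)
  grid <- sort(config$soft_power_grid)
  thr <- config$scale_free_r2_threshold
  if (nrow(r_normal) < 20L) {
    warning("fewer than 20 genes; scale-free fit skipped, using smallest ",
            "soft power ", grid[1L])
    fit <- list(beta_grid = grid, r2 = rep(NA_real_, length(grid)),
                beta = grid[1L], achieved_r2 = NA_real_)
    class(fit) <- "soft_power_fit"
    return(fit)
  }
  # A node is non-isolated in the similarity layer iff its largest
  # off-diagonal correlation survives the threshold, i.e.
  # ((1 + max r) / 2)^beta >= hard_threshold; mirrored for dissimilarity.
  # Both reduce to per-node extreme correlations, so admissibility needs
  # no matrix powering.
  admissible_frac <- function(r, beta) {
    rr <- unclass(r)
    diag(rr) <- NA
    rmax <- apply(rr, 1L, max, na.rm = TRUE)
    rmin <- apply(rr, 1L, min, na.rm = TRUE)
    cut <- if (config$hard_threshold > 0)
      2 * config$hard_threshold^(1 / beta) - 1 else -1
    min(mean((1 + rmax) / 2 >= (cut + 1) / 2),
        mean((1 - rmin) / 2 >= (cut + 1) / 2))
  }
  ok <- vapply(grid, function(b)
    min(admissible_frac(r_normal, b), admissible_frac(r_tumor, b)) >= 0.5,
    NA)
  if (!any(ok)) {
    warning("no soft power keeps both network layers populated; ",
            "falling back on the smallest grid power ", grid[1L])
    ok[1L] <- TRUE
  }
  r2 <- rep(NA_real_, length(grid))
  per_group <- lapply(list(r_normal, r_tumor), function(r)
    vapply(grid[ok], function(b) {
      w <- cor_transform(unclass(r), "similarity", b)
      diag(w) <- 0
      scale_free_r2(rowSums(w))
    }, 0))
  r2[ok] <- pmin(per_group[[1L]], per_group[[2L]])
  pass <- which(ok & r2 >= thr)
  if (length(pass)) {
    pick <- pass[1L]
  } else {
    pick <- which.max(r2)  # NAs (inadmissible) never win
    warning("no admissible soft power reaches signed R^2 >= ", thr,
            " in both groups; using argmax of the minimum, beta = ",
            grid[pick], " (min R^2 = ", signif(r2[pick], 3), ")")
  }
  fit <- list(beta_grid = grid, r2 = r2, beta = grid[pick],
              achieved_r2 = r2[pick])
  class(fit) <- "soft_power_fit"
  fit
}

#' Full RCC pipeline for a cohort
#'
#' Builds the normal- and tumor-group dual network pairs on the cohort's
#' full gene set -- with one joint soft power shared by both groups (see
#' [select_joint_soft_power()]) -- computes the RCC table for all genes,
#' and runs the paired Wilcoxon contrast of log2(RCC) restricted to the
#' candidate biomarker genes.
#'
#' @param cohort An annotated [expression_cohort()].
#' @param biomarker_genes Character vector of genes to test; must all be
#'   cohort genes.
#' @param config A [pipeline_config()] (supplies the soft-power grid, hard
#'   threshold and `distance_mode`).
#' @return A list with `table` (the full [rcc_table()]), `test` (the
#'   [wilcoxon_paired()] result), `biomarker_genes`, and the two
#'   `dual_network_pair`s (`normal_pair`, `tumor_pair`).
#' @export
rcc_pipeline <- function(cohort, biomarker_genes,
                         config = pipeline_config()) {
  validate_config(config)
  missing <- setdiff(biomarker_genes, cohort$genes)
  if (length(missing))
    stop("biomarker gene(s) absent from the cohort: ",
         paste(missing, collapse = ", "))
  if (!length(biomarker_genes)) stop("empty biomarker gene list")
  r_normal <- pearson_matrix(cohort, "normal")
  r_tumor <- pearson_matrix(cohort, "tumor")
  fit <- select_joint_soft_power(r_normal, r_tumor, config)
  normal_pair <- build_dual_network(cohort, "normal", config, beta = fit$beta)
  tumor_pair <- build_dual_network(cohort, "tumor", config, beta = fit$beta)
  normal_pair$scale_free_r2 <- tumor_pair$scale_free_r2 <- fit$achieved_r2
  normal_pair$soft_power_fit <- tumor_pair$soft_power_fit <- fit
  tab <- rcc_table(normal_pair, tumor_pair, config$distance_mode)
  sel <- tab[match(biomarker_genes, tab$gene), , drop = FALSE]
  test <- wilcoxon_paired(sel$log2_rcc_n, sel$log2_rcc_p)
  list(table = tab, test = test, biomarker_genes = biomarker_genes,
       normal_pair = normal_pair, tumor_pair = tumor_pair)
}

#' Write an RCC table to TSV
#' @param table An `rcc_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rcc_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bar plot of log2(RCC) for selected genes in both groups
#'
#' @param x An `rcc_table`.
#' @param genes Genes to display (default: the 20 with the largest
#'   absolute log2(RCC) difference).
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted matrix.
#' @export
plot.rcc_table <- function(x, genes = NULL, ...) {
  ok <- x[x$defined, , drop = FALSE]
  if (is.null(genes)) {
    ord <- order(-abs(ok$log2_rcc_n - ok$log2_rcc_p))
    ok <- ok[utils::head(ord, 20L), , drop = FALSE]
  } else {
    ok <- ok[match(genes, ok$gene), , drop = FALSE]
  }
  m <- t(as.matrix(ok[, c("log2_rcc_n", "log2_rcc_p")]))
  dimnames(m) <- list(c("normal", "tumor"), ok$gene)
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = rownames(m),
                    ylab = "log2(RCC)", ...)
  invisible(m)
}
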