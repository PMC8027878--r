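# Paired similarity / dissimilarity weighted co-expression networks.

#' Pearson correlation matrix for one sample group
#'
#' Pairwise Pearson correlation of gene expression profiles across the
#' samples of a group; the edge-strength source for both network layers.
#' Genes with zero variance in the group get correlation 0 off the
#' diagonal (with a warning) and stay in the matrix as prospective
#' isolated nodes, so the gene set is identical across all four networks.
#'
#' @param cohort An annotated [expression_cohort()].
#' @param group `"tumor"` or `"normal"`; the group needs >= 3 samples.
#' @return A `correlation_matrix`: symmetric genes x genes matrix with unit
#'   diagonal and a `zero_variance` attribute naming flagged genes.
#' @export
pearson_matrix <- function(cohort, group = c("tumor", "normal")) {
  group <- match.arg(group)
  ids <- if (group == "tumor") tumor_samples(cohort) else normal_samples(cohort)
  if (length(ids) < 3L)
    stop("group '", group, "' has fewer than 3 samples")
  x <- t(cohort$values[, ids, drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  zero_var <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  if (length(zero_var)) {
    warning("zero-variance gene(s) in group '", group, "' kept as isolated ",
            "nodes: ", paste(zero_var, collapse = ", "))
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  structure(r, zero_variance = zero_var, class = c("correlation_matrix",
                                                   class(r)))
}

#' Similarity / dissimilarity soft-power transforms
#'
#' Maps a Pearson correlation r into a `[0, 1]` edge weight:
#' similarity `((1 + r) / 2)^beta` (large for strong positive
#' co-expression) or dissimilarity `((1 - r) / 2)^beta` (large for strong
#' negative co-expression; also interpretable as a distance). At beta = 1
#' the two transforms sum to 1; raising beta shrinks weak correlations.
#'
#' @param r Correlation value(s) in `[-1, 1]`; vector or matrix.
#' @param kind `"similarity"` or `"dissimilarity"`.
#' @param beta Soft power, >= 1.
#' @return Weights with the shape of `r`, in `[0, 1]`.
#' @export
cor_transform <- function(r, kind = c("similarity", "dissimilarity"),
                          beta = 1) {
  kind <- match.arg(kind)
  if (length(beta) != 1L || !is.finite(beta) || beta < 1)
    stop("beta must be a single power >= 1")
  if (any(r < -1 | r > 1, na.rm = TRUE)) stop("correlations must be in [-1, 1]")
  base <- if (kind == "similarity") (1 + r) / 2 else (1 - r) / 2
  base^beta
}

#' Signed scale-free topology fit index for a connectivity vector
#'
#' Bins the connectivities into 10 equal-width bins, regresses the log10
#' per-bin frequency (proportion of nodes) on the log10 per-bin mean
#' connectivity over non-empty bins, and returns R-squared signed by the
#' negated slope: +R^2 for the decreasing log-log relationship a
#' scale-free degree distribution implies, -R^2 for an increasing one.
#'
#' @param k Numeric vector of node connectivities (weighted degrees).
#' @param nbins Number of bins (default 10).
#' @return Signed R-squared in `[-1, 1]`; 0 (with a warning) when the
#'   connectivities are degenerate.
#' @export
scale_free_r2 <- function(k, nbins = 10L) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 2L) {
    warning("degenerate connectivities; scale-free fit undefined, using 0")
    return(0)
  }
  breaks <- seq(min(k), max(k), length.out = nbins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  ok <- !is.na(dk) & dk > 0
  if (sum(ok) < 3L) {
    warning("fewer than 3 usable connectivity bins; scale-free fit 0")
    return(0)
  }
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  slope <- stats::coef(fit)[[2L]]
  r2 <- summary(fit)$r.squared
  -sign(slope) * r2
}

#' Signed scale-free fit of a weight matrix
#'
#' Connectivity of node i is the row sum of its off-diagonal weights
#' (pre-thresholding); the signed fit index comes from [scale_free_r2()].
#'
#' @param weights Symmetric nonnegative weight matrix over >= 20 genes.
#' @param nbins Number of connectivity bins.
#' @return Signed R-squared.
#' @export
scale_free_fit <- function(weights, nbins = 10L) {
  if (nrow(weights) < 20L)
    stop("scale-free fit needs at least 20 genes")
  w <- weights
  diag(w) <- 0
  scale_free_r2(rowSums(w), nbins = nbins)
}

#' Select the soft power by scale-free topology fit
#'
#' Evaluates the similarity transform of the correlation matrix at every
#' power in the grid and picks the smallest power whose signed fit index
#' reaches the threshold; if none does, the argmax power is used with a
#' warning. For fewer than 20 genes the fit index is undefined and the
#' smallest grid power is returned with a warning.
#'
#' @param r A [pearson_matrix()] (or plain correlation matrix).
#' @param config A [pipeline_config()] supplying `soft_power_grid` and
#'   `scale_free_r2_threshold`.
#' @return A `soft_power_fit`: list with `beta_grid`, `r2` (per-power
#'   signed fit), `beta` (chosen power) and `achieved_r2`.
#' @export
select_soft_power <- function(r, config = pipeline_config()) {
  validate_config(config)
  grid <- sort(config$soft_power_grid)
  thr <- config$scale_free_r2_threshold
  if (nrow(r) < 20L) {
    warning("fewer than 20 genes; scale-free fit skipped, using smallest ",
            "soft power ", grid[1L])
    fit <- list(beta_grid = grid, r2 = rep(NA_real_, length(grid)),
                beta = grid[1L], achieved_r2 = NA_real_)
    class(fit) <- "soft_power_fit"
    return(fit)
  }
  r2 <- vapply(grid, function(b) {
    w <- cor_transform(r, "similarity", b)
    diag(w) <- 0
    scale_free_r2(rowSums(w))
  }, 0)
  pass <- which(r2 >= thr)
  if (length(pass)) {
    pick <- pass[1L]
  } else {
    pick <- which.max(r2)
    warning("no soft power reaches signed R^2 >= ", thr,
            "; using argmax beta = ", grid[pick],
            " (R^2 = ", signif(r2[pick], 3), ")")
  }
  fit <- list(beta_grid = grid, r2 = r2, beta = grid[pick],
              achieved_r2 = r2[pick])
  class(fit) <- "soft_power_fit"
  fit
}

#' @export
print.soft_power_fit <- function(x, ...) {
  cat("soft_power_fit: beta =", x$beta, "(signed R^2 =",
      signif(x$achieved_r2, 4), ")\n")
  invisible(x)
}

network_layer <- function(kind, group, genes, weights, beta, hard_threshold) {
  structure(list(kind = kind, group = group, genes = genes,
                 weights = weights, beta = beta,
                 hard_threshold = hard_threshold),
            class = "network_layer")
}

#' Build the similarity/dissimilarity network pair for one sample group
#'
#' Computes the group's Pearson matrix, selects one soft power by
#' scale-free fit of the similarity transform, applies the same power to
#' both transforms, removes self-loops (zero diagonal) and prunes weak
#' edges by the hard threshold (weights strictly below it become 0, i.e.
#' no edge).
#'
#' @param cohort An annotated [expression_cohort()].
#' @param group `"tumor"` or `"normal"` (>= 3 samples).
#' @param config A [pipeline_config()].
#' @param beta Optional fixed soft power, bypassing selection.
#' @return A `dual_network_pair`: list with `similarity` and
#'   `dissimilarity` `network_layer`s sharing genes, group and beta, plus
#'   `beta`, `scale_free_r2` and the `soft_power_fit`.
#' @export
build_dual_network <- function(cohort, group = c("tumor", "normal"),
                               config = pipeline_config(), beta = NULL) {
  group <- match.arg(group)
  validate_config(config)
  r <- pearson_matrix(cohort, group)
  if (is.null(beta)) {
    fit <- select_soft_power(r, config)
    beta <- fit$beta
  } else {
    fit <- list(beta_grid = beta, r2 = NA_real_, beta = beta,
                achieved_r2 = NA_real_)
    class(fit) <- "soft_power_fit"
  }
  layers <- lapply(c("similarity", "dissimilarity"), function(kind) {
    w <- cor_transform(unclass(r), kind, beta)
    diag(w) <- 0
    w[w < config$hard_threshold] <- 0
    network_layer(kind, group, rownames(r), w, beta, config$hard_threshold)
  })
  structure(list(similarity = layers[[1L]], dissimilarity = layers[[2L]],
                 group = group, beta = beta,
                 scale_free_r2 = fit$achieved_r2, soft_power_fit = fit),
            class = "dual_network_pair")
}

#' @export
print.dual_network_pair <- function(x, ...) {
  n <- length(x$similarity$genes)
  ne <- function(l) sum(l$weights > 0) / 2
  cat("dual_network_pair (group:", x$group, ")\n")
  cat("  genes:", n, "| beta:", x$beta, "| signed R^2:",
      signif(x$scale_free_r2, 4), "\n")
  cat("  edges: similarity", ne(x$similarity), "| dissimilarity",
      ne(x$dissimilarity), "\n")
  invisible(x)
}

#' Write a network layer as a weighted edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `weight` (retained edges only,
#' upper triangle), plus a JSON sidecar recording group, kind, beta, hard
#' threshold and the achieved scale-free fit.
#'
#' @param layer A `network_layer`.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @param scale_free_r2 Optional achieved fit index for the sidecar.
#' @return `path`, invisibly.
#' @export
write_network_layer <- function(layer, path, scale_free_r2 = NA_real_) {
  w <- layer$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  el <- data.frame(gene_a = layer$genes[idx[, 1L]],
                   gene_b = layer$genes[idx[, 2L]],
                   weight = w[idx], stringsAsFactors = FALSE)
  el <- el[order(el$gene_a, el$gene_b), , drop = FALSE]
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(group = layer$group, kind = layer$kind, beta = layer$beta,
               hard_threshold = layer$hard_threshold,
               scale_free_r2 = scale_free_r2,
               n_genes = length(layer$genes), n_edges = nrow(el))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
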