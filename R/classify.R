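# Repeated cross-validated linear-SVM evaluation of biomarker panels.

#' Define a feature set for panel evaluation
#'
#' @param label Feature-set label, conventionally `"upregulated"`,
#'   `"downregulated"` or `"random"`.
#' @param genes Ordered character vector of gene symbols.
#' @param seed Seed recorded for random draws (NA otherwise).
#' @return A list of class `feature_set`.
#' @export
feature_set <- function(label, genes, seed = NA_integer_) {
  genes <- as.character(genes)
  if (!length(genes)) stop("feature set needs at least one gene")
  if (anyDuplicated(genes)) stop("duplicate genes in feature set")
  structure(list(label = as.character(label), genes = genes,
                 seed = as.integer(seed)),
            class = "feature_set")
}

# Empirical ROC step curve: scores oriented so larger means "tumor".
# Returns the polyline vertices including (0, 0) and (1, 1); tied scores
# collapse to one vertex (diagonal segment), so the trapezoid area equals
# the midrank (Mann-Whitney) AUC estimate.
roc_points <- function(scores, labels) {
  pos <- labels == "tumor"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("ROC needs both classes")
  o <- order(scores, decreasing = TRUE)
  ys <- pos[o]
  tp <- cumsum(ys)
  fp <- cumsum(!ys)
  last_of_tie <- !duplicated(scores[o], fromLast = TRUE)
  list(fpr = c(0, fp[last_of_tie] / n0), tpr = c(0, tp[last_of_tie] / n1))
}

auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1L) + roc$tpr[-1L]) / 2)
}

# Stratified fold labels: each class shuffled then dealt round-robin.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

roc_summary <- function(label, genes, mean_auc, sd_auc, fpr_grid, mean_tpr,
                        n_repeats, n_folds, auc_per_repeat) {
  structure(list(label = label, genes = genes, mean_auc = mean_auc,
                 sd_auc = sd_auc, fpr_grid = fpr_grid, mean_tpr = mean_tpr,
                 n_repeats = n_repeats, n_folds = n_folds,
                 auc_per_repeat = auc_per_repeat),
            class = "roc_summary")
}

#' Evaluate a biomarker panel with a repeated cross-validated linear SVM
#'
#' For each of `cv_repeats` repetitions (repeat r reseeded with
#' `master_seed + r`), samples are split into `cv_folds` stratified folds;
#' per fold, the panel's features are z-scored with training-fold
#' statistics only, a linear-kernel SVM (cost 1, no class weighting) is
#' fitted on the training folds and held-out samples are scored with the
#' signed decision values oriented so larger means tumor. Held-out scores
#' are pooled across the folds of a repetition into one ROC curve and its
#' trapezoid AUC; the summary reports the mean and SD of the per-repeat
#' AUCs and the mean ROC curve by vertical averaging on a fixed 101-point
#' FPR grid.
#'
#' @param cohort An annotated [expression_cohort()] containing both groups,
#'   with at least `cv_folds` samples per group.
#' @param features A [feature_set()] whose genes are all in the cohort.
#' @param config A [pipeline_config()].
#' @return A `roc_summary`: `label`, `genes`, `mean_auc`, `sd_auc`,
#'   `fpr_grid`, `mean_tpr`, `n_repeats`, `n_folds`, `auc_per_repeat`.
#' @export
evaluate_panel <- function(cohort, features, config = pipeline_config()) {
  validate_config(config)
  if (!inherits(features, "feature_set")) stop("'features' must be a feature_set")
  missing <- setdiff(features$genes, cohort$genes)
  if (length(missing))
    stop("feature gene(s) absent from the cohort: ",
         paste(missing, collapse = ", "))
  ann <- need_annotations(cohort)
  y <- factor(ann$group, levels = c("normal", "tumor"))
  if (any(table(y) < config$cv_folds))
    stop("each class needs at least cv_folds = ", config$cv_folds,
         " samples for stratified folds")
  x <- t(cohort$values[features$genes, , drop = FALSE])
  k <- config$cv_folds
  reps <- config$cv_repeats
  grid <- seq(0, 1, length.out = 101L)
  aucs <- numeric(reps)
  tprs <- matrix(NA_real_, reps, length(grid))
  for (r in seq_len(reps)) {
    set.seed(config$master_seed + r)
    folds <- stratified_folds(y, k)
    scores <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      mu <- colMeans(x[tr, , drop = FALSE])
      sdv <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
      xte <- sweep(sweep(x[!tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
      fit <- e1071::svm(xtr, y[tr], kernel = "linear", cost = 1,
                        scale = FALSE)
      pr <- stats::predict(fit, xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      s <- as.numeric(dv)
      if (sub("/.*$", "", colnames(dv)[1L]) != "tumor") s <- -s
      scores[!tr] <- s
    }
    roc <- roc_points(scores, as.character(y))
    aucs[r] <- auc_trapezoid(roc)
    tprs[r, ] <- stats::approx(roc$fpr, roc$tpr, xout = grid,
                               ties = max, rule = 2)$y
  }
  roc_summary(features$label, features$genes, mean(aucs),
              stats::sd(aucs), grid, colMeans(tprs), reps, k, aucs)
}

#' Random-gene baseline panel
#'
#' Draws `random_gene_count` cohort genes uniformly without replacement
#' (seeded from the master seed by a fixed offset) and evaluates them with
#' [evaluate_panel()]; the comparison group against which candidate panels
#' must win.
#'
#' @param cohort An annotated [expression_cohort()].
#' @param config A [pipeline_config()].
#' @return A `roc_summary` labelled `"random"`.
#' @export
random_baseline <- function(cohort, config = pipeline_config()) {
  validate_config(config)
  if (length(cohort$genes) < config$random_gene_count)
    stop("cohort has fewer genes than random_gene_count")
  seed <- config$master_seed + 9973L
  set.seed(seed)
  genes <- sample(cohort$genes, config$random_gene_count)
  evaluate_panel(cohort, feature_set("random", genes, seed = seed), config)
}

#' Compare evaluated panels against the random baseline
#'
#' @param summaries List of `roc_summary` objects (>= 2), typically the
#'   up- and downregulated panels plus the random baseline.
#' @return A `panel_comparison` data.frame ranked by decreasing mean AUC
#'   with columns `label`, `n_genes`, `mean_auc`, `sd_auc` and
#'   `beats_random` (strictly higher mean AUC than the random baseline;
#'   NA when no baseline is present or for the baseline itself).
#' @export
compare_panels <- function(summaries) {
  if (length(summaries) < 2L) stop("need at least two panel summaries")
  for (s in summaries)
    if (!inherits(s, "roc_summary")) stop("summaries must be roc_summary objects")
  df <- data.frame(label = vapply(summaries, `[[`, "", "label"),
                   n_genes = vapply(summaries, function(s) length(s$genes), 0L),
                   mean_auc = vapply(summaries, `[[`, 0, "mean_auc"),
                   sd_auc = vapply(summaries, `[[`, 0, "sd_auc"),
                   stringsAsFactors = FALSE)
  base <- df$mean_auc[df$label == "random"]
  df$beats_random <- if (length(base))
    ifelse(df$label == "random", NA, df$mean_auc > max(base))
  else NA
  df <- df[order(-df$mean_auc), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("panel_comparison", "data.frame")
  df
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("roc_summary [%s]: mean AUC %.4f (SD %.4f), %d x %d-fold CV, %d genes\n",
              x$label, x$mean_auc, x$sd_auc, x$n_repeats, x$n_folds,
              length(x$genes)))
  invisible(x)
}

#' Plot mean ROC curves of one or more panel evaluations
#'
#' Overlays the vertically averaged ROC curves with the chance diagonal.
#'
#' @param x A `roc_summary`.
#' @param ... Further `roc_summary` objects to overlay.
#' @param main Plot title.
#' @return Invisibly, NULL.
#' @export
plot.roc_summary <- function(x, ..., main = "Mean ROC") {
  extra <- Filter(function(s) inherits(s, "roc_summary"), list(...))
  all <- c(list(x), extra)
  cols <- seq_along(all) + 1L
  graphics::plot(c(0, 1), c(0, 1), type = "n", xlab = "False positive rate",
                 ylab = "True positive rate", main = main)
  graphics::abline(0, 1, lty = 2, col = "blue")
  for (i in seq_along(all))
    graphics::lines(all[[i]]$fpr_grid, all[[i]]$mean_tpr, col = cols[i],
                    lwd = 2)
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)",
                                    vapply(all, `[[`, "", "label"),
                                    vapply(all, `[[`, 0, "mean_auc")),
                   col = cols, lwd = 2, bty = "n")
  invisible(NULL)
}
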