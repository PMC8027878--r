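# Synthetic cohort generator: planted effect classes and correlated modules.

EFFECT_CLASSES <- c("global_up", "global_down", "stage_specific",
                    "progressive_up", "progressive_down", "null")

#' Specify a planted per-gene effect
#'
#' Effect sizes are expressed on the log2 scale in units of the gene's own
#' standard deviation, which makes the power of rank-based screening
#' predictable independently of the gene's baseline abundance.
#'
#' @param gene Gene symbol.
#' @param klass One of `"global_up"`, `"global_down"`, `"stage_specific"`,
#'   `"progressive_up"`, `"progressive_down"`, `"null"`.
#' @param effect_size Shift in within-gene SD units (>= 0; must be 0 for
#'   class `"null"` and positive otherwise).
#' @param target_stage Focal stage, required (and only allowed) for
#'   `"stage_specific"` effects.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(gene, klass, effect_size = 0,
                        target_stage = NA_character_) {
  klass <- match.arg(klass, EFFECT_CLASSES)
  effect_size <- as.numeric(effect_size)
  if (effect_size < 0) stop("effect_size must be >= 0")
  if ((klass == "null") != (effect_size == 0))
    stop("effect_size must be 0 iff klass is 'null'")
  if (klass == "stage_specific") {
    if (is.na(target_stage) || !target_stage %in% STAGES)
      stop("stage_specific effects need target_stage in I..IV")
  } else if (!is.na(target_stage)) {
    stop("target_stage is only meaningful for stage_specific effects")
  }
  structure(list(gene = as.character(gene), klass = klass,
                 effect_size = effect_size,
                 target_stage = as.character(target_stage)),
            class = "effect_spec")
}

#' Specify a synthetic cohort design
#'
#' The generative model draws, for gene \eqn{g} and sample \eqn{s}, a log2
#' signal \eqn{\mu_g + \lambda f_{m(g),s} + \sqrt{1-\lambda^2}\,
#' \epsilon_{gs}} with \eqn{\epsilon_{gs} \sim N(0, \sigma_g)} and a module
#' factor \eqn{f_{m,s} \sim N(0, \sigma_g)} shared by all genes of module
#' \eqn{m} within sample \eqn{s}, so that within-module pairwise Pearson
#' correlation is \eqn{\lambda^2}. Tumor samples add
#' `effect_size`\eqn{\cdot\sigma_g} according to the effect class (all
#' tumors for global effects; only the focal stage for stage-specific
#' effects; `effect_size`\eqn{\cdot\sigma_g\cdot} stage/4 for progressive
#' effects, stage I = 1 .. IV = 4). Tumors with unrecorded stage receive a
#' latent stage for effect generation which is then masked in the
#' annotations. Emitted values are \eqn{2^{\mathrm{log2\ signal}}}, clipped
#' at zero (fractional, emulating RSEM normalized estimates).
#'
#' @param n_genes Total gene count.
#' @param n_tumor,n_normal Group sizes (both >= 2).
#' @param stage_proportions Named numeric over `I`,`II`,`III`,`IV`,`unknown`
#'   summing to 1 (rescaled if within 0.01 of 1, tolerating rounded
#'   percentages).
#' @param effect_specs List of [effect_spec()]s; genes not listed are null.
#' @param module_assignments Named integer vector mapping gene symbol to
#'   correlation-module id; unlisted genes are module-free.
#' @param module_loading Factor loading \eqn{\lambda \in [0,1)}.
#' @param baseline_log_mean_range,baseline_log_sd_range Ranges for the
#'   per-gene baseline log2 mean \eqn{\mu_g} and SD \eqn{\sigma_g}.
#' @param rewire_tumor If TRUE, tumor samples use a freshly drawn module
#'   assignment (same module sizes, re-drawn member genes), planting a
#'   co-expression rewiring signal detectable by the RCC contrast.
#' @param seed Seed making generation fully deterministic.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_genes, n_tumor, n_normal,
                       stage_proportions,
                       effect_specs = list(),
                       module_assignments = NULL,
                       module_loading = 0,
                       baseline_log_mean_range = c(3, 9),
                       baseline_log_sd_range = c(0.5, 2),
                       rewire_tumor = FALSE,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_tumor <- as.integer(n_tumor)
  n_normal <- as.integer(n_normal)
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (n_tumor < 2L || n_normal < 2L) stop("n_tumor and n_normal must be >= 2")
  if (is.null(names(stage_proportions)) ||
      !setequal(names(stage_proportions), ALL_STAGES))
    stop("stage_proportions must be named over I, II, III, IV, unknown")
  stage_proportions <- unlist(stage_proportions)[ALL_STAGES]
  if (any(stage_proportions < 0)) stop("stage proportions must be >= 0")
  if (abs(sum(stage_proportions) - 1) > 0.01)
    stop("stage proportions must sum to 1")
  stage_proportions <- stage_proportions / sum(stage_proportions)
  if (sum(stage_proportions[STAGES]) <= 0)
    stop("at least one known stage needs positive probability")
  if (!(module_loading >= 0 && module_loading^2 < 1))
    stop("module_loading^2 must be < 1")
  for (es in effect_specs)
    if (!inherits(es, "effect_spec")) stop("effect_specs must be effect_spec objects")
  eg <- vapply(effect_specs, `[[`, "", "gene")
  if (anyDuplicated(eg))
    stop("duplicate effect spec for gene(s): ",
         paste(unique(eg[duplicated(eg)]), collapse = ", "))
  if (!is.null(module_assignments)) {
    if (is.null(names(module_assignments)))
      stop("module_assignments must be named by gene symbol")
    module_assignments <- vapply(module_assignments, as.integer, 0L)
  }
  structure(list(n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
                 stage_proportions = stage_proportions,
                 effect_specs = effect_specs,
                 module_assignments = module_assignments,
                 module_loading = as.numeric(module_loading),
                 baseline_log_mean_range = as.numeric(baseline_log_mean_range),
                 baseline_log_sd_range = as.numeric(baseline_log_sd_range),
                 rewire_tumor = isTRUE(rewire_tumor),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Preset cohort designs emulating gastro-esophageal TCGA cohorts
#'
#' `stomach_like` mirrors a stomach adenocarcinoma cohort layout (415
#' tumors, 35 normals; stage mix 13.7/29.6/40.7/9.9% plus 6% unrecorded);
#' `esophagus_like` mirrors an esophageal carcinoma layout (185 tumors, 11
#' normals; stage mix 9.7/42.2/30.3/4.9% plus 13% unrecorded). Both plant
#' five genes per effect class (`global_up`, `global_down`,
#' `stage_specific` with focal stages cycling I--IV, `progressive_up`,
#' `progressive_down`) and four correlation modules of 20 genes at loading
#' 0.6, among 500 genes total.
#'
#' @param preset `"stomach_like"` or `"esophagus_like"`.
#' @param seed Simulation seed.
#' @param n_genes Total gene count (default 500).
#' @param effect_size Planted shift in SD units (default 1.5).
#' @param rewire_tumor Passed to [sim_design()].
#' @return A `sim_design`.
#' @export
default_design <- function(preset = c("stomach_like", "esophagus_like"),
                           seed = 1L, n_genes = 500L, effect_size = 1.5,
                           rewire_tumor = FALSE) {
  preset <- match.arg(preset)
  if (preset == "stomach_like") {
    n_tumor <- 415L; n_normal <- 35L
    props <- c(I = 0.137, II = 0.296, III = 0.407, IV = 0.099,
               unknown = 0.060)
  } else {
    n_tumor <- 185L; n_normal <- 11L
    props <- c(I = 0.097, II = 0.422, III = 0.303, IV = 0.049,
               unknown = 0.130)
  }
  n_genes <- as.integer(n_genes)
  genes <- sprintf("g%04d", seq_len(n_genes))
  planted_classes <- c("global_up", "global_down", "stage_specific",
                       "progressive_up", "progressive_down")
  n_planted <- 5L * length(planted_classes)
  n_module_genes <- 80L
  if (n_genes < n_planted + n_module_genes)
    stop("preset designs need at least ", n_planted + n_module_genes, " genes")
  specs <- list()
  idx <- 0L
  for (cl in planted_classes) {
    for (i in 1:5) {
      idx <- idx + 1L
      ts <- if (cl == "stage_specific") STAGES[((i - 1L) %% 4L) + 1L]
            else NA_character_
      specs[[idx]] <- effect_spec(genes[idx], cl, effect_size, ts)
    }
  }
  mod_genes <- genes[n_planted + seq_len(n_module_genes)]
  modules <- stats::setNames(rep(1:4, each = 20L), mod_genes)
  sim_design(n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
             stage_proportions = props, effect_specs = specs,
             module_assignments = modules, module_loading = 0.6,
             rewire_tumor = rewire_tumor, seed = seed)
}

#' Simulate an expression cohort with known ground truth
#'
#' Deterministic given the design's seed: the same design yields a
#' bit-identical cohort. See [sim_design()] for the generative model.
#'
#' @param design A [sim_design()] (or [default_design()]) object.
#' @return A list with elements `cohort` (an annotated
#'   [expression_cohort()]) and `truth` (a data.frame of class `sim_truth`
#'   with one row per gene: `gene`, `klass`, `effect_size`, `target_stage`,
#'   `module`, plus realized stage counts as an attribute).
#' @export
simulate_cohort <- function(design) {
  if (!inherits(design, "sim_design")) stop("'design' must be a sim_design")
  set.seed(design$seed)
  n_genes <- design$n_genes
  genes <- sprintf("g%04d", seq_len(n_genes))
  listed <- vapply(design$effect_specs, `[[`, "", "gene")
  bad <- setdiff(listed, genes)
  if (length(bad))
    stop("effect spec for gene(s) outside the cohort: ",
         paste(bad, collapse = ", "))
  if (!is.null(design$module_assignments)) {
    bad <- setdiff(names(design$module_assignments), genes)
    if (length(bad))
      stop("module assignment for gene(s) outside the cohort: ",
           paste(bad, collapse = ", "))
  }

  n_tumor <- design$n_tumor
  n_normal <- design$n_normal
  n <- n_tumor + n_normal
  samples <- c(sprintf("T%03d", seq_len(n_tumor)),
               sprintf("N%03d", seq_len(n_normal)))
  group <- rep(c("tumor", "normal"), c(n_tumor, n_normal))

  # Observed stage labels for tumors; tumors labeled "unknown" get a latent
  # known stage (drawn from the known-stage mix) used for effect generation
  # and then masked in the annotations.
  props <- design$stage_proportions
  observed <- sample(ALL_STAGES, n_tumor, replace = TRUE, prob = props)
  latent <- observed
  masked <- latent == "unknown"
  if (any(masked)) {
    pk <- props[STAGES] / sum(props[STAGES])
    latent[masked] <- sample(STAGES, sum(masked), replace = TRUE, prob = pk)
  }
  stage_idx <- match(latent, STAGES)  # 1..4 per tumor

  mu <- stats::runif(n_genes, design$baseline_log_mean_range[1L],
                     design$baseline_log_mean_range[2L])
  sigma <- stats::runif(n_genes, design$baseline_log_sd_range[1L],
                        design$baseline_log_sd_range[2L])

  lambda <- design$module_loading
  assign_normal <- integer(n_genes)
  names(assign_normal) <- genes
  if (!is.null(design$module_assignments))
    assign_normal[names(design$module_assignments)] <- design$module_assignments
  assign_tumor <- assign_normal
  if (design$rewire_tumor && any(assign_normal > 0L)) {
    # same module sizes, freshly drawn member genes
    sizes <- table(assign_normal[assign_normal > 0L])
    assign_tumor <- integer(n_genes)
    names(assign_tumor) <- genes
    pool <- sample(genes)
    off <- 0L
    for (m in names(sizes)) {
      assign_tumor[pool[off + seq_len(sizes[[m]])]] <- as.integer(m)
      off <- off + sizes[[m]]
    }
  }
  module_ids <- sort(unique(c(assign_normal[assign_normal > 0L],
                              assign_tumor[assign_tumor > 0L])))

  # Standard-normal building blocks; scaled per gene below. Module members
  # get lambda * f + sqrt(1 - lambda^2) * noise so their marginal SD stays
  # sigma_g; module-free genes keep full-SD noise.
  z_noise <- matrix(stats::rnorm(n_genes * n), n_genes, n)
  z_module <- if (length(module_ids))
    matrix(stats::rnorm(length(module_ids) * n), length(module_ids), n,
           dimnames = list(module_ids, NULL))
  else NULL

  tcols <- seq_len(n_tumor)
  ncols <- n_tumor + seq_len(n_normal)
  noise_mult <- matrix(1, n_genes, n)
  noise_mult[assign_normal > 0L, ncols] <- sqrt(1 - lambda^2)
  noise_mult[assign_tumor > 0L, tcols] <- sqrt(1 - lambda^2)
  log2x <- mu + sigma * noise_mult * z_noise
  if (!is.null(z_module) && lambda > 0) {
    for (g in which(assign_normal > 0L)) {
      m <- as.character(assign_normal[g])
      log2x[g, ncols] <- log2x[g, ncols] + sigma[g] * lambda * z_module[m, ncols]
    }
    for (g in which(assign_tumor > 0L)) {
      m <- as.character(assign_tumor[g])
      log2x[g, tcols] <- log2x[g, tcols] + sigma[g] * lambda * z_module[m, tcols]
    }
  }

  # Planted effects, additive on log2 scale in units of sigma_g.
  for (es in design$effect_specs) {
    g <- match(es$gene, genes)
    shift <- switch(es$klass,
      null = numeric(n_tumor),
      global_up = rep(es$effect_size, n_tumor),
      global_down = rep(-es$effect_size, n_tumor),
      stage_specific = ifelse(latent == es$target_stage, es$effect_size, 0),
      progressive_up = es$effect_size * stage_idx / 4,
      progressive_down = -es$effect_size * stage_idx / 4)
    log2x[g, seq_len(n_tumor)] <- log2x[g, seq_len(n_tumor)] + sigma[g] * shift
  }

  values <- pmax(2^log2x, 0)
  dimnames(values) <- list(genes, samples)
  ann <- data.frame(sample_id = samples, group = group,
                    stage = c(observed, rep("unknown", n_normal)),
                    stringsAsFactors = FALSE)
  cohort <- expression_cohort(values, ann)

  klass <- rep("null", n_genes)
  esize <- numeric(n_genes)
  tstage <- rep(NA_character_, n_genes)
  for (es in design$effect_specs) {
    g <- match(es$gene, genes)
    klass[g] <- es$klass
    esize[g] <- es$effect_size
    tstage[g] <- es$target_stage
  }
  truth <- data.frame(gene = genes, klass = klass, effect_size = esize,
                      target_stage = tstage,
                      module = ifelse(assign_normal > 0L, assign_normal, NA),
                      stringsAsFactors = FALSE)
  if (design$rewire_tumor)
    truth$module_tumor <- ifelse(assign_tumor > 0L, assign_tumor, NA)
  attr(truth, "stage_counts") <-
    table(factor(c(observed, rep("unknown", n_normal))[group == "tumor"],
                 levels = ALL_STAGES))
  class(truth) <- c("sim_truth", "data.frame")
  list(cohort = cohort, truth = truth)
}

#' Write a simulated cohort (expression, annotations, truth) to a directory
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(sim$cohort, paths[["expression"]])
  write_annotations(sim$cohort, paths[["annotations"]])
  utils::write.table(as.data.frame(sim$truth), paths[["truth"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
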