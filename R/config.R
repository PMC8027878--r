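# Pipeline configuration.

#' Pipeline configuration
#'
#' Collects the tunable parameters shared by the screening, network,
#' centrality and classification stages.
#'
#' @param alpha Two-sided significance level for the rank-based screens
#'   (default 0.05; raw p-values, no multiplicity correction drives the
#'   labels, though a BH q-value column is reported).
#' @param top_k Number of "leading" genes per direction (default 5).
#' @param soft_power_grid Candidate soft powers for the co-expression
#'   transforms (default 1:20).
#' @param scale_free_r2_threshold Minimum signed scale-free fit index for
#'   accepting a soft power (default 0.85, the conventional WGCNA choice).
#' @param hard_threshold Edge weights strictly below this cutoff are removed
#'   from the networks (default 0.01).
#' @param cv_folds Stratified cross-validation folds (default 5).
#' @param cv_repeats Cross-validation repetitions (default 50).
#' @param random_gene_count Size of the random-gene baseline feature set
#'   (default 5).
#' @param master_seed Master random seed; stage-level seeds are derived
#'   from it by fixed offsets (default 1).
#' @param distance_mode How dissimilarity-network edge weights map to
#'   shortest-path lengths: `"inverse"` (length = 1/weight, same contract
#'   as the similarity layer; default) or `"direct"` (the dissimilarity
#'   weight, already a distance, is used as the length).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05,
                            top_k = 5L,
                            soft_power_grid = 1:20,
                            scale_free_r2_threshold = 0.85,
                            hard_threshold = 0.01,
                            cv_folds = 5L,
                            cv_repeats = 50L,
                            random_gene_count = 5L,
                            master_seed = 1L,
                            distance_mode = c("inverse", "direct")) {
  cfg <- structure(list(alpha = as.numeric(alpha),
                        top_k = as.integer(top_k),
                        soft_power_grid = as.numeric(soft_power_grid),
                        scale_free_r2_threshold = as.numeric(scale_free_r2_threshold),
                        hard_threshold = as.numeric(hard_threshold),
                        cv_folds = as.integer(cv_folds),
                        cv_repeats = as.integer(cv_repeats),
                        random_gene_count = as.integer(random_gene_count),
                        master_seed = as.integer(master_seed),
                        distance_mode = match.arg(distance_mode)),
                   class = "pipeline_config")
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Re-checks every invariant of [pipeline_config()]; useful after
#' modifying a configuration's fields directly.
#'
#' @param cfg A `pipeline_config`.
#' @return The configuration, invisibly errors otherwise.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must be in (0, 1)")
  if (cfg$top_k < 1L) stop("top_k must be >= 1")
  if (!length(cfg$soft_power_grid) || any(cfg$soft_power_grid < 1))
    stop("soft_power_grid must be a non-empty set of powers >= 1")
  if (!(cfg$hard_threshold >= 0 && cfg$hard_threshold < 1))
    stop("hard_threshold must be in [0, 1)")
  if (cfg$cv_folds < 2L) stop("cv_folds must be >= 2")
  if (cfg$cv_repeats < 1L) stop("cv_repeats must be >= 1")
  if (cfg$random_gene_count < 1L) stop("random_gene_count must be >= 1")
  if (is.na(cfg$master_seed)) stop("master_seed must be an integer")
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults, unknown keys are an error.
#'
#' @param path Path to the YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to a YAML file
#' @param config A `pipeline_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (length(val) > 6L)
      val <- paste0(val[1L], "..", val[length(val)])
    cat(sprintf("  %-24s %s\n", nm, paste(val, collapse = " ")))
  }
  invisible(x)
}
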