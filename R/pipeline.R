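# End-to-end orchestration: simulate/load -> screen -> network -> rcc ->
# classify -> report, with a machine-readable run manifest.

#' Run the full biomarker-mining pipeline
#'
#' Executes every stage in order on either a simulated preset cohort or
#' user-supplied files, writing per-stage TSV/JSON outputs and a run
#' manifest into `out_dir`. The leading up/down genes from the screen feed
#' both the RCC contrast (as the candidate biomarker set) and the SVM
#' panel evaluation (as the up/down feature sets, compared against the
#' random-gene baseline). Reruns with the same inputs and configuration
#' produce byte-identical tables.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()]; its `master_seed` drives every
#'   stochastic stage by fixed offsets.
#' @param preset Simulation preset passed to [default_design()], or NULL
#'   when `expr`/`anno` files are given.
#' @param expr,anno,panel Paths to an expression TSV, annotation TSV and
#'   optional plasma-panel gene list (used instead of simulation when
#'   `preset` is NULL).
#' @param ... Further arguments (e.g. `n_genes`, `effect_size`) passed to
#'   [default_design()] when simulating.
#' @return A `run_manifest` list (also written to `manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         preset = "stomach_like", expr = NULL, anno = NULL,
                         panel = NULL, ...) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "plasmaseek",
                   version = as.character(utils::packageVersion("plasmaseek")),
                   config = unclass(config), preset = preset,
                   seeds = list(master = config$master_seed),
                   stages = list(), warnings = character())
  note <- function(w) manifest$warnings <<- c(manifest$warnings, w)
  run_stage <- function(name, fun) {
    message("[plasmaseek] stage: ", name)
    files <- withCallingHandlers(fun(), warning = function(w) {
      note(paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    # outputs under out_dir are recorded relative to it so the manifest is
    # reproducible across working directories
    in_out <- startsWith(files, paste0(out_dir, "/")) |
      startsWith(files, out_dir)
    files[in_out] <- basename(files[in_out])
    manifest$stages[[name]] <<- list(files = as.list(files))
    files
  }

  cohort <- NULL
  unmapped <- character()
  run_stage("input", function() {
    if (!is.null(preset)) {
      design <- default_design(preset, seed = config$master_seed, ...)
      sim <- simulate_cohort(design)
      cohort <<- sim$cohort
      write_cohort(sim, out_dir)
    } else {
      if (is.null(expr) || is.null(anno))
        stop("either a simulation preset or expr + anno files are required")
      co <- read_expression(expr)
      co <- read_annotations(anno, co)
      if (!is.null(panel)) {
        res <- restrict_to_panel(co, read_gene_panel(panel))
        co <- res$cohort
        unmapped <<- res$unmapped
      }
      cohort <<- co
      c(expression = expr, annotations = anno)
    }
  })
  manifest$n_genes <- length(cohort$genes)
  manifest$n_samples <- length(cohort$samples)
  manifest$unmapped_panel_symbols <- unmapped

  tab <- NULL
  lead_up <- lead_down <- character()
  run_stage("screen", function() {
    tab <<- screen_cohort(cohort, config)
    lead_up <<- suppressWarnings(leading_genes(tab, "up", config$top_k))
    lead_down <<- suppressWarnings(leading_genes(tab, "down", config$top_k))
    ss <- stage_specific_genes(cohort, tab, config)
    pg <- progressive_genes(cohort, tab, config)
    f1 <- file.path(out_dir, "screen.tsv")
    write_differential_table(tab, f1)
    f2 <- file.path(out_dir, "screen_summary.json")
    jsonlite::write_json(list(alpha = config$alpha,
                              n_significant = sum(tab$p < config$alpha),
                              leading_up = lead_up,
                              leading_down = lead_down,
                              stage_specific = ss[c("up", "down")],
                              progressive = pg),
                         f2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    c(table = f1, summary = f2)
  })

  normal_pair <- tumor_pair <- NULL
  run_stage("network", function() {
    # one joint soft power so the downstream RCC contrast compares like
    # with like (see select_joint_soft_power)
    fit <- select_joint_soft_power(pearson_matrix(cohort, "normal"),
                                   pearson_matrix(cohort, "tumor"), config)
    normal_pair <<- build_dual_network(cohort, "normal", config,
                                       beta = fit$beta)
    tumor_pair <<- build_dual_network(cohort, "tumor", config,
                                      beta = fit$beta)
    normal_pair$scale_free_r2 <<- tumor_pair$scale_free_r2 <<-
      fit$achieved_r2
    files <- character()
    for (pair in list(normal_pair, tumor_pair))
      for (kind in c("similarity", "dissimilarity")) {
        f <- file.path(out_dir,
                       sprintf("network_%s_%s.tsv", pair$group, kind))
        write_network_layer(pair[[kind]], f, pair$scale_free_r2)
        files <- c(files, f)
      }
    files
  })

  biomarkers <- unique(c(lead_up, lead_down))
  rcc_res <- NULL
  run_stage("rcc", function() {
    tab_rcc <- rcc_table(normal_pair, tumor_pair, config$distance_mode)
    f1 <- file.path(out_dir, "rcc.tsv")
    write_rcc_table(tab_rcc, f1)
    f2 <- file.path(out_dir, "rcc_test.json")
    test <- if (length(biomarkers) >= 3L) {
      sel <- tab_rcc[match(biomarkers, tab_rcc$gene), , drop = FALSE]
      tryCatch(wilcoxon_paired(sel$log2_rcc_n, sel$log2_rcc_p),
               error = function(e) NULL)
    } else NULL
    rcc_res <<- list(table = tab_rcc, test = test)
    payload <- if (is.null(test))
      list(tested = FALSE, biomarkers = biomarkers,
           note = "fewer than 3 usable biomarker pairs")
    else
      list(tested = TRUE, biomarkers = biomarkers, w = test$w, p = test$p,
           n_pairs = test$n_pairs, n_dropped = test$n_dropped)
    jsonlite::write_json(payload, f2, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    c(table = f1, test = f2)
  })

  panels <- NULL
  run_stage("classify", function() {
    summaries <- list()
    if (length(lead_up))
      summaries <- c(summaries, list(
        evaluate_panel(cohort, feature_set("upregulated", lead_up), config)))
    if (length(lead_down))
      summaries <- c(summaries, list(
        evaluate_panel(cohort, feature_set("downregulated", lead_down),
                       config)))
    summaries <- c(summaries, list(random_baseline(cohort, config)))
    panels <<- summaries
    f1 <- file.path(out_dir, "panels.json")
    jsonlite::write_json(lapply(summaries, function(s)
      list(label = s$label, genes = s$genes, mean_auc = s$mean_auc,
           sd_auc = s$sd_auc, n_repeats = s$n_repeats,
           n_folds = s$n_folds)),
      f1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    f2 <- file.path(out_dir, "roc_curves.tsv")
    grid <- summaries[[1L]]$fpr_grid
    roc_df <- data.frame(fpr = grid)
    for (s in summaries) roc_df[[paste0("tpr_", s$label)]] <- s$mean_tpr
    utils::write.table(roc_df, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(panels = f1, roc = f2)
  })

  run_stage("report", function() {
    f <- file.path(out_dir, "report.txt")
    writeLines(pipeline_report_text(manifest, out_dir), f)
    f
  })

  all_files <- unlist(lapply(manifest$stages, function(s) unlist(s$files)),
                      use.names = FALSE)
  missing <- all_files[!(file.exists(all_files) |
                         file.exists(file.path(out_dir, all_files)))]
  if (length(missing))
    stop("manifest lists missing output file(s): ",
         paste(missing, collapse = ", "))
  manifest$files <- all_files
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  attr(manifest, "out_dir") <- out_dir
  invisible(manifest)
}

# Compose the plain-text report from a manifest and its output directory.
pipeline_report_text <- function(manifest, out_dir) {
  section <- function(title) c(title, strrep("-", nchar(title)))
  lines <- c("plasmaseek run report", "=====================", "")
  lines <- c(lines, sprintf("genes: %s  samples: %s  master seed: %s",
                            manifest$n_genes, manifest$n_samples,
                            manifest$config$master_seed), "")
  stages <- names(manifest$stages)

  lines <- c(lines, section("Screening"))
  f <- file.path(out_dir, "screen_summary.json")
  if ("screen" %in% stages && file.exists(f)) {
    s <- jsonlite::read_json(f, simplifyVector = TRUE)
    lines <- c(lines,
               sprintf("significant genes (p < %s): %s", s$alpha,
                       s$n_significant),
               paste("leading up:  ", paste(s$leading_up, collapse = ", ")),
               paste("leading down:", paste(s$leading_down, collapse = ", ")))
    lines <- c(lines, "", section("Stage-specific genes"))
    for (dir in c("up", "down")) {
      m <- s$stage_specific[[dir]]
      for (st in names(m))
        if (length(m[[st]]))
          lines <- c(lines, sprintf("stage %s (%s): %s", st, dir,
                                    paste(unlist(m[[st]]), collapse = ", ")))
    }
    lines <- c(lines, "", section("Progressive genes"),
               paste("up:  ", paste(unlist(s$progressive$up), collapse = ", ")),
               paste("down:", paste(unlist(s$progressive$down), collapse = ", ")))
  } else lines <- c(lines, "not run")
  lines <- c(lines, "")

  lines <- c(lines, section("RCC network contrast"))
  f <- file.path(out_dir, "rcc_test.json")
  if ("rcc" %in% stages && file.exists(f)) {
    s <- jsonlite::read_json(f, simplifyVector = TRUE)
    if (isTRUE(s$tested))
      lines <- c(lines,
                 sprintf("paired Wilcoxon on log2(RCC) of %d biomarkers: W = %s, p = %s (pairs %s, dropped %s)",
                         length(s$biomarkers), s$w, signif(s$p, 4),
                         s$n_pairs, s$n_dropped))
    else lines <- c(lines, "not testable: fewer than 3 usable biomarker pairs")
  } else lines <- c(lines, "not run")
  lines <- c(lines, "")

  lines <- c(lines, section("Panel classification (linear SVM)"))
  f <- file.path(out_dir, "panels.json")
  if ("classify" %in% stages && file.exists(f)) {
    s <- jsonlite::read_json(f, simplifyVector = TRUE)
    for (i in seq_len(nrow(s)))
      lines <- c(lines,
                 sprintf("%-13s mean AUC %.4f (SD %.4f) over %d x %d-fold CV",
                         s$label[i], s$mean_auc[i], s$sd_auc[i],
                         s$n_repeats[i], s$n_folds[i]))
  } else lines <- c(lines, "not run")
  lines <- c(lines, "")

  if (length(manifest$warnings)) {
    lines <- c(lines, section("Warnings"), manifest$warnings)
  }
  lines
}

#' Human-readable summary of a pipeline run
#'
#' Regenerates the textual report (leading genes, stage-specific and
#' progressive lists, RCC contrast, AUC table) from a run's manifest and
#' output files; stages that did not run are marked "not run". The text is
#' a pure function of the manifest and output files.
#'
#' @param manifest A `run_manifest` (from [run_pipeline()]), or the path
#'   to a run's output directory or `manifest.json`.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest)) {
    path <- manifest
    if (dir.exists(path)) path <- file.path(path, "manifest.json")
    if (!file.exists(path)) stop("no manifest found at ", path)
    out_dir <- dirname(path)
    manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    out_dir <- attr(manifest, "out_dir")
    if (is.null(out_dir)) stop("manifest carries no output directory")
  }
  required <- c("input", "screen")
  missing <- setdiff(required, names(manifest$stages))
  if (length(missing))
    stop("incomplete manifest; missing stage(s): ",
         paste(missing, collapse = ", "))
  lines <- pipeline_report_text(manifest, out_dir)
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("plasmaseek run_manifest:", length(x$stages), "stages,",
      length(x$files), "files\n")
  cat("  stages:", paste(names(x$stages), collapse = ", "), "\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
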