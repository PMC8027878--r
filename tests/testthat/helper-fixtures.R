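# Small in-code fixtures shared across test files.

# 3-gene x 4-sample cohort with tumor/normal annotations.
tiny_cohort <- function() {
  vals <- matrix(c(1, 2, 3, 4,
                   10, 20, 30, 40,
                   5, 5, 5, 5), nrow = 3, byrow = TRUE,
                 dimnames = list(c("BIRC5", "APOC2", "STMN1"),
                                 c("s1", "s2", "s3", "s4")))
  ann <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                    group = c("tumor", "tumor", "normal", "normal"),
                    stage = c("I", "II", "unknown", "unknown"),
                    stringsAsFactors = FALSE)
  expression_cohort(vals, ann)
}

write_tiny_expression <- function(path = tempfile(fileext = ".tsv")) {
  write_expression(tiny_cohort(), path)
  path
}

# Wrap a weight matrix as a network layer for centrality tests.
as_layer <- function(weights, kind = "similarity", group = "normal",
                     beta = 1, hard_threshold = 0) {
  genes <- sprintf("n%02d", seq_len(nrow(weights)))
  dimnames(weights) <- list(genes, genes)
  structure(list(kind = kind, group = group, genes = genes,
                 weights = weights, beta = beta,
                 hard_threshold = hard_threshold),
            class = "network_layer")
}

# Minimal dual_network_pair from two weight matrices.
as_pair <- function(w_sim, w_dis, group = "normal", beta = 1) {
  structure(list(similarity = as_layer(w_sim, "similarity", group, beta),
                 dissimilarity = as_layer(w_dis, "dissimilarity", group, beta),
                 group = group, beta = beta, scale_free_r2 = NA_real_),
            class = "dual_network_pair")
}

# Null design helper: no planted effects, optional modules.
null_design <- function(seed, n_genes = 200, n_tumor = 415, n_normal = 35,
                        modules = FALSE, module_loading = 0.6) {
  props <- c(I = 0.137, II = 0.296, III = 0.407, IV = 0.099,
             unknown = 0.061)
  ma <- if (modules)
    stats::setNames(rep(1:4, each = 20), sprintf("g%04d", 26:105))
  else NULL
  sim_design(n_genes, n_tumor, n_normal, props,
             module_assignments = ma,
             module_loading = if (modules) module_loading else 0,
             seed = seed)
}
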