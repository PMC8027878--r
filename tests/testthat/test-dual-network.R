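# Correlation matrices, soft-power transforms, scale-free fit, network pairs.

test_that("pearson_matrix evaluates the correlation formula", {
  vals <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(6, 4, 2),
                d = c(1, 3, 2))
  colnames(vals) <- c("s1", "s2", "s3")
  ann <- data.frame(sample_id = colnames(vals), group = "tumor",
                    stage = "unknown")
  co <- expression_cohort(vals, ann)
  r <- pearson_matrix(co, "tumor")
  expect_equal(unclass(r)["a", "b"], 1)
  expect_equal(unclass(r)["a", "c"], -1)
  expect_equal(unclass(r)["a", "d"], 0.5, tolerance = 1e-12)
  expect_equal(diag(unclass(r)), stats::setNames(rep(1, 4), rownames(vals)))
})

test_that("pearson_matrix matches brute-force covariance on random data", {
  set.seed(9)
  vals <- matrix(stats::rexp(200), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("s%02d", 1:10)))
  ann <- data.frame(sample_id = colnames(vals), group = "normal",
                    stage = "unknown")
  co <- expression_cohort(vals, ann)
  r <- unclass(pearson_matrix(co, "normal"))
  for (i in 1:20) for (j in 1:20) {
    xi <- vals[i, ]; xj <- vals[j, ]
    want <- mean((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(mean((xi - mean(xi))^2) * mean((xj - mean(xj))^2))
    expect_equal(r[i, j], want, tolerance = 1e-10)
  }
})

test_that("zero-variance genes become isolated nodes, not dropped", {
  vals <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(2, 2, 2, 2))
  colnames(vals) <- sprintf("s%d", 1:4)
  ann <- data.frame(sample_id = colnames(vals), group = "tumor",
                    stage = "unknown")
  co <- expression_cohort(vals, ann)
  expect_warning(r <- pearson_matrix(co, "tumor"), "zero-variance")
  expect_equal(unclass(r)["c", "a"], 0)
  expect_equal(unclass(r)["c", "c"], 1)
  expect_error(pearson_matrix(tiny_cohort(), "tumor"), "fewer than 3")
})

test_that("transforms hit their fixed points and worked values", {
  for (b in c(1, 2, 7, 20)) {
    expect_equal(cor_transform(1, "similarity", b), 1)
    expect_equal(cor_transform(1, "dissimilarity", b), 0)
  }
  expect_equal(cor_transform(0, "similarity", 1), 0.5)
  expect_equal(cor_transform(0, "dissimilarity", 1), 0.5)
  expect_equal(cor_transform(0.5, "similarity", 2), 0.5625, tolerance = 1e-12)
  expect_equal(cor_transform(0.5, "dissimilarity", 2), 0.0625,
               tolerance = 1e-12)
  expect_error(cor_transform(0.5, "similarity", 0.5), "beta")
  expect_error(cor_transform(1.5, "similarity", 2), "\\[-1, 1\\]")
})

test_that("transform identities and monotonicity hold over random r", {
  set.seed(21)
  r <- stats::runif(10000, -1, 1)
  s1 <- cor_transform(r, "similarity", 1)
  d1 <- cor_transform(r, "dissimilarity", 1)
  expect_equal(s1 + d1, rep(1, length(r)), tolerance = 1e-12)
  for (b in c(1, 3, 8, 20)) {
    s <- cor_transform(r, "similarity", b)
    d <- cor_transform(r, "dissimilarity", b)
    expect_true(all(s >= 0 & s <= 1 & d >= 0 & d <= 1))
    o <- order(r)
    expect_false(is.unsorted(s[o]))
    expect_false(is.unsorted(rev(d[o])))
  }
  # raising beta never increases a weight
  expect_true(all(cor_transform(r, "similarity", 5) <=
                  cor_transform(r, "similarity", 2) + 1e-15))
})

test_that("signed scale-free fit index recognizes exact power laws", {
  # ten equally spaced connectivity values, one per equal-width bin, with
  # multiplicities proportional to 1/k: exactly collinear in log-log with
  # negative slope
  k_vals <- 10 * (1:10)
  counts <- round(2520 / (1:10))  # 2520 = lcm(1..10) keeps ratios exact
  k <- rep(k_vals, counts)
  expect_equal(suppressWarnings(scale_free_r2(k)), 1, tolerance = 1e-12)
  # increasing power law: frequency proportional to k -> signed R^2 = -1
  k2 <- rep(k_vals, 1:10)
  expect_equal(suppressWarnings(scale_free_r2(k2)), -1, tolerance = 1e-12)
  expect_warning(flat <- scale_free_r2(rep(3, 50)), "degenerate")
  expect_equal(flat, 0)
})

test_that("homogeneous random graphs fail the scale-free criterion", {
  set.seed(33)
  w <- random_weight_matrix(100, density = 0.3)
  expect_lt(scale_free_fit(w), 0.85)
  expect_error(scale_free_fit(w[1:10, 1:10]), "at least 20")
})

test_that("soft-power selection follows the threshold rule", {
  # strong modules (loading 0.8) must yield an accepted power
  d <- null_design(3, n_genes = 200, n_tumor = 60, n_normal = 60,
                   modules = TRUE, module_loading = 0.8)
  sim <- simulate_cohort(d)
  r <- pearson_matrix(sim$cohort, "tumor")
  fit <- select_soft_power(r, pipeline_config())
  expect_gte(fit$beta, 1)
  expect_gte(fit$achieved_r2, 0.85)
  # degenerate threshold 0: the smallest power always passes
  fit0 <- select_soft_power(r, pipeline_config(scale_free_r2_threshold = 0))
  expect_equal(fit0$beta, 1)
  # single-candidate grid is chosen regardless of fit
  fit6 <- suppressWarnings(
    select_soft_power(r, pipeline_config(soft_power_grid = 6,
                                         scale_free_r2_threshold = 0.999)))
  expect_equal(fit6$beta, 6)
})

test_that("build_dual_network enforces its postconditions", {
  set.seed(2)
  n <- 30
  vals <- matrix(stats::rexp(n * 12), n, 12,
                 dimnames = list(sprintf("g%02d", 1:n), sprintf("s%02d", 1:12)))
  ann <- data.frame(sample_id = colnames(vals), group = "normal",
                    stage = "unknown")
  co <- expression_cohort(vals, ann)
  pair <- suppressWarnings(build_dual_network(co, "normal",
                                              pipeline_config()))
  for (layer in list(pair$similarity, pair$dissimilarity)) {
    w <- layer$weights
    expect_identical(w, t(w))
    expect_equal(unname(diag(w)), rep(0, n))
    expect_true(all(w == 0 | w >= 0.01))
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(layer$beta, pair$beta)
  }
})

test_that("perfectly correlated genes produce the boundary edges", {
  s <- seq_len(6)
  vals <- rbind(a = s, b = 2 * s, c = 7 - s,
                matrix(stats::runif(6 * 20), 20, 6,
                       dimnames = list(sprintf("g%02d", 1:20), NULL)))
  colnames(vals) <- sprintf("s%d", 1:6)
  ann <- data.frame(sample_id = colnames(vals), group = "tumor",
                    stage = "unknown")
  co <- expression_cohort(vals, ann)
  pair <- suppressWarnings(build_dual_network(co, "tumor", pipeline_config(),
                                              beta = 1))
  # r(a,b) = 1: similarity edge 1, dissimilarity edge absent
  expect_equal(pair$similarity$weights["a", "b"], 1)
  expect_equal(pair$dissimilarity$weights["a", "b"], 0)
  # r(a,c) = -1: mirrored
  expect_equal(pair$dissimilarity$weights["a", "c"], 1)
  expect_equal(pair$similarity$weights["a", "c"], 0)
})

test_that("hard threshold keeps boundary weights and prunes below", {
  # r = 0.9599 at beta 1: similarity 0.97995 and dissimilarity 0.02005
  # both survive the 0.01 threshold
  expect_equal(cor_transform(0.9599, "similarity", 1), 0.97995)
  expect_equal(cor_transform(0.9599, "dissimilarity", 1), 0.02005)
  # and the pruning rule is strictly-less-than
  d <- null_design(3, n_genes = 25, n_tumor = 20, n_normal = 10)
  sim <- simulate_cohort(d)
  pair <- suppressWarnings(build_dual_network(sim$cohort, "tumor",
                                              pipeline_config(), beta = 12))
  w <- pair$similarity$weights
  expect_true(all(w[w > 0] >= 0.01))
})

test_that("edge retention is nonincreasing in beta", {
  d <- null_design(29, n_genes = 40, n_tumor = 25, n_normal = 10)
  sim <- simulate_cohort(d)
  edges <- vapply(c(1, 3, 6, 10, 15), function(b) {
    pair <- suppressWarnings(build_dual_network(sim$cohort, "tumor",
                                                pipeline_config(), beta = b))
    sum(pair$similarity$weights > 0) + sum(pair$dissimilarity$weights > 0)
  }, 0)
  expect_false(is.unsorted(rev(edges)))
})

test_that("network layers serialize as edge lists with sidecars", {
  d <- null_design(37, n_genes = 30, n_tumor = 20, n_normal = 10)
  sim <- simulate_cohort(d)
  pair <- suppressWarnings(build_dual_network(sim$cohort, "tumor",
                                              pipeline_config(), beta = 2))
  path <- tempfile(fileext = ".tsv")
  write_network_layer(pair$similarity, path, pair$scale_free_r2)
  el <- utils::read.delim(path)
  w <- pair$similarity$weights
  expect_equal(nrow(el), sum(w > 0) / 2)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$beta, 2)
  expect_equal(meta$kind, "similarity")
})
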