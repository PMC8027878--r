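# Rank-based screening: exact-test oracle agreement, screen behavior,
# leading/stage-specific/progressive calls.

test_that("mann_whitney_u matches the enumeration oracle on small tie-free inputs", {
  # every group-size combination up to 5x5, several random draws each
  set.seed(101)
  for (n1 in 2:5) for (n2 in 2:5) for (rep in 1:3) {
    x <- sample(100, n1 + n2)  # distinct -> tie-free
    tumor <- x[seq_len(n1)]
    normal <- x[-seq_len(n1)]
    got <- mann_whitney_u(tumor, normal)
    want <- mw_enum_oracle(tumor, normal)
    expect_identical(got$u, want$u)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("mann_whitney_u handles worked examples and degenerate input", {
  # clean separation of 3 vs 3: U = 9, exact two-sided p = 0.1
  got <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_equal(got$u, 9)
  expect_equal(got$p, 0.1, tolerance = 1e-12)
  # identical paired samples: central U, p = 1
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$p, 1)
  # constant gene: fully tied, p = 1, central U
  got <- mann_whitney_u(rep(5, 10), rep(5, 4))
  expect_equal(got$p, 1)
  expect_equal(got$u, 20)
  expect_error(mann_whitney_u(1, c(1, 2)), "at least 2")
})

test_that("U complement identity holds across random inputs with ties", {
  set.seed(77)
  for (i in 1:25) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x <- sample(8, n1, replace = TRUE)  # heavy ties on purpose
    y <- sample(8, n2, replace = TRUE)
    u1 <- mann_whitney_u(x, y)$u
    u2 <- mann_whitney_u(y, x)$u
    expect_equal(u1 + u2, n1 * n2)
  }
})

test_that("screen recovers planted global genes and orders by p", {
  d <- default_design("stomach_like", seed = 7, n_genes = 150)
  sim <- simulate_cohort(d)
  tab <- screen_cohort(sim$cohort, pipeline_config(), classify = FALSE)
  expect_false(is.unsorted(tab$p))
  planted_up <- sim$truth$gene[sim$truth$klass == "global_up"]
  hit <- tab[match(planted_up, tab$gene), ]
  expect_true(all(hit$p < 0.05))
  expect_true(all(hit$direction == "up"))
  planted_down <- sim$truth$gene[sim$truth$klass == "global_down"]
  expect_true(all(tab$direction[match(planted_down, tab$gene)] == "down"))
})

test_that("screen is invariant under permutation of sample columns", {
  d <- null_design(13, n_genes = 40, n_tumor = 30, n_normal = 10)
  sim <- simulate_cohort(d)
  co <- sim$cohort
  set.seed(5)
  perm <- sample(length(co$samples))
  co2 <- expression_cohort(co$values[, perm],
                           co$annotations[perm, , drop = FALSE])
  t1 <- screen_cohort(co, classify = FALSE)
  t2 <- screen_cohort(co2, classify = FALSE)
  expect_equal(t1[order(t1$gene), c("gene", "u", "p", "direction")],
               t2[order(t2$gene), c("gene", "u", "p", "direction")],
               ignore_attr = TRUE)
})

test_that("leading_genes selects top-k significant genes of a direction", {
  d <- default_design("stomach_like", seed = 19, n_genes = 150,
                      effect_size = 2)
  sim <- simulate_cohort(d)
  tab <- screen_cohort(sim$cohort, classify = FALSE)
  lu <- leading_genes(tab, "up", 5)
  expect_setequal(lu, sim$truth$gene[sim$truth$klass == "global_up"])
  # ascending p within the list
  expect_false(is.unsorted(tab$p[match(lu, tab$gene)]))
  # requesting more than available returns all qualifying with a warning
  few <- tab[tab$direction == "down" & tab$p < 0.05, ]
  expect_warning(ld <- leading_genes(tab, "down", nrow(few) + 5),
                 "significant")
  expect_length(ld, nrow(few))
})

test_that("stage-specific calls find the planted focal stage", {
  d <- null_design(23, n_genes = 80, n_tumor = 415, n_normal = 35)
  d$effect_specs <- list(effect_spec("g0001", "stage_specific", 2,
                                     target_stage = "I"))
  sim <- simulate_cohort(d)
  tab <- screen_cohort(sim$cohort, classify = FALSE)
  ss <- stage_specific_genes(sim$cohort, tab, pipeline_config())
  expect_true("g0001" %in% ss$up[["I"]])
  expect_false("g0001" %in% unlist(ss$up[c("II", "III", "IV")]))
  pmat <- attr(ss, "stage_specific_p")
  expect_lt(pmat["g0001", "I"], 0.05)
})

test_that("stage handling degrades gracefully", {
  # all-unknown stages: empty map with warning
  d <- null_design(31, n_genes = 25, n_tumor = 20, n_normal = 10)
  d$stage_proportions <- c(I = 0, II = 0.001, III = 0, IV = 0,
                           unknown = 0.999)
  sim <- simulate_cohort(d)
  ann <- sim$cohort$annotations
  if (any(ann$stage != "unknown")) {
    ann$stage[] <- "unknown"
    sim$cohort <- expression_cohort(sim$cohort$values, ann)
  }
  tab <- suppressWarnings(screen_cohort(sim$cohort, classify = FALSE))
  expect_warning(ss <- stage_specific_genes(sim$cohort, tab),
                 "no tumors with known stage")
  expect_length(ss$up, 0)
  expect_warning(pg <- progressive_genes(sim$cohort, tab), "fewer than two")
  expect_length(pg$up, 0)
})

test_that("progressive calls detect monotone trends and mirror for down", {
  cfg <- pipeline_config()
  d <- null_design(41, n_genes = 60, n_tumor = 415, n_normal = 35)
  d$effect_specs <- list(effect_spec("g0001", "progressive_up", 2),
                         effect_spec("g0002", "progressive_down", 2),
                         effect_spec("g0003", "global_up", 2))
  sim <- simulate_cohort(d)
  tab <- screen_cohort(sim$cohort, cfg, classify = FALSE)
  pg <- progressive_genes(sim$cohort, tab, cfg)
  expect_true("g0001" %in% pg$up)
  expect_true("g0002" %in% pg$down)
  expect_false("g0001" %in% pg$down)
})

test_that("a flat global shift is rarely called progressive", {
  # equal shift at all stages: the trend criterion should not fire often
  hits <- 0L
  for (seed in 1:10) {
    d <- null_design(seed + 300, n_genes = 25, n_tumor = 300, n_normal = 30)
    d$effect_specs <- list(effect_spec("g0001", "global_up", 2))
    sim <- simulate_cohort(d)
    tab <- screen_cohort(sim$cohort, classify = FALSE)
    pg <- progressive_genes(sim$cohort, tab)
    if ("g0001" %in% pg$up) hits <- hits + 1L
  }
  expect_lte(hits, 2L)
})

test_that("jonckheere_trend is calibrated and directional", {
  set.seed(55)
  stages <- rep(c("I", "II", "III", "IV"), times = c(20, 30, 30, 20))
  # strong increasing trend
  x <- stats::rnorm(length(stages)) + 0.8 * match(stages, c("I","II","III","IV"))
  expect_lt(jonckheere_trend(x, stages, "increasing")$p, 1e-4)
  expect_gt(jonckheere_trend(x, stages, "decreasing")$p, 0.5)
  # null calibration: one-sided p roughly uniform
  ps <- replicate(200, jonckheere_trend(stats::rnorm(length(stages)),
                                        stages, "increasing")$p)
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.05)
  expect_error(jonckheere_trend(1:5, rep("I", 5)), ">= 2 distinct stages")
})

test_that("pattern labels agree with the planted truth", {
  d <- default_design("stomach_like", seed = 3, n_genes = 150,
                      effect_size = 2)
  sim <- simulate_cohort(d)
  tab <- screen_cohort(sim$cohort, pipeline_config())
  got <- tab$pattern[match(sim$truth$gene, tab$gene)]
  tr <- sim$truth$klass
  expect_identical(got[tr == "global_up"], rep("leading_up", 5))
  expect_identical(got[tr == "global_down"], rep("leading_down", 5))
  expect_identical(got[tr == "progressive_up"], rep("progressive_up", 5))
  expect_identical(got[tr == "progressive_down"], rep("progressive_down", 5))
  expect_identical(got[tr == "stage_specific"], rep("stage_specific", 5))
})

test_that("null screens flag roughly alpha of the genes", {
  d <- null_design(201, n_genes = 200)
  sim <- simulate_cohort(d)
  tab <- screen_cohort(sim$cohort, classify = FALSE)
  frac <- mean(tab$p < 0.05)
  # 99% binomial band for one 200-gene screen
  expect_gte(frac, stats::qbinom(0.005, 200, 0.05) / 200)
  expect_lte(frac, stats::qbinom(0.995, 200, 0.05) / 200)
})
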