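test_that("r2 equals an independent frequency-count oracle", {
  for (s in 1:8) {
    p <- withr::with_seed(300 + s, {
      mat <- matrix(sample(c("A", "G"), 60, replace = TRUE,
                           prob = c(0.65, 0.35)), nrow = 10)
      rownames(mat) <- sprintf("s%02d", 1:10)
      if (s > 4) mat[cbind(sample(10, 3), sample(6, 3))] <- "N"
      aligned_panel(mat)
    })
    vt <- suppressMessages(call_snps(p))
    vt <- vt[vt$n_alleles == 2L, ]
    if (nrow(vt) < 2L) next
    ld <- suppressMessages(ld_matrix(vt))
    for (k in seq_len(nrow(ld))) {
      a <- vt$geno[[match(ld$id1[k], vt$variant_id)]]
      b <- vt$geno[[match(ld$id2[k], vt$variant_id)]]
      expect_equal(ld$r2[k], oracle_r2(a, b), tolerance = 1e-12)
    }
    expect_true(all(ld$r2 >= 0 & ld$r2 <= 1 + 1e-12))
    expect_true(all(ld$p >= 0 & ld$p <= 1))
  }
})

test_that("identical columns give r2 = 1 and label swaps change nothing", {
  p <- make_panel(c("AG", "AG", "TC", "TC", "AG"))
  vt <- suppressMessages(call_snps(p))
  ld <- suppressMessages(ld_matrix(vt))
  expect_equal(ld$r2, 1)
  # swapping which base is major at one site leaves r2 untouched
  swapped <- chartr("AT", "TA", p$mat[, 1L])
  p2 <- aligned_panel(cbind(swapped, p$mat[, 2L]))
  ld2 <- suppressMessages(ld_matrix(suppressMessages(call_snps(p2))))
  expect_equal(ld2$r2, ld$r2, tolerance = 1e-12)
})

test_that("the default panel yields choose(22, 2) LD pairs", {
  cfg <- zmbt1_sim_config(seed = 8)
  sim <- simulate_panel(cfg)
  vt <- suppressMessages(call_variants(sim$panel, cfg$model))
  ld <- suppressMessages(ld_matrix(vt))
  expect_equal(nrow(ld), choose(22, 2))
  expect_equal(ld$distance, abs(ld$pos2 - ld$pos1))
})

test_that("Fisher p is 1 when a site is nearly fixed in the shared subset", {
  p <- make_panel(c("AG", "AG", "AG", "AG", "AG", "AG", "AG", "TG",
                    "AC", "AC"))
  vt <- suppressMessages(call_snps(p))
  ld <- suppressMessages(ld_matrix(vt))
  expect_equal(ld$p, 1)
})

test_that("decay fits recover exact linear data and its decay distance", {
  d <- seq(50, 2400, by = 50)
  ld <- structure(
    tibble::tibble(id1 = "a", id2 = "b", pos1 = 0L, pos2 = d,
                   distance = d, r2 = 0.8 - 0.0002 * d, p = 0.01),
    class = c("ld_pairs", "tbl_df", "tbl", "data.frame")
  )
  fit <- fit_ld_decay(ld, n = 80)
  expect_equal(fit$selected, "linear")
  lin <- fit$models[fit$models$model == "linear", ]
  expect_equal(lin$params[[1L]][["a"]], 0.8, tolerance = 1e-9)
  expect_equal(lin$params[[1L]][["b"]], -0.0002, tolerance = 1e-9)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_equal(lin$distance_at_target, 3500, tolerance = 1e-6)
  expect_equal(glance(fit)$selected, "linear")
  td <- tidy(fit)
  expect_true(all(c("model", "term", "estimate") %in% names(td)))

  # intercept 0.7334, slope -0.00029: the curve crosses 0.1 near 2184 bp
  ld2 <- ld
  ld2$r2 <- 0.7334 - 0.00029 * d
  fit2 <- fit_ld_decay(ld2, n = 80)
  lin2 <- fit2$models[fit2$models$model == "linear", ]
  expect_equal(lin2$distance_at_target, (0.7334 - 0.1) / 0.00029,
               tolerance = 1e-6)
  expect_equal(lin2$distance_at_target, 2184, tolerance = 1e-3)
})

test_that("the Remington fit recovers a known recombination scale", {
  rho_true <- 2e-3
  d <- seq(10, 2400, length.out = 200)
  hits <- 0L
  for (s in 1:100) {
    r2 <- withr::with_seed(400 + s, {
      pmax(0, genediv:::remington_expectation(rho_true * d, 80) +
             rnorm(length(d), 0, 0.02))
    })
    ld <- structure(
      tibble::tibble(id1 = "a", id2 = "b", pos1 = 0L, pos2 = as.integer(d),
                     distance = d, r2 = r2, p = 0.01),
      class = c("ld_pairs", "tbl_df", "tbl", "data.frame")
    )
    fit <- fit_ld_decay(ld, n = 80)
    rem <- fit$models[fit$models$model == "remington", ]
    if (rem$converged &&
        abs(rem$params[[1L]][["rho"]] - rho_true) / rho_true < 0.15) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 95L)
})

test_that("four-gamete intervals reduce to the Hudson-Kaplan minimum", {
  # one explicit four-gamete pair
  p <- make_panel(c("AA", "AG", "GA", "GG"))
  vt <- suppressMessages(call_snps(p))
  res <- hudson_kaplan_rm(vt)
  expect_equal(res$rm, 1L)
  expect_equal(res$intervals$left, 1L)
  expect_equal(res$intervals$right, 2L)
  # tree-compatible data: no event
  p0 <- make_panel(c("AA", "AG", "AG", "GG", "GG"))
  expect_equal(hudson_kaplan_rm(suppressMessages(call_snps(p0)))$rm, 0L)

  # greedy equals the exhaustive minimum on random small panels
  checked <- 0L
  for (s in 1:40) {
    p <- withr::with_seed(500 + s, {
      mat <- matrix(sample(c("A", "G"), 8 * 8, replace = TRUE,
                           prob = c(0.65, 0.35)), nrow = 8)
      rownames(mat) <- sprintf("s%02d", 1:8)
      aligned_panel(mat)
    })
    vt <- suppressMessages(call_snps(p))
    vt <- vt[vt$n_alleles == 2L, ]
    if (nrow(vt) < 2L) next
    got <- hudson_kaplan_rm(vt)$rm
    geno <- do.call(cbind, purrr::map(vt$geno, ~ .x))
    expect_equal(got, oracle_rm(geno, vt$position),
                 info = sprintf("seed %d", 500 + s))
    checked <- checked + 1L
  }
  expect_gte(checked, 30L)
})

test_that("recombination-free panels always give Rm = 0", {
  for (s in 1:25) {
    p <- simulate_neutral_panel(12, 10, 60, seed = 600 + s)
    vt <- suppressMessages(call_snps(p))
    expect_equal(hudson_kaplan_rm(vt)$rm, 0L)
  }
  # and the planted recombinant gives exactly one interval spanning the
  # crossover
  cfg <- zmbt1_sim_config(seed = 9)
  sim <- simulate_panel(cfg)
  vt <- suppressMessages(call_variants(sim$panel, cfg$model))
  res <- hudson_kaplan_rm(vt)
  expect_equal(res$rm, 1L)
  expect_lt(res$intervals$left, cfg$recombinant$breakpoint)
  expect_gt(res$intervals$right, cfg$recombinant$breakpoint)
})
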