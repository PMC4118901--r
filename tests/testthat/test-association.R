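cfg <- zmbt1_sim_config(seed = 12)
sim <- simulate_panel(cfg)
vt <- suppressMessages(call_variants(sim$panel, cfg$model))

test_that("the MAF filter drops rare alleles with a >= boundary", {
  filtered <- suppressMessages(maf_filter(vt, 0.05))
  # 3/80 = 0.0375 alleles (and singletons) go; 4/80 = 0.05 stays
  freqs <- purrr::map(filtered$alleles, ~ .x$count / sum(vt$alleles[[1]]$count))
  kept_counts <- unlist(purrr::map(filtered$alleles, "count"))
  expect_true(all(kept_counts >= 4L))
  expect_false("snp6" %in% filtered$variant_id)    # the singleton SNP
  # the tri-allelic indel reduces to a biallelic contrast: the 3 lines
  # with the rare allele become missing, the 27-line allele survives
  tri_before <- vt[vt$kind == "indel" & vt$n_alleles == 3L, ]
  tri_after <- filtered[filtered$variant_id == tri_before$variant_id, ]
  expect_equal(tri_after$n_alleles, 2L)
  expect_equal(sum(is.na(tri_after$geno[[1L]])), 3L)
  expect_equal(sort(tri_after$alleles[[1L]]$count), c(27L, 50L))
  # a balanced SNP is untouched
  p5050 <- make_panel(c(rep("AG", 2), rep("GG", 2)))
  v <- suppressMessages(call_snps(p5050))
  expect_equal(suppressMessages(maf_filter(v, 0.05))$alleles,
               v$alleles)
})

test_that("with no structure the partial F equals the squared t", {
  withr::with_seed(31, {
    y <- rnorm(40)
    x <- rbinom(40, 1, 0.4)
  })
  phen <- tibble::tibble(sample_id = sprintf("l%02d", 1:40), tr = y)
  g <- setNames(ifelse(x == 1, "G", "A"), phen$sample_id)
  vt1 <- tibble::tibble(
    variant_id = "v1", kind = "snp", position = 1L, span = 1L,
    region = NA_character_, class = "parsimony_informative",
    coding_effect = NA_character_, n_alleles = 2L,
    alleles = list(tibble::tibble(allele = c("A", "G"),
                                  count = c(sum(x == 0), sum(x == 1)))),
    geno = list(g)
  )
  res <- glm_association(vt1, phen, q = NULL, welch = FALSE)
  tt <- t.test(y[x == 1], y[x == 0], var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  # class means are plain group averages
  expect_equal(res$mean_major, mean(y[x == 0]), tolerance = 1e-12)
  expect_equal(res$mean_minor, mean(y[x == 1]), tolerance = 1e-12)
  expect_equal(res$sd_minor, sd(y[x == 1]), tolerance = 1e-12)
})

test_that("marker R2 is invariant to affine trait rescaling", {
  filtered <- suppressMessages(maf_filter(vt, 0.05))
  q <- simulate_q(cfg, sim$truth)
  phen <- simulate_phenotypes(cfg, sim$truth, q)
  r1 <- glm_association(filtered[1:5, ], phen, q, traits = "dH")
  phen2 <- dplyr::mutate(phen, dH = 3.7 * dH - 100)
  r2 <- glm_association(filtered[1:5, ], phen2, q, traits = "dH")
  expect_equal(r1$marker_r2, r2$marker_r2, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  expect_true(all(r1$marker_r2 >= 0 & r1$marker_r2 <= 1))
})

test_that("adding the marker never increases residual error", {
  q <- simulate_q(cfg, sim$truth)
  phen <- simulate_phenotypes(cfg, sim$truth, q)
  filtered <- suppressMessages(maf_filter(vt, 0.05))
  res <- glm_association(filtered, phen, q, traits = c("dH", "PV"))
  expect_true(all(res$marker_r2 >= -1e-12, na.rm = TRUE))
  expect_true(all(res$f >= 0, na.rm = TRUE))
})

test_that("null markers reject at the nominal rate under the Q model", {
  tr <- sim$truth
  q <- simulate_q(cfg, tr)
  ids <- names(tr$sample_haplotype)
  x <- as.numeric(ids %in% tr$indel_carriers$iX[[1L]]$samples)
  qm <- as.matrix(q[match(ids, q$sample_id), c("Q1", "Q2")])
  rej <- withr::with_seed(77, {
    replicate(1000, {
      y <- rnorm(length(ids))
      red <- lm(y ~ qm)
      full <- lm(y ~ qm + x)
      f <- (sum(red$residuals^2) - sum(full$residuals^2)) /
        (sum(full$residuals^2) / full$df.residual)
      pf(f, 1, full$df.residual, lower.tail = FALSE) < 0.05
    })
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("the allele-class t test detects a planted half-sd shift", {
  hits <- withr::with_seed(41, {
    replicate(200, {
      y <- c(rnorm(27, -0.5), rnorm(50, 0))
      carrier <- c(rep(TRUE, 27), rep(FALSE, 50))
      allele_class_test(y, carrier)$t_p < 0.05
    })
  })
  expect_gt(mean(hits), 0.5)
  # and stays calibrated under the null
  null_p <- withr::with_seed(42, {
    replicate(400, {
      y <- rnorm(60)
      allele_class_test(y, rep(c(TRUE, FALSE), 30))$t_p
    })
  })
  expect_gt(mean(null_p < 0.05), 0.02)
  expect_lt(mean(null_p < 0.05), 0.09)
})

test_that("trait summaries and correlations behave on stylized inputs", {
  q <- simulate_q(cfg, sim$truth)
  phen <- simulate_phenotypes(cfg, sim$truth, q)
  ts <- trait_summaries(phen)
  expect_equal(nrow(ts), 11L)
  expect_true(all(ts$min <= ts$mean & ts$mean <= ts$max))
  expect_true(all(ts$f > 0))
  expect_true(all(ts$p < 0.01))   # replicate noise well below line spread

  # duplicated trait correlates perfectly
  dup <- dplyr::mutate(phen, dH2 = dH)
  tc <- trait_correlations(dup[, c("sample_id", "replicate", "dH", "dH2")])
  expect_equal(tc$r, 1, tolerance = 1e-12)
  # constant trait: sd 0, correlation undefined
  const <- dplyr::mutate(phen[, c("sample_id", "replicate", "dH")],
                         flat = 1)
  ts2 <- trait_summaries(const)
  expect_equal(ts2$sd[ts2$trait == "flat"], 0)
  tc2 <- trait_correlations(const)
  expect_true(is.na(tc2$r[tc2$trait1 == "dH" & tc2$trait2 == "flat"]))

  # independent traits: small mean |r|, ~5% significant
  sim_ind <- withr::with_seed(55, {
    tibble::tibble(sample_id = sprintf("l%03d", 1:80),
                   !!!setNames(purrr::map(1:10, ~ rnorm(80)),
                               paste0("t", 1:10)))
  })
  tci <- trait_correlations(sim_ind)
  expect_lt(mean(abs(tci$r)), 0.15)
  expect_lt(mean(tci$p < 0.05), 0.15)
})

test_that("rank-deficient designs are flagged rather than fitted", {
  phen <- tibble::tibble(sample_id = sprintf("l%02d", 1:20),
                         tr = rnorm(20))
  x <- rep(c(0, 1), each = 10)
  q <- tibble::tibble(sample_id = phen$sample_id, Q1 = x, Q2 = 1 - x)
  g <- setNames(ifelse(x == 1, "G", "A"), phen$sample_id)
  vt1 <- tibble::tibble(
    variant_id = "v1", kind = "snp", position = 1L, span = 1L,
    region = NA_character_, class = "parsimony_informative",
    coding_effect = NA_character_, n_alleles = 2L,
    alleles = list(tibble::tibble(allele = c("A", "G"), count = c(10L, 10L))),
    geno = list(g)
  )
  res <- glm_association(vt1, phen, q)
  expect_true(is.na(res$p))
})
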