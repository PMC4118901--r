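test_that("simulation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(simulate_study(zmbt1_sim_config(seed = 21), d1))
  suppressMessages(simulate_study(zmbt1_sim_config(seed = 21), d2))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and a different seed changes the sequence content
  d3 <- withr::local_tempdir()
  suppressMessages(simulate_study(zmbt1_sim_config(seed = 22), d3))
  expect_false(identical(readLines(file.path(d1, "alignment.fasta")),
                         readLines(file.path(d3, "alignment.fasta"))))
})

test_that("written study files read back into consistent objects", {
  d <- withr::local_tempdir()
  paths <- suppressMessages(simulate_study(zmbt1_sim_config(seed = 23), d))
  panel <- suppressMessages(read_alignment(paths$alignment,
                                           reference_id = "B73ref"))
  model <- suppressMessages(read_gene_model(paths$gene_model))
  phen <- read_phenotypes(paths$phenotypes, panel)
  q <- read_qmatrix(paths$qmatrix, panel)
  expect_equal(n_samples(panel), 80L)
  expect_equal(alignment_length(panel), max(model$regions$end))
  expect_equal(nrow(phen), 80L * 3L)
  expect_equal(nrow(q), 80L)
  expect_equal(rowSums(q[, -1L]), rep(1, 80), tolerance = 1e-9)
  truth <- jsonlite::read_json(paths$truth)
  expect_equal(length(truth$sample_haplotype), 80L)
  # no reader crashes on generator output; variant calling agrees with truth
  vt <- suppressMessages(call_variants(panel, model))
  expect_equal(sum(vt$kind == "snp"), length(truth$snp_positions))
})

test_that("a mutation-free configuration yields a monomorphic panel", {
  cfg <- zmbt1_sim_config(seed = 2)
  cfg$snps <- cfg$snps[0, ]
  cfg$indels <- cfg$indels[0, ]
  cfg$recombinant <- NULL
  cfg$haplotypes <- tibble::tibble(name = paste0("Hap_", 1:2),
                                   count = c(40L, 40L))
  cfg$structure$home <- c(Hap_1 = 1L, Hap_2 = 2L)
  sim <- simulate_panel(cfg)
  vt <- suppressMessages(call_variants(sim$panel, cfg$model))
  expect_equal(nrow(vt), 0L)
  ds <- suppressMessages(summarize_regions(sim$panel, cfg$model, vt))
  expect_true(all(ds$pi == 0))
  expect_true(all(is.nan(ds$tajima_D)))
  expect_equal(nrow(collapse_haplotypes(sim$panel)), 1L)
})

test_that("haplotype assignment uses exact counts, multinomial on request", {
  cfg <- zmbt1_sim_config(seed = 2)
  sim <- simulate_panel(cfg)
  expect_equal(unname(sim$truth$haplotype_counts),
               cfg$haplotypes$count)
  cfg$multinomial <- TRUE
  sim2 <- simulate_panel(cfg)
  expect_equal(sum(sim2$truth$haplotype_counts), 80L)
  expect_false(identical(sim2$truth$haplotype_counts,
                         sim$truth$haplotype_counts))
})

test_that("Q matrices are valid admixture rows", {
  cfg <- zmbt1_sim_config(seed = 13)
  truth <- simulate_panel(cfg)$truth
  q <- simulate_q(cfg, truth)
  expect_equal(rowSums(q[, -1L]), rep(1, 80), tolerance = 1e-12)
  expect_true(all(q[, -1L] >= 0))
  cfg$structure$K <- 1L
  q1 <- simulate_q(cfg, truth)
  expect_equal(q1$Q1, rep(1, 80))
})

test_that("planted phenotype effects carry the target variance share", {
  r2s <- purrr::map_dbl(1:40, function(s) {
    cfg <- zmbt1_sim_config(seed = 900 + s)
    truth <- simulate_panel(cfg)$truth
    phen <- simulate_phenotypes(cfg, truth)
    ids <- names(truth$sample_haplotype)
    x <- as.numeric(ids %in% truth$indel_carriers$iX[[1L]]$samples)
    y <- tapply(phen$dH, phen$sample_id, mean)[ids]
    summary(lm(y ~ x))$r.squared
  })
  expect_lt(abs(mean(r2s) - 0.0926), 0.03)
  # a beta = 0 trait shows only noise-level association
  null_r2 <- purrr::map_dbl(1:40, function(s) {
    cfg <- zmbt1_sim_config(seed = 950 + s)
    truth <- simulate_panel(cfg)$truth
    phen <- simulate_phenotypes(cfg, truth)
    ids <- names(truth$sample_haplotype)
    x <- as.numeric(ids %in% truth$indel_carriers$iX[[1L]]$samples)
    y <- tapply(phen$PV, phen$sample_id, mean)[ids]
    summary(lm(y ~ x))$r.squared
  })
  expect_lt(mean(null_r2), 0.05)
})

test_that("a zero-variance trait degrades gracefully in the ANOVA", {
  cfg <- zmbt1_sim_config(seed = 3)
  cfg$traits <- tibble::tibble(
    name = "flat", mean = 5, sd = 0,
    causal_variant = NA_character_, causal_allele = NA_character_,
    target_r2 = NA_real_, direction = NA_real_
  )
  cfg$replicate_sd_frac <- 0
  truth <- simulate_panel(cfg)$truth
  phen <- simulate_phenotypes(cfg, truth)
  ts <- trait_summaries(phen)
  expect_equal(ts$sd, 0)
  expect_true(is.na(ts$f))
})

# planted genotypes are a deterministic function of the design, so one
# variant table serves every confounding replicate
variant_cache_conf <- suppressMessages(maf_filter(call_variants(
  simulate_panel(zmbt1_sim_config(seed = 1))$panel,
  zmbt1_sim_config()$model
)))

test_that("structure tilts confound the naive model but not the Q model", {
  rates <- purrr::map_dfr(1:30, function(s) {
    cfg <- zmbt1_sim_config(seed = 700 + s)
    # trait driven by subpopulation only, no causal variant
    cfg$traits <- tibble::tibble(
      name = "conf", mean = 0, sd = 1,
      causal_variant = NA_character_, causal_allele = NA_character_,
      target_r2 = NA_real_, direction = NA_real_
    )
    # the shift singles out subpopulation 2, whose haplotypes carry a
    # coherent block of markers, so ignoring Q inflates their signal
    cfg$pop_effects <- list(conf = c(0, 2, 0))
    truth <- simulate_panel(cfg)$truth
    q <- simulate_q(cfg, truth)
    phen <- simulate_phenotypes(cfg, truth, q)
    vt <- variant_cache_conf
    res_q <- glm_association(vt, phen, q, traits = "conf")
    res_naive <- glm_association(vt, phen, q = NULL, traits = "conf")
    tibble::tibble(naive = mean(res_naive$p < 0.05),
                   corrected = mean(res_q$p < 0.05))
  })
  expect_gt(mean(rates$naive), mean(rates$corrected) + 0.05)
})

test_that("neutral panels have the requested number of segregating sites", {
  p <- simulate_neutral_panel(30, 15, 200, seed = 5)
  vt <- suppressMessages(call_snps(p))
  expect_equal(nrow(vt), 15L)
  expect_equal(n_samples(p), 30L)
  expect_error(simulate_neutral_panel(10, 50, 40), "exceed")
})
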