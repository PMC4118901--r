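#' Simulation configuration for a candidate-gene panel
#'
#' Builds the configuration consumed by [simulate_panel()],
#' [simulate_phenotypes()] and [simulate_q()]. The default configuration
#' (`zmbt1_sim_config()`) emulates a maize starch-gene amplicon panel: 80
#' inbred lines over a 2,436 bp 7-region gene model, 22 planted SNPs and 8
#' indel events (37 indel columns; one tri-allelic in-frame coding
#' deletion with no-deletion/-3/-6 alleles), 11 full-length haplotypes
#' with counts 29/16/18/9/1/1/2/1/1/1/1 collapsing to 6 CDS haplotypes
#' (32/16/18/9/2/3), exactly one singleton SNP and two singleton indels,
#' one recombinant haplotype (a single crossover between two haplotype
#' backgrounds, yielding one four-gamete interval), a 3-subpopulation
#' admixture structure tilted by haplotype, and one causal variant (the
#' -3 allele of the coding indel) explaining a target fraction of the
#' variance of one gelatinization trait.
#'
#' @param seed Integer seed; every simulated artefact is a deterministic
#'   function of it.
#' @param n_samples Unused override hook; the planted haplotype counts
#'   define the default panel size.
#' @param ... Fields overriding the default configuration (same names as
#'   the returned list).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- zmbt1_sim_config(seed)
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' @rdname sim_config
#' @export
zmbt1_sim_config <- function(seed = 1L) {
  model <- gene_model(
    tibble::tribble(
      ~name,      ~kind,      ~start, ~end,
      "promoter", "promoter",      1,  520,
      "exon1",    "exon",        521, 1144,
      "intron1",  "intron",     1145, 1275,
      "exon2",    "exon",       1276, 1437,
      "intron2",  "intron",     1438, 1565,
      "exon3",    "exon",       1566, 2099,
      "utr3",     "utr3",       2100, 2436
    ),
    cds_regions = c("exon1", "exon2", "exon3"),
    strand = "+", gene = "ZmBT1like"
  )
  haplotypes <- tibble::tibble(
    name = paste0("Hap_", 1:11),
    count = c(29L, 16L, 18L, 9L, 1L, 1L, 2L, 1L, 1L, 1L, 1L)
  )
  # planted SNPs; coding ones carry a forced reference codon so their
  # synonymous/nonsynonymous status is guaranteed by construction
  snps <- tibble::tribble(
    ~id,     ~position, ~carriers,              ~alt, ~codon, ~ref_codon,
    "p1",     101L, c("Hap_2"),                  NA,   NA,    NA,
    "p2",     205L, c("Hap_2"),                  NA,   NA,    NA,
    "p3",     310L, c("Hap_2"),                  NA,   NA,    NA,
    "p4",     421L, c("Hap_2"),                  NA,   NA,    NA,
    "p5",     450L, c("Hap_4", "Hap_6", "Hap_9"), NA, NA,   NA,
    "p6",     470L, c("Hap_5"),                  NA,   NA,    NA,
    "p7",     500L, c("Hap_2", "Hap_3"),         NA,   NA,    NA,
    "e1",     640L, c("Hap_2"),                 "G",  40L, "GCA",
    "e2",     730L, c("Hap_2"),                 "G",  70L, "GCA",
    "e3",     820L, c("Hap_2"),                 "G", 100L, "GCA",
    "e4",     910L, c("Hap_4", "Hap_6", "Hap_9"), "G", 130L, "GCA",
    "e5",    1000L, c("Hap_6", "Hap_9"),        "G", 160L, "GCA",
    "x1",    1649L, c("Hap_2"),                 "G", 290L, "GCA",
    "x2",    1709L, c("Hap_4", "Hap_6", "Hap_9"), "G", 310L, "GCA",
    "x3",    1769L, c("Hap_4", "Hap_6", "Hap_9"), "G", 330L, "GCA",
    "x4",    2037L, c("Hap_7"),                 "A", 420L, "GCA",
    "u1",    2150L, c("Hap_2"),                  NA,   NA,    NA,
    "u2",    2200L, c("Hap_2"),                  NA,   NA,    NA,
    "u3",    2250L, c("Hap_2"),                  NA,   NA,    NA,
    "u4",    2300L, c("Hap_4", "Hap_6", "Hap_9"), NA, NA,   NA,
    "u5",    2350L, c("Hap_2"),                  NA,   NA,    NA,
    "u6",    2400L, c("Hap_2"),                  NA,   NA,    NA
  )
  snps$carriers <- purrr::map(snps$carriers, identity)
  indels <- tibble::tibble(
    id = c("iP", "iE1", "iI1a", "iI1b", "iI1c", "iI2", "iX", "iU"),
    start = c(60L, 548L, 1150L, 1180L, 1200L, 1460L, 1977L, 2120L),
    span = c(1L, 3L, 10L, 5L, 4L, 7L, 6L, 1L),
    alleles = list(
      list(list(label = "del1", gaps = 1L, carriers = "Hap_8")),
      list(list(label = "del3", gaps = 3L, carriers = c("Hap_6", "Hap_9"))),
      list(list(label = "del10", gaps = 10L, carriers = "Hap_2")),
      list(list(label = "del5", gaps = 5L, carriers = "Hap_2")),
      list(list(label = "del4", gaps = 4L,
                carriers = c("Hap_4", "Hap_6", "Hap_9"))),
      list(list(label = "del7", gaps = 7L, carriers = c("Hap_2", "Hap_9"))),
      list(list(label = "del3", gaps = 3L, carriers = c("Hap_3", "Hap_4")),
           list(label = "del6", gaps = 6L, carriers = "Hap_7")),
      list(list(label = "del1", gaps = 1L, carriers = "Hap_10"))
    )
  )
  # forced codons anchoring the designed coding consequences: the
  # tri-allelic deletion removes E (GAA) or ED (GAA GAT); the terminal
  # codon is the stop
  forced_codons <- tibble::tibble(
    codon = c(10L, 400L, 401L, 402L, 440L),
    bases = c("GCT", "GAA", "GAT", "GGT", "TAA")
  )
  traits <- tibble::tibble(
    name = c("PV", "TV", "BD", "FV", "SB", "PT", "PTP",
             "To", "Tp", "Tc", "dH"),
    mean = c(1317.013, 926.856, 390.156, 2575.488, 1258.563, 5.336,
             72.759, 70.912, 75.591, 81.266, 6.225),
    sd = c(405.135, 250.758, 216.227, 841.476, 593.455, 0.391, 2.641,
           1.219, 1.037, 1.989, 1.008),
    causal_variant = c(rep(NA_character_, 10L), "iX"),
    causal_allele = c(rep(NA_character_, 10L), "del3"),
    target_r2 = c(rep(NA_real_, 10L), 0.0926),
    direction = c(rep(NA_real_, 10L), -1)
  )
  list(
    seed = as.integer(seed),
    mode = "planted",
    model = model,
    reference_id = "B73ref",
    haplotypes = haplotypes,
    snps = snps,
    indels = indels,
    forced_codons = forced_codons,
    recombinant = list(name = "Hap_11", left = "Hap_3", right = "Hap_7",
                       breakpoint = 700L),
    multinomial = FALSE,
    traits = traits,
    replicates = 3L,
    replicate_sd_frac = 0.3,
    structure = list(
      K = 3L,
      home = c(Hap_1 = 1L, Hap_3 = 1L,
               Hap_2 = 2L, Hap_6 = 2L, Hap_9 = 2L,
               Hap_4 = 3L, Hap_5 = 3L, Hap_7 = 3L, Hap_8 = 3L,
               Hap_10 = 3L, Hap_11 = 3L),
      home_prob = 0.6,
      concentration = 20,
      own_weight = 0.9
    ),
    pop_effects = NULL,   # optional K-vector per trait name, for confounding
    domains = tibble::tibble(
      name = c("carrier_1", "carrier_2", "carrier_3"),
      start = c(40L, 160L, 280L),
      end = c(130L, 250L, 370L)
    ),
    neutral = list(S = 20L, L = 600L)
  )
}

# complement map used when planting alternative alleles at noncoding sites
.alt_map <- c(A = "G", C = "T", G = "A", T = "C")

#' Simulate an aligned panel with planted variants
#'
#' Draws a random reference sequence (stop-free codons over the CDS, the
#' forced codons of the configuration applied on top), builds each
#' haplotype by applying its planted SNP alleles and deletion gap runs,
#' splices the optional recombinant haplotype from its two parental
#' backgrounds at the configured breakpoint, and assigns samples to
#' haplotypes by exact counts (or multinomially when
#' `cfg$multinomial = TRUE`). With `cfg$mode = "neutral"` an
#' infinite-sites panel on a random coalescent genealogy is returned
#' instead (see [simulate_neutral_panel()]).
#'
#' Everything is a deterministic function of `cfg$seed`.
#'
#' @param cfg A `sim_config` list.
#' @return A list with `panel` (an [aligned_panel]) and `truth` (planted
#'   ground truth: sample-to-haplotype map, per-variant carrier ids,
#'   causal variant, recombination interval bounds).
#' @export
simulate_panel <- function(cfg) {
  if (identical(cfg$mode, "neutral")) {
    panel <- simulate_neutral_panel(
      n = sum(cfg$haplotypes$count), S = cfg$neutral$S, L = cfg$neutral$L,
      seed = cfg$seed
    )
    return(list(panel = panel, truth = list(mode = "neutral")))
  }
  withr::with_seed(cfg$seed, {
    L <- max(cfg$model$regions$end)
    ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    cds <- cds_columns(cfg$model)
    # stop-free random codons over the CDS
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
    n_codons <- length(cds) %/% 3L
    codons <- sample(sense, n_codons, replace = TRUE)
    for (k in seq_len(nrow(cfg$forced_codons))) {
      codons[cfg$forced_codons$codon[k]] <- cfg$forced_codons$bases[k]
    }
    ref[cds] <- unlist(strsplit(codons, "", fixed = TRUE))
    # forced reference codons under coding SNPs
    for (k in which(!is.na(cfg$snps$ref_codon))) {
      codon_i <- cfg$snps$codon[k]
      ref[cds[(3L * codon_i - 2L):(3L * codon_i)]] <-
        strsplit(cfg$snps$ref_codon[k], "", fixed = TRUE)[[1L]]
    }
    snps <- cfg$snps
    snps$alt <- ifelse(is.na(snps$alt), unname(.alt_map[ref[snps$position]]),
                       snps$alt)

    hap_names <- cfg$haplotypes$name
    direct <- setdiff(hap_names, cfg$recombinant$name)
    hap_seq <- list()
    for (h in direct) {
      s <- ref
      for (k in seq_len(nrow(snps))) {
        if (h %in% snps$carriers[[k]]) s[snps$position[k]] <- snps$alt[k]
      }
      for (k in seq_len(nrow(cfg$indels))) {
        for (al in cfg$indels$alleles[[k]]) {
          if (h %in% al$carriers) {
            s[seq.int(cfg$indels$start[k],
                      cfg$indels$start[k] + al$gaps - 1L)] <- "-"
          }
        }
      }
      hap_seq[[h]] <- s
    }
    if (!is.null(cfg$recombinant)) {
      rc <- cfg$recombinant
      bp <- rc$breakpoint
      hap_seq[[rc$name]] <- c(hap_seq[[rc$left]][seq_len(bp)],
                              hap_seq[[rc$right]][seq.int(bp + 1L, L)])
    }
    counts <- cfg$haplotypes$count
    n <- sum(counts)
    assignment <- if (isTRUE(cfg$multinomial)) {
      sample(hap_names, n, replace = TRUE, prob = counts / n)
    } else {
      rep(hap_names, counts)
    }
    ids <- sprintf("line%03d", seq_len(n))
    mat <- do.call(rbind, hap_seq[assignment])
    rownames(mat) <- ids
    panel <- aligned_panel(mat, ids, reference_id = cfg$reference_id,
                           reference = ref)
    truth <- list(
      seed = cfg$seed,
      sample_haplotype = setNames(assignment, ids),
      haplotype_counts = setNames(
        as.integer(table(factor(assignment, hap_names))), hap_names),
      snp_carriers = setNames(purrr::map(seq_len(nrow(snps)), function(k) {
        carried <- snps$carriers[[k]]
        if (!is.null(cfg$recombinant) &&
            snp_on_recombinant(snps$position[k], carried, cfg$recombinant)) {
          carried <- c(carried, cfg$recombinant$name)
        }
        ids[assignment %in% carried]
      }), snps$id),
      snp_positions = setNames(snps$position, snps$id),
      indel_carriers = setNames(
        purrr::map(seq_len(nrow(cfg$indels)), function(k) {
          purrr::map(cfg$indels$alleles[[k]], function(al) {
            carried <- al$carriers
            if (!is.null(cfg$recombinant) &&
                snp_on_recombinant(cfg$indels$start[k], carried,
                                   cfg$recombinant)) {
              carried <- c(carried, cfg$recombinant$name)
            }
            list(label = al$label, samples = ids[assignment %in% carried])
          })
        }), cfg$indels$id),
      causal = list(
        variant = cfg$traits$causal_variant[!is.na(cfg$traits$causal_variant)],
        allele = cfg$traits$causal_allele[!is.na(cfg$traits$causal_allele)],
        trait = cfg$traits$name[!is.na(cfg$traits$causal_variant)],
        target_r2 = cfg$traits$target_r2[!is.na(cfg$traits$target_r2)]
      ),
      recombinant = cfg$recombinant
    )
    list(panel = panel, truth = truth)
  })
}

# does the recombinant inherit the variant at `position` from a carrier
# background?
snp_on_recombinant <- function(position, carriers, rc) {
  parent <- if (position <= rc$breakpoint) rc$left else rc$right
  parent %in% carriers
}

#' Neutral-equilibrium panel on a random coalescent genealogy
#'
#' Places `S` infinite-sites mutations on a random coalescent tree
#' (branch-length-weighted), each on its own column; derived alleles go to
#' the tips below the mutated branch. No recombination, so the panel is
#' always tree-compatible (four-gamete clean). Intended for sanity bands
#' on the neutrality statistics, not as a full coalescent simulator.
#'
#' @param n Number of samples.
#' @param S Number of segregating sites.
#' @param L Alignment length (mutated columns are spread over it).
#' @param seed Integer seed.
#' @return An [aligned_panel].
#' @export
simulate_neutral_panel <- function(n, S, L = 600L, seed = 1L) {
  if (S >= L) abort("`L` must exceed `S`.")
  withr::with_seed(seed, {
    tree <- ape::rcoal(n)
    edge_len <- tree$edge.length
    tips_below <- phangorn::Descendants(tree, tree$edge[, 2L], type = "tips")
    mat <- matrix("A", nrow = n, ncol = L,
                  dimnames = list(sprintf("line%03d", seq_len(n)), NULL))
    cols <- sort(sample.int(L, S))
    picks <- sample.int(length(edge_len), S, replace = TRUE,
                        prob = edge_len / sum(edge_len))
    for (k in seq_len(S)) {
      mat[tips_below[[picks[k]]], cols[k]] <- "G"
    }
    aligned_panel(mat)
  })
}

#' Simulate phenotypes with a planted causal variant
#'
#' Per-line trait values are `mean + beta * x + Q %*% pop_effects + eps`
#' with `eps ~ N(0, sd^2 (1 - R2))`; `x` is the centred carrier indicator
#' of the causal allele and `beta` is solved from the target marker
#' R-squared given the realized allele frequency
#' (`beta = direction * sd * sqrt(R2) / sd(x)`). Replicate rows add
#' within-line noise of `replicate_sd_frac * sd`.
#'
#' @param cfg A `sim_config`.
#' @param truth Truth list from [simulate_panel()].
#' @param q Optional Q tibble from [simulate_q()]; needed only when
#'   `cfg$pop_effects` is set.
#' @return A phenotype tibble (`sample_id`, `replicate`, trait columns).
#' @export
simulate_phenotypes <- function(cfg, truth, q = NULL) {
  ids <- names(truth$sample_haplotype)
  n <- length(ids)
  withr::with_seed(cfg$seed + 2L, {
    cols <- purrr::pmap(cfg$traits, function(name, mean, sd, causal_variant,
                                             causal_allele, target_r2,
                                             direction, ...) {
      mu <- mean; sigma <- sd   # unshadow base::mean / stats::sd
      y <- rep(mu, n)
      resid_var <- sigma^2
      if (!is.na(causal_variant)) {
        carriers <- causal_carriers(truth, causal_variant, causal_allele)
        x <- as.numeric(ids %in% carriers)
        if (stats::sd(x) > 0 && sigma > 0) {
          beta <- direction * sigma * sqrt(target_r2) / stats::sd(x)
          y <- y + beta * (x - base::mean(x))
          resid_var <- sigma^2 * (1 - target_r2)
        }
      }
      if (!is.null(cfg$pop_effects) && !is.null(cfg$pop_effects[[name]])) {
        qm <- as.matrix(q[match(ids, q$sample_id),
                          setdiff(names(q), "sample_id"), drop = FALSE])
        eff <- cfg$pop_effects[[name]]
        y <- y + as.numeric(qm %*% (eff - mean(eff)))
      }
      y + rnorm(n, 0, sqrt(resid_var))
    })
    names(cols) <- cfg$traits$name
    line_tbl <- tibble::tibble(sample_id = ids, !!!cols)
    reps <- max(1L, cfg$replicates %||% 1L)
    out <- tidyr::crossing(line_tbl, replicate = seq_len(reps))
    for (k in seq_len(nrow(cfg$traits))) {
      tr <- cfg$traits$name[k]
      wsd <- (cfg$replicate_sd_frac %||% 0) * cfg$traits$sd[k]
      if (reps > 1L && wsd > 0) {
        out[[tr]] <- out[[tr]] + rnorm(nrow(out), 0, wsd)
      }
    }
    dplyr::select(dplyr::arrange(out, .data$sample_id, .data$replicate),
                  "sample_id", "replicate", dplyr::everything())
  })
}

causal_carriers <- function(truth, variant, allele) {
  if (variant %in% names(truth$snp_carriers)) {
    return(truth$snp_carriers[[variant]])
  }
  if (variant %in% names(truth$indel_carriers)) {
    alleles <- truth$indel_carriers[[variant]]
    hit <- purrr::detect(alleles, ~ .x$label == allele)
    if (is.null(hit)) abort(sprintf("Allele '%s' not planted at '%s'.",
                                    allele, variant))
    return(hit$samples)
  }
  abort(sprintf("Causal variant '%s' not in the planted truth.", variant))
}

#' Simulate an admixture Q matrix tilted by haplotype
#'
#' Each line's subpopulation is drawn from a haplotype-tilted distribution
#' (probability `home_prob` on the haplotype's home subpopulation), so
#' subpopulations have different haplotype frequencies without being
#' haplotype partitions; the line's admixture row is then a Dirichlet draw
#' concentrated on that subpopulation (weight `own_weight` on the own
#' component). Rows sum to 1. With `K = 1` a single column of ones is
#' returned.
#'
#' @param cfg A `sim_config`.
#' @param truth Truth list from [simulate_panel()].
#' @return A tibble `sample_id`, `Q1..QK`.
#' @export
simulate_q <- function(cfg, truth) {
  ids <- names(truth$sample_haplotype)
  K <- cfg$structure$K
  if (K == 1L) {
    return(tibble::tibble(sample_id = ids, Q1 = rep(1, length(ids))))
  }
  withr::with_seed(cfg$seed + 1L, {
    own <- cfg$structure$own_weight
    conc <- cfg$structure$concentration
    home <- cfg$structure$home[truth$sample_haplotype]
    hp <- cfg$structure$home_prob
    pops <- vapply(home, function(h) {
      w <- rep((1 - hp) / (K - 1), K)
      w[h] <- hp
      sample.int(K, 1L, prob = w)
    }, integer(1L))
    rows <- purrr::map(pops, function(p) {
      w <- rep((1 - own) / (K - 1), K)
      w[p] <- own
      g <- rgamma(K, shape = conc * w, rate = 1)
      g / sum(g)
    })
    qm <- do.call(rbind, rows)
    colnames(qm) <- paste0("Q", seq_len(K))
    tibble::tibble(sample_id = ids, !!!tibble::as_tibble(qm))
  })
}

#' Simulate and write a full study to disk
#'
#' Runs [simulate_panel()], [simulate_q()] and [simulate_phenotypes()]
#' and writes `alignment.fasta`, `gene_model.yaml`, `phenotypes.csv`,
#' `qmatrix.tsv` and `truth.json` into `dir`. Outputs are byte-identical
#' under a fixed seed.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly; the simulated objects
#'   are attached as attributes `panel`, `truth`, `phenotypes`, `q`.
#' @export
simulate_study <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_panel(cfg)
  q <- simulate_q(cfg, sim$truth)
  phen <- simulate_phenotypes(cfg, sim$truth, q = q)
  paths <- list(
    alignment = file.path(dir, "alignment.fasta"),
    gene_model = file.path(dir, "gene_model.yaml"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    qmatrix = file.path(dir, "qmatrix.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_alignment(sim$panel, paths$alignment)
  write_gene_model(cfg$model, paths$gene_model)
  write_phenotypes(phen, paths$phenotypes)
  write_qmatrix(q, paths$qmatrix)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  out <- paths
  attr(out, "panel") <- sim$panel
  attr(out, "truth") <- sim$truth
  attr(out, "phenotypes") <- phen
  attr(out, "q") <- q
  invisible(out)
}
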