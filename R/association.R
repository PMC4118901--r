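#' Minor-allele-frequency filter
#'
#' Drops alleles whose frequency (over called samples) is strictly below
#' the threshold: samples carrying a dropped allele become missing for
#' that variant, so a tri-allelic indel whose rarest allele is below
#' threshold reduces to a biallelic contrast (an allele at exactly the
#' threshold is retained). Variants left with fewer than two alleles are
#' removed.
#'
#' @param vt A variant table.
#' @param threshold Minimum allele frequency, default 0.05.
#' @return The filtered variant tibble; dropped variant ids are reported.
#' @export
maf_filter <- function(vt, threshold = 0.05) {
  if (nrow(vt) == 0L) return(vt)
  filtered <- purrr::pmap(
    list(vt$alleles, vt$geno),
    function(alleles, geno) {
      n_called <- sum(alleles$count)
      keep <- alleles$count / n_called >= threshold
      kept <- alleles[keep, , drop = FALSE]
      geno[!geno %in% kept$allele] <- NA_character_
      list(alleles = kept, geno = geno)
    }
  )
  vt$alleles <- purrr::map(filtered, "alleles")
  vt$geno <- purrr::map(filtered, "geno")
  vt$n_alleles <- purrr::map_int(vt$alleles, nrow)
  drop <- vt$n_alleles < 2L
  if (any(drop)) {
    inform(sprintf("MAF filter (%.3g) removed %d variant(s): %s", threshold,
                   sum(drop), paste(vt$variant_id[drop], collapse = ", ")))
  }
  vt[!drop, , drop = FALSE]
}

#' Structured-population GLM marker-trait association
#'
#' Fits, for every variant x trait pair, the fixed-effects linear model
#' `trait ~ intercept + Q + marker` on per-line trait means, where Q is
#' the admixture matrix (encoded as K-1 columns to avoid collinearity with
#' the intercept) and the marker is the 0/1 major/minor contrast of the
#' two most frequent alleles (samples carrying other alleles are excluded
#' for that variant). Marker significance is the partial F-test of the
#' full model against the Q-only model; the marker R-squared is the
#' fraction of total phenotypic variance explained,
#' `(SSE_reduced - SSE_full) / SS_total`. Per-allele-class means/sds and a
#' two-sample t comparison are reported alongside.
#'
#' @param vt A (typically MAF-filtered) variant table.
#' @param phen Phenotype tibble (`sample_id`, optional `replicate`, trait
#'   columns); replicates are averaged to line means.
#' @param q Q-matrix tibble (`sample_id` + admixture columns), or `NULL`
#'   for an unstructured model.
#' @param traits Trait names to test (default: all).
#' @param welch Use the Welch unequal-variance t-test for the allele-class
#'   comparison (default `TRUE`; `FALSE` gives the pooled-variance test).
#' @return A tibble with one row per variant x trait: sample size, partial
#'   `f` and `p`, `p_bonferroni`, `marker_r2`, allele labels and class
#'   means/sds, and the t-test columns. Rank-deficient designs (marker
#'   collinear with Q) are flagged with `p = NA`.
#' @export
glm_association <- function(vt, phen, q = NULL, traits = NULL, welch = TRUE) {
  means <- line_means(phen)
  traits <- traits %||% setdiff(names(means), "sample_id")
  missing_tr <- setdiff(traits, names(means))
  if (length(missing_tr)) {
    abort(sprintf("Unknown trait(s): %s", paste(missing_tr, collapse = ", ")))
  }
  samples <- intersect(variant_samples(vt), means$sample_id)
  if (!is.null(q)) samples <- intersect(samples, q$sample_id)
  if (length(samples) < 5L) abort("Fewer than 5 samples shared across inputs.")
  means <- means[match(samples, means$sample_id), , drop = FALSE]
  qmat <- NULL
  if (!is.null(q)) {
    qm <- as.matrix(q[match(samples, q$sample_id),
                      setdiff(names(q), "sample_id"), drop = FALSE])
    # K-1 encoding: drop the last admixture column
    if (ncol(qm) > 1L) qm <- qm[, -ncol(qm), drop = FALSE]
    qmat <- qm
  }

  rows <- purrr::map(seq_len(nrow(vt)), function(i) {
    al <- vt$alleles[[i]]
    major <- al$allele[1L]
    minor <- al$allele[2L]
    g <- vt$geno[[i]][samples]
    x <- ifelse(g == major, 0, ifelse(g == minor, 1, NA))
    purrr::map(traits, function(tr) {
      y <- means[[tr]]
      ok <- !is.na(x) & !is.na(y)
      fit <- marker_fit(y[ok], x[ok], qmat[ok, , drop = FALSE], welch)
      tibble::tibble(
        variant_id = vt$variant_id[i], trait = tr, n = sum(ok),
        allele_major = major, allele_minor = minor, !!!fit
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out
}

marker_fit <- function(y, x, qmat, welch) {
  empty <- list(f = NA_real_, p = NA_real_, marker_r2 = NA_real_,
                mean_major = NA_real_, sd_major = NA_real_,
                mean_minor = NA_real_, sd_minor = NA_real_,
                t = NA_real_, t_p = NA_real_)
  if (length(unique(x)) < 2L || length(y) < 5L) return(empty)
  red <- if (is.null(qmat)) lm(y ~ 1) else lm(y ~ qmat)
  full <- if (is.null(qmat)) lm(y ~ x) else lm(y ~ qmat + x)
  # marker collinear with structure -> x drops out of the fit
  if (any(is.na(coef(full)))) return(empty)
  sse_red <- sum(red$residuals^2)
  sse_full <- sum(full$residuals^2)
  df_res <- full$df.residual
  f <- (sse_red - sse_full) / (sse_full / df_res)
  p <- pf(f, 1, df_res, lower.tail = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  cls <- allele_class_test(y, x == 1, welch = welch)
  c(list(f = f, p = p, marker_r2 = (sse_red - sse_full) / ss_tot), cls)
}

#' Two-sample comparison of allele classes
#'
#' Means and standard deviations per allele class, and a two-sample t-test
#' (Welch by default) between carriers and non-carriers of the minor
#' allele.
#'
#' @param y Trait values.
#' @param carrier Logical: `TRUE` for minor-allele carriers.
#' @param welch Unequal-variance test (default) or pooled.
#' @return A list `mean_major`, `sd_major`, `mean_minor`, `sd_minor`,
#'   `t`, `t_p`.
#' @export
allele_class_test <- function(y, carrier, welch = TRUE) {
  y0 <- y[!carrier & !is.na(carrier)]
  y1 <- y[carrier & !is.na(carrier)]
  out <- list(mean_major = mean(y0), sd_major = sd(y0),
              mean_minor = mean(y1), sd_minor = sd(y1),
              t = NA_real_, t_p = NA_real_)
  if (length(y0) >= 2L && length(y1) >= 2L && (sd(y0) > 0 || sd(y1) > 0)) {
    tt <- t.test(y1, y0, var.equal = !welch)
    out$t <- unname(tt$statistic)
    out$t_p <- tt$p.value
  }
  out
}

line_means <- function(phen) {
  traits <- setdiff(names(phen), c("sample_id", "replicate"))
  dplyr::summarise(
    dplyr::group_by(phen, .data$sample_id),
    dplyr::across(dplyr::all_of(traits), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
}

#' Descriptive trait statistics with across-line ANOVA
#'
#' Mean, standard deviation, minimum and maximum of the per-line trait
#' means, plus the one-way ANOVA F and p across lines when replicate
#' measurements are present (the F test asks whether lines differ more
#' than replicates within a line).
#'
#' @param phen Phenotype tibble (`sample_id`, optional `replicate`, trait
#'   columns).
#' @return A tibble with one row per trait.
#' @export
trait_summaries <- function(phen) {
  traits <- setdiff(names(phen), c("sample_id", "replicate"))
  means <- line_means(phen)
  has_reps <- "replicate" %in% names(phen) &&
    any(duplicated(phen$sample_id))
  purrr::map_dfr(traits, function(tr) {
    v <- means[[tr]]
    f <- p <- NA_real_
    if (has_reps) {
      sub <- phen[!is.na(phen[[tr]]), c("sample_id", tr)]
      if (sd(sub[[tr]]) > 0) {
        av <- summary(aov(sub[[tr]] ~ factor(sub$sample_id)))[[1L]]
        f <- av[["F value"]][1L]
        p <- av[["Pr(>F)"]][1L]
        if (is.na(f)) {   # zero within-line variance
          warn(sprintf("Trait '%s' has zero within-line variance; F reported as Inf.", tr))
          f <- Inf; p <- 0
        }
      }
    }
    tibble::tibble(trait = tr, mean = mean(v, na.rm = TRUE),
                   sd = sd(v, na.rm = TRUE), min = min(v, na.rm = TRUE),
                   max = max(v, na.rm = TRUE), f = f, p = p)
  })
}

#' Pairwise Pearson correlations between traits
#'
#' Pearson r on per-line means for every unordered trait pair, with the
#' two-sided t-based p-value. Constant traits give `NA`.
#'
#' @param phen Phenotype tibble.
#' @return A tibble `trait1`, `trait2`, `n`, `r`, `p`.
#' @export
trait_correlations <- function(phen) {
  means <- line_means(phen)
  traits <- setdiff(names(means), "sample_id")
  pairs <- combn(traits, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    t1 <- pairs[1L, k]; t2 <- pairs[2L, k]
    x <- means[[t1]]; y <- means[[t2]]
    ok <- !is.na(x) & !is.na(y)
    nn <- sum(ok)
    r <- p <- NA_real_
    if (nn >= 3L && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
      r <- cor(x[ok], y[ok])
      tstat <- r * sqrt((nn - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tstat), nn - 2)
    }
    tibble::tibble(trait1 = t1, trait2 = t2, n = nn, r = r, p = p)
  })
}
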