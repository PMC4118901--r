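#' Neutrality-test constants for sample size n
#'
#' The harmonic-number constants of the Tajima test and the corrected
#' coefficients of the Fu and Li starred tests (the no-outgroup forms).
#' All constants depend only on the number of sampled sequences `n`.
#'
#' @param n Number of sequences (>= 2; the tests themselves need n >= 4).
#' @return A list with `n`, `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`,
#'   `e2`, and the starred-test coefficients `u_Dstar`, `v_Dstar`,
#'   `u_Fstar`, `v_Fstar`.
#' @export
neutrality_constants <- function(n) {
  if (n < 2L) abort("Neutrality constants need n >= 2.")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  # starred (no-outgroup) coefficients, corrected forms
  an1 <- a1 + 1 / n
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  v_Dstar <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
                2 * (n * a1 * (a1 + 1)) / (n - 1)^2) / (a1^2 + a2)
  u_Dstar <- (n / (n - 1)) * (a1 - n / (n - 1)) - v_Dstar
  v_Fstar <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
                (2 * (n - 1) * a1) / n^2 - 8 * a2 / n) / (a1^2 + a2)
  u_Fstar <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
                (3 * n * (n - 1))) / a1 - v_Fstar
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2, u_Dstar = u_Dstar, v_Dstar = v_Dstar,
       u_Fstar = u_Fstar, v_Fstar = v_Fstar)
}

#' Per-site nucleotide diversity (pi)
#'
#' The average number of pairwise nucleotide differences per site over a
#' gap-free column set. Pairs involving missing bases (`N`) are compared
#' over their shared called sites only; the pair denominator stays
#' `choose(N, 2)` so pi is the mean pairwise difference count divided by
#' the net length.
#'
#' @param panel An [aligned_panel].
#' @param columns Alignment columns to use (the region's gap-excluded
#'   column set); defaults to all gap-free columns.
#' @return Per-site pi (`NaN` when the column set is empty).
#' @export
pairwise_pi <- function(panel, columns = NULL) {
  mat <- panel$mat
  if (is.null(columns)) {
    columns <- which(!apply(mat == "-", 2L, any))
  }
  if (!length(columns)) return(NaN)
  n <- nrow(mat)
  npairs <- choose(n, 2)
  total_diffs <- sum(vapply(columns, function(j) {
    x <- mat[, j]
    x <- x[!x %in% c("N", "-")]
    m <- length(x)
    if (m < 2L) return(0)
    tab <- table(x)
    choose(m, 2) - sum(choose(as.integer(tab), 2))
  }, numeric(1L)))
  (total_diffs / npairs) / length(columns)
}

#' Watterson's theta per site
#'
#' `S / (a1 * L)`: the segregating-site estimator of the population
#' mutation rate, corrected for sample size through the harmonic number
#' `a1`.
#'
#' @param S Number of segregating (SNP) sites.
#' @param n Number of sequences.
#' @param L Net length in bp (gap-excluded sites).
#' @return Per-site theta (0 when `S = 0`, `NaN` when `L = 0`).
#' @export
watterson_theta <- function(S, n, L) {
  if (L <= 0) return(NaN)
  if (S == 0) return(0)
  S / (neutrality_constants(n)$a1 * L)
}

#' Tajima's D
#'
#' The normalized difference between the pairwise-difference and
#' segregating-site estimates of diversity. Positive values indicate an
#' excess of intermediate-frequency polymorphism (balancing selection or
#' population contraction).
#'
#' @param pi Per-site nucleotide diversity.
#' @param S Number of segregating sites (>= 1 for a defined statistic).
#' @param n Number of sequences (>= 4).
#' @param L Net length in bp, so that `pi * L` is the mean number of
#'   pairwise differences.
#' @return The D statistic (`NaN` when `S = 0`).
#' @export
tajimas_d <- function(pi, S, n, L) {
  if (S == 0) return(NaN)
  if (n < 4L) abort("Tajima's D needs n >= 4.")
  k <- neutrality_constants(n)
  (pi * L - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Two-sided p-value for Tajima's D (beta approximation)
#'
#' D is treated as a scaled beta variable on its theoretical range
#' `[Dmin, Dmax]` with mean 0 and variance 1 (the classical
#' moment-matched approximation used for the tabulated confidence
#' bounds).
#'
#' @param D The observed statistic.
#' @param n Number of sequences.
#' @return Two-sided p-value.
#' @export
tajimas_d_pvalue <- function(D, n) {
  if (is.na(D)) return(NA_real_)
  k <- neutrality_constants(n)
  dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  dmax <- ((n + 1) / (2 * n) - 1 / k$a1) / sqrt(k$e2)
  m <- -dmin / (dmax - dmin)            # mean of the unit-scaled variable
  v <- 1 / (dmax - dmin)^2              # its variance
  shape_sum <- m * (1 - m) / v - 1
  alpha <- m * shape_sum
  beta <- (1 - m) * shape_sum
  x <- (D - dmin) / (dmax - dmin)
  x <- min(max(x, 0), 1)
  2 * min(pbeta(x, alpha, beta), 1 - pbeta(x, alpha, beta))
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Contrast the number of singleton mutations (external-branch excess)
#' with the total number of segregating sites (D*) or the mean pairwise
#' difference (F*), using the corrected starred-test coefficients.
#'
#' @param S Number of segregating sites.
#' @param eta_s Number of singleton mutations (minor allele in exactly one
#'   sequence).
#' @param pi Per-site nucleotide diversity.
#' @param n Number of sequences.
#' @param L Net length in bp.
#' @return Named numeric vector `c(Dstar =, Fstar =)` (`NaN` when
#'   `S = 0`).
#' @export
fu_li_star <- function(S, eta_s, pi, n, L) {
  if (S == 0) return(c(Dstar = NaN, Fstar = NaN))
  k <- neutrality_constants(n)
  dstar <- ((n / (n - 1)) * S - k$a1 * eta_s) /
    sqrt(k$u_Dstar * S + k$v_Dstar * S^2)
  fstar <- (pi * L - ((n - 1) / n) * eta_s) /
    sqrt(k$u_Fstar * S + k$v_Fstar * S^2)
  c(Dstar = dstar, Fstar = fstar)
}

# star labels from a two-sided p-value
signif_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

# normal-approximation two-sided p for the starred statistics (documented
# approximation; the exact percentage points are tabulated, not closed-form)
star_test_pvalue <- function(stat) {
  if (is.na(stat)) return(NA_real_)
  2 * pnorm(-abs(stat))
}

#' Per-region diversity and neutrality summary
#'
#' Computes, for every annotated region, for the entire locus and for any
#' requested region unions (e.g. all exons pooled), the net gap-excluded
#' length, segregating-site and singleton counts, pi, Watterson's theta,
#' Tajima's D and Fu and Li's D*/F* with significance flags. Gap handling
#' is complete deletion of indel columns: `L_net = L_gross - indel sites`.
#' The indel bookkeeping (events, sites, mean length) is included so the
#' output mirrors the usual per-region polymorphism table.
#'
#' @param panel An [aligned_panel].
#' @param model A [gene_model].
#' @param vt Optional variant table (computed when missing).
#' @param unions Named list of region-name character vectors to pool; the
#'   default pools all regions of kind `exon` as `"exons"`.
#' @return A tibble with one row per region, union and `entire`:
#'   `region`, `L_gross`, `L_net`, `n_variants`, `n_snps`,
#'   `n_indel_events`, `n_indel_sites`, `mean_indel_length`, `S`,
#'   `eta_s`, `pi`, `theta_w`, `tajima_D`, `tajima_p`, `tajima_sig`,
#'   `fu_li_Dstar`, `Dstar_sig`, `fu_li_Fstar`, `Fstar_sig`.
#' @export
summarize_regions <- function(panel, model, vt = NULL, unions = NULL) {
  if (is.null(vt)) vt <- call_variants(panel, model)
  if (is.null(unions)) {
    ex <- model$regions$name[model$regions$kind == "exon"]
    unions <- if (length(ex) > 1L) list(exons = ex) else list()
  }
  n <- n_samples(panel)
  scopes <- c(
    setNames(as.list(model$regions$name), model$regions$name),
    unions,
    list(entire = model$regions$name)
  )
  rows <- purrr::imap(scopes, function(region_names, label) {
    cols <- region_columns(model, region_names)
    scope_stats(panel, vt, cols, label, n)
  })
  out <- dplyr::bind_rows(rows)
  inform(sprintf(
    "Diversity summary over %d scopes (n = %d): entire S = %d, pi = %.5f.",
    nrow(out), n, out$S[out$region == "entire"],
    out$pi[out$region == "entire"]
  ))
  out
}

scope_stats <- function(panel, vt, cols, label, n) {
  indels <- vt[vt$kind == "indel", , drop = FALSE]
  indel_here <- indels[indels$position %in% cols, , drop = FALSE]
  indel_cols <- unlist(purrr::map2(
    indel_here$position, indel_here$span,
    function(p, s) seq.int(p, p + s - 1L)
  ), use.names = FALSE)
  net_cols <- setdiff(cols, indel_cols)
  snps <- vt[vt$kind == "snp" & vt$position %in% cols, , drop = FALSE]
  S <- nrow(snps)
  eta_s <- sum(snps$class == "singleton")
  pi <- if (length(net_cols)) pairwise_pi(panel, net_cols) else NaN
  L_net <- length(net_cols)
  D <- if (S > 0) tajimas_d(pi, S, n, L_net) else NaN
  Dp <- tajimas_d_pvalue(D, n)
  fl <- fu_li_star(S, eta_s, pi, n, L_net)
  n_events <- nrow(indel_here)
  n_sites <- sum(indel_here$span)
  tibble::tibble(
    region = label,
    L_gross = length(cols), L_net = L_net,
    n_variants = S + n_events, n_snps = S,
    n_indel_events = n_events, n_indel_sites = n_sites,
    mean_indel_length = if (n_events > 0L) n_sites / n_events else NaN,
    S = S, eta_s = eta_s,
    pi = if (S == 0 && L_net > 0) 0 else pi,
    theta_w = if (L_net > 0) watterson_theta(S, n, L_net) else NaN,
    tajima_D = D, tajima_p = Dp, tajima_sig = signif_stars(Dp),
    fu_li_Dstar = fl[["Dstar"]],
    Dstar_sig = signif_stars(star_test_pvalue(fl[["Dstar"]])),
    fu_li_Fstar = fl[["Fstar"]],
    Fstar_sig = signif_stars(star_test_pvalue(fl[["Fstar"]]))
  )
}

#' Wide polymorphism-parameter table
#'
#' Reshapes a [summarize_regions()] result into the conventional layout
#' with regions as columns and parameters as rows (`NAN` printed for
#' undefined entries), ready for TSV export.
#'
#' @param ds A tibble from [summarize_regions()].
#' @return A tibble with a `parameter` column and one column per region.
#' @export
diversity_table <- function(ds) {
  params <- c(
    "Total length (bp)" = "L_gross",
    "Number of all sequence variants" = "n_variants",
    "Number of nucleotide substitutions" = "n_snps",
    "Number of indels" = "n_indel_events",
    "Number of indel sites" = "n_indel_sites",
    "Average indel length" = "mean_indel_length",
    "pi" = "pi", "theta_w" = "theta_w"
  )
  num <- purrr::imap(params, function(col, lab) {
    vals <- ds[[col]]
    tibble::tibble(parameter = lab,
                   !!!setNames(as.list(format_nan(vals)), ds$region))
  })
  stars <- list(
    tibble::tibble(parameter = "Tajima's D",
                   !!!setNames(as.list(paste0(format_nan(ds$tajima_D),
                                              ds$tajima_sig)), ds$region)),
    tibble::tibble(parameter = "Fu and Li's D*",
                   !!!setNames(as.list(paste0(format_nan(ds$fu_li_Dstar),
                                              ds$Dstar_sig)), ds$region)),
    tibble::tibble(parameter = "Fu and Li's F*",
                   !!!setNames(as.list(paste0(format_nan(ds$fu_li_Fstar),
                                              ds$Fstar_sig)), ds$region))
  )
  dplyr::bind_rows(num, stars)
}

format_nan <- function(x) {
  out <- ifelse(is.na(x), "NAN",
                ifelse(x == round(x), format(x, trim = TRUE),
                       format(round(x, 5), trim = TRUE)))
  sub("NaN", "NAN", out, fixed = TRUE)
}
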