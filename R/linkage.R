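#' Pairwise linkage disequilibrium between SNP sites
#'
#' Computes r-squared and a two-sided Fisher exact p-value for every
#' unordered pair of biallelic SNPs, treating inbred lines as haploid
#' haplotypes. For each pair only samples called at both sites are used;
#' pairs monomorphic in that shared subset are skipped with a log entry.
#' Multi-allelic variants and indel events are excluded.
#'
#' @param vt A variant table; only rows with `kind == "snp"` and two
#'   alleles enter the matrix.
#' @param panel Unused hook for future missing-data policies (the
#'   genotypes in `vt` are authoritative).
#' @return An `ld_pairs` tibble: `id1`, `id2`, `pos1`, `pos2`,
#'   `distance`, `r2`, `p`.
#' @export
ld_matrix <- function(vt, panel = NULL) {
  snps <- vt[vt$kind == "snp" & vt$n_alleles == 2L, , drop = FALSE]
  dropped <- sum(vt$kind == "snp") - nrow(snps)
  if (dropped > 0L) {
    inform(sprintf("Excluding %d non-biallelic SNP(s) from LD.", dropped))
  }
  snps <- dplyr::arrange(snps, .data$position)
  m <- nrow(snps)
  if (m < 2L) {
    return(structure(
      tibble::tibble(id1 = character(), id2 = character(), pos1 = integer(),
                     pos2 = integer(), distance = integer(), r2 = double(),
                     p = double()),
      class = c("ld_pairs", "tbl_df", "tbl", "data.frame")
    ))
  }
  genos <- purrr::map(seq_len(m), function(i) {
    g <- snps$geno[[i]]
    g == snps$alleles[[i]]$allele[1L]   # TRUE = major allele, NA = missing
  })
  pairs <- combn(m, 2L)
  skipped <- 0L
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    a <- genos[[i]]; b <- genos[[j]]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
    nn <- sum(tab)
    pA <- sum(tab[1L, ]) / nn
    pB <- sum(tab[, 1L]) / nn
    D <- tab[1L, 1L] / nn - pA * pB
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    tibble::tibble(
      id1 = snps$variant_id[i], id2 = snps$variant_id[j],
      pos1 = snps$position[i], pos2 = snps$position[j],
      distance = abs(snps$position[j] - snps$position[i]),
      r2 = r2, p = fisher.test(tab)$p.value
    )
  })
  if (skipped > 0L) {
    inform(sprintf("Skipped %d pair(s) monomorphic in the shared subset.",
                   skipped))
  }
  structure(dplyr::bind_rows(rows),
            class = c("ld_pairs", "tbl_df", "tbl", "data.frame"))
}

# Hill-Weir drift-recombination expectation of r2 at C = rho * d, adjusted
# for sample size n
remington_expectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit LD-decay regressions across five model families
#'
#' Least-squares fits of r-squared against inter-site distance `d` for the
#' linear (`a + b d`), loglinear (`a + b ln d`), exponential
#' (`a e^(b d)`), power (`a d^b`) and Remington (Hill-Weir
#' drift-recombination expectation with fitted recombination scale
#' `C = rho d`) families. The coefficient of determination is computed on
#' the original r-squared scale for every family, and the family with the
#' highest R-squared among converged fits is selected. For each family the
#' distance at which the fitted curve predicts `r2 = r2_target` is solved
#' (smallest positive root; `NA` when unreachable).
#'
#' @param ld An `ld_pairs` tibble from [ld_matrix()].
#' @param n Sample size used in the Remington expectation.
#' @param r2_target Decay threshold, default 0.1.
#' @return An `ld_decay_fit` object: list with `models` (tibble of family,
#'   parameter list, `r_squared`, `distance_at_target`, `converged`),
#'   `selected`, `r2_target`, `n` and the fitting `data`.
#' @export
fit_ld_decay <- function(ld, n, r2_target = 0.1) {
  d <- ld$distance
  y <- ld$r2
  if (length(d) < 3L) abort("LD-decay fitting needs at least 3 pairs.")
  sst <- sum((y - mean(y))^2)
  r2_of <- function(pred) 1 - sum((y - pred)^2) / sst

  fits <- list()
  lin <- lm(y ~ d)
  a <- coef(lin)[[1L]]; b <- coef(lin)[[2L]]
  fits$linear <- list(
    params = c(a = a, b = b), r_squared = r2_of(predict(lin)),
    converged = TRUE,
    dist = if (b < 0 && a > r2_target) (a - r2_target) / -b else NA_real_
  )
  ll <- lm(y ~ log(d))
  a <- coef(ll)[[1L]]; b <- coef(ll)[[2L]]
  fits$loglinear <- list(
    params = c(a = a, b = b), r_squared = r2_of(predict(ll)),
    converged = TRUE,
    dist = if (b < 0) exp((r2_target - a) / b) else NA_real_
  )
  eps <- 1e-6
  start_exp <- lm(log(pmax(y, eps)) ~ d)
  fits$exponential <- nls_family(
    y ~ a * exp(b * d), d, y,
    start = list(a = exp(coef(start_exp)[[1L]]), b = coef(start_exp)[[2L]]),
    dist_fun = function(p) {
      if (p[["b"]] < 0 && p[["a"]] > r2_target) {
        log(r2_target / p[["a"]]) / p[["b"]]
      } else NA_real_
    }, r2_of = r2_of
  )
  start_pow <- lm(log(pmax(y, eps)) ~ log(d))
  fits$power <- nls_family(
    y ~ a * d^b, d, y,
    start = list(a = exp(coef(start_pow)[[1L]]), b = coef(start_pow)[[2L]]),
    dist_fun = function(p) {
      if (p[["b"]] < 0) (r2_target / p[["a"]])^(1 / p[["b"]]) else NA_real_
    }, r2_of = r2_of
  )
  # Remington family: log-spaced grid over the per-bp recombination scale
  # seeds the nonlinear fit
  grid <- 10^seq(-5, -1, length.out = 25)
  sse <- vapply(grid, function(rho) {
    sum((y - remington_expectation(rho * d, n))^2)
  }, numeric(1L))
  fits$remington <- nls_family(
    y ~ remington_expectation(rho * d, n), d, y,
    start = list(rho = grid[which.min(sse)]),
    dist_fun = function(p) {
      f <- function(x) remington_expectation(p[["rho"]] * x, n) - r2_target
      if (f(1) <= 0) return(NA_real_)
      hi <- 10
      while (f(hi) > 0 && hi < 1e9) hi <- hi * 10
      if (f(hi) > 0) return(NA_real_)
      uniroot(f, c(1, hi))$root
    }, r2_of = r2_of
  )

  models <- tibble::tibble(
    model = names(fits),
    params = unname(purrr::map(fits, "params")),
    r_squared = unname(purrr::map_dbl(fits, "r_squared")),
    distance_at_target = unname(purrr::map_dbl(fits, "dist")),
    converged = unname(purrr::map_lgl(fits, "converged"))
  )
  ok <- models$converged
  selected <- models$model[ok][which.max(models$r_squared[ok])]
  structure(
    list(models = models, selected = selected, r2_target = r2_target,
         n = n, data = tibble::tibble(distance = d, r2 = y)),
    class = "ld_decay_fit"
  )
}

nls_family <- function(formula, d, y, start, dist_fun, r2_of) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data.frame(d = d, y = y),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(params = unlist(start), r_squared = NA_real_,
                converged = FALSE, dist = NA_real_))
  }
  p <- coef(fit)
  list(params = p, r_squared = r2_of(predict(fit)), converged = TRUE,
       dist = dist_fun(p))
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("<ld_decay_fit> %d pairs, selected model: %s\n",
              nrow(x$data), x$selected))
  sel <- x$models[x$models$model == x$selected, ]
  cat(sprintf("  R-squared %.4f; distance at r2 = %g: %s bp\n",
              sel$r_squared, x$r2_target,
              format(round(sel$distance_at_target))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an LD-decay fit
#'
#' One row per fitted parameter per model family.
#'
#' @param x An `ld_decay_fit`.
#' @param ... Unused.
#' @return A tibble `model`, `term`, `estimate`.
#' @export
tidy.ld_decay_fit <- function(x, ...) {
  dplyr::bind_rows(purrr::map2(
    x$models$model, x$models$params,
    function(m, p) tibble::tibble(model = m, term = names(p),
                                  estimate = unname(p))
  ))
}

#' @rdname tidy.ld_decay_fit
#' @return `glance()`: a one-row tibble with the selected model, its
#'   R-squared and distance at the decay target.
#' @export
glance.ld_decay_fit <- function(x, ...) {
  sel <- x$models[x$models$model == x$selected, ]
  tibble::tibble(
    selected = x$selected, r_squared = sel$r_squared,
    distance_at_target = sel$distance_at_target,
    r2_target = x$r2_target, n_pairs = nrow(x$data), n = x$n
  )
}

#' Hudson-Kaplan minimum number of recombination events
#'
#' Applies the four-gamete test to every pair of biallelic SNPs and
#' reduces the incompatible intervals to the minimal set of disjoint
#' intervals: intervals containing a smaller incompatible interval are
#' discarded, then disjoint intervals are counted greedily left to right.
#' `Rm` is the number of retained intervals; each must contain at least
#' one crossover (or recurrent mutation).
#'
#' @param vt A variant table (biallelic SNPs are used).
#' @param panel Unused hook (genotypes in `vt` are authoritative).
#' @return An `rm_report`: list with `rm` and `intervals`
#'   (tibble `left`, `right` in alignment coordinates).
#' @export
hudson_kaplan_rm <- function(vt, panel = NULL) {
  snps <- vt[vt$kind == "snp" & vt$n_alleles == 2L, , drop = FALSE]
  snps <- dplyr::arrange(snps, .data$position)
  m <- nrow(snps)
  incompat <- list()
  if (m >= 2L) {
    genos <- purrr::map(seq_len(m), function(i) {
      g <- snps$geno[[i]]
      g == snps$alleles[[i]]$allele[1L]
    })
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        a <- genos[[i]]; b <- genos[[j]]
        ok <- !is.na(a) & !is.na(b)
        gam <- unique(paste(a[ok], b[ok]))
        if (length(gam) == 4L) {
          incompat[[length(incompat) + 1L]] <-
            c(snps$position[i], snps$position[j])
        }
      }
    }
  }
  intervals <- reduce_intervals(incompat)
  structure(list(rm = nrow(intervals), intervals = intervals),
            class = "rm_report")
}

# Hudson-Kaplan reduction: drop intervals containing another incompatible
# interval, then greedily pick disjoint intervals by right endpoint
reduce_intervals <- function(incompat) {
  if (!length(incompat)) {
    return(tibble::tibble(left = integer(), right = integer()))
  }
  iv <- unique(do.call(rbind, incompat))
  keep <- vapply(seq_len(nrow(iv)), function(k) {
    !any(iv[, 1L] >= iv[k, 1L] & iv[, 2L] <= iv[k, 2L] &
           (iv[, 1L] > iv[k, 1L] | iv[, 2L] < iv[k, 2L]))
  }, logical(1L))
  iv <- iv[keep, , drop = FALSE]
  iv <- iv[order(iv[, 2L], iv[, 1L]), , drop = FALSE]
  chosen <- list()
  last_right <- -Inf
  for (k in seq_len(nrow(iv))) {
    if (iv[k, 1L] >= last_right) {   # open intervals: touching is disjoint
      chosen[[length(chosen) + 1L]] <- iv[k, ]
      last_right <- iv[k, 2L]
    }
  }
  res <- do.call(rbind, chosen)
  tibble::tibble(left = as.integer(res[, 1L]), right = as.integer(res[, 2L]))
}

#' @export
print.rm_report <- function(x, ...) {
  cat(sprintf("<rm_report> Rm = %d\n", x$rm))
  if (x$rm > 0L) {
    cat(paste(sprintf("  interval %d-%d bp", x$intervals$left,
                      x$intervals$right), collapse = "\n"), "\n")
  }
  invisible(x)
}
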