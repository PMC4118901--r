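# Independent oracles and small fixture builders. Every oracle here is a
# deliberately naive re-implementation kept separate from the package code
# paths it checks.

make_panel <- function(seqs, ids = NULL, reference = NULL,
                       reference_id = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_along(seqs))
  aligned_panel(seqs, ids, reference = reference,
                reference_id = reference_id)
}

random_panel <- function(n, L, seed, miss_prob = 0) {
  withr::with_seed(seed, {
    mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE),
                  nrow = n)
    if (miss_prob > 0) {
      mat[runif(n * L) < miss_prob] <- "N"
    }
    rownames(mat) <- sprintf("s%02d", seq_len(n))
    aligned_panel(mat)
  })
}

# brute-force pi: explicit double loop over sample pairs, counting
# differences over shared called sites, divided by C(n,2) * L
oracle_pi <- function(panel, columns = NULL) {
  mat <- panel$mat
  columns <- columns %||% seq_len(ncol(mat))
  n <- nrow(mat)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- mat[i, columns]
      b <- mat[j, columns]
      ok <- a != "N" & b != "N" & a != "-" & b != "-"
      total <- total + sum(a[ok] != b[ok])
    }
  }
  (total / choose(n, 2)) / length(columns)
}

# frequency-count r2 oracle from explicit haplotype tallies
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  aa <- sort(unique(a)); bb <- sort(unique(b))
  pA <- mean(a == aa[1L])
  pB <- mean(b == bb[1L])
  pAB <- mean(a == aa[1L] & b == bb[1L])
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# exhaustive minimum number of recombination points hitting all
# incompatible (four-gamete) intervals: tries all subsets of candidate
# breakpoints (midpoints between adjacent SNPs)
oracle_rm <- function(geno_mat, positions) {
  m <- ncol(geno_mat)
  incomp <- list()
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        gam <- unique(paste(geno_mat[, i], geno_mat[, j]))
        if (length(gam) == 4L) {
          incomp[[length(incomp) + 1L]] <- c(positions[i], positions[j])
        }
      }
    }
  }
  if (!length(incomp)) return(0L)
  cand <- (positions[-1L] + positions[-length(positions)]) / 2
  for (k in seq_along(cand)) {
    combos <- combn(cand, k)
    for (c_i in seq_len(ncol(combos))) {
      pts <- combos[, c_i]
      hit <- vapply(incomp, function(iv) {
        any(pts > iv[1L] & pts < iv[2L])
      }, logical(1L))
      if (all(hit)) return(k)
    }
  }
  length(incomp)
}

# independent closed-form neutrality statistics (coded from the published
# formulas, separately from the package implementation)
oracle_neutrality <- function(panel) {
  mat <- panel$mat
  n <- nrow(mat)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  seg <- which(vapply(seq_len(ncol(mat)),
                      function(j) length(unique(mat[, j])) > 1L,
                      logical(1L)))
  S <- length(seg)
  k_hat <- 0
  for (p in seq_len(n - 1L)) {
    for (q2 in (p + 1L):n) k_hat <- k_hat + sum(mat[p, ] != mat[q2, ])
  }
  k_hat <- k_hat / choose(n, 2)
  eta_s <- sum(vapply(seg, function(j) {
    tab <- table(mat[, j])
    sum(tab) - max(tab) == 1L
  }, logical(1L)))
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  an1 <- a1 + 1 / n
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
           2 * (n * a1 * (a1 + 1)) / (n - 1)^2) / (a1^2 + a2)
  uD <- (n / (n - 1)) * (a1 - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * S - a1 * eta_s) / sqrt(uD * S + vD * S^2)
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           (2 * (n - 1) * a1) / n^2 - 8 * a2 / n) / (a1^2 + a2)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / a1 - vF
  Fstar <- (k_hat - ((n - 1) / n) * eta_s) / sqrt(uF * S + vF * S^2)
  list(S = S, eta_s = eta_s, k_hat = k_hat, D = D, Dstar = Dstar,
       Fstar = Fstar)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
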