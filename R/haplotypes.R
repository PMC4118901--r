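#' Collapse aligned sequences into haplotypes
#'
#' Groups identical sequences over a column set (gaps significant) into
#' haplotypes, numbered by descending member count with ties broken by the
#' first-occurring sample. Missing bases (`N`) make a sequence
#' non-identical only at called positions: a sample whose `N` pattern is
#' the sole difference joins the otherwise-identical haplotype (ties go to
#' the larger haplotype); a sample matching no complete sequence forms its
#' own haplotype.
#'
#' @param panel An [aligned_panel].
#' @param columns Columns defining the haplotype (default: all).
#' @param scope Label stored on the result: `"full_length"` or `"cds"`.
#'   Passing `scope = "cds"` with a `model` sets `columns` to the CDS.
#' @param model Optional [gene_model], needed for `scope = "cds"` when
#'   `columns` is missing.
#' @return A `haplotype_table`: tibble with `haplotype`, `count`,
#'   `members` (list of sample ids) and `sequence` (representative), with
#'   attributes `n`, `Hd` and `scope`.
#' @export
collapse_haplotypes <- function(panel, columns = NULL,
                                scope = c("full_length", "cds"),
                                model = NULL) {
  scope <- match.arg(scope)
  if (is.null(columns)) {
    columns <- if (scope == "cds") {
      if (is.null(model)) abort("`model` is needed for scope = \"cds\".")
      cds_columns(model)
    } else {
      seq_len(alignment_length(panel))
    }
  }
  sub <- panel$mat[, columns, drop = FALSE]
  keys <- apply(sub, 1L, paste, collapse = "")
  ids <- panel$sample_ids
  has_n <- grepl("N", keys, fixed = TRUE)

  complete <- split(seq_along(keys)[!has_n], keys[!has_n])
  groups <- purrr::map(complete, identity)
  # attach N-bearing samples to their closest complete match
  for (i in which(has_n)) {
    chars <- sub[i, ]
    called <- chars != "N"
    match_grp <- NA_integer_
    best_size <- -1L
    for (g in seq_along(groups)) {
      rep_chars <- sub[groups[[g]][1L], ]
      if (all(chars[called] == rep_chars[called])) {
        if (length(groups[[g]]) > best_size) {
          match_grp <- g
          best_size <- length(groups[[g]])
        }
      }
    }
    if (is.na(match_grp)) {
      groups <- c(groups, list(i))
    } else {
      groups[[match_grp]] <- c(groups[[match_grp]], i)
    }
  }
  counts <- unname(lengths(groups))
  first <- unname(purrr::map_int(groups, min))
  ord <- order(-counts, first)
  groups <- unname(groups[ord])
  tab <- tibble::tibble(
    haplotype = paste0("Hap_", seq_along(groups)),
    count = unname(lengths(groups)),
    members = purrr::map(groups, ~ ids[sort(.x)]),
    sequence = purrr::map_chr(groups, ~ paste(sub[.x[1L], ], collapse = ""))
  )
  n <- nrow(sub)
  structure(tab, n = n, scope = scope,
            Hd = haplotype_diversity(tab$count, n),
            class = c("haplotype_table", class(tab)))
}

#' Haplotype diversity (Nei's Hd)
#'
#' `Hd = (n/(n-1)) * (1 - sum p_i^2)`: the probability that two haplotypes
#' drawn without replacement differ.
#'
#' @param counts Haplotype member counts.
#' @param n Total sample count (default `sum(counts)`).
#' @return Hd in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  if (n < 2L) abort("Haplotype diversity needs n >= 2.")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Map full-length haplotypes onto CDS haplotypes
#'
#' The CDS partition must refine the full-length partition: every
#' full-length haplotype maps into exactly one CDS haplotype (a violation
#' is a hard error). The result is the conventional membership table with
#' one row per full-length haplotype.
#'
#' @param full,cds `haplotype_table`s from [collapse_haplotypes()].
#' @return A tibble `haplotype`, `count`, `cds_haplotype`, `members`.
#' @export
haplotype_mapping <- function(full, cds) {
  cds_of <- setNames(
    rep(cds$haplotype, lengths(cds$members)),
    unlist(cds$members)
  )
  mapped <- purrr::map_chr(full$members, function(m) {
    hit <- unique(unname(cds_of[m]))
    if (length(hit) != 1L) {
      abort(sprintf(
        "Full-length haplotype spans %d CDS haplotypes (%s); the CDS partition must refine the full-length one.",
        length(hit), paste(hit, collapse = ", ")
      ))
    }
    hit
  })
  tibble::tibble(haplotype = full$haplotype, count = full$count,
                 cds_haplotype = mapped, members = full$members)
}

#' Translate CDS haplotypes to protein haplotypes
#'
#' Gaps are removed per haplotype before translation with the standard
#' genetic code (minus-strand genes are reverse-complemented first); a
#' terminal stop is trimmed. Haplotypes whose gap-stripped length is not a
#' multiple of 3, or that contain an internal stop, are translated to the
#' first stop and flagged as frameshift. CDS haplotypes encoding the same
#' protein are grouped; per protein haplotype the amino-acid variants
#' (substitutions and residue deletions) are reported against the longest
#' (no-deletion) protein, whose residue coordinates anchor the domain
#' analysis.
#'
#' @param cds_haps A `haplotype_table` with `scope = "cds"`.
#' @param model The [gene_model] (for strand).
#' @return A tibble `protein`, `count`, `cds_haplotypes` (list),
#'   `aa_seq`, `frameshift`, `variants` (list of position/ref/alt/change
#'   tibbles; coordinates on the reference protein).
#' @export
translate_cds_haplotypes <- function(cds_haps, model = NULL) {
  minus <- !is.null(model) && model$strand == "-"
  aa <- purrr::map(cds_haps$sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    chars <- chars[chars != "-"]
    if (minus) chars <- rev_comp(chars)
    translate_chars(chars)
  })
  prot <- purrr::map_chr(aa, "protein")
  fshift <- purrr::map_lgl(aa, "frameshift")
  groups <- split(seq_len(nrow(cds_haps)), prot)
  first <- unname(purrr::map_int(groups, ~ min(.x)))
  sizes <- unname(purrr::map_int(groups, ~ sum(cds_haps$count[.x])))
  ord <- order(-sizes, first)
  aa_seqs <- names(groups)[ord]
  groups <- unname(groups[ord])
  out <- tibble::tibble(
    protein = paste0("Prot_", seq_along(groups)),
    count = sizes[ord],
    cds_haplotypes = purrr::map(groups, ~ cds_haps$haplotype[.x]),
    aa_seq = aa_seqs,
    frameshift = unname(purrr::map_lgl(groups, ~ any(fshift[.x])))
  )
  ref_seq <- out$aa_seq[which.max(nchar(out$aa_seq))]
  out$variants <- purrr::map(out$aa_seq, protein_variants, ref = ref_seq)
  out
}

translate_chars <- function(chars) {
  extra <- length(chars) %% 3L
  frameshift <- extra != 0L
  if (frameshift) chars <- chars[seq_len(length(chars) - extra)]
  codons <- paste0(chars[c(TRUE, FALSE, FALSE)], chars[c(FALSE, TRUE, FALSE)],
                   chars[c(FALSE, FALSE, TRUE)])
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  aas[is.na(aas)] <- "X"   # codons containing N
  stop_at <- which(aas == "*")
  if (length(stop_at)) {
    if (stop_at[1L] < length(aas)) frameshift <- TRUE
    aas <- aas[seq_len(stop_at[1L] - 1L)]
  }
  list(protein = paste(aas, collapse = ""), frameshift = frameshift)
}

# amino-acid differences vs the reference protein; in-frame deletions are
# located by greedy anchored comparison (equal-length tails after the gap)
protein_variants <- function(seq, ref) {
  if (seq == ref) {
    return(tibble::tibble(position = integer(), ref = character(),
                          alt = character(), change = character()))
  }
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  r <- strsplit(ref, "", fixed = TRUE)[[1L]]
  rows <- list()
  i <- 1L; j <- 1L
  while (j <= length(r)) {
    if (i <= length(s) && s[i] == r[j]) {
      i <- i + 1L; j <- j + 1L
    } else if (length(s) - i < length(r) - j) {
      # deletion in seq relative to ref at ref position j
      rows[[length(rows) + 1L]] <- tibble::tibble(
        position = j, ref = r[j], alt = "-", change = "deletion")
      j <- j + 1L
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        position = j, ref = r[j],
        alt = if (i <= length(s)) s[i] else "-", change = "substitution")
      i <- i + 1L; j <- j + 1L
    }
  }
  dplyr::bind_rows(rows)
}

#' Overlap of protein variants with annotated domains
#'
#' Flags, for every amino-acid variant of every protein haplotype, whether
#' it falls inside configured domain intervals (1-based closed residue
#' coordinates on the reference protein, e.g. the three Mito_carr spans of
#' a mitochondrial carrier protein).
#'
#' @param proteins Result of [translate_cds_haplotypes()].
#' @param domains A data frame with `name`, `start`, `end` (residue
#'   coordinates).
#' @return A tibble `protein`, `position`, `change`, `domain`, `overlap`.
#' @export
domain_overlap <- function(proteins, domains) {
  domains <- tibble::as_tibble(domains)
  vars <- tidyr::unnest(
    dplyr::select(proteins, "protein", "variants"), "variants"
  )
  if (nrow(vars) == 0L) {
    return(tibble::tibble(protein = character(), position = integer(),
                          change = character(), domain = character(),
                          overlap = logical()))
  }
  out <- tidyr::crossing(
    dplyr::select(vars, "protein", "position", "change"),
    dplyr::select(domains, domain = "name", "start", "end")
  )
  out$overlap <- out$position >= out$start & out$position <= out$end
  dplyr::select(out, "protein", "position", "change", "domain", "overlap")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> scope=%s, %d haplotypes, n=%d, Hd=%.4f\n",
              attr(x, "scope"), nrow(x), attr(x, "n"), attr(x, "Hd")))
  NextMethod()
}
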