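#' Call SNPs and indel events from an aligned panel
#'
#' Derives the variant table that bridges the alignment to every downstream
#' statistic. Columns containing any gap character belong to indel events
#' and are excluded from SNP calling; maximal contiguous runs of
#' gap-containing columns form one (possibly multi-allelic) indel event, so
#' nested deletions such as \{0, -3, -6\} over the same block are a single
#' tri-allelic event. `N` bases are missing data: they are excluded from
#' allele counts and never create a variant on their own.
#'
#' Each variant row records the observed allele strings with counts
#' (descending; ties broken toward the reference allele when a reference is
#' attached, else lexicographically -- the first allele is the major one)
#' and the per-sample allele assignment in the `geno` list-column.
#'
#' @param panel An [aligned_panel].
#' @param model Optional [gene_model]; when given, variants get region
#'   labels and coding-effect annotation, and site classes are filled in.
#' @return A tibble with one row per variant: `variant_id`, `kind`
#'   (`snp`/`indel`), `position` (first affected column), `span`, `region`,
#'   `class` (`singleton`/`parsimony_informative`), `coding_effect`,
#'   `n_alleles`, `alleles` (list of allele/count tibbles) and `geno`
#'   (list of named per-sample allele vectors).
#' @export
call_variants <- function(panel, model = NULL) {
  gapcol <- apply(panel$mat == "-", 2L, any)
  vt <- dplyr::bind_rows(
    call_snps(panel, gap_columns = which(gapcol)),
    call_indels(panel, gap_columns = which(gapcol))
  )
  if (nrow(vt) == 0L) return(vt)
  vt <- dplyr::arrange(vt, .data$position)
  vt$variant_id <- unsplit(
    lapply(split(seq_len(nrow(vt)), vt$kind), seq_along),
    vt$kind
  )
  vt$variant_id <- paste0(vt$kind, vt$variant_id)
  vt <- classify_sites(vt)
  if (!is.null(model)) {
    vt$region <- region_of(model, vt$position)
    vt <- annotate_coding_effect(vt, panel, model)
  }
  vt
}

#' @rdname call_variants
#' @param gap_columns Integer columns that belong to indel events
#'   (computed automatically by [call_variants()]).
#' @export
call_snps <- function(panel, model = NULL, gap_columns = NULL) {
  mat <- panel$mat
  if (is.null(gap_columns)) gap_columns <- which(apply(mat == "-", 2L, any))
  cols <- setdiff(seq_len(ncol(mat)), gap_columns)
  rows <- purrr::map(cols, function(j) {
    x <- mat[, j]
    x[x == "N"] <- NA_character_
    tab <- table(x, useNA = "no")
    if (length(tab) < 2L) return(NULL)
    alleles <- order_alleles(tab, ref = ref_base(panel, j))
    tibble::tibble(
      kind = "snp", position = j, span = 1L,
      n_alleles = nrow(alleles),
      alleles = list(alleles),
      geno = list(setNames(as.character(x), rownames(mat)))
    )
  })
  out <- dplyr::bind_rows(rows)
  finish_partial(out, panel, model)
}

#' @rdname call_variants
#' @export
call_indels <- function(panel, model = NULL, gap_columns = NULL) {
  mat <- panel$mat
  if (is.null(gap_columns)) gap_columns <- which(apply(mat == "-", 2L, any))
  if (!length(gap_columns)) {
    return(finish_partial(NULL, panel, model))
  }
  runs <- split(gap_columns, cumsum(c(1L, diff(gap_columns) != 1L)))
  rows <- purrr::map(runs, function(block) {
    sub <- mat[, block, drop = FALSE]
    pat <- apply(sub, 1L, paste, collapse = "")
    pat[grepl("N", pat, fixed = TRUE)] <- NA_character_
    tab <- table(pat, useNA = "no")
    ref_pat <- if (!is.null(panel$reference)) {
      paste(panel$reference[block], collapse = "")
    } else NULL
    alleles <- order_alleles(tab, ref = ref_pat)
    tibble::tibble(
      kind = "indel", position = block[1L], span = length(block),
      n_alleles = nrow(alleles),
      alleles = list(alleles),
      geno = list(setNames(as.character(pat), rownames(mat)))
    )
  })
  finish_partial(dplyr::bind_rows(rows), panel, model)
}

# order alleles by descending count; ties toward the reference allele when
# available, else lexicographic
order_alleles <- function(tab, ref = NULL) {
  al <- names(tab)
  cnt <- as.integer(tab)
  is_ref <- if (!is.null(ref)) al == ref else rep(FALSE, length(al))
  ord <- order(-cnt, -is_ref, al)
  tibble::tibble(allele = al[ord], count = cnt[ord])
}

ref_base <- function(panel, j) {
  if (is.null(panel$reference)) NULL else panel$reference[j]
}

# shared tail for the partial callers when used standalone
finish_partial <- function(out, panel, model) {
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble::tibble(
      variant_id = character(), kind = character(), position = integer(),
      span = integer(), region = character(), class = character(),
      coding_effect = character(), n_alleles = integer(),
      alleles = list(), geno = list()
    ))
  }
  out$variant_id <- paste0(out$kind, seq_len(nrow(out)))
  out$region <- if (!is.null(model)) region_of(model, out$position)
                else NA_character_
  out <- classify_sites(out)
  out$coding_effect <- NA_character_
  if (!is.null(model)) out <- annotate_coding_effect(out, panel, model)
  dplyr::select(out, "variant_id", "kind", "position", "span", "region",
                "class", "coding_effect", "n_alleles", "alleles", "geno")
}

#' Classify variants as singleton or parsimony-informative
#'
#' A variant is a singleton when exactly one sample carries a non-major
#' allele (over called, non-missing samples); otherwise it is
#' parsimony-informative.
#'
#' @param vt A variant tibble.
#' @return `vt` with the `class` column filled.
#' @export
classify_sites <- function(vt) {
  if (nrow(vt) == 0L) {
    vt$class <- character()
    return(vt)
  }
  vt$class <- purrr::map_chr(vt$alleles, function(a) {
    minor_carriers <- sum(a$count) - max(a$count)
    if (minor_carriers == 1L) "singleton" else "parsimony_informative"
  })
  vt
}

#' Annotate coding consequences of variants
#'
#' Coding SNPs are labelled synonymous/nonsynonymous by substituting the
#' minor allele into the majority-allele codon and translating with the
#' standard genetic code (minus-strand genes are reverse-complemented
#' first). Coding indel events are labelled in-frame when every allele's
#' length change is a multiple of 3, else frameshift. An internal stop
#' introduced by a substitution is flagged with a warning, not an error.
#'
#' @param vt A variant tibble.
#' @param panel The [aligned_panel] the variants were called from.
#' @param model A [gene_model] with a defined CDS.
#' @return `vt` with the `coding_effect` column filled: one of
#'   `noncoding`, `synonymous`, `nonsynonymous`, `inframe_del`,
#'   `inframe_ins`, `frameshift`.
#' @export
annotate_coding_effect <- function(vt, panel, model) {
  cds <- cds_columns(model)
  if (!length(cds) || nrow(vt) == 0L) {
    vt$coding_effect <- rep(NA_character_, nrow(vt))
    return(vt)
  }
  cds_seq <- majority_sequence(panel, cds)
  minus <- model$strand == "-"
  if (minus) cds_seq <- rev_comp(cds_seq)
  code <- Biostrings::GENETIC_CODE
  n_codons <- length(cds_seq) %/% 3L

  vt$coding_effect <- purrr::pmap_chr(
    list(vt$kind, vt$position, vt$span, vt$alleles, vt$variant_id),
    function(kind, position, span, alleles, id) {
      cols <- seq.int(position, position + span - 1L)
      if (!any(cols %in% cds)) return("noncoding")
      if (kind == "indel") {
        gmaj <- stringr::str_count(alleles$allele[1L], stringr::fixed("-"))
        delta <- stringr::str_count(alleles$allele[-1L], stringr::fixed("-")) - gmaj
        if (any(delta %% 3L != 0L)) return("frameshift")
        if (all(delta >= 0)) "inframe_del" else "inframe_ins"
      } else {
        idx <- match(position, cds)
        if (minus) idx <- length(cds) - idx + 1L
        codon_i <- (idx - 1L) %/% 3L + 1L
        offset <- (idx - 1L) %% 3L + 1L
        ref_codon <- cds_seq[(3L * codon_i - 2L):(3L * codon_i)]
        ref_aa <- code[[paste(ref_codon, collapse = "")]]
        minor <- setdiff(alleles$allele, alleles$allele[1L])
        changed <- FALSE
        for (b in minor) {
          alt_codon <- ref_codon
          alt_codon[offset] <- if (minus) rev_comp(b) else b
          alt_aa <- code[[paste(alt_codon, collapse = "")]]
          if (alt_aa == "*" && codon_i < n_codons) {
            warn(sprintf("Variant %s introduces an internal stop codon.", id))
          }
          if (alt_aa != ref_aa) changed <- TRUE
        }
        if (changed) "nonsynonymous" else "synonymous"
      }
    }
  )
  vt
}

# majority base (gaps and N excluded) per column; ties toward the reference
majority_sequence <- function(panel, columns) {
  vapply(columns, function(j) {
    x <- panel$mat[, j]
    x <- x[!x %in% c("N", "-")]
    if (!length(x)) return("N")
    tab <- table(x)
    order_alleles(tab, ref = ref_base(panel, j))$allele[1L]
  }, character(1L))
}

rev_comp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  rev(unname(comp[x]))
}

#' Sample ids covered by a variant table
#'
#' @param vt A variant tibble.
#' @return Character vector of sample ids.
#' @export
variant_samples <- function(vt) {
  if (nrow(vt) == 0L) return(character())
  names(vt$geno[[1L]])
}

#' Per-region variant bookkeeping
#'
#' Counts variants, SNPs, indel events and indel sites per annotated
#' region, with the mean indel length (sites / events, `NaN` when a region
#' has no indel event). An `entire` row sums over all regions.
#'
#' @param vt A variant tibble with filled `region`.
#' @param model A [gene_model].
#' @return A tibble with one row per region plus `entire`.
#' @export
summarize_variants <- function(vt, model) {
  per_region <- purrr::map(model$regions$name, function(rn) {
    sub <- vt[!is.na(vt$region) & vt$region == rn, , drop = FALSE]
    region_counts(sub, rn)
  })
  out <- dplyr::bind_rows(per_region, region_counts(vt, "entire"))
  out$length <- c(model$regions$end - model$regions$start + 1L,
                  sum(model$regions$end - model$regions$start + 1L))
  dplyr::select(out, "region", "length", dplyr::everything())
}

region_counts <- function(sub, label) {
  n_events <- sum(sub$kind == "indel")
  n_sites <- sum(sub$span[sub$kind == "indel"])
  tibble::tibble(
    region = label,
    n_variants = nrow(sub),
    n_snps = sum(sub$kind == "snp"),
    n_indel_events = n_events,
    n_indel_sites = n_sites,
    mean_indel_length = if (n_events > 0L) n_sites / n_events else NaN
  )
}
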