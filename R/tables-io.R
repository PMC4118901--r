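#' Read a phenotype table
#'
#' Reads a CSV with a `sample_id` column, an optional integer `replicate`
#' column, and one numeric column per trait (e.g. the RVA pasting traits
#' PV, TV, BD, FV, SB, PT, PTP and DSC gelatinization traits To, Tp, Tc,
#' dH). Non-numeric trait cells are a hard error with row/column context;
#' empty cells become `NA`. When a panel is supplied, rows whose id does
#' not resolve against it are logged and dropped.
#'
#' @param path CSV path with a header row.
#' @param panel Optional [aligned_panel] used to validate sample ids.
#' @return A tibble with `sample_id`, optional `replicate`, and trait
#'   columns.
#' @export
read_phenotypes <- function(path, panel = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"sample_id" %in% names(raw)) {
    abort(sprintf("'%s' must have a `sample_id` column.", path))
  }
  traits <- setdiff(names(raw), c("sample_id", "replicate"))
  for (tr in traits) {
    vals <- raw[[tr]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "" & is.na(num))
    if (length(bad)) {
      abort(sprintf("Non-numeric value '%s' in trait column '%s', row %d of '%s'.",
                    vals[bad[1L]], tr, bad[1L], path))
    }
    raw[[tr]] <- num
  }
  if ("replicate" %in% names(raw)) {
    raw$replicate <- as.integer(raw$replicate)
  }
  if (!is.null(panel)) {
    unknown <- setdiff(unique(raw$sample_id), panel$sample_ids)
    if (length(unknown)) {
      inform(sprintf("Dropping %d phenotype row(s) with ids not in the panel: %s",
                     sum(raw$sample_id %in% unknown),
                     paste(head(unknown, 5L), collapse = ", ")))
      raw <- raw[!raw$sample_id %in% unknown, , drop = FALSE]
    }
  }
  raw
}

#' Write a phenotype table
#'
#' @param phen Phenotype tibble from [read_phenotypes()] or
#'   [simulate_phenotypes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path) {
  readr::write_csv(phen, path, progress = FALSE)
  invisible(path)
}

#' Read a population-structure Q matrix
#'
#' Whitespace- or tab-separated file whose first column is the sample id
#' and remaining columns are admixture proportions (one per subpopulation,
#' or K-1 of them). Rows must sum to 1 within 1e-6 (K encoding) or to at
#' most 1 (K-1 encoding).
#'
#' @param path Path to the Q file (header row required).
#' @param panel Optional [aligned_panel] used to validate sample ids.
#' @return A tibble with `sample_id` and numeric Q columns.
#' @export
read_qmatrix <- function(path, panel = NULL) {
  q <- readr::read_table(path, col_types = readr::cols(), progress = FALSE)
  names(q)[1L] <- "sample_id"
  qcols <- setdiff(names(q), "sample_id")
  if (!length(qcols)) abort(sprintf("'%s' has no Q columns.", path))
  for (cc in qcols) {
    if (!is.numeric(q[[cc]])) {
      abort(sprintf("Q column '%s' in '%s' is not numeric.", cc, path))
    }
  }
  validate_qmatrix(q)
  if (!is.null(panel)) {
    unknown <- setdiff(unique(q$sample_id), panel$sample_ids)
    if (length(unknown)) {
      inform(sprintf("Dropping %d Q row(s) with ids not in the panel.",
                     length(unknown)))
      q <- q[!q$sample_id %in% unknown, , drop = FALSE]
    }
  }
  q
}

validate_qmatrix <- function(q) {
  qcols <- setdiff(names(q), "sample_id")
  vals <- as.matrix(q[qcols])
  if (any(vals < -1e-9 | vals > 1 + 1e-9)) {
    abort("Q entries must lie in [0, 1].")
  }
  sums <- rowSums(vals)
  if (any(sums > 1 + 1e-6)) {
    abort(sprintf("Q row %d sums to %.4f (> 1).",
                  which(sums > 1 + 1e-6)[1L], max(sums)))
  }
  invisible(q)
}

#' Write a Q matrix
#'
#' @param q Q tibble from [read_qmatrix()] or [simulate_q()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qmatrix <- function(q, path) {
  readr::write_tsv(q, path, progress = FALSE)
  invisible(path)
}

#' Write or read a variant table as TSV
#'
#' One row per variant with metadata columns followed by one genotype
#' column per sample; a write/read round trip is lossless. Allele counts
#' are serialized as `allele:count` pairs.
#'
#' @param vt A variant table from [call_variants()].
#' @param path TSV path.
#' @return `path` (write) or the reconstructed variant tibble (read).
#' @export
write_variant_table <- function(vt, path) {
  samples <- variant_samples(vt)
  meta <- dplyr::select(vt, -dplyr::any_of(c("alleles", "geno")))
  meta$alleles <- purrr::map_chr(vt$alleles, function(a) {
    paste(sprintf("%s:%d", a$allele, a$count), collapse = ",")
  })
  genos <- purrr::map(vt$geno, function(g) {
    out <- g[samples]
    out[is.na(out)] <- "."
    out
  })
  gm <- do.call(rbind, genos)
  colnames(gm) <- samples
  readr::write_tsv(dplyr::bind_cols(meta, tibble::as_tibble(gm)), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  meta_cols <- c("variant_id", "kind", "position", "span", "region",
                 "class", "coding_effect", "n_alleles", "alleles")
  samples <- setdiff(names(raw), meta_cols)
  alleles <- purrr::map(raw$alleles, function(s) {
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    tibble::tibble(allele = purrr::map_chr(parts, 1L),
                   count = as.integer(purrr::map_chr(parts, 2L)))
  })
  geno <- purrr::map(seq_len(nrow(raw)), function(i) {
    g <- as.character(raw[i, samples])
    g[g == "."] <- NA_character_
    setNames(g, samples)
  })
  tibble::tibble(
    variant_id = raw$variant_id,
    kind = raw$kind,
    position = as.integer(raw$position),
    span = as.integer(raw$span),
    region = raw$region,
    class = if ("class" %in% names(raw)) raw$class else NA_character_,
    coding_effect = if ("coding_effect" %in% names(raw)) raw$coding_effect
                    else NA_character_,
    n_alleles = as.integer(raw$n_alleles),
    alleles = alleles,
    geno = geno
  )
}

#' Export a variant table as a minimal VCF
#'
#' Writes a VCF 4.2 text file with `CHROM` set to the gene name, `POS` the
#' alignment column, symbolic `<DEL>`-style alleles for indel events (with
#' the event span in `INFO/SPAN`), and one haploid genotype column per
#' sample.
#'
#' @param vt A variant table.
#' @param path Output path.
#' @param gene CHROM label, default `"gene"`.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vt, path, gene = "gene") {
  samples <- variant_samples(vt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SPAN,Number=1,Type=Integer,Description=\"Alignment columns affected\">",
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"snp or indel\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  for (i in seq_len(nrow(vt))) {
    al <- vt$alleles[[i]]
    labels <- al$allele
    if (vt$kind[i] == "indel") {
      vcf_alleles <- ifelse(grepl("-", labels, fixed = TRUE),
                            sprintf("<DEL%d>", stringr::str_count(labels, "-")),
                            labels)
    } else {
      vcf_alleles <- labels
    }
    ref <- vcf_alleles[1L]
    alt <- paste(vcf_alleles[-1L], collapse = ",")
    g <- vt$geno[[i]][samples]
    gt <- as.character(match(g, labels) - 1L)
    gt[is.na(gt)] <- "."
    writeLines(paste(c(
      gene, vt$position[i], vt$variant_id[i], ref,
      if (nzchar(alt)) alt else ".", ".", "PASS",
      sprintf("SPAN=%d;KIND=%s", vt$span[i], vt$kind[i]), "GT", gt
    ), collapse = "\t"), con)
  }
  invisible(path)
}
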