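#' Aligned panel of inbred-line sequences
#'
#' An `aligned_panel` holds a gapped multiple sequence alignment of one gene
#' amplicon across a panel of inbred lines, stored as an N x L character
#' matrix over the alphabet `A, C, G, T, N, -`. Inbred lines are treated as
#' haploid haplotypes; `N` is missing data and `-` marks alignment gaps
#' (indel events). An optional reference row (e.g. the B73 allele used to
#' anchor the annotation) is kept alongside the panel but takes part in no
#' statistic unless it is explicitly listed among the samples.
#'
#' @param seqs Character vector of aligned sequences (equal lengths), or an
#'   N x L character matrix of single characters.
#' @param sample_ids Unique sample identifiers, one per sequence.
#' @param reference_id Optional name of the reference sequence.
#' @param reference Optional reference sequence (same alignment length),
#'   kept as annotation only.
#'
#' @return An object of class `aligned_panel` with fields `mat` (N x L
#'   character matrix, rownames = sample ids), `sample_ids`, `reference_id`
#'   and `reference` (character vector of length L, or `NULL`).
#' @export
aligned_panel <- function(seqs, sample_ids = NULL, reference_id = NULL,
                          reference = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    sample_ids <- sample_ids %||% rownames(mat)
  } else {
    seqs <- toupper(as.character(seqs))
    sample_ids <- sample_ids %||% names(seqs)
    if (is.null(sample_ids)) {
      abort("`sample_ids` must be supplied when `seqs` has no names.")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- sample_ids[lens != lens[1L]][1L]
      abort(sprintf(
        "Alignment is ragged: record '%s' has length %d, expected %d.",
        bad, nchar(seqs[sample_ids == bad][1L]), lens[1L]
      ))
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (nrow(mat) < 2L) abort("An aligned panel needs at least 2 samples.")
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("Duplicated sample id: '%s'.",
                  sample_ids[duplicated(sample_ids)][1L]))
  }
  if (length(sample_ids) != nrow(mat)) {
    abort("`sample_ids` length does not match the number of sequences.")
  }
  mat <- toupper(mat)
  bad <- setdiff(unique(as.vector(mat)), .panel_alphabet)
  if (length(bad)) {
    abort(sprintf("Alignment contains characters outside {A,C,G,T,N,-}: %s",
                  paste(bad, collapse = ", ")))
  }
  rownames(mat) <- sample_ids
  if (!is.null(reference)) {
    reference <- toupper(unlist(strsplit(paste(reference, collapse = ""), "",
                                         fixed = TRUE)))
    if (length(reference) != ncol(mat)) {
      abort("Reference length does not match the alignment length.")
    }
  }
  structure(
    list(mat = mat, sample_ids = sample_ids,
         reference_id = reference_id, reference = reference),
    class = "aligned_panel"
  )
}

#' @export
print.aligned_panel <- function(x, ...) {
  cat(sprintf("<aligned_panel> %d samples x %d alignment columns\n",
              nrow(x$mat), ncol(x$mat)))
  if (!is.null(x$reference_id)) {
    cat(sprintf("  reference: %s (annotation only)\n", x$reference_id))
  }
  invisible(x)
}

#' @export
dim.aligned_panel <- function(x) dim(x$mat)

#' Number of samples and alignment length
#'
#' @param panel An [aligned_panel].
#' @return Integer count.
#' @export
n_samples <- function(panel) nrow(panel$mat)

#' @rdname n_samples
#' @export
alignment_length <- function(panel) ncol(panel$mat)

#' Read a gapped FASTA alignment
#'
#' Reads a pre-aligned FASTA file into an [aligned_panel]. Sequences are
#' uppercased; ragged record lengths are a hard error naming the offending
#' record. When `reference_id` names one of the records, that record is
#' removed from the sample set and kept as an annotation-only reference
#' (set `reference_as_sample = TRUE` to keep it in both roles).
#'
#' @param path Path to a FASTA file with at least two records.
#' @param reference_id Optional record name to treat as the reference.
#' @param reference_as_sample Keep the reference row as an ordinary sample
#'   as well? Default `FALSE`.
#' @return An [aligned_panel].
#' @export
read_alignment <- function(path, reference_id = NULL,
                           reference_as_sample = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("FASTA file '%s' is empty.", path))
  seqs <- toupper(as.character(set))
  ids <- names(set)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    ref_len <- as.numeric(names(sort(table(lens), decreasing = TRUE))[1L])
    bad <- ids[lens != ref_len][1L]
    abort(sprintf(
      "Alignment in '%s' is ragged: record '%s' has length %d, modal length is %d.",
      path, bad, lens[ids == bad][1L], ref_len
    ))
  }
  reference <- NULL
  if (!is.null(reference_id)) {
    if (!reference_id %in% ids) {
      abort(sprintf("Reference record '%s' not found in '%s'.",
                    reference_id, path))
    }
    reference <- seqs[[reference_id]]
    if (!reference_as_sample) {
      keep <- ids != reference_id
      seqs <- seqs[keep]
      ids <- ids[keep]
    }
  }
  if (length(seqs) < 2L) {
    abort(sprintf("FASTA file '%s' holds fewer than 2 sample records.", path))
  }
  panel <- aligned_panel(seqs, ids, reference_id = reference_id,
                         reference = reference)
  inform(sprintf("Read alignment '%s': %d samples x %d columns.",
                 basename(path), n_samples(panel), alignment_length(panel)))
  panel
}

#' Write an aligned panel to FASTA
#'
#' The reference row, when present, is written first under its own id so a
#' write/read round trip restores the panel exactly.
#'
#' @param panel An [aligned_panel].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(panel, path) {
  seqs <- apply(panel$mat, 1L, paste, collapse = "")
  if (!is.null(panel$reference) && !panel$reference_id %in% panel$sample_ids) {
    seqs <- c(setNames(paste(panel$reference, collapse = ""),
                       panel$reference_id), seqs)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}
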