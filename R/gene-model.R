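#' Gene-structure annotation
#'
#' A `gene_model` carries the ordered, non-overlapping named regions of the
#' amplicon (promoter, exons, introns, UTRs) in 1-based inclusive alignment
#' coordinates, plus the ordered list of exons whose concatenation forms the
#' CDS. The annotation is authoritative for every per-region statistic; the
#' package never assumes a particular amplicon length.
#'
#' @param regions A data frame with columns `name`, `kind` (one of
#'   `promoter`, `exon`, `intron`, `utr5`, `utr3`), `start`, `end`
#'   (1-based inclusive alignment columns).
#' @param cds_regions Character vector of region names (exons, in order)
#'   forming the CDS; concatenated length must be divisible by 3.
#' @param strand `"+"` or `"-"`.
#' @param gene Optional gene name.
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(regions, cds_regions = character(), strand = "+",
                       gene = NULL) {
  regions <- tibble::as_tibble(regions)
  need <- c("name", "kind", "start", "end")
  if (!all(need %in% names(regions))) {
    abort("`regions` needs columns name, kind, start, end.")
  }
  kinds <- c("promoter", "exon", "intron", "utr5", "utr3")
  if (!all(regions$kind %in% kinds)) {
    abort(sprintf("Unknown region kind(s): %s",
                  paste(setdiff(regions$kind, kinds), collapse = ", ")))
  }
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (any(regions$end < regions$start)) {
    bad <- regions$name[regions$end < regions$start][1L]
    abort(sprintf("Region '%s' has end < start.", bad))
  }
  if (any(regions$start < 1L)) abort("Region coordinates must be >= 1.")
  if (anyDuplicated(regions$name)) abort("Region names must be unique.")
  regions <- dplyr::arrange(regions, .data$start)
  if (nrow(regions) > 1L &&
      any(regions$start[-1L] <= regions$end[-nrow(regions)])) {
    i <- which(regions$start[-1L] <= regions$end[-nrow(regions)])[1L]
    abort(sprintf("Regions '%s' and '%s' overlap.",
                  regions$name[i], regions$name[i + 1L]))
  }
  if (!all(cds_regions %in% regions$name)) {
    abort("Every CDS region name must appear in `regions`.")
  }
  strand <- match.arg(strand, c("+", "-"))
  obj <- structure(
    list(regions = regions, cds_regions = cds_regions, strand = strand,
         gene = gene),
    class = "gene_model"
  )
  cds_len <- length(cds_columns(obj))
  if (cds_len > 0L && cds_len %% 3L != 0L) {
    abort(sprintf("CDS length %d is not divisible by 3.", cds_len))
  }
  obj
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model>%s %d regions, strand %s\n",
              if (is.null(x$gene)) "" else paste0(" ", x$gene),
              nrow(x$regions), x$strand))
  lens <- x$regions$end - x$regions$start + 1L
  for (i in seq_len(nrow(x$regions))) {
    cat(sprintf("  %-10s %-8s %5d-%5d (%d bp)\n", x$regions$name[i],
                x$regions$kind[i], x$regions$start[i], x$regions$end[i],
                lens[i]))
  }
  if (length(x$cds_regions)) {
    cat(sprintf("  CDS: %s (%d bp)\n", paste(x$cds_regions, collapse = " + "),
                length(cds_columns(x))))
  }
  invisible(x)
}

#' Alignment columns belonging to regions
#'
#' @param model A [gene_model].
#' @param region_names Region names; defaults to all regions.
#' @return Sorted integer vector of 1-based alignment columns.
#' @export
region_columns <- function(model, region_names = NULL) {
  r <- model$regions
  if (!is.null(region_names)) {
    missing <- setdiff(region_names, r$name)
    if (length(missing)) {
      abort(sprintf("Unknown region(s): %s", paste(missing, collapse = ", ")))
    }
    r <- r[match(region_names, r$name), , drop = FALSE]
  }
  sort(unlist(purrr::map2(r$start, r$end, seq.int), use.names = FALSE))
}

#' @rdname region_columns
#' @details `cds_columns()` returns the CDS columns in translation order
#'   (concatenated exons; reverse-complementation for minus-strand genes is
#'   applied at translation time, not here).
#' @export
cds_columns <- function(model) {
  r <- model$regions[match(model$cds_regions, model$regions$name), ,
                     drop = FALSE]
  unlist(purrr::map2(r$start, r$end, seq.int), use.names = FALSE)
}

#' Region lookup for alignment positions
#'
#' @param model A [gene_model].
#' @param positions Integer alignment columns.
#' @return Character vector of region names (`NA` outside any region).
#' @export
region_of <- function(model, positions) {
  r <- model$regions
  out <- rep(NA_character_, length(positions))
  for (i in seq_len(nrow(r))) {
    hit <- positions >= r$start[i] & positions <= r$end[i]
    out[hit] <- r$name[i]
  }
  out
}

#' Read a gene-structure annotation from a YAML config
#'
#' Expected schema:
#' ```yaml
#' gene: ZmBT1
#' strand: "+"
#' regions:
#'   - {name: promoter, kind: promoter, start: 1,   end: 520}
#'   - {name: exon1,    kind: exon,     start: 521, end: 1144}
#' cds: [exon1, exon2, exon3]
#' ```
#'
#' @param path Path to the YAML file.
#' @return A [gene_model]; region lengths are reported via [message()].
#' @export
read_gene_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions)) abort(sprintf("'%s' has no `regions` key.", path))
  regions <- dplyr::bind_rows(lapply(cfg$regions, tibble::as_tibble))
  model <- gene_model(regions,
                      cds_regions = as.character(cfg$cds %||% character()),
                      strand = cfg$strand %||% "+",
                      gene = cfg$gene)
  lens <- model$regions$end - model$regions$start + 1L
  inform(sprintf(
    "Gene model%s: %s; total %d bp, CDS %d bp.",
    if (is.null(model$gene)) "" else paste0(" ", model$gene),
    paste(sprintf("%s=%d", model$regions$name, lens), collapse = ", "),
    sum(lens), length(cds_columns(model))
  ))
  model
}

#' Write a gene model to YAML
#'
#' @param model A [gene_model].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  cfg <- list(
    gene = model$gene, strand = model$strand,
    regions = purrr::pmap(model$regions, function(name, kind, start, end) {
      list(name = name, kind = kind, start = start, end = end)
    }),
    cds = as.list(model$cds_regions)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
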