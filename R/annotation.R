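#' Construct a genome annotation
#'
#' A genome annotation is a tibble of gene records (one row per gene) carrying
#' the chromosome geometry as attributes. Coordinates are 1-based and
#' inclusive, following GenBank/GFF convention; a gene wrapping the
#' replication origin is stored with `start > end` and is handled internally
#' by splitting it into two arcs.
#'
#' @param genes A data frame with columns `locus_tag`, `start`, `end`,
#'   `strand` and optionally `name`, `category`. Additional columns are kept.
#' @param genome_id Identifier of the chromosome (e.g. an accession).
#' @param genome_length Chromosome length in base pairs.
#' @param circular Is the chromosome circular? Bacterial chromosomes are.
#' @param ori Optional base-pair coordinate of the replication origin.
#'
#' @return A tibble of class `genome_annotation` with attributes
#'   `genome_id`, `genome_length`, `circular` and `ori`.
#' @export
genome_annotation <- function(genes, genome_id, genome_length,
                              circular = TRUE, ori = NULL) {
  genes <- as_tibble(genes)
  required <- c("locus_tag", "start", "end", "strand")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"name" %in% names(genes)) genes$name <- genes$locus_tag
  if (!"category" %in% names(genes)) genes$category <- NA_character_
  if (nrow(genes) == 0) abort("annotation contains no genes")
  if (!is.numeric(genome_length) || genome_length < 1) {
    abort("`genome_length` must be a positive number of base pairs")
  }
  bad <- genes$start < 1 | genes$end < 1 |
    genes$start > genome_length | genes$end > genome_length
  if (any(bad)) {
    abort(paste0("gene coordinates outside [1, genome_length] for: ",
                 paste(head(genes$locus_tag[bad], 5), collapse = ", ")))
  }
  structure(
    genes,
    genome_id = genome_id,
    genome_length = as.numeric(genome_length),
    circular = isTRUE(circular),
    ori = ori,
    class = c("genome_annotation", class(genes))
  )
}

#' Chromosome length of an annotation
#' @param x A `genome_annotation`.
#' @return Length in base pairs.
#' @export
genome_length <- function(x) {
  len <- attr(x, "genome_length")
  if (is.null(len)) abort("object has no `genome_length` attribute")
  len
}

#' Read a genome annotation from GFF3 or TSV
#'
#' The TSV layout is six columns: `locus_tag`, `name`, `start`, `end`,
#' `strand`, `category`. GFF3 files are parsed with rtracklayer; gene
#' features must carry a `locus_tag` attribute and may carry a `category`
#' attribute.
#'
#' @param path File path.
#' @param genome_id Identifier for the chromosome.
#' @param genome_length Chromosome length in bp. For GFF3 input, taken from
#'   the `##sequence-region` pragma when not supplied.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @inheritParams genome_annotation
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, genome_id = NULL, genome_length = NULL,
                            format = c("auto", "gff3", "tsv"),
                            circular = TRUE, ori = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gff3")
    meta <- as.data.frame(S4Vectors::mcols(gr))
    if (!"locus_tag" %in% names(meta)) {
      abort("GFF3 features carry no `locus_tag` attribute")
    }
    genes <- tibble(
      locus_tag = as.character(meta$locus_tag),
      name = if ("Name" %in% names(meta)) as.character(meta$Name) else
        as.character(meta$locus_tag),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      category = if ("category" %in% names(meta)) as.character(meta$category)
        else NA_character_
    )
    genes$strand[!genes$strand %in% c("+", "-")] <- "+"
    if (is.null(genome_length)) {
      lines <- readLines(path, n = 50)
      sr <- grep("^##sequence-region", lines, value = TRUE)
      if (length(sr) > 0) {
        genome_length <- as.numeric(strsplit(sr[1], "\\s+")[[1]][4])
      } else {
        genome_length <- max(genes$end)
      }
    }
    if (is.null(genome_id)) {
      genome_id <- as.character(GenomicRanges::seqnames(gr)[1])
    }
  } else {
    genes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (is.null(genome_length)) {
      abort("`genome_length` must be supplied for TSV annotations")
    }
    if (is.null(genome_id)) genome_id <- "genome"
  }
  genome_annotation(genes, genome_id = genome_id,
                    genome_length = genome_length,
                    circular = circular, ori = ori)
}

#' Write a genome annotation
#'
#' @param ann A [genome_annotation()].
#' @param path Output path.
#' @param format `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(
      tibble(locus_tag = ann$locus_tag, name = ann$name,
             start = ann$start, end = ann$end,
             strand = ann$strand, category = ann$category),
      path
    )
    return(invisible(path))
  }
  # hand-assembled GFF3: keeps wrapped genes (start > end) representable,
  # which GRanges would reject
  id <- attr(ann, "genome_id") %||% "genome"
  len <- genome_length(ann)
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d", id, as.integer(len)))
  attr_col <- sprintf("ID=%s;locus_tag=%s;Name=%s%s",
                      ann$locus_tag, ann$locus_tag, ann$name,
                      ifelse(is.na(ann$category), "",
                             paste0(";category=", ann$category)))
  body <- sprintf("%s\tgxe\tgene\t%d\t%d\t.\t%s\t.\t%s",
                  id, as.integer(ann$start), as.integer(ann$end),
                  ann$strand, attr_col)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a deleted-segment (scar) table
#'
#' Three tab-separated columns: `label`, `start`, `end` (1-based inclusive,
#' parent coordinates). Segments must be pairwise non-overlapping.
#'
#' @param path File path.
#' @return A tibble with columns `label`, `start`, `end`.
#' @export
read_deletion_segments <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_segments(seg)
}

validate_segments <- function(seg) {
  seg <- as_tibble(seg)
  if (!all(c("label", "start", "end") %in% names(seg))) {
    abort("segment table needs columns `label`, `start`, `end`")
  }
  if (any(seg$end < seg$start)) abort("segment with end < start")
  if (nrow(seg) > 1) {
    o <- order(seg$start)
    s <- seg[o, ]
    if (any(s$start[-1] <= s$end[-nrow(s)])) {
      abort("deletion segments overlap")
    }
  }
  seg
}

# endpoint-difference circular gap between closed intervals [gs,ge], [ss,se];
# 0 when they share at least one base
circular_gap <- function(gs, ge, ss, se, len) {
  overlap <- gs <= se & ss <= ge
  d1 <- (ss - ge) %% len
  d2 <- (gs - se) %% len
  ifelse(overlap, 0, pmin(d1, d2))
}

#' Circular distance from genes to the nearest scar
#'
#' The distance from a gene to a deletion scar is measured on the circular
#' chromosome, in both traversal directions, between the nearer gene boundary
#' and the nearer scar boundary; a gene overlapping or sharing a boundary
#' with a scar is at distance 0. The result never exceeds half the genome
#' length. Genes wrapping the origin (`start > end`) are split into two arcs
#' and the smaller distance is used.
#'
#' @param genes A `genome_annotation` or data frame with `locus_tag`,
#'   `start`, `end`.
#' @param scars Deletion-segment tibble (`label`, `start`, `end`), parent
#'   coordinates.
#' @param genome_length Chromosome length in bp; taken from `genes` when it
#'   is a `genome_annotation`.
#' @return A tibble with columns `locus_tag`, `scar_distance` (bp).
#' @export
scar_distances <- function(genes, scars, genome_length = NULL) {
  if (is.null(genome_length)) genome_length <- genome_length(genes)
  if (is.null(scars) || nrow(scars) == 0) {
    abort("no scars defined: cannot compute scar distances")
  }
  len <- as.numeric(genome_length)
  dist_one <- function(gs, ge) {
    arcs <- if (gs > ge) list(c(gs, len), c(1, ge)) else list(c(gs, ge))
    min(vapply(arcs, function(a) {
      min(circular_gap(a[1], a[2], scars$start, scars$end, len))
    }, numeric(1)))
  }
  tibble(
    locus_tag = genes$locus_tag,
    scar_distance = mapply(dist_one, genes$start, genes$end)
  )
}

#' Distance from a single gene to the nearest scar
#'
#' Scalar convenience wrapper around [scar_distances()].
#'
#' @param start,end Gene coordinates (1-based inclusive; `start > end` wraps
#'   the origin).
#' @param scars Deletion-segment tibble.
#' @param genome_length Chromosome length in bp.
#' @return Distance in bp.
#' @export
distance_to_nearest_scar <- function(start, end, scars, genome_length) {
  scar_distances(tibble(locus_tag = "gene", start = start, end = end),
                 scars, genome_length)$scar_distance
}

#' Remove deleted segments and compact coordinates
#'
#' Builds the reduced-genome coordinate system: genes overlapping any scar
#' are dropped and the remaining genes are shifted left by the total deleted
#' length preceding them, mirroring how a reduced strain's chromosome is laid
#' out after segment excision.
#'
#' @param ann Parent `genome_annotation`.
#' @param scars Deletion-segment tibble on parent coordinates.
#' @param genome_id Identifier for the compacted genome.
#' @return A `genome_annotation` with compacted coordinates and reduced
#'   length.
#' @export
compact_genome <- function(ann, scars, genome_id = NULL) {
  scars <- validate_segments(scars)
  scars <- scars[order(scars$start), , drop = FALSE]
  len <- genome_length(ann)
  if (any(scars$end > len)) abort("scar beyond genome end")
  cummax_end <- cummax(scars$end)
  seg_len <- scars$end - scars$start + 1
  cumlen <- cumsum(seg_len)
  # interval [a, b] (a <= b) overlaps some scar iff a scar starting at or
  # before b reaches back to a
  hits_interval <- function(a, b) {
    j <- findInterval(b, scars$start)
    j > 0 & cummax_end[pmax(j, 1)] >= a
  }
  hit <- ifelse(ann$start <= ann$end,
                hits_interval(ann$start, ann$end),
                hits_interval(ann$start, len) | hits_interval(1, ann$end))
  keep <- ann[!hit, , drop = FALSE]
  # cumulative deleted length strictly before each coordinate
  shift <- function(pos) {
    j <- findInterval(pos - 1, scars$start)
    full <- ifelse(j > 1, cumlen[pmax(j - 1, 1)], 0)
    partial <- ifelse(
      j > 0,
      pmax(0, pmin(scars$end[pmax(j, 1)], pos - 1) -
             scars$start[pmax(j, 1)] + 1),
      0
    )
    full + partial
  }
  new_len <- len - sum(seg_len)
  out <- keep
  out$start <- keep$start - shift(keep$start)
  out$end <- keep$end - shift(keep$end)
  genome_annotation(
    as_tibble(as.data.frame(out)),
    genome_id = genome_id %||% paste0(attr(ann, "genome_id"), "_compacted"),
    genome_length = new_len,
    circular = attr(ann, "circular") %||% TRUE,
    ori = NULL
  )
}
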