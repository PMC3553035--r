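#' Read an expression matrix with sample metadata
#'
#' The expression table is a TSV whose first column holds locus tags and
#' whose remaining columns are samples; values are log10 mRNA concentrations
#' (log10 pM). The metadata table is a TSV with columns `sample_id`,
#' `strain`, `condition`, `replicate`.
#'
#' @param table_path Path to the expression TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @param genes Optional character vector restricting the gene universe.
#' @return A long tibble with columns `locus_tag`, `sample_id`, `strain`,
#'   `condition`, `replicate`, `expr` — one row per gene per sample.
#' @export
read_expression <- function(table_path, meta_path, genes = NULL) {
  tab <- readr::read_tsv(table_path, show_col_types = FALSE, progress = FALSE)
  names(tab)[1] <- "locus_tag"
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "strain", "condition", "replicate")
  if (!all(need %in% names(meta))) {
    abort(paste0("metadata needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(meta[c("strain", "condition", "replicate")])) {
    abort("duplicated (strain, condition, replicate) in metadata")
  }
  dup <- tab$locus_tag[duplicated(tab$locus_tag)]
  if (length(dup) > 0) {
    abort(paste0("duplicated locus tag(s) in expression table: ",
                 paste(unique(head(dup, 5)), collapse = ", ")))
  }
  sample_cols <- setdiff(names(tab), "locus_tag")
  missing_meta <- setdiff(sample_cols, meta$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("sample(s) missing from metadata: ",
                 paste(missing_meta, collapse = ", ")))
  }
  for (sc in sample_cols) {
    col <- tab[[sc]]
    if (!is.numeric(col)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      abort(sprintf("non-numeric value in column '%s', row %d", sc,
                    if (is.na(bad_row)) 1L else bad_row))
    }
  }
  long <- tidyr::pivot_longer(tab, -"locus_tag",
                              names_to = "sample_id", values_to = "expr")
  # empty cells mean the gene is not assayed in that sample (e.g. deleted
  # genes on the reduced strain); they are dropped, not imputed
  if (anyNA(long$expr)) {
    inform(sprintf("dropping %d unassayed gene-sample cells",
                   sum(is.na(long$expr))))
    long <- long[!is.na(long$expr), ]
  }
  long <- inner_join(long, meta, by = "sample_id")
  long <- select(long, "locus_tag", "sample_id", "strain", "condition",
                 "replicate", "expr")
  if (!is.null(genes)) {
    absent <- setdiff(genes, unique(long$locus_tag))
    if (length(absent) > 0) {
      warn(paste0(length(absent),
                  " requested gene(s) absent from the expression table"))
    }
    long <- filter(long, .data$locus_tag %in% genes)
  }
  long
}

#' Write an expression matrix and metadata to TSV
#'
#' Inverse of [read_expression()]: the long tibble is written as a wide
#' gene-by-sample table plus a metadata table.
#'
#' @param expr Long expression tibble as returned by [read_expression()].
#' @param table_path,meta_path Output paths.
#' @return `table_path`, invisibly.
#' @export
write_expression <- function(expr, table_path, meta_path) {
  wide <- tidyr::pivot_wider(
    select(expr, "locus_tag", "sample_id", "expr"),
    names_from = "sample_id", values_from = "expr"
  )
  readr::write_tsv(wide, table_path)
  meta <- distinct(select(expr, "sample_id", "strain", "condition",
                          "replicate"))
  readr::write_tsv(meta, meta_path)
  invisible(table_path)
}

#' Average replicates within each strain-by-condition cell
#'
#' Means are taken in log10 space (the analysis space for these data); no
#' re-exponentiation is performed.
#'
#' @param expr Long expression tibble (see [read_expression()]).
#' @return A tibble with columns `locus_tag`, `strain`, `condition`,
#'   `mean_expr`, `n_replicates`.
#' @export
condition_means <- function(expr) {
  if (nrow(expr) == 0) abort("no expression rows to average")
  out <- summarise(
    group_by(expr, .data$locus_tag, .data$strain, .data$condition),
    mean_expr = mean(.data$expr),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
  out
}

#' Extract one condition's per-gene mean as a two-column tibble
#'
#' @param means Output of [condition_means()].
#' @param strain,condition Cell to extract.
#' @return Tibble `locus_tag`, `mean_expr`.
#' @export
condition_mean_vector <- function(means, strain, condition) {
  out <- filter(means, .data$strain == !!strain,
                .data$condition == !!condition)
  if (nrow(out) == 0) {
    abort(sprintf("no samples for condition (%s, %s)", strain, condition))
  }
  select(out, "locus_tag", "mean_expr")
}
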