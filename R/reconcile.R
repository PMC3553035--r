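#' Reconcile a parent and a reduced genome
#'
#' Classifies every tagged parent gene as *common* (present in the reduced
#' strain with matching sequence), *deleted* (absent from the reduced
#' strain), or *mutated* (present but sequence-mismatched, supplied as a
#' list). Repeated locus tags in the parent are resolved by keeping the
#' first occurrence in genome order before classification, so
#' `common + deleted + mutated` always partitions the de-duplicated parent
#' gene set.
#'
#' Records whose locus tag or name is `oriC` are excluded from the gene set
#' unless `include_ori = TRUE` (the origin is a site, not a gene).
#'
#' @param parent,reduced `genome_annotation` objects.
#' @param mutated_tags Character vector of parent locus tags with mismatched
#'   sequences (may be empty). Tags absent from the parent are an error.
#' @param scars Optional deletion-segment tibble (`label`, `start`, `end`) on
#'   parent coordinates. When `NULL`, scars are derived by merging runs of
#'   consecutive deleted genes into segments.
#' @param include_ori Keep an `oriC` record in the common set?
#'
#' @return An object of class `genome_comparison`: a list with character
#'   vectors `common`, `deleted`, `mutated`, the `scars` tibble, and a
#'   per-gene `classification` tibble (`locus_tag`, `start`, `end`,
#'   `status`). Use [tidy()] for the per-gene table and [glance()] for the
#'   counts.
#' @export
reconcile_genomes <- function(parent, reduced, mutated_tags = character(),
                              scars = NULL, include_ori = FALSE) {
  if (nrow(parent) == 0 || nrow(reduced) == 0) {
    abort("empty annotation: both genomes must contain genes")
  }
  mutated_tags <- unique(as.character(mutated_tags))
  p <- as_tibble(as.data.frame(parent))
  if (!include_ori) {
    p <- p[!(p$locus_tag == "oriC" | p$name %in% "oriC"), , drop = FALSE]
  }
  # de-duplicate repeated locus tags: first occurrence in genome order
  p <- p[order(p$start, p$end), , drop = FALSE]
  p <- p[!duplicated(p$locus_tag), , drop = FALSE]

  missing_mut <- setdiff(mutated_tags, p$locus_tag)
  if (length(missing_mut) > 0) {
    abort(paste0("mutated tag(s) absent from parent: ",
                 paste(missing_mut, collapse = ", ")))
  }

  reduced_tags <- unique(reduced$locus_tag)
  status <- ifelse(!p$locus_tag %in% reduced_tags, "deleted",
                   ifelse(p$locus_tag %in% mutated_tags, "mutated", "common"))
  classification <- tibble(
    locus_tag = p$locus_tag, start = p$start, end = p$end, status = status
  )

  if (is.null(scars)) {
    scars <- scars_from_deleted(classification)
  } else {
    scars <- validate_segments(scars)
  }

  structure(
    list(
      common = classification$locus_tag[status == "common"],
      deleted = classification$locus_tag[status == "deleted"],
      mutated = classification$locus_tag[status == "mutated"],
      scars = scars,
      classification = classification,
      parent_id = attr(parent, "genome_id"),
      reduced_id = attr(reduced, "genome_id"),
      genome_length = genome_length(parent)
    ),
    class = "genome_comparison"
  )
}

# merge runs of consecutive deleted genes (in genome order) into segments
scars_from_deleted <- function(classification) {
  cl <- classification[order(classification$start), ]
  del <- cl$status == "deleted"
  if (!any(del)) {
    return(tibble(label = character(), start = numeric(), end = numeric()))
  }
  run <- rle(del)
  idx_end <- cumsum(run$lengths)
  idx_start <- idx_end - run$lengths + 1
  keep <- which(run$values)
  tibble(
    label = paste0("scar_", seq_along(keep)),
    start = cl$start[idx_start[keep]],
    end = vapply(keep, function(i) {
      max(cl$end[idx_start[i]:idx_end[i]])
    }, numeric(1))
  )
}

#' @export
print.genome_comparison <- function(x, ...) {
  cat("<genome_comparison> ", x$parent_id, " vs ", x$reduced_id, "\n", sep = "")
  cat("  common:  ", length(x$common), "\n",
      "  deleted: ", length(x$deleted), "\n",
      "  mutated: ", length(x$mutated), "\n",
      "  scars:   ", nrow(x$scars), "\n", sep = "")
  invisible(x)
}

#' @rdname reconcile_genomes
#' @param x A `genome_comparison`.
#' @param ... Unused.
#' @method tidy genome_comparison
#' @export
tidy.genome_comparison <- function(x, ...) {
  x$classification
}

#' @rdname reconcile_genomes
#' @method glance genome_comparison
#' @export
glance.genome_comparison <- function(x, ...) {
  tibble(
    n_parent = nrow(x$classification),
    n_common = length(x$common),
    n_deleted = length(x$deleted),
    n_mutated = length(x$mutated),
    n_scars = nrow(x$scars)
  )
}

#' Serialize a genome comparison
#'
#' Writes the comparison as JSON (gene sets + scars) and, optionally, a TSV
#' of per-gene classification with scar distances.
#'
#' @param comparison A `genome_comparison`.
#' @param json_path Output JSON path (`NULL` to skip).
#' @param tsv_path Output TSV path (`NULL` to skip).
#' @return The comparison, invisibly.
#' @export
write_comparison <- function(comparison, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        parent = comparison$parent_id, reduced = comparison$reduced_id,
        common = comparison$common, deleted = comparison$deleted,
        mutated = comparison$mutated,
        scars = comparison$scars
      ),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(tsv_path)) {
    tab <- comparison$classification
    if (nrow(comparison$scars) > 0) {
      tab <- left_join(
        tab,
        scar_distances(tab, comparison$scars, comparison$genome_length),
        by = "locus_tag"
      )
    }
    readr::write_tsv(tab, tsv_path)
  }
  invisible(comparison)
}
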