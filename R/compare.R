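#' Wilcoxon-Mann-Whitney test on scar distances of two gene groups
#'
#' Compares the circular distances to the nearest genomic scar between two
#' gene groups (e.g. DEGs versus genes with conserved expression). Exact
#' enumeration is used for small tie-free samples (both groups <= 20),
#' otherwise the normal approximation with tie correction.
#'
#' @param distances_a,distances_b Numeric vectors of distances (bp), both
#'   non-empty.
#' @param labels Length-2 character vector naming the groups.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (referring to group A relative to group B).
#' @return A one-row tibble of class `distance_test`: group labels and
#'   sizes, medians, the rank-sum statistic `W`, `p_value`, and `method`.
#' @export
scar_distance_test <- function(distances_a, distances_b,
                               labels = c("A", "B"),
                               alternative = "two.sided") {
  if (length(distances_a) == 0 || length(distances_b) == 0) {
    abort("both groups must be non-empty")
  }
  exact <- length(distances_a) <= 20 && length(distances_b) <= 20 &&
    !any(duplicated(c(distances_a, distances_b)))
  wt <- suppressWarnings(
    wilcox.test(distances_a, distances_b, alternative = alternative,
                exact = exact, correct = !exact)
  )
  structure(
    tibble(
      group_a = labels[1], group_b = labels[2],
      n_a = length(distances_a), n_b = length(distances_b),
      median_a = median(distances_a), median_b = median(distances_b),
      statistic = unname(wt$statistic),
      p_value = wt$p.value,
      method = if (exact) "exact" else "normal approximation",
      alternative = alternative
    ),
    class = c("distance_test", class(tibble()))
  )
}

#' Compare a gene subset's cross-condition correlation with the universe
#'
#' Computes the Pearson correlation of two expression vectors over a gene
#' subset and over the full universe, and assesses the difference by
#' bootstrap: genes are resampled with replacement within each group and the
#' difference of correlations recomputed; the two-sided empirical P-value is
#' the bootstrap probability mass on the other side of zero (doubled,
#' capped at 1).
#'
#' @param pairs Tibble with columns `locus_tag`, `x`, `y` — the two
#'   condition means per gene for every universe gene.
#' @param subset_tags Gene subset (>= 3 tags, all in the universe).
#' @param n_boot Bootstrap resamples (>= 100; default 1000).
#' @param seed Integer seed.
#' @param label Subset label for the output.
#' @return A one-row tibble of class `correlation_comparison`: `subset`,
#'   `n_subset`, `r_subset`, `n_universe`, `r_universe`, `difference`,
#'   `p_value`.
#' @export
correlation_comparison <- function(pairs, subset_tags, n_boot = 1000,
                                   seed = 1, label = "subset") {
  if (n_boot < 100) abort("`n_boot` must be at least 100")
  if (length(subset_tags) < 3) abort("subset must contain at least 3 genes")
  outside <- setdiff(subset_tags, pairs$locus_tag)
  if (length(outside) > 0) {
    abort(paste0("subset gene(s) outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  sub <- pairs[pairs$locus_tag %in% subset_tags, ]
  r_sub <- cor(sub$x, sub$y)
  r_uni <- cor(pairs$x, pairs$y)

  set.seed(seed)
  ns <- nrow(sub)
  nu <- nrow(pairs)
  boot_diff <- vapply(seq_len(n_boot), function(i) {
    is <- sample.int(ns, replace = TRUE)
    iu <- sample.int(nu, replace = TRUE)
    cor(sub$x[is], sub$y[is]) - cor(pairs$x[iu], pairs$y[iu])
  }, numeric(1))
  p <- min(1, 2 * min(mean(boot_diff <= 0), mean(boot_diff >= 0)))

  structure(
    tibble(
      subset = label, n_subset = ns, r_subset = r_sub,
      n_universe = nu, r_universe = r_uni,
      difference = r_sub - r_uni, p_value = p
    ),
    n_boot = n_boot,
    class = c("correlation_comparison", class(tibble()))
  )
}

#' Per-gene transcriptional changes from genome reduction, heat shock, and
#' both
#'
#' From the four strain-by-condition mean-expression cells, computes for
#' each gene the genomic contribution (reduced minus parent, both under the
#' normal condition), the environmental contribution (parent under heat
#' shock minus parent under normal), and the simultaneous contribution
#' (reduced under heat shock minus parent under normal) — all in log10
#' units.
#'
#' @param means Output of [condition_means()] covering both strains and both
#'   conditions on a shared gene set.
#' @param strains Length-2 named character vector mapping `parent` and
#'   `reduced` to the strain labels in `means`.
#' @param conditions Length-2 named character vector mapping `normal` and
#'   `heatshock` to the condition labels in `means`.
#' @return A tibble `locus_tag`, `dt_genomic`, `dt_environment`,
#'   `dt_simultaneous` over the genes present in all four cells.
#' @export
delta_t <- function(means,
                    strains = c(parent = "parent", reduced = "reduced"),
                    conditions = c(normal = "normal",
                                   heatshock = "heatshock")) {
  cell <- function(s, cc) {
    v <- condition_mean_vector(means, strains[[s]], conditions[[cc]])
    stats::setNames(v$mean_expr, v$locus_tag)
  }
  pn <- cell("parent", "normal")
  ph <- cell("parent", "heatshock")
  rn <- cell("reduced", "normal")
  rh <- cell("reduced", "heatshock")
  tags <- Reduce(intersect, list(names(pn), names(ph), names(rn), names(rh)))
  if (length(tags) == 0) abort("no genes shared across all four conditions")
  tibble(
    locus_tag = tags,
    dt_genomic = unname(rn[tags] - pn[tags]),
    dt_environment = unname(ph[tags] - pn[tags]),
    dt_simultaneous = unname(rh[tags] - pn[tags])
  )
}
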