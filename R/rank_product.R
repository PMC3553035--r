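parse_cell <- function(x) {
  if (is.character(x) && length(x) == 1 && grepl(":", x)) {
    x <- strsplit(x, ":", fixed = TRUE)[[1]]
  }
  if (length(x) != 2) {
    abort("a condition cell must be 'strain:condition' or c(strain, condition)")
  }
  x
}

cell_matrix <- function(expr, cell) {
  sub <- filter(expr, .data$strain == cell[1], .data$condition == cell[2])
  if (nrow(sub) == 0) {
    abort(sprintf("no samples for condition (%s, %s)", cell[1], cell[2]))
  }
  wide <- tidyr::pivot_wider(
    select(sub, "locus_tag", "replicate", "expr"),
    names_from = "replicate", values_from = "expr"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$locus_tag
  m
}

#' Rank-product differential expression between two conditions
#'
#' For each of `K` replicate-pair comparisons (see `pairing`), genes are
#' ranked by the replicate difference (descending for upregulation in `b`
#' relative to `a`, ascending for downregulation; ties get average ranks).
#' The rank
#' product of a gene is the geometric mean of its ranks over the `K`
#' comparisons; consistently extreme genes have rank products near 1. The
#' null distribution is built from `n_perm` permutations that redraw the
#' ranks of every comparison uniformly at random, and the proportion of
#' false positives (pfp) of a gene is the expected number of null rank
#' products at least as extreme, divided by the gene's rank position.
#'
#' @param expr Long expression tibble (see [read_expression()]).
#' @param a,b Condition cells, `"strain:condition"` strings or
#'   two-element character vectors; `a` is the reference, so `direction =
#'   "up"` means higher expression in `b`.
#' @param n_perm Number of rank-redraw permutations (>= 10; default 1000).
#' @param pairing `"disjoint"` (default) pairs replicate i of `a` with
#'   replicate i of `b`, giving `K = min(nA, nB)` mutually independent
#'   comparisons so the rank-redraw null is exact and the pfp is calibrated;
#'   `"cross"` uses all `nA * nB` replicate pairs (the classic rank-product
#'   layout), which uses every replicate of an unbalanced design but makes
#'   the comparisons dependent and the pfp slightly anti-conservative.
#' @param seed Integer seed for the permutation null.
#' @return A tibble of class `rank_product_tbl` with columns `locus_tag`,
#'   `fold_change` (log10 difference of condition means, `b - a`), `rp_up`,
#'   `rp_down`, `pfp_up`, `pfp_down`, `direction` (direction of the smaller
#'   pfp; the DEG call is made by [call_degs()]).
#' @export
rank_product <- function(expr, a, b, n_perm = 1000,
                         pairing = c("disjoint", "cross"), seed = 1) {
  pairing <- match.arg(pairing)
  if (n_perm < 10) abort("`n_perm` must be at least 10")
  a <- parse_cell(a)
  b <- parse_cell(b)
  ma <- cell_matrix(expr, a)
  mb <- cell_matrix(expr, b)
  shared <- intersect(rownames(ma), rownames(mb))
  if (length(shared) < 2) abort("fewer than 2 genes shared between conditions")
  if (length(shared) < nrow(ma) || length(shared) < nrow(mb)) {
    inform(sprintf("restricting to %d genes present in both conditions",
                   length(shared)))
  }
  ma <- ma[shared, , drop = FALSE]
  mb <- mb[shared, , drop = FALSE]
  n <- length(shared)
  if (pairing == "disjoint") {
    K <- min(ncol(ma), ncol(mb))
    if (ncol(ma) != ncol(mb)) {
      inform(sprintf(
        "unbalanced design: disjoint pairing uses %d of %d x %d replicates",
        K, ncol(ma), ncol(mb)))
    }
    idx <- cbind(seq_len(K), seq_len(K))
  } else {
    K <- ncol(ma) * ncol(mb)
    idx <- as.matrix(expand.grid(seq_len(ncol(ma)), seq_len(ncol(mb))))
  }

  rank_up <- matrix(0, n, K)
  rank_down <- matrix(0, n, K)
  for (col in seq_len(K)) {
    d <- mb[, idx[col, 2]] - ma[, idx[col, 1]]
    rank_down[, col] <- rank(d, ties.method = "average")
    rank_up[, col] <- rank(-d, ties.method = "average")
  }
  rp_up <- exp(rowMeans(log(rank_up)))
  rp_down <- exp(rowMeans(log(rank_down)))

  set.seed(seed)
  null_rp <- numeric(n_perm * n)
  logr <- matrix(0, n, K)
  for (p in seq_len(n_perm)) {
    for (kk in seq_len(K)) logr[, kk] <- log(sample.int(n))
    null_rp[((p - 1) * n + 1):(p * n)] <- exp(rowMeans(logr))
  }
  null_sorted <- sort(null_rp)
  e_of <- function(rp) findInterval(rp, null_sorted) / n_perm
  # running maximum along the RP ordering enforces monotone pfp, so a gene
  # never carries a smaller false-positive proportion than a better-ranked one
  pfp_of <- function(rp) {
    pfp <- e_of(rp) / rank(rp, ties.method = "average")
    ord <- order(rp)
    pfp[ord] <- cummax(pfp[ord])
    pfp
  }
  pfp_up <- pfp_of(rp_up)
  pfp_down <- pfp_of(rp_down)

  means_a <- rowMeans(ma)
  means_b <- rowMeans(mb)
  structure(
    tibble(
      locus_tag = shared,
      fold_change = means_b - means_a,
      rp_up = rp_up, rp_down = rp_down,
      pfp_up = pfp_up, pfp_down = pfp_down,
      direction = ifelse(pfp_up <= pfp_down, "up", "down")
    ),
    contrast = list(a = a, b = b),
    pairing = pairing,
    n_comparisons = K,
    n_perm = n_perm,
    class = c("rank_product_tbl", class(tibble()))
  )
}

#' Call differentially expressed genes from rank-product results
#'
#' Genes with `pfp_up < fdr_cutoff` are called up, `pfp_down < fdr_cutoff`
#' down; a gene passing in both directions keeps the direction with the
#' smaller pfp (logged). Lowering the cutoff never adds genes.
#'
#' @param results A [rank_product()] tibble.
#' @param fdr_cutoff pfp (false-discovery) cutoff; the headline analyses use
#'   0.001.
#' @return A tibble `locus_tag`, `direction`, `pfp`, `fold_change` — the DEG
#'   set.
#' @export
call_degs <- function(results, fdr_cutoff = 0.001) {
  up <- results$pfp_up < fdr_cutoff
  down <- results$pfp_down < fdr_cutoff
  both <- up & down
  if (any(both)) {
    inform(sprintf(
      "%d gene(s) passed in both directions; keeping the smaller-pfp direction",
      sum(both)))
    keep_up <- results$pfp_up <= results$pfp_down
    up[both] <- keep_up[both]
    down[both] <- !keep_up[both]
  }
  bind_rows(
    tibble(locus_tag = results$locus_tag[up], direction = "up",
           pfp = results$pfp_up[up],
           fold_change = results$fold_change[up]),
    tibble(locus_tag = results$locus_tag[down], direction = "down",
           pfp = results$pfp_down[down],
           fold_change = results$fold_change[down])
  )
}

#' Overlap of two DEG sets with direction concordance
#'
#' @param deg_a,deg_b DEG tibbles from [call_degs()] (columns `locus_tag`,
#'   `direction`), drawn from the same gene universe.
#' @return A list: `summary` (one-row tibble with `n_a`, `n_b`, `n_overlap`,
#'   `n_same_direction`, `n_reversed`) and `genes` (per-gene listing of the
#'   overlap with both directions).
#' @export
overlap_degs <- function(deg_a, deg_b) {
  genes <- inner_join(
    select(deg_a, "locus_tag", direction_a = "direction"),
    select(deg_b, "locus_tag", direction_b = "direction"),
    by = "locus_tag"
  )
  genes$concordant <- genes$direction_a == genes$direction_b
  list(
    summary = tibble(
      n_a = nrow(deg_a), n_b = nrow(deg_b),
      n_overlap = nrow(genes),
      n_same_direction = sum(genes$concordant),
      n_reversed = sum(!genes$concordant)
    ),
    genes = genes
  )
}
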