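#' Read / write gene-set collections in GMT format
#'
#' @param path GMT file path (one set per line: name, description, member
#'   tags, tab-separated).
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @return `write_gmt()`: `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ES of one set given sorted hit positions in a ranked list of length n,
# with hit weights w (|score|^weight at the hit positions, in rank order)
running_sum_es <- function(positions, w, n) {
  m <- length(positions)
  if (m == 0 || m == n) return(0)
  cw <- cumsum(w) / sum(w)
  miss <- 1 / (n - m)
  after <- cw - (positions - seq_len(m)) * miss
  before <- c(0, cw[-m]) - (positions - seq_len(m)) * miss
  es_pos <- max(c(0, after))
  es_neg <- min(c(0, before))
  if (es_pos >= -es_neg) es_pos else es_neg
}

#' Preranked gene-set enrichment over regulon sets
#'
#' Classic running-sum enrichment: genes are ordered by a ranking score
#' (here, the signed difference of condition means); walking down the list,
#' the running sum rises by `|score|^weight` (normalized) at members of the
#' set and falls uniformly at non-members. The enrichment score ES is the
#' maximum deviation from zero; its sign gives the direction (positive =
#' concentrated among increased genes). Significance uses gene-set
#' permutations: `n_perm` random sets of the same size drawn from the
#' universe. NES is ES divided by the mean absolute null ES of matching
#' sign, and the FDR q-value compares each NES against the pooled null NES
#' distribution, as in the original GSEA procedure.
#'
#' @param scores Tibble with columns `locus_tag` and `score` (the ranking
#'   metric; signed difference of condition means).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#'   Members outside the scored universe are dropped; sets smaller than
#'   `min_size` after restriction are skipped with a message.
#' @param weight Exponent on `|score|` for hit increments (1 = weighted,
#'   0 = classic Kolmogorov-Smirnov style).
#' @param n_perm Gene-set permutations per set (default 1000).
#' @param min_size Minimum restricted set size (default 15).
#' @param seed Integer seed.
#' @return A tibble of class `gsea_tbl`: `set`, `size`, `es`, `nes`,
#'   `fdr_q`, `direction` (`increased`/`decreased`).
#' @export
preranked_gsea <- function(scores, sets, weight = 1, n_perm = 1000,
                           min_size = 15, seed = 1) {
  if (!all(c("locus_tag", "score") %in% names(scores))) {
    abort("`scores` needs columns `locus_tag` and `score`")
  }
  set.seed(seed)
  ord <- order(scores$score, decreasing = TRUE)
  tags <- scores$locus_tag[ord]
  s_abs_w <- abs(scores$score[ord])^weight
  n <- length(tags)
  pos_of <- stats::setNames(seq_len(n), tags)

  restricted <- lapply(sets, function(g) intersect(g, tags))
  sizes <- lengths(restricted)
  skip <- sizes < min_size
  if (any(skip)) {
    inform(sprintf("skipping %d set(s) below min_size = %d: %s",
                   sum(skip), min_size,
                   paste(head(names(sets)[skip], 5), collapse = ", ")))
  }
  keep <- names(sets)[!skip]
  if (length(keep) == 0) {
    return(structure(tibble(set = character(), size = integer(),
                            es = numeric(), nes = numeric(),
                            fdr_q = numeric(), direction = character()),
                     class = c("gsea_tbl", class(tibble()))))
  }

  es_of_positions <- function(p) {
    p <- sort(p)
    running_sum_es(p, s_abs_w[p], n)
  }

  es_obs <- vapply(restricted[keep], function(g) {
    es_of_positions(unname(pos_of[g]))
  }, numeric(1))

  null_es <- lapply(keep, function(nm) {
    m <- sizes[[nm]]
    vapply(seq_len(n_perm), function(i) {
      es_of_positions(sample.int(n, m))
    }, numeric(1))
  })
  names(null_es) <- keep

  normalize <- function(es, null) {
    mp <- mean(abs(null[null >= 0]))
    mn <- mean(abs(null[null < 0]))
    ifelse(es >= 0, es / mp, es / mn)
  }
  nes_obs <- vapply(keep, function(nm) {
    normalize(es_obs[[nm]], null_es[[nm]])
  }, numeric(1))
  nes_null <- unlist(lapply(keep, function(nm) {
    normalize(null_es[[nm]], null_es[[nm]])
  }), use.names = FALSE)
  nes_null <- nes_null[is.finite(nes_null)]

  fdr_of <- function(nes) {
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(nes_null[nes_null >= 0] >= nes)
      den <- mean(nes_obs[nes_obs >= 0] >= nes)
    } else {
      num <- mean(nes_null[nes_null < 0] <= nes)
      den <- mean(nes_obs[nes_obs < 0] <= nes)
    }
    if (!is.finite(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }
  fdr_q <- vapply(nes_obs, fdr_of, numeric(1))

  structure(
    tibble(
      set = keep,
      size = unname(sizes[keep]),
      es = unname(es_obs),
      nes = unname(nes_obs),
      fdr_q = unname(fdr_q),
      direction = unname(ifelse(es_obs >= 0, "increased", "decreased"))
    ),
    n_perm = n_perm, weight = weight, min_size = min_size,
    class = c("gsea_tbl", class(tibble()))
  )
}

#' One-tailed binomial enrichment of functional categories among DEGs
#'
#' For each gene category and DEG direction (`up`, `down`, `all`), tests
#' whether DEGs of that direction hit the category more often than expected
#' from the category's share of the universe:
#' `P = P(X >= x)` with `X ~ Binomial(n, p0)`, `x` the observed DEG count in
#' the category, `n` the DEG count of that direction, and `p0` the universe
#' fraction in the category. P-values are reported raw (no multiplicity
#' correction).
#'
#' @param degs DEG tibble (`locus_tag`, `direction`), a subset of `universe`.
#' @param categories Tibble `locus_tag`, `category` covering every universe
#'   gene.
#' @param universe Character vector of analysis genes.
#' @return A tibble: `category`, `direction`, `x` (DEGs in category), `n`
#'   (DEGs of direction), `universe_count`, `p0`, `p_value`.
#' @export
binomial_category_enrichment <- function(degs, categories, universe) {
  if (nrow(degs) == 0) {
    warn("empty DEG set: returning no enrichment rows")
    return(tibble(category = character(), direction = character(),
                  x = integer(), n = integer(), universe_count = integer(),
                  p0 = numeric(), p_value = numeric()))
  }
  outside <- setdiff(degs$locus_tag, universe)
  if (length(outside) > 0) {
    abort(paste0("DEG(s) outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  cat_map <- stats::setNames(categories$category, categories$locus_tag)
  uncat <- setdiff(universe, categories$locus_tag)
  if (length(uncat) > 0) {
    abort(paste0("universe gene(s) without a category: ",
                 paste(head(uncat, 5), collapse = ", ")))
  }
  uni_cat <- cat_map[universe]
  uni_counts <- table(uni_cat)
  cats <- names(uni_counts)
  N <- length(universe)

  rows <- list()
  for (dir in c("up", "down", "all")) {
    d <- if (dir == "all") degs else degs[degs$direction == dir, ]
    n <- nrow(d)
    deg_counts <- table(factor(cat_map[d$locus_tag], levels = cats))
    for (ct in cats) {
      x <- as.integer(deg_counts[[ct]])
      p0 <- as.integer(uni_counts[[ct]]) / N
      p <- if (n == 0) 1 else pbinom(x - 1, n, p0, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- tibble(
        category = ct, direction = dir, x = x, n = n,
        universe_count = as.integer(uni_counts[[ct]]), p0 = p0, p_value = p
      )
    }
  }
  bind_rows(rows)
}

#' Count enriched regulatory networks by perturbation and direction
#'
#' Bookkeeping over a Table-1-style listing of enriched networks: filters at
#' an FDR q cutoff and counts rows per perturbation and direction.
#'
#' @param networks Tibble with columns `perturbation`, `direction`, `fdr_q`
#'   (e.g. stacked [preranked_gsea()] results labelled by perturbation, or a
#'   printed table read from TSV).
#' @param fdr_cutoff FDR q cutoff (default 0.25).
#' @return A tibble `perturbation`, `direction`, `n`, plus per-perturbation
#'   totals with `direction = "all"`.
#' @export
count_enriched_networks <- function(networks, fdr_cutoff = 0.25) {
  kept <- filter(networks, .data$fdr_q < fdr_cutoff)
  by_dir <- count(kept, .data$perturbation, .data$direction, name = "n")
  totals <- count(kept, .data$perturbation, name = "n")
  totals$direction <- "all"
  bind_rows(by_dir, select(totals, "perturbation", "direction", "n"))
}
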