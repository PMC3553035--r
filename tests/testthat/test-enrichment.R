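# independent running-sum oracle over the whole ranked list
es_oracle <- function(scores, members, weight = 1) {
  ord <- order(scores$score, decreasing = TRUE)
  tags <- scores$locus_tag[ord]
  s <- abs(scores$score[ord])^weight
  hit <- tags %in% members
  nr <- sum(s[hit])
  inc <- ifelse(hit, s / nr, -1 / (length(tags) - sum(hit)))
  running <- cumsum(inc)
  # running sum returns to zero at the end by construction
  stopifnot(abs(running[length(running)]) < 1e-10)
  running[which.max(abs(running))]
}

test_that("a set of the very top genes attains the maximal ES of 1", {
  scores <- tibble::tibble(locus_tag = sprintf("g%03d", 1:100),
                           score = seq(5, -5, length.out = 100))
  res <- preranked_gsea(scores, list(top = sprintf("g%03d", 1:20)),
                        n_perm = 50, min_size = 5, seed = 1)
  expect_equal(res$es, 1)
  expect_equal(res$direction, "increased")
  bottom <- preranked_gsea(scores, list(bot = sprintf("g%03d", 81:100)),
                           n_perm = 50, min_size = 5, seed = 1)
  expect_equal(bottom$es, -1)
  expect_equal(bottom$direction, "decreased")
})

test_that("ES equals the hand running-sum oracle on a 10-gene list", {
  scores <- tibble::tibble(
    locus_tag = letters[1:10],
    score = c(3.0, 2.2, 1.5, 0.9, 0.4, -0.2, -0.8, -1.4, -2.1, -3.0)
  )
  set3 <- c("b", "e", "h")
  res <- preranked_gsea(scores, list(s = set3), n_perm = 50, min_size = 2,
                        seed = 2)
  expect_equal(res$es, es_oracle(scores, set3, weight = 1))
  res0 <- preranked_gsea(scores, list(s = set3), weight = 0, n_perm = 50,
                         min_size = 2, seed = 2)
  expect_equal(res0$es, es_oracle(scores, set3, weight = 0))
})

test_that("ES agrees with fgsea's statistic on random inputs", {
  set.seed(51)
  for (i in 1:5) {
    n <- 80
    scores <- tibble::tibble(locus_tag = sprintf("g%02d", 1:n),
                             score = rnorm(n))
    members <- sample(scores$locus_tag, 12)
    mine <- preranked_gsea(scores, list(s = members), n_perm = 20,
                           min_size = 5, seed = 3)$es
    stats_sorted <- sort(stats::setNames(scores$score, scores$locus_tag),
                         decreasing = TRUE)
    ref <- fgsea::calcGseaStat(stats_sorted,
                               which(names(stats_sorted) %in% members),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("weight-0 scoring is invariant to monotone score rescaling", {
  set.seed(52)
  scores <- tibble::tibble(locus_tag = sprintf("g%02d", 1:50),
                           score = rnorm(50))
  members <- sample(scores$locus_tag, 10)
  a <- preranked_gsea(scores, list(s = members), weight = 0, n_perm = 30,
                      min_size = 5, seed = 4)
  rescaled <- dplyr::mutate(scores, score = exp(score / 2))
  b <- preranked_gsea(rescaled, list(s = members), weight = 0, n_perm = 30,
                      min_size = 5, seed = 4)
  expect_equal(a$es, b$es)
})

test_that("sets below min_size are skipped with a message", {
  scores <- tibble::tibble(locus_tag = sprintf("g%02d", 1:30),
                           score = rnorm(30))
  expect_message(
    res <- preranked_gsea(scores, list(tiny = scores$locus_tag[1:3],
                                       ok = scores$locus_tag[1:20]),
                          n_perm = 20, min_size = 15, seed = 1),
    "min_size"
  )
  expect_equal(res$set, "ok")
})

test_that("null scores produce a false-positive proportion near or below
          the nominal FDR", {
  set.seed(53)
  called <- 0; total <- 0
  for (s in 1:5) {
    scores <- tibble::tibble(locus_tag = sprintf("g%03d", 1:400),
                             score = rnorm(400))
    sets <- lapply(1:20, function(i) sample(scores$locus_tag, 25))
    names(sets) <- sprintf("s%02d", 1:20)
    res <- preranked_gsea(scores, sets, n_perm = 100, min_size = 10,
                          seed = s)
    called <- called + sum(res$fdr_q < 0.25, na.rm = TRUE)
    total <- total + nrow(res)
  }
  expect_lt(called / total, 0.35)
})

test_that("binomial category P equals the direct tail summation", {
  # universe of 100 genes, 10 in the category; 10 DEGs, 5 hits
  p0 <- 0.1
  direct <- sum(vapply(5:10, function(k) {
    choose(10, k) * p0^k * (1 - p0)^(10 - k)
  }, numeric(1)))
  universe <- sprintf("g%03d", 1:100)
  categories <- tibble::tibble(
    locus_tag = universe,
    category = rep(c("A", "B"), c(10, 90))
  )
  degs <- tibble::tibble(
    locus_tag = c(universe[1:5], universe[11:15]),
    direction = "up"
  )
  enr <- binomial_category_enrichment(degs, categories, universe)
  got <- enr$p_value[enr$category == "A" & enr$direction == "up"]
  expect_equal(got, direct, tolerance = 1e-12)
})

test_that("binomial P behaves at the boundaries and decreases in x", {
  universe <- sprintf("g%02d", 1:40)
  categories <- tibble::tibble(locus_tag = universe,
                               category = rep(c("A", "B"), c(8, 32)))
  # no DEG hits in category: P(X >= 0) is vacuously 1; n = 0 also gives 1
  degs0 <- tibble::tibble(locus_tag = universe[9:12], direction = "up")
  enr0 <- binomial_category_enrichment(degs0, categories, universe)
  expect_equal(enr0$p_value[enr0$category == "A" & enr0$direction == "up"], 1)
  expect_equal(enr0$p_value[enr0$category == "A" & enr0$direction == "down"],
               1)
  # degenerate category holding every gene
  all_cat <- tibble::tibble(locus_tag = universe, category = "A")
  enr1 <- binomial_category_enrichment(degs0, all_cat, universe)
  row <- enr1[enr1$direction == "up", ]
  expect_equal(row$p_value, 1)
  expect_equal(row$x, row$n)
  # monotone in x at fixed n, p0
  ps <- vapply(0:6, function(x) pbinom(x - 1, 6, 0.3, lower.tail = FALSE),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("empty DEG sets warn and return nothing", {
  universe <- sprintf("g%02d", 1:10)
  categories <- tibble::tibble(locus_tag = universe, category = "A")
  expect_warning(
    out <- binomial_category_enrichment(
      tibble::tibble(locus_tag = character(), direction = character()),
      categories, universe),
    "empty"
  )
  expect_equal(nrow(out), 0)
})

test_that("filtering the printed network table reproduces its row counts", {
  path <- system.file("extdata", "regulon_networks.tsv", package = "gxe")
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  counts <- count_enriched_networks(tab, fdr_cutoff = 0.25)
  get <- function(p, d) counts$n[counts$perturbation == p &
                                   counts$direction == d]
  expect_equal(get("genome_reduction", "all"), 24)
  expect_equal(get("genome_reduction", "increased"), 22)
  expect_equal(get("genome_reduction", "decreased"), 2)
  expect_equal(get("heat_shock", "all"), 12)
  expect_equal(get("heat_shock", "increased"), 7)
  expect_equal(get("heat_shock", "decreased"), 5)
})

test_that("GMT files round-trip through the readers", {
  dir <- withr::local_tempdir()
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  write_gmt(sets, file.path(dir, "sets.gmt"))
  back <- read_gmt(file.path(dir, "sets.gmt"))
  expect_equal(back[order(names(back))], sets[order(names(sets))])
})
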