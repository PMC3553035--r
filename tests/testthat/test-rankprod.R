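test_that("a gene ranked first in every comparison has rank product 1", {
  tags <- sprintf("g%d", 1:6)
  base <- matrix(0, 6, 2)
  up <- base
  up[1, ] <- 5  # gene 1 hugely higher in condition B
  up <- up + matrix(seq(0, 0.5, length.out = 12), 6, 2)
  expr <- toy_expression(tags, list("parent:normal" = base,
                                    "reduced:normal" = up))
  rp <- rank_product(expr, "parent:normal", "reduced:normal",
                     n_perm = 50, seed = 1)
  expect_equal(rp$rp_up[rp$locus_tag == "g1"], 1)
  expect_true(all(rp$rp_up >= 1 & rp$rp_up <= 6))
  expect_true(all(rp$rp_down >= 1 & rp$rp_down <= 6))
})

test_that("rank products equal hand-computed geometric means on a toy", {
  tags <- sprintf("g%d", 1:5)
  a <- matrix(c(1, 2, 3, 4, 5,
                1.5, 2.5, 3.5, 4.5, 5.5), 5, 2)
  b <- matrix(c(2, 1, 5, 3, 4,
                2.2, 1.1, 5.5, 3.3, 4.4), 5, 2)
  expr <- toy_expression(tags, list("A:normal" = a, "B:normal" = b))

  # cross pairing: all four comparison lists
  rp <- rank_product(expr, "A:normal", "B:normal", n_perm = 20,
                     pairing = "cross", seed = 1)
  ranks_up <- sapply(1:2, function(i) sapply(1:2, function(j) {
    rank(-(b[, j] - a[, i]))
  }))
  dim(ranks_up) <- c(5, 4)
  want_up <- apply(ranks_up, 1, function(r) prod(r)^(1 / 4))
  expect_equal(rp$rp_up[match(tags, rp$locus_tag)], want_up)

  ranks_down <- sapply(1:2, function(i) sapply(1:2, function(j) {
    rank(b[, j] - a[, i])
  }))
  dim(ranks_down) <- c(5, 4)
  want_down <- apply(ranks_down, 1, function(r) prod(r)^(1 / 4))
  expect_equal(rp$rp_down[match(tags, rp$locus_tag)], want_down)

  # disjoint pairing: the two same-index comparisons only
  rp2 <- rank_product(expr, "A:normal", "B:normal", n_perm = 20, seed = 1)
  want2 <- sqrt(rank(-(b[, 1] - a[, 1])) * rank(-(b[, 2] - a[, 2])))
  expect_equal(rp2$rp_up[match(tags, rp2$locus_tag)], want2)
})

test_that("rank product depends only on ranks (monotone invariance)", {
  set.seed(41)
  tags <- sprintf("g%d", 1:30)
  a <- matrix(rnorm(90), 30, 3)
  b <- matrix(rnorm(90, 0.2), 30, 3)
  e1 <- toy_expression(tags, list("A:normal" = a, "B:normal" = b))
  rp1 <- rank_product(e1, "A:normal", "B:normal", n_perm = 30, seed = 5)
  # strictly increasing transform of every replicate difference pattern:
  # scaling both conditions by a positive constant preserves all ranks
  e2 <- dplyr::mutate(e1, expr = 3 * expr + 10)
  rp2 <- rank_product(e2, "A:normal", "B:normal", n_perm = 30, seed = 5)
  expect_equal(rp1$rp_up, rp2$rp_up)
  expect_equal(rp1$pfp_up, rp2$pfp_up)
})

test_that("pfp is non-decreasing along the rank-product ordering", {
  set.seed(42)
  tags <- sprintf("g%d", 1:50)
  e <- toy_expression(tags, list("A:normal" = matrix(rnorm(150), 50, 3),
                                 "B:normal" = matrix(rnorm(150), 50, 3)))
  rp <- rank_product(e, "A:normal", "B:normal", n_perm = 100, seed = 2)
  ord <- order(rp$rp_up)
  expect_true(all(diff(rp$pfp_up[ord]) > -1e-9))
})

test_that("null data yields a conservative pfp call rate and spikes are
          recovered", {
  set.seed(43)
  rates <- vapply(1:5, function(s) {
    tags <- sprintf("g%d", 1:200)
    e <- toy_expression(tags,
                        list("A:normal" = matrix(rnorm(600, sd = 0.1), 200, 3),
                             "B:normal" = matrix(rnorm(600, sd = 0.1), 200, 3)))
    rp <- rank_product(e, "A:normal", "B:normal", n_perm = 100, seed = s)
    nrow(call_degs(rp, 0.05)) / 200
  }, numeric(1))
  expect_lte(mean(rates), 0.08)

  # spike recovery: 20 of 200 genes shifted by 0.5 log10
  recalls <- vapply(1:3, function(s) {
    set.seed(100 + s)
    base <- matrix(rnorm(600, sd = 0.1), 200, 3)
    shifted <- matrix(rnorm(600, sd = 0.1), 200, 3)
    spike <- sample(200, 20)
    shifted[spike, ] <- shifted[spike, ] +
      sample(c(-0.5, 0.5), 20, replace = TRUE)
    e <- toy_expression(sprintf("g%d", 1:200),
                        list("A:normal" = base, "B:normal" = shifted))
    rp <- rank_product(e, "A:normal", "B:normal", n_perm = 100, seed = s)
    degs <- call_degs(rp, 0.05)
    mean(sprintf("g%d", spike) %in% degs$locus_tag)
  }, numeric(1))
  expect_gte(mean(recalls), 0.9)
})

test_that("DEG calling respects the cutoff and is monotone in it", {
  set.seed(44)
  tags <- sprintf("g%d", 1:50)
  e <- toy_expression(tags, list("A:normal" = matrix(rnorm(150), 50, 3),
                                 "B:normal" = matrix(rnorm(150, 0.5), 50, 3)))
  rp <- rank_product(e, "A:normal", "B:normal", n_perm = 100, seed = 3)
  expect_equal(nrow(call_degs(rp, 0)), 0)
  sets <- lapply(c(0.01, 0.05, 0.2), function(q) call_degs(rp, q)$locus_tag)
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
  # a gene never carries both directions
  degs <- call_degs(rp, 0.2)
  expect_equal(anyDuplicated(degs$locus_tag), 0)
})

test_that("DEG overlap bookkeeping counts concordant and reversed genes", {
  a <- tibble::tibble(locus_tag = c("x", "y", "z"),
                      direction = c("up", "down", "up"))
  expect_equal(overlap_degs(a, a)$summary$n_overlap, 3)
  expect_equal(overlap_degs(a, a)$summary$n_same_direction, 3)

  b <- tibble::tibble(locus_tag = c("q", "r"), direction = c("up", "up"))
  expect_equal(overlap_degs(a, b)$summary$n_overlap, 0)

  c_ <- tibble::tibble(locus_tag = c("x", "y"), direction = c("up", "up"))
  ol <- overlap_degs(a, c_)
  expect_equal(ol$summary$n_overlap, 2)
  expect_equal(ol$summary$n_reversed, 1)
  expect_equal(ol$genes$locus_tag[!ol$genes$concordant], "y")
})
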