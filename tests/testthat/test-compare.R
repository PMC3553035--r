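# exhaustive enumeration oracle for the two-sample rank-sum P-value
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2  # Mann-Whitney U of A
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, function(idx) {
    sum(ranks[idx]) - n * (n + 1) / 2
  })
  mu <- length(a) * length(b) / 2
  mean(abs(u_all - mu) >= abs(obs - mu) - 1e-9)
}

test_that("identical groups are not distinguished", {
  x <- c(5, 9, 13, 21)
  res <- scar_distance_test(x, x)
  expect_gt(res$p_value, 0.9)
})

test_that("the exact rank-sum P equals full enumeration on small groups", {
  res <- scar_distance_test(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, enumerate_ranksum_p(c(1, 2, 3), c(10, 20, 30)))

  set.seed(61)
  for (i in 1:10) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- sample(1000, na); b <- sample(2000, nb) / 2 + 0.25
    res <- scar_distance_test(a, b)
    expect_equal(res$p_value, enumerate_ranksum_p(a, b), tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact P within 0.02 for n <= 10", {
  set.seed(62)
  for (i in 1:10) {
    a <- sample(1e6, sample(5:10, 1))
    b <- sample(1e6, sample(5:10, 1)) + 0.5
    exact_p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = TRUE)$p.value)
    approx_p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})

test_that("a planted 5-kb shift is detected with high power", {
  set.seed(63)
  detected <- vapply(1:10, function(s) {
    a <- runif(100, 0, 2e4)
    b <- a + 5000
    scar_distance_test(a, b)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(detected), 0.9)
  expect_error(scar_distance_test(numeric(0), 1:3), "non-empty")
})

test_that("delta_t matches hand subtraction and is linear", {
  tags <- c("x", "y", "z")
  mk <- function(pn, ph, rn, rh) {
    dplyr::bind_rows(
      tibble::tibble(locus_tag = tags, strain = "parent",
                     condition = "normal", mean_expr = pn, n_replicates = 1),
      tibble::tibble(locus_tag = tags, strain = "parent",
                     condition = "heatshock", mean_expr = ph,
                     n_replicates = 1),
      tibble::tibble(locus_tag = tags, strain = "reduced",
                     condition = "normal", mean_expr = rn, n_replicates = 1),
      tibble::tibble(locus_tag = tags, strain = "reduced",
                     condition = "heatshock", mean_expr = rh,
                     n_replicates = 1)
    )
  }
  m <- mk(c(1, 2, 3), c(2, 2, 5), c(0, 3, 3), c(1.5, 3.5, 4))
  dt <- delta_t(m)
  expect_equal(dt$dt_genomic, c(0, 3, 3) - c(1, 2, 3))
  expect_equal(dt$dt_environment, c(2, 2, 5) - c(1, 2, 3))
  expect_equal(dt$dt_simultaneous, c(1.5, 3.5, 4) - c(1, 2, 3))

  # equal conditions: all deltas vanish
  m0 <- mk(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  dt0 <- delta_t(m0)
  expect_true(all(abs(c(dt0$dt_genomic, dt0$dt_environment,
                        dt0$dt_simultaneous)) < 1e-14))

  # linearity: delta_t of summed inputs = sum of delta_t outputs
  m1 <- mk(c(1, 0, 2), c(0, 1, 1), c(2, 2, 2), c(1, 1, 1))
  m2 <- mk(c(0, 1, 1), c(1, 0, 3), c(0, 1, 0), c(2, 0, 2))
  msum <- m1
  msum$mean_expr <- m1$mean_expr + m2$mean_expr
  dsum <- delta_t(msum)
  d1 <- delta_t(m1); d2 <- delta_t(m2)
  expect_equal(dsum$dt_genomic, d1$dt_genomic + d2$dt_genomic)
  expect_equal(dsum$dt_simultaneous,
               d1$dt_simultaneous + d2$dt_simultaneous)
})

test_that("correlation comparison recovers planted correlations and is
          calm when subset equals universe", {
  set.seed(64)
  n <- 2000
  z <- rnorm(n)
  x <- z + rnorm(n, sd = sqrt(1 / 0.8^2 - 1))
  pairs <- tibble::tibble(locus_tag = sprintf("g%d", 1:n),
                          x = x, y = z)
  res <- correlation_comparison(pairs, pairs$locus_tag, n_boot = 200,
                                seed = 1, label = "all")
  expect_lt(abs(res$r_universe - 0.8), 0.03)
  expect_gt(res$p_value, 0.5)

  # y = x exactly
  idpairs <- tibble::tibble(locus_tag = sprintf("g%d", 1:50),
                            x = rnorm(50))
  idpairs$y <- idpairs$x
  res_id <- correlation_comparison(idpairs, idpairs$locus_tag[1:10],
                                   n_boot = 100, seed = 2)
  expect_equal(res_id$r_subset, 1)
  expect_equal(res_id$r_universe, 1)
  expect_error(
    correlation_comparison(idpairs, idpairs$locus_tag[1:2], n_boot = 100),
    "at least 3"
  )
})
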