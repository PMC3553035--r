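test_that("reconciliation classifies toy genomes and handles identity", {
  parent <- toy_annotation(10)
  # delete g003, g007; mutate g005
  reduced_genes <- as.data.frame(parent)[-c(3, 7), ]
  reduced <- genome_annotation(reduced_genes, "reduced", 1000)
  cmp <- reconcile_genomes(parent, reduced, mutated_tags = "g005")
  expect_setequal(cmp$deleted, c("g003", "g007"))
  expect_equal(cmp$mutated, "g005")
  expect_length(cmp$common, 7)

  same <- reconcile_genomes(parent, parent)
  expect_length(same$common, 10)
  expect_equal(nrow(same$scars), 0)
})

test_that("repeated locus tags keep the first occurrence in genome order", {
  tags <- c("a", "b", "b", "c")
  ann <- toy_annotation(4, tags = tags)
  cmp <- reconcile_genomes(ann, ann)
  expect_equal(nrow(cmp$classification), 3)
  # the surviving 'b' is the earlier one
  expect_equal(cmp$classification$start[cmp$classification$locus_tag == "b"],
               101)
})

test_that("oriC is excluded unless requested", {
  ann <- toy_annotation(5, tags = c("g1", "g2", "oriC", "g4", "g5"))
  cmp <- reconcile_genomes(ann, ann)
  expect_length(cmp$common, 4)
  cmp_ori <- reconcile_genomes(ann, ann, include_ori = TRUE)
  expect_length(cmp_ori$common, 5)
})

test_that("reconciliation errors are informative", {
  parent <- toy_annotation(5)
  expect_error(reconcile_genomes(parent, parent, mutated_tags = "zzz"), "zzz")
  expect_error(genome_annotation(tibble::tibble(), "x", 100), "missing column")
})

test_that("partition property holds across random reconciliations", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    parent <- toy_annotation(n)
    drop <- sample(n, sample(0:(n - 1), 1))
    reduced_genes <- as.data.frame(parent)
    if (length(drop) > 0) reduced_genes <- reduced_genes[-drop, ]
    if (nrow(reduced_genes) == 0) next
    kept <- setdiff(parent$locus_tag, parent$locus_tag[drop])
    mut <- sample(kept, min(2, length(kept)))
    cmp <- reconcile_genomes(parent,
                             genome_annotation(reduced_genes, "r", n * 100),
                             mutated_tags = mut)
    expect_equal(
      length(cmp$common) + length(cmp$deleted) + length(cmp$mutated), n
    )
    expect_length(intersect(cmp$common, cmp$deleted), 0)
  }
})

test_that("scars derived from consecutive deleted genes merge runs", {
  parent <- toy_annotation(10)
  reduced_genes <- as.data.frame(parent)[-c(3, 4, 8), ]
  cmp <- reconcile_genomes(parent,
                           genome_annotation(reduced_genes, "r", 1000))
  expect_equal(nrow(cmp$scars), 2)
  expect_equal(cmp$scars$start, c(201, 701))
  expect_equal(cmp$scars$end, c(380, 780))
})

test_that("scar distance follows the wrap-around path and boundary rules", {
  scars <- tibble::tibble(label = "s1", start = 990, end = 995)
  # wrap-around beats the long way round
  expect_equal(distance_to_nearest_scar(10, 10, scars, 1000), 15)
  # overlap and shared boundary are distance zero
  expect_equal(distance_to_nearest_scar(992, 993, scars, 1000), 0)
  expect_equal(distance_to_nearest_scar(980, 990, scars, 1000), 0)
  # gene wholly inside a dominating scar
  big <- tibble::tibble(label = "s", start = 1, end = 999)
  expect_equal(distance_to_nearest_scar(500, 510, big, 1000), 0)
  # empty scar list errors
  expect_error(
    distance_to_nearest_scar(1, 5, tibble::tibble(label = character(),
                                                  start = numeric(),
                                                  end = numeric()), 1000),
    "no scars"
  )
})

test_that("scar distance matches a brute-force base-to-base oracle", {
  set.seed(42)
  len <- 300
  for (i in 1:25) {
    gs <- sample(len, 1)
    ge <- (gs + sample(0:20, 1) - 1) %% len + 1  # may wrap
    ss <- sample(len, 1)
    se <- min(len, ss + sample(0:15, 1))
    scars <- tibble::tibble(label = "s", start = ss, end = se)
    got <- distance_to_nearest_scar(gs, ge, scars, len)
    want <- brute_interval_distance(gs, ge, ss, se, len)
    expect_equal(got, want, info = sprintf("gene [%d,%d] scar [%d,%d]",
                                           gs, ge, ss, se))
    expect_lte(got, len / 2)
  }
})

test_that("coordinate compaction shifts genes by preceding deleted length", {
  parent <- toy_annotation(10)  # genes at 1,101,...,901, len 80
  scars <- tibble::tibble(label = c("a", "b"),
                          start = c(95, 405), end = c(104, 490))
  red <- compact_genome(parent, scars)
  # g001 untouched; g002 overlaps scar a; g005 overlaps scar b
  expect_false("g002" %in% red$locus_tag)
  expect_false("g005" %in% red$locus_tag)
  expect_equal(genome_length(red), 1000 - 10 - 86)
  g3 <- red[red$locus_tag == "g003", ]
  expect_equal(g3$start, 201 - 10)
  g6 <- red[red$locus_tag == "g006", ]
  expect_equal(g6$start, 501 - 10 - 86)
})
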