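# small builders shared across test files

toy_annotation <- function(n = 10, gene_len = 80, spacing = 100,
                           genome_length = n * spacing, id = "parent",
                           tags = sprintf("g%03d", seq_len(n))) {
  start <- (seq_len(n) - 1) * spacing + 1
  genome_annotation(
    tibble::tibble(
      locus_tag = tags,
      name = tags,
      start = start,
      end = start + gene_len - 1,
      strand = rep(c("+", "-"), length.out = n),
      category = rep(sprintf("C%02d", 1:5), length.out = n)
    ),
    genome_id = id, genome_length = genome_length
  )
}

# long expression tibble from a named list of per-condition replicate
# matrices: cells[["strain:condition"]] is genes x replicates
toy_expression <- function(tags, cells) {
  rows <- lapply(names(cells), function(nm) {
    sc <- strsplit(nm, ":", fixed = TRUE)[[1]]
    m <- cells[[nm]]
    do.call(rbind, lapply(seq_len(ncol(m)), function(r) {
      tibble::tibble(
        locus_tag = tags,
        sample_id = paste(sc[1], sc[2], r, sep = "_"),
        strain = sc[1], condition = sc[2], replicate = r,
        expr = m[, r]
      )
    }))
  })
  dplyr::bind_rows(rows)
}

# brute-force circular base-to-base distance between two closed intervals
brute_interval_distance <- function(gs, ge, ss, se, len) {
  gene_bases <- if (gs <= ge) gs:ge else c(gs:len, 1:ge)
  scar_bases <- ss:se
  d <- outer(gene_bases, scar_bases, function(a, b) {
    pmin((a - b) %% len, (b - a) %% len)
  })
  min(d)
}

# small planted-periodicity study used by periodicity + deletion-null tests
small_periodic_spec <- function(..., seed = 7) {
  synthetic_spec(
    genome_length = 1e6, n_genes = 950, gene_length = 900,
    lambda = round(1e6 / 7), amplitude = 0.2, sigma = 0.1,
    n_segments = 0, n_spiked = 0, delta = 0, seed = seed, ...
  )
}
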