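#' Specification for a synthetic genome-reduction study
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' mirror the dimensions of a genome-reduced *E. coli* study: a 4.64-Mb
#' circular chromosome carrying ~4400 tagged genes, ~40 deletion segments
#' totalling ~0.7 Mb, a sinusoidal positional expression component whose
#' wavelength fits the chromosome seven times (663 kb), log10-scale
#' expression with condition effects, spike-in differentially expressed
#' genes, and a simultaneous-perturbation condition built with a known
#' epistasis coefficient.
#'
#' @param genome_length Chromosome length in bp.
#' @param n_genes Number of tagged genes tiled on the chromosome.
#' @param gene_length Gene length in bp (genes are tiled with even spacing).
#' @param n_segments Number of deletion segments.
#' @param segment_length_meanlog,segment_length_sdlog Log-normal parameters
#'   for segment lengths (bp).
#' @param segments Optional explicit segment tibble (`label`, `start`,
#'   `end`); overrides random placement.
#' @param lambda Wavelength of the positional sinusoid, bp.
#' @param amplitude Amplitude of the positional sinusoid, log10 units.
#' @param baseline_mean,gene_sd Mean and between-gene s.d. of baseline
#'   expression (log10 pM).
#' @param rho Correlation between the per-gene genomic effect (ΔT from
#'   genome reduction) and environmental effect (ΔT from heat shock).
#' @param dt_sd Standard deviation of each per-gene condition effect (log10).
#' @param n_spiked Spike-in DEGs per perturbation.
#' @param delta Spike effect size, log10 units (random sign per gene).
#' @param alpha Epistasis coefficient used to build the
#'   simultaneous-perturbation condition: its mean expression is
#'   `baseline + (1 + alpha) * (dT_genomic + dT_environmental)`.
#' @param alpha_spiked Epistasis coefficient applied to the spiked (DEG)
#'   genes; defaults to `alpha`. Setting it more negative plants a stronger
#'   compression on the DEG union.
#' @param sigma Replicate noise s.d. (log10).
#' @param n_reps_normal,n_reps_heatshock Replicates per condition.
#' @param n_gene_sets,set_size_range Random regulon-style gene sets emitted
#'   for enrichment testing.
#' @param seed Integer seed; the generator is deterministic given the spec.
#'
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = 4641652,
                           n_genes = 4406,
                           gene_length = 900,
                           n_segments = 40,
                           segment_length_meanlog = log(15000),
                           segment_length_sdlog = 0.5,
                           segments = NULL,
                           lambda = round(4641652 / 7),
                           amplitude = 0.2,
                           baseline_mean = 1.0,
                           gene_sd = 0.5,
                           rho = 0.6,
                           dt_sd = 0.2,
                           n_spiked = 50,
                           delta = 0.5,
                           alpha = -0.29,
                           alpha_spiked = alpha,
                           sigma = 0.1,
                           n_reps_normal = 3,
                           n_reps_heatshock = 3,
                           n_gene_sets = 20,
                           set_size_range = c(15, 120),
                           seed = 1) {
  spec <- list(
    genome_length = genome_length, n_genes = n_genes,
    gene_length = gene_length, n_segments = n_segments,
    segment_length_meanlog = segment_length_meanlog,
    segment_length_sdlog = segment_length_sdlog,
    segments = segments,
    lambda = lambda, amplitude = amplitude,
    baseline_mean = baseline_mean, gene_sd = gene_sd,
    rho = rho, dt_sd = dt_sd,
    n_spiked = n_spiked, delta = delta,
    alpha = alpha, alpha_spiked = alpha_spiked,
    sigma = sigma,
    n_reps_normal = n_reps_normal, n_reps_heatshock = n_reps_heatshock,
    n_gene_sets = n_gene_sets, set_size_range = set_size_range,
    seed = seed
  )
  if (spec$lambda >= spec$genome_length / 2) {
    abort("`lambda` must be below half the genome length")
  }
  if (spec$sigma < 0) abort("`sigma` must be non-negative")
  if (abs(spec$rho) > 1) abort("`rho` must lie in [-1, 1]")
  if (spec$n_genes < 1) abort("`n_genes` must be positive")
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a parent/reduced annotation pair with known truth
#'
#' Genes are tiled evenly on a circular chromosome; deletion segments are
#' placed uniformly at random without overlap (or taken from
#' `spec$segments`); the reduced genome is the parent with segment-overlapping
#' genes removed and coordinates compacted. Deterministic under
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `parent` and `reduced` annotations, the `scars`
#'   tibble, and the `comparison` (a `genome_comparison` ground truth).
#' @export
simulate_genome_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  slot <- floor(spec$genome_length / spec$n_genes)
  glen <- min(spec$gene_length, slot - 10)
  if (glen < 1) abort("genes do not fit: reduce `n_genes` or `gene_length`")
  start <- (seq_len(spec$n_genes) - 1) * slot + 1
  genes <- tibble(
    locus_tag = sprintf("g%05d", seq_len(spec$n_genes)),
    name = sprintf("gene%05d", seq_len(spec$n_genes)),
    start = start,
    end = start + glen - 1,
    strand = sample(c("+", "-"), spec$n_genes, replace = TRUE),
    category = sample(sprintf("C%02d", 1:23), spec$n_genes, replace = TRUE)
  )
  parent <- genome_annotation(genes, "parent", spec$genome_length)

  scars <- spec$segments
  if (is.null(scars)) {
    scars <- place_segments(
      n = spec$n_segments,
      lengths = round(stats::rlnorm(spec$n_segments,
                                    spec$segment_length_meanlog,
                                    spec$segment_length_sdlog)),
      genome_length = spec$genome_length
    )
  } else if (nrow(scars) > 0) {
    scars <- validate_segments(scars)
  }

  if (nrow(scars) == 0) {
    reduced <- genome_annotation(genes, "reduced", spec$genome_length)
  } else {
    reduced <- compact_genome(parent, scars, genome_id = "reduced")
  }
  comparison <- reconcile_genomes(parent, reduced, character(), scars = scars)
  list(parent = parent, reduced = reduced, scars = scars,
       comparison = comparison)
}

# uniform non-overlapping placement with bounded retries
place_segments <- function(n, lengths, genome_length, max_tries = 1000) {
  if (n == 0) {
    return(tibble(label = character(), start = numeric(), end = numeric()))
  }
  lengths <- pmax(1, lengths)
  if (sum(lengths) >= genome_length) {
    abort("deletion segments exceed the genome length")
  }
  placed <- tibble(label = character(), start = numeric(), end = numeric())
  for (i in seq_len(n)) {
    len <- lengths[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(genome_length - len + 1, 1)
      e <- s + len - 1
      if (nrow(placed) == 0 ||
          !any(s <= placed$end & placed$start <= e)) {
        placed <- bind_rows(placed,
                            tibble(label = sprintf("scar_%02d", i),
                                   start = s, end = e))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("could not place deletion segments without overlap after bounded retries")
    }
  }
  arrange(placed, .data$start)
}

#' Generate expression data with known ground truth
#'
#' Per-gene baseline = global mean + sinusoid of the gene's genomic position
#' + a gene-specific effect; per-gene genomic and environmental condition
#' effects are drawn bivariate-normal with correlation `rho`; spiked DEGs
#' receive an extra ±`delta`; the simultaneous condition mean is
#' `baseline + (1 + alpha) * (dT_genomic + dT_environmental)`; replicates add
#' Gaussian noise with s.d. `sigma`.
#'
#' @param spec A [synthetic_spec()].
#' @param pair Output of [simulate_genome_pair()] (parent, reduced,
#'   comparison).
#' @return A list with `expr` (long expression tibble across the four
#'   strain-by-condition cells) and `truth` (per-gene effects, spike tables,
#'   and the generating parameters).
#' @export
simulate_expression <- function(spec, pair) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(pair$parent) || is.null(pair$comparison)) {
    abort("`pair` must come from simulate_genome_pair()")
  }
  set.seed(spec$seed + 1L)
  parent <- pair$parent
  n <- nrow(parent)
  mid <- (parent$start + parent$end) / 2
  phase <- runif(1, 0, 2 * pi)
  baseline <- spec$baseline_mean +
    spec$amplitude * sin(2 * pi * mid / spec$lambda + phase) +
    rnorm(n, 0, spec$gene_sd)

  z1 <- rnorm(n)
  z2 <- rnorm(n)
  dtg <- spec$dt_sd * z1
  dte <- spec$dt_sd * (spec$rho * z1 + sqrt(1 - spec$rho^2) * z2)

  common <- pair$comparison$common
  is_common <- parent$locus_tag %in% common
  spike_gr <- spike_hs <- rep(NA_character_, n)
  n_sp <- min(spec$n_spiked, sum(is_common))
  if (n_sp > 0 && spec$delta != 0) {
    idx_gr <- sample(which(is_common), n_sp)
    sgn_gr <- sample(c(-1, 1), n_sp, replace = TRUE)
    dtg[idx_gr] <- dtg[idx_gr] + sgn_gr * spec$delta
    spike_gr[idx_gr] <- ifelse(sgn_gr > 0, "up", "down")
    idx_hs <- sample(which(is_common), n_sp)
    sgn_hs <- sample(c(-1, 1), n_sp, replace = TRUE)
    dte[idx_hs] <- dte[idx_hs] + sgn_hs * spec$delta
    spike_hs[idx_hs] <- ifelse(sgn_hs > 0, "up", "down")
  }

  alpha_gene <- ifelse(!is.na(spike_gr) | !is.na(spike_hs),
                       spec$alpha_spiked, spec$alpha)

  cond_mean <- list(
    parent_normal = baseline,
    parent_heatshock = baseline + dte,
    reduced_normal = baseline + dtg,
    reduced_heatshock = baseline + (1 + alpha_gene) * (dtg + dte)
  )

  rows <- list()
  for (strain in c("parent", "reduced")) {
    keep <- if (strain == "parent") rep(TRUE, n) else is_common
    for (condition in c("normal", "heatshock")) {
      mu <- cond_mean[[paste(strain, condition, sep = "_")]][keep]
      n_rep <- if (condition == "normal") spec$n_reps_normal else
        spec$n_reps_heatshock
      for (r in seq_len(n_rep)) {
        rows[[length(rows) + 1]] <- tibble(
          locus_tag = parent$locus_tag[keep],
          sample_id = paste(strain, condition, r, sep = "_"),
          strain = strain, condition = condition, replicate = r,
          expr = mu + rnorm(sum(keep), 0, spec$sigma)
        )
      }
    }
  }
  expr <- bind_rows(rows)

  truth_genes <- tibble(
    locus_tag = parent$locus_tag,
    position = mid,
    common = is_common,
    baseline = baseline,
    dt_genomic = dtg,
    dt_environment = dte,
    spiked_gr = spike_gr,
    spiked_hs = spike_hs,
    alpha_gene = alpha_gene
  )
  list(
    expr = expr,
    truth = list(
      genes = truth_genes,
      lambda = spec$lambda, phase = phase,
      alpha = spec$alpha, alpha_spiked = spec$alpha_spiked
    )
  )
}

#' Generate random regulon-style gene sets
#'
#' @param spec A [synthetic_spec()].
#' @param universe Character vector of gene tags to draw from.
#' @return A named list of character vectors (a gene-set collection).
#' @export
simulate_gene_sets <- function(spec, universe) {
  set.seed(spec$seed + 2L)
  sizes <- sample(seq(spec$set_size_range[1], spec$set_size_range[2]),
                  spec$n_gene_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(universe, min(k, length(universe))))
  names(sets) <- sprintf("regulon_%02d", seq_along(sets))
  sets
}

#' Run the whole generator
#'
#' Convenience wrapper: genome pair, expression, and gene sets in one call.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `parent`, `reduced`, `scars`, `comparison`, `expr`,
#'   `truth`, `gene_sets`.
#' @export
simulate_study <- function(spec) {
  pair <- simulate_genome_pair(spec)
  ex <- simulate_expression(spec, pair)
  sets <- simulate_gene_sets(spec, pair$comparison$common)
  c(pair, ex, list(gene_sets = sets))
}

#' Write a synthetic study to disk in the formats the readers consume
#'
#' Emits GFF3 annotations, the scar TSV, the wide expression TSV plus
#' metadata TSV, a GMT of gene sets, and truth tables.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation(study$parent, file.path(dir, "parent.gff3"))
  write_annotation(study$reduced, file.path(dir, "reduced.gff3"))
  readr::write_tsv(study$scars, file.path(dir, "scars.tsv"))
  write_expression(study$expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "samples.tsv"))
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  readr::write_tsv(study$truth$genes, file.path(dir, "truth_genes.tsv"))
  jsonlite::write_json(
    study$truth[c("lambda", "phase", "alpha", "alpha_spiked")],
    file.path(dir, "truth_params.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
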