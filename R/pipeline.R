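pipeline_defaults <- function() {
  list(
    parent_annotation = NULL, reduced_annotation = NULL,
    expression = NULL, metadata = NULL,
    gene_sets = NULL, scar_table = NULL, mutated_tags = NULL,
    parent_genome_length = NULL, reduced_genome_length = NULL,
    bin_size = 100, window = 500,
    min_wavelength = 1e5, max_wavelength = NULL,
    n_perm_deg = 1000, n_perm_gsea = 1000, n_perm_deletion = 999,
    n_boot = 1000,
    fdr_deg = 0.001, fdr_gsea = 0.25, gsea_min_size = 15,
    deletion_statistic = "period_count",
    seed = 1, out_dir = "gxe_output"
  )
}

#' Validate a pipeline configuration
#'
#' @param config A named list, or the path of a YAML file holding one.
#' @return The completed configuration list (defaults filled in), or an
#'   error if a referenced file is missing or a cutoff is out of range.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  required <- c("parent_annotation", "reduced_annotation", "expression",
                "metadata")
  for (key in required) {
    if (is.null(cfg[[key]])) abort(paste0("config is missing `", key, "`"))
  }
  for (key in c(required, "gene_sets", "scar_table", "mutated_tags")) {
    path <- cfg[[key]]
    if (!is.null(path) && !file.exists(path)) {
      abort(paste0("config file for `", key, "` does not exist: ", path))
    }
  }
  for (key in c("fdr_deg", "fdr_gsea")) {
    if (cfg[[key]] <= 0 || cfg[[key]] >= 1) {
      abort(paste0("`", key, "` must lie in (0, 1)"))
    }
  }
  cfg
}

stage_seed <- function(master, stage_index) {
  (as.integer(master) + 101L * as.integer(stage_index)) %% .Machine$integer.max
}

#' Run the full comparative-transcriptome pipeline
#'
#' Orchestrates every analysis stage from a configuration: genome
#' reconciliation, condition averaging, chromosomal periodicity of all four
#' strain-by-condition cells, the random-deletion null, rank-product DEG
#' calling for the genome-reduction and heat-shock contrasts, regulon GSEA
#' and category enrichment, scar-distance and correlation statistics, and
#' the epistasis fit. Stage outputs are written to `out_dir` as TSV/JSON,
#' plus a single machine-readable `summary.json`. Fully deterministic under
#' the configured seed (each random stage gets a seed derived from the
#' master seed).
#'
#' @param config Named list or YAML path; see [validate_config()] for the
#'   recognised fields.
#' @return The summary list, invisibly (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(parameters = cfg[!vapply(cfg, is.null, logical(1))])

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # --- genomes -------------------------------------------------------------
  parent <- run_stage("annotation", function() {
    read_annotation(cfg$parent_annotation, genome_id = "parent",
                    genome_length = cfg$parent_genome_length)
  })
  reduced <- read_annotation(cfg$reduced_annotation, genome_id = "reduced",
                             genome_length = cfg$reduced_genome_length)
  scars <- if (!is.null(cfg$scar_table)) {
    read_deletion_segments(cfg$scar_table)
  } else {
    NULL
  }
  mutated <- if (!is.null(cfg$mutated_tags)) {
    readLines(cfg$mutated_tags)
  } else {
    character()
  }
  comparison <- run_stage("reconcile", function() {
    reconcile_genomes(parent, reduced, mutated, scars = scars)
  })
  write_comparison(comparison,
                   json_path = file.path(cfg$out_dir, "comparison.json"),
                   tsv_path = file.path(cfg$out_dir, "classification.tsv"))
  summary$reconciliation <- as.list(glance(comparison))

  # --- expression ----------------------------------------------------------
  expr <- run_stage("expression", function() {
    read_expression(cfg$expression, cfg$metadata)
  })
  means <- condition_means(expr)

  # --- periodicity ---------------------------------------------------------
  summary$periodicity <- list()
  cells <- expand.grid(strain = c("parent", "reduced"),
                       condition = c("normal", "heatshock"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    st <- cells$strain[i]
    cc <- cells$condition[i]
    ann <- if (st == "parent") parent else reduced
    vals <- condition_mean_vector(means, st, cc)
    vals <- vals[vals$locus_tag %in% ann$locus_tag, ]
    prof <- bin_expression(vals, ann, bin_size = cfg$bin_size)
    prof <- smooth_profile(prof, window = cfg$window)
    pg <- periodogram(prof, min_wavelength = cfg$min_wavelength,
                      max_wavelength = cfg$max_wavelength)
    readr::write_tsv(as_tibble(pg),
                     file.path(cfg$out_dir,
                               sprintf("periodogram_%s_%s.tsv", st, cc)))
    pk <- major_peak(pg)
    summary$periodicity[[paste(st, cc, sep = "_")]] <- list(
      major_peak_wavelength = pk$wavelength,
      major_peak_power = pk$power,
      significant = pk$significant,
      n_periods = count_periods(attr(pg, "span"), pk$wavelength)
    )
  }

  # --- random-deletion null ------------------------------------------------
  if (!is.null(scars) && nrow(scars) > 0) {
    dn <- run_stage("deletion_null", function() {
      random_deletion_test(
        parent, condition_mean_vector(means, "parent", "normal"),
        scars, statistic = cfg$deletion_statistic,
        n_perm = cfg$n_perm_deletion,
        bin_size = cfg$bin_size, window = cfg$window,
        min_wavelength = cfg$min_wavelength,
        max_wavelength = cfg$max_wavelength,
        seed = stage_seed(cfg$seed, 1)
      )
    })
    summary$deletion_null <- as.list(glance(dn))
  }

  # --- differential expression --------------------------------------------
  common_expr <- filter(expr, .data$locus_tag %in% comparison$common)
  rp_gr <- run_stage("deg_gr", function() {
    rank_product(common_expr, a = "parent:normal", b = "reduced:normal",
                 n_perm = cfg$n_perm_deg, seed = stage_seed(cfg$seed, 2))
  })
  rp_hs <- rank_product(common_expr, a = "parent:normal",
                        b = "parent:heatshock",
                        n_perm = cfg$n_perm_deg,
                        seed = stage_seed(cfg$seed, 3))
  readr::write_tsv(as_tibble(rp_gr), file.path(cfg$out_dir, "rank_product_gr.tsv"))
  readr::write_tsv(as_tibble(rp_hs), file.path(cfg$out_dir, "rank_product_hs.tsv"))
  degs_gr <- call_degs(rp_gr, cfg$fdr_deg)
  degs_hs <- call_degs(rp_hs, cfg$fdr_deg)
  ol <- overlap_degs(degs_gr, degs_hs)
  summary$degs <- list(
    n_gr = nrow(degs_gr), n_gr_up = sum(degs_gr$direction == "up"),
    n_gr_down = sum(degs_gr$direction == "down"),
    n_hs = nrow(degs_hs), n_hs_up = sum(degs_hs$direction == "up"),
    n_hs_down = sum(degs_hs$direction == "down"),
    overlap = as.list(ol$summary)
  )

  # --- enrichment ----------------------------------------------------------
  if (!is.null(cfg$gene_sets)) {
    sets <- read_gmt(cfg$gene_sets)
    common_means <- filter(means, .data$locus_tag %in% comparison$common)
    score_gr <- delta_scores(common_means, "reduced", "normal",
                             "parent", "normal")
    score_hs <- delta_scores(common_means, "parent", "heatshock",
                             "parent", "normal")
    gsea_gr <- preranked_gsea(score_gr, sets, n_perm = cfg$n_perm_gsea,
                              min_size = cfg$gsea_min_size,
                              seed = stage_seed(cfg$seed, 4))
    gsea_hs <- preranked_gsea(score_hs, sets, n_perm = cfg$n_perm_gsea,
                              min_size = cfg$gsea_min_size,
                              seed = stage_seed(cfg$seed, 5))
    networks <- bind_rows(
      mutate(as_tibble(gsea_gr), perturbation = "genome_reduction"),
      mutate(as_tibble(gsea_hs), perturbation = "heat_shock")
    )
    readr::write_tsv(networks, file.path(cfg$out_dir, "gsea_networks.tsv"))
    summary$networks <- as.data.frame(
      count_enriched_networks(networks, cfg$fdr_gsea))
  }

  if (!all(is.na(parent$category))) {
    cats <- select(as_tibble(as.data.frame(parent)), "locus_tag", "category")
    cats <- filter(cats, .data$locus_tag %in% comparison$common)
    enr <- binomial_category_enrichment(
      filter(degs_gr, .data$locus_tag %in% comparison$common),
      cats, comparison$common
    )
    readr::write_tsv(enr, file.path(cfg$out_dir, "category_enrichment_gr.tsv"))
  }

  # --- scar distances and correlations ------------------------------------
  if (!is.null(scars) && nrow(scars) > 0) {
    cl <- comparison$classification
    common_cl <- cl[cl$status == "common", ]
    dist <- scar_distances(common_cl, comparison$scars,
                           comparison$genome_length)
    is_deg <- dist$locus_tag %in% degs_gr$locus_tag
    if (any(is_deg) && any(!is_deg)) {
      dt_test <- scar_distance_test(dist$scar_distance[is_deg],
                                    dist$scar_distance[!is_deg],
                                    labels = c("DEGs_gr", "nonDEGs"))
      summary$scar_distance <- as.list(dt_test)
    }
    readr::write_tsv(mutate(dist, deg_gr = is_deg),
                     file.path(cfg$out_dir, "scar_distances.tsv"))
  }

  dtab <- delta_t(means)
  pairs_env <- pair_table(means, "parent", "normal", "parent", "heatshock")
  if (nrow(degs_gr) >= 3) {
    summary$correlation_gr <- as.list(
      correlation_comparison(pairs_env, degs_gr$locus_tag,
                             n_boot = cfg$n_boot,
                             seed = stage_seed(cfg$seed, 6),
                             label = "DEGs_gr")
    )
  }
  pairs_gen <- pair_table(means, "parent", "normal", "reduced", "normal")
  if (nrow(degs_hs) >= 3) {
    summary$correlation_hs <- as.list(
      correlation_comparison(pairs_gen, degs_hs$locus_tag,
                             n_boot = cfg$n_boot,
                             seed = stage_seed(cfg$seed, 7),
                             label = "DEGs_hs")
    )
  }

  # --- epistasis -----------------------------------------------------------
  fit_all <- estimate_alpha(dtab$dt_genomic + dtab$dt_environment,
                            dtab$dt_simultaneous,
                            n_boot = cfg$n_boot,
                            seed = stage_seed(cfg$seed, 8),
                            subset_label = "all common")
  summary$epistasis_all <- as.list(glance(fit_all))
  deg_union <- union(degs_gr$locus_tag, degs_hs$locus_tag)
  if (length(deg_union) >= 3) {
    sub <- dtab[dtab$locus_tag %in% deg_union, ]
    fit_deg <- estimate_alpha(sub$dt_genomic + sub$dt_environment,
                              sub$dt_simultaneous,
                              n_boot = cfg$n_boot,
                              seed = stage_seed(cfg$seed, 9),
                              subset_label = "DEG union")
    summary$epistasis_deg_union <- as.list(glance(fit_deg))
  }
  readr::write_tsv(dtab, file.path(cfg$out_dir, "delta_t.tsv"))

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}

delta_scores <- function(means, s1, c1, s2, c2) {
  a <- condition_mean_vector(means, s1, c1)
  b <- condition_mean_vector(means, s2, c2)
  joined <- inner_join(a, b, by = "locus_tag", suffix = c("_a", "_b"))
  tibble(locus_tag = joined$locus_tag,
         score = joined$mean_expr_a - joined$mean_expr_b)
}

pair_table <- function(means, sx, cx, sy, cy) {
  x <- condition_mean_vector(means, sx, cx)
  y <- condition_mean_vector(means, sy, cy)
  joined <- inner_join(x, y, by = "locus_tag", suffix = c("_x", "_y"))
  tibble(locus_tag = joined$locus_tag,
         x = joined$mean_expr_x, y = joined$mean_expr_y)
}
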