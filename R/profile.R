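#' Project per-gene expression onto genome-position bins
#'
#' Each gene's expression value is assigned to every bin its coordinates
#' overlap. Bins covered by several genes hold the mean of the contributing
#' values; bins covered by no gene hold the genome-wide mean expression (so
#' annotation gaps do not inject spurious low-frequency power). The profile
#' is circular: genes wrapping the origin contribute to bins at both ends.
#'
#' @param values A data frame with columns `locus_tag` and a value column
#'   (default `mean_expr`) of per-gene expression.
#' @param annotation A [genome_annotation()] containing every gene in
#'   `values`.
#' @param bin_size Bin width in bp (default 100).
#' @param value_col Name of the value column in `values`.
#' @return A tibble of class `binned_profile` with columns `bin`, `start`
#'   (bp of the bin's first base) and `value`, and attributes `bin_size`,
#'   `genome_length`, `span` (`n_bins * bin_size`), `smoothed`.
#' @export
bin_expression <- function(values, annotation, bin_size = 100,
                           value_col = "mean_expr") {
  if (!value_col %in% names(values)) {
    abort(paste0("`values` has no column '", value_col, "'"))
  }
  len <- genome_length(annotation)
  n_bins <- ceiling(len / bin_size)
  idx <- match(values$locus_tag, annotation$locus_tag)
  if (anyNA(idx)) {
    abort(paste0("gene(s) missing coordinates in the annotation: ",
                 paste(head(values$locus_tag[is.na(idx)], 5), collapse = ", ")))
  }
  gs <- annotation$start[idx]
  ge <- annotation$end[idx]
  v <- values[[value_col]]

  # split origin-wrapping genes into two arcs
  wrap <- gs > ge
  if (any(wrap)) {
    gs <- c(gs[!wrap], gs[wrap], rep(1, sum(wrap)))
    ge <- c(ge[!wrap], rep(len, sum(wrap)), ge[wrap])
    v <- c(v[!wrap], v[wrap], v[wrap])
  }
  b1 <- (gs - 1) %/% bin_size + 1
  b2 <- (ge - 1) %/% bin_size + 1
  counts <- b2 - b1 + 1
  bins <- sequence(counts) - 1L + rep(b1, counts)
  vals <- rep(v, counts)

  sums <- numeric(n_bins)
  hits <- numeric(n_bins)
  agg <- rowsum(vals, bins)
  where <- as.integer(rownames(agg))
  sums[where] <- agg[, 1]
  hits[where] <- tabulate(bins, n_bins)[where]

  out <- ifelse(hits > 0, sums / pmax(hits, 1), mean(values[[value_col]]))
  structure(
    tibble(bin = seq_len(n_bins),
           start = (seq_len(n_bins) - 1) * bin_size + 1,
           value = out),
    bin_size = bin_size,
    genome_length = len,
    span = n_bins * bin_size,
    smoothed = FALSE,
    window = NA_integer_,
    class = c("binned_profile", class(tibble()))
  )
}

#' Construct a binned profile from an already-binned series
#'
#' Wraps a numeric vector of per-bin values (e.g. a simulated or externally
#' binned series) as a `binned_profile` so it can be smoothed and
#' spectrum-analysed.
#'
#' @param values Numeric vector of per-bin values, in genome order.
#' @param bin_size Bin width in bp.
#' @param genome_length Chromosome length in bp (default
#'   `length(values) * bin_size`).
#' @param smoothed Mark the profile as already smoothed?
#' @return A `binned_profile` tibble.
#' @export
binned_profile <- function(values, bin_size = 100,
                           genome_length = length(values) * bin_size,
                           smoothed = FALSE) {
  n <- length(values)
  structure(
    tibble(bin = seq_len(n),
           start = (seq_len(n) - 1) * bin_size + 1,
           value = as.numeric(values)),
    bin_size = bin_size,
    genome_length = genome_length,
    span = n * bin_size,
    smoothed = smoothed,
    window = NA_integer_,
    class = c("binned_profile", class(tibble()))
  )
}

#' Circular moving-average smoothing of a binned profile
#'
#' Centred moving average with wrap-around (the chromosome is circular).
#' An even window is widened by one bin so the window is symmetric. The
#' profile mean is preserved exactly.
#'
#' @param profile A [bin_expression()] profile.
#' @param window Window width in bins (default 500, i.e. 50 kb at 100-bp
#'   bins).
#' @return A smoothed `binned_profile`.
#' @export
smooth_profile <- function(profile, window = 500) {
  n <- nrow(profile)
  if (window >= n) abort("`window` must be smaller than the number of bins")
  if (window < 1) abort("`window` must be at least 1")
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) {
    out <- profile
    attr(out, "smoothed") <- TRUE
    attr(out, "window") <- w
    return(out)
  }
  h <- (w - 1L) %/% 2L
  x <- profile$value
  xx <- c(x[(n - h + 1):n], x, x[1:h])
  cs <- c(0, cumsum(xx))
  sm <- (cs[(1:n) + w] - cs[1:n]) / w
  out <- profile
  out$value <- sm
  attr(out, "smoothed") <- TRUE
  attr(out, "window") <- w
  out
}
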