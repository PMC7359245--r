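#' Scan a population of methylomes for per-site JSD and MET
#'
#' Position-synchronous scan over many per-sample methylation tables. At every
#' position covered in at least one sample, builds the implicit
#' methylome-by-state count matrix (samples without a row contribute zero
#' coverage and hence zero weight) and computes the coverage-weighted plug-in
#' Jensen-Shannon divergence, the weighted methylation level, the mixture and
#' average entropies, and the phase-plane cytosine type.
#'
#' @param samples A named list of methylation tables (tibbles with columns
#'   `chrom`, `pos`, `n_meth`, `n_unmeth`) or a named character vector of file
#'   paths read via [read_methylation_table()].
#' @param context Either `NULL` (context recorded as `"unknown"`), a genome
#'   (named character vector or `DNAStringSet`, contexts assigned with
#'   [assign_context()]), or a tibble with columns `chrom`, `pos`, `context`.
#' @param thresholds A [phase_thresholds()] object for classification.
#' @param weighting `"coverage"` (plug-in weights, the default) or `"equal"`.
#' @param min_samples Drop sites covered in fewer samples (default 1, i.e.
#'   keep everything; `samples_covered` is always reported so stricter
#'   filtering can happen downstream).
#' @param min_coverage Drop sites with total coverage below this (default 1).
#' @param dialect Dialect passed to [read_methylation_table()] when `samples`
#'   are paths.
#' @return A coordinate-sorted tibble with columns `chrom`, `pos`, `met`,
#'   `jsd`, `h_mix`, `h_avg`, `coverage`, `samples_covered`, `context`,
#'   `ctype`.
#' @examples
#' pop <- list(
#'   a = tibble::tibble(chrom = "Chr1", pos = 0L, n_meth = 15L, n_unmeth = 0L),
#'   b = tibble::tibble(chrom = "Chr1", pos = 0L, n_meth = 11L, n_unmeth = 1L),
#'   c = tibble::tibble(chrom = "Chr1", pos = 0L, n_meth = 5L, n_unmeth = 4L)
#' )
#' scan_methylomes(pop)
#' @export
scan_methylomes <- function(samples, context = NULL,
                            thresholds = phase_thresholds(),
                            weighting = c("coverage", "equal"),
                            min_samples = 1, min_coverage = 1,
                            dialect = "methyldackel") {
  weighting <- match.arg(weighting)
  if (length(samples) < 1) stop("need at least one sample", call. = FALSE)
  if (is.character(samples)) {
    samples <- purrr::map(samples, read_methylation_table, dialect = dialect)
  }
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- sprintf("sample_%02d", seq_along(samples))
  }
  purrr::walk(samples, .check_sites,
              need = c("chrom", "pos", "n_meth", "n_unmeth"))
  long <- dplyr::bind_rows(samples, .id = "sample")
  long <- dplyr::mutate(long, cov = .data$n_meth + .data$n_unmeth)
  long <- dplyr::filter(long, .data$cov > 0)
  if (nrow(long) == 0) {
    stop("no coverage: all samples are empty or all counts are zero",
         call. = FALSE)
  }
  long <- dplyr::mutate(long,
                        p = .data$n_meth / .data$cov,
                        h = binary_entropy(.data$p))
  grouped <- dplyr::group_by(long, .data$chrom, .data$pos)
  stats <- if (weighting == "coverage") {
    dplyr::summarise(
      grouped,
      coverage = sum(.data$cov),
      samples_covered = dplyr::n(),
      met = sum(.data$n_meth) / .data$coverage,
      h_avg = sum(.data$cov * .data$h) / .data$coverage,
      h_mix = binary_entropy(.data$met),
      .groups = "drop"
    )
  } else {
    dplyr::summarise(
      grouped,
      coverage = sum(.data$cov),
      samples_covered = dplyr::n(),
      met = sum(.data$n_meth) / .data$coverage,
      h_avg = mean(.data$h),
      h_mix = binary_entropy(mean(.data$p)),
      .groups = "drop"
    )
  }
  # snap float noise so identical distributions give exactly zero
  stats <- dplyr::mutate(
    stats,
    jsd = pmax(.data$h_mix - .data$h_avg, 0),
    jsd = ifelse(.data$jsd < 1e-12, 0, .data$jsd)
  )
  stats <- dplyr::filter(stats, .data$samples_covered >= min_samples,
                         .data$coverage >= min_coverage)
  stats$context <- .resolve_context(context, stats$chrom, stats$pos)
  stats$ctype <- classify_ctype(stats$met, stats$jsd, thresholds)
  cols <- c("chrom", "pos", "met", "jsd", "h_mix", "h_avg", "coverage",
            "samples_covered", "context", "ctype")
  dplyr::arrange(stats[, cols], .data$chrom, .data$pos)
}

.resolve_context <- function(context, chrom, pos) {
  if (is.null(context)) return(rep("unknown", length(pos)))
  if (is.data.frame(context)) {
    .check_sites(context, c("chrom", "pos", "context"))
    key <- paste(chrom, pos)
    idx <- match(key, paste(context$chrom, context$pos))
    out <- context$context[idx]
    out[is.na(out)] <- "unknown"
    return(out)
  }
  assign_context(context, chrom, pos)
}

#' Genome-wide proportions of cytosine types
#'
#' Tabulates the percentage of LMC/HMC/MMC/MSC sites, by sequence context.
#' Within each context the four percentages sum to 100.
#'
#' @param sites Classified site-statistics tibble (columns `context`,
#'   `ctype`).
#' @param by Grouping column name, default `"context"`; use `NULL` for a
#'   single overall table.
#' @return A tibble with columns `<by>`, `ctype`, `n`, `percent`.
#' @export
ctype_proportions <- function(sites, by = "context") {
  .check_sites(sites, c("ctype", by))
  if (nrow(sites) == 0) {
    warning("empty site stream; returning empty proportion table")
    return(tibble::tibble(ctype = factor(levels = c("LMC", "HMC", "MMC",
                                                    "MSC")),
                          n = integer(), percent = numeric()))
  }
  grp <- if (is.null(by)) character() else by
  out <- dplyr::count(sites, dplyr::across(dplyr::all_of(grp)), .data$ctype,
                      .drop = FALSE, name = "n")
  out <- dplyr::group_by(out, dplyr::across(dplyr::all_of(grp)))
  out <- dplyr::mutate(out, percent = 100 * .data$n / sum(.data$n))
  dplyr::ungroup(out)
}

#' Bin a per-site signal into genome-tiling intervals
#'
#' Averages a per-site signal (or the fraction of sites of a given cytosine
#' type) over non-overlapping, half-open genomic bins of fixed width. Bins
#' with no contributing sites carry `NA`, never zero. The last bin of a
#' chromosome is truncated to the chromosome length when `chrom_sizes` is
#' given.
#'
#' @param sites Site-statistics tibble.
#' @param bin_width Bin width in bases (e.g. `50000`).
#' @param statistic `"mean_jsd"`, `"mean_met"`, or `"ctype_fraction"`.
#' @param ctype Cytosine type used when `statistic = "ctype_fraction"`
#'   (default `"MSC"`).
#' @param chrom_sizes Optional named vector of chromosome lengths; defaults
#'   to the maximal observed position + 1 per chromosome.
#' @return A tibble of class `binned_signal` with columns `chrom`, `start`,
#'   `end`, `value`, `n_sites`.
#' @export
bin_signal <- function(sites, bin_width,
                       statistic = c("mean_jsd", "mean_met",
                                     "ctype_fraction"),
                       ctype = "MSC", chrom_sizes = NULL) {
  statistic <- match.arg(statistic)
  .check_sites(sites)
  stopifnot(bin_width > 0)
  val <- switch(statistic,
                mean_jsd = sites$jsd,
                mean_met = sites$met,
                ctype_fraction = as.numeric(sites$ctype == ctype))
  per_site <- tibble::tibble(chrom = sites$chrom,
                             start = (sites$pos %/% bin_width) * bin_width,
                             v = val)
  agg <- dplyr::summarise(dplyr::group_by(per_site, .data$chrom, .data$start),
                          value = mean(.data$v), n_sites = dplyr::n(),
                          .groups = "drop")
  upto <- chrom_sizes %||% tapply(sites$pos + 1, sites$chrom, max)
  upto <- as.list(upto)
  bins <- .tile_bins(upto, bin_width)
  out <- dplyr::left_join(bins, agg, by = c("chrom", "start"))
  out$n_sites[is.na(out$n_sites)] <- 0L
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  structure(out, class = c("binned_signal", class(out)),
            bin_width = bin_width, statistic = statistic)
}

#' Spearman correlation and clustering of binned genomic signals
#'
#' Computes pairwise Spearman rank correlations between binned signals on a
#' common binning (bins missing in either member of a pair are dropped
#' pairwise) and clusters them hierarchically on the distance `1 - rho` with
#' average linkage.
#'
#' @param signals A named list of [bin_signal()] outputs on identical bins,
#'   or a numeric matrix/data frame with one column per signal.
#' @param linkage Agglomeration method for `stats::hclust`, default
#'   `"average"`.
#' @return An object of class `signal_clust` with elements `rho` (correlation
#'   matrix), `hclust`, and `order` (leaf labels).
#' @export
correlate_signals <- function(signals, linkage = "average") {
  if (is.list(signals) && !is.data.frame(signals)) {
    if (length(signals) < 2) stop("need >= 2 signals", call. = FALSE)
    if (is.null(names(signals))) {
      names(signals) <- sprintf("signal_%02d", seq_along(signals))
    }
    keys <- purrr::map(signals, ~ paste(.x$chrom, .x$start))
    if (length(unique(purrr::map_chr(keys, paste, collapse = ";"))) != 1) {
      stop("signals are not on identical bins", call. = FALSE)
    }
    mat <- do.call(cbind, purrr::map(signals, "value"))
  } else {
    mat <- as.matrix(signals)
    if (ncol(mat) < 2) stop("need >= 2 signals", call. = FALSE)
  }
  nm <- colnames(mat)
  for (a in seq_len(ncol(mat) - 1)) {
    for (b in seq(a + 1, ncol(mat))) {
      shared <- sum(stats::complete.cases(mat[, c(a, b)]))
      if (shared < 3) {
        stop("fewer than 3 shared non-missing bins for pair ", nm[a], " / ",
             nm[b], call. = FALSE)
      }
    }
  }
  rho <- stats::cor(mat, method = "spearman", use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = linkage)
  structure(list(rho = rho, hclust = hc, order = nm[hc$order]),
            class = "signal_clust")
}

#' @export
print.signal_clust <- function(x, ...) {
  cat("Spearman clustering of", ncol(x$rho), "binned signals\n")
  cat("leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}
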