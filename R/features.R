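#' Metagene profile of a per-site signal
#'
#' Averages a per-site signal across a set of genomic features, with fixed
#' flanks split into literal base-pair bins and the feature body rescaled to
#' a fixed number of bins so features of different lengths are comparable.
#' Minus-strand features are orientation-flipped before binning, so the
#' profile reads 5' to 3'. Each bin's value is the arithmetic mean over all
#' (feature, site) pairs mapping to it; bins no pair maps to are `NA`.
#'
#' @param sites Site-statistics tibble (from [scan_methylomes()]).
#' @param features Feature tibble with columns `chrom`, `start`, `end` and
#'   optionally `strand` (default `"+"`).
#' @param signal Column of `sites` to profile: `"jsd"` or `"met"`.
#' @param flank_width Flank size in bases on each side (default 2000).
#' @param flank_bin Flank bin width in bases (default 50); must divide
#'   `flank_width`.
#' @param body_bins Number of length-scaled bins across the feature body
#'   (default 60).
#' @return An object of class `meta_profile`: a tibble with columns
#'   `segment` (`upstream`/`body`/`downstream`), `bin`, `value`, `n_pairs`,
#'   plus attributes recording the binning and `n_features`.
#' @export
metagene_profile <- function(sites, features, signal = c("jsd", "met"),
                             flank_width = 2000, flank_bin = 50,
                             body_bins = 60) {
  signal <- match.arg(signal)
  .check_sites(sites, c("chrom", "pos", signal))
  .check_features(features)
  if (nrow(features) < 1) stop("need at least one feature", call. = FALSE)
  if (flank_width %% flank_bin != 0) {
    stop("`flank_bin` must divide `flank_width` exactly", call. = FALSE)
  }
  n_flank <- flank_width %/% flank_bin
  strand <- if ("strand" %in% names(features)) features$strand else
    rep("+", nrow(features))
  short <- features$end - features$start < body_bins
  if (any(short)) {
    warning(sum(short), " feature(s) shorter than ", body_bins,
            " bases; body bins are mapped proportionally")
  }
  pairs <- .overlap_pairs(sites, features, flank = flank_width)
  prof_cols <- c("segment", "bin")
  if (nrow(pairs) > 0) {
    pos <- sites$pos[pairs$site_idx]
    fs <- features$start[pairs$feature_idx]
    fe <- features$end[pairs$feature_idx]
    minus <- strand[pairs$feature_idx] == "-"
    len <- fe - fs
    # oriented offset from the 5' end of the extended feature
    u <- ifelse(minus, (fe - 1 - pos) + flank_width, pos - fs + flank_width)
    keep <- u >= 0 & u < 2 * flank_width + len
    u <- u[keep]; len <- len[keep]
    segment <- ifelse(u < flank_width, "upstream",
               ifelse(u < flank_width + len, "body", "downstream"))
    bin <- integer(length(u))
    is_up <- segment == "upstream"
    is_body <- segment == "body"
    is_dn <- segment == "downstream"
    bin[is_up] <- u[is_up] %/% flank_bin
    bin[is_body] <- pmin(
      as.integer(floor((u[is_body] - flank_width) / len[is_body] *
                         body_bins)),
      body_bins - 1L)
    bin[is_dn] <- (u[is_dn] - flank_width - len[is_dn]) %/% flank_bin
    vals <- tibble::tibble(segment = segment, bin = bin,
                           v = sites[[signal]][pairs$site_idx][keep])
    agg <- dplyr::summarise(dplyr::group_by(vals, .data$segment, .data$bin),
                            value = mean(.data$v), n_pairs = dplyr::n(),
                            .groups = "drop")
  } else {
    agg <- tibble::tibble(segment = character(), bin = integer(),
                          value = numeric(), n_pairs = integer())
  }
  grid <- dplyr::bind_rows(
    tibble::tibble(segment = "upstream", bin = seq_len(n_flank) - 1L),
    tibble::tibble(segment = "body", bin = seq_len(body_bins) - 1L),
    tibble::tibble(segment = "downstream", bin = seq_len(n_flank) - 1L)
  )
  out <- dplyr::left_join(grid, agg, by = prof_cols)
  out$n_pairs[is.na(out$n_pairs)] <- 0L
  out$segment <- factor(out$segment,
                        levels = c("upstream", "body", "downstream"))
  structure(out, class = c("meta_profile", class(out)),
            signal = signal, flank_width = flank_width,
            flank_bin = flank_bin, body_bins = body_bins,
            n_features = nrow(features))
}

#' Per-gene cytosine-type counts
#'
#' Counts classified sites and metastable (MSC) sites inside each feature
#' body, the input to metastable-gene selection.
#'
#' @param sites Classified site-statistics tibble.
#' @param genes Feature tibble with an `id` column.
#' @return A tibble with one row per gene: `id`, `n_sites`, `n_msc`,
#'   `msc_prop` (0 for genes without classified sites).
#' @export
gene_ctype_counts <- function(sites, genes) {
  .check_sites(sites, c("chrom", "pos", "ctype"))
  .check_features(genes)
  if (!"id" %in% names(genes)) stop("`genes` needs an `id` column",
                                    call. = FALSE)
  pairs <- .overlap_pairs(sites, genes, flank = 0)
  counts <- if (nrow(pairs) > 0) {
    tbl <- tibble::tibble(id = genes$id[pairs$feature_idx],
                          ctype = sites$ctype[pairs$site_idx])
    tbl <- dplyr::filter(tbl, !is.na(.data$ctype))
    dplyr::summarise(dplyr::group_by(tbl, .data$id),
                     n_sites = dplyr::n(),
                     n_msc = sum(.data$ctype == "MSC"), .groups = "drop")
  } else {
    tibble::tibble(id = character(), n_sites = integer(), n_msc = integer())
  }
  out <- dplyr::left_join(tibble::tibble(id = genes$id), counts, by = "id")
  out$n_sites[is.na(out$n_sites)] <- 0L
  out$n_msc[is.na(out$n_msc)] <- 0L
  out$msc_prop <- ifelse(out$n_sites > 0, out$n_msc / out$n_sites, 0)
  out
}

#' Select metastable genes (MSGs)
#'
#' Ranks genes by the proportion of metastable cytosines among their
#' classified sites and selects those strictly above the given quantile of
#' that proportion (default: the top 5%). Selection is by value threshold,
#' so a group of tied genes is never split: either the whole tie group is
#' above the cut or none of it is.
#'
#' @param gene_stats Output of [gene_ctype_counts()].
#' @param quantile Quantile cut on the MSC proportion, default 0.95.
#' @param min_sites Minimum number of classified sites for a gene to be
#'   eligible (default 1).
#' @return The selected rows of `gene_stats`, with attributes `cutoff` and
#'   `n_eligible`. Empty (with a warning) when no gene has a positive MSC
#'   proportion.
#' @export
select_msgs <- function(gene_stats, quantile = 0.95, min_sites = 1) {
  stopifnot(is.data.frame(gene_stats),
            all(c("id", "n_sites", "msc_prop") %in% names(gene_stats)))
  stopifnot(quantile > 0, quantile < 1, min_sites >= 0)
  eligible <- dplyr::filter(gene_stats, .data$n_sites >= min_sites)
  if (nrow(eligible) == 0 || all(eligible$msc_prop == 0)) {
    warning("no gene has a positive metastable-site proportion; ",
            "returning an empty set")
    out <- eligible[0, ]
    attr(out, "cutoff") <- NA_real_
    attr(out, "n_eligible") <- nrow(eligible)
    return(out)
  }
  cutoff <- stats::quantile(eligible$msc_prop, quantile, names = FALSE,
                            type = 7)
  out <- dplyr::arrange(dplyr::filter(eligible, .data$msc_prop > cutoff),
                        dplyr::desc(.data$msc_prop))
  attr(out, "cutoff") <- cutoff
  attr(out, "n_eligible") <- nrow(eligible)
  out
}

#' Binned fraction of metastable genes
#'
#' Per genome-tiling bin, the number of MSGs over the total number of genes,
#' each gene assigned to the bin containing its start. Bins without genes
#' are `NA`.
#'
#' @param msgs Character vector of selected gene ids (or a tibble with an
#'   `id` column, e.g. from [select_msgs()]).
#' @param genes Feature tibble with an `id` column.
#' @param bin_width Bin width in bases.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return A `binned_signal` tibble with columns `chrom`, `start`, `end`,
#'   `value`, `n_genes`, `n_msg`.
#' @export
msg_fraction_track <- function(msgs, genes, bin_width, chrom_sizes = NULL) {
  if (is.data.frame(msgs)) msgs <- msgs$id
  .check_features(genes)
  if (!"id" %in% names(genes)) stop("`genes` needs an `id` column",
                                    call. = FALSE)
  unknown <- setdiff(msgs, genes$id)
  if (length(unknown) > 0) {
    stop("unknown MSG id(s): ", paste(utils::head(unknown, 3),
                                      collapse = ", "), call. = FALSE)
  }
  stopifnot(bin_width > 0)
  per_gene <- tibble::tibble(
    chrom = genes$chrom,
    start = (genes$start %/% bin_width) * bin_width,
    is_msg = genes$id %in% msgs
  )
  agg <- dplyr::summarise(dplyr::group_by(per_gene, .data$chrom, .data$start),
                          n_genes = dplyr::n(),
                          n_msg = sum(.data$is_msg), .groups = "drop")
  upto <- chrom_sizes %||% tapply(genes$end, genes$chrom, max)
  bins <- .tile_bins(as.list(upto), bin_width)
  out <- dplyr::left_join(bins, agg, by = c("chrom", "start"))
  out$n_genes[is.na(out$n_genes)] <- 0L
  out$n_msg[is.na(out$n_msg)] <- 0L
  out$value <- ifelse(out$n_genes > 0, out$n_msg / out$n_genes, NA_real_)
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  structure(out, class = c("binned_signal", class(out)),
            bin_width = bin_width, statistic = "msg_fraction")
}

#' Relative-distance spatial association
#'
#' For every query feature midpoint lying within the span of the reference
#' midpoints on its chromosome, computes the distance to the nearest
#' reference midpoint divided by the distance between the two flanking
#' reference midpoints — a number in `[0, 0.5]`. Under spatial independence
#' the relative distances are uniform, so every histogram bin has expected
#' frequency `1 / n_bins`.
#'
#' @param query,reference Feature tibbles (`chrom`, `start`, `end`).
#' @param n_bins Number of histogram bins over `[0, 0.5]` (default 50).
#' @return A tibble with columns `bin_low`, `bin_high`, `count`, `freq`
#'   (frequencies sum to 1), with attributes `n_used` and `n_dropped`.
#' @export
relative_distance <- function(query, reference, n_bins = 50) {
  .check_features(query, "query")
  .check_features(reference, "reference")
  stopifnot(n_bins >= 1)
  qmid <- (query$start + query$end) %/% 2
  rmid <- (reference$start + reference$end) %/% 2
  d_all <- numeric(0)
  n_dropped <- 0L
  for (ch in unique(query$chrom)) {
    qm <- qmid[query$chrom == ch]
    rm_ <- sort(rmid[reference$chrom == ch])
    if (length(rm_) < 2) {
      n_dropped <- n_dropped + length(qm)
      next
    }
    inside <- qm >= rm_[1] & qm <= rm_[length(rm_)]
    n_dropped <- n_dropped + sum(!inside)
    qm <- qm[inside]
    if (length(qm) == 0) next
    i <- findInterval(qm, rm_, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(rm_) - 1L)
    left <- rm_[i]; right <- rm_[i + 1]
    gap <- right - left
    d <- ifelse(gap > 0, pmin(qm - left, right - qm) / gap, 0)
    d_all <- c(d_all, d)
  }
  breaks <- seq(0, 0.5, length.out = n_bins + 1)
  # right-open bins; include.lowest folds d == 0.5 into the last bin
  counts <- if (length(d_all) > 0) {
    tabulate(cut(d_all, breaks, include.lowest = TRUE, right = FALSE,
                 labels = FALSE), nbins = n_bins)
  } else integer(n_bins)
  out <- tibble::tibble(
    bin_low = breaks[-(n_bins + 1)],
    bin_high = breaks[-1],
    count = counts,
    freq = if (sum(counts) > 0) counts / sum(counts) else rep(0, n_bins)
  )
  attr(out, "n_used") <- length(d_all)
  attr(out, "n_dropped") <- n_dropped
  out
}

.new_perm_test <- function(observed, null_values, statistic, n, extra = list()) {
  b <- sum(null_values >= observed)
  structure(
    c(list(
      observed = observed,
      null_values = null_values,
      p_value = b / n,
      p_smoothed = (b + 1) / (n + 1),
      n_permutations = n,
      statistic = statistic
    ), extra),
    class = "perm_test"
  )
}

#' Structural-domain contrast permutation test
#'
#' Tests whether a binned genomic signal is elevated in compacted structural
#' domains (CSD, negative eigenvalue) relative to loose domains (LSD,
#' positive eigenvalue). The observed statistic is
#' `mean(signal | CSD) - mean(signal | LSD)`; the null is built by randomly
#' permuting the domain labels over bins, preserving the observed number of
#' CSD and LSD bins. The primary p-value is the one-sided fraction of null
#' statistics at least as large as the observed one; `p_positive`, the null
#' probability of a positive difference, is also reported.
#'
#' @param signal A [bin_signal()] tibble (or any tibble with `chrom`,
#'   `start`, `value`).
#' @param segmentation Tibble with columns `chrom`, `start`, `end`, `eigen`
#'   (sign convention: negative = CSD) on the same bins as `signal`.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Optional integer seed; the global RNG state is restored.
#' @return A `perm_test` object; see [tidy.perm_test()].
#' @export
csd_lsd_test <- function(signal, segmentation, n_permutations = 1000,
                         seed = NULL) {
  .check_sites(signal, c("chrom", "start", "value"))
  .check_features(segmentation, "segmentation")
  if (!"eigen" %in% names(segmentation)) {
    stop("`segmentation` needs an `eigen` column", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    tibble::as_tibble(signal)[, c("chrom", "start", "value")],
    segmentation[, c("chrom", "start", "eigen")],
    by = c("chrom", "start")
  )
  joined <- dplyr::filter(joined, !is.na(.data$value), .data$eigen != 0)
  if (nrow(joined) == 0) {
    stop("signal and segmentation share no usable bins", call. = FALSE)
  }
  csd <- joined$eigen < 0
  n_csd <- sum(csd); n_lsd <- sum(!csd)
  if (n_csd == 0 || n_lsd == 0) {
    stop("degenerate segmentation: both eigenvalue signs must be present",
         call. = FALSE)
  }
  s <- joined$value
  observed <- mean(s[csd]) - mean(s[!csd])
  total <- sum(s); n <- length(s)
  null_values <- .with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n, n_csd)
      sc <- sum(s[idx])
      sc / n_csd - (total - sc) / n_lsd
    }, numeric(1))
  })
  .new_perm_test(
    observed, null_values,
    statistic = "mean(signal | CSD) - mean(signal | LSD)",
    n = n_permutations,
    extra = list(p_positive = mean(null_values > 0),
                 n_csd = n_csd, n_lsd = n_lsd)
  )
}

#' Gene-to-element proximity randomization test
#'
#' Tests whether a gene set (e.g. metastable genes) lies near transposable
#' elements more often than random gene sets of the same size drawn without
#' replacement from a background (e.g. protein-coding, non-TE genes). A gene
#' is "near" an element when its interval extended by `near_dist` on both
#' sides overlaps any element. The observed statistic `g` is the near
#' fraction of the gene set; the p-value is the fraction of random sets with
#' `g` at least as large.
#'
#' @param msgs Character vector of gene ids (or tibble with `id`), a subset
#'   of `genes$id`.
#' @param genes Background feature tibble with an `id` column.
#' @param tes Element feature tibble.
#' @param near_dist Extension in bases defining "near" (default 2000).
#' @param n_draws Number of random gene sets (default 10000).
#' @param seed Optional integer seed; the global RNG state is restored.
#' @return A `perm_test` object with extra element `near_by_gene`.
#' @export
msg_te_proximity_test <- function(msgs, genes, tes, near_dist = 2000,
                                  n_draws = 10000, seed = NULL) {
  if (is.data.frame(msgs)) msgs <- msgs$id
  .check_features(genes, "genes")
  .check_features(tes, "tes")
  if (!"id" %in% names(genes)) stop("`genes` needs an `id` column",
                                    call. = FALSE)
  if (length(msgs) > nrow(genes)) {
    stop("gene set is larger than the background", call. = FALSE)
  }
  unknown <- setdiff(msgs, genes$id)
  if (length(unknown) > 0) {
    stop("gene set contains ids absent from the background: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  near <- .genes_near(genes, tes, near_dist)
  g_obs <- mean(near[genes$id %in% msgs])
  m <- length(msgs)
  null_values <- .with_seed(seed, {
    vapply(seq_len(n_draws), function(i) mean(near[sample.int(length(near),
                                                              m)]),
           numeric(1))
  })
  .new_perm_test(
    g_obs, null_values,
    statistic = sprintf("fraction of genes within %d bp of an element",
                        near_dist),
    n = n_draws,
    extra = list(near_by_gene = stats::setNames(near, genes$id))
  )
}

# logical: does each gene, extended by near_dist, overlap any element?
.genes_near <- function(genes, tes, near_dist) {
  if (nrow(tes) == 0) return(rep(FALSE, nrow(genes)))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$start - near_dist, 0) + 1L,
                     end = genes$end + near_dist)
  )
  gr_tes <- GenomicRanges::GRanges(
    tes$chrom, IRanges::IRanges(start = tes$start + 1L, end = tes$end)
  )
  GenomicRanges::countOverlaps(gr_genes, gr_tes) > 0
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Randomization test:", x$statistic, "\n")
  cat(sprintf("observed = %.6g over %d permutations\n", x$observed,
              x$n_permutations))
  cat(sprintf("p (null >= observed) = %.4g; add-one smoothed = %.4g\n",
              x$p_value, x$p_smoothed))
  if (!is.null(x$p_positive)) {
    cat(sprintf("p (null difference > 0) = %.4g\n", x$p_positive))
  }
  invisible(x)
}
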