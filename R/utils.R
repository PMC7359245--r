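#' @importFrom rlang %||%
#' @importFrom dplyr .data
NULL

# run code under a temporary RNG state; NULL seed means use the current stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.check_sites <- function(sites, need = c("chrom", "pos")) {
  if (!is.data.frame(sites)) stop("`sites` must be a data frame", call. = FALSE)
  miss <- setdiff(need, names(sites))
  if (length(miss) > 0) {
    stop("`sites` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(sites)
}

.check_features <- function(features, what = "features") {
  if (!is.data.frame(features)) {
    stop("`", what, "` must be a data frame", call. = FALSE)
  }
  miss <- setdiff(c("chrom", "start", "end"), names(features))
  if (length(miss) > 0) {
    stop("`", what, "` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(features$start >= features$end)
  if (length(bad) > 0) {
    id <- if ("id" %in% names(features)) features$id[bad[1]] else bad[1]
    stop("feature ", id, " has start >= end", call. = FALSE)
  }
  invisible(features)
}

# overlap pairs between point sites and (possibly flank-extended) features;
# returns integer indices (site_idx, feature_idx). Coordinates are 0-based
# half-open tibbles; GRanges conversion happens only here.
.overlap_pairs <- function(sites, features, flank = 0) {
  gr_sites <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
  fstart <- pmax(features$start - flank, 0)
  gr_feat <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = fstart + 1L,
                              end = features$end + flank)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_sites, gr_feat))
  tibble::tibble(
    site_idx = S4Vectors::queryHits(hits),
    feature_idx = S4Vectors::subjectHits(hits)
  )
}

# genome-tiling half-open bins per chromosome; `upto` is a named vector of
# chromosome lengths (or maximal positions + 1 if lengths are unknown)
.tile_bins <- function(upto, bin_width) {
  purrr::map_dfr(names(upto), function(ch) {
    n_bins <- ceiling(upto[[ch]] / bin_width)
    start <- (seq_len(n_bins) - 1) * bin_width
    tibble::tibble(chrom = ch, start = start,
                   end = pmin(start + bin_width, upto[[ch]]))
  })
}
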