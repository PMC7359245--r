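#' Shannon entropy of a discrete distribution
#'
#' Computes \eqn{H(P) = -\sum_k p_k \log_b p_k} with the convention
#' \eqn{0 \log 0 = 0}. With the default base 2 the result is in bits.
#'
#' @param probs Numeric vector of probabilities; must be non-negative and sum
#'   to 1 within `1e-9`.
#' @param base Logarithm base; 2 (the default) measures entropy in bits.
#' @return A single non-negative number, at most `log(length(probs), base)`.
#' @examples
#' shannon_entropy(c(0.5, 0.5))   # 1 bit
#' shannon_entropy(c(1, 0))       # 0 bits
#' @export
shannon_entropy <- function(probs, base = 2) {
  if (!is.numeric(probs) || length(probs) < 1) {
    stop("`probs` must be a non-empty numeric vector", call. = FALSE)
  }
  neg <- which(probs < 0)
  if (length(neg) > 0) {
    stop("negative probability at index ", neg[1], call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("probabilities sum to ", format(sum(probs)), ", not 1", call. = FALSE)
  }
  p <- probs[probs > 0]
  -sum(p * log(p, base = base))
}

#' Binary entropy function
#'
#' Entropy in bits of a two-state distribution with success probability `p`.
#' Vectorised; this is the envelope curve of the (MET, JSD) phase plane:
#' per-site JSD can never exceed `binary_entropy(met)`.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return Numeric vector of entropies in bits.
#' @export
binary_entropy <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)
  q <- 1 - p
  out <- numeric(length(p))
  ok <- !is.na(p) & p > 0 & p < 1
  out[ok] <- -p[ok] * log2(p[ok]) - q[ok] * log2(q[ok])
  out[is.na(p)] <- NA_real_
  out
}

# entropy (bits) of each row of a probability matrix; rows need not be checked
.row_entropy <- function(P) {
  logP <- matrix(0, nrow(P), ncol(P))
  pos <- P > 0
  logP[pos] <- log2(P[pos])
  -rowSums(P * logP)
}

.as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    if (all(c("n_meth", "n_unmeth") %in% names(counts))) {
      counts <- cbind(counts$n_meth, counts$n_unmeth)
    } else {
      counts <- as.matrix(counts)
    }
  }
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || nrow(counts) < 1 || ncol(counts) < 2) {
    stop("`counts` must be a numeric matrix with >= 1 row and >= 2 columns",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("read counts must be non-negative", call. = FALSE)
  counts
}

#' Plug-in Jensen-Shannon divergence at a single site
#'
#' Given a read-count matrix with one row per methylome and one column per
#' state (column 1 = methylated, column 2 = unmethylated; more states are
#' allowed), computes the plug-in JSD estimate
#' \deqn{\hat D = H(\sum_j \hat\pi_j \hat P_j) - \sum_j \hat\pi_j H(\hat P_j)}
#' where each row's distribution \eqn{\hat P_j} is the row normalised by its
#' coverage and the weights \eqn{\hat\pi_j} are either coverage proportions
#' (row coverage over total coverage; the default) or equal over covered rows.
#' Rows with zero coverage receive weight zero. The weighted methylation level
#' MET is total methylated reads over total reads.
#'
#' @param counts Integer matrix (methylomes x states) of read counts, or a
#'   data frame with columns `n_meth` and `n_unmeth`.
#' @param weighting `"coverage"` (default) or `"equal"`.
#' @return A one-row tibble with columns `met`, `jsd`, `h_mix`, `h_avg`
#'   (bits), `coverage`, `samples_covered`, `k_states`.
#' @examples
#' site_divergence(rbind(c(15, 0), c(11, 1), c(5, 4)))
#' @seealso [site_terms()] for the per-methylome breakdown of the same
#'   computation.
#' @export
site_divergence <- function(counts, weighting = c("coverage", "equal")) {
  weighting <- match.arg(weighting)
  counts <- .as_count_matrix(counts)
  n_j <- rowSums(counts)
  n <- sum(n_j)
  if (n == 0) stop("no coverage: all read counts are zero", call. = FALSE)
  covered <- n_j > 0
  P <- counts[covered, , drop = FALSE] / n_j[covered]
  w <- if (weighting == "coverage") n_j[covered] / n else
    rep(1 / sum(covered), sum(covered))
  mix <- colSums(w * P)
  h_mix <- shannon_entropy(mix)
  h_avg <- sum(w * .row_entropy(P))
  tibble::tibble(
    met = sum(counts[, 1]) / n,
    jsd = max(h_mix - h_avg, 0),
    h_mix = h_mix,
    h_avg = h_avg,
    coverage = as.integer(n),
    samples_covered = as.integer(sum(covered)),
    k_states = ncol(counts)
  )
}

#' Per-methylome terms of the plug-in JSD computation
#'
#' Expands a single-site count matrix into the per-methylome quantities that
#' enter the JSD estimate: coverage, methylation level, weight, entropy, and
#' the weight-entropy product whose sum is the average entropy.
#'
#' @inheritParams site_divergence
#' @return A tibble with one row per methylome: `n_meth`, `n_unmeth`,
#'   `coverage`, `p_meth`, `weight`, `entropy`, `weighted_entropy`.
#' @export
site_terms <- function(counts, weighting = c("coverage", "equal")) {
  weighting <- match.arg(weighting)
  counts <- .as_count_matrix(counts)
  if (ncol(counts) != 2) stop("site_terms() expects two states", call. = FALSE)
  n_j <- rowSums(counts)
  n <- sum(n_j)
  if (n == 0) stop("no coverage: all read counts are zero", call. = FALSE)
  covered <- n_j > 0
  w <- if (weighting == "coverage") n_j / n else
    ifelse(covered, 1 / sum(covered), 0)
  p <- ifelse(covered, counts[, 1] / n_j, NA_real_)
  h <- ifelse(covered, binary_entropy(ifelse(covered, p, 0)), NA_real_)
  tibble::tibble(
    methylome = seq_len(nrow(counts)),
    n_meth = counts[, 1],
    n_unmeth = counts[, 2],
    coverage = as.integer(n_j),
    p_meth = p,
    weight = w,
    entropy = h,
    weighted_entropy = w * h
  )
}

#' Weighted methylation level (MET) at a single site
#'
#' Total methylated reads over total reads across the population sample,
#' i.e. the coverage-weighted average of the per-methylome levels.
#'
#' @inheritParams site_divergence
#' @return A number in `[0, 1]`.
#' @export
met_level <- function(counts) {
  counts <- .as_count_matrix(counts)
  n <- sum(counts)
  if (n == 0) stop("no coverage: all read counts are zero", call. = FALSE)
  sum(counts[, 1]) / n
}

#' Phase-plane classification thresholds
#'
#' Thresholds splitting the (MET, JSD) plane into the four cytosine types:
#' low-methylated (LMC, MET < `met_low`), high-methylated (HMC,
#' MET > `met_high`), and within the middle band medium-methylated (MMC) or
#' metastable (MSC, JSD > `jsd_metastable` bits). MET values exactly at a
#' boundary fall in the middle band.
#'
#' @param met_low,met_high MET boundaries, defaults 0.2 and 0.8.
#' @param jsd_metastable JSD threshold in bits for metastable sites,
#'   default 0.7.
#' @return An object of class `phase_thresholds`.
#' @export
phase_thresholds <- function(met_low = 0.2, met_high = 0.8,
                             jsd_metastable = 0.7) {
  stopifnot(is.numeric(met_low), is.numeric(met_high),
            is.numeric(jsd_metastable))
  if (!(0 < met_low && met_low < met_high && met_high < 1)) {
    stop("need 0 < met_low < met_high < 1", call. = FALSE)
  }
  if (!(0 < jsd_metastable && jsd_metastable < 1)) {
    stop("need 0 < jsd_metastable < 1", call. = FALSE)
  }
  structure(
    list(met_low = met_low, met_high = met_high,
         jsd_metastable = jsd_metastable),
    class = "phase_thresholds"
  )
}

#' @export
print.phase_thresholds <- function(x, ...) {
  cat("Phase-plane thresholds: LMC if MET <", x$met_low,
      "| HMC if MET >", x$met_high,
      "| MSC if JSD >", x$jsd_metastable, "bit in the middle band\n")
  invisible(x)
}

#' Classify sites in the (MET, JSD) phase plane
#'
#' Vectorised four-way classification into LMC / HMC / MMC / MSC.
#'
#' @param met Numeric vector of weighted methylation levels in `[0, 1]`.
#' @param jsd Numeric vector of JSD values in bits (same length).
#' @param thresholds A [phase_thresholds()] object.
#' @return A factor with levels `LMC`, `HMC`, `MMC`, `MSC`.
#' @examples
#' classify_ctype(c(0.1, 0.5, 0.5, 0.9), c(0.3, 0.75, 0.3, 0.1))
#' @export
classify_ctype <- function(met, jsd, thresholds = phase_thresholds()) {
  stopifnot(inherits(thresholds, "phase_thresholds"),
            length(met) == length(jsd))
  if (any(met < -1e-12 | met > 1 + 1e-12, na.rm = TRUE)) {
    stop("`met` must lie in [0, 1]", call. = FALSE)
  }
  if (any(jsd < -1e-9, na.rm = TRUE)) {
    stop("`jsd` must be non-negative", call. = FALSE)
  }
  lab <- ifelse(met < thresholds$met_low, "LMC",
         ifelse(met > thresholds$met_high, "HMC",
         ifelse(jsd > thresholds$jsd_metastable, "MSC", "MMC")))
  factor(lab, levels = c("LMC", "HMC", "MMC", "MSC"))
}
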