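#' Simulate a population of methylomes with known ground truth
#'
#' Generates a synthetic chromosome, a set of cytosine sites with assigned
#' sequence contexts, and per-sample read-count tables emulating
#' bisulfite-sequencing calls over a population. Each site follows one of
#' four population models:
#' \describe{
#'   \item{conserved_low}{every individual methylated at rate `theta_low`
#'     (unmethylated region; yields LMC sites)}
#'   \item{conserved_high}{every individual at `theta_high` (methylated
#'     region; HMC sites)}
#'   \item{intermediate}{every individual at `theta_mid` (MMC sites: medium
#'     MET but low divergence)}
#'   \item{metastable}{each individual independently draws the high state
#'     with probability `metastable_mix`, else the low state — the
#'     population segregates into methylated and unmethylated
#'     subpopulations (MSC sites)}
#' }
#' Per-site per-sample coverage is negative binomial (`coverage_dispersion`
#' is the NB size; `Inf` gives Poisson); methylated counts are binomial in
#' the coverage at the individual's rate. Samples have no row at sites where
#' their coverage draw is zero, exercising the scanner's zero-weight
#' handling. Output is deterministic given `seed`.
#'
#' @param n_samples Number of methylomes (default 10).
#' @param n_sites Number of cytosine sites (default 1000).
#' @param site_mix Named fractions over the four site models (summing to 1).
#' @param context_mix Named fractions of CG/CHG/CHH sites.
#' @param theta_low,theta_mid,theta_high Methylation rates of the low,
#'   intermediate and high states (defaults 0.03, 0.5, 0.97).
#' @param metastable_mix Per-individual probability of the high state at
#'   metastable sites (default 0.5).
#' @param coverage_mean,coverage_dispersion Negative-binomial coverage mean
#'   (default 30) and size (default 10; `Inf` = Poisson).
#' @param genome_length Chromosome length in bases; defaults to 20 bases per
#'   site.
#' @param chrom Chromosome name (default `"Chr1"`).
#' @param metastable_regions Optional feature tibble; sites falling inside
#'   get the metastable model with probability
#'   `metastable_rate_in_regions`, overriding the drawn model (used to plant
#'   metastable genes).
#' @param metastable_rate_in_regions See above (default 0.6).
#' @param seed Optional integer seed.
#' @return A list with elements `samples` (named list of methylation
#'   tables), `truth` (tibble: `chrom`, `pos`, `context`, `kind`), `genome`
#'   (`Biostrings::DNAStringSet`), and `params`.
#' @export
simulate_population <- function(n_samples = 10, n_sites = 1000,
                                site_mix = c(conserved_low = 0.70,
                                             conserved_high = 0.20,
                                             intermediate = 0.08,
                                             metastable = 0.02),
                                context_mix = c(CG = 0.15, CHG = 0.15,
                                                CHH = 0.70),
                                theta_low = 0.03, theta_mid = 0.5,
                                theta_high = 0.97, metastable_mix = 0.5,
                                coverage_mean = 30,
                                coverage_dispersion = 10,
                                genome_length = NULL, chrom = "Chr1",
                                metastable_regions = NULL,
                                metastable_rate_in_regions = 0.6,
                                seed = NULL) {
  stopifnot(n_samples >= 1, n_sites >= 1, coverage_mean > 0)
  if (!(0 < theta_low && theta_low < theta_mid && theta_mid < theta_high &&
        theta_high < 1)) {
    stop("need 0 < theta_low < theta_mid < theta_high < 1", call. = FALSE)
  }
  if (!(0 < metastable_mix && metastable_mix < 1)) {
    stop("need 0 < metastable_mix < 1", call. = FALSE)
  }
  kinds <- c("conserved_low", "conserved_high", "intermediate", "metastable")
  if (!setequal(names(site_mix), kinds) || abs(sum(site_mix) - 1) > 1e-6 ||
      any(site_mix < 0)) {
    stop("`site_mix` must be fractions over ", paste(kinds, collapse = ", "),
         " summing to 1", call. = FALSE)
  }
  if (!setequal(names(context_mix), c("CG", "CHG", "CHH")) ||
      abs(sum(context_mix) - 1) > 1e-6 || any(context_mix < 0)) {
    stop("`context_mix` must be CG/CHG/CHH fractions summing to 1",
         call. = FALSE)
  }
  genome_length <- genome_length %||% (n_sites * 20L)
  slot <- genome_length %/% n_sites
  if (slot < 8) stop("genome too short for ", n_sites, " sites",
                     call. = FALSE)
  .with_seed(seed, {
    contexts <- sample(names(context_mix), n_sites, replace = TRUE,
                       prob = context_mix)
    kind <- sample(kinds, n_sites, replace = TRUE, prob = site_mix[kinds])
    pos <- (seq_len(n_sites) - 1L) * slot + 2L
    if (!is.null(metastable_regions)) {
      .check_features(metastable_regions, "metastable_regions")
      inside <- .overlap_pairs(tibble::tibble(chrom = chrom, pos = pos),
                               metastable_regions, flank = 0)$site_idx
      hit <- unique(inside)
      flip <- hit[stats::runif(length(hit)) < metastable_rate_in_regions]
      kind[flip] <- "metastable"
    }
    genome <- .build_genome(genome_length, pos, contexts, chrom)
    theta_site <- c(conserved_low = theta_low, conserved_high = theta_high,
                    intermediate = theta_mid)[kind]
    # theta matrix sites x samples
    theta <- matrix(rep(theta_site, n_samples), n_sites, n_samples)
    is_ms <- kind == "metastable"
    if (any(is_ms)) {
      high <- matrix(stats::runif(sum(is_ms) * n_samples) < metastable_mix,
                     sum(is_ms), n_samples)
      theta[is_ms, ] <- ifelse(high, theta_high, theta_low)
    }
    coverage <- if (is.finite(coverage_dispersion)) {
      matrix(stats::rnbinom(n_sites * n_samples, mu = coverage_mean,
                            size = coverage_dispersion), n_sites, n_samples)
    } else {
      matrix(stats::rpois(n_sites * n_samples, coverage_mean), n_sites,
             n_samples)
    }
    meth <- matrix(stats::rbinom(n_sites * n_samples, as.vector(coverage),
                                 as.vector(theta)), n_sites, n_samples)
    samples <- purrr::map(seq_len(n_samples), function(j) {
      keep <- coverage[, j] > 0
      tibble::tibble(chrom = chrom, pos = pos[keep],
                     n_meth = meth[keep, j],
                     n_unmeth = coverage[keep, j] - meth[keep, j])
    })
    names(samples) <- sprintf("sample_%02d", seq_len(n_samples))
    truth <- tibble::tibble(chrom = chrom, pos = pos, context = contexts,
                            kind = kind)
    list(
      samples = samples, truth = truth, genome = genome,
      params = list(n_samples = n_samples, n_sites = n_sites,
                    site_mix = site_mix, context_mix = context_mix,
                    theta_low = theta_low, theta_mid = theta_mid,
                    theta_high = theta_high, metastable_mix = metastable_mix,
                    coverage_mean = coverage_mean,
                    coverage_dispersion = coverage_dispersion,
                    genome_length = genome_length, chrom = chrom,
                    seed = seed)
    )
  })
}

# chromosome of A/T filler with a context motif at each site; motifs use
# H in {A, T} so no cytosine appears outside the planted positions and the
# planted G partners (CG/CHG), whose reverse-strand contexts are consistent
.build_genome <- function(genome_length, pos, contexts, chrom) {
  bases <- sample(c("A", "T"), genome_length, replace = TRUE)
  h <- sample(c("A", "T"), length(pos), replace = TRUE)
  motif <- cbind("C",
                 ifelse(contexts == "CG", "G", h),
                 ifelse(contexts == "CG", sample(c("A", "T"), length(pos),
                                                 replace = TRUE),
                 ifelse(contexts == "CHG", "G",
                        sample(c("A", "T"), length(pos), replace = TRUE))))
  for (k in 1:3) bases[pos + k] <- motif[, k]
  seq <- paste(bases, collapse = "")
  Biostrings::DNAStringSet(stats::setNames(seq, chrom))
}

#' Simulate toy annotations with planted structure
#'
#' Places non-overlapping genes on a chromosome, designates a planted
#' fraction of them as metastable genes (MSGs), scatters transposable
#' elements so they fall near planted MSGs with elevated probability, and
#' tiles the chromosome with an alternating-sign structural-domain
#' segmentation. Ground truth is returned for recovery tests.
#'
#' @param genome_length Chromosome length in bases.
#' @param n_genes,n_tes Number of genes and elements.
#' @param msg_fraction Fraction of genes planted as MSGs (default 0.05).
#' @param gene_length,te_length Feature lengths in bases (defaults 2000,
#'   400).
#' @param near_dist Distance within which a "near" element is placed
#'   (default 2000).
#' @param te_near_msg_prob Probability that an element is placed next to a
#'   planted MSG rather than uniformly (default 0.8; ignored when no MSGs
#'   are planted).
#' @param seg_bin Segmentation bin width (default 50000).
#' @param chrom Chromosome name.
#' @param seed Optional integer seed.
#' @return A list with `genes`, `tes` (feature tibbles), `msgs` (planted
#'   gene ids), and `segmentation` (tibble with signed `eigen`).
#' @export
simulate_annotations <- function(genome_length, n_genes = 50, n_tes = 30,
                                 msg_fraction = 0.05, gene_length = 2000,
                                 te_length = 400, near_dist = 2000,
                                 te_near_msg_prob = 0.8, seg_bin = 50000,
                                 chrom = "Chr1", seed = NULL) {
  stopifnot(n_genes >= 1, genome_length > 0)
  slot <- genome_length %/% n_genes
  if (slot <= gene_length) {
    stop("overcrowded genome: ", n_genes, " genes of ", gene_length,
         " bases do not fit in ", genome_length, call. = FALSE)
  }
  .with_seed(seed, {
    offset <- floor(stats::runif(n_genes) * (slot - gene_length))
    start <- (seq_len(n_genes) - 1L) * slot + as.integer(offset)
    genes <- tibble::tibble(
      chrom = chrom, start = start, end = start + gene_length,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      id = sprintf("gene_%03d", seq_len(n_genes)),
      category = "gene"
    )
    n_msg <- round(msg_fraction * n_genes)
    msgs <- if (n_msg > 0) sort(sample(genes$id, n_msg)) else character()
    tes <- if (n_tes > 0) {
      te_start <- integer(n_tes)
      for (t in seq_len(n_tes)) {
        near <- length(msgs) > 0 && stats::runif(1) < te_near_msg_prob
        if (near) {
          g <- genes[genes$id == sample(msgs, 1), ]
          lo <- g$end + 50L
          hi <- g$end + near_dist - te_length
          te_start[t] <- lo + floor(stats::runif(1) * max(hi - lo, 1))
        } else {
          te_start[t] <- floor(stats::runif(1) * (genome_length - te_length))
        }
      }
      tibble::tibble(
        chrom = chrom, start = te_start, end = te_start + te_length,
        strand = sample(c("+", "-"), n_tes, replace = TRUE),
        id = sprintf("te_%03d", seq_len(n_tes)),
        category = "TE"
      )
    } else {
      tibble::tibble(chrom = character(), start = integer(),
                     end = integer(), strand = character(),
                     id = character(), category = character())
    }
    n_seg <- max(ceiling(genome_length / seg_bin), 2)
    seg_start <- (seq_len(n_seg) - 1L) * as.integer(seg_bin)
    sign <- sample(c(-1, 1), n_seg, replace = TRUE)
    if (length(unique(sign)) == 1) sign[sample.int(n_seg, 1)] <- -sign[1]
    segmentation <- tibble::tibble(
      chrom = chrom, start = seg_start,
      end = pmin(seg_start + as.integer(seg_bin), genome_length),
      eigen = sign * stats::runif(n_seg, 0.1, 1)
    )
    list(genes = genes, tes = tes, msgs = msgs, segmentation = segmentation)
  })
}

#' Simulate a complete annotated methylome study
#'
#' Convenience wrapper composing [simulate_annotations()] and
#' [simulate_population()]: genes are placed first, a planted subset is
#' designated metastable, and the population's site models are biased so
#' that sites inside planted genes are predominantly metastable. The result
#' feeds the whole pipeline (scan, classification, MSG selection, proximity
#' and domain tests) with known ground truth.
#'
#' @param n_samples,n_sites,coverage_mean,coverage_dispersion,seed Passed to
#'   [simulate_population()].
#' @param n_genes,n_tes,msg_fraction,gene_length,te_near_msg_prob Passed to
#'   [simulate_annotations()].
#' @param genome_length Chromosome length; default places 20 bases per site.
#' @param metastable_rate_in_msgs Metastable-model rate for sites inside
#'   planted genes (default 0.6).
#' @return The [simulate_population()] list plus elements `genes`, `tes`,
#'   `msgs`, `segmentation`.
#' @export
simulate_methylome_study <- function(n_samples = 10, n_sites = 4000,
                                     n_genes = 40, n_tes = 30,
                                     msg_fraction = 0.05,
                                     gene_length = 1000,
                                     genome_length = NULL,
                                     coverage_mean = 30,
                                     coverage_dispersion = 10,
                                     te_near_msg_prob = 0.8,
                                     metastable_rate_in_msgs = 0.6,
                                     seed = NULL) {
  genome_length <- genome_length %||% (n_sites * 20L)
  .with_seed(seed, {
    ann <- simulate_annotations(genome_length, n_genes = n_genes,
                                n_tes = n_tes, msg_fraction = msg_fraction,
                                gene_length = gene_length,
                                te_near_msg_prob = te_near_msg_prob)
    planted <- ann$genes[ann$genes$id %in% ann$msgs, ]
    pop <- simulate_population(
      n_samples = n_samples, n_sites = n_sites,
      coverage_mean = coverage_mean,
      coverage_dispersion = coverage_dispersion,
      genome_length = genome_length,
      metastable_regions = if (nrow(planted) > 0) planted else NULL,
      metastable_rate_in_regions = metastable_rate_in_msgs
    )
    c(pop, ann)
  })
}
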