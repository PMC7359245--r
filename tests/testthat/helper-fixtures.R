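# shared fixtures and independent oracles used across the suite

# the three-methylome worked example: rows are methylomes, columns are
# (methylated, unmethylated) read counts at one site
table2_counts <- rbind(c(15L, 0L), c(11L, 1L), c(5L, 4L))

table2_samples <- function() {
  purrr::map(seq_len(nrow(table2_counts)), function(j) {
    tibble::tibble(chrom = "Chr1", pos = 100L,
                   n_meth = table2_counts[j, 1],
                   n_unmeth = table2_counts[j, 2])
  }) |> rlang::set_names(c("a", "b", "c"))
}

# independent oracle: JSD with coverage weights equals the mutual
# information of the joint frequency table counts / n, by brute-force
# double summation over all cells
mi_oracle <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  pj <- rowSums(p)
  pk <- colSums(p)
  mi <- 0
  for (j in seq_len(nrow(p))) {
    for (k in seq_len(ncol(p))) {
      if (p[j, k] > 0) {
        mi <- mi + p[j, k] * log2(p[j, k] / (pj[j] * pk[k]))
      }
    }
  }
  mi
}

# random count matrix with at least one positive entry
random_counts <- function(s, K = 2, max_n = 30) {
  repeat {
    m <- matrix(rpois(s * K, lambda = runif(1, 0.5, max_n / 2)), s, K)
    if (sum(m) > 0) return(m)
  }
}

# slow reference entropy for a probability vector
entropy_oracle <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

# pattern-matching oracle for forward-strand cytosine context
context_regex_oracle <- function(seq, pos0) {
  vapply(pos0, function(p) {
    tri <- substr(seq, p + 1, p + 3)
    if (substr(tri, 1, 1) != "C") return("none")
    if (grepl("^CG", tri)) return("CG")
    if (grepl("^C[ACT]G", tri)) return("CHG")
    if (grepl("^C[ACT][ACT]", tri)) return("CHH")
    "none"
  }, character(1))
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
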