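# brute-force metagene oracle: loop over every (feature, site) pair
profile_oracle <- function(sites, features, signal, flank_width, flank_bin,
                           body_bins) {
  acc <- list()
  for (f in seq_len(nrow(features))) {
    fs <- features$start[f]; fe <- features$end[f]
    minus <- (features$strand %||% rep("+", nrow(features)))[f] == "-"
    for (s in seq_len(nrow(sites))) {
      if (sites$chrom[s] != features$chrom[f]) next
      p <- sites$pos[s]
      u <- if (minus) (fe - 1 - p) + flank_width else p - fs + flank_width
      if (u < 0 || u >= 2 * flank_width + (fe - fs)) next
      len <- fe - fs
      if (u < flank_width) {
        seg <- "upstream"; bin <- u %/% flank_bin
      } else if (u < flank_width + len) {
        seg <- "body"
        bin <- min(floor((u - flank_width) / len * body_bins),
                   body_bins - 1)
      } else {
        seg <- "downstream"; bin <- (u - flank_width - len) %/% flank_bin
      }
      acc[[length(acc) + 1]] <- data.frame(segment = seg, bin = bin,
                                           v = sites[[signal]][s])
    }
  }
  df <- do.call(rbind, acc)
  stats::aggregate(v ~ segment + bin, df, mean)
}

test_that("a constant signal gives a flat metagene profile", {
  sites <- tibble::tibble(chrom = "Chr1", pos = seq(0L, 9999L, 10L),
                          jsd = 0.4, met = 0.4)
  feats <- tibble::tibble(chrom = "Chr1", start = c(3000L, 6000L),
                          end = c(4200L, 7500L), strand = c("+", "-"))
  prof <- metagene_profile(sites, feats, signal = "jsd")
  expect_equal(prof$value[prof$n_pairs > 0],
               rep(0.4, sum(prof$n_pairs > 0)))
  expect_equal(attr(prof, "n_features"), 2L)
  # flank bin count is exactly flank_width / flank_bin
  expect_equal(sum(prof$segment == "upstream"), 2000 / 50)
})

test_that("minus-strand features give the mirror-image profile", {
  set.seed(41)
  sites <- tibble::tibble(chrom = "Chr1", pos = 0:7999,
                          jsd = runif(8000))
  plus <- tibble::tibble(chrom = "Chr1", start = 3000L, end = 4200L,
                         strand = "+")
  minus <- dplyr::mutate(plus, strand = "-")
  p_plus <- metagene_profile(sites, plus, body_bins = 60)
  p_minus <- metagene_profile(sites, minus, body_bins = 60)
  expect_equal(p_minus$value[p_minus$segment == "body"],
               rev(p_plus$value[p_plus$segment == "body"]))
  expect_equal(p_minus$value[p_minus$segment == "upstream"],
               rev(p_plus$value[p_plus$segment == "downstream"]))
})

test_that("metagene binning matches the brute-force oracle", {
  set.seed(42)
  sites <- tibble::tibble(chrom = "Chr1",
                          pos = sort(sample.int(30000, 2500)),
                          jsd = runif(2500))
  feats <- tibble::tibble(
    chrom = "Chr1",
    start = as.integer(seq(2000, 25000, length.out = 10)),
    strand = sample(c("+", "-"), 10, replace = TRUE)
  )
  feats$end <- feats$start + as.integer(runif(10, 300, 2500))
  prof <- metagene_profile(sites, feats, signal = "jsd",
                           flank_width = 1000, flank_bin = 50,
                           body_bins = 20)
  oracle <- profile_oracle(sites, feats, "jsd", 1000, 50, 20)
  got <- dplyr::inner_join(
    tibble::as_tibble(prof),
    tibble::as_tibble(oracle),
    by = c("segment", "bin"))
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$value, got$v, tolerance = 1e-12)
  # profile is invariant to feature order and to duplicating the stream
  prof2 <- metagene_profile(sites, feats[sample(1:10), ], signal = "jsd",
                            flank_width = 1000, flank_bin = 50,
                            body_bins = 20)
  expect_equal(tibble::as_tibble(prof), tibble::as_tibble(prof2))
  prof3 <- metagene_profile(dplyr::bind_rows(sites, sites), feats,
                            signal = "jsd", flank_width = 1000,
                            flank_bin = 50, body_bins = 20)
  expect_equal(prof$value, prof3$value)
  # short features are mapped proportionally, with a warning
  tiny <- tibble::tibble(chrom = "Chr1", start = 100L, end = 110L,
                         strand = "+")
  expect_warning(metagene_profile(sites, tiny, body_bins = 20), "shorter")
})

test_that("metastable-gene selection honours the strict-above-quantile rule", {
  # exactly five genes with signal: all five selected
  gs <- tibble::tibble(id = sprintf("g%03d", 1:100),
                       n_sites = 50L,
                       n_msc = c(rep(0L, 95), 10L, 12L, 15L, 20L, 25L))
  gs$msc_prop <- gs$n_msc / gs$n_sites
  sel <- select_msgs(gs)
  expect_setequal(sel$id, sprintf("g%03d", 96:100))
  # all genes tied: nothing is strictly above the cut
  tied <- dplyr::mutate(gs, n_msc = 5L, msc_prop = 0.1)
  expect_equal(nrow(select_msgs(tied)), 0)
  # all zero: empty set with a warning
  zero <- dplyr::mutate(gs, n_msc = 0L, msc_prop = 0)
  expect_warning(out <- select_msgs(zero), "empty")
  expect_equal(nrow(out), 0)
  # tie groups are never split
  props <- c(rep(0, 90), rep(0.5, 10))
  tie_group <- tibble::tibble(id = sprintf("g%03d", 1:100), n_sites = 50L,
                              n_msc = as.integer(props * 50),
                              msc_prop = props)
  sel2 <- select_msgs(tie_group)
  expect_true(nrow(sel2) %in% c(0L, 10L))
  # genes below min_sites are ineligible (leaving only zero-signal genes)
  sparse <- gs
  sparse$n_sites[96:100] <- 2L
  expect_warning(sel3 <- select_msgs(sparse, min_sites = 10), "empty")
  expect_equal(nrow(sel3), 0)
})

test_that("the MSG fraction track normalises by gene count per bin", {
  genes <- tibble::tibble(
    chrom = "Chr1",
    start = as.integer(c(seq(0, 900, 100), 1500L, 1600L)),
    end = as.integer(c(seq(0, 900, 100), 1500L, 1600L)) + 50L,
    id = sprintf("g%02d", 1:12)
  )
  msgs <- c("g01", "g02", "g11")
  track <- msg_fraction_track(msgs, genes, bin_width = 1000)
  expect_equal(track$value[1], 2 / 10)
  expect_equal(track$value[2], 1 / 2)
  expect_equal(track$n_genes, c(10L, 2L))
  # no MSGs anywhere: all-zero track over gene-bearing bins
  none <- msg_fraction_track(character(), genes, bin_width = 1000)
  expect_equal(none$value, c(0, 0))
  expect_error(msg_fraction_track("nope", genes, 1000), "unknown MSG")
})

test_that("relative distances concentrate at 0 and 0.5 in the edge cases", {
  refs <- tibble::tibble(chrom = "Chr1",
                         start = as.integer(seq(0, 9000, 1000)),
                         end = as.integer(seq(0, 9000, 1000)) + 100L)
  coincident <- refs[2:9, ]
  h0 <- relative_distance(coincident, refs, n_bins = 50)
  expect_equal(h0$freq[1], 1)
  expect_equal(sum(h0$freq), 1)
  midway <- dplyr::mutate(refs[1:9, ], start = start + 500L,
                          end = end + 500L)
  h5 <- relative_distance(midway, refs, n_bins = 50)
  expect_equal(h5$freq[50], 1)
  # chromosomes with fewer than two references are skipped and counted
  lonely <- dplyr::mutate(refs[1, ], chrom = "Chr9")
  mixed_q <- dplyr::bind_rows(coincident,
                              tibble::tibble(chrom = "Chr9", start = 5L,
                                             end = 10L))
  h <- relative_distance(mixed_q, dplyr::bind_rows(refs, lonely))
  expect_equal(attr(h, "n_dropped"), 1L)
  expect_equal(attr(h, "n_used"), 8L)
})

test_that("relative distance is uniform under spatial independence", {
  set.seed(43)
  refs <- tibble::tibble(chrom = "Chr1",
                         start = sort(sample.int(1000000, 200)))
  refs$end <- refs$start + 10L
  qpos <- sample(seq(min(refs$start), max(refs$start)), 10000)
  queries <- tibble::tibble(chrom = "Chr1", start = qpos, end = qpos + 10L)
  h <- relative_distance(queries, refs)   # default 50 bins
  expect_equal(sum(h$freq), 1)
  p0 <- 1 / 50
  se <- sqrt(p0 * (1 - p0) / attr(h, "n_used"))
  expect_true(all(abs(h$freq - p0) <= 3 * se))
})

test_that("the domain-contrast test finds planted shifts and not flat signal", {
  seg <- tibble::tibble(chrom = "Chr1",
                        start = as.integer((0:199) * 50000))
  seg$end <- seg$start + 50000L
  set.seed(44)
  seg$eigen <- sample(rep(c(-0.5, 0.5), each = 100))
  flat <- tibble::tibble(chrom = "Chr1", start = seg$start, value = 0.25)
  res_flat <- csd_lsd_test(flat, seg, n_permutations = 200, seed = 1)
  expect_equal(res_flat$observed, 0)
  expect_equal(res_flat$p_value, 1)

  shifted <- flat
  shifted$value <- rnorm(200, mean = ifelse(seg$eigen < 0, 0.30, 0.25),
                         sd = 0.1)
  res <- csd_lsd_test(shifted, seg, n_permutations = 1000, seed = 2)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$observed, 0)
  # reproducible under the same seed; p-values well-formed
  res_b <- csd_lsd_test(shifted, seg, n_permutations = 1000, seed = 2)
  expect_equal(res$null_values, res_b$null_values)
  expect_gte(res$p_smoothed, res$p_value)
  expect_lte(res$p_smoothed, 1)
  # degenerate segmentation is rejected
  allneg <- dplyr::mutate(seg, eigen = -abs(eigen))
  expect_error(csd_lsd_test(shifted, allneg, 100), "both eigenvalue signs")
})

test_that("the proximity test detects planted gene-element association", {
  set.seed(45)
  n_genes <- 500
  genes <- tibble::tibble(
    chrom = "Chr1",
    start = as.integer((0:(n_genes - 1)) * 10000),
    end = as.integer((0:(n_genes - 1)) * 10000 + 2000),
    id = sprintf("g%03d", 1:n_genes)
  )
  msg_ids <- genes$id[1:50]
  near_msg <- runif(50) < 0.8
  near_bg <- runif(n_genes - 50) < 0.2
  owners <- c(genes$start[1:50][near_msg] + 2500,
              genes$start[51:n_genes][near_bg] + 2500)
  tes <- tibble::tibble(chrom = "Chr1", start = as.integer(owners),
                        end = as.integer(owners) + 400L)
  res <- msg_te_proximity_test(msg_ids, genes, tes, near_dist = 2000,
                               n_draws = 2000, seed = 9)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$observed, mean(near_msg))
  expect_gte(res$p_smoothed, res$p_value)

  # when every gene is near an element the null equals the observed
  every <- tibble::tibble(chrom = "Chr1", start = genes$start,
                          end = genes$start + 100L)
  res_all <- msg_te_proximity_test(msg_ids, genes, every, n_draws = 100,
                                   seed = 1)
  expect_equal(res_all$observed, 1)
  expect_equal(res_all$p_value, 1)
  # no elements: degenerate zero fraction
  res_none <- msg_te_proximity_test(msg_ids, genes, tes[0, ], n_draws = 100,
                                    seed = 1)
  expect_equal(res_none$observed, 0)
  expect_equal(res_none$p_value, 1)
  expect_error(msg_te_proximity_test(c(msg_ids, "zz"), genes, tes),
               "absent")
})

test_that("permutation results tidy into draws and one-row summaries", {
  seg <- tibble::tibble(chrom = "Chr1", start = as.integer((0:19) * 1000))
  seg$end <- seg$start + 1000L
  seg$eigen <- rep(c(-1, 1), 10)
  sig <- tibble::tibble(chrom = "Chr1", start = seg$start,
                        value = runif(20))
  res <- csd_lsd_test(sig, seg, n_permutations = 50, seed = 3)
  td <- tidy(res)
  expect_equal(nrow(td), 50)
  expect_equal(unique(td$observed), res$observed)
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("p_value", "p_smoothed", "p_positive") %in% names(gl)))
  expect_true(gl$p_value >= 0 && gl$p_value <= 1)
})
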