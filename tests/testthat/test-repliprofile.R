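uniform_records <- function(n, len, chrom = "chr1", seed = NULL) {
  data.frame(chrom = chrom, pos = sample.int(len, n, replace = TRUE) - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("window table measures distance to the nearest feature centre", {
  withr::local_seed(1)
  sizes <- c(chr1 = 1e6)
  feats <- data.frame(chrom = "chr1", centre = 25000)
  tab <- build_window_table(uniform_records(5000, 1e6),
                            binning_scheme(50000, 50000), sizes, feats)
  expect_equal(tab$d[tab$start == 50000], 50000)  # midpoint 75 kb vs 25 kb
  expect_equal(tab$d[tab$start == 0], 0)
  expect_error(build_window_table(uniform_records(10, 1e6),
                                  binning_scheme(50000, 50000), sizes,
                                  feats[0, ]), "no features")
})

test_that("nearest-centre distances match a brute-force scan", {
  withr::local_seed(2)
  sizes <- c(chr1 = 1e7)
  feats <- data.frame(chrom = "chr1",
                      centre = sort(sample.int(1e7, 3)))
  tab <- build_window_table(uniform_records(2000, 1e7),
                            binning_scheme(50000, 50000), sizes, feats)
  mid <- floor((tab$start + tab$end) / 2)
  oracle <- vapply(mid, function(m) min(abs(m - feats$centre)), numeric(1))
  expect_equal(tab$d, oracle)
})

test_that("aberrant-count windows are flagged, not dropped", {
  withr::local_seed(3)
  sizes <- c(chr1 = 1e6)
  recs <- uniform_records(20000, 1e6)
  # plant a 20x pile-up inside one window
  pile <- data.frame(chrom = "chr1", pos = rep(425000L, 20000),
                     strand = "+", stringsAsFactors = FALSE)
  tab <- build_window_table(rbind(recs, pile), binning_scheme(50000, 50000),
                            sizes, data.frame(chrom = "chr1", centre = 0))
  expect_equal(tab$start[tab$flag_reason == "aberrant_count"], 400000)
  expect_equal(nrow(tab), 20L)                 # full accounting retained
  # exclusion intervals flag overlapping windows
  tab2 <- build_window_table(recs, binning_scheme(50000, 50000), sizes,
                             data.frame(chrom = "chr1", centre = 0),
                             exclude = data.frame(chrom = "chr1",
                                                  start = 760000,
                                                  end = 770000))
  expect_true(tab2$flagged[tab2$start == 750000])
})

test_that("distance-profile bins report t-based confidence intervals", {
  tab <- data.frame(chrom = "chr1", start = 0, end = 1,
                    count = c(10, 10, 10, 8, 10, 12),
                    d = c(10, 20, 30, 150000, 150001, 150002),
                    flagged = FALSE, flag_reason = "")
  p <- distance_profile(tab, max_dist = 3e6, bin = 1e5)
  expect_equal(p$mean, c(10, 10))
  expect_equal(p$n, c(3L, 3L))
  expect_equal(p$ci_half[1], 0)
  expect_equal(p$ci_half[2], qt(0.975, 2) * (2 / sqrt(3)))
  # empty bins are omitted, truncation applies
  expect_equal(nrow(p), 2L)
  p2 <- distance_profile(tab, max_dist = 1e5)
  expect_equal(nrow(p2), 1L)
})

test_that("profiles of uniform records are flat within their intervals", {
  withr::local_seed(7)
  sizes <- c(chr1 = 2e7)
  feats <- data.frame(chrom = "chr1", centre = c(4e6, 12e6))
  tab <- build_window_table(uniform_records(200000, 2e7),
                            binning_scheme(50000, 50000), sizes, feats)
  p <- distance_profile(tab, max_dist = 3e6)
  grand <- sum(p$mean * p$n) / sum(p$n)
  expect_true(all(abs(p$mean - grand) <= p$ci_half + 1e-9))
  # bin populations plus dropped windows account for all unflagged windows
  unflagged <- sum(!tab$flagged)
  dropped <- sum(!tab$flagged & tab$d >= 3e6)
  expect_equal(sum(p$n) + dropped, unflagged)
})

test_that("early-subset distances can exclude windows nearer other zones", {
  tab <- data.frame(chrom = "chr1", start = (0:9) * 1e5,
                    end = (1:10) * 1e5, count = 5,
                    d = NA, flagged = FALSE, flag_reason = "")
  feats <- data.frame(chrom = "chr1", centre = c(50000, 750000))
  tab$d <- traelr:::nearest_centre_distance(tab, feats)
  early <- feats[1, , drop = FALSE]
  p_all <- distance_profile(tab, feature_subset = early,
                            exclude_nearer_other = FALSE)
  p_excl <- distance_profile(tab, feature_subset = early,
                             exclude_nearer_other = TRUE)
  # windows nearer the late zone drop out, shortening the profile
  expect_gt(sum(p_all$n), sum(p_excl$n))
  expect_lte(max(p_excl$bin_end), 400000)
})

test_that("stratification flags the exact top quantile and nothing else", {
  tab <- data.frame(chrom = "chr1", start = (0:99) * 1000,
                    end = (1:100) * 1000, count = 1, d = 1000,
                    flagged = FALSE, flag_reason = "")
  score <- 1:100
  s <- stratify_windows(tab, score, 0.25)
  expect_equal(sum(s$flagged), 25L)
  expect_true(all(score[s$flagged] > quantile(score, 0.75)))
  expect_identical(stratify_windows(tab, score, 0), tab)
  expect_error(stratify_windows(tab, score, 1), "0, 1")
  expect_error(stratify_windows(tab, score, -0.1), "0, 1")
})

test_that("AUCs integrate the step profile and compare by t-test", {
  flat <- function(h) data.frame(bin_start = (0:9) * 1e5,
                                 bin_end = (1:10) * 1e5,
                                 mean = h, ci_half = 0, n = 10)
  a <- auc_compare(list(flat(1), flat(1)), list(flat(2), flat(2)),
                   range = c(0, 1e6))
  expect_equal(a$auc_a, c(1e6, 1e6))
  expect_equal(a$auc_b, c(2e6, 2e6))
  # identical groups: zero differences
  same <- auc_compare(list(flat(1), flat(1)), list(flat(1), flat(1)),
                      range = c(0, 1e6))
  expect_equal(same$auc_a, same$auc_b)
  expect_equal(same$p, 1)
  # AUC is linear in the profile
  expect_equal(auc_compare(list(flat(3), flat(3)), list(flat(1), flat(1)),
                           range = c(0, 1e6))$auc_a, 3 * a$auc_a)
  expect_error(auc_compare(list(flat(1)), list(flat(1), flat(1)),
                           c(0, 1e6)), ">= 2")
})

test_that("paired AUC t-test matches the closed-form statistic", {
  withr::local_seed(12)
  prof <- function(h) data.frame(bin_start = (0:9) * 1e5,
                                 bin_end = (1:10) * 1e5,
                                 mean = h, ci_half = 0, n = 10)
  base <- runif(4, 1, 2)
  shift <- base + 1 + rnorm(4, 0, 0.1)
  res <- auc_compare(lapply(shift, prof), lapply(base, prof),
                     range = c(0, 1e6))
  d <- res$auc_a - res$auc_b
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_manual)
  expect_lt(res$p, 0.01)
})

test_that("metaplots are flat at 1 for uniform density and strand-symmetric", {
  withr::local_seed(23)
  recs <- uniform_records(150000, 3e6)
  gene_p <- data.frame(chrom = "chr1", start = 1e6, end = 1.5e6,
                       strand = "+", score = 1)
  mp <- gene_metaplot(recs, gene_p, strata = list(c(0, 1)))
  expect_true(all(abs(mp$density - 1) < 0.25))
  expect_equal(mean(mp$density[mp$bin_class == "body"]), 1, tolerance = 0.05)
  gene_m <- gene_p
  gene_m$strand <- "-"
  mm <- gene_metaplot(recs, gene_m, strata = list(c(0, 1)))
  expect_equal(mm$density, rev(mp$density))
  # short genes are skipped and tallied
  short <- data.frame(chrom = "chr1", start = 10, end = 15, strand = "+",
                      score = 1)
  ms <- gene_metaplot(recs, rbind(gene_p, short), strata = list(c(0, 1)))
  expect_equal(attr(ms, "skipped"), 1L)
  expect_equal(unique(ms$n_genes), 1L)
})
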