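#' Windowed read-count table with distance to nearest feature
#'
#' Sums break records in non-overlapping windows, flags windows with
#' aberrant counts (robust outlier rule: count outside median +/- k * MAD,
#' catching e.g. CNVs and peri-centromeres) or overlapping an exclusion set,
#' and annotates each window with the distance from its midpoint to the
#' nearest feature centre (typically initiation-zone centres). Flagged
#' windows are kept in the table and marked, never silently dropped.
#'
#' @param records break record data.frame.
#' @param scheme a [binning_scheme()] with `step = window` (default 50 kb).
#' @param genome_sizes named chromosome lengths.
#' @param features data.frame with `chrom` and `centre` (or `start`/`end`,
#'   from which centres are taken); at least one feature is required.
#' @param exclude optional data.frame of intervals (`chrom`, `start`, `end`)
#'   to flag.
#' @param mad_k multiplier for the MAD outlier rule; `Inf` disables it (for
#'   inputs known to be free of copy-number artefacts).
#' @return data.frame with `chrom`, `start`, `end`, `count`, `d` (bp to the
#'   nearest feature centre; `NA` when the chromosome has no feature),
#'   `flagged`, `flag_reason`; the feature table is attached as attribute
#'   `"features"`.
#' @export
build_window_table <- function(records, scheme = binning_scheme(50000, 50000),
                               genome_sizes, features, exclude = NULL,
                               mad_k = 5) {
  features <- as_centres(features)
  if (nrow(features) == 0L) stop("no features supplied", call. = FALSE)
  counts <- count_breaks(records, scheme, genome_sizes)
  tab <- data.frame(chrom = counts$chrom, start = counts$start,
                    end = counts$end, count = counts$F + counts$R,
                    stringsAsFactors = FALSE)
  tab$d <- nearest_centre_distance(tab, features)
  if (is.finite(mad_k)) {
    med <- median(tab$count)
    dev <- mad(tab$count)
    aberrant <- abs(tab$count - med) > mad_k * dev
  } else {
    aberrant <- rep(FALSE, nrow(tab))
  }
  excluded <- rep(FALSE, nrow(tab))
  if (!is.null(exclude) && nrow(exclude)) {
    gr_w <- GenomicRanges::GRanges(tab$chrom,
                                   IRanges::IRanges(tab$start + 1L, tab$end))
    gr_e <- GenomicRanges::GRanges(exclude$chrom,
                                   IRanges::IRanges(exclude$start + 1L,
                                                    exclude$end))
    excluded <- GenomicRanges::countOverlaps(gr_w, gr_e) > 0L
  }
  tab$flagged <- aberrant | excluded | is.na(tab$d)
  tab$flag_reason <- ifelse(aberrant, "aberrant_count",
                            ifelse(excluded, "excluded",
                                   ifelse(is.na(tab$d), "no_feature", "")))
  attr(tab, "features") <- features
  tab
}

# normalise a feature table to (chrom, centre)
as_centres <- function(features) {
  check_columns(features, "chrom")
  centre <- if ("centre" %in% names(features)) {
    features$centre
  } else {
    check_columns(features, c("start", "end"))
    floor((features$start + features$end) / 2)
  }
  data.frame(chrom = features$chrom, centre = centre,
             stringsAsFactors = FALSE)
}

# distance from window midpoints to the nearest feature centre on the same
# chromosome (NA when the chromosome has none)
nearest_centre_distance <- function(windows, features) {
  mid <- floor((windows$start + windows$end) / 2)
  d <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    cs <- sort(features$centre[features$chrom == ch])
    if (length(cs) == 0L) next
    i <- windows$chrom == ch
    m <- mid[i]
    lo <- findInterval(m, cs)
    d_left <- ifelse(lo >= 1L, m - cs[pmax(lo, 1L)], Inf)
    d_right <- ifelse(lo < length(cs), cs[pmin(lo + 1L, length(cs))] - m, Inf)
    d[i] <- pmin(d_left, d_right)
  }
  d
}

#' Mean read count as a function of distance from feature centres
#'
#' Unflagged windows are grouped into fixed-width distance bins (default
#' 100 kb) by distance to the nearest feature centre, and each bin reports
#' the mean window read count, a t-based confidence-interval half-width at
#' `conf_level`, and the number of windows. The profile is truncated at
#' `max_dist` (default 3 Mb; far regions are too rare for a useful
#' confidence interval). Empty bins are omitted.
#'
#' With `feature_subset` (e.g. only the earliest-replicating zones),
#' distances are measured to the subset centres; with
#' `exclude_nearer_other = TRUE`, windows that lie closer to a feature
#' outside the subset than to any subset feature are dropped.
#'
#' @param table window table from [build_window_table()].
#' @param max_dist truncation distance in bp.
#' @param bin distance bin width in bp.
#' @param conf_level confidence level for the interval.
#' @param feature_subset optional data.frame of feature centres (subset of
#'   the table's features).
#' @param exclude_nearer_other drop windows nearer to a non-subset feature.
#' @return data.frame with `bin_start`, `bin_end`, `mean`, `ci_half`, `n`.
#' @export
distance_profile <- function(table, max_dist = 3e6, bin = 1e5,
                             conf_level = 0.95, feature_subset = NULL,
                             exclude_nearer_other = FALSE) {
  check_columns(table, c("count", "d", "flagged"))
  t <- table[!table$flagged & !is.na(table$d), , drop = FALSE]
  d <- t$d
  if (!is.null(feature_subset)) {
    feature_subset <- as_centres(feature_subset)
    d_sub <- nearest_centre_distance(t, feature_subset)
    keep <- !is.na(d_sub)
    if (exclude_nearer_other) keep <- keep & (d_sub <= t$d + 1e-9)
    t <- t[keep, , drop = FALSE]
    d <- d_sub[keep]
  }
  keep <- d < max_dist
  t <- t[keep, , drop = FALSE]
  d <- d[keep]
  if (nrow(t) == 0L) {
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      mean = numeric(0), ci_half = numeric(0),
                      n = integer(0)))
  }
  idx <- floor(d / bin)
  agg <- split(t$count, idx)
  bins <- as.numeric(names(agg))
  n <- vapply(agg, length, integer(1))
  m <- vapply(agg, mean, numeric(1))
  s <- vapply(agg, function(v) if (length(v) > 1L) sd(v) else NA_real_,
              numeric(1))
  ci <- rep(NA_real_, length(n))
  multi <- n > 1L
  ci[multi] <- qt(1 - (1 - conf_level) / 2, n[multi] - 1L) *
    s[multi] / sqrt(n[multi])
  out <- data.frame(bin_start = bins * bin, bin_end = (bins + 1) * bin,
                    mean = m, ci_half = ci, n = n, row.names = NULL)
  out[order(out$bin_start), , drop = FALSE]
}

#' Flag the most highly scored windows
#'
#' Flags the top `drop_top_fraction` of unflagged windows by an external
#' score (e.g. a nascent-transcription proxy), so that profiles can be
#' recomputed on the transcriptionally quiet part of the genome. The
#' threshold is the `1 - drop_top_fraction` type-7 quantile of the unflagged
#' scores; windows at or above it are flagged (ties at the threshold are
#' dropped).
#'
#' @param table window table from [build_window_table()].
#' @param score numeric score per window (same row order as `table`).
#' @param drop_top_fraction fraction in \[0, 1) of top-scoring windows to
#'   flag; 0 is the identity.
#' @return the table with updated `flagged`/`flag_reason`.
#' @export
stratify_windows <- function(table, score, drop_top_fraction) {
  stopifnot(length(score) == nrow(table))
  if (!is.numeric(drop_top_fraction) || drop_top_fraction < 0 ||
      drop_top_fraction >= 1) {
    stop("drop_top_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (drop_top_fraction == 0) return(table)
  active <- !table$flagged
  if (any(is.na(score[active]))) {
    stop("score missing for unflagged window(s)", call. = FALSE)
  }
  thr <- quantile(score[active], probs = 1 - drop_top_fraction, type = 7,
                  names = FALSE)
  hit <- active & score >= thr
  table$flagged[hit] <- TRUE
  table$flag_reason[hit] <- "score_stratified"
  table
}

#' Compare groups of distance profiles by area under the curve
#'
#' Each replicate profile is reduced to the integral of its piecewise-
#' constant mean read count over a distance range (AUC; a flat profile at
#' height h over a 1 Mb range has AUC h * 1e6), and the two groups are
#' compared with a two-sided t-test: paired across matched replicates
#' (default) or Welch unpaired.
#'
#' @param profiles_a,profiles_b lists of [distance_profile()] tables, at
#'   least two per group; for a paired test, matched by position.
#' @param range numeric length-2 distance range (bp) over which to
#'   integrate; each bin contributes its mean times its overlap with the
#'   range.
#' @param paired paired or Welch test.
#' @return list with `auc_a`, `auc_b` (per replicate), `t`, `p`, `paired`.
#' @export
auc_compare <- function(profiles_a, profiles_b, range, paired = TRUE) {
  if (length(profiles_a) < 2L || length(profiles_b) < 2L) {
    stop("need >= 2 replicate profiles per group", call. = FALSE)
  }
  one_auc <- function(p) {
    overlap <- pmax(0, pmin(p$bin_end, range[2]) - pmax(p$bin_start, range[1]))
    sum(p$mean * overlap)
  }
  auc_a <- vapply(profiles_a, one_auc, numeric(1))
  auc_b <- vapply(profiles_b, one_auc, numeric(1))
  tt <- if (paired) {
    if (length(auc_a) != length(auc_b)) {
      stop("paired test needs equal group sizes", call. = FALSE)
    }
    if (sd(auc_a - auc_b) == 0) {
      list(statistic = if (all(auc_a == auc_b)) 0 else Inf,
           p.value = if (all(auc_a == auc_b)) 1 else 0)
    } else {
      t.test(auc_a, auc_b, paired = TRUE)
    }
  } else {
    t.test(auc_a, auc_b, paired = FALSE)
  }
  list(auc_a = auc_a, auc_b = auc_b, t = unname(tt$statistic),
       p = tt$p.value, paired = paired)
}

#' Metagene profile of break density, stratified by gene score
#'
#' Averages break read density over genes plus flanks, with the gene body
#' rescaled to a fixed number of bins and genes on the minus strand reversed
#' so that 5' to 3' runs left to right. Genes are partitioned into strata by
#' score percentile bands (e.g. a nascent-transcription proxy). Each stratum
#' profile is normalized so that the mean density over the outer halves of
#' both flanks equals 1, making background levels comparable across strata.
#'
#' @param records break record data.frame.
#' @param genes data.frame with `chrom`, `start`, `end`, `strand` and a
#'   `score` column used for stratification.
#' @param flank flank size in bp on each side.
#' @param strata list of `c(lo, hi)` percentile bands partitioning \[0, 1\].
#' @param body_bins number of scaled gene-body bins.
#' @param flank_bins number of fixed-width bins per flank.
#' @return data.frame with `stratum`, `bin` (1-based, upstream flank then
#'   body then downstream flank), `bin_class` (`flank5`, `body`, `flank3`),
#'   `density` (normalized mean density) and `n_genes`; genes shorter than
#'   one body bin are skipped and counted in attribute `"skipped"`.
#' @export
gene_metaplot <- function(records, genes, flank = 1e5,
                          strata = list(c(0, 0.4), c(0.4, 0.7),
                                        c(0.7, 0.9), c(0.9, 1)),
                          body_bins = 20L, flank_bins = 20L) {
  check_columns(genes, c("chrom", "start", "end", "strand", "score"))
  n <- nrow(genes)
  pct <- (rank(genes$score, ties.method = "first") - 0.5) / n
  stratum_of <- rep(NA_integer_, n)
  for (i in seq_along(strata)) {
    b <- strata[[i]]
    stratum_of[pct > b[1] & pct <= b[2]] <- i
  }
  stratum_of[pct <= strata[[1]][2] & is.na(stratum_of)] <- 1L
  labels <- vapply(strata, function(b) {
    sprintf("%g-%g%%", 100 * b[1], 100 * b[2])
  }, character(1))

  fw <- flank / flank_bins
  total_bins <- 2L * flank_bins + body_bins
  skip <- 0L
  acc <- matrix(0, nrow = length(strata), ncol = total_bins)
  ngenes <- integer(length(strata))
  by_chrom <- split(records$pos, records$chrom)
  for (g in seq_len(n)) {
    len <- genes$end[g] - genes$start[g]
    if (len < body_bins) { skip <- skip + 1L; next }
    pos <- by_chrom[[genes$chrom[g]]]
    prof <- numeric(total_bins)
    if (!is.null(pos)) {
      p <- pos[pos >= genes$start[g] - flank & pos < genes$end[g] + flank]
      up <- p[p < genes$start[g]]
      body <- p[p >= genes$start[g] & p < genes$end[g]]
      down <- p[p >= genes$end[g]]
      prof[seq_len(flank_bins)] <-
        tabulate(floor((up - (genes$start[g] - flank)) / fw) + 1L,
                 flank_bins) / fw
      prof[flank_bins + seq_len(body_bins)] <-
        tabulate(floor((body - genes$start[g]) / len * body_bins) + 1L,
                 body_bins) / (len / body_bins)
      prof[flank_bins + body_bins + seq_len(flank_bins)] <-
        tabulate(floor((down - genes$end[g]) / fw) + 1L, flank_bins) / fw
    }
    if (genes$strand[g] == "-") prof <- rev(prof)
    s <- stratum_of[g]
    acc[s, ] <- acc[s, ] + prof
    ngenes[s] <- ngenes[s] + 1L
  }
  out <- vector("list", length(strata))
  outer_idx <- c(seq_len(flank_bins %/% 2),
                 total_bins - seq_len(flank_bins %/% 2) + 1L)
  for (s in seq_along(strata)) {
    prof <- if (ngenes[s] > 0L) acc[s, ] / ngenes[s] else rep(NA_real_,
                                                              total_bins)
    bg <- mean(prof[outer_idx])
    if (is.finite(bg) && bg > 0) prof <- prof / bg
    out[[s]] <- data.frame(
      stratum = labels[s], bin = seq_len(total_bins),
      bin_class = rep(c("flank5", "body", "flank3"),
                      c(flank_bins, body_bins, flank_bins)),
      density = prof, n_genes = ngenes[s], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skip
  res
}

#' Body/flank enrichment of a metaplot stratum
#'
#' Mean normalized density over gene-body bins divided by the mean over the
#' outer flank halves (which is 1 by construction after normalization).
#'
#' @param metaplot output of [gene_metaplot()].
#' @param stratum stratum label to summarise (default: last stratum).
#' @return numeric ratio.
#' @export
metaplot_body_ratio <- function(metaplot, stratum = NULL) {
  if (is.null(stratum)) stratum <- utils::tail(unique(metaplot$stratum), 1L)
  m <- metaplot[metaplot$stratum == stratum, , drop = FALSE]
  mean(m$density[m$bin_class == "body"])
}

#' Write a distance profile as TSV
#'
#' @param profile a [distance_profile()] table.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_profile <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
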