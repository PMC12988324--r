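# in-code fixtures shared across the suite

default_layout <- read_layout()
default_table <- trael_barcodes()

# random aligned-read table for dedup tests; duplicates arise naturally from
# the small position/UMI pools
random_aligned_reads <- function(n, n_pos = 20L, n_umi = 10L,
                                 lq_fraction = 0.5, n_seq = 5L) {
  pos <- sample(seq(1000L, 1000L * n_pos, by = 1000L), n, replace = TRUE)
  data.frame(
    qname = sprintf("r%05d", sample.int(n)),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = pos,
    end = pos + 50L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    mapq = ifelse(runif(n) < lq_fraction, 10L, 42L),
    umi = sample(replicate(n_umi, paste(sample(c("A", "C", "G", "T"), 8,
                                               replace = TRUE),
                                        collapse = "")), n, replace = TRUE),
    seq = sample(replicate(n_seq, paste(sample(c("A", "C", "G", "T"), 50,
                                               replace = TRUE),
                                        collapse = "")), n, replace = TRUE),
    sample = "s1",
    stringsAsFactors = FALSE
  )
}

# independent brute-force deduplication: group by the two key rules and keep
# the coordinate-first (name tie-break) read of each group
brute_force_dedup <- function(reads, policy = dedup_policy()) {
  pos <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  hq <- reads$mapq > policy$hq_threshold
  key <- ifelse(hq,
                paste("hq", reads$sample, reads$chrom, pos, reads$strand,
                      reads$umi),
                paste("lq", reads$sample, reads$umi,
                      substr(reads$seq, 1L, policy$prefix_length)))
  keep <- unlist(lapply(split(seq_len(nrow(reads)), key), function(idx) {
    o <- order(reads$chrom[idx], pos[idx], reads$strand[idx],
               reads$qname[idx])
    idx[o[1L]]
  }))
  sort(reads$qname[keep])
}

# log-probability of a given state path under the model
path_loglik <- function(increments, model, path) {
  p <- match(path, model$states)
  ll <- traelr:::emission_loglik(increments, model)
  lt <- log(model$trans)
  lp <- log(1 / 3) + ll[1L, p[1L]]
  n <- length(p)
  if (n > 1L) for (j in 2:n) lp <- lp + lt[p[j - 1L], p[j]] + ll[j, p[j]]
  unname(lp)
}

# exhaustive decoding: enumerate all 3^n state paths (n <= 12) and return
# the best path and its log-probability
enumerate_viterbi <- function(increments, model) {
  n <- length(increments)
  ll <- traelr:::emission_loglik(increments, model)
  lt <- log(model$trans)
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  scores <- log(1 / 3)
  for (j in seq_len(n)) {
    scores <- scores + ll[cbind(j, grid[, j])]
    if (j > 1L) scores <- scores + lt[cbind(grid[, j - 1L], grid[, j])]
  }
  best <- which.max(scores)
  list(path = model$states[grid[best, ]], loglik = unname(scores[best]),
       n_optimal = sum(scores > scores[best] - 1e-9))
}

# small single-origin fork model on one chromosome
lone_origin_model <- function(len = 2e6, iz_start = 9e5, iz_end = 1.1e6,
                              n_cells = 5L, reads_per_cell = 2000,
                              speed = speed_profile(), ...) {
  fork_model(
    genome = c(chr1 = len),
    izs = data.frame(chrom = "chr1", start = iz_start, end = iz_end,
                     efficiency = 1, t_mean = 1, t_sd = 0.1),
    speed = speed, n_cells = n_cells, reads_per_cell = reads_per_cell, ...
  )
}

# synthetic RFD track with planted initiation/termination zones:
# the RFD rises from -1 to +1 over `zone_bins` bins at each IZ and falls
# back over each TZ, with Gaussian noise of sd mu/4 on the increments;
# returns the track plus the planted IZ centres
planted_iz_track <- function(n_iz = 10L, period_bins = 24L, bin = 50000,
                             zone_bins = 5L, lead_bins = 3L,
                             noise_factor = 1 / 4) {
  mu <- 2 / zone_bins
  inc <- numeric(0)
  iz_centres <- numeric(0)
  for (i in seq_len(n_iz)) {
    up <- rep(mu, zone_bins)
    flat1 <- rep(0, (period_bins - 2L * zone_bins) %/% 2L)
    dn <- rep(-mu, zone_bins)
    flat2 <- rep(0, period_bins - 2L * zone_bins - length(flat1))
    start_bin <- lead_bins + (i - 1L) * period_bins
    iz_centres <- c(iz_centres, (start_bin + zone_bins / 2) * bin)
    inc <- c(inc, up, flat1, dn, flat2)
  }
  inc <- c(rep(0, lead_bins), inc)
  inc <- inc + rnorm(length(inc), 0, mu * noise_factor)
  rfd <- -1 + cumsum(c(0, inc))
  n <- length(rfd)
  track <- data.frame(chrom = "chr1", start = (0:(n - 1L)) * bin,
                      end = (1:n) * bin, rfd = rfd,
                      stringsAsFactors = FALSE)
  list(track = track, iz_centres = iz_centres, mu = mu, bin = bin,
       increments = inc)
}
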