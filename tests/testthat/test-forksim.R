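test_that("model construction validates zones and speed", {
  expect_error(fork_model(c(chr1 = 1e6),
                          data.frame(chrom = "chr1", start = c(0, 5e4),
                                     end = c(1e5, 1.5e5), efficiency = 1,
                                     t_mean = 1, t_sd = 0)), "overlap")
  expect_error(speed_profile(base = -1))
  expect_error(speed_profile(dist_breaks = 1e6, dist_factors = 1))
})

test_that("a lone origin replicates rightward right of itself", {
  withr::local_seed(31)
  model <- lone_origin_model(len = 1e6, iz_start = 499999,
                             iz_end = 500001, n_cells = 1L)
  cell <- simulate_cell(model, "chr1")
  x0 <- cell$origins$pos
  expect_true(all(cell$rightward[cell$rg$mid > x0 + 1]))
  expect_true(all(!cell$rightward[cell$rg$mid < x0 - 1]))
  expect_equal(length(cell$terminations), 0L)
})

test_that("termination sits at the midpoint for synchronous origins", {
  withr::local_seed(32)
  model <- fork_model(
    genome = c(chr1 = 2e6),
    izs = data.frame(chrom = "chr1", start = c(499999, 1499999),
                     end = c(500001, 1500001), efficiency = 1,
                     t_mean = 1, t_sd = 0),
    grid = 500L
  )
  cell <- simulate_cell(model, "chr1")
  expect_equal(length(cell$terminations), 1L)
  expect_lt(abs(cell$terminations - 1e6), 2 * model$grid + 2)
})

test_that("firing-time offsets displace termination by v * dt / 2", {
  withr::local_seed(33)
  dt <- 100
  v <- 1000
  model <- fork_model(
    genome = c(chr1 = 2e6),
    izs = data.frame(chrom = "chr1", start = c(499999, 1499999),
                     end = c(500001, 1500001), efficiency = 1,
                     t_mean = c(1, 1 + dt), t_sd = 0),
    speed = speed_profile(base = v), grid = 500L
  )
  cell <- simulate_cell(model, "chr1")
  # origin 2 fires dt later, termination moves v*dt/2 = 50 kb toward it
  expect_lt(abs(cell$terminations - (1e6 + v * dt / 2)),
            2 * model$grid + 2)
})

test_that("constant speed gives uniform read positions", {
  withr::local_seed(34)
  model <- lone_origin_model(len = 2e6, n_cells = 10L,
                             reads_per_cell = 2000)
  sim <- simulate_replication(model, samples = "s1")
  counts <- count_breaks(sim_break_records(sim),
                         binning_scheme(50000, 50000), model$genome)
  tot <- counts$F + counts$R
  p <- chisq.test(tot)$p.value
  expect_gt(p, 0.01)
})

test_that("read density halves where speed doubles", {
  withr::local_seed(35)
  model <- fork_model(
    genome = c(chr1 = 2e6),
    izs = data.frame(chrom = "chr1", start = 0, end = 2e4, efficiency = 1,
                     t_mean = 1, t_sd = 0.1),
    speed = speed_profile(base = 1000,
                          regions = data.frame(chrom = "chr1", start = 1e6,
                                               end = 2e6, factor = 2)),
    n_cells = 20L, reads_per_cell = 3000
  )
  sim <- simulate_replication(model, samples = "s1")
  r <- sim_break_records(sim)
  ratio <- sum(r$pos >= 1e6) / sum(r$pos < 1e6)
  expect_equal(ratio, 0.5, tolerance = 0.05)
})

test_that("fork polarity maps to read strand", {
  withr::local_seed(36)
  model <- lone_origin_model(len = 2e6, iz_start = 999999, iz_end = 1000001,
                             n_cells = 5L, reads_per_cell = 1000)
  sim <- simulate_replication(model, samples = "s1")
  right_reads <- sim$reads[sim$reads$pos > 1.1e6, ]
  left_reads <- sim$reads[sim$reads$pos < 0.9e6, ]
  expect_true(all(right_reads$strand == "-"))
  expect_true(all(left_reads$strand == "+"))
})

test_that("truth RFD matches the strand fractions of sampled reads", {
  withr::local_seed(37)
  model <- lone_origin_model(len = 2e6, n_cells = 20L,
                             reads_per_cell = 5000)
  sim <- simulate_replication(model, samples = "s1")
  tr <- truth_rfd(sim, binning_scheme(100000, 100000))
  emp <- compute_rfd(count_breaks(sim_break_records(sim),
                                  binning_scheme(100000, 100000),
                                  model$genome))
  ok <- !is.na(tr$rfd) & !is.na(emp$rfd)
  expect_gt(cor(tr$rfd[ok], emp$rfd[ok]), 0.95)
})

test_that("simulation is deterministic under a fixed seed", {
  model <- lone_origin_model(len = 3e5, iz_start = 1e5, iz_end = 2e5,
                             n_cells = 2L, reads_per_cell = 200,
                             noT_fraction = 0.1, duplicate_rate = 0.1)
  s1 <- simulate_replication(model, samples = "index1", seed = 99)
  s2 <- simulate_replication(model, samples = "index1", seed = 99)
  expect_identical(s1$reads, s2$reads)
  g1 <- random_genome(model)
  dir <- withr::local_tempdir()
  set.seed(7)
  emit_fastq(s1, g1, fastq_out = file.path(dir, "a.fastq"))
  set.seed(7)
  emit_fastq(s2, g1, fastq_out = file.path(dir, "b.fastq"))
  expect_identical(readLines(file.path(dir, "a.fastq")),
                   readLines(file.path(dir, "b.fastq")))
})

test_that("emitted inserts slice the genome at the break", {
  withr::local_seed(38)
  model <- lone_origin_model(len = 1e5, iz_start = 4e4, iz_end = 6e4,
                             n_cells = 2L, reads_per_cell = 100,
                             noT_fraction = 0.2, duplicate_rate = 0.2)
  sim <- simulate_replication(model, samples = "index1")
  genome <- random_genome(model)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "x.fastq")
  truth <- emit_fastq(sim, genome, fastq_out = fq)
  lines <- readLines(fq)
  ids <- sub("^@", "", lines[seq(1, length(lines), 4)])
  seqs <- setNames(lines[seq(2, length(lines), 4)], ids)
  chr <- as.character(genome[["chr1"]])
  eligible <- which(!truth$truncated & truth$t_class == "T")
  for (i in sample(eligible, min(20, length(eligible)))) {
    r <- sim$reads[i, ]
    s <- seqs[[r$read_id]]
    ins <- substring(s, 13 + r$polyT_run)
    ref <- if (r$strand == "-") {
      revcomp(substr(chr, r$pos + 2 - nchar(ins), r$pos + 1))
    } else {
      substr(chr, r$pos + 1, r$pos + nchar(ins))
    }
    expect_identical(ins, ref)
    expect_identical(substr(s, 1, 8), r$umi)
  }
  # duplicate pairs share UMI and insert
  dup <- sim$reads[sim$reads$is_duplicate, ][1, ]
  orig <- sim$reads[sim$reads$molecule == dup$molecule &
                      !sim$reads$is_duplicate, ]
  expect_identical(dup$umi, orig$umi)
  expect_identical(substring(seqs[[dup$read_id]], 13),
                   substring(seqs[[orig$read_id]], 13))
  # noT reads start with a non-T base after the barcode
  noT_ids <- truth$read_id[truth$t_class == "noT"]
  first_base <- substr(seqs[noT_ids], 13, 13)
  expect_true(all(first_base != "T"))
})

test_that("emitted alignments validate as sorted SAM with planted MAPQs", {
  withr::local_seed(39)
  model <- lone_origin_model(len = 2e5, iz_start = 8e4, iz_end = 1.2e5,
                             n_cells = 3L, reads_per_cell = 500)
  sim <- simulate_replication(model, samples = "s1")
  aln <- emit_alignments(sim, lq_fraction = 0.3)
  # truth round-trips through the break reduction
  br <- reduce_to_break(aln)
  expect_equal(br$pos, aln$truth_pos)
  # low-MAPQ fraction within binomial CI of the configured rate
  n <- max(sim$reads$molecule)
  n_lq <- sum(aln$mapq <= 20)
  ci <- qbinom(c(0.0005, 0.9995), n, 0.3)
  expect_gte(n_lq, ci[1])
  expect_lte(n_lq, ci[2])
  # SAM passes samtools-side validation via Rsamtools conversion
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, model$genome, sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  pos <- Rsamtools::scanBam(bam)[[1]]$pos
  expect_true(!is.unsorted(pos))
})
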