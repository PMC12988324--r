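#' Position-dependent replication fork speed
#'
#' Fork speed v(x) > 0 (bp per time unit) is the product of a base speed, a
#' piecewise-constant factor of the distance d to the nearest initiation-zone
#' centre, and an optional per-region factor. Expected TrAEL-seq read density
#' is proportional to fork residence time 1/v(x), so a speed profile directly
#' encodes the read-density landscape the pipeline should recover.
#'
#' @param base base speed in bp per time unit.
#' @param dist_breaks increasing distances (bp) at which the distance factor
#'   changes.
#' @param dist_factors factors per distance interval
#'   (`length(dist_breaks) + 1`); e.g. `dist_breaks = 1e6`,
#'   `dist_factors = c(1, 2)` doubles speed beyond 1 Mb from a zone centre.
#' @param regions optional data.frame (`chrom`, `start`, `end`, `factor`)
#'   multiplying speed inside intervals (e.g. slower forks in transcribed
#'   gene bodies).
#' @return object of class `speed_profile`.
#' @export
speed_profile <- function(base = 1000, dist_breaks = numeric(0),
                          dist_factors = 1, regions = NULL) {
  stopifnot(base > 0, length(dist_factors) == length(dist_breaks) + 1L,
            all(dist_factors > 0), !is.unsorted(dist_breaks))
  if (!is.null(regions)) {
    check_columns(regions, c("chrom", "start", "end", "factor"))
    stopifnot(all(regions$factor > 0))
  }
  structure(list(base = base, dist_breaks = dist_breaks,
                 dist_factors = dist_factors, regions = regions),
            class = "speed_profile")
}

# evaluate v at positions x (bp) on chrom given distance d to nearest IZ centre
speed_at <- function(speed, chrom, x, d) {
  v <- rep(speed$base, length(x))
  if (length(speed$dist_breaks)) {
    v <- v * speed$dist_factors[findInterval(d, speed$dist_breaks) + 1L]
  } else {
    v <- v * speed$dist_factors[1L]
  }
  if (!is.null(speed$regions)) {
    reg <- speed$regions[speed$regions$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(reg))) {
      hit <- x >= reg$start[i] & x < reg$end[i]
      v[hit] <- v[hit] * reg$factor[i]
    }
  }
  v
}

#' Replication fork model
#'
#' Defines the ground truth for simulated TrAEL-seq data: a genome of named
#' chromosome lengths, initiation zones with firing efficiency and
#' firing-time distribution, a fork-speed profile, and library parameters.
#' In each simulated cell, every zone fires with its efficiency at a time
#' drawn from a normal distribution truncated at 0, at a uniform position
#' within the zone; every genomic position is replicated by whichever fork
#' arrives first (passive replication of unfired zones falls out of the
#' arrival-time sweep). Reads are placed with density proportional to
#' residence time 1/v and carry the polarity of the replicating fork:
#' rightward forks yield reverse-strand reads, leftward forks forward-strand
#' reads (the captured leading-strand 3' end points back toward the origin).
#'
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param izs data.frame with `chrom`, `start`, `end`, `efficiency` in
#'   (0, 1], `t_mean`, `t_sd` (firing time mean and spread, time units);
#'   zones must not overlap.
#' @param speed a [speed_profile()].
#' @param n_cells cells per simulated sample.
#' @param reads_per_cell expected captured reads per cell (Poisson).
#' @param duplicate_rate probability that a read gains one PCR duplicate
#'   (identical UMI and position).
#' @param noT_fraction fraction of reads emitted without the templated
#'   poly-T (the putative RNA-derived class).
#' @param grid residence-grid resolution in bp.
#' @return object of class `fork_model`.
#' @export
fork_model <- function(genome, izs, speed = speed_profile(),
                       n_cells = 50L, reads_per_cell = 1000,
                       duplicate_rate = 0, noT_fraction = 0, grid = 1000L) {
  stopifnot(!is.null(names(genome)), all(genome > 0))
  check_columns(izs, c("chrom", "start", "end", "efficiency", "t_mean",
                       "t_sd"))
  stopifnot(all(izs$efficiency > 0), all(izs$efficiency <= 1),
            all(izs$start < izs$end), all(izs$t_sd >= 0),
            all(izs$chrom %in% names(genome)),
            duplicate_rate >= 0, duplicate_rate <= 1,
            noT_fraction >= 0, noT_fraction <= 1)
  for (ch in unique(izs$chrom)) {
    z <- izs[izs$chrom == ch, , drop = FALSE]
    z <- z[order(z$start), , drop = FALSE]
    if (nrow(z) > 1L && any(z$start[-1L] < z$end[-nrow(z)])) {
      stop("initiation zones overlap on ", ch, call. = FALSE)
    }
  }
  izs$centre <- floor((izs$start + izs$end) / 2)
  structure(list(genome = genome, izs = izs, speed = speed,
                 n_cells = as.integer(n_cells),
                 reads_per_cell = reads_per_cell,
                 duplicate_rate = duplicate_rate,
                 noT_fraction = noT_fraction, grid = as.integer(grid)),
            class = "fork_model")
}

# residence grid for one chromosome: cell boundaries, midpoints, widths,
# speed and residence time per cell
residence_grid <- function(model, chrom) {
  len <- model$genome[[chrom]]
  bounds <- unique(c(seq(0, len, by = model$grid), len))
  mid <- (utils::head(bounds, -1L) + utils::tail(bounds, -1L)) / 2
  width <- diff(bounds)
  centres <- model$izs$centre[model$izs$chrom == chrom]
  d <- if (length(centres)) {
    vapply(mid, function(m) min(abs(m - centres)), numeric(1))
  } else {
    rep(Inf, length(mid))
  }
  v <- speed_at(model$speed, chrom, mid, d)
  list(bounds = bounds, mid = mid, width = width, v = v,
       residence = width / v,
       cum = cumsum(c(0, width / v)))   # cumulative residence at boundaries
}

# cumulative residence time at arbitrary positions (piecewise linear)
cum_residence_at <- function(rg, x) {
  i <- pmin(pmax(findInterval(x, rg$bounds, rightmost.closed = TRUE), 1L),
            length(rg$width))
  rg$cum[i] + (x - rg$bounds[i]) / rg$v[i]
}

#' Simulate replication of one chromosome in one cell
#'
#' Samples fired origins and computes, for every residence-grid cell, which
#' fork replicates it (the fork with the earliest arrival time, where travel
#' time is the integral of 1/v along the path) and in which direction.
#' Chromosomes where no origin fires are resampled so that every position is
#' replicated exactly once.
#'
#' @param model a [fork_model()].
#' @param chrom chromosome name.
#' @return list with `origins` (data.frame `pos`, `time`), `rightward`
#'   (logical per grid cell), `terminations` (boundary coordinates where
#'   converging forks meet) and the residence grid `rg`.
#' @export
simulate_cell <- function(model, chrom) {
  izs <- model$izs[model$izs$chrom == chrom, , drop = FALSE]
  if (nrow(izs) == 0L) stop("no initiation zone on ", chrom, call. = FALSE)
  repeat {
    fired <- runif(nrow(izs)) < izs$efficiency
    if (any(fired)) break
  }
  z <- izs[fired, , drop = FALSE]
  pos <- z$start + runif(nrow(z)) * (z$end - z$start)
  time <- rnorm(nrow(z), z$t_mean, z$t_sd)
  for (k in 1:10) {
    neg <- time < 0
    if (!any(neg)) break
    time[neg] <- rnorm(sum(neg), z$t_mean[neg], z$t_sd[neg])
  }
  time[time < 0] <- 0

  rg <- residence_grid(model, chrom)
  c0 <- cum_residence_at(rg, pos)
  cm <- cum_residence_at(rg, rg$mid)
  arrival <- outer(c0, cm, function(a, b) abs(b - a)) + time   # origins x cells
  winner <- max.col(-t(arrival), ties.method = "first")
  rightward <- rg$mid >= pos[winner]
  flips <- which(diff(!rightward) == 1L)       # R -> L boundaries
  list(origins = data.frame(pos = pos, time = time),
       rightward = rightward,
       terminations = rg$bounds[flips + 1L],
       rg = rg)
}

#' Simulate a multiplexed TrAEL-seq experiment
#'
#' Runs the per-cell replication model for each sample, places reads by
#' residence-time sampling (density proportional to 1/v) with fork-polarity
#' strands, attaches random 8-nt UMIs, clones PCR duplicates and assigns
#' poly-T run lengths (1 + Geometric(0.5); 0 for the noT fraction). Also
#' accumulates, per residence-grid cell, the rightward and leftward residence
#' mass across all cells, from which the ground-truth RFD track is computed.
#'
#' @param model a [fork_model()].
#' @param samples character vector of sample names (one library each).
#' @param seed optional integer seed for reproducibility.
#' @return list with `reads` (data.frame `read_id`, `molecule`, `sample`,
#'   `cell`, `chrom`, `pos` (0-based break-adjacent base), `strand`, `umi`,
#'   `polyT_run`, `t_class`, `is_duplicate`), `truth` (per-chromosome list
#'   with `right`, `left` residence accumulators and grid), and `model`.
#' @export
simulate_replication <- function(model, samples = "sample1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(model$genome)
  truth <- lapply(chroms, function(ch) {
    rg <- residence_grid(model, ch)
    list(rg = rg, right = numeric(length(rg$mid)),
         left = numeric(length(rg$mid)))
  })
  names(truth) <- chroms
  # chromosome read shares follow total residence (uniform-speed genomes
  # reduce to length-proportional shares)
  res_tot <- vapply(truth, function(t) sum(t$rg$residence), numeric(1))
  share <- res_tot / sum(res_tot)

  out <- vector("list", length(samples) * model$n_cells * length(chroms))
  k <- 0L
  for (smp in samples) {
    for (cell in seq_len(model$n_cells)) {
      for (ci in seq_along(chroms)) {
        ch <- chroms[ci]
        map <- simulate_cell(model, ch)
        r <- map$rg$residence
        truth[[ch]]$right <- truth[[ch]]$right + r * map$rightward
        truth[[ch]]$left <- truth[[ch]]$left + r * !map$rightward
        n <- rpois(1L, model$reads_per_cell * share[ci])
        if (n == 0L) next
        cells <- sample.int(length(r), n, replace = TRUE, prob = r)
        pos <- floor(map$rg$bounds[cells] +
                       runif(n) * map$rg$width[cells])
        right <- map$rightward[cells]
        k <- k + 1L
        out[[k]] <- data.frame(
          sample = smp, cell = cell, chrom = ch, pos = pos,
          strand = ifelse(right, "-", "+"), stringsAsFactors = FALSE)
      }
    }
  }
  reads <- do.call(rbind, out[seq_len(k)])
  n <- nrow(reads)
  reads$read_id <- sprintf("sim%08d", seq_len(n))
  reads$molecule <- seq_len(n)
  reads$umi <- random_dna(n, 8L)
  reads$t_class <- ifelse(runif(n) < model$noT_fraction, "noT", "T")
  reads$polyT_run <- ifelse(reads$t_class == "noT", 0L,
                            1L + rgeom(n, 0.5))
  reads$is_duplicate <- FALSE
  if (model$duplicate_rate > 0) {
    dup <- which(runif(n) < model$duplicate_rate)
    if (length(dup)) {
      clones <- reads[dup, , drop = FALSE]
      clones$is_duplicate <- TRUE
      clones$read_id <- sprintf("sim%08d", n + seq_along(dup))
      reads <- rbind(reads, clones)
    }
  }
  reads <- reads[, c("read_id", "molecule", "sample", "cell", "chrom", "pos",
                     "strand", "umi", "polyT_run", "t_class", "is_duplicate")]
  list(reads = reads, truth = truth, model = model)
}

#' Ground-truth RFD track from a simulation
#'
#' Aggregates the simulator's rightward/leftward residence accumulators into
#' windows of a binning scheme. The truth RFD of a window is
#' `(right - left) / (right + left)` residence mass, i.e.
#' `2 P(rightward read) - 1` under residence-time sampling.
#'
#' @param sim result of [simulate_replication()].
#' @param scheme a [binning_scheme()].
#' @return data.frame with `chrom`, `start`, `end`, `rfd`.
#' @export
truth_rfd <- function(sim, scheme) {
  out <- lapply(names(sim$truth), function(ch) {
    t <- sim$truth[[ch]]
    wins <- scheme_windows(scheme, sim$model$genome[[ch]])
    # grid cells belong to a window when their midpoint falls inside it;
    # cumulative sums give all (possibly overlapping) window totals at once
    cum_r <- c(0, cumsum(t$right))
    cum_l <- c(0, cumsum(t$left))
    lo <- findInterval(wins$start, t$rg$mid, left.open = TRUE) + 1L
    hi <- findInterval(wins$end, t$rg$mid, left.open = TRUE)
    right <- ifelse(hi >= lo, cum_r[hi + 1L] - cum_r[lo], 0)
    left <- ifelse(hi >= lo, cum_l[hi + 1L] - cum_l[lo], 0)
    tot <- right + left
    data.frame(chrom = ch, start = wins$start, end = wins$end,
               rfd = ifelse(tot > 0, (right - left) / tot, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Truth break records from simulated reads
#'
#' Formats simulated reads as break records (bypassing FASTQ emission,
#' alignment and deduplication) for direct testing of the windowing, RFD and
#' profiling stages.
#'
#' @param sim result of [simulate_replication()].
#' @param mapq mapping quality to attach.
#' @param include_duplicates keep cloned PCR duplicates.
#' @return break record data.frame as from [reduce_to_break()].
#' @export
sim_break_records <- function(sim, mapq = 42L, include_duplicates = FALSE) {
  r <- sim$reads
  if (!include_duplicates) r <- r[!r$is_duplicate, , drop = FALSE]
  data.frame(chrom = r$chrom, pos = r$pos, strand = r$strand,
             mapq = mapq, umi = r$umi, sample = r$sample,
             t_class = r$t_class, stringsAsFactors = FALSE)
}

#' Generate a random genome sequence for a fork model
#'
#' @param model a [fork_model()].
#' @return [Biostrings::DNAStringSet] of the model's chromosomes.
#' @export
random_genome <- function(model) {
  seqs <- lapply(model$genome, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  })
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Emit simulated reads as a multiplexed FASTQ file with truth table
#'
#' Builds raw multiplexed reads in the TrAEL-seq layout: 8-nt UMI, 4-nt
#' in-read sample barcode, poly-T run, then the captured-strand insert. A
#' reverse-strand read at break position p carries the reverse complement of
#' the forward-strand sequence ending at p; a forward-strand read carries
#' the forward-strand sequence starting at p. Reads of the noT class get a
#' poly-T run of 0 and their first insert base substituted with a random
#' non-T base (emulating a non-templated RNA-derived 3' end; the truth
#' coordinate is unchanged). Reads that would run off a chromosome end are
#' truncated and flagged in the truth table.
#'
#' @param sim result of [simulate_replication()].
#' @param genome_seqs [Biostrings::DNAStringSet] named by chromosome (e.g.
#'   from [random_genome()] or a FASTA read with
#'   [Biostrings::readDNAStringSet()]).
#' @param table a [barcode_table()] mapping sample names (index names) to
#'   barcodes.
#' @param read_length total read length in nt.
#' @param fastq_out path for the FASTQ file (`.gz` supported).
#' @param truth_out optional path for the truth TSV.
#' @param layout a [read_layout()].
#' @return invisibly, the truth data.frame (`read_id`, `sample`, `chrom`,
#'   `pos`, `strand`, `is_duplicate`, `t_class`, `truncated`).
#' @export
emit_fastq <- function(sim, genome_seqs, table = trael_barcodes(),
                       read_length = 60L, fastq_out, truth_out = NULL,
                       layout = read_layout()) {
  r <- sim$reads
  if (!all(r$sample %in% table$index_name)) {
    stop("simulated sample names must match barcode table index names",
         call. = FALSE)
  }
  bc <- setNames(table$in_read, table$index_name)[r$sample]
  header <- layout$umi_length + layout$barcode_length
  ins_len <- read_length - header - r$polyT_run
  if (any(ins_len < 1L)) ins_len <- pmax(ins_len, 1L)

  n <- nrow(r)
  insert <- character(n)
  truncated <- logical(n)
  for (ch in unique(r$chrom)) {
    i <- which(r$chrom == ch)
    len <- sim$model$genome[[ch]]
    p <- r$pos[i]                               # 0-based
    rev <- r$strand[i] == "-"
    start1 <- ifelse(rev, pmax(1L, p + 2L - ins_len[i]), p + 1L)
    end1 <- ifelse(rev, p + 1L, pmin(len, p + ins_len[i]))
    truncated[i] <- (end1 - start1 + 1L) < ins_len[i]
    v <- Biostrings::Views(genome_seqs[[ch]], start = start1, end = end1)
    s <- Biostrings::DNAStringSet(v)
    s[rev] <- Biostrings::reverseComplement(s[rev])
    insert[i] <- as.character(s)
  }
  noT <- r$t_class == "noT"
  if (any(noT)) {
    sub1 <- sample(c("A", "C", "G"), sum(noT), replace = TRUE)
    substr(insert[noT], 1L, 1L) <- sub1
  }
  seqs <- paste0(r$umi, bc, strrep("T", r$polyT_run), insert)
  quals <- strrep("I", nchar(seqs))
  con <- open_text(fastq_out, "w")
  on.exit(close(con))
  writeLines(paste0("@", r$read_id, "\n", seqs, "\n+\n", quals), con)
  truth <- data.frame(read_id = r$read_id, sample = r$sample,
                      chrom = r$chrom, pos = r$pos, strand = r$strand,
                      is_duplicate = r$is_duplicate, t_class = r$t_class,
                      truncated = truncated, stringsAsFactors = FALSE)
  if (!is.null(truth_out)) {
    write.table(truth, truth_out, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(truth)
}

#' Emit simulated reads as perfect alignments
#'
#' Bypasses mapping: each read becomes an alignment at its truth coordinate
#' with the break-adjacent base at the 5' end (reverse-strand reads end at
#' the break position, forward-strand reads start at it). Mapping qualities
#' follow a two-component model: a configurable fraction of molecules are
#' "multi-copy" with low MAPQ, the rest unique with high MAPQ; PCR
#' duplicates inherit their molecule's sequence and MAPQ. Without genome
#' sequences, each molecule gets a random sequence (duplicates share it), so
#' the sequence-prefix deduplication key is still exercised.
#'
#' @param sim result of [simulate_replication()].
#' @param read_length aligned read length in nt.
#' @param mapq_hq,mapq_lq MAPQ of unique and multi-copy molecules.
#' @param lq_fraction fraction of molecules drawn as multi-copy.
#' @param genome_seqs optional [Biostrings::DNAStringSet] for true sequences.
#' @return coordinate-sorted aligned read data.frame (see
#'   [read_alignments()]) with a `truth_pos` column.
#' @export
emit_alignments <- function(sim, read_length = 40L, mapq_hq = 42L,
                            mapq_lq = 10L, lq_fraction = 0,
                            genome_seqs = NULL) {
  r <- sim$reads
  n <- nrow(r)
  lens <- sim$model$genome[r$chrom]
  rev <- r$strand == "-"
  start <- ifelse(rev, pmax(0, r$pos - read_length + 1L), r$pos)
  end <- ifelse(rev, r$pos + 1L, pmin(lens, r$pos + read_length))
  n_mol <- max(r$molecule)
  mol_lq <- runif(n_mol) < lq_fraction
  mapq <- ifelse(mol_lq[r$molecule], mapq_lq, mapq_hq)
  seq <- if (is.null(genome_seqs)) {
    mol_seq <- random_dna(n_mol, read_length)
    substr(mol_seq[r$molecule], 1L, end - start)
  } else {
    s <- character(n)
    for (ch in unique(r$chrom)) {
      i <- which(r$chrom == ch)
      v <- Biostrings::Views(genome_seqs[[ch]], start = start[i] + 1L,
                             end = end[i])
      x <- Biostrings::DNAStringSet(v)
      x[rev[i]] <- Biostrings::reverseComplement(x[rev[i]])
      s[i] <- as.character(x)
    }
    s
  }
  aln <- data.frame(qname = paste0(r$read_id, "_", r$umi),
                    chrom = r$chrom, start = start, end = end,
                    strand = r$strand, mapq = mapq, umi = r$umi, seq = seq,
                    sample = r$sample, truth_pos = r$pos,
                    stringsAsFactors = FALSE)
  aln[order(aln$chrom, aln$start, aln$qname), , drop = FALSE]
}

#' Write aligned reads as a coordinate-sorted SAM file
#'
#' @param aln aligned read data.frame (read-orientation `seq`; the SEQ field
#'   is reverse-complemented for reverse-strand records as SAM requires).
#' @param genome_sizes named chromosome lengths for the header.
#' @param path output SAM path.
#' @return invisibly, the path.
#' @export
write_sam <- function(aln, genome_sizes, path) {
  aln <- aln[order(aln$chrom, aln$start, aln$qname), , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome_sizes),
                      as.integer(genome_sizes)))
  rev <- aln$strand == "-"
  seq_out <- aln$seq
  if (any(rev)) seq_out[rev] <- revcomp(aln$seq[rev])
  width <- aln$end - aln$start
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                 aln$qname, ifelse(rev, 16L, 0L), aln$chrom,
                 as.integer(aln$start) + 1L, as.integer(aln$mapq),
                 as.integer(width), seq_out, strrep("I", nchar(seq_out)))
  writeLines(c(header, rec), path)
  invisible(path)
}
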