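#' Sliding-window binning scheme
#'
#' Windows are 0-based half-open intervals `[k*step, k*step + window)`
#' anchored at coordinate 0 on each chromosome; the final partial window is
#' kept. RFD tracks use 20 kb windows spaced every 2 kb; read-density
#' profiles use non-overlapping 50 kb windows.
#'
#' @param window window size in bp.
#' @param step step between window starts in bp (`step = window` gives
#'   non-overlapping windows).
#' @return object of class `binning_scheme`.
#' @export
binning_scheme <- function(window = 20000L, step = 2000L) {
  stopifnot(window >= step, step >= 1)
  structure(list(window = as.numeric(window), step = as.numeric(step)),
            class = "binning_scheme")
}

# all windows of a scheme for one chromosome, as a data.frame
scheme_windows <- function(scheme, chrom_len) {
  starts <- seq(0, max(0, chrom_len - 1), by = scheme$step)
  data.frame(start = starts, end = pmin(starts + scheme$window, chrom_len))
}

#' Count break records in sliding windows, by strand
#'
#' Each record whose position falls inside a window increments that window on
#' its strand; with `step < window` a record contributes to up to
#' `window/step` overlapping windows. Counting uses
#' [GenomicRanges::countOverlaps()].
#'
#' @param records break record data.frame ([reduce_to_break()]).
#' @param scheme a [binning_scheme()].
#' @param genome_sizes named vector of chromosome lengths; records beyond a
#'   chromosome end are an error.
#' @return data.frame with columns `chrom`, `start`, `end`, `F` (forward
#'   strand count), `R` (reverse strand count).
#' @export
count_breaks <- function(records, scheme, genome_sizes) {
  check_columns(records, c("chrom", "pos", "strand"))
  stopifnot(!is.null(names(genome_sizes)))
  unknown <- setdiff(unique(records$chrom), names(genome_sizes))
  if (length(unknown)) {
    stop("records on chromosome(s) absent from genome_sizes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  over <- records$pos < 0 | records$pos >= genome_sizes[records$chrom]
  if (any(over)) {
    stop(sum(over), " record(s) beyond chromosome end", call. = FALSE)
  }
  win_list <- lapply(names(genome_sizes), function(ch) {
    w <- scheme_windows(scheme, genome_sizes[[ch]])
    w$chrom <- ch
    w
  })
  wins <- do.call(rbind, win_list)
  gr_w <- GenomicRanges::GRanges(wins$chrom,
                                 IRanges::IRanges(wins$start + 1L, wins$end))
  gr_r <- GenomicRanges::GRanges(records$chrom,
                                 IRanges::IRanges(records$pos + 1L, width = 1L))
  fwd <- records$strand == "+"
  data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
             F = GenomicRanges::countOverlaps(gr_w, gr_r[fwd]),
             R = GenomicRanges::countOverlaps(gr_w, gr_r[!fwd]),
             stringsAsFactors = FALSE)
}

#' Replication fork directionality per window
#'
#' RFD = (R - F) / (R + F), where R and F are reverse- and forward-strand
#' read counts. Because TrAEL-seq captures the leading-strand 3' end,
#' positive values report forks moving left-to-right and negative values
#' forks moving right-to-left; the track lives in \[-1, +1\]. Windows with
#' fewer than `min_reads` total reads are reported as missing (`NA`).
#'
#' @param counts stranded window counts from [count_breaks()].
#' @param min_reads minimum R + F for a defined value.
#' @return the input data.frame with an added `rfd` column.
#' @export
#' @examples
#' compute_rfd(data.frame(chrom = "c", start = 0, end = 10, F = 10, R = 30))$rfd
compute_rfd <- function(counts, min_reads = 1L) {
  check_columns(counts, c("F", "R"))
  tot <- counts$R + counts$F
  counts$rfd <- ifelse(tot >= min_reads & tot > 0,
                       (counts$R - counts$F) / tot, NA_real_)
  counts
}

#' Total-count normalization across multiplexed sets
#'
#' Read counts within a multiplexed set already reflect the relative TrAEL
#' signal of its samples, so no within-set normalization is applied. Across
#' sets, each whole set is scaled by one factor so that every set's summed
#' read count equals the mean set total; within-set ratios are preserved
#' exactly.
#'
#' @param totals named numeric vector of per-sample read totals.
#' @param sets named character vector (or factor) mapping each sample in
#'   `totals` to its multiplexed set.
#' @return list with `factors` (one per set), `sample_factors` (one per
#'   sample) and `scaled` (scaled totals).
#' @export
#' @examples
#' normalize_sets(c(a = 6e5, b = 4e5, c = 3e6),
#'                c(a = "set1", b = "set1", c = "set2"))
normalize_sets <- function(totals, sets) {
  stopifnot(!is.null(names(totals)), all(names(totals) %in% names(sets)))
  sets <- as.character(sets[names(totals)])
  set_tot <- tapply(totals, sets, sum)
  if (any(set_tot <= 0)) stop("empty multiplexed set", call. = FALSE)
  factors <- mean(set_tot) / set_tot
  sample_factors <- setNames(as.numeric(factors[sets]), names(totals))
  list(factors = setNames(as.numeric(factors), names(set_tot)),
       sample_factors = sample_factors,
       scaled = totals * sample_factors)
}

format_bedgraph <- function(chrom, start, end, value) {
  sprintf("%s\t%d\t%d\t%.4f", chrom, as.integer(start), as.integer(end), value)
}

#' Write count and RFD tracks as bedGraph
#'
#' Emits a forward-count, a reverse-count and (when an `rfd` column is
#' present) an RFD bedGraph. Missing windows are omitted; values are written
#' with fixed 4-decimal formatting, intervals sorted by chromosome and start.
#'
#' @param track data.frame from [count_breaks()] / [compute_rfd()].
#' @param prefix output path prefix; files are `<prefix>.fwd.bedgraph`,
#'   `<prefix>.rev.bedgraph`, `<prefix>.rfd.bedgraph`.
#' @return invisibly, named vector of the files written.
#' @export
write_tracks <- function(track, prefix) {
  check_columns(track, c("chrom", "start", "end"))
  t <- track[order(track$chrom, track$start), , drop = FALSE]
  files <- c()
  if ("F" %in% names(t)) {
    f <- paste0(prefix, ".fwd.bedgraph")
    writeLines(format_bedgraph(t$chrom, t$start, t$end, t$F), f)
    files["fwd"] <- f
    r <- paste0(prefix, ".rev.bedgraph")
    writeLines(format_bedgraph(t$chrom, t$start, t$end, t$R), r)
    files["rev"] <- r
  }
  if ("rfd" %in% names(t)) {
    keep <- !is.na(t$rfd)
    f <- paste0(prefix, ".rfd.bedgraph")
    writeLines(format_bedgraph(t$chrom[keep], t$start[keep], t$end[keep],
                               t$rfd[keep]), f)
    files["rfd"] <- f
  }
  invisible(files)
}

#' Read a bedGraph file
#'
#' @param path bedGraph file (no track line).
#' @param value_name name for the score column.
#' @return data.frame with `chrom`, `start`, `end` and the score column.
#' @export
read_bedgraph <- function(path, value_name = "value") {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", value_name))
  df
}
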