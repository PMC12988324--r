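#' Aligned read tables
#'
#' Alignments are handled as a plain data.frame with columns `qname`, `chrom`,
#' `start`, `end` (0-based half-open span), `strand` (`"+"`/`"-"`), `mapq`,
#' `umi`, `seq` (read-orientation sequence), `sample`. [read_alignments()]
#' builds one from a coordinate-sorted SAM/BAM file; the simulator's
#' [emit_alignments()] builds one directly.
#'
#' @param path SAM or BAM file. SAM text is converted with
#'   [Rsamtools::asBam()] before import.
#' @param sample sample identifier to attach (default: file basename).
#' @param umi_from `"name"` to take the UMI as the final underscore token of
#'   the read name (the demultiplexer convention), or the name of a SAM tag
#'   (e.g. `"RX"`).
#' @return data.frame of aligned reads (see Details).
#' @export
read_alignments <- function(path, sample = NULL, umi_from = "name") {
  stopifnot(file.exists(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", bam), overwrite = TRUE,
                     indexDestination = FALSE)
    path <- bam
  }
  what <- c("qname", "flag", "rname", "pos", "qwidth", "mapq", "seq")
  param <- if (identical(umi_from, "name")) {
    Rsamtools::ScanBamParam(what = what)
  } else {
    Rsamtools::ScanBamParam(what = what, tag = umi_from)
  }
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  mapped <- !bitwAnd(b$flag, 4L)
  rev <- bitwAnd(b$flag, 16L) != 0L
  umi <- if (identical(umi_from, "name")) {
    umi_from_name(b$qname)
  } else {
    as.character(b$tag[[umi_from]])
  }
  df <- data.frame(
    qname = b$qname,
    chrom = as.character(b$rname),
    start = b$pos - 1L,                       # SAM POS is 1-based
    end = b$pos - 1L + b$qwidth,
    strand = ifelse(rev, "-", "+"),
    mapq = b$mapq,
    umi = umi,
    seq = as.character(b$seq),
    sample = sample %||% sub("\\.(sam|bam)$", "", basename(path),
                             ignore.case = TRUE),
    stringsAsFactors = FALSE
  )
  df[mapped, , drop = FALSE]
}

# 0-based coordinate of the 5'-most base in read orientation
break_pos <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

#' Reduce aligned reads to single-base break records
#'
#' Each retained alignment is reduced to the single base immediately 5' of
#' the captured strand break: the alignment start for forward-strand reads,
#' the last aligned base for reverse-strand reads. Reverse-strand records
#' report forks moving left-to-right (the leading-strand 3' end points back
#' toward the origin), forward-strand records forks moving right-to-left.
#'
#' @param reads aligned read data.frame (see [read_alignments()]).
#' @param t_class T/noT class to attach (recycled), or a vector.
#' @return data.frame of break records with columns `chrom`, `pos` (0-based),
#'   `strand`, `mapq`, `umi`, `sample`, `t_class`.
#' @export
#' @examples
#' r <- data.frame(qname = "r1", chrom = "chr1", start = 100, end = 150,
#'                 strand = "-", mapq = 42, umi = "ACGTACGT", seq = "",
#'                 sample = "s1")
#' reduce_to_break(r)$pos  # 149
reduce_to_break <- function(reads, t_class = "T") {
  check_columns(reads, c("chrom", "start", "end", "strand", "mapq", "umi",
                         "sample"))
  stopifnot(all(reads$start < reads$end))
  data.frame(chrom = reads$chrom,
             pos = break_pos(reads$start, reads$end, reads$strand),
             strand = reads$strand,
             mapq = reads$mapq,
             umi = reads$umi,
             sample = reads$sample,
             t_class = rep_len(t_class, nrow(reads)),
             stringsAsFactors = FALSE)
}

#' Deduplication policy
#'
#' High-quality alignments (MAPQ above `hq_threshold`, i.e. uniquely mapped)
#' are deduplicated by mapped position and UMI, so identical molecules at
#' multiple genomic copies survive as distinct records (copy-number
#' awareness). Low-quality alignments (MAPQ at or below the threshold,
#' multi-mappers whose position is unreliable) are deduplicated by UMI alone;
#' because the 8-nt UMI keyspace (4^8 = 65,536) is smaller than typical
#' library complexity, the first `prefix_length` bases of the read sequence
#' are appended to the UMI key.
#'
#' @param hq_threshold MAPQ above which the position-aware key is used.
#' @param prefix_length read-sequence prefix length added to the low-quality
#'   key.
#' @return object of class `dedup_policy`.
#' @export
dedup_policy <- function(hq_threshold = 20L, prefix_length = 10L) {
  stopifnot(hq_threshold >= 0, prefix_length >= 1)
  structure(list(hq_threshold = as.integer(hq_threshold),
                 prefix_length = as.integer(prefix_length)),
            class = "dedup_policy")
}

#' Copy-number-aware UMI deduplication
#'
#' Applies the dual-key scheme of [dedup_policy()] per sample. The survivor
#' within each duplicate group is the first read in coordinate-sorted order
#' (chrom, break position, strand), with read name as the tie-break, making
#' the output deterministic. Deduplication is idempotent and the output is a
#' subset of the input.
#'
#' @param reads aligned read data.frame; a missing (`NA` or empty) UMI is an
#'   error.
#' @param policy a [dedup_policy()].
#' @return list with `reads` (the retained subset, coordinate-sorted) and
#'   `stats` (data.frame with per-class input/retained/duplicate counts).
#' @export
deduplicate_reads <- function(reads, policy = dedup_policy()) {
  check_columns(reads, c("qname", "chrom", "start", "end", "strand", "mapq",
                         "umi", "seq", "sample"))
  bad <- is.na(reads$umi) | reads$umi == ""
  if (any(bad)) {
    stop("read(s) without UMI: ",
         paste(utils::head(reads$qname[bad], 3L), collapse = ", "),
         call. = FALSE)
  }
  pos <- break_pos(reads$start, reads$end, reads$strand)
  ord <- order(reads$chrom, pos, reads$strand, reads$qname)
  r <- reads[ord, , drop = FALSE]
  pos <- pos[ord]
  hq <- r$mapq > policy$hq_threshold
  key <- character(nrow(r))
  key[hq] <- paste(r$sample[hq], r$chrom[hq], pos[hq], r$strand[hq],
                   r$umi[hq], sep = "\r")
  lq <- !hq
  key[lq] <- paste(r$sample[lq], r$umi[lq],
                   substr(r$seq[lq], 1L, policy$prefix_length), sep = "\r")
  keep <- !duplicated(paste(hq, key, sep = "\r"))
  stats <- data.frame(
    class = c("hq", "lq"),
    input = c(sum(hq), sum(lq)),
    retained = c(sum(keep & hq), c(sum(keep & lq))),
    stringsAsFactors = FALSE
  )
  stats$duplicates <- stats$input - stats$retained
  list(reads = r[keep, , drop = FALSE], stats = stats)
}

#' Filter break records or alignments by mapping quality
#'
#' The standard analysis filter keeps records with MAPQ at or above
#' `min_mapq` (default 20); disable it for multi-copy region analyses.
#'
#' @param records data.frame with a `mapq` column.
#' @param min_mapq minimum retained MAPQ.
#' @param enabled if `FALSE`, the identity.
#' @return the filtered data.frame.
#' @export
filter_by_mapq <- function(records, min_mapq = 20L, enabled = TRUE) {
  check_columns(records, "mapq")
  if (!enabled) return(records)
  records[records$mapq >= min_mapq, , drop = FALSE]
}

#' Write break records as BED6
#'
#' One line per record: chrom, pos, pos+1, name = UMI, score = MAPQ, strand.
#'
#' @param records break record data.frame from [reduce_to_break()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_breaks_bed <- function(records, path) {
  ord <- order(records$chrom, records$pos)
  r <- records[ord, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", r$chrom, as.integer(r$pos),
                   as.integer(r$pos) + 1L, r$umi, as.integer(r$mapq), r$strand)
  writeLines(lines, path)
  invisible(path)
}
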