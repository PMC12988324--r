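#' Read layout of a multiplexed TrAEL-seq read
#'
#' TrAEL-seq reads start with an 8-nt unique molecular identifier (UMI),
#' followed by a 4-nt inline sample barcode placed at the adaptor ligation
#' junction, then the poly-T run templated from the terminal-transferase
#' A-tail, then genomic insert. DNA-derived reads carry at least one T at the
#' first post-barcode position; reads without it form the "noT" class.
#'
#' @param umi_length UMI length in nucleotides.
#' @param barcode_length inline barcode length in nucleotides.
#' @param min_remaining_length minimum insert length (nt) after trimming;
#'   shorter reads are discarded as unmappable.
#' @param barcode_mismatch_tolerance maximum Hamming distance for barcode
#'   rescue; assignment requires a unique best match within tolerance.
#' @return object of class `read_layout`.
#' @export
#' @examples
#' read_layout()
read_layout <- function(umi_length = 8L, barcode_length = 4L,
                        min_remaining_length = 20L,
                        barcode_mismatch_tolerance = 1L) {
  stopifnot(umi_length > 0, barcode_length > 0, min_remaining_length >= 1,
            barcode_mismatch_tolerance >= 0,
            barcode_mismatch_tolerance < barcode_length)
  structure(list(umi_length = as.integer(umi_length),
                 barcode_length = as.integer(barcode_length),
                 min_remaining_length = as.integer(min_remaining_length),
                 barcode_mismatch_tolerance = as.integer(barcode_mismatch_tolerance)),
            class = "read_layout")
}

#' Sample barcode table
#'
#' Barcodes are specified as they appear on the adaptor strand. Because the
#' sequenced read traverses the adaptor on the complementary strand, the
#' barcode observed in the read is by default the reverse complement of the
#' adaptor sequence (`orientation = "reverse_complement_in_read"`); set
#' `orientation = "as_adaptor"` if barcodes are already given in read
#' orientation.
#'
#' A warning is emitted when the in-read barcodes are not separated by more
#' than twice the mismatch tolerance: with the unique-best assignment rule
#' this can only send corrupted reads to UNASSIGNED, never to the wrong
#' sample.
#'
#' @param index_name character vector of sample names.
#' @param adaptor_barcode character vector of barcodes (DNA alphabet).
#' @param orientation `"reverse_complement_in_read"` (default) or
#'   `"as_adaptor"`.
#' @param tolerance mismatch tolerance used for the separation check.
#' @return data.frame of class `barcode_table` with columns `index_name`,
#'   `adaptor_barcode`, `in_read`.
#' @export
#' @examples
#' barcode_table(c("s1", "s2"), c("GACT", "CAAG"))
barcode_table <- function(index_name, adaptor_barcode,
                          orientation = c("reverse_complement_in_read",
                                          "as_adaptor"),
                          tolerance = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(length(index_name) == length(adaptor_barcode),
            !anyDuplicated(index_name))
  adaptor_barcode <- toupper(adaptor_barcode)
  if (any(!grepl("^[ACGT]+$", adaptor_barcode))) {
    stop("barcodes must use the DNA alphabet A/C/G/T", call. = FALSE)
  }
  widths <- nchar(adaptor_barcode)
  if (length(unique(widths)) != 1L) stop("barcodes must share one length")
  in_read <- if (orientation == "reverse_complement_in_read") {
    revcomp(adaptor_barcode)
  } else {
    adaptor_barcode
  }
  if (anyDuplicated(in_read)) stop("in-read barcodes are not distinct")
  if (length(in_read) > 1L) {
    d <- outer(in_read, in_read, Vectorize(hamming))
    mind <- min(d[upper.tri(d)])
    if (mind <= 2L * tolerance) {
      warning(sprintf(paste0("minimum pairwise barcode distance is %d, not ",
                             "> %d; %d-mismatch reads may be ambiguous and ",
                             "will be left UNASSIGNED"),
                      mind, 2L * tolerance, tolerance), call. = FALSE)
    }
  }
  structure(data.frame(index_name = as.character(index_name),
                       adaptor_barcode = adaptor_barcode,
                       in_read = in_read,
                       stringsAsFactors = FALSE),
            orientation = orientation,
            class = c("barcode_table", "data.frame"))
}

#' The six published multiplexing barcodes
#'
#' Adaptor-strand sequences of the six multiplexing indexes with equivalent
#' ligation efficiency (indexes 1, 3, 5, 6, 7 and 8).
#'
#' @inheritParams barcode_table
#' @return a [barcode_table()].
#' @export
trael_barcodes <- function(orientation = "reverse_complement_in_read") {
  suppressWarnings(barcode_table(
    index_name = c("index1", "index3", "index5", "index6", "index7", "index8"),
    adaptor_barcode = c("GACT", "CAAG", "CCTT", "GGAA", "GCAC", "TGGC"),
    orientation = orientation
  ))
}

#' Read a barcode table from a two-column TSV
#'
#' @param path TSV with columns index_name, adaptor_barcode (no header, or a
#'   header starting with `index_name`).
#' @inheritParams barcode_table
#' @return a [barcode_table()].
#' @export
read_barcode_table <- function(path,
                               orientation = "reverse_complement_in_read") {
  first <- readLines(path, n = 1L)
  header <- grepl("^index_name", first)
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  barcode_table(df[[1]], df[[2]], orientation = orientation)
}

# vectorised barcode assignment: returns index into table, NA for
# no/ambiguous match within tolerance
match_barcodes <- function(bc, table, tolerance) {
  k <- nrow(table)
  n <- length(bc)
  if (n == 0L) return(integer(0))
  width <- nchar(table$in_read[1])
  obs <- matrix(unlist(strsplit(bc, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
  dist <- matrix(0L, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    ref <- strsplit(table$in_read[j], "", fixed = TRUE)[[1]]
    dist[, j] <- rowSums(obs != matrix(ref, n, width, byrow = TRUE))
  }
  best <- apply(dist, 1L, min)
  nbest <- rowSums(dist == best)
  hit <- max.col(-dist, ties.method = "first")
  hit[best > tolerance | nbest > 1L] <- NA_integer_
  hit
}

# vectorised core shared by parse_read() and demultiplex_fastq():
# returns a data.frame with one row per input read
parse_reads <- function(seqs, quals, layout, table) {
  n <- length(seqs)
  header_len <- layout$umi_length + layout$barcode_length
  min_total <- header_len + layout$min_remaining_length
  out <- data.frame(umi = NA_character_, sample = "UNASSIGNED",
                    polyT_run = NA_integer_, t_class = NA_character_,
                    insert = NA_character_, insert_quality = NA_character_,
                    status = "discarded", stringsAsFactors = FALSE)[rep(1L, n), ]
  rownames(out) <- NULL
  if (n == 0L) return(out[0L, ])
  long <- nchar(seqs) >= min_total
  if (!any(long)) return(out)
  s <- seqs[long]
  q <- quals[long]
  umi <- substr(s, 1L, layout$umi_length)
  bc <- substr(s, layout$umi_length + 1L, header_len)
  rest <- substring(s, header_len + 1L)
  rest_q <- substring(q, header_len + 1L)
  run <- attr(regexpr("^T*", rest), "match.length")
  insert <- substring(rest, run + 1L)
  insert_q <- substring(rest_q, run + 1L)
  keep <- nchar(insert) >= layout$min_remaining_length
  hit <- match_barcodes(bc, table, layout$barcode_mismatch_tolerance)
  sample <- ifelse(is.na(hit), "UNASSIGNED", table$index_name[hit])
  status <- ifelse(!keep, "discarded",
                   ifelse(is.na(hit), "unassigned", "assigned"))
  out$umi[long] <- umi
  out$sample[long] <- sample
  out$polyT_run[long] <- run
  out$t_class[long] <- ifelse(run >= 1L, "T", "noT")
  out$insert[long] <- insert
  out$insert_quality[long] <- insert_q
  out$status[long] <- status
  out$t_class[out$status == "discarded"] <- NA_character_
  out
}

#' Parse one raw multiplexed TrAEL-seq read
#'
#' Splits a raw read into UMI, sample barcode, poly-T run and genomic insert
#' according to the layout, and classifies it as DNA-derived (`T`, at least
#' one T trimmed) or putatively RNA-derived (`noT`).
#'
#' @param raw_sequence,raw_quality read sequence and per-base quality strings.
#' @param layout a [read_layout()].
#' @param table a [barcode_table()].
#' @return list with elements `umi`, `sample` (index name or `"UNASSIGNED"`),
#'   `polyT_run`, `t_class`, `insert`, `insert_quality`, `status`
#'   (`"assigned"`, `"unassigned"` or `"discarded"`).
#' @export
#' @examples
#' tb <- trael_barcodes()
#' parse_read(paste0("ACGTACGT", "AGTC", "TTT", "GATTACAGATTACAGATTACA"),
#'            strrep("I", 36), read_layout(), tb)
parse_read <- function(raw_sequence, raw_quality, layout = read_layout(),
                       table = trael_barcodes()) {
  stopifnot(length(raw_sequence) == 1L, length(raw_quality) == 1L,
            nchar(raw_sequence) == nchar(raw_quality))
  as.list(parse_reads(raw_sequence, raw_quality, layout, table))
}

open_text <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Demultiplex a multiplexed TrAEL-seq FASTQ file
#'
#' Streams a (optionally gzipped) FASTQ file, parses each read with
#' [parse_read()] semantics, and writes per-sample outputs split into T
#' (DNA-derived) and noT classes, plus a file of unassigned reads. The UMI is
#' appended to the read name after an underscore so downstream stages can
#' recover it from alignments. Every input read is accounted for exactly once:
#' assigned + unassigned + discarded = total.
#'
#' @param fastq path to the input FASTQ (`.gz` supported).
#' @param layout a [read_layout()].
#' @param table a [barcode_table()].
#' @param out_dir output directory (created if needed).
#' @param prefix filename prefix for outputs.
#' @param gz logical; gzip the outputs.
#' @param chunk_size reads per streaming chunk.
#' @return invisibly, a list with `summary` (per-sample data.frame with
#'   columns sample, assigned, T, noT), `total`, `unassigned`, `discarded`,
#'   `polyT_histogram` (named counts of poly-T run lengths among emitted
#'   reads) and `files` (named character vector of paths written).
#' @export
demultiplex_fastq <- function(fastq, layout = read_layout(),
                              table = trael_barcodes(),
                              out_dir = ".", prefix = "demux",
                              gz = FALSE, chunk_size = 100000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gz) ".fastq.gz" else ".fastq"
  samples <- table$index_name
  files <- c(
    setNames(file.path(out_dir, paste0(prefix, "_", samples, "_T", ext)),
             paste0(samples, "_T")),
    setNames(file.path(out_dir, paste0(prefix, "_", samples, "_noT", ext)),
             paste0(samples, "_noT")),
    unassigned = file.path(out_dir, paste0(prefix, "_unassigned", ext))
  )
  cons <- lapply(files, open_text, mode = "w")
  on.exit(lapply(cons, close), add = TRUE)

  counts <- matrix(0, nrow = length(samples), ncol = 2L,
                   dimnames = list(samples, c("T", "noT")))
  n_total <- 0L
  n_unassigned <- 0L
  n_discarded <- 0L
  polyt <- integer(0)

  con <- open_text(fastq, "rt")
  on.exit(close(con), add = TRUE)
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L) {
      stop("malformed FASTQ: truncated record at read ",
           n_total + length(lines) %/% 4L + 1L, call. = FALSE)
    }
    idx <- seq(1L, length(lines), by = 4L)
    hdr <- lines[idx]
    seqs <- lines[idx + 1L]
    plus <- lines[idx + 2L]
    quals <- lines[idx + 3L]
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                   nchar(seqs) != nchar(quals))
    if (length(bad)) {
      stop("malformed FASTQ record at read ", n_total + bad[1L], call. = FALSE)
    }
    p <- parse_reads(seqs, quals, layout, table)
    n_total <- n_total + nrow(p)
    n_discarded <- n_discarded + sum(p$status == "discarded")

    emit <- p$status != "discarded"
    if (any(emit)) {
      h <- add_umi_to_header(hdr[emit], p$umi[emit])
      rec <- paste(h, p$insert[emit], "+", p$insert_quality[emit], sep = "\n")
      pe <- p[emit, , drop = FALSE]
      tab <- table(factor(pe$polyT_run))
      polyt <- merge_counts(polyt, tab)
      grp <- ifelse(pe$status == "unassigned", "unassigned",
                    paste0(pe$sample, "_", pe$t_class))
      for (g in unique(grp)) {
        writeLines(rec[grp == g], cons[[g]])
      }
      n_unassigned <- n_unassigned + sum(pe$status == "unassigned")
      ass <- pe$status == "assigned"
      if (any(ass)) {
        tc <- table(factor(pe$sample[ass], levels = samples),
                    factor(pe$t_class[ass], levels = c("T", "noT")))
        counts <- counts + unclass(tc)
      }
    }
  }
  summary_df <- data.frame(sample = samples,
                           assigned = rowSums(counts),
                           T = counts[, "T"], noT = counts[, "noT"],
                           row.names = NULL, stringsAsFactors = FALSE)
  res <- list(summary = summary_df, total = n_total,
              unassigned = n_unassigned, discarded = n_discarded,
              polyT_histogram = polyt, files = files)
  class(res) <- "trael_demux"
  invisible(res)
}

add_umi_to_header <- function(headers, umi) {
  name <- sub("\\s.*$", "", headers)
  rest <- sub("^\\S+", "", headers)
  paste0(name, "_", umi, rest)
}

merge_counts <- function(a, b) {
  b <- setNames(as.integer(b), names(b))
  keys <- union(names(a), names(b))
  out <- setNames(integer(length(keys)), keys)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out[order(as.integer(names(out)))]
}

#' @export
print.trael_demux <- function(x, ...) {
  cat("TrAEL-seq demultiplexing summary\n")
  cat(sprintf("  total reads: %d (assigned %d, unassigned %d, discarded %d)\n",
              x$total, sum(x$summary$assigned), x$unassigned, x$discarded))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Extract the UMI from read names produced by the demultiplexer
#'
#' The demultiplexer appends `_<UMI>` to the read name; the UMI is the final
#' underscore-separated token.
#'
#' @param names character vector of read names.
#' @return character vector of UMIs.
#' @export
umi_from_name <- function(names) sub(".*_", "", names)
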