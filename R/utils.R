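#' @importFrom methods as is
#' @importFrom stats complete.cases dnorm mad median qt quantile rbinom rgeom
#'   rnorm rpois runif sd setNames t.test
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over a character vector, delegating to
#' [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("GACT", "TTTA"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character scalars of equal length.
#' @return integer number of mismatching positions.
#' @export
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Number of distinct DNA words of a given length
#'
#' The size of the UMI keyspace: 4^k distinct k-mers over {A,C,G,T}. For the
#' 8-nt UMI this is 65,536, smaller than typical library complexity, which is
#' why multi-mapping reads get the read-sequence prefix added to the
#' deduplication key.
#'
#' @param k word length in nucleotides.
#' @return numeric count of distinct words.
#' @export
#' @examples
#' umi_keyspace(8)
umi_keyspace <- function(k = 8L) {
  stopifnot(k >= 1)
  4^k
}

# random fixed-length DNA words
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# stop() unless all columns are present
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read a chromosome sizes table
#'
#' Two-column TSV (chrom, length), as produced by `samtools faidx` cut to the
#' first two columns.
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_genome_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
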