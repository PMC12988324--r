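#' Three-state HMM over RFD increments
#'
#' Initiation zones appear as ascending runs of the RFD track and termination
#' zones as descending runs, so per-window RFD increments are modelled with a
#' three-state Gaussian hidden Markov model: UP (mean +mu), DOWN (mean -mu)
#' and FLAT (mean 0), with a shared standard deviation and a symmetric sticky
#' transition matrix (self-transition probability `p_stay`). This is a
#' self-contained, equivalent-function segmenter in the spirit of published
#' RFD HMM callers; externally produced initiation-zone BED files can be used
#' instead wherever zone centres are consumed.
#'
#' @param mu emission mean magnitude of the UP/DOWN states (> 0).
#' @param sigma shared emission standard deviation (> 0).
#' @param p_stay self-transition probability in (0, 1).
#' @return object of class `segmentation_model`.
#' @export
segmentation_model <- function(mu, sigma, p_stay = 0.99) {
  stopifnot(mu > 0, sigma > 0, p_stay > 0, p_stay < 1)
  states <- c("FLAT", "UP", "DOWN")
  trans <- matrix((1 - p_stay) / 2, 3, 3, dimnames = list(states, states))
  diag(trans) <- p_stay
  structure(list(states = states,
                 means = c(FLAT = 0, UP = mu, DOWN = -mu),
                 sigma = sigma, p_stay = p_stay, trans = trans),
            class = "segmentation_model")
}

#' Per-window RFD increments
#'
#' First difference of an RFD series over non-overlapping (or
#' step-subsampled) windows; a missing neighbour propagates missing.
#'
#' @param rfd numeric RFD vector (may contain `NA`).
#' @return numeric vector of length `length(rfd) - 1`.
#' @export
#' @examples
#' delta_rfd(c(-1, 0, 1))
delta_rfd <- function(rfd) {
  if (length(rfd) < 2L) return(numeric(0))
  diff(rfd)
}

# per-state emission log-likelihoods; NA observations emit a neutral,
# slightly FLAT-favouring value (mean 0, sigma inflated 10x) so the chain
# stays connected across gaps
emission_loglik <- function(x, model) {
  n <- length(x)
  ll <- matrix(NA_real_, n, 3L, dimnames = list(NULL, model$states))
  ok <- !is.na(x)
  for (s in model$states) {
    ll[ok, s] <- dnorm(x[ok], model$means[[s]], model$sigma, log = TRUE)
    ll[!ok, s] <- dnorm(0, 0, model$sigma * 10, log = TRUE)
  }
  ll
}

#' Viterbi decoding of the segmentation HMM
#'
#' Maximum-probability state path in log space, with uniform initial state
#' probabilities. Ties are broken deterministically toward FLAT (state order
#' FLAT, UP, DOWN; the first maximum wins).
#'
#' @param increments numeric vector of RFD increments (`NA` allowed).
#' @param model a [segmentation_model()].
#' @return character vector of states, same length as `increments`.
#' @export
viterbi_segment <- function(increments, model) {
  n <- length(increments)
  if (n == 0L) return(character(0))
  ll <- emission_loglik(increments, model)
  ltrans <- log(model$trans)
  v <- matrix(-Inf, n, 3L)
  back <- matrix(1L, n, 3L)
  v[1L, ] <- log(1 / 3) + ll[1L, ]
  if (n > 1L) {
    for (i in 2:n) {
      for (j in 1:3) {
        cand <- v[i - 1L, ] + ltrans[, j]
        back[i, j] <- which.max(cand)
        v[i, j] <- cand[back[i, j]] + ll[i, j]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  if (n > 1L) {
    for (i in (n - 1L):1L) path[i] <- back[i + 1L, path[i + 1L]]
  }
  model$states[path]
}

#' Fit the segmentation model to RFD increments
#'
#' Initial `mu` and `sigma` come from the tails of the increment
#' distribution by method of moments (`mu`: half the spread between the mean
#' upper and lower deciles; `sigma`: standard deviation of the central 80%),
#' then up to `max_iter` Baum-Welch iterations refine them with `p_stay` held
#' fixed and the UP/DOWN means tied to +/-mu.
#'
#' @param increments numeric vector of RFD increments.
#' @param p_stay fixed self-transition probability.
#' @param max_iter maximum Baum-Welch iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return a [segmentation_model()].
#' @export
fit_segmentation_model <- function(increments, p_stay = 0.99, max_iter = 20L,
                                   tol = 1e-6) {
  x <- increments[!is.na(increments)]
  if (length(x) < 10L) stop("too few increments to fit a model", call. = FALSE)
  qs <- quantile(x, c(0.1, 0.9), names = FALSE)
  mu <- (mean(x[x >= qs[2]]) - mean(x[x <= qs[1]])) / 2
  mid <- x[x > qs[1] & x < qs[2]]
  sigma <- if (length(mid) > 2L) sd(mid) else sd(x)
  if (!is.finite(mu) || mu <= 0) mu <- max(abs(x)) / 2
  if (!is.finite(sigma) || sigma <= 0) sigma <- max(mu / 4, 1e-3)
  model <- segmentation_model(mu, sigma, p_stay)

  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    fb <- forward_backward(x, model)
    if (is.finite(prev_ll) &&
        abs(fb$loglik - prev_ll) < tol * (abs(prev_ll) + 1)) break
    prev_ll <- fb$loglik
    g <- fb$gamma                      # n x 3 posterior, cols FLAT/UP/DOWN
    w_up <- g[, "UP"]; w_dn <- g[, "DOWN"]
    denom <- sum(w_up) + sum(w_dn)
    if (denom > 0) {
      mu_new <- (sum(w_up * x) - sum(w_dn * x)) / denom
      if (is.finite(mu_new) && mu_new > 1e-8) model$means <- c(
        FLAT = 0, UP = mu_new, DOWN = -mu_new)
    }
    m <- model$means[colnames(g)]
    resid2 <- (matrix(x, length(x), 3L) -
                 matrix(m, length(x), 3L, byrow = TRUE))^2
    sigma_new <- sqrt(sum(g * resid2) / length(x))
    if (is.finite(sigma_new) && sigma_new > 1e-8) model$sigma <- sigma_new
  }
  segmentation_model(model$means[["UP"]], model$sigma, p_stay)
}

# scaled forward-backward; returns gamma (posterior state probabilities)
# and the data log-likelihood
forward_backward <- function(x, model) {
  n <- length(x)
  e <- exp(emission_loglik(x, model))
  a <- matrix(0, n, 3L)
  cscale <- numeric(n)
  a[1L, ] <- e[1L, ] / 3
  cscale[1L] <- sum(a[1L, ])
  a[1L, ] <- a[1L, ] / cscale[1L]
  for (i in seq_len(n)[-1L]) {
    a[i, ] <- (a[i - 1L, ] %*% model$trans) * e[i, ]
    cscale[i] <- sum(a[i, ])
    a[i, ] <- a[i, ] / cscale[i]
  }
  b <- matrix(0, n, 3L)
  b[n, ] <- 1
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      b[i, ] <- (model$trans %*% (e[i + 1L, ] * b[i + 1L, ])) / cscale[i + 1L]
    }
  }
  g <- a * b
  g <- g / rowSums(g)
  colnames(g) <- model$states
  list(gamma = g, loglik = sum(log(cscale)))
}

#' Call initiation and termination zones from a state path
#'
#' Maximal UP runs of at least `min_zone_bins` bins become initiation zones
#' (IZ), maximal DOWN runs termination zones (TZ). Bin `i` (0-based) spans
#' `[origin + i*bin_width, origin + (i+1)*bin_width)`; the zone centre is the
#' midpoint rounded down.
#'
#' @param states character state path from [viterbi_segment()].
#' @param bin_width genomic width of one bin (bp).
#' @param chrom chromosome name for the calls.
#' @param origin genomic coordinate of the first bin's start.
#' @param min_zone_bins minimum run length for a call.
#' @param deltas optional increment values used to report the mean increment
#'   per zone.
#' @return data.frame with `chrom`, `start`, `end`, `type` (IZ/TZ), `centre`,
#'   `mean_delta`, `n_bins`, sorted by start.
#' @export
call_zones <- function(states, bin_width, chrom = "chr", origin = 0,
                       min_zone_bins = 3L, deltas = NULL) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), type = character(0),
                      centre = numeric(0), mean_delta = numeric(0),
                      n_bins = integer(0), stringsAsFactors = FALSE)
  if (length(states) == 0L) return(empty)
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("UP", "DOWN") & r$lengths >= min_zone_bins
  if (!any(keep)) return(empty)
  i1 <- starts[keep]; i2 <- ends[keep]
  gstart <- origin + (i1 - 1L) * bin_width
  gend <- origin + i2 * bin_width
  md <- if (is.null(deltas)) {
    rep(NA_real_, sum(keep))
  } else {
    mapply(function(a, b) mean(deltas[a:b], na.rm = TRUE), i1, i2)
  }
  out <- data.frame(chrom = chrom, start = gstart, end = gend,
                    type = ifelse(r$values[keep] == "UP", "IZ", "TZ"),
                    centre = floor((gstart + gend) / 2),
                    mean_delta = md,
                    n_bins = r$lengths[keep],
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Segment an RFD track into initiation and termination zones
#'
#' Convenience wrapper: takes a non-overlapping windowed RFD track (one row
#' per window), computes increments per chromosome, fits one model across
#' the genome (unless one is supplied), decodes each chromosome with
#' [viterbi_segment()] and calls zones with [call_zones()].
#'
#' @param track data.frame with `chrom`, `start`, `end`, `rfd`
#'   (non-overlapping windows; overlapping windows are an error).
#' @param model optional [segmentation_model()]; fitted when `NULL`.
#' @param min_zone_bins minimum zone length in bins.
#' @param p_stay self-transition probability when fitting.
#' @return data.frame of zone calls (see [call_zones()]).
#' @export
segment_rfd <- function(track, model = NULL, min_zone_bins = 3L,
                        p_stay = 0.99) {
  check_columns(track, c("chrom", "start", "end", "rfd"))
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  by_chrom <- split(track, track$chrom)
  for (t in by_chrom) {
    if (nrow(t) > 1L && any(t$start[-1L] < t$end[-nrow(t)])) {
      stop("segment_rfd needs non-overlapping windows (step = window)",
           call. = FALSE)
    }
  }
  incs <- lapply(by_chrom, function(t) delta_rfd(t$rfd))
  if (is.null(model)) {
    model <- fit_segmentation_model(unlist(incs), p_stay = p_stay)
  }
  calls <- lapply(names(by_chrom), function(ch) {
    d <- incs[[ch]]
    if (length(d) == 0L) return(NULL)
    t <- by_chrom[[ch]]
    path <- viterbi_segment(d, model)
    call_zones(path, bin_width = t$start[2L] - t$start[1L], chrom = ch,
               origin = t$start[1L], min_zone_bins = min_zone_bins,
               deltas = d)
  })
  out <- do.call(rbind, calls)
  if (is.null(out)) {
    return(call_zones(character(0), 1))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write zone calls as BED6
#'
#' Score is `1000 * |mean increment|`, clipped to \[0, 1000\].
#'
#' @param zones zone calls from [segment_rfd()] or [call_zones()].
#' @param path output BED file.
#' @return invisibly, the path.
#' @export
write_zones_bed <- function(zones, path) {
  score <- pmin(1000, round(1000 * abs(ifelse(is.na(zones$mean_delta), 0,
                                              zones$mean_delta))))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", zones$chrom,
                     as.integer(zones$start), as.integer(zones$end),
                     zones$type, as.integer(score)), path)
  invisible(path)
}

#' Read a BED file of features
#'
#' Minimal BED3+ reader used for initiation-zone, gene and exclusion
#' intervals; the optional 4th and 6th columns become `name` and `strand`.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `centre` and, when
#'   present, `name`, `score` and `strand`.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$name <- df[[4]]
  if (ncol(df) >= 5L) out$score <- df[[5]]
  if (ncol(df) >= 6L) out$strand <- df[[6]]
  out$centre <- floor((out$start + out$end) / 2)
  out
}
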