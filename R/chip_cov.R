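# ChIP-seq enrichment: total-count normalization of IP against input,
# 50-kb sliding-window smoothing for plots, and the 10x-background /
# 30-bp peak rule with sequence extraction around peak centers.

#' Construct a per-bp coverage track
#'
#' @param values Nonnegative per-bp signal over the chromosome.
#' @param label One of `"IP"`, `"input"`, `"normalized"`, `"enrichment"`.
#' @param circular Circular chromosome flag (default TRUE).
#' @return Object of class `CoverageTrack`.
#' @export
coverage_track <- function(values, label = "IP", circular = TRUE) {
  if (any(values < 0, na.rm = TRUE)) stop("coverage must be nonnegative")
  structure(list(values = as.numeric(values),
                 total = sum(values, na.rm = TRUE),
                 label = label, circular = circular),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack (%s): %d bp, total %.4g\n",
              x$label, length(x$values), x$total))
  invisible(x)
}

#' Input-normalized ChIP enrichment
#'
#' Each track is first scaled by its total read count; the enrichment at
#' position x is the ratio of the normalized IP to the normalized input.
#' Positions where the input is zero are undefined (NA).
#'
#' @param ip,input [coverage_track()]s over the same chromosome.
#' @return An enrichment `CoverageTrack` (NA = undefined).
#' @export
normalize_tracks <- function(ip, input) {
  stopifnot(inherits(ip, "CoverageTrack"), inherits(input, "CoverageTrack"))
  if (length(ip$values) != length(input$values))
    stop("chromosome length mismatch")
  if (ip$total <= 0 || input$total <= 0) stop("zero-total track")
  enr <- (ip$values / ip$total) / (input$values / input$total)
  enr[input$values == 0] <- NA_real_
  coverage_track(enr, label = "enrichment", circular = ip$circular)
}

# NA-aware centered running mean over w positions, circular or truncated
running_mean <- function(x, w, circular = TRUE) {
  n <- length(x)
  def <- !is.na(x)
  v <- x; v[!def] <- 0
  lh <- (w - 1L) %/% 2L; rh <- w - 1L - lh
  if (circular) {
    v2 <- c(v[(n - lh + 1L):n], v, v[1:rh])
    d2 <- c(def[(n - lh + 1L):n], def, def[1:rh])
  } else {
    v2 <- c(rep(0, lh), v, rep(0, rh))
    d2 <- c(rep(FALSE, lh), def, rep(FALSE, rh))
  }
  cs <- c(0, cumsum(v2)); cd <- c(0, cumsum(d2))
  i <- seq_len(n)
  s <- cs[i + w] - cs[i]
  k <- cd[i + w] - cd[i]
  out <- s / k
  out[k == 0] <- NA_real_
  out[!def] <- NA_real_
  out
}

#' Smooth a coverage track with a sliding window
#'
#' Centered moving average (circular on circular chromosomes); undefined
#' positions are excluded from the window with renormalization and stay
#' undefined in the output.
#'
#' @param track A [coverage_track()].
#' @param window Window size in bp (default 50000).
#' @return Smoothed `CoverageTrack`.
#' @export
smooth_track <- function(track, window = 5e4) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (window <= 0) stop("window must be positive")
  if (window > length(track$values)) stop("window exceeds chromosome")
  sm <- running_mean(track$values, as.integer(window), track$circular)
  out <- coverage_track(pmax(sm, 0), label = track$label,
                        circular = track$circular)
  out$values <- sm
  out
}

#' Average a per-bp track into fixed-size bins
#'
#' @param track A [coverage_track()].
#' @param bin_size Bin size in bp.
#' @return data.frame with 0-based half-open `start`, `end` and `value`
#'   (mean of defined per-bp values in the bin).
#' @export
bin_track <- function(track, bin_size) {
  n <- length(track$values)
  bin <- (seq_len(n) - 1L) %/% bin_size
  value <- tapply(track$values, bin, mean, na.rm = TRUE)
  start <- as.integer(names(value)) * bin_size
  data.frame(start = start, end = pmin(start + bin_size, n),
             value = as.numeric(value))
}

#' Call enrichment peaks (fold-over-background run rule)
#'
#' Peaks are maximal runs of positions whose enrichment is at least
#' `fold` times the background for at least `min_run` consecutive bp,
#' merged across the origin on circular chromosomes. The peak center is
#' the midpoint of the run.
#'
#' @param track An enrichment [coverage_track()].
#' @param background Background level; default the median of the defined
#'   track values.
#' @param fold Fold threshold (default 10).
#' @param min_run Minimum run length in bp (default 30).
#' @return data.frame with 0-based half-open `start`, `end`, `center`,
#'   `length`, `max_fold` (max value / background in the run). For a peak
#'   wrapping the origin `end > chrom_length`.
#' @export
call_peaks <- function(track, background = NULL, fold = 10,
                       min_run = 30L) {
  stopifnot(inherits(track, "CoverageTrack"))
  x <- track$values
  n <- length(x)
  if (sum(!is.na(x)) < min_run) stop("track defined on too few positions")
  if (is.null(background)) background <- stats::median(x, na.rm = TRUE)
  if (is.na(background) || background <= 0)
    stop("background must be positive")
  hot <- !is.na(x) & x >= fold * background
  if (!any(hot)) return(empty_peaks())
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge the run touching position n with the run starting at 1
  wrapped <- FALSE
  if (track$circular && nrow(runs) > 1L &&
      runs$start[1] == 1L && runs$end[nrow(runs)] == n) {
    runs$end[nrow(runs)] <- n + runs$end[1]
    runs <- runs[-1L, , drop = FALSE]
    wrapped <- TRUE
  } else if (track$circular && nrow(runs) == 1L &&
             runs$start[1] == 1L && runs$end[1] == n) {
    # uniformly hot track: one chromosome-wide peak
  }
  runs <- runs[runs$end - runs$start + 1L >= min_run, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty_peaks())
  len <- runs$end - runs$start + 1L
  center <- (runs$start - 1L) + len %/% 2L
  max_fold <- vapply(seq_len(nrow(runs)), function(k) {
    idx <- wrap_index(runs$start[k]:runs$end[k], n)
    max(x[idx], na.rm = TRUE) / background
  }, numeric(1))
  data.frame(start = runs$start - 1L, end = runs$end,
             center = center %% n, length = len, max_fold = max_fold)
}

empty_peaks <- function() {
  data.frame(start = integer(0), end = integer(0), center = integer(0),
             length = integer(0), max_fold = numeric(0))
}

#' Extract sequences around peak centers
#'
#' Returns `center - flank .. center + flank` (length `2*flank + 1`) for
#' each peak, wrapping across the origin of a circular genome; intended
#' for export to external motif-discovery tools.
#'
#' @param peaks A [call_peaks()] data.frame.
#' @param genome Genome sequence (character or [Biostrings::DNAString]).
#' @param flank Flank size in bp (default 50).
#' @param circular Circular genome flag (default TRUE).
#' @return A [Biostrings::DNAStringSet], one record per peak, named
#'   `peak_<i>_<center>`.
#' @export
peak_sequences <- function(peaks, genome, flank = 50L, circular = TRUE) {
  if (flank < 0) stop("flank must be nonnegative")
  g <- as.character(genome)
  L <- nchar(g)
  seqs <- vapply(seq_len(nrow(peaks)), function(k) {
    pos <- (peaks$center[k] - flank):(peaks$center[k] + flank)
    if (circular) pos <- pos %% L
    else {
      if (any(pos < 0 | pos >= L)) stop("peak flank outside linear genome")
    }
    paste(substring(g, pos + 1L, pos + 1L), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("peak_%d_%d", seq_len(nrow(peaks)), peaks$center)
  out
}
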