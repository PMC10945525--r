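# Directional index and CID boundary calling. For each bin the contact
# vectors to the left and right (from the correlation matrix, at one-bin
# lags out to max_range) are compared with a distance-matched paired
# t-test; sign changes of the t statistic flanked by significant bins
# mark domain boundaries.

#' Row-row correlation matrix of a balanced contact map
#'
#' Entry (i,j) is the Pearson correlation of rows i and j of the
#' normalized matrix, computed over unmasked columns. Bins whose row has
#' zero variance are masked in the output.
#'
#' @param cm A normalized [contact_map()].
#' @return Object of class `CorrelationMap`: list with `matrix` (NA at
#'   masked bins), `masked_bins`, `circular`, `bin_size`.
#' @export
correlation_map <- function(cm) {
  stopifnot(inherits(cm, "ContactMap"))
  N <- nrow(cm$matrix)
  keep <- setdiff(seq_len(N), cm$masked_bins)
  sub <- cm$matrix[keep, keep, drop = FALSE]
  degenerate <- keep[apply(sub, 1, stats::sd) == 0]
  keep2 <- setdiff(keep, degenerate)
  C <- matrix(NA_real_, N, N)
  sub2 <- cm$matrix[keep2, keep, drop = FALSE]
  C[keep2, keep2] <- stats::cor(t(sub2))
  structure(list(matrix = C,
                 masked_bins = sort(union(cm$masked_bins, degenerate)),
                 circular = cm$circular, bin_size = cm$bin_size),
            class = "CorrelationMap")
}

#' Directional index track
#'
#' For each bin i, the left vector L = (corr(i, i-1), ..., corr(i, i-K))
#' and right vector R = (corr(i, i+1), ..., corr(i, i+K)), K =
#' `max_range / bin_size` lags, are compared with a two-sided paired
#' t-test on the distance-matched differences R - L. Positive t means
#' rightward (downstream) contacts dominate. Lags with a missing value on
#' either side are dropped pairwise. For display, t is truncated to
#' [-2, 2] (|t| = 2 corresponding to p ~ 0.05 at the default 19 df).
#'
#' @param corr A [correlation_map()] (or, with `use_correlation = FALSE`
#'   inside [directional_index_from_map()], a raw normalized map).
#' @param max_range Maximum lag distance in bp (default 100000).
#' @return Object of class `DITrack`: list with per-bin `t_raw`,
#'   `t_disp`, `p`, `df`, plus `bin_size`, `max_range`, `circular`.
#' @export
directional_index <- function(corr, max_range = 1e5) {
  stopifnot(inherits(corr, c("CorrelationMap", "ContactMap")))
  C <- corr$matrix
  if (inherits(corr, "ContactMap")) {
    C[corr$masked_bins, ] <- NA; C[, corr$masked_bins] <- NA
  }
  N <- nrow(C)
  K <- as.integer(max_range %/% corr$bin_size)
  if (K < 2) stop("fewer than 2 lags")
  idx <- seq_len(N)
  D <- matrix(NA_real_, K, N)        # distance-matched differences R - L
  for (d in seq_len(K)) {
    if (corr$circular) {
      right <- C[cbind(idx, wrap_index(idx + d, N))]
      left  <- C[cbind(idx, wrap_index(idx - d, N))]
    } else {
      right <- left <- rep(NA_real_, N)
      okr <- idx + d <= N; okl <- idx - d >= 1L
      right[okr] <- C[cbind(idx[okr], idx[okr] + d)]
      left[okl]  <- C[cbind(idx[okl], idx[okl] - d)]
    }
    D[d, ] <- right - left
  }
  if (!corr$circular)                 # edge bins get no DI value
    D[, idx <= K | idx > N - K] <- NA_real_
  n_ok <- colSums(!is.na(D))
  mean_d <- colMeans(D, na.rm = TRUE)
  sd_d <- apply(D, 2, stats::sd, na.rm = TRUE)
  t_raw <- rep(NA_real_, N); p <- rep(NA_real_, N)
  ok <- n_ok >= 2 & !is.na(sd_d) & sd_d > 0
  t_raw[ok] <- mean_d[ok] / (sd_d[ok] / sqrt(n_ok[ok]))
  # identical vectors on both sides: t = 0 by convention
  t_raw[n_ok >= 2 & !is.na(sd_d) & sd_d == 0 & mean_d == 0] <- 0
  df <- pmax(n_ok - 1L, 1L)
  p[!is.na(t_raw)] <- 2 * stats::pt(-abs(t_raw[!is.na(t_raw)]),
                                    df[!is.na(t_raw)])
  structure(list(t_raw = t_raw, t_disp = pmin(pmax(t_raw, -2), 2),
                 p = p, df = df, bin_size = corr$bin_size,
                 max_range = max_range, circular = corr$circular),
            class = "DITrack")
}

#' Call CID boundaries from a directional-index track
#'
#' A boundary is placed at every sign change of the raw t statistic where
#' at least `min_significant_flank` bins immediately on each side are
#' significant (|t| >= the two-sided critical value at `alpha`) with a
#' constant sign on each flank. Boundary `position` is the index of the
#' bin left of the transition (the boundary lies between `position` and
#' `position + 1`, wrapping on circular maps).
#'
#' @param di A [directional_index()] track.
#' @param min_significant_flank Bins required significant on each side
#'   (default 3).
#' @param alpha Two-sided significance level (default 0.05).
#' @return data.frame with `position`, `left_sign`, `right_sign`,
#'   `significant` (all returned calls are significant).
#' @export
call_cids <- function(di, min_significant_flank = 3L, alpha = 0.05) {
  stopifnot(inherits(di, "DITrack"))
  t <- di$t_raw
  N <- length(t)
  tcrit <- stats::qt(1 - alpha / 2, di$df)
  sig <- !is.na(t) & abs(t) >= tcrit
  s <- sign(t); s[is.na(s)] <- 0
  f <- min_significant_flank
  calls <- list()
  last <- if (di$circular) N else N - 1L
  for (i in seq_len(last)) {
    j <- if (di$circular) wrap_index(i + 1L, N) else i + 1L
    if (s[i] == 0 || s[j] == 0 || s[i] == s[j]) next
    li <- wrap_index(i - (f - 1L):0, N)
    ri <- wrap_index(j + 0:(f - 1L), N)
    if (!di$circular && (i - f + 1L < 1L || j + f - 1L > N)) next
    if (all(sig[li]) && all(s[li] == s[i]) &&
        all(sig[ri]) && all(s[ri] == s[j])) {
      calls[[length(calls) + 1L]] <-
        data.frame(position = i,
                   left_sign = ifelse(s[i] > 0, "+", "-"),
                   right_sign = ifelse(s[j] > 0, "+", "-"),
                   significant = TRUE)
    }
  }
  if (length(calls) == 0L)
    return(data.frame(position = integer(0), left_sign = character(0),
                      right_sign = character(0), significant = logical(0)))
  do.call(rbind, calls)
}
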