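# matS motif scanning on circular genomes, Ter-domain delimitation by the
# 100-kb-gap rule, Ter summary statistics, and dif-centered matS density
# profiles with cross-species percentile envelopes.

#' The packaged matS consensus
#'
#' The previously published 13-bp palindromic matS consensus in IUPAC
#' notation. Any other IUPAC word or a position-weight matrix may be
#' supplied to the scanner instead.
#' @export
MATS_CONSENSUS <- "GTGACRNYGTCAC"

#' Scan a genome for motif occurrences on both strands
#'
#' IUPAC mode matches a degenerate consensus word exactly (ambiguity
#' codes in the motif expand, `N` in the genome does not match); PWM mode
#' scores with a position-weight matrix at `min_score`. Matches wrap
#' across the origin of a circular genome. A site matching identically on
#' both strands (perfect palindrome) is reported once, on the plus
#' strand.
#'
#' @param genome Character or [Biostrings::DNAString] over ACGTN.
#' @param circular Circular genome flag (default TRUE).
#' @param motif IUPAC consensus string (default [MATS_CONSENSUS]).
#' @param pwm Optional position-weight matrix (rows ACGT) for
#'   [Biostrings::matchPWM]; overrides `motif`.
#' @param min_score PWM score threshold (default `"90%"`).
#' @return data.frame with 0-based `position` (match start on the plus
#'   strand), `strand`, `sequence` (plus-strand word), sorted by position.
#' @export
scan_motif <- function(genome, circular = TRUE, motif = MATS_CONSENSUS,
                       pwm = NULL, min_score = "90%") {
  g <- toupper(as.character(genome))
  L <- nchar(g)
  mlen <- if (is.null(pwm)) nchar(motif) else ncol(pwm)
  subject_chr <- if (circular && L > mlen) {
    paste0(g, substr(g, 1L, mlen - 1L))
  } else g
  subject <- Biostrings::DNAString(subject_chr)
  hit_starts <- function(pattern) {
    if (is.null(pwm)) {
      v <- Biostrings::matchPattern(pattern, subject,
                                    fixed = c(pattern = FALSE,
                                              subject = TRUE))
    } else {
      v <- Biostrings::matchPWM(pattern, subject, min.score = min_score)
    }
    Biostrings::start(v) - 1L            # 0-based
  }
  if (is.null(pwm)) {
    fwd_pat <- Biostrings::DNAString(motif)
    rev_pat <- Biostrings::reverseComplement(fwd_pat)
  } else {
    fwd_pat <- pwm
    rev_pat <- Biostrings::reverseComplement(pwm)
  }
  fwd <- hit_starts(fwd_pat)
  rev <- hit_starts(rev_pat)
  pos <- c(fwd, rev) %% L
  strand <- c(rep("+", length(fwd)), rep("-", length(rev)))
  df <- data.frame(position = pos, strand = strand,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  # palindromic double hit: same start on both strands, keep "+"
  df <- df[order(df$position, df$strand), , drop = FALSE]
  df <- df[!duplicated(df$position), , drop = FALSE]
  if (nrow(df)) {
    g2 <- if (circular) paste0(g, substr(g, 1L, mlen - 1L)) else g
    df$sequence <- substring(g2, df$position + 1L, df$position + mlen)
  } else df$sequence <- character(0)
  rownames(df) <- NULL
  df
}

#' Delimit the Ter domain from matS site positions
#'
#' Sites are clustered so that consecutive gaps within a cluster are
#' below `gap` (gaps measured around the circle, including the wrap);
#' Ter is the cluster with the longest first-to-last span, ties broken by
#' more sites, then by smaller start. With at least two clusters the
#' flanking gaps of the winner are >= `gap` by construction.
#'
#' @param sites Site positions in bp (0-based starts), or a
#'   [scan_motif()] data.frame.
#' @param chrom_length Chromosome length in bp.
#' @param circular Circular chromosome flag (default TRUE).
#' @param gap Gap threshold in bp (default 1e5).
#' @return Object of class `TerDomain`: list with `start`, `end` (first
#'   and last site positions; `end < start` means the domain wraps),
#'   `n_sites`, `size_kb` (span), `sites` (positions in domain order).
#' @export
delimit_ter <- function(sites, chrom_length, circular = TRUE, gap = 1e5) {
  pos <- if (is.data.frame(sites)) sites$position else sites
  pos <- sort(unique(as.numeric(pos)))
  if (length(pos) == 0L) stop("zero sites")
  n <- length(pos)
  if (n == 1L) {
    return(structure(list(start = pos, end = pos, n_sites = 1L,
                          size_kb = 0, sites = pos,
                          chrom_length = chrom_length),
                     class = "TerDomain"))
  }
  gaps <- diff(pos)
  wrap_gap <- if (circular) chrom_length - pos[n] + pos[1] else Inf
  gaps <- c(gaps, wrap_gap)             # gap i follows site i
  big <- which(gaps >= gap)
  if (length(big) == 0L) {
    # every gap small: on a circle all sites form one wrapped cluster;
    # open it at the largest gap
    big <- which.max(gaps)
  }
  # clusters: runs of sites between consecutive big gaps (circularly)
  clusters <- list()
  nb <- length(big)
  for (k in seq_len(nb)) {
    from <- wrap_index(big[k] + 1L, n)          # first site after gap
    to <- big[wrap_index(k + 1L, nb)]           # site before next gap
    idx <- if (from <= to) from:to else c(from:n, 1:to)
    clusters[[k]] <- pos[idx]
  }
  span <- vapply(clusters, function(cl) {
    s <- (cl[length(cl)] - cl[1]) %% chrom_length
    if (length(cl) == 1L) 0 else s
  }, numeric(1))
  nsite <- lengths(clusters)
  starts <- vapply(clusters, `[`, numeric(1), 1L)
  ord <- order(-span, -nsite, starts)
  best <- clusters[[ord[1]]]
  structure(list(start = best[1], end = best[length(best)],
                 n_sites = length(best),
                 size_kb = span[ord[1]] / 1000,
                 sites = best, chrom_length = chrom_length),
            class = "TerDomain")
}

#' @export
print.TerDomain <- function(x, ...) {
  cat(sprintf("TerDomain: [%g, %g] bp, %d sites, span %.1f kb\n",
              x$start, x$end, x$n_sites, x$size_kb))
  invisible(x)
}

#' Ter-domain summary statistics
#'
#' The Table-1-style row: Ter size, site count, site density per 100 kb
#' of Ter, Ter fraction of the chromosome, and whether the domain
#' contains the dif site.
#'
#' @param ter A [delimit_ter()] result, or a list with `start`, `end`,
#'   `n_sites`, `size_kb`.
#' @param chrom_length Chromosome length in bp.
#' @param dif Optional dif position in bp.
#' @return List with `size_kb`, `n_sites`, `density_per_100kb` (NA for a
#'   degenerate zero-span domain), `fraction_of_chromosome` (percent),
#'   `contains_dif`.
#' @export
ter_stats <- function(ter, chrom_length, dif = NULL) {
  density <- if (ter$size_kb > 0) ter$n_sites / ter$size_kb * 100
  else NA_real_
  contains <- if (is.null(dif)) NA else {
    in_circular_interval(dif, ter$start, (ter$end + 1) %% chrom_length,
                         chrom_length)
  }
  list(size_kb = ter$size_kb, n_sites = ter$n_sites,
       density_per_100kb = density,
       fraction_of_chromosome = ter$size_kb * 1000 / chrom_length * 100,
       contains_dif = contains)
}

#' dif-centered matS density profile
#'
#' Re-centers the circular coordinate on dif and counts sites per
#' contiguous window of `window` bp, indexed by signed offset from dif
#' (window 0 spans dif). Every site falls in exactly one window, so the
#' counts sum to the total number of sites.
#'
#' @param sites Site positions in bp, or a [scan_motif()] data.frame.
#' @param dif dif position in bp.
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp (default 1e5).
#' @return data.frame with `offset_kb` (window-center offset from dif)
#'   and `count`, covering the full circle.
#' @export
density_profile <- function(sites, dif, chrom_length, window = 1e5) {
  if (window <= 0) stop("window must be positive")
  if (dif < 0 || dif >= chrom_length) stop("dif outside chromosome")
  pos <- if (is.data.frame(sites)) sites$position else sites
  nwin <- ceiling(chrom_length / window)
  # window m (0-based) covers [dif + (m - 1/2) w, dif + (m + 1/2) w)
  m <- floor(((pos - dif + window / 2) %% chrom_length) / window)
  m <- pmin(m, nwin - 1L)
  to_signed <- function(m) ifelse(m <= nwin / 2, m, m - nwin)
  k_all <- sort(to_signed(0:(nwin - 1L)))
  counts <- table(factor(to_signed(m), levels = k_all))
  data.frame(offset_kb = k_all * window / 1000,
             count = as.integer(counts))
}

#' Cross-species percentile envelope of density profiles
#'
#' Per-offset median and quartiles (linear-interpolation convention)
#' across a list of dif-centered [density_profile()]s; offsets present in
#' only some species use the available values.
#'
#' @param profiles List of [density_profile()] data.frames.
#' @return data.frame with `offset_kb`, `q25`, `median`, `q75`, `n`.
#' @export
species_envelope <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  offs <- sort(unique(unlist(lapply(profiles, `[[`, "offset_kb"))))
  rows <- lapply(offs, function(o) {
    vals <- unlist(lapply(profiles, function(p) p$count[p$offset_kb == o]))
    if (length(vals) == 0L) return(NULL)
    q <- quantiles_lin(vals)
    data.frame(offset_kb = o, q25 = q[1], median = q[2], q75 = q[3],
               n = length(vals))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no overlapping offsets")
  out
}
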