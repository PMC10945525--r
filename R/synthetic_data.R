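# Synthetic inputs with the statistical structure the analyses assume:
# distance-decay contact maps with a locus-dependent contact-range
# parameter and insulated Ter, ChIP experiments with
# replication-following enrichment, genomes with planted matS/dif, and
# programmed segment transpositions with exact coordinate liftover.

IUPAC_EXPAND <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

# sample one concrete instance of an IUPAC consensus
instantiate_motif <- function(motif) {
  codes <- strsplit(toupper(motif), "")[[1]]
  if (!all(codes %in% names(IUPAC_EXPAND))) stop("invalid IUPAC code")
  paste(vapply(codes, function(cd) {
    ch <- IUPAC_EXPAND[[cd]]
    if (length(ch) == 1L) ch else sample(ch, 1L)
  }, character(1)), collapse = "")
}

#' Generate a random genome with planted motif sites
#'
#' Uniform-random ACGT background with concrete motif instances
#' (degenerate codes sampled) written at the planted positions; the
#' background is rejection-resampled until the only matches of the motif
#' on either strand are the planted ones.
#'
#' @param length Genome length in bp.
#' @param planted_sites 0-based start positions of planted sites
#'   (non-overlapping).
#' @param motif IUPAC consensus (default [MATS_CONSENSUS]).
#' @param dif Optional dif position in bp (recorded as a feature).
#' @param circular Circular genome flag (default TRUE).
#' @param seed Integer seed.
#' @param max_rounds Resampling rounds before giving up (default 50).
#' @return List with `sequence` (character), `features` (data.frame of
#'   `name`, `position`), `sites` (planted positions), `motif`.
#' @export
gen_genome <- function(length, planted_sites = integer(0),
                       motif = MATS_CONSENSUS, dif = NULL,
                       circular = TRUE, seed = 1L, max_rounds = 50L) {
  mlen <- nchar(motif)
  planted_sites <- sort(as.numeric(planted_sites))
  if (any(diff(planted_sites) < mlen))
    stop("planted sites overlap")
  if (length(planted_sites) && (max(planted_sites) + mlen > length) &&
      !circular)
    stop("planted site extends past the end of a linear genome")
  with_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    for (p in planted_sites) {
      inst <- strsplit(instantiate_motif(motif), "")[[1]]
      idx <- ((p + seq_len(mlen) - 1L) %% length) + 1L
      base[idx] <- inst
    }
    genome <- paste(base, collapse = "")
    for (round in seq_len(max_rounds)) {
      hits <- scan_motif(genome, circular = circular, motif = motif)
      spurious <- setdiff(hits$position, planted_sites)
      if (length(spurious) == 0L) break
      if (round == max_rounds)
        stop("could not avoid spurious matches; site density too high?")
      for (p in spurious) {       # re-randomize the offending window
        idx <- ((p + seq_len(mlen) - 1L) %% length) + 1L
        idx <- idx[!(((idx - 1L)) %in%
                       unlist(lapply(planted_sites, function(q)
                         (q + seq_len(mlen) - 1L) %% length)))]
        base[idx] <- sample(c("A", "C", "G", "T"), length(idx),
                            replace = TRUE)
      }
      genome <- paste(base, collapse = "")
    }
    feats <- data.frame(name = character(0), position = numeric(0))
    if (!is.null(dif))
      feats <- rbind(feats, data.frame(name = "dif", position = dif))
    if (length(planted_sites))
      feats <- rbind(feats, data.frame(name = "matS",
                                       position = planted_sites))
    list(sequence = genome, features = feats, sites = planted_sites,
         motif = motif)
  })
}

#' Transpose a genome segment with exact coordinate liftover
#'
#' Excises the segment `[a, b)`, closes the gap, and reinserts the
#' segment (reverse-complemented if `inverted`) at the original
#' coordinate `c` (which must lie outside the segment). Coordinates move
#' as in literal string cut-and-paste; the returned liftover is a
#' bijection on `0..length-1`.
#'
#' @param genome Genome sequence (character), or `NULL` to transform
#'   coordinates only.
#' @param segment `c(a, b)`: 0-based half-open interval to move.
#' @param insertion_point 0-based coordinate `c` in the original genome,
#'   outside `[a, b)`.
#' @param inverted Reinsert reverse-complemented (default FALSE).
#' @param length Genome length (required if `genome` is NULL).
#' @return List with `sequence` (or NULL), `liftover(pos)` and
#'   `liftover_inv(pos)` vectorized coordinate maps, `segment_new`
#'   (new half-open location of the segment).
#' @export
transpose_segment <- function(genome = NULL, segment, insertion_point,
                              inverted = FALSE, length = NULL) {
  a <- segment[1]; b <- segment[2]
  if (is.null(length)) length <- nchar(genome)
  L <- length
  if (!(a >= 0 && b <= L && a < b)) stop("invalid segment")
  cc <- insertion_point
  if (cc >= a && cc < b) stop("insertion point inside segment")
  seg_len <- b - a
  cprime <- if (cc < a) cc else cc - seg_len  # insertion in gap-closed coords
  lift <- function(pos) {
    out <- numeric(base::length(pos))
    inside <- pos >= a & pos < b
    out[inside] <- if (inverted) cprime + (b - 1 - pos[inside])
    else cprime + (pos[inside] - a)
    q <- ifelse(pos[!inside] < a, pos[!inside], pos[!inside] - seg_len)
    out[!inside] <- ifelse(q < cprime, q, q + seg_len)
    out
  }
  lift_inv <- function(pos) {
    out <- numeric(base::length(pos))
    inside <- pos >= cprime & pos < cprime + seg_len
    out[inside] <- if (inverted) b - 1 - (pos[inside] - cprime)
    else a + (pos[inside] - cprime)
    q <- ifelse(pos[!inside] < cprime, pos[!inside], pos[!inside] - seg_len)
    out[!inside] <- ifelse(q < a, q, q + seg_len)
    out
  }
  new_seq <- NULL
  if (!is.null(genome)) {
    seg <- substr(genome, a + 1, b)
    if (inverted)
      seg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seg)))
    closed <- paste0(substr(genome, 1, a), substr(genome, b + 1, L))
    new_seq <- paste0(substr(closed, 1, cprime), seg,
                      substr(closed, cprime + 1, L - seg_len))
  }
  list(sequence = new_seq, liftover = lift, liftover_inv = lift_inv,
       segment_new = c(cprime, cprime + seg_len))
}

#' Generate a synthetic raw contact map
#'
#' Poisson counts around the expectation
#' `mu(i,j) = depth * exp(-d(i,j)*bin_size / min(lambda_i, lambda_j)) *
#' prod(insulation factors of boundaries crossed on the shorter arc)`,
#' with circular bin distance `d`. `lambda` is the per-locus contact-range
#' parameter in bp; an insulated Ter is modeled by reducing `lambda`
#' inside `ter_interval`; CID structure by multiplicative insulation at
#' boundary edges.
#'
#' @param chrom_length Chromosome length in bp (default 4,600,000).
#' @param bin_size Bin size in bp (default 5000).
#' @param lambda Decay length in bp: scalar or per-bin vector
#'   (default 200000).
#' @param ter_interval Optional `c(first, last)` 1-based bin interval
#'   with reduced lambda.
#' @param ter_lambda_factor Multiplier applied to lambda inside Ter
#'   (default 0.25).
#' @param cid_boundaries Integer bin edges `k` (boundary between bins `k`
#'   and `k+1`, wrapping at `N`).
#' @param insulation Insulation factor(s) in (0,1] per boundary
#'   (default 0.5).
#' @param depth Expected counts per bin pair at distance 0 (default 500).
#' @param circular Circular chromosome flag (default TRUE).
#' @param seed Integer seed.
#' @param noise `"poisson"` (default) or `"none"` (expected counts).
#' @return A raw [contact_map()]; attribute `mu` holds the expectation.
#' @export
gen_contact_map <- function(chrom_length = 46e5, bin_size = 5000,
                            lambda = 2e5, ter_interval = NULL,
                            ter_lambda_factor = 0.25,
                            cid_boundaries = integer(0),
                            insulation = 0.5, depth = 500,
                            circular = TRUE, seed = 1L,
                            noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  N <- ceiling(chrom_length / bin_size)
  lam <- rep_len(lambda, N)
  if (!is.null(ter_interval)) {
    ti <- ter_interval[1]:ter_interval[2]
    lam[wrap_index(ti, N)] <- lam[wrap_index(ti, N)] * ter_lambda_factor
  }
  if (any(lam <= 0)) stop("lambda must be positive")
  ij <- seq_len(N)
  dmat <- outer(ij, ij, function(i, j) {
    d <- abs(i - j)
    if (circular) pmin(d, N - d) else d
  })
  lmin <- outer(lam, lam, pmin)
  mu <- depth * exp(-dmat * bin_size / lmin)
  if (length(cid_boundaries)) {
    insulation <- rep_len(insulation, length(cid_boundaries))
    dlin <- outer(ij, ij, function(i, j) abs(i - j))
    # the lo->hi arc is the shorter one iff its length <= N/2 (ties: lo->hi)
    fwd_short <- if (circular) 2 * dlin <= N else
      matrix(TRUE, N, N)
    for (k in seq_along(cid_boundaries)) {
      e <- cid_boundaries[k]       # edge between bins e and e+1 (wrap)
      crossed_fwd <- outer(ij, ij, function(i, j) {
        lo <- pmin(i, j); hi <- pmax(i, j)
        lo <= e & e < hi           # lo->hi arc crosses edge e
      })
      crossed <- ifelse(fwd_short, crossed_fwd, !crossed_fwd & dlin > 0)
      mu <- mu * ifelse(crossed, insulation[k], 1)
    }
  }
  mu <- (mu + t(mu)) / 2
  M <- if (noise == "none") mu else with_seed(seed, {
    up <- which(upper.tri(mu, diag = TRUE))
    counts <- numeric(base::length(mu))
    counts[up] <- stats::rpois(base::length(up), mu[up])
    cm <- matrix(counts, N, N)
    cm <- cm + t(cm)
    diag(cm) <- diag(cm) / 2
    cm
  })
  out <- contact_map(M, bin_size, chrom_length, circular, state = "raw")
  attr(out, "mu") <- mu
  out
}

#' Generate a synthetic ChIP experiment (IP + input tracks)
#'
#' Input is flat Poisson coverage at `depth` reads/bp; IP follows the
#' same rate times an enrichment profile: `enrichment_fold` inside the
#' replicated interval, baseline inside the Ter-excluded interval, plus
#' optional narrow planted peaks. Deterministic (`noise = "none"`) mode
#' returns the expected coverage.
#'
#' @param chrom_length Chromosome length in bp (default 1e6).
#' @param replicated_interval 0-based half-open bp interval with
#'   replication-following enrichment (NULL = none).
#' @param enrichment_fold Fold inside the replicated interval
#'   (default 3, the middle of the observed 2-4x range).
#' @param ter_excluded_interval 0-based half-open bp interval forced to
#'   baseline (NULL = none).
#' @param peaks Optional data.frame with `center`, `fold`, `width` for
#'   narrow planted peaks (override the regional profile).
#' @param depth Mean reads per bp (default 100).
#' @param circular Circular chromosome flag (default TRUE).
#' @param seed Integer seed.
#' @param noise `"poisson"` (default) or `"none"`.
#' @return List with `ip` and `input` [coverage_track()]s; attribute
#'   `fold_profile` holds the planted per-bp fold.
#' @export
gen_chip_experiment <- function(chrom_length = 1e6,
                                replicated_interval = NULL,
                                enrichment_fold = 3,
                                ter_excluded_interval = NULL,
                                peaks = NULL, depth = 100,
                                circular = TRUE, seed = 1L,
                                noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  if (enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  L <- as.integer(chrom_length)
  fold <- rep(1, L)
  pos0 <- seq_len(L) - 1L
  if (!is.null(replicated_interval)) {
    sel <- in_circular_interval(pos0, replicated_interval[1],
                                replicated_interval[2], L)
    fold[sel] <- enrichment_fold
  }
  if (!is.null(ter_excluded_interval)) {
    sel <- in_circular_interval(pos0, ter_excluded_interval[1],
                                ter_excluded_interval[2], L)
    fold[sel] <- 1
  }
  if (!is.null(peaks) && nrow(peaks)) {
    for (k in seq_len(nrow(peaks))) {
      half <- peaks$width[k] %/% 2L
      idx <- (peaks$center[k] - half):(peaks$center[k] - half +
                                         peaks$width[k] - 1L)
      fold[(idx %% L) + 1L] <- peaks$fold[k]
    }
  }
  ip_rate <- depth * fold
  input_rate <- rep(depth, L)
  if (noise == "poisson") {
    vals <- with_seed(seed, list(ip = stats::rpois(L, ip_rate),
                                 input = stats::rpois(L, input_rate)))
  } else {
    vals <- list(ip = ip_rate, input = input_rate)
  }
  out <- list(ip = coverage_track(vals$ip, "IP", circular),
              input = coverage_track(vals$input, "input", circular))
  attr(out, "fold_profile") <- fold
  out
}

#' Generate read pairs with a planted event-class composition
#'
#' Builds a pair table whose classification under [classify_events()] has
#' exactly the requested composition: `n_self` same-fragment pairs,
#' `n_uncut` adjacent inward-facing pairs, and `n_valid` pairs between
#' distant fragments.
#'
#' @param rmap A [digest_genome()] result with at least 4 fragments.
#' @param n_valid,n_self,n_uncut Event counts.
#' @param seed Integer seed.
#' @return data.frame with `readID`, `pos1`, `strand1`, `pos2`, `strand2`.
#' @export
gen_pair_events <- function(rmap, n_valid = 100L, n_self = 10L,
                            n_uncut = 10L, seed = 1L) {
  frags <- rmap$fragments
  nf <- nrow(frags)
  if (nf < 4L) stop("need at least 4 fragments")
  L <- rmap$chrom_length
  rand_pos <- function(f) {                 # position within fragment f
    floor(stats::runif(length(f), frags$start[f], frags$end[f])) %% L
  }
  with_seed(seed, {
    rows <- list()
    if (n_self > 0) {
      f <- sample(nf, n_self, replace = TRUE)
      rows$self <- data.frame(pos1 = rand_pos(f), strand1 = "+",
                              pos2 = rand_pos(f), strand2 = "-")
    }
    if (n_uncut > 0) {
      f <- sample(nf, n_uncut, replace = TRUE)
      f2 <- wrap_index(f + 1L, nf)
      if (!rmap$circular) { f <- pmin(f, nf - 1L); f2 <- f + 1L }
      rows$uncut <- data.frame(pos1 = rand_pos(f), strand1 = "+",
                               pos2 = rand_pos(f2), strand2 = "-")
    }
    if (n_valid > 0) {
      f <- sample(nf, n_valid, replace = TRUE)
      off <- sample(2:(nf - 2L), n_valid, replace = TRUE)
      f2 <- wrap_index(f + off, nf)
      rows$valid <- data.frame(pos1 = rand_pos(f),
                               strand1 = sample(c("+", "-"), n_valid,
                                                replace = TRUE),
                               pos2 = rand_pos(f2),
                               strand2 = sample(c("+", "-"), n_valid,
                                                replace = TRUE))
    }
    out <- do.call(rbind, rows)
    out <- out[sample(nrow(out)), , drop = FALSE]
    out <- cbind(readID = sprintf("read_%d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}
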