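# Contact-map construction: restriction digest, pair-event filtering,
# binning, SCN balancing and log2 ratio maps.
#
# Coordinates are 0-based half-open internally; bins and fragments are
# numbered 1-based in genome order.

#' Digest a genome with a restriction enzyme
#'
#' Locates all occurrences of a fixed-length recognition site and returns
#' the induced fragment tiling. On a circular chromosome the last fragment
#' wraps through the origin so that fragments tile the genome exactly once.
#'
#' @param sequence Genome sequence: a character string or
#'   [Biostrings::DNAString].
#' @param circular Is the chromosome circular? Default `TRUE`.
#' @param site Recognition sequence (fixed-length DNA word). Default
#'   `"CCGG"` (HpaII).
#' @param cut_offset Offset of the cut within the site, in bp from the
#'   site start. Default 1 (`C^CGG`).
#' @return An object of class `RestrictionMap`: a list with
#'   `chrom_length`, `circular`, `cut_positions` (0-based bp, sorted) and
#'   `fragments` (data.frame with 0-based half-open `start`/`end`; for the
#'   wrapping fragment `end > chrom_length`).
#' @export
digest_genome <- function(sequence, circular = TRUE, site = "CCGG",
                          cut_offset = 1L) {
  seq_chr <- as.character(sequence)
  L <- nchar(seq_chr)
  if (L == 0L) stop("empty sequence")
  if (nchar(site) > L) stop("recognition site longer than the sequence")
  subject <- if (circular) {
    paste0(seq_chr, substr(seq_chr, 1L, nchar(site) - 1L))
  } else seq_chr
  hits <- Biostrings::matchPattern(Biostrings::DNAString(site),
                                   Biostrings::DNAString(subject))
  starts0 <- Biostrings::start(hits) - 1L          # 0-based match starts
  cuts <- sort(unique((starts0 + cut_offset) %% L))
  k <- length(cuts)
  if (k == 0L) {
    frags <- data.frame(start = 0, end = L)
  } else if (circular) {
    frags <- data.frame(start = cuts,
                        end   = c(cuts[-1L], cuts[1L] + L))
  } else {
    frags <- data.frame(start = c(0, cuts), end = c(cuts, L))
    frags <- frags[frags$start < frags$end, , drop = FALSE]
    rownames(frags) <- NULL
  }
  structure(list(chrom_length = L, circular = circular,
                 cut_positions = cuts, fragments = frags,
                 site = site, cut_offset = cut_offset),
            class = "RestrictionMap")
}

#' Assign positions to restriction fragments
#'
#' @param pos 0-based bp positions.
#' @param rmap A [digest_genome()] result.
#' @return 1-based fragment indices in genome order.
#' @export
assign_fragment <- function(pos, rmap) {
  if (any(pos < 0 | pos >= rmap$chrom_length))
    stop("position outside chromosome")
  cuts <- rmap$cut_positions
  k <- length(cuts)
  if (k == 0L) return(rep(1L, length(pos)))
  idx <- findInterval(pos, cuts)
  if (rmap$circular) {
    idx[idx == 0L] <- k    # before the first cut: wrapping fragment
    idx
  } else {
    idx + 1L
  }
}

#' Classify read pairs into ligation-event classes
#'
#' Assigns each mate to its restriction fragment and classifies the pair:
#' both mates in the same fragment are self-circularization candidates
#' (`self_fragment`); mates in adjacent fragments reading toward each
#' other (forward mate on the upstream fragment, reverse mate on the
#' downstream one) are uncut co-linear molecules (`uncut_adjacent`); all
#' other pairs are `valid`. Only valid pairs carry contact information.
#'
#' @param pairs data.frame with columns `pos1`, `strand1`, `pos2`,
#'   `strand2` (strands `"+"`/`"-"`, positions 0-based bp).
#' @param rmap A [digest_genome()] result.
#' @return The input with columns `frag1`, `frag2`, `event_class` added.
#' @export
classify_events <- function(pairs, rmap) {
  stopifnot(all(c("pos1", "strand1", "pos2", "strand2") %in% names(pairs)))
  f1 <- assign_fragment(pairs$pos1, rmap)
  f2 <- assign_fragment(pairs$pos2, rmap)
  nfrag <- nrow(rmap$fragments)
  cls <- rep("valid", nrow(pairs))
  cls[f1 == f2] <- "self_fragment"

  # uncut co-linear: adjacent fragments, inward-facing strands
  is_adj_up <- function(fa, fb) {            # fa immediately upstream of fb
    fb == fa + 1L | (rmap$circular & fa == nfrag & fb == 1L)
  }
  up1 <- is_adj_up(f1, f2) & pairs$strand1 == "+" & pairs$strand2 == "-"
  up2 <- is_adj_up(f2, f1) & pairs$strand2 == "+" & pairs$strand1 == "-"
  cls[(up1 | up2) & cls == "valid"] <- "uncut_adjacent"

  pairs$frag1 <- f1
  pairs$frag2 <- f2
  pairs$event_class <- cls
  pairs
}

#' Construct a ContactMap container
#'
#' @param matrix Symmetric nonnegative matrix of binned contacts.
#' @param bin_size Bin size in bp.
#' @param chrom_length Chromosome length in bp.
#' @param circular Circular chromosome flag.
#' @param masked_bins Integer vector of masked (1-based) bin indices.
#' @param state `"raw"` or `"normalized"`.
#' @return An object of class `ContactMap`.
#' @export
contact_map <- function(matrix, bin_size, chrom_length, circular = TRUE,
                        masked_bins = integer(0), state = "raw") {
  N <- ceiling(chrom_length / bin_size)
  stopifnot(nrow(matrix) == N, ncol(matrix) == N)
  if (max(abs(matrix - t(matrix))) > 1e-8 * max(1, max(abs(matrix))))
    stop("contact matrix must be symmetric")
  if (any(matrix < 0)) stop("contact matrix must be nonnegative")
  structure(list(matrix = matrix, bin_size = bin_size,
                 chrom_length = chrom_length, circular = circular,
                 masked_bins = sort(unique(as.integer(masked_bins))),
                 state = state),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap: %d x %d bins of %d bp (%s, %s), %d masked\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_size,
              if (x$circular) "circular" else "linear",
              x$state, length(x$masked_bins)))
  invisible(x)
}

#' Bin valid pair events into a raw contact map
#'
#' Each valid event increments the symmetric pair of cells `(i,j)` and
#' `(j,i)` once; events within one bin increment the diagonal cell once.
#'
#' @param events data.frame with `pos1`, `pos2` (0-based bp); typically
#'   the `valid`-class rows of [classify_events()].
#' @param bin_size Bin size in bp (default 5000).
#' @param chrom_length Chromosome length in bp.
#' @param circular Circular chromosome flag.
#' @return A raw [contact_map()].
#' @export
bin_contacts <- function(events, bin_size = 5000, chrom_length,
                         circular = TRUE) {
  if (bin_size <= 0) stop("bin_size must be positive")
  N <- ceiling(chrom_length / bin_size)
  M <- matrix(0, N, N)
  if (nrow(events) > 0) {
    b1 <- pmin(events$pos1 %/% bin_size + 1L, N)
    b2 <- pmin(events$pos2 %/% bin_size + 1L, N)
    i <- pmin(b1, b2); j <- pmax(b1, b2)
    tab <- table(i + (j - 1) * N)
    idx <- as.integer(names(tab))
    M[idx] <- as.numeric(tab)
    M <- M + t(M)
    diag(M) <- diag(M) / 2     # diagonal events counted once
  }
  contact_map(M, bin_size, chrom_length, circular, state = "raw")
}

#' Balance a contact map by sequential component normalization (SCN)
#'
#' Iterative alternating L1 row/column normalization with symmetrization
#' (averaging with the transpose) after each sweep, run until the
#' coefficient of variation of the unmasked row sums falls below `tol`.
#' Low-coverage bins (raw marginal below `mask_frac` of the median
#' marginal, or zero) are masked before balancing and stay all-zero.
#'
#' @param cm A raw [contact_map()].
#' @param max_iter Maximum sweeps (default 200).
#' @param tol Convergence tolerance on the row-sum CV (default 1e-6).
#' @param mask_frac Low-coverage mask fraction of the median marginal
#'   (default 0.1).
#' @return A normalized `ContactMap`; attribute `converged` reports
#'   whether `tol` was reached (a warning is raised otherwise).
#' @export
scn_normalize <- function(cm, max_iter = 200L, tol = 1e-6,
                          mask_frac = 0.1) {
  stopifnot(inherits(cm, "ContactMap"))
  M <- cm$matrix
  N <- nrow(M)
  marg <- rowSums(M)
  masked <- union(cm$masked_bins,
                  which(marg == 0 | marg < mask_frac * stats::median(marg)))
  keep <- setdiff(seq_len(N), masked)
  if (length(keep) == 0L) stop("all bins masked")
  S <- M[keep, keep, drop = FALSE]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    rs <- rowSums(S)
    if (any(rs == 0)) stop("zero row sum inside unmasked block")
    S <- S / rs
    S <- t(t(S) / colSums(S))
    S <- (S + t(S)) / 2
    rs <- rowSums(S)
    if (stats::sd(rs) / mean(rs) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("SCN did not reach tol=%g in %d sweeps", tol, max_iter))
  out <- matrix(0, N, N)
  out[keep, keep] <- S
  res <- contact_map(out, cm$bin_size, cm$chrom_length, cm$circular,
                     masked_bins = masked, state = "normalized")
  attr(res, "converged") <- converged
  res
}

# shift a matrix by (di, dj); circular wrap or NA fill
shift_matrix <- function(m, di, dj, circular) {
  n <- nrow(m); p <- ncol(m)
  if (circular) {
    m[wrap_index(seq_len(n) - di, n), wrap_index(seq_len(p) - dj, p),
      drop = FALSE]
  } else {
    out <- matrix(NA_real_, n, p)
    si <- seq_len(n) - di; sj <- seq_len(p) - dj
    oki <- si >= 1 & si <= n; okj <- sj >= 1 & sj <= p
    out[oki, okj] <- m[si[oki], sj[okj], drop = FALSE]
    out
  }
}

#' Gaussian-smooth a matrix with NA-aware kernel renormalization
#'
#' Undefined (NA) entries are excluded from the kernel mass, which is
#' renormalized over the defined entries; NA entries stay NA.
#'
#' @param m Numeric matrix (NA = undefined).
#' @param sigma Kernel standard deviation in bins; `0` returns `m`.
#' @param circular Wrap the kernel around the matrix edges.
#' @return Smoothed matrix, same shape.
#' @export
gaussian_smooth_matrix <- function(m, sigma, circular = TRUE) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  g <- stats::dnorm(-r:r, sd = sigma)
  val <- m; val[is.na(m)] <- 0
  def <- (!is.na(m)) * 1
  num <- matrix(0, nrow(m), ncol(m)); den <- num
  for (di in -r:r) {
    for (dj in -r:r) {
      w <- g[di + r + 1] * g[dj + r + 1]
      sv <- shift_matrix(val, di, dj, circular)
      sd_ <- shift_matrix(def, di, dj, circular)
      sv[is.na(sv)] <- 0; sd_[is.na(sd_)] <- 0
      num <- num + w * sv
      den <- den + w * sd_
    }
  }
  out <- num / den
  out[def == 0] <- NA_real_
  out
}

#' Log2 ratio of two normalized contact maps
#'
#' Entrywise `log2(a/b)` on entries defined (positive, unmasked) in both
#' maps, Gaussian-smoothed with standard deviation `sigma` bins (undefined
#' entries are excluded from the kernel and its mass renormalized).
#' Positive values mean more contacts in `a` than in `b`.
#'
#' @param a,b Normalized [contact_map()]s of identical shape.
#' @param sigma Smoothing standard deviation in bins (default 1).
#' @return An object of class `RatioMap`: list with `matrix` (smoothed
#'   log2 ratio, NA where undefined), `unsmoothed`, `smoothing_sigma` and
#'   `undefined_mask`.
#' @export
log_ratio_map <- function(a, b, sigma = 1) {
  stopifnot(inherits(a, "ContactMap"), inherits(b, "ContactMap"))
  if (!all(dim(a$matrix) == dim(b$matrix))) stop("shape mismatch")
  if (a$state != "normalized" || b$state != "normalized")
    stop("both maps must be normalized")
  defined <- a$matrix > 0 & b$matrix > 0
  lr <- matrix(NA_real_, nrow(a$matrix), ncol(a$matrix))
  lr[defined] <- log2(a$matrix[defined] / b$matrix[defined])
  sm <- gaussian_smooth_matrix(lr, sigma, circular = a$circular)
  structure(list(matrix = sm, unsmoothed = lr, smoothing_sigma = sigma,
                 undefined_mask = !defined),
            class = "RatioMap")
}
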