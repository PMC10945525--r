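# Range of cis contacts: robust thresholding of a balanced contact map,
# connected-component size filtering, diamond morphological closing, and
# the per-bin width of the significant band perpendicular to the main
# diagonal. Range (kb) = width_bins * bin_size / 2, the signal being
# symmetric on both sides of the locus.

#' Robust location/scale statistics of a contact map
#'
#' Median and median absolute deviation over the unmasked entries, with
#' the robust standard-deviation estimate `sigma = 1.4826 * mad`.
#'
#' @param cm A normalized [contact_map()].
#' @return List with `median`, `mad`, `sigma`.
#' @export
robust_stats <- function(cm) {
  stopifnot(inherits(cm, "ContactMap"))
  keep <- setdiff(seq_len(nrow(cm$matrix)), cm$masked_bins)
  if (length(keep) == 0L) stop("no unmasked entries")
  x <- cm$matrix[keep, keep]
  med <- stats::median(x)
  mad_ <- stats::median(abs(x - med))
  list(median = med, mad = mad_, sigma = 1.4826 * mad_)
}

#' Label connected components of a boolean matrix (8-connectivity)
#'
#' Pixels touching horizontally, vertically or diagonally belong to one
#' component; on circular maps adjacency wraps across both matrix edges.
#'
#' @param mask Logical matrix.
#' @param circular Wrap adjacency across edges.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, circular = TRUE) {
  n <- nrow(mask); p <- ncol(mask)
  lab <- matrix(0L, n, p)
  on <- which(mask)
  if (length(on) == 0L) return(lab)
  id <- matrix(0L, n, p)
  id[on] <- seq_along(on)
  # adjacency via half the 8-neighbour offsets (the rest by symmetry)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    sh <- shift_matrix(id * 1, -o[1], -o[2], circular)  # neighbour's id
    sh[is.na(sh)] <- 0
    sel <- which(mask & sh > 0)
    from <- c(from, id[sel]); to <- c(to, as.integer(sh[sel]))
  }
  g <- igraph::make_graph(rbind(from, to), n = length(on),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[on] <- as.integer(comp)
  lab
}

# diamond (Manhattan-ball) dilation/erosion by shifting; erosion pads
# with TRUE outside a linear map so that closing is extensive at edges
dilate_diamond <- function(mask, r, circular = TRUE) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  m <- mask * 1
  for (di in -r:r) {
    w <- r - abs(di)
    for (dj in -w:w) {
      s <- shift_matrix(m, di, dj, circular)
      s[is.na(s)] <- 0
      out <- out | (s > 0)
    }
  }
  out
}

erode_diamond <- function(mask, r, circular = TRUE) {
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  m <- mask * 1
  for (di in -r:r) {
    w <- r - abs(di)
    for (dj in -w:w) {
      s <- shift_matrix(m, di, dj, circular)
      s[is.na(s)] <- 1          # outside a linear map counts as filled
      out <- out & (s > 0)
    }
  }
  out
}

#' Significant-contact mask of a balanced map
#'
#' Binarizes at `value > median + k_sigma * sigma` (robust sigma), labels
#' connected components with 8-connectivity, discards components smaller
#' than `min_component` points, then applies morphological closing with a
#' diamond structuring element of radius `closing_radius` to fill holes
#' within the retained elements.
#'
#' @param cm A normalized [contact_map()].
#' @param k_sigma Threshold multiplier (default 1).
#' @param min_component Minimum component size in points (default 30).
#' @param closing_radius Diamond radius in bins (default 5).
#' @return Object of class `SignificanceMask`: list with logical `mask`,
#'   the pre-closing `component_mask`, parameters, and `circular`.
#' @export
significance_mask <- function(cm, k_sigma = 1, min_component = 30L,
                              closing_radius = 5L) {
  if (k_sigma < 0) stop("k_sigma must be nonnegative")
  rs <- robust_stats(cm)
  thr <- rs$median + k_sigma * rs$sigma
  raw <- cm$matrix > thr
  if (length(cm$masked_bins)) {
    raw[cm$masked_bins, ] <- FALSE
    raw[, cm$masked_bins] <- FALSE
  }
  lab <- label_components(raw, cm$circular)
  sizes <- tabulate(lab)
  keep_labels <- which(sizes >= min_component)
  comp <- matrix(lab %in% keep_labels, nrow(raw), ncol(raw))
  closed <- if (closing_radius > 0) {
    erode_diamond(dilate_diamond(comp, closing_radius, cm$circular),
                  closing_radius, cm$circular)
  } else comp
  structure(list(mask = closed, component_mask = comp,
                 k_sigma = k_sigma, min_component = min_component,
                 closing_radius = closing_radius, threshold = thr,
                 circular = cm$circular, bin_size = cm$bin_size),
            class = "SignificanceMask")
}

#' Per-bin diagonal width and range of cis contacts
#'
#' For each bin `i` the significant band is measured perpendicular to the
#' main diagonal: walking the anti-diagonal points `(i+t, i-t)` for
#' `t = 0, +/-1, ...`, the maximal contiguous run of significant points
#' containing `t = 0` gives the width in bins (odd by symmetry, 0 if the
#' diagonal point itself is not significant). The range in kb is
#' `width_bins * bin_size / 2`.
#'
#' @param sigmask A [significance_mask()] (or a logical symmetric matrix;
#'   then `bin_size` and `circular` must be given).
#' @param bin_size Bin size in bp (taken from `sigmask` if present).
#' @param circular Wrap anti-diagonal runs around the map edges.
#' @return Object of class `WidthProfile`: list with `width_bins`,
#'   `range_kb`, `bin_size`.
#' @export
diagonal_width_profile <- function(sigmask, bin_size = NULL,
                                   circular = NULL) {
  if (inherits(sigmask, "SignificanceMask")) {
    mask <- sigmask$mask
    if (is.null(bin_size)) bin_size <- sigmask$bin_size
    if (is.null(circular)) circular <- sigmask$circular
  } else mask <- sigmask
  if (is.null(bin_size) || is.null(circular))
    stop("bin_size and circular required with a bare mask")
  if (!isTRUE(all(mask == t(mask)))) stop("mask must be symmetric")
  N <- nrow(mask)
  width <- integer(N)
  alive <- mask[cbind(seq_len(N), seq_len(N))]
  width[alive] <- 1L
  tmax <- if (circular) N %/% 2 else N - 1L
  for (t in seq_len(tmax)) {
    if (!any(alive)) break
    i <- which(alive)
    ip <- i + t; im <- i - t
    if (circular) {
      ip <- wrap_index(ip, N); im <- wrap_index(im, N)
      ok <- mask[cbind(ip, im)]
    } else {
      inb <- ip <= N & im >= 1L
      ok <- inb
      ok[inb] <- mask[cbind(ip[inb], im[inb])]
    }
    alive[i[!ok]] <- FALSE
    width[i[ok]] <- width[i[ok]] + 2L
  }
  structure(list(width_bins = width,
                 range_kb = width * (bin_size / 1000) / 2,
                 bin_size = bin_size),
            class = "WidthProfile")
}

#' Summarize the range of cis contacts over a region
#'
#' Median and quartiles (linear-interpolation convention) of the per-bin
#' range over a bin interval, which may wrap on a circular map.
#'
#' @param profile A [diagonal_width_profile()] result.
#' @param region Integer vector `c(start, end)` of 1-based bin indices,
#'   inclusive; `end < start` wraps through the origin. `NULL` = all bins.
#' @return List with `region`, `median`, `q25`, `q75`, `n_bins`.
#' @export
summarize_range <- function(profile, region = NULL) {
  N <- length(profile$range_kb)
  bins <- if (is.null(region)) seq_len(N)
  else if (region[1] <= region[2]) region[1]:region[2]
  else c(region[1]:N, 1:region[2])
  if (length(bins) == 0L) stop("empty region")
  x <- profile$range_kb[bins]
  q <- quantiles_lin(x)
  list(region = if (is.null(region)) c(1L, N) else region,
       q25 = q[1], median = q[2], q75 = q[3], n_bins = length(bins))
}
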