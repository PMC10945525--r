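# Independent brute-force oracles used to check the pipeline
# implementations on small instances. These deliberately re-derive each
# quantity from its definition (loops, explicit enumeration) and share no
# code with the package internals.

# --- Sinkhorn balancing oracle: plain alternating normalization with
#     explicit loops, run to machine precision ----------------------------
oracle_sinkhorn <- function(M, iters = 10000) {
  for (it in seq_len(iters)) {
    for (i in seq_len(nrow(M))) M[i, ] <- M[i, ] / sum(M[i, ])
    for (j in seq_len(ncol(M))) M[, j] <- M[, j] / sum(M[, j])
    M <- (M + t(M)) / 2
    rs <- rowSums(M)
    if (max(rs) - min(rs) < 1e-14) break
  }
  M
}

# --- connected components, 8-connectivity, by flood fill ----------------
oracle_label <- function(mask, circular = FALSE) {
  n <- nrow(mask); p <- ncol(mask)
  lab <- matrix(0L, n, p)
  cur <- 0L
  for (i0 in seq_len(n)) for (j0 in seq_len(p)) {
    if (!mask[i0, j0] || lab[i0, j0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- cur
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        i <- q[1] + di; j <- q[2] + dj
        if (circular) {
          i <- ((i - 1) %% n) + 1; j <- ((j - 1) %% p) + 1
        } else if (i < 1 || i > n || j < 1 || j > p) next
        if (mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- cur
          queue[[length(queue) + 1]] <- c(i, j)
        }
      }
    }
  }
  lab
}

# --- diamond closing by explicit point-set dilation/erosion -------------
oracle_close <- function(mask, r, circular = FALSE) {
  n <- nrow(mask); p <- ncol(mask)
  offsets <- expand.grid(di = -r:r, dj = -r:r)
  offsets <- offsets[abs(offsets$di) + abs(offsets$dj) <= r, ]
  dil <- matrix(FALSE, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    if (!mask[i, j]) next
    for (k in seq_len(nrow(offsets))) {
      ii <- i + offsets$di[k]; jj <- j + offsets$dj[k]
      if (circular) { ii <- ((ii - 1) %% n) + 1; jj <- ((jj - 1) %% p) + 1 }
      else if (ii < 1 || ii > n || jj < 1 || jj > p) next
      dil[ii, jj] <- TRUE
    }
  }
  out <- matrix(FALSE, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    keep <- TRUE
    for (k in seq_len(nrow(offsets))) {
      ii <- i + offsets$di[k]; jj <- j + offsets$dj[k]
      if (circular) { ii <- ((ii - 1) %% n) + 1; jj <- ((jj - 1) %% p) + 1 }
      else if (ii < 1 || ii > n || jj < 1 || jj > p) next  # outside = filled
      if (!dil[ii, jj]) { keep <- FALSE; break }
    }
    out[i, j] <- keep
  }
  out
}

# --- per-bin perpendicular diagonal width by explicit walking -----------
oracle_width <- function(mask, circular = FALSE) {
  N <- nrow(mask)
  w <- integer(N)
  for (i in seq_len(N)) {
    if (!mask[i, i]) next
    w[i] <- 1L
    tmax <- if (circular) N %/% 2 else N - 1
    for (t in seq_len(tmax)) {
      ip <- i + t; im <- i - t
      if (circular) {
        ip <- ((ip - 1) %% N) + 1; im <- ((im - 1) %% N) + 1
      } else if (ip > N || im < 1) break
      if (!mask[ip, im]) break
      w[i] <- w[i] + 2L
    }
  }
  w
}

# --- full mask -> components -> size filter -> closing -> width oracle --
oracle_range_pipeline <- function(values, threshold, min_component, r,
                                  circular = FALSE) {
  mask <- values > threshold
  lab <- oracle_label(mask, circular)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_component])
  comp <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  closed <- oracle_close(comp, r, circular)
  oracle_width(closed, circular)
}

# --- discrete Gaussian smoothing with NA renormalization, loops ---------
oracle_gauss <- function(m, sigma, circular = FALSE) {
  r <- ceiling(3 * sigma)
  n <- nrow(m); p <- ncol(m)
  out <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    if (is.na(m[i, j])) next
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (circular) { ii <- ((ii - 1) %% n) + 1; jj <- ((jj - 1) %% p) + 1 }
      else if (ii < 1 || ii > n || jj < 1 || jj > p) next
      if (is.na(m[ii, jj])) next
      w <- dnorm(di, sd = sigma) * dnorm(dj, sd = sigma)
      num <- num + w * m[ii, jj]; den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# small synthetic normalized map helper for module tests
small_norm_map <- function(N = 60, lambda = 5e4, depth = 300, seed = 1,
                           ...) {
  cm <- gen_contact_map(chrom_length = N * 5000, bin_size = 5000,
                        lambda = lambda, depth = depth, seed = seed, ...)
  scn_normalize(cm)
}
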