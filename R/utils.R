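#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are deterministic without clobbering the
#' session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 1-based circular index into 1..n
wrap_index <- function(i, n) ((i - 1L) %% n) + 1L

# circular genomic distance in bins between 1-based bin indices
circ_dist <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

# linear-interpolation quantiles (type 7), the convention used throughout
quantiles_lin <- function(x, probs = c(0.25, 0.5, 0.75)) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = TRUE)
}

# membership of 0-based position p in a possibly wrapping half-open
# interval [start, end) on a circle of length len
in_circular_interval <- function(p, start, end, len) {
  p <- p %% len; start <- start %% len; end <- end %% len
  if (start <= end) p >= start & p < end else p >= start | p < end
}
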