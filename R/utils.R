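#' @useDynLib clemalign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft median quantile runif sd t.test
#' @importFrom utils read.csv write.csv head
NULL

# Smallest integer >= n whose prime factors are all in {2, 3, 5}.
# R's mixed-radix FFT degrades badly on sizes with large prime factors,
# so spectral correlation pads to the next smooth size.
next_fast_size <- function(n) {
  if (n <= 2) return(2L)
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(as.integer(m))
    m <- m + 1L
  }
}

# Raised-cosine (Tukey) edge taper, `frac` of each edge tapered.
taper_window <- function(nr, nc, frac = 0.1) {
  tuk <- function(n) {
    if (frac <= 0) return(rep(1, n))
    w <- rep(1, n)
    m <- max(1L, floor(frac * n))
    i <- seq_len(m)
    ramp <- 0.5 * (1 - cos(pi * (i - 0.5) / m))
    w[i] <- ramp
    w[n + 1 - i] <- ramp
    w
  }
  outer(tuk(nr), tuk(nc))
}

# Deterministic seed splitting: one user seed expands to per-stage seeds
# (MINSTD step with a stage offset), so sub-analyses are independently
# reproducible. All derived seeds stay below 2^31 - 1.
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  ((abs(seed) %% 2147483647) * 48271 + 97 * stage) %% 2147483647
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One timestamped line per pipeline stage, to stderr.
log_stage <- function(..., quiet = FALSE) {
  if (isTRUE(quiet)) return(invisible(NULL))
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  invisible(NULL)
}

# Matrix view of whatever the caller handed in (RasterImage, PatternMask,
# plain matrix). Masks come back as 0/1 numerics.
as_pixel_matrix <- function(x) {
  if (inherits(x, "RasterImage")) return(x$pixels + 0)
  if (inherits(x, "PatternMask")) return(x$mask + 0)
  if (inherits(x, "GlobalMap")) return(as_pixel_matrix(x$image))
  if (is.matrix(x)) return(x + 0)
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a 2-D image", call. = FALSE)
}
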