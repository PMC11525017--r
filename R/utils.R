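#' Derive a deterministic per-unit RNG seed from a master seed
#'
#' Uses two multiplicative Lehmer steps (multiplier 48271 modulo 2^31 - 1),
#' so every unit (case, bootstrap replicate, trial replicate) gets its own
#' reproducible substream and earlier units are unchanged when more units are
#' requested.  All intermediate products stay below 2^53, so the arithmetic
#' is exact in doubles.
#'
#' @param master master seed (integer-valued scalar).
#' @param i unit index (positive integer-valued scalar).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master, i) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(i), length(i) == 1L, i >= 0)
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.numeric(master)) %% (m - 1)) + 1
  s <- (s * 48271) %% m
  s <- (s + (as.numeric(i) %% m) * 69621) %% m
  s <- (s * 48271) %% m
  as.integer(if (s == 0) 1 else s)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Canonical "MLH1+PMS2"-style pattern string for a set of lost proteins.
canonical_pattern <- function(lost) {
  lost <- intersect(PROTEINS, lost)
  paste(lost, collapse = "+")
}

# Split a pattern string back into a protein vector ("" -> character(0)).
split_pattern <- function(pattern) {
  if (is.na(pattern) || !nzchar(pattern)) return(character(0))
  strsplit(pattern, "+", fixed = TRUE)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quantile function of a two-component Beta mixture, tabulated once on a
# fine grid and inverted by linear interpolation (error < 1e-4 in the value).
qbetamix_fun <- function(w, hi, mod) {
  x <- seq(0, 1, length.out = 8193)
  p <- w * pbeta(x, hi[1], hi[2]) + (1 - w) * pbeta(x, mod[1], mod[2])
  approxfun(p, x, yleft = 0, yright = 1, ties = "ordered")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
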