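# Shared internal helpers: deterministic seeding, interpolation, spectra.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# user's stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed from a master seed and a set of small integer
# keys (subject index, action, trial, stage). Plain modular polynomial hash in
# double arithmetic; all intermediates stay far below 2^53 and the result is a
# valid 32-bit seed.
hash_seed <- function(master, ...) {
  keys <- c(...)
  h <- as.double(master) %% 2147483629
  for (k in keys) h <- (h * 69069 + as.double(k) + 1) %% 2147483629
  as.integer(h)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Row-wise softmax for an n x k matrix.
softmax_rows <- function(m) {
  z <- exp(m - apply(m, 1L, max))
  z / rowSums(z)
}

# Linear-interpolation resampling of a vector to a new length, sampling the
# original index range uniformly (endpoints preserved).
resample_linear <- function(x, new_len) {
  n <- length(x)
  if (new_len == n) return(x)
  if (n == 1L) return(rep(x, new_len))
  pos <- seq(1, n, length.out = new_len)
  stats::approx(seq_len(n), x, xout = pos)$y
}

# Bilinear resize of a matrix to out_r x out_c, sampling the source grid at
# uniformly spaced positions with endpoint alignment (the convention used for
# scalogram standardisation).
resize_bilinear <- function(m, out_r, out_c) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- if (nr == 1L) rep(1, out_r) else seq(1, nr, length.out = out_r)
  ci <- if (nc == 1L) rep(1, out_c) else seq(1, nc, length.out = out_c)
  r0 <- pmin(floor(ri), nr - 1L); r0[nr == 1L] <- 1L
  c0 <- pmin(floor(ci), nc - 1L); c0[nc == 1L] <- 1L
  if (nr == 1L) { r0 <- rep(1L, out_r); fr <- rep(0, out_r) } else fr <- ri - r0
  if (nc == 1L) { c0 <- rep(1L, out_c); fc <- rep(0, out_c) } else fc <- ci - c0
  r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
  a <- m[r0, c0, drop = FALSE]; b <- m[r1, c0, drop = FALSE]
  d <- m[r0, c1, drop = FALSE]; e <- m[r1, c1, drop = FALSE]
  wr <- matrix(fr, out_r, out_c)
  wc <- matrix(fc, out_r, out_c, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + d * (1 - wr) * wc + e * wr * wc
}

# Welch power spectral density: Hamming-windowed segments with 50% overlap,
# averaged periodograms. Returns frequencies (Hz) and power per bin.
welch_psd <- function(x, fs, seg_len = min(256L, length(x)), overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  if (seg_len == 1L) win <- 1
  nfreq <- floor(seg_len / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * win
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[seq_len(nfreq)]
  }
  list(freq = (seq_len(nfreq) - 1) * fs / seg_len,
       power = acc / length(starts))
}

onehot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
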