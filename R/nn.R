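# Minimal dense neural-network primitives with explicit backward passes.
#
# Feature maps live in matrices with one column per channel and rows ordered
# (h fastest, then w, then image), matching the C++ im2col/col2im/maxpool
# kernels; convolutions are im2col + BLAS GEMM. Each forward returns the
# cache its backward needs. Parameters are flat named lists of matrices so
# the optimizer, gradient clipping and parameter counting stay generic.

init_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  list(W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
       b = numeric(cout))
}

# Slice a batch out of a tensor_set / signal_set input array (2-D scalogram
# stacks are a single array; raw 1-D signal sets carry one array per branch).
get_batch_x <- function(ts, ix) {
  if (is.list(ts$x))
    list(emg = ts$x$emg[, , ix, drop = FALSE],
         kine = ts$x$kine[, , ix, drop = FALSE])
  else ts$x[, , , ix, drop = FALSE]
}

init_linear <- function(din, dout) {
  list(W = matrix(stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

# Convolution WITHOUT the bias add: every conv here feeds a batch-norm
# layer, so its bias is folded into the batch-norm shift instead (exact in
# both modes; in training mode a conv bias ahead of batch norm cancels in
# the centering step and receives exactly zero gradient).
conv_fwd <- function(x, H, W, B, Wm, kh = 3L, kw = 3L, ph = 1L, pw = 1L) {
  cols <- im2col_hw(x, H, W, B, kh, kw, ph, pw)
  list(y = cols %*% Wm, cols = cols)
}

# db is identically zero: the conv bias is folded into the following batch
# norm, which cancels it from the training-mode output (see bn_fwd).
conv_bwd <- function(dy, cache, H, W, B, Wm, kh = 3L, kw = 3L,
                     ph = 1L, pw = 1L, cin) {
  dW <- crossprod(cache$cols, dy)
  dx <- col2im_hw(dy %*% t(Wm), H, W, B, kh, kw, ph, pw, cin)
  list(dx = dx, dW = dW, db = numeric(ncol(dy)))
}

# Batch normalisation over rows (i.e. over batch x spatial positions), one
# statistic per channel column. Training uses batch statistics (biased
# variance) and updates running statistics with momentum; evaluation uses
# the running statistics. `bias` is the folded bias of the preceding conv:
# it shifts the batch mean (hence the running statistics) but cancels from
# the normalised output in training mode.
bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5, bias = NULL) {
  if (is.null(bias)) bias <- numeric(ncol(x))
  if (training) {
    m <- nrow(x)
    mu <- colMeans(x)
    v <- colmeans_prod(x, x) - mu^2
    v <- pmax(v, 0)
    inv <- 1 / sqrt(v + eps)
    xhat <- colscale_add(x, inv, -mu * inv)
    unb <- if (m > 1) v * m / (m - 1) else v
    run_mean <- (1 - momentum) * run_mean + momentum * (mu + bias)
    run_var <- (1 - momentum) * run_var + momentum * unb
    y <- colscale_add(xhat, gamma, beta)
    list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma),
         run_mean = run_mean, run_var = run_var)
  } else {
    inv <- 1 / sqrt(run_var + eps)
    xhat <- colscale_add(x, inv, (bias - run_mean) * inv)
    y <- colscale_add(xhat, gamma, beta)
    list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma),
         run_mean = run_mean, run_var = run_var)
  }
}

bn_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  dgamma <- colmeans_prod(dy, xhat) * nrow(dy)
  dbeta <- colSums(dy)
  dxhat <- colscale_add(dy, cache$gamma, numeric(length(cache$gamma)))
  dx <- bn_bwd_dx(dxhat, xhat, colMeans(dxhat),
                  colmeans_prod(dxhat, xhat), cache$inv)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

linear_fwd <- function(x, W, b) {
  y <- x %*% W
  y + rep(b, each = nrow(y))
}

linear_bwd <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

# Global average pooling: (H*W*B) x C -> B x C.
gap_fwd <- function(x, HW, B) {
  rowsum(x, group = rep(seq_len(B), each = HW), reorder = FALSE) / HW
}

gap_bwd <- function(dy, HW) {
  dy[rep(seq_len(nrow(dy)), each = HW), , drop = FALSE] / HW
}

softmax_ce_loss <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dy <- p
  dy[idx] <- dy[idx] - 1
  list(loss = loss, dlogits = dy / n, prob = p)
}
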