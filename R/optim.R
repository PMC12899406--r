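# AdamW optimiser with decoupled weight decay, and global-norm gradient
# clipping, operating on the flat named parameter lists of amwfnet_model.

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, opt, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 1e-4) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    step <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (step + weight_decay * params[[nm]])
  }
  list(params = params, opt = opt)
}

# Scale all gradients so the global L2 norm does not exceed max_norm.
# Returns the clipped gradients and the post-clip norm.
clip_global_norm <- function(grads, max_norm = 1) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    sc <- max_norm / (total + 1e-12)
    grads <- lapply(grads, function(g) g * sc)
    total <- max_norm
  }
  list(grads = grads, norm = total)
}
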