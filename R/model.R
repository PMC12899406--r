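# The dual-branch wavelet-fusion classifier: shared-shape per-plane image
# encoders, channel-wise attention pooling, temperature-gated modality
# fusion and an action-aware head, with full analytic backpropagation.

#' Construct the action-aware multimodal wavelet fusion model
#'
#' Builds the dual-branch network. Each scalogram plane is passed as a
#' separate 1-channel image through a branch-shared encoder of four
#' double-convolution blocks (3x3 conv + batch norm + ReLU, twice, then 2x2
#' max pool) with channel progression `1 -> channels[1] -> ... ->
#' channels[4]`, followed by global average pooling to a D-dimensional
#' vector per plane (D = `channels[4]`). A channel-wise attention MLP
#' (D -> D/2 -> 1, softmax over planes) pools each branch to one vector;
#' a gating MLP (2D -> `gate_hidden` -> 2) with temperature-`tau` softmax
#' convexly fuses the two branch vectors; the classifier concatenates an
#' 18-dimensional action one-hot (146 = 128 + 18 at default width) and maps
#' through a hidden layer (128, ReLU, dropout 0.3) to 6 logits. The two
#' branch encoders are structurally identical but weight-independent.
#'
#' Ablation variants: `"semg_only"` / `"kine_only"` drop the other branch
#' and the gate; `"no_action"` omits the one-hot context; `"concat"`
#' replaces the gate by concatenation plus a linear 2D -> D reduction.
#'
#' @param input_size Spatial size of the square scalogram input; must be
#'   divisible by 16 (four 2x2 pools).
#' @param channels Length-4 integer, encoder channel progression.
#' @param gate_hidden,head_hidden Hidden widths of gate and classifier.
#' @param tau Gating softmax temperature (> 0).
#' @param dropout Classifier dropout rate.
#' @param n_emg,n_kine Planes per branch (8 muscles, 3 kinematic channels).
#' @param n_actions,n_classes Action vocabulary and output width.
#' @param variant One of `"full"`, `"semg_only"`, `"kine_only"`,
#'   `"no_action"`, `"concat"`.
#' @param seed Seed for weight initialisation.
#' @return A list of class `amwfnet_model` with elements `config`, `params`
#'   (named list of weight matrices) and `state` (batch-norm running
#'   statistics).
#' @examples
#' m <- amwfnet_model()
#' count_parameters(m)   # 1268554
#' @export
amwfnet_model <- function(input_size = 128, channels = c(32, 64, 128, 128),
                          gate_hidden = 256, head_hidden = 128,
                          tau = 2.5, dropout = 0.3,
                          n_emg = 8, n_kine = 3,
                          n_actions = 18, n_classes = 6,
                          variant = c("full", "semg_only", "kine_only",
                                      "no_action", "concat"),
                          seed = 42) {
  variant <- match.arg(variant)
  stop_if_not(input_size %% 16 == 0, "input_size must be divisible by 16")
  stop_if_not(tau > 0, "temperature tau must be > 0")
  stop_if_not(length(channels) == 4, "channels must have length 4")
  D <- channels[4]
  cfg <- list(input_size = input_size, channels = channels, D = D,
              attn_hidden = max(1L, D %/% 2L),
              gate_hidden = gate_hidden, head_hidden = head_hidden,
              tau = tau, dropout = dropout,
              n_emg = n_emg, n_kine = n_kine,
              n_actions = n_actions, n_classes = n_classes,
              variant = variant, bn_momentum = 0.1, bn_eps = 1e-5,
              type = "2d", kh = 3L, kw = 3L, ph = 1L, pw = 1L,
              pool = c(2L, 2L),
              input_hw_emg = c(input_size, input_size),
              input_hw_kine = c(input_size, input_size))
  build_model(cfg, seed)
}

# Shared constructor: allocates encoder / attention / gate / head parameters
# from a completed config (used by both the 2-D scalogram model and the raw
# 1-D dual-stream baseline).
build_model <- function(cfg, seed) {
  variant <- cfg$variant
  channels <- cfg$channels
  D <- cfg$D
  gate_hidden <- cfg$gate_hidden
  with_seed(seed, {
    params <- list()
    state <- list()
    add_encoder <- function(prefix) {
      cin <- 1L
      for (i in 1:4) {
        cout <- channels[i]
        for (j in 1:2) {
          cv <- init_conv(cfg$kh, cfg$kw, cin, cout)
          params[[sprintf("%s.b%d.conv%d.W", prefix, i, j)]] <<- cv$W
          params[[sprintf("%s.b%d.conv%d.b", prefix, i, j)]] <<- cv$b
          params[[sprintf("%s.b%d.bn%d.gamma", prefix, i, j)]] <<- rep(1, cout)
          params[[sprintf("%s.b%d.bn%d.beta", prefix, i, j)]] <<- numeric(cout)
          state[[sprintf("%s.b%d.bn%d.mean", prefix, i, j)]] <<- numeric(cout)
          state[[sprintf("%s.b%d.bn%d.var", prefix, i, j)]] <<- rep(1, cout)
          cin <- cout
        }
      }
    }
    add_attention <- function(prefix) {
      fc1 <- init_linear(D, cfg$attn_hidden)
      fc2 <- init_linear(cfg$attn_hidden, 1L)
      params[[paste0(prefix, ".fc1.W")]] <<- fc1$W
      params[[paste0(prefix, ".fc1.b")]] <<- fc1$b
      params[[paste0(prefix, ".fc2.W")]] <<- fc2$W
      params[[paste0(prefix, ".fc2.b")]] <<- fc2$b
    }
    use_emg <- variant != "kine_only"
    use_kine <- variant != "semg_only"
    if (use_emg) { add_encoder("enc_emg"); add_attention("attn_emg") }
    if (use_kine) { add_encoder("enc_kine"); add_attention("attn_kine") }
    if (use_emg && use_kine) {
      if (variant == "concat") {
        red <- init_linear(2L * D, D)
        params[["fuse.red.W"]] <- red$W
        params[["fuse.red.b"]] <- red$b
      } else {
        g1 <- init_linear(2L * D, gate_hidden)
        g2 <- init_linear(gate_hidden, 2L)
        params[["gate.fc1.W"]] <- g1$W
        params[["gate.fc1.b"]] <- g1$b
        params[["gate.fc2.W"]] <- g2$W
        params[["gate.fc2.b"]] <- g2$b
      }
    }
    head_in <- D + if (variant == "no_action") 0L else cfg$n_actions
    h1 <- init_linear(head_in, cfg$head_hidden)
    h2 <- init_linear(cfg$head_hidden, cfg$n_classes)
    params[["head.fc1.W"]] <- h1$W
    params[["head.fc1.b"]] <- h1$b
    params[["head.fc2.W"]] <- h2$W
    params[["head.fc2.b"]] <- h2$b
    structure(list(config = cfg, params = params, state = state),
              class = "amwfnet_model")
  })
}

#' Count trainable parameters
#'
#' Sums the sizes of all weight, bias and batch-norm affine tensors
#' (running statistics are buffers, not parameters). The default
#' architecture has 1,268,554 trainable parameters, about 1.27 million,
#' i.e. roughly 4.84 MB at 4 bytes per parameter.
#'
#' @param model An [amwfnet_model()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Architecture fingerprint
#'
#' A machine-readable summary of every parameter tensor (name, dimensions,
#' size) plus the total count; convertible to JSON for run manifests.
#'
#' @param model An [amwfnet_model()].
#' @return List with `variant`, `layers` (data frame of name/dims/size) and
#'   `total_parameters`.
#' @export
architecture_fingerprint <- function(model) {
  layers <- data.frame(
    name = names(model$params),
    dims = vapply(model$params, function(p)
      paste(if (is.null(dim(p))) length(p) else dim(p), collapse = "x"), ""),
    size = vapply(model$params, length, integer(1)),
    row.names = NULL)
  list(variant = model$config$variant, layers = layers,
       total_parameters = count_parameters(model))
}

#' @export
print.amwfnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<amwfnet_model> variant %s | input %dx%d | channels %s | D=%d | tau=%g\n",
              cfg$variant, cfg$input_size, cfg$input_size,
              paste(cfg$channels, collapse = "-"), cfg$D, cfg$tau))
  cat(sprintf("  %d trainable parameters (%.2f M, %.2f MB at 4 bytes)\n",
              count_parameters(x), count_parameters(x) / 1e6,
              count_parameters(x) * 4 / 2^20))
  invisible(x)
}

## ---- branch encoder -----------------------------------------------------

#' Encode a stack of scalogram planes to per-plane feature vectors
#'
#' Runs each plane independently (shared weights, input channel 1) through
#' the branch encoder and global average pooling.
#'
#' @param model An [amwfnet_model()].
#' @param planes Array `(S, S, N)` for one trial or `(S, S, N, B)` for a
#'   batch, values in [0, 1].
#' @param branch `"emg"` or `"kine"`.
#' @param training Logical; training mode updates batch-norm statistics.
#' @return List with `F` (`(B*N) x D` feature matrix, plane index fastest),
#'   `cache` (for backprop) and `model` (with updated running statistics
#'   when `training = TRUE`).
#' @export
encode_branch <- function(model, planes, branch = c("emg", "kine"),
                          training = FALSE) {
  branch <- match.arg(branch)
  prefix <- paste0("enc_", branch)
  cfg <- model$config
  hw <- cfg[[paste0("input_hw_", branch)]]
  d <- dim(planes)
  if (length(d) == 3L) d <- c(d, 1L)
  stop_if_not(d[1] == hw[1] && d[2] == hw[2],
              sprintf("planes must be %dx%d", hw[1], hw[2]))
  nb <- d[3] * d[4]                      # planes are independent images
  x <- matrix(as.numeric(planes), ncol = 1L)  # (H*W*nb) x 1, channel dim 1
  H <- d[1]; W <- d[2]
  fh <- cfg$pool[1]; fw <- cfg$pool[2]
  cache <- list(dims = c(H, W, nb))
  for (i in 1:4) {
    for (j in 1:2) {
      key <- function(part) sprintf("%s.b%d.%s", prefix, i, part)
      cv <- conv_fwd(x, H, W, nb, model$params[[key(sprintf("conv%d.W", j))]],
                     cfg$kh, cfg$kw, cfg$ph, cfg$pw)
      bn <- bn_fwd(cv$y, model$params[[key(sprintf("bn%d.gamma", j))]],
                   model$params[[key(sprintf("bn%d.beta", j))]],
                   model$state[[key(sprintf("bn%d.mean", j))]],
                   model$state[[key(sprintf("bn%d.var", j))]],
                   training, cfg$bn_momentum, cfg$bn_eps,
                   bias = model$params[[key(sprintf("conv%d.b", j))]])
      if (training) {
        model$state[[key(sprintf("bn%d.mean", j))]] <- bn$run_mean
        model$state[[key(sprintf("bn%d.var", j))]] <- bn$run_var
      }
      rl <- relu_fwd(bn$y)
      cache[[sprintf("b%d_%d", i, j)]] <-
        list(conv_cols = cv$cols, bn = bn$cache, mask = rl$mask, H = H, W = W)
      x <- rl$y
    }
    mp <- maxpool_fwd(x, H, W, nb, fh, fw)
    cache[[sprintf("pool%d", i)]] <- list(idx = mp$idx, n_in = nrow(x),
                                          H = H, W = W)
    x <- mp$y
    H <- H %/% fh; W <- W %/% fw
  }
  cache$final_hw <- H * W
  Fmat <- gap_fwd(x, H * W, nb)
  list(F = Fmat, cache = cache, model = model)
}

encode_branch_bwd <- function(model, dF, cache, branch) {
  prefix <- paste0("enc_", branch)
  cfg <- model$config
  grads <- list()
  nb <- cache$dims[3]
  dx <- gap_bwd(dF, cache$final_hw)
  for (i in 4:1) {
    pc <- cache[[sprintf("pool%d", i)]]
    dx <- maxpool_bwd(dx, pc$idx, pc$n_in)
    for (j in 2:1) {
      key <- function(part) sprintf("%s.b%d.%s", prefix, i, part)
      cc <- cache[[sprintf("b%d_%d", i, j)]]
      dx <- dx * cc$mask
      bnb <- bn_bwd(dx, cc$bn)
      grads[[key(sprintf("bn%d.gamma", j))]] <- bnb$dgamma
      grads[[key(sprintf("bn%d.beta", j))]] <- bnb$dbeta
      Wm <- model$params[[key(sprintf("conv%d.W", j))]]
      cin <- nrow(Wm) %/% (cfg$kh * cfg$kw)
      cb <- conv_bwd(bnb$dx, list(cols = cc$conv_cols), cc$H, cc$W, nb,
                     Wm, cfg$kh, cfg$kw, cfg$ph, cfg$pw, cin = cin)
      grads[[key(sprintf("conv%d.W", j))]] <- cb$dW
      grads[[key(sprintf("conv%d.b", j))]] <- cb$db
      dx <- cb$dx
    }
  }
  grads
}

## ---- attention pooling ----------------------------------------------------

#' Channel-wise attention pooling
#'
#' Scores each plane's feature vector with a small MLP (D -> D/2 -> ReLU ->
#' 1), normalises the scores with a softmax across the N planes of the
#' branch, and returns the attention-weighted sum of the rows.
#'
#' @param model An [amwfnet_model()].
#' @param F `(B*N) x D` feature matrix (plane index fastest), e.g. from
#'   [encode_branch()].
#' @param branch `"emg"` or `"kine"`.
#' @param n_planes Planes per trial N; defaults to the branch's plane count.
#' @return List with `f_modality` (`B x D`), `alpha` (`N x B`, columns sum
#'   to 1) and `cache`.
#' @export
attention_pool <- function(model, F, branch = c("emg", "kine"),
                           n_planes = NULL) {
  branch <- match.arg(branch)
  prefix <- paste0("attn_", branch)
  cfg <- model$config
  N <- n_planes %||% if (branch == "emg") cfg$n_emg else cfg$n_kine
  stop_if_not(nrow(F) %% N == 0, "nrow(F) must be a multiple of n_planes")
  B <- nrow(F) %/% N
  W1 <- model$params[[paste0(prefix, ".fc1.W")]]
  b1 <- model$params[[paste0(prefix, ".fc1.b")]]
  W2 <- model$params[[paste0(prefix, ".fc2.W")]]
  b2 <- model$params[[paste0(prefix, ".fc2.b")]]
  h <- linear_fwd(F, W1, b1)
  rl <- relu_fwd(h)
  scores <- linear_fwd(rl$y, W2, b2)           # (B*N) x 1
  smat <- matrix(scores, N, B)
  alpha <- matrix(apply(smat, 2L, softmax), N, B)
  if (N == 1L) alpha <- matrix(1, 1L, B)
  av <- as.vector(alpha)
  grp <- rep(seq_len(B), each = N)
  f_mod <- rowsum(F * av, group = grp, reorder = FALSE)
  list(f_modality = f_mod, alpha = alpha,
       cache = list(F = F, h = rl$y, mask = rl$mask, alpha = alpha,
                    N = N, B = B, grp = grp))
}

attention_pool_bwd <- function(model, dfmod, cache, branch, dalpha_extra = NULL) {
  prefix <- paste0("attn_", branch)
  N <- cache$N; B <- cache$B
  alpha <- cache$alpha
  av <- as.vector(alpha)
  # f_mod = sum_i alpha_i F_i
  dF <- dfmod[cache$grp, , drop = FALSE] * av
  dalpha <- matrix(rowSums(dfmod[cache$grp, , drop = FALSE] * cache$F), N, B)
  if (!is.null(dalpha_extra)) dalpha <- dalpha + dalpha_extra
  # softmax backward per column
  dscore <- alpha * sweep(dalpha, 2L, colSums(alpha * dalpha))
  W2 <- model$params[[paste0(prefix, ".fc2.W")]]
  l2 <- linear_bwd(matrix(as.vector(dscore), ncol = 1L), cache$h, W2)
  dh <- l2$dx * cache$mask
  W1 <- model$params[[paste0(prefix, ".fc1.W")]]
  l1 <- linear_bwd(dh, cache$F, W1)
  dF <- dF + l1$dx
  grads <- list()
  grads[[paste0(prefix, ".fc2.W")]] <- l2$dW
  grads[[paste0(prefix, ".fc2.b")]] <- l2$db
  grads[[paste0(prefix, ".fc1.W")]] <- l1$dW
  grads[[paste0(prefix, ".fc1.b")]] <- l1$db
  list(dF = dF, grads = grads)
}

## ---- gated fusion ---------------------------------------------------------

#' Temperature-gated modality fusion
#'
#' Concatenates the two branch vectors, maps through the gating MLP to two
#' logits, applies a temperature-scaled softmax `w = softmax(l / tau)` and
#' returns the convex combination `w_emg * f_emg + w_kine * f_kine`.
#'
#' @param model An [amwfnet_model()] (variant with a gate).
#' @param f_emg,f_kine `B x D` branch feature matrices.
#' @return List with `f_fused` (`B x D`), `w` (`B x 2`, rows sum to 1) and
#'   `cache`.
#' @export
gated_fuse <- function(model, f_emg, f_kine) {
  tau <- model$config$tau
  stop_if_not(tau > 0, "temperature tau must be > 0")
  fcat <- cbind(f_emg, f_kine)
  h <- linear_fwd(fcat, model$params[["gate.fc1.W"]], model$params[["gate.fc1.b"]])
  rl <- relu_fwd(h)
  l <- linear_fwd(rl$y, model$params[["gate.fc2.W"]], model$params[["gate.fc2.b"]])
  w <- softmax_rows(l / tau)
  f_fused <- f_emg * w[, 1] + f_kine * w[, 2]
  list(f_fused = f_fused, w = w,
       cache = list(fcat = fcat, h = rl$y, mask = rl$mask, w = w,
                    f_emg = f_emg, f_kine = f_kine, tau = tau))
}

gated_fuse_bwd <- function(model, dfused, cache) {
  w <- cache$w; tau <- cache$tau
  df_emg <- dfused * w[, 1]
  df_kine <- dfused * w[, 2]
  dw <- cbind(rowSums(dfused * cache$f_emg), rowSums(dfused * cache$f_kine))
  dl <- (w * (dw - rowSums(w * dw))) / tau
  l2 <- linear_bwd(dl, cache$h, model$params[["gate.fc2.W"]])
  dh <- l2$dx * cache$mask
  l1 <- linear_bwd(dh, cache$fcat, model$params[["gate.fc1.W"]])
  D <- ncol(df_emg)
  df_emg <- df_emg + l1$dx[, seq_len(D), drop = FALSE]
  df_kine <- df_kine + l1$dx[, D + seq_len(D), drop = FALSE]
  grads <- list("gate.fc2.W" = l2$dW, "gate.fc2.b" = l2$db,
                "gate.fc1.W" = l1$dW, "gate.fc1.b" = l1$db)
  list(df_emg = df_emg, df_kine = df_kine, grads = grads)
}

## ---- action-aware head ----------------------------------------------------

#' Action-aware classification head
#'
#' Concatenates a one-hot encoding of the action ID (positions 1..18) to
#' the fused feature vector (composite width 146 at default D = 128) and
#' maps through hidden-128 / ReLU / dropout-0.3 / linear-6. Dropout is
#' active only in training mode, so evaluation is deterministic.
#'
#' @param model An [amwfnet_model()].
#' @param f_fused `B x D` fused feature matrix.
#' @param action_id Integer vector of length B, actions in 1..18.
#' @param training Logical; enables dropout.
#' @return List with `logits` (`B x 6`) and `cache`.
#' @export
classify <- function(model, f_fused, action_id, training = FALSE) {
  cfg <- model$config
  check_action_id(action_id)
  if (cfg$variant == "no_action") {
    z <- f_fused
  } else {
    oh <- matrix(0, nrow(f_fused), cfg$n_actions)
    oh[cbind(seq_along(action_id), action_id)] <- 1
    z <- cbind(f_fused, oh)
  }
  h <- linear_fwd(z, model$params[["head.fc1.W"]], model$params[["head.fc1.b"]])
  rl <- relu_fwd(h)
  hd <- rl$y
  dmask <- NULL
  if (training && cfg$dropout > 0) {
    dmask <- matrix(stats::rbinom(length(hd), 1L, 1 - cfg$dropout),
                    nrow(hd), ncol(hd)) / (1 - cfg$dropout)
    hd <- hd * dmask
  }
  logits <- linear_fwd(hd, model$params[["head.fc2.W"]], model$params[["head.fc2.b"]])
  list(logits = logits,
       cache = list(z = z, h = rl$y, mask = rl$mask, dmask = dmask, hd = hd))
}

classify_bwd <- function(model, dlogits, cache) {
  l2 <- linear_bwd(dlogits, cache$hd, model$params[["head.fc2.W"]])
  dh <- l2$dx
  if (!is.null(cache$dmask)) dh <- dh * cache$dmask
  dh <- dh * cache$mask
  l1 <- linear_bwd(dh, cache$z, model$params[["head.fc1.W"]])
  D <- model$config$D
  grads <- list("head.fc2.W" = l2$dW, "head.fc2.b" = l2$db,
                "head.fc1.W" = l1$dW, "head.fc1.b" = l1$db)
  list(dfused = l1$dx[, seq_len(D), drop = FALSE], grads = grads)
}

## ---- full model -----------------------------------------------------------

#' Full forward pass
#'
#' Runs a batch of 11-plane scalogram tensors through both branches,
#' attention pooling, gated fusion and the action-aware head.
#'
#' @param model An [amwfnet_model()].
#' @param x Array `(S, S, 11, B)` (or `(S, S, 11)` for one trial) with the
#'   8 sEMG planes before the 3 kinematic planes.
#' @param action_id Integer vector of length B.
#' @param training Logical; enables batch-norm batch statistics and dropout.
#' @return List with `logits`, `alpha_emg` (8 x B), `alpha_kine` (3 x B),
#'   `w` (`B x 2` gate weights or NULL), `cache` and `model` (updated
#'   running statistics under training).
#' @export
model_forward <- function(model, x, action_id, training = FALSE) {
  cfg <- model$config
  if (is.list(x)) {           # raw 1-D signal batch: one array per branch
    planes_emg <- x$emg
    planes_kine <- x$kine
    reshape1d <- function(a) {
      if (is.null(a)) return(NULL)
      d <- dim(a)
      if (length(d) == 2L) d <- c(d, 1L)
      array(a, c(1L, d))      # height-1 images
    }
    planes_emg <- reshape1d(planes_emg)
    planes_kine <- reshape1d(planes_kine)
  } else {
    d <- dim(x)
    if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
    stop_if_not(d[3] == cfg$n_emg + cfg$n_kine,
                sprintf("expected %d planes", cfg$n_emg + cfg$n_kine))
    planes_emg <- x[, , seq_len(cfg$n_emg), , drop = FALSE]
    planes_kine <- x[, , cfg$n_emg + seq_len(cfg$n_kine), , drop = FALSE]
  }
  use_emg <- cfg$variant != "kine_only"
  use_kine <- cfg$variant != "semg_only"
  cache <- list()
  alpha_emg <- alpha_kine <- w <- NULL
  f_emg <- f_kine <- NULL
  if (use_emg) {
    eb <- encode_branch(model, planes_emg, "emg", training)
    model <- eb$model
    ap <- attention_pool(model, eb$F, "emg")
    f_emg <- ap$f_modality; alpha_emg <- ap$alpha
    cache$enc_emg <- eb$cache; cache$attn_emg <- ap$cache
  }
  if (use_kine) {
    kb <- encode_branch(model, planes_kine, "kine", training)
    model <- kb$model
    ap <- attention_pool(model, kb$F, "kine")
    f_kine <- ap$f_modality; alpha_kine <- ap$alpha
    cache$enc_kine <- kb$cache; cache$attn_kine <- ap$cache
  }
  if (use_emg && use_kine) {
    if (cfg$variant == "concat") {
      fcat <- cbind(f_emg, f_kine)
      f_fused <- linear_fwd(fcat, model$params[["fuse.red.W"]],
                            model$params[["fuse.red.b"]])
      cache$fuse <- list(fcat = fcat)
    } else {
      gf <- gated_fuse(model, f_emg, f_kine)
      f_fused <- gf$f_fused; w <- gf$w
      cache$gate <- gf$cache
    }
  } else {
    f_fused <- if (use_emg) f_emg else f_kine
  }
  cl <- classify(model, f_fused, action_id, training)
  cache$head <- cl$cache
  list(logits = cl$logits, alpha_emg = alpha_emg, alpha_kine = alpha_kine,
       w = w, cache = cache, model = model)
}

# Analytic gradients for one batch given the loss gradient w.r.t. logits.
model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  use_emg <- cfg$variant != "kine_only"
  use_kine <- cfg$variant != "semg_only"
  hb <- classify_bwd(model, dlogits, cache$head)
  grads <- hb$grads
  dfused <- hb$dfused
  if (use_emg && use_kine) {
    if (cfg$variant == "concat") {
      lr <- linear_bwd(dfused, cache$fuse$fcat, model$params[["fuse.red.W"]])
      grads[["fuse.red.W"]] <- lr$dW
      grads[["fuse.red.b"]] <- lr$db
      D <- cfg$D
      df_emg <- lr$dx[, seq_len(D), drop = FALSE]
      df_kine <- lr$dx[, D + seq_len(D), drop = FALSE]
    } else {
      gb <- gated_fuse_bwd(model, dfused, cache$gate)
      grads <- c(grads, gb$grads)
      df_emg <- gb$df_emg; df_kine <- gb$df_kine
    }
  } else if (use_emg) df_emg <- dfused else df_kine <- dfused
  if (use_emg) {
    ab <- attention_pool_bwd(model, df_emg, cache$attn_emg, "emg")
    grads <- c(grads, ab$grads)
    grads <- c(grads, encode_branch_bwd(model, ab$dF, cache$enc_emg, "emg"))
  }
  if (use_kine) {
    ab <- attention_pool_bwd(model, df_kine, cache$attn_kine, "kine")
    grads <- c(grads, ab$grads)
    grads <- c(grads, encode_branch_bwd(model, ab$dF, cache$enc_kine, "kine"))
  }
  grads
}
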