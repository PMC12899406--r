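small_model <- function(seed = 7, ...) {
  amwfnet_model(input_size = 32, channels = c(4, 6, 8, 8), gate_hidden = 16,
                head_hidden = 12, seed = seed, ...)
}

test_that("the default architecture reproduces the published size", {
  m <- amwfnet_model()
  expect_equal(count_parameters(m), 1268554L)
  expect_equal(round(count_parameters(m) / 1e6, 2), 1.27)
  expect_equal(count_parameters(m) * 4 / 2^20, 4.84, tolerance = 0.01)
  enc <- grepl("^enc_emg", names(m$params))
  expect_equal(sum(vapply(m$params[enc], length, integer(1))), 583008L)
  # composite head input 146 = 128 + 18, output width 6
  expect_equal(dim(m$params[["head.fc1.W"]]), c(146L, 128L))
  expect_equal(ncol(m$params[["head.fc2.W"]]), 6L)
  # attention MLP reduces D -> D/2 -> 1
  expect_equal(dim(m$params[["attn_emg.fc1.W"]]), c(128L, 64L))
  expect_equal(dim(m$params[["attn_emg.fc2.W"]]), c(64L, 1L))
  # gate MLP: 256 -> 256 -> 2
  expect_equal(dim(m$params[["gate.fc1.W"]]), c(256L, 256L))
  expect_equal(dim(m$params[["gate.fc2.W"]]), c(256L, 2L))
})

test_that("parameter count is architecture-determined, not seed-dependent", {
  expect_equal(count_parameters(amwfnet_model(seed = 1)),
               count_parameters(amwfnet_model(seed = 999)))
  fp <- architecture_fingerprint(amwfnet_model(seed = 1))
  expect_equal(fp$total_parameters, 1268554L)
  expect_true(all(fp$layers$size > 0))
})

test_that("encoder maps plane stacks to per-plane feature rows", {
  m <- small_model()
  set.seed(1)
  planes <- array(stats::runif(32 * 32 * 8 * 2), c(32, 32, 8, 2))
  eb <- encode_branch(m, planes, "emg")
  expect_equal(dim(eb$F), c(16L, 8L))      # (B*N) x D with D = 8
  # identical planes through shared weights give identical rows
  planes2 <- planes
  planes2[, , 3, 1] <- planes2[, , 5, 1]
  F2 <- encode_branch(m, planes2, "emg")$F
  expect_equal(F2[3, ], F2[5, ])
  expect_error(encode_branch(m, array(0, c(16, 16, 8, 1)), "emg"), "32x32")
})

test_that("attention pooling is a softmax-weighted convex combination", {
  m <- small_model()
  set.seed(2)
  F <- matrix(stats::rnorm(8 * 8), 8, 8)
  ap <- attention_pool(m, F, "emg")
  expect_equal(colSums(ap$alpha), 1, ignore_attr = TRUE)
  expect_true(all(ap$alpha > 0))
  # identical rows -> uniform weights 1/N
  Fu <- matrix(rep(F[1, ], each = 8), 8, 8)
  apu <- attention_pool(m, Fu, "emg")
  expect_equal(as.vector(apu$alpha), rep(1 / 8, 8))
  expect_equal(apu$f_modality[1, ], F[1, ])
  # N = 1 degenerates to identity
  ap1 <- attention_pool(m, F[1, , drop = FALSE], "emg", n_planes = 1)
  expect_equal(as.vector(ap1$alpha), 1)
  expect_equal(ap1$f_modality[1, ], F[1, ])
})

test_that("attention pooling is permutation-equivariant", {
  m <- small_model()
  set.seed(3)
  F <- matrix(stats::rnorm(8 * 8), 8, 8)
  perm <- sample(8)
  a <- attention_pool(m, F, "emg")
  b <- attention_pool(m, F[perm, , drop = FALSE], "emg")
  expect_equal(as.vector(b$alpha), as.vector(a$alpha)[perm])
  expect_equal(b$f_modality, a$f_modality)
})

test_that("the gate computes the temperature softmax exactly", {
  m <- small_model()
  set.seed(4)
  f_e <- matrix(stats::rnorm(3 * 8), 3, 8)
  f_k <- matrix(stats::rnorm(3 * 8), 3, 8)
  gf <- gated_fuse(m, f_e, f_k)
  expect_equal(rowSums(gf$w), rep(1, 3))
  expect_true(all(gf$w > 0 & gf$w < 1))
  # equal logits -> (0.5, 0.5) at any tau (pin the gate output layer)
  meq <- small_model()
  meq$params[["gate.fc2.W"]][] <- 0
  meq$params[["gate.fc2.b"]] <- c(-0.7, -0.7)
  expect_equal(as.vector(gated_fuse(meq, f_e, f_k)$w), rep(0.5, 6))
  # fused vector lies on the segment between the branch vectors
  lam <- gf$w[, 1]
  expect_equal(gf$f_fused, f_e * lam + f_k * (1 - lam))
  expect_true(all(sqrt(rowSums(gf$f_fused^2)) <=
                    pmax(sqrt(rowSums(f_e^2)), sqrt(rowSums(f_k^2))) + 1e-9))
})

test_that("fixed logits reproduce the hand-evaluated softmax and its limits", {
  tau <- 2.5
  w <- amwfnet:::softmax(c(2, 0) / tau)
  expect_equal(w[1], exp(0.8) / (exp(0.8) + 1))
  # temperature limits: tau -> Inf equalises, tau -> 0 selects the winner
  expect_equal(amwfnet:::softmax(c(2, 0) / 1e6), c(0.5, 0.5), tolerance = 1e-5)
  expect_equal(amwfnet:::softmax(c(2, 0) / 1e-3), c(1, 0), tolerance = 1e-6)
  # monotonicity in the logit gap, entropy non-decreasing in tau
  gaps <- seq(-2, 2, by = 0.5)
  w_e <- vapply(gaps, function(g) amwfnet:::softmax(c(g, 0) / tau)[1], 0)
  expect_true(all(diff(w_e) > 0))
  ent <- function(t) { p <- amwfnet:::softmax(c(2, 0) / t); -sum(p * log(p)) }
  ents <- vapply(c(0.5, 1, 1.5, 2, 2.5, 3, 5, 8, 10), ent, 0)
  expect_true(all(diff(ents) >= 0))
  expect_error(amwfnet_model(tau = 0), "tau")
})

test_that("the classifier concatenates the action one-hot and is deterministic in eval mode", {
  m <- small_model()
  set.seed(5)
  f <- matrix(stats::rnorm(2 * 8), 2, 8)
  cl <- classify(m, f, c(7L, 18L))
  expect_equal(dim(cl$logits), c(2L, 6L))
  expect_equal(ncol(cl$cache$z), 8L + 18L)
  expect_equal(cl$cache$z[1, 8L + 7L], 1)
  expect_equal(sum(cl$cache$z[1, 9:26]), 1)
  expect_error(classify(m, f, c(0L, 1L)), "1..18")
  # repeated eval-mode forwards agree (dropout disabled)
  x <- array(stats::runif(32 * 32 * 11 * 2), c(32, 32, 11, 2))
  l1 <- model_forward(m, x, c(3L, 12L))$logits
  l2 <- model_forward(m, x, c(3L, 12L))$logits
  expect_identical(l1, l2)
})

test_that("analytic gradients match numerical differentiation", {
  m <- amwfnet_model(input_size = 16, channels = c(2, 3, 4, 4),
                     gate_hidden = 6, head_hidden = 5, dropout = 0,
                     seed = 3)
  set.seed(2)
  x <- array(stats::runif(16 * 16 * 11 * 2), c(16, 16, 11, 2))
  aid <- c(5L, 18L); y <- c(2L, 4L)
  loss_fn <- function(mod) {
    fw <- model_forward(mod, x, aid, training = TRUE)
    amwfnet:::softmax_ce_loss(fw$logits, y)$loss
  }
  fw <- model_forward(m, x, aid, training = TRUE)
  grads <- amwfnet:::model_backward(
    m, fw$cache, amwfnet:::softmax_ce_loss(fw$logits, y)$dlogits)
  eps <- 1e-5
  set.seed(42)
  for (nm in c("enc_emg.b1.conv1.W", "enc_kine.b4.conv2.W",
               "enc_emg.b2.bn1.gamma", "attn_emg.fc1.W", "attn_kine.fc2.b",
               "gate.fc1.W", "gate.fc2.b", "head.fc1.W", "head.fc2.b")) {
    for (i in sample(length(m$params[[nm]]),
                     min(3, length(m$params[[nm]])))) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
      ana <- as.numeric(grads[[nm]])[i]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("ablation variants change only the named component", {
  set.seed(6)
  x <- array(stats::runif(32 * 32 * 11 * 2), c(32, 32, 11, 2))
  full <- small_model()
  for (v in c("semg_only", "kine_only", "no_action", "concat")) {
    mv <- small_model(variant = v)
    fw <- model_forward(mv, x, c(1L, 9L))
    expect_equal(dim(fw$logits), c(2L, 6L))
    if (v == "semg_only") {
      expect_null(fw$alpha_kine)
      expect_false(any(grepl("enc_kine|gate", names(mv$params))))
    }
    if (v == "kine_only") expect_null(fw$alpha_emg)
    if (v == "no_action")
      expect_equal(nrow(mv$params[["head.fc1.W"]]), 8L)
    if (v == "concat") {
      expect_true("fuse.red.W" %in% names(mv$params))
      expect_false(any(grepl("^gate", names(mv$params))))
      expect_null(fw$w)
    }
  }
  expect_error(amwfnet_model(variant = "bogus"), "arg")
})

test_that("model checkpoints round-trip with a JSON fingerprint", {
  m <- small_model()
  dir <- withr::local_tempdir()
  save_model(m, dir)
  expect_true(file.exists(file.path(dir, "fingerprint.json")))
  fp <- jsonlite::read_json(file.path(dir, "fingerprint.json"))
  expect_equal(fp$total_parameters, count_parameters(m))
  m2 <- load_model(dir)
  expect_identical(m2$params, m$params)
})
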