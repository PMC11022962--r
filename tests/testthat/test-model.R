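make_tiny_setup <- function(n_channels = 6, n_bands = 4, hidden = 3,
                            gcn_channels = c(4, 5), seed = 2,
                            n_segments = 5, dropout = 0) {
  cfg <- model_config(bilstm_hidden = hidden, gcn_channels = gcn_channels,
                      dropout = dropout)
  set.seed(seed)
  tensors <- lapply(seq_len(n_segments), function(i) {
    x <- array(rnorm(n_channels * 4 * n_bands), c(n_channels, 4, n_bands))
    structure(x, class = "feature_tensor", label = i %% 2L)
  })
  g <- adjacency_from_data(matrix(rnorm(n_channels * 100), n_channels, 100))
  gs <- graph_stack(g, length(gcn_channels))
  params <- init_model_params(cfg, n_channels, n_bands)
  labels <- vapply(tensors, attr, 0L, "label")
  list(cfg = cfg, tensors = tensors, gs = gs, params = params,
       labels = labels)
}

test_that("BiLSTM node encoding has shape (channels, 2*hidden) incl. the 64-channel case", {
  cfg <- model_config(bilstm_hidden = 16, gcn_channels = c(32, 64))
  set.seed(1)
  params <- init_model_params(cfg, 64, 4)
  x <- array(rnorm(64 * 4 * 4), c(64, 4, 4))
  H <- bilstm_encode(x, params)
  expect_identical(dim(H), c(64L, 32L))
  expect_true(all(is.finite(H)))
  # determinism: same input, same params -> identical output
  expect_identical(H, bilstm_encode(x, params))
})

test_that("all-zero LSTM parameters yield all-zero node features", {
  cfg <- model_config(bilstm_hidden = 4, gcn_channels = 4)
  set.seed(1)
  params <- init_model_params(cfg, 3, 2)
  params$lstm <- rapply(params$lstm, function(w) w * 0, how = "replace")
  H <- bilstm_encode(array(rnorm(3 * 4 * 2), c(3, 4, 2)), params)
  expect_equal(max(abs(H)), 0)
})

test_that("NaN in the feature tensor is caught before the recurrence", {
  cfg <- model_config(bilstm_hidden = 2, gcn_channels = 2)
  set.seed(1)
  params <- init_model_params(cfg, 2, 2)
  x <- array(NA_real_, c(2, 4, 2))
  expect_error(bilstm_encode(x, params), "NaN")
})

test_that("gcn_layer reproduces identity and hand-computed cases", {
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_layer(H, diag(4), diag(3)), H)

  S <- matrix(0.5, 2, 2)
  out <- gcn_layer(matrix(c(1, 3), 2, 1), S, matrix(2, 1, 1))
  expect_equal(out, matrix(4, 2, 1))

  # negative pre-activation rectified to zero under the bounded ReLU
  out2 <- gcn_layer(matrix(c(-1, -3), 2, 1), diag(2), matrix(1, 1, 1),
                    activation = function(z) brelu(z, 6))
  expect_equal(out2, matrix(0, 2, 1))

  expect_error(gcn_layer(H, diag(3), diag(3)), "dimension mismatch")
})

test_that("gcn_layer matches a naive triple-loop oracle on random small graphs", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    din <- sample(2:4, 1); dout <- sample(2:4, 1)
    S <- propagation_matrix(adjacency_from_data(matrix(rnorm(n * 60), n, 60)))
    H <- matrix(rnorm(n * din), n, din)
    W <- matrix(rnorm(din * dout), din, dout)
    act <- function(z) brelu(z, 6)
    expect_equal(unname(gcn_layer(H, S, W, act)),
                 gcn_oracle(unname(S), H, W, act), tolerance = 1e-6)
  }
})

test_that("bounded ReLU clamps at 0 and at the cap", {
  expect_equal(brelu(-1), 0)
  expect_equal(brelu(0.5), 0.5)
  expect_equal(brelu(10, cap = 6), 6)
  expect_equal(brelu(c(-2, 3, 99), cap = 6), c(0, 3, 6))
  expect_error(brelu(1, cap = -1))
})

test_that("spectral pooling halves node count and reduces groups correctly", {
  H <- matrix(rnorm(64 * 3), 64, 3)
  asg <- rep(1:32, each = 2)
  expect_identical(dim(spectral_pool(H, asg)), c(32L, 3L))

  # identical rows + mean reducer -> coarse equals fine
  Hdup <- matrix(rep(1:4, each = 2), 4, 2)
  expect_equal(spectral_pool(Hdup, c(1, 1, 2, 2), "mean"),
               Hdup[c(1, 3), ])

  # elementwise max by hand: {[1,5],[3,2]} -> [3,5]
  expect_equal(spectral_pool(rbind(c(1, 5), c(3, 2)), c(1, 1), "max"),
               rbind(c(3, 5)))

  expect_error(spectral_pool(H, rep(1, 10)), "assignment")
})

test_that("forward pass yields proper probabilities and is deterministic in eval mode", {
  ts <- make_tiny_setup(dropout = 0.5)
  p1 <- model_forward(ts$tensors, ts$gs, ts$params, ts$cfg)
  expect_identical(dim(p1), c(5L, 2L))
  expect_equal(rowSums(p1), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p1 >= 0 & p1 <= 1))
  p2 <- model_forward(ts$tensors, ts$gs, ts$params, ts$cfg)
  expect_identical(p1, p2)  # dropout disabled outside training
})

test_that("node counts halve through the stack: 64 -> 32 -> 16", {
  ts <- make_tiny_setup(n_channels = 64, hidden = 2, gcn_channels = c(3, 4),
                        n_segments = 2)
  arr <- braingcn:::.stack_tensors(ts$tensors)
  fc <- braingcn:::.net_forward(arr, ts$params, ts$gs, ts$cfg)
  expect_equal(fc$cache$gcache[[1]]$n, 64)
  expect_equal(fc$cache$gcache[[2]]$n, 32)
  expect_equal(fc$cache$n_final, 16)
})

test_that("loss reproduces hand-computed values", {
  # perfect prediction, no penalty -> ~0
  p <- rbind(c(1, 0), c(0, 1))
  expect_lt(model_loss(p, c(0L, 1L)), 1e-10)
  # uniform prediction -> log 2 per sample
  pu <- matrix(0.5, 3, 2)
  expect_equal(model_loss(pu, c(0L, 1L, 0L)), log(2), tolerance = 1e-12)
  # lambda = 1, single weight 2, zero data term -> 4
  params <- list(dense = list(W = matrix(2, 1, 1)))
  expect_equal(model_loss(rbind(c(1, 0)), 0L, params, lambda = 1), 4,
               tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  ts <- make_tiny_setup()
  arr <- braingcn:::.stack_tensors(ts$tensors)
  lam <- 1e-3
  lg <- braingcn:::.net_loss_grad(arr, ts$labels, ts$params, ts$gs,
                                  ts$cfg, lam)
  theta <- braingcn:::.param_flatten(ts$params)
  gflat <- braingcn:::.param_flatten(lg$grad)
  set.seed(99)
  idx <- sample(length(theta), max(20L, length(theta) %/% 100L))
  eps <- 1e-5
  for (i in idx) {
    tp <- theta; tp[i] <- theta[i] + eps
    tm <- theta; tm[i] <- theta[i] - eps
    lp <- braingcn:::.net_loss_grad(
      arr, ts$labels, braingcn:::.param_unflatten(tp, ts$params),
      ts$gs, ts$cfg, lam)$loss
    lm <- braingcn:::.net_loss_grad(
      arr, ts$labels, braingcn:::.param_unflatten(tm, ts$params),
      ts$gs, ts$cfg, lam)$loss
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - gflat[i]) /
                max(abs(num) + abs(gflat[i]), 1e-6), 1e-3)
  }
})

test_that("weighted cross-entropy gradients are also exact", {
  ts <- make_tiny_setup(seed = 6)
  arr <- braingcn:::.stack_tensors(ts$tensors)
  w <- c(2, 0.5, 2, 0.5, 2)
  lg <- braingcn:::.net_loss_grad(arr, ts$labels, ts$params, ts$gs,
                                  ts$cfg, 0, sample_w = w)
  theta <- braingcn:::.param_flatten(ts$params)
  gflat <- braingcn:::.param_flatten(lg$grad)
  set.seed(3)
  for (i in sample(length(theta), 10)) {
    eps <- 1e-5
    tp <- theta; tp[i] <- theta[i] + eps
    tm <- theta; tm[i] <- theta[i] - eps
    num <- (braingcn:::.net_loss_grad(
              arr, ts$labels, braingcn:::.param_unflatten(tp, ts$params),
              ts$gs, ts$cfg, 0, sample_w = w)$loss -
            braingcn:::.net_loss_grad(
              arr, ts$labels, braingcn:::.param_unflatten(tm, ts$params),
              ts$gs, ts$cfg, 0, sample_w = w)$loss) / (2 * eps)
    expect_lt(abs(num - gflat[i]) /
                max(abs(num) + abs(gflat[i]), 1e-6), 1e-3)
  }
})

test_that("forward is consistent under channel permutation", {
  ts <- make_tiny_setup(n_channels = 8, seed = 10)
  set.seed(31)
  perm <- sample(8)
  # permute channels of the data and rebuild graph from permuted data;
  # probabilities must be unchanged (graph + assignments permute along)
  data <- matrix(rnorm(8 * 120), 8, 120)
  g1 <- adjacency_from_data(data)
  g2 <- adjacency_from_data(data[perm, ])
  gs1 <- graph_stack(g1, 2)
  gs2 <- graph_stack(g2, 2)
  # same coarsening structure up to relabelling
  expect_equal(sort(table(gs1$assignment[[1]])),
               sort(table(gs2$assignment[[1]])), ignore_attr = TRUE)
  expect_equal(unname(gs2$S[[1]]), unname(gs1$S[[1]][perm, perm]),
               tolerance = 1e-12)
})

test_that("parameter flatten/unflatten is a faithful round trip", {
  ts <- make_tiny_setup()
  v <- braingcn:::.param_flatten(ts$params)
  back <- braingcn:::.param_unflatten(v, ts$params)
  expect_equal(back, ts$params)
  expect_identical(braingcn:::.param_flatten(back), v)
})
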