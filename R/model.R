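#' Network configuration
#'
#' Architecture of the classifier: a shared-weight bidirectional LSTM over
#' each channel's band-feature sequence (node encoder), then one graph
#' convolution + bounded-ReLU + 50% pooling block per entry of
#' `gcn_channels`, then dropout, a dense layer and softmax.
#'
#' @param bilstm_hidden Hidden units per LSTM direction (node feature
#'   dimension is `2 * bilstm_hidden`).
#' @param gcn_channels Output width of each GCN layer; its length sets the
#'   number of GCN/pooling levels.
#' @param brelu_cap Upper bound of the bounded ReLU.
#' @param dropout Dropout rate applied before the dense head (training
#'   only).
#' @param n_classes Number of output classes (2: control vs. depressed).
#' @param l2_lambda L2 penalty coefficient on all weights and biases.
#' @param pool_reducer `"max"` or `"mean"` aggregation within pooled node
#'   groups.
#' @return A `model_config` list.
#' @export
model_config <- function(bilstm_hidden = 16, gcn_channels = c(32, 64),
                         brelu_cap = 6, dropout = 0.5, n_classes = 2,
                         l2_lambda = 1e-4, pool_reducer = c("max", "mean")) {
  stopifnot(bilstm_hidden >= 1, length(gcn_channels) >= 1,
            all(gcn_channels >= 1), brelu_cap > 0,
            dropout >= 0, dropout < 1, l2_lambda >= 0)
  structure(list(bilstm_hidden = as.integer(bilstm_hidden),
                 gcn_channels = as.integer(gcn_channels),
                 brelu_cap = brelu_cap, dropout = dropout,
                 n_classes = as.integer(n_classes),
                 l2_lambda = l2_lambda,
                 pool_reducer = match.arg(pool_reducer)),
            class = "model_config")
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.lstm_dir_init <- function(d, h) {
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1          # forget-gate bias at 1 (standard)
  list(Wx = .glorot(d, 4 * h), Wh = .glorot(h, 4 * h), b = b)
}

#' Initialise model parameters
#'
#' Glorot-uniform weights (forget-gate biases at 1, other biases 0), drawn
#' from the current R RNG; call `set.seed()` first (or use the training
#' functions, which do) for reproducibility.
#'
#' @param config A [model_config()].
#' @param n_nodes Channel count of the input graph.
#' @param n_bands Band count d of the feature tensor.
#' @return A `model_params` nested list (`lstm$fwd/bwd`, `gcn`, `dense`).
#' @export
init_model_params <- function(config, n_nodes, n_bands) {
  h <- config$bilstm_hidden
  widths <- c(2L * h, config$gcn_channels)
  gcn <- lapply(seq_along(config$gcn_channels), function(l)
    list(W = .glorot(widths[l], widths[l + 1]),
         b = numeric(widths[l + 1])))
  n_final <- n_nodes
  for (l in seq_along(config$gcn_channels)) n_final <- ceiling(n_final / 2)
  flat_dim <- n_final * utils::tail(widths, 1)
  structure(list(lstm = list(fwd = .lstm_dir_init(n_bands, h),
                             bwd = .lstm_dir_init(n_bands, h)),
                 gcn = gcn,
                 dense = list(W = .glorot(flat_dim, config$n_classes),
                              b = numeric(config$n_classes))),
            class = "model_params")
}

#' Bounded rectified linear unit
#'
#' `min(max(x, 0), cap)`, elementwise.
#'
#' @param x Numeric vector/matrix.
#' @param cap Positive saturation bound.
#' @return Same shape as `x`.
#' @export
brelu <- function(x, cap = 6) {
  stopifnot(cap > 0)
  pmin(pmax(x, 0), cap)
}

#' Encode a feature tensor into graph node features with the BiLSTM
#'
#' One shared-weight LSTM pair runs over every channel's length-t,
#' d-dimensional band sequence, forward and backward; each channel's node
#' feature is the concatenation of the two final hidden states.
#'
#' @param tensor A `feature_tensor` (channels x t x bands), normalised.
#' @param params `model_params` (only the `lstm` component is used).
#' @return Node-feature matrix (channels x `2 * hidden`).
#' @export
bilstm_encode <- function(tensor, params) {
  if (anyNA(tensor) || any(!is.finite(tensor)))
    stop("feature tensor contains NaN/Inf; refuse to run the recurrence")
  arr <- array(tensor, dim = c(dim(tensor), 1L))
  xs <- .step_inputs(arr)
  fwd <- .lstm_dir_forward(xs, params$lstm$fwd)
  bwd <- .lstm_dir_forward(rev(xs), params$lstm$bwd)
  cbind(fwd$h, bwd$h)
}

#' One graph convolution layer
#'
#' Computes `activation(S %*% H %*% W + b)`: symmetric-normalised
#' neighbourhood aggregation followed by a trainable linear map.
#'
#' @param H Node features (n x d_in).
#' @param S Propagation matrix (n x n), see [propagation_matrix()].
#' @param W Weight matrix (d_in x d_out).
#' @param activation Elementwise activation (default identity).
#' @param b Optional bias vector (length d_out).
#' @return Node features (n x d_out).
#' @export
gcn_layer <- function(H, S, W, activation = identity, b = NULL) {
  if (ncol(S) != nrow(H) || ncol(H) != nrow(W))
    stop("dimension mismatch: S ", nrow(S), "x", ncol(S),
         ", H ", nrow(H), "x", ncol(H), ", W ", nrow(W), "x", ncol(W))
  Z <- S %*% H %*% W
  if (!is.null(b)) Z <- Z + rep(b, each = nrow(Z))
  activation(Z)
}

#' Pool node features over one coarsening level
#'
#' Each coarse node's feature is the elementwise `max` (default) or `mean`
#' of its group's rows, halving the node count.
#'
#' @param H Node features (n x d).
#' @param level A `pooling_level` (or bare assignment vector).
#' @param reducer `"max"` or `"mean"`.
#' @return Coarse node features (`ceiling(n/2)` x d).
#' @export
spectral_pool <- function(H, level, reducer = c("max", "mean")) {
  reducer <- match.arg(reducer)
  asg <- if (inherits(level, "pooling_level")) level$assignment else level
  if (length(asg) != nrow(H))
    stop("assignment covers ", length(asg), " nodes but H has ",
         nrow(H), " rows")
  m <- max(asg)
  out <- matrix(0, m, ncol(H))
  for (g in seq_len(m)) {
    rows <- which(asg == g)
    out[g, ] <- if (reducer == "max") {
      Reduce(pmax, lapply(rows, function(r) H[r, ]))
    } else {
      colMeans(H[rows, , drop = FALSE])
    }
  }
  out
}

#' Full forward pass: class probabilities for feature tensors
#'
#' Pipeline: BiLSTM node encoding, then per level
#' (graph convolution, bounded ReLU, 50% pooling), then dropout (training
#' mode only), flatten, dense layer, softmax.
#'
#' @param tensors A `feature_tensor` or list of them (all same shape).
#' @param gstack A [graph_stack()] matching the channel count.
#' @param params `model_params`.
#' @param config `model_config`.
#' @param training Logical; enables dropout (stochastic, uses the R RNG).
#' @return Matrix (segments x classes) of probabilities, rows summing
#'   to 1; columns `control`, `depressed`.
#' @export
model_forward <- function(tensors, gstack, params, config,
                          training = FALSE) {
  arr <- .stack_tensors(tensors)
  fc <- .net_forward(arr, params, gstack, config, training = training)
  probs <- fc$probs
  colnames(probs) <- c("control", "depressed")[seq_len(ncol(probs))]
  probs
}

#' Cross-entropy loss with L2 penalty
#'
#' Mean over segments of `-sum_c y_c log p_c` (probabilities clamped at
#' 1e-12 to guard `log(0)`), plus `lambda` times the sum of squares of all
#' trainable weights and biases.
#'
#' @param probs Probability matrix (segments x classes).
#' @param labels Integer vector of class labels (0/1) or one-hot matrix.
#' @param params Optional `model_params` contributing the L2 term.
#' @param lambda L2 coefficient (>= 0).
#' @return Scalar loss (>= 0).
#' @export
model_loss <- function(probs, labels, params = NULL, lambda = 0) {
  stopifnot(lambda >= 0)
  y <- .one_hot(labels, ncol(probs))
  ce <- -mean(rowSums(y * log(pmax(probs, 1e-12))))
  l2 <- if (!is.null(params) && lambda > 0)
    lambda * sum(.param_flatten(params)^2) else 0
  ce + l2
}

.one_hot <- function(labels, k) {
  if (is.matrix(labels)) return(labels)
  y <- matrix(0, length(labels), k)
  y[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  y
}
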