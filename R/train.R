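#' Training configuration
#'
#' Defaults mirror the full-data regime (Adam, 100 epochs, batch 512,
#' learning rate 1e-5); [train_preset()] provides a scaled-down
#' configuration for small synthetic studies.
#'
#' @param optimizer Currently `"adam"`.
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size (clamped to the dataset size with a
#'   warning when larger).
#' @param learning_rate Adam step size.
#' @param k_folds Cross-validation fold count.
#' @param inner_train_frac Fraction of training subjects used for weight
#'   updates; the rest monitor per-epoch accuracy and select the best
#'   checkpoint.
#' @param class_weights If `TRUE`, cross-entropy terms are weighted by
#'   inverse class frequency of the training set, removing the
#'   majority-class prior; off by default.
#' @param seed Integer seed driving initialisation, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = "adam", epochs = 100, batch_size = 512,
                         learning_rate = 1e-5, k_folds = 10,
                         inner_train_frac = 0.9, class_weights = FALSE,
                         seed = 1L) {
  stopifnot(optimizer == "adam", epochs >= 1, batch_size >= 1,
            learning_rate > 0, k_folds >= 2,
            inner_train_frac > 0, inner_train_frac <= 1,
            is.logical(class_weights))
  structure(list(optimizer = optimizer, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 k_folds = as.integer(k_folds),
                 inner_train_frac = inner_train_frac,
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Scaled-down training preset for small synthetic studies
#'
#' 20 epochs, batch 64, Adam learning rate 1e-3: a budget suited to
#' hundreds (not thousands) of segments. Balanced class weights are on:
#' with cohorts of ~20 subjects, leave-subjects-out folds make the
#' training class prior swing fold to fold, and an unweighted fit on
#' weakly informative data drifts to the training majority class, biasing
#' the held-out estimate downward; inverse-frequency weighting removes
#' that prior term so chance-level data scores at chance.
#'
#' @param ... Overrides passed to [train_config()].
#' @export
train_preset <- function(...) {
  args <- utils::modifyList(
    list(epochs = 20, batch_size = 64, learning_rate = 1e-3,
         class_weights = TRUE), list(...))
  do.call(train_config, args)
}

.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}

# Run RNG-dependent code under a seed without disturbing the caller's RNG.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Train the classifier on feature tensors
#'
#' Minimises the regularised cross-entropy with minibatch Adam for a fixed
#' epoch budget. When a monitor set is supplied, per-epoch accuracy on it
#' is recorded and the best-monitor checkpoint is returned; otherwise the
#' final parameters are.
#'
#' @param tensors List of normalised `feature_tensor`s (training set).
#' @param labels Integer labels (0/1), one per tensor.
#' @param gstack A [graph_stack()] built from training-subject data.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param monitor Optional list(tensors, labels) for per-epoch monitoring.
#' @return List with `params`, `history` (data.frame of epoch, train loss,
#'   monitor accuracy) and `best_epoch`.
#' @export
train_model <- function(tensors, labels, gstack, model_cfg,
                        train_cfg = train_config(), monitor = NULL) {
  stopifnot(length(tensors) >= 1L, length(labels) == length(tensors))
  n_seg <- length(tensors)
  bs <- train_cfg$batch_size
  if (bs > n_seg) {
    warning("batch_size ", bs, " exceeds dataset size ", n_seg,
            "; clamping")
    bs <- n_seg
  }
  arr_all <- .stack_tensors(tensors)
  n_nodes <- dim(arr_all)[1]
  if (gstack$n_nodes != n_nodes)
    stop("graph has ", gstack$n_nodes, " nodes but tensors have ",
         n_nodes, " channels")
  mon_arr <- if (!is.null(monitor)) .stack_tensors(monitor$tensors)
  lam <- model_cfg$l2_lambda
  sample_w <- if (isTRUE(train_cfg$class_weights)) {
    tab <- tabulate(as.integer(labels) + 1L, nbins = 2L)
    (n_seg / (2 * tab))[as.integer(labels) + 1L]
  }
  .with_seed(train_cfg$seed, {
    params <- init_model_params(model_cfg, n_nodes, dim(arr_all)[3])
    theta <- .param_flatten(params)
    opt <- .adam_init(length(theta))
    hist <- data.frame(epoch = seq_len(train_cfg$epochs),
                       train_loss = NA_real_, monitor_acc = NA_real_)
    best <- list(acc = -Inf, theta = theta, epoch = 0L)
    for (ep in seq_len(train_cfg$epochs)) {
      idx <- sample.int(n_seg)
      ep_loss <- 0; n_b <- 0L
      for (start in seq(1L, n_seg, by = bs)) {
        bidx <- idx[start:min(start + bs - 1L, n_seg)]
        lg <- .net_loss_grad(arr_all[, , , bidx, drop = FALSE],
                             labels[bidx], params, gstack, model_cfg,
                             lam, training = TRUE,
                             sample_w = sample_w[bidx])
        if (!is.finite(lg$loss))
          stop("non-finite loss at epoch ", ep, ", batch ", n_b + 1L,
               "; try a smaller learning rate")
        st <- .adam_step(opt, theta, .param_flatten(lg$grad),
                         train_cfg$learning_rate)
        opt <- st$state
        theta <- st$theta
        params <- .param_unflatten(theta, params)
        ep_loss <- ep_loss + lg$loss; n_b <- n_b + 1L
      }
      hist$train_loss[ep] <- ep_loss / n_b
      if (!is.null(monitor)) {
        pr <- .net_forward(mon_arr, params, gstack, model_cfg)$probs
        acc <- mean((pr[, 2] > pr[, 1]) == (monitor$labels == 1L))
        hist$monitor_acc[ep] <- acc
        if (acc > best$acc) best <- list(acc = acc, theta = theta, epoch = ep)
      }
    }
    final <- if (!is.null(monitor)) .param_unflatten(best$theta, params)
             else params
    list(params = final, history = hist,
         best_epoch = if (!is.null(monitor)) best$epoch
                      else train_cfg$epochs)
  })
}

#' Confusion-matrix metrics
#'
#' @param tp,fp,tn,fn Non-negative integer counts; positive class is
#'   "depressed" (label 1).
#' @return A `fold_metrics` list with the counts, `accuracy`, `precision`,
#'   `sensitivity`, `specificity` and `f1` (ratios with empty denominators
#'   are `NaN`).
#' @export
fold_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  prec <- tp / (tp + fp)
  sens <- tp / (tp + fn)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / (tp + fp + tn + fn),
                 precision = prec,
                 sensitivity = sens,
                 specificity = tn / (tn + fp),
                 f1 = 2 * prec * sens / (prec + sens)),
            class = "fold_metrics")
}

#' @export
print.fold_metrics <- function(x, ...) {
  cat(sprintf(
    "<fold_metrics> acc %.3f | prec %.3f | sens %.3f | spec %.3f | f1 %.3f (TP %d FP %d TN %d FN %d)\n",
    x$accuracy, x$precision, x$sensitivity, x$specificity, x$f1,
    x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Evaluate trained parameters on a labelled segment set
#'
#' Predicts argmax class per segment and tallies the confusion matrix
#' (rows = true class, columns = predicted class).
#'
#' @param params `model_params`.
#' @param tensors List of normalised `feature_tensor`s.
#' @param labels Integer labels (0/1).
#' @param gstack Matching [graph_stack()].
#' @param model_cfg [model_config()].
#' @return List with `metrics` ([fold_metrics()]) and `confusion`
#'   (2x2 matrix).
#' @export
evaluate_model <- function(params, tensors, labels, gstack, model_cfg) {
  if (length(tensors) == 0L) stop("empty evaluation set")
  probs <- model_forward(tensors, gstack, params, model_cfg)
  pred <- as.integer(probs[, 2] > probs[, 1])
  truth <- as.integer(labels)
  conf <- matrix(0L, 2, 2,
                 dimnames = list(true = c("control", "depressed"),
                                 predicted = c("control", "depressed")))
  for (i in seq_along(pred))
    conf[truth[i] + 1L, pred[i] + 1L] <- conf[truth[i] + 1L, pred[i] + 1L] + 1L
  list(metrics = fold_metrics(tp = conf[2, 2], fp = conf[1, 2],
                              tn = conf[1, 1], fn = conf[2, 1]),
       confusion = conf)
}

#' Subject-wise k-fold partition
#'
#' Shuffles the subjects under `seed` and splits them into k near-equal
#' validation groups, so no subject ever contributes segments to both the
#' training and the validation side of a fold.
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return List of k lists, each with `train` and `val` subject-id
#'   vectors.
#' @export
subjectwise_kfold <- function(subject_ids, k = 10, seed = 1L) {
  subjects <- unique(as.character(subject_ids))
  n <- length(subjects)
  if (n < k) stop("only ", n, " subjects for ", k, " folds")
  shuffled <- .with_seed(seed, sample(subjects))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(k), function(f) {
    val <- shuffled[starts[f]:ends[f]]
    list(train = setdiff(subjects, val), val = val)
  })
}

#' Assemble a labelled dataset from raw recordings
#'
#' Runs the preprocessing chain on each recording and computes one feature
#' tensor per segment. The preprocessed continuous recordings are kept so
#' the per-fold brain network can be estimated from training subjects
#' only.
#'
#' @param recordings List of `eeg_recording`s.
#' @param spec [filter_spec()].
#' @param baseline_s Baseline window (s), `NULL` to skip.
#' @param window_s,stride_s Segmentation parameters.
#' @param bands Band list.
#' @param t_subwindows Sub-windows per segment.
#' @param feature_kind `"DE"` or `"PSD"`.
#' @param channels Optional channel subset.
#' @return An `eeg_dataset`: list with `recordings` (preprocessed),
#'   `tensors`, `labels`, `subject_ids` (per segment) and `subjects`
#'   (per-subject table).
#' @export
build_dataset <- function(recordings, spec = filter_spec(),
                          baseline_s = NULL, window_s = 4, stride_s = 2,
                          bands = eeg_bands(), t_subwindows = 4,
                          feature_kind = "DE", channels = NULL) {
  prepped <- lapply(recordings, preprocess_recording, spec = spec,
                    baseline_s = baseline_s, window_s = window_s,
                    stride_s = stride_s, channels = channels)
  recs <- lapply(prepped, `[[`, "recording")
  segs <- unlist(lapply(prepped, `[[`, "segments"), recursive = FALSE)
  tensors <- build_feature_tensors(segs, bands = bands,
                                   t_subwindows = t_subwindows,
                                   feature_kind = feature_kind)
  structure(
    list(recordings = recs,
         tensors = tensors,
         labels = vapply(segs, `[[`, 0L, "label"),
         subject_ids = vapply(segs, `[[`, "", "subject_id"),
         subjects = data.frame(
           subject_id = vapply(recs, `[[`, "", "subject_id"),
           label = vapply(recs, `[[`, 0L, "label"))),
    class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d subjects (%d depressed), %d segments\n",
              nrow(x$subjects), sum(x$subjects$label == 1L),
              length(x$tensors)))
  invisible(x)
}

#' Subject-wise cross-validation of the full pipeline
#'
#' For each fold: the brain network (adjacency, propagation matrices,
#' pooling hierarchy) is estimated from the concatenated preprocessed
#' recordings of the training subjects only; z-score statistics are fitted
#' on training segments only; an inner subject-wise split of the training
#' subjects monitors per-epoch accuracy and selects the checkpoint; the
#' held-out subjects' segments are then scored. All randomness derives
#' from `train_cfg$seed` (fold f uses `seed + f`), so a rerun with the
#' same seed reproduces the metrics exactly.
#'
#' @param dataset An `eeg_dataset` from [build_dataset()].
#' @param model_cfg [model_config()].
#' @param train_cfg [train_config()]; its `k_folds` and `seed` drive the
#'   partition.
#' @param signed_policy Edge-sign policy for the propagation matrix.
#' @param verbose Print one line per fold.
#' @return A `cv_result`: list with `folds` (per-fold [fold_metrics()]),
#'   `summary` (mean/sd data.frame), `confusion` (pooled counts) and the
#'   fold partition.
#' @export
cross_validate <- function(dataset, model_cfg = model_config(),
                           train_cfg = train_config(),
                           signed_policy = "abs", verbose = FALSE) {
  k <- train_cfg$k_folds
  folds <- subjectwise_kfold(dataset$subjects$subject_id, k,
                             train_cfg$seed)
  levels <- length(model_cfg$gcn_channels)
  rec_by_id <- stats::setNames(dataset$recordings,
                               dataset$subjects$subject_id)
  fold_out <- vector("list", k)
  pooled <- matrix(0L, 2, 2)
  for (f in seq_len(k)) {
    fd <- folds[[f]]
    # leakage-free fold fits: graph + normaliser from training subjects
    train_mat <- do.call(cbind,
                         lapply(rec_by_id[fd$train], function(r) r$data))
    g <- adjacency_from_data(train_mat,
                             rec_by_id[[fd$train[1]]]$channel_names)
    gstack <- graph_stack(g, levels, signed_policy)
    tr_idx <- which(dataset$subject_ids %in% fd$train)
    stats_ <- fit_normalizer(dataset$tensors[tr_idx])
    norm_all <- lapply(dataset$tensors, apply_normalizer, stats = stats_)
    # inner subject-wise split of the training subjects for monitoring,
    # stratified by class so the monitor set sees both classes
    lab_by_id <- stats::setNames(dataset$subjects$label,
                                 dataset$subjects$subject_id)
    inner_train <- .with_seed(train_cfg$seed + 1000L + f, {
      unlist(lapply(split(fd$train, lab_by_id[fd$train]), function(grp) {
        cap <- if (train_cfg$inner_train_frac < 1 && length(grp) > 1L)
          length(grp) - 1L else length(grp)
        n_keep <- max(1L, min(cap, round(train_cfg$inner_train_frac *
                                           length(grp))))
        if (length(grp) == 1L) grp else sample(grp, n_keep)
      }), use.names = FALSE)
    })
    inner_val <- setdiff(fd$train, inner_train)
    it_idx <- which(dataset$subject_ids %in% inner_train)
    iv_idx <- which(dataset$subject_ids %in% inner_val)
    monitor <- if (length(iv_idx) > 0L)
      list(tensors = norm_all[iv_idx], labels = dataset$labels[iv_idx])
    fold_cfg <- train_cfg
    fold_cfg$seed <- train_cfg$seed + f
    fit <- train_model(norm_all[it_idx], dataset$labels[it_idx], gstack,
                       model_cfg, fold_cfg, monitor = monitor)
    va_idx <- which(dataset$subject_ids %in% fd$val)
    ev <- evaluate_model(fit$params, norm_all[va_idx],
                         dataset$labels[va_idx], gstack, model_cfg)
    fold_out[[f]] <- ev$metrics
    pooled <- pooled + ev$confusion
    if (verbose)
      message(sprintf("fold %2d/%d: %d val segments, accuracy %.3f",
                      f, k, length(va_idx), ev$metrics$accuracy))
  }
  metric_names <- c("accuracy", "precision", "sensitivity", "specificity",
                    "f1")
  tab <- sapply(metric_names,
                function(m) vapply(fold_out, `[[`, 0, m))
  summary <- data.frame(
    metric = metric_names,
    mean = colMeans(tab, na.rm = TRUE),
    sd = apply(tab, 2, stats::sd, na.rm = TRUE),
    row.names = NULL)
  structure(list(folds = fold_out, summary = summary, confusion = pooled,
                 partition = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds\n", length(x$folds)))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
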