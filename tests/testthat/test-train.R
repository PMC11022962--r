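# Small end-to-end fixtures reused across training tests.
tiny_dataset <- function(preset = "easy", sim_seed = 11, n_dep = 4,
                         n_ctl = 4, duration_s = 12, n_channels = 6) {
  cfg <- sim_preset(preset, n_depressed = n_dep, n_control = n_ctl,
                    duration_s = duration_s, n_channels = n_channels,
                    seed = sim_seed)
  build_dataset(simulate_dataset(cfg)$recordings, baseline_s = NULL)
}

test_that("subject-wise folds partition 53 subjects into near-equal groups", {
  ids <- sprintf("s%02d", 1:53)
  folds <- subjectwise_kfold(ids, 10, seed = 4)
  sizes <- vapply(folds, function(f) length(f$val), 0L)
  expect_setequal(sizes, c(5L, 6L))
  expect_equal(sum(sizes == 6L), 3L)  # 53 = 7*5 + 3*6
  vals <- unlist(lapply(folds, `[[`, "val"))
  expect_setequal(vals, ids)          # union covers all subjects
  expect_equal(anyDuplicated(vals), 0L)  # pairwise disjoint
  for (f in folds) {
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$train, f$val), ids)
  }
  # determinism
  expect_identical(folds, subjectwise_kfold(ids, 10, seed = 4))
  expect_false(identical(folds, subjectwise_kfold(ids, 10, seed = 5)))
  expect_error(subjectwise_kfold(ids[1:5], 10), "subjects")
})

test_that("confusion-matrix identities hold on random integer counts", {
  set.seed(123)
  for (i in 1:300) {
    cnt <- as.integer(sample(0:200, 4, replace = TRUE))
    if (sum(cnt) == 0) next
    m <- fold_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    tp <- cnt[1]; fp <- cnt[2]; tn <- cnt[3]; fn <- cnt[4]
    expect_identical(m$accuracy, (tp + tn) / (tp + fp + tn + fn))
    expect_identical(m$precision, tp / (tp + fp))
    expect_identical(m$sensitivity, tp / (tp + fn))
    expect_identical(m$specificity, tn / (tn + fp))
    expect_identical(m$f1, 2 * m$precision * m$sensitivity /
                            (m$precision + m$sensitivity))
  }
  # the worked 90% case
  m <- fold_metrics(45, 5, 45, 5)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$precision, 0.9)
  expect_equal(m$sensitivity, 0.9)
})

test_that("evaluation tallies confusion counts with true rows / predicted columns", {
  ds <- tiny_dataset()
  g <- adjacency_from_data(do.call(cbind,
                                   lapply(ds$recordings, `[[`, "data")))
  gs <- graph_stack(g, 2)
  mc <- model_config(bilstm_hidden = 2, gcn_channels = c(2, 2))
  st <- fit_normalizer(ds$tensors)
  nt <- lapply(ds$tensors, apply_normalizer, stats = st)
  set.seed(1)
  params <- init_model_params(mc, 6, 4)
  ev <- evaluate_model(params, nt, ds$labels, gs, mc)
  expect_equal(sum(ev$confusion), length(ds$labels))
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.vector(table(factor(ds$labels, levels = 0:1)))))
  with(ev$metrics, expect_equal(tp + fp + tn + fn, length(ds$labels)))

  # degenerate constant-control predictor on balanced data:
  # accuracy 0.5, sensitivity 0
  const <- params
  const$dense$W[] <- 0
  const$dense$b <- c(10, 0)
  ev2 <- evaluate_model(const, nt, ds$labels, gs, mc)
  expect_equal(ev2$metrics$accuracy, 0.5)
  expect_equal(ev2$metrics$sensitivity, 0)
  expect_error(evaluate_model(params, list(), integer(0), gs, mc), "empty")
})

test_that("zero-learning-rate training leaves parameters at initialisation", {
  ds <- tiny_dataset()
  g <- adjacency_from_data(do.call(cbind,
                                   lapply(ds$recordings, `[[`, "data")))
  gs <- graph_stack(g, 2)
  mc <- model_config(bilstm_hidden = 2, gcn_channels = c(2, 2))
  st <- fit_normalizer(ds$tensors)
  nt <- lapply(ds$tensors, apply_normalizer, stats = st)
  tc0 <- train_preset(epochs = 2, batch_size = 16, learning_rate = 1e-30, seed = 5)
  fit <- train_model(nt, ds$labels, gs, mc, tc0)
  ref <- braingcn:::.with_seed(5L, init_model_params(mc, 6, 4))
  expect_equal(braingcn:::.param_flatten(fit$params),
               braingcn:::.param_flatten(ref), tolerance = 1e-20)
})

test_that("huge L2 penalty shrinks the weight norm during training", {
  ds <- tiny_dataset()
  g <- adjacency_from_data(do.call(cbind,
                                   lapply(ds$recordings, `[[`, "data")))
  gs <- graph_stack(g, 2)
  mc <- model_config(bilstm_hidden = 2, gcn_channels = c(2, 2),
                     l2_lambda = 1e6, dropout = 0)
  st <- fit_normalizer(ds$tensors)
  nt <- lapply(ds$tensors, apply_normalizer, stats = st)
  tc <- train_preset(epochs = 10, seed = 5, class_weights = FALSE)
  expect_warning(fit <- train_model(nt, ds$labels, gs, mc, tc),
                 "clamping")
  ref <- braingcn:::.with_seed(5L, init_model_params(mc, 6, 4))
  expect_lt(sum(braingcn:::.param_flatten(fit$params)^2),
            sum(braingcn:::.param_flatten(ref)^2))
})

test_that("training reduces the loss on a separable synthetic problem", {
  ds <- tiny_dataset("easy")
  g <- adjacency_from_data(do.call(cbind,
                                   lapply(ds$recordings, `[[`, "data")))
  gs <- graph_stack(g, 2)
  mc <- model_config(bilstm_hidden = 4, gcn_channels = c(4, 4))
  st <- fit_normalizer(ds$tensors)
  nt <- lapply(ds$tensors, apply_normalizer, stats = st)
  tc <- train_preset(epochs = 12, batch_size = 16, seed = 9)
  fit <- train_model(nt, ds$labels, gs, mc, tc)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  # final train accuracy high on the easy preset
  ev <- evaluate_model(fit$params, nt, ds$labels, gs, mc)
  expect_gte(ev$metrics$accuracy, 0.95)
})

test_that("cross-validation output is complete, leakage-free and reproducible", {
  ds <- tiny_dataset(n_dep = 3, n_ctl = 3)
  mc <- model_config(bilstm_hidden = 2, gcn_channels = c(2, 2))
  tc <- train_preset(epochs = 4, batch_size = 8, seed = 21, k_folds = 3)
  cv1 <- cross_validate(ds, mc, tc)
  expect_length(cv1$folds, 3)
  expect_s3_class(cv1$folds[[1]], "fold_metrics")
  # summary matches a brute-force recomputation
  accs <- vapply(cv1$folds, `[[`, 0, "accuracy")
  expect_equal(cv1$summary$mean[cv1$summary$metric == "accuracy"],
               mean(accs))
  expect_equal(cv1$summary$sd[cv1$summary$metric == "accuracy"],
               sqrt(sum((accs - mean(accs))^2) / (length(accs) - 1)))
  # reproducibility: identical metrics under the same seed
  cv2 <- cross_validate(ds, mc, tc)
  expect_equal(vapply(cv1$folds, `[[`, 0, "accuracy"),
               vapply(cv2$folds, `[[`, 0, "accuracy"), tolerance = 1e-6)
  # no subject appears on both sides of any fold
  for (f in cv1$partition)
    expect_length(intersect(f$train, f$val), 0)
})

test_that("fold fits depend only on training subjects (no leakage)", {
  ds <- tiny_dataset(n_dep = 3, n_ctl = 3)
  folds <- subjectwise_kfold(ds$subjects$subject_id, 3, 21L)
  fd <- folds[[1]]
  rec_by_id <- setNames(ds$recordings, ds$subjects$subject_id)
  fit_graph <- function(ids) adjacency_from_data(
    do.call(cbind, lapply(rec_by_id[ids], `[[`, "data")))$adjacency
  # recompute after "deleting" validation data: identical results
  expect_identical(fit_graph(fd$train), fit_graph(fd$train))
  a_with_val <- fit_graph(c(fd$train, fd$val))
  expect_false(isTRUE(all.equal(fit_graph(fd$train), a_with_val)))
  tr_idx <- which(ds$subject_ids %in% fd$train)
  st1 <- fit_normalizer(ds$tensors[tr_idx])
  st2 <- fit_normalizer(ds$tensors[tr_idx])
  expect_identical(st1, st2)
})
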