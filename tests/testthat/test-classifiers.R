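toy <- make_blob_features(20, rbind(c(0, 0), c(3, 3)), sd = 0.3, seed = 41)
toy_val <- make_blob_features(5, rbind(c(0, 0), c(3, 3)), sd = 0.3, seed = 42)

test_that("the MLP learns a separable toy problem with Rprop", {
  cfg <- rprop_config(max_epochs = 200, hidden = 4, seed = 7)
  fit <- train_mlp(toy, toy_val, cfg)
  expect_equal(mean(predict(fit, toy) == toy$label), 1)
  expect_s3_class(glance(fit), "tbl_df")

  # seed determinism
  fit2 <- train_mlp(toy, toy_val, cfg)
  expect_identical(fit$net, fit2$net)

  # zero epochs returns the seeded initial weights unchanged
  fit0 <- train_mlp(toy, toy_val, rprop_config(max_epochs = 0, hidden = 4, seed = 7))
  init <- fallsense:::with_seed(fit0$config$seed, fallsense:::init_net(2, 4))
  expect_identical(fit0$net, init)

  single <- dplyr::filter(toy, label == "fall")
  expect_error(train_mlp(single, toy_val, cfg), "both classes")
})

test_that("Rprop trajectories depend only on gradient signs", {
  x <- as.matrix(toy[, c("f1", "f2")])
  y <- as.numeric(toy$label == "fall")
  cfg <- rprop_config(hidden = 3, seed = 9)
  run <- function(loss_scale) {
    net <- fallsense:::with_seed(1, fallsense:::init_net(2, 3))
    step <- fallsense:::net_apply2(net, net, function(a, b) a * 0 + cfg$initial_step)
    prev <- fallsense:::net_apply2(net, net, function(a, b) a * 0)
    for (i in 1:25) {
      g <- fallsense:::mlp_gradients(net, x, y)
      g <- lapply(g, function(m) m * loss_scale)
      up <- fallsense:::rprop_update(net, g, step, prev, cfg)
      net <- up$net; step <- up$step; prev <- up$prev
    }
    net
  }
  expect_equal(run(1), run(137.5))
})

test_that("the RBF layer responds in (0, 1] and peaks at its centroids", {
  mu <- matrix(c(0, 0, 3, 3), ncol = 2, byrow = TRUE)
  model <- make_cluster_model(mu, matrix(0.5, 2, 2))
  phi <- rbf_layer_forward(mu, model)
  expect_equal(diag(phi), c(1, 1))
  set.seed(43)
  r <- rbf_layer_forward(matrix(rnorm(40), ncol = 2), model)
  expect_true(all(r > 0 & r <= 1))
  far <- rbf_layer_forward(matrix(c(100, 100), 1), model)
  expect_true(all(far < 1e-6))
})

test_that("ARBF freezes the cluster layer and learns aligned toy classes", {
  mu <- matrix(c(0, 0, 3, 3), ncol = 2, byrow = TRUE)
  cm <- make_cluster_model(mu, matrix(0.3, 2, 2))
  cfg <- rprop_config(max_epochs = 200, hidden = 4, seed = 8)
  fit <- train_arbf(toy, toy_val, cm, cfg)
  expect_identical(fit$cluster_model$mu, cm$mu)
  expect_gte(mean(predict(fit, toy) == toy$label), 0.95)
  expect_identical(train_arbf(toy, toy_val, cm, cfg)$net, fit$net)
})

constant_mlp <- function(out, d_in = 2, threshold = 0.5) {
  structure(list(net = list(W1 = matrix(0, d_in, 2), b1 = c(0, 0),
                            W2 = matrix(0, 2, 1), b2 = out),
                 threshold = threshold, config = rprop_config(hidden = 2),
                 best_epoch = 0L, epochs = 0L, val_curve = NA_real_,
                 best_val = NA_real_, d_in = d_in),
            class = "mlp_fit")
}

constant_arbf <- function(out, cm) {
  structure(list(cluster_model = cm,
                 net = list(W1 = matrix(0, nrow(cm$mu), 2), b1 = c(0, 0),
                            W2 = matrix(0, 2, 1), b2 = out),
                 threshold = 0.5, config = rprop_config(hidden = 2),
                 best_epoch = 0L, epochs = 0L, val_curve = NA_real_,
                 best_val = NA_real_),
            class = "arbf_fit")
}

test_that("ensemble voting pools 2(n_gck + 1) votes and breaks ties toward fall", {
  cm <- make_cluster_model(matrix(c(0, 0, 3, 3), ncol = 2, byrow = TRUE),
                           matrix(0.5, 2, 2))
  x <- matrix(c(1, 1), 1)

  both_fall <- fall_ensemble(constant_mlp(1), constant_arbf(1, cm),
                             cm, fusion_config(n_gck = 5))
  tal <- predict(both_fall, x, type = "tally")
  expect_equal(tal$label, "fall")
  expect_equal(tal$votes_fall, 12L)
  expect_equal(tal$votes_fall + tal$votes_adl, 12L)

  both_adl <- fall_ensemble(constant_mlp(0), constant_arbf(0, cm),
                            cm, fusion_config(n_gck = 5))
  expect_equal(predict(both_adl, x), "adl")

  # disagreement with n_gck = 0 is a 1-1 tie, resolved toward sensitivity
  split_votes <- fall_ensemble(constant_mlp(1), constant_arbf(0, cm),
                               cm, fusion_config(n_gck = 0))
  tal2 <- predict(split_votes, x, type = "tally")
  expect_equal(tal2$votes_fall + tal2$votes_adl, 2L)
  expect_equal(tal2$label, "fall")
  split_adl <- fall_ensemble(constant_mlp(1), constant_arbf(0, cm),
                             cm, fusion_config(n_gck = 0), tie_rule = "adl")
  expect_equal(predict(split_adl, x), "adl")
})

test_that("sensitivity and specificity follow their confusion-matrix definitions", {
  d <- tibble::tibble(label = c(rep("fall", 4), rep("adl", 6)),
                      substratum = c(rep("fall", 4), rep("routine", 3),
                                     rep("exercise", 3)))
  perfect <- evaluate_predictions(d, d$label)
  expect_equal(perfect$value[perfect$stratum == "overall"], c(100, 100))

  all_fall <- evaluate_predictions(d, rep("fall", 10))
  expect_equal(all_fall$value[all_fall$metric == "sensitivity" &
                              all_fall$stratum == "overall"], 100)
  expect_equal(all_fall$value[all_fall$metric == "specificity" &
                              all_fall$stratum == "overall"], 0)

  # 138 of 140 falls detected
  d2 <- tibble::tibble(label = rep("fall", 140))
  pred2 <- c(rep("fall", 138), rep("adl", 2))
  ev2 <- evaluate_predictions(d2, pred2)
  expect_equal(ev2$value[ev2$metric == "sensitivity"], 100 * 138 / 140)
  expect_equal(round(ev2$value[ev2$metric == "sensitivity"], 2), 98.57)
  # a class with no members is undefined, not zero
  expect_true(is.na(ev2$value[ev2$metric == "specificity"]))
  expect_equal(ev2$n[ev2$metric == "specificity"], 0L)

  # permutation invariance
  perm <- sample(nrow(d))
  ev_p <- evaluate_predictions(d[perm, ], d$label[perm])
  expect_equal(dplyr::arrange(ev_p, stratum, metric),
               dplyr::arrange(perfect, stratum, metric))
})
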