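small_cfg <- function(...) {
  do.call(agent_config,
          utils::modifyList(list(alpha = 3e-4, epochs = 2L, seed = 7L),
                            list(...)))
}

test_that("training is bit-reproducible under a fixed seed", {
  u <- quick_user(seed = 70L, n_train = 12L, n_test = 6L, T = 600L)
  m1 <- train_user_model(u, agent = small_cfg())
  m2 <- train_user_model(u, agent = small_cfg())
  expect_identical(m1$params$theta, m2$params$theta)
  expect_identical(m1$params$theta_target, m2$params$theta_target)
  expect_identical(m1$log, m2$log)

  # a different seed gives a different run
  m3 <- train_user_model(u, agent = small_cfg(seed = 8L))
  expect_false(identical(m1$params$theta, m3$params$theta))
})

test_that("the reward log has epochs x n_train rows with the three logged curves", {
  u <- quick_user(seed = 71L, n_train = 12L, n_test = 0L, T = 600L)
  m <- train_user_model(u, agent = small_cfg())
  expect_equal(nrow(m$log), 2L * 12L)
  expect_named(m$log, c("episode", "reward", "trailing_mean5", "v0", "epsilon"))
  expect_identical(m$log$episode, seq_len(24L))
  # trailing mean recomputed by brute force
  oracle <- vapply(seq_len(24L), function(i)
    mean(m$log$reward[max(1, i - 4):i]), numeric(1))
  expect_equal(m$log$trailing_mean5, oracle)
  expect_true(all(diff(m$log$epsilon) <= 0))
})

test_that("an untrained agent scores at chance on balanced test data", {
  accs <- vapply(1:3, function(i) {
    u <- quick_user(seed = 72L + i, n_train = 12L, n_test = 12L, T = 600L)
    m <- train_user_model(u, agent = agent_config(epochs = 0L, seed = i))
    evaluate_user(m, u$testing)$classification_accuracy
  }, numeric(1))
  expect_lt(mean(accs), 0.4)   # chance is 1/6 on six balanced classes
  expect_gte(min(accs), 0)
})

test_that("checkpoint save/load round-trips and resume matches an uninterrupted run", {
  u <- quick_user(seed = 73L, n_train = 12L, n_test = 6L, T = 600L)

  full <- train_user_model(u, agent = small_cfg(epochs = 3L))

  part_cfg <- small_cfg(epochs = 1L)
  part <- train_user_model(u, agent = part_cfg)
  ckpt <- tempfile(fileext = ".rds")
  save_checkpoint(part, ckpt)
  restored <- load_checkpoint(ckpt)
  expect_identical(restored$params$theta, part$params$theta)
  expect_identical(restored$log, part$log)

  restored$agent$epochs <- 3L
  resumed <- train_user_model(u, resume = restored)
  expect_equal(resumed$params$theta, full$params$theta, tolerance = 1e-12)
  expect_equal(resumed$log$reward, full$log$reward)
  unlink(ckpt)

  expect_error(load_checkpoint(tempfile()), "does not exist")
  junk <- tempfile(fileext = ".rds")
  saveRDS(list(1), junk)
  expect_error(load_checkpoint(junk), "not an emgq")
  unlink(junk)
})

test_that("the recurrent (LSTM) variant trains, predicts, and resets state per episode", {
  u <- quick_user(seed = 74L, n_train = 12L, n_test = 6L, T = 600L)
  cfg <- agent_config(alpha = 1e-3, epochs = 2L, seed = 9L,
                      variant = "recurrent")
  m <- train_user_model(u, agent = cfg)
  expect_equal(m$params$arch$variant, "recurrent")
  expect_equal(nrow(m$log), 24L)

  p <- predict_sample(m, u$testing[[1]])
  expect_s3_class(p, "emgq_prediction")
  expect_true(p$dominant %in% GESTURES)
  expect_length(p$point_labels, 600L)

  # deterministic under the seed, like the feed-forward variant
  m2 <- train_user_model(u, agent = cfg)
  expect_identical(m$params$theta, m2$params$theta)
})

test_that("model methods expose parameters, predictions and training curves", {
  u <- quick_user(seed = 75L, n_train = 12L, n_test = 6L, T = 600L)
  m <- train_user_model(u, agent = small_cfg())

  th <- coef(m)
  expect_named(th, c("W1", "b1", "W2", "b2", "W3", "b3"))
  expect_equal(dim(th$W1), c(40L, 50L))
  expect_equal(dim(th$W3), c(50L, 6L))
  expect_identical(coef(m, "theta_target"), m$params$theta_target)

  df <- predict(m, u$testing)
  expect_equal(nrow(df), 6L)
  expect_true(all(df$dominant %in% GESTURES))

  one <- predict(m, u$testing[[1]])
  expect_s3_class(one, "emgq_prediction")

  expect_output(print(m), "emgq_model")
  expect_output(summary(m), "episodes")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})

test_that("a trained model beats the untrained baseline on its test split", {
  u <- quick_user(seed = 76L, n_train = 24L, n_test = 12L, T = 600L)
  m0 <- train_user_model(u, agent = agent_config(epochs = 0L, seed = 3L))
  m5 <- train_user_model(u, agent = agent_config(alpha = 3e-4, epochs = 5L,
                                                 seed = 3L))
  a0 <- evaluate_user(m0, u$testing)$classification_accuracy
  a5 <- evaluate_user(m5, u$testing)$classification_accuracy
  expect_gt(a5, a0)
  expect_gte(a5, 0.5)
})
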