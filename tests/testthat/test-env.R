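test_that("window truth labels follow the majority-of-mask rule", {
  # relax recording: every window truth is relax
  set.seed(30)
  rx <- emg_sample(matrix(rnorm(8 * 1000, 0, 0.05), 8, 1000), "relax",
                   sample_id = "rx")
  expect_true(all(make_episode(rx)$truth == "relax"))

  # full-mask recording: every window truth is the gesture
  expect_true(all(make_episode(const_sample(gesture = "open"))$truth == "open"))

  # burst [400, 700): truth flips exactly where in-mask points exceed 150
  s <- burst_sample(400, 700, gesture = "pinch")
  ep <- make_episode(s)
  oracle <- vapply(ep$starts, function(a) {
    inmask <- length(intersect((a + 1L):(a + 300L), 401:700))
    if (inmask > 150) "pinch" else "relax"
  }, character(1))
  expect_identical(ep$truth, oracle)
  expect_true(any(ep$truth == "pinch") && any(ep$truth == "relax"))
})

test_that("per-window rewards are +1 for correct and -1 for wrong actions", {
  ep <- make_episode(const_sample(gesture = "fist"))
  r1 <- env_step(ep, "fist")
  expect_equal(r1$reward, 1)
  expect_false(r1$done)
  expect_equal(r1$obs, ep$obs[2, ])
  r2 <- env_step(r1$episode, "open")
  expect_equal(r2$reward, -1)
  expect_error(env_step(ep, "thumbsUp"), "unknown action")
})

test_that("terminal reward adds the recognition bonus on a fully correct episode", {
  # 980 points: the 18 window spans tile the recording exactly, so the
  # full-mask prediction region equals the mask and rho is exactly 1
  s <- const_sample(T = 980L, gesture = "waveOut")
  ep <- make_episode(s)
  repeat {
    res <- env_step(ep, ep$truth[ep$t])
    if (res$done) break
    ep <- res$episode
  }
  expect_equal(res$reward, 11)   # +1 last window, +10 recognition at rho = 1
  expect_equal(res$rho, 1)
  expect_equal(res$dominant, "waveOut")
  expect_error(env_step(res$episode, "fist"), "finished")
})

test_that("episode cumulative reward stays inside its theoretical bounds", {
  set.seed(31)
  s <- burst_sample(300, 900, gesture = "waveIn")
  for (rep_i in 1:5) {
    ep <- make_episode(s)
    total <- 0
    repeat {
      res <- env_step(ep, sample(GESTURES, 1))
      total <- total + res$reward
      if (res$done) break
      ep <- res$episode
    }
    N <- make_episode(s)$N
    expect_lte(total, N * 1 + 10)
    expect_gte(total, N * -1 - 10)
  }
})

test_that("overlap factor matches set arithmetic and its edge conventions", {
  lab <- function(idx, T, g = "fist") {
    x <- rep("relax", T); x[idx] <- g; x
  }
  expect_equal(overlap_factor(lab(101:200, 400), lab(151:250, 400)), 0.5)
  expect_equal(overlap_factor(lab(1:50, 400), lab(1:50, 400)), 1)
  expect_equal(overlap_factor(lab(1:50, 400), lab(200:250, 400)), 0)
  expect_equal(overlap_factor(rep("relax", 100), rep("relax", 100)), 1)
  expect_equal(overlap_factor(lab(1:10, 100), rep("relax", 100)), 0)
  expect_equal(overlap_factor(rep("relax", 100), lab(1:10, 100)), 0)
  expect_error(overlap_factor(rep("relax", 10), rep("relax", 11)), "length")

  # symmetric when both sides carry a single matching label
  set.seed(32)
  for (i in 1:20) {
    a <- lab(sample(200, 60), 200); b <- lab(sample(200, 60), 200)
    expect_equal(overlap_factor(a, b), overlap_factor(b, a))
  }
})

test_that("an oracle policy recognises full-mask and relax recordings with rho = 1", {
  run_oracle <- function(s) {
    ep <- make_episode(s)
    repeat {
      res <- env_step(ep, ep$truth[ep$t])
      if (res$done) return(res)
      ep <- res$episode
    }
  }
  full <- run_oracle(const_sample(T = 980L, gesture = "pinch"))
  expect_equal(full$rho, 1)
  expect_equal(full$reward, 11)

  set.seed(33)
  rx <- emg_sample(matrix(rnorm(8 * 1000, 0, 0.05), 8, 1000), "relax",
                   sample_id = "rx")
  res <- run_oracle(rx)
  expect_equal(res$rho, 1)        # both label sets empty
  expect_equal(res$dominant, "relax")
  expect_equal(res$reward, 11)

  # partial burst: localisation is window-limited but still above the
  # recognition threshold for a long burst
  pb <- run_oracle(burst_sample(100, 900, gesture = "open"))
  expect_gt(pb$rho, 0.75)
  expect_lt(pb$rho, 1)
})
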