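traj_corpus <- function() {
  build_corpus(list(
    elig = list(users = list(u1 = solo_user(t = c(10, 20, 30),
                                            despair = c(3, NA, 5)))),
    inel = list(users = list(u1 = solo_user(despair = c(4, 4, 4)))),
    act = list(si_label = "active", discloser = "u1",
               users = list(u1 = solo_user(despair = c(9, 9, 9)))),
    deep = list(users = list(u1 = list(t = c(5, 15, 25, 35),
                                       despair = c(7, 2, NA, 6))))))
}

test_that("eligibility uses the max score over the first window messages", {
  el <- eligible_sessions(traj_corpus(), "despair")
  expect_true("elig" %in% el$session_id)     # {3, absent, 5} qualifies
  expect_false("inel" %in% el$session_id)    # {4,4,4} all below threshold
  expect_false("act" %in% el$session_id)     # active SI always excluded
  expect_equal(el$initial_intensity[el$session_id == "elig"], 5)
})

test_that("optimism eligibility thresholds on negative-emotion distress", {
  co <- build_corpus(list(
    S1 = list(users = list(u1 = solo_user(despair = c(6, 5, 4),
                                          optimism = c(2, 2, 3))))))
  el <- eligible_sessions(co, "optimism")
  expect_equal(el$session_id, "S1")  # qualified by despair >= 5, not optimism
  el2 <- eligible_sessions(co, "optimism", threshold_emotions = "optimism")
  expect_equal(nrow(el2), 0)
})

test_that("unknown emotion names are rejected", {
  expect_error(eligible_sessions(traj_corpus(), "anger"))
})

test_that("interpolation is exact on its knots and linear between them", {
  co <- build_corpus(list(
    S1 = list(users = list(u1 = list(t = c(10, 20, 30),
                                     despair = c(9, 3, 6))))))
  cv <- interpolate_trajectory(co, "S1", "u1", "despair", grid_points = 5)
  expect_equal(cv$values, c(9, 6, 3, 4.5, 6))

  two <- build_corpus(list(
    S1 = list(users = list(u1 = solo_user(despair = c(6, NA, 2))))))
  cv2 <- interpolate_trajectory(two, "S1", "u1", "despair", grid_points = 3)
  expect_equal(cv2$values[2], 4)  # midpoint of {6, 2}

  flat <- build_corpus(list(
    S1 = list(users = list(u1 = list(t = 1:4 * 10, despair = c(5, 5, 5, 5))))))
  cvf <- interpolate_trajectory(flat, "S1", "u1", "despair")
  expect_true(all(cvf$values == 5))
})

test_that("interpolation never leaves the knot range and hits every knot", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(2:8, 1)
    sc <- sample(1:10, m, replace = TRUE)
    co <- build_corpus(list(S1 = list(users = list(u1 = list(
      t = seq_len(max(m, 3)) * 10,
      despair = c(sc, rep(NA, max(0, 3 - m))))))))
    grid_points <- (m - 1) * 4 + 1  # grid contains every knot
    cv <- interpolate_trajectory(co, "S1", "u1", "despair", grid_points)
    expect_true(all(cv$values >= min(sc) - 1e-12 & cv$values <= max(sc) + 1e-12))
    knots <- (seq_len(m) - 1) / (m - 1)
    expect_equal(cv$values[match(round(knots, 12), round(cv$grid, 12))], sc)
    if (!is.unsorted(sc)) expect_true(!is.unsorted(cv$values))
  }
})

test_that("visits with fewer than two scored messages are skipped with a reason", {
  co <- build_corpus(list(
    S1 = list(users = list(u1 = solo_user(despair = c(6, NA, NA))))))
  expect_message(out <- interpolate_trajectory(co, "S1", "u1", "despair"),
                 "fewer than 2")
  expect_null(out)
})

test_that("aggregation averages pointwise and is permutation invariant", {
  mk <- function(vals) crisischat:::new_trajectory_curve(
    "despair", seq(0, 1, length.out = length(vals)), vals, 1L)
  one <- aggregate_trajectories(list(mk(c(4, 5, 6))))
  expect_equal(one$values, c(4, 5, 6))
  expect_equal(one$n, 1)

  two <- aggregate_trajectories(list(mk(c(4, 4, 4)), mk(c(6, 6, 6))))
  expect_equal(two$values, c(5, 5, 5))

  set.seed(1)
  curves <- lapply(1:6, function(i) mk(runif(3, 1, 10)))
  a <- aggregate_trajectories(curves)
  b <- aggregate_trajectories(curves[sample(6)])
  expect_equal(a$values, b$values)
  expect_equal(a$sd, b$sd)

  expect_error(aggregate_trajectories(list(mk(c(1, 2)), mk(c(1, 2, 3)))),
               "grid")
})

test_that("percent change reads reduction for negative emotions, increase for optimism", {
  mk <- function(emotion, vals) crisischat:::new_trajectory_curve(
    emotion, seq(0, 1, length.out = length(vals)), vals, 1L)
  pc <- percent_change(mk("depression", c(6.74, 5, 3.74)))
  expect_equal(as.numeric(pc), (6.74 - 3.74) / 6.74 * 100, tolerance = 1e-12)
  expect_equal(attr(pc, "direction"), "reduction")

  expect_equal(as.numeric(percent_change(mk("despair", c(5, 5, 5)))), 0)

  up <- percent_change(mk("optimism", c(2, 2.5, 3)))
  expect_equal(as.numeric(up), 50)
  expect_equal(attr(up, "direction"), "increase")
})

test_that("noise-free generation recovers configured begin/end through the pipeline", {
  cfg <- generator_config(n_sessions = 400, seed = 31, noise_sd = 0,
                          p_absent = 0, users_per_session = c("1" = 1),
                          prevalence = list(passive = 0.5, active = 0))
  ep <- cfg$emotion_params
  ep[, "begin_sd"] <- 1e-8
  ep[, "end_sd"] <- 1e-8
  cfg <- generator_config(n_sessions = 400, seed = 31, noise_sd = 0,
                          p_absent = 0, users_per_session = c("1" = 1),
                          prevalence = list(passive = 0.5, active = 0),
                          emotion_params = ep)
  co <- generate_corpus(cfg)
  cv <- group_trajectory(co, "depression", "passive_si")
  row <- ep[ep$group == "passive_si" & ep$emotion == "depression", ]
  # integer rounding of the latent line is the only remaining distortion
  expect_lt(abs(cv$values[1] - row$begin_mean), 0.51)
  expect_lt(abs(cv$values[length(cv$values)] - row$end_mean), 0.51)
})

test_that("group trajectories aggregate eligible visits only", {
  co <- enriched_corpus()
  cv <- group_trajectory(co, "despair", "passive_si")
  el <- eligible_sessions(co, "despair", groups = "passive_si")
  expect_lte(cv$n, nrow(el))
  expect_gt(cv$n, 50)
  expect_true(all(cv$values >= 1 & cv$values <= 10))
  expect_gt(cv$values[1], tail(cv$values, 1))  # distress declines on average
})
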