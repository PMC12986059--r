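test_that("identical config and seed give byte-identical corpora", {
  cfg <- generator_config(n_sessions = 60, seed = 123,
                          prevalence = list(passive = 0.1, active = 0.1))
  f1 <- tempfile(); f2 <- tempfile()
  write_corpus(generate_corpus(cfg), f1)
  write_corpus(generate_corpus(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))

  other <- generate_corpus(generator_config(n_sessions = 60, seed = 124,
                                            prevalence = list(passive = 0.1,
                                                              active = 0.1)))
  expect_false(identical(other, generate_corpus(cfg)))
})

test_that("zero prevalence yields a corpus without SI sessions or referrals", {
  co <- generate_corpus(generator_config(n_sessions = 150, seed = 4,
                                         prevalence = list(passive = 0, active = 0)))
  expect_true(all(co$sessions$si_label == "none"))
  expect_false(any(co$flags$kind == "referral"))
  expect_true(all(co$visits$group == "non_exposed_non_si"))
})

test_that("invalid configurations error before any sampling", {
  expect_error(generator_config(prevalence = list(passive = 1.5)), "probability")
  expect_error(generator_config(users_per_session = c("1" = 0.5, "2" = 0.4)),
               "sum to 1")
  expect_error(generator_config(prevalence = list(passive = 0.5, active = 0.5),
                                users_per_session = c("4" = 1)),
               "prevalence")
  expect_error(generator_config(latency = list(moderator_lead = c(mean = 500, sd = 50))),
               "calibration infeasible")
})

test_that("generated corpora satisfy every corpus invariant across seeds", {
  for (seed in c(1, 2, 3)) {
    co <- generate_corpus(generator_config(
      n_sessions = 120, seed = seed,
      users_per_session = c("1" = 0.3, "2" = 0.4, "3" = 0.3),
      prevalence = list(passive = 0.15, active = 0.1)))
    expect_length(validate_corpus(co), 0)
  }
})

test_that("every active-SI session carries a protocol question and a referral", {
  co <- enriched_corpus()
  act <- co$sessions$session_id[co$sessions$si_label == "active"]
  expect_gt(length(act), 20)
  f <- co$flags
  prot <- f$session_id[f$kind == "protocol_question"]
  refs <- f$session_id[f$kind == "referral"]
  expect_true(all(act %in% prot))
  expect_true(all(act %in% refs))
  expect_true(all(refs %in% act))  # and nowhere else
})

test_that("sample_latency draws are positive with the configured moments", {
  cfg <- generator_config()
  set.seed(11)
  x <- sample_latency("active", cfg, 100000)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 71.32), 3 * 89 / sqrt(100000))
  expect_lt(abs(sd(x) - 89) / 89, 0.05)

  degenerate <- generator_config(latency = list(active = c(mean = 50, sd = 0)),
                                 ordering = list(p_ai_first_active = 1))
  expect_equal(sample_latency("active", degenerate, 5), rep(50, 5))
})

test_that("the signed flag delta matches the printed moments and ordering rate", {
  cfg <- generator_config()
  set.seed(21)
  d <- crisischat:::sample_flag_delta(200000, "active", cfg)
  expect_lt(abs(mean(d) - 71.32), 3 * 89 / sqrt(200000))
  expect_lt(abs(sd(d) - 89) / 89, 0.05)
  expect_lt(abs(mean(d > 0) - 0.8126), 3 * sqrt(0.8126 * 0.1874 / 200000))
  d <- crisischat:::sample_flag_delta(200000, "passive", cfg)
  expect_lt(abs(mean(d) - 79.87), 3 * 95.71 / sqrt(200000))
  expect_lt(abs(mean(d > 0) - 0.7752), 3 * sqrt(0.7752 * 0.2248 / 200000))
})

test_that("emotion series follow the configured begin/end levels", {
  # flat latent path: begin = end = 7 with zero SD
  ep <- generator_config()$emotion_params
  ep[ep$group == "passive_si" & ep$emotion == "despair",
     c("begin_mean", "begin_sd", "end_mean", "end_sd")] <- c(7, 1e-8, 7, 1e-8)
  cfg_flat <- generator_config(noise_sd = 0, p_absent = 0, emotion_params = ep)
  set.seed(5)
  expect_equal(simulate_emotion_series("passive_si", "despair", 6, cfg_flat),
               rep(7L, 6))

  none <- generator_config(p_absent = 1)
  set.seed(6)
  expect_true(all(is.na(simulate_emotion_series("passive_si", "despair", 8, none))))

  # first/last means recover the passive-SI depression levels (6.74 / 3.74)
  cfg0 <- generator_config(p_absent = 0)
  set.seed(7)
  firsts <- lasts <- numeric(4000)
  for (i in seq_len(4000)) {
    s <- simulate_emotion_series("passive_si", "depression", 5, cfg0)
    firsts[i] <- s[1]; lasts[i] <- s[5]
  }
  expect_lt(abs(mean(firsts) - 6.74), 3 * sd(firsts) / sqrt(4000) + 0.02)
  expect_lt(abs(mean(lasts) - 3.74), 3 * sd(lasts) / sqrt(4000) + 0.03)
})

test_that("per-visit SI prevalence converges to the configured rates", {
  co <- cached_corpus("prevalence_default", function() {
    generate_corpus(generator_config(n_sessions = 20000, seed = 99))
  })
  prev <- prevalence_summary(co)
  n <- prev$n_visits
  for (cl in c("passive", "active")) {
    p0 <- c(passive = 0.0198, active = 0.0121)[[cl]]
    expect_lt(abs(prev$visit_rate[[cl]] - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("scores never leave 1..10 and zeros are never stored", {
  co <- enriched_corpus()
  for (e in EMOTIONS) {
    x <- co$messages[[e]]
    x <- x[!is.na(x)]
    expect_true(all(x >= 1 & x <= 10))
    expect_true(is.integer(co$messages[[e]]))
  }
})
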