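toy_confusion_corpus <- function() {
  build_corpus(list(
    both = list(si_label = "passive", discloser = "u1",
                users = list(u1 = solo_user(despair = c(6, 5, 4))),
                flags = flag_df(list("ai", "crisis_flag", 30),
                                list("moderator", "protocol_question", 95))),
    ai_only = list(users = list(u1 = solo_user()),
                   flags = flag_df(list("ai", "crisis_flag", 12))),
    mod_only = list(si_label = "passive", discloser = "u1",
                    users = list(u1 = solo_user(despair = c(7, 6, 5))),
                    flags = flag_df(list("moderator", "protocol_question", 40))),
    neither = list(users = list(u1 = solo_user()))))
}

test_that("confusion counts put one session in each cell", {
  cc <- confusion_counts(toy_confusion_corpus())
  expect_equal(cc[c("tp", "fp", "fn", "tn")], list(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(cc$n, 4)
})

test_that("confusion counts ignore message content entirely", {
  co <- toy_confusion_corpus()
  cc1 <- confusion_counts(co)
  co$messages$text <- "completely different text"
  co$messages$despair <- NA_integer_
  expect_equal(confusion_counts(co)[c("tp", "fp", "fn", "tn")],
               cc1[c("tp", "fp", "fn", "tn")])
})

test_that("agreement in every session leaves no off-diagonal counts", {
  co <- build_corpus(list(
    a = list(si_label = "passive", discloser = "u1",
             users = list(u1 = solo_user(despair = c(6, 5, 4))),
             flags = flag_df(list("ai", "crisis_flag", 10),
                             list("moderator", "protocol_question", 60))),
    b = list(users = list(u1 = solo_user()))))
  cc <- confusion_counts(co)
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
})

test_that("detection metrics evaluate the printed ratio formulas", {
  m <- detection_metrics(confusion_from_counts(tp = 8, fp = 2, fn = 2, tn = 88))
  expect_equal(m$percent[["sensitivity"]], 80.00)
  expect_equal(m$percent[["precision"]], 80.00)
  expect_equal(m$percent[["accuracy"]], 96.00)

  perfect <- detection_metrics(confusion_from_counts(5, 0, 0, 95))
  expect_true(all(perfect$percent == 100))

  expect_error(detection_metrics(confusion_from_counts(0, 0, 0, 0)), "zero")
})

test_that("zero denominators are flagged as undefined, not reported as 0", {
  m <- detection_metrics(confusion_from_counts(tp = 0, fp = 3, fn = 0, tn = 7))
  expect_true(is.na(m$fraction[["sensitivity"]]))
  expect_true("sensitivity" %in% m$undefined)
  expect_false(is.na(m$fraction[["specificity"]]))
})

test_that("sensitivity and NPV are invariant to scaling all counts", {
  base <- detection_metrics(confusion_from_counts(8, 2, 2, 88))
  scaled <- detection_metrics(confusion_from_counts(8 * 7, 2 * 7, 2 * 7, 88 * 7))
  expect_equal(base$fraction, scaled$fraction)
  expect_equal(base$fraction[["accuracy"]], (8 + 88) / 100)
})

latency_corpus_toy <- function(diffs, si = "passive") {
  specs <- lapply(seq_along(diffs), function(i) {
    t1 <- 100
    list(si_label = si, discloser = "u1",
         users = list(u1 = solo_user(despair = c(6, 5, 4))),
         flags = flag_df(list("ai", "crisis_flag", t1),
                         list("moderator", "protocol_question", t1 + diffs[i])))
  })
  names(specs) <- sprintf("L%02d", seq_along(diffs))
  build_corpus(specs)
}

test_that("flag latency statistics include negative differences", {
  st <- flag_latency_stats(latency_corpus_toy(c(10, 20, -6)), "passive")
  expect_equal(st$n, 3)
  expect_equal(st$mean, 8)
  expect_equal(st$p_ai_first, 2 / 3)

  zero <- flag_latency_stats(latency_corpus_toy(c(0, 0)), "passive")
  expect_equal(zero$mean, 0)
  expect_equal(zero$sd, 0)
  expect_equal(zero$p_ai_first, 0)  # a tie is not "AI first"

  none <- flag_latency_stats(latency_corpus_toy(c(5, 5)), "active")
  expect_equal(none$n, 0)
  expect_true(is.na(none$mean))
})

test_that("referral latency measures time from the last question", {
  co <- build_corpus(list(
    r1 = list(si_label = "active", discloser = "u1",
              users = list(u1 = solo_user(despair = c(8, 7, 7))),
              flags = flag_df(list("moderator", "protocol_question", 50),
                              list("moderator", "safety_question", 80),
                              list("moderator", "referral", 180))),
    r2 = list(si_label = "active", discloser = "u1",
              users = list(u1 = solo_user(despair = c(9, 8, 8))),
              flags = flag_df(list("moderator", "protocol_question", 40),
                              list("moderator", "referral", 340)))))
  st <- referral_latency_stats(co)
  expect_equal(st$n, 2)
  expect_equal(st$mean, 200)  # (180-80, 340-40)

  instant <- build_corpus(list(
    r1 = list(si_label = "active", discloser = "u1",
              users = list(u1 = solo_user(despair = c(8, 7, 7))),
              flags = flag_df(list("moderator", "protocol_question", 50),
                              list("moderator", "referral", 50)))))
  expect_equal(referral_latency_stats(instant)$mean, 0)
  expect_equal(referral_latency_stats(toy_confusion_corpus())$n, 0)
})

test_that("prevalence arithmetic reproduces published-scale rates and ratio", {
  p <- prevalence_from_counts(n_passive = 8929, n_active = 5472,
                              n_visits = 449946, n_exposed_visits = 22346)
  expect_equal(p$visit_pct[["passive"]], 1.98)
  expect_equal(p$exposure_pct, 4.97)
  expect_equal(p$ratio_label, "1.6:1")
  expect_equal(p$ratio, 8929 / 5472, tolerance = 1e-12)
})

test_that("a corpus without SI has zero rates and an undefined ratio", {
  co <- build_corpus(list(S1 = list(users = list(u1 = solo_user()))))
  prev <- prevalence_summary(co)
  expect_equal(unname(prev$visit_rate), c(0, 0))
  expect_true(is.na(prev$ratio))
  expect_equal(prev$exposure_rate, 0)
})

test_that("prevalence summary counts monthly cases consistently", {
  co <- enriched_corpus()
  prev <- prevalence_summary(co)
  m <- prev$monthly
  for (cl in c("passive", "active")) {
    expect_equal(sum(m$n[m$si_label == cl]), unname(prev$counts[[cl]]))
  }
  expect_equal(prev$session_rate[["passive"]],
               prev$counts[["passive"]] / prev$n_sessions)
})

test_that("simulated AI sensitivity tracks the configured flag model", {
  co <- latency_corpus()
  cc <- confusion_counts(co)
  sens <- cc$tp / (cc$tp + cc$fn)
  p0 <- 12602 / 14401
  expect_lt(abs(sens - p0), 3 * sqrt(p0 * (1 - p0) / (cc$tp + cc$fn)))
})
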