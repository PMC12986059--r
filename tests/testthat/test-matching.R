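test_that("logit is the log-odds with the expected symmetry", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.75), log(3))
  expect_equal(logit(1 - 0.3), -logit(0.3))
  expect_error(logit(0), "inside")
  expect_error(logit(1.2), "inside")
})

test_that("a null propensity model returns the marginal treated fraction", {
  set.seed(10)
  n <- 4000
  rec <- data.frame(id = seq_len(n),
                    treated = rep(c(TRUE, FALSE), c(1200, 2800)),
                    initial_intensity = runif(n, 1, 10))
  fit <- fit_propensity(rec)
  expect_true(fit$converged)
  expect_lt(abs(mean(fit$propensity) - 0.3), 0.01)
  expect_lt(sd(fit$propensity), 0.03)
})

test_that("the IRLS fit recovers known coefficients and matches glm", {
  set.seed(11)
  n <- 10000
  x <- runif(n, 1, 10)
  topic <- sample(c("a", "b", "c"), n, replace = TRUE)
  eta <- -4 + 0.8 * x + 0.5 * (topic == "b")
  y <- rbinom(n, 1, plogis(eta))
  rec <- data.frame(id = seq_len(n), treated = y == 1,
                    initial_intensity = x, topic = topic)
  fit <- fit_propensity(rec)
  gref <- glm(y ~ x + I(topic == "b") + I(topic == "c"), family = binomial)
  se <- summary(gref)$coefficients["x", "Std. Error"]
  expect_lt(abs(fit$coefficients[["intensity"]] - 0.8), 3 * se)
  # same likelihood optimum as the reference fitter
  expect_equal(sort(unname(fit$propensity)), sort(unname(fitted(gref))),
               tolerance = 1e-6)

  # tiny hand-built single-covariate fit agrees coefficient-by-coefficient
  rec4 <- data.frame(id = 1:6, treated = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
                     initial_intensity = c(1, 2, 3, 4, 5, 6))
  f4 <- fit_propensity(rec4)
  g4 <- glm(treated ~ initial_intensity, family = binomial, data = rec4)
  expect_equal(unname(f4$coefficients), unname(coef(g4)), tolerance = 1e-6)
})

test_that("perfect separation errors with ridge advice, and ridge rescues it", {
  rec <- data.frame(id = 1:8, treated = rep(c(FALSE, TRUE), each = 4),
                    initial_intensity = c(1, 2, 3, 4, 6, 7, 8, 9))
  expect_error(fit_propensity(rec), "ridge")
  fit <- fit_propensity(rec, ridge = 1e-6)
  expect_true(fit$converged)
  # the penalized optimum is near-saturated; scores may round to 0/1 but
  # downstream matching clips them before the logit
  expect_true(all(fit$propensity >= 0 & fit$propensity <= 1))
  set.seed(2)
  expect_s3_class(match_pairs(rec, fit$propensity, caliper = Inf), "match_result")
})

# helper: records whose propensities produce the requested logits
records_for_logits <- function(tr_logit, co_logit) {
  lg <- c(tr_logit, co_logit)
  data.frame(id = sprintf("u%02d", seq_along(lg)),
             treated = rep(c(TRUE, FALSE), c(length(tr_logit), length(co_logit))),
             initial_intensity = 5)
}

props_for_logits <- function(records, tr_logit, co_logit) {
  setNames(plogis(c(tr_logit, co_logit)), records$id)
}

test_that("caliper matching keeps the enumerated optimal pair and excludes the rest", {
  rec <- records_for_logits(c(0.00, 0.05), c(0.004, 0.30))
  pr <- props_for_logits(rec, c(0.00, 0.05), c(0.004, 0.30))
  for (s in 1:5) {  # any processing order gives the same answer here
    set.seed(s)
    res <- match_pairs(rec, pr, caliper = 0.01)
    expect_equal(nrow(res$pairs), 1)
    expect_equal(res$pairs$treated_id, "u01")
    expect_equal(res$pairs$control_id, "u03")
    expect_equal(res$pairs$distance, 0.004, tolerance = 1e-9)
    expect_equal(res$excluded, "u02")
  }
})

test_that("identical propensities match everyone at distance zero", {
  rec <- records_for_logits(rep(0.2, 5), rep(0.2, 7))
  pr <- props_for_logits(rec, rep(0.2, 5), rep(0.2, 7))
  set.seed(3)
  res <- match_pairs(rec, pr, caliper = 0.01)
  expect_equal(nrow(res$pairs), 5)
  expect_true(all(res$pairs$distance == 0))

  # caliper = Inf on equal-sized arms pairs everything
  rec2 <- records_for_logits(rnorm(6), rnorm(6))
  pr2 <- setNames(plogis(rnorm(12)), rec2$id)
  set.seed(4)
  res2 <- match_pairs(rec2, pr2, caliper = Inf)
  expect_equal(nrow(res2$pairs), 6)
})

test_that("greedy matching agrees with a brute-force oracle on small instances", {
  for (s in 1:25) {
    set.seed(1000 + s)
    nt <- sample(3:5, 1); nc <- sample(3:7, 1)
    tl <- round(rnorm(nt, 0, 0.3), 3)
    cl <- round(rnorm(nc, 0, 0.3), 3)
    tid <- sprintf("t%02d", seq_len(nt)); cid <- sprintf("c%02d", seq_len(nc))
    rec <- data.frame(id = c(tid, cid),
                      treated = rep(c(TRUE, FALSE), c(nt, nc)),
                      initial_intensity = 5)
    pr <- setNames(plogis(c(tl, cl)), rec$id)
    caliper <- sample(c(0.05, 0.2, Inf), 1)
    set.seed(s)
    res <- match_pairs(rec, pr, caliper = caliper)
    set.seed(s)
    ord <- sample.int(nt)
    # match_pairs clips propensities; mirror the induced logits exactly
    lg <- qlogis(pmin(pmax(pr, 1e-12), 1 - 1e-12))
    oracle <- greedy_oracle(tid, lg[tid], cid, lg[cid], caliper, ord)
    expect_equal(nrow(res$pairs), length(oracle$pairs))
    for (k in seq_along(oracle$pairs)) {
      expect_true(any(res$pairs$treated_id == oracle$pairs[[k]][1] &
                        res$pairs$control_id == oracle$pairs[[k]][2]))
    }
    expect_setequal(res$excluded, oracle$excluded)
    # structural invariants hold on every run
    expect_true(all(res$pairs$distance <= caliper))
    expect_false(any(duplicated(res$pairs$control_id)))
    expect_lte(nrow(res$pairs), min(nt, nc))
  }
})

test_that("no controls means every treated unit is excluded", {
  rec <- records_for_logits(c(0, 0.1), numeric(0))
  pr <- setNames(plogis(c(0, 0.1)), rec$id)
  set.seed(1)
  res <- match_pairs(rec, pr)
  expect_equal(nrow(res$pairs), 0)
  expect_setequal(res$excluded, rec$id)
})

test_that("standardized mean differences match hand arithmetic", {
  rec <- data.frame(id = 1:4, treated = c(TRUE, TRUE, FALSE, FALSE),
                    initial_intensity = c(6, 8, 5, 7))
  pr <- setNames(rep(0.5, 4), rec$id)
  set.seed(1)
  res <- match_pairs(rec, pr, caliper = Inf)
  smd <- standardized_mean_diff(rec, res)
  pooled <- sqrt((var(c(6, 8)) + var(c(5, 7))) / 2)
  expect_equal(smd$smd_before[smd$covariate == "intensity"],
               (7 - 6) / pooled)

  same <- data.frame(id = 1:4, treated = c(TRUE, TRUE, FALSE, FALSE),
                     initial_intensity = c(6, 8, 6, 8))
  set.seed(1)
  res2 <- match_pairs(same, setNames(rep(0.5, 4), same$id), caliper = Inf)
  smd2 <- standardized_mean_diff(same, res2)
  expect_equal(smd2$smd_before, 0)
})

test_that("matching on true propensities improves covariate balance", {
  set.seed(21)
  n <- 5000
  x <- runif(n, 1, 10)
  topic <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.6, 0.4))
  p <- plogis(-3.5 + 0.45 * x + 0.8 * (topic == "b"))
  treated <- runif(n) < p
  rec <- data.frame(id = seq_len(n), treated = treated,
                    initial_intensity = x, topic = topic)
  fit <- fit_propensity(rec)
  res <- match_pairs(rec, fit$propensity, caliper = 0.05)
  expect_gt(nrow(res$pairs), 200)
  smd <- standardized_mean_diff(rec, res)
  int <- smd[smd$covariate == "intensity", ]
  expect_gt(abs(int$smd_before), 0.3)   # confounding present before matching
  expect_lt(abs(int$smd_after), abs(int$smd_before))
  expect_lt(abs(int$smd_after), 0.1)
})
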