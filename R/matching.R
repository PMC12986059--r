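# Propensity-score estimation and 1:1 nearest-neighbour caliper matching.
#
# The propensity model is a logistic regression of treatment on initial
# emotional intensity and conversation topic (one-hot, reference level =
# most frequent topic), fitted by iteratively reweighted least squares.
# Matching is greedy nearest-neighbour without replacement on the logit of
# the propensity score with a hard caliper: pairs farther apart than the
# caliper are excluded.

# Design matrix: intercept + intensity + topic dummies (reference dropped).
match_design <- function(records) {
  x <- cbind(`(Intercept)` = 1, intensity = records$initial_intensity)
  topics <- records$topic
  if (!is.null(topics) && length(unique(topics)) > 1) {
    ref <- names(sort(table(topics), decreasing = TRUE))[1]
    lev <- setdiff(sort(unique(topics)), ref)
    for (tp in lev) x <- cbind(x, as.numeric(topics == tp))
    colnames(x) <- c("(Intercept)", "intensity", paste0("topic_", lev))
  }
  x
}

#' Fit the propensity model by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression of treatment status on initial
#' emotional intensity plus topic dummies, iterated to gradient norm
#' below `tol` (default 1e-8) or `max_iter` sweeps. When the likelihood is
#' unbounded (perfect separation), the fit stops with an error advising the
#' ridge switch; `ridge > 0` adds an L2 penalty (excluding the intercept)
#' that restores a finite optimum.
#'
#' @param records data.frame with columns `id`, `treated` (logical),
#'   `initial_intensity` and optionally `topic`.
#' @param ridge L2 penalty (default 0; use e.g. 1e-6 under separation).
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return object of class `propensity_fit`: `coefficients`, `propensity`
#'   (named by `id`), `converged`, `iterations`.
#' @export
fit_propensity <- function(records, ridge = 0, tol = 1e-8, max_iter = 100) {
  stopifnot(is.data.frame(records), all(c("id", "treated", "initial_intensity")
                                        %in% names(records)))
  y <- as.numeric(records$treated)
  if (all(y == 1) || all(y == 0)) {
    stop("need at least one treated and one control record", call. = FALSE)
  }
  x <- match_design(records)
  p <- ncol(x)
  pen <- ridge * c(0, rep(1, p - 1))  # intercept unpenalized
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- expit(eta)
    grad <- drop(crossprod(x, y - mu)) - pen * beta
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    h <- crossprod(x, x * w) + diag(pen, p)
    step <- tryCatch(solve(h, grad), error = function(e) NULL)
    if (is.null(step)) {
      stop("propensity fit failed: singular information matrix; ",
           "consider ridge = 1e-6", call. = FALSE)
    }
    beta <- beta + step
    if (ridge == 0 && max(abs(beta)) > 30) {
      stop("propensity fit did not converge (likely perfect separation); ",
           "refit with ridge = 1e-6", call. = FALSE)
    }
  }
  if (!converged) {
    stop("propensity fit did not converge in ", max_iter,
         " iterations; consider ridge = 1e-6", call. = FALSE)
  }
  prop <- expit(drop(x %*% beta))
  names(prop) <- as.character(records$id)
  structure(list(coefficients = stats::setNames(beta, colnames(x)),
                 propensity = prop, converged = converged, iterations = iter,
                 ridge = ridge),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("propensity_fit: %d units, converged in %d IRLS iterations%s\n",
              length(x$propensity), x$iterations,
              if (x$ridge > 0) sprintf(" (ridge %.2g)", x$ridge) else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.propensity_fit <- function(object, ...) object$coefficients

#' Greedy 1:1 nearest-neighbour matching with a logit caliper
#'
#' Treated units are processed in a random order (drawn from R's RNG — seed
#' the pipeline for reproducibility; randomisation avoids systematic order
#' bias). Each treated unit takes the nearest not-yet-used control on the
#' logit propensity scale; ties break toward the lowest control id. A pair
#' whose |logit difference| exceeds the caliper is discarded and the
#' treated unit recorded as excluded. Matching is without replacement: a
#' control is used at most once.
#'
#' @param records data.frame with `id` and `treated`.
#' @param propensities named numeric vector of propensity scores covering
#'   every record id (e.g. `fit_propensity(records)$propensity`). Values
#'   are clipped to \[1e-12, 1 - 1e-12\] before the logit.
#' @param caliper maximum |logit difference| (default 0.01).
#' @return object of class `match_result`: `pairs` (data.frame of
#'   treated_id, control_id, distance), `excluded` (treated ids), `caliper`.
#' @export
match_pairs <- function(records, propensities, caliper = 0.01) {
  stopifnot(all(as.character(records$id) %in% names(propensities)))
  pr <- pmin(pmax(propensities[as.character(records$id)], 1e-12), 1 - 1e-12)
  lg <- log(pr / (1 - pr))
  treated_ids <- as.character(records$id[records$treated])
  control_ids <- as.character(records$id[!records$treated])
  tl <- lg[treated_ids]
  # controls sorted by logit; ties in id order so "lowest id" wins searches
  co <- order(lg[control_ids], control_ids)
  cl <- lg[control_ids][co]
  cid <- control_ids[co]
  used <- rep(FALSE, length(cid))
  ord <- sample.int(length(treated_ids))
  res_t <- res_c <- character(0)
  res_d <- numeric(0)
  excluded <- character(0)
  for (i in ord) {
    avail <- which(!used)
    if (!length(avail)) { excluded <- c(excluded, treated_ids[i]); next }
    d <- abs(cl[avail] - tl[i])
    # nearest available control; equidistant ties -> lowest control id
    best <- order(d, cid[avail])[1]
    dist <- d[best]
    if (dist > caliper) {
      excluded <- c(excluded, treated_ids[i])
    } else {
      used[avail[best]] <- TRUE
      res_t <- c(res_t, treated_ids[i])
      res_c <- c(res_c, cid[avail[best]])
      res_d <- c(res_d, dist)
    }
  }
  pairs <- data.frame(treated_id = res_t, control_id = res_c,
                      distance = res_d, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(pairs$control_id), all(pairs$distance <= caliper))
  structure(list(pairs = pairs, excluded = excluded, caliper = caliper,
                 n_treated = length(treated_ids), n_control = length(control_ids)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d pairs (caliper %g logit units), %d treated excluded\n",
              nrow(x$pairs), x$caliper, length(x$excluded)))
  if (nrow(x$pairs)) {
    cat(sprintf("  |logit distance|: median %.2g, max %.2g\n",
                stats::median(x$pairs$distance), max(x$pairs$distance)))
  }
  invisible(x)
}

smd_one <- function(xt, xc) {
  sp <- sqrt((stats::var(xt) + stats::var(xc)) / 2)
  d <- mean(xt) - mean(xc)
  if (sp == 0) { if (d == 0) 0 else Inf } else d / sp
}

#' Standardized mean differences before and after matching
#'
#' Balance diagnostic: for every matching covariate (initial intensity plus
#' a one-hot column per topic), SMD = (mean treated - mean control) /
#' pooled SD, computed once over all records and once over the matched
#' pairs only.
#'
#' @param records data.frame with `id`, `treated`, `initial_intensity`,
#'   optionally `topic`.
#' @param result a `match_result` from [match_pairs()].
#' @return data.frame with columns `covariate`, `smd_before`, `smd_after`.
#' @export
standardized_mean_diff <- function(records, result) {
  stopifnot(inherits(result, "match_result"), nrow(result$pairs) >= 1)
  ids <- as.character(records$id)
  covs <- data.frame(intensity = records$initial_intensity)
  if (!is.null(records$topic)) {
    for (tp in sort(unique(records$topic))) {
      covs[[paste0("topic_", tp)]] <- as.numeric(records$topic == tp)
    }
  }
  before_t <- records$treated
  it <- match(result$pairs$treated_id, ids)
  ic <- match(result$pairs$control_id, ids)
  out <- data.frame(covariate = names(covs),
                    smd_before = NA_real_, smd_after = NA_real_)
  for (j in seq_along(covs)) {
    x <- covs[[j]]
    out$smd_before[j] <- smd_one(x[before_t], x[!before_t])
    out$smd_after[j] <- smd_one(x[it], x[ic])
  }
  out
}
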