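#' Kaplan-Meier product-limit estimator
#'
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over distinct
#' event times, with the usual convention that deaths precede censorings
#' at tied times (a subject censored at t is still at risk for a death
#' at t).
#'
#' @param time positive follow-up times.
#' @param event 0/1 death indicator.
#' @return object of class \code{km_fit}: data.frame(time, n_risk,
#'   n_event, n_censor, surv) over all distinct observed times.
#' @export
km_fit <- function(time, event) {
  if (length(time) == 0L) stop("need at least one record")
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  ts <- sort(unique(time))
  n_risk <- vapply(ts, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ts, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ts, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ts, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_fit", "data.frame"))
}

#' Survival probability at a time point
#'
#' Step-function evaluation of a [km_fit()] estimate (right-continuous).
#'
#' @param fit a \code{km_fit}.
#' @param t time point(s).
#' @return estimated survival probability at each \code{t}.
#' @export
km_surv_at <- function(fit, t) {
  vapply(t, function(tt) {
    idx <- which(fit$time <= tt)
    if (length(idx) == 0L) 1 else fit$surv[max(idx)]
  }, numeric(1))
}

#' Log-rank test for equality of survival curves
#'
#' Accumulates observed minus expected deaths over event times with the
#' hypergeometric variance; the global statistic is the quadratic form on
#' the first g-1 groups (chi-square with g-1 df).  With
#' \code{pairwise = TRUE} every two-group comparison is also run.
#'
#' @param time positive follow-up times.
#' @param event 0/1 death indicator.
#' @param group group label per record.
#' @param pairwise also compute all pairwise two-group tests.
#' @return list(statistic, df, p_value, observed, expected) plus, when
#'   requested, \code{pairwise}: data.frame(group1, group2, statistic,
#'   p_value).
#' @export
log_rank <- function(time, event, group, pairwise = FALSE) {
  group <- factor(group)
  g <- nlevels(group)
  if (g < 2L) stop("need at least 2 groups")
  if (any(table(group) == 0L)) stop("empty group")
  if (sum(event) == 0L) stop("no events in any group")
  ts <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(g), levels(group))
  V <- matrix(0, g, g)
  for (t in ts) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n_gt <- vapply(levels(group), function(l) sum(at_risk & group == l),
                   numeric(1))
    d_t <- sum(time == t & event == 1)
    d_gt <- vapply(levels(group), function(l)
      sum(time == t & event == 1 & group == l), numeric(1))
    O <- O + d_gt
    E <- E + d_t * n_gt / n_t
    if (n_t > 1) {
      mult <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + mult * (diag(n_gt / n_t, g) - tcrossprod(n_gt / n_t))
    }
  }
  idx <- seq_len(g - 1L)
  stat <- drop(t(O[idx] - E[idx]) %*%
                 solve(V[idx, idx, drop = FALSE], (O - E)[idx]))
  res <- list(statistic = stat, df = g - 1L,
              p_value = stats::pchisq(stat, g - 1L, lower.tail = FALSE),
              observed = O, expected = E)
  if (pairwise) {
    prs <- utils::combn(levels(group), 2L)
    res$pairwise <- do.call(rbind, apply(prs, 2L, function(pr) {
      sel <- group %in% pr
      sub <- log_rank(time[sel], event[sel], droplevels(group[sel]))
      data.frame(group1 = pr[1], group2 = pr[2],
                 statistic = sub$statistic, p_value = sub$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  res
}

# Breslow/Efron partial log-likelihood with analytic gradient and observed
# information.  Subjects are swept in decreasing-time order so each risk
# set is a running sum; O(n p^2) overall.
cox_partial <- function(beta, time, event, X, ties = "breslow") {
  n <- nrow(X); p <- ncol(X)
  ord <- order(time, decreasing = TRUE)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0; score <- numeric(p); info <- matrix(0, p, p)
  s0 <- 0; s1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    t <- time[i]
    j <- i
    while (j <= n && time[j] == t) {      # add the tied block to risk set
      xi <- X[j, ]
      s0 <- s0 + w[j]
      s1 <- s1 + w[j] * xi
      S2 <- S2 + w[j] * tcrossprod(xi)
      j <- j + 1L
    }
    dead <- i:(j - 1L)
    dead <- dead[event[dead] == 1]
    d <- length(dead)
    if (d > 0L) {
      xd <- X[dead, , drop = FALSE]
      ll <- ll + sum(eta[dead])
      score <- score + colSums(xd)
      if (ties == "breslow") {
        ll <- ll - d * log(s0)
        score <- score - d * s1 / s0
        info <- info + d * (S2 / s0 - tcrossprod(s1 / s0))
      } else {                            # Efron
        wd0 <- sum(w[dead]); wd1 <- colSums(w[dead] * xd)
        wd2 <- crossprod(sqrt(w[dead]) * xd)
        for (k in seq_len(d) - 1L) {
          f <- k / d
          s0k <- s0 - f * wd0
          s1k <- s1 - f * wd1
          S2k <- S2 - f * wd2
          ll <- ll - log(s0k)
          score <- score - s1k / s0k
          info <- info + S2k / s0k - tcrossprod(s1k / s0k)
        }
      }
    }
    i <- j
  }
  list(loglik = ll, gradient = unname(score), information = unname(info))
}

#' Cox partial log-likelihood and gradient
#'
#' Evaluates the (Breslow or Efron) partial log-likelihood, its analytic
#' gradient and the observed information at an arbitrary coefficient
#' vector.  Exposed so the gradient can be checked against finite
#' differences.
#'
#' @param beta coefficient vector (length = ncol(X)).
#' @param time,event follow-up and 0/1 death indicator.
#' @param X numeric design matrix (no intercept).
#' @param ties "breslow" or "efron".
#' @return list(loglik, gradient, information).
#' @export
cox_partial_loglik <- function(beta, time, event, X,
                               ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  cox_partial(beta, time, event, as.matrix(X), ties)
}

#' Cox proportional hazards regression
#'
#' Maximises the partial likelihood by Newton-Raphson starting at zero;
#' convergence when the largest absolute score component falls below 1e-8
#' or the relative log-likelihood change below 1e-10.  Standard errors are
#' the square roots of the inverse observed information diagonal.
#'
#' @param time positive follow-up times.
#' @param event 0/1 death indicator.
#' @param X numeric design matrix (one column per covariate; expand
#'   factors with \code{stats::model.matrix} first).
#' @param ties tie handling: "breslow" (default) or "efron".
#' @param max_iter Newton iteration cap (error past it).
#' @return object of class \code{cox_fit}: coefficients table (coef, se,
#'   hr, ci_lower, ci_upper, z, p_value), loglik, null loglik, iterations.
#' @export
cox_fit <- function(time, event, X, ties = c("breslow", "efron"),
                    max_iter = 50L) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (sum(event) < ncol(X))
    stop("fewer events than covariates")
  const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  if (any(const))
    stop("constant covariate(s): ", paste(colnames(X)[const], collapse = ", "))
  beta <- numeric(ncol(X))
  ll_null <- cox_partial(beta, time, event, X, ties)$loglik
  ll_old <- ll_null
  for (it in seq_len(max_iter)) {
    pl <- cox_partial(beta, time, event, X, ties)
    if (max(abs(pl$gradient)) < 1e-8) break
    step <- solve(pl$information, pl$gradient)
    # step-halving keeps Newton ascent monotone on flat likelihoods
    ll_new <- -Inf
    for (h in 1:30) {
      cand <- beta + step
      ll_new <- cox_partial(cand, time, event, X, ties)$loglik
      if (ll_new >= ll_old - 1e-12) break
      step <- step / 2
    }
    beta <- beta + step
    if (any(abs(beta) > 20))
      stop("divergence (possible perfect separation): |coef| > 20")
    if (abs(ll_new - ll_old) < 1e-10 * (abs(ll_old) + 1e-10)) break
    ll_old <- ll_new
    if (it == max_iter)
      stop(sprintf(
        "no convergence in %d iterations (last max |score| = %.3g)",
        max_iter, max(abs(pl$gradient))))
  }
  pl <- cox_partial(beta, time, event, X, ties)
  se <- sqrt(diag(solve(pl$information)))
  zcrit <- stats::qnorm(0.975)
  tab <- data.frame(
    term = colnames(X), coef = beta, se = se, hr = exp(beta),
    ci_lower = exp(beta - zcrit * se), ci_upper = exp(beta + zcrit * se),
    z = beta / se,
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE)
  structure(list(coefficients = tab, loglik = pl$loglik,
                 loglik_null = ll_null, iterations = it, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (%s ties), loglik %.3f\n",
              x$ties, x$loglik))
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Assemble post-index survival records
#'
#' Joins covariates, Charlson categories and cluster labels into the
#' analysis table for [km_fit()], [log_rank()] and [cox_fit()].
#'
#' @param covariates covariate table with time_days, death, age, sex and
#'   comorbidity flag columns.
#' @param labels cluster label per covariate row.
#' @param charlson_weights weight table for [charlson_category()].
#' @return data.frame(patient_id, time, event, age, sex, charlson,
#'   cluster).
#' @export
survival_records <- function(covariates, labels,
                             charlson_weights = default_charlson_weights()) {
  flags <- intersect(names(charlson_weights), colnames(covariates))
  data.frame(
    patient_id = covariates$patient_id,
    time = covariates$time_days,
    event = covariates$death,
    age = covariates$age,
    sex = factor(covariates$sex),
    charlson = droplevels(charlson_category(covariates[, flags, drop = FALSE],
                                            charlson_weights)),
    cluster = factor(labels),
    stringsAsFactors = FALSE)
}
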