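#' Split patients into high/low risk by a TTB cutoff
#'
#' High-risk means TTB strictly greater than the cutoff; boundary ties go to
#' the low-risk group. With `cutoff = "from-data"` the median of the supplied
#' TTB values is used — the study derived the cutoff from the manual
#' delineations of the cross-validation cohort and reused that same value on
#' external data, which this signature supports by passing the stored number.
#'
#' @param records data.frame with a `ttb` column (e.g. from
#'   [simulate_survival()]), or a numeric TTB vector.
#' @param cutoff `"from-data"` or a numeric cutoff in ml.
#' @return Logical vector (`TRUE` = high risk) with the applied cutoff in
#'   attribute `cutoff`.
#' @export
median_split <- function(records, cutoff = "from-data") {
  ttb <- if (is.data.frame(records)) records$ttb else as.numeric(records)
  if (length(ttb) == 0) stop("no records supplied")
  if (identical(cutoff, "from-data")) cutoff <- stats::median(ttb)
  structure(ttb > cutoff, cutoff = cutoff)
}

# Breslow or Efron partial log-likelihood, score and information for a single
# numeric covariate. Times are grouped into distinct event times.
cox_partial <- function(beta, time, event, x, ties = "breslow") {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ex <- exp(beta * x)
  # risk-set sums from the tail: subject i is at risk at all t <= time_i
  n <- length(time)
  cs0 <- rev(cumsum(rev(ex)))
  cs1 <- rev(cumsum(rev(x * ex)))
  cs2 <- rev(cumsum(rev(x * x * ex)))
  ll <- 0; u <- 0; info <- 0
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && time[j + 1L] == time[i]) j <- j + 1L
    dead <- which(event[i:j]) + i - 1L
    d <- length(dead)
    if (d > 0) {
      ll <- ll + beta * sum(x[dead])
      s0 <- cs0[i]; s1 <- cs1[i]; s2 <- cs2[i]
      if (ties == "breslow") {
        ll <- ll - d * log(s0)
        u <- u + sum(x[dead]) - d * s1 / s0
        info <- info + d * (s2 / s0 - (s1 / s0)^2)
      } else {  # efron
        t0 <- sum(exp(beta * x[dead]))
        t1 <- sum(x[dead] * exp(beta * x[dead]))
        t2 <- sum(x[dead]^2 * exp(beta * x[dead]))
        for (k in seq_len(d) - 1L) {
          a0 <- s0 - k / d * t0
          a1 <- s1 - k / d * t1
          a2 <- s2 - k / d * t2
          ll <- ll - log(a0)
          u <- u - a1 / a0
          info <- info + a2 / a0 - (a1 / a0)^2
        }
        u <- u + sum(x[dead])
      }
    }
    i <- j + 1L
  }
  list(loglik = ll, score = u, info = info)
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood for a single covariate by
#' Newton-Raphson to `|delta beta| < 1e-8`, with Breslow (default) or Efron
#' handling of tied event times, and reports the Wald test. Implemented
#' directly so the fit is verifiable against a one-dimensional grid search of
#' the partial likelihood; the `survival` package serves as an independent
#' cross-check in the test suite, not as the implementation.
#'
#' @param records data.frame with `time` (> 0) and `event` (logical) columns.
#' @param covariate numeric or logical vector, typically the binary high/low
#'   TTB group from [median_split()].
#' @param ties `"breslow"` or `"efron"`.
#' @param max_iter Newton-Raphson iteration cap.
#' @return An object of class `cox_result`: `beta`, `hazard_ratio`, `se`,
#'   `p_value`, `significant` (p < 0.05), `n_high`, `n_low`, `loglik`,
#'   `iterations`.
#' @export
cox_univariate <- function(records, covariate, ties = c("breslow", "efron"),
                           max_iter = 100L) {
  ties <- match.arg(ties)
  time <- records$time; event <- as.logical(records$event)
  x <- as.numeric(covariate)
  if (length(x) != length(time)) stop("covariate length mismatch")
  if (!any(event)) stop("no events observed; Cox model is undefined")
  if (stats::var(x) == 0) stop("covariate is constant; one group is empty")
  beta <- 0
  for (it in seq_len(max_iter)) {
    pl <- cox_partial(beta, time, event, x, ties)
    # flat likelihood (e.g. monotone under complete separation): the score
    # has vanished, so the current beta is the numerical maximizer
    if (abs(pl$score) < 1e-9) break
    if (pl$info <= 1e-12) stop("singular information matrix")
    step <- pl$score / pl$info
    beta <- beta + step
    if (abs(step) < 1e-8) break
    if (it == max_iter) stop("Newton-Raphson did not converge in ", max_iter,
                             " iterations")
  }
  final <- cox_partial(beta, time, event, x, ties)
  se <- 1 / sqrt(final$info)
  p <- 2 * stats::pnorm(-abs(beta) / se)
  is_binary <- all(x %in% c(0, 1))
  structure(list(beta = beta, hazard_ratio = exp(beta), se = se,
                 p_value = p, significant = p < 0.05,
                 n_high = if (is_binary) sum(x == 1) else NA_integer_,
                 n_low = if (is_binary) sum(x == 0) else NA_integer_,
                 loglik = final$loglik, iterations = it, ties = ties),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH (univariate, %s ties): HR = %.3f (beta = %.4f, se = %.4f)\n",
              x$ties, x$hazard_ratio, x$beta, x$se))
  cat(sprintf("  Wald p = %.4g%s", x$p_value,
              if (x$significant) " (significant at 0.05)\n" else "\n"))
  if (!is.na(x$n_high)) {
    cat(sprintf("  groups: %d high / %d low\n", x$n_high, x$n_low))
  }
  invisible(x)
}

#' Kaplan-Meier product-limit estimator per group
#'
#' @param records data.frame with `time` and `event` columns.
#' @param groups vector assigning each record to a group (e.g. the high/low
#'   split from [median_split()]).
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`; each group's curve starts at `surv = 1` at time 0 and drops only
#'   at event times.
#' @export
kaplan_meier <- function(records, groups) {
  time <- records$time; event <- as.logical(records$event)
  groups <- as.factor(groups)
  out <- lapply(levels(groups), function(g) {
    sel <- groups == g
    if (!any(sel)) stop("empty group: ", g)
    t <- time[sel]; e <- event[sel]
    ut <- sort(unique(t[e]))
    surv <- 1
    rows <- data.frame(group = g, time = 0, n_risk = sum(sel), n_event = 0L,
                       surv = 1)
    for (tt in ut) {
      n_risk <- sum(t >= tt)
      n_event <- sum(t == tt & e)
      surv <- surv * (1 - n_event / n_risk)
      rows <- rbind(rows, data.frame(group = g, time = tt, n_risk = n_risk,
                                     n_event = n_event, surv = surv))
    }
    rows
  })
  do.call(rbind, out)
}

#' Concordance of risk-group assignments between two methods
#'
#' Compares the binary high/low classifications derived from two delineation
#' methods (e.g. manual vs automated TTB) and, when an outcome-based truth
#' labelling is supplied, the per-method misclassification against it.
#'
#' @param groups_a,groups_b logical/binary vectors of equal length.
#' @param outcome_truth optional binary truth labelling; the criterion that
#'   defines it (e.g. observed death before a landmark) is the caller's
#'   choice and is passed in explicitly.
#' @return list with `discordant_pct` and, when a truth is given,
#'   `misclassified_a_pct` and `misclassified_b_pct` (all in percent).
#' @export
classification_concordance <- function(groups_a, groups_b,
                                       outcome_truth = NULL) {
  if (length(groups_a) != length(groups_b)) stop("group vectors differ in length")
  a <- as.logical(groups_a); b <- as.logical(groups_b)
  out <- list(discordant_pct = 100 * mean(a != b))
  if (!is.null(outcome_truth)) {
    tr <- as.logical(outcome_truth)
    if (length(tr) != length(a)) stop("outcome_truth length mismatch")
    out$misclassified_a_pct <- 100 * mean(a != tr)
    out$misclassified_b_pct <- 100 * mean(b != tr)
  }
  out
}
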