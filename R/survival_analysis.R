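#' Kaplan-Meier estimate with restricted mean
#'
#' Product-limit estimator with Greenwood variance, the median survival time
#' (smallest time with `S(t) <= 0.5`; `NA` when never reached) with its
#' confidence interval, and the restricted mean survival time — the area
#' under the curve up to the largest observed time — with a normal-theory
#' confidence interval. Events precede censorings at tied times (the
#' standard convention). Follow-up is in months.
#'
#' @param time Positive follow-up times.
#' @param event Logical (or 0/1) event indicators; `TRUE` =
#'   progression/death observed.
#' @param conf Confidence level (default 0.95).
#' @return List of class `km_curve`: `time`, `n_risk`, `n_event`, `surv`,
#'   `std_err` (Greenwood SE of S), `median`, `median_ci`, `rmean`,
#'   `rmean_se`, `rmean_ci`, `rmean_tmax`, `n`, `events`.
#' @export
km_estimate <- function(time, event, conf = 0.95) {
  if (length(time) == 0) stop("empty survival table", call. = FALSE)
  if (any(time <= 0)) stop("times must be > 0", call. = FALSE)
  event <- as.logical(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.int = conf, conf.type = "log")
  tmax <- max(time)
  tab <- summary(fit, rmean = tmax)$table
  sm <- summary(fit, censored = TRUE)
  z <- stats::qnorm((1 + conf) / 2)
  rmean <- unname(tab["rmean"])
  rmean_se <- unname(tab["se(rmean)"])
  lcl <- tab[grep("LCL", names(tab))]
  ucl <- tab[grep("UCL", names(tab))]
  structure(list(
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    surv = sm$surv, std_err = sm$std.err,
    median = unname(tab["median"]),
    median_ci = c(lower = unname(lcl), upper = unname(ucl)),
    rmean = rmean, rmean_se = rmean_se,
    rmean_ci = c(lower = rmean - z * rmean_se,
                 upper = rmean + z * rmean_se),
    rmean_tmax = tmax,
    n = length(time), events = sum(event)
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier: n = %d, events = %d; median %s; restricted mean %.2f (%.2f-%.2f) up to t = %.2f\n",
    x$n, x$events,
    if (is.na(x$median)) "not reached" else sprintf("%.2f", x$median),
    x$rmean, x$rmean_ci[1], x$rmean_ci[2], x$rmean_tmax))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison with hypergeometric variance; chi-square on
#' `k - 1` degrees of freedom. Invariant to relabeling the groups.
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels (>= 2 nonempty groups).
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  counts <- table(group)
  if (length(counts) < 2 || any(counts == 0))
    stop("need >= 2 nonempty groups", call. = FALSE)
  d <- survival::survdiff(survival::Surv(time, as.logical(event)) ~ group)
  df <- length(d$n) - 1
  list(chisq = unname(d$chisq), df = df,
       p = stats::pchisq(d$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization (Newton-Raphson, at most 50 iterations)
#' with Breslow handling of tied event times by default (Efron available).
#' Wald standard errors come from the inverse information. Monotone
#' likelihood (separation in time order) is flagged; coefficients are then
#' reported at the iteration cap. A covariate with no contrast (identical
#' for all subjects) is reported with coefficient 0 and hazard ratio 1.
#'
#' @param time,event As in [km_estimate()].
#' @param covariates Data frame or matrix of finite numeric covariates.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf Confidence level for hazard-ratio intervals.
#' @return List of class `cox_fit`: `coefficients`, `se`, `hr`, `hr_ci`
#'   (matrix), `loglik` (partial log-likelihood at the solution),
#'   `score_test` (score chi-square at beta = 0), `monotone` (separation
#'   flag), `n`, `events`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron"),
                    conf = 0.95) {
  ties <- match.arg(ties)
  event <- as.logical(event)
  if (sum(event) < 1) stop("need >= 1 event", call. = FALSE)
  X <- as.matrix(as.data.frame(covariates))
  if (!all(is.finite(X))) stop("covariates must be finite", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  const <- apply(X, 2, function(v) max(v) == min(v))
  coefs <- stats::setNames(rep(0, ncol(X)), colnames(X))
  ses <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  monotone <- FALSE
  loglik <- NA_real_
  score <- NA_real_

  if (any(!const)) {
    Xf <- X[, !const, drop = FALSE]
    monotone_msg <- paste0("coefficient may be infinite|beta may be infinite|",
                           "Loglik converged before|did not converge")
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ Xf, ties = ties,
                      control = survival::coxph.control(iter.max = 50)),
      warning = function(w) {
        if (grepl(monotone_msg, conditionMessage(w))) monotone <<- TRUE
        invokeRestart("muffleWarning")
      })
    coefs[!const] <- unname(stats::coef(fit))
    vd <- diag(fit$var)
    ses[!const] <- ifelse(vd >= 0, sqrt(vd), NA_real_)
    loglik <- fit$loglik[2]
    score <- unname(fit$score)
  }
  z <- stats::qnorm((1 + conf) / 2)
  hr_ci <- cbind(lower = exp(coefs - z * ses), upper = exp(coefs + z * ses))
  structure(list(coefficients = coefs, se = ses, hr = exp(coefs),
                 hr_ci = hr_ci, loglik = loglik, score_test = score,
                 monotone = monotone, n = length(time),
                 events = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (n = %d, events = %d)%s\n", x$n, x$events,
              if (x$monotone) " [monotone likelihood]" else ""))
  for (i in seq_along(x$coefficients))
    cat(sprintf("  %s: HR %.3f (%.3f-%.3f)\n",
                names(x$coefficients)[i], x$hr[i],
                x$hr_ci[i, 1], x$hr_ci[i, 2]))
  invisible(x)
}

#' Marker-dichotomized survival report
#'
#' For every marker, dichotomizes its scores at the given cut-off,
#' estimates the Kaplan-Meier restricted mean survival (with confidence
#' interval) per low/high group, and compares the groups by the log-rank
#' test — one row pair per marker, the layout of a published
#' marker-survival table. Markers with an empty group after the cut are
#' skipped with a warning.
#'
#' @param scores Long score data frame (`sample_id`, `gene`, `score`), e.g.
#'   from [normalize_ct()] restricted to patients.
#' @param cuts Named numeric vector of fixed cut-offs (names = markers), or
#'   a single `"median"` / `"p70"` applied per marker.
#' @param surv Data frame with `sample_id`, `time`, `event`.
#' @param endpoint Label recorded in the output (e.g. `"OS"`, `"PFS"`).
#' @param conf Confidence level.
#' @return Data frame: `marker`, `endpoint`, `group`, `n`, `events`,
#'   `mean`, `mean_lcl`, `mean_ucl`, `logrank_p`, `cutoff`.
#' @export
marker_survival_report <- function(scores, cuts, surv, endpoint = "OS",
                                   conf = 0.95) {
  markers <- if (is.numeric(cuts)) names(cuts) else unique(scores$gene)
  if (is.numeric(cuts) && is.null(names(cuts)))
    stop("numeric 'cuts' must be named by marker", call. = FALSE)
  rows <- list()
  for (m in markers) {
    s <- scores[scores$gene == m & !is.na(scores$score), ]
    dat <- merge(s, surv, by = "sample_id")
    if (nrow(dat) == 0) {
      warning("marker ", m, ": no samples joinable to survival data; skipped",
              call. = FALSE)
      next
    }
    cut_m <- if (is.numeric(cuts)) cuts[[m]] else cuts
    grp <- suppressWarnings(dichotomize(dat$score, cut_m))
    if (any(table(grp) == 0)) {
      warning("marker ", m, ": empty ",
              names(which(table(grp) == 0))[1],
              " group at cut ", format(attr(grp, "cutoff")), "; skipped",
              call. = FALSE)
      next
    }
    lr <- logrank_test(dat$time, dat$event, grp)
    for (g in levels(grp)) {
      km <- km_estimate(dat$time[grp == g], dat$event[grp == g], conf)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, endpoint = endpoint, group = g,
        n = km$n, events = km$events,
        mean = km$rmean, mean_lcl = km$rmean_ci[1],
        mean_ucl = km$rmean_ci[2],
        logrank_p = lr$p, cutoff = attr(grp, "cutoff"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}
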