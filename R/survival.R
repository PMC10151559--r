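#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the curve as a plain
#' table. Events tied with censoring at the same time follow the standard
#' convention: events precede censorings.
#'
#' @param times non-negative follow-up times (months).
#' @param events event indicators, 1 = event observed, 0 = censored.
#' @param endpoint endpoint name stored as an attribute.
#' @return data.frame with `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   at each distinct observed time.
#' @export
km_estimate <- function(times, events, endpoint = "OS") {
  check_survival_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  attr(out, "endpoint") <- endpoint
  out
}

#' k-sample log-rank test
#'
#' Standard log-rank chi-square on `k - 1` degrees of freedom via
#' [survival::survdiff()], with the per-group observed and expected event
#' counts exposed.
#'
#' @param times follow-up times.
#' @param events event indicators (0/1).
#' @param groups group labels (>= 2 non-empty groups).
#' @return `list(chi2, df, p, observed, expected, n)`.
#' @export
logrank_test <- function(times, events, groups) {
  check_survival_input(times, events)
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       observed = stats::setNames(as.vector(sd$obs), levels(groups)),
       expected = stats::setNames(as.vector(sd$exp), levels(groups)),
       n = stats::setNames(as.vector(sd$n), levels(groups)))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood Newton-Raphson fit with Breslow tie handling
#' ([survival::coxph()]). Non-convergence and monotone-likelihood
#' (complete-separation) fits are flagged rather than returned silently; a
#' constant covariate carries no information and returns `beta = 0` with
#' infinite standard error, flagged.
#'
#' @param times follow-up times.
#' @param events event indicators (0/1; at least one event required).
#' @param covariate numeric (or binary) per-sample covariate.
#' @return `list(beta, se, p, flagged, n_event)`.
#' @export
cox_univariate <- function(times, events, covariate) {
  check_survival_input(times, events)
  if (sum(events) < 1) stop("need at least one observed event")
  x <- as.numeric(covariate)
  if (length(x) != length(times)) stop("covariate length mismatch")
  if (stats::var(x) == 0) {
    return(list(beta = 0, se = Inf, p = NA_real_, flagged = TRUE,
                n_event = sum(events)))
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 20) flagged <- TRUE
  list(beta = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)),
       flagged = flagged, n_event = sum(events))
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative-case / dynamic-control AUC at fixed horizons: at horizon `t`,
#' cases are samples with an observed event by `t`, controls are samples
#' still at risk beyond `t`. Pairs are weighted by the inverse of the
#' censoring-distribution Kaplan-Meier estimate (evaluated just before the
#' case's event time for cases, at `t` for controls), and tied marker values
#' receive half credit. Horizons with no case or no control yield `NA` with
#' a warning. With no censoring all weights are 1 and the estimate reduces
#' to plain exhaustive pair counting.
#'
#' @param times follow-up times.
#' @param events event indicators (0/1).
#' @param marker numeric risk marker (higher = more at risk).
#' @param horizons evaluation times (default `c(12, 24, 36, 48, 60)`
#'   months).
#' @return data.frame with `horizon`, `auc`, `n_case`, `n_control`;
#'   attribute `method = "IPCW cumulative/dynamic"`.
#' @export
time_dependent_auc <- function(times, events, marker,
                               horizons = c(12, 24, 36, 48, 60)) {
  check_survival_input(times, events)
  stopifnot(length(marker) == length(times))
  # censoring-distribution KM (events flipped); G(t) right-continuous,
  # g_left(t) = G(t-)
  cfit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  G <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  G_left <- stats::stepfun(cfit$time, c(1, cfit$surv), right = TRUE)

  res <- lapply(horizons, function(h) {
    case <- times <= h & events == 1
    ctrl <- times > h
    if (!any(case) || !any(ctrl)) {
      warning("no case or no control at horizon ", h, "; AUC undefined")
      return(data.frame(horizon = h, auc = NA_real_,
                        n_case = sum(case), n_control = sum(ctrl)))
    }
    w_case <- 1 / pmax(G_left(times[case]), .Machine$double.eps)
    w_ctrl <- rep(1 / pmax(G(h), .Machine$double.eps), sum(ctrl))
    mc <- marker[case]
    md <- marker[ctrl]
    conc <- outer(mc, md, ">") + 0.5 * outer(mc, md, "==")
    num <- sum((w_case %o% w_ctrl) * conc)
    den <- sum(w_case) * sum(w_ctrl)
    data.frame(horizon = h, auc = num / den,
               n_case = sum(case), n_control = sum(ctrl))
  })
  out <- do.call(rbind, res)
  attr(out, "method") <- "IPCW cumulative/dynamic"
  out
}

check_survival_input <- function(times, events) {
  if (length(times) == 0) stop("empty survival input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and non-negative")
  }
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  invisible(TRUE)
}
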