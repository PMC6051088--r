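#' Assign patients to expression tertiles
#'
#' Patients are sorted from high to low expression (ties broken by a stable
#' sort on patient id); the top floor(n/3) form the high group, the bottom
#' floor(n/3) the low group, and the remainder stays in mid so the extreme
#' groups remain balanced.
#'
#' @param expression Named numeric vector (names = patient ids), length >= 6.
#' @return Named factor with levels low, mid, high.
#' @export
tertile_groups <- function(expression) {
  n <- length(expression)
  if (n < 6) stop("need at least 6 patients for tertile grouping")
  if (is.null(names(expression))) stop("expression must be named by patient")
  if (length(unique(expression)) == 1) {
    stop("all expression values are equal: tertile grouping is undefined")
  }
  ord <- order(-expression, names(expression))
  q <- n %/% 3L
  grp <- rep("mid", n)
  grp[ord[seq_len(q)]] <- "high"
  grp[ord[(n - q + 1L):n]] <- "low"
  setNames(factor(grp, levels = c("low", "mid", "high")), names(expression))
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times <= t of (1 - d_j / n_j).  Censored-only data
#' give S identically 1.
#'
#' @param time Follow-up times in days, >= 0.
#' @param event 1 = death, 0 = censored.
#' @return data.frame with columns time (distinct event times), n_risk,
#'   n_event, survival.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("no records")
  if (any(time < 0)) stop("negative follow-up time")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  ev_times <- sort(unique(time[event == 1]))
  if (length(ev_times) == 0) {
    return(data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), survival = numeric()))
  }
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1),
                    numeric(1))
  data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
             survival = cumprod(1 - n_event / n_risk))
}

#' Weighted log-rank test (Gehan-Breslow-Wilcoxon or log-rank)
#'
#' At each distinct event time j with n_j at risk (pooled), d_j events and
#' n_1j / d_1j at risk / events in group 1:
#' U = sum w_j (d_1j - d_j n_1j / n_j),
#' V = sum w_j^2 d_j (n_1j / n_j)(1 - n_1j / n_j)(n_j - d_j)/(n_j - 1),
#' statistic = U^2 / V ~ chi-square(1).  Gehan-Breslow-Wilcoxon uses
#' w_j = n_j (emphasizing early differences); the log-rank uses w_j = 1.
#' Event times with n_j = 1 contribute nothing to V.
#'
#' @param time,event Follow-up times and status (1 = death).
#' @param group Factor or vector with exactly two levels present.
#' @param weights `"gehan_breslow_wilcoxon"` (default) or `"log_rank"`.
#' @return List of class `knmir_survtest` with statistic, p, weights_kind,
#'   n_per_group.
#' @export
weighted_logrank <- function(time, event, group,
                             weights = c("gehan_breslow_wilcoxon",
                                         "log_rank")) {
  weights <- match.arg(weights)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("exactly two non-empty groups are required")
  if (sum(event) == 0) stop("no events: the test is undefined")
  ev_times <- sort(unique(time[event == 1]))
  g1 <- group == levels(group)[1]

  U <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(time == t & event == 1)
    n_1j <- sum(at_risk & g1)
    d_1j <- sum(time == t & event == 1 & g1)
    w <- if (weights == "gehan_breslow_wilcoxon") n_j else 1
    U <- U + w * (d_1j - d_j * n_1j / n_j)
    if (n_j > 1) {
      V <- V + w^2 * d_j * (n_1j / n_j) * (1 - n_1j / n_j) *
        (n_j - d_j) / (n_j - 1)
    }
  }
  stat <- if (V > 0) U^2 / V else 0
  p <- if (V > 0) stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1
  structure(list(statistic = stat, p = p, weights_kind = weights,
                 n_per_group = table(group), U = U, V = V),
            class = "knmir_survtest")
}

#' @export
print.knmir_survtest <- function(x, ...) {
  cat(sprintf("%s test: chi-square = %.4f, p = %.4g (n = %s)\n",
              x$weights_kind, x$statistic, x$p,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Tertile survival association for one locus
#'
#' Groups patients by expression tertile and compares the high and low
#' tertiles (mid excluded; `high_vs_rest` pools mid with low) with both the
#' Gehan-Breslow-Wilcoxon and the log-rank weighting.
#'
#' @param expression Named numeric vector of per-patient expression.
#' @param time,event Per-patient follow-up and status, aligned with
#'   `expression` by name.
#' @param comparison `"high_vs_low"` (default) or `"high_vs_rest"`.
#' @return List with `groups`, `gbw`, `log_rank`, and per-group
#'   [km_estimate()] curves.
#' @export
survival_association <- function(expression, time, event,
                                 comparison = c("high_vs_low",
                                                "high_vs_rest")) {
  comparison <- match.arg(comparison)
  groups <- tertile_groups(expression)
  ids <- names(groups)
  time <- time[ids]; event <- event[ids]
  if (comparison == "high_vs_low") {
    keep <- groups %in% c("high", "low")
    g <- droplevels(groups[keep])
    t2 <- time[keep]; e2 <- event[keep]
  } else {
    g <- factor(ifelse(groups == "high", "high", "rest"),
                levels = c("rest", "high"))
    t2 <- time; e2 <- event
  }
  list(
    groups = groups,
    gbw = weighted_logrank(t2, e2, g, "gehan_breslow_wilcoxon"),
    log_rank = weighted_logrank(t2, e2, g, "log_rank"),
    km = lapply(split(seq_along(t2), g), function(i) {
      km_estimate(t2[i], e2[i])
    })
  )
}
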