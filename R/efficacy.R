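#' Ellipsoid tumour volume from caliper measurements
#'
#' \deqn{V = \frac{4}{3}\pi \frac{W}{2}\frac{L}{2}\frac{H}{2}
#'         = \frac{\pi}{6} W L H} in mm^3.
#'
#' @param W,L,H Caliper width, length, height in mm; all > 0. Vectorised.
#' @return Volume in mm^3.
#' @examples
#' tumour_volume(2, 2, 2)   # 4*pi/3
#' @export
tumour_volume <- function(W, L, H) {
  if (any(!is.finite(c(W, L, H))) || any(c(W, L, H) <= 0))
    stop("caliper dimensions must be positive", call. = FALSE)
  (pi / 6) * W * L * H
}

#' Relative tumour growth from baseline
#'
#' Per-day tumour volumes divided by the volume at the baseline day.
#'
#' @param track Data frame with columns `day`, `W_mm`, `L_mm`, `H_mm`
#'   (days increasing).
#' @param baseline_day Day index of the baseline measurement; defaults to
#'   the first day in the track. Must be present in `track$day`.
#' @return Data frame with `day`, `volume_mm3`, `rel_growth`.
#' @export
relative_growth <- function(track, baseline_day = NULL) {
  stopifnot(is.data.frame(track),
            all(c("day", "W_mm", "L_mm", "H_mm") %in% names(track)))
  if (is.unsorted(track$day, strictly = TRUE))
    stop("'day' must be strictly increasing", call. = FALSE)
  if (is.null(baseline_day)) baseline_day <- track$day[1L]
  i0 <- match(baseline_day, track$day)
  if (is.na(i0))
    stop("baseline day ", baseline_day, " has no measurement", call. = FALSE)
  v <- tumour_volume(track$W_mm, track$L_mm, track$H_mm)
  if (v[i0] <= 0) stop("baseline volume must be positive", call. = FALSE)
  data.frame(day = track$day, volume_mm3 = v, rel_growth = v / v[i0])
}

#' First tumour-doubling day
#'
#' Earliest measured day at which the relative growth from baseline reaches
#' 2. The first crossing is returned even if the tumour later regresses.
#'
#' @inheritParams relative_growth
#' @return The day of first doubling, or `NA` if never reached.
#' @export
doubling_event <- function(track, baseline_day = NULL) {
  rg <- relative_growth(track, baseline_day)
  hit <- which(rg$rel_growth >= 2)
  if (!length(hit)) NA_real_ else rg$day[hit[1L]]
}

#' Kaplan-Meier product-limit estimator
#'
#' Survival step function for right-censored time-to-event data (the
#' tumour-related-death endpoint: first day the volume exceeds 2000 mm^3).
#' Computed via [survival::survfit()].
#'
#' @param time_days Event/censoring times, \eqn{\ge 0}.
#' @param event 1 (or `TRUE`) = event, 0 = censored.
#' @return Object of class `"km_curve"`: a list with `table` (columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`) and `step`, a right-
#'   continuous step function `t -> S(t)` with `S(0^-) = 1`.
#' @examples
#' km <- km_estimator(c(10, 20, 25, 35, 40, 45, 15, 30),
#'                    c(1, 1, 1, 1, 1, 1, 0, 0))
#' km$step(22)
#' @export
km_estimator <- function(time_days, event) {
  if (any(time_days < 0)) stop("negative event times", call. = FALSE)
  if (!length(time_days)) stop("no survival records", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time_days, as.integer(event)) ~ 1)
  tab <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv)
  et <- tab$time[tab$n_event > 0]
  es <- tab$surv[tab$n_event > 0]
  step <- if (length(et)) stats::stepfun(et, c(1, es), right = FALSE)
  else function(t) rep(1, length(t))
  structure(list(table = tab, step = step), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", sum(x$table$n_event), "events,",
      sum(x$table$n_censor), "censored\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ..., xlab = "days", ylab = "S(t)") {
  tt <- c(0, x$table$time)
  graphics::plot(tt, x$step(tt), type = "s", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Pairwise log-rank (Mantel-Cox) test
#'
#' Observed-versus-expected chi-square on the pooled risk sets of two
#' groups, with tied event times handled by the standard pooled-risk-set
#' treatment. Computed via [survival::survdiff()] (`rho = 0`).
#'
#' @param time_a,event_a Times and event indicators for group A.
#' @param time_b,event_b Times and event indicators for group B.
#' @return List with `chisq` (1 df), `p_value`, `n_events`.
#' @details With no events in either group the hazards are indistinguishable
#'   and `p = 1` is returned with a warning.
#' @export
logrank_pair <- function(time_a, event_a, time_b, event_b) {
  ea <- as.integer(event_a); eb <- as.integer(event_b)
  if (any(c(time_a, time_b) < 0)) stop("negative event times", call. = FALSE)
  if (sum(ea) + sum(eb) == 0) {
    warning("no events in either group; p = 1", call. = FALSE)
    return(list(chisq = 0, p_value = 1, n_events = 0L))
  }
  time <- c(time_a, time_b)
  event <- c(ea, eb)
  grp <- factor(rep(c("a", "b"), c(length(time_a), length(time_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- unname(sd$chisq)
  list(chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n_events = sum(event))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of comparisons, \eqn{\ge 1}.
#' @return Per-comparison threshold `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 6)   # the 6-comparison threshold
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(m) || m < 1 || m != as.integer(m))
    stop("'m' must be a positive integer", call. = FALSE)
  alpha / m
}
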