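#' Nuclide physical constants
#'
#' Container for the physical constants of one radionuclide: half-life,
#' derived decay constant, and (optionally) the gamma line and gamma-counter
#' energy window used to measure it.
#'
#' @param name Nuclide label, e.g. `"Ac-225"`.
#' @param half_life Half-life, in the unit given by `unit`. Must be positive.
#' @param unit Time unit of `half_life`: one of `"s"`, `"min"`, `"h"`, `"d"`.
#'   Stored internally in seconds.
#' @param gamma_line_kev Optional gamma emission energy in keV.
#' @param counting_window_kev Optional length-2 numeric, the `[lo, hi]` keV
#'   window used on the gamma counter. Must be a non-empty interval.
#' @param branching_fraction Fraction of parent decays feeding this nuclide,
#'   in (0, 1]. Defaults to 1.
#'
#' @return An object of class `"nuclide"`: a list with fields `name`,
#'   `half_life_s`, `lambda_per_s` (= ln 2 / half-life), `gamma_line_kev`,
#'   `counting_window_kev`, `branching_fraction`.
#'
#' @examples
#' bi213 <- nuclide("Bi-213", 45.6, "min", gamma_line_kev = 440,
#'                  counting_window_kev = c(380, 520))
#' nuclide_lambda(bi213, "min")   # ln(2)/45.6
#' @export
nuclide <- function(name, half_life, unit = c("s", "min", "h", "d"),
                    gamma_line_kev = NULL, counting_window_kev = NULL,
                    branching_fraction = 1) {
  unit <- match.arg(unit)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life) || length(half_life) != 1L ||
      !is.finite(half_life) || half_life <= 0)
    stop("'half_life' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(branching_fraction) || length(branching_fraction) != 1L ||
      branching_fraction <= 0 || branching_fraction > 1)
    stop("'branching_fraction' must lie in (0, 1]", call. = FALSE)
  if (!is.null(counting_window_kev)) {
    if (length(counting_window_kev) != 2L ||
        !all(is.finite(counting_window_kev)) ||
        counting_window_kev[2L] <= counting_window_kev[1L])
      stop("'counting_window_kev' must be a non-empty interval c(lo, hi)",
           call. = FALSE)
  }
  hl_s <- half_life * .time_unit_seconds(unit)
  structure(list(
    name = name,
    half_life_s = hl_s,
    lambda_per_s = decay_constant(hl_s),
    gamma_line_kev = gamma_line_kev,
    counting_window_kev = counting_window_kev,
    branching_fraction = branching_fraction
  ), class = "nuclide")
}

.time_unit_seconds <- function(unit) {
  switch(unit, s = 1, min = 60, h = 3600, d = 86400,
         stop("unknown time unit: ", unit, call. = FALSE))
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s  t1/2 = %g s (%g min), lambda = %.6g s^-1\n",
              x$name, x$half_life_s, x$half_life_s / 60, x$lambda_per_s))
  if (!is.null(x$counting_window_kev))
    cat(sprintf("  counting window: %g-%g keV\n",
                x$counting_window_kev[1], x$counting_window_kev[2]))
  invisible(x)
}

#' Decay constant of a nuclide in a chosen time unit
#'
#' @param x A [nuclide()] object.
#' @param unit Time unit for the returned rate (per second by default).
#' @return Decay constant in `1/unit`.
#' @export
nuclide_lambda <- function(x, unit = c("s", "min", "h", "d")) {
  stopifnot(inherits(x, "nuclide"))
  unit <- match.arg(unit)
  x$lambda_per_s * .time_unit_seconds(unit)
}

#' Decay constant from half-life
#'
#' `lambda = ln(2) / t_half`. Unit-agnostic: the returned rate is in the
#' reciprocal of the input unit.
#'
#' @param half_life Positive half-life (any time unit).
#' @return Decay constant, `1/unit`.
#' @examples
#' decay_constant(45.6)  # min^-1 if input is minutes
#' @export
decay_constant <- function(half_life) {
  if (!is.numeric(half_life) || any(!is.finite(half_life)) ||
      any(half_life <= 0))
    stop("'half_life' must be positive and finite", call. = FALSE)
  log(2) / half_life
}

#' Daughter ingrowth activity under a constant parent
#'
#' Activity of a short-lived daughter growing in towards equilibrium with a
#' parent whose activity is treated as constant over the measurement:
#' \deqn{A_2(t) = A_1 (1 - e^{-\lambda_2 t}) + A_2(0) e^{-\lambda_2 t}.}
#' This is the model fitted to post-sacrifice organ counting series: the
#' asymptote `A_parent` is the carrier-bound equilibrium activity and
#' `A_daughter_0` the total daughter activity at the time origin.
#'
#' @param A_parent Parent (equilibrium) activity amplitude, \eqn{\ge 0}.
#' @param A_daughter_0 Daughter activity at `t = 0`, \eqn{\ge 0}.
#' @param lambda2 Daughter decay constant (> 0), in `1/unit(t)`.
#' @param t Time(s) since the origin, \eqn{\ge 0}; vectorised.
#' @return Daughter activity at each `t`, same unit as the amplitudes.
#' @examples
#' lam <- decay_constant(45.6)               # min^-1
#' ingrowth_activity(100, 0, lam, 45.6)      # one half-life: 50
#' @export
ingrowth_activity <- function(A_parent, A_daughter_0, lambda2, t) {
  if (!is.numeric(A_parent) || !is.numeric(A_daughter_0) ||
      any(A_parent < 0) || any(A_daughter_0 < 0))
    stop("activities must be non-negative", call. = FALSE)
  if (!is.numeric(lambda2) || any(lambda2 <= 0))
    stop("'lambda2' must be positive", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  e <- exp(-lambda2 * t)
  A_parent * (1 - e) + A_daughter_0 * e
}

#' Decay-correct an activity to an earlier reference time
#'
#' Multiplies a measured activity by `exp(lam * dt)` so that it refers to a
#' time `dt` earlier than the measurement (e.g. back to injection time).
#'
#' @param activity Measured activity.
#' @param lam Decay constant, `1/unit(dt)`.
#' @param dt Elapsed time between the reference time and the measurement
#'   (\eqn{\ge 0}; `dt = 0` is a no-op).
#' @return Activity referenced to the earlier time.
#' @export
decay_correct <- function(activity, lam, dt) {
  stopifnot(is.numeric(activity), is.numeric(lam), is.numeric(dt))
  activity * exp(lam * dt)
}

#' Secular/transient equilibrium activity ratio
#'
#' For a parent-daughter pair with \eqn{\lambda_2 > \lambda_1}, the
#' asymptotic daughter/parent activity ratio is
#' \eqn{\lambda_2 / (\lambda_2 - \lambda_1)}; it tends to 1 (secular
#' equilibrium) as \eqn{\lambda_1 \to 0}.
#'
#' @param lambda1 Parent decay constant (> 0).
#' @param lambda2 Daughter decay constant (> `lambda1`).
#' @return Unitless equilibrium activity ratio.
#' @export
equilibrium_activity_ratio <- function(lambda1, lambda2) {
  if (!is.numeric(lambda1) || !is.numeric(lambda2) ||
      any(lambda1 <= 0) || any(lambda2 <= lambda1))
    stop("need lambda2 > lambda1 > 0 (no equilibrium otherwise)",
         call. = FALSE)
  lambda2 / (lambda2 - lambda1)
}

#' Assemble a decay chain
#'
#' A decay chain is a directed acyclic graph of [nuclide()] members with
#' parent-to-daughter edges carrying branching fractions.
#'
#' @param members List of [nuclide()] objects, ordered so that parents
#'   precede daughters.
#' @param edges Data frame with columns `parent`, `daughter` (nuclide names)
#'   and `branching` (fraction of parent decays feeding that daughter).
#'   `NULL` (default) links consecutive members with branching 1.
#' @return Object of class `"decay_chain"`.
#' @examples
#' ch <- ac225_chain()
#' bateman_activities(ch, c("Ac-225" = 100), t = 300, unit = "min")
#' @export
decay_chain <- function(members, edges = NULL) {
  stopifnot(is.list(members), length(members) >= 1L,
            all(vapply(members, inherits, logical(1), "nuclide")))
  nm <- vapply(members, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate nuclide names", call. = FALSE)
  if (is.null(edges)) {
    edges <- if (length(nm) > 1L)
      data.frame(parent = nm[-length(nm)], daughter = nm[-1L],
                 branching = 1, stringsAsFactors = FALSE)
    else
      data.frame(parent = character(), daughter = character(),
                 branching = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges),
            all(c("parent", "daughter", "branching") %in% names(edges)))
  if (nrow(edges)) {
    if (!all(edges$parent %in% nm) || !all(edges$daughter %in% nm))
      stop("edge endpoints must be chain members", call. = FALSE)
    if (any(edges$branching <= 0 | edges$branching > 1))
      stop("branching fractions must lie in (0, 1]", call. = FALSE)
    out <- tapply(edges$branching, edges$parent, sum)
    if (any(out > 1 + 1e-12))
      stop("outgoing branching fractions exceed 1 for: ",
           paste(names(out)[out > 1 + 1e-12], collapse = ", "), call. = FALSE)
  }
  # acyclicity + every non-root has a parent, via topological elimination
  .chain_topo_order(nm, edges)
  structure(list(members = members, names = nm, edges = edges),
            class = "decay_chain")
}

.chain_topo_order <- function(nm, edges) {
  remaining <- nm
  order <- character(0)
  repeat {
    roots <- remaining[!(remaining %in% edges$daughter[
      edges$parent %in% remaining])]
    if (!length(roots)) {
      if (length(remaining)) stop("decay chain contains a cycle",
                                  call. = FALSE)
      break
    }
    order <- c(order, roots)
    remaining <- setdiff(remaining, roots)
    if (!length(remaining)) break
  }
  order
}

#' @export
print.decay_chain <- function(x, ...) {
  cat("<decay_chain> ", paste(x$names, collapse = " -> "), "\n")
  invisible(x)
}

#' Default Ac-225 chain used for gamma-counting analysis
#'
#' Ac-225 (10 d) -> Fr-221 (4.8 min) -> Bi-213 (45.6 min), with the
#' sub-second At-217 step merged into the Fr-221 -> Bi-213 edge (it is
#' instantaneous at minute resolution) and the branch below Bi-213 omitted
#' (nothing below Bi-213 is measured). Counting windows are 170-270 keV for
#' Fr-221 (218 keV line) and 380-520 keV for Bi-213 (440 keV line).
#'
#' @param include_fr If `FALSE`, return the two-member Ac-225 -> Bi-213
#'   chain (Fr-221 merged as well), convenient for the ingrowth model.
#' @return A [decay_chain()].
#' @export
ac225_chain <- function(include_fr = TRUE) {
  ac <- nuclide("Ac-225", 10, "d")
  fr <- nuclide("Fr-221", 4.8, "min", gamma_line_kev = 218,
                counting_window_kev = c(170, 270))
  bi <- nuclide("Bi-213", 45.6, "min", gamma_line_kev = 440,
                counting_window_kev = c(380, 520))
  if (include_fr) decay_chain(list(ac, fr, bi)) else decay_chain(list(ac, bi))
}

#' Read a nuclide table from a YAML config
#'
#' Expected layout: a top-level list `nuclides`, each entry with keys
#' `name`, `half_life_value`, `half_life_unit` (s/min/h/d), and optionally
#' `gamma_line_kev`, `window_kev` (length-2), `branching`.
#'
#' @param path Path to the YAML file.
#' @return A named list of [nuclide()] objects.
#' @export
read_nuclide_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$nuclides)) cfg$nuclides else cfg
  out <- lapply(entries, function(e) {
    nuclide(e$name, e$half_life_value, e$half_life_unit,
            gamma_line_kev = e$gamma_line_kev,
            counting_window_kev = if (!is.null(e$window_kev))
              as.numeric(e$window_kev),
            branching_fraction = if (!is.null(e$branching)) e$branching else 1)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
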