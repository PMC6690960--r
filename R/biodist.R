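#' Injected-dose counting standard
#'
#' A counted aliquot representing a known fraction of the injected dose,
#' used to normalise organ count rates to percent injected dose per gram.
#'
#' @param counts_rate Count rate of the standard (e.g. cpm), > 0.
#' @param fraction_of_injected Fraction of the injected dose the standard
#'   represents, in (0, 1].
#' @return Object of class `"dose_standard"`.
#' @export
dose_standard <- function(counts_rate, fraction_of_injected = 1) {
  if (!is.numeric(counts_rate) || counts_rate <= 0)
    stop("'counts_rate' must be positive", call. = FALSE)
  if (!is.numeric(fraction_of_injected) || fraction_of_injected <= 0 ||
      fraction_of_injected > 1)
    stop("'fraction_of_injected' must lie in (0, 1]", call. = FALSE)
  structure(list(counts_rate = counts_rate,
                 fraction_of_injected = fraction_of_injected),
            class = "dose_standard")
}

#' Percent injected dose per gram
#'
#' Converts an organ count rate into %ID/g against a dose standard:
#' \deqn{100 \cdot \frac{rate / (rate_{std} / f_{std})}{mass}.}
#' Both rates can be decay-corrected to a common reference time (typically
#' injection time, with the parent Ac-225 decay constant, since equilibrium
#' windows track the parent).
#'
#' @param sample_rate Organ count rate.
#' @param mass_g Organ mass in grams, > 0.
#' @param standard A [dose_standard()].
#' @param lam Decay constant used for the correction (default 0: rates
#'   already co-referenced).
#' @param dt_sample,dt_standard Time elapsed from the common reference to
#'   each count.
#' @return %ID/g (unitless percent).
#' @examples
#' std <- dose_standard(1000, fraction_of_injected = 0.01)
#' percent_id_per_gram(470, 0.1, std)   # 4.7 %ID/g
#' @export
percent_id_per_gram <- function(sample_rate, mass_g, standard, lam = 0,
                                dt_sample = 0, dt_standard = 0) {
  stopifnot(inherits(standard, "dose_standard"))
  if (!is.numeric(mass_g) || any(mass_g <= 0))
    stop("'mass_g' must be positive", call. = FALSE)
  if (any(sample_rate < 0))
    stop("'sample_rate' must be non-negative", call. = FALSE)
  s <- decay_correct(sample_rate, lam, dt_sample)
  id_rate <- decay_correct(standard$counts_rate, lam, dt_standard) /
    standard$fraction_of_injected
  100 * (s / id_rate) / mass_g
}

#' Carrier loading efficiency
#'
#' Fraction of the total activity recovered in the carrier-containing
#' size-exclusion fractions, as a percentage.
#'
#' @param fraction_activities Numeric vector of per-fraction activities.
#' @param selected Indices (or logical mask) of the carrier-containing
#'   fractions.
#' @return Percent of total activity in the selected fractions.
#' @export
loading_efficiency <- function(fraction_activities, selected) {
  stopifnot(is.numeric(fraction_activities))
  total <- sum(fraction_activities)
  if (total <= 0) stop("total activity must be positive", call. = FALSE)
  sel <- fraction_activities[selected]
  if (!length(sel)) {
    warning("no fractions selected; loading efficiency is 0", call. = FALSE)
    return(0)
  }
  100 * sum(sel) / total
}

#' iTLC labelling efficiency
#'
#' Fraction of the total lane activity that migrated with the mobile phase
#' (at or beyond the front threshold), as a percentage.
#'
#' @param positions Numeric vector of lane positions.
#' @param intensities Activity/intensity at each position, \eqn{\ge 0}.
#' @param front_threshold Position at/above which activity counts as having
#'   travelled with the mobile phase.
#' @return Percent labelling efficiency.
#' @export
itlc_labelling_efficiency <- function(positions, intensities,
                                      front_threshold) {
  stopifnot(is.numeric(positions), is.numeric(intensities),
            length(positions) == length(intensities))
  if (any(intensities < 0))
    stop("intensities must be non-negative", call. = FALSE)
  total <- sum(intensities)
  if (total <= 0) stop("all-zero lane profile", call. = FALSE)
  100 * sum(intensities[positions >= front_threshold]) / total
}

#' Ratio of two organs' %ID/g
#'
#' @param a,b %ID/g values or rows/lists with a `pct_id_per_g` element
#'   (numerator `a`, denominator `b`).
#' @return Unitless ratio `a / b`.
#' @export
organ_ratio <- function(a, b) {
  get_val <- function(x) {
    if (is.numeric(x)) x else as.list(x)$pct_id_per_g
  }
  va <- get_val(a); vb <- get_val(b)
  if (!is.numeric(vb) || any(vb <= 0))
    stop("denominator %ID/g must be positive", call. = FALSE)
  va / vb
}

#' Build a %ID/g biodistribution table from counting CSVs
#'
#' Reads an organ-counts table and a dose-standards table and returns tidy
#' per-animal, per-organ %ID/g records.
#'
#' @param organs Data frame or CSV path with columns `animal_id`, `group`,
#'   `organ`, `mass_g`, `rate_cpm`, `window`, `t_count_min`.
#' @param standards Data frame or CSV path with columns `id`, `rate_cpm`,
#'   `fraction_of_injected`, `t_count_min`. The first standard is used
#'   unless organs carry a matching `standard_id` column.
#' @param lam Decay constant (per minute) for referencing counts to a common
#'   time; defaults to the Ac-225 constant (equilibrium windows track the
#'   parent).
#' @return Data frame of biodistribution records with `pct_id_per_g`.
#' @export
biodist_table <- function(organs, standards,
                          lam = decay_constant(10 * 1440)) {
  if (is.character(organs)) organs <- utils::read.csv(organs)
  if (is.character(standards)) standards <- utils::read.csv(standards)
  need <- c("animal_id", "group", "organ", "mass_g", "rate_cpm")
  if (!all(need %in% names(organs)))
    stop("organ table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"t_count_min" %in% names(organs)) organs$t_count_min <- 0
  if (!"t_count_min" %in% names(standards)) standards$t_count_min <- 0
  pick_std <- function(row) {
    i <- if ("standard_id" %in% names(organs) && "id" %in% names(standards))
      match(row$standard_id, standards$id) else 1L
    standards[i, , drop = FALSE]
  }
  organs$pct_id_per_g <- vapply(seq_len(nrow(organs)), function(i) {
    row <- organs[i, , drop = FALSE]
    std <- pick_std(row)
    percent_id_per_gram(row$rate_cpm, row$mass_g,
                        dose_standard(std$rate_cpm,
                                      std$fraction_of_injected),
                        lam = lam, dt_sample = row$t_count_min,
                        dt_standard = std$t_count_min)
  }, numeric(1))
  organs
}

#' Grouped bar chart of a biodistribution table
#'
#' Base-graphics bar chart of group-mean %ID/g per organ with standard
#' deviation whiskers, mirroring the usual biodistribution figure layout.
#'
#' @param biodist Data frame from [biodist_table()] (needs `group`, `organ`,
#'   `pct_id_per_g`).
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix of group-by-organ means.
#' @export
plot_biodist <- function(biodist, ...) {
  m <- tapply(biodist$pct_id_per_g, list(biodist$group, biodist$organ), mean)
  s <- tapply(biodist$pct_id_per_g, list(biodist$group, biodist$organ),
              stats::sd)
  bp <- graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                          ylab = "%ID/g",
                          ylim = c(0, 1.15 * max(m + ifelse(is.na(s), 0, s))),
                          ...)
  ok <- !is.na(s) & s > 0
  graphics::arrows(bp[ok], (m + s)[ok], bp[ok], (m - s)[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(m)
}
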