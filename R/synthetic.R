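#' Free-daughter redistribution model
#'
#' Instantaneous redistribution of recoiled free daughter activity: each
#' organ releases a fraction of its carrier-bound equilibrium activity; the
#' pooled free activity is split between the kidneys (the free-Bi-213-avid
#' organ), the urine, and the rest of the body. The canonical split for free
#' Bi-213 is 40% kidneys / 30% urine / 30% elsewhere.
#'
#' @param release_fraction Named numeric vector, organ -> fraction of its
#'   equilibrium activity released as free daughter (in `[0, 1]`; organs not
#'   named release nothing).
#' @param kidney_uptake_fraction,urine_fraction,other_fraction Fractions of
#'   the pooled free activity going to the kidneys, urine and the remaining
#'   carcass; must sum to 1.
#' @return Object of class `"redistribution_model"`.
#' @export
redistribution_model <- function(release_fraction,
                                 kidney_uptake_fraction = 0.4,
                                 urine_fraction = 0.3,
                                 other_fraction = 0.3) {
  stopifnot(is.numeric(release_fraction), !is.null(names(release_fraction)))
  if (any(release_fraction < 0 | release_fraction > 1))
    stop("release fractions must lie in [0, 1]", call. = FALSE)
  f <- c(kidney_uptake_fraction, urine_fraction, other_fraction)
  if (any(f < 0 | f > 1))
    stop("destination fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-9)
    stop("kidney + urine + other fractions must sum to 1", call. = FALSE)
  structure(list(release_fraction = release_fraction,
                 kidney_uptake_fraction = kidney_uptake_fraction,
                 urine_fraction = urine_fraction,
                 other_fraction = other_fraction),
            class = "redistribution_model")
}

#' Redistribute free daughter activity across organs
#'
#' Applies a [redistribution_model()] to a carrier biodistribution: free
#' daughter released from each organ (`release_fraction` times its
#' equilibrium activity times its mass) is pooled and redistributed, and the
#' per-organ activity at sacrifice is the retained plus received activity,
#' converted back to %ID/g. Mass-weighted total activity is conserved
#' exactly (the urine and carcass pools hold the remainder).
#'
#' @param carrier_biodist Named numeric vector: organ -> carrier-bound
#'   equilibrium activity in %ID/g.
#' @param model A [redistribution_model()]. Requires a `"kidney"` organ if
#'   its kidney fraction is positive.
#' @param masses Named numeric vector: organ -> mass in grams.
#' @return Data frame with columns `organ`, `A_eq_true`, `A0_true`,
#'   `mass_g`; attributes `urine_pool` and `other_pool` hold the activity
#'   (in %ID units) leaving the measured organs.
#' @examples
#' m <- redistribution_model(c(blood = 0.94))
#' simulate_redistribution(c(blood = 17.9, spleen = 86, kidney = 4.7), m,
#'                         c(blood = 1.5, spleen = 0.1, kidney = 0.4))
#' @export
simulate_redistribution <- function(carrier_biodist, model, masses) {
  stopifnot(inherits(model, "redistribution_model"),
            is.numeric(carrier_biodist), !is.null(names(carrier_biodist)),
            is.numeric(masses))
  organs <- names(carrier_biodist)
  if (!all(organs %in% names(masses)))
    stop("every organ needs a mass", call. = FALSE)
  if (any(masses[organs] <= 0)) stop("masses must be positive", call. = FALSE)
  if (any(carrier_biodist < 0))
    stop("carrier %ID/g must be non-negative", call. = FALSE)
  if (model$kidney_uptake_fraction > 0 && !"kidney" %in% organs)
    stop("model routes free daughter to 'kidney' but no such organ given",
         call. = FALSE)
  mass <- masses[organs]
  activity <- carrier_biodist * mass                 # %ID units
  rel <- setNames(numeric(length(organs)), organs)
  known <- intersect(names(model$release_fraction), organs)
  rel[known] <- model$release_fraction[known]
  released <- rel * activity
  pooled <- sum(released)
  retained <- activity - released
  received <- setNames(numeric(length(organs)), organs)
  if ("kidney" %in% organs)
    received["kidney"] <- pooled * model$kidney_uptake_fraction
  A0_activity <- retained + received
  out <- data.frame(organ = organs,
                    A_eq_true = unname(carrier_biodist),
                    A0_true = unname(A0_activity / mass),
                    mass_g = unname(mass),
                    stringsAsFactors = FALSE)
  attr(out, "urine_pool") <- pooled * model$urine_fraction
  attr(out, "other_pool") <- pooled * model$other_fraction +
    if ("kidney" %in% organs) 0 else pooled * model$kidney_uptake_fraction
  out
}

#' Simulate one organ's post-sacrifice counting series
#'
#' Expected values follow the two-amplitude ingrowth curve with the organ's
#' true amplitudes; observed values are Poisson counts at a given
#' counts-per-activity-unit scale (plus optional background), divided back
#' by the scale. `counts_per_unit = Inf` is the noise-free mode: the exact
#' expected curve is returned.
#'
#' @param A_eq_true,A0_true True equilibrium and sacrifice-time activities
#'   (any consistent unit).
#' @param lambda2 Daughter decay constant, per minute.
#' @param schedule Increasing measurement times in minutes (default 10-min
#'   cycles over 18 h).
#' @param counts_per_unit Expected counts per activity unit per measurement;
#'   `Inf` for noise-free.
#' @param background Expected background counts per measurement.
#' @param seed Optional integer seed (reproducible draws).
#' @return Data frame with columns `t_min`, `value` (activity units).
#' @export
simulate_counting_series <- function(A_eq_true, A0_true,
                                     lambda2 = decay_constant(45.6),
                                     schedule = seq(0, 1080, by = 10),
                                     counts_per_unit = Inf,
                                     background = 0, seed = NULL) {
  if (!length(schedule)) stop("empty counting schedule", call. = FALSE)
  if (any(diff(schedule) <= 0))
    stop("schedule must be strictly increasing", call. = FALSE)
  if (!is.numeric(counts_per_unit) || counts_per_unit <= 0)
    stop("'counts_per_unit' must be positive", call. = FALSE)
  mu <- ingrowth_activity(A_eq_true, A0_true, lambda2, schedule)
  if (is.infinite(counts_per_unit)) {
    value <- mu
  } else {
    if (!is.null(seed)) set.seed(seed)
    counts <- stats::rpois(length(mu), mu * counts_per_unit + background)
    value <- pmax(counts - background, 0) / counts_per_unit
  }
  data.frame(t_min = schedule, value = value)
}

#' Table-like intravenous group specifications
#'
#' Convenience specs for the two intravenous carrier formulations: carrier
#' biodistributions and release fractions chosen so that the blood and
#' spleen free-daughter ratios of the generated truths match the published
#' group means (blood 0.06/0.14, spleen 0.67/0.64 for the chelator and
#' nanoparticle formulations respectively); the kidney receives the pooled
#' free daughter.
#'
#' @param cv Between-animal coefficient of variation (lognormal).
#' @return A list with `carrier_biodist`, `model`, `cv`, usable as one entry
#'   of `group_specs` in [simulate_cohort()].
#' @export
dtpa_group_spec <- function(cv = 0.2) {
  list(carrier_biodist = c(blood = 17.9, spleen = 86, kidney = 4.7),
       model = redistribution_model(c(blood = 0.94, spleen = 0.33)),
       cv = cv)
}

#' @rdname dtpa_group_spec
#' @export
inpo4_group_spec <- function(cv = 0.2) {
  list(carrier_biodist = c(blood = 8.8, spleen = 69, kidney = 2.6),
       model = redistribution_model(c(blood = 0.86, spleen = 0.36)),
       cv = cv)
}

#' Simulate a full counting cohort
#'
#' Draws per-animal carrier biodistributions lognormally around the group
#' means, applies the redistribution model per animal, simulates each
#' organ's counting series, and emits every table the retention pipeline
#' consumes (counting series, organ masses with equilibrium count rates,
#' dose standards), plus the underlying truths for recovery testing.
#'
#' @param n_per_group Animals per group (\eqn{\ge 1}).
#' @param group_specs Named list of group specifications, each a list with
#'   `carrier_biodist` (named %ID/g vector), `model`
#'   (a [redistribution_model()]) and `cv` (between-animal lognormal CV).
#'   Defaults to the two intravenous formulation specs.
#' @param masses Named organ masses in grams.
#' @param lambda2 Daughter decay constant, per minute.
#' @param schedule Counting schedule in minutes.
#' @param counts_per_unit Poisson scale (counts per %ID unit per
#'   measurement); `Inf` for noise-free series.
#' @param seed Integer seed.
#' @param outdir If non-`NULL`, the CSV bundle (`series.csv`, `organs.csv`,
#'   `standards.csv`) and `truth.json` are written there.
#' @return List with data frames `series` (`animal_id, group, organ, t_min,
#'   value, window`), `organs` (`animal_id, group, organ, mass_g, rate_cpm,
#'   window, t_count_min`), `standards` (`id, rate_cpm,
#'   fraction_of_injected, t_count_min`) and `truth` (per animal and organ
#'   `A_eq_true`, `A0_true`, `ratio_true`).
#' @details Series values are whole-organ count rates; the injected dose is
#'   100 %ID units so a standard representing 1% of the dose counts at
#'   `counts_per_unit` per minute. Between-animal draws are lognormal with
#'   the group mean as mean and the stated CV (activities are positive and
#'   right-skewed).
#' @export
simulate_cohort <- function(n_per_group,
                            group_specs = list(DTPA = dtpa_group_spec(),
                                               InPO4 = inpo4_group_spec()),
                            masses = c(blood = 1.5, spleen = 0.1,
                                       kidney = 0.4),
                            lambda2 = decay_constant(45.6),
                            schedule = seq(0, 1080, by = 10),
                            counts_per_unit = 1000, seed = NULL,
                            outdir = NULL) {
  stopifnot(n_per_group >= 1, length(group_specs) >= 1,
            !is.null(names(group_specs)))
  if (!is.null(seed)) set.seed(seed)
  sdlog <- function(cv) sqrt(log(1 + cv^2))
  series <- list(); organs <- list(); truth <- list()
  window <- "Bi-213 380-520 keV"
  for (g in names(group_specs)) {
    spec <- group_specs[[g]]
    sl <- sdlog(spec$cv)
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s_%02d", g, i)
      bio <- spec$carrier_biodist
      if (spec$cv > 0)
        bio <- bio * stats::rlnorm(length(bio), -sl^2 / 2, sl)
      tr <- simulate_redistribution(bio, spec$model, masses)
      tr$animal_id <- id; tr$group <- g
      tr$ratio_true <- ifelse(tr$A_eq_true > 0,
                              tr$A0_true / tr$A_eq_true, NA_real_)
      truth[[id]] <- tr
      for (k in seq_len(nrow(tr))) {
        cs <- simulate_counting_series(
          tr$A_eq_true[k] * tr$mass_g[k], tr$A0_true[k] * tr$mass_g[k],
          lambda2, schedule, counts_per_unit)
        series[[paste(id, tr$organ[k])]] <- data.frame(
          animal_id = id, group = g, organ = tr$organ[k],
          t_min = cs$t_min, value = cs$value, window = window,
          stringsAsFactors = FALSE)
      }
      organs[[id]] <- data.frame(
        animal_id = id, group = g, organ = tr$organ,
        mass_g = tr$mass_g,
        rate_cpm = tr$A_eq_true * tr$mass_g *
          if (is.finite(counts_per_unit)) counts_per_unit else 1,
        window = window, t_count_min = 0, stringsAsFactors = FALSE)
    }
  }
  cpu <- if (is.finite(counts_per_unit)) counts_per_unit else 1
  standards <- data.frame(id = "std1", rate_cpm = cpu,
                          fraction_of_injected = 0.01, t_count_min = 0,
                          stringsAsFactors = FALSE)
  out <- list(series = do.call(rbind, c(series, make.row.names = FALSE)),
              organs = do.call(rbind, c(organs, make.row.names = FALSE)),
              standards = standards,
              truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$series, file.path(outdir, "series.csv"),
                     row.names = FALSE)
    utils::write.csv(out$organs, file.path(outdir, "organs.csv"),
                     row.names = FALSE)
    utils::write.csv(out$standards, file.path(outdir, "standards.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$truth, file.path(outdir, "truth.json"),
                         dataframe = "rows", digits = NA)
  }
  out
}

#' Simulate a tumour-growth and survival cohort
#'
#' Per-animal exponential tumour growth with lognormal doubling times,
#' optional spontaneous regression, caliper measurements twice a week, and
#' time-to-event records under the humane-endpoint rule (first measurement
#' day with volume > 2000 mm^3; censoring at the study end).
#'
#' @param n Animals in the group.
#' @param group Group label written into the output tables.
#' @param doubling_days Mean untreated tumour doubling time in days.
#' @param doubling_cv Between-animal CV of the doubling time.
#' @param regress_prob Probability an animal's tumour switches to regression
#'   at a uniform random day in `regress_window`.
#' @param treatment_effect Growth-rate multiplier (1 = untreated, 0 = full
#'   growth arrest).
#' @param regress_window Length-2 day range for the regression switch.
#' @param baseline_volume Mean tumour volume at treatment start, mm^3.
#' @param censor_day Study end (days after treatment start).
#' @param jitter_cv Caliper measurement noise (per-axis lognormal CV).
#' @param seed Optional integer seed.
#' @return List with `tracks` (`animal_id, group, day, W_mm, L_mm, H_mm`)
#'   and `survival` (`animal_id, group, time_days, event, cause`).
#' @export
simulate_tumour_cohort <- function(n, group = "group",
                                   doubling_days = 18, doubling_cv = 0.5,
                                   regress_prob = 0, treatment_effect = 1,
                                   regress_window = c(10, 60),
                                   baseline_volume = 100, censor_day = 115,
                                   jitter_cv = 0.03, seed = NULL) {
  stopifnot(n >= 1, treatment_effect >= 0, regress_prob >= 0,
            regress_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  days <- sort(unique(c(seq(0, censor_day, by = 7),
                        seq(4, censor_day, by = 7))))
  sl <- sqrt(log(1 + doubling_cv^2))
  tracks <- list(); surv <- list()
  for (i in seq_len(n)) {
    id <- sprintf("%s_%02d", group, i)
    Td <- doubling_days * stats::rlnorm(1, -sl^2 / 2, sl)
    g <- (log(2) / Td) * treatment_effect
    v0 <- baseline_volume * stats::rlnorm(1, -0.02, 0.2)
    regress <- stats::runif(1) < regress_prob
    t_switch <- if (regress) stats::runif(1, regress_window[1],
                                          regress_window[2]) else Inf
    vol <- ifelse(days <= t_switch,
                  v0 * exp(g * days),
                  v0 * exp(g * t_switch) * exp(-0.05 * (days - t_switch)))
    d_eq <- (6 * vol / pi)^(1 / 3)
    jit <- function() d_eq * stats::rlnorm(length(d_eq),
                                            -log(1 + jitter_cv^2) / 2,
                                            sqrt(log(1 + jitter_cv^2)))
    W <- jit(); L <- jit(); H <- jit()
    tracks[[id]] <- data.frame(animal_id = id, group = group, day = days,
                               W_mm = W, L_mm = L, H_mm = H,
                               stringsAsFactors = FALSE)
    vmeas <- tumour_volume(W, L, H)
    hit <- which(vmeas > 2000)
    if (length(hit)) {
      surv[[id]] <- data.frame(animal_id = id, group = group,
                               time_days = days[hit[1L]], event = 1L,
                               cause = "tumour_volume",
                               stringsAsFactors = FALSE)
    } else {
      surv[[id]] <- data.frame(animal_id = id, group = group,
                               time_days = censor_day, event = 0L,
                               cause = "study_end", stringsAsFactors = FALSE)
    }
  }
  list(tracks = do.call(rbind, c(tracks, make.row.names = FALSE)),
       survival = do.call(rbind, c(surv, make.row.names = FALSE)))
}
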