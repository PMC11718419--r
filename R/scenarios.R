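#' Translocation schedules
#'
#' `reinforcement_schedule()` encodes a completed reinforcement programme:
#' by default 12 animals spread over 5 annual events (simulation years
#' 1-5), an even sex ratio and sources alternating between the two
#' Carpathian gene pools.  `periodic_schedule()` encodes a long-term
#' management programme of one event every `interval` years over a
#' 50-year horizon, starting one lynx generation (5 years) after the end
#' of the completed reinforcement.
#'
#' @param n_total total animals of the completed reinforcement.
#' @param years event years of the completed reinforcement.
#' @param sources source label(s), recycled over events.
#' @return data.frame `year, n_males, n_females, source` usable as the
#'   `events` argument of [run_simulation()].
#' @export
reinforcement_schedule <- function(n_total = 12, years = 1:5,
                                   sources = c("Slovakia", "Romania")) {
  k <- length(years)
  n <- rep(n_total %/% k, k)
  extra <- n_total - sum(n)
  if (extra > 0) n[seq_len(extra)] <- n[seq_len(extra)] + 1L
  split_sexes(data.frame(year = as.integer(years), n = n,
                         source = rep_len(sources, k),
                         stringsAsFactors = FALSE))
}

#' @rdname reinforcement_schedule
#' @param interval years between periodic events.
#' @param n_per_event animals per periodic event.
#' @param start first periodic event year (default 10: one generation
#'   after the year-5 end of the completed reinforcement).
#' @param program_years programme duration (events occur in
#'   `[start, start + program_years)`).
#' @param source source label of the periodic events.
#' @export
periodic_schedule <- function(interval, n_per_event, start = 10,
                              program_years = 50, source = "Slovakia") {
  stopifnot(interval > 0, n_per_event >= 0)
  years <- seq(start, start + program_years - 1, by = interval)
  split_sexes(data.frame(year = as.integer(years), n = n_per_event,
                         source = source, stringsAsFactors = FALSE))
}

## per-event sex composition: as even as possible, alternating the extra
## animal between sexes at odd counts
split_sexes <- function(d) {
  males <- d$n %/% 2
  odd <- which(d$n %% 2 == 1)
  males[odd] <- males[odd] + rep_len(c(1L, 0L), length(odd))
  data.frame(year = d$year, n_males = males, n_females = d$n - males,
             source = d$source, stringsAsFactors = FALSE)
}

#' Translocation scenario specification
#'
#' @param label scenario name.
#' @param schedule translocation schedule (possibly empty data.frame for a
#'   no-action scenario); see [reinforcement_schedule()].
#' @param n_years simulated years.
#' @param thresholds warning and critical mean-IBD thresholds.
#' @param reference_year year from which "years below the warning
#'   threshold" is counted (default: the last scheduled event, or 0 for
#'   no-action).
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(label, schedule = NULL, n_years = 90,
                          thresholds = c(warning = 0.15, critical = 0.25),
                          reference_year = NULL) {
  if (is.null(schedule)) {
    schedule <- data.frame(year = integer(0), n_males = integer(0),
                           n_females = integer(0), source = character(0))
  }
  stopifnot(thresholds[1] < thresholds[2])
  if (is.null(reference_year)) {
    reference_year <- if (nrow(schedule)) max(schedule$year) else 0L
  }
  structure(list(label = label, schedule = schedule, n_years = n_years,
                 thresholds = thresholds, reference_year = reference_year),
            class = "scenario_spec")
}

#' A 2019-like population start state
#'
#' Returns a generator closure for [run_simulation()]: each replicate
#' draws a fresh population of size `n0` with genotypes from the
#' (drifted) target-population allele frequencies and baseline
#' identity-by-descent sampled from the calibration distribution.
#'
#' @param freqs target-population [allele_freqs()].
#' @param n0 initial census size (all age classes).
#' @param baseline_f numeric vector of baseline F values (e.g.
#'   `calibration$baseline_f`).
#' @param params [demographic_params()].
#' @return function() -> `lynx_population`.
#' @export
lynx_start_state <- function(freqs, n0 = 130, baseline_f = 0,
                             params = demographic_params()) {
  force(freqs); force(n0); force(baseline_f); force(params)
  function() initialize_population(freqs, n0, baseline_f = baseline_f,
                                   params = params)
}

#' Start scenarios from calibration end states
#'
#' Returns a generator closure for [run_simulation()] that draws, for each
#' replicate, one of the surviving end-state populations of the founder
#' calibration (genotypes, ages, pedigree kinship and standing inbreeding
#' included), i.e. the calibrated model's own present-day state.
#'
#' @param snapshots list of `lynx_population` objects
#'   (`calibration$snapshots`).
#' @return function() -> `lynx_population`.
#' @export
snapshot_start_state <- function(snapshots) {
  if (!length(snapshots)) {
    stop("no calibration snapshots available (all replicates extinct?)")
  }
  force(snapshots)
  function() {
    pop <- snapshots[[sample.int(length(snapshots), 1L)]]
    pop$year <- 0L
    pop
  }
}

#' Run a translocation scenario
#'
#' Executes the scenario schedule with [run_simulation()] and derives the
#' threshold-crossing summary from the replicate-mean IBD curve: how long
#' mean inbreeding stays below the warning threshold after the reference
#' year, when it exceeds the critical threshold, extinction statistics and
#' the number of animals translocated.
#'
#' @param spec [scenario_spec()].
#' @param init start-state generator (see [lynx_start_state()]) or a
#'   `lynx_population`.
#' @param sources named list of [allele_freqs()] resolving the schedule's
#'   source labels.
#' @param source_he Fe denominator heterozygosity.
#' @param params [demographic_params()].
#' @param n_replicates,seed replication control.
#' @param compute_ne,ne_every see [run_simulation()].
#' @return object of class `scenario_result`: `spec`, `trajectories`,
#'   `derived` (list: `years_below_warning`, `first_year_above_critical`,
#'   `extinction`, `n_translocated`).
#' @export
run_scenario <- function(spec, init, sources = NULL, source_he = NA_real_,
                         params = demographic_params(), n_replicates = 50,
                         seed = 1, compute_ne = FALSE, ne_every = 5) {
  stopifnot(inherits(spec, "scenario_spec"))
  events <- if (nrow(spec$schedule)) spec$schedule else NULL
  traj <- run_simulation(init, params = params, n_years = spec$n_years,
                         n_replicates = n_replicates, seed = seed,
                         events = events, sources = sources,
                         source_he = source_he, compute_ne = compute_ne,
                         ne_every = ne_every)
  derived <- derive_thresholds(traj, spec)
  structure(list(spec = spec, trajectories = traj, derived = derived),
            class = "scenario_result")
}

#' Threshold crossings of the replicate-mean IBD curve
#'
#' Recomputable from stored trajectories: no hidden state.
#'
#' @param traj trajectory_set.
#' @param spec scenario_spec.
#' @return list: `years_below_warning` (years from the reference year
#'   until mean IBD first returns above the warning threshold),
#'   `first_year_above_critical` (simulation year when mean IBD first
#'   exceeds the critical threshold after having been below it; `NA` if
#'   never below or never returning), `extinction`
#'   ([extinction_summary()]), `n_translocated` per programme.
#' @export
derive_thresholds <- function(traj, spec) {
  s <- summary(traj)
  curve <- s$ibd; yrs <- s$year
  warn <- spec$thresholds[1]; crit <- spec$thresholds[2]
  ref <- spec$reference_year

  cross_span <- function(thr) {
    below <- which(curve < thr & yrs > ref)
    if (!length(below)) return(c(NA_integer_, NA_integer_))
    t_down <- yrs[below[1]]
    up <- which(yrs > t_down & curve >= thr)
    t_up <- if (length(up)) yrs[up[1]] else NA_integer_
    c(t_down, t_up)
  }
  w <- cross_span(warn)
  k <- cross_span(crit)
  list(
    years_below_warning = if (is.na(w[1])) 0L else
      (if (is.na(w[2])) max(yrs) else w[2]) - ref,
    warning_span = w,
    first_year_above_critical = k[2],
    extinction = extinction_summary(traj),
    n_translocated = sum(spec$schedule$n_males + spec$schedule$n_females)
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario:", x$spec$label, "-", x$spec$n_years, "years,",
      max(x$trajectories$replicate), "replicates,",
      x$derived$n_translocated, "animals translocated\n")
  d <- x$derived
  cat(sprintf("  mean IBD below %.2f for %s years after year %d\n",
              x$spec$thresholds[1], d$years_below_warning,
              x$spec$reference_year))
  cat(sprintf("  mean IBD first exceeds %.2f in year %s\n",
              x$spec$thresholds[2], d$first_year_above_critical))
  e <- d$extinction
  cat(sprintf("  extinction: %.0f%% of replicates%s\n", 100 * e$p_extinct,
              if (!is.na(e$mean_year))
                sprintf(" (mean year %.1f)", e$mean_year) else ""))
  invisible(x)
}

#' @export
plot.scenario_result <- function(x, ...) {
  plot(x$trajectories, metric = "ibd",
       main = x$spec$label, ...)
  invisible(x)
}

#' Minimum translocation size for an inbreeding target
#'
#' For a periodic translocation programme at a given interval, searches
#' (ascending from one animal per event) for the smallest per-event
#' number of animals that keeps the replicate-mean identity-by-descent
#' below the threshold at every year between the first periodic event and
#' the end of the 50-year programme.  The completed reinforcement precedes
#' the programme, and translocated animals are assumed to integrate and
#' breed.
#'
#' @param interval years between events (3, 5, 10, 15, 20 or 25 in the
#'   reference scenario set; any positive value accepted).
#' @param source source label for the periodic events.
#' @param init start-state generator (see [lynx_start_state()]).
#' @param sources named list of [allele_freqs()].
#' @param source_he Fe denominator.
#' @param threshold mean-IBD threshold to stay below (default 0.15).
#' @param n_max give up beyond this many animals per event.
#' @param params,n_replicates,seed simulation control.
#' @param include_reinforcement prepend the completed 12-animal
#'   reinforcement (years 1-5)?
#' @param program_start,program_years periodic-programme timing.
#' @return list of class `min_translocation`: `interval`,
#'   `n_per_event` (`NA` if the threshold is not achievable with
#'   `n_max`), `n_events`, `total_per_50y` (events actually scheduled x
#'   n) and `total_per_50y_rate` (rounded `n * 50 / interval`), plus the
#'   accepted `scenario_result`.
#' @export
minimum_translocation_size <- function(interval, source = "Slovakia",
                                       init, sources, source_he,
                                       threshold = 0.15, n_max = 20,
                                       params = demographic_params(),
                                       n_replicates = 50, seed = 1,
                                       include_reinforcement = TRUE,
                                       program_start = 10,
                                       program_years = 50) {
  base <- if (include_reinforcement) reinforcement_schedule() else NULL
  program_end <- program_start + program_years
  accepted <- NULL; n_star <- NA_integer_
  for (n in seq_len(n_max)) {
    sched <- periodic_schedule(interval, n, start = program_start,
                               program_years = program_years,
                               source = source)
    full <- rbind(base, sched)
    spec <- scenario_spec(
      label = sprintf("interval %d, %d per event", interval, n),
      schedule = full, n_years = program_end,
      reference_year = program_start)
    res <- run_scenario(spec, init, sources = sources,
                        source_he = source_he, params = params,
                        n_replicates = n_replicates, seed = seed)
    s <- summary(res$trajectories)
    window <- s$year > program_start & s$year <= program_end
    ok <- all(s$ibd[window] < threshold, na.rm = FALSE) &&
      !anyNA(s$ibd[window])
    if (ok) { n_star <- n; accepted <- res; break }
  }
  n_events <- length(seq(program_start, program_end - 1, by = interval))
  structure(list(interval = interval, source = source,
                 n_per_event = n_star, n_events = n_events,
                 total_per_50y = if (is.na(n_star)) NA_integer_ else
                   n_star * n_events,
                 total_per_50y_rate = if (is.na(n_star)) NA_integer_ else
                   as.integer(round(n_star * 50 / interval)),
                 threshold = threshold, result = accepted),
            class = "min_translocation")
}

#' @export
print.min_translocation <- function(x, ...) {
  cat(sprintf("interval %d years, %s source: ", x$interval, x$source))
  if (is.na(x$n_per_event)) {
    cat("threshold", x$threshold, "not achievable\n")
  } else {
    cat(sprintf(
      "%d per event (%d events; %d per 50 years, rate convention %d)\n",
      x$n_per_event, x$n_events, x$total_per_50y, x$total_per_50y_rate))
  }
  invisible(x)
}
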