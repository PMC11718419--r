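#' Run replicated forward simulations
#'
#' Advances a population year by year (one mating season per year):
#' scheduled translocations, then mating, then survival; after each year
#' census size, breeding-age count, observed and expected heterozygosity,
#' effective inbreeding against the source gene pool, mean
#' identity-by-descent F and (optionally) the LD estimate of Ne from a
#' monitoring-style sample of adults are recorded.  A replicate ends
#' early at extinction (zero census, or one sex absent from all age
#' classes).
#'
#' @param init a function with no arguments returning a fresh
#'   `lynx_population` (called once per replicate so the initial state is
#'   resampled), or a `lynx_population` reused as identical start state.
#' @param params [demographic_params()].
#' @param n_years years to simulate.
#' @param n_replicates independent replicates.
#' @param seed RNG seed (each replicate derives its own stream).
#' @param events optional translocation schedule: data.frame with columns
#'   `year` (1-based simulation year), `n_males`, `n_females` and `source`
#'   (name into the `sources` list).
#' @param sources named list of [allele_freqs()] used by `events`.
#' @param source_he source-population heterozygosity used as the Fe
#'   denominator (`NA` disables Fe).
#' @param compute_ne estimate LD-Ne each `ne_every` years from a sample of
#'   at most `ne_sample` adults?
#' @param ne_every,ne_sample Ne monitoring cadence and sample size.
#' @param ne_years optional explicit years at which to estimate Ne
#'   (overrides `ne_every`).
#' @return object of class `trajectory_set`: data.frame
#'   `(replicate, year, census, adults, ho, he, fe, ibd, ne)` with an
#'   `extinction` attribute (per-replicate extinction year, `NA` if
#'   extant).
#' @export
run_simulation <- function(init, params = demographic_params(),
                           n_years = 50, n_replicates = 50, seed = 1,
                           events = NULL, sources = NULL,
                           source_he = NA_real_,
                           compute_ne = FALSE, ne_every = 1,
                           ne_sample = 50, ne_years = NULL) {
  if (!is.null(events)) {
    stopifnot(is.data.frame(events),
              all(c("year", "n_males", "n_females", "source") %in%
                    names(events)))
    if (any(events$year < 1 | events$n_males < 0 | events$n_females < 0)) {
      stop("invalid translocation schedule")
    }
    if (!all(events$source %in% names(sources))) {
      stop("schedule references unknown sources: ",
           paste(setdiff(events$source, names(sources)), collapse = ", "))
    }
  }
  out <- vector("list", n_replicates)
  extinction <- rep(NA_integer_, n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed((seed * 1000L + r) %% .Machine$integer.max)
    pop <- if (is.function(init)) init() else init
    rows <- vector("list", n_years)
    for (t in seq_len(n_years)) {
      if (!is.null(events)) {
        ev <- events[events$year == t, , drop = FALSE]
        for (e in seq_len(nrow(ev))) {
          pop <- translocate(pop, ev$n_males[e], ev$n_females[e],
                             sources[[ev$source[e]]])
        }
      }
      cohort <- mating_step(pop, params)
      pop <- survival_step(pop, cohort, params)
      if (is_extinct(pop)) {
        extinction[r] <- t
        rows[[t]] <- cbind(year = t, pop_metrics(pop))
        break
      }
      rows[[t]] <- cbind(
        year = t,
        pop_metrics(pop, source_he = source_he,
                    compute_ne = compute_ne &&
                      (if (is.null(ne_years)) t %% ne_every == 0
                       else t %in% ne_years),
                    ne_sample = ne_sample))
    }
    out[[r]] <- cbind(replicate = r, do.call(rbind, rows))
  }
  traj <- do.call(rbind, out)
  rownames(traj) <- NULL
  structure(traj, extinction = extinction, n_years = n_years,
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  ext <- attr(x, "extinction")
  cat("trajectory_set:", max(x$replicate), "replicates,",
      attr(x, "n_years"), "years\n")
  cat(sum(!is.na(ext)), "replicate(s) went extinct")
  if (any(!is.na(ext))) {
    cat(sprintf(" (mean extinction year %.1f)", mean(ext, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' Replicate-mean trajectories
#'
#' Averages each recorded metric over the replicates still extant in a
#' given year.
#'
#' @param object trajectory_set.
#' @param ... unused.
#' @return data.frame with one row per year: means of census, adults, ho,
#'   he, fe, ibd, ne plus `n_extant`.
#' @export
summary.trajectory_set <- function(object, ...) {
  x <- as.data.frame(object)
  alive <- x[x$census > 0, , drop = FALSE]
  years <- sort(unique(x$year))
  res <- do.call(rbind, lapply(years, function(t) {
    d <- alive[alive$year == t, , drop = FALSE]
    if (!nrow(d)) {
      return(data.frame(year = t, census = 0, adults = 0, ho = NA, he = NA,
                        fe = NA, ibd = NA, ne = NA, n_extant = 0L))
    }
    data.frame(year = t, census = mean(d$census), adults = mean(d$adults),
               ho = mean(d$ho, na.rm = TRUE), he = mean(d$he, na.rm = TRUE),
               fe = mean(d$fe, na.rm = TRUE), ibd = mean(d$ibd, na.rm = TRUE),
               ne = if (all(is.na(d$ne))) NA_real_ else
                 mean(d$ne[is.finite(d$ne)], na.rm = TRUE),
               n_extant = nrow(d))
  }))
  rownames(res) <- NULL
  res
}

#' @export
plot.trajectory_set <- function(x, metric = "ibd", ...) {
  s <- summary(x)
  graphics::plot(s$year, s[[metric]], type = "l", lwd = 2,
                 xlab = "simulation year", ylab = metric, ...)
  if (metric == "ibd") {
    graphics::abline(h = c(0.15, 0.25), lty = 2, col = c("grey50", "red"))
  }
  invisible(x)
}

#' Mean extinction time of a trajectory set
#'
#' @param x trajectory_set.
#' @return list with `n_extinct`, `p_extinct` and `mean_year` (mean
#'   extinction year among extinct replicates, `NA` if none).
#' @export
extinction_summary <- function(x) {
  stopifnot(inherits(x, "trajectory_set"))
  ext <- attr(x, "extinction")
  list(n_extinct = sum(!is.na(ext)),
       p_extinct = mean(!is.na(ext)),
       mean_year = if (any(!is.na(ext))) mean(ext, na.rm = TRUE) else NA_real_)
}
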