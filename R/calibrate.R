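#' Published monitoring estimates used as calibration targets
#'
#' Effective-inbreeding and effective-population-size estimates of the
#' Dinaric lynx monitoring series, expressed in years since the 1973
#' six-animal reintroduction: Fe = 0.176 in the 1980s (year 12), 0.260 in
#' 2001-2010 (year 32) and 0.316 in 2017-2019 (year 45); LD-Ne = 13.4 for
#' the last two temporal groups (midpoint year 42).
#'
#' @return list with data.frames `fe` (`year, fe`) and `ne` (`year, ne`).
#' @export
lynx_empirical_targets <- function() {
  list(fe = data.frame(year = c(12L, 32L, 45L), fe = c(0.176, 0.260, 0.316)),
       ne = data.frame(year = 42L, ne = 13.4))
}

#' Calibrate lethal equivalents from the founding bottleneck
#'
#' Simulates the population from its historical founding (six animals from
#' the source population, containing a mother-son and a full-sib pair) for
#' a grid of lethal-equivalent values `B`, and scores each `B` by the
#' discrepancy between the simulated and the empirical monitoring series:
#' the mean absolute error of replicate-mean Fe at the target years plus
#' the mean relative error of LD-Ne at its target years, equally
#' weighted.  Replicates that went extinct before a target year are
#' excluded from that year's mean; a `B` whose replicates all died before
#' some target scores `Inf`.  The best `B` is returned together with the
#' pooled distribution of individual identity-by-descent coefficients at
#' the calibration horizon, which seeds the baseline inbreeding of
#' subsequent scenario simulations.
#'
#' @param source source-population [allele_freqs()].
#' @param b_grid candidate lethal-equivalent values.
#' @param n_iterations replicates per candidate.
#' @param horizon calibration length in years.
#' @param empirical_targets see [lynx_empirical_targets()].
#' @param params [demographic_params()] (its `lethal_equivalents` value is
#'   overridden by the grid).
#' @param founder_kinship declared founder kinships
#'   (default [default_founder_kinship()]).
#' @param n_founders founders (half male, half female).
#' @param ne_sample monitoring sample size for the simulated LD-Ne.
#' @param seed RNG seed.
#' @return object of class `founder_calibration`: `b_grid`, `score`,
#'   `fit` (per-B simulated values at the targets), `b` (selected),
#'   `baseline_f` (pooled end-state F values at the selected B),
#'   `snapshots` (surviving end-state `lynx_population`s at the selected
#'   B -- the model-consistent present-day start states for scenario
#'   simulations, see [snapshot_start_state()]), `p_extinct` per B.
#' @export
calibrate_founders <- function(source,
                               b_grid = seq(0.1, 6, by = 0.25),
                               n_iterations = 100, horizon = 45,
                               empirical_targets = lynx_empirical_targets(),
                               params = demographic_params(),
                               founder_kinship = default_founder_kinship(),
                               n_founders = 6, ne_sample = 50, seed = 1) {
  if (!length(b_grid)) stop("empty lethal-equivalents grid")
  stopifnot(inherits(source, "allele_freqs"), n_iterations > 0)
  source_he <- expected_het_freqs(source)
  fe_t <- empirical_targets$fe; ne_t <- empirical_targets$ne
  ne_years <- ne_t$year

  score <- numeric(length(b_grid))
  fit <- vector("list", length(b_grid))
  p_ext <- numeric(length(b_grid))
  pooled_f <- vector("list", length(b_grid))
  snapshots_b <- vector("list", length(b_grid))
  for (bi in seq_along(b_grid)) {
    p <- params; p$lethal_equivalents <- b_grid[bi]
    fe_mat <- matrix(NA_real_, n_iterations, nrow(fe_t))
    ne_mat <- matrix(NA_real_, n_iterations, nrow(ne_t))
    end_f <- list(); end_pop <- list()
    for (r in seq_len(n_iterations)) {
      set.seed((seed * 100000L + bi * 1000L + r) %% .Machine$integer.max)
      pop <- founder_population(source, ceiling(n_founders / 2),
                                floor(n_founders / 2),
                                founder_kinship = founder_kinship,
                                params = p)
      for (t in seq_len(horizon)) {
        pop <- survival_step(pop, mating_step(pop, p), p)
        if (is_extinct(pop)) break
        if (t %in% fe_t$year) {
          he <- pop_metrics(pop)$he
          fe_mat[r, match(t, fe_t$year)] <-
            effective_inbreeding(he, source_he)
        }
        if (t %in% ne_years) {
          m <- pop_metrics(pop, compute_ne = TRUE, ne_sample = ne_sample)
          ne_mat[r, match(t, ne_years)] <- m$ne
        }
      }
      if (!is_extinct(pop)) {
        end_f[[length(end_f) + 1L]] <- pop$f
        end_pop[[length(end_pop) + 1L]] <- pop
      }
    }
    p_ext[bi] <- 1 - length(end_f) / n_iterations
    fe_sim <- colMeans(fe_mat, na.rm = TRUE)
    ne_sim <- apply(ne_mat, 2, function(v) {
      v <- v[is.finite(v)]; if (length(v)) mean(v) else NA_real_
    })
    fit[[bi]] <- list(fe = fe_sim, ne = ne_sim)
    if (anyNA(fe_sim) || anyNA(ne_sim)) {
      score[bi] <- Inf
    } else {
      score[bi] <- mean(abs(fe_sim - fe_t$fe)) / 2 +
        mean(abs(ne_sim - ne_t$ne) / ne_t$ne) / 2
    }
    pooled_f[[bi]] <- unlist(end_f)
    snapshots_b[[bi]] <- end_pop
  }
  if (all(!is.finite(score))) stop("all candidate B values led to extinction")
  best <- which.min(score)
  structure(list(b_grid = b_grid, score = score, fit = fit,
                 b = b_grid[best], baseline_f = pooled_f[[best]],
                 snapshots = snapshots_b[[best]],
                 p_extinct = p_ext, horizon = horizon,
                 n_iterations = n_iterations,
                 empirical_targets = empirical_targets,
                 source_he = source_he),
            class = "founder_calibration")
}

#' @export
print.founder_calibration <- function(x, ...) {
  cat("founder calibration over", length(x$b_grid), "lethal-equivalent",
      "candidates,", x$n_iterations, "iterations x", x$horizon, "years\n")
  cat(sprintf("selected B = %.2f (discrepancy %.4f)\n", x$b,
              min(x$score)))
  best <- which.min(x$score)
  cat("simulated Fe at target years:",
      paste(sprintf("%.3f", x$fit[[best]]$fe), collapse = ", "),
      "(empirical:",
      paste(sprintf("%.3f", x$empirical_targets$fe$fe), collapse = ", "),
      ")\n")
  cat(sprintf("baseline IBD distribution: n = %d, mean = %.3f\n",
              length(x$baseline_f), mean(x$baseline_f)))
  invisible(x)
}

#' @export
coef.founder_calibration <- function(object, ...) {
  c(lethal_equivalents = object$b)
}

#' @export
plot.founder_calibration <- function(x, ...) {
  ok <- is.finite(x$score)
  graphics::plot(x$b_grid[ok], x$score[ok], type = "b", pch = 16,
                 xlab = "lethal equivalents (B)",
                 ylab = "discrepancy vs empirical series", ...)
  graphics::abline(v = x$b, lty = 2)
  invisible(x)
}
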