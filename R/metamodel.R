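#' Latin-hypercube simulation design for the baseline metamodel
#'
#' Samples the demographic input space (natural mortality, lethal
#' equivalents, kitten survival rate, litter size, census population
#' size) with a Latin hypercube, runs the individual-based model for each
#' input row, and records the simulation outputs (mean IBD, LD-Ne,
#' expected heterozygosity) at the evaluation years.  Replicates that
#' collapse before an evaluation year contribute their last recorded
#' value (the population's state at collapse).
#'
#' @param freqs target-population [allele_freqs()] for the start state.
#' @param baseline_f baseline IBD distribution for the start state.
#' @param n_runs design rows.
#' @param ranges named list of `c(min, max)` for the five inputs
#'   `natural_mortality`, `lethal_equivalents`, `kitten_survival`,
#'   `litter_size`, `census_size`.
#' @param evaluation_years years at which outputs are recorded.
#' @param n_replicates simulation replicates per design row (outputs are
#'   replicate means).
#' @param ne_sample LD-Ne monitoring sample size.
#' @param seed RNG seed.
#' @return data.frame of class `metamodel_dataset`: the five inputs plus
#'   `<output>_y<year>` columns for outputs `ibd`, `ne`, `hexp`.
#' @export
build_design <- function(freqs, baseline_f = 0, n_runs = 200,
                         ranges = list(natural_mortality = c(0.05, 0.30),
                                       lethal_equivalents = c(0.1, 6),
                                       kitten_survival = c(0.3, 0.7),
                                       litter_size = c(1.5, 2.7),
                                       census_size = c(50, 240)),
                         evaluation_years = c(10, 25, 45),
                         n_replicates = 3, ne_sample = 50, seed = 1) {
  stopifnot(n_runs > 0, length(ranges) == 5)
  set.seed(seed)
  U <- lhs::randomLHS(n_runs, length(ranges))
  X <- as.data.frame(mapply(function(u, r) r[1] + u * (r[2] - r[1]),
                            as.data.frame(U), ranges))
  names(X) <- names(ranges)
  X$census_size <- round(X$census_size)

  out <- lapply(seq_len(n_runs), function(i) {
    p <- demographic_params(
      natural_mortality = X$natural_mortality[i],
      juvenile_mortality = 1 - X$kitten_survival[i],
      litter_mean = X$litter_size[i],
      lethal_equivalents = X$lethal_equivalents[i])
    traj <- run_simulation(
      lynx_start_state(freqs, n0 = X$census_size[i],
                       baseline_f = baseline_f, params = p),
      params = p, n_years = max(evaluation_years),
      n_replicates = n_replicates, seed = seed + i,
      compute_ne = TRUE, ne_years = evaluation_years,
      ne_sample = ne_sample)
    design_outputs(traj, evaluation_years)
  })
  d <- cbind(X, do.call(rbind, out))
  structure(d, evaluation_years = evaluation_years,
            inputs = names(ranges),
            class = c("metamodel_dataset", "data.frame"))
}

#' Simulation design over translocation-programme inputs
#'
#' Inputs are the translocation frequency (interval in years), numbers of
#' translocated males and females per event, and the source population;
#' demography is held at its defaults.  Outputs as in [build_design()].
#'
#' @param init start-state generator ([lynx_start_state()]).
#' @param sources named list of at least two source [allele_freqs()].
#' @param source_he Fe denominator (unused in outputs but kept in the
#'   trajectories).
#' @param n_runs design rows.
#' @param intervals candidate translocation intervals.
#' @param n_range inclusive range of per-sex animals per event.
#' @param evaluation_years,n_replicates,ne_sample,seed as in
#'   [build_design()].
#' @param params [demographic_params()].
#' @return data.frame of class `metamodel_dataset` with inputs
#'   `frequency`, `n_males`, `n_females`, `source`.
#' @export
build_translocation_design <- function(init, sources,
                                       source_he = NA_real_, n_runs = 200,
                                       intervals = c(3, 5, 10, 15, 20, 25),
                                       n_range = c(1, 5),
                                       evaluation_years = c(10, 25, 45),
                                       n_replicates = 3, ne_sample = 50,
                                       params = demographic_params(),
                                       seed = 1) {
  stopifnot(length(sources) >= 2, n_runs > 0)
  set.seed(seed)
  X <- data.frame(
    frequency = sample(intervals, n_runs, replace = TRUE),
    n_males = sample(seq(n_range[1], n_range[2]), n_runs, replace = TRUE),
    n_females = sample(seq(n_range[1], n_range[2]), n_runs, replace = TRUE),
    source = factor(sample(names(sources), n_runs, replace = TRUE)))
  out <- lapply(seq_len(n_runs), function(i) {
    years <- seq(1, max(evaluation_years), by = X$frequency[i])
    events <- data.frame(year = as.integer(years),
                         n_males = X$n_males[i],
                         n_females = X$n_females[i],
                         source = as.character(X$source[i]))
    traj <- run_simulation(init, params = params,
                           n_years = max(evaluation_years),
                           n_replicates = n_replicates, seed = seed + i,
                           events = events, sources = sources,
                           source_he = source_he, compute_ne = TRUE,
                           ne_years = evaluation_years,
                           ne_sample = ne_sample)
    design_outputs(traj, evaluation_years)
  })
  d <- cbind(X, do.call(rbind, out))
  structure(d, evaluation_years = evaluation_years,
            inputs = c("frequency", "n_males", "n_females", "source"),
            class = c("metamodel_dataset", "data.frame"))
}

## replicate-mean outputs at evaluation years, carrying the last recorded
## state forward past a collapse
design_outputs <- function(traj, evaluation_years) {
  s <- summary(traj)
  all_years <- seq_len(max(evaluation_years))
  locf <- function(v) {
    ok <- which(!is.na(v))
    if (!length(ok)) return(v)
    idx <- findInterval(seq_along(v), ok)
    v[ok[pmax(idx, 1)]]
  }
  get_at <- function(metric) {
    ## reindex over the full year range: once every replicate has
    ## collapsed, summary() has no row, and the collapse state carries
    v <- s[[metric]][match(all_years, s$year)]
    if (metric == "ne") v[!is.finite(v)] <- NA
    v <- locf(v)
    v[evaluation_years]
  }
  vals <- c(get_at("ibd"), get_at("ne"), get_at("he"))
  names(vals) <- paste0(rep(c("ibd", "ne", "hexp"),
                            each = length(evaluation_years)),
                        "_y", evaluation_years)
  as.data.frame(as.list(vals))
}

#' Random-forest metamodel with mean-decrease-in-impurity importance
#'
#' Fits a regression random forest per output (each simulation statistic
#' at each evaluation year), on a random train/validation split.
#' Importance is the mean decrease in impurity (residual-sum-of-squares
#' node-purity gain), normalised to sum to 1 within each fitted model,
#' then averaged over evaluation years per statistic with a 95%
#' t-interval across years.  Validation mean squared error is reported
#' per output.
#'
#' @param dataset `metamodel_dataset` from [build_design()] or
#'   [build_translocation_design()].
#' @param split_fraction fraction of rows used for training.
#' @param ntree trees per forest.
#' @param seed RNG seed.
#' Effective-population-size outputs are fitted on the log scale (Ne is a
#' scale parameter with a heavy right tail); their errors are reported on
#' that scale.
#'
#' @return object of class `rf_metamodel`: `importance` (features x
#'   statistics, averaged over years), `importance_ci` (lower/upper
#'   arrays), `mdi_overall` (features, averaged over all models), `mse`
#'   and `var_validation` per output column (held-out split), plus
#'   `oob_mse` and `var_train` (out-of-bag generalisation error against
#'   the mean predictor).
#' @export
fit_rf_metamodel <- function(dataset, split_fraction = 0.8, ntree = 500,
                             seed = 1) {
  stopifnot(inherits(dataset, "metamodel_dataset"))
  if (nrow(dataset) < 50) stop("need at least 50 design rows")
  set.seed(seed)
  inputs <- attr(dataset, "inputs")
  years <- attr(dataset, "evaluation_years")
  outputs <- setdiff(names(dataset), inputs)
  d <- as.data.frame(dataset)
  ## impute rare missing outputs (collapsed runs with no Ne) by the median
  for (o in outputs) {
    v <- d[[o]]
    if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    d[[o]] <- v
  }
  n <- nrow(d)
  train <- sample.int(n, floor(split_fraction * n))
  valid <- setdiff(seq_len(n), train)

  mdi <- matrix(NA_real_, length(inputs), length(outputs),
                dimnames = list(inputs, outputs))
  mse <- stats::setNames(numeric(length(outputs)), outputs)
  vv <- mse
  oob_mse <- mse; var_y <- mse
  for (o in outputs) {
    ## effective population size is a scale parameter: fitted on log
    y <- if (grepl("^ne", o)) log(d[[o]]) else d[[o]]
    if (stats::sd(y[train]) == 0) {
      stop("importance undefined for constant output '", o, "'")
    }
    fit <- randomForest::randomForest(
      x = d[train, inputs, drop = FALSE], y = y[train], ntree = ntree,
      importance = FALSE)
    imp <- randomForest::importance(fit, type = 2)[, 1]
    mdi[, o] <- imp[inputs] / sum(imp)
    pred <- stats::predict(fit, d[valid, inputs, drop = FALSE])
    mse[o] <- mean((pred - y[valid])^2)
    vv[o] <- stats::var(y[valid])
    oob_mse[o] <- mean((fit$predicted - y[train])^2)
    var_y[o] <- stats::var(y[train])
  }
  stats <- unique(sub("_y\\d+$", "", outputs))
  imp_mean <- sapply(stats, function(st) {
    cols <- grep(paste0("^", st, "_y"), outputs, value = TRUE)
    rowMeans(mdi[, cols, drop = FALSE])
  })
  imp_ci <- lapply(c(lower = -1, upper = 1), function(sgn) {
    sapply(stats, function(st) {
      cols <- grep(paste0("^", st, "_y"), outputs, value = TRUE)
      m <- mdi[, cols, drop = FALSE]
      k <- ncol(m)
      if (k < 2) return(m[, 1])
      rowMeans(m) + sgn * stats::qt(0.975, k - 1) *
        apply(m, 1, stats::sd) / sqrt(k)
    })
  })
  structure(list(importance = imp_mean, importance_ci = imp_ci,
                 importance_by_output = mdi,
                 mdi_overall = rowMeans(mdi),
                 mse = mse, var_validation = vv,
                 oob_mse = oob_mse, var_train = var_y,
                 n_train = length(train), n_valid = length(valid),
                 ntree = ntree, evaluation_years = years),
            class = "rf_metamodel")
}

#' @export
print.rf_metamodel <- function(x, ...) {
  cat("random-forest metamodel:", x$ntree, "trees,", x$n_train,
      "training /", x$n_valid, "validation rows\n")
  cat("MDI importance (averaged over evaluation years",
      paste(x$evaluation_years, collapse = ", "), "):\n")
  ord <- order(x$mdi_overall, decreasing = TRUE)
  print(round(cbind(overall = x$mdi_overall, x$importance)[ord, ], 3))
  cat("validation MSE within output variance for",
      sum(x$mse <= x$var_validation), "of", length(x$mse), "outputs\n")
  invisible(x)
}

#' @export
plot.rf_metamodel <- function(x, ...) {
  ord <- order(x$mdi_overall)
  graphics::barplot(x$mdi_overall[ord], horiz = TRUE, las = 1,
                    xlab = "mean decrease in impurity (normalised)", ...)
  invisible(x)
}
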