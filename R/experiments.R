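#' Named scenario presets
#'
#' Parameter sets for the stock in-silico experiments: `control` (defaults),
#' `no_sdf1_chemotaxis` (Sdf1 chemotaxis weight zeroed; no streams form),
#' `no_placode_cil` (placodal CIL probability zero; uniform broad-front
#' invasion), `low_adhesion` / `high_adhesion` (NC-NC persistent adhesion 0 /
#' 2; thinner / wider streams), and `width_0.5`, `width_1.5`, `width_2`
#' (lattice width scaled, initial cell rows unchanged so linear densities are
#' preserved).
#'
#' @param name preset name.
#' @return an `nc_params` object.
#' @export
preset_params <- function(name = c("control", "no_sdf1_chemotaxis",
                                   "no_placode_cil", "low_adhesion",
                                   "high_adhesion", "width_0.5", "width_1.5",
                                   "width_2")) {
  name <- match.arg(name)
  p <- nc_params()
  switch(name,
    control = p,
    no_sdf1_chemotaxis = set_params(p, lambda_S_eff = 0),
    no_placode_cil = set_params(p, p_CIL_PL = 0),
    low_adhesion = set_params(p, lambda_M_NC_NC = 0),
    high_adhesion = set_params(p, lambda_M_NC_NC = 2),
    "width_0.5" = scale_width(p, 0.5),
    "width_1.5" = scale_width(p, 1.5),
    "width_2" = scale_width(p, 2))
}

#' Scale the lattice width, keeping linear cell densities
#'
#' Multiplies the lattice width by `w` (rounded to whole 5-site patch
#' columns); the number of initial NC and placode rows is unchanged, so the
#' linear cell density along the AP axis is preserved.
#'
#' @param params an `nc_params` object.
#' @param w relative width, > 0.
#' @return an `nc_params` object.
#' @export
scale_width <- function(params, w) {
  stopifnot(w > 0)
  width <- max(5L, 5L * round(params$lattice_width * w / 5))
  set_params(params, lattice_width = as.integer(width))
}

#' Build a scenario configuration
#'
#' Bundles a parameter set with named overrides, a relative system width, a
#' replicate seed list, and the metric sampling interval.
#'
#' @param params base `nc_params` (default the control preset).
#' @param overrides named list of parameter overrides, applied via
#'   [set_params()] (entry-wise matrix names like `lambda_M_NC_NC` allowed).
#' @param width relative system width (1 = 180 sites); applied after
#'   overrides, rows held constant.
#' @param n_rep number of replicates (ignored if `seeds` given).
#' @param seeds integer vector of distinct replicate seeds.
#' @param n_mcs run length (default the parameter set's `total_MCS`).
#' @param sample_every metric sampling interval in MCS.
#' @param stream_depth transect depth for [count_streams()].
#' @return an object of class `nc_scenario_config`.
#' @export
scenario_config <- function(params = nc_params(), overrides = list(),
                            width = 1, n_rep = 20, seeds = seq_len(n_rep),
                            n_mcs = NULL, sample_every = 600,
                            stream_depth = 0.5) {
  if (anyDuplicated(seeds)) stop("replicate seeds must be distinct")
  if (length(overrides)) params <- do.call(set_params, c(list(params), overrides))
  if (width != 1) params <- scale_width(params, width)
  viol <- validate_params(params)
  if (length(viol)) stop("invalid scenario parameters:\n  ",
                         paste(viol, collapse = "\n  "))
  cfg <- list(params = params, width = width, seeds = as.integer(seeds),
              n_mcs = if (is.null(n_mcs)) params$total_MCS else as.integer(n_mcs),
              sample_every = sample_every, stream_depth = stream_depth,
              overrides = overrides)
  class(cfg) <- "nc_scenario_config"
  cfg
}

replicate_summary <- function(sim, cfg) {
  mask <- cell_mask(sim$state, "NC")
  dm <- density_probability(mask)
  wl <- width_length(dm)
  m <- sim$metrics
  list(metrics = data.frame(
         seed = sim$seed, W = wl[["W"]], L = wl[["L"]],
         aspect = wl[["L"]] / wl[["W"]],
         n_streams = count_streams(mask, depth = cfg$stream_depth),
         speed_nc = mean(m$speed_nc, na.rm = TRUE),
         speed_pl = mean(m$speed_pl, na.rm = TRUE),
         emt_insertions = sum(m$emt_insertions),
         n_cells = max(m$n_cells), ok = TRUE),
       density = dm, nc_mask = mask,
       conc = m[, c("mcs", "mean_cA", "mean_cS", "mean_cI")])
}

#' Run a replicated scenario
#'
#' Runs every replicate to the configured length, measures the final stream
#' morphology per replicate (density probability map, W, L, stream count,
#' mean speeds), pools the density maps count-weighted across replicates, and
#' aggregates ensemble means with SEM over replicates only. Replicates whose
#' width or length is undefined (the no-stream outcome) are tallied in
#' `no_stream_fraction` and excluded from the W/L means rather than imputed.
#' A numerical failure in one replicate is recorded and the scenario
#' continues with the remaining seeds.
#'
#' @param config an `nc_scenario_config`.
#' @param keep_states keep each replicate's final `nc_state` (memory-heavy).
#' @param progress print one line per replicate.
#' @return an object of class `nc_scenario_result`: list with `replicates`
#'   (one-row-per-replicate data frame), `summary` (ensemble means and SEMs),
#'   `pooled` (W/L from the pooled density map), `pooled_density`, `conc`
#'   (ensemble-averaged concentration time series), `nc_masks`, `config`.
#' @export
run_scenario <- function(config, keep_states = FALSE, progress = FALSE) {
  reps <- list(); dens <- list(); masks <- list(); concs <- list()
  states <- list()
  for (s in config$seeds) {
    r <- tryCatch({
      sim <- run_simulation(config$params, s, n_mcs = config$n_mcs)
      out <- replicate_summary(sim, config)
      if (keep_states) states[[as.character(s)]] <- sim$state
      out
    }, error = function(e) {
      warning("replicate seed ", s, " failed: ", conditionMessage(e))
      list(metrics = data.frame(seed = s, W = NA, L = NA, aspect = NA,
                                n_streams = NA, speed_nc = NA, speed_pl = NA,
                                emt_insertions = NA, n_cells = NA, ok = FALSE),
           density = NULL, nc_mask = NULL, conc = NULL)
    })
    reps[[length(reps) + 1L]] <- r$metrics
    if (!is.null(r$density)) dens[[length(dens) + 1L]] <- r$density
    if (!is.null(r$nc_mask)) masks[[length(masks) + 1L]] <- r$nc_mask
    if (!is.null(r$conc)) concs[[length(concs) + 1L]] <- r$conc
    if (progress) {
      message(sprintf("  seed %d: W=%.1f L=%.1f streams=%s", s,
                      r$metrics$W, r$metrics$L, r$metrics$n_streams))
    }
  }
  reps <- do.call(rbind, reps)
  sem <- function(v) { v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_ }
  pooled_map <- pool_density(dens)
  conc <- NULL
  if (length(concs)) {
    conc <- concs[[1]]
    if (length(concs) > 1)
      for (k in 2:length(concs))
        conc[, -1] <- conc[, -1] + concs[[k]][, -1]
    conc[, -1] <- conc[, -1] / length(concs)
  }
  res <- list(
    replicates = reps,
    summary = list(
      W_mean = mean(reps$W, na.rm = TRUE), W_sem = sem(reps$W),
      L_mean = mean(reps$L, na.rm = TRUE), L_sem = sem(reps$L),
      n_streams_mean = mean(reps$n_streams, na.rm = TRUE),
      n_streams_sem = sem(reps$n_streams),
      speed_nc_mean = mean(reps$speed_nc, na.rm = TRUE),
      no_stream_fraction = mean(is.na(reps$W) | is.na(reps$L)),
      n_ok = sum(reps$ok)),
    pooled = width_length(pooled_map),
    pooled_density = pooled_map,
    conc = conc,
    nc_masks = masks,
    states = if (keep_states) states else NULL,
    config = config)
  class(res) <- "nc_scenario_result"
  res
}

#' @export
print.nc_scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<nc_scenario_result> %d replicates (%d ok)\n",
              nrow(x$replicates), s$n_ok))
  cat(sprintf("  W = %.1f +/- %.1f, L = %.1f +/- %.1f s.u. (mean +/- SEM over defined replicates)\n",
              s$W_mean, s$W_sem, s$L_mean, s$L_sem))
  cat(sprintf("  pooled-density W = %.1f, L = %.1f; streams = %.1f; no-stream fraction = %.2f\n",
              x$pooled[["W"]], x$pooled[["L"]], s$n_streams_mean,
              s$no_stream_fraction))
  invisible(x)
}

#' Stream count as a function of system width
#'
#' Runs the scenario at each relative width (initial rows constant) and
#' counts streams along the standard transect in each replicate's final
#' configuration. When at least two widths are supplied the relation is
#' summarized by an ordinary least squares fit of the ensemble-mean count on
#' relative width.
#'
#' @param widths numeric vector of relative widths (> 0).
#' @param config an `nc_scenario_config`; its `width` is replaced per sweep
#'   point.
#' @param progress print progress lines.
#' @return list with `table` (width, mean count, SEM, n), `fit` (lm or `NULL`
#'   if a single width makes the fit underdetermined), and `results` (the
#'   per-width `nc_scenario_result`s).
#' @export
width_sweep <- function(widths, config, progress = FALSE) {
  stopifnot(all(widths > 0))
  results <- lapply(widths, function(w) {
    cfg <- config
    cfg$params <- scale_width(cfg$params, w / cfg$width)
    cfg$width <- w
    if (progress) message("width ", w)
    run_scenario(cfg, progress = progress)
  })
  tab <- data.frame(
    width = widths,
    n_streams = vapply(results, function(r) r$summary$n_streams_mean, 0),
    sem = vapply(results, function(r)
      if (is.na(r$summary$n_streams_sem)) NA_real_ else r$summary$n_streams_sem, 0),
    n_rep = vapply(results, function(r) r$summary$n_ok, 0L))
  fit <- if (length(widths) >= 2) lm(n_streams ~ width, data = tab) else NULL
  list(table = tab, fit = fit, results = results)
}

#' One-dimensional parameter sweep of stream morphology
#'
#' Runs the scenario at each value of one parameter and reports the ensemble
#' stream width and length with SEM; replicates without streams are counted
#' in `no_stream_fraction`, not averaged.
#'
#' @param parameter parameter name as accepted by [set_params()] (e.g.
#'   `"lambda_S_eff"`, `"p_CIL_PL"`, `"lambda_M_NC_NC"`).
#' @param values numeric vector of parameter values.
#' @param config an `nc_scenario_config`.
#' @param progress print progress lines.
#' @return list with `table` (value, W, W_sem, L, L_sem, no_stream_fraction)
#'   and `results`.
#' @export
sweep_1d <- function(parameter, values, config, progress = FALSE) {
  results <- lapply(values, function(v) {
    cfg <- config
    cfg$params <- do.call(set_params,
                          c(list(cfg$params), stats::setNames(list(v), parameter)))
    if (progress) message(parameter, " = ", v)
    run_scenario(cfg, progress = progress)
  })
  tab <- data.frame(
    value = values,
    W = vapply(results, function(r) r$summary$W_mean, 0),
    W_sem = vapply(results, function(r) r$summary$W_sem, 0),
    L = vapply(results, function(r) r$summary$L_mean, 0),
    L_sem = vapply(results, function(r) r$summary$L_sem, 0),
    no_stream_fraction = vapply(results, function(r)
      r$summary$no_stream_fraction, 0))
  names(tab)[1] <- parameter
  list(table = tab, results = results)
}

#' Two-parameter morphology map
#'
#' Full-factorial grid over two parameters; each grid point reports the
#' ensemble stream width, length and their relative standard errors,
#' renderable as a box-glyph morphology map (box size = W x L, shading =
#' relative SEM).
#'
#' @param param_x,param_y parameter names as accepted by [set_params()].
#' @param values_x,values_y numeric vectors of grid values.
#' @param config an `nc_scenario_config`.
#' @param progress print progress lines.
#' @return data frame with one row per grid point: the two parameter values,
#'   `W`, `L`, `rel_sem` (mean of the relative SEMs of W and L), and
#'   `no_stream_fraction`.
#' @export
morphology_map <- function(param_x, values_x, param_y, values_y, config,
                           progress = FALSE) {
  grid <- expand.grid(x = values_x, y = values_y)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    ov <- stats::setNames(list(grid$x[i], grid$y[i]), c(param_x, param_y))
    cfg$params <- do.call(set_params, c(list(cfg$params), ov))
    if (progress) message(param_x, "=", grid$x[i], " ", param_y, "=", grid$y[i])
    r <- run_scenario(cfg)
    s <- r$summary
    rel <- mean(c(s$W_sem / s$W_mean, s$L_sem / s$L_mean), na.rm = TRUE)
    data.frame(x = grid$x[i], y = grid$y[i], W = s$W_mean, L = s$L_mean,
               rel_sem = rel, no_stream_fraction = s$no_stream_fraction)
  })
  out <- do.call(rbind, rows)
  names(out)[1:2] <- c(param_x, param_y)
  out
}
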