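#' Energy change of a copy attempt
#'
#' Evaluates the change in the Potts energy `H` (area constraint plus contact
#' energies over the 8-neighborhood) if the target site were overwritten by
#' the source site's label (or by medium for a retraction). Computed
#' incrementally from the affected cells and local bonds only.
#'
#' @param state an `nc_state` object.
#' @param params an `nc_params` object.
#' @param target integer `c(x, y)`, 1-based lattice coordinates of the site to
#'   overwrite (x = column / AP axis, y = row / DV axis).
#' @param source integer `c(x, y)` of a lattice neighbor supplying the copied
#'   label, or `NULL` for a retraction attempt (overwrite with medium).
#' @return the energy change (numeric scalar).
#' @export
delta_H <- function(state, params, target, source = NULL) {
  s <- if (is.null(source)) c(0L, 0L) else as.integer(source)
  cpp_eval_attempt(state, unclass(params), target[1], target[2],
                   s[1], s[2], 0L)$dH
}

#' Work bias of a copy attempt
#'
#' The bias `W` added to the Metropolis exponent: extension-only chemotaxis
#' (active only when a cell extends into medium, with the extending cell's
#' per-substance weights; placodes have none), persistent-adhesion spring
#' forces, and polarized motility, the last two projected on the
#' attempt-induced centroid displacement of each affected cell.
#'
#' @inheritParams delta_H
#' @return the work bias (numeric scalar).
#' @export
work_bias <- function(state, params, target, source = NULL) {
  s <- if (is.null(source)) c(0L, 0L) else as.integer(source)
  cpp_eval_attempt(state, unclass(params), target[1], target[2],
                   s[1], s[2], 0L)$W
}

#' Evaluate a fully specified copy attempt
#'
#' Returns the energy change, work bias and acceptance probability
#' `min(1, exp(W - dH))` of the attempt, optionally repeating the acceptance
#' draw `nrep` times (consuming the RNG stream) without modifying the state.
#' Attempts that would erase a cell's last site report `p = 0`.
#'
#' @inheritParams delta_H
#' @param nrep number of acceptance draws to simulate.
#' @return list with `dH`, `W`, `p`, `accepted` (count out of `nrep`), `xval`.
#' @export
eval_attempt <- function(state, params, target, source = NULL, nrep = 0L) {
  s <- if (is.null(source)) c(0L, 0L) else as.integer(source)
  cpp_eval_attempt(state, unclass(params), target[1], target[2],
                   s[1], s[2], as.integer(nrep))
}

#' Perform one random elementary copy attempt
#'
#' Draws a target site uniformly; with probability `p_medium_retraction` the
#' overwrite value is medium, otherwise the label of a uniformly drawn Moore
#' neighbor; accepts with probability `min(1, exp(W - dH))` and applies the
#' overwrite (lattice, areas, centroids) on acceptance.
#'
#' @inheritParams delta_H
#' @return list with the updated `state` and counts `accepted`, `invalid`.
#' @export
attempt_copy <- function(state, params) {
  cpp_attempt_copy(state, unclass(params))
}

#' Advance the simulation by whole Monte Carlo steps
#'
#' One MCS is `lattice_width * lattice_height` elementary copy attempts
#' followed, in fixed order, by persistent-link updates, CIL switching,
#' polarity updates, one MCS of reaction-diffusion field time, and dorsal EMT
#' insertion of new NC cells.
#'
#' @inheritParams delta_H
#' @param n number of MCS to run.
#' @return list with the updated `state` and a `metrics` data frame holding
#'   one row per MCS (acceptance counts, mean NC/placode centroid speeds,
#'   mean concentrations over the cell lattice, link/CIL/EMT event counts).
#' @export
run_mcs <- function(state, params, n = 1) {
  res <- cpp_run(state, unclass(params), as.integer(n))
  list(state = res$state, metrics = as.data.frame(res$metrics))
}

#' Run a full simulation
#'
#' Seeds the RNG stream, builds the initial two-tissue configuration and runs
#' `n_mcs` Monte Carlo steps, optionally collecting NC occupancy snapshots at
#' a fixed sampling interval.
#'
#' @param params an `nc_params` object.
#' @param seed integer seed for the simulation's single RNG stream.
#' @param n_mcs number of MCS to run (default `params$total_MCS`).
#' @param sample_every if non-`NULL`, record an NC occupancy mask (and
#'   optionally the full label lattice) every `sample_every` MCS.
#' @param keep_sigma also keep the full label lattice at each sample.
#' @param progress print a line every 600 MCS.
#' @return an object of class `nc_sim`: list with `state` (final), `metrics`
#'   (per-MCS data frame), `samples` (list of `list(mcs, nc_mask, sigma?)`),
#'   `params`, `seed`.
#' @export
run_simulation <- function(params, seed, n_mcs = params$total_MCS,
                           sample_every = NULL, keep_sigma = FALSE,
                           progress = FALSE) {
  state <- init_simulation(params, seed)
  metrics <- vector("list", 0)
  samples <- list()
  done <- 0L
  chunk <- if (is.null(sample_every)) n_mcs else sample_every
  while (done < n_mcs) {
    step <- min(chunk, n_mcs - done)
    res <- run_mcs(state, params, step)
    state <- res$state
    metrics[[length(metrics) + 1L]] <- res$metrics
    done <- done + step
    if (!is.null(sample_every)) {
      smp <- list(mcs = state$mcs, nc_mask = cell_mask(state, "NC"))
      if (keep_sigma) smp$sigma <- state$sigma
      samples[[length(samples) + 1L]] <- smp
    }
    if (progress && (done %% 600 == 0 || done == n_mcs))
      message(sprintf("  MCS %d / %d (%d cells)", done, n_mcs,
                      nrow(state$cells)))
  }
  out <- list(state = state,
              metrics = if (length(metrics)) do.call(rbind, metrics)
                        else data.frame(),
              samples = samples, params = params, seed = seed)
  class(out) <- "nc_sim"
  out
}

#' @export
print.nc_sim <- function(x, ...) {
  cat(sprintf("<nc_sim> seed %d, %d MCS run\n", x$seed, x$state$mcs))
  print(x$state)
  invisible(x)
}

#' Current lattice contact pairs
#'
#' Unordered pairs of distinct cells adjacent over the 8-neighborhood.
#'
#' @inheritParams delta_H
#' @return integer matrix with columns `i`, `j`.
#' @export
lattice_contacts <- function(state, params) {
  cpp_contacts(state, unclass(params))
}
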