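# Full-length simulation ensembles shared by the quantitative acceptance
# tests. Built lazily and cached for the session so each scenario runs once.

.ens_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .ens_cache)) assign(key, builder(), envir = .ens_cache)
  get(key, envir = .ens_cache)
}

# one full-length control replicate, reduced to the quantities the tests use
run_control_rep <- function(params, seed) {
  sim <- run_simulation(params, seed)
  mask <- cell_mask(sim$state, "NC")
  pl <- cell_mask(sim$state, "PL")
  dm <- density_probability(mask)
  wl <- width_length(dm)
  m <- sim$metrics
  list(W = wl[["W"]], L = wl[["L"]], mask = mask, density = dm,
       n_streams = count_streams(mask),
       speed_nc = mean(m$speed_nc), speed_pl = mean(m$speed_pl),
       invasion_depth = max(which(rowSums(mask) > 0)) - 11,
       mixing = nc_pl_mixing(mask, pl),
       conc = m[, c("mcs", "mean_cA", "mean_cS", "mean_cI")])
}

# fraction of NC sites with a placode site among their 8 neighbors: high when
# NC disperse into the placodal tissue, low when streams stay segregated
nc_pl_mixing <- function(nc_mask, pl_mask) {
  H <- nrow(nc_mask); W <- ncol(nc_mask)
  near_pl <- matrix(FALSE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    ys <- max(1, 1 + dy):min(H, H + dy); xs <- max(1, 1 + dx):min(W, W + dx)
    near_pl[ys - dy, xs - dx] <- near_pl[ys - dy, xs - dx] | pl_mask[ys, xs]
  }
  mean(near_pl[nc_mask])
}

control_ensemble <- function(n = 4) {
  cached("control", function() lapply(seq_len(n), function(s)
    run_control_rep(nc_params(), s)))
}

cil03_ensemble <- function(n = 2) {
  cached("cil03", function() lapply(seq_len(n), function(s)
    run_control_rep(set_params(nc_params(), p_CIL_PL = 0.3), s)))
}

halfwidth_ensemble <- function(n = 2) {
  cached("halfwidth", function() lapply(seq_len(n), function(s)
    run_control_rep(nc_params(lattice_width = 90), s)))
}

gate_run <- function(name) {
  cached(paste0("gate_", name), function()
    run_control_rep(preset_params(name), 1))
}

sem <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
}
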