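#' Net per-site source rates of a substance
#'
#' NC-occupied sites secrete the co-attractant A at rate `S_A` and take up
#' Sdf1 at rate `U_S` (a negative source, clamped at the available
#' concentration when applied); placode-occupied sites secrete Sdf1 at `S_S`
#' and the inhibitor at `S_I`; medium contributes nothing.
#'
#' @param state an `nc_state` object.
#' @param params an `nc_params` object.
#' @param substance one of `"A"`, `"S"`, `"I"`.
#' @return numeric matrix over the cell lattice (rates per MCS).
#' @export
source_map <- function(state, params, substance) {
  if (!substance %in% c("A", "S", "I"))
    stop("unknown substance: ", substance)
  cpp_source_map(state, unclass(params), substance)
}

#' Advance the concentration fields
#'
#' Integrates `dc/dt = D lap(c) - delta c + S(sigma)` for each substance over
#' `n` MCS of model time, using `field_substeps_per_MCS` explicit forward
#' Euler substeps per MCS with a 5-point Laplacian on the halo-extended
#' lattice and zero-flux outer boundaries. The cell configuration (and hence
#' the source map) is held fixed. Concentrations remain non-negative; a
#' non-finite value aborts with an error naming the substance and substep.
#'
#' @inheritParams source_map
#' @param n number of MCS of field time.
#' @return the state with advanced fields (lattice and cells unchanged).
#' @export
step_fields <- function(state, params, n = 1) {
  viol <- grep("field_substeps", validate_params(params), value = TRUE)
  if (length(viol)) stop(viol)
  cpp_step_fields(state, unclass(params), as.integer(n))
}

#' Characteristic decay length of a substance
#'
#' `sqrt(D / delta)`: the length scale over which a steadily secreted
#' substance falls off. For the default inhibitor parameters this is about
#' 2.89 s.u. (around half the 5.64 s.u. cell diameter), for Sdf1 about 36.5
#' s.u.
#'
#' @inheritParams source_map
#' @return length in lattice sites; `Inf` if the decay rate is zero.
#' @export
decay_length <- function(substance, params) {
  if (!substance %in% c("A", "S", "I"))
    stop("unknown substance: ", substance)
  D <- params[[paste0("D_", substance)]]
  del <- params[[paste0("delta_", substance)]]
  if (del == 0) return(Inf)
  sqrt(D / del)
}
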