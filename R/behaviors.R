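#' Update the polarity vectors of all cells
#'
#' Applies the persistence rule `p <- (1 - deltaP) p + dr`, where `dr` is each
#' cell's centroid displacement over the last MCS and `deltaP` depends on the
#' cell type and whether the cell touches another cell. Cells in the CIL state
#' are additionally repolarized by `-lambda_CIL` times the normalized sum of
#' vectors to all contacting neighbors (skipped when that sum is zero).
#'
#' Inside [run_mcs()] the displacements are accumulated automatically; this
#' entry point takes them explicitly so the rule can be exercised in
#' isolation.
#'
#' @param state an `nc_state` object.
#' @param params an `nc_params` object.
#' @param displacement numeric `n_cells x 2` matrix of last-MCS centroid
#'   displacements (defaults to zero).
#' @return the state with updated polarity vectors.
#' @export
update_polarity <- function(state, params, displacement = NULL) {
  n <- nrow(state$cells)
  if (is.null(displacement)) displacement <- matrix(0, n, 2)
  cpp_update_polarity(state, unclass(params), displacement)
}

#' Update CIL states
#'
#' For each new contact (a pair of adjacent cells that was not in contact at
#' the previous update) involving at least one NC cell, each participant
#' independently switches to the CIL state with its type's probability
#' (`p_CIL_NC`, `p_CIL_PL`). Placode-placode contacts never trigger. Cells
#' whose triggering contacts have all ended leave the CIL state. The state's
#' stored contact set is refreshed.
#'
#' @inheritParams update_polarity
#' @return list with the updated `state` and counts `entries`, `exits`.
#' @export
update_cil <- function(state, params) {
  cpp_update_cil(state, unclass(params))
}

#' Update persistent adhesion links
#'
#' Contacting unlinked pairs link with probability `p_link_form`; linked pairs
#' that lost lattice contact unlink deterministically; remaining linked pairs
#' unlink with probability `max(0, min(1, (|r_ij| - d0) / link_break_divisor))`
#' where `r_ij` is the centroid distance and `d0` the spring rest length.
#'
#' @inheritParams update_polarity
#' @return list with the updated `state` and counts `formed`, `broken`.
#' @export
update_links <- function(state, params) {
  cpp_update_links(state, unclass(params))
}

#' Link breakage probability
#'
#' @param r centroid distance of the linked pair [s.u.].
#' @param d0 spring rest length [s.u.].
#' @param divisor scale of the breakage law (default 100).
#' @return probability in `[0, 1]`, `max(0, min(1, (r - d0)/divisor))`.
#' @export
link_break_prob <- function(r, d0, divisor = 100) {
  pmax(0, pmin(1, (r - d0) / divisor))
}

#' Insert new NC cells at the dorsal edge (EMT)
#'
#' Scans the dorsal (top) strip for cell-free rectangles of one cell width by
#' half a cell height (5 x 3 sites) anchored at the top edge; each qualifying
#' window receives one new NC cell with a fresh id, zero polarity and no
#' links, which then grows toward the target area under the volume
#' constraint. Models the continuous dorsal production of migratory NC by
#' epithelial-to-mesenchymal transition.
#'
#' @inheritParams update_polarity
#' @return list with the updated `state` and the number of `insertions`.
#' @export
emt_insert <- function(state, params) {
  cpp_emt_insert(state, unclass(params))
}
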