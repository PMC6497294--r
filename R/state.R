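#' @useDynLib ncstreams, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm runif sd
#' @importFrom utils read.csv write.csv
NULL

empty_fields <- function(params) {
  he <- params$lattice_height + 2 * params$halo
  we <- params$lattice_width + 2 * params$halo
  z <- matrix(0, he, we)
  list(A = z, S = z, I = z)
}

#' Build a simulation state from a label lattice
#'
#' Constructs a consistent state (cell registry with areas and centroids,
#' zero polarities, no links, no CIL, zero concentration fields, clock at 0)
#' from an explicit label matrix. Useful for constructing test configurations
#' and for re-analyzing saved snapshots.
#'
#' @param sigma integer matrix, `lattice_height x lattice_width`; 0 = medium,
#'   positive entries are cell labels `1..n` (every label up to `max(sigma)`
#'   must occupy at least one site).
#' @param types cell types by label: integer vector (1 = NC, 2 = placode) or
#'   character (`"NC"`/`"PL"`), length `max(sigma)`.
#' @param params an `nc_params` object whose lattice dimensions match `sigma`.
#' @return an `nc_state` object.
#' @export
state_from_sigma <- function(sigma, types, params) {
  if (is.character(types)) types <- match(types, c("NC", "PL"))
  if (any(is.na(types)) || !all(types %in% 1:2))
    stop("types must be 1/2 or \"NC\"/\"PL\"")
  n <- max(0L, max(sigma))
  if (length(types) != n)
    stop("need one type per cell label: max(sigma) = ", n)
  if (nrow(sigma) != params$lattice_height || ncol(sigma) != params$lattice_width)
    stop("sigma dimensions do not match params lattice")
  lab <- as.vector(sigma)
  occ <- lab > 0
  if (n > 0 && !setequal(unique(lab[occ]), seq_len(n)))
    stop("labels must be contiguous 1..n with every cell occupying >= 1 site")
  xs <- rep(seq_len(ncol(sigma)), each = nrow(sigma))
  ys <- rep(seq_len(nrow(sigma)), ncol(sigma))
  area <- tabulate(lab[occ], nbins = n)
  cx <- as.vector(tapply(xs[occ], lab[occ], mean))
  cy <- as.vector(tapply(ys[occ], lab[occ], mean))
  cells <- data.frame(
    id = seq_len(n), type = as.integer(types), area = as.integer(area),
    cx = if (n) cx else numeric(0), cy = if (n) cy else numeric(0),
    px = numeric(n), py = numeric(n), cil = logical(n))
  st <- list(
    sigma = matrix(as.integer(sigma), nrow(sigma), ncol(sigma)),
    cells = cells,
    fields = empty_fields(params),
    links = matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))),
    contacts = matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))),
    mcs = 0L)
  class(st) <- "nc_state"
  st
}

#' Initialize the two-tissue starting configuration
#'
#' Lays out cells as 5 x 5 square patches: 2 rows of NC cells at the dorsal
#' (top) edge and 13 rows of placodal cells directly beneath, the remainder of
#' the lattice cell-free. All polarities are zero, no persistent links or CIL
#' states exist, all concentrations are zero. Cell ids are assigned row-major.
#' A lattice width not divisible by the patch size drops the rightmost partial
#' patch column. Also seeds the simulation RNG stream via `set.seed(seed)`.
#'
#' @param params an `nc_params` object.
#' @param seed integer >= 0; seeds the single RNG stream all subsequent
#'   stochastic updates consume.
#' @return an `nc_state` object (deterministic given `params`).
#' @export
#' @examples
#' st <- init_simulation(nc_params(), seed = 1)
#' table(st$cells$type)   # 36 NC, 468 placode cells
init_simulation <- function(params, seed) {
  stopifnot(length(seed) == 1, seed >= 0, seed == round(seed))
  viol <- validate_params(params)
  if (length(viol))
    stop("invalid parameters:\n  ", paste(viol, collapse = "\n  "))
  patch <- 5L
  n_rows_nc <- 2L
  n_rows_pl <- 13L
  W <- params$lattice_width; H <- params$lattice_height
  ncols <- W %/% patch
  if (ncols < 1L)
    stop("configuration error: lattice too narrow for one 5 x 5 patch")
  if (H < patch * (n_rows_nc + n_rows_pl))
    stop("configuration error: lattice too short for 15 patch rows")
  sigma <- matrix(0L, H, W)
  id <- 0L
  for (r in seq_len(n_rows_nc + n_rows_pl)) {
    ys <- ((r - 1L) * patch + 1L):(r * patch)
    for (cc in seq_len(ncols)) {
      id <- id + 1L
      xs <- ((cc - 1L) * patch + 1L):(cc * patch)
      sigma[ys, xs] <- id
    }
  }
  types <- rep(c(1L, 2L), c(n_rows_nc * ncols, n_rows_pl * ncols))
  st <- state_from_sigma(sigma, types, params)
  st$seed <- as.integer(seed)
  set.seed(seed)
  st
}

#' Logical mask of sites occupied by a cell type
#'
#' @param state an `nc_state` object.
#' @param type `"NC"` or `"PL"`.
#' @return logical matrix of the lattice dimensions.
#' @export
cell_mask <- function(state, type = "NC") {
  tcode <- match.arg(type, c("NC", "PL"))
  tcode <- match(tcode, c("NC", "PL"))
  m <- matrix(FALSE, nrow(state$sigma), ncol(state$sigma))
  occ <- state$sigma > 0
  m[occ] <- state$cells$type[state$sigma[occ]] == tcode
  m
}

#' @export
print.nc_state <- function(x, ...) {
  tt <- table(factor(x$cells$type, 1:2, c("NC", "PL")))
  cat(sprintf("<nc_state> %d x %d lattice, MCS %d\n",
              ncol(x$sigma), nrow(x$sigma), x$mcs))
  cat(sprintf("  %d cells (%d NC, %d PL), %d links, %d in CIL state\n",
              nrow(x$cells), tt[["NC"]], tt[["PL"]],
              nrow(x$links), sum(x$cells$cil)))
  cat(sprintf("  occupied area %d sites; mean c(A,S,I) over core = %.3g, %.3g, %.3g\n",
              sum(x$sigma > 0),
              mean(core_field(x, "A")), mean(core_field(x, "S")),
              mean(core_field(x, "I"))))
  invisible(x)
}

#' Extract the core-lattice part of a concentration field
#'
#' @param state an `nc_state` object.
#' @param substance `"A"`, `"S"` or `"I"`.
#' @param halo halo width used when the state was built (taken from the field
#'   dimensions).
#' @return numeric matrix over the cell lattice (halo stripped).
#' @export
core_field <- function(state, substance = c("A", "S", "I"), halo = NULL) {
  substance <- match.arg(substance)
  f <- state$fields[[substance]]
  H <- nrow(state$sigma); W <- ncol(state$sigma)
  if (is.null(halo)) halo <- (nrow(f) - H) %/% 2
  f[halo + seq_len(H), halo + seq_len(W), drop = FALSE]
}
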