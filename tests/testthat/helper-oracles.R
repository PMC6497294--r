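# Independent brute-force oracles and small state builders used across tests.

# Total Potts energy by full summation over the lattice: area-constraint terms
# plus contact energies over every unordered 8-neighbor site pair. Independent
# of the engine's incremental bookkeeping.
full_H <- function(sigma, types, params) {
  H <- nrow(sigma); W <- ncol(sigma)
  n <- max(sigma, 0L)
  vol <- 0
  if (n > 0) {
    area <- tabulate(sigma[sigma > 0], nbins = n)
    vol <- sum(params$lambda_V * (area - params$V_T)^2)
  }
  tcode <- function(lab) ifelse(lab == 0L, 0L, types[pmax(lab, 1L)] * (lab > 0))
  Jm <- params$J
  bond <- 0
  for (off in list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))) {  # E, SE, S, SW
    dx <- off[1]; dy <- off[2]
    x1 <- max(1, 1 - dx):min(W, W - dx)
    y1 <- max(1, 1 - dy):min(H, H - dy)
    a <- sigma[y1, x1, drop = FALSE]
    b <- sigma[y1 + dy, x1 + dx, drop = FALSE]
    d <- a != b
    if (any(d)) {
      ta <- tcode(a[d]); tb <- tcode(b[d])
      bond <- bond + sum(Jm[cbind(ta + 1L, tb + 1L)])
    }
  }
  vol + bond
}

# Brute-force NC density probability: double loop over all site pairs.
brute_rho <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  sites <- which(mask != 0, arr.ind = TRUE)   # (row = y, col = x)
  num <- matrix(0, 2 * H - 1, 2 * W - 1)
  den <- matrix(0, 2 * H - 1, 2 * W - 1)
  for (i in seq_len(nrow(sites))) {
    y <- sites[i, 1]; x <- sites[i, 2]
    for (dy in -(H - 1):(H - 1)) for (dx in -(W - 1):(W - 1)) {
      y2 <- y + dy; x2 <- x + dx
      if (y2 >= 1 && y2 <= H && x2 >= 1 && x2 <= W) {
        den[dy + H, dx + W] <- den[dy + H, dx + W] + 1
        if (mask[y2, x2] != 0) num[dy + H, dx + W] <- num[dy + H, dx + W] + 1
      }
    }
  }
  rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
  num <- num + rot180(num)
  den <- den + rot180(den)
  rho <- num / den
  rho[den == 0] <- NA_real_
  list(rho = rho, num = num, den = den)
}

# Parameters for a small fast test lattice: fields trivial (D = 0, one
# substep), EMT off, no retraction-independent extras changed.
tiny_params <- function(W = 30, H = 30, ...) {
  nc_params(lattice_width = W, lattice_height = H, halo = 5,
            D_A = 0, D_S = 0, D_I = 0, field_substeps_per_MCS = 1,
            emt_enabled = FALSE, ...)
}

# A single rectangular cell of the given type on an otherwise empty lattice.
single_cell_state <- function(params, x0 = 10, y0 = 10, w = 5, h = 5,
                              type = 1L) {
  sigma <- matrix(0L, params$lattice_height, params$lattice_width)
  sigma[y0:(y0 + h - 1), x0:(x0 + w - 1)] <- 1L
  state_from_sigma(sigma, type, params)
}

# Two square cells separated by `gap` columns (gap = 0: touching).
two_cell_state <- function(params, types = c(1L, 1L), gap = 0, w = 5,
                           x0 = 5, y0 = 10) {
  sigma <- matrix(0L, params$lattice_height, params$lattice_width)
  sigma[y0:(y0 + w - 1), x0:(x0 + w - 1)] <- 1L
  x1 <- x0 + w + gap
  sigma[y0:(y0 + w - 1), x1:(x1 + w - 1)] <- 2L
  state_from_sigma(sigma, types, params)
}

# Random (possibly fragmented) labeling with all labels present.
random_sigma <- function(W, H, n_cells, fill = 0.6) {
  repeat {
    sigma <- matrix(0L, H, W)
    k <- round(fill * W * H)
    sigma[sample(W * H, k)] <- sample(seq_len(n_cells), k, replace = TRUE)
    if (length(unique(sigma[sigma > 0])) == n_cells) return(sigma)
  }
}
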