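#' NC density probability function
#'
#' For every lattice offset `r`, the probability that a site at offset `r`
#' from an NC-occupied reference site is itself NC-occupied, averaged over all
#' NC-occupied reference sites; offsets falling outside the lattice are
#' excluded from both the numerator and the sample count; the reference counts
#' of `+r` and `-r` are pooled (every occupied pair is tallied from both of
#' its ends), so `rho(r) = rho(-r)` holds exactly. This pair-correlation
#' map outlines the average local neighborhood of an NC cell; in stream-forming
#' configurations it is an elongated core oriented along the DV axis whose
#' axis profiles define the characteristic stream width and length.
#'
#' @param nc_mask logical (or 0/1) matrix of NC occupancy,
#'   `lattice_height x lattice_width`.
#' @return an `nc_density` object: list with `rho` (probability matrix over
#'   offsets, rows = DV offsets `dy`, columns = AP offsets `dx`), `num` and
#'   `counts` (per-offset numerator and sample counts, poolable across runs),
#'   `dx`, `dy` (offset coordinates), and `n_sites`. An empty mask yields an
#'   undefined-map sentinel (`undefined = TRUE`, `rho = NULL`).
#' @seealso [width_length()], [pool_density()]
#' @export
density_probability <- function(nc_mask) {
  m <- matrix(as.integer(nc_mask != 0), nrow(nc_mask), ncol(nc_mask))
  H <- nrow(m); W <- ncol(m)
  if (sum(m) == 0) {
    out <- list(rho = NULL, num = NULL, counts = NULL,
                dx = integer(0), dy = integer(0),
                n_sites = 0, undefined = TRUE)
    class(out) <- "nc_density"
    return(out)
  }
  t <- cpp_density_tallies(m)
  # Symmetrized estimator: every occupied pair is counted from both ends, so
  # the numerator is symmetric by construction; pooling the reference counts
  # of +r and -r makes rho(r) = rho(-r) hold exactly and keeps boundary
  # offsets from being estimated from one-sided, low-count tails.
  rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
  num <- t$num + rot180(t$num)
  cnt <- t$denom + rot180(t$denom)
  rho <- num / cnt
  rho[cnt == 0] <- NA_real_
  out <- list(rho = rho, num = num, counts = cnt,
              dx = -(W - 1):(W - 1), dy = -(H - 1):(H - 1),
              n_sites = t$n_sites, undefined = FALSE)
  class(out) <- "nc_density"
  out
}

#' Pool density maps over an ensemble
#'
#' Count-weighted pooling: numerators and sample counts are summed across
#' runs before dividing, so offsets sampled more often weigh more. All maps
#' must share the lattice dimensions; undefined maps are skipped.
#'
#' @param maps list of `nc_density` objects.
#' @return a pooled `nc_density` object.
#' @export
pool_density <- function(maps) {
  maps <- Filter(function(d) !isTRUE(d$undefined), maps)
  if (!length(maps)) {
    out <- list(rho = NULL, num = NULL, counts = NULL, dx = integer(0),
                dy = integer(0), n_sites = 0, undefined = TRUE)
    class(out) <- "nc_density"
    return(out)
  }
  num <- Reduce(`+`, lapply(maps, `[[`, "num"))
  cnt <- Reduce(`+`, lapply(maps, `[[`, "counts"))
  rho <- num / cnt
  rho[cnt == 0] <- NA_real_
  out <- list(rho = rho, num = num, counts = cnt,
              dx = maps[[1]]$dx, dy = maps[[1]]$dy,
              n_sites = sum(vapply(maps, `[[`, 0, "n_sites")),
              undefined = FALSE)
  class(out) <- "nc_density"
  out
}

#' @export
print.nc_density <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("<nc_density> undefined (empty NC mask)\n")
  } else {
    wl <- width_length(x)
    cat(sprintf("<nc_density> offsets %d x %d, %g reference sites; W = %s, L = %s s.u.\n",
                length(x$dx), length(x$dy), x$n_sites,
                format(wl[["W"]], digits = 4), format(wl[["L"]], digits = 4)))
  }
  invisible(x)
}

# first 0.5-crossings on both sides of the origin of a profile indexed by
# integer offsets; linear interpolation between the bracketing offsets.
# Returns NA if the profile reaches undefined territory before crossing.
cross_half <- function(offsets, values, level = 0.5) {
  i0 <- which(offsets == 0)
  locus <- function(idx_seq) {
    prev_v <- values[i0]
    prev_o <- 0
    for (i in idx_seq) {
      v <- values[i]
      if (is.na(v)) return(NA_real_)
      if (v < level)
        return(prev_o + (prev_v - level) / (prev_v - v) * (offsets[i] - prev_o))
      prev_v <- v; prev_o <- offsets[i]
    }
    NA_real_
  }
  if (is.na(values[i0]) || values[i0] < level) return(c(NA_real_, NA_real_))
  right <- locus(seq(i0 + 1L, length(offsets)))
  left <- locus(seq(i0 - 1L, 1L))
  c(left, right)
}

#' Characteristic stream width and length
#'
#' Extracts `W` from the AP-axis profile of the density probability map
#' through the origin and `L` from the DV-axis profile: each is the distance
#' between the two loci where the profile first falls below 0.5 on either
#' side of the origin (50% probability of NC presence), with the crossing
#' located by linear interpolation between the bracketing offsets. If a
#' profile never falls below 0.5 on one side, or the crossing distance is at
#' least the lattice extent along that axis (a correlation "width" cannot
#' exceed the domain that holds it — such profiles mean laterally
#' unsegmented, broad-front configurations), the measure is reported as the
#' undefined sentinel `NA` (the no-streams outcome), never thrown.
#'
#' @param dmap an `nc_density` object.
#' @return named numeric vector `c(W = , L = )` in lattice sites.
#' @export
width_length <- function(dmap) {
  if (isTRUE(dmap$undefined)) return(c(W = NA_real_, L = NA_real_))
  ap <- dmap$rho[which(dmap$dy == 0), ]
  dv <- dmap$rho[, which(dmap$dx == 0)]
  wcr <- cross_half(dmap$dx, ap)
  lcr <- cross_half(dmap$dy, dv)
  # lattice extents recovered from the offset ranges
  wmax <- (length(dmap$dx) + 1) / 2
  lmax <- (length(dmap$dy) + 1) / 2
  w <- if (anyNA(wcr)) NA_real_ else wcr[2] - wcr[1]
  l <- if (anyNA(lcr)) NA_real_ else lcr[2] - lcr[1]
  c(W = if (!is.na(w) && w >= wmax) NA_real_ else w,
    L = if (!is.na(l) && l >= lmax) NA_real_ else l)
}

#' Count NC streams along a horizontal transect
#'
#' Counts connected runs of NC occupancy along the lattice row at a given
#' fractional depth into the initial placodal region, merging runs separated
#' by fewer than `merge_gap` empty sites. Automates the visual stream count
#' of final configurations.
#'
#' @param nc_mask logical NC occupancy matrix.
#' @param depth fraction in (0, 1) of the placodal region depth below the
#'   initial NC/placode interface at which to take the transect.
#' @param interface_y lattice row of the initial NC/placode interface
#'   (default 10: two 5-site NC patch rows).
#' @param region_height depth of the initial placodal region in sites
#'   (default 65: thirteen 5-site patch rows).
#' @param merge_gap runs separated by fewer than this many empty sites are
#'   merged (default 2).
#' @return integer stream count.
#' @export
count_streams <- function(nc_mask, depth = 0.5, interface_y = 10,
                          region_height = 65, merge_gap = 2) {
  stopifnot(depth > 0, depth < 1)
  yline <- interface_y + round(depth * region_height)
  yline <- max(1L, min(nrow(nc_mask), as.integer(yline)))
  row <- as.integer(nc_mask[yline, ] != 0)
  # merge short gaps
  r <- rle(row)
  short_gap <- r$values == 0 & r$lengths < merge_gap
  interior <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
  r$values[short_gap & interior] <- 1L
  row <- inverse.rle(r)
  r2 <- rle(row)
  sum(r2$values == 1L)
}

#' Mean centroid speed from trajectories
#'
#' Average per-MCS centroid displacement magnitude over cells of a type,
#' computed from a long-format trajectory table and averaged over the sampled
#' window. Displacements between consecutive samples are divided by the
#' sample spacing, so sparsely sampled trajectories give a lower bound on the
#' per-MCS speed for meandering cells.
#'
#' @param trajectories data frame with columns `id`, `type` (1 = NC, 2 = PL or
#'   `"NC"`/`"PL"`), `mcs`, `cx`, `cy`.
#' @param type which cells to average over, `"NC"` or `"PL"`.
#' @return mean speed in s.u./MCS; `NA` if no cells of the type have at least
#'   two time points.
#' @export
mean_speed <- function(trajectories, type = "NC") {
  tcode <- if (is.character(trajectories$type))
    type else match(type, c("NC", "PL"))
  tr <- trajectories[trajectories$type == tcode, , drop = FALSE]
  if (!nrow(tr)) return(NA_real_)
  sp <- unlist(lapply(split(tr, tr$id), function(d) {
    d <- d[order(d$mcs), ]
    if (nrow(d) < 2) return(NULL)
    dt <- diff(d$mcs)
    sqrt(diff(d$cx)^2 + diff(d$cy)^2) / dt
  }))
  if (!length(sp)) return(NA_real_)
  mean(sp)
}

#' Convert simulation units to physical units
#'
#' Lengths convert at `microns_per_site` um per lattice site, times at
#' `seconds_per_MCS` s per MCS, and speeds (s.u./MCS) to um/min. With the
#' default calibration (3.5 um, 10 s), 0.1 s.u./MCS is 2.1 um/min and 3600
#' MCS is 10 hours.
#'
#' @param value numeric value(s) in simulation units.
#' @param quantity one of `"length"`, `"time"`, `"speed"`.
#' @param params an `nc_params` object carrying the calibration.
#' @return value in um, s, or um/min respectively.
#' @export
to_physical <- function(value, quantity = c("length", "time", "speed"),
                        params = nc_params()) {
  quantity <- match.arg(quantity)
  switch(quantity,
    length = value * params$microns_per_site,
    time = value * params$seconds_per_MCS,
    speed = value * params$microns_per_site / (params$seconds_per_MCS / 60))
}
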