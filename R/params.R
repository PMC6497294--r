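#' Model parameters for the neural crest / placode simulation
#'
#' Constructs the full parameter set of the cellular Potts model: secretion,
#' diffusion and decay rates of the three diffusible substances (co-attractant
#' `A`, Sdf1 `S`, inhibitor `I`), chemotaxis weights of neural crest (NC)
#' cells, self-propulsion and polarity-persistence parameters, contact
#' inhibition of locomotion (CIL) parameters, persistent-adhesion spring
#' strengths, the Potts contact-energy matrix `J`, lattice geometry, and the
#' physical calibration (3.5 um per lattice site, 10 s per Monte Carlo step).
#'
#' Defaults reproduce the control scenario: a 180 x 95 lattice with two rows
#' of NC patches above thirteen rows of placode patches, run for 3600 MCS.
#' Placodal cells have no chemotaxis (their weights are structurally zero and
#' not part of the parameter set). All rates are per MCS; lengths are in
#' lattice sites (s.u.).
#'
#' @param ... named overrides of any default listed below. Matrix-valued
#'   parameters (`lambda_M`, `J`) can be overridden whole or entry-wise via
#'   [set_params()].
#'
#' @section Main parameters:
#' \describe{
#'   \item{`S_A`, `S_S`, `S_I`}{secretion rates of A (by NC), S and I (by
#'     placodes), per occupied site per MCS (5, 20, 0.7).}
#'   \item{`D_A`, `D_S`, `D_I`}{diffusion coefficients, s.u.^2/MCS (8, 8,
#'     0.005).}
#'   \item{`delta_A`, `delta_S`, `delta_I`}{decay rates, 1/MCS (0.006, 0.006,
#'     0.0006).}
#'   \item{`lambda_A`, `lambda_S_eff`, `lambda_I`}{NC chemotaxis weights
#'     (1, 150, -100); the Sdf1 weight is the effective product quoted as
#'     150 in the source parameter table.}
#'   \item{`lambda_P_NC`, `lambda_P_PL`}{self-propulsion strengths (6, 12).}
#'   \item{`deltaP_*`}{polarity decay per MCS by type and contact status
#'     (NC: 0.3 free / 0.08 contact; placode: 0.5 / 0.1).}
#'   \item{`lambda_CIL`, `p_CIL_NC`, `p_CIL_PL`}{CIL repolarization strength
#'     (0.5) and per-type switching probabilities on new contact (1, 1).}
#'   \item{`lambda_M`}{2 x 2 persistent-adhesion spring strength per cell-type
#'     pair (NC, PL), default 5 everywhere.}
#'   \item{`lambda_V`, `V_T`}{area-constraint stiffness (5) and target area
#'     (25 s.u.^2).}
#'   \item{`J`}{3 x 3 symmetric contact-energy matrix over (medium, NC, PL).}
#'   \item{`U_S`}{Sdf1 uptake rate per NC-occupied site (20/MCS), clamped so
#'     concentrations stay non-negative.}
#'   \item{`field_substeps_per_MCS`}{explicit Euler substeps per MCS (40);
#'     must satisfy max(D) / substeps <= 0.25.}
#' }
#'
#' @return a list of class `nc_params`.
#' @seealso [validate_params()], [set_params()], [link_rest_length()],
#'   [preset_params()]
#' @export
#' @examples
#' p <- nc_params()
#' validate_params(p)           # character(0): defaults are consistent
#' p2 <- nc_params(lattice_width = 90)
nc_params <- function(...) {
  p <- list(
    # secretion / diffusion / decay of A (co-attractant), S (Sdf1), I (inhibitor)
    S_A = 5, S_S = 20, S_I = 0.7,
    D_A = 8, D_S = 8, D_I = 0.005,
    delta_A = 0.006, delta_S = 0.006, delta_I = 0.0006,
    # NC chemotaxis weights (placodes: structurally zero)
    lambda_A = 1, lambda_S_eff = 150, lambda_I = -100,
    # self-propulsion and polarity persistence
    lambda_P_NC = 6, lambda_P_PL = 12,
    deltaP_NC_free = 0.3, deltaP_NC_contact = 0.08,
    deltaP_PL_free = 0.5, deltaP_PL_contact = 0.1,
    # contact inhibition of locomotion
    lambda_CIL = 0.5, p_CIL_NC = 1, p_CIL_PL = 1,
    # persistent adhesion springs, per cell-type pair; the NC-NC strength sits
    # midway between the low (0) and high (2) perturbation endpoints
    lambda_M = matrix(c(1, 5, 5, 5), 2, 2,
                      dimnames = list(c("NC", "PL"), c("NC", "PL"))),
    # area constraint
    lambda_V = 5, V_T = 25,
    # contact energies over (medium, NC, placode); symmetric, J(0,0) = 0
    J = matrix(c(0, 5, 5,
                 5, 3, 20,
                 5, 20, 10), 3, 3, byrow = TRUE,
               dimnames = list(c("0", "NC", "PL"), c("0", "NC", "PL"))),
    # Sdf1 uptake by NC
    U_S = 20,
    # geometry and schedule
    lattice_width = 180, lattice_height = 95, halo = 100,
    total_MCS = 3600, field_substeps_per_MCS = 40,
    p_medium_retraction = 0.1, p_link_form = 0.1, link_break_divisor = 100,
    emt_enabled = TRUE,
    # physical calibration
    microns_per_site = 3.5, seconds_per_MCS = 10
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  class(p) <- "nc_params"
  p
}

#' Override parameters, including entries of matrix-valued ones
#'
#' Scalar parameters are addressed by name. Entries of `lambda_M` and `J` are
#' addressed as `lambda_M_NC_NC`, `lambda_M_NC_PL`, `J_NC_0`, `J_PL_PL`, ...
#' (symmetry is preserved automatically).
#'
#' @param params an `nc_params` object.
#' @param ... named values to set.
#' @return the modified `nc_params` object.
#' @export
#' @examples
#' p <- set_params(nc_params(), lambda_M_NC_NC = 0, lambda_S_eff = 300)
set_params <- function(params, ...) {
  over <- list(...)
  for (nm in names(over)) {
    val <- over[[nm]]
    if (nm %in% names(params)) {
      params[[nm]] <- val
    } else if (grepl("^(lambda_M|J)_(NC|PL|0)_(NC|PL|0)$", nm)) {
      parts <- strsplit(nm, "_")[[1]]
      mat <- parts[1]
      if (mat == "lambda") { # lambda_M_X_Y splits into 4 parts
        mat <- "lambda_M"; i <- parts[3]; j <- parts[4]
      } else {
        i <- parts[2]; j <- parts[3]
      }
      m <- params[[mat]]
      if (!all(c(i, j) %in% rownames(m)))
        stop("invalid pair for ", mat, ": ", nm)
      m[i, j] <- val
      m[j, i] <- val
      params[[mat]] <- m
    } else {
      stop("unknown parameter: ", nm)
    }
  }
  params
}

#' Equilibrium distance of persistently linked cells
#'
#' The rest length of the persistent-adhesion springs, `d0 = 2 sqrt(V_T /
#' pi)`: the diameter of a disk with the target cell area. For the default
#' `V_T = 25` this is about 5.642 s.u.
#'
#' @param params an `nc_params` object.
#' @return rest length in lattice sites.
#' @export
link_rest_length <- function(params) {
  2 * sqrt(params$V_T / pi)
}

#' Check a parameter set for internal consistency
#'
#' Reports, without throwing, every violated invariant: negative rates or
#' diffusion/decay coefficients, non-positive target area, asymmetric contact
#' energies, and an explicit-scheme stability violation (`max(D) / substeps`
#' must not exceed 0.25 on the unit-spaced lattice).
#'
#' @param params an `nc_params` object.
#' @return character vector of violation messages; empty if consistent.
#' @export
validate_params <- function(params) {
  v <- character(0)
  nonneg <- c("S_A", "S_S", "S_I", "D_A", "D_S", "D_I",
              "delta_A", "delta_S", "delta_I", "U_S",
              "p_CIL_NC", "p_CIL_PL", "p_medium_retraction", "p_link_form")
  for (nm in nonneg)
    if (!is.numeric(params[[nm]]) || length(params[[nm]]) != 1 ||
        is.na(params[[nm]]) || params[[nm]] < 0)
      v <- c(v, paste0(nm, ": must be a single non-negative number"))
  for (nm in c("p_CIL_NC", "p_CIL_PL", "p_medium_retraction", "p_link_form"))
    if (is.numeric(params[[nm]]) && length(params[[nm]]) == 1 &&
        !is.na(params[[nm]]) && params[[nm]] > 1)
      v <- c(v, paste0(nm, ": probability exceeds 1"))
  if (!is.numeric(params$V_T) || params$V_T <= 0)
    v <- c(v, "V_T: target area must be positive")
  if (!isTRUE(all.equal(params$J, t(params$J))))
    v <- c(v, "J: contact-energy matrix must be symmetric")
  if (!isTRUE(all.equal(params$lambda_M, t(params$lambda_M))))
    v <- c(v, "lambda_M: spring-strength matrix must be symmetric")
  if (params$lattice_width < 1 || params$lattice_height < 1)
    v <- c(v, "lattice: width and height must be at least 1")
  n <- params$field_substeps_per_MCS
  if (!is.numeric(n) || n < 1 || n != round(n)) {
    v <- c(v, "field_substeps_per_MCS: must be a positive integer")
  } else {
    Dmax <- max(params$D_A, params$D_S, params$D_I)
    if (Dmax / n > 0.25)
      v <- c(v, sprintf(paste0("field_substeps_per_MCS: explicit scheme unstable, ",
                               "max(D)/substeps = %.4g > 0.25"), Dmax / n))
  }
  if (params$total_MCS < 0) v <- c(v, "total_MCS: must be non-negative")
  v
}

#' @export
print.nc_params <- function(x, ...) {
  cat("<nc_params> cellular Potts model parameter set\n")
  cat(sprintf("  lattice %d x %d (+%d halo), %d MCS, %d field substeps/MCS\n",
              x$lattice_width, x$lattice_height, x$halo,
              x$total_MCS, x$field_substeps_per_MCS))
  cat(sprintf("  substances  A: S=%g D=%g delta=%g | S: S=%g D=%g delta=%g U=%g | I: S=%g D=%g delta=%g\n",
              x$S_A, x$D_A, x$delta_A, x$S_S, x$D_S, x$delta_S, x$U_S,
              x$S_I, x$D_I, x$delta_I))
  cat(sprintf("  NC chemotaxis (A,S,I): %g, %g, %g; placodes: none\n",
              x$lambda_A, x$lambda_S_eff, x$lambda_I))
  cat(sprintf("  motility lambda_P (NC,PL): %g, %g; CIL lambda=%g p=(%g,%g)\n",
              x$lambda_P_NC, x$lambda_P_PL, x$lambda_CIL, x$p_CIL_NC, x$p_CIL_PL))
  cat(sprintf("  lambda_V=%g V_T=%g d0=%.3f; lambda_M(NC,NC)=%g\n",
              x$lambda_V, x$V_T, link_rest_length(x), x$lambda_M["NC", "NC"]))
  viol <- validate_params(x)
  if (length(viol)) cat("  !!", length(viol), "invariant violation(s); see validate_params()\n")
  invisible(x)
}

#' Write a parameter set to an annotated YAML file
#'
#' Every field appears under its model-definition name with a short comment
#' giving its meaning and units, so a scenario file is self-documenting.
#'
#' @param params an `nc_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  notes <- c(
    S_A = "secretion rate of co-attractant A by NC [1/MCS]",
    S_S = "secretion rate of Sdf1 S by placodes [1/MCS]",
    S_I = "secretion rate of inhibitor I by placodes [1/MCS]",
    D_A = "diffusion of A [s.u.^2/MCS]", D_S = "diffusion of S [s.u.^2/MCS]",
    D_I = "diffusion of I [s.u.^2/MCS]",
    delta_A = "decay of A [1/MCS]", delta_S = "decay of S [1/MCS]",
    delta_I = "decay of I [1/MCS]",
    lambda_A = "NC chemotaxis weight, co-attractant",
    lambda_S_eff = "NC chemotaxis weight, Sdf1 (effective)",
    lambda_I = "NC chemotaxis weight, inhibitor (negative = repulsion)",
    lambda_P_NC = "self-propulsion strength, NC",
    lambda_P_PL = "self-propulsion strength, placode",
    deltaP_NC_free = "polarity decay, NC without contact",
    deltaP_NC_contact = "polarity decay, NC with contact",
    deltaP_PL_free = "polarity decay, placode without contact",
    deltaP_PL_contact = "polarity decay, placode with contact",
    lambda_CIL = "CIL repolarization strength",
    p_CIL_NC = "CIL switching probability, NC",
    p_CIL_PL = "CIL switching probability, placode",
    lambda_M = "persistent adhesion spring strength per type pair",
    lambda_V = "cell incompressibility", V_T = "target cell area [s.u.^2]",
    J = "contact energies over (medium, NC, placode)",
    U_S = "Sdf1 uptake rate per NC site [1/MCS]",
    lattice_width = "cell lattice width (AP axis) [s.u.]",
    lattice_height = "cell lattice height (DV axis) [s.u.]",
    halo = "field-only lattice extension on each side [s.u.]",
    total_MCS = "simulation length [MCS]",
    field_substeps_per_MCS = "explicit diffusion substeps per MCS",
    p_medium_retraction = "probability a copy attempt writes medium",
    p_link_form = "per-MCS link formation probability for contacting pairs",
    link_break_divisor = "divisor in link break probability (|r|-d0)/divisor",
    emt_enabled = "insert new NC cells at the dorsal edge (EMT)",
    microns_per_site = "physical calibration [um per lattice site]",
    seconds_per_MCS = "physical calibration [s per MCS]"
  )
  lines <- character(0)
  for (nm in names(unclass(params))) {
    cm <- if (nm %in% names(notes)) paste0("  # ", notes[[nm]]) else ""
    val <- params[[nm]]
    if (is.matrix(val)) {
      lines <- c(lines, paste0(nm, ":", cm))
      body <- strsplit(yaml::as.yaml(apply(val, 1, as.vector, simplify = FALSE)),
                       "\n")[[1]]
      lines <- c(lines, paste0("  ", body))
    } else {
      v <- sub("\n$", "", yaml::as.yaml(val))
      lines <- c(lines, paste0(nm, ": ", v, cm))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file written by [write_params_yaml()] or by hand.
#' @return an `nc_params` object.
#' @export
read_params_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  p <- nc_params()
  bad <- setdiff(names(raw), names(p))
  if (length(bad)) stop("unknown parameter(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  for (nm in names(raw)) {
    val <- raw[[nm]]
    if (is.matrix(p[[nm]])) {
      m <- do.call(rbind, val)
      dimnames(m) <- dimnames(p[[nm]])
      p[[nm]] <- m
    } else {
      p[[nm]] <- val
    }
  }
  p
}
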