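#' @importFrom stats approx cor lm coef median mad qnorm rbinom rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv modifyList head tail
NULL

# vacuum permittivity, F/m
EPS0 <- 8.8541878128e-12

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, msg, ...) if (isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)

#' Suspending medium description
#'
#' A homogeneous conductive medium (typically PBS) in which particles are
#' suspended during impedance detection.
#'
#' @param conductivity Electrical conductivity in S/m (> 0).
#' @param relative_permittivity Relative permittivity (>= 1).
#' @return An object of class `medium`.
#' @export
#' @examples
#' pbs <- medium(conductivity = 1.6, relative_permittivity = 78)
medium <- function(conductivity = 1.6, relative_permittivity = 78) {
  stop_if(!is.numeric(conductivity) || conductivity <= 0,
          "medium conductivity must be > 0 S/m")
  stop_if(relative_permittivity < 1, "relative permittivity must be >= 1")
  structure(list(conductivity = conductivity,
                 relative_permittivity = relative_permittivity),
            class = "medium")
}

#' Single-shell cell description
#'
#' Represents a cell as a conducting cytoplasm sphere wrapped in a thin,
#' poorly conducting membrane shell (the single-shell dielectric model).
#' Dimensions are accepted at the boundary in micrometres (diameter) and
#' nanometres (membrane thickness) and converted to SI internally.
#'
#' @param diameter Cell diameter in micrometres, in (1, 50).
#' @param membrane_thickness Membrane thickness in nanometres.
#' @param membrane_conductivity Membrane conductivity, S/m (>= 0).
#' @param membrane_relative_permittivity Membrane relative permittivity (>= 1).
#' @param cytoplasm_conductivity Cytoplasm conductivity, S/m (>= 0).
#' @param cytoplasm_relative_permittivity Cytoplasm relative permittivity (>= 1).
#' @param label Class label: one of "WBC", "TUMOR", "OTHER".
#' @param subtype Free-text subtype (e.g. "MCF-7").
#' @return An object of class `shelled_cell`.
#' @seealso [cell_preset()] for shipped parameter sets.
#' @export
shelled_cell <- function(diameter, membrane_thickness = 7,
                         membrane_conductivity = 1e-7,
                         membrane_relative_permittivity = 6.5,
                         cytoplasm_conductivity = 0.65,
                         cytoplasm_relative_permittivity = 60,
                         label = c("WBC", "TUMOR", "OTHER"),
                         subtype = "") {
  label <- match.arg(label)
  stop_if(diameter <= 1 || diameter >= 50, "diameter must lie in (1, 50) um")
  stop_if(membrane_thickness <= 0, "membrane thickness must be > 0 nm")
  stop_if(membrane_thickness * 1e-3 >= diameter / 2,
          "membrane thickness must be smaller than the cell radius")
  stop_if(membrane_conductivity < 0 || cytoplasm_conductivity < 0,
          "conductivities must be >= 0")
  stop_if(membrane_relative_permittivity < 1 ||
          cytoplasm_relative_permittivity < 1, "permittivities must be >= 1")
  structure(list(diameter = diameter,
                 membrane_thickness = membrane_thickness,
                 membrane_conductivity = membrane_conductivity,
                 membrane_relative_permittivity = membrane_relative_permittivity,
                 cytoplasm_conductivity = cytoplasm_conductivity,
                 cytoplasm_relative_permittivity = cytoplasm_relative_permittivity,
                 label = label, subtype = subtype),
            class = "shelled_cell")
}

#' Homogeneous bead description
#'
#' A solid dielectric sphere (e.g. a polystyrene calibration particle).
#'
#' @param diameter Diameter in micrometres, in (1, 50).
#' @param relative_permittivity Relative permittivity (>= 1).
#' @param conductivity Conductivity, S/m (>= 0).
#' @return An object of class `bead_particle`.
#' @export
bead_particle <- function(diameter, relative_permittivity = 2.5,
                          conductivity = 0) {
  stop_if(diameter <= 1 || diameter >= 50, "diameter must lie in (1, 50) um")
  stop_if(conductivity < 0, "conductivity must be >= 0")
  stop_if(relative_permittivity < 1, "relative permittivity must be >= 1")
  structure(list(diameter = diameter,
                 relative_permittivity = relative_permittivity,
                 conductivity = conductivity,
                 label = "OTHER", subtype = "bead"),
            class = "bead_particle")
}

# complex (absolute) permittivity eps* = eps0*er - j*sigma/omega
complex_permittivity <- function(relative_permittivity, conductivity, frequency) {
  EPS0 * relative_permittivity - 1i * conductivity / (2 * pi * frequency)
}

#' Equivalent complex permittivity of a shelled sphere
#'
#' Collapses the single-shell model (cytoplasm core of radius R - t inside a
#' membrane shell of outer radius R) into one homogeneous sphere with the
#' standard two-phase mixture result
#' \deqn{\epsilon_p^* = \epsilon_{mem}^* \frac{\gamma^3 + 2K}{\gamma^3 - K},
#'   \quad \gamma = R/(R - t),\quad
#'   K = \frac{\epsilon_{cyt}^* - \epsilon_{mem}^*}
#'            {\epsilon_{cyt}^* + 2\epsilon_{mem}^*}}
#' where \eqn{\epsilon^* = \epsilon_0\epsilon_r - j\sigma/\omega}.
#'
#' @param cell A [shelled_cell()].
#' @param frequency Field frequency in Hz (> 0). May be a vector.
#' @return Complex relative permittivity (equivalent \eqn{\epsilon_p^*/\epsilon_0}),
#'   same length as `frequency`.
#' @export
equivalent_complex_permittivity <- function(cell, frequency) {
  stopifnot(inherits(cell, "shelled_cell"))
  stop_if(any(frequency <= 0), "frequency must be > 0 Hz")
  R <- cell$diameter * 1e-6 / 2
  t <- cell$membrane_thickness * 1e-9
  stop_if(t >= R, "membrane thickness must be smaller than the radius")
  g3 <- (R / (R - t))^3
  em <- complex_permittivity(cell$membrane_relative_permittivity,
                             cell$membrane_conductivity, frequency)
  ec <- complex_permittivity(cell$cytoplasm_relative_permittivity,
                             cell$cytoplasm_conductivity, frequency)
  K <- (ec - em) / (ec + 2 * em)
  em * (g3 + 2 * K) / (g3 - K) / EPS0
}

#' Complex Clausius-Mossotti factor
#'
#' Frequency-dependent polarizability contrast between a particle and the
#' suspending medium,
#' \eqn{CM = (\epsilon_p^* - \epsilon_m^*) / (\epsilon_p^* + 2\epsilon_m^*)},
#' which sets the amplitude and phase of the impedance perturbation a particle
#' produces at each excitation frequency. Its real part is bounded in
#' \[-0.5, 1\] for physical parameters.
#'
#' @param particle A [shelled_cell()] or [bead_particle()].
#' @param medium A [medium()].
#' @param frequency Frequency in Hz (> 0). May be a vector.
#' @return Complex factor, same length as `frequency`.
#' @export
#' @examples
#' clausius_mossotti(bead_particle(10), medium(), c(0.5e6, 1e6, 2e6))
clausius_mossotti <- function(particle, medium, frequency) {
  stopifnot(inherits(medium, "medium"))
  stop_if(any(frequency <= 0), "frequency must be > 0 Hz")
  ep <- if (inherits(particle, "shelled_cell")) {
    equivalent_complex_permittivity(particle, frequency) * EPS0
  } else if (inherits(particle, "bead_particle")) {
    complex_permittivity(particle$relative_permittivity,
                         particle$conductivity, frequency)
  } else stop("particle must be a shelled_cell or bead_particle", call. = FALSE)
  em <- complex_permittivity(medium$relative_permittivity,
                             medium$conductivity, frequency)
  (ep - em) / (ep + 2 * em)
}

#' Specific membrane capacitance of a single-shell cell
#'
#' Convenience quantity \eqn{C_{mem} = \epsilon_0 \epsilon_{mem} / t}, F/m^2.
#'
#' @param cell A [shelled_cell()].
#' @return Specific membrane capacitance in F/m^2.
#' @export
membrane_capacitance <- function(cell) {
  stopifnot(inherits(cell, "shelled_cell"))
  EPS0 * cell$membrane_relative_permittivity / (cell$membrane_thickness * 1e-9)
}
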