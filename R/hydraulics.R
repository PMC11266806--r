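# Analytic hydraulic-resistance and flow-divider arithmetic for the
# flow-resistance-ratio (FR ratio) outlet designs.

#' Microchannel geometry
#'
#' @param shape "rectangular" or "trapezoidal".
#' @param width Channel width, um.
#' @param height Channel height, um (rectangular), or omit and give
#'   `inner_height`/`outer_height` for a trapezoid.
#' @param length Channel length, mm.
#' @param viscosity Fluid dynamic viscosity, Pa s (water at room temperature
#'   by default).
#' @param inner_height,outer_height Trapezoid heights at the two side walls,
#'   um.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(shape = c("rectangular", "trapezoidal"),
                             width, height = NULL, length,
                             viscosity = 1e-3,
                             inner_height = NULL, outer_height = NULL) {
  shape <- match.arg(shape)
  if (shape == "trapezoidal") {
    stop_if(is.null(inner_height) || is.null(outer_height),
            "trapezoidal channels need inner_height and outer_height")
    height <- (inner_height + outer_height) / 2
  }
  stop_if(any(c(width, height, length, viscosity) <= 0),
          "all channel dimensions must be > 0")
  structure(list(shape = shape, width = width, height = height,
                 length = length, viscosity = viscosity,
                 inner_height = inner_height, outer_height = outer_height),
            class = "channel_geometry")
}

#' Hydraulic resistance of a straight microchannel
#'
#' Laminar (Poiseuille) resistance of a rectangular duct from the standard
#' series solution,
#' \deqn{R = \frac{12 \mu L}{w h^3}
#'   \left[1 - \sum_{n \ odd} \frac{192 h}{\pi^5 n^5 w}
#'   \tanh\left(\frac{n \pi w}{2 h}\right)\right]^{-1}, \quad w \ge h.}
#' Trapezoidal channels use the rectangular equivalent at the mean height
#' times a documented correction factor (hook for a calibrated value; the
#' separation advantages of the trapezoid are hydrodynamic, not resistive,
#' and out of scope here).
#'
#' @param geometry A [channel_geometry()].
#' @param n_terms Number of odd series terms.
#' @param trapezoid_correction Multiplicative correction applied to the
#'   mean-height rectangular equivalent for trapezoidal channels.
#' @return Hydraulic resistance, Pa s / m^3.
#' @export
channel_resistance <- function(geometry, n_terms = 50,
                               trapezoid_correction = 1) {
  stopifnot(inherits(geometry, "channel_geometry"))
  w <- geometry$width * 1e-6
  h <- geometry$height * 1e-6
  L <- geometry$length * 1e-3
  if (h > w) { tmp <- w; w <- h; h <- tmp }  # series requires w >= h
  n <- 2 * seq_len(n_terms) - 1
  corr <- 1 - sum(192 * h / (pi^5 * n^5 * w) * tanh(n * pi * w / (2 * h)))
  R <- 12 * geometry$viscosity * L / (w * h^3 * corr)
  if (geometry$shape == "trapezoidal") R <- R * trapezoid_correction
  R
}

#' Flow divider
#'
#' A junction splitting one inlet into parallel outlet branches that share
#' the same pressure drop, so outlet flows are proportional to inverse
#' resistance. Only relative resistances matter.
#'
#' @param inlet_flow Inlet flow rate (any unit; outlets come back in the
#'   same unit).
#' @param resistances Relative flow resistances of the outlet branches
#'   (length >= 2).
#' @return An object of class `flow_divider`.
#' @export
flow_divider <- function(inlet_flow, resistances) {
  stop_if(length(resistances) < 2, "need at least 2 outlets")
  stop_if(any(resistances <= 0), "resistances must be > 0")
  stop_if(inlet_flow <= 0, "inlet flow must be > 0")
  structure(list(inlet_flow = inlet_flow, resistances = resistances),
            class = "flow_divider")
}

#' Outlet flows of a divider
#'
#' @param divider A [flow_divider()].
#' @return Numeric vector of outlet flows in the inlet's unit; sums to the
#'   inlet flow exactly.
#' @export
#' @examples
#' # spiral outlet design: inner:outer resistance ratio 2.0 at 3 ml/min
#' divider_flows(flow_divider(3.0, c(2.0, 1.0)))   # inner outlet: 1 ml/min
#' # serpentine trifurcation: central:side ratio 1.10 at 1000 ul/min
#' divider_flows(flow_divider(1000, c(1.10, 1, 1)))  # central: 312.5 ul/min
divider_flows <- function(divider) {
  stopifnot(inherits(divider, "flow_divider"))
  g <- 1 / divider$resistances
  divider$inlet_flow * g / sum(g)
}

#' Cell throughput of an inlet stream
#'
#' @param concentration Cells per ml.
#' @param flow_ml_min Flow rate, ml/min.
#' @return Cells per second.
#' @export
cell_throughput <- function(concentration, flow_ml_min) {
  stop_if(concentration < 0 || flow_ml_min < 0, "inputs must be >= 0")
  concentration * flow_ml_min / 60
}
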