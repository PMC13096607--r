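#' Geometry of the modelled cartilage layer
#'
#' The two articulating plugs are represented as a single axisymmetric
#' layer whose thickness is the average of the pair's thicknesses.
#'
#' @param radius Plug radius \[mm\] (default 3.5, i.e. 7 mm diameter).
#' @param thickness Model layer thickness \[mm\] (average of the two
#'   plugs).
#' @param n_r,n_z Element counts in the radial and axial directions
#'   (default 60 x 40 = 2,400 elements).
#' @return A `creep_geometry` list.
#' @export
creep_geometry <- function(radius = 3.5, thickness = 1.7,
                           n_r = 60, n_z = 40) {
  stopifnot(radius > 0, thickness > 0, n_r >= 1, n_z >= 1)
  structure(list(radius = radius, thickness = thickness,
                 n_r = as.integer(n_r), n_z = as.integer(n_z)),
            class = "creep_geometry")
}

#' Creep loading protocol
#'
#' A constant nominal compressive stress held for the duration of the
#' experiment; the load is ramped on linearly over `ramp_duration` (the
#' physical test loads at 1 mm/s displacement rate, which reaches the
#' target stress within a fraction of a second at this stress scale).
#'
#' @param applied_stress Nominal compressive stress \[MPa\] (default
#'   0.78).
#' @param ramp_duration Load ramp time \[s\] (default 0.5).
#' @param hold_duration Total simulated time \[s\] (default 10,000).
#' @param output_times Monotone sampling grid \[s\]; default is the ramp
#'   end plus 80 log-spaced times to `hold_duration`.
#' @return A `loading_protocol` list.
#' @export
loading_protocol <- function(applied_stress = 0.78, ramp_duration = 0.5,
                             hold_duration = 10000, output_times = NULL) {
  stopifnot(applied_stress > 0, ramp_duration > 0,
            hold_duration > ramp_duration)
  if (is.null(output_times)) {
    output_times <- c(ramp_duration,
                      ramp_duration + 10^seq(log10(0.05),
                                             log10(hold_duration -
                                                     ramp_duration),
                                             length.out = 80))
  }
  stopifnot(all(diff(output_times) > 0),
            max(output_times) <= hold_duration + 1e-9)
  structure(list(applied_stress = applied_stress,
                 ramp_duration = ramp_duration,
                 hold_duration = hold_duration,
                 output_times = output_times),
            class = "loading_protocol")
}

#' Build the structured axisymmetric mesh
#'
#' Structured quadrilateral mesh of bilinear displacement / bilinear pore
#' pressure elements on \[0, radius\] x \[0, thickness\]; nodes are
#' numbered axially first (z-fastest) to keep the assembled system
#' banded. Boundary tags identify the symmetry axis (r = 0), the free
#' outer edge (r = radius), the cartilage-bone interface (z = 0) and the
#' platen contact surface (z = thickness).
#'
#' @param geometry A [creep_geometry()].
#' @return A `fe_mesh` with nodal coordinates \[mm\], element
#'   connectivity, and boundary node index vectors.
#' @export
#' @examples
#' m <- build_mesh(creep_geometry(thickness = 1.7))
#' nrow(m$elems)  # 2400
build_mesh <- function(geometry) {
  stopifnot(inherits(geometry, "creep_geometry"))
  n_r <- geometry$n_r; n_z <- geometry$n_z
  r <- seq(0, geometry$radius, length.out = n_r + 1)
  z <- seq(0, geometry$thickness, length.out = n_z + 1)
  # z-fastest numbering: node (i, j) -> i * (n_z + 1) + j + 1
  nodes <- cbind(r = rep(r, each = n_z + 1), z = rep(z, times = n_r + 1))
  nid <- function(i, j) i * (n_z + 1) + j + 1
  ii <- rep(0:(n_r - 1), each = n_z)
  jj <- rep(0:(n_z - 1), times = n_r)
  elems <- cbind(nid(ii, jj), nid(ii + 1, jj),
                 nid(ii + 1, jj + 1), nid(ii, jj + 1))
  structure(list(
    nodes = nodes, elems = elems, geometry = geometry,
    axis_nodes = nid(0, 0:n_z),
    outer_nodes = nid(n_r, 0:n_z),
    bottom_nodes = nid(0:n_r, 0),
    top_nodes = nid(0:n_r, n_z)),
    class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  g <- x$geometry
  cat(sprintf(paste0("Axisymmetric u-p mesh: %d x %d = %d elements, ",
                     "%d nodes (%.3g mm x %.3g mm)\n"),
              g$n_r, g$n_z, nrow(x$elems), nrow(x$nodes),
              g$radius, g$thickness))
  invisible(x)
}
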