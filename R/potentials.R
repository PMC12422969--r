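# Analytic 2D toy potentials for the Langevin metadynamics driver.
# These are desk-scale stand-ins for the molecular system: the two CVs
# are the coordinates themselves, so the exact free-energy surface is
# the potential itself (up to a constant).

#' Analytic toy potential
#'
#' Two forms are provided:
#' \describe{
#' \item{`tilted_double_well`}{`U(x, y) = barrier*(x^2 - 1)^2 -
#'   (delta/4)*(3x - x^3) + 0.5*ky*y^2`. The tilt term has zero slope
#'   at `x = +/-1`, so the minima sit exactly at `(+1, 0)` and
#'   `(-1, 0)` with `U(-1,0) - U(+1,0) = delta` exactly (the right
#'   well is the deeper one for positive `delta`). `barrier` sets the
#'   quartic barrier height at `x = 0`.}
#' \item{`harmonic`}{`U(x, y) = 0.5*kx*(x - x0)^2 +
#'   0.5*ky*(y - y0)^2`.}
#' }
#'
#' @param form `"tilted_double_well"` or `"harmonic"`.
#' @param barrier,delta,ky double-well parameters (kJ/mol; `ky` in
#'   kJ/mol per CV-unit^2).
#' @param kx,x0,y0 harmonic parameters.
#' @return object of class `toy_potential`.
#' @export
toy_potential <- function(form = c("tilted_double_well", "harmonic"),
                          barrier = 12, delta = 5, ky = 10,
                          kx = 10, x0 = 0, y0 = 0) {
  form <- match.arg(form)
  params <- if (form == "tilted_double_well") {
    stopifnot(barrier > 0, ky > 0)
    c(barrier = barrier, delta = delta, ky = ky)
  } else {
    stopifnot(kx > 0, ky > 0)
    c(kx = kx, ky = ky, x0 = x0, y0 = y0)
  }
  structure(list(form = form, params = params), class = "toy_potential")
}

#' Evaluate a toy potential
#'
#' @param pot a [toy_potential()].
#' @param x,y coordinates (vectorized).
#' @return energy in kJ/mol.
#' @export
toy_potential_energy <- function(pot, x, y) {
  stopifnot(inherits(pot, "toy_potential"))
  p <- pot$params
  if (pot$form == "tilted_double_well") {
    p[["barrier"]] * (x^2 - 1)^2 -
      (p[["delta"]] / 4) * (3 * x - x^3) + 0.5 * p[["ky"]] * y^2
  } else {
    0.5 * p[["kx"]] * (x - p[["x0"]])^2 +
      0.5 * p[["ky"]] * (y - p[["y0"]])^2
  }
}

#' Gradient of a toy potential
#'
#' @inheritParams toy_potential_energy
#' @return list with vectors `dx`, `dy` (kJ/mol per CV unit).
#' @export
toy_potential_grad <- function(pot, x, y) {
  stopifnot(inherits(pot, "toy_potential"))
  p <- pot$params
  if (pot$form == "tilted_double_well") {
    list(dx = 4 * p[["barrier"]] * x * (x^2 - 1) +
           (3 * p[["delta"]] / 4) * (x^2 - 1),
         dy = p[["ky"]] * y)
  } else {
    list(dx = p[["kx"]] * (x - p[["x0"]]),
         dy = p[["ky"]] * (y - p[["y0"]]))
  }
}

# integer code for the C++ driver
potential_code <- function(pot) {
  switch(pot$form, tilted_double_well = 1L, harmonic = 2L)
}
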