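check_z <- function(z, z_hat, lower = 0L) {
  if (anyNA(z) || any(z < lower) || any(z > z_hat) || any(z != floor(z))) {
    stop("copy number z out of range [", lower, ", ", z_hat, "]")
  }
  as.integer(z)
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || !(alpha %in% c(0, 1))) {
    stop("alpha must be 0 (no antibiotics) or 1 (antibiotics)")
  }
  as.integer(alpha)
}

#' Bacterial division rate
#'
#' Plasmid-free cells (`z = 0`) divide at `beta0` without antibiotics and not
#' at all in their presence. Plasmid-bearing cells are resistant and divide at
#' `beta0 * (1 - burden_scale*z/z_hat)+` in either environment: the metabolic
#' burden reduces the division rate linearly with the load, reaching zero at
#' the cap (for `burden_scale = 1`). The positive part guards against
#' negative rates.
#'
#' @param z copy number(s), `0..z_hat` (vectorized).
#' @param alpha environment flag: 0 without, 1 with antibiotics.
#' @param params [model_parameters()].
#' @return Division rate(s), per hour.
#' @examples
#' p <- model_parameters()
#' division_rate(0, 0, p)   # 1/h
#' division_rate(0, 1, p)   # 0: no reproduction under antibiotics
#' division_rate(25, 1, p)  # 0.5/h: burden only, alpha-independent for z >= 1
#' @export
division_rate <- function(z, alpha, params) {
  stopifnot(inherits(params, "plasmid_params"))
  z <- check_z(z, params$z_hat)
  alpha <- check_alpha(alpha)
  out <- params$beta0 * pmax(0, 1 - params$burden_scale * z / params$z_hat)
  out[z == 0L] <- if (alpha == 1L) 0 else params$beta0
  out
}

#' Bacterial death rate
#'
#' Only plasmid-free cells die, and only in the presence of antibiotics, at
#' rate `mu0`; any plasmid confers full protection.
#'
#' @inheritParams division_rate
#' @return Death rate(s), per hour.
#' @export
death_rate <- function(z, alpha, params) {
  stopifnot(inherits(params, "plasmid_params"))
  z <- check_z(z, params$z_hat)
  alpha <- check_alpha(alpha)
  ifelse(z == 0L & alpha == 1L, params$mu0, 0)
}

#' Plasmid replication rate within a cell
#'
#' Logistic birth process: `b * z * (1 - z/z_hat)`, zero at `z = 0` and at
#' the carrying capacity `z = z_hat`.
#'
#' @inheritParams division_rate
#' @return Replication rate(s), per hour.
#' @export
plasmid_birth_rate <- function(z, params) {
  stopifnot(inherits(params, "plasmid_params"))
  z <- check_z(z, params$z_hat)
  params$b * z * (1 - z / params$z_hat)
}

#' Per-plasmid fitness cost of the linear burden
#'
#' Under the linear burden model each plasmid reduces the division rate by
#' the fraction `burden_scale / z_hat`, i.e. `100 * burden_scale / z_hat`
#' percent: 2% per plasmid at `z_hat = 50` and 0.125% at `z_hat = 800`.
#'
#' @param params [model_parameters()].
#' @return Percent reduction of the division rate per plasmid.
#' @export
burden_per_plasmid_pct <- function(params) {
  stopifnot(inherits(params, "plasmid_params"))
  100 * params$burden_scale / params$z_hat
}
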