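#' Two-generation conceptual model of segregation
#'
#' A deterministic caricature that isolates the two forces shaping the
#' evolutionarily stable strategy. A newborn cell with `z0` plasmids divides
#' after the fixed time `T(z0) = 1/(beta0 (1 - z0/z_hat))`; its fitness is
#' the division rate `f0(z0) = beta0 (1 - z0/z_hat)`. During the cell cycle
#' plasmids replicate logistically, so the load just before division is the
#' logistic flow evaluated at `T(z0)`:
#' `F(z0) = z_hat z0 / (z0 + (z_hat - z0) exp(-(b/beta0)/(1 - z0/z_hat)))`,
#' with `F(z0) <= z_hat`. Division splits the load `(1+a)F/2` versus
#' `(1-a)F/2` with asymmetry `a` in `[0, 1]`. Because the burden is linear,
#' the first-generation mean fitness is independent of `a`; because `F` is
#' concave, the second-generation mean fitness increases with `a`; and under
#' the protection factor `q(z) = z/(K + z)` (the value of carrying plasmids
#' when antibiotics may appear) the protected first-generation mean fitness
#' decreases with `a`.
#'
#' Copy numbers are treated as continuous here - the argument is
#' deterministic.
#'
#' @param z0 initial (newborn) copy number, `0 <= z0 < z_hat` (vectorized).
#' @param params [model_parameters()] (only `beta0`, `b`, `z_hat` are used;
#'   the conceptual model carries no burden scaling).
#' @return `fitness_f0`: per-hour fitness; `division_time`: hours;
#'   `end_of_cycle_load`: copy number (real-valued).
#' @name conceptual_model
NULL

check_z0_cont <- function(z0, z_hat, strict_upper = FALSE) {
  if (anyNA(z0) || any(z0 < 0) || any(z0 > z_hat) ||
      (strict_upper && any(z0 >= z_hat))) {
    stop("z0 must lie in [0, z_hat", if (strict_upper) ")" else "]")
  }
  as.numeric(z0)
}

#' @rdname conceptual_model
#' @export
fitness_f0 <- function(z0, params) {
  stopifnot(inherits(params, "plasmid_params"))
  z0 <- check_z0_cont(z0, params$z_hat)
  params$beta0 * (1 - z0 / params$z_hat)
}

#' @rdname conceptual_model
#' @export
division_time <- function(z0, params) {
  stopifnot(inherits(params, "plasmid_params"))
  z0 <- check_z0_cont(z0, params$z_hat)
  if (any(z0 >= params$z_hat)) {
    stop("division time is infinite at z0 = z_hat (the cell never divides)")
  }
  1 / fitness_f0(z0, params)
}

#' @rdname conceptual_model
#' @export
end_of_cycle_load <- function(z0, params) {
  stopifnot(inherits(params, "plasmid_params"))
  z_hat <- params$z_hat
  z0 <- check_z0_cont(z0, z_hat)
  out <- numeric(length(z0))
  at_cap <- z0 >= z_hat
  out[at_cap] <- z_hat                    # limiting value; flagged below
  i <- !at_cap
  bT <- (params$b / params$beta0) / (1 - z0[i] / z_hat)
  out[i] <- z_hat * z0[i] / (z0[i] + (z_hat - z0[i]) * exp(-bT))
  if (any(at_cap)) attr(out, "at_cap") <- which(at_cap)
  out
}

#' Daughter fitnesses under asymmetric segregation
#'
#' The mother's end-of-cycle load `F(z0)` is split `(1+a)/2` versus
#' `(1-a)/2`; the daughters' fitnesses are
#' `f_pm = beta0 (1 - (1 +- a) F(z0) / (2 z_hat))`. Both are non-negative
#' since `F <= z_hat`, and their mean is independent of `a`.
#'
#' @inheritParams conceptual_model
#' @param a asymmetry in `[0, 1]`; `a = 0` is equal segregation.
#' @return A data.frame: `f_plus` (heavier daughter) and `f_minus` (lighter
#'   daughter), per hour.
#' @export
daughter_fitnesses <- function(z0, a, params) {
  stopifnot(inherits(params, "plasmid_params"))
  if (any(a < 0) || any(a > 1)) stop("a must lie in [0, 1]")
  Fz <- end_of_cycle_load(z0, params)
  data.frame(
    f_plus = params$beta0 * (1 - (1 + a) * Fz / (2 * params$z_hat)),
    f_minus = params$beta0 * (1 - (1 - a) * Fz / (2 * params$z_hat))
  )
}

#' Mean fitness in the second generation
#'
#' With `z1 = F(z0)`, the four grandchildren start from loads
#' `(1 +- a)F((1 +- a) z1/2)/2` and the mean fitness is
#' `beta0 (1 - [F((1+a)z1/2) + F((1-a)z1/2)] / (4 z_hat))`. Concavity of `F`
#' makes this strictly increasing in `a`: dumping plasmids into one daughter
#' pays off one generation later.
#'
#' @inheritParams daughter_fitnesses
#' @return Mean second-generation fitness, per hour.
#' @export
gen2_average_fitness <- function(z0, a, params) {
  stopifnot(inherits(params, "plasmid_params"))
  if (any(a < 0) || any(a > 1)) stop("a must lie in [0, 1]")
  z1 <- end_of_cycle_load(z0, params)
  Fp <- end_of_cycle_load((1 + a) * z1 / 2, params)
  Fm <- end_of_cycle_load((1 - a) * z1 / 2, params)
  params$beta0 * (1 - (Fp + Fm) / (4 * params$z_hat))
}

#' Protection factor
#'
#' Relative fitness retained against the risk of plasmid loss when starting
#' with `z` plasmids: `q(z) = z / (K + z)`, increasing and concave with
#' `q(0) = 0`, `q(K) = 1/2`, `q -> 1`. `K` is the copy number at half
#' protection.
#'
#' @param z copy number(s), >= 0 (continuous).
#' @param K half-protection copy number, > 0.
#' @return Values in `[0, 1)`.
#' @export
protection_factor <- function(z, K) {
  if (any(z < 0)) stop("z must be non-negative")
  if (length(K) != 1L || K <= 0) stop("K must be a single positive number")
  z / (K + z)
}

#' Protected mean fitness in the first generation
#'
#' Weights each daughter's fitness by her protection factor:
#' `f1_bar = (q((1+a)z1/2) f_plus + q((1-a)z1/2) f_minus) / 2` with
#' `z1 = F(z0)`. Because `q` is concave increasing, the loss of protection
#' in the lighter daughter outweighs the gain in the heavier one: the
#' protected mean fitness decreases in `a`, favoring equal segregation at
#' low copy numbers.
#'
#' @inheritParams daughter_fitnesses
#' @param K half-protection copy number.
#' @return Protected mean first-generation fitness, per hour.
#' @export
protected_gen1_fitness <- function(z0, a, K, params) {
  z1 <- end_of_cycle_load(z0, params)
  ff <- daughter_fitnesses(z0, a, params)
  qp <- protection_factor((1 + a) * z1 / 2, K)
  qm <- protection_factor((1 - a) * z1 / 2, K)
  (qp * ff$f_plus + qm * ff$f_minus) / 2
}

#' Tabulate the conceptual model
#'
#' Writes (or returns) a table of `F(z0)`, `f0(z0)` and the mean fitnesses
#' of the first (protected) and second generation over grids of `z0` and
#' the asymmetry `a` - the ingredients of the concavity picture.
#'
#' @param params [model_parameters()].
#' @param z0_grid newborn copy numbers (default `0..z_hat - 1`).
#' @param a_grid asymmetries in `[0, 1]`.
#' @param K half-protection copy number.
#' @param path optional TSV output path.
#' @return A data.frame in long format over `(z0, a)`.
#' @export
tabulate_conceptual <- function(params, z0_grid = NULL,
                                a_grid = c(0, 0.25, 0.5, 0.75, 1),
                                K = 5, path = NULL) {
  stopifnot(inherits(params, "plasmid_params"))
  if (is.null(z0_grid)) z0_grid <- seq(0, params$z_hat - 1)
  rows <- expand.grid(z0 = z0_grid, a = a_grid)
  rows$F_z0 <- end_of_cycle_load(rows$z0, params)
  rows$f0 <- fitness_f0(rows$z0, params)
  ff <- daughter_fitnesses(rows$z0, rows$a, params)
  rows$f_plus <- ff$f_plus
  rows$f_minus <- ff$f_minus
  rows$f1_bar_protected <- protected_gen1_fitness(rows$z0, rows$a, K, params)
  rows$f2_bar <- gen2_average_fitness(rows$z0, rows$a, params)
  if (!is.null(path)) {
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rows
}
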