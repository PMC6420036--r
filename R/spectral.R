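#' Spectral bound and dominant eigenvector of the generator
#'
#' The spectral bound `lambda1` (eigenvalue of `A` with largest real part) is
#' the asymptotic exponential growth rate of the plasmid-bearing
#' subpopulation; by Perron-Frobenius theory for the irreducible,
#' essentially non-negative `A` it is real and carries a strictly positive
#' eigenvector `y_hat`, returned normalized to sum 1 (the stationary
#' copy-number composition).
#'
#' @param system a [build_generator()] result.
#' @return An object of class `spectral_result`: `lambda1` (per hour),
#'   `y_hat` (length `z_hat`, sums to 1), and the residual
#'   `max |A y_hat - lambda1 y_hat|`.
#' @export
spectral_bound <- function(system) {
  stopifnot(inherits(system, "generator_system"))
  A <- system$A
  if (nrow(A) == 1L) {
    return(structure(list(lambda1 = A[1L, 1L], y_hat = 1, residual = 0),
                     class = "spectral_result"))
  }
  ev <- eigen(A)
  i <- which.max(Re(ev$values))
  lambda1 <- ev$values[i]
  if (abs(Im(lambda1)) > 1e-8 * (1 + abs(Re(lambda1)))) {
    stop("dominant eigenvalue has a non-negligible imaginary part; ",
         "generator is not of the expected Perron type")
  }
  lambda1 <- Re(lambda1)
  y <- Re(ev$vectors[, i])
  if (sum(y) < 0) y <- -y
  if (any(y < -1e-8 * max(abs(y)))) {
    stop("dominant eigenvector is not sign-definite; A may be reducible")
  }
  y <- pmax(y, 0)
  y <- y / sum(y)
  residual <- max(abs(A %*% y - lambda1 * y))
  structure(list(lambda1 = lambda1, y_hat = as.numeric(y),
                 residual = residual),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("lambda1 = %.8g /h (residual %.2g)\n", x$lambda1, x$residual))
  invisible(x)
}

#' Stationary copy-number distribution of the plasmid-bearing subpopulation
#'
#' Normalized dominant eigenvector of the generator, with the locations of
#' its local maxima (modes). Modes are strict local maxima of the exact
#' distribution, boundary points included: under strongly asymmetric
#' segregation the distribution is typically bimodal, with a large low-copy
#' mode and a smaller one at the carrying capacity.
#'
#' @param params [model_parameters()].
#' @param strategy a [segregation_strategy()].
#' @return A list: `z`, `density` (sums to 1), `modes` (copy numbers of the
#'   local maxima), `lambda1`.
#' @export
stationary_distribution <- function(params, strategy) {
  sys <- build_generator(params, strategy)
  sb <- spectral_bound(sys)
  y <- sb$y_hat
  n <- length(y)
  is_mode <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1L || y[i] > y[i - 1L]
    right_ok <- i == n || y[i] > y[i + 1L]
    left_ok && right_ok
  }, logical(1))
  list(z = seq_len(n), density = y, modes = which(is_mode),
       lambda1 = sb$lambda1)
}

#' Time-averaged growth rate of the plasmid-free subpopulation
#'
#' Over one period of the antibiotic schedule the plasmid-free class grows at
#' `beta(0, alpha(t)) - mu(0, alpha(t))`; the time average is
#' `(1 - phi) beta0 - phi mu0` where `phi` is the antibiotic fraction.
#'
#' @param schedule an [environment_schedule()].
#' @param params [model_parameters()].
#' @return Average growth rate `lambda0_bar`, per hour.
#' @export
plasmid_free_growth <- function(schedule, params) {
  stopifnot(inherits(params, "plasmid_params"))
  phi <- antibiotic_fraction(schedule)
  (1 - phi) * params$beta0 - phi * params$mu0
}

#' Plasmid persistence dichotomy
#'
#' Compares the time-averaged plasmid-free growth rate `lambda0_bar` with the
#' spectral bound `lambda1` of the plasmid-bearing block: the plasmid is lost
#' (its population fraction tends to 0) when `lambda0_bar > lambda1` and a
#' stable plasmid-bearing subpopulation persists when
#' `lambda0_bar < lambda1`; within `tol` the verdict is `"marginal"`.
#'
#' @param schedule an [environment_schedule()].
#' @param params [model_parameters()].
#' @param strategy a [segregation_strategy()].
#' @param tol half-width of the marginal band, per hour.
#' @return An object of class `persistence_verdict`: `lambda0_bar`,
#'   `lambda1`, `verdict` in `c("lost", "persists", "marginal")`.
#' @export
persistence_check <- function(schedule, params, strategy, tol = 1e-6) {
  l0 <- plasmid_free_growth(schedule, params)
  l1 <- spectral_bound(build_generator(params, strategy))$lambda1
  verdict <- if (abs(l0 - l1) < tol) "marginal"
             else if (l0 > l1) "lost" else "persists"
  structure(list(lambda0_bar = l0, lambda1 = l1, verdict = verdict),
            class = "persistence_verdict")
}

#' @export
print.persistence_verdict <- function(x, ...) {
  cat(sprintf("lambda0_bar = %.6g /h, lambda1 = %.6g /h -> plasmid %s\n",
              x$lambda0_bar, x$lambda1, x$verdict))
  invisible(x)
}

#' Integrate the structured population forward in time
#'
#' Solves `x0' = (beta(0, alpha) - mu(0, alpha)) x0 + B'y`, `y' = A y` with a
#' piecewise-constant antibiotic schedule. Within each schedule segment the
#' system is linear time-invariant and is propagated exactly with the matrix
#' exponential of the augmented `(1 + z_hat)`-dimensional system, so the only
#' error is the output-grid discretization of `alpha(t)` switch times (which
#' are hit exactly).
#'
#' @param params [model_parameters()].
#' @param strategy a [segregation_strategy()].
#' @param schedule an [environment_schedule()].
#' @param x0 initial plasmid-free population size (>= 0).
#' @param y0 initial plasmid-bearing state, length `z_hat` (>= 0); a single
#'   number is recycled.
#' @param t_end end time, hours.
#' @param n_out number of output rows (equally spaced in time, plus segment
#'   boundaries).
#' @return A data.frame: `t`, `x0`, `y_total`, `y1..y<z_hat>`.
#' @export
integrate_population <- function(params, strategy, schedule, x0, y0, t_end,
                                 n_out = 201) {
  stopifnot(inherits(params, "plasmid_params"),
            inherits(schedule, "environment_schedule"))
  z_hat <- params$z_hat
  if (length(y0) == 1L) y0 <- rep(y0, z_hat)
  if (length(y0) != z_hat) stop("y0 must have length z_hat")
  if (x0 < 0 || any(y0 < 0)) stop("initial state must be non-negative")
  if (t_end <= 0) stop("t_end must be positive")
  sys <- build_generator(params, strategy)

  aug <- function(alpha) {
    l0 <- division_rate(0L, alpha, params) - death_rate(0L, alpha, params)
    M <- matrix(0, z_hat + 1L, z_hat + 1L)
    M[1L, 1L] <- l0
    M[1L, -1L] <- sys$B
    M[-1L, -1L] <- sys$A
    M
  }

  # output times: uniform grid plus exact segment boundaries
  times <- seq(0, t_end, length.out = max(2L, n_out))
  dur <- schedule$durations
  if (!any(is.infinite(dur))) {
    bounds <- cumsum(rep(dur, length.out = 1000L * length(dur)))
    times <- sort(unique(c(times, bounds[bounds < t_end])))
  }

  state <- c(x0, y0)
  out <- matrix(NA_real_, length(times), z_hat + 1L)
  out[1L, ] <- state
  seg_i <- 1L; seg_left <- dur[1L]
  M <- aug(schedule$alpha[1L]); t_cur <- 0
  for (k in seq_along(times)[-1L]) {
    target <- times[k]
    while (t_cur < target - 1e-12) {
      step <- min(target - t_cur, seg_left)
      state <- as.numeric(Matrix::expm(M * step) %*% state)
      t_cur <- t_cur + step
      seg_left <- seg_left - step
      if (seg_left <= 1e-12) {
        seg_i <- seg_i %% length(dur) + 1L
        seg_left <- dur[seg_i]
        M <- aug(schedule$alpha[seg_i])
      }
    }
    state <- pmax(state, 0)  # clip float dust; exact flow is non-negative
    out[k, ] <- state
  }
  df <- data.frame(t = times, x0 = out[, 1L],
                   y_total = rowSums(out[, -1L, drop = FALSE]))
  ymat <- out[, -1L, drop = FALSE]
  colnames(ymat) <- paste0("y", seq_len(z_hat))
  cbind(df, as.data.frame(ymat))
}

#' Expected plasmid loads of the two daughters
#'
#' For a mother dividing with `z0` plasmids under segregation probability
#' `p = strategy[z0]`, returns the expected copy numbers of the
#' lower-share and higher-share daughter under two conventions:
#' role-based, i.e. the selected daughter's mean `p z0` versus
#' `(1 - p) z0` (with canonical `p <= 0.5` the selected daughter is the lower
#' one), and order-statistic, i.e. exact `E[min(Z, z0 - Z)]` and
#' `E[max(Z, z0 - Z)]` for `Z ~ Binomial(z0, p)`.
#'
#' @param strategy a [segregation_strategy()].
#' @param z0 mother copy number(s), `1..length(strategy)`.
#' @param method `"role"` (default) or `"order"`.
#' @return A data.frame: `z0`, `lower`, `upper`.
#' @export
expected_daughter_loads <- function(strategy, z0,
                                    method = c("role", "order")) {
  method <- match.arg(method)
  stopifnot(inherits(strategy, "segregation_strategy"))
  z0 <- check_z(z0, length(strategy), lower = 1L)
  p <- as.numeric(strategy)[z0]
  if (method == "role") {
    lo <- pmin(p, 1 - p) * z0
    hi <- pmax(p, 1 - p) * z0
  } else {
    lo <- hi <- numeric(length(z0))
    for (i in seq_along(z0)) {
      zd <- 0:z0[i]
      g <- dbinom(zd, z0[i], p[i])
      lo[i] <- sum(pmin(zd, z0[i] - zd) * g)
      hi[i] <- sum(pmax(zd, z0[i] - zd) * g)
    }
  }
  data.frame(z0 = z0, lower = lo, upper = hi)
}
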