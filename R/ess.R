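#' Structurally flat strategy coordinates
#'
#' Coordinates of the segregation strategy on which the growth rate
#' `lambda1` provably does not depend: `z = 1` (the two-daughter kernel of a
#' one-plasmid mother is `p`-independent) and any `z` with zero division rate
#' (that mother never divides, e.g. `z = z_hat` under the full burden).
#' These coordinates are frozen at 0.5 by convention and excluded from
#' convergence norms, agreement checks and strategy feature extraction.
#'
#' @param params [model_parameters()].
#' @return Logical vector over `z = 1..z_hat`; `TRUE` marks flat coordinates.
#' @export
flat_coordinates <- function(params) {
  stopifnot(inherits(params, "plasmid_params"))
  zz <- seq_len(params$z_hat)
  beta <- division_rate(zz, 0L, params)
  zz == 1L | beta == 0
}

lambda1_of <- function(params, p) {
  spectral_bound(build_generator(params, p))$lambda1
}

#' Gradient of the growth rate with respect to the segregation strategy
#'
#' `d lambda1 / d p_z` for every mother copy number `z`. The default
#' `"adjoint"` method uses first-order eigenvalue perturbation,
#' `w' (dA/dp_z) v / (w'v)` with `v`, `w` the right and left dominant
#' eigenvectors; `dA/dp_z` is analytic (column `z` only) from the derivative
#' of the binomial segregation kernel. `"fd"` uses central finite
#' differences with step `h`, clipped at the box boundaries; it serves as an
#' independent cross-check. If the dominant eigenpair is degenerate the
#' adjoint method falls back to `"fd"` with a warning.
#'
#' @param params [model_parameters()].
#' @param strategy a [segregation_strategy()].
#' @param method `"adjoint"` (default) or `"fd"`.
#' @param h finite-difference step.
#' @return Numeric gradient over `z = 1..z_hat`, per hour per unit `p`.
#' @export
lyapunov_gradient <- function(params, strategy,
                              method = c("adjoint", "fd"), h = 1e-5) {
  method <- match.arg(method)
  z_hat <- params$z_hat
  p <- as_strategy(strategy, z_hat)
  if (method == "fd") {
    g <- numeric(z_hat)
    for (i in seq_len(z_hat)) {
      lo <- max(0, p[i] - h); hi <- min(0.5, p[i] + h)
      if (hi <= lo) { g[i] <- 0; next }
      pp <- p; pp[i] <- hi
      pm <- p; pm[i] <- lo
      g[i] <- (lambda1_of(params, pp) - lambda1_of(params, pm)) / (hi - lo)
    }
    return(g)
  }
  sys <- build_generator(params, p)
  A <- sys$A
  er <- eigen(A)
  i <- which.max(Re(er$values))
  gap <- sort(Re(er$values), decreasing = TRUE)
  if (length(gap) > 1L && gap[1L] - gap[2L] < 1e-10) {
    warning("near-degenerate dominant eigenpair; falling back to ",
            "finite differences")
    return(lyapunov_gradient(params, p, method = "fd", h = h))
  }
  v <- Re(er$vectors[, i]); if (sum(v) < 0) v <- -v
  el <- eigen(t(A))
  j <- which.max(Re(el$values))
  w <- Re(el$vectors[, j]); if (sum(w) < 0) w <- -w
  wv <- sum(w * v)
  g <- numeric(z_hat)
  for (z0 in seq_len(z_hat)) {
    if (sys$beta[z0] == 0) next          # flat: mother never divides
    zd <- seq_len(z0)
    dk <- dsegregation_kernel(zd, z0, p[z0])
    g[z0] <- sys$beta[z0] * sum(w[zd] * dk) * v[z0] / wv
  }
  g
}

#' Maximize the growth rate by projected steepest ascent
#'
#' Follows the artificial-time ascent flow `dp/ds = grad lambda1(p)` with a
#' projected-gradient Euler discretization: adaptive step size with
#' backtracking (only `lambda1`-improving steps are accepted), projection
#' onto the box `[0, 0.5]^z_hat`, and termination when the sup-norm of the
#' projected gradient over non-flat coordinates falls below `tol`.
#' Structurally flat coordinates ([flat_coordinates()]) are frozen at 0.5.
#'
#' @param params [model_parameters()].
#' @param init initial strategy (a [segregation_strategy()] or numeric
#'   vector).
#' @param tol convergence tolerance on the projected-gradient sup-norm,
#'   per hour per unit `p`.
#' @param max_iter maximum number of ascent iterations.
#' @param step0 initial step size in artificial time.
#' @return An object of class `ess_result`: `p_star`
#'   ([segregation_strategy()]), `lambda1_star`, `trajectory` (data.frame
#'   `s`, `lambda1` at accepted iterates), `converged`,
#'   `gradient_norm_final`, `flat` (logical mask), `n_iter`.
#' @export
steepest_ascent <- function(params, init, tol = 1e-6, max_iter = 5000,
                            step0 = 0.1) {
  z_hat <- params$z_hat
  p <- as.numeric(as_strategy(init, z_hat))
  flat <- flat_coordinates(params)
  p[flat] <- 0.5
  eta <- step0
  l <- lambda1_of(params, p)
  s_traj <- 0; l_traj <- l; s_cur <- 0
  converged <- FALSE; gnorm <- NA_real_; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- lyapunov_gradient(params, p)
    g[flat] <- 0
    pg <- pmin(pmax(p + g, 0), 0.5) - p   # projected gradient
    gnorm <- max(abs(pg))
    if (gnorm < tol) { converged <- TRUE; break }
    repeat {
      pn <- pmin(pmax(p + eta * g, 0), 0.5)
      pn[flat] <- 0.5
      ln <- lambda1_of(params, pn)
      if (ln >= l || eta < 1e-14) break
      eta <- eta / 2
    }
    if (ln < l) break                     # no improving step found
    p <- pn; l <- ln
    s_cur <- s_cur + eta
    s_traj <- c(s_traj, s_cur); l_traj <- c(l_traj, l)
    eta <- eta * 1.5
  }
  structure(
    list(p_star = segregation_strategy(p), lambda1_star = l,
         trajectory = data.frame(s = s_traj, lambda1 = l_traj),
         converged = converged, gradient_norm_final = gnorm,
         flat = flat, n_iter = it, params = params),
    class = "ess_result"
  )
}

#' @export
print.ess_result <- function(x, ...) {
  cat(sprintf(
    "ESS search: lambda1* = %.8g /h after %d iterations (%s)\n",
    x$lambda1_star, x$n_iter,
    if (x$converged) "converged" else "NOT converged"))
  ident <- !x$flat
  cat(sprintf("  min p* over identifiable z: %.4f; onset (dev > 0.05): %s\n",
              min(x$p_star[ident]),
              format(onset_threshold(x))))
  if (!is.null(x$n_starts_agreeing)) {
    cat(sprintf("  starts agreeing with the best run: %d\n",
                x$n_starts_agreeing))
  }
  invisible(x)
}

#' Multi-start search for the evolutionarily stable segregation strategy
#'
#' Runs [steepest_ascent()] from a set of initial strategies - uniform 0.45
#' (near-equal; exactly 0.5 is a stationary point of the ascent flow by the
#' `p -> 1-p` symmetry and would never move), uniform 0.25, and seeded
#' uniform-random vectors - and returns the best run, annotated with how
#' many runs agree with it (sup-norm over non-flat coordinates < 0.02).
#'
#' @param params [model_parameters()].
#' @param n_starts number of starts (>= 1).
#' @param seed integer seed for the random starts (optional).
#' @param ... passed to [steepest_ascent()].
#' @return An `ess_result` with an extra field `n_starts_agreeing`.
#' @export
multi_start_ess <- function(params, n_starts = 3, seed = NULL, ...) {
  stopifnot(n_starts >= 1)
  z_hat <- params$z_hat
  if (!is.null(seed)) set.seed(seed)
  inits <- list(rep(0.45, z_hat), rep(0.25, z_hat))
  while (length(inits) < n_starts) {
    inits <- c(inits, list(runif(z_hat, 0, 0.5)))
  }
  inits <- inits[seq_len(n_starts)]
  runs <- lapply(inits, function(p0) steepest_ascent(params, p0, ...))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "lambda1_star"))]]
  ident <- !best$flat
  agree <- vapply(runs, function(r) {
    max(abs(as.numeric(r$p_star)[ident] -
            as.numeric(best$p_star)[ident])) < 0.02
  }, logical(1))
  best$n_starts_agreeing <- sum(agree)
  best$n_starts <- n_starts
  best
}

#' Verify that a strategy is a local maximum of the growth rate
#'
#' Varies the strategy locally around `p_star` and checks that no probe
#' improves `lambda1` by more than `tol`: first each coordinate alone by
#' `+/- delta` (these detect saddle points such as uniform equal
#' segregation, where random full-vector probes average away the
#' second-order gain), then `n_probes` random in-box perturbations of
#' magnitude `delta`.
#'
#' @param params [model_parameters()].
#' @param p_star candidate strategy.
#' @param delta perturbation magnitude per coordinate.
#' @param n_probes number of additional random probes.
#' @param seed optional integer seed.
#' @param tol improvement tolerance, per hour; the default allows the
#'   first-order slack `delta * tol_ascent` left by a converged ascent run.
#' @return `TRUE` if no probe improves `lambda1(p_star)` beyond `tol`.
#' @export
verify_local_max <- function(params, p_star, delta = 0.02, n_probes = 100,
                             seed = NULL, tol = 1e-7) {
  p <- as.numeric(as_strategy(p_star, params$z_hat))
  if (delta == 0) return(TRUE)
  if (!is.null(seed)) set.seed(seed)
  l0 <- lambda1_of(params, p)
  for (i in seq_along(p)) {
    for (sgn in c(-1, 1)) {
      probe <- p
      probe[i] <- min(max(p[i] + sgn * delta, 0), 0.5)
      if (lambda1_of(params, probe) > l0 + tol) return(FALSE)
    }
  }
  for (i in seq_len(n_probes)) {
    probe <- pmin(pmax(p + runif(length(p), -delta, delta), 0), 0.5)
    if (lambda1_of(params, probe) > l0 + tol) return(FALSE)
  }
  TRUE
}

#' Onset copy number of unequal segregation
#'
#' The smallest mother copy number `z` (`1 <= z < z_hat`, flat coordinates
#' excluded) at which the strategy deviates from equal segregation by more
#' than `deviation_tol`; `NA` if the strategy is equal everywhere.
#'
#' @param strategy a [segregation_strategy()] or an `ess_result`.
#' @param deviation_tol deviation from 0.5 that counts as unequal.
#' @param params optional [model_parameters()] to determine flat
#'   coordinates; taken from the `ess_result` when available.
#' @return Integer copy number, or `NA_integer_`.
#' @export
onset_threshold <- function(strategy, deviation_tol = 0.05, params = NULL) {
  if (inherits(strategy, "ess_result")) {
    params <- strategy$params
    strategy <- strategy$p_star
  }
  p <- as.numeric(strategy)
  z_hat <- length(p)
  excl <- rep(FALSE, z_hat)
  if (!is.null(params)) excl <- flat_coordinates(params)
  excl[z_hat] <- TRUE                     # onset is sought on 1 <= z < z_hat
  dev <- abs(p - 0.5) > deviation_tol & !excl
  if (!any(dev)) return(NA_integer_)
  which(dev)[1L]
}

#' Sensitivity sweep of the ESS over model parameters
#'
#' Re-optimizes the segregation strategy over a grid of `(b, z_hat,
#' burden_scale)` values and summarizes each optimum: maximal growth rate,
#' minimum segregation probability over identifiable copy numbers, onset of
#' unequal segregation, and whether the optimum is equal segregation
#' everywhere (max deviation from 0.5 over non-flat z below 0.05).
#'
#' @param grid data.frame with columns among `b`, `z_hat`, `burden_scale`
#'   (missing columns fall back to `base` values).
#' @param base [model_parameters()] supplying the non-swept values.
#' @param ... passed to [multi_start_ess()].
#' @return A data.frame with one row per grid point; failed points carry
#'   `NA` results and the error message in `note`.
#' @export
sensitivity_sweep <- function(grid, base = model_parameters(), ...) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, , drop = FALSE]
    pt <- list(
      z_hat = if ("z_hat" %in% names(g)) g$z_hat else base$z_hat,
      b = if ("b" %in% names(g)) g$b else base$b,
      burden_scale = if ("burden_scale" %in% names(g)) g$burden_scale
                     else base$burden_scale
    )
    row <- data.frame(b = pt$b, z_hat = pt$z_hat,
                      burden_scale = pt$burden_scale,
                      lambda1_star = NA_real_, min_p = NA_real_,
                      onset_z = NA_integer_, equal_everywhere = NA,
                      converged = NA, note = "")
    out <- tryCatch({
      pars <- model_parameters(z_hat = pt$z_hat, b = pt$b,
                               beta0 = base$beta0, mu0 = base$mu0,
                               burden_scale = pt$burden_scale)
      ess <- multi_start_ess(pars, ...)
      ident <- !ess$flat
      row$lambda1_star <- ess$lambda1_star
      row$min_p <- min(as.numeric(ess$p_star)[ident])
      row$onset_z <- onset_threshold(ess)
      row$equal_everywhere <-
        max(abs(as.numeric(ess$p_star)[ident] - 0.5)) < 0.05
      row$converged <- ess$converged
      row
    }, error = function(e) { row$note <- conditionMessage(e); row })
    res[[i]] <- out
  }
  do.call(rbind, res)
}

#' Export an ESS result as TSV plus JSON metadata
#'
#' @param ess an `ess_result`.
#' @param path base path; writes `<path>.tsv` (columns `z`, `p_star_z`) and
#'   `<path>.json` (growth rate, convergence diagnostics).
#' @return The two paths, invisibly.
#' @export
write_ess_tsv <- function(ess, path) {
  stopifnot(inherits(ess, "ess_result"))
  tsv <- paste0(path, ".tsv")
  js <- paste0(path, ".json")
  write.table(
    data.frame(z = seq_along(ess$p_star), p_star_z = as.numeric(ess$p_star)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(lambda1_star = ess$lambda1_star, converged = ess$converged,
               n_iter = ess$n_iter,
               gradient_norm_final = ess$gradient_norm_final,
               flat_z = which(ess$flat))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
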