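#' Model parameters for the plasmid-structured population
#'
#' Bundles the rates and the copy-number cap that define the structured model:
#' a cell with `z` plasmids replicates plasmids logistically at rate
#' `b*z*(1 - z/z_hat)` and divides at rate `beta0*(1 - burden_scale*z/z_hat)+`
#' (the positive part), except that plasmid-free cells divide at `beta0`
#' without antibiotics and not at all with antibiotics, and die at `mu0` only
#' with antibiotics. `burden_scale` scales the metabolic burden on division
#' only; `burden_scale = 1` reproduces the default linear burden under which
#' cells at the cap no longer divide.
#'
#' @param z_hat maximal plasmid copy number per cell (integer >= 2), plasmids.
#' @param b logistic plasmid replication parameter, per hour.
#' @param beta0 maximal bacterial division rate, per hour.
#' @param mu0 death rate of plasmid-free cells under antibiotics, per hour.
#' @param burden_scale dimensionless factor in `[0, 1]` scaling the metabolic
#'   burden of the plasmid load on the division rate.
#' @return An object of class `plasmid_params`.
#' @examples
#' model_parameters()                 # defaults: z_hat 50, b 1.2, beta0 1, mu0 5
#' model_parameters(z_hat = 100, b = 0.5)
#' @export
model_parameters <- function(z_hat = 50, b = 1.2, beta0 = 1, mu0 = 5,
                             burden_scale = 1) {
  if (length(z_hat) != 1L || !is.finite(z_hat) || z_hat < 2 ||
      z_hat != as.integer(z_hat)) {
    stop("z_hat must be a single integer >= 2")
  }
  for (nm in c("b", "beta0", "mu0")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0) {
      stop(nm, " must be a single non-negative rate (per hour)")
    }
  }
  if (length(burden_scale) != 1L || !is.finite(burden_scale) ||
      burden_scale < 0 || burden_scale > 1) {
    stop("burden_scale must be in [0, 1]")
  }
  structure(
    list(z_hat = as.integer(z_hat), b = b, beta0 = beta0, mu0 = mu0,
         burden_scale = burden_scale),
    class = "plasmid_params"
  )
}

#' @export
print.plasmid_params <- function(x, ...) {
  cat("Plasmid-structured model parameters\n")
  cat(sprintf("  z_hat (max copy number): %d plasmids\n", x$z_hat))
  cat(sprintf("  b  (plasmid replication): %g /h\n", x$b))
  cat(sprintf("  beta0 (max division rate): %g /h\n", x$beta0))
  cat(sprintf("  mu0 (plasmid-free death rate, antibiotics): %g /h\n", x$mu0))
  cat(sprintf("  burden_scale: %g\n", x$burden_scale))
  invisible(x)
}

#' Segregation strategy
#'
#' The evolving trait: for a mother dividing with `z` plasmids, each plasmid
#' independently moves into a randomly selected daughter with probability
#' `p[z]`. Because the two-daughter segregation kernel is invariant under
#' `p -> 1 - p`, strategies are canonicalized to `[0, 0.5]`: entries above
#' 0.5 are reflected (with a warning).
#'
#' @param p numeric vector of segregation probabilities, indexed by mother
#'   copy number `z = 1..z_hat`; entries in `[0, 1]`, canonicalized to
#'   `[0, 0.5]`.
#' @return An object of class `segregation_strategy` (a numeric vector with
#'   attributes).
#' @seealso [uniform_strategy()], [segregation_kernel()]
#' @export
segregation_strategy <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 1L || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p must be probabilities in [0, 1], one per mother copy number")
  }
  if (any(p > 0.5)) {
    warning("entries above 0.5 reflected to the canonical range [0, 0.5]")
    p <- pmin(p, 1 - p)
  }
  structure(p, class = "segregation_strategy")
}

#' Uniform segregation strategy
#'
#' @param value common segregation probability (0.5 = equal segregation).
#' @param z_hat maximal copy number (length of the strategy vector).
#' @return A [segregation_strategy()].
#' @export
uniform_strategy <- function(value = 0.5, z_hat = 50) {
  segregation_strategy(rep(value, z_hat))
}

#' @export
print.segregation_strategy <- function(x, ...) {
  cat(sprintf("Segregation strategy over z = 1..%d\n", length(x)))
  print(unclass(x), ...)
  invisible(x)
}

as_strategy <- function(p, z_hat) {
  if (!inherits(p, "segregation_strategy")) p <- segregation_strategy(p)
  if (length(p) != z_hat) {
    stop("strategy length (", length(p), ") must equal z_hat (", z_hat, ")")
  }
  p
}

#' Antibiotic environment schedule
#'
#' A periodic schedule of antibiotic presence: an ordered set of segments
#' `(duration, alpha)` with `alpha = 1` during antibiotic episodes and
#' `alpha = 0` otherwise, repeated forever. A single segment encodes a
#' constant environment.
#'
#' @param durations segment durations in hours (all > 0).
#' @param alpha binary vector (0/1) of the same length.
#' @return An object of class `environment_schedule`.
#' @seealso [constant_environment()], [antibiotic_fraction()]
#' @export
environment_schedule <- function(durations, alpha) {
  durations <- as.numeric(durations)
  alpha <- as.integer(alpha)
  if (length(durations) == 0L) stop("schedule must have at least one segment")
  if (length(durations) != length(alpha)) {
    stop("durations and alpha must have equal length")
  }
  if (any(!is.finite(durations) & !is.infinite(durations)) ||
      any(durations <= 0)) {
    stop("segment durations must be positive")
  }
  if (!all(alpha %in% c(0L, 1L))) stop("alpha must be binary (0/1)")
  structure(list(durations = durations, alpha = alpha),
            class = "environment_schedule")
}

#' Constant environment
#'
#' @param alpha 0 (no antibiotics) or 1 (antibiotics always present).
#' @return An [environment_schedule()] with a single infinite segment.
#' @export
constant_environment <- function(alpha = 0) {
  environment_schedule(Inf, alpha)
}

#' Fraction of time with antibiotics
#'
#' The fraction `phi` of one schedule period during which antibiotics are
#' present; for a constant environment it is simply `alpha`.
#'
#' @param schedule an [environment_schedule()].
#' @return A number in `[0, 1]`.
#' @export
antibiotic_fraction <- function(schedule) {
  stopifnot(inherits(schedule, "environment_schedule"))
  d <- schedule$durations
  if (any(is.infinite(d))) {
    # constant after the first infinite segment; earlier finite ones vanish
    return(as.numeric(schedule$alpha[which(is.infinite(d))[1L]]))
  }
  sum(d[schedule$alpha == 1L]) / sum(d)
}

#' @export
print.environment_schedule <- function(x, ...) {
  if (any(is.infinite(x$durations))) {
    cat(sprintf("Constant environment: alpha = %d\n",
                x$alpha[which(is.infinite(x$durations))[1L]]))
  } else {
    cat(sprintf("Periodic environment, period %g h, antibiotic fraction %g\n",
                sum(x$durations), antibiotic_fraction(x)))
    for (i in seq_along(x$durations)) {
      cat(sprintf("  %g h at alpha = %d\n", x$durations[i], x$alpha[i]))
    }
  }
  invisible(x)
}

#' Write or read a segregation strategy as TSV
#'
#' Two columns: `z` (mother copy number) and `p_z`.
#'
#' @param strategy a [segregation_strategy()].
#' @param path file path.
#' @return `write_strategy_tsv` returns `path` invisibly;
#'   `read_strategy_tsv` returns a [segregation_strategy()].
#' @export
write_strategy_tsv <- function(strategy, path) {
  stopifnot(inherits(strategy, "segregation_strategy"))
  df <- data.frame(z = seq_along(strategy), p_z = as.numeric(strategy))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_strategy_tsv
#' @export
read_strategy_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("z", "p_z") %in% names(df))) {
    stop("strategy TSV needs columns 'z' and 'p_z'")
  }
  df <- df[order(df$z), ]
  if (!identical(as.integer(df$z), seq_len(nrow(df)))) {
    stop("column 'z' must enumerate 1..z_hat")
  }
  segregation_strategy(df$p_z)
}
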