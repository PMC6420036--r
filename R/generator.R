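#' Assemble the master-equation generator of the plasmid-bearing block
#'
#' Builds the linear system governing the plasmid-bearing subpopulation
#' `y_z(t)`, `z = 1..z_hat`, and the flux into the plasmid-free class:
#' `y' = A y`, `x0' = lambda0(alpha) x0 + B'y`. Column `z0` of `A` combines
#' the logistic plasmid-replication shift (loss `-b z0 (1 - z0/z_hat)` on the
#' diagonal, gain on the subdiagonal), the division loss `-beta(z0)`, and the
#' division inflow `k(z; z0) beta(z0)` for daughters with `z >= 1` plasmids;
#' `B[z0] = k(0; z0) beta(z0)` collects daughters born plasmid-free. Neither
#' `A` nor `B` depends on the environment: plasmid-bearing cells divide at
#' the same burden-limited rate with and without antibiotics.
#'
#' Mass balance holds column-wise: `colSums(A) + B = beta(z)` (each division
#' removes one cell and adds two daughters).
#'
#' @param params [model_parameters()].
#' @param strategy a [segregation_strategy()] of length `z_hat`.
#' @return An object of class `generator_system`: list with the dense matrix
#'   `A` (`z_hat x z_hat`, per hour), vector `B` (per hour), `beta` (division
#'   rates over `z = 1..z_hat`), and the inputs used.
#' @examples
#' sys <- build_generator(model_parameters(), uniform_strategy(0.5, 50))
#' range(colSums(sys$A) + sys$B - sys$beta)   # ~ 0: mass balance
#' @export
build_generator <- function(params, strategy) {
  stopifnot(inherits(params, "plasmid_params"))
  z_hat <- params$z_hat
  p <- as_strategy(strategy, z_hat)
  zz <- seq_len(z_hat)
  beta <- division_rate(zz, 0L, params)   # alpha-independent for z >= 1
  repl <- plasmid_birth_rate(zz, params)

  A <- matrix(0, z_hat, z_hat)
  # logistic plasmid replication: z -> z + 1
  diag(A) <- -repl - beta
  if (z_hat >= 2L) {
    A[cbind(zz[-1L], zz[-z_hat])] <- A[cbind(zz[-1L], zz[-z_hat])] +
      repl[-z_hat]
  }
  # division inflow: mother z0 -> daughters z = 1..z0 (z = 0 goes to B)
  B <- numeric(z_hat)
  for (z0 in zz) {
    if (beta[z0] == 0) next
    zd <- seq_len(z0)
    A[zd, z0] <- A[zd, z0] + segregation_kernel(zd, z0, p[z0]) * beta[z0]
    B[z0] <- segregation_kernel(0L, z0, p[z0]) * beta[z0]
  }
  structure(
    list(A = A, B = B, beta = beta, params = params, strategy = p),
    class = "generator_system"
  )
}

#' @export
print.generator_system <- function(x, ...) {
  cat(sprintf("Generator system over z = 1..%d\n", x$params$z_hat))
  cat(sprintf("  max |colSums(A) + B - beta|: %.3g\n",
              max(abs(colSums(x$A) + x$B - x$beta))))
  invisible(x)
}

#' Export a generator system as TSV
#'
#' Writes the dense matrix `A` (rows/columns labelled by copy number) and a
#' second file with the flux vector `B` and division rates.
#'
#' @param system a [build_generator()] result.
#' @param path base path; writes `<path>_A.tsv` and `<path>_B.tsv`.
#' @return The two paths, invisibly.
#' @export
write_generator_tsv <- function(system, path) {
  stopifnot(inherits(system, "generator_system"))
  z <- seq_len(nrow(system$A))
  a_path <- paste0(path, "_A.tsv")
  b_path <- paste0(path, "_B.tsv")
  A <- as.data.frame(system$A)
  names(A) <- paste0("z", z)
  write.table(cbind(z = z, A), a_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(z = z, B = system$B, beta = system$beta), b_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(a_path, b_path))
}
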