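#' Simulate single-cell lineages of the plasmid process
#'
#' Event-driven exact stochastic simulation of the single-cell dynamics:
#' each cell carries competing exponential clocks for plasmid replication
#' (rate `b z (1 - z/z_hat)`, one copy at a time), division (rate
#' `beta(z, alpha)`) and death (rate `mu(z, alpha)`). At division the
#' selected daughter receives `Binomial(z0, p[z0])` plasmids and her sister
#' the rest; every division of a plasmid-bearing mother is recorded. When
#' the census exceeds `max_cells`, uniformly random cells are removed down
#' to the cap; the cumulative log correction is tracked so per-capita growth
#' estimates refer to pre-subsampling counts (see [lineage_growth_rate()]).
#'
#' @param params [model_parameters()].
#' @param strategy a [segregation_strategy()].
#' @param schedule an [environment_schedule()]; default no antibiotics.
#' @param t_max simulated time, hours.
#' @param init_z integer vector of initial copy numbers (one cell each);
#'   lineage ids are assigned `1..length(init_z)` and inherited.
#' @param max_cells population cap for the subsampling control.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param drop_plasmid_free if `TRUE`, daughters born without plasmids are
#'   discarded (their number is counted): the census then follows the
#'   plasmid-bearing block `y' = Ay` alone, which is the relevant process
#'   for stationary-composition and growth-rate comparisons, since under
#'   `alpha = 0` plasmid-free cells would otherwise take over a capped
#'   census.
#' @param ts_dt sampling interval of the population time series, hours.
#' @param max_records cap on stored division records.
#' @return An object of class `lineage_sim`: `records` (data.frame with
#'   `lineage`, `time`, `mother_z`, `daughter1_z` (the selected daughter),
#'   `daughter2_z`), `census` (data.frame `z`, `lineage` of the final
#'   population), `ts` (data.frame `t`, `n`, `log_corr`), and `meta`
#'   (event counters, inputs).
#' @export
simulate_lineages <- function(params, strategy,
                              schedule = constant_environment(0),
                              t_max, init_z, max_cells = 10000,
                              seed = NULL, drop_plasmid_free = FALSE,
                              ts_dt = 0.25, max_records = 2e6) {
  stopifnot(inherits(params, "plasmid_params"),
            inherits(schedule, "environment_schedule"))
  p <- as_strategy(strategy, params$z_hat)
  if (!is.null(seed)) set.seed(seed)
  dur <- schedule$durations
  dur[is.infinite(dur)] <- t_max + 1  # constant segment never ends in-run
  raw <- sim_lineages_cpp(
    params$z_hat, params$b, params$beta0, params$mu0, params$burden_scale,
    as.numeric(p), dur, schedule$alpha, t_max, as.integer(max_cells),
    as.integer(init_z), drop_plasmid_free, ts_dt, as.integer(max_records))
  records <- data.frame(
    lineage = raw$rec_lineage, time = raw$rec_time,
    mother_z = raw$rec_mother_z, daughter1_z = raw$rec_d1,
    daughter2_z = raw$rec_d2)
  structure(
    list(records = records,
         census = data.frame(z = raw$census_z, lineage = raw$census_lineage),
         ts = data.frame(t = raw$ts_t, n = raw$ts_n,
                         log_corr = raw$ts_log_corr),
         meta = list(t_end = raw$t_end, log_corr = raw$log_corr,
                     n_replications = raw$n_replications,
                     n_divisions = raw$n_divisions,
                     n_deaths = raw$n_deaths,
                     n_subsampled = raw$n_subsampled,
                     n_dropped_plasmid_free = raw$n_dropped_plasmid_free,
                     records_skipped = raw$records_skipped,
                     max_cells = max_cells,
                     drop_plasmid_free = drop_plasmid_free,
                     params = params, strategy = p, seed = seed)),
    class = "lineage_sim")
}

#' @export
print.lineage_sim <- function(x, ...) {
  cat(sprintf(
    "Lineage simulation: %.4g divisions recorded, final census %d cells (t = %.3g h)\n",
    nrow(x$records), nrow(x$census), x$meta$t_end))
  invisible(x)
}

#' Per-capita growth rate from a lineage simulation
#'
#' Least-squares slope of `log(N(t)) + log_corr(t)` over `t >= t_min`,
#' where `log_corr` undoes the subsampling of the population cap; for a
#' plasmid-bearing-only simulation in a constant environment this estimates
#' the spectral bound `lambda1`.
#'
#' @param sim a [simulate_lineages()] result.
#' @param t_min burn-in time to discard, hours.
#' @return Estimated growth rate, per hour.
#' @export
lineage_growth_rate <- function(sim, t_min = 0) {
  stopifnot(inherits(sim, "lineage_sim"))
  ts <- sim$ts[sim$ts$t >= t_min & sim$ts$n > 0, ]
  if (nrow(ts) < 2L) stop("not enough time-series points after t_min")
  unname(coef(lm(I(log(ts$n) + ts$log_corr) ~ ts$t))[2L])
}

#' Attach a fluorescence proxy to division records
#'
#' Emulates a GFP readout in which fluorescence correlates with copy
#' number: `f = gain * z + N(0, noise_sd)`, truncated at 0, applied to the
#' mother and both daughters of every record.
#'
#' @param records a data.frame of division records (from
#'   [simulate_lineages()]`$records`) or a `lineage_sim`.
#' @param gain fluorescence units per plasmid (> 0).
#' @param noise_sd additive Gaussian noise, fluorescence units (>= 0).
#' @param seed optional integer seed.
#' @return The records with added columns `mother_f`, `f1`, `f2`.
#' @export
fluorescence_proxy <- function(records, gain = 10, noise_sd = 0,
                               seed = NULL) {
  if (inherits(records, "lineage_sim")) records <- records$records
  stopifnot(is.data.frame(records), gain > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  noise <- function() if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  records$mother_f <- pmax(0, gain * records$mother_z + noise())
  records$f1 <- pmax(0, gain * records$daughter1_z + noise())
  records$f2 <- pmax(0, gain * records$daughter2_z + noise())
  records
}

#' Per-stratum histograms of the daughters' fluorescence shares
#'
#' Mothers are stratified by their fluorescence - by default into
#' `n_strata` equal bins of `mother_f / max(mother_f)` (`"max-relative"`),
#' alternatively into empirical quantile strata (`"quantile"`). Within each
#' stratum the shares `f1/(f1+f2)` and `f2/(f1+f2)` of both daughters are
#' histogrammed over `[0, 1]`. Each division contributes the symmetric pair
#' `(s, 1-s)`, and bins are filled via the lower share and its mirror, so
#' every histogram is exactly symmetric about 0.5 by construction (a share
#' of exactly 0.5 is split over the two central bins).
#'
#' @param fluor records with fluorescence columns ([fluorescence_proxy()]).
#' @param n_strata number of mother strata.
#' @param n_bins number of share bins over `[0, 1]` (even).
#' @param strata_mode `"max-relative"` (default) or `"quantile"`.
#' @return A data.frame: `stratum`, `bin_lo`, `bin_hi`, `count`; attribute
#'   `"dropped"` counts divisions with `f1 + f2 = 0`.
#' @export
share_histograms <- function(fluor, n_strata = 10, n_bins = 20,
                             strata_mode = c("max-relative", "quantile")) {
  strata_mode <- match.arg(strata_mode)
  stopifnot(is.data.frame(fluor), nrow(fluor) > 0,
            all(c("mother_f", "f1", "f2") %in% names(fluor)))
  if (n_bins %% 2 != 0) stop("n_bins must be even (symmetric about 0.5)")
  tot <- fluor$f1 + fluor$f2
  dropped <- sum(tot == 0)
  fluor <- fluor[tot > 0, ]
  tot <- tot[tot > 0]
  if (nrow(fluor) == 0) stop("no divisions with positive total fluorescence")

  if (strata_mode == "max-relative") {
    rel <- fluor$mother_f / max(fluor$mother_f)
    stratum <- pmin(n_strata, pmax(1L, ceiling(rel * n_strata)))
    stratum[rel == 0] <- 1L
  } else {
    qs <- stats::quantile(fluor$mother_f,
                          probs = seq(0, 1, length.out = n_strata + 1L))
    stratum <- findInterval(fluor$mother_f, qs, rightmost.closed = TRUE,
                            all.inside = TRUE)
  }

  s_low <- pmin(fluor$f1, fluor$f2) / tot      # in [0, 0.5]
  half <- n_bins / 2
  edges <- seq(0, 1, length.out = n_bins + 1L)
  out <- vector("list", n_strata)
  for (st in seq_len(n_strata)) {
    sl <- s_low[stratum == st]
    counts <- numeric(n_bins)
    if (length(sl)) {
      at_half <- sl >= 0.5                     # exact halves: split centre
      lo <- sl[!at_half]
      idx <- pmin(half, findInterval(lo, edges, left.open = FALSE))
      tab <- tabulate(idx, nbins = half)
      counts[seq_len(half)] <- tab
      counts[n_bins + 1 - seq_len(half)] <- tab  # mirror of the upper share
      counts[half] <- counts[half] + sum(at_half)
      counts[half + 1] <- counts[half + 1] + sum(at_half)
    }
    out[[st]] <- data.frame(stratum = st, bin_lo = edges[-length(edges)],
                            bin_hi = edges[-1L], count = counts)
  }
  res <- do.call(rbind, out)
  attr(res, "dropped") <- dropped
  res
}

#' Rank plot of daughter fluorescence by mother rank
#'
#' Orders mothers by increasing fluorescence (ties kept in record order;
#' the rank substitutes for the mother's copy number) and reports the two
#' daughters' fluorescences as ordered (lower, higher) pairs - the
#' label-blind analogue of the expected-daughter-load curves: a single
#' fused branch at low ranks that bifurcates where segregation becomes
#' unequal.
#'
#' @param fluor records with fluorescence columns ([fluorescence_proxy()]).
#' @return A data.frame: `rank`, `mother_f`, `daughter_low_f`,
#'   `daughter_high_f`.
#' @export
rank_plot_table <- function(fluor) {
  stopifnot(is.data.frame(fluor), nrow(fluor) > 0,
            all(c("mother_f", "f1", "f2") %in% names(fluor)))
  ord <- order(fluor$mother_f)               # stable sort: ties by record
  data.frame(rank = seq_len(nrow(fluor)),
             mother_f = fluor$mother_f[ord],
             daughter_low_f = pmin(fluor$f1, fluor$f2)[ord],
             daughter_high_f = pmax(fluor$f1, fluor$f2)[ord])
}

#' Re-estimate the segregation strategy from division records
#'
#' For each observed mother copy number `z`, estimates `p_z` from the
#' selected daughter's share of plasmids (`daughter1_z / mother_z`; the
#' records identify the selected daughter, so the estimator is the binomial
#' MLE pooled over divisions) and canonicalizes to `[0, 0.5]`. Clopper-
#' Pearson confidence intervals come from the pooled binomial counts. When
#' the selected daughter is not identified in the records the lower share
#' `min(d1, d2)/z` is used instead (biased towards 0; flagged in the
#' output). Copy numbers never observed as dividing mothers are reported
#' with `n = 0` and `NA` estimates.
#'
#' @param records division records (or a `lineage_sim`).
#' @param z_hat maximal copy number (rows to report); defaults to the
#'   largest observed mother.
#' @param conf confidence level of the intervals.
#' @return A data.frame: `z`, `n` (divisions), `p_hat`, `lower`, `upper`,
#'   `estimator`.
#' @export
estimate_strategy <- function(records, z_hat = NULL, conf = 0.95) {
  if (inherits(records, "lineage_sim")) records <- records$records
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (is.null(z_hat)) z_hat <- max(records$mother_z)
  selected <- "daughter1_z" %in% names(records)
  out <- data.frame(z = seq_len(z_hat), n = 0L, p_hat = NA_real_,
                    lower = NA_real_, upper = NA_real_,
                    estimator = if (selected) "selected-daughter"
                                else "lower-share")
  for (z in seq_len(z_hat)) {
    rec <- records[records$mother_z == z, ]
    out$n[z] <- nrow(rec)
    if (nrow(rec) == 0L) next
    if (selected) {
      succ <- sum(rec$daughter1_z)
      trials <- nrow(rec) * z
    } else {
      succ <- sum(pmin(rec$daughter1_z, rec$daughter2_z))
      trials <- nrow(rec) * z
    }
    bt <- binom.test(succ, trials, conf.level = conf)
    est <- succ / trials
    ci <- as.numeric(bt$conf.int)
    if (est > 0.5) {                       # canonical form: reflect
      est <- 1 - est
      ci <- rev(1 - ci)
    }
    out$p_hat[z] <- est
    out$lower[z] <- min(ci)
    out$upper[z] <- pmin(ci[2L], 1)        # interval may straddle 0.5
  }
  out
}

#' Write or read division records as TSV with a JSON sidecar
#'
#' The TSV holds the records; `<path>.json` stores the generating
#' parameters, strategy, seed and a schema version.
#'
#' @param sim a [simulate_lineages()] result.
#' @param path TSV path.
#' @return `write_division_records` returns the paths invisibly;
#'   `read_division_records` returns a list `records`, `meta`.
#' @export
write_division_records <- function(sim, path) {
  stopifnot(inherits(sim, "lineage_sim"))
  write.table(sim$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- sim$meta
  side <- list(schema = "plasmidseg-division-records/1",
               params = unclass(meta$params),
               strategy = as.numeric(meta$strategy),
               seed = meta$seed, t_end = meta$t_end,
               max_cells = meta$max_cells,
               drop_plasmid_free = meta$drop_plasmid_free,
               n_divisions = meta$n_divisions,
               n_subsampled = meta$n_subsampled)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(path, paste0(path, ".json")))
}

#' @rdname write_division_records
#' @export
read_division_records <- function(path) {
  records <- read.table(path, header = TRUE, sep = "\t")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else NULL
  list(records = records, meta = meta)
}
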