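#' Per-clone acinar fractions at the end of the window
#'
#' For every clone passing the inclusion filters (at least one progenitor
#' alive at `t`, and at least one acinar cell alive at `t`, both applied by
#' default and individually toggleable), returns the acinar fraction of
#' living cells. This is the simulated analogue of the acinar fractions read
#' off the observed clone-composition histograms, where the same filters
#' apply to the experimental clones.
#'
#' @param ensemble A `clone_ensemble`.
#' @param t Hours since window start (default: the window end).
#' @param require_progenitor,require_acinar Inclusion filters.
#' @return Numeric vector of acinar fractions in `[0, 1]`; may be empty if
#'   no clone passes the filters (callers decide how to handle that).
#' @export
clonal_acinar_fractions <- function(ensemble, t = window_hours(ensemble$params),
                                    require_progenitor = TRUE,
                                    require_acinar = TRUE) {
  comp <- composition_at(ensemble, t)
  keep <- rep.int(TRUE, nrow(comp))
  if (require_progenitor) keep <- keep & comp[, "progenitor"] >= 1L
  if (require_acinar) keep <- keep & comp[, "acinar"] >= 1L
  comp <- comp[keep, , drop = FALSE]
  if (nrow(comp) == 0L) return(numeric(0))
  unname(comp[, "acinar"] / rowSums(comp))
}

#' Pooled population fractions from groups of clones
#'
#' Emulates whole-pancreas stainings: consecutive, disjoint groups of
#' `group_size` clones are pooled cell-wise and the acinar and endocrine
#' fractions of the pooled population are reported per group and per
#' timepoint, on the percent scale. Clones left over after the last complete
#' group are dropped.
#'
#' @param ensemble A `clone_ensemble`.
#' @param group_size Clones per pooled group (reference protocol: 100, the
#'   approximate founder population sampled by one stained pancreas).
#' @param timepoints Embryonic days at which to evaluate; must lie inside
#'   the simulation window.
#' @return A data frame with columns `group`, `timepoint`, `lineage`
#'   (`"acinar"` or `"endocrine"`) and `frac_percent`.
#' @export
grouped_population_fractions <- function(ensemble, group_size = 100,
                                         timepoints = c(10.5, 11.5, 12.5, 14.5)) {
  stopifnot(inherits(ensemble, "clone_ensemble"),
            group_size >= 1, length(timepoints) >= 1)
  p <- ensemble$params
  if (ensemble$n_clones < group_size)
    stop("fewer clones than `group_size`", call. = FALSE)
  n_groups <- ensemble$n_clones %/% group_size
  grp <- (seq_len(ensemble$n_clones) - 1L) %/% group_size + 1L
  grp[grp > n_groups] <- NA_integer_
  out <- list()
  for (e_day in timepoints) {
    t <- (e_day - p$window_start) * 24
    comp <- composition_at(ensemble, t)
    keep <- !is.na(grp)
    pooled <- rowsum(comp[keep, , drop = FALSE], grp[keep])
    tot <- rowSums(pooled)
    out[[length(out) + 1L]] <- data.frame(
      group = rep(as.integer(rownames(pooled)), 2L),
      timepoint = e_day,
      lineage = rep(c("acinar", "endocrine"), each = nrow(pooled)),
      frac_percent = 100 * c(pooled[, "acinar"] / tot,
                             pooled[, "endocrine"] / tot)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gaussian kernel density estimate
#'
#' The likelihood primitive of the model comparison: a density built by
#' centring one gaussian kernel of standard deviation `bandwidth` on each
#' sample and averaging. Evaluation at a point is the mean of the kernel
#' densities there, so the density integrates to 1 exactly.
#'
#' @param samples Numeric vector of at least one sample.
#' @param bandwidth Kernel standard deviation, strictly positive, in the
#'   same units as the samples.
#' @return An object of class `kde_density`.
#' @examples
#' k <- kde_pdf(c(0, 2), bandwidth = 1)
#' density_at(k, 1)  # exp(-0.5)/sqrt(2*pi)
#' @export
kde_pdf <- function(samples, bandwidth) {
  if (!is.numeric(samples) || length(samples) < 1L || anyNA(samples))
    stop("`samples` must be a non-empty numeric vector without NAs",
         call. = FALSE)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("`bandwidth` must be a single positive number", call. = FALSE)
  structure(list(samples = as.numeric(samples), bandwidth = bandwidth),
            class = "kde_density")
}

#' Evaluate a kernel density estimate
#'
#' @param density A `kde_density`.
#' @param x Points at which to evaluate.
#' @return Density values, same length as `x`.
#' @export
density_at <- function(density, x) {
  stopifnot(inherits(density, "kde_density"), is.numeric(x))
  s <- density$samples
  bw <- density$bandwidth
  vapply(x, function(xi) mean(stats::dnorm(xi, mean = s, sd = bw)), 1)
}

#' @export
print.kde_density <- function(x, ...) {
  cat(sprintf("<kde_density> %d samples, gaussian bandwidth %g\n",
              length(x$samples), x$bandwidth))
  invisible(x)
}

#' Log-likelihood of observations under a kernel density
#'
#' Sums `log(PDF(x_i))` over the observations. Density values below `floor`
#' are floored before taking logs so that observations far outside the
#' simulated support keep the scan finite; the number of floored evaluations
#' is reported in the `n_floored` attribute.
#'
#' @param density A `kde_density`.
#' @param observations Non-empty numeric vector.
#' @param floor Density floor (default `1e-12`).
#' @return The summed log-likelihood with attribute `n_floored`.
#' @export
dataset_log_likelihood <- function(density, observations, floor = 1e-12) {
  if (!is.numeric(observations) || length(observations) < 1L)
    stop("`observations` must be non-empty", call. = FALSE)
  p <- density_at(density, observations)
  structure(sum(log(pmax(p, floor))), n_floored = sum(p < floor))
}

#' Combine two dataset log-likelihoods into -2 log L
#'
#' The joint likelihood of the two datasets is the product `L1 * L2`; in log
#' space the combined deviance is `-2 (log L1 + log L2)`.
#'
#' @param loglik1,loglik2 Finite log-likelihoods.
#' @return `-2 * (loglik1 + loglik2)`.
#' @export
combined_neg2_loglik <- function(loglik1, loglik2) {
  stopifnot(is.finite(loglik1), is.finite(loglik2))
  -2 * (as.numeric(loglik1) + as.numeric(loglik2))
}

#' Likelihood surface over a (c, q) parameter grid
#'
#' For every grid point, simulates a fresh ensemble of `n_sim` clones,
#' builds the two kernel densities — per-clone acinar fractions at the
#' window end (bandwidth `bw_clonal`, fraction scale) and pooled group
#' fractions per timepoint and lineage (bandwidth `bw_grouped`, percent
#' scale) — evaluates the two observed datasets under them, and records the
#' combined deviance `-2 log(L1 L2)`. Each grid cell draws its own seed
#' keyed by `(seed, c, q)`, so the surface is reproducible, independent of
#' the traversal order, and identical across subgrids.
#'
#' @param observed_clonal Numeric vector of observed per-clone acinar
#'   fractions in `[0, 1]`.
#' @param observed_grouped Data frame with columns `timepoint`, `lineage`
#'   (`"acinar"`/`"endocrine"`) and `frac_percent`, as produced by
#'   [grouped_population_fractions()] or read from a fractions CSV.
#' @param model 1 or 2.
#' @param c_grid,q_grid Probability grids. The defaults cover
#'   `c` in 0.05-0.60 and `q` in 0.05-0.95 in steps of 0.05.
#' @param n_sim Clones per grid cell (reference protocol: 2500).
#' @param seed Integer seed for the whole scan.
#' @param bw_clonal Bandwidth of the clonal-fraction density (default
#'   0.015 on the fraction scale).
#' @param bw_grouped Bandwidth of the pooled-fraction density (default 6.5
#'   on the percent scale).
#' @param group_size Clones pooled per simulated pancreas (default 100).
#' @param params Template [model_params()] supplying window and cell-cycle
#'   settings; its `model`, `c`, `q` and `seed` are overridden per cell.
#' @param floor Density floor, see [dataset_log_likelihood()].
#' @param require_progenitor,require_acinar Clone inclusion filters for the
#'   clonal dataset, see [clonal_acinar_fractions()].
#' @return A data frame of class `likelihood_surface` with columns `model`,
#'   `c`, `q`, `neg2_loglik`, `n_floored`, `n_clonal_sim` (clones passing
#'   the filters) and `empty` (no simulated clone passed the filters, cell
#'   floored).
#' @seealso [compare_models()], [surface_argmin()]
#' @export
scan_likelihood <- function(observed_clonal, observed_grouped, model,
                            c_grid = seq(0.05, 0.60, by = 0.05),
                            q_grid = seq(0.05, 0.95, by = 0.05),
                            n_sim = 2500, seed = 1L,
                            bw_clonal = 0.015, bw_grouped = 6.5,
                            group_size = 100, params = model_params(),
                            floor = 1e-12,
                            require_progenitor = TRUE, require_acinar = TRUE) {
  stopifnot(length(c_grid) >= 1, length(q_grid) >= 1,
            length(observed_clonal) >= 1, is.data.frame(observed_grouped),
            all(c("timepoint", "lineage", "frac_percent") %in%
                  names(observed_grouped)))
  timepoints <- sort(unique(observed_grouped$timepoint))
  rows <- vector("list", length(c_grid) * length(q_grid))
  r <- 0L
  for (i in seq_along(c_grid)) {
    for (j in seq_along(q_grid)) {
      p <- params
      p$model <- switch(as.character(model), "1" = 1L, "2" = 2L,
                        stop("`model` must be 1 or 2", call. = FALSE))
      p$c <- c_grid[i]
      p$q <- q_grid[j]
      # per-cell seed keyed by the (c, q) values themselves, so any subgrid
      # or traversal order reproduces the same cell
      p$seed <- derive_seed(seed, round(p$c * 1e6), round(p$q * 1e6))
      ens <- simulate_ensemble(p, n_sim)

      fr <- clonal_acinar_fractions(ens,
                                    require_progenitor = require_progenitor,
                                    require_acinar = require_acinar)
      empty <- length(fr) == 0L
      if (empty) {
        ll1 <- length(observed_clonal) * log(floor)
        nf <- length(observed_clonal)
      } else {
        ll1 <- dataset_log_likelihood(kde_pdf(fr, bw_clonal),
                                      observed_clonal, floor = floor)
        nf <- attr(ll1, "n_floored")
      }

      sim_grouped <- grouped_population_fractions(ens, group_size, timepoints)
      ll2 <- 0
      for (tp in timepoints) {
        for (lin in c("acinar", "endocrine")) {
          obs <- observed_grouped$frac_percent[
            observed_grouped$timepoint == tp & observed_grouped$lineage == lin]
          if (length(obs) == 0L) next
          sims <- sim_grouped$frac_percent[
            sim_grouped$timepoint == tp & sim_grouped$lineage == lin]
          llx <- dataset_log_likelihood(kde_pdf(sims, bw_grouped), obs,
                                        floor = floor)
          ll2 <- ll2 + as.numeric(llx)
          nf <- nf + attr(llx, "n_floored")
        }
      }

      r <- r + 1L
      rows[[r]] <- data.frame(model = p$model, c = c_grid[i], q = q_grid[j],
                              neg2_loglik = combined_neg2_loglik(as.numeric(ll1), ll2),
                              n_floored = nf, n_clonal_sim = length(fr),
                              empty = empty)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "c_grid") <- c_grid
  attr(out, "q_grid") <- q_grid
  attr(out, "seed") <- seed
  class(out) <- c("likelihood_surface", "data.frame")
  out
}

#' Best-fitting grid point of a likelihood surface
#'
#' @param surface A `likelihood_surface`.
#' @return One-row data frame with the `(c, q)` minimising `-2 log L` (ties
#'   broken toward smaller `c`, then smaller `q`).
#' @export
surface_argmin <- function(surface) {
  stopifnot(inherits(surface, "likelihood_surface"))
  s <- surface[order(surface$neg2_loglik, surface$c, surface$q), ]
  s[1L, c("model", "c", "q", "neg2_loglik")]
}

#' Akaike information criterion
#'
#' The default `"standard"` convention is `AIC = 2k - 2 ln(L)`. The
#' `"as_printed"` convention `2k - ln(L)` mirrors a formula sometimes
#' written without the factor 2; only the standard convention reproduces
#' the published relative model probability of 0.02 from the published AIC
#' pair, so it is the default.
#'
#' @param k Number of free parameters (both fate models have `k = 2`:
#'   `c` and `q`).
#' @param max_loglik Maximised log-likelihood.
#' @param convention `"standard"` or `"as_printed"`.
#' @return The AIC value.
#' @export
aic_score <- function(k, max_loglik, convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  if (convention == "standard") 2 * k - 2 * max_loglik else 2 * k - max_loglik
}

#' Relative Akaike model probabilities
#'
#' `p_i = exp((AIC_min - AIC_i) / 2)`: the relative likelihood that model
#' `i` is as good as the preferred (minimum-AIC) model, which gets exactly 1.
#'
#' @param aic_values At least two finite AIC values.
#' @return Probabilities in `(0, 1]`, same order as the input.
#' @examples
#' relative_probability(c(-14.5, -22.1))  # c(0.022, 1)
#' @export
relative_probability <- function(aic_values) {
  stopifnot(is.numeric(aic_values), length(aic_values) >= 2L,
            all(is.finite(aic_values)))
  exp((min(aic_values) - aic_values) / 2)
}

#' Compare two fate models fitted on the same data
#'
#' Takes the likelihood surfaces of the two models (same observed data),
#' extracts each model's maximum log-likelihood (`-min(-2 log L) / 2`),
#' scores both with [aic_score()] and reports relative probabilities.
#'
#' @param surface1,surface2 `likelihood_surface` objects for Model 1 and
#'   Model 2.
#' @param k Free-parameter count per model (default 2 for both).
#' @param convention AIC convention, see [aic_score()].
#' @return A list of class `model_comparison` with elements `table` (model,
#'   max_loglik, aic, relative_probability), `preferred` (model id) and
#'   `convention`.
#' @export
compare_models <- function(surface1, surface2, k = 2,
                           convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  stopifnot(inherits(surface1, "likelihood_surface"),
            inherits(surface2, "likelihood_surface"))
  k <- rep_len(k, 2L)
  ml <- c(-min(surface1$neg2_loglik) / 2, -min(surface2$neg2_loglik) / 2)
  aic <- c(aic_score(k[1L], ml[1L], convention),
           aic_score(k[2L], ml[2L], convention))
  tab <- data.frame(model = c(surface1$model[1L], surface2$model[1L]),
                    max_loglik = ml, aic = aic,
                    relative_probability = relative_probability(aic))
  structure(list(table = tab, preferred = tab$model[which.min(tab$aic)],
                 convention = convention),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> preferred: model %d (AIC convention: %s)\n",
              x$preferred, x$convention))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Probability of fully acinar-committed clones by tracing start day
#'
#' The commitment-wave prediction: clones whose tracing starts near the
#' endocrine-bias minimum (around E11.5-E12 under Model 2) are far more
#' likely to consist solely of acinar cells at E14.5 than clones started at
#' E9.5, where the bias forces the first differentiating daughters to the
#' endocrine fate. For each start day, `n_sim` clones are simulated from a
#' single progenitor over `[start, E14.5]` — the fate bias is always
#' evaluated on the global E9.5-E14.5 normalisation — and the fraction that
#' are purely acinar at E14.5 is returned.
#'
#' @param params Template [model_params()]; its window start is replaced by
#'   each start day, and per-day seeds are derived from `params$seed`.
#' @param start_days Embryonic days in `[9.5, 14.5)`.
#' @param n_sim Clones per start day.
#' @return Data frame with columns `start_day`, `probability`, `n_clones`.
#' @export
unipotent_acinar_probability <- function(params, start_days, n_sim = 2500) {
  stopifnot(inherits(params, "model_params"),
            all(start_days >= .NORM_START_E), all(start_days < .NORM_END_E))
  probs <- vapply(seq_along(start_days), function(d) {
    p <- params
    p$window_start <- start_days[d]
    p$window_end <- .NORM_END_E
    if (!is.null(params$seed)) p$seed <- derive_seed(params$seed, d)
    ens <- simulate_ensemble(p, n_sim)
    comp <- composition_at(ens, window_hours(p))
    mean(comp[, "progenitor"] == 0L & comp[, "endocrine"] == 0L &
           comp[, "acinar"] > 0L)
  }, 1)
  data.frame(start_day = start_days, probability = probs, n_clones = n_sim)
}
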