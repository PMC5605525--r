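#' Synthetic clone observation tables
#'
#' Generates clone-composition tables with the statistical structure of the
#' clonal tracing screens. Each labelled founder is one of three kinds:
#' an already-differentiated endocrine cell (a single-cell endocrine
#' clone), a NEUROG3-stage endocrine precursor (divides at most once more,
#' giving a 1-2-cell endocrine clone), or a replicating progenitor whose
#' clone is grown with the stochastic fate model. At E9.5 differentiated
#' endocrine cells and NEUROG3+ precursors each make up about 12% of the
#' bud, which the founder mixture reflects.
#'
#' The tracing driver censors founders: the ubiquitous driver (`"rosa26"`)
#' labels everything; `"hnf1b"` is not expressed in mature endocrine cells
#' (those founders are excluded with probability `hnf1b_endocrine_censor`)
#' and is detected in only ~68% of NEUROG3+ precursors (excluded with
#' probability `hnf1b_precursor_censor`); `"ptf1a"` never labels
#' endocrine-committed founders, and its progenitor-founded clones are
#' additionally conditioned (by bounded resampling) on containing at least
#' one non-endocrine cell at harvest, so that driver yields no
#' endocrine-only clones, as in the corresponding screen. Censored founders
#' are replaced by redrawing the founder type among the remaining kinds, so
#' `n_clones` clones are always returned.
#'
#' Simulated fate states map to the harvest-stage markers as
#' progenitor -> SOX9 (ductal), acinar -> CPA1, endocrine -> PAX6.
#'
#' @param params A [model_params()]; `params$seed` drives all randomness.
#' @param n_clones Number of clones to emit.
#' @param driver `"rosa26"`, `"hnf1b"` or `"ptf1a"`.
#' @param founder_mix Probabilities of (endocrine, precursor, progenitor)
#'   founders before censoring.
#' @param hnf1b_endocrine_censor,hnf1b_precursor_censor Exclusion
#'   probabilities under the `"hnf1b"` driver.
#' @param p_ventral Probability a clone sits in the ventral bud.
#' @return A [clone_observations()] data frame with an added `founder`
#'   column (`"endocrine"`, `"precursor"` or `"progenitor"`).
#' @export
synth_clone_observations <- function(params, n_clones,
                                     driver = c("rosa26", "hnf1b", "ptf1a"),
                                     founder_mix = c(endocrine = 0.12,
                                                     precursor = 0.12,
                                                     progenitor = 0.76),
                                     hnf1b_endocrine_censor = 1,
                                     hnf1b_precursor_censor = 0.32,
                                     p_ventral = 0.15) {
  driver <- match.arg(driver)
  stopifnot(inherits(params, "model_params"), n_clones >= 1,
            length(founder_mix) == 3L, all(founder_mix >= 0),
            sum(founder_mix) > 0)
  w <- founder_mix / sum(founder_mix)
  w <- switch(driver,
              rosa26 = w,
              hnf1b = c(w[1L] * (1 - hnf1b_endocrine_censor),
                        w[2L] * (1 - hnf1b_precursor_censor), w[3L]),
              ptf1a = c(0, 0, w[3L]))
  w <- w / sum(w)
  if (!is.null(params$seed)) set.seed(params$seed)
  founder <- sample(c("endocrine", "precursor", "progenitor"), n_clones,
                    replace = TRUE, prob = w)
  location <- sample(c("ventral", "dorsal"), n_clones, replace = TRUE,
                     prob = c(p_ventral, 1 - p_ventral))

  n_duct <- integer(n_clones)
  n_endo <- integer(n_clones)
  n_acin <- integer(n_clones)
  n_endo[founder == "endocrine"] <- 1L

  n_prec <- sum(founder == "precursor")
  if (n_prec) {
    # a precursor behaves like a forced-endocrine progenitor: it divides at
    # most once inside the window and both daughters are endocrine
    pp <- params
    pp$c <- 1; pp$q <- 1; pp$model <- 1L; pp$seed <- NULL
    comp <- composition_at(simulate_ensemble(pp, n_prec), window_hours(pp))
    n_endo[founder == "precursor"] <- pmax(comp[, "endocrine"], 1L)
  }

  n_prog <- sum(founder == "progenitor")
  if (n_prog) {
    pp <- params
    pp$seed <- NULL
    comp <- composition_at(simulate_ensemble(pp, n_prog), window_hours(pp))
    n_duct[founder == "progenitor"] <- comp[, "progenitor"]
    n_endo[founder == "progenitor"] <- comp[, "endocrine"]
    n_acin[founder == "progenitor"] <- comp[, "acinar"]
  }

  if (driver == "ptf1a") {
    # Ptf1a-high founders are not on the endocrine path: their clones are
    # conditioned on contributing at least one non-endocrine cell, so the
    # generator reproduces that screen's absence of endocrine-only clones
    redo <- which(n_duct == 0L & n_acin == 0L)
    tries <- 0L
    while (length(redo) > 0L && tries < 100L) {
      comp <- composition_at(simulate_ensemble(pp, length(redo)),
                             window_hours(pp))
      n_duct[redo] <- comp[, "progenitor"]
      n_endo[redo] <- comp[, "endocrine"]
      n_acin[redo] <- comp[, "acinar"]
      redo <- redo[comp[, "progenitor"] == 0L & comp[, "acinar"] == 0L]
      tries <- tries + 1L
    }
    if (length(redo) > 0L)
      warning("could not avoid endocrine-only clones within 100 resampling ",
              "rounds; ", length(redo), " remain")
  }

  obs <- clone_observations(seq_len(n_clones), n_duct, n_endo, n_acin,
                            location)
  obs$founder <- founder
  obs
}

#' Synthetic 3D pancreatic bud point cloud
#'
#' Samples cell centroids inside a sphere with a minimum-separation
#' rejection rule (nuclei do not overlap) and paints a marker intensity
#' field over them: constant (`"uniform"`), monotone along the y axis
#' (`"posterior_gradient"`, emulating the posterior-high HNF1B pattern) or
#' elevated inside an off-centre subsphere (`"lateral_cluster"`, emulating
#' the lateral PTF1A cluster), plus gaussian noise.
#'
#' @param n_cells Number of cells (at least 10).
#' @param bud_radius_um Bud radius (default 40 um, the scale of an E9.5
#'   dorsal bud).
#' @param pattern `"uniform"`, `"posterior_gradient"` or
#'   `"lateral_cluster"`.
#' @param noise_sd Gaussian intensity noise (default 5).
#' @param min_sep_um Minimum centroid separation (default 5 um).
#' @param base,amplitude Intensity baseline and pattern amplitude.
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling attempts per cell before declaring
#'   the packing infeasible.
#' @return Data frame `cell_id`, `x_um`, `y_um`, `z_um`, `intensity` with
#'   attribute `pattern`.
#' @export
synth_bud_cloud <- function(n_cells, bud_radius_um = 40,
                            pattern = c("uniform", "posterior_gradient",
                                        "lateral_cluster"),
                            noise_sd = 5, min_sep_um = 5,
                            base = 100, amplitude = 100,
                            seed = NULL, max_tries = 200) {
  pattern <- match.arg(pattern)
  stopifnot(n_cells >= 10, bud_radius_um > 0, min_sep_um >= 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(NA_real_, n_cells, 3L)
  placed <- 0L
  tries <- 0L
  while (placed < n_cells) {
    if (tries > max_tries * n_cells)
      stop("infeasible packing: could not place ", n_cells,
           " cells with min separation ", min_sep_um, " um", call. = FALSE)
    cand <- stats::runif(3L, -bud_radius_um, bud_radius_um)
    tries <- tries + 1L
    if (sum(cand^2) > bud_radius_um^2) next
    if (placed > 0L) {
      d2 <- rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2L, cand)^2)
      if (min(d2) < min_sep_um^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- cand
  }
  r <- bud_radius_um
  intensity <- switch(pattern,
    uniform = rep(base, n_cells),
    posterior_gradient = base + amplitude * (pts[, 2L] + r) / (2 * r),
    lateral_cluster = {
      ctr <- c(0.6 * r, 0, 0)
      inside <- rowSums(sweep(pts, 2L, ctr)^2) < (0.45 * r)^2
      base + amplitude * inside
    })
  if (noise_sd > 0) intensity <- intensity + stats::rnorm(n_cells, 0, noise_sd)
  out <- data.frame(cell_id = seq_len(n_cells), x_um = pts[, 1L],
                    y_um = pts[, 2L], z_um = pts[, 3L],
                    intensity = pmax(intensity, 0))
  attr(out, "pattern") <- pattern
  out
}

#' Synthetic label-dilution (H2B-GFP) field
#'
#' Emulates the doxycycline-suppression experiment: founders carry a
#' nuclear label of `initial_intensity` that is halved at every division,
#' so a final cell's intensity is `initial / 2^n_div`. Founders are placed
#' along the pancreas length axis; with `spatial_bias > 0` the expected
#' cell-cycle length shrinks linearly with distance from the axis midpoint
#' (peripheral cells cycle faster), so central cells retain label — the
#' spatial structure the retention maps display. Endocrine progeny never
#' divide, so their label stops diluting at birth: endocrine cells formed
#' early after suppression are strong retainers, and an endocrine founder
#' that never divides keeps the full initial intensity.
#'
#' @param params A [model_params()] providing the tracing window, fate
#'   parameters and the baseline (central) cell-cycle distribution;
#'   `params$seed` drives all randomness.
#' @param n_founders Number of labelled founder cells.
#' @param axis_length_um Length of the modelled axis (default 400 um).
#' @param spatial_bias Fractional cycle-length reduction at the axis
#'   extremes, in `[0, 1)`: cycle scale at normalised distance `p` from the
#'   centre is `scale * (1 - spatial_bias * p)`. 0 disables the bias.
#' @param initial_intensity Founder label intensity (default 1000, strictly
#'   above `detection_floor`).
#' @param detection_floor Intensities at or below this are reported as 0.
#' @param scatter_um Progeny scatter around the founder position.
#' @return Data frame `cell_id`, `clone_id`, `x_um`, `y_um`, `z_um`,
#'   `state`, `n_div`, `gfp`.
#' @export
synth_label_dilution <- function(params, n_founders = 40,
                                 axis_length_um = 400, spatial_bias = 0.5,
                                 initial_intensity = 1000,
                                 detection_floor = 0, scatter_um = 15) {
  stopifnot(inherits(params, "model_params"), n_founders >= 1,
            spatial_bias >= 0, spatial_bias < 1,
            initial_intensity > detection_floor, detection_floor >= 0)
  if (!is.null(params$seed)) set.seed(params$seed)
  x0 <- stats::runif(n_founders, 0, axis_length_um)
  peripheral <- abs(x0 / axis_length_um - 0.5) * 2
  out <- vector("list", n_founders)
  hrs <- window_hours(params)
  for (i in seq_len(n_founders)) {
    p <- params
    p$seed <- NULL
    p$cycle <- gamma_cycle(params$cycle$shape,
                           params$cycle$scale *
                             (1 - spatial_bias * peripheral[i]))
    tree <- simulate_ensemble(p, 1L)
    alive <- tree$cells[.alive_at(tree$cells, hrs), ]
    m <- nrow(alive)
    out[[i]] <- data.frame(
      clone_id = i,
      x_um = x0[i] + stats::rnorm(m, 0, scatter_um),
      y_um = stats::rnorm(m, 0, scatter_um),
      z_um = stats::rnorm(m, 0, scatter_um),
      state = as.character(alive$state),
      n_div = alive$n_div,
      gfp = initial_intensity / 2^alive$n_div)
  }
  res <- do.call(rbind, out)
  res$gfp[res$gfp <= detection_floor] <- 0
  res <- cbind(cell_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Synthetic whole-pancreas lineage fractions
#'
#' End-to-end wrapper: simulates `n_pancreata * clones_per_pancreas` clones
#' and pools them into per-pancreas acinar/endocrine fractions at the
#' requested embryonic days, in the exact shape the likelihood scan
#' consumes as its grouped observed dataset.
#'
#' @param params A [model_params()]; `params$seed` drives the simulation.
#' @param timepoints Embryonic days (default E10.5, E11.5, E12.5, E14.5).
#' @param n_pancreata Number of pooled groups (default 3).
#' @param clones_per_pancreas Clones per group (default 100).
#' @return Data frame `timepoint`, `lineage`, `frac_percent` (plus `group`).
#' @export
synth_bulk_fractions <- function(params,
                                 timepoints = c(10.5, 11.5, 12.5, 14.5),
                                 n_pancreata = 3, clones_per_pancreas = 100) {
  stopifnot(n_pancreata >= 1, clones_per_pancreas >= 1)
  ens <- simulate_ensemble(params, n_pancreata * clones_per_pancreas)
  grouped_population_fractions(ens, group_size = clones_per_pancreas,
                               timepoints = timepoints)
}
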