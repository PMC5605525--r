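test_that("synthetic clone tables are reproducible and driver-censored", {
  p <- model_params(model = 2, c = 0.2, q = 0.1, seed = 17)
  a <- synth_clone_observations(p, 150, driver = "rosa26")
  b <- synth_clone_observations(p, 150, driver = "rosa26")
  expect_identical(a, b)
  expect_identical(nrow(a), 150L)
  # Ptf1a tracing yields no endocrine-only clones by construction
  pt <- synth_clone_observations(p, 200, driver = "ptf1a")
  expect_false(any(classify_potency(pt) == "uni_endocrine"))
  expect_true(all(pt$founder == "progenitor"))
  # Hnf1b never labels mature endocrine founders at the default censor
  hn <- synth_clone_observations(p, 200, driver = "hnf1b")
  expect_false(any(hn$founder == "endocrine"))
  expect_true(any(hn$founder == "precursor"))
  # rosa26 labels everything, including single-cell endocrine clones
  expect_true(any(a$founder == "endocrine"))
  expect_true(all(a$n_ductal + a$n_endocrine + a$n_acinar >= 1))
})

test_that("forced-endocrine parameters make every clone purely endocrine", {
  p <- model_params(model = 1, c = 1, q = 1, seed = 23)
  obs <- synth_clone_observations(p, 80, driver = "rosa26")
  expect_true(all(classify_potency(obs) == "uni_endocrine"))
})

test_that("synthetic clone counts equal the fate-model composition", {
  p <- model_params(model = 2, c = 0.25, q = 0.15, seed = 29)
  obs <- synth_clone_observations(p, 120, driver = "rosa26",
                                  founder_mix = c(0, 0, 1))
  # with progenitor-only founders the generator is exactly the fate model
  set.seed(29)
  invisible(sample(c("endocrine", "precursor", "progenitor"), 120,
                   replace = TRUE, prob = c(0, 0, 1)))
  invisible(sample(c("ventral", "dorsal"), 120, replace = TRUE,
                   prob = c(0.15, 0.85)))
  pp <- p; pp$seed <- NULL
  comp <- composition_at(simulate_ensemble(pp, 120), window_hours(pp))
  expect_equal(obs$n_ductal, unname(comp[, "progenitor"]))
  expect_equal(obs$n_endocrine, unname(comp[, "endocrine"]))
  expect_equal(obs$n_acinar, unname(comp[, "acinar"]))
})

test_that("bud clouds respect packing and paint the requested pattern", {
  u <- synth_bud_cloud(120, pattern = "uniform", noise_sd = 0, seed = 1)
  expect_identical(nrow(u), 120L)
  expect_equal(length(unique(u$intensity)), 1L)
  expect_true(all(u$x_um^2 + u$y_um^2 + u$z_um^2 <= 40^2 + 1e-9))
  expect_gt(min(dist(u[, c("x_um", "y_um", "z_um")])), 5 - 1e-9)
  g <- synth_bud_cloud(120, pattern = "posterior_gradient", noise_sd = 0,
                       seed = 2)
  o <- order(g$y_um)
  expect_true(all(diff(g$intensity[o]) > 0))
  cl <- synth_bud_cloud(120, pattern = "lateral_cluster", noise_sd = 0,
                        seed = 3)
  expect_identical(sort(unique(cl$intensity)), c(100, 200))
  # reproducibility and infeasible packings
  expect_identical(synth_bud_cloud(60, seed = 9), synth_bud_cloud(60, seed = 9))
  expect_error(synth_bud_cloud(500, bud_radius_um = 10, min_sep_um = 8,
                               seed = 4, max_tries = 20), "infeasible")
})

test_that("regionalised bud patterns score higher assortativity than uniform", {
  score <- function(pattern, seed) {
    cloud <- synth_bud_cloud(250, pattern = pattern, noise_sd = 5, seed = seed)
    neighborhood_assortativity(neighbor_graph(cloud, threshold = 10),
                               setNames(cloud$intensity, cloud$cell_id))
  }
  seeds <- 1:12
  uni <- vapply(seeds, function(s) score("uniform", s), 1)
  grad <- vapply(seeds, function(s) score("posterior_gradient", s), 1)
  clus <- vapply(seeds, function(s) score("lateral_cluster", s), 1)
  expect_true(all(grad > uni))
  expect_true(all(clus > uni))
  dg <- mean(grad) - mean(uni)
  expect_gt(dg, 3 * sd(grad - uni) / sqrt(length(seeds)))
  dc <- mean(clus) - mean(uni)
  expect_gt(dc, 3 * sd(clus - uni) / sqrt(length(seeds)))
})

test_that("label dilution halves intensity per division", {
  p <- model_params(model = 1, c = 0.2, q = 0.5,
                    window_start = 11.5, window_end = 14.5, seed = 41)
  ld <- synth_label_dilution(p, n_founders = 15, spatial_bias = 0,
                             initial_intensity = 1000)
  expect_equal(ld$gfp, 1000 / 2^ld$n_div)
  # endocrine progeny stop diluting: they retain at least as much label as
  # the division count of any cell in their clone would suggest
  expect_true(all(ld$gfp > 0))
  ld2 <- synth_label_dilution(p, n_founders = 15, spatial_bias = 0,
                              initial_intensity = 1000, detection_floor = 50)
  expect_true(all(ld2$gfp == 0 | ld2$gfp > 50))
  # a 3-division cell carries 1/8 of the initial label
  expect_true(any(ld$n_div == 3))
  expect_equal(unique(ld$gfp[ld$n_div == 3]), 125)
})

test_that("central-slow bias concentrates top retainers centrally", {
  p <- model_params(model = 1, c = 0, q = 0,
                    window_start = 11.5, window_end = 14.5)
  centralness <- function(seed, bias) {
    p$seed <- seed
    ld <- synth_label_dilution(p, n_founders = 30, spatial_bias = bias,
                               axis_length_um = 400)
    sox <- ld[ld$state != "endocrine", ]
    top <- top_retainers(setNames(sox$gfp, sox$cell_id), 0.10)
    mean(abs(ld$x_um[match(as.integer(top), ld$cell_id)] - 200))
  }
  biased <- vapply(1:8, function(s) centralness(s, 0.5), 1)
  control <- vapply(1:8, function(s) centralness(s, 0), 1)
  expect_lt(mean(biased), mean(control))
})

test_that("bulk fraction tables behave like staged pancreata", {
  p0 <- model_params(model = 1, c = 0, q = 0, seed = 51)
  fr0 <- synth_bulk_fractions(p0, n_pancreata = 2, clones_per_pancreas = 50)
  expect_true(all(fr0$frac_percent == 0))
  p <- model_params(model = 2, c = 0.25, q = 0.1, seed = 52)
  fr <- synth_bulk_fractions(p, n_pancreata = 3)
  expect_true(all(fr$frac_percent >= 0 & fr$frac_percent <= 100))
  tot <- aggregate(frac_percent ~ group + timepoint, fr, sum)
  expect_true(all(tot$frac_percent <= 100 + 1e-9))
  # hereditary acinar fate accumulates between E10.5 and E14.5
  ac <- aggregate(frac_percent ~ timepoint, fr[fr$lineage == "acinar", ], mean)
  expect_gt(ac$frac_percent[ac$timepoint == 14.5],
            ac$frac_percent[ac$timepoint == 10.5])
})

test_that("csv round-trips preserve observation tables", {
  p <- model_params(model = 2, c = 0.2, q = 0.1, seed = 61)
  obs <- synth_clone_observations(p, 40)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_clones_csv(obs, f1, provenance = "seed=61")
  expect_match(readLines(f1, n = 1), "seed=61")
  back <- read_clones_csv(f1)
  expect_equal(back$n_ductal, obs$n_ductal)
  expect_equal(back$n_endocrine, obs$n_endocrine)
  expect_equal(back$n_acinar, obs$n_acinar)
  fr <- synth_bulk_fractions(p, n_pancreata = 2)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_fractions_csv(fr, f2)
  fr2 <- read_fractions_csv(f2)
  expect_equal(fr2$frac_percent, fr$frac_percent)
  expect_equal(fr2$timepoint, fr$timepoint)
})
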