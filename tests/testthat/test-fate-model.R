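test_that("endocrine bias follows the two model forms", {
  # Model 1: constant bias f = q regardless of time
  expect_equal(endocrine_bias(1, q = 0.37, t_norm = 0.8), 0.37)
  expect_equal(endocrine_bias(1, q = 0.37, t_norm = c(0, 0.5, 1)),
               rep(0.37, 3))
  # Model 2 boundary values: cos(0) = 1 forces f = 1, cos(pi) = -1 leaves q
  expect_equal(endocrine_bias(2, q = 0.2, t_norm = 0), 1)
  expect_equal(endocrine_bias(2, q = 0.2, t_norm = 0.5), 0.2)
  expect_equal(endocrine_bias(2, q = 0.2, t_norm = 1), 1)
  # symmetric about the E12 midpoint, minimum exactly q, range [q, 1]
  tt <- seq(0, 0.5, by = 0.01)
  for (q in c(0, 0.3, 0.9)) {
    f <- endocrine_bias(2, q, tt)
    expect_equal(f, endocrine_bias(2, q, 1 - tt))
    expect_true(all(f >= q - 1e-12 & f <= 1 + 1e-12))
    expect_equal(min(f), q)
    expect_equal(which.min(f), length(tt))
  }
  expect_error(endocrine_bias(2, 0.2, -0.01), "t_norm")
  expect_error(endocrine_bias(2, 0.2, 1.01), "t_norm")
})

test_that("cell-cycle draws match the closed-form gamma moments", {
  set.seed(101)
  x <- draw_cycle_length(1e5, gamma_cycle(shape = 10, scale = 1.35))
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 13.5) / 13.5, 0.01)
  expect_lt(abs(var(x) - 10 * 1.35^2) / (10 * 1.35^2), 0.05)
  # variance -> 0 limit at fixed mean: samples concentrate at the mean
  y <- draw_cycle_length(1e4, gamma_cycle(shape = 1e6, scale = 13.5 / 1e6))
  expect_lt(max(abs(y - 13.5)), 0.5)
  expect_error(gamma_cycle(shape = -1), "shape")
  expect_error(gamma_cycle(scale = 0), "scale")
})

test_that("fate assignment reproduces the multinomial (1-c, cf, c(1-f))", {
  expect_equal(unique(assign_fate(100, c = 0, f = 0.5)), "progenitor")
  expect_equal(unique(assign_fate(100, c = 1, f = 1)), "endocrine")
  set.seed(7)
  n <- 1e5
  s <- assign_fate(n, c = 0.5, f = 0.3)
  probs <- c(progenitor = 0.5, endocrine = 0.15, acinar = 0.35)
  for (st in names(probs)) {
    p <- probs[[st]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(s == st) - p), 3 * se)
  }
})

test_that("degenerate parameter corners give the predicted lineages", {
  # c = 0: pure expansion, every cell stays a progenitor
  ens <- simulate_ensemble(model_params(model = 1, c = 0, q = 0, seed = 11), 50)
  expect_true(all(ens$cells$state == "progenitor"))
  # c = 1, f = 1: the founder's two daughters are endocrine and absorbing
  ens <- simulate_ensemble(model_params(model = 1, c = 1, q = 1, seed = 12), 200)
  sz <- table(tabulate(ens$cells$clone, nbins = 200))
  expect_true(all(names(sz) %in% c("1", "3")))  # undivided root, or root + 2
  kids <- ens$cells[!is.na(ens$cells$parent_id), ]
  expect_true(all(kids$state == "endocrine"))
})

test_that("mean clone size under pure expansion matches the renewal-equation oracle", {
  oracle <- renewal_expected_size(shape = 10, scale = 1.35, t_end = 120)
  ens <- simulate_ensemble(model_params(model = 1, c = 0, q = 0, seed = 13), 1000)
  sizes <- clone_sizes(ens, 120)
  # clone sizes are heavy-tailed; allow 3 standard errors around the oracle
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - oracle), 3 * se)
})

test_that("ensembles are reproducible and seeds matter", {
  p <- model_params(model = 2, c = 0.2, q = 0.1, seed = 42)
  e1 <- simulate_ensemble(p, 40)
  e2 <- simulate_ensemble(p, 40)
  expect_identical(e1$cells, e2$cells)
  p$seed <- 43L
  e3 <- simulate_ensemble(p, 40)
  expect_false(identical(e1$cells, e3$cells))
})

test_that("lineage trees have one root and binary divisions", {
  ens <- simulate_ensemble(model_params(model = 2, c = 0.3, q = 0.2, seed = 5), 30)
  for (i in c(1, 7, 30)) {
    tree <- lineage(ens, i)
    expect_identical(sum(is.na(tree$cells$parent_id)), 1L)
    kids <- table(tree$cells$parent_id)
    expect_true(all(kids == 2L))
    # parents exist and precede their children in time
    idx <- match(tree$cells$parent_id, tree$cells$cell_id)
    nonroot <- !is.na(tree$cells$parent_id)
    expect_false(anyNA(idx[nonroot]))
    expect_true(all(tree$cells$birth[nonroot] >=
                      tree$cells$birth[idx[nonroot]]))
  }
})

test_that("composition_at matches manual enumeration on the hand-built tree", {
  tree <- hand_tree()
  expect_equal(composition_at(tree, 0),
               c(progenitor = 1L, acinar = 0L, endocrine = 0L))
  expect_equal(composition_at(tree, 20),
               c(progenitor = 1L, acinar = 0L, endocrine = 1L))
  expect_equal(composition_at(tree, 40),
               c(progenitor = 0L, acinar = 1L, endocrine = 2L))
  expect_equal(composition_at(tree, 120),
               c(progenitor = 0L, acinar = 2L, endocrine = 2L))
  expect_error(composition_at(tree, -1), "must lie in")
  expect_error(composition_at(tree, 121), "must lie in")
})

test_that("composition counts are conserved across an ensemble", {
  ens <- simulate_ensemble(model_params(model = 2, c = 0.25, q = 0.3, seed = 8), 100)
  for (t in c(0, 30, 75, 120)) {
    comp <- composition_at(ens, t)
    expect_true(all(rowSums(comp) >= 1))
    expect_identical(unname(rowSums(composition_at(ens, 0))), rep(1, 100))
  }
})

test_that("acinar heredity holds: children of acinar cells are acinar", {
  ens <- simulate_ensemble(model_params(model = 2, c = 0.35, q = 0.3, seed = 21), 300)
  dd <- division_daughter_states(ens)
  expect_true(all(dd$state[dd$parent_state == "acinar"] == "acinar"))
})

test_that("larger differentiation probability shrinks clones", {
  p1 <- model_params(model = 1, c = 0.1, q = 0.5, seed = 31)
  p2 <- model_params(model = 1, c = 0.4, q = 0.5, seed = 32)
  s1 <- clone_sizes(simulate_ensemble(p1, 400), 120)
  s2 <- clone_sizes(simulate_ensemble(p2, 400), 120)
  expect_gt(mean(s1), mean(s2))
})

test_that("under Model 2 acinar commitment is impossible at the window start", {
  # f = 1 exactly at t_norm = 0: a differentiating daughter there must be
  # endocrine, whatever q
  for (q in c(0, 0.2, 0.9)) {
    expect_equal(endocrine_bias(2, q, 0), 1)
    set.seed(34)
    expect_false(any(assign_fate(1e4, c = 0.5,
                                 f = endocrine_bias(2, q, 0)) == "acinar"))
  }
  # and simulated daughters born in the first hours are overwhelmingly
  # endocrine among differentiated ones (f stays near 1 early on)
  ens <- simulate_ensemble(model_params(model = 2, c = 0.5, q = 0.05, seed = 33), 500)
  dd <- division_daughter_states(ens)
  early <- dd[dd$birth < 6 & dd$state != "progenitor", ]
  expect_gt(nrow(early), 20)
  expect_gt(mean(early$state == "endocrine"), 0.95)
})
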