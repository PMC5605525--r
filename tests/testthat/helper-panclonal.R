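# Shared fixtures and independent oracles, all built in code.

# A hand-built three-division lineage over a 120 h window:
#
#   1 (progenitor, divides at 10 h)
#   +-- 2 (progenitor, divides at 30 h)
#   |   +-- 4 (acinar, divides at 50 h)
#   |   |   +-- 6 (acinar, alive)        +-- 7 (acinar, alive)
#   |   +-- 5 (endocrine, alive from 30 h)
#   +-- 3 (endocrine, alive from 10 h)
hand_tree <- function() {
  cells <- data.frame(
    cell_id = 1:7,
    parent_id = c(NA, 1L, 1L, 2L, 2L, 4L, 4L),
    birth = c(0, 10, 10, 30, 30, 50, 50),
    cycle = c(10, 20, NA, 20, NA, 200, 300),
    state = factor(c("progenitor", "progenitor", "endocrine", "acinar",
                     "endocrine", "acinar", "acinar"),
                   levels = c("progenitor", "acinar", "endocrine")),
    n_div = c(0L, 1L, 1L, 2L, 2L, 3L, 3L)
  )
  structure(list(cells = cells, params = model_params(seed = 1)),
            class = "lineage_tree")
}

# Brute-force Delaunay edges by the empty-circumsphere definition: a
# tetrahedron belongs to the triangulation iff no other point lies strictly
# inside its circumsphere; edges are the vertex pairs of accepted tetrahedra.
brute_delaunay_edges <- function(xyz) {
  n <- nrow(xyz)
  edges <- NULL
  combs <- utils::combn(n, 4)
  for (k in seq_len(ncol(combs))) {
    v <- combs[, k]
    a <- xyz[v[1L], ]
    M <- rbind(xyz[v[2L], ] - a, xyz[v[3L], ] - a, xyz[v[4L], ] - a)
    if (abs(det(M)) < 1e-9) next
    x <- solve(M, 0.5 * rowSums(M^2))
    cc <- a + x
    r2 <- sum(x^2)
    others <- setdiff(seq_len(n), v)
    d2 <- colSums((t(xyz[others, , drop = FALSE]) - cc)^2)
    if (all(d2 > r2 * (1 - 1e-9))) edges <- rbind(edges, t(utils::combn(v, 2)))
  }
  if (is.null(edges)) return(NULL)
  e <- unique(cbind(pmin(edges[, 1L], edges[, 2L]),
                    pmax(edges[, 1L], edges[, 2L])))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

# Expected population size of one clone by numerical solution of the
# renewal equation: a standard cell divides after a full gamma cycle, the
# founder after a uniform fraction of one.
renewal_expected_size <- function(shape, scale, t_end, dt = 0.02) {
  tg <- seq(0, t_end, by = dt)
  n <- length(tg)
  f <- stats::dgamma(tg, shape, scale = scale)
  S <- stats::pgamma(tg, shape, scale = scale, lower.tail = FALSE)
  m <- numeric(n)
  m[1L] <- 1
  for (i in 2:n) {
    conv <- sum(m[i:1] * f[1:i]) - 0.5 * (m[i] * f[1L] + m[1L] * f[i])
    m[i] <- S[i] + 2 * dt * conv
  }
  # first-division offset U | T ~ Uniform(0, T): density g(u) = E[T^-1; T > u]
  g <- vapply(tg, function(u) {
    stats::integrate(function(s) stats::dgamma(s, shape, scale = scale) / s,
                     lower = max(u, 1e-9), upper = Inf)$value
  }, 1)
  G <- cumsum(g) * dt
  conv <- sum(m[n:1] * g[1:n]) * dt - 0.5 * dt * (m[n] * g[1L] + m[1L] * g[n])
  (1 - G[n]) + 2 * conv
}

# Daughter fates joined to their parents' states, for frequency checks.
division_daughter_states <- function(ensemble) {
  cells <- ensemble$cells
  key <- cells$clone * (max(cells$cell_id) + 1) + cells$cell_id
  pkey <- cells$clone * (max(cells$cell_id) + 1) + cells$parent_id
  parent_state <- cells$state[match(pkey, key)]
  data.frame(state = cells$state[!is.na(cells$parent_id)],
             parent_state = parent_state[!is.na(cells$parent_id)],
             birth = cells$birth[!is.na(cells$parent_id)])
}

rotate3 <- function(xyz, ax, ay, az, shift = c(0, 0, 0)) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  sweep(xyz %*% t(Rz %*% Ry %*% Rx), 2L, -shift)
}
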