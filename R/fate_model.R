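#' Endocrine fate bias f
#'
#' The probability, conditional on differentiating, that a newborn daughter
#' adopts the endocrine rather than the acinar fate. Model 1 uses a constant
#' bias `f = q`. Model 2 lets the bias vary over the tracing window,
#' `f(t) = q + 0.5 (1 - q) (1 + cos(2 pi t))` with `t` the normalised time
#' `(E - 9.5) / 5`: `f` equals 1 at E9.5 and E14.5 and dips to its minimum
#' `q` at E12, the stage at which NEUROG3+ endocrine precursors are rarest
#' and acinar commitment is therefore most likely.
#'
#' @param model 1 or 2 (see [model_params()]).
#' @param q Bias parameter in `[0, 1]`.
#' @param t_norm Normalised time in `[0, 1]`; vectorised. Values outside the
#'   unit interval are an error: the cosine form is defined on one period
#'   only and is never extrapolated, so callers must normalise embryonic time
#'   first.
#' @return Numeric vector of biases in `[q, 1]`.
#' @examples
#' endocrine_bias(1, q = 0.37, t_norm = 0.8) # constant: 0.37
#' endocrine_bias(2, q = 0.2, t_norm = 0)    # 1 at the window start
#' endocrine_bias(2, q = 0.2, t_norm = 0.5)  # minimum q at E12
#' @export
endocrine_bias <- function(model, q, t_norm) {
  model <- switch(as.character(model[1L]),
                  "1" = , "model1" = , "MODEL1" = 1L,
                  "2" = , "model2" = , "MODEL2" = 2L,
                  stop("`model` must be 1 or 2", call. = FALSE))
  stopifnot(is.numeric(q), length(q) == 1L, q >= 0, q <= 1,
            is.numeric(t_norm))
  if (any(!is.finite(t_norm)) || any(t_norm < 0) || any(t_norm > 1))
    stop("`t_norm` must lie in [0, 1]; normalise embryonic time as (E - 9.5) / 5",
         call. = FALSE)
  if (model == 1L) rep_len(q, length(t_norm))
  else q + 0.5 * (1 - q) * (1 + cos(2 * pi * t_norm))
}

#' Draw gamma-distributed cell-cycle lengths
#'
#' @param n Number of draws.
#' @param cycle A [gamma_cycle()] object.
#' @return `n` strictly positive cycle lengths in hours.
#' @examples
#' set.seed(1)
#' mean(draw_cycle_length(1e4, gamma_cycle())) # close to 13.5
#' @export
draw_cycle_length <- function(n, cycle = gamma_cycle()) {
  if (!inherits(cycle, "gamma_cycle"))
    stop("`cycle` must be a gamma_cycle object", call. = FALSE)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  stats::rgamma(n, shape = cycle$shape, scale = cycle$scale)
}

#' Assign fates to newborn daughter cells
#'
#' Each daughter independently remains a progenitor with probability
#' `1 - c`, becomes endocrine with probability `c * f`, and acinar with
#' probability `c * (1 - f)`. A single uniform deviate is consumed per
#' daughter.
#'
#' @param n Number of daughters.
#' @param c Differentiation probability in `[0, 1]`.
#' @param f Endocrine bias in `[0, 1]`; scalar or length `n` (one value per
#'   daughter, e.g. evaluated at each division time).
#' @return Character vector of states among
#'   `"progenitor"`, `"acinar"`, `"endocrine"`.
#' @examples
#' set.seed(1)
#' table(assign_fate(1000, c = 0.5, f = 0.3))
#' @export
assign_fate <- function(n, c, f) {
  stopifnot(is.numeric(c), length(c) == 1L, c >= 0, c <= 1,
            is.numeric(f), all(f >= 0), all(f <= 1),
            length(f) == 1L || length(f) == n)
  .STATES[.assign_fate_int(n, c, rep_len(f, n))]
}

.assign_fate_int <- function(n, c, f) {
  u <- stats::runif(n)
  s <- rep.int(.STATE_P, n)
  s[u >= 1 - c] <- .STATE_E
  s[u >= 1 - c + c * f] <- .STATE_A
  s
}

# Unique per-clone cell ids for a batch of daughters created in one
# generation; `next_id` holds the next free id per clone.
.per_clone_ids <- function(clones, next_id) {
  o <- order(clones)
  r <- rle(clones[o])
  ids <- integer(length(clones))
  ids[o] <- next_id[clones[o]] + (sequence(r$lengths) - 1L)
  ids
}

#' Simulate an ensemble of independent clones
#'
#' Runs the stochastic branching process for `n_clones` independent clones,
#' each founded by a single progenitor at the window start. The founder's
#' first division happens at an offset drawn uniformly in `[0, t_cc]`
#' (its cell-cycle phase at labelling is unknown); at every division two
#' daughters are created and independently fate-assigned with the endocrine
#' bias evaluated at the moment of division. Endocrine cells never divide;
#' acinar cells keep dividing (their proliferation is approximated by the
#' progenitor cycle distribution) and all their descendants stay acinar.
#' There is no cell death. A clone whose founder never divides inside the
#' window is a valid single-cell lineage.
#'
#' All clones are simulated from one R random stream, so a fixed
#' `params$seed` makes the whole ensemble bit-reproducible.
#'
#' @param params A [model_params()] object.
#' @param n_clones Number of independent clones; the reference protocol uses
#'   2500 per parameter set.
#' @return An object of class `clone_ensemble`: a list with `cells` (one row
#'   per cell ever created: `clone`, `cell_id`, `parent_id`, `birth`,
#'   `cycle`, `state`, `n_div`), `params`, and `n_clones`. `birth` is in
#'   hours since the window start; `cycle` is the founder's first-division
#'   offset for roots, the drawn cycle length for other replicating cells,
#'   and `NA` for endocrine cells, which never divide.
#' @seealso [simulate_clone()], [composition_at()], [lineage()]
#' @examples
#' ens <- simulate_ensemble(model_params(model = 2, c = 0.2, q = 0.1, seed = 1),
#'                          n_clones = 10)
#' table(ens$cells$state)
#' @export
simulate_ensemble <- function(params, n_clones = 2500) {
  stopifnot(inherits(params, "model_params"),
            is.numeric(n_clones), length(n_clones) == 1L, n_clones >= 1)
  n <- as.integer(n_clones)
  if (!is.null(params$seed)) set.seed(params$seed)

  hrs <- window_hours(params)
  off <- .norm_offset_h(params)
  span <- .norm_span_h()
  cyc <- params$cycle

  # founders
  t_cc <- stats::rgamma(n, shape = cyc$shape, scale = cyc$scale)
  first_div <- stats::runif(n) * t_cc

  col_clone <- list(seq_len(n))
  col_id <- list(rep.int(1L, n))
  col_par <- list(rep.int(NA_integer_, n))
  col_birth <- list(numeric(n))
  col_cycle <- list(first_div)
  col_state <- list(rep.int(.STATE_P, n))
  col_ndiv <- list(rep.int(0L, n))
  g <- 1L

  next_id <- rep.int(2L, n)

  keep <- first_div <= hrs
  a_clone <- seq_len(n)[keep]
  a_id <- rep.int(1L, n)[keep]
  a_div <- first_div[keep]
  a_state <- rep.int(.STATE_P, length(a_clone))
  a_ndiv <- rep.int(0L, length(a_clone))

  while (length(a_clone)) {
    m <- length(a_clone)
    d_clone <- rep(a_clone, each = 2L)
    d_par <- rep(a_id, each = 2L)
    d_birth <- rep(a_div, each = 2L)
    d_ndiv <- rep(a_ndiv, each = 2L) + 1L
    d_state <- rep.int(.STATE_A, 2L * m)   # acinar lineage is hereditary

    prog_par <- rep(a_state == .STATE_P, each = 2L)
    k <- sum(prog_par)
    if (k) {
      f <- endocrine_bias(params$model, params$q,
                          (off + d_birth[prog_par]) / span)
      d_state[prog_par] <- .assign_fate_int(k, params$c, f)
    }

    d_id <- .per_clone_ids(d_clone, next_id)
    next_id <- next_id + tabulate(d_clone, nbins = n)

    replicating <- d_state != .STATE_E
    d_cycle <- rep.int(NA_real_, 2L * m)
    nr <- sum(replicating)
    if (nr)
      d_cycle[replicating] <- stats::rgamma(nr, shape = cyc$shape,
                                            scale = cyc$scale)

    g <- g + 1L
    col_clone[[g]] <- d_clone
    col_id[[g]] <- d_id
    col_par[[g]] <- d_par
    col_birth[[g]] <- d_birth
    col_cycle[[g]] <- d_cycle
    col_state[[g]] <- d_state
    col_ndiv[[g]] <- d_ndiv

    nxt <- replicating & (d_birth + d_cycle) <= hrs
    a_clone <- d_clone[nxt]
    a_id <- d_id[nxt]
    a_div <- (d_birth + d_cycle)[nxt]
    a_state <- d_state[nxt]
    a_ndiv <- d_ndiv[nxt]
  }

  cells <- data.frame(
    clone = unlist(col_clone, use.names = FALSE),
    cell_id = unlist(col_id, use.names = FALSE),
    parent_id = unlist(col_par, use.names = FALSE),
    birth = unlist(col_birth, use.names = FALSE),
    cycle = unlist(col_cycle, use.names = FALSE),
    state = factor(.STATES[unlist(col_state, use.names = FALSE)],
                   levels = .STATES),
    n_div = unlist(col_ndiv, use.names = FALSE)
  )
  structure(list(cells = cells, params = params, n_clones = n),
            class = "clone_ensemble")
}

#' @export
print.clone_ensemble <- function(x, ...) {
  cat(sprintf("<clone_ensemble> %d clones, %d cells total (model %d, c = %g, q = %g)\n",
              x$n_clones, nrow(x$cells), x$params$model, x$params$c,
              x$params$q))
  invisible(x)
}

#' Simulate a single clone
#'
#' @inheritParams simulate_ensemble
#' @return An object of class `lineage_tree`: a list with `cells` (as in
#'   [simulate_ensemble()], without the `clone` column) and `params`.
#' @examples
#' tree <- simulate_clone(model_params(model = 1, c = 0.3, q = 0.4, seed = 7))
#' nrow(tree$cells)
#' @export
simulate_clone <- function(params) {
  lineage(simulate_ensemble(params, n_clones = 1L), 1L)
}

#' Extract one lineage tree from an ensemble
#'
#' @param ensemble A `clone_ensemble`.
#' @param i Clone index in `1:n_clones`.
#' @return A `lineage_tree`.
#' @export
lineage <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "clone_ensemble"),
            length(i) == 1L, i >= 1, i <= ensemble$n_clones)
  cells <- ensemble$cells[ensemble$cells$clone == i,
                          c("cell_id", "parent_id", "birth", "cycle",
                            "state", "n_div")]
  rownames(cells) <- NULL
  structure(list(cells = cells, params = ensemble$params),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  comp <- composition_at(x, window_hours(x$params))
  cat(sprintf("<lineage_tree> %d cells ever created; at window end: %d progenitor, %d acinar, %d endocrine\n",
              nrow(x$cells), comp[["progenitor"]], comp[["acinar"]],
              comp[["endocrine"]]))
  invisible(x)
}

# Which cells are alive at time t (hours since window start)? A cell is
# alive if it was born by t and has not yet divided: endocrine cells never
# divide, replicating cells divide at birth + cycle. At the exact division
# instant the parent is counted as divided and its daughters as alive.
.alive_at <- function(cells, t) {
  div_t <- cells$birth + cells$cycle
  cells$birth <= t & (is.na(div_t) | div_t > t)
}

#' Cell-state composition of living cells at a time point
#'
#' Counts the cells alive at `t` hours after the window start, split by fate
#' state. Counts always sum to the number of living cells.
#'
#' @param x A `lineage_tree` or `clone_ensemble`.
#' @param t Hours since the window start, within `[0, window length]`.
#' @return For a tree, a named integer vector
#'   `(progenitor, acinar, endocrine)`; for an ensemble, an
#'   `n_clones x 3` matrix with those columns.
#' @examples
#' tree <- simulate_clone(model_params(model = 2, c = 0.2, q = 0.1, seed = 2))
#' composition_at(tree, 0)    # always a single progenitor
#' composition_at(tree, 120)
#' @export
composition_at <- function(x, t) UseMethod("composition_at")

.check_t <- function(params, t) {
  hrs <- window_hours(params)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0 || t > hrs)
    stop(sprintf("`t` must lie in [0, %g] hours", hrs), call. = FALSE)
}

#' @export
composition_at.lineage_tree <- function(x, t) {
  .check_t(x$params, t)
  alive <- .alive_at(x$cells, t)
  tab <- tabulate(as.integer(x$cells$state[alive]), nbins = 3L)
  stats::setNames(tab, .STATES)
}

#' @export
composition_at.clone_ensemble <- function(x, t) {
  .check_t(x$params, t)
  alive <- .alive_at(x$cells, t)
  idx <- (x$cells$clone[alive] - 1L) * 3L + as.integer(x$cells$state[alive])
  m <- matrix(tabulate(idx, nbins = 3L * x$n_clones), ncol = 3L, byrow = TRUE)
  colnames(m) <- .STATES
  m
}

#' Number of living cells per clone at a time point
#'
#' @inheritParams composition_at
#' @return Integer vector of clone sizes.
#' @export
clone_sizes <- function(x, t) {
  if (inherits(x, "lineage_tree")) sum(composition_at(x, t))
  else rowSums(composition_at(x, t))
}
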