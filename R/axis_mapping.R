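#' Dorsal-pancreas length axis
#'
#' The 1D reference frame for label-retention mapping: the straight line
#' from the distal-most point of the dorsal epithelium to the proximal
#' landmark at the duodenal root. Projection operates on xy coordinates
#' only.
#'
#' @param distal,proximal Numeric `(x, y)` coordinates in micrometres; must
#'   be distinct.
#' @return An object of class `axis_frame` with elements `distal`,
#'   `proximal`, `length_um` and the unit direction `u`.
#' @export
axis_frame <- function(distal, proximal) {
  stopifnot(is.numeric(distal), length(distal) == 2L,
            is.numeric(proximal), length(proximal) == 2L,
            all(is.finite(c(distal, proximal))))
  d <- proximal - distal
  len <- sqrt(sum(d^2))
  if (len == 0) stop("landmarks must be distinct", call. = FALSE)
  structure(list(distal = as.numeric(distal), proximal = as.numeric(proximal),
                 length_um = len, u = d / len),
            class = "axis_frame")
}

#' Project cells onto the length axis
#'
#' Orthogonal projection of each xy point onto the landmark line. The axis
#' position is the signed distance of the foot point from the distal
#' landmark (positive toward the proximal landmark; positions outside
#' `[0, axis length]` are legal and reported unclamped), and the off-axis
#' distance is the perpendicular distance to the line.
#'
#' @param points Data frame with columns `cell_id`, `x_um`, `y_um`
#'   (additional columns ignored).
#' @param frame An [axis_frame()].
#' @return Data frame `cell_id`, `axis_position_um`, `off_axis_um`.
#' @examples
#' fr <- axis_frame(c(0, 0), c(10, 0))
#' project_points(data.frame(cell_id = 1, x_um = 3, y_um = 4), fr)
#' @export
project_points <- function(points, frame) {
  stopifnot(is.data.frame(points),
            all(c("cell_id", "x_um", "y_um") %in% names(points)),
            inherits(frame, "axis_frame"))
  dx <- points$x_um - frame$distal[1L]
  dy <- points$y_um - frame$distal[2L]
  pos <- dx * frame$u[1L] + dy * frame$u[2L]
  off <- abs(dx * (-frame$u[2L]) + dy * frame$u[1L])
  data.frame(cell_id = points$cell_id, axis_position_um = pos,
             off_axis_um = off)
}

#' Select the top label retainers
#'
#' The `ceiling(fraction * n)` cells with the highest values (e.g. the top
#' 10% GFP-retaining SOX9+ cells). Ties are broken by ascending `cell_id`
#' so the selection is deterministic.
#'
#' @param values Per-cell numeric values named by `cell_id` (unnamed values
#'   are assigned ids `1:n`).
#' @param fraction Fraction in `(0, 1]` (default 0.10).
#' @return Character vector of the selected `cell_id`s.
#' @examples
#' top_retainers(c(a = 5, b = 9, c = 9, d = 1), fraction = 0.5) # "b" "c"
#' @export
top_retainers <- function(values, fraction = 0.10) {
  stopifnot(is.numeric(values), length(values) >= 1L,
            is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction <= 1)
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  k <- ceiling(fraction * length(values))
  num <- suppressWarnings(as.numeric(ids))
  o <- if (anyNA(num)) order(-values, ids) else order(-values, num)
  ids[o][seq_len(k)]
}

#' 1D kernel density of axis positions
#'
#' Shares the gaussian-KDE contract of [kde_pdf()]; provided under its own
#' name because the axis analysis treats it as a distinct step.
#'
#' @param positions Axis positions in micrometres.
#' @param bandwidth Kernel standard deviation in micrometres.
#' @return A `kde_density`.
#' @export
density_1d <- function(positions, bandwidth) {
  kde_pdf(positions, bandwidth)
}

#' 2D kernel density on a grid
#'
#' Product-gaussian KDE of xy points evaluated on a rectangular grid
#' covering the data plus four bandwidths on every side; the grid integral
#' of the result is 1 up to the quadrature error.
#'
#' @param points Data frame with `x_um`, `y_um` columns (or a two-column
#'   matrix).
#' @param bandwidth Kernel standard deviation in micrometres (default
#'   30 um, an isotropic smoothing at roughly the scale of a few cell
#'   diameters).
#' @param n_grid Grid resolution per axis (default 80).
#' @return List with `x`, `y` (grid coordinates) and `z`
#'   (`n_grid x n_grid` density matrix, `z[i, j]` at `(x[i], y[j])`).
#' @export
density_2d <- function(points, bandwidth = 30, n_grid = 80) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x_um", "y_um") %in% names(points)))
    xy <- cbind(points$x_um, points$y_um)
  } else xy <- as.matrix(points)
  stopifnot(nrow(xy) >= 1L, is.numeric(bandwidth), bandwidth > 0)
  pad <- 4 * bandwidth
  gx <- seq(min(xy[, 1L]) - pad, max(xy[, 1L]) + pad, length.out = n_grid)
  gy <- seq(min(xy[, 2L]) - pad, max(xy[, 2L]) + pad, length.out = n_grid)
  kx <- outer(gx, xy[, 1L], function(g, s) stats::dnorm(g, s, bandwidth))
  ky <- outer(gy, xy[, 2L], function(g, s) stats::dnorm(g, s, bandwidth))
  z <- (kx %*% t(ky)) / nrow(xy)
  list(x = gx, y = gy, z = z)
}

#' Compare axis positions of small and large clones
#'
#' Splits clones into equal-count "small" and "large" groups at the size
#' median (with an odd clone count the median clone joins neither group,
#' keeping the groups equal) and compares the distribution of mean
#' projected clone positions with a rank-based (Wilcoxon rank-sum) test.
#'
#' @param cells Data frame with columns `clone_id`, `x_um`, `y_um`.
#' @param frame An [axis_frame()].
#' @param sizes Optional named vector of clone sizes; defaults to the
#'   number of cells per clone in `cells`.
#' @return A list of class `clone_position_comparison`: `clones` (per-clone
#'   size, group and mean axis position), `median_small`, `median_large`,
#'   `rank_statistic` (Mann-Whitney W, large vs small) and `p_value`.
#' @export
compare_clone_positions <- function(cells, frame, sizes = NULL) {
  stopifnot(is.data.frame(cells),
            all(c("clone_id", "x_um", "y_um") %in% names(cells)),
            inherits(frame, "axis_frame"))
  cells$cell_id <- seq_len(nrow(cells))
  proj <- project_points(cells, frame)
  pos <- tapply(proj$axis_position_um, cells$clone_id, mean)
  ids <- names(pos)
  if (is.null(sizes)) {
    sz <- as.integer(table(cells$clone_id)[ids])
  } else {
    sz <- as.numeric(sizes[ids])
    if (anyNA(sz)) stop("`sizes` missing for some clones", call. = FALSE)
  }
  n <- length(ids)
  if (n < 2L) stop("at least 2 clones are required", call. = FALSE)
  o <- order(sz, ids)
  half <- n %/% 2L
  group <- rep(NA_character_, n)
  group[o[seq_len(half)]] <- "small"
  group[o[seq.int(n - half + 1L, n)]] <- "large"
  small <- pos[!is.na(group) & group == "small"]
  large <- pos[!is.na(group) & group == "large"]
  wt <- stats::wilcox.test(large, small, exact = FALSE)
  structure(list(
    clones = data.frame(clone_id = ids, size = sz, group = group,
                        mean_axis_position_um = as.numeric(pos)),
    median_small = stats::median(small), median_large = stats::median(large),
    rank_statistic = unname(wt$statistic), p_value = wt$p.value),
    class = "clone_position_comparison")
}

#' @export
print.clone_position_comparison <- function(x, ...) {
  cat(sprintf("<clone_position_comparison> %d clones: median axis position %0.1f um (small) vs %0.1f um (large); W = %g, p = %.3g\n",
              nrow(x$clones), x$median_small, x$median_large,
              x$rank_statistic, x$p_value))
  invisible(x)
}
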