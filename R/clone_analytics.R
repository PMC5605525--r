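.POTENCY_LEVELS <- c("uni_ductal", "uni_endocrine", "uni_acinar",
                     "bi_ducto_endocrine", "bi_ducto_acinar",
                     "bi_acino_endocrine", "multipotent")

#' Build a clone observation table
#'
#' One row per clone with the marker-class counts scored at the harvest
#' stage: SOX9+ ductal/progenitor cells, PAX6+ endocrine cells and CPA1+
#' acinar cells, plus the anatomical location of the clone.
#'
#' @param clone_id Integer or character clone identifiers.
#' @param n_ductal,n_endocrine,n_acinar Non-negative counts (SOX9+, PAX6+,
#'   CPA1+ cells respectively); each clone must contain at least one cell.
#' @param location `"dorsal"`, `"ventral"` or `"unknown"`; recycled.
#' @return A data frame of class `clone_observations`.
#' @export
clone_observations <- function(clone_id, n_ductal, n_endocrine, n_acinar,
                               location = "unknown") {
  stopifnot(length(clone_id) == length(n_ductal),
            length(n_ductal) == length(n_endocrine),
            length(n_endocrine) == length(n_acinar))
  if (any(n_ductal < 0 | n_endocrine < 0 | n_acinar < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(n_ductal + n_endocrine + n_acinar == 0))
    stop("every clone must contain at least one cell", call. = FALSE)
  location <- rep_len(as.character(location), length(clone_id))
  if (!all(location %in% c("dorsal", "ventral", "unknown")))
    stop("`location` must be dorsal, ventral or unknown", call. = FALSE)
  structure(data.frame(clone_id = clone_id, n_ductal = as.integer(n_ductal),
                       n_endocrine = as.integer(n_endocrine),
                       n_acinar = as.integer(n_acinar), location = location),
            class = c("clone_observations", "data.frame"))
}

#' Classify clone potency
#'
#' The potency class of a clone is determined solely by which lineages are
#' present among its progeny: one of the three unipotent classes, three
#' bipotent classes, or multipotent when all three lineages are represented.
#' Scaling all counts by a positive factor never changes the class.
#'
#' @param clones A `clone_observations` data frame (or any data frame with
#'   `n_ductal`, `n_endocrine`, `n_acinar` columns).
#' @return Factor of potency classes, one per clone, with levels
#'   `uni_ductal`, `uni_endocrine`, `uni_acinar`, `bi_ducto_endocrine`,
#'   `bi_ducto_acinar`, `bi_acino_endocrine`, `multipotent`.
#' @examples
#' cl <- clone_observations(1:3, n_ductal = c(0, 1, 3),
#'                          n_endocrine = c(6, 0, 2), n_acinar = c(0, 0, 5))
#' classify_potency(cl)
#' @export
classify_potency <- function(clones) {
  stopifnot(all(c("n_ductal", "n_endocrine", "n_acinar") %in% names(clones)))
  d <- clones$n_ductal > 0
  e <- clones$n_endocrine > 0
  a <- clones$n_acinar > 0
  if (any(!d & !e & !a))
    stop("all-zero clone encountered", call. = FALSE)
  cls <- character(nrow(clones))
  cls[d & !e & !a] <- "uni_ductal"
  cls[!d & e & !a] <- "uni_endocrine"
  cls[!d & !e & a] <- "uni_acinar"
  cls[d & e & !a] <- "bi_ducto_endocrine"
  cls[d & !e & a] <- "bi_ducto_acinar"
  cls[!d & e & a] <- "bi_acino_endocrine"
  cls[d & e & a] <- "multipotent"
  factor(cls, levels = .POTENCY_LEVELS)
}

#' Labelling index
#'
#' Percentage of screened embryos/pancreata that contained a labelled clone,
#' reported to one decimal: e.g. 20 clones in 170 embryos gives 11.8%.
#'
#' @param n_clones Number of samples with a clone.
#' @param n_samples Number of samples screened; must be positive and at
#'   least `n_clones`.
#' @return Percentage rounded to one decimal.
#' @export
labelling_index <- function(n_clones, n_samples) {
  stopifnot(is.numeric(n_clones), is.numeric(n_samples))
  if (any(n_samples <= 0)) stop("`n_samples` must be positive", call. = FALSE)
  if (any(n_clones > n_samples))
    stop("`n_clones` cannot exceed `n_samples`", call. = FALSE)
  round(100 * n_clones / n_samples, 1)
}

#' Probability of double labelling
#'
#' The chance that two independent labelling events hit the same pancreatic
#' bud is approximated by the square of the labelling index: an index of
#' 0.118 gives 100 * 0.118^2 = 1.4%.
#'
#' @param index Labelling index as a fraction in `[0, 1]`.
#' @param digits Decimal places of the reported percentage (1 for the
#'   low-index experiments, 0 where whole percent is reported).
#' @return Percentage rounded to `digits`.
#' @export
double_label_probability <- function(index, digits = 1) {
  stopifnot(is.numeric(index), all(index >= 0), all(index <= 1))
  round(100 * index^2, digits)
}

#' Group labelled cells into clones by spatial proximity
#'
#' Implements the clone-membership rule used for short tracing periods:
#' labelled cells belong to the same clone when they are connected by a
#' chain of pairwise distances strictly below `max_dist` (single linkage;
#' 30 um by default, the estimated migratory range over one day).
#'
#' @param cells Data frame with columns `cell_id`, `x_um`, `y_um`, `z_um`.
#' @param max_dist Chaining distance in micrometres (strict `<`).
#' @return The input with a `clone` column appended; clones are numbered by
#'   their first cell in input order, so the partition is invariant to input
#'   ordering up to relabelling (and the labels themselves only depend on
#'   the order of first appearance).
#' @examples
#' cells <- data.frame(cell_id = 1:3, x_um = c(0, 20, 40), y_um = 0, z_um = 0)
#' merge_cells_into_clones(cells)$clone  # chain: one clone of three
#' @export
merge_cells_into_clones <- function(cells, max_dist = 30) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "x_um", "y_um", "z_um") %in% names(cells)),
            is.numeric(max_dist), max_dist > 0)
  n <- nrow(cells)
  if (n == 0L) {
    cells$clone <- integer(0)
    return(cells)
  }
  d <- as.matrix(stats::dist(cells[, c("x_um", "y_um", "z_um")]))
  adj <- d < max_dist
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  cells$clone <- as.integer(factor(memb, levels = unique(memb)))
  cells
}

#' Potency spectrum of a clone collection
#'
#' @param clones A `clone_observations` data frame.
#' @return Data frame with one row per potency class: `class`, `n` and
#'   `percent` (exact, summing to 100; round for reporting).
#' @examples
#' cl <- clone_observations(1:24, n_ductal = c(rep(1, 22), 0, 0),
#'                          n_endocrine = c(rep(1, 22), 0, 0),
#'                          n_acinar = c(rep(0, 22), 3, 5))
#' potency_spectrum(cl)  # 2/24 unipotent acinar ~ 8%
#' @export
potency_spectrum <- function(clones) {
  if (nrow(clones) == 0L) stop("no clones supplied", call. = FALSE)
  cls <- classify_potency(clones)
  tab <- table(cls)
  data.frame(class = factor(names(tab), levels = .POTENCY_LEVELS),
             n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(cls))
}

#' Plot-ready clone composition table
#'
#' Long-format stacked counts per clone, deterministically ordered by total
#' clone size (descending) with ties broken by ascending `clone_id`, ready
#' for a stacked-bar rendering of the clone-size/composition histograms.
#'
#' @param clones A `clone_observations` data frame.
#' @return Data frame with columns `rank`, `clone_id`, `total`, `marker`
#'   (`sox9`, `pax6`, `cpa1`) and `count`.
#' @export
composition_table <- function(clones) {
  if (nrow(clones) == 0L) stop("no clones supplied", call. = FALSE)
  total <- clones$n_ductal + clones$n_endocrine + clones$n_acinar
  o <- order(-total, clones$clone_id)
  n <- nrow(clones)
  data.frame(rank = rep(seq_len(n), times = 3L),
             clone_id = rep(clones$clone_id[o], times = 3L),
             total = rep(total[o], times = 3L),
             marker = rep(c("sox9", "pax6", "cpa1"), each = n),
             count = c(clones$n_ductal[o], clones$n_endocrine[o],
                       clones$n_acinar[o]))
}

#' High-expresser mask on 8-bit intensities
#'
#' Flags cells whose mean nuclear intensity exceeds a grey-value threshold
#' (strictly above; the reference rule for putative acinar progenitors is
#' PTF1A above 80 on 8-bit images).
#'
#' @param intensities Grey values in `[0, 255]`.
#' @param threshold Grey-value threshold (default 80).
#' @return Logical mask, `TRUE` where `intensity > threshold`.
#' @export
high_expresser_mask <- function(intensities, threshold = 80) {
  stopifnot(is.numeric(intensities), is.numeric(threshold),
            length(threshold) == 1L)
  if (any(!is.finite(intensities)) || any(intensities < 0) ||
      any(intensities > 255))
    stop("intensities must lie in [0, 255] (8-bit grey values)",
         call. = FALSE)
  intensities > threshold
}
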