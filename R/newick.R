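#' Export a lineage tree as annotated Newick text
#'
#' Serialises a simulated clone as a Newick string. Every node (internal and
#' leaf) carries a label `c<cell_id>|<state>|b<birth>` encoding the cell id,
#' fate state and birth time (hours since window start, 6 decimals), and a
#' branch length equal to the cell's lifetime inside the window: the cycle
#' length for cells that divide, and `window end - birth` for cells still
#' alive at the window end. Parsing with [parse_lineage()] and re-exporting
#' is byte-identical.
#'
#' @param tree A `lineage_tree`.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @examples
#' tree <- simulate_clone(model_params(model = 1, c = 1, q = 1, seed = 3))
#' export_lineage(tree)
#' @export
export_lineage <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "lineage_tree"))
  cells <- tree$cells
  if (nrow(cells) == 0L) stop("empty lineage", call. = FALSE)
  if (sum(is.na(cells$parent_id)) != 1L)
    stop("malformed tree: expected exactly one root", call. = FALSE)
  hrs <- window_hours(tree$params)
  div_t <- cells$birth + cells$cycle
  divides <- !is.na(div_t) & div_t <= hrs
  branch <- ifelse(divides, cells$cycle, hrs - cells$birth)
  kids <- split(seq_len(nrow(cells)), factor(cells$parent_id,
                                             levels = cells$cell_id))
  n_kids <- lengths(kids)[match(cells$cell_id, names(kids))]
  n_kids[is.na(n_kids)] <- 0L
  if (any(n_kids != 0L & n_kids != 2L))
    stop("malformed tree: every dividing cell must have exactly 2 children",
         call. = FALSE)
  lab <- sprintf("c%d|%s|b%.6f", cells$cell_id, as.character(cells$state),
                 cells$birth)
  root <- which(is.na(cells$parent_id))
  rec <- function(i) {
    ch <- kids[[as.character(cells$cell_id[i])]]
    core <- if (is.null(ch) || length(ch) == 0L) lab[i]
            else paste0("(", rec(ch[1L]), ",", rec(ch[2L]), ")", lab[i])
    sprintf("%s:%.6f", core, branch[i])
  }
  txt <- paste0(rec(root), ";")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Parse annotated Newick text back into a lineage tree
#'
#' Inverse of [export_lineage()]. Cell ids, states and birth times are
#' recovered from node labels; divisions-from-root are recomputed from the
#' topology. Leaf cells are assigned `cycle = NA` (their residual cycle
#' beyond the window is not serialised), which leaves re-export unchanged
#' because leaf branch lengths are window-end residuals by construction.
#'
#' @param text A Newick string produced by [export_lineage()] (or a file
#'   path containing one).
#' @param params Optional [model_params()] to attach; defaults to the
#'   package defaults with a window spanning the reconstructed tree.
#' @return A `lineage_tree`.
#' @export
parse_lineage <- function(text, params = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  df <- .newick_nodes(text)
  decode <- regmatches(df$label,
                       regexec("^c([0-9]+)\\|([a-z]+)\\|b([0-9.]+)$", df$label))
  bad <- vapply(decode, length, 1L) != 4L
  if (any(bad))
    stop("unrecognised node label(s): ", paste(df$label[bad], collapse = ", "),
         call. = FALSE)
  cell_id <- vapply(decode, function(m) as.integer(m[2L]), 1L)
  state <- vapply(decode, function(m) m[3L], "")
  if (!all(state %in% .STATES))
    stop("unknown fate state in labels", call. = FALSE)
  birth <- vapply(decode, function(m) as.numeric(m[4L]), 1)
  parent_id <- ifelse(is.na(df$parent), NA_integer_, cell_id[df$parent])
  is_leaf <- !(seq_len(nrow(df)) %in% df$parent)
  cycle <- ifelse(is_leaf, NA_real_, df$branch)

  # divisions from root via repeated parent lookup
  n_div <- integer(nrow(df))
  idx_of <- match(parent_id, cell_id)
  depth <- function(i) {
    d <- 0L
    while (!is.na(idx_of[i])) { i <- idx_of[i]; d <- d + 1L }
    d
  }
  n_div <- vapply(seq_len(nrow(df)), depth, 1L)

  if (is.null(params)) params <- model_params()
  cells <- data.frame(cell_id = cell_id, parent_id = parent_id,
                      birth = birth, cycle = cycle,
                      state = factor(state, levels = .STATES), n_div = n_div)
  cells <- cells[order(cells$n_div, cells$cell_id), ]
  rownames(cells) <- NULL
  structure(list(cells = cells, params = params), class = "lineage_tree")
}

# Minimal recursive-descent reader for the writer's own output: every node
# is labelled and carries a branch length, children come in pairs. Returns
# label/branch/parent-index per node. ape::read.tree is not used because it
# rejects the single-leaf trees that single-cell clones produce.
.newick_nodes <- function(text) {
  s <- sub(";\\s*$", "", trimws(text))
  pos <- 1L
  nchr <- nchar(s)
  labels <- character(0); branches <- numeric(0); parents <- integer(0)
  peek <- function() substr(s, pos, pos)
  read_node <- function(parent) {
    kids <- integer(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids <- c(kids, read_node(NA_integer_))  # parent patched below
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick near position ", pos, call. = FALSE)
      }
    }
    m <- regmatches(substr(s, pos, nchr),
                    regexpr("^[^(),:;]+:[0-9eE+.-]+", substr(s, pos, nchr)))
    if (length(m) == 0L)
      stop("malformed Newick: expected label:length at position ", pos,
           call. = FALSE)
    pos <<- pos + nchar(m)
    parts <- strsplit(m, ":", fixed = TRUE)[[1L]]
    labels <<- c(labels, parts[1L])
    branches <<- c(branches, as.numeric(parts[2L]))
    parents <<- c(parents, parent)
    me <- length(labels)
    if (length(kids)) parents[kids] <<- me
    me
  }
  read_node(NA_integer_)
  if (pos <= nchr) stop("trailing characters in Newick text", call. = FALSE)
  data.frame(label = labels, branch = branches, parent = parents)
}

#' Write a lineage tree (or ensemble) as a flat CSV
#'
#' Columns: `clone` (ensembles only), `cell_id`, `parent_id`, `birth_h`,
#' `cycle_h`, `state`, `n_div`. A provenance comment header records the
#' generating parameters.
#'
#' @param x A `lineage_tree` or `clone_ensemble`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_lineage_csv <- function(x, file) {
  stopifnot(inherits(x, c("lineage_tree", "clone_ensemble")))
  cells <- x$cells
  names(cells)[names(cells) == "birth"] <- "birth_h"
  names(cells)[names(cells) == "cycle"] <- "cycle_h"
  p <- x$params
  hdr <- sprintf("# panclonal lineage export: model=%d c=%g q=%g window=E%g-E%g shape=%g scale=%g seed=%s",
                 p$model, p$c, p$q, p$window_start, p$window_end,
                 p$cycle$shape, p$cycle$scale,
                 if (is.null(p$seed)) "NA" else p$seed)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(cells, con, row.names = FALSE)
  invisible(file)
}

#' Read a flat lineage CSV written by [write_lineage_csv()]
#'
#' @param file Path to the CSV.
#' @return A data frame of cell records.
#' @export
read_lineage_csv <- function(file) {
  df <- utils::read.csv(file, comment.char = "#")
  df$state <- factor(df$state, levels = .STATES)
  df
}
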