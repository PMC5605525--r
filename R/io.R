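#' Write a clone observation table as CSV
#'
#' Columns `clone_id,n_sox9,n_pax6,n_cpa1,location` (SOX9 = ductal, PAX6 =
#' endocrine, CPA1 = acinar), preceded by a provenance comment header.
#'
#' @param clones A [clone_observations()] data frame.
#' @param file Output path.
#' @param provenance Optional character string recorded in the header.
#' @return `file`, invisibly.
#' @export
write_clones_csv <- function(clones, file, provenance = NULL) {
  stopifnot(is.data.frame(clones))
  df <- data.frame(clone_id = clones$clone_id, n_sox9 = clones$n_ductal,
                   n_pax6 = clones$n_endocrine, n_cpa1 = clones$n_acinar,
                   location = clones$location)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# panclonal clone observations",
                    if (!is.null(provenance)) paste0(": ", provenance)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' Read a clone observation CSV
#'
#' @param file Path to a CSV written by [write_clones_csv()].
#' @return A [clone_observations()] data frame.
#' @export
read_clones_csv <- function(file) {
  df <- utils::read.csv(file, comment.char = "#")
  clone_observations(df$clone_id, df$n_sox9, df$n_pax6, df$n_cpa1,
                     df$location)
}

#' Write / read per-pancreas fraction tables
#'
#' Long-format CSV with columns `timepoint_e,lineage,frac_percent` (plus
#' `group` when present), the grouped observed dataset of the likelihood
#' scan.
#'
#' @param fractions Data frame from [grouped_population_fractions()] or
#'   [synth_bulk_fractions()].
#' @param file Path.
#' @param provenance Optional provenance string for the header comment.
#' @return `file` (write) or the data frame with columns `timepoint`,
#'   `lineage`, `frac_percent` (read).
#' @export
write_fractions_csv <- function(fractions, file, provenance = NULL) {
  stopifnot(all(c("timepoint", "lineage", "frac_percent") %in%
                  names(fractions)))
  df <- fractions
  names(df)[names(df) == "timepoint"] <- "timepoint_e"
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# panclonal lineage fractions",
                    if (!is.null(provenance)) paste0(": ", provenance)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_fractions_csv
#' @export
read_fractions_csv <- function(file) {
  df <- utils::read.csv(file, comment.char = "#")
  names(df)[names(df) == "timepoint_e"] <- "timepoint"
  df
}

#' Write a likelihood surface as long-format CSV
#'
#' @param surface A `likelihood_surface` from [scan_likelihood()].
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_surface_csv <- function(surface, file) {
  stopifnot(inherits(surface, "likelihood_surface"))
  utils::write.csv(as.data.frame(surface), file, row.names = FALSE)
  invisible(file)
}

#' Read a likelihood surface CSV
#'
#' @param file Path written by [write_surface_csv()].
#' @return A `likelihood_surface`.
#' @export
read_surface_csv <- function(file) {
  df <- utils::read.csv(file)
  attr(df, "c_grid") <- sort(unique(df$c))
  attr(df, "q_grid") <- sort(unique(df$q))
  class(df) <- c("likelihood_surface", "data.frame")
  df
}

#' Write a model comparison as JSON
#'
#' @param comparison A `model_comparison` from [compare_models()].
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_comparison_json <- function(comparison, file) {
  stopifnot(inherits(comparison, "model_comparison"))
  obj <- list(convention = comparison$convention,
              preferred_model = comparison$preferred,
              models = comparison$table)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
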