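#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a duplication verdict
#'
#' One row per leaf character (family, position) with its parsimony length,
#' retention index and permutation p-value.
#'
#' @param x A `duplication_verdict`.
#' @param ... Unused.
#' @return A tibble with columns `character`, `fitch_length`,
#'   `retention_index`, `p_value`.
#' @export
tidy.duplication_verdict <- function(x, ...) {
  tibble(
    character = c("family", "position"),
    fitch_length = c(x$L_family, x$L_position),
    retention_index = c(x$RI_family, x$RI_position),
    p_value = c(x$p_family, x$p_position)
  )
}

#' One-row summary of a duplication verdict
#' @param x A `duplication_verdict`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.duplication_verdict <- function(x, ...) {
  tibble(
    verdict = x$verdict,
    ri_difference = x$RI_family - x$RI_position,
    delta = x$delta,
    n_leaves = x$n_leaves,
    n_outgroup = x$n_outgroup,
    n_perm = x$n_perm
  )
}

#' One-row summary of a pipeline report
#' @param x An `mcr_pipeline_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mcr_pipeline_report <- function(x, ...) {
  tibble(
    n_proteins = x$n_proteins,
    n_hits = x$n_hits,
    n_partial = x$n_partial,
    n_columns_before = x$n_columns_before,
    n_columns_after = x$n_columns_after,
    verdict = x$verdict$verdict,
    truth_model = x$truth_model,
    seed = x$seed
  )
}

#' Tidy a pipeline report
#'
#' The family-by-position hit table of the run.
#'
#' @param x An `mcr_pipeline_report`.
#' @param ... Unused.
#' @return A tibble with `family`, `position_index`, `n_hits`.
#' @export
tidy.mcr_pipeline_report <- function(x, ...) {
  x$family_position_table
}
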