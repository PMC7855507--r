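# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Venn count object
#'
#' @param x a `sciq_venn` from [venn_counts()].
#' @param ... unused.
#' @return tibble with columns `region`, `n` and a final `union` row.
#' @export
tidy.sciq_venn <- function(x, ...) {
  dplyr::bind_rows(x$regions,
                   tibble::tibble(region = "union", n = x$union))
}

#' One-row summary of a Venn count object
#' @param x a `sciq_venn`.
#' @param ... unused.
#' @return one-row tibble: `n_sets`, `union`.
#' @export
glance.sciq_venn <- function(x, ...) {
  n_sets <- sum(!grepl("&", x$regions$region))
  tibble::tibble(n_sets = n_sets, union = x$union)
}

#' Tidy a clustering result into its leaf ordering
#' @param x a `sciq_clustering` from [cluster_profiles()].
#' @param ... unused.
#' @return tibble: `block`, `gene_id`, `position`.
#' @export
tidy.sciq_clustering <- function(x, ...) x$ordering

#' Tidy a profile table into long form
#' @param x a `sciq_profile_table` from [build_profile_table()].
#' @param ... unused.
#' @return tibble: `gene_id`, `group`, `mean_fpkm`, `scaled`,
#'   `injury_flag`, `development_flag`.
#' @export
tidy.sciq_profile_table <- function(x, ...) {
  longify <- function(df, value) {
    tidyr::pivot_longer(df, -"gene_id", names_to = "group",
                        values_to = value)
  }
  longify(x$means, "mean_fpkm") |>
    dplyr::left_join(longify(x$scaled, "scaled"),
                     by = c("gene_id", "group")) |>
    dplyr::left_join(longify(x$injury_flags, "injury_flag"),
                     by = c("gene_id", "group")) |>
    dplyr::left_join(
      dplyr::rename(x$development_flags, development_flag = "flag"),
      by = "gene_id")
}

#' Per-scorer summary of a DE suite result
#'
#' @param x a `sciq_de` tibble from [run_de_suite()].
#' @param t [thresholds()] used to count significant genes.
#' @param ... unused.
#' @return tibble: one row per `method_id` with gene counts and the number
#'   of genes passing the thresholds, split by direction.
#' @export
glance.sciq_de <- function(x, t = thresholds(), ...) {
  threshold_filter(x, t) |>
    dplyr::group_by(.data$method_id) |>
    dplyr::summarise(n_significant = dplyr::n(),
                     n_up = sum(.data$sign > 0),
                     n_down = sum(.data$sign < 0),
                     .groups = "drop") |>
    dplyr::right_join(
      dplyr::summarise(dplyr::group_by(x, .data$method_id),
                       n_genes = dplyr::n(), .groups = "drop"),
      by = "method_id") |>
    dplyr::mutate(dplyr::across(c("n_significant", "n_up", "n_down"),
                                ~ dplyr::coalesce(.x, 0L)))
}
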