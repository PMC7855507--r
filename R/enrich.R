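# Category overrepresentation of consensus gene sets by binomial test with
# Bonferroni correction, and per-category fold-change table extraction.

#' Construct a validated annotation map
#'
#' Validates a two-column category-to-gene table against a gene universe and
#' (by default) collects genes lacking any category into a synthetic
#' `"unclassified"` category, giving the drop rule of
#' [significant_categories()] a concrete referent.
#'
#' @param annotation tibble with columns `category_id`, `gene_id`.
#' @param universe character vector: the full reference gene list (all genes
#'   in the genome annotation).
#' @param add_unclassified logical; add the synthetic `"unclassified"`
#'   category (default TRUE).
#' @return tibble of class `sciq_annotation` with the universe attached as
#'   attribute `"universe"`.
#' @export
annotation_map <- function(annotation, universe, add_unclassified = TRUE) {
  if (!all(c("category_id", "gene_id") %in% names(annotation))) {
    stop("annotation must have columns category_id and gene_id", call. = FALSE)
  }
  universe <- unique(as.character(universe))
  bad <- setdiff(annotation$gene_id, universe)
  if (length(bad) > 0) {
    stop("annotation contains genes outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  sizes <- table(annotation$category_id)
  if (any(sizes == 0)) stop("empty categories are not allowed", call. = FALSE)
  out <- dplyr::distinct(tibble::as_tibble(annotation),
                         .data$category_id, .data$gene_id)
  if (add_unclassified) {
    orphan <- setdiff(universe, out$gene_id)
    if (length(orphan) > 0) {
      out <- dplyr::bind_rows(
        out, tibble::tibble(category_id = "unclassified", gene_id = orphan))
    }
  }
  attr(out, "universe") <- universe
  class(out) <- c("sciq_annotation", class(out))
  out
}

#' Binomial over/underrepresentation test per category
#'
#' For each category with `K` of the `N` universe genes, and `k` of the `n`
#' study genes, computes the binomial tails for `X ~ Binomial(n, K/N)`:
#' `p_over = P(X >= k)` and `p_under = P(X <= k)`. The reported p-value is
#' the smaller tail and `direction` names it (`"over"`/`"under"`); no
#' two-sided doubling is applied, since the two directions are reported
#' separately. Study genes outside the universe are dropped with a warning.
#'
#' @param study gene set (character vector or tibble with `gene_id`).
#' @param annotation an [annotation_map()] (or plain category/gene tibble
#'   with a `universe` argument).
#' @param universe optional; overrides the annotation's attached universe.
#' @return tibble of class `sciq_overrep`: `category_id`, `observed`,
#'   `category_size`, `study_size`, `expected`, `fold_enrichment`,
#'   `direction`, `pvalue`, `p_over`, `p_under`.
#' @export
binomial_overrep <- function(study, annotation, universe = NULL) {
  study <- as_gene_set(study)
  if (is.null(universe)) universe <- attr(annotation, "universe")
  if (is.null(universe)) {
    stop("no gene universe: pass `universe` or use annotation_map()",
         call. = FALSE)
  }
  if (length(study) == 0) stop("study set is empty", call. = FALSE)
  outside <- setdiff(study, universe)
  if (length(outside) > 0) {
    warning("dropping ", length(outside), " study gene(s) outside the universe",
            call. = FALSE)
    study <- intersect(study, universe)
    if (length(study) == 0) stop("study set is empty after dropping unknown genes",
                                 call. = FALSE)
  }
  n <- length(study)
  N <- length(universe)
  annotation |>
    dplyr::group_by(.data$category_id) |>
    dplyr::summarise(
      observed = sum(.data$gene_id %in% study),
      category_size = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      study_size = n,
      expected = .data$study_size * .data$category_size / N,
      fold_enrichment = .data$observed / .data$expected,
      p_over = stats::pbinom(.data$observed - 1, .data$study_size,
                             .data$category_size / N, lower.tail = FALSE),
      p_under = stats::pbinom(.data$observed, .data$study_size,
                              .data$category_size / N),
      direction = ifelse(.data$p_over <= .data$p_under, "over", "under"),
      pvalue = pmin(.data$p_over, .data$p_under)
    ) |>
    dplyr::select("category_id", "observed", "category_size", "study_size",
                  "expected", "fold_enrichment", "direction", "pvalue",
                  "p_over", "p_under") |>
    structure(class = c("sciq_overrep", class(tibble::tibble())))
}

#' Bonferroni correction
#'
#' `p_bonf = min(1, pvalue * m)` where `m` is the number of hypotheses
#' (default: the number of categories actually tested in this run; the value
#' used is recorded in the `m` column).
#'
#' @param results tibble from [binomial_overrep()].
#' @param m number of tests; must be at least the number of rows.
#' @return `results` with columns `p_bonf` and `m` added.
#' @export
bonferroni_adjust <- function(results, m = nrow(results)) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (m < nrow(results)) {
    stop("m (", m, ") is smaller than the number of tested categories (",
         nrow(results), ")", call. = FALSE)
  }
  results$p_bonf <- pmin(1, results$pvalue * m)
  results$m <- m
  results
}

#' Significant categories with -log10 transform
#'
#' Retains categories with Bonferroni-corrected p at or below `alpha`
#' (boundary inclusive), drops the `"unclassified"` category when flagged,
#' and annotates `neg_log10_p_bonf` for plotting.
#'
#' @param results tibble from [bonferroni_adjust()].
#' @param alpha significance level (default 0.05).
#' @param drop_unclassified logical (default TRUE).
#' @return filtered tibble with `neg_log10_p_bonf` added, sorted by p.
#' @export
significant_categories <- function(results, alpha = 0.05,
                                   drop_unclassified = TRUE) {
  if (!"p_bonf" %in% names(results)) {
    stop("results must have p_bonf; run bonferroni_adjust() first", call. = FALSE)
  }
  out <- dplyr::filter(results, .data$p_bonf <= alpha)
  if (drop_unclassified) {
    out <- dplyr::filter(out, .data$category_id != "unclassified")
  }
  out |>
    dplyr::mutate(neg_log10_p_bonf = -log10(.data$p_bonf)) |>
    dplyr::arrange(.data$p_bonf, .data$category_id)
}

#' Per-category gene-by-time-point fold-change table
#'
#' Extracts the genes of one annotation category that appear in any of the
#' supplied consensus sets and tabulates their consensus log2 fold change per
#' time-point (absent calls are `NA`). When an `ages` mapping from time-point
#' label to injury age is supplied, genes whose calls all fall in a single
#' age are flagged in `unique_age`.
#'
#' @param category one category id.
#' @param annotation an [annotation_map()] or category/gene tibble.
#' @param consensus_sets named list of consensus tibbles ([vote()] output);
#'   names are the time-point column labels.
#' @param ages optional named character: label -> age group.
#' @return tibble: `gene_id`, one log2FC column per label, `unique_age`.
#' @export
extract_category_genes <- function(category, annotation, consensus_sets,
                                   ages = NULL) {
  members <- annotation$gene_id[annotation$category_id == category]
  if (length(members) == 0) {
    stop("unknown or empty category: ", category, call. = FALSE)
  }
  if (is.null(names(consensus_sets))) {
    stop("consensus_sets must be a named list (time-point labels)", call. = FALSE)
  }
  long <- purrr::imap(consensus_sets, function(cs, lab) {
    tibble::tibble(gene_id = cs$gene_id, label = lab,
                   avg_log2fc = cs$avg_log2fc)
  }) |> dplyr::bind_rows()
  long <- dplyr::filter(long, .data$gene_id %in% members)
  if (nrow(long) == 0) {
    return(tibble::tibble(gene_id = character(0)))
  }
  wide <- tidyr::pivot_wider(long, names_from = "label",
                             values_from = "avg_log2fc")
  # keep column order = input label order
  wide <- wide[, c("gene_id", intersect(names(consensus_sets), names(wide)))]
  if (!is.null(ages)) {
    wide$unique_age <- vapply(wide$gene_id, function(g) {
      labs <- long$label[long$gene_id == g]
      a <- unique(ages[labs])
      if (length(a) == 1) unname(a) else NA_character_
    }, character(1))
  }
  dplyr::arrange(wide, .data$gene_id)
}
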