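# Consensus voting across DE scorers, and the Venn set algebra across
# time-points and injury ages.

#' Significance thresholds for consensus calling
#'
#' @param padj_max maximum FDR-adjusted p-value (default 0.05).
#' @param abs_log2fc_min minimum |log2 fold change| (default 1, i.e. 2-fold).
#' @param inclusive logical; `TRUE` (default) retains genes at exactly the
#'   boundary (`padj <= padj_max`, `|log2FC| >= abs_log2fc_min`), `FALSE`
#'   uses strict inequalities.
#' @return list of class `sciq_thresholds`.
#' @export
thresholds <- function(padj_max = 0.05, abs_log2fc_min = 1, inclusive = TRUE) {
  if (!is.finite(padj_max) || padj_max <= 0 || padj_max > 1) {
    stop("padj_max must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(abs_log2fc_min) || abs_log2fc_min < 0) {
    stop("abs_log2fc_min must be >= 0", call. = FALSE)
  }
  structure(list(padj_max = padj_max, abs_log2fc_min = abs_log2fc_min,
                 inclusive = isTRUE(inclusive)),
            class = "sciq_thresholds")
}

#' Filter a DE result table at significance thresholds
#'
#' Retains genes passing both the adjusted-p and the fold-change-magnitude
#' cut, in either direction.
#'
#' @param de_result tibble with columns `gene_id`, `log2FC`, `padj` (and
#'   optionally `method_id`, preserved).
#' @param t a [thresholds()] object.
#' @return tibble with columns (`method_id`,) `gene_id`, `sign`, `log2FC`.
#' @export
threshold_filter <- function(de_result, t = thresholds()) {
  stopifnot(inherits(t, "sciq_thresholds"))
  if (!"padj" %in% names(de_result) || anyNA(de_result$padj)) {
    stop("de_result must have a populated padj column", call. = FALSE)
  }
  keep <- if (t$inclusive) {
    de_result$padj <= t$padj_max & abs(de_result$log2FC) >= t$abs_log2fc_min
  } else {
    de_result$padj < t$padj_max & abs(de_result$log2FC) > t$abs_log2fc_min
  }
  out <- de_result[keep, , drop = FALSE]
  cols <- intersect(c("method_id", "gene_id", "log2FC"), names(out))
  out <- dplyr::mutate(out[, cols], sign = sign(.data$log2FC))
  tibble::as_tibble(out)
}

#' Consensus vote across DE scorers
#'
#' A gene enters the consensus set when it passes the thresholds in at least
#' `min_support` scorers with concordant direction. The consensus fold change
#' is the mean of the log2 fold changes over the supporting (significant)
#' scorers only — values from scorers where the gene did not pass are
#' ignored. Genes whose supporting scorers disagree in sign are excluded
#' with a warning.
#'
#' @param filtered tibble from [threshold_filter()] applied to each scorer,
#'   stacked, with a `method_id` column — or a list of per-scorer filtered
#'   tibbles (names used as method ids when the column is absent).
#' @param min_support minimum number of supporting scorers (default 2).
#' @param label optional free-text label (e.g. `"P7SCI+1d"`) attached to the
#'   result.
#' @return tibble of class `sciq_consensus` with columns `gene_id`,
#'   `support`, `avg_log2fc`, `direction` (+1/-1) and, when given, `label`.
#' @export
vote <- function(filtered, min_support = 2, label = NULL) {
  if (is.list(filtered) && !is.data.frame(filtered)) {
    ids <- names(filtered)
    if (is.null(ids)) ids <- paste0("scorer", seq_along(filtered))
    filtered <- dplyr::bind_rows(purrr::map2(filtered, ids, function(df, id) {
      if (!"method_id" %in% names(df)) df$method_id <- id
      df
    }))
  }
  if (!all(c("method_id", "gene_id", "log2FC") %in% names(filtered))) {
    stop("filtered must have columns method_id, gene_id, log2FC", call. = FALSE)
  }
  if (min_support < 1) stop("min_support must be >= 1", call. = FALSE)

  per_gene <- filtered |>
    dplyr::distinct(.data$method_id, .data$gene_id, .keep_all = TRUE) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      support = dplyr::n(),
      avg_log2fc = mean(.data$log2FC),
      concordant = length(unique(sign(.data$log2FC))) == 1,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$support >= min_support)

  conflicted <- per_gene$gene_id[!per_gene$concordant]
  if (length(conflicted) > 0) {
    warning("excluding ", length(conflicted),
            " gene(s) with sign conflict among supporting scorers: ",
            paste(utils::head(conflicted, 5), collapse = ", "), call. = FALSE)
  }
  out <- per_gene |>
    dplyr::filter(.data$concordant) |>
    dplyr::mutate(direction = sign(.data$avg_log2fc)) |>
    dplyr::select("gene_id", "support", "avg_log2fc", "direction") |>
    dplyr::arrange(.data$gene_id)
  if (!is.null(label)) out$label <- label
  class(out) <- c("sciq_consensus", class(out))
  out
}

#' Venn region counts for 2-3 gene sets
#'
#' Exact cardinalities of every exclusive region of the Venn diagram, plus
#' the union size (which equals the sum of the region counts).
#'
#' @param sets named list of 2-3 gene sets (character vectors, or tibbles
#'   with a `gene_id` column such as [vote()] output).
#' @return list of class `sciq_venn` with elements `regions` (tibble:
#'   `region`, `n`) and `union` (integer).
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2 || length(sets) > 3) {
    stop("venn_counts takes 2 or 3 sets", call. = FALSE)
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_along(sets)]
  }
  sets <- purrr::map(sets, as_gene_set)
  all_genes <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  if (length(all_genes) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  # enumerate all non-empty membership patterns, including empty regions
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)
  }))
  counts <- vapply(combos, function(p) sum(pattern == p), integer(1))
  structure(
    list(regions = tibble::tibble(region = combos, n = unname(counts)),
         union = length(all_genes)),
    class = "sciq_venn"
  )
}

#' Percentage of one gene set shared with another
#'
#' `100 * |a intersect b| / |a|`, rounded to the nearest integer percent.
#'
#' @param a,b gene sets (character vectors or tibbles with `gene_id`);
#'   `a` must be nonempty.
#' @return integer percentage.
#' @export
shared_fraction <- function(a, b) {
  a <- as_gene_set(a)
  b <- as_gene_set(b)
  if (length(a) == 0) stop("set 'a' is empty", call. = FALSE)
  round(100 * length(intersect(a, b)) / length(a))
}

#' Genes unique to one collection of consensus sets
#'
#' Set difference `union(a) \ union(b)`: each argument may be a single gene
#' set or a list of per-time-point sets whose union is taken first (the
#' cross-age subtraction of gene lists).
#'
#' @param a,b gene sets, tibbles with `gene_id`, or lists thereof.
#' @return sorted character vector of gene ids.
#' @export
unique_genes <- function(a, b) {
  unionize <- function(x) {
    if (is.list(x) && !is.data.frame(x)) {
      unique(unlist(purrr::map(x, as_gene_set)))
    } else as_gene_set(x)
  }
  sort(setdiff(unionize(a), unionize(b)))
}

#' Build labelled gene sets of given sizes
#'
#' Constructs two synthetic identifier sets with prescribed cardinalities and
#' intersection size, so printed Venn counts can be pushed through the same
#' set algebra as real gene lists.
#'
#' @param n_a,n_b,n_ab sizes of set A, set B and their intersection.
#' @param labels names for the two sets.
#' @return named list of two character vectors.
#' @export
sets_from_counts <- function(n_a, n_b, n_ab, labels = c("A", "B")) {
  stopifnot(n_ab <= n_a, n_ab <= n_b, n_ab >= 0)
  shared <- sprintf("shared_%d", seq_len(n_ab))
  a_only <- sprintf("a_only_%d", seq_len(n_a - n_ab))
  b_only <- sprintf("b_only_%d", seq_len(n_b - n_ab))
  out <- list(c(shared, a_only), c(shared, b_only))
  names(out) <- labels
  out
}
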