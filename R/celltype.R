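# Cell-type-association analysis: map gene ids onto a multi-cell-type
# reference transcriptome, filter background, express each gene as a
# percentage of its summed expression across cell types, cluster within
# time-point blocks, and rank top unique genes.

celltype_cols <- function(df, exclude = c("gene_id", "reference_id", "label",
                                          "timepoint", "group")) {
  cols <- setdiff(names(df), exclude)
  num <- cols[vapply(df[cols], is.numeric, logical(1))]
  if (length(num) < 2) {
    stop("expected at least 2 numeric cell-type columns", call. = FALSE)
  }
  num
}

#' Map gene ids onto a cell-type reference
#'
#' Joins a gene set to the reference expression table through an id map.
#' Genes with no mapping, or mapping to a reference id absent from the
#' table, are dropped and reported (attribute `"dropped"`). A source id
#' mapping to several reference rows is resolved to the row with the larger
#' total expression; such genes are recorded in attribute `"duplicates"`.
#'
#' @param genes gene set (character vector or tibble with `gene_id`).
#' @param reference tibble: `reference_id` + one expression column per cell
#'   type (FPKM scale).
#' @param id_map tibble with columns `gene_id`, `reference_id`.
#' @return tibble: `gene_id`, `reference_id`, cell-type expression columns;
#'   attributes `dropped` and `duplicates` hold the affected source ids.
#' @export
map_ids <- function(genes, reference, id_map) {
  genes <- as_gene_set(genes)
  if (!is.data.frame(id_map) || nrow(id_map) == 0) {
    stop("id_map is empty", call. = FALSE)
  }
  ct <- celltype_cols(reference)
  ref_tot <- tibble::tibble(
    reference_id = reference$reference_id,
    .total = rowSums(reference[, ct])
  )
  hits <- id_map |>
    dplyr::filter(.data$gene_id %in% genes,
                  .data$reference_id %in% reference$reference_id) |>
    dplyr::left_join(ref_tot, by = "reference_id")

  dup_ids <- unique(hits$gene_id[duplicated(hits$gene_id)])
  if (length(dup_ids) > 0) {
    message("resolved ", length(dup_ids),
            " gene(s) with multiple reference rows by maximum total expression")
    hits <- hits |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::arrange(dplyr::desc(.data$.total), .data$reference_id,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  dropped <- sort(setdiff(genes, hits$gene_id))
  out <- hits |>
    dplyr::select("gene_id", "reference_id") |>
    dplyr::left_join(reference[, c("reference_id", ct)], by = "reference_id") |>
    dplyr::arrange(.data$gene_id)
  attr(out, "dropped") <- dropped
  attr(out, "duplicates") <- sort(dup_ids)
  out
}

#' Background expression filter
#'
#' Retains a gene only when its expression rises above the background level
#' in at least one cell type — i.e. the maximum across cell types is
#' strictly greater than `threshold` (0.1 FPKM by default; a maximum of
#' exactly 0.1 does not pass).
#'
#' @param mapped tibble from [map_ids()] (gene rows with cell-type columns).
#' @param threshold background expression level (default 0.1).
#' @return filtered tibble; excluded gene ids in attribute `"excluded"`.
#' @export
background_filter <- function(mapped, threshold = 0.1) {
  ct <- celltype_cols(mapped)
  mx <- do.call(pmax, mapped[ct])
  out <- mapped[mx > threshold, , drop = FALSE]
  attr(out, "excluded") <- sort(mapped$gene_id[mx <= threshold])
  attr(out, "dropped") <- attr(mapped, "dropped")
  out
}

#' Percentage-of-sum cell-type profiles
#'
#' Rescales each gene's cell-type expression to percentages of its summed
#' expression across all cell types; every row sums to 100 (within 1e-9).
#'
#' @param mapped tibble of background-filtered genes with cell-type columns.
#' @return tibble of class `sciq_profiles`: `gene_id` + one percentage
#'   column per cell type.
#' @export
percentage_profile <- function(mapped) {
  ct <- celltype_cols(mapped)
  tot <- rowSums(mapped[ct])
  if (any(tot <= 0)) {
    stop("zero summed expression for gene(s): ",
         paste(utils::head(mapped$gene_id[tot <= 0], 5), collapse = ", "),
         " (apply background_filter first)", call. = FALSE)
  }
  out <- mapped[, c("gene_id", ct)]
  out[ct] <- 100 * out[ct] / tot
  class(out) <- c("sciq_profiles", class(tibble::tibble()))
  out
}

# Deterministic leaf order for an hclust tree: at every merge, the subtree
# containing the lexicographically smallest label goes left.
ordered_leaves <- function(hc) {
  n <- length(hc$labels)
  rec <- function(node) {
    if (node < 0) return(hc$labels[-node])
    left <- rec(hc$merge[node, 1])
    right <- rec(hc$merge[node, 2])
    if (min(left) <= min(right)) c(left, right) else c(right, left)
  }
  rec(nrow(hc$merge))
}

#' Hierarchically cluster profiles within time-point blocks
#'
#' Within each block, genes are clustered agglomeratively on their percentage
#' profiles with distance `1 - Pearson correlation` and average linkage
#' (both configurable). Leaf order is made deterministic: at every merge the
#' subtree containing the lexicographically smallest gene id goes left.
#' Blocks with a single profile pass through; empty blocks are skipped with
#' a message.
#'
#' @param profiles tibble from [percentage_profile()], optionally with a
#'   grouping column.
#' @param group name of the block column (e.g. `"timepoint"`); `NULL`
#'   clusters all rows as one block.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return list of class `sciq_clustering`: `ordering` (tibble: block,
#'   `gene_id`, `position`) and `trees` (named list of `hclust` objects;
#'   `NULL` for single-gene blocks).
#' @export
cluster_profiles <- function(profiles, group = NULL,
                             distance = c("correlation", "euclidean"),
                             linkage = "average") {
  distance <- match.arg(distance)
  blocks <- if (is.null(group)) {
    list(all = profiles)
  } else {
    split(profiles, profiles[[group]])
  }
  trees <- list()
  ordering <- purrr::imap(blocks, function(df, block) {
    if (nrow(df) == 0) {
      message("skipping empty block: ", block)
      return(NULL)
    }
    ct <- celltype_cols(df)
    if (nrow(df) == 1) {
      trees[[block]] <<- NULL
      return(tibble::tibble(block = block, gene_id = df$gene_id, position = 1L))
    }
    m <- as.matrix(df[, ct])
    rownames(m) <- df$gene_id
    d <- if (distance == "correlation") {
      stats::as.dist(1 - stats::cor(t(m)))
    } else {
      stats::dist(m)
    }
    hc <- stats::hclust(d, method = linkage)
    hc$labels <- df$gene_id
    trees[[block]] <<- hc
    leaves <- ordered_leaves(hc)
    tibble::tibble(block = block, gene_id = leaves,
                   position = seq_along(leaves))
  }) |> dplyr::bind_rows()
  structure(list(ordering = ordering, trees = trees),
            class = "sciq_clustering")
}

#' Top regulated genes, up and down
#'
#' Ranks a gene set by consensus log2 fold change and returns the `n`
#' strongest upregulations and the `n` strongest downregulations. Short
#' lists are returned whole when fewer than `n` genes qualify; ties are
#' broken lexicographically by gene id.
#'
#' @param genes tibble with columns `gene_id`, `avg_log2fc` (e.g. [vote()]
#'   output restricted to a unique set).
#' @param n list length per direction (default 10).
#' @return tibble: `direction` (`"up"`/`"down"`), `rank`, `gene_id`,
#'   `avg_log2fc`.
#' @export
top_unique <- function(genes, n = 10) {
  stopifnot(all(c("gene_id", "avg_log2fc") %in% names(genes)))
  up <- genes |>
    dplyr::filter(.data$avg_log2fc > 0) |>
    dplyr::arrange(dplyr::desc(.data$avg_log2fc), .data$gene_id) |>
    utils::head(n)
  down <- genes |>
    dplyr::filter(.data$avg_log2fc < 0) |>
    dplyr::arrange(.data$avg_log2fc, .data$gene_id) |>
    utils::head(n)
  dplyr::bind_rows(
    dplyr::mutate(up, direction = "up", rank = dplyr::row_number()),
    dplyr::mutate(down, direction = "down", rank = dplyr::row_number())
  ) |>
    dplyr::select("direction", "rank", "gene_id", "avg_log2fc")
}
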