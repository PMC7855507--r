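#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator into a single validated
#' object. The generator emulates a two-group bulk RNA-seq comparison
#' (injured vs age-matched control spinal cord) with negative-binomial counts,
#' per-sample depth variation, a planted fraction of differentially expressed
#' genes at a fixed |log2 fold change|, a seven-cell-type reference
#' transcriptome with planted marker genes, and a gene-category annotation
#' with planted enriched categories — all with recorded ground truth so every
#' downstream stage can be scored.
#'
#' @param n_genes number of genes to simulate.
#' @param n_replicates_per_group biological replicates per group (default 4).
#' @param mean_log_expression natural-log location of the log-normal gene-mean
#'   distribution; the default 4 puts the median gene at ~55 expected counts
#'   per sample.
#' @param dispersion negative-binomial dispersion shared by all genes
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param library_size_cv coefficient of variation of the multiplicative
#'   per-sample depth factors (log-normal, mean 1).
#' @param fraction_de fraction of genes planted as differentially expressed.
#' @param lfc_magnitude planted |log2 fold change| for DE genes; the sign is
#'   split approximately evenly between up- and down-regulation.
#' @param n_cell_types number of cell types in the synthetic reference
#'   (default 7, the CNS panel: astrocytes, neurons, endothelial cells,
#'   microglia, OPCs, newly formed and myelinating oligodendrocytes).
#' @param marker_fraction fraction of genes planted as single-cell-type
#'   markers in the reference.
#' @param below_background_fraction fraction of (non-marker) genes whose
#'   reference expression is kept below the 0.1 FPKM background level in
#'   every cell type.
#' @param unmapped_fraction fraction of genes deliberately left out of the
#'   source-to-reference id map.
#' @param n_categories number of annotation categories.
#' @param n_enriched_categories how many categories are planted as enriched
#'   for DE genes.
#' @param enriched_category_fold factor (>= 1) by which the DE rate inside a
#'   planted category exceeds the global DE rate.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output from every `simulate_*()` function.
#'
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 5000,
                              n_replicates_per_group = 4,
                              mean_log_expression = 4,
                              dispersion = 0.1,
                              library_size_cv = 0.2,
                              fraction_de = 0.05,
                              lfc_magnitude = 2,
                              n_cell_types = 7,
                              marker_fraction = 0.3,
                              below_background_fraction = 0.05,
                              unmapped_fraction = 0.05,
                              n_categories = 50,
                              n_enriched_categories = 2,
                              enriched_category_fold = 5,
                              seed = 1L) {
  check_count <- function(x, field) {
    if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
      stop("invalid config field '", field, "': must be a positive integer",
           call. = FALSE)
    }
  }
  check_prop <- function(x, field) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
      stop("invalid config field '", field, "': must be in [0, 1]", call. = FALSE)
    }
  }
  check_nonneg <- function(x, field) {
    if (length(x) != 1 || !is.finite(x) || x < 0) {
      stop("invalid config field '", field, "': must be nonnegative", call. = FALSE)
    }
  }
  check_count(n_genes, "n_genes")
  check_count(n_replicates_per_group, "n_replicates_per_group")
  check_count(n_cell_types, "n_cell_types")
  check_count(n_categories, "n_categories")
  check_count(n_enriched_categories, "n_enriched_categories")
  check_prop(fraction_de, "fraction_de")
  check_prop(marker_fraction, "marker_fraction")
  check_prop(below_background_fraction, "below_background_fraction")
  check_prop(unmapped_fraction, "unmapped_fraction")
  check_nonneg(dispersion, "dispersion")
  check_nonneg(library_size_cv, "library_size_cv")
  if (!is.finite(lfc_magnitude) || lfc_magnitude <= 0) {
    stop("invalid config field 'lfc_magnitude': must be positive", call. = FALSE)
  }
  if (!is.finite(enriched_category_fold) || enriched_category_fold < 1) {
    stop("invalid config field 'enriched_category_fold': must be >= 1",
         call. = FALSE)
  }
  if (!is.finite(mean_log_expression)) {
    stop("invalid config field 'mean_log_expression': must be finite",
         call. = FALSE)
  }
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed)) {
    stop("invalid config field 'seed': must be an integer", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_replicates_per_group = as.integer(n_replicates_per_group),
    mean_log_expression = mean_log_expression,
    dispersion = dispersion,
    library_size_cv = library_size_cv,
    fraction_de = fraction_de,
    lfc_magnitude = lfc_magnitude,
    n_cell_types = as.integer(n_cell_types),
    marker_fraction = marker_fraction,
    below_background_fraction = below_background_fraction,
    unmapped_fraction = unmapped_fraction,
    n_categories = as.integer(n_categories),
    n_enriched_categories = as.integer(n_enriched_categories),
    enriched_category_fold = enriched_category_fold,
    seed = as.integer(seed)
  ), class = "sim_config")
}

gene_ids_for <- function(n) sprintf("g%05d", seq_len(n))

celltype_names <- function(k) {
  canonical <- c("astrocytes", "neurons", "endothelial", "microglia",
                 "OPCs", "newly_formed_oligodendrocytes",
                 "myelinating_oligodendrocytes")
  if (k == length(canonical)) canonical else sprintf("celltype_%02d", seq_len(k))
}

#' Simulate a two-group RNA-seq count matrix with planted differential expression
#'
#' Gene means are drawn log-normal (location `mean_log_expression`, scale 1);
#' per-sample depth factors are log-normal with coefficient of variation
#' `library_size_cv`; counts are negative-binomial draws with mean
#' `mu_g * s_j * 2^(lfc_g)` in the injured group (Poisson when dispersion is
#' 0). A `fraction_de` subset of genes carries a planted log2 fold change of
#' fixed magnitude and approximately even sign split. Gene lengths (log-normal
#' around 2 kb) are generated alongside so FPKM-based scoring is drivable
#' end-to-end.
#'
#' @param config a [simulation_config()].
#' @param gene_means optional vector of expected counts per gene at unit
#'   depth, overriding the log-normal draw (recycled to `n_genes`).
#'
#' @return A list with elements
#'   `counts` (tibble: gene_id + one column per sample),
#'   `metadata` (tibble: sample, group),
#'   `lengths` (tibble: gene_id, length in bp),
#'   `truth` (tibble: gene_id, is_de, true_lfc).
#' @export
simulate_counts <- function(config, gene_means = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    nrep <- config$n_replicates_per_group
    ids <- gene_ids_for(n)

    mu <- if (is.null(gene_means)) {
      stats::rlnorm(n, meanlog = config$mean_log_expression, sdlog = 1)
    } else rep_len(gene_means, n)

    n_de <- round(config$fraction_de * n)
    de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
    signs <- numeric(n)
    if (n_de > 0) {
      half <- rep(c(1, -1), length.out = n_de)
      signs[de_idx] <- sample(half)
    }
    true_lfc <- signs * config$lfc_magnitude

    samples <- c(sprintf("injured_%d", seq_len(nrep)),
                 sprintf("control_%d", seq_len(nrep)))
    group <- rep(c("injured", "control"), each = nrep)

    cv <- config$library_size_cv
    sdlog <- sqrt(log(1 + cv^2))
    size_factor <- stats::rlnorm(2 * nrep, meanlog = -sdlog^2 / 2, sdlog = sdlog)

    mu_mat <- outer(mu, size_factor) *
      2^(true_lfc %o% as.numeric(group == "injured"))
    cnt <- if (config$dispersion > 0) {
      matrix(stats::rnbinom(n * 2 * nrep, mu = mu_mat, size = 1 / config$dispersion),
             nrow = n)
    } else {
      matrix(stats::rpois(n * 2 * nrep, lambda = mu_mat), nrow = n)
    }
    colnames(cnt) <- samples

    lengths <- pmax(200L, round(stats::rlnorm(n, meanlog = log(2000), sdlog = 0.5)))

    list(
      counts = dplyr::bind_cols(tibble::tibble(gene_id = ids),
                                tibble::as_tibble(cnt)),
      metadata = tibble::tibble(sample = samples, group = group),
      lengths = tibble::tibble(gene_id = ids, length = as.integer(lengths)),
      truth = tibble::tibble(gene_id = ids, is_de = signs != 0,
                             true_lfc = true_lfc)
    )
  })
}

#' Simulate a cell-type reference transcriptome with planted markers
#'
#' Builds an FPKM-scale expression table over `n_cell_types` cell types.
#' Planted marker genes carry at least 90% of their expression in one cell
#' type; non-markers are roughly uniform across types; a
#' `below_background_fraction` subset of non-marker genes is kept below the
#' 0.1 FPKM background level in every cell type. An id map from source gene
#' ids to reference ids is generated with an `unmapped_fraction` of genes
#' deliberately missing, exercising the exclusion rules of the cell-type
#' association stage.
#'
#' @param config a [simulation_config()].
#'
#' @return A list with elements
#'   `reference` (tibble: reference_id + one FPKM column per cell type),
#'   `id_map` (tibble: gene_id, reference_id),
#'   `truth` (tibble: gene_id, marker_celltype, below_background, mapped).
#' @export
simulate_celltype_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cell_types < 2) {
    stop("invalid config field 'n_cell_types': need at least 2 cell types",
         call. = FALSE)
  }
  withr::with_seed(config$seed + 1L, {
    n <- config$n_genes
    k <- config$n_cell_types
    ids <- gene_ids_for(n)
    types <- celltype_names(k)

    n_marker <- floor(config$marker_fraction * n)
    marker_idx <- if (n_marker > 0) sort(sample.int(n, n_marker)) else integer(0)
    marker_type <- rep(NA_character_, n)
    marker_type[marker_idx] <- sample(types, n_marker, replace = TRUE)

    non_marker <- setdiff(seq_len(n), marker_idx)
    n_low <- min(length(non_marker), floor(config$below_background_fraction * n))
    low_idx <- if (n_low > 0) sort(sample(non_marker, n_low)) else integer(0)

    scale <- stats::rlnorm(n, meanlog = 2, sdlog = 1)
    expr <- matrix(0, nrow = n, ncol = k, dimnames = list(NULL, types))
    for (i in seq_len(n)) {
      if (!is.na(marker_type[i])) {
        w <- rep(0.05 / (k - 1), k)
        w[match(marker_type[i], types)] <- 0.95
      } else {
        w <- stats::rgamma(k, shape = 20)
        w <- w / sum(w)
      }
      expr[i, ] <- w * scale[i]
    }
    if (n_low > 0) {
      expr[low_idx, ] <- matrix(stats::runif(n_low * k, 0, 0.08),
                                nrow = n_low)
    }

    n_unmapped <- floor(config$unmapped_fraction * n)
    unmapped_idx <- if (n_unmapped > 0) sort(sample.int(n, n_unmapped)) else integer(0)
    mapped <- !(seq_len(n) %in% unmapped_idx)
    ref_ids <- sprintf("ref%05d", seq_len(n))

    list(
      reference = dplyr::bind_cols(
        tibble::tibble(reference_id = ref_ids),
        tibble::as_tibble(expr)
      ),
      id_map = tibble::tibble(gene_id = ids[mapped],
                              reference_id = ref_ids[mapped]),
      truth = tibble::tibble(
        gene_id = ids,
        marker_celltype = marker_type,
        below_background = seq_len(n) %in% low_idx,
        mapped = mapped
      )
    )
  })
}

#' Simulate a gene-category annotation with planted enrichment
#'
#' Assigns genes to `n_categories` categories of varied size (30-300 genes,
#' the scale of reduced-ontology biological-process terms).
#' The first `n_enriched_categories` categories are planted so that their DE
#' member rate is `enriched_category_fold` times the global DE rate recorded
#' in `truth`; all other categories sample genes uniformly.
#'
#' @param config a [simulation_config()].
#' @param truth the `truth` tibble from [simulate_counts()] (needs `is_de`).
#'
#' @return A list with elements
#'   `annotation` (tibble: category_id, gene_id),
#'   `enriched_categories` (character),
#'   `universe` (character, all gene ids).
#' @export
simulate_annotation <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("gene_id", "is_de") %in% names(truth))) {
    stop("truth must have columns gene_id and is_de", call. = FALSE)
  }
  if (config$enriched_category_fold < 1) {
    stop("invalid config field 'enriched_category_fold': must be >= 1",
         call. = FALSE)
  }
  withr::with_seed(config$seed + 2L, {
    ids <- truth$gene_id
    de_ids <- ids[truth$is_de]
    bg_ids <- ids[!truth$is_de]
    global_rate <- length(de_ids) / length(ids)

    n_cat <- config$n_categories
    n_enr <- min(config$n_enriched_categories, n_cat)
    cat_ids <- sprintf("cat%03d", seq_len(n_cat))
    sizes <- sample(30:300, n_cat, replace = TRUE)
    if (any(sizes < 1)) stop("empty categories are not allowed", call. = FALSE)

    member <- vector("list", n_cat)
    for (i in seq_len(n_cat)) {
      m <- sizes[i]
      if (i <= n_enr && length(de_ids) > 0) {
        rate <- min(1, config$enriched_category_fold * global_rate)
        k_de <- min(length(de_ids), round(m * rate))
        member[[i]] <- c(sample(de_ids, k_de),
                         sample(bg_ids, m - k_de))
      } else {
        member[[i]] <- sample(ids, m)
      }
    }
    annotation <- tibble::tibble(
      category_id = rep(cat_ids, lengths(member)),
      gene_id = unlist(member, use.names = FALSE)
    )
    list(
      annotation = annotation,
      enriched_categories = if (n_enr > 0 && length(de_ids) > 0)
        cat_ids[seq_len(n_enr)] else character(0),
      universe = ids
    )
  })
}
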