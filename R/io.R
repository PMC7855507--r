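# TSV readers/writers and the end-to-end pipeline driver. All tabular
# exchange is TSV with required headers so outputs stay diffable.

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample ids with a gene-id first column. Cells
#' must be nonnegative whole numbers; violations are reported with their
#' gene/sample position, and duplicate gene ids are rejected.
#'
#' @param path TSV file path.
#' @return tibble: `gene_id` + one integer column per sample.
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    !!rlang::sym("gene_id") := readr::col_character()
  ))
  if (names(df)[1] != "gene_id") {
    names(df)[1] <- "gene_id"
  }
  m <- counts_to_matrix(df, what = basename(path))
  assert_integer_counts(m, what = basename(path))
  df[-1] <- lapply(df[-1], as.integer)
  df
}

#' Read sample metadata (sample, group, ...) from TSV
#' @param path TSV file path with at least columns `sample`, `group`.
#' @return tibble.
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample", "group") %in% names(df))) {
    stop(basename(path), " must have columns 'sample' and 'group'", call. = FALSE)
  }
  df
}

#' Read a gene length table from TSV
#' @param path TSV with columns `gene_id`, `length`.
#' @return tibble.
#' @export
read_gene_lengths <- function(path) {
  df <- readr::read_tsv(path, col_types = "ci")
  if (!all(c("gene_id", "length") %in% names(df))) {
    stop(basename(path), " must have columns 'gene_id' and 'length'", call. = FALSE)
  }
  if (any(df$length <= 0)) stop("gene lengths must be positive", call. = FALSE)
  df
}

#' Read a category-to-gene annotation from 2-column TSV
#' @param path TSV with columns `category_id`, `gene_id`.
#' @return tibble.
#' @export
read_annotation <- function(path) {
  readr::read_tsv(path, col_types = "cc")
}

#' Read a cell-type reference expression table from TSV
#' @param path TSV with `reference_id` first column, one numeric column per
#'   cell type.
#' @return tibble.
#' @export
read_celltype_reference <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    !!rlang::sym("reference_id") := readr::col_character()
  ))
  if (names(df)[1] != "reference_id") names(df)[1] <- "reference_id"
  df
}

#' Read a source-to-reference id map from TSV
#' @param path TSV with columns `gene_id`, `reference_id`.
#' @return tibble.
#' @export
read_id_map <- function(path) {
  readr::read_tsv(path, col_types = "cc")
}

#' Pipeline configuration
#'
#' Collects the options of a full synthetic-data pipeline run.
#'
#' @param sim a [simulation_config()] driving the synthetic inputs.
#' @param out_dir output directory (created if absent).
#' @param t significance [thresholds()].
#' @param min_support consensus votes required (default 2).
#' @param alpha Bonferroni significance level for categories (default 0.05).
#' @param background cell-type background expression level (default 0.1).
#' @param n_candidates how many planted DE genes to carry into the
#'   candidate-profile stage (default 20).
#' @return list of class `sciq_run_config`.
#' @export
pipeline_config <- function(sim = simulation_config(), out_dir,
                            t = thresholds(), min_support = 2, alpha = 0.05,
                            background = 0.1, n_candidates = 20) {
  stopifnot(inherits(sim, "sim_config"), inherits(t, "sciq_thresholds"))
  structure(list(sim = sim, out_dir = out_dir, thresholds = t,
                 min_support = min_support, alpha = alpha,
                 background = background, n_candidates = n_candidates),
            class = "sciq_run_config")
}

write_stage <- function(df, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(df, path)
  path
}

#' Run the full synthetic-data analysis pipeline
#'
#' Chains simulate, DE scoring, consensus voting, category
#' overrepresentation, cell-type association and the candidate profile
#' table, writing every stage output as TSV plus a JSON run manifest with
#' per-file checksums. Reruns with the same configuration and seed
#' reproduce byte-identical TSV outputs (the manifest differs only in its
#' timestamps).
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sciq_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  files <- character(0)
  stage <- "simulate"
  result <- tryCatch({
    sim <- simulate_counts(config$sim)
    ref <- simulate_celltype_reference(config$sim)
    ann <- simulate_annotation(config$sim, sim$truth)
    files <- c(files,
               write_stage(sim$counts, config$out_dir, "counts.tsv"),
               write_stage(sim$metadata, config$out_dir, "metadata.tsv"),
               write_stage(sim$lengths, config$out_dir, "gene_lengths.tsv"),
               write_stage(sim$truth, config$out_dir, "truth.tsv"),
               write_stage(ref$reference, config$out_dir, "celltype_reference.tsv"),
               write_stage(ref$id_map, config$out_dir, "id_map.tsv"),
               write_stage(ann$annotation, config$out_dir, "annotation.tsv"))

    stage <- "de"
    de <- run_de_suite(sim$counts, sim$metadata, sim$lengths)
    files <- c(files, write_stage(de, config$out_dir, "de_results.tsv"))

    stage <- "consensus"
    filtered <- threshold_filter(de, config$thresholds)
    consensus <- withCallingHandlers(
      vote(filtered, min_support = config$min_support, label = "synthetic"),
      warning = function(w) {
        note("consensus: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    files <- c(files, write_stage(consensus, config$out_dir, "consensus.tsv"))

    stage <- "enrich"
    amap <- annotation_map(ann$annotation, ann$universe)
    overrep <- if (nrow(consensus) > 0) {
      binomial_overrep(consensus, amap) |>
        bonferroni_adjust() |>
        significant_categories(alpha = config$alpha)
    } else {
      note("enrich: empty consensus set, stage skipped")
      tibble::tibble()
    }
    files <- c(files, write_stage(overrep, config$out_dir, "enriched_categories.tsv"))

    stage <- "celltype"
    mapped <- map_ids(consensus, ref$reference, ref$id_map)
    note("celltype: ", length(attr(mapped, "dropped")), " unmapped gene(s) excluded")
    kept <- background_filter(mapped, threshold = config$background)
    note("celltype: ", length(attr(kept, "excluded")),
         " sub-background gene(s) excluded")
    profiles <- if (nrow(kept) > 0) percentage_profile(kept) else tibble::tibble()
    files <- c(files, write_stage(profiles, config$out_dir, "celltype_profiles.tsv"))

    stage <- "profiles"
    fpkm <- fpkm_matrix(sim$counts, sim$lengths)
    candidates <- utils::head(sim$truth$gene_id[sim$truth$is_de],
                              config$n_candidates)
    if (length(candidates) == 0) {
      candidates <- utils::head(sim$truth$gene_id, config$n_candidates)
    }
    ptab <- build_profile_table(candidates, fpkm, sim$metadata,
                                injury_calls = list(injured = consensus))
    files <- c(files,
               write_stage(ptab$means, config$out_dir, "profile_means.tsv"),
               write_stage(ptab$scaled, config$out_dir, "profile_scaled.tsv"),
               write_stage(ptab$injury_flags, config$out_dir, "profile_flags.tsv"))
    TRUE
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    tool = paste0("sciquorum ", as.character(utils::packageVersion("sciquorum"))),
    seed = config$sim$seed,
    config = unclass(config$sim),
    thresholds = unclass(config$thresholds),
    min_support = config$min_support,
    alpha = config$alpha,
    background = config$background,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    warnings = warnings_log,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
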