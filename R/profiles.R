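# Candidate-gene expression profile tables: group-mean FPKM for a supplied
# candidate list, row-relative scaling, and significance flags for injury
# and development contrasts.

#' Min-max scale a row of expression values
#'
#' Rescales to \[0, 1\] by the row's range; constant rows map to 0.5
#' everywhere so the heatmap stays well-defined. Invariant under positive
#' affine transforms of the row.
#'
#' @param values numeric vector.
#' @param method `"minmax"` (default) or `"zscore"` (standardised; constant
#'   rows again map to a flat 0.5... see Details).
#' @return numeric vector, same length.
#' @export
row_relative <- function(values, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (length(values) == 0) stop("row is empty", call. = FALSE)
  rng <- range(values)
  if (method == "minmax") {
    if (rng[1] == rng[2]) return(rep(0.5, length(values)))
    (values - rng[1]) / (rng[2] - rng[1])
  } else {
    s <- stats::sd(values)
    if (s == 0) return(rep(0.5, length(values)))
    (values - mean(values)) / s
  }
}

#' Candidate-gene expression profile table
#'
#' Builds the expression table behind a candidate-gene heatmap: group-mean
#' FPKM per candidate, row-relative scaled values, a per-cell injury
#' significance flag (the gene has a consensus DE call for that injured
#' group), and a per-gene development flag (a consensus call in the
#' control-vs-control contrast). Candidates absent from the FPKM table are
#' reported, not fatal.
#'
#' @param candidates character vector of gene ids (the user-supplied list).
#' @param fpkm tibble: `gene_id` + one FPKM column per sample.
#' @param metadata tibble: `sample`, `group` (group labels become the table
#'   columns).
#' @param injury_calls named list of consensus tibbles ([vote()] output);
#'   each name must be one of the group labels (the injured group whose
#'   cells the flag marks).
#' @param development_calls optional consensus tibble for the
#'   control-vs-control (developmental) contrast.
#' @param method row scaling passed to [row_relative()].
#' @return list of class `sciq_profile_table`: `means` (tibble gene x
#'   group), `scaled` (same shape, row-relative), `injury_flags` (logical
#'   tibble, same shape), `development_flags` (tibble: gene_id, flag),
#'   `missing` (character).
#' @export
build_profile_table <- function(candidates, fpkm, metadata, injury_calls,
                                development_calls = NULL,
                                method = "minmax") {
  if (length(candidates) == 0) stop("candidate list is empty", call. = FALSE)
  m <- counts_to_matrix(fpkm, what = "fpkm")
  grp <- groups_for(m, metadata)
  missing <- sort(setdiff(candidates, rownames(m)))
  if (length(missing) > 0) {
    message(length(missing), " candidate gene(s) not present in the FPKM table: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  present <- candidates[candidates %in% rownames(m)]
  if (length(present) == 0) stop("no candidate gene found in the FPKM table",
                                 call. = FALSE)

  groups <- unique(grp)
  means <- vapply(groups, function(g) {
    rowMeans(m[present, grp == g, drop = FALSE])
  }, numeric(length(present)))
  means <- matrix(means, nrow = length(present),
                  dimnames = list(present, groups))
  scaled <- t(apply(means, 1, row_relative, method = method))
  dimnames(scaled) <- dimnames(means)

  bad <- setdiff(names(injury_calls), groups)
  if (length(bad) > 0) {
    stop("injury_calls labels not among group labels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  flags <- matrix(FALSE, nrow = length(present), ncol = length(groups),
                  dimnames = list(present, groups))
  for (lab in names(injury_calls)) {
    flags[, lab] <- present %in% injury_calls[[lab]]$gene_id
  }
  dev_flag <- if (is.null(development_calls)) {
    rep(FALSE, length(present))
  } else {
    present %in% development_calls$gene_id
  }

  as_tbl <- function(x) {
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(x)),
                     tibble::as_tibble(x))
  }
  structure(list(
    means = as_tbl(means),
    scaled = as_tbl(scaled),
    injury_flags = as_tbl(flags),
    development_flags = tibble::tibble(gene_id = present, flag = dev_flag),
    missing = missing
  ), class = "sciq_profile_table")
}
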