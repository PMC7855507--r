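# Internal helpers shared across modules.

# Convert a wide counts tibble (gene_id + one column per sample) to an
# integer matrix with gene rownames. Validates shape, uniqueness and
# integrality; `what` names the offending object in error messages.
counts_to_matrix <- function(counts, what = "counts") {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    stop(what, " must be a data frame with a gene_id column and >= 1 sample column",
         call. = FALSE)
  }
  gene_col <- names(counts)[1]
  ids <- as.character(counts[[gene_col]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene identifiers in ", what, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(what, " contains non-numeric cells", call. = FALSE)
  if (any(m < 0)) stop(what, " contains negative values", call. = FALSE)
  rownames(m) <- ids
  m
}

# Check that counts are whole numbers (FPKM-derived pseudo-counts are rounded
# before they get here).
assert_integer_counts <- function(m, what = "counts") {
  off <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(off) > 0) {
    stop(what, " must be whole numbers; first offending cell at gene '",
         rownames(m)[off[1, 1]], "', sample '", colnames(m)[off[1, 2]], "'",
         call. = FALSE)
  }
  invisible(m)
}

# Align a per-sample metadata table to the columns of a count matrix and
# return the group label vector in column order.
groups_for <- function(m, metadata) {
  if (!all(c("sample", "group") %in% names(metadata))) {
    stop("metadata must have columns 'sample' and 'group'", call. = FALSE)
  }
  idx <- match(colnames(m), metadata$sample)
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  as.character(metadata$group[idx])
}

# Size-factor tibbles are (sample, size_factor); internally we want a named
# vector aligned to matrix columns.
factors_for <- function(m, size_factors) {
  if (is.numeric(size_factors) && !is.null(names(size_factors))) {
    f <- size_factors[colnames(m)]
  } else {
    idx <- match(colnames(m), size_factors$sample)
    if (anyNA(idx)) {
      stop("size factors missing for samples: ",
           paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    f <- size_factors$size_factor[idx]
  }
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("size factors must be positive and finite", call. = FALSE)
  }
  stats::setNames(as.numeric(f), colnames(m))
}

geometric_mean <- function(x) exp(mean(log(x)))

# Extract a character vector of gene ids from a character vector, a consensus
# tibble, or anything with a gene_id column.
as_gene_set <- function(x) {
  if (is.character(x)) return(unique(x))
  if (is.data.frame(x) && "gene_id" %in% names(x)) return(unique(x$gene_id))
  stop("expected a character vector of gene ids or a data frame with a gene_id column",
       call. = FALSE)
}
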