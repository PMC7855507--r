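# Differential-expression scorers: one negative-binomial exact-test core run
# under three normalization strategies (upper-quartile, median-of-ratios, and
# FPKM/total-count), mirroring how parallel DE algorithms differ mainly in how
# they place samples on a common count scale.

#' Upper-quartile size factors
#'
#' Per-sample scaling factors proportional to the 75th percentile of each
#' sample's counts, computed over genes that are nonzero in at least one
#' sample, then rescaled to unit geometric mean. Quantiles use linear
#' interpolation between order statistics (R's default type 7 convention).
#'
#' @param counts tibble with a `gene_id` first column and one integer column
#'   per sample.
#' @return tibble with columns `sample`, `size_factor`.
#' @export
size_factors_upper_quartile <- function(counts) {
  m <- counts_to_matrix(counts)
  assert_integer_counts(m)
  zero_samples <- colnames(m)[colSums(m) == 0]
  if (length(zero_samples) > 0) {
    stop("sample(s) with all-zero counts: ",
         paste(zero_samples, collapse = ", "), call. = FALSE)
  }
  keep <- rowSums(m) > 0
  q75 <- apply(m[keep, , drop = FALSE], 2, stats::quantile,
               probs = 0.75, names = FALSE, type = 7)
  if (any(q75 <= 0)) {
    stop("sample(s) with zero upper quartile: ",
         paste(colnames(m)[q75 <= 0], collapse = ", "), call. = FALSE)
  }
  f <- q75 / geometric_mean(q75)
  tibble::tibble(sample = colnames(m), size_factor = unname(f))
}

#' Median-of-ratios size factors
#'
#' The geometric-mean reference estimator: for each sample, the size factor
#' is the median over reference genes of the ratio of the sample's count to
#' the gene's geometric mean across samples. Reference genes are those with
#' no zero count in any sample.
#'
#' @inheritParams size_factors_upper_quartile
#' @return tibble with columns `sample`, `size_factor`.
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- counts_to_matrix(counts)
  assert_integer_counts(m)
  ref <- rowSums(m == 0) == 0
  if (!any(ref)) {
    stop("no gene with all-positive counts; cannot form the geometric-mean reference",
         call. = FALSE)
  }
  logm <- log(m[ref, , drop = FALSE])
  ref_log_mean <- rowMeans(logm)
  f <- apply(exp(logm - ref_log_mean), 2, stats::median)
  tibble::tibble(sample = colnames(m), size_factor = unname(f))
}

#' FPKM matrix
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM_gj = count_gj * 1e9 / (length_g * total_j)` where `total_j` is the
#' sample's total count.
#'
#' @inheritParams size_factors_upper_quartile
#' @param lengths tibble with columns `gene_id`, `length` (bp), covering
#'   every gene in `counts`.
#' @return tibble, same shape as `counts`, FPKM values.
#' @export
fpkm_matrix <- function(counts, lengths) {
  m <- counts_to_matrix(counts)
  idx <- match(rownames(m), lengths$gene_id)
  if (anyNA(idx)) {
    stop("missing gene length for: ",
         paste(utils::head(rownames(m)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  len <- lengths$length[idx]
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  totals <- colSums(m)
  fpkm <- m * 1e9 / (len %o% totals)
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(fpkm))
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments estimate on normalized counts, pooled across groups
#' (within-group means and variances, dispersion `(v - m) / m^2` averaged
#' with degrees-of-freedom weights), floored at 0. With `shrink = TRUE`
#' (default) each gene's estimate is averaged 50/50 with the mean raw
#' dispersion of genes in the same expression decile, which stabilises the
#' very noisy per-gene moments at typical replicate numbers.
#'
#' @inheritParams size_factors_upper_quartile
#' @param metadata tibble with columns `sample`, `group`; at least 2 samples
#'   per group.
#' @param size_factors tibble from one of the `size_factors_*` estimators
#'   (or a named numeric vector).
#' @param shrink logical; apply decile-trend shrinkage.
#' @return tibble with columns `gene_id`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, metadata, size_factors, shrink = TRUE) {
  m <- counts_to_matrix(counts)
  grp <- groups_for(m, metadata)
  f <- factors_for(m, size_factors)
  tab <- table(grp)
  if (any(tab < 2)) {
    stop("group(s) with fewer than 2 replicates: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  norm <- sweep(m, 2, f, "/")

  num <- 0
  den <- 0
  for (g in names(tab)) {
    sub <- norm[, grp == g, drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    df <- ncol(sub) - 1
    phi_g <- ifelse(mu > 0, (v - mu) / mu^2, 0)
    num <- num + df * phi_g
    den <- den + df
  }
  phi <- pmax(0, num / den)

  if (shrink) {
    base_mean <- rowMeans(norm)
    decile <- dplyr::ntile(base_mean, 10)
    trend <- tapply(phi, decile, mean)
    phi <- 0.5 * phi + 0.5 * as.numeric(trend[as.character(decile)])
  }
  tibble::tibble(gene_id = rownames(m), dispersion = unname(phi))
}

# Exact conditional two-group test for negative-binomial counts.
# Group sums of normalized counts are treated as sums of iid NB draws with a
# shared per-sample mean under the null; conditioning the first group's sum
# on the overall total gives a beta-binomial (negative-hypergeometric)
# distribution with shape parameters n_A/phi and n_B/phi, independent of the
# common mean. As phi -> 0 this degenerates to Binomial(t, n_A / (n_A + n_B)).
# Two-sided p-value: double the smaller tail (observed value included), cap 1.
exact_nb_pvalue <- function(s_a, s_b, n_a, n_b, phi) {
  t <- s_a + s_b
  if (t == 0) return(1)
  if (phi < 1e-10) {
    p <- n_a / (n_a + n_b)
    lower <- stats::pbinom(s_a, t, p)
    upper <- stats::pbinom(s_a - 1, t, p, lower.tail = FALSE)
    return(min(1, 2 * min(lower, upper)))
  }
  r_a <- n_a / phi
  r_b <- n_b / phi
  s <- 0:t
  logp <- lchoose(t, s) + lbeta(s + r_a, t - s + r_b) - lbeta(r_a, r_b)
  pr <- exp(logp)
  pr <- pr / sum(pr)  # guard against accumulated rounding at large t
  lower <- sum(pr[seq_len(s_a + 1)])
  upper <- sum(pr[(s_a + 1):(t + 1)])
  min(1, 2 * min(lower, upper))
}

#' Exact negative-binomial test for a two-group count matrix
#'
#' Per gene, normalized counts are summed within each group (and rounded to
#' the nearest integer); the first group's sum is tested against the total
#' with an exact conditional test — beta-binomial under negative-binomial
#' dispersion, exact binomial in the Poisson limit (dispersion 0). The log2
#' fold change is `log2((mean_norm_num + pseudo) / (mean_norm_den + pseudo))`.
#'
#' @inheritParams estimate_dispersion
#' @param dispersions tibble from [estimate_dispersion()] (or named vector).
#' @param pseudo_count pseudo-count (normalized scale) keeping fold changes
#'   finite at zeros; default 1.
#' @param numerator,denominator group labels for the fold-change ratio;
#'   default `"injured"` over `"control"` when present, otherwise first
#'   metadata group over the second.
#' @return tibble with columns `gene_id`, `base_mean`, `log2FC`, `pvalue`.
#' @export
nb_test <- function(counts, metadata, size_factors, dispersions,
                    pseudo_count = 1, numerator = NULL, denominator = NULL) {
  m <- counts_to_matrix(counts)
  grp <- groups_for(m, metadata)
  f <- factors_for(m, size_factors)
  levels <- unique(grp)
  if (length(levels) != 2) {
    stop("nb_test requires exactly two groups; got ",
         paste(levels, collapse = ", "), call. = FALSE)
  }
  if (is.null(numerator)) {
    numerator <- if ("injured" %in% levels) "injured" else levels[1]
  }
  if (is.null(denominator)) denominator <- setdiff(levels, numerator)
  stopifnot(numerator %in% levels, denominator %in% levels)

  phi <- if (is.data.frame(dispersions)) {
    stats::setNames(dispersions$dispersion, dispersions$gene_id)[rownames(m)]
  } else dispersions[rownames(m)]
  if (anyNA(phi)) stop("dispersion missing for some genes", call. = FALSE)

  norm <- sweep(m, 2, f, "/")
  a_cols <- grp == numerator
  b_cols <- grp == denominator
  n_a <- sum(a_cols)
  n_b <- sum(b_cols)
  mean_a <- rowMeans(norm[, a_cols, drop = FALSE])
  mean_b <- rowMeans(norm[, b_cols, drop = FALSE])
  s_a <- round(rowSums(norm[, a_cols, drop = FALSE]))
  s_b <- round(rowSums(norm[, b_cols, drop = FALSE]))

  pval <- vapply(seq_len(nrow(m)), function(i) {
    exact_nb_pvalue(s_a[i], s_b[i], n_a, n_b, phi[i])
  }, numeric(1))

  tibble::tibble(
    gene_id = rownames(m),
    base_mean = unname(rowMeans(norm)),
    log2FC = unname(log2((mean_a + pseudo_count) / (mean_b + pseudo_count))),
    pvalue = pval
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1 and monotone in
#' p-value rank. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return numeric vector of adjusted p-values, same length.
#' @export
adjust_bh <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the three-scorer differential-expression suite
#'
#' Runs the exact negative-binomial test three times on the same data under
#' the three normalization strategies:
#' * `UQ` — upper-quartile size factors on raw counts;
#' * `MOR` — median-of-ratios (geometric-mean reference) size factors;
#' * `FPKM` — counts converted to FPKM and rescaled to a common depth (the
#'   geometric-mean total count), i.e. total-count normalization via the
#'   FPKM route; tested with unit size factors.
#'
#' Each scorer estimates its own dispersions and is Benjamini-Hochberg
#' adjusted independently.
#'
#' @inheritParams estimate_dispersion
#' @param lengths gene length tibble for the FPKM scorer.
#' @param pseudo_count pseudo-count for fold changes (default 1).
#' @param shrink logical, dispersion shrinkage (default TRUE).
#' @inheritParams nb_test
#' @return tibble of class `sciq_de` with columns `method_id`, `gene_id`,
#'   `base_mean`, `log2FC`, `pvalue`, `padj`.
#' @export
run_de_suite <- function(counts, metadata, lengths, pseudo_count = 1,
                         shrink = TRUE, numerator = NULL, denominator = NULL) {
  run_one <- function(cnt, size_factors, method_id) {
    disp <- estimate_dispersion(cnt, metadata, size_factors, shrink = shrink)
    res <- nb_test(cnt, metadata, size_factors, disp,
                   pseudo_count = pseudo_count,
                   numerator = numerator, denominator = denominator)
    res$padj <- adjust_bh(res$pvalue)
    dplyr::bind_cols(tibble::tibble(method_id = method_id), res)
  }

  m <- counts_to_matrix(counts)
  unit <- tibble::tibble(sample = colnames(m), size_factor = 1)

  fpkm <- fpkm_matrix(counts, lengths)
  len <- lengths$length[match(fpkm$gene_id, lengths$gene_id)]
  depth <- geometric_mean(colSums(m))
  pseudo <- fpkm
  pseudo[, -1] <- round(as.matrix(fpkm[, -1]) * len * depth / 1e9)

  out <- dplyr::bind_rows(
    run_one(counts, size_factors_upper_quartile(counts), "UQ"),
    run_one(counts, size_factors_median_of_ratios(counts), "MOR"),
    run_one(pseudo, unit, "FPKM")
  )
  class(out) <- c("sciq_de", class(out))
  out
}
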