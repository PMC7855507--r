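# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Benjamini-Hochberg step-up by direct enumeration:
# adj_(i) = min_{j >= i} min(1, p_(j) * n / j), mapped back to input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(pmin(1, ranked))))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Upper binomial tail P(X >= k) by direct pmf summation.
binom_upper_oracle <- function(k, n, q) {
  if (k > n) return(0)
  sum(stats::dbinom(k:n, n, q))
}

# Lower binomial tail P(X <= k) by direct pmf summation.
binom_lower_oracle <- function(k, n, q) {
  sum(stats::dbinom(0:min(k, n), n, q))
}

# Exact conditional NB test p-value via an independent route: the
# conditional pmf of the first group's sum given the total is proportional
# to the product of the two groups' NB pmfs (any common success probability
# cancels after normalization).
nb_conditional_oracle <- function(s_a, s_b, n_a, n_b, phi) {
  t <- s_a + s_b
  r_a <- n_a / phi
  r_b <- n_b / phi
  s <- 0:t
  w <- stats::dnbinom(s, size = r_a, prob = 0.5) *
    stats::dnbinom(t - s, size = r_b, prob = 0.5)
  pr <- w / sum(w)
  min(1, 2 * min(sum(pr[s <= s_a]), sum(pr[s >= s_a])))
}

# O(n^3) agglomerative clustering with average linkage: scan all pairs at
# every step. Returns merge heights and the partition after each merge
# (each cluster as a sorted id string) for comparison against hclust.
average_linkage_oracle <- function(d_matrix, labels) {
  clusters <- as.list(labels)
  heights <- numeric(0)
  partitions <- list()
  avg_dist <- function(a, b) {
    mean(d_matrix[a, b])
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          d <- avg_dist(clusters[[i]], clusters[[j]])
          if (d < best_d) {
            best_d <- d
            best <- c(i, j)
          }
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_d)
    partitions <- c(partitions, list(
      sort(vapply(clusters, function(cl) paste(sort(cl), collapse = "|"),
                  character(1)))))
  }
  list(heights = heights, partitions = partitions)
}

# Toy two-group count fixture with named samples.
toy_counts <- function(values, n_genes, samples) {
  m <- matrix(values, nrow = n_genes)
  colnames(m) <- samples
  dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%02d", seq_len(n_genes))),
    tibble::as_tibble(m)
  )
}

toy_metadata <- function(samples, groups) {
  tibble::tibble(sample = samples, group = groups)
}

unit_factors <- function(samples) {
  tibble::tibble(sample = samples, size_factor = 1)
}
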