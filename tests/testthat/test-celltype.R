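ref_fixture <- function() {
  types <- c("astrocytes", "neurons", "endothelial", "microglia",
             "OPCs", "newly_formed_oligodendrocytes",
             "myelinating_oligodendrocytes")
  ref <- tibble::tibble(
    reference_id = sprintf("r%d", 1:6),
    !!!stats::setNames(as.list(rep(0, 7)), types)
  )
  m <- matrix(0, 6, 7, dimnames = list(NULL, types))
  m[1, ] <- c(2, 3, 5, 0, 0, 0, 0)
  m[2, ] <- rep(1, 7)                    # uniform
  m[3, ] <- c(0, 0, 0, 10, 0, 0, 0)      # microglia only
  m[4, ] <- rep(0.05, 7)                 # below background
  m[5, ] <- c(0.2, rep(0, 6))            # barely above background
  m[6, ] <- rep(0.1, 7)                  # max exactly at the boundary
  ref[types] <- tibble::as_tibble(m)
  ref
}

id_map_fixture <- tibble::tibble(
  gene_id = sprintf("g%d", 1:6),
  reference_id = sprintf("r%d", 1:6)
)

test_that("id mapping drops unmapped genes and resolves duplicates by expression", {
  ref <- ref_fixture()
  out <- map_ids(c("g1", "g3", "ghost"), ref, id_map_fixture)
  expect_setequal(out$gene_id, c("g1", "g3"))
  expect_equal(attr(out, "dropped"), "ghost")

  all_mapped <- map_ids(c("g1", "g2"), ref, id_map_fixture)
  expect_length(attr(all_mapped, "dropped"), 0)

  # one source id pointing at two reference rows: the higher-total row wins
  dup_map <- dplyr::bind_rows(id_map_fixture,
                              tibble::tibble(gene_id = "g1", reference_id = "r2"))
  expect_message(dup <- map_ids("g1", ref, dup_map), "multiple reference rows")
  expect_equal(dup$reference_id, "r1")   # total 10 for r1 beats 7 for r2
  expect_equal(attr(dup, "duplicates"), "g1")

  expect_error(map_ids("g1", ref, id_map_fixture[0, ]), "empty")
})

test_that("background filter is strict at 0.1", {
  ref <- ref_fixture()
  mapped <- map_ids(sprintf("g%d", 1:6), ref, id_map_fixture)
  kept <- background_filter(mapped, threshold = 0.1)
  expect_setequal(kept$gene_id, c("g1", "g2", "g3", "g5"))
  # all-0.05 and max-exactly-0.1 rows are excluded and reported
  expect_equal(attr(kept, "excluded"), c("g4", "g6"))
})

test_that("percentage profiles sum to 100 and match arithmetic", {
  ref <- ref_fixture()
  mapped <- background_filter(map_ids(sprintf("g%d", 1:6), ref, id_map_fixture))
  prof <- percentage_profile(mapped)
  ct <- setdiff(names(prof), c("gene_id", "reference_id"))
  expect_true(all(abs(rowSums(prof[ct]) - 100) < 1e-9))

  g1 <- unlist(prof[prof$gene_id == "g1", ct])
  expect_equal(unname(g1[1:3]), c(20, 30, 50))
  g2 <- unlist(prof[prof$gene_id == "g2", ct])
  expect_equal(unname(g2), rep(100 / 7, 7))
  g3 <- unlist(prof[prof$gene_id == "g3", ct])
  expect_equal(unname(g3), c(0, 0, 0, 100, 0, 0, 0))

  # scale invariance: multiplying a reference row leaves the profile unchanged
  scaled <- mapped
  ctm <- setdiff(names(scaled), c("gene_id", "reference_id"))
  scaled[scaled$gene_id == "g1", ctm] <-
    scaled[scaled$gene_id == "g1", ctm] * 37.5
  expect_equal(percentage_profile(scaled), prof)

  zero <- mapped
  zero[zero$gene_id == "g1", ctm] <- 0
  expect_error(percentage_profile(zero), "g1")
})

test_that("clustering merges identical and proportional profiles first", {
  prof <- tibble::tibble(
    gene_id = c("a1", "a2", "b1", "c1"),
    t1 = c(10, 10, 20, 90),
    t2 = c(80, 80, 60, 5),
    t3 = c(10, 10, 20, 5)
  )
  cl <- cluster_profiles(prof)
  ord <- cl$ordering$gene_id
  expect_equal(abs(diff(match(c("a1", "a2"), ord))), 1)   # identical: adjacent
  expect_equal(cl$trees$all$merge[1, ], c(-1, -2))        # and merged first

  # proportional rows have zero correlation distance, orthogonal ones do not
  prop <- tibble::tibble(
    gene_id = c("p1", "p2", "q1"),
    t1 = c(1, 2, 9), t2 = c(2, 4, 1), t3 = c(3, 6, 2)
  )
  cl2 <- cluster_profiles(prop)
  expect_equal(sort(cl2$trees$all$merge[1, ]), c(-2, -1))

  single <- cluster_profiles(prof[1, ])
  expect_equal(single$ordering$position, 1L)
})

test_that("clustering agrees with a brute-force agglomeration oracle", {
  withr::with_seed(131, {
    for (i in 1:5) {
      n <- 6
      prof <- tibble::tibble(
        gene_id = sprintf("g%d", 1:n),
        a = runif(n, 0, 100), b = runif(n, 0, 100),
        c = runif(n, 0, 100), d = runif(n, 0, 100)
      )
      m <- as.matrix(prof[, -1])
      rownames(m) <- prof$gene_id
      dm <- 1 - cor(t(m))
      cl <- cluster_profiles(prof)
      oracle <- average_linkage_oracle(dm, prof$gene_id)
      expect_equal(cl$trees$all$height, oracle$heights, tolerance = 1e-12)
      # same partition after every merge step
      hc <- cl$trees$all
      for (step in seq_len(nrow(hc$merge))) {
        members <- stats::cutree(hc, k = n - step)
        got <- sort(vapply(split(names(members), members),
                           function(g) paste(sort(g), collapse = "|"),
                           character(1)))
        expect_equal(unname(got), unname(oracle$partitions[[step]]))
      }
    }
  })
})

test_that("deterministic leaf order puts the lexicographically smallest subtree left", {
  prof <- tibble::tibble(
    gene_id = c("z9", "a1", "m5"),
    t1 = c(10, 11, 90), t2 = c(80, 79, 5), t3 = c(10, 10, 5)
  )
  cl <- cluster_profiles(prof)
  # z9 and a1 cluster together; the pair contains a1 so it goes left
  expect_equal(cl$ordering$gene_id[3], "m5")
  expect_equal(cl$ordering$gene_id[1] %in% c("a1", "z9"), TRUE)
  expect_lt(match("a1", cl$ordering$gene_id), match("z9", cl$ordering$gene_id))
})

test_that("synthetic markers cluster into contiguous same-cell-type blocks", {
  ok <- 0
  total <- 0
  for (seed in 1:10) {
    cfg <- simulation_config(n_genes = 120, marker_fraction = 0.5,
                             below_background_fraction = 0,
                             unmapped_fraction = 0, seed = seed)
    ref <- simulate_celltype_reference(cfg)
    markers <- ref$truth[!is.na(ref$truth$marker_celltype), ]
    mapped <- map_ids(markers$gene_id, ref$reference, ref$id_map)
    prof <- percentage_profile(background_filter(mapped))
    cl <- cluster_profiles(prof)
    ord <- cl$ordering$gene_id
    type_seq <- markers$marker_celltype[match(ord, markers$gene_id)]
    # genes inside a maximal run of their own cell type count as grouped
    runs <- rle(type_seq)
    biggest <- tapply(runs$lengths, runs$values, max)
    n_by_type <- table(type_seq)
    ok <- ok + sum(biggest[names(n_by_type)])
    total <- total + length(ord)
  }
  expect_gte(ok / total, 0.95)
})

test_that("top_unique ranks both directions with deterministic ties", {
  withr::with_seed(141, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:15),
      avg_log2fc = c(round(runif(12, 0.5, 5), 2), -1.2, -3.4, -0.7)
    )
  })
  out <- top_unique(genes, n = 10)
  up <- out[out$direction == "up", ]
  expect_equal(nrow(up), 10)
  expect_equal(up$avg_log2fc, sort(genes$avg_log2fc[1:12], decreasing = TRUE)[1:10])
  down <- out[out$direction == "down", ]
  expect_equal(nrow(down), 3)   # fewer than 10 downregulated: returned whole
  expect_equal(down$avg_log2fc, c(-3.4, -1.2, -0.7))

  tied <- tibble::tibble(gene_id = c("gb", "ga", "gc"),
                         avg_log2fc = c(2, 2, 2))
  t2 <- top_unique(tied, n = 2)
  expect_equal(t2$gene_id[t2$direction == "up"], c("ga", "gb"))
})
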