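test_that("cut_tree removes the highest merges", {
  t4 <- agglomerate(ultrametric4(), "upgma")
  p2 <- cut_tree(t4, 2)
  expect_equal(split(p2$region, p2$cluster) |> lapply(sort) |> unname(),
               list(c("A", "B", "C"), "D"))
  p3 <- cut_tree(t4, 3)
  expect_equal(split(p3$region, p3$cluster) |> lapply(sort) |> unname(),
               list(c("A", "B"), "C", "D"))
  p4 <- cut_tree(t4, 4)
  expect_equal(sort(table(p4$cluster) |> as.integer()), rep(1L, 4))
  expect_error(cut_tree(t4, 1), class = "archipel_config_error")
  expect_error(cut_tree(t4, 5), class = "archipel_config_error")

  # oracle: stats::cutree on monotone trees
  for (s in 1:4) {
    D <- random_dissim(7, seed = 200 + s)
    t <- agglomerate(D, "upgma")
    hc <- as.hclust(t)
    for (k in 2:6) {
      mine <- cut_tree(t, k)
      ct <- stats::cutree(hc, k)
      # same partition up to relabelling
      expect_equal(recovery_report(
        tibble::tibble(region = names(ct), cluster = unname(ct)), mine)$exact,
        TRUE)
    }
  }
})

test_that("silhouette widths follow the definition", {
  # two clusters of 2, within 0.1, between 0.9
  D <- matrix(0.9, 4, 4); D[1:2, 1:2] <- 0.1; D[3:4, 3:4] <- 0.1; diag(D) <- 0
  dimnames(D) <- list(paste0("r", 1:4), paste0("r", 1:4))
  p <- tibble::tibble(region = paste0("r", 1:4), cluster = c(1, 1, 2, 2))
  sw <- silhouette_widths(D, p)
  expect_equal(sw$width, rep((0.9 - 0.1) / 0.9, 4))
  expect_equal(attr(sw, "mean_width"), (0.9 - 0.1) / 0.9)

  # all singletons: widths 0 by convention
  p1 <- tibble::tibble(region = paste0("r", 1:4), cluster = 1:4)
  expect_equal(silhouette_widths(D, p1)$width, rep(0, 4))

  # range property on random inputs
  for (s in 1:5) {
    Dr <- random_dissim(6, seed = 300 + s)
    pr <- tibble::tibble(region = rownames(Dr),
                         cluster = sample(1:3, 6, replace = TRUE))
    if (length(unique(pr$cluster)) < 2) next
    w <- silhouette_widths(Dr, pr)$width
    expect_true(all(w >= -1 & w <= 1))
  }

  expect_error(silhouette_widths(D, tibble::tibble(region = paste0("r", 1:4),
                                                   cluster = 1)),
               class = "archipel_config_error")
})

test_that("mantel statistic correlates distance with cluster separation", {
  D <- matrix(0.9, 4, 4); D[1:2, 1:2] <- 0.1; D[3:4, 3:4] <- 0.1; diag(D) <- 0
  dimnames(D) <- list(paste0("r", 1:4), paste0("r", 1:4))
  good <- tibble::tibble(region = paste0("r", 1:4), cluster = c(1, 1, 2, 2))
  expect_equal(mantel_statistic(D, good), 1)

  # anti-structured partition groups the most dissimilar regions
  bad <- tibble::tibble(region = paste0("r", 1:4), cluster = c(1, 2, 1, 2))
  expect_lt(mantel_statistic(D, bad), 0)

  # invariant under cluster relabelling and region order permutation
  relab <- tibble::tibble(region = paste0("r", 1:4), cluster = c(9, 9, 4, 4))
  expect_equal(mantel_statistic(D, relab), mantel_statistic(D, good))
  perm <- sample(4)
  expect_equal(mantel_statistic(D[perm, perm], good), mantel_statistic(D, good))

  # k = n makes the model matrix constant
  expect_error(mantel_statistic(D, tibble::tibble(region = paste0("r", 1:4),
                                                  cluster = 1:4)),
               class = "archipel_undefined_statistic")

  # random partitions on unstructured distances: mean r near 0
  set.seed(99)
  Dr <- random_dissim(10, seed = 55)
  rs <- replicate(200, {
    pr <- tibble::tibble(region = rownames(Dr),
                         cluster = sample(rep(1:2, 5)))
    mantel_statistic(Dr, pr)
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("mantel agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  Dr <- random_dissim(8, seed = 42)
  pr <- tibble::tibble(region = rownames(Dr),
                       cluster = rep(1:2, each = 4))
  model <- outer(pr$cluster, pr$cluster, `!=`) * 1
  dimnames(model) <- dimnames(Dr)
  vg <- vegan::mantel(stats::as.dist(Dr), stats::as.dist(model),
                      permutations = 0)
  expect_equal(mantel_statistic(Dr, pr), unname(vg$statistic),
               tolerance = 1e-10)
})

test_that("optimal_k recovers a planted 3-block matrix under both criteria", {
  n <- 9
  blocks <- rep(1:3, each = 3)
  D <- matrix(0.8, n, n)
  for (b in 1:3) D[blocks == b, blocks == b] <- 0.15
  diag(D) <- 0
  # mild asymmetric jitter, kept symmetric
  set.seed(1); J <- matrix(runif(n * n, 0, 0.02), n); J <- (J + t(J)) / 2
  D <- D + J; diag(D) <- 0
  dimnames(D) <- list(paste0("b", 1:n), paste0("b", 1:n))
  t <- agglomerate(dissim_matrix(D), "upgma")
  for (crit in c("silhouette", "mantel")) {
    ok <- optimal_k(D, t, 6, crit)
    expect_equal(ok$k_best, 3)
    expect_equal(nrow(ok$profile), 5)          # every k in 2..6, no skips
    expect_true(all(is.finite(ok$profile$score)))
    expect_equal(recovery_report(
      tibble::tibble(region = rownames(D), cluster = blocks),
      ok$partition)$exact, TRUE)
  }

  # 2 leaves: k = 2 trivially (silhouette only; mantel needs k <= n-1)
  m2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- agglomerate(m2, "upgma")
  expect_equal(optimal_k(m2, t2, 2, "silhouette")$k_best, 2)
})

test_that("bootstrap supports are reproducible, bounded, and saturate on clean blocks", {
  # well-separated 2-block checklist: no shared species across blocks
  pres <- rbind(matrix(rep(c(1L, 0L), c(15, 15)), 3, 30, byrow = TRUE),
                matrix(rep(c(0L, 1L), c(15, 15)), 3, 30, byrow = TRUE))
  df <- tibble::as_tibble(as.data.frame(t(pres)))
  names(df) <- paste0("Bk", 1:6)
  df <- dplyr::bind_cols(tibble::tibble(species = paste0("s", 1:30)), df)
  cl <- as_checklist(df)

  bt <- bootstrap_support(cl, "jaccard", "upgma",
                          n_trees = 20, n_iterations = 5, seed = 11)
  expect_length(bt$support, 5)
  expect_true(all(bt$support >= 0 & bt$support <= 100))
  # the root bipartition is always contained
  expect_equal(bt$support[length(bt$support)], 100)
  # the two clean blocks are recovered by every species resample
  sets <- vapply(archipel:::dendro_leafsets(bt), paste, character(1),
                 collapse = "+")
  expect_equal(unname(bt$support[sets == "Bk1+Bk2+Bk3"]), 100)

  # determinism under a fixed seed
  bt2 <- bootstrap_support(cl, "jaccard", "upgma",
                           n_trees = 20, n_iterations = 5, seed = 11)
  expect_identical(bt$support, bt2$support)
  expect_equal(attr(bt, "n_replicates"), 100)

  # 3-leaf checklist: single informative bipartition, support in range
  cl3 <- random_checklist(n_species = 12, n_regions = 3, seed = 8)
  bt3 <- bootstrap_support(cl3, "jaccard", "upgma",
                           n_trees = 10, n_iterations = 5, seed = 2)
  expect_true(all(bt3$support >= 0 & bt3$support <= 100))
})

test_that("bootstrap discards undefined replicates and aborts past 10 percent", {
  # a region with a single recorded species often empties under resampling
  df <- tibble::tibble(
    species = paste0("s", 1:12),
    X = c(1L, rep(1L, 11)),
    Y = c(1L, rep(1L, 11)),
    Z = c(1L, rep(0L, 11))
  )
  cl <- as_checklist(df)
  expect_error(
    bootstrap_support(cl, "simpson", "upgma",
                      n_trees = 10, n_iterations = 10, seed = 4),
    class = "archipel_bootstrap_error")
})

test_that("more replicates shrink the Monte-Carlo spread of supports", {
  cfg <- synthetic_config(regions = sprintf("S%02d", 1:6),
                          cluster_assignment = rep(1:2, each = 3),
                          n_cosmopolitan = 15, pool_size = 25, n_endemics = 2,
                          shared_endemics = tibble::tibble(combo = character(),
                                                          n = integer()),
                          p_within = 0.85, p_leak = 0.35, detection = 1,
                          p_missing_depth = 0, p_deep = 0, p_flagged = 0)
  support_sd <- function(n_total) {
    sup <- sapply(1:8, function(s) {
      g <- generate_checklist(cfg, seed = 500)   # same data every time
      bt <- bootstrap_support(g$checklist, "jaccard", "upgma",
                              n_trees = n_total, n_iterations = 1,
                              seed = 1000 + s)
      bt$support[-length(bt$support)]
    })
    mean(apply(sup, 1, sd))
  }
  expect_gt(support_sd(40), support_sd(360))
})
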