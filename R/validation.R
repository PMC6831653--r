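#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 last merges. Because merges are recorded in the order
#' they happen, this equals cutting at the k-1 highest merge heights for
#' monotone linkages (UPGMA, complete, Ward); for centroid trees with
#' height inversions the cut is by merge order, which stays well defined.
#'
#' @param t an `archipel_dendro`
#' @param k integer number of clusters, `2 <= k <=` number of leaves
#' @return tibble with columns `region`, `cluster` (ids 1..k, numbered by
#'   leaf order of first appearance)
#' @export
cut_tree <- function(t, k) {
  n <- length(t$labels)
  if (k < 2 || k > n) {
    abort_archipel(sprintf("k = %d out of range [2, %d]", k, n),
                   "archipel_config_error")
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  leaf_idx <- vector("list", n - 1L)
  n_merge <- n - k
  for (s in seq_len(n - 1L)) {
    grab <- function(code) if (code < 0) -code else leaf_idx[[code]]
    li <- grab(t$merge[s, 1]); ri <- grab(t$merge[s, 2])
    leaf_idx[[s]] <- c(li, ri)
    if (s <= n_merge) parent[find(ri[1])] <- find(li[1])
  }
  root <- vapply(seq_len(n), find, integer(1))
  ids <- match(root, unique(root))          # number clusters by leaf order
  tibble::tibble(region = t$labels, cluster = ids)
}

as_assignment <- function(p) {
  if (is.data.frame(p)) stats::setNames(p$cluster, p$region)
  else p
}

#' Silhouette widths of a partition against a dissimilarity matrix
#'
#' For each region, `s(i) = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean
#' dissimilarity to the other members of its own cluster and `b_i` the
#' smallest mean dissimilarity to any other cluster. Regions in singleton
#' clusters get `s(i) = 0` by convention.
#'
#' @param D dissimilarity matrix
#' @param p partition: tibble with `region`, `cluster` (as from
#'   [cut_tree()]) or a named cluster vector
#' @return tibble with columns `region`, `cluster`, `width`; the mean width
#'   is attached as attribute `mean_width`
#' @export
silhouette_widths <- function(D, p) {
  D <- as.matrix(D)
  asg <- as_assignment(p)
  labs <- rownames(D)
  asg <- asg[labs]
  if (anyNA(asg)) {
    abort_archipel("partition does not cover all regions of D",
                   "archipel_validation_error")
  }
  k <- length(unique(asg))
  if (k < 2) {
    abort_archipel("silhouette undefined for a single cluster",
                   "archipel_config_error")
  }
  widths <- vapply(seq_along(labs), function(i) {
    own <- which(asg == asg[i]); own <- own[own != i]
    if (!length(own)) return(0)            # singleton convention
    a_i <- mean(D[i, own])
    b_i <- min(vapply(setdiff(unique(asg), asg[i]), function(cl) {
      mean(D[i, which(asg == cl)])
    }, numeric(1)))
    (b_i - a_i) / max(a_i, b_i)
  }, numeric(1))
  out <- tibble::tibble(region = labs, cluster = unname(asg), width = widths)
  attr(out, "mean_width") <- mean(widths)
  out
}

#' Mantel statistic of a partition against a dissimilarity matrix
#'
#' Pearson correlation between the strict upper triangle of `D` and a
#' binary model matrix coding 1 for region pairs in *different* clusters,
#' so that well-structured partitions (small within, large between
#' dissimilarities) score positively.
#'
#' @inheritParams silhouette_widths
#' @return Pearson correlation in `[-1, 1]`
#' @export
mantel_statistic <- function(D, p) {
  D <- as.matrix(D)
  asg <- as_assignment(p)
  labs <- rownames(D)
  asg <- asg[labs]
  if (anyNA(asg)) {
    abort_archipel("partition does not cover all regions of D",
                   "archipel_validation_error")
  }
  model <- outer(asg, asg, `!=`) * 1
  x <- upper_tri_vec(D); y <- upper_tri_vec(model)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_archipel("Mantel statistic undefined: zero variance (is k = 1 or k = n?)",
                   "archipel_undefined_statistic")
  }
  stats::cor(x, y)
}

#' Optimal number of clusters by silhouette or Mantel criterion
#'
#' Cuts the dendrogram at every k in `2..k_max`, scores each partition
#' (mean silhouette width, or Mantel statistic), and returns the best k
#' together with the full k-score profile. Ties go to the smallest k.
#'
#' @param D dissimilarity matrix the tree was built from
#' @param t an `archipel_dendro` on the same regions
#' @param k_max largest k to evaluate (`<= n` for silhouette, `<= n - 1`
#'   for Mantel, whose model matrix is constant at k = n)
#' @param criterion `"silhouette"` or `"mantel"`
#' @return an `archipel_optimal_k`: list with `criterion`, `profile`
#'   (tibble k, score), `k_best`, `partition` (tibble region, cluster),
#'   `score_best`
#' @export
optimal_k <- function(D, t, k_max = NULL, criterion = c("silhouette", "mantel")) {
  criterion <- match.arg(criterion)
  n <- length(t$labels)
  k_hi <- if (criterion == "mantel") n - 1L else n
  k_max <- min(k_max %||% k_hi, k_hi)
  if (k_max < 2) {
    abort_archipel("k_max must be at least 2", "archipel_config_error")
  }
  ks <- 2:k_max
  parts <- purrr::map(ks, ~ cut_tree(t, .x))
  score <- purrr::map_dbl(parts, function(p) {
    if (criterion == "silhouette") attr(silhouette_widths(D, p), "mean_width")
    else mantel_statistic(D, p)
  })
  best <- which.max(score)                  # which.max takes the smallest tie
  structure(list(
    criterion = criterion,
    profile = tibble::tibble(k = ks, score = score),
    k_best = ks[best],
    partition = parts[[best]],
    score_best = score[best]
  ), class = "archipel_optimal_k")
}

#' @export
print.archipel_optimal_k <- function(x, ...) {
  cat(sprintf("# Optimal clusters by %s: k = %d (score %.3f)\n",
              x$criterion, x$k_best, x$score_best))
  print(x$profile)
  invisible(x)
}

#' Bootstrap node support for a dendrogram
#'
#' Builds the reference tree on the full checklist, then resamples species
#' (columns) with replacement `n_trees * n_iterations` times, rebuilding the
#' dissimilarity matrix and tree for each replicate with leaf input order
#' randomized. The support of an internal node is 100 times the fraction of
#' replicate trees containing the identical leaf-set bipartition anywhere.
#' Replicates whose resampled matrix leaves the index undefined (an emptied
#' region) are discarded and counted; more than 10 percent discarded aborts
#' the run.
#'
#' @param c a checklist
#' @param index dissimilarity index name
#' @param linkage linkage name
#' @param n_trees trees per iteration (default 100)
#' @param n_iterations iterations (default 100); the two knobs only set the
#'   total replicate count `n_trees * n_iterations`
#' @param seed integer seed for reproducibility
#' @return the reference `archipel_dendro` with `support` filled in
#'   (percent, one value per internal node; the root bipartition is 100 by
#'   construction) and attributes `n_replicates`, `n_discarded`
#' @export
bootstrap_support <- function(c, index = "jaccard", linkage = "upgma",
                              n_trees = 100, n_iterations = 100, seed = NULL) {
  stopifnot(n_trees >= 1, n_iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  D <- build_dissimilarity(c, index)
  ref <- agglomerate(D, linkage)
  m <- presence_matrix(c)
  n_reg <- nrow(m); n_sp <- ncol(m)
  total <- as.integer(n_trees) * as.integer(n_iterations)

  ref_sets <- dendro_leafsets(ref)
  ref_keys <- vapply(ref_sets, set_key, character(1))
  counts <- stats::setNames(integer(length(ref_keys)), ref_keys)
  discarded <- 0L
  for (rep in seq_len(total)) {
    cols <- sample.int(n_sp, n_sp, replace = TRUE)
    perm <- sample.int(n_reg)
    mb <- m[perm, cols, drop = FALSE]
    Db <- tryCatch(build_dissimilarity_matrix(mb, index),
                   archipel_undefined_index = function(e) NULL)
    if (is.null(Db)) { discarded <- discarded + 1L; next }
    tb <- agglomerate(Db, linkage, tie_break = "order")
    keys <- vapply(dendro_leafsets(tb), set_key, character(1))
    hit <- ref_keys %in% keys
    counts[hit] <- counts[hit] + 1L
  }
  valid <- total - discarded
  if (discarded > 0.1 * total) {
    abort_archipel(sprintf(
      "bootstrap aborted: %d of %d replicates produced an undefined %s matrix",
      discarded, total, index), "archipel_bootstrap_error")
  }
  ref$support <- 100 * as.numeric(counts) / valid
  attr(ref, "n_replicates") <- valid
  attr(ref, "n_discarded") <- discarded
  ref
}
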