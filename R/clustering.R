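LINKAGES <- c("upgma", "complete", "centroid", "ward")

# preference orders used to break model-selection ties
LINKAGE_PREFERENCE <- c("upgma", "complete", "ward", "centroid")
INDEX_PREFERENCE <- c("jaccard", "sorensen", "simpson", "ochiai")

#' Agglomerative clustering of a dissimilarity matrix
#'
#' Lance-Williams agglomeration under four linkage schemes: UPGMA (average),
#' complete, centroid and Ward's minimum variance. Centroid and Ward operate
#' on squared dissimilarities internally (the Ward.D2 convention) and report
#' merge heights back on the input dissimilarity scale, so the height of a
#' merge is the linkage dissimilarity at which the two clusters join.
#'
#' Ties in the minimal linkage value are broken deterministically: merge the
#' pair whose concatenated, sorted leaf-label tuple sorts first
#' (`tie_break = "label"`), making the result independent of input order.
#' `tie_break = "order"` takes the first minimal pair in scan order instead;
#' the bootstrap uses it together with per-replicate leaf-order
#' randomization so tie artifacts wash out across replicates.
#'
#' Centroid linkage can produce height inversions (a merge lower than an
#' earlier one); they are retained and flagged via the `inversions`
#' attribute, never repaired.
#'
#' @param D an `archipel_dissim` matrix (or any symmetric matrix with zero
#'   diagonal and labels)
#' @param linkage one of `"upgma"`, `"complete"`, `"centroid"`, `"ward"`
#' @param tie_break `"label"` (default, deterministic) or `"order"`
#' @return an `archipel_dendro`: list with `merge` (hclust-style),
#'   `height`, `labels`, `order`, `method`, optional `support`
#' @export
agglomerate <- function(D, linkage = "upgma", tie_break = c("label", "order")) {
  linkage <- match.arg(linkage, LINKAGES)
  tie_break <- match.arg(tie_break)
  D <- as.matrix(D)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("R", seq_len(nrow(D)))
  }
  if (!isSymmetric(unname(D), tol = 1e-10) || any(D < 0)) {
    abort_archipel("input must be a symmetric non-negative dissimilarity matrix",
                   "archipel_validation_error")
  }
  labs <- rownames(D)
  n <- nrow(D)
  stopifnot(n >= 2)

  squared <- linkage %in% c("centroid", "ward")
  W <- if (squared) unname(D)^2 else unname(D)
  diag(W) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  code <- -seq_len(n)                      # hclust codes: -leaf, +merge row
  members <- as.list(labs)                 # leaf labels per active cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- W[idx, idx, drop = FALSE]
    m <- min(sub)
    cand <- which(sub == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1L && tie_break == "label") {
      keys <- vapply(seq_len(nrow(cand)), function(r) {
        set_key(c(members[[idx[cand[r, 1]]]], members[[idx[cand[r, 2]]]]))
      }, character(1))
      cand <- cand[order(keys)[1], , drop = FALSE]
    } else {
      cand <- cand[1, , drop = FALSE]
    }
    i <- idx[cand[1, 1]]; j <- idx[cand[1, 2]]

    height[s] <- if (squared) sqrt(max(m, 0)) else m
    merge[s, ] <- sort(c(code[i], code[j]))
    ni <- size[i]; nj <- size[j]

    k <- idx[idx != i & idx != j]
    if (length(k)) {
      dik <- W[i, k]; djk <- W[j, k]
      new <- switch(linkage,
        upgma    = (ni * dik + nj * djk) / (ni + nj),
        complete = pmax(dik, djk),
        centroid = (ni * dik + nj * djk) / (ni + nj) - ni * nj * m / (ni + nj)^2,
        ward     = ((size[k] + ni) * dik + (size[k] + nj) * djk - size[k] * m) /
                   (size[k] + ni + nj)
      )
      W[i, k] <- new; W[k, i] <- new
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    W[j, ] <- Inf; W[, j] <- Inf
    code[i] <- s
    members[[i]] <- c(members[[i]], members[[j]])
  }

  inversions <- any(diff(height) < -1e-10)
  new_dendro(merge, height, labs, method = linkage,
             index = attr(D, "index"), inversions = inversions)
}

new_dendro <- function(merge, height, labels, method = NA_character_,
                       index = NULL, inversions = FALSE, support = NULL) {
  structure(list(
    merge = merge, height = height, labels = labels,
    order = dendro_leaf_order(merge),
    method = method, index = index,
    inversions = inversions, support = support
  ), class = "archipel_dendro")
}

# left-to-right leaf order for plotting / hclust compatibility
dendro_leaf_order <- function(merge) {
  expand <- function(code) {
    if (code < 0) return(-code)
    c(expand(merge[code, 1]), expand(merge[code, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.archipel_dendro <- function(x, ...) {
  cat(sprintf("# Dendrogram: %d leaves, %s linkage%s%s\n",
              length(x$labels), x$method,
              if (!is.null(x$index)) paste0(", ", x$index, " index") else "",
              if (isTRUE(x$inversions)) " [height inversions]" else ""))
  cat("  leaves:", paste(x$labels, collapse = ", "), "\n")
  if (!is.null(x$support)) cat("  bootstrap supports attached\n")
  invisible(x)
}

#' @export
as.hclust.archipel_dendro <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = x$index),
            class = "hclust")
}

# list of sorted leaf-label sets, one per merge row (internal node)
dendro_leafsets <- function(t) {
  n <- length(t$labels)
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    grab <- function(code) if (code < 0) t$labels[-code] else sets[[code]]
    sets[[s]] <- sort(c(grab(t$merge[s, 1]), grab(t$merge[s, 2])))
  }
  sets
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the merge height of the lowest common ancestor of leaves
#' i and j — the dissimilarity at which they first belong to one cluster.
#'
#' @param t an `archipel_dendro`
#' @return symmetric numeric matrix with zero diagonal, labelled by leaves
#' @export
cophenetic_matrix <- function(t) {
  n <- length(t$labels)
  out <- matrix(0, n, n, dimnames = list(t$labels, t$labels))
  leaf_idx <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    grab <- function(code) if (code < 0) -code else leaf_idx[[code]]
    li <- grab(t$merge[s, 1]); ri <- grab(t$merge[s, 2])
    out[li, ri] <- t$height[s]
    out[ri, li] <- t$height[s]
    leaf_idx[[s]] <- c(li, ri)
  }
  out
}

#' Cophenetic correlation between a matrix and its dendrogram
#'
#' Pearson correlation between the strict upper triangles of the input
#' dissimilarity matrix and the cophenetic matrix of the tree: how
#' faithfully the dendrogram represents the original distances. Equals 1
#' exactly when the input is ultrametric and the linkage preserves it.
#'
#' @param D dissimilarity matrix used to build the tree
#' @param t an `archipel_dendro`
#' @return Pearson correlation in `[-1, 1]`
#' @export
cophenetic_correlation <- function(D, t) {
  D <- as.matrix(D)
  if (nrow(D) < 3) {
    abort_archipel("cophenetic correlation needs at least 3 leaves",
                   "archipel_validation_error")
  }
  cop <- cophenetic_matrix(t)
  cop <- cop[rownames(D), colnames(D)]
  x <- upper_tri_vec(D); y <- upper_tri_vec(cop)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_archipel("cophenetic correlation undefined: zero variance in distances",
                   "archipel_undefined_statistic")
  }
  stats::cor(x, y)
}

#' Select the best index x linkage combination by cophenetic correlation
#'
#' Builds the dissimilarity matrix for every requested index, clusters it
#' under every requested linkage, and scores each combination by the
#' cophenetic correlation between matrix and dendrogram. Ties are broken by
#' a documented preference order: UPGMA > complete > Ward > centroid, then
#' Jaccard > Sorensen > Simpson > Ochiai.
#'
#' @param c a checklist
#' @param indices subset of `"jaccard"`, `"sorensen"`, `"simpson"`, `"ochiai"`
#' @param linkages subset of `"upgma"`, `"complete"`, `"centroid"`, `"ward"`
#' @return an `archipel_model_selection`: list with `grid` (tibble of
#'   index, linkage, cophenetic_r), `best` (one-row tibble), `tree_best`,
#'   `matrix_best`
#' @export
select_model <- function(c, indices = DISSIM_INDICES, linkages = LINKAGES) {
  indices <- match.arg(indices, DISSIM_INDICES, several.ok = TRUE)
  linkages <- match.arg(linkages, LINKAGES, several.ok = TRUE)
  grid <- tidyr::expand_grid(index = indices, linkage = linkages)
  mats <- purrr::map(indices, ~ build_dissimilarity(c, .x))
  names(mats) <- indices
  trees <- purrr::map2(grid$index, grid$linkage,
                       ~ agglomerate(mats[[.x]], .y))
  grid$cophenetic_r <- unname(purrr::map2_dbl(mats[grid$index], trees,
                                              cophenetic_correlation))
  ord <- order(-grid$cophenetic_r,
               match(grid$linkage, LINKAGE_PREFERENCE),
               match(grid$index, INDEX_PREFERENCE))
  best_row <- ord[1]
  structure(list(
    grid = grid[, c("index", "linkage", "cophenetic_r")],
    best = grid[best_row, c("index", "linkage", "cophenetic_r")],
    tree_best = trees[[best_row]],
    matrix_best = mats[[grid$index[best_row]]]
  ), class = "archipel_model_selection")
}

#' @export
print.archipel_model_selection <- function(x, ...) {
  cat("# Model selection by cophenetic correlation\n")
  print(dplyr::arrange(x$grid, dplyr::desc(.data$cophenetic_r)))
  cat(sprintf("best: %s / %s (r = %.3f)\n",
              x$best$index, x$best$linkage, x$best$cophenetic_r))
  invisible(x)
}

dendro_newick_string <- function(t, halve_heights = FALSE, digits = 15) {
  n <- length(t$labels)
  scale <- if (halve_heights) 0.5 else 1
  fmt <- function(x) sprintf("%.*g", digits, x)
  min_leaf <- function(code) {
    if (code < 0) return(t$labels[-code])
    min(min_leaf(t$merge[code, 1]), min_leaf(t$merge[code, 2]))
  }
  node_str <- function(code, parent_height) {
    if (code < 0) {
      return(paste0(t$labels[-code], ":", fmt(parent_height * scale)))
    }
    h <- t$height[code]
    lab <- if (!is.null(t$support)) {
      s <- t$support[code]
      if (is.na(s)) "" else fmt(s)
    } else ""
    kids <- t$merge[code, ]
    if (min_leaf(kids[2]) < min_leaf(kids[1])) kids <- rev(kids)
    paste0("(", node_str(kids[1], h), ",",
           node_str(kids[2], h), ")", lab,
           if (!is.na(parent_height)) paste0(":", fmt((parent_height - h) * scale)) else "")
  }
  paste0(node_str(n - 1L, NA_real_), ";")
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths are height differences: a child's branch is parent merge
#' height minus child height, with leaves at height 0, so branch lengths
#' live on the dissimilarity scale. Bootstrap supports (when attached) are
#' written as internal node labels. `halve_heights = TRUE` applies the
#' display convention that splits each merge height symmetrically between
#' the two branches (a 2-leaf tree at height 0.4 becomes `(A:0.2,B:0.2);`).
#'
#' @param t an `archipel_dendro`
#' @param path output file path
#' @param halve_heights halve all heights for display (default `FALSE`)
#' @return `path`, invisibly
#' @export
export_newick <- function(t, path, halve_heights = FALSE) {
  writeLines(dendro_newick_string(t, halve_heights), path)
  invisible(path)
}

#' Read a dendrogram back from Newick text
#'
#' Inverse of [export_newick()] (without height halving): leaf heights are
#' assumed 0 and internal node heights are recovered from root-to-node path
#' lengths. Internal node labels are parsed as bootstrap supports.
#'
#' @param path Newick file path
#' @return an `archipel_dendro`
#' @export
read_newick <- function(path) {
  phy <- ape::read.tree(path)
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  heights <- max(depth[seq_len(n)]) - depth
  internal <- (n + 1L):(n + phy$Nnode)
  ord <- internal[order(heights[internal])]
  code <- integer(n + phy$Nnode)
  code[seq_len(n)] <- -seq_len(n)
  merge <- matrix(0L, phy$Nnode, 2L)
  hgt <- numeric(phy$Nnode)
  sup <- rep(NA_real_, phy$Nnode)
  labs <- phy$node.label
  for (s in seq_along(ord)) {
    node <- ord[s]
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    stopifnot(length(kids) == 2)
    merge[s, ] <- sort(code[kids])
    hgt[s] <- heights[node]
    code[node] <- s
    if (!is.null(labs)) {
      lab <- labs[node - n]
      if (!is.na(lab) && nzchar(lab)) sup[s] <- as.numeric(lab)
    }
  }
  support <- if (!is.null(labs) && any(!is.na(sup))) sup else NULL
  new_dendro(merge, hgt, phy$tip.label, support = support)
}
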