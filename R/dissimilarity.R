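DISSIM_INDICES <- c("jaccard", "sorensen", "simpson", "ochiai")

#' Pairwise presence/absence counts for two regions
#'
#' The 2x2 match/mismatch counts underlying all the compositional indices:
#' `a` species shared by both regions, `b` present only in the first,
#' `c` present only in the second.
#'
#' @param c a checklist
#' @param r1,r2 distinct region labels
#' @return a one-row tibble with columns `a`, `b`, `c`
#' @export
#' @examples
#' cl <- as_checklist(data.frame(species = c("s1", "s2", "s3"),
#'                               A = c(1, 1, 0), B = c(1, 0, 1)))
#' pairwise_counts(cl, "A", "B")
pairwise_counts <- function(c, r1, r2) {
  regs <- regions(c)
  unknown <- setdiff(c(r1, r2), regs)
  if (length(unknown)) {
    abort_archipel(sprintf("unknown region(s): %s", paste(unknown, collapse = ", ")),
                   "archipel_config_error")
  }
  stopifnot(r1 != r2)
  p1 <- c[[r1]]; p2 <- c[[r2]]
  tibble::tibble(a = sum(p1 == 1 & p2 == 1),
                 b = sum(p1 == 1 & p2 == 0),
                 c = sum(p1 == 0 & p2 == 1))
}

#' Presence/absence dissimilarity from pairwise counts
#'
#' Dissimilarity = 1 - similarity, for the four classical indices:
#' Jaccard `1 - a/(a+b+c)`, Sorensen `1 - 2a/(2a+b+c)`,
#' Ochiai `1 - a/sqrt((a+b)(a+c))`, and the turnover-only Simpson
#' (beta-sim) `1 - a/(a + min(b, c))`. Simpson of nested assemblages is 0.
#' Vectorized over count triples.
#'
#' @param counts a data frame with columns `a`, `b`, `c` (e.g. from
#'   [pairwise_counts()]), or a numeric vector of `a` values
#' @param index one of `"jaccard"`, `"sorensen"`, `"simpson"`, `"ochiai"`
#' @param b,c counts, when `counts` is given as the `a` vector
#' @return numeric vector of dissimilarities in `[0, 1]`
#' @export
#' @examples
#' dissim(2, "jaccard", b = 1, c = 1)   # 0.5
#' dissim(3, "simpson", b = 0, c = 2)   # 0: nested assemblages
dissim <- function(counts, index, b = NULL, c = NULL) {
  index <- match.arg(index, DISSIM_INDICES)
  if (is.data.frame(counts)) {
    a <- counts$a; b <- counts$b; c <- counts$c
  } else {
    a <- counts
  }
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0))
  if (index %in% c("jaccard", "sorensen")) {
    if (any(a + b + c == 0)) {
      abort_archipel(sprintf("%s dissimilarity undefined: both regions empty", index),
                     "archipel_undefined_index")
    }
  } else {
    if (any(a + b == 0 | a + c == 0)) {
      abort_archipel(sprintf("%s dissimilarity undefined: a region is empty", index),
                     "archipel_undefined_index")
    }
  }
  switch(index,
    jaccard  = 1 - a / (a + b + c),
    sorensen = 1 - 2 * a / (2 * a + b + c),
    simpson  = 1 - a / (a + pmin(b, c)),
    ochiai   = 1 - a / sqrt((a + b) * (a + c))
  )
}

#' Construct a dissimilarity matrix object
#'
#' @param values symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`
#' @param labels region labels (defaults to `rownames(values)`)
#' @param index the index name the matrix was computed under
#' @return a `archipel_dissim` matrix
#' @export
dissim_matrix <- function(values, labels = rownames(values), index = "jaccard") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(values)))
  if (!isSymmetric(unname(values), tol = 1e-12)) {
    abort_archipel("dissimilarity matrix must be symmetric", "archipel_validation_error")
  }
  if (any(diag(values) != 0)) {
    abort_archipel("dissimilarity diagonal must be zero", "archipel_validation_error")
  }
  if (any(values < -1e-12 | values > 1 + 1e-12)) {
    abort_archipel("dissimilarities must lie in [0, 1]", "archipel_validation_error")
  }
  values[values < 0] <- 0; values[values > 1] <- 1
  dimnames(values) <- list(labels, labels)
  structure(values, index = index, class = c("archipel_dissim", "matrix", "array"))
}

#' Region-by-region dissimilarity matrix of a checklist
#'
#' Computes all pairwise counts from the presence matrix and applies the
#' chosen index. Fails with the offending region pair when an index is
#' undefined (an empty region under Ochiai/Simpson, two empty regions under
#' any index).
#'
#' @param c a checklist
#' @param index one of `"jaccard"`, `"sorensen"`, `"simpson"`, `"ochiai"`
#' @return an `archipel_dissim` matrix (symmetric, zero diagonal, labelled)
#' @export
build_dissimilarity <- function(c, index = "jaccard") {
  index <- match.arg(index, DISSIM_INDICES)
  m <- presence_matrix(c)
  build_dissimilarity_matrix(m, index)
}

# core used by both the user surface and the bootstrap fast path:
# m is a regions x species 0/1 matrix
build_dissimilarity_matrix <- function(m, index) {
  labs <- rownames(m)
  a <- tcrossprod(m)                       # shared species counts
  tot <- rowSums(m)
  n <- nrow(m)
  bm <- matrix(tot, n, n) - a              # only in row region
  cm <- t(bm)                              # only in column region
  if (index %in% c("jaccard", "sorensen")) {
    bad <- a + bm + cm == 0
  } else {
    bad <- outer(tot, tot, function(x, y) x == 0 | y == 0)
  }
  diag(bad) <- FALSE
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    abort_archipel(
      sprintf("%s dissimilarity undefined for region pair (%s, %s)",
              index, labs[ij[1]], labs[ij[2]]),
      "archipel_undefined_index"
    )
  }
  v <- switch(index,
    jaccard  = 1 - a / (a + bm + cm),
    sorensen = 1 - 2 * a / (2 * a + bm + cm),
    simpson  = 1 - a / (a + pmin(bm, cm)),
    ochiai   = 1 - a / sqrt((a + bm) * (a + cm))
  )
  diag(v) <- 0
  v <- (v + t(v)) / 2                      # remove float asymmetry
  dissim_matrix(v, labs, index)
}

#' @export
print.archipel_dissim <- function(x, ...) {
  cat(sprintf("# %s dissimilarity, %d regions\n", attr(x, "index"), nrow(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Tidy a dissimilarity matrix into region pairs
#'
#' @param x an `archipel_dissim` matrix
#' @param ... unused
#' @return tibble with columns `region1`, `region2`, `dissimilarity`
#'   (strict upper triangle)
#' @method tidy archipel_dissim
#' @export
tidy.archipel_dissim <- function(x, ...) {
  labs <- rownames(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    region1 = labs[ut[, 1]],
    region2 = labs[ut[, 2]],
    dissimilarity = x[upper.tri(x)],
    index = attr(x, "index")
  )
}
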