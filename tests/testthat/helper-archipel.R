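# shared fixtures and independent oracles

# a small checklist built in code: 5 species, 3 regions, with metadata
tiny_checklist <- function() {
  as_checklist(tibble::tibble(
    species = paste0("sp", 1:5),
    taxon_group = "gastropods",
    family = c("Conidae", "Conidae", "Rissoidae", "Muricidae", "Modulidae"),
    genus = c("Conus", "Conus", "Alvania", "Hexaplex", "Modulus"),
    depth_min_m = c(0, 10, NA, 250, 5),
    depth_max_m = c(30, 60, NA, 600, 50),
    status = c(NA, NA, "introduced", NA, NA),
    endemic_scope = c("A", NA, NA, NA, "A+B"),
    A = c(1L, 1L, 1L, 1L, 1L),
    B = c(0L, 1L, 1L, 0L, 1L),
    C = c(0L, 0L, 1L, 1L, 0L)
  ))
}

# random checklist with plain Bernoulli presence (no planted structure)
random_checklist <- function(n_species = 30, n_regions = 5, p = 0.5,
                             seed = 1, group = "other") {
  set.seed(seed)
  regs <- paste0("Rg", LETTERS[seq_len(n_regions)])
  repeat {
    pres <- matrix(rbinom(n_species * n_regions, 1L, p), n_species)
    if (all(colSums(pres) > 0) && all(rowSums(pres) > 0)) break
  }
  df <- tibble::tibble(
    species = sprintf("rsp%03d", seq_len(n_species)),
    taxon_group = group,
    depth_min_m = round(runif(n_species, 0, 100), 1)
  )
  df$depth_max_m <- df$depth_min_m + round(runif(n_species, 1, 100), 1)
  for (i in seq_len(n_regions)) df[[regs[i]]] <- pres[, i]
  as_checklist(df, regions = regs)
}

# brute-force dissimilarity from raw presence sets, one pair at a time
naive_dissim_matrix <- function(cl, index) {
  regs <- regions(cl)
  n <- length(regs)
  out <- matrix(0, n, n, dimnames = list(regs, regs))
  sets <- lapply(regs, function(r) cl$species[cl[[r]] == 1L])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- length(intersect(sets[[i]], sets[[j]]))
    b <- length(setdiff(sets[[i]], sets[[j]]))
    cc <- length(setdiff(sets[[j]], sets[[i]]))
    out[i, j] <- switch(index,
      jaccard  = 1 - a / (a + b + cc),
      sorensen = 1 - 2 * a / (2 * a + b + cc),
      simpson  = 1 - a / (a + min(b, cc)),
      ochiai   = 1 - a / sqrt((a + b) * (a + cc)))
  }
  out
}

# canonical view of a tree: leaf-set of every internal node with its height,
# sorted -- lets us compare trees across merge-code conventions
canonical_tree <- function(merge, height, labels) {
  n <- length(labels)
  sets <- vector("list", n - 1)
  out <- character(n - 1)
  for (s in seq_len(n - 1)) {
    grab <- function(code) if (code < 0) labels[-code] else sets[[code]]
    sets[[s]] <- sort(c(grab(merge[s, 1]), grab(merge[s, 2])))
    out[s] <- paste0(paste(sets[[s]], collapse = "+"), "@",
                     signif(height[s], 8))
  }
  sort(out)
}

canon_archipel <- function(t) canonical_tree(t$merge, t$height, t$labels)
canon_hclust <- function(h) canonical_tree(h$merge, h$height, h$labels)

# a symmetric matrix with distinct random entries
random_dissim <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- sample(seq(0.05, 0.95, length.out = n * (n - 1) / 2))
  m <- m + t(m)
  dimnames(m) <- list(paste0("L", seq_len(n)), paste0("L", seq_len(n)))
  m
}

# ultrametric 4-leaf example: d(A,B)=2, d(A,C)=d(B,C)=6, d(.,D)=10
ultrametric4 <- function() {
  m <- matrix(c(0, 2, 6, 10,
                2, 0, 6, 10,
                6, 6, 0, 10,
                10, 10, 10, 0), 4, 4, byrow = TRUE,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m
}

extdata <- function(f) system.file("extdata", f, package = "archipel")
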