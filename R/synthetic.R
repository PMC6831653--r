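#' Configuration for the synthetic checklist generator
#'
#' Describes a world with planted biogeographic structure: regions grouped
#' into `k` true clusters, a cosmopolitan species pool present everywhere,
#' per-cluster species pools occurring in member regions with probability
#' `p_within` and leaking into non-member regions with probability
#' `p_leak`, single-region endemics, endemics shared between designated
#' region subsets, and an overall detection probability thinning every true
#' presence (incomplete sampling). Defaults emulate the scale of real
#' multi-archipelago littoral checklists: 12 regions in 3 clusters and
#' roughly 600 species, with mild leak and slightly incomplete detection.
#'
#' @param regions region labels (default `R01..R12`)
#' @param cluster_assignment integer cluster id per region (default: 3
#'   contiguous blocks of equal size)
#' @param n_cosmopolitan species present in all regions (default 60)
#' @param pool_size per-cluster pool sizes, scalar or per-cluster
#'   (default 150)
#' @param n_endemics single-region endemics per region, scalar or
#'   per-region (default 8)
#' @param shared_endemics data frame `combo` (plus-separated region
#'   labels), `n`; `NULL` plants a small default set inside each cluster
#' @param p_within presence probability of a pool species in its cluster's
#'   regions (default 0.9)
#' @param p_leak presence probability outside the cluster (default 0.05)
#' @param detection probability a true presence is recorded (default 0.95)
#' @param p_missing_depth fraction of species with missing depth metadata
#'   (default 0.05)
#' @param p_deep fraction of species given a deep (>200 m) shallow limit,
#'   so depth filters have something to remove (default 0.05)
#' @param p_flagged fraction of species given an exclusion status flag
#'   (default 0.05)
#' @param taxon_group group label of the generated checklist
#' @param seed integer seed stored with the config
#' @return a validated `archipel_synthetic_config`
#' @export
synthetic_config <- function(regions = sprintf("R%02d", 1:12),
                             cluster_assignment = NULL,
                             n_cosmopolitan = 60,
                             pool_size = 150,
                             n_endemics = 8,
                             shared_endemics = NULL,
                             p_within = 0.9, p_leak = 0.05, detection = 0.95,
                             p_missing_depth = 0.05, p_deep = 0.05,
                             p_flagged = 0.05,
                             taxon_group = "other", seed = NULL) {
  n <- length(regions)
  stopifnot(n >= 2, !anyDuplicated(regions))
  if (is.null(cluster_assignment)) {
    k <- if (n >= 6) 3 else 2
    cluster_assignment <- rep(seq_len(k), each = ceiling(n / k))[seq_len(n)]
  }
  stopifnot(length(cluster_assignment) == n)
  cluster_assignment <- match(cluster_assignment, unique(cluster_assignment))
  k <- max(cluster_assignment)
  pool_size <- rep_len(pool_size, k)
  n_endemics <- rep_len(n_endemics, n)
  probs <- c(p_within = p_within, p_leak = p_leak, detection = detection,
             p_missing_depth = p_missing_depth, p_deep = p_deep,
             p_flagged = p_flagged)
  if (any(probs < 0 | probs > 1)) {
    abort_archipel("probabilities must lie in [0, 1]", "archipel_config_error")
  }
  if (is.null(shared_endemics)) {
    shared_endemics <- purrr::map_dfr(seq_len(k), function(cl) {
      mem <- regions[cluster_assignment == cl]
      if (length(mem) < 2) return(NULL)
      combos <- c(paste(mem[1:2], collapse = "+"),
                  if (length(mem) >= 3) paste(mem[1:3], collapse = "+"))
      tibble::tibble(combo = combos, n = 3L)
    })
  }
  shared_endemics <- tibble::as_tibble(shared_endemics)
  if (nrow(shared_endemics)) {
    sets <- strsplit(shared_endemics$combo, "+", fixed = TRUE)
    if (any(lengths(sets) < 2) || !all(unlist(sets) %in% regions)) {
      abort_archipel("shared_endemics combos must name >= 2 known regions",
                     "archipel_config_error")
    }
  }
  structure(list(
    regions = regions, cluster_assignment = cluster_assignment,
    n_cosmopolitan = n_cosmopolitan, pool_size = pool_size,
    n_endemics = n_endemics, shared_endemics = shared_endemics,
    p_within = p_within, p_leak = p_leak, detection = detection,
    p_missing_depth = p_missing_depth, p_deep = p_deep,
    p_flagged = p_flagged, taxon_group = taxon_group, seed = seed
  ), class = "archipel_synthetic_config")
}

#' Generate a synthetic checklist with known ground truth
#'
#' Samples presence independently per species-by-region cell under the
#' configured probabilities, then thins every recorded presence by the
#' detection probability. Endemics and shared endemics are deterministically
#' present in their home region(s) before thinning. Species left with no
#' recorded presence are dropped (and counted in the `n_dropped`
#' attribute); endemic annotations reflect the *recorded* occurrences, as
#' they would in a curated checklist.
#'
#' @param cfg an `archipel_synthetic_config`
#' @param seed integer seed; overrides `cfg$seed`
#' @return list with elements `checklist`, `truth` (list: `partition`
#'   tibble region/cluster, `annotations` tibble species/endemic_scope,
#'   `config`)
#' @export
generate_checklist <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "archipel_synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  regs <- cfg$regions
  n_reg <- length(regs)
  k <- max(cfg$cluster_assignment)

  blocks <- list()
  # cosmopolitan block
  if (cfg$n_cosmopolitan > 0) {
    blocks$cosmo <- list(
      names = sprintf("cosmo_sp%04d", seq_len(cfg$n_cosmopolitan)),
      pres = matrix(1L, cfg$n_cosmopolitan, n_reg)
    )
  }
  # cluster pools
  for (cl in seq_len(k)) {
    ns <- cfg$pool_size[cl]
    if (ns == 0) next
    member <- cfg$cluster_assignment == cl
    p <- ifelse(member, cfg$p_within, cfg$p_leak)
    pres <- matrix(stats::rbinom(ns * n_reg, 1L,
                                 rep(p, each = ns)), ns, n_reg)
    blocks[[paste0("pool", cl)]] <- list(
      names = sprintf("cl%d_sp%04d", cl, seq_len(ns)),
      pres = pres
    )
  }
  # single-region endemics
  for (r in seq_len(n_reg)) {
    ne <- cfg$n_endemics[r]
    if (ne == 0) next
    pres <- matrix(0L, ne, n_reg); pres[, r] <- 1L
    blocks[[paste0("end", r)]] <- list(
      names = sprintf("end_%s_sp%03d", regs[r], seq_len(ne)),
      pres = pres
    )
  }
  # shared endemics
  if (nrow(cfg$shared_endemics)) {
    for (i in seq_len(nrow(cfg$shared_endemics))) {
      cb <- cfg$shared_endemics$combo[i]
      ns <- cfg$shared_endemics$n[i]
      if (ns == 0) next
      mem <- strsplit(cb, "+", fixed = TRUE)[[1]]
      pres <- matrix(0L, ns, n_reg)
      pres[, match(mem, regs)] <- 1L
      blocks[[paste0("sh", i)]] <- list(
        names = sprintf("shend%02d_sp%03d", i, seq_len(ns)),
        pres = pres
      )
    }
  }

  names_all <- unlist(lapply(blocks, `[[`, "names"), use.names = FALSE)
  pres <- do.call(rbind, lapply(blocks, `[[`, "pres"))
  is_endemic_block <- grepl("^(end_|shend)", names_all)
  n_sp <- length(names_all)

  # detection thinning on every recorded presence
  if (cfg$detection < 1) {
    keep <- matrix(stats::rbinom(length(pres), 1L, cfg$detection),
                   nrow(pres), ncol(pres))
    pres <- pres * keep
  }

  recorded <- rowSums(pres) > 0
  n_dropped <- sum(!recorded)
  if (any(colSums(pres[recorded, , drop = FALSE]) == 0)) {
    abort_archipel(
      "a region ended with zero recorded species; enlarge the pools or detection",
      "archipel_generation_error")
  }

  # depth and status metadata
  deep <- stats::runif(n_sp) < cfg$p_deep
  depth_min <- ifelse(deep, stats::runif(n_sp, 210, 500),
                      stats::runif(n_sp, 0, 45))
  depth_max <- depth_min + stats::runif(n_sp, 5, 150)
  missing_depth <- stats::runif(n_sp) < cfg$p_missing_depth
  depth_min[missing_depth] <- NA_real_
  depth_max[missing_depth] <- NA_real_
  flagged <- stats::runif(n_sp) < cfg$p_flagged & !is_endemic_block
  status <- rep(NA_character_, n_sp)
  status[flagged] <- sample(c("pelagic", "bathypelagic", "deep_water",
                              "anchialine", "introduced"),
                            sum(flagged), replace = TRUE)

  # endemic annotations from recorded occurrences
  scope <- rep(NA_character_, n_sp)
  for (i in which(is_endemic_block & recorded)) {
    occ <- regs[pres[i, ] == 1L]
    scope[i] <- paste(occ, collapse = "+")
  }

  df <- tibble::tibble(
    species = names_all,
    taxon_group = cfg$taxon_group,
    family = NA_character_, genus = NA_character_,
    depth_min_m = round(depth_min, 1), depth_max_m = round(depth_max, 1),
    status = status, endemic_scope = scope
  )
  pm <- as.data.frame(pres); names(pm) <- regs
  df <- dplyr::bind_cols(df, tibble::as_tibble(pm))[recorded, ]
  checklist <- as_checklist(df, regions = regs, taxon_group = cfg$taxon_group)
  attr(checklist, "n_dropped") <- n_dropped

  list(
    checklist = checklist,
    truth = list(
      partition = tibble::tibble(region = regs,
                                 cluster = cfg$cluster_assignment),
      annotations = tibble::tibble(species = checklist$species,
                                   endemic_scope = checklist$endemic_scope),
      config = cfg
    )
  )
}

# proportion of region pairs on which two partitions agree (Rand index)
rand_index <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 2)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}

#' Agreement between a planted and an inferred partition
#'
#' Reports whether the inferred partition matches the planted one exactly
#' (up to cluster relabelling) and the Rand index: the proportion of region
#' pairs classified alike (together vs apart) by both partitions.
#'
#' @param truth tibble with `region`, `cluster` (planted)
#' @param inferred tibble with `region`, `cluster` (from [cut_tree()] or
#'   [optimal_k()])
#' @return tibble with columns `exact`, `rand`, `k_true`, `k_inferred`
#' @export
recovery_report <- function(truth, inferred) {
  truth <- tibble::as_tibble(truth)
  inferred <- tibble::as_tibble(inferred)
  if (!setequal(truth$region, inferred$region)) {
    abort_archipel("partitions cover different region sets",
                   "archipel_validation_error")
  }
  b <- inferred$cluster[match(truth$region, inferred$region)]
  a <- truth$cluster
  exact <- identical(
    sort(unname(vapply(split(truth$region, a), set_key, character(1)))),
    sort(unname(vapply(split(truth$region, b), set_key, character(1))))
  )
  tibble::tibble(
    exact = exact,
    rand = rand_index(a, b),
    k_true = length(unique(a)),
    k_inferred = length(unique(b))
  )
}
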