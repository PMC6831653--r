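#' The ten molluscan Provincial Index Taxa
#'
#' Families and subfamilies of warm-water gastropods whose per-family
#' endemism percentages are averaged into the Provincial Combined Index:
#' Turbinellidae, Modulidae, Conidae, Conorbidae (=Conilithidae), Muricinae,
#' Fasciolariinae, Volutinae (=Lyriinae), Olivinae, Cancellariinae and
#' Plesiotritoninae.
#'
#' @return character vector of the 10 index taxon names, in canonical order
#' @export
provincial_index_taxa <- function() {
  c("Turbinellidae", "Modulidae", "Conidae", "Conorbidae", "Muricinae",
    "Fasciolariinae", "Volutinae", "Olivinae", "Cancellariinae",
    "Plesiotritoninae")
}

#' Genus-to-subfamily table for the subfamily-level index taxa
#'
#' Five of the ten Provincial Index Taxa are subfamilies; species are mapped
#' to them through their genus. The table lists the Atlantic genera of
#' Muricinae, Fasciolariinae, Volutinae, Olivinae, Cancellariinae and
#' Plesiotritoninae; it can be replaced or extended by the caller.
#'
#' @return tibble with columns `genus`, `index_taxon`
#' @export
index_taxon_genera <- function() {
  tibble::tibble(
    genus = c(
      "Aspella", "Attiliosa", "Bolinus", "Calotrophon", "Chicoreus",
      "Dermomurex", "Hexaplex", "Paziella", "Phyllonotus", "Purpurellus",
      "Siratus", "Timbellus", "Vokesimurex",
      "Cinctura", "Fasciollaria", "Leucozonia", "Polygona", "Triplofusus",
      "Enaeta",
      "Americoliva", "Oliva",
      "Agatrix", "Gerdiella",
      "Loxotaphrus", "Tritonoharpa"
    ),
    index_taxon = c(
      rep("Muricinae", 13),
      rep("Fasciolariinae", 5),
      rep("Volutinae", 1),
      rep("Olivinae", 2),
      rep("Cancellariinae", 2),
      rep("Plesiotritoninae", 2)
    )
  )
}

# endemic_scope strings -> list of label vectors ("A+B" -> c("A","B"))
parse_endemic_scope <- function(scope) {
  lapply(ifelse(is.na(scope), "", scope), function(s) {
    if (!nzchar(s)) character(0) else strsplit(s, "+", fixed = TRUE)[[1]]
  })
}

#' Per-region richness and endemism summary
#'
#' Totals come from the presence columns; endemics are species whose
#' `endemic_scope` names exactly that single region. The attribute
#' `widespread` reports how many species occur in every one of the
#' designated archipelagos (the "present in all archipelagos" fraction).
#'
#' @param c a checklist (filtered as desired)
#' @param archipelagos region labels treated as the focal archipelago set;
#'   defaults to all regions
#' @return tibble with columns `region`, `n_species`, `n_endemic`,
#'   `pct_endemic` (half-up, one decimal; `NA` for an empty region), plus
#'   attribute `widespread` (tibble `n_pool`, `n_widespread`,
#'   `pct_widespread`)
#' @export
richness_endemism <- function(c, archipelagos = regions(c)) {
  unknown <- setdiff(archipelagos, regions(c))
  if (length(unknown)) {
    abort_archipel(sprintf("unknown archipelago label(s): %s",
                           paste(unknown, collapse = ", ")),
                   "archipel_config_error")
  }
  scopes <- parse_endemic_scope(c$endemic_scope)
  bad <- lengths(scopes) > 0 &
    !vapply(scopes, function(s) all(s %in% regions(c)), logical(1))
  if (any(bad)) {
    abort_archipel(sprintf("endemic_scope of '%s' names regions outside the checklist",
                           c$species[bad][1]),
                   "archipel_validation_error")
  }
  single <- vapply(scopes, function(s) if (length(s) == 1) s else NA_character_,
                   character(1))
  m <- presence_matrix(c)
  out <- tibble::tibble(
    region = archipelagos,
    n_species = as.integer(rowSums(m[archipelagos, , drop = FALSE])),
    n_endemic = unname(vapply(archipelagos, function(r)
      sum(!is.na(single) & single == r), integer(1)))
  )
  out$pct_endemic <- ifelse(out$n_species > 0,
                            round_half_up(100 * out$n_endemic / out$n_species, 1),
                            NA_real_)
  pool <- nrow(c)
  in_all <- sum(colSums(m[archipelagos, , drop = FALSE] == 1L) ==
                length(archipelagos))
  attr(out, "widespread") <- tibble::tibble(
    n_pool = pool, n_widespread = as.integer(in_all),
    pct_widespread = if (pool > 0) round_half_up(100 * in_all / pool, 1) else NA_real_
  )
  out
}

#' Endemism percentages from printed counts
#'
#' Convenience for auditing published richness tables: given per-region
#' totals and endemic counts, computes the endemism percentage with the
#' same half-up one-decimal rounding the rest of the package reports.
#'
#' @param counts data frame with columns `region`, `n_species`, `n_endemic`
#' @return the input as a tibble with `pct_endemic` added
#' @export
endemism_from_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("region", "n_species", "n_endemic") %in% names(counts)))
  stopifnot(all(counts$n_endemic <= counts$n_species))
  counts$pct_endemic <- ifelse(counts$n_species > 0,
                               round_half_up(100 * counts$n_endemic / counts$n_species, 1),
                               NA_real_)
  counts
}

pit_values <- function(df) {
  ifelse(df$n_species > 0, 100 * df$n_endemic / df$n_species, NA_real_)
}

#' Molluscan Provincial Index for one region
#'
#' For each of the ten Provincial Index Taxa, counts the species of the
#' checklist present in `region` (N), the ones endemic to it (n, from
#' `endemic_scope`), and the per-family endemism percentage
#' `PIT = 100 n / N`. The Provincial Combined Index is the mean of the ten
#' PIT values with empty families (N = 0) contributing zero; it is
#' undefined (`NA`) only when *no* index family has any species. A combined
#' index above 50 percent confers molluscan provincial status, 25-50
#' percent (inclusive at both ends) subprovincial status.
#'
#' Species are assigned to an index taxon by their `family` column or, for
#' the subfamily-level taxa, by their `genus` through `genus_map`. A
#' species matching more than one index taxon is an error.
#'
#' @param c a gastropod checklist
#' @param region region label to score
#' @param genus_map genus-to-subfamily table (default [index_taxon_genera()])
#' @return an `archipel_provincial_index`: list with `region`, `families`
#'   (tibble family, n_species, n_endemic, pit), `pct`, `status`
#' @export
provincial_index <- function(c, region, genus_map = index_taxon_genera()) {
  if (!region %in% regions(c)) {
    abort_archipel(sprintf("unknown region '%s'", region), "archipel_config_error")
  }
  taxa <- provincial_index_taxa()
  by_family <- !is.na(c$family) & c$family %in% taxa
  by_genus <- !is.na(c$genus) & c$genus %in% genus_map$genus
  mapped_family <- ifelse(by_family, c$family,
                          genus_map$index_taxon[match(c$genus, genus_map$genus)])
  conflict <- by_family & by_genus &
    c$family != genus_map$index_taxon[match(c$genus, genus_map$genus)]
  if (any(conflict)) {
    abort_archipel(sprintf("species '%s' maps to more than one index taxon",
                           c$species[conflict][1]),
                   "archipel_validation_error")
  }
  in_index <- by_family | by_genus
  scopes <- parse_endemic_scope(c$endemic_scope)
  endemic_here <- vapply(scopes, function(s) identical(s, region), logical(1))
  present <- c[[region]] == 1L
  fam <- purrr::map_dfr(taxa, function(f) {
    sel <- in_index & mapped_family == f & present
    tibble::tibble(family = f,
                   n_species = sum(sel),
                   n_endemic = sum(sel & endemic_here))
  })
  provincial_index_from_counts(fam, region = region)
}

#' Provincial Index from printed per-family counts
#'
#' The same PIT/PCT arithmetic as [provincial_index()], starting from a
#' table of per-family totals and endemic counts (as printed in published
#' Provincial Index tables). Families omitted from the input are taken as
#' empty (N = 0).
#'
#' @param counts data frame with columns `family`, `n_species`, `n_endemic`
#' @param region optional region label carried into the result
#' @return an `archipel_provincial_index`
#' @export
provincial_index_from_counts <- function(counts, region = NA_character_) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("family", "n_species", "n_endemic") %in% names(counts)))
  taxa <- provincial_index_taxa()
  unknown <- setdiff(counts$family, taxa)
  if (length(unknown)) {
    abort_archipel(sprintf("not a Provincial Index Taxon: %s",
                           paste(unknown, collapse = ", ")),
                   "archipel_config_error")
  }
  if (anyDuplicated(counts$family)) {
    abort_archipel("duplicated family in counts", "archipel_validation_error")
  }
  stopifnot(all(counts$n_endemic <= counts$n_species))
  fam <- tibble::tibble(family = taxa) |>
    dplyr::left_join(counts, by = "family") |>
    dplyr::mutate(n_species = dplyr::coalesce(.data$n_species, 0L),
                  n_endemic = dplyr::coalesce(.data$n_endemic, 0L))
  fam$pit <- pit_values(fam)
  pct <- if (all(fam$n_species == 0)) NA_real_ else
    sum(fam$pit, na.rm = TRUE) / length(taxa)
  structure(list(
    region = region,
    families = fam,
    pct = pct,
    status = classify_provincial_status(pct)
  ), class = "archipel_provincial_index")
}

#' Classify a Provincial Combined Index value
#'
#' Above 50 percent: provincial status; between 25 and 50 percent
#' (inclusive at both boundaries, the documented convention): subprovincial
#' status; below 25 percent: no rank; undefined input: not applicable.
#'
#' @param pct Provincial Combined Index in `[0, 100]`, or `NA`
#' @param boundaries length-2 numeric `(subprovince, province)` thresholds
#' @return one of `"province"`, `"subprovince"`, `"none"`, `"not_applicable"`
#' @export
classify_provincial_status <- function(pct, boundaries = c(25, 50)) {
  if (is.na(pct)) return("not_applicable")
  if (pct < 0 || pct > 100) {
    abort_archipel("Provincial Combined Index must lie in [0, 100]",
                   "archipel_validation_error")
  }
  if (pct > boundaries[2]) "province"
  else if (pct >= boundaries[1]) "subprovince"
  else "none"
}

#' @export
print.archipel_provincial_index <- function(x, ...) {
  cat(sprintf("# Provincial Index%s\n",
              if (!is.na(x$region)) paste0(" - ", x$region) else ""))
  fam <- x$families
  fam$pit <- round_half_up(fam$pit, 1)
  print(fam)
  cat(sprintf("Provincial Combined Index: %s -> %s\n",
              if (is.na(x$pct)) "n.a." else sprintf("%.1f%%", round_half_up(x$pct, 1)),
              x$status))
  invisible(x)
}

#' Shared-endemics occupancy and combination analysis
#'
#' Restricts the checklist to species annotated as endemics shared between
#' two or more of the study archipelagos (plus-separated `endemic_scope`)
#' and summarizes in how many and in which archipelagos each occurs. A
#' species annotated as shared but recorded in fewer than two of the
#' archipelagos is a validation error.
#'
#' @param c a checklist whose `endemic_scope` annotations are curated
#' @param archipelagos the study archipelago labels (default: all regions)
#' @return an `archipel_shared_endemics`: list with `species` (tibble
#'   species, combo, occupancy), `occupancy` (tibble occupancy, n, pct),
#'   `combinations` (tibble combo, size, n), `archipelagos`
#' @export
shared_endemics <- function(c, archipelagos = regions(c)) {
  unknown <- setdiff(archipelagos, regions(c))
  if (length(unknown)) {
    abort_archipel(sprintf("unknown archipelago label(s): %s",
                           paste(unknown, collapse = ", ")),
                   "archipel_config_error")
  }
  scopes <- parse_endemic_scope(c$endemic_scope)
  shared <- lengths(scopes) >= 2 &
    vapply(scopes, function(s) all(s %in% archipelagos), logical(1))
  m <- presence_matrix(c)[archipelagos, , drop = FALSE]
  sp <- which(shared)
  if (length(sp)) {
    occ_sets <- lapply(sp, function(i) archipelagos[m[, i] == 1L])
    short <- lengths(occ_sets) < 2
    if (any(short)) {
      abort_archipel(sprintf(
        "species '%s' is annotated as a shared endemic but recorded in %d archipelago(s)",
        c$species[sp[short][1]], lengths(occ_sets)[short][1]),
        "archipel_validation_error")
    }
    combo <- vapply(occ_sets, function(s)
      paste(archipelagos[archipelagos %in% s], collapse = "+"), character(1))
  } else {
    combo <- character(0)
  }
  species <- tibble::tibble(
    species = c$species[sp],
    combo = combo,
    occupancy = lengths(if (length(sp)) lapply(combo, function(x)
      strsplit(x, "+", fixed = TRUE)[[1]]) else list())
  )
  total <- nrow(species)
  classes <- 2:max(2, length(archipelagos))
  occupancy <- tibble::tibble(
    occupancy = classes,
    n = vapply(classes, function(k) sum(species$occupancy == k), integer(1))
  )
  occupancy$pct <- if (total > 0) round_half_up(100 * occupancy$n / total, 1) else NA_real_
  combinations <- species |>
    dplyr::count(.data$combo, name = "n") |>
    dplyr::mutate(size = lengths(strsplit(.data$combo, "+", fixed = TRUE))) |>
    dplyr::select("combo", "size", "n") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$combo)
  structure(list(species = species, occupancy = occupancy,
                 combinations = combinations, archipelagos = archipelagos),
            class = "archipel_shared_endemics")
}

#' @export
print.archipel_shared_endemics <- function(x, ...) {
  cat(sprintf("# Shared endemics: %d species across %d archipelagos\n",
              nrow(x$species), length(x$archipelagos)))
  print(x$occupancy)
  invisible(x)
}

#' Presence/absence checklist of the shared endemics
#'
#' Turns a shared-endemics table back into a species-by-archipelago
#' checklist, the input for clustering the archipelagos on their shared
#' endemic faunas alone (the strongest biogeographic signal: shared
#' restricted taxa act like synapomorphies).
#'
#' @param table an `archipel_shared_endemics`
#' @param taxon_group group label for the resulting checklist
#' @return a checklist of the shared-endemic species over the archipelagos
#' @export
shared_endemics_matrix <- function(table, taxon_group = "other") {
  stopifnot(inherits(table, "archipel_shared_endemics"))
  if (nrow(table$species) == 0) {
    abort_archipel("no shared endemics to build a matrix from",
                   "archipel_validation_error")
  }
  arch <- table$archipelagos
  pres <- vapply(arch, function(r) {
    vapply(strsplit(table$species$combo, "+", fixed = TRUE),
           function(s) as.integer(r %in% s), integer(1))
  }, integer(nrow(table$species)))
  pres <- matrix(pres, nrow = nrow(table$species))
  df <- tibble::as_tibble(as.data.frame(pres))
  names(df) <- arch
  df <- dplyr::bind_cols(
    tibble::tibble(species = table$species$species,
                   endemic_scope = table$species$combo),
    df
  )
  as_checklist(df, regions = arch, taxon_group = taxon_group)
}

#' Build a shared-endemics checklist from combination counts
#'
#' Expands printed per-combination counts ("27 species occur in
#' MAD+SEL+CAN") into an explicit presence/absence checklist of synthetic
#' species names, so that published combination tables can be re-analysed
#' through the same pipeline as raw checklists.
#'
#' @param combos data frame with columns `combo` (plus-separated
#'   archipelago labels) and `n` (species count)
#' @param archipelagos ordered archipelago labels; defaults to the labels
#'   appearing in `combos`
#' @param taxon_group group label for the checklist
#' @return a checklist with one synthetic species per counted occurrence
#' @export
checklist_from_combos <- function(combos, archipelagos = NULL,
                                  taxon_group = "other") {
  combos <- tibble::as_tibble(combos)
  stopifnot(all(c("combo", "n") %in% names(combos)))
  sets <- strsplit(combos$combo, "+", fixed = TRUE)
  if (is.null(archipelagos)) archipelagos <- unique(unlist(sets))
  if (any(lengths(sets) < 2)) {
    abort_archipel("each combination must span at least 2 archipelagos",
                   "archipel_validation_error")
  }
  rows <- purrr::map2_dfr(combos$combo, combos$n, function(cb, n) {
    if (n == 0) return(NULL)
    tibble::tibble(species = sprintf("%s_sp%03d", gsub("+", "", cb, fixed = TRUE),
                                     seq_len(n)),
                   endemic_scope = cb)
  })
  for (r in archipelagos) {
    rows[[r]] <- vapply(strsplit(rows$endemic_scope, "+", fixed = TRUE),
                        function(s) as.integer(r %in% s), integer(1))
  }
  cl <- as_checklist(rows, regions = archipelagos, taxon_group = taxon_group)
  # canonicalize scope order to the archipelago order
  cl$endemic_scope <- vapply(strsplit(cl$endemic_scope, "+", fixed = TRUE),
                             function(s) paste(archipelagos[archipelagos %in% s],
                                               collapse = "+"), character(1))
  cl
}

#' Occupancy summary from printed per-group occupancy counts
#'
#' Aggregates a table of shared-endemic occupancy counts (rows: taxon
#' group, columns: occupancy class, count) into per-group and pooled
#' percentages. This is the audit path for published occupancy tables: the
#' pooled row is the column-sum of the per-group rows.
#'
#' @param counts data frame with columns `group`, `occupancy`, `n`
#' @return tibble with columns `group`, `occupancy`, `n`, `pct` including a
#'   pooled `"all"` group
#' @export
occupancy_from_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("group", "occupancy", "n") %in% names(counts)))
  pooled <- counts |>
    dplyr::group_by(.data$occupancy) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(group = "all")
  out <- dplyr::bind_rows(counts, pooled) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(pct = if (sum(.data$n) > 0)
      round_half_up(100 * .data$n / sum(.data$n), 1) else NA_real_) |>
    dplyr::ungroup()
  out[, c("group", "occupancy", "n", "pct")]
}
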