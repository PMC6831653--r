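#' @importFrom rlang .data
NULL

# metadata columns every checklist carries, in canonical order
CHECKLIST_META_COLS <- c(
  "species", "taxon_group", "family", "genus",
  "depth_min_m", "depth_max_m", "status", "endemic_scope"
)

#' Recognized taxon groups and status flags
#'
#' `taxon_groups()` lists the marine groups a checklist may declare;
#' `status_flags()` lists the per-species status flags understood by
#' [apply_status_filter()]. Pelagic, bathypelagic, deep-water, exclusively
#' anchialine, introduced and dubious records are the categories routinely
#' excluded from littoral biogeographic checklists before analysis.
#'
#' @return character vector
#' @export
taxon_groups <- function() {
  c("fishes", "echinoderms", "gastropods", "brachyurans",
    "polychaetes", "macroalgae", "other")
}

#' @rdname taxon_groups
#' @export
status_flags <- function() {
  c("pelagic", "bathypelagic", "deep_water", "anchialine",
    "introduced", "dubious")
}

#' Build a checklist from a data frame
#'
#' A checklist is a tibble with one row per species: the metadata columns
#' `species`, `taxon_group`, `family`, `genus`, `depth_min_m`, `depth_max_m`,
#' `status` (semicolon-separated flags), `endemic_scope` (blank, a single
#' region label, or plus-separated labels for endemics shared between
#' regions), followed by one 0/1 presence column per geographic region.
#' Missing metadata columns are added as `NA`. Presence columns must be
#' strictly binary; anything else is rejected rather than coerced.
#'
#' @param df data frame with metadata and presence columns
#' @param regions character vector naming the presence columns, in order.
#'   Defaults to every non-metadata column.
#' @param taxon_group optional group label applied when the column is absent
#' @return a validated checklist tibble (class `archipel_checklist`)
#' @export
#' @examples
#' df <- data.frame(species = c("a", "b"), AZO = c(1, 0), MAD = c(1, 1))
#' as_checklist(df)
as_checklist <- function(df, regions = NULL, taxon_group = NULL) {
  df <- tibble::as_tibble(df)
  if (!"species" %in% names(df)) {
    abort_archipel("checklist needs a `species` column", "archipel_structure_error")
  }
  if (is.null(regions)) {
    regions <- setdiff(names(df), CHECKLIST_META_COLS)
  }
  if (!is.null(taxon_group) && !"taxon_group" %in% names(df)) {
    df$taxon_group <- taxon_group
  }
  for (col in setdiff(CHECKLIST_META_COLS, names(df))) {
    df[[col]] <- if (col %in% c("depth_min_m", "depth_max_m")) NA_real_ else NA_character_
  }
  df$species <- as.character(df$species)
  for (col in c("taxon_group", "family", "genus", "status", "endemic_scope")) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in c("depth_min_m", "depth_max_m")) df[[col]] <- as.double(df[[col]])
  for (r in regions) {
    v <- df[[r]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (any(is.na(v)) || !all(v %in% c(0, 1))) {
      bad <- which(is.na(v) | !(v %in% c(0, 1)))[1]
      abort_archipel(
        sprintf("presence column '%s' has a non-binary cell at species '%s'",
                r, df$species[bad]),
        "archipel_parse_error"
      )
    }
    df[[r]] <- as.integer(v)
  }
  df <- df[, c(CHECKLIST_META_COLS, regions)]
  out <- structure(df,
    regions = regions,
    class = c("archipel_checklist", class(df))
  )
  validate_checklist(out)
}

#' @export
#' @rdname as_checklist
#' @param x object to test
is_checklist <- function(x) inherits(x, "archipel_checklist")

#' Region labels of a checklist
#' @param c a checklist
#' @return character vector of region labels, in column order
#' @export
regions <- function(c) attr(c, "regions")

validate_checklist <- function(c) {
  regs <- regions(c)
  if (length(regs) < 2) {
    abort_archipel("a checklist needs at least 2 region columns",
                   "archipel_structure_error")
  }
  if (anyDuplicated(regs)) {
    abort_archipel("region labels must be unique", "archipel_structure_error")
  }
  if (any(!nzchar(c$species) | is.na(c$species))) {
    abort_archipel("species names must be nonempty", "archipel_validation_error")
  }
  if (anyDuplicated(c$species)) {
    dup <- c$species[duplicated(c$species)][1]
    abort_archipel(
      sprintf("duplicate species name within one checklist: '%s'", dup),
      "archipel_validation_error"
    )
  }
  grp <- unique(c$taxon_group[!is.na(c$taxon_group)])
  if (length(grp) > 1) {
    abort_archipel("a checklist holds a single taxon group; split the input",
                   "archipel_validation_error")
  }
  bad_depth <- !is.na(c$depth_min_m) & !is.na(c$depth_max_m) &
    c$depth_min_m > c$depth_max_m
  if (any(bad_depth)) {
    abort_archipel(
      sprintf("depth_min_m > depth_max_m for species '%s'",
              c$species[bad_depth][1]),
      "archipel_validation_error"
    )
  }
  if (nrow(c) > 0) {
    zero <- rowSums(as.matrix(c[, regs])) == 0
    if (any(zero)) {
      rlang::warn(sprintf(
        "%d species present in no region (retained, flagged): %s",
        sum(zero), paste(utils::head(c$species[zero], 3), collapse = ", ")
      ), class = "archipel_all_zero_rows")
    }
  }
  c
}

# keep the class/attributes through dplyr-style row subsetting
checklist_keep <- function(c, keep_rows, regions_keep = NULL) {
  regs <- regions_keep %||% regions(c)
  df <- tibble::as_tibble(c)[keep_rows, c(CHECKLIST_META_COLS, regs)]
  structure(df, regions = regs,
            class = c("archipel_checklist", class(tibble::tibble())))
}

#' Presence/absence matrix of a checklist
#'
#' @param c a checklist
#' @return integer matrix, regions in rows, species in columns
#' @export
presence_matrix <- function(c) {
  regs <- regions(c)
  m <- t(as.matrix(tibble::as_tibble(c)[, regs]))
  dimnames(m) <- list(regs, c$species)
  storage.mode(m) <- "integer"
  m
}

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a species checklist from delimited text
#'
#' Expects one species per row with the metadata columns of [as_checklist()]
#' and at least two region presence columns. Presence cells are parsed
#' strictly: `0`, `1`, or blank (blank is recorded as absence, with a
#' warning). Blank metadata stays missing, never zero.
#'
#' @param path file path to a TSV/CSV checklist
#' @param delim field delimiter; inferred from the extension when `NULL`
#'   (`.csv` comma, otherwise tab)
#' @return a checklist tibble
#' @export
read_checklist <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort_archipel(sprintf("no such file: %s", path), "archipel_io_error")
  }
  delim <- infer_delim(path, delim)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE, show_col_types = FALSE)
  if (!"species" %in% names(df)) {
    abort_archipel("header must name a `species` column", "archipel_structure_error")
  }
  regs <- setdiff(names(df), CHECKLIST_META_COLS)
  if (length(regs) < 2) {
    abort_archipel("fewer than 2 region columns in header", "archipel_structure_error")
  }
  blank_to_na <- function(v) ifelse(nzchar(v), v, NA_character_)
  for (col in intersect(CHECKLIST_META_COLS, names(df))) {
    df[[col]] <- blank_to_na(df[[col]])
  }
  for (col in intersect(c("depth_min_m", "depth_max_m"), names(df))) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad)) {
      abort_archipel(
        sprintf("malformed %s '%s' at species '%s'",
                col, v[bad][1], df$species[bad][1]),
        "archipel_parse_error"
      )
    }
    df[[col]] <- num
  }
  n_blank <- 0L
  for (r in regs) {
    v <- df[[r]]
    ok <- v %in% c("0", "1", "", NA)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      abort_archipel(
        sprintf("malformed presence cell '%s' at species '%s', region column '%s'",
                v[bad], df$species[bad], r),
        "archipel_parse_error"
      )
    }
    blank <- !nzchar(v) | is.na(v)
    n_blank <- n_blank + sum(blank)
    df[[r]] <- as.integer(ifelse(blank, 0L, as.integer(v)))
  }
  if (n_blank > 0) {
    rlang::warn(sprintf("%d blank presence cells read as absence (0)", n_blank))
  }
  as_checklist(df, regions = regs)
}

#' Write a checklist to delimited text
#'
#' Inverse of [read_checklist()]: fixed column order (metadata, then regions),
#' blanks for missing metadata, so that write-then-read reproduces the
#' checklist exactly and output is byte-stable.
#'
#' @param c a checklist
#' @param path output file path
#' @param delim field delimiter; inferred from the extension when `NULL`
#' @return `path`, invisibly
#' @export
write_checklist <- function(c, path, delim = NULL) {
  delim <- infer_delim(path, delim)
  readr::write_delim(tibble::as_tibble(c), path, delim = delim, na = "")
  invisible(path)
}

#' Filter a checklist by shallow depth limit
#'
#' Retains species whose shallow limit of occurrence (`depth_min_m`) lies at
#' or above the isobath `max_depth_m` — a species living 10-300 m is
#' reachable from the littoral zone and is kept under a 50 m threshold.
#' Species with missing depth are retained with a warning: expert-curated
#' checklists often omit depth, and absence of a record must not silently
#' delete data.
#'
#' @param c a checklist
#' @param max_depth_m positive isobath threshold in metres (conventionally
#'   50 for gastropods and macroalgae, 200 for fishes, echinoderms,
#'   brachyurans and polychaetes)
#' @return the filtered checklist
#' @export
apply_depth_filter <- function(c, max_depth_m) {
  stopifnot(is.numeric(max_depth_m), length(max_depth_m) == 1, max_depth_m > 0)
  missing_depth <- is.na(c$depth_min_m)
  keep <- missing_depth | c$depth_min_m <= max_depth_m
  if (any(missing_depth & keep)) {
    rlang::warn(sprintf("%d species with missing depth retained",
                        sum(missing_depth)), class = "archipel_missing_depth")
  }
  rlang::inform(sprintf("depth filter (<= %g m): removed %d of %d species",
                        max_depth_m, sum(!keep), nrow(c)))
  checklist_keep(c, keep)
}

parse_status <- function(status) {
  strsplit(as.character(ifelse(is.na(status), "", status)), ";", fixed = TRUE)
}

#' Filter a checklist by status flags
#'
#' Removes species whose status flags intersect `excluded`. The standard
#' exclusion set for littoral biogeography drops pelagic, bathypelagic,
#' deep-water, exclusively anchialine and introduced species.
#'
#' @param c a checklist
#' @param excluded character vector of flags, a subset of [status_flags()]
#' @return the filtered checklist
#' @export
apply_status_filter <- function(c, excluded = c("pelagic", "bathypelagic",
                                                "deep_water", "anchialine",
                                                "introduced")) {
  unknown <- setdiff(excluded, status_flags())
  if (length(unknown)) {
    abort_archipel(sprintf("unknown status flag(s): %s",
                           paste(unknown, collapse = ", ")),
                   "archipel_config_error")
  }
  flags <- parse_status(c$status)
  drop <- vapply(flags, function(f) length(intersect(f, excluded)) > 0, logical(1))
  per_flag <- vapply(excluded, function(fl)
    sum(vapply(flags, function(f) fl %in% f, logical(1))), integer(1))
  if (length(excluded)) {
    rlang::inform(sprintf(
      "status filter: removed %d species (%s)",
      sum(drop),
      paste(sprintf("%s=%d", excluded, per_flag), collapse = ", ")
    ))
  }
  checklist_keep(c, !drop)
}

#' Restrict a checklist to a subset of regions
#'
#' Presence columns are restricted to `keep` (in the given order); species
#' absent from every kept region are dropped, with a message.
#'
#' @param c a checklist
#' @param keep ordered character vector of region labels, length >= 2
#' @return the restricted checklist
#' @export
subset_regions <- function(c, keep) {
  unknown <- setdiff(keep, regions(c))
  if (length(unknown)) {
    abort_archipel(sprintf("unknown region label(s): %s",
                           paste(unknown, collapse = ", ")),
                   "archipel_config_error")
  }
  if (length(keep) < 2) {
    abort_archipel("keep at least 2 regions", "archipel_structure_error")
  }
  pres <- as.matrix(tibble::as_tibble(c)[, keep, drop = FALSE])
  keep_rows <- rowSums(pres) > 0
  if (any(!keep_rows)) {
    rlang::inform(sprintf("subset_regions: dropped %d species absent from kept regions",
                          sum(!keep_rows)))
  }
  checklist_keep(c, keep_rows, regions_keep = keep)
}

#' Rename regions via an alias table
#'
#' Region label matching elsewhere in the package is exact and
#' case-sensitive; this helper maps alias labels onto canonical ones before
#' analysis.
#'
#' @param c a checklist
#' @param aliases named character vector, `c(alias = "canonical")`
#' @return the relabelled checklist
#' @export
normalize_regions <- function(c, aliases) {
  regs <- regions(c)
  hit <- regs %in% names(aliases)
  new <- regs
  new[hit] <- unname(aliases[regs[hit]])
  df <- tibble::as_tibble(c)
  names(df)[match(regs, names(df))] <- new
  as_checklist(df, regions = new)
}

#' @export
print.archipel_checklist <- function(x, ...) {
  grp <- unique(x$taxon_group[!is.na(x$taxon_group)])
  cat(sprintf("# A checklist: %d species x %d regions (%s)\n",
              nrow(x), length(regions(x)),
              if (length(grp)) grp[1] else "unlabelled"))
  NextMethod()
}
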