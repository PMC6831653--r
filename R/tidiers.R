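#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dendrogram into its merge table
#'
#' @param x an `archipel_dendro`
#' @param ... unused
#' @return tibble with one row per internal node: `node`, `height`,
#'   `support` (when attached), and the member leaves as a
#'   plus-separated string
#' @method tidy archipel_dendro
#' @export
tidy.archipel_dendro <- function(x, ...) {
  sets <- dendro_leafsets(x)
  tibble::tibble(
    node = seq_along(x$height),
    height = x$height,
    support = if (is.null(x$support)) NA_real_ else x$support,
    leaves = vapply(sets, paste, character(1), collapse = "+")
  )
}

#' @method glance archipel_dendro
#' @export
glance.archipel_dendro <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(x$labels),
    method = x$method,
    index = x$index %||% NA_character_,
    inversions = isTRUE(x$inversions),
    min_support = if (is.null(x$support)) NA_real_ else min(x$support),
    n_replicates = attr(x, "n_replicates") %||% NA_integer_
  )
}

#' @method tidy archipel_model_selection
#' @export
tidy.archipel_model_selection <- function(x, ...) x$grid

#' @method glance archipel_model_selection
#' @export
glance.archipel_model_selection <- function(x, ...) x$best

#' @method tidy archipel_optimal_k
#' @export
tidy.archipel_optimal_k <- function(x, ...) x$profile

#' @method glance archipel_optimal_k
#' @export
glance.archipel_optimal_k <- function(x, ...) {
  tibble::tibble(criterion = x$criterion, k_best = x$k_best,
                 score_best = x$score_best)
}

#' @method tidy archipel_provincial_index
#' @export
tidy.archipel_provincial_index <- function(x, ...) {
  dplyr::mutate(x$families, region = x$region)
}

#' @method glance archipel_provincial_index
#' @export
glance.archipel_provincial_index <- function(x, ...) {
  tibble::tibble(region = x$region,
                 pct = x$pct,
                 pct_reported = round_half_up(x$pct, 1),
                 status = x$status)
}

#' @method tidy archipel_shared_endemics
#' @export
tidy.archipel_shared_endemics <- function(x, ...) x$species

#' @method glance archipel_shared_endemics
#' @export
glance.archipel_shared_endemics <- function(x, ...) {
  tibble::tibble(n_shared = nrow(x$species),
                 n_archipelagos = length(x$archipelagos),
                 max_occupancy = if (nrow(x$species)) max(x$species$occupancy)
                                 else NA_integer_)
}

#' @method tidy archipel_report
#' @export
tidy.archipel_report <- function(x, ...) x$selection$grid

#' @method glance archipel_report
#' @export
glance.archipel_report <- function(x, ...) {
  tibble::tibble(
    taxon_group = x$taxon_group,
    n_species = x$log$n_species[nrow(x$log)],
    best_index = x$selection$best$index,
    best_linkage = x$selection$best$linkage,
    cophenetic_r = x$selection$best$cophenetic_r,
    k_silhouette = x$optimal_silhouette$k_best,
    k_mantel = x$optimal_mantel$k_best
  )
}
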