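#' Collapse an allele table to a non-redundant set
#'
#' Conservative coordinate-based deduplication: only alleles more than
#' `max_sep` bp apart are considered unique. Within each chromosome,
#' alleles are sorted by (position, allele number) and chained by single
#' linkage — an allele joins the current cluster iff it lies within
#' `max_sep` bp of the previous allele in sorted order. Each cluster keeps
#' the allele with the lowest allele number as representative (the choice
#' among coincident alleles is arbitrary; the earliest-isolated one is
#' kept); all other members are redundant.
#'
#' @param alleles Allele tibble (columns `allele_name`, `allele_number`,
#'   `chrom`, `position`, ...). Duplicate allele names are an error.
#' @param max_sep Maximum separation in bp (default 10).
#' @return The allele tibble with added columns `cluster` (id, unique
#'   across chromosomes), `is_unique` (logical) and `representative` (name
#'   of the cluster representative).
#' @examples
#' tbl <- tibble::tibble(
#'   allele_name = c("ttTi5", "ttTi300", "ttTi400"),
#'   allele_number = c(5L, 300L, 400L),
#'   chrom = "I", position = c(1000L, 1008L, 1020L), precise = TRUE,
#'   strain_id = NA_character_, plate_id = NA_character_)
#' collapse_alleles(tbl)  # ttTi300 collapses onto ttTi5; ttTi400 is unique
#' @export
collapse_alleles <- function(alleles, max_sep = 10L) {
  if (anyDuplicated(alleles$allele_name)) {
    dup <- alleles$allele_name[duplicated(alleles$allele_name)][1]
    stop("duplicate allele name `", dup, "`", call. = FALSE)
  }
  if (nrow(alleles) == 0) {
    return(dplyr::mutate(alleles, cluster = integer(), is_unique = logical(),
                         representative = character()))
  }
  alleles |>
    dplyr::arrange(.data$chrom, .data$position, .data$allele_number) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      .gap = .data$position - dplyr::lag(.data$position),
      .new = is.na(.data$.gap) | .data$.gap > max_sep
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(cluster = cumsum(.data$.new)) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(
      representative = .data$allele_name[which.min(.data$allele_number)],
      is_unique = .data$allele_name == .data$representative
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".gap", -".new")
}

#' Classify redundant alleles against their representatives
#'
#' Summarizes a collapsed allele table the way the published redundancy
#' analysis did: how many redundant alleles sit at exactly the same
#' coordinate as a non-redundant allele, and how many of those carry an
#' allele number within `proximity` of their representative's — the
#' signature of plate-local cross-contamination, since allele numbers
#' record isolation history and strains were handled in 24-well plates.
#'
#' @param collapsed Output of [collapse_alleles()].
#' @param proximity Allele-number difference bound (default 25, strict).
#' @return An object of class `mos_redundancy`: counts (`n_total`,
#'   `n_unique`, `n_redundant`, `n_exact_match`, `n_exact_and_proximal`)
#'   and a `pairs` tibble (`allele_name`, `representative`,
#'   `coord_distance`, `number_distance`, `exact`, `proximal`). Use
#'   [generics::tidy()] for the pairs and [generics::glance()] for the
#'   counts.
#' @export
classify_redundant <- function(collapsed, proximity = 25L) {
  red <- dplyr::filter(collapsed, !.data$is_unique)
  rep_tbl <- collapsed |>
    dplyr::filter(.data$is_unique) |>
    dplyr::select(representative = "allele_name",
                  rep_number = "allele_number", rep_position = "position")
  pairs <- red |>
    dplyr::left_join(rep_tbl, by = "representative") |>
    dplyr::transmute(
      allele_name = .data$allele_name,
      representative = .data$representative,
      coord_distance = abs(.data$position - .data$rep_position),
      number_distance = abs(.data$allele_number - .data$rep_number),
      exact = .data$coord_distance == 0L,
      proximal = .data$exact & .data$number_distance < proximity
    )
  structure(list(
    n_total = nrow(collapsed),
    n_unique = sum(collapsed$is_unique),
    n_redundant = nrow(pairs),
    n_exact_match = sum(pairs$exact),
    n_exact_and_proximal = sum(pairs$proximal),
    proximity = as.integer(proximity),
    pairs = pairs
  ), class = "mos_redundancy")
}

#' @export
print.mos_redundancy <- function(x, ...) {
  cat("<mos_redundancy>\n")
  cat(sprintf("  %d alleles: %d unique + %d redundant\n",
              x$n_total, x$n_unique, x$n_redundant))
  cat(sprintf("  exact coordinate matches: %d; of these, %d with allele-number difference < %d\n",
              x$n_exact_match, x$n_exact_and_proximal, x$proximity))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy mos_redundancy
#' @export
tidy.mos_redundancy <- function(x, ...) {
  x$pairs
}

#' @importFrom generics glance
#' @method glance mos_redundancy
#' @export
glance.mos_redundancy <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total, n_unique = x$n_unique, n_redundant = x$n_redundant,
    n_exact_match = x$n_exact_match,
    n_exact_and_proximal = x$n_exact_and_proximal
  )
}
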