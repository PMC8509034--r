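# Cross-region set comparison of flagged proteins.

# Normalise the various accepted inputs to a tibble(region, accession)
# of flagged members plus the full region roster (a region with an empty
# flagged set still counts as a region).
as_region_membership <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("region", "accession") %in% names(x))) {
      plf_abort("expected columns `region` and `accession`", "bad_argument")
    }
    regions <- sort(unique(x$region))
    y <- x
    if ("flagged" %in% names(y)) y <- filter(y, .data$flagged)
    list(members = distinct(as_tibble(y), .data$region, .data$accession),
         regions = regions)
  } else if (is.list(x) && !is.null(names(x))) {
    list(members = tibble(region = rep(names(x), lengths(x)),
                          accession = unlist(x, use.names = FALSE)) |>
           distinct(.data$region, .data$accession),
         regions = sort(names(x)))
  } else {
    plf_abort("expected a data frame with region/accession columns or a named list of accession vectors",
              "bad_argument")
  }
}

#' Intersect per-region flagged-protein sets
#'
#' Enumerates every Venn cell (all `2^k - 1` region combinations for k
#' regions) of the per-region flagged-protein sets, together with the
#' all-region intersection, the per-region exclusive sets and the union.
#'
#' @param x Either a protein-level summary with columns `region`,
#'   `accession` and (optionally) logical `flagged` — e.g. the output of
#'   [flag_significant_proteins()], which is filtered to flagged rows —
#'   or a named list of accession character vectors, one per region.
#' @return An object of class `plf_region_sets`: a list with `cells`
#'   (tibble of every Venn cell: `cell` label, `n_regions`, `count`,
#'   list-column `accessions`), `sets` (the per-region input sets),
#'   `shared_all`, `exclusive` (named list) and `union`.
#' @examples
#' intersect_regions(list(
#'   posterior = c("A", "B", "C"),
#'   lateral = c("B", "C", "D"),
#'   anterior = c("C", "E")
#' ))
#' @export
intersect_regions <- function(x) {
  parsed <- as_region_membership(x)
  members <- parsed$members
  regions <- parsed$regions
  if (length(regions) < 2) {
    plf_abort("region intersection requires >= 2 regions", "too_few_regions")
  }
  sets <- map(regions, function(r) sort(members$accession[members$region == r]))
  names(sets) <- regions
  # Venn cell of an accession = the exact combination of regions holding it.
  cell_of <- members |>
    summarise(cell = paste(sort(unique(.data$region)), collapse = "&"),
              n_regions = n_distinct(.data$region),
              .by = "accession")
  all_cells <- unlist(map(seq_along(regions), function(k) {
    apply(combn(regions, k), 2, paste, collapse = "&")
  }))
  observed <- cell_of |>
    summarise(count = n(),
              accessions = list(sort(.data$accession)),
              .by = c("cell", "n_regions"))
  cells <- tibble(cell = all_cells,
                  n_regions = lengths(strsplit(all_cells, "&", fixed = TRUE))) |>
    left_join(select(observed, "cell", "count", "accessions"), by = "cell") |>
    mutate(count = coalesce(.data$count, 0L),
           accessions = map(.data$accessions, function(a) a %||% character(0))) |>
    arrange(.data$n_regions, .data$cell)
  exclusive <- map(regions, function(r) {
    sort(cell_of$accession[cell_of$cell == r])
  })
  names(exclusive) <- regions
  structure(
    list(
      cells = cells,
      sets = sets,
      shared_all = sort(cell_of$accession[cell_of$n_regions == length(regions)]),
      exclusive = exclusive,
      union = sort(unique(members$accession))
    ),
    class = "plf_region_sets"
  )
}

#' @export
print.plf_region_sets <- function(x, ...) {
  cat("PLF region sets (", length(x$sets), " regions)\n", sep = "")
  for (r in names(x$sets)) {
    cat("  ", r, ": ", length(x$sets[[r]]), " flagged (",
        length(x$exclusive[[r]]), " exclusive)\n", sep = "")
  }
  cat("  shared by all regions: ", length(x$shared_all), "\n", sep = "")
  cat("  union: ", length(x$union), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.plf_region_sets <- function(x, ...) {
  x$cells
}

#' Proteins found only by location fingerprinting
#'
#' Set difference between the PLF-flagged union and a list of proteins
#' significant by abundance-based quantification: the proteins whose
#' structural difference is invisible to whole-protein abundance
#' comparison.
#'
#' @param plf_union Character vector of PLF-flagged accessions, or a
#'   `plf_region_sets` object (its union is used).
#' @param abundance_significant Character vector of accessions
#'   significant by abundance-based quantification.
#' @return Character vector of accessions unique to the PLF approach.
#'   Warns when the two non-empty input sets share no accession at all,
#'   which usually indicates mismatched identifier schemes.
#' @export
plf_unique <- function(plf_union, abundance_significant) {
  if (inherits(plf_union, "plf_region_sets")) plf_union <- plf_union$union
  plf_union <- unique(as.character(plf_union))
  abundance_significant <- unique(as.character(abundance_significant))
  if (length(plf_union) > 0 && length(abundance_significant) > 0 &&
      length(intersect(plf_union, abundance_significant)) == 0) {
    plf_warn("the PLF and abundance sets share no accession; check that both use the same identifier scheme",
             "zero_overlap")
  }
  sort(setdiff(plf_union, abundance_significant))
}
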