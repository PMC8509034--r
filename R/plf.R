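# End-to-end PLF analysis wrapper and its broom-style methods.

#' Peptide location fingerprinting analysis
#'
#' Runs the full analysis on peptide records and a protein table: locate
#' peptides, aggregate spectral counts into fixed-size segments per
#' (protein, region), normalise each sample's whole-protein count to the
#' experiment-wide median, test every segment between the two groups with
#' per-protein Bonferroni correction, build aged-minus-young difference
#' profiles, flag proteins with at least one significant segment, and —
#' when at least two regions are present — scale the profiles of shared
#' proteins for cross-region composite overlay.
#'
#' @param peptides Peptide record tibble ([read_peptide_table()] or
#'   [simulate_study()]`$peptides`).
#' @param proteins Protein table ([read_protein_fasta()]).
#' @param samples Optional declared design (`region`, `sample_id`,
#'   `group`); defaults to the samples observed in `peptides`.
#' @param nominal_size Segment size in residues (default 50).
#' @param groups The two group labels, reference (young role) first.
#' @param alpha_levels Star-annotation thresholds (default
#'   `c(0.05, 0.01, 0.001)`).
#' @param alpha Protein-flagging threshold on corrected p (default 0.05).
#' @param tail_mode Divisor for difference profiles: actual tail-segment
#'   length (`"actual"`, default) or the nominal size everywhere
#'   (`"strict"`).
#' @param occurrence_policy Within-protein multi-occurrence policy, see
#'   [locate_peptides()].
#' @return An object of class `plf_analysis`: a list with
#'   `segment_tests`, `protein_summary`, `differences`, `composite`
#'   (`NULL` for a single region), `normalized`, `exclusions` (every
#'   dropped sample or protein with a reason code) and `params`.
#'   [tidy()] returns the segment-level table, [glance()] the
#'   protein-level summary.
#' @export
plf <- function(peptides, proteins, samples = NULL, nominal_size = 50,
                groups = c("young", "aged"),
                alpha_levels = c(0.05, 0.01, 0.001), alpha = 0.05,
                tail_mode = c("actual", "strict"),
                occurrence_policy = c("first", "all", "error")) {
  tail_mode <- match.arg(tail_mode)
  occurrence_policy <- match.arg(occurrence_policy)
  peptides <- validate_peptide_records(peptides, groups = groups)
  located <- locate_peptides(peptides, proteins, occurrence_policy)
  counts <- count_segments(located, proteins, samples, nominal_size)
  normalized <- normalize_segments(counts)
  tests <- test_segments(normalized, groups, alpha_levels, tail_mode,
                         nominal_size)
  differences <- suppressWarnings(
    difference_profiles(normalized, groups, tail_mode, nominal_size)
  )
  summary <- flag_significant_proteins(tests, alpha)
  composite <- if (n_distinct(counts$region) >= 2) {
    composite_scale(differences)
  } else NULL
  exclusions <- bind_rows(
    attr(normalized, "absences") |>
      mutate(reason = "zero_total_sample"),
    attr(tests, "exclusions") |>
      mutate(sample_id = NA_character_, group = NA_character_)
  ) |>
    select("region", "accession", "sample_id", "group", "reason") |>
    arrange(.data$region, .data$accession)
  structure(
    list(
      segment_tests = tests,
      protein_summary = summary,
      differences = differences,
      composite = composite,
      normalized = normalized,
      exclusions = exclusions,
      params = list(nominal_size = nominal_size, groups = groups,
                    alpha_levels = alpha_levels, alpha = alpha,
                    tail_mode = tail_mode,
                    occurrence_policy = occurrence_policy)
    ),
    class = "plf_analysis"
  )
}

#' @export
print.plf_analysis <- function(x, ...) {
  regions <- unique(x$protein_summary$region)
  cat("PLF analysis: ", length(regions), " region(s), ",
      n_distinct(x$segment_tests$accession), " tested protein(s)\n", sep = "")
  for (r in regions) {
    s <- filter(x$protein_summary, .data$region == r)
    cat("  ", r, ": ", sum(s$flagged), " / ", nrow(s),
        " proteins flagged (corrected p <= ", x$params$alpha, ")\n", sep = "")
  }
  if (nrow(x$exclusions) > 0) {
    cat("  exclusions: ", nrow(x$exclusions), " (see $exclusions)\n", sep = "")
  }
  invisible(x)
}

#' @describeIn plf Segment-level test results as a tibble.
#' @param x A `plf_analysis` object.
#' @param ... Unused.
#' @export
tidy.plf_analysis <- function(x, ...) {
  x$segment_tests
}

#' @describeIn plf Protein-level summary as a tibble.
#' @export
glance.plf_analysis <- function(x, ...) {
  x$protein_summary
}

#' Plot the segment profile of one protein
#'
#' Group mean normalised counts per segment (bars with standard-deviation
#' error bars), with significance stars above segments reaching the
#' corrected thresholds, faceted by tissue region.
#'
#' @param object A `plf_analysis` object.
#' @param accession Protein to plot.
#' @param regions Optional subset of regions.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plf_analysis <- function(object, accession, regions = NULL, ...) {
  d <- filter(object$segment_tests, .data$accession == !!accession)
  if (!is.null(regions)) d <- filter(d, .data$region %in% regions)
  if (nrow(d) == 0) {
    plf_abort(paste0("no tested segments for accession ", accession),
              "unknown_accession")
  }
  groups <- object$params$groups
  long <- bind_rows(
    d |> transmute(.data$region, .data$segment, group = groups[1],
                   mean = .data$mean_young, sd = .data$sd_young),
    d |> transmute(.data$region, .data$segment, group = groups[2],
                   mean = .data$mean_aged, sd = .data$sd_aged)
  )
  stars <- d |>
    filter(.data$stars != "") |>
    mutate(y = pmax(.data$mean_young, .data$mean_aged) * 1.12)
  ggplot(long, aes(x = factor(.data$segment), y = .data$mean,
                   fill = .data$group)) +
    geom_col(position = position_dodge(width = 0.9), width = 0.8) +
    geom_errorbar(aes(ymin = pmax(.data$mean - .data$sd, 0),
                      ymax = .data$mean + .data$sd),
                  position = position_dodge(width = 0.9), width = 0.3,
                  linewidth = 0.3) +
    geom_text(data = stars, aes(x = factor(.data$segment), y = .data$y,
                                label = .data$stars),
              inherit.aes = FALSE, vjust = 0) +
    facet_wrap(~region, ncol = 1) +
    labs(x = "50-aa segment", y = "Mean normalised spectral count",
         fill = NULL, title = accession) +
    theme_minimal()
}

#' Plot difference profiles along a protein
#'
#' Line plot of the aged-minus-young per-residue peptide-yield difference
#' per segment, one line per tissue region. With `composite = TRUE`
#' (default when the analysis covers several regions) each region's
#' profile is max-absolute scaled onto `[-1, 1]` for overlay.
#'
#' @param object A `plf_analysis` object.
#' @param accession Protein to plot.
#' @param composite Use the composite-scaled profiles (default when
#'   available).
#' @return A ggplot object.
#' @export
plot_difference_profile <- function(object, accession,
                                    composite = !is.null(object$composite)) {
  d <- if (composite) {
    if (is.null(object$composite)) {
      plf_abort("composite requires >= 2 regions", "composite_regions")
    }
    object$composite |> mutate(value = .data$scaled)
  } else {
    object$differences |> mutate(value = .data$diff)
  }
  d <- filter(d, .data$accession == !!accession)
  if (nrow(d) == 0) {
    plf_abort(paste0("no difference profile for accession ", accession),
              "unknown_accession")
  }
  ggplot(d, aes(x = .data$segment, y = .data$value, colour = .data$region)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "50-aa segment",
         y = if (composite) "Scaled yield difference (aged - young)"
             else "Yield difference per residue (aged - young)",
         colour = "Region", title = accession) +
    theme_minimal()
}
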