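# The statistical core: group summaries, difference profiles, per-segment
# tests with per-protein Bonferroni correction, protein flagging, and
# cross-region composite scaling.
#
# Throughout, `groups` names the two study groups with the REFERENCE group
# first; result columns use the young/aged role names of the two-group
# ageing design (element 1 -> "young", element 2 -> "aged"), and the
# difference sign convention is positive = higher peptide yield in the
# second (aged) group.

# Star annotation for corrected p-values. alpha_levels are the three
# thresholds (single, double, triple star), decreasing.
star_annotation <- function(p, alpha_levels = c(0.05, 0.01, 0.001)) {
  a <- sort(as.numeric(alpha_levels), decreasing = TRUE)
  out <- rep("", length(p))
  out[!is.na(p) & p <= a[1]] <- "*"
  out[!is.na(p) & p <= a[2]] <- "**"
  out[!is.na(p) & p <= a[3]] <- "***"
  out
}

# Per-(region, protein) retained-sample census and the exclusion rules
# that depend on it: proteins present in only one group are excluded
# entirely; proteins with a single retained sample in a group cannot be
# tested (no within-group variance).
unit_census <- function(normalized, groups) {
  normalized |>
    distinct(.data$region, .data$accession, .data$group, .data$sample_id) |>
    count(.data$region, .data$accession, .data$group, name = "n_samples") |>
    summarise(
      n_groups = n_distinct(.data$group),
      min_n = min(.data$n_samples),
      .by = c("region", "accession")
    ) |>
    mutate(reason = case_when(
      .data$n_groups < 2 ~ "one_group",
      .data$min_n < 2 ~ "single_sample",
      TRUE ~ NA_character_
    ))
}

# Long per-group per-segment summary used by both the difference profiles
# and the tests. One-group proteins are already removed here.
segment_group_stats <- function(normalized, groups) {
  unknown <- setdiff(unique(normalized$group), groups)
  if (length(unknown) > 0) {
    plf_abort(paste0("unknown group label(s): ", brief(unknown)),
              "unknown_group")
  }
  census <- unit_census(normalized, groups)
  kept <- census |> filter(.data$reason != "one_group" | is.na(.data$reason))
  stats_long <- normalized |>
    semi_join(kept, by = c("region", "accession")) |>
    summarise(
      n = n(),
      mean = mean(.data$norm_count),
      sd = if (n() > 1) sd(.data$norm_count) else NA_real_,
      any_count = any(.data$count > 0),
      .by = c("region", "accession", "segment", "seg_start", "seg_end",
              "seg_length", "group")
    )
  attr(stats_long, "census") <- census
  stats_long
}

# Pivot the long group stats to one row per segment with young/aged role
# columns.
segment_stats_wide <- function(stats_long, groups) {
  role <- c("young", "aged")
  if (nrow(stats_long) == 0) {
    return(tibble(
      region = character(0), accession = character(0), segment = integer(0),
      seg_start = integer(0), seg_end = integer(0), seg_length = integer(0),
      n_young = integer(0), n_aged = integer(0),
      mean_young = numeric(0), mean_aged = numeric(0),
      sd_young = numeric(0), sd_aged = numeric(0),
      testable_segment = logical(0)
    ))
  }
  stats_long |>
    mutate(role = role[match(.data$group, groups)]) |>
    select(-"group") |>
    pivot_wider(names_from = "role",
                values_from = c("n", "mean", "sd", "any_count")) |>
    mutate(testable_segment = coalesce(.data$any_count_young, FALSE) |
             coalesce(.data$any_count_aged, FALSE)) |>
    select(-"any_count_young", -"any_count_aged")
}

#' Per-group, per-segment means and standard deviations
#'
#' Averages normalised segment counts within each group. Proteins
#' retained in only one group (after zero-total sample exclusion) are
#' excluded entirely; the exclusions are attached as the `"exclusions"`
#' attribute, with reasons `"one_group"` or `"single_sample"` (the latter
#' proteins remain in the output but cannot be tested).
#'
#' @param normalized Output of [normalize_segments()].
#' @param groups The two group labels, reference (young role) first.
#' @return A tibble with one row per (region, protein, segment): group
#'   sample sizes, means and standard deviations (`sd` is `NA` for a
#'   single-sample group) under young/aged role names.
#' @export
summarize_groups <- function(normalized, groups = c("young", "aged")) {
  stats_long <- segment_group_stats(normalized, groups)
  census <- attr(stats_long, "census")
  out <- segment_stats_wide(stats_long, groups) |>
    arrange(.data$region, .data$accession, .data$segment)
  attr(out, "exclusions") <- census |>
    filter(!is.na(.data$reason)) |>
    select("region", "accession", "reason")
  out
}

#' Aged-minus-young difference profiles
#'
#' For every segment, the difference of group mean normalised counts
#' (aged minus young) divided by the segment length: the per-residue
#' peptide-yield difference along the primary structure. By default the
#' divisor is the segment's actual residue length (the terminal segment
#' may be shorter than nominal); `tail_mode = "strict"` divides by the
#' nominal size for every segment.
#'
#' Proteins present in only one group are excluded. Proteins with a
#' single retained sample in a group are kept here (a mean needs one
#' value) but trigger a warning since they cannot be tested.
#'
#' @inheritParams summarize_groups
#' @param tail_mode `"actual"` (default) or `"strict"`.
#' @param nominal_size Nominal segment length used by `"strict"` mode.
#' @return A tibble with one row per (region, protein, segment) and a
#'   `diff` column; positive values mean higher peptide yield in aged.
#' @export
difference_profiles <- function(normalized, groups = c("young", "aged"),
                                tail_mode = c("actual", "strict"),
                                nominal_size = 50) {
  tail_mode <- match.arg(tail_mode)
  wide <- summarize_groups(normalized, groups)
  excl <- attr(wide, "exclusions")
  singles <- excl |> filter(.data$reason == "single_sample")
  if (nrow(singles) > 0) {
    plf_warn(paste0(nrow(singles), " protein/region unit(s) have a group with ",
                    "a single retained sample; their difference profiles are ",
                    "reported but they are excluded from testing: ",
                    brief(paste0(singles$accession, "@", singles$region))),
             "single_sample")
  }
  out <- wide |>
    mutate(
      divisor = if (tail_mode == "actual") .data$seg_length else nominal_size,
      diff = (.data$mean_aged - .data$mean_young) / .data$divisor
    ) |>
    select("region", "accession", "segment", "seg_start", "seg_end",
           "seg_length", "mean_young", "mean_aged", "diff")
  attr(out, "exclusions") <- excl
  out
}

#' Per-segment two-group tests with per-protein Bonferroni correction
#'
#' Compares normalised per-sample segment counts between the two groups,
#' segment by segment, with an unpaired pooled-variance comparison: the
#' one-way F statistic with one numerator degree of freedom, identical to
#' the square of the pooled two-sample t statistic, whose two-sided
#' p-value is reported as `raw_p`. Each protein is treated as its own
#' separate experiment: `corrected_p = min(1, raw_p * m)` where `m` is
#' that protein's number of testable segments in the region. Segments
#' with zero counts in every sample of both groups are untestable
#' (`raw_p` `NA`) and excluded from `m`. If all values in a segment are
#' identical across both groups, `raw_p` is 1 by definition.
#'
#' Proteins present in only one group, or with fewer than two retained
#' samples in a group, are excluded from testing; see the `"exclusions"`
#' attribute of the result.
#'
#' @inheritParams difference_profiles
#' @param alpha_levels The three significance thresholds used for star
#'   annotation of `corrected_p` (default `c(0.05, 0.01, 0.001)` for
#'   `*`/`**`/`***`).
#' @return A tibble with one row per (region, protein, segment): group
#'   sizes, means, standard deviations, the per-residue difference
#'   (`diff`), `raw_p`, `corrected_p`, `stars` and `m` (the Bonferroni
#'   family size). Untestable segments carry `NA` p-values and empty
#'   stars.
#' @export
test_segments <- function(normalized, groups = c("young", "aged"),
                          alpha_levels = c(0.05, 0.01, 0.001),
                          tail_mode = c("actual", "strict"),
                          nominal_size = 50) {
  tail_mode <- match.arg(tail_mode)
  stats_long <- segment_group_stats(normalized, groups)
  census <- attr(stats_long, "census")
  testable_units <- census |> filter(is.na(.data$reason))
  wide <- segment_stats_wide(stats_long, groups) |>
    semi_join(testable_units, by = c("region", "accession"))
  out <- wide |>
    mutate(
      pooled_var = ((.data$n_young - 1) * .data$sd_young^2 +
                      (.data$n_aged - 1) * .data$sd_aged^2) /
        (.data$n_young + .data$n_aged - 2),
      df = .data$n_young + .data$n_aged - 2,
      t_stat = (.data$mean_aged - .data$mean_young) /
        sqrt(.data$pooled_var * (1 / .data$n_young + 1 / .data$n_aged)),
      raw_p = case_when(
        !.data$testable_segment ~ NA_real_,
        .data$pooled_var == 0 & .data$mean_aged == .data$mean_young ~ 1,
        .data$pooled_var == 0 ~ 0,
        TRUE ~ 2 * pt(-abs(.data$t_stat), .data$df)
      )
    ) |>
    mutate(m = sum(!is.na(.data$raw_p)), .by = c("region", "accession")) |>
    mutate(
      corrected_p = pmin(1, .data$raw_p * .data$m),
      stars = star_annotation(.data$corrected_p, alpha_levels),
      divisor = if (tail_mode == "actual") .data$seg_length else nominal_size,
      diff = (.data$mean_aged - .data$mean_young) / .data$divisor
    ) |>
    select("region", "accession", "segment", "seg_start", "seg_end",
           "seg_length", "n_young", "n_aged", "mean_young", "mean_aged",
           "sd_young", "sd_aged", "diff", "raw_p", "corrected_p", "stars",
           "m") |>
    arrange(.data$region, .data$accession, .data$segment)
  attr(out, "exclusions") <- census |>
    filter(!is.na(.data$reason)) |>
    select("region", "accession", "reason")
  out
}

#' Flag proteins with at least one significant segment
#'
#' A protein is flagged for a region when at least one of its segments
#' reaches `corrected_p <= alpha` there.
#'
#' @param tests Output of [test_segments()].
#' @param alpha Protein-flagging threshold on the corrected p-value
#'   (default 0.05).
#' @return A protein-level tibble per (region, protein): `n_segments`,
#'   `n_testable`, `min_corrected_p` and logical `flagged`.
#' @export
flag_significant_proteins <- function(tests, alpha = 0.05) {
  tests |>
    summarise(
      n_segments = n(),
      n_testable = sum(!is.na(.data$raw_p)),
      min_corrected_p = if (all(is.na(.data$corrected_p))) NA_real_
        else min(.data$corrected_p, na.rm = TRUE),
      flagged = any(.data$corrected_p <= alpha, na.rm = TRUE),
      .by = c("region", "accession")
    ) |>
    arrange(.data$region, .data$accession)
}

#' Scale difference profiles for cross-region composite overlay
#'
#' Divides each region's difference profile by that region's maximum
#' absolute segment value, mapping every region onto `[-1, 1]` so that
#' profiles from tissue regions with different detection depths can be
#' overlaid. All-zero profiles stay at zero. Only proteins shared by at
#' least two regions are scaled.
#'
#' @param diffs Output of [difference_profiles()] (or [test_segments()];
#'   any tibble with `region`, `accession`, `segment` and `diff`).
#' @return The input restricted to proteins present in `>= 2` regions,
#'   with a `scaled` column added.
#' @export
composite_scale <- function(diffs) {
  if (n_distinct(diffs$region) < 2) {
    plf_abort("composite requires >= 2 regions", "composite_regions")
  }
  multi <- diffs |>
    distinct(.data$region, .data$accession) |>
    count(.data$accession) |>
    filter(.data$n >= 2)
  diffs |>
    semi_join(multi, by = "accession") |>
    mutate(
      max_abs = max(abs(.data$diff)),
      scaled = if_else(.data$max_abs == 0, 0, .data$diff / .data$max_abs),
      .by = c("region", "accession")
    ) |>
    select(-"max_abs")
}
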