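# Whole-protein abundance normalisation of segment counts.

#' Normalise segment counts to the experiment-wide median protein total
#'
#' For each (protein, region) analysis unit, every sample's whole-protein
#' spectrum count (its row total over segments) is rescaled to the
#' experiment-wide median of the positive totals across all samples of
#' both groups. This makes per-segment comparisons independent of
#' whole-protein abundance differences between samples: after
#' normalisation every retained sample's row sums to the same anchor.
#'
#' Samples with a zero total for a protein carry no scale information;
#' they are dropped from that protein's table and recorded as absences
#' (retrievable via `attr(x, "absences")`). The median anchor is computed
#' over the positive totals only. Presence in only one group is handled
#' downstream by the one-group exclusion rule.
#'
#' @param counts Long segment count table from [count_segments()].
#' @return The table restricted to retained samples, with columns added:
#'   `total` (the sample's raw whole-protein count), `median_total` (the
#'   unit's anchor) and `norm_count` (`count * median_total / total`).
#'   The dropped (sample, protein) pairs are attached as the `"absences"`
#'   attribute.
#' @export
normalize_segments <- function(counts) {
  if (nrow(counts) == 0) {
    plf_abort("empty segment count table", "empty_input")
  }
  totals <- counts |>
    summarise(total = sum(.data$count),
              .by = c("region", "accession", "sample_id", "group"))
  absences <- totals |>
    filter(.data$total == 0) |>
    select("region", "accession", "sample_id", "group")
  retained <- filter(totals, .data$total > 0)
  anchors <- retained |>
    summarise(median_total = median(.data$total),
              .by = c("region", "accession"))
  out <- counts |>
    inner_join(retained, by = c("region", "accession", "sample_id", "group")) |>
    inner_join(anchors, by = c("region", "accession")) |>
    mutate(norm_count = .data$count * .data$median_total / .data$total)
  attr(out, "absences") <- absences
  out
}
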