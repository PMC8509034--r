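# Fixed-size segmentation of protein primary structures and aggregation
# of peptide spectral counts into per-(protein, region) sample x segment
# count tables.

#' Tile a protein into fixed-size segments
#'
#' Divides a protein of `protein_length` residues into consecutive
#' segments of `nominal_size` residues (default 50). Segments tile the
#' protein exactly: segment 1 starts at residue 1 and the last segment —
#' the only one allowed to be shorter than `nominal_size` — ends at the
#' final residue. The terminal short segment is kept as its own segment,
#' never merged into the penultimate one, preserving C-terminal
#' resolution.
#'
#' @param protein_length Residue count, `>= 1`.
#' @param nominal_size Segment size in residues, `>= 1` (default 50).
#' @return A tibble with columns `segment` (1-based index), `start`,
#'   `end` (inclusive residue coordinates) and `length`.
#' @examples
#' segment_boundaries(120, 50)
#' @export
segment_boundaries <- function(protein_length, nominal_size = 50) {
  if (!is.numeric(protein_length) || length(protein_length) != 1 ||
      is.na(protein_length) || protein_length < 1 ||
      protein_length != round(protein_length)) {
    plf_abort("`protein_length` must be a single integer >= 1", "bad_argument")
  }
  if (!is.numeric(nominal_size) || length(nominal_size) != 1 ||
      is.na(nominal_size) || nominal_size < 1 ||
      nominal_size != round(nominal_size)) {
    plf_abort("`nominal_size` must be a single integer >= 1", "bad_argument")
  }
  k <- ceiling(protein_length / nominal_size)
  start <- as.integer((seq_len(k) - 1) * nominal_size + 1)
  end <- as.integer(pmin(start + nominal_size - 1, protein_length))
  tibble(segment = seq_len(k), start = start, end = end,
         length = end - start + 1L)
}

#' Map a located peptide onto protein segments
#'
#' Returns the indices of every segment whose residue interval intersects
#' the peptide's `[start, end]` interval. A peptide spanning a segment
#' boundary is a member of both adjoining segments; a peptide long enough
#' to overlap more than two segments is a member of all of them.
#'
#' @param start,end 1-based inclusive residue coordinates of the peptide.
#' @param segments A segment table from [segment_boundaries()].
#' @return Integer vector of segment indices, in increasing order.
#' @examples
#' segs <- segment_boundaries(120, 50)
#' map_peptide_to_segments(48, 55, segs)  # spans segments 1 and 2
#' @export
map_peptide_to_segments <- function(start, end, segments) {
  if (!is.numeric(start) || !is.numeric(end) || length(start) != 1 ||
      length(end) != 1 || is.na(start) || is.na(end) ||
      start < 1 || end < start || end > max(segments$end)) {
    plf_abort("peptide coordinates must satisfy 1 <= start <= end <= protein length",
              "bad_coordinates")
  }
  segments$segment[segments$start <= end & segments$end >= start]
}

#' Aggregate located peptides into segment count tables
#'
#' Sums peptide spectral counts into 50-aa (or `nominal_size`) segments,
#' per (protein, region) analysis unit and per sample. A peptide
#' overlapping k segments contributes its full spectral count to each of
#' the k segments (spanning peptides are counted in every segment they
#' touch, so the grid total can exceed the raw count total — this is
#' intentional). Every sample declared in the design appears as rows for
#' every protein detected in its region, even when all its counts are
#' zero.
#'
#' @param located Located peptides from [locate_peptides()].
#' @param proteins Protein table from [read_protein_fasta()].
#' @param samples Optional design tibble with columns `region`,
#'   `sample_id`, `group` declaring which samples exist; defaults to the
#'   samples observed in `located`.
#' @param nominal_size Segment size in residues (default 50).
#' @return A long tibble with one row per
#'   (region, protein, segment, sample): columns `region`, `accession`,
#'   `segment`, `seg_start`, `seg_end`, `seg_length`, `sample_id`,
#'   `group`, `count`.
#' @export
count_segments <- function(located, proteins, samples = NULL,
                           nominal_size = 50) {
  if (is.null(samples)) {
    samples <- distinct(located, .data$region, .data$sample_id, .data$group)
  }
  dup <- samples |>
    distinct(.data$region, .data$sample_id, .data$group) |>
    count(.data$region, .data$sample_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    plf_abort(paste0("sample(s) declared with more than one group: ",
                     brief(dup$sample_id)), "inconsistent_samples")
  }
  x <- located |>
    left_join(select(proteins, "accession", protein_length = "length"),
              by = "accession")
  if (any(is.na(x$protein_length))) {
    plf_abort(paste0("accession(s) absent from the protein table: ",
                     brief(x$accession[is.na(x$protein_length)])),
              "unknown_accession")
  }
  if (any(x$start < 1 | x$end > x$protein_length | x$start > x$end)) {
    plf_abort("located peptide coordinates fall outside their protein",
              "bad_coordinates")
  }
  # Segment membership by tiling arithmetic: residue r lies in segment
  # (r - 1) %/% nominal_size + 1; a peptide covers the contiguous run of
  # segments between its two end residues.
  s1 <- (x$start - 1L) %/% nominal_size + 1L
  s2 <- (x$end - 1L) %/% nominal_size + 1L
  k <- s2 - s1 + 1L
  expanded <- x[rep(seq_len(nrow(x)), k), c("region", "accession", "sample_id",
                                            "group", "spectral_count")]
  expanded$segment <- as.integer(sequence(k) + rep(s1, k) - 1L)
  agg <- expanded |>
    summarise(count = sum(.data$spectral_count),
              .by = c("region", "accession", "sample_id", "group", "segment"))
  units <- distinct(agg, .data$region, .data$accession)
  seg_tbl <- proteins |>
    filter(.data$accession %in% units$accession) |>
    mutate(segs = map(.data$length, segment_boundaries, nominal_size = nominal_size)) |>
    select("accession", "segs") |>
    unnest("segs") |>
    rename(seg_start = "start", seg_end = "end", seg_length = "length")
  grid <- units |>
    inner_join(samples, by = "region", relationship = "many-to-many") |>
    inner_join(seg_tbl, by = "accession", relationship = "many-to-many")
  grid |>
    left_join(agg, by = c("region", "accession", "sample_id", "group", "segment")) |>
    mutate(count = coalesce(.data$count, 0L)) |>
    select("region", "accession", "segment", "seg_start", "seg_end",
           "seg_length", "sample_id", "group", "count") |>
    arrange(.data$region, .data$accession, .data$segment, .data$group,
            .data$sample_id)
}

#' Write per-protein segment count grids as delimited text
#'
#' Debug export: one tab-separated file per (region, protein), rows =
#' samples, columns = segment indices.
#'
#' @param counts Output of [count_segments()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_segment_grids <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  units <- distinct(counts, .data$region, .data$accession)
  paths <- pmap(units, function(region, accession) {
    wide <- counts |>
      filter(.data$region == !!region, .data$accession == !!accession) |>
      select("sample_id", "group", "segment", "count") |>
      pivot_wider(names_from = "segment", values_from = "count",
                  names_prefix = "seg_")
    path <- file.path(dir, paste0(accession, "_", region, ".tsv"))
    readr::write_tsv(wide, path, progress = FALSE)
    path
  })
  invisible(unlist(paths))
}
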