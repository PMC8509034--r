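# Orchestration: end-to-end runs that read inputs from disk and write a
# delimited result bundle plus a machine-readable manifest.

#' Run a complete PLF analysis from files on disk
#'
#' Reads a FASTA and one or more peptide tables, runs [plf()], and
#' writes the result bundle to `out_dir`: segment-level tests,
#' protein-level summary, difference profiles (raw and, with several
#' regions, composite-scaled), the exclusion log, the cross-region Venn
#' partition, optionally the PLF-unique set against an abundance-based
#' significant list, and a JSON manifest recording every parameter and
#' the MD5 checksum of every input. Identical inputs and parameters
#' produce byte-identical bundles. On failure, partial outputs are
#' removed.
#'
#' @param fasta Path to the protein FASTA.
#' @param peptide_tables Character vector of peptide table paths.
#' @param out_dir Output directory (created if needed).
#' @param samples Optional path to a sample design table (`region`,
#'   `sample_id`, `group`, tab- or comma-delimited) declaring samples
#'   that must appear even with zero counts.
#' @param abundance_list Optional path to a text file of accessions
#'   (one per line) significant by abundance-based quantification.
#' @param min_probability Minimum peptide identification probability
#'   (default 0.95).
#' @inheritParams plf
#' @return Invisibly, a list with the `plf_analysis` object and the
#'   paths written.
#' @export
run_plf <- function(fasta, peptide_tables, out_dir, samples = NULL,
                    abundance_list = NULL, nominal_size = 50,
                    min_probability = 0.95, groups = c("young", "aged"),
                    alpha_levels = c(0.05, 0.01, 0.001), alpha = 0.05,
                    tail_mode = c("actual", "strict"),
                    occurrence_policy = c("first", "all", "error")) {
  tail_mode <- match.arg(tail_mode)
  occurrence_policy <- match.arg(occurrence_policy)
  inputs <- c(fasta, peptide_tables, samples, abundance_list)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0) {
    plf_abort(paste0("input file(s) not found: ", brief(missing_in)),
              "missing_file")
  }
  proteins <- read_protein_fasta(fasta)
  peptides <- bind_rows(map(peptide_tables, read_peptide_table,
                            min_probability = min_probability,
                            groups = groups))
  design <- if (!is.null(samples)) {
    header <- readr::read_lines(samples, n_max = 1)
    delim <- if (grepl("\t", header)) "\t" else ","
    readr::read_delim(samples, delim = delim, col_types = readr::cols(.default = "c"),
                      progress = FALSE)
  } else NULL
  fit <- plf(peptides, proteins, samples = design,
             nominal_size = nominal_size, groups = groups,
             alpha_levels = alpha_levels, alpha = alpha,
             tail_mode = tail_mode, occurrence_policy = occurrence_policy)

  regions <- unique(fit$protein_summary$region)
  venn <- if (length(regions) >= 2) intersect_regions(fit$protein_summary)
          else NULL
  unique_set <- if (!is.null(abundance_list)) {
    abundance <- readr::read_lines(abundance_list)
    abundance <- abundance[nzchar(abundance)]
    flagged_union <- unique(
      fit$protein_summary$accession[fit$protein_summary$flagged]
    )
    plf_unique(flagged_union, abundance)
  } else NULL

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(x, name, writer = readr::write_tsv) {
    path <- file.path(out_dir, name)
    writer(x, path, progress = FALSE)
    written <<- c(written, path)
    path
  }
  tryCatch({
    emit(fit$segment_tests, "segment_tests.tsv")
    emit(fit$protein_summary, "protein_summary.tsv")
    emit(fit$differences, "differences.tsv")
    if (!is.null(fit$composite)) emit(fit$composite, "composite.tsv")
    emit(fit$exclusions, "exclusions.tsv")
    if (!is.null(venn)) {
      emit(venn$cells |>
             mutate(accessions = map_chr(.data$accessions, paste,
                                         collapse = ";")),
           "venn_cells.tsv")
    }
    if (!is.null(unique_set)) {
      path <- file.path(out_dir, "plf_unique.txt")
      writeLines(unique_set, path)
      written <- c(written, path)
    }
    manifest <- list(
      tool = "plfr",
      parameters = list(
        nominal_size = nominal_size, min_probability = min_probability,
        groups = groups, alpha_levels = alpha_levels, alpha = alpha,
        tail_mode = tail_mode, occurrence_policy = occurrence_policy
      ),
      inputs = lapply(stats::setNames(inputs, basename(inputs)),
                      function(p) unname(tools::md5sum(p))),
      outputs = basename(written)
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <- c(written, manifest_path)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(list(analysis = fit, venn = venn, plf_unique = unique_set,
                 paths = written))
}

#' Simulate a study and write it to disk
#'
#' Convenience wrapper: [simulate_study()] then [write_study()], plus a
#' JSON manifest of the generating parameters.
#'
#' @param spec A [plf_study_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the `plf_simulation` and the paths written.
#' @export
run_simulate <- function(spec, out_dir) {
  sim <- simulate_study(spec)
  paths <- write_study(sim, out_dir)
  manifest <- list(
    tool = "plfr",
    parameters = spec[setdiff(names(spec), "proteome")],
    proteome = if (is.null(spec$proteome)) "generated" else "supplied",
    outputs = basename(unlist(paths))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(list(simulation = sim, paths = c(paths, manifest = manifest_path)))
}
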