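# Input readers and peptide location.
#
# Coordinate convention used throughout the package: residue positions are
# 1-based and intervals are inclusive at both ends, matching the residue
# numbering used in protein domain diagrams.

# 20 standard residues plus ambiguity/rare codes B, Z, X, U, O.
AA_ALPHABET_RE <- "[^ACDEFGHIKLMNPQRSTVWYBZXUO]"

#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-record, wrapped or unwrapped) FASTA file of amino-acid
#' sequences into the protein table used throughout the package. The
#' accession is the first whitespace-delimited token of each header;
#' UniProt-style `db|ACC|name` tokens are reduced to the central accession.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `sequence` (upper case) and
#'   `length` (residue count).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P00001|TEST", "MKRPEPTIDEK"), fa)
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    plf_abort(paste0("FASTA file not found: ", path), "missing_file")
  }
  # read as raw strings so that alphabet violations surface as this
  # package's own named error rather than a parser failure
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) plf_abort(
      paste0("could not parse FASTA file '", path, "': ", conditionMessage(e)),
      "fasta_parse"
    )
  )
  if (length(set) == 0) {
    plf_abort(paste0("FASTA file '", path, "' contains no records"), "empty_fasta")
  }
  first_token <- sub("\\s.*$", "", names(set))
  accession <- map_chr(strsplit(first_token, "|", fixed = TRUE), function(p) {
    if (length(p) >= 2) p[[2]] else p[[1]]
  })
  sequence <- toupper(as.character(set))
  bad <- grepl(AA_ALPHABET_RE, sequence)
  if (any(bad)) {
    plf_abort(
      paste0("sequence(s) with characters outside the amino-acid alphabet: ",
             brief(accession[bad])),
      "alphabet"
    )
  }
  if (any(nchar(sequence) < 1)) {
    plf_abort(
      paste0("empty sequence(s): ", brief(accession[nchar(sequence) < 1])),
      "empty_sequence"
    )
  }
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0) {
    plf_abort(paste0("duplicate accession(s) in FASTA: ", brief(dup)),
              "duplicate_accession")
  }
  tibble(accession = unname(accession), sequence = unname(sequence),
         length = nchar(sequence))
}

#' Read a per-sample peptide identification table
#'
#' Reads a delimited peptide list of the kind exported from PSM-scoring
#' software. The delimiter (comma or tab) is sniffed from the header line.
#' Required columns: `sample_id`, `group`, `region`, `accession`,
#' `peptide_seq`, `spectral_count`; optional: `probability`.
#'
#' Rows whose identification probability falls below `min_probability` are
#' dropped; rows with no probability value are kept (the filter is then
#' assumed to have been applied upstream). Group and region labels are
#' normalised to lower case. Modified-residue annotations in the peptide
#' sequence — bracketed or parenthesised mass tags and any other
#' non-letter characters — are stripped, since the modification set is
#' fixed upstream of this pipeline.
#'
#' @param path Path to a comma- or tab-delimited text file with a header.
#' @param min_probability Minimum identification probability retained,
#'   in `[0, 1]`. Default 0.95.
#' @param groups Character vector of the two valid group labels, reference
#'   group first. Default `c("young", "aged")`.
#' @return A tibble of validated peptide records, one row per
#'   (sample, peptide) observation.
#' @export
read_peptide_table <- function(path, min_probability = 0.95,
                               groups = c("young", "aged")) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    plf_abort(paste0("peptide table not found: ", path), "missing_file")
  }
  if (!is.numeric(min_probability) || length(min_probability) != 1 ||
      is.na(min_probability) || min_probability < 0 || min_probability > 1) {
    plf_abort("`min_probability` must be a single number in [0, 1]",
              "bad_argument")
  }
  header <- readr::read_lines(path, n_max = 1)
  if (length(header) == 0) {
    plf_abort(paste0("peptide table '", path, "' is empty"), "empty_table")
  }
  delim <- if (grepl("\t", header)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, trim_ws = TRUE)
  required <- c("sample_id", "group", "region", "accession", "peptide_seq",
                "spectral_count")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    plf_abort(paste0("peptide table is missing required column(s): ",
                     paste(missing_cols, collapse = ", ")), "missing_column")
  }
  validate_peptide_records(
    tibble(
      sample_id = tbl$sample_id,
      group = tolower(tbl$group),
      region = tolower(tbl$region),
      accession = tbl$accession,
      peptide_seq = clean_peptide_seq(tbl$peptide_seq),
      spectral_count = parse_spectral_count(tbl$spectral_count),
      probability = parse_probability(tbl)
    ),
    groups = groups,
    min_probability = min_probability
  )
}

# Strip modification annotations: bracketed/parenthesised tags and any
# residual non-letter characters (terminal dots, charge marks, ...).
clean_peptide_seq <- function(x) {
  x <- gsub("\\[[^]]*\\]|\\([^)]*\\)", "", x)
  toupper(gsub("[^A-Za-z]", "", x))
}

parse_spectral_count <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  bad <- is.na(num) | num != round(num) | num < 0
  if (any(bad)) {
    plf_abort(paste0("spectral_count must be a non-negative integer; offending value(s): ",
                     brief(x[bad])), "bad_spectral_count")
  }
  as.integer(num)
}

parse_probability <- function(tbl) {
  if (!"probability" %in% names(tbl)) return(rep(NA_real_, nrow(tbl)))
  raw <- tbl$probability
  num <- suppressWarnings(as.numeric(sub("%$", "", raw)))
  # "95%"-style values are accepted and rescaled to fractions
  pct <- !is.na(num) & grepl("%$", raw)
  num[pct] <- num[pct] / 100
  bad <- (!is.na(raw) & raw != "" & is.na(num)) | (!is.na(num) & (num < 0 | num > 1))
  if (any(bad)) {
    plf_abort(paste0("probability must lie in [0, 1]; offending value(s): ",
                     brief(raw[bad])), "bad_probability")
  }
  num
}

# All (possibly overlapping) start positions of pattern p in string s.
# gregexpr() reports non-overlapping matches only, which would miss e.g.
# the middle occurrence of "AA" in "AAAA".
find_occurrences <- function(s, p) {
  out <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(p, substring(s, from), fixed = TRUE)
    if (i == -1L) break
    pos <- from + as.integer(i) - 1L
    out <- c(out, pos)
    from <- pos + 1L
  }
  out
}

# Shared validation for peptide records, whether read from disk or built
# in code (e.g. by the simulator).
validate_peptide_records <- function(tbl, groups = c("young", "aged"),
                                     min_probability = 0) {
  if (length(groups) != 2 || anyDuplicated(groups)) {
    plf_abort("`groups` must name exactly two distinct group labels",
              "bad_argument")
  }
  unknown <- setdiff(unique(tbl$group), groups)
  if (length(unknown) > 0) {
    plf_abort(paste0("unknown group label(s): ", brief(unknown),
                     " (expected one of: ", paste(groups, collapse = ", "), ")"),
              "unknown_group")
  }
  if (any(nchar(tbl$peptide_seq) < 1)) {
    plf_abort("peptide_seq must contain at least one residue", "empty_peptide")
  }
  if (any(tbl$spectral_count < 0)) {
    plf_abort("spectral_count must be >= 0", "bad_spectral_count")
  }
  if ("probability" %in% names(tbl)) {
    tbl <- tbl[is.na(tbl$probability) | tbl$probability >= min_probability, ,
               drop = FALSE]
  }
  as_tibble(tbl)
}

#' Locate peptides within their parent proteins
#'
#' Finds the residue coordinates of each peptide record by exact substring
#' search (case-insensitive) of `peptide_seq` in the parent protein's
#' sequence. Coordinates are 1-based and inclusive.
#'
#' When a peptide occurs more than once in its parent protein:
#' * `"first"` (default) uses the lowest start position and emits one
#'   warning summarising the multiplicity — the upstream exclusivity filter
#'   makes within-protein multiplicity rare, and counting every occurrence
#'   would double-count spectra;
#' * `"all"` emits one located record per occurrence, each carrying the
#'   full spectral count;
#' * `"error"` rejects the record.
#'
#' @param peptides A peptide record tibble (see [read_peptide_table()]).
#' @param proteins A protein table (see [read_protein_fasta()]).
#' @param occurrence_policy One of `"first"`, `"all"`, `"error"`.
#' @return The input records with `start` and `end` coordinate columns
#'   added (and possibly expanded rows under `"all"`).
#' @export
locate_peptides <- function(peptides, proteins,
                            occurrence_policy = c("first", "all", "error")) {
  occurrence_policy <- match.arg(occurrence_policy)
  missing_acc <- setdiff(unique(peptides$accession), proteins$accession)
  if (length(missing_acc) > 0) {
    plf_abort(paste0("accession(s) absent from the protein table: ",
                     brief(missing_acc)), "unknown_accession")
  }
  key <- distinct(peptides, .data$accession, .data$peptide_seq) |>
    left_join(select(proteins, "accession", "sequence"), by = "accession")
  occ <- map2(key$sequence, toupper(key$peptide_seq), find_occurrences)
  n_occ <- lengths(occ)
  if (any(n_occ == 0)) {
    i <- which(n_occ == 0)
    plf_abort(
      paste0("peptide(s) not found in their parent protein: ",
             brief(paste0(key$accession[i], ":", key$peptide_seq[i]))),
      "peptide_not_found"
    )
  }
  multi <- n_occ > 1
  if (any(multi) && occurrence_policy == "error") {
    i <- which(multi)
    plf_abort(
      paste0("peptide(s) with multiple occurrences in their parent protein: ",
             brief(paste0(key$accession[i], ":", key$peptide_seq[i]))),
      "multiple_occurrences"
    )
  }
  if (any(multi) && occurrence_policy == "first") {
    plf_warn(
      paste0(sum(multi), " peptide(s) occur more than once in their parent ",
             "protein; the first (lowest) position was used: ",
             brief(paste0(key$accession[multi], ":", key$peptide_seq[multi]))),
      "multiple_occurrences"
    )
  }
  key$start_list <- if (occurrence_policy == "all") occ else map(occ, 1)
  located <- key |>
    select("accession", "peptide_seq", "start_list") |>
    unnest("start_list") |>
    rename(start = "start_list")
  out <- peptides |>
    inner_join(located, by = c("accession", "peptide_seq"),
               relationship = "many-to-many") |>
    mutate(end = .data$start + nchar(.data$peptide_seq) - 1L)
  as_tibble(out)
}
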