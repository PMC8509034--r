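# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use different algorithms from the package
# (per-residue marking, boundary-pair enumeration) so that agreement is
# informative.

# Per-residue membership oracle for segment mapping: mark every residue
# with its segment by walking the tiling, then take the set over the
# peptide's residues.
oracle_map <- function(start, end, protein_length, nominal_size) {
  seg_id <- integer(protein_length)
  seg <- 0L
  pos <- 1L
  while (pos <= protein_length) {
    seg <- seg + 1L
    e <- min(pos + nominal_size - 1L, protein_length)
    seg_id[pos:e] <- seg
    pos <- e + 1L
  }
  sort(unique(seg_id[start:end]))
}

# Brute-force tryptic digestion oracle: enumerate every pair of cleavage
# boundaries, count the internal boundaries as missed cleavages.
oracle_digest <- function(s, missed_cleavage_max, length_window) {
  s <- toupper(s)
  n <- nchar(s)
  res <- strsplit(s, "", fixed = TRUE)[[1]]
  sites <- if (n > 1) which(res[-n] %in% c("K", "R") & res[-1] != "P")
           else integer(0)
  b <- c(0L, sites, n)
  rows <- list()
  for (i in seq_len(length(b) - 1)) {
    for (j in (i + 1):length(b)) {
      missed <- j - i - 1L
      if (missed > missed_cleavage_max) next
      st <- b[i] + 1L
      en <- b[j]
      L <- en - st + 1L
      if (L >= length_window[1] && L <= length_window[2]) {
        rows[[length(rows) + 1]] <- data.frame(
          peptide_seq = substring(s, st, en), start = st, end = en,
          missed_cleavages = missed
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peptide_seq = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

# Write a FASTA file from a named character vector, optionally wrapping
# lines.
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta"),
                        width = NULL) {
  lines <- unlist(lapply(names(seqs), function(a) {
    s <- seqs[[a]]
    body <- if (is.null(width)) s else {
      starts <- seq(1, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1, nchar(s)))
    }
    c(paste0(">", a), body)
  }))
  writeLines(lines, path)
  path
}

write_peptide_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

# A minimal valid peptide record tibble builder with defaults.
pep_rec <- function(accession, peptide_seq, spectral_count = 1L,
                    sample_id = "s1", group = "young", region = "posterior",
                    probability = NA_real_) {
  tibble::tibble(sample_id = sample_id, group = group, region = region,
                 accession = accession, peptide_seq = peptide_seq,
                 spectral_count = as.integer(spectral_count),
                 probability = probability)
}

# Build a normalized-segment table directly from a per-sample count
# matrix for one protein/region, bypassing file IO: rows = samples.
counts_from_matrix <- function(mat, groups, region = "posterior",
                               accession = "P1", nominal_size = 50,
                               protein_length = ncol(mat) * nominal_size) {
  segs <- plfr::segment_boundaries(protein_length, nominal_size)
  stopifnot(nrow(segs) == ncol(mat))
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    tibble::tibble(
      region = region, accession = accession, segment = segs$segment,
      seg_start = segs$start, seg_end = segs$end, seg_length = segs$length,
      sample_id = paste0("s", i), group = groups[i],
      count = as.numeric(mat[i, ])
    )
  })
  dplyr::bind_rows(rows)
}
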