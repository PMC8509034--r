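test_that("segment boundaries tile the protein with a short terminal segment", {
  b <- segment_boundaries(120, 50)
  expect_equal(b$start, c(1L, 51L, 101L))
  expect_equal(b$end, c(50L, 100L, 120L))
  expect_equal(b$length, c(50L, 50L, 20L))

  expect_equal(nrow(segment_boundaries(50, 50)), 1)
  b2 <- segment_boundaries(101, 50)
  expect_equal(b2$end, c(50L, 100L, 101L))
  expect_equal(b2$length[3], 1L)

  # tiling invariants on assorted sizes
  for (pl in c(1, 7, 49, 50, 51, 1000)) {
    b <- segment_boundaries(pl, 50)
    expect_equal(b$start[1], 1L)
    expect_equal(b$end[nrow(b)], as.integer(pl))
    if (nrow(b) > 1) {
      expect_equal(b$start[-1], b$end[-nrow(b)] + 1L)
      expect_true(all(b$length[-nrow(b)] == 50L))
    }
    expect_true(b$length[nrow(b)] >= 1 && b$length[nrow(b)] <= 50)
  }

  expect_error(segment_boundaries(0, 50), class = "plfr_error_bad_argument")
  expect_error(segment_boundaries(100, 0), class = "plfr_error_bad_argument")
})

test_that("peptides map to every segment they intersect", {
  segs <- segment_boundaries(120, 50)
  expect_equal(map_peptide_to_segments(48, 55, segs), c(1L, 2L))
  expect_equal(map_peptide_to_segments(50, 50, segs), 1L)
  expect_equal(map_peptide_to_segments(49, 120, segs), c(1L, 2L, 3L))
  expect_error(map_peptide_to_segments(100, 130, segs),
               class = "plfr_error_bad_coordinates")
})

test_that("segment mapping agrees with the per-residue membership oracle", {
  set.seed(7)
  for (i in 1:300) {
    pl <- sample(1:3000, 1)
    ns <- sample(1:60, 1)
    st <- sample(pl, 1)
    en <- min(pl, st + sample(0:80, 1))
    segs <- segment_boundaries(pl, ns)
    expect_identical(map_peptide_to_segments(st, en, segs),
                     oracle_map(st, en, pl, ns))
  }
})

test_that("spanning peptides contribute their full count to every overlapped segment", {
  proteins <- tibble::tibble(
    accession = "P1",
    sequence = paste(rep("A", 120), collapse = ""), length = 120L
  )
  located <- pep_rec("P1", substring(proteins$sequence, 48, 55),
                     spectral_count = 3L)
  located$start <- 48L
  located$end <- 55L
  counts <- count_segments(located, proteins)
  expect_equal(sum(counts$count), 6L)  # full count in both segments
  expect_equal(counts$count[counts$segment %in% 1:2], c(3L, 3L))
  expect_equal(counts$count[counts$segment == 3], 0L)
})

test_that("declared samples appear as all-zero rows and counts add up", {
  proteins <- tibble::tibble(
    accession = "P1",
    sequence = paste(rep("A", 60), collapse = ""), length = 60L
  )
  located <- dplyr::bind_rows(
    pep_rec("P1", "AAAAAAA", 2L, sample_id = "s1"),
    pep_rec("P1", "AAAAAAAAA", 5L, sample_id = "s1")
  )
  located$start <- c(1L, 10L)
  located$end <- c(7L, 18L)
  design <- tibble::tibble(region = "posterior",
                           sample_id = c("s1", "s2"),
                           group = c("young", "aged"))
  counts <- count_segments(located, proteins, samples = design)
  expect_equal(counts$count[counts$sample_id == "s1" & counts$segment == 1], 7L)
  s2 <- counts[counts$sample_id == "s2", ]
  expect_equal(nrow(s2), 2)
  expect_true(all(s2$count == 0))
})

test_that("inconsistent sample metadata is rejected", {
  design <- tibble::tibble(region = "posterior",
                           sample_id = c("s1", "s1"),
                           group = c("young", "aged"))
  proteins <- tibble::tibble(accession = "P1", sequence = "AAAAAAA",
                             length = 7L)
  located <- pep_rec("P1", "AAAA")
  located$start <- 1L
  located$end <- 4L
  expect_error(count_segments(located, proteins, samples = design),
               class = "plfr_error_inconsistent_samples")
})

test_that("grid totals equal counts weighted by segments overlapped", {
  set.seed(11)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pl <- 430L
  seqc <- paste(sample(alphabet, pl, replace = TRUE), collapse = "")
  proteins <- tibble::tibble(accession = "P1", sequence = seqc, length = pl)
  st <- sample(pl - 40, 25)
  en <- pmin(pl, st + sample(5:39, 25, replace = TRUE))
  located <- pep_rec("P1", substring(seqc, st, en),
                     spectral_count = sample(1:9, 25, replace = TRUE))
  located$start <- as.integer(st)
  located$end <- as.integer(en)
  counts <- count_segments(located, proteins, nominal_size = 50)
  n_overlap <- mapply(function(s, e) {
    length(oracle_map(s, e, pl, 50))
  }, st, en)
  expect_equal(sum(counts$count), sum(located$spectral_count * n_overlap))
  # all peptides shorter than the segment size: at most doubled
  expect_lte(sum(counts$count), 2 * sum(located$spectral_count))
})
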