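test_that("tryptic digestion obeys the K/R-not-before-P rule", {
  d <- digest_tryptic("AKRPGK", missed_cleavage_max = 1,
                      length_window = c(1, 35))
  expect_setequal(d$peptide_seq, c("AK", "RPGK", "AKRPGK"))
  expect_equal(d$start[d$peptide_seq == "RPGK"], 3L)
  expect_equal(d$end[d$peptide_seq == "RPGK"], 6L)

  d2 <- digest_tryptic("MKR", missed_cleavage_max = 0,
                       length_window = c(1, 35))
  expect_setequal(d2$peptide_seq, c("MK", "R"))
})

test_that("digestion agrees with the boundary-pair enumeration oracle", {
  set.seed(61)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWYKRKRP", "")[[1]]
  for (i in 1:40) {
    s <- paste(sample(alphabet, sample(5:120, 1), replace = TRUE),
               collapse = "")
    mc <- sample(0:3, 1)
    win <- sort(sample(1:40, 2))
    got <- digest_tryptic(s, mc, win)
    want <- oracle_digest(s, mc, win)
    got <- got[order(got$start, got$end), ]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$peptide_seq, want$peptide_seq)
    expect_equal(got$missed_cleavages, want$missed_cleavages)
  }
})

test_that("the detectability length window is enforced", {
  set.seed(67)
  s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWYKR", "")[[1]], 500,
                    replace = TRUE), collapse = "")
  d <- digest_tryptic(s, 2, c(7, 35))
  expect_true(all(nchar(d$peptide_seq) >= 7 & nchar(d$peptide_seq) <= 35))
})

test_that("the same seed reproduces an identical dataset", {
  spec <- plf_study_spec(n_proteins = 6, length_range = c(150, 250),
                         regions = c("posterior", "anterior"), seed = 9)
  s1 <- simulate_study(spec)
  s2 <- simulate_study(spec)
  expect_identical(s1$peptides, s2$peptides)
  expect_identical(s1$proteins, s2$proteins)
  # and different seeds give different tables with identical schemas
  s3 <- simulate_study(plf_study_spec(n_proteins = 6,
                                      length_range = c(150, 250),
                                      regions = c("posterior", "anterior"),
                                      seed = 10))
  expect_false(identical(s1$peptides, s3$peptides))
  expect_identical(names(s1$peptides), names(s3$peptides))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_study(plf_study_spec(n_proteins = 2, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("every simulated peptide locates exactly in its parent protein", {
  sim <- simulate_study(plf_study_spec(n_proteins = 8, seed = 21))
  located <- suppressWarnings(
    locate_peptides(sim$peptides, sim$proteins, "first")
  )
  expect_equal(nrow(located) >= nrow(sim$peptides), TRUE)
  with(located, expect_true(all(
    substring(sim$proteins$sequence[match(accession, sim$proteins$accession)],
              start, end) == peptide_seq
  )))
})

test_that("a zero fold-change silences the targeted peptides in the aged group", {
  prot <- random_proteome(1, c(200, 200), seed = 3)
  eff <- tibble::tibble(accession = prot$accession, start = 1L, end = 200L,
                        group = "aged", fold_change = 0)
  sim <- simulate_study(plf_study_spec(proteome = prot, regions = "posterior",
                                       baseline_total = 300, effects = eff,
                                       seed = 12))
  expect_true(all(sim$peptides$group == "young"))
  expect_error(
    plf_study_spec(proteome = prot,
                   effects = tibble::tibble(accession = "NOPE", start = 1L,
                                            end = 5L, group = "aged",
                                            fold_change = 2)),
    class = "plfr_error_unknown_accession"
  )
})

test_that("with no effects the aged/young mean-count ratio approaches 1", {
  prot <- random_proteome(1, c(300, 300), seed = 8)
  spec <- plf_study_spec(proteome = prot, regions = "posterior",
                         n_young = 200, n_aged = 200, baseline_total = 300,
                         dispersion = 25, seed = 13)
  sim <- simulate_study(spec)
  means <- sim$peptides |>
    dplyr::summarise(mean_count = sum(spectral_count) / 200,
                     .by = c(peptide_seq, group)) |>
    tidyr::pivot_wider(names_from = group, values_from = mean_count)
  means <- means[!is.na(means$young) & !is.na(means$aged) &
                   means$young >= 1, ]
  expect_gt(nrow(means), 10)
  ratio <- means$aged / means$young
  expect_equal(median(ratio), 1, tolerance = 0.1)
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("implanted suppression shows up where it was implanted", {
  prot <- random_proteome(1, c(300, 300), seed = 31)
  eff <- tibble::tibble(accession = prot$accession, start = 101L, end = 200L,
                        group = "aged", fold_change = 0.25)
  sim <- simulate_study(plf_study_spec(proteome = prot, regions = "posterior",
                                       baseline_total = 400, dispersion = 25,
                                       effects = eff, seed = 37))
  fit <- plf(sim$peptides, sim$proteins, samples = sim$samples)
  tt <- tidy(fit)
  # the affected segments (3 and 4) show suppressed aged yield
  expect_true(all(tt$diff[tt$segment %in% 3:4] < 0))
})
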