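# The statistical core, checked against independent routes from stats::
# and against hand-computed constants.

norm_from <- function(mat, groups) {
  normalize_segments(counts_from_matrix(mat, groups))
}

test_that("group means and standard deviations are the textbook statistics", {
  mat <- rbind(c(2, 1), c(4, 1), c(6, 1), c(3, 2), c(3, 2), c(3, 2))
  groups <- rep(c("young", "aged"), each = 3)
  counts <- counts_from_matrix(mat, groups)
  norm <- counts
  norm$norm_count <- norm$count  # bypass rescaling to test the summary alone
  norm$total <- 1
  norm$median_total <- 1
  gs <- summarize_groups(norm)
  seg1_young <- gs[gs$segment == 1, ]
  expect_equal(seg1_young$mean_young, 4)
  expect_equal(seg1_young$sd_young, 2)
  expect_equal(seg1_young$n_young, 3L)
})

test_that("proteins present in one group are excluded entirely", {
  mat <- rbind(c(3, 4), c(5, 2), c(4, 4))
  norm <- norm_from(mat, groups = c("young", "young", "young"))
  tests <- test_segments(norm)
  expect_equal(nrow(tests), 0)
  excl <- attr(tests, "exclusions")
  expect_equal(excl$reason, "one_group")
  # and never flagged
  expect_equal(nrow(flag_significant_proteins(tests)), 0)
})

test_that("a single-sample group blocks testing but keeps the difference profile", {
  mat <- rbind(c(10, 2), c(12, 4), c(11, 3), c(5, 5))
  groups <- c("young", "young", "young", "aged")
  norm <- norm_from(mat, groups)
  tests <- test_segments(norm)
  expect_equal(nrow(tests), 0)
  expect_equal(attr(tests, "exclusions")$reason, "single_sample")
  expect_warning(d <- difference_profiles(norm),
                 class = "plfr_warning_single_sample")
  expect_equal(nrow(d), 2)
})

test_that("difference profiles divide by segment length with a strict-nominal mode", {
  # 66-residue protein: tail segment has 16 residues; equal row totals so
  # normalization is the identity and the tail means are 0 (young) vs 1 (aged)
  mat <- rbind(c(10, 0), c(10, 0), c(9, 1), c(9, 1))
  counts <- counts_from_matrix(mat, rep(c("young", "aged"), each = 2),
                               protein_length = 66)
  norm <- normalize_segments(counts)
  d_actual <- difference_profiles(norm, tail_mode = "actual")
  d_strict <- difference_profiles(norm, tail_mode = "strict", nominal_size = 50)
  expect_equal(d_actual$diff[d_actual$segment == 2], (1 - 0) / 16)
  expect_equal(d_strict$diff[d_strict$segment == 2], (1 - 0) / 50)

  # equal means give exactly zero
  counts0 <- counts_from_matrix(rbind(c(4, 2), c(4, 2), c(4, 2), c(4, 2)),
                                rep(c("aged", "young"), each = 2))
  expect_true(all(difference_profiles(normalize_segments(counts0))$diff == 0))
})

test_that("raw p-values match the pooled-t route from stats:: to 1e-10", {
  young <- c(1, 2, 3)
  aged <- c(4, 5, 6)
  # equal row totals so normalization is the identity for this design:
  # young rows (1,9), (2,8), (3,7); aged rows (4,6), (5,5), (6,4)
  mat <- rbind(c(1, 9), c(2, 8), c(3, 7), c(4, 6), c(5, 5), c(6, 4))
  groups <- rep(c("young", "aged"), each = 3)
  tests <- test_segments(norm_from(mat, groups))
  seg1 <- tests[tests$segment == 1, ]
  p_t <- stats::t.test(aged, young, var.equal = TRUE)$p.value
  p_f <- stats::oneway.test(v ~ g,
                            data = data.frame(v = c(young, aged),
                                              g = rep(c("y", "a"), each = 3)),
                            var.equal = TRUE)$p.value
  expect_equal(seg1$raw_p, p_t, tolerance = 1e-10)
  expect_equal(seg1$raw_p, p_f, tolerance = 1e-10)
  expect_equal(seg1$raw_p, 0.02131164, tolerance = 1e-6)
  expect_equal(seg1$mean_young, 2)
  expect_equal(seg1$mean_aged, 5)
})

test_that("degenerate segments get the defined p-values", {
  # all values identical across both groups -> raw p 1, no stars
  mat <- rbind(c(2, 3), c(2, 3), c(2, 3), c(2, 3))
  tests <- test_segments(norm_from(mat, rep(c("young", "aged"), each = 2)))
  expect_equal(tests$raw_p, c(1, 1))
  expect_equal(tests$stars, c("", ""))

  # zero variance but different means -> p 0
  mat2 <- rbind(c(10, 0), c(10, 0), c(0, 10), c(0, 10))
  tests2 <- test_segments(norm_from(mat2, rep(c("young", "aged"), each = 2)))
  expect_equal(tests2$raw_p, c(0, 0))
})

test_that("Bonferroni correction and star thresholds match p.adjust on a p x m grid", {
  p_grid <- c(1e-6, 1e-4, 0.0009, 0.001 / 28, 0.0252 / 28, 0.002, 0.01, 0.02,
              0.049, 0.05, 0.051, 0.2, 0.5, 1)
  for (m in c(1, 2, 5, 28, 100)) {
    corrected <- pmin(1, p_grid * m)
    oracle <- vapply(p_grid, function(p) {
      stats::p.adjust(rep(p, m), method = "bonferroni")[1]
    }, numeric(1))
    expect_equal(corrected, oracle, tolerance = 1e-15)
    stars <- plfr:::star_annotation(corrected)
    expected <- ifelse(corrected <= 0.001, "***",
                ifelse(corrected <= 0.01, "**",
                ifelse(corrected <= 0.05, "*", "")))
    expect_identical(stars, expected)
  }
  # the worked constant: raw 0.0009 with 28 testable segments
  expect_equal(min(1, 0.0009 * 28), 0.0252)
  expect_identical(plfr:::star_annotation(0.0252), "*")
})

test_that("corrected p is the raw p scaled by the count of testable segments", {
  # 3 segments, one of them all-zero -> m = 2
  mat <- rbind(c(5, 1, 0), c(6, 2, 0), c(1, 5, 0), c(2, 6, 0))
  tests <- test_segments(norm_from(mat, rep(c("young", "aged"), each = 2)))
  expect_equal(unique(tests$m), 2L)
  expect_true(is.na(tests$raw_p[tests$segment == 3]))
  testable <- tests[!is.na(tests$raw_p), ]
  expect_equal(testable$corrected_p, pmin(1, testable$raw_p * 2))
})

test_that("protein flagging follows the corrected 0.05 threshold", {
  tests <- tibble::tibble(
    region = "posterior", accession = c("A", "A", "B", "B"),
    raw_p = c(0.01, 0.5, 0.02, 0.9), corrected_p = c(0.04, 1, 0.07, 1)
  )
  fl <- flag_significant_proteins(tests)
  expect_true(fl$flagged[fl$accession == "A"])
  expect_false(fl$flagged[fl$accession == "B"])
  expect_equal(fl$min_corrected_p, c(0.04, 0.07))
})

test_that("swapping group labels negates differences and preserves p-values", {
  set.seed(53)
  mat <- matrix(rpois(6 * 4, 15) + 1, nrow = 6)
  groups <- rep(c("young", "aged"), each = 3)
  swapped <- rep(c("aged", "young"), each = 3)
  a <- test_segments(norm_from(mat, groups))
  b <- test_segments(norm_from(mat, swapped))
  expect_equal(b$diff, -a$diff, tolerance = 1e-12)
  expect_equal(b$raw_p, a$raw_p, tolerance = 1e-12)
  expect_equal(b$corrected_p, a$corrected_p, tolerance = 1e-12)
  expect_equal(b$mean_young, a$mean_aged)
})

test_that("composite scaling maps each region onto [-1, 1]", {
  d <- tibble::tibble(
    region = rep(c("posterior", "anterior"), each = 2),
    accession = "P1", segment = rep(1:2, 2),
    diff = c(0.02, -0.04, 0.5, 0.25)
  )
  cs <- composite_scale(d)
  expect_equal(cs$scaled, c(0.5, -1, 1, 0.5))

  # all-zero profiles stay at zero
  d0 <- d
  d0$diff <- 0
  expect_true(all(composite_scale(d0)$scaled == 0))

  expect_error(composite_scale(d[d$region == "posterior", ]),
               class = "plfr_error_composite_regions")
})
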