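# Synthetic study generator: tryptic digestion, random proteomes, and
# seeded simulation of per-region peptide tables with overdispersed
# spectral counts and implanted region-specific yield perturbations.

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to lysine (K) or arginine (R),
#' suppressed when the following residue is proline (P), and emits every
#' product with up to `missed_cleavage_max` missed cleavages, filtered to
#' the detectability length window. Coordinates are 1-based inclusive.
#'
#' @param sequence Amino-acid string.
#' @param missed_cleavage_max Maximum number of uncut internal sites per
#'   peptide (default 2).
#' @param length_window Two-element vector, minimum and maximum peptide
#'   length retained (default `c(7, 35)`, a typical detectable range).
#' @return A tibble with columns `peptide_seq`, `start`, `end`,
#'   `missed_cleavages`.
#' @examples
#' digest_tryptic("AKRPGK", missed_cleavage_max = 1, length_window = c(1, 35))
#' @export
digest_tryptic <- function(sequence, missed_cleavage_max = 2,
                           length_window = c(7, 35)) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) < 1) {
    plf_abort("`sequence` must be a single non-empty string", "bad_argument")
  }
  if (missed_cleavage_max < 0) {
    plf_abort("`missed_cleavage_max` must be >= 0", "bad_argument")
  }
  s <- toupper(sequence)
  n <- nchar(s)
  res <- strsplit(s, "", fixed = TRUE)[[1]]
  # cut sites: after K/R except before P (and never after the last residue)
  site <- which(res[-n] %in% c("K", "R") & res[-1] != "P")
  frag_start <- c(1L, site + 1L)
  frag_end <- c(site, n)
  nfrag <- length(frag_start)
  out <- map(0:missed_cleavage_max, function(mc) {
    if (nfrag - mc < 1) return(NULL)
    i <- seq_len(nfrag - mc)
    tibble(start = frag_start[i], end = frag_end[i + mc], missed_cleavages = mc)
  })
  out <- bind_rows(out)
  len <- out$end - out$start + 1L
  out <- out[len >= length_window[1] & len <= length_window[2], , drop = FALSE]
  out$peptide_seq <- if (nrow(out) == 0) character(0)
                     else substring(s, out$start, out$end)
  as_tibble(out[, c("peptide_seq", "start", "end", "missed_cleavages")])
}

#' Generate a random proteome with tryptic-realistic composition
#'
#' Random amino-acid sequences with the combined K+R frequency near the
#' ~11% typical of real proteomes, so tryptic peptide lengths are
#' realistic. Intended as input to [simulate_study()]; a user FASTA can
#' be supplied instead.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Two-element integer vector; each protein's length
#'   is drawn uniformly from this range. Use equal bounds for fixed
#'   lengths.
#' @param seed Optional integer; when given, the proteome is drawn under
#'   this seed without disturbing the caller's RNG state.
#' @return A protein tibble (`accession`, `sequence`, `length`) with
#'   accessions `SYNP0001`, `SYNP0002`, ...
#' @export
random_proteome <- function(n_proteins, length_range = c(300, 800),
                            seed = NULL) {
  draw <- function() {
    # K and R at 5.5% each; P at 5%; the remaining 17 residues uniform.
    other <- setdiff(strsplit("ACDEFGHILMNQSTVWY", "")[[1]], character(0))
    alphabet <- c("K", "R", "P", other)
    weights <- c(0.055, 0.055, 0.05, rep(0.84 / length(other), length(other)))
    len_choices <- seq(length_range[1], length_range[2])
    # sample() treats a length-1 vector as 1:n; guard the fixed-length case
    lens <- if (length(len_choices) == 1) rep(len_choices, n_proteins)
            else sample(len_choices, n_proteins, replace = TRUE)
    tibble(
      accession = sprintf("SYNP%04d", seq_len(n_proteins)),
      sequence = map_chr(lens, function(L) {
        paste(sample(alphabet, L, replace = TRUE, prob = weights),
              collapse = "")
      }),
      length = as.integer(lens)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Parameterise a synthetic two-group, multi-region study
#'
#' Bundles and validates everything that determines a simulated dataset:
#' the proteome, the replicate design, the count model and the implanted
#' effects. The seed fully determines the output of [simulate_study()].
#'
#' The count model: each protein draws a baseline expected total
#' spectral count (log-normal across proteins); each detectable tryptic
#' peptide receives a fixed uniform detectability weight (weights are
#' normalised within protein, so the baseline is the expected
#' whole-protein total). For every (sample, protein) a shared
#' Gamma(dispersion, dispersion) factor scales all of that protein's
#' peptide expectations, and counts are Poisson draws of the scaled
#' expectations — marginally each count is negative-binomial with size
#' `dispersion`, and replicate-to-replicate whole-protein totals vary
#' with coefficient of variation about `1/sqrt(dispersion)` (the
#' overdispersed replicate noise of spectral counting, dominated by
#' whole-protein abundance variation). Implanted effects multiply the
#' expectations of every peptide overlapping their residue interval, in
#' the stated group (and region, when given), wholesale.
#'
#' @param proteome Protein tibble; default `NULL` generates one with
#'   [random_proteome()] under the study seed.
#' @param n_proteins,length_range Passed to [random_proteome()] when no
#'   proteome is supplied.
#' @param regions Character vector of tissue-region labels.
#' @param n_young,n_aged Replicates per group: either a single number
#'   used for every region or a named vector by region (e.g.
#'   `c(posterior = 2, left_lateral = 3, anterior = 3)` to emulate a
#'   3 vs 2 posterior design).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-protein expected total spectral count (defaults `log(300)` and
#'   0.7: typical totals of tens to a few thousand).
#' @param baseline_total Optional fixed expected total overriding the
#'   log-normal draw (used by calibration scenarios).
#' @param detect_prob Probability that a digestible peptide is detectable
#'   at all (default 0.6).
#' @param length_window,missed_cleavage_max Digestion parameters, see
#'   [digest_tryptic()].
#' @param dispersion Negative-binomial size of the marginal count
#'   distribution; `Inf` gives Poisson counts. Default 25 (replicate
#'   CV about 20%).
#' @param effects Implanted perturbations: a data frame with columns
#'   `accession`, `start`, `end`, `group`, `fold_change` and optionally
#'   `region` (`NA` = all regions). `fold_change >= 0`; intervals must
#'   lie within their protein.
#' @param groups The two group labels, reference first.
#' @param seed Integer seed; fully determines the simulated dataset.
#' @return A validated `plf_study_spec` object.
#' @export
plf_study_spec <- function(proteome = NULL, n_proteins = 50,
                           length_range = c(300, 800),
                           regions = c("posterior", "left_lateral", "anterior"),
                           n_young = 3, n_aged = 3,
                           baseline_meanlog = log(300), baseline_sdlog = 0.7,
                           baseline_total = NULL,
                           detect_prob = 0.6, length_window = c(7, 35),
                           missed_cleavage_max = 2, dispersion = 25,
                           effects = NULL, groups = c("young", "aged"),
                           seed = 1L) {
  if (length(groups) != 2 || anyDuplicated(groups)) {
    plf_abort("`groups` must name exactly two distinct groups", "bad_argument")
  }
  if (length(regions) < 1 || anyDuplicated(regions)) {
    plf_abort("`regions` must be distinct labels", "bad_argument")
  }
  reps_by_region <- function(n, what) {
    if (!is.null(names(n))) {
      if (!setequal(names(n), regions)) {
        plf_abort(paste0("named `", what, "` must cover exactly the regions"),
                  "bad_argument")
      }
      n[regions]
    } else {
      if (length(n) != 1 || n < 1) {
        plf_abort(paste0("`", what, "` must be a positive count or a named vector by region"),
                  "bad_argument")
      }
      stats::setNames(rep(n, length(regions)), regions)
    }
  }
  if (is.null(effects)) {
    effects <- tibble(accession = character(0), start = integer(0),
                      end = integer(0), group = character(0),
                      fold_change = numeric(0), region = character(0))
  } else {
    effects <- as_tibble(effects)
    req <- c("accession", "start", "end", "group", "fold_change")
    if (!all(req %in% names(effects))) {
      plf_abort(paste0("`effects` needs columns: ", paste(req, collapse = ", ")),
                "bad_argument")
    }
    if (!"region" %in% names(effects)) effects$region <- NA_character_
    if (any(effects$fold_change < 0)) {
      plf_abort("`fold_change` must be >= 0", "bad_argument")
    }
    if (!all(effects$group %in% groups)) {
      plf_abort("effect `group` labels must match the study groups",
                "bad_argument")
    }
    if (!all(is.na(effects$region) | effects$region %in% regions)) {
      plf_abort("effect `region` labels must match the study regions",
                "bad_argument")
    }
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    plf_abort("`seed` must be a single integer", "bad_argument")
  }
  spec <- structure(
    list(
      proteome = proteome, n_proteins = n_proteins,
      length_range = length_range, regions = regions,
      n_young = reps_by_region(n_young, "n_young"),
      n_aged = reps_by_region(n_aged, "n_aged"),
      baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
      baseline_total = baseline_total,
      detect_prob = detect_prob, length_window = length_window,
      missed_cleavage_max = missed_cleavage_max, dispersion = dispersion,
      effects = effects, groups = groups, seed = as.integer(seed)
    ),
    class = "plf_study_spec"
  )
  if (!is.null(proteome)) validate_effects(effects, proteome)
  spec
}

validate_effects <- function(effects, proteome) {
  if (nrow(effects) == 0) return(invisible(TRUE))
  j <- match(effects$accession, proteome$accession)
  if (anyNA(j)) {
    plf_abort(paste0("effect(s) reference unknown accession(s): ",
                     brief(effects$accession[is.na(j)])), "unknown_accession")
  }
  bad <- effects$start < 1 | effects$end > proteome$length[j] |
    effects$start > effects$end
  if (any(bad)) {
    plf_abort(paste0("effect interval(s) fall outside their protein: ",
                     brief(effects$accession[bad])), "bad_coordinates")
  }
  invisible(TRUE)
}

#' @export
print.plf_study_spec <- function(x, ...) {
  cat("Synthetic PLF study spec\n")
  cat("  proteome: ",
      if (is.null(x$proteome)) paste0(x$n_proteins, " random proteins (",
                                      x$length_range[1], "-", x$length_range[2], " aa)")
      else paste0(nrow(x$proteome), " supplied proteins"), "\n", sep = "")
  cat("  regions: ", paste(x$regions, collapse = ", "), "\n", sep = "")
  cat("  replicates (", x$groups[1], " vs ", x$groups[2], "): ",
      paste(paste0(x$regions, " ", x$n_young, "v", x$n_aged), collapse = ", "),
      "\n", sep = "")
  cat("  dispersion (NB size): ", x$dispersion, "; detect_prob: ",
      x$detect_prob, "\n", sep = "")
  cat("  effects: ", nrow(x$effects), "; seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a synthetic spectral-count study
#'
#' Draws a complete synthetic dataset — proteome, per-region peptide
#' tables in the exact schema [read_peptide_table()] consumes, the
#' sample design, and the ground-truth effect table — under the count
#' model described in [plf_study_spec()]. The same spec (including seed)
#' always produces an identical dataset; the caller's RNG state is left
#' untouched.
#'
#' @param spec A [plf_study_spec()] object.
#' @return An object of class `plf_simulation`: a list with `proteins`,
#'   `peptides` (columns `sample_id`, `group`, `region`, `accession`,
#'   `peptide_seq`, `spectral_count`; zero counts are not emitted),
#'   `samples` (the declared design), `effects` and `spec`.
#' @export
simulate_study <- function(spec) {
  if (!inherits(spec, "plf_study_spec")) {
    plf_abort("`spec` must be a plf_study_spec object", "bad_argument")
  }
  withr::with_seed(spec$seed, {
    proteome <- spec$proteome %||%
      random_proteome(spec$n_proteins, spec$length_range)
    validate_effects(spec$effects, proteome)

    # Digest every protein; fix detectability and weights once per study.
    peps <- proteome |>
      mutate(dig = map(.data$sequence, digest_tryptic,
                       missed_cleavage_max = spec$missed_cleavage_max,
                       length_window = spec$length_window)) |>
      select("accession", "dig") |>
      unnest("dig")
    peps <- peps[runif(nrow(peps)) < spec$detect_prob, , drop = FALSE]
    peps$weight <- runif(nrow(peps))
    peps <- peps |>
      mutate(weight = .data$weight / sum(.data$weight), .by = "accession")

    baseline <- tibble(
      accession = proteome$accession,
      baseline = spec$baseline_total %||%
        rlnorm(nrow(proteome), spec$baseline_meanlog, spec$baseline_sdlog)
    )

    samples <- bind_rows(map(spec$regions, function(r) {
      tibble(
        region = r,
        group = rep(spec$groups, c(spec$n_young[[r]], spec$n_aged[[r]])),
        replicate = c(seq_len(spec$n_young[[r]]), seq_len(spec$n_aged[[r]]))
      )
    })) |>
      mutate(sample_id = paste(.data$region, .data$group, .data$replicate,
                               sep = "_")) |>
      select("region", "sample_id", "group")

    grid <- tidyr::expand_grid(samples, select(peps, "accession", "peptide_seq",
                                               "start", "end", "weight")) |>
      left_join(baseline, by = "accession")

    # Implanted effects: multiply expectations of overlapping peptides in
    # the matching group (and region, when stated), wholesale.
    grid$fold <- 1
    if (nrow(spec$effects) > 0) {
      for (i in seq_len(nrow(spec$effects))) {
        e <- spec$effects[i, ]
        hit <- grid$accession == e$accession & grid$group == e$group &
          grid$start <= e$end & grid$end >= e$start &
          (is.na(e$region) | grid$region == e$region)
        grid$fold[hit] <- grid$fold[hit] * e$fold_change
      }
    }

    # Shared per-(sample, protein) overdispersion factor, then Poisson.
    lam <- grid |>
      distinct(.data$sample_id, .data$accession) |>
      mutate(lambda = if (is.finite(spec$dispersion)) {
        rgamma(n(), shape = spec$dispersion, rate = spec$dispersion)
      } else 1)
    grid <- grid |>
      left_join(lam, by = c("sample_id", "accession")) |>
      mutate(mu = .data$baseline * .data$weight * .data$fold * .data$lambda,
             spectral_count = rpois(n(), .data$mu)) |>
      filter(.data$spectral_count > 0)

    peptides <- grid |>
      summarise(spectral_count = as.integer(sum(.data$spectral_count)),
                .by = c("sample_id", "group", "region", "accession",
                        "peptide_seq")) |>
      arrange(.data$region, .data$group, .data$sample_id, .data$accession,
              .data$peptide_seq)

    structure(
      list(proteins = proteome, peptides = peptides, samples = samples,
           effects = spec$effects, spec = spec),
      class = "plf_simulation"
    )
  })
}

#' @export
print.plf_simulation <- function(x, ...) {
  cat("Synthetic PLF study: ", nrow(x$proteins), " proteins, ",
      nrow(x$samples), " samples, ", nrow(x$peptides),
      " peptide observations, ", nrow(x$effects), " implanted effect(s)\n",
      sep = "")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits the FASTA and the delimited peptide tables (one CSV per region)
#' that [read_protein_fasta()] and [read_peptide_table()] consume, plus
#' the sample design and the ground-truth effect table.
#'
#' @param sim A `plf_simulation` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_study <- function(sim, dir) {
  if (!inherits(sim, "plf_simulation")) {
    plf_abort("`sim` must be a plf_simulation object", "bad_argument")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "proteome.fasta")
  seqs <- Biostrings::AAStringSet(sim$proteins$sequence)
  names(seqs) <- sim$proteins$accession
  Biostrings::writeXStringSet(seqs, fasta, width = 60)
  tables <- map_chr(unique(sim$peptides$region), function(r) {
    path <- file.path(dir, paste0("peptides_", r, ".csv"))
    readr::write_csv(filter(sim$peptides, .data$region == r), path,
                     progress = FALSE)
    path
  })
  samples_path <- file.path(dir, "samples.tsv")
  readr::write_tsv(sim$samples, samples_path, progress = FALSE)
  effects_path <- file.path(dir, "effects.tsv")
  readr::write_tsv(sim$effects, effects_path, progress = FALSE)
  invisible(list(fasta = fasta, peptide_tables = tables,
                 samples = samples_path, effects = effects_path))
}
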