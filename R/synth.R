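# A 43-nt guideline-perfect block (12-nt flank + 19-nt core + 12-nt flank):
# core GC 7/19 = 36.8%, G at the sense 5' end, A at the core 3' end (so the
# antisense 5' base is U), 6 A/U in the seed 7-mer; flanks pool to 50% GC;
# the 2 nt upstream of the core are AA and the 2 nt downstream UU, giving
# both overhang classes their best value. Planting it guarantees rank key
# (0, 0, 0, start).
IDEAL_FLANK_UP <- "GCGCGCGCGCAA"
IDEAL_CORE     <- "GCAUGGCAUAUGCAUAUUA"
IDEAL_FLANK_DN <- "UUGCAUAUAUAU"

#' Simulate a random transcript, optionally with planted target sites
#'
#' Generates a seeded random mRNA with i.i.d. background composition at a
#' chosen GC fraction, writes an AUG at the coding start, and optionally
#' overwrites planted regions: either the built-in guideline-perfect block
#' (core plus designed flanks and overhang context, which [design_sirnas()]
#' must rank first) or a user-supplied 19-nt core.
#'
#' @param length Transcript length in nt.
#' @param gc Background GC fraction in `[0, 1]` (default 0.5).
#' @param seed RNG seed (required; generation is deterministic given it).
#' @param cds_start 0-based position at which an AUG is written (default 0).
#' @param planted_sites Positions of planted cores, either an integer vector
#'   of 0-based core start offsets (each planted as the "ideal" block), or a
#'   data frame with columns `offset` and `template` where `template` is
#'   `"ideal"` or an explicit 19-nt core. Ideal sites overwrite
#'   `offset - 12 .. offset + 30` and must fit inside the sequence; planted
#'   regions must not overlap each other or the AUG.
#' @param id Record identifier (default `"synth1"`).
#' @return A one-row transcript tibble (`id`, `seq`, `cds_start`).
#' @examples
#' simulate_transcript(400, gc = 0.5, seed = 1, planted_sites = 120)
#' @export
simulate_transcript <- function(length, gc = 0.5, seed, cds_start = 0L,
                                planted_sites = NULL, id = "synth1") {
  stopifnot(length >= cds_start + 3L, gc >= 0, gc <= 1)
  withr::local_seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  chars <- sample(names(probs), length, replace = TRUE, prob = probs)
  write_at <- function(chars, s, offset) {   # offset 0-based
    v <- strsplit(s, "")[[1L]]
    if (offset < 0L || offset + length(v) > length(chars)) {
      stop("planted region [", offset, ", ", offset + length(v),
           ") out of bounds for length ", length(chars))
    }
    chars[offset + seq_along(v)] <- v
    chars
  }
  chars <- write_at(chars, "AUG", cds_start)
  if (!is.null(planted_sites)) {
    if (!is.data.frame(planted_sites)) {
      planted_sites <- tibble::tibble(offset = as.integer(planted_sites),
                                      template = "ideal")
    }
    blocks <- purrr::pmap(planted_sites, function(offset, template) {
      if (identical(template, "ideal")) {
        list(start = offset - nchar(IDEAL_FLANK_UP),
             s = paste0(IDEAL_FLANK_UP, IDEAL_CORE, IDEAL_FLANK_DN))
      } else {
        stopifnot(nchar(template) == 19L)
        list(start = offset, s = to_rna(template))
      }
    })
    starts <- vapply(blocks, function(b) as.integer(b$start), integer(1))
    ends <- starts + vapply(blocks, function(b) nchar(b$s), integer(1))
    ord <- order(starts)
    if (any(starts[ord][-1L] < ends[ord][-length(ord)])) {
      stop("planted sites overlap")
    }
    if (any(starts < cds_start + 3L & ends > cds_start)) {
      stop("planted site overlaps the initiation codon at cds_start = ", cds_start)
    }
    for (b in blocks) chars <- write_at(chars, b$s, b$start)
  }
  transcript(id, paste(chars, collapse = ""), cds_start = as.integer(cds_start))
}

#' Simulate a transcriptome of random subjects
#'
#' @param n Number of subjects.
#' @param length Length of each subject in nt (recycled).
#' @param gc Background GC fraction (default 0.5).
#' @param seed RNG seed.
#' @param prefix Id prefix; subjects are named `prefix1 .. prefixN`.
#' @return Transcript tibble with `n` rows (AUG forced at position 0 of each).
#' @export
simulate_transcriptome <- function(n, length, gc = 0.5, seed, prefix = "subj") {
  withr::local_seed(seed)
  seeds <- sample.int(.Machine$integer.max, n)
  lens <- rep_len(length, n)
  purrr::map_dfr(seq_len(n), function(i) {
    simulate_transcript(lens[[i]], gc = gc, seed = seeds[[i]],
                        id = paste0(prefix, i))
  })
}

#' Introduce random substitutions into a sequence
#'
#' Utility for planting near-exact off-target decoys: substitutes
#' `n_mismatches` distinct positions with a different base each.
#'
#' @param s A single RNA string.
#' @param n_mismatches Number of positions to mutate.
#' @param seed RNG seed.
#' @return The mutated string, at Hamming distance exactly `n_mismatches`
#'   from `s`.
#' @export
mutate_sequence <- function(s, n_mismatches, seed) {
  s <- to_rna(s)
  if (n_mismatches == 0L) return(s)
  withr::local_seed(seed)
  v <- strsplit(s, "")[[1L]]
  pos <- sample(seq_along(v), n_mismatches)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "U"), v[p]), 1L)
  paste(v, collapse = "")
}

#' Simulate a knockdown dose-response experiment
#'
#' Draws relative mRNA levels from the decay model with multiplicative
#' lognormal noise: `rel = a * exp(-b * x) * exp(eps)`, `eps ~ N(0, sigma^2)`.
#' Multiplicative noise keeps ratios positive and matches the log-linear
#' model fitted by [fit_decay()]. With `noise_sigma = 0` the values are the
#' exact model predictions.
#'
#' @param a Amplitude at dose 0.
#' @param b Decay rate per micromolar.
#' @param doses Numeric vector of concentrations in micromolar.
#' @param replicates Observations per dose (default 1).
#' @param noise_sigma Lognormal sigma (default 0).
#' @param seed RNG seed.
#' @return Tibble of `length(doses) * replicates` rows with columns `conc`
#'   and `rel_mrna`, ready for [fit_decay()].
#' @examples
#' simulate_dose_data(0.9, 0.028, c(0, 25, 50, 100), replicates = 4,
#'                    noise_sigma = 0.1, seed = 42)
#' @export
simulate_dose_data <- function(a, b, doses, replicates = 1L, noise_sigma = 0,
                               seed) {
  stopifnot(a > 0, b >= 0, replicates >= 1L, noise_sigma >= 0)
  withr::local_seed(seed)
  conc <- rep(doses, each = replicates)
  eps <- stats::rnorm(length(conc), 0, noise_sigma)
  tibble::tibble(conc = conc, rel_mrna = a * exp(-b * conc) * exp(eps))
}

#' Write a canonical bundle of synthetic fixtures to a directory
#'
#' Emits a small self-consistent test bundle: a FASTA of transcripts with one
#' planted guideline-perfect site each, a decoy transcriptome FASTA, and a
#' simulated dose-response CSV.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @return `dir`, invisibly. Files: `targets.fa`, `transcriptome.fa`,
#'   `dose_response.csv`.
#' @export
write_fixture_bundle <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::local_seed(seed)
  seeds <- sample.int(.Machine$integer.max, 4)
  targets <- dplyr::bind_rows(
    simulate_transcript(600, gc = 0.5, seed = seeds[[1]], planted_sites = 150,
                        id = "gene1"),
    simulate_transcript(800, gc = 0.45, seed = seeds[[2]], planted_sites = 300,
                        id = "gene2"))
  write_transcripts(targets, file.path(dir, "targets.fa"))
  write_transcripts(simulate_transcriptome(5, 500, seed = seeds[[3]]),
                    file.path(dir, "transcriptome.fa"))
  dose <- simulate_dose_data(0.9, 0.028, c(0, 25, 50, 100), replicates = 4,
                             noise_sigma = 0.1, seed = seeds[[4]])
  readr::write_csv(dplyr::rename(dose, conc_uM = "conc"),
                   file.path(dir, "dose_response.csv"))
  invisible(dir)
}
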