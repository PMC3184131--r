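#' Format designed candidates as a report table
#'
#' Converts the internal candidate tibble (0-based half-open coordinates,
#' unrounded percentages) into the human-facing report layout: 1-based
#' inclusive coordinates, GC percentages rounded to 1 decimal, one row per
#' candidate sorted by rank within gene.
#'
#' @param candidates Candidate tibble from [design_sirnas()], optionally
#'   after [annotate_offtargets()].
#' @return Tibble with columns `gene_id`, `start_1based`, `end_1based`,
#'   `sense21`, `antisense21`, `core19`, `gc_core_pct`, `flank_gc_pct`,
#'   `flank_gc_dev`, `au_in_seed7`, `downstream_offset`, the pass flags,
#'   `s_overhang_class`, `as_overhang_class`, `rank`, `selected` (0/1) and
#'   `offtarget_hits` (`NA` when no screen was run).
#' @export
design_report <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  hits <- if ("offtarget_hits" %in% names(candidates)) {
    candidates$offtarget_hits
  } else {
    rep(NA_integer_, nrow(candidates))
  }
  out <- tibble::tibble(
    gene_id = candidates$transcript_id,
    start_1based = candidates$start + 1L,
    end_1based = candidates$start + nchar(candidates$core),
    sense21 = candidates$sense21,
    antisense21 = candidates$antisense21,
    core19 = candidates$core,
    gc_core_pct = round(candidates$gc_core, 1),
    flank_gc_pct = round(candidates$flank_gc, 1),
    flank_gc_dev = round(candidates$flank_gc_dev, 1),
    au_in_seed7 = candidates$au_in_seed7,
    downstream_offset = candidates$downstream_offset,
    pass_gc_core = candidates$pass_gc,
    pass_sense_5p = candidates$pass_sense5,
    pass_antisense_5p = candidates$pass_antisense5,
    pass_position = candidates$pass_position,
    pass_au_seed7 = candidates$pass_au,
    s_overhang_class = candidates$s_overhang_class,
    as_overhang_class = candidates$as_overhang_class,
    rank = candidates$rank,
    selected = as.integer(candidates$selected),
    offtarget_hits = hits
  )
  dplyr::arrange(out, .data$gene_id, .data$rank)
}

#' Write a design report as TSV
#'
#' Tab-separated, UTF-8, Unix newlines, `NA` for missing values; the header
#' row is always emitted, even for an empty report. Output is byte-identical
#' across runs for identical inputs.
#'
#' @param candidates Candidate tibble from [design_sirnas()].
#' @param path Output path, or `""` for standard output.
#' @return The report tibble, invisibly.
#' @export
write_design_report <- function(candidates, path = "") {
  rep <- design_report(candidates)
  if (identical(path, "")) {
    readr::write_tsv(rep, stdout(), na = "NA")
  } else {
    readr::write_tsv(rep, path, na = "NA")
  }
  invisible(rep)
}

#' Run the design pipeline end to end (CLI backend)
#'
#' Reads transcripts, designs siRNAs, optionally screens them against a
#' transcriptome, and writes the TSV report. This is the function behind the
#' `design` subcommand of the shipped command-line script
#' (`system.file("cli", "sirnadesign.R", package = "sirnadesign")`).
#'
#' @param fasta Path to the target FASTA.
#' @param cds_map Optional coding-start map (see [read_transcripts()]).
#' @param out Output TSV path, or `""` for standard output.
#' @param params A [design_params()] object.
#' @param transcriptome Optional FASTA path for off-target screening.
#' @param max_mismatches Off-target Hamming cutoff (default 2).
#' @return Integer exit status, invisibly: 0 when every gene received
#'   `n_select` selected siRNAs, 3 when any gene received fewer (the report
#'   is still written).
#' @export
run_design <- function(fasta, cds_map = NULL, out = "",
                       params = design_params(), transcriptome = NULL,
                       max_mismatches = 2L) {
  tx <- read_transcripts(fasta, cds_map)
  status <- 0L
  withCallingHandlers(
    cand <- design_sirnas(tx, params),
    warning = function(w) {
      if (grepl("could be selected", conditionMessage(w))) {
        status <<- 3L
        message(conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  if (!is.null(transcriptome)) {
    subjects <- read_transcripts(transcriptome)
    cand <- annotate_offtargets(cand, subjects, max_mismatches = max_mismatches)
  }
  write_design_report(cand, out)
  invisible(status)
}

#' Run an off-target scan for one core (CLI backend)
#'
#' @param core A 19-nt core sequence.
#' @param transcriptome FASTA path to screen against.
#' @param max_mismatches Hamming cutoff (default 2).
#' @param out Output TSV path, or `""` for standard output.
#' @param exclude_id Optional subject id to exclude (the intended target).
#' @return The hit tibble (1-based coordinates), invisibly.
#' @export
run_offtarget <- function(core, transcriptome, max_mismatches = 2L, out = "",
                          exclude_id = NULL) {
  subjects <- read_transcripts(transcriptome)
  index <- build_offtarget_index(subjects)
  hits <- scan_offtargets(core, index, max_mismatches, exclude_id)
  hits <- dplyr::mutate(hits, subject_start_1based = .data$subject_start + 1L)
  hits <- dplyr::select(hits, "subject_id", "subject_start_1based", "strand",
                        "mismatches")
  if (identical(out, "")) readr::write_tsv(hits, stdout(), na = "NA")
  else readr::write_tsv(hits, out, na = "NA")
  invisible(hits)
}

#' Fit the knockdown model to a dose table (CLI backend)
#'
#' @param csv Path to a dose-response CSV (see [read_dose_table()]).
#' @param level Knockdown level for the effective concentration (default 0.5).
#' @param out Output CSV path for per-point residuals, or `""` for standard
#'   output.
#' @return The fitted [decay_fit()], invisibly. Fit parameters and the
#'   effective concentration are written to the message stream.
#' @export
run_fit <- function(csv, level = 0.5, out = "") {
  fit <- fit_decay(read_dose_table(csv))
  message(sprintf("a = %.6g  b = %.6g per uM  R = %.4f  n = %d",
                  fit$a, fit$b, fit$R, fit$n))
  ec <- tryCatch(effective_concentration(fit, level), error = function(e) NA_real_)
  if (is.finite(ec)) {
    message(sprintf("effective concentration at level %.2g: %.2f uM", level, ec))
  } else {
    message("effective concentration at level ", level, ": not reached")
  }
  resid <- augment(fit)
  if (identical(out, "")) readr::write_csv(resid, stdout(), na = "NA")
  else readr::write_csv(resid, out, na = "NA")
  invisible(fit)
}
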