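#' Design parameters for the siRNA guideline
#'
#' Bundles every tunable threshold of the eight-criterion design guideline.
#' Defaults are the guideline's published values; change them only with a
#' reason.
#'
#' @param core_len Length in nt of the base-paired duplex core (default 19).
#' @param strand_len Length in nt of each full strand, core plus the 2-nt 3'
#'   overhang (default 21; must equal `core_len + 2`).
#' @param gc_min,gc_max Bounds in percent on the GC content of the core
#'   (criterion GC_CORE; defaults 35 and 55).
#' @param min_downstream Minimum distance in nt between the end of the AUG
#'   codon and the core start (criterion POSITION; default 75), keeping the
#'   duplex clear of translation-initiation factor binding sites.
#' @param flank_len Length in nt of each flanking window on the mRNA
#'   (default 12); flank GC is pooled over the concatenated
#'   `2 * flank_len` nt.
#' @param flank_gc_target Preferred pooled flank GC in percent (criterion
#'   FLANK_GC; default 50). Deviation from it is the primary ranking key.
#' @param flank_gc_max_dev Optional hard cutoff in percent on
#'   `|flank_gc - flank_gc_target|`; `NULL` (the default) keeps FLANK_GC
#'   rank-only, since no numeric band is published.
#' @param au_min_in_seed7 Minimum count of A/U bases among the 7 nt at the 5'
#'   end of the antisense strand (criterion AU_SEED7; default 4, i.e. "more
#'   than three").
#' @param n_select How many siRNAs to select per gene (default 2).
#' @param require_nonoverlap If `TRUE` (default) the selected cores must not
#'   overlap on the mRNA, so the selected pair targets distinct positions.
#' @return A list of class `design_params`.
#' @examples
#' design_params()
#' design_params(gc_max = 60, n_select = 3)
#' @export
design_params <- function(core_len = 19L, strand_len = 21L,
                          gc_min = 35, gc_max = 55,
                          min_downstream = 75L,
                          flank_len = 12L,
                          flank_gc_target = 50, flank_gc_max_dev = NULL,
                          au_min_in_seed7 = 4L,
                          n_select = 2L, require_nonoverlap = TRUE) {
  p <- list(core_len = as.integer(core_len), strand_len = as.integer(strand_len),
            gc_min = gc_min, gc_max = gc_max,
            min_downstream = as.integer(min_downstream),
            flank_len = as.integer(flank_len),
            flank_gc_target = flank_gc_target,
            flank_gc_max_dev = flank_gc_max_dev,
            au_min_in_seed7 = as.integer(au_min_in_seed7),
            n_select = as.integer(n_select),
            require_nonoverlap = isTRUE(require_nonoverlap))
  stopifnot(p$gc_min >= 0, p$gc_min <= p$gc_max, p$gc_max <= 100,
            p$core_len + 2L == p$strand_len,
            p$au_min_in_seed7 <= 7L, p$n_select >= 1L,
            p$flank_len >= 2L, p$min_downstream >= 0L)
  structure(p, class = "design_params")
}

#' @export
print.design_params <- function(x, ...) {
  cat("siRNA design parameters\n")
  cat(sprintf("  core %d nt, strand %d nt; core GC in [%g, %g]%%\n",
              x$core_len, x$strand_len, x$gc_min, x$gc_max))
  cat(sprintf("  core start >= AUG end + %d nt\n", x$min_downstream))
  cat(sprintf("  flanks %d nt each, pooled GC target %g%% (%s)\n",
              x$flank_len, x$flank_gc_target,
              if (is.null(x$flank_gc_max_dev)) "rank-only"
              else sprintf("hard cutoff dev <= %g", x$flank_gc_max_dev)))
  cat(sprintf("  >= %d A/U in antisense seed 7-mer; select %d%s per gene\n",
              x$au_min_in_seed7, x$n_select,
              if (x$require_nonoverlap) " non-overlapping" else ""))
  invisible(x)
}

#' Enumerate candidate target sites along transcripts
#'
#' Slides a `core_len` window over each transcript, keeping every placement
#' with a full `flank_len` window on both sides. Windows without complete
#' flanks are never candidates because their flanking GC is undefined.
#'
#' @param transcripts Transcript tibble from [read_transcripts()] or
#'   [transcript()].
#' @param params A [design_params()] object.
#' @return Tibble with one row per candidate site, in ascending `start` within
#'   each transcript: `transcript_id`, `start` (0-based index of the core on
#'   the mRNA), `core`, `flank_up`, `flank_down` (verbatim mRNA substrings),
#'   `upstream2`/`downstream2` (the 2 nt abutting the core on each side).
#'   Transcripts shorter than `core_len + 2 * flank_len` contribute no rows
#'   (a message is emitted).
#' @export
enumerate_sites <- function(transcripts, params = design_params()) {
  stopifnot(is.data.frame(transcripts))
  fl <- params$flank_len; cl <- params$core_len
  per <- function(id, seq) {
    n <- nchar(seq)
    hi <- n - cl - fl
    if (hi < fl) {
      message("transcript '", id, "' (", n,
              " nt) is shorter than the minimum design window; no candidates")
      return(NULL)
    }
    start <- fl:hi
    tibble::tibble(
      transcript_id = id,
      start = as.integer(start),
      core = substr(rep(seq, length(start)), start + 1L, start + cl),
      flank_up = substr(rep(seq, length(start)), start - fl + 1L, start),
      flank_down = substr(rep(seq, length(start)), start + cl + 1L, start + cl + fl)
    )
  }
  out <- purrr::map2(transcripts$id, transcripts$seq, per)
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble::tibble(transcript_id = character(), start = integer(),
                          core = character(), flank_up = character(),
                          flank_down = character(), upstream2 = character(),
                          downstream2 = character()))
  }
  dplyr::mutate(out,
                upstream2 = substr(.data$flank_up, fl - 1L, fl),
                downstream2 = substr(.data$flank_down, 1L, 2L))
}

#' Evaluate the guideline criteria at each candidate site
#'
#' Computes, per site, the quantities and pass flags of the sequence-level
#' criteria: core GC content (GC_CORE), the sense-strand 5' base (SENSE_5P,
#' wants G/C), the antisense-strand 5' base (ANTISENSE_5P, the complement of
#' the core's last base, wants A/U), distance downstream of the initiation
#' codon (POSITION), pooled flanking GC (FLANK_GC), and the A/U count in the
#' seed-proximal 7-mer at the antisense 5' end (AU_SEED7) — which equals the
#' A/U count of the last 7 core bases.
#'
#' @param sites Site tibble from [enumerate_sites()].
#' @param transcripts The transcript tibble the sites were derived from
#'   (supplies `cds_start`).
#' @param params A [design_params()] object.
#' @return `sites` with criterion columns appended: `gc_core`, `pass_gc`,
#'   `sense5`, `pass_sense5`, `antisense5`, `pass_antisense5`,
#'   `downstream_offset`, `pass_position`, `flank_gc`, `flank_gc_dev`,
#'   `au_in_seed7`, `pass_au`.
#' @export
evaluate_sites <- function(sites, transcripts, params = design_params()) {
  if (nrow(sites) == 0L) {
    return(dplyr::mutate(sites,
      gc_core = numeric(0), pass_gc = logical(0), sense5 = character(0),
      pass_sense5 = logical(0), antisense5 = character(0),
      pass_antisense5 = logical(0), downstream_offset = integer(0),
      pass_position = logical(0), flank_gc = numeric(0),
      flank_gc_dev = numeric(0), au_in_seed7 = integer(0), pass_au = logical(0)))
  }
  cl <- params$core_len
  cds <- stats::setNames(transcripts$cds_start, transcripts$id)
  last_base <- substr(sites$core, cl, cl)
  seed7 <- substr(sites$core, cl - 6L, cl)
  dplyr::mutate(sites,
    gc_core = gc_content(.data$core),
    pass_gc = .data$gc_core >= params$gc_min & .data$gc_core <= params$gc_max,
    sense5 = substr(.data$core, 1L, 1L),
    pass_sense5 = .data$sense5 %in% c("G", "C"),
    antisense5 = chartr("ACGU", "UGCA", last_base),
    pass_antisense5 = .data$antisense5 %in% c("A", "U"),
    downstream_offset = .data$start - (unname(cds[.data$transcript_id]) + 3L),
    pass_position = .data$downstream_offset >= params$min_downstream,
    flank_gc = gc_content(paste0(.data$flank_up, .data$flank_down)),
    flank_gc_dev = abs(.data$flank_gc - params$flank_gc_target),
    au_in_seed7 = nchar(seed7) - nchar(gsub("[AU]", "", seed7)),
    pass_au = .data$au_in_seed7 >= params$au_min_in_seed7
  )
}

#' Construct the 21-nt duplex strands for candidate sites
#'
#' The antisense (guide) strand is the reverse complement of the 19-nt core
#' plus a fixed `UU` 3' overhang. The sense strand is the core plus the next
#' two mRNA bases taken verbatim (no substitution is ever made; an unfavorable
#' overhang only demotes rank). Overhang classes grade the two overhang
#' criteria: the antisense overhang counts as `UU` only when the mRNA bases
#' upstream of the core are `AA`, so the synthetic `UU` still base-pairs with
#' the target; the sense overhang is classed `UU`, `AA`, `U_FIRST` (U then
#' any base), `U_SECOND` (any base then U) or `FAIL`.
#'
#' @param sites Site tibble from [enumerate_sites()] (evaluated or not).
#' @return `sites` with `sense21`, `antisense21`, `s_overhang`, `as_overhang`,
#'   `s_overhang_class` and `as_overhang_class` appended.
#' @export
construct_duplexes <- function(sites) {
  if (nrow(sites) == 0L) {
    return(dplyr::mutate(sites, sense21 = character(0), antisense21 = character(0),
      s_overhang = character(0), as_overhang = character(0),
      s_overhang_class = character(0), as_overhang_class = character(0)))
  }
  s_oh <- sites$downstream2
  dplyr::mutate(sites,
    sense21 = paste0(.data$core, s_oh),
    antisense21 = paste0(rna_revcomp(.data$core), "UU"),
    s_overhang = s_oh,
    as_overhang = "UU",
    s_overhang_class = dplyr::case_when(
      s_oh == "UU" ~ "UU",
      s_oh == "AA" ~ "AA",
      substr(s_oh, 1L, 1L) == "U" ~ "U_FIRST",
      substr(s_oh, 2L, 2L) == "U" ~ "U_SECOND",
      TRUE ~ "FAIL"),
    as_overhang_class = ifelse(.data$upstream2 == "AA", "UU", "OTHER")
  )
}

# rank penalties for the overhang classes; smaller is better
s_overhang_penalty <- function(class) {
  unname(c(UU = 0L, AA = 1L, U_FIRST = 2L, U_SECOND = 2L, FAIL = 3L)[class])
}
as_overhang_penalty <- function(class) {
  unname(c(UU = 0L, OTHER = 1L)[class])
}

#' Design siRNAs for each transcript by staged filter-then-rank selection
#'
#' Runs the full guideline per gene: (1) enumerate every candidate site with
#' complete flanks; (2) hard-filter on the sequence criteria (core GC within
#' bounds, G/C sense 5' end, A/U antisense 5' end, AU-rich seed 7-mer);
#' (3) keep sites far enough downstream of the initiation codon; (4) if
#' `flank_gc_max_dev` is set, hard-filter on flank-GC deviation; (5) rank
#' survivors by flank-GC deviation, then sense-overhang class, then
#' antisense-overhang class, then position; (6) flag the best `n_select`
#' candidates as selected, greedily skipping candidates whose core overlaps an
#' already-selected core when `require_nonoverlap`.
#'
#' @param transcripts Transcript tibble ([read_transcripts()], [transcript()]).
#' @param params A [design_params()] object.
#' @return A tibble of all surviving candidates (not just the selected ones),
#'   ranked within each transcript, carrying the site, criterion, and duplex
#'   columns plus `s_penalty`, `as_penalty`, `rank` (1 = best) and `selected`
#'   (logical). Identical inputs always give identical output; ties in all
#'   rank keys are broken by `start`. A gene yielding fewer than `n_select`
#'   selected candidates triggers a warning naming it.
#' @examples
#' tx <- simulate_transcript(400, gc = 0.5, seed = 7, planted_sites = 120)
#' design_sirnas(tx)
#' @export
design_sirnas <- function(transcripts, params = design_params()) {
  sites <- enumerate_sites(transcripts, params)
  ev <- evaluate_sites(sites, transcripts, params)
  surv <- dplyr::filter(ev,
    .data$pass_gc & .data$pass_sense5 & .data$pass_antisense5 & .data$pass_au,
    .data$pass_position)
  if (!is.null(params$flank_gc_max_dev)) {
    surv <- dplyr::filter(surv, .data$flank_gc_dev <= params$flank_gc_max_dev)
  }
  surv <- construct_duplexes(surv)
  if (nrow(surv) == 0L) {
    for (id in transcripts$id) {
      warning("transcript '", id, "': 0 of ", params$n_select,
              " requested siRNAs could be selected", call. = FALSE)
    }
    return(dplyr::mutate(surv, s_penalty = integer(0), as_penalty = integer(0),
                         rank = integer(0), selected = logical(0)))
  }
  surv <- dplyr::mutate(surv,
                        s_penalty = s_overhang_penalty(.data$s_overhang_class),
                        as_penalty = as_overhang_penalty(.data$as_overhang_class))
  surv <- dplyr::arrange(surv, .data$transcript_id, .data$flank_gc_dev,
                         .data$s_penalty, .data$as_penalty, .data$start)
  surv <- dplyr::group_by(surv, .data$transcript_id)
  surv <- dplyr::mutate(surv, rank = dplyr::row_number())
  surv <- dplyr::mutate(surv, selected = select_nonoverlapping(
    .data$start, params$core_len, params$n_select, params$require_nonoverlap))
  surv <- dplyr::ungroup(surv)
  n_sel <- dplyr::count(dplyr::filter(surv, .data$selected), .data$transcript_id)
  for (id in transcripts$id) {
    got <- n_sel$n[match(id, n_sel$transcript_id)]
    if (is.na(got)) got <- 0L
    if (got < params$n_select) {
      warning("transcript '", id, "': only ", got, " of ", params$n_select,
              " requested siRNAs could be selected", call. = FALSE)
    }
  }
  surv
}

# greedy selection down the ranked order, optionally skipping core overlaps
select_nonoverlapping <- function(start, core_len, n_select, require_nonoverlap) {
  sel <- logical(length(start))
  taken <- integer(0)
  for (i in seq_along(start)) {
    if (sum(sel) >= n_select) break
    if (require_nonoverlap && length(taken) &&
        any(abs(start[i] - taken) < core_len)) next
    sel[i] <- TRUE
    taken <- c(taken, start[i])
  }
  sel
}
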