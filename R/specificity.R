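#' Build a k-mer index over a transcriptome for off-target scanning
#'
#' Indexes every k-mer of every subject sequence, on both the given strand and
#' its reverse complement, mapping word -> (subject, strand, position).
#' Construction is deterministic. The returned object also retains the
#' subject sequences, so [scan_offtargets()] can re-index at a smaller word
#' size when completeness demands it.
#'
#' @param transcriptome Transcript tibble (or any data frame with `id` and
#'   `seq` columns) to screen against.
#' @param k Word size in nt (default 11). Must not exceed the core length you
#'   intend to scan with.
#' @return An object of class `offtarget_index`.
#' @export
build_offtarget_index <- function(transcriptome, k = 11L) {
  stopifnot(is.data.frame(transcriptome), nrow(transcriptome) > 0L, k >= 1L)
  seqs <- to_rna(transcriptome$seq)
  ids <- as.character(transcriptome$id)
  env <- new.env(hash = TRUE, parent = emptyenv())
  add_strand <- function(subj_i, s, strand) {
    n <- nchar(s)
    if (n < k) return(invisible())
    pos <- 1:(n - k + 1L)
    words <- substring(s, pos, pos + k - 1L)
    by_word <- split(pos, words)
    for (w in names(by_word)) {
      entry <- list(subject = subj_i, strand = strand, pos = by_word[[w]])
      env[[w]] <- c(env[[w]], list(entry))
    }
  }
  for (i in seq_along(seqs)) {
    add_strand(i, seqs[[i]], "sense")
    add_strand(i, rna_revcomp(seqs[[i]]), "antisense")
  }
  structure(list(k = as.integer(k), ids = ids, seqs = seqs, env = env),
            class = "offtarget_index")
}

#' @export
print.offtarget_index <- function(x, ...) {
  cat(sprintf("off-target k-mer index: %d subject(s), k = %d, %d distinct words\n",
              length(x$ids), x$k, length(ls(x$env))))
  invisible(x)
}

# distinct indexed words (exposed for inspection/tests)
index_words <- function(index) sort(ls(index$env))

# Hamming distance between two equal-length RNA strings
hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

#' Scan a core sequence for off-target matches in a transcriptome
#'
#' Finds every ungapped placement of the 19-nt core, on either strand of any
#' subject other than the intended target, with at most `max_mismatches`
#' mismatches. Matching is seeded from the k-mer index and verified by full
#' Hamming comparison. Completeness is guaranteed by the pigeonhole
#' principle: the core is cut into `max_mismatches + 1` disjoint words, at
#' least one of which must match exactly; if the index word size exceeds
#' `floor(core_len / (max_mismatches + 1))` the index is rebuilt internally
#' at that size, so no qualifying hit is ever missed. This is an offline,
#' exhaustive stand-in for a heuristic BLASTN specificity search.
#'
#' @param core A single 19-nt RNA string (the sense-orientation target core).
#' @param index An `offtarget_index` from [build_offtarget_index()].
#' @param max_mismatches Maximum Hamming distance to report (default 2, the
#'   conventional near-perfect 17/19-identity band).
#' @param exclude_id Subject id of the intended target, excluded from hits.
#' @return Tibble of hits sorted by (`mismatches`, `subject_id`,
#'   `subject_start`): columns `subject_id`, `subject_start` (0-based on the
#'   subject's given strand), `strand` (`"sense"` if the core matches the
#'   subject as given, `"antisense"` if it matches the reverse complement)
#'   and `mismatches`.
#' @export
scan_offtargets <- function(core, index, max_mismatches = 2L, exclude_id = NULL) {
  stopifnot(inherits(index, "offtarget_index"), length(core) == 1L)
  core <- to_rna(core)
  core_len <- nchar(core)
  if (core_len != 19L) stop("core must be exactly 19 nt, got ", core_len)
  mm <- as.integer(max_mismatches)
  stopifnot(mm >= 0L)
  k_needed <- core_len %/% (mm + 1L)
  if (index$k > k_needed) {
    index <- build_offtarget_index(
      tibble::tibble(id = index$ids, seq = index$seqs), k = k_needed)
  }
  k <- index$k
  n_seed <- mm + 1L
  seed_off <- (seq_len(n_seed) - 1L) * k          # 0-based offsets into core
  seeds <- substring(core, seed_off + 1L, seed_off + k)
  slen <- nchar(index$seqs)
  rseqs <- rna_revcomp(index$seqs)
  hits <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seq_len(n_seed)) {
    entries <- index$env[[seeds[[s]]]]
    if (is.null(entries)) next
    for (e in entries) {
      subj <- e$subject
      if (!is.null(exclude_id) && index$ids[[subj]] %in% exclude_id) next
      strand_seq <- if (e$strand == "sense") index$seqs[[subj]] else rseqs[[subj]]
      n <- slen[[subj]]
      for (p in e$pos) {
        w <- p - seed_off[[s]]                    # 1-based window start
        if (w < 1L || w + core_len - 1L > n) next
        key <- paste(subj, e$strand, w)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        d <- hamming(core, substr(strand_seq, w, w + core_len - 1L))
        if (d <= mm) {
          fwd_start <- if (e$strand == "sense") w - 1L else n - (w - 1L) - core_len
          hits[[length(hits) + 1L]] <- tibble::tibble(
            subject_id = index$ids[[subj]],
            subject_start = as.integer(fwd_start),
            strand = e$strand,
            mismatches = as.integer(d))
        }
      }
    }
  }
  out <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(subject_id = character(), subject_start = integer(),
                   strand = character(), mismatches = integer())
  dplyr::arrange(out, .data$mismatches, .data$subject_id, .data$subject_start)
}

#' Annotate designed candidates with off-target hit counts
#'
#' Runs [scan_offtargets()] for each candidate core against a transcriptome,
#' excluding the candidate's own transcript, and appends the hit count. A
#' candidate with any hit within `max_mismatches` elsewhere is flagged
#' non-specific.
#'
#' @param candidates Candidate tibble from [design_sirnas()].
#' @param transcriptome Transcript tibble to screen against.
#' @param max_mismatches Maximum Hamming distance counted (default 2).
#' @param k Index word size passed to [build_offtarget_index()].
#' @return `candidates` with `offtarget_hits` (integer) and `nonspecific`
#'   (logical) columns appended.
#' @export
annotate_offtargets <- function(candidates, transcriptome,
                                max_mismatches = 2L, k = 11L) {
  # index directly at the pigeonhole word size so each scan can reuse it
  k <- min(k, 19L %/% (as.integer(max_mismatches) + 1L))
  index <- build_offtarget_index(transcriptome, k = k)
  n_hits <- purrr::map2_int(candidates$core, candidates$transcript_id,
    function(core, id) nrow(scan_offtargets(core, index, max_mismatches,
                                            exclude_id = id)))
  dplyr::mutate(candidates, offtarget_hits = n_hits,
                nonspecific = n_hits > 0L)
}
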