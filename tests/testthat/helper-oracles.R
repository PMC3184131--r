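# Independent brute-force oracles, written against the documented contracts
# only (base-R string ops, no reuse of the package's code paths).

oracle_revcomp <- function(s) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_gc_pct <- function(s) {
  100 * nchar(gsub("[^GC]", "", s)) / nchar(s)
}

# Exhaustive enumerate-filter-sort re-implementation of the staged design.
# Returns survivors ordered by the rank key, with rank and selected flags.
oracle_design <- function(id, seq, cds_start, params) {
  fl <- params$flank_len; cl <- params$core_len
  n <- nchar(seq)
  hi <- n - cl - fl
  empty <- data.frame(start = integer(), rank = integer(), selected = logical())
  if (hi < fl) return(empty)
  start <- fl:hi                                    # 0-based
  core <- substring(seq, start + 1, start + cl)
  flank_up <- substring(seq, start - fl + 1, start)
  flank_down <- substring(seq, start + cl + 1, start + cl + fl)
  gc <- vapply(core, oracle_gc_pct, numeric(1), USE.NAMES = FALSE)
  first <- substring(core, 1, 1)
  last <- substring(core, cl, cl)
  seed7 <- substring(core, cl - 6, cl)
  au7 <- nchar(seed7) - nchar(gsub("[AU]", "", seed7))
  offset <- start - (cds_start + 3)
  fgc <- vapply(paste0(flank_up, flank_down), oracle_gc_pct, numeric(1),
                USE.NAMES = FALSE)
  dev <- abs(fgc - params$flank_gc_target)
  down2 <- substring(flank_down, 1, 2)
  up2 <- substring(flank_up, fl - 1, fl)
  s_pen <- integer(length(start))
  for (i in seq_along(start)) {
    s_pen[i] <- if (down2[i] == "UU") 0L else if (down2[i] == "AA") 1L
      else if (substring(down2[i], 1, 1) == "U") 2L
      else if (substring(down2[i], 2, 2) == "U") 2L else 3L
  }
  as_pen <- ifelse(up2 == "AA", 0L, 1L)
  keep <- gc >= params$gc_min & gc <= params$gc_max &
    first %in% c("G", "C") & last %in% c("A", "U") &
    au7 >= params$au_min_in_seed7 & offset >= params$min_downstream
  if (!is.null(params$flank_gc_max_dev)) {
    keep <- keep & dev <= params$flank_gc_max_dev
  }
  if (!any(keep)) return(empty)
  d <- data.frame(start = start, dev = dev, s_pen = s_pen, as_pen = as_pen)[keep, ]
  d <- d[order(d$dev, d$s_pen, d$as_pen, d$start), ]
  d$rank <- seq_len(nrow(d))
  d$selected <- FALSE
  taken <- integer(0)
  for (i in seq_len(nrow(d))) {
    if (length(taken) >= params$n_select) break
    if (params$require_nonoverlap && length(taken) &&
        any(abs(d$start[i] - taken) < cl)) next
    d$selected[i] <- TRUE
    taken <- c(taken, d$start[i])
  }
  d
}

# All-window ungapped Hamming scan of a core against a transcriptome, both
# strands, reported in forward-strand coordinates.
oracle_scan <- function(core, subjects, max_mismatches, exclude_id = NULL) {
  cl <- nchar(core)
  qc <- strsplit(core, "")[[1]]
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$id[i]
    if (!is.null(exclude_id) && id %in% exclude_id) next
    for (strand in c("sense", "antisense")) {
      s <- if (strand == "sense") subjects$seq[i] else oracle_revcomp(subjects$seq[i])
      n <- nchar(s)
      if (n < cl) next
      sc <- strsplit(s, "")[[1]]
      for (w in 1:(n - cl + 1)) {
        d <- sum(qc != sc[w:(w + cl - 1)])
        if (d <= max_mismatches) {
          fwd <- if (strand == "sense") w - 1 else n - (w - 1) - cl
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = id, subject_start = as.integer(fwd),
            strand = strand, mismatches = as.integer(d))
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(subject_id = character(), subject_start = integer(),
                      strand = character(), mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$mismatches, out$subject_id, out$subject_start), , drop = FALSE]
}

# guideline-perfect 43-nt block used to build hand-crafted transcripts
ideal_block <- function(flank_up = "GCGCGCGCGCAA",
                        core = "GCAUGGCAUAUGCAUAUUA",
                        flank_down = "UUGCAUAUAUAU") {
  paste0(flank_up, core, flank_down)
}
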