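#' Convert DNA or RNA sequences to uppercase RNA
#'
#' Normalizes character sequences to the RNA alphabet `{A, C, G, U}`:
#' lowercase letters are upcased and every `T` becomes `U`. The operation is
#' idempotent, so already-normalized RNA passes through unchanged.
#'
#' @param x Character vector of sequences over `{A,C,G,T,U}` (any case).
#' @return Character vector of the same length, uppercase RNA.
#' @examples
#' to_rna(c("ATGC", "augc", "AUGC"))
#' @export
to_rna <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("acgtu", "ACGTU", x)
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGU]", "", out[bad]), "")))
    stop("invalid sequence character(s): ", paste(ch, collapse = ", "),
         " (only A/C/G/T/U accepted; IUPAC ambiguity codes are rejected)")
  }
  out
}

#' Reverse complement of RNA sequences
#'
#' @param x Character vector of RNA sequences over `{A,C,G,U}`.
#' @return Character vector of reverse complements (A<->U, G<->C). Applying
#'   the function twice returns the input.
#' @examples
#' rna_revcomp("GCAUGGCAUAUGCAUAUUA")
#' @export
rna_revcomp <- function(x) {
  x <- to_rna(x)
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

#' GC content of sequences, in percent
#'
#' @param x Character vector of non-empty RNA sequences.
#' @return Numeric vector in `[0, 100]`: `100 * (G + C) / length`. The value
#'   is not rounded; round only when reporting.
#' @examples
#' gc_content(c("GCGC", "AUAU", "GCAU"))
#' @export
gc_content <- function(x) {
  x <- to_rna(x)
  if (any(nchar(x) == 0L)) stop("gc_content is undefined for an empty sequence")
  set <- Biostrings::RNAStringSet(x)
  gc <- Biostrings::letterFrequency(set, letters = c("G", "C"))
  unname(100 * rowSums(gc) / nchar(x))
}

#' Read transcripts from a FASTA file
#'
#' Reads mRNA/cDNA records (DNA or RNA alphabet), normalizes them to RNA, and
#' resolves the coding-sequence start (the A of the initiation codon AUG) for
#' each record. Candidate siRNA target positions are later measured relative
#' to this anchor.
#'
#' @param path Path to a FASTA file (multi-record, wrapped or unwrapped).
#' @param cds_map Optional coding-start annotation: either a named integer
#'   vector of 0-based AUG indices keyed by record id, or a path to a
#'   two-column tab-delimited file `id<TAB>1-based AUG position`. Records
#'   absent from the map fall back to their first AUG occurrence; records
#'   with no AUG at all are dropped with a warning.
#' @return A tibble with one row per transcript and columns `id` (character),
#'   `seq` (uppercase RNA) and `cds_start` (0-based integer index of the AUG),
#'   in file order.
#' @seealso [design_sirnas()] which consumes this tibble.
#' @export
read_transcripts <- function(path, cds_map = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record: ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  seqs <- tryCatch(to_rna(seqs), error = function(e) {
    # re-run per record so the error names the offender
    for (i in seq_along(seqs)) {
      tryCatch(to_rna(seqs[[i]]),
               error = function(e2) stop("record '", ids[[i]], "': ",
                                         conditionMessage(e2), call. = FALSE))
    }
  })
  map <- resolve_cds_map(cds_map)
  transcript(ids, seqs, cds_start = map[ids])
}

# cds_map argument -> named integer vector of 0-based indices (possibly empty)
resolve_cds_map <- function(cds_map) {
  if (is.null(cds_map)) return(stats::setNames(integer(0), character(0)))
  if (is.character(cds_map) && length(cds_map) == 1L && is.null(names(cds_map))) {
    tab <- utils::read.table(cds_map, sep = "\t", header = FALSE,
                             col.names = c("id", "pos"),
                             colClasses = c("character", "integer"))
    return(stats::setNames(tab$pos - 1L, tab$id))  # file is 1-based
  }
  if (is.null(names(cds_map)) || any(names(cds_map) == "")) {
    stop("cds_map must be a named vector of 0-based AUG indices or a file path")
  }
  stats::setNames(as.integer(cds_map), names(cds_map))
}

#' Construct a transcript table
#'
#' Builds the transcript tibble consumed by the design functions, validating
#' the alphabet and the initiation-codon anchor. When `cds_start` is missing
#' for a record it defaults to the first AUG occurrence; records with no AUG
#' are dropped with a warning.
#'
#' @param id Character vector of identifiers.
#' @param seq Character vector of sequences (DNA or RNA; normalized to RNA).
#' @param cds_start Optional integer vector (may contain `NA`) of 0-based AUG
#'   indices, recycled against `id`.
#' @return Tibble with columns `id`, `seq`, `cds_start` (0-based). For every
#'   row, `substr(seq, cds_start + 1, cds_start + 3) == "AUG"`.
#' @export
transcript <- function(id, seq, cds_start = NA_integer_) {
  seq <- to_rna(seq)
  stopifnot(length(id) == length(seq))
  cds_start <- rep_len(as.integer(cds_start), length(id))
  first_aug <- as.integer(regexpr("AUG", seq, fixed = TRUE)) - 1L
  cds_start <- ifelse(is.na(cds_start), first_aug, cds_start)
  no_aug <- cds_start < 0L
  if (any(no_aug)) {
    warning("dropping record(s) with no AUG and no cds_start annotation: ",
            paste(id[no_aug], collapse = ", "))
    id <- id[!no_aug]; seq <- seq[!no_aug]; cds_start <- cds_start[!no_aug]
  }
  bad <- cds_start > nchar(seq) - 3L |
    substr(seq, cds_start + 1L, cds_start + 3L) != "AUG"
  if (any(bad)) {
    stop("cds_start does not point at an AUG codon for: ",
         paste(id[bad], collapse = ", "))
  }
  tibble::tibble(id = as.character(id), seq = seq, cds_start = cds_start)
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts Tibble with columns `id` and `seq` (see [transcript()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  set <- Biostrings::RNAStringSet(stats::setNames(transcripts$seq, transcripts$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
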