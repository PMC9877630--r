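#' @importFrom methods as is
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head tail
NULL

IUPAC_DNA <- "ACGTRYSWKMBDHVN"

.empty_features <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  s <- toupper(seq)
  if (nchar(s) && grepl(sprintf("[^%s]", IUPAC_DNA), s))
    stop(what, " contains non-IUPAC DNA characters", call. = FALSE)
  s
}

#' DNA sequence record
#'
#' The universal currency of the toolkit: a named double-stranded DNA
#' molecule represented by its top strand (5'->3'), a topology flag and a
#' table of feature annotations. Coordinates are 0-based, half-open
#' internally; position arithmetic on circular records wraps modulo the
#' length.
#'
#' @param seq Top-strand sequence, IUPAC DNA letters (case-insensitive).
#' @param id Record identifier.
#' @param topology `"linear"` or `"circular"`.
#' @param features Optional `data.frame` with columns `label`, `start`,
#'   `end` (0-based, half-open) and `strand` (`"+"`/`"-"`).
#' @return An object of class `dna_record`.
#' @examples
#' r <- dna_record("acgtACGT", "toy")
#' record_length(r)
#' @export
dna_record <- function(seq, id = "record", topology = c("linear", "circular"),
                       features = NULL) {
  topology <- match.arg(topology)
  s <- .check_dna(seq)
  if (is.null(features)) features <- .empty_features()
  stopifnot(all(c("label", "start", "end", "strand") %in% names(features)))
  features <- features[, c("label", "start", "end", "strand"), drop = FALSE]
  if (nrow(features)) {
    bad <- features$start < 0L | features$end > nchar(s) |
      features$end < features$start
    if (any(bad))
      stop("feature coordinates out of range for '", id, "'", call. = FALSE)
  }
  structure(list(id = as.character(id), seq = s, topology = topology,
                 features = features),
            class = "dna_record")
}

#' @export
print.dna_record <- function(x, ...) {
  cat(sprintf("<dna_record> %s: %d bp, %s, %d feature(s)\n",
              x$id, nchar(x$seq), x$topology, nrow(x$features)))
  s <- x$seq
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  ", s, "\n", sep = "")
  invisible(x)
}

#' @rdname dna_record
#' @param x A `dna_record`.
#' @export
record_length <- function(x) nchar(x$seq)

#' @rdname dna_record
#' @export
is_circular <- function(x) identical(x$topology, "circular")

## 0-based half-open substring with wrap-around; end may exceed the length
## by at most one full turn (end - start <= L).
cyc_substr <- function(seq, start, end) {
  L <- nchar(seq)
  if (end < start) stop("cyc_substr: end < start", call. = FALSE)
  if (end - start > L) stop("cyc_substr: span longer than molecule", call. = FALSE)
  start <- start %% L
  stop_at <- start + (end - start)
  if (stop_at <= L) return(substr(seq, start + 1L, stop_at))
  paste0(substr(seq, start + 1L, L), substr(seq, 1L, stop_at - L))
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed. IUPAC ambiguity codes are handled;
#' the operation is an involution.
#'
#' @param seq A DNA string (or character vector of strings).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GATG")  # "CATC"
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    s <- .check_dna(s, "reverse_complement input")
    if (!nchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a DNA coding sequence
#'
#' Standard genetic code; the input length must be a multiple of 3 and must
#' not contain ambiguity codes.
#'
#' @param seq In-frame DNA string.
#' @return Amino-acid string (stop codon rendered as `*`).
#' @examples
#' translate_dna("GGTGGATCCGGAGGTTCT")  # "GGSGGS"
#' @export
translate_dna <- function(seq) {
  s <- .check_dna(seq)
  if (nchar(s) %% 3 != 0)
    stop("sequence length is not a multiple of 3 (frameshift)", call. = FALSE)
  if (!nchar(s)) return("")
  if (grepl("[^ACGT]", s))
    stop("cannot translate through ambiguity codes", call. = FALSE)
  as.character(Biostrings::translate(Biostrings::DNAString(s)))
}

#' Extract a (possibly wrapping) sub-sequence of a record
#'
#' @param record A [dna_record()].
#' @param start,end 0-based half-open coordinates; on circular records `end`
#'   may exceed the length to indicate a span across the origin.
#' @return Character string.
#' @export
record_subseq <- function(record, start, end) {
  if (!is_circular(record) && (start < 0 || end > record_length(record)))
    stop("coordinates out of range on a linear record", call. = FALSE)
  cyc_substr(record$seq, start, end)
}
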