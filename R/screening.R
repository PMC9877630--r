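#' Predict E. coli colony colour for a plasmid
#'
#' The pBTR vectors carry a PnptII::mScarlet-I expression cassette between
#' the two BsaI sites: colonies transformed with an intact vector are
#' reddish-pink (bright red under green excitation), while recombinants in
#' which the insert has replaced the cassette are white. Intactness is a
#' structural test: the full-length cassette sequence must occur in the
#' plasmid (either orientation, across the origin included).
#'
#' @param plasmid Circular [dna_record()].
#' @param cassette Cassette sequence: a DNA string, a [dna_record()], or a
#'   record carrying a feature whose label contains "mScarlet" (e.g. a
#'   [mock_vector()]), from which the cassette is extracted.
#' @return A `colony_prediction`: `color` (`"reddish_pink"`/`"white"`),
#'   `basis`, `fluorescence_note`.
#' @export
predict_colony <- function(plasmid, cassette) {
  if (!is(plasmid, "dna_record") || !is_circular(plasmid))
    stop("colony prediction needs a circular plasmid record", call. = FALSE)
  cas <- vector_cassette(cassette)
  dbl <- paste0(plasmid$seq, substr(plasmid$seq, 1L,
                                    min(nchar(cas) - 1L,
                                        nchar(plasmid$seq))))
  intact <- grepl(cas, dbl, fixed = TRUE) ||
    grepl(reverse_complement(cas), dbl, fixed = TRUE)
  color <- if (intact) "reddish_pink" else "white"
  structure(list(
    color = color,
    basis = if (intact)
      "intact PnptII::mScarlet-I cassette present"
    else "cassette absent or disrupted",
    fluorescence_note = if (intact)
      "bright red under green excitation" else "no red fluorescence"),
    class = "colony_prediction")
}

#' @export
print.colony_prediction <- function(x, ...) {
  cat(sprintf("<colony_prediction> %s (%s; %s)\n", x$color, x$basis,
              x$fluorescence_note))
  invisible(x)
}

#' Extract the screening-cassette sequence
#'
#' @param x A DNA string, a [dna_record()] whose whole sequence is the
#'   cassette, or an annotated record with an "mScarlet" feature.
#' @return Cassette DNA string.
#' @export
vector_cassette <- function(x) {
  if (is.character(x) && length(x) == 1) return(.check_dna(x, "cassette"))
  if (!is(x, "dna_record")) stop("cannot interpret cassette", call. = FALSE)
  hits <- grep("mScarlet", x$features$label, ignore.case = TRUE)
  if (!length(hits)) return(x$seq)
  f <- x$features[hits[1L], ]
  cyc_substr(x$seq, f$start, f$end)
}

#' Restriction-digest screening of a plasmid
#'
#' Compares the predicted restriction map of a plasmid against an expected
#' band list within a per-band length tolerance (gel resolution). Each
#' expected band is matched greedily to the nearest unmatched observed
#' fragment.
#'
#' @param plasmid A [dna_record()].
#' @param enzymes Enzyme(s), as in [digest()].
#' @param expected Numeric vector of expected band lengths (bp).
#' @param tolerance Allowed deviation per band in nt.
#' @return A `screen_report`: `pass`, per-band table `bands`, and any
#'   unexplained observed fragments.
#' @export
screen_by_digest <- function(plasmid, enzymes, expected, tolerance = 0) {
  if (!length(expected))
    stop("expected band list is empty", call. = FALSE)
  if (any(expected <= 0)) stop("expected lengths must be positive",
                               call. = FALSE)
  observed <- as.integer(restriction_map(plasmid, enzymes))
  free <- rep(TRUE, length(observed))
  rows <- lapply(sort(expected, decreasing = TRUE), function(e) {
    d <- abs(observed - e)
    d[!free] <- Inf
    i <- which.min(d)
    if (length(observed) && is.finite(d[i]) && d[i] <= tolerance) {
      free[i] <<- FALSE
      data.frame(expected = e, observed = observed[i],
                 delta = observed[i] - e, match = TRUE)
    } else {
      data.frame(expected = e, observed = NA_integer_,
                 delta = NA_integer_, match = FALSE)
    }
  })
  bands <- do.call(rbind, rows)
  structure(list(pass = all(bands$match), bands = bands,
                 unmatched_observed = observed[free]),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %s\n", if (x$pass) "PASS" else "FAIL"))
  print(x$bands, row.names = FALSE)
  if (length(x$unmatched_observed))
    cat("unmatched observed fragment(s):",
        paste(x$unmatched_observed, collapse = ", "), "\n")
  invisible(x)
}
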