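#' Restriction enzyme specification
#'
#' Describes a type-IIS or classical restriction endonuclease by its
#' top-strand recognition sequence and two cut offsets. For type-IIS
#' enzymes (`cut_inside = FALSE`) the offsets count nucleotides 3' of the
#' recognition sequence on each strand, so BsaI is
#' `GGTCTC`, top 1, bottom 5 -- the GGTCTC(N1)/(N5) notation -- and leaves
#' 5' overhangs of length `bottom - top = 4`. For classical enzymes
#' (`cut_inside = TRUE`) the offsets are measured from the 5' start of the
#' recognition sequence (HindIII `A^AGCTT` is top 1, bottom 5).
#'
#' @param name Enzyme name.
#' @param recognition Top-strand recognition sequence (concrete bases).
#' @param top_cut_offset,bottom_cut_offset Integer cut offsets (see above).
#' @param cut_inside Logical; classical-enzyme offset convention.
#' @return An object of class `enzyme_spec`.
#' @examples
#' bsai()
#' @export
enzyme_spec <- function(name, recognition, top_cut_offset, bottom_cut_offset,
                        cut_inside = FALSE) {
  recognition <- .check_dna(recognition, "recognition sequence")
  if (grepl("[^ACGT]", recognition))
    stop("recognition sequence must be concrete ACGT", call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 top_cut_offset = as.integer(top_cut_offset),
                 bottom_cut_offset = as.integer(bottom_cut_offset),
                 cut_inside = isTRUE(cut_inside)),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s %s(%d/%d)%s, overhang %d nt\n", x$name,
              x$recognition, x$top_cut_offset, x$bottom_cut_offset,
              if (x$cut_inside) " [cuts within site]" else "",
              overhang_length(x)))
  invisible(x)
}

#' @rdname enzyme_spec
#' @param enzyme An `enzyme_spec`.
#' @export
overhang_length <- function(enzyme) {
  abs(enzyme$bottom_cut_offset - enzyme$top_cut_offset)
}

.enzyme_cache <- new.env(parent = emptyenv())

#' Built-in enzyme table
#'
#' The enzymes needed to replay pBTR vector construction and colony
#' screening (BsaI plus the classical enzymes used in the cloning steps),
#' shipped as a plain-text table under `extdata`. User tables with the same
#' columns can be loaded through `file`.
#'
#' @param file Optional path to a user enzyme table (TSV with columns
#'   `name`, `recognition`, `top_cut_offset`, `bottom_cut_offset`,
#'   `cut_inside`).
#' @return A `data.frame` of enzyme definitions.
#' @export
enzyme_table <- function(file = NULL) {
  if (is.null(file)) {
    if (is.null(.enzyme_cache$table)) {
      path <- system.file("extdata", "enzymes.tsv", package = "pbtrkit")
      .enzyme_cache$table <- read.delim(path, stringsAsFactors = FALSE)
    }
    return(.enzyme_cache$table)
  }
  read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname enzyme_table
#' @param name Enzyme name present in the table.
#' @export
get_enzyme <- function(name, file = NULL) {
  tab <- enzyme_table(file)
  i <- match(name, tab$name)
  if (is.na(i))
    stop("unknown enzyme '", name, "'; available: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  enzyme_spec(tab$name[i], tab$recognition[i], tab$top_cut_offset[i],
              tab$bottom_cut_offset[i], as.logical(tab$cut_inside[i]))
}

#' @rdname enzyme_table
#' @export
bsai <- function() get_enzyme("BsaI")

.as_enzyme <- function(x) {
  if (is(x, "enzyme_spec")) return(x)
  if (is.character(x) && length(x) == 1) return(get_enzyme(x))
  stop("expected an enzyme_spec or an enzyme name", call. = FALSE)
}

## Overlapping match start positions (0-based) of a fixed pattern.
.find_starts <- function(seq, pattern) {
  if (nchar(seq) < nchar(pattern)) return(integer())
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer())
  as.integer(m) - 1L
}

#' Find recognition sites on both strands
#'
#' Scans the top strand for the recognition sequence (+ sites) and for its
#' reverse complement (- sites). Circular records are scanned across the
#' origin. Palindromic recognition sequences are reported once per
#' position, on the + strand.
#'
#' @param record A [dna_record()].
#' @param enzyme An [enzyme_spec()] or enzyme name.
#' @return `data.frame` with columns `position` (0-based start of the
#'   top-strand match) and `strand`, sorted by position.
#' @examples
#' find_sites(dna_record("AAAAGGTCTCAGATGCTTTT"), bsai())
#' @export
find_sites <- function(record, enzyme) {
  enzyme <- .as_enzyme(enzyme)
  rec <- enzyme$recognition
  rlen <- nchar(rec)
  s <- record$seq
  L <- nchar(s)
  scan <- if (is_circular(record) && L >= rlen)
    paste0(s, substr(s, 1L, rlen - 1L)) else s
  plus <- .find_starts(scan, rec)
  rc <- reverse_complement(rec)
  minus <- if (identical(rc, rec)) integer() else .find_starts(scan, rc)
  out <- data.frame(position = c(plus, minus),
                    strand = rep(c("+", "-"), c(length(plus), length(minus))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Cut coordinates for every usable site: data.frame(t, b) of top/bottom
## strand cut indices (0-based, a cut at index i falls between bases i-1
## and i). Sites whose cut window leaves a linear molecule are skipped
## (physically uncuttable); on circular molecules coordinates wrap.
.cut_table <- function(record, enzyme) {
  enzyme <- .as_enzyme(enzyme)
  sites <- find_sites(record, enzyme)
  if (!nrow(sites))
    return(data.frame(t = integer(), b = integer(), enzyme = character(),
                      stringsAsFactors = FALSE))
  rlen <- nchar(enzyme$recognition)
  L <- record_length(record)
  circ <- is_circular(record)
  if (enzyme$cut_inside) {
    off_t <- enzyme$top_cut_offset; off_b <- enzyme$bottom_cut_offset
    t <- ifelse(sites$strand == "+", sites$position + off_t,
                sites$position + rlen - off_b)
    b <- ifelse(sites$strand == "+", sites$position + off_b,
                sites$position + rlen - off_t)
  } else {
    off_t <- rlen + enzyme$top_cut_offset
    off_b <- rlen + enzyme$bottom_cut_offset
    t <- ifelse(sites$strand == "+", sites$position + off_t,
                sites$position - enzyme$bottom_cut_offset)
    b <- ifelse(sites$strand == "+", sites$position + off_b,
                sites$position - enzyme$top_cut_offset)
  }
  keep <- rep(TRUE, length(t))
  if (!circ) {
    keep <- pmin(t, b) >= 0 & pmax(t, b) <= L
  } else if (length(t)) {
    d <- b - t
    t <- t %% L
    b <- t + d
  }
  out <- data.frame(t = as.integer(t[keep]), b = as.integer(b[keep]),
                    enzyme = enzyme$name, stringsAsFactors = FALSE)
  unique(out)
}

.cut_windows_ok <- function(record, cuts) {
  if (!nrow(cuts)) return(invisible(TRUE))
  L <- record_length(record)
  lo <- pmin(cuts$t, cuts$b); hi <- pmax(cuts$t, cuts$b)
  for (i in seq_len(nrow(cuts))) {
    if (hi[i] > lo[i]) {
      w <- cyc_substr(record$seq, lo[i] %% L, lo[i] %% L + (hi[i] - lo[i]))
      if (grepl("[^ACGT]", w))
        stop("cut through ambiguity code at position ", lo[i], " in '",
             record$id, "'", call. = FALSE)
    }
  }
  if (nrow(cuts) > 1) {
    ## pairwise overlap of cut windows is physically undefined
    for (i in seq_len(nrow(cuts) - 1)) for (j in (i + 1):nrow(cuts)) {
      if (lo[i] < hi[j] && lo[j] < hi[i] && hi[i] > lo[i] && hi[j] > lo[j])
        stop("overlapping cut windows at positions ", lo[i], " and ", lo[j],
             " in '", record$id, "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

.blunt <- function() list(seq = "", type = "blunt")
.ovh <- function(seq, type) {
  if (!nchar(seq)) .blunt() else list(seq = seq, type = type)
}

#' Sticky-ended DNA fragment
#'
#' A double-stranded fragment with explicit overhangs at each end, the unit
#' of digestion and ligation. `top` is the fragment's top strand between
#' its two top-strand cut points (so fragment lengths sum to the parent
#' molecule's length); overhang sequences are read 5'->3' on the
#' protruding strand, with `type` `"5"`, `"3"` or `"blunt"`.
#'
#' @param top,bottom Top and bottom strand sequences (each 5'->3').
#' @param l_ovh,r_ovh Overhang descriptors `list(seq=, type=)`.
#' @param prov Provenance: list of entries `list(src=, start=, len=,
#'   strand=, src_len=, circular=)` mapping the top strand back to source
#'   coordinates.
#' @param features Feature table in fragment-local coordinates.
#' @return An object of class `sticky_fragment`.
#' @export
sticky_fragment <- function(top, bottom, l_ovh, r_ovh, prov = list(),
                            features = NULL) {
  if (is.null(features)) features <- .empty_features()
  structure(list(top = top, bottom = bottom, l_ovh = l_ovh, r_ovh = r_ovh,
                 prov = prov, features = features),
            class = "sticky_fragment")
}

#' @export
print.sticky_fragment <- function(x, ...) {
  fmt <- function(o) if (o$type == "blunt") "blunt" else
    sprintf("%s' %s", o$type, o$seq)
  cat(sprintf("<sticky_fragment> %d nt top strand | left: %s | right: %s\n",
              nchar(x$top), fmt(x$l_ovh), fmt(x$r_ovh)))
  invisible(x)
}

#' @rdname sticky_fragment
#' @param fragment A `sticky_fragment`.
#' @export
fragment_length <- function(fragment) nchar(fragment$top)

#' @rdname sticky_fragment
#' @export
flip_fragment <- function(fragment) {
  prov <- rev(lapply(fragment$prov, function(p) {
    p$strand <- if (p$strand == "+") "-" else "+"
    p
  }))
  feats <- fragment$features
  if (nrow(feats)) {
    L <- nchar(fragment$bottom)
    new_start <- L - feats$end
    feats$end <- L - feats$start
    feats$start <- new_start
    feats$strand <- ifelse(feats$strand == "+", "-", "+")
  }
  sticky_fragment(fragment$bottom, fragment$top, fragment$r_ovh,
                  fragment$l_ovh, prov, feats)
}

.frag_between <- function(record, cut1, cut2) {
  L <- record_length(record)
  s <- record$seq
  t1 <- cut1$t; b1 <- cut1$b; t2 <- cut2$t; b2 <- cut2$b
  top <- cyc_substr(s, t1, t2)
  bottom <- reverse_complement(cyc_substr(s, b1 %% L, b1 %% L + (b2 - b1)))
  l_ovh <- if (b1 > t1) .ovh(cyc_substr(s, t1 %% L, t1 %% L + (b1 - t1)), "5")
           else if (b1 < t1) .ovh(reverse_complement(
             cyc_substr(s, b1 %% L, b1 %% L + (t1 - b1))), "3")
           else .blunt()
  r_ovh <- if (b2 > t2) .ovh(reverse_complement(
             cyc_substr(s, t2 %% L, t2 %% L + (b2 - t2))), "5")
           else if (b2 < t2) .ovh(cyc_substr(s, b2 %% L, b2 %% L + (t2 - b2)),
                                  "3")
           else .blunt()
  prov <- list(list(src = record$id, start = t1 %% L, len = nchar(top),
                    strand = "+", src_len = L,
                    circular = is_circular(record)))
  feats <- .transfer_features(record, t1, t2)
  sticky_fragment(top, bottom, l_ovh, r_ovh, prov, feats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Features of `record` fully contained in [from, to) (cyclic allowed),
## remapped to fragment-local coordinates. Split features are dropped with
## a warning.
.transfer_features <- function(record, from, to) {
  feats <- record$features
  out <- .empty_features()
  if (!nrow(feats)) return(out)
  L <- record_length(record)
  span <- to - from
  for (k in seq_len(nrow(feats))) {
    fs <- (feats$start[k] - from) %% L
    fe <- fs + (feats$end[k] - feats$start[k])
    if (fe <= span) {
      row <- feats[k, ]; row$start <- fs; row$end <- fe
      out <- rbind(out, row)
    } else if (fs < span) {
      warning("feature '", feats$label[k], "' split by digestion; dropped",
              call. = FALSE)
    }  # else: feature lies entirely outside this fragment
  }
  rownames(out) <- NULL
  out
}

#' Digest a record into sticky fragments
#'
#' Cuts the molecule at every usable recognition site of the given
#' enzyme(s). A circular record with k cut positions yields k fragments, a
#' linear record k+1 (uncut linear molecules come back as one blunt-ended
#' fragment). An uncut circular record is returned unchanged as a single
#' fragment flagged `uncut`. Cutting through an ambiguity code, or two
#' sites with overlapping cut windows, is an error.
#'
#' @param record A [dna_record()].
#' @param enzymes An [enzyme_spec()], enzyme name, or list of either.
#' @return List of [sticky_fragment()]s, in molecule order.
#' @examples
#' digest(dna_record("AAAAGGTCTCAGATGCTTTT"), bsai())
#' @export
digest <- function(record, enzymes) {
  if (is(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  if (is.character(enzymes)) enzymes <- as.list(enzymes)
  cuts <- do.call(rbind, lapply(enzymes, function(e) .cut_table(record, e)))
  cuts <- unique(cuts[, c("t", "b")])
  L <- record_length(record)
  if (is_circular(record)) {
    if (!nrow(cuts)) {
      frag <- sticky_fragment(record$seq, reverse_complement(record$seq),
                              .blunt(), .blunt(),
                              list(list(src = record$id, start = 0L, len = L,
                                        strand = "+", src_len = L,
                                        circular = TRUE)),
                              record$features)
      attr(frag, "uncut") <- TRUE
      attr(frag, "circular") <- TRUE
      return(structure(list(frag), uncut = TRUE))
    }
    cuts <- cuts[order(cuts$t %% L), , drop = FALSE]
    .cut_windows_ok(record, cuts)
    k <- nrow(cuts)
    frags <- vector("list", k)
    for (i in seq_len(k)) {
      c1 <- as.list(cuts[i, ])
      c2 <- as.list(cuts[if (i == k) 1L else i + 1L, ])
      if (i == k || c2$t <= c1$t) { c2$t <- c2$t + L; c2$b <- c2$b + L }
      frags[[i]] <- .frag_between(record, c1, c2)
    }
    frags
  } else {
    cuts <- cuts[order(cuts$t), , drop = FALSE]
    .cut_windows_ok(record, cuts)
    bounds <- rbind(data.frame(t = 0L, b = 0L), cuts[, c("t", "b")],
                    data.frame(t = L, b = L))
    lapply(seq_len(nrow(bounds) - 1L), function(i)
      .frag_between(record, as.list(bounds[i, ]), as.list(bounds[i + 1L, ])))
  }
}

#' Restriction map: fragment lengths of a digestion
#'
#' @param record A [dna_record()].
#' @param enzymes Enzyme(s) as in [digest()].
#' @return Sorted integer vector of fragment lengths (summing to the record
#'   length); an uncut circular record returns its length with attribute
#'   `uncut = TRUE`.
#' @export
restriction_map <- function(record, enzymes) {
  frags <- digest(record, enzymes)
  lens <- sort(vapply(frags, fragment_length, integer(1)))
  if (isTRUE(attr(frags, "uncut"))) attr(lens, "uncut") <- TRUE
  lens
}

#' Overhang combinatorics and expected site spacing
#'
#' `overhang_space()` enumerates all distinct sticky ends of a given length
#' (4^4 = 256 for the 4-nt 5' overhangs left by BsaI).
#' `expected_site_spacing()` is the analytic mean spacing of a fixed
#' recognition sequence under uniform base composition (4^6 = 4096 bp for a
#' six-cutter, counting one strand); `sample_site_spacing()` estimates the
#' same quantity from a seeded random-sequence scan.
#'
#' @param width Overhang length in nt.
#' @return For `overhang_space()`, a character vector of all overhangs.
#' @export
overhang_space <- function(width = 4) {
  b <- c("A", "C", "G", "T")
  g <- do.call(expand.grid, c(rep(list(b), width), stringsAsFactors = FALSE))
  sort(do.call(paste0, g))
}

#' @rdname overhang_space
#' @param recognition_length Recognition-sequence length in bp.
#' @export
expected_site_spacing <- function(recognition_length = 6) {
  4^recognition_length
}

#' @rdname overhang_space
#' @param genome_length Length of the random sequence to scan.
#' @param recognition Recognition sequence to count (one strand).
#' @param seed RNG seed.
#' @export
sample_site_spacing <- function(genome_length = 1e7, recognition = "GGTCTC",
                                seed = 1) {
  s <- with_seed(seed, paste(sample(c("A", "C", "G", "T"),
                                    genome_length, replace = TRUE),
                             collapse = ""))
  n <- length(.find_starts(s, recognition))
  if (!n) stop("no sites found; sequence too short", call. = FALSE)
  genome_length / n
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards; used so that every fixture generator is reproducible without
#' disturbing the session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
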