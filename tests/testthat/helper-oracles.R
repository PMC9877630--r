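# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths: the reverse
# complement is a chartr table, circle identity is a naive minimum over
# rotations, and the ligation oracle is a full cross-product enumeration.

oracle_rc <- function(s) {
  if (!nchar(s)) return("")
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
                     "")[[1]]), collapse = "")
}

oracle_canonical_circle <- function(s) {
  L <- nchar(s)
  rots <- function(x) {
    d <- paste0(x, x)
    vapply(0:(L - 1L), function(i) substr(d, i + 1L, i + L), character(1))
  }
  min(c(rots(s), rots(oracle_rc(s))))
}

# Full enumeration of circular ligation products over species with
# unlimited copies: every tuple of (species, orientation) up to max_len is
# generated with expand.grid and filtered on junction compatibility and
# closure. Returns the sorted set of canonical product sequences.
oracle_circles <- function(fragments, max_len, allow_blunt = FALSE) {
  ends <- list()
  for (i in seq_along(fragments)) {
    f <- fragments[[i]]
    ends[[2 * i - 1]] <- list(top = f$top, l = f$l_ovh, r = f$r_ovh)
    ff <- flip_fragment(f)
    ends[[2 * i]] <- list(top = ff$top, l = ff$l_ovh, r = ff$r_ovh)
  }
  ok_join <- function(r, l) {
    if (r$type != l$type) return(FALSE)
    if (r$type == "blunt") return(allow_blunt)
    identical(l$seq, oracle_rc(r$seq))
  }
  out <- character()
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(seq_along(ends)), len))
    for (row in seq_len(nrow(grid))) {
      idx <- as.integer(grid[row, ])
      good <- TRUE
      for (k in seq_len(len)) {
        a <- ends[[idx[k]]]
        b <- ends[[idx[if (k == len) 1L else k + 1L]]]
        if (!ok_join(a$r, b$l)) { good <- FALSE; break }
      }
      if (good) {
        seq <- paste(vapply(idx, function(i) ends[[i]]$top, character(1)),
                     collapse = "")
        out <- c(out, oracle_canonical_circle(seq))
      }
    }
  }
  sort(unique(out))
}

product_canonicals <- function(products) {
  sort(unique(vapply(products, function(p)
    oracle_canonical_circle(p$record$seq), character(1))))
}

# a bare sticky fragment with 5' overhangs, for ligation unit tests
make_frag <- function(l, core, r, src = "frag") {
  l_ovh <- if (nchar(l)) list(seq = l, type = "5") else list(seq = "", type = "blunt")
  r_ovh <- if (nchar(r)) list(seq = r, type = "5") else list(seq = "", type = "blunt")
  # top strand = left overhang + duplex; the right overhang (on the bottom
  # strand) contributes rc(r) to the NEXT fragment's top, so the duplex of
  # this fragment ends where the cut fell: emulate digestion output by
  # putting rc(r) at the very end of the top strand of the next piece.
  top <- paste0(l, core)
  bottom <- paste0(r, oracle_rc(core))
  sticky_fragment(top, bottom, l_ovh, r_ovh,
                  prov = list(list(src = src, start = 0L, len = nchar(top),
                                   strand = "+", src_len = nchar(top),
                                   circular = FALSE)))
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")
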