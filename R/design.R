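#' The pBTR destination-vector registry
#'
#' Every pBTR vector, with its Golden Gate adapter pair (the constant
#' primer 5' tails, written with their `N` placeholders), set membership
#' (BTR1/BTR2), application category, plant selection marker and the two
#' backbone overhangs exposed after BsaI digestion. The adapter columns
#' follow the pattern `NNNNGGTCTCN` + 4-nt fusion sequence: four protective
#' bases, the BsaI recognition sequence, a one-base spacer, then the 4-mer
#' that becomes the insert-side sticky end. The reverse complement of each
#' adapter's 3'-terminal 4-mer is the matching vector overhang.
#'
#' @return data.frame with one row per vector.
#' @export
pbtr_registry <- function() {
  if (is.null(.enzyme_cache$registry)) {
    path <- system.file("extdata", "pbtr_registry.tsv", package = "pbtrkit")
    .enzyme_cache$registry <- read.delim(path, stringsAsFactors = FALSE)
  }
  .enzyme_cache$registry
}

#' @rdname pbtr_registry
#' @export
list_vectors <- function() pbtr_registry()

#' Look up a destination vector
#'
#' @param name Vector name as in the registry (e.g. `"pK35BTR1"`).
#' @return A `vector_spec`: name, set, category, plant marker, adapter
#'   pair, and the two backbone overhangs (`upstream` receives the
#'   insert's 5' end).
#' @examples
#' get_vector("pK35BTR1")$overhangs
#' @export
get_vector <- function(name) {
  reg <- pbtr_registry()
  i <- match(name, reg$name)
  if (is.na(i))
    stop("unknown vector '", name, "'; valid names: ",
         paste(reg$name, collapse = ", "), call. = FALSE)
  row <- reg[i, ]
  structure(list(name = row$name, set = row$set, category = row$category,
                 plant_marker = row$plant_marker,
                 fwd_adapter = row$fwd_adapter,
                 rev_adapter = row$rev_adapter,
                 overhangs = c(upstream = row$ovh_upstream,
                               downstream = row$ovh_downstream)),
            class = "vector_spec")
}

#' @export
print.vector_spec <- function(x, ...) {
  cat(sprintf(
    "<vector_spec> %s (set %s, %s, marker %s)\n  adapters %s / %s\n  backbone overhangs %s / %s\n",
    x$name, x$set, x$category, x$plant_marker, x$fwd_adapter, x$rev_adapter,
    x$overhangs[["upstream"]], x$overhangs[["downstream"]]))
  invisible(x)
}

.as_vector_spec <- function(x) {
  if (is(x, "vector_spec")) return(x)
  if (is.character(x) && length(x) == 1) return(get_vector(x))
  stop("expected a vector_spec or registry vector name", call. = FALSE)
}

.adapter_tail4 <- function(adapter) substr(adapter, nchar(adapter) - 3L,
                                           nchar(adapter))

.concretize_adapter <- function(adapter, protective = "CAGT", spacer = "A") {
  stopifnot(nchar(protective) == 4, nchar(spacer) == 1)
  stopifnot(grepl("^NNNNGGTCTCN", adapter))
  paste0(protective, "GGTCTC", spacer, substr(adapter, 12L, nchar(adapter)))
}

.stop_codons <- c("TAA", "TAG", "TGA")

#' Wallace-rule melting temperature
#'
#' The classical 2(A+T) + 4(G+C) estimate used to size the gene-specific
#' primer region; no nearest-neighbour thermodynamics.
#'
#' @param seq Primer sequence.
#' @return Tm estimate in degrees C.
#' @export
wallace_tm <- function(seq) {
  s <- .check_dna(seq)
  n_gc <- nchar(gsub("[^GC]", "", s))
  n_at <- nchar(gsub("[^AT]", "", s))
  2 * n_at + 4 * n_gc
}

#' Design an adapter-tailed primer pair for a pBTR vector
#'
#' Builds the two PCR primers that give an insert the sticky ends matching
#' a destination vector: 4 protective bases + `GGTCTC` + 1-nt spacer +
#' the vector's 4-nt fusion sequence (adapter taken verbatim from the
#' registry), followed by a gene-specific region of 18-28 nt -- the
#' shortest length whose Wallace-rule Tm reaches `tm_target`, else 28.
#' For subcellular-localisation (GFP fusion) vectors the insert must end
#' in a stop codon, which is removed so the open reading frame runs into
#' the eGFP linker.
#'
#' @param fdi Insert as a [dna_record()] (or DNA string), >= 36 nt.
#' @param vector Vector name or `vector_spec`.
#' @param protective Protective 5' bases (default `"CAGT"`).
#' @param spacer The single spacer base in `GGTCTCN` (default `"A"`).
#' @param tm_target Target gene-specific Tm in degrees C.
#' @return A `primer_pair` with elements `forward`, `reverse`,
#'   `tm_forward`, `tm_reverse`, the concrete adapters, and
#'   `stop_removed`.
#' @export
design_primers <- function(fdi, vector, protective = "CAGT", spacer = "A",
                           tm_target = 55) {
  if (is.character(fdi)) fdi <- dna_record(fdi, "fdi")
  vec <- .as_vector_spec(vector)
  s <- fdi$seq
  if (nchar(s) < 36)
    stop("FDI '", fdi$id, "' is shorter than the 36 nt minimum",
         call. = FALSE)
  stop_removed <- FALSE
  if (vec$category == "subcellular_GFP") {
    last <- substr(s, nchar(s) - 2L, nchar(s))
    if (!last %in% .stop_codons)
      stop("GFP-fusion design requires the FDI to end in a stop codon ('",
           fdi$id, "' ends in ", last, ")", call. = FALSE)
    s <- substr(s, 1L, nchar(s) - 3L)
    stop_removed <- TRUE
  }
  gs <- function(region) {
    for (len in 18:28) {
      cand <- substr(region, 1L, len)
      if (wallace_tm(cand) >= tm_target) return(cand)
    }
    substr(region, 1L, 28L)
  }
  gs_f <- gs(s)
  gs_r <- gs(reverse_complement(s))
  ad_f <- .concretize_adapter(vec$fwd_adapter, protective, spacer)
  ad_r <- .concretize_adapter(vec$rev_adapter, protective, spacer)
  structure(list(forward = paste0(ad_f, gs_f),
                 reverse = paste0(ad_r, gs_r),
                 fwd_adapter = ad_f, rev_adapter = ad_r,
                 gene_specific = c(forward = gs_f, reverse = gs_r),
                 tm_forward = wallace_tm(gs_f),
                 tm_reverse = wallace_tm(gs_r),
                 vector = vec$name, template = fdi$id,
                 stop_removed = stop_removed),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> for %s on %s%s\n  F: 5'-%s-3' (gene-specific Tm %g C)\n  R: 5'-%s-3' (gene-specific Tm %g C)\n",
              x$template, x$vector,
              if (x$stop_removed) " [stop codon removed]" else "",
              x$forward, x$tm_forward, x$reverse, x$tm_reverse))
  invisible(x)
}

#' Simulate PCR with an adapter-tailed primer pair
#'
#' Checks that the gene-specific regions anneal to the template termini
#' and returns the linear amplicon: forward adapter + template (stop codon
#' stripped for GFP designs) + reverse complement of the reverse adapter.
#'
#' @param template The FDI [dna_record()] the pair was designed on.
#' @param pair A `primer_pair` from [design_primers()].
#' @return Linear amplicon [dna_record()].
#' @export
simulate_pcr <- function(template, pair) {
  if (!is(pair, "primer_pair")) stop("expected a primer_pair", call. = FALSE)
  s <- template$seq
  if (pair$stop_removed) s <- substr(s, 1L, nchar(s) - 3L)
  if (!startsWith(s, pair$gene_specific[["forward"]]))
    stop("forward primer does not anneal to '", template$id, "'",
         call. = FALSE)
  if (!endsWith(s, reverse_complement(pair$gene_specific[["reverse"]])))
    stop("reverse primer does not anneal to '", template$id, "'",
         call. = FALSE)
  dna_record(paste0(pair$fwd_adapter, s,
                    reverse_complement(pair$rev_adapter)),
             paste0(template$id, "_amplicon"), "linear")
}

.set_overhang_pairs <- list(BTR1 = c("CATC", "GGAT"),
                            BTR2 = c("TCTA", "GAGC"))

.is_palindrome <- function(x) identical(x, reverse_complement(x))

#' Choose a pBTR vector set for an insert
#'
#' Computes every internal BsaI junction overhang of the insert. A set is
#' admissible iff no internal overhang equals (or reverse-complements)
#' either of the set's backbone overhangs -- otherwise the internal sticky
#' end could ligate onto a vector/adapter end and mis-joined products
#' (chimeras) become possible, in which case the other set is used.
#' Palindromic internal overhangs are flagged: they self-anneal whatever
#' the set, and call for a raised insert:vector molar ratio rather than a
#' set switch.
#'
#' @param fdi Insert [dna_record()] (the raw fragment, not the amplicon).
#' @param sets Candidate sets, tried in order.
#' @param pairs Named list of set overhang pairs (defaults to the
#'   overexpression-vector pairs CATC/GGAT and TCTA/GAGC).
#' @return List: `chosen` (set name or `NA`), `admissible`, per-set
#'   diagnostics, `internal_overhangs`, `palindromic`.
#' @export
select_vector_set <- function(fdi, sets = c("BTR1", "BTR2"), pairs = NULL) {
  if (is.null(pairs)) pairs <- .set_overhang_pairs
  cuts <- .cut_table(fdi, bsai())
  windows <- vapply(seq_len(nrow(cuts)), function(i)
    cyc_substr(fdi$seq, min(cuts$t[i], cuts$b[i]),
               max(cuts$t[i], cuts$b[i])), character(1))
  palin <- windows[vapply(windows, .is_palindrome, logical(1))]
  adm <- vapply(sets, function(st) {
    pr <- pairs[[st]]
    !any(windows %in% c(pr, reverse_complement(pr)))
  }, logical(1))
  chosen <- if (any(adm)) sets[which(adm)[1L]] else NA_character_
  diagnostics <- data.frame(set = sets, admissible = adm,
                            overhangs = vapply(sets, function(st)
                              paste(pairs[[st]], collapse = "/"),
                              character(1)),
                            stringsAsFactors = FALSE)
  notes <- character()
  if (length(palin))
    notes <- c(notes, paste0(
      "palindromic internal overhang(s) ", paste(unique(palin), collapse = "/"),
      ": self-ligation possible in any set; raise the insert:vector molar ",
      "ratio to 3-5:1"))
  if (is.na(chosen))
    notes <- c(notes, "both sets collide with internal overhangs")
  list(chosen = chosen, diagnostics = diagnostics,
       internal_overhangs = unname(windows), palindromic = unique(palin),
       notes = notes)
}

#' Plan a one-pot reaction for one or more inserts
#'
#' Designs primers, simulates the PCRs, and assembles a ready-to-run
#' [reaction_spec()]. The molar ratio defaults to 1:1 insert:vector and is
#' raised to 3:1 (recommended range 3-5:1) when any insert's internal BsaI
#' site yields a palindromic sticky end. The terminal hold is 4 C/60 min
#' iff any insert carries an internal site, else 37 C/10 min.
#'
#' @param fdis One [dna_record()] or a list of them (raw inserts).
#' @param vector_record The destination vector molecule (circular record,
#'   e.g. from [mock_vector()]).
#' @param vector Vector name or `vector_spec` used for the adapter design;
#'   defaults to the name of `vector_record`.
#' @param ... Passed to [design_primers()].
#' @return A [reaction_spec()]; attribute `plan` carries the primer pairs
#'   and the ratio recommendation.
#' @export
plan_reaction <- function(fdis, vector_record, vector = NULL, ...) {
  if (is(fdis, "dna_record")) fdis <- list(fdis)
  vec <- .as_vector_spec(vector %||% sub("_mock$", "", vector_record$id))
  pairs <- lapply(fdis, design_primers, vector = vec, ...)
  amps <- mapply(simulate_pcr, fdis, pairs, SIMPLIFY = FALSE)
  n_internal <- vapply(fdis, function(f) nrow(find_sites(f, bsai())),
                       integer(1))
  palin <- unlist(lapply(fdis, function(f)
    select_vector_set(f)$palindromic))
  ratio <- if (length(palin)) 3 else 1
  prog <- pbtr_program(internal_sites = any(n_internal > 0))
  rx <- reaction_spec(vector_record, amps,
                      ratios = rep(ratio, length(amps)), program = prog)
  attr(rx, "plan") <- list(primer_pairs = pairs,
                           ratio = ratio,
                           ratio_range = if (length(palin)) "3-5:1" else "1:1",
                           internal_sites = n_internal,
                           palindromic = unique(palin))
  rx
}

#' The GGSGGS fusion linker
#'
#' Constant DNA linker placed between an insert and eGFP in the
#' subcellular-localisation vectors; its translation is the GGSGGS
#' peptide.
#'
#' @return List with `dna` and `peptide`.
#' @export
pbtr_linker <- function() {
  list(dna = "GGTGGATCCGGAGGTTCT", peptide = "GGSGGS")
}

#' Predict the C-terminal eGFP fusion open reading frame
#'
#' Concatenates the stop-stripped insert, the GGSGGS linker and the eGFP
#' coding sequence, verifies the reading frame (single terminal stop, no
#' internal stops, GGSGGS at the junction) and returns the fusion ORF as
#' an annotated record.
#'
#' @param fdi_no_stop In-frame insert with its stop codon already removed
#'   ([dna_record()] or string).
#' @param vector A `subcellular_GFP` vector (name or spec).
#' @param egfp eGFP coding sequence; defaults to the packaged synthetic
#'   stand-in [synthetic_egfp()].
#' @return [dna_record()] of the fusion ORF; attribute `protein` carries
#'   the translation.
#' @export
build_fusion <- function(fdi_no_stop, vector, egfp = NULL) {
  if (is.character(fdi_no_stop)) fdi_no_stop <- dna_record(fdi_no_stop, "fdi")
  vec <- .as_vector_spec(vector)
  if (vec$category != "subcellular_GFP")
    stop("'", vec$name, "' is not a subcellular-localisation (GFP) vector",
         call. = FALSE)
  s <- fdi_no_stop$seq
  if (nchar(s) %% 3 != 0)
    stop("frameshift: insert length ", nchar(s),
         " is not a multiple of 3", call. = FALSE)
  last <- substr(s, nchar(s) - 2L, nchar(s))
  if (last %in% .stop_codons)
    stop("insert still ends in a stop codon (", last,
         "); remove it before fusion", call. = FALSE)
  if (is.null(egfp)) egfp <- synthetic_egfp()
  if (is(egfp, "dna_record")) egfp <- egfp$seq
  lk <- pbtr_linker()
  orf <- paste0(s, lk$dna, egfp)
  prot <- translate_dna(orf)
  body <- substr(prot, 1L, nchar(prot) - 1L)
  if (substr(prot, nchar(prot), nchar(prot)) != "*" || grepl("\\*", body))
    stop("fusion ORF does not end in a single terminal stop", call. = FALSE)
  junction <- nchar(s) / 3
  if (substr(prot, junction + 1L, junction + 6L) != lk$peptide)
    stop("linker translation mismatch at the fusion junction", call. = FALSE)
  feats <- data.frame(
    label = c(fdi_no_stop$id, "GGSGGS linker", "eGFP (synthetic stand-in)"),
    start = c(0L, nchar(s), nchar(s) + nchar(lk$dna)),
    end = c(nchar(s), nchar(s) + nchar(lk$dna), nchar(orf)),
    strand = "+", stringsAsFactors = FALSE)
  rec <- dna_record(orf, paste0(fdi_no_stop$id, "_eGFP_fusion"), "linear",
                    feats)
  attr(rec, "protein") <- prot
  rec
}
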