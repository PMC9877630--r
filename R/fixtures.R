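## Synthetic test-input generators: random inserts with controlled BsaI
## architectures and minimal mock pBTR vectors. Everything is
## deterministic under an explicit seed so fixtures are built in code at
## test time.

.random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

## remove every occurrence of the given motifs (and of nothing else) by
## resampling one base inside each hit until the string is clean.
.scrub_motifs <- function(seq, motifs, circular = FALSE, max_rounds = 200) {
  for (round in seq_len(max_rounds)) {
    scan <- if (circular) paste0(seq, substr(seq, 1L, max(nchar(motifs)) - 1L))
            else seq
    hits <- unlist(lapply(motifs, function(m) .find_starts(scan, m)))
    if (!length(hits)) return(seq)
    p <- (hits[1L] + 2L) %% nchar(seq)  # a base inside the motif
    old <- substr(seq, p + 1L, p + 1L)
    substr(seq, p + 1L, p + 1L) <- sample(setdiff(c("A", "C", "G", "T"), old),
                                          1L)
  }
  stop("could not scrub motifs from random sequence", call. = FALSE)
}

.forbidden_motifs <- c("GGTCTC", "GAGACC")

.palindromic_overhangs <- c("GATC", "AATT", "ACGT", "AGCT", "CATG", "CTAG",
                            "GTAC", "TGCA", "TCGA", "TTAA", "CCGG", "GGCC",
                            "CGCG", "GCGC", "ATAT", "TATA")

#' Generate a synthetic insert (FDI) with a controlled BsaI architecture
#'
#' Produces a random linear fragment that contains exactly
#' `n_internal_sites` BsaI recognition matches (both strands counted) and
#' no accidental extras. Each planted site is a `GGTCTCA` + overhang
#' motif, so the junction sticky end released at that site is the
#' requested 4-mer. This emulates the site architectures of real cloning
#' targets: no internal site, two internal sites, or a site whose
#' overhang is its own reverse complement (palindromic).
#'
#' @param length Fragment length in nt (>= 60).
#' @param n_internal_sites Number of internal BsaI sites.
#' @param internal_overhangs Character vector of 4-mers (recycled), or
#'   `"random"`.
#' @param palindromic If `TRUE`, the first overhang is drawn from the
#'   palindromic 4-mers.
#' @param gc_content Base composition of the random background.
#' @param seed Integer seed; the same spec + seed gives the identical
#'   sequence.
#' @return Linear [dna_record()] with the planted sites annotated.
#' @export
generate_fdi <- function(length, n_internal_sites = 0,
                         internal_overhangs = "random",
                         palindromic = FALSE, gc_content = 0.5, seed = 1) {
  if (length < 60) stop("length must be >= 60", call. = FALSE)
  n <- as.integer(n_internal_sites)
  margin <- 25L
  if (n > 0 && (2L * margin + n * 11L + (n - 1L) * 25L) > length)
    stop("infeasible spec: ", n, " internal sites do not fit in ",
         length, " nt", call. = FALSE)
  with_seed(seed, {
    ovh <- if (identical(internal_overhangs, "random")) {
      pool <- overhang_space(4)
      pool <- if (palindromic) .palindromic_overhangs
              else setdiff(pool, .palindromic_overhangs)
      if (n > 0) sample(pool, n, replace = FALSE) else character()
    } else {
      out <- rep(toupper(internal_overhangs), length.out = max(n, 1L))[seq_len(n)]
      if (palindromic && n > 0 && !any(vapply(out, .is_palindrome, logical(1))))
        out[1L] <- sample(.palindromic_overhangs, 1L)
      out
    }
    for (attempt in 1:50) {
      s <- .scrub_motifs(.random_dna(length, gc_content), .forbidden_motifs)
      if (n > 0) {
        span <- length - 2L * margin
        pos <- margin + floor((seq_len(n) - 0.5) / n * span) - 5L
        for (i in seq_len(n)) {
          motif <- paste0("GGTCTCA", ovh[i])
          substr(s, pos[i] + 1L, pos[i] + 11L) <- motif
        }
      }
      total <- base::length(.find_starts(s, "GGTCTC")) +
        base::length(.find_starts(s, "GAGACC"))
      if (total == n) {
        feats <- if (n > 0)
          data.frame(label = paste0("BsaI site (overhang ", ovh, ")"),
                     start = as.integer(pos), end = as.integer(pos) + 11L,
                     strand = "+", stringsAsFactors = FALSE)
        else NULL
        return(dna_record(s, sprintf("synthFDI_L%d_n%d_seed%d",
                                     length, n, seed),
                          "linear", feats))
      }
    }
  })
  stop("could not generate a clean fragment; relax the spec", call. = FALSE)
}

#' Build a minimal mock pBTR destination vector
#'
#' A circular molecule with the designed Golden Gate junctions of the
#' requested vector: two tandem BsaI recognition sites in reverse
#' orientation flanking a stuffer that stands in for the
#' PnptII::mScarlet-I screening cassette (annotated as such, labelled
#' synthetic). Digestion releases a backbone whose overhangs equal the
#' vector's pair, and both recognition sequences leave with the
#' stuffer-side fragment, so the backbone cannot re-expose a site.
#' A HindIII and an XbaI site are planted in the backbone for screening
#' digests.
#'
#' @param set `"BTR1"` or `"BTR2"` (uses the 35S overexpression vector of
#'   that set), or pass `vector` for any registry entry.
#' @param stuffer_length Stuffer length in nt (>= 50).
#' @param seed Integer seed.
#' @param vector Optional registry vector name or spec overriding `set`.
#' @param backbone_length Backbone length in nt.
#' @return Circular [dna_record()]; the cassette is retrievable with
#'   [vector_cassette()].
#' @export
mock_vector <- function(set = c("BTR1", "BTR2"), stuffer_length = 300,
                        seed = 1, vector = NULL, backbone_length = 2000) {
  if (is.null(vector)) {
    if (!is.character(set) || !all(set %in% c("BTR1", "BTR2")))
      stop("unknown set; use \"BTR1\" or \"BTR2\"", call. = FALSE)
    set <- match.arg(set)
    vector <- if (set == "BTR1") "pK35BTR1" else "pK35BTR2"
  }
  vec <- .as_vector_spec(vector)
  if (stuffer_length < 50) stop("stuffer_length must be >= 50", call. = FALSE)
  if (backbone_length < 200) stop("backbone_length must be >= 200",
                                  call. = FALSE)
  fwd4 <- .adapter_tail4(vec$fwd_adapter)
  rev4 <- .adapter_tail4(vec$rev_adapter)
  scrub_list <- c(.forbidden_motifs, "AAGCTT", "TCTAGA", "GAATTC")
  with_seed(seed, {
    for (attempt in 1:50) {
      backbone <- .scrub_motifs(.random_dna(backbone_length), scrub_list)
      substr(backbone, 151L, 156L) <- "AAGCTT"   # HindIII
      substr(backbone, 651L, 656L) <- "TCTAGA"   # XbaI
      stuffer <- .scrub_motifs(.random_dna(stuffer_length), scrub_list)
      seq <- paste0(reverse_complement(rev4), backbone, fwd4, "T", "GAGACC",
                    stuffer, "GGTCTC", "A")
      n_sites <- base::length(.find_starts(paste0(seq, substr(seq, 1, 5)),
                                           "GGTCTC")) +
        base::length(.find_starts(paste0(seq, substr(seq, 1, 5)), "GAGACC"))
      if (n_sites == 2L) {
        L <- nchar(seq)
        cas_start <- 4L + backbone_length + 11L + 10L
        cas_end <- cas_start + stuffer_length - 20L
        feats <- data.frame(
          label = c("PnptII::mScarlet-I cassette (synthetic stand-in)",
                    "BsaI junction (reverse)", "BsaI junction (forward)"),
          start = c(cas_start, 4L + backbone_length,
                    L - 7L),
          end = c(cas_end, 4L + backbone_length + 11L, L),
          strand = c("+", "-", "+"), stringsAsFactors = FALSE)
        return(dna_record(seq, paste0(vec$name, "_mock"), "circular", feats))
      }
    }
  })
  stop("could not assemble a clean mock vector; try another seed",
       call. = FALSE)
}

.synthetic_egfp_cache <- new.env(parent = emptyenv())

#' Synthetic eGFP coding-sequence stand-in
#'
#' A deterministic 720-nt open reading frame (239 codons + stop) used in
#' place of the real eGFP CDS, which is not redistributed with the
#' package. It has no internal stop codon and no BsaI site; it is a
#' synthetic stand-in, suitable only for frame/junction arithmetic, not
#' for expressing a fluorophore.
#'
#' @return [dna_record()] of the synthetic CDS.
#' @export
synthetic_egfp <- function() {
  if (!is.null(.synthetic_egfp_cache$rec)) return(.synthetic_egfp_cache$rec)
  codons <- c("GCT", "GAA", "GGT", "AAA", "CTG", "GAC", "TTC", "CAT",
              "ATC", "GTT", "AAC", "TGG", "CCA", "TCC", "ACC", "TAC")
  body <- paste(codons[(seq_len(238L) - 1L) %% length(codons) + 1L],
                collapse = "")
  seq <- paste0("ATG", body, "TAA")
  stopifnot(nchar(seq) == 720,
            !grepl("GGTCTC", seq), !grepl("GAGACC", seq))
  rec <- dna_record(seq, "eGFP_synthetic", "linear")
  .synthetic_egfp_cache$rec <- rec
  rec
}
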