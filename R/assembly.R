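#' Reaction program for the one-pot digestion-ligation
#'
#' The pBTR default is 10 cycles of 37 C/3 min (digestion), 16 C/3 min and
#' 12 C/2 min (ligation), followed by a terminal hold. The hold is
#' 4 C/60 min (ligation-favouring) when any insert carries an internal
#' BsaI site -- so that the insert split at its internal sites can
#' re-ligate into the intact molecule -- and 37 C/10 min (one extra
#' digestion, suppressing empty vectors) otherwise. A published variant of
#' the same program runs the 16 C step for 5 min; both presets are
#' equivalent for species-set simulation.
#'
#' @param n_cycles Number of digestion-ligation cycles.
#' @param cycle_steps List of `c(temperature_C, minutes)` steps per cycle.
#' @param terminal_hold `c(temperature_C, minutes)` final hold.
#' @return An object of class `reaction_program`.
#' @export
reaction_program <- function(n_cycles = 10,
                             cycle_steps = list(c(37, 3), c(16, 3), c(12, 2)),
                             terminal_hold = c(37, 10)) {
  structure(list(n_cycles = as.integer(n_cycles),
                 cycle_steps = lapply(cycle_steps, as.numeric),
                 terminal_hold = as.numeric(terminal_hold)),
            class = "reaction_program")
}

#' @rdname reaction_program
#' @param internal_sites Does any insert carry an internal type-IIS site?
#' @param variant `"results"` (16 C for 3 min) or `"methods"` (5 min).
#' @export
pbtr_program <- function(internal_sites = FALSE,
                         variant = c("results", "methods")) {
  variant <- match.arg(variant)
  mid <- if (variant == "results") c(16, 3) else c(16, 5)
  reaction_program(10, list(c(37, 3), mid, c(12, 2)),
                   if (internal_sites) c(4, 60) else c(37, 10))
}

#' @export
print.reaction_program <- function(x, ...) {
  steps <- paste(vapply(x$cycle_steps, function(s)
    sprintf("%g C/%g min", s[1], s[2]), character(1)), collapse = ", ")
  cat(sprintf("<reaction_program> %d cycles of [%s]; hold %g C/%g min\n",
              x$n_cycles, steps, x$terminal_hold[1], x$terminal_hold[2]))
  invisible(x)
}

#' One-pot reaction description
#'
#' @param vector_record The destination vector (circular [dna_record()]).
#' @param fdis List of insert molecules (normally adapter-tailed PCR
#'   amplicons, see [simulate_pcr()]).
#' @param enzyme The type-IIS enzyme driving the reaction.
#' @param ratios Named or positional molar ratios of the FDIs relative to
#'   the vector (annotation only; the simulation is species-set logic).
#' @param ligase Ligase present?
#' @param program A [reaction_program()].
#' @return An object of class `reaction_spec`.
#' @export
reaction_spec <- function(vector_record, fdis, enzyme = bsai(),
                          ratios = NULL, ligase = TRUE, program = NULL) {
  if (!is(vector_record, "dna_record") || !is_circular(vector_record))
    stop("destination vector must be a circular dna_record", call. = FALSE)
  if (is(fdis, "dna_record")) fdis <- list(fdis)
  enzyme <- .as_enzyme(enzyme)
  if (is.null(ratios)) ratios <- rep(1, length(fdis))
  if (any(ratios <= 0)) stop("molar ratios must be positive", call. = FALSE)
  if (is.null(program)) {
    internal <- any(vapply(fdis, function(f)
      nrow(find_sites(f, enzyme)) > 2L, logical(1)))
    program <- pbtr_program(internal_sites = internal)
  }
  structure(list(vector_record = vector_record, fdis = fdis,
                 enzyme = enzyme, ratios = ratios, ligase = isTRUE(ligase),
                 program = program),
            class = "reaction_spec")
}

.ends_compatible <- function(r_ovh, l_ovh, allow_blunt = FALSE) {
  if (r_ovh$type != l_ovh$type) return(FALSE)
  if (r_ovh$type == "blunt") return(allow_blunt)
  identical(l_ovh$seq, reverse_complement(r_ovh$seq))
}

.frag_key <- function(f) paste(f$top, f$l_ovh$seq, f$l_ovh$type,
                               f$r_ovh$seq, f$r_ovh$type, sep = "|")

## Booth's algorithm: lexicographically least rotation of a string, O(n).
.least_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  b <- utf8ToInt(s)
  b <- c(b, b)
  f <- rep.int(-1L, 2L * n)
  k <- 0L
  for (j in 1L:(2L * n - 1L)) {
    sj <- b[j + 1L]
    i <- f[j - k]
    while (i != -1L && sj != b[k + i + 2L]) {
      if (sj < b[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != b[k + i + 2L]) {
      if (sj < b[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  intToUtf8(b[(k + 1L):(k + n)])
}

## canonical string identity for a circular DNA molecule: lexicographic
## minimum over all rotations of the sequence and of its reverse
## complement.
.canonical_rotation <- function(seq) {
  if (!nchar(seq)) return("")
  min(.least_rotation(seq), .least_rotation(reverse_complement(seq)))
}

#' Circular assembly product
#'
#' A circular ligation product together with its ordered fragment
#' composition and a classification assigned by the one-pot simulator:
#' `desired` (vector backbone + one complete insert), `empty_vector`
#' (backbone rejoined with vector-derived stuffer), `cassette_circle`
#' (vector-derived stuffer only), `concatemer` (two or more complete
#' backbone/insert units) or `chimera` (any other mis-joined circle).
#'
#' @param record Circular [dna_record()] of the product.
#' @param composition Ordered list of oriented [sticky_fragment()]s.
#' @param klass Classification string.
#' @return An object of class `assembly_product`.
#' @export
assembly_product <- function(record, composition, klass = "unclassified") {
  structure(list(record = record, composition = composition, klass = klass),
            class = "assembly_product")
}

#' @export
print.assembly_product <- function(x, ...) {
  cat(sprintf("<assembly_product> %s: %d bp circle, %d fragment(s) [%s]\n",
              x$record$id, record_length(x$record), length(x$composition),
              x$klass))
  invisible(x)
}

.product_from_chain <- function(chain, idx = NULL) {
  top <- paste(vapply(chain, `[[`, character(1), "top"), collapse = "")
  feats <- .empty_features()
  off <- 0L
  for (f in chain) {
    if (nrow(f$features)) {
      ff <- f$features
      ff$start <- ff$start + off
      ff$end <- ff$end + off
      feats <- rbind(feats, ff)
    }
    off <- off + nchar(f$top)
  }
  id <- if (is.null(idx)) "assembly_product" else paste0("product_", idx)
  assembly_product(dna_record(top, id, "circular", feats), chain)
}

#' Enumerate circular ligation products
#'
#' Enumerates every distinct circular product of at most `max_fragments`
#' pieces in which each junction joins an overhang to its exact reverse
#' complement (cohesive-end ligation; blunt joins are only enabled for
#' classical subcloning via `allow_blunt`). Each input fragment is a
#' species available in unlimited copies. Rotationally and reflectively
#' equivalent circles are reported once; linear dead-ends are discarded.
#'
#' @param fragments List of [sticky_fragment()]s.
#' @param max_fragments Maximum number of pieces per circle.
#' @param allow_blunt Allow blunt-blunt junctions.
#' @return List of [assembly_product()]s (classification `"unclassified"`).
#' @export
ligate <- function(fragments, max_fragments = 6, allow_blunt = FALSE) {
  if (!is.numeric(max_fragments) || max_fragments < 1)
    stop("max_fragments must be >= 1", call. = FALSE)
  if (is(fragments, "sticky_fragment")) fragments <- list(fragments)
  n <- length(fragments)
  if (!n) return(list())
  oriented <- lapply(fragments, function(f) list(f, flip_fragment(f)))
  seen <- character()
  products <- list()

  close_chain <- function(chain_frag, comp_key) {
    first <- chain_frag[[1L]]
    last <- chain_frag[[length(chain_frag)]]
    if (!.ends_compatible(last$r_ovh, first$l_ovh, allow_blunt)) return()
    key <- .canonical_rotation(paste(vapply(chain_frag, `[[`, character(1),
                                            "top"), collapse = ""))
    key <- paste0(key, "#", length(chain_frag))
    if (key %in% seen) return()
    seen <<- c(seen, key)
    products[[length(products) + 1L]] <<-
      .product_from_chain(chain_frag, length(products) + 1L)
  }

  extend <- function(chain_frag, chain_id, start) {
    close_chain(chain_frag, chain_id)
    if (length(chain_frag) >= max_fragments) return()
    last <- chain_frag[[length(chain_frag)]]
    for (j in start:n) for (o in 1:2) {
      cand <- oriented[[j]][[o]]
      if (.ends_compatible(last$r_ovh, cand$l_ovh, allow_blunt)) {
        extend(c(chain_frag, list(cand)), c(chain_id, j * 2L + o), start)
      }
    }
  }

  for (s in seq_len(n)) {
    ## canonical start: lowest species index present, forward orientation
    extend(list(oriented[[s]][[1L]]), s * 2L + 1L, s)
  }
  products
}

## ---- provenance mapping -------------------------------------------------

## flat provenance table of a product: one row per provenance entry, in
## circle order, with product-coordinate offsets.
.prov_table <- function(product) {
  rows <- list()
  off <- 0L
  for (f in product$composition) {
    for (p in f$prov) {
      rows[[length(rows) + 1L]] <- data.frame(
        src = p$src, start = p$start, len = p$len, strand = p$strand,
        src_len = p$src_len, circular = p$circular, offset = off,
        stringsAsFactors = FALSE)
      off <- off + p$len
    }
  }
  do.call(rbind, rows)
}

## Does product interval [from, from+width) map to a single contiguous
## run of one source molecule on one strand?
.interval_inherited <- function(prov, from, width, total) {
  from <- from %% total
  pos <- (from + seq_len(width) - 1L) %% total
  src <- character(width); at <- integer(width); strand <- character(width)
  for (i in seq_len(width)) {
    j <- max(which(prov$offset <= pos[i]))
    p <- prov[j, ]
    d <- pos[i] - p$offset
    if (d >= p$len) return(FALSE)
    src[i] <- p$src; strand[i] <- p$strand
    at[i] <- if (p$strand == "+") (p$start + d) %% p$src_len
             else (p$start + p$len - 1L - d) %% p$src_len
  }
  if (length(unique(src)) != 1L || length(unique(strand)) != 1L) return(FALSE)
  step <- if (strand[1] == "+") 1L else -1L
  sl <- prov$src_len[match(src[1], prov$src)]
  all(diff(at) %% sl == step %% sl)
}

## Is the fragment a contiguous slice of one source molecule (as opposed
## to a fused piece spanning a ligated junction)? Used when re-digesting
## products: every circle that could be built from a fused piece is
## already enumerated from its elementary pieces within the
## `max_fragments` bound, so only contiguous slices can be new species.
.is_source_contiguous <- function(frag) {
  p <- frag$prov
  if (length(p) <= 1L) return(TRUE)
  for (i in seq_len(length(p) - 1L)) {
    a <- p[[i]]; b <- p[[i + 1L]]
    if (a$src != b$src || a$strand != b$strand) return(FALSE)
    ok <- if (a$strand == "+") (a$start + a$len) %% a$src_len == b$start
          else (b$start + b$len) %% a$src_len == a$start
    if (!ok) return(FALSE)
  }
  TRUE
}

## Sites of `enzyme` in a circular product that are NOT simple restorations
## of a contiguous stretch of one source molecule.
.novel_sites <- function(product, enzyme) {
  enzyme <- .as_enzyme(enzyme)
  sites <- find_sites(product$record, enzyme)
  if (!nrow(sites)) return(sites)
  prov <- .prov_table(product)
  total <- record_length(product$record)
  rlen <- nchar(enzyme$recognition)
  keep <- vapply(seq_len(nrow(sites)), function(i)
    !.interval_inherited(prov, sites$position[i], rlen, total), logical(1))
  sites[keep, , drop = FALSE]
}

## Re-digest a circular product, preserving provenance through the
## composition (sites restored at junctions become cuttable again).
.digest_product <- function(product, enzyme) {
  rec <- product$record
  cuts <- .cut_table(rec, enzyme)
  if (!nrow(cuts)) return(list())
  prov <- .prov_table(rec_prod <- product)
  L <- record_length(rec)
  cuts <- cuts[order(cuts$t %% L), , drop = FALSE]
  .cut_windows_ok(rec, cuts)
  k <- nrow(cuts)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    c1 <- as.list(cuts[i, ]); c2 <- as.list(cuts[if (i == k) 1L else i + 1L, ])
    if (i == k || c2$t <= c1$t) { c2$t <- c2$t + L; c2$b <- c2$b + L }
    f <- .frag_between(rec, c1, c2)
    f$prov <- .slice_prov(prov, c1$t %% L, nchar(f$top), L)
    out[[i]] <- f
  }
  out
}

## provenance of product interval [from, from+width): split entries.
.slice_prov <- function(prov, from, width, total) {
  res <- list()
  remaining <- width
  pos <- from %% total
  while (remaining > 0L) {
    j <- max(which(prov$offset <= pos))
    p <- prov[j, ]
    d <- pos - p$offset
    take <- min(p$len - d, remaining)
    start <- if (p$strand == "+") (p$start + d) %% p$src_len
             else p$start  ## minus-strand entries keep source-interval start
    if (p$strand == "-") {
      ## entry covers source interval [p$start, p$start+p$len) reversed;
      ## taking product offsets [d, d+take) maps to source
      ## [p$start + p$len - d - take, p$start + p$len - d)
      start <- (p$start + p$len - d - take) %% p$src_len
    }
    res[[length(res) + 1L]] <- list(src = p$src, start = as.integer(start),
                                    len = as.integer(take),
                                    strand = p$strand,
                                    src_len = p$src_len,
                                    circular = p$circular)
    pos <- (pos + take) %% total
    remaining <- remaining - take
  }
  res
}

## ---- one-pot simulation ---------------------------------------------------

.sources_of <- function(frag) unique(vapply(frag$prov, `[[`, character(1), "src"))

.classify_product <- function(product, info) {
  comp <- product$composition
  srcs <- lapply(comp, .sources_of)
  is_backbone <- vapply(comp, function(f) {
    s <- .sources_of(f)
    length(s) == 1L && s == info$vector_id &&
      identical(.frag_key(f), info$backbone_key) ||
      length(s) == 1L && s == info$vector_id &&
      identical(.frag_key(flip_fragment(f)), info$backbone_key)
  }, logical(1))
  vec_only <- vapply(srcs, function(s) all(s == info$vector_id), logical(1))
  nb <- sum(is_backbone)
  if (nb == 0L) {
    return(if (all(vec_only)) "cassette_circle" else "chimera")
  }
  if (nb >= 2L) return("concatemer")
  ## rotate the backbone to the front; reflect so the backbone is forward
  i <- which(is_backbone)
  comp <- c(comp[i:length(comp)], comp[seq_len(i - 1L)])
  if (!identical(.frag_key(comp[[1L]]), info$backbone_key)) {
    comp <- c(comp[1L], rev(lapply(comp[-1L], flip_fragment)))
    comp[[1L]] <- flip_fragment(comp[[1L]])
  }
  rest <- comp[-1L]
  if (!length(rest)) return("chimera")  # backbone self-circle (cannot arise)
  rest_srcs <- unique(unlist(lapply(rest, .sources_of)))
  if (all(rest_srcs == info$vector_id)) return("empty_vector")
  if (length(rest_srcs) != 1L || !rest_srcs %in% names(info$payloads))
    return("chimera")
  expected <- info$payloads[[rest_srcs]]
  got <- vapply(rest, .frag_key, character(1))
  if (identical(got, expected)) return("desired")
  "chimera"
}

#' Simulate the one-pot, one-way digestion-ligation reaction
#'
#' Iterates digestion and ligation to a species-set fixpoint. Circular
#' products that still expose a recognition site of the reaction enzyme
#' are re-digested on the next cycle; products lacking all sites are
#' terminal. When the terminal hold is ligation-favouring (4 C), circles
#' whose every remaining site is an exact restoration of a contiguous
#' stretch of an input molecule (an insert re-ligated at its own internal
#' sites, or a re-formed vector) are also collected as terminal species --
#' which is how inserts with internal BsaI sites end up cloned intact.
#' When the hold is 37 C, one extra digestion removes every
#' site-containing circle, suppressing empty vectors.
#'
#' @param reaction A [reaction_spec()].
#' @param max_fragments Bound on pieces per enumerated circle.
#' @return List of terminal [assembly_product()]s with classification;
#'   attribute `warnings` carries junction-collision diagnostics.
#' @export
simulate_one_pot <- function(reaction, max_fragments = 6) {
  if (!is(reaction, "reaction_spec"))
    stop("expected a reaction_spec (no destination vector flagged)",
         call. = FALSE)
  enzyme <- reaction$enzyme
  vec <- reaction$vector_record

  vfrags <- digest(vec, enzyme)
  if (isTRUE(attr(vfrags, "uncut")))
    stop("destination vector '", vec$id, "' has no ", enzyme$name, " site",
         call. = FALSE)
  has_site <- vapply(vfrags, function(f) {
    r <- dna_record(f$top, "tmp")
    nrow(find_sites(r, enzyme)) > 0L
  }, logical(1))
  if (sum(!has_site) != 1L)
    stop("cannot identify a unique site-free backbone in '", vec$id, "'",
         call. = FALSE)
  backbone <- vfrags[[which(!has_site)]]

  payloads <- list()
  pool <- list()
  pool_keys <- character()
  add <- function(frags) {
    for (f in frags) {
      k <- .frag_key(f)
      if (!k %in% pool_keys) {
        pool[[length(pool) + 1L]] <<- f
        pool_keys <<- c(pool_keys, k)
      }
    }
  }
  add(vfrags)
  collision <- character()
  vec_ovh <- c(backbone$l_ovh$seq, backbone$r_ovh$seq)
  for (f in reaction$fdis) {
    ffrags <- digest(f, enzyme)
    if (length(ffrags) < 3L)
      stop("FDI '", f$id, "' does not release an insert (needs two ",
           enzyme$name, " adapter sites)", call. = FALSE)
    payload <- ffrags[2:(length(ffrags) - 1L)]
    payloads[[f$id]] <- vapply(payload, .frag_key, character(1))
    internal_ovh <- unlist(lapply(payload[-length(payload)],
                                  function(x) x$r_ovh$seq))
    bad <- internal_ovh[internal_ovh %in% c(vec_ovh,
                                            reverse_complement(vec_ovh))]
    if (length(bad))
      collision <- c(collision, sprintf(
        "internal %s overhang(s) %s of '%s' collide with the vector overhangs; switch vector sets",
        enzyme$name, paste(unique(bad), collapse = "/"), f$id))
    add(ffrags)
  }
  info <- list(vector_id = vec$id, backbone_key = .frag_key(backbone),
               payloads = payloads)

  hold_ligation <- reaction$program$terminal_hold[1] <= 16
  n_sites <- nrow(find_sites(vec, enzyme)) +
    sum(vapply(reaction$fdis, function(f) nrow(find_sites(f, enzyme)),
               integer(1)))
  max_iter <- n_sites + 2L

  terminal <- list()
  terminal_keys <- character()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("digestion-ligation fixpoint not reached within ", max_iter,
           " iterations; cyclic species: ",
           paste(head(pool_keys, 3), collapse = " ; "), call. = FALSE)
    }
    n_before <- length(pool)
    products <- ligate(pool, max_fragments = max_fragments)
    for (p in products) {
      sites <- find_sites(p$record, enzyme)
      ok <- if (!nrow(sites)) TRUE
            else hold_ligation && nrow(.novel_sites(p, enzyme)) == 0L
      key <- .canonical_rotation(p$record$seq)
      if (ok) {
        if (!key %in% terminal_keys) {
          p$klass <- .classify_product(p, info)
          terminal[[length(terminal) + 1L]] <- p
          terminal_keys <- c(terminal_keys, key)
        }
      } else if (nrow(sites)) {
        add(Filter(.is_source_contiguous, .digest_product(p, enzyme)))
      }
    }
    if (length(pool) == n_before) break
  }
  if (length(collision)) {
    for (w in unique(collision)) warning(w, call. = FALSE)
    attr(terminal, "warnings") <- unique(collision)
  }
  attr(terminal, "iterations") <- iter
  terminal
}

#' Simulate a multiplexed one-pot reaction
#'
#' Several inserts sharing one adapter pair are cloned into one vector in a
#' single tube; every insert presents the same two overhangs as the
#' backbone accepts once, so the terminal desired products are exactly one
#' single-insert construct per insert and no multi-insert stacking is
#' possible.
#'
#' @param reaction A [reaction_spec()] with k FDIs.
#' @param max_fragments Bound on pieces per circle.
#' @return List with `products` (all terminal products) and `census`
#'   (data.frame of desired constructs, one row per insert cloned).
#' @export
simulate_multiplex <- function(reaction, max_fragments = 6) {
  enzyme <- reaction$enzyme
  ends <- lapply(reaction$fdis, function(f) {
    fr <- digest(f, enzyme)
    if (length(fr) < 3L)
      stop("FDI '", f$id, "' lacks the adapter sites", call. = FALSE)
    c(fr[[2L]]$l_ovh$seq, fr[[length(fr) - 1L]]$r_ovh$seq)
  })
  if (length(ends) > 1L) {
    ref <- ends[[1L]]
    same <- vapply(ends, function(e) identical(e, ref), logical(1))
    if (!all(same))
      stop("FDIs carry mismatched adapter sets: ",
           paste(vapply(reaction$fdis[!same], `[[`, character(1), "id"),
                 collapse = ", "), call. = FALSE)
  }
  products <- simulate_one_pot(reaction, max_fragments)
  desired <- Filter(function(p) p$klass == "desired", products)
  insert_of <- vapply(desired, function(p) {
    s <- setdiff(unique(unlist(lapply(p$composition, .sources_of))),
                 reaction$vector_record$id)
    paste(s, collapse = "+")
  }, character(1))
  census <- data.frame(insert = insert_of,
                       product_length = vapply(desired, function(p)
                         record_length(p$record), integer(1)),
                       stringsAsFactors = FALSE)
  list(products = products, census = census)
}

#' Classical two-enzyme subcloning
#'
#' Replays a conventional digestion-ligation step: both molecules are cut
#' with the named enzyme(s), one fragment of each is selected, and the two
#' are ligated into a circle (the insert is tried in both orientations).
#' With `insert_source = NULL` the selected vector fragment is
#' self-circularised (a deletion/religation step). Blunt ends ligate only
#' to blunt ends here; a blunt end facing a sticky end is an error naming
#' the offending ends.
#'
#' @param vector_record,insert_source [dna_record()]s (insert optional).
#' @param enzymes Enzyme(s), as in [digest()].
#' @param keep Selection rule per molecule:
#'   `list(vector = ..., insert = ...)` where each rule is `"largest"`,
#'   `"smallest"`, a fragment index, or a length-2 numeric range matching
#'   exactly one fragment.
#' @param id Id of the recombinant record.
#' @return Circular [dna_record()] of the recombinant.
#' @export
subclone <- function(vector_record, insert_source = NULL, enzymes,
                     keep = list(vector = "largest", insert = "smallest"),
                     id = NULL) {
  pick <- function(frags, rule, what) {
    lens <- vapply(frags, fragment_length, integer(1))
    if (identical(rule, "largest")) return(frags[[which.max(lens)]])
    if (identical(rule, "smallest")) return(frags[[which.min(lens)]])
    if (is.numeric(rule) && length(rule) == 1L) return(frags[[rule]])
    if (is.numeric(rule) && length(rule) == 2L) {
      hit <- which(lens >= rule[1] & lens <= rule[2])
      if (length(hit) != 1L)
        stop(length(hit), " ", what, " fragment(s) in length range [",
             rule[1], ", ", rule[2], "]", call. = FALSE)
      return(frags[[hit]])
    }
    stop("unknown selection rule for ", what, call. = FALSE)
  }
  fmt_end <- function(o) if (o$type == "blunt") "blunt"
             else sprintf("%s'-%s", o$type, o$seq)
  vfr <- pick(digest(vector_record, enzymes), keep$vector, "vector")
  if (is.null(insert_source)) {
    if (!.ends_compatible(vfr$r_ovh, vfr$l_ovh, allow_blunt = TRUE))
      stop("vector fragment ends are not mutually compatible: left ",
           fmt_end(vfr$l_ovh), ", right ", fmt_end(vfr$r_ovh), call. = FALSE)
    prod <- .product_from_chain(list(vfr))
  } else {
    ifr <- pick(digest(insert_source, enzymes), keep$insert, "insert")
    ok_fwd <- .ends_compatible(vfr$r_ovh, ifr$l_ovh, TRUE) &&
      .ends_compatible(ifr$r_ovh, vfr$l_ovh, TRUE)
    flp <- flip_fragment(ifr)
    ok_rev <- .ends_compatible(vfr$r_ovh, flp$l_ovh, TRUE) &&
      .ends_compatible(flp$r_ovh, vfr$l_ovh, TRUE)
    mixed_blunt <- (vfr$r_ovh$type == "blunt") != (ifr$l_ovh$type == "blunt") ||
      (ifr$r_ovh$type == "blunt") != (vfr$l_ovh$type == "blunt")
    if (!ok_fwd && !ok_rev) {
      stop("incompatible ends: vector [left ", fmt_end(vfr$l_ovh),
           ", right ", fmt_end(vfr$r_ovh), "] vs insert [left ",
           fmt_end(ifr$l_ovh), ", right ", fmt_end(ifr$r_ovh), "]",
           if (mixed_blunt) " -- a blunt end faces a sticky end" else "",
           call. = FALSE)
    }
    if (ok_fwd && ok_rev)
      warning("insert ligates in both orientations; returning forward",
              call. = FALSE)
    prod <- .product_from_chain(list(vfr, if (ok_fwd) ifr else flp))
  }
  rec <- prod$record
  rec$id <- id %||% paste0(vector_record$id, "_recombinant")
  rec
}

#' Tabulate assembly products
#'
#' @param products List of [assembly_product()]s.
#' @param enzyme Optional enzyme whose remaining sites are counted.
#' @return data.frame, one row per product.
#' @export
product_table <- function(products, enzyme = NULL) {
  if (!length(products))
    return(data.frame(id = character(), klass = character(),
                      length = integer(), n_fragments = integer(),
                      composition = character(), sites = integer(),
                      stringsAsFactors = FALSE))
  data.frame(
    id = vapply(products, function(p) p$record$id, character(1)),
    klass = vapply(products, `[[`, character(1), "klass"),
    length = vapply(products, function(p) record_length(p$record),
                    integer(1)),
    n_fragments = vapply(products, function(p) length(p$composition),
                         integer(1)),
    composition = vapply(products, function(p)
      paste(vapply(p$composition, function(f)
        paste(.sources_of(f), collapse = "+"), character(1)),
        collapse = ";"), character(1)),
    sites = if (is.null(enzyme)) NA_integer_ else
      vapply(products, function(p)
        nrow(find_sites(p$record, enzyme)), integer(1)),
    stringsAsFactors = FALSE)
}

#' Read/write a plain-text reaction configuration
#'
#' JSON configuration naming the molecule files (FASTA/GenBank, relative to
#' the config file), roles, molar ratios, enzyme and program, consumable by
#' [simulate_one_pot()].
#'
#' @param path Config path.
#' @return A [reaction_spec()].
#' @export
read_reaction_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  dir <- dirname(path)
  vec <- NULL; fdis <- list(); ratios <- numeric()
  for (m in cfg$molecules) {
    rec <- read_record(file.path(dir, m$file),
                       topology = m$topology %||% NULL)
    if (identical(m$role, "vector")) {
      if (!is.null(vec))
        stop("config names more than one destination vector", call. = FALSE)
      rec$topology <- "circular"
      vec <- rec
    } else {
      fdis[[length(fdis) + 1L]] <- rec
      ratios <- c(ratios, m$ratio %||% 1)
    }
  }
  if (is.null(vec)) stop("config names no destination vector", call. = FALSE)
  prog <- if (!is.null(cfg$program))
    reaction_program(cfg$program$n_cycles %||% 10,
                     lapply(cfg$program$cycle_steps %||%
                              list(c(37, 3), c(16, 3), c(12, 2)), unlist),
                     unlist(cfg$program$terminal_hold %||% c(37, 10)))
  else NULL
  reaction_spec(vec, fdis, enzyme = cfg$enzyme %||% "BsaI",
                ratios = ratios, program = prog)
}

#' @rdname read_reaction_config
#' @param reaction A [reaction_spec()].
#' @param dir Directory receiving the config and FASTA files.
#' @param name Base name for the config.
#' @export
write_reaction_config <- function(reaction, dir, name = "reaction") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mols <- list()
  vfile <- paste0(reaction$vector_record$id, ".fa")
  write_record(reaction$vector_record, file.path(dir, vfile), "fasta")
  mols[[1]] <- list(file = vfile, role = "vector", ratio = 1)
  for (i in seq_along(reaction$fdis)) {
    f <- reaction$fdis[[i]]
    ffile <- paste0(f$id, ".fa")
    write_record(f, file.path(dir, ffile), "fasta")
    mols[[length(mols) + 1L]] <- list(file = ffile, role = "fdi",
                                      ratio = reaction$ratios[i])
  }
  cfg <- list(molecules = mols, enzyme = reaction$enzyme$name,
              program = list(n_cycles = reaction$program$n_cycles,
                             cycle_steps = reaction$program$cycle_steps,
                             terminal_hold = reaction$program$terminal_hold))
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
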