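test_that("BsaI enzyme model matches GGTCTC(N1)/(N5)", {
  e <- bsai()
  expect_identical(e$recognition, "GGTCTC")
  expect_identical(e$top_cut_offset, 1L)
  expect_identical(e$bottom_cut_offset, 5L)
  expect_identical(overhang_length(e), 4L)
  expect_error(get_enzyme("NoSuchI"), "unknown enzyme")
})

test_that("find_sites sees both strands and circular origin-spanning sites", {
  r <- dna_record("AAAAGGTCTCAGATGCTTTT")
  s <- find_sites(r, bsai())
  expect_identical(s$position, 4L)
  expect_identical(s$strand, "+")

  r2 <- dna_record("TTGGATAGAGACCAAAA")
  s2 <- find_sites(r2, bsai())
  expect_identical(s2$strand, "-")
  expect_identical(substr(r2$seq, s2$position + 1, s2$position + 6), "GAGACC")

  # site spanning the origin of a circular record; oracle = scan of the
  # doubled sequence, deduplicated modulo length
  seq <- "CTCAGATGCTTTTTTTTTTACGGT"  # circular: ...GGT + CTC... across origin
  circ <- dna_record(seq, "ori", "circular")
  dbl <- paste0(seq, seq)
  L <- nchar(seq)
  naive <- unique((which(vapply(seq_len(2 * L - 5), function(i)
    substr(dbl, i, i + 5) == "GGTCTC", logical(1))) - 1L) %% L)
  got <- find_sites(circ, bsai())
  expect_identical(sort(got$position), sort(as.integer(naive)))
  expect_identical(nrow(got), 1L)
  expect_identical(nrow(find_sites(dna_record(seq, "lin", "linear"), bsai())),
                   0L)
})

test_that("find_sites matches a naive per-position scan on random input", {
  set.seed(21)
  for (i in 1:15) {
    s <- random_dna_str(sample(200:2000, 1))
    topo <- sample(c("linear", "circular"), 1)
    r <- dna_record(s, "rnd", topo)
    scan <- if (topo == "circular") paste0(s, substr(s, 1, 5)) else s
    naive <- function(pat) {
      hits <- which(vapply(seq_len(max(nchar(scan) - 5, 0)), function(p)
        substr(scan, p, p + 5) == pat, logical(1))) - 1L
      unique(hits %% nchar(s))
    }
    expected <- rbind(
      data.frame(position = naive("GGTCTC"),
                 strand = rep("+", length(naive("GGTCTC")))),
      data.frame(position = naive("GAGACC"),
                 strand = rep("-", length(naive("GAGACC")))))
    expected <- expected[order(expected$position, expected$strand), ]
    got <- find_sites(r, bsai())
    expect_identical(got$position, as.integer(expected$position))
    expect_identical(got$strand, expected$strand)
  }
})

test_that("digest cut geometry: the forced GATG example", {
  fr <- digest(dna_record("AAAAGGTCTCAGATGCTTTT"), bsai())
  expect_length(fr, 2)
  expect_identical(fr[[2]]$l_ovh$seq, "GATG")
  expect_identical(fr[[2]]$l_ovh$type, "5")
  expect_identical(nchar(fr[[2]]$l_ovh$seq), 4L)
  expect_identical(fr[[1]]$r_ovh$seq, "CATC")  # complementary face
  expect_identical(fr[[1]]$top, "AAAAGGTCTCA")
  expect_identical(fr[[2]]$top, "GATGCTTTT")
})

test_that("pBTR-style cassettes give the set overhangs, sites on stuffer", {
  v1 <- mock_vector("BTR1", seed = 3)
  fr1 <- digest(v1, bsai())
  expect_length(fr1, 2)
  backbone <- fr1[[1]]; stuffer <- fr1[[2]]
  expect_setequal(c(backbone$l_ovh$seq, backbone$r_ovh$seq),
                  c("CATC", "GGAT"))
  expect_false(grepl("GGTCTC|GAGACC", backbone$top))
  expect_true(grepl("GGTCTC", stuffer$top) && grepl("GAGACC", stuffer$top))

  v2 <- mock_vector("BTR2", seed = 3)
  fr2 <- digest(v2, bsai())
  backbone2 <- fr2[[1]]
  expect_setequal(c(backbone2$l_ovh$seq, backbone2$r_ovh$seq),
                  c("TCTA", "GAGC"))
})

test_that("digest edge cases: uncut circles, ambiguity, overlapping windows", {
  circ <- dna_record(random_dna_str(100), "c", "circular")
  while (nrow(find_sites(circ, bsai())) > 0)
    circ <- dna_record(random_dna_str(100), "c", "circular")
  fr <- digest(circ, bsai())
  expect_true(attr(fr, "uncut"))
  expect_identical(fr[[1]]$top, circ$seq)

  amb <- dna_record("AAAAGGTCTCAGNTGCTTTT")  # N inside the overhang window
  expect_error(digest(amb, bsai()), "ambiguity")

  # two sites whose 4-nt cut windows overlap
  clash <- dna_record("AAAGGTCTCATTTGAGACCAAAA")
  expect_error(digest(clash, bsai()), "overlapping cut windows")
})

test_that("fragment lengths always sum to the input length", {
  set.seed(31)
  for (i in 1:8) {
    fdi <- generate_fdi(sample(300:1500, 1), sample(0:2, 1), seed = i)
    amp <- simulate_pcr(fdi, design_primers(fdi, "pK35BTR1"))
    fr <- digest(amp, bsai())
    expect_identical(sum(vapply(fr, fragment_length, integer(1))),
                     record_length(amp))
  }
  v <- mock_vector("BTR1", seed = 9)
  expect_identical(sum(vapply(digest(v, bsai()), fragment_length,
                              integer(1))), record_length(v))
})

test_that("digestion of a circular record is rotation-invariant", {
  v <- mock_vector("BTR2", seed = 4)
  key <- function(f) paste(f$top, f$l_ovh$seq, f$r_ovh$seq)
  ref <- sort(vapply(digest(v, bsai()), key, character(1)))
  set.seed(7)
  for (off in sample(record_length(v) - 1, 5)) {
    rot <- dna_record(paste0(substr(v$seq, off + 1, record_length(v)),
                             substr(v$seq, 1, off)), "rot", "circular")
    expect_identical(sort(vapply(digest(rot, bsai()), key, character(1))),
                     ref)
  }
})

test_that("digesting a site-free product is the identity (one-way design)", {
  fdi <- generate_fdi(700, 0, seed = 13)
  v <- mock_vector("BTR1", seed = 13)
  prods <- simulate_one_pot(plan_reaction(fdi, v), max_fragments = 2)
  d <- Filter(function(p) p$klass == "desired", prods)[[1]]
  fr <- digest(d$record, bsai())
  expect_true(attr(fr, "uncut"))
})

test_that("restriction_map computes arc lengths and flags uncut circles", {
  # circular length-100 record with HindIII cut positions 10 and 40
  s <- strrep("A", 100)
  substr(s, 10, 15) <- "AAGCTT"   # site start 9 (0-based), cut t = 10
  substr(s, 40, 45) <- "AAGCTT"   # cut t = 40
  r <- dna_record(s, "toy", "circular")
  expect_identical(as.integer(restriction_map(r, "HindIII")), c(30L, 70L))

  un <- dna_record(strrep("A", 64), "u", "circular")
  m <- restriction_map(un, "HindIII")
  expect_true(attr(m, "uncut"))
  expect_identical(as.integer(m), 64L)

  # order-independence of the enzyme list
  v <- mock_vector("BTR1", seed = 3)
  expect_identical(restriction_map(v, list("HindIII", "XbaI")),
                   restriction_map(v, list("XbaI", "HindIII")))
})

test_that("classical enzymes in the built-in table cut as published", {
  # HindIII A^AGCTT leaves AGCT 5' overhangs
  s <- paste0(strrep("C", 20), "AAGCTT", strrep("G", 20))
  fr <- digest(dna_record(s), "HindIII")
  expect_identical(fr[[2]]$l_ovh, list(seq = "AGCT", type = "5"))
  # SacI GAGCT^C leaves AGCT 3' overhangs
  s2 <- paste0(strrep("C", 20), "GAGCTC", strrep("G", 20))
  fr2 <- digest(dna_record(s2), "SacI")
  expect_identical(fr2[[2]]$l_ovh$type, "3")
  expect_identical(fr2[[1]]$r_ovh$seq, "AGCT")
  # PmeI cuts blunt
  s3 <- paste0(strrep("C", 20), "GTTTAAAC", strrep("G", 20))
  fr3 <- digest(dna_record(s3), "PmeI")
  expect_identical(fr3[[1]]$r_ovh$type, "blunt")
})
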