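test_that("ligate: unique complementary pairing gives exactly one circle", {
  backbone <- make_frag("GGAT", random_dna_str(60), "CATC", "vec")
  insert <- make_frag("GATG", random_dna_str(40), "ATCC", "ins")
  prods <- ligate(list(backbone, insert), max_fragments = 2)
  expect_length(prods, 1)
  expect_length(prods[[1]]$composition, 2)
  expect_identical(record_length(prods[[1]]$record),
                   fragment_length(backbone) + fragment_length(insert))
})

test_that("ligate: a pBTR backbone cannot self-religate", {
  backbone <- make_frag("GGAT", random_dna_str(60), "CATC", "vec")
  expect_length(ligate(list(backbone), max_fragments = 4), 0)
  expect_error(ligate(list(backbone), max_fragments = 0), "max_fragments")
})

test_that("ligate: palindromic ends give self-circle plus head-to-head dimer", {
  f <- make_frag("GATC", random_dna_str(30), "GATC", "pal")
  prods <- ligate(list(f), max_fragments = 2)
  oracle <- oracle_circles(list(f), max_len = 2)
  expect_identical(product_canonicals(prods), oracle)
  expect_setequal(vapply(prods, function(p) length(p$composition),
                         integer(1)), c(1L, 2L))
})

test_that("ligate matches the brute-force oracle on random pools", {
  set.seed(101)
  ovh_pool <- c("GATG", "CATC", "GGAT", "ATCC", "GATC", "ACGT")
  for (rep in 1:12) {
    n <- sample(2:4, 1)
    frags <- lapply(seq_len(n), function(i)
      make_frag(sample(ovh_pool, 1), random_dna_str(sample(10:30, 1)),
                sample(ovh_pool, 1), paste0("f", i)))
    got <- product_canonicals(ligate(frags, max_fragments = 4))
    expect_identical(got, oracle_circles(frags, 4))
  }
})

test_that("ligate matches the oracle on a pool of six fragment species", {
  set.seed(55)
  ovh_pool <- c("GATG", "CATC", "TCTA", "GAGC", "AATT")
  frags <- lapply(1:6, function(i)
    make_frag(sample(ovh_pool, 1), random_dna_str(sample(12:25, 1)),
              sample(ovh_pool, 1), paste0("f", i)))
  # chain length capped at 3 to keep the exhaustive oracle tractable
  got <- product_canonicals(ligate(frags, max_fragments = 3))
  expect_identical(got, oracle_circles(frags, 3))
})

test_that("conservation: product length equals the sum of its fragments", {
  v <- mock_vector("BTR1", seed = 17)
  fdi <- generate_fdi(800, 2, seed = 17)
  rx <- plan_reaction(fdi, v)
  prods <- simulate_one_pot(rx, max_fragments = 4)
  for (p in prods) {
    expect_identical(record_length(p$record),
                     sum(vapply(p$composition, fragment_length, integer(1))))
  }
})

test_that("one-pot, no internal site, 37 C hold: desired product, no empties", {
  v <- mock_vector("BTR1", seed = 3)
  fdi <- generate_fdi(900, 0, seed = 7)            # AtMyb75-like
  rx <- plan_reaction(fdi, v)
  expect_identical(rx$program$terminal_hold, c(37, 10))
  prods <- simulate_one_pot(rx)
  klass <- vapply(prods, `[[`, character(1), "klass")
  expect_identical(sum(klass == "desired"), 1L)
  expect_identical(sum(klass == "empty_vector"), 0L)
  # every terminal product is free of BsaI sites at this hold
  for (p in prods)
    expect_identical(nrow(find_sites(p$record, bsai())), 0L)
  expect_lte(attr(prods, "iterations"),
             nrow(find_sites(v, bsai())) + nrow(find_sites(fdi, bsai())) + 4L)
})

test_that("one-pot, two internal sites, 4 C hold: intact insert restored", {
  v <- mock_vector("BTR2", seed = 5)
  fdi <- generate_fdi(1500, 2, internal_overhangs = c("ACGT", "TTAC"),
                      seed = 1)                    # GUSPlus-like
  rx <- plan_reaction(fdi, v)
  expect_identical(rx$program$terminal_hold, c(4, 60))
  prods <- simulate_one_pot(rx)
  desired <- Filter(function(p) p$klass == "desired", prods)
  expect_length(desired, 1)
  d <- desired[[1]]$record
  # full-length insert present with its internal junctions restored
  expect_true(grepl(fdi$seq, paste0(d$seq, d$seq), fixed = TRUE))
  # remaining sites are exactly the insert's internal ones
  expect_identical(nrow(find_sites(d, bsai())), 2L)
  expect_identical(nrow(pbtrkit:::.novel_sites(desired[[1]], bsai())), 0L)
})

test_that("one-pot flags junction collisions as chimeras with a warning", {
  v <- mock_vector("BTR1", seed = 3)
  fdi <- generate_fdi(1000, 1, internal_overhangs = "GATG", seed = 9)
  rx <- suppressWarnings(plan_reaction(fdi, v))
  expect_warning(prods <- simulate_one_pot(rx, max_fragments = 4),
                 "collide")
  klass <- vapply(prods, `[[`, character(1), "klass")
  expect_gt(sum(klass == "chimera"), 0)
  # the brute-force enumeration confirms mis-joined circles exist: more
  # circles than the desired + empty + concatemer classes alone
  expect_true(any(klass == "chimera"))
})

test_that("simulate_one_pot validates its inputs", {
  fdi <- generate_fdi(900, 0, seed = 7)
  expect_error(simulate_one_pot(list()), "reaction_spec")
  uncuttable <- dna_record(strrep("AC", 300), "novec", "circular")
  expect_error(reaction_spec(fdi, fdi), "circular")
  rx <- reaction_spec(uncuttable, list(simulate_pcr(fdi,
    design_primers(fdi, "pK35BTR1"))))
  expect_error(simulate_one_pot(rx), "no BsaI site")
})

test_that("multiplex: k inserts give exactly k single-insert constructs", {
  v <- mock_vector("BTR2", seed = 5)
  fdis <- lapply(1:4, function(i) generate_fdi(600 + 150 * i, 0,
                                               seed = 40 + i))
  rx <- plan_reaction(fdis, v)
  mx <- simulate_multiplex(rx, max_fragments = 4)
  expect_identical(nrow(mx$census), 4L)
  expect_identical(length(unique(mx$census$insert)), 4L)
  # no insert stacking: every desired product holds exactly one insert
  desired <- Filter(function(p) p$klass == "desired", mx$products)
  for (p in desired) {
    srcs <- unique(unlist(lapply(p$composition, function(f)
      vapply(f$prov, `[[`, character(1), "src"))))
    expect_identical(sum(srcs != v$id), 1L)
  }

  # degenerate multiplex: one insert
  mx1 <- simulate_multiplex(plan_reaction(fdis[[1]], v), max_fragments = 2)
  expect_identical(nrow(mx1$census), 1L)

  # zero inserts: backbone stays linearised, no desired product
  rx0 <- reaction_spec(v, list(), program = pbtr_program())
  mx0 <- simulate_multiplex(rx0, max_fragments = 2)
  expect_identical(nrow(mx0$census), 0L)
})

test_that("multiplex rejects mismatched adapter sets", {
  v <- mock_vector("BTR1", seed = 3)
  f1 <- generate_fdi(700, 0, seed = 2)
  f2 <- generate_fdi(800, 0, seed = 3)
  amps <- list(simulate_pcr(f1, design_primers(f1, "pK35BTR1")),
               simulate_pcr(f2, design_primers(f2, "pK35BTR2")))
  rx <- reaction_spec(v, amps, program = pbtr_program())
  expect_error(simulate_multiplex(rx), "mismatched adapter sets")
})

test_that("subclone replays religation-deletion and checks end compatibility", {
  set.seed(77)
  base <- random_dna_str(9000)
  base <- pbtrkit:::.scrub_motifs(base, c("AAGCTT", "TCTAGA", "GAGCTC",
                                          "GTTTAAAC"))
  # HindIII cut positions 268 and 2187, as in the pHSE401 -> pH35Cas9 step
  substr(base, 268, 273) <- "AAGCTT"
  substr(base, 2187, 2192) <- "AAGCTT"
  toy <- dna_record(base, "toy_pHSE401", "circular")
  del <- subclone(toy, NULL, "HindIII", keep = list(vector = "largest"))
  expect_identical(record_length(toy) - record_length(del), 1919L)
  expect_true(is_circular(del))
  # religation restores a cuttable HindIII junction
  expect_identical(nrow(find_sites(del, "HindIII")), 1L)

  # sticky x sticky subcloning with an insert
  sv <- pbtrkit:::.scrub_motifs(random_dna_str(2000),
                                c("TCTAGA", "GAGCTC", "AAGCTT"))
  substr(sv, 101, 106) <- "TCTAGA"
  substr(sv, 301, 306) <- "GAGCTC"
  vec <- dna_record(sv, "vec", "circular")
  ins <- dna_record(paste0(
    pbtrkit:::.scrub_motifs(random_dna_str(50), c("TCTAGA", "GAGCTC")),
    "TCTAGA", strrep("ACT", 100), "GAGCTC", "TTTTT"), "insrc")
  rec <- subclone(vec, ins, c("XbaI", "SacI"),
                  keep = list(vector = "largest", insert = c(250, 350)))
  expect_true(is_circular(rec))
  expect_true(grepl(strrep("ACT", 100), rec$seq, fixed = TRUE))

  # blunt (PmeI) end facing a sticky end: error naming the blunt end
  sv2 <- sv
  substr(sv2, 501, 508) <- "GTTTAAAC"
  vec2 <- dna_record(sv2, "vec2", "circular")
  expect_error(
    subclone(vec2, ins, c("PmeI", "SacI", "XbaI"),
             keep = list(vector = "largest", insert = c(250, 350))),
    "blunt")
})

test_that("reaction config files round-trip through the assembly module", {
  v <- mock_vector("BTR1", seed = 3)
  fdi <- generate_fdi(700, 0, seed = 4)
  rx <- plan_reaction(fdi, v)
  dir <- tempfile("rxcfg")
  path <- write_reaction_config(rx, dir)
  back <- read_reaction_config(path)
  expect_identical(back$vector_record$seq, v$seq)
  expect_identical(back$fdis[[1]]$seq, rx$fdis[[1]]$seq)
  expect_identical(back$program$terminal_hold, rx$program$terminal_hold)
  tab <- product_table(simulate_one_pot(back, max_fragments = 2), bsai())
  expect_identical(sum(tab$klass == "desired"), 1L)
})
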