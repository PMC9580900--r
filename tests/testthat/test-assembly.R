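# The reaction simulators: end algebra, ligation, Golden Gate, Gibson and
# recombinase-mediated joining.

enzdb <- default_db("enzymes")

test_that("end compatibility follows polarity and window sequence", {
  e5 <- function(s) list(polarity = "5p", seq = s, phos = TRUE)
  expect_true(ends_compatible(e5("AATT"), e5("AATT")))
  expect_false(ends_compatible(e5("AATT"), e5("AGCT")))
  expect_true(ends_compatible(list(polarity = "blunt", seq = "", phos = TRUE),
                              list(polarity = "blunt", seq = "", phos = TRUE)))
  expect_false(ends_compatible(e5("AATT"),
                               list(polarity = "3p", seq = "AATT", phos = TRUE)))
})

test_that("end modifications fill in, chew back and dephosphorylate", {
  frs <- digest("TTGAATTCTT", pick_enzymes("EcoRI"))
  f <- frs[[2]] # AATT 5' overhang on the left
  filled <- modify_end(f, "left", "fill_in")
  expect_equal(filled$left_end$polarity, "blunt")
  expect_equal(filled$extent, f$extent) # duplex regains AATT
  expect_error(modify_end(f, "left", "chew_back"), "3'")
  pst <- digest("AACTGCAGAA", pick_enzymes("PstI"))
  chewed <- modify_end(pst[[1]], "right", "chew_back")
  expect_equal(chewed$right_end$polarity, "blunt")
  expect_equal(nchar(pst[[1]]$extent) - nchar(chewed$extent), 4L)
  # a dephosphorylated x dephosphorylated junction cannot ligate
  a <- modify_end(frs[[1]], "right", "dephosphorylate")
  b <- modify_end(frs[[2]], "left", "dephosphorylate")
  expect_false(plasmidkit:::junction_ok(a$right_end, b$left_end))
  expect_true(plasmidkit:::junction_ok(a$right_end, frs[[2]]$left_end))
})

test_that("vector plus insert with matched sticky ends gives one product", {
  set.seed(53)
  both <- pick_enzymes(c("XbaI", "SalI"))
  vec_seq <- plant(plant(rnd_dna(1000), 100, "TCTAGA"), 600, "GTCGAC")
  ins_seq <- plant(plant(rnd_dna(400), 50, "TCTAGA"), 350, "GTCGAC")
  vec <- digest(dna_record(vec_seq, name = "vector", topology = "circular"),
                both)
  ins <- digest(dna_record(ins_seq, name = "insert"), both)
  backbone <- vec[[which.max(fragments_tbl(vec)$size)]]
  middle <- Filter(function(f) f$left_end$seq != f$right_end$seq &&
                     nzchar(f$left_end$seq), ins)[[1]]
  plan <- ligate(list(backbone, middle))
  expect_length(plan$products, 1L)
  prod <- plan$products[[1]]
  expect_equal(prod$topology, "circular")
  expect_equal(seq_length(prod), backbone$size + middle$size)
  # provenance lists every input
  expect_true(grepl("vector", prod$comment) && grepl("insert", prod$comment))
})

test_that("a self-compatible fragment circularises and counts are capped", {
  frs <- digest(dna_record(plant(plant(rnd_dna(300), 50, "GAATTC"),
                                 250, "GAATTC"), topology = "circular"),
                pick_enzymes("EcoRI"))
  small <- frs[[which.min(fragments_tbl(frs)$size)]]
  plan <- ligate(list(small))
  expect_equal(seq_length(plan$products[[1]]), small$size)
  expect_error(ligate(rep(list(small), 4)), "one to three")
  # incompatible ends refuse the reaction
  ecor <- digest("TTGAATTCTT", pick_enzymes("EcoRI"))[[1]]
  hind <- digest("TTAAGCTTAA", pick_enzymes("HindIII"))[[2]]
  expect_error(ligate(list(ecor, hind), allow_reversal = FALSE), "no compatible")
})

test_that("Golden Gate assembly reproduces the declared fixture product", {
  fx <- make_fixture("gg_set", seed = 59)
  plan <- golden_gate_assemble(fx$fragments, fx$enzyme)
  expect_length(plan$products, 1L)
  prod <- plan$products[[1]]
  expect_equal(canonical_rotation(prod$bases),
               canonical_rotation(toupper(fx$product$bases)))
  # no residual recognition sites in the product
  expect_equal(nrow(find_cut_sites(prod, fx$enzyme)), 0L)
  # every input is named in the comment
  for (f in fx$fragments) expect_true(grepl(f$name, prod$comment))
})

test_that("overhang mismatches leave the circle open", {
  fx <- make_fixture("gg_set", seed = 61)
  # corrupt one junction overhang inside the second fragment's left tail
  f2 <- fx$fragments[[2]]
  spacer <- nchar(fx$enzyme$recognition) + 1L
  ov <- substr(f2$bases, spacer + 1L, spacer + 3L)
  flip <- chartr("ACGT", "TGCA", ov)
  substr(f2$bases, spacer + 1L, spacer + 3L) <- flip
  fx$fragments[[2]] <- f2
  expect_error(golden_gate_assemble(fx$fragments, fx$enzyme), "dangling|closed")
})

test_that("five designed fragments assemble uniquely", {
  fx <- make_fixture("gg_set", seed = 67, params = list(n_fragments = 5L,
                                                        span = 200L))
  plan <- golden_gate_assemble(fx$fragments, fx$enzyme)
  expect_length(plan$products, 1L)
  expect_equal(canonical_rotation(plan$products[[1]]$bases),
               canonical_rotation(toupper(fx$product$bases)))
})

test_that("Golden Gate design closes through virtual PCR and assembly", {
  set.seed(71)
  bsa <- pick_enzymes("BsaI")
  recs <- lapply(1:3, function(i) {
    dna_record(plasmidkit:::random_dna_avoiding(500, "GGTCTC"),
               name = sprintf("tpl%d", i))
  })
  frs <- lapply(recs, function(r) list(record = r, start = 50, end = 450))
  des <- golden_gate_design(frs, bsa, seed = 9)
  # hard constraints: no identical, revcomp-identical or palindromic pair
  ov <- des$junctions$overlap_sequence
  rc <- vapply(ov, reverse_complement, character(1))
  expect_equal(anyDuplicated(ov), 0L)
  expect_false(any(ov %in% rc[duplicated(c(ov, rc))]))
  expect_false(any(ov == rc))
  # determinism under the seed
  des2 <- golden_gate_design(frs, bsa, seed = 9)
  expect_identical(des$primers$sequence, des2$primers$sequence)
  # closure: simulate each PCR, then assemble
  amps <- lapply(seq_along(recs), function(i) {
    pr <- des$primers[des$primers$fragment == recs[[i]]$name, ]
    sites <- find_binding_sites(recs[[i]],
                                tibble::tibble(name = pr$name,
                                               sequence = pr$sequence),
                                min_anneal = 15, max_mismatch = 0)
    expect_equal(nrow(sites), 2L)
    simulate_pcr(recs[[i]], sites[sites$strand == "+", ][1, ],
                 sites[sites$strand == "-", ][1, ])
  })
  plan <- golden_gate_assemble(amps, bsa)
  expect_equal(canonical_rotation(plan$products[[1]]$bases),
               canonical_rotation(toupper(des$products[[1]]$bases)))
})

test_that("Gibson overlaps reach the melting threshold and concatenate", {
  fx <- make_fixture("gibson_set", seed = 73)
  frs <- lapply(fx$records, function(r) list(record = r, kind = "pcr_with_tails"))
  plan <- gibson_design(frs, min_overlap_tm = 52)
  expect_true(all(plan$junctions$overlap_tm >= 52))
  expect_equal(plan$products[[1]]$bases,
               paste(vapply(fx$records, `[[`, character(1), "bases"),
                     collapse = ""))
  # non-templated inserted bases enter the product and the adjacent tail
  plan2 <- gibson_design(frs, inserted_bases = c("GGATCCT", "", ""))
  expect_equal(plan2$products[[1]]$bases,
               paste0(fx$records[[1]]$bases, "GGATCCT",
                      fx$records[[2]]$bases, fx$records[[3]]$bases))
  fwd2 <- plan2$primers$sequence[plan2$primers$name == "gib_frag_2_gib_fwd"]
  expect_true(grepl("GGATCCT", fwd2))
})

test_that("tail placement follows fragment kinds and survives simulation", {
  fx <- make_fixture("gibson_set", seed = 79)
  frs <- lapply(fx$records, function(r) list(record = r, kind = "pcr_with_tails"))
  frs[[2]]$kind <- "pcr_no_tails"
  plan <- gibson_design(frs)
  pr <- plan$primers
  # the no-tails fragment's primers have no 5' extension
  expect_equal(pr$sequence[pr$name == "gib_frag_2_gib_fwd"],
               substr(fx$records[[2]]$bases, 1, 20))
  # its upstream partner's reverse primer carries the full overlap
  j1 <- plan$junctions[plan$junctions$junction == 1, ]
  expect_equal(j1$host, "rev")
  rev1 <- pr$sequence[pr$name == "gib_frag_1_gib_rev"]
  expect_true(startsWith(rev1, reverse_complement(j1$overlap_sequence)))
  # simulate both PCRs and confirm the junction overlap is duplicated
  sim <- function(i) {
    p <- pr[pr$fragment == fx$records[[i]]$name, ]
    sites <- find_binding_sites(fx$records[[i]],
                                tibble::tibble(name = p$name,
                                               sequence = p$sequence),
                                min_anneal = 15, max_mismatch = 0)
    simulate_pcr(fx$records[[i]], sites[sites$strand == "+", ][1, ],
                 sites[sites$strand == "-", ][1, ])
  }
  m1 <- sim(1); m2 <- sim(2)
  ovl <- j1$overlap_sequence
  expect_true(endsWith(toupper(m1$bases), toupper(ovl)))
  expect_true(startsWith(toupper(m2$bases), toupper(ovl)))
  # a junction between two non-PCR fragments is refused
  frs2 <- lapply(fx$records, function(r) list(record = r, kind = "pcr_no_tails"))
  expect_error(gibson_design(frs2), "neither neighbor")
})

test_that("recombinase prototypes assemble and invert", {
  protos <- default_db("prototypes")
  sites <- protos$sites
  payload <- strrep("ACGT", 30)
  insert <- dna_record(paste0("TT", sites$attB1$sequence, payload,
                              sites$attB2$sequence, "GG"), name = "ins")
  donor <- dna_record(paste0(sites$attP1$sequence, strrep("CCT", 40),
                             sites$attP2$sequence, strrep("GAT", 50)),
                      name = "donor", topology = "circular")
  entry <- recombinase_assemble("BP(1-2)", list(insert, donor))$products[[1]]
  expect_setequal(entry$features$name, c("attL1", "attL2"))
  expect_true(grepl("ins", entry$comment) && grepl("donor", entry$comment))
  # wrong orientation finds no substrate
  flipped <- dna_record(reverse_complement(insert$bases), name = "flip")
  expect_error(recombinase_assemble("BP(1-2)", list(flipped, donor)),
               "slot")
  # LR on the entry clone regenerates attB-flanked payload
  dest <- dna_record(paste0(sites$attR1$sequence, strrep("TTA", 40),
                            sites$attR2$sequence, strrep("CGA", 45)),
                     name = "dest", topology = "circular")
  expr <- recombinase_assemble("LR(1-2)", list(entry, dest))$products[[1]]
  circ_has <- function(rec, q) nrow(pk_search(rec, q, strand = "top")) > 0
  expect_true(circ_has(expr, payload))
  expect_true(circ_has(expr, sites$attB1$sequence))
  expect_true(circ_has(expr, sites$attB2$sequence))
})
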