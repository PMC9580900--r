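# Site search, digestion, partial digests, the enzyme calculator and
# site-creating mutagenesis.

ecoRI <- pick_enzymes("EcoRI")

test_that("cut coordinates follow the declared offsets", {
  s <- find_cut_sites(dna_record("TTGAATTCTT"), ecoRI)
  expect_equal(nrow(s), 1L)
  expect_equal(s$top_cut, 3L)     # cut after position 3
  expect_equal(s$bottom_cut, 7L)  # cut after position 7
  expect_equal(s$polarity, "5p")
  # 3' overhang cutter
  p <- find_cut_sites(dna_record("AACTGCAGAA"), pick_enzymes("PstI"))
  expect_equal(p$top_cut, 7L)
  expect_equal(p$bottom_cut, 3L)
  expect_equal(p$polarity, "3p")
})

test_that("non-palindromic recognitions are found on both strands", {
  sap <- pick_enzymes("SapI")
  fwd <- paste0(strrep("T", 20), "GCTCTTC", strrep("T", 20))
  rev <- paste0(strrep("T", 20), reverse_complement("GCTCTTC"), strrep("T", 20))
  expect_equal(find_cut_sites(dna_record(fwd), sap)$strand, "+")
  expect_equal(find_cut_sites(dna_record(rev), sap)$strand, "-")
})

test_that("methylation rules suppress sites only when the flag is on", {
  mbo <- pick_enzymes("MboI")
  expect_equal(nrow(find_cut_sites(dna_record("AAGATCAA"), mbo, dam = TRUE)), 0L)
  expect_equal(nrow(find_cut_sites(dna_record("AAGATCAA"), mbo, dam = FALSE)), 1L)
  # XbaI is blocked only when a GATC overlaps its site
  xba <- pick_enzymes("XbaI")
  blocked <- dna_record("AATCTAGATCAA")   # TCTAGA followed by TC -> GATC
  clear <- dna_record("AATCTAGAGGAA")
  expect_equal(nrow(find_cut_sites(blocked, xba, dam = TRUE)), 0L)
  expect_equal(nrow(find_cut_sites(blocked, xba, dam = FALSE)), 1L)
  expect_equal(nrow(find_cut_sites(clear, xba, dam = TRUE)), 1L)
})

test_that("hexamer-indexed search equals the naive sliding-window oracle", {
  set.seed(41)
  for (i in 1:8) {
    s <- rnd_dna(3000)
    for (j in seq_len(nrow(default_enzymes))) {
      pat <- default_enzymes$recognition[j]
      expect_identical(plasmidkit:::hexamer_search(s, pat),
                       naive_iupac_scan(s, pat), label = pat)
    }
  }
})

test_that("digestion yields typed fragments that conserve length", {
  frs <- digest("TTGAATTCTT", ecoRI)
  expect_length(frs, 2L)
  expect_equal(frs[[1]]$extent, "TTGAATT")
  expect_equal(frs[[1]]$size, 3)
  expect_equal(frs[[1]]$right_end,
               list(polarity = "5p", seq = "AATT", phos = TRUE))
  expect_equal(frs[[2]]$extent, "AATTCTT")
  expect_equal(frs[[2]]$left_end$seq, "AATT")
  expect_equal(sum(fragments_tbl(frs)$size), 10)
  # circular record, two cuts -> two fragments summing to length
  circ <- dna_record(plant(plant(strrep("A", 100), 10, "GAATTC"),
                           60, "GAATTC"), topology = "circular")
  f2 <- digest(circ, ecoRI)
  expect_length(f2, 2L)
  expect_equal(sum(fragments_tbl(f2)$size), 100)
  # uncut circular is an explicit condition
  expect_error(digest(dna_record(strrep("ACT", 40), topology = "circular"),
                      ecoRI), class = "pk_uncut_error")
})

test_that("type IIS sites too close to a linear end are flagged uncuttable", {
  sap <- pick_enzymes("SapI")
  near_end <- dna_record(paste0("GCTCTTC", "AA")) # cuts would fall off
  s <- find_cut_sites(near_end, sap)
  expect_equal(nrow(s), 1L)
  expect_false(s$cuttable)
  expect_length(digest(near_end, sap), 1L) # treated as uncut
})

test_that("digest-then-religate regenerates the parent up to rotation", {
  set.seed(43)
  enzset <- pick_enzymes(c("EcoRI", "PstI"))
  done <- 0L
  while (done < 8L) {
    rec <- dna_record(rnd_dna(600), topology = "circular")
    frs <- tryCatch(digest(rec, enzset), pk_uncut_error = function(e) NULL)
    if (is.null(frs) || length(frs) > 3L) next
    done <- done + 1L
    plan <- ligate(frs, allow_reversal = FALSE)
    expect_true(any(vapply(plan$products, function(p) {
      canonical_rotation(p$bases) == canonical_rotation(toupper(rec$bases))
    }, logical(1))))
  }
})

test_that("partial digest enumerates species with exact arithmetic", {
  one_site <- dna_record(plant(strrep("A", 100), 38, "GAATTC"))
  pd <- partial_digest(one_site, ecoRI, 0.5)
  expect_equal(pd$size, c(100, 62, 38))
  expect_equal(pd$mass_percent, c(50, 31, 19))
  # p = 1 reduces to the full digest
  pd1 <- partial_digest(one_site, ecoRI, 1)
  expect_equal(sort(pd1$size), sort(fragments_tbl(digest(one_site, ecoRI))$size))
  # p = 0 leaves one full-length band at 100%
  pd0 <- partial_digest(one_site, ecoRI, 0)
  expect_equal(pd0$size, 100)
  expect_equal(pd0$mass_percent, 100)
  # molar abundances over species sum to 1 before aggregation
  multi <- dna_record(plant(plant(plant(strrep("C", 300), 50, "GAATTC"),
                                  150, "GAATTC"), 250, "GAATTC"))
  pdm <- partial_digest(multi, ecoRI, 0.3)
  expect_equal(sum(pdm$mass_percent), 100, tolerance = 1e-9)
  # each species contributes (cuts+1) fragments; total moles per species = 1
  expect_error(partial_digest(dna_record(strrep("GAATTC", 20)), ecoRI, 0.5,
                              cap = 10), "cap")
})

test_that("the enzyme calculator applies select, deselect and AND", {
  rec <- dna_record(paste0("TT", "GAATTC", "TT", "GAATTC", "TT", "AAGCTT", "TT"))
  counts <- count_sites(rec, default_enzymes)
  uniq <- enzyme_calculator(counts, 1, group = "common", op = "select")
  expect_identical(uniq, "HindIII")
  both <- enzyme_calculator(counts, c(1, 2), group = "common",
                            current = uniq, op = "select")
  expect_setequal(both, c("EcoRI", "HindIII"))
  # AND of disjoint sets is empty
  expect_length(enzyme_calculator(counts, 1, group = "common",
                                  current = "EcoRI", op = "and"), 0L)
  # deselect removes exactly the filtered members
  expect_identical(enzyme_calculator(counts, 1, group = "common",
                                     current = both, op = "deselect"),
                   "EcoRI")
})

test_that("silent-site proposals preserve the translation", {
  pm <- propose_site_mutations("GAATTT", ecoRI, mode = "silent")
  expect_equal(nrow(pm), 1L)
  expect_equal(pm$edits[[1]], "T6>C")
  # the edit really is synonymous
  expect_equal(as.character(translate_dna("GAATTC")),
               as.character(translate_dna("GAATTT")))
  expect_error(propose_site_mutations("GAATT", ecoRI, mode = "silent"),
               "divisible")
  # existing sites are excluded even at zero allowed changes
  expect_equal(nrow(propose_site_mutations("GAAATT", ecoRI,
                                           mode = "diagnostic",
                                           max_changes = 0)), 0L)
})

test_that("diagnostic proposals equal a brute-force edit enumeration", {
  set.seed(47)
  enzset <- pick_enzymes(c("EcoRI", "HindIII", "EcoRV"))
  for (rep in 1:6) {
    s <- rnd_dna(24)
    got <- propose_site_mutations(s, enzset, mode = "diagnostic",
                                  max_changes = 1)
    got_keys <- sort(paste(got$enzyme, got$position, got$strand))
    # oracle: try every single-base edit and record every *new* site
    keys <- character(0)
    for (pos in 1:24) for (b in c("A", "C", "G", "T")) {
      if (substr(s, pos, pos) == b) next
      mut <- s
      substr(mut, pos, pos) <- b
      for (j in seq_len(nrow(enzset))) {
        pat <- enzset$recognition[j]
        before <- naive_iupac_scan(s, pat)
        after <- naive_iupac_scan(mut, pat)
        for (q in setdiff(after, before)) {
          # the edit must fall inside the new site
          if (pos >= q && pos <= q + nchar(pat) - 1L) {
            keys <- c(keys, paste(enzset$name[j], q, "+"))
          }
        }
      }
    }
    expect_identical(got_keys, sort(unique(keys)))
  }
})
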