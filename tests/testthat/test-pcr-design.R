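# Primer binding-site search, PCR simulation, de-novo primer scanning and
# dCAPS design.

enzdb <- default_db("enzymes")

test_that("binding sites anchor at the 3' end and respect thresholds", {
  set.seed(83)
  tpl <- dna_record(rnd_dna(1500), name = "tpl")
  p20 <- substr(tpl$bases, 301, 320)
  tailed <- paste0("GCGCGCGC", p20)
  mm_seq <- p20
  substr(mm_seq, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                    substr(mm_seq, 20, 20))[1]
  primers <- tibble::tibble(name = c("exact", "tailed", "mm3p"),
                            sequence = c(p20, tailed, mm_seq))
  bs <- find_binding_sites(tpl, primers, min_anneal = 12, max_mismatch = 1,
                           max_3prime_mismatch = 0)
  ex <- bs[bs$primer == "exact", ]
  expect_equal(ex$three_prime_position, 320L)
  expect_equal(ex$match_count, 20L)
  expect_equal(ex$mismatch_count, 0L)
  # the 5' tail is excluded: matched-region Tm differs from full-primer Tm
  tl <- bs[bs$primer == "tailed", ]
  expect_equal(tl$three_prime_position, 320L)
  expect_gt(tl$tm_full_primer, tl$tm_matched_region)
  # a terminal mismatch is rejected at 0 allowed, reported at 1
  expect_false("mm3p" %in% bs$primer)
  bs2 <- find_binding_sites(tpl, primers, min_anneal = 12, max_mismatch = 1,
                            max_3prime_mismatch = 1)
  expect_true("mm3p" %in% bs2$primer)
  expect_error(find_binding_sites(tpl, primers, max_mismatch = 11), "ten")
})

test_that("unique_only keeps single-site primers", {
  tpl <- dna_record(paste0(strrep("T", 30), "ACGTACGTACGTACG",
                           strrep("C", 30), "ACGTACGTACGTACG",
                           strrep("G", 30)))
  primers <- tibble::tibble(name = c("dup", "uni"),
                            sequence = c("ACGTACGTACGTACG",
                                         paste0(strrep("T", 8), "ACGTACG")))
  all_sites <- find_binding_sites(tpl, primers, min_anneal = 8,
                                  max_mismatch = 0)
  expect_gt(sum(all_sites$primer == "dup"), 1L)
  uni <- find_binding_sites(tpl, primers, min_anneal = 8, max_mismatch = 0,
                            unique_only = TRUE)
  expect_false("dup" %in% uni$primer)
})

test_that("binding-site search equals an exhaustive anchored scan", {
  set.seed(89)
  for (i in 1:30) {
    tpl <- rnd_dna(200)
    # half the cases: a planted primer with sprinkled mismatches
    primer <- if (i %% 2 == 0) {
      p <- substr(tpl, 80, 99)
      for (k in sample(1:19, sample(0:2, 1))) {
        substr(p, k, k) <- sample(c("A", "C", "G", "T"), 1)
      }
      p
    } else {
      rnd_dna(15)
    }
    got <- find_binding_sites(dna_record(tpl),
                              tibble::tibble(name = "p", sequence = primer),
                              min_anneal = 8, max_mismatch = 2,
                              max_3prime_mismatch = 1)
    expect_identical(binding_keys(got),
                     naive_binding_sites(tpl, primer, 8, 2, 1))
  }
})

test_that("PCR products splice primers, tails and template spans", {
  set.seed(97)
  tpl <- dna_record(rnd_dna(3000), name = "tpl", topology = "circular")
  fwd_seq <- substr(tpl$bases, 501, 520)
  rev_seq <- reverse_complement(substr(tpl$bases, 901, 920))
  sites <- find_binding_sites(tpl, tibble::tibble(name = c("f", "r"),
                                                  sequence = c(fwd_seq, rev_seq)),
                              min_anneal = 12, max_mismatch = 0)
  fwd <- sites[sites$strand == "+", ][1, ]; rev <- sites[sites$strand == "-", ][1, ]
  prod <- simulate_pcr(tpl, fwd, rev)
  expect_equal(seq_length(prod), 920L - 501L + 1L)
  expect_equal(toupper(prod$bases), toupper(substr(tpl$bases, 501, 920)))
  # 10-nt tails on both primers add 20 bases
  t10 <- strrep("A", 10)
  sites2 <- find_binding_sites(tpl, tibble::tibble(
    name = c("f", "r"), sequence = c(paste0(t10, fwd_seq), paste0(t10, rev_seq))),
    min_anneal = 12, max_mismatch = 0)
  prod2 <- simulate_pcr(tpl, sites2[sites2$strand == "+", ][1, ],
                        sites2[sites2$strand == "-", ][1, ])
  expect_equal(seq_length(prod2), 420L + 20L)
  # product carries primer features and provenance
  expect_equal(prod$features$type, c("primer_bind", "primer_bind"))
  expect_true(grepl("tpl", prod$comment))
  # geometry errors
  expect_error(simulate_pcr(tpl, fwd, fwd), "opposite")
})

test_that("amplifying across a circular origin equals rotate-then-amplify", {
  set.seed(101)
  tpl <- dna_record(rnd_dna(3000), name = "tpl", topology = "circular")
  fwd_seq <- substr(tpl$bases, 2901, 2920)
  rev_seq <- reverse_complement(substr(tpl$bases, 101, 120))
  pr <- tibble::tibble(name = c("f", "r"), sequence = c(fwd_seq, rev_seq))
  s1 <- find_binding_sites(tpl, pr, min_anneal = 12, max_mismatch = 0)
  p1 <- simulate_pcr(tpl, s1[s1$strand == "+", ][1, ], s1[s1$strand == "-", ][1, ])
  rot <- rotate_origin(tpl, 2501)
  s2 <- find_binding_sites(rot, pr, min_anneal = 12, max_mismatch = 0)
  p2 <- simulate_pcr(rot, s2[s2$strand == "+", ][1, ], s2[s2$strand == "-", ][1, ])
  expect_equal(p1$bases, p2$bases)
})

test_that("a simulated product re-annotates with its own primers", {
  set.seed(103)
  tpl <- dna_record(rnd_dna(800), name = "tpl")
  fwd_seq <- substr(tpl$bases, 101, 120)
  rev_seq <- reverse_complement(substr(tpl$bases, 401, 420))
  sites <- find_binding_sites(tpl, tibble::tibble(name = c("f", "r"),
                                                  sequence = c(fwd_seq, rev_seq)),
                              min_anneal = 12, max_mismatch = 0)
  prod <- simulate_pcr(tpl, sites[sites$strand == "+", ][1, ],
                       sites[sites$strand == "-", ][1, ])
  lib <- load_feature_library(text = c(
    sprintf("fwd\t%s\t#ff0000\tprimer_bind\tboth", fwd_seq),
    sprintf("rev\t%s\t#0000ff\tprimer_bind\tboth", rev_seq)))
  ann <- scan_with_library(dna_record(prod$bases), lib)
  expect_setequal(ann$features$name, c("fwd", "rev"))
  expect_equal(unname(ann$features$segments[[1]][1, ]), c(1L, 20L))
})

test_that("candidate primers satisfy every bound and screen hairpins", {
  set.seed(107)
  for (i in 1:5) {
    sel <- rnd_dna(150)
    cand <- suppressWarnings(
      find_candidate_primers(sel, len_min = 18, len_max = 24,
                             tm_min = 48, tm_max = 62, gc_min = 35,
                             gc_max = 65, gc_clamp = 1))
    if (nrow(cand) == 0) next
    expect_true(all(cand$length >= 18 & cand$length <= 24))
    expect_true(all(cand$tm >= 48 & cand$tm <= 62))
    expect_true(all(cand$gc_percent >= 35 & cand$gc_percent <= 65))
    expect_true(all(substr(cand$sequence, cand$length, cand$length) %in%
                    c("G", "C")))
  }
  # poly-A selection with a GC floor is infeasible
  expect_warning(empty <- find_candidate_primers(strrep("A", 80), gc_min = 40),
                 "")
  expect_equal(nrow(empty), 0L)
  # a built-in 8-mer 3' hairpin seed is excluded at default thresholds
  stem <- "GCCGGCGC"
  sel <- paste0("ATTATCATCATTA", stem, "TTTT", reverse_complement(stem))
  cand <- suppressWarnings(
    find_candidate_primers(sel, len_min = nchar(sel), len_max = nchar(sel),
                           tm_min = 0, tm_max = 100, gc_min = 0, gc_max = 100,
                           gc_clamp = 0))
  expect_equal(nrow(cand), 0L)
  # brute-force complementary-run oracle agrees on the screen statistic
  run <- plasmidkit:::longest_comp_run(sel, sel)
  expect_gte(run, 8L)
})

test_that("the worked dCAPS scenario yields 250 -> 200 + 50", {
  fx <- make_fixture("dcaps_case", seed = 109)
  des <- design_dcaps(fx$template, fx$snp_position, fx$ref_base, fx$alt_base,
                      pick_enzymes(fx$enzyme), max_primer_edits = 1,
                      amplicon_length_target = fx$amplicon_length_target,
                      primer_len = fx$primer_len)
  row <- des[des$strand == "+" & des$n_edits == 1, ][1, ]
  expect_equal(row$cut_allele, "alt")
  expect_equal(sort(unlist(row$bands_alt)), c(50, 200))
  expect_equal(unlist(row$bands_ref), 250)
  # cut-allele bands always sum to the uncut amplicon length
  for (k in seq_len(nrow(des))) {
    expect_equal(sum(unlist(des$bands_alt[k])), des$amplicon_length[k])
    expect_equal(sum(unlist(des$bands_ref[k])), des$amplicon_length[k])
  }
})

test_that("dCAPS designs survive an independent PCR + digest round trip", {
  set.seed(113)
  enz6 <- pick_enzymes(c("EcoRI", "HindIII", "BamHI", "SalI", "EcoRV", "XhoI"))
  checked <- 0L
  for (case in 1:40) {
    e <- enz6[sample.int(nrow(enz6), 1), ]
    recog <- strsplit(e$recognition, "")[[1]]
    m <- length(recog)
    tpl <- plasmidkit:::random_dna_avoiding(600, e$recognition)
    snp <- 300L
    i_snp <- sample(2:m, 1)       # SNP inside the site, not at its start
    q <- snp - i_snp + 1L
    edit_at <- q + sample.int(i_snp - 1L, 1) - 1L # a primer-covered slot
    dist <- snp - 1L - edit_at
    if (dist < 1L || dist > 5L) next
    site <- recog
    tch <- strsplit(tpl, "")[[1]]
    # template matches the site except at the edit slot and the SNP
    for (j in seq_len(m)) tch[q + j - 1L] <- site[j]
    tch[edit_at] <- setdiff(c("A", "C", "G", "T"), site[edit_at - q + 1L])[1]
    ref <- setdiff(c("A", "C", "G", "T"), site[i_snp])[1]
    alt <- site[i_snp]
    tch[snp] <- ref
    tpl <- paste(tch, collapse = "")
    if (length(naive_iupac_scan(tpl, e$recognition)) > 0) next
    des <- design_dcaps(tpl, snp, ref, alt, e, max_primer_edits = 2,
                        amplicon_length_target = 220L)
    if (nrow(des) == 0) next
    checked <- checked + 1L
    row <- des[des$strand == "+", ][1, ]
    if (is.na(row$enzyme)) row <- des[1, ]
    # independent route: bind the designed primers on each allele template
    for (allele in c("ref", "alt")) {
      base <- if (allele == "ref") ref else alt
      at <- tpl
      substr(at, snp, snp) <- base
      arec <- dna_record(at, name = allele)
      pr <- tibble::tibble(name = c("geno", "far"),
                           sequence = c(row$primer, row$far_primer))
      sites <- find_binding_sites(arec, pr, min_anneal = 10,
                                  max_mismatch = 3, max_3prime_mismatch = 2)
      fw <- sites[sites$primer == "geno" & sites$strand == "+", ]
      rv <- sites[sites$primer == "far" & sites$strand == "-", ]
      expect_gte(nrow(fw), 1L)
      expect_gte(nrow(rv), 1L)
      amp <- simulate_pcr(arec, fw[which.max(fw$match_count), ], rv[1, ])
      frs <- digest(amp, e)
      got <- sort(fragments_tbl(frs)$size)
      want <- sort(unlist(if (allele == "ref") row$bands_ref else row$bands_alt))
      expect_equal(got, want)
      cut <- length(frs) > 1L
      expect_equal(cut, row$cut_allele == allele)
    }
  }
  expect_gte(checked, 10L)
})
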