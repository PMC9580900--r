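# Text/SVG renderings, palette generator, molar calculator, repeat
# insertion, fixtures and the command-line dispatcher.

enzdb <- default_db("enzymes")

test_that("the text map aligns tracks under 60-base lines", {
  rec <- dna_record(plant(rnd_dna(150), 30, "GAATTC"), name = "tm")
  rec <- add_feature(rec, "blockA", 10, 25)
  out <- text_map(rec, tracks = c("index", "features", "enzymes",
                                  "bottom_strand"),
                  enzymes = pick_enzymes("EcoRI"))
  # index labels each line start with its 1-based position
  idx <- grep("^\\s*\\d+  ", out)
  starts <- as.integer(sub("^\\s*(\\d+).*", "\\1", out[idx]))
  expect_equal(starts, c(1L, 61L, 121L))
  # bottom strand is the base-wise complement, not reversed
  top_line <- sub("^\\s*1  ", "", out[idx[1]])
  bottom <- out[idx[1] + 1L]
  expect_equal(trimws(bottom), complement_bases(top_line))
  # enzyme name sits above its recognition start column
  enz_line <- out[grep("EcoRI", out)]
  col <- as.integer(regexpr("EcoRI", enz_line))
  expect_equal(col - 10L, 30L) # 10-character gutter
  # feature bar covers the feature span
  bar <- out[grep("blockA", out)]
  expect_equal(as.integer(regexpr("=+", bar)) - 10L, 10L)
})

test_that("the ORF map marks starts, stops and qualifying regions", {
  om <- orf_map_text("ATGTAA", min_region = 3)
  expect_equal(length(om), 6L)
  plus1 <- sub("^\\+1 ", "", om[1])
  expect_equal(substr(plus1, 1, 1), "M")
  expect_equal(substr(plus1, 4, 4), "*")
  expect_equal(stop_codon_class("TAG"), "amber")
  expect_equal(stop_codon_class("TAA"), "ochre")
  expect_equal(stop_codon_class("TGA"), "opal")
  # highlighted regions equal a brute-force six-frame enumeration
  set.seed(157)
  s <- rnd_dna(900)
  regions <- attr(orf_map_text(s, min_region = 90), "regions")
  table <- plasmidkit:::GENETIC_CODES[["1"]]
  stops <- names(table)[table == "*"]
  expected <- 0L
  for (fr in c(1, 2, 3, -1, -2, -3)) {
    seq <- if (fr > 0) s else reverse_complement(s)
    off <- abs(fr) - 1L
    n_codon <- (nchar(seq) - off) %/% 3L
    codons <- substring(seq, off + 3 * seq_len(n_codon) - 2,
                        off + 3 * seq_len(n_codon))
    bounds <- c(0L, which(codons %in% stops), n_codon + 1L)
    lens <- diff(bounds) - 1L
    expected <- expected + sum(lens * 3L >= 90L)
  }
  expect_equal(nrow(regions), expected)
})

test_that("SVG output is well-formed and spans are data-linked", {
  rec <- make_fixture("plasmid", seed = 8)$record
  svg <- render_svg(rec, enzymes = pick_enzymes("EcoRI"))
  doc <- xml2::read_xml(paste(svg, collapse = "\n"))
  feats <- xml2::xml_find_all(doc, "//*[@class='feature']")
  expect_equal(length(feats), nrow(rec$features))
  spans <- xml2::xml_attr(feats, "data-span")
  expect_true(all(grepl("^\\d+\\.\\.\\d+$", spans)))
  # linear map of the same record
  lin <- render_svg(dna_record(rec$bases, features = rec$features))
  expect_silent(xml2::read_xml(paste(lin, collapse = "\n")))
  # gel rendering: lane groups and band order follow migration
  gel <- gel_lanes(list(ladder = "ladder", cut = c(3000, 1200, 500)),
                   default_db("ladders")[default_db("ladders")$name == "1kb", ])
  gsvg <- render_svg(gel)
  gdoc <- xml2::read_xml(paste(gsvg, collapse = "\n"))
  lanes <- xml2::xml_find_all(gdoc, "//*[@class='lane']")
  expect_equal(length(lanes), 2L)
  bands <- xml2::xml_find_all(lanes[[2]], ".//*[@class='band']")
  ys <- as.numeric(xml2::xml_attr(bands, "y"))
  sizes <- as.numeric(xml2::xml_attr(bands, "data-size"))
  expect_true(all(diff(ys[order(-sizes)]) > 0))
})

test_that("gel lanes conserve mass, order migration and merge doublets", {
  ladder <- default_db("ladders")[default_db("ladders")$name == "1kb", ]
  gel <- gel_lanes(list(ladder = "ladder", x = c(4000, 2000, 1990, 300)),
                   ladder)
  x <- gel[gel$lane == "x", ]
  expect_equal(sum(x$mass_percent), 100, tolerance = 1e-9)
  expect_true(all(diff(x$migration[order(-x$size)]) > 0))
  # 2000 and 1990 differ by 0.5% -> one doublet band
  expect_equal(nrow(x), 3L)
  expect_true(any(x$doublet))
  # the ladder lane reproduces its own sizes in order
  lad <- gel[gel$lane == "ladder", ]
  expect_equal(sort(lad$size, decreasing = TRUE), sort(ladder$bands[[1]]$size,
                                                       decreasing = TRUE))
  # identical lanes migrate identically
  g2 <- gel_lanes(list(a = c(1000, 500), b = c(1000, 500)), ladder)
  expect_equal(g2$migration[g2$lane == "a"], g2$migration[g2$lane == "b"])
  expect_gt(g2$migration[g2$size == 500][1], g2$migration[g2$size == 1000][1])
})

test_that("palette hues are evenly spaced and readable on black and white", {
  pal <- generate_palette(4, seed = 1)
  expect_equal(pal$hue, c(0, 90, 180, 270))
  for (n in c(1, 3, 8)) {
    for (seed in 1:10) {
      p <- generate_palette(n, seed = seed)
      rgb <- grDevices::col2rgb(p$hex) / 255
      for (k in seq_len(n)) {
        expect_gt(contrast_ratio(rgb[, k], c(0, 0, 0)), 3)
        expect_gt(contrast_ratio(rgb[, k], c(1, 1, 1)), 3)
      }
    }
  }
  expect_identical(generate_palette(6, seed = 33), generate_palette(6, seed = 33))
})

test_that("molar-ratio volumes follow the 650 Da/bp arithmetic", {
  parts <- tibble::tibble(name = c("vector", "insert"),
                          length_bp = c(1000, 1000),
                          conc_ng_ul = c(65, 65), ratio = c(1, 3))
  v <- molar_ratio_volumes(parts, total_pmol = 0.4)
  expect_equal(v$pmol_per_ul[1], 0.1, tolerance = 1e-9)
  expect_equal(v$volume_ul[2] / v$volume_ul[1], 3, tolerance = 1e-9)
  same <- molar_ratio_volumes(tibble::tibble(
    name = c("a", "b"), length_bp = c(2000, 2000),
    conc_ng_ul = c(40, 40), ratio = c(1, 1)), total_pmol = 0.2)
  expect_equal(same$volume_ul[1], same$volume_ul[2])
  ref <- molar_ratio_volumes(parts, reference = list(name = "vector",
                                                     volume_ul = 2))
  expect_equal(ref$volume_ul[1], 2)
  expect_equal(ref$volume_ul[2], 6)
  expect_error(molar_ratio_volumes(tibble::tibble(
    name = "x", length_bp = 100, conc_ng_ul = 0, ratio = 1),
    total_pmol = 1), "concentration")
})

test_that("repeat insertion shifts and stretches features", {
  rec <- dna_record("ACGTACGTACGT")
  rec <- add_feature(rec, "before", 2, 4)
  rec <- add_feature(rec, "spanning", 3, 8)
  out <- insert_repeat(rec, 5, "AT", 3)
  expect_equal(seq_length(out), 18L)
  expect_equal(unname(out$features$segments[[1]][1, ]), c(2L, 4L))
  expect_equal(unname(out$features$segments[[2]][1, ]), c(3L, 14L))
  expect_error(insert_repeat(rec, 99, "AT", 1), "position")
})

test_that("fixtures are deterministic and carry their planted structure", {
  a <- make_fixture("plasmid", seed = 5)
  b <- make_fixture("plasmid", seed = 5)
  expect_identical(a$record$bases, b$record$bases)
  expect_equal(nrow(find_cut_sites(a$record, pick_enzymes("EcoRI"))), 1L)
  expect_equal(nrow(find_cut_sites(a$record, pick_enzymes("HindIII"))), 2L)
  gg <- make_fixture("gg_set", seed = 5)
  expect_identical(gg$product$bases, make_fixture("gg_set", seed = 5)$product$bases)
})

test_that("the CLI drives the package end to end", {
  dir <- withr::local_tempdir()
  gb <- file.path(dir, "p.gb")
  write_genbank(make_fixture("plasmid", seed = 3)$record, path = gb)
  st <- capture.output(res <- pk_cli_main(c("stats", gb)))
  expect_equal(res$length, 3000L)
  expect_true(any(grepl("gc_percent", st)))
  dg <- capture.output(tbl <- pk_cli_main(c("digest", "--enzymes",
                                            "EcoRI,HindIII", gb)))
  expect_equal(sum(tbl$size), 3000)
  conv <- capture.output(pk_cli_main(c("convert", "--strip-apeinfo", gb)))
  expect_false(any(grepl("ApEinfo", conv)))
  ann <- capture.output(pk_cli_main(c("annotate", gb)))
  expect_true(any(grepl("T7 promoter", ann)))
  pal <- capture.output(p <- pk_cli_main(c("palette", "--n", "5", "--seed", "2")))
  expect_equal(nrow(p), 5L)
  so <- capture.output(hits <- pk_cli_main(c("search", "--query", "GAATTC", gb)))
  expect_equal(nrow(hits[hits$strand == "+", ]), 1L)
  orfs <- capture.output(o <- pk_cli_main(c("orfs", "--min-codons", "15", gb)))
  expect_true(nrow(o) >= 0L)
  svg <- file.path(dir, "map.svg")
  capture.output(pk_cli_main(c("map", "--svg", svg, "--enzymes", "EcoRI", gb)))
  expect_silent(xml2::read_xml(svg))
  expect_error(pk_cli_main(c("digest", "--enzymes", "NoSuch", gb)), "unknown")
})

test_that("record tidiers and plots cover the result types", {
  rec <- make_fixture("plasmid", seed = 10)$record
  td <- tidy(rec)
  expect_equal(nrow(td), 2L)
  g <- glance(rec)
  expect_equal(g$length, 3000L)
  p1 <- ggplot2::autoplot(rec)
  expect_s3_class(p1, "ggplot")
  gel <- gel_lanes(list(a = c(2000, 700)), default_db("ladders")[2, ])
  p2 <- ggplot2::autoplot(gel)
  expect_s3_class(p2, "ggplot")
})
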