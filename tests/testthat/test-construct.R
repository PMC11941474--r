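random_spacer <- function(n = 34) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("the toy kit satisfies the kit invariants", {
  kit <- toy_kit()
  expect_s3_class(kit, "cloning_kit")
  expect_false(identical(kit$repeat1, kit$repeat2))
  expect_equal(kit$spacer_len, 34)
  expect_error(cloning_kit("AAAA", "AAAA", "CCCC", "GGGG"),
               class = "cas3design_error_identical_repeats")
  # a backbone missing a feature is rejected
  expect_error(cloning_kit("AAAA", "TTTT", "CCCC", "GGGG",
                           backbone = "AAAATTTTCCCC"),
               class = "cas3design_error_bad_kit")
})

test_that("kit JSON round-trips through read_kit/write_kit", {
  kit <- toy_kit()
  f <- withr::local_tempfile(fileext = ".json")
  write_kit(kit, f)
  back <- read_kit(f)
  expect_equal(unclass(back), unclass(kit))
  shipped <- system.file("extdata", "toy_kit.json", package = "cas3design")
  expect_equal(unclass(read_kit(shipped)), unclass(kit))
})

test_that("spacer primers carry the spacer in their overhangs", {
  kit <- toy_kit()
  spacer <- paste(rep(c("A", "C", "G", "T"), length.out = 34), collapse = "")
  ps <- design_spacer_primers(spacer, kit)
  primers <- generics::tidy(ps)
  expect_setequal(primers$name,
                  c("fixed_fwd", "fixed_rev", "spacer_fwd", "spacer_rev"))
  expect_true(grepl(spacer, primers$seq[primers$name == "spacer_fwd"],
                    fixed = TRUE))
  expect_true(grepl(revcomp(spacer), primers$seq[primers$name == "spacer_rev"],
                    fixed = TRUE))
  # determinism
  expect_identical(ps, design_spacer_primers(spacer, kit))
  # wrong length and ambiguity are rejected
  expect_error(design_spacer_primers("ACGT", kit),
               class = "cas3design_error_bad_spacer_length")
  expect_error(design_spacer_primers(paste(rep("N", 34), collapse = ""), kit),
               class = "cas3design_error")
})

test_that("a destination-enzyme site inside the spacer is flagged, not fatal", {
  kit <- toy_kit()
  spacer <- paste0("TTCGAA", paste(rep("A", 28), collapse = ""))
  expect_warning(ps <- design_spacer_primers(spacer, kit),
                 "destination-enzyme")
  expect_true(ps$destination_site_in_spacer)
})

test_that("digestion cuts at recognition-site starts around the circle", {
  d <- digest_circular("AAACATATGCCCTTCGAAGGG",
                       c(NdeI = "CATATG", BstBI = "TTCGAA"))
  expect_equal(nrow(d), 2)
  expect_equal(d$cut_offset, c(3L, 12L))
  expect_equal(d$seq, c("CATATGCCC", "TTCGAAGGGAAA"))
  expect_equal(sum(nchar(d$seq)), nchar("AAACATATGCCCTTCGAAGGG"))

  single <- digest_circular("AAACATATGCCC", c(NdeI = "CATATG"))
  expect_equal(nrow(single), 1)
  expect_equal(nchar(single$seq), 12)
  expect_error(digest_circular("AAAATTTT", c(NdeI = "CATATG")),
               class = "cas3design_error_enzyme_no_site")
})

test_that("digestion sees recognition sites on both strands", {
  # GAATTC (EcoRI) is palindromic; use an asymmetric site to test strands:
  # GGTCTC occurs only as its reverse complement GAGACC in this circle
  d <- digest_circular("AAAAGAGACCTTTT", c(BsaI = "GGTCTC"))
  expect_equal(d$cut_offset, 4L)
})

test_that("simulate_gibson merges at terminal overlaps and circularizes", {
  out <- simulate_gibson(c("AAAACCCCGGGG", "GGGGTTTTAAAA"), min_overlap = 4)
  expect_equal(out, canonical_rotation("AAAACCCCGGGGTTTT"))
  expect_equal(nchar(out), 16)
  # no shared terminus in either orientation
  expect_error(simulate_gibson(c("AAAACCCC", "GGGGAAGG"), min_overlap = 4),
               class = "cas3design_error_no_assembly")
})

test_that("assembly is orientation-agnostic for double-stranded fragments", {
  frags <- c("AAAACCCCGGGG", "GGGGTTTTAAAA")
  flipped <- c(frags[1], revcomp(frags[2]))
  expect_equal(simulate_gibson(flipped, min_overlap = 4),
               simulate_gibson(frags, min_overlap = 4))
})

test_that("the full cloning round trip reconstructs the spacer plasmid", {
  kit <- toy_kit()
  dg <- digest_circular(kit$backbone, kit$enzymes[kit$destination_enzymes])
  backbone_kept <- dg$seq[!grepl(kit$repeat1, dg$seq, fixed = TRUE)]
  set.seed(55)
  for (rep in 1:25) {
    spacer <- random_spacer()
    ps <- suppressWarnings(design_spacer_primers(spacer, kit))
    asm <- simulate_gibson(c(ps$fragment_A, ps$fragment_B), backbone_kept,
                           kit$min_overlap)
    expect_equal(asm, oracle_spacer_plasmid(kit, spacer))
    expect_equal(circ_count_test(paste0(kit$repeat1, spacer, kit$repeat2),
                                 asm), 1L)
  }
})

test_that("repair template arithmetic: arms, junction and edited length", {
  g <- generate_genome(10000, gc = 0.6, seed = 3)
  cargo <- paste(rep(c("A", "T", "G", "C"), length.out = 51), collapse = "")
  d <- design_repair_template(g, list(record_id = "synthetic", start = 4000,
                                      end = 6000), arm_len = 1000,
                              cargo = cargo)
  expect_equal(d$left_arm, slice_interval(g, "synthetic", 3000, 4000))
  expect_equal(d$right_arm, slice_interval(g, "synthetic", 6000, 7000))
  expect_equal(nchar(d$edited_locus), 10000 - 2000 + 51)
  expect_equal(d$junction_seq, paste0(d$left_arm, cargo, d$right_arm))

  plain <- design_repair_template(g, list(record_id = "synthetic",
                                          start = 4000, end = 6000),
                                  arm_len = 1000)
  expect_equal(nchar(plain$edited_locus), 8000)
  expect_equal(plain$junction_seq, paste0(plain$left_arm, plain$right_arm))
})

test_that("insufficient flank reports the maximum feasible arm length", {
  g <- generate_genome(5000, gc = 0.6, seed = 4)
  err <- tryCatch(
    design_repair_template(g, list(record_id = "synthetic", start = 500,
                                   end = 1500), arm_len = 1000),
    cas3design_error_insufficient_flank = function(e) conditionMessage(e))
  expect_match(err, "500")
})

test_that("enzyme screening of the template matches the substring oracle", {
  g0 <- generate_genome(8000, gc = 0.6, seed = 5)
  # plant a HindIII site inside the left arm
  g <- plant_sites(g0, "AAGCTT", data.frame(offset = 3500, strand = "+"))
  d <- design_repair_template(g, list(record_id = "synthetic", start = 4000,
                                      end = 5000), arm_len = 1000)
  hind <- d$enzyme_violations[d$enzyme_violations$enzyme == "HindIII", ]
  expect_true(500 %in% hind$offset)  # 3500 is 500 into the [3000,4000) arm
  for (enzyme in c("NdeI", "HindIII", "BstBI", "NcoI", "SnaBI")) {
    site <- c(NdeI = "CATATG", HindIII = "AAGCTT", BstBI = "TTCGAA",
              NcoI = "CCATGG", SnaBI = "TACGTA")[[enzyme]]
    want <- oracle_site_offsets(site, d$junction_seq)
    got <- sort(unique(
      d$enzyme_violations$offset[d$enzyme_violations$enzyme == enzyme]))
    expect_equal(got, want)
  }
})

test_that("template design is strand-consistent under genome reverse complement", {
  g <- generate_genome(9000, gc = 0.6, seed = 6)
  n <- 9000
  del <- list(record_id = "synthetic", start = 4000, end = 5500)
  d <- design_repair_template(g, del, arm_len = 800)
  grc <- genome_set(c(synthetic = revcomp(as.character(g[[1]]))))
  mirrored <- list(record_id = "synthetic", start = n - del$end,
                   end = n - del$start)
  drc <- design_repair_template(grc, mirrored, arm_len = 800)
  expect_equal(drc$junction_seq, revcomp(d$junction_seq))
})

test_that("predict_edited_locus windows the junction and contains the cargo once", {
  g <- generate_genome(10000, gc = 0.6, seed = 7)
  cargo <- "ATTATTCCGGAATTGGCCAATTACGCGCGTACGTATTGGCCAACCGGTTA"
  cargo <- paste0(cargo, "T")  # 51 nt
  d <- design_repair_template(g, list(record_id = "synthetic", start = 4000,
                                      end = 6000), arm_len = 1000,
                              cargo = cargo)
  w0 <- predict_edited_locus(d, window = 0)
  expect_equal(w0$seq, cargo)
  w <- predict_edited_locus(d, window = 200)
  expect_equal(lengths(regmatches(w$seq, gregexpr(cargo, w$seq,
                                                  fixed = TRUE))), 1L)
  # reported coordinates reproduce the window in the edited record
  expect_equal(substr(d$edited_locus, w$offset + 1,
                      w$offset + nchar(w$seq)), w$seq)
  expect_equal(substr(w$seq, w$junction_start + 1, w$junction_end), cargo)
  big <- predict_edited_locus(d, window = 1e6)
  expect_true(big$truncated)
  expect_equal(big$seq, d$edited_locus)
})

test_that("edited-length conservation holds across random designs", {
  set.seed(91)
  g <- generate_genome(12000, gc = 0.72, seed = 91)
  for (rep in 1:20) {
    s <- sample(2000:6000, 1)
    e <- s + sample(100:3000, 1)
    arm <- sample(200:1000, 1)
    cargo <- if (rep %% 2 == 0) random_spacer(51) else ""
    d <- design_repair_template(g, list(record_id = "synthetic", start = s,
                                        end = e), arm_len = arm,
                                cargo = cargo)
    expect_equal(nchar(d$edited_locus), 12000 - (e - s) + nchar(cargo))
  }
})

test_that("tidy and glance methods summarise cloning objects", {
  kit <- toy_kit()
  ps <- design_spacer_primers(random_spacer(), kit)
  expect_equal(nrow(generics::tidy(ps)), 4)
  expect_equal(generics::glance(ps)$spacer_length, 34)
  g <- generate_genome(6000, gc = 0.6, seed = 8)
  d <- design_repair_template(g, list(record_id = "synthetic", start = 2000,
                                      end = 3000), arm_len = 500)
  expect_equal(generics::glance(d)$edited_length, 5000)
  expect_equal(generics::tidy(d)$length, c(500, 0, 500))
})
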