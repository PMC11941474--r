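make_planted_genome <- function(extra_copies, seed = 17, length = 1e5,
                                strands = NULL) {
  proto <- fixture_protospacer()
  g <- generate_genome(length, gc = 0.72, seed = seed)
  offsets <- c(2000, 15000, 40000, 60000, 80000, 95000)[
    seq_len(extra_copies + 1)]
  if (is.null(strands)) {
    strands <- rep(c("+", "-"), length.out = extra_copies + 1)
  }
  g2 <- plant_sites(g, paste0("TTC", proto),
                    data.frame(offset = offsets, strand = strands))
  list(genome = g2, proto = proto, offsets = offsets, strands = strands)
}

test_that("full-length counting includes the on-target site and all planted copies", {
  for (k in c(0, 1, 2, 5)) {
    px <- make_planted_genome(k)
    expect_equal(count_full_length(px$proto, px$genome), k + 1)
  }
})

test_that("a candidate queried against a motif-free genome scores zero", {
  g <- genome_set(c(chr = paste(rep("G", 500), collapse = "")))
  expect_equal(count_full_length(fixture_protospacer(), g), 0)
  expect_equal(count_seed_pam(substr(fixture_protospacer(), 1, 8), g), 0)
})

test_that("seed-only plants raise seed_pam_count but not full_length_count", {
  px <- make_planted_genome(0)
  proto <- px$proto
  seed8 <- substr(proto, 1, 8)
  # same PAM+seed, divergent distal sequence: a seed off-target
  decoy <- paste0("TTC", seed8, "GGCCGGCCGGAACCTTGGCCAA")
  g3 <- plant_sites(px$genome, decoy,
                    data.frame(offset = c(30000, 50000, 70000),
                               strand = c("+", "-", "+")))
  expect_equal(count_full_length(proto, g3), 1)
  expect_equal(count_seed_pam(seed8, g3), 4)
})

test_that("a seed match without an adjacent PAM contributes nothing", {
  seed8 <- substr(fixture_protospacer(), 1, 8)
  g <- generate_genome(5e4, gc = 0.72, seed = 23)
  # plant the bare seed (no PAM) and one PAM+seed copy
  g2 <- plant_sites(g, paste0("GGG", seed8), data.frame(offset = 10000,
                                                        strand = "+"))
  g3 <- plant_sites(g2, paste0("TTC", seed8), data.frame(offset = 30000,
                                                         strand = "+"))
  expect_equal(count_seed_pam(seed8, g3), 1)
})

test_that("mismatch_scan at radius 0 equals full-length counting", {
  px <- make_planted_genome(2)
  hits <- mismatch_scan(px$proto, px$genome, max_mm = 0)
  expect_equal(nrow(hits), count_full_length(px$proto, px$genome))
  expect_true(all(hits$mismatches == 0))
  expect_true(all(hits$pam_present))
})

test_that("a single-mismatch copy appears only once the radius allows it", {
  px <- make_planted_genome(0)
  variant <- px$proto
  substr(variant, 17, 17) <- if (substr(variant, 17, 17) == "A") "C" else "A"
  g2 <- plant_sites(px$genome, paste0("TTC", variant),
                    data.frame(offset = 55000, strand = "+"))
  h0 <- mismatch_scan(px$proto, g2, max_mm = 0)
  expect_false(any(h0$start == 55003))
  h1 <- mismatch_scan(px$proto, g2, max_mm = 1)
  row <- h1[h1$start == 55003, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$mismatches, 1L)
  expect_true(row$pam_present)
})

test_that("mismatch_scan agrees with the brute-force Hamming oracle", {
  set.seed(404)
  for (gc in c(0.3, 0.72)) {
    for (rep in 1:3) {
      s <- random_dna(4000, gc)
      g <- genome_set(c(chr = s))
      q_start <- sample(1:(4000 - 34), 1)
      query <- substr(s, q_start, q_start + 33)
      if (grepl("[^ACGT]", query)) next
      for (mm in 0:4) {
        got <- mismatch_scan(query, g, max_mm = mm)
        want <- oracle_hamming_both(query, s, mm)
        expect_equal(nrow(got), nrow(want))
        expect_equal(got$start, want$start)
        expect_equal(got$strand, want$strand)
        expect_equal(got$mismatches, as.integer(want$mm))
      }
    }
  }
})

test_that("mismatch hit sets are nested and non-decreasing in the radius", {
  px <- make_planted_genome(1)
  keys <- lapply(0:3, function(mm) {
    h <- mismatch_scan(px$proto, px$genome, max_mm = mm)
    paste(h$record_id, h$start, h$strand)
  })
  for (j in 2:4) expect_true(all(keys[[j - 1]] %in% keys[[j]]))
})

test_that("counts are invariant under reverse-complementing the genome", {
  px <- make_planted_genome(2)
  s <- as.character(px$genome[[1]])
  grc <- genome_set(c(synthetic = revcomp(s)))
  expect_equal(count_full_length(px$proto, grc),
               count_full_length(px$proto, px$genome))
  expect_equal(count_seed_pam(substr(px$proto, 1, 8), grc),
               count_seed_pam(substr(px$proto, 1, 8), px$genome))
})

test_that("on-target identification and require_pam filtering work", {
  px <- make_planted_genome(1)
  ot <- list(record_id = "synthetic", proto_start = px$offsets[1] + 3,
             strand = "+")
  hits <- mismatch_scan(px$proto, px$genome, max_mm = 0, on_target = ot)
  expect_equal(sum(hits$is_on_target), 1)
  expect_equal(hits$start[hits$is_on_target], px$offsets[1] + 3)
  hp <- mismatch_scan(px$proto, px$genome, max_mm = 0, require_pam = TRUE)
  expect_true(all(hp$pam_present))
  expect_lte(nrow(hp), count_seed_pam(substr(px$proto, 1, 8), px$genome))
})

test_that("annotate_spacers fills both counts for every candidate", {
  g <- generate_genome(30000, gc = 0.72, seed = 31)
  cand <- extract_spacers(g, list(record_id = "synthetic", start = 10000,
                                  end = 14000))
  ann <- annotate_spacers(cand, g)
  expect_true(all(ann$full_length_count >= 1))
  expect_true(all(ann$seed_pam_count >= 1))
  # spot-check against direct counting
  for (k in seq_len(min(5, nrow(ann)))) {
    expect_equal(ann$full_length_count[k],
                 count_full_length(ann$protospacer[k], g))
    expect_equal(ann$seed_pam_count[k], count_seed_pam(ann$seed[k], g))
  }
})

test_that("default filters keep exactly the (1,1) candidates", {
  g <- generate_genome(30000, gc = 0.72, seed = 37)
  region <- list(record_id = "synthetic", start = 8000, end = 12000)
  ann <- annotate_spacers(extract_spacers(g, region), g)
  ranked <- rank_spacers(ann, filter_spec(), region)
  expect_true(all(ranked$full_length_count == 1))
  expect_true(all(ranked$seed_pam_count == 1))
  expect_equal(nrow(ranked),
               sum(ann$full_length_count == 1 & ann$seed_pam_count == 1))
})

test_that("ranking is deterministic and respects the position preference", {
  g <- generate_genome(30000, gc = 0.72, seed = 41)
  region <- list(record_id = "synthetic", start = 8000, end = 12000)
  ann <- annotate_spacers(extract_spacers(g, region), g)
  r1 <- rank_spacers(ann, filter_spec(position = "edge"), region)
  r2 <- rank_spacers(ann[sample(nrow(ann)), ],
                     filter_spec(position = "edge"), region)
  expect_identical(r1, r2)
  # the first edge-preferred candidate is closest to a boundary
  mid <- (r1$proto_start + r1$proto_end) / 2
  d_edge <- pmin(mid - region$start, region$end - mid)
  expect_equal(d_edge[1], min(d_edge))
  rm <- rank_spacers(ann, filter_spec(position = "middle"), region)
  midm <- (rm$proto_start + rm$proto_end) / 2
  d_mid <- abs(midm - (region$start + region$end) / 2)
  expect_equal(d_mid[1], min(d_mid))
})

test_that("a stricter-than-unity filter is rejected", {
  expect_error(filter_spec(max_full_length = 0),
               class = "cas3design_error_bad_filter")
})

test_that("offtarget_summary bundles counts and a mismatch histogram", {
  px <- make_planted_genome(1)
  sm <- offtarget_summary(px$proto, substr(px$proto, 1, 8), px$genome,
                          max_mm = 1)
  expect_equal(sm$full_length_count, 2L)
  expect_gte(sm$seed_pam_count, 2L)
  expect_true(is.data.frame(sm$mismatch_histogram))
  expect_equal(sm$mismatch_histogram$hits[sm$mismatch_histogram$mismatches == 0],
               2L)
})
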