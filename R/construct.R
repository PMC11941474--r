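DEFAULT_ENZYMES <- c(NdeI = "CATATG", HindIII = "AAGCTT", BstBI = "TTCGAA",
                     NcoI = "CCATGG", SnaBI = "TACGTA")

circ_count <- function(feature, circle) {
  dbl <- paste0(circle, substr(circle, 1, nchar(feature) - 1))
  m <- gregexpr(feature, dbl, fixed = TRUE)[[1]]
  sum(m > 0)
}

# substring of a circular sequence, 0-based half-open, end may wrap
circ_substr <- function(circle, start, end) {
  n <- nchar(circle)
  len <- end - start
  start <- start %% n
  if (start + len <= n) {
    substr(circle, start + 1, start + len)
  } else {
    paste0(substr(circle, start + 1, n), substr(circle, 1, len - (n - start)))
  }
}

#' Define a spacer-cloning kit
#'
#' Holds the plasmid-side constants of the two-PCR Gibson spacer-cloning
#' strategy: the two CRISPR repeats flanking the spacer slot (the second
#' repeat is sequence-modified to prevent recombination between the
#' repeats), the two fixed primer annealing sites up- and downstream of the
#' slot, the destination digestion enzymes, and optionally the full circular
#' backbone for in-silico assembly verification.
#'
#' @param repeat1,repeat2 the two CRISPR repeats (must differ).
#' @param upstream_anneal,downstream_anneal fixed primer annealing sites.
#' @param backbone full circular plasmid sequence, or `NULL`. When given,
#'   each of the four features above must occur exactly once (circularly).
#' @param enzymes named character vector of restriction recognition sites.
#' @param destination_enzymes names of the enzymes whose double digest
#'   removes the spacer slot and the origin of replication (default BstBI +
#'   NdeI, so only correctly assembled plasmids replicate).
#' @param min_overlap minimum Gibson overlap in nt (default 20, a standard
#'   assembly homology length).
#' @param spacer_len expected spacer length (default 34 nt).
#' @return a `cloning_kit` object.
#' @seealso [toy_kit()], [read_kit()]
#' @export
cloning_kit <- function(repeat1, repeat2, upstream_anneal, downstream_anneal,
                        backbone = NULL, enzymes = DEFAULT_ENZYMES,
                        destination_enzymes = c("BstBI", "NdeI"),
                        min_overlap = 20, spacer_len = 34) {
  repeat1 <- assert_dna(repeat1, "repeat1", iupac = FALSE)
  repeat2 <- assert_dna(repeat2, "repeat2", iupac = FALSE)
  upstream_anneal <- assert_dna(upstream_anneal, "upstream_anneal",
                                iupac = FALSE)
  downstream_anneal <- assert_dna(downstream_anneal, "downstream_anneal",
                                  iupac = FALSE)
  if (identical(repeat1, repeat2)) {
    abort_cas3("repeat1 and repeat2 must differ (anti-recombination design)",
               "identical_repeats")
  }
  if (!all(destination_enzymes %in% names(enzymes))) {
    abort_cas3("destination enzymes must be named in `enzymes`", "bad_kit")
  }
  if (!is.null(backbone)) {
    backbone <- assert_dna(backbone, "backbone", iupac = FALSE)
    for (f in c("repeat1", "repeat2", "upstream_anneal", "downstream_anneal")) {
      k <- circ_count(get(f), backbone)
      if (k != 1L) {
        abort_cas3(sprintf("%s occurs %d times in the backbone (need exactly 1)",
                           f, k), "bad_kit")
      }
    }
  }
  structure(list(repeat1 = repeat1, repeat2 = repeat2,
                 upstream_anneal = upstream_anneal,
                 downstream_anneal = downstream_anneal,
                 backbone = backbone, enzymes = enzymes,
                 destination_enzymes = destination_enzymes,
                 min_overlap = min_overlap, spacer_len = spacer_len),
            class = "cloning_kit")
}

#' @export
print.cloning_kit <- function(x, ...) {
  cat("<cloning_kit>\n",
      sprintf("  repeats: %d / %d nt, spacer slot %d nt\n",
              nchar(x$repeat1), nchar(x$repeat2), x$spacer_len),
      sprintf("  backbone: %s\n",
              if (is.null(x$backbone)) "none"
              else paste0(nchar(x$backbone), " bp circular")),
      sprintf("  destination digest: %s; min overlap %d nt\n",
              paste(x$destination_enzymes, collapse = " + "), x$min_overlap),
      sep = "")
  invisible(x)
}

#' A synthetic toy cloning kit for examples and verification
#'
#' A small (344 bp) synthetic circular backbone with the geometry of the real
#' spacer-cloning plasmid: upstream fixed-primer site, BstBI site, repeat 1,
#' a 30-nt placeholder slot, the modified repeat 2, a mock origin region,
#' NdeI site, downstream fixed-primer site. The BstBI + NdeI double digest
#' removes the slot together with the mock origin. All sequences are
#' synthetic stand-ins; real plasmid sequences can be supplied through
#' [read_kit()].
#'
#' @return a `cloning_kit`.
#' @export
toy_kit <- function() {
  parts <- c(
    stuffer1 = "AACTGGTCGGGGACGAACGGACAACGGAGTTTGGCTCCAGGGCAGAAGAGCCGTCTGCCGGATGTCCTGCCCCGCGCGGC",
    upstream_anneal = "GCCGTGCCCCGCCAATCGTG",
    gap1 = "GCCGAA",
    bstbi = "TTCGAA",
    gap2 = "TTGC",
    repeat1 = "GTTGGGCCGTCGGGGGAACTAG",
    slot = "GATGTCTGCCGTTTCACCGCTGGTCCCGAG",
    repeat2 = "GCGCGCCCTGGGGCTGTTAACC",
    gap3 = "TTAT",
    ori = "CCCTCCCCGCTTAGTGCGAGCCGGCCGTGCGAGCGACTCCCCCCCCATCAGGCGCCGGCC",
    gap4 = "GACC",
    ndei = "CATATG",
    downstream_anneal = "CGCTCGGGGCCAGCACAACT",
    stuffer2 = "GCACCGGGGCCACCGCCCATCGCCTGCCGGCCAAGCCCCAGCCACGAAGGCCGACTTTAC")
  cloning_kit(repeat1 = parts[["repeat1"]], repeat2 = parts[["repeat2"]],
              upstream_anneal = parts[["upstream_anneal"]],
              downstream_anneal = parts[["downstream_anneal"]],
              backbone = paste(parts, collapse = ""))
}

#' Read / write a cloning-kit configuration
#'
#' The kit lives in a JSON file with fields named exactly as the
#' [cloning_kit()] arguments, so users can drop in the sequences of their
#' own plasmid without touching code.
#'
#' @param path JSON file path.
#' @return for `read_kit`, a `cloning_kit`; for `write_kit`, `path`
#'   invisibly.
#' @export
read_kit <- function(path) {
  if (!file.exists(path)) {
    abort_cas3(sprintf("kit file not found: %s", path), "missing_file")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cloning_kit(repeat1 = x$repeat1, repeat2 = x$repeat2,
              upstream_anneal = x$upstream_anneal,
              downstream_anneal = x$downstream_anneal,
              backbone = x$backbone %||% NULL,
              enzymes = if (!is.null(x$enzymes)) unlist(x$enzymes)
                        else DEFAULT_ENZYMES,
              destination_enzymes = x$destination_enzymes %||%
                c("BstBI", "NdeI"),
              min_overlap = x$min_overlap %||% 20,
              spacer_len = x$spacer_len %||% 34)
}

#' @rdname read_kit
#' @param kit a `cloning_kit`.
#' @export
write_kit <- function(kit, path) {
  x <- unclass(kit)
  x$enzymes <- as.list(x$enzymes)  # keep enzyme names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Design the four spacer-cloning primers
#'
#' Implements the two-PCR Gibson strategy: two fixed primers anneal up- and
#' downstream of the spacer slot, and two spacer-carrying primers anneal to
#' the repeats with the 34-nt spacer in their 5' overhangs. PCR A (fixed
#' forward + spacer reverse) ends in repeat1 + spacer; PCR B (spacer forward
#' + fixed reverse) starts with spacer + repeat2 and carries the origin
#' region back into the assembly. The two products therefore overlap each
#' other across the spacer and overlap the digested backbone ends, so a
#' standard Gibson assembly reconstitutes the plasmid with the new spacer
#' between the repeats.
#'
#' @param spacer unambiguous DNA string of the kit's configured length.
#' @param kit a [cloning_kit()] with a backbone (needed to predict the PCR
#'   products).
#' @return a `primer_set`: primer tibble plus predicted `fragment_A` and
#'   `fragment_B`. If the spacer contains a destination-enzyme recognition
#'   site the set is flagged (`destination_site_in_spacer`) with a warning —
#'   cloning remains possible since digestion precedes assembly, but the site
#'   deserves attention.
#' @export
design_spacer_primers <- function(spacer, kit = toy_kit()) {
  spacer <- assert_dna(spacer, "spacer", iupac = FALSE)
  if (nchar(spacer) != kit$spacer_len) {
    abort_cas3(sprintf("spacer must be %d nt (got %d)", kit$spacer_len,
                       nchar(spacer)), "bad_spacer_length")
  }
  dest_sites <- kit$enzymes[kit$destination_enzymes]
  flagged <- any(vapply(dest_sites, function(s) {
    grepl(s, spacer, fixed = TRUE) || grepl(revcomp(s), spacer, fixed = TRUE)
  }, logical(1)))
  if (flagged) {
    rlang::warn("spacer contains a destination-enzyme recognition site")
  }
  primers <- tibble(
    name = c("fixed_fwd", "fixed_rev", "spacer_fwd", "spacer_rev"),
    seq = c(kit$upstream_anneal, revcomp(kit$downstream_anneal),
            paste0(spacer, kit$repeat2),
            revcomp(paste0(kit$repeat1, spacer))))
  primers$length <- nchar(primers$seq)
  primers$gc <- gc_fraction(primers$seq)
  fragment_A <- fragment_B <- NULL
  if (!is.null(kit$backbone)) {
    bb <- kit$backbone; n <- nchar(bb)
    pos0 <- function(f) {
      dbl <- paste0(bb, substr(bb, 1, nchar(f) - 1))
      regexpr(f, dbl, fixed = TRUE)[[1]] - 1L
    }
    u <- pos0(kit$upstream_anneal)
    r1 <- pos0(kit$repeat1); r2 <- pos0(kit$repeat2)
    d <- pos0(kit$downstream_anneal)
    span <- function(s, e) circ_substr(bb, s, if (e < s) e + n else e)
    fragment_A <- paste0(span(u, r1 + nchar(kit$repeat1)), spacer)
    fragment_B <- paste0(spacer, span(r2, d + nchar(kit$downstream_anneal)))
  }
  structure(list(spacer = spacer, primers = primers,
                 fragment_A = fragment_A, fragment_B = fragment_B,
                 destination_site_in_spacer = flagged,
                 min_overlap = kit$min_overlap),
            class = "primer_set")
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("<primer_set> spacer %s\n", x$spacer))
  print(x$primers)
  if (!is.null(x$fragment_A)) {
    cat(sprintf("predicted fragments: A %d nt, B %d nt\n",
                nchar(x$fragment_A), nchar(x$fragment_B)))
  }
  if (x$destination_site_in_spacer) {
    cat("! spacer contains a destination-enzyme site\n")
  }
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @exportS3Method generics::tidy
tidy.primer_set <- function(x, ...) x$primers

#' @exportS3Method generics::glance
glance.primer_set <- function(x, ...) {
  tibble(spacer_length = nchar(x$spacer),
         fragment_a_length = if (is.null(x$fragment_A)) NA_integer_
                             else nchar(x$fragment_A),
         fragment_b_length = if (is.null(x$fragment_B)) NA_integer_
                             else nchar(x$fragment_B),
         destination_site_in_spacer = x$destination_site_in_spacer)
}

#' Digest a circular sequence with restriction enzymes
#'
#' Cuts the circle at the start offset of every recognition-site occurrence
#' (blunt-cut abstraction: sticky-end chemistry is irrelevant to the
#' overlap-based Gibson verification). Recognition sites are searched on both
#' strands.
#'
#' @param circle circular DNA string.
#' @param sites named character vector of recognition sequences; every
#'   enzyme must cut at least once.
#' @return a tibble with `cut_offset` (0-based), `enzyme`, and `seq` (the
#'   fragment starting at that cut), in position order. A single cut yields
#'   one full-length linear fragment.
#' @export
digest_circular <- function(circle, sites) {
  circle <- assert_dna(circle, "circle", iupac = FALSE)
  if (is.null(names(sites)) || any(!nzchar(names(sites)))) {
    names(sites) <- sites
  }
  cuts <- purrr::map_dfr(names(sites), function(nm) {
    site <- sites[[nm]]
    offs <- integer()
    for (s in unique(c(site, revcomp(site)))) {
      dbl <- paste0(circle, substr(circle, 1, nchar(s) - 1))
      m <- gregexpr(s, dbl, fixed = TRUE)[[1]]
      m <- m[m > 0 & m <= nchar(circle)]
      offs <- c(offs, m - 1L)
    }
    offs <- sort(unique(offs))
    if (length(offs) == 0L) {
      abort_cas3(sprintf("enzyme %s (%s) has no recognition site", nm, site),
                 "enzyme_no_site")
    }
    tibble(cut_offset = offs, enzyme = nm)
  }) |>
    arrange(.data$cut_offset) |>
    distinct(.data$cut_offset, .keep_all = TRUE)
  n <- nchar(circle)
  ends <- c(cuts$cut_offset[-1], cuts$cut_offset[1] + n)
  cuts$seq <- vapply(seq_len(nrow(cuts)), function(k) {
    circ_substr(circle, cuts$cut_offset[k], ends[k])
  }, character(1))
  cuts
}

# Largest terminal overlap k >= min_overlap with suffix(x, k) == prefix(y, k)
terminal_overlap <- function(x, y, min_overlap) {
  if (min_overlap < 1 || nchar(x) < min_overlap || nchar(y) < min_overlap) {
    return(0L)
  }
  p0 <- substr(y, 1, min_overlap)
  hits <- gregexpr(p0, x, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  if (length(hits) == 0L) return(0L)
  ks <- nchar(x) - hits + 1L
  ks <- sort(ks[ks >= min_overlap & ks <= nchar(y)], decreasing = TRUE)
  for (k in ks) {
    if (substr(x, nchar(x) - k + 1, nchar(x)) == substr(y, 1, k)) {
      return(as.integer(k))
    }
  }
  0L
}

#' Lexicographically minimal rotation of a circular sequence
#'
#' Canonical form used to compare assembled circles independent of where the
#' assembly happened to start.
#'
#' @param s DNA string representing a circle.
#' @return the canonical rotation.
#' @export
canonical_rotation <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(s)
  d <- paste0(s, s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  best <- NULL
  for (i in which(ch == min(ch))) {
    r <- substr(d, i, i + n - 1)
    if (is.null(best) || r < best) best <- r
  }
  best %||% s
}

#' Simulate a Gibson assembly
#'
#' Joins double-stranded fragments at exact terminal overlaps of at least
#' `min_overlap` nt into a single circle, trying both orientations of every
#' fragment (the first fragment's given orientation fixes the reported
#' strand). Errors distinctly when no circular arrangement exists and when
#' more than one distinct circle can form.
#'
#' @param fragments character vector of fragment sequences (PCR products).
#' @param backbone_digested optional character vector of digested-backbone
#'   fragments to include in the assembly.
#' @param min_overlap minimum junction overlap in nt.
#' @return the assembled circular sequence in canonical rotation
#'   ([canonical_rotation()]).
#' @export
#' @examples
#' simulate_gibson(c("AAAACCCCGGGG", "GGGGTTTTAAAA"), min_overlap = 4)
simulate_gibson <- function(fragments, backbone_digested = NULL,
                            min_overlap = 20) {
  frags <- c(fragments, backbone_digested)
  frags <- vapply(frags, assert_dna, character(1), what = "fragment",
                  iupac = FALSE, USE.NAMES = FALSE)
  nf <- length(frags)
  if (nf == 0L) abort_cas3("no fragments", "empty_input")
  if (nf > 8L) abort_cas3("too many fragments for exhaustive assembly",
                          "too_many_fragments")
  orient <- function(s, flip) if (flip) revcomp(s) else s
  results <- character()
  if (nf == 1L) {
    k0 <- terminal_overlap(frags[1], frags[1], min_overlap)
    if (k0 > 0L) results <- substr(frags[1], 1, nchar(frags[1]) - k0)
  } else {
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }))
    }
    rest <- perms(seq_len(nf)[-1])
    flips <- expand.grid(rep(list(c(FALSE, TRUE)), nf - 1))
    for (ord in rest) {
      for (fi in seq_len(nrow(flips))) {
        chain <- c(frags[1],
                   mapply(orient, frags[ord],
                          as.logical(flips[fi, ]), USE.NAMES = FALSE))
        merged <- chain[1]
        ok <- TRUE
        for (j in 2:length(chain)) {
          k <- terminal_overlap(chain[j - 1], chain[j], min_overlap)
          if (k == 0L) { ok <- FALSE; break }
          merged <- paste0(merged, substr(chain[j], k + 1, nchar(chain[j])))
        }
        if (!ok) next
        k0 <- terminal_overlap(chain[length(chain)], chain[1], min_overlap)
        if (k0 == 0L) next
        results <- c(results, substr(merged, 1, nchar(merged) - k0))
      }
    }
  }
  if (length(results) == 0L) {
    abort_cas3("fragments cannot circularize: no terminal overlap chain found",
               "no_assembly")
  }
  canon <- unique(vapply(results, canonical_rotation, character(1),
                         USE.NAMES = FALSE))
  if (length(canon) > 1L) {
    abort_cas3("ambiguous assembly: multiple distinct circles possible",
               "ambiguous_assembly")
  }
  canon
}

#' Design a repair template for a deletion or substitution
#'
#' Selects two homology arms of `arm_len` bp flanking the deletion interval
#' (1 kb by default, the standard repair-template flank), optionally places a
#' cargo sequence (e.g. the 51-bp PhiC31 attB site) between them, screens the
#' fused template for restriction sites of every kit enzyme on both strands,
#' and predicts the edited locus.
#'
#' @param genomes a genome set.
#' @param deletion the interval to delete: `"record:start-end"` (1-based
#'   inclusive) or a list with `record_id`, `start`, `end` (0-based
#'   half-open).
#' @param arm_len homology-arm length in bp (default 1000).
#' @param cargo DNA string inserted between the arms in the given orientation
#'   (default empty: plain deletion).
#' @param enzymes named recognition-site vector to screen for (default: the
#'   kit platform enzymes).
#' @return a `repair_template` object: arms, `junction_seq`
#'   (left + cargo + right), `enzyme_violations` tibble, and the full
#'   `edited_locus` sequence (original record with the deletion replaced by
#'   the cargo).
#' @export
design_repair_template <- function(genomes, deletion, arm_len = 1000,
                                   cargo = "", enzymes = DEFAULT_ENZYMES) {
  if (is.character(deletion)) deletion <- parse_region(deletion)
  if (nchar(cargo) > 0) cargo <- assert_dna(cargo, "cargo", iupac = FALSE)
  i <- get_record(genomes, deletion$record_id)
  n <- Biostrings::width(genomes)[i]
  if (deletion$start < 0 || deletion$end > n ||
      deletion$end <= deletion$start) {
    abort_cas3("deletion interval out of record bounds", "out_of_bounds")
  }
  max_arm <- min(deletion$start, n - deletion$end)
  if (arm_len < 1 || arm_len > max_arm) {
    abort_cas3(sprintf("insufficient flanking sequence: maximum feasible arm_len is %d",
                       max_arm), "insufficient_flank")
  }
  left_arm <- slice_interval(genomes, deletion$record_id,
                             deletion$start - arm_len, deletion$start)
  right_arm <- slice_interval(genomes, deletion$record_id,
                              deletion$end, deletion$end + arm_len)
  junction_seq <- paste0(left_arm, cargo, right_arm)
  violations <- purrr::map_dfr(names(enzymes), function(nm) {
    site <- enzymes[[nm]]
    purrr::map_dfr(unique(c(`+` = site, `-` = revcomp(site))), function(s) {
      m <- gregexpr(s, junction_seq, fixed = TRUE)[[1]]
      m <- m[m > 0]
      if (length(m) == 0L) return(NULL)
      tibble(enzyme = nm, offset = m - 1L,
             strand = if (s == site) "+" else "-")
    })
  })
  if (nrow(violations) == 0L) {
    violations <- tibble(enzyme = character(), offset = integer(),
                         strand = character())
  } else {
    violations <- arrange(violations, .data$offset, .data$enzyme)
  }
  s <- as.character(genomes[[i]])
  edited <- paste0(substr(s, 1, deletion$start), cargo,
                   substr(s, deletion$end + 1, n))
  structure(list(record_id = deletion$record_id,
                 deletion = list(start = deletion$start, end = deletion$end),
                 arm_len = arm_len, left_arm = left_arm,
                 right_arm = right_arm, cargo = cargo,
                 junction_seq = junction_seq,
                 enzyme_violations = violations,
                 edited_locus = edited, original_length = n),
            class = "repair_template")
}

#' @export
print.repair_template <- function(x, ...) {
  cat(sprintf("<repair_template> %s: delete [%d,%d) (%d bp), arms %d bp, cargo %d bp\n",
              x$record_id, x$deletion$start, x$deletion$end,
              x$deletion$end - x$deletion$start, x$arm_len, nchar(x$cargo)))
  cat(sprintf("edited locus: %d bp (was %d); %d enzyme site(s) in template\n",
              nchar(x$edited_locus), x$original_length,
              nrow(x$enzyme_violations)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.repair_template <- function(x, ...) {
  parts <- tibble(part = c("left_arm", "cargo", "right_arm"),
                  seq = c(x$left_arm, x$cargo, x$right_arm))
  parts$length <- nchar(parts$seq)
  parts$gc <- ifelse(parts$length > 0, gc_fraction(parts$seq), NA_real_)
  parts
}

#' @exportS3Method generics::glance
glance.repair_template <- function(x, ...) {
  tibble(record_id = x$record_id,
         deletion_start = x$deletion$start, deletion_end = x$deletion$end,
         deletion_length = x$deletion$end - x$deletion$start,
         arm_length = x$arm_len, cargo_length = nchar(x$cargo),
         edited_length = nchar(x$edited_locus),
         original_length = x$original_length,
         n_enzyme_sites = nrow(x$enzyme_violations))
}

#' Predicted edited locus around the repair junction
#'
#' Returns the edited sequence within `window` bases of the junction (the
#' point where the two arms fuse, spanning the cargo if present), suitable as
#' a mapping reference for verifying an edit by sequencing.
#'
#' @param design a [design_repair_template()] result.
#' @param window bases of context either side of the junction span.
#' @return a list: `seq`, `junction_start`/`junction_end` (0-based, within
#'   `seq`), `offset` (of `seq` within the edited record) and `truncated`
#'   (whether the window was clipped at a record end).
#' @export
predict_edited_locus <- function(design, window = 500) {
  if (window < 0) abort_cas3("window must be >= 0", "bad_window")
  len <- nchar(design$edited_locus)
  j_start <- design$deletion$start
  j_end <- j_start + nchar(design$cargo)
  s <- max(0, j_start - window)
  e <- min(len, j_end + window)
  list(seq = substr(design$edited_locus, s + 1, e),
       junction_start = j_start - s, junction_end = j_end - s,
       offset = s, truncated = (j_start - window < 0) || (j_end + window > len))
}

#' Plot a repair-template design
#'
#' Schematic of the deleted interval, homology arms and cargo along the
#' original coordinates.
#'
#' @param design a `repair_template`.
#' @return a ggplot object.
#' @export
plot_repair_template <- function(design) {
  d <- design$deletion
  df <- tibble(
    part = factor(c("left arm", "deletion", "cargo", "right arm"),
                  levels = c("left arm", "deletion", "cargo", "right arm")),
    xmin = c(d$start - design$arm_len, d$start, d$start, d$end),
    xmax = c(d$start, d$end, d$start + nchar(design$cargo),
             d$end + design$arm_len),
    y = c(1, 2, 3, 1))
  df <- df[df$xmax > df$xmin, ]
  ggplot2::ggplot(df, ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                   ymin = .data$y - 0.3,
                                   ymax = .data$y + 0.3,
                                   fill = .data$part)) +
    ggplot2::geom_rect() +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Repair-template design") +
    ggplot2::theme_minimal()
}
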