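IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# Exact IUPAC-class membership test of `text` against `pattern`, both plain
# strings of equal length. Any text letter outside A/C/G/T fails its class.
iupac_matches <- function(pattern, text) {
  if (nchar(pattern) != nchar(text)) return(FALSE)
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  t <- strsplit(text, "", fixed = TRUE)[[1]]
  all(mapply(function(pc, tc) grepl(tc, IUPAC_CLASS[[pc]], fixed = TRUE),
             p, t))
}

count_exact_both_strands <- function(query, genomes, iupac = FALSE) {
  fx <- if (iupac) c(pattern = FALSE, subject = TRUE) else TRUE
  total <- 0L
  for (i in seq_along(genomes)) {
    subj <- if (iupac) masked_record(genomes, i) else genomes[[i]]
    total <- total +
      Biostrings::countPattern(query, subj, fixed = fx) +
      Biostrings::countPattern(revcomp(query), subj, fixed = fx)
  }
  as.integer(total)
}

#' Count exact whole-length occurrences of a protospacer
#'
#' Number of exact occurrences of the full protospacer on both strands of all
#' records, overlapping occurrences included. No PAM is required: this is the
#' whole-length evaluation, which differs from the seed evaluation exactly in
#' its PAM independence. The on-target site itself is counted, so a perfectly
#' specific spacer extracted from the same genome scores 1.
#'
#' @param protospacer unambiguous DNA string (the full-length spacer target).
#' @param genomes the search universe: all records of the host genome.
#' @return integer count.
#' @export
count_full_length <- function(protospacer, genomes) {
  protospacer <- assert_dna(protospacer, "protospacer", iupac = FALSE)
  count_exact_both_strands(protospacer, genomes)
}

#' Count PAM-dependent seed matches of a protospacer
#'
#' Number of exact occurrences, on both strands of all records, of the PAM
#' motif concatenated with the PAM-proximal seed in the correct geometry
#' (for the default type I-C system, the 11-mer `TTC` + 8-nt seed). A seed
#' match without an adjacent PAM contributes nothing — seed off-targets only
#' count when a PAM site is present. The on-target site is included.
#'
#' @param seed the PAM-proximal seed sequence (default length 8); a full
#'   protospacer may be passed together with `seed_len` to take its
#'   PAM-proximal part.
#' @param genomes the search universe.
#' @param motif a [pam_motif()] or pattern string.
#' @param seed_len number of PAM-proximal bases to use (default: all of
#'   `seed`).
#' @return integer count.
#' @export
count_seed_pam <- function(seed, genomes, motif = pam_motif(),
                           seed_len = nchar(seed)) {
  motif <- as_pam_motif(motif)
  seed <- assert_dna(seed, "seed", iupac = FALSE)
  if (seed_len < 1 || seed_len > nchar(seed)) {
    abort_cas3("seed_len out of range", "bad_lengths")
  }
  query <- if (motif$side == "5prime") {
    paste0(motif$pattern, substr(seed, 1, seed_len))
  } else {
    paste0(substr(seed, nchar(seed) - seed_len + 1, nchar(seed)),
           motif$pattern)
  }
  count_exact_both_strands(query, genomes, iupac = TRUE)
}

# Is a valid PAM adjacent to the window [s, e) (0-based, plus-strand coords)
# in the geometry implied by the motif side and the hit strand?
has_adjacent_pam <- function(genomes, record_id, s, e, strand, motif) {
  plen <- nchar(motif$pattern)
  n <- Biostrings::width(genomes)[get_record(genomes, record_id)]
  pam_5prime_side <- (motif$side == "5prime") == (strand == "+")
  iv <- if (pam_5prime_side) c(s - plen, s) else c(e, e + plen)
  if (iv[1] < 0 || iv[2] > n) {
    if (!is_circular(genomes, record_id)) return(FALSE)
    iv <- iv %% n
    if (iv[2] <= iv[1]) iv[2] <- iv[2] + n
  }
  pam_txt <- slice_interval(genomes, record_id, iv[1], iv[2], strand)
  pam_txt <- gsub("[^ACGT]", "-", pam_txt)
  iupac_matches(motif$pattern, pam_txt)
}

#' Mismatch-tolerant genome-wide search for a protospacer
#'
#' Reports every window on both strands of all records within Hamming
#' distance `max_mm` of the protospacer (no indels). Each hit carries its
#' mismatch count, whether a valid PAM flanks it in the correct geometry,
#' and whether it is the on-target site. Genome ambiguity letters count as
#' mismatches.
#'
#' @param protospacer unambiguous DNA string.
#' @param genomes the search universe.
#' @param max_mm maximum Hamming distance, `0 <= max_mm <= nchar(protospacer)`
#'   (default 3, a conservative screening radius).
#' @param require_pam keep only PAM-flanked hits (default `FALSE`).
#' @param motif a [pam_motif()] used for the PAM-adjacency flag.
#' @param on_target optional list `(record_id, proto_start, strand)`
#'   identifying the candidate's own locus, used to set `is_on_target`.
#' @return a tibble: `record_id`, `start`, `end`, `strand`, `seq`,
#'   `mismatches`, `pam_present`, `is_on_target`, ordered by record, start,
#'   strand.
#' @export
mismatch_scan <- function(protospacer, genomes, max_mm = 3,
                          require_pam = FALSE, motif = pam_motif(),
                          on_target = NULL) {
  protospacer <- assert_dna(protospacer, "protospacer", iupac = FALSE)
  L <- nchar(protospacer)
  if (max_mm < 0 || max_mm > L) {
    abort_cas3("max_mm must be in [0, spacer length]", "bad_mismatch")
  }
  motif <- as_pam_motif(motif)
  pchars <- list("+" = strsplit(protospacer, "", fixed = TRUE)[[1]],
                 "-" = strsplit(revcomp(protospacer), "", fixed = TRUE)[[1]])
  hits <- purrr::map_dfr(seq_along(genomes), function(i) {
    rec <- names(genomes)[i]
    subj <- genomes[[i]]
    purrr::map_dfr(c("+", "-"), function(str) {
      pat <- if (str == "+") protospacer else revcomp(protospacer)
      v <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                    with.indels = FALSE, fixed = TRUE)
      # windows hanging off the record ends are not genomic sites
      v <- v[BiocGenerics::start(v) >= 1L &
               BiocGenerics::end(v) <= length(subj)]
      if (length(v) == 0L) return(NULL)
      s0 <- BiocGenerics::start(v) - 1L
      txt <- as.character(v)
      mm <- vapply(txt, function(x) {
        sum(strsplit(x, "", fixed = TRUE)[[1]] != pchars[[str]])
      }, integer(1), USE.NAMES = FALSE)
      seq_out <- if (str == "+") txt else revcomp(txt)
      tibble(record_id = rec, start = s0, end = s0 + L,
             strand = str, seq = seq_out, mismatches = mm)
    })
  })
  if (nrow(hits) == 0L) {
    return(tibble(record_id = character(), start = integer(),
                  end = integer(), strand = character(), seq = character(),
                  mismatches = integer(), pam_present = logical(),
                  is_on_target = logical()))
  }
  hits$pam_present <- vapply(seq_len(nrow(hits)), function(k) {
    has_adjacent_pam(genomes, hits$record_id[k], hits$start[k], hits$end[k],
                     hits$strand[k], motif)
  }, logical(1))
  hits$is_on_target <- if (is.null(on_target)) FALSE else {
    hits$record_id == on_target$record_id &
      hits$start == on_target$proto_start &
      hits$strand == on_target$strand
  }
  if (require_pam) hits <- filter(hits, .data$pam_present)
  hits |>
    mutate(.rec = match(.data$record_id, names(genomes))) |>
    arrange(.data$.rec, .data$start, .data$strand) |>
    select(-".rec")
}

#' Off-target summary for one candidate
#'
#' Bundles the two specificity evaluations — whole-length exact count and
#' PAM-dependent seed count — with an optional mismatch histogram from
#' [mismatch_scan()]. A candidate unique in its genome on both evaluations
#' reads (1, 1): the on-target site is always counted.
#'
#' @param protospacer full-length protospacer.
#' @param seed PAM-proximal seed.
#' @param genomes the search universe.
#' @param motif a [pam_motif()].
#' @param max_mm if non-`NULL`, also run a mismatch scan at this radius.
#' @return a list with `full_length_count`, `seed_pam_count`, and
#'   `mismatch_histogram` (a tibble of hit counts per mismatch count, or
#'   `NULL`).
#' @export
offtarget_summary <- function(protospacer, seed, genomes,
                              motif = pam_motif(), max_mm = NULL) {
  out <- list(
    full_length_count = count_full_length(protospacer, genomes),
    seed_pam_count = count_seed_pam(seed, genomes, motif),
    mismatch_histogram = NULL)
  if (!is.null(max_mm)) {
    hits <- mismatch_scan(protospacer, genomes, max_mm = max_mm,
                          motif = motif)
    out$mismatch_histogram <- hits |>
      count(.data$mismatches, name = "hits")
  }
  out
}

#' Annotate candidates with off-target counts
#'
#' Adds `full_length_count` and `seed_pam_count` columns to a candidate
#' table, querying both strands of every record in `genomes`.
#'
#' @param candidates a tibble from [extract_spacers()].
#' @param genomes the search universe (typically the full host genome, all
#'   records — self-targeting anywhere in the host matters).
#' @param motif the [pam_motif()] used for extraction.
#' @return the candidate tibble with two added integer columns.
#' @export
annotate_spacers <- function(candidates, genomes, motif = pam_motif()) {
  motif <- as_pam_motif(motif)
  if (nrow(candidates) == 0L) {
    candidates$full_length_count <- integer()
    candidates$seed_pam_count <- integer()
    return(candidates)
  }
  fl <- purrr::map_int(unique(candidates$protospacer),
                       count_full_length, genomes = genomes)
  names(fl) <- unique(candidates$protospacer)
  sp <- purrr::map_int(unique(candidates$seed), count_seed_pam,
                       genomes = genomes, motif = motif)
  names(sp) <- unique(candidates$seed)
  candidates |>
    mutate(full_length_count = unname(fl[.data$protospacer]),
           seed_pam_count = unname(sp[.data$seed]))
}

#' Specify candidate filtering rules
#'
#' Defaults keep exactly the "specific" candidates: unique whole-length and
#' unique PAM+seed occurrence in the genome, i.e. off-target summary (1, 1).
#'
#' @param max_full_length maximum whole-length count (default 1).
#' @param max_seed_pam maximum PAM+seed count (default 1).
#' @param gc_min,gc_max allowed protospacer GC range (defaults 0, 1).
#' @param position position preference inside the target region used for
#'   ranking: `"none"` (genomic order), `"edge"` (closest to a region
#'   boundary first) or `"middle"` (closest to the region midpoint first).
#'   Editing outcomes can depend on where the spacer sits relative to the
#'   repair templates, so the preference is exposed rather than fixed.
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(max_full_length = 1, max_seed_pam = 1,
                        gc_min = 0, gc_max = 1,
                        position = c("none", "edge", "middle")) {
  if (max_full_length < 1 || max_seed_pam < 1) {
    abort_cas3("count limits must be >= 1 (the on-target site is counted)",
               "bad_filter")
  }
  structure(list(max_full_length = max_full_length,
                 max_seed_pam = max_seed_pam,
                 gc_min = gc_min, gc_max = gc_max,
                 position = match.arg(position)),
            class = "filter_spec")
}

#' Filter and rank annotated candidates
#'
#' Removes candidates violating the [filter_spec()] and orders survivors by
#' (seed+PAM count, whole-length count, position criterion, coordinate,
#' strand with `+` before `-`). The ordering is total and deterministic:
#' permuting the input never changes the output order.
#'
#' @param candidates an annotated candidate tibble ([annotate_spacers()]).
#' @param filter a [filter_spec()].
#' @param region the target region (list or `"record:start-end"` string),
#'   required for the `"edge"`/`"middle"` position preferences.
#' @return the filtered, ordered tibble with a `rank` column.
#' @export
rank_spacers <- function(candidates, filter = filter_spec(), region = NULL) {
  if (!all(c("full_length_count", "seed_pam_count") %in% names(candidates))) {
    abort_cas3("candidates must be annotated first (annotate_spacers)",
               "unannotated")
  }
  if (is.character(region)) region <- parse_region(region)
  out <- candidates |>
    filter(.data$full_length_count <= filter$max_full_length,
           .data$seed_pam_count <= filter$max_seed_pam,
           .data$gc_fraction >= filter$gc_min,
           .data$gc_fraction <= filter$gc_max)
  if (nrow(out) == 0L) return(mutate(out, rank = integer()))
  mid <- (out$proto_start + out$proto_end) / 2
  pos_key <- switch(filter$position,
    none = out$proto_start,
    edge = {
      if (is.null(region)) abort_cas3("position = 'edge' needs a region",
                                      "missing_region")
      pmin(mid - region$start, region$end - mid)
    },
    middle = {
      if (is.null(region)) abort_cas3("position = 'middle' needs a region",
                                      "missing_region")
      abs(mid - (region$start + region$end) / 2)
    })
  out |>
    mutate(.pos = pos_key,
           .strand_ord = match(.data$strand, c("+", "-"))) |>
    arrange(.data$seed_pam_count, .data$full_length_count, .data$.pos,
            .data$proto_start, .data$.strand_ord) |>
    select(-".pos", -".strand_ord") |>
    mutate(rank = dplyr::row_number())
}

#' Annotate, filter and rank in one step
#'
#' @inheritParams annotate_spacers
#' @inheritParams rank_spacers
#' @return the filtered, ordered candidate tibble.
#' @export
annotate_and_rank <- function(candidates, genomes, motif = pam_motif(),
                              filter = filter_spec(), region = NULL) {
  candidates |>
    annotate_spacers(genomes, motif) |>
    rank_spacers(filter, region)
}
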