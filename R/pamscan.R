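#' Describe a PAM motif and its geometry
#'
#' A PAM motif is an IUPAC pattern plus the side of the protospacer it sits
#' on. Type I systems such as the compact I-C CASCADE-Cas3 read a 5'-TTC-3'
#' PAM immediately 5' of the protospacer (`side = "5prime"`, the default);
#' `side = "3prime"` reproduces the Cas9 geometry, where the 5'-NGG-3' PAM
#' lies 3' of the protospacer.
#'
#' @param pattern IUPAC DNA pattern, length >= 1 (default `"TTC"`).
#' @param side `"5prime"` or `"3prime"`, the PAM's position relative to the
#'   protospacer on the protospacer's own strand.
#' @return a `pam_motif` object.
#' @export
#' @examples
#' pam_motif("TTC")
#' pam_motif("NGG", side = "3prime") # SpyCas9 geometry
pam_motif <- function(pattern = "TTC", side = c("5prime", "3prime")) {
  pattern <- assert_dna(pattern, "PAM pattern")
  if (nchar(pattern) < 1L) abort_cas3("PAM pattern is empty", "bad_motif")
  side <- match.arg(side)
  structure(list(pattern = pattern, side = side), class = "pam_motif")
}

#' @export
print.pam_motif <- function(x, ...) {
  cat(sprintf("<pam_motif> 5'-%s-3' (%s of protospacer)\n", x$pattern, x$side))
  invisible(x)
}

as_pam_motif <- function(motif) {
  if (inherits(motif, "pam_motif")) motif else pam_motif(motif)
}

# Masked copy of one record for motif scans: every ambiguity letter becomes
# "-", which no IUPAC pattern letter matches. This enforces the convention
# that an N in the genome can never be claimed as (part of) a PAM, while an N
# in the motif matches any of A/C/G/T.
masked_record <- function(genomes, i) {
  Biostrings::DNAString(gsub("[^ACGT]", "-", as.character(genomes[[i]])))
}

match_starts0 <- function(pattern, subject, max_mm = 0) {
  v <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mm,
                                fixed = c(pattern = FALSE, subject = TRUE))
  BiocGenerics::start(v) - 1L
}

#' Scan a genome for PAM motif occurrences
#'
#' Finds every occurrence of the motif on the requested strands of every
#' record. Overlapping occurrences are all reported, and the two strands are
#' scanned independently (a palindromic match counts once per strand). All
#' coordinates are 0-based half-open on the plus strand; `pam_seq` is the
#' motif as read 5'->3' on its own strand.
#'
#' @param genomes a genome set ([genome_set()] / [read_genome()]).
#' @param motif a [pam_motif()] or IUPAC pattern string.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @return a tibble with columns `record_id`, `pam_start`, `pam_end`,
#'   `strand`, `pam_seq`, ordered by record, then plus-strand coordinate,
#'   then strand (`+` before `-`).
#' @export
#' @examples
#' g <- genome_set(c(chr = "GTTCACGAATTC"))
#' scan_pam(g, "TTC")
scan_pam <- function(genomes, motif = pam_motif(), strands = "both") {
  motif <- as_pam_motif(motif)
  strands <- match.arg(strands, c("both", "+", "-"))
  res <- purrr::map_dfr(seq_along(genomes), function(i) {
    subj <- masked_record(genomes, i)
    plen <- nchar(motif$pattern)
    rows <- list()
    if (strands %in% c("both", "+")) {
      s0 <- match_starts0(motif$pattern, subj)
      rows$fwd <- tibble(record_id = names(genomes)[i], pam_start = s0,
                         pam_end = s0 + plen, strand = "+")
    }
    if (strands %in% c("both", "-")) {
      s0 <- match_starts0(revcomp(motif$pattern), subj)
      rows$rev <- tibble(record_id = names(genomes)[i], pam_start = s0,
                         pam_end = s0 + plen, strand = "-")
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(res) == 0L) {
    return(tibble(record_id = character(), pam_start = integer(),
                  pam_end = integer(), strand = character(),
                  pam_seq = character()))
  }
  res <- res |>
    mutate(.rec = match(.data$record_id, names(genomes))) |>
    arrange(.data$.rec, .data$pam_start, .data$strand) |>
    select(-".rec")
  recstrs <- stats::setNames(as.character(genomes), names(genomes))
  raw <- substring(recstrs[res$record_id], res$pam_start + 1, res$pam_end)
  neg <- res$strand == "-"
  if (any(neg)) raw[neg] <- revcomp(raw[neg])
  res$pam_seq <- unname(raw)
  res
}

count_motif_occurrences <- function(genomes, pattern) {
  fwd <- 0L; rev <- 0L
  for (i in seq_along(genomes)) {
    subj <- masked_record(genomes, i)
    fwd <- fwd + Biostrings::countPattern(
      pattern, subj, fixed = c(pattern = FALSE, subject = TRUE))
    rev <- rev + Biostrings::countPattern(
      revcomp(pattern), subj, fixed = c(pattern = FALSE, subject = TRUE))
  }
  c(forward = fwd, reverse = rev)
}

#' Genome-wide PAM census
#'
#' Counts every occurrence of the motif on both strands of all records and
#' reports the mean spacing between PAM sites. This is the calculation behind
#' the comparison of PAM availability between the type I-C TTC PAM and the
#' Cas9 NGG PAM in high-GC genomes: in a ~72% GC chromosome, TTC sites are
#' roughly an order of magnitude rarer than NGG sites.
#'
#' @param genomes a genome set.
#' @param motif a [pam_motif()] or pattern string.
#' @return a one-row tibble: `pattern`, `side`, `total_count`,
#'   `forward_count`, `reverse_count`, `genome_length` (sum of record
#'   lengths), `mean_spacing_bp` (genome_length / total_count, one decimal;
#'   `NA` when the motif never occurs).
#' @export
#' @examples
#' pam_census(genome_set(c(chr = "GTTCACGAATTC")), "TTC")
pam_census <- function(genomes, motif = pam_motif()) {
  motif <- as_pam_motif(motif)
  counts <- count_motif_occurrences(genomes, motif$pattern)
  total <- sum(counts)
  glen <- sum(Biostrings::width(genomes))
  tibble(pattern = motif$pattern, side = motif$side,
         total_count = as.integer(total),
         forward_count = as.integer(counts[["forward"]]),
         reverse_count = as.integer(counts[["reverse"]]),
         genome_length = glen,
         mean_spacing_bp = if (total > 0) round(glen / total, 1) else NA_real_)
}

#' Extract protospacer candidates next to PAM sites in a region
#'
#' For every PAM occurrence lying entirely inside the target region (both
#' strands), takes the `spacer_len` bases immediately adjacent on the PAM's
#' own strand — 3' of the motif for a 5'-side PAM (type I-C), 5' of it for a
#' 3'-side PAM (Cas9) — as the protospacer candidate. Candidates whose
#' protospacer would run off the record end are dropped (unless the record is
#' circular, in which case the slice wraps). The seed is the PAM-proximal
#' `seed_len` bases of the protospacer — its prefix for a 5'-side PAM, its
#' suffix for a 3'-side PAM.
#'
#' @param genomes a genome set.
#' @param region the target region: a `"record:start-end"` string (1-based
#'   inclusive, as on the command line) or a list with `record_id`, `start`,
#'   `end` (0-based half-open).
#' @param motif a [pam_motif()] or pattern string.
#' @param spacer_len protospacer length in nt (default 34, the type I-C
#'   spacer length).
#' @param seed_len seed length in nt (default 8: recognition tolerates
#'   mismatches poorly in the first 8 PAM-proximal bases).
#' @return a tibble of candidates: PAM coordinates and sequence, protospacer
#'   coordinates (`proto_start`, `proto_end`, 0-based half-open plus-strand),
#'   `protospacer`, `seed`, `gc_fraction`.
#' @export
#' @examples
#' g <- genome_set(c(chr = "ATTCGGCCAAAT"))
#' extract_spacers(g, list(record_id = "chr", start = 0, end = 12),
#'                 spacer_len = 4, seed_len = 2)
extract_spacers <- function(genomes, region, motif = pam_motif(),
                            spacer_len = 34, seed_len = 8) {
  motif <- as_pam_motif(motif)
  if (is.character(region)) region <- parse_region(region)
  if (spacer_len < 1 || seed_len < 1 || seed_len > spacer_len) {
    abort_cas3("need spacer_len >= seed_len >= 1", "bad_lengths")
  }
  i <- get_record(genomes, region$record_id)
  n <- Biostrings::width(genomes)[i]
  if (region$start < 0 || region$end > n) {
    abort_cas3("target region out of record bounds", "out_of_bounds")
  }
  empty <- tibble(record_id = character(), strand = character(),
                  pam_start = integer(), pam_end = integer(),
                  pam_seq = character(), proto_start = integer(),
                  proto_end = integer(), protospacer = character(),
                  seed = character(), gc_fraction = numeric())
  if (region$end - region$start < nchar(motif$pattern)) return(empty)
  sites <- scan_pam(genomes[i], motif) |>
    filter(.data$pam_start >= region$start, .data$pam_end <= region$end)
  if (nrow(sites) == 0L) return(empty)
  circ <- is_circular(genomes, region$record_id)
  # protospacer interval on plus-strand coordinates, by strand and PAM side
  downstream <- (motif$side == "5prime" & sites$strand == "+") |
                (motif$side == "3prime" & sites$strand == "-")
  ps <- ifelse(downstream, sites$pam_end, sites$pam_start - spacer_len)
  pe <- ps + spacer_len
  keep <- if (circ) rep(TRUE, nrow(sites)) else (ps >= 0 & pe <= n)
  sites <- sites[keep, ]; ps <- ps[keep]; pe <- pe[keep]
  if (nrow(sites) == 0L) return(empty)
  ps <- ifelse(ps < 0, ps + n, ps)  # circular wrap on the left
  pe <- ps + spacer_len
  proto <- vapply(seq_len(nrow(sites)), function(k) {
    slice_interval(genomes, region$record_id, ps[k], pe[k], sites$strand[k])
  }, character(1))
  seed <- if (motif$side == "5prime") {
    substr(proto, 1, seed_len)
  } else {
    substr(proto, spacer_len - seed_len + 1, spacer_len)
  }
  sites |>
    mutate(proto_start = as.integer(ps), proto_end = as.integer(pe),
           protospacer = proto, seed = seed,
           gc_fraction = gc_fraction(proto))
}

#' Plot candidate protospacers along the target region
#'
#' One segment per candidate at its genomic position, split by strand and
#' (when the table has been annotated) coloured by the seed+PAM off-target
#' count, the quantity used for specificity filtering.
#'
#' @param candidates a candidate tibble from [extract_spacers()] or
#'   [annotate_spacers()].
#' @return a ggplot object.
#' @export
plot_candidates <- function(candidates) {
  p <- ggplot2::ggplot(candidates,
                       ggplot2::aes(x = .data$proto_start,
                                    xend = .data$proto_end,
                                    y = .data$strand, yend = .data$strand))
  if ("seed_pam_count" %in% names(candidates)) {
    p <- p + ggplot2::geom_segment(
      ggplot2::aes(colour = factor(.data$seed_pam_count)), linewidth = 3) +
      ggplot2::labs(colour = "seed+PAM hits")
  } else {
    p <- p + ggplot2::geom_segment(linewidth = 3)
  }
  p + ggplot2::labs(x = "position (bp, 0-based)", y = "strand",
                    title = "Protospacer candidates") +
    ggplot2::theme_minimal()
}

#' Plot a PAM census comparison
#'
#' Bar chart of mean PAM spacing per motif, the quantity that makes a T-rich
#' PAM attractive in high-GC genomes.
#'
#' @param census_tbl one or more [pam_census()] rows bound together.
#' @return a ggplot object.
#' @export
plot_census <- function(census_tbl) {
  ggplot2::ggplot(census_tbl,
                  ggplot2::aes(x = .data$pattern, y = .data$mean_spacing_bp)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "PAM motif", y = "mean spacing (bp)",
                  title = "PAM density") +
    ggplot2::theme_minimal()
}
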