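#' Build a genome set from named sequences
#'
#' The package's search universe is a [Biostrings::DNAStringSet] whose records
#' carry a per-record `circular` flag in `mcols()`. Sequences are
#' uppercase-normalized and validated against the IUPAC DNA alphabet
#' (`U` and anything non-IUPAC is rejected).
#'
#' @param seqs a named character vector of DNA strings, or a `DNAStringSet`.
#' @param circular logical, recycled to one flag per record. Bacterial
#'   chromosomes handled here (e.g. *Streptomyces* chromosomes) are linear, so
#'   the default is `FALSE`; wrap-around slicing is opt-in per record.
#' @return a `DNAStringSet` with a `circular` metadata column.
#' @export
#' @examples
#' genome_set(c(chr = "ACGTACGT"))
genome_set <- function(seqs, circular = FALSE) {
  if (methods::is(seqs, "XStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (length(seqs) == 0L) abort_cas3("no sequences given", "empty_input")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort_cas3("every record needs a non-empty id", "missing_id")
  }
  if (anyDuplicated(ids)) {
    abort_cas3(sprintf("duplicate record ids: %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "duplicate_ids")
  }
  seqs <- vapply(seq_along(seqs), function(i) {
    s <- assert_dna(seqs[[i]], sprintf("record '%s'", ids[i]))
    if (nchar(s) < 1L) abort_cas3(sprintf("record '%s' is empty", ids[i]),
                                  "empty_sequence")
    s
  }, character(1))
  out <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  S4Vectors::mcols(out)$circular <- rep_len(as.logical(circular), length(out))
  out
}

#' Read a genome FASTA
#'
#' Reads a single- or multi-record FASTA into a genome set. Record ids are the
#' first whitespace-delimited token of each header; input order is preserved.
#'
#' @param path path to a FASTA file.
#' @param circular logical, recycled per record (see [genome_set()]).
#' @return a `DNAStringSet` genome set.
#' @export
read_genome <- function(path, circular = FALSE) {
  if (!file.exists(path)) {
    abort_cas3(sprintf("file not found: %s", path), "missing_file")
  }
  # read as raw strings first: DNAStringSet parsing would silently drop
  # letters outside its alphabet instead of rejecting them
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) {
                  abort_cas3(sprintf("cannot read FASTA '%s': %s", path,
                                     conditionMessage(e)), "bad_fasta")
                })
  if (length(x) == 0L) {
    abort_cas3(sprintf("FASTA '%s' contains no records", path), "empty_fasta")
  }
  names(x) <- sub("\\s.*$", "", names(x))
  genome_set(x, circular = circular)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

record_ids <- function(genomes) names(genomes)

get_record <- function(genomes, record_id) {
  i <- match(record_id, names(genomes))
  if (is.na(i)) {
    abort_cas3(sprintf("no record '%s' in genome set", record_id),
               "unknown_record")
  }
  i
}

is_circular <- function(genomes, record_id) {
  mc <- S4Vectors::mcols(genomes)
  circ <- if (!is.null(mc) && "circular" %in% colnames(mc)) mc$circular
          else rep(FALSE, length(genomes))
  isTRUE(circ[get_record(genomes, record_id)])
}

#' Reverse complement of DNA strings
#'
#' IUPAC-aware reverse complementation (N stays N, R pairs with Y, ...).
#'
#' @param seq character vector of DNA strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("TTC") # "GAA"
revcomp <- function(seq) {
  if (length(seq) == 0L) return(character())
  seq <- vapply(seq, assert_dna, character(1), USE.NAMES = FALSE)
  unname(as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))))
}

#' Extract an interval from a genome record
#'
#' Coordinates are 0-based half-open internally ("[start, end)"). On the `-`
#' strand the reverse complement of the plus-strand substring is returned.
#' Intervals may run past the record end only for records flagged circular,
#' in which case the slice wraps around the origin.
#'
#' @param genomes a genome set ([genome_set()]).
#' @param record_id record to slice.
#' @param start,end 0-based half-open interval, `end > start`.
#' @param strand `"+"` or `"-"`.
#' @return a DNA string.
#' @export
#' @examples
#' g <- genome_set(c(chr = "GATTACA"))
#' slice_interval(g, "chr", 1, 4)        # "ATT"
#' slice_interval(g, "chr", 1, 4, "-")   # "AAT"
slice_interval <- function(genomes, record_id, start, end, strand = "+") {
  i <- get_record(genomes, record_id)
  n <- Biostrings::width(genomes)[i]
  start <- as.numeric(start); end <- as.numeric(end)
  if (start < 0 || end <= start) {
    abort_cas3("need 0 <= start < end", "bad_interval")
  }
  circ <- is_circular(genomes, record_id)
  if (!circ && end > n) {
    abort_cas3(sprintf("interval [%d,%d) out of bounds for linear record '%s' (length %d)",
                       start, end, record_id, n), "out_of_bounds")
  }
  if (circ && (end - start) > n) {
    abort_cas3("interval longer than the circular record", "out_of_bounds")
  }
  s <- as.character(genomes[[i]])
  out <- if (end <= n) {
    substr(s, start + 1, end)
  } else {
    paste0(substr(s, start + 1, n), substr(s, 1, end - n))
  }
  if (strand == "-") out <- revcomp(out)
  out
}

#' Generate a random synthetic genome
#'
#' Draws i.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`
#' under a fixed seed, emulating the base composition (but not the codon or
#' repeat structure) of a high-GC bacterial chromosome. Identical arguments
#' give bytewise-identical output; the caller's RNG stream is left untouched.
#'
#' @param length genome length in bp (>= 1).
#' @param gc target GC fraction in `[0, 1]`; streptomycete chromosomes are
#'   around 0.72.
#' @param seed integer seed.
#' @param id record id for the single generated record.
#' @param circular logical flag for the generated record.
#' @return a one-record genome set.
#' @export
generate_genome <- function(length, gc = 0.72, seed = 1, id = "synthetic",
                            circular = FALSE) {
  if (length < 1) abort_cas3("length must be >= 1", "bad_length")
  if (gc < 0 || gc > 1) abort_cas3("gc must be in [0, 1]", "bad_gc")
  bases <- with_local_seed(seed, {
    sample(c("A", "C", "G", "T"), size = length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  genome_set(stats::setNames(paste(bases, collapse = ""), id),
             circular = circular)
}

#' Plant copies of a sequence into a genome
#'
#' Overwrites the genome at each given offset with `insert` (or its reverse
#' complement for `-` strand plants), leaving the genome length unchanged.
#' Used to build ground-truth fixtures with known on-/off-target sites.
#'
#' @param genomes a genome set.
#' @param insert DNA string to plant.
#' @param positions a data frame with columns `offset` (0-based) and `strand`
#'   (`"+"`/`"-"`), or a numeric vector of offsets (all `+`).
#' @param record_id record to modify (default: the first record).
#' @return the modified genome set.
#' @export
plant_sites <- function(genomes, insert, positions,
                        record_id = record_ids(genomes)[1]) {
  insert <- assert_dna(insert, "insert")
  if (is.numeric(positions)) {
    positions <- tibble(offset = positions, strand = "+")
  }
  positions <- as_tibble(positions)
  if (nrow(positions) == 0L) return(genomes)
  i <- get_record(genomes, record_id)
  n <- Biostrings::width(genomes)[i]
  w <- nchar(insert)
  off <- as.numeric(positions$offset)
  if (any(off < 0 | off + w > n)) {
    abort_cas3("plant offset out of bounds", "out_of_bounds")
  }
  o <- order(off)
  if (any(diff(off[o]) < w)) {
    abort_cas3("planted copies overlap", "overlapping_plants")
  }
  s <- as.character(genomes[[i]])
  for (k in seq_len(nrow(positions))) {
    piece <- if (positions$strand[k] == "-") revcomp(insert) else insert
    substr(s, off[k] + 1, off[k] + w) <- piece
  }
  seqs <- stats::setNames(as.character(genomes), names(genomes))
  seqs[[record_id]] <- s
  mc <- S4Vectors::mcols(genomes)
  genome_set(seqs, circular = if (!is.null(mc)) mc$circular else FALSE)
}

#' Write spacer candidates as BED6
#'
#' One line per candidate protospacer: 0-based half-open coordinates, the
#' candidate name, the seed+PAM off-target count as the score (0 when the
#' table is unannotated), and the strand.
#'
#' @param candidates a candidate tibble from [extract_spacers()] (optionally
#'   annotated by [annotate_spacers()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(candidates, path) {
  score <- if ("seed_pam_count" %in% names(candidates)) {
    candidates$seed_pam_count
  } else {
    rep(0L, nrow(candidates))
  }
  name <- sprintf("spacer_%s_%d_%s", candidates$record_id,
                  candidates$proto_start, candidates$strand)
  bed <- tibble(chrom = candidates$record_id,
                start = candidates$proto_start,
                end = candidates$proto_end,
                name = name, score = score, strand = candidates$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a report table as TSV
#'
#' Adds 1-based inclusive coordinate columns alongside any internal 0-based
#' half-open ones (columns ending in `_start` gain a `*_start1` twin) so bench
#' users can read positions directly.
#'
#' @param tbl a tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(tbl, path) {
  for (col in grep("(^|_)start$", names(tbl), value = TRUE)) {
    tbl[[paste0(col, "1")]] <- as.integer(tbl[[col]]) + 1L
  }
  readr::write_tsv(tbl, path)
  invisible(path)
}
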