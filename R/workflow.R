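#' End-to-end design of a deletion or substitution experiment
#'
#' Runs the whole design workflow for one target interval: extracts
#' protospacer candidates across the deletion region (edges and interior),
#' annotates and ranks them genome-wide, designs the repair template
#' (homology arms, optional cargo, restriction screening), and generates the
#' Gibson spacer-cloning primers for the top candidates. Optionally writes
#' TSV/BED/FASTA reports and a parameter log; re-running with the same
#' inputs produces byte-identical files (nothing consults the clock or
#' unseeded randomness).
#'
#' @param genomes a genome set ([read_genome()]).
#' @param deletion the interval to delete: `"record:start-end"` (1-based
#'   inclusive) or a 0-based half-open list.
#' @param motif a [pam_motif()].
#' @param spacer_len,seed_len protospacer and seed lengths (defaults 34, 8).
#' @param arm_len homology-arm length (default 1000).
#' @param cargo optional cargo sequence placed between the arms.
#' @param kit a [cloning_kit()]; its spacer length is aligned to
#'   `spacer_len`.
#' @param filter a [filter_spec()].
#' @param top_k number of ranked candidates to design primers for.
#' @param out_dir if non-`NULL`, directory to write reports into.
#' @return a `deletion_design` object: `candidates` (all, annotated),
#'   `ranked` (survivors in rank order), `template`, `primer_sets` (one per
#'   top candidate), and `params`.
#' @export
design_deletion <- function(genomes, deletion, motif = pam_motif(),
                            spacer_len = 34, seed_len = 8, arm_len = 1000,
                            cargo = "", kit = toy_kit(),
                            filter = filter_spec(), top_k = 3,
                            out_dir = NULL) {
  motif <- as_pam_motif(motif)
  if (is.character(deletion)) deletion <- parse_region(deletion)
  kit$spacer_len <- spacer_len
  candidates <- extract_spacers(genomes, deletion, motif,
                                spacer_len = spacer_len, seed_len = seed_len)
  if (nrow(candidates) == 0L) {
    abort_cas3(sprintf("no PAM in region %s",
                       format_region(deletion$record_id, deletion$start,
                                     deletion$end)),
               "no_candidates")
  }
  annotated <- annotate_spacers(candidates, genomes, motif)
  ranked <- rank_spacers(annotated, filter, deletion)
  if (nrow(ranked) == 0L) {
    abort_cas3("no candidate survives the off-target filters",
               "no_surviving_candidate")
  }
  template <- design_repair_template(genomes, deletion, arm_len = arm_len,
                                     cargo = cargo, enzymes = kit$enzymes)
  top <- utils::head(ranked, top_k)
  primer_sets <- purrr::map(top$protospacer, design_spacer_primers, kit = kit)
  names(primer_sets) <- sprintf("candidate_%d", seq_len(nrow(top)))
  out <- structure(list(candidates = annotated, ranked = ranked,
                        template = template, primer_sets = primer_sets,
                        params = list(
                          deletion = deletion, pam = motif$pattern,
                          pam_side = motif$side, spacer_len = spacer_len,
                          seed_len = seed_len, arm_len = arm_len,
                          cargo_len = nchar(cargo), top_k = top_k,
                          filter = unclass(filter))),
                   class = "deletion_design")
  if (!is.null(out_dir)) write_design_reports(out, out_dir)
  out
}

#' @export
print.deletion_design <- function(x, ...) {
  d <- x$params$deletion
  cat(sprintf("<deletion_design> %s [%d,%d): %d candidates, %d pass filters\n",
              d$record_id, d$start, d$end, nrow(x$candidates),
              nrow(x$ranked)))
  cat(sprintf("top candidate: %s (full-length %d, seed+PAM %d)\n",
              x$ranked$protospacer[1], x$ranked$full_length_count[1],
              x$ranked$seed_pam_count[1]))
  print(glance(x$template))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.deletion_design <- function(x, ...) {
  tibble(n_candidates = nrow(x$candidates),
         n_surviving = nrow(x$ranked),
         top_spacer = x$ranked$protospacer[1],
         top_seed_pam_count = x$ranked$seed_pam_count[1],
         top_full_length_count = x$ranked$full_length_count[1],
         edited_length = nchar(x$template$edited_locus))
}

#' @exportS3Method generics::tidy
tidy.deletion_design <- function(x, ...) x$ranked

#' Write the report files for a deletion design
#'
#' Emits `candidates.tsv` (all annotated candidates, with 1-based coordinate
#' twins), `candidates.bed` (BED6, score = seed+PAM count),
#' `ranked.tsv`, `primers.tsv` and `primers.fasta` for the top candidates,
#' `repair_template.fasta`, `edited_locus.fasta`, and `run_log.txt`
#' recording every parameter and the package version.
#'
#' @param design a `deletion_design`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_design_reports <- function(design, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_report_tsv(design$candidates, p("candidates.tsv"))
  write_bed(design$candidates, p("candidates.bed"))
  write_report_tsv(design$ranked, p("ranked.tsv"))
  primer_tbl <- purrr::imap_dfr(design$primer_sets, function(ps, nm) {
    mutate(tidy(ps), candidate = nm, .before = 1)
  })
  readr::write_tsv(primer_tbl, p("primers.tsv"))
  write_fasta(stats::setNames(primer_tbl$seq,
                              paste(primer_tbl$candidate, primer_tbl$name,
                                    sep = "_")),
              p("primers.fasta"))
  tpl <- design$template
  tpl_seqs <- c(left_arm = tpl$left_arm, right_arm = tpl$right_arm,
                junction = tpl$junction_seq)
  if (nchar(tpl$cargo) > 0) tpl_seqs <- c(tpl_seqs, cargo = tpl$cargo)
  write_fasta(tpl_seqs, p("repair_template.fasta"))
  write_fasta(stats::setNames(tpl$edited_locus,
                              paste0(tpl$record_id, "_edited")),
              p("edited_locus.fasta"))
  params <- design$params
  log_lines <- c(
    sprintf("cas3design version %s",
            as.character(utils::packageVersion("cas3design"))),
    sprintf("deletion: %s", format_region(params$deletion$record_id,
                                          params$deletion$start,
                                          params$deletion$end)),
    sprintf("pam: %s (%s)", params$pam, params$pam_side),
    sprintf("spacer_len: %d  seed_len: %d", params$spacer_len,
            params$seed_len),
    sprintf("arm_len: %d  cargo_len: %d  top_k: %d", params$arm_len,
            params$cargo_len, params$top_k),
    sprintf("filter: max_full_length=%d max_seed_pam=%d gc=[%g,%g] position=%s",
            params$filter$max_full_length, params$filter$max_seed_pam,
            params$filter$gc_min, params$filter$gc_max,
            params$filter$position))
  writeLines(log_lines, p("run_log.txt"))
  invisible(out_dir)
}

#' Command wrappers for the CLI
#'
#' Thin, file-oriented wrappers over the package operations, used by the
#' `cas3design` command-line script (`inst/cli/cas3design`): `cmd_census`
#' runs PAM censuses, `cmd_design` the end-to-end deletion workflow,
#' `cmd_offtarget` a single-spacer off-target report, `cmd_primers` the
#' spacer-cloning primer design, `cmd_template` the repair-template design,
#' `cmd_verify_assembly` the in-silico Gibson round trip for a spacer, and
#' `cmd_fixture` the seeded synthetic-genome generator.
#'
#' @param genome_path path to a genome FASTA.
#' @param pams character vector of PAM patterns (`census`).
#' @name cli-commands
#' @return tibbles or design objects; see the underlying functions.
#' @export
cmd_census <- function(genome_path, pams = c("TTC", "NGG")) {
  g <- read_genome(genome_path)
  purrr::map_dfr(pams, function(p) {
    side <- if (toupper(p) == "NGG") "3prime" else "5prime"
    pam_census(g, pam_motif(p, side = side))
  })
}

#' @rdname cli-commands
#' @param region,deletion 1-based inclusive `"record:start-end"` strings.
#' @param out_dir report directory.
#' @param ... passed on to [design_deletion()].
#' @export
cmd_design <- function(genome_path, deletion, out_dir = NULL, ...) {
  design_deletion(read_genome(genome_path), deletion, out_dir = out_dir, ...)
}

#' @rdname cli-commands
#' @param spacer a protospacer sequence.
#' @param pam PAM pattern.
#' @param seed_len seed length.
#' @param max_mm mismatch radius for the per-hit report.
#' @param require_pam restrict mismatch hits to PAM-flanked ones.
#' @export
cmd_offtarget <- function(genome_path, spacer, pam = "TTC", seed_len = 8,
                          max_mm = 3, require_pam = FALSE) {
  g <- read_genome(genome_path)
  motif <- pam_motif(pam)
  seed <- if (motif$side == "5prime") substr(spacer, 1, seed_len) else
    substr(spacer, nchar(spacer) - seed_len + 1, nchar(spacer))
  list(summary = tibble(
         spacer = spacer,
         full_length_count = count_full_length(spacer, g),
         seed_pam_count = count_seed_pam(seed, g, motif)),
       hits = mismatch_scan(spacer, g, max_mm = max_mm,
                            require_pam = require_pam, motif = motif))
}

#' @rdname cli-commands
#' @param kit_path path to a kit JSON ([read_kit()]); `NULL` for the toy kit.
#' @export
cmd_primers <- function(spacer, kit_path = NULL) {
  kit <- if (is.null(kit_path)) toy_kit() else read_kit(kit_path)
  design_spacer_primers(spacer, kit)
}

#' @rdname cli-commands
#' @param arm_len homology-arm length.
#' @param cargo_path optional FASTA whose first record is the cargo.
#' @export
cmd_template <- function(genome_path, deletion, arm_len = 1000,
                         cargo_path = NULL, kit_path = NULL) {
  kit <- if (is.null(kit_path)) toy_kit() else read_kit(kit_path)
  cargo <- if (is.null(cargo_path)) "" else
    as.character(read_genome(cargo_path)[[1]])
  design_repair_template(read_genome(genome_path), deletion,
                         arm_len = arm_len, cargo = cargo,
                         enzymes = kit$enzymes)
}

#' @rdname cli-commands
#' @export
cmd_verify_assembly <- function(spacer, kit_path = NULL) {
  kit <- if (is.null(kit_path)) toy_kit() else read_kit(kit_path)
  if (is.null(kit$backbone)) {
    abort_cas3("assembly verification needs a kit with a backbone", "bad_kit")
  }
  ps <- design_spacer_primers(spacer, kit)
  digested <- digest_circular(kit$backbone,
                              kit$enzymes[kit$destination_enzymes])
  keep <- !grepl(kit$repeat1, digested$seq, fixed = TRUE)
  simulate_gibson(c(ps$fragment_A, ps$fragment_B),
                  backbone_digested = digested$seq[keep],
                  min_overlap = kit$min_overlap)
}

#' @rdname cli-commands
#' @param length,gc,seed synthetic-genome parameters ([generate_genome()]).
#' @param out_fasta output FASTA path.
#' @export
cmd_fixture <- function(length, gc = 0.72, seed = 1, out_fasta = NULL) {
  g <- generate_genome(length, gc = gc, seed = seed)
  if (!is.null(out_fasta)) write_fasta(g, out_fasta)
  g
}
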