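# Independent brute-force oracles, deliberately written in plain base R with
# no calls into the package's matching code paths.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_revcomp <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

iupac_regex <- function(pat) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste0(map[strsplit(pat, "", fixed = TRUE)[[1]]], collapse = "")
}

# 0-based start offsets of every (overlapping) occurrence of an IUPAC
# pattern on the plus strand; genome ambiguity letters match nothing.
oracle_match_starts <- function(pattern, subject) {
  L <- nchar(pattern); n <- nchar(subject)
  if (n < L) return(integer())
  wins <- substring(subject, 1:(n - L + 1), L:n)
  which(grepl(paste0("^", iupac_regex(pattern), "$"), wins)) - 1L
}

oracle_count_both <- function(pattern, subject) {
  length(oracle_match_starts(pattern, subject)) +
    length(oracle_match_starts(oracle_revcomp(pattern), subject))
}

# plus-strand sliding Hamming scan: data.frame(start, mm) for mm <= max_mm
oracle_hamming <- function(query, subject, max_mm) {
  L <- nchar(query); n <- nchar(subject)
  if (n < L) return(data.frame(start = integer(), mm = integer()))
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  nw <- n - L + 1
  mm <- integer(nw)
  for (j in seq_len(L)) mm <- mm + (s[j:(j + nw - 1)] != q[j])
  idx <- which(mm <= max_mm)
  data.frame(start = idx - 1L, mm = mm[idx])
}

oracle_hamming_both <- function(query, subject, max_mm) {
  fwd <- oracle_hamming(query, subject, max_mm)
  rev <- oracle_hamming(oracle_revcomp(query), subject, max_mm)
  out <- rbind(cbind(fwd, strand = rep("+", nrow(fwd))),
               cbind(rev, strand = rep("-", nrow(rev))))
  out[order(out$start, out$strand), , drop = FALSE]
}

# 0-based offsets of a literal site on either strand of a linear sequence
oracle_site_offsets <- function(site, subject) {
  offs <- integer()
  for (s in unique(c(site, oracle_revcomp(site)))) {
    m <- gregexpr(s, subject, fixed = TRUE)[[1]]
    offs <- c(offs, m[m > 0] - 1L)
  }
  sort(unique(offs))
}

# direct string surgery: toy backbone with `spacer` replacing the slot
# between the repeats, as a canonical-rotation string
oracle_spacer_plasmid <- function(kit, spacer) {
  bb <- kit$backbone
  r1e <- regexpr(kit$repeat1, bb, fixed = TRUE) + nchar(kit$repeat1) - 1L
  r2s <- regexpr(kit$repeat2, bb, fixed = TRUE)
  canonical_rotation(paste0(substr(bb, 1, r1e), spacer,
                            substr(bb, r2s, nchar(bb))))
}

# occurrences of a literal string in a circular sequence
circ_count_test <- function(x, circle) {
  dbl <- paste0(circle, substr(circle, 1, nchar(x) - 1))
  m <- gregexpr(x, dbl, fixed = TRUE)[[1]]
  sum(m > 0)
}

# a fixed 34-nt protospacer whose seed (first 8 nt) is AT-rich, so chance
# occurrences of PAM+seed in a high-GC background are vanishingly unlikely
fixture_protospacer <- function() {
  paste0("ATTATAAT", "GCGTCCGGAGCATCGATTGGCCAATA")
}
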