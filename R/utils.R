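#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

abort_cas3 <- function(message, class) {
  rlang::abort(message, class = c(paste0("cas3design_error_", class),
                                  "cas3design_error"))
}

assert_dna <- function(x, what = "sequence", iupac = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort_cas3(sprintf("%s must be a single character string", what),
               "bad_sequence")
  }
  x <- toupper(x)
  letters <- if (iupac) IUPAC_LETTERS else c("A", "C", "G", "T")
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]), letters)
  if (length(bad) > 0L) {
    abort_cas3(sprintf("%s contains non-DNA letters: %s", what,
                       paste(bad, collapse = ", ")),
               "non_dna_alphabet")
  }
  x
}

#' GC fraction of a DNA string
#'
#' Fraction of G or C letters among the unambiguous (A/C/G/T) letters of each
#' input sequence. Ambiguity letters are ignored in both numerator and
#' denominator; S (G or C) is not counted.
#'
#' @param seq character vector of DNA strings.
#' @return numeric vector of fractions in `[0, 1]` (NaN for sequences with no
#'   unambiguous letters).
#' @export
gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    acgt <- ch %in% c("A", "C", "G", "T")
    if (!any(acgt)) return(NaN)
    sum(ch %in% c("G", "C")) / sum(acgt)
  }, numeric(1), USE.NAMES = FALSE)
}

# Run code under a temporary RNG state so seeded generators never clobber the
# caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parse a 1-based inclusive region string
#'
#' Converts the bench-user coordinate convention used on the command line
#' (`"record:start-end"`, 1-based, inclusive of both endpoints) to the
#' package's internal 0-based half-open convention.
#'
#' @param spec a string like `"chr:1001-2000"`.
#' @return a list with `record_id`, `start` (0-based) and `end` (exclusive).
#' @seealso [format_region()] for the inverse.
#' @export
#' @examples
#' parse_region("chr:1-10") # start 0, end 10
parse_region <- function(spec) {
  m <- regmatches(spec, regexec("^(.+):([0-9]+)-([0-9]+)$", spec))[[1]]
  if (length(m) != 4L) {
    abort_cas3(sprintf("cannot parse region '%s'; expected record:start-end",
                       spec), "bad_region")
  }
  start1 <- as.numeric(m[3]); end1 <- as.numeric(m[4])
  if (start1 < 1 || end1 < start1) {
    abort_cas3(sprintf("region '%s' has an empty or negative extent", spec),
               "bad_region")
  }
  list(record_id = m[2], start = start1 - 1, end = end1)
}

#' Format an internal region as a 1-based inclusive string
#'
#' @param record_id record name.
#' @param start,end 0-based half-open interval.
#' @return a `"record:start-end"` string (1-based inclusive).
#' @export
format_region <- function(record_id, start, end) {
  sprintf("%s:%d-%d", record_id, as.integer(start) + 1L, as.integer(end))
}
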