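#' Construct a primer pair
#'
#' A forward primer (5'->3' on the plus strand) and a reverse primer
#' (5'->3' as conventionally written, i.e. on the minus strand), with
#' bounds on the product size. Product size is measured from the forward
#' primer's 5' start to the reverse primer's 5' start on the plus strand,
#' inclusive of both primer footprints — the convention under which the
#' 341F/805R V3-V4 product is ~465 nt.
#'
#' @param forward,reverse `primer` objects or IUPAC strings.
#' @param min_amplicon_len,max_amplicon_len Product size bounds in nt. The
#'   defaults (50-2000) only guard against pathological self-priming on
#'   long records.
#' @return An object of class `primer_pair`.
#' @examples
#' primer_pair("CCTACGGGNBGCWSCAG", "GACTACNVGGGTATCTAATCC")
#' @export
primer_pair <- function(forward, reverse,
                        min_amplicon_len = 50L, max_amplicon_len = 2000L) {
  forward <- .as_primer(forward, "forward")
  reverse <- .as_primer(reverse, "reverse")
  stopifnot(min_amplicon_len > 0L, min_amplicon_len <= max_amplicon_len)
  structure(list(forward = forward, reverse = reverse,
                 min_amplicon_len = as.integer(min_amplicon_len),
                 max_amplicon_len = as.integer(max_amplicon_len)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s + %s (product %d-%d nt)\n",
              x$forward$name, x$reverse$name,
              x$min_amplicon_len, x$max_amplicon_len))
  invisible(x)
}

# Count mismatches of an encoded primer against an encoded subject window.
# A position mismatches when the primer code's base set and the subject
# code's base set are disjoint (bitwAnd == 0). In strict-subject mode any
# non-ACGT subject code counts as a mismatch regardless of the primer code.
.count_mm <- function(pmask, smask_window, strict_subject = FALSE) {
  mm <- bitwAnd(pmask, smask_window) == 0L
  if (strict_subject) {
    mm <- mm | !(smask_window %in% c(1L, 2L, 4L, 8L))
  }
  sum(mm)
}

#' Mismatches of a primer placed at a position
#'
#' Counts positions where the primer code's base set and the subject code's
#' base set are disjoint. Subject ambiguity codes expand like primer codes
#' (intersection semantics), so `N` in the subject matches anything; with
#' `strict_subject = TRUE` any non-ACGT subject character is a mismatch.
#'
#' @param primer A `primer` or IUPAC string.
#' @param subject Subject nucleotide string.
#' @param pos 1-based start of the window on the subject.
#' @param strict_subject Count ambiguous subject characters as mismatches.
#' @return Integer mismatch count.
#' @examples
#' mismatches_at("ASC", "ATC", 1) # 1: S={C,G} vs T
#' @export
mismatches_at <- function(primer, subject, pos, strict_subject = FALSE) {
  primer <- .as_primer(primer)
  subject <- .canonicalize(subject, "subject")
  L <- primer$length
  if (pos < 1L || pos + L - 1L > nchar(subject)) {
    stop("primer window out of subject bounds", call. = FALSE)
  }
  pmask <- .encode(primer$sequence)
  smask <- .encode(substring(subject, pos, pos + L - 1L))
  .count_mm(pmask, smask, strict_subject)
}

# Core sliding scan on an encoded subject. Returns integer starts (1-based)
# and mismatch counts for windows with <= max_mismatch mismatches.
.scan_encoded <- function(pmask, smask, max_mismatch, strict_subject = FALSE) {
  L <- length(pmask)
  n <- length(smask)
  nw <- n - L + 1L
  if (nw < 1L) return(list(start = integer(0), mismatches = integer(0)))
  # windows-by-position matrix of subject masks; rowSums of disjointness
  idx <- outer(seq_len(nw), 0L:(L - 1L), `+`)
  disjoint <- bitwAnd(smask[idx], rep(pmask, each = nw)) == 0L
  if (strict_subject) {
    disjoint <- disjoint | !(smask[idx] %in% c(1L, 2L, 4L, 8L))
  }
  dim(disjoint) <- c(nw, L)
  mm <- as.integer(rowSums(disjoint))
  keep <- mm <= max_mismatch
  list(start = which(keep), mismatches = mm[keep])
}

#' Find degenerate-primer binding sites on a sequence
#'
#' Slides the primer along the plus strand of the subject; for
#' `strand = "minus"` the reverse complement of the primer is slid instead,
#' so hits always carry plus-strand coordinates. At `max_mismatch = 0` this
#' reproduces exact degenerate matching (the mismatch-0 screening mode).
#'
#' @inheritParams mismatches_at
#' @param max_mismatch Maximum mismatches allowed (0-3 typical).
#' @param strand `"plus"` or `"minus"`.
#' @return A data.frame with columns `start`, `end` (1-based inclusive,
#'   plus strand), `strand` and `mismatches`, sorted by `start`.
#' @export
find_hits <- function(primer, subject, max_mismatch = 0L,
                      strand = c("plus", "minus"), strict_subject = FALSE) {
  primer <- .as_primer(primer)
  strand <- match.arg(strand)
  subject <- .canonicalize(subject, "subject")
  query <- if (strand == "minus") reverse_complement(primer$sequence) else primer$sequence
  hits <- .scan_encoded(.encode(query), .encode(subject), max_mismatch, strict_subject)
  data.frame(start = hits$start,
             end = hits$start + primer$length - 1L,
             strand = rep(strand, length(hits$start)),
             mismatches = hits$mismatches,
             stringsAsFactors = FALSE)
}

# Internal amplicon engine on pre-encoded subject; returns data.frame rows.
.amplicons_encoded <- function(pair, smask, max_mismatch, strict_subject = FALSE) {
  fw <- .scan_encoded(.encode(pair$forward$sequence), smask,
                      max_mismatch, strict_subject)
  if (length(fw$start) == 0L) return(NULL)
  rc <- reverse_complement(pair$reverse$sequence)
  rv <- .scan_encoded(.encode(rc), smask, max_mismatch, strict_subject)
  if (length(rv$start) == 0L) return(NULL)
  Lr <- pair$reverse$length
  out <- NULL
  for (i in seq_along(fw$start)) {
    fs <- fw$start[i]
    # reverse primer 5' end on the plus strand = end of its binding window
    r5 <- rv$start + Lr - 1L
    len <- r5 - fs + 1L
    ok <- rv$start > fs & len >= pair$min_amplicon_len & len <= pair$max_amplicon_len
    if (any(ok)) {
      out <- rbind(out, data.frame(
        fwd_start = fs, fwd_mm = fw$mismatches[i],
        rev_start = r5[ok], rev_mm = rv$mismatches[ok],
        amplicon_len = len[ok], stringsAsFactors = FALSE))
    }
  }
  out
}

#' Simulate amplicon formation on one sequence
#'
#' Enumerates all (forward plus-strand site, reverse minus-strand site)
#' combinations with the reverse site strictly downstream of the forward
#' site and the product size within the pair's bounds. A record is covered
#' by the pair iff at least one amplicon forms.
#'
#' @param pair A `primer_pair`.
#' @param subject Subject nucleotide string (or a single-record slice of a
#'   `refset`'s `records`).
#' @param seq_id Id reported in the output.
#' @inheritParams find_hits
#' @return A data.frame with columns `seq_id`, `fwd_start`, `fwd_mm`,
#'   `rev_start` (reverse primer 5' position on the plus strand), `rev_mm`
#'   and `amplicon_len`; zero rows when no amplicon forms.
#' @export
simulate_amplicon <- function(pair, subject, max_mismatch = 0L,
                              seq_id = "seq", strict_subject = FALSE) {
  stopifnot(inherits(pair, "primer_pair"))
  subject <- .canonicalize(subject, "subject")
  out <- .amplicons_encoded(pair, .encode(subject), max_mismatch, strict_subject)
  if (is.null(out)) {
    return(data.frame(seq_id = character(0), fwd_start = integer(0),
                      fwd_mm = integer(0), rev_start = integer(0),
                      rev_mm = integer(0), amplicon_len = integer(0),
                      stringsAsFactors = FALSE))
  }
  cbind(data.frame(seq_id = rep(seq_id, nrow(out)), stringsAsFactors = FALSE), out)
}

#' Which records of a reference set are covered by a primer pair
#'
#' @param pair A `primer_pair`.
#' @param rs A `refset`.
#' @param max_mismatch Maximum mismatches per primer site.
#' @param mode `"pair"` (default) requires amplicon formation; `"forward"`
#'   or `"reverse"` require only that single primer to have a site (the
#'   per-primer view of coverage).
#' @param strict_subject See [mismatches_at()].
#' @return Logical vector in refset record order.
#' @export
covered <- function(pair, rs, max_mismatch = 0L,
                    mode = c("pair", "forward", "reverse"),
                    strict_subject = FALSE) {
  stopifnot(inherits(pair, "primer_pair"), inherits(rs, "refset"))
  mode <- match.arg(mode)
  seqs <- rs$records$sequence
  vapply(seqs, function(s) {
    smask <- .encode(.canonicalize(s, "subject"))
    switch(mode,
      pair = !is.null(.amplicons_encoded(pair, smask, max_mismatch, strict_subject)),
      forward = length(.scan_encoded(.encode(pair$forward$sequence), smask,
                                     max_mismatch, strict_subject)$start) > 0L,
      reverse = length(.scan_encoded(.encode(reverse_complement(pair$reverse$sequence)),
                                     smask, max_mismatch, strict_subject)$start) > 0L
    )
  }, logical(1L), USE.NAMES = FALSE)
}

#' Amplicon report for a whole reference set
#'
#' Runs [simulate_amplicon()] over every record and stacks the hits.
#'
#' @inheritParams covered
#' @return A data.frame of amplicon hits (1-based coordinates).
#' @export
amplicon_report <- function(pair, rs, max_mismatch = 0L, strict_subject = FALSE) {
  stopifnot(inherits(pair, "primer_pair"), inherits(rs, "refset"))
  rows <- lapply(seq_len(nrow(rs$records)), function(i) {
    simulate_amplicon(pair, rs$records$sequence[i], max_mismatch,
                      seq_id = rs$records$id[i], strict_subject = strict_subject)
  })
  do.call(rbind, rows)
}
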