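# IUPAC nucleotide ambiguity codes as 4-bit masks: A=1, C=2, G=4, T=8.
# Bitmask algebra makes matching (empty intersection test), complementation
# and minimal-code lookup O(1) table operations.
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A|G
  Y = 10L, # C|T
  S = 6L,  # C|G
  W = 9L,  # A|T
  K = 12L, # G|T
  M = 3L,  # A|C
  B = 14L, # C|G|T
  D = 13L, # A|G|T
  H = 11L, # A|C|T
  V = 7L,  # A|C|G
  N = 15L  # A|C|G|T
)

# mask -> symbol (minimal code for any nonempty subset of {A,C,G,T})
.MASK_SYMBOL <- character(15L)
.MASK_SYMBOL[.IUPAC_MASK] <- names(.IUPAC_MASK)

.BASES <- c("A", "C", "G", "T")

#' IUPAC nucleotide ambiguity code table
#'
#' The 15 IUPAC one-letter nucleotide codes and the subset of \{A,C,G,T\}
#' each denotes. The symbol/base-set relation is a bijection.
#'
#' @return A data.frame with columns `symbol`, `bases` (comma-separated),
#'   and `size` (number of bases denoted).
#' @examples
#' iupac_codes()
#' @export
iupac_codes <- function() {
  data.frame(
    symbol = names(.IUPAC_MASK),
    bases = vapply(.IUPAC_MASK, function(m) paste(.BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L], collapse = ","), ""),
    size = vapply(.IUPAC_MASK, function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L), 0L),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Canonicalize a nucleotide string: upper case, U -> T. Errors (with the
# offending symbol and its position) on anything outside the 15 codes.
# Gaps and stray characters are rejected, never skipped.
.canonicalize <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- chartr("u", "U", toupper(x))
  x <- gsub("U", "T", x, fixed = TRUE)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(.IUPAC_MASK))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC symbol '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  x
}

# Encode a canonical IUPAC string to its integer mask vector.
.encode <- function(x) unname(.IUPAC_MASK[strsplit(x, "", fixed = TRUE)[[1]]])

.mask_to_bases <- function(mask) .BASES[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]

#' Expand an IUPAC code to its base set
#'
#' @param symbol A single IUPAC nucleotide code (case-insensitive; `U` is
#'   accepted and treated as `T`).
#' @return Character vector of the bases (subset of A, C, G, T) the code
#'   denotes, e.g. `expand_code("W")` is `c("A", "T")`.
#' @examples
#' expand_code("W") # A, T
#' expand_code("B") # C, G, T
#' @export
expand_code <- function(symbol) {
  symbol <- .canonicalize(symbol, "code")
  if (nchar(symbol) != 1L) stop("expand_code() takes a single code", call. = FALSE)
  .mask_to_bases(.IUPAC_MASK[[symbol]])
}

#' Minimal IUPAC code for a base set
#'
#' Inverse of [expand_code()]: the unique code whose base set equals `bases`.
#'
#' @param bases Nonempty character vector drawn from A, C, G, T (duplicates
#'   allowed).
#' @return A single IUPAC symbol.
#' @examples
#' code_for(c("A", "T")) # "W"
#' @export
code_for <- function(bases) {
  if (length(bases) == 0L) stop("code_for() requires a nonempty base set", call. = FALSE)
  bases <- unique(gsub("U", "T", toupper(bases)))
  if (!all(bases %in% .BASES)) {
    stop(sprintf("code_for(): not a base: '%s'", setdiff(bases, .BASES)[1]), call. = FALSE)
  }
  mask <- sum(.IUPAC_MASK[bases])
  .MASK_SYMBOL[mask]
}

#' Watson-Crick complement of an IUPAC code
#'
#' The complement of a degenerate code is the code denoting the complements
#' of its base set; the operation is an involution (W and S are
#' self-complementary, V maps to B, etc.).
#'
#' @inheritParams expand_code
#' @return A single IUPAC symbol.
#' @examples
#' complement_code("V") # "B"
#' @export
complement_code <- function(symbol) {
  symbol <- .canonicalize(symbol, "code")
  if (nchar(symbol) != 1L) stop("complement_code() takes a single code", call. = FALSE)
  .MASK_SYMBOL[.complement_mask(.IUPAC_MASK[[symbol]])]
}

# complement of a mask: swap A<->T bits (1<->8) and C<->G bits (2<->4)
.complement_mask <- function(mask) {
  bitwOr(bitwOr(ifelse(bitwAnd(mask, 1L) > 0L, 8L, 0L),
                ifelse(bitwAnd(mask, 8L) > 0L, 1L, 0L)),
         bitwOr(ifelse(bitwAnd(mask, 2L) > 0L, 4L, 0L),
                ifelse(bitwAnd(mask, 4L) > 0L, 2L, 0L)))
}

#' Reverse complement of an IUPAC sequence
#'
#' @param x A primer object or an IUPAC character string, written 5'->3'.
#' @return The same type as the input: the positionwise complement in
#'   reversed order (also 5'->3').
#' @examples
#' reverse_complement("GACTACNVGGGTATCTAATCC")
#' @export
reverse_complement <- function(x) {
  if (inherits(x, "primer")) {
    return(primer(paste0(x$name, "_rc"), reverse_complement(x$sequence)))
  }
  x <- .canonicalize(x)
  masks <- rev(.complement_mask(.encode(x)))
  paste(.MASK_SYMBOL[masks], collapse = "")
}

#' Construct a primer
#'
#' A primer is a named IUPAC nucleotide sequence written 5'->3'. Input is
#' case-insensitive and `U` is mapped to `T`; any symbol outside the 15
#' IUPAC codes is an error naming the symbol and its position.
#'
#' @param name Label for the primer.
#' @param sequence IUPAC character string, length >= 1.
#' @return An object of class `primer` with elements `name`, `sequence`
#'   (canonical upper-case string) and `length`.
#' @examples
#' primer("Pro341FB", "CCTACGGGNBGCWSCAG")
#' @export
primer <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L)
  sequence <- .canonicalize(sequence, sprintf("primer '%s'", name))
  if (nchar(sequence) < 1L) stop("primer sequence must have length >= 1", call. = FALSE)
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "primer"
  )
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s  5'-%s-3'  (length %d, degeneracy %d)\n",
              x$name, x$sequence, x$length, degeneracy(x)))
  invisible(x)
}

.as_primer <- function(x, name = "primer") {
  if (inherits(x, "primer")) x else primer(name, x)
}

#' Degeneracy of a primer
#'
#' The number of distinct non-degenerate (ACGT-only) sequences the primer
#' represents: the product over positions of the size of each code's base
#' set. This is the parsimony cost used by the degeneration optimizer.
#'
#' @param x A primer object or IUPAC string.
#' @return A positive number (may exceed integer range for long, highly
#'   degenerate inputs).
#' @examples
#' degeneracy("CCTACGGGNBGCWSCAG") # 48
#' @export
degeneracy <- function(x) {
  x <- .as_primer(x)
  sizes <- vapply(.encode(x$sequence),
                  function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L), 0L)
  prod(sizes)
}

#' Enumerate all non-degenerate expansions of a primer
#'
#' @param x A primer object or IUPAC string.
#' @param cap Refuse to enumerate if the degeneracy exceeds this bound
#'   (guards against combinatorial blowup).
#' @return Character vector of all distinct ACGT-only sequences matching the
#'   primer, in lexicographic order.
#' @examples
#' enumerate_expansions("AW") # "AA" "AT"
#' @export
enumerate_expansions <- function(x, cap = 10000L) {
  x <- .as_primer(x)
  d <- degeneracy(x)
  if (d > cap) {
    stop(sprintf("primer '%s' is too degenerate to enumerate (degeneracy %s > cap %s)",
                 x$name, format(d), format(cap)), call. = FALSE)
  }
  sets <- lapply(.encode(x$sequence), .mask_to_bases)
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  out <- do.call(paste0, rev(grid))
  sort(unique(out))
}
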