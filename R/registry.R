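#' Built-in primer registry
#'
#' The universal 16S primers this package ships by name: the Pro-series
#' V3-V4 pair and its W-degenerate forward variant (Pro341FB is Pro341F
#' with position 13 widened A -> W), plus the V1-V3, V3-V4 and V4 primers
#' they are conventionally compared against.
#'
#' @return Named character vector of IUPAC sequences (5'->3').
#' @export
primer_registry <- function() {
  c(Pro341FB = "CCTACGGGNBGCWSCAG",
    Pro341F  = "CCTACGGGNBGCASCAG",
    Pro805R  = "GACTACNVGGGTATCTAATCC",
    `341F`   = "CCTACGGGNGGCWGCAG",
    `805R`   = "GACTACHVGGGTATCTAATCC",
    `27F`    = "AGAGTTTGATCCTGGCTCAG",
    `534R`   = "ATTACCGCGGCTGCTGG",
    `515F`   = "GTGCCAGCMGCCGCGGTAA",
    `806R`   = "GGACTACHVGGGTWTCTAAT")
}

#' Resolve a primer by registry name or literal sequence
#'
#' @param x A registry name (see [primer_registry()]) or an IUPAC sequence.
#' @return A `primer`.
#' @export
resolve_primer <- function(x) {
  reg <- primer_registry()
  if (x %in% names(reg)) return(primer(x, reg[[x]]))
  ok <- tryCatch({ .canonicalize(x); TRUE }, error = function(e) FALSE)
  if (!ok) {
    stop(sprintf("'%s' is neither a registered primer (%s) nor a valid IUPAC sequence",
                 x, paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  primer(x, x)
}
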