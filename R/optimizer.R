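#' Configuration for the degeneration search
#'
#' @param target_rank,target_name The clade whose coverage the search tries
#'   to maximize (e.g. family "Candidatus Brocadiaceae").
#' @param max_positions_changed Maximum number of primer positions widened
#'   in a single proposal (default 1: single-position edits).
#' @param max_degeneracy Cap on the proposed primer's degeneracy; proposals
#'   above it are not enumerated (parsimony guard).
#' @param protect_3prime Number of 3'-terminal positions never edited:
#'   3'-end mismatches abolish polymerase extension, so widening there
#'   cannot be validated by coverage alone. Set 0 to search all positions.
#' @param max_mismatch Mismatch allowance used when scoring coverage
#'   (default 0, the mismatch-0 selection metric).
#' @param min_len Quality filter applied to the target subset before
#'   profiling and scoring (strictly-greater-than, default 1200 nt).
#' @param site_search_mismatch Relaxed mismatch allowance used only to
#'   locate the binding site in target records the base primer misses.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(target_rank, target_name,
                             max_positions_changed = 1L,
                             max_degeneracy = 96L,
                             protect_3prime = 3L,
                             max_mismatch = 0L,
                             min_len = 1200L,
                             site_search_mismatch = 3L) {
  stopifnot(target_rank %in% .RANKS,
            max_positions_changed >= 1L, max_degeneracy >= 1L,
            protect_3prime >= 0L, max_mismatch >= 0L, min_len >= 0L)
  structure(list(target_rank = target_rank, target_name = target_name,
                 max_positions_changed = as.integer(max_positions_changed),
                 max_degeneracy = as.integer(max_degeneracy),
                 protect_3prime = as.integer(protect_3prime),
                 max_mismatch = as.integer(max_mismatch),
                 min_len = as.integer(min_len),
                 site_search_mismatch = as.integer(site_search_mismatch)),
            class = "optimizer_config")
}

#' Per-position base frequencies at the primer binding site
#'
#' Locates the base primer's binding site in each target record — using a
#' relaxed mismatch allowance so that records the primer currently misses
#' still contribute — and tallies the A/C/G/T composition under each primer
#' position. Sites are located independently per record (best hit: fewest
#' mismatches, ties to the leftmost), so indels between records do not
#' smear the profile. Ambiguous subject characters under a position are not
#' tallied.
#'
#' @param base_primer A `primer` or IUPAC string.
#' @param target_set A `refset` of the clade of interest.
#' @param max_mismatch Site-location allowance (default 3).
#' @return A list with `profile` (4 x L integer matrix, rows A/C/G/T,
#'   columns primer positions), `n_located` and `n_unlocated` record
#'   counts.
#' @export
site_allele_profile <- function(base_primer, target_set, max_mismatch = 3L) {
  base_primer <- .as_primer(base_primer)
  stopifnot(inherits(target_set, "refset"))
  if (length(target_set) == 0L) {
    stop("target set is empty; no binding sites to profile", call. = FALSE)
  }
  L <- base_primer$length
  pmask <- .encode(base_primer$sequence)
  prof <- matrix(0L, nrow = 4L, ncol = L,
                 dimnames = list(.BASES, seq_len(L)))
  n_located <- 0L
  for (s in target_set$records$sequence) {
    smask <- .encode(.canonicalize(s, "subject"))
    hits <- .scan_encoded(pmask, smask, max_mismatch)
    if (length(hits$start) == 0L) next
    n_located <- n_located + 1L
    best <- hits$start[which.min(hits$mismatches)]
    window <- smask[best:(best + L - 1L)]
    for (j in seq_len(L)) {
      b <- match(window[j], c(1L, 2L, 4L, 8L))
      if (!is.na(b)) prof[b, j] <- prof[b, j] + 1L
    }
  }
  if (n_located == 0L) {
    stop("no target record has a locatable binding site", call. = FALSE)
  }
  list(profile = prof, n_located = n_located,
       n_unlocated = length(target_set) - n_located)
}

# All strict widenings of one mask: masks that are proper supersets.
.strict_supersets <- function(mask) {
  all_masks <- 1:15
  all_masks[bitwAnd(all_masks, mask) == mask & all_masks != mask]
}

# Enumerate candidate edits: combinations of <= max_positions positions,
# each widened to a strict superset code, with total degeneracy capped.
.enumerate_candidates <- function(base_masks, editable, max_positions,
                                  max_degeneracy) {
  sizes <- vapply(base_masks, function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L), 0L)
  base_deg <- prod(sizes)
  per_pos <- lapply(editable, function(p) {
    ws <- .strict_supersets(base_masks[p])
    if (length(ws) == 0L) return(NULL)
    data.frame(pos = p, new_mask = ws)
  })
  per_pos <- per_pos[!vapply(per_pos, is.null, TRUE)]
  cands <- list()
  add_combo <- function(rows) {
    masks <- base_masks
    masks[rows$pos] <- rows$new_mask
    d <- prod(vapply(masks, function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L), 0L))
    if (d <= max_degeneracy) {
      cands[[length(cands) + 1L]] <<- list(masks = masks, edits = rows, degeneracy = d)
    }
  }
  # depth-limited product over distinct positions
  recurse <- function(start_idx, chosen) {
    if (nrow(chosen) > 0L) add_combo(chosen)
    if (nrow(chosen) >= max_positions) return()
    for (i in seq_along(per_pos)) {
      if (i < start_idx) next
      tab <- per_pos[[i]]
      for (r in seq_len(nrow(tab))) {
        recurse(i + 1L, rbind(chosen, tab[r, , drop = FALSE]))
      }
    }
  }
  recurse(1L, data.frame(pos = integer(0), new_mask = integer(0)))
  cands
}

#' Propose parsimony-ranked degenerations of a base primer
#'
#' The systematic search: enumerate every strict base-set widening of the
#' base forward primer at unprotected positions (up to
#' `max_positions_changed` positions at once, degeneracy capped), score
#' each candidate's pair coverage — amplicon formation with the unchanged
#' reverse primer — on the target clade and on the full reference set, and
#' rank by (1) target coverage gain, descending; (2) degeneracy multiplier,
#' ascending (parsimony); (3) number of positions changed; (4) 5'-most
#' edited position; (5) primer string. Only candidates that gain target
#' coverage are returned. Because every candidate is a positionwise
#' superset of the base, global coverage can only grow; the global delta is
#' reported, not constrained.
#'
#' @param base Base forward `primer` (or IUPAC string).
#' @param pair_reverse Reverse `primer` kept fixed during the search.
#' @param global_set A `refset`: the full collection coverage must not lose.
#' @param config An [optimizer_config()].
#' @return A data.frame of class `degeneration_proposals` with one row per
#'   proposal: `positions_changed`, `old_codes`, `new_codes`,
#'   `proposed_sequence`, `degeneracy`, `degeneracy_multiplier`,
#'   `target_total`, `target_gain_pct`, `global_delta_pct`,
#'   `parsimony_rank`. Attributes `base_primer` and `config` carry the
#'   inputs. Zero rows when the target is already fully covered or no
#'   widening helps.
#' @export
propose_degenerations <- function(base, pair_reverse, global_set, config) {
  base <- .as_primer(base, "base")
  pair_reverse <- .as_primer(pair_reverse, "reverse")
  stopifnot(inherits(global_set, "refset"), inherits(config, "optimizer_config"))

  hq <- filter_high_quality(global_set, config$min_len)
  target <- subset_by_taxon(hq, config$target_rank, config$target_name)
  if (length(target) == 0L) {
    stop(sprintf("no high-quality record for %s '%s'",
                 config$target_rank, config$target_name), call. = FALSE)
  }
  L <- base$length
  editable <- seq_len(max(0L, L - config$protect_3prime))
  if (length(editable) == 0L) {
    stop("protect_3prime leaves no editable position", call. = FALSE)
  }

  base_pair <- primer_pair(base, pair_reverse)
  cov_target_base <- covered(base_pair, target, config$max_mismatch)
  cov_global_base <- covered(base_pair, hq, config$max_mismatch)
  n_t <- length(target)
  n_g <- length(hq)

  # monotonicity shortcut: a superset primer keeps every base hit, so only
  # base-uncovered records can change state under a candidate
  open_t <- which(!cov_target_base)
  open_g <- which(!cov_global_base)
  if (length(open_t) == 0L) {
    return(.empty_proposals(base, config))
  }

  base_masks <- .encode(base$sequence)
  base_deg <- degeneracy(base)
  cands <- .enumerate_candidates(base_masks, editable,
                                 config$max_positions_changed,
                                 config$max_degeneracy)
  if (length(cands) == 0L) return(.empty_proposals(base, config))

  gain_rows <- lapply(cands, function(cand) {
    cseq <- paste(.MASK_SYMBOL[cand$masks], collapse = "")
    cpair <- primer_pair(primer("candidate", cseq), pair_reverse)
    gained_t <- sum(covered(cpair, .new_refset(target$records[open_t, , drop = FALSE]),
                            config$max_mismatch))
    if (gained_t == 0L) return(NULL)
    gained_g <- sum(covered(cpair, .new_refset(hq$records[open_g, , drop = FALSE]),
                            config$max_mismatch))
    edits <- cand$edits[order(cand$edits$pos), , drop = FALSE]
    data.frame(
      positions_changed = paste(edits$pos, collapse = ","),
      old_codes = paste(.MASK_SYMBOL[base_masks[edits$pos]], collapse = ","),
      new_codes = paste(.MASK_SYMBOL[edits$new_mask], collapse = ","),
      proposed_sequence = cseq,
      degeneracy = cand$degeneracy,
      degeneracy_multiplier = cand$degeneracy / base_deg,
      n_positions = nrow(edits),
      first_position = edits$pos[1],
      target_total = n_t,
      target_gain_pct = 100 * gained_t / n_t,
      global_delta_pct = 100 * gained_g / n_g,
      stringsAsFactors = FALSE)
  })
  gain_rows <- gain_rows[!vapply(gain_rows, is.null, TRUE)]
  if (length(gain_rows) == 0L) return(.empty_proposals(base, config))
  out <- do.call(rbind, gain_rows)
  ord <- order(-out$target_gain_pct, out$degeneracy_multiplier,
               out$n_positions, out$first_position, out$proposed_sequence)
  out <- out[ord, , drop = FALSE]
  out$parsimony_rank <- seq_len(nrow(out))
  out$n_positions <- NULL
  out$first_position <- NULL
  rownames(out) <- NULL
  attr(out, "base_primer") <- base
  attr(out, "config") <- config
  class(out) <- c("degeneration_proposals", "data.frame")
  out
}

.empty_proposals <- function(base, config) {
  out <- data.frame(positions_changed = character(0), old_codes = character(0),
                    new_codes = character(0), proposed_sequence = character(0),
                    degeneracy = numeric(0), degeneracy_multiplier = numeric(0),
                    target_total = integer(0), target_gain_pct = numeric(0),
                    global_delta_pct = numeric(0), parsimony_rank = integer(0),
                    stringsAsFactors = FALSE)
  attr(out, "base_primer") <- base
  attr(out, "config") <- config
  class(out) <- c("degeneration_proposals", "data.frame")
  out
}

#' Audit a proposed degeneration across taxonomic ranks
#'
#' Full before/after comparison of the base and proposed primers (each
#' paired with the same reverse primer) at the requested ranks, plus a
#' monotonicity audit asserting that no taxon lost coverage — the checkable
#' form of "improved target coverage without affecting previous coverage".
#'
#' @param proposal One row of a [propose_degenerations()] result (or the
#'   whole object, in which case its top-ranked row is used).
#' @param pair_reverse The reverse primer.
#' @param global_set The `refset` to audit on.
#' @param ranks_to_report Ranks for the per-rank delta tables.
#' @param max_mismatch Mismatch allowance.
#' @return A list with `proposed_sequence`, `degeneracy_before/after`,
#'   `deltas` (named list of delta data.frames per rank) and
#'   `no_taxon_lost` (TRUE when every delta is >= 0).
#' @export
verify_proposal <- function(proposal, pair_reverse, global_set,
                            ranks_to_report = rank_ladder(),
                            max_mismatch = 0L) {
  if (inherits(proposal, "degeneration_proposals")) {
    if (nrow(proposal) == 0L) stop("empty proposal list", call. = FALSE)
    base <- attr(proposal, "base_primer")
    row <- proposal[1L, ]
  } else {
    stop("proposal must come from propose_degenerations()", call. = FALSE)
  }
  pair_reverse <- .as_primer(pair_reverse, "reverse")
  prop_primer <- primer(paste0(base$name, "_prop"), row$proposed_sequence)
  if (identical(prop_primer$sequence, base$sequence)) {
    stop("proposal identical to the base primer", call. = FALSE)
  }
  pairA <- primer_pair(base, pair_reverse)
  pairB <- primer_pair(prop_primer, pair_reverse)
  deltas <- lapply(ranks_to_report, function(rk) {
    compare_primer_pairs(pairA, pairB, global_set, rk, max_mismatch)
  })
  names(deltas) <- ranks_to_report
  all_d <- unlist(lapply(deltas, function(d) d$delta_pct))
  list(proposed_sequence = prop_primer$sequence,
       degeneracy_before = degeneracy(base),
       degeneracy_after = degeneracy(prop_primer),
       deltas = deltas,
       no_taxon_lost = all(is.na(all_d) | all_d >= 0))
}
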