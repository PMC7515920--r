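#' Per-taxon coverage table at one rank
#'
#' For every taxon name present at `rank` in the reference set, the number
#' of records, the number covered by the primer pair (amplicon formation,
#' see [covered()]) and the coverage percentage. Records lacking an
#' annotation at that rank are reported in an explicit `"unclassified"` row
#' rather than silently dropped, so totals across rows always equal the
#' refset size. An empty taxon's coverage is `NA` (undefined), which is
#' distinct from 0%.
#'
#' @param pair A `primer_pair`.
#' @param rs A `refset`.
#' @param rank One of [rank_ladder()].
#' @param max_mismatch Mismatches allowed per site (default 0, the
#'   mismatch-0 screening mode).
#' @param mode Coverage mode, see [covered()].
#' @return A data.frame with columns `rank`, `taxon`, `total`, `matched`,
#'   `coverage_pct`, sorted by taxon name with `"unclassified"` last.
#' @export
coverage_by_rank <- function(pair, rs, rank, max_mismatch = 0L, mode = "pair") {
  stopifnot(inherits(rs, "refset"))
  if (!rank %in% .RANKS) {
    stop(sprintf("unknown rank '%s'", rank), call. = FALSE)
  }
  cov <- covered(pair, rs, max_mismatch, mode = mode)
  taxa <- rs$records[[rank]]
  taxa[is.na(taxa)] <- "unclassified"
  names_sorted <- sort(setdiff(unique(taxa), "unclassified"))
  if ("unclassified" %in% taxa) names_sorted <- c(names_sorted, "unclassified")
  total <- as.integer(table(factor(taxa, levels = names_sorted)))
  matched <- vapply(names_sorted, function(tx) sum(cov[taxa == tx]), 0L)
  data.frame(rank = rep(rank, length(names_sorted)),
             taxon = names_sorted,
             total = total,
             matched = as.integer(matched),
             coverage_pct = ifelse(total > 0L, 100 * matched / total, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

# join two coverage tables on taxon; totals must agree (same refset)
.delta_table <- function(covA, covB, rank) {
  stopifnot(identical(covA$taxon, covB$taxon))
  data.frame(rank = rep(rank, nrow(covA)),
             taxon = covA$taxon,
             total = covA$total,
             coverage_pct_a = covA$coverage_pct,
             coverage_pct_b = covB$coverage_pct,
             delta_pct = covB$coverage_pct - covA$coverage_pct,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare two primer pairs at one rank
#'
#' Per-taxon coverage of pair A and pair B on the same reference set, with
#' the difference in percentage points (B minus A). `min_delta_pct = 25`
#' reproduces the display rule that only shows taxa whose coverage changed
#' by more than 25 points.
#'
#' @param pairA,pairB `primer_pair` objects (A is the baseline).
#' @inheritParams coverage_by_rank
#' @param min_delta_pct Keep only rows with `|delta_pct| >= min_delta_pct`.
#' @return A data.frame with columns `rank`, `taxon`, `total`,
#'   `coverage_pct_a`, `coverage_pct_b`, `delta_pct`, sorted by descending
#'   delta then taxon name.
#' @export
compare_primer_pairs <- function(pairA, pairB, rs, rank, max_mismatch = 0L,
                                 min_delta_pct = 0, mode = "pair") {
  covA <- coverage_by_rank(pairA, rs, rank, max_mismatch, mode)
  covB <- coverage_by_rank(pairB, rs, rank, max_mismatch, mode)
  out <- .delta_table(covA, covB, rank)
  keep <- !is.na(out$delta_pct) & abs(out$delta_pct) >= min_delta_pct
  keep <- keep | (is.na(out$delta_pct) & min_delta_pct <= 0)
  out <- out[keep, , drop = FALSE]
  ord <- order(-ifelse(is.na(out$delta_pct), -Inf, out$delta_pct), out$taxon)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage deltas along a root-to-genus lineage path
#'
#' Walks a rank->name chain (e.g. phylum Planctomycetes, class
#' Planctomycetia, ..., genus Candidatus Brocadia) and reports, for each
#' step, the two pairs' coverage of that taxon and the delta — the
#' descending-the-tree view of a primer improvement. A name absent at its
#' rank yields a row with total 0 and `NA` coverage (flagged, not fatal).
#'
#' @inheritParams compare_primer_pairs
#' @param lineage_path Named character vector, names from [rank_ladder()]
#'   in ladder order, values taxon names.
#' @return A data.frame with one row per rank on the path, columns as in
#'   [compare_primer_pairs()].
#' @export
lineage_drilldown <- function(pairA, pairB, rs, lineage_path,
                              max_mismatch = 0L, mode = "pair") {
  stopifnot(inherits(rs, "refset"), length(lineage_path) >= 1L)
  ranks <- names(lineage_path)
  if (is.null(ranks) || !all(ranks %in% .RANKS)) {
    stop("lineage_path must be a named vector with ranks from the ladder", call. = FALSE)
  }
  if (is.unsorted(match(ranks, .RANKS))) {
    stop("lineage_path ranks must follow ladder order", call. = FALSE)
  }
  rows <- lapply(seq_along(lineage_path), function(i) {
    rk <- ranks[i]
    nm <- .norm_name(lineage_path[[i]])
    sub <- subset_by_taxon(rs, rk, nm)
    if (length(sub) == 0L) {
      return(data.frame(rank = rk, taxon = nm, total = 0L,
                        coverage_pct_a = NA_real_, coverage_pct_b = NA_real_,
                        delta_pct = NA_real_, stringsAsFactors = FALSE))
    }
    ca <- sum(covered(pairA, sub, max_mismatch, mode = mode))
    cb <- sum(covered(pairB, sub, max_mismatch, mode = mode))
    n <- length(sub)
    data.frame(rank = rk, taxon = nm, total = n,
               coverage_pct_a = 100 * ca / n, coverage_pct_b = 100 * cb / n,
               delta_pct = 100 * (cb - ca) / n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a coverage or delta table as TSV
#'
#' Plain TSV with a `#`-prefixed provenance header (tool version and a
#' one-line configuration echo).
#'
#' @param x A data.frame from [coverage_by_rank()], [compare_primer_pairs()]
#'   or [lineage_drilldown()].
#' @param path Output path.
#' @param config Optional named character vector echoed into the header.
#' @return Invisibly, `path`.
#' @export
write_coverage_tsv <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("primertax"))
  writeLines(sprintf("# primertax %s", ver), con)
  if (!is.null(config)) {
    writeLines(sprintf("# %s", paste(names(config), config, sep = "=",
                                     collapse = " ")), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
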