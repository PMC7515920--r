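# Rank ladder used throughout: the six ranks coverage tables are computed on.
# Intermediate RDP ranks (subclass, suborder, ...) are dropped on import.
.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' The taxonomic rank ladder
#'
#' @return Character vector `kingdom, phylum, class, order, family, genus`.
#' @export
rank_ladder <- function() .RANKS

# trim + collapse internal whitespace; "Candidatus" stays part of the name
.norm_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  x[x == ""] <- NA_character_
  x
}

# Enforce the ladder invariant: an absent rank implies all deeper ranks absent.
.truncate_lineage <- function(lin) {
  miss <- which(is.na(lin))
  if (length(miss) > 0L && miss[1] < length(.RANKS)) {
    lin[seq(miss[1], length(.RANKS))] <- NA_character_
  }
  lin
}

.empty_lineage <- function() {
  stats::setNames(rep(NA_character_, length(.RANKS)), .RANKS)
}

# Parse an RDP-style header lineage: `Lineage=Root;rootrank;Name;rank;...`
# name;rank pairs, names possibly quoted. Returns a named lineage vector or
# NULL when unparsable.
.parse_rdp_lineage <- function(header) {
  m <- regmatches(header, regexpr("Lineage=.*$", header))
  if (length(m) == 0L) return(NULL)
  body <- sub("^Lineage=", "", m)
  parts <- strsplit(body, ";", fixed = TRUE)[[1]]
  parts <- gsub('^"|"$', "", trimws(parts))
  if (length(parts) < 2L) return(NULL)
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  names_ <- parts[seq(1L, length(parts), by = 2L)]
  ranks_ <- tolower(parts[seq(2L, length(parts), by = 2L)])
  ranks_[ranks_ == "domain"] <- "kingdom"
  lin <- .empty_lineage()
  keep <- ranks_ %in% .RANKS
  if (!any(keep)) return(NULL)
  lin[ranks_[keep]] <- .norm_name(names_[keep])
  .truncate_lineage(lin)
}

# Parse a rank-prefixed lineage string `k__X;p__Y;c__;...` (greengenes-style
# prefixes). Missing or empty fields are absent ranks.
.parse_prefixed_lineage <- function(x) {
  prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__")
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  lin <- .empty_lineage()
  ok <- FALSE
  for (p in parts) {
    hit <- which(startsWith(p, prefixes))
    if (length(hit) == 1L) {
      ok <- TRUE
      lin[names(prefixes)[hit]] <- .norm_name(substring(p, 4L))
    }
  }
  if (!ok) return(NULL)
  .truncate_lineage(lin)
}

# Construct a refset from a records data.frame (id, sequence, lineage cols).
.new_refset <- function(records, provenance = "in-memory",
                        parse_report = NULL) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$id)) {
    stop(sprintf("duplicated sequence id '%s'",
                 records$id[duplicated(records$id)][1]), call. = FALSE)
  }
  records$length <- nchar(records$sequence)
  rownames(records) <- NULL
  if (is.null(parse_report)) {
    parse_report <- list(n_records = nrow(records), lineage_failures = 0L,
                         char_replacements = 0L, orphans = 0L)
  }
  structure(list(records = records, provenance = provenance,
                 parse_report = parse_report),
            class = "refset")
}

#' Build a reference set in memory
#'
#' @param ids Character vector of unique sequence ids.
#' @param sequences Nucleotide strings (IUPAC alphabet).
#' @param lineages A data.frame (or list of named vectors) with columns from
#'   [rank_ladder()]; missing columns become absent ranks.
#' @param provenance Free-text label recorded on the set.
#' @return An object of class `refset`.
#' @export
refset <- function(ids, sequences, lineages = NULL, provenance = "in-memory") {
  n <- length(ids)
  stopifnot(length(sequences) == n)
  rec <- data.frame(id = as.character(ids),
                    sequence = toupper(as.character(sequences)),
                    stringsAsFactors = FALSE)
  for (r in .RANKS) rec[[r]] <- rep(NA_character_, n)
  if (!is.null(lineages)) {
    lineages <- as.data.frame(lineages, stringsAsFactors = FALSE)
    for (r in intersect(.RANKS, names(lineages))) {
      rec[[r]] <- .norm_name(as.character(lineages[[r]]))
    }
    if (nrow(rec) > 0L) {
      lin_mat <- t(apply(rec[.RANKS], 1L, .truncate_lineage))
      rec[.RANKS] <- as.data.frame(lin_mat, stringsAsFactors = FALSE)
    }
  }
  .new_refset(rec, provenance)
}

#' @export
print.refset <- function(x, ...) {
  cat(sprintf("<refset> %d records (%s)\n", nrow(x$records), x$provenance))
  pr <- x$parse_report
  cat(sprintf("  lineage failures: %d; character replacements: %d; orphan taxonomy rows: %d\n",
              pr$lineage_failures, pr$char_replacements, pr$orphans))
  invisible(x)
}

#' @export
length.refset <- function(x) nrow(x$records)

# Replace anything outside the IUPAC alphabet (after U->T) by N and count.
.sanitize_sequences <- function(seqs) {
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad_pat <- "[^ACGTRYSWKMBDHVN]"
  n_bad <- sum(vapply(gregexpr(bad_pat, seqs), function(m) sum(m > 0L), 0L))
  if (n_bad > 0L) {
    seqs <- gsub(bad_pat, "N", seqs)
    warning(sprintf("%d non-IUPAC characters replaced by N", n_bad), call. = FALSE)
  }
  list(sequences = seqs, replaced = n_bad)
}

#' Read a taxonomically annotated 16S reference set
#'
#' Reads FASTA and attaches one lineage per record, either from RDP-style
#' headers (`Lineage=Root;rootrank;Bacteria;domain;...` name/rank pairs) or
#' from a two-column sidecar TSV (`seq_id<TAB>k__...;p__...;...;g__...`).
#' Records whose lineage cannot be parsed are kept with an empty lineage and
#' counted in the parse report. Sequence characters outside the IUPAC
#' alphabet are replaced by `N` with a warning (public 16S records contain
#' stray characters; failing hard would block whole-database runs).
#'
#' @param fasta_path Path to a FASTA file. Duplicated ids are fatal.
#' @param taxonomy_path Optional path to the sidecar TSV; when `NULL` the
#'   RDP header dialect is assumed. TSV ids absent from the FASTA are
#'   recorded as orphans, not errors.
#' @return A `refset`; its `parse_report` counts records, lineage failures,
#'   character replacements and orphan taxonomy rows.
#' @export
read_refset <- function(fasta_path, taxonomy_path = NULL) {
  if (!file.exists(fasta_path)) {
    stop(sprintf("FASTA file not found: %s", fasta_path), call. = FALSE)
  }
  raw <- Biostrings::readBStringSet(fasta_path)
  headers <- names(raw)
  ids <- vapply(strsplit(headers, "[ \t]"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated FASTA id '%s'", ids[duplicated(ids)][1]), call. = FALSE)
  }
  san <- .sanitize_sequences(as.character(raw))

  lineage_failures <- 0L
  orphans <- 0L
  lin_list <- vector("list", length(ids))

  if (is.null(taxonomy_path)) {
    for (i in seq_along(ids)) {
      lin <- .parse_rdp_lineage(headers[i])
      if (is.null(lin)) {
        lineage_failures <- lineage_failures + 1L
        lin <- .empty_lineage()
      }
      lin_list[[i]] <- lin
    }
  } else {
    if (!file.exists(taxonomy_path)) {
      stop(sprintf("taxonomy file not found: %s", taxonomy_path), call. = FALSE)
    }
    tsv <- utils::read.delim(taxonomy_path, header = FALSE, sep = "\t",
                             quote = "", comment.char = "#",
                             stringsAsFactors = FALSE,
                             col.names = c("id", "lineage")[1:2],
                             colClasses = "character", fill = TRUE)
    tax_map <- new.env(parent = emptyenv())
    for (j in seq_len(nrow(tsv))) {
      sid <- tsv$id[j]
      if (!sid %in% ids) {
        orphans <- orphans + 1L
        next
      }
      assign(sid, tsv$lineage[j], envir = tax_map)
    }
    for (i in seq_along(ids)) {
      lin <- NULL
      if (exists(ids[i], envir = tax_map, inherits = FALSE)) {
        lin <- .parse_prefixed_lineage(get(ids[i], envir = tax_map))
      }
      if (is.null(lin)) {
        lineage_failures <- lineage_failures + 1L
        lin <- .empty_lineage()
      }
      lin_list[[i]] <- lin
    }
  }

  lin_df <- as.data.frame(do.call(rbind, lin_list), stringsAsFactors = FALSE)
  rec <- cbind(data.frame(id = ids, sequence = san$sequences,
                          stringsAsFactors = FALSE),
               lin_df)
  .new_refset(rec, provenance = fasta_path,
              parse_report = list(n_records = length(ids),
                                  lineage_failures = lineage_failures,
                                  char_replacements = san$replaced,
                                  orphans = orphans))
}

#' Write a reference set as FASTA plus taxonomy sidecar TSV
#'
#' Emits the same dialects [read_refset()] consumes: plain FASTA and a
#' two-column `seq_id<TAB>k__...;...;g__...` sidecar.
#'
#' @param rs A `refset`.
#' @param fasta_path,taxonomy_path Output paths.
#' @return Invisibly, `rs`.
#' @export
write_refset <- function(rs, fasta_path, taxonomy_path) {
  stopifnot(inherits(rs, "refset"))
  rec <- rs$records
  fasta <- paste0(">", rec$id, "\n", rec$sequence)
  writeLines(fasta, fasta_path)
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__")
  lin <- apply(rec[.RANKS], 1L, function(v) {
    v[is.na(v)] <- ""
    paste0(prefixes, v, collapse = ";")
  })
  writeLines(paste(rec$id, lin, sep = "\t"), taxonomy_path)
  invisible(rs)
}

#' Keep only high-quality (long) reference sequences
#'
#' Retains records whose sequence length is strictly greater than `min_len`;
#' the default reproduces the `> 1200 bp` quality rule used for 16S
#' reference screening.
#'
#' @param rs A `refset`.
#' @param min_len Length threshold in nt (strict inequality).
#' @return A `refset` with the retained records, input order preserved.
#' @export
filter_high_quality <- function(rs, min_len = 1200L) {
  stopifnot(inherits(rs, "refset"), min_len >= 0L)
  keep <- rs$records$length > min_len
  .new_refset(rs$records[keep, , drop = FALSE],
              provenance = sprintf("%s [len > %d]", rs$provenance, min_len),
              parse_report = rs$parse_report)
}

#' Subset a reference set by taxon
#'
#' Exact (case-sensitive, whitespace-normalized) name match at one rank;
#' `Candidatus` is part of the name, never stripped.
#'
#' @param rs A `refset`.
#' @param rank One of [rank_ladder()].
#' @param name Taxon name at that rank.
#' @return A `refset` (possibly empty) of the matching records.
#' @export
subset_by_taxon <- function(rs, rank, name) {
  stopifnot(inherits(rs, "refset"))
  if (!rank %in% .RANKS) {
    stop(sprintf("unknown rank '%s' (expected one of: %s)",
                 rank, paste(.RANKS, collapse = ", ")), call. = FALSE)
  }
  name <- .norm_name(name)
  keep <- !is.na(rs$records[[rank]]) & rs$records[[rank]] == name
  .new_refset(rs$records[keep, , drop = FALSE],
              provenance = sprintf("%s [%s=%s]", rs$provenance, rank, name),
              parse_report = rs$parse_report)
}
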