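#' The five anammox genera
#'
#' Genus names of the known anaerobic ammonium oxidizers, all within family
#' Candidatus Brocadiaceae (order Candidatus Brocadiales, phylum
#' Planctomycetes).
#'
#' @return Character vector of five genus names, Candidatus prefix included.
#' @export
anammox_genera <- function() {
  c("Candidatus Brocadia", "Candidatus Kuenenia",
    "Candidatus Anammoxoglobus", "Candidatus Jettenia",
    "Candidatus Scalindua")
}

# drop an optional "Candidatus " prefix and normalize whitespace, so genus
# matching tolerates the prefix being present or absent in profiles
.genus_key <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  tolower(sub("^Candidatus ", "", x))
}

# extract the g__ (genus) and leading kingdom fields from a rank-prefixed
# lineage string like "sk__Bacteria;k__;p__...;g__Nitrosomonas"
.lineage_genus <- function(lineage) {
  m <- regexpr("g__[^;]*", lineage)
  out <- rep(NA_character_, length(lineage))
  out[m > 0L] <- sub("^g__", "", regmatches(lineage, m))
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

.lineage_kingdom <- function(lineage) {
  m <- regexpr("(sk|k|d)__[^;]*", lineage)
  out <- rep(NA_character_, length(lineage))
  hit <- m > 0L
  out[hit] <- sub("^(sk|k|d)__", "", regmatches(lineage, m))
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

#' Read per-sample taxonomic abundance profiles
#'
#' Consumes a flat, already-downloaded TSV of community profiles (columns
#' `study_id`, `sample_id`, `biome`, `experiment_type`, `lineage`, `count`;
#' one row per sample x lineage) and applies the survey filters: biome
#' substring, exact experiment type, and a free keyword matched
#' case-insensitively against the biome and study metadata fields.
#'
#' @param tsv_path Path to the profiles TSV.
#' @param biome Substring the biome field must contain (case-insensitive),
#'   e.g. `"wastewater"`; `NULL` for no filter.
#' @param experiment_type Exact experiment type (case-insensitive), e.g.
#'   `"amplicon"`; `NULL` for no filter.
#' @param keyword Free keyword, e.g. `"sludge"`; `NULL` for no filter.
#' @return A data.frame of class `abundance_profiles` with the input
#'   columns, rows failing the filters dropped.
#' @export
read_profiles <- function(tsv_path, biome = NULL, experiment_type = NULL,
                          keyword = NULL) {
  if (!file.exists(tsv_path)) {
    stop(sprintf("profiles file not found: %s", tsv_path), call. = FALSE)
  }
  df <- utils::read.delim(tsv_path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  required <- c("study_id", "sample_id", "biome", "experiment_type",
                "lineage", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("profiles TSV is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$count <- as.numeric(df$count)
  keep <- rep(TRUE, nrow(df))
  if (!is.null(biome)) {
    keep <- keep & grepl(biome, df$biome, ignore.case = TRUE, fixed = FALSE)
  }
  if (!is.null(experiment_type)) {
    keep <- keep & tolower(df$experiment_type) == tolower(experiment_type)
  }
  if (!is.null(keyword)) {
    meta <- paste(df$biome, df$study_id, sep = " ")
    keep <- keep & grepl(keyword, meta, ignore.case = TRUE)
  }
  out <- df[keep, required, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("abundance_profiles", "data.frame")
  out
}

#' Prevalence summary across samples and studies
#'
#' Summarizes a profile collection into genus richness and the prevalence
#' of named taxon sets: a sample is positive for a set iff any listed genus
#' (Candidatus prefix optional) — or, for a kingdom-level set written
#' `"kingdom:Name"`, any lineage under that kingdom — reaches
#' `min_count`. The built-in set `anammox` is the five [anammox_genera()].
#'
#' @param profiles An `abundance_profiles` data.frame (or any data.frame
#'   with the same columns).
#' @param taxa_of_interest Named list of taxon sets; each element is a
#'   character vector of genus names and/or `"kingdom:Name"` entries.
#' @param min_count Minimum count for a lineage to count as present
#'   (default 1, i.e. any nonzero abundance is evidence of presence).
#' @return A list of class `prevalence_summary`: `n_studies`, `n_samples`,
#'   `n_genera` (distinct genera with nonzero count in at least one
#'   sample), `prevalence` (data.frame: set, n_positive, pct_samples,
#'   n_studies_positive) and `per_study` (data.frame of per-study sample
#'   and positive counts). Percentages are `NA` when there are no samples.
#' @export
summarize_prevalence <- function(profiles,
                                 taxa_of_interest = list(
                                   archaea = "kingdom:Archaea",
                                   anammox = anammox_genera()),
                                 min_count = 1) {
  stopifnot(is.data.frame(profiles))
  samples <- unique(profiles[c("study_id", "sample_id")])
  n_samples <- nrow(samples)
  n_studies <- length(unique(samples$study_id))
  present <- profiles$count >= min_count
  gen <- .lineage_genus(profiles$lineage)
  n_genera <- length(unique(gen[present & !is.na(gen) & profiles$count > 0]))

  sample_key <- paste(profiles$study_id, profiles$sample_id, sep = "\r")
  all_keys <- paste(samples$study_id, samples$sample_id, sep = "\r")

  prev_rows <- lapply(names(taxa_of_interest), function(set_name) {
    set <- taxa_of_interest[[set_name]]
    kingdoms <- sub("^kingdom:", "", set[startsWith(set, "kingdom:")])
    genera <- set[!startsWith(set, "kingdom:")]
    hit <- rep(FALSE, nrow(profiles))
    if (length(genera) > 0L) {
      hit <- hit | (!is.na(gen) & .genus_key(gen) %in% .genus_key(genera))
    }
    if (length(kingdoms) > 0L) {
      kng <- .lineage_kingdom(profiles$lineage)
      hit <- hit | (!is.na(kng) & tolower(kng) %in% tolower(kingdoms))
    }
    pos_keys <- unique(sample_key[hit & present])
    pos_studies <- length(unique(profiles$study_id[hit & present]))
    data.frame(set = set_name,
               n_positive = length(pos_keys),
               pct_samples = if (n_samples > 0L) 100 * length(pos_keys) / n_samples else NA_real_,
               n_studies_positive = pos_studies,
               stringsAsFactors = FALSE)
  })
  prevalence <- do.call(rbind, prev_rows)

  per_study <- do.call(rbind, lapply(unique(samples$study_id), function(st) {
    st_keys <- all_keys[samples$study_id == st]
    row <- data.frame(study_id = st, n_samples = length(st_keys),
                      stringsAsFactors = FALSE)
    for (set_name in names(taxa_of_interest)) {
      set <- taxa_of_interest[[set_name]]
      kingdoms <- sub("^kingdom:", "", set[startsWith(set, "kingdom:")])
      genera <- set[!startsWith(set, "kingdom:")]
      hit <- rep(FALSE, nrow(profiles))
      if (length(genera) > 0L) {
        hit <- hit | (!is.na(gen) & .genus_key(gen) %in% .genus_key(genera))
      }
      if (length(kingdoms) > 0L) {
        kng <- .lineage_kingdom(profiles$lineage)
        hit <- hit | (!is.na(kng) & tolower(kng) %in% tolower(kingdoms))
      }
      row[[paste0("n_", set_name)]] <-
        length(unique(sample_key[hit & present & profiles$study_id == st]))
    }
    row
  }))

  structure(list(n_studies = n_studies, n_samples = n_samples,
                 n_genera = n_genera, prevalence = prevalence,
                 per_study = per_study),
            class = "prevalence_summary")
}

#' @export
print.prevalence_summary <- function(x, ...) {
  cat(sprintf("<prevalence_summary> %d genera in %d samples from %d studies\n",
              x$n_genera, x$n_samples, x$n_studies))
  print(x$prevalence, row.names = FALSE)
  invisible(x)
}
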