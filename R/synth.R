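# run expr under a private, seeded RNG stream; the caller's RNG state is
# untouched (bit-reproducible fixtures, no global randomness)
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Describe one synthetic clade
#'
#' A clade is a set of records sharing a lineage, each carrying one planted
#' forward and one planted reverse primer site on an i.i.d. uniform ACGT
#' background. The planted forward site is a random expansion of
#' `fwd_template`; rows of `alt_alleles` (`position`, `base`, `freq`) then
#' replace the base at `position` by `base` with probability `freq` per
#' record — the mechanism for planting a variant allele the template primer
#' does not cover. The reverse site is the reverse complement of a random
#' expansion of `rev_template`. Sites are placed at a random offset per
#' record, so binding sites shift between records as they would across real
#' 16S sequences.
#'
#' @param lineage Named character vector over [rank_ladder()].
#' @param n Number of records.
#' @param fwd_template,rev_template IUPAC strings (both written 5'->3',
#'   the reverse on the minus strand).
#' @param alt_alleles Optional data.frame with columns `position` (1-based
#'   on the forward template), `base`, `freq`.
#' @param len_range Record length bounds in nt (uniform integer draw).
#' @param amplicon_len_range Planted product size bounds (forward 5' start
#'   to reverse 5' start, inclusive).
#' @return A list of class `synth_clade`.
#' @export
synth_clade <- function(lineage, n,
                        fwd_template, rev_template,
                        alt_alleles = NULL,
                        len_range = c(1300L, 1600L),
                        amplicon_len_range = c(440L, 490L)) {
  fwd_template <- .canonicalize(fwd_template, "fwd_template")
  rev_template <- .canonicalize(rev_template, "rev_template")
  stopifnot(n >= 1L, length(len_range) == 2L, len_range[1] <= len_range[2])
  min_amp <- nchar(fwd_template) + nchar(rev_template)
  if (amplicon_len_range[1] <= min_amp) {
    stop("amplicon_len_range too small: planted sites would overlap", call. = FALSE)
  }
  if (len_range[1] < amplicon_len_range[2]) {
    stop("len_range too small for the planted amplicon", call. = FALSE)
  }
  if (!is.null(alt_alleles)) {
    stopifnot(all(c("position", "base", "freq") %in% names(alt_alleles)),
              all(alt_alleles$freq >= 0 & alt_alleles$freq <= 1),
              all(alt_alleles$position >= 1L),
              all(alt_alleles$position <= nchar(fwd_template)))
  }
  structure(list(lineage = lineage, n = as.integer(n),
                 fwd_template = fwd_template, rev_template = rev_template,
                 alt_alleles = alt_alleles,
                 len_range = as.integer(len_range),
                 amplicon_len_range = as.integer(amplicon_len_range)),
            class = "synth_clade")
}

#' Describe a synthetic reference set
#'
#' @param clades List of [synth_clade()] objects.
#' @param decoys Optional list with `n`, `lineage` and optionally
#'   `len_range`: background-only records carrying no planted site.
#' @param seed Mandatory integer seed; the same spec and seed reproduce the
#'   set byte for byte.
#' @return A list of class `synth_refset_spec`.
#' @export
synth_refset_spec <- function(clades, decoys = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(clades) >= 1L || !is.null(decoys),
            all(vapply(clades, inherits, TRUE, "synth_clade")))
  structure(list(clades = clades, decoys = decoys, seed = as.integer(seed)),
            class = "synth_refset_spec")
}

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# one random non-degenerate expansion of an IUPAC template
.rand_expansion <- function(template) {
  sets <- lapply(.encode(template), .mask_to_bases)
  paste(vapply(sets, function(s) s[sample.int(length(s), 1L)], ""), collapse = "")
}

#' Generate a synthetic reference set with ground truth
#'
#' Deterministic (seeded) generator emulating a clade-structured 16S
#' reference set: uniform ACGT background, one planted forward and reverse
#' primer site per non-decoy record with controlled variant-allele
#' frequencies. The ground-truth table records each site's position and
#' planted forward-site sequence, plus — for every primer pair supplied in
#' `pairs` — the expected covered flag computed by positionwise base-set
#' arithmetic on the planted sites (independent of the matcher; chance
#' background hits are vanishingly rare for 17+ nt primers and are not
#' modelled).
#'
#' @param spec A [synth_refset_spec()].
#' @param pairs Optional named list of `primer_pair`s to precompute
#'   expected coverage for (columns `covered_<name>`).
#' @param fasta_path,taxonomy_path Optional output paths; when given the
#'   set is also written in the dialects [read_refset()] consumes.
#' @return A list with `refset` (a `refset`) and `truth` (data.frame).
#' @export
generate_refset <- function(spec, pairs = NULL,
                            fasta_path = NULL, taxonomy_path = NULL) {
  stopifnot(inherits(spec, "synth_refset_spec"))
  .with_seed(spec$seed, {
    ids <- character(0); seqs <- character(0)
    lin_rows <- list(); truth_rows <- list()
    k <- 0L
    for (ci in seq_along(spec$clades)) {
      cl <- spec$clades[[ci]]
      Lf <- nchar(cl$fwd_template); Lr <- nchar(cl$rev_template)
      for (ri in seq_len(cl$n)) {
        k <- k + 1L
        len <- sample(cl$len_range[1]:cl$len_range[2], 1L)
        amp <- sample(cl$amplicon_len_range[1]:cl$amplicon_len_range[2], 1L)
        fwd_start <- sample.int(len - amp + 1L, 1L)
        rev5 <- fwd_start + amp - 1L

        fwd_site <- strsplit(.rand_expansion(cl$fwd_template), "")[[1]]
        if (!is.null(cl$alt_alleles)) {
          for (ai in seq_len(nrow(cl$alt_alleles))) {
            if (stats::runif(1L) < cl$alt_alleles$freq[ai]) {
              fwd_site[cl$alt_alleles$position[ai]] <-
                toupper(cl$alt_alleles$base[ai])
            }
          }
        }
        fwd_site <- paste(fwd_site, collapse = "")
        rev_site_minus <- .rand_expansion(cl$rev_template)
        rev_site_plus <- reverse_complement(rev_site_minus)

        body <- strsplit(.rand_dna(len), "")[[1]]
        body[fwd_start:(fwd_start + Lf - 1L)] <- strsplit(fwd_site, "")[[1]]
        body[(rev5 - Lr + 1L):rev5] <- strsplit(rev_site_plus, "")[[1]]
        sq <- paste(body, collapse = "")

        id <- sprintf("SYN%03d_%04d", ci, ri)
        ids <- c(ids, id); seqs <- c(seqs, sq)
        lin_rows[[k]] <- cl$lineage
        truth_rows[[k]] <- data.frame(
          id = id, clade = ci, decoy = FALSE, length = len,
          fwd_start = fwd_start, rev_start = rev5, amplicon_len = amp,
          fwd_site = fwd_site, rev_site = rev_site_minus,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(spec$decoys)) {
      dl <- spec$decoys
      lr <- if (is.null(dl$len_range)) c(1300L, 1600L) else as.integer(dl$len_range)
      for (ri in seq_len(dl$n)) {
        k <- k + 1L
        len <- sample(lr[1]:lr[2], 1L)
        id <- sprintf("SYNDEC_%04d", ri)
        ids <- c(ids, id); seqs <- c(seqs, .rand_dna(len))
        lin_rows[[k]] <- dl$lineage
        truth_rows[[k]] <- data.frame(
          id = id, clade = NA_integer_, decoy = TRUE, length = len,
          fwd_start = NA_integer_, rev_start = NA_integer_,
          amplicon_len = NA_integer_, fwd_site = NA_character_,
          rev_site = NA_character_, stringsAsFactors = FALSE)
      }
    }
    lineages <- do.call(rbind, lapply(lin_rows, function(l) {
      out <- .empty_lineage()
      out[intersect(names(l), .RANKS)] <- l[intersect(names(l), .RANKS)]
      out
    }))
    rs <- refset(ids, seqs, as.data.frame(lineages, stringsAsFactors = FALSE),
                 provenance = sprintf("synthetic (seed %d)", spec$seed))
    truth <- do.call(rbind, truth_rows)

    if (!is.null(pairs)) {
      for (pn in names(pairs)) {
        pr <- pairs[[pn]]
        truth[[paste0("covered_", pn)]] <- vapply(seq_len(nrow(truth)), function(i) {
          if (truth$decoy[i]) return(FALSE)
          .site_matches(truth$fwd_site[i], pr$forward$sequence) &&
            .site_matches(truth$rev_site[i], pr$reverse$sequence) &&
            truth$amplicon_len[i] >= pr$min_amplicon_len &&
            truth$amplicon_len[i] <= pr$max_amplicon_len
        }, logical(1L))
      }
    }
    if (!is.null(fasta_path)) {
      stopifnot(!is.null(taxonomy_path))
      write_refset(rs, fasta_path, taxonomy_path)
    }
    list(refset = rs, truth = truth)
  })
}

# positionwise base-set arithmetic: does a concrete planted site fall within
# a (possibly degenerate) primer's expansion set?
.site_matches <- function(site, primer_seq) {
  if (is.na(site) || nchar(site) != nchar(primer_seq)) return(FALSE)
  all(bitwAnd(.encode(site), .encode(primer_seq)) == .encode(site))
}

#' Generate synthetic per-sample abundance profiles with ground truth
#'
#' Emulates an amplicon-survey download: `n_samples` samples spread over
#' `n_studies` studies, each sample carrying counts for a random draw of
#' genera from a shared pool, with archaea-positive and anammox-positive
#' status planted per sample at the given prevalences. Defaults mirror a
#' wastewater-survey scale: 49 studies, 3433 samples, a pool sized so the
#' survey exposes ~1465 distinct genera, archaea in 22.5% and anammox taxa
#' in 3.7% of samples. Anammox-positive samples receive counts for one or
#' more of the five [anammox_genera()]; archaea-positive samples receive
#' archaeal lineages.
#'
#' @param n_studies,n_samples Survey size.
#' @param n_genera Target distinct-genus richness of the pool (the five
#'   anammox genera are part of this budget).
#' @param archaea_prevalence,anammox_prevalence Per-sample planting
#'   probabilities in `[0, 1]`.
#' @param genera_per_sample Bounds on the genus count drawn per sample.
#' @param seed Mandatory integer seed.
#' @param path Optional TSV output path ([read_profiles()] dialect).
#' @return A list with `profiles` (data.frame) and `truth` (data.frame:
#'   `study_id`, `sample_id`, `archaea_positive`, `anammox_positive`).
#' @export
generate_profiles <- function(n_studies = 49L, n_samples = 3433L,
                              n_genera = 1465L,
                              archaea_prevalence = 0.225,
                              anammox_prevalence = 0.037,
                              genera_per_sample = c(20L, 60L),
                              seed, path = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(archaea_prevalence >= 0, archaea_prevalence <= 1,
            anammox_prevalence >= 0, anammox_prevalence <= 1,
            n_genera > 10L)
  .with_seed(seed, {
    n_arch_pool <- max(3L, round(0.1 * (n_genera - 5L)))
    n_bact_pool <- n_genera - 5L - n_arch_pool
    bact_genera <- sprintf("BactGenus%04d", seq_len(n_bact_pool))
    arch_genera <- sprintf("ArchGenus%04d", seq_len(n_arch_pool))
    bact_lin <- sprintf("sk__Bacteria;p__P%02d;c__C;o__O;f__F;g__%s",
                        (seq_len(n_bact_pool) %% 30L) + 1L, bact_genera)
    arch_lin <- sprintf("sk__Archaea;p__Euryarchaeota;c__C;o__O;f__F;g__%s",
                        arch_genera)
    anam_lin <- sprintf(
      "sk__Bacteria;p__Planctomycetes;c__Planctomycetia;o__Candidatus Brocadiales;f__Candidatus Brocadiaceae;g__%s",
      anammox_genera())

    if (n_samples == 0L) {
      empty <- data.frame(study_id = character(0), sample_id = character(0),
                          biome = character(0), experiment_type = character(0),
                          lineage = character(0), count = numeric(0),
                          stringsAsFactors = FALSE)
      truth <- data.frame(study_id = character(0), sample_id = character(0),
                          archaea_positive = logical(0),
                          anammox_positive = logical(0),
                          stringsAsFactors = FALSE)
      if (!is.null(path)) {
        utils::write.table(empty, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
      return(list(profiles = empty, truth = truth))
    }

    study_of <- sprintf("STUDY%03d", ((seq_len(n_samples) - 1L) %% n_studies) + 1L)
    sample_id <- sprintf("SAMPLE%05d", seq_len(n_samples))
    arch_pos <- stats::runif(n_samples) < archaea_prevalence
    anam_pos <- stats::runif(n_samples) < anammox_prevalence

    rows <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      ng <- sample(genera_per_sample[1]:genera_per_sample[2], 1L)
      # cycle the pool so every genus appears across the survey
      picks <- unique(c(
        sample.int(n_bact_pool, min(ng, n_bact_pool)),
        ((i - 1L) * 7L + seq_len(5L) - 1L) %% n_bact_pool + 1L))
      lin <- bact_lin[picks]
      if (arch_pos[i]) {
        na <- sample(1:3, 1L)
        lin <- c(lin, arch_lin[sample.int(n_arch_pool, na)])
      }
      if (anam_pos[i]) {
        lin <- c(lin, anam_lin[sample.int(5L, sample(1:2, 1L))])
      }
      rows[[i]] <- data.frame(
        study_id = study_of[i], sample_id = sample_id[i],
        biome = "root:Engineered:Wastewater:Activated sludge",
        experiment_type = "amplicon",
        lineage = lin,
        count = stats::rpois(length(lin), 50) + 1L,
        stringsAsFactors = FALSE)
    }
    profiles <- do.call(rbind, rows)
    rownames(profiles) <- NULL
    truth <- data.frame(study_id = study_of, sample_id = sample_id,
                        archaea_positive = arch_pos,
                        anammox_positive = anam_pos,
                        stringsAsFactors = FALSE)
    if (!is.null(path)) {
      utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    list(profiles = profiles, truth = truth)
  })
}
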