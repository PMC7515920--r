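# shared fixture builders; everything is generated in code at test time

PRO341F <- "CCTACGGGNBGCASCAG"
PRO341FB <- "CCTACGGGNBGCWSCAG"
PRO805R <- "GACTACNVGGGTATCTAATCC"

pair_341f <- function() primer_pair(primer("Pro341F", PRO341F),
                                    primer("Pro805R", PRO805R))
pair_341fb <- function() primer_pair(primer("Pro341FB", PRO341FB),
                                     primer("Pro805R", PRO805R))

# random IUPAC primer with bounded degeneracy (rejection-free: widen greedily)
rand_iupac_primer <- function(len, max_deg = 64L) {
  tab <- primertax::iupac_codes()
  repeat {
    # mostly plain bases, a few degenerate codes
    sym <- sample(tab$symbol, len, replace = TRUE,
                  prob = ifelse(tab$size == 1L, 10, 1))
    p <- paste(sym, collapse = "")
    if (degeneracy(p) <= max_deg) return(p)
  }
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# independent matcher oracle: union of exact fixed-string matches over the
# full expansion set of the primer (reverse-complemented for minus strand)
brute_force_starts <- function(primer_seq, subject, strand = "plus") {
  q <- if (strand == "minus") reverse_complement(primer_seq) else primer_seq
  starts <- integer(0)
  for (e in enumerate_expansions(q, cap = 1e6)) {
    m <- gregexpr(e, subject, fixed = TRUE)[[1]]
    # overlapping matches: rescan from each match + 1
    pos <- m[m > 0L]
    if (length(pos) > 0L) {
      extra <- integer(0)
      for (p in pos) {
        nxt <- p
        repeat {
          nxt <- nxt + 1L
          if (nxt + nchar(e) - 1L > nchar(subject)) break
          if (substring(subject, nxt, nxt + nchar(e) - 1L) == e) {
            extra <- c(extra, nxt)
          } else break
        }
      }
      starts <- c(starts, pos, extra)
    }
  }
  sort(unique(starts))
}

# a small mixed-taxonomy refset built by hand (no planted primer sites)
toy_refset <- function() {
  refset(
    ids = sprintf("T%02d", 1:5),
    sequences = c(rand_dna(300), rand_dna(300), rand_dna(300),
                  rand_dna(300), rand_dna(300)),
    lineages = data.frame(
      kingdom = c("Bacteria", "Bacteria", "Bacteria", "Bacteria", "Archaea"),
      phylum = c("Planctomycetes", "Planctomycetes", "Proteobacteria",
                 "Proteobacteria", "Euryarchaeota"),
      class = c("Planctomycetia", "Planctomycetia", "Gamma", "Gamma", "Methano"),
      order = c("Candidatus Brocadiales", "Candidatus Brocadiales",
                "Enterobacterales", "Enterobacterales", "Methanobacteriales"),
      family = c("Candidatus Brocadiaceae", "Candidatus Brocadiaceae",
                 "Enterobacteriaceae", "Enterobacteriaceae", "Methanobacteriaceae"),
      genus = c("Candidatus Brocadia", "Candidatus Kuenenia",
                "Escherichia", "Salmonella", "Methanobacterium"),
      stringsAsFactors = FALSE))
}

# benchmark refset: planted-allele clade plus decoys, with ground truth
benchmark_refset <- function(seed, n_clade = 12L, n_decoy = 8L,
                             allele_freq = 0.75) {
  spec <- synth_refset_spec(
    clades = list(brocadiaceae_benchmark_clade(n = n_clade,
                                               allele_freq = allele_freq)),
    decoys = list(n = n_decoy,
                  lineage = c(kingdom = "Bacteria", phylum = "Proteobacteria",
                              class = "Gamma", order = "Enterobacterales",
                              family = "Enterobacteriaceae",
                              genus = "Escherichia")),
    seed = seed)
  generate_refset(spec, pairs = list(F = pair_341f(), FB = pair_341fb()))
}

# exhaustive optimizer oracle: best single-position strict widening under the
# published ranking (target gain desc, degeneracy multiplier asc, 5'-most
# position asc, lexicographic sequence), scored by full pair coverage
oracle_best_single_widening <- function(base_seq, reverse_seq, target_rs,
                                        protect_3prime = 3L, max_deg = 96L) {
  codes <- primertax::iupac_codes()
  base_chars <- strsplit(base_seq, "")[[1]]
  L <- length(base_chars)
  rev_p <- primer("rev", reverse_seq)
  base_cov <- mean(covered(primer_pair(primer("b", base_seq), rev_p), target_rs))
  best <- NULL
  for (p in seq_len(L - protect_3prime)) {
    old_set <- expand_code(base_chars[p])
    for (sym in codes$symbol) {
      new_set <- expand_code(sym)
      if (!all(old_set %in% new_set) || length(new_set) <= length(old_set)) next
      cand_chars <- base_chars
      cand_chars[p] <- sym
      cand <- paste(cand_chars, collapse = "")
      if (degeneracy(cand) > max_deg) next
      gain <- mean(covered(primer_pair(primer("c", cand), rev_p), target_rs)) - base_cov
      if (gain <= 0) next
      mult <- degeneracy(cand) / degeneracy(base_seq)
      key <- list(gain = gain, mult = mult, pos = p, seq = cand)
      if (is.null(best) ||
          gain > best$gain + 1e-12 ||
          (abs(gain - best$gain) < 1e-12 && (mult < best$mult ||
            (mult == best$mult && (p < best$pos ||
              (p == best$pos && cand < best$seq)))))) {
        best <- key
      }
    }
  }
  best
}
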