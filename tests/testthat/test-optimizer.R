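test_that("site allele profiles tally planted alleles per primer position", {
  g <- benchmark_refset(seed = 501, n_clade = 10, n_decoy = 0, allele_freq = 0.7)
  target <- subset_by_taxon(g$refset, "family", "Candidatus Brocadiaceae")
  prof <- site_allele_profile(primer("Pro341F", PRO341F), target)
  expect_equal(prof$n_located, 10)
  expect_equal(prof$n_unlocated, 0)
  # position 13 composition equals the planted allele counts
  n_alt <- sum(substring(g$truth$fwd_site, 13, 13) == "T")
  expect_equal(unname(prof$profile["T", 13]), n_alt)
  expect_equal(unname(prof$profile["A", 13]), 10 - n_alt)
  expect_equal(unname(prof$profile["C", 13] + prof$profile["G", 13]), 0)
  # columns sum to the located-record count at every position
  expect_true(all(colSums(prof$profile) == 10))

  # a target identical to one expansion profiles as that expansion
  e <- enumerate_expansions(PRO341F)[1]
  rs1 <- refset("one", paste0(strrep("G", 50), e, strrep("C", 50)))
  p1 <- site_allele_profile(primer("p", PRO341F), rs1)
  expect_equal(sum(p1$profile), nchar(PRO341F))
  expect_equal(paste(rownames(p1$profile)[apply(p1$profile, 2, which.max)],
                     collapse = ""), e)

  expect_error(site_allele_profile(primer("p", PRO341F),
                                   refset("x", rand_dna(100))),
               "no target record")
})

test_that("the search recovers the planted W degeneration and ranks by parsimony", {
  g <- benchmark_refset(seed = 502, n_clade = 12, n_decoy = 8, allele_freq = 0.7)
  cfg <- optimizer_config("family", "Candidatus Brocadiaceae", min_len = 1200L)
  props <- propose_degenerations(primer("Pro341F", PRO341F),
                                 primer("Pro805R", PRO805R), g$refset, cfg)
  expect_s3_class(props, "degeneration_proposals")
  expect_gt(nrow(props), 0)
  top <- props[1, ]
  expect_equal(top$positions_changed, "13")
  expect_equal(top$old_codes, "A")
  expect_equal(top$new_codes, "W")
  expect_equal(top$proposed_sequence, PRO341FB)
  expect_equal(top$degeneracy, 48)
  expect_equal(top$degeneracy_multiplier, 2)
  # soundness: every proposal is a positionwise superset of the base
  for (i in seq_len(nrow(props))) {
    pm <- primertax:::.encode(props$proposed_sequence[i])
    bm <- primertax:::.encode(PRO341F)
    expect_true(all(bitwAnd(pm, bm) == bm))
    expect_gt(props$degeneracy_multiplier[i], 1)
    expect_gt(props$target_gain_pct[i], 0)
    expect_true(props$global_delta_pct[i] >= 0)
  }
  # parsimony ordering within equal gain
  gmax <- max(props$target_gain_pct)
  best <- props[props$target_gain_pct == gmax, ]
  expect_false(is.unsorted(best$degeneracy_multiplier))
})

test_that("a fully covered target yields an empty proposal list", {
  g <- benchmark_refset(seed = 503, n_clade = 6, n_decoy = 0, allele_freq = 0)
  cfg <- optimizer_config("family", "Candidatus Brocadiaceae")
  props <- propose_degenerations(primer("Pro341F", PRO341F),
                                 primer("Pro805R", PRO805R), g$refset, cfg)
  expect_equal(nrow(props), 0)
  expect_error(propose_degenerations(primer("Pro341F", PRO341F),
                                     primer("Pro805R", PRO805R), g$refset,
                                     optimizer_config("family", "NoSuchFamily")),
               "no high-quality record")
})

test_that("a two-allele target is resolved by the minimal covering code", {
  # equal T and G alternative alleles at position 13: the minimal single
  # code covering {A,T,G} is D, which the exhaustive oracle must also pick
  clade <- synth_clade(
    lineage = c(kingdom = "Bacteria", phylum = "Planctomycetes",
                class = "Planctomycetia", order = "Candidatus Brocadiales",
                family = "Candidatus Brocadiaceae", genus = "Candidatus Brocadia"),
    n = 12, fwd_template = PRO341F, rev_template = PRO805R,
    alt_alleles = data.frame(position = c(13, 13), base = c("T", "G"),
                             freq = c(0.9, 0.45)))
  # freq rows apply sequentially: ~45% G (overrides), ~45% T, ~10% A
  g <- generate_refset(synth_refset_spec(clades = list(clade), seed = 504))
  cfg <- optimizer_config("family", "Candidatus Brocadiaceae")
  props <- propose_degenerations(primer("Pro341F", PRO341F),
                                 primer("Pro805R", PRO805R), g$refset, cfg)
  alt <- unique(substring(g$truth$fwd_site, 13, 13))
  expect_true(all(c("T", "G") %in% alt))  # both alleles drawn under this seed
  top <- props[1, ]
  expect_equal(top$new_codes, "D")
  target <- subset_by_taxon(g$refset, "family", "Candidatus Brocadiaceae")
  oracle <- oracle_best_single_widening(PRO341F, PRO805R, target)
  expect_equal(top$proposed_sequence, oracle$seq)
})

test_that("verify_proposal audits the monotonicity of the accepted edit", {
  g <- benchmark_refset(seed = 505, n_clade = 10, n_decoy = 6, allele_freq = 0.75)
  cfg <- optimizer_config("family", "Candidatus Brocadiaceae")
  props <- propose_degenerations(primer("Pro341F", PRO341F),
                                 primer("Pro805R", PRO805R), g$refset, cfg)
  audit <- verify_proposal(props, primer("Pro805R", PRO805R), g$refset)
  expect_equal(audit$proposed_sequence, PRO341FB)
  expect_equal(audit$degeneracy_before, 24)
  expect_equal(audit$degeneracy_after, 48)
  expect_true(audit$no_taxon_lost)
  # gain concentrated in the planted clade: other families unchanged
  fam <- audit$deltas$family
  other <- fam[fam$taxon != "Candidatus Brocadiaceae", ]
  expect_true(all(other$delta_pct == 0))
  expect_gt(fam$delta_pct[fam$taxon == "Candidatus Brocadiaceae"], 0)
  # drilldown consistency at family rank
  dd <- lineage_drilldown(pair_341f(), pair_341fb(), g$refset,
                          c(family = "Candidatus Brocadiaceae"))
  expect_equal(dd$delta_pct,
               fam$delta_pct[fam$taxon == "Candidatus Brocadiaceae"])
})

test_that("3'-protection and degeneracy caps prune the candidate space", {
  g <- benchmark_refset(seed = 506, n_clade = 8, n_decoy = 0, allele_freq = 0.8)
  # protecting the 3'-terminal 5 positions of the 17-mer freezes position 13,
  # and no other position can rescue a record mismatching there
  cfg_tight <- optimizer_config("family", "Candidatus Brocadiaceae",
                                protect_3prime = 5L)
  props <- propose_degenerations(primer("Pro341F", PRO341F),
                                 primer("Pro805R", PRO805R), g$refset, cfg_tight)
  expect_equal(nrow(props), 0)
  # an impossible degeneracy cap removes every candidate
  cfg_cap <- optimizer_config("family", "Candidatus Brocadiaceae",
                              max_degeneracy = 24L)
  expect_equal(nrow(propose_degenerations(primer("Pro341F", PRO341F),
                                          primer("Pro805R", PRO805R),
                                          g$refset, cfg_cap)), 0)
})
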