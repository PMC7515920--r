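test_that("refset generation is seed-deterministic, byte for byte", {
  spec <- synth_refset_spec(
    clades = list(brocadiaceae_benchmark_clade(n = 6, allele_freq = 0.5)),
    decoys = list(n = 4, lineage = c(kingdom = "Bacteria",
                                     phylum = "Proteobacteria")),
    seed = 901)
  fa1 <- withr::local_tempfile(); tx1 <- withr::local_tempfile()
  fa2 <- withr::local_tempfile(); tx2 <- withr::local_tempfile()
  g1 <- generate_refset(spec, fasta_path = fa1, taxonomy_path = tx1)
  g2 <- generate_refset(spec, fasta_path = fa2, taxonomy_path = tx2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(tx1), readLines(tx2))
  expect_identical(g1$truth, g2$truth)
  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); generate_refset(spec); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated sets round-trip through the reader and match ground truth", {
  spec <- synth_refset_spec(
    clades = list(brocadiaceae_benchmark_clade(n = 10, allele_freq = 0.6)),
    decoys = list(n = 6, lineage = c(kingdom = "Bacteria",
                                     phylum = "Proteobacteria",
                                     class = "Gamma", order = "O",
                                     family = "F", genus = "G")),
    seed = 902)
  fa <- withr::local_tempfile(); tx <- withr::local_tempfile()
  g <- generate_refset(spec, pairs = list(F = pair_341f(), FB = pair_341fb()),
                       fasta_path = fa, taxonomy_path = tx)
  back <- read_refset(fa, tx)
  expect_equal(back$records$sequence, g$refset$records$sequence)
  expect_equal(back$records[rank_ladder()], g$refset$records[rank_ladder()])
  expect_equal(back$records$length, g$truth$length)

  # matcher agrees with construction-time expected coverage on the re-read set
  expect_equal(covered(pair_341f(), back), g$truth$covered_F)
  expect_equal(covered(pair_341fb(), back), g$truth$covered_FB)
  # planted coordinates are where the simulator finds the amplicon
  i <- which(!g$truth$decoy)[1]
  amp <- simulate_amplicon(pair_341fb(), back$records$sequence[i])
  expect_true(g$truth$fwd_start[i] %in% amp$fwd_start)
  expect_true(g$truth$amplicon_len[i] %in% amp$amplicon_len)
})

test_that("decoy-only sets are uncovered and infeasible geometry is rejected", {
  spec <- synth_refset_spec(
    clades = list(),
    decoys = list(n = 10, lineage = c(kingdom = "Bacteria", phylum = "X"),
                  len_range = c(500, 600)),
    seed = 903)
  g <- generate_refset(spec, pairs = list(FB = pair_341fb()))
  expect_false(any(covered(pair_341fb(), g$refset)))
  expect_false(any(g$truth$covered_FB))

  expect_error(synth_clade(lineage = c(kingdom = "Bacteria"), n = 2,
                           fwd_template = PRO341F, rev_template = PRO805R,
                           amplicon_len_range = c(20, 30)),
               "sites would overlap")
  expect_error(synth_refset_spec(clades = list()), "seed is mandatory")
})

test_that("profile generation plants prevalences the summary recovers exactly", {
  gp <- generate_profiles(n_studies = 8, n_samples = 400, n_genera = 120,
                          archaea_prevalence = 0.225,
                          anammox_prevalence = 0.05, seed = 904)
  sm <- summarize_prevalence(gp$profiles)
  expect_equal(sm$n_samples, 400)
  expect_equal(sm$n_studies, 8)
  prev <- sm$prevalence
  expect_equal(prev$n_positive[prev$set == "anammox"],
               sum(gp$truth$anammox_positive))
  expect_equal(prev$n_positive[prev$set == "archaea"],
               sum(gp$truth$archaea_positive))
  expect_equal(prev$pct_samples[prev$set == "anammox"],
               100 * mean(gp$truth$anammox_positive))

  # TSV round trip through the reader
  path <- withr::local_tempfile(fileext = ".tsv")
  gp2 <- generate_profiles(n_studies = 4, n_samples = 50, n_genera = 40,
                           anammox_prevalence = 0.2, seed = 905, path = path)
  back <- read_profiles(path, biome = "wastewater")
  sm2 <- summarize_prevalence(back)
  expect_equal(sm2$n_samples, 50)
  expect_equal(sm2$prevalence$n_positive[sm2$prevalence$set == "anammox"],
               sum(gp2$truth$anammox_positive))

  # degenerate corners
  z <- generate_profiles(n_studies = 2, n_samples = 40, n_genera = 30,
                         anammox_prevalence = 0, seed = 906)
  smz <- summarize_prevalence(z$profiles)
  expect_equal(smz$prevalence$n_positive[smz$prevalence$set == "anammox"], 0)
  e <- generate_profiles(n_samples = 0, seed = 907)
  expect_equal(nrow(e$profiles), 0)
  expect_true(all(is.na(summarize_prevalence(e$profiles)$prevalence$pct_samples)))
})
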