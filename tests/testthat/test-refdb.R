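write_fixture_fasta <- function(ids, seqs, headers = ids) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(paste0(">", headers, "\n", seqs), path)
  path
}

test_that("sidecar-TSV reference sets read losslessly with a parse report", {
  seqs <- c("ACGTACGTACGT", "GGGGCCCCAAAA", "TTTTACGTGGCC")
  fa <- write_fixture_fasta(c("s1", "s2", "s3"), seqs)
  tax <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "s1\tk__Bacteria;p__Planctomycetes;c__Planctomycetia;o__Candidatus Brocadiales;f__Candidatus Brocadiaceae;g__Candidatus Brocadia",
    "s2\tk__Bacteria;p__Proteobacteria;c__Gamma;o__;f__;g__",
    "s3\tk__Archaea;p__Euryarchaeota"), tax)

  rs <- read_refset(fa, tax)
  expect_s3_class(rs, "refset")
  expect_length(rs, 3)
  expect_equal(rs$parse_report$lineage_failures, 0)
  expect_equal(rs$records$sequence, seqs)  # loss-free on sequence content
  expect_equal(rs$records$genus[1], "Candidatus Brocadia")
  expect_equal(rs$records$family[1], "Candidatus Brocadiaceae")
  expect_true(is.na(rs$records$order[2]))  # empty prefix = absent rank
  expect_true(is.na(rs$records$class[3]))
})

test_that("malformed taxonomy lines and orphans are counted, not fatal", {
  fa <- write_fixture_fasta(c("a", "b", "c"),
                            c("ACGTACGT", "ACGTACGT", "ACGTACGT"))
  tax <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tk__Bacteria;p__Firmicutes",
               "b\tthis is not a lineage",
               "zzz\tk__Bacteria;p__Orphan",
               "c\tk__Bacteria;p__Actinobacteria"), tax)
  rs <- read_refset(fa, tax)
  expect_length(rs, 3)  # malformed record kept, with empty lineage
  expect_equal(rs$parse_report$lineage_failures, 1)
  expect_equal(rs$parse_report$orphans, 1)
  expect_true(is.na(rs$records$kingdom[rs$records$id == "b"]))
})

test_that("RDP-dialect headers round-trip lineages, dropping unofficial ranks", {
  hdr <- paste0("S000001 Candidatus Brocadia anammoxidans\t",
                'Lineage=Root;rootrank;Bacteria;domain;"Planctomycetes";phylum;',
                "Planctomycetia;class;Planctomycetidae;subclass;",
                '"Candidatus Brocadiales";order;Candidatus Brocadiaceae;family;',
                "Candidatus Brocadia;genus")
  fa <- write_fixture_fasta("S000001", "ACGTACGTNNACGT", headers = hdr)
  rs <- read_refset(fa)
  expect_equal(rs$records$kingdom, "Bacteria")
  expect_equal(rs$records$phylum, "Planctomycetes")     # quotes stripped
  expect_equal(rs$records$order, "Candidatus Brocadiales")
  expect_equal(rs$records$genus, "Candidatus Brocadia")
  expect_equal(rs$parse_report$lineage_failures, 0)
})

test_that("duplicated FASTA ids are fatal; stray characters become N", {
  fa_dup <- write_fixture_fasta(c("x", "x"), c("ACGT", "ACGT"))
  expect_error(read_refset(fa_dup), "duplicated FASTA id 'x'")

  fa <- write_fixture_fasta("ok", "ACG.TAC!GT")
  expect_warning(rs <- read_refset(fa), "2 non-IUPAC characters")
  expect_equal(rs$records$sequence, "ACGNTACNGT")
  expect_equal(rs$parse_report$char_replacements, 2)
})

test_that("high-quality filter is strict and idempotent", {
  rs <- refset(c("a", "b", "c"),
               c(strrep("A", 1500), strrep("C", 1200), strrep("G", 900)))
  f <- filter_high_quality(rs, 1200)
  expect_equal(f$records$id, "a")  # 1200 is excluded: strictly greater
  expect_equal(filter_high_quality(f, 1200)$records, f$records)
  expect_length(filter_high_quality(rs, 0), 3)
  expect_length(filter_high_quality(refset(character(0), character(0)), 1200), 0)
})

test_that("taxon subsetting partitions the refset and validates the rank", {
  set.seed(5)
  rs <- toy_refset()
  broc <- subset_by_taxon(rs, "family", "Candidatus Brocadiaceae")
  expect_length(broc, 2)
  expect_length(subset_by_taxon(rs, "genus", "NotAGenus"), 0)
  expect_error(subset_by_taxon(rs, "tribe", "X"), "unknown rank")

  # partition property at phylum rank
  phyla <- unique(rs$records$phylum)
  sizes <- vapply(phyla, function(p) length(subset_by_taxon(rs, "phylum", p)), 0L)
  expect_equal(sum(sizes), length(rs))
  ids <- unlist(lapply(phyla, function(p) subset_by_taxon(rs, "phylum", p)$records$id))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("write_refset emits the dialect read_refset consumes", {
  set.seed(6)
  rs <- toy_refset()
  fa <- withr::local_tempfile(fileext = ".fasta")
  tx <- withr::local_tempfile(fileext = ".tsv")
  write_refset(rs, fa, tx)
  back <- read_refset(fa, tx)
  expect_equal(back$records$sequence, rs$records$sequence)
  expect_equal(back$records[rank_ladder()], rs$records[rank_ladder()])
})
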