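test_that("the default fixture has the published sampling structure", {
  fx <- make_fixture(seed = 1)
  expect_equal(nrow(fx$alignment), 93L)
  expect_equal(aln_length(fx$alignment), 658L)
  hap_counts <- table(fx$haplogroups$group)
  expect_equal(unname(hap_counts[c("A", "P1", "P2", "P3", "H")]),
               c(22L, 18L, 6L, 4L, 2L), ignore_attr = TRUE)
  tax_counts <- table(fx$taxa$group)
  expect_equal(unname(tax_counts["acentria"]), 25L, ignore_attr = TRUE)
  # 22 of the 25 acentria samples sit in haplogroup A, 3 in P2
  joined <- dplyr::inner_join(fx$haplogroups, fx$taxa, by = "sample_id",
                              suffix = c("_hap", "_tax"))
  ace <- joined[joined$group_tax == "acentria", ]
  expect_equal(sum(ace$group_hap == "A"), 22L)
  expect_equal(sum(ace$group_hap == "P2"), 3L)
})

test_that("every planted statistic is recovered exactly (core round-trip)", {
  fx <- make_fixture(seed = 1)
  aln <- fx$alignment
  hap <- fx$haplogroups
  d <- distance_matrix(aln)
  for (i in seq_len(nrow(fx$truth$groups))) {
    row <- fx$truth$groups[i, ]
    fs <- fixed_substitutions(aln, hap, row$group, row$reference)
    expect_equal(attr(fs, "count"), as.integer(row$diagnostic_count))
    expect_equal(fs$position, row$diagnostic_positions[[1]])
    cp <- min_intergroup(d, hap, row$group, row$reference)
    expect_equal(cp$differing_sites, as.integer(row$closest_pair_total))
    expect_equal(cp$p, row$closest_p)
    expect_equal(cp$p_percent, row$closest_p_percent)
  }
  # clustering recovers the haplogroup partition and the introgression
  complex_ids <- hap$sample_id[hap$group %in% fx$truth$complex_haplogroups]
  dc <- distance_matrix(restrict_alignment(aln, complex_ids))
  cl_complex <- single_linkage_clusters(dc, fx$truth$cluster_threshold)
  expect_equal(length(unique(cl_complex$cluster)),
               fx$truth$n_complex_clusters)
  cl_all <- single_linkage_clusters(d, fx$truth$cluster_threshold)
  expect_equal(length(unique(cl_all$cluster)), fx$truth$n_total_clusters)
  disc <- discordant_samples(cl_all, fx$taxa)
  expect_setequal(disc$sample_id, fx$truth$introgression$sample_ids)
})

test_that("the fixture is deterministic given (config, seed)", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(make_fixture(seed = 5)$alignment, f1)
  write_fasta(make_fixture(seed = 5)$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed -> different backbone
  expect_false(identical(make_fixture(seed = 5)$alignment$sequence,
                         make_fixture(seed = 6)$alignment$sequence))
})

test_that("a degenerate config with no divergence yields all-zero statistics", {
  cfg <- fixture_config(
    groups = list(list(label = "G", taxon = "g", n = 3, prefix = "GGG",
                       diagnostic_count = 0, closest_pair_total = 0)),
    reference = list(label = "R", taxon = "r", n = 3, private_sites = 0,
                     prefix = "RRR"),
    introgression = NULL, outgroups = list())
  fx <- make_fixture(cfg, seed = 2)
  fs <- fixed_substitutions(fx$alignment, fx$haplogroups, "G", "R")
  expect_equal(attr(fs, "count"), 0L)
  cp <- min_intergroup(distance_matrix(fx$alignment), fx$haplogroups,
                       "G", "R")
  expect_equal(cp$p, 0)
})

test_that("invalid configs are rejected", {
  expect_error(fixture_config(L = 50), "config-error.*site budget")
  expect_error(
    fixture_config(groups = list(list(label = "G", taxon = "g", n = 4,
                                      diagnostic_count = 9,
                                      closest_pair_total = 5))),
    "config-error.*closest_pair_total")
  expect_error(
    fixture_config(introgression = list(donor = "nope", recipient_taxon = "x",
                                        n = 1)),
    "config-error.*donor")
})
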