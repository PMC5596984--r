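test_that("p_distance handles identity, counting, masking and errors", {
  expect_equal(p_distance("ACGT", "ACGT"),
               tibble::tibble(p = 0, compared_sites = 4L,
                              differing_sites = 0L))
  # 16 differences over 658 unmasked sites renders as 2.4 %
  a <- strrep("A", 658)
  b <- paste0(strrep("C", 16), strrep("A", 642))
  d <- p_distance(a, b)
  expect_equal(d$p, 16 / 658)
  expect_equal(d$compared_sites, 658L)
  expect_equal(render_percent(d$p), "2.4 %")
  # gap site excluded under pairwise deletion
  d2 <- p_distance("AC-T", "ACGT")
  expect_equal(d2$compared_sites, 3L)
  expect_equal(d2$p, 0)
  expect_error(p_distance("ACGT", "ACG"), "alignment-error")
  expect_error(p_distance("NN--", "ACGT"), "undefined-distance")
})

test_that("ambiguity codes follow the site policy", {
  # treated as missing: R masked, 3 compared
  d <- p_distance("ACGR", "ACGA", site_policy(ambiguity = "treat_as_missing"))
  expect_equal(d$compared_sites, 3L)
  expect_equal(d$differing_sites, 0L)
  # strict mismatch: an ambiguity never matches anything, even itself
  d <- p_distance("ACGR", "ACGR", site_policy(ambiguity = "strict_mismatch"))
  expect_equal(d$compared_sites, 4L)
  expect_equal(d$differing_sites, 1L)
})

test_that("distance_matrix matches the brute-force double loop", {
  aln0 <- as_alignment(data.frame(sample_id = c("a", "b", "c"),
                                  sequence = rep("ACGTACGT", 3)))
  m0 <- pdist_matrix(distance_matrix(aln0))
  expect_true(all(m0 == 0))

  set.seed(101)
  for (rep in 1:25) {
    aln <- rand_alignment(sample(3:12, 1), sample(20:100, 1))
    for (policy in both_policies) {
      got <- pdist_matrix(distance_matrix(aln, policy))
      want <- oracle_matrix(aln, policy)
      expect_equal(got, want, tolerance = 0)
    }
  }
})

test_that("distance_matrix agrees with ape::dist.dna on clean sequences", {
  skip_if_not_installed("ape")
  set.seed(7)
  aln <- rand_alignment(10, 120, gap_prob = 0, ambig_prob = 0)
  got <- pdist_matrix(distance_matrix(aln))
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln$sequence), "")))
  rownames(bin) <- aln$sample_id
  want <- as.matrix(ape::dist.dna(bin, model = "raw",
                                  pairwise.deletion = TRUE))
  expect_equal(got, want[rownames(got), colnames(got)], tolerance = 1e-12)
})

test_that("min_intergroup finds the closest pair, with deterministic ties", {
  aln <- as_alignment(data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    sequence  = c("AAAA", "AATT", "AAAC", "CCCC")))
  grp <- as_grouping(data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                                group = c("G1", "G1", "G2", "G2")))
  d <- distance_matrix(aln)
  cp <- min_intergroup(d, grp, "G1", "G2")
  expect_equal(cp$sample_a, "a1")
  expect_equal(cp$sample_b, "b1")
  expect_equal(cp$p, 0.25)
  expect_equal(cp$n_ties, 1L)
  # orientation follows the group arguments
  cp_rev <- min_intergroup(d, grp, "G2", "G1")
  expect_equal(cp_rev$sample_a, "b1")
  expect_equal(cp_rev$p, cp$p)

  # ties: two pairs at the same minimum, lexicographically first reported
  aln2 <- as_alignment(data.frame(
    sample_id = c("a1", "a2", "b1"),
    sequence  = c("AAAT", "AATA", "AAAA")))
  grp2 <- as_grouping(data.frame(sample_id = c("a1", "a2", "b1"),
                                 group = c("G1", "G1", "G2")))
  cp2 <- min_intergroup(distance_matrix(aln2), grp2, "G1", "G2")
  expect_equal(cp2$n_ties, 2L)
  expect_equal(cp2$sample_a, "a1")
  expect_equal(nrow(cp2$ties[[1]]), 2L)

  expect_error(min_intergroup(d, grp, "G1", "G1"), "input-error.*overlap")
  expect_error(min_intergroup(d, grp, "G1", "G3"), "input-error")
})

test_that("min_intergroup equals the brute-force minimum over random groupings", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    aln <- rand_alignment(n, 60)
    labels <- sample(paste0("g", 1:3), n, replace = TRUE)
    # ensure every label occurs
    labels[1:3] <- paste0("g", 1:3)
    grp <- as_grouping(tibble::tibble(sample_id = aln$sample_id,
                                      group = labels))
    d <- distance_matrix(aln)
    dm <- oracle_matrix(aln, site_policy())
    for (pair in list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3"))) {
      ia <- aln$sample_id[labels == pair[1]]
      ib <- aln$sample_id[labels == pair[2]]
      want <- min(dm[ia, ib, drop = FALSE])
      got <- min_intergroup(d, grp, pair[1], pair[2])
      expect_equal(got$p, want)
      expect_equal(unname(dm[got$sample_a, got$sample_b]), want)
    }
  }
})

test_that("fixed_substitutions enumerates invariable differences", {
  aln <- as_alignment(data.frame(
    sample_id = c("s1", "s2", "t1", "t2"),
    sequence  = c("ACGT", "ACGA", "TCGT", "TCGA")))
  grp <- as_grouping(data.frame(sample_id = c("s1", "s2", "t1", "t2"),
                                group = c("S", "S", "T", "T")))
  fx <- fixed_substitutions(aln, grp, "S", "T")
  expect_equal(attr(fx, "count"), 1L)
  expect_equal(fx$position, 1L)        # site 4 polymorphic in both groups
  expect_equal(fx$state_a, "A")
  expect_equal(fx$state_b, "T")
  expect_equal(attr(fx, "evaluated_sites"), 4L)
  expect_equal(glance(fx)$count, 1L)

  # identical groups: zero fixed differences
  aln2 <- as_alignment(data.frame(sample_id = c("u1", "u2"),
                                  sequence = c("ACGT", "ACGT")))
  grp2 <- as_grouping(data.frame(sample_id = c("u1", "u2"),
                                 group = c("U", "V")))
  w <- capture_warnings(fx2 <- fixed_substitutions(aln2, grp2, "U", "V"))
  expect_match(w, "single member", all = TRUE)
  expect_length(w, 2L)  # one warning per singleton group
  expect_equal(attr(fx2, "count"), 0L)

  # symmetric up to state swap
  fy <- fixed_substitutions(aln, grp, "T", "S")
  expect_equal(fy$position, fx$position)
  expect_equal(fy$state_a, fx$state_b)
  expect_equal(fy$state_b, fx$state_a)
})

test_that("sites with one group fully masked are not evaluated", {
  aln <- as_alignment(data.frame(
    sample_id = c("s1", "s2", "t1", "t2"),
    sequence  = c("NCGT", "NCGA", "TCGT", "TCGA")))
  grp <- as_grouping(data.frame(sample_id = c("s1", "s2", "t1", "t2"),
                                group = c("S", "S", "T", "T")))
  fx <- fixed_substitutions(aln, grp, "S", "T")
  expect_equal(attr(fx, "evaluated_sites"), 3L)   # site 1 unevaluable
  expect_equal(attr(fx, "count"), 0L)
  # complete deletion drops a site masked in any member
  aln3 <- as_alignment(data.frame(
    sample_id = c("s1", "s2", "t1", "t2"),
    sequence  = c("ACGT", "ACG-", "TCGT", "TCGT")))
  fx3 <- fixed_substitutions(aln3, grp, "S", "T",
                             site_policy("complete_deletion"))
  expect_equal(attr(fx3, "evaluated_sites"), 3L)
  expect_equal(attr(fx3, "count"), 1L)
})

test_that("fixed_substitutions matches the per-site oracle on random instances", {
  set.seed(303)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    aln <- rand_alignment(n, sample(20:80, 1))
    labels <- c("A", "B", sample(c("A", "B"), n - 2, replace = TRUE))
    grp <- as_grouping(tibble::tibble(sample_id = aln$sample_id,
                                      group = labels))
    for (policy in both_policies) {
      got <- suppressWarnings(
        fixed_substitutions(aln, grp, "A", "B", policy))
      expect_equal(attr(got, "count"), oracle_fixed(aln, grp, "A", "B", policy))
    }
  }
})

test_that("shrinking a group never decreases the diagnostic count", {
  set.seed(404)
  for (rep in 1:15) {
    aln <- rand_alignment(8, 40, gap_prob = 0.03, ambig_prob = 0.03)
    grp <- as_grouping(tibble::tibble(
      sample_id = aln$sample_id,
      group = rep(c("A", "B"), each = 4)))
    full <- attr(suppressWarnings(
      fixed_substitutions(aln, grp, "A", "B")), "count")
    drop_id <- sample(grp$sample_id[grp$group == "A"], 1)
    shrunk_grp <- as_grouping(grp[grp$sample_id != drop_id, ])
    shrunk_aln <- restrict_alignment(aln, shrunk_grp$sample_id)
    shrunk <- attr(suppressWarnings(
      fixed_substitutions(shrunk_aln, shrunk_grp, "A", "B")), "count")
    expect_gte(shrunk, full)
  }
})

test_that("diagnostic density bounds the minimal inter-group p-distance", {
  # under complete deletion with no masked sites, every diagnostic site
  # separates every inter-group pair
  set.seed(505)
  for (rep in 1:10) {
    aln <- rand_alignment(8, 50, gap_prob = 0, ambig_prob = 0)
    grp <- as_grouping(tibble::tibble(
      sample_id = aln$sample_id, group = rep(c("A", "B"), each = 4)))
    policy <- site_policy("complete_deletion")
    fx <- fixed_substitutions(aln, grp, "A", "B", policy)
    cp <- min_intergroup(distance_matrix(aln, policy), grp, "A", "B")
    expect_lte(attr(fx, "count") / attr(fx, "evaluated_sites"), cp$p)
  }
})

test_that("divergence_summary reports every unordered pair, stably", {
  fx <- make_fixture(seed = 1)
  keep <- fx$haplogroups$group %in% c("P1", "A", "H")
  grp <- as_grouping(fx$haplogroups[keep, ])
  aln <- restrict_alignment(fx$alignment, grp$sample_id)
  s1 <- divergence_summary(aln, grp)
  expect_equal(nrow(s1), 3L)  # 3 groups -> 3 unordered pairs
  expect_identical(s1, divergence_summary(aln, grp))

  # two groups -> one row
  grp2 <- as_grouping(grp[grp$group %in% c("P1", "A"), ])
  s2 <- divergence_summary(restrict_alignment(aln, grp2$sample_id), grp2)
  expect_equal(nrow(s2), 1L)
  expect_error(divergence_summary(aln, as_grouping(grp[grp$group == "A", ])),
               "input-error")
})
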