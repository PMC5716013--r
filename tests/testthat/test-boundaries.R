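test_that("microhomology on definitional examples", {
  mh <- microhomology("TTTTTCAG", "GTAAACAG", "TTAAA")
  expect_identical(mh$k5, 3L)  # shared suffix CAG
  mh2 <- microhomology("TTTT", "GTAAACCAG", "GTACCC")
  expect_identical(mh2$k3, 3L)  # shared prefix GTA
  expect_identical(mh2$k, 3L)
  # case-insensitive, verbatim comparison
  mh3 <- microhomology("ttcag", "GTAAACAG", "AAAA")
  expect_identical(mh3$k5, 3L)
})

test_that("microhomology equals the brute-force oracle on random triples", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  for (i in 1:1000) {
    up <- paste(sample(bases, sample(0:10, 1), replace = TRUE), collapse = "")
    intr <- paste(sample(bases, sample(2:12, 1), replace = TRUE), collapse = "")
    dn <- paste(sample(bases, sample(0:10, 1), replace = TRUE), collapse = "")
    cap <- sample(c(4, 8), 1)
    got <- suppressWarnings(microhomology(up, intr, dn, cap = cap))
    want <- oracle_microhomology(up, intr, dn, cap = cap)
    expect_identical(got$k5, as.integer(want$k5))
    expect_identical(got$k3, as.integer(want$k3))
    expect_identical(got$k, as.integer(want$k))
  }
})

test_that("the cap limits the homology searched", {
  up <- strrep("A", 12)
  intr <- paste0("GT", strrep("A", 12))
  expect_identical(microhomology(up, intr, "CCC")$k5, 8L)
  expect_identical(microhomology(up, intr, "CCC", cap = 12)$k5, 12L)
  expect_identical(microhomology(up, intr, "CCC", cap = 3)$k5, 3L)
})

test_that("empty flanks warn and score zero on that side", {
  expect_warning(mh <- microhomology("", "GTAAAG", "AGTT"), "empty flank")
  expect_identical(mh$k5, 0L)
  expect_true(mh$warning)
  expect_gte(mh$k3, 0L)
  expect_error(microhomology("AAA", "G", "TTT"))  # intron must be >= 2 bp
})

test_that("k5 + k3 is invariant across equivalent slid placements", {
  # sliding the intron right by one base keeps the spliced product iff the
  # intron's first base equals the downstream exon's first base; under that
  # slide k5+k3 (the run of offset-L matches through the junction) is
  # unchanged while k5 and k3 individually trade off -- provided no run is
  # cut short by running off the end of a flank, so truncated cases are
  # excluded below
  slide_right <- function(up, intr, dn) {
    list(up = paste0(up, substr(intr, 1, 1)),
         intr = paste0(substr(intr, 2, nchar(intr)), substr(dn, 1, 1)),
         dn = substr(dn, 2, nchar(dn)))
  }
  # documented counterexample to max-invariance: k changes 2 -> 3 here,
  # while k5+k3 stays 3
  a <- microhomology("TAA", "AAAA", "AT", cap = 8)
  s <- slide_right("TAA", "AAAA", "AT")
  b <- microhomology(s$up, s$intr, s$dn, cap = 8)
  expect_identical(a$k5 + a$k3, 3L)
  expect_identical(b$k5 + b$k3, 3L)
  set.seed(23)
  bases <- c("A", "C", "G", "T")
  found <- 0
  while (found < 200) {
    up <- paste(sample(bases, 6, replace = TRUE), collapse = "")
    intr <- paste(sample(bases, sample(4:9, 1), replace = TRUE), collapse = "")
    dn <- paste(sample(bases, 6, replace = TRUE), collapse = "")
    if (substr(intr, 1, 1) != substr(dn, 1, 1)) next  # not slidable
    # a generous cap so only flank length could truncate a run
    a <- suppressWarnings(microhomology(up, intr, dn, cap = 20))
    s <- slide_right(up, intr, dn)
    b <- suppressWarnings(microhomology(s$up, s$intr, s$dn, cap = 20))
    truncated <- function(m, u, i, d)
      m$k5 == min(nchar(u), nchar(i)) || m$k3 == min(nchar(i), nchar(d))
    if (truncated(a, up, intr, dn) || truncated(b, s$up, s$intr, s$dn)) next
    found <- found + 1
    expect_identical(a$k5 + a$k3, b$k5 + b$k3)
  }
})

test_that("survey recovers planted microhomology and flags its absence", {
  td <- simulate_dataset(sim_config(n_leaves = 4, loss_prob = 0,
                                    micro_k = 3, mut_rate = 0), seed = 301)
  sv <- microhomology_survey(td$structures)
  expect_identical(nrow(sv$per_intron), 4L * 9L)
  expect_true(all(sv$per_intron$k5 == 3L))
  expect_true(all(sv$per_slot$modal_k >= 3L))
  expect_gte(sum(sv$per_slot$modal_k == 3L), 8L)
  expect_false(any(sv$per_slot$low_homology))
  expect_identical(microhomology_survey(list())$per_intron, data.frame())
})

test_that("unplanted flanks match the closed-form null rate", {
  # with uniform base composition P(k >= 1) = 1 - (3/4)^2 = 0.4375;
  # tolerance fixed in advance at 4 binomial SE for 270 introns (0.121)
  ks <- integer(0)
  for (s in 1:30) {
    td <- simulate_dataset(sim_config(n_leaves = 2, loss_prob = 0,
                                      micro_k = 0, mut_rate = 0),
                           seed = 9000 + s)
    sv <- microhomology_survey(td$structures[1])
    ks <- c(ks, sv$per_intron$k)
  }
  expect_length(ks, 270L)
  expect_lt(abs(mean(ks >= 1) - 0.4375), 0.121)
})

test_that("penultimate base is read at exon position -2", {
  g <- paste0("ATGGCCTTAGACCGATGG",          # exon 1, ends ...TGG
              "GTAAGTCCTTAGACCGATCCTAAG",
              "GCTTACGATCCGTTACGGACT",       # exon 2, ends ...ACT
              "GTACGTTCCTTAGACCGATCCTTCCAACAG",
              "CATGCTTACGATCCG")
  gs <- gene_structure(g, data.frame(start = c(1, 43, 94),
                                     end = c(18, 63, 108)), gene_id = "g")
  expect_identical(penultimate_base(gs, 1), "G")
  expect_identical(penultimate_base(gs, 2), "C")
})

test_that("penultimate test contrasts the two groups exactly", {
  # no signal: identical compositions give p = 1
  same <- c("A", "A", "C", "G")
  r <- penultimate_test(same, same, phase = 1)
  expect_equal(r$p_value, 1)
  # disjoint 8 vs 8: two-sided Fisher equals the hand-computed
  # hypergeometric value 2 / choose(16, 8)
  r2 <- penultimate_test(rep("G", 8), rep("A", 8), phase = 1)
  expect_equal(r2$p_value, 2 / choose(16, 8))
  expect_identical(dim(r2$table), c(2L, 2L))
  expect_identical(unname(rowSums(r2$table)), c(8, 8))
  expect_warning(penultimate_test(same, same, phase = 0), "not phase 1")
  expect_error(penultimate_test(character(0), same))
})

test_that("relaxation simulation yields small p at full strength", {
  ps <- vapply(1:200, function(r) {
    g <- simulate_penultimate(12, 12, strength = 1, seed = 500 + r)
    penultimate_test(g$bases_present, g$bases_absent, phase = 1)$p_value
  }, numeric(1))
  expect_lt(stats::median(ps), 0.05)
  # no relaxation: the groups are identical and p is always 1
  g0 <- simulate_penultimate(12, 12, strength = 0, seed = 1)
  expect_equal(
    penultimate_test(g0$bases_present, g0$bases_absent, phase = 1)$p_value, 1)
})

test_that("size_stats aggregates intron lengths per slot", {
  mk <- function(id, ilen) {
    e1 <- strrep("A", 20)
    intr <- paste0("GT", strrep("C", ilen - 4), "AG")
    e2 <- strrep("T", 20)
    gene_structure(paste0(e1, intr, e2),
                   data.frame(start = c(1, 21 + ilen), end = c(20, 40 + ilen)),
                   gene_id = id)
  }
  ss <- size_stats(list(mk("g1", 68), mk("g2", 1071)))
  expect_identical(ss$slot, 1L)
  expect_identical(ss$n, 2L)
  expect_identical(ss$mean_bp, 569.5)
  expect_identical(ss$median_bp, 569.5)
  ss1 <- size_stats(list(mk("solo", 100)))
  expect_identical(ss1$mean_bp, 100)
  expect_identical(ss1$median_bp, 100)
  expect_identical(nrow(size_stats(list())), 0L)
})
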