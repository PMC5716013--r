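test_that("simulated trees are rooted, binary and reproducible", {
  for (n in c(2, 5, 16)) {
    tr <- simulate_tree(n, seed = 4)
    expect_identical(sort(tr$tip.label), sort(paste0("t", 1:n)))
    expect_true(ape::is.rooted(tr))
    expect_true(ape::is.binary(tr))
  }
  expect_identical(ape::write.tree(simulate_tree(10, seed = 8)),
                   ape::write.tree(simulate_tree(10, seed = 8)))
  expect_false(identical(ape::write.tree(simulate_tree(10, seed = 8)),
                         ape::write.tree(simulate_tree(10, seed = 9))))
})

test_that("zero loss probability leaves every slot present", {
  tr <- simulate_tree(8, seed = 1)
  sim <- simulate_events(tr, sim_config(n_leaves = 8, loss_prob = 0), seed = 2)
  expect_identical(nrow(sim$events), 0L)
  expect_true(all(sim$leaf_states == "P"))
})

test_that("replaying the event log reproduces the leaf states", {
  set.seed(3)
  for (rep in 1:10) {
    cfg <- sim_config(n_leaves = 12, loss_prob = 0.12, gain_prob = 0.03)
    tr <- simulate_tree(12, seed = 100 + rep)
    sim <- simulate_events(tr, cfg, seed = 200 + rep)
    # walk root -> leaf and apply logged events along the path
    n_tip <- length(tr$tip.label)
    lab <- c(tr$tip.label, as.character((n_tip + 1):(n_tip + tr$Nnode)))
    parent <- integer(n_tip + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    for (li in seq_len(n_tip)) {
      path <- li
      while (path[1] != n_tip + 1L) path <- c(parent[path[1]], path)
      st <- rep(TRUE, cfg$n_introns)
      for (v in path[-1]) {
        hit <- sim$events$branch == lab[v]
        for (r in which(hit))
          st[sim$events$slot[r]] <- sim$events$type[r] == "gain"
      }
      expect_identical(unname(sim$leaf_states[tr$tip.label[li], ]),
                       ifelse(st, "P", "A"))
    }
  }
})

test_that("emitted genes splice correctly and respect the truth matrix", {
  td <- simulate_dataset(sim_config(n_leaves = 8, loss_prob = 0.12), seed = 402)
  tdf <- as.data.frame(td$matrix)
  for (li in seq_along(td$structures)) {
    gs <- td$structures[[li]]
    # cdna is the spliced genomic
    expect_identical(td$cdna[[gs$gene_id]], spliced_sequence(gs))
    # every emitted intron is GT..AG
    expect_true(all(gs$introns$donor == "GT"))
    expect_true(all(gs$introns$acceptor == "AG"))
    # the alignment row ungaps to the genomic sequence
    expect_identical(gsub("-", "", td$alignment[[gs$gene_id]], fixed = TRUE),
                     td$genomic[[gs$gene_id]])
    # intron count equals the number of P states in the truth matrix
    row <- tdf[tdf$gene == gs$gene_id, paste0("i", 1:9)]
    expect_identical(nrow(gs$introns), sum(row == "P"))
  }
  # alignment rows all share the ancestral coordinate length
  expect_length(unique(nchar(td$alignment)), 1L)
})

test_that("inference on emitted sequences recovers the truth matrix", {
  td <- simulate_dataset(sim_config(n_leaves = 6, loss_prob = 0.15), seed = 77)
  structures <- lapply(names(td$genomic), function(g)
    infer_introns(td$genomic[[g]], td$cdna[[g]], gene_id = g, cds_start = 1))
  proj <- project_introns(td$alignment, structures)
  map <- suppressWarnings(cluster_slots(proj))
  pm <- build_matrix(map, data.frame(gene = names(td$genomic),
                                     species = names(td$genomic),
                                     clade = "sim"),
                     n_slots = 9)
  got <- as.data.frame(pm)[, paste0("i", 1:9)]
  want <- as.data.frame(td$matrix)[, paste0("i", 1:9)]
  expect_identical(got, want)
})

test_that("planted microhomology is exact with a mismatch at k+1", {
  for (k in c(2, 5)) {
    td <- simulate_dataset(sim_config(n_leaves = 3, loss_prob = 0,
                                      micro_k = k, mut_rate = 0),
                           seed = 500 + k)
    for (gs in td$structures) {
      for (i in seq_len(nrow(gs$introns))) {
        ctx <- boundary_context(gs, i, k = k + 1)
        mh <- microhomology(ctx$upstream, ctx$intron, ctx$downstream,
                            cap = k + 1)
        expect_identical(mh$k5, as.integer(k))
      }
    }
  }
})

test_that("a planted motif appears verbatim at the logged offsets", {
  cfg <- sim_config(n_leaves = 5, loss_prob = 0, mut_rate = 0.01,
                    motif = list(string = "GTAACATG", slot = 4))
  td <- simulate_dataset(cfg, seed = 610)
  expect_identical(sort(unique(td$motif_sites$gene)), sort(paste0("t", 1:5)))
  ids <- vapply(td$structures, function(x) x$gene_id, character(1))
  for (r in seq_len(nrow(td$motif_sites))) {
    gs <- td$structures[[match(td$motif_sites$gene[r], ids)]]
    # no losses here, so the intron ordinal equals the ancestral slot
    slot_idx <- td$motif_sites$slot[r]
    intr <- substring(gs$genomic, gs$introns$start[slot_idx],
                      gs$introns$end[slot_idx])
    o <- td$motif_sites$offset_in_intron[r]
    expect_identical(substring(intr, o, o + 7), "GTAACATG")
    expect_identical(scan_mismatches(intr, "GTAACATG")$mismatches, 0L)
  }
})

test_that("dataset directories contain a consistent file set", {
  dir <- withr::local_tempdir()
  td <- simulate_dataset(sim_config(n_leaves = 4, loss_prob = 0.1),
                         seed = 909, dir = dir)
  expect_setequal(list.files(dir),
                  c("genomic.fasta", "cdna.fasta", "alignment.afa", "tree.nwk",
                    "truth_matrix.tsv", "truth_events.tsv", "manifest.txt"))
  g <- read_fasta(file.path(dir, "genomic.fasta"))
  expect_identical(as.character(g), unname(td$genomic))
  a <- read_alignment(file.path(dir, "alignment.afa"))
  expect_identical(as.character(a), unname(td$alignment))
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, names(td$genomic))
  pm <- read_matrix(file.path(dir, "truth_matrix.tsv"))
  expect_identical(as.data.frame(pm), as.data.frame(td$matrix))
  expect_true(any(grepl("seed\t909", readLines(file.path(dir, "manifest.txt")))))
})

test_that("penultimate generator honors strength and sizes", {
  g <- simulate_penultimate(7, 9, strength = 0, constrained_base = "C",
                            seed = 3)
  expect_identical(g$bases_present, rep("C", 7))
  expect_identical(g$bases_absent, rep("C", 9))
  g1 <- simulate_penultimate(5, 400, strength = 1, seed = 4)
  # fully relaxed: roughly uniform base usage in the loser group
  tab <- table(factor(g1$bases_absent, levels = c("A", "C", "G", "T")))
  expect_true(all(tab > 50))
})
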