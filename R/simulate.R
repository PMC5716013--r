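#' Simulation configuration
#'
#' Bundles the parameters of the synthetic intron-evolution generator. The
#' defaults describe a 16-leaf clade evolving a 10-exon/9-intron ancestral
#' gene with a per-branch intron loss probability of 0.05 and no gains —
#' the regime of a structurally dynamic gene in which most slots survive in
#' most lineages but parallel losses are common.
#'
#' @param n_leaves number of leaves.
#' @param n_introns ancestral intron count (exons = n_introns + 1).
#' @param loss_prob per-branch probability that a present intron is lost.
#' @param gain_prob per-branch probability that an absent slot is regained.
#' @param exon_len uniform bounds (bp) for ancestral exon lengths.
#' @param intron_median median ancestral intron length (bp; log-normal).
#' @param intron_sdlog log-normal sdlog for intron lengths.
#' @param micro_k planted splice-junction microhomology length (0 = none).
#' @param motif optional list(string, noise, slot): motif planted once in
#'   the ancestral intron of that slot.
#' @param mut_rate per-base per-branch substitution probability (splice
#'   dinucleotides, planted homology tracts and planted motifs are protected,
#'   emulating their selective constraint).
#' @param base_comp base composition (A,C,G,T).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_leaves = 16, n_introns = 9, loss_prob = 0.05,
                       gain_prob = 0, exon_len = c(80, 200),
                       intron_median = 200, intron_sdlog = 0.6,
                       micro_k = 0, motif = NULL, mut_rate = 0.01,
                       base_comp = rep(0.25, 4)) {
  stopifnot(n_leaves >= 2, n_introns >= 0,
            loss_prob >= 0, loss_prob <= 1, gain_prob >= 0, gain_prob <= 1,
            length(exon_len) == 2, exon_len[1] >= 15,
            intron_median >= 20, micro_k >= 0, micro_k <= 8,
            mut_rate >= 0, mut_rate <= 1)
  if (!is.null(motif)) {
    stopifnot(is.list(motif), !is.null(motif$string), !is.null(motif$slot))
    if (is.null(motif$noise)) motif$noise <- 0
    if (nchar(motif$string) > intron_median)
      stop("planted motif longer than the median intron length", call. = FALSE)
  }
  structure(list(n_leaves = n_leaves, n_introns = n_introns,
                 loss_prob = loss_prob, gain_prob = gain_prob,
                 exon_len = exon_len, intron_median = intron_median,
                 intron_sdlog = intron_sdlog, micro_k = micro_k,
                 motif = motif, mut_rate = mut_rate, base_comp = base_comp),
            class = "sim_config")
}

#' Simulate a random rooted binary tree
#'
#' Grows a tree by sequential random attachment: each new leaf is attached
#' to a uniformly chosen branch (including the root stem), which yields the
#' uniform (proportional-to-distinguishable-arrangements) distribution over
#' labeled rooted binary topologies.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed integer seed; identical seeds give identical trees.
#' @return an [ape::phylo] with tips `t1..tn`; no branch lengths.
#' @export
simulate_tree <- function(n_leaves, seed = NULL) {
  stopifnot(n_leaves >= 2)
  with_seed(seed, {
    # nodes as a parent/children structure; node 1 is the root
    children <- list(c(2L, 3L)); parent <- c(NA, 1L, 1L)
    is_leaf <- c(FALSE, TRUE, TRUE)
    leaf_name <- c(NA, "t1", "t2")
    root <- 1L
    for (k in 3:n_leaves) {
      if (n_leaves < 3) break
      # attachable branches: every non-root node's stem, plus the root stem
      cand <- c(which(!is.na(parent)), root)
      v <- cand[sample(length(cand), 1)]
      new_int <- length(parent) + 1L
      new_leaf <- length(parent) + 2L
      if (v == root) {  # attach above the root: new root
        parent <- c(parent, NA, new_int)
        children[[new_int]] <- c(root, new_leaf)
        parent[root] <- new_int
        root <- new_int
      } else {
        p <- parent[v]
        children[[p]][children[[p]] == v] <- new_int
        parent <- c(parent, p, new_int)
        children[[new_int]] <- c(v, new_leaf)
        parent[v] <- new_int
      }
      is_leaf <- c(is_leaf, FALSE, TRUE)
      leaf_name <- c(leaf_name, NA, paste0("t", k))
    }
    nwk <- function(v) {
      if (is_leaf[v]) return(leaf_name[v])
      paste0("(", paste(vapply(children[[v]], nwk, character(1)),
                        collapse = ","), ")")
    }
    ape::read.tree(text = paste0(nwk(root), ";"))
  })
}

#' Simulate intron loss/gain histories on a tree
#'
#' Every slot starts present at the root; on each branch, independently per
#' slot, a present slot is lost with `loss_prob` and (when `gain_prob > 0`)
#' an absent slot is regained with `gain_prob`. Loss and gain are Bernoulli
#' per branch (topology-only, matching event-count parsimony analyses), not
#' rate-by-length.
#'
#' @param tree a rooted [ape::phylo].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `leaf_states` (leaves x slots character matrix of
#'   P/A), `node_states` (all nodes), `events` (data frame branch =
#'   child-node label, slot, type), `tree`.
#' @export
simulate_events <- function(tree, config = sim_config(), seed = NULL) {
  tp <- prep_tree(tree)
  S <- config$n_introns
  with_seed(seed, {
    node_states <- matrix(TRUE, nrow = tp$n_node, ncol = S)
    ev <- list()
    for (v in rev(tp$post)) {  # preorder
      if (v == tp$root) next
      st <- node_states[tp$parent[v], ]
      for (j in seq_len(S)) {
        if (st[j] && stats::runif(1) < config$loss_prob) {
          st[j] <- FALSE
          ev[[length(ev) + 1]] <- data.frame(branch = tp$labels[v], slot = j,
                                             type = "loss",
                                             stringsAsFactors = FALSE)
        } else if (!st[j] && config$gain_prob > 0 &&
                   stats::runif(1) < config$gain_prob) {
          st[j] <- TRUE
          ev[[length(ev) + 1]] <- data.frame(branch = tp$labels[v], slot = j,
                                             type = "gain",
                                             stringsAsFactors = FALSE)
        }
      }
      node_states[v, ] <- st
    }
    events <- if (length(ev) > 0) do.call(rbind, ev) else
      data.frame(branch = character(0), slot = integer(0), type = character(0))
    leaf_states <- matrix(ifelse(node_states[seq_len(tp$n_tip), , drop = FALSE],
                                 "P", "A"),
                          nrow = tp$n_tip,
                          dimnames = list(tp$tree$tip.label,
                                          paste0("i", seq_len(S))))
    list(leaf_states = leaf_states, node_states = node_states,
         events = events, tree = tree)
  })
}

#' Emit synthetic gene sequences for a simulated history
#'
#' Samples one ancestral gene (exons, GT..AG introns, optional planted
#' microhomology and motif), evolves it down the tree with per-branch point
#' mutations, splices lost introns out of descendant lineages (a regained
#' slot re-inserts the ancestral intron), and returns sequences plus the
#' complete ground truth. The emitted "alignment" is built from the known
#' homology (ancestral coordinates), with gaps where a lineage lacks an
#' intron.
#'
#' @param tree a rooted [ape::phylo].
#' @param sim result of [simulate_events()] on the same tree.
#' @param config the same [sim_config()].
#' @param seed integer seed.
#' @return a `sim_truth` list: `tree`, `events`, `structures` (per-leaf
#'   `gene_structure`), `genomic`, `cdna`, `alignment` (named character
#'   vectors), `matrix` (true [presence_matrix]), `motif_sites` (data frame
#'   gene, slot, offset_in_intron), `config`.
#' @export
emit_sequences <- function(tree, sim, config = sim_config(), seed = NULL) {
  tp <- prep_tree(tree)
  S <- config$n_introns
  with_seed(seed, {
    # ancestral segments: exons e1..e(S+1), introns i1..iS
    exon_lens <- round(stats::runif(S + 1, config$exon_len[1], config$exon_len[2]))
    exons <- lapply(exon_lens, function(L)
      strsplit(random_dna(L, config$base_comp), "", fixed = TRUE)[[1]])
    introns <- vector("list", S)
    motif_offsets <- rep(NA_integer_, S)
    for (j in seq_len(S)) {
      L <- max(20, round(stats::rlnorm(1, log(config$intron_median),
                                       config$intron_sdlog)))
      b <- strsplit(random_dna(L, config$base_comp), "", fixed = TRUE)[[1]]
      b[1:2] <- c("G", "T"); b[(L - 1):L] <- c("A", "G")
      if (!is.null(config$motif) && config$motif$slot == j) {
        w <- nchar(config$motif$string)
        if (L < w + 8) stop("target intron too short for the motif", call. = FALSE)
        o <- sample(3:(L - w - 2), 1)
        b[o:(o + w - 1)] <- strsplit(normalize_dna(config$motif$string), "",
                                     fixed = TRUE)[[1]]
        motif_offsets[j] <- o
      }
      introns[[j]] <- b
    }
    # plant 5' microhomology: upstream exon suffix = intron suffix (k bases),
    # with a forced mismatch at k+1 so the planted length is exact
    k <- config$micro_k
    if (k > 0) {
      for (j in seq_len(S)) {
        ei <- exons[[j]]; ii <- introns[[j]]
        Le <- length(ei); Li <- length(ii)
        ei[(Le - k + 1):Le] <- ii[(Li - k + 1):Li]
        mismatch_base <- setdiff(DNA_BASES, ii[Li - k])
        ei[Le - k] <- sample(mismatch_base, 1)
        exons[[j]] <- ei
      }
    }
    # positions protected from mutation (constraint emulation)
    protect <- lapply(seq_len(S), function(j) {
      L <- length(introns[[j]])
      p <- c(1:2, (L - 1):L)
      if (!is.na(motif_offsets[j])) {
        w <- nchar(config$motif$string)
        p <- c(p, motif_offsets[j]:(motif_offsets[j] + w - 1))
      }
      p
    })
    protect_exon <- lapply(seq_len(S + 1), function(j) {
      if (k > 0 && j <= S) (length(exons[[j]]) - k + 1):length(exons[[j]])
      else integer(0)
    })

    mutate <- function(seg, protected) {
      if (config$mut_rate == 0) return(seg)
      hit <- which(stats::runif(length(seg)) < config$mut_rate)
      hit <- setdiff(hit, protected)
      for (p in hit) seg[p] <- sample(setdiff(DNA_BASES, seg[p]), 1)
      seg
    }

    node_seqs <- vector("list", tp$n_node)
    node_seqs[[tp$root]] <- list(exons = exons, introns = introns)
    for (v in rev(tp$post)) {  # preorder
      if (v == tp$root) next
      sq <- node_seqs[[tp$parent[v]]]
      sq$exons <- lapply(seq_along(sq$exons), function(j)
        mutate(sq$exons[[j]], protect_exon[[j]]))
      sq$introns <- lapply(seq_along(sq$introns), function(j)
        mutate(sq$introns[[j]], protect[[j]]))
      node_seqs[[v]] <- sq
    }

    leaves <- tp$tree$tip.label
    genomic <- character(length(leaves)); cdna <- character(length(leaves))
    aligned <- character(length(leaves))
    structures <- vector("list", length(leaves))
    motif_sites <- list()
    for (li in seq_along(leaves)) {
      sq <- node_seqs[[li]]
      present <- sim$leaf_states[leaves[li], ] == "P"
      segs <- character(0); aln <- character(0)
      exon_df <- data.frame(start = integer(0), end = integer(0))
      pos <- 0L
      merge_next <- FALSE
      for (j in seq_len(S + 1)) {
        e <- paste(sq$exons[[j]], collapse = "")
        if (merge_next) {
          # previous intron is lost in this lineage: the flanking exons fuse
          exon_df$end[nrow(exon_df)] <- pos + nchar(e)
        } else {
          exon_df <- rbind(exon_df,
                           data.frame(start = pos + 1L, end = pos + nchar(e)))
        }
        pos <- pos + nchar(e)
        segs <- c(segs, e); aln <- c(aln, e)
        if (j <= S) {
          istr <- paste(sq$introns[[j]], collapse = "")
          merge_next <- !present[j]
          if (present[j]) {
            segs <- c(segs, istr); aln <- c(aln, istr)
            pos <- pos + nchar(istr)
            if (!is.na(motif_offsets[j]))
              motif_sites[[length(motif_sites) + 1]] <-
                data.frame(gene = leaves[li], slot = j,
                           offset_in_intron = motif_offsets[j],
                           stringsAsFactors = FALSE)
          } else {
            aln <- c(aln, strrep("-", nchar(istr)))
          }
        }
      }
      genomic[li] <- paste(segs, collapse = "")
      aligned[li] <- paste(aln, collapse = "")
      structures[[li]] <- gene_structure(genomic[li], exon_df,
                                         gene_id = leaves[li],
                                         species = leaves[li], cds_start = 1)
      cdna[li] <- structures[[li]]$cdna
    }
    names(genomic) <- leaves; names(cdna) <- leaves; names(aligned) <- leaves
    truth_pm <- presence_matrix(data.frame(
      gene = leaves, species = leaves, clade = "sim",
      as.data.frame(sim$leaf_states, stringsAsFactors = FALSE),
      stringsAsFactors = FALSE, check.names = FALSE))
    structure(list(tree = tree, events = sim$events, structures = structures,
                   genomic = genomic, cdna = cdna, alignment = aligned,
                   matrix = truth_pm,
                   motif_sites = if (length(motif_sites) > 0)
                     do.call(rbind, motif_sites) else
                     data.frame(gene = character(0), slot = integer(0),
                                offset_in_intron = integer(0)),
                   config = config),
              class = "sim_truth")
  })
}

#' Run the full generator and write a dataset directory
#'
#' @param config a [sim_config()].
#' @param seed integer seed driving tree, events and sequences.
#' @param dir optional output directory; when given, writes genomic.fasta,
#'   cdna.fasta, alignment.afa, tree.nwk, truth_matrix.tsv, truth_events.tsv
#'   and manifest.txt.
#' @return a `sim_truth` (see [emit_sequences()]).
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1, dir = NULL) {
  tree <- simulate_tree(config$n_leaves, seed = seed)
  sim <- simulate_events(tree, config, seed = seed + 1L)
  truth <- emit_sequences(tree, sim, config, seed = seed + 2L)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(truth$genomic, file.path(dir, "genomic.fasta"))
    write_fasta(truth$cdna, file.path(dir, "cdna.fasta"))
    write_fasta(truth$alignment, file.path(dir, "alignment.afa"))
    write_newick(tree, file.path(dir, "tree.nwk"))
    write_matrix(truth$matrix, file.path(dir, "truth_matrix.tsv"))
    utils::write.table(truth$events, file.path(dir, "truth_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- unlist(lapply(config, function(x)
      paste(format(x, digits = 10), collapse = ",")))
    writeLines(c(sprintf("seed\t%d", seed),
                 paste(names(cfg), cfg, sep = "\t")),
               file.path(dir, "manifest.txt"))
  }
  truth
}

#' Penultimate-base relaxation generator
#'
#' Emits exon penultimate bases for two groups of genes: carriers of a
#' downstream phase-1 intron, where the base is held at a fixed splicing-
#' constrained identity, and losers, where with probability `strength` the
#' base has drifted to a uniform random base (codon third position free to
#' mutate after the splicing constraint is released).
#'
#' @param n_with,n_without group sizes.
#' @param strength relaxation probability in the loser group (1 = fully
#'   relaxed).
#' @param constrained_base the base enforced in carriers.
#' @param seed integer seed.
#' @return list with `bases_present`, `bases_absent`.
#' @export
simulate_penultimate <- function(n_with, n_without, strength = 1,
                                 constrained_base = "G", seed = NULL) {
  with_seed(seed, {
    bp <- rep(constrained_base, n_with)
    ba <- vapply(seq_len(n_without), function(i) {
      if (stats::runif(1) < strength) sample(DNA_BASES, 1) else constrained_base
    }, character(1))
    list(bases_present = bp, bases_absent = ba)
  })
}
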