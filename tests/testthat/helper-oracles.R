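# Independent brute-force oracles used to validate the fast implementations.
# Everything here is written for clarity, not speed, and shares no code with
# the package internals.

# --- exhaustive parsimony ---------------------------------------------------

# All rooted binary topologies on the given labels, as newick strings.
# Built by sequential insertion of each label into every edge (including the
# root stem) of every smaller tree, which enumerates each topology once.
all_rooted_topologies <- function(labels) {
  trees <- labels[1]
  for (k in 2:length(labels)) {
    leaf <- labels[k]
    out <- character(0)
    for (t in trees) {
      # insert above every subtree: every position where a subtree starts
      spots <- subtree_spans(t)
      for (s in seq_len(nrow(spots))) {
        sub <- substr(t, spots$from[s], spots$to[s])
        out <- c(out, paste0(substr(t, 1, spots$from[s] - 1),
                             "(", sub, ",", leaf, ")",
                             substr(t, spots$to[s] + 1, nchar(t))))
      }
    }
    trees <- out
  }
  paste0(trees, ";")
}

# Character spans of every subtree (leaf or parenthesized group) in a newick
# fragment without the trailing semicolon.
subtree_spans <- function(t) {
  chars <- strsplit(t, "", fixed = TRUE)[[1]]
  from <- integer(0); to <- integer(0)
  depth <- 0
  i <- 1
  n <- length(chars)
  starts <- integer(0)  # stack of '(' positions
  word_start <- NA
  for (i in seq_len(n)) {
    c <- chars[i]
    if (c == "(") {
      starts <- c(starts, i)
    } else if (c == ")") {
      if (!is.na(word_start)) { from <- c(from, word_start); to <- c(to, i - 1) }
      word_start <- NA
      from <- c(from, starts[length(starts)]); to <- c(to, i)
      starts <- starts[-length(starts)]
    } else if (c %in% c(",", ";")) {
      if (!is.na(word_start)) { from <- c(from, word_start); to <- c(to, i - 1) }
      word_start <- NA
    } else {
      if (is.na(word_start) &&
          (i == 1 || chars[i - 1] %in% c("(", ","))) word_start <- i
      if (i == n && !is.na(word_start)) { from <- c(from, word_start); to <- c(to, n) }
    }
  }
  data.frame(from = from, to = to)
}

# Edge list (parent, child) and leaf numbering for a phylo object.
tree_edges <- function(tree) {
  list(edge = tree$edge, n_tip = length(tree$tip.label),
       root = length(tree$tip.label) + 1L, tips = tree$tip.label)
}

# Minimum Sankoff cost by exhaustive enumeration over all internal-node
# assignments. Leaves with a fixed state contribute their leaf-edge cost
# given the parent's state; ND leaves contribute the cheaper of the two.
# Returns a vector of minima, one per leaf-state vector (rows of `states`,
# a character matrix with columns in tree tip order). Vectorized over state
# vectors: the cost matrix (assignments x state vectors) is grown leaf by
# leaf, with the newest leaf's state varying slowest so columns line up with
# expand.grid order (first leaf fastest), as produced by all_state_vectors.
oracle_sankoff <- function(tree, states, cost_loss = 1, cost_gain = 1,
                           root_state = "P") {
  te <- tree_edges(tree)
  n_int <- tree$Nnode
  int_nodes <- te$n_tip + seq_len(n_int)
  # all 2^n_int internal assignments; TRUE = present
  grid <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), n_int)))
  colnames(grid) <- int_nodes
  if (root_state != "free")
    grid <- grid[grid[, as.character(te$root)] == (root_state == "P"), ,
                 drop = FALSE]
  # internal-edge costs per assignment
  int_cost <- numeric(nrow(grid))
  for (e in seq_len(nrow(te$edge))) {
    p <- te$edge[e, 1]; c <- te$edge[e, 2]
    if (c <= te$n_tip) next
    pp <- grid[, as.character(p)]; cc <- grid[, as.character(c)]
    int_cost <- int_cost + ifelse(pp & !cc, cost_loss,
                                  ifelse(!pp & cc, cost_gain, 0))
  }
  leaf_parent <- integer(te$n_tip)
  for (e in seq_len(nrow(te$edge)))
    if (te$edge[e, 2] <= te$n_tip) leaf_parent[te$edge[e, 2]] <- te$edge[e, 1]
  M <- matrix(int_cost, ncol = 1)
  for (l in seq_len(te$n_tip)) {
    pp <- grid[, as.character(leaf_parent[l])]
    cP <- ifelse(pp, 0, cost_gain)
    cA <- ifelse(pp, cost_loss, 0)
    cND <- pmin(cP, cA)
    M <- cbind(M + cP, M + cA, M + cND)
  }
  minima <- apply(M, 2, min)
  idx <- as.integer(
    1 + colSums(t(matrix(match(states, c("P", "A", "ND")) - 1L,
                         nrow = nrow(states))) *
                3^(seq_len(te$n_tip) - 1L)))
  minima[idx]
}

# Minimum Dollo loss count by exhaustive enumeration: root present, gains
# forbidden anywhere (including leaf edges), ND leaves free. Same
# vectorization as oracle_sankoff; forbidden configurations carry Inf.
oracle_dollo <- function(tree, states) {
  te <- tree_edges(tree)
  n_int <- tree$Nnode
  int_nodes <- te$n_tip + seq_len(n_int)
  grid <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), n_int)))
  colnames(grid) <- int_nodes
  grid <- grid[grid[, as.character(te$root)], , drop = FALSE]
  int_cost <- numeric(nrow(grid))
  for (e in seq_len(nrow(te$edge))) {
    p <- te$edge[e, 1]; c <- te$edge[e, 2]
    if (c <= te$n_tip) next
    pp <- grid[, as.character(p)]; cc <- grid[, as.character(c)]
    int_cost <- int_cost + ifelse(!pp & cc, Inf, as.numeric(pp & !cc))
  }
  leaf_parent <- integer(te$n_tip)
  for (e in seq_len(nrow(te$edge)))
    if (te$edge[e, 2] <= te$n_tip) leaf_parent[te$edge[e, 2]] <- te$edge[e, 1]
  M <- matrix(int_cost, ncol = 1)
  for (l in seq_len(te$n_tip)) {
    pp <- grid[, as.character(leaf_parent[l])]
    cP <- ifelse(pp, 0, Inf)       # a leaf gain is forbidden
    cA <- ifelse(pp, 1, 0)         # loss where the parent is present
    cND <- pmin(cP, cA)            # free leaf, cheapest choice
    M <- cbind(M + cP, M + cA, M + cND)
  }
  minima <- apply(M, 2, min)
  idx <- as.integer(
    1 + colSums(t(matrix(match(states, c("P", "A", "ND")) - 1L,
                         nrow = nrow(states))) *
                3^(seq_len(te$n_tip) - 1L)))
  out <- minima[idx]
  out[is.infinite(out)] <- NA_real_
  out
}

# All leaf-state vectors over {P, A, ND} for n leaves, as a character matrix.
all_state_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(c("P", "A", "ND")), n),
                        stringsAsFactors = FALSE))
}

# --- boundaries -------------------------------------------------------------

# Naive character-by-character microhomology.
oracle_microhomology <- function(up, intr, dn, cap = 8) {
  up <- toupper(up); intr <- toupper(intr); dn <- toupper(dn)
  uc <- strsplit(up, "", fixed = TRUE)[[1]]
  ic <- strsplit(intr, "", fixed = TRUE)[[1]]
  dc <- strsplit(dn, "", fixed = TRUE)[[1]]
  k5 <- 0
  while (k5 < min(length(uc), length(ic), cap) &&
         uc[length(uc) - k5] == ic[length(ic) - k5]) k5 <- k5 + 1
  k3 <- 0
  while (k3 < min(length(ic), length(dc), cap) && ic[k3 + 1] == dc[k3 + 1])
    k3 <- k3 + 1
  list(k5 = k5, k3 = k3, k = max(k5, k3))
}

# --- clustering -------------------------------------------------------------

# Transitive closure single-linkage by repeated passes over the full
# pairwise adjacency, with no sorting tricks.
oracle_cluster <- function(proj, tol = 0, same_phase = TRUE) {
  n <- nrow(proj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (abs(proj$column[i] - proj$column[j]) > tol) next
      if (same_phase && proj$phase[i] != proj$phase[j]) next
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # rank clusters by median column
  meds <- tapply(proj$column, comp, median)
  slot_of <- rank(meds, ties.method = "first")
  as.integer(slot_of[as.character(comp)])
}

# --- misc -------------------------------------------------------------------

random_states <- function(tips, p_nd = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- sample(c("P", "A", "ND"), length(tips), replace = TRUE,
              prob = c((1 - p_nd) / 2, (1 - p_nd) / 2, p_nd))
  stats::setNames(s, tips)
}

# Dinucleotide counts of a sequence, as a named table.
dinuc_counts <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}
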