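#' Discover fixed-width motifs by one-occurrence-per-sequence EM
#'
#' Fits an OOPS motif model: every input sequence contains exactly one site
#' of a fixed-width motif described by a position probability matrix against
#' a 0-order background estimated from the input. Each motif is fitted by
#' expectation-maximization from several seeded initializations (each built
#' from a randomly chosen width-`width` subsequence), keeping the converged
#' model with the highest log-likelihood ratio; subsequent motifs are found
#' after masking the sites of earlier ones. Ranking and significance use a
#' surrogate score (log-likelihood ratio penalized by the log number of
#' possible site configurations); this score is internally consistent but
#' deliberately not comparable to MEME e-values.
#'
#' @param sequences named (or unnamed) character vector of DNA sequences.
#' @param width motif width (bp).
#' @param n_motifs number of motifs to report.
#' @param restarts EM restarts per motif.
#' @param seed integer seed; identical seeds give identical results.
#' @param max_iter,tol EM iteration cap and LLR convergence threshold.
#' @param pseudo_frac pseudocount added to each count cell, as a fraction of
#'   the background probability of the base.
#' @return list of `motif_model` objects, ranked by score. Each has `theta`
#'   (width x 4 position probability matrix), `background`, `sites` (data
#'   frame seq, offset), `llr`, `score`, `width`, `llr_trace`, `converged`.
#' @export
discover_motifs <- function(sequences, width = 12, n_motifs = 1, restarts = 5,
                            seed = NULL, max_iter = 200, tol = 1e-6,
                            pseudo_frac = 0.01) {
  stopifnot(length(sequences) >= 2)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  seqs <- normalize_dna(sequences)
  short <- nchar(seqs) < width
  if (all(short)) stop("all sequences shorter than the motif width", call. = FALSE)
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than width excluded", call. = FALSE)
    seqs <- seqs[!short]
  }
  enc <- lapply(seqs, encode_dna)
  # 0-order background from the input set (N excluded)
  cnt <- table(factor(unlist(lapply(enc, function(v) v[v < 4])), levels = 0:3))
  bg <- as.numeric(cnt) + 1
  bg <- bg / sum(bg)
  with_seed(seed, {
    models <- list()
    masked <- enc
    for (m in seq_len(n_motifs)) {
      best <- NULL
      for (r in seq_len(restarts)) {
        theta0 <- seed_theta(masked, width, bg)
        if (is.null(theta0)) break
        fit <- cpp_em_oops(masked, as.integer(width), theta0, bg,
                           as.integer(max_iter), tol, pseudo_frac)
        if (is.null(best) || fit$llr > best$llr) best <- fit
      }
      if (is.null(best)) break
      # With pseudocounts the M-step maximizes a MAP objective, so the raw
      # LLR may dip by tiny amounts; only warn on substantive decreases.
      if (any(diff(best$llr_trace) < -1e-3))
        warning("EM log-likelihood ratio decreased; not converged", call. = FALSE)
      noff <- vapply(masked, length, integer(1)) - width + 1L
      score <- best$llr - sum(log(noff))
      theta <- best$theta
      dimnames(theta) <- list(NULL, DNA_BASES)
      models[[m]] <- structure(
        list(theta = theta, background = stats::setNames(bg, DNA_BASES),
             sites = data.frame(seq = names(seqs), offset = best$offsets,
                                stringsAsFactors = FALSE),
             llr = best$llr, score = score, width = width,
             llr_trace = best$llr_trace, converged = best$converged),
        class = "motif_model")
      # erase found sites for the next motif
      if (m < n_motifs) {
        for (i in seq_along(masked)) {
          o <- best$offsets[i]
          masked[[i]][o:(o + width - 1L)] <- 4L
        }
      }
    }
    models[order(vapply(models, function(x) x$score, numeric(1)),
                 decreasing = TRUE)]
  })
}

# Initialize theta from a random unmasked W-mer: 0.7 on the seed base,
# 0.1 elsewhere.
seed_theta <- function(enc, width, bg) {
  for (try in 1:50) {
    i <- sample(length(enc), 1)
    L <- length(enc[[i]]) - width + 1L
    if (L < 1) next
    o <- sample(L, 1)
    win <- enc[[i]][o:(o + width - 1L)]
    if (any(win > 3)) next
    theta <- matrix(0.1, nrow = width, ncol = 4)
    theta[cbind(seq_len(width), win + 1L)] <- 0.7
    return(theta)
  }
  NULL
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model: width %d, LLR %.2f, score %.2f, consensus %s\n",
              x$width, x$llr, x$score, consensus_string(x)))
  invisible(x)
}

consensus_string <- function(model) {
  paste(DNA_BASES[apply(model$theta, 1, which.max)], collapse = "")
}

#' Core consensus of a motif model
#'
#' The core is the maximal run of motif positions whose top base exceeds the
#' probability threshold; the primary core is the longest such run (leftmost
#' on ties). The full-width consensus shows IUPAC degeneracy codes outside
#' the core.
#'
#' @param model a `motif_model`.
#' @param threshold top-base probability defining a core position.
#' @return list with `core` (string over ACGT; empty when no position
#'   exceeds the threshold), `start` (position of the core in the motif),
#'   `runs` (all maximal runs), `full_consensus` (IUPAC, core uppercase).
#' @export
core_of <- function(model, threshold = 0.8) {
  top <- apply(model$theta, 1, max)
  base <- DNA_BASES[apply(model$theta, 1, which.max)]
  above <- top > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0)
    return(list(core = "", start = NA_integer_, runs = runs,
                full_consensus = iupac_consensus(model$theta, integer(0))))
  runs$length <- runs$end - runs$start + 1L
  primary <- runs[which.max(runs$length), ]  # which.max -> leftmost on ties
  core_pos <- primary$start:primary$end
  list(core = paste(base[core_pos], collapse = ""),
       start = primary$start, runs = runs,
       full_consensus = iupac_consensus(model$theta, core_pos))
}

IUPAC_CODE <- c(A = "A", C = "C", G = "G", T = "T",
                AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

iupac_consensus <- function(theta, core_pos, include = 0.25) {
  out <- character(nrow(theta))
  for (w in seq_len(nrow(theta))) {
    if (w %in% core_pos) {
      out[w] <- DNA_BASES[which.max(theta[w, ])]
    } else {
      keep <- DNA_BASES[theta[w, ] >= include]
      if (length(keep) == 0) keep <- DNA_BASES[which.max(theta[w, ])]
      out[w] <- tolower(IUPAC_CODE[[paste(keep, collapse = "")]])
    }
  }
  paste(out, collapse = "")
}

#' Best match of a core motif in a sequence
#'
#' Minimum Hamming distance of the core over all ungapped offsets on the
#' forward strand.
#'
#' @param sequence DNA string.
#' @param core motif string over ACGT.
#' @return list with `mismatches` and `offset` (1-based start of the best
#'   match; for a sequence shorter than the core, mismatches is defined as
#'   the core length and a warning is raised).
#' @export
scan_mismatches <- function(sequence, core) {
  s <- normalize_dna(sequence); core <- normalize_dna(core)
  n <- nchar(s); w <- nchar(core)
  if (n < w) {
    warning("sequence shorter than core; all-mismatch by definition",
            call. = FALSE)
    return(list(mismatches = w, offset = NA_integer_))
  }
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  cv <- strsplit(core, "", fixed = TRUE)[[1]]
  n_off <- n - w + 1L
  mism <- integer(n_off)
  for (p in seq_len(w))
    mism <- mism + (sv[seq_len(n_off) + p - 1L] != cv[p])
  best <- which.min(mism)
  list(mismatches = as.integer(mism[best]), offset = as.integer(best))
}

#' Empirical motif significance from resampled null sets
#'
#' Runs discovery on the target set and on each null set with identical
#' parameters, and reports the fraction of null sets whose best surrogate
#' score is at least the target's. Each run's seed is derived from the base
#' seed plus a content fingerprint of its sequence set, so a null set
#' identical to the target is scored identically (the self-comparison gives
#' exactly p = 1) while distinct sets get their own reproducible seeds. The
#' caller is responsible for making the null sets comparable in number and
#' length to the target (see [shuffle_sequences()]).
#'
#' @param target character vector of DNA sequences.
#' @param null_sets list of character vectors, at least 20 (fewer gives too
#'   coarse a p-value granularity and is refused).
#' @param width,restarts,max_iter,tol passed to [discover_motifs()].
#' @param seed integer base seed; each run adds its set's fingerprint.
#' @return list with `p` (empirical p-value), `target_score`, `null_scores`,
#'   `n_replicates`.
#' @export
empirical_pvalue <- function(target, null_sets, width = 12, restarts = 5,
                             seed = 1, max_iter = 200, tol = 1e-6) {
  if (length(null_sets) < 20)
    stop("at least 20 null sets required for a usable p-value", call. = FALSE)
  run <- function(set) {
    discover_motifs(set, width = width, n_motifs = 1,
                    restarts = restarts, seed = seed + set_fingerprint(set),
                    max_iter = max_iter, tol = tol)[[1]]
  }
  tgt <- run(target)
  null_scores <- vapply(null_sets, function(s) run(s)$score, numeric(1))
  list(p = mean(null_scores >= tgt$score - 1e-9),
       target_score = tgt$score, null_scores = null_scores,
       n_replicates = length(null_sets))
}

# Position-weighted content fingerprint of a sequence set, used to derive
# per-run seeds: identical sets map to the same seed (so the diagnostic
# self-comparison is exactly reproducible), permuted or shuffled sets do
# not. Plain double arithmetic keeps the sum exact for any realistic size.
set_fingerprint <- function(set) {
  v <- utf8ToInt(paste(unname(set), collapse = "\n"))
  as.integer(sum((v %% 64) * (seq_along(v) %% 97)) %% 100003)
}

#' Shuffle sequences preserving composition
#'
#' `mononucleotide` permutes bases; `dinucleotide` preserves dinucleotide
#' frequencies using a random Eulerian walk on the dinucleotide transition
#' multigraph (random arborescence toward the terminal base, remaining
#' edges in random order).
#'
#' @param sequences character vector of DNA sequences.
#' @param method shuffle order to preserve.
#' @param seed integer seed.
#' @return character vector of shuffled sequences.
#' @export
shuffle_sequences <- function(sequences,
                              method = c("dinucleotide", "mononucleotide"),
                              seed = NULL) {
  method <- match.arg(method)
  with_seed(seed, {
    vapply(normalize_dna(sequences), function(s) {
      v <- strsplit(s, "", fixed = TRUE)[[1]]
      if (method == "mononucleotide") return(paste(sample(v), collapse = ""))
      dinuc_shuffle_one(v)
    }, character(1), USE.NAMES = FALSE)
  })
}

# Altschul-Erikson style dinucleotide shuffle on a character vector.
dinuc_shuffle_one <- function(v) {
  n <- length(v)
  if (n < 3) return(paste(v, collapse = ""))
  first <- v[1]; last <- v[n]
  edges <- split(v[-1], v[-n])  # outgoing edge targets per source base
  verts <- names(edges)
  for (attempt in 1:200) {
    # pick a candidate last edge out of each non-terminal vertex
    last_edge <- vapply(verts, function(u) {
      if (u == last && length(edges[[u]]) == 0) return(NA_character_)
      sample(edges[[u]], 1)
    }, character(1))
    # those last edges must let every vertex reach the terminal vertex
    ok <- TRUE
    for (u in verts) {
      if (u == last) next
      seen <- character(0); w <- u
      repeat {
        if (w == last) break
        if (w %in% seen || !w %in% verts || is.na(last_edge[[w]])) { ok <- FALSE; break }
        seen <- c(seen, w); w <- last_edge[[w]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  if (!ok) return(paste(c(first, sample(v[-1])), collapse = ""))  # fallback
  # order the remaining edges randomly, append the chosen last edge
  shuffled <- lapply(verts, function(u) {
    e <- edges[[u]]
    if (u != last || length(e) > 0) {
      le <- last_edge[[u]]
      i <- match(le, e)
      e <- c(sample(e[-i]), le)
    }
    e
  })
  names(shuffled) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n); out[1] <- first
  u <- first
  for (i in 2:n) {
    nxt <- shuffled[[u]][ptr[[u]]]
    ptr[[u]] <- ptr[[u]] + 1L
    out[i] <- nxt
    u <- nxt
  }
  paste(out, collapse = "")
}

#' Generate a synthetic motif-discovery set with a planted site
#'
#' Emits random background sequences each carrying one planted occurrence of
#' a consensus (with per-position substitution noise; `N` positions are
#' drawn from the background) at a random offset, plus the ground-truth
#' sites.
#'
#' @param n number of sequences.
#' @param length sequence length (bp).
#' @param consensus planted consensus string (IUPAC `N` allowed).
#' @param noise per-position probability of replacing a non-N consensus base
#'   with a random base.
#' @param seed integer seed.
#' @param base_comp background base composition (A,C,G,T).
#' @return list with `sequences` (named character vector) and `sites` (data
#'   frame seq, offset).
#' @export
simulate_motif_set <- function(n, length, consensus, noise = 0.1, seed = NULL,
                               base_comp = rep(0.25, 4)) {
  w <- nchar(consensus)
  stopifnot(length >= w)
  cons <- strsplit(normalize_dna(consensus), "", fixed = TRUE)[[1]]
  with_seed(seed, {
    seqs <- character(n); offs <- integer(n)
    for (i in seq_len(n)) {
      s <- strsplit(random_dna(length, base_comp), "", fixed = TRUE)[[1]]
      o <- sample(length - w + 1L, 1)
      site <- cons
      for (p in seq_len(w)) {
        if (site[p] == "N" || stats::runif(1) < noise)
          site[p] <- sample(DNA_BASES, 1, prob = base_comp)
      }
      s[o:(o + w - 1L)] <- site
      seqs[i] <- paste(s, collapse = "")
      offs[i] <- o
    }
    names(seqs) <- sprintf("seq%03d", seq_len(n))
    list(sequences = seqs, sites = data.frame(seq = names(seqs), offset = offs,
                                              stringsAsFactors = FALSE))
  })
}
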