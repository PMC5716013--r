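#' Splice-junction microhomology
#'
#' Direct-repeat microhomology around an intron, the signature expected when
#' an intron was deleted by non-homologous end joining of a double-strand
#' break: `k5` is the length of the longest common suffix of the upstream
#' exon and the intron, `k3` the longest common prefix of the intron and the
#' downstream exon, and `k = max(k5, k3)`. Comparison is exact,
#' case-insensitive, and capped at `cap` (default 8, the upper end of the
#' microhomology range typical of NHEJ deletions). The sum `k5 + k3` is
#' invariant to equivalent (slid) placements of the intron; the reported `k`
#' is made deterministic by the leftmost-placement convention of
#' [infer_introns()].
#'
#' @param upstream_exon,intron,downstream_exon DNA strings (verbatim; no
#'   normalization beyond case).
#' @param cap maximum homology length searched.
#' @return list with `k5`, `k3`, `k`, `cap`, `warning` (TRUE when a flank
#'   was empty).
#' @export
microhomology <- function(upstream_exon, intron, downstream_exon, cap = 8) {
  stopifnot(nchar(intron) >= 2)
  up <- toupper(upstream_exon); intr <- toupper(intron)
  dn <- toupper(downstream_exon)
  warn <- FALSE
  if (nchar(up) == 0 || nchar(dn) == 0) {
    warn <- TRUE
    warning("empty flank; that side's homology is 0", call. = FALSE)
  }
  common_suffix <- function(a, b, cap) {
    m <- min(nchar(a), nchar(b), cap)
    k <- 0L
    while (k < m && substr(a, nchar(a) - k, nchar(a) - k) ==
                    substr(b, nchar(b) - k, nchar(b) - k)) k <- k + 1L
    k
  }
  common_prefix <- function(a, b, cap) {
    m <- min(nchar(a), nchar(b), cap)
    k <- 0L
    while (k < m && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L))
      k <- k + 1L
    k
  }
  k5 <- common_suffix(up, intr, cap)
  k3 <- common_prefix(intr, dn, cap)
  list(k5 = k5, k3 = k3, k = max(k5, k3), cap = cap, warning = warn)
}

#' Microhomology survey across genes and slots
#'
#' Computes [microhomology()] for every intron of every structure and
#' aggregates the distribution of `k` per ancestral slot. Slots whose modal
#' `k` is below 2 are flagged (microhomology of at least 2 bp is the usual
#' NHEJ signature).
#'
#' @param structures list of `gene_structure` objects.
#' @param map optional `homology_map` assigning introns to slots; without a
#'   map, the intron ordinal is used as the slot.
#' @param cap maximum homology length searched.
#' @return list with `per_intron` (data frame gene, intron_index, slot, k5,
#'   k3, k) and `per_slot` (data frame slot, n, modal_k, mean_k,
#'   low_homology flag).
#' @export
microhomology_survey <- function(structures, map = NULL, cap = 8) {
  rows <- list()
  for (gs in structures) {
    ni <- nrow(gs$introns)
    if (ni == 0) next
    for (i in seq_len(ni)) {
      ctx <- suppressWarnings(boundary_context(gs, i, k = cap))
      mh <- suppressWarnings(microhomology(ctx$upstream, ctx$intron,
                                           ctx$downstream, cap = cap))
      slot <- i
      if (!is.null(map)) {
        hit <- map$slot[map$gene == gs$gene_id & map$intron_index == i]
        slot <- if (length(hit) == 1) hit else NA_integer_
      }
      rows[[length(rows) + 1]] <-
        data.frame(gene = gs$gene_id, intron_index = i, slot = slot,
                   k5 = mh$k5, k3 = mh$k3, k = mh$k, stringsAsFactors = FALSE)
    }
  }
  per_intron <- do.call(rbind, rows)
  if (is.null(per_intron))
    return(list(per_intron = data.frame(), per_slot = data.frame()))
  per_slot <- do.call(rbind, lapply(split(per_intron, per_intron$slot), function(d) {
    tab <- table(d$k)
    modal <- as.integer(names(tab)[which.max(tab)])
    data.frame(slot = d$slot[1], n = nrow(d), modal_k = modal,
               mean_k = mean(d$k), low_homology = modal < 2)
  }))
  rownames(per_slot) <- NULL
  list(per_intron = per_intron, per_slot = per_slot)
}

#' Exon penultimate base upstream of an intron
#'
#' The base at position -2 of the exon immediately upstream of the given
#' intron. For a phase-1 intron this is the third base of the terminal
#' codon, the position whose selective constraint is released once the
#' downstream intron (and hence its splicing requirement) is lost.
#'
#' @param structure a `gene_structure`.
#' @param intron_index 1-based intron ordinal.
#' @return single uppercase base.
#' @export
penultimate_base <- function(structure, intron_index) {
  ex <- structure$exons[intron_index, ]
  if (nrow(ex) != 1 || is.na(ex$start) || ex$end - ex$start < 1)
    stop("upstream exon too short for a penultimate base", call. = FALSE)
  substring(structure$genomic, ex$end - 1L, ex$end - 1L)
}

#' Test for relaxed constraint at the exon penultimate base
#'
#' Contrasts the base composition at exon position -2 between genes that
#' retain the downstream intron and genes that lost it, with a two-sided
#' Fisher exact test on the 2 x k contingency table (empty base columns
#' dropped). The biological rationale applies to phase-1 introns, where the
#' -2 position is a codon third base; a non-phase-1 slot triggers a warning
#' but the test is still computed.
#'
#' @param bases_present,bases_absent character vectors of single bases for
#'   the intron-carrying and intron-lacking groups.
#' @param phase optional slot phase (0/1/2), used only for the warning.
#' @return list with `table` (2 x k contingency), `p_value`, `test`.
#' @export
penultimate_test <- function(bases_present, bases_absent, phase = NULL) {
  stopifnot(length(bases_present) > 0, length(bases_absent) > 0)
  if (!is.null(phase) && !is.na(phase) && phase != 1)
    warning("slot is not phase 1; the constraint-release rationale may not apply",
            call. = FALSE)
  b <- factor(c(toupper(bases_present), toupper(bases_absent)),
              levels = DNA_BASES)
  g <- factor(rep(c("intron_present", "intron_absent"),
                  c(length(bases_present), length(bases_absent))),
              levels = c("intron_present", "intron_absent"))
  tab <- table(g, b)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  # a single observed base carries no contrast at all: p = 1 by convention
  p <- if (ncol(tab) < 2) 1 else stats::fisher.test(tab)$p.value
  list(table = tab, p_value = p, test = "fisher_exact_two_sided")
}

#' Per-slot intron length statistics
#'
#' @param structures list of `gene_structure` objects.
#' @param map optional `homology_map`; without it the intron ordinal is the
#'   slot.
#' @return data frame: slot, n, mean_bp, median_bp. Slots carried by no gene
#'   are absent from the table.
#' @export
size_stats <- function(structures, map = NULL) {
  sv <- microhomology_survey(structures, map)$per_intron
  if (nrow(sv) == 0)
    return(data.frame(slot = integer(0), n = integer(0),
                      mean_bp = numeric(0), median_bp = numeric(0)))
  lens <- unlist(lapply(structures, function(gs) {
    stats::setNames(gs$introns$length,
                    paste(gs$gene_id, gs$introns$index, sep = "#"))
  }))
  sv$len <- lens[paste(sv$gene, sv$intron_index, sep = "#")]
  out <- do.call(rbind, lapply(split(sv, sv$slot), function(d) {
    data.frame(slot = d$slot[1], n = nrow(d), mean_bp = mean(d$len),
               median_bp = stats::median(d$len))
  }))
  rownames(out) <- NULL
  out
}
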