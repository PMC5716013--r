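#' Project intron positions onto alignment columns
#'
#' Maps each intron's insertion point (the genomic position of the last
#' upstream-exon base) through the gap structure of a multiple alignment to
#' an alignment column, so intron positions become comparable across genes.
#'
#' @param alignment named character vector of aligned sequences (`-` gaps),
#'   as returned by [read_alignment()]; names must include every structure's
#'   `gene_id`.
#' @param structures list of `gene_structure` objects.
#' @param mode `"genomic"`: the alignment rows are genomic sequences and the
#'   insertion point is the exon end on the genomic sequence; `"cdna"`: the
#'   rows are spliced (exon-only) sequences and the insertion point is the
#'   number of spliced bases upstream of the intron.
#' @return data frame: `gene`, `intron_index`, `column`, `phase`.
#' @export
project_introns <- function(alignment, structures, mode = c("genomic", "cdna")) {
  mode <- match.arg(mode)
  rows <- lapply(structures, function(gs) {
    if (!gs$gene_id %in% names(alignment))
      stop("gene missing from alignment: ", gs$gene_id, call. = FALSE)
    aln <- alignment[[gs$gene_id]]
    bare <- ungap(aln)
    ref <- if (mode == "genomic") gs$genomic else gs$cdna
    if (bare != ref)
      stop(sprintf("alignment row for '%s' does not match its %s sequence",
                   gs$gene_id, mode), call. = FALSE)
    if (nrow(gs$introns) == 0) return(NULL)
    # column index of each ungapped position
    notgap <- strsplit(aln, "", fixed = TRUE)[[1]] != "-"
    col_of <- which(notgap)
    pos <- if (mode == "genomic") gs$exons$end[gs$introns$index]
           else cumsum(gs$exons$end - gs$exons$start + 1L)[gs$introns$index]
    data.frame(gene = gs$gene_id, intron_index = gs$introns$index,
               column = col_of[pos], phase = gs$introns$phase,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), intron_index = integer(0),
                      column = integer(0), phase = integer(0))
  rownames(out) <- NULL
  out
}

#' Cluster projected intron positions into ancestral slots
#'
#' Single-linkage clustering of intron projections: two projections are
#' linked when their columns differ by at most `column_tolerance` and (if
#' `require_same_phase`) their phases are equal. Clusters are ordered by
#' median column and numbered as ancestral slots 1..S. Nearby positions with
#' different phases therefore stay distinct slots, which is how
#' paralog-specific intron positions in the same gene region are kept apart.
#'
#' @param projections data frame from [project_introns()].
#' @param column_tolerance maximum column difference for linkage (default 0:
#'   positions must agree exactly).
#' @param require_same_phase require equal phase for linkage. Ignored (with
#'   a warning) when any phase is `NA`.
#' @return a `homology_map`: data frame `gene`, `intron_index`, `slot`, with
#'   attributes `n_slots` and `slot_columns` (median column per slot).
#' @export
cluster_slots <- function(projections, column_tolerance = 0,
                          require_same_phase = TRUE) {
  p <- projections
  n <- nrow(p)
  if (n == 0) {
    return(structure(data.frame(gene = character(0), intron_index = integer(0),
                                slot = integer(0)),
                     n_slots = 0L, slot_columns = numeric(0),
                     class = c("homology_map", "data.frame")))
  }
  use_phase <- require_same_phase
  if (use_phase && anyNA(p$phase)) {
    warning("phases missing; clustering on column only", call. = FALSE)
    use_phase <- FALSE
  }
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(p$column)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (p$column[j] - p$column[i] > column_tolerance) break
      if (use_phase && p$phase[i] != p$phase[j]) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  meds <- tapply(p$column, comp, stats::median)
  slot_of_comp <- rank(meds, ties.method = "first")
  slot <- as.integer(slot_of_comp[as.character(comp)])
  # a gene may carry at most one intron per slot
  dup <- duplicated(data.frame(p$gene, slot)) |
    duplicated(data.frame(p$gene, slot), fromLast = TRUE)
  if (any(dup)) {
    d <- p[dup, ]
    stop("ambiguous clustering: multiple introns of one gene fall in one slot: ",
         paste(sprintf("%s#%d", d$gene, d$intron_index), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(gene = p$gene, intron_index = p$intron_index, slot = slot,
                    stringsAsFactors = FALSE)
  # slot mapping within a gene must be strictly increasing (no crossing)
  for (g in unique(out$gene)) {
    sub <- out[out$gene == g, ]
    sub <- sub[order(sub$intron_index), ]
    if (is.unsorted(sub$slot, strictly = TRUE))
      stop("crossing slot mapping for gene ", g, call. = FALSE)
  }
  structure(out, n_slots = max(slot),
            slot_columns = as.numeric(sort(meds)),
            class = c("homology_map", "data.frame"))
}

#' Build a presence/absence matrix from a homology map
#'
#' A gene is `P` (present) at a slot iff one of its introns maps there, `A`
#' otherwise. `ND` states come only from explicit annotations (for example
#' PCR-undetermined introns); clustering never produces `ND`.
#'
#' @param map a `homology_map` from [cluster_slots()].
#' @param genes data frame with columns `gene`, `species`, `clade` (or a
#'   character vector of gene ids, in which case species/clade are copied
#'   from the gene id).
#' @param nd_annotations optional data frame with columns `gene`, `slot`
#'   marking states to overlay as `ND`.
#' @param n_slots number of slots; default: taken from the map.
#' @return a [presence_matrix] with slot columns `i1..iS`.
#' @export
build_matrix <- function(map, genes, nd_annotations = NULL, n_slots = NULL) {
  if (is.character(genes))
    genes <- data.frame(gene = genes, species = genes, clade = NA_character_,
                        stringsAsFactors = FALSE)
  if (is.null(n_slots)) n_slots <- attr(map, "n_slots")
  if (is.null(n_slots)) n_slots <- max(map$slot, 0L)
  states <- matrix("A", nrow = nrow(genes), ncol = n_slots,
                   dimnames = list(NULL, paste0("i", seq_len(n_slots))))
  gi <- match(map$gene, genes$gene)
  if (anyNA(gi)) stop("homology map names genes absent from `genes`", call. = FALSE)
  states[cbind(gi, map$slot)] <- "P"
  if (!is.null(nd_annotations) && nrow(nd_annotations) > 0) {
    ndi <- match(nd_annotations$gene, genes$gene)
    states[cbind(ndi, nd_annotations$slot)] <- "ND"
  }
  df <- cbind(genes[, c("gene", "species", "clade")],
              as.data.frame(states, stringsAsFactors = FALSE))
  presence_matrix(df)
}

#' Summaries of a presence/absence matrix
#'
#' Computes per-gene intron counts and, per clade, how many species are
#' "intact" (carry every slot). Species-level collapsing rules:
#' `gene_level` treats every gene row separately; `all_copies` counts a
#' species intact only if every gene copy is intact; `any_copy` counts it if
#' at least one copy is. For intact counting, `ND` is treated as present
#' (absence of evidence is not counted as loss).
#'
#' @param pm a [presence_matrix].
#' @param rule species collapsing rule.
#' @return list with `per_gene` (data frame gene, species, clade,
#'   n_present), `min_introns`, `max_introns`, and `intact_by_clade` (data
#'   frame clade, n_species, n_intact at species level, or gene counts under
#'   `gene_level`).
#' @export
summarize_matrix <- function(pm, rule = c("all_copies", "any_copy", "gene_level")) {
  rule <- match.arg(rule)
  if (nrow(pm) == 0) stop("empty presence matrix", call. = FALSE)
  sc <- slot_names(pm)
  st <- as.matrix(as.data.frame(pm)[, sc, drop = FALSE])
  n_present <- rowSums(st == "P")
  per_gene <- data.frame(gene = pm$gene, species = pm$species,
                         clade = pm$clade, n_present = n_present,
                         stringsAsFactors = FALSE)
  gene_intact <- rowSums(st == "P" | st == "ND") == length(sc)
  if (rule == "gene_level") {
    agg <- stats::aggregate(gene_intact, by = list(clade = pm$clade), FUN = sum)
    tot <- stats::aggregate(gene_intact, by = list(clade = pm$clade), FUN = length)
    intact <- data.frame(clade = agg$clade, n_species = tot$x, n_intact = agg$x)
  } else {
    f <- if (rule == "all_copies") all else any
    sp <- unique(pm[, c("species", "clade")])
    sp$intact <- vapply(seq_len(nrow(sp)), function(i) {
      f(gene_intact[pm$species == sp$species[i]])
    }, logical(1))
    agg <- stats::aggregate(sp$intact, by = list(clade = sp$clade), FUN = sum)
    tot <- stats::aggregate(sp$intact, by = list(clade = sp$clade), FUN = length)
    intact <- data.frame(clade = agg$clade, n_species = tot$x, n_intact = agg$x)
  }
  list(per_gene = per_gene,
       min_introns = min(n_present),
       max_introns = max(n_present),
       intact_by_clade = intact,
       rule = rule)
}
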