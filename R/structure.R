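#' Infer exon/intron structure from a genomic/cDNA sequence pair
#'
#' Aligns a cDNA to its own genomic sequence with a splice-aware dynamic
#' program (exon match +1, mismatch -2, intron open -4, intron extension 0;
#' exons align without indels). The genomic sequence must begin and end with
#' exonic sequence. When `require_gt_ag` is set, introns may only be placed
#' at `GT..AG` boundaries; equally scoring (slidable) placements resolve to
#' the leftmost donor.
#'
#' @param genomic genomic DNA string.
#' @param cdna spliced (cDNA) DNA string; must not be longer than `genomic`.
#' @param min_exon minimum internal exon length (bp); shorter inferred exons
#'   raise an error, preventing spurious micro-exons.
#' @param min_intron minimum intron length (bp).
#' @param require_gt_ag restrict intron placement to GT..AG boundaries.
#' @param min_identity minimum fraction of cDNA bases matching their aligned
#'   genomic base for the inference to be accepted.
#' @param gene_id,species identifiers carried on the result.
#' @param cds_start 1-based position of the first coding base in the cDNA
#'   (needed for intron phases; may be set later, see [compute_phase()]).
#' @return a `gene_structure`: list with `gene_id`, `species`, `genomic`,
#'   `cdna`, `exons` (data frame of 1-based closed intervals on the genomic
#'   sequence), `introns` (data frame: index, start, end, length, phase,
#'   donor, acceptor), `cds_start`, `identity`.
#' @export
infer_introns <- function(genomic, cdna, min_exon = 15, min_intron = 20,
                          require_gt_ag = TRUE, min_identity = 0.99,
                          gene_id = "gene", species = NA_character_,
                          cds_start = NULL) {
  genomic <- normalize_dna(genomic)
  cdna <- normalize_dna(cdna)
  check_dna(c(genomic = genomic, cdna = cdna))
  if (nchar(cdna) < 1 || nchar(genomic) < nchar(cdna))
    stop("cdna must be non-empty and no longer than genomic", call. = FALSE)
  res <- cpp_spliced_align(genomic, cdna, as.integer(min_intron),
                           isTRUE(require_gt_ag))
  if (!isTRUE(res$ok))
    stop(sprintf(paste0("spliced-alignment inference failed for '%s': no ",
                        "alignment spans the cDNA under min_intron=%d%s"),
                 gene_id, min_intron,
                 if (require_gt_ag) " with GT..AG boundaries" else ""),
         call. = FALSE)
  identity <- res$matches / nchar(cdna)
  if (identity < min_identity)
    stop(sprintf(paste0("spliced-alignment inference failed for '%s': best ",
                        "alignment identity %.4f below %.4f (score %d)"),
                 gene_id, identity, min_identity, res$score), call. = FALSE)
  exons <- data.frame(start = res$exon_starts, end = res$exon_ends)
  internal <- exons[-c(1, nrow(exons)), , drop = FALSE]
  if (nrow(internal) > 0 && any(internal$end - internal$start + 1 < min_exon))
    stop(sprintf("inferred internal exon shorter than min_exon=%d in '%s'",
                 min_exon, gene_id), call. = FALSE)
  gs <- structure(list(gene_id = gene_id, species = species,
                       genomic = genomic, cdna = cdna, exons = exons,
                       introns = NULL, cds_start = cds_start,
                       identity = identity),
                  class = "gene_structure")
  gs$introns <- derive_introns(gs)
  gs
}

#' Build a gene structure from known exon coordinates
#'
#' Used when exon intervals are already known (e.g. from a simulation
#' ground truth or an annotation) rather than inferred.
#'
#' @inheritParams infer_introns
#' @param exons data frame with columns `start`, `end` (1-based, closed),
#'   strictly increasing and non-overlapping.
#' @return a `gene_structure`.
#' @export
gene_structure <- function(genomic, exons, gene_id = "gene",
                           species = NA_character_, cds_start = NULL) {
  genomic <- normalize_dna(genomic)
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end")]
  if (any(exons$end < exons$start) ||
      any(utils::head(exons$end, -1) >= utils::tail(exons$start, -1)))
    stop("exons must be non-overlapping and strictly increasing", call. = FALSE)
  if (exons$end[nrow(exons)] > nchar(genomic))
    stop("exon interval outside genomic sequence", call. = FALSE)
  cdna <- paste(substring(genomic, exons$start, exons$end), collapse = "")
  gs <- structure(list(gene_id = gene_id, species = species,
                       genomic = genomic, cdna = cdna, exons = exons,
                       introns = NULL, cds_start = cds_start, identity = 1),
                  class = "gene_structure")
  gs$introns <- derive_introns(gs)
  gs
}

# Introns are exactly the gaps between consecutive exons.
derive_introns <- function(gs) {
  ex <- gs$exons
  n <- nrow(ex)
  if (n < 2) {
    return(data.frame(index = integer(0), start = integer(0), end = integer(0),
                      length = integer(0), phase = integer(0),
                      donor = character(0), acceptor = character(0),
                      stringsAsFactors = FALSE))
  }
  start <- ex$end[-n] + 1L
  end <- ex$start[-1] - 1L
  if (any(end - start + 1L < 2L))
    stop("gap between consecutive exons is shorter than 2 bases; ",
         "adjacent exons must be merged", call. = FALSE)
  data.frame(
    index = seq_len(n - 1L),
    start = start, end = end, length = end - start + 1L,
    phase = if (is.null(gs$cds_start)) NA_integer_ else
      vapply(seq_len(n - 1L), function(i) phase_of(gs, i), integer(1)),
    donor = substring(gs$genomic, start, start + 1L),
    acceptor = substring(gs$genomic, end - 1L, end),
    stringsAsFactors = FALSE
  )
}

phase_of <- function(gs, intron_index) {
  upstream <- sum(gs$exons$end[seq_len(intron_index)] -
                    gs$exons$start[seq_len(intron_index)] + 1L)
  coding <- upstream - (gs$cds_start - 1L)
  as.integer(max(0L, coding) %% 3L)
}

#' @export
print.gene_structure <- function(x, ...) {
  cat(sprintf("gene_structure '%s': %d bp genomic, %d exon(s), %d intron(s)\n",
              x$gene_id, nchar(x$genomic), nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#' Intron phase
#'
#' Phase is the number of coding bases upstream of the intron, counted from
#' the start codon, modulo 3 (0 = between codons, 1 = after the first codon
#' base, 2 = after the second).
#'
#' @param structure a `gene_structure`.
#' @param intron_index 1-based intron ordinal.
#' @param cds_start optional override for the structure's CDS start (1-based
#'   position in the cDNA). The CDS start is never guessed: if it is unset
#'   both here and on the structure, an error instructs the caller to set it.
#' @return integer phase, 0, 1 or 2.
#' @export
compute_phase <- function(structure, intron_index, cds_start = NULL) {
  stopifnot(inherits(structure, "gene_structure"))
  if (intron_index < 1 || intron_index > nrow(structure$introns))
    stop("intron_index out of range", call. = FALSE)
  if (!is.null(cds_start)) structure$cds_start <- cds_start
  if (is.null(structure$cds_start))
    stop("CDS start offset unset: pass cds_start (1-based position of the ",
         "start codon in the cDNA); it is not guessed", call. = FALSE)
  phase_of(structure, intron_index)
}

#' Splice-junction context of an intron
#'
#' Returns the verbatim upstream-exon suffix, intron sequence and
#' downstream-exon prefix around one intron. Flanks shorter than `k` are
#' returned truncated with `truncated = TRUE`, with a warning.
#'
#' @param structure a `gene_structure`.
#' @param intron_index 1-based intron ordinal.
#' @param k flank length requested on each side.
#' @return list with `upstream`, `intron`, `downstream`, `truncated`.
#' @export
boundary_context <- function(structure, intron_index, k) {
  stopifnot(inherits(structure, "gene_structure"), k >= 1)
  intr <- structure$introns[intron_index, ]
  if (nrow(intr) != 1 || is.na(intr$start))
    stop("intron_index out of range", call. = FALSE)
  up_ex <- structure$exons[intron_index, ]
  dn_ex <- structure$exons[intron_index + 1L, ]
  up_len <- up_ex$end - up_ex$start + 1L
  dn_len <- dn_ex$end - dn_ex$start + 1L
  truncated <- up_len < k || dn_len < k
  if (truncated)
    warning("flank shorter than k; returning truncated flank", call. = FALSE)
  ku <- min(k, up_len); kd <- min(k, dn_len)
  list(
    upstream = substring(structure$genomic, up_ex$end - ku + 1L, up_ex$end),
    intron = substring(structure$genomic, intr$start, intr$end),
    downstream = substring(structure$genomic, dn_ex$start, dn_ex$start + kd - 1L),
    truncated = truncated
  )
}

#' Spliced sequence implied by a structure's exons
#' @param structure a `gene_structure`.
#' @return character string: concatenation of the exon substrings.
#' @export
spliced_sequence <- function(structure) {
  paste(substring(structure$genomic, structure$exons$start,
                  structure$exons$end), collapse = "")
}

#' Per-intron table for a list of structures
#' @param structures list of `gene_structure` objects.
#' @return data frame: gene, index, start, end, length, phase, donor, acceptor.
#' @export
intron_table <- function(structures) {
  do.call(rbind, lapply(structures, function(gs) {
    if (nrow(gs$introns) == 0) return(NULL)
    cbind(gene = gs$gene_id, gs$introns, stringsAsFactors = FALSE)
  }))
}

#' Write exon features as GFF3
#'
#' Emits one `gene` and per-exon `exon` features (1-based inclusive
#' coordinates, forward strand) for each structure.
#'
#' @param structures list of `gene_structure` objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_structures_gff3 <- function(structures, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gs in structures) {
    writeLines(sprintf("%s\tintronevo\tgene\t1\t%d\t.\t+\t.\tID=%s",
                       gs$gene_id, nchar(gs$genomic), gs$gene_id), con)
    for (i in seq_len(nrow(gs$exons))) {
      writeLines(sprintf("%s\tintronevo\texon\t%d\t%d\t.\t+\t.\tID=%s.exon%d;Parent=%s",
                         gs$gene_id, gs$exons$start[i], gs$exons$end[i],
                         gs$gene_id, i, gs$gene_id), con)
    }
  }
  invisible(path)
}
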