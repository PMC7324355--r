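#' Classify a patient-only consensus rearrangement
#'
#' Rule order: (1) membership in a linked multi-group component or any
#' inter-chromosomal junction makes the event a `chromothripsis_member`;
#' (2) duplication-loop geometry is a `tandem_multiplication` when the loop
#' span exceeds `unit_threshold` and a `repeat_expansion` otherwise (loops
#' smaller than the colinearity tolerance are not detectable as junctions at
#' all, which bounds the threshold from below); (3) an
#' unaligned insert whose sequence matches a library element at
#' `id_threshold` identity over at least half of its length is a
#' `mobile_element_insertion:<element>`; (4) everything else is `other`.
#' The order is total: every consensus receives exactly one category.
#'
#' @param cr A `consensus_rearrangement`.
#' @param library An [element_library()] (or `NULL` to skip rule 3).
#' @param id_threshold Minimum local-alignment identity for element matching.
#' @param unit_threshold Loop span (bases) separating tandem multiplications
#'   from repeat expansions.
#' @param linked Is this event part of a linked multi-group component?
#' @return Category string.
#' @export
classify_event <- function(cr, library = NULL, id_threshold = 0.8,
                           unit_threshold = 5000, linked = FALSE) {
  tf <- cr$junctions
  if (linked || any(tf$chrom_l != tf$chrom_r)) return("chromothripsis_member")
  delta <- junction_delta(tf)
  back <- which(!is.na(delta) & delta < 0)
  if (length(back)) {
    span <- max(abs(delta[back]))
    return(if (span > unit_threshold) "tandem_multiplication"
           else "repeat_expansion")
  }
  if (length(cr$gap_seqs) && !is.null(library)) {
    for (gs in cr$gap_seqs) {
      el <- match_element(gs, library, id_threshold)
      if (!is.na(el)) return(paste0("mobile_element_insertion:", el))
    }
  }
  "other"
}

#' Match an inserted sequence against an element library
#'
#' Local alignment (Smith-Waterman as implemented in Biostrings) of the
#' insert against every library consensus; a hit requires identity of at
#' least `id_threshold` over at least `min_cover` of the insert length.
#'
#' @param seq Character DNA string (the unaligned insert).
#' @param library An [element_library()].
#' @param id_threshold Identity threshold in \[0, 1\].
#' @param min_cover Minimum aligned fraction of the insert.
#' @return Best matching element name, or `NA_character_`.
#' @export
match_element <- function(seq, library, id_threshold = 0.8, min_cover = 0.5) {
  best <- NA_character_; best_pid <- 0
  for (el in names(library)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq), Biostrings::DNAString(library[[el]]),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2)
    cover <- Biostrings::nchar(Biostrings::alignedPattern(aln)) / nchar(seq)
    pid <- Biostrings::pid(aln, type = "PID2") / 100
    if (cover >= min_cover && pid >= id_threshold && pid > best_pid) {
      best <- el; best_pid <- pid
    }
  }
  best
}

#' Gene impact of a reconstruction
#'
#' A gene is `deleted` when its interval lies fully inside a deletion call,
#' `disrupted` when any breakend falls strictly inside the gene, and
#' `intact` otherwise. Enlarging a deletion can never move a gene from
#' deleted to intact.
#'
#' @param deletions Deletion data.frame (`chrom`, `start`, `end`).
#' @param junctions Breakend table (`chrom`, `pos`), e.g. from
#'   [all_breakends()], or a junction data.frame with `chrom_l`/`chrom_r`
#'   columns.
#' @param genes BED-style data.frame (`chrom`, `start`, `end`, `name`).
#' @return data.frame `gene`, `status`, `evidence`.
#' @export
gene_impact <- function(deletions, junctions, genes) {
  if (!is.null(junctions$chrom_l))
    junctions <- data.frame(
      chrom = c(junctions$chrom_l, junctions$chrom_r),
      pos = c(junctions$pos_l, junctions$pos_r), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    del <- deletions[deletions$chrom == g$chrom &
                     deletions$start <= g$start & deletions$end >= g$end, ]
    if (nrow(del))
      return(data.frame(gene = g$name, status = "deleted",
                        evidence = sprintf("deletion %s:%d-%d", del$chrom[1],
                                           del$start[1], del$end[1]),
                        stringsAsFactors = FALSE))
    hit <- junctions[junctions$chrom == g$chrom & junctions$pos > g$start &
                     junctions$pos < g$end, ]
    if (nrow(hit))
      return(data.frame(gene = g$name, status = "disrupted",
                        evidence = sprintf("breakend %s:%d", hit$chrom[1],
                                           round(hit$pos[1])),
                        stringsAsFactors = FALSE))
    data.frame(gene = g$name, status = "intact", evidence = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per row, dCt = Ct_gene - Ct_reference. Per patient replicate,
#' ddCt = dCt_patient - mean(dCt_controls) and fold = 2^(-ddCt). The
#' replicate SD is the SD of the per-replicate folds.
#'
#' @param ct_table data.frame with columns `sample`, `role` (`patient` or
#'   `control`), `gene`, `reference_gene`, `ct_gene`, `ct_reference` and
#'   optionally `replicate`.
#' @return data.frame per gene: `fold_change` (mean over patient
#'   replicates), `fold_sd`, `ddct_mean`, `n_replicates`.
#' @export
delta_delta_ct <- function(ct_table) {
  need <- c("sample", "role", "gene", "reference_gene", "ct_gene",
            "ct_reference")
  if (!all(need %in% names(ct_table)))
    stop("ct_table must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(ct_table$ct_reference) | is.na(ct_table$ct_gene))
  if (length(bad))
    stop("missing Ct value in row ", bad[1], " (sample ",
         ct_table$sample[bad[1]], ", gene ", ct_table$gene[bad[1]], ")")
  if (any(ct_table$ct_gene <= 0 | ct_table$ct_reference <= 0))
    stop("Ct values must be positive")
  ct_table$dct <- ct_table$ct_gene - ct_table$ct_reference
  out <- lapply(unique(ct_table$gene), function(g) {
    t <- ct_table[ct_table$gene == g, ]
    ctl <- t$dct[t$role == "control"]
    pat <- t$dct[t$role == "patient"]
    if (!length(ctl)) stop("no control samples for gene ", g)
    if (!length(pat)) stop("no patient samples for gene ", g)
    ddct <- pat - mean(ctl)
    fold <- 2^(-ddct)
    data.frame(gene = g, fold_change = mean(fold),
               fold_sd = if (length(fold) > 1) stats::sd(fold) else 0,
               ddct_mean = mean(ddct), n_replicates = length(pat),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
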