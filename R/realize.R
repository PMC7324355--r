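#' Realize derivative chromosomes from a plan
#'
#' Builds, for each derivative layout, the coordinate map from derivative
#' coordinates to oriented reference intervals, and (when the genome carries
#' sequences) the derivative sequence as the concatenation of fragment
#' subsequences, reverse-complemented for reverse-oriented fragments.
#'
#' @param plan A `rearrangement_plan` (fragment overlap and layout validity
#'   are enforced at plan construction).
#' @return Object of class `realized_genome`: list with `plan` and
#'   `derivatives`, each derivative a list with `name`, `map` (data.frame:
#'   `frag_id`, `chrom`, `start`, `end`, `strand`, `der_start`, `der_end`),
#'   `length` and `sequence` (`DNAString` or `NULL`).
#' @export
realize_derivatives <- function(plan) {
  stopifnot(inherits(plan, "rearrangement_plan"))
  fr <- plan$fragments
  genome <- plan$genome
  ders <- lapply(names(plan$derivatives), function(dn) {
    ids <- plan$derivatives[[dn]]
    f <- fr[as.character(ids), ]
    sizes <- f$end - f$start
    der_end <- cumsum(sizes)
    map <- data.frame(frag_id = f$id, chrom = f$chrom, start = f$start,
                      end = f$end, strand = f$strand,
                      der_start = der_end - sizes, der_end = der_end,
                      stringsAsFactors = FALSE)
    seq <- NULL
    if (!is.null(genome$sequences)) {
      pieces <- lapply(seq_len(nrow(map)), function(i) {
        s <- Biostrings::subseq(genome$sequences[[map$chrom[i]]],
                                start = map$start[i] + 1, end = map$end[i])
        if (map$strand[i] == "-") Biostrings::reverseComplement(s) else s
      })
      seq <- if (length(pieces) == 1) pieces[[1]]
             else do.call(Biostrings::xscat, pieces)
    }
    list(name = dn, map = map, length = sum(sizes), sequence = seq)
  })
  names(ders) <- names(plan$derivatives)
  structure(list(plan = plan, derivatives = ders), class = "realized_genome")
}

#' @export
print.realized_genome <- function(x, ...) {
  for (d in x$derivatives)
    cat(d$name, ": ", nrow(d$map), " fragments, ",
        format(d$length, big.mark = ","), " bases\n", sep = "")
  invisible(x)
}

#' Write a plan's truth tables and sequences to disk
#'
#' Serializes the ground truth of a simulation: fragments TSV (id, chrom,
#' start, end, strand, derivative, rank), junctions TSV (breakend notation),
#' deletions as 6-column BED, the whole plan as JSON, and reference plus
#' derivative FASTA when sequences are available.
#'
#' @param rg A `realized_genome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_truth <- function(rg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plan <- rg$plan
  files <- character()
  frag <- do.call(rbind, lapply(names(plan$derivatives), function(dn) {
    ids <- plan$derivatives[[dn]]
    f <- plan$fragments[as.character(ids), ]
    f$derivative <- dn
    f$rank <- seq_along(ids)
    f
  }))
  p <- file.path(dir, "fragments.tsv")
  utils::write.table(frag, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  p <- file.path(dir, "junctions.tsv")
  utils::write.table(plan$truth_junctions, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, p)
  del <- plan$truth_deletions
  bed <- data.frame(chrom = del$chrom, start = del$start, end = del$end,
                    name = sprintf("deletion_%d", seq_len(nrow(del))),
                    score = 0, strand = ".")
  p <- file.path(dir, "deletions.bed")
  utils::write.table(bed, p, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  files <- c(files, p)
  p <- file.path(dir, "plan.json")
  jsonlite::write_json(list(
    chrom_lengths = as.list(plan$genome$lengths),
    fragments = plan$fragments,
    derivatives = plan$derivatives,
    truth_junctions = plan$truth_junctions,
    truth_deletions = plan$truth_deletions), p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)
  if (!is.null(plan$genome$sequences)) {
    p <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(plan$genome$sequences, p)
    files <- c(files, p)
    ders <- Biostrings::DNAStringSet(lapply(rg$derivatives, `[[`, "sequence"))
    names(ders) <- names(rg$derivatives)
    p <- file.path(dir, "derivatives.fa")
    Biostrings::writeXStringSet(ders, p)
    files <- c(files, p)
  }
  invisible(files)
}
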