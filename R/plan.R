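#' @title Rearrangement plans
#' @description A rearrangement plan is the ground truth of a simulated
#' rearranged genome: reference fragments (0-based half-open coordinates, with
#' an orientation), derivative layouts (ordered fragment ids), and the implied
#' truth tables of junctions and deletions.
#' @name rearrangement_plan
NULL

new_fragments <- function(id, chrom, start, end, strand) {
  data.frame(id = as.integer(id), chrom = as.character(chrom),
             start = as.numeric(start), end = as.numeric(end),
             strand = as.character(strand), stringsAsFactors = FALSE)
}

# Breakend contributed by a fragment when it sits LEFT of a junction in the
# derivative traversal: a forward fragment exits at its reference end ("head":
# retained sequence lies toward smaller coordinates), a reverse fragment exits
# at its reference start ("tail": retained sequence toward larger coordinates).
frag_left_breakend <- function(frag) {
  if (frag$strand == "+") c(chrom = frag$chrom, pos = frag$end, side = "head")
  else c(chrom = frag$chrom, pos = frag$start, side = "tail")
}
# Breakend when the fragment sits RIGHT of a junction (entry point).
frag_right_breakend <- function(frag) {
  if (frag$strand == "+") c(chrom = frag$chrom, pos = frag$start, side = "tail")
  else c(chrom = frag$chrom, pos = frag$end, side = "head")
}

#' Assemble and validate a rearrangement plan
#'
#' @param genome A `toy_genome`.
#' @param fragments data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (`+` forward / `-` reverse); 0-based half-open reference
#'   coordinates. Fragments may not overlap in the reference.
#' @param derivatives Named list: derivative name -> integer vector of
#'   fragment ids in derivative order. Every fragment id must appear in
#'   exactly one derivative; the first and last fragment of each derivative
#'   must extend to a terminus of its source chromosome.
#' @return Object of class `rearrangement_plan` with truth tables
#'   `truth_junctions` (one row per adjacency, in derivative traversal frame)
#'   and `truth_deletions` (maximal uncovered reference intervals interior to
#'   each chromosome's covered span).
#' @export
rearrangement_plan <- function(genome, fragments, derivatives) {
  stopifnot(inherits(genome, "toy_genome"))
  fr <- fragments
  if (anyDuplicated(fr$id)) stop("fragment ids must be unique")
  if (!all(fr$strand %in% c("+", "-"))) stop("fragment strand must be + or -")
  if (!all(fr$chrom %in% names(genome$lengths)))
    stop("fragment chromosome not in genome")
  len <- genome$lengths[fr$chrom]
  if (any(fr$start < 0 | fr$start >= fr$end | fr$end > len))
    stop("fragment coordinates out of range")
  # no reference overlap between fragments of the same chromosome
  for (ch in unique(fr$chrom)) {
    f <- fr[fr$chrom == ch, ]
    f <- f[order(f$start), ]
    if (nrow(f) > 1 && any(f$start[-1] < f$end[-nrow(f)]))
      stop("fragments overlap in the reference on ", ch)
  }
  used <- unlist(derivatives)
  if (anyDuplicated(used)) stop("a fragment id appears in more than one derivative")
  if (!setequal(used, fr$id)) stop("every fragment must appear in exactly one derivative")
  if (is.null(names(derivatives))) stop("derivatives must be named")
  rownames(fr) <- as.character(fr$id)
  for (dn in names(derivatives)) {
    ids <- derivatives[[dn]]
    first <- fr[as.character(ids[1]), ]
    last <- fr[as.character(ids[length(ids)]), ]
    ok_first <- (first$strand == "+" && first$start == 0) ||
      (first$strand == "-" && first$end == genome$lengths[[first$chrom]])
    ok_last <- (last$strand == "+" && last$end == genome$lengths[[last$chrom]]) ||
      (last$strand == "-" && last$start == 0)
    if (!ok_first || !ok_last)
      stop("terminal fragments of ", dn, " must extend to a chromosome terminus")
  }
  plan <- structure(list(genome = genome, fragments = fr,
                         derivatives = derivatives), class = "rearrangement_plan")
  plan$truth_junctions <- plan_truth_junctions(plan)
  plan$truth_deletions <- plan_truth_deletions(plan)
  # adjacent fragments in a derivative must not be reference-colinear,
  # otherwise the adjacency is invisible to junction extraction
  tj <- plan$truth_junctions
  col <- tj$chrom_l == tj$chrom_r &
    ((tj$side_l == "head" & tj$side_r == "tail" & abs(tj$pos_r - tj$pos_l) <= 0) |
     (tj$side_l == "tail" & tj$side_r == "head" & abs(tj$pos_l - tj$pos_r) <= 0))
  if (any(col)) stop("derivative-adjacent fragments are reference-colinear")
  plan
}

plan_truth_junctions <- function(plan) {
  fr <- plan$fragments
  out <- list()
  for (dn in names(plan$derivatives)) {
    ids <- plan$derivatives[[dn]]
    if (length(ids) < 2) next
    for (k in seq_len(length(ids) - 1)) {
      a <- fr[as.character(ids[k]), ]
      b <- fr[as.character(ids[k + 1]), ]
      bl <- frag_left_breakend(a)
      br <- frag_right_breakend(b)
      out[[length(out) + 1]] <- data.frame(
        derivative = dn, rank = k,
        chrom_l = bl[["chrom"]], pos_l = as.numeric(bl[["pos"]]), side_l = bl[["side"]],
        chrom_r = br[["chrom"]], pos_r = as.numeric(br[["pos"]]), side_r = br[["side"]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(derivative = character(), rank = integer(),
                      chrom_l = character(), pos_l = numeric(), side_l = character(),
                      chrom_r = character(), pos_r = numeric(), side_r = character()))
  do.call(rbind, out)
}

plan_truth_deletions <- function(plan) {
  fr <- plan$fragments
  out <- list()
  for (ch in unique(fr$chrom)) {
    f <- fr[fr$chrom == ch, ]
    ir <- IRanges::reduce(IRanges::IRanges(start = f$start + 1, end = f$end))
    if (length(ir) > 1) {
      gaps <- IRanges::gaps(ir, start = min(IRanges::start(ir)),
                            end = max(IRanges::end(ir)))
      if (length(gaps))
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = IRanges::start(gaps) - 1, end = IRanges::end(gaps),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  d <- do.call(rbind, out)
  d[order(d$chrom, d$start), , drop = FALSE]
}

#' @export
print.rearrangement_plan <- function(x, ...) {
  cat("rearrangement_plan:", nrow(x$fragments), "fragments,",
      length(x$derivatives), "derivatives,",
      nrow(x$truth_junctions), "junctions,",
      nrow(x$truth_deletions), "deletions\n")
  invisible(x)
}

#' Coverage conservation check for a plan
#'
#' For each chromosome, the covered span from the first to the last fragment
#' equals the sum of fragment lengths plus the sum of deletion lengths.
#'
#' @param plan A `rearrangement_plan`.
#' @return `TRUE` invisibly; stops if conservation is violated.
#' @export
check_conservation <- function(plan) {
  fr <- plan$fragments
  for (ch in unique(fr$chrom)) {
    f <- fr[fr$chrom == ch, ]
    d <- plan$truth_deletions[plan$truth_deletions$chrom == ch, ]
    span <- max(f$end) - min(f$start)
    if (span != sum(f$end - f$start) + sum(d$end - d$start))
      stop("conservation violated on ", ch)
  }
  invisible(TRUE)
}

#' Generate a random two-chromosome rearrangement plan
#'
#' Builds a random reciprocal-translocation-plus-chromothripsis plan on two
#' toy chromosomes: each chromosome is tiled into fragments (optionally
#' separated by deletion gaps) and the fragments are shuffled into two
#' derivative layouts, each anchored at one terminus of each chromosome.
#' Fragment sizes are kept large relative to simulated read lengths so that
#' read grouping is unambiguous.
#'
#' @param seed Integer seed.
#' @param n_frags_per_derivative Integer range (length 2) for the number of
#'   fragments per derivative.
#' @param frag_size Range of fragment lengths in bases.
#' @param gap_size Range of deletion-gap lengths in bases.
#' @param gap_prob Probability that two reference-adjacent fragments are
#'   separated by a deletion gap (otherwise they touch).
#' @param with_sequence Passed to [build_toy_genome()].
#' @return A `rearrangement_plan`.
#' @export
random_plan <- function(seed, n_frags_per_derivative = c(2, 10),
                        frag_size = c(120000, 260000),
                        gap_size = c(30000, 200000),
                        gap_prob = 0.5, with_sequence = FALSE) {
  rng <- local_rng(seed)
  repeat {
    n1 <- n_frags_per_derivative[1] +
      rng$sample_int(n_frags_per_derivative[2] - n_frags_per_derivative[1] + 1, 1) - 1
    n2 <- n_frags_per_derivative[1] +
      rng$sample_int(n_frags_per_derivative[2] - n_frags_per_derivative[1] + 1, 1) - 1
    n <- n1 + n2
    if (n >= 4) break
  }
  # split the n fragments over the two chromosomes: each chromosome needs >= 2
  # (one terminal anchor for each derivative)
  nA <- 2 + rng$sample_int(n - 3, 1) - 1
  nA <- max(2, min(n - 2, nA))
  nB <- n - nA
  tile <- function(k, rng) {
    sizes <- round(rng$runif(k, frag_size[1], frag_size[2]))
    gaps <- ifelse(rng$runif(k - 1) < gap_prob,
                   round(rng$runif(k - 1, gap_size[1], gap_size[2])), 0)
    start <- cumsum(c(0, sizes[-k] + gaps))
    list(start = start, end = start + sizes, len = sum(sizes) + sum(gaps))
  }
  tA <- tile(nA, rng)
  tB <- tile(nB, rng)
  genome <- build_toy_genome(c(cA = tA$len, cB = tB$len),
                             seed = seed, with_sequence = with_sequence)
  fr <- rbind(
    new_fragments(seq_len(nA), "cA", tA$start, tA$end, "+"),
    new_fragments(nA + seq_len(nB), "cB", tB$start, tB$end, "+"))
  # anchors: der1 = cA-leftmost ... cB-rightmost; der2 = cB-leftmost ... cA-rightmost
  idA <- seq_len(nA); idB <- nA + seq_len(nB)
  a1 <- idA[1]; a2 <- idA[nA]; b1 <- idB[1]; b2 <- idB[nB]
  interior <- setdiff(c(idA, idB), c(a1, a2, b1, b2))
  interior <- interior[rng$sample_int(length(interior), length(interior))]
  k1 <- n1 - 2  # interior slots of der1
  d1 <- c(a1, if (k1 > 0) interior[seq_len(k1)], b2)
  rest <- if (k1 > 0) interior[-seq_len(k1)] else interior
  d2 <- c(b1, rest, a2)
  # random orientations for interior fragments; a draw that leaves a
  # reference-colinear derivative adjacency (invisible to junction
  # extraction) is redrawn
  base_strand <- fr$strand
  for (attempt in 1:50) {
    fr$strand <- base_strand
    flip <- interior[rng$runif(length(interior)) < 0.5]
    fr$strand[fr$id %in% flip] <- "-"
    plan <- tryCatch(rearrangement_plan(genome, fr, list(der1 = d1, der2 = d2)),
                     error = function(e) e)
    if (!inherits(plan, "error")) return(plan)
    if (!grepl("colinear", conditionMessage(plan))) stop(plan)
  }
  stop("could not draw a non-colinear orientation vector")
}
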