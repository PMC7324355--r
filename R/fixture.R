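#' Canonical chromothripsis fixture: t(8;18)-style two-derivative layout
#'
#' Builds the package's canonical rearrangement plan on a two-chromosome toy
#' genome: 19 fragments, 15 from the chr8 analog (ids 1-5, 8-13, 16-19) and 4
#' from the chr18 analog (ids 6, 7, 14, 15). Derivative A carries fragments
#' 1-14 in order, derivative B fragments 15-19, so the two derivatives have 14
#' and 5 fragments. The reference intervals are chosen so that the uncovered
#' interior gaps are exactly 456, 1957, 520 and 3529 kb on the chr8 analog and
#' 1528 kb on the chr18 analog. Five fragments are reverse-oriented, and three
#' fragments are tiny (6, 9 and 8 kb) so that single long reads span their
#' flanking junctions, collapsing the 17 adjacencies into 14 read groups.
#'
#' True breakpoint coordinates of the motivating case are not published; the
#' fixture's coordinates are synthetic, and only deletion sizes, fragment
#' counts and chromosome-of-origin assignments are meaningful.
#'
#' @param genome A `toy_genome` with two chromosomes of at least 12 Mb and
#'   6 Mb (in that order); see [fixture_genome()].
#' @return A `rearrangement_plan`.
#' @export
chromothripsis_fixture <- function(genome) {
  stopifnot(inherits(genome, "toy_genome"))
  if (length(genome$lengths) < 2)
    stop("fixture genome needs two chromosomes")
  c8 <- names(genome$lengths)[1]
  c18 <- names(genome$lengths)[2]
  if (genome$lengths[[c8]] < 12e6 || genome$lengths[[c18]] < 6e6)
    stop("fixture genome too small to host the planted deletions")
  kb <- 1000
  # chr8-analog reference order: 1,11,4,9,17,12,2 |456| 8,18,5 |1957| 13,3 |520| 10,16 |3529| 19
  f8 <- list(
    list(1L,     0,   400), list(11L,  400,   780), list(4L,   780,  1230),
    list(9L,  1230,  1236), list(17L, 1236,  1244), list(12L, 1244,  1664),
    list(2L,  1664,  2014),                        # gap 456 kb
    list(8L,  2470,  3020), list(18L, 3020,  3500), list(5L,  3500,  3800),
                                                   # gap 1957 kb
    list(13L, 5757,  6272), list(3L,  6272,  6772), # gap 520 kb
    list(10L, 7292,  7301), list(16L, 7301,  7901), # gap 3529 kb
    list(19L, 11430, 12000))
  # chr18-analog reference order: 15, 6 |1528| 7, 14
  f18 <- list(
    list(15L, 0, 1200), list(6L, 1200, 2100),      # gap 1528 kb
    list(7L, 3628, 4628), list(14L, 4628, 6000))
  rows <- function(x, chrom) do.call(rbind, lapply(x, function(f)
    new_fragments(f[[1]], chrom, f[[2]] * kb, f[[3]] * kb, "+")))
  fr <- rbind(rows(f8, c8), rows(f18, c18))
  reverse_ids <- c(3L, 7L, 10L, 12L, 17L)  # fixed orientation vector, >= 4 inversions
  fr$strand[fr$id %in% reverse_ids] <- "-"
  rearrangement_plan(genome, fr,
                     list(derA = 1:14, derB = 15:19))
}

#' Toy genome sized for the canonical fixture
#'
#' @param seed Integer seed.
#' @param with_sequence Generate bases (`TRUE`) or lengths only.
#' @return A `toy_genome` with `chr8t` (12 Mb) and `chr18t` (6 Mb).
#' @export
fixture_genome <- function(seed = 1L, with_sequence = FALSE) {
  build_toy_genome(c(chr8t = 12e6, chr18t = 6e6), seed = seed,
                   with_sequence = with_sequence)
}
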