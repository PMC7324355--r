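#' Chain aligned segments per read
#'
#' Drops segments shorter than `min_seg_len` on the read, resolves read
#' overlaps larger than `max_overlap` by keeping the segment with the higher
#' identity x length score, and orders each read's surviving segments by
#' forward-read start. Secondary/supplementary status is not distinguished:
#' all records of a read compete.
#'
#' @param segments Segment data.frame (see [parse_paf()]).
#' @param min_seg_len Minimum segment length on the read, bases.
#' @param max_overlap Maximum tolerated read overlap between kept segments.
#' @return Filtered, ordered segment data.frame.
#' @export
chain_segments <- function(segments, min_seg_len = 200, max_overlap = 50) {
  s <- segments[segments$read_end - segments$read_start >= min_seg_len, ,
                drop = FALSE]
  if (!nrow(s)) return(empty_chains())
  s <- s[order(s$read_id, s$read_start), , drop = FALSE]
  n <- nrow(s)
  has_ovl <- c(FALSE, s$read_id[-1] == s$read_id[-n] &
                 s$read_start[-1] < s$read_end[-n] - max_overlap)
  if (any(has_ovl)) {
    keep <- logical(n)
    for (rid in unique(s$read_id[has_ovl])) {
      idx <- which(s$read_id == rid)
      score <- (s$read_end[idx] - s$read_start[idx]) * s$identity[idx]
      ord <- idx[order(-score)]
      acc <- integer(0)
      for (i in ord) {
        ovl <- pmin(s$read_end[acc], s$read_end[i]) -
          pmax(s$read_start[acc], s$read_start[i])
        if (!length(acc) || all(ovl <= max_overlap)) acc <- c(acc, i)
      }
      keep[acc] <- TRUE
    }
    clean <- !(s$read_id %in% unique(s$read_id[has_ovl]))
    s <- s[keep | clean, , drop = FALSE]
    s <- s[order(s$read_id, s$read_start), , drop = FALSE]
  }
  rownames(s) <- NULL
  s
}

empty_junctions <- function() {
  data.frame(read_id = character(), jidx = integer(),
             chrom_l = character(), pos_l = numeric(), side_l = character(),
             chrom_r = character(), pos_r = numeric(), side_r = character(),
             read_gap = numeric(), gap_seq = character(),
             l_start = numeric(), l_end = numeric(),
             r_start = numeric(), r_end = numeric(),
             chrom_a = character(), pos_a = numeric(), side_a = character(),
             chrom_b = character(), pos_b = numeric(), side_b = character(),
             flipped = logical(), stringsAsFactors = FALSE)
}

#' Extract rearrangement junctions from segment chains
#'
#' One junction per adjacent segment pair that is not colinear. Colinear
#' means: same chromosome, same strand, and reference advance consistent
#' with read advance within `colinear_gap_tol`. Breakend sides follow the
#' strand of each flanking segment: a forward segment left of the junction
#' contributes its reference end as a `head` breakend (retained sequence
#' toward smaller coordinates), a reverse segment its reference start as a
#' `tail` breakend; symmetric on the right. Each junction is reported both in
#' read-traversal frame (`_l`/`_r`) and in canonical frame (`_a`/`_b`,
#' breakends ordered lexicographically so that equal junctions compare equal
#' regardless of read direction).
#'
#' @param chains Ordered segment data.frame (one or many reads).
#' @param colinear_gap_tol Tolerance in bases for colinearity.
#' @return Junction data.frame.
#' @export
extract_junctions <- function(chains, colinear_gap_tol = 1000) {
  n <- nrow(chains)
  if (n < 2) return(empty_junctions())
  ch <- chains[order(chains$read_id, chains$read_start), , drop = FALSE]
  li <- which(ch$read_id[-n] == ch$read_id[-1])
  if (!length(li)) return(empty_junctions())
  ri <- li + 1
  same_chrom <- ch$ref_chrom[li] == ch$ref_chrom[ri]
  same_strand <- ch$strand[li] == ch$strand[ri]
  read_gap <- ch$read_start[ri] - ch$read_end[li]
  ref_gap <- ifelse(ch$strand[li] == "+",
                    ch$ref_start[ri] - ch$ref_end[li],
                    ch$ref_start[li] - ch$ref_end[ri])
  colinear <- same_chrom & same_strand &
    abs(ref_gap - read_gap) <= colinear_gap_tol
  li <- li[!colinear]; ri <- ri[!colinear]
  if (!length(li)) return(empty_junctions())
  lfwd <- ch$strand[li] == "+"
  rfwd <- ch$strand[ri] == "+"
  j <- data.frame(
    read_id = ch$read_id[li],
    jidx = stats::ave(li, ch$read_id[li], FUN = seq_along),
    chrom_l = ch$ref_chrom[li],
    pos_l = ifelse(lfwd, ch$ref_end[li], ch$ref_start[li]),
    side_l = ifelse(lfwd, "head", "tail"),
    chrom_r = ch$ref_chrom[ri],
    pos_r = ifelse(rfwd, ch$ref_start[ri], ch$ref_end[ri]),
    side_r = ifelse(rfwd, "tail", "head"),
    read_gap = ch$read_start[ri] - ch$read_end[li],
    gap_seq = ch$gap_seq[ri],
    l_start = ch$ref_start[li], l_end = ch$ref_end[li],
    r_start = ch$ref_start[ri], r_end = ch$ref_end[ri],
    stringsAsFactors = FALSE)
  canonicalize_junctions(j)
}

# Append canonical-frame columns: breakends ordered by (chrom, pos, side).
canonicalize_junctions <- function(j) {
  keep <- paste(j$chrom_l, formatC(j$pos_l, format = "f", digits = 0, width = 12,
                                   flag = "0"), j$side_l) <=
          paste(j$chrom_r, formatC(j$pos_r, format = "f", digits = 0, width = 12,
                                   flag = "0"), j$side_r)
  j$chrom_a <- ifelse(keep, j$chrom_l, j$chrom_r)
  j$pos_a <- ifelse(keep, j$pos_l, j$pos_r)
  j$side_a <- ifelse(keep, j$side_l, j$side_r)
  j$chrom_b <- ifelse(keep, j$chrom_r, j$chrom_l)
  j$pos_b <- ifelse(keep, j$pos_r, j$pos_l)
  j$side_b <- ifelse(keep, j$side_r, j$side_l)
  j$flipped <- !keep
  j
}

#' Junctions of a single read chain
#'
#' Convenience wrapper around [extract_junctions()] for one read.
#'
#' @param chain Segment data.frame of one read.
#' @param colinear_gap_tol Colinearity tolerance, bases.
#' @return Junction data.frame.
#' @export
junctions_of <- function(chain, colinear_gap_tol = 1000) {
  extract_junctions(chain, colinear_gap_tol)
}

#' Construct a canonical junction row
#'
#' @param chrom_l,pos_l,side_l,chrom_r,pos_r,side_r The two oriented
#'   breakends in traversal order.
#' @return One-row canonical junction data.frame.
#' @export
canonical_junction <- function(chrom_l, pos_l, side_l, chrom_r, pos_r, side_r) {
  j <- data.frame(read_id = NA_character_, jidx = 1L,
                  chrom_l = chrom_l, pos_l = as.numeric(pos_l), side_l = side_l,
                  chrom_r = chrom_r, pos_r = as.numeric(pos_r), side_r = side_r,
                  read_gap = 0, gap_seq = NA_character_,
                  l_start = NA_real_, l_end = NA_real_,
                  r_start = NA_real_, r_end = NA_real_,
                  stringsAsFactors = FALSE)
  canonicalize_junctions(j)
}

# Single-linkage clustering of canonical junctions: two junctions join a
# cluster when both breakends are within match_tol and sides/chromosomes are
# identical. Returns integer cluster ids aligned with rows of j.
cluster_junctions <- function(j, match_tol) {
  n <- nrow(j)
  if (!n) return(integer(0))
  key <- paste(j$chrom_a, j$side_a, j$chrom_b, j$side_b)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    ord <- idx[order(j$pos_a[idx])]
    lo <- 1
    for (hi in 2:length(ord)) {
      while (j$pos_a[ord[hi]] - j$pos_a[ord[lo]] > match_tol) lo <- lo + 1
      if (lo > hi - 1) next
      for (m in lo:(hi - 1)) {
        if (abs(j$pos_b[ord[hi]] - j$pos_b[ord[m]]) <= match_tol)
          union_(ord[hi], ord[m])
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Lower median: for even counts take the smaller central value, so consensus
# coordinates are deterministic integers.
lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

# Consensus coordinates per junction cluster.
cluster_consensus <- function(j, cl) {
  rows <- lapply(split(seq_len(nrow(j)), cl), function(idx) {
    data.frame(cluster = cl[idx[1]],
               chrom_a = j$chrom_a[idx[1]], pos_a = lower_median(j$pos_a[idx]),
               side_a = j$side_a[idx[1]],
               chrom_b = j$chrom_b[idx[1]], pos_b = lower_median(j$pos_b[idx]),
               side_b = j$side_b[idx[1]],
               n_obs = length(idx),
               spread = max(diff(range(j$pos_a[idx])), diff(range(j$pos_b[idx]))),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$cluster), , drop = FALSE]
}

# Does any junction in table `a` match any in table `b` (canonical frames,
# same sides/chromosomes, both breakends within tol)?
junctions_match_any <- function(a, b, tol) {
  if (!nrow(a) || !nrow(b)) return(FALSE)
  ka <- paste(a$chrom_a, a$side_a, a$chrom_b, a$side_b)
  kb <- paste(b$chrom_a, b$side_a, b$chrom_b, b$side_b)
  for (k in intersect(unique(ka), unique(kb))) {
    ia <- which(ka == k); ib <- which(kb == k)
    for (i in ia) {
      if (any(abs(b$pos_a[ib] - a$pos_a[i]) <= tol &
              abs(b$pos_b[ib] - a$pos_b[i]) <= tol))
        return(TRUE)
    }
  }
  FALSE
}
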