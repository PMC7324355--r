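#' Open ends of a consensus rearrangement
#'
#' Each consensus rearrangement has exactly two open ends: the
#' reference-facing flanks of its outermost segments, where the rearranged
#' allele continues into unrearranged sequence. A forward first segment opens
#' at its reference start extending toward smaller coordinates; a reverse
#' first segment at its reference end extending toward larger; symmetric for
#' the last segment.
#'
#' @param cr A `consensus_rearrangement`.
#' @return data.frame with two rows: `group_id`, `terminal`
#'   (`first`/`last`), `chrom`, `pos`, `dir`
#'   (`toward_smaller`/`toward_larger`).
#' @export
open_ends <- function(cr) {
  s1 <- cr$segments[1, ]
  s2 <- cr$segments[nrow(cr$segments), ]
  data.frame(
    group_id = cr$group_id,
    terminal = c("first", "last"),
    chrom = c(s1$chrom, s2$chrom),
    pos = c(if (s1$strand == "+") s1$start else s1$end,
            if (s2$strand == "+") s2$end else s2$start),
    dir = c(if (s1$strand == "+") "toward_smaller" else "toward_larger",
            if (s2$strand == "+") "toward_larger" else "toward_smaller"),
    stringsAsFactors = FALSE)
}

#' All junction breakends of a consensus set
#'
#' Flattens every junction of every consensus rearrangement into one breakend
#' table, with the owning group id — the input expected by [gene_impact()]
#' and by the link-candidate blocking rule.
#'
#' @param crs List of `consensus_rearrangement`.
#' @return data.frame `group_id`, `chrom`, `pos`.
#' @export
all_breakends <- function(crs) {
  do.call(rbind, lapply(crs, function(cr) {
    tf <- cr$junctions
    data.frame(group_id = cr$group_id,
               chrom = c(tf$chrom_l, tf$chrom_r),
               pos = c(tf$pos_l, tf$pos_r), stringsAsFactors = FALSE)
  }))
}

#' Build the link-candidate graph over open ends
#'
#' Two open ends are a link candidate iff they lie on the same chromosome
#' facing each other (one extends toward larger coordinates at `p1`, the
#' other toward smaller at `p2`, with `p1 <= p2`) and no breakend of any
#' third group lies strictly inside `(p1, p2)`. An open end with no
#' third-group breakend between it and a chromosome terminus in its
#' extension direction is additionally terminus-capable.
#'
#' @param crs List of `consensus_rearrangement` (deduplicated by traversal
#'   frame).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return List with `ends` (open-end table, `end_id` keyed), `candidates`
#'   (data.frame `end_a`, `end_b`) and `termini` (data.frame `end_id`,
#'   `chrom`, `terminus_pos`).
#' @export
build_link_graph <- function(crs, chrom_lengths) {
  stopifnot(length(crs) > 0)
  ends <- do.call(rbind, lapply(crs, open_ends))
  ends$end_id <- seq_len(nrow(ends))
  bks <- all_breakends(crs)
  blocked <- function(chrom, lo, hi, exclude_groups) {
    b <- bks[bks$chrom == chrom & !(bks$group_id %in% exclude_groups), ]
    any(b$pos > lo & b$pos < hi)
  }
  cand <- list()
  larger <- which(ends$dir == "toward_larger")
  smaller <- which(ends$dir == "toward_smaller")
  for (i in larger) for (k in smaller) {
    if (ends$group_id[i] == ends$group_id[k]) next
    if (ends$chrom[i] != ends$chrom[k]) next
    if (ends$pos[i] > ends$pos[k]) next
    if (blocked(ends$chrom[i], ends$pos[i], ends$pos[k],
                c(ends$group_id[i], ends$group_id[k]))) next
    cand[[length(cand) + 1]] <- data.frame(end_a = ends$end_id[i],
                                           end_b = ends$end_id[k])
  }
  term <- list()
  for (i in seq_len(nrow(ends))) {
    L <- chrom_lengths[[ends$chrom[i]]]
    if (ends$dir[i] == "toward_larger") {
      if (!blocked(ends$chrom[i], ends$pos[i], L, ends$group_id[i]))
        term[[length(term) + 1]] <- data.frame(end_id = ends$end_id[i],
                                               chrom = ends$chrom[i],
                                               terminus_pos = L)
    } else {
      if (!blocked(ends$chrom[i], 0, ends$pos[i], ends$group_id[i]))
        term[[length(term) + 1]] <- data.frame(end_id = ends$end_id[i],
                                               chrom = ends$chrom[i],
                                               terminus_pos = 0)
    }
  }
  list(ends = ends,
       candidates = if (length(cand)) do.call(rbind, cand)
                    else data.frame(end_a = integer(), end_b = integer()),
       termini = if (length(term)) do.call(rbind, term)
                 else data.frame(end_id = integer(), chrom = character(),
                                 terminus_pos = numeric()))
}

#' Order and orient consensus rearrangements into derivative chromosomes
#'
#' Selects a perfect matching on open ends — every end either linked to
#' exactly one facing candidate or assigned a free chromosome terminus —
#' forming simple paths. If exactly one valid matching exists, the
#' reconstructions are returned and the arrangement is declared unique.
#' Zero valid matchings raise an `inconsistent rearrangement` error;
#' several raise an `ambiguous` error (alternatives are never picked
#' silently; set `enumerate = TRUE` to inspect them all).
#'
#' @param crs List of `consensus_rearrangement` objects.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param enumerate Return the list of all valid arrangements instead of
#'   insisting on uniqueness.
#' @return List of `derivative_reconstruction` objects (one per derivative
#'   path), each with `path` (oriented segment table), `fragments` (maximal
#'   colinear fragments), `groups` (group ids in path order) and `termini`.
#'   With `enumerate = TRUE`, a list of such lists.
#' @export
link <- function(crs, chrom_lengths, enumerate = FALSE) {
  lg <- build_link_graph(crs, chrom_lengths)
  valid <- link_matchings(lg)
  if (enumerate)
    return(lapply(valid, build_reconstructions, lg = lg, crs = crs,
                  chrom_lengths = chrom_lengths))
  if (!length(valid))
    stop("inconsistent rearrangement: no valid ordering of the ",
         length(crs), " groups exists", call. = FALSE)
  if (length(valid) > 1)
    stop("ambiguous rearrangement: ", length(valid),
         " distinct orderings are consistent with the data; ",
         "rerun with enumerate = TRUE to inspect them", call. = FALSE)
  build_reconstructions(valid[[1]], lg, crs, chrom_lengths)
}

# Backtracking search for perfect matchings on open ends: every end is
# either paired with one candidate or assigned a free terminus; assignments
# whose group graph contains a cycle are rejected.
link_matchings <- function(lg) {
  n_ends <- nrow(lg$ends)
  # option lists per end
  opt_partner <- lapply(seq_len(n_ends), function(i) {
    c(lg$candidates$end_b[lg$candidates$end_a == i],
      lg$candidates$end_a[lg$candidates$end_b == i])
  })
  term_keys <- paste0(lg$termini$chrom, ":",
                      format(lg$termini$terminus_pos, scientific = FALSE,
                             trim = TRUE))
  opt_term <- lapply(seq_len(n_ends), function(i)
    term_keys[lg$termini$end_id == i])
  solutions <- list()
  assign_vec <- rep(NA_character_, n_ends)  # "end:<id>" or "term:<key>"
  used_term <- character(0)
  recurse <- function() {
    i <- which(is.na(assign_vec))[1]
    if (is.na(i)) {
      solutions[[length(solutions) + 1]] <<- assign_vec
      return(invisible())
    }
    for (p in opt_partner[[i]]) {
      if (!is.na(assign_vec[p])) next
      assign_vec[i] <<- paste0("end:", p)
      assign_vec[p] <<- paste0("end:", i)
      recurse()
      assign_vec[i] <<- NA_character_
      assign_vec[p] <<- NA_character_
    }
    for (tk in opt_term[[i]]) {
      if (tk %in% used_term) next
      assign_vec[i] <<- paste0("term:", tk)
      used_term <<- c(used_term, tk)
      recurse()
      assign_vec[i] <<- NA_character_
      used_term <<- setdiff(used_term, tk)
    }
    invisible()
  }
  recurse()
  # reject assignments containing cycles (a component with no terminus end)
  Filter(function(a) !has_cycle(a, lg$ends), solutions)
}

has_cycle <- function(assign_vec, ends) {
  linked <- grepl("^end:", assign_vec)
  seen <- rep(FALSE, length(assign_vec))
  # start marking from terminus ends, crossing groups and links
  other_end <- function(i) {
    gid <- ends$group_id[i]
    setdiff(which(ends$group_id == gid), i)
  }
  for (s in which(!linked)) {
    i <- s
    while (!seen[i]) {
      seen[i] <- TRUE
      o <- other_end(i)
      seen[o] <- TRUE
      if (grepl("^end:", assign_vec[o]))
        i <- as.integer(sub("end:", "", assign_vec[o]))
      else break
    }
  }
  !all(seen)
}

build_reconstructions <- function(assign_vec, lg, crs, chrom_lengths) {
  ends <- lg$ends
  crs_by_id <- stats::setNames(crs, vapply(crs, function(x)
    as.character(x$group_id), character(1)))
  term_ends <- which(grepl("^term:", assign_vec))
  ord <- term_ends[order(ends$chrom[term_ends], ends$pos[term_ends])]
  visited <- character(0)
  recons <- list()
  for (start_end in ord) {
    gid <- as.character(ends$group_id[start_end])
    if (gid %in% visited) next
    segs <- list(); groups <- integer(); termini <- character()
    # entry terminus extension
    e <- ends[start_end, ]
    tk <- sub("term:", "", assign_vec[start_end])
    tpos <- as.numeric(sub(".*:", "", tk))
    termini <- c(termini, tk)
    if (e$dir == "toward_smaller") {
      if (e$pos > 0) segs[[length(segs) + 1]] <-
        data.frame(chrom = e$chrom, start = 0, end = e$pos, strand = "+",
                   stringsAsFactors = FALSE)
    } else {
      if (e$pos < tpos) segs[[length(segs) + 1]] <-
        data.frame(chrom = e$chrom, start = e$pos, end = tpos, strand = "-",
                   stringsAsFactors = FALSE)
    }
    cur <- start_end
    repeat {
      gid <- as.character(ends$group_id[cur])
      visited <- c(visited, gid)
      cr <- crs_by_id[[gid]]
      oriented <- if (ends$terminal[cur] == "first") cr else reverse_frame(cr)
      segs[[length(segs) + 1]] <- oriented$segments
      groups <- c(groups, cr$group_id)
      exit <- setdiff(which(ends$group_id == ends$group_id[cur]), cur)
      a <- assign_vec[exit]
      ex <- ends[exit, ]
      if (grepl("^term:", a)) {
        tk <- sub("term:", "", a)
        tpos <- as.numeric(sub(".*:", "", tk))
        termini <- c(termini, tk)
        if (ex$dir == "toward_larger") {
          if (ex$pos < tpos) segs[[length(segs) + 1]] <-
            data.frame(chrom = ex$chrom, start = ex$pos, end = tpos,
                       strand = "+", stringsAsFactors = FALSE)
        } else {
          if (ex$pos > 0) segs[[length(segs) + 1]] <-
            data.frame(chrom = ex$chrom, start = 0, end = ex$pos,
                       strand = "-", stringsAsFactors = FALSE)
        }
        break
      }
      nxt <- as.integer(sub("end:", "", a))
      nx <- ends[nxt, ]
      if (ex$dir == "toward_larger") {
        if (ex$pos < nx$pos) segs[[length(segs) + 1]] <-
          data.frame(chrom = ex$chrom, start = ex$pos, end = nx$pos,
                     strand = "+", stringsAsFactors = FALSE)
      } else {
        if (nx$pos < ex$pos) segs[[length(segs) + 1]] <-
          data.frame(chrom = ex$chrom, start = nx$pos, end = ex$pos,
                     strand = "-", stringsAsFactors = FALSE)
      }
      cur <- nxt
    }
    path <- do.call(rbind, segs)
    rownames(path) <- NULL
    recons[[length(recons) + 1]] <- structure(
      list(name = sprintf("der%d", length(recons) + 1), path = path,
           fragments = merge_colinear(path), groups = groups,
           termini = termini,
           terminal_status = rep("reaches_chromosome_terminus", 2)),
      class = "derivative_reconstruction")
  }
  recons
}

#' @export
print.derivative_reconstruction <- function(x, ...) {
  cat(x$name, ": ", nrow(x$fragments), " fragments from ",
      length(x$groups), " group(s) [", paste(x$termini, collapse = " -> "),
      "]\n", sep = "")
  invisible(x)
}

#' Merge colinear path segments into maximal fragments
#'
#' Adjacent path segments on the same chromosome and strand whose reference
#' coordinates are contiguous within `tol` merge into one fragment; the
#' result is the breakpoint-to-breakpoint fragment list of a derivative.
#'
#' @param path Segment data.frame (`chrom`, `start`, `end`, `strand`) in
#'   traversal order, or a `derivative_reconstruction`.
#' @param tol Contiguity tolerance in bases.
#' @return Fragment data.frame with a `rank` column.
#' @export
merge_colinear <- function(path, tol = 1000) {
  if (inherits(path, "derivative_reconstruction")) path <- path$path
  if (!nrow(path)) return(cbind(path, rank = integer()))
  out <- path[1, , drop = FALSE]
  for (i in seq_len(nrow(path) - 1) + 1) {
    cur <- out[nrow(out), ]
    nxt <- path[i, ]
    mergeable <- cur$chrom == nxt$chrom && cur$strand == nxt$strand &&
      ((cur$strand == "+" && abs(nxt$start - cur$end) <= tol) ||
       (cur$strand == "-" && abs(cur$start - nxt$end) <= tol))
    if (mergeable) {
      if (cur$strand == "+") out$end[nrow(out)] <- nxt$end
      else out$start[nrow(out)] <- nxt$start
    } else out <- rbind(out, nxt)
  }
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Infer deletions from derivative reconstructions
#'
#' Per chromosome, the union of all fragment source intervals is formed;
#' uncovered gaps interior to the covered span of size at least `min_size`
#' are deletion calls. Gaps at chromosome termini are never called: the
#' derivatives claim the termini, so missing terminal sequence would be an
#' incomplete reconstruction, not a deletion.
#'
#' @param recons List of `derivative_reconstruction`.
#' @param chrom_lengths Named chromosome lengths.
#' @param min_size Minimum deletion size in bases.
#' @return data.frame `chrom`, `start`, `end`, `length`.
#' @export
infer_deletions <- function(recons, chrom_lengths, min_size = 10000) {
  frags <- do.call(rbind, lapply(recons, function(r) r$fragments))
  out <- list()
  for (ch in unique(frags$chrom)) {
    f <- frags[frags$chrom == ch, ]
    ir <- IRanges::reduce(IRanges::IRanges(start = f$start + 1, end = f$end))
    if (length(ir) > 1) {
      gp <- IRanges::gaps(ir, start = min(IRanges::start(ir)),
                          end = max(IRanges::end(ir)))
      gp <- gp[IRanges::width(gp) >= min_size]
      if (length(gp))
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = IRanges::start(gp) - 1, end = IRanges::end(gp),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric()))
  d <- do.call(rbind, out)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  d$length <- d$end - d$start
  rownames(d) <- NULL
  d
}

#' Concordance between inferred deletions and array calls
#'
#' Matches each deletion call to the overlapping array interval with the
#' highest reciprocal overlap and reports size differences; unmatched
#' entries on either side are listed.
#'
#' @param deletions Deletion data.frame (`chrom`, `start`, `end`).
#' @param array_calls BED-style data.frame (`chrom`, `start`, `end`).
#' @return List with `matched` (per-locus table: reciprocal overlap
#'   fraction, size difference), `unmatched_deletions`, `unmatched_array`.
#' @export
interval_concordance <- function(deletions, array_calls) {
  matched <- list()
  used <- logical(nrow(array_calls))
  for (i in seq_len(nrow(deletions))) {
    d <- deletions[i, ]
    best <- 0; bj <- NA_integer_
    for (j in seq_len(nrow(array_calls))) {
      a <- array_calls[j, ]
      if (a$chrom != d$chrom) next
      ovl <- min(d$end, a$end) - max(d$start, a$start)
      if (ovl <= 0) next
      rec <- min(ovl / (d$end - d$start), ovl / (a$end - a$start))
      if (rec > best) { best <- rec; bj <- j }
    }
    if (!is.na(bj)) {
      used[bj] <- TRUE
      a <- array_calls[bj, ]
      matched[[length(matched) + 1]] <- data.frame(
        chrom = d$chrom, del_start = d$start, del_end = d$end,
        array_start = a$start, array_end = a$end,
        reciprocal_overlap = best,
        size_difference = (d$end - d$start) - (a$end - a$start),
        stringsAsFactors = FALSE)
    } else {
      matched[[length(matched) + 1]] <- data.frame(
        chrom = d$chrom, del_start = d$start, del_end = d$end,
        array_start = NA_real_, array_end = NA_real_,
        reciprocal_overlap = 0, size_difference = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  m <- if (length(matched)) do.call(rbind, matched)
       else data.frame(chrom = character(), del_start = numeric(),
                       del_end = numeric(), array_start = numeric(),
                       array_end = numeric(), reciprocal_overlap = numeric(),
                       size_difference = numeric())
  list(matched = m[!is.na(m$array_start), , drop = FALSE],
       unmatched_deletions = m[is.na(m$array_start), c("chrom", "del_start", "del_end"), drop = FALSE],
       unmatched_array = array_calls[!used, , drop = FALSE])
}
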