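#' Merge a rearrangement group into a consensus rearrangement
#'
#' Breakpoint-level consensus: junction clusters are formed at `match_tol`,
#' the consensus coordinate of each breakend is the lower median of member
#' positions, and the ordered, oriented reference segments traversed by the
#' rearranged allele are derived from the members' chains after orienting
#' every read into a common frame (reads traversing the event in opposite
#' directions are flipped before ordering). Groups whose reads imply
#' inconsistent segment orders are flagged unresolvable, not guessed.
#'
#' @param group One group from [group_reads()].
#' @param config A [detect_config()].
#' @return Object of class `consensus_rearrangement` with `segments`
#'   (data.frame `chrom`, `start`, `end`, `strand`, in traversal order),
#'   `junctions` (traversal frame, one row per adjacent segment pair, with
#'   per-junction coordinate `spread`), `support` and `read_ids`; or an
#'   object of class `unresolved_group` carrying the reason.
#' @export
consensus_rearrangement <- function(group, config = detect_config()) {
  j <- group$junctions
  cl <- cluster_junctions(j, config$match_tol)
  cons <- cluster_consensus(j, cl)
  k <- nrow(cons)
  unresolved <- function(reason)
    structure(list(group_id = group$group_id, reason = reason,
                   support = group$support, read_ids = group$read_ids),
              class = "unresolved_group")
  # junction adjacency path from read traversals
  if (k > 1) {
    edges <- list()
    for (rid in unique(j$read_id)) {
      idx <- which(j$read_id == rid)
      idx <- idx[order(j$jidx[idx])]
      if (length(idx) > 1)
        edges[[length(edges) + 1]] <- cbind(cl[idx[-length(idx)]], cl[idx[-1]])
    }
    if (!length(edges)) return(unresolved("disconnected junctions"))
    e <- unique(do.call(rbind, edges))
    e <- unique(t(apply(e, 1, sort)))
    g <- igraph::graph_from_edgelist(matrix(as.character(e), ncol = 2),
                                     directed = FALSE)
    if (igraph::vcount(g) < k || igraph::components(g)$no > 1)
      return(unresolved("disconnected junctions"))
    deg <- igraph::degree(g)
    if (any(deg > 2) || igraph::ecount(g) != k - 1)
      return(unresolved("branched or cyclic junction order"))
    ends <- names(deg)[deg == 1]
    key <- function(cid) {
      r <- cons[cons$cluster == as.integer(cid), ]
      paste(r$chrom_a, formatC(r$pos_a, format = "f", digits = 0, width = 12,
                               flag = "0"), r$side_a, r$chrom_b, r$side_b)
    }
    start <- ends[order(vapply(ends, key, character(1)))][1]
    path <- as.integer(names(igraph::shortest_paths(
      g, from = start, to = setdiff(ends, start))$vpath[[1]]))
  } else path <- cons$cluster[1]

  # orientation of each junction in the path frame
  orient <- rep(NA, k)  # TRUE: traversal (left,right) = canonical (a,b)
  names(orient) <- as.character(path)
  if (k == 1) {
    orient[1] <- TRUE
  } else {
    pos_in_path <- match(cl, path)
    for (rid in unique(j$read_id)) {
      idx <- which(j$read_id == rid)
      idx <- idx[order(j$jidx[idx])]
      if (length(idx) < 2) next
      p <- pos_in_path[idx]
      if (all(diff(p) == 1)) dirf <- TRUE
      else if (all(diff(p) == -1)) dirf <- FALSE
      else return(unresolved("read junction order inconsistent with path"))
      for (m in seq_along(idx)) {
        ab <- if (dirf) !j$flipped[idx[m]] else j$flipped[idx[m]]
        slot <- as.character(cl[idx[m]])
        if (is.na(orient[slot])) orient[slot] <- ab
        else if (orient[slot] != ab)
          return(unresolved("members disagree on traversal orientation"))
      }
    }
    if (anyNA(orient)) return(unresolved("unoriented junction"))
  }

  # traversal-frame junction table
  tf <- do.call(rbind, lapply(seq_len(k), function(i) {
    r <- cons[cons$cluster == path[i], ]
    ab <- orient[as.character(path[i])]
    data.frame(cluster = r$cluster,
               chrom_l = if (ab) r$chrom_a else r$chrom_b,
               pos_l = if (ab) r$pos_a else r$pos_b,
               side_l = if (ab) r$side_a else r$side_b,
               chrom_r = if (ab) r$chrom_b else r$chrom_a,
               pos_r = if (ab) r$pos_b else r$pos_a,
               side_r = if (ab) r$side_b else r$side_a,
               n_obs = r$n_obs, spread = r$spread, stringsAsFactors = FALSE)
  }))

  # interior segments between consecutive junctions
  segs <- list()
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      p <- tf$pos_r[i]; q <- tf$pos_l[i + 1]
      if (tf$chrom_r[i] != tf$chrom_l[i + 1])
        return(unresolved("adjacent junctions on different chromosomes"))
      if (tf$side_r[i] == "tail" && tf$side_l[i + 1] == "head" && p < q)
        segs[[i]] <- data.frame(chrom = tf$chrom_r[i], start = p, end = q,
                                strand = "+", stringsAsFactors = FALSE)
      else if (tf$side_r[i] == "head" && tf$side_l[i + 1] == "tail" && q < p)
        segs[[i]] <- data.frame(chrom = tf$chrom_r[i], start = q, end = p,
                                strand = "-", stringsAsFactors = FALSE)
      else return(unresolved("incompatible adjacent junction geometry"))
    }
  }

  # outer segments from member extents (maximal reach into flanking sequence)
  flank_coords <- function(cluster_id, left) {
    idx <- which(cl == cluster_id)
    ab <- orient[as.character(cluster_id)]
    # does this row's (l, r) match the frame's (L, R)?
    matches <- if (ab) !j$flipped[idx] else j$flipped[idx]
    if (left)
      data.frame(start = ifelse(matches, j$l_start[idx], j$r_start[idx]),
                 end = ifelse(matches, j$l_end[idx], j$r_end[idx]))
    else
      data.frame(start = ifelse(matches, j$r_start[idx], j$l_start[idx]),
                 end = ifelse(matches, j$r_end[idx], j$l_end[idx]))
  }
  fc <- flank_coords(path[1], left = TRUE)
  first <- if (tf$side_l[1] == "head")
    data.frame(chrom = tf$chrom_l[1], start = min(fc$start), end = tf$pos_l[1],
               strand = "+", stringsAsFactors = FALSE)
  else
    data.frame(chrom = tf$chrom_l[1], start = tf$pos_l[1], end = max(fc$end),
               strand = "-", stringsAsFactors = FALSE)
  fc <- flank_coords(path[k], left = FALSE)
  last <- if (tf$side_r[k] == "tail")
    data.frame(chrom = tf$chrom_r[k], start = tf$pos_r[k], end = max(fc$end),
               strand = "+", stringsAsFactors = FALSE)
  else
    data.frame(chrom = tf$chrom_r[k], start = min(fc$start), end = tf$pos_r[k],
               strand = "-", stringsAsFactors = FALSE)
  segments <- do.call(rbind, c(list(first), segs, list(last)))
  rownames(segments) <- NULL
  if (any(segments$end <= segments$start))
    return(unresolved("degenerate segment"))
  structure(list(group_id = group$group_id, segments = segments,
                 junctions = tf, support = group$support,
                 read_ids = group$read_ids,
                 gap_seqs = as.character(stats::na.omit(unique(j$gap_seq)))),
            class = "consensus_rearrangement")
}

#' Consensus for every group
#'
#' @param groups A `rearrangement_groups` object (typically the survivors of
#'   [subtract_controls()]).
#' @param config A [detect_config()].
#' @return List with `consensus` (list of `consensus_rearrangement`) and
#'   `unresolved` (list of `unresolved_group`, reported rather than dropped
#'   silently).
#' @export
consensus_all <- function(groups, config = detect_config()) {
  res <- lapply(groups$groups, consensus_rearrangement, config = config)
  ok <- vapply(res, inherits, logical(1), "consensus_rearrangement")
  list(consensus = res[ok], unresolved = res[!ok])
}

#' @export
print.consensus_rearrangement <- function(x, ...) {
  cat("consensus_rearrangement #", x$group_id, ": ", nrow(x$segments),
      " segments, ", nrow(x$junctions), " junction(s), support ",
      x$support, "\n", sep = "")
  invisible(x)
}

#' Reverse the traversal frame of a consensus rearrangement
#'
#' @param cr A `consensus_rearrangement`.
#' @return The same event traversed in the opposite direction.
#' @export
reverse_frame <- function(cr) {
  segs <- cr$segments[rev(seq_len(nrow(cr$segments))), , drop = FALSE]
  segs$strand <- ifelse(segs$strand == "+", "-", "+")
  rownames(segs) <- NULL
  tf <- cr$junctions[rev(seq_len(nrow(cr$junctions))), , drop = FALSE]
  tf2 <- tf
  tf2$chrom_l <- tf$chrom_r; tf2$pos_l <- tf$pos_r; tf2$side_l <- tf$side_r
  tf2$chrom_r <- tf$chrom_l; tf2$pos_r <- tf$pos_l; tf2$side_r <- tf$side_l
  rownames(tf2) <- NULL
  out <- cr
  out$segments <- segs
  out$junctions <- tf2
  out
}

#' Are two consensus rearrangements the same event up to traversal direction?
#'
#' True iff the two are identical, or identical after fully reversing one
#' frame (reversed segment list with flipped strands). Used to deduplicate
#' events discovered in opposite read orientations.
#'
#' @param cr_a,cr_b `consensus_rearrangement` objects.
#' @param tol Coordinate tolerance in bases (0 compares exactly).
#' @return Logical flag.
#' @export
traversal_frames_equal <- function(cr_a, cr_b, tol = 0) {
  same <- function(a, b) {
    if (nrow(a$segments) != nrow(b$segments)) return(FALSE)
    sa <- a$segments; sb <- b$segments
    all(sa$chrom == sb$chrom & sa$strand == sb$strand &
        abs(sa$start - sb$start) <= tol & abs(sa$end - sb$end) <= tol)
  }
  same(cr_a, cr_b) || same(reverse_frame(cr_a), cr_b)
}

#' Build consensus rearrangements directly from a plan's truth junctions
#'
#' The coordinate-level analog of merging reads group-by-group when the
#' grouping is known: consecutive derivative adjacencies whose intervening
#' fragment is short enough to be spanned by single long reads (`span`)
#' collapse into one consensus. Used to exercise the linking stage without
#' read simulation.
#'
#' @param plan A `rearrangement_plan`.
#' @param span Maximal fragment length (bases) considered read-spannable.
#' @param flank Outer segment extent in bases.
#' @return List of `consensus_rearrangement` objects.
#' @export
consensus_from_plan <- function(plan, span = 20000, flank = 10000) {
  fr <- plan$fragments
  out <- list()
  for (dn in names(plan$derivatives)) {
    ids <- plan$derivatives[[dn]]
    tj <- plan$truth_junctions[plan$truth_junctions$derivative == dn, ]
    if (!nrow(tj)) next
    tj <- tj[order(tj$rank), ]
    # adjacency i and i+1 share derivative fragment ids[i+1]
    runs <- cumsum(c(1, vapply(seq_len(nrow(tj) - 1), function(i) {
      f <- fr[as.character(ids[i + 1]), ]
      as.integer(f$end - f$start > span)
    }, integer(1))))
    for (rn in unique(runs)) {
      rows <- tj[runs == rn, , drop = FALSE]
      k <- nrow(rows)
      segs <- list()
      lfrag <- fr[as.character(ids[rows$rank[1]]), ]
      ext <- min(flank, lfrag$end - lfrag$start)
      segs[[1]] <- if (rows$side_l[1] == "head")
        data.frame(chrom = rows$chrom_l[1], start = rows$pos_l[1] - ext,
                   end = rows$pos_l[1], strand = "+", stringsAsFactors = FALSE)
      else
        data.frame(chrom = rows$chrom_l[1], start = rows$pos_l[1],
                   end = rows$pos_l[1] + ext, strand = "-",
                   stringsAsFactors = FALSE)
      if (k > 1) for (i in seq_len(k - 1)) {
        f <- fr[as.character(ids[rows$rank[i] + 1]), ]
        segs[[i + 1]] <- data.frame(chrom = f$chrom, start = f$start,
                                    end = f$end, strand = f$strand,
                                    stringsAsFactors = FALSE)
      }
      rfrag <- fr[as.character(ids[rows$rank[k] + 1]), ]
      ext <- min(flank, rfrag$end - rfrag$start)
      segs[[k + 1]] <- if (rows$side_r[k] == "tail")
        data.frame(chrom = rows$chrom_r[k], start = rows$pos_r[k],
                   end = rows$pos_r[k] + ext, strand = "+",
                   stringsAsFactors = FALSE)
      else
        data.frame(chrom = rows$chrom_r[k], start = rows$pos_r[k] - ext,
                   end = rows$pos_r[k], strand = "-", stringsAsFactors = FALSE)
      tf <- data.frame(cluster = seq_len(k),
                       chrom_l = rows$chrom_l, pos_l = rows$pos_l,
                       side_l = rows$side_l, chrom_r = rows$chrom_r,
                       pos_r = rows$pos_r, side_r = rows$side_r,
                       n_obs = 1L, spread = 0, stringsAsFactors = FALSE)
      out[[length(out) + 1]] <- structure(
        list(group_id = length(out) + 1L,
             segments = do.call(rbind, segs), junctions = tf,
             support = 1L, read_ids = character(),
             gap_seqs = character()),
        class = "consensus_rearrangement")
    }
  }
  out
}
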