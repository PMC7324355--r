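# Independent brute-force oracle for the linking stage: enumerates every
# complete end-pairing (link or terminus per end) by direct recursion with a
# from-scratch validity predicate, and returns the set of valid matchings in
# a canonical string form. Written against the linking rules only; shares no
# code with the package's search.

oracle_ends <- function(crs) {
  do.call(rbind, lapply(seq_along(crs), function(i) {
    s <- crs[[i]]$segments
    f <- s[1, ]; l <- s[nrow(s), ]
    data.frame(
      cr = i,
      chrom = c(f$chrom, l$chrom),
      pos = c(ifelse(f$strand == "+", f$start, f$end),
              ifelse(l$strand == "+", l$end, l$start)),
      up = c(f$strand == "+", l$strand != "+"),  # TRUE: extends toward smaller
      stringsAsFactors = FALSE)
  }))
}

oracle_breakends <- function(crs) {
  do.call(rbind, lapply(seq_along(crs), function(i) {
    tf <- crs[[i]]$junctions
    data.frame(cr = i, chrom = c(tf$chrom_l, tf$chrom_r),
               pos = c(tf$pos_l, tf$pos_r), stringsAsFactors = FALSE)
  }))
}

oracle_matchings <- function(crs, chrom_lengths) {
  ends <- oracle_ends(crs)
  bks <- oracle_breakends(crs)
  n <- nrow(ends)
  clear <- function(chrom, lo, hi, skip) {
    b <- bks[bks$chrom == chrom & !(bks$cr %in% skip), ]
    !any(b$pos > lo & b$pos < hi)
  }
  pair_ok <- function(i, j) {
    if (ends$cr[i] == ends$cr[j]) return(FALSE)
    if (ends$chrom[i] != ends$chrom[j]) return(FALSE)
    if (ends$up[i] == ends$up[j]) return(FALSE)
    lo <- if (ends$up[i]) j else i  # the toward-larger end
    hi <- if (ends$up[i]) i else j
    ends$pos[lo] <= ends$pos[hi] &&
      clear(ends$chrom[i], ends$pos[lo], ends$pos[hi],
            c(ends$cr[i], ends$cr[j]))
  }
  term_ok <- function(i, key) {
    ch <- sub(":.*", "", key)
    tp <- as.numeric(sub(".*:", "", key))
    if (ch != ends$chrom[i]) return(FALSE)
    if (tp == 0 && ends$up[i]) clear(ch, 0, ends$pos[i], ends$cr[i])
    else if (tp > 0 && !ends$up[i]) clear(ch, ends$pos[i], tp, ends$cr[i])
    else FALSE
  }
  term_keys <- c(paste0(names(chrom_lengths), ":0"),
                 paste0(names(chrom_lengths), ":",
                        format(unlist(chrom_lengths), scientific = FALSE,
                               trim = TRUE)))
  sols <- character(0)
  assign <- rep(NA_character_, n)
  used <- character(0)
  no_cycle <- function() {
    seen <- rep(FALSE, n)
    for (s in which(grepl("^T", assign))) {
      i <- s
      repeat {
        seen[i] <- TRUE
        o <- setdiff(which(ends$cr == ends$cr[i]), i)
        seen[o] <- TRUE
        if (grepl("^P", assign[o])) i <- as.integer(sub("P", "", assign[o]))
        else break
      }
    }
    all(seen)
  }
  rec <- function() {
    i <- which(is.na(assign))[1]
    if (is.na(i)) {
      if (no_cycle()) {
        tok <- sort(c(
          vapply(which(grepl("^P", assign)), function(k)
            paste0("P", min(k, as.integer(sub("P", "", assign[k]))), "-",
                   max(k, as.integer(sub("P", "", assign[k])))), character(1)),
          vapply(which(grepl("^T", assign)), function(k)
            paste0("T", k, "=", sub("T", "", assign[k])), character(1))))
        sols <<- c(sols, paste(unique(tok), collapse = ";"))
      }
      return(invisible())
    }
    for (j in setdiff(which(is.na(assign)), i)) {
      if (pair_ok(i, j)) {
        assign[i] <<- paste0("P", j); assign[j] <<- paste0("P", i)
        rec()
        assign[i] <<- NA_character_; assign[j] <<- NA_character_
      }
    }
    for (key in setdiff(term_keys, used)) {
      if (term_ok(i, key)) {
        assign[i] <<- paste0("T", key); used <<- c(used, key)
        rec()
        assign[i] <<- NA_character_; used <<- setdiff(used, key)
      }
    }
    invisible()
  }
  rec()
  sort(unique(sols))
}

# Canonicalize a package assignment vector ("end:<j>" / "term:<key>") into
# the oracle's string form for comparison.
canon_assign <- function(assign_vec) {
  tok <- c(
    vapply(which(grepl("^end:", assign_vec)), function(k) {
      j <- as.integer(sub("end:", "", assign_vec[k]))
      paste0("P", min(k, j), "-", max(k, j))
    }, character(1)),
    vapply(which(grepl("^term:", assign_vec)), function(k)
      paste0("T", k, "=", sub("term:", "", assign_vec[k])), character(1)))
  paste(sort(unique(tok)), collapse = ";")
}

package_matchings <- function(crs, chrom_lengths) {
  lg <- build_link_graph(crs, chrom_lengths)
  sort(unique(vapply(thripsis:::link_matchings(lg), canon_assign, character(1))))
}
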