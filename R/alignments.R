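#' Parse PAF alignments into aligned segments
#'
#' Standard 12+ column PAF (minimap2/LAST dialects); SAM-style tag columns
#' beyond the twelfth are tolerated and ignored. PAF query coordinates are
#' already on the read's forward orientation. Identity is computed as
#' matches / alignment block length.
#'
#' @param lines Character vector of PAF lines (or a file path of length 1
#'   that exists on disk).
#' @return Segment data.frame (`read_id`, `read_start`, `read_end`,
#'   `ref_chrom`, `ref_start`, `ref_end`, `strand`, `identity`,
#'   `read_length`, `gap_seq`).
#' @export
parse_paf <- function(lines) {
  if (length(lines) == 1 && !grepl("\t", lines) && file.exists(lines))
    lines <- readLines(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_chains())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(parts, length, integer(1))
  if (any(n < 12))
    stop("malformed PAF at line ", which(n < 12)[1], ": fewer than 12 columns")
  m <- t(vapply(parts, function(p) p[1:12], character(12)))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop("malformed PAF at line ", which(is.na(v))[1],
           ": non-numeric coordinate in column ", col)
    v
  }
  strand <- m[, 5]
  if (!all(strand %in% c("+", "-")))
    stop("malformed PAF at line ", which(!strand %in% c("+", "-"))[1],
         ": unknown strand")
  qlen <- num(2); qs <- num(3); qe <- num(4)
  ts <- num(8); te <- num(9); nmatch <- num(10); alen <- num(11)
  data.frame(read_id = m[, 1], read_start = qs, read_end = qe,
             ref_chrom = m[, 6], ref_start = ts, ref_end = te,
             strand = strand,
             identity = ifelse(alen > 0, nmatch / alen, 0),
             read_length = qlen, gap_seq = NA_character_,
             stringsAsFactors = FALSE)
}

#' Parse MAF alignments into aligned segments
#'
#' LAST-dialect MAF: `a score=...` blocks with two (or more) `s` lines, the
#' second `s` line being the query. MAF starts are counted on the annotated
#' strand; minus-strand query coordinates are converted to forward-read
#' coordinates. Identity is the fraction of matching alignment columns.
#'
#' @param text Character vector of MAF lines, a single string, or a path.
#' @return Segment data.frame as in [parse_paf()].
#' @export
parse_maf <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else if (length(text) == 1)
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  out <- list()
  i <- 1
  while (i <= length(text)) {
    if (grepl("^a", text[i])) {
      s_lines <- list()
      j <- i + 1
      while (j <= length(text) && !grepl("^a", text[j])) {
        if (grepl("^s\\s", text[j])) s_lines[[length(s_lines) + 1]] <- text[j]
        j <- j + 1
      }
      if (length(s_lines) < 2)
        stop("MAF block at line ", i, " has fewer than two s-lines")
      f <- function(s) {
        p <- strsplit(trimws(s), "\\s+")[[1]]
        list(name = p[2], start = as.numeric(p[3]), size = as.numeric(p[4]),
             strand = p[5], src_size = as.numeric(p[6]),
             seq = if (length(p) >= 7) p[7] else NA_character_)
      }
      ref <- f(s_lines[[1]]); qry <- f(s_lines[[2]])
      if (anyNA(c(ref$start, ref$size, qry$start, qry$size)))
        stop("MAF block at line ", i, ": non-numeric coordinate")
      if (qry$strand == "+") {
        rs <- qry$start; re <- qry$start + qry$size
      } else {
        rs <- qry$src_size - qry$start - qry$size
        re <- qry$src_size - qry$start
      }
      ident <- 1
      if (!is.na(ref$seq) && !is.na(qry$seq)) {
        a <- strsplit(toupper(ref$seq), "")[[1]]
        b <- strsplit(toupper(qry$seq), "")[[1]]
        ident <- sum(a == b & a != "-") / length(a)
      }
      out[[length(out) + 1]] <- data.frame(
        read_id = qry$name, read_start = rs, read_end = re,
        ref_chrom = ref$name, ref_start = ref$start,
        ref_end = ref$start + ref$size,
        strand = qry$strand, identity = ident, read_length = qry$src_size,
        gap_seq = NA_character_, stringsAsFactors = FALSE)
      i <- j
    } else i <- i + 1
  }
  if (!length(out)) return(empty_chains())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render segment chains as PAF text
#'
#' @param chains Segment data.frame.
#' @return Character vector of PAF lines.
#' @export
write_paf <- function(chains) {
  if (!nrow(chains)) return(character())
  alen <- pmax(chains$read_end - chains$read_start,
               chains$ref_end - chains$ref_start)
  rlen <- chains$read_length
  sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t60",
          chains$read_id, as.integer(rlen), as.integer(chains$read_start),
          as.integer(chains$read_end), chains$strand, chains$ref_chrom,
          as.integer(0), as.integer(chains$ref_start),
          as.integer(chains$ref_end),
          as.integer(round(chains$identity * alen)), as.integer(alen))
}
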