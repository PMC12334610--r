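#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats median rnorm runif setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Parse a CIGAR string into parallel op / length vectors.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    stop("read has no CIGAR string")
  }
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  list(
    op  = substring(toks, nchar(toks), nchar(toks)),
    len = as.integer(substring(toks, 1L, nchar(toks) - 1L))
  )
}

# Reference-space width of an alignment (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

# Per-op reference/query offsets (plain vectors; this sits on the hot
# path). rstart and qstart are 0-based offsets of the first base of each
# op on the reference and the query.
cigar_blocks <- function(ref_start0, cigar) {
  cg <- parse_cigar(cigar)
  ref_c <- cg$op %in% c("M", "D", "N", "=", "X")
  qry_c <- cg$op %in% c("M", "I", "S", "=", "X")
  n <- length(cg$op)
  rstart <- ref_start0 + cumsum(c(0L, ifelse(ref_c, cg$len, 0L)))[seq_len(n)]
  qstart <- cumsum(c(0L, ifelse(qry_c, cg$len, 0L)))[seq_len(n)]
  list(op = cg$op, len = cg$len, rstart = rstart, qstart = qstart,
       ref = ref_c, qry = qry_c)
}

# Scalar CIGAR walk: base and Phred quality of one read at one 0-based
# reference position. Returns list(base, q), NA base inside D/N.
walk_to_base <- function(ref_start0, cigar, seq, qual, pos) {
  cg <- parse_cigar(cigar)
  rcur <- ref_start0
  qcur <- 0L
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]
    len <- cg$len[k]
    if (op == "M" || op == "=" || op == "X") {
      if (pos < rcur + len) {
        off <- qcur + (pos - rcur)
        q <- if (is.na(qual) || qual == "*") {
          NA_integer_
        } else {
          utf8ToInt(substr(qual, off + 1L, off + 1L)) - 33L
        }
        return(list(base = substr(seq, off + 1L, off + 1L), q = q))
      }
      rcur <- rcur + len
      qcur <- qcur + len
    } else if (op == "D" || op == "N") {
      if (pos < rcur + len) return(list(base = NA_character_, q = NA_integer_))
      rcur <- rcur + len
    } else if (op == "I" || op == "S") {
      qcur <- qcur + len
    }
  }
  stop("position outside the read's reference span")
}

# Phred string (offset 33) -> integer qualities; "*" -> NULL.
phred_values <- function(qual) {
  if (is.na(qual) || identical(qual, "*")) return(NULL)
  utf8ToInt(qual) - 33L
}

# Filesystem-safe token for variant / site identifiers.
sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

empty_read_frame <- function() {
  data.frame(
    read_id = character(), chrom = character(), ref_start0 = integer(),
    ref_end0 = integer(), cigar = character(), flag = integer(),
    seq = character(), qual = character(), sa = character(),
    stringsAsFactors = FALSE
  )
}
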