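#' Select primary alignments spanning a position
#'
#' Fetches primary alignments from a coordinate-sorted, indexed BAM whose
#' reference interval contains the given 1-based position. Secondary and
#' supplementary records are excluded; supplementary segments of retained
#' reads remain visible through their SA tag.
#'
#' @param bam Path to an indexed BAM file, or an open `BamFile`.
#' @param chrom Reference sequence name.
#' @param pos 1-based reference position.
#' @return A data.frame with one row per read: `read_id`, `chrom`,
#'   `ref_start0` / `ref_end0` (0-based half-open reference span), `cigar`,
#'   `flag`, `seq`, `qual`, `sa` (SA tag or `NA`).
#' @export
select_spanning_reads <- function(bam, chrom, pos) {
  bf <- if (methods::is(bam, "BamFile")) bam else Rsamtools::BamFile(bam)
  targets <- Rsamtools::scanBamHeader(bf)$targets
  if (!chrom %in% names(targets)) {
    warning("sequence '", chrom, "' absent from BAM header", call. = FALSE)
    return(empty_read_frame())
  }
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos)),
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE
    ),
    what = c("qname", "flag", "pos", "cigar", "seq", "qual"),
    tag = "SA"
  )
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  if (!length(res$qname)) return(empty_read_frame())
  sa <- res$tag$SA
  if (is.null(sa)) sa <- rep(NA_character_, length(res$qname))
  reads <- data.frame(
    read_id = res$qname, chrom = chrom, ref_start0 = res$pos - 1L,
    ref_end0 = NA_integer_, cigar = res$cigar, flag = res$flag,
    seq = as.character(res$seq), qual = as.character(res$qual),
    sa = as.character(sa), stringsAsFactors = FALSE
  )
  reads$ref_end0 <- reads$ref_start0 +
    vapply(reads$cigar, cigar_ref_width, integer(1), USE.NAMES = FALSE)
  pos0 <- pos - 1L
  out <- reads[reads$ref_start0 <= pos0 & pos0 < reads$ref_end0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove chimeric reads
#'
#' Drops reads with a supplementary (split) alignment segment outside the
#' target region -- reads mapping both within the gene of interest and
#' elsewhere. Supplementary segments are taken from the SA tag of the
#' primary record.
#'
#' @param reads Data.frame from [select_spanning_reads()].
#' @param region A `target_region` (0-based half-open).
#' @return The retained subset of `reads`.
#' @export
remove_chimeric_reads <- function(reads, region) {
  if (!nrow(reads)) return(reads)
  keep <- vapply(seq_len(nrow(reads)), function(i) {
    sa <- reads$sa[i]
    if (is.na(sa) || !nzchar(sa)) return(TRUE)
    segs <- strsplit(sa, ";", fixed = TRUE)[[1]]
    segs <- segs[nzchar(segs)]
    for (s in segs) {
      f <- strsplit(s, ",", fixed = TRUE)[[1]]
      seg_chrom <- f[1]
      seg_start0 <- as.integer(f[2]) - 1L
      seg_end0 <- seg_start0 + cigar_ref_width(f[4])
      inside <- seg_chrom == region$chrom &&
        seg_start0 >= region$start && seg_end0 <= region$end
      if (!inside) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Base and quality carried by a read at reference positions
#'
#' Walks the read's CIGAR. At aligned positions (M/=/X) the query base and
#' its Phred quality are returned; positions inside a deletion (D) or a
#' reference skip (N, a spliced-out intron) carry no base. Insertions and
#' clips never map to a reference position.
#'
#' @param read A one-row data.frame (or list) with `read_id`, `ref_start0`,
#'   `cigar`, `seq`, `qual`.
#' @param pos 0-based reference position(s); each must lie within the read's
#'   reference span.
#' @return A data.frame with columns `read_id`, `pos`, `base` (`NA` when
#'   absent) and `phred_q` (`NA` when absent or when the read stores no
#'   qualities).
#' @export
base_at_position <- function(read, pos) {
  blocks <- cigar_blocks(read$ref_start0, read$cigar)
  keep <- blocks$ref
  rstart <- blocks$rstart[keep]
  rlen <- blocks$len[keep]
  qstart <- blocks$qstart[keep]
  op <- blocks$op[keep]
  span_end <- rstart[length(rstart)] + rlen[length(rlen)]
  if (any(pos < read$ref_start0 | pos >= span_end)) {
    stop("position outside the read's reference span")
  }
  idx <- findInterval(pos, rstart)
  aligned <- op[idx] %in% c("M", "=", "X")
  base <- rep(NA_character_, length(pos))
  q <- rep(NA_integer_, length(pos))
  if (any(aligned)) {
    qoff <- qstart[idx[aligned]] + (pos[aligned] - rstart[idx[aligned]])
    base[aligned] <- substring(read$seq, qoff + 1L, qoff + 1L)
    qv <- phred_values(read$qual)
    if (!is.null(qv)) q[aligned] <- qv[qoff + 1L]
  }
  data.frame(read_id = read$read_id, pos = pos, base = base, phred_q = q,
             stringsAsFactors = FALSE)
}

#' Base observations across a read set at one position
#'
#' Applies [base_at_position()] to every read whose span contains the site.
#' Reads that store no base qualities (`*`) are excluded with a counted
#' warning, since the quality gate cannot be evaluated for them.
#'
#' @param reads Data.frame of reads.
#' @param pos0 0-based reference position.
#' @return A data.frame of observations (`read_id`, `pos`, `base`,
#'   `phred_q`), with attribute `n_no_qual` counting excluded reads.
#' @export
observations_at <- function(reads, pos0) {
  cover <- reads$ref_start0 <= pos0 & pos0 < reads$ref_end0
  reads <- reads[cover, , drop = FALSE]
  no_qual <- is.na(reads$qual) | reads$qual == "*"
  if (any(no_qual)) {
    warning(sum(no_qual), " read(s) without base qualities excluded",
            call. = FALSE)
  }
  reads <- reads[!no_qual, , drop = FALSE]
  n <- nrow(reads)
  base <- rep(NA_character_, n)
  q <- rep(NA_integer_, n)
  rs <- reads$ref_start0
  cg <- reads$cigar
  sq <- reads$seq
  ql <- reads$qual
  for (i in seq_len(n)) {
    hit <- walk_to_base(rs[i], cg[i], sq[i], ql[i], pos0)
    base[i] <- hit$base
    q[i] <- hit$q
  }
  obs <- data.frame(read_id = reads$read_id, pos = pos0, base = base,
                    phred_q = q, stringsAsFactors = FALSE)
  attr(obs, "n_no_qual") <- sum(no_qual)
  obs
}

#' Phred-scale base-call reliability
#'
#' Converts a Phred quality `q` to the percentage probability that the base
#' call is correct, `100 * (1 - 10^(-q/10))`: Q10 is 90% reliable, Q20 99%.
#'
#' @param q Non-negative Phred quality value(s).
#' @return Reliability in percent.
#' @examples
#' phred_reliability(10) # 90
#' @export
phred_reliability <- function(q) {
  if (any(q < 0)) stop("Phred quality must be non-negative")
  100 * (1 - 10^(-q / 10))
}
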