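# Shared fixture builders and independent oracles, all generated in code.

# Write a BAM (sorted + indexed) from a record table. Columns: qname, flag,
# rname, pos (1-based), cigar, seq, qual; optional sa (SA tag value).
make_bam <- function(records, seqlengths, dir = tempfile("bam")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  records <- records[order(match(records$rname, names(seqlengths)),
                           records$pos), , drop = FALSE]
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    line <- paste(r$qname, r$flag, r$rname, r$pos, 60, r$cigar,
                  "*", 0, 0, r$seq, r$qual, sep = "\t")
    if (!is.null(records$sa) && !is.na(r$sa) && nzchar(r$sa)) {
      line <- paste0(line, "\tSA:Z:", r$sa)
    }
    line
  }, character(1))
  sam <- file.path(dir, "reads.sam")
  writeLines(c(hdr, lines), sam)
  suppressMessages(
    Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                     indexDestination = TRUE)
  )
}

# Query seq/qual of given length, deterministic content.
mk_seq <- function(n, base = "A") paste(rep(base, n), collapse = "")
mk_qual <- function(n, q = 30) paste(rep(intToUtf8(q + 33L), n), collapse = "")

# A minimal gene_models object from an exon table.
make_gene_models <- function(chrom, starts, ends, gene = "G1", tx = "T1") {
  structure(
    list(exons = data.frame(
      chrom = chrom, start = as.integer(starts), end = as.integer(ends),
      strand = "+", gene_name = gene, transcript_id = tx,
      stringsAsFactors = FALSE
    )),
    class = "gene_models"
  )
}

# --- independent CIGAR-expansion oracle -------------------------------------
# Expands a CIGAR base by base into a reference-position -> (op, query
# offset) map, using GenomicAlignments as an independent parser.
oracle_cigar_map <- function(ref_start0, cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  pos <- integer()
  op_at <- character()
  qoff <- integer()
  rcur <- ref_start0
  qcur <- 0L
  for (k in seq_along(ops)) {
    o <- ops[k]
    l <- lens[k]
    if (o %in% c("M", "=", "X")) {
      pos <- c(pos, rcur + 0:(l - 1L))
      op_at <- c(op_at, rep(o, l))
      qoff <- c(qoff, qcur + 0:(l - 1L))
      rcur <- rcur + l
      qcur <- qcur + l
    } else if (o %in% c("D", "N")) {
      pos <- c(pos, rcur + 0:(l - 1L))
      op_at <- c(op_at, rep(o, l))
      qoff <- c(qoff, rep(NA_integer_, l))
      rcur <- rcur + l
    } else if (o %in% c("I", "S")) {
      qcur <- qcur + l
    }
  }
  data.frame(pos = pos, op = op_at, qoff = qoff, stringsAsFactors = FALSE)
}

# Introns from the oracle map: maximal runs of N of length >= min_intron.
oracle_introns <- function(map, min_intron = 20) {
  is_n <- map$op == "N"
  r <- rle(is_n)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_intron
  data.frame(start = map$pos[starts[keep]],
             end = map$pos[ends[keep]] + 1L)
}

# Random spliced-alignment generator for property tests.
random_alignment <- function() {
  n_seg <- sample(1:4, 1)
  ops <- "M"
  lens <- sample(5:60, 1)
  if (n_seg > 1) {
    for (k in seq_len(n_seg - 1)) {
      gap_op <- sample(c("N", "D", "I"), 1)
      ops <- c(ops, gap_op, "M")
      gap_len <- if (gap_op == "N") sample(5:400, 1) else sample(1:10, 1)
      lens <- c(lens, gap_len, sample(5:60, 1))
    }
  }
  if (runif(1) < 0.3) {
    ops <- c("S", ops)
    lens <- c(sample(1:20, 1), lens)
  }
  if (runif(1) < 0.3) {
    ops <- c(ops, "S")
    lens <- c(lens, sample(1:20, 1))
  }
  qlen <- sum(lens[ops %in% c("M", "I", "S")])
  list(
    read_id = "r", chrom = "c",
    ref_start0 = sample(0:5000, 1),
    cigar = paste0(lens, ops, collapse = ""),
    seq = paste(sample(c("A", "C", "G", "T"), qlen, replace = TRUE),
                collapse = ""),
    qual = intToUtf8(sample(2:40, qlen, replace = TRUE) + 33L),
    flag = 0L
  )
}

# --- independent exact-test oracle ------------------------------------------
# Brute-force two-sided Fisher p for table [[a,b],[c,d]]: enumerate every
# table with the same margins, point probabilities from lchoose.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  N <- m + n
  support <- max(0L, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(N, k)
  p <- exp(logp)
  p_obs <- p[support == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# --- independent MEC oracle -------------------------------------------------
# Minimum MEC cost by enumerating every complete haplotype labelling.
oracle_mec_cost <- function(m) {
  S <- ncol(m)
  best <- Inf
  for (code in 0:(2^S - 1)) {
    h <- as.integer(intToBits(code)[1:S])
    cost <- 0
    for (i in seq_len(nrow(m))) {
      d1 <- 0L
      d2 <- 0L
      for (j in seq_len(S)) {
        if (is.na(m[i, j])) next
        if (m[i, j] != h[j]) d1 <- d1 + 1L else d2 <- d2 + 1L
      }
      cost <- cost + min(d1, d2)
    }
    best <- min(best, cost)
  }
  best
}

# Random allele-call matrix built from two true haplotypes + noise/missing.
random_call_matrix <- function(S, n_reads, flip = 0.1, miss = 0.3) {
  h1 <- sample(0:1, S, replace = TRUE)
  m <- matrix(NA_integer_, n_reads, S,
              dimnames = list(sprintf("r%03d", seq_len(n_reads)), NULL))
  for (i in seq_len(n_reads)) {
    h <- if (runif(1) < 0.5) h1 else 1L - h1
    calls <- ifelse(runif(S) < flip, 1L - h, h)
    calls[runif(S) < miss] <- NA_integer_
    if (all(is.na(calls))) calls[sample(S, 1)] <- h[1]
    m[i, ] <- calls
  }
  m
}

# Two-scenario fixture (effect gene + null-twin gene) for pipeline tests.
two_gene_fixture <- function(dir, seed = 1, n_reads = 100, error_rate = 0,
                             ...) {
  eff <- mcardle_like_preset(n_reads = n_reads, error_rate = error_rate,
                             seed = seed)
  nul <- null_twin(mcardle_like_preset(n_reads = n_reads,
                                       error_rate = error_rate, seed = seed))
  nul$chrom <- "chrSIM2"
  nul$gene_name <- "SIMG2"
  simulate_scenario(list(eff, nul), dir, seed = seed)
}
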