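#' Coverage and quality gate at a candidate allele-informative SNV
#'
#' A candidate SNV is usable only when at least `min_reads` spanning reads
#' carry an actual base (A/C/G/T, i.e. not spliced out or deleted) with
#' base quality at or above `min_bq` at its position -- regardless of which
#' allele the base supports. The defaults (10 reads, Q10 = 90% reliability)
#' are the transcriptome-mode settings; amplicon mode raises `min_bq` to 15.
#'
#' @param observations Data.frame from [observations_at()].
#' @param min_reads Minimum number of qualifying observations.
#' @param min_bq Minimum Phred base quality.
#' @return A list: `pass` (logical), `observations` (the qualifying subset),
#'   `n_no_base` (spliced-out/deleted), `n_low_quality`.
#' @export
gate_candidate_snv <- function(observations, min_reads = 10, min_bq = 10) {
  has_base <- !is.na(observations$base) &
    observations$base %in% c("A", "C", "G", "T")
  good_q <- !is.na(observations$phred_q) & observations$phred_q >= min_bq
  keep <- has_base & good_q
  list(
    pass = sum(keep) >= min_reads,
    observations = observations[keep, , drop = FALSE],
    n_no_base = sum(!has_base),
    n_low_quality = sum(has_base & !good_q)
  )
}

#' Partition reads into two alleles at an informative SNV
#'
#' Reads whose gated base matches the reference allele go to the `ref` set,
#' reads matching the alternate allele to the `alt` set. Reads carrying any
#' other base are sequencing errors under a bi-allelic site and are counted
#' in `n_other_base` and excluded, which lowers the effective mis-partition
#' rate below the Phred bound.
#'
#' @param observations Gated observations (see [gate_candidate_snv()]).
#' @param snv A list/one-row data.frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt` (single bases) and optionally `site_id`.
#' @return An `allele_partition`: list with `site_id`, `chrom`, `pos`,
#'   `ref_read_ids`, `alt_read_ids`, `n_other_base`, `n_low_quality`.
#' @export
partition_reads <- function(observations, snv) {
  site_id <- if (!is.null(snv$site_id) && !is.na(snv$site_id)) {
    snv$site_id
  } else {
    sprintf("%s:%d", snv$chrom, snv$pos)
  }
  is_ref <- observations$base == snv$ref
  is_alt <- observations$base == snv$alt
  structure(
    list(
      site_id = site_id, chrom = snv$chrom, pos = snv$pos,
      ref_allele = snv$ref, alt_allele = snv$alt,
      ref_read_ids = observations$read_id[is_ref],
      alt_read_ids = observations$read_id[is_alt],
      n_other_base = sum(!is_ref & !is_alt),
      n_low_quality = 0L
    ),
    class = "allele_partition"
  )
}

#' @export
print.allele_partition <- function(x, ...) {
  cat(sprintf("allele_partition %s: ref %d, alt %d, other-base %d\n",
              x$site_id, length(x$ref_read_ids), length(x$alt_read_ids),
              x$n_other_base))
  invisible(x)
}

#' Use a splicing variant as its own allele-informative site
#'
#' An exonic SNV splicing variant (or an intronic one expressed through
#' intron-retention reads) can itself separate the two alleles. Behaves as
#' [gate_candidate_snv()] followed by [partition_reads()]; returns `NULL`
#' when the variant is not an SNV or the gate fails (e.g. an intronic
#' variant spliced out of every read).
#'
#' @param variant One row of [read_splicing_variants()] output.
#' @param observations Observations at the variant's own position.
#' @param min_reads,min_bq Gate parameters, as in [gate_candidate_snv()].
#' @return An `allele_partition`, or `NULL`.
#' @export
self_informative_site <- function(variant, observations, min_reads = 10,
                                  min_bq = 10) {
  if (nchar(variant$ref) != 1L || nchar(variant$alt) != 1L) return(NULL)
  gate <- gate_candidate_snv(observations, min_reads = min_reads,
                             min_bq = min_bq)
  if (!gate$pass) return(NULL)
  partition_reads(
    gate$observations,
    list(chrom = variant$chrom, pos = variant$pos,
         ref = variant$ref, alt = variant$alt,
         site_id = sprintf("%s:%d", variant$chrom, variant$pos))
  )
}

# MEC cost of haplotype vector h (0/1) against call matrix m (reads x sites,
# entries 0/1/NA). Missing calls contribute no cost.
mec_cost_of <- function(m, h) {
  hm <- matrix(h, nrow = nrow(m), ncol = length(h), byrow = TRUE)
  d1 <- rowSums(m != hm, na.rm = TRUE)
  cov <- rowSums(!is.na(m))
  sum(pmin(d1, cov - d1))
}

# Coordinate-descent refinement of h to a local MEC minimum; deterministic
# sweep order, first-site label fixed by complementing when needed.
refine_h <- function(m, h) {
  repeat {
    improved <- FALSE
    cost <- mec_cost_of(m, h)
    for (s in seq_along(h)) {
      h2 <- h
      h2[s] <- 1L - h2[s]
      c2 <- mec_cost_of(m, h2)
      if (c2 < cost) {
        h <- h2
        cost <- c2
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  h
}

#' Phase allele-informative sites by minimum error correction
#'
#' Given per-read allele calls over `S >= 2` sites (0 = reference allele,
#' 1 = alternate, `NA` = not covered or not gated), finds the haplotype
#' vector minimizing the minimum-error-correction (MEC) cost: the total
#' number of calls that must be flipped for every read to match one of the
#' two complementary haplotypes. The label of the first site is fixed at 0,
#' so haplotype 2 is always the complement. Exhaustive search over the
#' `2^(S-1)` phasings is used for `S <= s_max`; beyond that, deterministic
#' greedy site-by-site extension with coordinate-descent refinement and
#' read-row restarts. Reads are assigned to the nearer haplotype by Hamming
#' distance over their covered sites, and left unassigned on ties.
#'
#' @param m Integer matrix (reads x sites) with entries 0/1/`NA`; row names
#'   are read ids. Columns must be in genomic order.
#' @param positions Optional site positions (defaults to column names or
#'   indices).
#' @param method `"auto"` (default), `"exhaustive"`, or `"greedy"`.
#' @param s_max Largest `S` phased exhaustively under `"auto"`.
#' @return A `phased_block`: list with `sites`, `h` (haplotype-1 vector),
#'   `read_assignment` (named vector in `{1, 2, NA}`), `mec_cost`, `method`.
#' @export
phase_informative_sites <- function(m, positions = NULL,
                                    method = c("auto", "exhaustive", "greedy"),
                                    s_max = 16) {
  method <- match.arg(method)
  S <- ncol(m)
  if (is.null(S) || S < 2L) {
    stop("phasing requires at least two sites; use partition_reads for one")
  }
  m <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  if (is.null(positions)) {
    positions <- if (!is.null(colnames(m))) colnames(m) else seq_len(S)
  }
  if (method == "auto") method <- if (S <= s_max) "exhaustive" else "greedy"

  if (method == "exhaustive") {
    best_h <- NULL
    best_cost <- Inf
    for (code in 0:(2^(S - 1L) - 1L)) {
      h <- c(0L, as.integer(bitwAnd(bitwShiftR(code, 0:(S - 2L)), 1L)))
      cost <- mec_cost_of(m, h)
      if (cost < best_cost) {
        best_cost <- cost
        best_h <- h
      }
    }
    h <- best_h
  } else {
    # greedy extension in genomic (column) order
    h <- 0L
    for (s in 2:S) {
      cand0 <- c(h, 0L)
      cand1 <- c(h, 1L)
      ms <- m[, seq_len(s), drop = FALSE]
      h <- if (mec_cost_of(ms, cand1) < mec_cost_of(ms, cand0)) cand1 else cand0
    }
    h <- refine_h(m, h)
    # restarts seeded from each distinct observed read pattern
    seeds <- unique(lapply(seq_len(nrow(m)), function(i) {
      r <- m[i, ]
      r[is.na(r)] <- 0L
      if (r[1] == 1L) r <- 1L - r
      r
    }))
    for (seed in seeds) {
      h2 <- refine_h(m, as.integer(seed))
      if (mec_cost_of(m, h2) < mec_cost_of(m, h)) h <- h2
    }
  }
  if (h[1] == 1L) h <- 1L - h

  hm <- matrix(h, nrow = nrow(m), ncol = S, byrow = TRUE)
  d1 <- rowSums(m != hm, na.rm = TRUE)
  cov <- rowSums(!is.na(m))
  d2 <- cov - d1
  assign <- ifelse(d1 < d2, 1L, ifelse(d2 < d1, 2L, NA_integer_))
  names(assign) <- rownames(m)
  structure(
    list(sites = positions, h = h,
         read_assignment = assign,
         mec_cost = sum(pmin(d1, d2)),
         method = method),
    class = "phased_block"
  )
}

#' @export
print.phased_block <- function(x, ...) {
  cat(sprintf(
    "phased_block over %d sites (%s): h1 = %s, MEC cost %d, %d/%d reads assigned\n",
    length(x$sites), x$method, paste(x$h, collapse = ""), x$mec_cost,
    sum(!is.na(x$read_assignment)), length(x$read_assignment)))
  invisible(x)
}

# Build the reads-x-sites allele-call matrix feeding the phaser. `sites` is
# a data.frame with chrom/pos/ref/alt (1-based pos), already gated;
# observations are taken per site at BQ >= min_bq.
allele_call_matrix <- function(reads, sites, min_bq = 10) {
  sites <- sites[order(sites$pos), , drop = FALSE]
  m <- matrix(NA_integer_, nrow = nrow(reads), ncol = nrow(sites),
              dimnames = list(reads$read_id,
                              sprintf("%s:%d", sites$chrom, sites$pos)))
  for (j in seq_len(nrow(sites))) {
    obs <- observations_at(reads, sites$pos[j] - 1L)
    ok <- !is.na(obs$base) & !is.na(obs$phred_q) & obs$phred_q >= min_bq
    obs <- obs[ok, , drop = FALSE]
    call <- ifelse(obs$base == sites$ref[j], 0L,
                   ifelse(obs$base == sites$alt[j], 1L, NA_integer_))
    m[match(obs$read_id, rownames(m)), j] <- call
  }
  m[rowSums(!is.na(m)) > 0L, , drop = FALSE]
}

# Convert a phased block into an allele_partition. Haplotype orientation:
# the haplotype carrying h = 0 ("reference allele") at `orient_site` (index
# into block$sites; default the first site) is reported as the ref set.
partition_from_block <- function(block, orient_site = 1L) {
  flip <- block$h[orient_site] == 1L
  hap_ref <- if (flip) 2L else 1L
  a <- block$read_assignment
  structure(
    list(
      site_id = paste0("hap:", paste(block$sites, collapse = "-")),
      chrom = NA_character_, pos = NA_integer_,
      ref_allele = NA_character_, alt_allele = NA_character_,
      ref_read_ids = names(a)[!is.na(a) & a == hap_ref],
      alt_read_ids = names(a)[!is.na(a) & a != hap_ref],
      n_other_base = 0L,
      n_low_quality = 0L
    ),
    class = "allele_partition"
  )
}

#' Write phased genotypes for a block as VCF records
#'
#' Emits one VCF 4.2 record per phased site with a phased genotype
#' (`0|1` when haplotype 1 carries the reference allele at the site,
#' `1|0` otherwise). Single-site separations carry no haplotype
#' information and produce no phased VCF.
#'
#' @param block A `phased_block`.
#' @param variants Data.frame with one row per block site (matched by
#'   `chrom:pos` against `block$sites`): columns `chrom`, `pos`, `ref`,
#'   `alt`, optionally `id` and `info`.
#' @param path Output path; a `.gz` suffix produces a bgzip-compressed file.
#' @return Invisibly, the path.
#' @export
emit_phased_vcf <- function(block, variants, path) {
  key <- sprintf("%s:%d", variants$chrom, variants$pos)
  idx <- match(block$sites, key)
  if (anyNA(idx)) {
    stop("internal consistency error: phased site(s) ",
         paste(block$sites[is.na(idx)], collapse = ", "),
         " have no matching input variant")
  }
  v <- variants[idx, , drop = FALSE]
  gt <- ifelse(block$h == 0L, "0|1", "1|0")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"),
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
            v$chrom, v$pos,
            if (!is.null(v$id)) ifelse(is.na(v$id), ".", v$id) else ".",
            v$ref, v$alt,
            if (!is.null(v$info)) ifelse(is.na(v$info), ".", v$info) else ".",
            gt)
  )
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".vcf")
    writeLines(lines, tmp)
    Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
    unlink(tmp)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}
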