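#' Define a simulation scenario
#'
#' A scenario describes one gene on its own reference sequence: exon/intron
#' structure, a heterozygous splicing variant (with SpliceAI-style
#' sub-scores), heterozygous allele-informative SNVs, the isoform mixture
#' each allele expresses, and the read/error model. All alternate alleles
#' lie on haplotype 1 (the "variant allele"); haplotype 2 carries the
#' reference base everywhere. The seed fully determines the emitted
#' fixture.
#'
#' @param chrom Reference name for the gene's sequence.
#' @param gene_name Gene symbol used in the GTF and SpliceAI annotation.
#' @param gene_start 1-based start of exon 1.
#' @param exon_lengths,intron_lengths Integer vectors (introns =
#'   exons - 1).
#' @param isoforms Named list; each element is a list with `exons`
#'   (indices of included exons) and `retained_introns` (indices of introns
#'   aligned through rather than spliced).
#' @param annotated Names of isoforms to include as transcripts in the
#'   emitted GTF.
#' @param mixtures 2 x K matrix of isoform probabilities (rows: allele 1 =
#'   variant allele, allele 2 = wild type; columns named by isoform). Rows
#'   must sum to 1.
#' @param variant_exon,variant_offset The splicing variant sits
#'   `variant_offset` bases upstream (5') of exon `variant_exon`'s first
#'   base -- an intronic acceptor-region position for positive offsets; 0
#'   places it on the exon's first base.
#' @param variant_ds,variant_dp SpliceAI sub-scores (AG, AL, DG, DL) and
#'   offsets for the variant's annotation.
#' @param snv_exons,snv_frac Informative SNVs are placed at fraction
#'   `snv_frac` into each listed exon.
#' @param n_reads Reads per allele (length 1 or 2).
#' @param error_rate Per-base substitution error probability.
#' @param q_mean,q_sd,q_range Phred quality model: discretized normal,
#'   clipped to `q_range`.
#' @param seed Integer seed.
#' @return A `sim_scenario` list with computed exon coordinates
#'   (`exon_start`, `exon_end`, 1-based inclusive) and variant/SNV
#'   positions.
#' @export
sim_scenario <- function(chrom = "chrSIM", gene_name = "SIMG1",
                         gene_start = 1001L,
                         exon_lengths = rep(150L, 14),
                         intron_lengths = rep(300L, 13),
                         isoforms = list(canonical = list(
                           exons = seq_along(exon_lengths),
                           retained_introns = integer()
                         )),
                         annotated = names(isoforms)[1],
                         mixtures = matrix(1, 2, 1,
                                           dimnames = list(NULL, names(isoforms)[1])),
                         variant_exon = 2L, variant_offset = 3L,
                         variant_ds = c(0.98, 0.98, 0, 0),
                         variant_dp = c(-3L, 3L, 0L, 0L),
                         snv_exons = 1L, snv_frac = 0.5,
                         n_reads = 100L, error_rate = 0.05,
                         q_mean = 20, q_sd = 5, q_range = c(2L, 40L),
                         seed = 1L) {
  n_ex <- length(exon_lengths)
  stopifnot(length(intron_lengths) == n_ex - 1L)
  exon_start <- integer(n_ex)
  exon_end <- integer(n_ex)
  cur <- gene_start
  for (i in seq_len(n_ex)) {
    exon_start[i] <- cur
    exon_end[i] <- cur + exon_lengths[i] - 1L
    if (i < n_ex) cur <- exon_end[i] + intron_lengths[i] + 1L
  }
  mixtures <- as.matrix(mixtures)
  if (is.null(colnames(mixtures)) || !all(colnames(mixtures) %in% names(isoforms))) {
    stop("mixture columns must name defined isoforms")
  }
  if (any(abs(rowSums(mixtures) - 1) > 1e-8)) {
    stop("mixture rows must sum to 1")
  }
  for (iso in isoforms) {
    if (any(iso$exons < 1 | iso$exons > n_ex) ||
        any(iso$retained_introns < 1 | iso$retained_introns > n_ex - 1L)) {
      stop("isoform references an undefined exon or intron")
    }
  }
  variant_pos <- exon_start[variant_exon] - variant_offset
  snv_pos <- vapply(snv_exons, function(e) {
    exon_start[e] + as.integer(floor(snv_frac * (exon_lengths[e] - 1L)))
  }, integer(1))
  if (any(snv_pos < gene_start | snv_pos > exon_end[n_ex])) {
    stop("informative SNV positions must lie inside the gene")
  }
  if (length(n_reads) == 1L) n_reads <- rep(n_reads, 2L)
  structure(
    list(chrom = chrom, gene_name = gene_name,
         exon_start = exon_start, exon_end = exon_end,
         gene_start = gene_start, gene_end = exon_end[n_ex],
         isoforms = isoforms, annotated = annotated, mixtures = mixtures,
         variant_pos = variant_pos, variant_ds = variant_ds,
         variant_dp = variant_dp, snv_pos = snv_pos,
         n_reads = n_reads, error_rate = error_rate,
         q_mean = q_mean, q_sd = q_sd, q_range = q_range, seed = seed),
    class = "sim_scenario"
  )
}

#' McArdle-like preset scenario
#'
#' A 14-exon muscle-gene-like scenario with an intronic acceptor-region
#' variant 3 bp upstream of exon 13. The variant allele expresses a mixture
#' of exon-13 skipping (0.22), retention of intron 12 (0.08), retention of
#' introns 12 and 13 (0.02) and canonical transcript (0.68); the wild-type
#' allele is near-canonical (0.97/0.01/0.01/0.01). Two exonic informative
#' SNVs (exons 3 and 8) phase with the variant.
#'
#' @param n_reads Reads per allele (default 100).
#' @param error_rate Per-base substitution rate (default 0.05).
#' @param seed Integer seed.
#' @return A `sim_scenario`.
#' @export
mcardle_like_preset <- function(n_reads = 100L, error_rate = 0.05, seed = 1L) {
  n_ex <- 14L
  isoforms <- list(
    canonical = list(exons = 1:n_ex, retained_introns = integer()),
    skip13 = list(exons = setdiff(1:n_ex, 13L), retained_introns = integer()),
    ir12 = list(exons = 1:n_ex, retained_introns = 12L),
    ir12_13 = list(exons = 1:n_ex, retained_introns = c(12L, 13L))
  )
  mixtures <- rbind(
    allele1 = c(canonical = 0.68, skip13 = 0.22, ir12 = 0.08, ir12_13 = 0.02),
    allele2 = c(canonical = 0.97, skip13 = 0.01, ir12 = 0.01, ir12_13 = 0.01)
  )
  sim_scenario(
    chrom = "chrSIM", gene_name = "SIMG1",
    exon_lengths = rep(150L, n_ex), intron_lengths = rep(300L, n_ex - 1L),
    isoforms = isoforms, annotated = c("canonical", "skip13"),
    mixtures = mixtures,
    variant_exon = 13L, variant_offset = 3L,
    variant_ds = c(0.98, 0.98, 0, 0), variant_dp = c(-3L, 3L, 0L, 0L),
    snv_exons = c(3L, 8L), snv_frac = 0.5,
    n_reads = n_reads, error_rate = error_rate, seed = seed
  )
}

#' Null twin of a scenario
#'
#' Replaces both allele mixtures by the wild-type (allele 2) mixture: the
#' null hypothesis that the variant has no splicing effect, under which
#' both alleles express the same isoform distribution.
#'
#' @param scenario A `sim_scenario`.
#' @return The scenario with identical mixtures on both alleles.
#' @export
null_twin <- function(scenario) {
  scenario$mixtures[1, ] <- scenario$mixtures[2, ]
  scenario
}

# Genomic M/N blocks of one isoform: data.frame(op, start0, len), gaps
# (skipped exons and spliced introns) merged into single N runs.
iso_blocks <- function(scn, iso_name) {
  iso <- scn$isoforms[[iso_name]]
  first <- min(iso$exons)
  last <- max(iso$exons)
  seg <- list()
  add <- function(s0, len, m) {
    n <- length(seg)
    if (n > 0L && !m && !seg[[n]]$m) {
      seg[[n]]$len <<- seg[[n]]$len + len
    } else {
      seg[[n + 1L]] <<- list(s0 = s0, len = len, m = m)
    }
  }
  for (j in first:last) {
    add(scn$exon_start[j] - 1L, scn$exon_end[j] - scn$exon_start[j] + 1L,
        j %in% iso$exons)
    if (j < last) {
      add(scn$exon_end[j], scn$exon_start[j + 1L] - scn$exon_end[j] - 1L,
          j %in% iso$retained_introns)
    }
  }
  data.frame(
    op = vapply(seg, function(s) if (s$m) "M" else "N", character(1)),
    start0 = vapply(seg, function(s) s$s0, integer(1)),
    len = vapply(seg, function(s) s$len, integer(1)),
    stringsAsFactors = FALSE
  )
}

# Variant table of a scenario: splicing variant + informative SNVs, with
# ref bases read off the reference sequence and deterministic transition
# alternates. Haplotype 1 carries every alternate allele.
scenario_variants <- function(scn, ref_chars) {
  pos <- c(scn$variant_pos, scn$snv_pos)
  ref <- ref_chars[pos - scn$gene_start + 1L]
  alt <- c(A = "G", C = "T", G = "A", T = "C")[ref]
  data.frame(
    chrom = scn$chrom, pos = pos, ref = unname(ref), alt = unname(alt),
    is_splice_variant = c(TRUE, rep(FALSE, length(scn$snv_pos))),
    stringsAsFactors = FALSE
  )
}

# Generate reads for one scenario using the current RNG state. Returns a
# list with sam record lines, truth rows and the variant table.
gen_scenario_data <- function(scn) {
  glen <- scn$gene_end - scn$gene_start + 1L
  ref_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  vars <- scenario_variants(scn, ref_chars)
  hap <- list(ref_chars, ref_chars)
  hap[[1]][vars$pos - scn$gene_start + 1L] <- vars$alt

  iso_names <- colnames(scn$mixtures)
  blocks <- lapply(setNames(iso_names, iso_names),
                   function(n) iso_blocks(scn, n))
  m_pos0 <- lapply(blocks, function(b) {
    mb <- b[b$op == "M", , drop = FALSE]
    unlist(lapply(seq_len(nrow(mb)), function(i) {
      mb$start0[i] + seq_len(mb$len[i]) - 1L
    }))
  })
  cigars <- vapply(blocks, function(b) {
    paste0(b$len, b$op, collapse = "")
  }, character(1))
  starts0 <- vapply(blocks, function(b) b$start0[1], integer(1))

  other <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
  sam <- character()
  truth <- list()
  for (allele in 1:2) {
    n <- scn$n_reads[allele]
    iso_draw <- iso_names[sample.int(length(iso_names), n, replace = TRUE,
                                     prob = scn$mixtures[allele, ])]
    for (r in seq_len(n)) {
      iso <- iso_draw[r]
      pos0 <- m_pos0[[iso]]
      bases <- hap[[allele]][pos0 - scn$gene_start + 2L]
      L <- length(bases)
      err <- which(runif(L) < scn$error_rate)
      if (length(err)) {
        bases[err] <- vapply(bases[err], function(b) {
          other[[b]][sample.int(3L, 1L)]
        }, character(1))
      }
      q <- pmin(pmax(as.integer(round(rnorm(L, scn$q_mean, scn$q_sd))),
                     scn$q_range[1]), scn$q_range[2])
      rid <- sprintf("%s_a%d_r%04d", scn$gene_name, allele, r)
      sam[length(sam) + 1L] <- paste(
        rid, 0L, scn$chrom, starts0[iso] + 1L, 60L, cigars[iso],
        "*", 0L, 0L, paste(bases, collapse = ""), intToUtf8(q + 33L),
        sep = "\t"
      )
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = rid, allele = allele, isoform = iso,
        stringsAsFactors = FALSE
      )
    }
  }
  list(sam = sam, truth = do.call(rbind, truth), variants = vars)
}

scenario_variant_id <- function(scn, vars) {
  v <- vars[vars$is_splice_variant, ]
  sprintf("%s:%d%s>%s", v$chrom, v$pos, v$ref, v$alt)
}

write_sim_vcf <- function(records, path, spliceai = NULL) {
  info <- rep(".", nrow(records))
  if (!is.null(spliceai)) info <- spliceai
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SpliceAI,Number=.,Type=String,Description=\"SpliceAI scores: ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT\t0/1",
            records$chrom, records$pos, records$ref, records$alt, info)
  )
  writeLines(lines, path)
  invisible(path)
}

write_sim_gtf <- function(scenarios, path) {
  lines <- character()
  for (scn in scenarios) {
    for (tx in scn$annotated) {
      iso <- scn$isoforms[[tx]]
      tx_id <- paste0(scn$gene_name, ".", tx)
      attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s";',
        scn$gene_name, tx_id, scn$gene_name
      )
      for (j in sort(iso$exons)) {
        lines[length(lines) + 1L] <- paste(
          scn$chrom, "sim", "exon", scn$exon_start[j], scn$exon_end[j],
          ".", "+", ".", attrs, sep = "\t"
        )
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate one or more scenarios into a fixture directory
#'
#' Deterministically (under `seed`) emits a coordinate-sorted indexed BAM
#' whose CIGARs are constructed from each read's true isoform (M across
#' exons and retained introns, N across spliced introns), with bases copied
#' from the read's haplotype under i.i.d. substitution errors and Phred
#' qualities from the quality model; a splicing-variant VCF with
#' SpliceAI-style annotation; an informative-SNV VCF; a GTF of the
#' annotated transcripts; and a per-read truth table.
#'
#' @param scenarios A `sim_scenario` or list of them (distinct `chrom` /
#'   `gene_name` each).
#' @param dir Output directory (created if needed).
#' @param seed Seed for all randomness; defaults to the first scenario's
#'   `seed` field.
#' @return A list with paths (`bam`, `splicing_vcf`, `snv_vcf`, `gtf`,
#'   `truth_path`), the `truth` data.frame, per-variant
#'   `expected_significant` flags, and the scenario list.
#' @export
simulate_scenario <- function(scenarios, dir, seed = NULL) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  if (is.null(seed)) seed <- scenarios[[1]]$seed
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  gens <- lapply(scenarios, gen_scenario_data)

  # SAM: header for every scenario chromosome, records in coordinate order
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           vapply(scenarios, function(s) {
             sprintf("@SQ\tSN:%s\tLN:%d", s$chrom, s$gene_end + 1000L)
           }, character(1)))
  rec <- unlist(lapply(gens, function(g) g$sam))
  pos <- as.integer(vapply(strsplit(rec, "\t", fixed = TRUE), `[`, "", 4L))
  chr <- vapply(strsplit(rec, "\t", fixed = TRUE), `[`, "", 3L)
  chr_rank <- match(chr, vapply(scenarios, function(s) s$chrom, character(1)))
  rec <- rec[order(chr_rank, pos)]
  sam_path <- file.path(dir, "reads.sam")
  writeLines(c(hdr, rec), sam_path)
  bam_path <- suppressMessages(
    Rsamtools::asBam(sam_path, file.path(dir, "reads"), overwrite = TRUE,
                     indexDestination = TRUE)
  )
  unlink(sam_path)

  all_vars <- do.call(rbind, lapply(gens, function(g) g$variants))
  sv <- all_vars[all_vars$is_splice_variant, , drop = FALSE]
  spliceai <- vapply(seq_along(gens), function(i) {
    scn <- scenarios[[i]]
    v <- gens[[i]]$variants[gens[[i]]$variants$is_splice_variant, ]
    sprintf("SpliceAI=%s", format_spliceai_annotation(data.frame(
      allele = v$alt, gene_symbol = scn$gene_name,
      ds_ag = scn$variant_ds[1], ds_al = scn$variant_ds[2],
      ds_dg = scn$variant_ds[3], ds_dl = scn$variant_ds[4],
      dp_ag = scn$variant_dp[1], dp_al = scn$variant_dp[2],
      dp_dg = scn$variant_dp[3], dp_dl = scn$variant_dp[4],
      stringsAsFactors = FALSE
    )))
  }, character(1))
  splicing_vcf <- file.path(dir, "splice_variants.vcf")
  write_sim_vcf(sv, splicing_vcf, spliceai = spliceai)

  snvs <- all_vars[!all_vars$is_splice_variant, , drop = FALSE]
  snv_vcf <- file.path(dir, "informative_snvs.vcf")
  write_sim_vcf(snvs, snv_vcf)

  gtf <- file.path(dir, "gene_models.gtf")
  write_sim_gtf(scenarios, gtf)

  truth <- do.call(rbind, lapply(gens, function(g) g$truth))
  truth_path <- file.path(dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  expected <- vapply(seq_along(gens), function(i) {
    m <- scenarios[[i]]$mixtures
    !isTRUE(all.equal(unname(m[1, ]), unname(m[2, ])))
  }, logical(1))
  names(expected) <- vapply(seq_along(gens), function(i) {
    scenario_variant_id(scenarios[[i]], gens[[i]]$variants)
  }, character(1))

  list(dir = dir, bam = bam_path, splicing_vcf = splicing_vcf,
       snv_vcf = snv_vcf, gtf = gtf, truth = truth,
       truth_path = truth_path, expected_significant = expected,
       scenarios = scenarios)
}
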