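#' Pipeline configuration
#'
#' Defaults reproduce the recommended settings: delta-score threshold 0.5,
#' coverage gate of 10 reads, base quality 10 (amplicon mode: 15), isoform
#' support 4, family-wise alpha 0.05. Amplicon mode additionally skips the
#' delta-threshold filter, since amplicon variant lists are user-curated.
#'
#' @param delta_threshold Minimum SpliceAI delta score.
#' @param min_informative_reads Coverage gate at candidate SNVs.
#' @param min_base_quality Phred gate at candidate SNVs (`NULL`: 10 in
#'   transcriptome mode, 15 in amplicon mode).
#' @param min_isoform_support Minimum reads per isoform group.
#' @param alpha Significance level on corrected p-values.
#' @param s_max Largest block phased exhaustively.
#' @param workers Parallel workers (one task per splicing variant).
#' @param prefix Output file prefix.
#' @param mode `"transcriptome"` or `"amplicon"`.
#' @param min_intron Minimum N-run length counted as an intron (bp).
#' @param single_exon_overlap Reciprocal-overlap fraction for single-exon
#'   grouping.
#' @param fuzz Junction-matching tolerance (bp) for annotation labels.
#' @param splice_region_only Restrict variants to positional splice
#'   regions.
#' @param branch_window Optional branch-point window, e.g. `c(18, 44)`.
#' @param pairs_level_correction Bonferroni over pairs instead of unique
#'   variants.
#' @param write_bams,write_isoform_tables,write_phased_vcf Toggle the
#'   per-pair file outputs (the summary TSV is always written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(delta_threshold = 0.5,
                            min_informative_reads = 10,
                            min_base_quality = NULL,
                            min_isoform_support = 4,
                            alpha = 0.05,
                            s_max = 16,
                            workers = 1,
                            prefix = "asi",
                            mode = c("transcriptome", "amplicon"),
                            min_intron = 20,
                            single_exon_overlap = 0.8,
                            fuzz = 0,
                            splice_region_only = FALSE,
                            branch_window = NULL,
                            pairs_level_correction = FALSE,
                            write_bams = TRUE,
                            write_isoform_tables = TRUE,
                            write_phased_vcf = TRUE) {
  mode <- match.arg(mode)
  if (is.null(min_base_quality)) {
    min_base_quality <- if (mode == "amplicon") 15 else 10
  }
  stopifnot(delta_threshold >= 0, delta_threshold <= 1,
            min_informative_reads >= 1, min_base_quality >= 0,
            min_isoform_support >= 1, alpha > 0, alpha < 1, workers >= 1)
  structure(
    list(delta_threshold = delta_threshold,
         min_informative_reads = min_informative_reads,
         min_base_quality = min_base_quality,
         min_isoform_support = min_isoform_support,
         alpha = alpha, s_max = s_max, workers = workers, prefix = prefix,
         mode = mode, min_intron = min_intron,
         single_exon_overlap = single_exon_overlap, fuzz = fuzz,
         splice_region_only = splice_region_only,
         branch_window = branch_window,
         pairs_level_correction = pairs_level_correction,
         write_bams = write_bams,
         write_isoform_tables = write_isoform_tables,
         write_phased_vcf = write_phased_vcf),
    class = "pipeline_config"
  )
}

# Process one selected splicing variant end to end (no file output here,
# so that workers stay side-effect free and merging is deterministic).
process_variant <- function(v, bam, snvs, gm, cfg) {
  logs <- character()
  res <- list(variant_id = v$variant_id, has_site = FALSE, pairs = list(),
              logs = logs)
  region <- suppressWarnings(derive_target_region(v, gm))
  reads <- select_spanning_reads(bam, v$chrom, v$pos)
  reads <- remove_chimeric_reads(reads, region)
  if (!nrow(reads)) {
    res$logs <- "no_spanning_reads"
    return(res)
  }

  cand <- snvs[snvs$chrom == v$chrom &
                 snvs$pos - 1L >= region$start &
                 snvs$pos - 1L < region$end, , drop = FALSE]
  cand <- cand[cand$pos != v$pos, , drop = FALSE]   # self site handled below

  site_rows <- list()   # gated sites: chrom/pos/ref/alt/site_id/partition
  for (i in seq_len(nrow(cand))) {
    obs <- suppressWarnings(observations_at(reads, cand$pos[i] - 1L))
    gate <- gate_candidate_snv(obs, min_reads = cfg$min_informative_reads,
                               min_bq = cfg$min_base_quality)
    if (!gate$pass) {
      logs <- c(logs, sprintf("gate_fail:%s", cand$site_id[i]))
      next
    }
    part <- partition_reads(gate$observations, cand[i, ])
    site_rows[[length(site_rows) + 1L]] <- list(
      chrom = cand$chrom[i], pos = cand$pos[i],
      ref = cand$ref[i], alt = cand$alt[i],
      site_id = cand$site_id[i], partition = part, self = FALSE
    )
  }
  if (v$is_snv) {
    obs <- suppressWarnings(observations_at(reads, v$pos - 1L))
    part <- self_informative_site(v, obs,
                                  min_reads = cfg$min_informative_reads,
                                  min_bq = cfg$min_base_quality)
    if (!is.null(part)) {
      site_rows[[length(site_rows) + 1L]] <- list(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        site_id = part$site_id, partition = part, self = TRUE
      )
    } else {
      logs <- c(logs, "self_site_unusable")
    }
  }
  if (!length(site_rows)) {
    res$logs <- c(logs, "no_informative_site")
    return(res)
  }
  res$has_site <- TRUE

  pairs <- lapply(site_rows, function(s) {
    list(site_id = s$site_id, partition = s$partition,
         haplotype_info = "", block = NULL, sites = NULL)
  })

  # phased-block pair when two or more sites gate
  if (length(site_rows) >= 2L) {
    sites <- do.call(rbind, lapply(site_rows, function(s) {
      data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                 self = s$self, stringsAsFactors = FALSE)
    }))
    sites <- sites[order(sites$pos), , drop = FALSE]
    m <- allele_call_matrix(reads, sites, min_bq = cfg$min_base_quality)
    if (nrow(m) > 0L) {
      block <- phase_informative_sites(m, s_max = cfg$s_max)
      orient <- if (any(sites$self)) which(sites$self)[1] else 1L
      part <- partition_from_block(block, orient_site = orient)
      gt <- ifelse(block$h == 0L, "0|1", "1|0")
      pairs[[length(pairs) + 1L]] <- list(
        site_id = part$site_id, partition = part,
        haplotype_info = paste(sprintf("%s=%s", block$sites, gt),
                               collapse = ";"),
        block = block, sites = sites
      )
    }
  }

  out_pairs <- list()
  for (p in pairs) {
    part <- p$partition
    pooled <- c(part$ref_read_ids, part$alt_read_ids)
    preads <- reads[reads$read_id %in% pooled, , drop = FALSE]
    iso <- collapse_isoforms(preads, min_support = cfg$min_isoform_support,
                             min_intron = cfg$min_intron,
                             single_exon_overlap = cfg$single_exon_overlap)
    if (!length(iso$groups)) {
      logs <- c(logs, sprintf("no_supported_isoform:%s", p$site_id))
      next
    }
    iso <- match_annotation(iso, gm, fuzz = cfg$fuzz)
    usage <- quantify_per_allele(iso, part)
    counts <- as.matrix(usage[, c("ref_count", "alt_count")])
    rownames(counts) <- usage$label
    if (any(colSums(counts) < 1)) {
      logs <- c(logs, sprintf("allele_without_reads:%s", p$site_id))
      next
    }
    pv <- per_isoform_exact_test(counts)
    rec <- summarize_pair(v$variant_id, p$site_id, pv, part,
                          haplotype_info = p$haplotype_info)
    out_pairs[[length(out_pairs) + 1L]] <- list(
      record = rec, usage = usage, partition = part,
      block = p$block, sites = p$sites
    )
  }
  res$pairs <- out_pairs
  res$logs <- logs
  res
}

#' Run the allele-level isoform-usage pipeline
#'
#' Per splicing variant: derive the target region, select spanning primary
#' reads, remove chimeric reads, gate candidate allele-informative SNVs,
#' partition reads per site (and phase multi-SNV reads into a haplotype
#' block), collapse reads into supported isoform groups, count per allele,
#' and test per-isoform usage with two-sided exact tests. Minimum
#' p-values are then Bonferroni-corrected across the unique splicing
#' variants tested.
#'
#' @param bam Coordinate-sorted, indexed BAM of splice-aware-aligned long
#'   reads.
#' @param splicing_vcf VCF of heterozygous putative splicing variants with
#'   SpliceAI annotations.
#' @param snv_vcf VCF of heterozygous candidate allele-informative SNVs.
#' @param gtf Gene models (GTF path or `gene_models` object).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return An `asi_run` object: `summary` (one row per tested pair, with
#'   corrected p-values and significance flags), `funnel` (variants in /
#'   with site / tested / significant), `logs`, `config`, `paths`.
#' @export
run_pipeline <- function(bam, splicing_vcf, snv_vcf, gtf, out_dir,
                         config = pipeline_config()) {
  for (f in c(bam, splicing_vcf, snv_vcf)) {
    if (!file.exists(f)) stop("input not found: ", f)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- as_gene_models(gtf)
  variants <- read_splicing_variants(splicing_vcf)
  snvs <- read_informative_snvs(snv_vcf)

  selected <- if (config$mode == "amplicon") {
    v <- variants[variants$het &
                    (is.na(variants$filter) |
                       variants$filter %in% c("PASS", ".")), , drop = FALSE]
    rownames(v) <- NULL
    v
  } else {
    select_splicing_variants(variants,
                             delta_threshold = config$delta_threshold,
                             splice_region_only = config$splice_region_only,
                             gene_models = gm,
                             branch_window = config$branch_window)
  }

  worker <- function(i) {
    process_variant(selected[i, ], bam, snvs, gm, config)
  }
  results <- if (config$workers > 1L && nrow(selected) > 1L) {
    parallel::mclapply(seq_len(nrow(selected)), worker,
                       mc.cores = config$workers)
  } else {
    lapply(seq_len(nrow(selected)), worker)
  }

  pair_records <- unlist(lapply(results, function(r) {
    lapply(r$pairs, function(p) p$record)
  }), recursive = FALSE)
  records <- if (length(pair_records)) do.call(rbind, pair_records) else NULL
  empty_summary <- data.frame(
    splicing_variant = character(), allele_informative_site = character(),
    ref_coverage = integer(), alt_coverage = integer(), min_p = numeric(),
    corrected_p = numeric(), haplotype_info = character(),
    significant = logical(), stringsAsFactors = FALSE
  )
  tested_variants <- unique(unlist(lapply(results, function(r) {
    if (length(r$pairs)) r$variant_id else NULL
  })))
  if (!is.null(records) && nrow(records)) {
    records <- bonferroni_correct(records, length(tested_variants),
                                  alpha = config$alpha,
                                  pairs_level = config$pairs_level_correction)
    records <- records[order(records$splicing_variant,
                             records$allele_informative_site), , drop = FALSE]
    rownames(records) <- NULL
  } else {
    records <- empty_summary
  }

  funnel <- c(
    variants_in = nrow(selected),
    variants_with_site = sum(vapply(results, function(r) r$has_site,
                                    logical(1))),
    variants_tested = length(tested_variants),
    variants_significant = length(unique(
      records$splicing_variant[records$significant]
    ))
  )

  summary_path <- file.path(
    out_dir, paste0(config$prefix, "_minpvalue005_spvar_corrected.tsv")
  )
  write.table(records[, c("splicing_variant", "allele_informative_site",
                          "ref_coverage", "alt_coverage", "min_p",
                          "corrected_p", "haplotype_info")],
              summary_path, sep = "\t", quote = FALSE, row.names = FALSE)

  # per-pair outputs
  used_names <- character()
  for (r in results) {
    for (p in r$pairs) {
      stem <- paste0(config$prefix, "_", sanitize_id(r$variant_id), "_",
                     sanitize_id(p$record$allele_informative_site))
      if (stem %in% used_names) {
        k <- 2L
        while (paste0(stem, "_", k) %in% used_names) k <- k + 1L
        stem <- paste0(stem, "_", k)
      }
      used_names <- c(used_names, stem)
      if (config$write_isoform_tables) {
        iso_dir <- file.path(out_dir, "isoforms")
        dir.create(iso_dir, showWarnings = FALSE)
        write.table(p$usage, file.path(iso_dir, paste0(stem, "_isoforms.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (config$write_bams) {
        bam_dir <- file.path(out_dir, "allele_bams")
        dir.create(bam_dir, showWarnings = FALSE)
        write_allele_bams(bam, p$partition, file.path(bam_dir, stem))
      }
      if (config$write_phased_vcf && !is.null(p$block)) {
        vcf_dir <- file.path(out_dir, "phased")
        dir.create(vcf_dir, showWarnings = FALSE)
        emit_phased_vcf(p$block, p$sites,
                        file.path(vcf_dir, paste0(stem, "_phased.vcf.gz")))
      }
    }
  }

  logs <- unlist(lapply(results, function(r) {
    if (length(r$logs)) paste0(r$variant_id, ":", r$logs) else NULL
  }))
  meta_path <- file.path(out_dir,
                         paste0(config$prefix, "_run_metadata.json"))
  jsonlite::write_json(
    list(package_version = as.character(packageVersion("isoallele")),
         config = unclass(config)[!vapply(unclass(config), is.null,
                                          logical(1))],
         funnel = as.list(funnel),
         logs = as.list(if (is.null(logs)) character() else logs)),
    meta_path, auto_unbox = TRUE, pretty = TRUE
  )

  structure(
    list(summary = records, funnel = funnel,
         logs = if (is.null(logs)) character() else logs,
         config = config,
         paths = list(out_dir = out_dir, summary = summary_path,
                      metadata = meta_path)),
    class = "asi_run"
  )
}

#' @export
print.asi_run <- function(x, ...) {
  f <- x$funnel
  cat("Allele-level isoform usage run\n")
  cat(sprintf("  variants: %d in -> %d with informative site -> %d tested -> %d significant\n",
              f["variants_in"], f["variants_with_site"], f["variants_tested"],
              f["variants_significant"]))
  if (nrow(x$summary)) {
    cat("  pairs tested:", nrow(x$summary), "\n")
    print(utils::head(x$summary[, c("splicing_variant",
                                    "allele_informative_site",
                                    "ref_coverage", "alt_coverage",
                                    "min_p", "corrected_p")], 10))
  } else {
    cat("  no variant-site pair reached the test stage\n")
  }
  invisible(x)
}

#' Write allele-separated BAM files for one pair
#'
#' Splits the original BAM records verbatim into a `_ref.bam` and an
#' `_alt.bam` by the partition's read-id sets; both files are indexed. An
#' empty allele still yields a (0-record) BAM.
#'
#' @param bam Source BAM path.
#' @param partition An `allele_partition`.
#' @param out_prefix Path prefix for the two outputs.
#' @return Character vector of the two BAM paths.
#' @export
write_allele_bams <- function(bam, partition, out_prefix) {
  write_one <- function(ids, suffix) {
    dest <- paste0(out_prefix, "_", suffix, ".bam")
    rules <- S4Vectors::FilterRules(list(function(x) x$qname %in% ids))
    Rsamtools::filterBam(
      Rsamtools::BamFile(bam), destination = dest, filter = rules,
      param = Rsamtools::ScanBamParam(what = "qname"),
      indexDestination = TRUE
    )
    dest
  }
  c(ref = write_one(partition$ref_read_ids, "ref"),
    alt = write_one(partition$alt_read_ids, "alt"))
}
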