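#' Parse a SpliceAI INFO annotation
#'
#' Decodes the standard pipe-delimited SpliceAI annotation
#' `ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`.
#' Several comma-separated records (one per annotated transcript/gene) may
#' be present. The delta score of each record is the maximum of its four
#' sub-scores: the maximal predicted probability that the variant alters
#' splicing by acceptor gain/loss or donor gain/loss.
#'
#' @param raw_field The annotation text (the value of the `SpliceAI` INFO
#'   key, without the key itself).
#' @param variant_id Optional identifier used in error messages.
#' @return A data.frame with one row per record and columns `allele`,
#'   `gene_symbol`, `ds_ag`, `ds_al`, `ds_dg`, `ds_dl`, `dp_ag`, `dp_al`,
#'   `dp_dg`, `dp_dl`, `delta_score`.
#' @examples
#' parse_spliceai_annotation("T|GSDMC|0.95|0.92|0.00|0.00|-2|-21|4|-43")
#' @export
parse_spliceai_annotation <- function(raw_field, variant_id = NULL) {
  ctx <- if (is.null(variant_id)) "" else paste0(" for variant ", variant_id)
  recs <- strsplit(raw_field, ",", fixed = TRUE)[[1]]
  rows <- lapply(recs, function(r) {
    tok <- strsplit(r, "|", fixed = TRUE)[[1]]
    if (length(tok) != 10L) {
      stop("malformed SpliceAI annotation", ctx, ": expected 10 tokens, got ",
           length(tok), " in '", r, "'")
    }
    ds <- suppressWarnings(as.numeric(tok[3:6]))
    dp <- suppressWarnings(as.integer(tok[7:10]))
    if (anyNA(ds)) {
      stop("malformed SpliceAI annotation", ctx,
           ": non-numeric delta sub-score in '", r, "'")
    }
    data.frame(
      allele = tok[1], gene_symbol = tok[2],
      ds_ag = ds[1], ds_al = ds[2], ds_dg = ds[3], ds_dl = ds[4],
      dp_ag = dp[1], dp_al = dp[2], dp_dg = dp[3], dp_dl = dp[4],
      delta_score = max(ds), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Serialize SpliceAI score records back to annotation text
#'
#' Inverse of [parse_spliceai_annotation()]; sub-scores are written with two
#' decimals (the SpliceAI convention) and offsets as plain integers.
#'
#' @param records A data.frame as returned by [parse_spliceai_annotation()].
#' @return A single annotation string.
#' @export
format_spliceai_annotation <- function(records) {
  paste(vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(r$allele, r$gene_symbol,
          sprintf("%.2f", r$ds_ag), sprintf("%.2f", r$ds_al),
          sprintf("%.2f", r$ds_dg), sprintf("%.2f", r$ds_dl),
          r$dp_ag, r$dp_al, r$dp_dg, r$dp_dl, sep = "|")
  }, character(1)), collapse = ",")
}

# Is a diploid GT string heterozygous for alt-allele index `alt_index`?
gt_is_het <- function(gt, alt_index = 1L) {
  if (is.na(gt)) return(FALSE)
  al <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  if (length(al) != 2L || anyNA(al)) return(FALSE)
  al[1] != al[2] && alt_index %in% al
}

#' Read heterozygous putative splicing variants from a VCF
#'
#' Parses a VCF of candidate splice-altering variants annotated with
#' SpliceAI-style scores (INFO key `SpliceAI`). Multi-allelic records are
#' split into bi-allelic candidates. When several transcript records
#' annotate one variant, the record with the maximal delta score is kept
#' (records whose ALLELE token matches the candidate alternate allele are
#' preferred when present).
#'
#' @param path VCF file (plain, gzip or bgzip).
#' @return A data.frame of class `splicing_variants` with one row per
#'   bi-allelic candidate: coordinates, alleles, genotype/heterozygosity,
#'   FILTER status, SpliceAI sub-scores and offsets, `delta_score`,
#'   `gene_symbol`, `variant_id`, and the original INFO string.
#' @export
read_splicing_variants <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- vcf@fix[, "INFO"]
  gt <- if (ncol(vcf@gt) >= 2L) {
    vcfR::extract.gt(vcf, element = "GT")[, 1L]
  } else {
    rep(NA_character_, nrow(fix))
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    sa_raw <- regmatches(info[i], regexpr("SpliceAI=[^;]+", info[i]))
    sa <- if (length(sa_raw)) sub("^SpliceAI=", "", sa_raw) else NA_character_
    for (j in seq_along(alts)) {
      vid <- sprintf("%s:%s%s>%s", fix[i, "CHROM"], fix[i, "POS"],
                     fix[i, "REF"], alts[j])
      sc <- list(gene_symbol = NA_character_,
                 ds_ag = NA_real_, ds_al = NA_real_, ds_dg = NA_real_,
                 ds_dl = NA_real_, dp_ag = NA_integer_, dp_al = NA_integer_,
                 dp_dg = NA_integer_, dp_dl = NA_integer_,
                 delta_score = NA_real_)
      if (!is.na(sa)) {
        recs <- parse_spliceai_annotation(sa, variant_id = vid)
        hit <- recs[recs$allele == alts[j], , drop = FALSE]
        if (!nrow(hit)) hit <- recs
        best <- hit[which.max(hit$delta_score), , drop = FALSE]
        sc <- as.list(best[, c("gene_symbol", "ds_ag", "ds_al", "ds_dg",
                               "ds_dl", "dp_ag", "dp_al", "dp_dg", "dp_dl",
                               "delta_score")])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = vid,
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        id = fix[i, "ID"], ref = fix[i, "REF"], alt = alts[j],
        filter = fix[i, "FILTER"], genotype = gt[i],
        het = gt_is_het(gt[i], alt_index = j),
        sc, info = info[i], stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      variant_id = character(), chrom = character(), pos = integer(),
      id = character(), ref = character(), alt = character(),
      filter = character(), genotype = character(), het = logical(),
      gene_symbol = character(), ds_ag = numeric(), ds_al = numeric(),
      ds_dg = numeric(), ds_dl = numeric(), dp_ag = integer(),
      dp_al = integer(), dp_dg = integer(), dp_dl = integer(),
      delta_score = numeric(), info = character(), stringsAsFactors = FALSE
    )
  }
  out$is_snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L
  class(out) <- c("splicing_variants", "data.frame")
  out
}

#' Read candidate allele-informative SNVs from a VCF
#'
#' Retains heterozygous single-nucleotide variants only: a heterozygous SNV
#' lets the base a read carries at its position assign the read to one of
#' the two parental alleles.
#'
#' @param path VCF file.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`, `site_id`.
#' @export
read_informative_snvs <- function(path) {
  v <- read_splicing_variants(path)
  v <- v[v$het & v$is_snv, c("chrom", "pos", "ref", "alt", "genotype")]
  v$site_id <- sprintf("%s:%d", v$chrom, v$pos)
  rownames(v) <- NULL
  class(v) <- "data.frame"
  v
}

#' Filter candidate splicing variants
#'
#' Keeps heterozygous, FILTER-PASS variants whose SpliceAI delta score
#' reaches `delta_threshold` (default 0.5, the recommended general-use
#' threshold; 0.2 favours recall, 0.8 precision). Optionally restricts to
#' positional splice regions via [splice_region_filter()].
#'
#' @param variants Output of [read_splicing_variants()].
#' @param delta_threshold Minimum delta score in `[0, 1]`.
#' @param splice_region_only If `TRUE`, also require the position to fall in
#'   a splice region of the annotation.
#' @param gene_models A `gene_models` object (required when
#'   `splice_region_only = TRUE`).
#' @param branch_window Optional branch-point window passed through to
#'   [splice_region_filter()].
#' @return The retained subset of `variants`.
#' @export
select_splicing_variants <- function(variants, delta_threshold = 0.5,
                                     splice_region_only = FALSE,
                                     gene_models = NULL,
                                     branch_window = NULL) {
  keep <- variants$het &
    (is.na(variants$filter) | variants$filter %in% c("PASS", ".")) &
    !is.na(variants$delta_score) &
    variants$delta_score >= delta_threshold
  out <- variants[keep, , drop = FALSE]
  if (splice_region_only) {
    if (is.null(gene_models)) stop("splice_region_only requires gene_models")
    in_region <- vapply(seq_len(nrow(out)), function(i) {
      splice_region_filter(out[i, ], gene_models, branch_window = branch_window)
    }, logical(1))
    out <- out[in_region, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Positional splice-region filter
#'
#' A snpEff-style positional analog: a variant is splice-region when it lies
#' 1-3 bases into an exon from an exon-intron junction, 3-8 bases into an
#' intron from a junction, or (optionally) within a branch-point window
#' upstream of an acceptor junction. Positions outside any annotated gene
#' return `FALSE`.
#'
#' @param variant A one-row data.frame (or list) with `chrom` and `pos`
#'   (1-based).
#' @param gene_models A `gene_models` object.
#' @param exon_window,intron_window Inclusive distance ranges (in bases from
#'   the junction, 1 = adjacent base).
#' @param branch_window `NULL` (disabled, the default) or an inclusive
#'   distance range into the intron from the acceptor junction, e.g.
#'   `c(18, 44)`.
#' @return `TRUE` or `FALSE`.
#' @export
splice_region_filter <- function(variant, gene_models,
                                 exon_window = c(1, 3),
                                 intron_window = c(3, 8),
                                 branch_window = NULL) {
  pos <- variant$pos
  introns <- transcript_introns(gene_models, chrom = variant$chrom)
  for (intr in introns) {
    if (!nrow(intr)) next
    for (k in seq_len(nrow(intr))) {
      donor_end1 <- intr$start[k]        # 1-based last base of upstream exon
      acc_start1 <- intr$end[k] + 1L     # 1-based first base of downstream exon
      in_win <- function(d, w) d >= w[1] && d <= w[2]
      # exonic side: distance 1 = junction-adjacent exon base
      if (in_win(donor_end1 - pos + 1L, exon_window)) return(TRUE)
      if (in_win(pos - acc_start1 + 1L, exon_window)) return(TRUE)
      # intronic side: distance 1 = first intron base
      if (in_win(pos - donor_end1, intron_window)) return(TRUE)
      if (in_win(acc_start1 - pos, intron_window)) return(TRUE)
      if (!is.null(branch_window) && in_win(acc_start1 - pos, branch_window)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Derive the per-variant target region
#'
#' The region of interest spans the minimal to maximal coordinates predicted
#' to be affected by SpliceAI (the variant position plus each sub-score
#' offset), expanded to the containing gene's annotated span when the gene
#' is present in the annotation.
#'
#' @param variant One row of [read_splicing_variants()] output.
#' @param gene_models A `gene_models` object, or `NULL`.
#' @return A `target_region`: list with `chrom`, `start`, `end` (0-based
#'   half-open) and `gene_symbol`.
#' @export
derive_target_region <- function(variant, gene_models = NULL) {
  dp <- c(variant$dp_ag, variant$dp_al, variant$dp_dg, variant$dp_dl)
  affected1 <- variant$pos + c(0L, dp[!is.na(dp)])
  start0 <- min(affected1) - 1L
  end0 <- max(affected1)
  gs <- if (!is.null(gene_models) && !is.na(variant$gene_symbol)) {
    gene_span(gene_models, variant$gene_symbol)
  } else {
    NULL
  }
  if (is.null(gs)) {
    if (!is.null(gene_models)) {
      warning("gene '", variant$gene_symbol, "' absent from annotation; ",
              "using the SpliceAI-affected window only", call. = FALSE)
    }
  } else {
    start0 <- min(start0, gs$start - 1L)
    end0 <- max(end0, gs$end)
  }
  structure(
    list(chrom = variant$chrom, start = start0, end = end0,
         gene_symbol = variant$gene_symbol),
    class = "target_region"
  )
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf("target_region %s:%d-%d (%s)\n", x$chrom, x$start, x$end,
              if (is.na(x$gene_symbol)) "?" else x$gene_symbol))
  invisible(x)
}
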