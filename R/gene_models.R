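#' Read gene models from a GTF file
#'
#' Imports exon features from an Ensembl-dialect GTF (attributes
#' `gene_name` / `gene_id` and `transcript_id`) into a light-weight table
#' used for splice-region filtering, target-region derivation and isoform
#' annotation matching.
#'
#' @param path Path to a GTF file.
#' @return An object of class `gene_models`: a list with element `exons`,
#'   a data.frame with columns `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`, `gene_name`, `transcript_id`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  gene <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  exons <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_name = as.character(gene),
    transcript_id = as.character(gr$transcript_id),
    stringsAsFactors = FALSE
  )
  structure(list(exons = exons), class = "gene_models")
}

as_gene_models <- function(x) {
  if (inherits(x, "gene_models")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_gene_models(x))
  stop("expected a gene_models object or a GTF path")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(unique(x$exons$gene_name)), "gene(s),",
      length(unique(x$exons$transcript_id)), "transcript(s),",
      nrow(x$exons), "exon rows\n")
  invisible(x)
}

# 1-based inclusive span of a gene, or NULL when absent.
gene_span <- function(gene_models, gene_symbol) {
  ex <- gene_models$exons[gene_models$exons$gene_name %in% gene_symbol, ]
  if (!nrow(ex)) return(NULL)
  list(chrom = ex$chrom[1], start = min(ex$start), end = max(ex$end))
}

# Intron chains per transcript: list of data.frames with 0-based half-open
# `start`/`end` columns (empty data.frame for single-exon transcripts).
transcript_introns <- function(gene_models, chrom = NULL) {
  ex <- gene_models$exons
  if (!is.null(chrom)) ex <- ex[ex$chrom == chrom, ]
  out <- lapply(split(ex, ex$transcript_id), function(t) {
    t <- t[order(t$start), ]
    if (nrow(t) < 2L) {
      return(data.frame(start = integer(), end = integer()))
    }
    data.frame(
      start = t$end[-nrow(t)],        # 0-based intron start = exon 1-based end
      end = t$start[-1L] - 1L         # 0-based half-open end
    )
  })
  out
}

# 1-based inclusive span per transcript.
transcript_spans <- function(gene_models, chrom = NULL) {
  ex <- gene_models$exons
  if (!is.null(chrom)) ex <- ex[ex$chrom == chrom, ]
  lapply(split(ex, ex$transcript_id), function(t) {
    list(chrom = t$chrom[1], start = min(t$start), end = max(t$end))
  })
}
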