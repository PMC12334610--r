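#' Extract a read's splice-junction chain
#'
#' The junction chain -- the ordered set of intron intervals spliced out of
#' the alignment -- is the identity key of an isoform. Every reference-skip
#' (N) run of at least `min_intron` bases becomes an intron; shorter skips
#' are treated as alignment noise. Reads retaining an intron align M across
#' it and so simply lack that interval from their chain.
#'
#' @param read A one-row data.frame/list with `chrom`, `ref_start0`,
#'   `cigar`, and optionally `flag` (for strand).
#' @param min_intron Minimum N-run length (bp) counted as an intron.
#' @return A `junction_chain`: list with `chrom`, `introns` (data.frame of
#'   0-based half-open `start`/`end`), `strand`.
#' @export
extract_junction_chain <- function(read, min_intron = 20) {
  blocks <- cigar_blocks(read$ref_start0, read$cigar)
  idx <- blocks$op == "N" & blocks$len >= min_intron
  strand <- if (!is.null(read$flag) && !is.na(read$flag)) {
    if (bitwAnd(read$flag, 16L) > 0L) "-" else "+"
  } else {
    "*"
  }
  structure(
    list(
      chrom = read$chrom,
      introns = data.frame(start = blocks$rstart[idx],
                           end = blocks$rstart[idx] + blocks$len[idx]),
      strand = strand
    ),
    class = "junction_chain"
  )
}

# Canonical string key of a chain ("" = single-exon read).
chain_key <- function(chain) {
  if (!nrow(chain$introns)) return("")
  paste(sprintf("%d-%d", chain$introns$start, chain$introns$end),
        collapse = ";")
}

#' Collapse reads into supported isoform groups
#'
#' Reads sharing an identical junction chain form one isoform group;
#' single-exon reads (empty chains) are clustered by reciprocal span
#' overlap. Groups supported by fewer than `min_support` reads are
#' discarded and their reads marked unassigned. Representative transcript
#' ends are the medians of member alignment starts/ends and are never
#' adjusted to annotation.
#'
#' @param reads Data.frame of reads (one variant-site pair, both alleles
#'   pooled).
#' @param min_support Minimum supporting reads per group (default 4).
#' @param min_intron Passed to [extract_junction_chain()].
#' @param single_exon_overlap Minimum reciprocal overlap fraction for
#'   clustering single-exon reads.
#' @return An `isoform_set`: list with `groups` (each a list with `chain`,
#'   `chrom`, `rep_start`, `rep_end`, `read_ids`, `n`, `label`) and
#'   `unassigned` (read ids).
#' @export
collapse_isoforms <- function(reads, min_support = 4, min_intron = 20,
                              single_exon_overlap = 0.8) {
  if (!nrow(reads)) {
    return(structure(list(groups = list(), unassigned = character()),
                     class = "isoform_set"))
  }
  chains <- lapply(seq_len(nrow(reads)), function(i) {
    extract_junction_chain(
      list(chrom = reads$chrom[i], ref_start0 = reads$ref_start0[i],
           cigar = reads$cigar[i], flag = reads$flag[i]),
      min_intron = min_intron
    )
  })
  keys <- vapply(chains, chain_key, character(1))
  # deterministic order regardless of input read order
  ord <- order(keys, reads$ref_start0, reads$ref_end0, reads$read_id)
  reads <- reads[ord, , drop = FALSE]
  chains <- chains[ord]
  keys <- keys[ord]

  groups <- list()
  multi <- which(keys != "")
  if (length(multi)) {
    for (k in unique(keys[multi])) {
      idx <- which(keys == k)
      groups[[length(groups) + 1L]] <- list(idx = idx, chain = chains[[idx[1]]])
    }
  }
  # single-exon reads: greedy reciprocal-overlap clustering against the
  # cluster seed span, in deterministic sorted order
  single <- which(keys == "")
  if (length(single)) {
    clusters <- list()
    for (i in single) {
      s <- reads$ref_start0[i]
      e <- reads$ref_end0[i]
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        cs <- clusters[[ci]]$seed
        ov <- max(0L, min(e, cs[2]) - max(s, cs[1]))
        if (ov / (e - s) >= single_exon_overlap &&
            ov / (cs[2] - cs[1]) >= single_exon_overlap) {
          clusters[[ci]]$idx <- c(clusters[[ci]]$idx, i)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        clusters[[length(clusters) + 1L]] <- list(seed = c(s, e), idx = i)
      }
    }
    for (cl in clusters) {
      groups[[length(groups) + 1L]] <- list(idx = cl$idx,
                                            chain = chains[[cl$idx[1]]])
    }
  }

  supported <- list()
  unassigned <- character()
  for (g in groups) {
    if (length(g$idx) >= min_support) {
      supported[[length(supported) + 1L]] <- list(
        chain = g$chain,
        chrom = reads$chrom[g$idx[1]],
        rep_start = as.integer(median(reads$ref_start0[g$idx])),
        rep_end = as.integer(median(reads$ref_end0[g$idx])),
        read_ids = reads$read_id[g$idx],
        n = length(g$idx),
        label = NA_character_
      )
    } else {
      unassigned <- c(unassigned, reads$read_id[g$idx])
    }
  }
  # stable group order: by chain key, then representative span
  if (length(supported)) {
    gk <- vapply(supported, function(g) chain_key(g$chain), character(1))
    gs <- vapply(supported, function(g) g$rep_start, integer(1))
    supported <- supported[order(gk, gs)]
  }
  structure(list(groups = supported, unassigned = unassigned),
            class = "isoform_set")
}

#' @export
print.isoform_set <- function(x, ...) {
  cat("isoform_set:", length(x$groups), "supported group(s),",
      length(x$unassigned), "unassigned read(s)\n")
  for (g in x$groups) {
    cat(sprintf("  %s  n=%d  [%d junctions]\n",
                if (is.na(g$label)) "(unlabelled)" else g$label,
                g$n, nrow(g$chain$introns)))
  }
  invisible(x)
}

#' Label isoform groups against annotated transcripts
#'
#' A group whose intron chain equals an annotated transcript's intron chain
#' exactly (or within `fuzz` bp per junction coordinate) takes that
#' transcript id; empty-chain groups match single-exon transcripts whose
#' span contains the representative span. Remaining groups are labelled
#' `novel-k` with deterministic ordinals.
#'
#' @param isoform_set Output of [collapse_isoforms()].
#' @param gene_models A `gene_models` object.
#' @param fuzz Per-coordinate junction tolerance in bp (default 0, exact).
#' @return The `isoform_set` with `label` filled on every group.
#' @export
match_annotation <- function(isoform_set, gene_models, fuzz = 0) {
  if (!length(isoform_set$groups)) return(isoform_set)
  chrom <- isoform_set$groups[[1]]$chrom
  anno <- transcript_introns(gene_models, chrom = chrom)
  spans <- transcript_spans(gene_models, chrom = chrom)
  tx_ids <- sort(names(anno))
  novel_k <- 0L
  for (gi in seq_along(isoform_set$groups)) {
    g <- isoform_set$groups[[gi]]
    label <- NA_character_
    for (tx in tx_ids) {
      ti <- anno[[tx]]
      if (nrow(g$chain$introns) == 0L) {
        sp <- spans[[tx]]
        if (nrow(ti) == 0L &&
            sp$start - 1L <= g$rep_start && g$rep_end <= sp$end) {
          label <- tx
          break
        }
      } else if (nrow(ti) == nrow(g$chain$introns) &&
                 all(abs(ti$start - g$chain$introns$start) <= fuzz) &&
                 all(abs(ti$end - g$chain$introns$end) <= fuzz)) {
        label <- tx
        break
      }
    }
    if (is.na(label)) {
      novel_k <- novel_k + 1L
      label <- sprintf("novel-%d", novel_k)
    }
    isoform_set$groups[[gi]]$label <- label
  }
  isoform_set
}

#' Count isoform support per allele and derive usage fractions
#'
#' Raw read counts per isoform group and allele (no library-size scaling),
#' with the usage fraction of isoform i in allele a defined as
#' `count(i, a) / sum_j count(j, a)`.
#'
#' @param isoform_set Output of [collapse_isoforms()] /
#'   [match_annotation()].
#' @param partition An `allele_partition`.
#' @return A data.frame with columns `label`, `chain`, `ref_count`,
#'   `alt_count`, `ref_usage`, `alt_usage`. Usage fractions are `NaN` for
#'   an allele with zero assigned reads (the pair is then skipped by the
#'   test stage).
#' @export
quantify_per_allele <- function(isoform_set, partition) {
  groups <- isoform_set$groups
  n <- length(groups)
  out <- data.frame(
    label = vapply(groups, function(g) g$label, character(1)),
    chain = vapply(groups, function(g) chain_key(g$chain), character(1)),
    ref_count = vapply(groups, function(g) {
      sum(g$read_ids %in% partition$ref_read_ids)
    }, integer(1)),
    alt_count = vapply(groups, function(g) {
      sum(g$read_ids %in% partition$alt_read_ids)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  out$ref_usage <- out$ref_count / sum(out$ref_count)
  out$alt_usage <- out$alt_count / sum(out$alt_count)
  out
}
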