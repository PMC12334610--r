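# Junction-chain extraction, isoform collapse, annotation matching and
# per-allele quantification.

mk_read <- function(id, pos1, cigar, chrom = "chr1") {
  cg <- isoallele:::parse_cigar(cigar)
  qlen <- sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X")])
  rlen <- sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
  data.frame(
    read_id = id, chrom = chrom, ref_start0 = pos1 - 1L,
    ref_end0 = pos1 - 1L + rlen, cigar = cigar, flag = 0L,
    seq = mk_seq(qlen), qual = mk_qual(qlen), sa = NA_character_,
    stringsAsFactors = FALSE
  )
}

test_that("junction chains collect reference skips of intron size", {
  # ref_start 999 (0-based), 100M200N100M -> one intron (1099, 1299)
  r <- list(chrom = "chr1", ref_start0 = 999L, cigar = "100M200N100M",
            flag = 0L)
  ch <- extract_junction_chain(r)
  expect_equal(ch$introns$start, 1099L)
  expect_equal(ch$introns$end, 1299L)
  expect_equal(ch$strand, "+")

  # single-exon read: empty chain
  expect_equal(nrow(extract_junction_chain(
    list(chrom = "chr1", ref_start0 = 0L, cigar = "300M", flag = 0L)
  )$introns), 0L)

  # two skips by cumulative reference lengths
  r2 <- list(chrom = "chr1", ref_start0 = 0L, cigar = "50M100N50M30N50M",
             flag = 16L)
  ch2 <- extract_junction_chain(r2)
  expect_equal(ch2$introns$start, c(50L, 200L))
  expect_equal(ch2$introns$end, c(150L, 230L))
  expect_equal(ch2$strand, "-")

  # skips below min_intron are alignment noise, not introns
  r3 <- list(chrom = "chr1", ref_start0 = 0L, cigar = "50M10N50M", flag = 0L)
  expect_equal(nrow(extract_junction_chain(r3, min_intron = 20)$introns), 0L)
  expect_equal(nrow(extract_junction_chain(r3, min_intron = 10)$introns), 1L)
})

test_that("collapse groups reads by chain identity under the support gate", {
  rx <- do.call(rbind, c(
    lapply(1:5, function(i) mk_read(paste0("x", i), 1, "50M100N50M")),
    lapply(1:3, function(i) mk_read(paste0("y", i), 1, "50M200N50M"))
  ))
  iso <- collapse_isoforms(rx, min_support = 4)
  expect_length(iso$groups, 1L)
  expect_equal(iso$groups[[1]]$n, 5L)
  expect_setequal(iso$unassigned, paste0("y", 1:3))

  # both chains at the threshold
  rx2 <- do.call(rbind, c(
    lapply(1:4, function(i) mk_read(paste0("x", i), 1, "50M100N50M")),
    lapply(1:4, function(i) mk_read(paste0("y", i), 1, "50M200N50M"))
  ))
  expect_length(collapse_isoforms(rx2, min_support = 4)$groups, 2L)

  # nothing supported
  iso0 <- collapse_isoforms(rx[1:3, ], min_support = 4)
  expect_length(iso0$groups, 0L)
  expect_length(iso0$unassigned, 3L)
})

test_that("collapse output is invariant to read order", {
  set.seed(3)
  rx <- do.call(rbind, c(
    lapply(1:6, function(i) mk_read(paste0("a", i), 1, "50M100N50M")),
    lapply(1:5, function(i) mk_read(paste0("b", i), 1, "50M")),
    lapply(1:4, function(i) mk_read(paste0("c", i), 11, "35M"))
  ))
  key <- function(iso) {
    lapply(iso$groups, function(g) list(isoallele:::chain_key(g$chain),
                                        sort(g$read_ids)))
  }
  iso1 <- collapse_isoforms(rx, min_support = 4)
  iso2 <- collapse_isoforms(rx[sample(nrow(rx)), ], min_support = 4)
  expect_equal(key(iso2), key(iso1))
  # the 35M reads overlap the 50M reads by only 35/50 = 70% < 80%, so the
  # single-exon reads form two clusters
  expect_length(iso1$groups, 3L)
})

test_that("annotation matching labels exact chains and numbers novel ones", {
  gm <- make_gene_models("chr1", c(1, 151, 301), c(100, 250, 400),
                         gene = "G1", tx = "ENST0001")
  # transcript introns (0-based half-open): (100,150) and (250,300)
  rx <- do.call(rbind, c(
    lapply(1:4, function(i) mk_read(paste0("m", i), 1, "100M50N100M50N100M")),
    lapply(1:4, function(i) mk_read(paste0("n", i), 1, "100M200N100M")),
    lapply(1:4, function(i) mk_read(paste0("o", i), 1, "100M250N50M"))
  ))
  iso <- match_annotation(collapse_isoforms(rx, min_support = 4), gm)
  labels <- vapply(iso$groups, function(g) g$label, character(1))
  expect_true("ENST0001" %in% labels)
  expect_setequal(setdiff(labels, "ENST0001"), c("novel-1", "novel-2"))
  # deterministic ordinals across runs
  iso2 <- match_annotation(collapse_isoforms(rx[sample(nrow(rx)), ],
                                             min_support = 4), gm)
  expect_equal(vapply(iso2$groups, function(g) g$label, character(1)), labels)
})

test_that("single-exon groups match single-exon transcripts by containment", {
  gm <- make_gene_models("chr1", 1, 500, gene = "G1", tx = "ENST_SE")
  rx <- do.call(rbind, lapply(1:4, function(i) mk_read(paste0("s", i), 10, "200M")))
  iso <- match_annotation(collapse_isoforms(rx, min_support = 4), gm)
  expect_equal(iso$groups[[1]]$label, "ENST_SE")
})

test_that("per-allele quantification yields raw counts and usage fractions", {
  rx <- do.call(rbind, c(
    lapply(1:10, function(i) mk_read(paste0("x", i), 1, "50M100N50M")),
    lapply(1:12, function(i) mk_read(paste0("y", i), 1, "50M200N50M"))
  ))
  iso <- collapse_isoforms(rx, min_support = 4)
  part <- structure(list(
    site_id = "chr1:10", ref_read_ids = c(paste0("x", 1:8), paste0("y", 1:2)),
    alt_read_ids = paste0("y", 3:12), n_other_base = 0L
  ), class = "allele_partition")
  q <- quantify_per_allele(iso, part)
  expect_equal(sort(q$ref_count), c(2L, 8L))
  expect_equal(q$ref_usage[order(q$ref_count)], c(0.2, 0.8))
  expect_equal(q$alt_usage[order(q$alt_count)], c(0.0, 1.0))
  expect_equal(sum(q$ref_usage), 1)
  expect_equal(sum(q$ref_count) + sum(q$alt_count),
               length(part$ref_read_ids) + length(part$alt_read_ids))
})

test_that("noiseless simulation round-trips isoform chains exactly", {
  scn <- mcardle_like_preset(n_reads = 30, error_rate = 0, seed = 4)
  fx <- simulate_scenario(scn, tempfile("rt"))
  reads <- select_spanning_reads(fx$bam, scn$chrom, scn$snv_pos[1])
  iso <- collapse_isoforms(reads, min_support = 1)
  # every simulated isoform recovered as exactly one group with the
  # simulated read membership
  expect_length(iso$groups, length(unique(fx$truth$isoform)))
  tr <- split(fx$truth$read_id, fx$truth$isoform)
  got <- lapply(iso$groups, function(g) sort(g$read_ids))
  for (members in tr) {
    expect_true(any(vapply(got, identical, logical(1),
                           y = sort(members))))
  }
  # intron counts: canonical 13, exon-13 skip 12, intron-12 retention 12,
  # double retention 11 (for the isoforms the mixture actually produced)
  exp_n <- c(canonical = 13L, skip13 = 12L, ir12 = 12L, ir12_13 = 11L)
  nintrons <- vapply(iso$groups, function(g) nrow(g$chain$introns), integer(1))
  expect_equal(sort(nintrons),
               sort(unname(exp_n[unique(fx$truth$isoform)])))
})
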