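# Parsing, filtering and region derivation for splicing-variant input.

test_that("SpliceAI annotation parsing recovers sub-scores, offsets and delta", {
  # high-delta acceptor-site example
  rec <- parse_spliceai_annotation("T|GSDMC|0.95|0.92|0.00|0.00|-2|-21|4|-43")
  expect_equal(nrow(rec), 1L)
  expect_equal(unlist(rec[, c("ds_ag", "ds_al", "ds_dg", "ds_dl")],
                      use.names = FALSE),
               c(0.95, 0.92, 0.00, 0.00))
  expect_equal(unlist(rec[, c("dp_ag", "dp_al", "dp_dg", "dp_dl")],
                      use.names = FALSE),
               c(-2L, -21L, 4L, -43L))
  expect_equal(rec$delta_score, 0.95)
  expect_equal(rec$gene_symbol, "GSDMC")

  # low-delta example
  rec2 <- parse_spliceai_annotation("C|WWC1|0.27|0.00|0.00|0.00|3|-2|37|-38")
  expect_equal(rec2$delta_score, 0.27)

  # degenerate all-zero record
  rec3 <- parse_spliceai_annotation("A|GENE|0.00|0.00|0.00|0.00|0|0|0|0")
  expect_equal(rec3$delta_score, 0)

  # several transcript records
  multi <- parse_spliceai_annotation(
    "T|GSDMC|0.95|0.92|0.00|0.00|-2|-21|4|-43,T|GSDMC2|0.10|0.00|0.00|0.00|1|2|3|4"
  )
  expect_equal(nrow(multi), 2L)
  expect_equal(multi$delta_score, c(0.95, 0.10))
})

test_that("malformed SpliceAI annotations raise errors naming the variant", {
  expect_error(
    parse_spliceai_annotation("T|GSDMC|0.95|0.92", variant_id = "chr8:129750591C>T"),
    "chr8:129750591C>T"
  )
  expect_error(
    parse_spliceai_annotation("T|G|x|0.0|0.0|0.0|1|2|3|4"),
    "non-numeric"
  )
})

test_that("parse -> serialize -> parse round-trips scores and offsets exactly", {
  raw <- "T|GSDMC|0.95|0.92|0.00|0.00|-2|-21|4|-43,C|WWC1|0.27|0.00|0.00|0.00|3|-2|37|-38"
  rec <- parse_spliceai_annotation(raw)
  expect_identical(format_spliceai_annotation(rec), raw)
  expect_identical(parse_spliceai_annotation(format_spliceai_annotation(rec)),
                   rec)
})

write_variant_vcf <- function(rows) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SpliceAI,Number=.,Type=String,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    rows
  ), f)
  f
}

test_that("VCF reading: heterozygosity, FILTER and multi-allelic splitting", {
  f <- write_variant_vcf(c(
    "chr8\t129750591\t.\tC\tT\t.\tPASS\tSpliceAI=T|GSDMC|0.95|0.92|0.00|0.00|-2|-21|4|-43\tGT\t0/1",
    "chr5\t168468948\t.\tT\tC\t.\tPASS\tSpliceAI=C|WWC1|0.27|0.00|0.00|0.00|3|-2|37|-38\tGT\t0|1",
    "chr1\t1000\t.\tG\tA\t.\tPASS\tSpliceAI=A|HOMG|0.99|0.00|0.00|0.00|1|1|1|1\tGT\t1/1",
    "chr2\t2000\t.\tA\tC,G\t.\tPASS\tSpliceAI=C|MA1|0.80|0.00|0.00|0.00|0|0|0|0,G|MA1|0.30|0.00|0.00|0.00|0|0|0|0\tGT\t1/2",
    "chr3\t3000\t.\tT\tA\t.\tLowQual\tSpliceAI=A|FG|0.90|0.00|0.00|0.00|0|0|0|0\tGT\t0/1"
  ))
  v <- read_splicing_variants(f)
  expect_equal(nrow(v), 6L)  # multi-allelic record split in two
  gsdmc <- v[v$gene_symbol == "GSDMC", ]
  expect_true(gsdmc$het)
  expect_equal(gsdmc$delta_score, 0.95)
  expect_false(v$het[v$gene_symbol == "HOMG"])
  ma <- v[v$gene_symbol == "MA1", ]
  expect_equal(ma$alt, c("C", "G"))
  expect_equal(ma$delta_score, c(0.80, 0.30))  # per-allele record matched
  expect_true(all(ma$het))                     # 1/2 is het for both alts

  sel <- select_splicing_variants(v, delta_threshold = 0.5)
  # homozygote, non-PASS and sub-threshold variants removed
  expect_setequal(sel$gene_symbol, c("GSDMC", "MA1"))
  expect_true(all(sel$het))
  expect_true(all(sel$filter == "PASS"))

  # GSDMC (0.95) retained at 0.5; WWC1 (0.27) removed at 0.5, kept at 0.2
  expect_true("GSDMC" %in% sel$gene_symbol)
  expect_false("WWC1" %in% sel$gene_symbol)
  expect_true("WWC1" %in% select_splicing_variants(v, 0.2)$gene_symbol)
})

test_that("retention is monotone in the delta threshold", {
  f <- write_variant_vcf(sprintf(
    "chr1\t%d\t.\tA\tG\t.\tPASS\tSpliceAI=G|G%d|%.2f|0.00|0.00|0.00|0|0|0|0\tGT\t0/1",
    seq(1000, 1900, by = 100), 1:10, seq(0.05, 0.95, by = 0.1)
  ))
  v <- read_splicing_variants(f)
  s02 <- select_splicing_variants(v, 0.2)$variant_id
  s05 <- select_splicing_variants(v, 0.5)$variant_id
  s08 <- select_splicing_variants(v, 0.8)$variant_id
  expect_true(all(s08 %in% s05))
  expect_true(all(s05 %in% s02))
  expect_true(length(s08) < length(s05) && length(s05) < length(s02))
})

test_that("splice-region filter applies exon, intron and branch windows", {
  # two-exon transcript: exon1 101-200, intron 201-300, exon2 301-400
  gm <- make_gene_models("chr1", c(101, 301), c(200, 400))
  srf <- function(pos, ...) {
    splice_region_filter(list(chrom = "chr1", pos = pos), gm, ...)
  }
  expect_true(srf(199))    # 2 bases into exon from donor junction
  expect_true(srf(200))    # junction-adjacent exon base
  expect_false(srf(197))   # 4 bases into exon
  expect_true(srf(205))    # 5 bases into intron (donor side)
  expect_false(srf(202))   # 2 bases into intron: below the 3-8 window
  expect_true(srf(295))    # 6 bases into intron (acceptor side)
  expect_false(srf(280))   # 21 bases into intron, branch window disabled
  expect_true(srf(280, branch_window = c(18, 44)))
  expect_false(srf(150))   # exon interior
  expect_false(splice_region_filter(list(chrom = "chr9", pos = 199), gm))
})

test_that("target region covers the SpliceAI-affected window and gene span", {
  v <- list(chrom = "chr1", pos = 1000L, gene_symbol = "G1",
            dp_ag = -2L, dp_al = -21L, dp_dg = 4L, dp_dl = -43L)
  # gene span contains the affected window: region = gene span
  gm <- make_gene_models("chr1", 501, 2000)
  r <- derive_target_region(v, gm)
  expect_equal(c(r$start, r$end), c(500L, 2000L))

  # gene absent: min/max affected coordinates only (1-based 957..1004)
  gm2 <- make_gene_models("chr1", 501, 2000, gene = "OTHER")
  expect_warning(r2 <- derive_target_region(v, gm2), "absent")
  expect_equal(c(r2$start, r2$end), c(956L, 1004L))

  # degenerate: all offsets zero -> single base
  v0 <- list(chrom = "chr1", pos = 1000L, gene_symbol = "G1",
             dp_ag = 0L, dp_al = 0L, dp_dg = 0L, dp_dl = 0L)
  r3 <- derive_target_region(v0, NULL)
  expect_equal(c(r3$start, r3$end), c(999L, 1000L))
  expect_true(r3$start < r3$end)
})
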