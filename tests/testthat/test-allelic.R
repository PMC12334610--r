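# SNV gating, allele partitioning and MEC haplotype phasing.

mk_obs <- function(bases, q = 30) {
  data.frame(
    read_id = sprintf("r%02d", seq_along(bases)),
    pos = 100L, base = bases, phred_q = rep_len(q, length(bases)),
    stringsAsFactors = FALSE
  )
}

test_that("coverage/quality gate requires 10 qualifying reads at BQ >= 10", {
  obs <- mk_obs(rep("A", 12), q = c(rep(30, 11), 5))
  g <- gate_candidate_snv(obs)
  expect_true(g$pass)
  expect_equal(nrow(g$observations), 11L)
  expect_equal(g$n_low_quality, 1L)

  expect_false(gate_candidate_snv(mk_obs(rep("A", 9)))$pass)

  # spliced-out observations (no base) never count
  obs2 <- mk_obs(c(rep("A", 9), NA, NA, NA))
  obs2$phred_q[is.na(obs2$base)] <- NA
  g2 <- gate_candidate_snv(obs2)
  expect_false(g2$pass)
  expect_equal(g2$n_no_base, 3L)

  # amplicon-mode quality floor of 15
  obs3 <- mk_obs(rep("A", 12), q = c(rep(20, 10), 12, 12))
  g3 <- gate_candidate_snv(obs3, min_bq = 15)
  expect_equal(nrow(g3$observations), 10L)
})

test_that("partitioning splits reads by allele and discards other bases", {
  snv <- list(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  p <- partition_reads(mk_obs(c("A", "A", "G", "G", "G", "T")), snv)
  expect_equal(length(p$ref_read_ids), 2L)
  expect_equal(length(p$alt_read_ids), 3L)
  expect_equal(p$n_other_base, 1L)
  expect_length(intersect(p$ref_read_ids, p$alt_read_ids), 0L)

  # degenerate: all reads on one allele
  p2 <- partition_reads(mk_obs(rep("A", 10)), snv)
  expect_equal(length(p2$alt_read_ids), 0L)

  # swapping ref/alt labels mirrors the partition
  p3 <- partition_reads(mk_obs(c("A", "A", "G", "G", "G", "T")),
                        list(chrom = "chr1", pos = 100L, ref = "G", alt = "A"))
  expect_setequal(p3$ref_read_ids, p$alt_read_ids)
  expect_setequal(p3$alt_read_ids, p$ref_read_ids)
})

test_that("partition conservation holds for random observation sets", {
  set.seed(11)
  snv <- list(chrom = "chr1", pos = 1L, ref = "C", alt = "T")
  for (i in 1:50) {
    n <- sample(1:40, 1)
    obs <- mk_obs(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  q = sample(0:40, n, replace = TRUE))
    g <- gate_candidate_snv(obs, min_reads = 1, min_bq = 10)
    p <- partition_reads(g$observations, snv)
    expect_equal(
      length(p$ref_read_ids) + length(p$alt_read_ids) + p$n_other_base,
      nrow(g$observations)
    )
  }
})

test_that("a splicing variant can serve as its own informative site", {
  v <- list(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  p <- self_informative_site(v, mk_obs(c(rep("A", 5), rep("G", 5))))
  expect_s3_class(p, "allele_partition")
  expect_equal(length(p$ref_read_ids), 5L)

  # gate failure (e.g. intronic variant spliced out of all reads)
  empty <- mk_obs(rep(NA_character_, 12))
  empty$phred_q <- NA_integer_
  expect_null(self_informative_site(v, empty))

  # indels never partition
  expect_null(self_informative_site(
    list(chrom = "chr1", pos = 100L, ref = "AT", alt = "A"),
    mk_obs(rep("A", 12))
  ))
})

test_that("MEC phasing resolves consistent and conflicted read sets", {
  m <- rbind(r1 = c(0, 0), r2 = c(0, 0), r3 = c(1, 1), r4 = c(1, 1))
  b <- phase_informative_sites(m)
  expect_equal(b$mec_cost, 0L)
  expect_equal(unname(b$read_assignment), c(1L, 1L, 2L, 2L))
  expect_equal(b$h[1], 0L)

  # one conflicted read (01): cost 1, tied read unassigned
  m2 <- rbind(m, r5 = c(0, 1))
  b2 <- phase_informative_sites(m2)
  expect_equal(b2$mec_cost, 1L)
  expect_true(is.na(b2$read_assignment["r5"]))
  expect_equal(unname(b2$read_assignment[1:4]), c(1L, 1L, 2L, 2L))

  # complementing the matrix swaps labels only
  b3 <- phase_informative_sites(1 - m)
  expect_equal(b3$mec_cost, 0L)
  expect_equal(unname(b3$read_assignment), c(2L, 2L, 1L, 1L))

  # missing calls carry no cost
  m4 <- matrix(c(0, NA, 1, 0, NA, 1), nrow = 3,
               dimnames = list(paste0("r", 1:3), NULL))
  expect_equal(phase_informative_sites(m4)$mec_cost, 0L)

  # single site is a precondition violation
  expect_error(phase_informative_sites(m[, 1, drop = FALSE]), "at least two")
})

test_that("read assignment is invariant to row order", {
  set.seed(5)
  m <- random_call_matrix(4, 20)
  b <- phase_informative_sites(m)
  perm <- sample(nrow(m))
  b2 <- phase_informative_sites(m[perm, ])
  expect_equal(b2$read_assignment[rownames(m)], b$read_assignment)
  expect_equal(b2$mec_cost, b$mec_cost)
})

test_that("exhaustive search attains the brute-force MEC minimum and the greedy heuristic matches it", {
  set.seed(21)
  for (i in 1:60) {
    S <- sample(2:6, 1)
    m <- random_call_matrix(S, sample(5:20, 1))
    ex <- phase_informative_sites(m, method = "exhaustive")
    expect_equal(ex$mec_cost, oracle_mec_cost(m))
    gr <- phase_informative_sites(m, method = "greedy")
    expect_equal(gr$mec_cost, ex$mec_cost)
  }
})

test_that("phased VCF records encode the block haplotype", {
  m <- matrix(c(0, 0, 1, 1, 1, 1, 0, 0), nrow = 4,
              dimnames = list(paste0("r", 1:4), c("chr1:100", "chr1:200")))
  b <- phase_informative_sites(m)
  expect_equal(b$h, c(0L, 1L))
  vars <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                     ref = c("A", "C"), alt = c("G", "T"),
                     stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  emit_phased_vcf(b, vars, path)
  lines <- readLines(path)
  gt <- vapply(strsplit(grep("^chr1", lines, value = TRUE), "\t"),
               function(x) x[10], character(1))
  expect_equal(gt, c("0|1", "1|0"))

  # a site with no matching variant is an internal consistency error
  expect_error(emit_phased_vcf(b, vars[1, ], tempfile()), "consistency")

  # bgzip output round-trips through vcfR
  gz <- tempfile(fileext = ".vcf.gz")
  emit_phased_vcf(b, vars, gz)
  back <- vcfR::read.vcfR(gz, verbose = FALSE)
  expect_equal(nrow(back@fix), 2L)
})

test_that("mis-partition rate under base errors stays within the Phred bound", {
  # partitioning with per-base error e mis-assigns ~e/3 of reads (only an
  # error matching the other allele's base mis-partitions); must stay well
  # below the 10% worst case implied by the BQ-10 gate
  set.seed(31)
  e <- 0.05
  n <- 4000
  truth <- sample(c("A", "G"), n, replace = TRUE)
  base <- truth
  err <- runif(n) < e
  base[err] <- vapply(truth[err], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  obs <- data.frame(read_id = sprintf("r%05d", 1:n), pos = 1L, base = base,
                    phred_q = 30L, stringsAsFactors = FALSE)
  p <- partition_reads(obs, list(chrom = "c", pos = 1L, ref = "A", alt = "G"))
  mis <- sum(p$ref_read_ids %in% obs$read_id[truth == "G"]) +
    sum(p$alt_read_ids %in% obs$read_id[truth == "A"])
  rate <- mis / (length(p$ref_read_ids) + length(p$alt_read_ids))
  expect_lt(rate, 0.10)
  # and close to e/3 (binomial 3.5-sigma tolerance)
  expect_lt(abs(rate - e / 3), 3.5 * sqrt((e / 3) / n))
})
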