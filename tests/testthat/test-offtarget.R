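test_that("a planted exact protospacer+PAM is found once with 0 mismatches", {
  set.seed(41)
  sp <- rand_dna(20)
  g <- c(chr1 = paste0(rand_dna(50), sp, "TGG", rand_dna(50)))
  # scrub accidental matches is unnecessary at mm 0 for a random 100-mer
  cand <- scan_offtargets(g, sp, max_mm = 0)
  hit <- cand[cand$n_mismatch == 0 & cand$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 51L)
  expect_equal(hit$protospacer, sp)
  expect_equal(hit$pam, "TGG")
})

test_that("sites without a valid PAM are excluded regardless of match", {
  set.seed(42)
  sp <- rand_dna(20)
  g <- c(chr1 = paste0(rand_dna(30), sp, "AGA", rand_dna(30)))
  cand <- scan_offtargets(g, sp, pam = "NGG", max_mm = 0)
  expect_equal(nrow(cand), 0L)
  # dropping the PAM requirement recovers the site
  cand2 <- scan_offtargets(g, sp, pam = NULL, max_mm = 0)
  expect_equal(cand2$start, 31L)
})

test_that("scan equals the exhaustive sliding-window oracle", {
  set.seed(43)
  for (i in 1:4) {
    sp <- rand_dna(20)
    toy <- make_toy_genome(sp, data.frame(mm = c(0, 2, 4, 6),
                                          strand = c("+", "-", "+", "-")),
                           genome_len = 4000, seed = 100 + i)
    want6 <- oracle_scan(toy$genome, sp, max_mm = 6L)
    for (mm in c(0L, 2L, 4L, 6L)) {
      got <- scan_offtargets(toy$genome, sp, max_mm = mm)
      want <- want6[want6$n_mismatch <= mm, , drop = FALSE]
      expect_equal(got$start, want$start, info = paste("mm", mm))
      expect_equal(got$strand, want$strand)
      expect_equal(got$n_mismatch, want$n_mismatch)
    }
  }
})

test_that("scan output is strand-symmetric under genome reverse complement", {
  set.seed(44)
  sp <- rand_dna(20)
  toy <- make_toy_genome(sp, data.frame(mm = c(1, 3), strand = c("+", "-")),
                         genome_len = 3000, seed = 9)
  glen <- nchar(toy$genome[[1]])
  fwd <- scan_offtargets(toy$genome, sp, max_mm = 4)
  rc <- c(chr1 = revcomp(toy$genome[[1]]))
  rev <- scan_offtargets(rc, sp, max_mm = 4)
  # a + site at [s, e] becomes a - site at [glen - e + 1, glen - s + 1]
  mirrored <- sort(glen - fwd$end + 1)
  expect_equal(sort(rev$start), mirrored)
  expect_equal(sort(rev$strand), sort(chartr("+-", "-+", fwd$strand)))
  expect_equal(sort(rev$n_mismatch), sort(fwd$n_mismatch))
})

test_that("minus-strand candidates report stranded and plus coordinates", {
  set.seed(45)
  sp <- rand_dna(20)
  toy <- make_toy_genome(sp, data.frame(mm = 1, strand = "-"),
                         genome_len = 2000, seed = 21)
  cand <- scan_offtargets(toy$genome, sp, max_mm = 1)
  expect_equal(cand$strand, "-")
  expect_equal(cand$start_stranded, cand$end)
  expect_equal(cand$end - cand$start + 1L, 20L)
  # reported protospacer is in its own orientation: mm positions vs spacer
  expect_equal(sum(strsplit(cand$protospacer, "")[[1]] !=
                   strsplit(sp, "")[[1]]), 1L)
})

test_that("SNVs inside 15-match loci are dependent; 14-match are not", {
  set.seed(46)
  sp <- rand_dna(20)
  toy <- make_toy_genome(sp, data.frame(mm = c(5, 6), strand = c("+", "+")),
                         genome_len = 4000, seed = 31)
  t5 <- toy$truth[toy$truth$mm == 5, ]
  t6 <- toy$truth[toy$truth$mm == 6, ]
  snvs <- data.frame(chrom = "chr1",
                     pos = c(t5$start + 5L, t6$start + 5L),
                     ref = "C", alt = "T", stringsAsFactors = FALSE)
  cl <- classify_snvs(snvs, toy$genome, sp, min_matches = 15)
  expect_equal(cl$snvs$class, c("sgRNA_dependent", "sgRNA_independent"))
  # strict > 15 matches demotes the 15-match locus too
  cls <- classify_snvs(snvs, toy$genome, sp, min_matches = 15, strict = TRUE)
  expect_equal(cls$snvs$class[1], "sgRNA_independent")
})

test_that("dependent count is non-increasing in min_matches", {
  set.seed(47)
  sp <- rand_dna(20)
  toy <- make_toy_genome(sp, data.frame(mm = c(0, 2, 4, 5),
                                        strand = c("+", "+", "-", "+")),
                         genome_len = 6000, seed = 41)
  snvs <- data.frame(chrom = "chr1", pos = toy$truth$start + 7L,
                     ref = "C", alt = "T", stringsAsFactors = FALSE)
  prev <- Inf
  for (m in c(10, 14, 15, 16, 18, 20)) {
    cl <- classify_snvs(snvs, toy$genome, sp, min_matches = m)
    ndep <- sum(cl$snvs$class != "sgRNA_independent")
    expect_lte(ndep, prev)
    prev <- ndep
  }
  # min_matches = L: only the perfect site qualifies (as on-target)
  cl20 <- classify_snvs(snvs, toy$genome, sp, min_matches = 20)
  expect_equal(sum(cl20$snvs$class == "on_target"), 1L)
  expect_equal(sum(cl20$snvs$class == "sgRNA_dependent"), 0L)
})

test_that("predicted/observed overlap counts follow locus identity", {
  cand <- data.frame(contig = "chr1", start = c(100L, 300L, 500L),
                     end = c(119L, 319L, 519L), strand = "+",
                     stringsAsFactors = FALSE)
  snvs <- data.frame(chrom = "chr1", pos = 305L, ref = "C", alt = "T",
                     stringsAsFactors = FALSE)
  v <- compare_predicted_observed(cand, snvs)
  expect_equal(v$both, 1L)
  expect_equal(v$predicted_only, 2L)
  expect_equal(v$observed_only, 0L)
  # disjoint sets
  v2 <- compare_predicted_observed(cand,
                                   data.frame(chrom = "chr1", pos = 9999L))
  expect_equal(v2$both, 0L)
  expect_equal(v2$observed_only, 1L)
})

test_that("SNV signature ratio collapses strands", {
  df <- data.frame(ref = c("C", "C", "C", "A"), alt = c("T", "T", "T", "G"))
  expect_equal(snv_type_ratio(df), 0.75)
  expect_equal(snv_type_ratio(data.frame(ref = "G", alt = "A")), 1)  # - strand C>T
  expect_equal(snv_type_ratio(data.frame(ref = c("A", "T"),
                                         alt = c("G", "C")), "ABE"), 1)
  expect_message(r <- snv_type_ratio(df[0, ]), "undefined")
  expect_true(is.na(r))
})

test_that("minimal VCF round-trips through write and read", {
  snvs <- data.frame(chrom = "chr1", pos = c(10L, 99L), ref = c("C", "G"),
                     alt = c("T", "A"), freq = c(0.25, NA),
                     stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_snv_vcf(snvs, f, contig_lengths = c(chr1 = 1000L))
  back <- read_snvs(f)
  expect_equal(back$pos, snvs$pos)
  expect_equal(back$ref, snvs$ref)
  expect_equal(back$alt, snvs$alt)
  expect_equal(back$freq, snvs$freq)
  # TSV input path
  f2 <- tempfile(fileext = ".tsv")
  write.table(snvs, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_snvs(f2)$pos, snvs$pos)
})
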