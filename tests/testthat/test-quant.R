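test_that("identity reads align with no substitutions or indels", {
  set.seed(31)
  ref <- make_ref_with_proto(proto_bases = c("6" = "C"))
  loc <- amplicon_locus("s", ref, 80, 99, "+", "CBE")
  aln <- align_reads(c(r1 = ref, r2 = ref), loc)
  expect_equal(nrow(aln$substitutions), 0L)
  expect_equal(nrow(aln$indels), 0L)
  expect_true(all(aln$reads$pass))
})

test_that("a planted substitution is recovered at its reference position", {
  set.seed(32)
  ref <- make_ref_with_proto(proto_bases = c("6" = "C"))
  read <- ref
  substr(read, 85, 85) <- "T"  # protospacer position 6 (start 80)
  loc <- amplicon_locus("s", ref, 80, 99, "+", "CBE")
  aln <- align_reads(c(r1 = read), loc)
  expect_equal(aln$substitutions$ref_pos, 85L)
  expect_equal(aln$substitutions$ref_base, "C")
  expect_equal(aln$substitutions$read_base, "T")
})

test_that("deletions are recorded once and left-aligned in homopolymers", {
  ref <- paste0(strrep("GC", 30), "TTAAAAACG", strrep("GA", 30))
  # delete two of the five As: leftmost placement is the first A (ref 63)
  read <- paste0(strrep("GC", 30), "TTAAACG", strrep("GA", 30))
  loc <- amplicon_locus("s", ref, 55, 74, "+", "CBE")
  aln <- align_reads(c(r1 = read), loc)
  expect_equal(nrow(aln$indels), 1L)
  expect_equal(aln$indels$type, "del")
  expect_equal(aln$indels$length, 2L)
  expect_equal(aln$indels$ref_pos, 63L)
  expect_equal(aln$indels$seq, "AA")
})

test_that("insertions are recovered with reference anchor and sequence", {
  set.seed(33)
  ref <- make_ref_with_proto()
  read <- paste0(substr(ref, 1, 90), "CTG", substr(ref, 91, 200))
  loc <- amplicon_locus("s", ref, 80, 99, "+", "CBE")
  aln <- align_reads(c(r1 = read), loc)
  ins <- aln$indels[aln$indels$type == "ins", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$length, 3L)
  # left-alignment may rotate the insertion within a repeat; re-applying
  # it to the reference must reproduce the read
  rebuilt <- paste0(substr(ref, 1, ins$ref_pos), ins$seq,
                    substr(ref, ins$ref_pos + 1, 200))
  expect_equal(rebuilt, read)
})

test_that("window statistic counts reads with canonical window edits only", {
  set.seed(34)
  ref <- make_ref_with_proto(proto_bases = c("2" = "C", "6" = "C"))
  loc <- amplicon_locus("s", ref, 80, 99, "+", "CBE")
  edit_at <- function(p, to = "T") {
    r <- ref; substr(r, 79 + p, 79 + p) <- to; r
  }
  # 3 reads edited at C6 (window), 1 at C2 (outside window), 6 unedited
  reads <- c(replicate(3, edit_at(6)), edit_at(2), replicate(6, ref))
  names(reads) <- paste0("r", 1:10)
  prof <- tally(align_reads(reads, loc))
  expect_equal(prof$n_pass, 10L)
  expect_equal(prof$n_window_edited, 3L)
  expect_equal(prof$window_freq, 0.3)
  cf <- conversion_freqs(prof, positions = c(2, 6))
  expect_equal(cf$freq_T, c(0.1, 0.3))
  # all unedited
  prof0 <- tally(align_reads(setNames(rep(ref, 10), paste0("u", 1:10)), loc))
  expect_equal(prof0$window_freq, 0)
  # non-canonical window substitution is not an "edit" by default...
  profG <- tally(align_reads(c(r1 = edit_at(6, "G"), r2 = ref), loc))
  expect_equal(profG$n_window_edited, 0L)
  # ...but counts under --any-substitution semantics
  expect_equal(tally(align_reads(c(r1 = edit_at(6, "G"), r2 = ref), loc),
                     any_substitution = TRUE)$n_window_edited, 1L)
})

test_that("window frequency is invariant to read order and duplication", {
  set.seed(35)
  ref <- make_ref_with_proto(proto_bases = c("6" = "C"))
  loc <- amplicon_locus("s", ref, 80, 99, "+", "CBE")
  e <- ref; substr(e, 85, 85) <- "T"
  reads <- setNames(c(e, e, ref, ref, ref), paste0("r", 1:5))
  f1 <- tally(align_reads(reads, loc))$window_freq
  f2 <- tally(align_reads(rev(reads), loc))$window_freq
  f3 <- tally(align_reads(setNames(rep(reads, 3), paste0("d", 1:15)),
                          loc))$window_freq
  expect_equal(f1, 0.4)
  expect_equal(f2, f1)
  expect_equal(f3, f1)
})

test_that("minus-strand loci give the same profile as the mirrored plus locus", {
  set.seed(36)
  # protospacer on the minus strand at plus 80..99 with C at protospacer
  # position 6: the plus-strand base at proto_end - 6 + 1 = 94 must be G
  refm <- strsplit(make_ref_with_proto(), "")[[1]]
  refm[94] <- "G"
  refm <- paste(refm, collapse = "")
  locm <- amplicon_locus("m", refm, 80, 99, "-", "CBE")
  readm <- refm; substr(readm, 94, 94) <- "A"   # C>T on protospacer strand
  profm <- tally(align_reads(c(r1 = readm, r2 = refm), locm))
  # mirrored plus-strand construction
  refp <- revcomp(refm)
  locp <- amplicon_locus("p", refp, 201 - 99, 201 - 80, "+", "CBE")
  profp <- tally(align_reads(c(r1 = revcomp(readm), r2 = refp), locp))
  expect_equal(profm$window_freq, 0.5)
  expect_equal(profp$window_freq, profm$window_freq)
  expect_equal(profp$positions$ref_base, profm$positions$ref_base)
  expect_equal(profp$positions[, c("A", "C", "G", "T")],
               profm$positions[, c("A", "C", "G", "T")])
})

test_that("quality masking at threshold 0 reproduces unmasked counts", {
  set.seed(37)
  ref <- make_ref_with_proto(proto_bases = c("6" = "C"))
  loc <- amplicon_locus("s", ref, 80, 99, "+", "CBE")
  e <- ref; substr(e, 85, 85) <- "T"
  reads <- setNames(c(e, ref), c("r1", "r2"))
  lowq <- strrep(rawToChar(as.raw(33 + 10)), 200)  # Q10 everywhere
  qr <- qreads(reads, rep(lowq, 2))
  aln <- align_reads(qr, loc, min_mean_qual = 0)
  expect_equal(tally(aln, min_qual = 20)$n_window_edited, 0L)  # masked
  expect_equal(tally(aln, min_qual = 0)$n_window_edited, 1L)   # unmasked
  # and low mean quality fails reads under the default filter
  expect_equal(sum(align_reads(qr, loc)$reads$pass), 0L)
})

test_that("reads not covering the protospacer are flagged, not dropped", {
  set.seed(38)
  ref <- make_ref_with_proto()
  loc <- amplicon_locus("s", ref, 80, 99, "+", "CBE")
  aln <- align_reads(c(full = ref, part = substr(ref, 90, 200)), loc)
  expect_equal(aln$reads$pass, c(TRUE, FALSE))
  expect_equal(tally(aln)$n_pass, 1L)
})

test_that("by-product table separates canonical from undesired conversions", {
  set.seed(39)
  ref <- make_ref_with_proto(proto_bases = c("6" = "C"))
  loc <- amplicon_locus("s", ref, 80, 99, "+", "CBE")
  eT <- ref; substr(eT, 85, 85) <- "T"
  eG <- ref; substr(eG, 85, 85) <- "G"
  reads <- setNames(c(rep(eT, 10), rep(eG, 1), rep(ref, 9)), paste0("r", 1:20))
  bp <- byproduct_table(tally(align_reads(reads, loc)))
  row6 <- bp[bp$position == 6, ]
  expect_equal(row6$canonical, 0.5)
  expect_equal(row6$to_G, 0.05)
  expect_equal(row6$undesired, 0.05)
  # all-canonical case has zero undesired everywhere
  bp2 <- byproduct_table(tally(align_reads(
    setNames(c(eT, ref), c("a", "b")), loc)))
  expect_true(all(bp2$undesired[bp2$depth > 0] == 0))
})

test_that("specificity metrics reproduce fold-reduction arithmetic", {
  m <- specificity_metrics(on = 0.94, offs = c(OT1 = 0.114),
                           comparator_offs = c(OT1 = 0.57))
  expect_equal(m$fold_reduction, 5.0)
  expect_false(m$censored)
  # identical profiles: fold change 1
  m2 <- specificity_metrics(0.9, c(OT1 = 0.2), c(OT1 = 0.2))
  expect_equal(m2$fold_reduction, 1)
  # below the detection floor: censored lower bound comparator/floor
  m3 <- specificity_metrics(0.9, c(OT1 = 0), c(OT1 = 0.57), floor = 0.001)
  expect_true(m3$censored)
  expect_equal(m3$fold_reduction, 0.57 / 0.001)
})

test_that("replicate statistics and the t test match closed forms", {
  rs <- replicate_stats(c(1, 1, 1))
  expect_equal(rs$mean, 1)
  expect_equal(rs$sem, 0)
  rs2 <- replicate_stats(c(2, 4, 6))
  expect_equal(rs2$mean, 4)
  expect_equal(rs2$sem, 2 / sqrt(3))
  expect_error(replicate_stats(5), "2 replicates")
  tt <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  # pooled-df Student form: df = n1 + n2 - 2
  expect_equal(two_sample_ttest(c(1, 2, 3), c(4, 5, 6, 7))$df, 5)
})
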