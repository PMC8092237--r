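test_that("hairpin-to-protospacer coordinate map is the stated reflection", {
  expect_equal(hairpin_to_protospacer(6, 12), 7)
  expect_equal(hairpin_to_protospacer(8, 12), 5)
  expect_equal(hairpin_to_protospacer(1, 1), 1)
  expect_equal(hairpin_to_protospacer(12, 12), 1)
  # involution / bijection on 1..H
  for (H in c(2L, 5L, 12L)) {
    p <- seq_len(H)
    expect_equal(sort(hairpin_to_protospacer(p, H)), p)
    expect_equal(hairpin_to_protospacer(hairpin_to_protospacer(p, H), H), p)
  }
  expect_error(hairpin_to_protospacer(13, 12), "range")
})

test_that("bubble nucleotide choice excludes WC and wobble partners", {
  expect_equal(choose_bubble_nt("A"), "C")  # U excluded
  expect_equal(choose_bubble_nt("G"), "A")  # C (WC) and U (wobble) excluded
  expect_equal(choose_bubble_nt("U"), "C")  # A (WC) and G (wobble) excluded
  expect_equal(choose_bubble_nt("C"), "C")  # G excluded; C-C mismatch fine
  for (o in c("A", "C", "G", "U"))
    expect_false(bases_pair(choose_bubble_nt(o), o, wobble = TRUE))
})

test_that("default CBE and ABE designs match the published constants", {
  cbe <- build_bh_sgrna(strrep("A", 20), design_spec("CBE"))
  expect_equal(nchar(cbe$extension), 12L)
  expect_equal(cbe$loop, "ACAA")
  expect_equal(cbe$extension, "UUUUUCCCUUUU")
  expect_equal(substr(cbe$full, 1, 16), "UUUUUCCCUUUUACAA")
  expect_equal(cbe$bubble_hairpin, 6:8)
  expect_equal(cbe$bubble_protospacer, 5:7)
  expect_equal(cbe$name, "H12-B3-P5")

  abe <- build_bh_sgrna(strrep("A", 20), design_spec("ABE"))
  expect_equal(abe$bubble_hairpin, 7:9)
  expect_equal(abe$bubble_protospacer, 4:6)
  expect_equal(abe$name, "H12-B3-P4")

  h2 <- build_bh_sgrna(strrep("A", 20),
                       design_spec("CBE", hairpin_len = 2, bubble_size = 0))
  expect_equal(h2$name, "H2")
  expect_equal(h2$extension, "UU")
})

test_that("pairing invariants hold on random spacers", {
  set.seed(7)
  for (i in 1:50) {
    sp <- rand_rna(20)
    for (ed in c("CBE", "ABE")) {
      d <- build_bh_sgrna(sp, design_spec(ed))
      H <- d$spec$hairpin_len
      ext <- strsplit(d$extension, "")[[1]]
      spr <- strsplit(d$spacer, "")[[1]]
      for (p in seq_len(H)) {
        opp <- spr[hairpin_to_protospacer(p, H)]
        if (p %in% d$bubble_hairpin) {
          expect_false(bases_pair(ext[p], opp, wobble = TRUE))
        } else {
          expect_true(bases_pair(ext[p], opp, wobble = FALSE))
        }
      }
    }
  }
})

test_that("design spec validation enforces the bubble-in-stem invariant", {
  expect_error(design_spec("CBE", hairpin_len = 12, bubble_size = 3,
                           bubble_start = 11), "P \\+ B - 1")
  expect_error(design_spec("CBE", hairpin_len = 13), "0..12")
  expect_warning(design_spec("CBE", hairpin_len = 4, bubble_size = 0,
                             bubble_start = 2), "ignored")
  expect_error(build_bh_sgrna(strrep("A", 10), design_spec("CBE")),
               "18..24")
  expect_error(build_bh_sgrna("AAAAAAAAAAAAAAAAAAAN", design_spec("CBE")),
               "residue")
})

test_that("design names round-trip across the whole default grid", {
  expect_equal(name_design(design_spec("CBE")), "H12-B3-P5")
  expect_equal(name_design(design_spec("CBE", 4, 0)), "H4")
  expect_equal(name_design(design_spec("CBE", 0, 0)), "WT")
  expect_error(parse_design_name("H12-B3"), "malformed")
  designs <- enumerate_series(strrep("A", 20), "CBE")
  for (nm in names(designs)) {
    spec <- parse_design_name(nm)
    expect_equal(name_design(spec), nm)
    expect_equal(spec$hairpin_len, designs[[nm]]$spec$hairpin_len)
    expect_equal(spec$bubble_size, designs[[nm]]$spec$bubble_size)
  }
})

test_that("series enumeration counts valid (H, B, P) combinations", {
  s5 <- enumerate_series(strrep("A", 20), "CBE",
                         H_set = 12, B_set = 3, P_set = 4:8)
  expect_equal(names(s5), paste0("H12-B3-P", 4:8))
  expect_equal(names(enumerate_series(strrep("A", 20), "CBE", H_set = 0)),
               "WT")
  full <- enumerate_series(strrep("A", 20), "CBE")
  # WT + 6 plain hairpins + valid bubble combos with P + B - 1 <= H
  n_bubble <- sum(vapply(c(2, 4, 6, 8, 10, 12), function(H)
    sum(outer(1:3, 4:8, function(B, P) P + B - 1 <= H)), numeric(1)))
  expect_equal(length(full), 1 + 6 + n_bubble)
  expect_false(any(duplicated(names(full))))
})

test_that("user-supplied bubbles are validated by the pairing predicate", {
  sp <- strrep("A", 20)
  ok <- build_bh_sgrna(sp, design_spec("CBE"), bubble_seq = "CCC")
  expect_equal(substr(ok$extension, 6, 8), "CCC")
  expect_error(build_bh_sgrna(sp, design_spec("CBE"), bubble_seq = "UUU"),
               "pairs")
  expect_error(build_bh_sgrna(sp, design_spec("CBE"), bubble_seq = "CC"),
               "length")
})

test_that("mismatched guides differ at exactly the requested positions", {
  sp <- rand_dna(20)
  tab <- enumerate_mismatched_guides(sp, list(1, c(5, 9), c(1, 8, 15)))
  expect_equal(tab$n_mismatch, 1:3)
  for (i in seq_len(nrow(tab))) {
    a <- strsplit(sp, "")[[1]]
    b <- strsplit(tab$sequence[i], "")[[1]]
    d <- which(a != b)
    expect_equal(d, as.integer(strsplit(tab$positions[i], ",")[[1]]))
  }
  # transversion-first rule on a poly-A spacer
  t1 <- enumerate_mismatched_guides(strrep("A", 20), 5)
  expect_equal(substr(t1$sequence, 5, 5), "C")
  expect_error(enumerate_mismatched_guides(sp, c(3, 3)), "duplicate")
  expect_error(enumerate_mismatched_guides(sp, 1:4), "1..3")
  # explicit nucleotides override the rule
  t2 <- enumerate_mismatched_guides(strrep("A", 20), list(5), list("G"))
  expect_equal(substr(t2$sequence, 5, 5), "G")
})
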