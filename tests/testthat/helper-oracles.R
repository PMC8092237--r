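# Independent oracles and small fixture builders used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# A random spacer without strong self-similarity: planting near-copies of
# a quasi-palindromic or self-overlapping spacer creates unavoidable
# extra hits on the opposite strand / at shifted offsets, which would make
# exact planted-truth bookkeeping ill-posed rather than reveal a scan bug.
rand_spacer_clean <- function(L = 20L, max_self = 12L) {
  repeat {
    sp <- strsplit(rand_dna(L), "")[[1]]
    rc <- rev(chartr("ACGT", "TGCA", sp))
    ok <- TRUE
    for (d in 0:(L - 6L)) {
      n <- L - d
      if (sum(sp[1:n] == rc[(d + 1):(d + n)]) > max_self ||
          sum(sp[(d + 1):(d + n)] == rc[1:n]) > max_self) { ok <- FALSE; break }
      if (d > 0L &&
          (sum(sp[1:n] == sp[(d + 1):(d + n)]) > max_self ||
           sum(sp[(d + 1):(d + n)] == sp[1:n]) > max_self)) { ok <- FALSE; break }
    }
    if (ok) return(paste(sp, collapse = ""))
  }
}
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")

# Brute-force maximum base-pair count by exhaustive recursion over all
# non-crossing structures (no dynamic programming, no memoisation).
brute_max_pairs <- function(seq, min_loop = 3L, wobble = TRUE) {
  res <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(res)
  can <- outer(res, res, function(a, b) bases_pair(a, b, wobble = wobble))
  rec <- function(lo, hi) {
    if (hi - lo <= min_loop) return(0L)
    best <- rec(lo + 1L, hi)              # lo unpaired
    js <- (lo + min_loop + 1L):hi
    for (j in js[can[lo, js]]) {
      best <- max(best, 1L + rec(lo + 1L, j - 1L) + rec(j + 1L, hi))
    }
    best
  }
  rec(1L, n)
}

# Exhaustive sliding-window off-target scan working on per-position
# character vectors, independent of the Biostrings matching used by
# scan_offtargets(). Character-level: no pattern matching involved.
oracle_scan <- function(genome, spacer, pam = "NGG", max_mm = 4L) {
  L <- nchar(spacer)
  sp <- strsplit(spacer, "")[[1]]
  rc1 <- function(v) rev(chartr("ACGT", "TGCA", v))  # on character vectors
  sp_rc <- rc1(sp)
  pam_res <- if (is.null(pam)) character(0) else strsplit(pam, "")[[1]]
  plen <- length(pam_res)
  pam_ok <- function(xx) all(pam_res == "N" | xx == pam_res)
  hits <- list()
  for (ctg in names(genome)) {
    g <- strsplit(toupper(genome[[ctg]]), "")[[1]]
    glen <- length(g)
    if (glen < L) next
    for (st in seq_len(glen - L + 1L)) {
      win <- g[st:(st + L - 1L)]
      # + strand: protospacer at st, PAM 3'
      mm <- sum(win != sp)
      if (mm <= max_mm && st + L - 1L + plen <= glen &&
          (plen == 0L || pam_ok(g[(st + L):(st + L + plen - 1L)])))
        hits[[length(hits) + 1L]] <- data.frame(
          contig = ctg, start = st, strand = "+", n_mismatch = mm,
          stringsAsFactors = FALSE)
      # - strand: window equals revcomp(protospacer); PAM 5', revcomp'd
      mm <- sum(win != sp_rc)
      if (mm <= max_mm && st - plen >= 1L &&
          (plen == 0L || pam_ok(rc1(g[(st - plen):(st - 1L)]))))
        hits[[length(hits) + 1L]] <- data.frame(
          contig = ctg, start = st, strand = "-", n_mismatch = mm,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), n_mismatch = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# Reference amplicon with a protospacer carrying chosen bases at chosen
# protospacer positions (plus strand).
make_ref_with_proto <- function(len = 200L, proto_start = 80L,
                                proto_bases = c()) {
  ref <- strsplit(rand_dna(len), "")[[1]]
  for (p in names(proto_bases))
    ref[proto_start + as.integer(p) - 1L] <- proto_bases[[p]]
  paste(ref, collapse = "")
}

qreads <- function(reads, quals) {
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads), Biostrings::PhredQuality(quals))
}
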