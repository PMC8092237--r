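#' @title Synthetic data generators with known truth
#' @name synthetic
#' @description Simulators for edited amplicon read sets, toy genomes with
#'   planted off-target loci, and SNV lists with known class labels. Every
#'   generator takes an explicit seed and is byte-reproducible, so each
#'   pipeline stage can be tested end to end against planted truth without
#'   any external data. Reads are single-end full-length amplicons with
#'   constant base quality (Q30 by default); the sequencing error rate is
#'   an independent knob, deliberately decoupled from the quality string.
NULL

.sample_bases <- function(n) sample(.DNA_BASES, n, replace = TRUE)

## substitute to a uniformly chosen different base
.mutate_base <- function(base) {
  vapply(base, function(b) sample(setdiff(.DNA_BASES, b), 1L), "",
         USE.NAMES = FALSE)
}

#' Simulate edited amplicon reads
#'
#' Draws reads from an amplicon reference, planting canonical edits
#' (C>T for CBE, A>G for ABE, on the protospacer strand) independently per
#' read and position at the configured rates, non-canonical ("undesired")
#' substitutions at target bases, at most one indel per read inside the
#' protospacer, and uniform sequencing errors. The per-read truth is
#' returned alongside the reads.
#'
#' @param locus an [amplicon_locus()].
#' @param n_reads number of reads.
#' @param edit_rates named numeric vector: canonical edit rate per
#'   protospacer position, e.g. `c("6" = 0.3)`. Positions must hold the
#'   editor's target base on the protospacer strand.
#' @param undesired_rate rate of non-canonical substitution at each
#'   target-base position; default 0.
#' @param indel_rate per-read probability of one indel (deletion or
#'   insertion, equal odds) inside the protospacer; default 0.
#' @param indel_len_max indel lengths are drawn uniformly from
#'   `1:indel_len_max`; default 3.
#' @param error_rate per-base uniform sequencing error rate; default 0.
#' @param seed integer seed (mandatory).
#' @param qual constant Phred quality of every base; default 30.
#' @param fastq optional path: write reads as FASTQ.
#' @param truth_tsv optional path: write the truth table as TSV.
#' @return List with `reads` (named character), `quals` (Phred+33
#'   strings), `truth` (data frame: id, window_edited, edited_positions,
#'   indel type/pos/len), and the arguments echoed in `config`.
#' @export
simulate_amplicon_reads <- function(locus, n_reads, edit_rates,
                                    undesired_rate = 0, indel_rate = 0,
                                    indel_len_max = 3L, error_rate = 0,
                                    seed, qual = 30L, fastq = NULL,
                                    truth_tsv = NULL) {
  stopifnot(inherits(locus, "amplicon_locus"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) stop("n_reads must be >= 1", call. = FALSE)
  rates <- c(edit_rates, undesired_rate, indel_rate, error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))

  ref_res <- strsplit(locus$reference, "", fixed = TRUE)[[1L]]
  reflen <- length(ref_res)
  proto <- strsplit(proto_seq(locus), "", fixed = TRUE)[[1L]]
  target <- if (locus$editor == "CBE") "C" else "A"
  canon_to <- if (locus$editor == "CBE") "T" else "G"
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  edit_pos <- as.integer(names(edit_rates))
  if (length(edit_pos)) {
    check_proto_pos(edit_pos, locus$L)
    off_target_base <- proto[edit_pos] != target
    if (any(off_target_base))
      stop(sprintf("protospacer position %d does not hold the %s target base %s",
                   edit_pos[which(off_target_base)[1L]], locus$editor, target),
           call. = FALSE)
  }
  ## protospacer position -> reference position and strand-aware bases
  p2ref <- function(p) if (locus$strand == "+") locus$proto_start + p - 1L
                       else locus$proto_end - p + 1L
  strand_base <- function(b) if (locus$strand == "+") b else unname(comp[b])

  mat <- matrix(rep(ref_res, n_reads), nrow = n_reads, byrow = TRUE)
  edited <- matrix(FALSE, nrow = n_reads, ncol = locus$L)

  for (k in seq_along(edit_pos)) {
    p <- edit_pos[k]
    hit <- runif(n_reads) < edit_rates[k]
    mat[hit, p2ref(p)] <- strand_base(canon_to)
    edited[hit, p] <- TRUE
  }
  if (undesired_rate > 0) {
    others <- setdiff(.DNA_BASES, c(target, canon_to))
    for (p in which(proto == target)) {
      hit <- which(runif(n_reads) < undesired_rate & !edited[, p])
      if (length(hit))
        mat[cbind(hit, p2ref(p))] <-
          strand_base(sample(others, length(hit), replace = TRUE))
    }
  }
  if (error_rate > 0) {
    err <- which(matrix(runif(n_reads * reflen) < error_rate,
                        nrow = n_reads), arr.ind = TRUE)
    if (nrow(err))
      mat[err] <- .mutate_base(mat[err])
  }

  ## collapse rows, then apply at most one indel per read
  reads <- apply(mat, 1L, paste, collapse = "")
  indel_type <- rep(NA_character_, n_reads)
  indel_pos <- rep(NA_integer_, n_reads)
  indel_len <- rep(NA_integer_, n_reads)
  if (indel_rate > 0) {
    has <- which(runif(n_reads) < indel_rate)
    for (i in has) {
      type <- sample(c("del", "ins"), 1L)
      len <- sample.int(indel_len_max, 1L)
      pos <- sample(locus$proto_start:(locus$proto_end - len), 1L)
      if (type == "del") {
        reads[i] <- paste0(substr(reads[i], 1L, pos - 1L),
                           substr(reads[i], pos + len, reflen))
      } else {
        reads[i] <- paste0(substr(reads[i], 1L, pos),
                           paste(.sample_bases(len), collapse = ""),
                           substr(reads[i], pos + 1L, reflen))
      }
      indel_type[i] <- type
      indel_pos[i] <- pos
      indel_len[i] <- len
    }
  }

  names(reads) <- sprintf("read%06d", seq_len(n_reads))
  quals <- vapply(nchar(reads), function(w)
    strrep(rawToChar(as.raw(qual + 33L)), w), "")
  win_edit <- apply(edited[, locus$window, drop = FALSE], 1L, any)
  truth <- data.frame(
    id = names(reads),
    window_edited = win_edit,
    edited_positions = apply(edited, 1L, function(e)
      paste(which(e), collapse = ",")),
    indel_type = indel_type, indel_pos = indel_pos, indel_len = indel_len,
    stringsAsFactors = FALSE)

  if (!is.null(fastq)) write_fastq(reads, quals, fastq)
  if (!is.null(truth_tsv))
    write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(reads = reads, quals = quals, truth = truth,
       config = list(n_reads = n_reads, edit_rates = edit_rates,
                     undesired_rate = undesired_rate,
                     indel_rate = indel_rate, error_rate = error_rate,
                     seed = as.integer(seed), qual = qual))
}

## Hamming distance of every window of `gseq` to `pat` (character scalars),
## vectorised over start positions; returns integer vector of length
## nchar(gseq) - L + 1
.hamming_profile <- function(gseq, pat) {
  g <- strsplit(gseq, "", fixed = TRUE)[[1L]]
  p <- strsplit(pat, "", fixed = TRUE)[[1L]]
  L <- length(p)
  n <- length(g) - L + 1L
  if (n < 1L) return(integer(0L))
  mm <- integer(n)
  for (i in seq_len(L))
    mm <- mm + (g[i:(i + n - 1L)] != p[i])
  mm
}

#' Build a toy genome with planted off-target loci
#'
#' Generates a uniform-composition random genome, scrubs it so every
#' window on either strand is at least `clean_min_mm` mismatches from the
#' spacer (rejection resampling of offending windows), then plants sites
#' with exactly the requested mismatch counts, each followed by a concrete
#' PAM, on the requested strands. The scrub margin makes oracle tests
#' exact: a scan at `max_mm <= clean_min_mm - 2` can only ever report
#' planted sites.
#'
#' @param spacer 20-nt spacer (DNA or RNA spelling).
#' @param planted data frame with columns `mm` (exact mismatch count) and
#'   `strand` (`"+"`/`"-"`); one row per site. Empty data frame plants
#'   nothing.
#' @param genome_len genome length; default 20000.
#' @param pam PAM pattern for the planted sites; `N` positions are drawn
#'   uniformly. Default `"NGG"`.
#' @param clean_min_mm minimum mismatches of every background window to
#'   the spacer; default 8.
#' @param seed integer seed (mandatory).
#' @param contig contig name; default `"chr1"`.
#' @param fasta,truth_tsv optional output paths.
#' @return List with `genome` (named character vector), `truth` (data
#'   frame: contig, start, end, strand, mm, protospacer, pam,
#'   mismatch_positions -- coordinates as in [scan_offtargets()]), and
#'   `spacer`.
#' @export
make_toy_genome <- function(spacer, planted = data.frame(mm = integer(0L),
                                                         strand = character(0L)),
                            genome_len = 20000L, pam = "NGG",
                            clean_min_mm = 8L, seed, contig = "chr1",
                            fasta = NULL, truth_tsv = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  spacer <- rev_transcribe(check_seq(transcribe(spacer), "RNA",
                                     what = "spacer"))
  L <- nchar(spacer)
  pam <- check_seq(pam, "DNA", allow_n = TRUE, what = "pam")
  plen <- nchar(pam)
  site_len <- L + plen
  genome_len <- as.integer(genome_len)
  n_sites <- nrow(planted)
  if (genome_len < (site_len + 2L * L) * max(1L, n_sites))
    stop("genome too short for the requested planted sites", call. = FALSE)
  if (n_sites && any(planted$mm > L))
    stop("planted mismatch count exceeds spacer length", call. = FALSE)
  set.seed(as.integer(seed))

  sp_rc <- revcomp(spacer)
  scrub <- function(g) {
    for (iter in 1:100) {
      gseq <- paste(g, collapse = "")
      bad <- unique(c(which(.hamming_profile(gseq, spacer) < clean_min_mm),
                      which(.hamming_profile(gseq, sp_rc) < clean_min_mm)))
      if (!length(bad)) return(g)
      for (b in bad) g[b:(b + L - 1L)] <- .sample_bases(L)
    }
    stop("could not scrub background within 100 rounds", call. = FALSE)
  }
  g <- scrub(.sample_bases(genome_len))

  truth <- data.frame(contig = character(0L), start = integer(0L),
                      end = integer(0L), strand = character(0L), mm = integer(0L),
                      protospacer = character(0L), pam = character(0L),
                      mismatch_positions = character(0L),
                      stringsAsFactors = FALSE)
  for (attempt in 1:100) {
    # a fresh background escapes layouts poisoned by chance near-matches
    # (e.g. planted-site echoes of partially self-complementary spacers)
    if (attempt %% 10L == 0L) g <- scrub(.sample_bases(genome_len))
    gg <- g
    rows <- vector("list", n_sites)
    occupied <- integer(0L)
    ok <- TRUE
    for (k in seq_len(n_sites)) {
      # keep sites L bp clear of each other and of the contig ends
      slot <- NULL
      for (try in 1:200) {
        cand <- sample((L + 1L):(genome_len - site_len - L), 1L)
        if (!any(abs(cand - occupied) < site_len + L)) { slot <- cand; break }
      }
      if (is.null(slot)) { ok <- FALSE; break }
      occupied <- c(occupied, slot)

      mm <- as.integer(planted$mm[k])
      strand <- as.character(planted$strand[k])
      proto <- strsplit(spacer, "", fixed = TRUE)[[1L]]
      mm_pos <- sort(sample.int(L, mm))
      proto[mm_pos] <- .mutate_base(proto[mm_pos])
      pam_res <- strsplit(pam, "", fixed = TRUE)[[1L]]
      pam_res[pam_res == "N"] <- .sample_bases(sum(pam_res == "N"))
      site <- paste(c(proto, pam_res), collapse = "")
      if (strand == "-") {
        ins <- revcomp(site)
        start <- slot + plen          # + strand start of the protospacer
      } else {
        ins <- site
        start <- slot
      }
      gg[slot:(slot + site_len - 1L)] <- strsplit(ins, "", fixed = TRUE)[[1L]]
      rows[[k]] <- data.frame(
        contig = contig, start = start, end = start + L - 1L,
        strand = strand, mm = mm, protospacer = paste(proto, collapse = ""),
        pam = paste(pam_res, collapse = ""),
        mismatch_positions = paste(mm_pos, collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (!ok) next
    ## verify planting introduced no accidental near-matches elsewhere
    gseq <- paste(gg, collapse = "")
    prof_f <- .hamming_profile(gseq, spacer)
    prof_r <- .hamming_profile(gseq, sp_rc)
    truth_k <- do.call(rbind, c(rows, list(truth)))
    plus_starts <- if (n_sites) truth_k$start[truth_k$strand == "+"] else integer(0L)
    minus_starts <- if (n_sites) truth_k$start[truth_k$strand == "-"] else integer(0L)
    near_f <- which(prof_f < clean_min_mm)
    near_r <- which(prof_r < clean_min_mm)
    if (setequal(near_f, plus_starts[truth_k$mm[truth_k$strand == "+"] < clean_min_mm]) &&
        setequal(near_r, minus_starts[truth_k$mm[truth_k$strand == "-"] < clean_min_mm])) {
      g <- gg
      if (n_sites) {
        truth <- truth_k
        truth <- truth[order(truth$start), , drop = FALSE]
        rownames(truth) <- NULL
      }
      genome <- setNames(paste(g, collapse = ""), contig)
      if (!is.null(fasta)) write_fasta(genome, fasta)
      if (!is.null(truth_tsv))
        write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                    row.names = FALSE)
      return(list(genome = genome, truth = truth, spacer = spacer))
    }
  }
  stop("could not place planted sites cleanly within 100 attempts",
       call. = FALSE)
}

#' Simulate SNVs with known dependence labels
#'
#' Places `n_dependent` SNVs inside qualifying planted loci (those within
#' `L - min_matches` mismatches of the spacer) and `n_independent` SNVs at
#' least `L` bp away from every qualifying locus. SNVs carry the CBE
#' signature: C>T on the protospacer strand, which reads as G>A on the +
#' strand for `-` strand loci; where the drawn position holds no C, the
#' reference base is mutated to a random different base.
#'
#' @param toy a [make_toy_genome()] result.
#' @param n_dependent,n_independent SNV counts per class.
#' @param min_matches qualifying-similarity threshold; default 15.
#' @param seed integer seed (mandatory).
#' @param vcf,truth_tsv optional output paths.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `freq`,
#'   `truth_class` (`sgRNA_dependent` / `sgRNA_independent` /
#'   `on_target`).
#' @export
simulate_snvs <- function(toy, n_dependent, n_independent,
                          min_matches = 15L, seed, vcf = NULL,
                          truth_tsv = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  L <- nchar(toy$spacer)
  qual_loci <- toy$truth[toy$truth$mm <= L - min_matches, , drop = FALSE]
  if (n_dependent > 0L && !nrow(qual_loci))
    stop("dependent SNVs require at least one qualifying planted locus",
         call. = FALSE)
  contig <- names(toy$genome)[1L]
  gseq <- toy$genome[[1L]]
  g <- strsplit(gseq, "", fixed = TRUE)[[1L]]

  rows <- list()
  if (n_dependent > 0L) {
    ## pool of candidate positions: deaminase-editable bases inside
    ## qualifying protospacers (C on the protospacer strand)
    pool <- do.call(rbind, lapply(seq_len(nrow(qual_loci)), function(k) {
      span <- qual_loci$start[k]:qual_loci$end[k]
      want <- if (qual_loci$strand[k] == "+") "C" else "G"
      cand <- span[g[span] == want]
      if (!length(cand)) cand <- span  # degenerate: no editable base
      data.frame(pos = cand, locus = k, stringsAsFactors = FALSE)
    }))
    pool <- pool[!duplicated(pool$pos), , drop = FALSE]
    if (nrow(pool) < n_dependent) {
      # too few editable bases: fall back to any protospacer position
      pool <- do.call(rbind, lapply(seq_len(nrow(qual_loci)), function(k)
        data.frame(pos = qual_loci$start[k]:qual_loci$end[k], locus = k,
                   stringsAsFactors = FALSE)))
      pool <- pool[!duplicated(pool$pos), , drop = FALSE]
    }
    if (nrow(pool) < n_dependent)
      stop("not enough positions inside qualifying loci for n_dependent SNVs",
           call. = FALSE)
    take <- pool[sample.int(nrow(pool), n_dependent), , drop = FALSE]
    for (r in seq_len(nrow(take))) {
      pos <- take$pos[r]
      k <- take$locus[r]
      ref <- g[pos]
      alt <- if (ref == "C") "T" else if (ref == "G") "A" else
        .mutate_base(ref)
      cls <- if (qual_loci$mm[k] == 0L) "on_target" else "sgRNA_dependent"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = contig, pos = pos, ref = ref, alt = alt,
        freq = round(runif(1L, 0.05, 0.95), 3L),
        truth_class = cls, stringsAsFactors = FALSE)
    }
  }
  if (n_independent > 0L) {
    forbidden <- unlist(lapply(seq_len(nrow(qual_loci)), function(k)
      (qual_loci$start[k] - L):(qual_loci$end[k] + L)))
    allowed <- setdiff(seq_len(nchar(gseq)), forbidden)
    cs <- allowed[g[allowed] == "C"]
    pos <- sample(cs, n_independent)
    for (p in pos)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = contig, pos = p, ref = "C", alt = "T",
        freq = round(runif(1L, 0.05, 0.95), 3L),
        truth_class = "sgRNA_independent", stringsAsFactors = FALSE)
  }
  snvs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0L), pos = integer(0L),
               ref = character(0L), alt = character(0L),
               freq = numeric(0L), truth_class = character(0L),
               stringsAsFactors = FALSE)
  snvs <- snvs[order(snvs$pos), , drop = FALSE]
  rownames(snvs) <- NULL
  # avoid duplicated positions across classes
  snvs <- snvs[!duplicated(paste(snvs$chrom, snvs$pos)), , drop = FALSE]

  if (!is.null(vcf))
    write_snv_vcf(snvs, vcf,
                  contig_lengths = setNames(nchar(gseq), contig))
  if (!is.null(truth_tsv))
    write.table(snvs, truth_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  snvs
}
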