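#' @title Quantification of base-editing outcomes from amplicon reads
#' @name quant
#' @description Semi-global alignment of amplicon reads to a reference,
#'   per-protospacer-position substitution tallies, the window-level
#'   editing statistic (a read is "edited" iff it carries at least one
#'   canonical conversion inside the editing window), indel frequency,
#'   by-product typing, and replicate statistics.
NULL

#' Describe an amplicon locus
#'
#' Bundles a reference amplicon with the protospacer interval it contains,
#' the protospacer strand, the editor, and the editing window in
#' protospacer coordinates (PAM-distal end = position 1). Default windows
#' are positions 4-8 for CBEs and 4-7 for ABEs. The PAM is 3' of the
#' protospacer on the protospacer strand.
#'
#' @param name locus name.
#' @param reference amplicon reference sequence (DNA).
#' @param proto_start,proto_end 1-based protospacer interval on the
#'   reference (+ strand coordinates).
#' @param strand protospacer strand, `"+"` or `"-"`.
#' @param editor `"CBE"` or `"ABE"`.
#' @param window editing window as an integer vector of protospacer
#'   positions; default depends on `editor`.
#' @return An object of class `amplicon_locus`.
#' @export
amplicon_locus <- function(name, reference, proto_start, proto_end,
                           strand = c("+", "-"), editor = c("CBE", "ABE"),
                           window = NULL) {
  strand <- match.arg(strand)
  editor <- match.arg(toupper(editor), c("CBE", "ABE"))
  reference <- check_seq(reference, "DNA", what = "reference")
  proto_start <- as.integer(proto_start)
  proto_end <- as.integer(proto_end)
  if (is.na(proto_start) || is.na(proto_end) || proto_start > proto_end ||
      proto_start < 1L || proto_end > nchar(reference))
    stop("protospacer interval must lie within the reference", call. = FALSE)
  L <- proto_end - proto_start + 1L
  if (is.null(window)) window <- if (editor == "CBE") 4:8 else 4:7
  window <- sort(unique(as.integer(window)))
  check_proto_pos(window, L)
  structure(list(name = name, reference = reference,
                 proto_start = proto_start, proto_end = proto_end,
                 strand = strand, editor = editor, window = window,
                 L = L),
            class = "amplicon_locus")
}

#' @export
print.amplicon_locus <- function(x, ...) {
  cat("<amplicon_locus> ", x$name, ": ", nchar(x$reference),
      " bp, protospacer ", x$proto_start, "-", x$proto_end, " (", x$strand,
      "), ", x$editor, " window ", min(x$window), "-", max(x$window),
      "\n", sep = "")
  invisible(x)
}

#' Protospacer sequence of a locus
#'
#' Returns the protospacer in its own 5'-to-3' orientation (reverse
#' complement of the reference slice for `-` strand loci).
#'
#' @param locus an [amplicon_locus()].
#' @return Character scalar of length `locus$L`.
#' @export
proto_seq <- function(locus) {
  s <- substr(locus$reference, locus$proto_start, locus$proto_end)
  if (locus$strand == "-") revcomp(s) else s
}

## left-align a deletion: shift start left while the base entering from the
## left equals the base leaving on the right (classic VCF normalisation)
.left_align_del <- function(ref_res, start, len) {
  while (start > 1L && ref_res[start - 1L] == ref_res[start + len - 1L])
    start <- start - 1L
  start
}

## left-align an insertion anchored after ref position `anchor`, sequence
## `ins` (character vector): rotate while ref[anchor] equals last inserted
.left_align_ins <- function(ref_res, anchor, ins) {
  len <- length(ins)
  while (anchor >= 1L && ref_res[anchor] == ins[len]) {
    ins <- c(ref_res[anchor], ins[-len])
    anchor <- anchor - 1L
  }
  list(anchor = anchor, seq = paste(ins, collapse = ""))
}

#' Align amplicon reads to a locus reference
#'
#' Semi-global alignment (every read base aligned; unaligned reference ends
#' are free) with affine gap scoring: match +2, mismatch -2, gap open -6,
#' gap extend -1. Indels are left-aligned after alignment so placement
#' within homopolymers is deterministic. Reads whose alignment does not
#' cover the full protospacer, or whose mean base quality falls below
#' `min_mean_qual`, are flagged as failing (never dropped silently).
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet], a
#'   [Biostrings::DNAStringSet] / named character vector (qualities then
#'   assumed perfect), or a FASTQ path.
#' @param locus an [amplicon_locus()].
#' @param min_mean_qual mean Phred quality below which a read fails;
#'   default 20.
#' @return An object of class `read_alignments`: list with `reads`
#'   (data frame: id, sstart, send, mean_qual, covers_proto, pass),
#'   `substitutions` (read_idx, ref_pos, ref_base, read_base, qual),
#'   `indels` (read_idx, ref_pos, type, length, seq; deletions give the
#'   1-based first deleted reference base, insertions the reference base
#'   the insertion follows), and `locus`.
#' @export
align_reads <- function(reads, locus, min_mean_qual = 20) {
  stopifnot(inherits(locus, "amplicon_locus"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  if (is.character(reads))
    reads <- Biostrings::DNAStringSet(reads)
  if (is(reads, "QualityScaledDNAStringSet")) {
    quals <- as(Biostrings::quality(reads), "IntegerList")
    # coercion drops quality metadata by design; silence the notice
    reads_plain <- suppressWarnings(Biostrings::DNAStringSet(reads))
  } else {
    quals <- NULL
    reads_plain <- reads
  }
  n <- length(reads_plain)
  if (n == 0L) stop("no reads", call. = FALSE)
  ids <- names(reads_plain)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    reads_plain, subject = Biostrings::DNAString(locus$reference),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 1)

  sstart <- Biostrings::start(Biostrings::subject(aln))
  send <- Biostrings::end(Biostrings::subject(aln))
  mean_q <- if (is.null(quals)) rep(41, n) else
    vapply(seq_len(n), function(i) mean(quals[[i]]), numeric(1L))
  covers <- sstart <= locus$proto_start & send >= locus$proto_end
  pass <- covers & mean_q >= min_mean_qual
  read_tab <- data.frame(id = ids, sstart = sstart, send = send,
                         mean_qual = mean_q, covers_proto = covers,
                         pass = pass, stringsAsFactors = FALSE)

  ## substitutions
  mt <- Biostrings::mismatchTable(aln)
  if (nrow(mt)) {
    q <- if (is.null(quals)) rep(41L, nrow(mt)) else {
      flat <- unlist(quals, use.names = FALSE)
      off <- cumsum(c(0L, Biostrings::width(reads_plain)))[mt$PatternId]
      flat[off + mt$PatternStart]
    }
    subs <- data.frame(read_idx = mt$PatternId,
                       ref_pos = mt$SubjectStart,
                       ref_base = as.character(mt$SubjectSubstring),
                       read_base = as.character(mt$PatternSubstring),
                       qual = q, stringsAsFactors = FALSE)
  } else {
    subs <- data.frame(read_idx = integer(0L), ref_pos = integer(0L),
                       ref_base = character(0L), read_base = character(0L),
                       qual = integer(0L), stringsAsFactors = FALSE)
  }

  ## indels, left-aligned
  ref_res <- strsplit(locus$reference, "", fixed = TRUE)[[1L]]
  ins_l <- Biostrings::insertion(aln)   # read coordinates of inserted bases
  del_l <- Biostrings::deletion(aln)    # reference coordinates deleted
  has_indel <- which(lengths(ins_l) + lengths(del_l) > 0L)
  indel_rows <- vector("list", length(has_indel))
  read_chars <- NULL
  for (ii in seq_along(has_indel)) {
    i <- has_indel[ii]
    dels <- del_l[[i]]
    inss <- ins_l[[i]]
    rows <- list()
    for (k in seq_len(length(dels))) {
      st <- .left_align_del(ref_res, IRanges::start(dels)[k],
                            IRanges::width(dels)[k])
      w <- IRanges::width(dels)[k]
      rows[[length(rows) + 1L]] <- data.frame(
        read_idx = i, ref_pos = st, type = "del", length = w,
        seq = paste(ref_res[st:(st + w - 1L)], collapse = ""),
        stringsAsFactors = FALSE)
    }
    if (length(inss)) {
      if (is.null(read_chars)) read_chars <- as.character(reads_plain)
      rres <- strsplit(read_chars[i], "", fixed = TRUE)[[1L]]
      dl_st <- IRanges::start(dels); dl_w <- IRanges::width(dels)
      for (k in seq_len(length(inss))) {
        ps <- IRanges::start(inss)[k]; w <- IRanges::width(inss)[k]
        prior_ins <- sum(IRanges::width(inss)[IRanges::end(inss) < ps])
        anchor <- sstart[i] - 1L + (ps - 1L - prior_ins)
        # account for deletions that precede this point on the reference
        repeat {
          add <- sum(dl_w[dl_st <= anchor])
          new_anchor <- sstart[i] - 1L + (ps - 1L - prior_ins) + add
          if (new_anchor == anchor) break
          anchor <- new_anchor
        }
        la <- .left_align_ins(ref_res, anchor, rres[ps:(ps + w - 1L)])
        rows[[length(rows) + 1L]] <- data.frame(
          read_idx = i, ref_pos = la$anchor, type = "ins", length = w,
          seq = la$seq, stringsAsFactors = FALSE)
      }
    }
    indel_rows[[ii]] <- do.call(rbind, rows)
  }
  indels <- if (length(indel_rows)) do.call(rbind, indel_rows) else
    data.frame(read_idx = integer(0L), ref_pos = integer(0L),
               type = character(0L), length = integer(0L),
               seq = character(0L), stringsAsFactors = FALSE)

  structure(list(reads = read_tab, substitutions = subs, indels = indels,
                 locus = locus),
            class = "read_alignments")
}

#' @export
print.read_alignments <- function(x, ...) {
  cat("<read_alignments> ", nrow(x$reads), " reads vs ", x$locus$name,
      " (", sum(x$reads$pass), " pass); ", nrow(x$substitutions),
      " substitutions, ", nrow(x$indels), " indel records\n", sep = "")
  invisible(x)
}

#' Tally editing outcomes into a profile
#'
#' Aggregates alignments over one locus into per-protospacer-position
#' substitution counts and read-level statistics. A read counts as
#' window-edited iff it carries at least one canonical conversion (C>T for
#' CBE, A>G for ABE, evaluated on the protospacer strand) at an
#' editing-window position; `any_substitution = TRUE` broadens "edit" to
#' any substitution in the window. A read counts as an indel read iff at
#' least one of its indels overlaps the protospacer interval (extended by
#' `indel_flank`). Substitutions with base quality below `min_qual` are
#' masked, i.e. treated as unedited reference calls.
#'
#' @param alignments a [align_reads()] result.
#' @param min_qual base-quality mask threshold; default 20 (0 disables
#'   masking).
#' @param any_substitution count any window substitution as an edit.
#' @param indel_flank extend the protospacer interval by this many bases
#'   when testing indel overlap; default 0.
#' @return An object of class `editing_profile`: list with `locus`,
#'   `n_reads`, `n_pass`, `n_window_edited`, `n_indel`, `window_freq`,
#'   `indel_freq`, and `positions`, a data frame over protospacer positions
#'   1..L with the protospacer-strand reference base, depth (pass reads
#'   with a base call), and counts of reads substituting to each base.
#' @export
tally <- function(alignments, min_qual = 20, any_substitution = FALSE,
                  indel_flank = 0L) {
  stopifnot(inherits(alignments, "read_alignments"))
  locus <- alignments$locus
  L <- locus$L
  pass_idx <- which(alignments$reads$pass)
  n_pass <- length(pass_idx)
  proto <- strsplit(proto_seq(locus), "", fixed = TRUE)[[1L]]

  subs <- alignments$substitutions
  subs <- subs[subs$read_idx %in% pass_idx & subs$qual >= min_qual &
               subs$ref_pos >= locus$proto_start &
               subs$ref_pos <= locus$proto_end, , drop = FALSE]
  if (nrow(subs)) {
    if (locus$strand == "+") {
      subs$proto_pos <- subs$ref_pos - locus$proto_start + 1L
      subs$base <- subs$read_base
    } else {
      subs$proto_pos <- locus$proto_end - subs$ref_pos + 1L
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      subs$base <- unname(comp[subs$read_base])
    }
  } else {
    subs$proto_pos <- integer(0L)
    subs$base <- character(0L)
  }

  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, .DNA_BASES))
  if (nrow(subs)) {
    tb <- table(factor(subs$proto_pos, levels = seq_len(L)),
                factor(subs$base, levels = .DNA_BASES))
    counts <- counts + unclass(tb)
  }

  ## depth: pass reads minus those with a deletion covering the position
  depth <- rep(n_pass, L)
  ind <- alignments$indels
  ind_pass <- ind[ind$read_idx %in% pass_idx, , drop = FALSE]
  dels <- ind_pass[ind_pass$type == "del", , drop = FALSE]
  if (nrow(dels)) {
    for (k in seq_len(nrow(dels))) {
      covered <- intersect(dels$ref_pos[k]:(dels$ref_pos[k] + dels$length[k] - 1L),
                           locus$proto_start:locus$proto_end)
      if (length(covered)) {
        pp <- if (locus$strand == "+") covered - locus$proto_start + 1L
              else locus$proto_end - covered + 1L
        depth[pp] <- depth[pp] - 1L
      }
    }
  }

  ## window-edited reads
  canon_from <- if (locus$editor == "CBE") "C" else "A"
  canon_to <- if (locus$editor == "CBE") "T" else "G"
  in_win <- subs$proto_pos %in% locus$window
  ref_proto <- proto[subs$proto_pos]
  is_edit <- if (any_substitution) in_win else
    in_win & ref_proto == canon_from & subs$base == canon_to
  n_window_edited <- length(unique(subs$read_idx[is_edit]))

  ## indel reads (overlap protospacer +- flank)
  fl_start <- locus$proto_start - indel_flank
  fl_end <- locus$proto_end + indel_flank
  if (nrow(ind_pass)) {
    iend <- ind_pass$ref_pos +
      ifelse(ind_pass$type == "del", ind_pass$length - 1L, 1L)
    overlaps <- ind_pass$ref_pos <= fl_end & iend >= fl_start
    n_indel <- length(unique(ind_pass$read_idx[overlaps]))
  } else n_indel <- 0L

  positions <- data.frame(position = seq_len(L), ref_base = proto,
                          depth = depth, counts,
                          stringsAsFactors = FALSE)
  structure(list(locus = locus, n_reads = nrow(alignments$reads),
                 n_pass = n_pass, n_window_edited = n_window_edited,
                 n_indel = n_indel,
                 window_freq = if (n_pass) n_window_edited / n_pass else NA_real_,
                 indel_freq = if (n_pass) n_indel / n_pass else NA_real_,
                 positions = positions),
            class = "editing_profile")
}

#' @export
print.editing_profile <- function(x, ...) {
  cat("<editing_profile> ", x$locus$name, " (", x$locus$editor, "): ",
      x$n_pass, "/", x$n_reads, " reads pass; window editing ",
      sprintf("%.2f%%", 100 * x$window_freq), "; indels ",
      sprintf("%.2f%%", 100 * x$indel_freq), "\n", sep = "")
  invisible(x)
}

#' Per-position conversion frequencies
#'
#' @param profile an [tally()] result.
#' @param positions protospacer positions (default: all).
#' @return Data frame with per-position conversion frequencies to each
#'   base (fraction of pass reads with a call), `NA` where depth is 0.
#' @export
conversion_freqs <- function(profile, positions = NULL) {
  stopifnot(inherits(profile, "editing_profile"))
  pt <- profile$positions
  if (!is.null(positions)) pt <- pt[pt$position %in% positions, , drop = FALSE]
  for (b in .DNA_BASES)
    pt[[paste0("freq_", b)]] <- ifelse(pt$depth > 0, pt[[b]] / pt$depth, NA_real_)
  pt
}

#' By-product typing at target bases
#'
#' Breaks down outcomes at every protospacer position holding the editor's
#' target base (C for CBE, A for ABE): the canonical conversion fraction
#' (C>T or A>G), each non-canonical substitution fraction, and their sum
#' (the "undesired" fraction). Fractions are of pass reads with a base
#' call at the position; positions with zero depth are reported as `NA`.
#'
#' @param profile an [tally()] result.
#' @return Data frame with columns `position`, `ref_base`, `depth`,
#'   `canonical`, one column per non-canonical base, `undesired`.
#' @export
byproduct_table <- function(profile) {
  stopifnot(inherits(profile, "editing_profile"))
  locus <- profile$locus
  target <- if (locus$editor == "CBE") "C" else "A"
  canon_to <- if (locus$editor == "CBE") "T" else "G"
  pt <- profile$positions[profile$positions$ref_base == target, , drop = FALSE]
  others <- setdiff(.DNA_BASES, c(target, canon_to))
  out <- data.frame(position = pt$position, ref_base = pt$ref_base,
                    depth = pt$depth, stringsAsFactors = FALSE)
  frac <- function(cnt) ifelse(pt$depth > 0, cnt / pt$depth, NA_real_)
  out$canonical <- frac(pt[[canon_to]])
  for (b in others) out[[paste0("to_", b)]] <- frac(pt[[b]])
  out$undesired <- frac(rowSums(pt[, others, drop = FALSE]))
  out
}

#' Specificity metrics: on:off ratios and fold reductions
#'
#' Compares off-target editing of a test run (e.g. a BH-sgRNA) against a
#' comparator run (e.g. the WT guide) over shared off-target loci.
#' `fold_reduction` is comparator off-target frequency / test off-target
#' frequency; test frequencies below the detection floor are censored at
#' the floor and the resulting fold change reported as a lower bound
#' (`censored = TRUE`).
#'
#' @param on test on-target profile (or its window frequency).
#' @param offs list of test off-target profiles (or numeric frequencies),
#'   named by locus.
#' @param comparator_offs matching comparator off-target frequencies or
#'   profiles (same order/names).
#' @param floor detection floor as a frequency; default 0.001 (0.1%).
#' @return Data frame with columns `locus`, `off_freq`, `on_off_ratio`,
#'   `comparator_off_freq`, `fold_reduction`, `censored`.
#' @export
specificity_metrics <- function(on, offs, comparator_offs = NULL,
                                floor = 0.001) {
  wf <- function(x) if (inherits(x, "editing_profile")) x$window_freq else
    as.numeric(x)
  as_flist <- function(x) {
    if (inherits(x, "editing_profile")) list(x)
    else if (is.numeric(x)) as.list(x)
    else x
  }
  on_f <- wf(on)
  off_f <- vapply(as_flist(offs), wf, numeric(1L))
  nms <- names(off_f)
  if (is.null(nms)) nms <- paste0("OT", seq_along(off_f))
  censored <- off_f < floor
  off_eff <- pmax(off_f, floor)
  out <- data.frame(locus = nms, off_freq = off_f,
                    on_off_ratio = on_f / off_eff,
                    stringsAsFactors = FALSE)
  if (!is.null(comparator_offs)) {
    comp_f <- vapply(as_flist(comparator_offs), wf, numeric(1L))
    out$comparator_off_freq <- comp_f
    out$fold_reduction <- comp_f / off_eff
  }
  out$censored <- censored
  out
}

#' Replicate mean and standard error
#'
#' @param values numeric vector of replicate measurements (n >= 2).
#' @return List with `mean`, `sem` (`sd/sqrt(n)`), `n`.
#' @examples
#' replicate_stats(c(2, 4, 6))  # mean 4, sem 2/sqrt(3)
#' @export
replicate_stats <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 replicates", call. = FALSE)
  list(mean = mean(values), sem = sd(values) / sqrt(n), n = n)
}

#' Two-sample Student t test (equal variance, two-tailed)
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 values per group", call. = FALSE)
  tt <- t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
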