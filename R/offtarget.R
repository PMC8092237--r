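#' @title Off-target enumeration and SNV classification
#' @name offtarget
#' @description Mismatch-tolerant scan of a genome for PAM-adjacent loci
#'   resembling a spacer, and classification of observed SNVs as on-target,
#'   guide-dependent (inside a locus sharing at least `min_matches` of the
#'   20 protospacer positions with the target, 15 by default), or
#'   guide-independent.
NULL

## expand a PAM pattern (N = any base) into per-position allowed sets
.pam_matches <- function(pam_seqs, pam_pattern) {
  if (!length(pam_seqs)) return(logical(0L))
  pat <- strsplit(pam_pattern, "", fixed = TRUE)[[1L]]
  ok <- rep(TRUE, length(pam_seqs))
  for (i in seq_along(pat)) {
    if (pat[i] == "N") next
    ok <- ok & substr(pam_seqs, i, i) == pat[i]
  }
  ok & nchar(pam_seqs) == length(pat)
}

.mismatch_info <- function(seqs, spacer) {
  L <- nchar(spacer)
  sp <- strsplit(spacer, "", fixed = TRUE)[[1L]]
  mm_n <- integer(length(seqs))
  mm_pos <- character(length(seqs))
  for (i in seq_along(seqs)) {
    res <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    d <- which(res != sp)
    mm_n[i] <- length(d)
    mm_pos[i] <- paste(d, collapse = ",")
  }
  list(n = mm_n, pos = mm_pos)
}

#' Scan a genome for candidate off-target loci
#'
#' Returns every position, on either strand, where an `L`-mer within
#' `max_mm` mismatches of the spacer is immediately followed (3', on the
#' site's strand) by a PAM matching `pam` (`N` = any base). Indels between
#' guide and locus are not modelled. For `-` strand sites the reported
#' `start`/`end` give the + strand interval of the protospacer and
#' `start_stranded` its 5' end on the `-` strand; `protospacer` and `pam`
#' are always in the site's own 5'-3' orientation.
#'
#' @param genome named character vector of contigs, a
#'   [Biostrings::DNAStringSet], or a FASTA path.
#' @param spacer 20-nt spacer (DNA or RNA spelling).
#' @param pam PAM pattern over A/C/G/T/N, default `"NGG"`; `NULL` drops
#'   the PAM requirement entirely.
#' @param max_mm maximum mismatches, default 4.
#' @return Data frame of candidates ordered by (contig, start, strand):
#'   `contig`, `start`, `end` (+ strand, 1-based inclusive), `strand`,
#'   `start_stranded`, `protospacer`, `pam`, `n_mismatch`,
#'   `mismatch_positions` (comma-separated protospacer coordinates).
#' @export
scan_offtargets <- function(genome, spacer, pam = "NGG", max_mm = 4L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome), length(genome) > 0L)
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  spacer <- rev_transcribe(check_seq(transcribe(spacer), "RNA",
                                     what = "spacer"))
  L <- nchar(spacer)
  use_pam <- !is.null(pam)
  if (use_pam) {
    pam <- check_seq(pam, "DNA", allow_n = TRUE, what = "pam")
    plen <- nchar(pam)
  } else plen <- 0L
  max_mm <- as.integer(max_mm)

  sp_fwd <- Biostrings::DNAString(spacer)
  sp_rev <- Biostrings::reverseComplement(sp_fwd)
  out <- list()
  for (ctg in names(genome)) {
    gseq <- toupper(genome[[ctg]])
    glen <- nchar(gseq)
    if (glen < L + plen) next
    gd <- Biostrings::DNAString(gseq)

    ## + strand: protospacer match, PAM immediately 3'
    hits <- Biostrings::matchPattern(sp_fwd, gd, max.mismatch = max_mm)
    st <- Biostrings::start(hits)
    keep <- st >= 1L & st + L - 1L + plen <= glen
    st <- st[keep]
    if (length(st)) {
      pams <- substring(gseq, st + L, st + L + plen - 1L)
      if (use_pam) {
        ok <- .pam_matches(pams, pam)
        st <- st[ok]; pams <- pams[ok]
      }
      if (length(st)) {
        protos <- substring(gseq, st, st + L - 1L)
        mi <- .mismatch_info(protos, spacer)
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, start = st, end = st + L - 1L, strand = "+",
          start_stranded = st, protospacer = protos, pam = pams,
          n_mismatch = mi$n, mismatch_positions = mi$pos,
          stringsAsFactors = FALSE)
      }
    }

    ## - strand: revcomp(spacer) on +, PAM immediately 5' as revcomp(pam)
    hits <- Biostrings::matchPattern(sp_rev, gd, max.mismatch = max_mm)
    st <- Biostrings::start(hits)
    keep <- st - plen >= 1L & st + L - 1L <= glen
    st <- st[keep]
    if (length(st)) {
      pams <- if (plen > 0L)
        vapply(substring(gseq, st - plen, st - 1L), revcomp, "",
               USE.NAMES = FALSE)
      else rep("", length(st))
      if (use_pam) {
        ok <- .pam_matches(pams, pam)
        st <- st[ok]; pams <- pams[ok]
      }
      if (length(st)) {
        protos <- vapply(substring(gseq, st, st + L - 1L), revcomp, "",
                         USE.NAMES = FALSE)
        mi <- .mismatch_info(protos, spacer)
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, start = st, end = st + L - 1L, strand = "-",
          start_stranded = st + L - 1L, protospacer = protos, pam = pams,
          n_mismatch = mi$n, mismatch_positions = mi$pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0L), start = integer(0L),
                      end = integer(0L), strand = character(0L),
                      start_stranded = integer(0L),
                      protospacer = character(0L), pam = character(0L),
                      n_mismatch = integer(0L),
                      mismatch_positions = character(0L),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read SNVs from a minimal VCF or TSV
#'
#' Accepts a minimal VCF (header lines starting with `#` skipped; columns
#' CHROM, POS, ID, REF, ALT used, `AF=` pulled from INFO when present) or
#' a TSV with columns `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path input path.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `freq`
#'   (`NA` when absent).
#' @export
read_snvs <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##") || startsWith(first, "#CHROM")) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    if (!length(body))
      return(data.frame(chrom = character(0L), pos = integer(0L),
                        ref = character(0L), alt = character(0L),
                        freq = numeric(0L), stringsAsFactors = FALSE))
    f <- strsplit(body, "\t", fixed = TRUE)
    info <- vapply(f, function(x) if (length(x) >= 8L) x[8L] else "", "")
    af <- suppressWarnings(as.numeric(sub("^.*AF=([0-9.eE+-]+).*$", "\\1",
                                          info)))
    af[!grepl("AF=", info)] <- NA_real_
    df <- data.frame(chrom = vapply(f, `[`, "", 1L),
                     pos = as.integer(vapply(f, `[`, "", 2L)),
                     ref = toupper(vapply(f, `[`, "", 4L)),
                     alt = toupper(vapply(f, `[`, "", 5L)),
                     freq = af, stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
    if (is.null(df$freq)) df$freq <- NA_real_
    df <- df[, c("chrom", "pos", "ref", "alt", "freq")]
  }
  if (any(df$ref == df$alt))
    stop("SNV with ref == alt", call. = FALSE)
  df
}

#' Write SNVs as a minimal VCF
#'
#' @param snvs data frame with `chrom`, `pos`, `ref`, `alt` (and optional
#'   `freq`, emitted as `AF=`).
#' @param path output path.
#' @param contig_lengths optional named vector used for `##contig` header
#'   lines.
#' @export
write_snv_vcf <- function(snvs, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- if (!is.null(snvs$freq))
    ifelse(is.na(snvs$freq), ".", sprintf("AF=%g", snvs$freq)) else
    rep(".", nrow(snvs))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  snvs$chrom, as.integer(snvs$pos), snvs$ref, snvs$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Classify SNVs as on-target, guide-dependent or guide-independent
#'
#' Finds every PAM-adjacent locus sharing at least `min_matches` of the
#' `L` protospacer positions with the spacer (i.e. at most
#' `L - min_matches` mismatches). An SNV inside a perfect-match locus is
#' `on_target`; inside any other qualifying locus (extended by
#' `window_flank`) it is `sgRNA_dependent`; otherwise `sgRNA_independent`.
#'
#' @param snvs data frame from [read_snvs()] (or with columns `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param genome genome as for [scan_offtargets()].
#' @param spacer 20-nt spacer.
#' @param pam PAM pattern; `NULL` classifies on protospacer similarity
#'   alone.
#' @param min_matches minimum matching positions for a guide-dependent
#'   locus; default 15.
#' @param strict require strictly more than `min_matches` matches.
#' @param window_flank extend qualifying protospacers by this many bases;
#'   default 0.
#' @return List with `snvs` (input plus `class`, `locus_contig`,
#'   `locus_start`, `locus_strand`, `locus_mismatches`), `summary` (counts
#'   per class), and `loci` (the qualifying loci, a [scan_offtargets()]
#'   data frame).
#' @export
classify_snvs <- function(snvs, genome, spacer, pam = "NGG",
                          min_matches = 15L, strict = FALSE,
                          window_flank = 0L) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(snvs)))
  spacer_dna <- rev_transcribe(check_seq(transcribe(spacer), "RNA",
                                         what = "spacer"))
  L <- nchar(spacer_dna)
  max_mm <- L - as.integer(min_matches) - if (strict) 1L else 0L
  if (max_mm < 0L)
    stop("min_matches exceeds the spacer length", call. = FALSE)
  loci <- scan_offtargets(genome, spacer_dna, pam = pam, max_mm = max_mm)

  cls <- rep("sgRNA_independent", nrow(snvs))
  l_ctg <- rep(NA_character_, nrow(snvs))
  l_start <- rep(NA_integer_, nrow(snvs))
  l_strand <- rep(NA_character_, nrow(snvs))
  l_mm <- rep(NA_integer_, nrow(snvs))
  if (nrow(loci)) {
    for (i in seq_len(nrow(snvs))) {
      hit <- which(loci$contig == snvs$chrom[i] &
                   snvs$pos[i] >= loci$start - window_flank &
                   snvs$pos[i] <= loci$end + window_flank)
      if (!length(hit)) next
      hit <- hit[order(loci$n_mismatch[hit], loci$start[hit])][1L]
      cls[i] <- if (loci$n_mismatch[hit] == 0L) "on_target" else
        "sgRNA_dependent"
      l_ctg[i] <- loci$contig[hit]
      l_start[i] <- loci$start[hit]
      l_strand[i] <- loci$strand[hit]
      l_mm[i] <- loci$n_mismatch[hit]
    }
  }
  snvs$class <- cls
  snvs$locus_contig <- l_ctg
  snvs$locus_start <- l_start
  snvs$locus_strand <- l_strand
  snvs$locus_mismatches <- l_mm
  summary <- c(on_target = sum(cls == "on_target"),
               sgRNA_dependent = sum(cls == "sgRNA_dependent"),
               sgRNA_independent = sum(cls == "sgRNA_independent"))
  list(snvs = snvs, summary = summary, loci = loci)
}

#' Compare predicted candidates with observed SNVs
#'
#' Venn-style overlap between predicted off-target loci and loci observed
#' to carry SNVs: `both` counts predicted loci containing at least one
#' SNV, `predicted_only` predicted loci with none, and `observed_only`
#' distinct SNV positions falling inside no predicted locus.
#'
#' @param candidates a [scan_offtargets()] data frame.
#' @param snvs data frame with `chrom`, `pos`.
#' @param flank extend candidate intervals by this many bases.
#' @return List with counts `both`, `predicted_only`, `observed_only`, and
#'   the membership tables `candidates` (plus `n_snvs`) and
#'   `unmatched_snvs`.
#' @export
compare_predicted_observed <- function(candidates, snvs, flank = 0L) {
  n_snv <- integer(nrow(candidates))
  matched <- rep(FALSE, nrow(snvs))
  for (k in seq_len(nrow(candidates))) {
    inside <- snvs$chrom == candidates$contig[k] &
      snvs$pos >= candidates$start[k] - flank &
      snvs$pos <= candidates$end[k] + flank
    n_snv[k] <- sum(inside)
    matched <- matched | inside
  }
  candidates$n_snvs <- n_snv
  list(both = sum(n_snv > 0L),
       predicted_only = sum(n_snv == 0L),
       observed_only = length(unique(paste(snvs$chrom, snvs$pos)[!matched])),
       candidates = candidates,
       unmatched_snvs = snvs[!matched, , drop = FALSE])
}

#' Fraction of SNVs carrying the editor's signature
#'
#' For CBEs the canonical signature is a C>T change on either strand, i.e.
#' C>T or (strand-collapsed) G>A on the + strand; for ABEs A>G or T>C.
#'
#' @param snvs data frame with `ref`, `alt` (typically one classification
#'   class).
#' @param editor `"CBE"` or `"ABE"`.
#' @return Fraction in `[0, 1]`, or `NA` with a message for an empty set.
#' @examples
#' snv_type_ratio(data.frame(ref = c("C", "C", "C", "A"),
#'                           alt = c("T", "T", "T", "G")))  # 0.75
#' @export
snv_type_ratio <- function(snvs, editor = c("CBE", "ABE")) {
  editor <- match.arg(toupper(editor), c("CBE", "ABE"))
  if (!nrow(snvs)) {
    message("no SNVs in class; ratio undefined")
    return(NA_real_)
  }
  ref <- toupper(snvs$ref); alt <- toupper(snvs$alt)
  canonical <- if (editor == "CBE")
    (ref == "C" & alt == "T") | (ref == "G" & alt == "A")
  else
    (ref == "A" & alt == "G") | (ref == "T" & alt == "C")
  mean(canonical)
}
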