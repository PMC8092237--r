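#' @title Nucleotide alphabets, pairing rules and sequence utilities
#' @name seq-core
#' @description Shared low-level vocabulary: alphabet validation, DNA/RNA
#'   interconversion, reverse complement, Watson-Crick / G-U wobble pairing
#'   predicates, and the protospacer coordinate convention (position 1 =
#'   PAM-distal end).
NULL

.DNA_BASES <- c("A", "C", "G", "T")
.RNA_BASES <- c("A", "C", "G", "U")

#' Validate a nucleotide sequence
#'
#' Checks a single sequence against a declared alphabet, uppercasing it
#' first. `N` is accepted only when `allow_n = TRUE` (PAM patterns); guides
#' must never contain `N`.
#'
#' @param x character scalar.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param allow_n allow the ambiguity code `N`.
#' @param what label used in error messages.
#' @return The validated, uppercased sequence.
#' @examples
#' check_seq("acgt", "DNA")
#' @export
check_seq <- function(x, alphabet = c("DNA", "RNA"), allow_n = FALSE,
                      what = "sequence") {
  alphabet <- match.arg(alphabet)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  x <- toupper(x)
  if (nchar(x) == 0L)
    stop(what, " must be non-empty", call. = FALSE)
  ok <- if (alphabet == "DNA") .DNA_BASES else .RNA_BASES
  if (allow_n) ok <- c(ok, "N")
  res <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!(res %in% ok))
  if (length(bad))
    stop(sprintf("invalid %s residue '%s' at position %d (alphabet %s)",
                 alphabet, res[bad[1L]], bad[1L], alphabet), call. = FALSE)
  x
}

#' Convert between DNA and RNA spellings
#'
#' `transcribe()` rewrites T as U; `rev_transcribe()` rewrites U as T.
#' Neither reverse-complements.
#'
#' @param x character vector of sequences.
#' @return Character vector in the target alphabet.
#' @export
transcribe <- function(x) chartr("Tt", "Uu", x)

#' @rdname transcribe
#' @export
rev_transcribe <- function(x) chartr("Uu", "Tt", x)

#' Reverse complement
#'
#' Reverse-complements a DNA or RNA sequence. The input alphabet is
#' detected from the residues (U implies RNA, T implies DNA; ambiguous
#' sequences default to DNA) unless given; the output alphabet is chosen by
#' `out_alphabet`. Applying the operation twice with a fixed alphabet
#' returns the input.
#'
#' @param x character scalar sequence.
#' @param out_alphabet `"DNA"` or `"RNA"` for the result.
#' @param in_alphabet optional explicit input alphabet.
#' @return Reverse complement as a character scalar.
#' @examples
#' revcomp("ACGT")              # "ACGT" (palindrome)
#' revcomp("AAAA", "RNA")      # "UUUU"
#' @export
revcomp <- function(x, out_alphabet = c("DNA", "RNA"), in_alphabet = NULL) {
  out_alphabet <- match.arg(out_alphabet)
  if (is.null(in_alphabet))
    in_alphabet <- if (grepl("U", toupper(x), fixed = TRUE)) "RNA" else "DNA"
  x <- check_seq(x, in_alphabet, allow_n = TRUE)
  xd <- rev_transcribe(x)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(xd)))
  if (out_alphabet == "RNA") transcribe(rc) else rc
}

#' Base-pairing predicate
#'
#' Tests whether two residues form a Watson-Crick pair, optionally also
#' accepting the G-U wobble pair. T is treated as U, so DNA spellings work
#' transparently. Vectorised and symmetric in its first two arguments.
#'
#' @param a,b residues (character vectors, recycled).
#' @param wobble also accept G-U / U-G.
#' @return Logical vector.
#' @examples
#' bases_pair("G", "C")                 # TRUE
#' bases_pair("G", "U", wobble = FALSE) # FALSE
#' bases_pair("G", "U", wobble = TRUE)  # TRUE
#' @export
bases_pair <- function(a, b, wobble = TRUE) {
  a <- chartr("Tt", "Uu", toupper(a))
  b <- chartr("Tt", "Uu", toupper(b))
  bad <- !(c(a, b) %in% .RNA_BASES)
  if (any(bad))
    stop("residues must be one of A, C, G, U/T", call. = FALSE)
  key <- paste0(a, b)
  wc <- key %in% c("AU", "UA", "CG", "GC")
  if (wobble) wc | key %in% c("GU", "UG") else wc
}

#' Check a protospacer position
#'
#' Protospacer positions count the PAM-distal end as position 1 and run to
#' the spacer length `L` at the PAM-proximal end.
#'
#' @param p integer position(s).
#' @param L spacer length.
#' @return `p`, invisibly, after validation.
#' @export
check_proto_pos <- function(p, L) {
  p <- as.integer(p)
  if (any(is.na(p)) || any(p < 1L) || any(p > L))
    stop(sprintf("protospacer position out of range 1..%d", L), call. = FALSE)
  invisible(p)
}

## ---- FASTA / FASTQ wrappers (gzip-transparent, via Biostrings) ----

#' Read and write FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] returning plain named character vectors,
#' gzip-transparent on read.
#'
#' @param path file path (`.gz` accepted for reading).
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  ss <- if (alphabet == "DNA") Biostrings::readDNAStringSet(path)
        else Biostrings::readRNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), length(seqs) > 0L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  is_rna <- any(grepl("U", toupper(seqs), fixed = TRUE))
  ss <- if (is_rna) Biostrings::RNAStringSet(toupper(seqs))
        else Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTQ file into a quality-scaled string set
#'
#' @param path FASTQ path (`.gz` accepted).
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
read_fastq <- function(path) {
  Biostrings::readQualityScaledDNAStringSet(path)
}

#' Write reads and Phred qualities to FASTQ
#'
#' @param reads named character vector of read sequences (DNA).
#' @param quals character vector of Phred+33 quality strings, same widths.
#' @param path output path.
#' @export
write_fastq <- function(reads, quals, path) {
  stopifnot(length(reads) == length(quals),
            all(nchar(reads) == nchar(quals)))
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads),
    Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}
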