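#' @title Bubble-hairpin guide design
#' @name designer
#' @description Construction of WT, hairpin (H#), and bubble-hairpin
#'   (H#-B#-P#) guides. The 5' extension is the reverse complement of the
#'   PAM-distal end of the spacer, joined to the spacer by a 5'-ACAA-3'
#'   tetraloop; the bubble is a run of extension residues replaced so they
#'   form neither Watson-Crick nor G-U pairs with the spacer positions they
#'   face.
NULL

#' Design parameters for a (bubble-)hairpin guide
#'
#' Captures the H#-B#-P# parameter space: extension (hairpin) length `H`
#' (loop excluded), bubble size `B`, and bubble start `P` given as the
#' first protospacer position facing the bubble. Defaults reproduce the
#' recommended designs: H12-B3-P5 for cytosine base editors and H12-B3-P4
#' for adenine base editors. `B = 0` yields a plain hairpin; `H = 0` the
#' unmodified (WT) guide.
#'
#' @param editor `"CBE"` or `"ABE"`.
#' @param hairpin_len extension length `H`, 0..12 (loop excluded).
#' @param bubble_size bubble size `B`, 0..`H`.
#' @param bubble_start first protospacer position facing the bubble `P`;
#'   default 5 (CBE) or 4 (ABE). Must satisfy `P >= 1` and
#'   `P + B - 1 <= H`.
#' @param loop tetraloop sequence (RNA), default `"ACAA"`.
#' @return An object of class `bh_design_spec`.
#' @examples
#' design_spec("CBE")                      # H12-B3-P5
#' design_spec("ABE")                      # H12-B3-P4
#' design_spec("CBE", hairpin_len = 2, bubble_size = 0)  # plain hairpin H2
#' @export
design_spec <- function(editor = c("CBE", "ABE"), hairpin_len = 12L,
                        bubble_size = 3L, bubble_start = NULL,
                        loop = "ACAA") {
  editor <- match.arg(toupper(editor), c("CBE", "ABE"))
  H <- as.integer(hairpin_len)
  B <- as.integer(bubble_size)
  if (is.na(H) || H < 0L || H > 12L)
    stop("hairpin_len must be an integer in 0..12", call. = FALSE)
  if (H == 0L) B <- 0L
  if (is.na(B) || B < 0L || B > H)
    stop("bubble_size must be an integer in 0..hairpin_len", call. = FALSE)
  if (B == 0L) {
    if (!is.null(bubble_start))
      warning("bubble_start ignored because bubble_size is 0", call. = FALSE)
    P <- NA_integer_
  } else {
    P <- as.integer(if (is.null(bubble_start)) {
      if (editor == "CBE") 5L else 4L
    } else bubble_start)
    if (is.na(P) || P < 1L || P + B - 1L > H)
      stop("bubble must lie within the paired region: need 1 <= P and P + B - 1 <= H",
           call. = FALSE)
  }
  loop <- if (H > 0L) check_seq(transcribe(loop), "RNA", what = "loop") else ""
  structure(list(editor = editor, hairpin_len = H, bubble_size = B,
                 bubble_start = P, loop = loop),
            class = "bh_design_spec")
}

#' @export
print.bh_design_spec <- function(x, ...) {
  cat("<bh_design_spec> ", name_design(x), "  editor=", x$editor,
      if (x$hairpin_len > 0L) paste0("  loop=", x$loop), "\n", sep = "")
  invisible(x)
}

#' Map a hairpin position to a protospacer position
#'
#' Hairpin positions count the 5' end of the extension as 1; protospacer
#' positions count the PAM-distal end as 1. Because the extension is the
#' reverse complement of the spacer's first `H` residues, hairpin position
#' `p` faces protospacer position `H + 1 - p`. The map is an involution on
#' `1..H` (it is its own inverse).
#'
#' @param p hairpin position(s), 1-based from the extension 5' end.
#' @param H extension length.
#' @return Integer protospacer position(s).
#' @examples
#' hairpin_to_protospacer(6:8, 12)  # 7 6 5 -- the CBE bubble
#' @export
hairpin_to_protospacer <- function(p, H) {
  p <- as.integer(p)
  H <- as.integer(H)
  if (any(is.na(p)) || any(p < 1L) || any(p > H))
    stop(sprintf("hairpin position out of range 1..%d", H), call. = FALSE)
  H + 1L - p
}

#' Choose a bubble nucleotide
#'
#' Picks the residue placed in the extension opposite a given spacer
#' residue so that the two can pair neither Watson-Crick nor G-U wobble.
#' The Watson-Crick partner and (if any) the wobble partner of the opposing
#' residue are excluded, then the first remaining residue in the fixed
#' priority order C, A, G, U is returned, making designs deterministic.
#'
#' @param opposing RNA residue(s) the bubble position faces (vectorised).
#' @return Character vector of chosen residues.
#' @examples
#' choose_bubble_nt(c("A", "G", "U", "C"))  # "C" "A" "C" "C"
#' @export
choose_bubble_nt <- function(opposing) {
  opposing <- chartr("Tt", "Uu", toupper(opposing))
  vapply(opposing, function(o) {
    cand <- c("C", "A", "G", "U")
    ok <- !bases_pair(cand, o, wobble = TRUE)
    cand[ok][1L]
  }, character(1L), USE.NAMES = FALSE)
}

#' Build a bubble-hairpin guide
#'
#' Constructs the full 5' region of a (bubble-)hairpin guide: the reverse
#' complement of the spacer's first `H` residues (the extension), the
#' tetraloop, and the spacer, with bubble positions substituted by
#' [choose_bubble_nt()] (or a user-supplied bubble sequence checked by the
#' same no-pairing rule). DNA spacers are transcribed to RNA first.
#'
#' @param spacer spacer sequence, DNA or RNA, default length 20 (18-24
#'   accepted with a warning); no `N` residues.
#' @param spec a [design_spec()] object (or arguments passed to it via
#'   `...`).
#' @param bubble_seq optional explicit bubble sequence (5' to 3' within the
#'   extension), length `B`; rejected if any residue pairs (Watson-Crick or
#'   wobble) with the spacer residue it faces.
#' @param scaffold optional 3' scaffold appended for oligo export (not
#'   folded, not validated beyond alphabet).
#' @param ... passed to [design_spec()] when `spec` is missing.
#' @return An object of class `bh_sgrna` with elements `name`, `editor`,
#'   `spacer`, `extension`, `loop`, `full` (extension+loop+spacer, plus
#'   scaffold if given), `bubble_hairpin` and `bubble_protospacer`
#'   (1-based position vectors), and `spec`.
#' @examples
#' g <- build_bh_sgrna(strrep("A", 20), design_spec("CBE"))
#' g$extension           # "UUUUUCCCUUUU"
#' g$bubble_hairpin      # 6 7 8
#' g$bubble_protospacer  # 5 6 7
#' @export
build_bh_sgrna <- function(spacer, spec = NULL, bubble_seq = NULL,
                           scaffold = NULL, ...) {
  if (is.null(spec)) spec <- design_spec(...)
  stopifnot(inherits(spec, "bh_design_spec"))
  spacer <- check_seq(transcribe(spacer), "RNA", what = "spacer")
  L <- nchar(spacer)
  if (L < 18L || L > 24L)
    stop("spacer length must be 18..24", call. = FALSE)
  if (L != 20L)
    warning(sprintf("spacer length %d differs from the canonical 20 nt", L),
            call. = FALSE)
  H <- spec$hairpin_len
  B <- spec$bubble_size
  if (H > L)
    stop("hairpin length exceeds spacer length", call. = FALSE)

  sp_res <- strsplit(spacer, "", fixed = TRUE)[[1L]]
  if (H > 0L) {
    ext_res <- strsplit(revcomp(substr(spacer, 1L, H), "RNA"), "",
                        fixed = TRUE)[[1L]]
  } else ext_res <- character(0L)

  if (B > 0L) {
    proto_pos <- spec$bubble_start + seq_len(B) - 1L      # P .. P+B-1
    hp_pos <- sort(hairpin_to_protospacer(proto_pos, H))  # involution
    opposing <- sp_res[hairpin_to_protospacer(hp_pos, H)]
    if (is.null(bubble_seq)) {
      ext_res[hp_pos] <- choose_bubble_nt(opposing)
    } else {
      bubble_seq <- check_seq(transcribe(bubble_seq), "RNA", what = "bubble_seq")
      bb <- strsplit(bubble_seq, "", fixed = TRUE)[[1L]]
      if (length(bb) != B)
        stop("bubble_seq must have length bubble_size", call. = FALSE)
      pairing <- bases_pair(bb, opposing, wobble = TRUE)
      if (any(pairing))
        stop(sprintf(
          "bubble_seq residue '%s' pairs (Watson-Crick or G-U) with opposing spacer residue '%s'",
          bb[which(pairing)[1L]], opposing[which(pairing)[1L]]), call. = FALSE)
      ext_res[hp_pos] <- bb
    }
  } else {
    proto_pos <- integer(0L)
    hp_pos <- integer(0L)
  }

  extension <- paste(ext_res, collapse = "")
  loop <- if (H > 0L) spec$loop else ""
  full <- paste0(extension, loop, spacer)
  if (!is.null(scaffold)) {
    scaffold <- check_seq(transcribe(scaffold), "RNA", what = "scaffold")
    full <- paste0(full, scaffold)
  }
  structure(list(name = name_design(spec), editor = spec$editor,
                 spacer = spacer, extension = extension, loop = loop,
                 full = full, scaffold = scaffold,
                 bubble_hairpin = hp_pos,
                 bubble_protospacer = sort(proto_pos),
                 spec = spec),
            class = "bh_sgrna")
}

#' @export
print.bh_sgrna <- function(x, ...) {
  cat("<bh_sgrna> ", x$name, " (", x$editor, ")\n", sep = "")
  cat("  5'-", x$extension, if (nzchar(x$loop)) paste0("[", x$loop, "]"),
      x$spacer, "-3'\n", sep = "")
  if (length(x$bubble_hairpin))
    cat("  bubble: hairpin ", paste(x$bubble_hairpin, collapse = ","),
        " <-> protospacer ", paste(x$bubble_protospacer, collapse = ","),
        "\n", sep = "")
  invisible(x)
}

#' Name a design; parse a design name
#'
#' Designs are named `"H{H}-B{B}-P{P}"`; plain hairpins (`B = 0`) are
#' `"H{H}"` and the unmodified guide (`H = 0`) is `"WT"`. `name_design()`
#' and `parse_design_name()` are mutual inverses on valid specs.
#'
#' @param spec a [design_spec()] object.
#' @return `name_design()`: character scalar.
#' @examples
#' name_design(design_spec("CBE"))       # "H12-B3-P5"
#' parse_design_name("H4")$hairpin_len   # 4
#' @export
name_design <- function(spec) {
  stopifnot(inherits(spec, "bh_design_spec"))
  if (spec$hairpin_len == 0L) return("WT")
  if (spec$bubble_size == 0L) return(sprintf("H%d", spec$hairpin_len))
  sprintf("H%d-B%d-P%d", spec$hairpin_len, spec$bubble_size,
          spec$bubble_start)
}

#' @rdname name_design
#' @param name design name such as `"H12-B3-P5"`, `"H4"` or `"WT"`.
#' @param editor editor the parsed spec is for.
#' @param loop loop passed through to [design_spec()].
#' @return `parse_design_name()`: a `bh_design_spec`.
#' @export
parse_design_name <- function(name, editor = "CBE", loop = "ACAA") {
  stopifnot(is.character(name), length(name) == 1L)
  if (toupper(name) == "WT")
    return(design_spec(editor, hairpin_len = 0L, bubble_size = 0L,
                       loop = loop))
  m <- regmatches(name, regexec("^H([0-9]+)(-B([0-9]+)-P([0-9]+))?$", name))[[1L]]
  if (!length(m))
    stop("malformed design name: ", name, call. = FALSE)
  H <- as.integer(m[2L])
  if (m[3L] == "")
    return(design_spec(editor, hairpin_len = H, bubble_size = 0L,
                       loop = loop))
  design_spec(editor, hairpin_len = H, bubble_size = as.integer(m[4L]),
              bubble_start = as.integer(m[5L]), loop = loop)
}

#' Enumerate a design series over the H/B/P grid
#'
#' Builds one design per valid (H, B, P) triple: WT when `0` is in
#' `H_set`, a plain hairpin for each `H` when `0` is in `B_set`, and a
#' bubble-hairpin for each combination with `P + B - 1 <= H`. Invalid
#' combinations are silently dropped; duplicates (by name) are removed and
#' output is ordered by (H, B, P).
#'
#' @param spacer spacer sequence (DNA or RNA).
#' @param editor `"CBE"` or `"ABE"`.
#' @param H_set hairpin lengths; default `c(0, 2, 4, 6, 8, 10, 12)`.
#' @param B_set bubble sizes; default `0:3` (0 = plain hairpin).
#' @param P_set bubble start positions; default `4:8`.
#' @param loop tetraloop.
#' @return A list of `bh_sgrna` objects, named by design name.
#' @examples
#' length(enumerate_series(strrep("A", 20), "CBE",
#'                         H_set = 12, B_set = 3, P_set = 4:8))  # 5
#' @export
enumerate_series <- function(spacer, editor = c("CBE", "ABE"),
                             H_set = c(0L, 2L, 4L, 6L, 8L, 10L, 12L),
                             B_set = 0:3, P_set = 4:8, loop = "ACAA") {
  editor <- match.arg(toupper(editor), c("CBE", "ABE"))
  if (!length(H_set) || !length(B_set))
    stop("H_set and B_set must be non-empty", call. = FALSE)
  H_set <- sort(unique(as.integer(H_set)))
  B_set <- sort(unique(as.integer(B_set)))
  P_set <- sort(unique(as.integer(P_set)))
  out <- list()
  for (H in H_set) {
    if (H == 0L) {  # WT regardless of B_set
      spec <- design_spec(editor, hairpin_len = 0L, bubble_size = 0L)
      out[[name_design(spec)]] <- build_bh_sgrna(spacer, spec)
      next
    }
    for (B in B_set) {
      if (B > H) next
      if (B == 0L) {
        spec <- design_spec(editor, hairpin_len = H, bubble_size = 0L,
                            loop = loop)
        out[[name_design(spec)]] <- build_bh_sgrna(spacer, spec)
      } else {
        for (P in P_set) {
          if (P < 1L || P + B - 1L > H) next
          spec <- design_spec(editor, hairpin_len = H, bubble_size = B,
                              bubble_start = P, loop = loop)
          out[[name_design(spec)]] <- build_bh_sgrna(spacer, spec)
        }
      }
    }
  }
  out
}

#' Tabulate designs for export
#'
#' @param designs list of `bh_sgrna` objects.
#' @return A data frame with columns `name`, `full_sequence`, `extension`,
#'   `loop`, `spacer`, `bubble_positions_hairpin`,
#'   `bubble_positions_protospacer`.
#' @export
design_table <- function(designs) {
  if (inherits(designs, "bh_sgrna")) designs <- list(designs)
  data.frame(
    name = vapply(designs, `[[`, "", "name"),
    full_sequence = vapply(designs, `[[`, "", "full"),
    extension = vapply(designs, `[[`, "", "extension"),
    loop = vapply(designs, `[[`, "", "loop"),
    spacer = vapply(designs, `[[`, "", "spacer"),
    bubble_positions_hairpin =
      vapply(designs, function(d) paste(d$bubble_hairpin, collapse = ","), ""),
    bubble_positions_protospacer =
      vapply(designs, function(d) paste(d$bubble_protospacer, collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Enumerate deliberately mismatched guides
#'
#' Produces guides differing from a spacer at exactly the requested
#' positions, for probing position-dependent specificity. Substitutions
#' follow a fixed transversion-first rule (A<->C, G<->U) unless explicit
#' replacement nucleotides are supplied.
#'
#' @param spacer spacer sequence (DNA or RNA; output follows the input
#'   alphabet).
#' @param positions integer vector (one guide) or list of integer vectors
#'   (one guide each); each vector has 1-3 distinct positions in
#'   `1..nchar(spacer)`.
#' @param nts optional replacement nucleotides parallel to `positions`
#'   (vector or list); each must differ from the spacer residue it
#'   replaces.
#' @return A data frame with columns `name`, `sequence`, `n_mismatch`,
#'   `positions`, `ref_nt`, `new_nt`.
#' @examples
#' enumerate_mismatched_guides(strrep("A", 20), list(5, c(1, 8, 15)))
#' @export
enumerate_mismatched_guides <- function(spacer, positions, nts = NULL) {
  is_rna <- grepl("U", toupper(spacer), fixed = TRUE)
  spacer_rna <- check_seq(transcribe(spacer), "RNA", what = "spacer")
  L <- nchar(spacer_rna)
  if (!is.list(positions)) positions <- list(positions)
  if (!is.null(nts) && !is.list(nts)) nts <- list(nts)
  flip <- c(A = "C", C = "A", G = "U", U = "G")
  rows <- lapply(seq_along(positions), function(i) {
    pos <- as.integer(positions[[i]])
    if (anyDuplicated(pos))
      stop("duplicate mismatch positions", call. = FALSE)
    k <- length(pos)
    if (k < 1L || k > 3L)
      stop("each guide must have 1..3 mismatch positions", call. = FALSE)
    check_proto_pos(pos, L)
    res <- strsplit(spacer_rna, "", fixed = TRUE)[[1L]]
    ref_nt <- res[pos]
    new_nt <- if (is.null(nts)) unname(flip[ref_nt]) else {
      nn <- chartr("Tt", "Uu", toupper(nts[[i]]))
      if (length(nn) != k || any(!nn %in% .RNA_BASES))
        stop("nts must supply one valid residue per position", call. = FALSE)
      if (any(nn == ref_nt))
        stop("replacement nucleotide equals the spacer residue", call. = FALSE)
      nn
    }
    res[pos] <- new_nt
    seq_out <- paste(res, collapse = "")
    if (!is_rna) seq_out <- rev_transcribe(seq_out)
    data.frame(name = paste0("MM", k, "-", paste(pos, collapse = ".")),
               sequence = seq_out, n_mismatch = k,
               positions = paste(pos, collapse = ","),
               ref_nt = paste(if (is_rna) ref_nt else rev_transcribe(ref_nt),
                              collapse = ","),
               new_nt = paste(if (is_rna) new_nt else rev_transcribe(new_nt),
                              collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
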