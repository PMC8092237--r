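#' @title Secondary-structure validation of hairpin guides
#' @name structure
#' @description Base-pair maximisation (Nussinov dynamic programming) over
#'   the designed 5' region (extension + loop + spacer), and reports that
#'   check the intended stem forms while the bubble stays open. The
#'   structural claims being verified are topological -- which pairs can
#'   form -- so pair counting, which admits an exact brute-force oracle, is
#'   used rather than thermodynamic folding.
NULL

## Weighted Nussinov DP. `weight` is an n x n matrix of pair weights
## (non-pairable or loop-violating entries must be 0/-Inf-like; we use NA
## to mean disallowed). Returns list(score matrix). Internal.
.nussinov_dp <- function(weight, n) {
  N <- matrix(0, n, n)
  if (n < 2L) return(N)
  for (d in seq_len(n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      best <- N[i, j - 1L]          # j unpaired
      ks <- i:(j - 1L)
      w <- weight[ks, j]
      ok <- which(!is.na(w))
      if (length(ok)) {
        for (k in ks[ok]) {
          left <- if (k > i) N[i, k - 1L] else 0
          val <- left + N[k + 1L, j - 1L] + weight[k, j]
          if (val > best) best <- val
        }
      }
      N[i, j] <- best
    }
  }
  N
}

## Deterministic traceback: at (i, j) prefer pairing j with the smallest
## admissible k, so returned pairs favour small i then small j. Internal.
.nussinov_traceback <- function(N, weight, n) {
  pairs <- matrix(integer(0L), ncol = 2L)
  if (n < 2L) return(pairs)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (i >= j) next
    target <- N[i, j]
    found <- FALSE
    for (k in i:(j - 1L)) {
      w <- weight[k, j]
      if (is.na(w)) next
      left <- if (k > i) N[i, k - 1L] else 0
      if (left + N[k + 1L, j - 1L] + w == target) {
        pairs <- rbind(pairs, c(k, j))
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        found <- TRUE
        break
      }
    }
    if (!found) stack[[length(stack) + 1L]] <- c(i, j - 1L)
  }
  pairs[order(pairs[, 1L]), , drop = FALSE]
}

.pair_weight_matrix <- function(res, min_loop, wobble, base_weight = 1,
                                bonus = NULL) {
  n <- length(res)
  W <- matrix(NA_real_, n, n)
  if (n >= 2L) {
    idx <- which(outer(seq_len(n), seq_len(n),
                       function(i, j) j - i > min_loop), arr.ind = TRUE)
    if (nrow(idx)) {
      can <- bases_pair(res[idx[, 1L]], res[idx[, 2L]], wobble = wobble)
      keep <- idx[can, , drop = FALSE]
      W[keep] <- base_weight
      if (!is.null(bonus)) W[keep] <- W[keep] + bonus[keep]
    }
  }
  W
}

.dot_bracket <- function(n, pairs) {
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1L]] <- "("
    db[pairs[, 2L]] <- ")"
  }
  paste(db, collapse = "")
}

#' Maximum base-pairing structure of an RNA sequence
#'
#' Computes a pseudoknot-free secondary structure maximising the number of
#' base pairs (Nussinov dynamic programming) under a minimum-loop
#' constraint (`j - i > min_loop` for every pair `(i, j)`), with G-U
#' wobble pairs allowed by default. The maximum pair count is unique; the
#' reported structure uses a deterministic traceback preferring pairs with
#' smaller 5' index.
#'
#' @param seq RNA sequence (DNA accepted, T read as U).
#' @param min_loop minimum number of unpaired residues enclosed by a pair;
#'   default 3.
#' @param allow_wobble allow G-U pairs; default TRUE.
#' @return An object of class `rna_structure`: list with `seq`, `pairs`
#'   (2-column matrix, i < j), `n_pairs`, `dot_bracket`, `min_loop`,
#'   `allow_wobble`.
#' @examples
#' nussinov_maxpairs("GGGAAACCC")$dot_bracket  # "(((...)))"
#' nussinov_maxpairs("AAAAAA")$n_pairs         # 0
#' nussinov_maxpairs("GCGC")$n_pairs           # 0 (loop constraint)
#' @export
nussinov_maxpairs <- function(seq, min_loop = 3L, allow_wobble = TRUE) {
  seq <- check_seq(transcribe(seq), "RNA", what = "seq")
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(res)
  W <- .pair_weight_matrix(res, min_loop, allow_wobble)
  N <- .nussinov_dp(W, n)
  pairs <- .nussinov_traceback(N, W, n)
  structure(list(seq = seq, pairs = pairs, n_pairs = nrow(pairs),
                 dot_bracket = .dot_bracket(n, pairs),
                 min_loop = as.integer(min_loop),
                 allow_wobble = allow_wobble),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> ", x$n_pairs, " pairs\n  ", x$seq, "\n  ",
      x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Intended stem pairs of a design
#'
#' The pairs the construction intends: every non-bubble extension position
#' `p` paired with the full-molecule position of the spacer residue it
#' faces (spacer position `H + 1 - p`, offset by extension and loop).
#'
#' @param design a [build_bh_sgrna()] object.
#' @return A 2-column integer matrix of (i, j) pairs, i < j, in
#'   full-molecule coordinates; zero rows for a WT guide.
#' @examples
#' nrow(intended_pairing(build_bh_sgrna(strrep("A", 20),
#'                                      design_spec("CBE"))))  # 9
#' @export
intended_pairing <- function(design) {
  stopifnot(inherits(design, "bh_sgrna"))
  H <- design$spec$hairpin_len
  if (H == 0L) return(matrix(integer(0L), ncol = 2L))
  loop_len <- nchar(design$loop)
  p <- setdiff(seq_len(H), design$bubble_hairpin)
  spacer_pos <- H + 1L - p
  cbind(i = p, j = H + loop_len + spacer_pos)
}

#' Fold a design and check the intended hairpin
#'
#' Folds the design's 5' region (extension + loop + spacer; any scaffold is
#' excluded) by weighted pair maximisation and reports (a) the largest
#' fraction of intended stem pairs contained in any maximum-pairing
#' structure and (b) how many bubble positions end up paired with the stem
#' residue they face. The weighting makes the search exact: among all
#' structures with the maximum pair count, the one containing the most
#' intended pairs is found.
#'
#' @param design a [build_bh_sgrna()] object.
#' @param min_fraction verdict threshold on the intended-pair fraction;
#'   default 1.0 (all intended pairs must be realisable).
#' @param min_loop,allow_wobble folding parameters, see
#'   [nussinov_maxpairs()].
#' @param exclude_loop keep the tetraloop residues unpaired during
#'   folding (default TRUE): the ACAA loop is a structural turn, and
#'   letting it pair would let spurious topologies outscore the stem.
#'   Set FALSE for a fully unconstrained fold.
#' @return An object of class `hairpin_report`: list with `name`,
#'   `structure`, `n_intended`, `n_intended_present`, `intended_fraction`
#'   (1 when there are no intended pairs), `bubble_paired` (count of bubble
#'   positions paired with their opposing stem residue), `verdict`
#'   (`"PASS"`/`"FAIL"`).
#' @examples
#' hairpin_report(build_bh_sgrna(strrep("A", 20), design_spec("CBE")))$verdict
#' @export
hairpin_report <- function(design, min_fraction = 1.0, min_loop = 3L,
                           allow_wobble = TRUE, exclude_loop = TRUE) {
  stopifnot(inherits(design, "bh_sgrna"))
  H <- design$spec$hairpin_len
  loop_len <- nchar(design$loop)
  region <- paste0(design$extension, design$loop, design$spacer)
  res <- strsplit(region, "", fixed = TRUE)[[1L]]
  n <- length(res)
  intended <- intended_pairing(design)

  # base weight 1000 per pair + 1 bonus for intended pairs: lexicographic
  # (max pair count, then max intended inclusion) since n pairs < 1000
  bonus <- matrix(0, n, n)
  if (nrow(intended)) bonus[intended] <- 1
  W <- .pair_weight_matrix(res, min_loop, allow_wobble,
                           base_weight = 1000, bonus = bonus)
  if (exclude_loop && H > 0L && loop_len > 0L) {
    lp <- (H + 1L):(H + loop_len)
    W[lp, ] <- NA_real_
    W[, lp] <- NA_real_
  }
  N <- .nussinov_dp(W, n)
  pairs <- .nussinov_traceback(N, W, n)
  struct <- structure(list(seq = region, pairs = pairs,
                           n_pairs = nrow(pairs),
                           dot_bracket = .dot_bracket(n, pairs),
                           min_loop = as.integer(min_loop),
                           allow_wobble = allow_wobble),
                      class = "rna_structure")

  key <- function(m) paste(m[, 1L], m[, 2L])
  n_int <- nrow(intended)
  n_present <- if (n_int) sum(key(intended) %in% key(pairs)) else 0L
  frac <- if (n_int) n_present / n_int else 1

  bubble_paired <- 0L
  if (length(design$bubble_hairpin)) {
    opp <- H + loop_len + (H + 1L - design$bubble_hairpin)
    bubble_paired <- sum(key(cbind(design$bubble_hairpin, opp)) %in% key(pairs))
  }
  verdict <- if (frac >= min_fraction && bubble_paired == 0L) "PASS" else "FAIL"
  structure(list(name = design$name, structure = struct,
                 n_intended = n_int, n_intended_present = n_present,
                 intended_fraction = frac, bubble_paired = bubble_paired,
                 verdict = verdict),
            class = "hairpin_report")
}

#' @export
print.hairpin_report <- function(x, ...) {
  cat("<hairpin_report> ", x$name, ": ", x$verdict, "  (",
      x$n_intended_present, "/", x$n_intended,
      " intended pairs; bubble positions paired: ", x$bubble_paired,
      ")\n", sep = "")
  print(x$structure)
  invisible(x)
}
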