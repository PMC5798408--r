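# Catalytic triad assembly and classification.
#
# LPT enzymes carry a catalytic triad of two histidines and an aspartate
# (H-1 in the C2 motif, H-2 and D-3 precisely spaced HxxxD in C3).  FITMs
# conserve the triad with glutamate (E-3) in place of aspartate; the wider
# FITM C3 context is the 14-residue consensus TAØYF-H-TØØ-E-KØØG.

# Extended C3 consensus, positions h2-5 .. h2+8.  "O" marks the hydrophobic
# class Ø = {F,I,L,V}; other entries are literal residues.
C3_CONTEXT_CONSENSUS <- c("T", "A", "O", "Y", "F", "H", "T", "O", "O",
                          "E", "K", "O", "O", "G")

new_triad <- function(h1_pos = NA_integer_, h1_res = NA_character_,
                      h2_pos = NA_integer_, h2_res = NA_character_,
                      third_pos = NA_integer_, third_res = NA_character_,
                      c2_middle = NA_character_,
                      context_score = NA_integer_,
                      f_minus1 = NA, k_plus5 = NA,
                      classification = "incomplete") {
  structure(list(h1_pos = h1_pos, h1_res = h1_res,
                 h2_pos = h2_pos, h2_res = h2_res,
                 third_pos = third_pos, third_res = third_res,
                 c2_middle = c2_middle, context_score = context_score,
                 f_minus1 = f_minus1, k_plus5 = k_plus5,
                 classification = classification),
            class = "triad_assignment")
}

#' @export
print.triad_assignment <- function(x, ...) {
  cat("Catalytic triad assignment:", x$classification, "\n")
  if (!is.na(x$h1_pos)) {
    cat(sprintf("  H-1: %s%d (C2 middle %s)\n", x$h1_res, x$h1_pos, x$c2_middle))
  }
  if (!is.na(x$h2_pos)) {
    cat(sprintf("  H-2: %s%d; third residue: %s%d\n",
                x$h2_res, x$h2_pos, x$third_res, x$third_pos))
    cat(sprintf("  C3 context score %d/14 (F at -1: %s, K at +5: %s)\n",
                x$context_score, x$f_minus1, x$k_plus5))
  }
  invisible(x)
}

#' Score the extended FITM C3 context
#'
#' Compares the 14 residues around a candidate H-2 (positions -5..+8) with
#' the consensus `TAØYF-H-TØØ-E-KØØG`, where Ø matches F/I/L/V and every
#' other position matches exactly.  Positions falling outside the sequence
#' simply do not score.
#'
#' @param seq Amino-acid string.
#' @param h2_pos 1-based position of the candidate H-2.
#' @return List with `score` (0-14), `f_minus1` (F immediately before H-2)
#'   and `k_plus5` (K five residues after H-2).
#' @examples
#' score_c3_context("TALYFHTLLEKLLG", 6)
#' @export
score_c3_context <- function(seq, h2_pos) {
  stopifnot(is.numeric(h2_pos), length(h2_pos) == 1L)
  n <- nchar(seq)
  score <- 0L
  for (j in seq_along(C3_CONTEXT_CONSENSUS)) {
    p <- h2_pos - 6L + j
    if (p < 1L || p > n) next
    res <- substring(seq, p, p)
    want <- C3_CONTEXT_CONSENSUS[j]
    hit <- if (want == "O") res %in% PHI_SET else res == want
    if (hit) score <- score + 1L
  }
  f1 <- h2_pos - 1L
  k5 <- h2_pos + 5L
  list(score = score,
       f_minus1 = f1 >= 1L && substring(seq, f1, f1) == "F",
       k_plus5 = k5 <= n && substring(seq, k5, k5) == "K")
}

#' Classify a catalytic triad
#'
#' Rules, in order: either motif missing -> `incomplete`; H-2 substituted
#' (as in the LPR/PRG pseudo-enzymes, where it is always N or S) ->
#' `likely_inactive`; H-1 substituted -> `likely_inactive` (strict default;
#' `lenient = TRUE` downgrades to `FITM_variant`, since some phosphatases
#' tolerate H-1 variation in a substrate-dependent way); then by the third
#' triad residue: D -> `LPT_canonical`, E -> `FITM_typical`, Q or H ->
#' `FITM_variant`, anything else -> `likely_inactive`.
#'
#' @param t A `triad_assignment`, or a length-3 character vector
#'   `c(h1_res, h2_res, third_res)`.
#' @param lenient Logical; see above.
#' @return Classification string.
#' @examples
#' classify_triad(c("H", "H", "E"))  # FITM_typical
#' classify_triad(c("D", "H", "E"))  # likely_inactive (H-1 substituted)
#' @export
classify_triad <- function(t, lenient = FALSE) {
  if (is.character(t) && length(t) == 3L) {
    t <- new_triad(h1_pos = 1L, h1_res = t[1L], h2_pos = 2L, h2_res = t[2L],
                   third_pos = 6L, third_res = t[3L])
  }
  stopifnot(inherits(t, "triad_assignment"))
  if (is.na(t$h1_pos) || is.na(t$h2_pos)) return("incomplete")
  if (is.na(t$h2_res) || t$h2_res != "H") return("likely_inactive")
  if (is.na(t$h1_res) || t$h1_res != "H") {
    return(if (lenient) "FITM_variant" else "likely_inactive")
  }
  third <- t$third_res
  if (is.na(third)) return("likely_inactive")
  switch(third,
         D = "LPT_canonical",
         E = "FITM_typical",
         Q = ,
         H = "FITM_variant",
         "likely_inactive")
}

#' Locate and classify the catalytic triad of a sequence
#'
#' Finds C2 ([ST]-x-H) and C3 (H-x-x-x-[DEQH]) hits and pairs them into a
#' triad assignment.  With a topology, C2 must lie in a luminal loop and C3
#' in a later luminal loop (in LPTs, C2 closes luminal loop 3/4 and C3 sits
#' in loop 5/6); without one, any pair with C3 downstream of C2 is eligible.
#' Among eligible pairs the one maximising the extended C3 context score
#' wins; ties break to the smallest H-2 position.  A missing motif (or no
#' eligible pair) yields `classification = "incomplete"`, with whatever
#' single motifs were found still reported.
#'
#' @param seq Amino-acid string.
#' @param top Optional `topology`.
#' @param middle_class,third_class Residue classes for [scan_c2()] and
#'   [scan_c3()].
#' @param lenient Passed to [classify_triad()].
#' @return A `triad_assignment`.
#' @export
find_triad <- function(seq, top = NULL,
                       middle_class = C2_MIDDLE_DEFAULT,
                       third_class = C3_THIRD_DEFAULT,
                       lenient = FALSE) {
  if (!is.null(top)) {
    stopifnot(inherits(top, "topology"))
    loops <- topology_loops(top)
    loops$idx <- seq_len(nrow(loops))
    lum <- loops[loops$side == "luminal", , drop = FALSE]
    c2 <- scan_in_loops(seq, lum, scan_c2, middle_class = middle_class)
    c3 <- scan_in_loops(seq, lum, scan_c3, third_class = third_class)
    c2$loop_idx <- loops$idx[match(c2$loop_label, loops$label)]
    c3$loop_idx <- loops$idx[match(c3$loop_label, loops$label)]
  } else {
    c2 <- scan_c2(seq, middle_class = middle_class)
    c3 <- scan_c3(seq, third_class = third_class)
  }
  res <- pair_triad(seq, c2, c3, with_topology = !is.null(top))
  t <- res$triad
  # an unpaired assignment (motif missing, or no eligible C2-C3 pair) is
  # incomplete even if both motifs were seen somewhere in the sequence
  t$classification <- if (res$paired) classify_triad(t, lenient = lenient)
                      else "incomplete"
  t
}

pair_triad <- function(seq, c2, c3, with_topology) {
  best <- NULL
  if (nrow(c2) && nrow(c3)) {
    for (a in seq_len(nrow(c2))) {
      for (b in seq_len(nrow(c3))) {
        eligible <- if (with_topology) {
          c3$loop_idx[b] > c2$loop_idx[a]
        } else {
          c3$start[b] > c2$end[a]
        }
        if (!eligible) next
        ctx <- score_c3_context(seq, c3$h_pos[b])
        cand <- list(a = a, b = b, ctx = ctx)
        if (is.null(best) ||
            ctx$score > best$ctx$score ||
            (ctx$score == best$ctx$score && c3$h_pos[b] < c3$h_pos[best$b])) {
          best <- cand
        }
      }
    }
  }
  if (!is.null(best)) {
    a <- best$a; b <- best$b; ctx <- best$ctx
    return(list(paired = TRUE, triad = new_triad(
      h1_pos = c2$h_pos[a], h1_res = substring(seq, c2$h_pos[a], c2$h_pos[a]),
      h2_pos = c3$h_pos[b], h2_res = substring(seq, c3$h_pos[b], c3$h_pos[b]),
      third_pos = c3$third_pos[b], third_res = c3$third_res[b],
      c2_middle = c2$c2_middle[a],
      context_score = ctx$score, f_minus1 = ctx$f_minus1,
      k_plus5 = ctx$k_plus5)))
  }
  # no eligible pair: report the individual motifs that were found
  t <- new_triad()
  if (nrow(c2)) {
    t$h1_pos <- c2$h_pos[1L]
    t$h1_res <- substring(seq, t$h1_pos, t$h1_pos)
    t$c2_middle <- c2$c2_middle[1L]
  }
  if (nrow(c3)) {
    t$h2_pos <- c3$h_pos[1L]
    t$h2_res <- substring(seq, t$h2_pos, t$h2_pos)
    t$third_pos <- c3$third_pos[1L]
    t$third_res <- c3$third_res[1L]
    ctx <- score_c3_context(seq, t$h2_pos)
    t$context_score <- ctx$score
    t$f_minus1 <- ctx$f_minus1
    t$k_plus5 <- ctx$k_plus5
  }
  list(paired = FALSE, triad = t)
}
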