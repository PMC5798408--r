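# Membrane topology: representation, loop enumeration and single-sequence
# prediction (hydropathy + positive-inside rule).

# Kyte-Doolittle hydropathy scale.  Ambiguity codes get 0 (indifferent).
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3,
  V = 4.2, X = 0, U = 0, B = -3.5, Z = -3.5
)

new_topology <- function(states, tmds, n_term_side) {
  structure(
    list(states = states, tmds = tmds, n_term_side = n_term_side,
         length = nchar(states)),
    class = "topology")
}

#' Build a topology object from a per-residue state string
#'
#' Transmembrane domains (TMDs) are the maximal runs of `M`; the N-terminal
#' side is the side of the first non-membrane state.  The two loops flanking
#' any one TMD must lie on opposite sides of the membrane.
#'
#' @param states Per-residue string over `i` (cytoplasmic), `M` (membrane),
#'   `o` (luminal); `I`/`O` are normalised to `i`/`o`.
#' @return A `topology` object: `states`, a `tmds` data frame of 1-based
#'   inclusive spans, `n_term_side`, `length`.
#' @examples
#' topology_from_states("iiiMMMMMMMMMMMMMMMMMMMMMooo")
#' @export
topology_from_states <- function(states) {
  stopifnot(is.character(states), length(states) == 1L)
  states <- normalise_states(states)
  if (!nzchar(states)) stop("empty topology state string")
  bad <- regexpr("[^iMo]", states)
  if (bad > 0L) {
    stop(sprintf("unknown topology state '%s' at position %d",
                 substr(states, bad, bad), bad))
  }
  ch <- strsplit(states, "")[[1]]
  r <- rle(ch)
  if (all(r$values == "M")) stop("all-membrane topology: no loop states")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_m <- r$values == "M"
  # side alternation: the non-M runs flanking each M run must differ
  for (k in which(is_m)) {
    if (k > 1L && k < length(r$values) && r$values[k - 1L] == r$values[k + 1L]) {
      stop(sprintf(
        "topology side does not alternate across the membrane span at %d-%d",
        starts[k], ends[k]))
    }
  }
  # non-adjacent same-side runs separated only by M runs are fine; but two
  # consecutive non-M runs cannot occur in an rle, so nothing more to check.
  tmds <- data.frame(start = starts[is_m], end = ends[is_m])
  first_side <- r$values[which(!is_m)[1L]]
  n_term_side <- if (first_side == "i") "cytoplasmic" else "luminal"
  new_topology(states, tmds, n_term_side)
}

side_flip <- function(side) {
  ifelse(side == "cytoplasmic", "luminal", "cytoplasmic")
}

#' Enumerate the loops of a topology
#'
#' Returns the N-terminal segment, every inter-TMD loop labelled
#' `"k/(k+1)"` (the segment between TMD k and TMD k+1) and the C-terminal
#' segment, each with its membrane side.  Loops and TMDs partition the
#' sequence; a zero-length loop (adjacent TMDs) is reported with
#' `length = 0` and `start > end`.
#'
#' @param top A `topology` object.
#' @return Data frame with columns `label`, `side`, `start`, `end`, `length`.
#' @export
topology_loops <- function(top) {
  stopifnot(inherits(top, "topology"))
  n_tmd <- nrow(top$tmds)
  len <- top$length
  if (n_tmd == 0L) {
    return(data.frame(label = "N-term", side = top$n_term_side,
                      start = 1L, end = len, length = len,
                      stringsAsFactors = FALSE))
  }
  starts <- c(1L, top$tmds$end + 1L)
  ends <- c(top$tmds$start - 1L, len)
  labels <- c("N-term",
              if (n_tmd > 1L) paste0(seq_len(n_tmd - 1L), "/", 2:n_tmd),
              "C-term")
  sides <- rep(c(top$n_term_side, side_flip(top$n_term_side)),
               length.out = n_tmd + 1L)
  data.frame(label = labels, side = sides, start = starts, end = ends,
             length = pmax(0L, ends - starts + 1L), stringsAsFactors = FALSE)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Membrane topology: %d residues, %d TMD(s), N-terminus %s\n",
              x$length, nrow(x$tmds), x$n_term_side))
  if (nrow(x$tmds)) {
    spans <- paste(sprintf("%d-%d", x$tmds$start, x$tmds$end), collapse = ", ")
    cat("  TMDs:", spans, "\n")
  }
  invisible(x)
}

#' Parameters for single-sequence topology prediction
#'
#' @param window Hydropathy sliding-window width (residues).
#' @param threshold Mean Kyte-Doolittle hydropathy above which a window
#'   centre is a membrane candidate.
#' @param min_tmd_len Candidate runs shorter than this (after merging) are
#'   discarded.
#' @param merge_gap Candidate runs separated by at most this many residues
#'   are merged.
#' @param flank_window Positive-inside rule counts K/R within this many
#'   residues of a TMD end (per cytoplasmic loop).
#' @param whole_loop If `TRUE`, the positive-inside rule counts K/R over
#'   entire cytoplasmic loops instead of the flanking windows.
#' @return A `predictor_params` list.
#' @export
predictor_params <- function(window = 19L, threshold = 1.6,
                             min_tmd_len = 15L, merge_gap = 3L,
                             flank_window = 15L, whole_loop = FALSE) {
  structure(list(window = as.integer(window), threshold = threshold,
                 min_tmd_len = as.integer(min_tmd_len),
                 merge_gap = as.integer(merge_gap),
                 flank_window = as.integer(flank_window),
                 whole_loop = isTRUE(whole_loop)),
            class = "predictor_params")
}

# TMD length bounds applied after merging: long candidate runs are trimmed
# symmetrically, short (but >= min_tmd_len) runs padded, to this range.
TMD_LEN_RANGE <- c(17L, 25L)

#' Predict membrane topology from sequence
#'
#' A deterministic single-sequence stand-in for consensus predictors:
#' candidate membrane segments are maximal runs of sliding-window
#' Kyte-Doolittle hydropathy above threshold (merged across short gaps,
#' length-normalised to 17-25 residues), and the orientation is chosen by
#' the positive-inside rule — of the two alternating side assignments, the
#' one placing more K/R (near TMD ends, or whole loops with
#' `whole_loop = TRUE`) on the cytoplasmic side wins; ties put the
#' N-terminus in the cytoplasm.
#'
#' @param seq Amino-acid string.
#' @param params A [predictor_params()] list.
#' @return A `topology` object.
#' @export
predict_topology <- function(seq, params = predictor_params()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  len <- nchar(seq)
  w <- params$window
  if (len < w) stop(sprintf("sequence length %d is below window size %d", len, w))
  ch <- strsplit(seq, "")[[1]]
  h <- KD_SCALE[ch]
  h[is.na(h)] <- 0
  half <- w %/% 2L
  win_mean <- stats::filter(h, rep(1 / w, w), sides = 2)
  centres <- which(!is.na(win_mean) & win_mean >= params$threshold)
  runs <- collapse_runs(centres, params$merge_gap)
  tmds <- normalise_tmds(runs, len, params$min_tmd_len, win_mean)
  if (nrow(tmds) == 0L) {
    side <- "cytoplasmic"
    states <- paste(rep(if (side == "cytoplasmic") "i" else "o", len),
                    collapse = "")
    return(new_topology(states, tmds, side))
  }
  n_term_side <- orient_positive_inside(ch, tmds, len, params)
  states_vec <- rep("", len)
  sides <- rep(c(n_term_side, side_flip(n_term_side)),
               length.out = nrow(tmds) + 1L)
  loop_starts <- c(1L, tmds$end + 1L)
  loop_ends <- c(tmds$start - 1L, len)
  for (k in seq_along(loop_starts)) {
    if (loop_starts[k] <= loop_ends[k]) {
      states_vec[loop_starts[k]:loop_ends[k]] <-
        if (sides[k] == "cytoplasmic") "i" else "o"
    }
  }
  for (k in seq_len(nrow(tmds))) states_vec[tmds$start[k]:tmds$end[k]] <- "M"
  new_topology(paste(states_vec, collapse = ""), tmds, n_term_side)
}

# Group sorted integer positions into runs, merging runs whose gap is <= gap.
collapse_runs <- function(pos, gap) {
  if (!length(pos)) return(data.frame(start = integer(0), end = integer(0)))
  brk <- which(diff(pos) > gap + 1L)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, length(pos))]
  data.frame(start = starts, end = ends)
}

# Typical membrane helix length; split pieces are trimmed towards it.
TMD_TYPICAL_LEN <- 21L

# Enforce TMD length bounds.  Candidate segments long enough to hold two
# helices are split at their hydropathy minimum (two TMDs around a short
# loop fuse into one above-threshold run); remaining over-long runs are
# trimmed, and short-but-valid runs padded, into the 17-25 window.
normalise_tmds <- function(runs, len, min_tmd_len, win_mean) {
  if (!nrow(runs)) return(runs)
  keep <- (runs$end - runs$start + 1L) >= min_tmd_len
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(runs)
  lo <- TMD_LEN_RANGE[1L]; hi <- TMD_LEN_RANGE[2L]

  pieces <- list()
  split_one <- function(s, e, from_split) {
    L <- e - s + 1L
    if (L > hi && L >= 2L * min_tmd_len + 6L) {
      # wide enough for two helices: cut at the least hydrophobic interior
      # position and process both halves
      interior <- (s + min_tmd_len):(e - min_tmd_len)
      cut <- interior[which.min(win_mean[interior])]
      split_one(s, cut - 1L, TRUE)
      split_one(cut + 1L, e, TRUE)
      return(invisible(NULL))
    }
    if (from_split) {
      # a split piece overshoots into the loop on its split side; shave the
      # less hydrophobic end back to a typical helix length
      while (e - s + 1L > TMD_TYPICAL_LEN) {
        if (win_mean[s] < win_mean[e]) s <- s + 1L else e <- e - 1L
      }
    } else if (L > hi) {
      trim <- L - hi
      s <- s + trim %/% 2L
      e <- s + hi - 1L
    }
    pieces[[length(pieces) + 1L]] <<- c(s, e)
    invisible(NULL)
  }
  for (k in seq_len(nrow(runs))) {
    split_one(runs$start[k], runs$end[k], FALSE)
  }
  runs <- data.frame(start = vapply(pieces, `[`, integer(1), 1L),
                     end = vapply(pieces, `[`, integer(1), 2L))
  runs <- runs[runs$end - runs$start + 1L >= min_tmd_len, , drop = FALSE]
  if (!nrow(runs)) return(runs)
  runs <- runs[order(runs$start), , drop = FALSE]

  for (k in seq_len(nrow(runs))) {
    L <- runs$end[k] - runs$start[k] + 1L
    if (L < lo) {
      pad <- lo - L
      left_lim <- if (k == 1L) 1L else runs$end[k - 1L] + 2L
      right_lim <- if (k == nrow(runs)) len else runs$start[k + 1L] - 2L
      add_l <- min(pad %/% 2L + pad %% 2L, runs$start[k] - left_lim)
      runs$start[k] <- runs$start[k] - max(0L, add_l)
      add_r <- min(lo - (runs$end[k] - runs$start[k] + 1L),
                   right_lim - runs$end[k])
      runs$end[k] <- runs$end[k] + max(0L, add_r)
    }
  }
  rownames(runs) <- NULL
  runs
}

# Choose N-terminal side maximising K+R in cytoplasmic loop residues near
# TMD ends (von Heijne's positive-inside rule); tie -> cytoplasmic N-terminus.
orient_positive_inside <- function(ch, tmds, len, params) {
  n_tmd <- nrow(tmds)
  loop_starts <- c(1L, tmds$end + 1L)
  loop_ends <- c(tmds$start - 1L, len)
  fl <- params$flank_window
  basic_in_loop <- vapply(seq_len(n_tmd + 1L), function(k) {
    s <- loop_starts[k]; e <- loop_ends[k]
    if (s > e) return(0L)
    if (!params$whole_loop) {
      keep <- logical(e - s + 1L)
      pos <- s:e
      if (k > 1L) keep <- keep | (pos <= loop_starts[k] + fl - 1L)
      if (k <= n_tmd) keep <- keep | (pos >= loop_ends[k] - fl + 1L)
      pos <- pos[keep]
    } else pos <- s:e
    sum(ch[pos] %in% c("K", "R"))
  }, integer(1))
  odd <- sum(basic_in_loop[seq(1L, n_tmd + 1L, by = 2L)])
  even <- sum(basic_in_loop[seq(2L, n_tmd + 1L, by = 2L)])
  if (odd >= even) "cytoplasmic" else "luminal"
}
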