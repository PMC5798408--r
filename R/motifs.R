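# Short-linear-motif scanners: ER retrieval signals (di-arginine, C-terminal
# lysine-based), the LPT catalytic-site motifs C1/C2/C3, the FITM luminal
# KxN motif and luminal cysteine pairs.
#
# Matching policy for ambiguity codes (X/U/B/Z): they satisfy no motif
# position — literal positions compare exactly and residue-class positions
# are explicit sets of standard residues — except the pure wildcard "x",
# which matches any character.

# Hydrophobic class for the "Ø" positions of the KxN motif and the extended
# C3 consensus.
PHI_SET <- c("F", "I", "L", "V")
C2_MIDDLE_DEFAULT <- c("G", "S", "D", "T", "L")
C3_THIRD_DEFAULT <- c("D", "E", "Q", "H")

# substring() errors on zero-length positions; scanners use this instead
chars_at <- function(seq, pos) {
  if (!length(pos)) character(0) else substring(seq, pos, pos)
}

empty_hits <- function() {
  data.frame(class = character(0), start = integer(0), end = integer(0),
             matched = character(0), stringsAsFactors = FALSE)
}

make_hits <- function(class, start, end, seq, ...) {
  if (!length(start)) {
    out <- empty_hits()
    extra <- list(...)
    for (nm in names(extra)) out[[nm]] <- extra[[nm]][0]
    return(out)
  }
  out <- data.frame(class = class, start = as.integer(start),
                    end = as.integer(end),
                    matched = substring(seq, start, end),
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Scan for di-arginine ER retention motifs
#'
#' A di-arginine motif is a pair of arginines at distance 1 (`RR`), 2
#' (`RxR`) or 3 (`RxxR`); the wildcard may be any residue, including another
#' R.  In `"greedy"` mode (the per-protein counting convention) the scan
#' moves left to right and pairs each unconsumed R with its nearest
#' downstream R at distance <= 3, so each arginine contributes to at most
#' one motif.  `"all_pairs"` reports every qualifying pair.
#'
#' @param seq Amino-acid string.
#' @param mode `"greedy"` or `"all_pairs"`.
#' @return A hit data frame (`class`, `start`, `end`, `matched`).
#' @examples
#' scan_diarginine("MRRA")
#' scan_diarginine("RRRR", mode = "all_pairs")
#' @export
scan_diarginine <- function(seq, mode = c("greedy", "all_pairs")) {
  mode <- match.arg(mode)
  pos <- which(strsplit(seq, "")[[1]] == "R")
  if (length(pos) < 2L) return(empty_hits())
  cls <- c("RR", "RxR", "RxxR")
  if (mode == "all_pairs") {
    pairs <- list()
    for (a in seq_along(pos)) {
      for (b in seq_along(pos)) {
        if (b > a && pos[b] - pos[a] <= 3L) {
          pairs[[length(pairs) + 1L]] <- c(pos[a], pos[b])
        }
      }
    }
    if (!length(pairs)) return(empty_hits())
    st <- vapply(pairs, `[`, integer(1), 1L)
    en <- vapply(pairs, `[`, integer(1), 2L)
  } else {
    consumed <- logical(length(pos))
    st <- en <- integer(0)
    for (a in seq_along(pos)) {
      if (consumed[a]) next
      b <- which(!consumed & seq_along(pos) > a & pos - pos[a] <= 3L)
      if (!length(b)) next
      b <- b[1L]
      consumed[c(a, b)] <- TRUE
      st <- c(st, pos[a]); en <- c(en, pos[b])
    }
    if (!length(st)) return(empty_hits())
  }
  o <- order(st, en)
  make_hits(cls[en[o] - st[o]], st[o], en[o], seq)
}

# C-terminal retrieval patterns, in priority order.  Each is described by
# residue requirements at offsets from the C-terminus (-1 = last residue);
# unlisted offsets within the pattern length are pure wildcards.
CTERM_PATTERNS <- list(
  KKxx  = list(len = 4L, req = c("-4" = "K", "-3" = "K")),
  KxKxx = list(len = 5L, req = c("-5" = "K", "-3" = "K")),
  RKxx  = list(len = 4L, req = c("-4" = "R", "-3" = "K")),
  RxKxx = list(len = 5L, req = c("-5" = "R", "-3" = "K")),
  KxRxx = list(len = 5L, req = c("-5" = "K", "-3" = "R")),
  HxHxx = list(len = 5L, req = c("-5" = "H", "-3" = "H")),
  KxHxx = list(len = 5L, req = c("-5" = "K", "-3" = "H"))
)

#' Scan the extreme C-terminus for a lysine-based retrieval signal
#'
#' Tests the final residues against, in priority order: the canonical
#' di-lysine signals `KKxx` and `KxKxx`, then the proven variants `RKxx`,
#' `RxKxx`, `KxRxx`, `HxHxx` and `KxHxx`.  At most one motif (the first
#' match) is returned; sequences shorter than a pattern skip that pattern.
#'
#' @param seq Amino-acid string.
#' @return A one-row hit data frame, or a zero-row frame if no signal.
#' @examples
#' scan_cterminal("MAWKKAA")
#' @export
scan_cterminal <- function(seq) {
  n <- nchar(seq)
  for (cls in names(CTERM_PATTERNS)) {
    p <- CTERM_PATTERNS[[cls]]
    if (n < p$len) next
    off <- as.integer(names(p$req))
    at <- n + off + 1L
    if (all(substring(seq, at, at) == p$req)) {
      return(make_hits(cls, n - p$len + 1L, n, seq))
    }
  }
  empty_hits()
}

# Generic fixed-length window scan.  matchers is a list, one per position:
# NULL for pure wildcard, otherwise a character vector of allowed residues.
scan_windows <- function(seq, matchers) {
  k <- length(matchers)
  n <- nchar(seq)
  if (n < k) return(integer(0))
  ch <- strsplit(seq, "")[[1]]
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    m <- matchers[[j]]
    if (is.null(m)) next
    ok <- ok & ch[seq.int(j, n - k + j)] %in% m
  }
  which(ok)
}

#' Scan for the LPT-specific C1 motif (K-x6-RP)
#'
#' @param region Amino-acid string (typically a luminal loop).
#' @return Hit data frame; each hit spans 9 residues.
#' @export
scan_c1 <- function(region) {
  st <- scan_windows(region, c(list("K"), rep(list(NULL), 6L),
                               list("R"), list("P")))
  make_hits("C1", st, st + 8L, region)
}

#' Scan for the C2 catalytic motif ([ST]-x-H, canonically "SGH")
#'
#' The histidine of a C2 hit is the candidate first triad histidine (H-1).
#' The middle position admits the naturally occurring substitutions of the
#' canonical glycine (S in FITM1, D in SAR/algal sequences, T and L in other
#' active phosphatases).
#'
#' @param region Amino-acid string.
#' @param middle_class Allowed middle residues.
#' @return Hit data frame with `c2_first`, `c2_middle` and `h_pos` columns.
#' @export
scan_c2 <- function(region, middle_class = C2_MIDDLE_DEFAULT) {
  st <- scan_windows(region, list(c("S", "T"), middle_class, "H"))
  make_hits("C2", st, st + 2L, region,
            c2_first = chars_at(region, st),
            c2_middle = chars_at(region, st + 1L),
            h_pos = st + 2L)
}

#' Scan for the C3 catalytic motif (H-x-x-x-[DEQH])
#'
#' The histidine is the candidate second triad histidine (H-2) and the fifth
#' residue the candidate third triad residue (aspartate in canonical LPTs,
#' typically glutamate in FITMs, sometimes Q or H).
#'
#' @param region Amino-acid string.
#' @param third_class Allowed fifth residues.
#' @return Hit data frame with `third_res`, `h_pos`, `third_pos` columns.
#' @export
scan_c3 <- function(region, third_class = C3_THIRD_DEFAULT) {
  st <- scan_windows(region, c(list("H"), rep(list(NULL), 3L),
                               list(third_class)))
  make_hits("C3", st, st + 4L, region,
            third_res = chars_at(region, st + 4L),
            h_pos = st, third_pos = st + 4L)
}

#' Scan for the FITM luminal KxN motif (x-x-N-Ø-Ø-N)
#'
#' Ø is a hydrophobic residue (F/I/L/V).  The first position is typically,
#' but not necessarily, lysine; `has_K` records whether it is.
#'
#' @param region Amino-acid string.
#' @param phi Hydrophobic residue set for the Ø positions.
#' @return Hit data frame with a `has_K` column.
#' @export
scan_kxn <- function(region, phi = PHI_SET) {
  st <- scan_windows(region, list(NULL, NULL, "N", phi, phi, "N"))
  make_hits("KxN", st, st + 5L, region,
            has_K = chars_at(region, st) == "K")
}

#' Detect a disulphide-capable cysteine pair
#'
#' If a region holds two or more cysteines, returns one hit spanning the
#' first and last cysteine; `n_cys` records how many lie in the region.
#' Intended for the long luminal loop 3/4, where FITMs and LPTs carry a
#' structural disulphide, but callable on any region.
#'
#' @param region Amino-acid string.
#' @return One-row hit data frame with `n_cys`, or zero rows.
#' @export
scan_cys_pair <- function(region) {
  pos <- which(strsplit(region, "")[[1]] == "C")
  if (length(pos) < 2L) {
    out <- empty_hits(); out$n_cys <- integer(0); return(out)
  }
  make_hits("CYS_PAIR", pos[1L], pos[length(pos)], region,
            n_cys = length(pos))
}

#' Assign motif hits to topology loops
#'
#' Each hit whose span lies entirely within one loop gains that loop's label
#' and side; hits overlapping a TMD (or spanning a loop boundary) get `NA`
#' for both and are excluded from side-filtered counts.
#'
#' @param hits A hit data frame (whole-sequence coordinates).
#' @param loops Loop table from [topology_loops()].
#' @return `hits` with `loop_label` and `side` columns added.
#' @export
assign_loops <- function(hits, loops) {
  hits$loop_label <- rep(NA_character_, nrow(hits))
  hits$side <- rep(NA_character_, nrow(hits))
  if (!nrow(hits)) return(hits)
  for (k in seq_len(nrow(loops))) {
    if (loops$length[k] == 0L) next
    inside <- hits$start >= loops$start[k] & hits$end <= loops$end[k]
    hits$loop_label[inside] <- loops$label[k]
    hits$side[inside] <- loops$side[k]
  }
  hits
}

# Scan each loop of one side separately, shifting spans back to sequence
# coordinates.  Motifs straddling a loop boundary cannot match.
scan_in_loops <- function(seq, loops, scanner, side = NULL, ...) {
  if (!is.null(side)) loops <- loops[loops$side == side, , drop = FALSE]
  loops <- loops[loops$length > 0L, , drop = FALSE]
  out <- NULL
  for (k in seq_len(nrow(loops))) {
    h <- scanner(substring(seq, loops$start[k], loops$end[k]), ...)
    if (!nrow(h)) next
    shift <- loops$start[k] - 1L
    h$start <- h$start + shift
    h$end <- h$end + shift
    if ("h_pos" %in% names(h)) h$h_pos <- h$h_pos + shift
    if ("third_pos" %in% names(h)) h$third_pos <- h$third_pos + shift
    h$loop_label <- loops$label[k]
    h$side <- loops$side[k]
    out <- if (is.null(out)) h else rbind(out, h)
  }
  if (is.null(out)) {
    out <- scanner(substring(seq, 1L, 0L), ...)
    out$loop_label <- character(0)
    out$side <- character(0)
  }
  out
}
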