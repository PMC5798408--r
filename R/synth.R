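# Synthetic polytopic membrane proteins with planted TMDs and motifs, plus
# exact ground truth, so every pipeline stage can be tested offline.

# Background excludes every residue that could complete a motif around a
# planted anchor (R, K, H, C; the hydrophobic class F/I/L/V; S/T and
# D/E/Q which flank planted histidines into spurious C2/C3 hits; and M,
# whose hydropathy is membrane-like).  See the methods vignette.
SYNTH_BACKGROUND <- c("A", "G", "N", "P", "W", "Y")
SYNTH_TMD_ALPHABET <- c("L", "I", "V", "F")

# Canonical planted instance per motif class; "." positions are filled from
# the background alphabet at generation time.
MOTIF_TEMPLATES <- list(
  RR = "RR", RxR = "R.R", RxxR = "R..R",
  KKxx = "KK..", KxKxx = "K.K..", RKxx = "RK..", RxKxx = "R.K..",
  KxRxx = "K.R..", HxHxx = "H.H..", KxHxx = "K.H..",
  C1 = "K......RP", C2 = "SGH", C3 = "H...E", KxN = "K.NLVN",
  CYS_PAIR = "C..C"
)
CTERM_CLASSES <- c("KKxx", "KxKxx", "RKxx", "RxKxx", "KxRxx", "HxHxx", "KxHxx")
DIARG_CLASSES <- c("RR", "RxR", "RxxR")

#' Specify a synthetic membrane protein
#'
#' Default anatomy emulates a FITM-like 6-TMD protein: cytoplasmic
#' N-terminus, 21-residue TMDs, a long luminal loop 3/4, and loops that
#' alternate sides.  Planted motifs are written over the background at a
#' loop-relative offset, with exact spans recorded as ground truth.
#'
#' @param n_tmds Number of transmembrane domains (>= 0).
#' @param tmd_len TMD length in residues.
#' @param loop_lens Lengths of the `n_tmds + 1` loops, N- to C-terminal.
#' @param n_term_side `"cytoplasmic"` or `"luminal"`.
#' @param planted_motifs List of `list(class=, loop=, offset=)` entries:
#'   motif class (see names of `fitmscan:::MOTIF_TEMPLATES`), loop label
#'   (`"N-term"`, `"1/2"`, ..., `"C-term"`), and 1-based offset within the
#'   loop.  `offset = NA` for a C-terminal signal class plants it flush with
#'   the protein's C-terminus.
#' @param background,tmd_alphabet Residue sets for loop background and TMD
#'   segments.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_tmds = 6L, tmd_len = 21L,
                           loop_lens = c(25L, 15L, 12L, 60L, 12L, 15L, 30L),
                           n_term_side = "cytoplasmic",
                           planted_motifs = list(),
                           background = SYNTH_BACKGROUND,
                           tmd_alphabet = SYNTH_TMD_ALPHABET,
                           seed = 1L) {
  n_tmds <- as.integer(n_tmds)
  stopifnot(n_tmds >= 0L, tmd_len >= 1L)
  if (length(loop_lens) != n_tmds + 1L) {
    stop(sprintf("need %d loop lengths for %d TMDs, got %d",
                 n_tmds + 1L, n_tmds, length(loop_lens)))
  }
  stopifnot(n_term_side %in% c("cytoplasmic", "luminal"))
  structure(list(n_tmds = n_tmds, tmd_len = as.integer(tmd_len),
                 loop_lens = as.integer(loop_lens), n_term_side = n_term_side,
                 planted_motifs = planted_motifs, background = background,
                 tmd_alphabet = tmd_alphabet, seed = as.integer(seed)),
            class = "synthetic_spec")
}

synth_loop_labels <- function(n_tmds) {
  if (n_tmds == 0L) return("N-term")
  c("N-term", if (n_tmds > 1L) paste0(seq_len(n_tmds - 1L), "/", 2:n_tmds),
    "C-term")
}

#' Generate one synthetic protein with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param id Record identifier.
#' @return List with `record` (one-row `protein_set`, source
#'   `"synthetic"`) and `truth` (list: `states` topology string, `hits`
#'   data frame of planted motifs with exact spans, loop labels and sides).
#' @examples
#' sp <- synthetic_spec(planted_motifs = list(
#'   list(class = "RR", loop = "2/3", offset = 4),
#'   list(class = "C2", loop = "3/4", offset = 50),
#'   list(class = "C3", loop = "5/6", offset = 5)))
#' generate_protein(sp)$truth$hits
#' @export
generate_protein <- function(spec, id = "synth1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  build_synthetic(spec, id)
}

# Assemble loop/TMD/loop... under the current RNG state.
build_synthetic <- function(spec, id) {
  labels <- synth_loop_labels(spec$n_tmds)
  sides <- rep(c(spec$n_term_side, side_flip(spec$n_term_side)),
               length.out = spec$n_tmds + 1L)
  segs <- list()
  states <- list()
  loop_start <- integer(length(labels))
  pos <- 1L
  for (k in seq_along(labels)) {
    L <- spec$loop_lens[k]
    loop_start[k] <- pos
    segs[[length(segs) + 1L]] <-
      paste(sample(spec$background, L, replace = TRUE), collapse = "")
    states[[length(states) + 1L]] <-
      paste(rep(if (sides[k] == "cytoplasmic") "i" else "o", L), collapse = "")
    pos <- pos + L
    if (k <= spec$n_tmds) {
      segs[[length(segs) + 1L]] <-
        paste(sample(spec$tmd_alphabet, spec$tmd_len, replace = TRUE),
              collapse = "")
      states[[length(states) + 1L]] <-
        paste(rep("M", spec$tmd_len), collapse = "")
      pos <- pos + spec$tmd_len
    }
  }
  seq <- paste(unlist(segs), collapse = "")
  st <- paste(unlist(states), collapse = "")

  truth <- empty_hits()
  truth$loop_label <- character(0)
  truth$side <- character(0)
  seq_ch <- strsplit(seq, "")[[1]]
  for (pm in spec$planted_motifs) {
    cls <- pm$class
    tmpl <- MOTIF_TEMPLATES[[cls]]
    if (is.null(tmpl)) stop("unknown motif class to plant: ", cls)
    k <- match(pm$loop, labels)
    if (is.na(k)) stop(sprintf("no loop '%s' for motif %s", pm$loop, cls))
    mlen <- nchar(tmpl)
    offset <- pm$offset
    if (is.null(offset) || is.na(offset)) {
      if (!cls %in% CTERM_CLASSES) {
        stop("offset is required for non-C-terminal motif ", cls)
      }
      offset <- spec$loop_lens[k] - mlen + 1L
    }
    if (offset < 1L || offset + mlen - 1L > spec$loop_lens[k]) {
      stop(sprintf("motif %s (length %d) does not fit loop '%s' at offset %d",
                   cls, mlen, pm$loop, offset))
    }
    at <- loop_start[k] + offset - 1L
    tch <- strsplit(tmpl, "")[[1]]
    fill <- tch == "."
    tch[fill] <- sample(spec$background, sum(fill), replace = TRUE)
    seq_ch[at:(at + mlen - 1L)] <- tch
    truth <- rbind(truth, data.frame(
      class = cls, start = at, end = at + mlen - 1L,
      matched = paste(tch, collapse = ""),
      loop_label = labels[k], side = sides[k], stringsAsFactors = FALSE))
  }
  seq <- paste(seq_ch, collapse = "")
  if (nrow(truth)) truth$matched <- substring(seq, truth$start, truth$end)
  list(record = new_protein_set(id, "synthetic membrane protein", seq,
                                "synthetic"),
       truth = list(states = st, hits = truth))
}

#' Generate a synthetic protein family
#'
#' Produces `n` diverged copies of the protein described by `spec`.  Each
#' member gets its own RNG substream (derived by index from `seed`), so
#' member `i` is reproducible regardless of `n`.  Substitutions are drawn
#' from the background alphabet and, unless `mutate_motifs = TRUE`, never
#' fall inside planted motif spans.
#'
#' @param n Number of family members.
#' @param spec A [synthetic_spec()].
#' @param divergence Per-site substitution probability in `[0, 1]`.
#' @param seed Integer seed for the family.
#' @param mutate_motifs Allow substitutions inside planted motifs.
#' @param id_prefix Member ids are `<id_prefix><i>`.
#' @return List of `n` elements, each a `list(record, truth)` as in
#'   [generate_protein()].
#' @export
generate_family <- function(n, spec, divergence = 0.05, seed = spec$seed,
                            mutate_motifs = FALSE, id_prefix = "fam") {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 1L,
            divergence >= 0, divergence <= 1)
  set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max, n)
  base <- generate_protein(spec)
  seq_ch <- strsplit(base$record$sequence, "")[[1]]
  st_ch <- strsplit(base$truth$states, "")[[1]]
  protected <- logical(length(seq_ch))
  if (!mutate_motifs && nrow(base$truth$hits)) {
    for (k in seq_len(nrow(base$truth$hits))) {
      protected[base$truth$hits$start[k]:base$truth$hits$end[k]] <- TRUE
    }
  }
  # only loop residues are mutated, keeping the hydrophobic TMDs intact
  mutable <- which(!protected & st_ch != "M")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(member_seeds[i])
    ch <- seq_ch
    hit <- mutable[stats::runif(length(mutable)) < divergence]
    for (p in hit) {
      alt <- setdiff(spec$background, ch[p])
      ch[p] <- if (length(alt)) sample(alt, 1L) else ch[p]
    }
    seq <- paste(ch, collapse = "")
    truth <- base$truth
    if (nrow(truth$hits)) {
      truth$hits$matched <- substring(seq, truth$hits$start, truth$hits$end)
    }
    out[[i]] <- list(
      record = new_protein_set(paste0(id_prefix, i),
                               "synthetic family member", seq, "synthetic"),
      truth = truth)
  }
  out
}

#' Write synthetic output files
#'
#' Emits `<prefix>.fasta`, `<prefix>.topo` (two-column topology dialect) and
#' `<prefix>.truth.json` (ground-truth motif spans) for a list of generated
#' proteins.
#'
#' @param generated A `list(record, truth)` or a list of them.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_synthetic <- function(generated, prefix) {
  if (!is.null(generated$record)) generated <- list(generated)
  recs <- do.call(rbind, lapply(generated, `[[`, "record"))
  class(recs) <- c("protein_set", "data.frame")
  paths <- paste0(prefix, c(".fasta", ".topo", ".truth.json"))
  write_fasta(recs, paths[1L])
  states <- stats::setNames(
    vapply(generated, function(g) g$truth$states, character(1)), recs$id)
  write_topology(states, paths[2L])
  truth <- lapply(generated, function(g) g$truth$hits)
  names(truth) <- recs$id
  jsonlite::write_json(truth, paths[3L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
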