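# Sequence and annotation input/output.

#' @importFrom utils write.table read.delim
NULL

# Residues accepted in input sequences: the 20 standard amino acids plus the
# ambiguity/rare codes X, U, B, Z.  Ambiguity codes are carried through but
# never satisfy a motif position (see scan_* functions).
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALLOWED <- c(AA_STANDARD, "X", "U", "B", "Z")

new_protein_set <- function(id, description, sequence, source) {
  out <- data.frame(
    id = as.character(id),
    description = as.character(description),
    sequence = as.character(sequence),
    source = as.character(source),
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased, a single terminal stop character (`*`) is
#' stripped, and the residue alphabet is validated (the 20 standard amino
#' acids plus X/U/B/Z).  Record identifiers are the first whitespace-delimited
#' token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @param source Provenance tag stored with each record
#'   (`"file"`, `"synthetic"` or `"fetched"`).
#' @return A `protein_set` data frame with columns `id`, `description`,
#'   `sequence` and `source`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a demo", "MRRA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, source = "file") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("no sequences could be read from '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no sequences in '", path, "'")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)  # terminal stop only
  if (any(!nzchar(ids))) stop("empty sequence identifier in '", path, "'")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1L])
  for (k in seq_along(seqs)) {
    if (!nzchar(seqs[k])) stop("empty sequence for id '", ids[k], "'")
    bad <- regexpr(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), seqs[k])
    if (bad > 0L) {
      stop(sprintf("illegal character '%s' in sequence '%s' at residue %d",
                   substr(seqs[k], bad, bad), ids[k], bad))
    }
  }
  new_protein_set(ids, desc, seqs, source)
}

#' Write a protein set to FASTA
#'
#' @param proteins A `protein_set` data frame (see [read_fasta()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  set <- Biostrings::BStringSet(proteins$sequence)
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  names(set) <- ifelse(nzchar(desc), paste(proteins$id, desc), proteins$id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

TOPO_STATES <- c("i", "M", "o")

#' Read per-residue membrane topology annotations
#'
#' Two dialects are accepted and auto-detected per line:
#' \describe{
#'   \item{two-column}{`id<TAB>statestring`, one protein per line.}
#'   \item{TOPCONS-style blocks}{framing lines are skipped; an id is taken
#'     from `Sequence name:` lines or `>` headers, and subsequent lines
#'     consisting solely of topology states are concatenated for that id.}
#' }
#' States are `i` (cytoplasmic, "inside"), `M` (membrane) and `o` (luminal /
#' extracytoplasmic, "outside"); uppercase `I`/`O` (reentrant states in some
#' predictor outputs) are normalised to `i`/`o`.
#'
#' @param path Path to the annotation file.
#' @param proteins Optional `protein_set`; when given, each state string is
#'   checked for an exact length match against the sequence of the same id.
#' @return A named character vector of state strings, one per protein id.
#' @export
read_topology <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  states <- character(0)
  current <- NA_character_
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("\t", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) stop("malformed topology line: ", ln)
      id <- trimws(parts[1L])
      st <- trimws(parts[2L])
      bad <- regexpr("[^iMoIO]", st)
      if (bad > 0L) {
        stop(sprintf("unknown topology state '%s' for '%s' at position %d",
                     substr(st, bad, bad), id, bad))
      }
      states[id] <- normalise_states(st)
      current <- NA_character_
    } else if (grepl("^>", ln)) {
      current <- sub("\\s.*$", "", sub("^>", "", ln))
    } else if (grepl("^Sequence name:", ln)) {
      current <- trimws(sub("^Sequence name:", "", ln))
    } else if (grepl("^[iMoIO]+$", ln) && grepl("[io]", ln)) {
      # A topology state line; requires at least one lowercase side state so
      # that amino-acid lines made only of I/M/O are not mistaken for states.
      if (is.na(current)) stop("topology states found before any sequence id")
      prev <- if (current %in% names(states)) states[[current]] else ""
      states[current] <- paste0(prev, normalise_states(ln))
    }
    # all other lines are predictor framing and are skipped
  }
  if (!length(states)) stop("no topology annotations in '", path, "'")
  if (!is.null(proteins)) {
    for (id in names(states)) {
      j <- match(id, proteins$id)
      if (is.na(j)) next
      if (nchar(states[[id]]) != nchar(proteins$sequence[j])) {
        stop(sprintf(
          "topology length %d does not match sequence length %d for '%s'",
          nchar(states[[id]]), nchar(proteins$sequence[j]), id))
      }
    }
  }
  states
}

normalise_states <- function(st) chartr("IO", "io", st)

#' Write a two-column topology annotation file
#'
#' @param states Named character vector of per-residue state strings.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(states, path) {
  writeLines(paste(names(states), states, sep = "\t"), path)
  invisible(path)
}

#' Read a protein-to-family group table
#'
#' @param path TSV with two columns, id and group label (no header, or a
#'   header line starting with `id`).
#' @return Named character vector mapping id to label.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("group table not found: ", path)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group table needs two columns: id, label")
  if (tolower(tab[1L, 1L]) %in% c("id", "#id")) tab <- tab[-1L, , drop = FALSE]
  ids <- as.character(tab[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("id mapped to more than one group: ", dup[1L])
  stats::setNames(as.character(tab[[2L]]), ids)
}

# Stable column order shared by the TSV report and the profile table.
PROFILE_COLUMNS <- c(
  "id", "n_diarg_total", "n_diarg_cyto", "cterm_motif", "kxn_present",
  "kxn_has_K", "cys_pair_34", "localization", "h1_pos", "h1_res", "h2_pos",
  "h2_res", "third_pos", "third_res", "c2_middle", "context_score",
  "f_minus1", "k_plus5", "triad_class"
)

#' Write a per-protein retention report
#'
#' TSV holds one row per protein in a stable column order; JSON is a lossless
#' dump that additionally carries every motif hit with its span, loop and
#' side assignment.
#'
#' @param profiles A list of `retention_profile` objects (see
#'   [build_profile()]).
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(profiles, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- profile_table(profiles)
    ok <- tryCatch({
      write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  na = "")
      TRUE
    }, error = function(e) stop("cannot write report to '", path, "': ",
                                conditionMessage(e), call. = FALSE))
  } else {
    payload <- lapply(profiles, profile_to_list)
    names(payload) <- NULL
    tryCatch(
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           na = "null"),
      error = function(e) stop("cannot write report to '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  invisible(path)
}

#' Tabulate retention profiles
#'
#' @param profiles A list of `retention_profile` objects.
#' @return A data frame with one row per profile in stable column order
#'   ([write_report()] TSV layout); zero rows for an empty list.
#' @export
profile_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    t <- p$triad
    data.frame(
      id = p$id,
      n_diarg_total = p$n_diarg_total,
      n_diarg_cyto = if (is.null(p$n_diarg_cyto)) NA_integer_ else p$n_diarg_cyto,
      cterm_motif = if (is.na(p$cterm_motif)) NA_character_ else p$cterm_motif,
      kxn_present = p$kxn_present,
      kxn_has_K = p$kxn_has_K,
      cys_pair_34 = p$cys_pair_34,
      localization = p$localization,
      h1_pos = t$h1_pos, h1_res = t$h1_res,
      h2_pos = t$h2_pos, h2_res = t$h2_res,
      third_pos = t$third_pos, third_res = t$third_res,
      c2_middle = t$c2_middle,
      context_score = t$context_score,
      f_minus1 = t$f_minus1, k_plus5 = t$k_plus5,
      triad_class = t$classification,
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    out <- as.data.frame(
      stats::setNames(rep(list(logical(0)), length(PROFILE_COLUMNS)),
                      PROFILE_COLUMNS))
    return(out)
  }
  out <- do.call(rbind, rows)
  out[, PROFILE_COLUMNS]
}

profile_to_list <- function(p) {
  list(
    id = p$id,
    n_diarg_total = p$n_diarg_total,
    n_diarg_cyto = if (is.null(p$n_diarg_cyto)) NULL else p$n_diarg_cyto,
    cterm_motif = if (is.na(p$cterm_motif)) NULL else p$cterm_motif,
    kxn_present = p$kxn_present,
    kxn_has_K = p$kxn_has_K,
    cys_pair_34 = p$cys_pair_34,
    localization = p$localization,
    triad = unclass(p$triad),
    hits = p$hits
  )
}
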