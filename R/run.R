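# Orchestration: whole-FASTA scans, family summaries and synthetic output,
# as called by the command-line front-end in inst/cli/fitmscan.

#' Read a YAML run configuration
#'
#' Recognised keys: `mode` ("cytoplasmic"/"all"), `diarg_mode`,
#' `middle_class`, `third_class`, `phi`, `luminal_restrict`, `lenient`, and
#' a `predictor` block (`window`, `threshold`, `min_tmd_len`, `merge_gap`,
#' `flank_window`, `whole_loop`).  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return List with `mode` and a [scan_config()] in `$config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("mode", "diarg_mode", "middle_class", "third_class", "phi",
             "luminal_restrict", "lenient", "predictor")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  pp <- do.call(predictor_params, as.list(raw$predictor))
  cfg <- scan_config(
    diarg_mode = if (is.null(raw$diarg_mode)) "greedy" else raw$diarg_mode,
    middle_class = if (is.null(raw$middle_class)) C2_MIDDLE_DEFAULT else raw$middle_class,
    third_class = if (is.null(raw$third_class)) C3_THIRD_DEFAULT else raw$third_class,
    phi = if (is.null(raw$phi)) PHI_SET else raw$phi,
    luminal_restrict = if (is.null(raw$luminal_restrict)) TRUE else raw$luminal_restrict,
    lenient = isTRUE(raw$lenient),
    predictor = pp)
  list(mode = if (is.null(raw$mode)) "all" else raw$mode, config = cfg)
}

#' Scan a FASTA file and write retention reports
#'
#' @param fasta Path to protein FASTA.
#' @param topology Optional path to a topology annotation file
#'   ([read_topology()] dialects).
#' @param predict Predict topology for proteins without a supplied one.
#' @param mode `"cytoplasmic"` (motifs mapped onto topology; requires a
#'   topology source) or `"all"` (whole-sequence counts only).
#' @param config A [scan_config()].
#' @param out_prefix If non-`NULL`, writes `<prefix>.tsv` and
#'   `<prefix>.json` reports.
#' @param quiet Suppress per-protein summary lines (written to stderr).
#' @return The profile table (invisibly the list of profiles as attribute
#'   `"profiles"`).
#' @export
run_scan <- function(fasta, topology = NULL, predict = FALSE,
                     mode = c("all", "cytoplasmic"), config = scan_config(),
                     out_prefix = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  proteins <- read_fasta(fasta)
  topo <- NULL
  if (!is.null(topology)) topo <- read_topology(topology, proteins)
  if (mode == "cytoplasmic" && is.null(topo) && !isTRUE(predict)) {
    stop("cytoplasmic mode needs a topology file or predict = TRUE")
  }
  profiles <- profile_proteins(proteins, topologies = topo,
                               predict = isTRUE(predict), config = config)
  if (!quiet) {
    for (p in profiles) {
      message(sprintf(
        "%s: %d di-arginine (cyto: %s), C-term %s, triad %s -> %s",
        p$id, p$n_diarg_total,
        if (is.null(p$n_diarg_cyto)) "-" else p$n_diarg_cyto,
        if (is.na(p$cterm_motif)) "none" else p$cterm_motif,
        p$triad$classification, p$localization))
    }
  }
  if (!is.null(out_prefix)) {
    write_report(profiles, paste0(out_prefix, ".tsv"), "tsv")
    write_report(profiles, paste0(out_prefix, ".json"), "json")
  }
  tab <- profile_table(profiles)
  attr(tab, "profiles") <- profiles
  invisible(tab)
}

#' Summarise motif statistics per family and compare groups
#'
#' @param fasta Path to protein FASTA covering all grouped proteins.
#' @param groups Path to an id-to-label TSV ([read_groups()]).
#' @param compare Optional character vector of two labels to compare.
#' @param topology,predict,config As in [run_scan()].
#' @param count_field `"total"` or `"cyto"` di-arginine counts.
#' @param out If non-`NULL`, the family summary TSV path.
#' @return List with `families` (summary data frame) and `comparison`
#'   (or `NULL`).
#' @export
run_family <- function(fasta, groups, compare = NULL, topology = NULL,
                       predict = FALSE, config = scan_config(),
                       count_field = c("total", "cyto"), out = NULL) {
  count_field <- match.arg(count_field)
  proteins <- read_fasta(fasta)
  grp <- read_groups(groups)
  missing <- setdiff(names(grp), proteins$id)
  if (length(missing)) {
    stop("grouped id not present in FASTA: ", missing[1L])
  }
  topo <- if (!is.null(topology)) read_topology(topology, proteins) else NULL
  keep <- proteins$id %in% names(grp)
  profiles <- profile_proteins(proteins[keep, , drop = FALSE],
                               topologies = topo, predict = isTRUE(predict),
                               config = config)
  labels <- grp[vapply(profiles, function(p) p$id, character(1))]
  fams <- lapply(split(profiles, labels), function(ps) {
    aggregate_family(ps, count_field = count_field,
                     label = grp[[ps[[1L]]$id]])
  })
  tab <- family_table(fams)
  if (!is.null(out)) {
    write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cmp <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2L)
    for (lb in compare) {
      if (!lb %in% names(fams)) stop("no such group to compare: ", lb)
    }
    cmp <- compare_groups(fams[[compare[1L]]], fams[[compare[2L]]])
  }
  list(families = tab, comparison = cmp)
}

#' Generate synthetic proteins from a YAML spec and write them out
#'
#' The YAML mirrors [synthetic_spec()] fields, plus optional `n_members`
#' and `divergence` to emit a diverged family instead of a single protein.
#' (`n_members`, not `n`: a bare `n` is a YAML 1.1 boolean.)
#'
#' @param spec A `synthetic_spec`, or the path to a YAML file describing
#'   one.
#' @param out_prefix Output prefix for [write_synthetic()].
#' @return Paths written, invisibly.
#' @export
run_synth <- function(spec, out_prefix) {
  n <- 1L
  divergence <- 0
  if (is.character(spec)) {
    raw <- yaml::read_yaml(spec)
    # exact indexing: $ would partial-match against n_tmds/n_term_side
    n <- if (is.null(raw[["n_members"]])) 1L else as.integer(raw[["n_members"]])
    divergence <- if (is.null(raw[["divergence"]])) 0 else raw[["divergence"]]
    raw[["n_members"]] <- NULL; raw[["divergence"]] <- NULL
    if (!is.null(raw[["planted_motifs"]])) {
      raw[["planted_motifs"]] <- lapply(raw[["planted_motifs"]], as.list)
    }
    spec <- do.call(synthetic_spec, raw)
  }
  stopifnot(inherits(spec, "synthetic_spec"))
  gen <- if (n > 1L) {
    generate_family(n, spec, divergence = divergence)
  } else {
    generate_protein(spec)
  }
  write_synthetic(gen, out_prefix)
}
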