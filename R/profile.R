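# Per-protein retention profiling, ER-localization prediction and
# family-level aggregation.

#' Scan configuration
#'
#' @param diarg_mode Di-arginine counting convention: `"greedy"`
#'   (non-overlapping pairs, default) or `"all_pairs"`.
#' @param middle_class,third_class,phi Residue-class overrides for the C2
#'   middle position, the C3 fifth position and the hydrophobic Ø class.
#' @param luminal_restrict If `TRUE` (default) the catalytic-site scanners
#'   (C1, C2, C3, KxN) are restricted to luminal loops whenever a topology
#'   is available — the LPT catalytic centre always faces the lumen.
#' @param lenient Lenient triad classification (see [classify_triad()]).
#' @param predictor [predictor_params()] used when topology is predicted.
#' @return A `scan_config` list.
#' @export
scan_config <- function(diarg_mode = c("greedy", "all_pairs"),
                        middle_class = C2_MIDDLE_DEFAULT,
                        third_class = C3_THIRD_DEFAULT,
                        phi = PHI_SET,
                        luminal_restrict = TRUE,
                        lenient = FALSE,
                        predictor = predictor_params()) {
  diarg_mode <- match.arg(diarg_mode)
  structure(list(diarg_mode = diarg_mode, middle_class = middle_class,
                 third_class = third_class, phi = phi,
                 luminal_restrict = isTRUE(luminal_restrict),
                 lenient = isTRUE(lenient), predictor = predictor),
            class = "scan_config")
}

#' Classify ER localization from retention motifs
#'
#' The motif-based location rule: a C-terminal di-lysine signal (or proven
#' variant) or at least two di-arginine motifs predict ER residence; exactly
#' one di-arginine is inconclusive; none predicts residence outside the ER.
#'
#' @param cterm_present Logical, any C-terminal retrieval signal.
#' @param n_diarg Non-negative di-arginine motif count.
#' @return `"ER"`, `"unsure"` or `"not_ER"`.
#' @examples
#' classify_er_localization(FALSE, 2)  # "ER"
#' classify_er_localization(FALSE, 1)  # "unsure"
#' @export
classify_er_localization <- function(cterm_present, n_diarg) {
  stopifnot(is.logical(cterm_present), length(cterm_present) == 1L,
            is.numeric(n_diarg), length(n_diarg) == 1L)
  if (is.na(n_diarg) || n_diarg < 0) stop("n_diarg must be a non-negative count")
  if (isTRUE(cterm_present)) return("ER")
  if (n_diarg >= 2) "ER" else if (n_diarg == 1) "unsure" else "not_ER"
}

#' Build the retention profile of one protein
#'
#' Runs every scanner.  The total di-arginine count always uses the whole
#' sequence (the high-throughput convention, which also counts luminal
#' motifs); the cytoplasmic count is computed only when a topology is given,
#' keeping hits that lie entirely within cytoplasmic loops.  The
#' localization call uses the cytoplasmic count when available, the total
#' otherwise.
#'
#' @param rec A one-row `protein_set`, or a sequence string (optionally
#'   named with its id).
#' @param top Optional `topology` for the sequence; overrides prediction.
#' @param config A [scan_config()].
#' @return A `retention_profile` object.
#' @export
build_profile <- function(rec, top = NULL, config = scan_config()) {
  if (is.character(rec)) {
    id <- if (!is.null(names(rec))) names(rec)[1L] else "seq1"
    seq <- unname(rec[1L])
  } else {
    stopifnot(is.data.frame(rec), nrow(rec) == 1L)
    id <- rec$id
    seq <- rec$sequence
  }
  if (!is.null(top)) {
    stopifnot(inherits(top, "topology"))
    if (top$length != nchar(seq)) {
      stop(sprintf("topology length %d does not match sequence length %d for '%s'",
                   top$length, nchar(seq), id))
    }
  }

  diarg <- scan_diarginine(seq, mode = config$diarg_mode)
  cterm <- scan_cterminal(seq)
  loops <- if (!is.null(top)) topology_loops(top) else NULL

  if (!is.null(loops)) {
    diarg <- assign_loops(diarg, loops)
    n_cyto <- sum(diarg$side == "cytoplasmic", na.rm = TRUE)
  } else {
    n_cyto <- NULL
  }

  if (!is.null(loops) && config$luminal_restrict) {
    c1 <- scan_in_loops(seq, loops, scan_c1, side = "luminal")
    kxn <- scan_in_loops(seq, loops, scan_kxn, side = "luminal",
                         phi = config$phi)
  } else {
    c1 <- scan_c1(seq)
    kxn <- scan_kxn(seq, phi = config$phi)
  }

  cys34 <- NA
  if (!is.null(loops)) {
    l34 <- loops[loops$label == "3/4" & loops$side == "luminal" &
                   loops$length > 0L, , drop = FALSE]
    if (nrow(l34) == 1L) {
      cys <- scan_cys_pair(substring(seq, l34$start, l34$end))
      cys34 <- nrow(cys) > 0L
      if (nrow(cys)) {
        cys$start <- cys$start + l34$start - 1L
        cys$end <- cys$end + l34$start - 1L
        cys$loop_label <- "3/4"
        cys$side <- "luminal"
      }
    } else cys <- scan_cys_pair("")
  } else cys <- scan_cys_pair("")

  triad <- find_triad(seq, top = top, middle_class = config$middle_class,
                      third_class = config$third_class,
                      lenient = config$lenient)

  n_for_call <- if (!is.null(n_cyto)) n_cyto else nrow(diarg)
  loc <- classify_er_localization(nrow(cterm) > 0L, n_for_call)

  if (!is.null(loops)) {
    cterm <- assign_loops(cterm, loops)
    c1 <- if (!"loop_label" %in% names(c1)) assign_loops(c1, loops) else c1
    kxn <- if (!"loop_label" %in% names(kxn)) assign_loops(kxn, loops) else kxn
  }
  hits <- rbind_hits(list(diarg, cterm, c1, kxn, cys))

  structure(list(
    id = id,
    n_diarg_total = nrow(diarg),
    n_diarg_cyto = n_cyto,
    cterm_motif = if (nrow(cterm)) cterm$class[1L] else NA_character_,
    kxn_present = nrow(kxn) > 0L,
    kxn_has_K = nrow(kxn) > 0L && any(kxn$has_K),
    cys_pair_34 = cys34,
    triad = triad,
    localization = loc,
    mode = if (is.null(top)) "all" else "cytoplasmic",
    hits = hits
  ), class = "retention_profile")
}

# rbind hit frames with unequal detail columns, filling with NA.
rbind_hits <- function(frames) {
  frames <- Filter(function(f) !is.null(f), frames)
  cols <- unique(unlist(lapply(frames, names)))
  frames <- lapply(frames, function(f) {
    for (nm in setdiff(cols, names(f))) f[[nm]] <- rep(NA, nrow(f))
    f[, cols, drop = FALSE]
  })
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  out
}

#' @export
print.retention_profile <- function(x, ...) {
  cyto <- if (is.null(x$n_diarg_cyto)) "not computed (no topology)"
          else x$n_diarg_cyto
  cat(sprintf("Retention profile for '%s'\n", x$id))
  cat(sprintf("  di-arginine motifs: %d total, cytoplasmic: %s\n",
              x$n_diarg_total, cyto))
  cat(sprintf("  C-terminal signal: %s\n",
              if (is.na(x$cterm_motif)) "none" else x$cterm_motif))
  cat(sprintf("  KxN motif: %s; loop 3/4 cysteine pair: %s\n",
              if (x$kxn_present) sprintf("yes (K at first position: %s)", x$kxn_has_K)
              else "no", x$cys_pair_34))
  cat(sprintf("  triad: %s; predicted localization: %s\n",
              x$triad$classification, x$localization))
  invisible(x)
}

#' Profile every protein in a set
#'
#' @param proteins A `protein_set`.
#' @param topologies Optional named vector of state strings (or named list
#'   of `topology` objects) keyed by protein id.
#' @param predict If `TRUE`, predict a topology for proteins without a
#'   supplied one.  A supplied topology always overrides prediction.
#' @param config A [scan_config()].
#' @return Named list of `retention_profile` objects, in input order.
#' @export
profile_proteins <- function(proteins, topologies = NULL, predict = FALSE,
                             config = scan_config()) {
  stopifnot(is.data.frame(proteins))
  out <- vector("list", nrow(proteins))
  names(out) <- proteins$id
  for (k in seq_len(nrow(proteins))) {
    id <- proteins$id[k]
    top <- NULL
    if (!is.null(topologies) && id %in% names(topologies)) {
      t <- topologies[[id]]
      top <- if (inherits(t, "topology")) t else topology_from_states(t)
    } else if (isTRUE(predict)) {
      top <- predict_topology(proteins$sequence[k], params = config$predictor)
    }
    out[[k]] <- build_profile(proteins[k, , drop = FALSE], top = top,
                              config = config)
  }
  out
}

#' Aggregate retention profiles into family statistics
#'
#' @param profiles Non-empty list of `retention_profile` objects.
#' @param count_field Which di-arginine count to aggregate: `"total"`
#'   (whole-sequence, the high-throughput family convention) or `"cyto"`
#'   (cytoplasmic loops only; requires topology-mode profiles).
#' @param label Family label.
#' @return A `family_stats` object: `label`, `n`, `mean_diarg`, `sd_diarg`,
#'   `n_cterm`, `n_kxn`, `count_field`.
#' @export
aggregate_family <- function(profiles, count_field = c("total", "cyto"),
                             label = "family") {
  count_field <- match.arg(count_field)
  if (!length(profiles)) stop("cannot aggregate an empty profile list")
  counts <- if (count_field == "total") {
    vapply(profiles, function(p) as.numeric(p$n_diarg_total), numeric(1))
  } else {
    missing <- vapply(profiles, function(p) is.null(p$n_diarg_cyto), logical(1))
    if (any(missing)) {
      ids <- vapply(profiles[missing], function(p) p$id, character(1))
      stop("cytoplasmic counts missing (no topology) for: ",
           paste(ids, collapse = ", "))
    }
    vapply(profiles, function(p) as.numeric(p$n_diarg_cyto), numeric(1))
  }
  n <- length(profiles)
  structure(list(
    label = label,
    n = n,
    mean_diarg = mean(counts),
    sd_diarg = if (n > 1L) stats::sd(counts) else 0,
    n_cterm = sum(vapply(profiles, function(p) !is.na(p$cterm_motif), logical(1))),
    n_kxn = sum(vapply(profiles, function(p) isTRUE(p$kxn_present), logical(1))),
    count_field = count_field
  ), class = "family_stats")
}

#' @export
print.family_stats <- function(x, ...) {
  cat(sprintf(
    "Family '%s': n=%d, mean di-arginine=%.2f (sd %.2f, %s count), C-terminal signal %d/%d, KxN %d/%d\n",
    x$label, x$n, x$mean_diarg, x$sd_diarg, x$count_field,
    x$n_cterm, x$n, x$n_kxn, x$n))
  invisible(x)
}

#' Tabulate family statistics
#'
#' @param stats_list List of `family_stats`.
#' @return Data frame with one row per family (label, n, mean/sd
#'   di-arginine, counts and fractions with a C-terminal signal and KxN).
#' @export
family_table <- function(stats_list) {
  do.call(rbind, lapply(stats_list, function(s) {
    data.frame(label = s$label, n = s$n, mean_diarg = s$mean_diarg,
               sd_diarg = s$sd_diarg, n_cterm = s$n_cterm,
               frac_cterm = s$n_cterm / s$n, n_kxn = s$n_kxn,
               count_field = s$count_field, stringsAsFactors = FALSE)
  }))
}

#' Compare the ER-retention propensity of two families
#'
#' A family is called "more ER-like" when it has both the higher mean
#' di-arginine count and at least as high a fraction of members with a
#' C-terminal retrieval signal; anything else is `"mixed"`.
#'
#' @param a,b `family_stats` computed with the same `count_field`.
#' @return List with `mean_diff` (a - b), the two C-terminal fractions and
#'   their ratio, and `verdict` (`"A"`, `"B"` or `"mixed"`).
#' @export
compare_groups <- function(a, b) {
  stopifnot(inherits(a, "family_stats"), inherits(b, "family_stats"))
  if (a$count_field != b$count_field) {
    stop("family statistics computed with different count fields: ",
         a$count_field, " vs ", b$count_field)
  }
  fa <- a$n_cterm / a$n
  fb <- b$n_cterm / b$n
  verdict <- if (a$mean_diarg > b$mean_diarg && fa >= fb) "A"
             else if (b$mean_diarg > a$mean_diarg && fb >= fa) "B"
             else "mixed"
  list(label_a = a$label, label_b = b$label,
       mean_diff = a$mean_diarg - b$mean_diarg,
       frac_cterm_a = fa, frac_cterm_b = fb,
       frac_cterm_ratio = if (fb == 0) ifelse(fa == 0, NA_real_, Inf) else fa / fb,
       verdict = verdict)
}
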