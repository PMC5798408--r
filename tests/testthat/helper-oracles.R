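# Independent reference implementations used to cross-check the scanners.
# These deliberately work character-by-character on the string, not through
# the package's own position machinery.

# Every arginine pair at distance <= 3, by direct quadratic enumeration.
oracle_diarg_all_pairs <- function(s) {
  n <- nchar(s)
  count <- 0L
  for (i in seq_len(n)) {
    if (substr(s, i, i) != "R") next
    for (j in seq_len(n)) {
      if (j > i && j - i <= 3L && substr(s, j, j) == "R") count <- count + 1L
    }
  }
  count
}

# Greedy non-overlapping pairing, simulated directly on the string with a
# consumed mask: repeatedly take the leftmost unconsumed R that has an
# unconsumed partner within 3 downstream, pair it with the nearest one.
oracle_diarg_greedy <- function(s) {
  n <- nchar(s)
  consumed <- rep(FALSE, n)
  count <- 0L
  repeat {
    found <- FALSE
    for (i in seq_len(n)) {
      if (consumed[i] || substr(s, i, i) != "R") next
      js <- if (i < n) (i + 1L):min(n, i + 3L) else integer(0)
      for (j in js) {
        if (!consumed[j] && substr(s, j, j) == "R") {
          consumed[i] <- consumed[j] <- TRUE
          count <- count + 1L
          found <- TRUE
          break
        }
      }
      if (found) break
      consumed[i] <- TRUE  # no partner ever: this R can never pair later
    }
    if (!found) break
  }
  count
}

# C-terminal retrieval signal by regex on the sequence tail, in the same
# priority order the package documents.
CTERM_ORACLE_REGEX <- c(
  KKxx = "KK..$", KxKxx = "K.K..$", RKxx = "RK..$", RxKxx = "R.K..$",
  KxRxx = "K.R..$", HxHxx = "H.H..$", KxHxx = "K.H..$"
)
oracle_cterm <- function(s) {
  for (cls in names(CTERM_ORACLE_REGEX)) {
    if (grepl(CTERM_ORACLE_REGEX[[cls]], s)) return(cls)
  }
  NA_character_
}

# Extended C3 context, scored by explicit position-by-position comparison.
oracle_context <- function(s, h2) {
  cons <- strsplit("TAOYFHTOOEKOOG", "")[[1]]
  phi <- c("F", "I", "L", "V")
  score <- 0L
  for (j in seq_along(cons)) {
    p <- h2 - 6L + j
    if (p < 1L || p > nchar(s)) next
    r <- substr(s, p, p)
    if (cons[j] == "O") {
      if (r %in% phi) score <- score + 1L
    } else if (r == cons[j]) score <- score + 1L
  }
  score
}

random_seq <- function(n, alphabet = c("A", "R", "K", "H", "N", "L", "S",
                                       "T", "G", "E", "D", "F", "V", "I",
                                       "P", "W", "Y", "C", "Q", "M")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All strings over an alphabet up to a maximum length.
all_strings <- function(alphabet, max_len) {
  out <- character(0)
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(as.matrix(grid), 1L, paste, collapse = ""))
  }
  out
}

# A FITM-like synthetic spec with one planted motif per scanner class.
demo_spec <- function(seed = 1L) {
  synthetic_spec(seed = seed, planted_motifs = list(
    list(class = "RR", loop = "N-term", offset = 3),
    list(class = "RxxR", loop = "2/3", offset = 5),
    list(class = "KxN", loop = "1/2", offset = 4),
    list(class = "CYS_PAIR", loop = "3/4", offset = 8),
    list(class = "C2", loop = "3/4", offset = 50),
    list(class = "C3", loop = "5/6", offset = 6),
    list(class = "KKxx", loop = "C-term", offset = NA)
  ))
}
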