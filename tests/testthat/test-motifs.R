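test_that("di-arginine scanning follows the pairing conventions", {
  h <- scan_diarginine("MRRA")
  expect_equal(nrow(h), 1L)
  expect_equal(h$class, "RR")
  expect_equal(c(h$start, h$end), c(2L, 3L))

  # RRRR: brute force gives 3 RR + 2 RxR + 1 RxxR pairs; greedy consumes
  # each arginine once
  ap <- scan_diarginine("RRRR", mode = "all_pairs")
  expect_equal(nrow(ap), 6L)
  expect_equal(sort(table(ap$class), decreasing = TRUE),
               sort(c(RR = 3L, RxR = 2L, RxxR = 1L), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(nrow(ap), oracle_diarg_all_pairs("RRRR"))
  gr <- scan_diarginine("RRRR", mode = "greedy")
  expect_equal(nrow(gr), 2L)
  expect_equal(nrow(gr), oracle_diarg_greedy("RRRR"))

  expect_equal(nrow(scan_diarginine("")), 0L)
  expect_equal(nrow(scan_diarginine("KAKA")), 0L)
  # the wildcard may itself be R, and X never counts as R
  expect_equal(scan_diarginine("RXR")$class, "RxR")
  expect_equal(nrow(scan_diarginine("XX")), 0L)
})

test_that("di-arginine scanners agree with brute-force oracles on random 30-mers", {
  set.seed(42)
  for (k in 1:300) {
    s <- random_seq(30, alphabet = c("R", "A", "K", "L"))
    expect_equal(nrow(scan_diarginine(s, "all_pairs")),
                 oracle_diarg_all_pairs(s), info = s)
    g <- scan_diarginine(s, "greedy")
    expect_equal(nrow(g), oracle_diarg_greedy(s), info = s)
    # each arginine participates in at most one greedy hit
    if (nrow(g)) {
      used <- c(g$start, g$end)
      expect_equal(anyDuplicated(used), 0L, info = s)
    }
    expect_lte(nrow(g), nrow(scan_diarginine(s, "all_pairs")))
  }
})

test_that("C-terminal retrieval signals follow the documented priority", {
  expect_equal(scan_cterminal("MAWKKAA")$class, "KKxx")
  expect_equal(scan_cterminal("MAWRKAA")$class, "RKxx")
  expect_equal(scan_cterminal("MAKWKAA")$class, "KxKxx")
  expect_equal(scan_cterminal("MARWKAA")$class, "RxKxx")
  expect_equal(scan_cterminal("MAKWRAA")$class, "KxRxx")
  expect_equal(scan_cterminal("MAHWHAA")$class, "HxHxx")
  expect_equal(scan_cterminal("MAKWHAA")$class, "KxHxx")
  expect_equal(nrow(scan_cterminal("MAWAKKA")), 0L)  # K not at -4/-3 or -5/-3
  # canonical KKxx outranks the 5-residue patterns when both would match
  expect_equal(scan_cterminal("MKKKAA")$class, "KKxx")
  # short sequences only test the patterns that fit
  expect_equal(scan_cterminal("KKAA")$class, "KKxx")
  expect_equal(nrow(scan_cterminal("KAA")), 0L)
  # spans point at the real C-terminus
  h <- scan_cterminal("MAWKKAA")
  expect_equal(c(h$start, h$end), c(4L, 7L))
  expect_equal(h$matched, "KKAA")
})

test_that("only the last five residues matter to the C-terminal scanner", {
  set.seed(11)
  for (k in 1:100) {
    s <- random_seq(8, alphabet = c("K", "R", "H", "A", "X"))
    a <- scan_cterminal(s)
    b <- scan_cterminal(paste0(random_seq(12), s))
    expect_equal(
      if (nrow(a)) a$class else NA_character_,
      if (nrow(b)) b$class else NA_character_, info = s)
  }
})

test_that("catalytic-site scanners match their fixed patterns", {
  expect_equal(nrow(scan_c1("KAAAAAARP")), 1L)
  expect_equal(scan_c1("KAAAAAARP")$matched, "KAAAAAARP")
  expect_equal(nrow(scan_c1("KAAAAAARA")), 0L)

  h <- scan_c2("ASGHA")
  expect_equal(nrow(h), 1L)
  expect_equal(h$h_pos, 4L)        # histidine of SGH = candidate H-1
  expect_equal(h$c2_middle, "G")
  expect_equal(scan_c2("ASSHA")$c2_middle, "S")   # FITM1-style middle
  expect_equal(nrow(scan_c2("ASGAA")), 0L)        # H required
  expect_equal(nrow(scan_c2("AGGHA")), 0L)        # first must be S/T

  h <- scan_c3("HAAAE")
  expect_equal(h$third_res, "E")
  expect_equal(c(h$h_pos, h$third_pos), c(1L, 5L))
  expect_equal(scan_c3("HAAAD")$third_res, "D")
  expect_equal(scan_c3("HAAAQ")$third_res, "Q")
  expect_equal(nrow(scan_c3("HAAAG")), 0L)

  expect_true(scan_kxn("KANLVN")$has_K)
  expect_false(scan_kxn("AANLVN")$has_K)
  expect_equal(nrow(scan_kxn("KANLAN")), 0L)   # A is not hydrophobic enough
  # ambiguity codes never satisfy a class position
  expect_equal(nrow(scan_kxn("KANXVN")), 0L)
  expect_equal(nrow(scan_c2("SXHA")), 0L)
  expect_equal(nrow(scan_c3("HAAAX")), 0L)
})

test_that("cysteine pairs span the first and last cysteine", {
  h <- scan_cys_pair("ACDDCA")
  expect_equal(c(h$start, h$end), c(2L, 5L))
  expect_equal(h$n_cys, 2L)
  expect_equal(nrow(scan_cys_pair("ACDDDA")), 0L)
  h3 <- scan_cys_pair("CACAC")
  expect_equal(c(h3$start, h3$end), c(1L, 5L))
  expect_equal(h3$n_cys, 3L)
})

test_that("every scanner's matched string equals the sequence at its span", {
  set.seed(9)
  for (k in 1:50) {
    s <- random_seq(40)
    for (h in list(scan_diarginine(s, "all_pairs"), scan_cterminal(s),
                   scan_c1(s), scan_c2(s), scan_c3(s), scan_kxn(s),
                   scan_cys_pair(s))) {
      if (nrow(h)) {
        expect_equal(h$matched, substring(s, h$start, h$end), info = s)
      }
    }
  }
})

test_that("hits are assigned to containing loops; straddlers are dropped", {
  # topology: 5i 21M 5o 21M 5i ; motifs planted by hand
  st <- paste0("iiiii", strrep("M", 21), "ooooo", strrep("M", 21), "iiiii")
  top <- topology_from_states(st)
  loops <- topology_loops(top)
  seq_ch <- strsplit(strrep("A", nchar(st)), "")[[1]]
  seq_ch[c(2, 3)] <- "R"            # inside cytoplasmic N-term
  seq_ch[c(28, 29)] <- "R"          # inside luminal loop 1/2
  seq_ch[c(26, 27)] <- c("A", "R")  # boundary pair: 25 is M, 27 is o
  seq_ch[25] <- "R"                 # R at TMD end pairs with R at 27
  s <- paste(seq_ch, collapse = "")
  hits <- assign_loops(scan_diarginine(s, "all_pairs"), loops)
  inside_nterm <- hits[hits$start == 2, ]
  expect_equal(inside_nterm$side, "cytoplasmic")
  expect_equal(inside_nterm$loop_label, "N-term")
  expect_equal(hits$side[hits$start == 28], "luminal")
  straddler <- hits[hits$start == 25, ]
  expect_true(all(is.na(straddler$side)))
  expect_true(all(is.na(straddler$loop_label)))
  # side-filtered counts exclude the straddler
  expect_equal(sum(hits$side == "cytoplasmic", na.rm = TRUE), 1L)
})
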