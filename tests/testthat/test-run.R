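# End-to-end orchestration (the command-line surface is a thin wrapper over
# run_scan / run_family / run_synth; see inst/cli/fitmscan).

test_that("run_scan writes reports matching the planted ground truth", {
  dir <- withr::local_tempdir()
  sp <- demo_spec(seed = 17L)
  paths <- run_synth(sp, file.path(dir, "demo"))
  out <- file.path(dir, "report")
  tab <- run_scan(file.path(dir, "demo.fasta"),
                  topology = file.path(dir, "demo.topo"),
                  mode = "cytoplasmic", out_prefix = out, quiet = TRUE)
  expect_true(file.exists(paste0(out, ".tsv")))
  expect_true(file.exists(paste0(out, ".json")))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_diarg_total, 2L)     # planted RR + RxxR
  expect_equal(tab$n_diarg_cyto, 2L)
  expect_equal(tab$cterm_motif, "KKxx")
  expect_true(tab$kxn_present)
  expect_true(tab$cys_pair_34)
  expect_equal(tab$triad_class, "FITM_typical")
  expect_equal(tab$localization, "ER")

  # without topology the cytoplasmic column stays empty
  tab2 <- run_scan(file.path(dir, "demo.fasta"), mode = "all", quiet = TRUE)
  expect_true(is.na(tab2$n_diarg_cyto))

  expect_error(run_scan(file.path(dir, "demo.fasta"), mode = "cytoplasmic",
                        quiet = TRUE), "topology")
  bad <- file.path(dir, "bad.fa")
  writeLines(c(">x", "MR1A"), bad)
  expect_error(run_scan(bad, quiet = TRUE), "illegal character")
})

test_that("run_family summarises groups and compares them", {
  dir <- withr::local_tempdir()
  high <- synthetic_spec(seed = 51L, planted_motifs = list(
    list(class = "RR", loop = "N-term", offset = 3),
    list(class = "RxR", loop = "2/3", offset = 2),
    list(class = "RR", loop = "4/5", offset = 2),
    list(class = "RxxR", loop = "C-term", offset = 10),
    list(class = "KKxx", loop = "C-term", offset = NA)))
  low <- synthetic_spec(seed = 52L)
  fam_a <- generate_family(6, high, divergence = 0.03, seed = 53L,
                           id_prefix = "a")
  fam_b <- generate_family(8, low, divergence = 0.03, seed = 54L,
                           id_prefix = "b")
  all <- c(fam_a, fam_b)
  recs <- do.call(rbind, lapply(all, `[[`, "record"))
  write_fasta(recs, file.path(dir, "fam.fasta"))
  writeLines(paste(recs$id, rep(c("groupA", "groupB"), c(6, 8)), sep = "\t"),
             file.path(dir, "groups.tsv"))

  res <- run_family(file.path(dir, "fam.fasta"), file.path(dir, "groups.tsv"),
                    compare = c("groupA", "groupB"),
                    out = file.path(dir, "families.tsv"))
  expect_equal(nrow(res$families), 2L)
  expect_equal(sort(res$families$label), c("groupA", "groupB"))
  a <- res$families[res$families$label == "groupA", ]
  expect_equal(a$n, 6L)
  expect_equal(a$mean_diarg, 4)
  expect_equal(a$n_cterm, 6L)
  expect_equal(res$comparison$verdict, "A")
  expect_true(file.exists(file.path(dir, "families.tsv")))

  # single-member group: sd is 0
  writeLines(c(paste0("a1\tsolo"),
               paste(recs$id[-1], "rest", sep = "\t")),
             file.path(dir, "groups2.tsv"))
  res2 <- run_family(file.path(dir, "fam.fasta"),
                     file.path(dir, "groups2.tsv"))
  expect_equal(res2$families$sd_diarg[res2$families$label == "solo"], 0)

  # an id in the group table but absent from the FASTA is an error
  writeLines("nosuch\tgroupA", file.path(dir, "groups3.tsv"))
  expect_error(run_family(file.path(dir, "fam.fasta"),
                          file.path(dir, "groups3.tsv")), "nosuch")
})

test_that("run_synth round-trips YAML specs deterministically", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "spec.yaml")
  writeLines(c(
    "n_tmds: 6",
    "seed: 77",
    "planted_motifs:",
    "  - {class: RR, loop: '2/3', offset: 4}",
    "  - {class: KKxx, loop: C-term, offset: .na}"
  ), yml)
  p1 <- run_synth(yml, file.path(dir, "s1"))
  p2 <- run_synth(yml, file.path(dir, "s2"))
  expect_true(all(file.exists(p1)))
  expect_identical(readLines(p1[1]), readLines(p2[1]))  # byte-identical FASTA

  ps <- read_fasta(p1[1])
  expect_equal(nrow(ps), 1L)   # no n_members key: one protein, not a family
  st <- read_topology(p1[2], ps)
  truth <- jsonlite::fromJSON(p1[3])[[1]]
  prof <- build_profile(ps[1, ], topology_from_states(st[[1]]))
  expect_equal(prof$n_diarg_total, 1L)
  expect_equal(prof$cterm_motif, "KKxx")
  expect_equal(truth$start[truth$class == "RR"],
               prof$hits$start[prof$hits$class == "RR"])

  # with n and divergence the spec emits a diverged family
  writeLines(c(
    "n_tmds: 6", "seed: 78", "n_members: 4", "divergence: 0.05",
    "planted_motifs:",
    "  - {class: RR, loop: '2/3', offset: 4}"
  ), yml)
  pf <- run_synth(yml, file.path(dir, "f1"))
  fam <- read_fasta(pf[1])
  expect_equal(nrow(fam), 4L)
  expect_equal(vapply(fam$sequence, function(s)
    nrow(scan_diarginine(s)), integer(1), USE.NAMES = FALSE), rep(1L, 4))

  writeLines(c("n_tmds: 3", "loop_lens: [5, 5]"), yml)
  expect_error(run_synth(yml, file.path(dir, "s3")), "loop lengths")
})

test_that("YAML run configuration maps onto scan options", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c(
    "mode: cytoplasmic",
    "diarg_mode: all_pairs",
    "middle_class: [G, S]",
    "lenient: true",
    "predictor:",
    "  window: 21",
    "  threshold: 1.5"
  ), yml)
  rc <- read_run_config(yml)
  expect_equal(rc$mode, "cytoplasmic")
  expect_equal(rc$config$diarg_mode, "all_pairs")
  expect_equal(rc$config$middle_class, c("G", "S"))
  expect_true(rc$config$lenient)
  expect_equal(rc$config$predictor$window, 21L)
  expect_equal(rc$config$predictor$threshold, 1.5)
  expect_equal(rc$config$predictor$merge_gap, 3L)   # untouched default

  writeLines("bogus_key: 1", yml)
  expect_error(read_run_config(yml), "unknown config keys")
})
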