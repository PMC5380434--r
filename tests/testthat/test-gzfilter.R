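# biased residue pool so zippers, leaders and polar spans actually occur
GZ_POOL <- c(rep("G", 6), rep(c("A", "V", "I", "L", "S", "T"), 2),
             "D", "E", "K", "R", "P", "C", "N", "Q", "H", "Y", "F", "M", "W")

test_that("detect_leader matches the regex oracle on random proteins", {
  set.seed(41)
  for (i in 1:2000) {
    p <- random_protein(sample(36:80, 1), pool = GZ_POOL)
    got <- detect_leader(p)
    want <- oracle_leader(p)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$cleavage_index, want)
      expect_equal(substr(got$dipeptide, 1, 1), "G")
    }
  }
})

test_that("detect_leader forced examples and bounds", {
  p <- paste0(strrep("L", 9), "GA", strrep("V", 30))   # cleavage at 11
  expect_equal(detect_leader(p)$cleavage_index, 11)
  # dipeptide ending before min_leader is ignored
  p2 <- paste0(strrep("L", 4), "GG", strrep("V", 40))
  expect_null(detect_leader(p2))
  # the earliest in-window cleavage wins
  p3 <- paste0(strrep("L", 10), "GS", strrep("L", 5), "GG", strrep("V", 30))
  expect_equal(detect_leader(p3)$cleavage_index, 12)
  expect_equal(detect_leader(p3)$dipeptide, "GS")
  expect_error(detect_leader("SHORT"), "max_leader")
})

test_that("find_zippers matches the maximal-run oracle on random proteins", {
  set.seed(42)
  for (i in 1:2000) {
    m <- random_protein(sample(10:80, 1), pool = GZ_POOL)
    got <- find_zippers(m)
    want <- oracle_zippers(m)
    expect_equal(nrow(got), nrow(want), info = m)
    if (nrow(got)) {
      expect_equal(got$first, want$first, info = m)
      expect_equal(got$last, want$last, info = m)
      expect_equal(got$n_anchors, want$n_anchors, info = m)
    }
  }
})

test_that("find_zippers forced examples", {
  # clean GxxxGxxxG
  z <- find_zippers("AAGAVIGAVIGAA")
  expect_equal(nrow(z), 1)
  expect_equal(z$first, 2L)
  expect_equal(z$last, 10L)
  expect_equal(z$n_anchors, 3L)
  # proline interruption splits the run into two sub-threshold halves
  z2 <- find_zippers("GAVIGAPIGAVIG")
  expect_equal(nrow(z2), 0)
  # charged interruption likewise
  z3 <- find_zippers("GAVIGADIGAVIG")
  expect_equal(nrow(z3), 0)
  # two separated motifs
  m <- paste0("GAVIGAVIGA", strrep("P", 3), "GAVIGAVIG")
  expect_equal(nrow(find_zippers(m)), 2)
  # anchors at period 3 or 5 are not motifs
  expect_equal(nrow(find_zippers("GAAGAAGAAG")), 0)
})

test_that("check_cterm matches the oracle on random tails", {
  set.seed(43)
  for (i in 1:2000) {
    m <- random_protein(sample(15:60, 1), pool = GZ_POOL)
    last0 <- sample(0:(nchar(m) - 1), 1)
    motifs <- data.frame(first = 0L, last = last0, n_anchors = 3L)
    expect_equal(check_cterm(m, motifs),
                 oracle_cterm(m, last0), info = paste(m, last0))
  }
})

test_that("check_polar_spans matches the sliding-window oracle", {
  set.seed(44)
  for (i in 1:2000) {
    m <- random_protein(sample(3:60, 1), pool = GZ_POOL)
    ts <- sample(c(list(NULL), as.list(0:nchar(m))), 1)[[1]]
    expect_equal(check_polar_spans(m, tail_start = ts),
                 oracle_polar_span(m, tail_start = ts),
                 info = paste(m, ts))
  }
})

test_that("check_flanks honours windows and termini", {
  cl <- residue_classes()
  m1 <- "AAPGAVIGAVIGAAA"  # P two before the first anchor (within window 3)
  z1 <- find_zippers(m1)
  expect_true(check_flanks(m1, z1[1, ], cl, flank_window = 3, require = "one"))
  # motif at the very start counts as flanked on the N side
  m2 <- "GAVIGAVIGAAAAAA"
  z2 <- find_zippers(m2)
  expect_true(check_flanks(m2, z2[1, ], cl, flank_window = 3, require = "one"))
  # buried motif, no flanker within 3 on either side
  m3 <- "AAAAAGAVIGAVIGAAAAA"
  z3 <- find_zippers(m3)
  expect_false(check_flanks(m3, z3[1, ], cl, flank_window = 3, require = "one"))
  expect_true(check_flanks(m3, z3[1, ], cl, flank_window = 3, require = "none"))
  # "both" needs flankers (or termini) on the two sides
  m4 <- "APGAVIGAVIGAAAAAA"
  z4 <- find_zippers(m4)
  expect_false(check_flanks(m4, z4[1, ], cl, flank_window = 3, require = "both"))
  m5 <- "APGAVIGAVIGDAAAA"
  z5 <- find_zippers(m5)
  expect_true(check_flanks(m5, z5[1, ], cl, flank_window = 3, require = "both"))
})

test_that("classify_toxin accepts a textbook toxin and reports criteria", {
  leader <- paste0("M", strrep("L", 12), "GG")       # cleavage at 15
  zipper <- "AVIGAVIGAVIGAVIG"                        # 4 anchors
  toxin <- paste0(leader, strrep("A", 30), zipper, "DKSTDN")
  toxin <- paste0(toxin, strrep("A", max(0, 60 - nchar(toxin))))
  v <- classify_toxin(paste0(leader, strrep("A", 28), zipper, "DKSTDN"))
  # assemble one that is definitely 60+ residues
  t2 <- paste0(leader, strrep("A", 40), zipper, "DKSTDN")
  v2 <- classify_toxin(t2)
  expect_true(v2$length_ok)
  expect_false(is.null(v2$leader))
  expect_true(v2$zipper_ok)
  expect_true(v2$overall)
})

test_that("single-rule violations flip exactly the intended criterion", {
  mk <- function(zipper, tail = "DKSTDN", pad = 40) {
    paste0("M", strrep("L", 12), "GG", strrep("A", pad), zipper, tail)
  }
  base <- mk("AVIGAVIGAVIGAVIG")
  expect_true(classify_toxin(base)$overall)
  # interrupted zipper
  vi <- classify_toxin(mk("AVIGAVIGAPIGAVIG"))
  expect_false(isTRUE(vi$zipper_ok))
  expect_false(vi$overall)
  # over-long protein
  vl <- classify_toxin(paste0(base, strrep("A", 160 - nchar(base))))
  expect_false(vl$length_ok)
  expect_false(vl$overall)
  # hydrophobic tail
  vt <- classify_toxin(mk("AVIGAVIGAVIGAVIG", tail = strrep("V", 25)))
  expect_false(isTRUE(vt$cterm_ok))
  expect_false(vt$overall)
  # no leader
  noleader <- paste0("M", strrep("L", 14), strrep("A", 40),
                     "AVIGAVIGAVIGAVIG", "DKSTDN")
  vn <- classify_toxin(noleader)
  expect_null(vn$leader)
  expect_false(vn$overall)
})

test_that("polar spans upstream of the tail are filtered out", {
  bad <- paste0("M", strrep("L", 12), "GG", strrep("A", 20),
                "STNQDE",                        # 6-window of charged/polar
                strrep("A", 14), "AVIGAVIGAVIGAVIG", "DKSTDN")
  v <- classify_toxin(bad)
  expect_false(isTRUE(v$polar_span_ok))
  expect_false(v$overall)
})

test_that("short proteins yield NA criteria counted as failures", {
  v <- classify_toxin("MGGAVI")
  expect_false(v$length_ok)
  expect_true(is.na(v$zipper_ok))
  expect_false(v$overall)
})

test_that("verdict_table tabulates one row per protein", {
  ps <- c(good = paste0("M", strrep("L", 12), "GG", strrep("A", 40),
                        "AVIGAVIGAVIGAVIG", "DKSTDN"),
          bad = strrep("A", 70))
  tab <- verdict_table(ps)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$id, c("good", "bad"))
  expect_true(tab$overall[1])
  expect_false(tab$overall[2])
})

test_that("composition_stats computes class fractions and mature-only errors", {
  x <- composition_stats("GAVIGAVIDRST")
  expect_equal(unname(x["small_hydrophobic"]), 8 / 12)
  expect_equal(unname(x["charged"]), 2 / 12)
  expect_equal(unname(x["polar"]), 2 / 12)
  p <- paste0("M", strrep("L", 12), "GG", strrep("V", 40))
  m <- composition_stats(p, mature_only = TRUE)
  expect_equal(unname(m["small_hydrophobic"]), 1)
  expect_error(composition_stats(strrep("L", 50), mature_only = TRUE,
                                 id = "seqX"), "seqX")
})
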