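make_tiny_hmm <- function(L_target, nrow_ = 3) {
  # random small alignment whose match-column count we control loosely
  repeat {
    aln <- random_small_msa(nrow_, L_target + sample(0:2, 1), gap_p = 0.25)
    h <- tryCatch(build_profile(aln), error = function(e) NULL)
    if (!is.null(h) && h$L <= L_target && h$L >= 1) return(h)
  }
}

test_that("msa validates rows and computes the match mask", {
  a <- msa(c("a", "b"), c("AC-G", "A--G"))
  expect_equal(a$match_mask, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(msa(c("a", "b"), c("ACG", "AC")), "differ in length")
  b <- msa(c("a", "b"), c("ac.g", "A--G"))   # dots and case normalised
  expect_equal(b$rows[1], "AC-G")
})

test_that("alignment I/O round trips FASTA and reads Stockholm", {
  a <- msa(c("s1", "s2"), c("ACDEF", "AC-EF"))
  p <- withr::local_tempfile(fileext = ".afa")
  write_alignment(a, p)
  b <- read_alignment(p)
  expect_equal(unname(b$rows), a$rows)
  expect_equal(b$names, a$names)
  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID test", "s1 ACD-F", "s2 ACDEF",
               "", "s1 GG", "s2 GG", "//"), sto)
  st <- read_alignment(sto)
  expect_equal(st$names, c("s1", "s2"))
  expect_equal(st$rows, c("ACD-FGG", "ACDEFGG"))  # blocks concatenated
})

test_that("build_profile emissions and transitions are normalised", {
  set.seed(31)
  for (i in 1:25) {
    aln <- random_small_msa(sample(2:6, 1), sample(3:12, 1))
    h <- build_profile(aln)
    expect_equal(unname(rowSums(h$match_emit)), rep(1, h$L), tolerance = 1e-12)
    expect_equal(sum(h$insert_emit), 1, tolerance = 1e-12)
    expect_equal(h$trans$BM + h$trans$BD, 1, tolerance = 1e-12)
    if (h$L > 1) {
      expect_equal(h$trans$MM + h$trans$MI + h$trans$MD,
                   rep(1, h$L - 1), tolerance = 1e-12)
      expect_equal(h$trans$IM + h$trans$II + h$trans$ID,
                   rep(1, h$L - 1), tolerance = 1e-12)
      expect_equal(h$trans$DM + h$trans$DD + h$trans$DI,
                   rep(1, h$L - 1), tolerance = 1e-12)
      expect_true(all(unlist(h$trans) > 0))  # Laplace smoothing
    }
  }
})

test_that("match emissions equal hand-computed pseudocount mixture", {
  aln <- msa(c("a", "b", "c"), c("AG", "AG", "CG"))
  h <- build_profile(aln, pseudocount_weight = 1)
  bg <- rep(1 / 20, 20)
  a_idx <- match("A", AA20_T); c_idx <- match("C", AA20_T)
  expect_equal(unname(h$match_emit[1, a_idx]), (2 + bg[1]) / 4)
  expect_equal(unname(h$match_emit[1, c_idx]), (1 + bg[2]) / 4)
  expect_equal(unname(h$match_emit[1, match("W", AA20_T)]), bg[1] / 4)
})

test_that("model-build errors are informative", {
  expect_error(build_profile(msa("only", "ACDEF")), ">= 2")
  allgap <- msa(c("a", "b", "c"), c("A--", "-C-", "--D"))
  expect_error(build_profile(allgap), "every column exceeds the gap threshold")
})

test_that("forward and Viterbi equal exhaustive path enumeration (L <= 3, |seq| <= 4)", {
  set.seed(32)
  n_checked <- 0
  while (n_checked < 150) {
    h <- make_tiny_hmm(3)
    prot <- random_protein(sample(1:4, 1))
    oracle <- oracle_hmm_scores(h, prot)
    expect_equal(score_forward(h, prot), oracle$forward, tolerance = 1e-9)
    expect_equal(align_viterbi(h, prot)$bit_score, oracle$viterbi,
                 tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("forward >= Viterbi on random model/sequence pairs", {
  set.seed(33)
  for (i in 1:300) {
    h <- make_tiny_hmm(sample(2:8, 1), nrow_ = sample(2:5, 1))
    prot <- random_protein(sample(2:25, 1))
    f <- score_forward(h, prot)
    v <- align_viterbi(h, prot)$bit_score
    expect_true(is.finite(f) && is.finite(v))
    expect_gte(f, v - 1e-9)
  }
})

test_that("Viterbi path is legal and consistent with its score", {
  set.seed(34)
  for (i in 1:40) {
    h <- make_tiny_hmm(sample(2:6, 1))
    prot <- random_protein(sample(3:20, 1))
    hit <- align_viterbi(h, prot, seq_id = "x")
    expect_equal(nchar(hit$aligned_row), h$L)
    idx <- as.integer(sub("^[MID]", "", hit$path))
    typ <- substr(hit$path, 1, 1)
    # model consumed globally: match/delete column indices hit 1..L in order
    mcols <- idx[typ %in% c("M", "D")]
    expect_equal(mcols, seq_len(h$L))
    # residues in aligned_row appear in sequence order
    aligned <- strsplit(hit$aligned_row, "")[[1]]
    expect_equal(sum(aligned != "-"), sum(typ == "M"))
  }
})

test_that("an exact consensus sequence outscores random sequences", {
  set.seed(35)
  rows <- replicate(4, paste(sample(AA20_T, 30, TRUE), collapse = ""))
  rows <- c(rows[1], rows[1], rows[1], rows[2])  # strong consensus
  h <- build_profile(msa(paste0("r", 1:4), rows))
  s_true <- h$consensus
  s_rand <- random_protein(30)
  expect_gt(score_forward(h, s_true), score_forward(h, s_rand) + 20)
})

test_that("unknown residues score as background (zero log-odds)", {
  h <- build_profile(msa(c("a", "b"), c("AAAA", "AAAA")))
  base <- score_forward(h, "XXXX")
  # an all-X sequence scores exactly the transition-only mass
  hx <- score_forward(h, "XXXXXXX")
  expect_true(is.finite(base) && is.finite(hx))
})

test_that("calibrate_threshold is reproducible and leaves the RNG alone", {
  h <- build_profile(msa(c("a", "b", "c"),
                         c("GAVIGAVIGA", "GAVIGAVIGA", "GAVLGAVLGA")))
  set.seed(99)
  before <- .Random.seed
  t1 <- calibrate_threshold(h, n_random = 100, length_dist = 10:30, seed = 5)
  expect_identical(.Random.seed, before)
  t2 <- calibrate_threshold(h, n_random = 100, length_dist = 10:30, seed = 5)
  expect_identical(t1, t2)
  t3 <- calibrate_threshold(h, n_random = 100, length_dist = 10:30, seed = 6)
  expect_false(identical(t1, t3))
  # alpha = 1 returns the minimum score of the null sample
  tmin <- calibrate_threshold(h, n_random = 100, length_dist = 10:30,
                              seed = 5, alpha = 1)
  expect_lte(tmin, t1)
  expect_error(calibrate_threshold(h, n_random = 50), "100")
})

test_that("msa_append grows the alignment in match-column space", {
  a <- msa(c("s1", "s2", "s3"), c("AC-DE", "AC-DE", "ACFDE"))
  expect_equal(sum(a$match_mask), 4)   # column 3 is majority-gap -> insert
  b <- msa_append(a, "hit1", "GGGG")
  expect_equal(length(b$rows), 4)
  expect_equal(nchar(b$rows[4]), 4)
  expect_error(msa_append(a, "bad", "GG"), "nchar")
})

test_that("Viterbi-aligned hits can rebuild a model (growing alignment)", {
  rows <- c("MAGAVIGAGL", "MAGAVIGAGL", "MAGALIGAGV")
  a <- msa(paste0("s", 1:3), rows)
  h <- build_profile(a)
  hit <- align_viterbi(h, "MAGAVIGAGL", "new")
  a2 <- msa_append(a, "new", hit$aligned_row)
  h2 <- build_profile(a2)
  expect_equal(h2$L, h$L)
  expect_gt(score_forward(h2, "MAGAVIGAGL"), 0)
})

test_that("HMMER3 export writes a structurally valid profile", {
  h <- build_profile(msa(c("a", "b"), c("ACDEF", "ACDEF")))
  p <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(h, p, name = "demo")
  lines <- readLines(p)
  expect_true(startsWith(lines[1], "HMMER3/f"))
  expect_true(any(grepl("^LENG  5$", lines)))
  expect_equal(tail(lines, 1), "//")
  # 3 lines per node (match emit, insert emit, transitions)
  node_lines <- grep("^\\s*[0-9]+ ", lines)
  expect_equal(length(node_lines), h$L)
})
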