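test_that("freshly drawn toxins always pass the classifier", {
  set.seed(71)
  params <- synth_params()
  for (i in 1:1000) {
    tox <- make_toxin_protein(params)
    v <- classify_toxin(tox$protein)
    expect_true(v$overall, info = tox$protein)
    expect_true(nchar(tox$protein) >= 60 && nchar(tox$protein) <= 151)
  }
})

test_that("family-derived toxins pass and resemble the family", {
  set.seed(72)
  params <- synth_params()
  fam <- cdzminer:::new_toxin_struct(params)
  for (i in 1:200) {
    tox <- make_toxin_protein(params, family = fam)
    expect_true(classify_toxin(tox$protein)$overall)
  }
})

test_that("drawn toxins have small-hydrophobic-rich mature regions", {
  set.seed(73)
  params <- synth_params()
  fr <- replicate(200, {
    tox <- make_toxin_protein(params)
    composition_stats(tox$protein, mature_only = TRUE)["small_hydrophobic"]
  })
  expect_true(all(fr >= 0.6))
})

test_that("each decoy class violates exactly the intended criterion", {
  set.seed(74)
  params <- synth_params()
  for (i in 1:200) {
    vi <- classify_toxin(make_decoy("decoy_interrupted", params)$protein)
    expect_false(isTRUE(vi$zipper_ok))
    vl <- classify_toxin(make_decoy("decoy_bad_length", params)$protein)
    expect_false(vl$length_ok)
    vn <- classify_toxin(make_decoy("decoy_no_leader", params)$protein)
    expect_null(vn$leader)
    vt <- classify_toxin(make_decoy("decoy_no_tail", params)$protein)
    expect_false(isTRUE(vt$cterm_ok))
    # the positional decoy is a bona fide toxin by sequence
    va <- classify_toxin(make_decoy("decoy_no_anchor", params)$protein)
    expect_true(va$overall)
  }
  expect_error(make_decoy("decoy_nonsense", params), "unknown decoy class")
})

test_that("reverse translation round trips and avoids internal start codons", {
  set.seed(75)
  params <- synth_params()
  for (i in 1:200) {
    prot <- make_toxin_protein(params)$protein
    dna <- reverse_translate(prot)
    expect_equal(nchar(dna), 3 * (nchar(prot) + 1))
    expect_equal(sub("\\*$", "", translate_dna(dna)), prot)
    codons <- substring(dna, seq(1, nchar(dna) - 2, 3),
                        seq(3, nchar(dna), 3))
    expect_false(any(codons[-1] %in% c("ATG", "GTG", "TTG")))
    expect_true(codons[1] == "ATG")
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
  }
  expect_error(reverse_translate("AML"), "M")
})

test_that("stop salting bounds stop-free gaps in all six frames", {
  set.seed(76)
  s <- cdzminer:::salt_stops(
    paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE,
                 prob = c(0.1, 0.4, 0.4, 0.1)), collapse = ""), max_gap = 150)
  max_orf_gap <- function(s) {
    worst <- 0L
    for (strand in 1:2) {
      x <- if (strand == 1) s else revcomp(s)
      for (f in 0:2) {
        pos <- seq(f + 1, nchar(x) - 2, by = 3)
        cods <- substring(x, pos, pos + 2)
        st <- c(0L, which(cods %in% c("TAA", "TAG", "TGA")),
                length(cods) + 1L)
        worst <- max(worst, max(diff(st)) * 3L)
      }
    }
    worst
  }
  expect_lte(max_orf_gap(s), 153)  # one codon of slack at segment edges
})

test_that("generation is deterministic and leaves the session RNG untouched", {
  set.seed(77)
  before <- .Random.seed
  a <- generate_synthetic(synth_params(seed = 5, n_genomes = 1))
  expect_identical(.Random.seed, before)
  b <- generate_synthetic(synth_params(seed = 5, n_genomes = 1))
  expect_identical(a$truth, b$truth)
  expect_identical(a$genomes[[1]]$sequence, b$genomes[[1]]$sequence)
  expect_identical(a$seed_msa$rows, b$seed_msa$rows)
  c2 <- generate_synthetic(synth_params(seed = 6, n_genomes = 1))
  expect_false(identical(a$genomes[[1]]$sequence, c2$genomes[[1]]$sequence))
})

test_that("planted elements match the truth table exactly", {
  x <- generate_synthetic(synth_params(seed = 9, n_genomes = 2))
  for (g in x$genomes) {
    tt <- x$truth[x$truth$genome_id == g$id, ]
    for (i in seq_len(nrow(tt))) {
      dna <- substr(g$sequence, tt$start[i] + 1, tt$end[i])
      if (tt$strand[i] == "-") dna <- revcomp(dna)
      expect_equal(sub("\\*$", "", translate_dna(dna)), tt$protein[i],
                   info = tt$element_id[i])
    }
    # features table mirrors the truth rows
    expect_setequal(g$features$id, tt$element_id)
  }
  # per-genome element counts: 2 anchor genes, >=1 toxin, 5 decoys
  counts <- table(x$truth$genome_id, x$truth$kind)
  expect_true(all(counts[, "anchor_gene"] == 2))
  expect_true(all(counts[, "true_toxin"] >= 1))
  expect_true(all(counts[, "decoy_no_anchor"] == 1))
})

test_that("distance constraints hold: toxins near anchors, orphans far", {
  x <- generate_synthetic(synth_params(seed = 10, n_genomes = 3))
  gap <- function(s1, e1, s2, e2) max(0, max(s2 - e1, s1 - e2))
  for (gid in names(x$genomes)) {
    tt <- x$truth[x$truth$genome_id == gid, ]
    anc <- tt[tt$kind == "anchor_gene", ]
    span <- c(min(anc$start), max(anc$end))
    for (i in which(tt$kind == "true_toxin")) {
      expect_lte(gap(span[1], span[2], tt$start[i], tt$end[i]), 10000)
    }
    for (i in which(tt$kind == "decoy_no_anchor")) {
      expect_gte(gap(span[1], span[2], tt$start[i], tt$end[i]), 15000)
    }
  }
})

test_that("seed alignment is gap-free with consistent width", {
  x <- generate_synthetic(synth_params(seed = 11, n_genomes = 1))
  expect_equal(length(x$seed_msa$rows), 4)
  expect_false(any(grepl("-", x$seed_msa$rows)))
  expect_true(all(x$seed_msa$match_mask))
  for (r in x$seed_msa$rows) {
    expect_true(classify_toxin(r)$overall)
  }
})

test_that("write_synth emits the documented plain-text files", {
  dir <- withr::local_tempdir()
  x <- generate_synthetic(synth_params(seed = 12, n_genomes = 1),
                          out_dir = dir)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_true(file.exists(file.path(dir, "seed_msa.afa")))
  expect_true(file.exists(file.path(dir, "params.yaml")))
  gid <- names(x$genomes)[1]
  fa <- read_fasta(file.path(dir, "genomes", paste0(gid, ".fasta")))
  expect_equal(fa[[1]]$sequence, x$genomes[[1]]$sequence)
  gb <- read_genbank(file.path(dir, "genomes", paste0(gid, ".gbk")))
  expect_equal(gb[[1]]$sequence, x$genomes[[1]]$sequence)
  expect_setequal(gb[[1]]$features$id, x$truth$element_id)
  tt <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  expect_equal(tt$element_id, x$truth$element_id)
  refs <- read_alignment(file.path(dir, "refs_abc.afa"))
  expect_equal(length(refs$rows), 4)
  # file output is byte-deterministic
  dir2 <- withr::local_tempdir()
  generate_synthetic(synth_params(seed = 12, n_genomes = 1), out_dir = dir2)
  f1 <- file.path(dir, "genomes", paste0(gid, ".gbk"))
  f2 <- file.path(dir2, "genomes", paste0(gid, ".gbk"))
  expect_identical(readLines(f1), readLines(f2))
})
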