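# Seeded generator of synthetic genomes carrying planted Cdz-like clusters
# (two-gene T1SS operon plus nearby small glycine-zipper toxins),
# single-violation decoys and a ground-truth table. Every planted toxin
# satisfies the rule classifier by construction; every decoy violates
# exactly one targeted rule. Intergenic background is salted with stop
# codons in all six frames so it cannot host spurious long ORFs, and planted
# genes are reverse-translated without internal in-frame start codons so
# each planted element yields exactly one candidate ORF.

LEADER_POOL <- c("A", "V", "I", "L", "F")
PAD_POOL <- c("A", "V", "I")
ZIP_X_POOL <- c("A", "V", "I")
TAIL_CHARGED <- c("D", "E", "K", "R")
TAIL_POOL <- c(TAIL_CHARGED, "S", "T", "N", "Q")
DECOY_CLASSES <- c("decoy_interrupted", "decoy_bad_length",
                   "decoy_no_leader", "decoy_no_tail", "decoy_no_anchor")

#' Synthetic-genome generator parameters
#'
#' Defaults emulate the study conditions: one T1SS-anchored cluster per
#' 120 kb contig carrying one to three small glycine-zipper toxins (class
#' probabilities 0.81/0.14/0.05, the observed toxin-count distribution),
#' leaders of 12-30 residues ending in G[G/A/S], zippers of 4-8 G anchors at
#' period 4 with small-hydrophobic intervening residues, and a short charged
#' or polar tail. One decoy of each violation class is planted per genome.
#'
#' @param seed RNG seed; the generator is bit-reproducible for a fixed seed.
#' @param n_genomes Number of contigs (default 20).
#' @param contig_len_nt Contig length (default 120000).
#' @param n_true_clusters Clusters planted per genome.
#' @param toxins_per_cluster Probabilities of 1, 2 or 3 toxins per cluster.
#' @param decoy_spec Named counts per violation class per genome.
#' @param leader_len,zipper_anchors Ranges for leader length (residues) and
#'   zipper anchor count.
#' @param tail_len Range for tail length (residues).
#' @param gc_background Background and codon-sampling GC fraction.
#' @param mutation_rate Per-residue class-preserving substitution rate
#'   applied to planted copies of the family consensus.
#' @param flank_nt Toxins are planted within this distance of their anchor
#'   operon; `decoy_no_anchor` is planted further than `flank_nt + 5000`
#'   from every anchor.
#' @return List of class `SynthParams`.
#' @export
synth_params <- function(seed = 1L, n_genomes = 20L, contig_len_nt = 120000L,
                         n_true_clusters = 1L,
                         toxins_per_cluster = c(`1` = 0.81, `2` = 0.14, `3` = 0.05),
                         decoy_spec = c(decoy_interrupted = 1L,
                                        decoy_bad_length = 1L,
                                        decoy_no_leader = 1L,
                                        decoy_no_tail = 1L,
                                        decoy_no_anchor = 1L),
                         leader_len = c(12L, 30L),
                         zipper_anchors = c(4L, 8L),
                         tail_len = c(4L, 12L),
                         gc_background = 0.55,
                         mutation_rate = 0.1,
                         flank_nt = 10000L) {
  stopifnot(n_genomes >= 1, contig_len_nt >= 40000,
            abs(sum(toxins_per_cluster) - 1) < 1e-9,
            all(decoy_spec >= 0),
            all(names(decoy_spec) %in% DECOY_CLASSES),
            leader_len[1] >= 10, leader_len[2] <= 30,
            zipper_anchors[1] >= 3)
  structure(as.list(environment()), class = "SynthParams")
}

## ---- toxin and decoy proteins ----------------------------------------------

# A toxin is assembled from segments:
#   leader_core (M + hydrophobic interior) | dipep (G + G/A/S) |
#   pad (small hydrophobic, no G) | zipper (G anchors at period 4,
#   intervening small hydrophobic) | tail (charged first, then
#   charged/polar)
# The mature protein (after the dipeptide) is pad+zipper+tail.

toxin_struct_protein <- function(st) {
  paste(c(st$leader_core, st$dipep, st$pad, st$zipper, st$tail),
        collapse = "")
}

new_zipper <- function(n_anchors) {
  z <- character(4 * (n_anchors - 1) + 1)
  z[seq(1, length(z), by = 4)] <- "G"
  xpos <- which(z == "")
  z[xpos] <- sample(ZIP_X_POOL, length(xpos), replace = TRUE)
  z
}

new_tail <- function(len) {
  c(sample(TAIL_CHARGED, 1), sample(TAIL_POOL, len - 1, replace = TRUE))
}

# Fresh toxin structure; used both for the family consensus and stand-alone
# draws.
new_toxin_struct <- function(params) {
  k <- sample(seq(params$leader_len[1], params$leader_len[2]), 1)
  n_anchor <- sample(seq(params$zipper_anchors[1], params$zipper_anchors[2]), 1)
  t_len <- sample(seq(params$tail_len[1], params$tail_len[2]), 1)
  pad_len <- sample(5:25, 1)
  zip_len <- 4 * (n_anchor - 1) + 1
  total <- k + pad_len + zip_len + t_len
  if (total < 60) pad_len <- pad_len + (60 - total)
  st <- list(
    leader_core = c("M", sample(LEADER_POOL, k - 3, replace = TRUE)),
    dipep = c("G", sample(c("G", "A", "S"), 1)),
    pad = sample(PAD_POOL, pad_len, replace = TRUE),
    zipper = new_zipper(n_anchor),
    tail = new_tail(t_len))
  st$n_anchors <- n_anchor
  st
}

mutate_pool <- function(x, pool, rate) {
  hit <- stats::runif(length(x)) < rate
  x[hit] <- sample(pool, sum(hit), replace = TRUE)
  x
}

# Class-preserving mutant of a family structure (anchors and the leader M/G
# stay fixed, segment lengths jitter slightly).
mutate_toxin_struct <- function(st, params, length_jitter = TRUE) {
  r <- params$mutation_rate
  out <- st
  ic <- seq_along(out$leader_core)[-1]
  out$leader_core[ic] <- mutate_pool(out$leader_core[ic], LEADER_POOL, r)
  if (stats::runif(1) < r) out$dipep[2] <- sample(c("G", "A", "S"), 1)
  out$pad <- mutate_pool(out$pad, PAD_POOL, r)
  xpos <- which(out$zipper != "G")
  out$zipper[xpos] <- mutate_pool(out$zipper[xpos], ZIP_X_POOL, r)
  out$tail[-1] <- mutate_pool(out$tail[-1], TAIL_POOL, r)
  if (stats::runif(1) < r) out$tail[1] <- sample(TAIL_CHARGED, 1)
  if (length_jitter) {
    dp <- sample(-2:2, 1)
    if (dp > 0) out$pad <- c(out$pad, sample(PAD_POOL, dp, replace = TRUE))
    if (dp < 0 && length(out$pad) + dp >= 1) {
      out$pad <- out$pad[seq_len(length(out$pad) + dp)]
    }
    dt <- sample(-1:1, 1)
    tl <- length(out$tail) + dt
    if (tl >= params$tail_len[1] && tl <= params$tail_len[2]) {
      if (dt > 0) out$tail <- c(out$tail, sample(TAIL_POOL, dt, replace = TRUE))
      if (dt < 0) out$tail <- out$tail[seq_len(tl)]
    }
  }
  # keep the full length inside the 60-151 window
  total <- length(out$leader_core) + 2 + length(out$pad) +
    length(out$zipper) + length(out$tail)
  if (total < 60) out$pad <- c(out$pad, sample(PAD_POOL, 60 - total, replace = TRUE))
  out
}

#' Draw a planted toxin protein
#'
#' Returns a protein guaranteed to satisfy [classify_toxin()] with default
#' parameters, plus its segment annotation. Uses the session RNG: seed with
#' `set.seed()` (or call through [generate_synthetic()]) for reproducible
#' draws.
#'
#' @param params [synth_params()].
#' @param family Optional family consensus structure to mutate; `NULL` draws
#'   a fresh structure.
#' @return List with `protein` and `struct`.
#' @export
make_toxin_protein <- function(params = synth_params(), family = NULL) {
  for (attempt in 1:100) {
    st <- if (is.null(family)) new_toxin_struct(params) else {
      mutate_toxin_struct(family, params)
    }
    p <- toxin_struct_protein(st)
    if (classify_toxin(p)$overall) {
      return(list(protein = p, struct = st))
    }
  }
  stop("failed to draw a classifier-passing toxin in 100 attempts")
}

#' Draw a single-violation decoy protein
#'
#' Starts from a (family-derived) toxin and perturbs exactly one rule:
#' `decoy_interrupted` plants a proline at a zipper x-position so no motif
#' survives, `decoy_bad_length` pads the mature region past 151 residues,
#' `decoy_no_leader` destroys the G[G/A/S] leader ending (and keeps every G
#' out of the leader search window), `decoy_no_tail` replaces the tail with
#' 25 hydrophobic residues, and `decoy_no_anchor` is a bona fide toxin whose
#' violation is positional (placed with no T1SS within range).
#'
#' @param violation_class One of the decoy class names.
#' @param params [synth_params()].
#' @param family Optional family consensus to derive from.
#' @return List with `protein`, `struct`, `class`.
#' @export
make_decoy <- function(violation_class, params = synth_params(),
                       family = NULL) {
  if (!violation_class %in% DECOY_CLASSES) {
    stop("unknown decoy class: ", violation_class)
  }
  base <- if (is.null(family)) new_toxin_struct(params) else {
    mutate_toxin_struct(family, params, length_jitter = FALSE)
  }
  st <- base
  if (violation_class == "decoy_interrupted") {
    # 4 anchors, interrupted dead centre: two 2-anchor halves, no motif
    st$zipper <- new_zipper(4L)
    st$n_anchors <- 4L
    st$zipper[7] <- "P"
  } else if (violation_class == "decoy_bad_length") {
    need <- 160L - (length(st$leader_core) + 2L + length(st$pad) +
                      length(st$zipper) + length(st$tail))
    st$pad <- c(st$pad, sample(PAD_POOL, max(need, 9L), replace = TRUE))
  } else if (violation_class == "decoy_no_leader") {
    st$dipep <- c("V", "V")
    k <- length(st$leader_core) + 2L
    short <- 36L - k - length(st$pad)
    if (short > 0) st$pad <- c(st$pad, sample(PAD_POOL, short, replace = TRUE))
  } else if (violation_class == "decoy_no_tail") {
    st$pad <- character(0)
    k <- length(st$leader_core) + 2L
    if (st$n_anchors < 6L) {
      st$zipper <- new_zipper(6L)
      st$n_anchors <- 6L
    }
    st$tail <- sample(c("A", "V", "L"), 25, replace = TRUE)
    deficit <- 60L - (k + length(st$zipper) + 25L)
    if (deficit > 0) {
      # grow the leader interior, keeping it inside the allowed window
      st$leader_core <- c(st$leader_core,
                          sample(LEADER_POOL, deficit, replace = TRUE))
    }
  }
  p <- toxin_struct_protein(st)
  v <- classify_toxin(p)
  expected_pass <- violation_class == "decoy_no_anchor"
  if (v$overall != expected_pass) {
    stop("decoy construction failed for ", violation_class)
  }
  list(protein = p, struct = st, class = violation_class)
}

## ---- reverse translation and background ------------------------------------

codon_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      code <- Biostrings::getGeneticCode("11")
      cache <<- split(names(code), unname(code))
    }
    cache
  }
})

codon_gc_weight <- function(codons, gc) {
  vapply(strsplit(codons, ""), function(b) {
    prod(ifelse(b %in% c("G", "C"), gc / 2, (1 - gc) / 2))
  }, 0)
}

#' Reverse-translate a protein
#'
#' Codons are sampled per residue with weights matching the target GC
#' fraction (no codon-usage table). The first residue must be M and is
#' always encoded ATG; internal codons never use ATG/GTG/TTG, so planted
#' genes contain no internal in-frame start codon. A stop codon is appended.
#'
#' @param protein Protein string starting with M.
#' @param gc Target GC fraction.
#' @return In-frame DNA string including the stop codon.
#' @export
reverse_translate <- function(protein, gc = 0.55) {
  res <- strsplit(toupper(protein), "")[[1]]
  stopifnot(res[1] == "M")
  tab <- codon_tables()
  starts <- c("ATG", "GTG", "TTG")
  pick <- function(aa, internal) {
    cods <- tab[[aa]]
    if (is.null(cods)) stop("cannot encode residue ", aa)
    if (internal) cods <- setdiff(cods, starts)
    if (length(cods) == 0) stop("no internal codon available for ", aa)
    w <- codon_gc_weight(cods, gc)
    sample(cods, 1, prob = w)
  }
  codons <- c("ATG",
              vapply(res[-1], pick, "", internal = TRUE),
              sample(c("TAA", "TAG", "TGA"), 1,
                     prob = codon_gc_weight(c("TAA", "TAG", "TGA"), gc)))
  paste(codons, collapse = "")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Ensure no reading frame on either strand runs more than max_gap nt without
# a stop codon, by overwriting codons mid-gap. Keeps intergenic background
# from hosting spurious long ORFs.
salt_stops <- function(s, max_gap = 150L) {
  stops_plus <- c("TAA", "TAG", "TGA")
  stops_minus <- c("TTA", "CTA", "TCA")  # read on the plus strand
  # Overwriting with this cassette places TAA at offsets 1, 5, 9 and TTA at
  # offsets 0, 4, 8 -- every residue class mod 3 -- so a single insertion
  # creates a stop in all six frames and later fixes can never undo it in a
  # way that reopens another frame indefinitely.
  cassette <- strsplit("TTAATTAATTAA", "")[[1]]
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  fix_frame <- function(f, patterns) {
    cs <- seq(f + 1L, n - 2L, by = 3L)
    codons <- paste0(v[cs], v[cs + 1L], v[cs + 2L])
    stop_i <- c(0L, which(codons %in% patterns), length(cs) + 1L)
    gaps <- which(diff(stop_i) * 3L > max_gap)
    changed <- FALSE
    for (g in gaps) {
      mid <- (stop_i[g] + stop_i[g + 1]) %/% 2L
      mid <- min(max(mid, 1L), length(cs))
      at <- min(cs[mid], n - length(cassette) + 1L)
      v[at + seq_along(cassette) - 1L] <<- cassette
      changed <- TRUE
    }
    changed
  }
  for (iter in 1:20) {
    changed <- FALSE
    for (f in 0:2) changed <- fix_frame(f, stops_plus) || changed
    for (f in 0:2) changed <- fix_frame(f, stops_minus) || changed
    if (!changed) break
  }
  paste(v, collapse = "")
}

## ---- anchor reference proteins ----------------------------------------------

ANCHOR_POOL <- setdiff(AA20, "M")

new_anchor_protein <- function(len) {
  paste(c("M", sample(ANCHOR_POOL, len - 1, replace = TRUE)), collapse = "")
}

mutate_protein <- function(protein, rate, pool = ANCHOR_POOL) {
  res <- strsplit(protein, "")[[1]]
  idx <- seq_along(res)[-1]
  hit <- idx[stats::runif(length(idx)) < rate]
  res[hit] <- sample(pool, length(hit), replace = TRUE)
  paste(res, collapse = "")
}

## ---- genome assembly --------------------------------------------------------

empty_truth <- function() {
  data.frame(genome_id = character(), element_id = character(),
             kind = character(), start = integer(), end = integer(),
             strand = character(), protein = character(),
             cluster = character(), stringsAsFactors = FALSE)
}

#' Generate synthetic genomes with planted Cdz-like clusters
#'
#' For each genome: a two-gene T1SS operon (ABC-transporter-like and
#' adaptor-like genes of 1.2-2 kb), one to three toxins within `flank_nt` of
#' the operon, one decoy per violation class (the `decoy_no_anchor` toxin is
#' planted beyond `flank_nt + 5000` of every anchor), and stop-salted
#' intergenic background. Also emits a 4-row seed alignment of noisy family
#' copies and 4-row reference alignments for the two anchor families.
#' Bit-identical output for a fixed seed.
#'
#' @param params [synth_params()].
#' @param out_dir Optional output directory; when given, writes
#'   `genomes/<id>.fasta`, `genomes/<id>.gbk`, `truth.tsv`, `seed_msa.afa`,
#'   `refs_abc.afa`, `refs_adaptor.afa` and `params.yaml`.
#' @return List of class `SynthData`: `genomes` (list of GenomeRecords),
#'   `truth` (data frame), `seed_msa` ([msa()]), `t1ss_refs` (list of two
#'   [msa()] objects), `params`.
#' @export
generate_synthetic <- function(params = synth_params(), out_dir = NULL) {
  rng <- local_rng(params$seed)
  on.exit(rng$restore())
  gc <- params$gc_background

  family <- new_toxin_struct(params)
  seed_rows <- vapply(1:4, function(i) {
    toxin_struct_protein(mutate_toxin_struct(family, params,
                                             length_jitter = FALSE))
  }, "")
  seed_msa <- msa(paste0("seed", 1:4), seed_rows)

  abc_ref <- new_anchor_protein(sample(420:650, 1))
  adaptor_ref <- new_anchor_protein(sample(380:550, 1))
  refs <- list(
    abc = msa(paste0("abc", 1:4),
              vapply(1:4, function(i) mutate_protein(abc_ref, 0.05), "")),
    adaptor = msa(paste0("adaptor", 1:4),
                  vapply(1:4, function(i) mutate_protein(adaptor_ref, 0.05), "")))

  genomes <- list()
  truth <- empty_truth()
  clen <- params$contig_len_nt

  for (g in seq_len(params$n_genomes)) {
    gid <- sprintf("synth_g%02d", g)
    s <- salt_stops(random_dna(clen, gc))
    occupied <- list()
    place <- function(len, lo, hi, margin = 60L) {
      for (try in 1:500) {
        pos <- sample(seq(lo, hi - len), 1)
        ok <- all(vapply(occupied, function(iv) {
          pos + len + margin <= iv[1] || pos >= iv[2] + margin
        }, TRUE))
        if (ok) return(pos)
      }
      stop("contig too short to place all elements; need > ",
           sum(vapply(occupied, function(iv) iv[2] - iv[1], 0)) + len + 20000,
           " nt")
    }
    splice <- function(dna, pos) {
      substr(s, pos + 1L, pos + nchar(dna)) <<- dna
      occupied[[length(occupied) + 1L]] <<- c(pos, pos + nchar(dna))
      c(pos, pos + nchar(dna))
    }
    feats <- empty_features()
    add_gene <- function(id, protein, pos, strand, kind, product, cluster) {
      dna <- reverse_translate(protein, gc)
      if (strand == "-") dna <- revcomp(dna)
      iv <- splice(dna, pos)
      feats <<- rbind(feats, feature(id, "CDS", gid, iv[1], iv[2], strand,
                                     product))
      truth <<- rbind(truth, data.frame(
        genome_id = gid, element_id = id, kind = kind,
        start = iv[1], end = iv[2], strand = strand, protein = protein,
        cluster = cluster, stringsAsFactors = FALSE))
      iv
    }

    anchor_spans <- list()
    for (cl in seq_len(params$n_true_clusters)) {
      cl_id <- sprintf("%s_c%d", gid, cl)
      strand <- sample(c("+", "-"), 1)
      abc <- mutate_protein(abc_ref, 0.05)
      ada <- mutate_protein(adaptor_ref, 0.05)
      len_a <- nchar(abc) * 3L + 3L
      len_b <- nchar(ada) * 3L + 3L
      gap <- sample(80:150, 1)
      op_len <- len_a + gap + len_b
      op_pos <- place(op_len, 16000L, clen - 16000L - op_len)
      iva <- add_gene(paste0(cl_id, "_abc"), abc, op_pos, strand,
                      "anchor_gene", "type I secretion ABC transporter", cl_id)
      ivb <- add_gene(paste0(cl_id, "_adaptor"), ada, op_pos + len_a + gap,
                      strand, "anchor_gene",
                      "type I secretion membrane fusion adaptor", cl_id)
      span <- c(min(iva[1], ivb[1]), max(iva[2], ivb[2]))
      anchor_spans[[length(anchor_spans) + 1L]] <- span

      n_tox <- sample(1:3, 1, prob = params$toxins_per_cluster)
      side <- sample(c(-1, 1), 1)
      d <- sample(300:7000, 1)
      tx_strand <- sample(c("+", "-"), 1)
      cursor <- if (side > 0) span[2] + d else NA
      for (t in seq_len(n_tox)) {
        tox <- make_toxin_protein(params, family)
        glen <- nchar(tox$protein) * 3L + 3L
        if (side > 0) {
          pos <- cursor
          cursor <- cursor + glen + sample(60:280, 1)
        } else {
          if (t == 1) cursor <- span[1] - d
          pos <- cursor - glen
          cursor <- pos - sample(60:280, 1)
        }
        add_gene(sprintf("%s_tox%d", cl_id, t), tox$protein, pos, tx_strand,
                 "true_toxin", "hypothetical protein", cl_id)
      }

      # in-window decoys: scanned by the pipeline, rejected by the rules
      for (dc in setdiff(DECOY_CLASSES, "decoy_no_anchor")) {
        for (k in seq_len(params$decoy_spec[[dc]] %||% 0L)) {
          dec <- make_decoy(dc, params, family)
          glen <- nchar(dec$protein) * 3L + 3L
          dd <- sample(300:7000, 1)
          dside <- sample(c(-1, 1), 1)
          pos <- if (dside > 0) {
            place(glen, span[2] + dd, min(span[2] + 9000L, clen - glen - 100L))
          } else {
            place(glen, max(span[1] - 9000L, 100L), span[1] - dd)
          }
          add_gene(sprintf("%s_%s%d", cl_id, dc, k), dec$protein, pos,
                   sample(c("+", "-"), 1), dc, "hypothetical protein", cl_id)
        }
      }
    }

    # orphan toxins: real toxins with no T1SS within flank_nt + margin
    n_orphan <- params$decoy_spec[["decoy_no_anchor"]] %||% 0L
    for (k in seq_len(n_orphan)) {
      dec <- make_decoy("decoy_no_anchor", params, family)
      glen <- nchar(dec$protein) * 3L + 3L
      margin <- params$flank_nt + 5000L
      for (try in 1:500) {
        pos <- place(glen, 100L, clen - glen - 100L)
        far <- all(vapply(anchor_spans, function(sp) {
          pos >= sp[2] + margin || pos + glen <= sp[1] - margin
        }, TRUE))
        if (far) break
        occupied <- occupied[-length(occupied)]  # undo reservation, retry
        pos <- NA
      }
      if (is.na(pos)) stop("could not place decoy_no_anchor away from anchors")
      occupied <- occupied[-length(occupied)]  # add_gene re-reserves via splice
      add_gene(sprintf("%s_decoy_no_anchor%d", gid, k), dec$protein, pos,
               sample(c("+", "-"), 1), "decoy_no_anchor",
               "hypothetical protein", "")
    }

    genomes[[gid]] <- genome_record(gid, s, "synthetic contig", feats)
  }

  out <- structure(list(genomes = genomes, truth = truth,
                        seed_msa = seed_msa, t1ss_refs = refs,
                        params = params),
                   class = "SynthData")
  if (!is.null(out_dir)) write_synth(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write a synthetic data set to disk
#'
#' @param x A `SynthData` object from [generate_synthetic()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synth <- function(x, out_dir) {
  dir.create(file.path(out_dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  for (g in x$genomes) {
    seqs <- g$sequence
    names(seqs) <- paste(g$id, g$description)
    write_fasta(seqs, file.path(out_dir, "genomes", paste0(g$id, ".fasta")))
    write_genbank(g, file.path(out_dir, "genomes", paste0(g$id, ".gbk")))
  }
  utils::write.table(x$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_alignment(x$seed_msa, file.path(out_dir, "seed_msa.afa"))
  write_alignment(x$t1ss_refs$abc, file.path(out_dir, "refs_abc.afa"))
  write_alignment(x$t1ss_refs$adaptor, file.path(out_dir, "refs_adaptor.afa"))
  p <- x$params
  p$toxins_per_cluster <- as.list(p$toxins_per_cluster)
  p$decoy_spec <- as.list(p$decoy_spec)
  yaml::write_yaml(unclass(p), file.path(out_dir, "params.yaml"))
  invisible(out_dir)
}
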