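# Discovery pipeline: T1SS anchor detection -> 10 kb flanking windows ->
# six-frame ORF enumeration -> iterative profile-HMM search with the
# glycine-zipper rule filter between iterations -> cluster assembly ->
# report tables. Everything is deterministic for a fixed config.

#' Default pipeline configuration
#'
#' Flat named list mirroring every tunable of the discovery procedure:
#' 10 kb anchor flanks, 5 kb anchor-gene grouping, 500 nt toxin adjacency,
#' 2 search iterations, 60-200 residue candidate ORFs, uniform-background
#' profile models and quantile-calibrated bit thresholds.
#'
#' @return Named list of class `CdzConfig`.
#' @export
default_config <- function() {
  structure(list(
    flank_nt = 10000L,
    anchor_group_gap_nt = 5000L,
    adjacency_gap_nt = 500L,
    n_iter = 2L,
    gap_threshold = 0.5,
    pseudocount_weight = 1,
    orf_min_res = 60L,
    orf_max_res = 200L,
    orf_all_starts = TRUE,
    genetic_code = "11",
    cal_n_random = 500L,
    cal_alpha = 1e-3,
    cal_seed = 1000L,
    anchor_mode = "annotated",
    anchor_min_res = 200L,
    anchor_max_res = 900L,
    anchor_cal_n_random = 100L,
    anchor_cal_alpha = 1e-3,
    anchor_cal_seed = 1001L
  ), class = "CdzConfig")
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys override [default_config()]; unknown keys are an
#' error (they are usually typos of real parameters).
#'
#' @param path YAML config file.
#' @return Named list of class `CdzConfig`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- default_config()
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(unclass(base), user)
  structure(out, class = "CdzConfig")
}

# protein encoded by a CDS feature (0-based half-open, stop codon included)
cds_protein <- function(genome, start, end, strand) {
  dna <- substr(genome$sequence, start + 1L, end)
  if (strand == "-") dna <- revcomp(dna)
  sub("\\*$", "", translate_dna(dna))
}

# gap in nt between two 0-based half-open intervals (0 when overlapping)
interval_gap <- function(s1, e1, s2, e2) {
  max(0L, max(s2 - e1, s1 - e2))
}

anchor_locus <- function(contig_id, genes, scores) {
  structure(list(contig_id = contig_id, genes = genes, score = scores,
                 span = c(min(genes$start), max(genes$end))),
            class = "AnchorLocus")
}

# group scored anchor genes (one contig) into loci by gap proximity
group_anchor_genes <- function(genes, scores, group_gap_nt) {
  o <- order(genes$start, genes$end)
  genes <- genes[o, , drop = FALSE]
  scores <- scores[o]
  grp <- cumsum(c(1L, vapply(seq_len(nrow(genes))[-1], function(i) {
    as.integer(genes$start[i] - max(genes$end[seq_len(i - 1)]) > group_gap_nt)
  }, 1L)))
  lapply(split(seq_len(nrow(genes)), grp), function(ix) {
    anchor_locus(genes$contig_id[1], genes[ix, , drop = FALSE], scores[ix])
  })
}

#' Locate T1SS anchor loci
#'
#' Scores every annotated CDS protein against each T1SS reference profile
#' (built from the supplied reference alignments) and keeps CDS whose best
#' forward bit score reaches the profile's calibrated threshold; kept genes
#' within `anchor_group_gap_nt` of each other form one locus. A user BED of
#' anchor intervals bypasses scoring entirely. Genomes without CDS
#' annotation can be scanned with `anchor_mode: six_frame`, which enumerates
#' 200-900 residue ORFs and scores those instead (slower).
#'
#' @param genomes List of [genome_record()] objects.
#' @param t1ss_refs Named list of reference alignments ([msa()] objects) or
#'   prebuilt `ProfileHmm` models, one per T1SS component family.
#' @param user_bed Optional path to (or data frame from) a BED file of
#'   anchor intervals; bypasses profile scoring.
#' @param config Pipeline configuration ([default_config()]).
#' @return List of `AnchorLocus` objects (possibly empty).
#' @export
find_anchors <- function(genomes, t1ss_refs = NULL, user_bed = NULL,
                         config = default_config()) {
  if (!is.null(user_bed)) {
    bed <- if (is.character(user_bed)) read_bed(user_bed) else user_bed
    out <- list()
    for (cid in unique(bed$contig_id)) {
      b <- bed[bed$contig_id == cid, , drop = FALSE]
      out <- c(out, group_anchor_genes(b, rep(NA_real_, nrow(b)),
                                       config$anchor_group_gap_nt))
    }
    return(unname(out))
  }
  if (is.null(t1ss_refs) || length(t1ss_refs) == 0) {
    stop("find_anchors needs T1SS reference alignments or a user BED")
  }
  profiles <- lapply(t1ss_refs, function(r) {
    if (inherits(r, "ProfileHmm")) r else {
      build_profile(r, gap_threshold = config$gap_threshold,
                    pseudocount_weight = config$pseudocount_weight)
    }
  })
  thresholds <- vapply(profiles, function(h) {
    calibrate_threshold(h, n_random = config$anchor_cal_n_random,
                        length_dist = config$anchor_min_res:config$anchor_max_res,
                        seed = config$anchor_cal_seed,
                        alpha = config$anchor_cal_alpha)
  }, 0)

  out <- list()
  for (g in genomes) {
    cds <- g$features[g$features$kind == "CDS", , drop = FALSE]
    if (nrow(cds) == 0) {
      if (!identical(config$anchor_mode, "six_frame")) {
        stop("genome '", g$id, "' has no CDS annotation: supply an anchor ",
             "BED or set anchor_mode: six_frame (ORFs of ",
             config$anchor_min_res, "-", config$anchor_max_res,
             " residues are scored as anchors; slower)")
      }
      op <- orf_params(config$anchor_min_res, config$anchor_max_res,
                       all_starts = FALSE, table = config$genetic_code)
      orfs <- enumerate_orfs(g$sequence, op, contig_id = g$id)
      cds <- if (nrow(orfs) == 0) empty_features() else {
        feature(orfs$orf_id, "CDS", orfs$contig_id, orfs$start, orfs$end,
                orfs$strand, "six-frame ORF")
      }
    }
    if (nrow(cds) == 0) next
    prot <- vapply(seq_len(nrow(cds)), function(i) {
      cds_protein(g, cds$start[i], cds$end[i], cds$strand[i])
    }, "")
    long_enough <- nchar(prot) >= config$anchor_min_res &
      nchar(prot) <= config$anchor_max_res
    best <- rep(-Inf, nrow(cds))
    pass <- rep(FALSE, nrow(cds))
    for (i in which(long_enough)) {
      sc <- vapply(profiles, score_forward, 0, protein = prot[i])
      best[i] <- max(sc)
      pass[i] <- any(sc >= thresholds)
    }
    if (!any(pass)) next
    hits <- cds[pass, , drop = FALSE]
    hits$kind <- "anchor"
    out <- c(out, group_anchor_genes(hits, best[pass],
                                     config$anchor_group_gap_nt))
  }
  unname(out)
}

#' @export
print.AnchorLocus <- function(x, ...) {
  cat(sprintf("AnchorLocus %s:[%d,%d) with %d gene(s)\n", x$contig_id,
              x$span[1], x$span[2], nrow(x$genes)))
  invisible(x)
}

## ---- iterative search --------------------------------------------------------

# enumerate candidate ORFs across windows, in genome coordinates
window_candidates <- function(windows, config) {
  op <- orf_params(config$orf_min_res, config$orf_max_res,
                   all_starts = config$orf_all_starts,
                   table = config$genetic_code)
  cand <- lapply(windows, function(w) {
    enumerate_orfs(w$seq, op, contig_id = w$window$contig_id,
                   offset = w$window$start)
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) return(cand)
  # windows of nearby anchors overlap; an ORF is one candidate regardless
  cand <- cand[!duplicated(cand$orf_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Iterative profile-HMM search over anchor windows
#'
#' Round 0 scores every candidate ORF (six-frame, 60-200 residues, from all
#' windows) with the model built from the seed alignment. ORFs whose forward
#' bit score reaches the calibrated threshold AND whose protein passes the
#' full glycine-zipper rule classifier are Viterbi-aligned and appended to
#' the alignment; the model is rebuilt and the search repeated, up to
#' `n_iter` rebuild rounds or until a round adds no hits. The accepted set
#' only ever grows. A model-build failure mid-iteration aborts with the
#' state of the last completed iteration (with a warning).
#'
#' @param windows List of windows from [extract_window()].
#' @param seed_msa Seed alignment ([msa()], >= 2 rows).
#' @param n_iter Number of rebuild rounds after the seed round (default 2;
#'   `n_iter = 0` scores with the seed model only).
#' @param config Pipeline configuration.
#' @param gz Classifier parameters ([gz_params()]).
#' @return List of class `SearchState`: `iteration`, `msa`, `hmm`,
#'   `accepted` (data frame of ORF calls with `bit_score` and `iteration`),
#'   `threshold_bits`, `log` (character vector).
#' @export
run_iterative_search <- function(windows, seed_msa, n_iter = 2L,
                                 config = default_config(),
                                 gz = gz_params()) {
  stopifnot(length(windows) >= 1, inherits(seed_msa, "Msa"),
            length(seed_msa$rows) >= 2, n_iter >= 0)
  cand <- window_candidates(windows, config)
  log <- character(0)
  n_cand <- if (is.null(cand)) 0L else nrow(cand)
  log <- c(log, sprintf("candidates: %d ORFs from %d windows",
                        n_cand, length(windows)))

  aln <- seed_msa
  accepted <- NULL
  hmm <- NULL
  threshold <- NA_real_
  last_done <- -1L

  for (it in 0:n_iter) {
    new_hmm <- tryCatch(
      build_profile(aln, gap_threshold = config$gap_threshold,
                    pseudocount_weight = config$pseudocount_weight),
      error = function(e) e)
    if (inherits(new_hmm, "error")) {
      warning("model build failed at iteration ", it, " (",
              conditionMessage(new_hmm), "); returning iteration ",
              last_done)
      log <- c(log, sprintf("iteration %d: model build failed: %s", it,
                            conditionMessage(new_hmm)))
      break
    }
    hmm <- new_hmm
    threshold <- calibrate_threshold(
      hmm, n_random = config$cal_n_random,
      length_dist = config$orf_min_res:config$orf_max_res,
      seed = config$cal_seed, alpha = config$cal_alpha)

    new_rows <- integer(0)
    if (n_cand > 0) {
      seen <- if (is.null(accepted)) character(0) else accepted$orf_id
      todo <- which(!(cand$orf_id %in% seen))
      bits <- vapply(todo, function(i) score_forward(hmm, cand$protein[i]), 0)
      ok <- bits >= threshold
      if (any(ok)) {
        pass <- vapply(todo[ok], function(i) {
          classify_toxin(cand$protein[i], gz)$overall
        }, TRUE)
        new_rows <- todo[ok][pass]
        new_bits <- bits[ok][pass]
      }
    }
    log <- c(log, sprintf(
      "iteration %d: threshold %.2f bits, %d new hit(s) accepted",
      it, threshold, length(new_rows)))
    if (length(new_rows)) {
      add <- cand[new_rows, , drop = FALSE]
      add$bit_score <- new_bits
      add$iteration <- it
      accepted <- rbind(accepted, add)
      hits <- lapply(new_rows, function(i) {
        align_viterbi(hmm, cand$protein[i], seq_id = cand$orf_id[i])
      })
      aln <- msa_append(aln, vapply(hits, `[[`, "", "seq_id"),
                        vapply(hits, `[[`, "", "aligned_row"))
    }
    last_done <- it
    if (length(new_rows) == 0) break   # alignment unchanged: converged
  }

  if (is.null(accepted)) {
    accepted <- data.frame(orf_id = character(), contig_id = character(),
                           start = integer(), end = integer(),
                           strand = character(), frame = integer(),
                           protein = character(), start_codon = character(),
                           bit_score = numeric(), iteration = integer(),
                           stringsAsFactors = FALSE)
  }
  rownames(accepted) <- NULL
  structure(list(iteration = max(last_done, 0L), msa = aln, hmm = hmm,
                 accepted = accepted, threshold_bits = threshold, log = log),
            class = "SearchState")
}

#' @export
print.SearchState <- function(x, ...) {
  cat(sprintf("SearchState: iteration %d, %d accepted, threshold %.2f bits\n",
              x$iteration, nrow(x$accepted), x$threshold_bits))
  invisible(x)
}

## ---- cluster assembly --------------------------------------------------------

#' Assemble toxin-anchor clusters
#'
#' Accepted ORFs sharing a stop codon (same contig, strand and stop-side
#' coordinate) are alternative starts of one gene and are first collapsed to
#' the highest-scoring one. Each surviving toxin is assigned to the nearest
#' anchor locus on its contig whose span lies within `flank_nt` (interval
#' gap distance); toxins with no anchor in range are dropped and reported
#' separately. Toxins in a cluster are sorted by position; consecutive
#' toxins closer than `adjacency_gap_nt` set the cluster's adjacency flag.
#'
#' @param accepted Accepted ORF data frame from [run_iterative_search()].
#' @param anchors List of `AnchorLocus` from [find_anchors()].
#' @param flank_nt Maximum toxin-to-anchor-span distance (default 10000).
#' @param adjacency_gap_nt Adjacency threshold between consecutive toxins.
#' @return List: `clusters` (list of `ClusterCall`) and `dropped` (data
#'   frame of out-of-range toxins with their nearest distance).
#' @export
assemble_clusters <- function(accepted, anchors, flank_nt = 10000L,
                              adjacency_gap_nt = 500L) {
  if (!is.null(accepted) && nrow(accepted) > 1) {
    stop_pos <- ifelse(accepted$strand == "+", accepted$end, accepted$start)
    key <- paste(accepted$contig_id, accepted$strand, stop_pos)
    o <- order(-accepted$bit_score, accepted$end - accepted$start)
    keep <- sort(o[!duplicated(key[o])])
    accepted <- accepted[keep, , drop = FALSE]
    rownames(accepted) <- NULL
  }
  n <- if (is.null(accepted)) 0L else nrow(accepted)
  assign_to <- rep(NA_integer_, n)
  dist_to <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- vapply(anchors, function(a) {
      if (!identical(a$contig_id, accepted$contig_id[i])) return(Inf)
      interval_gap(a$span[1], a$span[2], accepted$start[i], accepted$end[i])
    }, 0)
    if (length(d) == 0 || all(is.infinite(d))) next
    j <- which.min(d)
    dist_to[i] <- d[j]
    if (d[j] <= flank_nt) assign_to[i] <- j
  }
  clusters <- list()
  for (j in seq_along(anchors)) {
    ix <- which(assign_to == j)
    if (length(ix) == 0) next
    tx <- accepted[ix, , drop = FALSE]
    tx$distance_nt <- dist_to[ix]
    o <- order(tx$start, tx$end)
    tx <- tx[o, , drop = FALSE]
    rownames(tx) <- NULL
    k <- nrow(tx)
    adj <- k > 1 && any(tx$start[-1] - tx$end[-k] < adjacency_gap_nt)
    cid <- sprintf("%s_cluster%d", anchors[[j]]$contig_id, j)
    clusters[[length(clusters) + 1L]] <- structure(
      list(cluster_id = cid, anchor = anchors[[j]], toxins = tx,
           toxin_count_class = if (k >= 3) "3+" else as.character(k),
           adjacent = adj),
      class = "ClusterCall")
  }
  dropped <- if (n == 0) accepted[0, , drop = FALSE] else {
    accepted[is.na(assign_to), , drop = FALSE]
  }
  if (nrow(dropped)) {
    dropped$nearest_anchor_nt <- dist_to[is.na(assign_to)]
  } else {
    dropped$nearest_anchor_nt <- numeric(0)
  }
  rownames(dropped) <- NULL
  list(clusters = clusters, dropped = dropped)
}

#' @export
print.ClusterCall <- function(x, ...) {
  cat(sprintf("ClusterCall %s: %d toxin(s) (class %s)%s\n", x$cluster_id,
              nrow(x$toxins), x$toxin_count_class,
              if (x$adjacent) ", adjacent" else ""))
  invisible(x)
}

#' Summary tables for a set of clusters
#'
#' @param clusters List of `ClusterCall`.
#' @param taxonomy_map Optional data frame (`id`, `lineage`) mapping contig
#'   ids to lineages; unmapped ids are grouped under `"unassigned"`.
#' @return List of data frames: `clusters` (one row per cluster),
#'   `class_distribution` (`toxin_count_class`, `count`, `percent`),
#'   `taxa` (`lineage`, `clusters`).
#' @export
summarize_clusters <- function(clusters, taxonomy_map = NULL) {
  if (length(clusters) == 0) {
    return(list(
      clusters = data.frame(contig_id = character(), cluster_id = character(),
                            anchor_start = integer(), anchor_end = integer(),
                            n_anchor_genes = integer(), n_toxins = integer(),
                            toxin_count_class = character(),
                            adjacent = logical(), lineage = character(),
                            stringsAsFactors = FALSE),
      class_distribution = data.frame(toxin_count_class = character(),
                                      count = integer(), percent = numeric(),
                                      stringsAsFactors = FALSE),
      taxa = data.frame(lineage = character(), clusters = integer(),
                        stringsAsFactors = FALSE)))
  }
  lin <- function(id) {
    if (is.null(taxonomy_map)) return("unassigned")
    hit <- taxonomy_map$lineage[match(id, taxonomy_map$id)]
    if (is.na(hit)) "unassigned" else hit
  }
  tab <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(contig_id = cl$anchor$contig_id, cluster_id = cl$cluster_id,
               anchor_start = cl$anchor$span[1], anchor_end = cl$anchor$span[2],
               n_anchor_genes = nrow(cl$anchor$genes),
               n_toxins = nrow(cl$toxins),
               toxin_count_class = cl$toxin_count_class,
               adjacent = cl$adjacent,
               lineage = lin(cl$anchor$contig_id),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  cls <- table(factor(tab$toxin_count_class, levels = c("1", "2", "3+")))
  dist <- data.frame(toxin_count_class = names(cls),
                     count = as.integer(cls),
                     percent = 100 * as.integer(cls) / sum(cls),
                     stringsAsFactors = FALSE)
  tx <- table(tab$lineage)
  taxa <- data.frame(lineage = names(tx), clusters = as.integer(tx),
                     stringsAsFactors = FALSE)
  list(clusters = tab, class_distribution = dist, taxa = taxa)
}

## ---- end-to-end orchestrator -------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full discovery pipeline
#'
#' Anchors are located (profile scoring or user BED), a `flank_nt` window is
#' cut around each anchor locus, candidate ORFs are searched iteratively
#' with the seed profile, survivors are assembled into anchor-toxin clusters
#' and summarised. With `out_dir` set, writes `clusters.gff3`, `toxins.faa`
#' (accepted toxin proteins), `report.tsv` (one row per accepted toxin,
#' clustered or dropped), `summary.tsv` (one row per cluster) and `run.log`
#' (config echo plus the iteration log). Byte-identical output for identical
#' inputs and config.
#'
#' @param genomes List of [genome_record()] objects.
#' @param seed_msa Seed alignment for the toxin family.
#' @param t1ss_refs Named list of T1SS reference alignments (ignored when
#'   `anchors_bed` is given).
#' @param anchors_bed Optional BED of anchor intervals.
#' @param taxonomy_map Optional taxonomy data frame for [summarize_clusters()].
#' @param config Pipeline configuration.
#' @param out_dir Optional output directory.
#' @return List of class `ScanResult`: `anchors`, `search` (SearchState),
#'   `clusters`, `dropped`, `summary`, `report`, `config`.
#' @export
scan_genomes <- function(genomes, seed_msa, t1ss_refs = NULL,
                         anchors_bed = NULL, taxonomy_map = NULL,
                         config = default_config(), out_dir = NULL) {
  anchors <- find_anchors(genomes, t1ss_refs, anchors_bed, config)
  by_id <- stats::setNames(genomes, vapply(genomes, `[[`, "", "id"))
  windows <- lapply(anchors, function(a) {
    extract_window(by_id[[a$contig_id]],
                   list(contig_id = a$contig_id, start = a$span[1],
                        end = a$span[2]),
                   flank_nt = config$flank_nt)
  })
  if (length(windows) > 0) {
    search <- run_iterative_search(windows, seed_msa, n_iter = config$n_iter,
                                   config = config)
  } else {
    empty_acc <- data.frame(
      orf_id = character(), contig_id = character(), start = integer(),
      end = integer(), strand = character(), frame = integer(),
      protein = character(), start_codon = character(),
      bit_score = numeric(), iteration = integer(), stringsAsFactors = FALSE)
    search <- structure(list(iteration = 0L, msa = seed_msa, hmm = NULL,
                             accepted = empty_acc,
                             threshold_bits = NA_real_,
                             log = "no anchors found; nothing searched"),
                        class = "SearchState")
  }
  asm <- assemble_clusters(search$accepted, anchors,
                           flank_nt = config$flank_nt,
                           adjacency_gap_nt = config$adjacency_gap_nt)
  summ <- summarize_clusters(asm$clusters, taxonomy_map)

  # per-toxin report: clustered toxins first (cluster order), then dropped
  rep_rows <- list()
  for (cl in asm$clusters) {
    tx <- cl$toxins
    tx$cluster_id <- cl$cluster_id
    tx$status <- "clustered"
    rep_rows[[length(rep_rows) + 1L]] <- tx
  }
  if (nrow(asm$dropped)) {
    d <- asm$dropped
    d$distance_nt <- d$nearest_anchor_nt
    d$nearest_anchor_nt <- NULL
    d$cluster_id <- NA_character_
    d$status <- "dropped_no_anchor"
    rep_rows[[length(rep_rows) + 1L]] <- d
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else {
    cbind(search$accepted[0, , drop = FALSE],
          data.frame(distance_nt = numeric(), cluster_id = character(),
                     status = character(), stringsAsFactors = FALSE))
  }
  rownames(report) <- NULL

  out <- structure(list(anchors = anchors, search = search,
                        clusters = asm$clusters, dropped = asm$dropped,
                        summary = summ, report = report, config = config),
                   class = "ScanResult")
  if (!is.null(out_dir)) write_scan_result(out, out_dir)
  out
}

#' @export
print.ScanResult <- function(x, ...) {
  cat(sprintf("ScanResult: %d anchor loci, %d accepted toxins, %d clusters\n",
              length(x$anchors), nrow(x$search$accepted), length(x$clusters)))
  invisible(x)
}

#' Write pipeline output files
#'
#' @param x A `ScanResult` from [scan_genomes()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_scan_result <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_gff3(x$clusters, file.path(out_dir, "clusters.gff3"))
  acc <- x$search$accepted
  seqs <- acc$protein
  names(seqs) <- acc$orf_id
  write_fasta(seqs, file.path(out_dir, "toxins.faa"))
  rep_cols <- c("orf_id", "contig_id", "start", "end", "strand",
                "bit_score", "iteration", "distance_nt", "cluster_id",
                "status")
  rep <- x$report[, intersect(rep_cols, names(x$report)), drop = FALSE]
  if (nrow(rep)) rep$bit_score <- sprintf("%.4f", rep$bit_score)
  write_tsv(rep, file.path(out_dir, "report.tsv"))
  write_tsv(x$summary$clusters, file.path(out_dir, "summary.tsv"))
  log <- c("# cdzminer scan",
           "## config",
           strsplit(yaml::as.yaml(unclass(x$config)), "\n")[[1]],
           "## search",
           x$search$log,
           "## clusters",
           sprintf("clusters: %d", length(x$clusters)),
           sprintf("dropped (no anchor in range): %d", nrow(x$dropped)))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
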