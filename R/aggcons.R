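# Aggregation-propensity consensus: external per-residue predictor tracks
# (AmylPred 2, WALZ, MetAmyl, PASTA 2.0 exports, or any boolean track) are
# combined per residue; a residue is aggregation-prone when at least k_min
# predictors agree. A built-in hydropathy-window predictor keeps the
# combiner testable offline.

#' Build a predictor track
#'
#' @param predictor_name Name of the predictor.
#' @param calls Logical vector, one call per residue.
#' @return List of class `PredictorTrack`.
#' @export
predictor_track <- function(predictor_name, calls) {
  stopifnot(is.logical(calls), length(calls) > 0, !anyNA(calls))
  structure(list(predictor_name = predictor_name, calls = calls),
            class = "PredictorTrack")
}

#' Per-residue consensus of predictor tracks
#'
#' A residue is flagged when at least `k_min` tracks call it; flagged
#' residues are merged into maximal disjoint intervals. Track order never
#' changes the result, and intervals at `k_min = 4` are a subset of those at
#' `k_min = 3`.
#'
#' @param tracks List of [predictor_track()] objects over the same protein.
#' @param k_min Minimum agreeing predictors (default 3, the >=3-of-4 rule).
#' @return List of class `ConsensusCall`: `intervals` (data frame of 0-based
#'   half-open `start`, `end`) and `support` (per-residue agreement count).
#' @export
consensus <- function(tracks, k_min = 3L) {
  stopifnot(length(tracks) >= k_min)
  lens <- vapply(tracks, function(t) length(t$calls), 1L)
  if (length(unique(lens)) != 1) {
    stop("track lengths differ: ",
         paste(sprintf("%s=%d", vapply(tracks, `[[`, "", "predictor_name"),
                       lens), collapse = ", "))
  }
  support <- Reduce(`+`, lapply(tracks, function(t) as.integer(t$calls)))
  flagged <- support >= k_min
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  intervals <- data.frame(start = starts[keep] - 1L, end = ends[keep])
  structure(list(intervals = intervals, support = support),
            class = "ConsensusCall")
}

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Built-in hydropathy-window predictor
#'
#' Flags a residue when the mean Kyte-Doolittle hydropathy of the centred
#' window reaches `cutoff`; windows are truncated at the sequence edges.
#' This is a stand-in predictor so the consensus combiner can be exercised
#' without external web-server exports.
#'
#' @param protein Protein string.
#' @param window Odd window length (default 7).
#' @param cutoff Mean hydropathy threshold (default 1.5).
#' @return A [predictor_track()].
#' @export
hydrophobic_window_predictor <- function(protein, window = 7L, cutoff = 1.5) {
  stopifnot(window %% 2 == 1)
  res <- strsplit(toupper(protein), "")[[1]]
  h <- unname(KD_SCALE[res])
  h[is.na(h)] <- 0
  half <- (window - 1L) / 2L
  n <- length(h)
  calls <- vapply(seq_len(n), function(i) {
    mean(h[max(1L, i - half):min(n, i + half)]) >= cutoff
  }, TRUE)
  predictor_track(sprintf("kd_window%d", window), calls)
}

#' Read predictor tracks from TSV
#'
#' Expected columns (no header): predictor name, sequence id, per-residue
#' 0/1 string.
#'
#' @param path TSV file.
#' @return Named list (by sequence id) of lists of [predictor_track()]s.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(list())
  out <- list()
  for (ln in seq_along(lines)) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3 || !grepl("^[01]+$", parts[3])) {
      stop("malformed track row at line ", ln, " of ", path)
    }
    calls <- strsplit(parts[3], "")[[1]] == "1"
    out[[parts[2]]] <- c(out[[parts[2]]],
                         list(predictor_track(parts[1], calls)))
  }
  out
}

#' Write predictor tracks as TSV
#'
#' @param tracks_by_seq Named list (sequence id) of lists of tracks, the
#'   shape returned by [read_tracks()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks_by_seq, path) {
  lines <- character(0)
  for (sid in names(tracks_by_seq)) {
    for (t in tracks_by_seq[[sid]]) {
      lines <- c(lines, paste(t$predictor_name, sid,
                              paste(as.integer(t$calls), collapse = ""),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export consensus intervals as BED-like TSV
#'
#' @param calls Named list of [consensus()] results (by sequence id).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_consensus_bed <- function(calls, path) {
  lines <- character(0)
  for (sid in names(calls)) {
    iv <- calls[[sid]]$intervals
    if (nrow(iv)) {
      lines <- c(lines, paste(sid, iv$start, iv$end, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
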