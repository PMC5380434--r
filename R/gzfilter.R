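# Rule-based toxin classifier. A Cdz-like toxin candidate must be (i) 60-151
# residues long (full translated ORF), (ii) carry an N-terminal secretion
# leader ending in the dipeptide G[G/A/S], (iii) harbour one or two
# glycine-zipper motifs (G anchors at exact period 4) flanked, but never
# interrupted, by a proline or charged residue (cysteine also interrupts),
# and (iv) end in a short, charged or polar C-terminal tail. Sequences with
# dense spans of polar/charged residues upstream of the tail are filtered
# out.

#' Residue class sets used by the classifier
#'
#' Histidine is treated as polar, not charged; zipper anchors are strictly G
#' by default, with an option to admit the broader (G/A/S)xxxG family.
#'
#' @param charged,polar,small_hydrophobic,zipper_anchor Residue sets.
#' @param forbidden_in_zipper Residues that interrupt a zipper at an
#'   intervening (x) position; default charged plus P and C.
#' @return List of class `ResidueClasses`.
#' @export
residue_classes <- function(charged = c("D", "E", "K", "R"),
                            polar = c("S", "T", "N", "Q", "H", "Y"),
                            small_hydrophobic = c("G", "A", "V", "I"),
                            zipper_anchor = c("G"),
                            forbidden_in_zipper = c(charged, "P", "C")) {
  stopifnot(length(intersect(zipper_anchor, forbidden_in_zipper)) == 0)
  structure(list(charged = charged, polar = polar,
                 small_hydrophobic = small_hydrophobic,
                 zipper_anchor = zipper_anchor,
                 forbidden_in_zipper = forbidden_in_zipper),
            class = "ResidueClasses")
}

#' Classifier parameter bundle
#'
#' Numeric defaults for the leader window, flank window, polar-span rule and
#' tail rule are package conventions (the motif definitions themselves are
#' fixed by the classifier rules); all are exposed here.
#'
#' @param classes [residue_classes()].
#' @param min_len,max_len Full-protein length band (60-151 residues).
#' @param min_leader,max_leader Allowed leader lengths.
#' @param min_anchors Minimum G anchors per zipper motif.
#' @param flank_window Residues searched for a flanking P/charged residue at
#'   each motif end.
#' @param flank_require `"one"` (default: at least one motif end flanked,
#'   termini count), `"both"`, or `"none"` (descriptive only).
#' @param max_tail,min_charged_polar_frac C-terminal tail rule.
#' @param span_window,span_max_charged_polar Polar/charged span filter:
#'   fail when any `span_window`-length window of the pre-tail mature region
#'   holds more than `span_max_charged_polar` charged+polar residues.
#' @return List of class `GzParams`.
#' @export
gz_params <- function(classes = residue_classes(),
                      min_len = 60L, max_len = 151L,
                      min_leader = 10L, max_leader = 35L,
                      min_anchors = 3L,
                      flank_window = 3L, flank_require = c("one", "both", "none"),
                      max_tail = 20L, min_charged_polar_frac = 0.4,
                      span_window = 6L, span_max_charged_polar = 4L) {
  structure(list(classes = classes, min_len = min_len, max_len = max_len,
                 min_leader = min_leader, max_leader = max_leader,
                 min_anchors = min_anchors, flank_window = flank_window,
                 flank_require = match.arg(flank_require),
                 max_tail = max_tail,
                 min_charged_polar_frac = min_charged_polar_frac,
                 span_window = span_window,
                 span_max_charged_polar = span_max_charged_polar),
            class = "GzParams")
}

#' Call the secretion leader peptide
#'
#' Finds the first cleavage point `i` in `[min_leader, max_leader]` (leader
#' length, in residues) such that the two preceding residues are G followed
#' by one of G/A/S; the mature protein starts at `i` (0-based).
#'
#' @param protein Protein string (longer than `max_leader`).
#' @param min_leader,max_leader Leader length bounds.
#' @return List with `cleavage_index` (0-based index of the first mature
#'   residue) and `dipeptide`, or `NULL` when no leader is found.
#' @export
detect_leader <- function(protein, min_leader = 10L, max_leader = 35L) {
  protein <- toupper(protein)
  n <- nchar(protein)
  if (n <= max_leader) stop("protein not longer than max_leader")
  res <- strsplit(protein, "")[[1]]
  for (i in seq(min_leader, max_leader)) {
    if (res[i - 1] == "G" && res[i] %in% c("G", "A", "S")) {
      return(list(cleavage_index = i,
                  dipeptide = paste0(res[i - 1], res[i])))
    }
  }
  NULL
}

mature_of <- function(protein, leader) {
  substr(protein, leader$cleavage_index + 1L, nchar(protein))
}

#' Find glycine-zipper motifs
#'
#' Maximal runs of anchor residues (G by default) at exact period 4 with at
#' least `min_anchors` anchors and no forbidden residue (P, C or charged) at
#' any intervening position. Sub-runs of a reported run are not reported.
#'
#' @param mature Mature protein string.
#' @param classes [residue_classes()].
#' @param min_anchors Minimum anchors per motif (default 3, the GxxxGxxxG
#'   core).
#' @return Data frame with one row per motif: `first`, `last` (0-based
#'   residue indices of the first/last anchor), `n_anchors`, and `anchors`
#'   (list column of 0-based anchor indices).
#' @export
find_zippers <- function(mature, classes = residue_classes(),
                         min_anchors = 3L) {
  mature <- toupper(mature)
  stopifnot(nzchar(mature))
  res <- strsplit(mature, "")[[1]]
  n <- length(res)
  is_anchor <- res %in% classes$zipper_anchor
  is_forbidden <- res %in% classes$forbidden_in_zipper
  out <- list()
  covered_start <- rep(FALSE, n)  # positions already inside a maximal run
  p <- 1L
  while (p <= n) {
    if (is_anchor[p] && !covered_start[p]) {
      # extend at period 4 while intervening residues are allowed
      last <- p
      while (last + 4L <= n && is_anchor[last + 4L] &&
             !any(is_forbidden[(last + 1L):(last + 3L)])) {
        last <- last + 4L
      }
      k <- (last - p) / 4L + 1L
      if (k >= min_anchors) {
        anchors <- seq(p, last, by = 4L)
        covered_start[anchors] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          first = p - 1L, last = last - 1L, n_anchors = as.integer(k))
        out[[length(out)]]$anchors <- I(list(anchors - 1L))
      }
    }
    p <- p + 1L
  }
  if (length(out) == 0) {
    z <- data.frame(first = integer(), last = integer(), n_anchors = integer())
    z$anchors <- I(list())
    return(z)
  }
  do.call(rbind, out)
}

#' Check that a zipper motif is flanked by proline/charged residues
#'
#' A motif end is flanked when a P or charged residue occurs within
#' `flank_window` residues beyond it, or when the sequence terminus falls
#' within that window (the motif running into the end of the mature protein
#' counts as flanked).
#'
#' @param mature Mature protein string.
#' @param motif One row of [find_zippers()] output.
#' @param classes [residue_classes()].
#' @param flank_window Window size in residues.
#' @param require `"one"` (either side suffices), `"both"`, or `"none"`
#'   (always `TRUE`).
#' @return Logical.
#' @export
check_flanks <- function(mature, motif, classes = residue_classes(),
                         flank_window = 3L, require = "one") {
  if (require == "none") return(TRUE)
  res <- strsplit(toupper(mature), "")[[1]]
  n <- length(res)
  flankers <- c("P", classes$charged)
  f <- motif$first + 1L  # 1-based
  l <- motif$last + 1L
  n_side <- (f - 1L) < flank_window ||
    any(res[(f - flank_window):(f - 1L)] %in% flankers)
  c_side <- (n - l) < flank_window ||
    any(res[(l + 1L):(l + flank_window)] %in% flankers)
  if (require == "both") n_side && c_side else n_side || c_side
}

#' Check the short charged/polar C-terminal tail
#'
#' The tail is everything after the last anchor of the last motif. It passes
#' when it is at most `max_tail` residues long and its charged+polar
#' fraction is at least `min_charged_polar_frac`; an empty tail passes.
#'
#' @param mature Mature protein string.
#' @param motifs [find_zippers()] output (at least one motif).
#' @param classes [residue_classes()].
#' @param max_tail,min_charged_polar_frac Tail rule parameters.
#' @return Logical.
#' @export
check_cterm <- function(mature, motifs, classes = residue_classes(),
                        max_tail = 20L, min_charged_polar_frac = 0.4) {
  stopifnot(nrow(motifs) >= 1)
  res <- strsplit(toupper(mature), "")[[1]]
  last_anchor <- max(motifs$last) + 1L  # 1-based
  if (last_anchor >= length(res)) return(TRUE)
  tail <- res[(last_anchor + 1L):length(res)]
  if (length(tail) > max_tail) return(FALSE)
  frac <- mean(tail %in% c(classes$charged, classes$polar))
  frac >= min_charged_polar_frac
}

#' Filter on polar/charged spans in the pre-tail mature region
#'
#' Returns `FALSE` (sequence filtered out) when any `window`-length window
#' of the mature region before the tail contains more than
#' `max_charged_polar` charged+polar residues.
#'
#' @param mature Mature protein string.
#' @param classes [residue_classes()].
#' @param window Window length in residues.
#' @param max_charged_polar Maximum charged+polar residues tolerated per
#'   window.
#' @param tail_start 0-based index where the tail begins (pre-tail region is
#'   `[0, tail_start)`); `NULL` scans the whole mature sequence.
#' @return Logical (`TRUE` = keep).
#' @export
check_polar_spans <- function(mature, classes = residue_classes(),
                              window = 6L, max_charged_polar = 4L,
                              tail_start = NULL) {
  res <- strsplit(toupper(mature), "")[[1]]
  stopifnot(length(res) > 0)
  if (!is.null(tail_start)) res <- res[seq_len(min(tail_start, length(res)))]
  if (length(res) == 0) return(TRUE)
  hit <- as.integer(res %in% c(classes$charged, classes$polar))
  if (length(hit) <= window) return(sum(hit) <= max_charged_polar)
  cs <- c(0, cumsum(hit))
  counts <- cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]
  all(counts <= max_charged_polar)
}

#' Classify a candidate toxin protein
#'
#' Applies the full rule cascade to one translated ORF. Criteria are
#' evaluated independently and `overall` is their pure conjunction:
#' full-length 60-151 residues, leader present, one or two zipper motifs,
#' every motif flanked, tail rule, polar-span rule. Criteria that cannot be
#' evaluated (e.g. the tail rule when no motif exists) are `NA` and count as
#' failures.
#'
#' @param protein Full translated ORF (no stop).
#' @param params [gz_params()].
#' @return List of class `FeatureVerdict` with fields `length_ok`, `leader`,
#'   `mature`, `zippers`, `n_zippers`, `zipper_ok`, `flank_ok`, `cterm_ok`,
#'   `polar_span_ok`, `overall`.
#' @export
classify_toxin <- function(protein, params = gz_params()) {
  protein <- toupper(protein)
  n <- nchar(protein)
  cl <- params$classes
  length_ok <- n >= params$min_len && n <= params$max_len

  leader <- if (n > params$max_leader) {
    detect_leader(protein, params$min_leader, params$max_leader)
  } else NULL
  mature <- if (!is.null(leader)) mature_of(protein, leader) else NA_character_

  zippers <- NULL; zipper_ok <- NA; flank_ok <- NA
  cterm_ok <- NA; polar_span_ok <- NA
  if (!is.null(leader) && nzchar(mature)) {
    zippers <- find_zippers(mature, cl, params$min_anchors)
    zipper_ok <- nrow(zippers) %in% c(1L, 2L)
    if (nrow(zippers) >= 1) {
      flank_ok <- all(vapply(seq_len(nrow(zippers)), function(i) {
        check_flanks(mature, zippers[i, ], cl, params$flank_window,
                     params$flank_require)
      }, TRUE))
      cterm_ok <- check_cterm(mature, zippers, cl, params$max_tail,
                              params$min_charged_polar_frac)
      polar_span_ok <- check_polar_spans(
        mature, cl, params$span_window, params$span_max_charged_polar,
        tail_start = max(zippers$last) + 1L)
    }
  }
  overall <- isTRUE(length_ok) && !is.null(leader) && isTRUE(zipper_ok) &&
    isTRUE(flank_ok) && isTRUE(cterm_ok) && isTRUE(polar_span_ok)
  structure(list(length_ok = length_ok, leader = leader, mature = mature,
                 zippers = zippers,
                 n_zippers = if (is.null(zippers)) NA_integer_ else nrow(zippers),
                 zipper_ok = zipper_ok, flank_ok = flank_ok,
                 cterm_ok = cterm_ok, polar_span_ok = polar_span_ok,
                 overall = overall),
            class = "FeatureVerdict")
}

#' @export
print.FeatureVerdict <- function(x, ...) {
  cat(sprintf(
    "FeatureVerdict: length %s leader %s zippers %s flank %s cterm %s spans %s -> %s\n",
    x$length_ok, !is.null(x$leader), x$zipper_ok, x$flank_ok, x$cterm_ok,
    x$polar_span_ok, x$overall))
  invisible(x)
}

#' Tabulate verdicts for a set of proteins
#'
#' @param proteins Named character vector of proteins.
#' @param params [gz_params()].
#' @return Data frame, one row per protein, one column per criterion.
#' @export
verdict_table <- function(proteins, params = gz_params()) {
  rows <- lapply(seq_along(proteins), function(i) {
    v <- classify_toxin(proteins[[i]], params)
    data.frame(id = names(proteins)[i], length = nchar(proteins[[i]]),
               length_ok = isTRUE(v$length_ok),
               leader_ok = !is.null(v$leader),
               leader_len = if (!is.null(v$leader)) v$leader$cleavage_index else NA_integer_,
               n_zippers = ifelse(is.na(v$n_zippers), 0L, v$n_zippers),
               zipper_ok = isTRUE(v$zipper_ok),
               flank_ok = isTRUE(v$flank_ok),
               cterm_ok = isTRUE(v$cterm_ok),
               polar_span_ok = isTRUE(v$polar_span_ok),
               overall = v$overall,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Residue class composition of a protein
#'
#' Fractions of small-hydrophobic ({G,A,V,I} by default), charged and polar
#' residues, optionally of the mature form after leader removal by the
#' G[G/A/S] rule.
#'
#' @param protein Protein string.
#' @param classes [residue_classes()].
#' @param mature_only Apply [detect_leader()] first and report on the mature
#'   region; an error names the sequence when no leader is found.
#' @param id Sequence name used in error messages.
#' @return Named numeric vector: `small_hydrophobic`, `charged`, `polar`.
#' @export
composition_stats <- function(protein, classes = residue_classes(),
                              mature_only = FALSE, id = "sequence") {
  protein <- toupper(protein)
  stopifnot(nzchar(protein))
  if (mature_only) {
    leader <- detect_leader(protein)
    if (is.null(leader)) stop("no leader found in ", id)
    protein <- mature_of(protein, leader)
  }
  res <- strsplit(protein, "")[[1]]
  c(small_hydrophobic = mean(res %in% classes$small_hydrophobic),
    charged = mean(res %in% classes$charged),
    polar = mean(res %in% classes$polar))
}
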