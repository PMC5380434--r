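# Profile hidden Markov model engine: model construction from a seed
# alignment, forward and Viterbi scoring in bits, score-threshold
# calibration. Scoring is glocal -- global in the model, local in the
# sequence -- so secretion leaders and tails outside the conserved zipper
# core carry no penalty. There is no composition bias correction, matching
# a search run with the bias filter off.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## ---- alignments ------------------------------------------------------------

#' Construct a multiple sequence alignment object
#'
#' @param names Sequence names.
#' @param rows Aligned rows (equal length; gaps as `-` or `.`).
#' @param gap_threshold Columns whose gap fraction is at most this value are
#'   match columns.
#' @return Object of class `Msa` with a `match_mask` attribute per column.
#' @export
msa <- function(names, rows, gap_threshold = 0.5) {
  stopifnot(length(names) == length(rows), length(rows) >= 1)
  rows <- toupper(gsub(".", "-", rows, fixed = TRUE))
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(rows, ""))
  gapfrac <- colMeans(mat == "-")
  structure(list(names = as.character(names), rows = rows,
                 match_mask = gapfrac <= gap_threshold,
                 gap_threshold = gap_threshold),
            class = "Msa")
}

#' @export
print.Msa <- function(x, ...) {
  cat(sprintf("Msa: %d rows x %d columns (%d match columns)\n",
              length(x$rows), nchar(x$rows[1]), sum(x$match_mask)))
  invisible(x)
}

#' Read a seed alignment (aligned FASTA or Stockholm)
#'
#' @param path Alignment file. Stockholm files are recognised by their
#'   `# STOCKHOLM` header; anything else is parsed as aligned FASTA.
#' @param gap_threshold Match-column rule passed to [msa()].
#' @return An [msa()] object.
#' @export
read_alignment <- function(path, gap_threshold = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("^# STOCKHOLM", first)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    nm <- vapply(parts, `[[`, "", 1)
    sq <- vapply(parts, `[[`, "", 2)
    rows <- vapply(split(sq, nm)[unique(nm)], paste, "", collapse = "")
    return(msa(unique(nm), unname(rows), gap_threshold))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty alignment: ", path)
  msa(sub("\\s.*$", "", names(set)), as.character(set), gap_threshold)
}

#' Write an alignment as aligned FASTA
#' @param x An [msa()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  seqs <- x$rows
  names(seqs) <- x$names
  write_fasta(seqs, path)
}

# Restrict an alignment to its match columns (used when growing the
# alignment with Viterbi-aligned hits, which carry one column per match
# state).
msa_match_view <- function(x) {
  mat <- do.call(rbind, strsplit(x$rows, ""))
  rows <- apply(mat[, x$match_mask, drop = FALSE], 1, paste, collapse = "")
  msa(x$names, rows, gap_threshold = x$gap_threshold)
}

# Append match-state rows (width = number of match columns) to a projected
# alignment.
msa_append <- function(x, names, rows) {
  xm <- msa_match_view(x)
  stopifnot(all(nchar(rows) == nchar(xm$rows[1])))
  msa(c(xm$names, names), c(xm$rows, rows), gap_threshold = x$gap_threshold)
}

## ---- model construction ----------------------------------------------------

#' Build a profile HMM from a seed alignment
#'
#' Match states sit at columns whose gap fraction is at most
#' `gap_threshold`. Match emissions are background-mixture pseudocounted
#' observed counts; insert states emit the background. Transitions are
#' estimated from the gap structure of the alignment with Laplace (+1)
#' smoothing, so every allowed transition has non-zero probability. Sequence
#' weighting is uniform.
#'
#' @param aln An [msa()] object (at least 2 rows).
#' @param gap_threshold Match-column gap-fraction rule (default 0.5).
#' @param pseudocount_weight Weight of the background mixture added to the
#'   observed emission counts (default 1).
#' @param background Length-20 background distribution over [AA20] order;
#'   default uniform (no composition correction).
#' @return Object of class `ProfileHmm`.
#' @export
build_profile <- function(aln, gap_threshold = 0.5, pseudocount_weight = 1,
                          background = NULL) {
  stopifnot(inherits(aln, "Msa"))
  if (length(aln$rows) < 2) stop("profile needs >= 2 aligned rows")
  if (is.null(background)) background <- rep(1 / 20, 20)
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-9)
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  gapfrac <- colMeans(mat == "-")
  mask <- gapfrac <= gap_threshold
  if (!any(mask)) {
    stop("model-build error: every column exceeds the gap threshold")
  }
  L <- sum(mask)
  midx <- which(mask)

  # emissions
  match_emit <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    col <- mat[, midx[j]]
    col <- col[col %in% AA20]
    cnt <- table(factor(col, levels = AA20))
    match_emit[j, ] <- (as.numeric(cnt) + pseudocount_weight * background) /
      (length(col) + pseudocount_weight)
  }

  # transition counts from per-row state walks
  nstate <- function(x) if (x == "-") "D" else "M"
  cBM <- cBD <- 0
  cMM <- cMI <- cMD <- rep(0, max(L - 1, 0))
  cIM <- cII <- cID <- rep(0, max(L - 1, 0))
  cDM <- cDD <- cDI <- rep(0, max(L - 1, 0))
  for (r in seq_len(nrow(mat))) {
    row <- mat[r, ]
    states <- vapply(row[midx], nstate, "")
    # insert residue counts between consecutive match columns
    if (states[1] == "M") cBM <- cBM + 1 else cBD <- cBD + 1
    for (j in seq_len(L - 1)) {
      between <- row[seq(midx[j] + 1L, length.out = max(midx[j + 1] - midx[j] - 1L, 0))]
      k <- sum(between != "-")
      from <- states[j]; to <- states[j + 1]
      if (k == 0) {
        if (from == "M" && to == "M") cMM[j] <- cMM[j] + 1
        if (from == "M" && to == "D") cMD[j] <- cMD[j] + 1
        if (from == "D" && to == "M") cDM[j] <- cDM[j] + 1
        if (from == "D" && to == "D") cDD[j] <- cDD[j] + 1
      } else {
        if (from == "M") cMI[j] <- cMI[j] + 1 else cDI[j] <- cDI[j] + 1
        cII[j] <- cII[j] + (k - 1)
        if (to == "M") cIM[j] <- cIM[j] + 1 else cID[j] <- cID[j] + 1
      }
    }
  }
  norm3 <- function(a, b, d) {
    tot <- a + b + d + 3
    list((a + 1) / tot, (b + 1) / tot, (d + 1) / tot)
  }
  tot_b <- cBM + cBD + 2
  trans <- list(
    BM = (cBM + 1) / tot_b, BD = (cBD + 1) / tot_b,
    MM = numeric(0), MI = numeric(0), MD = numeric(0),
    IM = numeric(0), II = numeric(0), ID = numeric(0),
    DM = numeric(0), DD = numeric(0), DI = numeric(0))
  if (L > 1) {
    m <- norm3(cMM, cMI, cMD); trans$MM <- m[[1]]; trans$MI <- m[[2]]; trans$MD <- m[[3]]
    i <- norm3(cIM, cII, cID); trans$IM <- i[[1]]; trans$II <- i[[2]]; trans$ID <- i[[3]]
    d <- norm3(cDM, cDD, cDI); trans$DM <- d[[1]]; trans$DD <- d[[2]]; trans$DI <- d[[3]]
  }
  consensus <- paste(AA20[apply(match_emit, 1, which.max)], collapse = "")
  structure(list(L = L, alphabet = AA20, match_emit = match_emit,
                 insert_emit = background, background = background,
                 trans = trans, pseudocount_weight = pseudocount_weight,
                 gap_threshold = gap_threshold, consensus = consensus),
            class = "ProfileHmm")
}

#' @export
print.ProfileHmm <- function(x, ...) {
  cat(sprintf("ProfileHmm: %d match states, consensus %s\n", x$L,
              x$consensus))
  invisible(x)
}

## ---- scoring ---------------------------------------------------------------

# log2(a) helpers tolerating 0 -> -Inf
log2p <- function(p) ifelse(p > 0, log2(p), -Inf)

# elementwise log2-sum-exp of two vectors
INV_LOG2 <- 1 / log(2)
lse2 <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(2^(-abs(a - b))) * INV_LOG2
  r[is.infinite(m) & m < 0] <- -Inf
  r
}
lse3 <- function(a, b, d) lse2(lse2(a, b), d)

# per-residue log-odds emission lookup: L x n matrix
emission_odds <- function(hmm, protein) {
  res <- strsplit(toupper(protein), "")[[1]]
  idx <- match(res, hmm$alphabet)
  eod <- log2(sweep(hmm$match_emit, 2, hmm$background, "/"))
  out <- matrix(0, hmm$L, length(res))
  known <- !is.na(idx)
  out[, known] <- eod[, idx[known], drop = FALSE]
  out  # unknown residues (X etc.) score as background: log-odds 0
}

hmm_log_trans <- function(hmm) lapply(hmm$trans, log2p)

# shared DP skeleton; mode "forward" (log-sum) or "viterbi" (max + traceback)
profile_dp <- function(hmm, protein, mode = c("forward", "viterbi")) {
  mode <- match.arg(mode)
  protein <- toupper(protein)
  if (!nzchar(protein)) stop("empty protein sequence")
  L <- hmm$L
  n <- nchar(protein)
  lt <- hmm_log_trans(hmm)
  E <- emission_odds(hmm, protein)
  nI <- max(L - 1, 0)
  comb <- if (mode == "forward") lse3 else function(a, b, d) pmax(a, b, d)

  # delete-chain prefix sums: S[j] = sum of log tDD over 1..j-1
  S <- c(0, cumsum(lt$DD))[seq_len(L)]
  d_chain_fwd <- function(entry) {
    r <- entry - S
    m <- max(r[is.finite(r)], -Inf)
    if (!is.finite(m)) return(rep(-Inf, L))
    S + m + log2(cumsum(2^(r - m)))
  }
  d_chain_vit <- function(entry) {
    r <- entry - S
    cm <- cummax(r)
    list(val = S + cm, from_entry = r >= cm)
  }

  Mprev <- rep(-Inf, L)
  Iprev <- rep(-Inf, nI)
  # column i = 0: all-delete prefixes reachable from B
  Dprev <- lt$BD + S
  end_best <- Dprev[L]          # empty-core / all-delete path
  end_arg <- 0L

  if (mode == "viterbi") {
    ptrM <- matrix(0L, n, L); ptrI <- matrix(0L, n, max(nI, 1))
    ptrDe <- matrix(0L, n + 1, L)       # entry origin: 1 M, 2 I, 3 B
    ptrDc <- matrix(FALSE, n + 1, L)    # TRUE = from entry, FALSE = from D[j-1]
    Mmat <- matrix(-Inf, n + 1, L); Imat <- matrix(-Inf, n + 1, max(nI, 1))
    Dmat <- matrix(-Inf, n + 1, L)
    Dmat[1, ] <- Dprev
    ptrDc[1, ] <- c(TRUE, rep(FALSE, L - 1)); ptrDe[1, 1] <- 3L
  }

  head_idx <- seq_len(max(L - 1, 0))
  sub <- function(v) v[head_idx]
  for (i in seq_len(n)) {
    fromM <- c(lt$BM, if (L > 1) sub(Mprev) + lt$MM)
    fromI <- c(-Inf, if (L > 1) Iprev + lt$IM)
    fromD <- c(-Inf, if (L > 1) sub(Dprev) + lt$DM)
    Mcur <- E[, i] + comb(fromM, fromI, fromD)
    Icur <- if (L > 1) comb(sub(Mprev) + lt$MI, Iprev + lt$II, sub(Dprev) + lt$DI) else numeric(0)
    entry_m <- c(-Inf, if (L > 1) sub(Mcur) + lt$MD)
    entry_i <- c(-Inf, if (L > 1) Icur + lt$ID)
    entry_b <- c(lt$BD, rep(-Inf, L - 1))
    entry <- comb(entry_m, entry_i, entry_b)
    if (mode == "forward") {
      Dcur <- d_chain_fwd(entry)
      end_best <- lse2(end_best, lse2(Mcur[L], Dcur[L]))
    } else {
      dv <- d_chain_vit(entry)
      Dcur <- dv$val
      ptrM[i, ] <- max.col(cbind(fromM, fromI, fromD), ties.method = "first")
      if (L > 1) {
        ptrI[i, seq_len(nI)] <- max.col(cbind(sub(Mprev) + lt$MI,
                                              Iprev + lt$II,
                                              sub(Dprev) + lt$DI),
                                        ties.method = "first")
      }
      ptrDe[i + 1, ] <- max.col(cbind(entry_m, entry_i, entry_b),
                                ties.method = "first")
      ptrDc[i + 1, ] <- dv$from_entry
      Mmat[i + 1, ] <- Mcur; if (nI > 0) Imat[i + 1, seq_len(nI)] <- Icur
      Dmat[i + 1, ] <- Dcur
      cand <- max(Mcur[L], Dcur[L])
      if (cand > end_best) {
        end_best <- cand
        end_arg <- i
      }
    }
    Mprev <- Mcur; Iprev <- Icur; Dprev <- Dcur
  }

  if (mode == "forward") return(end_best)
  list(score = end_best, end_i = end_arg,
       Mmat = Mmat, Imat = Imat, Dmat = Dmat,
       ptrM = ptrM, ptrI = ptrI, ptrDe = ptrDe, ptrDc = ptrDc)
}

#' Forward bit score of a protein against a profile
#'
#' log2 of the summed odds, over all glocal alignments, of the joint model
#' probability versus the background probability of the aligned residues.
#' Always at least the Viterbi bit score of the same pair.
#'
#' @param hmm A [build_profile()] model.
#' @param protein Protein string; non-standard residues score as background.
#' @return Bit score (finite scalar).
#' @export
score_forward <- function(hmm, protein) {
  stopifnot(inherits(hmm, "ProfileHmm"))
  profile_dp(hmm, protein, "forward")
}

#' Viterbi alignment of a protein to a profile
#'
#' Best single state path and its bit score. Ties break toward Match over
#' Insert over Delete, and toward entering a delete chain over extending
#' one, so the result is deterministic. The `aligned_row` has one column per
#' match state (residue or `-`); insertions are dropped from the row and
#' retained in `path`.
#'
#' @param hmm A [build_profile()] model.
#' @param protein Protein string.
#' @param seq_id Identifier stored in the hit.
#' @return List of class `HmmHit`: `seq_id`, `bit_score`, `path` (character
#'   vector of state labels), `aligned_row`.
#' @export
align_viterbi <- function(hmm, protein, seq_id = "seq") {
  stopifnot(inherits(hmm, "ProfileHmm"))
  dp <- profile_dp(hmm, protein, "viterbi")
  L <- hmm$L
  res <- strsplit(toupper(protein), "")[[1]]
  # choose final state at the recorded end column (M preferred over D)
  i <- dp$end_i
  state <- if (i > 0 && dp$Mmat[i + 1, L] >= dp$Dmat[i + 1, L]) "M" else "D"
  j <- L
  path <- character(0)
  aligned <- rep("-", L)
  repeat {
    if (state == "M") {
      path <- c(paste0("M", j), path)
      aligned[j] <- res[i]
      p <- dp$ptrM[i, j]
      i <- i - 1L
      if (j == 1L) break                       # only B feeds M_1
      state <- c("M", "I", "D")[p]
      j <- j - 1L
    } else if (state == "I") {
      # I_j emits residue i and connects back to node-j states at i-1
      path <- c(paste0("I", j), path)
      p <- dp$ptrI[i, j]
      i <- i - 1L
      state <- c("M", "I", "D")[p]
    } else { # D_j: silent, same column i
      path <- c(paste0("D", j), path)
      if (dp$ptrDc[i + 1, j]) {
        p <- dp$ptrDe[i + 1, j]
        if (p == 3L) break                     # entered from B
        state <- c("M", "I")[p]
        j <- j - 1L
      } else {
        j <- j - 1L                            # extend the delete chain
      }
    }
  }
  structure(list(seq_id = seq_id, bit_score = dp$score, path = path,
                 aligned_row = paste(aligned, collapse = "")),
            class = "HmmHit")
}

#' Calibrate a bit-score acceptance threshold
#'
#' Scores `n_random` background-composed random sequences and returns the
#' `1 - alpha` quantile of their forward bits. Reproducible for a fixed
#' seed; the caller's RNG state is untouched.
#'
#' @param hmm A [build_profile()] model.
#' @param n_random Number of random sequences (>= 100; `alpha = 1` returns
#'   their minimum score).
#' @param length_dist Integer vector of lengths to sample from (default
#'   60:200, the candidate ORF band).
#' @param seed RNG seed for the calibration stream.
#' @param alpha Upper tail mass (default 1e-3).
#' @return Bit-score threshold (scalar).
#' @export
calibrate_threshold <- function(hmm, n_random = 500L, length_dist = 60:200,
                                seed = 1L, alpha = 1e-3) {
  stopifnot(n_random >= 100)
  rng <- local_rng(seed)
  lens <- sample(length_dist, n_random, replace = TRUE)
  probs <- hmm$background
  scores <- vapply(lens, function(l) {
    s <- paste(sample(AA20, l, replace = TRUE, prob = probs), collapse = "")
    score_forward(hmm, s)
  }, 0)
  rng$restore()
  stats::quantile(scores, probs = 1 - alpha, names = FALSE, type = 7)
}

# Scoped RNG: seed a stream and hand back a restore function so library code
# never perturbs the caller's .Random.seed.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

## ---- HMMER3 export ---------------------------------------------------------

#' Export a model in HMMER3 ASCII profile format
#'
#' Best-effort interoperability sink: emissions and the seven canonical
#' per-node transitions are written (the model's rare I->D and D->I mass is
#' renormalised away, as the HMMER3 architecture has no such edges).
#'
#' @param hmm A [build_profile()] model.
#' @param path Output file.
#' @param name Model name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_hmmer3 <- function(hmm, path, name = "cdzminer_profile") {
  L <- hmm$L
  fmt <- function(p) {
    ifelse(p > 0, sprintf("%8.5f", -log(p)), "       *")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("HMMER3/f [cdzminer]",
               paste0("NAME  ", name),
               paste0("LENG  ", L),
               "ALPH  amino"), con)
  writeLines(paste0("HMM          ",
                    paste(sprintf("%7s", AA20), collapse = " ")), con)
  writeLines(paste("           ", "m->m", "m->i", "m->d", "i->m", "i->i",
                   "d->m", "d->d", sep = "     "), con)
  ins <- paste(fmt(hmm$insert_emit), collapse = " ")
  # node 0: begin transitions
  writeLines(paste0("  COMPO ", paste(fmt(hmm$background), collapse = " ")), con)
  writeLines(paste0("        ", ins), con)
  writeLines(paste0("        ",
                    paste(fmt(c(hmm$trans$BM, 1e-9, hmm$trans$BD, 0.5, 0.5, 1, 0)),
                          collapse = " ")), con)
  for (j in seq_len(L)) {
    writeLines(sprintf("%7d %s", j,
                       paste(fmt(hmm$match_emit[j, ]), collapse = " ")), con)
    writeLines(paste0("        ", ins), con)
    if (j < L) {
      im <- hmm$trans$IM[j] / (hmm$trans$IM[j] + hmm$trans$II[j])
      dm <- hmm$trans$DM[j] / (hmm$trans$DM[j] + hmm$trans$DD[j])
      tr <- c(hmm$trans$MM[j], hmm$trans$MI[j], hmm$trans$MD[j],
              im, 1 - im, dm, 1 - dm)
    } else {
      tr <- c(1, 0, 0, 1, 0, 1, 0)
    }
    writeLines(paste0("        ", paste(fmt(tr), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
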