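# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately use naive loop-based logic, never the package's
# vectorised implementations.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len, pool = AA20_T) {
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

random_dna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## ---- ORF oracle (naive nested loops, one strand) ----------------------------

oracle_orfs_plus <- function(s, min_res, max_res,
                             start_codons = c("ATG", "GTG", "TTG"),
                             all_starts = TRUE) {
  code <- Biostrings::getGeneticCode("11")
  stops <- names(code)[code == "*"]
  n <- nchar(s)
  rows <- list()
  for (f in 0:2) {
    pos <- seq(f + 1L, n, by = 3L)
    pos <- pos[pos + 2L <= n]
    if (length(pos) < 2) next
    cods <- substring(s, pos, pos + 2L)
    for (a in seq_along(cods)) {
      if (!(cods[a] %in% start_codons)) next
      b <- a + 1L
      while (b <= length(cods) && !(cods[b] %in% stops)) b <- b + 1L
      if (b > length(cods)) next
      plen <- b - a
      if (plen < min_res || plen > max_res) next
      prot <- paste(vapply(cods[a:(b - 1)], function(cd) {
        aa <- code[[cd]]
        if (is.null(aa) || is.na(aa)) "X" else aa
      }, ""), collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        start = pos[a] - 1L, end = pos[b] + 2L, frame = f,
        protein = prot, start_codon = cods[a], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(start = integer(), end = integer(), frame = integer(),
               protein = character(), start_codon = character(),
               stringsAsFactors = FALSE)
  }
  if (!all_starts && nrow(out) > 1) {
    # longest per stop = smallest start per end
    out <- out[order(out$end, out$start), , drop = FALSE]
    out <- out[!duplicated(paste(out$frame, out$end)), , drop = FALSE]
  }
  out
}

oracle_orfs <- function(s, min_res, max_res, all_starts = TRUE) {
  rc <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  n <- nchar(s)
  fwd <- oracle_orfs_plus(s, min_res, max_res, all_starts = all_starts)
  if (nrow(fwd)) fwd$strand <- "+"
  rev <- oracle_orfs_plus(rc(s), min_res, max_res, all_starts = all_starts)
  if (nrow(rev)) {
    tmp <- rev$start
    rev$start <- n - rev$end
    rev$end <- n - tmp
    rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  out[order(out$start, out$end, match(out$strand, c("+", "-"))), , drop = FALSE]
}

## ---- classifier oracles ------------------------------------------------------

oracle_leader <- function(protein, min_leader = 10L, max_leader = 35L) {
  # regex-based: positions of G[GAS] dipeptides (second residue position)
  m <- gregexpr("(?=G[GAS])", toupper(protein), perl = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  ends <- as.integer(m) + 1L
  ok <- ends[ends >= min_leader & ends <= max_leader]
  if (length(ok) == 0) NULL else ok[1]
}

# maximal period-4 anchor runs: a run is reported iff it has >= min_anchors
# anchors and cannot be extended one period to the left
oracle_zippers <- function(mature, min_anchors = 3L) {
  res <- strsplit(toupper(mature), "")[[1]]
  n <- length(res)
  forb <- c("D", "E", "K", "R", "P", "C")
  link_ok <- function(p) {
    # anchor at p and p+4 with clean intervening residues
    p + 4L <= n && res[p] == "G" && res[p + 4L] == "G" &&
      !any(res[(p + 1L):(p + 3L)] %in% forb)
  }
  out <- list()
  for (p in seq_len(n)) {
    if (res[p] != "G") next
    if (p - 4L >= 1L && link_ok(p - 4L)) next   # extendable left
    last <- p
    while (link_ok(last)) last <- last + 4L
    k <- (last - p) / 4L + 1L
    if (k >= min_anchors) {
      out[[length(out) + 1L]] <- c(first = p - 1L, last = last - 1L,
                                   n_anchors = k)
    }
  }
  if (length(out) == 0) {
    return(data.frame(first = integer(), last = integer(),
                      n_anchors = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

oracle_cterm <- function(mature, last_anchor0, max_tail = 20L,
                         min_frac = 0.4) {
  res <- strsplit(toupper(mature), "")[[1]]
  tail_res <- res[seq_len(length(res)) > last_anchor0 + 1L]
  if (length(tail_res) == 0) return(TRUE)
  if (length(tail_res) > max_tail) return(FALSE)
  good <- c("D", "E", "K", "R", "S", "T", "N", "Q", "H", "Y")
  sum(tail_res %in% good) / length(tail_res) >= min_frac
}

oracle_polar_span <- function(mature, tail_start = NULL, window = 6L,
                              max_cp = 4L) {
  res <- strsplit(toupper(mature), "")[[1]]
  if (!is.null(tail_start)) res <- res[seq_len(min(tail_start, length(res)))]
  if (length(res) == 0) return(TRUE)
  cp <- c("D", "E", "K", "R", "S", "T", "N", "Q", "H", "Y")
  if (length(res) <= window) return(sum(res %in% cp) <= max_cp)
  for (i in 1:(length(res) - window + 1L)) {
    if (sum(res[i:(i + window - 1L)] %in% cp) > max_cp) return(FALSE)
  }
  TRUE
}

## ---- consensus oracle --------------------------------------------------------

oracle_consensus <- function(mat, k_min) {
  # mat: logical matrix, tracks x residues
  support <- integer(ncol(mat))
  for (j in seq_len(ncol(mat))) support[j] <- sum(mat[, j])
  flag <- support >= k_min
  iv <- list()
  j <- 1L
  while (j <= length(flag)) {
    if (flag[j]) {
      k <- j
      while (k < length(flag) && flag[k + 1L]) k <- k + 1L
      iv[[length(iv) + 1L]] <- c(start = j - 1L, end = k)
      j <- k + 1L
    } else j <- j + 1L
  }
  list(support = support,
       intervals = if (length(iv)) as.data.frame(do.call(rbind, iv)) else {
         data.frame(start = integer(), end = integer())
       })
}

## ---- profile HMM path-enumeration oracle ------------------------------------

# Enumerate every glocal path (N-flank offset + state walk B -> ... -> M_L/D_L)
# and return log2 of the summed and of the maximal odds. Matches the model's
# path space: flank residues are free, insert emissions are background
# (odds 1), and each (offset, walk) pair is one path.
oracle_hmm_scores <- function(hmm, protein) {
  res <- strsplit(toupper(protein), "")[[1]]
  n <- length(res)
  L <- hmm$L
  tr <- hmm$trans
  odds <- function(j, i) {
    a <- match(res[i], hmm$alphabet)
    if (is.na(a)) 1 else hmm$match_emit[j, a] / hmm$background[a]
  }
  terms <- numeric(0)
  walk <- function(type, j, i, w) {
    # arrived in state (type, j) having consumed residues up to i, odds w
    if (j == L && type %in% c("M", "D")) {
      terms <<- c(terms, w)
      return(invisible())
    }
    if (type == "M" || type == "I") {
      tmm <- if (type == "M") tr$MM[j] else tr$IM[j]
      tmi <- if (type == "M") tr$MI[j] else tr$II[j]
      tmd <- if (type == "M") tr$MD[j] else tr$ID[j]
      if (i < n) walk("M", j + 1L, i + 1L, w * tmm * odds(j + 1L, i + 1L))
      if (i < n) walk("I", j, i + 1L, w * tmi)
      walk("D", j + 1L, i, w * tmd)
    } else { # D
      if (i < n) walk("M", j + 1L, i + 1L, w * tr$DM[j] * odds(j + 1L, i + 1L))
      if (i < n) walk("I", j, i + 1L, w * tr$DI[j])
      walk("D", j + 1L, i, w * tr$DD[j])
    }
  }
  for (i0 in 0:n) {
    if (i0 < n) walk("M", 1L, i0 + 1L, tr$BM * odds(1L, i0 + 1L))
    walk("D", 1L, i0, tr$BD)
  }
  list(forward = log2(sum(terms)), viterbi = log2(max(terms)))
}

## ---- misc --------------------------------------------------------------------

random_small_msa <- function(nrow_ = 3L, ncol_ = 3L, gap_p = 0.2) {
  rows <- vapply(seq_len(nrow_), function(i) {
    ch <- sample(AA20_T, ncol_, replace = TRUE)
    gap <- runif(ncol_) < gap_p
    ch[gap] <- "-"
    paste(ch, collapse = "")
  }, "")
  # ensure at least one match column (not all-gap heavy)
  rows[1] <- paste(sample(AA20_T, ncol_, replace = TRUE), collapse = "")
  msa(paste0("s", seq_len(nrow_)), rows)
}
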