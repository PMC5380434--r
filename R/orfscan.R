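# Six-frame ORF enumeration within anchor windows. "All possible ORFs" is
# read as every start->stop pair, so nested starts sharing a stop are
# reported individually; longest-per-stop is available via all_starts = FALSE.

#' ORF enumeration parameters
#'
#' @param min_res,max_res Protein length bounds in residues (default 60-200,
#'   the small-protein band scanned around T1SS loci).
#' @param start_codons Start codon set; default the bacterial table-11 set.
#' @param all_starts Report every start sharing a stop (`TRUE`) or only the
#'   longest ORF per (strand, stop) (`FALSE`).
#' @param table Genetic code id passed to [Biostrings::getGeneticCode()]
#'   (default "11", bacterial).
#' @return List of class `OrfParams`.
#' @export
orf_params <- function(min_res = 60L, max_res = 200L,
                       start_codons = c("ATG", "GTG", "TTG"),
                       all_starts = TRUE, table = "11") {
  stopifnot(min_res > 0, min_res <= max_res, length(start_codons) > 0)
  structure(list(min_res = as.integer(min_res), max_res = as.integer(max_res),
                 start_codons = toupper(start_codons),
                 all_starts = isTRUE(all_starts), table = table),
            class = "OrfParams")
}

genetic_code_map <- function(table = "11") {
  Biostrings::getGeneticCode(table)
}

#' Translate a DNA string
#'
#' Codons containing any non-ACGT base translate to `X`; such codons never
#' act as stop codons.
#'
#' @param dna In-frame DNA (length a multiple of 3 is not required; trailing
#'   bases are dropped).
#' @param table Genetic code id.
#' @return Protein string (stops as `*`).
#' @export
translate_dna <- function(dna, table = "11") {
  code <- genetic_code_map(table)
  n <- nchar(dna) %/% 3L
  if (n == 0) return("")
  starts <- seq(1L, by = 3L, length.out = n)
  codons <- substring(toupper(dna), starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# ORFs on the plus strand of `s`; returns codon-indexed calls.
orfs_one_strand <- function(s, params) {
  code <- genetic_code_map(params$table)
  stop_codons <- names(code)[code == "*"]
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2) next
    cs <- seq(f + 1L, by = 3L, length.out = ncod)
    codons <- substring(s, cs, cs + 2L)
    stops <- which(codons %in% stop_codons)
    if (length(stops) == 0) next
    starts <- which(codons %in% params$start_codons)
    if (length(starts) == 0) next
    # first stop strictly after each start
    nxt <- stops[findInterval(starts, stops) + 1L]
    keep <- !is.na(nxt)
    starts <- starts[keep]; nxt <- nxt[keep]
    plen <- nxt - starts
    keep <- plen >= params$min_res & plen <= params$max_res
    starts <- starts[keep]; nxt <- nxt[keep]
    if (length(starts) == 0) next
    if (!params$all_starts) {
      # longest per stop = smallest start index per stop
      first <- !duplicated(nxt)  # starts ascending, nxt non-decreasing
      ord <- order(nxt, starts)
      starts <- starts[ord]; nxt <- nxt[ord]
      first <- !duplicated(nxt)
      starts <- starts[first]; nxt <- nxt[first]
    }
    prot <- vapply(seq_along(starts), function(i) {
      translate_dna(substr(s, cs[starts[i]], cs[nxt[i]] - 1L), params$table)
    }, "")
    out[[length(out) + 1L]] <- data.frame(
      nt_start = cs[starts] - 1L,          # 0-based
      nt_end = cs[nxt] + 2L,               # includes stop codon
      frame = f,
      protein = prot,
      start_codon = codons[starts],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(nt_start = integer(), nt_end = integer(),
                      frame = integer(), protein = character(),
                      start_codon = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Enumerate candidate ORFs in a window
#'
#' Every start codon whose in-frame stop lies inside the window and whose
#' translated length (excluding the stop) falls in
#' `[min_res, max_res]` yields one call, on both strands. ORFs must be fully
#' contained in the window. The reported nucleotide interval includes the
#' stop codon; coordinates are 0-based half-open on the plus strand of the
#' contig.
#'
#' @param window_seq Plus-strand window sequence.
#' @param params [orf_params()].
#' @param contig_id Contig the window came from.
#' @param offset 0-based contig position of the first window base.
#' @return Data frame of ORF calls ordered by contig position then strand
#'   (`+` before `-`): `orf_id`, `contig_id`, `start`, `end`, `strand`,
#'   `frame`, `protein`, `start_codon`.
#' @export
enumerate_orfs <- function(window_seq, params = orf_params(),
                           contig_id = "window", offset = 0L) {
  window_seq <- toupper(window_seq)
  stopifnot(nchar(window_seq) >= 3)
  n <- nchar(window_seq)
  fwd <- orfs_one_strand(window_seq, params)
  if (nrow(fwd)) {
    fwd$strand <- "+"
    fwd$start <- fwd$nt_start
    fwd$end <- fwd$nt_end
  }
  rev <- orfs_one_strand(revcomp(window_seq), params)
  if (nrow(rev)) {
    rev$strand <- "-"
    # mirror coordinates back to the plus strand
    rev$start <- n - rev$nt_end
    rev$end <- n - rev$nt_start
  }
  both <- rbind(fwd, rev)
  if (nrow(both) == 0) {
    return(data.frame(orf_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      frame = integer(), protein = character(),
                      start_codon = character(), stringsAsFactors = FALSE))
  }
  both$start <- both$start + as.integer(offset)
  both$end <- both$end + as.integer(offset)
  both <- both[order(both$start, both$end, match(both$strand, c("+", "-"))), ]
  both$contig_id <- contig_id
  both$orf_id <- sprintf("%s:%d-%d:%s", contig_id, both$start, both$end,
                         both$strand)
  rownames(both) <- NULL
  both[, c("orf_id", "contig_id", "start", "end", "strand", "frame",
           "protein", "start_codon")]
}

#' Export ORF proteins as FASTA
#'
#' Headers encode `contig:start-end:strand`.
#'
#' @param orfs Data frame from [enumerate_orfs()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  seqs <- orfs$protein
  names(seqs) <- orfs$orf_id
  write_fasta(seqs, path)
}
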