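# Genome and alignment I/O. All internal coordinates are 0-based half-open
# [start, end); GenBank and GFF3 (1-based inclusive) are converted at the
# boundary, BED is already 0-based half-open. Contigs are treated as linear.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Construct a genome record
#'
#' A `GenomeRecord` bundles one contig sequence with its feature table. It is
#' the container every other module consumes.
#'
#' @param id Contig identifier (unique within a collection).
#' @param sequence DNA string over the IUPAC alphabet; stored uppercased.
#' @param description Free-text description.
#' @param features Feature table as returned by [empty_features()].
#' @return An object of class `GenomeRecord`.
#' @export
genome_record <- function(id, sequence, description = "",
                          features = empty_features()) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("GenomeRecord '", id, "': sequence is empty")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), IUPAC_DNA)
  if (length(bad) > 0) {
    stop("GenomeRecord '", id, "': non-IUPAC characters: ",
         paste(bad, collapse = ", "))
  }
  stopifnot(is.data.frame(features))
  structure(list(id = id, description = description,
                 sequence = sequence, features = features),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord %s: %d nt, %d features\n",
              x$id, nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

#' Empty feature table
#'
#' Features use 0-based half-open nucleotide intervals. `kind` is one of
#' `CDS`, `anchor`, `toxin_candidate`, `other`.
#'
#' @return Zero-row data frame with the feature columns.
#' @export
empty_features <- function() {
  data.frame(id = character(), kind = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             product = character(), stringsAsFactors = FALSE)
}

#' Build a feature row
#'
#' @param id,kind,contig_id,strand,product Feature annotation fields.
#' @param start,end 0-based half-open interval in nucleotides.
#' @return One-row feature data frame.
#' @export
feature <- function(id, kind, contig_id, start, end, strand = "+",
                    product = "") {
  stopifnot(start >= 0, start < end, strand %in% c("+", "-"))
  data.frame(id = id, kind = kind, contig_id = contig_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand, product = product, stringsAsFactors = FALSE)
}

#' Read genome FASTA
#'
#' One `GenomeRecord` per header; sequence lines are concatenated and
#' uppercased. Duplicate ids and non-IUPAC characters are errors (the
#' offending line is named).
#'
#' @param path FASTA file.
#' @return List of [genome_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0) stop("empty input: ", path)
  seqs <- toupper(as.character(set))
  ok <- !grepl(paste0("[^", paste(IUPAC_DNA, collapse = ""), "]"), seqs)
  if (any(!ok)) {
    # locate the first offending line for the error message
    lines <- readLines(path, warn = FALSE)
    pat <- paste0("[^", paste(IUPAC_DNA, collapse = ""), "acgtryswkmbdhvn]")
    bad_line <- which(!startsWith(lines, ">") & grepl(pat, toupper(lines)))[1]
    stop("non-IUPAC characters in ", path, " at line ",
         ifelse(is.na(bad_line), "?", bad_line))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  desc <- sub("^\\S+\\s*", "", names(set))
  mapply(function(i, s, d) genome_record(i, s, d),
         ids, seqs, desc, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector (DNA or protein).
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) == 0 || !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' Involution over IUPAC DNA: `revcomp(revcomp(x)) == x`.
#'
#' @param dna DNA string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Extract the flanking window around an anchor
#'
#' The window `[anchor$start - flank_nt, anchor$end + flank_nt)` is clipped to
#' the contig bounds; partial windows at contig edges are kept.
#'
#' @param genome A [genome_record()].
#' @param anchor One-row feature data frame (or list) with `contig_id`,
#'   `start`, `end` and optionally `id`.
#' @param flank_nt Flank size in nucleotides (default 10000, the 10 kb
#'   context used for T1SS-anchored searches).
#' @return List with `window` (contig_id, start, end, anchor_ref) and `seq`
#'   (the plus-strand subsequence).
#' @export
extract_window <- function(genome, anchor, flank_nt = 10000L) {
  stopifnot(flank_nt > 0)
  if (!identical(as.character(anchor$contig_id), genome$id)) {
    stop("anchor contig '", anchor$contig_id, "' does not match genome '",
         genome$id, "'")
  }
  len <- nchar(genome$sequence)
  if (anchor$start < 0 || anchor$end > len) {
    stop("anchor off contig: [", anchor$start, ",", anchor$end,
         ") vs length ", len)
  }
  s <- max(0L, as.integer(anchor$start) - as.integer(flank_nt))
  e <- min(len, as.integer(anchor$end) + as.integer(flank_nt))
  list(window = list(contig_id = genome$id, start = s, end = e,
                     anchor_ref = if (!is.null(anchor$id)) as.character(anchor$id) else NA_character_),
       seq = substr(genome$sequence, s + 1L, e))
}

## ---- GenBank flat files ----------------------------------------------------
## Minimal reader/writer for the subset emitted by the synthetic generator:
## LOCUS/DEFINITION, FEATURES with source and CDS (complement() and join()
## locations), ORIGIN. No installed R package parses GenBank flat files from
## disk, hence the hand-rolled boundary code.

parse_gb_location <- function(loc) {
  joined <- grepl("^join\\(", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  joined <- joined || grepl("^join\\(", loc)
  loc <- gsub("join\\(|\\)", "", loc)
  nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  if (length(nums) < 2) stop("unparseable GenBank location: ", loc)
  # spanning interval; GenBank 1-based inclusive -> 0-based half-open
  list(start = min(nums) - 1L, end = max(nums), strand = strand,
       joined = joined)
}

#' Read a GenBank flat file
#'
#' CDS features are captured with coordinates converted from 1-based
#' inclusive to internal 0-based half-open; `complement()` sets the strand.
#' Multi-exon `join()` CDS are recorded as a single spanning interval and
#' flagged with a warning.
#'
#' @param path GenBank flat file (one or more LOCUS entries).
#' @return List of [genome_record()] objects.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty input: ", path)
  recs <- list()
  entry_starts <- which(startsWith(lines, "LOCUS"))
  if (length(entry_starts) == 0) stop("no LOCUS entry in ", path)
  entry_ends <- c(entry_starts[-1] - 1L, length(lines))
  for (k in seq_along(entry_starts)) {
    chunk <- lines[entry_starts[k]:entry_ends[k]]
    id <- strsplit(trimws(sub("^LOCUS", "", chunk[1])), "\\s+")[[1]][1]
    def_i <- grep("^DEFINITION", chunk)
    description <- if (length(def_i)) trimws(sub("^DEFINITION", "", chunk[def_i[1]])) else ""
    feats <- empty_features()
    fi <- grep("^FEATURES", chunk)
    oi <- grep("^ORIGIN", chunk)
    if (length(oi) == 0) stop("GenBank entry ", id, " has no ORIGIN")
    if (length(fi)) {
      fl <- chunk[(fi + 1):(oi - 1)]
      key_lines <- grep("^     \\S", fl)
      for (j in seq_along(key_lines)) {
        from <- key_lines[j]
        to <- if (j < length(key_lines)) key_lines[j + 1] - 1L else length(fl)
        block <- fl[from:to]
        key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
        if (key != "CDS") next
        loc <- sub("^\\s*CDS\\s+", "", block[1])
        # location may continue onto following lines until a qualifier
        extra <- block[-1]
        qual_start <- grep("^\\s*/", extra)
        if (length(qual_start) == 0) qual_start <- length(extra) + 1L
        if (qual_start[1] > 1) {
          loc <- paste0(loc, paste(trimws(extra[seq_len(qual_start[1] - 1)]),
                                   collapse = ""))
        }
        pl <- parse_gb_location(loc)
        if (pl$joined) {
          warning("join() CDS in ", id, " recorded as spanning interval")
        }
        quals <- trimws(extra[grepl("^\\s*/", extra)])
        get_q <- function(name) {
          m <- grep(paste0("^/", name, "="), quals, value = TRUE)
          if (length(m) == 0) return("")
          gsub("\"", "", sub(paste0("^/", name, "="), "", m[1]))
        }
        lt <- get_q("locus_tag")
        feats <- rbind(feats, feature(
          id = if (nzchar(lt)) lt else paste0(id, "_cds", nrow(feats) + 1L),
          kind = "CDS", contig_id = id, start = pl$start, end = pl$end,
          strand = pl$strand, product = get_q("product")))
      }
    }
    seq_lines <- chunk[(oi + 1):length(chunk)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    recs[[id]] <- genome_record(id, sequence, description, feats)
  }
  recs
}

#' Write a GenBank flat file
#'
#' Emits the minimal subset read back by [read_genbank()]: LOCUS, DEFINITION,
#' FEATURES (source plus CDS with locus_tag/product) and ORIGIN.
#'
#' @param genome A [genome_record()]; its `CDS` and `anchor` features are
#'   written as CDS entries.
#' @param path Output file; appends when `append = TRUE` so multi-record
#'   files can be built contig by contig.
#' @param append Append to an existing file.
#' @param date Fixed date string for the LOCUS line, so output is
#'   byte-deterministic.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path, append = FALSE, date = "01-JAN-2026") {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  len <- nchar(genome$sequence)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT %s",
                     genome$id, len, date), con)
  writeLines(paste0("DEFINITION  ", genome$description), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  f <- genome$features
  f <- f[f$kind %in% c("CDS", "anchor"), , drop = FALSE]
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", f$id[i]), con)
      if (nzchar(f$product[i])) {
        writeLines(sprintf("                     /product=\"%s\"", f$product[i]), con)
      }
    }
  }
  writeLines("ORIGIN", con)
  s <- genome$sequence
  pos <- seq(1L, len, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, len))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tolower(blocks), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

## ---- GFF3 and BED ----------------------------------------------------------

gff3_escape <- function(x) gsub("([;=,&\t])", "", x)

#' Write discovered clusters as GFF3
#'
#' One feature per anchor gene and per toxin candidate, with the cluster id in
#' the attributes column. Internal 0-based half-open intervals become GFF3
#' 1-based inclusive.
#'
#' @param clusters List of cluster calls from [assemble_clusters()], or an
#'   empty list (a valid header-only file is written).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(clusters, path) {
  lines <- "##gff-version 3"
  for (cl in clusters) {
    cid <- cl$cluster_id
    g <- cl$anchor$genes
    for (i in seq_len(nrow(g))) {
      lines <- c(lines, paste(
        g$contig_id[i], "cdzminer", "CDS", g$start[i] + 1L, g$end[i],
        ".", g$strand[i], ".",
        sprintf("ID=%s;cluster_id=%s;kind=anchor_gene",
                gff3_escape(g$id[i]), cid), sep = "\t"))
    }
    tx <- cl$toxins
    for (i in seq_len(nrow(tx))) {
      lines <- c(lines, paste(
        tx$contig_id[i], "cdzminer", "CDS", tx$start[i] + 1L, tx$end[i],
        ".", tx$strand[i], ".",
        sprintf("ID=%s;cluster_id=%s;kind=toxin_candidate",
                gff3_escape(tx$orf_id[i]), cid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a cdzminer GFF3
#'
#' Round-trip reader for [write_gff3()] output; coordinates return to
#' internal 0-based half-open.
#'
#' @param path GFF3 file.
#' @return Data frame with contig_id, start, end, strand, id, cluster_id, kind.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(), id = character(),
                      cluster_id = character(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  attr_get <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, "=[^;]*"), a))
    if (length(m) == 0) NA_character_ else sub(paste0(key, "="), "", m)
  }
  data.frame(
    contig_id = vapply(parts, `[[`, "", 1),
    start = vapply(parts, function(p) as.integer(p[[4]]) - 1L, 1L),
    end = vapply(parts, function(p) as.integer(p[[5]]), 1L),
    strand = vapply(parts, `[[`, "", 7),
    id = vapply(parts, function(p) attr_get(p[[9]], "ID"), ""),
    cluster_id = vapply(parts, function(p) attr_get(p[[9]], "cluster_id"), ""),
    kind = vapply(parts, function(p) attr_get(p[[9]], "kind"), ""),
    stringsAsFactors = FALSE)
}

#' Read user-supplied anchor intervals (BED)
#'
#' BED is 0-based half-open, matching the internal convention; no conversion
#' is applied. Columns beyond the sixth are ignored.
#'
#' @param path BED3+ file.
#' @return Feature data frame with `kind = "anchor"`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # BED rows may carry 3-6 columns; fill = TRUE tolerates the ragged shape
  tab <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3 || anyNA(tab[[2]]) || anyNA(tab[[3]])) {
    stop("BED file needs at least 3 columns: ", path)
  }
  n <- nrow(tab)
  ids <- if (ncol(tab) >= 4) as.character(tab[[4]]) else rep("", n)
  ids[is.na(ids) | ids == ""] <- paste0("anchor", seq_len(n))[is.na(ids) | ids == ""]
  strands <- if (ncol(tab) >= 6) as.character(tab[[6]]) else rep("+", n)
  strands[is.na(strands) | !strands %in% c("+", "-")] <- "+"
  feats <- feature(id = ids, kind = "anchor",
                   contig_id = as.character(tab[[1]]),
                   start = tab[[2]], end = tab[[3]], strand = strands)
  feats
}
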