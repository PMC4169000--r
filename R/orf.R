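# standard genetic code, NCBI table 1, codon order T/C/A/G
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- apply(expand.grid(b3 = bases, b2 = bases, b1 = bases)[, 3:1],
                  1, paste0, collapse = "")
  aa <- strsplit(paste0("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
                        "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

.stop_codons <- c("TAA", "TAG", "TGA")

.check_nt <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) == 0) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) {
    stop("illegal characters in sequence (alphabet is ACGTN)")
  }
  seq
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character scalar over ACGTN (case-insensitive).
#' @return Reverse complement, upper case.
#' @export
reverse_complement <- function(seq) {
  seq <- .check_nt(seq)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]),
        collapse = "")
}

#' Translate a nucleotide sequence in a given frame
#'
#' Standard-code translation of the complete codons starting at
#' \code{offset}; stop codons render as \code{"*"} and any codon
#' containing N (or otherwise unknown) as \code{"X"}.
#'
#' @param seq Nucleotide string over ACGTN.
#' @param offset Frame offset in \{0, 1, 2\}.
#' @return Amino-acid string (possibly empty).
#' @export
translate <- function(seq, offset = 0) {
  stopifnot(offset %in% 0:2)
  seq <- .check_nt(seq)
  n_codons <- (nchar(seq) - offset) %/% 3
  if (n_codons <= 0) return("")
  starts <- offset + 1 + 3 * (seq_len(n_codons) - 1)
  codons <- substring(seq, starts, starts + 2)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' ORF search policy
#'
#' @param allow_partial Report 5'- and/or 3'-partial ORFs (default TRUE):
#'   a frame-start..stop stretch with no upstream stop needs no ATG, and a
#'   trailing ATG..sequence-end stretch needs no stop. With
#'   \code{allow_partial = FALSE} only complete ATG..stop ORFs are
#'   reported.
#' @param min_nt Minimum ORF length in nucleotides (multiple of 3;
#'   default 3). For transcript annotation a noise filter of 150 nt
#'   (50 aa) is a reasonable choice.
#' @return A policy list.
#' @export
orf_policy <- function(allow_partial = TRUE, min_nt = 3) {
  stopifnot(min_nt >= 3, min_nt %% 3 == 0)
  list(allow_partial = isTRUE(allow_partial), min_nt = as.integer(min_nt))
}

# maximal ORFs of one frame on one strand; codon-index arithmetic only.
# Segments of the frame are delimited by stop codons. A segment preceded
# by a stop must start at an ATG; the frame-leading segment may start at
# the frame edge when partials are allowed. Every ORF must encode at
# least one amino acid.
.frame_orfs <- function(codons, frame, strand, seq_len_nt, policy) {
  n <- length(codons)
  if (n == 0) return(NULL)
  is_stop <- codons %in% .stop_codons
  is_start <- codons == "ATG"
  stops <- which(is_stop)
  seg_lo <- c(1L, stops + 1L)
  seg_stop <- c(stops, NA_integer_)      # NA marks the open trailing segment
  out <- vector("list", length(seg_lo))
  for (s in seq_along(seg_lo)) {
    lo <- seg_lo[s]
    stop_at <- seg_stop[s]
    bounded_right <- !is.na(stop_at)
    hi <- if (bounded_right) stop_at else n
    if (lo > hi) next
    left_open <- (lo == 1L)              # frame edge, not a previous stop
    coding_hi <- if (bounded_right) hi - 1L else hi
    if (coding_hi < lo) next             # segment is a bare stop codon
    if (left_open && policy$allow_partial) {
      start <- lo
    } else {
      hits <- which(is_start[lo:coding_hi])
      if (!length(hits)) next
      start <- lo + hits[1] - 1L
    }
    if (!bounded_right && !policy$allow_partial) next
    nt_length <- (hi - start + 1L) * 3L
    if (nt_length < policy$min_nt) next
    complete5 <- is_start[start]
    # coordinates on the scanned strand, 0-based half-open
    s0 <- frame + (start - 1L) * 3L
    e0 <- frame + hi * 3L
    if (strand == "-") {
      tmp <- seq_len_nt - e0
      e0 <- seq_len_nt - s0
      s0 <- tmp
    }
    pep_codons <- codons[start:coding_hi]
    aa <- .codon_table[pep_codons]
    aa[is.na(aa)] <- "X"
    out[[s]] <- data.frame(
      strand = strand, frame = frame, start = s0, end = e0,
      nt_length = nt_length, complete5 = complete5,
      complete3 = bounded_right,
      peptide = paste(aa, collapse = ""),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out)) do.call(rbind, out) else NULL
}

#' Find all maximal ORFs in the six reading frames
#'
#' Scans the three frames of both strands of an assembled transcript for
#' maximal open reading frames under the given policy: complete
#' (ATG..stop), 5'-partial (frame start..stop, no upstream stop),
#' 3'-partial (ATG..sequence end), and fully open frames when partials
#' are allowed. Codons containing N translate to X and never match a
#' start or stop. Coordinates are 0-based half-open on the forward
#' strand regardless of ORF strand.
#'
#' @param seq Nucleotide string over ACGTN, length >= 3.
#' @param policy An [orf_policy()].
#' @return Data.frame of ORF records (strand, frame, start, end,
#'   nt_length, complete5, complete3, peptide); zero rows when none.
#' @export
six_frame_orfs <- function(seq, policy = orf_policy()) {
  seq <- .check_nt(seq)
  L <- nchar(seq)
  if (L < 3) stop("sequence shorter than one codon")
  strands <- c("+" = seq, "-" = reverse_complement(seq))
  res <- list()
  for (strand in names(strands)) {
    s <- strands[[strand]]
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3
      if (n_codons == 0) next
      starts <- frame + 1 + 3 * (seq_len(n_codons) - 1)
      codons <- substring(s, starts, starts + 2)
      res[[length(res) + 1]] <- .frame_orfs(codons, frame, strand, L,
                                            policy)
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      nt_length = integer(), complete5 = logical(),
                      complete3 = logical(), peptide = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pick the best ORF of a transcript
#'
#' The longest ORF under the policy; ties broken by completeness
#' (complete over partial), then forward over reverse strand, then lower
#' frame, then smaller forward-strand start. Deterministic.
#'
#' @inheritParams six_frame_orfs
#' @return A one-row ORF record, or \code{NULL} when the sequence has no
#'   ORF under the policy.
#' @export
best_orf <- function(seq, policy = orf_policy()) {
  orfs <- six_frame_orfs(seq, policy)
  if (nrow(orfs) == 0) return(NULL)
  complete <- orfs$complete5 & orfs$complete3
  ord <- order(-orfs$nt_length, -complete,
               orfs$strand != "+", orfs$frame, orfs$start)
  orfs[ord[1], , drop = FALSE]
}

#' Trim the 5' UTR of a transcript at its best complete ORF
#'
#' Removes the sequence upstream of the start codon of the best
#' complete (ATG..stop) forward-strand ORF; transcripts without such an
#' ORF are returned unchanged.
#'
#' @inheritParams six_frame_orfs
#' @return The (possibly trimmed) nucleotide string.
#' @export
trim_utr5 <- function(seq, policy = orf_policy()) {
  seq <- .check_nt(seq)
  top <- best_orf(seq, orf_policy(allow_partial = FALSE,
                                  min_nt = policy$min_nt))
  if (is.null(top) || top$strand != "+") return(seq)
  substring(seq, top$start + 1, nchar(seq))
}

#' Predict the best ORF for every record of a FASTA file
#'
#' Reads a (wrapped or unwrapped, multi-record) FASTA file, predicts the
#' best ORF per sequence, and optionally writes the ORF table as TSV and
#' the peptides as FASTA.
#'
#' @param fasta_path Input FASTA of assembled transcripts.
#' @param policy An [orf_policy()].
#' @param tsv_out,peptides_out Optional output paths.
#' @return Data.frame of best-ORF records with a leading \code{seq_id}
#'   column (sequences without an ORF are omitted).
#' @export
predict_orfs <- function(fasta_path, policy = orf_policy(),
                         tsv_out = NULL, peptides_out = NULL) {
  seqs <- read_fasta(fasta_path)
  rows <- lapply(names(seqs), function(id) {
    top <- best_orf(seqs[[id]], policy)
    if (is.null(top)) return(NULL)
    cbind(data.frame(seq_id = id, stringsAsFactors = FALSE), top)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character())
  rownames(out) <- NULL
  if (!is.null(tsv_out)) {
    utils::write.table(out, tsv_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(peptides_out) && nrow(out)) {
    write_fasta(stats::setNames(out$peptide, out$seq_id), peptides_out)
  }
  out
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, seqtype = "DNA",
                             forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(recs, `[[`, "", 1)), names(recs))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector (nucleotide or peptide).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names(seqs), path)
  invisible(path)
}
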