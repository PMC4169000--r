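# Independent oracles used across the suite. Each re-derives the expected
# behaviour by a different route than the package implementation.

# Two-sided Fisher p by direct enumeration of the hypergeometric support
# using binomial-coefficient arithmetic (lchoose), summing probabilities
# no larger than the observed table's.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  tot <- a + b + c + d
  ks <- max(0, c1 - (c + d)):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(tot - r1, c1 - ks) - lchoose(tot, c1)
  p <- exp(logp)
  p_obs <- p[ks == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Brute-force six-frame ORF scanner: walks every codon position of every
# frame on both strands with substring tests, emitting maximal ORFs under
# the same policy semantics as the package (segments delimited by stops;
# a segment preceded by a stop must start at ATG; the frame-leading
# segment may start at the frame edge when partials are allowed; ORFs
# encode >= 1 amino acid).
oracle_orfs <- function(seq, allow_partial = TRUE, min_nt = 3) {
  seq <- toupper(seq)
  L <- nchar(seq)
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      # nt start positions of the complete codons of this frame
      pos <- seq(frame + 1, L - 2, by = 3)
      pos <- pos[pos + 2 <= L]
      if (!length(pos)) next
      cod <- substring(s, pos, pos + 2)
      n <- length(cod)
      i <- 1
      repeat {
        if (i > n) break
        # next stop at or after i
        j <- i
        while (j <= n && !(cod[j] %in% stops)) j <- j + 1
        bounded <- j <= n
        last_coding <- if (bounded) j - 1 else n
        start <- NA_integer_
        if (i == 1 && allow_partial) {
          start <- 1L
        } else {
          for (k in i:max(i, last_coding)) {
            if (k <= last_coding && cod[k] == "ATG") {
              start <- k
              break
            }
          }
        }
        ok <- !is.na(start) && start <= last_coding &&
          (bounded || allow_partial)
        if (ok) {
          hi <- if (bounded) j else n
          nt_len <- (hi - start + 1L) * 3L
          if (nt_len >= min_nt) {
            s0 <- pos[start] - 1L
            e0 <- pos[hi] + 2L
            if (strand == "-") {
              tmp <- L - e0
              e0 <- L - s0
              s0 <- tmp
            }
            rows[[length(rows) + 1]] <- data.frame(
              strand = strand, frame = frame, start = s0, end = e0,
              nt_length = nt_len,
              complete5 = cod[start] == "ATG",
              complete3 = bounded,
              stringsAsFactors = FALSE
            )
          }
        }
        if (!bounded) break
        i <- j + 1L
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      nt_length = integer(), complete5 = logical(),
                      complete3 = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$strand, out$frame, out$start), ]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# canonical form for comparing ORF record sets
orf_key <- function(df) {
  df <- df[order(df$strand, df$frame, df$start), ]
  paste(df$strand, df$frame, df$start, df$end, df$nt_length,
        df$complete5, df$complete3, sep = ":", collapse = "|")
}
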