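test_that("a minimal complete ORF is found with correct anatomy", {
  orfs <- six_frame_orfs("ATGAAATAA")
  complete <- orfs[orfs$complete5 & orfs$complete3, ]
  expect_equal(nrow(complete), 1)
  expect_equal(complete$nt_length, 9)
  expect_equal(complete$peptide, "MK")
  expect_equal(complete$start, 0)
  expect_equal(complete$end, 9)
  expect_equal(complete$strand, "+")
})

test_that("complete-only policy rejects startless or stopless frames", {
  expect_equal(nrow(six_frame_orfs("CCCCCC",
                                   orf_policy(allow_partial = FALSE))), 0)
  # partial policy still reports the open frames
  expect_gt(nrow(six_frame_orfs("CCCCCC")), 0)
  expect_error(six_frame_orfs(""), "empty")
  expect_error(six_frame_orfs("ATGXX"), "illegal")
})

test_that("translation follows the standard code with N giving X", {
  expect_equal(translate("ATGTTTTAA", 0), "MF*")
  expect_equal(translate("NATG", 1), "M")
  expect_equal(translate("AANTTT", 0), "XF")
  expect_error(translate("ATG", 5))
  # oracle: reference implementation over a long random sequence
  set.seed(55)
  s <- random_dna(999)
  ref <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                            no.init.codon = TRUE))
  expect_equal(translate(s, 0), ref)
})

test_that("six-frame scan equals the brute-force oracle", {
  set.seed(56)
  for (i in 1:60) {
    len <- sample(3:600, 1)
    s <- random_dna(len, alphabet = c("A", "C", "G", "T",
                                      if (i %% 5 == 0) "N"))
    for (partial in c(TRUE, FALSE)) {
      got <- six_frame_orfs(s, orf_policy(allow_partial = partial))
      want <- oracle_orfs(s, allow_partial = partial)
      expect_equal(orf_key(got), orf_key(want),
                   info = paste("seq", i, "partial", partial))
    }
  }
})

test_that("reported complete ORFs re-extract to ATG...stop", {
  set.seed(57)
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }
  for (i in 1:25) {
    s <- random_dna(sample(60:500, 1))
    orfs <- six_frame_orfs(s)
    complete <- orfs[orfs$complete5 & orfs$complete3, ]
    for (j in seq_len(nrow(complete))) {
      sub <- substring(s, complete$start[j] + 1, complete$end[j])
      if (complete$strand[j] == "-") sub <- revcomp(sub)
      expect_equal(substring(sub, 1, 3), "ATG")
      expect_true(substring(sub, nchar(sub) - 2) %in%
                  c("TAA", "TAG", "TGA"))
      expect_equal(nchar(sub) %% 3, 0)
    }
  }
})

test_that("ORF length spectrum is invariant under reverse complement", {
  set.seed(58)
  for (i in 1:20) {
    s <- random_dna(sample(30:400, 1))
    expect_equal(sort(six_frame_orfs(s)$nt_length),
                 sort(six_frame_orfs(reverse_complement(s))$nt_length))
  }
})

test_that("best ORF picks the longest with a deterministic tie-break", {
  one <- best_orf("CCATGAAATTTTAACC", orf_policy(allow_partial = FALSE))
  expect_equal(one$peptide, "MKF")
  # the 36-nt ORF beats the 12-nt ORF
  seq2 <- paste0("ATG", strrep("A", 30), "TAA", "ATG", strrep("A", 6),
                 "TAA")
  top <- best_orf(seq2, orf_policy(allow_partial = FALSE))
  expect_equal(top$nt_length, 36)
  expect_equal(top$start, 0)
  # strand symmetry of the winner's length
  set.seed(59)
  for (i in 1:10) {
    s <- random_dna(300)
    expect_equal(best_orf(s)$nt_length,
                 best_orf(reverse_complement(s))$nt_length)
  }
  expect_null(best_orf("CCCCCC", orf_policy(allow_partial = FALSE)))
})

test_that("minimum-length policy filters short ORFs", {
  seq2 <- paste0("ATG", strrep("A", 30), "TAA")
  expect_equal(nrow(six_frame_orfs(seq2,
                                   orf_policy(allow_partial = FALSE,
                                              min_nt = 150))), 0)
  expect_equal(six_frame_orfs(seq2, orf_policy(allow_partial = FALSE,
                                               min_nt = 36))$nt_length, 36)
})

test_that("UTR trimming drops sequence upstream of the best start codon", {
  s <- paste0("CCCCC", "ATG", strrep("GGA", 20), "TAA")
  expect_equal(trim_utr5(s), paste0("ATG", strrep("GGA", 20), "TAA"))
  # no complete forward ORF: unchanged
  expect_equal(trim_utr5("CCCCCC"), "CCCCCC")
})

test_that("FASTA round trip and per-record best-ORF prediction", {
  seqs <- c(tx1 = paste0("ATG", strrep("GCT", 30), "TAA"),
            tx2 = "CCCCCCCCC")
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  back <- read_fasta(fa)
  expect_equal(unname(back), unname(seqs))
  expect_equal(names(back), names(seqs))
  out_tsv <- tempfile(fileext = ".tsv")
  out_pep <- tempfile(fileext = ".fasta")
  orfs <- predict_orfs(fa, orf_policy(allow_partial = FALSE),
                       tsv_out = out_tsv, peptides_out = out_pep)
  expect_equal(orfs$seq_id, "tx1")
  expect_equal(orfs$peptide, paste0("M", strrep("A", 30)))
  expect_true(file.exists(out_tsv))
  peps <- read_fasta(out_pep)
  expect_equal(nchar(peps[["tx1"]]), 31)
})
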