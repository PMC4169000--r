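#' Load the shipped annotated-transcript fixture
#'
#' Reads the TSV transcription of the screen's published summary table of
#' transcripts characterized in detail (one row per transcript: name,
#' primary-knockdown z-score, DGE class, expression-pattern type,
#' taxon-restriction flag, complete-ORF flag) and validates it against a
#' guard so silent edits of the fixture are caught: exactly 46 records,
#' 25 with negative and 21 with positive z.
#'
#' @param path Fixture path; defaults to the copy installed with the
#'   package.
#' @return Data.frame of annotated transcripts with columns \code{name},
#'   \code{wnt3_z}, \code{dge_class}, \code{pattern}, \code{restricted},
#'   \code{orf_complete}.
#' @export
load_table1_fixture <- function(path = system.file("extdata", "table1.tsv",
                                                   package = "dgescreen")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("annotated-transcript fixture not found")
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("name", "wnt3_z", "dge_class", "pattern", "restricted",
            "orf_complete")
  if (!identical(colnames(tab), need)) {
    stop("fixture columns drifted; expected: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) != 46 || sum(tab$wnt3_z < 0) != 25 ||
      sum(tab$wnt3_z > 0) != 21) {
    stop("fixture guard failed: expected 46 records ",
         "(25 under-, 21 over-expressed), got ", nrow(tab))
  }
  patterns <- c("O", "O_endo", "IE", "A", "D", "D_A")
  if (!all(tab$pattern %in% patterns) || !all(tab$dge_class %in% 1:4)) {
    stop("fixture guard failed: unknown pattern or class label")
  }
  tab
}
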