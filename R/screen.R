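#' Significance tier of a transcript from its primary-knockdown z-score
#'
#' Two-tier thresholding of the screening z-score: a loose tier at
#' |z| >= \code{loose} (default 3.3) and a strict tier at |z| >=
#' \code{strict} (default 5). Boundary values belong to the more
#' significant tier.
#'
#' @param z Finite numeric vector of z-scores.
#' @param loose,strict Positive cutoffs with loose <= strict.
#' @return Character vector in \{none, loose_under, loose_over,
#'   strict_under, strict_over\}.
#' @export
tier_transcript <- function(z, loose = 3.3, strict = 5) {
  stopifnot(loose > 0, loose <= strict)
  if (any(!is.finite(z))) stop("z must be finite")
  ifelse(z <= -strict, "strict_under",
  ifelse(z <= -loose, "loose_under",
  ifelse(z >= strict, "strict_over",
  ifelse(z >= loose, "loose_over", "none"))))
}

#' Flag probable injection artifacts
#'
#' A transcript elevated (z > \code{strict}) in the primary knockdown and
#' in both of two phenotypically opposite knockdowns responds to the
#' injection procedure rather than to the targeted gene.
#'
#' @param z_wnt3,z_fz1,z_fz3 z-score vectors for the three knockdowns.
#' @param strict Strict cutoff (default 5).
#' @return Logical vector.
#' @export
flag_injection_artifact <- function(z_wnt3, z_fz1, z_fz3, strict = 5) {
  if (missing(z_wnt3) || missing(z_fz1) || missing(z_fz3)) {
    stop("artifact flagging requires z for wnt3, fz1 and fz3")
  }
  z_wnt3 > strict & z_fz1 > strict & z_fz3 > strict
}

#' Flag probable contaminant transcripts
#'
#' A transcript strongly depleted (z < -\code{strict}) in both the primary
#' knockdown and the opposite-phenotype knockdown is a likely foreign
#' (e.g. bacterial) contaminant over-represented in the un-manipulated
#' control; the fz1 response is not required.
#'
#' @param z_wnt3,z_fz3 z-score vectors for the two required knockdowns.
#' @param strict Strict cutoff (default 5).
#' @return Logical vector.
#' @export
flag_contaminant <- function(z_wnt3, z_fz3, strict = 5) {
  if (missing(z_wnt3) || missing(z_fz3)) {
    stop("contaminant flagging requires z for wnt3 and fz3")
  }
  z_wnt3 < -strict & z_fz3 < -strict
}

#' Assign the four-way DGE class from paired knockdown z-scores
#'
#' Transcripts beyond the strict cutoff in the primary (wnt3) knockdown
#' are split by the strength of their secondary (fz1) response:
#' \itemize{
#'   \item class 1: z_wnt3 <= -strict and z_fz1 > -strict (weak secondary);
#'   \item class 2: z_wnt3 <= -strict and z_fz1 <= -strict;
#'   \item class 3: z_wnt3 >= +strict and z_fz1 < +strict;
#'   \item class 4: z_wnt3 >= +strict and z_fz1 >= +strict.
#' }
#' Everything else is unclassified (class NA). Exact-boundary fz1 values
#' fall on the strongly-affected side (classes 2/4); this choice is
#' configurable only by shifting the cutoff.
#'
#' @param z_wnt3,z_fz1 Finite z-score vectors.
#' @param strict Strict cutoff (default 5).
#' @return Integer vector in \{1, 2, 3, 4, NA\}.
#' @export
assign_dge_class <- function(z_wnt3, z_fz1, strict = 5) {
  if (any(!is.finite(z_wnt3)) || any(!is.finite(z_fz1))) {
    stop("z-scores must be finite")
  }
  cls <- rep(NA_integer_, length(z_wnt3))
  under <- z_wnt3 <= -strict
  over <- z_wnt3 >= strict
  cls[under & z_fz1 > -strict] <- 1L
  cls[under & z_fz1 <= -strict] <- 2L
  cls[over & z_fz1 < strict] <- 3L
  cls[over & z_fz1 >= strict] <- 4L
  cls
}

#' Run the full screening stage on per-condition z-scores
#'
#' Applies, in order: tiering on the primary (wnt3) z-score, injection
#' artifact flagging, contaminant flagging, then DGE class assignment for
#' unflagged strict-tier transcripts. Flags take precedence over classes:
#' a flagged transcript is never classified.
#'
#' @param z Data.frame with a \code{gene} column and one z-score column
#'   per condition; \code{wnt3} and \code{fz1} are required, \code{fz3}
#'   and \code{stbm} optional (artifact/contaminant flags need
#'   \code{fz3}).
#' @param loose,strict Tier cutoffs.
#' @return ScreenRecord data.frame: gene, the z columns, tier,
#'   artifact_flag, contaminant_flag, dge_class (integer, NA for
#'   unclassified).
#' @export
run_screen <- function(z, loose = 3.3, strict = 5) {
  need <- c("gene", "wnt3", "fz1")
  if (!all(need %in% colnames(z))) {
    stop("z table must contain columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(z$gene)) stop("duplicate gene ids in z table")
  out <- z
  out$tier <- tier_transcript(z$wnt3, loose, strict)
  if ("fz3" %in% colnames(z)) {
    out$artifact_flag <- flag_injection_artifact(z$wnt3, z$fz1, z$fz3,
                                                 strict)
    out$contaminant_flag <- flag_contaminant(z$wnt3, z$fz3, strict)
  } else {
    out$artifact_flag <- rep(FALSE, nrow(z))
    out$contaminant_flag <- rep(FALSE, nrow(z))
  }
  # under the default rules a transcript cannot satisfy both (the artifact
  # rule needs z_wnt3 > strict, the contaminant rule z_wnt3 < -strict);
  # contaminant wins if a cutoff configuration ever allowed both
  stopifnot(!any(out$artifact_flag & out$contaminant_flag))
  out$dge_class <- assign_dge_class(z$wnt3, z$fz1, strict)
  out$dge_class[out$artifact_flag | out$contaminant_flag] <- NA_integer_
  out
}
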