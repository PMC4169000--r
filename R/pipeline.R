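#' Compute per-condition z-score tables against a control
#'
#' For every non-control condition, compares the condition's pooled
#' counts (summed over its replicate libraries, the usual treatment of
#' replicate tag-count lanes) against the control's pooled counts: M and
#' A are computed per gene, the random-sampling offset log2(n1/n2)
#' implied by the pooled library totals is removed from M, and the
#' residual is calibrated either against a technical-replicate noise
#' model (MATR; preferred, indexed by A so it transfers across depths)
#' or, when no replicate pair exists, against the theoretical
#' random-sampling standard deviation.
#'
#' @param tables Named list of [tag_count_table()], one per condition.
#' @param control Name of the control condition.
#' @param noise Optional \code{noise_model}; when NULL, models are fitted
#'   from the first two libraries of every duplicated condition and
#'   averaged. When no condition is duplicated the theoretical
#'   random-sampling z is used, with a logged warning.
#' @param pseudocount,window_size,min_count Passed to the MA and noise
#'   machinery.
#' @return List with \code{z} (data.frame: gene + one column per
#'   condition), \code{ma} (per-condition MAStat data.frames with
#'   columns gene, M, A, z, p, low_count), and \code{noise} (the model
#'   used, or NULL).
#' @export
compute_condition_zscores <- function(tables, control = "uninjected",
                                      noise = NULL, pseudocount = 0.5,
                                      window_size = 500, min_count = 10) {
  stopifnot(control %in% names(tables))
  genes <- rownames(tables[[control]]$counts)
  for (tab in tables) {
    if (!identical(rownames(tab$counts), genes)) {
      stop("[zscore] condition tables have inconsistent gene sets")
    }
  }
  if (is.null(noise)) {
    dup <- names(tables)[vapply(tables, function(t) ncol(t$counts) >= 2,
                                logical(1))]
    if (length(dup) == 0) {
      warning("[zscore] no replicated condition; falling back to the ",
              "theoretical random-sampling z", call. = FALSE)
    } else {
      models <- lapply(tables[dup], function(t) {
        c1 <- t$counts[, 1]; c2 <- t$counts[, 2]
        off <- log2(t$totals[1] / t$totals[2])
        # offset-correct replicate M so models from unequal-depth pairs
        # are comparable
        m <- fit_noise_model(c1, c2, window_size = window_size,
                             min_count = min_count,
                             pseudocount = pseudocount)
        m$mean_m <- m$mean_m - off
        m
      })
      noise <- average_noise_models(models)
      message(sprintf("[zscore] noise model from %d replicate pair(s): %s",
                      length(dup), paste(dup, collapse = ", ")))
    }
  }
  ctrl_counts <- rowSums(tables[[control]]$counts)
  ctrl_total <- sum(tables[[control]]$totals)
  conditions <- setdiff(names(tables), control)
  z_tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  ma_tabs <- list()
  for (cond in conditions) {
    cc <- rowSums(tables[[cond]]$counts)
    ct <- sum(tables[[cond]]$totals)
    ma <- compute_ma(cc, ctrl_counts, pseudocount)
    offset <- log2(ct / ctrl_total)
    resid <- ma$M - offset
    if (!is.null(noise)) {
      z <- matr_zscore(resid, ma$A, noise)
    } else {
      mom <- rsm_null_moments(pmax(cc + ctrl_counts, 1), ct / (ct + ctrl_total))
      z <- resid / sqrt(mom$varM)
      z[cc + ctrl_counts == 0] <- NA_real_
    }
    z[!is.finite(z)] <- 0  # K = 0 genes carry no evidence
    z_tab[[cond]] <- z
    ma_tabs[[cond]] <- data.frame(
      gene = genes, M = ma$M, A = ma$A, z = z,
      p = two_sided_p(z), low_count = (cc + ctrl_counts) < min_count,
      stringsAsFactors = FALSE
    )
  }
  list(z = z_tab, ma = ma_tabs, noise = noise)
}

#' Run the full screening pipeline
#'
#' End-to-end composition of the screen: simulate (or accept) count
#' tables, fit the replicate noise model, compute per-condition z-scores
#' against the control, apply tiering / artifact and contaminant
#' flagging / DGE class assignment, and (for simulations) evaluate
#' recovery against the planted truth. With an \code{out_dir}, all
#' intermediate tables are written as TSV; the run is deterministic for
#' a fixed configuration and seed.
#'
#' @param x A [sim_config()] or a named list of [tag_count_table()].
#' @param control Control condition name (default "uninjected").
#' @param loose,strict Tier cutoffs (defaults 3.3 and 5).
#' @param pseudocount,window_size,min_count Statistical tuning knobs.
#' @param out_dir Optional output directory for TSV reports.
#' @param verbose Emit stage messages to standard error (default TRUE).
#' @return List with \code{screen} (ScreenRecord data.frame), \code{z},
#'   \code{ma}, \code{noise}, plus \code{truth} and \code{recovery} when
#'   simulating.
#' @export
run_pipeline <- function(x, control = "uninjected", loose = 3.3,
                         strict = 5, pseudocount = 0.5, window_size = 500,
                         min_count = 10, out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  truth <- NULL
  if (inherits(x, "sim_config")) {
    say("[simulate] %d genes, %d libraries, seed %d", x$n_genes,
        length(x$library_sizes), x$seed)
    sim <- simulate_experiment(x)
    tables <- sim$tables
    truth <- sim$truth
  } else if (is.list(x) &&
             all(vapply(x, inherits, logical(1), "tag_count_table"))) {
    tables <- x
  } else {
    stop("[input] x must be a sim_config or a named list of ",
         "tag_count_table objects")
  }
  zres <- compute_condition_zscores(tables, control = control,
                                    pseudocount = pseudocount,
                                    window_size = window_size,
                                    min_count = min_count)
  say("[zscore] %d genes x %d conditions", nrow(zres$z),
      ncol(zres$z) - 1L)
  screen <- run_screen(zres$z, loose = loose, strict = strict)
  say("[screen] %d strict-tier, %d artifact, %d contaminant, %d classified",
      sum(screen$tier %in% c("strict_under", "strict_over")),
      sum(screen$artifact_flag), sum(screen$contaminant_flag),
      sum(!is.na(screen$dge_class)))
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- evaluate_recovery(screen, truth)
    say("[recovery] class recovery %.3f", recovery$class_recovery)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cond in names(tables)) {
      write_count_table(tables[[cond]],
                        file.path(out_dir, paste0("counts_", cond, ".tsv")))
    }
    for (cond in names(zres$ma)) {
      .write_tsv(zres$ma[[cond]],
                 file.path(out_dir, paste0("mastat_", cond, ".tsv")))
    }
    .write_tsv(screen, file.path(out_dir, "screen.tsv"))
    if (!is.null(truth)) {
      .write_tsv(truth, file.path(out_dir, "truth.tsv"))
    }
    say("[write] reports in %s", out_dir)
  }
  say("[done] %.1f s", proc.time()[["elapsed"]] - t0)
  list(screen = screen, z = zres$z, ma = zres$ma, noise = zres$noise,
       truth = truth, recovery = recovery)
}

# TSV writer shared by all reports: UTF-8, tab-separated, Unix newlines
.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
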