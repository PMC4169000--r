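#' Configuration for a simulated tag-count screen
#'
#' Defines the statistical structure of a simulated cross-perturbation
#' DGE experiment: a log2-normal distribution of baseline transcript
#' abundances, per-library sequencing depths, gamma-Poisson (negative
#' binomial) overdispersion between technical replicates, and planted
#' gene fractions for the four response classes plus injection artifacts
#' and contaminants.
#'
#' The default design mirrors the screen the simulator emulates: five
#' conditions (an uninjected control and four morpholino knockdowns),
#' with duplicated libraries for the control and the primary knockdown.
#' Planted effects per label, with e = \code{effect_log2fc}:
#' \itemize{
#'   \item class 1: log2FC -e in \code{wnt3} only;
#'   \item class 2: -e in \code{wnt3}, \code{fz1} and \code{stbm};
#'   \item class 3: +e in \code{wnt3} only;
#'   \item class 4: +e in \code{wnt3}, \code{fz1} and \code{stbm};
#'   \item artifact: +e in every morpholino condition;
#'   \item contaminant: abundance multiplied by \code{contaminant_factor}
#'     in every morpholino condition (full abundance in the control);
#'   \item null: no effect anywhere.
#' }
#'
#' @param n_genes Number of genes (default 20000).
#' @param baseline_log2_mean,baseline_log2_sd Parameters of the log2-normal
#'   baseline abundance distribution.
#' @param mean_depth Mean reads per gene used to size libraries when
#'   \code{library_sizes} is NULL (default 100).
#' @param library_sizes Named integer vector of library totals; names are
#'   \code{<condition>_<replicate>}. Defaults to \code{mean_depth * n_genes}
#'   for every library of the standard design.
#' @param dispersion Negative-binomial dispersion: variance m + dispersion
#'   m^2 at mean m; 0 gives Poisson replicates.
#' @param planted_fractions Named proportions for labels \code{class1},
#'   \code{class2}, \code{class3}, \code{class4}, \code{artifact},
#'   \code{contaminant}, \code{null}; must sum to 1.
#' @param effect_log2fc Magnitude of planted condition effects (log2).
#' @param contaminant_factor Relative abundance of contaminant genes in
#'   morpholino libraries (default 0.1).
#' @param seed Master integer seed; per-library substreams are derived
#'   deterministically from it.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 20000,
                       baseline_log2_mean = 5,
                       baseline_log2_sd = 1.5,
                       mean_depth = 100,
                       library_sizes = NULL,
                       dispersion = 0.02,
                       planted_fractions = c(class1 = 0.01, class2 = 0.01,
                                             class3 = 0.01, class4 = 0.01,
                                             artifact = 0.0025,
                                             contaminant = 0.0025,
                                             null = 0.955),
                       effect_log2fc = 4,
                       contaminant_factor = 0.1,
                       seed = 1L) {
  labels <- c("class1", "class2", "class3", "class4",
              "artifact", "contaminant", "null")
  if (n_genes <= 0) stop("n_genes must be strictly positive")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (effect_log2fc <= 0) stop("effect_log2fc must be positive")
  if (!setequal(names(planted_fractions), labels)) {
    stop("planted_fractions must name exactly: ",
         paste(labels, collapse = ", "))
  }
  planted_fractions <- planted_fractions[labels]
  if (any(planted_fractions < 0) ||
      abs(sum(planted_fractions) - 1) > 1e-9) {
    stop("planted_fractions must be non-negative and sum to 1")
  }
  if (is.null(library_sizes)) {
    libs <- c("uninjected_1", "uninjected_2", "wnt3_1", "wnt3_2",
              "fz1_1", "fz3_1", "stbm_1")
    library_sizes <- stats::setNames(rep(mean_depth * n_genes,
                                         length(libs)), libs)
  }
  if (any(library_sizes <= 0)) stop("library sizes must be strictly positive")
  if (is.null(names(library_sizes)) || anyDuplicated(names(library_sizes))) {
    stop("library_sizes must have unique names of the form condition_rep")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         library_sizes = library_sizes,
         dispersion = dispersion,
         planted_fractions = planted_fractions,
         effect_log2fc = effect_log2fc,
         contaminant_factor = contaminant_factor,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# condition name of a library id "condition_rep"
.lib_condition <- function(lib) sub("_[0-9]+$", "", lib)

# deterministic sub-seed for library index i under master seed
.sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + i * 7919) %% 2147483563) + 1L
}

# planted log2 fold change matrix: genes x conditions
.planted_lfc <- function(labels, conditions, effect, contaminant_factor) {
  lfc <- matrix(0, nrow = length(labels), ncol = length(conditions),
                dimnames = list(NULL, conditions))
  mo <- setdiff(conditions, "uninjected")
  set_if <- function(lab, conds, value) {
    conds <- intersect(conds, conditions)
    lfc[labels == lab, conds] <<- value
  }
  set_if("class1", "wnt3", -effect)
  set_if("class2", c("wnt3", "fz1", "stbm"), -effect)
  set_if("class3", "wnt3", effect)
  set_if("class4", c("wnt3", "fz1", "stbm"), effect)
  set_if("artifact", mo, effect)
  set_if("contaminant", mo, log2(contaminant_factor))
  lfc
}

#' Simulate a cross-perturbation tag-count experiment
#'
#' Draws one count table per condition under the configured design and
#' returns them with the planted ground truth. The expected count of gene
#' g in library l is proportional to baseline_g * 2^lfc(g, condition),
#' rescaled so that the expected column total equals the configured
#' library size; realized counts are negative binomial (Poisson when
#' \code{dispersion = 0}). The same seed gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @return List with \code{tables} (named list of
#'   \code{tag_count_table}, one per condition) and \code{truth}
#'   (data.frame: gene, label, baseline, and one lfc_* column per
#'   condition).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  libs <- names(config$library_sizes)
  conditions <- unique(.lib_condition(libs))

  # label assignment: largest-remainder apportionment, then shuffled under
  # the master seed so labels are not confounded with baseline order
  frac <- config$planted_fractions
  counts <- floor(frac * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(frac * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  labels <- rep(names(frac), counts)

  set.seed(config$seed)
  labels <- sample(labels)
  baseline <- 2^stats::rnorm(n, config$baseline_log2_mean,
                             config$baseline_log2_sd)
  lfc <- .planted_lfc(labels, conditions, config$effect_log2fc,
                      config$contaminant_factor)

  counts_by_lib <- matrix(0L, nrow = n, ncol = length(libs),
                          dimnames = list(genes, libs))
  for (i in seq_along(libs)) {
    cond <- .lib_condition(libs[i])
    w <- baseline * 2^lfc[, cond]
    mu <- config$library_sizes[i] * w / sum(w)
    set.seed(.sub_seed(config$seed, i))
    counts_by_lib[, i] <- if (config$dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    } else {
      stats::rpois(n, mu)
    }
  }

  tables <- lapply(conditions, function(cond) {
    cols <- libs[.lib_condition(libs) == cond]
    tag_count_table(counts_by_lib[, cols, drop = FALSE])
  })
  names(tables) <- conditions

  truth <- data.frame(gene = genes, label = labels, baseline = baseline,
                      stringsAsFactors = FALSE)
  for (cond in conditions) truth[[paste0("lfc_", cond)]] <- lfc[, cond]

  list(tables = tables, truth = truth)
}

#' Compare screen output against planted truth
#'
#' Maps each screen record to a predicted label (artifact or contaminant
#' flag, else its DGE class, else null) and tabulates it against the
#' planted label. Precision and recall are reported per label; labels
#' absent from the truth are omitted from the recall table rather than
#' reported as 0/0.
#'
#' @param screen ScreenRecord data.frame from [run_screen()].
#' @param truth Truth data.frame from [simulate_experiment()].
#' @return List with \code{confusion} (true x predicted table),
#'   \code{stats} (per-label precision/recall/n), and
#'   \code{class_recovery} (fraction of planted class-1..4 genes
#'   assigned their true class).
#' @export
evaluate_recovery <- function(screen, truth) {
  if (!setequal(screen$gene, truth$gene)) {
    stop("screen and truth must cover the same gene universe")
  }
  truth <- truth[match(screen$gene, truth$gene), ]
  predicted <- ifelse(screen$artifact_flag, "artifact",
               ifelse(screen$contaminant_flag, "contaminant",
               ifelse(screen$dge_class %in% 1:4,
                      paste0("class", screen$dge_class), "null")))
  levels <- c("class1", "class2", "class3", "class4",
              "artifact", "contaminant", "null")
  confusion <- table(true = factor(truth$label, levels),
                     predicted = factor(predicted, levels))
  present <- levels[rowSums(confusion) > 0]
  stats <- data.frame(
    label = present,
    n = as.integer(rowSums(confusion)[present]),
    precision = vapply(present, function(l) {
      np <- sum(confusion[, l])
      if (np == 0) NA_real_ else confusion[l, l] / np
    }, numeric(1)),
    recall = vapply(present, function(l) {
      confusion[l, l] / sum(confusion[l, ])
    }, numeric(1)),
    row.names = NULL
  )
  cls <- intersect(present, paste0("class", 1:4))
  class_recovery <- if (length(cls)) {
    sum(diag(confusion[cls, cls, drop = FALSE])) /
      sum(confusion[cls, , drop = FALSE])
  } else {
    NA_real_
  }
  list(confusion = confusion, stats = stats, class_recovery = class_recovery)
}
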