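#' Structure-recovery metrics over a slot universe
#'
#' Counts true/false positives and negatives of an inferred edge support
#' against ground truth over a fixed set of assessable slots, and
#' reports \eqn{TPR = TP/(TP+FN)} and \eqn{FDR = FP/(TP+FP)}. FDR is
#' defined as 0 when nothing is predicted. Direction matters: `(i, j)`
#' and `(j, i)` are distinct slots.
#'
#' @param true_support,inferred_support two-column matrices of `(row,
#'   col)` index pairs (as returned by [support_indices()]).
#' @param universe two-column matrix of all assessable slots; both
#'   supports must be subsets.
#' @return List with `tpr`, `fdr`, and `counts` (tp, fp, tn, fn).
#' @export
structure_metrics <- function(true_support, inferred_support, universe) {
  key <- function(s) {
    if (is.null(s) || nrow(s) == 0L) return(character(0))
    paste(s[, 1], s[, 2], sep = ":")
  }
  kt <- key(true_support)
  ki <- key(inferred_support)
  ku <- key(universe)
  if (!all(kt %in% ku) || !all(ki %in% ku)) {
    stop("structure_metrics: supports must lie inside the slot universe")
  }
  tp <- sum(ki %in% kt)
  fp <- length(ki) - tp
  fn <- length(kt) - tp
  tn <- length(ku) - tp - fp - fn
  list(tpr = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' All off-diagonal gene-gene slots
#'
#' The assessable universe for gene-adjacency recovery: self-loops are
#' excluded because neither truth nor inference can contain them.
#'
#' @param m number of genes.
#' @return Two-column matrix of `(row, col)` pairs.
#' @export
b_slot_universe <- function(m) {
  u <- expand.grid(row = seq_len(m), col = seq_len(m))
  u <- as.matrix(u[u$row != u$col, ])
  rownames(u) <- NULL
  u
}

#' eQTL-assignment metrics
#'
#' Each gene contributes one prediction slot: a correct assignment is a
#' true positive; a wrong SNP is one false positive plus one false
#' negative (the true eQTL was missed); no assignment while a true eQTL
#' exists is a false negative.
#'
#' @param true_snp,inferred_snp integer vectors mapping genes to SNP
#'   indices (`NA` = no assignment).
#' @return List with `tpr`, `fdr`, `counts`.
#' @export
eqtl_assignment_metrics <- function(true_snp, inferred_snp) {
  stopifnot(length(true_snp) == length(inferred_snp))
  tp <- sum(!is.na(true_snp) & !is.na(inferred_snp) &
              true_snp == inferred_snp)
  fp <- sum(!is.na(inferred_snp) &
              (is.na(true_snp) | true_snp != inferred_snp))
  fn <- sum(!is.na(true_snp) &
              (is.na(inferred_snp) | true_snp != inferred_snp))
  list(tpr = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
       counts = c(tp = tp, fp = fp, fn = fn))
}

#' Simulation benchmark of structure recovery
#'
#' For each setting (network size M, sample size N, expected edges per
#' gene Eg), mode, and replicate: simulate a dataset with
#' [sgrn_simulate()], infer with [ial()], and score gene-edge and
#' eQTL-assignment recovery against the generating truth. Replicate
#' seeds are `base_seed + replicate - 1` for auditability; the whole
#' table is reproducible from `base_seed`.
#'
#' @param settings data frame with columns `M`, `N`, `Eg`.
#' @param modes character vector, subset of `c("ial1", "ial2")`.
#' @param replicates number of replicate networks per cell.
#' @param base_seed integer seed.
#' @param config_args named list of [ial_config()] overrides applied to
#'   every run.
#' @return Data frame, one row per setting x mode x replicate, with
#'   TPR/FDR for B edges and for the eQTL assignment, plus edge counts
#'   and the replicate seed. Failed replicates are recorded with `NA`
#'   metrics and the error message, not fatal.
#' @export
run_benchmark <- function(settings, modes = c("ial1", "ial2"),
                          replicates = 10, base_seed = 1L,
                          config_args = list()) {
  stopifnot(is.data.frame(settings),
            all(c("M", "N", "Eg") %in% names(settings)))
  if (replicates < 1) stop("run_benchmark: replicates must be >= 1")
  modes <- match.arg(modes, c("ial1", "ial2"), several.ok = TRUE)
  rows <- list()
  for (s in seq_len(nrow(settings))) {
    M <- settings$M[s]
    N <- settings$N[s]
    Eg <- settings$Eg[s]
    for (rep_i in seq_len(replicates)) {
      seed <- as.integer(base_seed + rep_i - 1L)
      sim <- sgrn_simulate(sgrn_sim_config(M, N, Eg, seed = seed))
      true_b <- support_indices(sim$model$B)
      true_snp <- seq_len(M)  # diagonal truth
      for (mode in modes) {
        row <- data.frame(M = M, N = N, Eg = Eg, mode = mode,
                          replicate = rep_i, seed = seed,
                          tpr_b = NA_real_, fdr_b = NA_real_,
                          tpr_eqtl = NA_real_, fdr_eqtl = NA_real_,
                          n_true_edges = nrow(true_b),
                          n_inferred_edges = NA_integer_,
                          error = NA_character_)
        fit <- tryCatch({
          cfg <- do.call(ial_config, c(list(mode = mode, seed = seed),
                                       config_args))
          if (mode == "ial1") {
            ial(sim$Y, sim$X, cfg, known_eqtls = true_snp)
          } else {
            ial(sim$Y, sim$X, cfg)
          }
        }, error = function(e) e)
        if (inherits(fit, "error")) {
          row$error <- conditionMessage(fit)
        } else {
          mb <- structure_metrics(true_b, fit$stage_supports$final_b,
                                  b_slot_universe(M))
          me <- eqtl_assignment_metrics(true_snp, fit$eqtl$snp_final)
          row$tpr_b <- mb$tpr
          row$fdr_b <- mb$fdr
          row$tpr_eqtl <- me$tpr
          row$fdr_eqtl <- me$fdr
          row$n_inferred_edges <- nrow(fit$stage_supports$final_b)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a benchmark table to per-cell means
#'
#' @param bench result of [run_benchmark()].
#' @return Data frame with one row per (N, M, Eg, mode) cell: mean TPR
#'   and FDR for gene edges and eQTL assignments, replicate count.
#' @export
summarize_benchmark <- function(bench) {
  agg <- stats::aggregate(
    bench[, c("tpr_b", "fdr_b", "tpr_eqtl", "fdr_eqtl")],
    by = bench[, c("N", "M", "Eg", "mode")],
    FUN = function(v) mean(v, na.rm = TRUE))
  n_rep <- stats::aggregate(list(replicates = bench$replicate),
                            by = bench[, c("N", "M", "Eg", "mode")],
                            FUN = length)
  out <- merge(agg, n_rep)
  out[order(out$Eg, out$N, out$M, out$mode), ]
}

#' Plot benchmark TPR/FDR against sample size
#'
#' One panel per metric, lines per (M, mode); mirrors how
#' structure-recovery accuracy is usually displayed against sample
#' size. Requires ggplot2.
#'
#' @param bench result of [run_benchmark()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(bench) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_benchmark requires the ggplot2 package")
  }
  summ <- summarize_benchmark(bench)
  long <- rbind(
    data.frame(summ[c("N", "M", "Eg", "mode")], metric = "TPR",
               value = summ$tpr_b),
    data.frame(summ[c("N", "M", "Eg", "mode")], metric = "FDR",
               value = summ$fdr_b))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$N, y = .data$value,
    colour = factor(.data$M), linetype = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(metric ~ Eg, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "samples (N)", y = NULL, colour = "genes (M)",
                  linetype = "mode") +
    ggplot2::theme_bw()
}
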