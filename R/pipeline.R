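#' Configuration for the IAL pipeline
#'
#' @param mode `"ial2"` (eQTLs unknown; full three-step pipeline) or
#'   `"ial1"` (eQTL map supplied; screening skipped, only the iterative
#'   adaptive lasso runs on the given SNP support).
#' @param alpha0 starting weight exponent for the gene block.
#' @param alpha_step increment of alpha per outer iteration.
#' @param alpha_max cap on alpha (reaching it is a distinct termination
#'   reason).
#' @param beta weight exponent for the SNP block, held fixed during the
#'   iteration. The default 0.5 follows the reference weighting; for
#'   expression data where genes correlate strongly with their eQTLs,
#'   `alpha = beta = 0.5` is the recommended configuration.
#' @param k_folds folds for every cross-validation (default 5).
#' @param n_k maximum number of candidate eQTLs kept per gene before the
#'   lasso-path finalization (default 5).
#' @param lambda_grid descending penalty grid shared by all CVs.
#' @param n_path,path_min_ratio lasso-path controls (see
#'   [lasso_path_eqtl()]).
#' @param tol,max_sweeps coordinate-descent controls for the fits that
#'   produce coefficients.
#' @param cv_tol,cv_max_sweeps looser coordinate-descent controls used
#'   only inside cross-validation, where solutions are ranked by
#'   held-out error and sub-tolerance coefficient changes cannot affect
#'   the ranking; the selected penalties are then used with the full
#'   tolerance.
#' @param max_inner cap on inner-loop iterations per alpha value.
#' @param zero_tol numeric-zero threshold for declaring an edge
#'   selected.
#' @param seed integer seed driving fold assignment (and thereby the
#'   whole run: two runs with the same seed and data are identical).
#' @return A list of class `ial_config`.
#' @export
ial_config <- function(mode = c("ial2", "ial1"), alpha0 = 0,
                       alpha_step = 0.5, alpha_max = 3, beta = 0.5,
                       k_folds = 5, n_k = 5,
                       lambda_grid = lambda_grid_default(),
                       n_path = 50, path_min_ratio = 0.01, tol = 1e-6,
                       max_sweeps = 10000, cv_tol = 1e-4,
                       cv_max_sweeps = 300, max_inner = 50,
                       zero_tol = 1e-8, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(alpha0 >= 0, alpha_step > 0, alpha_max > 0, beta >= 0,
            k_folds >= 2, n_k >= 1, length(lambda_grid) >= 1,
            tol > 0, zero_tol >= 0)
  structure(list(mode = mode, alpha0 = alpha0, alpha_step = alpha_step,
                 alpha_max = alpha_max, beta = beta,
                 k_folds = as.integer(k_folds), n_k = as.integer(n_k),
                 lambda_grid = lambda_grid, n_path = as.integer(n_path),
                 path_min_ratio = path_min_ratio, tol = tol,
                 max_sweeps = as.integer(max_sweeps), cv_tol = cv_tol,
                 cv_max_sweeps = as.integer(cv_max_sweeps),
                 max_inner = as.integer(max_inner), zero_tol = zero_tol,
                 seed = as.integer(seed)),
            class = "ial_config")
}

count_offdiag_support <- function(B, zero_tol) {
  Bo <- B
  diag(Bo) <- 0
  sum(abs(Bo) > zero_tol)
}

#' Infer a SNP-gene regulatory network by iterative adaptive lasso
#'
#' Runs the full pipeline on an expression matrix `Y` (genes x samples)
#' and a genotype matrix `X` (SNPs x samples, coded `{1,2,3}`):
#'
#' 1. *Ridge initialization* (Step 1-1): per-gene closed-form ridge fit
#'    with `(lambda1, lambda2)` chosen by K-fold CV.
#' 2. *Elastic-net screen* (Step 1-2): l1 on SNP coefficients (l2 kept
#'    on gene coefficients) retains a sparse candidate eQTL set per
#'    gene.
#' 3. *Lasso-path finalization* (Step 2): a single eQTL per gene, the
#'    candidate entering the lasso path earliest.
#' 4. *Iterative adaptive lasso* (Step 3): B and F are re-initialized by
#'    a ridge refit restricted to the selected eQTL support (no penalty
#'    on the retained SNP coefficient), per-gene `(lambda1, lambda2)`
#'    are estimated once by CV of the adaptive lasso, and the weighted
#'    fit is then iterated — weights recomputed from the latest estimate
#'    each pass, the exponent alpha increased once the edge count
#'    \eqn{N_e(B)} stabilizes — until an entire inner loop changes
#'    nothing (or alpha reaches its cap).
#'
#' In `"ial1"` mode the known eQTL map replaces steps 1-3's SNP
#' selection and only Step 3 runs (a per-gene `lambda1` is still
#' cross-validated for the restricted ridge initialization).
#'
#' @param Y expression matrix, genes x samples.
#' @param X genotype matrix, SNPs x samples.
#' @param config an [ial_config()].
#' @param known_eqtls integer vector (length = number of genes) mapping
#'   each gene to its SNP index; required in `"ial1"` mode, forbidden in
#'   `"ial2"` mode.
#' @return An object of class `sgrn_fit`: `B` and `F` (final coefficient
#'   matrices), `eqtl` (per-gene SNP assignment, entry lambdas, flags),
#'   `stage_supports`, `lambdas`, `trace` (per-iteration alpha and edge
#'   counts), `iterations`, `termination`, `mode`, `config`.
#' @export
ial <- function(Y, X, config = ial_config(), known_eqtls = NULL) {
  stopifnot(is.matrix(Y), is.matrix(X))
  if (ncol(Y) != ncol(X)) {
    stop("ial: Y and X must have the same number of samples")
  }
  M <- nrow(Y)
  Ms <- nrow(X)
  if (config$mode == "ial1" && is.null(known_eqtls)) {
    stop("ial: mode 'ial1' requires a known eQTL map (gene -> SNP index)")
  }
  if (config$mode == "ial2" && !is.null(known_eqtls)) {
    stop("ial: mode 'ial2' infers eQTLs; do not pass known_eqtls")
  }
  if (!is.null(known_eqtls)) {
    stopifnot(length(known_eqtls) == M)
    if (anyNA(known_eqtls) || !all(known_eqtls %in% seq_len(Ms))) {
      stop("ial: known_eqtls must map every gene to a valid SNP index")
    }
  }
  gene_ids <- rownames(Y)
  snp_ids <- rownames(X)
  Yc <- center_rows(Y)
  Xc <- center_rows(X)
  ztol <- config$zero_tol

  with_seed(config$seed, {
    folds <- make_folds(ncol(Yc), config$k_folds)
    fc <- fold_contexts(Yc, Xc, folds)
    ctx <- xprod_context(Yc, Xc)

    lambdas <- list()
    stage_supports <- list()
    eqtl <- list(snp = rep(NA_integer_, M),
                 entry_lambda = rep(NA_real_, M),
                 flag = rep("known", M))

    if (config$mode == "ial2") {
      ## Step 1-1: ridge CV + fit
      rcv <- ridge_cv(Yc, Xc, lambda_grid = config$lambda_grid,
                      k_folds = config$k_folds, folds = folds)
      lambdas$ridge_lambda1 <- rcv$lambda1
      lambdas$ridge_lambda2 <- rcv$lambda2
      ## Step 1-2: elastic-net SNP screen
      F_cand <- matrix(0, M, Ms)
      en_l2 <- numeric(M)
      for (i in seq_len(M)) {
        en_l2[i] <- elastic_net_cv_gene(fc, i, rcv$lambda1[i],
                                        lambda_grid = config$lambda_grid,
                                        tol = config$cv_tol,
                                        max_sweeps = config$cv_max_sweeps)
        fit <- elastic_net_fit_gene_ctx(ctx, i, rcv$lambda1[i], en_l2[i],
                                        tol = config$tol,
                                        max_sweeps = config$max_sweeps)
        F_cand[i, ] <- fit$f
      }
      lambdas$en_lambda2 <- en_l2
      stage_supports$step1_2 <- support_indices(F_cand, ztol)
      ## Step 2: lasso-path single-eQTL finalization
      for (i in seq_len(M)) {
        sel <- lasso_path_eqtl_ctx(ctx, i, F_cand[i, ], n_k = config$n_k,
                                   n_path = config$n_path,
                                   path_min_ratio = config$path_min_ratio,
                                   zero_tol = ztol, tol = config$tol,
                                   max_sweeps = config$max_sweeps)
        eqtl$snp[i] <- sel$snp
        eqtl$entry_lambda[i] <- sel$entry_lambda
        eqtl$flag[i] <- sel$flag
      }
      lambda1_R <- rcv$lambda1
    } else {
      eqtl$snp <- as.integer(known_eqtls)
      rcvr <- ridge_cv_restricted(Yc, Xc, eqtl$snp,
                                  lambda_grid = config$lambda_grid,
                                  k_folds = config$k_folds, folds = folds)
      lambda1_R <- rcvr$lambda1
      lambdas$ridge_lambda1 <- lambda1_R
    }
    step2 <- cbind(row = seq_len(M), col = eqtl$snp)
    stage_supports$step2 <- step2[!is.na(step2[, "col"]), , drop = FALSE]

    ## Step 3: iterative adaptive lasso (Algorithm: ridge-restricted
    ## init, one CV of the weighted fit, then the two nested loops)
    init <- refit_ridge_restricted_ctx(ctx, eqtl$snp, lambda1_R)
    B_cur <- init$B
    F_cur <- init$F
    G_full <- stacked_gram(ctx)
    alpha <- config$alpha0
    l1_hat <- l2_hat <- numeric(M)
    weights_of <- function(i, a) {
      make_weights(B_cur[i, ], F_cur[i, ], a, config$beta, ztol)
    }
    for (i in seq_len(M)) {
      cv <- adaptive_lasso_cv_gene(fc, i, weights_of(i, alpha),
                                   grid1 = config$lambda_grid,
                                   grid2 = config$lambda_grid,
                                   tol = config$cv_tol,
                                   max_sweeps = config$cv_max_sweeps)
      l1_hat[i] <- cv$lambda1
      l2_hat[i] <- cv$lambda2
    }
    lambdas$al_lambda1 <- l1_hat
    lambdas$al_lambda2 <- l2_hat

    fit_all <- function(a) {
      Bn <- matrix(0, M, M)
      Fn <- matrix(0, M, Ms)
      for (i in seq_len(M)) {
        s <- adaptive_lasso_fit_gene_ctx(ctx, G_full, i,
                                         weights_of(i, a),
                                         l1_hat[i], l2_hat[i],
                                         init_b = B_cur[i, ],
                                         init_f = F_cur[i, ],
                                         tol = config$tol,
                                         max_sweeps = config$max_sweeps)
        Bn[i, ] <- s$b
        Fn[i, ] <- s$f
      }
      list(B = Bn, F = Fn)
    }

    trace <- list()
    record <- function(outer, inner, a) {
      trace[[length(trace) + 1L]] <<- data.frame(
        outer = outer, inner = inner, alpha = a,
        ne_b = count_offdiag_support(B_cur, ztol),
        ne_f = sum(abs(F_cur) > ztol))
    }

    ## first weighted pass (weights from the ridge-restricted refit, at
    ## the starting exponent); each outer round then raises alpha and
    ## iterates reweighted fits until the edge count stops moving
    pass <- fit_all(alpha)
    B_cur <- pass$B
    F_cur <- pass$F
    outer <- 0L
    total_inner <- 1L
    record(outer, 0L, alpha)
    termination <- NULL
    repeat {
      outer <- outer + 1L
      alpha <- config$alpha0 + outer * config$alpha_step
      if (alpha > config$alpha_max + 1e-12) {
        termination <- "alpha_max_reached"
        break
      }
      ne_before_outer <- count_offdiag_support(B_cur, ztol)
      inner <- 0L
      repeat {
        inner <- inner + 1L
        total_inner <- total_inner + 1L
        ne_prev <- count_offdiag_support(B_cur, ztol)
        pass <- fit_all(alpha)
        B_cur <- pass$B
        F_cur <- pass$F
        record(outer, inner, alpha)
        ne_new <- count_offdiag_support(B_cur, ztol)
        if (ne_new == ne_prev || inner >= config$max_inner) break
      }
      if (count_offdiag_support(B_cur, ztol) == ne_before_outer) {
        termination <- "no_change"
        break
      }
    }

    stage_supports$final_b <- support_indices(B_cur, ztol)
    stage_supports$final_f <- support_indices(F_cur, ztol)
    eqtl_final <- eqtl$snp
    eqtl_final[!is.na(eqtl_final) &
                 abs(F_cur[cbind(seq_len(M),
                                 ifelse(is.na(eqtl$snp), 1L, eqtl$snp))])
               <= ztol] <- NA_integer_

    structure(list(B = B_cur, F = F_cur,
                   eqtl = data.frame(gene = seq_len(M), snp = eqtl$snp,
                                     snp_final = eqtl_final,
                                     entry_lambda = eqtl$entry_lambda,
                                     flag = eqtl$flag),
                   stage_supports = stage_supports, lambdas = lambdas,
                   trace = do.call(rbind, trace),
                   iterations = list(outer = outer,
                                     inner_total = total_inner),
                   termination = termination, mode = config$mode,
                   gene_ids = gene_ids, snp_ids = snp_ids,
                   config = config),
              class = "sgrn_fit")
  })
}

#' @export
print.sgrn_fit <- function(x, ...) {
  cat(sprintf("SGRN fit (%s): %d genes, %d SNPs\n", toupper(x$mode),
              nrow(x$B), ncol(x$F)))
  cat(sprintf("  gene-gene edges: %d; eQTL assignments: %d (of %d genes)\n",
              nrow(x$stage_supports$final_b),
              sum(!is.na(x$eqtl$snp_final)), nrow(x$B)))
  cat(sprintf("  outer iterations: %d (termination: %s), inner passes: %d\n",
              x$iterations$outer, x$termination,
              x$iterations$inner_total))
  invisible(x)
}
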