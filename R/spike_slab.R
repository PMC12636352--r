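# Spike-and-slab Bayesian variable selection: Gibbs sampling, posterior
# inclusion probabilities, PIP-based FDR selection, prediction, and Geweke
# convergence diagnostics.
#
# Model:  y = C alpha + X beta + eps,  eps ~ N(0, deltae^2 I)
#         beta_j ~ (1 - gamma_j) N(0, delta0^2) + gamma_j N(0, delta1^2)
#         gamma_j ~ Bernoulli(pi), pi ~ Beta(a_pi, b_pi)
#         delta1^-2 ~ Gamma(a1, b1), deltae^-2 ~ Gamma(a_e, b_e)
# delta0^2 (the spike variance) is fixed from the data so that background
# effects explain a fraction q of the expression variance.

#' Spike-and-slab model specification
#'
#' @param q fraction of expression variance attributed to background
#'   (spike) effects; sets the spike variance via [compute_delta0()].
#' @param a_pi,b_pi Beta prior on the inclusion probability `pi`.
#' @param a1,b1 Gamma prior on the slab precision `1/delta1^2`.
#' @param a_e,b_e Gamma prior on the residual precision `1/deltae^2`.
#' @param fix_pi,fix_delta1_sq,fix_deltae_sq optional fixed values
#'   collapsing the corresponding prior to a point mass (used for
#'   small-problem exact cross-checks).
#' @return a `bvs_spec` list.
#' @export
bvs_spec <- function(q = 0.05, a_pi = 1, b_pi = 1, a1 = 0.01, b1 = 0.01,
                     a_e = 0.01, b_e = 0.01, fix_pi = NULL,
                     fix_delta1_sq = NULL, fix_deltae_sq = NULL) {
  stopifnot(q > 0, q < 1, a_pi > 0, b_pi > 0, a1 > 0, b1 > 0, a_e > 0, b_e > 0)
  structure(list(q = q, a_pi = a_pi, b_pi = b_pi, a1 = a1, b1 = b1,
                 a_e = a_e, b_e = b_e, fix_pi = fix_pi,
                 fix_delta1_sq = fix_delta1_sq, fix_deltae_sq = fix_deltae_sq),
            class = "bvs_spec")
}

#' Spike variance from the data
#'
#' `delta0^2 = q * Var(y) / sum_j Var(X_j)` (sample variances): the spike
#' is scaled so that if every column carried a background effect of this
#' variance, background effects would jointly explain a fraction `q` of
#' the expression variance.
#'
#' @param y response vector.
#' @param X count matrix.
#' @param q background variance fraction in (0,1), default 0.05.
#' @return scalar `delta0^2`.
#' @export
compute_delta0 <- function(y, X, q = 0.05) {
  stopifnot(q > 0, q < 1, length(y) >= 2)
  sv <- sum(col_vars(X))
  if (sv == 0) stop("all count-matrix columns are constant; delta0^2 undefined")
  q * var(y) / sv
}

# column sample variances, for dense or sparse matrices
col_vars <- function(X) {
  n <- nrow(X)
  mu <- Matrix::colMeans(X)
  (Matrix::colSums(X^2) - n * mu^2) / (n - 1)
}

#' Fit the spike-and-slab regression by Gibbs sampling
#'
#' Each sweep updates, per column j, the pair (gamma_j, beta_j) — gamma_j
#' from its conditional with beta_j integrated out under the two-component
#' normal prior, then beta_j from its conjugate normal conditional — then
#' the covariate effects alpha (flat prior), pi, the slab variance and the
#' residual variance from their conjugate conditionals. PIP_j is the mean
#' of the retained gamma_j draws.
#'
#' @param matrix a `cluster_count_matrix`, or a list with elements `X`,
#'   `y` and optionally `C` (defaults to an intercept).
#' @param spec a [bvs_spec()].
#' @param iters,burn_in,thin MCMC schedule (defaults 10000/5000/5).
#' @param seed integer seed (default 1).
#' @param center_y centre the response before fitting; defaults on when
#'   `C` has no intercept-like column (all-equal column).
#' @param random_scan update columns in random order each sweep instead of
#'   ascending index.
#' @param fdr_target target FDR for the selected set (default 0.1).
#' @return object of class `bvs_fit`: per-cluster `pip`, `beta_mean`,
#'   `beta_slab_mean`, covariate effects `alpha_mean`, retained `traces`,
#'   `geweke` report, `fdr_table`, `selected` cluster ids, and the model
#'   metadata.
#' @export
fit_bvs <- function(matrix, spec = bvs_spec(), iters = 10000, burn_in = 5000,
                    thin = 5, seed = 1, center_y = NULL, random_scan = FALSE,
                    fdr_target = 0.1) {
  X <- matrix$X
  y <- matrix$y
  C <- matrix$C
  if (is.null(C)) C <- base::matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  if (any(!is.finite(y))) stop("non-finite response values")
  stopifnot(nrow(X) == length(y), nrow(C) == length(y), iters > burn_in)
  has_intercept <- any(apply(C, 2, function(col) length(unique(col)) == 1 && col[1] != 0))
  if (is.null(center_y)) center_y <- !has_intercept
  y_offset <- 0
  if (isTRUE(center_y)) {
    y_offset <- mean(y)
    y <- y - y_offset
  }
  delta0_sq <- compute_delta0(y, X, spec$q)
  Xs <- methods::as(methods::as(X, "CsparseMatrix"), "generalMatrix")
  # one-hot indicator covariates (e.g. per-pangene baselines) get an O(n)
  # group-sum update inside the sampler
  is_indicator <- ncol(C) > 1 && all(C %in% c(0, 1)) && all(rowSums(C) == 1)
  c_group <- if (is_indicator) max.col(C) - 1L else integer(0)
  set.seed(seed)
  res <- cpp_gibbs(y, if (is_indicator) base::matrix(0, 0, 0) else C,
                   c_group, if (is_indicator) ncol(C) else 0L,
                   Xs@p, Xs@i, Xs@x, ncol(Xs),
                   delta0_sq, spec$a_pi, spec$b_pi, spec$a1, spec$b1,
                   spec$a_e, spec$b_e, as.integer(iters), as.integer(burn_in),
                   as.integer(thin),
                   !is.null(spec$fix_pi), spec$fix_pi %||% 0.5,
                   !is.null(spec$fix_delta1_sq), spec$fix_delta1_sq %||% 1,
                   !is.null(spec$fix_deltae_sq), spec$fix_deltae_sq %||% 1,
                   isTRUE(random_scan))
  cluster_id <- colnames(X) %||% sprintf("cluster_%d", seq_len(ncol(X)))
  traces <- list(pi = res$trace_pi, delta1_sq = res$trace_delta1_sq,
                 deltae_sq = res$trace_deltae_sq, size = as.numeric(res$trace_size))
  gw <- vapply(list(log_deltae_sq = log(traces$deltae_sq), pi = traces$pi,
                    size = traces$size), geweke_z, 0)
  fdr <- pip_fdr(setNames(res$pip, cluster_id), target = fdr_target)
  out <- list(pip = setNames(res$pip, cluster_id),
              beta_mean = setNames(res$beta_mean, cluster_id),
              beta_slab_mean = setNames(res$beta_slab_mean, cluster_id),
              alpha_mean = setNames(res$alpha_mean, colnames(C)),
              traces = traces,
              geweke = list(z = gw, converged = all(abs(gw) <= 1.96, na.rm = TRUE)),
              fdr_table = fdr$fdr_table, fdr_threshold = fdr$threshold,
              selected = fdr$selected, fdr_target = fdr_target,
              delta0_sq = delta0_sq, spec = spec, y_offset = y_offset,
              cluster_id = cluster_id, covariate_names = colnames(C),
              mcmc = list(iters = iters, burn_in = burn_in, thin = thin,
                          seed = seed, n_kept = res$n_kept))
  class(out) <- "bvs_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bvs_fit <- function(x, ...) {
  cat(sprintf("<bvs_fit> %d clusters; %d selected at FDR <= %.2g; Geweke %s\n",
              length(x$pip), length(x$selected), x$fdr_target,
              if (x$geweke$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' PIP-based FDR selection
#'
#' For each candidate threshold t (the distinct PIP values, descending),
#' the Bayesian local FDR of selecting `{i : PIP_i >= t}` is the mean of
#' `1 - PIP` over that set. The selection is the largest such set with
#' FDR at or below `target`.
#'
#' @param pips named numeric vector of posterior inclusion probabilities.
#' @param target FDR target (default 0.1).
#' @return list: `threshold` (PIP cutoff; `Inf` when nothing is
#'   selectable), `selected` (names), `fdr_table` (data.frame `threshold`,
#'   `n_selected`, `fdr`).
#' @export
pip_fdr <- function(pips, target = 0.1) {
  if (!length(pips)) {
    return(list(threshold = Inf, selected = character(0),
                fdr_table = data.frame(threshold = numeric(0),
                                       n_selected = integer(0), fdr = numeric(0))))
  }
  stopifnot(all(pips >= 0 & pips <= 1))
  if (is.null(names(pips))) names(pips) <- seq_along(pips)
  thr <- sort(unique(pips), decreasing = TRUE)
  ord <- order(-pips)
  sorted <- pips[ord]
  cum_fdr <- cumsum(1 - sorted) / seq_along(sorted)
  n_at_thr <- vapply(thr, function(t) sum(sorted >= t), 0L)
  tab <- data.frame(threshold = thr, n_selected = n_at_thr,
                    fdr = cum_fdr[n_at_thr])
  ok <- which(tab$fdr <= target)
  if (!length(ok)) {
    return(list(threshold = Inf, selected = character(0), fdr_table = tab))
  }
  best <- ok[which.max(tab$n_selected[ok])]
  list(threshold = tab$threshold[best],
       selected = names(sorted)[seq_len(tab$n_selected[best])],
       fdr_table = tab)
}

#' Predict expression from a fitted model
#'
#' `yhat = C_new %*% alpha_mean + X_new %*% beta_mean` (posterior-mean
#' plug-in). Columns must align with the training matrix.
#'
#' @param object a `bvs_fit`.
#' @param C_new,X_new covariate and count matrices for new rows.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.bvs_fit <- function(object, C_new, X_new, ...) {
  if (ncol(X_new) != length(object$beta_mean)) {
    stop("X_new has ", ncol(X_new), " columns; model has ", length(object$beta_mean))
  }
  if (!is.null(colnames(X_new)) &&
      !identical(colnames(X_new), object$cluster_id)) {
    stop("X_new columns do not match training clusters; project onto training columns first")
  }
  if (ncol(C_new) != length(object$alpha_mean)) {
    stop("C_new has ", ncol(C_new), " columns; model has ", length(object$alpha_mean))
  }
  as.numeric(C_new %*% object$alpha_mean + X_new %*% object$beta_mean) + object$y_offset
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `first_frac` of a chain against the mean
#' of the last `last_frac`, with segment variances estimated by batch
#' means (10 batches per segment):
#' `z = (m_A - m_B) / sqrt(v_A/n_A + v_B/n_B)`. |z| <= 1.96 on all
#' monitored traces is taken as converged.
#'
#' @param trace numeric chain (length >= 20).
#' @param first_frac,last_frac segment fractions (defaults 0.1 and 0.5).
#' @return z score (0 for a constant chain; `Inf`-signed for zero-variance
#'   segments with unequal means).
#' @export
geweke_z <- function(trace, first_frac = 0.1, last_frac = 0.5) {
  n <- length(trace)
  if (n < 20) stop("trace too short for the Geweke diagnostic")
  a <- trace[seq_len(max(2, floor(first_frac * n)))]
  b <- trace[seq(n - max(2, floor(last_frac * n)) + 1, n)]
  seg_var <- function(x) {
    nb <- min(10L, length(x))
    batch <- cut(seq_along(x), nb, labels = FALSE)
    means <- tapply(x, batch, mean)
    # long-run variance estimate: batch size * var(batch means)
    (length(x) / nb) * var(as.numeric(means))
  }
  va <- seg_var(a); vb <- seg_var(b)
  denom <- sqrt(va / length(a) + vb / length(b))
  if (denom == 0) {
    if (mean(a) == mean(b)) return(0)
    return(sign(mean(a) - mean(b)) * Inf)
  }
  (mean(a) - mean(b)) / denom
}

#' Serialize a fit to TSV + JSON metadata
#'
#' @param fit a `bvs_fit`.
#' @param path output TSV path; metadata written alongside as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_bvs_fit <- function(fit, path) {
  tab <- data.frame(cluster_id = fit$cluster_id, pip = fit$pip,
                    beta_mean = fit$beta_mean, beta_slab_mean = fit$beta_slab_mean,
                    selected = fit$cluster_id %in% fit$selected)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(mcmc = fit$mcmc, delta0_sq = fit$delta0_sq,
               fdr_target = fit$fdr_target, fdr_threshold = fit$fdr_threshold,
               geweke_z = as.list(fit$geweke$z), converged = fit$geweke$converged,
               spec = fit$spec[c("q", "a_pi", "b_pi", "a1", "b1", "a_e", "b_e")])
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
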