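# Cross-validated selection of the k-mer size. Clusters and the
# prevalence filter are re-derived inside each training fold so no test
# promoter leaks into the feature definitions.

#' Assign rows to cross-validation folds
#'
#' `by_gene` deals shuffled rows round-robin; `by_pangene` /
#' `by_accession` deal shuffled groups, keeping all rows of a group in one
#' fold (no group spans train and test).
#'
#' @param promoters `promoter_set` (or data.frame with `gene_id`,
#'   `pangene_id`, `accession_id`).
#' @param scheme one of `"by_gene"`, `"by_pangene"`, `"by_accession"`.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return integer fold assignment (1..n_folds) per row.
#' @export
make_folds <- function(promoters, scheme = c("by_gene", "by_pangene", "by_accession"),
                       n_folds = 10, seed = 1) {
  scheme <- match.arg(scheme)
  n <- nrow(promoters)
  set.seed(seed)
  if (scheme == "by_gene") {
    return(sample(rep_len(seq_len(n_folds), n)))
  }
  grp <- if (scheme == "by_pangene") promoters$pangene_id else promoters$accession_id
  groups <- unique(grp)
  if (length(groups) < n_folds) {
    stop("fewer ", sub("by_", "", scheme), " groups (", length(groups),
         ") than folds (", n_folds, ")")
  }
  shuffled <- sample(groups)
  fold_of_group <- setNames(rep_len(seq_len(n_folds), length(shuffled)), shuffled)
  unname(fold_of_group[grp])
}

#' Cross-validated prediction accuracy over k-mer sizes
#'
#' For each k: within each fold, enumerates and clusters k-mers on the
#' training promoters only, builds the prevalence-filtered count matrix,
#' fits the spike-and-slab model, projects held-out promoters onto the
#' training clusters and predicts their expression. Per-fold R^2 is the
#' squared Pearson correlation between predicted and observed expression
#' (`r2 = "ss"` uses 1 - SSE/SST instead).
#'
#' @param promoters `promoter_set`.
#' @param expression data.frame `gene_id`, `expression`.
#' @param k_values integer k-mer sizes to evaluate.
#' @param scheme fold scheme, see [make_folds()].
#' @param spec a [bvs_spec()].
#' @param iters,burn_in,thin reduced MCMC schedule for CV (default
#'   3000/1000/2).
#' @param n_folds folds (default 10).
#' @param seed integer seed (folds and fits).
#' @param covariates passed to [build_count_matrix()].
#' @param min_prevalence cluster prevalence threshold.
#' @param r2 `"pearson"` (default) or `"ss"`.
#' @return data.frame `k`, `scheme`, `fold`, `r2`, plus a `summary`
#'   attribute (`k`, `mean_r2`).
#' @export
cv_r2 <- function(promoters, expression, k_values = 7:12,
                  scheme = "by_gene", spec = bvs_spec(), iters = 3000,
                  burn_in = 1000, thin = 2, n_folds = 10, seed = 1,
                  covariates = NULL, min_prevalence = 0.01,
                  r2 = c("pearson", "ss")) {
  r2 <- match.arg(r2)
  folds <- make_folds(promoters, scheme, n_folds, seed)
  m <- match(promoters$gene_id, expression$gene_id)
  if (anyNA(m)) stop("expression missing for some promoters")
  rows <- list()
  for (k in k_values) {
    for (f in seq_len(n_folds)) {
      train <- promoters[folds != f, , drop = FALSE]
      test <- promoters[folds == f, , drop = FALSE]
      class(train) <- class(test) <- class(promoters)
      enum <- enumerate_kmers(train, k)
      cl <- cluster_kmers(order_kmers(enum), k)
      mat <- tryCatch(
        build_count_matrix(cl, enum, train, expression, covariates = covariates,
                           min_prevalence = min_prevalence),
        error = function(e) NULL)
      if (is.null(mat)) next
      fit <- fit_bvs(mat, spec, iters = iters, burn_in = burn_in, thin = thin,
                     seed = seed + f)
      X_new <- count_in_promoters(cl, test, mat$retained_cluster_idx)
      genes_new <- rownames(X_new)
      C_new <- build_covariates_for_test(covariates, mat, test, genes_new)
      yhat <- predict(fit, C_new, X_new)
      yobs <- expression$expression[match(genes_new, expression$gene_id)]
      if (sd(yobs) == 0 || sd(yhat) == 0) {
        warning("fold ", f, " (k=", k, "): degenerate predictions/response; fold skipped")
        next
      }
      fold_r2 <- if (r2 == "pearson") cor(yhat, yobs)^2 else {
        1 - sum((yobs - yhat)^2) / sum((yobs - mean(yobs))^2)
      }
      rows[[length(rows) + 1L]] <- data.frame(k = k, scheme = scheme, fold = f,
                                              r2 = fold_r2)
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$k), function(d) {
    data.frame(k = d$k[1], mean_r2 = mean(d$r2))
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}

# Covariates for held-out rows. Pangene indicators are projected onto the
# training pangene levels (unseen pangenes get all-zero covariates, i.e.
# the grand baseline); an intercept carries over as an intercept.
build_covariates_for_test <- function(covariates, mat, test, genes_new) {
  if (is.null(covariates)) {
    return(matrix(1, length(genes_new), 1, dimnames = list(genes_new, "intercept")))
  }
  if (identical(covariates, "pangene")) {
    pan_new <- test$pangene_id[match(genes_new, test$gene_id)]
    levels_train <- colnames(mat$C)
    C_new <- matrix(0, length(genes_new), length(levels_train),
                    dimnames = list(genes_new, levels_train))
    hit <- match(pan_new, levels_train)
    has <- !is.na(hit)
    C_new[cbind(which(has), hit[has])] <- 1
    return(C_new)
  }
  mm <- match(genes_new, rownames(covariates))
  if (anyNA(mm)) stop("covariates missing for held-out genes")
  as.matrix(covariates)[mm, , drop = FALSE]
}

#' Pick the best k
#'
#' Argmax of mean R^2; ties go to the smaller k.
#'
#' @param results output of [cv_r2()] (or its `summary` attribute, or any
#'   data.frame with `k` and `mean_r2`).
#' @return the selected k (integer).
#' @export
select_k <- function(results) {
  summ <- attr(results, "summary")
  if (is.null(summ)) summ <- results
  if (!nrow(summ)) stop("no CV results")
  summ <- summ[order(summ$k), , drop = FALSE]
  summ$k[which.max(summ$mean_r2)]
}
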