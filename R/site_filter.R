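# Per-pangene functional-site filtering of significant k-mer clusters.
# A cluster's global effect averages over all its genomic occurrences,
# functional or not; regressing expression on its occurrence count within
# each pangene isolates the loci where the site actually acts.

#' Per-pangene effect of one cluster
#'
#' Ordinary least squares of expression on occurrence count within one
#' pangene, with a two-sided t-test on the slope.
#'
#' @param counts occurrence counts per gene of the pangene.
#' @param expr expression values per gene.
#' @return list `slope`, `se`, `p`, `n`; `NULL` when the pair is not
#'   testable (< 3 genes or zero count variance).
#' @export
per_pangene_effect <- function(counts, expr) {
  n <- length(counts)
  if (n < 3 || var(counts) == 0) return(NULL)
  if (var(expr) == 0) {
    # flat response: no effect, and no evidence against none
    return(list(slope = 0, se = 0, p = 1, n = n))
  }
  fit <- lm(expr ~ counts)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 2) return(NULL)
  list(slope = unname(cf[2, 1]), se = unname(cf[2, 2]),
       p = unname(cf[2, 4]), n = n)
}

#' Filter significant clusters to putative functional sites
#'
#' For each selected cluster and each pangene where the cluster occurs in
#' at least one member with varying counts, fits the per-pangene
#' regression. P-values are Benjamini-Hochberg adjusted across all tested
#' (cluster, pangene) pairs (global scope by default; `bh_scope =
#' "per_cluster"` adjusts within each cluster). A pair is retained when
#' `q < alpha` and the slope agrees in sign with the cluster's global
#' posterior-mean effect.
#'
#' @param fit a `bvs_fit` with a non-empty selected set.
#' @param matrix the `cluster_count_matrix` the fit used.
#' @param alpha FDR level for retention (default 0.05).
#' @param clusters optional cluster ids to test (default `fit$selected`).
#' @param bh_scope `"global"` or `"per_cluster"`.
#' @return data.frame `cluster_id`, `pangene_id`, `n_genes`, `slope`,
#'   `se`, `p`, `q`, `sign_concordant`, `retained`, with a
#'   `retention` attribute (per-cluster fraction of tested pangenes
#'   retained).
#' @export
filter_functional_sites <- function(fit, matrix, alpha = 0.05, clusters = NULL,
                                    bh_scope = c("global", "per_cluster")) {
  bh_scope <- match.arg(bh_scope)
  if (is.null(clusters)) clusters <- fit$selected
  if (!length(clusters)) stop("no selected clusters to filter")
  clusters <- intersect(clusters, colnames(matrix$X))
  pan_split <- split(seq_along(matrix$y), matrix$pangene_id)
  rows <- list()
  for (cl in clusters) {
    xj <- matrix$X[, cl]
    for (pg in names(pan_split)) {
      idx <- pan_split[[pg]]
      if (!any(xj[idx] > 0)) next
      eff <- per_pangene_effect(xj[idx], matrix$y[idx])
      if (is.null(eff)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cl, pangene_id = pg, n_genes = eff$n, slope = eff$slope,
        se = eff$se, p = eff$p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(cluster_id = character(0), pangene_id = character(0),
                      n_genes = integer(0), slope = numeric(0), se = numeric(0),
                      p = numeric(0), q = numeric(0), sign_concordant = logical(0),
                      retained = logical(0))
    attr(out, "retention") <- data.frame(cluster_id = character(0),
                                         n_tested = integer(0), n_retained = integer(0),
                                         retention = numeric(0))
    return(out)
  }
  tab <- do.call(rbind, rows)
  tab$q <- if (bh_scope == "global") {
    p.adjust(tab$p, "BH")
  } else {
    stats::ave(tab$p, tab$cluster_id, FUN = function(p) p.adjust(p, "BH"))
  }
  beta <- fit$beta_mean[tab$cluster_id]
  tab$sign_concordant <- sign(tab$slope) == sign(beta) & sign(beta) != 0
  tab$retained <- tab$q < alpha & tab$sign_concordant
  rownames(tab) <- NULL
  ret <- do.call(rbind, lapply(split(tab, tab$cluster_id), function(d) {
    data.frame(cluster_id = d$cluster_id[1], n_tested = nrow(d),
               n_retained = sum(d$retained), retention = mean(d$retained),
               stringsAsFactors = FALSE)
  }))
  rownames(ret) <- NULL
  attr(tab, "retention") <- ret
  tab
}
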