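# Pangene-level promoter-similarity and expression-variability metrics.

#' Alignment-free promoter similarity
#'
#' Number of distinct k-mers shared between two promoter sequences
#' (default k = 31). K-mers containing `N` are excluded. For two 2000 bp
#' promoters the score ranges from 0 to 1970 (= 2000 - 31 + 1).
#'
#' @param seq_a,seq_b DNA strings.
#' @param k k-mer size (default 31).
#' @return integer shared-k-mer count.
#' @export
promoter_similarity <- function(seq_a, seq_b, k = 31) {
  stopifnot(k >= 1)
  if (k > min(nchar(seq_a), nchar(seq_b))) {
    warning("k exceeds a sequence length; similarity is 0")
    return(0)
  }
  cpp_shared_kmers(seq_a, seq_b, as.integer(k))
}

#' Mean pairwise promoter similarity of one pangene
#'
#' Averages [promoter_similarity()] over all unordered pairs of the
#' pangene's promoters. The log2 value is `log2(mean score)`, with a mean
#' score of 0 reported as 0 (documented floor matching the scale's lower
#' bound).
#'
#' @param sequences character vector of >= 2 promoter sequences.
#' @param k k-mer size.
#' @return list with `mean_score` and `log2_similarity`.
#' @export
pangene_similarity <- function(sequences, k = 31) {
  n <- length(sequences)
  if (n < 2) stop("pangene similarity undefined for fewer than 2 promoters")
  total <- 0
  npair <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      total <- total + promoter_similarity(sequences[i], sequences[j], k)
      npair <- npair + 1L
    }
  }
  mean_score <- total / npair
  list(mean_score = mean_score,
       log2_similarity = if (mean_score > 0) log2(mean_score) else 0)
}

#' Expression variability of one pangene
#'
#' `log10(CV^2)` of the pangene members' `log2(TPM+1)` values, with CV the
#' sample standard deviation over the mean. Values are clamped at a floor
#' of -6 (invariant pangenes) and pangenes with mean 0 are flagged silent
#' (`NA`).
#'
#' @param values numeric vector (>= 2) of `log2(TPM+1)` per gene.
#' @param floor lower clamp for `log10(CV^2)`.
#' @return `log10(CV^2)` (scalar; `NA` for silent pangenes).
#' @export
expression_cv <- function(values, floor = -6) {
  if (length(values) < 2) stop("need >= 2 expression values")
  m <- mean(values)
  if (m == 0) return(NA_real_)  # silent pangene
  cv2 <- (sd(values) / m)^2
  if (cv2 <= 0) return(floor)
  max(floor, log10(cv2))
}

#' Summarise promoter and expression variation per pangene
#'
#' Convenience wrapper computing, for every pangene with >= 2 members,
#' `n_genes`, mean expression, mean pairwise similarity, `log2` similarity
#' and `log10(CV^2)`.
#'
#' @param promoters a `promoter_set`.
#' @param expression data.frame `gene_id`, `expression`.
#' @param k k-mer size for similarity (default 31).
#' @return data.frame, one row per pangene.
#' @export
pangene_variation <- function(promoters, expression, k = 31) {
  m <- match(promoters$gene_id, expression$gene_id)
  if (anyNA(m)) stop("expression missing for gene(s): ",
                     paste(head(promoters$gene_id[is.na(m)], 5), collapse = ", "))
  expr <- expression$expression[m]
  out <- lapply(split(seq_len(nrow(promoters)), promoters$pangene_id), function(idx) {
    if (length(idx) < 2) return(NULL)
    sim <- pangene_similarity(promoters$sequence[idx], k)
    data.frame(pangene_id = promoters$pangene_id[idx[1]], n_genes = length(idx),
               mean_expr = mean(expr[idx]), similarity = sim$mean_score,
               log2_similarity = sim$log2_similarity,
               log10_cv2 = expression_cv(expr[idx]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Decorrelate expression variability from mean expression
#'
#' Subtracts from each pangene's `log10(CV^2)` the expected value at its
#' mean expression, estimated as a centred running median over pangenes
#' ordered by mean expression (window shrinking symmetrically at the
#' edges). Removes the systematic decay of CV^2 with expression level.
#'
#' @param table data.frame with columns `mean_expr` and `log10_cv2`
#'   (e.g. from [pangene_variation()]).
#' @param window odd window width; default `max(101, 1%)` of the pangene
#'   count, capped at the table size.
#' @return the table with an added `norm_log10_cv2` column.
#' @export
normalize_cv <- function(table, window = NULL) {
  n <- nrow(table)
  ok <- !is.na(table$log10_cv2)
  table$norm_log10_cv2 <- NA_real_
  nn <- sum(ok)
  if (nn < 3) {
    warning("fewer than 3 pangenes; normalization is the identity")
    table$norm_log10_cv2[ok] <- table$log10_cv2[ok]
    return(table)
  }
  if (is.null(window)) window <- max(101, ceiling(0.01 * nn))
  window <- min(window, nn)
  if (window %% 2 == 0) window <- window - 1L
  ord <- order(table$mean_expr[ok])
  x <- table$log10_cv2[ok][ord]
  expected <- if (window >= 3) {
    as.numeric(runmed(x, window, endrule = "median"))
  } else x
  norm <- x - expected
  idx <- which(ok)[ord]
  table$norm_log10_cv2[idx] <- norm
  table
}

#' Select highly variable pangenes
#'
#' Drops small (fewer than `min_genes` members) and weakly expressed
#' (`mean_expr < min_expr`) pangenes, then flags as highly variable (hv)
#' those in the lowest `top_fraction` quantile of `log2` similarity (most
#' dissimilar promoters) AND the highest `top_fraction` quantile of
#' normalized `log10(CV^2)`. The complementary least-variable (lv) set uses
#' the opposite tails. Quantiles use linear interpolation (type 7) and
#' inclusive comparisons.
#'
#' @param table output of [normalize_cv()].
#' @param top_fraction fraction in (0,1) defining the variable tails.
#' @param min_genes minimum pangene size (default 6: pangenes with fewer
#'   members are excluded).
#' @param min_expr minimum mean `log2(TPM+1)` (default 1).
#' @return the filtered table with logical columns `hv_flag`, `lv_flag`.
#' @export
select_hv <- function(table, top_fraction = 0.30, min_genes = 6, min_expr = 1.0) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  keep <- table$n_genes >= min_genes & table$mean_expr >= min_expr &
    !is.na(table$norm_log10_cv2)
  tab <- table[keep, , drop = FALSE]
  if (nrow(tab) == 0) {
    warning("no pangenes pass the size/expression filters")
    tab$hv_flag <- logical(0)
    tab$lv_flag <- logical(0)
    return(tab)
  }
  q_sim_lo <- quantile(tab$log2_similarity, top_fraction, type = 7, names = FALSE)
  q_sim_hi <- quantile(tab$log2_similarity, 1 - top_fraction, type = 7, names = FALSE)
  q_cv_hi <- quantile(tab$norm_log10_cv2, 1 - top_fraction, type = 7, names = FALSE)
  q_cv_lo <- quantile(tab$norm_log10_cv2, top_fraction, type = 7, names = FALSE)
  tab$hv_flag <- tab$log2_similarity <= q_sim_lo & tab$norm_log10_cv2 >= q_cv_hi
  tab$lv_flag <- tab$log2_similarity >= q_sim_hi & tab$norm_log10_cv2 <= q_cv_lo
  rownames(tab) <- NULL
  tab
}

#' Bootstrap comparison of two group means
#'
#' Resamples each group with replacement `n_boot` times and reports the
#' bootstrap distribution of the difference in means (a - b) with a
#' percentile confidence interval.
#'
#' @param group_a,group_b numeric vectors.
#' @param n_boot bootstrap replicates (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return list with `mean_diff`, `ci` (length-2), `boot_a`, `boot_b`,
#'   `boot_diff`.
#' @export
bootstrap_mean_ci <- function(group_a, group_b, n_boot = 10000, conf = 0.95,
                              seed = NULL) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  if (n_boot < 100) warning("n_boot < 100 gives unstable percentile intervals")
  if (!is.null(seed)) set.seed(seed)
  na <- length(group_a); nb <- length(group_b)
  boot_a <- vapply(seq_len(n_boot), function(i) mean(group_a[sample.int(na, na, TRUE)]), 0)
  boot_b <- vapply(seq_len(n_boot), function(i) mean(group_b[sample.int(nb, nb, TRUE)]), 0)
  d <- boot_a - boot_b
  alpha <- (1 - conf) / 2
  list(mean_diff = mean(group_a) - mean(group_b),
       ci = quantile(d, c(alpha, 1 - alpha), names = FALSE),
       boot_a = boot_a, boot_b = boot_b, boot_diff = d)
}
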