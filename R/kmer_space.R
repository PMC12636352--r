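# K-mer enumeration, deterministic one-mismatch clustering, and the
# prevalence-filtered cluster count matrix.

#' Enumerate promoter k-mers
#'
#' Slides a stride-1 window of width `k` over every promoter (forward
#' strand of the oriented promoter); windows containing `N` are skipped.
#' Per-occurrence positions are retained for downstream peak-overlap
#' analysis.
#'
#' @param promoters a `promoter_set` (or data.frame with `gene_id`,
#'   `sequence`).
#' @param k k-mer size (1-31).
#' @return object of class `kmer_enumeration`: list with `kmer` (unique
#'   k-mers), `count` (total pan-genome occurrences), `occurrences`
#'   (data.frame `seq_idx` = promoter row index, `kmer_idx`, `pos` with
#'   0-based promoter offsets), `k`, `gene_ids` (per `seq_idx`).
#' @export
enumerate_kmers <- function(promoters, k) {
  k <- as.integer(k)
  lens <- nchar(promoters$sequence)
  if (k > max(lens)) stop("k is larger than every promoter")
  res <- cpp_enumerate_kmers(promoters$sequence, k)
  if (!length(res$kmer)) stop("no valid k-mer windows found")
  out <- list(kmer = res$kmer, count = res$count,
              occurrences = data.frame(seq_idx = res$occ_seq,
                                       kmer_idx = res$occ_kmer, pos = res$occ_pos),
              k = k, gene_ids = promoters$gene_id)
  class(out) <- "kmer_enumeration"
  out
}

#' Order k-mers for clustering
#'
#' Descending total count, ties broken by ascending lexicographic order.
#' The deterministic ordering makes greedy clustering reproducible.
#'
#' @param enum a `kmer_enumeration`, or a named numeric vector of counts.
#' @return data.frame `kmer`, `count` in clustering order.
#' @export
order_kmers <- function(enum) {
  if (inherits(enum, "kmer_enumeration")) {
    kmer <- enum$kmer; count <- enum$count
  } else {
    kmer <- names(enum); count <- as.numeric(enum)
  }
  if (!length(kmer)) stop("no k-mers to order")
  ord <- order(-count, kmer, method = "radix")
  data.frame(kmer = kmer[ord], count = count[ord], stringsAsFactors = FALSE)
}

#' Greedy one-mismatch k-mer clustering
#'
#' Scans k-mers in the given order; each k-mer joins the earliest-founded
#' cluster whose representative is within Hamming distance 1 (no indels),
#' otherwise it founds a new cluster with itself as representative. With
#' equal-length words, an identity threshold of `1 - 1/k` permits exactly
#' one substitution, which this rule reproduces deterministically.
#' Membership is decided against the representative only, so a k-mer at
#' distance 2 from the representative founds its own cluster even if it is
#' within distance 1 of another member.
#'
#' @param ordered data.frame from [order_kmers()] (columns `kmer`,
#'   `count`), or a character vector of k-mers in clustering order.
#' @param k k-mer size; all k-mers must have this length.
#' @return object of class `kmer_clusters`: list with `members`
#'   (data.frame `kmer`, `count`, `cluster`), `representative` (character,
#'   per cluster in founding order), `cluster_id`, `k`.
#' @export
cluster_kmers <- function(ordered, k) {
  if (is.character(ordered)) ordered <- data.frame(kmer = ordered, count = 1,
                                                   stringsAsFactors = FALSE)
  k <- as.integer(k)
  if (any(nchar(ordered$kmer) != k)) stop("all k-mers must have length k")
  res <- cpp_cluster_kmers(ordered$kmer, k)
  n_cl <- length(res$rep_idx)
  out <- list(members = data.frame(kmer = ordered$kmer, count = ordered$count,
                                   cluster = res$cluster, stringsAsFactors = FALSE),
              representative = ordered$kmer[res$rep_idx],
              cluster_id = sprintf("cluster_%d", seq_len(n_cl)),
              k = k)
  class(out) <- "kmer_clusters"
  out
}

#' @export
print.kmer_clusters <- function(x, ...) {
  cat(sprintf("<kmer_clusters> k=%d: %d k-mers in %d clusters\n",
              x$k, nrow(x$members), length(x$representative)))
  invisible(x)
}

# Map each unique k-mer of an enumeration to a cluster index (0 = none).
match_kmers_to_clusters <- function(clusters, enum_kmers, assign_new = FALSE) {
  idx <- match(enum_kmers, clusters$members$kmer)
  cl <- ifelse(is.na(idx), 0L, clusters$members$cluster[idx])
  if (assign_new && any(cl == 0L)) {
    new <- which(cl == 0L)
    cl[new] <- cpp_assign_kmers(clusters$representative, enum_kmers[new], clusters$k)
  }
  cl
}

#' Build the cluster count matrix
#'
#' Entry (i, j) is the total number of occurrences in promoter i of all
#' member k-mers of cluster j. Clusters present in a fraction of promoters
#' `<= min_prevalence` are dropped (strictly-greater retention rule).
#' Rows are canonicalized by gene-id sort and aligned with the response
#' `y` (expression) and covariates `C`.
#'
#' @param clusters a `kmer_clusters`.
#' @param enum the `kmer_enumeration` the clusters were built from (or one
#'   recomputed on the same promoters).
#' @param promoters the `promoter_set` (row annotations).
#' @param expression data.frame `gene_id`, `expression`; promoters without
#'   an expression value are dropped with a warning.
#' @param covariates optional numeric matrix (rows aligned to promoters by
#'   `gene_id` rownames) or the string `"pangene"` for per-pangene
#'   indicator covariates; default is an intercept column.
#' @param min_prevalence prevalence threshold (default 0.01).
#' @return object of class `cluster_count_matrix`: list with `X` (genes x
#'   clusters count matrix), `y`, `C`, `gene_id`, `pangene_id`,
#'   `accession_id`, `cluster_id`, `representative`, `k`.
#' @export
build_count_matrix <- function(clusters, enum, promoters, expression,
                               covariates = NULL, min_prevalence = 0.01) {
  if (!identical(enum$gene_ids, promoters$gene_id)) {
    stop("enum was not built from these promoters (gene_id mismatch)")
  }
  m <- match(promoters$gene_id, expression$gene_id)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " promoter(s) without expression dropped")
  }
  keep_idx <- which(!is.na(m))
  ord <- keep_idx[order(promoters$gene_id[keep_idx], method = "radix")]
  genes <- promoters$gene_id[ord]
  y <- expression$expression[m[ord]]
  pan <- promoters$pangene_id[ord]
  acc <- promoters$accession_id[ord]
  row_of_seq <- integer(nrow(promoters))  # promoter row -> X row (0 = dropped)
  row_of_seq[ord] <- seq_along(ord)

  cl_of_kmer <- match_kmers_to_clusters(clusters, enum$kmer)
  n_cl <- length(clusters$representative)
  agg <- cpp_count_pairs(enum$occurrences$seq_idx, enum$occurrences$kmer_idx,
                         cl_of_kmer, row_of_seq, n_cl)

  n <- length(genes)
  retained <- which(agg$prevalence / n > min_prevalence)
  if (!length(retained)) stop("no clusters pass the prevalence filter")

  keep <- agg$cluster %in% retained
  col_of_cluster <- integer(n_cl)
  col_of_cluster[retained] <- seq_along(retained)
  # sparse storage: after the prevalence filter the matrix stays large but
  # sparse at pan-genome scale
  X <- Matrix::sparseMatrix(i = agg$row[keep],
                            j = col_of_cluster[agg$cluster[keep]],
                            x = as.numeric(agg$n[keep]),
                            dims = c(n, length(retained)),
                            dimnames = list(genes, clusters$cluster_id[retained]))

  C <- build_covariates(covariates, genes, pan)
  out <- list(X = X, y = y, C = C, gene_id = genes, pangene_id = pan,
              accession_id = acc, cluster_id = clusters$cluster_id[retained],
              representative = clusters$representative[retained],
              retained_cluster_idx = retained, k = clusters$k)
  class(out) <- "cluster_count_matrix"
  out
}

build_covariates <- function(covariates, genes, pan) {
  n <- length(genes)
  if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(genes, "intercept"))
  } else if (identical(covariates, "pangene")) {
    f <- factor(pan)
    C <- matrix(0, n, nlevels(f), dimnames = list(genes, levels(f)))
    C[cbind(seq_len(n), as.integer(f))] <- 1
    C
  } else {
    if (is.null(rownames(covariates))) stop("covariate matrix needs gene_id rownames")
    mm <- match(genes, rownames(covariates))
    if (anyNA(mm)) stop("covariates missing for some genes")
    as.matrix(covariates)[mm, , drop = FALSE]
  }
}

#' @export
print.cluster_count_matrix <- function(x, ...) {
  cat(sprintf("<cluster_count_matrix> %d genes x %d clusters (k=%d), %d covariate column(s)\n",
              nrow(x$X), ncol(x$X), x$k, ncol(x$C)))
  invisible(x)
}

#' Count cluster occurrences in new promoters
#'
#' Projects promoters onto an existing cluster set: each k-mer window is
#' assigned to the earliest cluster whose representative is within Hamming
#' distance 1 (same rule as training); unassigned k-mers contribute 0.
#' Used to score held-out promoters in cross-validation.
#'
#' @param clusters a `kmer_clusters`.
#' @param promoters new `promoter_set`.
#' @param retained_cluster_idx integer cluster indices defining the columns
#'   (e.g. from a `cluster_count_matrix`).
#' @return count matrix, rows = gene_id (sorted), columns = retained clusters.
#' @export
count_in_promoters <- function(clusters, promoters, retained_cluster_idx) {
  enum <- enumerate_kmers(promoters, clusters$k)
  cl_of_kmer <- match_kmers_to_clusters(clusters, enum$kmer, assign_new = TRUE)
  genes <- sort(unique(promoters$gene_id))
  occ <- data.table::data.table(
    gene = match(promoters$gene_id[enum$occurrences$seq_idx], genes),
    cluster = cl_of_kmer[enum$occurrences$kmer_idx])
  X <- matrix(0, nrow = length(genes), ncol = length(retained_cluster_idx),
              dimnames = list(genes, clusters$cluster_id[retained_cluster_idx]))
  occ <- occ[cluster %in% retained_cluster_idx]
  if (nrow(occ)) {
    agg <- occ[, .(n = .N), by = .(gene, cluster)]
    X[cbind(agg$gene, match(agg$cluster, retained_cluster_idx))] <- agg$n
  }
  X
}

utils::globalVariables(c("cluster", "kmer_idx", "gene_id", "npres", "row",
                         "gene", ".", ".N"))
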