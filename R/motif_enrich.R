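# Motif enrichment of significant k-mer clusters: cluster-derived PWMs, an
# exact-p-value log-odds scanner, permutation enrichment against a motif
# library, and peak-overlap enrichment against interval sets.

DNA_BASES <- c("A", "C", "G", "T")

#' Read a MEME-format motif library
#'
#' Parses minimal MEME text format: `MOTIF` blocks with
#' `letter-probability matrix` sections over the ACGT alphabet.
#'
#' @param path MEME file path.
#' @return list of PWMs; each a list with `motif_id`, `width`, `prob`
#'   (4 x w matrix, rows ACGT), `background` (length-4, from the file's
#'   `Background letter frequencies` line when present, else uniform).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_idx <- grep("^Background letter frequencies", lines)
  if (length(bg_idx)) {
    for (off in 1:2) {
      if (bg_idx[1] + off > length(lines)) break
      tok <- strsplit(trimws(lines[bg_idx[1] + off]), "\\s+")[[1]]
      if (length(tok) >= 8 && all(DNA_BASES %in% tok[c(TRUE, FALSE)])) {
        vals <- suppressWarnings(as.numeric(tok[c(FALSE, TRUE)]))
        names(vals) <- tok[c(TRUE, FALSE)]
        bg <- unname(vals[DNA_BASES])
        break
      }
    }
  }
  motif_at <- grep("^MOTIF", lines)
  if (!length(motif_at)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (i in seq_along(motif_at)) {
    id <- strsplit(trimws(lines[motif_at[i]]), "\\s+")[[1]][2]
    block_end <- if (i < length(motif_at)) motif_at[i + 1] - 1 else length(lines)
    block <- lines[motif_at[i]:block_end]
    lp <- grep("letter-probability matrix", block)
    if (!length(lp)) stop("motif ", id, " lacks a letter-probability matrix")
    rows <- list()
    for (ln in block[-seq_len(lp[1])]) {
      tok <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (length(tok) == 4 && !anyNA(tok)) rows[[length(rows) + 1L]] <- tok
      else if (length(rows)) break
    }
    if (!length(rows)) stop("motif ", id, ": empty probability matrix")
    prob <- t(do.call(rbind, rows))
    rownames(prob) <- DNA_BASES
    out[[id]] <- list(motif_id = id, width = ncol(prob), prob = prob,
                      background = bg)
  }
  out
}

#' Build a PWM from a k-mer cluster
#'
#' Position-wise base counts of the cluster's member k-mers, weighted by
#' their pan-genome frequencies, plus a pseudocount, normalized per
#' column.
#'
#' @param cluster either a `kmer_clusters` element view (data.frame with
#'   `kmer`, `count`) or a named numeric vector of member frequencies.
#' @param pseudocount added to every cell before normalization.
#' @param motif_id identifier for the resulting PWM.
#' @param background background base probabilities (default uniform).
#' @return a PWM list as from [read_meme()].
#' @export
cluster_pwm <- function(cluster, pseudocount = 0.01, motif_id = "cluster",
                        background = rep(0.25, 4)) {
  if (is.data.frame(cluster)) {
    kmers <- cluster$kmer; w8 <- cluster$count
  } else {
    kmers <- names(cluster); w8 <- as.numeric(cluster)
  }
  if (!length(kmers) || sum(w8) <= 0) stop("cluster has zero total frequency")
  k <- nchar(kmers[1])
  stopifnot(all(nchar(kmers) == k))
  mat <- matrix(pseudocount, 4, k, dimnames = list(DNA_BASES, NULL))
  chars <- strsplit(kmers, "")
  for (i in seq_along(kmers)) {
    for (j in seq_len(k)) {
      mat[chars[[i]][j], j] <- mat[chars[[i]][j], j] + w8[i]
    }
  }
  prob <- sweep(mat, 2, colSums(mat), "/")
  list(motif_id = motif_id, width = k, prob = prob,
       background = background / sum(background))
}

pwm_logodds <- function(pwm) {
  log2(pwm$prob / pwm$background)
}

#' Exact log-odds score threshold for a target p-value
#'
#' Computes the exact null distribution of the PWM log-odds score of a
#' random w-mer drawn from the background, by dynamic programming over
#' positions on an integer-discretized score grid (bin width = score
#' range / `n_bins`). The threshold is the smallest discretized score
#' whose tail probability is at most `p_target`.
#'
#' @param pwm a PWM list.
#' @param p_target target p-value (default 1e-4, the usual scan cutoff).
#' @param n_bins discretization bins over the score range (default 10000).
#' @return list `threshold` (log-odds score), `p_attained` (tail
#'   probability at the threshold), `score_grid`, `tail_prob` (the full
#'   discretized null tail), `bin_width`.
#' @export
pwm_threshold <- function(pwm, p_target = 1e-4, n_bins = 10000) {
  stopifnot(p_target > 0, p_target <= 1)
  lo <- pwm_logodds(pwm)
  w <- ncol(lo)
  rng <- sum(apply(lo, 2, max)) - sum(apply(lo, 2, min))
  bw <- if (rng > 0) rng / n_bins else 1
  ints <- round(lo / bw)  # integer score per (base, position)
  mins <- apply(ints, 2, min)
  maxs <- apply(ints, 2, max)
  offset <- sum(mins)
  size <- sum(maxs - mins) + 1L
  dist <- numeric(size)  # dist[i+1] = P(int score = offset + i)
  dist[1] <- 1
  reach <- 1L
  for (j in seq_len(w)) {
    new <- numeric(size)
    for (b in 1:4) {
      sh <- ints[b, j] - mins[j]
      if (pwm$background[b] == 0) next
      idx <- seq_len(reach)
      new[idx + sh] <- new[idx + sh] + dist[idx] * pwm$background[b]
    }
    dist <- new
    reach <- min(size, reach + max(maxs[j] - mins[j], 0L))
  }
  tail_p <- rev(cumsum(rev(dist)))
  grid <- (offset + seq_len(size) - 1L) * bw
  ok <- which(tail_p <= p_target)
  if (!length(ok)) {
    thr <- grid[size] + bw  # nothing reaches p_target; threshold above max
    pat <- 0
  } else {
    thr <- grid[ok[1]]
    pat <- tail_p[ok[1]]
  }
  if (p_target >= 1) { thr <- grid[1]; pat <- 1 }
  list(threshold = thr, p_attained = pat, score_grid = grid,
       tail_prob = tail_p, bin_width = bw)
}

score_word <- function(lo, word) {
  idx <- match(strsplit(word, "")[[1]], DNA_BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(lo[cbind(idx, seq_along(idx))])
}

#' Scan a k-mer against a PWM
#'
#' Scores all alignments of the shorter of (k-mer, PWM) within the longer,
#' on both strands (TF binding is strand-agnostic), and reports the best
#' log-odds score. Matched means best score at or above `threshold`.
#' K-mers with non-ACGT bases never match.
#'
#' @param pwm a PWM list.
#' @param kmer DNA string.
#' @param threshold log-odds threshold, e.g. from [pwm_threshold()].
#' @return list `matched` (logical), `best_score`.
#' @export
scan_kmer <- function(pwm, kmer, threshold) {
  lo <- pwm_logodds(pwm)
  w <- ncol(lo)
  best <- -Inf
  for (word in c(kmer, revcomp(kmer))) {
    n <- nchar(word)
    if (n >= w) {
      for (off in 0:(n - w)) {
        s <- score_word(lo, substr(word, off + 1, off + w))
        if (!is.na(s) && s > best) best <- s
      }
    } else {
      # k-mer shorter than the motif: slide it along the motif columns
      for (off in 0:(w - n)) {
        s <- score_word(lo[, (off + 1):(off + n), drop = FALSE], word)
        if (!is.na(s) && s > best) best <- s
      }
    }
  }
  list(matched = is.finite(best) && best >= threshold, best_score = best)
}

cluster_members_list <- function(clusters, ids = NULL) {
  memb <- split(clusters$members$kmer, clusters$members$cluster)
  names(memb) <- clusters$cluster_id[as.integer(names(memb))]
  if (!is.null(ids)) memb <- memb[ids]
  memb
}

# Which clusters have >= 1 member matching >= 1 library motif.
clusters_matching_library <- function(member_list, motif_library, p_target = 1e-4) {
  thresholds <- lapply(motif_library, pwm_threshold, p_target = p_target)
  all_kmers <- unique(unlist(member_list, use.names = FALSE))
  kmer_hit <- setNames(logical(length(all_kmers)), all_kmers)
  for (mi in seq_along(motif_library)) {
    pwm <- motif_library[[mi]]
    thr <- thresholds[[mi]]$threshold
    todo <- names(kmer_hit)[!kmer_hit]
    if (!length(todo)) break
    hits <- vapply(todo, function(km) scan_kmer(pwm, km, thr)$matched, TRUE)
    kmer_hit[todo[hits]] <- TRUE
  }
  vapply(member_list, function(kms) any(kmer_hit[kms]), TRUE)
}

#' Permutation enrichment of significant clusters for library motifs
#'
#' Observed statistic: number of significant clusters with at least one
#' member k-mer matching at least one library motif at the exact-p scan
#' threshold. The null redraws `|sig|` clusters uniformly without
#' replacement from the full model cluster set `n_iter` times. The
#' empirical p-value uses the +1 correction:
#' `p = (1 + #{null >= observed}) / (1 + n_iter)`.
#'
#' @param sig_ids significant cluster ids.
#' @param clusters the `kmer_clusters` object.
#' @param all_ids the full set of model cluster ids (the sampling frame).
#' @param motif_library list of PWMs from [read_meme()].
#' @param p_target scan p-value threshold (default 1e-4).
#' @param n_iter permutations (default 10000).
#' @param seed integer seed.
#' @return list `observed`, `fold` (observed / null mean), `p_empirical`,
#'   `null_mean`, `null_sd`, `null_quantiles`, `n_iter`, `seed`, and the
#'   per-cluster `matched` flags.
#' @export
permutation_enrichment <- function(sig_ids, clusters, all_ids, motif_library,
                                   p_target = 1e-4, n_iter = 10000, seed = 1) {
  if (!length(motif_library)) stop("empty motif library")
  stopifnot(all(sig_ids %in% all_ids))
  memb <- cluster_members_list(clusters, all_ids)
  hit <- clusters_matching_library(memb, motif_library, p_target)
  observed <- sum(hit[sig_ids])
  set.seed(seed)
  ns <- length(sig_ids)
  null <- vapply(seq_len(n_iter), function(i) {
    sum(hit[sample(all_ids, ns, replace = FALSE)])
  }, 0)
  list(observed = observed,
       fold = if (mean(null) > 0) observed / mean(null) else NA_real_,
       p_empirical = (1 + sum(null >= observed)) / (1 + n_iter),
       null_mean = mean(null), null_sd = sd(null),
       null_quantiles = quantile(null, c(0.025, 0.5, 0.975)),
       n_iter = n_iter, seed = seed, matched = hit)
}

#' Genomic intervals of cluster occurrences
#'
#' Maps every member-k-mer occurrence (promoter offset) back to genome
#' coordinates using each promoter's interval. For a + strand promoter at
#' `[start, end)`, offset o gives `[start+o, start+o+k)`; for a - strand
#' promoter (sequence was reverse-complemented at extraction), the
#' arithmetic mirrors to `[end-o-k, end-o)`.
#'
#' @param clusters a `kmer_clusters`.
#' @param enum the matching `kmer_enumeration` (carries offsets).
#' @param promoters `promoter_set` with interval columns (`contig`,
#'   `start`, `end`, `strand`); promoters lacking an interval are skipped
#'   with a warning.
#' @param ids cluster ids to locate (default: all).
#' @return data.frame `cluster_id`, `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open genomic intervals).
#' @export
occurrence_positions <- function(clusters, enum, promoters, ids = NULL) {
  if (is.null(promoters$contig)) stop("promoters carry no genomic intervals")
  if (!identical(enum$gene_ids, promoters$gene_id)) {
    stop("enum was not built from these promoters (gene_id mismatch)")
  }
  cl_of_kmer <- match_kmers_to_clusters(clusters, enum$kmer)
  occ <- enum$occurrences
  keep_cl <- if (is.null(ids)) cl_of_kmer > 0 else
    clusters$cluster_id[pmax(cl_of_kmer, 1)] %in% ids & cl_of_kmer > 0
  occ <- occ[keep_cl[occ$kmer_idx], , drop = FALSE]
  pm <- occ$seq_idx
  has_loc <- !is.na(promoters$contig[pm])
  if (any(!has_loc)) {
    warning(sum(!has_loc), " occurrence(s) on promoters without intervals skipped")
    occ <- occ[has_loc, , drop = FALSE]
    pm <- pm[has_loc]
  }
  k <- enum$k
  plus <- promoters$strand[pm] == "+"
  gstart <- ifelse(plus, promoters$start[pm] + occ$pos,
                   promoters$end[pm] - occ$pos - k)
  data.frame(cluster_id = clusters$cluster_id[cl_of_kmer[occ$kmer_idx]],
             gene_id = promoters$gene_id[pm], contig = promoters$contig[pm],
             start = gstart, end = gstart + k, stringsAsFactors = FALSE)
}

# Fraction of each cluster's occurrences overlapping >= 1 peak (any shared
# base, half-open semantics).
overlap_fraction <- function(occ, peaks) {
  if (!nrow(occ)) return(numeric(0))
  q <- GenomicRanges::GRanges(occ$contig,
                              IRanges::IRanges(occ$start + 1L, occ$end))
  s <- GenomicRanges::GRanges(peaks$contig,
                              IRanges::IRanges(peaks$start + 1L, peaks$end))
  hit <- IRanges::overlapsAny(q, s)
  vapply(split(hit, occ$cluster_id), mean, 0)
}

#' Peak-overlap enrichment of significant clusters
#'
#' For each cluster, the fraction of its occurrences whose genomic
#' interval intersects at least one peak. Clusters are binned at
#' `bin_threshold` (strictly greater = high-confidence bin) and the fold
#' enrichment is `P(significant cluster in high bin) / P(model cluster in
#' high bin)`, with a percentile bootstrap CI resampling clusters within
#' each group.
#'
#' @param sig_ids significant cluster ids.
#' @param all_ids full model cluster ids (the comparison group).
#' @param occurrences data.frame from [occurrence_positions()] covering at
#'   least `all_ids`.
#' @param peaks interval data.frame from [read_bed()] (0-based half-open).
#' @param bin_threshold high-bin cutoff on the overlap fraction
#'   (default 0.20, strict >).
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list `fraction` (per cluster), `high_bin` (logical per
#'   cluster), `rate_sig`, `rate_all`, `fold`, `ci`, `n_boot`, `seed`.
#' @export
peak_overlap_enrichment <- function(sig_ids, all_ids, occurrences, peaks,
                                    bin_threshold = 0.20, n_boot = 1000,
                                    conf = 0.95, seed = 1) {
  frac <- overlap_fraction(occurrences[occurrences$cluster_id %in% all_ids, ,
                                       drop = FALSE], peaks)
  missing <- setdiff(all_ids, names(frac))
  if (length(missing)) {
    warning(length(missing), " cluster(s) with zero located occurrences excluded")
  }
  high <- frac > bin_threshold
  sig <- intersect(sig_ids, names(frac))
  all_present <- intersect(all_ids, names(frac))
  rate_sig <- mean(high[sig])
  rate_all <- mean(high[all_present])
  fold <- if (rate_all > 0) rate_sig / rate_all else NA_real_
  set.seed(seed)
  alpha <- (1 - conf) / 2
  boot <- vapply(seq_len(n_boot), function(i) {
    rs <- mean(high[sample(sig, length(sig), replace = TRUE)])
    ra <- mean(high[sample(all_present, length(all_present), replace = TRUE)])
    if (ra > 0) rs / ra else NA_real_
  }, 0)
  list(fraction = frac, high_bin = high, rate_sig = rate_sig,
       rate_all = rate_all, fold = fold,
       ci = quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE),
       n_boot = n_boot, seed = seed)
}
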