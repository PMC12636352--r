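# Independent brute-force oracles and small fixture builders shared by the
# test files. Everything here is deliberately naive and separate from the
# package's own code paths.

# all k-mers of a string by plain substring extraction (N windows dropped)
naive_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- vapply(seq_len(n - k + 1), function(i) substr(s, i, i + k - 1), "")
  km[!grepl("[^ACGT]", km)]
}

naive_shared <- function(a, b, k) {
  length(intersect(unique(naive_kmers(a, k)), unique(naive_kmers(b, k))))
}

naive_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

make_promoters <- function(seqs, pangene = NULL, accession = NULL) {
  n <- length(seqs)
  df <- data.frame(
    pangene_id = pangene %||% sprintf("pan%03d", seq_len(n)),
    accession_id = accession %||% sprintf("acc%02d", seq_len(n)),
    gene_id = sprintf("g%03d", seq_len(n)),
    sequence = seqs, stringsAsFactors = FALSE)
  class(df) <- c("promoter_set", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact posterior inclusion probabilities for the spike-and-slab model with
# all hyperparameters fixed (point-mass priors), no covariates, by
# enumerating the 2^p inclusion configurations and integrating beta
# analytically: y | gamma ~ N(0, X D X' + de2 I).
enumerate_pips <- function(y, X, d02, d12, de2, pi) {
  n <- length(y)
  p <- ncol(X)
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  logw <- apply(configs, 1, function(g) {
    D <- diag(ifelse(g == 1, d12, d02), p)
    S <- X %*% D %*% t(X) + de2 * diag(n)
    as.numeric(mvtnorm_logd(y, S)) + sum(g) * log(pi) + (p - sum(g)) * log(1 - pi)
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  as.numeric(t(configs) %*% w)
}

mvtnorm_logd <- function(y, S) {
  ch <- chol(S)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, y, transpose = TRUE)^2))
}

# brute-force PWM score tail over all 4^w words, on the same integer grid
# the DP uses
brute_pwm_tail <- function(pwm, bin_width) {
  lo <- log2(pwm$prob / pwm$background)
  ints <- round(lo / bin_width)
  w <- ncol(lo)
  words <- expand.grid(rep(list(1:4), w))
  scores <- apply(words, 1, function(b) sum(ints[cbind(b, seq_len(w))]))
  probs <- apply(words, 1, function(b) prod(pwm$background[b]))
  list(score = scores * bin_width, prob = probs)
}

# per-pangene fixture with one planted k-mer driving expression
planted_fixture <- function(n_pangenes = 20, n_acc = 10, len = 120,
                            motif = "ACGTACGTACG", beta = 2, sigma = 0.3,
                            carrier_frac = 0.5, seed = 1) {
  set.seed(seed)
  seqs <- character(0); pan <- character(0); acc <- character(0)
  carries <- logical(0)
  for (pg in seq_len(n_pangenes)) {
    anc <- random_seq(len)
    for (a in seq_len(n_acc)) {
      s <- anc
      carrier <- runif(1) < carrier_frac
      if (carrier) {
        at <- 20
        s <- paste0(substr(s, 1, at), motif, substr(s, at + nchar(motif) + 1, len))
      }
      seqs <- c(seqs, s); pan <- c(pan, sprintf("pan%03d", pg))
      acc <- c(acc, sprintf("acc%02d", a)); carries <- c(carries, carrier)
    }
  }
  prom <- make_promoters(seqs, pan, acc)
  mu <- stats::setNames(stats::rnorm(n_pangenes, 2, 1), sprintf("pan%03d", seq_len(n_pangenes)))
  y <- unname(mu[pan]) + beta * carries + stats::rnorm(length(seqs), 0, sigma)
  list(promoters = prom,
       expression = data.frame(gene_id = prom$gene_id, expression = y),
       carries = carries, motif = motif, beta = beta)
}
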