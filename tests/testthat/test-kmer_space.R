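test_that("enumeration slides stride-1 windows and skips N", {
  e <- enumerate_kmers(make_promoters("AAAAA"), 4)
  expect_equal(e$kmer, "AAAA")
  expect_equal(e$count, 2)
  e2 <- enumerate_kmers(make_promoters("AANAA"), 2)
  expect_equal(e2$kmer, "AA")
  expect_equal(e2$count, 2)
  e3 <- enumerate_kmers(make_promoters("ACGT"), 4)
  expect_equal(e3$kmer, "ACGT")
  expect_equal(e3$count, 1)
  expect_error(enumerate_kmers(make_promoters("ACG"), 10), "larger")
  # positions are 0-based window starts
  e4 <- enumerate_kmers(make_promoters("ACGTACGT"), 4)
  occ <- e4$occurrences
  expect_equal(occ$pos[occ$kmer_idx == match("ACGT", e4$kmer)], c(0L, 4L))
})

test_that("k-mer ordering is by count descending then lexicographic", {
  counts <- c(AAAT = 3, TTTT = 5, AAAA = 5)
  expect_equal(order_kmers(counts)$kmer, c("AAAA", "TTTT", "AAAT"))
  expect_equal(order_kmers(c(GG = 1))$kmer, "GG")
  expect_equal(order_kmers(c(CA = 2, AC = 2, AA = 2))$kmer, c("AA", "AC", "CA"))
})

test_that("greedy clustering follows the representative-only Hamming-1 rule", {
  cl <- cluster_kmers(c("AAAA", "TTTT", "AAAT"), 4)
  expect_equal(cl$members$cluster, c(1L, 2L, 1L))
  expect_equal(cl$representative, c("AAAA", "TTTT"))
  # Hamming distance 2 -> separate clusters
  cl2 <- cluster_kmers(c("AAAA", "AATT"), 4)
  expect_equal(length(cl2$representative), 2L)
  # distance 1 from a member but 2 from the representative founds a cluster
  cl3 <- cluster_kmers(c("AAAA", "AAAT", "AATT"), 4)
  expect_equal(cl3$members$cluster, c(1L, 1L, 2L))
  expect_equal(cl3$representative, c("AAAA", "AATT"))
  expect_error(cluster_kmers(c("AAAA", "AAA"), 4), "length")
})

test_that("clustering partitions the input deterministically", {
  set.seed(11)
  kmers <- unique(replicate(300, random_seq(6)))
  ord <- order_kmers(setNames(rep(1, length(kmers)), kmers))
  cl <- cluster_kmers(ord, 6)
  # partition: every k-mer in exactly one cluster
  expect_equal(nrow(cl$members), length(kmers))
  expect_true(all(cl$members$cluster >= 1 &
                    cl$members$cluster <= length(cl$representative)))
  # every member within Hamming 1 of its representative
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  d <- mapply(hamming, cl$members$kmer, cl$representative[cl$members$cluster])
  expect_true(all(d <= 1))
  # determinism: identical input gives byte-identical clusters
  cl2 <- cluster_kmers(ord, 6)
  expect_identical(cl, cl2)
})

test_that("count matrix counts member occurrences and filters by prevalence", {
  # 201 promoters; cluster {AAAA, AAAT} occurs in promoter 1 only via "AAAAAT"
  # (background promoters avoid A so no foreign k-mer can join the cluster)
  set.seed(2)
  rand_cgt <- function(n) paste(sample(c("C", "G", "T"), n, TRUE), collapse = "")
  seqs <- c("AAAAATGGCC", vapply(1:200, function(i) rand_cgt(10), ""))
  prom <- make_promoters(seqs)
  expr <- data.frame(gene_id = prom$gene_id, expression = rnorm(201))
  enum <- enumerate_kmers(prom, 4)
  cl <- cluster_kmers(order_kmers(enum), 4)
  mat <- build_count_matrix(cl, enum, prom, expr, min_prevalence = 0)
  # AAAA x2 (overlapping) + AAAT x1 in the same cluster
  target <- cl$members$cluster[match("AAAA", cl$members$kmer)]
  expect_equal(cl$members$cluster[match("AAAT", cl$members$kmer)], target)
  cid <- cl$cluster_id[target]
  expect_equal(as.numeric(mat$X[mat$gene_id == prom$gene_id[1], cid]), 3)
  # the truncated window variant has one window fewer
  e5 <- enumerate_kmers(make_promoters("AAAAT"), 4)
  expect_equal(sum(e5$count), 2)
  # strict > prevalence rule at threshold 1/201 < 0.01 < 3/201
  prev <- Matrix::colSums(mat$X > 0) / nrow(mat$X)
  mat2 <- build_count_matrix(cl, enum, prom, expr, min_prevalence = 0.01)
  expect_true(all(Matrix::colSums(mat2$X > 0) / nrow(mat2$X) > 0.01))
  expect_false(cid %in% colnames(mat2$X))  # 1/201 <= 0.01 -> dropped
})

test_that("column sums equal total occurrences and row order is canonical", {
  set.seed(4)
  prom <- make_promoters(vapply(1:30, function(i) random_seq(40), ""))
  expr <- data.frame(gene_id = prom$gene_id, expression = rnorm(30))
  enum <- enumerate_kmers(prom, 5)
  cl <- cluster_kmers(order_kmers(enum), 5)
  mat <- build_count_matrix(cl, enum, prom, expr, min_prevalence = 0)
  # conservation: column sums = total occurrences of member k-mers
  memb_tot <- tapply(cl$members$count, cl$members$cluster, sum)
  expect_equal(as.numeric(Matrix::colSums(mat$X)),
               as.numeric(memb_tot[as.character(mat$retained_cluster_idx)]))
  # permuting promoter input order changes nothing (rows are gene-sorted)
  ord <- sample(30)
  prom2 <- prom[ord, ]; class(prom2) <- class(prom)
  enum2 <- enumerate_kmers(prom2, 5)
  cl2 <- cluster_kmers(order_kmers(enum2), 5)
  mat2 <- build_count_matrix(cl2, enum2, prom2, expr, min_prevalence = 0)
  expect_identical(cl2$representative, cl$representative)
  expect_equal(as.matrix(mat2$X), as.matrix(mat$X))
  expect_equal(mat2$y, mat$y)
})

test_that("promoters without expression are dropped with a warning", {
  prom <- make_promoters(c("ACGTACGTAC", "TGCATGCATG"))
  expr <- data.frame(gene_id = prom$gene_id[1], expression = 1)
  enum <- enumerate_kmers(prom, 4)
  cl <- cluster_kmers(order_kmers(enum), 4)
  expect_warning(mat <- build_count_matrix(cl, enum, prom, expr,
                                           min_prevalence = 0),
                 "without expression")
  expect_equal(nrow(mat$X), 1)
})

test_that("held-out promoters are projected onto training clusters", {
  prom <- make_promoters(c("AAAACGCGCG", "TTTTGCGCGC"))
  enum <- enumerate_kmers(prom, 4)
  cl <- cluster_kmers(order_kmers(enum), 4)
  idx <- seq_along(cl$representative)
  # a new promoter whose k-mers are 1 mismatch from training representatives
  new <- make_promoters("AAATCGCGCG")
  Xn <- count_in_promoters(cl, new, idx)
  # AAAT is Hamming-1 from AAAA's cluster representative
  aaaa_cl <- cl$cluster_id[cl$members$cluster[match("AAAA", cl$members$kmer)]]
  expect_gte(Xn[1, aaaa_cl], 1)
})
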