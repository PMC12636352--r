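write_test_meme <- function(path, motifs, bg = c(0.25, 0.25, 0.25, 0.25)) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]))
  for (id in names(motifs)) {
    m <- motifs[[id]]
    lines <- c(lines, "", paste("MOTIF", id),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m)),
               apply(m, 2, function(col) sprintf(" %.6f %.6f %.6f %.6f",
                                                 col[1], col[2], col[3], col[4])))
  }
  writeLines(lines, path)
}

sharp_pwm <- function(consensus, p = 0.94) {
  k <- nchar(consensus)
  m <- matrix((1 - p) / 3, 4, k, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m[cbind(idx, seq_len(k))] <- p
  m
}

test_that("MEME parsing round-trips probabilities and background", {
  path <- withr::local_tempfile(fileext = ".meme")
  mats <- list(m1 = sharp_pwm("ACGTAC"), m2 = sharp_pwm("TTGACA"))
  write_test_meme(path, mats, bg = c(0.3, 0.2, 0.2, 0.3))
  lib <- read_meme(path)
  expect_named(lib, c("m1", "m2"))
  expect_equal(lib$m1$prob, mats$m1, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(lib$m1$width, 6)
  expect_equal(lib$m2$background, c(0.3, 0.2, 0.2, 0.3))
})

test_that("cluster PWMs weight member k-mers by frequency", {
  p1 <- cluster_pwm(c(ACGT = 10), pseudocount = 0.01)
  expect_gt(p1$prob["A", 1], 0.99)
  expect_gt(p1$prob["T", 4], 0.99)
  p2 <- cluster_pwm(c(AAAA = 1, AAAT = 1), pseudocount = 0)
  expect_equal(unname(p2$prob["A", 4]), 0.5)
  expect_equal(unname(p2$prob["T", 4]), 0.5)
  p3 <- cluster_pwm(c(AAAA = 3, AAAT = 1), pseudocount = 0)
  expect_equal(unname(p3$prob["A", 4]), 0.75)
  expect_equal(unname(p3$prob["T", 4]), 0.25)
  expect_equal(unname(colSums(p3$prob)), rep(1, 4))
  expect_error(cluster_pwm(c(AAAA = 0)), "zero total frequency")
})

test_that("exact score distribution matches brute-force enumeration", {
  # widths 2..8 against all 4^w words on the same integer grid
  set.seed(31)
  for (w in c(2, 4, 6, 8)) {
    pwm <- list(motif_id = "t", width = w,
                prob = sharp_pwm(paste(sample(c("A", "C", "G", "T"), w, TRUE),
                                       collapse = ""), p = 0.8),
                background = c(0.25, 0.25, 0.25, 0.25))
    thr <- pwm_threshold(pwm, p_target = 1e-3)
    brute <- brute_pwm_tail(pwm, thr$bin_width)
    # compare the tail at each DP grid point with exhaustive enumeration
    for (gp in thr$score_grid[seq(1, length(thr$score_grid),
                                  length.out = 25)]) {
      expect_equal(thr$tail_prob[which.min(abs(thr$score_grid - gp))],
                   sum(brute$prob[brute$score >= gp - 1e-9]),
                   tolerance = 1e-12)
    }
    # the threshold really attains <= p_target
    expect_lte(sum(brute$prob[brute$score >= thr$threshold - 1e-9]), 1e-3)
  }
})

test_that("threshold boundaries behave", {
  pwm <- list(motif_id = "t", width = 3, prob = sharp_pwm("ACG"),
              background = rep(0.25, 4))
  thr1 <- pwm_threshold(pwm, p_target = 1)
  expect_equal(thr1$threshold, min(thr1$score_grid))
  # a PWM equal to the background scores 0 everywhere
  flat <- list(motif_id = "f", width = 4,
               prob = matrix(0.25, 4, 4, dimnames = list(c("A","C","G","T"), NULL)),
               background = rep(0.25, 4))
  thrf <- pwm_threshold(flat, p_target = 1e-4)
  expect_true(all(abs(thrf$score_grid) < 1e-9))
})

test_that("k-mer scanning covers both strands and rejects non-ACGT", {
  pwm <- list(motif_id = "t", width = 6, prob = sharp_pwm("ACGTAC"),
              background = rep(0.25, 4))
  thr <- pwm_threshold(pwm, 1e-3)$threshold
  expect_true(scan_kmer(pwm, "ACGTAC", thr)$matched)
  expect_true(scan_kmer(pwm, "GTACGT", thr)$matched)  # reverse complement
  expect_true(scan_kmer(pwm, "TTACGTACTT", thr)$matched)  # embedded
  expect_false(scan_kmer(pwm, "ACNTAC", thr)$matched)
  expect_false(scan_kmer(pwm, "GGGGGG", thr)$matched)
})

test_that("permutation enrichment finds planted motif matches", {
  # clusters: 5 significant ones matching the library, 45 background that
  # cannot match a C/G-free motif
  sig_kmers <- paste0(c("ACGTAC"), c("AA", "AT", "CA", "GG", "TT"))
  bg_kmers <- vapply(1:45, function(i)
    paste(sample(c("A", "T"), 8, TRUE), collapse = ""), "")
  all_kmers <- c(sig_kmers, bg_kmers)
  cl <- cluster_kmers(all_kmers, 8)
  ids <- cl$cluster_id[cl$members$cluster[match(all_kmers, cl$members$kmer)]]
  sig_ids <- unique(ids[1:5])
  all_ids <- unique(ids)
  lib <- list(m = list(motif_id = "m", width = 6, prob = sharp_pwm("ACGTAC"),
                       background = rep(0.25, 4)))
  res <- permutation_enrichment(sig_ids, cl, all_ids, lib, n_iter = 400,
                                seed = 2)
  expect_equal(res$observed, length(sig_ids))
  expect_equal(res$p_empirical, 1 / 401)
  expect_gt(res$fold, 1)
  # sig == all: null equals observed, p ~ 1, fold = 1
  res2 <- permutation_enrichment(all_ids, cl, all_ids, lib, n_iter = 50,
                                 seed = 2)
  expect_equal(res2$fold, 1)
  expect_equal(res2$p_empirical, 1)
  expect_error(permutation_enrichment(sig_ids, cl, all_ids, list()), "empty")
})

test_that("occurrences map back to genome coordinates on both strands", {
  genome <- c(ctg = paste0(strrep("T", 1000), "ACGTACGTTTT",
                           strrep("C", 989), "AAAACGTACGT", strrep("G", 989)))
  ann <- data.frame(gene_id = c("gp", "gm"), contig = "ctg",
                    start = c(1000L, 2000L), end = c(1011L, 3000L),
                    strand = c("+", "-"))
  iv <- data.frame(gene_id = c("gp", "gm"), contig = "ctg",
                   start = c(1000L, 2000L), end = c(1011L, 3000L),
                   strand = c("+", "-"))
  idm <- data.frame(gene_id = c("gp", "gm"), pangene_id = c("p1", "p2"),
                    accession_id = "a")
  prom <- extract_promoters(genome, iv, idm)
  enum <- enumerate_kmers(prom, 8)
  cl <- cluster_kmers(order_kmers(enum), 8)
  occ <- occurrence_positions(cl, enum, prom)
  # + strand: offset o -> [start + o, start + o + k)
  o1 <- occ[occ$gene_id == "gp" & occ$start == 1000, ]
  expect_equal(o1$end, 1008)
  # - strand: offset o -> [end - o - k, end - o); verify by re-extracting
  om <- occ[occ$gene_id == "gm", ][1, ]
  sub <- substr(genome[["ctg"]], om$start + 1, om$end)
  k_obs <- cl$members$kmer[cl$members$cluster ==
                             match(om$cluster_id, cl$cluster_id)]
  expect_true(revcomp(sub) %in% k_obs || sub %in% k_obs)
  # boundary: last valid window ends exactly at the promoter end
  offs_p <- enum$occurrences$pos[enum$occurrences$seq_idx == 1]
  expect_equal(max(offs_p), (1011 - 1000) - 8)
})

test_that("peak overlap uses half-open adjacency and yields fold enrichment", {
  occ <- data.frame(cluster_id = c("c1", "c1", "c2"),
                    gene_id = "g", contig = "chr",
                    start = c(10L, 100L, 10L), end = c(21L, 111L, 20L))
  peaks <- data.frame(contig = "chr", start = 20L, end = 30L)
  fr <- kmerbash:::overlap_fraction(occ, peaks)
  # [10,21) shares base 20 with [20,30); [10,20) does not
  expect_equal(unname(fr["c1"]), 0.5)
  expect_equal(unname(fr["c2"]), 0)
  # constructed enrichment: sig clusters always in peaks, background at 50%
  occ2 <- data.frame(
    cluster_id = rep(sprintf("s%02d", 1:20), each = 2),
    gene_id = "g", contig = "chr",
    start = rep(c(25L, 25L, 200L, 200L), 10), end = rep(c(36L, 36L, 211L, 211L), 10))
  res <- peak_overlap_enrichment(sprintf("s%02d", seq(1, 20, 2)),
                                 sprintf("s%02d", 1:20), occ2, peaks,
                                 n_boot = 200, seed = 1)
  expect_equal(res$rate_sig, 1)
  expect_equal(res$rate_all, 0.5)
  expect_equal(res$fold, 2)
})
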