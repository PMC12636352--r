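test_that("shared k-mer similarity matches a brute-force oracle", {
  expect_equal(promoter_similarity("ACGTACGT", "CGTACGTA", k = 4), 4)
  expect_equal(naive_shared("ACGTACGT", "CGTACGTA", 4), 4)
  set.seed(7)
  for (i in 1:10) {
    a <- random_seq(80); b <- random_seq(80)
    k <- sample(2:8, 1)
    expect_equal(promoter_similarity(a, b, k), naive_shared(a, b, k))
    # symmetry and self-similarity
    expect_equal(promoter_similarity(a, b, k), promoter_similarity(b, a, k))
    expect_equal(promoter_similarity(a, a, k),
                 length(unique(naive_kmers(a, k))))
    expect_lte(promoter_similarity(a, b, k), nchar(a) - k + 1)
  }
})

test_that("similarity handles N bases and disjoint alphabets", {
  expect_equal(promoter_similarity(strrep("A", 50), strrep("C", 50), 4), 0)
  # windows containing N are excluded on both sides
  expect_equal(promoter_similarity("AANAA", "AAAAA", 2), 1)
  expect_warning(s <- promoter_similarity("ACG", "ACGTACGT", 5), "similarity is 0")
  expect_equal(s, 0)
})

test_that("pangene similarity averages all unordered pairs", {
  # three identical sequences: every pair shares all distinct k-mers
  s <- random_seq(40)
  ps <- pangene_similarity(rep(s, 3), k = 5)
  expect_equal(ps$mean_score, length(unique(naive_kmers(s, 5))))
  expect_equal(ps$log2_similarity, log2(ps$mean_score))
  # mean of pairwise scores {0, x, y} checked by hand on constructed strings
  a <- strrep("A", 10); c <- strrep("C", 10)
  ps2 <- pangene_similarity(c(a, a, c), k = 3)
  # pairs: (a,a)=1 shared k-mer, (a,c)=0, (a,c)=0 -> mean 1/3
  expect_equal(ps2$mean_score, 1 / 3)
  expect_error(pangene_similarity("ACGT"), "fewer than 2")
  # zero mean score reported at the documented floor of 0
  expect_equal(pangene_similarity(c(a, c), k = 3)$log2_similarity, 0)
})

test_that("expression CV matches hand-computed values and is scale invariant", {
  # {1,3}: mean 2, sd sqrt(2), CV^2 = 0.5
  expect_equal(expression_cv(c(1, 3)), log10(0.5))
  expect_equal(round(expression_cv(c(1, 3)), 3), -0.301)
  expect_equal(expression_cv(c(2, 2, 2)), -6)   # zero variance -> floor
  expect_true(is.na(expression_cv(c(0, 0))))    # silent pangene flagged
  v <- c(0.5, 1.2, 3.3, 2.1)
  expect_equal(expression_cv(v), expression_cv(7 * v))
})

test_that("running-median normalization removes the mean-expression trend", {
  # all pangenes share one value -> all normalized values 0
  tab <- data.frame(mean_expr = runif(50), log10_cv2 = rep(0.7, 50))
  expect_equal(normalize_cv(tab, window = 7)$norm_log10_cv2, rep(0, 50))
  # strictly linear trend: interior normalized values are ~0
  tab2 <- data.frame(mean_expr = seq(0, 5, length.out = 201),
                     log10_cv2 = seq(1, -1, length.out = 201))
  norm <- normalize_cv(tab2, window = 21)$norm_log10_cv2
  expect_equal(norm[30:170], rep(0, 141), tolerance = 1e-12)
  # equivariance: adding a constant leaves normalized values unchanged
  tab3 <- tab2
  tab3$log10_cv2 <- tab3$log10_cv2 + 2.5
  expect_equal(normalize_cv(tab3, window = 21)$norm_log10_cv2, norm)
})

test_that("normalization decorrelates variability from mean expression", {
  set.seed(3)
  n <- 2000
  mean_expr <- sort(runif(n, 0, 8))
  log10_cv2 <- 1 - 0.4 * mean_expr + rnorm(n, 0, 0.3)  # injected trend
  tab <- normalize_cv(data.frame(mean_expr = mean_expr, log10_cv2 = log10_cv2))
  rho_before <- cor(log10_cv2, mean_expr, method = "spearman")
  rho_after <- cor(tab$norm_log10_cv2, mean_expr, method = "spearman")
  expect_gt(abs(rho_before), 0.5)
  expect_lt(abs(rho_after), 0.1)
})

test_that("hv selection applies size, expression and quantile filters", {
  tab <- data.frame(pangene_id = sprintf("p%02d", 1:10),
                    n_genes = c(5, rep(10, 9)),
                    mean_expr = c(3, 0.5, rep(3, 8)),
                    log2_similarity = c(5, 5, 1:8),
                    norm_log10_cv2 = c(1, 1, 8:1 / 10))
  sel <- select_hv(tab, top_fraction = 0.3)
  # small pangene and weakly expressed pangene are excluded outright
  expect_false(any(c("p01", "p02") %in% sel$pangene_id))
  expect_equal(nrow(sel), 8)
  # brute-force quantile check on the 8 survivors
  qs <- quantile(sel$log2_similarity, 0.3)
  qc <- quantile(sel$norm_log10_cv2, 0.7)
  manual <- sel$log2_similarity <= qs & sel$norm_log10_cv2 >= qc
  expect_equal(sel$hv_flag, manual)
  # order invariance
  shuf <- tab[sample(nrow(tab)), ]
  sel2 <- select_hv(shuf, top_fraction = 0.3)
  expect_setequal(sel2$pangene_id[sel2$hv_flag], sel$pangene_id[sel$hv_flag])
})

test_that("bootstrap mean comparison behaves on degenerate and real input", {
  set.seed(5)
  x <- rnorm(80)
  bb <- bootstrap_mean_ci(x, x, n_boot = 500, seed = 1)
  expect_true(bb$ci[1] <= 0 && bb$ci[2] >= 0)
  bb2 <- bootstrap_mean_ci(c(10, 10, 10), c(10, 10, 10), n_boot = 200, seed = 1)
  expect_true(all(bb2$boot_a == 10))
  expect_equal(unname(bb2$ci), c(0, 0))
  # clear separation excludes 0
  a <- rnorm(200, 0); b <- rnorm(200, 1)
  bb3 <- bootstrap_mean_ci(a, b, n_boot = 1000, seed = 2)
  expect_true(bb3$ci[2] < 0)
  expect_warning(bootstrap_mean_ci(a, b, n_boot = 50), "n_boot")
})
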