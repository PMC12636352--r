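test_that("a mutation-free pan-genome gives identical alleles per pangene", {
  sim <- simulate_pangenome(n_pangenes = 4, n_accessions = 5, promoter_len = 100,
                            snp_rate = 0, indel_rate = 0, sv_insert_prob = 0,
                            planted_motifs = 0, seed = 1)
  lens <- tapply(nchar(sim$promoters$sequence), sim$promoters$pangene_id, unique)
  expect_true(all(lengths(lens) == 1))
  for (pg in unique(sim$promoters$pangene_id)) {
    seqs <- sim$promoters$sequence[sim$promoters$pangene_id == pg]
    expect_equal(length(unique(seqs)), 1)
    # self-similarity of identical alleles
    ps <- pangene_similarity(seqs, k = 31)
    expect_equal(ps$mean_score, promoter_similarity(seqs[1], seqs[1], 31))
  }
})

test_that("planted motifs appear exactly in carrier alleles", {
  sim <- simulate_pangenome(n_pangenes = 10, n_accessions = 8,
                            promoter_len = 300, snp_rate = 0, indel_rate = 0,
                            sv_insert_prob = 0, planted_motifs = 2,
                            carrier_pangene_frac = 0.5, seed = 4)
  ca <- sim$truth$carriers
  for (mi in seq_len(nrow(sim$truth$motifs))) {
    m <- sim$truth$motifs$motif[mi]
    has <- grepl(m, sim$promoters$sequence, fixed = TRUE)
    carriers <- paste(ca$pangene_id[ca$motif == m], ca$accession_id[ca$motif == m])
    expect_setequal(paste(sim$promoters$pangene_id, sim$promoters$accession_id)[has],
                    carriers)
    # recorded offsets point at the motif
    sub <- ca[ca$motif == m, ]
    gid <- sprintf("%s_%s", sub$pangene_id, sub$accession_id)
    seqs <- sim$promoters$sequence[match(gid, sim$promoters$gene_id)]
    expect_true(all(substr(seqs, sub$offset + 1, sub$offset + nchar(m)) == m))
  }
})

test_that("SV-carried motifs lengthen their promoter by at least 50 bp", {
  sim <- simulate_pangenome(n_pangenes = 8, n_accessions = 10,
                            promoter_len = 400, snp_rate = 0, indel_rate = 0,
                            sv_insert_prob = 0, planted_motifs = 2,
                            sv_motif_frac = 1, carrier_pangene_frac = 0.5,
                            seed = 6)
  ca <- sim$truth$carriers
  for (i in seq_len(nrow(ca))) {
    gid <- sprintf("%s_%s", ca$pangene_id[i], ca$accession_id[i])
    len <- nchar(sim$promoters$sequence[sim$promoters$gene_id == gid])
    expect_gte(len, 400 + 50)
  }
})

test_that("expression follows the additive model exactly when noiseless", {
  sim <- simulate_pangenome(n_pangenes = 6, n_accessions = 6, promoter_len = 200,
                            snp_rate = 0, indel_rate = 0, sv_insert_prob = 0,
                            planted_motifs = 1, beta_true = 2,
                            carrier_pangene_frac = 0.5, noise_sd = 0, seed = 8)
  expr <- simulate_expression(sim$promoters, sim$truth, seed = 9)
  mu <- sim$truth$baseline[sim$promoters$pangene_id]
  m <- sim$truth$motifs$motif[1]
  has <- grepl(m, sim$promoters$sequence, fixed = TRUE)
  expect_equal(expr$expression, unname(mu) + 2 * has)
})

test_that("residual noise has the configured variance", {
  sim <- simulate_pangenome(n_pangenes = 50, n_accessions = 20,
                            promoter_len = 60, snp_rate = 0, indel_rate = 0,
                            sv_insert_prob = 0, planted_motifs = 0,
                            noise_sd = 0.7, seed = 10)
  expr <- simulate_expression(sim$promoters, sim$truth, seed = 11)
  resid <- expr$expression - unname(sim$truth$baseline[sim$promoters$pangene_id])
  n <- length(resid)
  se <- 0.7^2 * sqrt(2 / (n - 1))  # SE of a normal sample variance
  expect_lt(abs(var(resid) - 0.49), 3 * se)
})

test_that("fixtures round-trip through disk deterministically", {
  sim <- simulate_pangenome(n_pangenes = 4, n_accessions = 4, promoter_len = 150,
                            planted_motifs = 1, seed = 12)
  expr <- simulate_expression(sim$promoters, sim$truth, seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture(sim, expr, d1, peaks = TRUE)
  back <- read_promoter_fasta(p1[["fasta"]])
  expect_equal(back$sequence, sim$promoters$sequence)
  expect_equal(back$pangene_id, sim$promoters$pangene_id)
  tr <- jsonlite::read_json(p1[["truth"]], simplifyVector = TRUE)
  expect_equal(tr$motifs$motif, sim$truth$motifs$motif)
  expect_equal(tr$noise_sd, sim$truth$noise_sd)
  # regenerating with the same seed gives byte-identical files
  sim2 <- simulate_pangenome(n_pangenes = 4, n_accessions = 4, promoter_len = 150,
                             planted_motifs = 1, seed = 12)
  expr2 <- simulate_expression(sim2$promoters, sim2$truth, seed = 13)
  p2 <- write_fixture(sim2, expr2, d2, peaks = TRUE)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  # the full modelling chain runs from these files alone
  prom <- read_promoter_fasta(p1[["fasta"]])
  ex <- read_expression(p1[["expression"]], transform = "none")
  enum <- enumerate_kmers(prom, 5)
  cl <- cluster_kmers(order_kmers(enum), 5)
  mat <- build_count_matrix(cl, enum, prom, ex, min_prevalence = 0.01)
  fit <- fit_bvs(mat, iters = 300, burn_in = 100, seed = 1)
  expect_true(all(fit$pip >= 0 & fit$pip <= 1))
})
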