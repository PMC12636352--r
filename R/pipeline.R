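# Orchestration: the end-to-end pipeline chaining variation metrics ->
# hv selection -> k-mer clustering -> spike-and-slab fit -> functional
# site filtering, plus reproducibility-stamped output writers. The shell
# entry point (inst/cli/kmerbash) is a thin wrapper over these functions.

config_hash <- function(config) {
  # order-independent FNV-1a hash of the flattened key=value config echo
  flat <- unlist(config)
  s <- paste(sort(paste0(names(flat), "=", as.character(flat))), collapse = ";")
  h <- 2166136261 %% 2147483648  # 31-bit state keeps bitwXor in integer range
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

#' Write a TSV with a reproducibility stamp
#'
#' Prefixes the file with comment lines recording the package version, the
#' seed and a hash of the run configuration, so every artifact is
#' traceable to the run that produced it.
#'
#' @param tab data.frame.
#' @param path output path.
#' @param seed,config run metadata.
#' @return `path`, invisibly.
#' @export
write_stamped_tsv <- function(tab, path, seed = NA, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kmerbash v%s seed=%s config=%s",
                     as.character(packageVersion("kmerbash")),
                     as.character(seed), config_hash(config)), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the promoter-bashing pipeline end to end
#'
#' Chains: per-pangene variation metrics, running-median CV normalization
#' and hv selection; k-mer enumeration and one-mismatch clustering on the
#' hv promoters; prevalence-filtered count matrix; spike-and-slab fit with
#' PIP-based FDR selection; per-pangene functional-site filtering.
#'
#' @param promoters a `promoter_set`.
#' @param expression data.frame `gene_id`, `expression` (log2(TPM+1)).
#' @param k k-mer size for the association model (default 11).
#' @param top_fraction hv quantile (default 0.30).
#' @param min_genes,min_expr hv pre-filters (defaults 6 and 1).
#' @param similarity_k k-mer size for promoter similarity (default 31).
#' @param min_prevalence cluster prevalence threshold (default 0.01).
#' @param covariates passed to [build_count_matrix()]; default
#'   per-pangene indicators (absorbing pangene baselines).
#' @param spec a [bvs_spec()].
#' @param iters,burn_in,thin MCMC schedule.
#' @param fdr_target PIP FDR target (default 0.1).
#' @param site_alpha functional-site FDR level (default 0.05).
#' @param select_hv_pangenes skip hv selection and model all pangenes when
#'   `FALSE`.
#' @param seed integer seed.
#' @param outdir optional directory for stamped TSV artifacts.
#' @param verbose log stage progress to stderr.
#' @return list with `variation`, `hv_table`, `clusters`, `matrix`,
#'   `fit`, `sites`, and `config`.
#' @export
run_pipeline <- function(promoters, expression, k = 11, top_fraction = 0.30,
                         min_genes = 6, min_expr = 1.0, similarity_k = 31,
                         min_prevalence = 0.01, covariates = "pangene",
                         spec = bvs_spec(), iters = 10000, burn_in = 5000,
                         thin = 5, fdr_target = 0.1, site_alpha = 0.05,
                         select_hv_pangenes = TRUE, seed = 1, outdir = NULL,
                         verbose = TRUE) {
  config <- list(k = k, top_fraction = top_fraction, min_genes = min_genes,
                 min_expr = min_expr, similarity_k = similarity_k,
                 min_prevalence = min_prevalence, q = spec$q, iters = iters,
                 burn_in = burn_in, thin = thin, fdr_target = fdr_target,
                 site_alpha = site_alpha, seed = seed)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(name) say("[%s] %s (%.1fs elapsed)", "kmerbash", name,
                              as.numeric(difftime(Sys.time(), t0, units = "secs")))

  stage("variation metrics")
  variation <- pangene_variation(promoters, expression, k = similarity_k)
  variation <- normalize_cv(variation)
  hv_table <- select_hv(variation, top_fraction, min_genes, min_expr)
  hv_ids <- if (select_hv_pangenes) hv_table$pangene_id[hv_table$hv_flag] else
    unique(promoters$pangene_id)
  if (!length(hv_ids)) stop("pipeline: empty hv pangene set")
  say("  %d pangenes measured, %d modeled", nrow(variation), length(hv_ids))

  hv_prom <- promoters[promoters$pangene_id %in% hv_ids, , drop = FALSE]
  class(hv_prom) <- class(promoters)

  stage("k-mer enumeration and clustering")
  enum <- enumerate_kmers(hv_prom, k)
  clusters <- cluster_kmers(order_kmers(enum), k)
  say("  %d unique %d-mers -> %d clusters", length(enum$kmer), k,
      length(clusters$representative))

  stage("count matrix")
  mat <- build_count_matrix(clusters, enum, hv_prom, expression,
                            covariates = covariates,
                            min_prevalence = min_prevalence)
  say("  %d genes x %d retained clusters", nrow(mat$X), ncol(mat$X))

  stage("spike-and-slab fit")
  fit <- fit_bvs(mat, spec, iters = iters, burn_in = burn_in, thin = thin,
                 seed = seed, fdr_target = fdr_target)
  say("  %d clusters selected at FDR <= %g", length(fit$selected), fdr_target)

  sites <- NULL
  if (length(fit$selected)) {
    stage("functional site filtering")
    sites <- filter_functional_sites(fit, mat, alpha = site_alpha)
    say("  %d/%d (cluster, pangene) pairs retained", sum(sites$retained),
        nrow(sites))
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_stamped_tsv(hv_table, file.path(outdir, "variation.tsv"), seed, config)
    sel <- data.frame(cluster_id = mat$cluster_id,
                      representative = mat$representative,
                      pip = fit$pip, beta_mean = fit$beta_mean,
                      beta_slab_mean = fit$beta_slab_mean,
                      selected = mat$cluster_id %in% fit$selected)
    write_stamped_tsv(sel, file.path(outdir, "clusters.tsv"), seed, config)
    if (!is.null(sites)) {
      write_stamped_tsv(sites, file.path(outdir, "functional_sites.tsv"),
                        seed, config)
    }
  }
  list(variation = variation, hv_table = hv_table, clusters = clusters,
       matrix = mat, fit = fit, sites = sites, config = config)
}
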