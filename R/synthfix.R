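# Synthetic pan-genome / pan-transcriptome generator with known ground
# truth. Each pangene descends from one random ancestral promoter, mutated
# independently per accession; planted motif k-mers with known effects on
# expression are carried either inside structural-variant insertions
# (presence/absence coincides with the SV) or written directly into the
# ancestral context. Purposely simple mutation model (iid substitutions,
# geometric indel lengths, uniform SV lengths): the fixtures exercise the
# inference, not molecular evolution.

# DNA as utf8 integer codes for speed; A=65 C=67 G=71 T=84
.base_codes <- c(65L, 67L, 71L, 84L)

random_dna <- function(n) intToUtf8(sample(.base_codes, n, replace = TRUE))

mutate_sequence <- function(seq, snp_rate, indel_rate, indel_mean_len = 3) {
  u <- utf8ToInt(seq)
  n <- length(u)
  # substitutions: cyclic shift by 1-3 among the other bases, vectorized
  nsub <- rbinom(1, n, snp_rate)
  if (nsub > 0) {
    at <- sample.int(n, nsub)
    idx <- match(u[at], .base_codes)
    u[at] <- .base_codes[((idx - 1L + sample.int(3, nsub, replace = TRUE)) %% 4L) + 1L]
  }
  # short indels, geometric lengths
  nind <- rbinom(1, n, indel_rate)
  for (i in seq_len(nind)) {
    len <- 1 + rgeom(1, 1 / indel_mean_len)
    pos <- sample.int(length(u), 1)
    if (runif(1) < 0.5) {  # deletion
      u <- u[-(pos:min(pos + len - 1, length(u)))]
    } else {               # insertion
      u <- append(u, sample(.base_codes, len, replace = TRUE), after = pos)
    }
  }
  intToUtf8(u)
}

#' Simulate a pan-genome of promoter alleles
#'
#' Per pangene, one random ancestral promoter is mutated independently per
#' accession: substitutions at `snp_rate` per base, short indels at
#' `indel_rate` (geometric lengths, mean 3 bp), and with probability
#' `sv_insert_prob` a structural-variant insertion of 50-900 bp. Planted
#' motif k-mers are carried by a random subset of accessions
#' (`carrier_accession_prob`) within a random subset of pangenes
#' (`carrier_pangene_frac`): a fraction `sv_motif_frac` of the motifs ride
#' inside a dedicated SV insertion (so motif presence/absence coincides
#' with the SV), the rest replace `k` bases of the ancestral context in
#' carriers only (SNP-like presence/absence). Defaults give 26 accessions
#' x 300 pangenes with 5 planted motifs.
#'
#' @param n_pangenes,n_accessions pan-genome dimensions.
#' @param promoter_len ancestral promoter length (default 2000 bp).
#' @param snp_rate per-base substitution probability (default 0.01).
#' @param indel_rate per-base short-indel initiation probability
#'   (default 0.002).
#' @param sv_insert_prob per-allele probability of a background SV
#'   insertion (default 0.15).
#' @param planted_motifs character vector of motif k-mers, or an integer
#'   count to draw random motifs of width `motif_width`.
#' @param motif_width width of drawn motifs (default 11).
#' @param beta_true effect per occurrence for each motif (log2 units);
#'   default alternating +2 / -2.
#' @param carrier_pangene_frac fraction of pangenes carrying each motif
#'   (default 0.15).
#' @param carrier_accession_prob probability an accession of a carrier
#'   pangene carries the motif (default 0.5).
#' @param sv_motif_frac fraction of motifs embedded in SV insertions, the
#'   rest in SNP-like context (default 0.5).
#' @param motif_divergence probability that a carrier pangene plants a
#'   one-substitution variant of the motif instead of the consensus
#'   (default 0). Mimics the mismatch tolerance of real TF sites: variant
#'   instances stay within Hamming distance 1 of the consensus, so
#'   one-mismatch clustering still groups the site family.
#' @param mu_mean,mu_sd per-pangene baseline distribution on the
#'   log2(TPM+1) scale (default N(2, 1)).
#' @param noise_sd residual SD sigma (default 0.7).
#' @param seed integer seed.
#' @return list with `promoters` (a `promoter_set`) and `truth` (list:
#'   `motifs` data.frame `motif`, `beta_true`, `context`; `carriers`
#'   data.frame `motif`, `pangene_id`, `accession_id`, `offset`;
#'   `baseline` per-pangene mu; `noise_sd`; `sv_events` data.frame).
#' @export
simulate_pangenome <- function(n_pangenes = 300, n_accessions = 26,
                               promoter_len = 2000, snp_rate = 0.01,
                               indel_rate = 0.002, sv_insert_prob = 0.15,
                               planted_motifs = 5, motif_width = 11,
                               beta_true = NULL, carrier_pangene_frac = 0.15,
                               carrier_accession_prob = 0.5,
                               sv_motif_frac = 0.5, motif_divergence = 0,
                               mu_mean = 2, mu_sd = 1,
                               noise_sd = 0.7, seed = 1) {
  stopifnot(snp_rate >= 0, snp_rate < 1, indel_rate >= 0, indel_rate < 1,
            sv_insert_prob >= 0, sv_insert_prob < 1)
  set.seed(seed)
  if (is.numeric(planted_motifs) && length(planted_motifs) == 1) {
    planted_motifs <- vapply(seq_len(planted_motifs),
                             function(i) random_dna(motif_width), "")
  }
  n_motifs <- length(planted_motifs)
  if (n_motifs && max(nchar(planted_motifs)) > promoter_len) {
    stop("planted motif longer than the promoter")
  }
  if (is.null(beta_true)) beta_true <- rep_len(c(2, -2), n_motifs)
  stopifnot(length(beta_true) == n_motifs)
  context <- if (n_motifs) {
    rep(c("sv", "snp"), c(round(sv_motif_frac * n_motifs),
                          n_motifs - round(sv_motif_frac * n_motifs)))
  } else character(0)

  pangene_ids <- sprintf("pan%04d", seq_len(n_pangenes))
  accession_ids <- sprintf("acc%02d", seq_len(n_accessions))
  # carrier map per motif
  carriers <- list()
  carrier_pg <- lapply(seq_len(n_motifs), function(mi) {
    sample(pangene_ids, max(1, round(carrier_pangene_frac * n_pangenes)))
  })

  rows <- vector("list", n_pangenes * n_accessions)
  sv_events <- list()
  ri <- 0L
  for (pg in seq_len(n_pangenes)) {
    anc <- random_dna(promoter_len)
    # pangene-specific motif anchor offsets for snp-context motifs
    snp_offsets <- sample.int(max(1, promoter_len - max(motif_width, 1) - 1),
                              max(1, n_motifs))
    # pangene-specific planted instance (consensus +/- divergence)
    instances <- vapply(seq_len(max(1, n_motifs)), function(mi) {
      if (!n_motifs) return("")
      m <- planted_motifs[mi]
      if (motif_divergence > 0 && runif(1) < motif_divergence) {
        u <- utf8ToInt(m)
        at <- sample.int(length(u), 1)
        idx <- match(u[at], .base_codes)
        u[at] <- .base_codes[((idx - 1L + sample.int(3, 1)) %% 4L) + 1L]
        intToUtf8(u)
      } else m
    }, "")
    for (ac in seq_len(n_accessions)) {
      s <- mutate_sequence(anc, snp_rate, indel_rate)
      # background SV insertion
      if (runif(1) < sv_insert_prob) {
        len <- sample(50:900, 1)
        pos <- sample.int(nchar(s), 1)
        s <- paste0(substr(s, 1, pos), random_dna(len),
                    substr(s, pos + 1, nchar(s)))
        sv_events[[length(sv_events) + 1L]] <- data.frame(
          pangene_id = pangene_ids[pg], accession_id = accession_ids[ac],
          type = "background_sv", length = len, carries_motif = NA_character_,
          stringsAsFactors = FALSE)
      }
      # planted motifs
      for (mi in seq_len(n_motifs)) {
        if (!pangene_ids[pg] %in% carrier_pg[[mi]]) next
        if (runif(1) >= carrier_accession_prob) next
        motif <- instances[mi]
        if (context[mi] == "sv") {
          len <- sample(50:300, 1)
          flank <- random_dna(len)
          ins_at <- sample.int(max(1, len - nchar(motif)), 1)
          sv <- paste0(substr(flank, 1, ins_at), motif,
                       substr(flank, ins_at + nchar(motif) + 1, len))
          pos <- sample.int(nchar(s), 1)
          s <- paste0(substr(s, 1, pos), sv, substr(s, pos + 1, nchar(s)))
          off <- pos + ins_at
          sv_events[[length(sv_events) + 1L]] <- data.frame(
            pangene_id = pangene_ids[pg], accession_id = accession_ids[ac],
            type = "motif_sv", length = nchar(sv), carries_motif = motif,
            stringsAsFactors = FALSE)
        } else {
          off <- min(snp_offsets[mi], nchar(s) - nchar(motif))
          s <- paste0(substr(s, 1, off), motif,
                      substr(s, off + nchar(motif) + 1, nchar(s)))
        }
        carriers[[length(carriers) + 1L]] <- data.frame(
          motif = planted_motifs[mi], instance = motif,
          pangene_id = pangene_ids[pg],
          accession_id = accession_ids[ac], offset = off,
          stringsAsFactors = FALSE)
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        pangene_id = pangene_ids[pg], accession_id = accession_ids[ac],
        gene_id = sprintf("%s_%s", pangene_ids[pg], accession_ids[ac]),
        sequence = s, stringsAsFactors = FALSE)
    }
  }
  promoters <- new_promoter_set(do.call(rbind, rows[seq_len(ri)]))
  truth <- list(
    motifs = if (n_motifs) data.frame(motif = planted_motifs,
                                      beta_true = beta_true, context = context,
                                      stringsAsFactors = FALSE)
             else data.frame(motif = character(0), beta_true = numeric(0),
                             context = character(0)),
    carriers = if (length(carriers)) do.call(rbind, carriers)
               else data.frame(motif = character(0), instance = character(0),
                               pangene_id = character(0),
                               accession_id = character(0), offset = integer(0)),
    baseline = setNames(rnorm(n_pangenes, mu_mean, mu_sd), pangene_ids),
    noise_sd = noise_sd,
    sv_events = if (length(sv_events)) do.call(rbind, sv_events)
                else data.frame(pangene_id = character(0),
                                accession_id = character(0), type = character(0),
                                length = integer(0), carries_motif = character(0)))
  list(promoters = promoters, truth = truth)
}

# Occurrences (possibly overlapping) of an exact motif string in a
# promoter: the same stride-1 forward-strand window rule as the k-mer
# enumeration. Motifs are plain ACGT strings, so a lookahead regex counts
# overlapping matches safely.
count_overlapping <- function(s, m) {
  if (nchar(s) < nchar(m)) return(0)
  at <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1]]
  if (at[1] == -1) 0 else length(at)
}

#' Simulate expression from planted ground truth
#'
#' `y_i = mu_g(i) + sum_j count_ij * beta_true_j + eps_i`, with
#' `eps ~ N(0, sigma^2)` and counts computed by the same stride-1
#' forward-strand window rule as the k-mer enumeration.
#'
#' @param promoters `promoter_set` from [simulate_pangenome()].
#' @param truth the matching `truth` list.
#' @param seed integer seed (noise only).
#' @return data.frame `gene_id`, `expression` (log2(TPM+1) scale).
#' @export
simulate_expression <- function(promoters, truth, seed = 1) {
  set.seed(seed)
  n <- nrow(promoters)
  y <- unname(truth$baseline[promoters$pangene_id])
  if (nrow(truth$motifs)) {
    for (mi in seq_len(nrow(truth$motifs))) {
      m <- truth$motifs$motif[mi]
      # every planted instance of the motif (the consensus plus any
      # pangene-diverged variants) counts toward the effect
      instances <- unique(c(m, truth$carriers$instance[truth$carriers$motif == m]))
      for (inst in instances) {
        cnt <- vapply(promoters$sequence, count_overlapping, 0, m = inst,
                      USE.NAMES = FALSE)
        y <- y + cnt * truth$motifs$beta_true[mi]
      }
    }
  }
  y <- y + rnorm(n, 0, truth$noise_sd)
  data.frame(gene_id = promoters$gene_id, expression = y,
             stringsAsFactors = FALSE)
}

#' Attribute k-mers to planted motifs by sequence overlap
#'
#' A cluster representative marks a planted site if it aligns to the motif
#' with at most `max_mismatch` mismatches over an overlap of at least
#' `min_overlap` bases at some relative shift. One-mismatch clustering and
#' window shifts across an insertion both produce such k-mers (the
#' "echo" clusters of a planted site), so ground-truth evaluation must
#' credit them to the motif rather than treat them as false discoveries.
#'
#' @param kmers character vector (e.g. cluster representatives).
#' @param motifs character vector of planted motifs.
#' @param min_overlap minimum aligned bases (default 8).
#' @param max_mismatch maximum mismatches within the overlap (default 1).
#' @return logical matrix, `length(kmers)` x `length(motifs)`.
#' @export
attribute_to_motifs <- function(kmers, motifs, min_overlap = 8, max_mismatch = 1) {
  one <- function(kmer, m) {
    k1 <- nchar(kmer); k2 <- nchar(m)
    a <- strsplit(kmer, "")[[1]]; b <- strsplit(m, "")[[1]]
    for (sh in -(k1 - min_overlap):(k2 - min_overlap)) {
      i1 <- max(1, 1 - sh); j1 <- min(k1, k2 - sh)
      if (j1 - i1 + 1 < min_overlap) next
      seg <- i1:j1
      if (sum(a[seg] != b[seg + sh]) <= max_mismatch) return(TRUE)
    }
    FALSE
  }
  out <- vapply(motifs, function(m) vapply(kmers, one, TRUE, m = m), logical(length(kmers)))
  matrix(out, nrow = length(kmers), dimnames = list(kmers, motifs))
}

#' Write a complete fixture to disk
#'
#' Emits promoter FASTA (canonical `pangene|accession|gene` headers),
#' expression TSV, membership TSV, ground-truth JSON and, when requested,
#' a synthetic peak BED covering the planted offsets. Regeneration with
#' the same seed yields byte-identical files.
#'
#' @param sim list from [simulate_pangenome()].
#' @param expression data.frame from [simulate_expression()].
#' @param outdir output directory (created if missing).
#' @param peaks also write `peaks.bed` over planted motif offsets.
#' @return named vector of written paths, invisibly.
#' @export
write_fixture <- function(sim, expression, outdir, peaks = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(outdir, "promoters.fa"),
             expression = file.path(outdir, "expression.tsv"),
             membership = file.path(outdir, "membership.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_promoter_fasta(sim$promoters, paths["fasta"])
  write.table(expression, paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  memb <- sim$promoters[c("pangene_id", "gene_id", "accession_id")]
  write.table(memb, paths["membership"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sim$truth
  truth$baseline <- as.list(truth$baseline)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  if (peaks && nrow(sim$truth$carriers)) {
    ca <- sim$truth$carriers
    gene <- sprintf("%s_%s", ca$pangene_id, ca$accession_id)
    k <- nchar(ca$motif)
    bed <- data.frame(contig = gene, start = ca$offset, end = ca$offset + k)
    paths <- c(paths, peaks = file.path(outdir, "peaks.bed"))
    write.table(bed, paths["peaks"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
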