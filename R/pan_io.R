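#' @useDynLib kmerbash, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats median quantile sd var runmed lm pt p.adjust cor
#'   rnorm rbinom rgeom runif setNames coef predict ave
#' @importFrom methods as
#' @importFrom Matrix colMeans colSums sparseMatrix
#' @importFrom utils head tail packageVersion write.table read.table
"_PACKAGE"

# Internal convention: all intervals are BED-style 0-based half-open.
# GFF3 input (1-based inclusive) is converted on read.

#' Reverse-complement a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character vectors; `N` is preserved.
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

new_promoter_set <- function(df) {
  stopifnot(all(c("pangene_id", "accession_id", "gene_id", "sequence") %in% names(df)))
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in promoter set: ",
         paste(head(unique(df$gene_id[duplicated(df$gene_id)]), 3), collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("promoter_set", "data.frame")
  df
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("<promoter_set> %d promoters, %d pangenes, %d accessions\n",
              nrow(x), length(unique(x$pangene_id)), length(unique(x$accession_id))))
  cat(sprintf("  sequence lengths: %d-%d bp\n",
              min(nchar(x$sequence)), max(nchar(x$sequence))))
  invisible(x)
}

#' Build upstream promoter windows from gene annotation
#'
#' For each gene, returns the window of up to `window_bp` bases immediately
#' upstream of the transcription start, in transcription orientation. The
#' transcription start is taken as the annotated gene start on the + strand
#' and the annotated gene end on the - strand. Windows are truncated at
#' coordinate 0 and, on the - strand, at the contig end.
#'
#' @param annotation data.frame with columns `gene_id`, `contig`, `start`,
#'   `end` (0-based half-open) and `strand` (`"+"` or `"-"`).
#' @param window_bp window size in bp (default 2000).
#' @param contig_lengths optional named vector of contig lengths, required to
#'   bound - strand windows.
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (0-based half-open intervals).
#' @export
make_promoter_bed <- function(annotation, window_bp = 2000, contig_lengths = NULL) {
  req <- c("gene_id", "contig", "start", "end", "strand")
  if (!all(req %in% names(annotation))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  }
  bad <- !annotation$strand %in% c("+", "-")
  if (any(bad)) {
    stop("gene(s) with unknown strand: ",
         paste(head(annotation$gene_id[bad], 5), collapse = ", "))
  }
  plus <- annotation$strand == "+"
  out_start <- integer(nrow(annotation))
  out_end <- integer(nrow(annotation))
  # + strand: [max(0, start - window), start)
  out_start[plus] <- pmax(0L, annotation$start[plus] - as.integer(window_bp))
  out_end[plus] <- annotation$start[plus]
  # - strand: [end, end + window), bounded by contig length
  if (any(!plus)) {
    if (is.null(contig_lengths)) {
      stop("contig_lengths is required when - strand genes are present")
    }
    len <- contig_lengths[annotation$contig[!plus]]
    if (anyNA(len)) stop("missing contig length for - strand gene bounds")
    out_start[!plus] <- annotation$end[!plus]
    out_end[!plus] <- pmin(as.integer(len), annotation$end[!plus] + as.integer(window_bp))
  }
  keep <- out_end > out_start
  data.frame(gene_id = annotation$gene_id[keep], contig = annotation$contig[keep],
             start = out_start[keep], end = out_end[keep],
             strand = annotation$strand[keep], stringsAsFactors = FALSE)
}

#' Extract promoter sequences from a genome
#'
#' Minus-strand windows are reverse-complemented, so every promoter reads
#' 5' to 3' toward the transcription start. Each record keeps its genomic
#' interval.
#'
#' @param genome named character vector or `DNAStringSet` of contig sequences.
#' @param intervals data.frame as produced by [make_promoter_bed()].
#' @param id_map data.frame with columns `gene_id`, `pangene_id`,
#'   `accession_id` mapping genes to pangene membership.
#' @return a `promoter_set` data.frame.
#' @export
extract_promoters <- function(genome, intervals, id_map) {
  if (inherits(genome, "DNAStringSet")) genome <- setNames(as.character(genome), names(genome))
  seqs <- character(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    ctg <- intervals$contig[i]
    if (!ctg %in% names(genome)) stop("unknown contig: ", ctg)
    if (intervals$end[i] > nchar(genome[[ctg]])) {
      stop(sprintf("interval [%d,%d) on %s beyond contig end (%d)",
                   intervals$start[i], intervals$end[i], ctg, nchar(genome[[ctg]])))
    }
    s <- substr(genome[[ctg]], intervals$start[i] + 1L, intervals$end[i])
    if (intervals$strand[i] == "-") s <- revcomp(s)
    seqs[i] <- s
  }
  m <- match(intervals$gene_id, id_map$gene_id)
  if (anyNA(m)) stop("id_map is missing gene(s): ",
                     paste(head(intervals$gene_id[is.na(m)], 5), collapse = ", "))
  new_promoter_set(data.frame(
    pangene_id = id_map$pangene_id[m], accession_id = id_map$accession_id[m],
    gene_id = intervals$gene_id, sequence = seqs,
    contig = intervals$contig, start = intervals$start, end = intervals$end,
    strand = intervals$strand, stringsAsFactors = FALSE))
}

#' Read / write promoter FASTA
#'
#' The interchange header dialect is `pangene|accession|gene`, optionally
#' followed by ` contig:start-end(strand)` carrying the genomic interval
#' (0-based half-open). `read_promoter_fasta()` alternatively accepts a
#' sidecar membership table (columns `pangene_id`, `gene_id`,
#' `accession_id`) with plain gene-id headers.
#'
#' @param path FASTA file path.
#' @param membership optional membership data.frame (sidecar alternative to
#'   the `|` header dialect).
#' @return `read_promoter_fasta()`: a `promoter_set`;
#'   `write_promoter_fasta()`: the path, invisibly.
#' @export
read_promoter_fasta <- function(path, membership = NULL) {
  dss <- Biostrings::readDNAStringSet(path)
  headers <- names(dss)
  first <- sub("\\s.*$", "", headers)
  rest <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (is.null(membership)) {
    parts <- strsplit(first, "|", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield != 3)) {
      stop("malformed FASTA header (expected 'pangene|accession|gene') at record ",
           which(nfield != 3)[1], ": ", first[which(nfield != 3)[1]])
    }
    pan <- vapply(parts, `[`, "", 1)
    acc <- vapply(parts, `[`, "", 2)
    gene <- vapply(parts, `[`, "", 3)
  } else {
    gene <- first
    m <- match(gene, membership$gene_id)
    if (anyNA(m)) stop("membership table missing gene(s): ",
                       paste(head(gene[is.na(m)], 5), collapse = ", "))
    pan <- membership$pangene_id[m]
    acc <- membership$accession_id[m]
  }
  df <- data.frame(pangene_id = pan, accession_id = acc, gene_id = gene,
                   sequence = as.character(dss), stringsAsFactors = FALSE)
  loc <- regmatches(rest, regexec("^(\\S+):(\\d+)-(\\d+)\\(([+.-])\\)$", rest))
  has_loc <- lengths(loc) == 5
  if (any(has_loc)) {
    df$contig <- df$strand <- NA_character_
    df$start <- df$end <- NA_integer_
    df$contig[has_loc] <- vapply(loc[has_loc], `[`, "", 2)
    df$start[has_loc] <- as.integer(vapply(loc[has_loc], `[`, "", 3))
    df$end[has_loc] <- as.integer(vapply(loc[has_loc], `[`, "", 4))
    df$strand[has_loc] <- vapply(loc[has_loc], `[`, "", 5)
  }
  rownames(df) <- NULL
  new_promoter_set(df)
}

#' @rdname read_promoter_fasta
#' @param promoters a `promoter_set`.
#' @export
write_promoter_fasta <- function(promoters, path) {
  hdr <- paste(promoters$pangene_id, promoters$accession_id, promoters$gene_id, sep = "|")
  if (!is.null(promoters$contig) && any(!is.na(promoters$contig))) {
    has <- !is.na(promoters$contig)
    hdr[has] <- sprintf("%s %s:%d-%d(%s)", hdr[has], promoters$contig[has],
                        promoters$start[has], promoters$end[has], promoters$strand[has])
  }
  dss <- Biostrings::DNAStringSet(promoters$sequence)
  names(dss) <- hdr
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

#' Read a per-gene expression table
#'
#' @param path TSV with columns `gene_id` and a numeric expression column
#'   (second column, any name).
#' @param transform `"log2_tpm1"` applies `log2(TPM + 1)` to raw TPM input;
#'   `"none"` keeps values as read (already transformed).
#' @return data.frame with columns `gene_id`, `expression`.
#' @export
read_expression <- function(path, transform = c("log2_tpm1", "none")) {
  transform <- match.arg(transform)
  tab <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  if (ncol(tab) < 2) stop("expression table needs gene_id plus a value column")
  val <- tab[[2]]
  if (!is.numeric(val)) stop("non-numeric expression values in ", path)
  if (anyNA(val) || any(!is.finite(val))) stop("missing/non-finite expression values")
  if (transform == "log2_tpm1") {
    if (any(val < 0)) stop("negative TPM values")
    val <- log2(val + 1)
  }
  gid <- as.character(tab[[1]])
  if (anyDuplicated(gid)) stop("duplicate gene_id in expression table")
  data.frame(gene_id = gid, expression = val, stringsAsFactors = FALSE)
}

#' Read a BED3+/narrowPeak interval file
#'
#' Coordinates are kept 0-based half-open as in the file; columns beyond the
#' sixth are ignored. Returns strand `"."` when absent.
#'
#' @param path BED path.
#' @return data.frame with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  tab <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE,
                           fill = TRUE)
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns")
  out <- data.frame(contig = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]), end = as.integer(tab[[3]]),
                    name = if (ncol(tab) >= 4) as.character(tab[[4]]) else NA_character_,
                    score = if (ncol(tab) >= 5) suppressWarnings(as.numeric(tab[[5]])) else NA_real_,
                    strand = if (ncol(tab) >= 6) as.character(tab[[6]]) else ".",
                    stringsAsFactors = FALSE)
  bad <- which(out$start >= out$end)
  if (length(bad)) stop("BED line ", bad[1], ": start >= end")
  out
}

#' Read gene records from a GFF3 file
#'
#' Uses [rtracklayer::import()] and converts coordinates to the internal
#' 0-based half-open convention. Only `gene` features are returned.
#'
#' @param path GFF3 path.
#' @return annotation data.frame suitable for [make_promoter_bed()].
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  data.frame(gene_id = as.character(ids),
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # 1-based -> 0-based
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read a pangene membership table
#'
#' @param path TSV with columns `pangene_id`, `gene_id`, `accession_id`.
#' @return data.frame with those columns.
#' @export
read_membership <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  req <- c("pangene_id", "gene_id", "accession_id")
  if (!all(req %in% names(tab))) {
    stop("membership table must have columns: ", paste(req, collapse = ", "))
  }
  tab[req]
}
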