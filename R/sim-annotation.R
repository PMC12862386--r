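#' Simulate a gene annotation
#'
#' Generates a compact single-isoform annotation (one transcript per gene)
#' with lognormal exon and intron lengths, a mixture of protein-coding and
#' lncRNA genes, and CDS spans leaving 5'/3' UTRs on coding transcripts.
#' Genes are laid head-to-tail along a small number of chromosomes with
#' intergenic gaps.
#'
#' @param n_genes Number of genes (>= 1).
#' @param exons_per_gene Integer range `c(min, max)` of exon counts.
#' @param exon_len_meanlog,exon_len_sdlog Lognormal parameters for exon
#'   lengths (nt).
#' @param intron_len_meanlog,intron_len_sdlog Lognormal parameters for
#'   intron lengths (nt).
#' @param frac_lncRNA Fraction of genes that are lncRNA (no CDS).
#' @param n_chroms Number of chromosomes genes are distributed over.
#' @param gap_mean Mean intergenic gap (nt).
#' @param seed Optional integer seed; the output is deterministic given it.
#'
#' @return A [genome_annotation()].
#' @export
sim_annotation <- function(n_genes,
                           exons_per_gene = c(2L, 8L),
                           exon_len_meanlog = log(150), exon_len_sdlog = 0.5,
                           intron_len_meanlog = log(1000),
                           intron_len_sdlog = 0.9,
                           frac_lncRNA = 0.15,
                           n_chroms = 2L,
                           gap_mean = 3000,
                           seed = NULL) {
  if (!is.numeric(n_genes) || n_genes < 1) abort("`n_genes` must be >= 1.")
  if (length(exons_per_gene) != 2L || any(exons_per_gene < 1) ||
      exons_per_gene[1] > exons_per_gene[2]) {
    abort("`exons_per_gene` must be c(min, max) with 1 <= min <= max.")
  }
  if (exon_len_sdlog < 0 || intron_len_sdlog < 0) {
    abort("Length distribution sdlog parameters must be >= 0.")
  }
  with_seed_if(seed, {
    n_genes <- as.integer(n_genes)
    chrom_of <- paste0("chr", 1L + (seq_len(n_genes) - 1L) %% n_chroms)
    cursor <- setNames(rep(0L, n_chroms), paste0("chr", seq_len(n_chroms)))
    strand_of <- sample(c("+", "-"), n_genes, replace = TRUE)
    coding <- runif(n_genes) >= frac_lncRNA

    genes <- vector("list", n_genes)
    exons <- vector("list", n_genes)
    cds <- vector("list", n_genes)

    for (i in seq_len(n_genes)) {
      gid <- sprintf("G%04d", i)
      txid <- sprintf("T%04d", i)
      chrom <- chrom_of[i]
      strand <- strand_of[i]
      n_ex <- if (exons_per_gene[1] == exons_per_gene[2]) exons_per_gene[1]
              else sample(seq(exons_per_gene[1], exons_per_gene[2]), 1L)
      ex_len <- pmax(10L, as.integer(round(
        rlnorm(n_ex, exon_len_meanlog, exon_len_sdlog))))
      in_len <- if (n_ex > 1L) pmax(30L, as.integer(round(
        rlnorm(n_ex - 1L, intron_len_meanlog, intron_len_sdlog)))) else integer()
      gap <- as.integer(round(gap_mean * (0.5 + runif(1))))
      gstart <- cursor[[chrom]] + gap
      starts <- integer(n_ex); ends <- integer(n_ex)
      pos <- gstart
      for (k in seq_len(n_ex)) {
        starts[k] <- pos
        ends[k] <- pos + ex_len[k]
        pos <- ends[k] + if (k < n_ex) in_len[k] else 0L
      }
      cursor[[chrom]] <- ends[n_ex]
      rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      genes[[i]] <- tibble(gene_id = gid, chrom = chrom, strand = strand,
                           gene_biotype = if (coding[i]) "protein_coding"
                                          else "lncRNA")
      exons[[i]] <- tibble(tx_id = txid, gene_id = gid, chrom = chrom,
                           strand = strand, exon_rank = rank,
                           start = starts, end = ends)
      if (coding[i]) {
        L <- sum(ex_len)
        u5 <- max(1L, as.integer(round(L * runif(1, 0.08, 0.20))))
        u3 <- max(1L, as.integer(round(L * runif(1, 0.10, 0.25))))
        if (u5 + u3 >= L - 3L) { u5 <- 1L; u3 <- 1L }
        ga <- spliced_to_genomic(starts, ends, strand, u5)
        gb <- spliced_to_genomic(starts, ends, strand, L - u3 - 1L)
        cds[[i]] <- tibble(tx_id = txid, gene_id = gid, chrom = chrom,
                           strand = strand,
                           start = min(ga, gb), end = max(ga, gb) + 1L)
      }
    }
    genome_annotation(
      genes = bind_rows(genes),
      transcripts = bind_rows(exons) |> distinct(.data$tx_id, .data$gene_id),
      exons = bind_rows(exons),
      cds = bind_rows(cds)
    )
  })
}

# Map a 0-based spliced-transcript offset to its genomic coordinate.
# `starts`/`ends` are genomic exon bounds in ascending genomic order.
spliced_to_genomic <- function(starts, ends, strand, offset) {
  lens <- ends - starts
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends); lens <- rev(lens) }
  cum <- cumsum(lens)
  k <- which(offset < cum)[1]
  within <- offset - if (k > 1L) cum[k - 1L] else 0L
  if (strand == "+") starts[k] + within else ends[k] - 1L - within
}
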