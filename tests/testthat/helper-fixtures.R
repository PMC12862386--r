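# Hand-built three-gene annotation with known structure:
#   G1 (+, coding)  exons [0,100) [200,300) [400,500), CDS span [50,450)
#   G2 (-, lncRNA)  exons [1000,1100) [1200,1300)
#   G3 (+, coding, single exon) exon [0,300) on chr2, CDS [60,240)
tiny_annotation <- function() {
  genome_annotation(
    genes = tibble::tibble(
      gene_id = c("G1", "G2", "G3"),
      chrom = c("chr1", "chr1", "chr2"),
      strand = c("+", "-", "+"),
      gene_biotype = c("protein_coding", "lncRNA", "protein_coding")),
    transcripts = tibble::tibble(tx_id = c("T1", "T2", "T3"),
                                 gene_id = c("G1", "G2", "G3")),
    exons = tibble::tibble(
      tx_id = c("T1", "T1", "T1", "T2", "T2", "T3"),
      gene_id = c("G1", "G1", "G1", "G2", "G2", "G3"),
      chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
      strand = c("+", "+", "+", "-", "-", "+"),
      exon_rank = c(1L, 2L, 3L, 2L, 1L, 1L),
      start = c(0L, 200L, 400L, 1000L, 1200L, 0L),
      end = c(100L, 300L, 500L, 1100L, 1300L, 300L)),
    cds = tibble::tibble(
      tx_id = c("T1", "T3"), gene_id = c("G1", "G3"),
      chrom = c("chr1", "chr2"), strand = c("+", "+"),
      start = c(50L, 60L), end = c(450L, 240L))
  )
}

# Fast vectorised single-exon annotation; used where only gene ids /
# abundances matter (differential tables, overlap-null simulations).
flat_annotation <- function(n_genes) {
  ids <- sprintf("G%05d", seq_len(n_genes))
  genome_annotation(
    genes = tibble::tibble(gene_id = ids, chrom = "chr1", strand = "+",
                           gene_biotype = "protein_coding"),
    transcripts = tibble::tibble(tx_id = sub("G", "T", ids), gene_id = ids),
    exons = tibble::tibble(tx_id = sub("G", "T", ids), gene_id = ids,
                           chrom = "chr1", strand = "+", exon_rank = 1L,
                           start = (seq_len(n_genes) - 1L) * 500L,
                           end = (seq_len(n_genes) - 1L) * 500L + 300L),
    cds = NULL
  )
}

random_track <- function(n, seed, chroms = c("chr1", "chr2"),
                         max_pos = 5000L) {
  withr::with_seed(seed, {
    tibble::tibble(chrom = sample(chroms, n, TRUE),
                   pos = sample.int(max_pos, n, TRUE) - 1L,
                   strand = sample(c("+", "-"), n, TRUE),
                   count = sample.int(5L, n, TRUE)) |>
      dplyr::distinct(chrom, pos, strand, .keep_all = TRUE)
  })
}

# ---- independent oracles -------------------------------------------------

# set difference on (chrom, pos, strand) keys via environment lookup
oracle_subtract <- function(protein, controls) {
  key <- function(t) paste(t$chrom, t$pos, t$strand)
  drop <- unlist(lapply(controls, key))
  protein[!key(protein) %in% drop, ]
}

# dictionary accumulation of counts
oracle_merge <- function(tracks) {
  env <- new.env()
  for (t in tracks) {
    for (i in seq_len(nrow(t))) {
      k <- paste(t$chrom[i], t$pos[i], t$strand[i])
      env[[k]] <- (if (is.null(env[[k]])) 0L else env[[k]]) + t$count[i]
    }
  }
  ks <- ls(env)
  parts <- do.call(rbind, strsplit(ks, " "))
  out <- tibble::tibble(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                        strand = parts[, 3],
                        count = unname(vapply(ks, \(k) env[[k]], integer(1))))
  out[order(out$chrom, out$pos, out$strand), ]
}

# adjacent-exon gap enumeration with deduplication
oracle_introns <- function(exons) {
  out <- list()
  for (tx in unique(exons$tx_id)) {
    e <- exons[exons$tx_id == tx, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    for (i in seq_len(nrow(e) - 1)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = e$chrom[1], start = e$end[i], end = e$start[i + 1],
        strand = e$strand[1])
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer(), strand = character()))
  d <- do.call(rbind, out)
  d <- unique(d)
  d[order(d$chrom, d$start), ]
}

# quadratic all-pairs stranded interval overlap; returns per-intron score sum
oracle_intron_scores <- function(peaks, introns) {
  score <- numeric(nrow(introns))
  for (i in seq_len(nrow(introns))) {
    for (j in seq_len(nrow(peaks))) {
      if (introns$chrom[i] == peaks$chrom[j] &&
          introns$strand[i] == peaks$strand[j] &&
          peaks$start[j] < introns$end[i] &&
          peaks$end[j] > introns$start[i]) {
        score[i] <- score[i] + peaks$score[j]
      }
    }
  }
  score
}

# one-way ANOVA F from the sum-of-squares definition
oracle_anova_f <- function(values, groups) {
  gm <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  k <- length(unique(groups)); n <- length(values)
  (ssb / (k - 1)) / (ssw / (n - k))
}

oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Newton-Raphson logistic regression (intercept + one slope)
oracle_logistic <- function(x, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    g <- crossprod(X, y - p)
    H <- crossprod(X * W, X)
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  unname(b)
}

# per-pixel 8/4-neighbour scan for thick boundaries
oracle_boundary <- function(mask, connectivity = 8) {
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand.grid(dr = -1:1, dc = -1:1) |>
      (\(g) split(as.matrix(g), seq_len(nrow(g))))() |>
      Filter(f = \(o) any(o != 0))
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr < 1 || rr > nrow(mask) || cc < 1 || cc > ncol(mask)) next
        if (mask[rr, cc] != mask[r, c]) { out[r, c] <- TRUE; break }
      }
    }
  }
  out
}

oracle_dilate_once <- function(x) {
  out <- matrix(FALSE, nrow(x), ncol(x))
  for (r in seq_len(nrow(x))) {
    for (c in seq_len(ncol(x))) {
      rs <- max(1, r - 1):min(nrow(x), r + 1)
      cs <- max(1, c - 1):min(ncol(x), c + 1)
      out[r, c] <- any(x[rs, cs])
    }
  }
  out
}

# classify site positions by disjoint gene-region segments (segments from
# gene_regions are non-overlapping in the simulated annotations)
oracle_classify_sites <- function(track, regions) {
  cls <- rep(NA_character_, nrow(track))
  for (ch in unique(regions$chrom)) {
    seg <- regions[regions$chrom == ch, ]
    seg <- seg[order(seg$start), ]
    sel <- which(track$chrom == ch)
    if (!length(sel)) next
    idx <- findInterval(track$pos[sel], seg$start)
    ok <- idx >= 1 & track$pos[sel] < seg$end[pmax(idx, 1)]
    cls[sel[ok]] <- seg$region[idx[ok]]
  }
  cls
}
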