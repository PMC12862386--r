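test_that("subtract_control matches the set-difference oracle", {
  prot <- random_track(400, seed = 1)
  ctrl <- list(random_track(150, seed = 2), random_track(150, seed = 3))
  got <- subtract_control(prot, ctrl)
  want <- oracle_subtract(prot, ctrl)
  expect_equal(dplyr::arrange(got, chrom, pos, strand),
               dplyr::arrange(want, chrom, pos, strand))
  # counts of surviving sites are untouched
  expect_true(all(got$count == prot$count[match(
    paste(got$chrom, got$pos, got$strand),
    paste(prot$chrom, prot$pos, prot$strand))]))
})

test_that("subtract_control mode='all' removes only the control intersection", {
  prot <- tibble::tibble(chrom = "chr1", pos = 0:3, strand = "+",
                         count = 1:4)
  c1 <- tibble::tibble(chrom = "chr1", pos = c(0L, 1L), strand = "+",
                       count = 1L)
  c2 <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L), strand = "+",
                       count = 1L)
  expect_equal(subtract_control(prot, list(c1, c2))$pos, 3L)
  expect_equal(subtract_control(prot, list(c1, c2), mode = "all")$pos,
               c(0L, 2L, 3L))
})

test_that("strand and chromosome are part of the subtraction key", {
  prot <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                         pos = c(5L, 5L, 5L),
                         strand = c("+", "-", "+"), count = 1L)
  ctrl <- tibble::tibble(chrom = "chr1", pos = 5L, strand = "+", count = 9L)
  left <- subtract_control(prot, ctrl)
  expect_equal(nrow(left), 2L)
  expect_false(any(left$chrom == "chr1" & left$strand == "+"))
})

test_that("merge_replicates matches the accumulation oracle", {
  tracks <- list(random_track(300, seed = 4), random_track(300, seed = 5),
                 random_track(300, seed = 6))
  got <- merge_replicates(tracks)
  want <- oracle_merge(tracks)
  expect_equal(dplyr::arrange(got, chrom, pos, strand) |>
                 dplyr::select(chrom, pos, strand, count),
               tibble::as_tibble(want))
  # uniqueness invariant
  expect_equal(nrow(got), nrow(dplyr::distinct(got, chrom, pos, strand)))
})

test_that("score_peaks recovers a planted cluster and rejects scatter", {
  ann <- flat_annotation(60)   # genes of length 300 at 500-nt spacing
  # gene 1 carries a dense cluster; scattered singletons elsewhere
  cluster <- tibble::tibble(chrom = "chr1", pos = c(100L, 101L, 103L),
                            strand = "+", count = c(10L, 8L, 12L))
  scatter <- tibble::tibble(chrom = "chr1",
                            pos = as.integer(500 * (1:59) + 7 * (1:59) %% 200),
                            strand = "+", count = 1L)
  track <- merge_replicates(list(cluster, scatter))
  peaks <- suppressMessages(
    score_peaks(track, ann, half_window = 3, n_perm = 200, seed = 42))
  top <- peaks[which.max(peaks$score), ]
  expect_equal(top$start, 100L)
  expect_equal(top$end, 104L)
  expect_equal(top$score, 30)
  expect_lt(top$fdr, 0.05)
  expect_equal(top$gene_id, "G00001")
})

test_that("peak FDR is calibrated on enrichment-free tracks", {
  # uniform scatter only: the strict filter should keep (almost) nothing
  ann <- flat_annotation(100)
  withr::with_seed(9, {
    track <- tibble::tibble(
      chrom = "chr1",
      pos = as.integer(sample.int(100 * 500, 400) - 1L),
      strand = "+", count = 1L) |>
      dplyr::distinct(chrom, pos, strand, .keep_all = TRUE) |>
      dplyr::filter((pos %% 500) < 300)   # keep sites inside gene bodies
  })
  peaks <- suppressMessages(
    score_peaks(track, ann, half_window = 3, n_perm = 300, seed = 10))
  kept <- filter_peaks(peaks)
  expect_lte(nrow(kept), 2L)
})

test_that("sites outside all genes are dropped with a message", {
  ann <- flat_annotation(3)
  track <- tibble::tibble(chrom = "chr1", pos = c(10L, 450L), strand = "+",
                          count = 5L)   # 450 is intergenic
  expect_message(score_peaks(track, ann, n_perm = 100, seed = 1),
                 "outside all genes")
})

test_that("score_peaks validates inputs", {
  ann <- flat_annotation(3)
  expect_error(score_peaks(tibble::tibble(chrom = "chr1", pos = 1L,
                                          strand = "+", count = 1L),
                           ann, n_perm = 10), ">= 100")
  expect_error(score_peaks(tibble::tibble(chrom = "chr1", pos = 1.5,
                                          strand = "+", count = 1L),
                           ann, n_perm = 100))
})

test_that("filter_peaks thresholds are strict", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(0L, 10L, 20L, 30L),
                          end = c(5L, 15L, 25L, 35L), strand = "+",
                          score = c(5, 6, 6, 4), fdr = c(0.01, 0.05, 0.049, 0.01),
                          gene_id = "G")
  kept <- filter_peaks(peaks)
  expect_equal(kept$start, 20L)   # only score > 5 AND fdr < 0.05
})

test_that("biotype annotation follows the precedence order", {
  ann <- tiny_annotation()
  # peak spanning the G1 intron-CDS boundary -> CDS wins over intron
  # peak spanning UTR5/CDS boundary -> CDS wins
  # peak fully inside intron 1 -> intron; peak outside genes -> intergenic
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(95L, 45L, 120L, 600L, 1050L),
    end = c(105L, 55L, 130L, 610L, 1060L),
    strand = c("+", "+", "+", "+", "-"),
    score = 10, fdr = 0.01, gene_id = NA_character_)
  ba <- annotate_biotypes(peaks, ann)
  expect_s3_class(ba, "biotype_assignment")
  expect_equal(ba$assignments$biotype,
               c("CDS", "CDS", "intron", "intergenic", "noncoding"))
  expect_equal(sum(ba$proportions$proportion), 1)
  # intronic host split: the single intronic peak sits in coding G1
  expect_equal(ba$intronic_host$host_biotype, "pre-mRNA")
  expect_equal(ba$intronic_host$proportion, 1)
})

test_that("strandedness is respected in biotype assignment", {
  ann <- tiny_annotation()
  pk <- tibble::tibble(chrom = "chr1", start = 1050L, end = 1060L,
                       strand = "+",   # G2 is minus-strand
                       score = 10, fdr = 0.01, gene_id = NA_character_)
  ba <- annotate_biotypes(pk, ann)
  expect_equal(ba$assignments$biotype, "intergenic")
})

test_that("junction metaprofile places offsets strand-correctly", {
  ann <- tiny_annotation()
  # G1 (+): intron 1 = [100,200): 3'SS first exonic nt = 200; 5'SS first
  # intronic nt = 100. G2 (-): intron = [1100,1200): 3'SS exonic nt = 1099,
  # 5'SS intronic nt = 1199.
  track <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1"),
    pos = c(200L, 95L, 1099L, 1204L),
    strand = c("+", "+", "-", "-"),
    count = c(4L, 2L, 8L, 1L))
  prof <- junction_metaprofile(track, ann, flank = 10)
  get <- function(j, off) prof$count[prof$junction == j & prof$offset == off]
  # first exonic nt at the 3'SS on both strands
  expect_equal(get("intron-exon", 0), 4L + 8L)
  # pos 95 ('+') and pos 1204 ('-') are both 5 nt transcriptionally
  # upstream of their exon-intron junctions
  expect_equal(get("exon-intron", -5), 2L + 1L)
  expect_equal(sum(prof$count), 4L + 2L + 8L + 1L)
})

test_that("junction metaprofile CPM normalises per profile", {
  ann <- sim_annotation(n_genes = 30, seed = 5)
  model <- binding_model(ss3_bias = 4)
  sim <- sim_crosslinks(ann, model, n_protein_reps = 1, n_control_reps = 1,
                        total_sites_per_rep = 5000, seed = 6)
  prof <- junction_metaprofile(sim$protein[[1]], ann, flank = 50)
  sums <- prof |>
    dplyr::group_by(junction) |>
    dplyr::summarise(s = sum(cpm), n = sum(count))
  expect_true(all(abs(sums$s[sums$n > 0] - 1e6) < 1e-6))
  expect_equal(nrow(prof), 2 * (2 * 50 + 1))
})

test_that("track BED round-trips", {
  tr <- random_track(100, seed = 12)
  path <- withr::local_tempfile(fileext = ".bed")
  write_track_bed(tr, path)
  back <- read_track_bed(path)
  expect_equal(dplyr::arrange(back, chrom, pos, strand),
               dplyr::arrange(tr, chrom, pos, strand))
})

test_that("peaks BED round-trips coordinates and scores", {
  pk <- tibble::tibble(chrom = "chr1", start = c(10L, 50L), end = c(20L, 60L),
                       strand = c("+", "-"), score = c(12, 7),
                       fdr = c(0.01, 0.002), gene_id = c("A", "B"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(pk, path)
  back <- read_peaks_bed(path)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$score, pk$score)
  expect_equal(back$gene_id, pk$gene_id)
})
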