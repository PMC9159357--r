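# hand-built reference: 400 nt, with a deliberate A-run at 200-210 and a
# T-run at 100-110 to probe the non-genomic check
make_ref <- function() {
  set.seed(99)
  b <- sample(c("C", "G"), 400, TRUE)   # no A/T background
  b[201:211] <- "A"
  b[101:111] <- "T"
  Biostrings::DNAStringSet(setNames(paste(b, collapse = ""), "chrT"))
}

read_row <- function(qname, flag, pos1, cigar, seq, mapq = 40L) {
  data.frame(sample_id = "s1", qname = qname, flag = flag, rname = "chrT",
             pos = pos1, mapq = mapq, cigar = cigar, seq = seq,
             stringsAsFactors = FALSE)
}

call_from <- function(rows, ref, ...) {
  f <- tempfile(fileext = ".sam")
  write_sam(do.call(rbind, rows), f, setNames(400L, "chrT"))
  call_pas_reads(f, ref, ...)
}

test_that("PAS-read calling applies the >=2 non-genomic 5'T rule", {
  ref <- make_ref()
  refstr <- as.character(ref[[1]])
  aln <- function(start1, len) substr(refstr, start1, start1 + len - 1)
  # forward read (minus-strand transcript), clip TTTA: 3 leading Ts, laid
  # back onto C/G background -> non-genomic -> PAS read at first aligned base
  r1 <- read_row("r1", 0L, 51L, "4S30M", paste0("TTTA", aln(51, 30)))
  # clip TA...: only 1 leading T -> not a PAS read
  r2 <- read_row("r2", 0L, 51L, "4S30M", paste0("TACC", aln(51, 30)))
  # clip TT laid back onto the genomic T-run at 100-110 -> genomic -> no call
  r3 <- read_row("r3", 0L, 108L, "2S30M", paste0("TT", aln(108, 30)))
  # low mapping quality is filtered even with a valid clip
  r4 <- read_row("r4", 0L, 51L, "4S30M", paste0("TTTA", aln(51, 30)), mapq = 5L)
  sites <- call_from(list(r1, r2, r3, r4), ref)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$position, 50L)      # 0-based first aligned base
  expect_equal(sites$strand, "-")
  expect_equal(sites$count, 1L)

  # reverse read (plus-strand transcript): trailing clip, read-orientation Ts
  # stored as As; non-genomic over the C/G background -> site at last aligned
  # base on the plus strand
  r5 <- read_row("r5", 16L, 21L, "30M3S", paste0(aln(21, 30), "AAA"))
  # same geometry but the clip lays back onto the genomic A-run -> no call
  r6 <- read_row("r6", 16L, 171L, "30M2S", paste0(aln(171, 30), "AA"))
  sites2 <- call_from(list(r5, r6), ref)
  expect_equal(nrow(sites2), 1)
  expect_equal(sites2$position, 49L)     # 0-based: pos0 20 + 30 - 1
  expect_equal(sites2$strand, "+")
})

test_that("missing reference contig is reported by name", {
  ref <- make_ref()
  r <- read_row("r1", 0L, 51L, "4S30M",
                paste0("TTTA", substr(as.character(ref[[1]]), 51, 80)))
  r$rname <- "chrMissing"
  f <- tempfile(fileext = ".sam")
  write_sam(r, f, setNames(400L, "chrMissing"))
  expect_error(call_pas_reads(f, ref), "chrMissing")
})

test_that("greedy clustering matches its specification on hand cases", {
  s <- data.frame(chrom = "c", strand = "+", position = c(100L, 110L, 140L),
                  n = c(10L, 3L, 5L))
  cl <- cluster_sites(s, window = 24)
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(cl$clusters$summit, c(100L, 140L))
  expect_equal(cl$clusters$total, c(13, 5))
  expect_equal(cl$membership, c(1L, 1L, 2L))

  # tie on total count: smaller coordinate becomes the summit and absorbs
  s2 <- data.frame(chrom = "c", strand = "+", position = c(100L, 112L),
                   n = c(5L, 5L))
  cl2 <- cluster_sites(s2, window = 24)
  expect_equal(nrow(cl2$clusters), 1)
  expect_equal(cl2$clusters$summit, 100L)

  # single site is its own cluster
  s3 <- data.frame(chrom = "c", strand = "-", position = 7L, n = 2L)
  cl3 <- cluster_sites(s3)
  expect_equal(cl3$clusters$summit, 7L)
  expect_equal(cl3$clusters$total, 2)

  expect_error(cluster_sites(s, window = -1), "window")
})

test_that("greedy clustering equals the brute-force oracle on random instances", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(1:12, 1)
    pos <- sample(1:300, n)
    tot <- sample(1:50, n, replace = TRUE)
    s <- data.frame(chrom = "c", strand = "+", position = pos, n = tot)
    cl <- cluster_sites(s, window = 24)
    orc <- oracle_cluster(pos, tot, 24)
    expect_equal(cl$clusters$summit, vapply(orc, `[[`, numeric(1), "summit"))
    expect_equal(cl$clusters$total, vapply(orc, `[[`, numeric(1), "count"))
    # count conservation and summit separation
    expect_equal(sum(cl$clusters$total), sum(tot))
    if (nrow(cl$clusters) > 1)
      expect_true(all(diff(sort(cl$clusters$summit)) > 24))
  }
})

test_that("cluster assignment distinguishes TPA, IPA and intergenic", {
  sim <- small_sim()
  p <- sim$annotation$pas
  cl <- data.frame(cluster_id = sprintf("X%03d", seq_len(nrow(p))),
                   chrom = p$chrom, strand = p$strand, summit = p$position,
                   n_sites = 1L, total = 1, stringsAsFactors = FALSE)
  asg <- assign_clusters(cl, sim$annotation)
  expect_equal(asg$gene_id, p$gene_id)
  expect_equal(asg$region_class, p$region_class)
  expect_equal(asg$host_intron, p$host_intron)

  # a summit 10 nt downstream of a gene end is intergenic (no extension)
  g1 <- sim$annotation$genes[1, ]
  off <- data.frame(cluster_id = "OFF", chrom = g1$chrom, strand = g1$strand,
                    summit = if (g1$strand == "+") g1$end + 10L
                             else g1$start - 11L,
                    n_sites = 1L, total = 1, stringsAsFactors = FALSE)
  asg2 <- assign_clusters(off, sim$annotation)
  expect_true(is.na(asg2$gene_id))
  expect_equal(asg2$region_class, "intergenic")
})

test_that("noise-free alignments round-trip to exact ground truth", {
  sim <- small_sim()
  cfg <- sim$config
  reads <- simulate_alignments(sim$counts, sim$annotation, sim$reference, cfg)
  d <- tempfile()
  files <- write_sam_files(reads, d, sim$annotation$seqlengths,
                           sim$samples$sample_id)
  sites <- call_pas_sites(files, sim$reference)
  cl <- cluster_sites(sites, window = 24)
  asg <- assign_clusters(cl$clusters, sim$annotation)
  expect_equal(nrow(asg), nrow(sim$annotation$pas))
  m <- match(paste(asg$chrom, asg$strand, asg$summit),
             with(sim$annotation$pas, paste(chrom, strand, position)))
  expect_false(anyNA(m))
  got <- as.matrix(asg[, sim$samples$sample_id])
  truth <- sim$counts[sim$annotation$pas$pas_id[m], ]
  dimnames(got) <- dimnames(truth)
  expect_equal(got, truth)
  # count conservation through clustering
  expect_equal(sum(cl$clusters$total), sum(sites[, -(1:3)]))
})

test_that("decoy reads never pass the PAS-read rule", {
  cfg <- sim_config(n_genes = 10, depth = 2000, decoy_fraction = 1, seed = 13)
  sim <- simulate_dataset(cfg)
  reads <- simulate_alignments(sim$counts, sim$annotation, sim$reference, cfg)
  f <- tempfile(fileext = ".sam")
  write_sam(reads[reads$sample_id == sim$samples$sample_id[1], ], f,
            sim$annotation$seqlengths)
  sites <- call_pas_reads(f, sim$reference)
  expect_equal(nrow(sites), 0)
})
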