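test_that("MLH is the per-sample heterozygous proportion", {
  calls <- rbind(c(0L, 1L, 2L, 1L),   # hom het hom het -> 0.5
                 c(0L, 0L, 2L, 2L),   # all hom -> 0
                 c(1L, 1L, NA, 1L))   # 3 usable, all het -> 1
  h <- mlh(toy_genotypes(calls))
  expect_equal(h$mlh, c(0.5, 0, 1))
  expect_equal(h$n_used, c(4, 4, 3))
  expect_equal(attr(h, "mean"), 0.5)
})

test_that("excess-homozygosity F follows the --het convention", {
  # four samples, p = 0.5 at every marker, n/(n-1) = 4/3:
  # E_hom per marker = 1 - 2 * 0.25 * 4/3 = 1/3, so E_hom = 10/3 over L = 10
  calls <- rbind(rep(0L, 10), rep(2L, 10), rep(1L, 10), rep(1L, 10))
  f <- het_inbreeding(toy_genotypes(calls))
  expect_equal(f$e_hom, rep(10 / 3, 4))
  # fully homozygous samples at p = 0.5 -> F = 1; all-het -> (0-E)/(L-E)
  expect_equal(f$F, c(1, 1, -0.5, -0.5))
  # closed form of the statistic itself: O 60, E 50, L 100 -> 0.2
  expect_equal((60 - 50) / (100 - 50), 0.2)
})

test_that("F(het) is centred on zero under Hardy-Weinberg sampling", {
  set.seed(61)
  n <- 120; m <- 800
  p <- runif(m, 0.1, 0.9)
  calls <- sapply(p, function(pp) rbinom(n, 2L, pp))
  f <- het_inbreeding(toy_genotypes(calls, spacing_bp = 1000L))
  se <- sd(f$F) / sqrt(n)
  expect_lt(abs(mean(f$F)), 3 * se + 1e-3)
})

test_that("ROH scan matches the definition on engineered fixtures", {
  p <- roh_params()
  # 60 homozygous SNPs at 20 kb spacing (1.18 Mb span), flanked by hets
  v <- c(rep(1L, 5), rep(0L, 60), rep(1L, 5))
  g <- toy_genotypes(matrix(v, 1), spacing_bp = 20000L)
  seg <- detect_roh(g, p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 60L)
  expect_equal(seg$length_kb, 59 * 20)
  expect_equal(seg$n_het, 0L)

  # 49 homozygous SNPs spanning > 1 Mb fail min_snp
  v2 <- c(rep(1L, 6), rep(0L, 49), rep(1L, 6))
  g2 <- toy_genotypes(matrix(v2, 1), spacing_bp = 25000L)
  expect_equal(nrow(detect_roh(g2, p)), 0L)

  # a 150 kb internal gap splits the run; neither side qualifies
  bp <- c(seq(1e6, by = 20000, length.out = 30),
          seq(1e6 + 29 * 20000 + 150000, by = 20000, length.out = 30))
  map <- data.frame(chrom = "1", id = sprintf("s%02d", 1:60), bp = bp,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  g3 <- genotype_matrix(matrix(0L, 1, 60), map)
  expect_equal(nrow(detect_roh(g3, p)), 0L)

  # alternating het/hom chromosome yields nothing
  g4 <- toy_genotypes(matrix(rep(c(0L, 1L), 60), 1), spacing_bp = 20000L)
  expect_equal(nrow(detect_roh(g4, p)), 0L)
})

test_that("ROH scan agrees with an independent loop re-implementation", {
  set.seed(31)
  p <- roh_params()
  for (rep in 1:6) {
    # mosaics of homozygous stretches and noisy regions over 2 chromosomes
    n_snp <- 800
    mk_chrom <- function() {
      v <- integer(0)
      while (length(v) < n_snp) {
        if (runif(1) < 0.4) {
          v <- c(v, rep(sample(c(0L, 2L), 1), sample(30:120, 1)))
        } else {
          v <- c(v, sample(c(0L, 1L, 2L, NA), sample(20:80, 1), TRUE,
                           prob = c(0.35, 0.25, 0.35, 0.05)))
        }
      }
      v[seq_len(n_snp)]
    }
    calls <- rbind(c(mk_chrom(), mk_chrom()), c(mk_chrom(), mk_chrom()))
    map <- data.frame(chrom = rep(c("1", "2"), each = n_snp),
                      id = sprintf("m%04d", seq_len(2 * n_snp)),
                      bp = rep(seq(1e6, by = 18000, length.out = n_snp), 2),
                      a1 = "A", a2 = "B", stringsAsFactors = FALSE)
    g <- genotype_matrix(calls, map)
    got <- detect_roh(g, p)
    got <- got[order(got$iid, got$chrom, got$start_bp), ]
    rownames(got) <- NULL
    want <- oracle_roh(g, p)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(want) <- NULL
      expect_equal(as.data.frame(got), want)
    }
  }
})

test_that("ROH output is invariant to marker renaming and chromosome order", {
  set.seed(32)
  v <- c(rep(1L, 4), rep(0L, 70), rep(1L, 4),
         sample(c(0L, 1L, 2L), 40, TRUE))
  calls <- matrix(rep(v, 2), 1)
  map <- data.frame(chrom = rep(c("2", "1"), each = length(v)),
                    id = sprintf("x%03d", seq_along(rep(v, 2))),
                    bp = rep(seq(2e6, by = 20000, length.out = length(v)), 2),
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, map)
  s1 <- detect_roh(g)
  map2 <- map
  map2$id <- sprintf("renamed%03d", seq_len(nrow(map)))
  g2 <- genotype_matrix(calls, map2)
  s2 <- detect_roh(g2)
  expect_equal(s1[, -1], s2[, -1])
  expect_equal(s1$start_bp, s2$start_bp)
})

test_that("F_ROH length classes follow the closed forms and are monotone", {
  seg <- data.frame(iid = "S1", chrom = "1", start_bp = 1e6, end_bp = 26e6,
                    length_kb = 25000, n_snps = 500, n_het = 0, n_missing = 0,
                    stringsAsFactors = FALSE)
  # map spanning 2,500 Mb of autosome
  map <- data.frame(chrom = as.character(1:25),
                    bp = 1, a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  map <- do.call(rbind, lapply(as.character(1:25), function(ch)
    data.frame(chrom = ch, id = paste0(ch, "_", 1:2), bp = c(1, 1e8),
               a1 = "A", a2 = "B", stringsAsFactors = FALSE)))
  fr <- froh(seg, map, samples = "S1")
  expect_equal(fr$l_autosome_bp, 25 * (1e8 - 1))
  expect_equal(fr$per_sample$froh_gt1mb, 25e6 / fr$l_autosome_bp)
  expect_equal(fr$per_sample$froh_gt8mb, fr$per_sample$froh_gt1mb)
  # a 3 Mb segment counts only in the >1 and >2 classes
  seg2 <- seg
  seg2$end_bp <- 4e6; seg2$length_kb <- 3000
  fr2 <- froh(seg2, map, samples = "S1")
  expect_gt(fr2$per_sample$froh_gt1mb, 0)
  expect_gt(fr2$per_sample$froh_gt2mb, 0)
  expect_equal(fr2$per_sample$froh_gt4mb, 0)
  expect_equal(fr2$per_sample$froh_gt8mb, 0)
  # monotone non-increasing on random segment sets
  set.seed(8)
  for (rep in 1:10) {
    k <- 40
    st <- runif(k, 1e6, 9e7)
    len <- 10^runif(k, 5.5, 7.3)
    rs <- data.frame(iid = sample(c("a", "b", "c"), k, TRUE),
                     chrom = sample(as.character(1:25), k, TRUE),
                     start_bp = st, end_bp = st + len,
                     length_kb = len / 1000, n_snps = 100, n_het = 0,
                     n_missing = 0, stringsAsFactors = FALSE)
    fr3 <- froh(rs, map, samples = c("a", "b", "c"))
    m <- as.matrix(fr3$per_sample[, sprintf("froh_gt%dmb", c(1, 2, 4, 8))])
    expect_true(all(diff(t(m)) <= 1e-12))
  }
})

test_that("the chance-ROH minimum run length follows the log bound", {
  expect_equal(min_roh_snps(0.05, 100000, 100, 0.30),
               as.integer(ceiling(log(0.05 / 1e7) / log(0.7))))
  expect_equal(min_roh_snps(0.05, 100000, 100, 0.30), 54L)
  expect_equal(min_roh_snps(0.05, 1, 1, 0.5), 5L)
  # more samples can only raise the requirement
  l1 <- min_roh_snps(0.05, 5e4, 100, 0.3)
  l2 <- min_roh_snps(0.05, 5e4, 200, 0.3)
  expect_gte(l2, l1)
  expect_error(min_roh_snps(0.05, 100, 10, 1), "mean_het")
})

test_that("thinning keeps the top-MAF SNP per genome segment", {
  # 3 SNPs in one bin: the MAF 0.3 SNP wins
  calls <- rbind(c(0L, 1L, 0L), c(0L, 1L, 1L), c(1L, 1L, 0L),
                 c(0L, 0L, 0L), c(0L, 0L, 1L))
  # MAFs: 0.1, 0.3, 0.2
  g <- toy_genotypes(calls, spacing_bp = 1000L)
  thin <- thin_for_ne(g, n_bins = 1L, min_maf = 0.05)
  expect_equal(ncol(thin$calls), 1L)
  expect_equal(unname(thin$calls[, 1]), calls[, 2])
  # bins whose SNPs are all below the MAF floor stay empty
  calls2 <- matrix(0L, 20, 2)
  calls2[1, ] <- 1L  # MAF 0.025
  g2 <- toy_genotypes(calls2)
  expect_error(thin_for_ne(g2, n_bins = 2L), "no eligible")
  # output never exceeds n_bins
  set.seed(12)
  g3 <- toy_genotypes(matrix(sample(0:2, 40 * 200, TRUE), 40, 200))
  expect_lte(ncol(thin_for_ne(g3, n_bins = 37L)$calls), 37L)
})

test_that("the drift-r2 estimator matches its closed form", {
  got <- canidiv:::ne_from_r2drift(1 / 300)
  expect_equal(got, (1 / 3 + sqrt(1 / 9 - 2.76 / 300)) * 150)
  expect_equal(got, 97.8852779, tolerance = 1e-7)
  expect_identical(canidiv:::ne_from_r2drift(0), Inf)
  expect_identical(canidiv:::ne_from_r2drift(-0.01), Inf)
})

test_that("ld_ne is stable across independent halves of one population", {
  set.seed(55)
  cfg <- genome_config(n_chromosomes = 8, chrom_length_bp = 8e7,
                       n_markers = 1200, missing_rate = 0)
  g <- wright_fisher(60, 25, cfg, sample_size = 60, seed = 55)
  h1 <- canidiv:::subset_genotypes(g, samples = 1:30)
  h2 <- canidiv:::subset_genotypes(g, samples = 31:60)
  t1 <- thin_for_ne(h1, n_bins = 600)
  t2 <- thin_for_ne(h2, n_bins = 600)
  n1 <- ld_ne(t1)$Ne
  n2 <- ld_ne(t2)$Ne
  expect_true(is.finite(n1) && is.finite(n2))
  expect_lt(abs(log(n1) - log(n2)), 1)
})
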