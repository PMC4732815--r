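#' Runs-of-homozygosity scan parameters
#'
#' Parameter block for [detect_roh()], with the standard SNP-array sliding
#' window defaults used for dense canine chips: 50-SNP windows allowing 1
#' heterozygote and 5 missing calls, a 5% window-hit threshold per SNP, and
#' run-level requirements of at least 50 SNPs, 1000 kb length, one SNP per
#' 50 kb on average, gaps of at most 100 kb between consecutive SNPs, and at
#' most 1 heterozygous call per run.
#'
#' @param window_snp SNPs per sliding window.
#' @param window_het maximum heterozygotes for a window to count as homozygous.
#' @param window_missing maximum missing calls per window.
#' @param window_threshold minimum fraction of homozygous windows covering a
#'   SNP for the SNP to be run-eligible.
#' @param min_snp minimum SNPs per emitted run.
#' @param min_kb minimum run length in kb.
#' @param max_density_kb_per_snp maximum average kb per SNP within a run.
#' @param max_gap_kb maximum gap in kb between consecutive SNPs in a run.
#' @param het_allowed_in_run maximum heterozygous calls inside an emitted run.
#' @return list of class `canidiv_roh_params`.
#' @export
roh_params <- function(window_snp = 50L, window_het = 1L, window_missing = 5L,
                       window_threshold = 0.05, min_snp = 50L, min_kb = 1000,
                       max_density_kb_per_snp = 50, max_gap_kb = 100,
                       het_allowed_in_run = 1L) {
  p <- list(window_snp = as.integer(window_snp),
            window_het = as.integer(window_het),
            window_missing = as.integer(window_missing),
            window_threshold = window_threshold,
            min_snp = as.integer(min_snp),
            min_kb = min_kb,
            max_density_kb_per_snp = max_density_kb_per_snp,
            max_gap_kb = max_gap_kb,
            het_allowed_in_run = as.integer(het_allowed_in_run))
  stopifnot(all(unlist(p) > 0))
  class(p) <- "canidiv_roh_params"
  p
}

#' Detect runs of homozygosity
#'
#' Sliding-window ROH scan. For each sample and chromosome a window of
#' `window_snp` consecutive SNPs slides along the map; a window is homozygous
#' when it contains at most `window_het` heterozygotes and `window_missing`
#' missing calls. Each SNP receives the fraction of overlapping windows that
#' are homozygous, and SNPs at or above `window_threshold` are run-eligible.
#' Maximal stretches of eligible SNPs, split wherever the gap between
#' consecutive SNPs exceeds `max_gap_kb`, become candidate runs; candidates
#' are trimmed so that both endpoints are homozygous non-missing calls (a
#' window allowing one heterozygote otherwise drags flanking heterozygotes
#' into every run), and a trimmed candidate is emitted when it has at least
#' `min_snp` SNPs, spans at least `min_kb` kb, averages at most
#' `max_density_kb_per_snp` kb per SNP and contains at most
#' `het_allowed_in_run` heterozygous calls.
#'
#' @param g a `canidiv_genotypes` with markers sorted by (chromosome, bp)
#'   (the canonical order maintained by [genotype_matrix()]).
#' @param params a [roh_params()] block.
#' @return data frame of class `canidiv_roh`, one row per run: `iid`, `chrom`,
#'   `start_bp`, `end_bp` (positions of the first/last SNP, inclusive),
#'   `length_kb`, `n_snps`, `n_het`, `n_missing`.
#' @export
detect_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "canidiv_genotypes"))
  map <- g$map
  for (ch in unique(map$chrom)) {
    bp <- map$bp[map$chrom == ch]
    if (is.unsorted(bp)) stop("marker map not sorted within chromosome ", ch)
  }
  res <- vector("list", 0L)
  chroms <- unique(map$chrom)
  for (ch in chroms) {
    sel <- which(map$chrom == ch)
    bp <- map$bp[sel]
    nsnp <- length(sel)
    if (nsnp < params$window_snp) next
    gap_break <- c(FALSE, diff(bp) > params$max_gap_kb * 1000)
    for (s in seq_len(nrow(g$calls))) {
      v <- g$calls[s, sel]
      segs <- roh_scan_chrom(v, bp, gap_break, params)
      if (!is.null(segs) && nrow(segs)) {
        segs$iid <- g$samples$iid[s]
        segs$chrom <- ch
        res[[length(res) + 1L]] <- segs
      }
    }
  }
  if (!length(res)) {
    out <- data.frame(iid = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      length_kb = numeric(0), n_snps = integer(0),
                      n_het = integer(0), n_missing = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, res)
    out <- out[, c("iid", "chrom", "start_bp", "end_bp", "length_kb",
                   "n_snps", "n_het", "n_missing")]
    rownames(out) <- NULL
  }
  class(out) <- c("canidiv_roh", "data.frame")
  out
}

# single sample x chromosome scan; v = calls, bp = positions,
# gap_break[i] TRUE when the gap before SNP i exceeds the limit
roh_scan_chrom <- function(v, bp, gap_break, p) {
  n <- length(v)
  het <- !is.na(v) & v == 1L
  miss <- is.na(v)
  w <- p$window_snp
  nw <- n - w + 1L
  hs <- cumsum(het)
  ms <- cumsum(miss)
  win_het <- hs[w:n] - c(0L, hs[seq_len(nw - 1L)])
  win_mis <- ms[w:n] - c(0L, ms[seq_len(nw - 1L)])
  win_ok <- as.integer(win_het <= p$window_het & win_mis <= p$window_missing)
  # per-SNP fraction of covering windows that are homozygous
  cw <- c(0L, cumsum(win_ok))
  lo <- pmax(1L, seq_len(n) - w + 1L)
  hi <- pmin(nw, seq_len(n))
  n_cover <- hi - lo + 1L
  n_ok <- cw[hi + 1L] - cw[lo]
  eligible <- n_ok / n_cover >= p$window_threshold
  # candidate runs: maximal eligible stretches, split at oversized gaps
  run_id <- cumsum(!eligible | gap_break)
  cand <- which(eligible)
  if (!length(cand)) return(NULL)
  pieces <- split(cand, run_id[cand])
  segs <- lapply(pieces, function(ix) {
    a <- ix[1L]; b <- ix[length(ix)]
    # endpoints must be homozygous non-missing calls
    while (a <= b && (het[a] || miss[a])) a <- a + 1L
    while (b >= a && (het[b] || miss[b])) b <- b - 1L
    if (a > b) return(NULL)
    len_kb <- (bp[b] - bp[a]) / 1000
    ns <- b - a + 1L
    nh <- sum(het[a:b])
    if (ns >= p$min_snp && len_kb >= p$min_kb &&
        len_kb / ns <= p$max_density_kb_per_snp &&
        nh <= p$het_allowed_in_run) {
      data.frame(start_bp = bp[a], end_bp = bp[b], length_kb = len_kb,
                 n_snps = ns, n_het = nh, n_missing = sum(miss[a:b]))
    } else NULL
  })
  segs <- segs[!vapply(segs, is.null, logical(1L))]
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

#' Genomic inbreeding from runs of homozygosity (F_ROH)
#'
#' F_ROH is the total ROH length divided by the SNP-covered autosomal genome
#' length, stratified by minimum run length. Longer-run classes capture more
#' recent common ancestors (>1/2/4/8 Mb roughly correspond to common ancestors
#' 50/25/12/6 generations back).
#'
#' @param segments result of [detect_roh()].
#' @param map post-QC marker map (`g$map`); `L_AUTOSOME` is the summed
#'   last-minus-first SNP position over autosomes on this map.
#' @param samples character vector of sample ids to report (samples without
#'   runs get F_ROH 0); defaults to the samples present in `segments`.
#' @param classes_mb minimum-length classes in Mb (strictly greater than).
#' @param autosomes chromosome labels counted in `L_AUTOSOME`.
#' @return list of class `canidiv_froh`: `per_sample` (data frame iid x class
#'   columns `froh_gt1mb` etc.), `by_class` (class summary: mean percent of
#'   genome, mean number of runs, mean SNPs per run, mean F_ROH),
#'   `l_autosome_bp`.
#' @export
froh <- function(segments, map, samples = NULL, classes_mb = c(1, 2, 4, 8),
                 autosomes = as.character(1:38)) {
  if (nrow(map) == 0L) stop("empty marker map")
  amap <- map[map$chrom %in% autosomes, , drop = FALSE]
  if (nrow(amap) == 0L) stop("no autosomal markers in map")
  l_aut <- sum(tapply(amap$bp, amap$chrom, function(b) max(b) - min(b)))
  if (is.null(samples)) samples <- unique(segments$iid)
  seg <- segments[segments$chrom %in% autosomes, , drop = FALSE]
  len_bp <- (seg$end_bp - seg$start_bp)
  per <- data.frame(iid = samples, stringsAsFactors = FALSE)
  by_class <- data.frame(class_mb = classes_mb,
                         pct_genome = NA_real_, mean_n_runs = NA_real_,
                         mean_snps_per_run = NA_real_, mean_froh = NA_real_)
  for (k in seq_along(classes_mb)) {
    thr <- classes_mb[k] * 1e6
    in_class <- len_bp > thr
    tot <- tapply(len_bp[in_class], factor(seg$iid[in_class], levels = samples),
                  sum)
    nrun <- tapply(len_bp[in_class], factor(seg$iid[in_class], levels = samples),
                   length)
    snps <- tapply(seg$n_snps[in_class], factor(seg$iid[in_class], levels = samples),
                   sum)
    tot[is.na(tot)] <- 0
    nrun[is.na(nrun)] <- 0
    fr <- as.numeric(tot) / l_aut
    per[[sprintf("froh_gt%gmb", classes_mb[k])]] <- fr
    per[[sprintf("nruns_gt%gmb", classes_mb[k])]] <- as.numeric(nrun)
    by_class$pct_genome[k] <- 100 * mean(fr)
    by_class$mean_n_runs[k] <- mean(as.numeric(nrun))
    by_class$mean_snps_per_run[k] <-
      if (any(nrun > 0)) sum(snps, na.rm = TRUE) / sum(nrun) else NA_real_
    by_class$mean_froh[k] <- mean(fr)
  }
  structure(list(per_sample = per, by_class = by_class, l_autosome_bp = l_aut),
            class = "canidiv_froh")
}

#' @export
print.canidiv_froh <- function(x, ...) {
  cat(sprintf("F_ROH over %d sample(s); L_AUTOSOME = %.1f Mb\n",
              nrow(x$per_sample), x$l_autosome_bp / 1e6))
  print(x$by_class, row.names = FALSE)
  invisible(x)
}

#' Minimum run length to control chance ROH
#'
#' The smallest number of contiguous homozygous SNPs needed so that fewer than
#' `alpha` runs arise by chance across the dataset, given mean heterozygosity:
#' the smallest integer `l` with
#' `ln(alpha / (n_snps * n_samples)) / ln(1 - mean_het) <= l`.
#'
#' @param alpha tolerated false-positive rate.
#' @param n_snps number of SNPs in the dataset.
#' @param n_samples number of samples.
#' @param mean_het mean SNP heterozygosity, strictly in (0, 1).
#' @return integer minimum SNP count.
#' @references Purfield et al. (2012) Runs of homozygosity and population
#'   history in cattle. BMC Genetics 13:70.
#' @export
min_roh_snps <- function(alpha, n_snps, n_samples, mean_het) {
  if (!(mean_het > 0 && mean_het < 1)) stop("mean_het must be in (0, 1)")
  stopifnot(alpha > 0, n_snps >= 1, n_samples >= 1)
  as.integer(ceiling(log(alpha / (n_snps * n_samples)) / log(1 - mean_het)))
}
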