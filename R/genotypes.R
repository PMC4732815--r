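#' SNP genotype matrix
#'
#' Container for diploid SNP calls: an integer matrix (samples x markers)
#' counting copies of the A1 allele (0, 1, 2, `NA` = missing), a marker map
#' and sample metadata.
#'
#' @param calls integer matrix, samples in rows, markers in columns.
#' @param map data frame with one row per marker: `chrom` (character),
#'   `id`, `bp` (1-based position), `a1`, `a2`. Within a chromosome positions
#'   must be non-decreasing after the canonical (chrom, bp) sort, which is
#'   applied here.
#' @param samples data frame with at least column `iid`; `fid`, `pat`, `mat`,
#'   `sex`, `pheno` are filled with PLINK defaults when absent.
#' @return object of class `canidiv_genotypes`.
#' @export
genotype_matrix <- function(calls, map, samples = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(map), nrow(map) == ncol(calls))
  if (is.null(samples)) {
    ids <- rownames(calls)
    if (is.null(ids)) ids <- sprintf("S%d", seq_len(nrow(calls)))
    samples <- data.frame(iid = ids, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(samples) == nrow(calls))
  if (is.null(samples$fid)) samples$fid <- samples$iid
  for (col in c("pat", "mat")) if (is.null(samples[[col]])) samples[[col]] <- "0"
  if (is.null(samples$sex)) samples$sex <- 0L
  if (is.null(samples$pheno)) samples$pheno <- -9
  map$chrom <- as.character(map$chrom)
  if (is.null(map$id)) map$id <- sprintf("snp%d", seq_len(nrow(map)))
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  bad <- calls < 0L | calls > 2L
  if (any(bad, na.rm = TRUE)) stop("genotype calls must be 0, 1, 2 or NA")
  # canonical marker order
  ord <- order(suppressWarnings(as.numeric(map$chrom)), map$chrom, map$bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  calls <- calls[, ord, drop = FALSE]
  dimnames(calls) <- list(samples$iid, map$id)
  structure(list(calls = calls, map = map, samples = samples),
            class = "canidiv_genotypes")
}

#' @export
print.canidiv_genotypes <- function(x, ...) {
  cat(sprintf("Genotypes: %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("Missing rate: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.canidiv_genotypes <- function(x) dim(x$calls)

subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(g$calls)) else samples
  mi <- if (is.null(markers)) seq_len(ncol(g$calls)) else markers
  genotype_matrix(g$calls[si, mi, drop = FALSE],
                  g$map[mi, , drop = FALSE],
                  g$samples[si, , drop = FALSE])
}

maf <- function(g) {
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Read PLINK genotype filesets
#'
#' Reads a PLINK text fileset (`.ped` + `.map`) or binary fileset
#' (`.bed` + `.bim` + `.fam`, SNP-major layout). Calls count copies of the A1
#' allele in `.bim` order (or the first allele observed per marker for text
#' input without allele declarations).
#'
#' @param prefix path prefix without extension.
#' @param format `"auto"` (detect from files present), `"text"` or `"binary"`.
#' @return a `canidiv_genotypes`.
#' @export
read_plink <- function(prefix, format = c("auto", "text", "binary")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(paste0(prefix, ".bed"))) "binary" else "text"
  }
  if (format == "binary") read_plink_binary(prefix) else read_plink_text(prefix)
}

read_plink_text <- function(prefix) {
  pedf <- paste0(prefix, ".ped")
  mapf <- paste0(prefix, ".map")
  if (!file.exists(pedf) || !file.exists(mapf)) {
    stop("missing .ped/.map at prefix: ", prefix)
  }
  map <- utils::read.table(mapf, colClasses = "character", stringsAsFactors = FALSE)
  names(map) <- c("chrom", "id", "cm", "bp")[seq_len(ncol(map))]
  map$bp <- as.integer(map$bp)
  m <- nrow(map)
  ped <- utils::read.table(pedf, colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(ped) != 6L + 2L * m) {
    stop(sprintf("dimension mismatch: .ped has %d genotype columns for %d markers",
                 ncol(ped) - 6L, m))
  }
  samples <- data.frame(fid = ped[[1L]], iid = ped[[2L]], pat = ped[[3L]],
                        mat = ped[[4L]], sex = as.integer(ped[[5L]]),
                        pheno = as.numeric(ped[[6L]]), stringsAsFactors = FALSE)
  n <- nrow(ped)
  calls <- matrix(NA_integer_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    x <- ped[[6L + 2L * j - 1L]]
    y <- ped[[6L + 2L * j]]
    miss <- x == "0" | y == "0"
    alleles <- sort(unique(c(x[!miss], y[!miss])))
    if (length(alleles) > 2L) {
      stop(sprintf("more than two alleles at marker %s (column %d)", map$id[j], j))
    }
    if (length(alleles) == 0L) alleles <- c("A", "B")
    if (length(alleles) == 1L) alleles <- c(alleles, setdiff(c("A", "B"), alleles)[1L])
    a1[j] <- alleles[1L]; a2[j] <- alleles[2L]
    calls[, j] <- (x == a1[j]) + (y == a1[j])
    calls[miss, j] <- NA_integer_
  }
  map$a1 <- a1; map$a2 <- a2
  genotype_matrix(calls, map, samples)
}

read_plink_binary <- function(prefix) {
  bedf <- paste0(prefix, ".bed")
  bimf <- paste0(prefix, ".bim")
  famf <- paste0(prefix, ".fam")
  if (!all(file.exists(c(bedf, bimf, famf)))) {
    stop("missing .bed/.bim/.fam at prefix: ", prefix)
  }
  bim <- utils::read.table(bimf, colClasses = "character", stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "id", "cm", "bp", "a1", "a2")
  bim$bp <- as.integer(bim$bp)
  fam <- utils::read.table(famf, colClasses = "character", stringsAsFactors = FALSE)
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  fam$sex <- as.integer(fam$sex)
  fam$pheno <- as.numeric(fam$pheno)
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bedf, what = "raw", n = 3L + m * bytes_per_snp)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    stop("not a PLINK .bed file: ", bedf)
  }
  if (raw[3L] != as.raw(0x01)) stop("only SNP-major .bed layout is supported")
  if (length(raw) != 3L + m * bytes_per_snp) {
    stop("dimension mismatch: .bed size does not match .bim/.fam")
  }
  body <- raw[-(1:3)]
  # unpack 2-bit codes: 00=hom A1 (2), 10=het (1), 11=hom A2 (0), 01=missing
  ints <- as.integer(body)
  codes <- matrix(0L, 4L, length(ints))
  codes[1L, ] <- ints %% 4L
  codes[2L, ] <- (ints %/% 4L) %% 4L
  codes[3L, ] <- (ints %/% 16L) %% 4L
  codes[4L, ] <- (ints %/% 64L) %% 4L
  dim(codes) <- c(4L * bytes_per_snp, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  calls <- matrix(NA_integer_, n, m)
  calls[codes == 0L] <- 2L
  calls[codes == 2L] <- 1L
  calls[codes == 3L] <- 0L
  genotype_matrix(calls, bim, fam)
}

#' Write PLINK genotype filesets
#'
#' Writes `.ped`/`.map` (text) or `.bed`/`.bim`/`.fam` (binary, SNP-major)
#' filesets that round-trip through [read_plink()].
#'
#' @param g a `canidiv_genotypes`.
#' @param prefix output path prefix.
#' @param format `"text"` or `"binary"`.
#' @export
write_plink <- function(g, prefix, format = c("text", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "canidiv_genotypes"))
  if (format == "text") write_plink_text(g, prefix) else write_plink_binary(g, prefix)
  invisible(prefix)
}

write_plink_text <- function(g, prefix) {
  map <- g$map
  utils::write.table(
    data.frame(map$chrom, map$id, if (is.null(map$cm)) 0 else map$cm, map$bp),
    paste0(prefix, ".map"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(g$calls); m <- ncol(g$calls)
  geno_cols <- vector("list", 2L * m)
  for (j in seq_len(m)) {
    x <- g$calls[, j]
    first <- ifelse(is.na(x), "0", ifelse(x >= 1L, map$a1[j], map$a2[j]))
    second <- ifelse(is.na(x), "0", ifelse(x == 2L, map$a1[j], map$a2[j]))
    geno_cols[[2L * j - 1L]] <- first
    geno_cols[[2L * j]] <- second
  }
  s <- g$samples
  out <- cbind(data.frame(s$fid, s$iid, s$pat, s$mat, s$sex, s$pheno,
                          stringsAsFactors = FALSE),
               as.data.frame(geno_cols, stringsAsFactors = FALSE,
                             col.names = sprintf("g%d", seq_len(2L * m))))
  utils::write.table(out, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

write_plink_binary <- function(g, prefix) {
  map <- g$map
  utils::write.table(
    data.frame(map$chrom, map$id, if (is.null(map$cm)) 0 else map$cm,
               map$bp, map$a1, map$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  s <- g$samples
  utils::write.table(
    data.frame(s$fid, s$iid, s$pat, s$mat, s$sex, s$pheno),
    paste0(prefix, ".fam"),
    sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(g$calls); m <- ncol(g$calls)
  bytes_per_snp <- ceiling(n / 4)
  # code per genotype: 2 copies A1 -> 0, het -> 2, 0 copies -> 3, NA -> 1
  codes <- matrix(1L, 4L * bytes_per_snp, m)
  x <- g$calls
  cc <- matrix(1L, n, m)
  cc[!is.na(x) & x == 2L] <- 0L
  cc[!is.na(x) & x == 1L] <- 2L
  cc[!is.na(x) & x == 0L] <- 3L
  codes[seq_len(n), ] <- cc
  dim(codes) <- c(4L, bytes_per_snp * m)
  packed <- as.raw(codes[1L, ] + 4L * codes[2L, ] + 16L * codes[3L, ] + 64L * codes[4L, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(packed, con)
}

#' Quality-control filtering of SNP genotypes
#'
#' Applies the standard SNP-array QC cascade: (1) remove samples with a
#' missing-call fraction above `max_sample_missing`; (2) optionally drop
#' non-autosomal markers; (3) keep markers whose call rate exceeds
#' `min_marker_callrate` (strict); (4) keep markers whose minor allele
#' frequency, computed on the surviving samples, passes `min_maf`
#' (`maf_op = "ge"` keeps MAF >= threshold, the default exclusion rule
#' "remove MAF < threshold"; `"gt"` requires strictly greater).
#'
#' @param g a `canidiv_genotypes`.
#' @param max_sample_missing remove samples with missingness above this.
#' @param min_marker_callrate keep markers with call rate strictly above this.
#' @param min_maf minor-allele-frequency threshold.
#' @param autosomes_only drop markers outside `autosomes`.
#' @param autosomes chromosome labels treated as autosomes (dog: 1-38).
#' @param maf_op comparison for the MAF rule, `"ge"` (default) or `"gt"`.
#' @return list with `genotypes` (filtered `canidiv_genotypes`) and `report`
#'   (class `canidiv_qc_report`).
#' @export
qc_filter <- function(g, max_sample_missing = 0.10, min_marker_callrate = 0.90,
                      min_maf = 0.05, autosomes_only = TRUE,
                      autosomes = as.character(1:38),
                      maf_op = c("ge", "gt")) {
  stopifnot(inherits(g, "canidiv_genotypes"))
  maf_op <- match.arg(maf_op)
  if (nrow(g$calls) == 0L || ncol(g$calls) == 0L) stop("empty genotype matrix")
  n0 <- nrow(g$calls); m0 <- ncol(g$calls)

  smiss <- rowMeans(is.na(g$calls))
  drop_samples <- smiss > max_sample_missing
  if (all(drop_samples)) stop("all samples removed by the missingness filter")
  g1 <- subset_genotypes(g, samples = which(!drop_samples))

  non_auto <- if (autosomes_only) !(g1$map$chrom %in% autosomes) else rep(FALSE, ncol(g1$calls))
  callrate <- colMeans(!is.na(g1$calls))
  fail_call <- !non_auto & callrate <= min_marker_callrate
  keep1 <- !non_auto & !fail_call
  g2 <- subset_genotypes(g1, markers = which(keep1))
  mafv <- maf(g2)
  fail_maf <- if (maf_op == "ge") mafv < min_maf else mafv <= min_maf
  fail_maf[is.na(fail_maf)] <- TRUE   # all-missing markers
  g3 <- subset_genotypes(g2, markers = which(!fail_maf))

  report <- structure(list(
    n_samples_in = n0, n_markers_in = m0,
    samples_removed = data.frame(iid = g$samples$iid[drop_samples],
                                 missing_rate = smiss[drop_samples],
                                 stringsAsFactors = FALSE),
    n_samples_removed = sum(drop_samples),
    n_markers_non_autosomal = sum(non_auto),
    n_markers_callrate = sum(fail_call),
    n_markers_maf = sum(fail_maf),
    n_samples_out = nrow(g3$calls),
    n_markers_out = ncol(g3$calls),
    params = list(max_sample_missing = max_sample_missing,
                  min_marker_callrate = min_marker_callrate,
                  min_maf = min_maf, maf_op = maf_op,
                  autosomes_only = autosomes_only)
  ), class = "canidiv_qc_report")
  list(genotypes = g3, report = report)
}

#' @export
print.canidiv_qc_report <- function(x, ...) {
  cat(sprintf("QC: %d samples x %d markers in\n", x$n_samples_in, x$n_markers_in))
  cat(sprintf("  samples removed (missing > %.0f%%): %d\n",
              100 * x$params$max_sample_missing, x$n_samples_removed))
  cat(sprintf("  markers removed: %d non-autosomal, %d call-rate, %d MAF\n",
              x$n_markers_non_autosomal, x$n_markers_callrate, x$n_markers_maf))
  cat(sprintf("  surviving: %d samples x %d markers\n",
              x$n_samples_out, x$n_markers_out))
  invisible(x)
}
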