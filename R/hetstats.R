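#' Multilocus heterozygosity and excess-homozygosity inbreeding
#'
#' `mlh()` returns each sample's multilocus heterozygosity: the proportion of
#' its non-missing genotyped loci that are heterozygous.
#'
#' `het_inbreeding()` returns the method-of-moments inbreeding coefficient
#' from observed versus expected homozygote counts (the PLINK `--het`
#' convention): per sample, `F = (O_hom - E_hom) / (L - E_hom)` where `E_hom`
#' sums `1 - 2 p (1-p) n/(n-1)` over the sample's non-missing markers, with
#' `p` the marker's A1 allele frequency across the matrix and `n` the number
#' of non-missing genotypes at that marker (the `n/(n-1)` factor is the
#' small-sample correction on expected heterozygosity). Markers observed in
#' fewer than two samples are skipped.
#'
#' @param g a `canidiv_genotypes` (normally post-QC).
#' @return data frame, one row per sample: for `mlh()` columns `iid`, `o_het`,
#'   `n_used`, `mlh`; for `het_inbreeding()` columns `iid`, `o_hom`, `e_hom`,
#'   `n_used`, `F`. Both carry the population mean as attribute `mean`.
#'   Samples with zero usable calls are dropped with a warning.
#' @export
mlh <- function(g) {
  stopifnot(inherits(g, "canidiv_genotypes"))
  het <- g$calls == 1L
  used <- !is.na(g$calls)
  n_used <- rowSums(used)
  o_het <- rowSums(het, na.rm = TRUE)
  empty <- n_used == 0L
  if (any(empty)) {
    warning(sprintf("%d sample(s) with no non-missing calls excluded", sum(empty)))
  }
  out <- data.frame(iid = g$samples$iid[!empty],
                    o_het = o_het[!empty],
                    n_used = n_used[!empty],
                    mlh = o_het[!empty] / n_used[!empty],
                    stringsAsFactors = FALSE)
  structure(out, mean = mean(out$mlh))
}

#' @rdname mlh
#' @export
het_inbreeding <- function(g) {
  stopifnot(inherits(g, "canidiv_genotypes"))
  x <- g$calls
  used <- !is.na(x)
  nm <- colSums(used)
  p <- colSums(x, na.rm = TRUE) / (2 * pmax(nm, 1L))
  usable <- nm >= 2L
  # expected homozygosity per marker with the n/(n-1) small-sample factor
  e_marker <- 1 - 2 * p * (1 - p) * nm / pmax(nm - 1L, 1L)
  e_marker[!usable] <- NA_real_
  used_ok <- used[, usable, drop = FALSE]
  o_hom <- rowSums(x[, usable, drop = FALSE] != 1L, na.rm = TRUE)
  e_hom <- as.vector(used_ok %*% e_marker[usable])
  L <- rowSums(used_ok)
  empty <- L == 0L
  if (any(empty)) {
    warning(sprintf("%d sample(s) with no usable calls excluded", sum(empty)))
  }
  Fhat <- (o_hom - e_hom) / (L - e_hom)
  out <- data.frame(iid = g$samples$iid[!empty],
                    o_hom = o_hom[!empty],
                    e_hom = e_hom[!empty],
                    n_used = L[!empty],
                    F = Fhat[!empty],
                    stringsAsFactors = FALSE)
  structure(out, mean = mean(out$F))
}
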