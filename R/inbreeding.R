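#' Pedigree inbreeding coefficients (tabular method)
#'
#' Computes Wright's inbreeding coefficient F for every animal by the
#' Meuwissen-Luo single-pass tabular algorithm on the additive relationship
#' recursion. Exact for any pedigree depth; founders have F = 0.
#'
#' @param ped a `canidiv_pedigree`.
#' @return object of class `canidiv_inbreeding`: data frame with columns
#'   `id`, `birth_year`, `F` (one row per animal, pedigree order) carrying
#'   the mean F as attribute `mean_F`.
#' @references Meuwissen & Luo (1992) Computing inbreeding coefficients in
#'   large populations. Genet Sel Evol 24:305.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "canidiv_pedigree"))
  rec <- ped$records
  n <- ped$n
  si <- rec$sire_idx
  di <- rec$dam_idx
  FF <- numeric(n)
  # Mendelian sampling variance D_i; depends only on parental F, available
  # in topological order. Unknown parent contributes no (1+F)/4 term.
  D <- numeric(n)
  for (i in seq_len(n)) {
    d <- 1
    if (si[i] > 0L) d <- d - 0.25 * (1 + FF[si[i]])
    if (di[i] > 0L) d <- d - 0.25 * (1 + FF[di[i]])
    D[i] <- d
    if (si[i] == 0L && di[i] == 0L) {
      FF[i] <- 0
      next
    }
    # accumulate L coefficients over the ancestor closure of i,
    # processing youngest first (indices descend in topological order)
    L <- numeric(i)
    L[i] <- 1
    active <- i
    aii <- 0
    while (length(active)) {
      j <- active[length(active)]   # active kept sorted ascending
      active <- active[-length(active)]
      lj <- L[j]
      aii <- aii + lj * lj * D[j]
      for (p in c(si[j], di[j])) {
        if (p > 0L) {
          if (L[p] == 0 && !(p %in% active)) {
            active <- sort(c(active, p))
          }
          L[p] <- L[p] + lj / 2
        }
      }
    }
    FF[i] <- aii - 1
  }
  out <- data.frame(id = rec$id, birth_year = rec$birth_year, F = FF,
                    stringsAsFactors = FALSE)
  structure(out, mean_F = mean(FF), class = c("canidiv_inbreeding", "data.frame"))
}

#' @export
print.canidiv_inbreeding <- function(x, ...) {
  cat(sprintf("Inbreeding coefficients for %d animals; mean F = %.4f\n",
              nrow(x), attr(x, "mean_F")))
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Mean inbreeding by birth year
#'
#' Yearly mean inbreeding coefficients over animals born in each year, the
#' series behind an inbreeding-over-time trend plot.
#'
#' @param inb result of [inbreeding()].
#' @param years optional inclusive integer range `c(from, to)`; default spans
#'   the observed birth years. Years with no animals are omitted.
#' @return data frame with columns `year`, `mean_F`, `n`.
#' @export
mean_inbreeding_by_year <- function(inb, years = NULL) {
  stopifnot(inherits(inb, "canidiv_inbreeding"))
  ok <- !is.na(inb$birth_year)
  if (!any(ok)) stop("no animals with a birth year")
  if (is.null(years)) {
    years <- range(inb$birth_year[ok])
  }
  if (length(years) != 2L || years[2] < years[1]) stop("empty or invalid year range")
  keep <- ok & inb$birth_year >= years[1] & inb$birth_year <= years[2]
  if (!any(keep)) stop("no animals born in the requested range")
  agg <- stats::aggregate(inb$F[keep], by = list(year = inb$birth_year[keep]),
                          FUN = function(v) c(mean(v), length(v)))
  data.frame(year = agg$year,
             mean_F = agg$x[, 1],
             n = as.integer(agg$x[, 2]))
}

#' Complete equivalent generations (EqG)
#'
#' EqG of an animal is the sum over all known ancestors of (1/2)^depth,
#' counting each occurrence of an ancestor along a distinct path: the number
#' of fully known generations the pedigree is "equivalent" to. Founders have
#' EqG 0; an animal with both parents known but nothing deeper has EqG 1.
#'
#' @param ped a `canidiv_pedigree`.
#' @param ref optional character vector of reference-population ids over which
#'   the mean and SD are computed (default: all animals).
#' @return data frame (`id`, `eqg`) for the reference animals, with attributes
#'   `mean` and `sd`.
#' @export
equivalent_generations <- function(ped, ref = NULL) {
  stopifnot(inherits(ped, "canidiv_pedigree"))
  rec <- ped$records
  n <- ped$n
  eqg <- numeric(n)
  for (i in seq_len(n)) {
    e <- 0
    if (rec$sire_idx[i] > 0L) e <- e + 0.5 * (1 + eqg[rec$sire_idx[i]])
    if (rec$dam_idx[i] > 0L) e <- e + 0.5 * (1 + eqg[rec$dam_idx[i]])
    eqg[i] <- e
  }
  idx <- if (is.null(ref)) seq_len(n) else ped_index(ped, ref)
  if (!length(idx)) stop("reference population is empty")
  out <- data.frame(id = rec$id[idx], eqg = eqg[idx], stringsAsFactors = FALSE)
  structure(out, mean = mean(out$eqg),
            sd = if (nrow(out) > 1L) stats::sd(out$eqg) else NA_real_)
}

#' Generation interval
#'
#' Mean parent-offspring birth-year difference over all parent links of the
#' reference animals; the average age of parents when progeny are born.
#' Links with a missing birth year on either side are skipped and counted.
#'
#' @param ped a `canidiv_pedigree`.
#' @param ref optional reference-population ids (offspring side); default all.
#' @return numeric mean interval in years, with attributes `n_links` and
#'   `n_skipped`.
#' @export
generation_interval <- function(ped, ref = NULL) {
  stopifnot(inherits(ped, "canidiv_pedigree"))
  rec <- ped$records
  idx <- if (is.null(ref)) seq_len(ped$n) else ped_index(ped, ref)
  diffs <- numeric(0)
  skipped <- 0L
  for (i in idx) {
    for (p in c(rec$sire_idx[i], rec$dam_idx[i])) {
      if (p > 0L) {
        if (!is.na(rec$birth_year[i]) && !is.na(rec$birth_year[p])) {
          diffs <- c(diffs, rec$birth_year[i] - rec$birth_year[p])
        } else {
          skipped <- skipped + 1L
        }
      }
    }
  }
  if (!length(diffs)) stop("no parent-offspring links with birth years on both sides")
  structure(mean(diffs), n_links = length(diffs), n_skipped = skipped)
}

#' Additive relationship matrix
#'
#' Numerator (additive) relationship matrix A for a set of animals, computed
#' by the tabular recursion over the ancestor closure and restricted to the
#' requested submatrix. Diagonals are 1 + F.
#'
#' @param ped a `canidiv_pedigree`.
#' @param ids animal ids for the returned submatrix (default: all animals).
#' @return symmetric numeric matrix with dimnames = ids, plus attribute
#'   `mean_offdiag` (mean off-diagonal relationship).
#' @export
relationship_matrix <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "canidiv_pedigree"))
  rec <- ped$records
  idx <- if (is.null(ids)) seq_len(ped$n) else ped_index(ped, ids)
  keep <- sort(unique(c(idx, ancestor_closure(ped, idx))))
  m <- length(keep)
  pos <- integer(ped$n)
  pos[keep] <- seq_len(m)
  si <- ifelse(rec$sire_idx[keep] > 0L, pos[pmax(rec$sire_idx[keep], 1L)], 0L)
  di <- ifelse(rec$dam_idx[keep] > 0L, pos[pmax(rec$dam_idx[keep], 1L)], 0L)
  A <- matrix(0, m, m)
  for (j in seq_len(m)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      js <- seq_len(j - 1L)
      v <- numeric(j - 1L)
      if (s > 0L) v <- v + 0.5 * A[js, s]
      if (d > 0L) v <- v + 0.5 * A[js, d]
      A[js, j] <- v
      A[j, js] <- v
    }
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  sel <- pos[idx]
  out <- A[sel, sel, drop = FALSE]
  dimnames(out) <- list(rec$id[idx], rec$id[idx])
  n <- nrow(out)
  attr(out, "mean_offdiag") <- if (n > 1L) {
    (sum(out) - sum(diag(out))) / (n * (n - 1L))
  } else NA_real_
  out
}
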