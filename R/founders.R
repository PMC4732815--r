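#' Founder and ancestor statistics from probabilities of gene origin
#'
#' Computes, for a reference population, the probability-of-gene-origin
#' summaries used to monitor diversity loss in closed breeds: the founder
#' count `f`, the effective number of founders `fe = 1 / sum(q^2)` where `q`
#' are the expected founder contributions to the reference gene pool, and the
#' effective number of ancestors `fa = 1 / sum(p^2)` where `p` are the
#' marginal contributions of ancestors selected greedily (each round picks the
#' ancestor explaining the largest share of the reference gene pool not yet
#' explained by previously selected ancestors).
#'
#' @section Gene origins:
#' Every gene lineage traced upward ends at an unknown-parent slot. An animal
#' with both parents unknown is a founder (origin mass 1 of its own genome);
#' an animal with exactly one unknown parent contributes half of its genome as
#' its own origin (a "half founder"). Contributions `q` therefore always sum
#' to 1 over origins.
#'
#' @param ped a `canidiv_pedigree`.
#' @param ref character vector of reference-population ids.
#' @param tol stop the greedy ancestor selection when the best marginal
#'   contribution falls below this (default 1e-9) or when all ancestry is
#'   explained.
#' @return object of class `canidiv_founder_stats`: list with
#'   `f` (number of contributing origins), `fe`, `fa`,
#'   `contributions` (data frame id, q over origins, decreasing),
#'   `marginal_contributions` (data frame id, p, cum_share in % in selection
#'   order).
#' @references Boichard, Maignel & Verrier (1997) The value of using
#'   probabilities of gene origin to measure genetic variability in a
#'   population. Genet Sel Evol 29:5.
#' @export
founder_stats <- function(ped, ref, tol = 1e-9) {
  stopifnot(inherits(ped, "canidiv_pedigree"))
  if (length(ref) == 0L) stop("reference population is empty")
  ridx <- ped_index(ped, ref)
  rec <- ped$records
  n <- ped$n
  si <- rec$sire_idx
  di <- rec$dam_idx
  # origin mass per animal: 0.5 per unknown parent slot
  origin_w <- 0.5 * ((si == 0L) + (di == 0L))

  # expected contribution flow: g[i] = expected fraction of the reference
  # gene pool whose lineage passes through (or starts at) i, optionally
  # blocking propagation through a selected set S
  flow <- function(blocked) {
    g <- numeric(n)
    g[ridx] <- g[ridx] + 1 / length(ridx)
    if (any(blocked)) g[ridx[blocked[ridx]]] <- 0
    for (i in n:1) {
      if (g[i] > 0 && !blocked[i]) {
        if (si[i] > 0L) g[si[i]] <- g[si[i]] + g[i] / 2
        if (di[i] > 0L) g[di[i]] <- g[di[i]] + g[i] / 2
      }
    }
    g
  }

  none <- logical(n)
  g0 <- flow(none)
  q <- g0 * origin_w
  origins <- which(q > 0)
  ordq <- origins[order(-q[origins], rec$id[origins])]
  f <- length(origins)
  fe <- 1 / sum(q[origins]^2)

  # greedy marginal-contribution ancestor selection.
  # candidates: proper ancestors of the reference set, plus reference members
  # that are themselves gene origins (their own mass is otherwise
  # unexplainable).
  cand <- rep(FALSE, n)
  cand[ancestor_closure(ped, ridx)] <- TRUE
  cand[ridx[origin_w[ridx] > 0]] <- TRUE
  sel <- logical(n)
  sel_order <- integer(0)
  p_marg <- numeric(0)
  explained <- 0
  # tie-break: earliest birth year (NA last), then lexicographic id
  byr_key <- ifelse(is.na(rec$birth_year), Inf, rec$birth_year)
  while (any(cand & !sel) && explained < 1 - tol) {
    g <- flow(sel)
    # h[i]: fraction of i's genome not descending from a selected ancestor
    h <- numeric(n)
    for (i in seq_len(n)) {
      up <- function(p) {
        if (p == 0L) 1 else if (sel[p]) 0 else h[p]
      }
      h[i] <- 0.5 * up(si[i]) + 0.5 * up(di[i])
    }
    m <- g * h
    m[!cand | sel] <- -Inf
    best <- which(m == max(m))
    if (length(best) > 1L) {
      best <- best[order(byr_key[best], rec$id[best])][1L]
    }
    if (m[best] < tol) break
    sel[best] <- TRUE
    sel_order <- c(sel_order, best)
    p_marg <- c(p_marg, m[best])
    explained <- explained + m[best]
  }
  fa <- 1 / sum(p_marg^2)
  structure(list(
    f = f,
    fe = fe,
    fa = fa,
    contributions = data.frame(id = rec$id[ordq], q = q[ordq],
                               stringsAsFactors = FALSE),
    marginal_contributions = data.frame(
      id = rec$id[sel_order], p = p_marg,
      cum_share = 100 * cumsum(p_marg),
      stringsAsFactors = FALSE)
  ), class = "canidiv_founder_stats")
}

#' @export
print.canidiv_founder_stats <- function(x, ...) {
  cat(sprintf("Founders f = %d, effective founders fe = %.2f, effective ancestors fa = %.2f\n",
              x$f, x$fe, x$fa))
  cat(sprintf("fe/f = %.3f, fa/fe = %.3f\n", x$fe / x$f, x$fa / x$fe))
  k <- which(x$marginal_contributions$cum_share >= 50)[1L]
  if (!is.na(k)) {
    cat(sprintf("%d ancestor(s) explain >= 50%% of the reference gene pool\n", k))
  }
  invisible(x)
}
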