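# Independent oracles used across the suite. These deliberately use naive
# algorithms (path enumeration, explicit loops) so that agreement with the
# package's production code is informative.

# --- inbreeding by common-ancestor path counting ----------------------------
# F_X = sum over common ancestors A of sire and dam, over pairs of ancestor
# paths meeting only at A, of (1/2)^(n1+n2+1) * (1 + F_A).
# All quantities are dyadic rationals at the depths tested, so doubles are
# exact and equality can be asserted without tolerance.

oracle_inbreeding <- function(ped) {
  rec <- ped$records
  n <- ped$n
  # all upward paths from index i: list of integer vectors (node sequences,
  # starting at i)
  paths_up <- function(i) {
    out <- list(c(i))
    for (p in c(rec$sire_idx[i], rec$dam_idx[i])) {
      if (p > 0L) {
        for (sub in paths_up(p)) out[[length(out) + 1L]] <- c(i, sub)
      }
    }
    out
  }
  Fo <- numeric(n)
  for (i in seq_len(n)) {
    s <- rec$sire_idx[i]
    d <- rec$dam_idx[i]
    if (s == 0L || d == 0L) {
      Fo[i] <- 0
      next
    }
    ps <- paths_up(s)
    pd <- paths_up(d)
    f <- 0
    for (a in ps) {
      for (b in pd) {
        anc <- a[length(a)]
        if (anc != b[length(b)]) next
        # paths may share only their endpoint
        if (length(intersect(a[-length(a)], b[-length(b)])) > 0L) next
        n1 <- length(a) - 1L
        n2 <- length(b) - 1L
        f <- f + 0.5^(n1 + n2 + 1) * (1 + Fo[anc])
      }
    }
    Fo[i] <- f
  }
  Fo
}

# --- naive recursive ancestor enumeration -----------------------------------
oracle_ancestors <- function(ped, id) {
  rec <- ped$records
  res <- new.env()
  walk <- function(i, depth) {
    for (p in c(rec$sire_idx[i], rec$dam_idx[i])) {
      if (p > 0L) {
        pid <- rec$id[p]
        res[[pid]] <- c(if (is.null(res[[pid]])) integer(0) else res[[pid]], depth)
        walk(p, depth + 1L)
      }
    }
  }
  walk(match(id, rec$id), 1L)
  out <- as.list(res)
  lapply(out, function(v) sort(unique(v)))
}

# --- founder contributions by exhaustive path enumeration -------------------
# expected contribution of every animal to a reference set: mean over ref of
# the sum over all upward paths of (1/2)^depth
oracle_contributions <- function(ped, ref) {
  rec <- ped$records
  n <- ped$n
  contrib <- numeric(n)
  add_paths <- function(i, w) {
    for (p in c(rec$sire_idx[i], rec$dam_idx[i])) {
      if (p > 0L) {
        contrib[p] <<- contrib[p] + w / 2
        add_paths(p, w / 2)
      }
    }
  }
  ridx <- match(ref, rec$id)
  for (i in ridx) {
    contrib[i] <- contrib[i] + 1 / length(ridx)
    add_paths(i, 1 / length(ridx))
  }
  stats::setNames(contrib, rec$id)
}

# --- random pedigree generator ----------------------------------------------
# random topology over at most n_max animals: each new animal picks 0, 1 or 2
# earlier animals as parents (always distinct), so arbitrary loop structures
# (full sibs, half sibs, parent-offspring matings) arise.
random_pedigree <- function(n_max, p_founder = 0.3) {
  n <- sample(3:n_max, 1L)
  id <- sprintf("A%02d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (stats::runif(1) > p_founder) {
      par <- sample(seq_len(i - 1L), 2L)
      sire[i] <- id[par[1L]]
      dam[i] <- id[par[2L]]
    }
  }
  # random parents are unordered, so role-based sex conflicts are expected
  suppressWarnings(pedigree(data.frame(id = id, sire = sire, dam = dam,
                                       birth_year = 2000L + seq_len(n),
                                       stringsAsFactors = FALSE)))
}

# --- naive ROH re-implementation --------------------------------------------
# same contract as detect_roh, written with explicit per-window loops
oracle_roh_chrom <- function(v, bp, p) {
  n <- length(v)
  if (n < p$window_snp) return(NULL)
  het <- !is.na(v) & v == 1L
  miss <- is.na(v)
  w <- p$window_snp
  nw <- n - w + 1L
  win_ok <- logical(nw)
  for (i in seq_len(nw)) {
    idx <- i:(i + w - 1L)
    win_ok[i] <- sum(het[idx]) <= p$window_het &&
      sum(miss[idx]) <= p$window_missing
  }
  eligible <- logical(n)
  for (j in seq_len(n)) {
    cov <- max(1L, j - w + 1L):min(nw, j)
    eligible[j] <- mean(win_ok[cov]) >= p$window_threshold
  }
  segs <- list()
  start <- NA_integer_
  flush <- function(a, b) {
    if (is.na(a)) return(NULL)
    while (a <= b && (het[a] || miss[a])) a <- a + 1L
    while (b >= a && (het[b] || miss[b])) b <- b - 1L
    if (a > b) return(NULL)
    len_kb <- (bp[b] - bp[a]) / 1000
    ns <- b - a + 1L
    if (ns >= p$min_snp && len_kb >= p$min_kb &&
        len_kb / ns <= p$max_density_kb_per_snp &&
        sum(het[a:b]) <= p$het_allowed_in_run) {
      data.frame(start_bp = bp[a], end_bp = bp[b], length_kb = len_kb,
                 n_snps = ns, n_het = sum(het[a:b]),
                 n_missing = sum(miss[a:b]))
    } else NULL
  }
  prev <- NA_integer_
  for (j in seq_len(n)) {
    gap_too_big <- !is.na(prev) && (bp[j] - bp[prev]) > p$max_gap_kb * 1000
    if (eligible[j]) {
      if (is.na(start)) {
        start <- j
      } else if (gap_too_big) {
        segs[[length(segs) + 1L]] <- flush(start, prev)
        start <- j
      }
      prev <- j
    } else {
      if (!is.na(start)) segs[[length(segs) + 1L]] <- flush(start, prev)
      start <- NA_integer_
      prev <- j
    }
  }
  if (!is.na(start)) segs[[length(segs) + 1L]] <- flush(start, prev)
  segs <- segs[!vapply(segs, is.null, logical(1L))]
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

oracle_roh <- function(g, p) {
  out <- list()
  for (ch in unique(g$map$chrom)) {
    sel <- which(g$map$chrom == ch)
    for (s in seq_len(nrow(g$calls))) {
      segs <- oracle_roh_chrom(g$calls[s, sel], g$map$bp[sel], p)
      if (!is.null(segs)) {
        segs$iid <- g$samples$iid[s]
        segs$chrom <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$iid, res$chrom, res$start_bp),
      c("iid", "chrom", "start_bp", "end_bp", "length_kb",
        "n_snps", "n_het", "n_missing")]
}

# --- small fixture builders --------------------------------------------------
fullsib_pedigree <- function() {
  pedigree(data.frame(id = c("A", "B", "C", "D", "E"),
                      sire = c(NA, NA, "A", "A", "C"),
                      dam = c(NA, NA, "B", "B", "D"),
                      stringsAsFactors = FALSE))
}

halfsib_pedigree <- function() {
  pedigree(data.frame(id = c("A", "B", "C", "D", "E", "F"),
                      sire = c(NA, NA, NA, "A", "A", "D"),
                      dam = c(NA, NA, NA, "B", "C", "E"),
                      stringsAsFactors = FALSE))
}

# genotype matrix from a plain call matrix on an evenly spaced 1-chromosome map
toy_genotypes <- function(calls, spacing_bp = 20000L, chrom = "1",
                          start_bp = 1e6) {
  m <- ncol(calls)
  map <- data.frame(chrom = chrom,
                    id = sprintf("s%03d", seq_len(m)),
                    bp = as.integer(start_bp + (seq_len(m) - 1L) * spacing_bp),
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  genotype_matrix(calls, map)
}
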