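#' Genome configuration for the simulators
#'
#' Describes the simulated genome: chromosome count and length, evenly spaced
#' marker positions, the founder allele-frequency range, a first-order
#' adjacent-marker LD parameter for founder haplotypes, a uniform
#' recombination map and a genotyping missing rate. The default is a
#' desk-scale dog-like genome: 38 autosomes of 60 Mb carrying 20,000 evenly
#' spaced SNPs in total, founder MAFs uniform on [0.05, 0.5], and 1 cM/Mb.
#'
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_bp chromosome length in bp (all chromosomes equal).
#' @param n_markers total marker count, split evenly across chromosomes.
#' @param founder_maf length-2 range of founder minor allele frequencies.
#' @param ld_rho probability that a founder haplotype copies its previous
#'   marker's allele (first-order LD chain); 0 = linkage equilibrium.
#' @param recomb_rate_cm_per_mb uniform recombination rate.
#' @param missing_rate per-call missing probability in emitted genotypes.
#' @return list of class `canidiv_genome_config`.
#' @export
genome_config <- function(n_chromosomes = 38L, chrom_length_bp = 60e6,
                          n_markers = 20000L, founder_maf = c(0.05, 0.5),
                          ld_rho = 0.5, recomb_rate_cm_per_mb = 1,
                          missing_rate = 0.001) {
  stopifnot(n_chromosomes >= 1, chrom_length_bp > 0, n_markers >= 0,
            length(founder_maf) == 2L, all(founder_maf > 0),
            all(founder_maf < 1), founder_maf[1] <= founder_maf[2],
            ld_rho >= 0, ld_rho < 1, recomb_rate_cm_per_mb >= 0,
            missing_rate >= 0, missing_rate < 1)
  per <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  positions <- lapply(per, function(k) {
    if (k == 0L) numeric(0)
    else round(seq(chrom_length_bp / (k + 1), chrom_length_bp * k / (k + 1),
                   length.out = k))
  })
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = chrom_length_bp,
                 n_markers = as.integer(n_markers),
                 markers_per_chrom = per,
                 positions = positions,
                 founder_maf = founder_maf,
                 ld_rho = ld_rho,
                 recomb_rate_cm_per_mb = recomb_rate_cm_per_mb,
                 missing_rate = missing_rate),
            class = "canidiv_genome_config")
}

#' Simulate a multi-generation pedigree with popular-sire skew
#'
#' Discrete-generation pedigree simulator emulating a closed breed registry:
#' each generation draws sires from the previous generation's males with
#' Dirichlet-distributed usage weights (low `sire_skew` concentrates matings
#' on few popular sires; high values approach equal use), dams uniformly, and
#' optionally truncates ancestry by masking parent links.
#'
#' @param n_founders number of founders (half male, half female; >= 2).
#' @param n_generations number of offspring generations.
#' @param n_per_gen offspring per generation.
#' @param sire_skew Dirichlet concentration for sire usage (> 0; lower = more
#'   skew). Default 1 (moderately unequal use, as seen in breed registries).
#' @param p_unknown probability that a parent link is recorded as unknown.
#' @param base_year founder birth year.
#' @param gen_gap_years mean generation gap in years.
#' @param seed optional RNG seed.
#' @return a `canidiv_pedigree`.
#' @export
simulate_pedigree <- function(n_founders = 100L, n_generations = 10L,
                              n_per_gen = 150L, sire_skew = 1,
                              p_unknown = 0, base_year = 1980L,
                              gen_gap_years = 3L, seed = NULL) {
  stopifnot(n_founders >= 2, n_generations >= 1, n_per_gen >= 1,
            sire_skew > 0, p_unknown >= 0, p_unknown < 1)
  if (!is.null(seed)) set.seed(seed)
  id <- sprintf("F%03d", seq_len(n_founders))
  sex <- rep(c("male", "female"), length.out = n_founders)
  sire <- rep(NA_character_, n_founders)
  dam <- rep(NA_character_, n_founders)
  year <- rep(as.integer(base_year), n_founders)
  prev_ids <- id
  prev_sex <- sex
  for (g in seq_len(n_generations)) {
    sires <- prev_ids[prev_sex == "male"]
    dams <- prev_ids[prev_sex == "female"]
    if (!length(sires) || !length(dams)) {
      stop("generation ", g, " has no available sires or dams")
    }
    ws <- stats::rgamma(length(sires), shape = sire_skew)
    if (sum(ws) == 0) ws <- rep(1, length(sires))
    off_id <- sprintf("G%02d_%03d", g, seq_len(n_per_gen))
    off_sire <- sample(sires, n_per_gen, replace = TRUE, prob = ws / sum(ws))
    off_dam <- sample(dams, n_per_gen, replace = TRUE)
    off_sex <- rep(c("male", "female"), length.out = n_per_gen)
    if (p_unknown > 0) {
      off_sire[stats::runif(n_per_gen) < p_unknown] <- NA_character_
      off_dam[stats::runif(n_per_gen) < p_unknown] <- NA_character_
    }
    id <- c(id, off_id)
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    sex <- c(sex, off_sex)
    year <- c(year, rep(as.integer(base_year + g * gen_gap_years), n_per_gen))
    prev_ids <- off_id
    prev_sex <- off_sex
  }
  suppressWarnings(pedigree(data.frame(id = id, sire = sire, dam = dam,
                                       sex = sex, birth_year = year,
                                       stringsAsFactors = FALSE)))
}

# --- haplotype segment machinery -------------------------------------------
# a haplotype on one chromosome is a pair of parallel vectors:
#   start: segment start positions (start[1] == 0), label: founder-haplotype id
# segment i covers [start[i], start[i+1]) and the last runs to chromosome end.

extract_segments <- function(hap, from, to) {
  i1 <- findInterval(from, hap$start)
  i2 <- findInterval(to, hap$start, left.open = TRUE)
  idx <- i1:i2
  s <- hap$start[idx]
  s[1L] <- from
  list(start = s, label = hap$label[idx])
}

concat_segments <- function(pieces) {
  start <- unlist(lapply(pieces, `[[`, "start"))
  label <- unlist(lapply(pieces, `[[`, "label"))
  # merge adjacent equal labels
  keep <- c(TRUE, label[-1L] != label[-length(label)])
  list(start = start[keep], label = label[keep])
}

# one gamete from two parental haplotypes on one chromosome
meiosis_chrom <- function(hapA, hapB, length_bp, morgans) {
  n_xo <- stats::rpois(1L, morgans)
  phase <- stats::rbinom(1L, 1L, 0.5)
  if (n_xo == 0L) {
    return(if (phase == 0L) hapA else hapB)
  }
  xo <- sort(stats::runif(n_xo, 0, length_bp))
  bounds <- c(0, xo, length_bp)
  pieces <- vector("list", length(bounds) - 1L)
  for (t in seq_len(length(bounds) - 1L)) {
    src <- if ((phase + t - 1L) %% 2L == 0L) hapA else hapB
    pieces[[t]] <- extract_segments(src, bounds[t], bounds[t + 1L])
  }
  concat_segments(pieces)
}

# autozygous intervals where the two haplotypes carry the same founder label
autozygous_intervals <- function(h1, h2, length_bp) {
  b <- sort(unique(c(h1$start, h2$start, length_bp)))
  lab1 <- h1$label[findInterval(b[-length(b)], h1$start)]
  lab2 <- h2$label[findInterval(b[-length(b)], h2$start)]
  eq <- lab1 == lab2
  if (!any(eq)) return(NULL)
  runs <- rle(eq)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- data.frame(start = b[starts[runs$values]],
                    end = b[ends[runs$values] + 1L])
  out
}

#' Gene-dropping simulation through a pedigree
#'
#' Drops uniquely labeled founder haplotypes through a pedigree with
#' recombination (Poisson crossovers, uniform positions, no interference) and
#' reports both the observed SNP genotypes and the realized ground truth:
#' per-animal autozygous fraction (the genome share where both haplotypes
#' carry the same founder-haplotype label), the autozygous tracts themselves,
#' and the pedigree inbreeding coefficient.
#'
#' Founder haplotype alleles are assigned from the configured allele-frequency
#' distribution with first-order adjacent-marker LD, so the genotypes show
#' realistic local redundancy.
#'
#' @param ped a `canidiv_pedigree`.
#' @param cfg a [genome_config()].
#' @param genotypes if `FALSE`, skip allele assignment and return only the
#'   truth (fast; useful for replicated autozygosity studies).
#' @param seed optional RNG seed.
#' @return list of class `canidiv_genedrop`: `genotypes` (a
#'   `canidiv_genotypes`, or `NULL`), `truth` (data frame `id`,
#'   `autozygous_fraction`, `pedigree_F`), `tracts` (data frame `id`, `chrom`,
#'   `start_bp`, `end_bp`).
#' @export
gene_drop <- function(ped, cfg = genome_config(), genotypes = TRUE,
                      seed = NULL) {
  stopifnot(inherits(ped, "canidiv_pedigree"),
            inherits(cfg, "canidiv_genome_config"))
  if (!is.null(seed)) set.seed(seed)
  rec <- ped$records
  n <- ped$n
  nc <- cfg$n_chromosomes
  L <- cfg$chrom_length_bp
  morgans <- L / 1e6 * cfg$recomb_rate_cm_per_mb / 100
  # any unknown parent slot contributes a fresh founder haplotype pair
  haps <- vector("list", n)   # haps[[i]][[h]][[chrom]]
  next_label <- 0L
  new_founder_hap <- function() {
    next_label <<- next_label + 1L
    lapply(seq_len(nc), function(c) list(start = 0, label = next_label))
  }
  gamete_from <- function(parent_idx) {
    hA <- haps[[parent_idx]][[1L]]
    hB <- haps[[parent_idx]][[2L]]
    lapply(seq_len(nc), function(c) meiosis_chrom(hA[[c]], hB[[c]], L, morgans))
  }
  for (i in seq_len(n)) {
    h1 <- if (rec$sire_idx[i] > 0L) gamete_from(rec$sire_idx[i]) else {
      hap <- new_founder_hap(); hap
    }
    h2 <- if (rec$dam_idx[i] > 0L) gamete_from(rec$dam_idx[i]) else new_founder_hap()
    haps[[i]] <- list(h1, h2)
  }
  n_hap_labels <- next_label
  # realized autozygosity + tracts
  auto_frac <- numeric(n)
  tract_list <- list()
  for (i in seq_len(n)) {
    tot <- 0
    for (c in seq_len(nc)) {
      iv <- autozygous_intervals(haps[[i]][[1L]][[c]], haps[[i]][[2L]][[c]], L)
      if (!is.null(iv)) {
        tot <- tot + sum(iv$end - iv$start)
        tract_list[[length(tract_list) + 1L]] <-
          data.frame(id = rec$id[i], chrom = as.character(c),
                     start_bp = iv$start, end_bp = iv$end,
                     stringsAsFactors = FALSE)
      }
    }
    auto_frac[i] <- tot / (nc * L)
  }
  tracts <- if (length(tract_list)) do.call(rbind, tract_list) else
    data.frame(id = character(0), chrom = character(0),
               start_bp = numeric(0), end_bp = numeric(0))
  inb <- inbreeding(ped)
  truth <- data.frame(id = rec$id, autozygous_fraction = auto_frac,
                      pedigree_F = inb$F, stringsAsFactors = FALSE)
  gm <- NULL
  if (genotypes && cfg$n_markers > 0L) {
    founder_alleles <- simulate_founder_haplotypes(n_hap_labels, cfg)
    calls <- matrix(NA_integer_, n, cfg$n_markers)
    col_off <- c(0L, cumsum(cfg$markers_per_chrom))
    for (i in seq_len(n)) {
      for (c in seq_len(nc)) {
        k <- cfg$markers_per_chrom[c]
        if (k == 0L) next
        pos <- cfg$positions[[c]]
        A <- founder_alleles[[c]]
        l1 <- haps[[i]][[1L]][[c]]
        l2 <- haps[[i]][[2L]][[c]]
        lab1 <- l1$label[findInterval(pos, l1$start)]
        lab2 <- l2$label[findInterval(pos, l2$start)]
        jj <- seq_len(k)
        calls[i, col_off[c] + jj] <-
          A[cbind(lab1, jj)] + A[cbind(lab2, jj)]
      }
    }
    if (cfg$missing_rate > 0) {
      calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
    }
    map <- data.frame(
      chrom = rep(as.character(seq_len(nc)), cfg$markers_per_chrom),
      id = sprintf("snp%05d", seq_len(cfg$n_markers)),
      bp = as.integer(unlist(cfg$positions)),
      a1 = "A", a2 = "B", stringsAsFactors = FALSE)
    gm <- genotype_matrix(calls, map,
                          data.frame(iid = rec$id, stringsAsFactors = FALSE))
  }
  structure(list(genotypes = gm, truth = truth, tracts = tracts),
            class = "canidiv_genedrop")
}

# founder haplotype alleles: per chromosome a (labels x markers) 0/1 matrix,
# first-order copy chain along the chromosome for LD
simulate_founder_haplotypes <- function(n_labels, cfg) {
  lapply(seq_len(cfg$n_chromosomes), function(c) {
    k <- cfg$markers_per_chrom[c]
    if (k == 0L) return(matrix(integer(0), n_labels, 0L))
    p <- stats::runif(k, cfg$founder_maf[1], cfg$founder_maf[2])
    A <- matrix(0L, n_labels, k)
    A[, 1L] <- stats::rbinom(n_labels, 1L, p[1L])
    if (k > 1L && cfg$ld_rho > 0) {
      for (j in 2:k) {
        copy <- stats::runif(n_labels) < cfg$ld_rho
        fresh <- stats::rbinom(n_labels, 1L, p[j])
        A[, j] <- ifelse(copy, A[, j - 1L], fresh)
      }
    } else if (k > 1L) {
      for (j in 2:k) A[, j] <- stats::rbinom(n_labels, 1L, p[j])
    }
    A
  })
}

#' Wright-Fisher forward simulation
#'
#' Discrete-generation random-mating diploid population of constant size `ne`
#' (canonical Wright-Fisher: each offspring draws two parents uniformly with
#' replacement, so selfing can occur); gametes recombine with
#' Poisson crossovers on the configured uniform map. Founder haplotypes start
#' in linkage equilibrium at frequencies drawn from the configured range.
#' A random sample of the final generation is genotyped on the configured
#' marker map.
#'
#' @param ne census (= effective, under random mating) population size, >= 2.
#' @param generations number of generations to evolve.
#' @param cfg a [genome_config()].
#' @param sample_size number of final-generation individuals genotyped;
#'   must not exceed `ne`.
#' @param seed optional RNG seed.
#' @return a `canidiv_genotypes` with attribute `true_ne`.
#' @export
wright_fisher <- function(ne, generations, cfg = genome_config(),
                          sample_size = ne, seed = NULL) {
  stopifnot(inherits(cfg, "canidiv_genome_config"))
  if (ne < 2) stop("ne must be at least 2")
  if (sample_size > ne) stop("sample_size cannot exceed ne")
  if (!is.null(seed)) set.seed(seed)
  nc <- cfg$n_chromosomes
  m <- cfg$n_markers
  if (m == 0L) stop("genome configuration has no markers")
  col_off <- c(0L, cumsum(cfg$markers_per_chrom))
  morgans_per_chrom <- cfg$chrom_length_bp / 1e6 * cfg$recomb_rate_cm_per_mb / 100
  p0 <- stats::runif(m, cfg$founder_maf[1], cfg$founder_maf[2])
  H <- matrix(stats::rbinom(2L * ne * m, 1L, rep(p0, each = 2L * ne)),
              nrow = 2L * ne, ncol = m)
  gamete <- function(H, ind) {
    a <- H[2L * ind - 1L, ]
    b <- H[2L * ind, ]
    out <- a
    for (c in seq_len(nc)) {
      k <- cfg$markers_per_chrom[c]
      if (k == 0L) next
      jj <- (col_off[c] + 1L):(col_off[c] + k)
      n_xo <- stats::rpois(1L, morgans_per_chrom)
      phase0 <- stats::rbinom(1L, 1L, 0.5)
      if (n_xo == 0L) {
        if (phase0 == 1L) out[jj] <- b[jj]
      } else {
        xo <- sort(stats::runif(n_xo, 0, cfg$chrom_length_bp))
        phase <- (phase0 + findInterval(cfg$positions[[c]], xo)) %% 2L
        out[jj] <- ifelse(phase == 0L, a[jj], b[jj])
      }
    }
    out
  }
  for (g in seq_len(generations)) {
    Hn <- matrix(0L, 2L * ne, m)
    for (i in seq_len(ne)) {
      par <- sample.int(ne, 2L, replace = TRUE)
      Hn[2L * i - 1L, ] <- gamete(H, par[1L])
      Hn[2L * i, ] <- gamete(H, par[2L])
    }
    H <- Hn
  }
  pick <- sort(sample.int(ne, sample_size))
  calls <- H[2L * pick - 1L, , drop = FALSE] + H[2L * pick, , drop = FALSE]
  if (cfg$missing_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  }
  map <- data.frame(
    chrom = rep(as.character(seq_len(nc)), cfg$markers_per_chrom),
    id = sprintf("snp%05d", seq_len(m)),
    bp = as.integer(unlist(cfg$positions)),
    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, map,
                       data.frame(iid = sprintf("WF%03d", seq_along(pick)),
                                  stringsAsFactors = FALSE))
  attr(g, "true_ne") <- ne
  g
}
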