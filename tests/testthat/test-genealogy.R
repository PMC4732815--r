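test_that("textbook inbreeding identities hold", {
  p <- fullsib_pedigree()
  f <- inbreeding(p)
  expect_equal(f$F[match(c("A", "B", "C", "D"), f$id)], c(0, 0, 0, 0))
  expect_equal(f$F[f$id == "E"], 0.25)   # full-sib mating
  ph <- halfsib_pedigree()
  fh <- inbreeding(ph)
  expect_equal(fh$F[fh$id == "F"], 0.125)  # half-sib mating
})

test_that("tabular inbreeding equals exact path counting on random topologies", {
  set.seed(101)
  for (rep in 1:150) {
    p <- random_pedigree(12, p_founder = 0.25)
    # dyadic rationals at these depths are exact in doubles: exact equality
    expect_identical(inbreeding(p)$F, oracle_inbreeding(p))
  }
})

test_that("mean inbreeding by year aggregates and filters correctly", {
  df <- data.frame(id = c("A", "B", "C", "D", "E"),
                   sire = c(NA, NA, "A", "A", "C"),
                   dam = c(NA, NA, "B", "B", "D"),
                   birth_year = c(2000, 2000, 2002, 2002, 2005),
                   stringsAsFactors = FALSE)
  inb <- inbreeding(pedigree(df))
  yr <- mean_inbreeding_by_year(inb)
  expect_equal(yr$year, c(2000, 2002, 2005))
  expect_equal(yr$mean_F, c(0, 0, 0.25))
  expect_equal(yr$n, c(2L, 2L, 1L))
  yr2 <- mean_inbreeding_by_year(inb, years = c(2001, 2003))
  expect_equal(yr2$year, 2002)
  expect_error(mean_inbreeding_by_year(inb, years = c(2003, 2001)), "range")
})

test_that("equivalent generations follow the closed forms", {
  # both parents known, nothing deeper -> 1
  p1 <- pedigree(data.frame(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                            dam = c(NA, NA, "B"), stringsAsFactors = FALSE))
  expect_equal(equivalent_generations(p1, "C")$eqg, 1)
  # complete 3-generation ancestry (parents, grandparents and
  # great-grandparents all known) -> 3
  ids <- c(sprintf("H%d", 1:8), sprintf("G%d", 1:4), sprintf("P%d", 1:2), "X")
  p3 <- pedigree(data.frame(
    id = ids,
    sire = c(rep(NA, 8), "H1", "H3", "H5", "H7", "G1", "G3", "P1"),
    dam = c(rep(NA, 8), "H2", "H4", "H6", "H8", "G2", "G4", "P2"),
    stringsAsFactors = FALSE))
  expect_equal(equivalent_generations(p3, "X")$eqg, 3)
  # one parent known, that parent with complete 2-generation ancestry -> 1.5
  p2 <- pedigree(data.frame(
    id = c("G1", "G2", "G3", "G4", "P1", "P2", "P", "X"),
    sire = c(rep(NA, 4), "G1", "G3", "P1", "P"),
    dam = c(rep(NA, 4), "G2", "G4", "P2", NA),
    stringsAsFactors = FALSE))
  expect_equal(equivalent_generations(p2, "X")$eqg, 0.5 + 2 * 0.25 + 4 * 0.125)
  # founders are 0
  expect_equal(equivalent_generations(p2, "G1")$eqg, 0)
})

test_that("generation interval averages parent-offspring year gaps", {
  df <- data.frame(id = c("A", "B", "C"),
                   sire = c(NA, NA, "A"), dam = c(NA, NA, "B"),
                   birth_year = c(2000, 2002, 2004),
                   stringsAsFactors = FALSE)
  l <- generation_interval(pedigree(df))
  expect_equal(as.numeric(l), 3)      # links of 4 and 2 years
  expect_equal(attr(l, "n_links"), 2L)
  # fixed 3-year spacing in the simulator
  ps <- simulate_pedigree(n_founders = 10, n_generations = 3, n_per_gen = 10,
                          gen_gap_years = 3, seed = 5)
  expect_equal(as.numeric(generation_interval(ps)), 3)
  df$birth_year <- NA
  expect_error(generation_interval(pedigree(df)), "birth years")
})

test_that("founder contributions, fe and fa follow the gene-origin bookkeeping", {
  p <- pedigree(data.frame(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                           dam = c(NA, NA, "B"), stringsAsFactors = FALSE))
  fs <- founder_stats(p, "C")
  expect_equal(sort(fs$contributions$q), c(0.5, 0.5))
  expect_equal(fs$f, 2L)
  expect_equal(fs$fe, 2)
  expect_equal(fs$fa, 2)

  # q = (0.75, 0.25): D = A x C with C = A x B
  p2 <- pedigree(data.frame(id = c("A", "B", "C", "D"),
                            sire = c(NA, NA, "A", "A"),
                            dam = c(NA, NA, "B", "C"),
                            stringsAsFactors = FALSE))
  fs2 <- founder_stats(p2, "D")
  expect_equal(fs2$contributions$q, c(0.75, 0.25))
  expect_equal(fs2$fe, 1.6)

  # origin masses always sum to 1 and fe <= f on arbitrary topologies
  set.seed(77)
  for (rep in 1:20) {
    ped <- random_pedigree(25)
    ref <- sample(ped$records$id, min(5L, ped$n))
    fs3 <- founder_stats(ped, ref)
    expect_equal(sum(fs3$contributions$q), 1, tolerance = 1e-12)
    expect_lte(fs3$fe, fs3$f + 1e-9)
  }
  # fa <= fe <= f on breeding-structured pedigrees; the greedy marginal
  # selection is prefix-suboptimal, so fa may exceed fe by a sliver --
  # allow 1% slack
  for (s in 1:5) {
    ped <- simulate_pedigree(n_founders = 14, n_generations = 4,
                             n_per_gen = 25, sire_skew = 0.5, seed = 300 + s)
    ref <- ped$records$id[(ped$n - 24):ped$n]
    fs4 <- founder_stats(ped, ref)
    expect_lte(fs4$fa, fs4$fe * 1.01)
    expect_lte(fs4$fe, fs4$f + 1e-9)
  }
})

test_that("founder contributions match path enumeration for full founders", {
  set.seed(99)
  for (rep in 1:15) {
    # pedigrees whose unknown parents come in pairs: origins = classic founders
    n <- 15L
    id <- sprintf("A%02d", 1:n)
    sire <- rep(NA_character_, n)
    dam <- rep(NA_character_, n)
    for (i in 5:n) {
      par <- sample(seq_len(i - 1L), 2L)
      sire[i] <- id[par[1]]
      dam[i] <- id[par[2]]
    }
    # unordered random parents: role-based sex conflicts are expected
    ped <- suppressWarnings(pedigree(data.frame(id = id, sire = sire,
                                                dam = dam,
                                                stringsAsFactors = FALSE)))
    ref <- id[(n - 3):n]
    fs <- founder_stats(ped, ref)
    oc <- oracle_contributions(ped, ref)
    expect_equal(stats::setNames(fs$contributions$q, fs$contributions$id),
                 oc[fs$contributions$id])
  }
})

test_that("a bottleneck ancestor drives fa towards 1, below fe", {
  # repeated backcrossing to one non-founder X funnels nearly all ancestry
  # through X
  rows <- list(c("A", NA, NA), c("B", NA, NA), c("X", "A", "B"),
               c("C0", NA, NA))
  prev <- "C0"
  for (k in 1:5) {
    rows[[length(rows) + 1L]] <- c(sprintf("G%d", k), "X", prev)
    prev <- sprintf("G%d", k)
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("id", "sire", "dam")
  ped <- pedigree(df)
  fs <- founder_stats(ped, "G5")
  expect_lt(fs$fa, fs$fe)
  expect_lt(fs$fa, 1.2)
  expect_equal(fs$marginal_contributions$id[1], "X")
  expect_equal(fs$marginal_contributions$p[1], 1 - 0.5^5)
})

test_that("marginal contributions are non-increasing and sum towards 1", {
  set.seed(123)
  ped <- simulate_pedigree(n_founders = 12, n_generations = 4, n_per_gen = 20,
                           sire_skew = 0.3, seed = 123)
  ref <- ped$records$id[(ped$n - 19):ped$n]
  fs <- founder_stats(ped, ref)
  p <- fs$marginal_contributions$p
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p >= 0))
  expect_lte(max(fs$marginal_contributions$cum_share), 100 + 1e-6)
  expect_gt(max(fs$marginal_contributions$cum_share), 99)
})

test_that("delta F and Ne follow the regression formulation", {
  # exact linear series: b recovered exactly
  yearly <- data.frame(year = 2000:2009, mean_F = 0.01 + 0.001 * (0:9))
  r <- delta_f_ne(yearly, f_n = 0.053, l = 3)
  expect_equal(r$b, 0.001)
  expect_equal(r$delta_F, 0.003 / 0.95)
  expect_equal(r$Ne, 0.95 / 0.006)
  expect_equal(r$Ne, 1 / (2 * r$delta_F))  # identity holds bit-for-bit
  # delta F = 1.2% per generation -> Ne truncates to 41
  y2 <- data.frame(year = 2000:2009, mean_F = 0.004 * (0:9))
  r2 <- delta_f_ne(y2, f_n = 0.012, l = 3)
  expect_equal(r2$delta_F, 0.012)
  expect_equal(trunc(r2$Ne), 41)
  # flat series: Ne undefined, not infinite
  y3 <- data.frame(year = 2000:2009, mean_F = rep(0.02, 10))
  r3 <- delta_f_ne(y3, f_n = 0.02, l = 3)
  expect_false(r3$ne_defined)
  expect_true(is.na(r3$Ne))
})

test_that("eqg-mode regression treats the slope as per-generation", {
  set.seed(8)
  eqg <- runif(50, 1, 5)
  f <- 0.01 + 0.012 * eqg
  r <- delta_f_ne(f_n = mean(f), mode = "eqg", f_individual = f,
                  eqg_individual = eqg)
  expect_equal(r$b, 0.012, tolerance = 1e-10)
  expect_equal(r$delta_F, 0.012 / (1 - (mean(f) - 0.012)), tolerance = 1e-10)
})

test_that("relationship matrix has the additive structure", {
  p <- fullsib_pedigree()
  A <- relationship_matrix(p)
  expect_equal(A["A", "B"], 0)       # unrelated founders
  expect_equal(A["A", "C"], 0.5)     # parent-offspring
  expect_equal(A["C", "D"], 0.5)     # full sibs
  expect_equal(A["E", "E"], 1.25)    # 1 + F for F = 0.25
  expect_true(isSymmetric(unclass(A)))
  # a_ii = 1 + F_i on random pedigrees
  set.seed(21)
  for (rep in 1:10) {
    ped <- random_pedigree(30)
    A <- relationship_matrix(ped)
    f <- inbreeding(ped)
    expect_equal(unname(diag(A)), 1 + f$F[match(rownames(A), f$id)])
  }
})
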