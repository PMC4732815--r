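# deterministic per-stage seed fan-out from one master seed
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 97L + stage * 1009L) %% 2147483647L
}

#' Genealogical diversity report
#'
#' Runs the pedigree half of the diversity analysis: inbreeding coefficients,
#' the yearly mean-F series, complete equivalent generations, generation
#' interval, founder/ancestor statistics and the inbreeding rate with the
#' realized effective population size.
#'
#' @param ped a `canidiv_pedigree`.
#' @param ref reference-population ids (default: all animals). In a genotyping
#'   study this is typically the genotyped animals plus all their ancestors
#'   (see [ref_with_ancestors()]).
#' @param rate_mode regression mode for [delta_f_ne()].
#' @return list of class `canidiv_genealogy_report` with elements
#'   `inbreeding`, `yearly` (Fig-1-style series or `NULL`), `eqg`,
#'   `generation_interval`, `founder_stats`, `rate` (or `NULL` when birth
#'   years are unavailable), `mean_F_ref`, `n_ref`.
#' @export
run_genealogy <- function(ped, ref = NULL, rate_mode = c("birth_year", "eqg")) {
  stopifnot(inherits(ped, "canidiv_pedigree"))
  rate_mode <- match.arg(rate_mode)
  if (is.null(ref)) ref <- ped$records$id
  ridx <- ped_index(ped, ref)
  inb <- inbreeding(ped)
  eqg <- equivalent_generations(ped, ref)
  fs <- founder_stats(ped, ref)
  mean_F_ref <- mean(inb$F[ridx])
  yearly <- NULL
  l <- tryCatch(generation_interval(ped, ref), error = function(e) NULL)
  rate <- NULL
  if (rate_mode == "birth_year") {
    yearly <- tryCatch(mean_inbreeding_by_year(inb), error = function(e) NULL)
    if (!is.null(yearly) && nrow(yearly) >= 3L && !is.null(l)) {
      rate <- delta_f_ne(yearly = yearly, f_n = mean_F_ref, l = l,
                         mode = "birth_year")
    }
  } else {
    rate <- delta_f_ne(f_n = mean_F_ref, l = l, mode = "eqg",
                       f_individual = inb$F[ridx], eqg_individual = eqg$eqg)
  }
  structure(list(inbreeding = inb, yearly = yearly, eqg = eqg,
                 generation_interval = l, founder_stats = fs, rate = rate,
                 mean_F_ref = mean_F_ref, n_ref = length(ridx), ref = ref),
            class = "canidiv_genealogy_report")
}

#' @export
print.canidiv_genealogy_report <- function(x, ...) {
  cat("Genealogical diversity report\n")
  cat(sprintf("  reference population: %d animals, mean F = %.4f\n",
              x$n_ref, x$mean_F_ref))
  cat(sprintf("  EqG = %.2f +/- %.2f\n", attr(x$eqg, "mean"), attr(x$eqg, "sd")))
  if (!is.null(x$generation_interval)) {
    cat(sprintf("  generation interval l = %.2f years\n",
                as.numeric(x$generation_interval)))
  }
  cat(sprintf("  f = %d, fe = %.1f, fa = %.1f\n",
              x$founder_stats$f, x$founder_stats$fe, x$founder_stats$fa))
  if (!is.null(x$rate)) {
    cat(sprintf("  delta F = %.4f (%.2f%%/generation), Ne = %s\n",
                x$rate$delta_F, 100 * x$rate$delta_F,
                if (x$rate$ne_defined) sprintf("%.1f", x$rate$Ne) else "undefined"))
  } else {
    cat("  delta F / Ne: unavailable (no usable birth years)\n")
  }
  invisible(x)
}

#' Reference population as genotyped animals plus ancestors
#'
#' The usual reference set for gene-origin statistics in a genotyping study:
#' the genotyped ids and every pedigree ancestor of any of them.
#'
#' @param ped a `canidiv_pedigree`.
#' @param genotyped_ids character vector of genotyped animal ids.
#' @return character vector of ids.
#' @export
ref_with_ancestors <- function(ped, genotyped_ids) {
  idx <- ped_index(ped, genotyped_ids)
  ped$records$id[sort(unique(c(idx, ancestor_closure(ped, idx))))]
}

#' Molecular diversity report
#'
#' Runs the SNP half of the analysis in pipeline order: QC, multilocus
#' heterozygosity, excess-homozygosity inbreeding, ROH detection, F_ROH by
#' length class, MAF-based thinning, LD-Ne, IBS distances, the mutual-kNN
#' population network and (when >= 3 samples survive QC) a neighbour-joining
#' tree. Each stage's input/output counts are recorded in `log`.
#'
#' @param g a `canidiv_genotypes` (raw; QC is applied here).
#' @param qc_params named list overriding [qc_filter()] defaults.
#' @param rohp a [roh_params()] block.
#' @param ne_bins segment count for [thin_for_ne()].
#' @param network_k,min_cluster parameters for [build_network()].
#' @param autosomes chromosome labels treated as autosomal.
#' @return list of class `canidiv_molecular_report`: `qc`, `genotypes`
#'   (post-QC), `mlh`, `het_f`, `roh`, `froh`, `ldne`, `ibs`, `network`,
#'   `tree`, `log`.
#' @export
run_molecular <- function(g, qc_params = list(), rohp = roh_params(),
                          ne_bins = 10000L, network_k = 10L, min_cluster = 2L,
                          autosomes = as.character(1:38)) {
  stopifnot(inherits(g, "canidiv_genotypes"))
  logs <- list()
  stage <- function(name, value) {
    logs[[name]] <<- value
  }
  qc <- do.call(qc_filter, c(list(g = g, autosomes = autosomes), qc_params))
  gq <- qc$genotypes
  stage("qc", c(samples_in = qc$report$n_samples_in,
                markers_in = qc$report$n_markers_in,
                samples_out = qc$report$n_samples_out,
                markers_out = qc$report$n_markers_out))
  h <- mlh(gq)
  f <- het_inbreeding(gq)
  stage("het", c(samples = nrow(h)))
  segs <- detect_roh(gq, rohp)
  stage("roh", c(segments = nrow(segs)))
  fr <- froh(segs, gq$map, samples = gq$samples$iid, autosomes = autosomes)
  thin <- tryCatch(thin_for_ne(gq, n_bins = ne_bins, autosomes = autosomes),
                   error = function(e) NULL)
  ne <- if (!is.null(thin) && ncol(thin$calls) >= 2L && nrow(thin$calls) >= 2L) {
    ld_ne(thin)
  } else NULL
  stage("ldne", c(snps = if (is.null(thin)) 0L else ncol(thin$calls)))
  d <- ibs_distance(gq)
  net <- if (nrow(gq$calls) > network_k) {
    build_network(d, k = network_k, min_cluster = min_cluster)
  } else NULL
  tree <- if (nrow(gq$calls) >= 3L) nj_tree(d) else NULL
  stage("structure", c(samples = nrow(gq$calls)))
  structure(list(qc = qc$report, genotypes = gq, mlh = h, het_f = f,
                 roh = segs, froh = fr, ldne = ne, ibs = d, network = net,
                 tree = tree, log = logs),
            class = "canidiv_molecular_report")
}

#' @export
print.canidiv_molecular_report <- function(x, ...) {
  cat("Molecular diversity report\n")
  cat(sprintf("  post-QC: %d samples x %d markers\n",
              x$qc$n_samples_out, x$qc$n_markers_out))
  cat(sprintf("  mean MLH = %.4f, mean F(het) = %.4f\n",
              attr(x$mlh, "mean"), attr(x$het_f, "mean")))
  cat(sprintf("  ROH: %d segments; %% genome >1Mb = %.2f\n",
              nrow(x$roh), x$froh$by_class$pct_genome[1L]))
  if (!is.null(x$ldne)) {
    cat(sprintf("  LD Ne = %s\n",
                if (is.finite(x$ldne$Ne)) sprintf("%.1f", x$ldne$Ne) else "Inf"))
  }
  if (!is.null(x$network)) {
    nc <- length(unique(stats::na.omit(x$network$nodes$cluster)))
    cat(sprintf("  network: %d cluster(s)\n", nc))
  }
  invisible(x)
}

#' Correlate pedigree and molecular inbreeding
#'
#' Pearson correlation (with two-sided p-value) between per-animal pedigree F
#' and each molecular inbreeding estimate (excess-homozygosity F and
#' F_ROH > 1 Mb) over the genotyped animals present in both analyses.
#'
#' @param genealogy a `canidiv_genealogy_report`.
#' @param molecular a `canidiv_molecular_report`.
#' @return data frame with one row per molecular estimator: `estimator`, `n`,
#'   `r`, `p_value`.
#' @export
cross_validate <- function(genealogy, molecular) {
  stopifnot(inherits(genealogy, "canidiv_genealogy_report"),
            inherits(molecular, "canidiv_molecular_report"))
  pedF <- stats::setNames(genealogy$inbreeding$F, genealogy$inbreeding$id)
  out <- list()
  hf <- molecular$het_f
  common <- intersect(hf$iid, names(pedF))
  if (length(common) < 3L) stop("fewer than 3 animals with both pedigree and molecular F")
  ct <- stats::cor.test(pedF[common],
                        hf$F[match(common, hf$iid)], method = "pearson")
  out[[1L]] <- data.frame(estimator = "F_het", n = length(common),
                          r = unname(ct$estimate), p_value = ct$p.value)
  fr <- molecular$froh$per_sample
  common2 <- intersect(fr$iid, names(pedF))
  ct2 <- stats::cor.test(pedF[common2],
                         fr$froh_gt1mb[match(common2, fr$iid)],
                         method = "pearson")
  out[[2L]] <- data.frame(estimator = "F_ROH_gt1Mb", n = length(common2),
                          r = unname(ct2$estimate), p_value = ct2$p.value)
  do.call(rbind, out)
}

#' Full diversity analysis
#'
#' Convenience wrapper running [run_genealogy()] on the pedigree (reference =
#' genotyped animals plus ancestors), [run_molecular()] on the genotypes, and
#' [cross_validate()] between them.
#'
#' @param ped a `canidiv_pedigree`.
#' @param g a `canidiv_genotypes` whose sample ids appear in the pedigree.
#' @param ... passed to [run_molecular()].
#' @return list of class `canidiv_diversity_report`: `genealogy`, `molecular`,
#'   `correlation`.
#' @export
full_run <- function(ped, g, ...) {
  ref <- ref_with_ancestors(ped, intersect(g$samples$iid, ped$records$id))
  gen <- run_genealogy(ped, ref = ref)
  mol <- run_molecular(g, ...)
  corr <- tryCatch(cross_validate(gen, mol), error = function(e) NULL)
  structure(list(genealogy = gen, molecular = mol, correlation = corr),
            class = "canidiv_diversity_report")
}

#' @export
print.canidiv_diversity_report <- function(x, ...) {
  print(x$genealogy)
  print(x$molecular)
  if (!is.null(x$correlation)) {
    cat("Pedigree-molecular inbreeding correlation:\n")
    print(x$correlation, row.names = FALSE)
  }
  invisible(x)
}

#' Write a diversity report to files
#'
#' Emits per-animal and summary TSVs, network files, the Newick tree, and a
#' machine-readable JSON summary. Repeated runs on identical inputs produce
#' byte-identical files.
#'
#' @param report a `canidiv_diversity_report`.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "canidiv_diversity_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  gen <- report$genealogy
  wt(data.frame(gen$inbreeding, eqg = gen$eqg$eqg[match(gen$inbreeding$id,
                                                        gen$eqg$id)]),
     "per_animal_f_eqg.tsv")
  if (!is.null(gen$yearly)) wt(gen$yearly, "mean_f_by_year.tsv")
  wt(gen$founder_stats$marginal_contributions, "ancestor_contributions.tsv")
  mol <- report$molecular
  wt(mol$roh, "roh_segments.tsv")
  wt(mol$froh$per_sample, "froh_per_sample.tsv")
  wt(mol$froh$by_class, "froh_by_class.tsv")
  wt(merge(mol$mlh, mol$het_f, by = "iid"), "het_stats.tsv")
  if (!is.null(mol$network)) {
    write_network(mol$network, file.path(dir, "network"))
    files <- c(files, file.path(dir, c("network.graphml", "network_edges.tsv",
                                       "network_nodes.tsv")))
  }
  if (!is.null(mol$tree)) {
    write_newick(mol$tree, file.path(dir, "nj_tree.nwk"))
    files <- c(files, file.path(dir, "nj_tree.nwk"))
  }
  summ <- list(
    genealogical = list(
      n_ref = gen$n_ref,
      mean_F = gen$mean_F_ref,
      eqg_mean = attr(gen$eqg, "mean"),
      eqg_sd = attr(gen$eqg, "sd"),
      generation_interval = if (!is.null(gen$generation_interval))
        as.numeric(gen$generation_interval) else NULL,
      f = gen$founder_stats$f,
      fe = gen$founder_stats$fe,
      fa = gen$founder_stats$fa,
      delta_F = if (!is.null(gen$rate)) gen$rate$delta_F else NULL,
      Ne = if (!is.null(gen$rate) && gen$rate$ne_defined) gen$rate$Ne else NULL
    ),
    molecular = list(
      n_samples = mol$qc$n_samples_out,
      n_markers = mol$qc$n_markers_out,
      mean_mlh = attr(mol$mlh, "mean"),
      mean_f_het = attr(mol$het_f, "mean"),
      pct_genome_roh_gt1mb = mol$froh$by_class$pct_genome[1L],
      ne_ld = if (!is.null(mol$ldne) && is.finite(mol$ldne$Ne))
        mol$ldne$Ne else NULL
    ),
    correlation = if (!is.null(report$correlation))
      report$correlation else NULL
  )
  path <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(files, path)
  invisible(files)
}
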