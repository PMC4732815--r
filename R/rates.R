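#' Inbreeding rate per generation and realized effective population size
#'
#' Estimates the per-generation inbreeding rate dF and the realized effective
#' population size Ne = 1 / (2 dF) from the trend of inbreeding over time.
#'
#' Two regression modes are offered. `"birth_year"` (the default) regresses
#' the yearly mean inbreeding coefficient on birth year, giving a per-year
#' slope `b`; the per-generation increase is then `l * b` with `l` the
#' generation interval, and
#' \deqn{\Delta F = (F_n - F_{n-1}) / (1 - F_{n-1}),\quad F_{n-1} = F_n - l b.}
#' `"eqg"` regresses individual F on complete equivalent generations, so the
#' slope is a per-generation increase directly (no `l` needed).
#'
#' @param yearly data frame with columns `year` and `mean_F`
#'   (see [mean_inbreeding_by_year()]); used in `"birth_year"` mode.
#' @param f_n mean inbreeding coefficient of the reference population.
#' @param l mean generation interval in years (see [generation_interval()]);
#'   required in `"birth_year"` mode.
#' @param mode `"birth_year"` or `"eqg"`.
#' @param f_individual,eqg_individual numeric vectors of per-animal F and EqG;
#'   used in `"eqg"` mode.
#' @return object of class `canidiv_rate`: list with `b` (regression slope),
#'   `l`, `delta_F`, `Ne` (`NA` with `ne_defined = FALSE` when `delta_F <= 0`),
#'   `mode`.
#' @export
delta_f_ne <- function(yearly = NULL, f_n, l = NULL,
                       mode = c("birth_year", "eqg"),
                       f_individual = NULL, eqg_individual = NULL) {
  mode <- match.arg(mode)
  if (mode == "birth_year") {
    if (is.null(yearly) || nrow(yearly) < 3L) {
      stop("birth_year mode needs a yearly mean-F series with >= 3 years")
    }
    if (is.null(l)) stop("birth_year mode needs the generation interval l")
    b <- unname(stats::coef(stats::lm(mean_F ~ year, data = yearly))[2L])
    gain <- as.numeric(l) * b
  } else {
    if (is.null(f_individual) || is.null(eqg_individual) ||
        length(f_individual) < 3L ||
        length(f_individual) != length(eqg_individual)) {
      stop("eqg mode needs matched per-animal F and EqG vectors (>= 3)")
    }
    b <- unname(stats::coef(stats::lm(f_individual ~ eqg_individual))[2L])
    gain <- b
    if (is.null(l)) l <- NA_real_
  }
  f_prev <- f_n - gain
  delta_F <- gain / (1 - f_prev)
  if (is.finite(delta_F) && abs(delta_F) < 1e-12) delta_F <- 0
  ne_defined <- is.finite(delta_F) && delta_F > 0
  structure(list(b = b, l = as.numeric(l), f_n = f_n,
                 delta_F = delta_F,
                 Ne = if (ne_defined) 1 / (2 * delta_F) else NA_real_,
                 ne_defined = ne_defined,
                 mode = mode),
            class = "canidiv_rate")
}

#' @export
print.canidiv_rate <- function(x, ...) {
  cat(sprintf("Inbreeding trend (%s regression): b = %.6f\n", x$mode, x$b))
  cat(sprintf("delta F per generation = %.5f (%.2f%%)\n",
              x$delta_F, 100 * x$delta_F))
  if (x$ne_defined) {
    cat(sprintf("Realized effective population size Ne = %.1f\n", x$Ne))
  } else {
    cat("Realized Ne undefined (delta F <= 0)\n")
  }
  invisible(x)
}
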