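#' Construct a validated pedigree
#'
#' Builds a `canidiv_pedigree` object from a data frame of animal records.
#' Parents that are referenced but have no row of their own are auto-registered
#' as founders (with a warning). Records are re-ordered so that every parent
#' precedes its offspring; a cycle through the parent links is an error.
#'
#' @param df data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` (`"male"`, `"female"` or `"unknown"`) and `birth_year`.
#'   Unknown parents are `NA`.
#' @param unknown_codes character vector of tokens normalised to unknown
#'   parents in addition to `NA` (default `"0"`, `""`, `"NA"`).
#' @return An object of class `canidiv_pedigree`: a list with element `records`
#'   (a data frame in parent-before-offspring order with integer parent
#'   indices `sire_idx`/`dam_idx`, 0 = unknown) and `n`.
#' @details Founder status is defined as both parents unknown. Sex is used
#'   only for sire/dam consistency warnings, never for computation. An animal
#'   recorded as a sire in one row and a dam in another (or whose recorded sex
#'   contradicts its parental role) has its sex reset to `"unknown"` with a
#'   warning.
#' @export
pedigree <- function(df, unknown_codes = c("0", "", "NA")) {
  stopifnot(is.data.frame(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree data frame must have columns id, sire, dam")
  }
  id   <- trimws(as.character(df$id))
  sire <- normalize_unknown(df$sire, unknown_codes)
  dam  <- normalize_unknown(df$dam, unknown_codes)
  sex  <- if ("sex" %in% names(df)) normalize_sex(df$sex) else rep("unknown", nrow(df))
  byr  <- if ("birth_year" %in% names(df)) suppressWarnings(as.integer(df$birth_year)) else rep(NA_integer_, nrow(df))

  if (anyNA(id) || any(id == "")) stop("missing animal id")
  if (anyDuplicated(id)) {
    stop("duplicate animal id: ", id[duplicated(id)][1L])
  }
  if (any(!is.na(sire) & sire == id)) stop("animal recorded as its own sire")
  if (any(!is.na(dam) & dam == id)) stop("animal recorded as its own dam")
  both <- !is.na(sire) & !is.na(dam) & sire == dam
  if (any(both)) stop("sire and dam identical for animal: ", id[both][1L])

  # auto-register referenced-but-absent parents as founders
  referenced <- unique(c(sire[!is.na(sire)], dam[!is.na(dam)]))
  absent <- setdiff(referenced, id)
  if (length(absent)) {
    warning(sprintf("%d parent(s) without their own record added as founders: %s",
                    length(absent), paste(utils::head(absent, 5L), collapse = ", ")))
    id   <- c(id, absent)
    sire <- c(sire, rep(NA_character_, length(absent)))
    dam  <- c(dam, rep(NA_character_, length(absent)))
    sex  <- c(sex, rep("unknown", length(absent)))
    byr  <- c(byr, rep(NA_integer_, length(absent)))
  }

  # sex sanity: sires should be male, dams female
  as_sire <- id %in% sire
  as_dam  <- id %in% dam
  bad <- (as_sire & as_dam) | (as_sire & sex == "female") | (as_dam & sex == "male")
  if (any(bad)) {
    warning(sprintf("sex conflict for %d animal(s) (used as sire and dam, or role contradicts recorded sex); sex set to unknown: %s",
                    sum(bad), paste(utils::head(id[bad], 5L), collapse = ", ")))
    sex[bad] <- "unknown"
  }
  # fill in sex from parental role when unrecorded
  sex[sex == "unknown" & as_sire & !bad] <- "male"
  sex[sex == "unknown" & as_dam & !bad]  <- "female"

  ord <- topo_order(id, sire, dam)
  records <- data.frame(
    id = id[ord], sire = sire[ord], dam = dam[ord],
    sex = sex[ord], birth_year = byr[ord],
    stringsAsFactors = FALSE
  )
  idx <- seq_len(nrow(records))
  names(idx) <- records$id
  records$sire_idx <- ifelse(is.na(records$sire), 0L, idx[records$sire])
  records$dam_idx  <- ifelse(is.na(records$dam), 0L, idx[records$dam])
  structure(list(records = records, n = nrow(records)),
            class = "canidiv_pedigree")
}

normalize_unknown <- function(x, unknown_codes) {
  x <- trimws(as.character(x))
  x[is.na(x) | x %in% unknown_codes] <- NA_character_
  x
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male", "1")] <- "male"
  out[x %in% c("f", "female", "2")] <- "female"
  out
}

# Kahn topological sort over parent -> offspring edges.
# Deterministic: ready animals processed in input order.
topo_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  out <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    v <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(out) < n) {
    on_cycle <- setdiff(idx, out)
    stop("cycle detected in pedigree involving animal: ", id[on_cycle[1L]])
  }
  out
}

#' Read a pedigree file
#'
#' Reads a delimited pedigree table (one row per animal) and returns a
#' validated, topologically ordered pedigree. Default dialect: comma-separated
#' with a header and columns `id,sire,dam,sex,birth_year`; other layouts are
#' handled through `col_map`.
#'
#' @param path file path.
#' @param sep field separator (default `","`; use `"\t"` for TSV).
#' @param col_map named character vector mapping the canonical column names
#'   (`id`, `sire`, `dam`, `sex`, `birth_year`) to the file's column names.
#'   `sex` and `birth_year` are optional.
#' @param unknown_codes tokens interpreted as an unknown parent.
#' @return A `canidiv_pedigree`.
#' @seealso [pedigree()], [write_pedigree()]
#' @export
read_pedigree <- function(path, sep = ",",
                          col_map = c(id = "id", sire = "sire", dam = "dam",
                                      sex = "sex", birth_year = "birth_year"),
                          unknown_codes = c("0", "", "NA")) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  for (k in need) {
    if (!col_map[[k]] %in% names(raw)) {
      stop("configured column missing from file: ", col_map[[k]])
    }
  }
  df <- data.frame(id = raw[[col_map[["id"]]]],
                   sire = raw[[col_map[["sire"]]]],
                   dam = raw[[col_map[["dam"]]]],
                   stringsAsFactors = FALSE)
  if (!is.na(col_map["sex"]) && col_map[["sex"]] %in% names(raw)) {
    df$sex <- raw[[col_map[["sex"]]]]
  }
  if (!is.na(col_map["birth_year"]) && col_map[["birth_year"]] %in% names(raw)) {
    df$birth_year <- raw[[col_map[["birth_year"]]]]
  }
  pedigree(df, unknown_codes = unknown_codes)
}

#' Write a pedigree to a delimited file
#'
#' Writes the canonical columns `id,sire,dam,sex,birth_year`; unknown parents
#' are written as `"0"`. A written pedigree reads back identically.
#'
#' @param ped a `canidiv_pedigree`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_pedigree <- function(ped, path, sep = ",") {
  stopifnot(inherits(ped, "canidiv_pedigree"))
  rec <- ped$records
  out <- data.frame(id = rec$id,
                    sire = ifelse(is.na(rec$sire), "0", rec$sire),
                    dam = ifelse(is.na(rec$dam), "0", rec$dam),
                    sex = rec$sex,
                    birth_year = ifelse(is.na(rec$birth_year), "NA",
                                        as.character(rec$birth_year)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.canidiv_pedigree <- function(x, ...) {
  rec <- x$records
  founders <- sum(rec$sire_idx == 0L & rec$dam_idx == 0L)
  cat(sprintf("Pedigree: %d animals (%d founders)\n", x$n, founders))
  if (any(!is.na(rec$birth_year))) {
    cat(sprintf("Birth years: %d-%d (%d missing)\n",
                min(rec$birth_year, na.rm = TRUE), max(rec$birth_year, na.rm = TRUE),
                sum(is.na(rec$birth_year))))
  }
  invisible(x)
}

#' @export
summary.canidiv_pedigree <- function(object, ...) {
  rec <- object$records
  cat(sprintf("Pedigree with %d animals\n", object$n))
  cat(sprintf("  founders (both parents unknown): %d\n",
              sum(rec$sire_idx == 0L & rec$dam_idx == 0L)))
  cat(sprintf("  one parent unknown: %d\n",
              sum(xor(rec$sire_idx == 0L, rec$dam_idx == 0L))))
  cat(sprintf("  sex: %d male / %d female / %d unknown\n",
              sum(rec$sex == "male"), sum(rec$sex == "female"),
              sum(rec$sex == "unknown")))
  invisible(object)
}

#' Enumerate the ancestors of an animal
#'
#' Returns every distinct ancestor of `id` together with the set of generation
#' depths at which it appears (an ancestor reached along several paths may
#' occur at several depths, e.g. a father also appearing as maternal
#' grandfather).
#'
#' @param ped a `canidiv_pedigree`.
#' @param id animal id.
#' @param max_depth maximum generation depth to search (default unlimited).
#' @return named list: for each ancestor id, a sorted integer vector of depths
#'   (parent = 1). A founder returns an empty list.
#' @export
ancestors_of <- function(ped, id, max_depth = Inf) {
  stopifnot(inherits(ped, "canidiv_pedigree"))
  rec <- ped$records
  i <- match(id, rec$id)
  if (is.na(i)) stop("unknown animal id: ", id)
  depths <- list()
  frontier <- i
  d <- 0L
  while (length(frontier) && d < max_depth) {
    d <- d + 1L
    nxt <- integer(0)
    for (j in frontier) {
      for (p in c(rec$sire_idx[j], rec$dam_idx[j])) {
        if (p > 0L) {
          pid <- rec$id[p]
          depths[[pid]] <- c(depths[[pid]], d)
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- nxt
  }
  lapply(depths, function(v) sort(unique(v)))
}

# integer indices of the proper-ancestor closure of a set of indices
ancestor_closure <- function(ped, idx) {
  rec <- ped$records
  seen <- logical(ped$n)
  stack <- idx
  while (length(stack)) {
    j <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (p in c(rec$sire_idx[j], rec$dam_idx[j])) {
      if (p > 0L && !seen[p]) {
        seen[p] <- TRUE
        stack <- c(stack, p)
      }
    }
  }
  which(seen)
}

# resolve a vector of ids to indices, with validation
ped_index <- function(ped, ids) {
  i <- match(ids, ped$records$id)
  if (anyNA(i)) stop("id(s) not in pedigree: ", paste(ids[is.na(i)][1:min(3, sum(is.na(i)))], collapse = ", "))
  i
}
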