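#' Validate and topologically order a pedigree
#'
#' A pedigree table has columns `id`, `sire`, `dam` (NA = unknown parent)
#' and usually `sex`, `line`, `generation`, `role`. Ordering is by parent
#' links only; a cycle raises an error naming the offending chain.
#'
#' @param ped pedigree data.frame.
#' @return the pedigree reordered so every parent precedes its offspring.
#' @export
sort_pedigree <- function(ped) {
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped))) stopf("pedigree needs columns id, sire, dam")
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  if (anyDuplicated(ped$id)) stopf("duplicated ids in pedigree")
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)   # NA = founder parent or unknown
  di <- match(ped$dam, ped$id)
  # Kahn's algorithm on the parent -> offspring graph
  npar <- (!is.na(si)) + (!is.na(di))
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(c(si[i], di[i]))) {
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
    }
  }
  order_out <- integer(0)
  ready <- which(npar == 0L)
  remaining <- npar
  while (length(ready)) {
    order_out <- c(order_out, ready)
    nxt <- integer(0)
    for (j in ready) {
      for (k in kids[[j]]) {
        hit <- sum(!is.na(c(si[k], di[k])) & c(si[k], di[k]) == j)
        remaining[k] <- remaining[k] - hit
        if (remaining[k] == 0L) nxt <- c(nxt, k)
      }
    }
    ready <- nxt
  }
  if (length(order_out) < n) {
    left <- setdiff(seq_len(n), order_out)
    # walk parent links from a stuck node until an id repeats
    chain <- left[1]
    repeat {
      p <- c(si[chain[length(chain)]], di[chain[length(chain)]])
      p <- p[!is.na(p) & p %in% left]
      if (!length(p)) break
      if (p[1] %in% chain) { chain <- c(chain, p[1]); break }
      chain <- c(chain, p[1])
    }
    stopf("pedigree cycle detected: %s", paste(ped$id[chain], collapse = " -> "))
  }
  ped[order_out, , drop = FALSE]
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds Wright's numerator relationship matrix A over the full ancestral
#' pedigree of `subset` by the recursive tabular method, then restricts it
#' to `subset`. Unknown parents are treated as unrelated, non-inbred
#' founders. The diagonal is `1 + F` with `F` the inbreeding coefficient.
#'
#' @param ped pedigree data.frame (`id`, `sire`, `dam`, ...).
#' @param subset ids to keep (default: all).
#' @return symmetric matrix with dimnames = subset ids.
#' @export
build_a_matrix <- function(ped, subset = NULL) {
  ped <- sort_pedigree(ped)
  ids <- ped$id
  if (is.null(subset)) subset <- ids
  subset <- as.character(subset)
  miss <- setdiff(subset, ids)
  if (length(miss)) stopf("subset id(s) not in pedigree: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  # prune to ancestors of the subset
  keep <- rep(FALSE, nrow(ped))
  names(keep) <- ids
  si <- match(ped$sire, ids); di <- match(ped$dam, ids)
  keep[subset] <- TRUE
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (!is.na(si[i])) keep[si[i]] <- TRUE
      if (!is.na(di[i])) keep[di[i]] <- TRUE
    }
  }
  ped <- ped[keep, , drop = FALSE]
  ids <- ped$id
  si <- match(ped$sire, ids); di <- match(ped$dam, ids)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A[subset, subset, drop = FALSE]
}

#' Mean pedigree inbreeding of a cohort
#'
#' Average of `diag(A) - 1` over the animals of one generation (optionally
#' one line).
#'
#' @param ped pedigree data.frame.
#' @param generation cohort generation number.
#' @param line optional line label; default pools lines.
#' @param role optional role filter (e.g. `"response"`).
#' @return mean inbreeding coefficient (fraction).
#' @export
mean_inbreeding <- function(ped, generation, line = NULL, role = NULL) {
  sel <- ped$generation == generation
  if (!is.null(line)) sel <- sel & !is.na(ped$line) & ped$line == line
  if (!is.null(role)) sel <- sel & ped$role == role
  ids <- as.character(ped$id[sel & !is.na(sel)])
  if (!length(ids)) stopf("no animal in generation %s%s", generation,
                          if (is.null(line)) "" else paste0(" of line ", line))
  A <- build_a_matrix(ped, ids)
  mean(diag(A)) - 1
}

#' Read / write a pedigree CSV
#'
#' Columns: id, sire, dam, sex, line, generation, role; empty or `0` parent
#' fields are treated as unknown.
#'
#' @param path file path.
#' @return `read_pedigree`: a pedigree data.frame.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  for (col in c("sire", "dam")) {
    v <- as.character(ped[[col]])
    v[v %in% c("", "0", "NA")] <- NA_character_
    ped[[col]] <- v
  }
  sort_pedigree(ped)
}

#' @rdname read_pedigree
#' @param ped pedigree data.frame.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
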