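#' Construct a cell-type allometry dataset
#'
#' A tidy table of organisms with total cell number `N` and cell-type number
#' `K`, plus their base-10 logs `n` and `k` in which all regression models
#' operate. Constraints `N >= 1`, `1 <= K <= N` are enforced: an organism has
#' at least one cell type and no more types than cells.
#'
#' @param N total cell numbers (>= 1).
#' @param K cell-type numbers (>= 1, <= N elementwise).
#' @param label optional organism labels (character).
#' @return A `data.frame` of class `allometry_dataset` with columns `label`,
#'   `N`, `K`, `n`, `k`.
#' @examples
#' allometry_dataset(N = c(1e3, 1e9), K = c(5, 120))
#' @export
allometry_dataset <- function(N, K, label = NULL) {
  if (length(N) != length(K)) stop_input("'N' and 'K' must have equal length")
  if (length(N) > 0) {
    if (!is.numeric(N) || any(!is.finite(N)) || any(N < 1))
      stop_input("all 'N' must be finite and >= 1")
    if (!is.numeric(K) || any(!is.finite(K)) || any(K < 1))
      stop_input("all 'K' must be finite and >= 1")
    bad <- which(K > N)
    if (length(bad) > 0)
      stop_input("K > N at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
                 ": an organism cannot have more cell types than cells")
  }
  if (is.null(label)) label <- rep(NA_character_, length(N))
  if (length(label) != length(N)) stop_input("'label' length mismatch")
  out <- data.frame(label = as.character(label),
                    N = as.numeric(N), K = as.numeric(K),
                    n = log10(as.numeric(N)), k = log10(as.numeric(K)),
                    stringsAsFactors = FALSE)
  class(out) <- c("allometry_dataset", "data.frame")
  out
}

## order-insensitive identity check used by model comparison
dataset_fingerprint <- function(dataset) {
  paste(nrow(dataset),
        paste(sort(sprintf("%.12g:%.12g", dataset$n, dataset$k)), collapse = "|"),
        sep = "#")
}

detect_column <- function(cols, wanted, exclude = character()) {
  hit <- which(vapply(cols, function(cn) {
    lc <- tolower(cn)
    grepl(wanted, lc, fixed = TRUE) && !any(vapply(exclude, grepl, TRUE, x = lc, fixed = TRUE))
  }, TRUE))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Read / write allometry datasets as CSV
#'
#' The CSV dialect is comma-separated, UTF-8, with a header row; scientific
#' notation is allowed. Default column names are `cells` and `cell_types`.
#' When those are absent, columns are auto-detected by case-insensitive
#' substring match: the types column matches both "cell" and "type", the
#' cells column matches "cell" but not "type". An optional label column is
#' picked up from names containing "label", "organism", "species" or "name".
#'
#' @param path CSV file path.
#' @param cells_col,types_col column names holding `N` and `K`; `NULL`
#'   (default) tries `cells` / `cell_types` then auto-detects.
#' @return `read_allometry_csv` returns an [allometry_dataset()];
#'   `write_allometry_csv` returns `path` invisibly.
#' @export
read_allometry_csv <- function(path, cells_col = NULL, types_col = NULL) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  cols <- names(raw)
  pick <- function(user, default, detect) {
    if (!is.null(user)) {
      if (!user %in% cols) stop_input("column '", user, "' not found in ", path)
      return(user)
    }
    if (default %in% cols) return(default)
    i <- detect()
    if (is.na(i)) stop_input("could not identify column (tried '", default,
                             "' and auto-detection) in ", path)
    cols[i]
  }
  tc <- pick(types_col, "cell_types",
             function() detect_column(cols, "type"))
  cc <- pick(cells_col, "cells",
             function() detect_column(cols, "cell", exclude = "type"))
  lab_i <- which(vapply(cols, function(cn)
    grepl("label|organism|species|name", tolower(cn)), TRUE))[1]
  N <- suppressWarnings(as.numeric(raw[[cc]]))
  K <- suppressWarnings(as.numeric(raw[[tc]]))
  bad <- which(is.na(N) | is.na(K))
  if (length(bad) > 0)
    stop_input("non-numeric cell counts at data row(s) ",
               paste(utils::head(bad, 5), collapse = ", "), " of ", path)
  allometry_dataset(N, K,
                    label = if (is.na(lab_i)) NULL else as.character(raw[[lab_i]]))
}

#' @rdname read_allometry_csv
#' @param dataset an [allometry_dataset()].
#' @export
write_allometry_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "allometry_dataset"))
  out <- data.frame(label = dataset$label,
                    cells = sprintf("%.12g", dataset$N),
                    cell_types = sprintf("%.12g", dataset$K),
                    stringsAsFactors = FALSE)
  if (all(is.na(out$label))) out$label <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
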