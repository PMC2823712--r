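#' Mixed-type data set container
#'
#' A `mix_dataset` holds an N x p table of observations over per-feature
#' domains (discrete with a fixed alphabet, or continuous).  Discrete
#' entries are stored internally as 1-based codes into their feature's
#' alphabet; missing values (the data's missing marker) are stored as `NA`
#' and are marginalized out of all likelihoods and excluded from all
#' parameter updates.
#'
#' @param data A data.frame (or list of equal-length columns) of
#'   observations; character/factor columns are discrete, numeric columns
#'   continuous, unless `schema` overrides.
#' @param schema Optional character vector (`"discrete"`/`"continuous"`),
#'   one entry per column, or `NULL` to infer from column types.
#' @param ids Sample identifiers (unique); defaults to row names or
#'   `s1..sN`.
#' @param missing Missing-value marker matched against raw cells (default
#'   `"?"`); numeric `NA` cells are always treated as missing.
#' @param alphabets Optional named list fixing the alphabet of discrete
#'   columns (otherwise the sorted unique observed symbols).
#' @return An object of class `mix_dataset` with elements `ids`, `columns`
#'   (internal codes/numerics), `domains`, and `feature_names`.
#' @examples
#' ds <- mix_dataset(data.frame(g = c("A", "C"), x = c(0.1, 2.3)))
#' ds$domains[[1]]$alphabet
#' @export
mix_dataset <- function(data, schema = NULL, ids = NULL, missing = "?",
                        alphabets = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  p <- ncol(data)
  n <- nrow(data)
  if (p < 1L || n < 1L) stop("dataset must have at least one row and one column")
  feature_names <- colnames(data) %||% paste0("f", seq_len(p))
  if (is.null(schema)) {
    schema <- vapply(data, function(col) {
      if (is.numeric(col)) "continuous" else "discrete"
    }, character(1))
  }
  schema <- rep_len(schema, p)
  if (!all(schema %in% c("discrete", "continuous"))) {
    stop("schema entries must be 'discrete' or 'continuous'")
  }
  if (is.null(ids)) {
    ids <- if (!is.null(attr(data, "row.names")) &&
               !identical(attr(data, "row.names"), seq_len(n))) {
      as.character(rownames(data))
    } else {
      paste0("s", seq_len(n))
    }
  }
  ids <- as.character(ids)
  if (length(ids) != n) stop("ids length must equal number of rows")
  if (anyDuplicated(ids)) stop("sample ids must be unique")

  columns <- vector("list", p)
  domains <- vector("list", p)
  for (j in seq_len(p)) {
    col <- data[[j]]
    if (schema[j] == "continuous") {
      raw <- as.character(col)
      raw[!is.na(raw) & raw == missing] <- NA
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & is.na(val))
      if (length(bad)) {
        stop(sprintf("cannot parse cell (row %d, column '%s') value '%s' as numeric",
                     bad[1L], feature_names[j], raw[bad[1L]]))
      }
      columns[[j]] <- val
      domains[[j]] <- list(type = "continuous")
    } else {
      sym <- as.character(col)
      sym[!is.na(sym) & sym == missing] <- NA
      ab <- alphabets[[feature_names[j]]] %||% sort(unique(sym[!is.na(sym)]))
      if (length(ab) == 0L) stop(sprintf("column '%s' has no observed symbols", feature_names[j]))
      columns[[j]] <- discrete_codes(ab, sym, feature_names[j])
      domains[[j]] <- list(type = "discrete", alphabet = as.character(ab))
    }
  }
  structure(list(ids = ids, columns = columns, domains = domains,
                 feature_names = feature_names, missing = missing),
            class = "mix_dataset")
}

#' @export
print.mix_dataset <- function(x, ...) {
  types <- vapply(x$domains, `[[`, character(1), "type")
  cat(sprintf("<mix_dataset> %d samples x %d features (%d discrete, %d continuous)\n",
              n_samples(x), n_features(x),
              sum(types == "discrete"), sum(types == "continuous")))
  invisible(x)
}

#' Dataset dimensions
#' @param dataset A `mix_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(dataset) length(dataset$ids)

#' @rdname n_samples
#' @export
n_features <- function(dataset) length(dataset$columns)

#' Decode a dataset back to a data.frame of raw values
#'
#' Discrete codes are mapped back to symbols; missing values become `NA`.
#'
#' @param x A `mix_dataset`.
#' @param ... Unused.
#' @export
as.data.frame.mix_dataset <- function(x, ...) {
  out <- lapply(seq_len(n_features(x)), function(j) {
    d <- x$domains[[j]]
    if (d$type == "discrete") d$alphabet[x$columns[[j]]] else x$columns[[j]]
  })
  names(out) <- x$feature_names
  df <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  rownames(df) <- x$ids
  df
}

# row subset, keeping domains/alphabets fixed
ds_subset <- function(dataset, idx) {
  dataset$ids <- dataset$ids[idx]
  dataset$columns <- lapply(dataset$columns, `[`, idx)
  dataset
}

# single row as list of raw values (symbols / numerics), NA = missing
ds_row <- function(dataset, i) {
  lapply(seq_len(n_features(dataset)), function(j) {
    d <- dataset$domains[[j]]
    v <- dataset$columns[[j]][i]
    if (d$type == "discrete" && !is.na(v)) d$alphabet[v] else v
  })
}

#' Read a delimited table as a dataset
#'
#' Reads a header-bearing CSV/TSV of mixed discrete and continuous columns.
#'
#' @param path File path; delimiter inferred from the extension (`.csv`
#'   comma, otherwise tab) unless `sep` is given.
#' @param schema Per-column types as in [mix_dataset()] (id column, when
#'   used, excluded); `NULL` infers: columns whose non-missing cells all
#'   parse as numbers are continuous.
#' @param missing Missing-value marker (default `"?"`).
#' @param sep Field separator override.
#' @param id_col Optional name or index of a column holding sample ids.
#' @return A `mix_dataset`.
#' @export
read_table <- function(path, schema = NULL, missing = "?", sep = NULL,
                       id_col = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty table: ", path)
  ids <- NULL
  if (!is.null(id_col)) {
    j <- if (is.character(id_col)) match(id_col, colnames(raw)) else as.integer(id_col)
    if (is.na(j)) stop("id_col not found: ", id_col)
    ids <- raw[[j]]
    raw <- raw[, -j, drop = FALSE]
  }
  if (is.null(schema)) {
    schema <- vapply(raw, function(col) {
      obs <- col[!is.na(col) & col != missing]
      num <- suppressWarnings(as.numeric(obs))
      if (length(obs) > 0 && !anyNA(num)) "continuous" else "discrete"
    }, character(1))
  }
  mix_dataset(raw, schema = schema, ids = ids, missing = missing)
}

#' Write a clustering result to a TSV file
#'
#' One row per sample: id, cluster label (0-based; `NA` when unassigned by
#' the entropy cutoff) and the per-component posterior probabilities.
#'
#' @param assignment A `cluster_assignment` as returned by [classify()].
#' @param dataset The `mix_dataset` that was classified.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_clustering <- function(assignment, dataset, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (length(assignment$labels) != n_samples(dataset)) {
    stop("assignment does not match dataset size")
  }
  K <- ncol(assignment$posterior)
  lab <- ifelse(is.na(assignment$labels), NA_integer_, assignment$labels - 1L)
  post <- apply(assignment$posterior, 2, function(col) sprintf("%.12g", col))
  if (is.null(dim(post))) post <- matrix(post, nrow = 1L)
  out <- data.frame(id = dataset$ids, label = lab, post,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("id", "label", paste0("posterior_", seq_len(K) - 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
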