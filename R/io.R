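# Plain-text file dialects: contact-sequence TSV, graphlet-stack text,
# node-by-time series tables, and JSON measure output.

#' Read and write contact-sequence files
#'
#' The contact-sequence dialect is a whitespace/tab-delimited text file.
#' Lines starting with `#` are comments, except the directives `#N=<int>`,
#' `#T=<int>` and `#index_base=<0|1>`. Data rows are
#' `i <TAB> j <TAB> t [<TAB> w]`. Files are 0-based by default
#' (`index_base = 0`); with `#index_base=1` indices are read as 1-based.
#' Internally the package always uses 1-based indices.
#'
#' @param path file path.
#' @return A [contact_sequence()].
#' @export
read_contact_sequence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  N <- T <- NULL
  base <- 0L
  rows <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*(N|T|index_base)\\s*=\\s*(\\d+)\\s*$", ln))[[1]]
      if (length(m) == 3) {
        val <- as.integer(m[3])
        switch(m[2], N = N <- val, T = T <- val, index_base = {
          if (!val %in% c(0L, 1L)) {
            stop("line ", k, ": index_base must be 0 or 1", call. = FALSE)
          }
          base <- val
        })
      }
      next
    }
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (!length(f) %in% c(3L, 4L)) {
      stop("line ", k, ": expected 3 or 4 fields, got ", length(f), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("line ", k, ": non-numeric field in ", sQuote(ln), call. = FALSE)
    if (any(v[1:3] != floor(v[1:3]))) {
      stop("line ", k, ": node and time indices must be integers", call. = FALSE)
    }
    if (v[1] == v[2]) stop("line ", k, ": self-loop (i == j) is forbidden", call. = FALSE)
    if (any(v[1:3] < base)) {
      stop("line ", k, ": negative or out-of-base index", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- v
  }
  off <- 1L - base  # shift to 1-based internal indices
  if (!length(rows)) {
    return(contact_sequence(integer(), integer(), integer(), N = N, T = T))
  }
  m <- do.call(rbind, rows)
  w <- if (ncol(m) == 4L) m[, 4] else NULL
  contact_sequence(i = m[, 1] + off, j = m[, 2] + off, t = m[, 3] + off,
                   w = w, N = N, T = T)
}

#' @rdname read_contact_sequence
#' @param cs a [contact_sequence()].
#' @param index_base base used for the indices written to file (0 or 1).
#' @export
write_contact_sequence <- function(cs, path, index_base = 0L) {
  stopifnot(inherits(cs, "contact_sequence"), index_base %in% c(0L, 1L))
  off <- index_base - 1L
  hdr <- c(sprintf("#N=%d", attr(cs, "N")), sprintf("#T=%d", attr(cs, "T")),
           sprintf("#index_base=%d", index_base))
  body <- if (nrow(cs)) {
    if (is.null(cs$w)) {
      sprintf("%d\t%d\t%d", cs$i + off, cs$j + off, cs$t + off)
    } else {
      sprintf("%d\t%d\t%d\t%s", cs$i + off, cs$j + off, cs$t + off,
              format(cs$w, trim = TRUE, digits = 15))
    }
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write graphlet-stack text files
#'
#' One block per time point: a `# t=<idx>` header line followed by the N x N
#' whitespace-delimited connectivity matrix; blocks are blank-line
#' separated. Blocks are read in file order; the `t=` index is
#' informational.
#'
#' @param path file path.
#' @return A [temporal_network()].
#' @export
read_graphlet_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  slices <- list()
  cur <- list()
  flush <- function() {
    if (length(cur)) {
      m <- do.call(rbind, lapply(cur, function(s) as.numeric(strsplit(trimws(s), "[ \t]+")[[1]])))
      slices[[length(slices) + 1L]] <<- m
      cur <<- list()
    }
  }
  for (ln in lines) {
    if (startsWith(trimws(ln), "#") || !nzchar(trimws(ln))) flush() else cur[[length(cur) + 1L]] <- ln
  }
  flush()
  if (!length(slices)) stop("no matrix blocks found in ", path, call. = FALSE)
  N <- nrow(slices[[1]])
  if (any(vapply(slices, function(m) nrow(m) != N || ncol(m) != N, logical(1)))) {
    stop("all graphlet blocks must be square matrices of equal size", call. = FALSE)
  }
  A <- array(unlist(lapply(slices, t)), c(N, N, length(slices)))
  A <- aperm(A, c(2, 1, 3))
  temporal_network(A)
}

#' @rdname read_graphlet_stack
#' @param tn a [temporal_network()].
#' @export
write_graphlet_stack <- function(tn, path) {
  stopifnot(inherits(tn, "temporal_network"))
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(n_times(tn))) {
    writeLines(sprintf("# t=%d", t - 1L), con)
    utils::write.table(tn[, , t], con, row.names = FALSE, col.names = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' Read and write node-by-time series tables
#'
#' Tab-delimited tables with one row per node and one column per time
#' point. If the first column is non-numeric it is taken as node labels.
#'
#' @param path file path.
#' @param transpose set to `TRUE` when the file is time-by-node.
#' @return A numeric matrix (nodes x time), rownames carrying labels.
#' @export
read_node_timeseries <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  labels <- NULL
  if (!is.numeric(df[[1]])) {
    labels <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  Y <- as.matrix(df)
  if (!is.numeric(Y)) stop("non-numeric values in time-series table", call. = FALSE)
  dimnames(Y) <- NULL
  if (transpose) {
    Y <- t(Y)
  } else if (!is.null(labels)) {
    rownames(Y) <- labels
  }
  Y
}

#' @rdname read_node_timeseries
#' @param Y nodes-x-time numeric matrix.
#' @export
write_node_timeseries <- function(Y, path) {
  df <- as.data.frame(Y)
  if (!is.null(rownames(Y))) df <- cbind(label = rownames(Y), df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a measure result as JSON
#'
#' Measure outputs are JSON objects
#' `{"measure": name, "params": {...}, "values": ...}` with scalar,
#' per-node, or per-pair values; infinities are encoded as `null`.
#'
#' @param measure measure name.
#' @param values scalar, vector, or data frame of values.
#' @param params named list of parameters used.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
measure_json <- function(measure, values, params = list(), path = NULL) {
  clean <- function(x) {
    if (is.data.frame(x)) { x[] <- lapply(x, clean); return(x) }
    if (is.numeric(x)) x[!is.finite(x) & !is.na(x)] <- NA
    x
  }
  obj <- list(measure = measure, params = params, values = clean(values))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
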