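#' Read a PLUMED-style COLVAR file
#'
#' Parses the `#! FIELDS ...` header and whitespace-separated numeric rows.
#' Repeated interior headers (from simulation restarts) are skipped and the
#' rows concatenated. Ragged rows raise a format error naming the line.
#'
#' @param path path to the file.
#' @return A `colvar_table`: a data.frame whose columns are the declared
#'   fields, with the field names in `attr(, "fields")`.
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !grepl("^#!\\s+FIELDS\\s+", lines[1]))
    stop("missing '#! FIELDS' header in ", path)
  fields <- strsplit(sub("^#!\\s+FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  is_comment <- grepl("^#", lines)
  headers <- which(is_comment & grepl("^#!\\s+FIELDS\\s+", lines))
  for (h in headers[-1]) {
    f2 <- strsplit(sub("^#!\\s+FIELDS\\s+", "", lines[h]), "\\s+")[[1]]
    if (!identical(f2, fields))
      stop("restart header at line ", h, " declares different fields")
  }
  data_lines <- lines[!is_comment]
  if (!length(data_lines)) {
    out <- as.data.frame(matrix(numeric(), 0, length(fields)))
    names(out) <- fields
    attr(out, "fields") <- fields
    class(out) <- c("colvar_table", class(out))
    return(out)
  }
  parsed <- strsplit(trimws(data_lines), "\\s+")
  nf <- lengths(parsed)
  if (any(nf != length(fields))) {
    bad <- which(nf != length(fields))[1]
    stop("row ", bad, " has ", nf[bad], " values; header declares ",
         length(fields))
  }
  mat <- matrix(as.numeric(unlist(parsed)), ncol = length(fields),
                byrow = TRUE)
  if (any(is.na(mat))) stop("non-numeric value in ", path)
  out <- as.data.frame(mat)
  names(out) <- fields
  if ("time" %in% fields && nrow(out) > 1 && any(diff(out$time) <= 0))
    warning("time column is not strictly increasing")
  attr(out, "fields") <- fields
  class(out) <- c("colvar_table", class(out))
  out
}

.fmt <- function(x) formatC(x, format = "e", digits = 9)

#' Write a PLUMED-style COLVAR file
#'
#' Writes a `#! FIELDS` header followed by the data in 10-significant-digit
#' scientific notation, so a write/read round-trip is value-identical at
#' that precision.
#'
#' @param x a data.frame (e.g. a `colvar_table`) or a
#'   [trajectory_dataset()]; datasets are written with columns
#'   `time`, the configuration variables, and `metad.bias`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(x, path) {
  if (inherits(x, "trajectory_dataset")) {
    d <- as.data.frame(x$samples)
    names(d) <- if (ncol(x$samples) == 1) "x"
      else paste0("x", seq_len(ncol(x$samples)))
    d <- cbind(time = x$times, d, `metad.bias` = x$bias_values)
    x <- d
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(x), collapse = " ")), con)
  if (nrow(x)) {
    body <- do.call(paste, lapply(x, .fmt))
    writeLines(body, con)
  }
  invisible(path)
}

#' Write a PLUMED-style HILLS file
#'
#' Columns: `time center sigma height biasf`.
#'
#' @param bias a [bias_state()].
#' @param path output path.
#' @param times deposition times (default: hill index).
#' @return `path`, invisibly.
#' @export
write_hills <- function(bias, path, times = NULL) {
  stopifnot(inherits(bias, "bias_state"))
  n <- length(bias$hill_centers)
  if (is.null(times)) times <- seq_len(n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time center sigma height biasf", con)
  if (n) {
    writeLines(paste(.fmt(times), .fmt(bias$hill_centers),
                     .fmt(bias$hill_widths), .fmt(bias$hill_heights),
                     .fmt(rep(bias$bias_factor, n))), con)
  }
  invisible(path)
}

#' Read a PLUMED-style HILLS file into a bias state
#'
#' Expects columns `time center sigma height biasf` (extra columns are
#' ignored). If the bias factor is not constant across rows a warning is
#' emitted and the last value is used.
#'
#' @param path path to the file.
#' @return A [bias_state()] reconstructing the deposited bias; deposition
#'   times are attached as `attr(, "times")`.
#' @export
read_hills <- function(path) {
  tab <- read_colvar(path)
  need <- c("center", "sigma", "height", "biasf")
  if (!all(need %in% names(tab)))
    stop("HILLS file must declare fields ", paste(need, collapse = ", "))
  if (nrow(tab) == 0)
    return(bias_state())
  bf <- tab$biasf
  if (length(unique(bf)) > 1)
    warning("bias factor varies across hills; using the last value")
  out <- bias_state(hill_centers = tab$center, hill_widths = tab$sigma,
                    hill_heights = tab$height,
                    bias_factor = bf[length(bf)],
                    hill_width = tab$sigma[length(tab$sigma)])
  attr(out, "times") <- tab$time
  out
}

#' Save / load package objects as a keyed container
#'
#' A single-file container for datasets, Markov models, embeddings and
#' parametric maps: the object's named arrays plus a provenance block
#' (class, package version, creation time) serialized with R's native
#' format.
#'
#' @param object object to save.
#' @param path file path.
#' @return `path` invisibly (`write_container`); the restored object
#'   (`read_container`).
#' @export
write_container <- function(object, path) {
  payload <- list(class = class(object), object = object,
                  provenance = list(package = "rwmanifold",
                                    version = "0.1.0",
                                    created = format(Sys.time())))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- readRDS(path)
  payload$object
}

#' Write a diffusion embedding to CSV
#'
#' Flat table: sample index, diffusion coordinates, stationary density.
#'
#' @param embedding a [spectral_decomposition()] result.
#' @param path output path.
#' @param d number of coordinates to write (default: all computed).
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(embedding, path,
                                d = ncol(embedding$coordinates)) {
  stopifnot(inherits(embedding, "diffusion_embedding"))
  co <- embedding$coordinates[, seq_len(d), drop = FALSE]
  out <- data.frame(sample = seq_len(nrow(co)))
  for (j in seq_len(d)) out[[paste0("coord", j - 1)]] <- co[, j]
  out$stationary_density <- embedding$left_eigenvector_0
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
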