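#' Write a surface as an ESRI ASCII grid
#'
#' Writes the 6-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows north-to-south. Values are
#' written with full double precision so that a read/write round trip is
#' bit-identical.
#'
#' @param field A `latent_field` (NA values are written as NODATA).
#' @param path Output file path.
#' @param nodata NODATA sentinel written in the header (default -9999).
#' @return `path`, invisibly.
#' @export
write_grid <- function(field, path, nodata = -9999) {
  stopifnot(inherits(field, "latent_field") || is.list(field))
  grid <- field$grid
  values <- field$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$nx),
    sprintf("nrows %d", grid$ny),
    sprintf("xllcorner %.17g", grid$origin[1]),
    sprintf("yllcorner %.17g", grid$origin[2]),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", nodata)), con)
  m <- matrix(values, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  for (j in grid$ny:1) {
    row <- m[j, ]
    row[is.na(row)] <- nodata
    writeLines(paste(sprintf("%.17g", row), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written in the dialect of [write_grid()].
#' @return A `latent_field`; NODATA cells become `NA` (stored via a plain
#'   list when NA present, since `latent_field` requires finite values).
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("truncated ESRI ASCII grid: ", path)
  hdr <- list()
  for (k in 1:6) {
    parts <- strsplit(trimws(lines[k]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L)
      stop("malformed header line ", k, " in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII header missing fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != ny)
    stop(sprintf("expected %d data rows, found %d in %s", ny,
                 length(body), path))
  rows <- lapply(body, function(l) {
    v <- as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
    if (length(v) != nx)
      stop(sprintf("row width %d != ncols %d in %s", length(v), nx, path))
    v
  })
  m <- do.call(rbind, rows)        # first row = northernmost
  m <- m[ny:1, , drop = FALSE]     # back to south-first
  m[m == hdr$nodata_value] <- NA
  grid <- grid_geometry(nx, ny, hdr$cellsize,
                        c(hdr$xllcorner, hdr$yllcorner))
  values <- as.numeric(t(m))
  if (any(is.na(values))) {
    out <- structure(list(grid = grid, values = values),
                     class = "latent_field")
  } else {
    out <- latent_field(grid, values)
  }
  out
}

#' Write a marked sample as a delimited point table
#'
#' Comma-separated columns `x`, `y`, `mark` (plus `covariate` when present),
#' with a header row. Design metadata is written as `#`-prefixed key/value
#' comment lines before the header.
#'
#' @param sample A `marked_sample`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_points <- function(sample, path) {
  stopifnot(inherits(sample, "marked_sample"))
  con <- file(path, "w")
  on.exit(close(con))
  d <- sample$design
  writeLines(c(
    sprintf("# design_kind = %s", d$kind),
    sprintf("# design_n = %d", d$n),
    sprintf("# design_preferentiality = %.17g", d$preferentiality),
    sprintf("# family = %s", sample$family)), con)
  df <- sample$data[, intersect(c("x", "y", "mark", "covariate"),
                                names(sample$data)), drop = FALSE]
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a delimited point table
#'
#' Expects a header row with at least columns `x`, `y`, `mark`; an optional
#' `covariate` column is kept. `#` comment lines (the sidecar design
#' metadata of [write_points()]) are honoured. Rows with non-numeric
#' entries raise a parse error naming the offending data row.
#'
#' @param path File path.
#' @param grid Optional `grid_geometry`; when supplied, coordinates are
#'   validated against the grid extent and cell indices attached.
#' @return A `marked_sample` (with design metadata when the sidecar comments
#'   are present, otherwise an "unknown" design).
#' @export
read_points <- function(path, grid = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) stop("no header row in ", path)
  header <- strsplit(body[1], ",")[[1]]
  need <- c("x", "y", "mark")
  if (!all(need %in% header))
    stop("point table must have columns x, y, mark (found: ",
         paste(header, collapse = ", "), ")")
  rows <- body[-1]
  parse_row <- function(k) {
    v <- strsplit(rows[k], ",")[[1]]
    if (length(v) != length(header))
      stop(sprintf("row %d of %s has %d fields, expected %d", k, path,
                   length(v), length(header)))
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num)))
      stop(sprintf("non-numeric value in row %d of %s (column %s)", k, path,
                   header[which(is.na(num))[1]]))
    num
  }
  if (length(rows)) {
    m <- do.call(rbind, lapply(seq_along(rows), parse_row))
    df <- as.data.frame(m)
    names(df) <- header
  } else {
    df <- as.data.frame(matrix(numeric(0), ncol = length(header),
                               dimnames = list(NULL, header)))
  }
  meta <- list(kind = "unknown", n = nrow(df), preferentiality = NA_real_,
               family = "gamma")
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=")[[1]]
    if (length(kv) == 2) {
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key == "design_kind") meta$kind <- val
      if (key == "design_n") meta$n <- as.integer(val)
      if (key == "design_preferentiality")
        meta$preferentiality <- as.numeric(val)
      if (key == "family") meta$family <- val
    }
  }
  if (!is.null(grid)) df$cell <- cell_index(grid, df$x, df$y)
  design <- sample_design(
    kind = if (meta$kind %in% c("preferential", "uniform")) meta$kind
           else "uniform",
    n = max(1L, nrow(df)),
    preferentiality = if (is.na(meta$preferentiality)) 0
                      else meta$preferentiality)
  design$kind <- meta$kind
  design$n <- nrow(df)
  new_marked_sample(df, design = design, family = meta$family,
                    grid = grid)
}

#' Parse a plain-text key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are
#' coerced to numeric when they parse as numbers, and to logical for
#' true/false. A single schema is shared by all command-line subcommands.
#'
#' @param path Config file path.
#' @return Named list of values.
#' @export
parse_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    kv <- regmatches(l, regexec("^([^=]+)=(.*)$", l))[[1]]
    if (length(kv) != 3)
      stop("malformed config line (expected key = value): ", l)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    else if (tolower(val) %in% c("true", "false"))
      val <- as.logical(toupper(val))
    out[[key]] <- val
  }
  out
}

#' Derive a stage seed from a master seed
#'
#' Deterministic splitting rule used everywhere the package needs several
#' independent random stages from one master seed: stage `k` gets
#' `(seed * 48271 + k * 1000003) mod (2^31 - 1)` (kept strictly below
#' 2^31 so it is a valid R integer seed).
#'
#' @param seed Master integer seed.
#' @param stage Integer stage index (>= 0).
#' @return Integer seed for the stage.
#' @export
derive_seed <- function(seed, stage) {
  s <- (as.double(seed) %% 2147483647) * 48271 +
    as.double(stage) * 1000003
  as.integer(s %% 2147483647)
}

# Tiny FNV-1a hash of a character vector, for run manifests.
.text_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
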