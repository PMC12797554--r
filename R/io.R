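#' Raster file I/O (ESRI ASCII grid)
#'
#' Plain-text single-band raster interchange. Values are written with 17
#' significant digits, so doubles round-trip bit-exactly; `NA` cells are
#' written as the nodata marker (default -9999). The on-disk row order is
#' north-to-south per the format; the in-memory convention (row 1 = south)
#' is restored on read.
#'
#' @param x a [raster_grid()].
#' @param path file path (conventionally `.asc`).
#' @param nodata nodata marker written to the header.
#' @return `read_raster` returns a [raster_grid()]; `write_raster` the path,
#'   invisibly.
#' @export
write_raster <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "raster_grid"))
  v <- x$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", formatC(x$origin[1L], digits = 17, format = "g")),
    paste("yllcorner", formatC(x$origin[2L], digits = 17, format = "g")),
    paste("cellsize", formatC(x$cell_size, digits = 17, format = "g")),
    paste("NODATA_value", nodata)), con)
  for (r in rev(seq_len(nrow(v))))
    writeLines(paste(formatC(v[r, ], digits = 17, format = "g"),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]   # back to row 1 = south
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  raster_grid(m, hdr$cellsize, origin = c(hdr$xllcorner, hdr$yllcorner))
}

#' Plot table I/O (CSV)
#'
#' @param plots plot table data.frame.
#' @param path CSV path.
#' @return `read_plot_table` returns the data.frame.
#' @export
write_plot_table <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plot_table
#' @export
read_plot_table <- function(path) {
  utils::read.csv(path)
}

# Polynomial rolling hash of a string (mod the Mersenne prime 2^31 - 1,
# exact in doubles), as 8 hex digits; enough to fingerprint a config.
config_hash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records everything needed to re-run an experiment bit-identically: the
#' seed, the full configuration (and its hash), the package version and a
#' timestamp.
#'
#' @param path output JSON path.
#' @param config configuration list (e.g. a [landscape_config()]).
#' @param seed the run seed.
#' @param extra optional named list merged into the manifest.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- c(list(
    seed = seed,
    config_hash = config_hash(as.character(cfg_json)),
    config = unclass(config),
    package = "forestscale",
    version = as.character(utils::packageVersion("forestscale")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration (JSON)
#'
#' The file may carry any subset of [landscape_config()] arguments under
#' `landscape`, and [experiment_spec()] arguments under `experiment`;
#' omitted entries fall back to the package defaults. Unknown keys are an
#' error naming the key.
#'
#' @param path JSON config path.
#' @param seed optional seed override.
#' @return list with `landscape` ([landscape_config()]) and `experiment`
#'   ([experiment_spec()]).
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- if (is.null(path)) list()
         else jsonlite::read_json(path, simplifyVector = TRUE)
  lc_args <- raw$landscape %||% list()
  ex_args <- raw$experiment %||% list()
  check_keys <- function(args, fn, label) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop("unknown ", label, " config key(s): ", paste(bad, collapse = ", "))
  }
  check_keys(lc_args, landscape_config, "landscape")
  check_keys(ex_args, experiment_spec, "experiment")
  if (!is.null(seed)) {
    lc_args$seed <- seed
    ex_args$seed <- seed
  }
  list(landscape = do.call(landscape_config, lc_args),
       experiment = do.call(experiment_spec, ex_args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
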