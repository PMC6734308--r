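# Data model and I/O for force-distance (FD) curves and 2-D FD maps.
#
# Sign convention: piezo height decreases toward the sample during the
# approach (larger height = farther away); acquisition order is time order,
# approach points precede retract points. Internal units are SI base
# (m, N, N/m); the TSV dialect declares its units (um, nN) in its header.

#' Construct a force-distance curve
#'
#' @param piezo_height piezo height series \[m\].
#' @param force cantilever force series \[N\].
#' @param segment per-point segment label, `"approach"` or `"retract"`
#'   (recycled if length 1). Approach points must precede retract points.
#' @param spring_constant cantilever spring constant \[N/m\], > 0.
#' @param tip_position optional tip-position (tip-sample separation) series
#'   \[m\]; normally absent until computed by [compute_tip_position].
#' @param meta named list of free-form annotations (pixel coordinates,
#'   specimen id, ...).
#' @return An object of class `fd_curve`.
#' @export
fd_curve <- function(piezo_height, force, segment = "approach",
                     spring_constant, tip_position = NULL, meta = list()) {
  n <- length(piezo_height)
  if (length(segment) == 1L) segment <- rep(segment, n)
  x <- structure(list(piezo_height = as.numeric(piezo_height),
                      force = as.numeric(force),
                      segment = as.character(segment),
                      spring_constant = as.numeric(spring_constant),
                      tip_position = if (is.null(tip_position)) NULL
                                     else as.numeric(tip_position),
                      meta = meta),
                 class = "fd_curve")
  validate_fd_curve(x)
}

#' Validate a force-distance curve
#'
#' Checks the `fd_curve` invariants: equal series lengths >= 2, positive
#' spring constant, segment labels in {approach, retract} with all approach
#' points preceding all retract points.
#'
#' @param x an `fd_curve`.
#' @return `x`, invisibly-checked; raises a validation error otherwise.
#' @export
validate_fd_curve <- function(x) {
  stopifnot(inherits(x, "fd_curve"))
  n <- length(x$piezo_height)
  if (n < 2L)
    stop("fd_curve must contain at least 2 points")
  if (length(x$force) != n || length(x$segment) != n)
    stop("piezo_height, force and segment must have equal length")
  if (!is.null(x$tip_position) && length(x$tip_position) != n)
    stop("tip_position must match the series length")
  if (!all(is.finite(x$piezo_height)) || !all(is.finite(x$force)))
    stop("piezo_height and force must be finite")
  if (length(x$spring_constant) != 1L || !is.finite(x$spring_constant) ||
      x$spring_constant <= 0)
    stop("spring_constant must be a single positive number")
  if (!all(x$segment %in% c("approach", "retract")))
    stop("segment labels must be 'approach' or 'retract'")
  seg <- as.integer(x$segment == "retract")
  if (is.unsorted(seg))
    stop("approach points must precede retract points")
  invisible(x)
  x
}

#' @export
print.fd_curve <- function(x, ...) {
  n_ap <- sum(x$segment == "approach")
  cat(sprintf("<fd_curve> %d points (%d approach, %d retract), k = %g N/m\n",
              length(x$force), n_ap, length(x$force) - n_ap,
              x$spring_constant))
  cat(sprintf("  height [%g, %g] um, force [%g, %g] nN, tip position %s\n",
              min(x$piezo_height) * 1e6, max(x$piezo_height) * 1e6,
              min(x$force) * 1e9, max(x$force) * 1e9,
              if (is.null(x$tip_position)) "not computed" else "computed"))
  invisible(x)
}

#' @export
length.fd_curve <- function(x) length(x$force)

#' Extract the approach segment of a curve
#'
#' The analysis pipeline uses only the approach part (baseline + indentation);
#' this returns those points with acquisition order preserved.
#'
#' @param curve an `fd_curve` with at least one approach point.
#' @return An `fd_curve` containing only approach-segment points.
#' @export
extract_approach <- function(curve) {
  validate_fd_curve(curve)
  keep <- curve$segment == "approach"
  if (!any(keep)) stop("curve has no approach points")
  fd_curve(curve$piezo_height[keep], curve$force[keep],
           curve$segment[keep], curve$spring_constant,
           tip_position = if (is.null(curve$tip_position)) NULL
                          else curve$tip_position[keep],
           meta = curve$meta)
}

# --- TSV dialect -----------------------------------------------------------
# Header:  # fdrate-curve v1
#          # columns: height[um] force[nN] segment{a,r}
#          # spring_constant[N/m]: <value>
#          # meta: <key> = <value>        (0..n lines)
# Body: tab-separated height_um, force_nN, segment (a|r), one point per row.

.known_dialects <- c("tsv")

.check_dialect <- function(dialect) {
  if (!dialect %in% .known_dialects)
    stop(sprintf("unknown dialect '%s' (available: %s)", dialect,
                 paste(.known_dialects, collapse = ", ")))
  dialect
}

#' Read a force-distance curve from file
#'
#' @param path path to a curve file.
#' @param dialect file format name; currently `"tsv"` (tab-separated columns
#'   `height[um] force[nN] segment{a,r}` with `#`-prefixed header lines).
#' @return An `fd_curve` with all values converted to SI base units
#'   (1 um = 1e-6 m, 1 nN = 1e-9 N).
#' @export
read_fd_curve <- function(path, dialect = "tsv") {
  .check_dialect(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!any(grepl("^# columns: height\\[um\\] force\\[nN\\] segment\\{a,r\\}", header)))
    stop("format error: missing '# columns: height[um] force[nN] segment{a,r}' header")
  kline <- grep("^# spring_constant\\[N/m\\]:", header, value = TRUE)
  if (length(kline) != 1L)
    stop("format error: missing column header 'spring_constant[N/m]'")
  k <- as.numeric(sub("^# spring_constant\\[N/m\\]:\\s*", "", kline))
  meta <- list()
  for (ml in grep("^# meta: ", header, value = TRUE)) {
    kv <- sub("^# meta: ", "", ml)
    eq <- regexpr(" = ", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 3, nchar(kv))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop("format error: expected 3 columns (height, force, segment)")
  height <- as.numeric(vapply(fields, `[[`, "", 1L))
  force <- as.numeric(vapply(fields, `[[`, "", 2L))
  seg <- vapply(fields, `[[`, "", 3L)
  if (anyNA(height)) stop("format error: non-numeric value in column height")
  if (anyNA(force)) stop("format error: non-numeric value in column force")
  if (!all(seg %in% c("a", "r")))
    stop("format error: segment column must contain 'a' or 'r'")
  fd_curve(height * 1e-6, force * 1e-9,
           ifelse(seg == "a", "approach", "retract"),
           spring_constant = k, meta = meta)
}

#' Write a force-distance curve to file
#'
#' Lossless (to double precision) counterpart of [read_fd_curve]; heights
#' are written in um and forces in nN with 17 significant digits.
#'
#' @param curve an `fd_curve`.
#' @param path output path.
#' @param dialect file format name; see [read_fd_curve].
#' @export
write_fd_curve <- function(curve, path, dialect = "tsv") {
  .check_dialect(dialect)
  validate_fd_curve(curve)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fdrate-curve v1",
               "# columns: height[um] force[nN] segment{a,r}",
               sprintf("# spring_constant[N/m]: %.17g", curve$spring_constant)),
             con)
  for (key in names(curve$meta))
    writeLines(sprintf("# meta: %s = %s", key, as.character(curve$meta[[key]])),
               con)
  writeLines(sprintf("%.17g\t%.17g\t%s",
                     curve$piezo_height * 1e6, curve$force * 1e9,
                     ifelse(curve$segment == "approach", "a", "r")),
             con)
  invisible(path)
}

# --- FD maps ---------------------------------------------------------------

#' Construct a 2-D FD map
#'
#' A grid of FD measurements, one curve per pixel; missing pixels are
#' allowed and kept as `NULL`.
#'
#' @param grid_shape integer vector `c(rows, cols)`.
#' @param pixel_size pixel edge length \[m\].
#' @return An object of class `fd_map`.
#' @export
fd_map <- function(grid_shape, pixel_size = 10e-6) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L), pixel_size > 0)
  structure(list(grid_shape = grid_shape,
                 pixels = vector("list", prod(grid_shape)),
                 pixel_size = pixel_size),
            class = "fd_map")
}

.pixel_index <- function(map, row, col) {
  if (row < 1L || row > map$grid_shape[1] || col < 1L || col > map$grid_shape[2])
    stop("pixel index outside grid")
  (row - 1L) * map$grid_shape[2] + col
}

#' Set one pixel of an FD map
#' @param map an `fd_map`.
#' @param row,col 1-based pixel coordinates.
#' @param curve an `fd_curve` (or `NULL` to mark the pixel missing).
#' @return The modified map.
#' @export
map_set_pixel <- function(map, row, col, curve) {
  stopifnot(inherits(map, "fd_map"))
  if (!is.null(curve)) validate_fd_curve(curve)
  map$pixels[[.pixel_index(map, row, col)]] <- curve
  map
}

#' Get one pixel of an FD map
#' @inheritParams map_set_pixel
#' @return The pixel's `fd_curve`, or `NULL` if missing.
#' @export
map_get_pixel <- function(map, row, col) {
  stopifnot(inherits(map, "fd_map"))
  map$pixels[[.pixel_index(map, row, col)]]
}

#' @export
print.fd_map <- function(x, ...) {
  cat(sprintf("<fd_map> %d x %d pixels (%d recorded), pixel size %g um\n",
              x$grid_shape[1], x$grid_shape[2],
              sum(!vapply(x$pixels, is.null, logical(1))),
              x$pixel_size * 1e6))
  invisible(x)
}

#' Write an FD map to a directory
#'
#' One TSV curve file per recorded pixel, named `r<row>_c<col>.tsv`, plus a
#' `map.json` with the grid shape and pixel size.
#'
#' @param map an `fd_map`.
#' @param dir output directory (created if missing).
#' @export
write_fd_map <- function(map, dir) {
  stopifnot(inherits(map, "fd_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(grid_shape = map$grid_shape,
                            pixel_size = map$pixel_size),
                       file.path(dir, "map.json"), auto_unbox = TRUE,
                       digits = NA)
  for (row in seq_len(map$grid_shape[1]))
    for (col in seq_len(map$grid_shape[2])) {
      cur <- map_get_pixel(map, row, col)
      if (!is.null(cur))
        write_fd_curve(cur, file.path(dir, sprintf("r%d_c%d.tsv", row, col)))
    }
  invisible(dir)
}

#' Read an FD map from a directory written by [write_fd_map]
#' @param dir directory containing `map.json` and per-pixel TSV files.
#' @return An `fd_map`.
#' @export
read_fd_map <- function(dir) {
  meta_path <- file.path(dir, "map.json")
  if (!file.exists(meta_path)) stop(sprintf("not an FD map directory: %s", dir))
  info <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  map <- fd_map(info$grid_shape, info$pixel_size)
  for (f in list.files(dir, pattern = "^r[0-9]+_c[0-9]+\\.tsv$")) {
    rc <- as.integer(regmatches(f, gregexpr("[0-9]+", f))[[1]])
    map <- map_set_pixel(map, rc[1], rc[2], read_fd_curve(file.path(dir, f)))
  }
  map
}
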