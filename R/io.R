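# Readers and writers for the pipeline's on-disk formats. Everything is
# plain text: tab-separated count tables with '#' metadata lines,
# MatrixMarket sparse matrices with gene/cell sidecar files, and a simple
# text raster format for volumes, label masks and 2D images (no TIFF
# library is available to R here; values round-trip at 12 significant
# digits).

#' Write / read a protein-by-sample count table (TSV)
#'
#' The file starts with `#`-prefixed metadata lines (experiment id, group
#' map, control ids, normalization flag), followed by a tab-separated
#' table whose first column is `protein_id`.
#'
#' @param table A [peptide_count_table].
#' @param path Output file path.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` returns a [peptide_count_table].
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "peptide_count_table"))
  meta <- c(
    sprintf("# experiment: %s", table$experiment),
    sprintf("# controls: %s", paste(table$control_ids, collapse = ",")),
    sprintf("# normalized: %s", table$normalized),
    sprintf(
      "# groups: %s",
      paste(sprintf("%s=%s", table$groups$sample, table$groups$group), collapse = ",")
    )
  )
  header <- paste(c("protein_id", colnames(table$counts)), collapse = "\t")
  body <- vapply(seq_len(nrow(table$counts)), function(i) {
    paste(c(
      rownames(table$counts)[i],
      sprintf("%.12g", table$counts[i, ])
    ), collapse = "\t")
  }, character(1))
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) {
    stop_spinescope(sprintf("File not found: %s.", path), "io")
  }
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s: ", key), meta, value = TRUE)
    if (length(hit) == 0L) {
      stop_spinescope(sprintf("Missing metadata line '# %s:' in %s.", key, path), "schema")
    }
    sub(sprintf("^# %s: ", key), "", hit[1])
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")], check.names = FALSE)
  if (!("protein_id" %in% names(df))) {
    stop_spinescope("Missing required column: protein_id.", "schema")
  }
  counts <- as.matrix(df[, setdiff(names(df), "protein_id"), drop = FALSE])
  if (!is.numeric(counts)) {
    stop_spinescope("Count columns must be numeric.", "schema")
  }
  if (any(counts < 0, na.rm = TRUE)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop_spinescope(
      sprintf(
        "Negative count at protein '%s', sample '%s'.",
        df$protein_id[bad[1]], colnames(counts)[bad[2]]
      ),
      "schema"
    )
  }
  rownames(counts) <- df$protein_id
  gm <- strsplit(strsplit(get_meta("groups"), ",")[[1]], "=")
  groups <- tibble(
    sample = vapply(gm, `[`, character(1), 1L),
    group = vapply(gm, `[`, character(1), 2L)
  )
  out <- peptide_count_table(
    counts,
    groups = groups,
    control_ids = strsplit(get_meta("controls"), ",")[[1]],
    experiment = get_meta("experiment")
  )
  out$normalized <- identical(get_meta("normalized"), "TRUE")
  out
}

#' Write / read a sparse count matrix as MatrixMarket + sidecars
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format), `genes.txt` and
#' `cells.txt` into `dir`.
#'
#' @param m A sparse or dense gene-by-cell matrix with dimnames.
#' @param dir Directory (created if needed).
#' @return `write_mtx_counts()` returns `dir` invisibly;
#'   `read_mtx_counts()` returns a `dgCMatrix` with dimnames.
#' @export
write_mtx_counts <- function(m, dir) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_spinescope("Matrix must have gene and cell names.", "schema")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.txt"))
  writeLines(colnames(m), file.path(dir, "cells.txt"))
  invisible(dir)
}

#' @rdname write_mtx_counts
#' @export
read_mtx_counts <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.txt", "cells.txt"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0L) {
    stop_spinescope(
      sprintf("Missing file(s): %s.", paste(missing_files, collapse = ", ")),
      "io"
    )
  }
  m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  dimnames(m) <- list(readLines(paths[2]), readLines(paths[3]))
  m
}

# ---- text rasters -----------------------------------------------------------

#' Write / read a 3D volume or label mask as plain text
#'
#' Format: `#`-prefixed header lines (`dims`, `voxel_size_nm`, optional
#' `role`), then one whitespace-separated line of values per (plane, row),
#' plane-major. Intensities are stored at 12 significant digits.
#'
#' @param vol An [em_volume], [voxel_mask] or numeric/logical/integer 3D
#'   array.
#' @param path Output file path.
#' @return `write_volume_text()` returns `path` invisibly;
#'   `read_volume_text()` returns an [em_volume] (or a [voxel_mask] when
#'   the file carries a role header and 0/1 values).
#' @export
write_volume_text <- function(vol, path) {
  role <- NULL
  vsz <- c(8, 8, 8)
  if (inherits(vol, "voxel_mask")) {
    role <- vol$role
    vsz <- vol$voxel_size_nm
    a <- vol$mask + 0L
  } else if (inherits(vol, "em_volume")) {
    vsz <- vol$voxel_size_nm
    a <- vol$voxels
  } else {
    a <- vol
  }
  d <- dim(a)
  header <- c(
    "# spinescope-volume 1",
    sprintf("# dims: %d %d %d", d[1], d[2], d[3]),
    sprintf("# voxel_size_nm: %.12g %.12g %.12g", vsz[1], vsz[2], vsz[3]),
    if (!is.null(role)) sprintf("# role: %s", role)
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  for (p in seq_len(d[1])) {
    plane <- matrix(sprintf("%.12g", a[p, , ]), d[2], d[3])
    writeLines(apply(plane, 1L, paste, collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_volume_text
#' @export
read_volume_text <- function(path) {
  if (!file.exists(path)) {
    stop_spinescope(sprintf("File not found: %s.", path), "io")
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  dims_line <- grep("^# dims: ", hdr, value = TRUE)
  if (length(dims_line) == 0L) {
    stop_spinescope("Not a spinescope volume file (missing '# dims:').", "schema")
  }
  d <- as.integer(strsplit(sub("^# dims: ", "", dims_line[1]), " ")[[1]])
  vsz_line <- grep("^# voxel_size_nm: ", hdr, value = TRUE)
  vsz <- as.numeric(strsplit(sub("^# voxel_size_nm: ", "", vsz_line[1]), " ")[[1]])
  role_line <- grep("^# role: ", hdr, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  if (length(vals) != prod(d)) {
    stop_spinescope("Volume payload size does not match the declared dims.", "schema")
  }
  # payload is plane-major, row-major within plane
  a <- array(NA_real_, d)
  per_plane <- d[2] * d[3]
  for (p in seq_len(d[1])) {
    a[p, , ] <- matrix(vals[((p - 1) * per_plane + 1):(p * per_plane)],
      d[2], d[3],
      byrow = TRUE
    )
  }
  if (length(role_line) > 0L) {
    voxel_mask(a > 0, role = sub("^# role: ", "", role_line[1]), voxel_size_nm = vsz)
  } else {
    em_volume(a, vsz)
  }
}

#' Write / read a 2D image as plain text
#'
#' @param img Numeric matrix.
#' @param path File path.
#' @return `write_image_text()` returns `path` invisibly;
#'   `read_image_text()` returns a numeric matrix.
#' @export
write_image_text <- function(img, path) {
  a <- array(img, c(1L, nrow(img), ncol(img)))
  write_volume_text(em_volume(a, c(1, 1, 1)), path)
}

#' @rdname write_image_text
#' @export
read_image_text <- function(path) {
  v <- read_volume_text(path)
  a <- if (inherits(v, "em_volume")) v$voxels else v$mask + 0
  matrix(a[1L, , ], dim(a)[2], dim(a)[3])
}
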