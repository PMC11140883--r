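#' Named anatomical landmarks
#'
#' Traditional reference points (eye canthi, nasion, ear centers, ...) used
#' to initialise the sagittal-plane search, to build registration masks and
#' to crop ear regions. Stored internally in the RAS (right-anterior-
#' superior) frame, millimetres.
#'
#' @param points n x 3 numeric matrix with one row per landmark, rownames =
#'   landmark names; or a named list of 3-vectors.
#' @param frame coordinate-frame label (default `"RAS"`).
#' @return Object of class `landmark_set` with fields `points` (named rows)
#'   and `frame`.
#' @export
landmark_set <- function(points, frame = "RAS") {
  if (is.list(points) && is.null(dim(points))) {
    nm <- names(points)
    points <- do.call(rbind, points)
    rownames(points) <- nm
  }
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  if (ncol(p) != 3) stop("landmarks must be 3D points")
  if (is.null(rownames(p)) || any(rownames(p) == ""))
    stop("every landmark needs a name")
  if (anyDuplicated(rownames(p))) stop("duplicate landmark labels")
  if (any(!is.finite(p))) stop("landmark coordinates must be finite")
  structure(list(points = p, frame = frame), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set (%s): %s>\n", x$frame,
              paste(rownames(x$points), collapse = ", ")))
  invisible(x)
}

#' @rdname landmark_set
#' @param x a `landmark_set`.
#' @param name landmark name.
#' @return `landmark()`: the named 3-vector.
#' @export
landmark <- function(x, name) {
  stopifnot(inherits(x, "landmark_set"))
  if (!name %in% rownames(x$points))
    stop(sprintf("no landmark named '%s'", name))
  drop(x$points[name, ])
}

#' Read landmarks from 3D Slicer FCSV or JSON
#'
#' The FCSV dialect is the 3D Slicer markups fiducial CSV: comment/header
#' lines start with `#`, data rows are `id,x,y,z,...,label,...`. A
#' `# CoordinateSystem = LPS` header is honoured by flipping x and y on
#' ingest, so the returned set is always RAS. The JSON dialect is this
#' package's own: `{"frame": "RAS", "points": {"name": [x, y, z], ...}}`.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"fcsv"` or `"json"`.
#' @return A [landmark_set()] in the RAS frame.
#' @export
read_landmarks <- function(path, dialect = c("auto", "fcsv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, fcsv = "fcsv", csv = "fcsv", json = "json",
                      stop(sprintf("cannot infer landmark dialect from '%s'",
                                   path)))
  }
  if (dialect == "fcsv") read_fcsv(path) else read_landmarks_json(path)
}

read_fcsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  lps <- any(grepl("CoordinateSystem\\s*=\\s*LPS", lines[hdr], ignore.case = TRUE))
  rows <- which(!hdr & nzchar(trimws(lines)))
  if (length(rows) == 0) stop(sprintf("no fiducial rows in '%s'", path))
  pts <- matrix(NA_real_, length(rows), 3)
  labels <- character(length(rows))
  for (i in seq_along(rows)) {
    ln <- rows[i]
    fields <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
    xyz <- suppressWarnings(as.numeric(fields[2:4]))
    if (length(fields) < 12 || any(!is.finite(xyz)))
      stop(sprintf("malformed fiducial row at line %d of '%s'", ln, path))
    pts[i, ] <- xyz
    labels[i] <- fields[12]
  }
  if (anyDuplicated(labels))
    stop(sprintf("duplicate landmark labels in '%s'", path))
  if (lps) pts[, 1:2] <- -pts[, 1:2]
  rownames(pts) <- labels
  landmark_set(pts, frame = "RAS")
}

read_landmarks_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- x$points
  if (is.null(pts) || length(pts) == 0) stop(sprintf("no points in '%s'", path))
  m <- do.call(rbind, lapply(pts, as.numeric))
  rownames(m) <- names(pts)
  frame <- toupper(x$frame %||% "RAS")
  if (frame == "LPS") {
    m[, 1:2] <- -m[, 1:2]
    frame <- "RAS"
  }
  landmark_set(m, frame = frame)
}

#' @rdname read_landmarks
#' @param lm a [landmark_set()].
#' @export
write_landmarks <- function(lm, path, dialect = c("auto", "fcsv", "json")) {
  stopifnot(inherits(lm, "landmark_set"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, fcsv = "fcsv", json = "json",
                      stop(sprintf("cannot infer landmark dialect from '%s'",
                                   path)))
  }
  if (dialect == "fcsv") {
    p <- lm$points
    n <- nrow(p)
    rows <- sprintf(
      "vtkMRMLMarkupsFiducialNode_%d,%.17g,%.17g,%.17g,0,0,0,1,1,1,0,%s,,",
      seq_len(n), p[, 1], p[, 2], p[, 3], rownames(p))
    writeLines(c("# Markups fiducial file version = 4.11",
                 "# CoordinateSystem = RAS",
                 paste0("# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,",
                        "label,desc,associatedNodeID"),
                 rows), path)
  } else {
    pts <- stats::setNames(
      lapply(seq_len(nrow(lm$points)), function(i) as.numeric(lm$points[i, ])),
      rownames(lm$points))
    jsonlite::write_json(list(frame = lm$frame, points = pts), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
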