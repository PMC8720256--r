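fmtNum <- function(x) formatC(x, format = "g", digits = 17)

inferFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "pcd")) return(ext)
  if (ext %in% c("xyz", "txt")) return("xyz")
  stop("cannot infer point cloud format from extension '", ext,
       "'; pass format= explicitly")
}

#' Read a point cloud file
#'
#' Supported dialects: PLY (ascii and binary_little_endian), PCD (ascii),
#' and whitespace-separated XYZ text (`x y z [label]` rows, `#` comments
#' ignored). Labels are picked up when the file carries an integer label
#' column/property and are absent otherwise. Readers never drop points: the
#' returned cloud has exactly as many points as the file has rows/elements.
#'
#' @param path File path.
#' @param format One of `"auto"` (by extension), `"ply"`, `"pcd"`, `"xyz"`.
#' @return A [LabeledCloud-class].
#' @export
readCloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- inferFormat(path)
  switch(format,
         xyz = readXYZ(path),
         ply = readPLY(path),
         pcd = readPCD(path))
}

#' Write a point cloud file
#'
#' Inverse of [readCloud()]: labels, when present, are stored as an integer
#' scalar field; coordinates are written at full double precision so a text
#' round-trip is exact.
#'
#' @param cloud A [LabeledCloud-class].
#' @param path Output path.
#' @param format One of `"auto"`, `"ply"`, `"pcd"`, `"xyz"`.
#' @param binary For PLY only: write `binary_little_endian` instead of
#'   ascii.
#' @return `path`, invisibly.
#' @export
writeCloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyz"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- inferFormat(path)
  stopifnot(is(cloud, "LabeledCloud"))
  validObject(cloud)
  switch(format,
         xyz = writeXYZ(cloud, path),
         ply = writePLY(cloud, path, binary = binary),
         pcd = writePCD(cloud, path))
  invisible(path)
}

readXYZ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data rows in ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  if (!all(nf %in% c(3L, 4L)) || length(unique(nf)) != 1L) {
    bad <- which(!nf %in% c(3L, 4L) | nf != nf[1L])[1L]
    stop("malformed row at line ", lineNo[bad], " of ", path,
         ": expected ", nf[1L], " columns")
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- lineNo[ceiling(which(is.na(vals))[1L] / nf[1L])]
    stop("non-numeric value at line ", bad, " of ", path)
  }
  m <- matrix(vals, ncol = nf[1L], byrow = TRUE)
  labels <- if (nf[1L] == 4L) as.integer(m[, 4L]) else NULL
  LabeledCloud(m[, 1:3, drop = FALSE], labels,
               name = tools::file_path_sans_ext(basename(path)))
}

writeXYZ <- function(cloud, path) {
  co <- cloudCoords(cloud)
  rows <- paste(fmtNum(co[, 1]), fmtNum(co[, 2]), fmtNum(co[, 3]))
  if (isLabeled(cloud)) rows <- paste(rows, cloudLabels(cloud))
  writeLines(rows, path)
}

plyTypeSize <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)

readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("unexpected end of PLY header in ", path)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  if (trimws(header[1L]) != "ply") stop(path, " is not a PLY file")
  fmtLine <- grep("^format ", header, value = TRUE)
  if (!length(fmtLine)) stop("PLY header missing format line in ", path)
  fmt <- strsplit(trimws(fmtLine[1L]), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt, "'")
  elLines <- grep("^element ", header)
  vline <- grep("^element vertex ", header)
  if (!length(vline)) stop("PLY file has no vertex element: ", path)
  nVert <- as.integer(strsplit(trimws(header[vline[1L]]), "\\s+")[[1L]][3L])
  nxt <- elLines[elLines > vline[1L]]
  endIdx <- if (length(nxt)) nxt[1L] else length(header)
  propLines <- header[(vline[1L] + 1L):(endIdx - 1L)]
  propLines <- grep("^property ", trimws(propLines), value = TRUE)
  if (any(grepl("^property list", propLines)))
    stop("PLY list properties are not supported for vertices")
  parts <- strsplit(propLines, "\\s+")
  types <- vapply(parts, `[`, character(1), 2L)
  names <- vapply(parts, `[`, character(1), 3L)
  if (!all(types %in% names(plyTypeSize)))
    stop("unsupported PLY property type: ",
         paste(setdiff(types, names(plyTypeSize)), collapse = ", "))
  need <- match(c("x", "y", "z"), names)
  if (anyNA(need)) stop("PLY vertex element lacks x/y/z properties")
  labCol <- match("label", names)

  if (fmt == "ascii") {
    lines <- readLines(con, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < nVert)
      stop("PLY body has ", length(lines), " rows, header promises ", nVert)
    toks <- strsplit(trimws(lines[seq_len(nVert)]), "\\s+")
    if (any(lengths(toks) != length(names))) {
      bad <- which(lengths(toks) != length(names))[1L]
      stop("malformed PLY vertex row ", bad, " in ", path)
    }
    vals <- suppressWarnings(as.numeric(unlist(toks)))
    if (anyNA(vals)) stop("non-numeric PLY vertex value in ", path)
    m <- matrix(vals, ncol = length(names), byrow = TRUE)
  } else {
    sizes <- plyTypeSize[types]
    rowBytes <- sum(sizes)
    raw <- readBin(con, "raw", n = nVert * rowBytes)
    if (length(raw) < nVert * rowBytes)
      stop("truncated binary PLY body in ", path)
    offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
    m <- matrix(0, nVert, length(names))
    base <- rep((seq_len(nVert) - 1L) * rowBytes, each = 1L)
    for (j in seq_along(names)) {
      sz <- sizes[j]
      pick <- as.vector(outer(seq_len(sz), base + offs[j], "+"))
      bytes <- raw[pick]
      m[, j] <- switch(as.character(sz),
        `1` = as.numeric(readBin(bytes, "integer", n = nVert, size = 1L,
                                 signed = !grepl("^u", types[j]))),
        `2` = as.numeric(readBin(bytes, "integer", n = nVert, size = 2L,
                                 endian = "little",
                                 signed = !grepl("^u", types[j]))),
        `4` = if (types[j] %in% c("float", "float32")) {
          as.numeric(readBin(bytes, "double", n = nVert, size = 4L,
                             endian = "little"))
        } else {
          as.numeric(readBin(bytes, "integer", n = nVert, size = 4L,
                             endian = "little"))
        },
        `8` = readBin(bytes, "double", n = nVert, size = 8L,
                      endian = "little"))
    }
  }
  labels <- if (!is.na(labCol)) as.integer(m[, labCol]) else NULL
  LabeledCloud(m[, need, drop = FALSE], labels,
               name = tools::file_path_sans_ext(basename(path)))
}

writePLY <- function(cloud, path, binary = FALSE) {
  co <- cloudCoords(cloud)
  hasLab <- isLabeled(cloud)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0"
              else "format ascii 1.0",
              "comment written by panicle3D",
              paste("element vertex", nrow(co)),
              "property double x", "property double y", "property double z",
              if (hasLab) "property int label",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    lab <- if (hasLab) cloudLabels(cloud) else NULL
    for (i in seq_len(nrow(co))) {
      writeBin(as.numeric(co[i, ]), con, size = 8L, endian = "little")
      if (hasLab) writeBin(as.integer(lab[i]), con, size = 4L,
                           endian = "little")
    }
  } else {
    rows <- paste(fmtNum(co[, 1]), fmtNum(co[, 2]), fmtNum(co[, 3]))
    if (hasLab) rows <- paste(rows, cloudLabels(cloud))
    writeLines(c(header, rows), path)
  }
}

readPCD <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hEnd <- grep("^DATA\\s", lines)
  if (!length(hEnd)) stop("PCD header missing DATA line in ", path)
  hEnd <- hEnd[1L]
  header <- lines[seq_len(hEnd)]
  getField <- function(key) {
    ln <- grep(paste0("^", key, "\\s"), header, value = TRUE)
    if (!length(ln)) return(NULL)
    strsplit(trimws(ln[1L]), "\\s+")[[1L]][-1L]
  }
  if (tolower(getField("DATA")[1L]) != "ascii")
    stop("only ascii PCD files are supported")
  fields <- getField("FIELDS")
  nPts <- as.integer(getField("POINTS")[1L])
  need <- match(c("x", "y", "z"), fields)
  if (anyNA(need)) stop("PCD file lacks x/y/z fields: ", path)
  labCol <- match("label", fields)
  body <- lines[-seq_len(hEnd)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nPts)
    stop("PCD body has ", length(body), " rows, header promises ", nPts)
  toks <- strsplit(trimws(body), "\\s+")
  if (any(lengths(toks) != length(fields))) {
    bad <- which(lengths(toks) != length(fields))[1L]
    stop("malformed PCD row ", bad, " in ", path)
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) stop("non-numeric PCD value in ", path)
  m <- matrix(vals, ncol = length(fields), byrow = TRUE)
  labels <- if (!is.na(labCol)) as.integer(m[, labCol]) else NULL
  LabeledCloud(m[, need, drop = FALSE], labels,
               name = tools::file_path_sans_ext(basename(path)))
}

writePCD <- function(cloud, path) {
  co <- cloudCoords(cloud)
  hasLab <- isLabeled(cloud)
  fields <- c("x", "y", "z", if (hasLab) "label")
  nf <- length(fields)
  header <- c("# .PCD v0.7 - Point Cloud Data file format",
              "VERSION 0.7",
              paste("FIELDS", paste(fields, collapse = " ")),
              paste("SIZE", paste(rep(ifelse(fields == "label", 4, 8)),
                                  collapse = " ")),
              paste("TYPE", paste(ifelse(fields == "label", "I", "F"),
                                  collapse = " ")),
              paste("COUNT", paste(rep(1L, nf), collapse = " ")),
              paste("WIDTH", nrow(co)),
              "HEIGHT 1",
              "VIEWPOINT 0 0 0 1 0 0 0",
              paste("POINTS", nrow(co)),
              "DATA ascii")
  rows <- paste(fmtNum(co[, 1]), fmtNum(co[, 2]), fmtNum(co[, 3]))
  if (hasLab) rows <- paste(rows, cloudLabels(cloud))
  writeLines(c(header, rows), path)
}

#' Save / load a labeled dataset archive
#'
#' A `CloudDataset` is stored as a single plain-text archive: a comment
#' line, a JSON header (names, split tags, point count), then one
#' `x y z label` block per cloud. The round-trip is lossless for
#' coordinates, labels, names and split tags.
#'
#' @param ds A [CloudDataset-class] whose members are all labeled and
#'   uniformly sized.
#' @param path Archive path (conventionally `.p3d`).
#' @return `saveDataset`: `path`, invisibly. `loadDataset`: the restored
#'   [CloudDataset-class].
#' @export
saveDataset <- function(ds, path) {
  stopifnot(is(ds, "CloudDataset"))
  validObject(ds)
  np <- nPoints(ds[[1L]])
  header <- jsonlite::toJSON(
    list(n = length(ds), npoints = np,
         names = vapply(cloudList(ds), cloudName, character(1)),
         splits = splitTags(ds)),
    auto_unbox = TRUE, null = "null", digits = NA)
  blocks <- vapply(cloudList(ds), function(cl) {
    co <- cloudCoords(cl)
    paste(paste(fmtNum(co[, 1]), fmtNum(co[, 2]), fmtNum(co[, 3]),
                cloudLabels(cl)), collapse = "\n")
  }, character(1))
  writeLines(c("# panicle3D dataset v1", as.character(header), blocks), path)
  invisible(path)
}

#' @rdname saveDataset
#' @export
loadDataset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !startsWith(lines[1L], "# panicle3D dataset"))
    stop(path, " is not a panicle3D dataset archive")
  hdr <- jsonlite::fromJSON(lines[2L])
  np <- as.integer(hdr$npoints)
  n <- as.integer(hdr$n)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n * np)
    stop("archive body has ", length(body), " rows, expected ", n * np)
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body),
                                                      "\\s+"))))
  if (anyNA(vals) || length(vals) != n * np * 4L)
    stop("malformed data rows in ", path)
  m <- matrix(vals, ncol = 4L, byrow = TRUE)
  clouds <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * np + 1L):(i * np)
    clouds[[i]] <- LabeledCloud(m[rows, 1:3, drop = FALSE],
                                as.integer(m[rows, 4L]),
                                name = hdr$names[i])
  }
  splits <- if (!is.null(hdr$splits)) as.character(hdr$splits) else NULL
  CloudDataset(clouds, splits)
}
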