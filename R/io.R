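#' Read a grayscale image
#'
#' Reads PGM (plain `P2` or raw `P5`) natively, and PNG through the `png`
#' package when it is installed.  Color input is converted to luminance
#' (Rec. 601 weights 0.299/0.587/0.114) and intensities are rescaled to
#' `[0, 1]` (8-bit by 1/255, 16-bit by 1/65535).
#'
#' @param path Path to the image file.
#' @return A numeric matrix in `[0, 1]`; rows are image rows (`y`), columns
#'   are image columns (`x`).
#' @export
#' @examples
#' p <- tempfile(fileext = ".pgm")
#' write_pgm(matrix(0.5, 4, 6), p)
#' img <- load_image(p)
#' dim(img)
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    pgm = read_pgm(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading '", path, "' requires the 'png' package")
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) {
        # luminance; alpha (4th channel), if any, is ignored
        0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
      } else a
    },
    stop("unsupported image format '", ext, "' for: ", path)
  )
  if (!is.matrix(img) || length(img) == 0L)
    stop("empty or unreadable image: ", path)
  img
}

#' Read a PGM image (plain P2 or raw P5)
#'
#' @param path Path to a `.pgm` file.
#' @return Numeric matrix scaled to `[0, 1]` by the file's maxval.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM (P2/P5) file: ", path)
  # header tokens: width, height, maxval; '#' starts a comment to end of line
  tokens <- integer(0)
  buf <- character(0)
  in_comment <- FALSE
  while (length(tokens) < 3L) {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L) stop("truncated PGM header: ", path)
    ch <- rawToChar(ch)
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
      next
    }
    if (ch == "#") {
      in_comment <- TRUE
      next
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (w < 1L || h < 1L || maxval < 1L) stop("invalid PGM header: ", path)
  n <- w * h
  if (magic == "P5") {
    if (maxval < 256L) {
      vals <- as.integer(readBin(con, "raw", n))
    } else {
      vals <- readBin(con, "integer", n, size = 2L, signed = FALSE,
                      endian = "big")
    }
  } else {
    txt <- rawToChar(readBin(con, "raw", file.size(path)))
    txt <- gsub("#[^\n]*", "", txt)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    if (length(vals) < n) stop("truncated PGM data: ", path)
    vals <- vals[seq_len(n)]
  }
  if (anyNA(vals)) stop("corrupt PGM data: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a PGM image
#'
#' @param img Numeric matrix in `[0, 1]` (values are clamped).
#' @param path Output path.
#' @param maxval Maximum gray value, 255 (8-bit) or 65535 (16-bit).
#' @param ascii Write plain-text `P2` (default) rather than raw `P5`.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L, ascii = TRUE) {
  stopifnot(is.matrix(img), maxval %in% c(255L, 65535L))
  vals <- round(pmin(pmax(img, 0), 1) * maxval)
  header <- sprintf("%s\n%d %d\n%d\n", if (ascii) "P2" else "P5",
                    ncol(img), nrow(img), maxval)
  if (ascii) {
    body <- apply(vals, 1L, paste, collapse = " ")
    writeLines(c(sub("\n$", "", header), body), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    v <- as.integer(t(vals))
    if (maxval < 256L) {
      writeBin(as.raw(v), con)
    } else {
      writeBin(v, con, size = 2L, endian = "big")
    }
  }
  invisible(path)
}

#' Write a template matrix as CSV
#'
#' Serializes a binary mask or orientation-code matrix as integer CSV with no
#' header; [read_template_csv()] reads it back.
#'
#' @param m Integer-valued matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template_csv <- function(m, path) {
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_template_csv
#' @export
read_template_csv <- function(path) {
  as.matrix(read.csv(path, header = FALSE))
}
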