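#' Read a labeled dataset from CSV or MAT file
#'
#' CSV files carry samples as rows with a header row and the class label
#' in the last column. MAT files follow the layout of the public
#' scikit-feature benchmark distribution: a samples x features matrix `X`
#' and a label vector `Y` (MAT v5; this reader supports uncompressed
#' numeric matrices plus zlib-compressed elements where the R runtime can
#' inflate them). Labels are re-encoded to consecutive integers with the
#' original values retained in `label_levels`.
#'
#' @param path Path to a `.csv` or `.mat` file.
#' @return A [labeled_dataset()] (no partition).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (grepl("\\.mat$", path, ignore.case = TRUE)) {
    vars <- read_mat5(path)
    if (is.null(vars$X)) stop("MAT file is missing variable `X`",
                              call. = FALSE)
    if (is.null(vars$Y)) stop("MAT file is missing variable `Y`",
                              call. = FALSE)
    X <- vars$X
    Y <- as.vector(vars$Y)
    if (length(Y) != nrow(X)) {
      stop(sprintf("`Y` length (%d) does not match `X` rows (%d)",
                   length(Y), nrow(X)), call. = FALSE)
    }
    return(labeled_dataset(X, Y))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("CSV must have at least one feature column and a label column",
                          call. = FALSE)
  X <- as.matrix(df[, -ncol(df), drop = FALSE])
  if (!is.numeric(X)) {
    bad <- colnames(df)[which(!vapply(df[, -ncol(df), drop = FALSE],
                                      is.numeric, logical(1)))[1]]
    stop(sprintf("non-numeric feature column: %s", bad), call. = FALSE)
  }
  labeled_dataset(X, df[[ncol(df)]])
}

#' Write a labeled dataset to CSV
#'
#' Samples as rows, header row, class label (original values) in the last
#' column named `label`.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  X <- dataset$features
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  df <- data.frame(X, check.names = FALSE)
  df$label <- dataset$label_levels[dataset$labels]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a labeled dataset as a MAT v5 file (X, Y layout)
#'
#' Emits uncompressed double matrices `X` (samples x features) and `Y`
#' (labels as a column vector), matching the scikit-feature benchmark
#' layout, readable by [read_dataset()] and by standard MAT readers.
#'
#' @inheritParams write_dataset_csv
#' @return `path`, invisibly.
#' @export
write_dataset_mat <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  con <- file(path, "wb")
  on.exit(close(con))
  # 128-byte header: 116 bytes text, 8 bytes subsys offset, version, "IM"
  txt <- charToRaw(sprintf("MATLAB 5.0 MAT-file, created by soschoa on %s",
                           format(Sys.time(), "%Y-%m-%d")))
  header <- raw(116)
  header[seq_along(txt)] <- txt
  writeBin(header, con)
  writeBin(raw(8), con)
  writeBin(as.raw(c(0x00, 0x01)), con)  # version 0x0100, little-endian
  writeBin(charToRaw("IM"), con)
  write_mat5_matrix(con, "X", unname(dataset$features))
  write_mat5_matrix(con, "Y",
                    matrix(as.numeric(dataset$label_levels[dataset$labels]),
                           ncol = 1))
  invisible(path)
}

# --- minimal MAT v5 encoder/decoder (double matrices only) ----------------

MI_INT8 <- 1L; MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_DOUBLE_CLASS <- 6L

pad8 <- function(nbytes) (8L - nbytes %% 8L) %% 8L

write_mat5_matrix <- function(con, name, m) {
  storage.mode(m) <- "double"
  nm <- charToRaw(name)
  data_bytes <- 8L * length(m)
  body <- 16L +                                 # array flags
    16L +                                       # dimensions (2 x int32 + tag)
    8L + length(nm) + pad8(length(nm)) +        # name
    8L + data_bytes + pad8(data_bytes)          # real part
  writeBin(as.integer(c(MI_MATRIX, body)), con, size = 4L)
  writeBin(as.integer(c(MI_UINT32, 8L)), con, size = 4L)
  writeBin(as.integer(c(MX_DOUBLE_CLASS, 0L)), con, size = 4L)
  writeBin(as.integer(c(MI_INT32, 8L)), con, size = 4L)
  writeBin(as.integer(dim(m)), con, size = 4L)
  writeBin(as.integer(c(MI_INT8, length(nm))), con, size = 4L)
  writeBin(c(nm, raw(pad8(length(nm)))), con)
  writeBin(as.integer(c(MI_DOUBLE, data_bytes)), con, size = 4L)
  writeBin(as.vector(m), con, size = 8L)
  if (pad8(data_bytes) > 0L) writeBin(raw(pad8(data_bytes)), con)
}

read_mat5 <- function(path) {
  raw_data <- readBin(path, "raw", file.size(path))
  if (length(raw_data) < 128L) stop("not a MAT v5 file", call. = FALSE)
  magic <- rawToChar(raw_data[127:128])
  if (!magic %in% c("IM", "MI")) {
    stop("not a MAT v5 file (bad endian indicator)", call. = FALSE)
  }
  if (magic == "MI") stop("big-endian MAT files are not supported",
                          call. = FALSE)
  vars <- list()
  pos <- 129L
  while (pos + 8L <= length(raw_data) + 1L) {
    tag <- readBin(raw_data[pos:(pos + 7L)], "integer", 2L, size = 4L)
    type <- tag[1]; nbytes <- tag[2]
    if (nbytes < 0L || pos + 7L + nbytes > length(raw_data)) {
      stop("corrupt MAT file: element size exceeds file length",
           call. = FALSE)
    }
    payload <- raw_data[(pos + 8L):(pos + 7L + nbytes)]
    if (type == MI_COMPRESSED) {
      payload <- tryCatch(
        memDecompress(payload, type = "gzip"),
        error = function(e) stop(
          "cannot inflate compressed MAT element in this R runtime",
          call. = FALSE))
      inner_tag <- readBin(payload[1:8], "integer", 2L, size = 4L)
      v <- parse_mat5_matrix(payload[9:(8L + inner_tag[2])])
    } else if (type == MI_MATRIX) {
      v <- parse_mat5_matrix(payload)
    } else {
      v <- NULL
    }
    if (!is.null(v)) vars[[v$name]] <- v$value
    # compressed elements are not 8-byte padded; others are
    pad <- if (type == MI_COMPRESSED) 0L else pad8(nbytes)
    pos <- pos + 8L + nbytes + pad
  }
  vars
}

# parse one miMATRIX payload; returns list(name, value) or NULL for
# unsupported classes
parse_mat5_matrix <- function(payload) {
  read_element <- function(at) {
    # handle the small-data-element format (length packed into the tag)
    head <- readBin(payload[at:(at + 3L)], "integer", 1L, size = 4L)
    small_len <- bitwAnd(bitwShiftR(head, 16L), 0xFFFFL)
    small_type <- bitwAnd(head, 0xFFFFL)
    if (small_len > 0L) {
      list(type = small_type, nbytes = small_len,
           data_at = at + 4L, next_at = at + 8L)
    } else {
      nb <- readBin(payload[(at + 4L):(at + 7L)], "integer", 1L, size = 4L)
      list(type = head, nbytes = nb, data_at = at + 8L,
           next_at = at + 8L + nb + pad8(nb))
    }
  }
  flags <- read_element(1L)
  cls <- as.integer(payload[flags$data_at])
  dims_el <- read_element(flags$next_at)
  dims <- readBin(payload[dims_el$data_at:(dims_el$data_at +
                                             dims_el$nbytes - 1L)],
                  "integer", dims_el$nbytes / 4L, size = 4L)
  name_el <- read_element(dims_el$next_at)
  name <- rawToChar(payload[name_el$data_at:(name_el$data_at +
                                               name_el$nbytes - 1L)])
  if (cls != MX_DOUBLE_CLASS || length(dims) != 2L) return(NULL)
  data_el <- read_element(name_el$next_at)
  n <- prod(dims)
  value <- decode_mat5_numeric(
    payload[data_el$data_at:(data_el$data_at + data_el$nbytes - 1L)],
    data_el$type, n)
  if (is.null(value)) return(NULL)
  list(name = name, value = matrix(value, dims[1], dims[2]))
}

decode_mat5_numeric <- function(bytes, type, n) {
  switch(as.character(type),
         "9" = readBin(bytes, "double", n, size = 8L),
         "7" = readBin(bytes, "double", n, size = 4L),       # miSINGLE
         "5" = as.numeric(readBin(bytes, "integer", n, size = 4L)),
         "6" = {  # miUINT32: R lacks unsigned 4-byte reads
           v <- as.numeric(readBin(bytes, "integer", n, size = 4L))
           ifelse(v < 0, v + 2^32, v)
         },
         "3" = as.numeric(readBin(bytes, "integer", n, size = 2L)),
         "4" = as.numeric(readBin(bytes, "integer", n, size = 2L,
                                  signed = FALSE)),
         "1" = as.numeric(readBin(bytes, "integer", n, size = 1L)),
         "2" = as.numeric(readBin(bytes, "integer", n, size = 1L,
                                  signed = FALSE)),
         NULL)
}
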