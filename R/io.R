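# Dataset input/output: delimited text (header of gene names, last column
# the class label) and the MATLAB-style container format used by common
# feature-selection benchmark repositories (expression matrix plus label
# vector).

#' Read an expression dataset
#'
#' Two formats are supported. `"delimited"` is a text table with a header
#' row of gene names, one row per sample and the class label in the last
#' column (any delimiter `data.table::fread` detects). `"mat"` is the
#' MATLAB Level-5 container used by feature-selection benchmark
#' repositories, holding one samples-by-genes matrix (conventionally `X`)
#' and one label vector (`Y`); variables with other names are matched by
#' shape. Labels are recoded to contiguous integer codes.
#'
#' @param path Path to the dataset file.
#' @param format `"delimited"` or `"mat"`.
#' @return An [fs_dataset()].
#' @export
read_dataset <- function(path, format = c("delimited", "mat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "delimited") read_dataset_delimited(path)
  else read_dataset_mat(path)
}

read_dataset_delimited <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L || ncol(dt) < 2L)
    stop("dataset needs at least one sample and one gene plus a label column",
         call. = FALSE)
  label_col <- ncol(dt)
  y <- dt[[label_col]]
  Xdf <- dt[, -label_col, drop = FALSE]
  non_num <- which(!vapply(Xdf, is.numeric, logical(1)))
  if (length(non_num) > 0L)
    stop(sprintf("non-numeric expression column '%s' (column %d)",
                 names(Xdf)[non_num[1]], non_num[1]), call. = FALSE)
  fs_dataset(as.matrix(Xdf), y, feature_names = names(Xdf))
}

read_dataset_mat <- function(path) {
  vars <- read_mat5(path)
  nm <- names(vars)
  pick_matrix <- function() {
    if ("X" %in% nm) return(vars[["X"]])
    sizes <- vapply(vars, length, numeric(1))
    is_mat <- vapply(vars, function(v) is.matrix(v) && all(dim(v) > 1L),
                     logical(1))
    if (!any(is_mat)) stop("no expression matrix found in container",
                           call. = FALSE)
    vars[[which(is_mat)[which.max(sizes[is_mat])]]]
  }
  X <- pick_matrix()
  pick_labels <- function() {
    if ("Y" %in% nm) return(drop(vars[["Y"]]))
    for (v in vars) {
      v <- drop(v)
      if (is.null(dim(v)) && length(v) == nrow(X) && !identical(v, X))
        return(v)
    }
    stop("no label vector found in container", call. = FALSE)
  }
  y <- pick_labels()
  if (length(y) != nrow(X))
    stop(sprintf("label vector length %d does not match %d samples",
                 length(y), nrow(X)), call. = FALSE)
  fs_dataset(X, y)
}

#' Write a dataset in the delimited exchange format
#'
#' Writes the transpose-free layout [read_dataset()] consumes: a header of
#' gene names, one row per sample, and the class label (original label
#' values) in a final `class` column. Synthetic data therefore round-trips
#' through the reader exactly.
#'
#' @param data An [fs_dataset()].
#' @param path Output file path; the extension picks the delimiter
#'   (`.csv` comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "fs_dataset"))
  df <- as.data.frame(data$X)
  names(df) <- data$feature_names
  df[["class"]] <- data$classes[data$y]
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

# --- Minimal MATLAB Level-5 (.mat) reader -------------------------------
# Little-endian files only; numeric (real) arrays only; zlib-compressed
# elements are inflated with memDecompress where the R build supports it.

MAT_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L,
                    `6` = 4L, `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L)

mat_read_numeric <- function(raw, type) {
  switch(as.character(type),
    "1" = readBin(raw, "integer", n = length(raw), size = 1L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(raw, "integer", n = length(raw), size = 1L, signed = FALSE,
                  endian = "little"),
    "3" = readBin(raw, "integer", n = length(raw) / 2L, size = 2L,
                  signed = TRUE, endian = "little"),
    "4" = readBin(raw, "integer", n = length(raw) / 2L, size = 2L,
                  signed = FALSE, endian = "little"),
    "5" = readBin(raw, "integer", n = length(raw) / 4L, size = 4L,
                  endian = "little"),
    "6" = {  # uint32: reinterpret negative int32 values
      v <- as.numeric(readBin(raw, "integer", n = length(raw) / 4L,
                              size = 4L, endian = "little"))
      v[v < 0] <- v[v < 0] + 2^32
      v
    },
    "7" = readBin(raw, "numeric", n = length(raw) / 4L, size = 4L,
                  endian = "little"),
    "9" = readBin(raw, "numeric", n = length(raw) / 8L, size = 8L,
                  endian = "little"),
    stop("unsupported MAT data type ", type, call. = FALSE))
}

# One tagged data element starting at byte offset `pos` (1-based).
# Returns list(type, data = raw payload, next_pos).
mat_element <- function(bytes, pos) {
  tag <- readBin(bytes[pos:(pos + 3L)], "integer", size = 4L,
                 endian = "little")
  small_len <- bitwAnd(bitwShiftR(tag, 16L), 0xFFFFL)
  if (small_len > 0L) {
    type <- bitwAnd(tag, 0xFFFFL)
    data <- if (small_len > 0L) bytes[(pos + 4L):(pos + 3L + small_len)]
            else raw(0)
    return(list(type = type, data = data, next_pos = pos + 8L))
  }
  type <- tag
  nbytes <- readBin(bytes[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                    endian = "little")
  data <- if (nbytes > 0L) bytes[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
  pad <- (8L - nbytes %% 8L) %% 8L
  list(type = type, data = data, next_pos = pos + 8L + nbytes + pad)
}

# Parse the body of a miMATRIX element into list(name, value) or NULL for
# unsupported (complex/sparse/non-numeric) arrays.
mat_parse_matrix <- function(body) {
  pos <- 1L
  flags_el <- mat_element(body, pos); pos <- flags_el$next_pos
  flags <- readBin(flags_el$data[1:4], "integer", size = 4L,
                   endian = "little")
  array_class <- bitwAnd(flags, 0xFFL)
  is_complex <- bitwAnd(flags, bitwShiftL(1L, 11L)) != 0L
  dims_el <- mat_element(body, pos); pos <- dims_el$next_pos
  dims <- mat_read_numeric(dims_el$data, 5L)
  name_el <- mat_element(body, pos); pos <- name_el$next_pos
  name <- rawToChar(name_el$data)
  if (!(array_class %in% 6:13) || is_complex || length(dims) != 2L)
    return(list(name = name, value = NULL))
  pr_el <- mat_element(body, pos)
  value <- as.numeric(mat_read_numeric(pr_el$data, pr_el$type))
  if (length(value) != prod(dims))
    stop("corrupt MAT array '", name, "': data length does not match dims",
         call. = FALSE)
  dim(value) <- dims
  list(name = name, value = value)
}

mat_inflate <- function(data) {
  out <- tryCatch(memDecompress(data, type = "gzip"), error = function(e) NULL)
  if (is.null(out))
    out <- tryCatch(memDecompress(data, type = "unknown"),
                    error = function(e) NULL)
  if (is.null(out))
    stop("cannot inflate compressed MAT element; re-save the file uncompressed",
         call. = FALSE)
  out
}

read_mat5 <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 136L) stop("file too short to be a MAT container",
                                 call. = FALSE)
  endian <- rawToChar(bytes[127:128])
  if (endian != "IM")
    stop("unsupported MAT container (big-endian or not Level 5)",
         call. = FALSE)
  pos <- 129L
  vars <- list()
  while (pos + 7L <= length(bytes)) {
    type <- readBin(bytes[pos:(pos + 3L)], "integer", size = 4L,
                    endian = "little")
    nbytes <- readBin(bytes[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                      endian = "little")
    body <- if (nbytes > 0L) bytes[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
    # compressed elements are written unpadded; plain ones pad to 8 bytes
    pad <- if (type == 15L) 0L else (8L - nbytes %% 8L) %% 8L
    pos <- pos + 8L + nbytes + pad
    if (type == 15L) {               # zlib-compressed element
      body <- mat_inflate(body)
      inner <- mat_element(body, 1L)
      type <- inner$type
      body <- inner$data
    }
    if (type != 14L) next            # skip non-matrix elements
    parsed <- mat_parse_matrix(body)
    if (!is.null(parsed$value)) vars[[parsed$name]] <- parsed$value
  }
  if (length(vars) == 0L) stop("no numeric arrays found in MAT container",
                               call. = FALSE)
  vars
}
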