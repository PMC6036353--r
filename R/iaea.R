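# IAEA-dialect phase-space files: a text header (key-value blocks beginning
# "$KEY:") plus a fixed-length binary record file.
#
# Record layout (little-endian):
#   byte 1                 signed particle type: |type| in {1 photon,
#                          2 electron, 3 positron}; sign(type) = sign(w)
#   4-byte float           energy in MeV; negated for the first particle
#                          of a new primary history
#   4-byte floats          each of X, Y, Z, U, V, Weight whose header flag
#                          is 1, in that order; flag 0 fields are constant
#                          and listed under $RECORD_CONSTANT
#   4-byte floats/ints     extra floats then extra longs (preserved opaquely)
#
# W never occupies record bytes: |w| = sqrt(max(0, 1 - u^2 - v^2)), with its
# sign carried by the type byte.

IAEA_FIELDS <- c("x", "y", "z", "u", "v", "weight")

#' Write a phase-space store as an IAEA-dialect file pair
#'
#' Fields are stored in single precision. `z` is written as a record
#' constant (the scoring plane); all other fields are per-record. Extra
#' floats/longs attached to the store as attributes `iaea_extra_floats` /
#' `iaea_extra_longs` (matrices with one row per particle) are appended to
#' each record and preserved opaquely.
#'
#' @param store a [phsp_store()].
#' @param header_path path for the text header (conventionally
#'   `.IAEAheader`).
#' @param record_path path for the binary records (conventionally
#'   `.IAEAphsp`). Defaults to `header_path` with the extension swapped.
#' @param allow_empty permit writing a store with zero particles.
#' @return invisibly, the record path.
#' @export
write_iaea <- function(store, header_path, record_path = NULL,
                       allow_empty = FALSE) {
  if (is.null(record_path)) {
    record_path <- sub("\\.IAEAheader$", "", header_path)
    record_path <- paste0(record_path, ".IAEAphsp")
  }
  n <- nrow(store)
  if (n == 0 && !allow_empty) {
    stop("refusing to write an empty store; set allow_empty = TRUE")
  }
  xf <- attr(store, "iaea_extra_floats")
  xl <- attr(store, "iaea_extra_longs")
  n_xf <- if (is.null(xf)) 0L else ncol(xf)
  n_xl <- if (is.null(xl)) 0L else ncol(xl)

  stored <- c(x = TRUE, y = TRUE, z = FALSE, u = TRUE, v = TRUE,
              weight = TRUE)
  record_length <- 1L + 4L * (1L + sum(stored) + n_xf + n_xl)

  counts <- counts_by_kind(store)
  hdr <- c(
    "$IAEA_INDEX:", "0", "",
    "$TITLE:", "fajtrace phase space", "",
    "$FILE_TYPE:", "0", "",
    "$BYTE_ORDER:", "1234", "",
    "$RECORD_LENGTH:", as.character(record_length), "",
    "$RECORD_CONTENTS:",
    paste0("    ", as.integer(stored["x"]), "     // X is stored ?"),
    paste0("    ", as.integer(stored["y"]), "     // Y is stored ?"),
    paste0("    ", as.integer(stored["z"]), "     // Z is stored ?"),
    paste0("    ", as.integer(stored["u"]), "     // U is stored ?"),
    paste0("    ", as.integer(stored["v"]), "     // V is stored ?"),
    paste0("    ", as.integer(stored["weight"]), "     // Weight is stored ?"),
    paste0("    ", n_xf, "     // Number of extra floats stored ?"),
    paste0("    ", n_xl, "     // Number of extra longs stored ?"),
    "",
    "$RECORD_CONSTANT:",
    paste0("    ", format(attr(store, "z_plane"), digits = 10),
           "     // Constant Z"),
    "",
    "$ORIG_HISTORIES:", format(attr(store, "n_original_histories"),
                               digits = 15, scientific = FALSE), "",
    "$PARTICLES:", as.character(n), "",
    "$PHOTONS:", as.character(counts[["photon"]]), "",
    "$ELECTRONS:", as.character(counts[["electron"]]), "",
    "$POSITRONS:", as.character(counts[["positron"]]), ""
  )
  tryCatch(writeLines(hdr, header_path),
           error = function(e) stop("cannot write header: ",
                                    conditionMessage(e)))

  # Assemble records column-wise into a raw matrix (one column per record).
  m <- matrix(as.raw(0), nrow = record_length, ncol = max(n, 1L))[, seq_len(n),
                                                                  drop = FALSE]
  type <- store$kind * ifelse(store$w < 0, -1L, 1L)
  m[1L, ] <- writeBin(as.integer(type), raw(), size = 1L)
  off <- 2L
  put_floats <- function(m, off, values) {
    b <- writeBin(as.numeric(values), raw(), size = 4L, endian = "little")
    m[off:(off + 3L), ] <- matrix(b, nrow = 4L)
    m
  }
  energy <- store$energy * ifelse(store$new_history, -1, 1)
  m <- put_floats(m, off, energy); off <- off + 4L
  for (f in IAEA_FIELDS) {
    if (!stored[[f]]) next
    m <- put_floats(m, off, store[[f]]); off <- off + 4L
  }
  if (n_xf) for (j in seq_len(n_xf)) {
    m <- put_floats(m, off, xf[, j]); off <- off + 4L
  }
  if (n_xl) for (j in seq_len(n_xl)) {
    b <- writeBin(as.integer(xl[, j]), raw(), size = 4L, endian = "little")
    m[off:(off + 3L), ] <- matrix(b, nrow = 4L)
    off <- off + 4L
  }
  con <- tryCatch(file(record_path, "wb"),
                  error = function(e) stop("cannot open record file: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  if (n) writeBin(as.vector(m), con)
  invisible(record_path)
}

parse_iaea_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  starts <- grep("^\\$", lines)
  if (!length(starts)) stop("malformed header: no $KEY blocks found")
  keys <- sub(":.*$", "", sub("^\\$", "", lines[starts]))
  ends <- c(starts[-1] - 1L, length(lines))
  blocks <- lapply(seq_along(starts), function(i) {
    body <- lines[(starts[i] + 1L):ends[i]]
    body <- body[nzchar(trimws(body))]
    body
  })
  names(blocks) <- keys
  blocks
}

header_value <- function(blocks, key, numeric = TRUE) {
  if (!key %in% names(blocks)) {
    stop("malformed header: missing $", key, " block")
  }
  v <- blocks[[key]]
  if (!length(v)) stop("malformed header: empty $", key, " block")
  first <- trimws(sub("//.*$", "", v[[1]]))
  if (numeric) as.numeric(first) else first
}

header_flags <- function(blocks) {
  v <- blocks[["RECORD_CONTENTS"]]
  if (is.null(v)) stop("malformed header: missing $RECORD_CONTENTS block")
  vals <- as.integer(trimws(sub("//.*$", "", v)))
  if (length(vals) < 8 || anyNA(vals)) {
    stop("malformed header: $RECORD_CONTENTS needs 8 integer flag lines")
  }
  list(stored = setNames(as.logical(vals[1:5]), c("x", "y", "z", "u", "v")),
       weight_stored = as.logical(vals[6]),
       n_extra_float = vals[7], n_extra_long = vals[8])
}

#' Read an IAEA-dialect phase-space file pair
#'
#' @param header_path path to the text header.
#' @param record_path path to the binary record file; defaults to
#'   `header_path` with the extension swapped.
#' @return a [phsp_store()]; extra floats/longs, if any, are attached as
#'   attributes `iaea_extra_floats` / `iaea_extra_longs`.
#' @export
read_iaea <- function(header_path, record_path = NULL) {
  if (is.null(record_path)) {
    record_path <- sub("\\.IAEAheader$", "", header_path)
    record_path <- paste0(record_path, ".IAEAphsp")
  }
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  if (!file.exists(record_path)) stop("record file not found: ", record_path)
  blocks <- parse_iaea_header(header_path)
  flags <- header_flags(blocks)
  record_length <- as.integer(header_value(blocks, "RECORD_LENGTH"))
  n_declared <- as.integer(header_value(blocks, "PARTICLES"))
  orig <- header_value(blocks, "ORIG_HISTORIES")

  expected_length <- 1L + 4L * (1L + sum(flags$stored) + flags$weight_stored +
                                  flags$n_extra_float + flags$n_extra_long)
  if (record_length != expected_length) {
    stop("malformed header: $RECORD_LENGTH (", record_length,
         ") inconsistent with $RECORD_CONTENTS (expects ",
         expected_length, ")")
  }

  size <- file.size(record_path)
  if (size %% record_length != 0) {
    stop("truncated record file: ", size, " bytes is not a multiple of the ",
         record_length, "-byte record; trailing partial record at byte offset ",
         size - size %% record_length)
  }
  n <- as.integer(size / record_length)
  if (n != n_declared) {
    stop("record file holds ", n, " records but header declares ", n_declared)
  }

  # record constants, in field order, for every unstored field
  constants <- list()
  if (any(!flags$stored) || !flags$weight_stored) {
    v <- blocks[["RECORD_CONSTANT"]]
    if (is.null(v)) stop("malformed header: missing $RECORD_CONSTANT block")
    vals <- as.numeric(trimws(sub("//.*$", "", v)))
    need <- c(names(flags$stored)[!flags$stored],
              if (!flags$weight_stored) "weight")
    if (length(vals) < length(need)) {
      stop("malformed header: $RECORD_CONSTANT lists ", length(vals),
           " values, needs ", length(need))
    }
    constants <- as.list(setNames(vals[seq_along(need)], need))
  }

  if (n == 0) {
    z_plane <- if (!is.null(constants$z)) constants$z else NA_real_
    empty <- data.frame(kind = integer(), energy = numeric(), x = numeric(),
                        y = numeric(), z = numeric(), u = numeric(),
                        v = numeric(), w = numeric(), weight = numeric(),
                        new_history = logical())
    return(phsp_store(empty, z_plane = z_plane, n_original_histories = orig))
  }

  raw_all <- readBin(record_path, "raw", n = size)
  m <- matrix(raw_all, nrow = record_length)
  type <- readBin(m[1L, ], "integer", n = n, size = 1L, signed = TRUE)
  get_floats <- function(off) {
    readBin(as.vector(m[off:(off + 3L), ]), "numeric", n = n, size = 4L,
            endian = "little")
  }
  off <- 2L
  energy_raw <- get_floats(off); off <- off + 4L
  fields <- list()
  for (f in c("x", "y", "z", "u", "v")) {
    if (flags$stored[[f]]) {
      fields[[f]] <- get_floats(off); off <- off + 4L
    } else {
      fields[[f]] <- rep(constants[[f]], n)
    }
  }
  if (flags$weight_stored) {
    fields$weight <- get_floats(off); off <- off + 4L
  } else {
    fields$weight <- rep(constants$weight, n)
  }
  xf <- xl <- NULL
  if (flags$n_extra_float) {
    xf <- vapply(seq_len(flags$n_extra_float), function(j) {
      v <- get_floats(off + 4L * (j - 1L)); v
    }, numeric(n))
    off <- off + 4L * flags$n_extra_float
    if (n == 1) xf <- matrix(xf, nrow = 1)
  }
  if (flags$n_extra_long) {
    xl <- vapply(seq_len(flags$n_extra_long), function(j) {
      readBin(as.vector(m[(off + 4 * (j - 1)):(off + 4 * j - 1), ]),
              "integer", n = n, size = 4L, endian = "little")
    }, integer(n))
    if (n == 1) xl <- matrix(xl, nrow = 1)
  }

  w_abs <- sqrt(pmax(0, 1 - fields$u^2 - fields$v^2))
  particles <- data.frame(
    kind = abs(type),
    energy = abs(energy_raw),
    x = fields$x, y = fields$y, z = fields$z,
    u = fields$u, v = fields$v,
    w = w_abs * ifelse(type < 0, -1, 1),
    weight = fields$weight,
    new_history = energy_raw < 0
  )
  z_plane <- if (!flags$stored[["z"]]) constants$z else particles$z[[1]]
  store <- phsp_store(particles, z_plane = z_plane,
                      n_original_histories = orig, validate = FALSE)
  if (!is.null(xf)) attr(store, "iaea_extra_floats") <- xf
  if (!is.null(xl)) attr(store, "iaea_extra_longs") <- xl
  store
}
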