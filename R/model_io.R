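EVHM_VERSION <- 1L

#' Save and load Potts models
#'
#' The `.evhm` container is a single file holding a one-line JSON header
#' (format tag, version, `L`, `q`, alphabet, index map, target sequence and
#' metadata, plus the expected payload length) followed by the model arrays
#' as little-endian IEEE-754 float64: first `h` (length `L*q`), then `J`
#' (length `L^2*q^2`), both in R column-major order. The round trip is
#' bit-exact.
#'
#' @param model an [potts_model()].
#' @param path file path (conventionally `*.evhm`).
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the restored `evh_potts`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "evh_potts"))
  header <- jsonlite::toJSON(list(
    format = "evhm", version = EVHM_VERSION,
    L = model$L, q = model$q, alphabet = model$alphabet,
    index_map = model$index_map,
    target_seq = model$target_seq,
    metadata = model$metadata,
    payload_doubles = model$L * model$q + model$L^2 * model$q^2
  ), auto_unbox = TRUE, null = "null", digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, "\n")), con)
  writeBin(as.vector(model$h), con, size = 8L, endian = "little")
  writeBin(as.vector(model$J), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == as.raw(0x0A))[1]
  if (is.na(nl)) stop("not an .evhm file: no header line found", call. = FALSE)
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(raw[seq_len(nl - 1L)]), simplifyVector = TRUE),
    error = function(e)
      stop("not an .evhm file: header is not valid JSON", call. = FALSE))
  if (!identical(header$format, "evhm"))
    stop("not an .evhm file: header format tag is '", header$format, "'",
         call. = FALSE)
  if (header$version != EVHM_VERSION)
    stop("model file version ", header$version,
         " is not supported by this reader (version ", EVHM_VERSION, ")",
         call. = FALSE)
  L <- header$L; q <- header$q
  expected <- header$payload_doubles
  payload <- raw[-seq_len(nl)]
  if (length(payload) != 8L * expected)
    stop("truncated or corrupt .evhm payload: expected ", 8L * expected,
         " bytes, found ", length(payload), call. = FALSE)
  vals <- readBin(payload, "double", n = expected, size = 8L, endian = "little")
  h <- matrix(vals[seq_len(L * q)], L, q)
  J <- array(vals[-seq_len(L * q)], dim = c(L, L, q, q))
  md <- header$metadata
  if (is.null(md)) md <- list()
  potts_model(h, J, alphabet = header$alphabet,
              index_map = header$index_map,
              target_seq = if (is.null(header$target_seq)) NULL
                           else as.integer(header$target_seq),
              metadata = md, enforce = FALSE)
}
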