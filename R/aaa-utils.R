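#' @useDynLib siftsmapper, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
NULL

# three-letter -> one-letter codes for the 20 standard amino acids
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

AA_LETTERS <- c(unname(AA3TO1), "X")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_aa_string <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop(sprintf("%s must be a non-empty string", what), call. = FALSE)
  bad <- setdiff(strsplit(seq, "")[[1]], AA_LETTERS)
  if (length(bad))
    stop(sprintf("%s contains non-amino-acid letters: %s", what,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  invisible(seq)
}

# gzip magic bytes 1f 8b, regardless of file extension
is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

read_text_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    if (is_gzip(source)) {
      con <- gzfile(source, "rt")
      on.exit(close(con))
      readLines(con, warn = FALSE)
    } else {
      readLines(source, warn = FALSE)
    }
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
}

# two/three-column tab-separated key-value tables (taxonomy, annotation, xref)
read_kv_tsv <- function(path, value_name, integer_value = TRUE) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 2L)
    stop(sprintf("expected >= 2 tab-separated columns in %s", path),
         call. = FALSE)
  out <- dt[, 1:2]
  data.table::setnames(out, c("key", value_name))
  if (integer_value) out[[value_name]] <- as.integer(out[[value_name]])
  out
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <- env$BLOSUM62
      storage.mode(m) <- "integer"
      cache <<- m
    }
    cache
  }
})
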