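# Focused PDBx/mmCIF reader/writer.
#
# Covers the subset of the STAR grammar that PDBx/mmCIF data files use:
# one data block, key-value items, loop_ tables, '...'/"..." quoting and
# semicolon text fields. Unknown ('?') and inapplicable ('.') values both
# read as NA; the writer emits NA as '?' and the empty string as '.'.
# Embedded quote characters followed by non-whitespace (legal in full CIF)
# are not supported.

mmcif_parse_error <- function(msg, category = NULL) {
  stop(structure(class = c("mmcif_parse_error", "error", "condition"),
                 list(message = if (is.null(category)) msg else
                   sprintf("%s (category %s)", msg, category),
                   call = NULL)))
}

tokenize_cif_line <- function(line) {
  out <- character(0)
  pos <- 1L
  n <- nchar(line)
  while (pos <= n) {
    while (pos <= n && substr(line, pos, pos) %in% c(" ", "\t")) pos <- pos + 1L
    if (pos > n) break
    ch <- substr(line, pos, pos)
    if (ch == "#") break
    if (ch == "'" || ch == "\"") {
      rest <- substr(line, pos + 1L, n)
      m <- regexpr(paste0(ch, "([ \t]|$)"), rest)
      if (m < 0) mmcif_parse_error(sprintf("unterminated quote in line: %s", line))
      out <- c(out, substr(rest, 1L, m - 1L))
      pos <- pos + 1L + m  # past closing quote
    } else {
      rest <- substr(line, pos, n)
      m <- regexpr("[ \t]", rest)
      tok <- if (m < 0) rest else substr(rest, 1L, m - 1L)
      out <- c(out, tok)
      pos <- pos + nchar(tok)
    }
  }
  out
}

# lines -> token stream; semicolon text fields become single tokens
cif_tokens <- function(lines) {
  toks <- vector("list", length(lines))
  k <- 0L
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      buf <- substring(line, 2L)
      i <- i + 1L
      body <- character(0)
      closed <- FALSE
      while (i <= n) {
        if (startsWith(lines[[i]], ";")) { closed <- TRUE; break }
        body <- c(body, lines[[i]])
        i <- i + 1L
      }
      if (!closed) mmcif_parse_error("unterminated text field")
      k <- k + 1L
      toks[[k]] <- structure(paste(c(buf, body), collapse = "\n"),
                             quoted = TRUE)
      i <- i + 1L
    } else {
      for (t in tokenize_cif_line(line)) {
        k <- k + 1L
        toks[[k]] <- t
      }
      i <- i + 1L
    }
  }
  toks[seq_len(k)]
}

decode_value <- function(tok) {
  if (isTRUE(attr(tok, "quoted"))) return(as.character(tok))
  if (tok == "?" || tok == ".") return(NA_character_)
  as.character(tok)
}

is_tag <- function(tok) !isTRUE(attr(tok, "quoted")) && startsWith(as.character(tok), "_")
is_kw <- function(tok, kw) !isTRUE(attr(tok, "quoted")) &&
  grepl(paste0("^", kw), as.character(tok), ignore.case = TRUE)

split_tag <- function(tag) {
  parts <- strsplit(sub("^_", "", tag), ".", fixed = TRUE)[[1]]
  if (length(parts) < 2L) mmcif_parse_error(sprintf("malformed item name %s", tag))
  c(parts[1], paste(parts[-1], collapse = "."))
}

#' Read a PDBx/mmCIF file
#'
#' @param source path to a plain or gzip-compressed mmCIF file (gzip is
#'   detected by magic bytes, not extension), or the file's text content.
#' @return object of class `mmcif`: a list with `block` (data-block name)
#'   and `categories`, a named list of character data.frames (one column per
#'   item keyword, one row per loop row; key-value categories have one row).
#' @export
read_mmcif <- function(source) {
  lines <- read_text_lines(source)
  toks <- cif_tokens(lines)
  block <- NA_character_
  cats <- list()   # category -> list(items = chr, values = list of chr vectors)
  i <- 1L
  n <- length(toks)
  add_pair <- function(tag, value) {
    st <- split_tag(tag)
    cat <- st[1]; item <- st[2]
    cur <- cats[[cat]] %||% list(items = character(0), values = list())
    cur$items <- c(cur$items, item)
    cur$values <- c(cur$values, list(value))
    cats[[cat]] <<- cur
  }
  while (i <= n) {
    tok <- toks[[i]]
    if (is_kw(tok, "data_")) {
      block <- sub("^data_", "", as.character(tok), ignore.case = TRUE)
      i <- i + 1L
    } else if (is_kw(tok, "loop_$")) {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && is_tag(toks[[i]])) {
        tags <- c(tags, as.character(toks[[i]]))
        i <- i + 1L
      }
      if (!length(tags)) mmcif_parse_error("loop_ without item names")
      vals <- list()
      while (i <= n && !is_tag(toks[[i]]) && !is_kw(toks[[i]], "loop_$") &&
             !is_kw(toks[[i]], "data_") && !is_kw(toks[[i]], "stop_$")) {
        vals <- c(vals, list(toks[[i]]))
        i <- i + 1L
      }
      cat <- split_tag(tags[1])[1]
      if (length(vals) %% length(tags) != 0L)
        mmcif_parse_error(sprintf("loop value count %d not a multiple of %d items",
                                  length(vals), length(tags)), cat)
      nr <- length(vals) %/% length(tags)
      decoded <- vapply(vals, decode_value, character(1))
      for (k in seq_along(tags)) {
        st <- split_tag(tags[k])
        if (st[1] != cat)
          mmcif_parse_error("loop mixes categories", cat)
        col <- decoded[seq(k, by = length(tags), length.out = nr)]
        cur <- cats[[cat]] %||% list(items = character(0), values = list())
        cur$items <- c(cur$items, st[2])
        cur$values <- c(cur$values, list(col))
        cats[[cat]] <- cur
      }
    } else if (is_tag(tok)) {
      if (i + 1L > n) mmcif_parse_error(sprintf("item %s has no value", tok))
      add_pair(as.character(tok), decode_value(toks[[i + 1L]]))
      i <- i + 2L
    } else {
      mmcif_parse_error(sprintf("unexpected token '%s'", as.character(tok)))
    }
  }
  categories <- lapply(cats, function(cur) {
    nr <- max(lengths(cur$values))
    if (any(lengths(cur$values) != nr))
      mmcif_parse_error("inconsistent column lengths")
    df <- as.data.frame(stats::setNames(cur$values, cur$items),
                        stringsAsFactors = FALSE, check.names = FALSE,
                        optional = TRUE)
    df
  })
  structure(list(block = block, categories = categories), class = "mmcif")
}

needs_quote <- function(v) {
  is.na(v) | v == "" | grepl("[ \t']", v) | grepl("^[_#$\\[\\]]", v) |
    grepl("^(data_|loop_|stop_|global_)", v, ignore.case = TRUE) |
    v %in% c(".", "?")
}

format_cif_value <- function(v) {
  if (is.na(v)) return("?")
  if (v == "") return(".")
  if (grepl("\n", v)) return(paste0("\n;", v, "\n;"))
  if (grepl("'", v)) return(paste0("\"", v, "\""))
  if (needs_quote(v)) return(paste0("'", v, "'"))
  v
}

#' Write a PDBx/mmCIF object to a file
#'
#' Categories with one row are written as key-value pairs; multi-row
#' categories as `loop_` tables. Category order is preserved.
#'
#' @param x an `mmcif` object (see [read_mmcif()])
#' @param path output path; `.gz` suffix triggers gzip compression
#' @return `path`, invisibly
#' @export
write_mmcif <- function(x, path) {
  out <- format_mmcif_lines(x)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

format_mmcif_lines <- function(x) {
  stopifnot(inherits(x, "mmcif"))
  out <- c(sprintf("data_%s", x$block %||% "block"), "#")
  for (cat in names(x$categories)) {
    df <- x$categories[[cat]]
    if (nrow(df) == 1L) {
      tags <- sprintf("_%s.%s", cat, names(df))
      w <- max(nchar(tags))
      for (k in seq_along(df)) {
        val <- format_cif_value(df[[k]][1])
        if (startsWith(val, "\n")) {
          out <- c(out, sprintf("%s%s", formatC(tags[k], width = -w), val))
        } else {
          out <- c(out, sprintf("%s %s", formatC(tags[k], width = -w), val))
        }
      }
    } else {
      out <- c(out, "loop_", sprintf("_%s.%s", cat, names(df)))
      if (nrow(df) > 0L) {
        cols <- lapply(df, function(col) vapply(col, format_cif_value, character(1)))
        any_multi <- any(vapply(cols, function(cc) any(grepl("\n", cc, fixed = TRUE)),
                                logical(1)))
        if (!any_multi) {
          out <- c(out, do.call(paste, c(cols, sep = " ")))
        } else {
          for (r in seq_len(nrow(df))) {
            vals <- vapply(cols, `[[`, character(1), r)
            line <- character(0)
            for (v in vals) {
              if (grepl("\n", v, fixed = TRUE)) {
                if (length(line)) { out <- c(out, paste(line, collapse = " ")); line <- character(0) }
                out <- c(out, sub("^\n", "", v))
              } else line <- c(line, v)
            }
            if (length(line)) out <- c(out, paste(line, collapse = " "))
          }
        }
      }
    }
    out <- c(out, "#")
  }
  out
}

mmcif_category <- function(x, name) x$categories[[name]]
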