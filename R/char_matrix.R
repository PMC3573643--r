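#' Discrete character matrix
#'
#' Container for taxa x discrete-character data as used in morphological
#' phylogenetics. Each cell is a set of one or more non-negative integer
#' states (polymorphic cells have two or more), or is missing (`?`) or
#' inapplicable (`-`). Inapplicable cells are kept as a distinct class for
#' reporting but are treated exactly like missing cells by every step and
#' likelihood computation.
#'
#' @param states list-matrix (taxa x characters) whose elements are integer
#'   vectors of states; use `NA_integer_` for missing/inapplicable cells.
#' @param taxa taxon labels (rownames).
#' @param cell_class character matrix with entries in
#'   `c("obs", "polymorphic", "missing", "inapplicable")`; derived from
#'   `states` when omitted (all NA cells become `"missing"`).
#' @param ordered logical per character: additive (ordered) coding.
#' @param weight non-negative numeric per character.
#' @param class character partition/class label per character.
#' @return An object of class `char_matrix`.
#' @export
char_matrix <- function(states, taxa = rownames(states), cell_class = NULL,
                        ordered = FALSE, weight = 1, class = "all") {
  stopifnot(is.matrix(states), is.list(states))
  ntax <- nrow(states); nchar <- ncol(states)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(ntax))
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  if (is.null(cell_class)) {
    cell_class <- matrix("obs", ntax, nchar)
    for (i in seq_len(ntax)) for (j in seq_len(nchar)) {
      s <- states[[i, j]]
      if (length(s) == 1L && is.na(s)) cell_class[i, j] <- "missing"
      else if (length(s) >= 2L) cell_class[i, j] <- "polymorphic"
    }
  }
  bad <- which(!cell_class %in% c("obs", "polymorphic", "missing", "inapplicable"))
  if (length(bad)) stop("invalid cell_class entries")
  for (i in seq_len(ntax)) for (j in seq_len(nchar)) {
    s <- states[[i, j]]
    if (!(length(s) == 1L && is.na(s))) {
      if (any(s < 0)) stop("states must be non-negative integers")
      states[[i, j]] <- sort(unique(as.integer(s)))
    } else states[[i, j]] <- NA_integer_
  }
  info <- data.frame(
    index = seq_len(nchar),
    ordered = rep_len(as.logical(ordered), nchar),
    weight = rep_len(as.numeric(weight), nchar),
    class = rep_len(as.character(class), nchar),
    stringsAsFactors = FALSE
  )
  if (any(info$weight < 0)) stop("character weights must be non-negative")
  rownames(states) <- taxa
  rownames(cell_class) <- taxa
  structure(list(states = states, taxa = taxa, cell_class = cell_class,
                 info = info), class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("char_matrix: %d taxa x %d characters (%d ordered)\n",
              length(x$taxa), nrow(x$info), sum(x$info$ordered)))
  cat(sprintf("  missing %.1f%% | inapplicable %.1f%% | polymorphic %.1f%%\n",
              100 * s$missing_frac, 100 * s$inapplicable_frac,
              100 * s$polymorphic_frac))
  invisible(x)
}

#' @export
summary.char_matrix <- function(object, ...) {
  cc <- object$cell_class
  n <- length(cc)
  list(n_taxa = length(object$taxa), n_char = nrow(object$info),
       missing_frac = sum(cc == "missing") / n,
       inapplicable_frac = sum(cc == "inapplicable") / n,
       polymorphic_frac = sum(cc == "polymorphic") / n)
}

# Cells usable in computations: observed or polymorphic.
is_scored <- function(cm, j) cm$cell_class[, j] %in% c("obs", "polymorphic")

#' Read a NEXUS characters block
#'
#' Parses a NEXUS `CHARACTERS` or `DATA` block into a [char_matrix()].
#' Supports `?` (missing), the gap symbol (default `-`, read as
#' inapplicable), and polymorphic cells written `(01)` or `{01}`. Comments in
#' square brackets are stripped. Interleaved matrices are handled by
#' accumulating rows per taxon. Character ordering flags, weights and class
#' labels are attached from an optional sidecar table (NEXUS assumptions
#' dialects vary too much to parse reliably); see [read_character_info()].
#'
#' @param text NEXUS file contents as a single string, or a file path.
#' @param info optional data frame as returned by [read_character_info()].
#' @return A `char_matrix`. The missing/polymorphic cell census is available
#'   via `summary()`.
#' @export
read_character_matrix <- function(text, info = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  text <- paste(text, collapse = "\n")
  text <- gsub("\\[[^]]*\\]", " ", text)  # strip NEXUS comments
  if (!grepl("#NEXUS", text, ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header)")
  blk <- regmatches(text, regexpr(
    "(?is)begin\\s+(characters|data)\\s*;.*?end\\s*;", text, perl = TRUE))
  if (!length(blk)) stop("no CHARACTERS or DATA block found")
  blk <- blk[[1]]

  dim_m <- regmatches(blk, regexpr("(?i)dimensions[^;]*;", blk, perl = TRUE))
  ntax <- as.integer(sub(".*(?i)ntax\\s*=\\s*(\\d+).*", "\\1", dim_m, perl = TRUE))
  nchr <- as.integer(sub(".*(?i)nchar\\s*=\\s*(\\d+).*", "\\1", dim_m, perl = TRUE))
  if (is.na(ntax) || is.na(nchr)) stop("DIMENSIONS must give NTAX and NCHAR")

  miss_sym <- "?"; gap_sym <- "-"; symbols <- strsplit("0123456789", "")[[1]]
  fmt_m <- regmatches(blk, regexpr("(?i)format[^;]*;", blk, perl = TRUE))
  if (length(fmt_m)) {
    fmt <- fmt_m[[1]]
    g <- regmatches(fmt, regexec("(?i)missing\\s*=\\s*(\\S)", fmt, perl = TRUE))[[1]]
    if (length(g) == 2) miss_sym <- g[2]
    g <- regmatches(fmt, regexec("(?i)gap\\s*=\\s*(\\S)", fmt, perl = TRUE))[[1]]
    if (length(g) == 2) gap_sym <- g[2]
    g <- regmatches(fmt, regexec("(?i)symbols\\s*=\\s*\"([^\"]*)\"", fmt, perl = TRUE))[[1]]
    if (length(g) == 2) symbols <- setdiff(strsplit(g[2], "")[[1]], " ")
  }
  state_of <- function(ch) {
    k <- match(ch, symbols)
    if (is.na(k)) return(NA_integer_)
    # digits keep their face value; other symbols follow their SYMBOLS rank
    if (grepl("[0-9]", ch)) as.integer(ch) else k - 1L
  }

  mat_m <- regmatches(blk, regexpr("(?is)matrix(.*?);", blk, perl = TRUE))
  if (!length(mat_m)) stop("no MATRIX statement found")
  body <- sub("(?is)^matrix", "", mat_m[[1]], perl = TRUE)
  body <- sub(";\\s*$", "", body)
  lines <- strsplit(body, "\n")[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  taxa <- character(0)
  rows <- list()
  for (ln in lines) {
    m <- regexec("^('[^']+'|\\S+)\\s+(.*)$", ln)
    parts <- regmatches(ln, m)[[1]]
    if (length(parts) != 3) stop("cannot parse matrix row: ", ln)
    tx <- gsub("^'|'$", "", parts[2])
    cells <- parse_cell_run(parts[3])
    if (!tx %in% taxa) { taxa <- c(taxa, tx); rows[[tx]] <- cells }
    else rows[[tx]] <- c(rows[[tx]], cells)
  }
  if (length(taxa) != ntax)
    stop(sprintf("matrix has %d taxa, DIMENSIONS says %d", length(taxa), ntax))

  states <- matrix(list(), ntax, nchr, dimnames = list(taxa, NULL))
  cls <- matrix("obs", ntax, nchr)
  for (i in seq_along(taxa)) {
    cells <- rows[[taxa[i]]]
    if (length(cells) != nchr)
      stop(sprintf("taxon '%s' has %d characters, expected %d",
                   taxa[i], length(cells), nchr))
    for (j in seq_len(nchr)) {
      toks <- cells[[j]]
      if (length(toks) == 1L && toks == miss_sym) {
        states[[i, j]] <- NA_integer_; cls[i, j] <- "missing"
      } else if (length(toks) == 1L && toks == gap_sym) {
        states[[i, j]] <- NA_integer_; cls[i, j] <- "inapplicable"
      } else {
        st <- vapply(toks, state_of, integer(1))
        if (anyNA(st))
          stop(sprintf("undeclared symbol '%s' at taxon '%s', character %d",
                       paste(toks[is.na(st)], collapse = ""), taxa[i], j))
        states[[i, j]] <- sort(unique(st))
        if (length(st) >= 2L) cls[i, j] <- "polymorphic"
      }
    }
  }
  cm <- char_matrix(states, taxa = taxa, cell_class = cls)
  if (!is.null(info)) cm <- apply_character_info(cm, info)
  cm
}

# Split a character-row string into a list of cells; each cell is a
# character vector of symbols ("(01)" -> c("0","1")).
parse_cell_run <- function(s) {
  s <- gsub("\\s+", "", s)
  chars <- strsplit(s, "")[[1]]
  cells <- list(); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "{")) {
      close <- if (ch == "(") ")" else "}"
      jj <- i + 1L; grp <- character(0)
      while (jj <= length(chars) && chars[jj] != close) {
        if (chars[jj] != ",") grp <- c(grp, chars[jj]); jj <- jj + 1L
      }
      if (jj > length(chars)) stop("unterminated polymorphism group")
      cells[[length(cells) + 1L]] <- grp
      i <- jj + 1L
    } else {
      cells[[length(cells) + 1L]] <- ch
      i <- i + 1L
    }
  }
  cells
}

#' Write a character matrix as NEXUS
#'
#' @param cm A `char_matrix`.
#' @param file Optional path; when `NULL` the NEXUS text is returned.
#' @export
write_character_matrix <- function(cm, file = NULL) {
  ntax <- length(cm$taxa); nchr <- nrow(cm$info)
  syms <- sort(unique(unlist(cm$states)))
  syms <- syms[!is.na(syms)]
  sym_str <- paste(syms, collapse = " ")
  rows <- vapply(seq_len(ntax), function(i) {
    cells <- vapply(seq_len(nchr), function(j) {
      cl <- cm$cell_class[i, j]
      if (cl == "missing") return("?")
      if (cl == "inapplicable") return("-")
      s <- cm$states[[i, j]]
      if (length(s) == 1L) as.character(s)
      else paste0("(", paste(s, collapse = ""), ")")
    }, character(1))
    sprintf("  %-12s %s", gsub(" ", "_", cm$taxa[i]), paste(cells, collapse = ""))
  }, character(1))
  txt <- c("#NEXUS", "BEGIN CHARACTERS;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", ntax, nchr),
           sprintf("  FORMAT MISSING=? GAP=- SYMBOLS=\"%s\";", sym_str),
           "  MATRIX", rows, "  ;", "END;")
  txt <- paste(txt, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read the character-info sidecar table
#'
#' Tab-separated with header; columns `index` (1-based character index),
#' `ordered` (TRUE/FALSE), optional `weight` and `class`.
#'
#' @param path file path or a data frame already in this layout.
#' @return data frame with columns index, ordered, weight, class.
#' @export
read_character_info <- function(path) {
  df <- if (is.data.frame(path)) path
        else utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("index", "ordered") %in% names(df)))
    stop("sidecar must have columns 'index' and 'ordered'")
  if (is.null(df$weight)) df$weight <- 1
  if (is.null(df$class)) df$class <- "all"
  df$ordered <- as.logical(df$ordered)
  df
}

#' Attach ordering flags, weights and class labels to a matrix
#'
#' @param cm A `char_matrix`.
#' @param info data frame from [read_character_info()].
#' @export
apply_character_info <- function(cm, info) {
  info <- read_character_info(info)
  if (any(info$index < 1 | info$index > nrow(cm$info)))
    stop("sidecar character index out of range")
  k <- info$index
  cm$info$ordered[k] <- info$ordered
  cm$info$weight[k] <- info$weight
  cm$info$class[k] <- info$class
  cm
}
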