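#' Sequence alignment with a partition map
#'
#' A light container: taxa x sites character matrix over
#' `{A,C,G,T,-,?}` plus IUPAC ambiguity codes, and a total site-to-partition
#' map. Every site belongs to exactly one named partition; partitions can be
#' flagged excluded without being dropped.
#'
#' @param seqs character matrix (taxa x sites) of upper-case residues.
#' @param taxa taxon labels.
#' @param partition integer vector (one entry per site) of partition ids, or
#'   `NULL` for a single partition named `"all"`.
#' @param partition_names names of the partitions (ids index into this).
#' @param type `"nucleotide"` or `"codon"`. Codon alignments must have length
#'   divisible by 3 and no internal stop codons under `code`.
#' @param code genetic code for codon alignments: `"vertebrate_mt"` or
#'   `"universal"`.
#' @return An object of class `seq_alignment`.
#' @export
seq_alignment <- function(seqs, taxa = rownames(seqs), partition = NULL,
                          partition_names = NULL,
                          type = c("nucleotide", "codon"),
                          code = c("vertebrate_mt", "universal")) {
  type <- match.arg(type); code <- match.arg(code)
  stopifnot(is.matrix(seqs), is.character(seqs))
  seqs <- toupper(seqs)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(seqs)))
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  ns <- ncol(seqs)
  if (is.null(partition)) {
    partition <- rep.int(1L, ns); partition_names <- "all"
  }
  if (length(partition) != ns)
    stop("partition map must cover every site exactly once")
  if (anyNA(partition)) {
    miss <- which(is.na(partition))
    stop("sites not covered by any partition: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  if (is.null(partition_names))
    partition_names <- paste0("p", sort(unique(partition)))
  if (type == "codon") {
    if (ns %% 3L != 0L)
      stop("codon alignment length ", ns, " is not divisible by 3")
    check_stop_codons(seqs, code)
  }
  rownames(seqs) <- taxa
  structure(list(seqs = seqs, taxa = taxa, partition = as.integer(partition),
                 partition_names = partition_names, type = type, code = code),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment (%s): %d taxa x %d sites, %d partition(s)\n",
              x$type, length(x$taxa), ncol(x$seqs), length(x$partition_names)))
  tb <- table(factor(x$partition_names[x$partition], levels = x$partition_names))
  for (nm in names(tb)) cat(sprintf("  %-20s %d sites\n", nm, tb[[nm]]))
  invisible(x)
}

#' Sites belonging to a partition
#' @param aln A `seq_alignment`.
#' @param name Partition name (or integer id).
#' @return Integer vector of site indices.
#' @export
partition_sites <- function(aln, name) {
  id <- if (is.numeric(name)) as.integer(name) else match(name, aln$partition_names)
  if (is.na(id)) stop("unknown partition: ", name)
  which(aln$partition == id)
}

check_stop_codons <- function(seqs, code) {
  stops <- genetic_code(code)$stops
  nc <- ncol(seqs) / 3L
  for (i in seq_len(nrow(seqs))) {
    cod <- vapply(seq_len(nc), function(k)
      paste(seqs[i, (3 * k - 2):(3 * k)], collapse = ""), character(1))
    bad <- which(cod %in% stops)
    if (length(bad))
      stop(sprintf("internal stop codon '%s' at codon %d in taxon '%s'",
                   cod[bad[1]], bad[1], rownames(seqs)[i]))
  }
  invisible(TRUE)
}

#' Read a sequence alignment
#'
#' Readers for the three interchange formats used throughout: FASTA, NEXUS
#' (`DATA`/`CHARACTERS` block with `DATATYPE=DNA`), and relaxed PHYLIP
#' (header `ntax nsites`, then `name sequence` records, whitespace inside
#' sequences allowed). A partition configuration (see
#' [read_partition_config()]) may be supplied; otherwise all sites form one
#' partition.
#'
#' @param text file path or file contents.
#' @param format one of `"fasta"`, `"nexus"`, `"phylip"`.
#' @param partitions optional partition config (path, text, or parsed list).
#' @param type,code passed to [seq_alignment()].
#' @return A `seq_alignment`.
#' @export
read_alignment <- function(text, format = c("fasta", "nexus", "phylip"),
                           partitions = NULL, type = "nucleotide",
                           code = "vertebrate_mt") {
  format <- match.arg(format)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  text <- paste(text, collapse = "\n")
  rec <- switch(format,
    fasta = parse_fasta(text),
    nexus = parse_nexus_dna(text),
    phylip = parse_relaxed_phylip(text))
  lens <- lengths(rec$seqs)
  if (length(unique(lens)) != 1L)
    stop("unequal sequence lengths: ", paste(unique(lens), collapse = ", "))
  seqs <- do.call(rbind, rec$seqs)
  rownames(seqs) <- rec$taxa
  part <- NULL; pnames <- NULL
  if (!is.null(partitions)) {
    cfg <- read_partition_config(partitions, n_sites = ncol(seqs))
    part <- cfg$map; pnames <- cfg$names
  }
  seq_alignment(seqs, taxa = rec$taxa, partition = part,
                partition_names = pnames, type = type, code = code)
}

parse_fasta <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers found")
  taxa <- sub("^>\\s*", "", lines[hdr])
  taxa <- sub("\\s.*$", "", taxa)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- lapply(seq_along(hdr), function(k) {
    s <- paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
    strsplit(toupper(gsub("\\s", "", s)), "")[[1]]
  })
  list(taxa = taxa, seqs = seqs)
}

parse_relaxed_phylip <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  ntax <- as.integer(hd[1]); nsite <- as.integer(hd[2])
  if (is.na(ntax) || is.na(nsite)) stop("bad PHYLIP header")
  taxa <- character(0); seqs <- list(); cur <- 0L
  for (ln in lines[-1]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (cur < ntax && length(parts) >= 2) {
      cur <- cur + 1L
      taxa[cur] <- parts[1]
      seqs[[cur]] <- strsplit(toupper(paste(parts[-1], collapse = "")), "")[[1]]
    } else {
      # continuation lines wrap onto the last started sequence
      seqs[[cur]] <- c(seqs[[cur]],
                       strsplit(toupper(paste(parts, collapse = "")), "")[[1]])
    }
  }
  if (length(taxa) != ntax) stop("PHYLIP: expected ", ntax, " taxa")
  if (any(lengths(seqs) != nsite))
    stop("PHYLIP: sequence length disagrees with header")
  list(taxa = taxa, seqs = seqs)
}

parse_nexus_dna <- function(text) {
  text <- gsub("\\[[^]]*\\]", " ", text)
  blk <- regmatches(text, regexpr(
    "(?is)begin\\s+(characters|data)\\s*;.*?end\\s*;", text, perl = TRUE))
  if (!length(blk)) stop("no DATA/CHARACTERS block found")
  blk <- blk[[1]]
  mat_m <- regmatches(blk, regexpr("(?is)matrix(.*?);", blk, perl = TRUE))
  if (!length(mat_m)) stop("no MATRIX statement found")
  body <- sub("(?is)^matrix", "", mat_m[[1]], perl = TRUE)
  body <- sub(";\\s*$", "", body)
  lines <- trimws(strsplit(body, "\n")[[1]])
  lines <- lines[nzchar(lines)]
  taxa <- character(0); seqs <- list()
  for (ln in lines) {
    parts <- regmatches(ln, regexec("^('[^']+'|\\S+)\\s+(\\S+)$", ln))[[1]]
    if (length(parts) != 3) stop("cannot parse NEXUS matrix row: ", ln)
    tx <- gsub("^'|'$", "", parts[2])
    chunk <- strsplit(toupper(parts[3]), "")[[1]]
    if (tx %in% taxa) seqs[[tx]] <- c(seqs[[tx]], chunk)
    else { taxa <- c(taxa, tx); seqs[[tx]] <- chunk }
  }
  list(taxa = taxa, seqs = seqs[taxa])
}

#' Write an alignment
#'
#' @param aln A `seq_alignment`.
#' @param format `"fasta"`, `"nexus"`, or `"phylip"`.
#' @param file optional path; when `NULL` the text is returned.
#' @export
write_alignment <- function(aln, format = c("fasta", "nexus", "phylip"),
                            file = NULL) {
  format <- match.arg(format)
  rows <- apply(aln$seqs, 1, paste, collapse = "")
  txt <- switch(format,
    fasta = paste(rbind(paste0(">", aln$taxa), rows), collapse = "\n"),
    phylip = paste(c(sprintf("%d %d", length(aln$taxa), ncol(aln$seqs)),
                     sprintf("%s  %s", aln$taxa, rows)), collapse = "\n"),
    nexus = paste(c("#NEXUS", "BEGIN DATA;",
                    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                            length(aln$taxa), ncol(aln$seqs)),
                    "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
                    "  MATRIX",
                    sprintf("  %-12s %s", gsub(" ", "_", aln$taxa), rows),
                    "  ;", "END;"), collapse = "\n"))
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Parse a partition configuration
#'
#' RAxML-style definitions, one per line: `name = ranges` where ranges are
#' comma-separated `a-b`, `a-b\3` (every third site, codon-position style),
#' or single indices. Indices are 1-based inclusive. Sites not claimed by any
#' definition are collected into a trailing `rest` partition. Overlapping
#' definitions are an error.
#'
#' @param x path, config text, or a named list of integer site vectors.
#' @param n_sites total number of sites in the alignment.
#' @return list with `map` (integer per site) and `names`.
#' @export
read_partition_config <- function(x, n_sites) {
  if (is.list(x) && !is.data.frame(x)) {
    sets <- x
  } else {
    if (length(x) == 1L && !grepl("\n|=", x) && file.exists(x))
      x <- paste(readLines(x, warn = FALSE), collapse = "\n")
    lines <- trimws(strsplit(paste(x, collapse = "\n"), "\n")[[1]])
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    sets <- list()
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("bad partition line: ", ln)
      nm <- trimws(kv[1])
      nm <- sub("^DNA,\\s*", "", nm)  # tolerate RAxML 'DNA, name' prefixes
      sets[[nm]] <- parse_site_ranges(trimws(kv[2]), n_sites)
    }
  }
  map <- rep.int(NA_integer_, n_sites)
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    if (any(s < 1 | s > n_sites))
      stop("partition '", names(sets)[k], "' has sites outside 1..", n_sites)
    clash <- s[!is.na(map[s])]
    if (length(clash))
      stop("partitions overlap at sites: ",
           paste(utils::head(clash, 10), collapse = ", "))
    map[s] <- k
  }
  nms <- names(sets)
  if (anyNA(map)) {
    nms <- c(nms, "rest")
    map[is.na(map)] <- length(nms)
  }
  list(map = map, names = nms)
}

parse_site_ranges <- function(spec, n_sites) {
  out <- integer(0)
  for (tok in trimws(strsplit(spec, ",")[[1]])) {
    m <- regmatches(tok, regexec("^(\\d+)-(\\d+)(\\\\(\\d+))?$", tok))[[1]]
    if (length(m)) {
      a <- as.integer(m[2]); b <- as.integer(m[3])
      by <- if (nzchar(m[4])) as.integer(m[5]) else 1L
      out <- c(out, seq.int(a, b, by = by))
    } else if (grepl("^\\d+$", tok)) {
      out <- c(out, as.integer(tok))
    } else stop("bad site range: ", tok)
  }
  sort(unique(out))
}

#' Translate a codon alignment to amino acids
#'
#' @param aln codon `seq_alignment`.
#' @return character matrix (taxa x codon sites) of one-letter amino acids;
#'   codons containing gaps or ambiguities become `"X"`.
#' @export
translate_codons <- function(aln) {
  stopifnot(aln$type == "codon")
  gc <- genetic_code(aln$code)
  nc <- ncol(aln$seqs) / 3L
  aa <- matrix("X", length(aln$taxa), nc, dimnames = list(aln$taxa, NULL))
  for (i in seq_len(nrow(aa))) for (k in seq_len(nc)) {
    cod <- paste(aln$seqs[i, (3 * k - 2):(3 * k)], collapse = "")
    hit <- gc$table[[cod]]
    if (!is.null(hit)) aa[i, k] <- hit
  }
  aa
}
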