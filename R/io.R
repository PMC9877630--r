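#' Read a sequence record from FASTA or GenBank
#'
#' FASTA parsing is delegated to Biostrings; GenBank flat files are parsed
#' with a small reader that understands the LOCUS topology flag, simple
#' `misc_feature` locations (`a..b` and `complement(a..b)`) with `/label`
#' qualifiers, and the ORIGIN block. GenBank coordinates (1-based,
#' inclusive) are converted to the package's 0-based half-open convention
#' at this boundary.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"fasta"` or `"genbank"`.
#' @param topology Override for FASTA input, which carries no topology;
#'   defaults to linear.
#' @return A [dna_record()] (the first record, if the file holds several;
#'   use [read_records()] for all of them).
#' @export
read_record <- function(path, format = c("auto", "fasta", "genbank"),
                        topology = NULL) {
  read_records(path, format, topology)[[1L]]
}

#' @rdname read_record
#' @export
read_records <- function(path, format = c("auto", "fasta", "genbank"),
                         topology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "fasta") {
    if (file.size(path) == 0L)
      stop("parse error: empty FASTA file '", path, "'", call. = FALSE)
    set <- tryCatch(Biostrings::readDNAStringSet(path),
                    error = function(e) stop("parse error in '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
    if (!length(set))
      stop("parse error: no sequences in '", path, "'", call. = FALSE)
    topo <- if (is.null(topology)) "linear" else topology
    ids <- sub("\\s.*$", "", names(set))
    lapply(seq_along(set), function(i)
      dna_record(as.character(set[[i]]), ids[i], topo))
  } else {
    .read_genbank(path)
  }
}

.read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(lines)))
    stop("parse error: empty GenBank file '", path, "'", call. = FALSE)
  starts <- grep("^LOCUS", lines)
  if (!length(starts))
    stop("parse error in '", path, "': no LOCUS line (line 1: '",
         if (length(lines)) lines[1] else "", "')", call. = FALSE)
  ends <- grep("^//", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    .parse_genbank_block(block, path, starts[i])
  })
}

.parse_genbank_block <- function(block, path, offset) {
  locus <- strsplit(trimws(block[1]), "\\s+")[[1]]
  if (length(locus) < 2)
    stop("parse error in '", path, "' line ", offset,
         ": malformed LOCUS line", call. = FALSE)
  id <- locus[2]
  topo <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  ori <- grep("^ORIGIN", block)
  if (!length(ori))
    stop("parse error in '", path, "': no ORIGIN block for '", id, "'",
         call. = FALSE)
  seq_lines <- block[(ori[1] + 1):length(block)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(seq))
    stop("parse error in '", path, "': empty ORIGIN block for '", id, "'",
         call. = FALSE)

  feats <- .empty_features()
  fstart <- grep("^FEATURES", block)
  if (length(fstart)) {
    flines <- block[(fstart[1] + 1):(ori[1] - 1)]
    cur <- NULL
    for (ln in flines) {
      m <- regmatches(ln, regexec(
        "^\\s{2,8}(\\S+)\\s+(complement\\()?<?(\\d+)\\.\\.>?(\\d+)\\)?\\s*$", ln))[[1]]
      if (length(m)) {
        if (!is.null(cur) && cur$key != "source")
          feats <- rbind(feats, cur$row)
        strand <- if (nzchar(m[3]) && grepl("complement", ln)) "-" else "+"
        cur <- list(key = m[2], row = data.frame(
          label = m[2], start = as.integer(m[4]) - 1L,
          end = as.integer(m[5]), strand = strand,
          stringsAsFactors = FALSE))
      } else if (!is.null(cur)) {
        q <- regmatches(ln, regexec("/(label|note)=\"?([^\"]+)\"?\\s*$", ln))[[1]]
        if (length(q)) cur$row$label <- q[3]
      }
    }
    if (!is.null(cur) && cur$key != "source") feats <- rbind(feats, cur$row)
  }
  dna_record(seq, id, topo, feats)
}

#' Write a sequence record to FASTA or GenBank
#'
#' Round-trips through [read_record()] reproduce residues, topology (for
#' GenBank) and features.
#'
#' @param record A [dna_record()].
#' @param path Output path.
#' @param format `"fasta"` or `"genbank"`.
#' @return The path, invisibly.
#' @export
write_record <- function(record, path, format = c("fasta", "genbank")) {
  if (!is(record, "dna_record")) stop("not a dna_record", call. = FALSE)
  if (is.character(format) && length(format) == 1 &&
      !format %in% c("fasta", "genbank"))
    stop("unknown format '", format, "' (use 'fasta' or 'genbank')",
         call. = FALSE)
  format <- match.arg(format)
  if (format == "fasta") {
    x <- Biostrings::DNAStringSet(setNames(record$seq, record$id))
    tryCatch(Biostrings::writeXStringSet(x, path),
             error = function(e) stop("cannot write '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
    return(invisible(path))
  }
  L <- record_length(record)
  lines <- c(sprintf("LOCUS       %-18s %d bp    DNA     %-8s SYN 01-JAN-2026",
                     record$id, L, record$topology),
             sprintf("DEFINITION  %s.", record$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", L))
  if (nrow(record$features)) {
    for (k in seq_len(nrow(record$features))) {
      f <- record$features[k, ]
      loc <- sprintf("%d..%d", f$start + 1L, f$end)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      lines <- c(lines,
                 sprintf("     misc_feature    %s", loc),
                 sprintf("                     /label=\"%s\"", f$label))
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(record$seq)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}
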