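#' Read a 4DN .pairs file
#'
#' Parses the `##/#` header (chromosome sizes and the `#columns:` line) and
#' the tab-separated records. Positions in .pairs files are 1-based; they are
#' kept 1-based in the returned data.frame and converted to 0-based bin
#' coordinates exactly once, at binning time.
#'
#' @param path Path to a `.pairs` (optionally gzipped) file.
#' @return A list with `records` (data.frame, columns per the `#columns`
#'   header), `chromsizes` (named integer vector), and `columns`.
#' @export
read_pairs <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  header <- character(0)
  n_head <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
    n_head <- n_head + 1L
  }
  close(con)
  cs_lines <- grep("^#chromsize:", header, value = TRUE)
  chromsizes <- NULL
  if (length(cs_lines)) {
    parts <- strsplit(sub("^#chromsize:\\s*", "", cs_lines), "\\s+")
    chromsizes <- stats::setNames(
      as.integer(vapply(parts, `[`, "", 2L)),
      vapply(parts, `[`, "", 1L))
  }
  col_line <- grep("^#columns:", header, value = TRUE)
  if (!length(col_line))
    stop("not a 4DN .pairs file: missing #columns header in ", path)
  columns <- strsplit(sub("^#columns:\\s*", "", col_line[1]), "\\s+")[[1]]
  rec <- data.table::fread(path, skip = n_head, header = FALSE, sep = "\t",
                           col.names = columns, data.table = FALSE,
                           showProgress = FALSE)
  list(records = rec, chromsizes = chromsizes, columns = columns)
}

#' Write a 4DN .pairs file
#'
#' Records are sorted by (chrom1, pos1, chrom2, pos2) and written with a
#' `## pairs format v1.0` header, `#chromsize:` lines and a `#columns:` line.
#'
#' @param records data.frame whose column names become the `#columns` header.
#'   Positions must already be 1-based.
#' @param path Output path.
#' @param chromsizes Named vector of chromosome lengths.
#' @param extra_header Optional additional comment lines (without leading #).
#' @export
write_pairs <- function(records, path, chromsizes, extra_header = character(0)) {
  ord <- order(records$chrom1, records$pos1, records$chrom2, records$pos2)
  records <- records[ord, , drop = FALSE]
  header <- c("## pairs format v1.0",
              "#shape: upper triangle",
              paste0("#", extra_header),
              sprintf("#chromsize: %s %d", names(chromsizes),
                      as.integer(chromsizes)),
              paste0("#columns: ", paste(names(records), collapse = " ")))
  header <- header[header != "#"]
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  data.table::fwrite(records, path, sep = "\t", append = TRUE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
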