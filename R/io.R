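## Readers and writers for the external formats consumed by the pipeline.
## Coordinates are 0-based half-open throughout (BED native).

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read proviral insertion sites from a BED file
#'
#' Each data line is one unique insertion. The insertion point is the BED
#' `start` coordinate; the `end` field is validated only (a warning is issued
#' when `end != start + 1`). Column 6, when present, carries the provirus
#' orientation. Records sharing the key `(chrom, pos, strand)` are merged by
#' summing their copy counts.
#'
#' @param path path to a BED3/BED6 file; `#`, `track` and `browser` lines are
#'   skipped.
#' @param copies_field 1-based index of the column holding the
#'   junction-fragment (copy) count for the insertion, or `NA` to assign one
#'   copy per record. Defaults to the BED score column (5). Missing,
#'   non-numeric or zero values in that column fall back to 1 copy.
#' @param strict if `TRUE` (default), a record with strand `"."` or a missing
#'   strand column is an error; if `FALSE` such records are kept with strand
#'   `NA` (they are ignored by orientation analyses).
#' @return a `data.frame` with columns `chrom`, `pos`, `strand`, `copies`,
#'   `id`, one row per unique insertion, carrying a `load_report` attribute
#'   (list with `n_records`, `n_unique`, `n_merged`, `n_unstranded`).
#' @export
read_insertions_bed <- function(path, copies_field = 5, strict = TRUE) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L) {
    out <- empty_insertions()
    attr(out, "load_report") <-
      list(n_records = 0L, n_unique = 0L, n_merged = 0L, n_unstranded = 0L)
    return(out)
  }
  fields <- split_fields(dat$lines)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stop("malformed BED line ", dat$lineno[bad[1]], ": fewer than 3 fields",
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED line ", dat$lineno[bad[1]],
         ": non-numeric coordinate", call. = FALSE)
  }
  bad <- which(start < 0)
  if (length(bad)) {
    stop("malformed BED line ", dat$lineno[bad[1]], ": negative start",
         call. = FALSE)
  }
  if (any(end != start + 1)) {
    warning("BED end != start + 1 for ", sum(end != start + 1),
            " record(s); the start coordinate is used as the insertion point")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                  ""), "")
  strand <- rep(NA_character_, length(fields))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  ok <- strand %in% c("+", "-")
  dot <- !ok
  if (any(dot)) {
    if (strict) {
      stop("line ", dat$lineno[which(dot)[1]],
           ": strand must be '+' or '-' (use strict = FALSE to keep ",
           "unstranded records)", call. = FALSE)
    }
    strand[dot] <- NA_character_
  }
  copies <- rep(1, length(fields))
  if (!is.na(copies_field)) {
    raw <- vapply(fields, function(f)
      if (length(f) >= copies_field) f[[copies_field]] else NA_character_, "")
    val <- suppressWarnings(as.numeric(raw))
    copies <- ifelse(is.na(val) | val < 1, 1, round(val))
  }
  df <- data.frame(chrom = chrom, pos = as.integer(start),
                   strand = strand, copies = as.integer(copies),
                   id = name, stringsAsFactors = FALSE)
  merged <- merge_insertions(df)
  attr(merged, "load_report") <- list(
    n_records = nrow(df), n_unique = nrow(merged),
    n_merged = nrow(df) - nrow(merged), n_unstranded = sum(is.na(strand)))
  merged
}

empty_insertions <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             copies = integer(), id = character(), stringsAsFactors = FALSE)
}

# Merge duplicate (chrom, pos, strand) records, summing copies. Strand NA is
# its own key level. The first id of each group is kept.
merge_insertions <- function(df) {
  if (nrow(df) == 0L) return(df)
  key <- paste(df$chrom, df$pos, ifelse(is.na(df$strand), ".", df$strand),
               sep = "\r")
  o <- order(df$chrom, df$pos, df$strand, method = "radix")
  df <- df[o, , drop = FALSE]
  key <- key[o]
  first <- !duplicated(key)
  copies <- as.integer(tapply(df$copies, key, sum)[key[first]])
  out <- df[first, , drop = FALSE]
  out$copies <- copies
  rownames(out) <- NULL
  out
}

#' Write insertion sites as BED6
#'
#' Inverse of [read_insertions_bed()]: `(chrom, pos, strand, copies)` survive
#' a write/read round trip exactly. The copy count is written to the score
#' column; unstranded records are written with strand `"."`.
#'
#' @param insertions insertion `data.frame` (see [read_insertions_bed()])
#' @param path output path
#' @export
write_insertions_bed <- function(insertions, path) {
  ins <- validate_insertions(insertions)
  id <- ins$id
  id[is.na(id) | id == ""] <- "."
  bed <- data.frame(ins$chrom, ins$pos, ins$pos + 1L, id, ins$copies,
                    ifelse(is.na(ins$strand), ".", ins$strand))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_insertions <- function(insertions) {
  need <- c("chrom", "pos", "strand", "copies")
  if (!all(need %in% names(insertions)))
    stop("insertions need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"id" %in% names(insertions)) insertions$id <- ""
  stopifnot(all(insertions$pos >= 0), all(insertions$copies >= 1))
  insertions
}

#' Read a refFlat-style gene table
#'
#' Expects a tab-separated table with at least six columns: gene id, symbol,
#' chromosome, strand (`+`/`-`), txStart, txEnd (0-based half-open). The TSS
#' is derived from the strand: `txStart` for forward genes, `txEnd - 1` for
#' reverse genes. Rows with `txStart >= txEnd` are dropped and counted in the
#' attached `load_report`.
#'
#' @param path path to the table; `#` lines are skipped.
#' @return `data.frame` with columns `gene_id`, `symbol`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `tss`.
#' @export
read_gene_table <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0L) return(empty_genes())
  fields <- split_fields(dat$lines)
  bad <- which(lengths(fields) < 6L)
  if (length(bad))
    stop("gene table line ", dat$lineno[bad[1]], ": fewer than 6 fields",
         call. = FALSE)
  g <- data.frame(
    gene_id = vapply(fields, `[[`, "", 1L),
    symbol  = vapply(fields, `[[`, "", 2L),
    chrom   = vapply(fields, `[[`, "", 3L),
    strand  = vapply(fields, `[[`, "", 4L),
    tx_start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L))),
    tx_end   = suppressWarnings(as.integer(vapply(fields, `[[`, "", 6L))),
    stringsAsFactors = FALSE)
  bad <- which(!(g$strand %in% c("+", "-")))
  if (length(bad))
    stop("gene table line ", dat$lineno[bad[1]], ": unknown strand token '",
         g$strand[bad[1]], "'", call. = FALSE)
  bad <- which(is.na(g$tx_start) | is.na(g$tx_end))
  if (length(bad))
    stop("gene table line ", dat$lineno[bad[1]], ": non-numeric coordinates",
         call. = FALSE)
  dup <- unique(g$gene_id[duplicated(g$gene_id)])
  if (length(dup))
    stop("duplicate gene_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  degenerate <- g$tx_start >= g$tx_end
  n_dropped <- sum(degenerate)
  g <- g[!degenerate, , drop = FALSE]
  g$tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end - 1L)
  rownames(g) <- NULL
  attr(g, "load_report") <- list(n_genes = nrow(g), n_dropped = n_dropped)
  g
}

empty_genes <- function() {
  data.frame(gene_id = character(), symbol = character(), chrom = character(),
             strand = character(), tx_start = integer(), tx_end = integer(),
             tss = integer(), stringsAsFactors = FALSE)
}

#' Read a chromatin-mark peak file
#'
#' Supports the ENCODE narrowPeak (10 columns) and broadPeak (9 columns)
#' dialects plus plain BED (3-6 columns). The column count is enforced per
#' dialect. The narrowPeak summit column is parsed but unused downstream.
#'
#' @param path peak file path
#' @param dialect one of `"narrowPeak"`, `"broadPeak"`, `"bed"`
#' @param mark_name label for the mark (e.g. `"H3K27ac"`); defaults to the
#'   file name without extension
#' @return `data.frame` with columns `chrom`, `start`, `end`, `score`
#'   (NA when absent), sorted by `(chrom, start)`; attributes `mark_name` and
#'   `dialect`.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "broadPeak", "bed"),
                       mark_name = NULL) {
  dialect <- match.arg(dialect)
  mark_name <- mark_name %||% sub("\\.[^.]*$", "", basename(path))
  dat <- read_data_lines(path)
  fields <- split_fields(dat$lines)
  nf <- lengths(fields)
  ok <- switch(dialect,
               narrowPeak = nf == 10L,
               broadPeak  = nf == 9L,
               bed        = nf >= 3L & nf <= 6L)
  if (any(!ok))
    stop(dialect, " line ", dat$lineno[which(!ok)[1]], ": expected ",
         switch(dialect, narrowPeak = "10", broadPeak = "9", bed = "3-6"),
         " columns, found ", nf[which(!ok)[1]], call. = FALSE)
  if (length(fields) == 0L) {
    pk <- data.frame(chrom = character(), start = integer(), end = integer(),
                     score = numeric(), stringsAsFactors = FALSE)
  } else {
    pk <- data.frame(
      chrom = vapply(fields, `[[`, "", 1L),
      start = as.integer(vapply(fields, `[[`, "", 2L)),
      end   = as.integer(vapply(fields, `[[`, "", 3L)),
      score = ifelse(nf >= 5L,
                     suppressWarnings(as.numeric(
                       vapply(fields, function(f)
                         if (length(f) >= 5L) f[[5L]] else NA_character_,
                         ""))),
                     NA_real_),
      stringsAsFactors = FALSE)
  }
  if (any(is.na(pk$start) | is.na(pk$end) | pk$start < 0 |
          pk$end <= pk$start))
    stop("invalid peak interval in ", path, call. = FALSE)
  if (any(!is.na(pk$score) & !is.finite(pk$score)))
    stop("non-finite peak score in ", path, call. = FALSE)
  pk <- pk[order(pk$chrom, pk$start, method = "radix"), , drop = FALSE]
  rownames(pk) <- NULL
  attr(pk, "mark_name") <- mark_name
  attr(pk, "dialect") <- dialect
  pk
}

#' Read a ranked gene list
#'
#' Two-column TSV (gene symbol, numeric score), e.g. expression intensity
#' ranks or ChIP peak p-score gene ranks. Rows are ordered by descending
#' score; duplicate symbols are an error.
#'
#' @param path file path; `#` lines skipped
#' @return `data.frame` with columns `gene`, `score`, sorted descending
#' @export
read_ranked_list <- function(path) {
  dat <- read_data_lines(path)
  fields <- split_fields(dat$lines)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("ranked list line ", dat$lineno[bad[1]], ": expected 2 columns",
         call. = FALSE)
  df <- data.frame(gene = vapply(fields, `[[`, "", 1L),
                   score = as.numeric(vapply(fields, `[[`, "", 2L)),
                   stringsAsFactors = FALSE)
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup))
    stop("duplicate symbols in ranked list: ", paste(dup, collapse = ", "),
         call. = FALSE)
  df <- df[order(-df$score, df$gene, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read an annotated gene set
#'
#' Plain text, one gene symbol per line; `#` starts a comment.
#'
#' @param path file path
#' @param name set name; defaults to the file name
#' @param background_fraction optional genome-wide fraction annotated with
#'   this set (e.g. 0.022 for cancer drivers), in (0, 1)
#' @return character vector of unique symbols with attributes `set_name` and
#'   `background_fraction`
#' @export
read_gene_set <- function(path, name = NULL, background_fraction = NULL) {
  dat <- read_data_lines(path)
  sym <- unique(trimws(dat$lines))
  sym <- sym[sym != ""]
  if (!is.null(background_fraction) &&
      (background_fraction <= 0 || background_fraction >= 1))
    stop("background_fraction must lie in (0, 1)", call. = FALSE)
  structure(sym,
            set_name = name %||% sub("\\.[^.]*$", "", basename(path)),
            background_fraction = background_fraction)
}

#' Write a TSV with provenance header
#'
#' All pipeline outputs are tab-separated with a leading block of `#`-prefixed
#' header lines recording the package version and the run parameters (seed
#' included), so any output can be regenerated from its own header.
#'
#' @param df data frame to write
#' @param path output path
#' @param params named list written as `# key: value` lines
#' @export
write_grip_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# gripr ", as.character(packageVersion("gripr"))), con)
  writeLines("# coordinates: 0-based half-open", con)
  for (k in names(params))
    writeLines(paste0("# ", k, ": ", paste(params[[k]], collapse = ",")), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_grip_tsv()]
#' @param path file path
#' @return data frame; header parameters in attribute `params`
#' @export
read_grip_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  params <- list()
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^# ([^:]+): (.*)$", h))[[1]]
    if (length(m) == 3L) params[[m[2]]] <- m[3]
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  if (length(body) <= 1L) {
    df <- data.frame()
  } else {
    df <- read.table(text = body, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, quote = "")
  }
  attr(df, "params") <- params
  df
}
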