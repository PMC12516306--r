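# Input parsing: configuration tables, simplified FASTA+BED input, sequence
# lengths and BED annotation intervals.
#
# Coordinate convention everywhere in this package: 0-based, half-open
# [start, end), matching BED and PAF.

entry_columns <- c(
  "sample_id", "label", "fasta_path", "annotation_path",
  "declared_strand", "length", "seq_name", "order_index", "annotations"
)

new_entries <- function(sample_id, label, fasta_path,
                        annotation_path = NA_character_,
                        declared_strand = NA_character_) {
  n <- length(sample_id)
  tibble::tibble(
    sample_id = as.character(sample_id),
    label = as.character(label),
    fasta_path = as.character(fasta_path),
    annotation_path = rep_len(as.character(annotation_path), n),
    declared_strand = rep_len(as.character(declared_strand), n),
    length = NA_integer_,
    seq_name = NA_character_,
    order_index = seq_len(n) - 1L,
    annotations = rep(list(NULL), n)
  )
}

detect_delimiter <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(",")
  if (ext == "tsv") return("\t")
  header <- readLines(path, n = 1L, warn = FALSE)
  has_tab <- grepl("\t", header, fixed = TRUE)
  has_comma <- grepl(",", header, fixed = TRUE)
  if (has_tab && has_comma) {
    dq_config_error(sprintf(
      "cannot detect delimiter of '%s': header mixes tabs and commas", path))
  }
  if (has_tab) "\t" else if (has_comma) "," else {
    dq_config_error(sprintf(
      "cannot detect delimiter of '%s': header contains neither tab nor comma",
      path))
  }
}

#' Parse a configuration table
#'
#' Reads the CSV/TSV configuration table describing the input sequences, one
#' sequence per row. Mandatory columns are `Fasta` (path to a FASTA file),
#' `SampleID` (unique identifier) and `Label` (display label); optional
#' columns are `Annotation` (path to a BED file) and `Strand` (declared
#' display orientation, `+` or `-`; empty means "infer automatically").
#'
#' The delimiter is taken from the file extension (`.csv`/`.tsv`) and sniffed
#' from the header line otherwise; a header mixing both delimiters is
#' rejected. Relative `Fasta`/`Annotation` paths are resolved against the
#' directory containing the configuration file.
#'
#' @param path path to the configuration table.
#' @return a tibble of sequence entries in file order, with columns
#'   `sample_id`, `label`, `fasta_path`, `annotation_path`,
#'   `declared_strand`, `length` (filled by [load_lengths()]), `seq_name`,
#'   `order_index` (0-based; index 0 is the reference sequence) and
#'   `annotations` (filled by [load_annotations()]).
#' @seealso [parse_simplified_input()] for the single-FASTA dialect.
#' @export
#' @examples
#' cfg <- tempfile(fileext = ".tsv")
#' fa <- tempfile(fileext = ".fa")
#' writeLines(">s1\nACGTACGT", fa)
#' writeLines(c("Fasta\tSampleID\tLabel", paste(fa, "s1", "Sample 1", sep = "\t")), cfg)
#' parse_config(cfg)
parse_config <- function(path) {
  if (!file.exists(path)) {
    dq_io_error(sprintf("configuration file not found: '%s'", path))
  }
  delim <- detect_delimiter(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          blank.lines.skip = TRUE)
  mandatory <- c("Fasta", "SampleID", "Label")
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0) {
    dq_config_error(sprintf(
      "configuration table '%s' is missing mandatory column(s): %s",
      path, paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    dq_validation_error(sprintf("configuration table '%s' has no data rows", path))
  }
  dup <- unique(df$SampleID[duplicated(df$SampleID)])
  if (length(dup) > 0) {
    dq_validation_error(sprintf(
      "duplicate SampleID value(s): %s", paste(dup, collapse = ", ")))
  }

  base_dir <- dirname(normalizePath(path, mustWork = TRUE))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p),
           p, file.path(base_dir, p))
  }

  strand <- if ("Strand" %in% names(df)) df$Strand else rep("", nrow(df))
  strand[is.na(strand)] <- ""
  bad <- which(!strand %in% c("", "+", "-"))
  if (length(bad) > 0) {
    dq_validation_error(sprintf(
      "invalid Strand value '%s' in row %d (allowed: '+', '-', empty)",
      strand[bad[1]], bad[1]))
  }
  strand[strand == ""] <- NA_character_

  annot <- if ("Annotation" %in% names(df)) df$Annotation else rep(NA_character_, nrow(df))
  annot[!is.na(annot) & annot == ""] <- NA_character_
  annot <- resolve(annot)
  fasta <- resolve(df$Fasta)

  for (i in seq_along(fasta)) {
    if (!file.exists(fasta[i])) {
      dq_io_error(sprintf(
        "row %d (SampleID '%s'): FASTA file not found: '%s'",
        i, df$SampleID[i], df$Fasta[i]))
    }
    if (!is.na(annot[i]) && !file.exists(annot[i])) {
      dq_io_error(sprintf(
        "row %d (SampleID '%s'): annotation file not found: '%s'",
        i, df$SampleID[i], annot[i]))
    }
  }

  new_entries(df$SampleID, df$Label, fasta,
              annotation_path = annot, declared_strand = strand)
}

#' Write sequence entries back to a configuration table
#'
#' Emits a TSV with columns `Fasta`, `SampleID`, `Label`, plus `Annotation`
#' and/or `Strand` when any entry carries them. Round-trips through
#' [parse_config()].
#'
#' @param entries entries tibble (see [parse_config()]).
#' @param path output file path (`.tsv`).
#' @return the path, invisibly usable, returned visibly for convenience.
#' @export
write_config <- function(entries, path) {
  out <- data.frame(Fasta = entries$fasta_path,
                    SampleID = entries$sample_id,
                    Label = entries$label,
                    check.names = FALSE)
  if (any(!is.na(entries$annotation_path))) {
    a <- entries$annotation_path
    a[is.na(a)] <- ""
    out$Annotation <- a
  }
  if (any(!is.na(entries$declared_strand))) {
    s <- entries$declared_strand
    s[is.na(s)] <- ""
    out$Strand <- s
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Parse the simplified single-FASTA input
#'
#' Alternative input dialect: all sequences combined into one multi-record
#' FASTA whose headers are the unique sample identifiers, optionally with one
#' combined BED file whose first column refers to those identifiers.
#'
#' @param fasta_path path to the multi-record FASTA.
#' @param bed_path optional path to a combined BED file.
#' @return an entries tibble structurally identical to [parse_config()]
#'   output; `sample_id` and `label` are the FASTA header tokens, lengths are
#'   already filled, and each entry's `annotations` list-column holds its BED
#'   intervals (empty tibble when the BED has none for it).
#' @export
parse_simplified_input <- function(fasta_path, bed_path = NULL) {
  if (!file.exists(fasta_path)) {
    dq_io_error(sprintf("FASTA file not found: '%s'", fasta_path))
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    dq_validation_error(sprintf(
      "duplicate FASTA header(s) in '%s': %s",
      fasta_path, paste(dup, collapse = ", ")))
  }
  if (any(Biostrings::width(seqs) == 0)) {
    empty <- ids[Biostrings::width(seqs) == 0]
    dq_validation_error(sprintf(
      "empty sequence record(s): %s", paste(empty, collapse = ", ")))
  }

  entries <- new_entries(ids, ids, fasta_path,
                         annotation_path = bed_path %||% NA_character_)
  entries$length <- as.integer(Biostrings::width(seqs))
  entries$seq_name <- ids

  intervals <- if (!is.null(bed_path)) parse_bed(bed_path) else empty_intervals()
  unknown <- setdiff(unique(intervals$sample_id), ids)
  if (length(unknown) > 0) {
    lines <- intervals$line[intervals$sample_id %in% unknown]
    dq_validation_error(sprintf(
      "BED line(s) %s refer to unknown sequence id(s): %s",
      paste(lines, collapse = ", "), paste(unknown, collapse = ", ")))
  }
  entries$annotations <- lapply(ids, function(id) {
    intervals[intervals$sample_id == id, , drop = FALSE]
  })
  validate_annotation_bounds(entries)
  entries
}

#' Fill sequence lengths (and FASTA record names) for each entry
#'
#' Reads each entry's FASTA and records the residue count. A single-record
#' FASTA contributes that record; in a multi-record FASTA the record whose
#' header token equals the entry's `sample_id` is preferred, otherwise the
#' first record is used with a logged warning.
#'
#' @param entries entries tibble from [parse_config()].
#' @return the entries with `length` and `seq_name` filled.
#' @export
load_lengths <- function(entries) {
  for (fp in unique(entries$fasta_path)) {
    seqs <- Biostrings::readDNAStringSet(fp)
    if (length(seqs) == 0) {
      dq_validation_error(sprintf("FASTA '%s' contains no records", fp))
    }
    tokens <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
    rows <- which(entries$fasta_path == fp)
    for (i in rows) {
      k <- if (length(seqs) == 1L) {
        1L
      } else if (entries$sample_id[i] %in% tokens) {
        match(entries$sample_id[i], tokens)
      } else {
        dq_log("WARN", "input", sprintf(
          "FASTA '%s' has %d records and none named '%s'; using the first",
          fp, length(seqs), entries$sample_id[i]))
        1L
      }
      len <- Biostrings::width(seqs)[k]
      if (len == 0) {
        dq_validation_error(sprintf(
          "sequence '%s' in '%s' is empty", tokens[k], fp))
      }
      entries$length[i] <- as.integer(len)
      entries$seq_name[i] <- tokens[k]
    }
  }
  entries
}

empty_intervals <- function() {
  tibble::tibble(sample_id = character(), start = integer(), end = integer(),
                 name = character(), color = character(), line = integer())
}

#' Parse a BED annotation file
#'
#' Accepts 3 to 9+ tab-separated columns with 0-based half-open intervals.
#' Column 4 becomes the interval name and column 9 (`itemRgb`, "R,G,B") the
#' display color; a malformed `itemRgb` yields a warning and an unset color.
#' Intervals without a color are drawn black.
#'
#' @param path path to the BED file.
#' @return a tibble with columns `sample_id` (BED column 1), `start`, `end`,
#'   `name`, `color` (hex or `NA`) and `line` (1-based source line number).
#' @export
parse_bed <- function(path) {
  if (!file.exists(path)) {
    dq_io_error(sprintf("BED file not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(#|track\\b|browser\\b)", lines))
  if (length(keep) == 0) return(empty_intervals())

  out <- lapply(keep, function(ln) {
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      dq_validation_error(sprintf(
        "BED '%s' line %d: fewer than 3 tab-separated columns", path, ln))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      dq_validation_error(sprintf(
        "BED '%s' line %d: non-integer coordinates '%s'/'%s'",
        path, ln, f[2], f[3]))
    }
    if (start < 0 || start >= end) {
      dq_validation_error(sprintf(
        "BED '%s' line %d: invalid interval [%d, %d) (need 0 <= start < end)",
        path, ln, start, end))
    }
    color <- NA_character_
    if (length(f) >= 9 && nzchar(f[9]) && f[9] != "0" && f[9] != ".") {
      rgbv <- suppressWarnings(as.integer(strsplit(f[9], ",", fixed = TRUE)[[1]]))
      if (length(rgbv) == 3 && !anyNA(rgbv) && all(rgbv >= 0 & rgbv <= 255)) {
        color <- grDevices::rgb(rgbv[1], rgbv[2], rgbv[3], maxColorValue = 255)
      } else {
        warning(sprintf("BED '%s' line %d: malformed itemRgb '%s'; ignoring",
                        path, ln, f[9]), call. = FALSE)
      }
    }
    tibble::tibble(
      sample_id = f[1], start = start, end = end,
      name = if (length(f) >= 4 && nzchar(f[4])) f[4] else NA_character_,
      color = color, line = as.integer(ln))
  })
  do.call(rbind, out)
}

#' Load annotation intervals for every entry
#'
#' For each entry with an `annotation_path`, parses the BED file and stores
#' the intervals in the `annotations` list-column. When a BED's first column
#' contains the entry's `sample_id`, only matching lines are kept (shared /
#' combined BED files); otherwise all lines are assigned to the entry
#' (per-sequence BED files keyed by contig name).
#'
#' @param entries entries tibble with lengths loaded.
#' @return the entries with `annotations` filled (empty tibble when no BED).
#' @export
load_annotations <- function(entries) {
  cache <- list()
  entries$annotations <- lapply(seq_len(nrow(entries)), function(i) {
    ap <- entries$annotation_path[i]
    if (is.na(ap)) return(empty_intervals())
    if (is.null(cache[[ap]])) cache[[ap]] <<- parse_bed(ap)
    iv <- cache[[ap]]
    if (entries$sample_id[i] %in% iv$sample_id) {
      iv <- iv[iv$sample_id == entries$sample_id[i], , drop = FALSE]
    } else {
      iv$sample_id <- rep(entries$sample_id[i], nrow(iv))
    }
    iv
  })
  validate_annotation_bounds(entries)
  entries
}

validate_annotation_bounds <- function(entries) {
  for (i in seq_len(nrow(entries))) {
    iv <- entries$annotations[[i]]
    if (is.null(iv) || nrow(iv) == 0 || is.na(entries$length[i])) next
    bad <- which(iv$end > entries$length[i])
    if (length(bad) > 0) {
      dq_validation_error(sprintf(
        "annotation interval [%d, %d) exceeds length %d of sequence '%s'",
        iv$start[bad[1]], iv$end[bad[1]], entries$length[i],
        entries$sample_id[i]))
    }
  }
  invisible(entries)
}
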