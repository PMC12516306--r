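# Alignment ingestion: PAF (minimap2, MashMap) and LastZ general-format
# parsing, a raw-output cache keyed per sequence pair, and external aligner
# invocation.
#
# An alignment record holds both sequences' 0-based half-open coordinates
# with query coordinates always on the forward strand (the PAF convention),
# the strand of the alignment, and its percent identity in [0, 100].

record_columns <- c("query_id", "target_id", "t_start", "t_end",
                    "q_start", "q_end", "strand", "percent_identity", "source")

empty_records <- function() {
  tibble::tibble(query_id = character(), target_id = character(),
                 t_start = numeric(), t_end = numeric(),
                 q_start = numeric(), q_end = numeric(),
                 strand = character(), percent_identity = numeric(),
                 source = character())
}

#' Validate alignment records
#'
#' Checks the record invariants: positive span on both sequences, strand in
#' `{+, -}`, percent identity in `[0, 100]`, and (when lengths are supplied)
#' coordinates within the sequences.
#'
#' @param records alignment-record tibble.
#' @param target_len,query_len optional sequence lengths (bp) to bound-check
#'   against.
#' @return the records, invisibly.
#' @export
validate_records <- function(records, target_len = NULL, query_len = NULL) {
  if (nrow(records) == 0) return(invisible(records))
  if (any(records$t_start < 0) || any(records$t_start >= records$t_end)) {
    dq_contract_error("alignment record with non-positive target span")
  }
  if (any(records$q_start < 0) || any(records$q_start >= records$q_end)) {
    dq_contract_error("alignment record with non-positive query span")
  }
  if (!all(records$strand %in% c("+", "-"))) {
    dq_contract_error("alignment record with strand outside {+, -}")
  }
  if (any(records$percent_identity < 0 | records$percent_identity > 100)) {
    dq_validation_error("percent identity outside [0, 100]")
  }
  if (!is.null(target_len) && any(records$t_end > target_len)) {
    dq_contract_error("alignment record exceeds target sequence length")
  }
  if (!is.null(query_len) && any(records$q_end > query_len)) {
    dq_contract_error("alignment record exceeds query sequence length")
  }
  invisible(records)
}

#' Bundle records for one sequence pair
#'
#' @param target_id,query_id the pair; the target is the sequence with the
#'   smaller input index, so pair geometry is deterministic.
#' @param records alignment-record tibble; all rows must name this pair.
#' @return an `alignment_set` list with `pair_key`, `records`, `is_self`.
#' @export
alignment_set <- function(target_id, query_id, records) {
  if (nrow(records) > 0 &&
      (!all(records$target_id == target_id) ||
       !all(records$query_id == query_id))) {
    dq_contract_error(sprintf(
      "records do not all belong to pair (%s, %s)", target_id, query_id))
  }
  structure(
    list(pair_key = c(target_id = target_id, query_id = query_id),
         records = records,
         is_self = identical(target_id, query_id)),
    class = "alignment_set")
}

read_stream <- function(stream) {
  if (length(stream) == 1L && !grepl("\n", stream) && file.exists(stream)) {
    readLines(stream, warn = FALSE)
  } else {
    unlist(strsplit(stream, "\n", fixed = TRUE), use.names = FALSE)
  }
}

#' Parse PAF alignments for one sequence pair
#'
#' Reads tab-separated PAF (12+ mandatory columns, as written by minimap2 or
#' MashMap). Percent identity is `100 * matches / alignment_block_length`
#' (columns 10 and 11); when an `id:f:` tag is present (MashMap's identity
#' estimate) it overrides the column ratio. Query coordinates stay on the
#' forward strand as PAF defines them. Lines for other pairs are skipped
#' with a logged count; a zero block length skips the line with a warning.
#'
#' @param stream a file path or a character vector of PAF lines.
#' @param pair character vector `c(target_id, query_id)` naming PAF columns
#'   6 and 1 respectively.
#' @return an alignment-record tibble.
#' @export
parse_paf <- function(stream, pair) {
  lines <- read_stream(stream)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_records())
  target_id <- pair[[1]]; query_id <- pair[[2]]

  rows <- vector("list", length(lines))
  skipped_pair <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) {
      dq_parse_error(sprintf(
        "PAF line %d has %d columns (12 required)", i, length(f)))
    }
    if (!(f[1] == query_id && f[6] == target_id)) {
      skipped_pair <- skipped_pair + 1L
      next
    }
    block <- as.numeric(f[11])
    if (is.na(block) || block == 0) {
      warning(sprintf("PAF line %d: zero alignment block length; skipped", i),
              call. = FALSE)
      next
    }
    pi <- 100 * as.numeric(f[10]) / block
    id_tag <- grep("^id:f:", f[-(1:12)], value = TRUE)
    if (length(id_tag) > 0) {
      v <- as.numeric(sub("^id:f:", "", id_tag[1]))
      pi <- if (!is.na(v) && v <= 1) 100 * v else v
    }
    rows[[i]] <- tibble::tibble(
      query_id = query_id, target_id = target_id,
      t_start = as.numeric(f[8]), t_end = as.numeric(f[9]),
      q_start = as.numeric(f[3]), q_end = as.numeric(f[4]),
      strand = f[5], percent_identity = pi, source = "paf")
  }
  if (skipped_pair > 0) {
    dq_log("INFO", "parse", sprintf(
      "PAF: skipped %d line(s) not matching pair (%s, %s)",
      skipped_pair, target_id, query_id))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) empty_records() else do.call(rbind, rows)
  validate_records(out)
  out
}

#' Parse LastZ general-format alignments for one sequence pair
#'
#' Expects the tabular "general" output with a header line naming at least
#' `name1`, `zstart1`, `end1`, `name2`, `strand2`, `zstart2+`, `end2+` and
#' `id%` (percentages like `"97.3%"`). Coordinates are the 0-based half-open
#' `z` variants. Rows with `strand2 == "-"` carry reverse-strand query
#' coordinates; they are converted to forward-strand coordinates as
#' `[L - end, L - start)` using the query length, taken from a `size2`
#' column when present and from `query_length` otherwise.
#'
#' @param stream a file path or character vector of lines.
#' @param pair `c(target_id, query_id)` matched against `name1`/`name2`.
#' @param query_length query sequence length in bp; required for minus-strand
#'   rows when the file has no `size2` column.
#' @return an alignment-record tibble.
#' @export
parse_lastz_general <- function(stream, pair, query_length = NULL) {
  lines <- read_stream(stream)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_records())

  header <- sub("^#\\s*", "", lines[[1]])
  fields <- strsplit(header, "\t", fixed = TRUE)[[1]]
  required <- c("name1", "zstart1", "end1", "name2", "strand2",
                "zstart2+", "end2+", "id%")
  missing <- setdiff(required, fields)
  if (length(missing) > 0) {
    dq_parse_error(sprintf(
      "LastZ general header is missing field(s): %s",
      paste(missing, collapse = ", ")))
  }
  col <- function(f, name) f[[match(name, fields)]]
  target_id <- pair[[1]]; query_id <- pair[[2]]

  rows <- list()
  for (i in seq_along(lines)[-1]) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < length(fields)) {
      dq_parse_error(sprintf("LastZ general line %d: too few columns", i))
    }
    if (!(col(f, "name1") == target_id && col(f, "name2") == query_id)) next
    pi <- as.numeric(sub("%$", "", col(f, "id%")))
    if (is.na(pi) || pi < 0 || pi > 100) {
      dq_validation_error(sprintf(
        "LastZ general line %d: id%% value '%s' outside [0, 100]",
        i, col(f, "id%")))
    }
    strand <- col(f, "strand2")
    qs <- as.numeric(col(f, "zstart2+")); qe <- as.numeric(col(f, "end2+"))
    if (strand == "-") {
      L <- if ("size2" %in% fields) as.numeric(col(f, "size2")) else query_length
      if (is.null(L) || is.na(L)) {
        dq_parse_error(sprintf(
          "LastZ general line %d: minus-strand row but no size2 column and no query_length given", i))
      }
      fwd <- reverse_interval(qs, qe, L)
      qs <- fwd[[1]]; qe <- fwd[[2]]
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      query_id = query_id, target_id = target_id,
      t_start = as.numeric(col(f, "zstart1")),
      t_end = as.numeric(col(f, "end1")),
      q_start = qs, q_end = qe,
      strand = strand, percent_identity = pi, source = "lastz")
  }
  out <- if (length(rows) == 0) empty_records() else do.call(rbind, rows)
  validate_records(out)
  out
}

#' Deterministic cache path for one pair's raw aligner output
#'
#' Sample identifiers are sanitized to filesystem-safe tokens; the path is
#' unique per unordered pair and aligner:
#' `<out_dir>/alignments/<idA>__<idB>.<aligner>.txt` with the sanitized ids
#' in sorted order. Two distinct ids whose sanitized forms collide raise an
#' error rather than silently sharing a file.
#'
#' @param out_dir run output directory.
#' @param target_id,query_id the pair.
#' @param aligner one of `"minimap2"`, `"lastz"`, `"mashmap"`.
#' @return the cache file path (the directory is not created here).
#' @export
cache_path <- function(out_dir, target_id, query_id, aligner) {
  sa <- sanitize_id(target_id); sb <- sanitize_id(query_id)
  if (!identical(target_id, query_id) && identical(sa, sb)) {
    dq_validation_error(sprintf(
      "sample ids '%s' and '%s' sanitize to the same token '%s'",
      target_id, query_id, sa))
  }
  ids <- sort(c(sa, sb))
  file.path(out_dir, "alignments",
            sprintf("%s__%s.%s.txt", ids[1], ids[2], aligner))
}

default_aligner_template <- function(aligner) {
  switch(aligner,
    minimap2 = "minimap2 -c -x asm20 --eqx {target} {query}",
    lastz = paste0("lastz {target} {query} --format=general:",
                   "name1,strand1,size1,zstart1,end1,",
                   "name2,strand2,size2,zstart2+,end2+,id%"),
    mashmap = "mashmap -r {target} -q {query} -o /dev/stdout",
    dq_config_error(sprintf("unknown aligner '%s'", aligner)))
}

parse_cached <- function(path, aligner, pair, query_length = NULL) {
  res <- tryCatch({
    if (aligner == "lastz") {
      parse_lastz_general(path, pair, query_length = query_length)
    } else {
      parse_paf(path, pair)
    }
  }, dq_error = function(e) e)
  if (inherits(res, "error")) {
    dq_io_error(sprintf("cached alignment file '%s' is unparseable: %s",
                        path, conditionMessage(res)))
  }
  res
}

# Sequences aligned pairwise must each live in their own FASTA; entries
# pointing into a multi-record FASTA get their record extracted once into
# <out_dir>/sequences/<sample_id>.fasta.
ensure_pair_fastas <- function(entries, out_dir) {
  shared <- entries$fasta_path[duplicated(entries$fasta_path) |
                                 duplicated(entries$fasta_path, fromLast = TRUE)]
  multi <- unique(shared)
  paths <- entries$fasta_path
  if (length(multi) == 0) return(paths)
  seq_dir <- file.path(out_dir, "sequences")
  dir.create(seq_dir, recursive = TRUE, showWarnings = FALSE)
  for (fp in multi) {
    seqs <- Biostrings::readDNAStringSet(fp)
    tokens <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
    for (i in which(entries$fasta_path == fp)) {
      dest <- file.path(seq_dir, paste0(sanitize_id(entries$sample_id[i]), ".fasta"))
      if (!file.exists(dest)) {
        k <- match(entries$seq_name[i], tokens)
        one <- seqs[k]
        names(one) <- entries$seq_name[i]
        Biostrings::writeXStringSet(one, dest)
      }
      paths[i] <- dest
    }
  }
  paths
}

#' Compute or load all pairwise alignments
#'
#' For the `n * (n + 1) / 2` ordered pairs `(i, j)` with `i <= j` over the
#' entries (self-alignments included; the lower-index sequence is the
#' target), loads the cached raw aligner output when present and otherwise
#' invokes the external aligner, storing its raw stdout under
#' [cache_path()] before parsing. Rerunning on the same `out_dir` therefore
#' performs no aligner calls.
#'
#' @param entries entries tibble with lengths loaded.
#' @param aligner `"minimap2"`, `"lastz"` or `"mashmap"`.
#' @param out_dir output directory (created if needed).
#' @param template command template with `{target}` and `{query}`
#'   placeholders; defaults per aligner.
#' @return a named list of [alignment_set()]s keyed `"<target>__<query>"`
#'   over sanitized ids, with attribute `n_aligner_calls` giving the number
#'   of external invocations performed.
#' @export
run_pairwise_alignments <- function(entries,
                                    aligner = c("minimap2", "lastz", "mashmap"),
                                    out_dir,
                                    template = NULL) {
  aligner <- match.arg(aligner)
  template <- template %||% default_aligner_template(aligner)
  san <- sanitize_id(entries$sample_id)
  if (anyDuplicated(san)) {
    dq_validation_error(sprintf(
      "sanitized sample ids collide: %s",
      paste(unique(san[duplicated(san)]), collapse = ", ")))
  }
  dir.create(file.path(out_dir, "alignments"),
             recursive = TRUE, showWarnings = FALSE)

  entries <- entries[order(entries$order_index), , drop = FALSE]
  fasta_paths <- NULL
  n <- nrow(entries)
  sets <- list()
  n_calls <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      tid <- entries$sample_id[i]; qid <- entries$sample_id[j]
      path <- cache_path(out_dir, tid, qid, aligner)
      if (!file.exists(path)) {
        if (is.null(fasta_paths)) fasta_paths <- ensure_pair_fastas(entries, out_dir)
        invoke_aligner(template, fasta_paths[i], fasta_paths[j], path)
        n_calls <- n_calls + 1L
      }
      pair_seq <- c(entries$seq_name[i], entries$seq_name[j])
      rec <- parse_cached(path, aligner, pair_seq,
                          query_length = entries$length[j])
      # aligner output names records by FASTA header; report sample ids
      if (nrow(rec) > 0) {
        rec$target_id <- tid
        rec$query_id <- qid
      }
      validate_records(rec, target_len = entries$length[i],
                       query_len = entries$length[j])
      sets[[pair_name(tid, qid)]] <- alignment_set(tid, qid, rec)
    }
  }
  dq_log("INFO", "align", sprintf(
    "%d pair(s): %d aligner call(s), %d loaded from cache",
    length(sets), n_calls, length(sets) - n_calls))
  attr(sets, "n_aligner_calls") <- n_calls
  sets
}

invoke_aligner <- function(template, target_fasta, query_fasta, cache_file) {
  cmd <- gsub("{target}", shQuote(target_fasta),
              gsub("{query}", shQuote(query_fasta), template, fixed = TRUE),
              fixed = TRUE)
  exe <- strsplit(cmd, "\\s+")[[1]][1]
  if (Sys.which(exe) == "") {
    dq_runtime_error(sprintf(
      "aligner executable '%s' not found on PATH and pair not cached", exe))
  }
  tmp <- paste0(cache_file, ".part")
  err <- tempfile("aligner_stderr_")
  status <- system2("sh", c("-c", shQuote(cmd)), stdout = tmp, stderr = err)
  if (status != 0) {
    msg <- paste(readLines(err, warn = FALSE), collapse = "\n")
    unlink(tmp)
    dq_runtime_error(sprintf(
      "aligner command failed (exit %d): %s\n%s", status, cmd, msg))
  }
  file.rename(tmp, cache_file)
  invisible(cache_file)
}
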