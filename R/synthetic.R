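# Seeded synthetic loci with exact ground truth.
#
# Sequences are concatenations of shared library blocks -- optionally
# reverse-complemented, point-mutated copies -- separated by random spacers.
# Because substitutions hit distinct positions and are always to a different
# base, the percent identity between any two copies of a block is an exact
# count of matching positions, not an expectation. Ground-truth alignment
# records therefore stand in for aligner output (exported as PAF) and make
# the whole pipeline testable without external tools.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

revcomp_chars <- function(v) rev(chartr("ACGT", "TGCA", v))

#' Describe a synthetic locus
#'
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @param block_library tibble with `block_id` and `length` (bp > 0).
#' @param arrangements list with one tibble per sequence, columns
#'   `block_id`, `orientation` (`+`/`-`) and `divergence` (substitutions
#'   per bp, in `[0, 0.3]`), giving the block order along that sequence.
#' @param sequence_strand per-sequence `+`/`-`; `-` reverse-complements the
#'   whole assembled sequence (a planted global inversion).
#' @param spacer_len random unrelated spacer placed before, between and
#'   after blocks (bp).
#' @param annotate_blocks block ids marked as features in the BED output.
#' @param annotation_colors optional named vector of colors per block id.
#' @param sample_ids sequence identifiers (default `S1..Sn`).
#' @return a validated `locus_spec` list.
#' @export
locus_spec <- function(seed,
                       block_library,
                       arrangements,
                       sequence_strand = NULL,
                       spacer_len = 1000,
                       annotate_blocks = character(0),
                       annotation_colors = NULL,
                       sample_ids = NULL) {
  n <- length(arrangements)
  if (n < 1) dq_validation_error("at least one sequence arrangement required")
  if (any(block_library$length <= 0)) {
    dq_validation_error("block lengths must be positive")
  }
  if (anyDuplicated(block_library$block_id)) {
    dq_validation_error("block ids must be unique")
  }
  sequence_strand <- sequence_strand %||% rep("+", n)
  sample_ids <- sample_ids %||% sprintf("S%d", seq_len(n))
  for (arr in arrangements) {
    if (!all(arr$block_id %in% block_library$block_id)) {
      dq_validation_error("arrangement refers to unknown block id")
    }
    if (!all(arr$orientation %in% c("+", "-"))) {
      dq_validation_error("block orientation must be '+' or '-'")
    }
    if (any(arr$divergence < 0 | arr$divergence > 0.3)) {
      dq_validation_error("divergence must lie in [0, 0.3]")
    }
  }
  if (!all(sequence_strand %in% c("+", "-"))) {
    dq_validation_error("sequence_strand must be '+' or '-'")
  }
  if (!all(annotate_blocks %in% block_library$block_id)) {
    dq_validation_error("annotate_blocks refers to unknown block id")
  }
  structure(
    list(seed = seed, block_library = block_library,
         arrangements = arrangements, sequence_strand = sequence_strand,
         spacer_len = spacer_len, annotate_blocks = annotate_blocks,
         annotation_colors = annotation_colors, sample_ids = sample_ids),
    class = "locus_spec")
}

#' The packaged study-scale locus: five sequences, ~60-100 kbp each
#'
#' Emulates a repeat-rich locus shared by five samples: five library blocks
#' (8-30 kbp), a tandem duplication (block B twice in S2), an inverted
#' block copy (C in S3), one globally reverse-complemented sequence (S4),
#' and per-copy divergences of 0-8%. Blocks A and D are annotated.
#'
#' @param seed RNG seed.
#' @return a [locus_spec()].
#' @export
default_locus_spec <- function(seed) {
  lib <- tibble::tibble(
    block_id = c("A", "B", "C", "D", "E"),
    length = c(30000L, 20000L, 15000L, 12000L, 8000L))
  arr <- function(...) {
    rows <- list(...)
    tibble::tibble(
      block_id = vapply(rows, `[[`, character(1), 1),
      orientation = vapply(rows, `[[`, character(1), 2),
      divergence = as.numeric(vapply(rows, `[[`, character(1), 3)))
  }
  locus_spec(
    seed = seed,
    block_library = lib,
    arrangements = list(
      arr(c("A", "+", "0"),    c("B", "+", "0"),    c("C", "+", "0"),
          c("D", "+", "0")),
      arr(c("A", "+", "0.02"), c("B", "+", "0.03"), c("B", "+", "0.05"),
          c("C", "+", "0.02"), c("D", "+", "0.04")),
      arr(c("A", "+", "0.05"), c("C", "-", "0.03"), c("D", "+", "0.02"),
          c("E", "+", "0")),
      arr(c("A", "+", "0.04"), c("B", "+", "0.02"), c("C", "+", "0.06"),
          c("D", "+", "0.03")),
      arr(c("A", "+", "0.08"), c("B", "+", "0.06"), c("D", "+", "0.05"),
          c("E", "+", "0.02"))),
    sequence_strand = c("+", "+", "+", "-", "+"),
    spacer_len = 1000,
    annotate_blocks = c("A", "D"),
    annotation_colors = c(A = "#008000", D = "#C00000"))
}

mutate_block <- function(base, k) {
  if (k == 0) return(base)
  pos <- sample(length(base), k)
  alt <- vapply(base[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  base[pos] <- alt
  base
}

#' Generate a synthetic locus with ground-truth alignments
#'
#' Builds the sequences, BED annotations and exact alignment records for
#' every sequence pair (self-pairs included: a full-length identity record
#' plus one record per distinct pair of block copies sharing a block id).
#' Record strand is the parity of the two copies' orientations; percent
#' identity is `100 * matches / block_length` with matches counted
#' position-by-position.
#'
#' @param spec a [locus_spec()].
#' @return a list: `entries` (tibble as from [parse_simplified_input()]),
#'   `sequences` (named character vector), `annotations` (named list of
#'   interval tibbles), `records` (named list, key `"<target>__<query>"`,
#'   of record tibbles carrying extra `n_matches`/`block_len` columns),
#'   `copies` (block-copy bookkeeping tibble) and the `spec`.
#' @export
generate_locus_set <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  with_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    lib <- spec$block_library
    block_seq <- lapply(seq_len(nrow(lib)), function(b)
      sample(bases, lib$length[b], replace = TRUE))
    names(block_seq) <- lib$block_id
    block_len <- setNames(lib$length, lib$block_id)

    n <- length(spec$arrangements)
    ids <- spec$sample_ids
    sequences <- character(n)
    copies <- list()       # one row per block copy, with its residue vector
    vecs <- list()

    for (s in seq_len(n)) {
      arr <- spec$arrangements[[s]]
      chunks <- list()
      pos <- 0L
      add_spacer <- function(pos, chunks) {
        sp <- sample(bases, spec$spacer_len, replace = TRUE)
        chunks[[length(chunks) + 1L]] <- sp
        list(pos = pos + spec$spacer_len, chunks = chunks)
      }
      st <- add_spacer(pos, chunks); pos <- st$pos; chunks <- st$chunks
      for (r in seq_len(nrow(arr))) {
        bid <- arr$block_id[r]
        len <- block_len[[bid]]
        k <- round(arr$divergence[r] * len)
        fwd <- mutate_block(block_seq[[bid]], k)
        emitted <- if (arr$orientation[r] == "-") revcomp_chars(fwd) else fwd
        chunks[[length(chunks) + 1L]] <- emitted
        vecs[[length(vecs) + 1L]] <- fwd
        copies[[length(copies) + 1L]] <- tibble::tibble(
          seq_index = s, sample_id = ids[s], block_id = bid,
          start = pos, end = pos + len,
          orientation = arr$orientation[r],
          vec = length(vecs))
        pos <- pos + len
        st <- add_spacer(pos, chunks); pos <- st$pos; chunks <- st$chunks
      }
      sequences[s] <- paste(unlist(chunks), collapse = "")
    }
    copies <- do.call(rbind, copies)
    seq_len_bp <- nchar(sequences)

    # planted global inversions: reverse-complement the assembled sequence
    # and remap every copy accordingly
    for (s in which(spec$sequence_strand == "-")) {
      L <- seq_len_bp[s]
      sequences[s] <- paste(revcomp_chars(strsplit(sequences[s], "")[[1]]),
                            collapse = "")
      rows <- which(copies$seq_index == s)
      m <- reverse_interval(copies$start[rows], copies$end[rows], L)
      copies$start[rows] <- m$start
      copies$end[rows] <- m$end
      copies$orientation[rows] <-
        ifelse(copies$orientation[rows] == "+", "-", "+")
    }

    records <- list()
    for (i in seq_len(n)) {
      for (j in i:n) {
        ci <- copies[copies$seq_index == i, , drop = FALSE]
        cj <- copies[copies$seq_index == j, , drop = FALSE]
        rows <- list()
        if (i == j) {
          rows[[1]] <- tibble::tibble(
            query_id = ids[j], target_id = ids[i],
            t_start = 0, t_end = seq_len_bp[i],
            q_start = 0, q_end = seq_len_bp[j],
            strand = "+", percent_identity = 100, source = "truth",
            n_matches = seq_len_bp[i], block_len = seq_len_bp[i])
        }
        for (a in seq_len(nrow(ci))) {
          bs <- if (i == j) seq_len(nrow(cj)) else seq_len(nrow(cj))
          for (b in bs) {
            if (i == j && b <= a) next  # one record per unordered copy pair
            if (ci$block_id[a] != cj$block_id[b]) next
            va <- vecs[[ci$vec[a]]]
            vb <- vecs[[cj$vec[b]]]
            matches <- sum(va == vb)
            len <- block_len[[ci$block_id[a]]]
            rows[[length(rows) + 1L]] <- tibble::tibble(
              query_id = ids[j], target_id = ids[i],
              t_start = ci$start[a], t_end = ci$end[a],
              q_start = cj$start[b], q_end = cj$end[b],
              strand = if (ci$orientation[a] == cj$orientation[b]) "+" else "-",
              percent_identity = 100 * matches / len, source = "truth",
              n_matches = matches, block_len = len)
          }
        }
        records[[pair_name(ids[i], ids[j])]] <-
          if (length(rows) == 0) {
            r <- empty_records(); r$n_matches <- numeric(0)
            r$block_len <- numeric(0); r
          } else {
            do.call(rbind, rows)
          }
      }
    }

    annotations <- lapply(seq_len(n), function(s) {
      rows <- copies[copies$seq_index == s &
                       copies$block_id %in% spec$annotate_blocks, , drop = FALSE]
      if (nrow(rows) == 0) return(empty_intervals())
      color <- rep(NA_character_, nrow(rows))
      if (!is.null(spec$annotation_colors)) {
        hit <- rows$block_id %in% names(spec$annotation_colors)
        color[hit] <- unname(spec$annotation_colors[rows$block_id[hit]])
      }
      tibble::tibble(sample_id = ids[s], start = rows$start, end = rows$end,
                     name = rows$block_id, color = color,
                     line = seq_len(nrow(rows)))
    })
    names(annotations) <- ids

    entries <- new_entries(ids, ids, NA_character_)
    entries$length <- as.integer(seq_len_bp)
    entries$seq_name <- ids
    entries$annotations <- annotations

    list(spec = spec, entries = entries,
         sequences = setNames(sequences, ids),
         annotations = annotations, records = records, copies = copies)
  })
}

#' Serialize alignment records as PAF lines
#'
#' Emits 12-column PAF with the exact `matches`/`block_len` counts, so the
#' percent identity survives the round trip.
#'
#' @param records record tibble carrying `n_matches` and `block_len`.
#' @param target_len,query_len sequence lengths (PAF columns 7 and 2).
#' @return character vector of PAF lines.
#' @export
format_paf <- function(records, target_len, query_len) {
  if (nrow(records) == 0) return(character(0))
  sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t60",
          records$query_id, as.integer(query_len),
          as.integer(records$q_start), as.integer(records$q_end),
          records$strand, records$target_id, as.integer(target_len),
          as.integer(records$t_start), as.integer(records$t_end),
          as.integer(records$n_matches), as.integer(records$block_len))
}

#' Serialize alignment records in the LastZ general dialect
#'
#' Header plus one row per record, with minus-strand query coordinates
#' converted back to strand-relative form (the inverse of what
#' [parse_lastz_general()] applies) and `id%` printed at full precision.
#'
#' @param records record tibble.
#' @param target_len,query_len sequence lengths (`size1`, `size2`).
#' @return character vector of lines (header first).
#' @export
format_lastz_general <- function(records, target_len, query_len) {
  header <- paste(c("#name1", "strand1", "size1", "zstart1", "end1",
                    "name2", "strand2", "size2", "zstart2+", "end2+", "id%"),
                  collapse = "\t")
  if (nrow(records) == 0) return(header)
  qs <- records$q_start; qe <- records$q_end
  minus <- records$strand == "-"
  if (any(minus)) {
    m <- reverse_interval(qs[minus], qe[minus], query_len)
    qs[minus] <- m$start; qe[minus] <- m$end
  }
  c(header, sprintf(
    "%s\t+\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%.17g%%",
    records$target_id, as.integer(target_len),
    as.integer(records$t_start), as.integer(records$t_end),
    records$query_id, records$strand, as.integer(query_len),
    as.integer(qs), as.integer(qe), records$percent_identity))
}

#' Write a generated locus to disk as pipeline inputs
#'
#' Creates per-sequence FASTA files, per-sequence BED files, a combined
#' multi-record FASTA, a combined BED, and a configuration table that
#' round-trips through [parse_config()].
#'
#' @param locus output of [generate_locus_set()].
#' @param dir destination directory (created if needed).
#' @param annotations include BED files and the `Annotation` column.
#' @param declared_strands optional named `+`/`-` vector filling the
#'   `Strand` column.
#' @return a list of paths: `config`, `fastas`, `beds`, `combined_fasta`,
#'   `combined_bed`, `dir`.
#' @export
write_locus <- function(locus, dir, annotations = TRUE,
                        declared_strands = NULL) {
  dir.create(file.path(dir, "seqs"), recursive = TRUE, showWarnings = FALSE)
  ids <- locus$entries$sample_id
  fastas <- character(0)
  beds <- character(0)
  bed_lines_all <- character(0)

  for (sid in ids) {
    fp <- file.path(dir, "seqs", paste0(sid, ".fasta"))
    writeLines(c(paste0(">", sid), chunk_fasta(locus$sequences[[sid]])), fp)
    fastas[sid] <- normalizePath(fp)
    iv <- locus$annotations[[sid]]
    if (annotations && nrow(iv) > 0) {
      lines <- format_bed(iv)
      bp <- file.path(dir, "seqs", paste0(sid, ".bed"))
      writeLines(lines, bp)
      beds[sid] <- normalizePath(bp)
      bed_lines_all <- c(bed_lines_all, lines)
    }
  }

  combined_fasta <- file.path(dir, "combined.fasta")
  writeLines(unlist(lapply(ids, function(sid)
    c(paste0(">", sid), chunk_fasta(locus$sequences[[sid]])))),
    combined_fasta)
  combined_bed <- NULL
  if (annotations && length(bed_lines_all) > 0) {
    combined_bed <- file.path(dir, "combined.bed")
    writeLines(bed_lines_all, combined_bed)
  }

  entries <- locus$entries
  entries$fasta_path <- unname(fastas[ids])
  entries$annotation_path <- ifelse(ids %in% names(beds),
                                    unname(beds[ids]), NA_character_)
  if (!is.null(declared_strands)) {
    entries$declared_strand <- ifelse(ids %in% names(declared_strands),
                                      unname(declared_strands[ids]),
                                      NA_character_)
  }
  config <- write_config(entries, file.path(dir, "config.tsv"))
  list(config = config, fastas = fastas, beds = beds,
       combined_fasta = combined_fasta, combined_bed = combined_bed,
       dir = dir)
}

chunk_fasta <- function(s, width = 80) {
  n <- nchar(s)
  substring(s, seq(1, n, width), pmin(seq(1, n, width) + width - 1, n))
}

format_bed <- function(iv) {
  has_color <- !is.na(iv$color)
  rgbv <- rep("0", nrow(iv))
  if (any(has_color)) {
    m <- grDevices::col2rgb(iv$color[has_color])
    rgbv[has_color] <- apply(m, 2, paste, collapse = ",")
  }
  name <- ifelse(is.na(iv$name), ".", iv$name)
  ifelse(has_color,
         sprintf("%s\t%d\t%d\t%s\t0\t+\t%d\t%d\t%s",
                 iv$sample_id, iv$start, iv$end, name,
                 iv$start, iv$end, rgbv),
         sprintf("%s\t%d\t%d\t%s", iv$sample_id, iv$start, iv$end, name))
}

#' Populate an alignment cache with ground-truth records
#'
#' Writes each pair's records in PAF form to [cache_path()] under
#' `out_dir`, so [run_pairwise_alignments()] loads them without invoking
#' any aligner.
#'
#' @param locus output of [generate_locus_set()].
#' @param out_dir the run output directory.
#' @param aligner cache dialect tag (PAF is written for `minimap2` and
#'   `mashmap`; the LastZ general dialect for `lastz`).
#' @return character vector of cache files written.
#' @export
write_truth_cache <- function(locus, out_dir, aligner = "minimap2") {
  dir.create(file.path(out_dir, "alignments"),
             recursive = TRUE, showWarnings = FALSE)
  ids <- locus$entries$sample_id
  len <- setNames(locus$entries$length, ids)
  written <- character(0)
  for (i in seq_along(ids)) {
    for (j in i:length(ids)) {
      rec <- locus$records[[pair_name(ids[i], ids[j])]]
      path <- cache_path(out_dir, ids[i], ids[j], aligner)
      lines <- if (aligner == "lastz") {
        format_lastz_general(rec, len[[i]], len[[j]])
      } else {
        format_paf(rec, len[[i]], len[[j]])
      }
      writeLines(lines, path)
      written <- c(written, path)
    }
  }
  written
}
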