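# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from stored data files.

options(dotquilt.quiet = TRUE)

# A minimal alignment-record tibble; spans default to simple blocks.
make_records <- function(target_id = "T", query_id = "Q",
                         t_start = 0, t_end = 100,
                         q_start = 0, q_end = 100,
                         strand = "+", pi = 100, source = "test") {
  n <- max(lengths(list(t_start, t_end, q_start, q_end, strand, pi)))
  tibble::tibble(
    query_id = rep_len(query_id, n), target_id = rep_len(target_id, n),
    t_start = rep_len(t_start, n), t_end = rep_len(t_end, n),
    q_start = rep_len(q_start, n), q_end = rep_len(q_end, n),
    strand = rep_len(strand, n),
    percent_identity = rep_len(pi, n), source = rep_len(source, n))
}

# Write a FASTA file with the given named sequences; returns its path.
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta"),
                        width = 60) {
  lines <- unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    n <- nchar(s)
    c(paste0(">", id),
      substring(s, seq(1, n, width), pmin(seq(1, n, width) + width - 1, n)))
  }))
  writeLines(lines, path)
  path
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Write a minimal config table; seqs is a named list of sequence strings.
write_tiny_config <- function(seqs, dir = tempfile(), strand = NULL,
                              sep = "\t", ext = ".tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(seqs)
  fastas <- vapply(ids, function(id) {
    write_fasta(seqs[id], file.path(dir, paste0(id, ".fa")))
  }, character(1))
  df <- data.frame(Fasta = fastas, SampleID = ids,
                   Label = paste("label", ids), check.names = FALSE)
  if (!is.null(strand)) df$Strand <- strand
  path <- file.path(dir, paste0("config", ext))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Entries tibble with lengths set directly (no files involved).
make_entries <- function(ids, lengths, declared = NA_character_) {
  e <- dotquilt:::new_entries(ids, ids, NA_character_,
                              declared_strand = declared)
  e$length <- as.integer(lengths)
  e$seq_name <- ids
  e$annotations <- rep(list(dotquilt:::empty_intervals()), length(ids))
  e
}

# A three-sequence locus small enough for per-test rendering.
tiny_locus_spec <- function(seed = 42) {
  locus_spec(
    seed = seed,
    block_library = tibble::tibble(block_id = c("X", "Y"),
                                   length = c(6000L, 8000L)),
    arrangements = list(
      tibble::tibble(block_id = c("X", "Y"), orientation = c("+", "+"),
                     divergence = c(0, 0)),
      tibble::tibble(block_id = c("Y", "X"), orientation = c("+", "-"),
                     divergence = c(0.05, 0.02)),
      tibble::tibble(block_id = c("X", "Y"), orientation = c("+", "+"),
                     divergence = c(0.01, 0.03))),
    spacer_len = 500,
    annotate_blocks = "X")
}
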