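# PAF / LastZ-general parsing, cache paths and aligner orchestration.

paf_line <- function(q = "Q", qlen = 1000, qs = 0, qe = 100, strand = "+",
                     t = "T", tlen = 1000, ts = 0, te = 100,
                     matches = 90, block = 100, extra = NULL) {
  paste(c(q, qlen, qs, qe, strand, t, tlen, ts, te, matches, block, 60,
          extra), collapse = "\t")
}

test_that("parse_paf computes percent identity from matches/block", {
  rec <- parse_paf(paf_line(matches = 90, block = 100), c("T", "Q"))
  expect_equal(rec$percent_identity, 90)
  expect_equal(rec$strand, "+")
  expect_equal(rec$t_start, 0)
  expect_equal(rec$q_end, 100)

  perfect <- parse_paf(paf_line(matches = 100, block = 100), c("T", "Q"))
  expect_equal(perfect$percent_identity, 100)
})

test_that("parse_paf keeps forward-strand query coords on minus records", {
  rec <- parse_paf(paf_line(strand = "-", qs = 200, qe = 300), c("T", "Q"))
  expect_equal(rec$strand, "-")
  expect_equal(c(rec$q_start, rec$q_end), c(200, 300))
})

test_that("parse_paf skips other pairs, zero blocks, and rejects short lines", {
  lines <- c(paf_line(), paf_line(q = "OTHER"), paf_line(t = "OTHER"))
  rec <- parse_paf(lines, c("T", "Q"))
  expect_equal(nrow(rec), 1L)

  expect_warning(z <- parse_paf(paf_line(matches = 0, block = 0), c("T", "Q")),
                 "block")
  expect_equal(nrow(z), 0L)

  expect_error(parse_paf("a\tb\tc", c("T", "Q")), "12",
               class = "dq_parse_error")
})

test_that("parse_paf honours a MashMap id:f tag over the column ratio", {
  rec <- parse_paf(paf_line(matches = 50, block = 100, extra = "id:f:97.5"),
                   c("T", "Q"))
  expect_equal(rec$percent_identity, 97.5)
  frac <- parse_paf(paf_line(matches = 50, block = 100, extra = "id:f:0.975"),
                    c("T", "Q"))
  expect_equal(frac$percent_identity, 97.5)
})

lastz_text <- function(rows,
                       fields = c("name1", "strand1", "size1", "zstart1",
                                  "end1", "name2", "strand2", "size2",
                                  "zstart2+", "end2+", "id%")) {
  c(paste0("#", paste(fields, collapse = "\t")), rows)
}

test_that("parse_lastz_general reads named columns and percent strings", {
  txt <- lastz_text("T\t+\t1000\t0\t100\tQ\t+\t500\t10\t110\t90.0%")
  rec <- parse_lastz_general(txt, c("T", "Q"))
  expect_equal(rec$percent_identity, 90)
  expect_equal(c(rec$t_start, rec$t_end), c(0, 100))
  expect_equal(c(rec$q_start, rec$q_end), c(10, 110))
})

test_that("minus-strand LastZ query coords are converted to forward strand", {
  # independent oracle: s' = L - e, e' = L - s with L = 100
  txt <- lastz_text("T\t+\t1000\t0\t10\tQ\t-\t100\t10\t20\t95%")
  rec <- parse_lastz_general(txt, c("T", "Q"))
  expect_equal(c(rec$q_start, rec$q_end), c(100 - 20, 100 - 10))
  expect_equal(rec$strand, "-")

  # no size2 column: query_length argument is required
  txt2 <- lastz_text("T\t0\t10\tQ\t-\t10\t20\t95%",
                     fields = c("name1", "zstart1", "end1", "name2",
                                "strand2", "zstart2+", "end2+", "id%"))
  rec2 <- parse_lastz_general(txt2, c("T", "Q"), query_length = 100)
  expect_equal(c(rec2$q_start, rec2$q_end), c(80, 90))
  expect_error(parse_lastz_general(txt2, c("T", "Q")), "size2",
               class = "dq_parse_error")
})

test_that("parse_lastz_general validates its header and id% range", {
  txt <- lastz_text("T\t+\t1000\t0\t100\tQ\t+\t500\t10\t110\t90.0%",
                    fields = c("name1", "strand1", "size1", "zstart1",
                               "end1", "name2", "strand2", "size2",
                               "zstart2+", "end2+", "identity"))
  expect_error(parse_lastz_general(txt, c("T", "Q")), "id%",
               class = "dq_parse_error")

  bad <- lastz_text("T\t+\t1000\t0\t100\tQ\t+\t500\t10\t110\t120%")
  expect_error(parse_lastz_general(bad, c("T", "Q")),
               class = "dq_validation_error")
})

test_that("the same alignments parse identically from PAF and LastZ dialects", {
  locus <- generate_locus_set(tiny_locus_spec())
  len <- setNames(locus$entries$length, locus$entries$sample_id)
  for (key in c("S1__S2", "S2__S3")) {
    rec <- locus$records[[key]]
    tid <- rec$target_id[1]; qid <- rec$query_id[1]
    from_paf <- parse_paf(format_paf(rec, len[[tid]], len[[qid]]),
                          c(tid, qid))
    from_lastz <- parse_lastz_general(
      format_lastz_general(rec, len[[tid]], len[[qid]]), c(tid, qid))
    cols <- c("t_start", "t_end", "q_start", "q_end", "strand")
    expect_equal(as.data.frame(from_paf[cols]),
                 as.data.frame(from_lastz[cols]))
    expect_equal(from_paf$percent_identity, from_lastz$percent_identity)
    expect_equal(nrow(from_paf), nrow(rec))  # conservation
  }
})

test_that("cache paths are deterministic, distinct, and collision-checked", {
  expect_identical(cache_path("out", "A", "B", "minimap2"),
                   cache_path("out", "A", "B", "minimap2"))
  expect_false(cache_path("out", "A", "B", "minimap2") ==
                 cache_path("out", "A", "C", "minimap2"))
  expect_false(cache_path("out", "A", "B", "minimap2") ==
                 cache_path("out", "A", "B", "lastz"))
  expect_error(cache_path("out", "a/b", "a_b", "minimap2"),
               class = "dq_validation_error")
})

test_that("cached alignments are reused with zero aligner invocations", {
  locus <- generate_locus_set(tiny_locus_spec())
  out <- tempfile(); dir.create(out)
  write_truth_cache(locus, out)
  sets <- run_pairwise_alignments(locus$entries, "minimap2", out)
  expect_equal(attr(sets, "n_aligner_calls"), 0L)
  expect_equal(length(sets), 6L)  # n(n+1)/2 for n = 3

  sets2 <- run_pairwise_alignments(locus$entries, "minimap2", out)
  expect_equal(attr(sets2, "n_aligner_calls"), 0L)
  for (k in names(sets)) {
    expect_equal(sets[[k]]$records, sets2[[k]]$records)
  }
})

test_that("an unparseable cache file errors by name, never regenerates", {
  locus <- generate_locus_set(tiny_locus_spec())
  out <- tempfile(); dir.create(out)
  write_truth_cache(locus, out)
  bad <- cache_path(out, "S1", "S2", "minimap2")
  writeLines("garbage line", bad)
  expect_error(run_pairwise_alignments(locus$entries, "minimap2", out),
               "S1__S2", class = "dq_io_error")
})

test_that("minimap2 is invoked for uncached pairs and results are cached", {
  locus <- generate_locus_set(tiny_locus_spec(seed = 11))
  dir <- tempfile()
  paths <- write_locus(locus, dir)
  entries <- load_lengths(parse_config(paths$config))
  out <- tempfile(); dir.create(out)
  sets <- run_pairwise_alignments(entries, "minimap2", out)
  expect_equal(attr(sets, "n_aligner_calls"), 6L)
  expect_equal(length(list.files(file.path(out, "alignments"))), 6L)
  # the shared X/Y blocks must be found between S1 and S3
  expect_gt(nrow(sets[["S1__S3"]]$records), 0)
  # second run: cache only
  sets2 <- run_pairwise_alignments(entries, "minimap2", out)
  expect_equal(attr(sets2, "n_aligner_calls"), 0L)
})
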