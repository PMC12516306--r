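# Orientation inference and coordinate reorientation.

test_that("orientation follows the strand with more aligned reference bp", {
  all_plus <- make_records("REF", "K", t_start = c(0, 500),
                           t_end = c(100, 900), strand = "+")
  d <- infer_orientation(all_plus, "K", "REF")
  expect_equal(d$strand, "+")
  expect_equal(d$basis, "inferred")
  expect_equal(d$forward_support, 500)
  expect_equal(d$reverse_support, 0)

  # one 50 kb minus record outweighs two plus records totalling 20 kb
  mixed <- make_records("REF", "K",
                        t_start = c(0, 0, 60000),
                        t_end = c(50000, 8000, 72000),
                        q_start = 0, q_end = 1000,
                        strand = c("-", "+", "+"))
  d2 <- infer_orientation(mixed, "K", "REF")
  expect_equal(d2$strand, "-")
  expect_equal(d2$forward_support, 20000)
  expect_equal(d2$reverse_support, 50000)
  # support conservation
  expect_equal(d2$forward_support + d2$reverse_support,
               sum(mixed$t_end - mixed$t_start))
})

test_that("no reference alignments falls back to '+' with a warning log", {
  d <- infer_orientation(make_records()[0, ], "K", "REF")
  expect_equal(d$strand, "+")
  expect_equal(d$basis, "fallback")
  expect_equal(d$forward_support + d$reverse_support, 0)
})

test_that("ties break to '+' and foreign pairs are a contract violation", {
  tie <- make_records("REF", "K", t_start = c(0, 200),
                      t_end = c(100, 300), strand = c("+", "-"))
  expect_equal(infer_orientation(tie, "K", "REF")$strand, "+")

  foreign <- make_records("OTHER", "K")
  expect_error(infer_orientation(foreign, "K", "REF"),
               class = "dq_contract_error")
})

test_that("declared strands win over inference; the reference is always '+'", {
  entries <- make_entries(c("R", "A", "B"), c(1000, 1000, 1000),
                          declared = c(NA, "-", NA))
  sets <- list()
  sets[[dotquilt:::pair_name("R", "A")]] <-
    alignment_set("R", "A", make_records("R", "A", strand = "+"))
  sets[[dotquilt:::pair_name("R", "B")]] <-
    alignment_set("R", "B", make_records("R", "B", strand = "-"))
  d <- resolve_orientations(entries, sets)
  expect_equal(d$R$strand, "+")
  expect_equal(d$A$strand, "-")   # declared beats the all-plus alignments
  expect_equal(d$A$basis, "declared")
  expect_equal(d$B$strand, "-")
  expect_equal(d$B$basis, "inferred")
})

test_that("reverse_interval maps, fixes symmetric intervals, and involutes", {
  expect_equal(reverse_interval(0, 10, 100), list(start = 90, end = 100))
  expect_equal(reverse_interval(40, 60, 100), list(start = 40, end = 60))
  expect_error(reverse_interval(-1, 10, 100), class = "dq_contract_error")
  expect_error(reverse_interval(5, 5, 100), class = "dq_contract_error")

  set.seed(1)
  for (k in 1:50) {
    L <- sample(10:10000, 1)
    s <- sample(0:(L - 2), 1)
    e <- sample((s + 1):L, 1)
    m <- reverse_interval(s, e, L)
    expect_true(m$start >= 0 && m$start < m$end && m$end <= L)
    back <- reverse_interval(m$start, m$end, L)
    expect_equal(c(back$start, back$end), c(s, e))
  }
})

test_that("reorienting alignments obeys the strand-parity law and involutes", {
  set.seed(2)
  rec <- make_records("T", "Q",
                      t_start = sample(0:400, 20), t_end = 0,
                      q_start = sample(0:400, 20), q_end = 0,
                      strand = sample(c("+", "-"), 20, replace = TRUE),
                      pi = runif(20, 80, 100))
  rec$t_end <- rec$t_start + sample(1:100, 20, replace = TRUE)
  rec$q_end <- rec$q_start + sample(1:100, 20, replace = TRUE)
  set <- alignment_set("T", "Q", rec)

  for (flips in list(c(FALSE, FALSE), c(TRUE, FALSE),
                     c(FALSE, TRUE), c(TRUE, TRUE))) {
    out <- reorient_alignments(set, flips[1], flips[2], 600, 600)
    expect_equal(nrow(out$records), nrow(rec))
    expect_equal(out$records$percent_identity, rec$percent_identity)
    # strand parity: final = original XOR flip_target XOR flip_query
    expected <- xor(rec$strand == "-", xor(flips[1], flips[2]))
    expect_equal(out$records$strand == "-", expected)
    # involution
    back <- reorient_alignments(out, flips[1], flips[2], 600, 600)
    expect_equal(back$records, rec)
  }

  # derived single case: '+' record, query flip only
  one <- alignment_set("T", "Q", make_records("T", "Q", t_start = 10,
                                              t_end = 60, q_start = 100,
                                              q_end = 150, strand = "+"))
  out <- reorient_alignments(one, FALSE, TRUE, 600, 600)
  expect_equal(out$records$strand, "-")
  expect_equal(c(out$records$q_start, out$records$q_end),
               c(600 - 150, 600 - 100))
  expect_equal(c(out$records$t_start, out$records$t_end), c(10, 60))
})

test_that("annotation reorientation preserves names/colors and involutes", {
  iv <- tibble::tibble(sample_id = "s", start = c(0L, 200L),
                       end = c(100L, 350L), name = c("g1", "g2"),
                       color = c("#008000", NA), line = 1:2)
  out <- reorient_annotations(iv, 1000)
  expect_equal(out$start, c(900L, 650L))
  expect_equal(out$end, c(1000L, 800L))
  expect_equal(out$name, iv$name)
  expect_equal(out$color, iv$color)
  expect_equal(reorient_annotations(out, 1000)$start, iv$start)

  empty <- iv[0, ]
  expect_equal(nrow(reorient_annotations(empty, 1000)), 0L)
  expect_error(reorient_annotations(iv, 300), class = "dq_contract_error")
})

test_that("reversing a sequence's input flips its inferred strand only", {
  # orientation stability: transform K's records as if the raw input of K
  # were reverse-complemented; the inference must flip
  rec <- make_records("REF", "K",
                      t_start = c(0, 3000), t_end = c(2000, 7000),
                      q_start = c(100, 4100), q_end = c(2100, 8100),
                      strand = c("+", "-"))
  before <- infer_orientation(rec, "K", "REF")
  flipped <- reorient_alignments(alignment_set("REF", "K", rec),
                                 FALSE, TRUE, 10000, 10000)
  after <- infer_orientation(flipped$records, "K", "REF")
  expect_true(before$strand != after$strand)
  expect_equal(before$forward_support, after$reverse_support)
  expect_equal(before$reverse_support, after$forward_support)
})
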