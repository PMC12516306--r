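# Display-orientation inference and coordinate reorientation.
#
# The first input sequence fixes the frame: every other sequence is shown
# forward or reverse-complemented depending on the strand carrying the bulk
# of its alignment to that reference. A declared Strand in the configuration
# always wins over inference.

#' Reverse a half-open interval on a sequence
#'
#' Maps `[start, end)` on a sequence of the given length to its coordinates
#' after reverse-complementing the sequence: `[length - end, length - start)`.
#' The operation is an involution. Vectorized over intervals.
#'
#' @param start,end 0-based half-open interval bounds (bp).
#' @param length sequence length (bp).
#' @return a list with elements `start` and `end` of the mapped interval.
#' @export
#' @examples
#' reverse_interval(0, 10, 100)   # [90, 100)
#' reverse_interval(40, 60, 100)  # fixed point of a symmetric interval
reverse_interval <- function(start, end, length) {
  if (any(start < 0) || any(start >= end) || any(end > length)) {
    dq_contract_error(sprintf(
      "interval [%s, %s) invalid on sequence of length %s",
      start[1], end[1], length[1]))
  }
  list(start = length - end, end = length - start)
}

orientation_decision <- function(sample_id, strand, basis,
                                 forward_support = 0, reverse_support = 0) {
  list(sample_id = sample_id, strand = strand, basis = basis,
       forward_support = forward_support, reverse_support = reverse_support)
}

#' Infer a sequence's display orientation from its reference alignments
#'
#' Sums the aligned target-span bp per strand over all alignments between
#' sequence `sample_id` and the reference. The sequence is reversed when the
#' minus strand carries strictly more aligned bp than the plus strand; ties
#' and an empty record set stay `+` (the empty case with `basis =
#' "fallback"` and a logged warning). Using the aggregate rather than the
#' single longest hit makes the call robust to one spurious long alignment.
#'
#' @param records alignment records between the reference (target) and
#'   `sample_id` (query).
#' @param sample_id the sequence being oriented.
#' @param reference_id the reference (first) sequence.
#' @return an orientation decision: list with `sample_id`, `strand`,
#'   `basis` (`"inferred"` or `"fallback"`), `forward_support`,
#'   `reverse_support` (bp).
#' @export
infer_orientation <- function(records, sample_id, reference_id) {
  if (nrow(records) > 0) {
    ok <- (records$target_id == reference_id & records$query_id == sample_id) |
      (records$target_id == sample_id & records$query_id == reference_id)
    if (!all(ok)) {
      dq_contract_error(sprintf(
        "records involve pairs other than (%s, %s)", reference_id, sample_id))
    }
  }
  if (nrow(records) == 0) {
    dq_log("WARN", "orient", sprintf(
      "'%s' has no alignments to reference '%s'; keeping '+'",
      sample_id, reference_id))
    return(orientation_decision(sample_id, "+", "fallback"))
  }
  span <- records$t_end - records$t_start
  fwd <- sum(span[records$strand == "+"])
  rev <- sum(span[records$strand == "-"])
  orientation_decision(sample_id, if (rev > fwd) "-" else "+",
                       "inferred", fwd, rev)
}

#' Resolve display orientations for all sequences
#'
#' The reference (order index 0) is always `+`. Any entry with a declared
#' strand keeps it (`basis = "declared"`); the rest are inferred from their
#' alignments to the reference via [infer_orientation()].
#'
#' @param entries entries tibble.
#' @param sets named list of alignment sets from
#'   [run_pairwise_alignments()].
#' @return a named list (by `sample_id`) of orientation decisions.
#' @export
resolve_orientations <- function(entries, sets) {
  entries <- entries[order(entries$order_index), , drop = FALSE]
  ref_id <- entries$sample_id[1]
  decisions <- list()
  for (i in seq_len(nrow(entries))) {
    sid <- entries$sample_id[i]
    d <- if (i == 1L) {
      orientation_decision(sid, "+", "reference")
    } else if (!is.na(entries$declared_strand[i])) {
      orientation_decision(sid, entries$declared_strand[i], "declared")
    } else {
      set <- sets[[pair_name(ref_id, sid)]]
      if (is.null(set)) {
        dq_contract_error(sprintf(
          "no alignment set for pair (%s, %s)", ref_id, sid))
      }
      infer_orientation(set$records, sid, ref_id)
    }
    dq_log("INFO", "orient", sprintf(
      "%s: strand %s (%s; +%g bp / -%g bp)",
      sid, d$strand, d$basis, d$forward_support, d$reverse_support))
    decisions[[sid]] <- d
  }
  decisions
}

#' Rewrite an alignment set after reversing one or both sequences
#'
#' Flipped sides have their coordinates mapped by [reverse_interval()]; the
#' strand toggles iff exactly one side flips. Record count and percent
#' identities are preserved; applying the same flips twice restores the
#' original set.
#'
#' @param set an [alignment_set()].
#' @param flip_target,flip_query whether each side is reversed.
#' @param target_len,query_len sequence lengths (bp).
#' @return the reoriented alignment set.
#' @export
reorient_alignments <- function(set, flip_target, flip_query,
                                target_len, query_len) {
  rec <- set$records
  if (nrow(rec) == 0 || (!flip_target && !flip_query)) return(set)
  if (flip_target) {
    m <- reverse_interval(rec$t_start, rec$t_end, target_len)
    rec$t_start <- m$start; rec$t_end <- m$end
  }
  if (flip_query) {
    m <- reverse_interval(rec$q_start, rec$q_end, query_len)
    rec$q_start <- m$start; rec$q_end <- m$end
  }
  if (xor(flip_target, flip_query)) {
    rec$strand <- ifelse(rec$strand == "+", "-", "+")
  }
  alignment_set(set$pair_key[["target_id"]], set$pair_key[["query_id"]], rec)
}

#' Rewrite annotation intervals after reversing their sequence
#'
#' Maps every interval by [reverse_interval()]; names and colors are kept.
#'
#' @param intervals annotation tibble (see [parse_bed()]).
#' @param length sequence length (bp).
#' @return the reoriented intervals.
#' @export
reorient_annotations <- function(intervals, length) {
  if (is.null(intervals) || nrow(intervals) == 0) return(intervals)
  bad <- which(intervals$end > length | intervals$start < 0)
  if (base::length(bad) > 0) {
    dq_contract_error(sprintf(
      "annotation interval [%d, %d)%s out of bounds for length %d",
      intervals$start[bad[1]], intervals$end[bad[1]],
      if (!is.na(intervals$name[bad[1]]))
        sprintf(" ('%s')", intervals$name[bad[1]]) else "",
      length))
  }
  m <- reverse_interval(intervals$start, intervals$end, length)
  intervals$start <- m$start
  intervals$end <- m$end
  intervals
}

#' Apply orientation decisions to all alignment sets and annotations
#'
#' Convenience pipeline step: every pair whose target and/or query sequence
#' is displayed reversed has its records rewritten by
#' [reorient_alignments()], and each reversed entry's annotations are
#' rewritten by [reorient_annotations()].
#'
#' @param entries entries tibble with lengths and annotations loaded.
#' @param sets named list of alignment sets.
#' @param decisions output of [resolve_orientations()].
#' @return list with reoriented `entries` and `sets`.
#' @export
apply_orientations <- function(entries, sets, decisions) {
  flip <- vapply(entries$sample_id,
                 function(s) decisions[[s]]$strand == "-", logical(1))
  len <- setNames(entries$length, entries$sample_id)
  sets <- lapply(sets, function(set) {
    t_id <- set$pair_key[["target_id"]]; q_id <- set$pair_key[["query_id"]]
    reorient_alignments(set, flip[[t_id]], flip[[q_id]],
                        len[[t_id]], len[[q_id]])
  })
  entries$annotations <- lapply(seq_len(nrow(entries)), function(i) {
    if (flip[i]) reorient_annotations(entries$annotations[[i]], entries$length[i])
    else entries$annotations[[i]]
  })
  list(entries = entries, sets = sets)
}
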