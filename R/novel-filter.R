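#' Candidate calls for novel miRNA discovery
#'
#' One row per (candidate, sample) detection emitted by a discovery tool:
#' the candidate id, its genomic coordinate (serialized
#' `chrom:start-end:strand`, 1-based inclusive), the tool's estimated
#' probability (percent) that the candidate is a true positive, the
#' detecting sample, the read support, and optionally the mature
#' sequence.
#'
#' @param candidate_id,sample_id Character vectors.
#' @param coordinate Coordinate strings `chrom:start-end:strand`.
#' @param probability Percent in `[0, 100]`.
#' @param read_support Non-negative integer read counts.
#' @param mature_sequence Optional RNA strings (`NA` allowed).
#' @return A `data.frame` of class `CandidateCalls`.
#' @export
candidate_calls <- function(candidate_id, coordinate, probability,
                            sample_id, read_support,
                            mature_sequence = NA_character_) {
  n <- length(candidate_id)
  out <- data.frame(candidate_id = as.character(candidate_id),
                    coordinate = as.character(coordinate),
                    probability = as.numeric(probability),
                    sample_id = as.character(sample_id),
                    read_support = as.integer(read_support),
                    mature_sequence = rep_len(as.character(mature_sequence), n),
                    stringsAsFactors = FALSE)
  if (any(out$probability < 0 | out$probability > 100, na.rm = TRUE))
    stopf("probabilities must lie in [0, 100]")
  if (any(out$read_support < 0, na.rm = TRUE))
    stopf("read_support must be non-negative")
  class(out) <- c("CandidateCalls", "data.frame")
  out
}

coordinate_pattern <- "^[A-Za-z0-9_.]+:[0-9]+-[0-9]+:[+-]$"

parse_coordinate <- function(coord) {
  if (!grepl(coordinate_pattern, coord)) return(NULL)
  parts <- strsplit(coord, ":", fixed = TRUE)[[1L]]
  span <- as.integer(strsplit(parts[2L], "-", fixed = TRUE)[[1L]])
  if (span[2L] < span[1L] || span[1L] < 1L) return(NULL)
  list(chrom = parts[1L], start = span[1L], end = span[2L],
       strand = parts[3L])
}

#' Filter novel miRNA candidates by probability and reproducibility
#'
#' Implements the two retention criteria for discovery-tool output: a
#' candidate is kept if it was called with an estimated true-positive
#' probability strictly above `min_probability` percent in at least
#' `min_samples` distinct samples ("more than three samples" read
#' literally as >= 4). With `mode = "per_sample"` (default, the stricter
#' reading) only calls individually above the probability bar count
#' toward the sample tally; `mode = "any"` requires one qualifying call
#' and counts every detecting sample. Records whose coordinate string is
#' malformed are rejected individually, with the reasons returned in the
#' `rejected` attribute. Candidate identity across samples is the exact
#' (candidate_id, coordinate) pair.
#'
#' @param calls A `CandidateCalls` table (or compatible data.frame).
#' @param min_probability Probability bar in percent (exclusive).
#' @param min_samples Minimum distinct detecting samples (inclusive).
#' @param mode `"per_sample"` or `"any"`; see above.
#' @return A `data.frame` with one row per retained candidate:
#'   `candidate_id`, `coordinate`, `n_samples_qualifying`,
#'   `max_probability`, ordered by candidate id. Attribute `rejected`
#'   lists per-record rejections.
#' @export
filter_novel_candidates <- function(calls, min_probability = 80,
                                    min_samples = 4L,
                                    mode = c("per_sample", "any")) {
  mode <- match.arg(mode)
  calls <- as.data.frame(calls)
  ok <- vapply(calls$coordinate, function(co) !is.null(parse_coordinate(co)),
               logical(1L), USE.NAMES = FALSE)
  rejected <- if (any(!ok)) {
    data.frame(candidate_id = calls$candidate_id[!ok],
               coordinate = calls$coordinate[!ok],
               reason = "malformed coordinate", stringsAsFactors = FALSE)
  } else {
    data.frame(candidate_id = character(0), coordinate = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  if (any(!ok))
    warnf("rejected %d call(s) with malformed coordinates", sum(!ok))
  calls <- calls[ok, , drop = FALSE]
  key <- paste(calls$candidate_id, calls$coordinate, sep = "\r")
  out <- lapply(sort(unique(key)), function(k) {
    sub <- calls[key == k, , drop = FALSE]
    qual <- sub[sub$probability > min_probability, , drop = FALSE]
    n_qual <- length(unique(qual$sample_id))
    keep <- if (mode == "per_sample") {
      n_qual >= min_samples
    } else {
      nrow(qual) >= 1L && length(unique(sub$sample_id)) >= min_samples
    }
    if (!keep) return(NULL)
    data.frame(candidate_id = sub$candidate_id[1L],
               coordinate = sub$coordinate[1L],
               n_samples_qualifying = if (mode == "per_sample") n_qual
                                      else length(unique(sub$sample_id)),
               max_probability = max(sub$probability),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(candidate_id = character(0), coordinate = character(0),
                      n_samples_qualifying = integer(0),
                      max_probability = numeric(0), stringsAsFactors = FALSE)
  attr(out, "rejected") <- rejected
  out
}

#' Summarize retained novel-miRNA candidates
#'
#' Per-candidate report over the retained set: coordinate, number of
#' distinct detecting samples, total read support, maximum probability,
#' and the mature sequence when available; rows in deterministic
#' candidate-id order.
#'
#' @param retained Output of [filter_novel_candidates()].
#' @param calls The full `CandidateCalls` table the filter saw.
#' @return A `data.frame`, one row per retained candidate (possibly
#'   empty, header always present).
#' @export
candidate_report <- function(retained, calls) {
  calls <- as.data.frame(calls)
  if (nrow(retained) == 0L) {
    return(data.frame(candidate_id = character(0), coordinate = character(0),
                      n_samples = integer(0), total_read_support = integer(0),
                      max_probability = numeric(0),
                      mature_sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(retained)), function(i) {
    sub <- calls[calls$candidate_id == retained$candidate_id[i] &
                 calls$coordinate == retained$coordinate[i], , drop = FALSE]
    seqs <- unique(sub$mature_sequence[!is.na(sub$mature_sequence)])
    data.frame(candidate_id = retained$candidate_id[i],
               coordinate = retained$coordinate[i],
               n_samples = length(unique(sub$sample_id)),
               total_read_support = sum(sub$read_support),
               max_probability = max(sub$probability),
               mature_sequence = if (length(seqs)) seqs[1L] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$candidate_id), , drop = FALSE]
}
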