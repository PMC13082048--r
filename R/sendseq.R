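# Paired 5'/3' RNA read classification against a two-orientation template:
# orientation by summed local-alignment score, then end-separation and
# start-site filters, and transcript-length profiling.

#' Local-alignment scoring parameters
#'
#' Affine-gap scores under the convention that the first position of a gap
#' scores `gap_open` and each subsequent position `gap_extend`.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (<= 0).
#' @param gap_open score of the first gap position (<= gap_extend).
#' @param gap_extend score of each further gap position (<= 0).
#' @return Object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -1, gap_open = -5,
                             gap_extend = -0.5) {
  if (match <= 0) .stopf("match score must be > 0")
  if (mismatch > 0) .stopf("mismatch score must be <= 0")
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    .stopf("need gap_open <= gap_extend <= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "alignment_params")
}

.check_seq <- function(s, what) {
  if (!nzchar(s)) .stopf("empty %s sequence", what)
  if (grepl("[^ACGTUacgtu]", s))
    .stopf("invalid character in %s sequence (allowed: A, C, G, T, U)", what)
  toupper(chartr("Uu", "Tt", s))  # U and T are equivalent
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Best local alignment of `query` against `reference`; returns the score
#' and one optimal reference interval, ties broken towards the smallest
#' reference start, then the shortest interval. U and T are treated as the
#' same character.
#'
#' @param query,reference sequences over A/C/G/T/U.
#' @param params an [alignment_params()].
#' @return List with `score`, `ref_start`, `ref_end` (1-based, closed;
#'   0/0 when no positive-scoring alignment exists).
#' @export
local_align <- function(query, reference, params = alignment_params()) {
  q <- .check_seq(query, "query"); r <- .check_seq(reference, "reference")
  v <- cpp_local_align(q, r, params$match, params$mismatch,
                       params$gap_open, params$gap_extend)
  list(score = v[1], ref_start = as.integer(v[2]), ref_end = as.integer(v[3]))
}

#' Template specification for read classification
#'
#' @param forward_rna,reverse_rna candidate RNA sequences for the two
#'   transcription directions (each in its own 5'->3' coordinates, position 1
#'   = its TSS).
#' @param forward_tss,reverse_tss 1-based TSS position on each RNA.
#' @param hairpin_region optional `c(start, end)` of the hairpin-encoding
#'   segment in forward-RNA template coordinates.
#' @param tss_window width (nt) of the accepted start-site window; a 5' end
#'   passes when `|pos - tss| <= tss_window / 2`.
#' @param min_end_separation minimal 5'-3' end distance (strictly greater
#'   than this passes).
#' @return Object of class `template_spec`.
#' @export
template_spec <- function(forward_rna, reverse_rna, forward_tss = 1,
                          reverse_tss = 1, hairpin_region = NULL,
                          tss_window = 10, min_end_separation = 15) {
  forward_rna <- .check_seq(forward_rna, "forward RNA")
  reverse_rna <- .check_seq(reverse_rna, "reverse RNA")
  if (!is.null(hairpin_region)) {
    stopifnot(length(hairpin_region) == 2)
    if (hairpin_region[1] < 1 || hairpin_region[2] > nchar(forward_rna) ||
        hairpin_region[1] > hairpin_region[2])
      .stopf("hairpin region outside template bounds")
  }
  structure(list(forward_rna = forward_rna, reverse_rna = reverse_rna,
                 forward_tss = forward_tss, reverse_tss = reverse_tss,
                 hairpin_region = hairpin_region, tss_window = tss_window,
                 min_end_separation = min_end_separation),
            class = "template_spec")
}

#' Classify one paired 5'/3' read against a template
#'
#' For each orientation, the total score is the best local alignment of the
#' 5' read plus the best local alignment of the 3' read against that
#' orientation's RNA; the higher-scoring orientation wins, and an exact tie
#' is ambiguous (unmapped). The 5' end is the aligned reference start of the
#' 5' read and the 3' end the aligned reference end of the 3' read. The end
#' separation must be strictly greater than `min_end_separation`, and the 5'
#' end must fall within half the TSS window of the TSS; failures are recorded
#' in `filters_failed` and set the orientation to `"unmapped"`.
#'
#' @param five_read,three_read read sequences.
#' @param template a [template_spec()].
#' @param params an [alignment_params()].
#' @param read_id read identifier.
#' @return Object of class `classified_read`: `read_id`, `orientation`
#'   (`"forward"`, `"reverse"` or `"unmapped"`), `five_prime`, `three_prime`
#'   (template coordinates), `score_forward`, `score_reverse`,
#'   `filters_failed` (character subset of `short_separation`, `tss_window`,
#'   `ambiguous`).
#' @export
classify_pair <- function(five_read, three_read, template,
                          params = alignment_params(), read_id = "read") {
  stopifnot(inherits(template, "template_spec"))
  score_orient <- function(rna) {
    a5 <- local_align(five_read, rna, params)
    a3 <- local_align(three_read, rna, params)
    list(score = a5$score + a3$score, five = a5$ref_start, three = a3$ref_end)
  }
  fwd <- score_orient(template$forward_rna)
  rev <- score_orient(template$reverse_rna)

  filters <- character(0)
  if (fwd$score == rev$score) {
    orientation <- "unmapped"; filters <- "ambiguous"
    best <- fwd; tss <- template$forward_tss
  } else if (fwd$score > rev$score) {
    orientation <- "forward"; best <- fwd; tss <- template$forward_tss
  } else {
    orientation <- "reverse"; best <- rev; tss <- template$reverse_tss
  }
  if (!"ambiguous" %in% filters) {
    if (!(best$three - best$five > template$min_end_separation))
      filters <- c(filters, "short_separation")
    if (!(abs(best$five - tss) <= template$tss_window / 2))
      filters <- c(filters, "tss_window")
    if (length(filters)) orientation <- "unmapped"
  }
  structure(list(read_id = read_id, orientation = orientation,
                 five_prime = best$five, three_prime = best$three,
                 score_forward = fwd$score, score_reverse = rev$score,
                 filters_failed = filters),
            class = "classified_read")
}

#' @export
print.classified_read <- function(x, ...) {
  cat(sprintf("classified_read %s: %s, 5' %d, 3' %d (F %.1f / R %.1f)%s\n",
              x$read_id, x$orientation, x$five_prime, x$three_prime,
              x$score_forward, x$score_reverse,
              if (length(x$filters_failed))
                paste0(" [", paste(x$filters_failed, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Classify a set of paired reads
#'
#' @param five_reads,three_reads character vectors of paired read sequences.
#' @param template a [template_spec()].
#' @param params an [alignment_params()].
#' @param read_ids optional identifiers.
#' @return data.frame with one row per pair (read_id, orientation,
#'   five_prime, three_prime, score_forward, score_reverse, filters_failed).
#' @export
classify_reads <- function(five_reads, three_reads, template,
                           params = alignment_params(), read_ids = NULL) {
  stopifnot(length(five_reads) == length(three_reads))
  if (is.null(read_ids)) read_ids <- sprintf("read%05d", seq_along(five_reads))
  rows <- lapply(seq_along(five_reads), function(i) {
    cr <- classify_pair(five_reads[i], three_reads[i], template, params,
                        read_id = read_ids[i])
    data.frame(read_id = cr$read_id, orientation = cr$orientation,
               five_prime = cr$five_prime, three_prime = cr$three_prime,
               score_forward = cr$score_forward,
               score_reverse = cr$score_reverse,
               filters_failed = paste(cr$filters_failed, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Transcript-length profiles and hairpin-boundary drop statistic
#'
#' Transcript length is `three_prime - five_prime + 1` per mapped read.
#' The drop statistic compares transcript coverage (the number of mapped
#' transcripts whose 3' end reaches at least a given position) averaged over
#' a 5-nt window just inside the hairpin boundary against the window just
#' outside: with 3' ends piling up at the boundary, coverage collapses
#' across it and the ratio is large; for uniform 3' ends it is close to 1.
#' The boundary defaults to the downstream edge of the template's hairpin
#' region and is evaluated on forward-orientation reads (whose coordinates
#' the region is given in).
#'
#' @param reads data.frame from [classify_reads()].
#' @param template a [template_spec()].
#' @param boundary override the boundary position (template coordinates).
#' @param window window width each side (nt, default 5).
#' @return List with `lengths` (per orientation), `three_prime_hist`
#'   (per-orientation tables), `drop_statistic` (NA when no boundary is
#'   known), `n_mapped`.
#' @export
length_profiles <- function(reads, template, boundary = NULL, window = 5) {
  stopifnot(is.data.frame(reads), inherits(template, "template_spec"))
  mapped <- reads[reads$orientation %in% c("forward", "reverse"), ,
                  drop = FALSE]
  if (nrow(mapped) == 0L) .stopf("no mapped reads")
  lens <- split(mapped$three_prime - mapped$five_prime + 1L,
                mapped$orientation)
  hist3 <- lapply(split(mapped$three_prime, mapped$orientation), table)

  if (is.null(boundary) && !is.null(template$hairpin_region))
    boundary <- template$hairpin_region[2]
  drop_stat <- NA_real_
  if (!is.null(boundary)) {
    fw <- mapped$three_prime[mapped$orientation == "forward"]
    coverage <- function(pos) sum(fw >= pos)
    inside <- mean(vapply(seq(boundary - window + 1, boundary), coverage,
                          numeric(1)))
    outside <- mean(vapply(seq(boundary + 1, boundary + window), coverage,
                           numeric(1)))
    drop_stat <- if (outside == 0) {
      if (inside == 0) NA_real_ else Inf
    } else inside / outside
  }
  list(lengths = lens, three_prime_hist = hist3,
       drop_statistic = drop_stat, n_mapped = nrow(mapped))
}

#' Welch comparison of two transcript-length samples
#'
#' Delegates to [compare_conditions()] without multiple-testing correction.
#'
#' @param a,b numeric length samples (each n >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
compare_length_distributions <- function(a, b) {
  res <- compare_conditions(list(a = a, b = b), correct = FALSE)
  list(t = res$t[1], df = res$df[1], p = res$p[1])
}

#' Read sequences from a FASTA or FASTQ file
#'
#' Minimal reader for the plain-text read files used by the classifier;
#' returns a named character vector of sequences.
#'
#' @param path path to a FASTA or FASTQ file (uncompressed).
#' @return Named character vector.
#' @export
read_seqs <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) .stopf("empty sequence file '%s'", path)
  if (startsWith(lines[1], "@")) {           # FASTQ: 4-line records
    if (length(lines) %% 4 != 0) .stopf("malformed FASTQ '%s'", path)
    ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
    seqs <- lines[seq(2, length(lines), by = 4)]
  } else if (startsWith(lines[1], ">")) {    # FASTA
    hdr <- grepl("^>", lines)
    ids <- sub("^>", "", lines[hdr])
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                   collapse = "")
  } else .stopf("'%s' is neither FASTA nor FASTQ", path)
  setNames(seqs, sub("\\s.*$", "", ids))
}
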