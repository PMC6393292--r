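#' Classify the junctions between adjacent same-strand fragments
#'
#' Within each (chromosome, strand) group, fragments sorted by start are
#' paired with their genomic neighbor and the junction between them is
#' labeled from the coordinates: `nick` when the intervals abut exactly
#' (`right.start == left.end`, i.e. 3'-OH and 5'-phosphate precisely
#' juxtaposed), `gap` when separated by >= 1 nt, `flap_overlap` when the
#' intervals overlap.  When a simulated `junction_state` is present on the
#' 5'-side fragment of the pair it is used directly as the label, and the
#' coordinate-derived label is retained for cross-checking (mismatch count in
#' attribute `state_coordinate_mismatches`).
#'
#' @param fragments a fragment `data.frame`, sorted by start within each
#'   (chrom, strand) group (unsorted input is an error).
#' @return a `data.frame` with one row per adjacent same-group pair: `left`,
#'   `right` (row indices into `fragments`, genomic order), `label`,
#'   `separation` (`right.start - left.end`, 0 = abutting) and
#'   `coordinate_label`.
#' @export
classify_junctions <- function(fragments) {
  validate_fragments(fragments)
  n <- nrow(fragments)
  if (n < 2) {
    return(data.frame(left = integer(0), right = integer(0),
                      label = character(0), separation = integer(0),
                      coordinate_label = character(0),
                      stringsAsFactors = FALSE))
  }
  grp <- paste(fragments$chrom, fragments$strand, sep = "\r")
  idx_by_grp <- split(seq_len(n), grp)
  left <- integer(0); right <- integer(0)
  for (ix in idx_by_grp) {
    if (is.unsorted(fragments$start[ix])) {
      stop("fragments must be sorted by start within each (chrom, strand) group")
    }
    if (length(ix) >= 2) {
      left <- c(left, ix[-length(ix)])
      right <- c(right, ix[-1])
    }
  }
  if (!length(left)) {
    return(data.frame(left = integer(0), right = integer(0),
                      label = character(0), separation = integer(0),
                      coordinate_label = character(0),
                      stringsAsFactors = FALSE))
  }
  sep <- fragments$start[right] - fragments$end[left]
  coord_label <- ifelse(sep == 0L, "nick",
                        ifelse(sep > 0L, "gap", "flap_overlap"))
  # the fragment whose 5' end sits at the junction: genomic right on "+"
  # (its 5' start meets the left fragment's 3' end), genomic left on "-"
  five_side <- ifelse(fragments$strand[left] == "+", right, left)
  state <- if ("junction_state" %in% names(fragments)) {
    fragments$junction_state[five_side]
  } else {
    rep(NA_character_, length(left))
  }
  label <- ifelse(is.na(state), coord_label,
                  ifelse(state == "flap", "flap_overlap", state))
  out <- data.frame(left = left, right = right, label = label,
                    separation = as.integer(sep),
                    coordinate_label = coord_label,
                    stringsAsFactors = FALSE)
  out <- out[order(out$left), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "state_coordinate_mismatches") <-
    sum(!is.na(state) & label != coord_label)
  out
}

#' Merge ligatable nicks in silico
#'
#' Models treating purified fragments with DNA ligase: every maximal run of
#' same-strand neighbors joined by `nick` junctions is replaced by a single
#' merged record spanning the run; `gap` and `flap_overlap` junctions are not
#' ligatable and are left alone.  Merging repeats until no nick junction
#' remains: a merged product whose new 3' end comes to abut a downstream 5'
#' start is itself ligatable and is sealed too (this only arises through
#' coordinate-derived labels on overlapping input; junction-state-annotated
#' data converges in one pass, where the output count equals the input count
#' minus the number of nick junctions).  The operation is idempotent.
#'
#' @param fragments a fragment `data.frame`, sorted as for
#'   [classify_junctions()].
#' @return the ligated fragment `data.frame`, genome-sorted.  The merged
#'   record keeps the junction annotation of the synthesis-most-upstream (5')
#'   constituent, since that junction is the one still unsealed.
#' @export
ligate_in_silico <- function(fragments) {
  validate_fragments(fragments)
  repeat {
    out <- ligate_pass(fragments)
    if (nrow(out) == nrow(fragments)) return(out)
    fragments <- out
  }
}

ligate_pass <- function(fragments) {
  n <- nrow(fragments)
  if (n < 2) return(fragments)
  junc <- classify_junctions(fragments)
  # nick junctions join neighbors within a (chrom, strand) group, so the
  # components to merge are maximal runs in group order
  nick_with_prev <- logical(n)
  nick_with_prev[junc$right[junc$label == "nick"]] <- TRUE
  grp <- paste(fragments$chrom, fragments$strand, sep = "\r")
  idx <- unlist(split(seq_len(n), grp), use.names = FALSE)
  run_id <- cumsum(!nick_with_prev[idx])
  runs <- split(idx, run_id)
  start_m <- vapply(runs, function(ix) min(fragments$start[ix]), integer(1))
  end_m <- vapply(runs, function(ix) max(fragments$end[ix]), integer(1))
  # 5'-most constituent (smallest start on "+", largest end on "-") keeps its
  # junction annotation: that junction is the one still unsealed
  head_i <- vapply(runs, function(ix) {
    if (fragments$strand[ix[1]] == "+") {
      ix[which.min(fragments$start[ix])]
    } else {
      ix[which.max(fragments$end[ix])]
    }
  }, integer(1))
  out <- fragments[head_i, , drop = FALSE]
  out$start <- start_m
  out$end <- end_m
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-labeling signal within a size window
#'
#' Each fragment carries one labeled end, so the gel signal in the quantified
#' region is the number of fragments shorter than the size cutoff.
#'
#' @param fragments a fragment `data.frame`.
#' @param size_cutoff exclusive length cutoff in nt (default 1000, the
#'   quantified sub-kilobase region).
#' @return integer count of fragments with `length < size_cutoff`.
#' @export
end_label_signal <- function(fragments, size_cutoff = 1000L) {
  validate_fragments(fragments)
  if (size_cutoff < 1) stop("size_cutoff must be >= 1")
  sum(fragments$end - fragments$start < size_cutoff)
}

#' Quantify the end-labeling signal lost upon ligation
#'
#' Compares the labeled signal below the size cutoff before and after
#' in-silico ligation.  Merged products that exceed the cutoff exit the
#' quantified region: that loss is the readout of how many fragments were
#' poised for ligation.
#'
#' @param pre_fragments fragments before ligation.
#' @param post_fragments the result of [ligate_in_silico()] on
#'   `pre_fragments`.
#' @param size_cutoff exclusive length cutoff in nt (default 1000).
#' @param replicate_id identifier carried into the report.
#' @return a one-row `data.frame` (a ligation report): `replicate_id`,
#'   `n_fragments_pre`, `n_fragments_post`, `signal_pre`, `signal_post`,
#'   `size_cutoff`, `percent_lost` = `100 * (signal_pre - signal_post) /
#'   signal_pre`.
#' @export
percent_signal_lost <- function(pre_fragments, post_fragments,
                                size_cutoff = 1000L, replicate_id = "rep1") {
  signal_pre <- end_label_signal(pre_fragments, size_cutoff)
  signal_post <- end_label_signal(post_fragments, size_cutoff)
  if (signal_pre == 0) stop("no signal below the size cutoff before ligation")
  data.frame(
    replicate_id = replicate_id,
    n_fragments_pre = nrow(pre_fragments),
    n_fragments_post = nrow(post_fragments),
    signal_pre = signal_pre,
    signal_post = signal_post,
    size_cutoff = as.integer(size_cutoff),
    percent_lost = 100 * (signal_pre - signal_post) / signal_pre,
    stringsAsFactors = FALSE
  )
}

#' Paired t-test for ligase-treated vs untreated replicates
#'
#' Standard paired two-sided t-test on per-replicate signal values without
#' and with ligase treatment (`df = n - 1`).
#'
#' @param value_minus_ligase numeric vector, one value per replicate.
#' @param value_plus_ligase numeric vector, same length and pairing.
#' @return list with `t`, `df` and two-sided `p` for the mean difference
#'   (minus - plus).
#' @export
paired_t_test <- function(value_minus_ligase, value_plus_ligase) {
  if (length(value_minus_ligase) != length(value_plus_ligase)) {
    stop("paired samples must have equal length")
  }
  if (length(value_minus_ligase) < 2) stop("need at least 2 replicate pairs")
  d <- value_minus_ligase - value_plus_ligase
  if (stats::var(d) == 0) stop("zero variance of paired differences")
  res <- stats::t.test(value_minus_ligase, value_plus_ligase, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
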