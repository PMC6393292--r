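#' Construct a set of oriented point features
#'
#' A feature set holds reference points for meta-profiles: nucleosome dyad
#' midpoints with an occupancy score, or transcription-factor binding-site
#' midpoints.  Midpoints are 0-based positions, unique per chromosome.
#'
#' @param chrom character vector of chromosome names.
#' @param midpoint integer vector of 0-based positions.
#' @param score numeric occupancy / binding strength (>= 0); mandatory for
#'   nucleosome dyads.
#' @param orientation character, each `"+"`, `"-"` or `"none"`.
#' @param kind `"nucleosome_dyad"` or `"tf_site"`.
#' @return a `data.frame` with columns `chrom`, `midpoint`, `score`,
#'   `orientation` and attribute `kind`.
#' @export
feature_set <- function(chrom, midpoint, score = NULL, orientation = NULL,
                        kind = c("nucleosome_dyad", "tf_site")) {
  kind <- match.arg(kind)
  n <- length(chrom)
  if (is.null(orientation)) orientation <- rep("none", n)
  if (is.null(score)) {
    if (kind == "nucleosome_dyad" && n > 0) {
      stop("nucleosome_dyad features require an occupancy score")
    }
    score <- rep(NA_real_, n)
  }
  df <- data.frame(
    chrom = as.character(chrom),
    midpoint = as.integer(midpoint),
    score = as.numeric(score),
    orientation = as.character(orientation),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    if (kind == "nucleosome_dyad" && any(is.na(df$score))) {
      stop("nucleosome_dyad features require an occupancy score")
    }
    if (any(!is.na(df$score) & df$score < 0)) stop("feature scores must be >= 0")
    if (!all(df$orientation %in% c("+", "-", "none"))) {
      stop("feature orientation must be '+', '-' or 'none'")
    }
    if (anyDuplicated(df[c("chrom", "midpoint")])) {
      stop("feature midpoints must be unique per (chrom, midpoint)")
    }
  }
  attr(df, "kind") <- kind
  df
}

#' Kind of a feature set
#' @param features a feature `data.frame` from [feature_set()].
#' @return `"nucleosome_dyad"` or `"tf_site"`.
#' @export
feature_kind <- function(features) {
  k <- attr(features, "kind", exact = TRUE)
  if (is.null(k)) stop("not a feature set: missing 'kind' attribute")
  k
}

#' Read point features from a BED file
#'
#' Features may be encoded as 1-bp intervals `[m, m+1)` or as wider intervals
#' whose midpoint `(start + end) %/% 2` is taken (`midpoint_mode`).  Scores
#' come from BED column 5 and orientation from column 6 (`"."` mapping to
#' `"none"`).
#'
#' @param path path to a BED file with >= 3 columns.
#' @param kind `"nucleosome_dyad"` or `"tf_site"`.
#' @param midpoint_mode if `TRUE` (default), wider intervals are collapsed to
#'   their integer midpoint; if `FALSE`, intervals must be exactly 1 bp.
#' @return a feature `data.frame` (see [feature_set()]).
#' @export
read_features <- function(path, kind = c("nucleosome_dyad", "tf_site"),
                          midpoint_mode = TRUE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("feature file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(feature_set(character(0), integer(0),
                       score = numeric(0), kind = kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  }
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default,
           character(1))
  }
  chrom <- get(1)
  start <- as.integer(get(2))
  end <- as.integer(get(3))
  if (!midpoint_mode && any(end - start != 1L)) {
    stop("feature intervals must be exactly 1 bp wide when midpoint_mode = FALSE")
  }
  midpoint <- (start + end) %/% 2L
  score_raw <- get(5)
  score <- suppressWarnings(as.numeric(score_raw))
  if (kind == "nucleosome_dyad" && any(is.na(score))) {
    stop("nucleosome_dyad BED requires a numeric score in column 5")
  }
  orientation <- get(6)
  orientation[is.na(orientation) | orientation == "."] <- "none"
  feature_set(chrom, midpoint, score = score, orientation = orientation,
              kind = kind)
}

#' Write point features to BED
#'
#' Each feature is written as a 1-bp interval `[m, m+1)`; orientation `"none"`
#' becomes `"."`.
#'
#' @param features a feature `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  kind <- feature_kind(features)
  if (nrow(features) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- ifelse(is.na(features$score), 0, features$score)
  strand <- ifelse(features$orientation == "none", ".", features$orientation)
  writeLines(paste(features$chrom, features$midpoint, features$midpoint + 1L,
                   paste0(substr(kind, 1, 1), seq_len(nrow(features))),
                   format_bed_score(score), strand, sep = "\t"),
             path)
  invisible(path)
}

#' Keep the most highly occupied nucleosome dyads
#'
#' Returns the `ceiling(fraction * n)` highest-scoring dyads.  Ties at the
#' score cutoff are broken by `(chrom, midpoint)` lexicographic order so the
#' selection is deterministic.
#'
#' @param features a nucleosome-dyad feature `data.frame` with scores.
#' @param fraction fraction of features to keep, in `(0, 1]` (default 0.5,
#'   the top half by occupancy).
#' @return the filtered feature `data.frame`, in `(chrom, midpoint)` order.
#' @export
select_top_occupied <- function(features, fraction = 0.5) {
  if (feature_kind(features) != "nucleosome_dyad") {
    stop("select_top_occupied applies to nucleosome_dyad features")
  }
  if (nrow(features) == 0) stop("empty feature set")
  if (any(is.na(features$score))) stop("occupancy scores required")
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be a single value in (0, 1]")
  }
  k <- ceiling(fraction * nrow(features))
  ord <- order(-features$score, features$chrom, features$midpoint)
  out <- features[sort(ord[seq_len(k)]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kind") <- feature_kind(features)
  out
}

#' Mirror features through the right end of each chromosome
#'
#' Counterpart of [mirror_fragments()]: midpoints map to `L - 1 - m` and
#' stranded orientations flip.
#'
#' @param features a feature `data.frame`.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return the mirrored feature `data.frame`.
#' @export
mirror_features <- function(features, chrom_lengths) {
  kind <- feature_kind(features)
  if (nrow(features) == 0) return(features)
  L <- chrom_lengths[features$chrom]
  if (any(is.na(L))) stop("chrom_lengths missing a chromosome present in features")
  out <- features
  out$midpoint <- as.integer(L - 1L - features$midpoint)
  out$orientation <- ifelse(features$orientation == "+", "-",
                            ifelse(features$orientation == "-", "+", "none"))
  attr(out, "kind") <- kind
  out
}
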