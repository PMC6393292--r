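#' Terminus meta-profiles around genomic point features
#'
#' A terminus profile holds, for each integer offset in `-window..+window`,
#' the aggregate signal of fragment 5' or 3' termini relative to feature
#' midpoints.  Offsets are in synthesis orientation: for a `+`-strand
#' fragment the offset is `terminus - midpoint`, for a `-`-strand fragment it
#' is `midpoint - terminus`, so Okazaki fragment synthesis always proceeds
#' toward positive offsets and profiles read left to right in fork direction.
#'
#' @name terminus_profile
#' @keywords internal
NULL

new_terminus_profile <- function(feature_kind, end_kind, window, values,
                                 raw_counts, n_features, n_termini,
                                 normalization = "raw", smoothing_bp = 1L) {
  stopifnot(length(values) == 2L * window + 1L)
  structure(
    list(
      feature_kind = feature_kind,
      end_kind = end_kind,
      window = as.integer(window),
      offsets = seq.int(-window, window),
      values = as.numeric(values),
      raw_counts = as.numeric(raw_counts),
      n_features = as.integer(n_features),
      n_termini = as.integer(n_termini),
      normalization = normalization,
      smoothing_bp = as.integer(smoothing_bp)
    ),
    class = "terminus_profile"
  )
}

#' @export
print.terminus_profile <- function(x, ...) {
  cat(sprintf(
    "terminus_profile: %s termini around %s features\n  window +/-%d nt, %d features, %d terminus-feature pairs\n  normalization: %s, smoothing: %d bp\n",
    sub("_", " ", x$end_kind), sub("_", " ", x$feature_kind), x$window,
    x$n_features, x$n_termini, x$normalization, x$smoothing_bp))
  invisible(x)
}

#' Aggregate fragment termini around features
#'
#' For each fragment terminus of the requested kind and each feature on the
#' same chromosome within `window` nt, one count is added at the
#' synthesis-oriented offset.  A terminus lying within the window of several
#' features contributes to each of them; `n_termini` therefore counts
#' terminus-feature pairs and equals the profile sum.
#'
#' @param fragments a fragment `data.frame`.
#' @param features a feature `data.frame` (non-empty).
#' @param end_kind `"five_prime"` or `"three_prime"`.
#' @param window half-window `W` in nt (>= 1); offsets run `-W..W`.
#' @return a raw `terminus_profile`.  An empty fragment set yields an
#'   all-zero profile flagged with attribute `empty_input`.
#' @export
aggregate_termini <- function(fragments, features,
                              end_kind = c("five_prime", "three_prime"),
                              window = 100L) {
  end_kind <- match.arg(end_kind)
  fkind <- feature_kind(features)
  if (nrow(features) == 0) stop("empty feature set")
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  nbin <- 2L * window + 1L
  counts <- numeric(nbin)
  n_pairs <- 0L
  if (nrow(fragments) > 0) {
    term <- fragment_termini(fragments)
    pos <- term[[end_kind]]
    plus <- term$strand == "+"
    for (ch in unique(term$chrom)) {
      mids <- sort(features$midpoint[features$chrom == ch])
      if (!length(mids)) next
      sel <- which(term$chrom == ch)
      p <- pos[sel]
      lo <- findInterval(p - window - 0.5, mids) + 1L
      hi <- findInterval(p + window + 0.5, mids)
      k <- hi - lo + 1L
      keep <- k > 0L
      if (!any(keep)) next
      idx <- sequence(k[keep], from = lo[keep])
      term_rep <- rep(sel[keep], k[keep])
      off <- pos[term_rep] - mids[idx]
      off[!plus[term_rep]] <- -off[!plus[term_rep]]
      counts <- counts + tabulate(off + window + 1L, nbins = nbin)
      n_pairs <- n_pairs + length(off)
    }
  }
  p <- new_terminus_profile(fkind, end_kind, window, counts, counts,
                            n_features = nrow(features), n_termini = n_pairs)
  if (nrow(fragments) == 0) attr(p, "empty_input") <- TRUE
  p
}

#' Smooth a profile with a centered moving average
#'
#' The window must be odd so it has an unambiguous center.  At the profile
#' edges the window truncates to the available offsets and the average is
#' taken over the truncated window, so total mass is not conserved there.
#'
#' @param profile a `terminus_profile`.
#' @param bp smoothing window width in bp, odd and >= 1 (`bp = 1` is the
#'   identity); 5 bp is the conventional display smoothing.
#' @return the smoothed profile (raw counts retained unsmoothed).
#' @export
smooth_profile <- function(profile, bp = 5L) {
  stopifnot(inherits(profile, "terminus_profile"))
  bp <- as.integer(bp)
  if (bp < 1) stop("smoothing width must be >= 1")
  if (bp %% 2L == 0L) stop("smoothing width must be odd (ambiguous center)")
  out <- profile
  out$values <- moving_average(profile$values, bp)
  out$smoothing_bp <- bp
  out
}

moving_average <- function(x, bp) {
  if (bp == 1L) return(x)
  h <- (bp - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Normalize a profile to its maximum or median
#'
#' Max normalization (`mode = "max"`) rescales so the largest value in the
#' range is exactly 1 — the convention for dyad profiles.  Median
#' normalization rescales so the median over the range is exactly 1 — the
#' convention for TF-site profiles, where enrichment is judged against
#' surrounding sequence.
#'
#' @param profile a `terminus_profile`.
#' @param mode `"max"` or `"median"`.
#' @return the normalized profile.
#' @export
normalize_profile <- function(profile, mode = c("max", "median")) {
  stopifnot(inherits(profile, "terminus_profile"))
  mode <- match.arg(mode)
  v <- profile$values
  if (all(v == 0)) stop("cannot normalize an all-zero profile")
  denom <- if (mode == "max") max(v) else stats::median(v)
  if (denom <= 0) {
    stop("cannot median-normalize: median of the range is zero while the maximum is nonzero")
  }
  out <- profile
  out$values <- v / denom
  out$normalization <- mode
  out
}

#' Offset of the profile maximum
#'
#' Ties are broken toward the smallest absolute offset, then toward the
#' negative (fork-proximal) one.
#'
#' @param profile a non-zero `terminus_profile`.
#' @return integer offset of the peak, in synthesis orientation.
#' @export
profile_peak_offset <- function(profile) {
  stopifnot(inherits(profile, "terminus_profile"))
  v <- profile$values
  if (all(v == 0)) stop("all-zero profile has no peak")
  cand <- which(v == max(v))
  off <- profile$offsets[cand]
  off[order(abs(off), off)][1]
}

# Cross-correlation shift core: argmax over integer lags of the correlation
# between two max-normalized signals, refined to sub-bin resolution by
# parabolic interpolation around the best lag.
xcorr_shift <- function(a, b, max_lag) {
  a <- a / max(a)
  b <- b / max(b)
  n <- length(a)
  lags <- seq.int(-max_lag, max_lag)
  cc <- vapply(lags, function(d) {
    if (d >= 0) {
      ka <- seq_len(n - d)
      sum(a[ka] * b[ka + d])
    } else {
      kb <- seq_len(n + d)
      sum(a[kb - d] * b[kb])
    }
  }, numeric(1))
  i <- which.max(cc)
  best <- lags[i]
  if (i > 1 && i < length(lags)) {
    y1 <- cc[i - 1]; y2 <- cc[i]; y3 <- cc[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) best <- best + 0.5 * (y1 - y3) / denom
  }
  best
}

#' Estimate the displacement between two profiles
#'
#' Cross-correlates the two max-normalized profiles over integer lags and
#' refines the best lag by parabolic interpolation.  Negative values mean
#' profile `b` is displaced toward negative offsets — the fork-proximal
#' direction — relative to `a`; cross-correlation rather than a peak or mean
#' difference keeps the estimate robust to changes in peak shape between
#' conditions.
#'
#' @param a,b `terminus_profile`s with identical feature kind, end kind,
#'   window and smoothing.
#' @param max_lag largest lag searched, in nt (default half the window).
#' @return shift estimate in nt (real-valued).
#' @export
compare_profiles <- function(a, b, max_lag = NULL) {
  stopifnot(inherits(a, "terminus_profile"), inherits(b, "terminus_profile"))
  if (a$window != b$window) stop("profile window mismatch")
  if (a$feature_kind != b$feature_kind) stop("profile feature_kind mismatch")
  if (a$end_kind != b$end_kind) stop("profile end_kind mismatch")
  if (a$smoothing_bp != b$smoothing_bp) stop("profile smoothing mismatch")
  if (all(a$values == 0) || all(b$values == 0)) stop("all-zero profile")
  if (is.null(max_lag)) max_lag <- a$window %/% 2L
  xcorr_shift(a$values, b$values, as.integer(max_lag))
}

#' 5'/3' end decoupling statistic
#'
#' Reduced nick translation moves 5' and 3' termini together (their profiles
#' stay superimposable up to the fragment length); ongoing strand
#' displacement without cleavage leaves 3' ends in place while 5' ends move
#' upstream, so the two profiles peak at different points.  The statistic is
#' the displacement of the 5' profile relative to the 3' profile, estimated
#' by cross-correlation.
#'
#' @param p5 a `five_prime` profile.
#' @param p3 a `three_prime` profile over the same features, window and
#'   smoothing.
#' @param threshold decoupling call threshold in nt (default 5): verdict is
#'   `"decoupled"` iff `|delta| > threshold`.
#' @return list with `delta` (nt, negative = 5' ends displaced fork-proximal
#'   of 3' ends) and `verdict` (`"coupled"` or `"decoupled"`).
#' @export
end_decoupling_statistic <- function(p5, p3, threshold = 5) {
  stopifnot(inherits(p5, "terminus_profile"), inherits(p3, "terminus_profile"))
  if (p5$end_kind != "five_prime" || p3$end_kind != "three_prime") {
    stop("end_decoupling_statistic requires a five_prime and a three_prime profile")
  }
  if (p5$window != p3$window) stop("profile window mismatch")
  if (p5$feature_kind != p3$feature_kind) stop("profile feature_kind mismatch")
  if (p5$smoothing_bp != p3$smoothing_bp) stop("profile smoothing mismatch")
  delta <- xcorr_shift(p3$values, p5$values, p3$window %/% 2L)
  list(delta = delta,
       verdict = if (abs(delta) > threshold) "decoupled" else "coupled")
}

#' Fragment-length periodicity by autocorrelation
#'
#' Builds the fragment-length histogram (1-nt bins over 50..2000 nt),
#' centers it on a local baseline (a 201-nt moving average, wider than any
#' plausible repeat, so gross histogram shape does not masquerade as
#' periodicity), and finds the lag maximizing the autocorrelation of the
#' residual.  For chromatin-patterned Okazaki fragments the best lag
#' recovers the nucleosome repeat length; loss of patterning collapses the
#' score.
#'
#' @param fragments a fragment `data.frame` (>= 1000 fragments recommended
#'   for a stable histogram; fewer triggers a flag, not an error).
#' @param max_lag largest lag searched in nt (default 400, i.e. more than
#'   twice the canonical repeat); the search starts at 100 nt.
#' @return list with `best_lag` (nt), `score` (autocorrelation at the best
#'   lag, normalized to the zero-lag value) and `n_fragments`.
#' @export
length_autocorrelation <- function(fragments, max_lag = 400L) {
  validate_fragments(fragments)
  if (nrow(fragments) == 0) stop("no fragments")
  max_lag <- as.integer(max_lag)
  if (max_lag < 100L + 1L) stop("max_lag must exceed the 100 nt search floor")
  lengths <- fragments$end - fragments$start
  lengths <- lengths[lengths >= 50 & lengths <= 2000]
  if (!length(lengths)) stop("no fragments with length in 50..2000 nt")
  h <- tabulate(lengths - 49L, nbins = 2000L - 50L + 1L)
  x <- h - moving_average(h, 201L)
  n <- length(x)
  denom <- sum(x^2)
  lags <- seq.int(100L, min(max_lag, n - 1L))
  ac <- vapply(lags, function(l) sum(x[seq_len(n - l)] * x[seq_len(n - l) + l]),
               numeric(1)) / denom
  i <- which.max(ac)
  out <- list(best_lag = lags[i], score = ac[i],
              n_fragments = length(lengths))
  if (length(lengths) < 1000) out$low_n <- TRUE
  out
}

#' Write a profile as TSV
#'
#' Three columns (`offset`, `raw_count`, `value`) under a commented header
#' carrying the profile metadata, so files are self-describing and
#' round-trip with [read_profile()].
#'
#' @param profile a `terminus_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "terminus_profile"))
  hdr <- sprintf(
    "# feature_kind=%s end_kind=%s window=%d smoothing_bp=%d normalization=%s n_features=%d n_termini=%d",
    profile$feature_kind, profile$end_kind, profile$window,
    profile$smoothing_bp, profile$normalization, profile$n_features,
    profile$n_termini)
  body <- paste(profile$offsets,
                fmt_num(profile$raw_counts),
                fmt_num(profile$values), sep = "\t")
  writeLines(c(hdr, paste("offset", "raw_count", "value", sep = "\t"), body),
             path)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#' @param path path to a profile TSV.
#' @return a `terminus_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[1]
  if (!startsWith(hdr, "# ")) stop("missing profile header")
  kv_pairs <- strsplit(strsplit(sub("^# ", "", hdr), " ")[[1]], "=")
  kv <- stats::setNames(vapply(kv_pairs, `[[`, character(1), 2),
                        vapply(kv_pairs, `[[`, character(1), 1))
  tab <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                           col.names = c("offset", "raw_count", "value"))
  new_terminus_profile(
    feature_kind = kv[["feature_kind"]], end_kind = kv[["end_kind"]],
    window = as.integer(kv[["window"]]), values = tab$value,
    raw_counts = tab$raw_count, n_features = as.integer(kv[["n_features"]]),
    n_termini = as.integer(kv[["n_termini"]]),
    normalization = kv[["normalization"]],
    smoothing_bp = as.integer(kv[["smoothing_bp"]]))
}

#' Plot a set of terminus profiles
#'
#' Simple line plot of one or more profiles over synthesis-oriented offsets
#' (synthesis proceeds left to right).  Requires ggplot2.
#'
#' @param profiles named list of `terminus_profile`s (names become the
#'   legend).
#' @return a ggplot object.
#' @export
plot_profiles <- function(profiles) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_profiles requires ggplot2")
  }
  if (inherits(profiles, "terminus_profile")) profiles <- list(profile = profiles)
  df <- do.call(rbind, lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    data.frame(sample = nm, offset = p$offsets, value = p$values,
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$value,
                                   colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "offset from feature midpoint (nt, synthesis left to right)",
                  y = "terminus signal") +
    ggplot2::theme_minimal()
}
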