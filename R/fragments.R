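#' Construct a table of Okazaki fragment records
#'
#' Fragments are mapped lagging-strand synthesis products represented as
#' 0-based half-open genomic intervals with a mandatory strand.  Simulated
#' fragments may additionally carry the ground-truth state of the junction at
#' their 5' end: a ligatable nick, a gap of `junction_len` nt, or a 5' flap of
#' `junction_len` nt.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start.
#' @param end integer vector, 0-based exclusive end (`end > start`).
#' @param strand character vector, each `"+"` or `"-"`.
#' @param name optional fragment identifiers (defaults to `frag1..fragN`).
#' @param score optional numeric score (BED column 5; defaults to 0).
#' @param junction_state optional character, each `NA`, `"nick"`, `"gap"` or
#'   `"flap"`; the junction at the fragment's 5' end.
#' @param junction_len optional integer, length in nt of the gap or flap;
#'   must be `NA` where `junction_state` is `NA` or `"nick"`, and >= 1
#'   otherwise.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `junction_state`, `junction_len`.
#' @export
fragment_records <- function(chrom, start, end, strand,
                             name = NULL, score = NULL,
                             junction_state = NULL, junction_len = NULL) {
  n <- length(chrom)
  if (is.null(name)) name <- if (n) paste0("frag", seq_len(n)) else character(0)
  if (is.null(score)) score <- rep(0, n)
  if (is.null(junction_state)) junction_state <- rep(NA_character_, n)
  if (is.null(junction_len)) junction_len <- rep(NA_integer_, n)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand),
    junction_state = as.character(junction_state),
    junction_len = as.integer(junction_len),
    stringsAsFactors = FALSE
  )
  validate_fragments(df)
  df
}

#' Validate a fragment table
#'
#' Checks the structural invariants of a fragment table: integer 0-based
#' half-open coordinates with `end > start`, strand restricted to `+`/`-`,
#' and junction annotations consistent (`nick` carries no length; `gap` and
#' `flap` carry a length >= 1).
#'
#' @param fragments a fragment `data.frame` as built by [fragment_records()].
#' @return the input, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_fragments <- function(fragments) {
  required <- c("chrom", "start", "end", "strand")
  missing <- setdiff(required, names(fragments))
  if (length(missing)) {
    stop("fragment table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(fragments) == 0) return(invisible(fragments))
  if (any(fragments$start < 0)) stop("fragment start must be >= 0")
  if (any(fragments$end <= fragments$start)) {
    stop("fragment end must exceed start (0-based half-open)")
  }
  if (!all(fragments$strand %in% c("+", "-"))) {
    stop("fragment strand must be '+' or '-'; unstranded fragments are rejected")
  }
  if ("junction_state" %in% names(fragments)) {
    js <- fragments$junction_state
    ok <- is.na(js) | js %in% c("nick", "gap", "flap")
    if (!all(ok)) stop("junction_state must be NA, 'nick', 'gap' or 'flap'")
    jl <- fragments$junction_len
    needs_len <- !is.na(js) & js %in% c("gap", "flap")
    if (any(needs_len & (is.na(jl) | jl < 1))) {
      stop("gap/flap junctions require junction_len >= 1")
    }
    if (any(!needs_len & !is.na(jl))) {
      stop("junction_len must be absent unless junction_state is gap or flap")
    }
  }
  invisible(fragments)
}

#' Read Okazaki fragments from a BED6(+1) file
#'
#' Expects tab-separated BED6 with mandatory strand in column 6.  An optional
#' seventh column carries the simulated junction state at the fragment's 5'
#' end in the dialect `"nick"`, `"gap:<n>"` or `"flap:<n>"`.
#'
#' @param path path to a BED file (no header, LF line endings).
#' @return a fragment `data.frame` (see [fragment_records()]).
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(fragment_records(character(0), integer(0), integer(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stop("malformed BED line ", which(nf < 6)[1], ": fewer than 6 columns")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- get(1)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1], ": non-integer coordinates")
  strand <- get(6)
  if (any(strand == ".")) {
    stop("malformed BED line ", which(strand == ".")[1],
         ": strand '.' not allowed; strand is mandatory for terminus assignment")
  }
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop("malformed BED line ", bad[1], ": invalid strand")
  junction_state <- rep(NA_character_, length(lines))
  junction_len <- rep(NA_integer_, length(lines))
  has7 <- nf >= 7
  if (any(has7)) {
    col7 <- vapply(fields[has7], `[[`, character(1), 7)
    parsed <- parse_junction_field(col7, which(has7))
    junction_state[has7] <- parsed$state
    junction_len[has7] <- parsed$len
  }
  fragment_records(chrom, start, end, strand,
                   name = get(4), score = suppressWarnings(as.numeric(get(5))),
                   junction_state = junction_state, junction_len = junction_len)
}

parse_junction_field <- function(x, line_no) {
  state <- rep(NA_character_, length(x))
  len <- rep(NA_integer_, length(x))
  is_nick <- x == "nick"
  state[is_nick] <- "nick"
  m <- regmatches(x, regexec("^(gap|flap):([0-9]+)$", x))
  for (i in seq_along(x)) {
    if (is_nick[i]) next
    if (length(m[[i]]) == 3) {
      state[i] <- m[[i]][2]
      len[i] <- as.integer(m[[i]][3])
      if (len[i] < 1) {
        stop("malformed BED line ", line_no[i], ": gap/flap length must be >= 1")
      }
    } else {
      stop("malformed BED line ", line_no[i],
           ": junction column must be 'nick', 'gap:<n>' or 'flap:<n>'")
    }
  }
  list(state = state, len = len)
}

#' Write fragments to a BED6(+1) file
#'
#' Round-trips with [read_fragments()]: the seventh junction column is written
#' only for fragments that carry a junction state, so files with no simulated
#' ground truth stay plain BED6.
#'
#' @param fragments a fragment `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  validate_fragments(fragments)
  if (nrow(fragments) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  base <- paste(fragments$chrom, fragments$start, fragments$end,
                fragments$name, format_bed_score(fragments$score),
                fragments$strand, sep = "\t")
  js <- fragments$junction_state
  has <- !is.na(js)
  if (any(has)) {
    col7 <- ifelse(js[has] == "nick", "nick",
                   paste0(js[has], ":", fragments$junction_len[has]))
    base[has] <- paste(base[has], col7, sep = "\t")
  }
  writeLines(base, path)
  invisible(path)
}

format_bed_score <- function(x) {
  out <- format(x, trim = TRUE, scientific = FALSE)
  out[x == round(x)] <- format(round(x[x == round(x)]), trim = TRUE,
                               scientific = FALSE)
  out
}

#' Extract 5' and 3' terminus positions of fragments
#'
#' Okazaki fragments are synthesized 5'->3', so the chemical ends map to
#' genomic coordinates by strand: on `+` the 5' terminus is `start` and the
#' 3' terminus is `end - 1` (the last synthesized nucleotide); on `-` the 5'
#' terminus is `end - 1` and the 3' terminus is `start`.
#'
#' @param fragments a fragment `data.frame`.
#' @return a `data.frame` with columns `chrom`, `strand`, `five_prime`,
#'   `three_prime` (0-based positions, both inside `[start, end)`).
#' @export
fragment_termini <- function(fragments) {
  validate_fragments(fragments)
  plus <- fragments$strand == "+"
  data.frame(
    chrom = fragments$chrom,
    strand = fragments$strand,
    five_prime = ifelse(plus, fragments$start, fragments$end - 1L),
    three_prime = ifelse(plus, fragments$end - 1L, fragments$start),
    stringsAsFactors = FALSE
  )
}

#' Mirror fragments through the right end of each chromosome
#'
#' Maps every position `x` to `L - 1 - x` (with `L` the chromosome length)
#' and flips strand, so synthesis direction is preserved relative to the
#' mirrored genome.  Used to check that oriented analyses are invariant under
#' a genome-wide coordinate mirror.
#'
#' @param fragments a fragment `data.frame`.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return the mirrored fragment `data.frame`.
#' @export
mirror_fragments <- function(fragments, chrom_lengths) {
  validate_fragments(fragments)
  if (nrow(fragments) == 0) return(fragments)
  L <- chrom_lengths[fragments$chrom]
  if (any(is.na(L))) stop("chrom_lengths missing a chromosome present in fragments")
  out <- fragments
  out$start <- as.integer(L - fragments$end)
  out$end <- as.integer(L - fragments$start)
  out$strand <- ifelse(fragments$strand == "+", "-", "+")
  validate_fragments(out)
  out
}
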