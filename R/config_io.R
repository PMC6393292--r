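# Flat key = value serialization of simulation configs / run manifests.
# Compound values use "a:b" pairs joined by commas.  Numbers are written so
# they round-trip exactly, which is what makes a run reproducible from its
# manifest alone.

fmt_num <- function(x) {
  s <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
  exact <- suppressWarnings(as.numeric(s)) == x
  s[!exact] <- sprintf("%.17g", x[!exact])
  s
}

fmt_named <- function(x) {
  paste(paste0(names(x), ":", fmt_num(unname(x))), collapse = ",")
}

parse_named <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  vals <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  names(vals) <- vapply(parts, `[[`, character(1), 1)
  vals
}

#' Write a simulation config (run manifest) to a key-value file
#'
#' @param config an `okz_sim_config`.
#' @param path output path.
#' @param conditions optional condition list recorded for panel runs.
#' @param extra optional named character vector of additional scalar entries
#'   (e.g. profiling options of a full workflow run).
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path, conditions = NULL, extra = NULL) {
  validate_sim_config(config)
  kv <- c(
    chrom_lengths = fmt_named(config$chrom_lengths),
    origins = paste(paste0(config$origins$chrom, ":",
                           config$origins$position), collapse = ","),
    nucleosome_repeat = fmt_num(config$nucleosome_repeat),
    dyad_jitter_sd = fmt_num(config$dyad_jitter_sd),
    multi_span_prob = fmt_num(config$multi_span_prob),
    n_fragments = fmt_num(config$n_fragments),
    condition = config$condition,
    terminus_shift = fmt_named(config$terminus_shift),
    terminus_sd = fmt_named(config$terminus_sd),
    ligatable_fraction = fmt_named(config$ligatable_fraction),
    gap_flap_len_mean = fmt_num(config$gap_flap_len_mean),
    tf_sites = paste(paste0(config$tf_sites$chrom, ":",
                            config$tf_sites$midpoint, ":",
                            config$tf_sites$orientation), collapse = ","),
    tf_barrier_weight = fmt_num(config$tf_barrier_weight),
    tf_footprint = fmt_num(config$tf_footprint),
    decoupled_flap_mode = as.character(config$decoupled_flap_mode),
    seed = fmt_num(config$seed)
  )
  if (!is.null(conditions)) {
    kv["conditions"] <- paste(conditions, collapse = ",")
  }
  if (!is.null(extra)) kv <- c(kv, extra)
  writeLines(paste(names(kv), "=", kv), path)
  invisible(path)
}

#' Read a simulation config back from a key-value file
#'
#' Inverse of [write_sim_config()]: reconstructs the `okz_sim_config` and any
#' panel condition list, so a panel run can be repeated byte-identically from
#' its manifest.
#'
#' @param path path to a manifest / config file.
#' @return list with elements `config` (an `okz_sim_config`), `conditions`
#'   (character or `NULL`) and `extra` (named character vector of entries not
#'   part of the simulation config).
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([^=]+?) = (.*)$", lines))
  bad <- which(lengths(m) != 3)
  if (length(bad)) stop("malformed config line ", bad[1])
  kv <- vapply(m, `[[`, character(1), 3)
  names(kv) <- vapply(m, `[[`, character(1), 2)
  need <- function(key) {
    if (!key %in% names(kv)) stop("config missing key: ", key)
    kv[[key]]
  }
  ori_parts <- strsplit(strsplit(need("origins"), ",")[[1]], ":")
  tf_parts <- strsplit(strsplit(need("tf_sites"), ",")[[1]], ":")
  cl <- parse_named(need("chrom_lengths"))
  config <- simulation_config(
    chrom_lengths = stats::setNames(as.integer(cl), names(cl)),
    origins = data.frame(
      chrom = vapply(ori_parts, `[[`, character(1), 1),
      position = as.integer(vapply(ori_parts, `[[`, character(1), 2)),
      stringsAsFactors = FALSE),
    nucleosome_repeat = as.integer(need("nucleosome_repeat")),
    dyad_jitter_sd = as.numeric(need("dyad_jitter_sd")),
    multi_span_prob = as.numeric(need("multi_span_prob")),
    n_fragments = as.integer(need("n_fragments")),
    condition = need("condition"),
    terminus_shift = parse_named(need("terminus_shift")),
    terminus_sd = parse_named(need("terminus_sd")),
    ligatable_fraction = parse_named(need("ligatable_fraction")),
    gap_flap_len_mean = as.numeric(need("gap_flap_len_mean")),
    tf_sites = data.frame(
      chrom = vapply(tf_parts, `[[`, character(1), 1),
      midpoint = as.integer(vapply(tf_parts, `[[`, character(1), 2)),
      orientation = vapply(tf_parts, `[[`, character(1), 3),
      stringsAsFactors = FALSE),
    tf_barrier_weight = as.numeric(need("tf_barrier_weight")),
    tf_footprint = as.integer(need("tf_footprint")),
    decoupled_flap_mode = need("decoupled_flap_mode") == "TRUE",
    seed = as.integer(need("seed"))
  )
  conditions <- if ("conditions" %in% names(kv)) {
    strsplit(kv[["conditions"]], ",")[[1]]
  }
  core <- c("chrom_lengths", "origins", "nucleosome_repeat", "dyad_jitter_sd",
            "multi_span_prob",
            "n_fragments", "condition", "terminus_shift", "terminus_sd",
            "ligatable_fraction", "gap_flap_len_mean", "tf_sites",
            "tf_barrier_weight", "tf_footprint", "decoupled_flap_mode",
            "seed", "conditions")
  extra <- kv[setdiff(names(kv), core)]
  list(config = config, conditions = conditions, extra = extra)
}
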