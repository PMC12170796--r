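# Study bundle file round-tripping: roster.csv, ratings.csv, signals.csv
# (long format), truth.json. readr writes shortest round-trippable doubles,
# so write_study() -> read_study() is lossless.

#' Write a study bundle to a directory
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    roster = file.path(dir, "roster.csv"),
    ratings = file.path(dir, "ratings.csv"),
    signals = file.path(dir, "signals.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(bundle$roster, paths["roster"])
  ratings <- bundle$ratings
  ratings$pre <- ifelse(is.na(ratings$pre), NA, sprintf("%.17g", ratings$pre))
  ratings$post <- sprintf("%.17g", ratings$post)
  readr::write_csv(ratings, paths["ratings"])

  sig_rows <- lapply(names(bundle$signals), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    vals <- bundle$signals[[key]]
    rate <- if (parts[3] == "smile") bundle$config$smile_rate_hz else bundle$config$hr_rate_hz
    tibble::tibble(
      participant = parts[1], round = as.integer(parts[2]),
      modality = parts[3], time_s = (seq_along(vals) - 1) / rate,
      value = vals
    )
  })
  sig <- dplyr::bind_rows(c(list(tibble::tibble(
    participant = character(), round = integer(), modality = character(),
    time_s = numeric(), value = numeric()
  )), sig_rows))
  # 17 significant digits round-trip IEEE doubles exactly
  sig$time_s <- sprintf("%.17g", sig$time_s)
  sig$value <- sprintf("%.17g", sig$value)
  readr::write_csv(sig, paths["signals"])

  cfg <- bundle$config
  truth <- bundle$truth
  for (cl in names(truth)) {
    # doubles as 17-digit strings so the JSON round-trips bit-exactly
    if (is.double(truth[[cl]])) truth[[cl]] <- sprintf("%.17g", truth[[cl]])
  }
  jsonlite::write_json(
    list(truth = truth, config = unclass(cfg)),
    paths["truth"], auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(paths)
}

#' Read a study bundle from a directory
#'
#' Validates the schema as it reads: missing columns and out-of-range values
#' are reported with file, line and column.
#'
#' @param dir Directory written by [write_study()].
#' @return A `study_bundle`.
#' @export
read_study <- function(dir) {
  roster_path <- file.path(dir, "roster.csv")
  ratings_path <- file.path(dir, "ratings.csv")
  signals_path <- file.path(dir, "signals.csv")
  truth_path <- file.path(dir, "truth.json")
  for (p in c(roster_path, ratings_path, signals_path, truth_path)) {
    if (!file.exists(p)) stop("missing study file: ", p)
  }

  # base R's strtod parses doubles with correct rounding, so the 17-digit
  # representations written by write_study() round-trip bit-exactly
  read_tbl <- function(p) tibble::as_tibble(utils::read.csv(p))
  roster <- read_tbl(roster_path)
  require_columns(roster, c("session", "round", "dyad_id", "member_a",
                            "member_b", "condition", "familiar_a",
                            "familiar_b", "pair_type"), roster_path)
  for (cl in c("session", "round", "familiar_a", "familiar_b")) {
    roster[[cl]] <- as.integer(roster[[cl]])
  }
  ratings <- read_tbl(ratings_path)
  ratings$round <- as.integer(ratings$round)
  ratings$familiarity <- as.integer(ratings$familiarity)
  require_columns(ratings, c("rater_id", "partner_id", "dyad_id", "round",
                             "condition", "measure", "pre", "post",
                             "familiarity"), ratings_path)
  validate_ratings(ratings, ratings_path)

  sig <- read_tbl(signals_path)
  require_columns(sig, c("participant", "round", "modality", "time_s",
                         "value"), signals_path)
  validate_signals(sig, signals_path)

  tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  cfg_list <- tr$config
  cfg_list$condition_effects <- if (length(cfg_list$condition_effects)) {
    unlist(cfg_list$condition_effects)
  } else {
    NULL
  }
  cfg <- do.call(sim_config, cfg_list[setdiff(names(cfg_list), character(0))])
  truth <- tibble::as_tibble(tr$truth)
  for (cl in setdiff(names(truth), "dyad_id")) {
    truth[[cl]] <- as.numeric(truth[[cl]])
  }

  signals <- split(sig$value, signal_key(sig$participant, sig$round, sig$modality))
  # split() orders by key; reorder each series by time
  ord <- split(sig$time_s, signal_key(sig$participant, sig$round, sig$modality))
  signals <- lapply(names(signals), function(k) signals[[k]][order(ord[[k]])])
  names(signals) <- names(ord)

  structure(
    list(roster = roster, signals = signals,
         ratings = ratings, truth = truth, config = cfg),
    class = "study_bundle"
  )
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("file ", path, ": missing column(s) ", paste(miss, collapse = ", "))
  }
}

validate_signals <- function(sig, path) {
  bad <- which(!is.finite(sig$value))
  if (length(bad)) {
    stop("file ", path, ", line ", bad[1] + 1,
         ", column 'value': non-numeric or missing value")
  }
  smile <- sig$modality == "smile"
  bad <- which(smile & (sig$value < 0 | sig$value > 100))
  if (length(bad)) {
    stop("file ", path, ", line ", bad[1] + 1,
         ", column 'value': smile intensity outside [0, 100]")
  }
  bad <- which(!smile & sig$value <= 0)
  if (length(bad)) {
    stop("file ", path, ", line ", bad[1] + 1,
         ", column 'value': non-positive heart rate")
  }
}

validate_ratings <- function(ratings, path) {
  mr <- measure_ranges()
  lo <- stats::setNames(mr$lo, mr$measure)
  hi <- stats::setNames(mr$hi, mr$measure)
  known <- ratings$measure %in% mr$measure
  rng <- known &
    ((!is.na(ratings$pre) &
        (ratings$pre < lo[ratings$measure] | ratings$pre > hi[ratings$measure])) |
       (!is.na(ratings$post) &
          (ratings$post < lo[ratings$measure] | ratings$post > hi[ratings$measure])))
  if (any(rng, na.rm = TRUE)) {
    bad <- which(rng)[1]
    stop("file ", path, ", line ", bad + 1,
         ", column 'pre'/'post': value outside the range of measure '",
         ratings$measure[bad], "'")
  }
}
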