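#' Enumerate pseudo pairs
#'
#' Pseudo pairs -- participants from the same condition who never (or, for
#' the round-matched scope, not at that moment) interacted -- form the
#' empirical null against which real-pair synchrony is compared: they were
#' exposed to the same task and environment but not to each other.
#'
#' Two scopes are supported. `"any"` pairs each participant's data with all
#' other possible partners of the same condition that were never actually
#' their partners, enumerating every combination of the two participants'
#' recordings (one per round each attended). `"round_matched"` pairs, within
#' each round, participants of the same condition who were both recorded in
#' that round but not paired with each other at that moment.
#'
#' @param roster A roster tibble ([make_roster()]).
#' @param condition Condition label to enumerate within.
#' @param scope `"any"` or `"round_matched"`.
#' @param within_session_only Restrict pseudo pairs to participants of the
#'   same session (only relevant when a condition spans several sessions).
#' @return A tibble with one row per pseudo data-pairing: `pair_id`,
#'   `condition`, `member_a`, `round_a`, `member_b`, `round_b`,
#'   `pair_type` (`"pseudo"`). Members are ordered lexicographically within
#'   each pair; no pairing duplicates a real one.
#' @export
#' @examples
#' r <- make_roster(6, 1, "gazing", seed = 1)
#' nrow(enumerate_pseudo_pairs(r, "gazing", "round_matched")) # C(6,2) - 3
enumerate_pseudo_pairs <- function(roster, condition,
                                   scope = c("any", "round_matched"),
                                   within_session_only = FALSE) {
  scope <- match.arg(scope)
  if (!condition %in% roster$condition) {
    stop("unknown condition label: ", condition)
  }
  rc <- roster[roster$condition == condition, , drop = FALSE]
  real_keys <- unique(pair_key(rc$member_a, rc$member_b))

  if (scope == "any") {
    # rounds each participant was recorded in (one recording per round)
    rec <- dplyr::bind_rows(
      tibble::tibble(participant = rc$member_a, round = rc$round,
                     session = rc$session),
      tibble::tibble(participant = rc$member_b, round = rc$round,
                     session = rc$session)
    )
    people <- sort(unique(rec$participant))
    if (length(people) < 2) return(empty_pseudo())
    combos <- utils::combn(people, 2)
    rows <- vector("list", ncol(combos))
    for (k in seq_len(ncol(combos))) {
      p <- combos[1, k]; q <- combos[2, k]
      if (pair_key(p, q) %in% real_keys) next
      rp <- rec[rec$participant == p, , drop = FALSE]
      rq <- rec[rec$participant == q, , drop = FALSE]
      if (within_session_only &&
          !any(rp$session %in% rq$session)) next
      g <- expand.grid(round_a = rp$round, round_b = rq$round)
      rows[[k]] <- tibble::tibble(
        condition = condition,
        member_a = p, round_a = g$round_a,
        member_b = q, round_b = g$round_b,
        pair_type = "pseudo"
      )
    }
    out <- dplyr::bind_rows(rows)
  } else {
    rows <- list()
    for (r in sort(unique(rc$round))) {
      rr <- rc[rc$round == r, , drop = FALSE]
      people <- sort(unique(c(rr$member_a, rr$member_b)))
      if (length(people) < 2) next
      real_r <- pair_key(rr$member_a, rr$member_b)
      combos <- utils::combn(people, 2)
      keep <- !(pair_key(combos[1, ], combos[2, ]) %in% real_r)
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = condition,
        member_a = combos[1, keep], round_a = r,
        member_b = combos[2, keep], round_b = r,
        pair_type = "pseudo"
      )
    }
    out <- dplyr::bind_rows(rows)
  }
  if (nrow(out) == 0) return(empty_pseudo())
  out$pair_id <- sprintf("pseudo_%s_%s_r%d_%s_r%d", out$condition,
                         out$member_a, out$round_a, out$member_b, out$round_b)
  out[, c("pair_id", "condition", "member_a", "round_a", "member_b",
          "round_b", "pair_type")]
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "~")
}

empty_pseudo <- function() {
  tibble::tibble(pair_id = character(), condition = character(),
                 member_a = character(), round_a = integer(),
                 member_b = character(), round_b = integer(),
                 pair_type = character())
}

#' Combined real and pseudo-pair synchrony table
#'
#' Runs the modality-appropriate preprocessing (smile: integer rounding plus
#' 4-sample rolling mean; heart rate: AR prewhitening), applies the
#' smiled-at-all eligibility rule, and computes one global-synchrony record
#' per real dyad and per enumerated pseudo pairing.
#'
#' @param bundle A `study_bundle` ([simulate_study()] or [read_study()]).
#' @param modality `"smile"` or `"hr"`.
#' @param scope Pseudo-pair scope; defaults to `"any"` for smile studies and
#'   `"round_matched"` for heart-rate studies.
#' @param method Correlation method.
#' @param smooth_samples Smile smoothing window (samples).
#' @param max_order Maximum AR order for prewhitening (`NULL` = AIC default).
#' @param max_pseudo_pairs Cap on enumerated pseudo pairings per condition;
#'   a seeded subsample is drawn when exceeded (default: no cap).
#' @param exclude_familiar Drop real dyads where any member reported prior
#'   familiarity before computing anything (robustness filter); pseudo pairs
#'   are then enumerated from the reduced roster.
#' @param seed Seed for the capped pseudo-pair subsample.
#' @return A tibble of synchrony records (see [global_synchrony()]); pairs
#'   with missing signals are skipped and listed in the `"skipped"`
#'   attribute, exclusion counts in the `"exclusions"` attribute.
#' @export
synchrony_table <- function(bundle, modality = c("smile", "hr"),
                            scope = NULL, method = "pearson",
                            smooth_samples = 4, max_order = NULL,
                            max_pseudo_pairs = Inf,
                            exclude_familiar = FALSE, seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(scope)) scope <- if (modality == "smile") "any" else "round_matched"
  roster <- bundle$roster
  if (exclude_familiar) {
    roster <- roster[roster$familiar_a == 0 & roster$familiar_b == 0, ,
                     drop = FALSE]
  }

  raw <- function(p, r) bundle$signals[[signal_key(p, r, modality)]]
  prep_cache <- new.env(parent = emptyenv())
  prepped <- function(p, r) {
    key <- signal_key(p, r, modality)
    if (!is.null(prep_cache[[key]])) return(prep_cache[[key]])
    x <- raw(p, r)
    if (is.null(x)) return(NULL)
    val <- if (modality == "smile") {
      list(series = prep_smile(x, smooth_samples), start = 1L)
    } else {
      if (stats::var(x) == 0) {
        list(series = x - mean(x), start = 1L)
      } else {
        pw <- prewhiten_ar(x, max_order)
        list(series = pw$residuals, start = pw$start_index)
      }
    }
    prep_cache[[key]] <- val
    val
  }

  pairings <- dplyr::bind_rows(
    tibble::tibble(
      pair_id = roster$dyad_id, condition = roster$condition,
      member_a = roster$member_a, round_a = roster$round,
      member_b = roster$member_b, round_b = roster$round,
      pair_type = "real"
    ),
    dplyr::bind_rows(lapply(unique(roster$condition), function(cc) {
      ep <- enumerate_pseudo_pairs(roster, cc, scope)
      if (nrow(ep) > max_pseudo_pairs) {
        keep <- with_substream(seed, paste0("pseudo_cap|", cc),
                               sample.int(nrow(ep), max_pseudo_pairs))
        ep <- ep[sort(keep), , drop = FALSE]
      }
      ep
    }))
  )

  records <- vector("list", nrow(pairings))
  skipped <- character(0)
  for (i in seq_len(nrow(pairings))) {
    p <- pairings[i, ]
    xa <- raw(p$member_a, p$round_a)
    xb <- raw(p$member_b, p$round_b)
    if (is.null(xa) || is.null(xb)) {
      skipped <- c(skipped, p$pair_id)
      next
    }
    if (modality == "smile") {
      elig <- smile_eligibility(xa, xb)
      if (!elig$eligible) {
        records[[i]] <- ineligible_record(p, method, elig$reason,
                                          mean(xa), mean(xb), length(xa))
        next
      }
      pa <- prepped(p$member_a, p$round_a)$series
      pb <- prepped(p$member_b, p$round_b)$series
      rec <- global_synchrony(pa, pb, method, prewhitened = FALSE,
                              pair_id = p$pair_id, condition = p$condition,
                              pair_type = p$pair_type)
    } else {
      pa <- prepped(p$member_a, p$round_a)
      pb <- prepped(p$member_b, p$round_b)
      # residuals start at (AR order + 1); align the two members in time by
      # trimming the longer residual series at the front
      start <- max(pa$start, pb$start)
      sa <- pa$series[(start - pa$start + 1L):length(pa$series)]
      sb <- pb$series[(start - pb$start + 1L):length(pb$series)]
      rec <- global_synchrony(sa, sb, method, prewhitened = TRUE,
                              pair_id = p$pair_id, condition = p$condition,
                              pair_type = p$pair_type)
      # report average HR on the bpm scale, not residual means
      rec$mean_a <- mean(xa)
      rec$mean_b <- mean(xb)
      rec$mean_pair <- (rec$mean_a + rec$mean_b) / 2
    }
    records[[i]] <- rec
  }

  out <- dplyr::bind_rows(records)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      pair_id = character(), condition = character(), pair_type = character(),
      method = character(), prewhitened = logical(), r = numeric(),
      mean_a = numeric(), mean_b = numeric(), mean_pair = numeric(),
      n_samples = integer(), eligible = logical(),
      exclusion_reason = character()
    )
  }
  attr(out, "skipped") <- skipped
  attr(out, "exclusions") <- table(out$exclusion_reason[!out$eligible])
  attr(out, "scope") <- scope
  out
}

ineligible_record <- function(p, method, reason, mean_a, mean_b, n) {
  tibble::tibble(
    pair_id = p$pair_id, condition = p$condition, pair_type = p$pair_type,
    method = method, prewhitened = FALSE, r = NA_real_,
    mean_a = mean_a, mean_b = mean_b, mean_pair = (mean_a + mean_b) / 2,
    n_samples = n, eligible = FALSE, exclusion_reason = reason
  )
}
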