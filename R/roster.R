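#' Build a round-robin pairing roster
#'
#' Emulates the speed-dating-like pairing design of dyadic meditation
#' studies: within each session every participant is sequentially paired with
#' different partners, one session per condition, with one participant
#' sitting out per round when the session size is odd. Repeat pairings are
#' avoided by construction (circle-method round robin) unless more rounds
#' are requested than distinct partners exist.
#'
#' @param n_participants Participants per session (>= 2).
#' @param n_rounds Pairing rounds per session.
#' @param conditions Character vector of condition labels; each condition is
#'   one session with its own participants.
#' @param seed Integer seed controlling the pairing order and familiarity
#'   draws.
#' @param allow_repeats If `TRUE`, rounds beyond the distinct round-robin
#'   schedule recycle earlier pairings instead of failing.
#' @param familiarity_prob Probability that one member reports prior
#'   familiarity (ordinal level 1--4) with the partner; 0 gives an
#'   all-stranger roster.
#'
#' @return A tibble with one row per real dyad pairing: `session`, `round`,
#'   `dyad_id`, `member_a`, `member_b`, `condition`, `familiar_a`,
#'   `familiar_b`, `pair_type` (all `"real"`). Participants sitting out are
#'   listed in the `sat_out` attribute.
#' @export
#' @examples
#' make_roster(4, 3, "gazing", seed = 1)
make_roster <- function(n_participants, n_rounds, conditions, seed = 1L,
                        allow_repeats = FALSE, familiarity_prob = 0) {
  stopifnot(n_participants >= 2, n_rounds >= 1, length(conditions) >= 1)
  n <- as.integer(n_participants)
  feasible <- if (n %% 2 == 0) n - 1L else n
  if (n_rounds > feasible && !allow_repeats) {
    stop(sprintf(
      "n_rounds = %d exceeds the %d distinct round-robin rounds for %d participants; set allow_repeats = TRUE to recycle pairings",
      n_rounds, feasible, n
    ))
  }

  rows <- list()
  sat_out <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    ids <- sprintf("s%d_p%02d", ci, seq_len(n))
    # seed-dependent relabelling so the schedule varies across seeds while
    # the circle-method guarantees of uniqueness are preserved
    perm <- with_substream(seed, paste0("roster|", cond), sample.int(n))
    ids <- ids[perm]
    sched <- circle_schedule(n, n_rounds)
    for (r in seq_len(n_rounds)) {
      prs <- sched[[r]]
      d <- 0L
      for (k in seq_len(nrow(prs))) {
        d <- d + 1L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          session = ci,
          round = r,
          dyad_id = sprintf("%s_r%d_d%02d", cond, r, d),
          member_a = ids[prs[k, 1]],
          member_b = ids[prs[k, 2]],
          condition = cond,
          pair_type = "real"
        )
      }
      out <- setdiff(seq_len(n), as.vector(prs))
      if (length(out)) {
        sat_out[[length(sat_out) + 1L]] <- tibble::tibble(
          session = ci, round = r, participant = ids[out], condition = cond
        )
      }
    }
  }
  roster <- dplyr::bind_rows(rows)

  fam <- with_substream(seed, "familiarity", {
    fa <- stats::rbinom(nrow(roster), 1, familiarity_prob) *
      sample(1:4, nrow(roster), replace = TRUE)
    fb <- stats::rbinom(nrow(roster), 1, familiarity_prob) *
      sample(1:4, nrow(roster), replace = TRUE)
    list(fa = fa, fb = fb)
  })
  roster$familiar_a <- fam$fa
  roster$familiar_b <- fam$fb
  roster <- roster[, c("session", "round", "dyad_id", "member_a", "member_b",
                       "condition", "familiar_a", "familiar_b", "pair_type")]
  attr(roster, "sat_out") <- if (length(sat_out)) {
    dplyr::bind_rows(sat_out)
  } else {
    tibble::tibble(session = integer(), round = integer(),
                   participant = character(), condition = character())
  }
  roster
}

# Circle-method round-robin schedule for n players over n_rounds rounds.
# Returns a list of 2-column matrices of player indices (1..n); with odd n a
# phantom bye is added and its partner sits out. Rounds beyond the distinct
# schedule recycle (callers gate this behind allow_repeats).
circle_schedule <- function(n, n_rounds) {
  m <- if (n %% 2 == 0) n else n + 1L # m even; player m is the bye when odd
  k <- m - 1L
  lapply(seq_len(n_rounds), function(r) {
    r0 <- (r - 1L) %% k
    pairs <- matrix(0L, nrow = m / 2, ncol = 2)
    # fixed player m meets rotating player r0
    pairs[1, ] <- c(m, r0 + 1L)
    row <- 1L
    for (i in 0:(k - 1L)) {
      j <- (2L * r0 - i) %% k
      if (i < j && i != r0 && j != r0) {
        row <- row + 1L
        pairs[row, ] <- c(i + 1L, j + 1L)
      }
    }
    pairs <- pairs[seq_len(row), , drop = FALSE]
    if (n %% 2 != 0) {
      pairs <- pairs[pairs[, 1] != m & pairs[, 2] != m, , drop = FALSE]
    }
    pairs
  })
}
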