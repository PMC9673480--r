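#' Per-feed milk volume from pre/post weights
#'
#' Volume is the post-minus-pre weight difference in grams, reported as mL
#' at density 1 g/mL. The result is missing when either weight is absent or
#' the difference is negative (a physically impossible intake).
#'
#' @param pre_weight_g,post_weight_g Numeric vectors of infant weights (g).
#' @return Numeric vector of volumes (mL); `NA` where undefined.
#' @examples
#' feed_volume(5000, 5080)   # 80
#' feed_volume(5100, 5080)   # NA
#' @export
feed_volume <- function(pre_weight_g, post_weight_g) {
  vol <- post_weight_g - pre_weight_g
  vol[!is.na(vol) & vol < 0] <- NA_real_
  vol
}

#' Quality-control a 24-h feed log
#'
#' Computes per-feed volumes, marks single feeds above `spike_limit_g`
#' (default 400 g) as missing, counts missing feeds, and flags the log for
#' discard when more than `max_missing` (default 3) feeds are missing.
#' Spikes are converted to missing *before* the missing count, so a spiked
#' feed contributes to the discard rule.
#'
#' @param log One dyad-visit feed log: a data frame with `pre_weight_g` and
#'   `post_weight_g` (one row per feed).
#' @param spike_limit_g Upper plausibility bound on a single feed (g).
#' @param max_missing Maximum tolerated missing feeds before discard.
#' @return A list with `log` (input plus `volume_ml`, `spike`, `missing`
#'   columns), `n_missing`, and `discard` (logical).
#' @export
qc_feed_log <- function(log, spike_limit_g = 400, max_missing = 3) {
  stopifnot(all(c("pre_weight_g", "post_weight_g") %in% names(log)))
  if (nrow(log) == 0) stop("feed log has no events", call. = FALSE)
  log <- tibble::as_tibble(log)
  vol <- feed_volume(log$pre_weight_g, log$post_weight_g)
  spike <- !is.na(vol) & vol > spike_limit_g
  vol[spike] <- NA_real_
  log$volume_ml <- vol
  log$spike <- spike
  log$missing <- is.na(vol)
  n_missing <- sum(log$missing)
  list(log = log, n_missing = n_missing, discard = n_missing > max_missing)
}

#' Hot-deck imputation of missing feed volumes
#'
#' Each missing feed volume is replaced by the volume of the nearest
#' non-missing feed of the same log by event index; on a distance tie the
#' preceding feed is preferred, and when no preceding donor exists the
#' nearest following feed is used. Deterministic, no randomness; non-missing
#' volumes are never altered.
#'
#' @param log Output `log` element of [qc_feed_log()] (must contain
#'   `volume_ml`).
#' @return The log with missing volumes imputed, an `imputed` flag column,
#'   and attribute `n_imputed`.
#' @export
hot_deck_impute <- function(log) {
  stopifnot("volume_ml" %in% names(log))
  vol <- log$volume_ml
  miss <- which(is.na(vol))
  donors <- which(!is.na(vol))
  if (length(miss) > 0 && length(donors) == 0) {
    stop("all feeds missing: no donor available for hot-deck imputation",
         call. = FALSE)
  }
  imputed <- rep(FALSE, length(vol))
  for (i in miss) {
    d <- abs(donors - i)
    best <- min(d)
    cand <- donors[d == best]
    donor <- if (any(cand < i)) max(cand[cand < i]) else min(cand)
    vol[i] <- vol[donor]
    imputed[i] <- TRUE
  }
  log$volume_ml <- vol
  log$imputed <- imputed
  attr(log, "n_imputed") <- length(miss)
  log
}

#' Summarise a QC'd and imputed feed log into 24-h intake measures
#'
#' @param log Imputed log from [hot_deck_impute()] (or the QC log when
#'   nothing was missing).
#' @param infant_weight_kg Infant weight in kg (> 0) for the per-kg measure;
#'   may be `NA`, in which case `per_kg_ml` is `NA`.
#' @param qc The QC result of [qc_feed_log()] for this log, used for
#'   bookkeeping counts and the discard status.
#' @return A one-row tibble: `total_24h_ml`, `per_feed_ml`, `per_kg_ml`,
#'   `n_feeds`, `n_missing`, `n_imputed`, `n_spike_excluded`, `status`.
#' @export
summarize_intake <- function(log, infant_weight_kg = NA_real_, qc = NULL) {
  if (!is.null(qc) && isTRUE(qc$discard)) {
    stop("feed log was discarded by QC (> 3 missing feeds); intake undefined",
         call. = FALSE)
  }
  if (!is.na(infant_weight_kg) && infant_weight_kg <= 0) {
    stop("infant_weight_kg must be > 0", call. = FALSE)
  }
  vol <- log$volume_ml
  if (any(is.na(vol))) stop("log still contains missing volumes", call. = FALSE)
  total <- sum(vol)
  n_feeds <- length(vol)
  tibble::tibble(
    total_24h_ml = total,
    per_feed_ml = total / n_feeds,
    per_kg_ml = total / infant_weight_kg,
    n_feeds = n_feeds,
    n_missing = if (!is.null(qc)) qc$n_missing else sum(log[["imputed"]] %||% FALSE),
    n_imputed = sum(log[["imputed"]] %||% FALSE),
    n_spike_excluded = sum(log[["spike"]] %||% FALSE),
    status = "ok"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute intake summaries for every dyad-visit feed log
#'
#' Applies the full pipeline - per-feed volumes, the > 400 g spike rule,
#' the > 3-missing discard rule, hot-deck imputation - to a long table of
#' feed events, one summary row per dyad-visit. Discarded logs yield a row
#' with `status = "discarded"` and `NA` intake.
#'
#' @param feed_logs Long tibble of feed events with `dyad_id`, `visit`,
#'   `pre_weight_g`, `post_weight_g` (as emitted by [generate_cohort()]).
#' @param visit_table Optional visit table supplying `infant_weight_g` for
#'   the per-kg measure.
#' @param spike_limit_g,max_missing QC parameters, see [qc_feed_log()].
#' @return A tibble with one row per dyad-visit.
#' @export
summarize_intake_all <- function(feed_logs, visit_table = NULL,
                                 spike_limit_g = 400, max_missing = 3) {
  stopifnot(all(c("dyad_id", "visit") %in% names(feed_logs)))
  weights <- NULL
  if (!is.null(visit_table) && "infant_weight_g" %in% names(visit_table)) {
    weights <- dplyr::select(visit_table, "dyad_id", "visit", "infant_weight_g")
  }
  out <- feed_logs |>
    dplyr::group_by(.data$dyad_id, .data$visit) |>
    dplyr::group_modify(function(df, key) {
      qc <- qc_feed_log(df, spike_limit_g = spike_limit_g,
                        max_missing = max_missing)
      if (qc$discard) {
        return(tibble::tibble(
          total_24h_ml = NA_real_, per_feed_ml = NA_real_, per_kg_ml = NA_real_,
          n_feeds = nrow(df), n_missing = qc$n_missing, n_imputed = 0L,
          n_spike_excluded = sum(qc$log$spike), status = "discarded"))
      }
      imp <- hot_deck_impute(qc$log)
      summarize_intake(imp, qc = qc)
    }) |>
    dplyr::ungroup()
  if (!is.null(weights)) {
    out <- out |>
      dplyr::left_join(weights, by = c("dyad_id", "visit")) |>
      dplyr::mutate(per_kg_ml = .data$total_24h_ml /
                      (.data$infant_weight_g / 1000)) |>
      dplyr::select(-"infant_weight_g")
  }
  out
}
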