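#' Classify one dual-reporter time-lapse track
#'
#' A reporter's onset is the first frame at which it is on and stays on for
#' `persistence_frames` consecutive observed frames (flicker guard). The
#' track is then categorized by which onsets exist and their order:
#' GFP before mCherry is a `transition` (G+R- then G+R+), mCherry present
#' whenever GFP is (equal onsets) is `both_throughout`, GFP without mCherry
#' is `GFP_only`, and mCherry without GFP — or before GFP — is
#' `mCherry_only`. The onset lag is computed only for transition cells.
#' A cell whose GFP is already on at the first frame is left-censored: its
#' true GFP onset (and so its true lag) predates observation.
#'
#' @param track data.frame with columns `time_h`, `gfp`, `mcherry`
#'   (0/1 or logical), times strictly increasing, >= 2 frames; optional
#'   `cell_id`.
#' @param persistence_frames consecutive on-frames required to call an
#'   onset (default 1).
#' @return one-row data.frame: cell_id, category, t_gfp_first,
#'   t_mcherry_first, lag_h, left_censored.
#' @export
classify_track <- function(track, persistence_frames = 1L) {
  stopifnot(all(c("time_h", "gfp", "mcherry") %in% names(track)))
  t <- track$time_h
  if (length(t) < 2 || any(diff(t) <= 0)) {
    stop("track needs >= 2 frames with strictly increasing times")
  }
  onset <- function(state) {
    state <- as.logical(state)
    runs <- rle(state)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    ok <- runs$values & runs$lengths >= persistence_frames
    if (!any(ok)) return(NA_real_)
    t[starts[which(ok)[1]]]
  }
  tg <- onset(track$gfp)
  tm <- onset(track$mcherry)
  cell <- if ("cell_id" %in% names(track)) track$cell_id[1] else NA_character_
  if (is.na(tg) && is.na(tm)) {
    warning("track has no persistent fluorescent onset; category missing")
    cat <- NA_character_
  } else if (!is.na(tg) && is.na(tm)) {
    cat <- "GFP_only"
  } else if (is.na(tg) || tm < tg) {
    cat <- "mCherry_only"
  } else if (tm > tg) {
    cat <- "transition"
  } else {
    cat <- "both_throughout"
  }
  data.frame(cell_id = cell, category = cat,
             t_gfp_first = tg, t_mcherry_first = tm,
             lag_h = if (identical(cat, "transition")) tm - tg else NA_real_,
             left_censored = !is.na(tg) && tg == t[1],
             stringsAsFactors = FALSE)
}

#' Classify every track in a long-format track table
#'
#' @param tracks data.frame with columns cell_id, time_h, gfp, mcherry
#'   (one row per cell per frame), as produced by [simulate_tracks()].
#' @param persistence_frames see [classify_track()].
#' @return data.frame with one classification row per cell.
#' @export
classify_tracks <- function(tracks, persistence_frames = 1L) {
  out <- lapply(split(tracks, tracks$cell_id), classify_track,
                persistence_frames = persistence_frames)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$cell_id), , drop = FALSE]
}

#' Mean and SEM of the GFP-to-mCherry onset lag
#'
#' Arithmetic mean and standard error (sample SD / sqrt(n)) of `lag_h`
#' over transition cells. Left-censored transition cells (GFP already on
#' at the first frame, so the lag is only a lower bound) are excluded
#' unless `include_censored`.
#'
#' @param classes classification table from [classify_tracks()].
#' @param include_censored include left-censored transition cells.
#' @return list: mean_h, sem_h (NA when n = 1), n.
#' @export
summarize_lags <- function(classes, include_censored = FALSE) {
  el <- classes$category %in% "transition"
  if (!include_censored) el <- el & !classes$left_censored
  lags <- classes$lag_h[el]
  if (length(lags) == 0) stop("no eligible transition cells")
  list(mean_h = mean(lags),
       sem_h = if (length(lags) > 1) {
         stats::sd(lags) / sqrt(length(lags))
       } else NA_real_,
       n = length(lags))
}

#' Crypt/villus co-localization fractions
#'
#' Per animal and region: the double-positive fraction of all detected
#' fluorescent cells, and of the GFP-positive cells; then per region the
#' mean and SEM across animals. Animal/region cells with a zero
#' denominator are excluded with a warning.
#'
#' @param counts data.frame as from [simulate_compartment_counts()]
#'   (animal_id, region, n_double, n_gfp_only, n_mcherry_only,
#'   n_total_cells).
#' @return list: `per_animal` (fractions per animal and region) and
#'   `summary` (per region: mean and SEM of both fractions, n animals).
#' @export
colocalization_fractions <- function(counts) {
  req <- c("animal_id", "region", "n_double", "n_gfp_only", "n_mcherry_only")
  stopifnot(all(req %in% names(counts)))
  det <- counts$n_double + counts$n_gfp_only + counts$n_mcherry_only
  gfp <- counts$n_double + counts$n_gfp_only
  bad <- det == 0 | gfp == 0
  if (any(bad)) {
    warning("excluding animal/region rows with zero denominator: ",
            paste(counts$animal_id[bad], counts$region[bad], collapse = "; "))
  }
  pa <- data.frame(animal_id = counts$animal_id, region = counts$region,
                   fraction_double_of_detected = ifelse(det > 0, counts$n_double / det, NA),
                   fraction_double_of_gfp = ifelse(gfp > 0, counts$n_double / gfp, NA),
                   stringsAsFactors = FALSE)
  pa <- pa[!bad, , drop = FALSE]
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  sm <- do.call(rbind, lapply(split(pa, pa$region), function(d) {
    data.frame(region = d$region[1], n_animals = nrow(d),
               mean_double_of_detected = mean(d$fraction_double_of_detected),
               sem_double_of_detected = sem(d$fraction_double_of_detected),
               mean_double_of_gfp = mean(d$fraction_double_of_gfp),
               sem_double_of_gfp = sem(d$fraction_double_of_gfp),
               stringsAsFactors = FALSE)
  }))
  rownames(sm) <- NULL
  list(per_animal = pa, summary = sm)
}
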