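# --- linking ----------------------------------------------------------------

# index of the nearest row of `cand` to point p, ties broken by
# lexicographic (x, y, z); returns c(index, distance)
nearestIdx <- function(p, cand) {
  d <- sqrt(colSums((t(cand) - p)^2))
  o <- order(d, cand[, 1], cand[, 2], cand[, 3])
  c(o[1L], d[o[1L]])
}

#' Link detections across timepoints into punctum tracks
#'
#' Consecutive-timepoint links are formed by mutual nearest neighbours within
#' `maxDisplacementUm` (default 0.5 um, the displacement scale below which
#' tracked puncta are considered the same object). Unlinked detections open
#' new tracks; a track that loses its match is closed, and a later
#' reappearance at the same site begins a new track (so a one-timepoint
#' disappearance counts as one loss plus one gain). With `allowGaps = TRUE`
#' a closed track may instead be bridged across a single missing timepoint to
#' a track starting two timepoints later at the same site (sensitivity-
#' analysis mode). Ties are broken by smaller centroid distance, then by
#' lexicographic coordinates, so linking is deterministic.
#'
#' @param detections data.frame as returned by [detectSeries()]: columns
#'   `timepoint`, `x_um`, `y_um`, `z_um` (other columns are carried along).
#' @param maxDisplacementUm gating radius in micrometres (default 0.5).
#' @param allowGaps bridge single-timepoint gaps (default `FALSE`).
#' @param nTimepoints total number of session timepoints (default: maximum
#'   timepoint seen).
#' @param intervalMin minutes between timepoints (default 30).
#' @return An object of class `punctaTracks`: a list with
#'   `tracks` (data.frame: `track_id`, `birth_tp`, `death_tp`, `censored`,
#'   `lifetime_min`), `presence` (logical matrix, tracks x timepoints),
#'   `detections` (the input with a `track_id` column), `nTimepoints` and
#'   `intervalMin`.
#' @export
linkDetections <- function(detections, maxDisplacementUm = 0.5,
                           allowGaps = FALSE, nTimepoints = NULL,
                           intervalMin = 30) {
  stopifnot(maxDisplacementUm > 0)
  need <- c("timepoint", "x_um", "y_um", "z_um")
  if (!all(need %in% names(detections)))
    stop("detections must have columns: ", paste(need, collapse = ", "))
  if (is.null(nTimepoints))
    nTimepoints <- if (nrow(detections) > 0) max(detections$timepoint) else 0L
  tpn <- as.integer(nTimepoints)

  det <- detections
  det$.row <- seq_len(nrow(det))
  det$track_id <- NA_integer_

  for (t in unique(det$timepoint)) {
    xyz <- det[det$timepoint == t, c("x_um", "y_um", "z_um"), drop = FALSE]
    if (anyDuplicated(xyz))
      stop("duplicate detections at identical coordinates at timepoint ", t,
           "; this indicates a detection-stage bug")
  }

  nextId <- 0L
  openTrack <- integer(0)   # track id open at the current timepoint
  openRow <- integer(0)     # detection row of that track at current tp
  for (t in seq_len(tpn)) {
    rows <- det$.row[det$timepoint == t]
    linkedRows <- integer(0)
    if (t > 1L && length(openRow) > 0L && length(rows) > 0L) {
      a <- as.matrix(det[openRow, c("x_um", "y_um", "z_um")])
      b <- as.matrix(det[rows, c("x_um", "y_um", "z_um")])
      nnAB <- t(vapply(seq_len(nrow(a)),
                       function(i) nearestIdx(a[i, ], b), numeric(2)))
      nnBA <- t(vapply(seq_len(nrow(b)),
                       function(j) nearestIdx(b[j, ], a), numeric(2)))
      stillOpen <- rep(TRUE, length(openRow))
      for (i in seq_len(nrow(a))) {
        j <- nnAB[i, 1L]
        if (nnAB[i, 2L] <= maxDisplacementUm && nnBA[j, 1L] == i) {
          det$track_id[det$.row == rows[j]] <- openTrack[i]
          linkedRows <- c(linkedRows, rows[j])
          openRow[i] <- rows[j]
          stillOpen[i] <- TRUE
        } else {
          stillOpen[i] <- FALSE
        }
      }
      openTrack <- openTrack[stillOpen]
      openRow <- openRow[stillOpen]
    } else if (t > 1L) {
      openTrack <- integer(0); openRow <- integer(0)
    }
    # unlinked detections open new tracks
    newRows <- setdiff(rows, linkedRows)
    for (r in newRows) {
      nextId <- nextId + 1L
      det$track_id[det$.row == r] <- nextId
      openTrack <- c(openTrack, nextId)
      openRow <- c(openRow, r)
    }
  }

  buildTracksObject(det, tpn, intervalMin,
                    allowGaps = allowGaps,
                    maxDisplacementUm = maxDisplacementUm)
}

buildTracksObject <- function(det, tpn, intervalMin, allowGaps = FALSE,
                              maxDisplacementUm = 0.5) {
  ids <- sort(unique(det$track_id))
  presence <- matrix(FALSE, length(ids), tpn,
                     dimnames = list(ids, NULL))
  for (k in seq_along(ids))
    presence[k, det$timepoint[det$track_id == ids[k]]] <- TRUE

  if (allowGaps && length(ids) > 1L) {
    # bridge a track ending at t to one starting at t+2 at the same site
    repeat {
      merged <- FALSE
      info <- lapply(seq_len(nrow(presence)), function(k) {
        w <- which(presence[k, ])
        c(first = w[1L], last = w[length(w)])
      })
      cand <- list()
      for (k in seq_len(nrow(presence))) {
        for (m in seq_len(nrow(presence))) {
          if (k == m) next
          if (info[[m]]["first"] - info[[k]]["last"] != 2L) next
          pa <- det[det$track_id == ids[k] &
                    det$timepoint == info[[k]]["last"],
                    c("x_um", "y_um", "z_um")]
          pb <- det[det$track_id == ids[m] &
                    det$timepoint == info[[m]]["first"],
                    c("x_um", "y_um", "z_um")]
          dd <- sqrt(sum((as.numeric(pa) - as.numeric(pb))^2))
          if (dd <= maxDisplacementUm)
            cand[[length(cand) + 1L]] <- c(k, m, dd)
        }
      }
      if (length(cand) > 0L) {
        cand <- do.call(rbind, cand)
        cand <- cand[order(cand[, 3L]), , drop = FALSE]
        k <- cand[1L, 1L]; m <- cand[1L, 2L]
        det$track_id[det$track_id == ids[m]] <- ids[k]
        presence[k, ] <- presence[k, ] | presence[m, ]
        # the bridged timepoint counts as present: no loss + gain pair
        presence[k, info[[k]]["last"] + 1L] <- TRUE
        presence <- presence[-m, , drop = FALSE]
        ids <- ids[-m]
        merged <- TRUE
      }
      if (!merged) break
    }
  }

  birth <- apply(presence, 1L, function(p) which(p)[1L])
  death <- apply(presence, 1L, function(p) {
    w <- which(p); w[length(w)]
  })
  censored <- death == tpn
  tracks <- data.frame(track_id = ids, birth_tp = birth, death_tp = death,
                       censored = censored,
                       lifetime_min = (death - birth + 1L) * intervalMin)
  det$.row <- NULL
  structure(list(tracks = tracks, presence = presence, detections = det,
                 nTimepoints = tpn, intervalMin = intervalMin),
            class = c("punctaTracks", "list"))
}

#' @export
print.punctaTracks <- function(x, ...) {
  cat("punctaTracks:", nrow(x$tracks), "track(s) over", x$nTimepoints,
      "timepoints (", x$intervalMin, "min interval )\n")
  cat("  present at t0:", sum(x$presence[, 1L]),
      "; at final timepoint:", sum(x$presence[, x$nTimepoints]), "\n")
  invisible(x)
}

#' Remove transient (transport-packet-like) tracks
#'
#' Drops tracks whose longest consecutive presence run is shorter than two
#' timepoints, the inclusion rule that minimizes the contribution of
#' transient transport packets to the turnover statistics.
#'
#' @param tracks a `punctaTracks` object from [linkDetections()].
#' @return The filtered `punctaTracks`; the number of removed tracks is
#'   attached as `attr(, "n_removed")`.
#' @export
filterTransients <- function(tracks) {
  stopifnot(inherits(tracks, "punctaTracks"))
  keep <- apply(tracks$presence, 1L, function(p) longestRun(p) >= 2L)
  out <- tracks
  out$tracks <- tracks$tracks[keep, , drop = FALSE]
  out$presence <- tracks$presence[keep, , drop = FALSE]
  out$detections <- tracks$detections[
    tracks$detections$track_id %in% tracks$tracks$track_id[keep], ,
    drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Survival times of newly formed puncta
#'
#' For every track born within the appearance window (by default the first
#' hour, i.e. at 30 or 60 min), the observed survival time in minutes from
#' birth to the last timepoint present, right-censored at the session end.
#'
#' @param tracks a filtered `punctaTracks` object.
#' @param appearanceWindowMin latest birth time (minutes) included
#'   (default 60).
#' @return A data.frame: `track_id`, `birth_min`, `survival_min`,
#'   `censored`; fractions surviving at least 60 and at least 120 minutes
#'   are attached as `attr(, "frac_surviving_60")` and
#'   `attr(, "frac_surviving_120")`.
#' @export
survivalTimes <- function(tracks, appearanceWindowMin = 60) {
  stopifnot(inherits(tracks, "punctaTracks"))
  tr <- tracks$tracks
  iv <- tracks$intervalMin
  birthMin <- (tr$birth_tp - 1L) * iv
  sel <- tr$birth_tp > 1L & birthMin <= appearanceWindowMin
  tr <- tr[sel, , drop = FALSE]
  out <- data.frame(track_id = tr$track_id,
                    birth_min = (tr$birth_tp - 1L) * iv,
                    survival_min = (tr$death_tp - tr$birth_tp) * iv,
                    censored = tr$censored)
  attr(out, "frac_surviving_60") <-
    if (nrow(out) > 0) mean(out$survival_min >= 60) else NA_real_
  attr(out, "frac_surviving_120") <-
    if (nrow(out) > 0) mean(out$survival_min >= 120) else NA_real_
  out
}
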