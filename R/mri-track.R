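## Diameter-based filtering, longitudinal tracking of individual tubers
## and condition-level growth summaries.

#' Apply the detectability and yield diameter rules
#'
#' Tubers whose final-session equivalent diameter is under
#' \code{yieldMin} (strictly: exactly 15 mm is retained) are removed from
#' every session, as they do not count towards tuber yield. Any remaining
#' record with a diameter below \code{detectMin} is flagged
#' sub-detectable but kept. Every tuber must have a record at the final
#' session, otherwise the yield rule cannot be applied.
#'
#' @param records data.frame with at least tuber_id, dase,
#'   eq_diameter_mm (e.g. rows of \code{\link{measureTubers}} across
#'   sessions)
#' @param detectMin detectability threshold in mm (default 3)
#' @param yieldMin yield-inclusion threshold at the final session in mm
#'   (default 15)
#' @param finalDase the final measurement day (default: max dase present)
#' @return list with \code{records} (retained rows plus a
#'   \code{subdetectable} flag) and \code{exclusions} (tuber_id,
#'   final_diameter_mm, reason)
#' @export
filterTubers <- function(records, detectMin = 3, yieldMin = 15,
                         finalDase = NULL) {
  stopIfNot(all(c("tuber_id", "dase", "eq_diameter_mm") %in% names(records)),
            "records needs tuber_id, dase and eq_diameter_mm columns")
  if (is.null(finalDase)) finalDase <- max(records$dase)
  fin <- records[records$dase == finalDase, , drop = FALSE]
  missing <- setdiff(unique(records$tuber_id), fin$tuber_id)
  stopIfNot(length(missing) == 0,
            "tuber(s) %s have no record at the final session (dase %s)",
            paste(missing, collapse = ","), finalDase)
  drop <- fin$tuber_id[fin$eq_diameter_mm < yieldMin]
  excl <- data.frame(
    tuber_id = drop,
    final_diameter_mm = fin$eq_diameter_mm[match(drop, fin$tuber_id)],
    reason = rep(sprintf("final equivalent diameter under %g mm (yield rule)",
                         yieldMin), length(drop)))
  keep <- records[!(records$tuber_id %in% drop), , drop = FALSE]
  keep$subdetectable <- keep$eq_diameter_mm < detectMin
  rownames(keep) <- NULL
  list(records = keep, exclusions = excl)
}

#' Track individual tubers across imaging sessions
#'
#' Pots keep a marked position between MRI sessions, so a tuber's
#' centroid barely moves; identities are therefore propagated by greedy
#' nearest-centroid matching between consecutive sessions, accepting
#' matches within \code{radius} mm (globally smallest distances first, so
#' when two tubers compete for one predecessor the closer one wins and
#' the other starts a new track). Unmatched tubers open new tracks.
#' Tracks are ranked Tuber-01, Tuber-02, ... by their last observed
#' volume, in decreasing order.
#'
#' @param sessions data.frame of per-session records (needs dase,
#'   tuber_id, volume_cm3, cz, cy, cx; \code{\link{measureTubers}} rows
#'   bound together), or a list of such data.frames
#' @param radius maximum centroid displacement in mm (default 15)
#' @return list with \code{growth} (track_id, tuber_label, dase,
#'   session_tuber_id, volume_cm3, eq_diameter_mm if present, cz, cy,
#'   cx), \code{ranking} (track_id, tuber_label, final_volume_cm3) and
#'   \code{log} (match decisions)
#' @export
trackTubers <- function(sessions, radius = 15) {
  if (is.list(sessions) && !is.data.frame(sessions))
    sessions <- do.call(rbind, sessions)
  need <- c("dase", "tuber_id", "volume_cm3", "cz", "cy", "cx")
  stopIfNot(all(need %in% names(sessions)),
            "sessions needs columns %s", paste(need, collapse = ", "))
  days <- sort(unique(sessions$dase))
  stopIfNot(length(days) >= 2, "at least two sessions are required")
  bySession <- lapply(days, function(d)
    sessions[sessions$dase == d, , drop = FALSE])

  first <- bySession[[1]]
  tracks <- lapply(seq_len(nrow(first)), function(i)
    list(rows = first[i, , drop = FALSE]))
  logRows <- list()
  for (s in seq_along(bySession)[-1]) {
    cur <- bySession[[s]]
    last <- t(vapply(tracks, function(tr) {
      r <- tr$rows[nrow(tr$rows), ]
      c(r$cz, r$cy, r$cx)
    }, numeric(3)))
    D <- outer(seq_len(nrow(last)), seq_len(nrow(cur)),
               Vectorize(function(i, j)
                 sqrt(sum((last[i, ] - c(cur$cz[j], cur$cy[j], cur$cx[j]))^2))))
    D <- matrix(D, nrow(last), nrow(cur))
    usedTr <- logical(nrow(last)); usedCur <- logical(nrow(cur))
    repeat {
      D2 <- D
      D2[usedTr, ] <- Inf; D2[, usedCur] <- Inf
      if (!any(is.finite(D2)) || min(D2) > radius) break
      w <- which(D2 == min(D2), arr.ind = TRUE)[1, ]
      i <- w[1]; j <- w[2]
      tracks[[i]]$rows <- rbind(tracks[[i]]$rows, cur[j, , drop = FALSE])
      usedTr[i] <- TRUE; usedCur[j] <- TRUE
      logRows[[length(logRows) + 1]] <- data.frame(
        dase = days[s], session_tuber_id = cur$tuber_id[j],
        track_id = i, distance_mm = D[i, j], action = "matched")
    }
    for (j in which(!usedCur)) {
      tracks[[length(tracks) + 1]] <- list(rows = cur[j, , drop = FALSE])
      logRows[[length(logRows) + 1]] <- data.frame(
        dase = days[s], session_tuber_id = cur$tuber_id[j],
        track_id = length(tracks), distance_mm = NA_real_,
        action = "new-track")
    }
  }
  finalVol <- vapply(tracks, function(tr)
    tr$rows$volume_cm3[nrow(tr$rows)], 0)
  rank <- order(finalVol, decreasing = TRUE)
  labels <- character(length(tracks))
  labels[rank] <- sprintf("Tuber-%02d", seq_along(tracks))
  growth <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    r <- tracks[[i]]$rows
    data.frame(track_id = i, tuber_label = labels[i], dase = r$dase,
               session_tuber_id = r$tuber_id, volume_cm3 = r$volume_cm3,
               eq_diameter_mm = if ("eq_diameter_mm" %in% names(r))
                 r$eq_diameter_mm else NA_real_,
               cz = r$cz, cy = r$cy, cx = r$cx)
  }))
  growth <- growth[order(growth$track_id, growth$dase), ]
  rownames(growth) <- NULL
  ranking <- data.frame(track_id = seq_along(tracks), tuber_label = labels,
                        final_volume_cm3 = finalVol)
  ranking <- ranking[order(ranking$final_volume_cm3, decreasing = TRUE), ]
  rownames(ranking) <- NULL
  list(growth = growth, ranking = ranking,
       log = if (length(logRows)) do.call(rbind, logRows) else NULL)
}

#' Summarise tuber counts and total volumes per condition
#'
#' Computes, for each condition and measurement day, the mean and
#' standard error of the per-plant tuber count and total tuber volume,
#' and (when every condition has at least two plants) Tukey HSD compact
#' letters comparing conditions at that day via
#' \code{\link{anovaTukeyLetters}}.
#'
#' @param records data.frame with plant_id, condition, dase, volume_cm3
#'   (one row per tuber, session and plant)
#' @param alpha significance level for the letters (default 0.05)
#' @return data.frame with condition, dase, n_plants, mean_count,
#'   se_count, mean_total_volume_cm3, se_total_volume_cm3, letter_count,
#'   letter_volume (letters NA when any condition has < 2 plants)
#' @export
summarizeConditions <- function(records, alpha = 0.05) {
  need <- c("plant_id", "condition", "dase", "volume_cm3")
  stopIfNot(all(need %in% names(records)),
            "records needs columns %s", paste(need, collapse = ", "))
  perPlant <- do.call(rbind, lapply(
    split(records, records[c("plant_id", "condition", "dase")], drop = TRUE),
    function(g) data.frame(plant_id = g$plant_id[1],
                           condition = g$condition[1], dase = g$dase[1],
                           n_tubers = nrow(g),
                           total_volume_cm3 = sum(g$volume_cm3))))
  out <- list()
  for (d in sort(unique(perPlant$dase))) {
    pd <- perPlant[perPlant$dase == d, , drop = FALSE]
    conds <- unique(pd$condition)
    nPer <- vapply(conds, function(cc) sum(pd$condition == cc), 0L)
    letters <- NULL
    if (length(conds) >= 2 && all(nPer >= 2)) {
      lc <- anovaTukeyLetters(pd$n_tubers, pd$condition, alpha = alpha)
      lv <- anovaTukeyLetters(pd$total_volume_cm3, pd$condition,
                              alpha = alpha)
      letters <- list(count = stats::setNames(lc$letters, lc$group),
                      volume = stats::setNames(lv$letters, lv$group))
    }
    for (cc in conds) {
      g <- pd[pd$condition == cc, ]
      n <- nrow(g)
      out[[length(out) + 1]] <- data.frame(
        condition = cc, dase = d, n_plants = n,
        mean_count = mean(g$n_tubers),
        se_count = if (n > 1) stats::sd(g$n_tubers) / sqrt(n) else NA_real_,
        mean_total_volume_cm3 = mean(g$total_volume_cm3),
        se_total_volume_cm3 = if (n > 1)
          stats::sd(g$total_volume_cm3) / sqrt(n) else NA_real_,
        letter_count = if (is.null(letters)) NA_character_
                       else unname(letters$count[cc]),
        letter_volume = if (is.null(letters)) NA_character_
                        else unname(letters$volume[cc]))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
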