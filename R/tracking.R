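# Gated one-to-one minimum-cost matching between two point sets.
# Costs are squared distances; pairs beyond max_dist are forbidden. The
# assignment problem is augmented with per-point "no match" alternatives
# priced just above the gate, so leaving a point unmatched is always preferred
# to an over-gate link; clue::solve_LSAP (Hungarian algorithm) solves the
# augmented square problem exactly.
match_points <- function(xy_a, xy_b, max_dist) {
  n <- nrow(xy_a)
  m <- nrow(xy_b)
  if (n == 0L || m == 0L) return(cbind(a = integer(0), b = integer(0)))
  d2 <- outer(xy_a[, 1], xy_b[, 1], "-")^2 + outer(xy_a[, 2], xy_b[, 2], "-")^2
  gate2 <- max_dist^2
  big <- 4 * gate2 + 1
  forbid <- 1e6 * (gate2 + 1)
  link <- d2
  link[link > gate2] <- forbid
  size <- n + m
  cost <- matrix(0, size, size)
  cost[seq_len(n), seq_len(m)] <- link
  cost[seq_len(n), m + seq_len(n)] <- forbid
  cost[cbind(seq_len(n), m + seq_len(n))] <- big
  cost[n + seq_len(m), seq_len(m)] <- forbid
  cost[cbind(n + seq_len(m), seq_len(m))] <- big
  sol <- clue::solve_LSAP(cost)
  a_idx <- seq_len(n)
  b_idx <- as.integer(sol[seq_len(n)])
  ok <- b_idx <= m & d2[cbind(a_idx, pmin(b_idx, m))] <= gate2
  cbind(a = a_idx[ok], b = b_idx[ok])
}

#' Link per-frame detections into trajectories
#'
#' A linear-assignment-problem tracker: detections in consecutive frames are
#' linked by the one-to-one pairing that minimizes total squared displacement
#' among pairs closer than `max_link_dist`; every unmatched detection starts a
#' new track. A second, gap-closing pass then re-joins terminated track ends
#' to later track starts across up to `max_gap` skipped frames, again by
#' minimum-cost matching gated at `max_gap_dist`, processing the shortest gaps
#' first. Every detection ends up in exactly one track; singleton tracks are
#' permitted. Defaults mirror common single-molecule TrackMate settings
#' (1.5 um link distance, 2-frame gap, 1.5 um gap distance).
#'
#' @param detections a detection table (data frame with columns
#'   `frame, x_um, y_um`, optionally `intensity` and `truth_id`).
#' @param max_link_dist maximum frame-to-frame link distance in micrometres.
#' @param max_gap maximum number of skipped frames bridged by gap closing.
#' @param max_gap_dist maximum distance in micrometres for a gap-closing link.
#' @param frame_interval frame interval in seconds, stored on the result.
#' @return A [trajectory_set()]; track ids are renumbered in order of first
#'   appearance (first frame, then x position) for determinism.
#' @export
link_detections <- function(detections, max_link_dist = 1.5, max_gap = 2,
                            max_gap_dist = 1.5, frame_interval = 0.02) {
  if (max_link_dist < 0 || max_gap_dist < 0) stop("distances must be >= 0")
  if (max_gap < 0) stop("max_gap must be >= 0")
  det <- as.data.frame(detections)
  if (nrow(det) == 0L) {
    return(trajectory_set(data.frame(track_id = integer(0), frame = integer(0),
                                     x_um = numeric(0), y_um = numeric(0)),
                          frame_interval = frame_interval))
  }
  if (!all(c("frame", "x_um", "y_um") %in% names(det))) {
    stop("detections need columns frame, x_um, y_um")
  }
  det <- det[order(det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det$.row <- seq_len(nrow(det))
  frames <- sort(unique(det$frame))
  by_frame <- split(det, det$frame)

  track_of <- integer(nrow(det))   # track id per detection row
  next_id <- 0L
  # active track state: id -> (last frame, x, y); stored as a data frame
  act_id <- integer(0); act_frame <- integer(0)
  act_x <- numeric(0); act_y <- numeric(0)

  for (f in frames) {
    cur <- by_frame[[as.character(f)]]
    prev_mask <- act_frame == f - 1L
    linked_det <- rep(FALSE, nrow(cur))
    if (any(prev_mask) && nrow(cur) > 0L) {
      ia <- which(prev_mask)
      mm <- match_points(cbind(act_x[ia], act_y[ia]),
                         cbind(cur$x_um, cur$y_um), max_link_dist)
      if (nrow(mm) > 0L) {
        ids <- act_id[ia[mm[, "a"]]]
        track_of[cur$.row[mm[, "b"]]] <- ids
        act_frame[ia[mm[, "a"]]] <- f
        act_x[ia[mm[, "a"]]] <- cur$x_um[mm[, "b"]]
        act_y[ia[mm[, "a"]]] <- cur$y_um[mm[, "b"]]
        linked_det[mm[, "b"]] <- TRUE
      }
    }
    n_new <- sum(!linked_det)
    if (n_new > 0L) {
      new_ids <- next_id + seq_len(n_new)
      next_id <- next_id + n_new
      track_of[cur$.row[!linked_det]] <- new_ids
      act_id <- c(act_id, new_ids)
      act_frame <- c(act_frame, rep(f, n_new))
      act_x <- c(act_x, cur$x_um[!linked_det])
      act_y <- c(act_y, cur$y_um[!linked_det])
    }
  }

  det$track_id <- track_of

  # gap closing: union-find over track segments, shortest gap first
  if (max_gap > 0L) {
    seg <- segment_table(det)
    parent <- seq_len(nrow(seg))
    find_root <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (g in seq_len(max_gap)) {
      roots <- unique(vapply(seq_len(nrow(seg)), find_root, integer(1)))
      ends <- data.frame(root = roots,
                         frame = seg$end_frame[roots],
                         x = seg$end_x[roots], y = seg$end_y[roots])
      starts <- data.frame(root = roots,
                           frame = seg$start_frame[roots],
                           x = seg$start_x[roots], y = seg$start_y[roots])
      # candidate pairs: end at frame f, start at frame f + g + 1
      for (f in sort(unique(ends$frame))) {
        ei <- which(ends$frame == f)
        si <- which(starts$frame == f + g + 1L)
        if (length(ei) == 0L || length(si) == 0L) next
        mm <- match_points(cbind(ends$x[ei], ends$y[ei]),
                           cbind(starts$x[si], starts$y[si]), max_gap_dist)
        for (r in seq_len(nrow(mm))) {
          ra <- ends$root[ei[mm[r, "a"]]]
          rb <- starts$root[si[mm[r, "b"]]]
          # merge: combined segment keeps ra's start and rb's end
          parent[rb] <- ra
          seg$end_frame[ra] <- seg$end_frame[rb]
          seg$end_x[ra] <- seg$end_x[rb]
          seg$end_y[ra] <- seg$end_y[rb]
        }
        if (nrow(mm) > 0L) {
          roots <- unique(vapply(seq_len(nrow(seg)), find_root, integer(1)))
          ends <- data.frame(root = roots, frame = seg$end_frame[roots],
                             x = seg$end_x[roots], y = seg$end_y[roots])
          starts <- data.frame(root = roots, frame = seg$start_frame[roots],
                               x = seg$start_x[roots], y = seg$start_y[roots])
        }
      }
    }
    root_of <- vapply(seq_len(nrow(seg)), find_root, integer(1))
    det$track_id <- seg$track_id[root_of[match(det$track_id, seg$track_id)]]
  }

  # renumber by first appearance (frame, then x) for determinism
  first <- det[!duplicated(det$track_id), c("track_id", "frame", "x_um")]
  first <- first[order(first$frame, first$x_um), ]
  remap <- stats::setNames(seq_len(nrow(first)), first$track_id)
  det$track_id <- as.integer(remap[as.character(det$track_id)])

  out <- det[, c("track_id", "frame", "x_um", "y_um")]
  trajectory_set(out, frame_interval = frame_interval)
}

# per-track segment summary (first/last frame and endpoint positions),
# ordered by track id
segment_table <- function(det) {
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  firsts <- det[!duplicated(det$track_id), , drop = FALSE]
  lasts <- det[!duplicated(det$track_id, fromLast = TRUE), , drop = FALSE]
  data.frame(track_id = firsts$track_id,
             start_frame = firsts$frame, start_x = firsts$x_um,
             start_y = firsts$y_um,
             end_frame = lasts$frame, end_x = lasts$x_um, end_y = lasts$y_um)
}

#' Filter tracks by minimum length
#'
#' @param tracks a [trajectory_set()].
#' @param min_length minimum number of localizations (default 1 = keep all;
#'   no track-length filter is applied by default because immobile molecules
#'   are part of the analysis).
#' @return A filtered [trajectory_set()]; warns if nothing is retained.
#' @export
filter_tracks <- function(tracks, min_length = 1L) {
  if (min_length < 1) stop("min_length must be >= 1")
  len <- table(tracks$track_id)
  keep <- names(len)[len >= min_length]
  out <- tracks[tracks$track_id %in% as.numeric(keep), , drop = FALSE]
  if (nrow(out) == 0L && nrow(tracks) > 0L) {
    warning("no tracks of length >= ", min_length, " retained")
  }
  message(sprintf("filter_tracks: retained %d of %d tracks (min_length = %d)",
                  length(keep), length(len), as.integer(min_length)))
  trajectory_set(as.data.frame(out), frame_interval = frame_interval(tracks))
}
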