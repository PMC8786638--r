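#' Optimally assign detections to tracks (Hungarian algorithm)
#'
#' Links predicted track positions to detections by minimising total
#' Euclidean distance over all one-to-one matchings (Munkres/Hungarian
#' assignment, via `clue::solve_LSAP`). Pairs whose distance exceeds the
#' gate are rejected: the track and the detection are both left unmatched.
#' Assignment is intended to be run independently per species.
#'
#' @param predicted Matrix (n_tracks x 2) of predicted positions.
#' @param detections Matrix (n_detections x 2) of detected centroids, in
#'   the same coordinates.
#' @param gate Maximum match distance; pairs farther apart are unmatched.
#' @return List with `matches` (two-column matrix `track`, `detection`),
#'   `unmatched_tracks` and `unmatched_detections` (integer indices).
#' @examples
#' assign_detections(rbind(c(0, 0), c(5, 5)), rbind(c(5, 5.1), c(0.1, 0)))
#' @export
assign_detections <- function(predicted, detections, gate = Inf) {
  predicted <- as_xy_matrix(predicted)
  detections <- as_xy_matrix(detections)
  nt <- nrow(predicted); nd <- nrow(detections)
  empty <- list(matches = cbind(track = integer(0), detection = integer(0)),
                unmatched_tracks = seq_len(nt),
                unmatched_detections = seq_len(nd))
  if (nt == 0L || nd == 0L) return(empty)

  cost <- sqrt(outer(predicted[, 1], detections[, 1], `-`)^2 +
                 outer(predicted[, 2], detections[, 2], `-`)^2)
  # pad to square; gated pairs get a large but finite penalty so that
  # feasible pairs are always preferred and gated ones can be stripped after
  big <- max(gate[is.finite(gate)], cost, 1) * 1e3 + 1
  n <- max(nt, nd)
  m <- matrix(big, n, n)
  m[seq_len(nt), seq_len(nd)] <- pmin(cost, big)
  m[seq_len(nt), seq_len(nd)][cost > gate] <- big
  sol <- clue::solve_LSAP(m)
  tr <- seq_len(nt)
  de <- as.integer(sol)[seq_len(nt)]
  ok <- de <= nd & cost[cbind(tr, pmin(de, nd))] <= gate
  matches <- cbind(track = tr[ok], detection = de[ok])
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), matches[, "track"]),
       unmatched_detections = setdiff(seq_len(nd), matches[, "detection"]))
}

as_xy_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L) return(matrix(numeric(0), 0L, 2L))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, ncol = 2L)
  stopifnot(ncol(x) == 2L)
  x
}
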