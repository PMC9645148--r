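#' @include canny.R
NULL

# Integer (drow, dcol) offsets tracing a circle of radius r, deduplicated.
.circleOffsets <- function(r) {
  n <- max(8L, ceiling(2 * pi * r))
  th <- 2 * pi * (seq_len(n) - 1L) / n
  o <- unique(cbind(round(r * cos(th)), round(r * sin(th))))
  o
}

#' Hough transform for circles
#'
#' Votes every edge pixel into a (row, col, radius) accumulator: for each
#' candidate radius, each edge pixel votes for all centres at that distance.
#' Candidates are ranked by raw vote count and near-duplicates (centres
#' closer than half the larger radius) are suppressed greedily, so two
#' disjoint circles each surface once. Deterministic given its input.
#'
#' @param edges An \linkS4class{EdgeMap} or a logical matrix of edge pixels.
#' @param rMin,rMax Radius search range in pixels, \code{rMin < rMax}.
#' @param nCandidates Maximum number of candidates returned.
#' @return A data.frame with columns \code{row}, \code{col}, \code{r},
#'   \code{votes} and \code{voteFrac} (votes divided by the number of
#'   accumulator cells on the circle, i.e. fraction of the circumference
#'   supported), sorted by votes descending. Empty edge maps give a
#'   zero-row data.frame.
#' @export
#' @examples
#' m <- matrix(FALSE, 64, 64)
#' th <- seq(0, 2 * pi, length.out = 200)
#' m[cbind(round(32 + 10 * cos(th)), round(32 + 10 * sin(th)))] <- TRUE
#' head(houghCircles(m, 5, 15), 1)
houghCircles <- function(edges, rMin, rMax, nCandidates = 10L) {
  if (methods::is(edges, "EdgeMap")) edges <- edgeFinal(edges)
  if (!(rMin < rMax) || rMin < 1)
    stop("radius range must satisfy 1 <= rMin < rMax")
  h <- nrow(edges); w <- ncol(edges)
  ep <- which(edges)
  out <- data.frame(row = numeric(0), col = numeric(0), r = numeric(0),
                    votes = numeric(0), voteFrac = numeric(0))
  if (!length(ep)) return(out)
  er <- ((ep - 1L) %% h) + 1L
  ec <- ((ep - 1L) %/% h) + 1L
  radii <- seq(as.integer(rMin), as.integer(rMax))
  cand <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    o <- .circleOffsets(r)
    # all candidate centres: edge pixel minus each offset
    cr <- rep(er, times = nrow(o)) - rep(o[, 1L], each = length(er))
    cc <- rep(ec, times = nrow(o)) - rep(o[, 2L], each = length(er))
    ok <- cr >= 1L & cr <= h & cc >= 1L & cc <= w
    acc <- tabulate((cc[ok] - 1L) * h + cr[ok], nbins = h * w)
    top <- order(acc, decreasing = TRUE)[seq_len(min(3L * nCandidates,
                                                     sum(acc > 0)))]
    if (!length(top)) next
    cand[[k]] <- data.frame(
      row = ((top - 1L) %% h) + 1L,
      col = ((top - 1L) %/% h) + 1L,
      r = r, votes = acc[top], voteFrac = acc[top] / nrow(o))
  }
  allc <- do.call(rbind, cand)
  if (is.null(allc) || !nrow(allc)) return(out)
  allc <- allc[order(-allc$votes, allc$r, allc$row, allc$col), ]
  # greedy non-maximum suppression in (row, col) space
  kept <- allc[0, ]
  for (i in seq_len(nrow(allc))) {
    if (nrow(kept) >= nCandidates) break
    ci <- allc[i, ]
    if (nrow(kept)) {
      d <- sqrt((kept$row - ci$row)^2 + (kept$col - ci$col)^2)
      if (any(d < pmax(kept$r, ci$r) / 2 + 2)) next
    }
    kept <- rbind(kept, ci)
  }
  rownames(kept) <- NULL
  kept
}
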