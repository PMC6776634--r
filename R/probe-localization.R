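#' Detect the probe-shadow region in a saturation frame
#'
#' The indentation probe shadows a patch of electrodes that stay
#' non-saturating under far-red light. This finds the largest 4-connected
#' component of non-saturating electrodes with at least `min_region`
#' members; smaller components (isolated flip noise) are discarded.
#' 4-connectivity (no diagonals) resists diagonal noise bridges.
#'
#' @param frame A logical `saturation_frame` (TRUE = saturating).
#' @param min_region Minimum component size, electrodes.
#' @return Integer matrix (n x 2) of (row, col) shadow coordinates, class
#'   `shadow_region`.
#' @export
detect_shadow <- function(frame, min_region = 8) {
  stopifnot(is.logical(frame), length(dim(frame)) == 2)
  nr <- nrow(frame); nc <- ncol(frame)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  # iterative flood fill over 4-neighbours
  for (start in which(!frame)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      nb <- c(if (r > 1L) cur - 1L, if (r < nr) cur + 1L,
              if (c > 1L) cur - nr, if (c < nc) cur + nr)
      nb <- nb[!frame[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      stack <- c(stack, nb)
    }
  }
  if (nxt == 0L) {
    stop(structure(class = c("retinamech_no_shadow", "error", "condition"),
                   list(message = "no non-saturating electrodes in frame",
                        call = sys.call())))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = nxt)
  best <- which.max(sizes)
  if (sizes[best] < min_region) {
    stop(structure(class = c("retinamech_no_shadow", "error", "condition"),
                   list(message = sprintf(
                     "largest shadow component has %d electrodes (< min_region = %d)",
                     sizes[best], min_region), call = sys.call())))
  }
  idx <- which(lab == best)
  structure(cbind(row = (idx - 1L) %% nr + 1L,
                  col = (idx - 1L) %/% nr + 1L),
            class = c("shadow_region", "matrix", "array"))
}

#' Estimate the probe center from a shadow region
#'
#' Centroid of the shadow coordinates, rounded to the nearest electrode;
#' exact half-way ties break toward the smaller row, then column.
#'
#' @param shadow A `shadow_region` (or any n x 2 coordinate matrix).
#' @return Integer (row, col) electrode coordinate.
#' @export
estimate_center <- function(shadow) {
  if (is.null(dim(shadow)) || nrow(shadow) == 0) {
    stop_invalid("shadow region must be non-empty")
  }
  ctr <- colMeans(shadow)
  # round half-way cases down (toward smaller index)
  snap <- function(x) ceiling(x - 0.5)
  c(row = snap(ctr[[1]]), col = snap(ctr[[2]]))
}

#' Locate the indentation probe from one or more saturation frames
#'
#' With several frames (timestamps), the one maximizing the contrast
#' between saturating and non-saturating electrode counts is selected, as
#' done by eye on the rig; `manual_override` bypasses estimation entirely.
#'
#' @param frames A `saturation_frame` or list of them.
#' @param min_region Minimum shadow size passed to [detect_shadow()].
#' @param manual_override Optional (row, col) coordinate returned as-is.
#' @return List with `center` (row, col), `shadow`, and `frame_index`.
#' @export
locate_probe <- function(frames, min_region = 8, manual_override = NULL) {
  if (!is.null(manual_override)) {
    return(list(center = c(row = manual_override[1], col = manual_override[2]),
                shadow = NULL, frame_index = NA_integer_))
  }
  if (!is.list(frames)) frames <- list(frames)
  # the frame where the saturating/non-saturating difference is most
  # noticeable: the one with the most saturating electrodes (light fully
  # on, shadow at its crispest)
  pick <- which.max(vapply(frames, sum, numeric(1)))
  shadow <- detect_shadow(frames[[pick]], min_region = min_region)
  list(center = estimate_center(shadow), shadow = shadow, frame_index = pick)
}
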