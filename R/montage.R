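#' Template 2-D positions for the default 32-channel 10-20 montage
#'
#' Head-top view with the nose pointing up; x grows to the right, y to the
#' front, and the outer 10-20 ring has radius 1. The two ocular channels
#' (VEOG, HEOG) carry no scalp position and never enter the adjacency graph.
#'
#' @return A data.frame with columns `channel`, `x`, `y`.
#' @export
#' @examples
#' head(montage_positions())
montage_positions <- function() {
  deg <- function(a) a * pi / 180
  ring <- function(ang) c(cos(deg(ang)), sin(deg(ang)))
  pos <- rbind(
    Fp1 = ring(108), Fp2 = ring(72),
    F7  = ring(144), F8  = ring(36),
    T7  = ring(180), T8  = ring(0),
    P7  = ring(-144), P8 = ring(-36),
    O1  = ring(-108), Oz = ring(-90), O2 = ring(-72),
    Fz  = c(0, 0.5),  Cz = c(0, 0),   Pz = c(0, -0.5),
    F3  = c(-0.39, 0.47), F4 = c(0.39, 0.47),
    C3  = c(-0.5, 0),     C4 = c(0.5, 0),
    P3  = c(-0.39, -0.47), P4 = c(0.39, -0.47),
    FC5 = c(-0.63, 0.28), FC1 = c(-0.22, 0.26),
    FC2 = c(0.22, 0.26),  FC6 = c(0.63, 0.28),
    CP5 = c(-0.63, -0.28), CP1 = c(-0.22, -0.26),
    CP2 = c(0.22, -0.26),  CP6 = c(0.63, -0.28),
    PO9 = c(-0.52, -0.95), PO10 = c(0.52, -0.95)
  )
  data.frame(channel = rownames(pos), x = pos[, 1], y = pos[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default channel set of the synthetic montage
#'
#' Thirty EEG channels of the 10-20 system plus two ocular channels.
#' @return Character vector of channel labels, EOG last.
#' @export
default_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2", "PO9", "PO10",
    "VEOG", "HEOG")
}

#' Channel adjacency graph from template positions
#'
#' Two channels are neighbours when their template 2-D distance is below
#' `threshold` (expressed in units of the outer 10-20 ring radius). Channels
#' without a template position (the ocular channels) have no neighbours.
#' The default threshold keeps the occipital chain O1-Oz-O2 and the right
#' parieto-occipital set P4-P8-O2 connected.
#'
#' @param channels character vector of channel labels.
#' @param threshold neighbour distance cutoff (default 0.55).
#' @return A symmetric logical matrix with `FALSE` diagonal, class
#'   `wm_adjacency`.
#' @export
#' @examples
#' adj <- channel_adjacency(c("O1", "Oz", "O2", "P4", "P8"))
#' adj["O1", "Oz"]
channel_adjacency <- function(channels, threshold = 0.55) {
  pos <- montage_positions()
  n <- length(channels)
  adj <- matrix(FALSE, n, n, dimnames = list(channels, channels))
  idx <- match(channels, pos$channel)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || is.na(idx[i]) || is.na(idx[j])) next
      d <- sqrt((pos$x[idx[i]] - pos$x[idx[j]])^2 +
                  (pos$y[idx[i]] - pos$y[idx[j]])^2)
      adj[i, j] <- d < threshold
    }
  }
  stopifnot(identical(adj, t(adj)))
  class(adj) <- c("wm_adjacency", class(adj))
  adj
}
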