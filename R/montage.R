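#' Standard 31-channel 10-20 montage
#'
#' Returns the scalp positions of the 31 EEG channels used throughout the
#' package (10-20 labels including the mastoids TP9/TP10 and the posterior
#' midline sites Cz, CP1, CP2, Pz, POz, O1, Oz, O2 over which the gastric
#' evoked potential is maximal). Positions are 2-D projected head
#' coordinates in units of the head radius (x: left-right, y:
#' posterior-anterior), the conventional representation for building
#' channel neighbourhoods.
#'
#' @return data.frame with columns `label`, `x`, `y`, `z` (z = 0 in the
#'   projected layout)
#' @export
montage_1020 <- function() {
  tab <- rbind(
    c("Fp1", -0.31,  0.95), c("Fp2",  0.31,  0.95),
    c("F7",  -0.81,  0.59), c("F3",  -0.38,  0.56), c("Fz", 0,  0.55),
    c("F4",   0.38,  0.56), c("F8",   0.81,  0.59),
    c("FC5", -0.65,  0.28), c("FC1", -0.22,  0.28),
    c("FC2",  0.22,  0.28), c("FC6",  0.65,  0.28),
    c("T7",  -1.00,  0.00), c("C3",  -0.50,  0.00), c("Cz", 0, 0),
    c("C4",   0.50,  0.00), c("T8",   1.00,  0.00),
    c("TP9", -1.05, -0.35), c("CP5", -0.65, -0.28), c("CP1", -0.22, -0.28),
    c("CP2",  0.22, -0.28), c("CP6",  0.65, -0.28), c("TP10", 1.05, -0.35),
    c("P7",  -0.81, -0.59), c("P3",  -0.38, -0.56), c("Pz", 0, -0.55),
    c("P4",   0.38, -0.56), c("P8",   0.81, -0.59),
    c("POz",  0.00, -0.78),
    c("O1",  -0.31, -0.95), c("Oz",   0.00, -0.95), c("O2",  0.31, -0.95))
  data.frame(label = tab[, 1], x = as.numeric(tab[, 2]),
             y = as.numeric(tab[, 3]), z = 0)
}

#' Channels defining the gastric evoked potential / LPP cluster
#' @return character vector of the eight posterior midline channel labels
#' @export
lpp_channels <- function()
  c("Cz", "CP1", "CP2", "Pz", "POz", "O1", "Oz", "O2")

#' Build a channel adjacency structure
#'
#' Two channels are neighbours iff their Euclidean distance in the montage
#' is at most `max_dist` (in units of the head radius). Used to define the
#' spatial part of spatiotemporal clustering.
#'
#' @param montage data.frame with `label`, `x`, `y` and optionally `z`
#'   columns (default [montage_1020()])
#' @param max_dist neighbourhood radius; default 0.4 head radii connects
#'   nearest 10-20 neighbours (e.g. Pz-POz) without skipping rings
#' @return object of class `gw_adjacency`: list with `labels` and the
#'   symmetric logical `matrix` (zero diagonal)
#' @export
build_adjacency <- function(montage = montage_1020(), max_dist = 0.4) {
  stopifnot(is.data.frame(montage),
            all(c("label", "x", "y") %in% names(montage)))
  z <- if ("z" %in% names(montage)) montage$z else 0
  xyz <- cbind(montage$x, montage$y, z)
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= max_dist
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$label, montage$label)
  if (any(rowSums(adj) == 0))
    warning("channels without neighbours: ",
            paste(montage$label[rowSums(adj) == 0], collapse = ", "))
  structure(list(labels = montage$label, matrix = adj),
            class = "gw_adjacency")
}
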