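#' Standard 63-channel 10-10 electrode montage
#'
#' Builds the 63-channel extended 10-20 ("10-10") montage used throughout the
#' package: a full scalp grid from Fp to O rows plus the mastoid electrodes
#' TP9/TP10 used for re-referencing. Positions are generated on a unit sphere
#' from the conventional two-arc construction: each electrode is placed by an
#' anterior-posterior rotation along the midline (18 degrees per 10% step of
#' the nasion-inion arc) followed by a lateral rotation about the
#' anterior-posterior axis (18 degrees per 10% step towards the ears). This
#' reproduces the standard layout geometry closely enough for neighbourhood
#' definitions and topographic display.
#'
#' @return A tibble with one row per electrode and columns `channel`,
#'   `x`, `y`, `z` (unit-sphere coordinates; x anterior, y left-to-right
#'   negative-to-positive is *left negative*, z up), and the generating angles
#'   `ap_deg` (anterior-posterior, anterior positive) and `lat_deg` (lateral,
#'   right positive). The same table ships as a plain-text coordinate file at
#'   `system.file("extdata", "montage_1010.tsv", package = "wakewave")`.
#' @examples
#' m <- montage_1010()
#' nrow(m) # 63
#' @export
montage_1010 <- function() {
  rows <- c(Fp = 72, AF = 54, F = 36, FC = 18, C = 0,
            CP = -18, P = -36, PO = -54, O = -72)
  cols <- c(z = 0, `1` = 18, `2` = 18, `3` = 36, `4` = 36,
            `5` = 54, `6` = 54, `7` = 72, `8` = 72, `9` = 90, `10` = 90)
  # lateral chains: T7/T8 sit on the C row, TP9/TP10 below the ears
  labels <- list(
    Fp = c("Fp1", "Fpz", "Fp2"),
    AF = c("AF7", "AF3", "AFz", "AF4", "AF8"),
    F  = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    FC = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
    C  = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
    CP = c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
           "TP8", "TP10"),
    P  = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
    PO = c("PO7", "PO3", "POz", "PO4", "PO8"),
    O  = c("O1", "Oz", "O2")
  )
  out <- purrr::imap_dfr(labels, function(chans, row) {
    ap <- rows[[row]]
    lat <- vapply(chans, function(ch) {
      suffix <- sub("^[A-Za-z]+", "", ch)
      if (suffix == "z") suffix <- "z"
      ang <- cols[[if (suffix == "") "z" else suffix]]
      side <- if (suffix == "z" || suffix == "") 0
      else if (as.integer(suffix) %% 2 == 1) -1 else 1
      side * ang
    }, numeric(1))
    # temporal chains map onto the outermost arcs regardless of row letter
    lat[chans %in% c("T7", "FT7", "TP7")] <- -72
    lat[chans %in% c("T8", "FT8", "TP8")] <- 72
    lat[chans == "TP9"] <- -90
    lat[chans == "TP10"] <- 90
    tibble::tibble(channel = chans, ap_deg = ap, lat_deg = unname(lat))
  })
  a <- out$ap_deg * pi / 180
  l <- out$lat_deg * pi / 180
  out$x <- sin(a)
  out$y <- cos(a) * sin(l)
  out$z <- cos(a) * cos(l)
  stopifnot(!anyDuplicated(out$channel), nrow(out) == 63L)
  out[, c("channel", "x", "y", "z", "ap_deg", "lat_deg")]
}

#' Channel adjacency from electrode positions
#'
#' Defines the neighbourhood structure used for cluster formation: two
#' electrodes are neighbours when their Euclidean (chord) distance on the
#' unit sphere is at most `distance_threshold`. The default of 0.45 links
#' each interior electrode to its lateral, anterior-posterior and diagonal
#' neighbours on the 10-10 grid (roughly eight neighbours), while keeping
#' distant sites (for example Fpz and Oz) unconnected.
#'
#' @param montage A montage tibble as returned by [montage_1010()], with
#'   `channel`, `x`, `y`, `z` columns.
#' @param distance_threshold Maximum chord distance (unit-sphere units) for
#'   two electrodes to count as neighbours.
#' @param channels Optional character vector restricting (and ordering) the
#'   channels; unknown labels raise an error.
#' @return A symmetric, irreflexive logical matrix with channel dimnames.
#' @examples
#' adj <- build_adjacency(montage_1010())
#' adj["Cz", "FCz"]   # TRUE
#' adj["Fpz", "Oz"]   # FALSE
#' @export
build_adjacency <- function(montage, distance_threshold = 0.45,
                            channels = NULL) {
  stopifnot(is.data.frame(montage),
            all(c("channel", "x", "y", "z") %in% names(montage)),
            is.numeric(distance_threshold), distance_threshold > 0)
  if (!is.null(channels)) {
    missing <- setdiff(channels, montage$channel)
    if (length(missing) > 0) {
      stop("Unknown channel label(s): ", paste(missing, collapse = ", "))
    }
    montage <- montage[match(channels, montage$channel), ]
  }
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= distance_threshold
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$channel, montage$channel)
  adj
}

# channel groups used by the synthetic generator's topographic coupling
frontal_weight <- function(channels) {
  row <- sub("^([A-Za-z]+?)[0-9z]+$", "\\1", channels)
  w <- numeric(length(channels))
  w[row %in% c("Fp", "AF")] <- 1
  w[row %in% c("F")] <- 0.7
  w[row %in% c("FC", "FT")] <- 0.4
  w
}

posterior_weight <- function(channels) {
  row <- sub("^([A-Za-z]+?)[0-9z]+$", "\\1", channels)
  w <- numeric(length(channels))
  w[row %in% c("O", "PO")] <- 1
  w[row %in% c("P")] <- 0.7
  w[row %in% c("CP", "TP")] <- 0.4
  w
}
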