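#' Scalp region to channel mapping
#'
#' Returns the fixed assignment of the 63 recorded channels (10-10 montage
#' names, FCz being the reference and therefore absent) to six scalp
#' regions. Region power spectra are unweighted means over these channel
#' groups.
#'
#' @return Named list of character vectors, one per region, in the canonical
#'   region order (`central`, `frontal`, `occipital`, `parietal`,
#'   `temporal_left`, `temporal_right`).
#' @examples
#' map <- region_map()
#' lengths(map)
#' @export
region_map <- function() {
  list(
    central        = c("FC1", "FC2", "C3", "C1", "Cz", "C2", "C4"),
    frontal        = c("Fp1", "AF3", "AFz", "AF4", "F1", "Fz", "F2"),
    occipital      = c("PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz"),
    parietal       = c("CP3", "CP1", "CPz", "CP2", "CP4", "P5", "P3", "P1",
                       "Pz", "P2", "P4", "P6"),
    temporal_left  = c("AF7", "F3", "F5", "F7", "FT7", "FC5", "FC3", "C5",
                       "T7", "TP7", "CP5", "P7", "FT9", "TP9"),
    temporal_right = c("AF8", "F4", "F6", "F8", "FC4", "FC6", "FT8", "C6",
                       "T8", "CP6", "TP8", "P8", "FT10", "TP10")
  )
}

#' Canonical region labels
#'
#' @return Character vector of the six region labels in canonical order.
#' @export
regions <- function() {
  c("central", "frontal", "occipital", "parietal",
    "temporal_left", "temporal_right")
}

# Normalize free-form region labels ("Occipital", "Temp. L") to canonical
# lowercase-underscore form; unknown labels raise an error.
normalize_region <- function(x) {
  z <- tolower(trimws(as.character(x)))
  z <- gsub("[ .]+", "_", z)
  z <- sub("^temp_l$|^temporal_l$|^left_temporal$", "temporal_left", z)
  z <- sub("^temp_r$|^temporal_r$|^right_temporal$", "temporal_right", z)
  bad <- setdiff(unique(z), regions())
  if (length(bad) > 0L) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  }
  z
}

# region of each channel label (vectorized); errors on unknown channels
channel_region <- function(channels) {
  map <- region_map()
  lookup <- rep(names(map), lengths(map))
  names(lookup) <- unlist(map, use.names = FALSE)
  unknown <- setdiff(channels, names(lookup))
  if (length(unknown) > 0L) {
    stop("channel(s) not in the montage: ", paste(unknown, collapse = ", "))
  }
  unname(lookup[channels])
}
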