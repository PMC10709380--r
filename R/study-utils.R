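# Small study utilities: exposure dosimetry integration and the
# counterbalanced blinding table.

#' Integrate spectrum-analyzer readings to a total power density
#'
#' Converts per-bin analyzer levels (dBm) to linear power, applies an
#' antenna-factor calibration, and sums over all bins. The package ships
#' only the identity calibration; a vendor calibration is supplied as a
#' `frequency -> factor` function.
#'
#' @param readings Data frame with columns `frequency` (Hz, sorted
#'   increasing) and `level_dbm` (dBm per bin).
#' @param antenna_factor Function mapping frequency (Hz) to a strictly
#'   positive calibration factor. Default: identity calibration (factor 1),
#'   in which case the result is in mW-equivalent units; with a vendor
#'   calibration the result is a power density (e.g. uW/m^2).
#' @return Non-negative scalar: the calibrated sum over bins.
#' @examples
#' r <- data.frame(frequency = c(9e8, 9.1e8), level_dbm = c(-10, -20))
#' integrate_power_density(r) # 0.1 + 0.01 = 0.11
#' @export
integrate_power_density <- function(readings, antenna_factor = function(f) 1) {
  if (NROW(readings) == 0L) stop("no spectrum readings")
  stopifnot(all(c("frequency", "level_dbm") %in% names(readings)))
  if (is.unsorted(readings$frequency)) stop("readings must be sorted by frequency")
  af <- antenna_factor(readings$frequency)
  af <- rep_len(af, nrow(readings))
  if (any(!is.finite(af)) || any(af <= 0)) stop("antenna factor must be strictly positive")
  sum(af * 10^(readings$level_dbm / 10))
}

#' Generate a counterbalanced blinding table
#'
#' Assigns the exposure ("RF on") session, A or B, to each subject so that
#' exactly half of the subjects receive the exposure in session A. The table
#' is what a double-blinded run keeps hidden from experimenter and subject;
#' it also defines the group labels used downstream (group 1 = RF in
#' session A, group 2 = RF in session B).
#'
#' @param n_subjects Even number of subjects.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return Data frame with columns `subject`, `rf_session` ("A"/"B") and
#'   `group` (1 for RF in A, 2 for RF in B).
#' @export
generate_blinding_table <- function(n_subjects, seed) {
  if (n_subjects %% 2L != 0L) stop("n_subjects must be even")
  a_arm <- with_seed(seed, sample.int(n_subjects, n_subjects %/% 2L))
  rf <- ifelse(seq_len(n_subjects) %in% a_arm, "A", "B")
  data.frame(subject = seq_len(n_subjects), rf_session = rf,
             group = ifelse(rf == "A", 1L, 2L))
}

#' Write a blinding table as CSV
#'
#' @param table Result of [generate_blinding_table()].
#' @param path File path; header is `subject,rf_session`.
#' @return `path`, invisibly.
#' @export
write_blinding_table <- function(table, path) {
  utils::write.csv(table[c("subject", "rf_session")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed from a base seed and stream indices,
# kept inside the 32-bit integer range.
sub_seed <- function(seed, ...) {
  idx <- c(...)
  as.integer((as.double(seed) + sum(c(7919, 104729, 1299709)[seq_along(idx)] * idx)) %%
               2147483647)
}
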