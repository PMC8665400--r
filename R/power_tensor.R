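#' Power tensors
#'
#' A power tensor stores source-space spectral power as a participants x
#' nodes x frequency-steps array, together with the frequency axis (Hz,
#' uniformly spaced) and the session label. The participant order is the
#' binding contract with the cohort table.
#'
#' @param values Non-negative numeric array, participants x nodes x steps.
#' @param freq_axis Strictly increasing, uniformly spaced frequency axis (Hz).
#' @param session `"pre"` or `"post"` (or `"ratio"` for derived tensors).
#' @param participant_order Character vector of participant ids, length
#'   `dim(values)[1]`.
#' @return A `power_tensor` object.
#' @export
power_tensor <- function(values, freq_axis, session, participant_order) {
  if (length(dim(values)) != 3L) stopf("values must be a 3D array")
  if (session %in% c("pre", "post") && any(values < 0))
    stopf("power values must be non-negative")
  check_freq_axis(freq_axis)
  if (length(freq_axis) != dim(values)[3])
    stopf("freq_axis length (%d) does not match the tensor (%d steps)",
          length(freq_axis), dim(values)[3])
  participant_order <- as.character(participant_order)
  if (length(participant_order) != dim(values)[1])
    stopf("participant_order length does not match the tensor")
  structure(list(values = values, freq_axis = as.numeric(freq_axis),
                 session = session, participant_order = participant_order),
            class = "power_tensor")
}

check_freq_axis <- function(freq_axis) {
  if (length(freq_axis) < 2L) return(invisible(TRUE))
  d <- diff(freq_axis)
  if (any(d <= 0)) stopf("freq_axis must be strictly increasing")
  if (max(d) - min(d) > 1e-9 * max(abs(freq_axis)))
    stopf("non-uniform spacing in freq_axis")
  invisible(TRUE)
}

#' @export
print.power_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("power_tensor [%s]: %d participants x %d nodes x %d steps (%.4g-%.4g Hz)\n",
              x$session, d[1], d[2], d[3], min(x$freq_axis), max(x$freq_axis)))
  invisible(x)
}

#' The default analysis frequency axis
#'
#' 2 to 45 Hz in 1/3-Hz steps (130 steps), so that four consecutive steps span
#' a 1-Hz interval.
#'
#' @return Numeric vector of frequencies (Hz).
#' @export
default_freq_axis <- function() seq(2, 45, by = 1 / 3)

#' Read a power tensor from a dataset directory
#'
#' Expects the plain-text layout written by [write_dataset()]: `meta.json`
#' carrying the frequency axis, node count and participant order, and one
#' whitespace-delimited nodes x steps matrix file per participant under
#' `<dir>/<session>/<id>.txt`.
#'
#' @param dir Dataset directory.
#' @param session `"pre"` or `"post"`.
#' @return A `power_tensor`.
#' @export
load_power_tensor <- function(dir, session = c("pre", "post")) {
  session <- match.arg(session)
  meta <- read_dataset_meta(dir)
  ids <- meta$participant_order
  n_nodes <- meta$n_nodes
  freq <- meta$freq_axis
  check_freq_axis(freq)
  s <- length(freq)
  values <- array(NA_real_, c(length(ids), n_nodes, s))
  for (i in seq_along(ids)) {
    f <- file.path(dir, session, paste0(ids[i], ".txt"))
    if (!file.exists(f)) stopf("missing matrix file for participant '%s': %s", ids[i], f)
    v <- scan(f, quiet = TRUE)
    if (length(v) != n_nodes * s)
      stopf("shape mismatch for participant '%s': expected %d x %d values, got %d",
            ids[i], n_nodes, s, length(v))
    values[i, , ] <- matrix(v, nrow = n_nodes, ncol = s, byrow = TRUE)
  }
  power_tensor(values, freq, session, ids)
}

read_dataset_meta <- function(dir) {
  path <- file.path(dir, "meta.json")
  if (!file.exists(path)) stopf("meta.json not found in '%s'", dir)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta$participant_order <- as.character(meta$participant_order)
  meta
}

#' Element-wise post/pre power ratio
#'
#' @param pre,post Matching `power_tensor`s (same participants, nodes and
#'   frequency axis); all pre values must be strictly positive.
#' @return A `power_tensor` with `session = "ratio"`.
#' @export
compute_ratio_tensor <- function(pre, post) {
  if (!identical(dim(pre$values), dim(post$values)))
    stopf("pre and post tensors have different shapes")
  if (!isTRUE(all.equal(pre$freq_axis, post$freq_axis, tolerance = 1e-12)))
    stopf("pre and post frequency axes differ")
  if (!identical(pre$participant_order, post$participant_order))
    stopf("participant order mismatch between pre and post tensors")
  if (any(pre$values <= 0))
    stopf("pre tensor has zero or negative values; ratio undefined")
  power_tensor(post$values / pre$values, pre$freq_axis, "ratio",
               pre$participant_order)
}
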