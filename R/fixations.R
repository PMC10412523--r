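#' Detect fixations by dispersion thresholding (I-DT)
#'
#' Identifies fixations as maximal runs of gaze samples whose spatial spread
#' stays below a dispersion threshold for at least a minimum duration. The
#' dispersion of a window is the maximum pairwise angular separation between
#' its unit gaze directions (the spherical analogue of the classic I-DT
#' extent). From each window start the algorithm grows the window while the
#' dispersion stays at or below `dispersion_deg`; the maximal window is
#' emitted as a fixation when its duration (`t[end] - t[start]`) reaches
#' `min_dur_s`, otherwise the start advances one sample. Windows longer than
#' `max_dur_s` are split greedily into consecutive fixations of at most
#' `max_dur_s` (trailing remnants shorter than `min_dur_s` are dropped);
#' set `split_long = FALSE` to keep long windows whole. Invalid samples are
#' excluded, and a window breaks wherever the gap between retained samples
#' exceeds `max_gap_s` (so blinks are not bridged). Fixations are
#' non-overlapping and time-ordered.
#'
#' @param gaze Gaze tibble (`t, gx, gy, gz, ..., valid`) with strictly
#'   increasing timestamps.
#' @param dispersion_deg Dispersion threshold in degrees (default 1.0, the
#'   midpoint of the 0.7-1.3 degree guideline range for this tracker class).
#' @param min_dur_s,max_dur_s Duration bounds in seconds (defaults 0.100 and
#'   0.500).
#' @param max_gap_s Largest inter-sample gap a window may bridge (default
#'   0.050 s).
#' @param split_long Split windows longer than `max_dur_s` (default TRUE).
#' @return Tibble with one row per fixation: `start_t`, `end_t`,
#'   `duration_s`, `cx, cy, cz` (unit centroid direction), `dispersion_deg`,
#'   `n_samples`.
#' @export
#' @examples
#' t <- seq(0, 0.3, by = 1 / 120)
#' g <- tibble::tibble(t = t, gx = 1, gy = 0, gz = 0,
#'   hx = 0, hy = 0, hz = 0, valid = TRUE)
#' detect_fixations(g)
detect_fixations <- function(gaze, dispersion_deg = 1.0,
                             min_dur_s = 0.100, max_dur_s = 0.500,
                             max_gap_s = 0.050, split_long = TRUE) {
  empty <- tibble::tibble(
    start_t = numeric(), end_t = numeric(), duration_s = numeric(),
    cx = numeric(), cy = numeric(), cz = numeric(),
    dispersion_deg = numeric(), n_samples = integer()
  )
  if (nrow(gaze) < 2) return(empty)
  if (!is_strictly_increasing(gaze$t)) {
    abort_validation(sprintf(
      "gaze timestamps are not strictly increasing at row %d",
      first_violation_index(gaze$t)
    ))
  }
  keep <- gaze$valid
  if (!any(keep)) return(empty)
  t <- gaze$t[keep]
  x <- cbind(gaze$gx, gaze$gy, gaze$gz)[keep, , drop = FALSE]

  # segment wherever the retained stream jumps more than max_gap_s
  breaks <- which(diff(t) > max_gap_s)
  seg_start <- c(1L, breaks + 1L)
  seg_end <- c(breaks, length(t))

  out <- list()
  for (s in seq_along(seg_start)) {
    i0 <- seg_start[s]
    i1 <- seg_end[s]
    if (i1 - i0 < 1) next
    out[[length(out) + 1]] <- idt_segment(
      t[i0:i1], x[i0:i1, , drop = FALSE],
      dispersion_deg, min_dur_s, max_dur_s, split_long
    )
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

# I-DT over one gap-free run of valid samples. The window growth works in
# cosine space (the running minimum pairwise cosine of the window equals
# cos(max pairwise angle)); growth, splitting and summarising are delegated
# to compiled code.
idt_segment <- function(t, x, thr_deg, min_dur, max_dur, split_long) {
  f <- idt_fixations_cpp(t, x, cos(deg2rad(thr_deg)), min_dur, max_dur,
    split_long)
  if (nrow(f) == 0) return(NULL)
  tibble::as_tibble(f)
}
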