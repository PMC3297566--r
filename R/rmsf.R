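#' Time-windowed per-residue backbone RMSF profile
#'
#' The trajectory is split into consecutive non-overlapping windows of
#' `window_ns` (a trailing partial window is dropped). Within each window
#' every frame is superposed onto the window-mean structure (the mean is
#' re-estimated once from the fitted frames); per-atom RMSF is the square
#' root of the time-averaged squared deviation from the window-mean
#' position; the per-residue value averages the residue's backbone atoms
#' (C, CA, N); the profile is the mean over windows. Splitting fluctuations
#' by window length separates slow (100 ns scale) from fast (ns scale)
#' backbone motions.
#'
#' @param traj A [trajectory()].
#' @param selection 1-based atom indices to report (typically
#'   [select_backbone()] of the domain); per-residue values are computed
#'   from the C/CA/N atoms present in the selection.
#' @param window_ns Window length in ns. `Inf` (default) uses one window
#'   spanning the whole trajectory.
#' @param fit_selection 1-based atom indices used for the superposition fit
#'   (default: `selection`). Fitting on the domain backbone while reporting
#'   the same atoms is the standard protocol.
#' @return A tibble of class `"rmsf_profile"` with columns `residue_number`,
#'   `rmsf` (Angstrom); attributes `window_ns`, `n_runs_averaged`,
#'   `n_windows`.
#' @export
compute_rmsf <- function(traj, selection, window_ns = Inf,
                         fit_selection = selection) {
  if (length(selection) == 0) stop("selection must be non-empty", call. = FALSE)
  nf <- n_frames(traj)
  dt <- if (nf > 1) diff(traj$frame_times[1:2]) else 1
  if (is.infinite(window_ns)) {
    win_len <- nf
  } else {
    win_len <- floor(window_ns * 1000 / dt)
    if (win_len > nf) {
      stop("window of ", window_ns, " ns exceeds the trajectory length",
           call. = FALSE)
    }
    if (win_len < 2) stop("window too short: fewer than 2 frames", call. = FALSE)
  }
  n_win <- nf %/% win_len
  fit_local <- match(fit_selection, selection)
  use_fit_sel <- !any(is.na(fit_local))
  per_atom <- matrix(0, nrow = n_win, ncol = length(selection))
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * win_len + 1):(w * win_len)
    block <- traj$coords[idx, selection, , drop = FALSE]
    fitted <- fit_window(block,
                         if (use_fit_sel) fit_local else seq_along(selection))
    mean_xyz <- apply(fitted, c(2, 3), mean)
    dev2 <- sweep(fitted, c(2, 3), mean_xyz)
    per_atom[w, ] <- sqrt(apply(dev2^2, 2, function(m) mean(rowSums(m))))
  }
  res <- traj$atoms$residue_number[selection]
  res_fac <- factor(res, levels = unique(res))
  profile_by_window <- vapply(
    seq_len(n_win),
    function(w) as.numeric(tapply(per_atom[w, ], res_fac, mean)),
    numeric(nlevels(res_fac)))
  if (nlevels(res_fac) == 1) {
    profile_by_window <- matrix(profile_by_window, nrow = 1)
  }
  out <- tibble::tibble(
    residue_number = as.integer(levels(res_fac)),
    rmsf = rowMeans(profile_by_window)
  )
  rmsf_profile(out, window_ns = window_ns, n_runs_averaged = 1L,
               n_windows = n_win)
}

# Superpose each frame of a window onto the window-mean structure. The
# mean is seeded by fitting everything onto the first frame (which makes
# the procedure exactly equivariant under rigid motion of input frames),
# then re-estimated once from the fitted frames before the final fit.
fit_window <- function(block, fit_idx) {
  n <- dim(block)[1]
  ref <- block[1, , , drop = FALSE]
  dim(ref) <- dim(ref)[2:3]
  fitted <- block
  for (pass in 1:2) {
    for (f in seq_len(n)) {
      xyz <- block[f, , , drop = FALSE]
      dim(xyz) <- dim(xyz)[2:3]
      sp <- superpose(xyz[fit_idx, , drop = FALSE],
                      ref[fit_idx, , drop = FALSE])
      fitted[f, , ] <- apply_superposition(sp, xyz)
    }
    if (pass == 1) ref <- apply(fitted, c(2, 3), mean)
  }
  fitted
}

rmsf_profile <- function(tbl, window_ns, n_runs_averaged, n_windows = NA) {
  attr(tbl, "window_ns") <- window_ns
  attr(tbl, "n_runs_averaged") <- n_runs_averaged
  attr(tbl, "n_windows") <- n_windows
  class(tbl) <- c("rmsf_profile", setdiff(class(tbl), "rmsf_profile"))
  tbl
}

#' Average RMSF profiles over independent runs
#'
#' Element-wise mean of per-residue RMSF values across runs with identical
#' residue lists and window length.
#'
#' @param profiles List of [compute_rmsf()] results.
#' @return An `"rmsf_profile"` tibble with `n_runs_averaged` set.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) == 0) stop("no profiles given", call. = FALSE)
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!identical(p$residue_number, ref$residue_number)) {
      stop("profiles have mismatched residue lists", call. = FALSE)
    }
    if (!identical(attr(p, "window_ns"), attr(ref, "window_ns"))) {
      stop("profiles have mismatched window lengths", call. = FALSE)
    }
  }
  vals <- vapply(profiles, function(p) p$rmsf, numeric(nrow(ref)))
  if (nrow(ref) == 1) vals <- matrix(vals, nrow = 1)
  out <- tibble::tibble(residue_number = ref$residue_number,
                        rmsf = rowMeans(vals))
  rmsf_profile(out, window_ns = attr(ref, "window_ns"),
               n_runs_averaged = length(profiles))
}

#' Per-residue RMSF difference between two systems
#'
#' Signed difference `a - b`, the quantity plotted when comparing a wild
#' type against a truncated or mutant form: positive values mark residues
#' more flexible in `a`.
#'
#' @param a,b [compute_rmsf()] / [average_profiles()] results over the same
#'   residues and window length.
#' @return Tibble with columns `residue_number`, `drmsf`.
#' @export
rmsf_difference <- function(a, b) {
  if (!identical(a$residue_number, b$residue_number)) {
    stop("profiles have mismatched residue lists", call. = FALSE)
  }
  if (!identical(attr(a, "window_ns"), attr(b, "window_ns"))) {
    stop("profiles have mismatched window lengths", call. = FALSE)
  }
  tibble::tibble(residue_number = a$residue_number, drmsf = a$rmsf - b$rmsf)
}

#' Write an RMSF profile as TSV
#' @param profile An `"rmsf_profile"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rmsf <- function(profile, path) {
  out <- tibble::tibble(
    residue_number = profile$residue_number,
    rmsf = profile$rmsf,
    window_ns = attr(profile, "window_ns"),
    n_runs = attr(profile, "n_runs_averaged"))
  readr::write_tsv(out, path)
  invisible(path)
}
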