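#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ concatenation: each frame is an atom count line, a comment
#' line, then `element x y z` rows (Å). No installed reader handles the
#' multi-frame variant, so this one is minimal and strict.
#'
#' @param path file path
#' @return tibble with columns `frame`, `atom`, `element`, `x`, `y`, `z`
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) <= length(lines)]
  out <- list()
  i <- 1L; frame <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i, call. = FALSE)
    frame <- frame + 1L
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    out[[frame]] <- tibble::tibble(
      frame = frame,
      atom = seq_len(n),
      element = vapply(parts, `[[`, "", 1),
      x = as.numeric(vapply(parts, `[[`, "", 2)),
      y = as.numeric(vapply(parts, `[[`, "", 3)),
      z = as.numeric(vapply(parts, `[[`, "", 4))
    )
    i <- i + 2L + n
  }
  dplyr::bind_rows(out)
}

#' Reduce a coordinate trajectory to membrane pose observables
#'
#' Per frame, computes the two observables the two-step protocol consumes:
#' the insertion depth d = |z_COM(chromophore) - z_COM(membrane center
#' reference)| and the tilt phi = arcsin(|v_z| / |v|) of an atomic-coordinate
#' reference vector to the xy membrane plane, folded into \[0, 90\]° because
#' the membrane normal has no preferred sign. The membrane is assumed to lie
#' in the xy-plane with normal along z; trajectories in another frame must be
#' rotated before calling this.
#'
#' @param coords tibble as returned by [read_xyz_trajectory()]
#' @param chromophore_atoms atom indices of the chromophore
#' @param masses atomic masses for the chromophore atoms (same length)
#' @param center_atoms atom indices of the membrane-center reference (e.g.
#'   terminal lipid tail atoms); their COM (unit masses) defines z = 0
#' @param ref particles spec ([ref_spec()]) for the tilt proxy vector,
#'   indices relative to the whole frame
#' @param time_step_ns optional time step to fill a `time_ns` column
#' @return tibble with columns `frame`, `time_ns`, `depth`, `tilt_deg`
#' @export
pose_series <- function(coords, chromophore_atoms, masses, center_atoms, ref,
                        time_step_ns = NA_real_) {
  if (length(chromophore_atoms) == 0 || length(center_atoms) == 0) {
    stop("empty atom selection", call. = FALSE)
  }
  stopifnot(length(masses) == length(chromophore_atoms), all(masses > 0))
  split(coords, coords$frame) |>
    purrr::imap(function(fr, key) {
      zc <- sum(fr$z[chromophore_atoms] * masses) / sum(masses)
      z0 <- mean(fr$z[center_atoms])
      v <- reference_vector(fr, ref)
      tibble::tibble(
        frame = fr$frame[1],
        depth = abs(zc - z0),
        tilt_deg = asin(abs(v[3]) / sqrt(sum(v^2))) * 180 / pi
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$frame) |>
    dplyr::mutate(time_ns = (.data$frame - 1) * time_step_ns,
                  .after = "frame")
}

#' Per-trajectory and pooled pose means
#'
#' Arithmetic means of depth and tilt per trajectory, and a pooled mean over
#' all frames of the non-excluded trajectories. Averaging frames (rather than
#' trajectory means) lets unequal-length runs contribute proportionally.
#'
#' @param series_list named list of pose tibbles (one per trajectory)
#' @param exclude logical vector (or trajectory names) marking trajectories
#'   to drop, e.g. after [detachment_screen()]
#' @return list with `per_trajectory` (tibble: trajectory, n_frames,
#'   depth_mean, tilt_mean, excluded) and `pooled` (one-row tibble)
#' @export
trajectory_means <- function(series_list, exclude = NULL) {
  nm <- names(series_list) %||% as.character(seq_along(series_list))
  excl <- if (is.null(exclude)) rep(FALSE, length(series_list))
          else if (is.character(exclude)) nm %in% exclude
          else rep_len(as.logical(exclude), length(series_list))
  per <- purrr::map2(series_list, seq_along(series_list), function(s, i) {
    tibble::tibble(trajectory = nm[i], n_frames = nrow(s),
                   depth_mean = mean(s$depth), tilt_mean = mean(s$tilt_deg),
                   excluded = excl[i])
  }) |> dplyr::bind_rows()
  kept <- dplyr::bind_rows(series_list[!excl])
  if (nrow(kept) == 0) stop("all trajectories excluded", call. = FALSE)
  list(
    per_trajectory = per,
    pooled = tibble::tibble(n_frames = nrow(kept),
                            depth_mean = mean(kept$depth),
                            tilt_mean = mean(kept$tilt_deg))
  )
}

#' Screen a trajectory for chromophore detachment
#'
#' A chromophore that leaves the membrane invalidates the pose statistics;
#' such runs are excluded. A trajectory is flagged as detached when its depth
#' exceeds `threshold` for more than `min_fraction` of the frames. The
#' default threshold of 40 Å sits safely above the outer (~30 Å) membrane
#' binding mode.
#'
#' @param series pose tibble with a `depth` column
#' @param threshold depth threshold in Å (> 0)
#' @param min_fraction fraction of frames above threshold that triggers
#'   exclusion (default 0.25)
#' @return list with `keep` (logical), `fraction_beyond` and the parameters
#' @export
detachment_screen <- function(series, threshold = 40, min_fraction = 0.25) {
  stopifnot(threshold > 0, min_fraction >= 0, min_fraction <= 1)
  frac <- mean(series$depth > threshold)
  list(keep = frac <= min_fraction, fraction_beyond = frac,
       threshold = threshold, min_fraction = min_fraction)
}

#' Write / read a precomputed pose table
#'
#' Two entry points into the pipeline: raw coordinates via [pose_series()],
#' or a precomputed (time, depth, tilt) table via these.
#'
#' @param series pose tibble
#' @param path file path
#' @export
write_pose_table <- function(series, path) readr::write_tsv(series, path)

#' @rdname write_pose_table
#' @export
read_pose_table <- function(path) {
  readr::read_delim(path, delim = "\t", comment = "#", show_col_types = FALSE)
}
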