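#' Sampling configuration for an extended-CAIPI multi-slab acquisition
#'
#' Describes the ky-kz phase-encode grid of one slab and the per-shot
#' trajectory parameters. Every shot of the extended-CAIPI scheme covers a
#' kz band of width `w = floor(Nkz/2) + 1`, the minimal width that forces
#' each shot to cross the central kz plane (the DC partition,
#' 0-based index `c = floor(Nkz/2)`), whose crossings serve as
#' self-navigation points. The triangular kz trajectory has period
#' `2w - 2` acquired lines.
#'
#' @param Ny number of phase-encode (ky) lines of the full grid.
#' @param Nkz number of kz planes in the slab (>= 2).
#' @param Nshot number of shots; at most `Nkz` (fewer shots give an
#'   accelerated variant).
#' @param Ry parallel-imaging acceleration factor along ky.
#' @param pf partial-Fourier fraction in `[3/4, 1]`; only the first
#'   `round(pf * Ny)` ky lines (low-ky side) are acquired.
#' @param dmax maximum allowed self-navigation distance, in grid-index
#'   units, for the greedy pattern search.
#' @return an object of class `sampling_config`.
#' @export
sampling_config <- function(Ny, Nkz, Nshot = Nkz, Ry = 1L, pf = 1,
                            dmax = Inf) {
  if (Nkz < 2) stop("Nkz must be >= 2")
  if (pf < 3 / 4 || pf > 1) stop("pf must lie in [3/4, 1]")
  if (Nshot > Nkz) stop("Nshot must not exceed Nkz")
  if (Nshot < 1 || Ry < 1 || Ny < 1) stop("invalid geometry")
  w <- Nkz %/% 2L + 1L
  structure(list(
    Ny = as.integer(Ny), Nkz = as.integer(Nkz), Nshot = as.integer(Nshot),
    Ry = as.integer(Ry), pf = pf, dmax = dmax,
    w = as.integer(w),
    kz_center = as.integer(Nkz %/% 2L),
    period = as.integer(2L * w - 2L),
    s_kz_max = as.integer(Nkz - w),
    s_ky_max = as.integer(Ry - 1L),
    s_p_max = as.integer(2L * w - 3L)
  ), class = "sampling_config")
}

#' @export
print.sampling_config <- function(x, ...) {
  cat(sprintf(
    "<sampling_config> %d x %d grid, %d shots, Ry=%d, pf=%.2f, w=%d (period %d), dmax=%s\n",
    x$Ny, x$Nkz, x$Nshot, x$Ry, x$pf, x$w, x$period, format(x$dmax)
  ))
  invisible(x)
}

#' Per-shot trajectory parameters
#'
#' @param s_ky ky shift in `[0, Ry - 1]`.
#' @param s_kz kz band shift in `[0, Nkz - w]`.
#' @param s_p periodic shift of the triangular waveform in `[0, 2w - 3]`.
#' @return an object of class `shot_params`.
#' @export
shot_params <- function(s_ky, s_kz, s_p) {
  structure(list(s_ky = as.integer(s_ky), s_kz = as.integer(s_kz),
                 s_p = as.integer(s_p)), class = "shot_params")
}

check_params <- function(config, params) {
  if (params$s_ky < 0 || params$s_ky > config$s_ky_max)
    stop("s_ky out of range [0, ", config$s_ky_max, "]")
  if (params$s_kz < 0 || params$s_kz > config$s_kz_max)
    stop("s_kz out of range [0, ", config$s_kz_max, "]")
  if (params$s_p < 0 || params$s_p > config$s_p_max)
    stop("s_p out of range [0, ", config$s_p_max, "]")
  invisible(TRUE)
}

acquired_ky <- function(config, s_ky, pf = config$pf) {
  ky_max <- round(pf * config$Ny) - 1L
  seq.int(s_ky, ky_max, by = config$Ry)
}

new_shot_pattern <- function(params, lines, is_kz0_traversal, config) {
  structure(list(params = params, lines = lines,
                 is_kz0_traversal = is_kz0_traversal,
                 Ny = config$Ny, Nkz = config$Nkz,
                 kz_center = config$kz_center),
            class = "shot_pattern")
}

#' Basic periodic extended-CAIPI shot trajectory
#'
#' Generates the triangular ("blip-up / blip-down") kz trajectory of one
#' EPI shot. For the n-th acquired ky line (n = 0, 1, ...):
#' `kz = s_kz + tri((n + s_p) mod (2w - 2))` with `tri(t) = t` for
#' `t <= w - 1` and `2w - 2 - t` otherwise, and `ky = s_ky + Ry * n`,
#' restricted to the acquired ky range (`pf` fraction of `Ny`).
#'
#' @param config a [sampling_config()].
#' @param params a [shot_params()].
#' @return a `shot_pattern`: ordered 0-based `(ky, kz)` line positions plus
#'   the generating parameters.
#' @export
basic_shot_trajectory <- function(config, params) {
  check_params(config, params)
  ky <- acquired_ky(config, params$s_ky)
  n <- seq_along(ky) - 1L
  t <- (n + params$s_p) %% config$period
  tri <- ifelse(t <= config$w - 1L, t, config$period - t)
  kz <- params$s_kz + tri
  new_shot_pattern(params, cbind(ky = ky, kz = as.integer(kz)),
                   FALSE, config)
}

#' Non-blipped shot traversing the central kz plane
#'
#' The first shot of the optimized pattern acquires every line on the
#' central kz plane (no kz blips), capturing an accurate magnitude image of
#' that plane for the structured low-rank phase reconstruction.
#'
#' @inheritParams basic_shot_trajectory
#' @param s_ky ky shift in `[0, Ry - 1]`.
#' @return a `shot_pattern` with `is_kz0_traversal = TRUE`.
#' @export
kz0_traversal_shot <- function(config, s_ky = 0L) {
  if (s_ky < 0 || s_ky > config$s_ky_max)
    stop("s_ky out of range [0, ", config$s_ky_max, "]")
  ky <- acquired_ky(config, s_ky)
  lines <- cbind(ky = ky, kz = rep(config$kz_center, length(ky)))
  new_shot_pattern(shot_params(s_ky, NA_integer_, NA_integer_),
                   lines, TRUE, config)
}

#' @export
print.shot_pattern <- function(x, ...) {
  cat(sprintf("<shot_pattern> %d lines on %d x %d grid%s; s_ky=%s s_kz=%s s_p=%s\n",
              nrow(x$lines), x$Ny, x$Nkz,
              if (x$is_kz0_traversal) " (kz0 traversal)" else "",
              format(x$params$s_ky), format(x$params$s_kz),
              format(x$params$s_p)))
  invisible(x)
}

#' Shot line table
#'
#' @param patterns a list of `shot_pattern` objects.
#' @return a tibble with columns `shot`, `ky`, `kz` (0-based indices).
#' @export
shot_lines <- function(patterns) {
  if (inherits(patterns, "shot_pattern")) patterns <- list(patterns)
  tibble::tibble(
    shot = rep(seq_along(patterns),
               vapply(patterns, function(p) nrow(p$lines), integer(1))),
    ky = unlist(lapply(patterns, function(p) p$lines[, "ky"])),
    kz = unlist(lapply(patterns, function(p) p$lines[, "kz"]))
  )
}

shot_mask <- function(pattern, config) {
  m <- matrix(0L, config$Ny, config$Nkz)
  m[cbind(pattern$lines[, "ky"] + 1L, pattern$lines[, "kz"] + 1L)] <- 1L
  m
}

#' Per-shot and combined sampling masks
#'
#' @param patterns list of `shot_pattern`s.
#' @param config a [sampling_config()].
#' @return a `sampling_masks` object: `per_shot` (Ny x Nkz x Nshot binary
#'   array) and `combined` (integer count matrix, the elementwise sum).
#' @export
sampling_masks <- function(patterns, config) {
  if (inherits(patterns, "shot_pattern")) patterns <- list(patterns)
  per <- vapply(patterns, shot_mask, matrix(0L, config$Ny, config$Nkz),
                config = config)
  dim(per) <- c(config$Ny, config$Nkz, length(patterns))
  structure(list(per_shot = per,
                 combined = apply(per, c(1, 2), sum),
                 Ny = config$Ny, Nkz = config$Nkz),
            class = "sampling_masks")
}

combined_upto <- function(masks, i) {
  if (i < 1 || i > dim(masks$per_shot)[3]) stop("shot index i out of range")
  if (i == 1) return(masks$per_shot[, , 1])
  apply(masks$per_shot[, , seq_len(i), drop = FALSE], c(1, 2), sum)
}

#' Overlap metric of an i-shot-combined sampling
#'
#' Number of ky-kz cells acquired more than once by the first `i` shots.
#'
#' @param masks a [sampling_masks()] object.
#' @param i number of shots to combine, in `[1, Nshot]`.
#' @return integer count.
#' @export
overlap_metric <- function(masks, i = dim(masks$per_shot)[3]) {
  sum(combined_upto(masks, i) > 1L)
}

# number of all-zero 3x3 sums of a count mask; boundary handling as in
# discrete convolution: "valid" counts fully-contained windows only,
# "same"/"full" zero-pad by 1/2 cells so windows may extend past the grid
gap_count <- function(combined, boundary = "valid") {
  if (nrow(combined) < 3 || ncol(combined) < 3)
    stop("grid smaller than 3x3")
  p <- switch(boundary, valid = 0L, same = 1L, full = 2L,
              stop("unknown boundary mode"))
  occ <- matrix(0, nrow(combined) + 2L * p, ncol(combined) + 2L * p)
  occ[p + seq_len(nrow(combined)), p + seq_len(ncol(combined))] <-
    (combined > 0) + 0
  # integral image of occupancy
  cs <- t(apply(apply(occ, 2, cumsum), 1, cumsum))
  pad <- matrix(0, nrow(cs) + 1, ncol(cs) + 1)
  pad[-1, -1] <- cs
  i <- seq_len(nrow(occ) - 2)
  j <- seq_len(ncol(occ) - 2)
  win <- pad[i + 3, j + 3, drop = FALSE] - pad[i, j + 3, drop = FALSE] -
    pad[i + 3, j, drop = FALSE] + pad[i, j, drop = FALSE]
  sum(win == 0)
}

#' Gap metric of an i-shot-combined sampling
#'
#' Number of 3x3 windows of the combined mask whose nine cells are all
#' unsampled. By default only fully-contained windows are counted
#' (`boundary = "valid"`); `"full"` counts zeros of the complete discrete
#' 3x3 ones-convolution (windows may extend past the grid edge), which is
#' the form the greedy pattern search penalizes so that coverage is pushed
#' out to the grid borders.
#'
#' @inheritParams overlap_metric
#' @param boundary `"valid"` (default), `"same"` or `"full"`.
#' @return integer count.
#' @export
gap_metric <- function(masks, i = dim(masks$per_shot)[3],
                       boundary = "valid") {
  gap_count(combined_upto(masks, i), boundary)
}

#' Self-navigation distance of a shot
#'
#' Shortest Euclidean distance, in grid-index units, from the shot's
#' self-navigation points (lines on the central kz plane) to the ky-kz grid
#' center `(floor(Ny/2), floor(Nkz/2))`.
#'
#' @param shot a `shot_pattern`.
#' @param config a [sampling_config()].
#' @return nonnegative number.
#' @export
nav_distance <- function(shot, config) {
  sel <- shot$lines[, "kz"] == config$kz_center
  if (!any(sel)) stop("shot has no self-navigation point")
  ky <- shot$lines[sel, "ky"]
  min(sqrt((ky - config$Ny %/% 2L)^2))
}

#' Greedy optimization of the multi-shot sampling pattern
#'
#' Starting from the kz0-traversal seed shot, each subsequent shot is chosen
#' by exhaustive search over all `(s_ky, s_kz, s_p)` candidates, discarding
#' candidates whose self-navigation distance exceeds `dmax` and selecting
#' the candidate minimizing `o_i + g_i + d_i` (overlap + gaps +
#' self-navigation distance of the candidate; the gap term is the
#' full-convolution count, see [gap_metric()], so border coverage is
#' rewarded too). Ties are broken
#' lexicographically by `(s_ky, s_kz, s_p)`; the search is deterministic.
#'
#' @param config a [sampling_config()] (its `dmax` is the hard constraint).
#' @param seed_shot the first shot; defaults to `kz0_traversal_shot(config)`.
#' @return list of `Nshot` `shot_pattern`s, with per-step metrics in
#'   attribute `"metrics"` (a tibble with columns `shot`, `o`, `g`, `d`).
#' @export
greedy_optimize <- function(config, seed_shot = kz0_traversal_shot(config)) {
  if (!seed_shot$is_kz0_traversal)
    stop("seed_shot must be the kz0 traversal shot")
  cand_grid <- expand.grid(s_p = 0:config$s_p_max,
                           s_kz = 0:config$s_kz_max,
                           s_ky = 0:config$s_ky_max)
  # lexicographic order by (s_ky, s_kz, s_p)
  cand_grid <- cand_grid[order(cand_grid$s_ky, cand_grid$s_kz, cand_grid$s_p), ]
  cands <- lapply(seq_len(nrow(cand_grid)), function(r) {
    p <- shot_params(cand_grid$s_ky[r], cand_grid$s_kz[r], cand_grid$s_p[r])
    sh <- basic_shot_trajectory(config, p)
    list(shot = sh, mask = shot_mask(sh, config),
         d = nav_distance(sh, config))
  })
  patterns <- list(seed_shot)
  comb <- shot_mask(seed_shot, config)
  metrics <- list(tibble::tibble(shot = 1L, o = sum(comb > 1L),
                                 g = gap_count(comb, "full"),
                                 d = nav_distance(seed_shot, config)))
  for (i in seq_len(config$Nshot - 1L) + 1L) {
    best <- NULL
    best_cost <- Inf
    for (cand in cands) {
      if (cand$d > config$dmax) next
      cm <- comb + cand$mask
      o <- sum(cm > 1L)
      g <- gap_count(cm, "full")
      cost <- o + g + cand$d
      if (cost < best_cost) {
        best_cost <- cost
        best <- list(cand = cand, o = o, g = g)
      }
    }
    if (is.null(best))
      stop("no feasible candidate at step ", i, " (all d > dmax)")
    patterns[[i]] <- best$cand$shot
    comb <- comb + best$cand$mask
    metrics[[i]] <- tibble::tibble(shot = i, o = best$o, g = best$g,
                                   d = best$cand$d)
  }
  attr(patterns, "metrics") <- do.call(rbind, metrics)
  patterns
}

#' Central-plane acceleration factor of one shot
#'
#' `Ny` divided by the number of ky lines the shot acquires on the central
#' kz plane, evaluated on a full-ky (`pf = 1`) grid. A shot whose triangle
#' touches the central plane only at the period extremum samples it once per
#' `2w - 2` lines; interior crossings occur twice per period.
#'
#' @inheritParams nav_distance
#' @return acceleration factor (fold under-sampling of the central plane).
#' @export
selfnav_acceleration <- function(shot, config) {
  full <- if (shot$is_kz0_traversal) {
    kz0_traversal_shot(config, shot$params$s_ky)
  } else {
    cfg1 <- config
    cfg1$pf <- 1
    basic_shot_trajectory(cfg1, shot$params)
  }
  n_nav <- sum(full$lines[, "kz"] == config$kz_center)
  if (n_nav == 0) stop("shot does not intersect the central plane")
  config$Ny / n_nav
}

#' Per-shot under-sampling factor of the slab encoding
#'
#' Total ky-kz grid cells divided by the cells acquired in one shot on a
#' full-ky grid: for a slab encoded by `Nkz` shot-equivalents at in-plane
#' acceleration `Ry` this equals `Nkz * Ry`.
#'
#' @param config a [sampling_config()].
#' @return under-sampling factor (number).
#' @export
per_shot_undersampling <- function(config) {
  n_lines <- length(acquired_ky(config, 0L, pf = 1))
  config$Ny * config$Nkz / n_lines
}

#' Plot a combined sampling pattern
#'
#' @param patterns list of `shot_pattern`s.
#' @param config a [sampling_config()].
#' @return a ggplot object showing acquired cells, colored by shot, with
#'   overlapped cells highlighted.
#' @export
plot_sampling <- function(patterns, config) {
  df <- shot_lines(patterns)
  counts <- sampling_masks(patterns, config)$combined
  df$overlap <- counts[cbind(df$ky + 1L, df$kz + 1L)] > 1L
  ggplot2::ggplot(df, ggplot2::aes(x = kz, y = ky)) +
    ggplot2::geom_tile(ggplot2::aes(fill = factor(shot)),
                       width = 0.9, height = 0.9) +
    ggplot2::geom_tile(data = df[df$overlap, , drop = FALSE],
                       fill = "white", width = 0.45, height = 0.45) +
    ggplot2::labs(x = "kz index", y = "ky index", fill = "shot") +
    ggplot2::theme_minimal()
}
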