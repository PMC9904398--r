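#' Generate a synthetic velocity-fluctuation profile
#'
#' Produces smooth non-negative \eqn{\sigma^2(z)} profiles of the shapes seen
#' in resolved suspension runs, for exercising the effective-temperature
#' solver without a simulation: fluctuations are largest inside the sediment
#' and decay with height.
#'
#' @param shape `"exponential_decay"` (\eqn{\sigma_0^2 e^{-z/\ell_\sigma}}),
#'   `"bottom_boosted"` (a constant background plus an exponential boost near
#'   the wall, \eqn{\sigma_b^2 + \sigma_0^2 e^{-z/\ell_\sigma}}), or
#'   `"constant"`.
#' @param grid Height grid covering \eqn{[0, H]}.
#' @param sigma0_sq Amplitude \eqn{\sigma_0^2 \ge 0}.
#' @param ell_sigma Decay length of the exponential shapes.
#' @param background Background level for `"bottom_boosted"`.
#' @return A [fluctuation_profile()] tagged `synthetic`.
#' @export
generate_synthetic_sigma2 <- function(shape = c("exponential_decay",
                                                "bottom_boosted", "constant"),
                                      grid, sigma0_sq, ell_sigma = NULL,
                                      background = 0) {
  shape <- match.arg(shape)
  if (sigma0_sq < 0 || background < 0) stop("amplitudes must be non-negative")
  s2 <- switch(shape,
    constant = rep(sigma0_sq, length(grid)),
    exponential_decay = {
      stopifnot(!is.null(ell_sigma), ell_sigma > 0)
      sigma0_sq * exp(-grid / ell_sigma)
    },
    bottom_boosted = {
      stopifnot(!is.null(ell_sigma), ell_sigma > 0)
      background + sigma0_sq * exp(-grid / ell_sigma)
    })
  fluctuation_profile(grid, s2, source = "synthetic")
}

#' Sample particle heights from a density profile
#'
#' Inverse-CDF sampling: draws `n` heights whose histogram converges to the
#' supplied normalised profile. Used for round-trip tests of the profile
#' fitters.
#'
#' @param profile A data frame with `z`, `rho` (normalised).
#' @param n Number of samples.
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return A numeric vector of `n` heights.
#' @export
sample_from_profile <- function(profile, n, seed = NULL) {
  z <- profile$z; rho <- profile$rho
  cdf <- pracma::cumtrapz(z, rho)[, 1]
  cdf <- cdf / tail(cdf, 1)
  # knots at both endpoints of every CDF rise, so flat (zero-density) runs
  # are jumped over instead of interpolated across
  J <- which(diff(cdf) > 0)
  idx <- sort(unique(c(J, J + 1L)))
  idx <- idx[!duplicated(cdf[idx])]
  draw <- function() {
    u <- runif(n)
    approx(cdf[idx], z[idx], xout = u, rule = 2)$y
  }
  if (is.null(seed)) return(draw())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  draw()
}

# ---- text I/O -------------------------------------------------------------

fmt_full <- function(x) sprintf("%.17g", x)

write_tsv_with_header <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, as.character(meta[[nm]])), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  num <- vapply(df, is.numeric, logical(1))
  body <- as.data.frame(df)
  for (j in which(num)) body[[j]] <- fmt_full(body[[j]])
  writeLines(do.call(paste, c(body, sep = "\t")), con)
}

read_tsv_with_header <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_lines]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- m[3]
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  if (length(body) < 1) stop(sprintf("%s: no header line found", path))
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(body) == 1) {
    df <- tibble::as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(structure(df, meta = meta))
  }
  cells <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(cells) != length(cols))
  if (length(bad))
    stop(sprintf("%s: malformed record at data line %d (expected %d fields, got %d)",
                 path, bad[1], length(cols), lengths(cells)[bad[1]]))
  m <- do.call(rbind, cells)
  df <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  names(df) <- cols
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(v)) df[[j]] <- v
  }
  structure(df, meta = meta)
}

#' Write / read a profile as TSV
#'
#' Plain-text TSV with `#`-prefixed header metadata (units, seed, provenance)
#' followed by a column-header line. Numbers are written with 17 significant
#' digits so the round trip is exact.
#'
#' @param profile A profile tibble (density, fluctuation or lambda-eff).
#' @param path Output file.
#' @param meta Named list of metadata entries for the header.
#' @return `write_profile_tsv` returns `path` invisibly; `read_profile_tsv`
#'   returns a tibble with a `meta` attribute.
#' @export
write_profile_tsv <- function(profile, path, meta = list()) {
  meta <- c(list(format = "activesed-profile", class = class(profile)[1]), meta)
  for (a in c("H", "dz", "n", "source", "mode", "alpha"))
    if (!is.null(attr(profile, a))) meta[[a]] <- attr(profile, a)
  write_tsv_with_header(tibble::as_tibble(profile), path, meta)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- read_tsv_with_header(path)
  meta <- attr(df, "meta")
  cl <- meta[["class"]]
  if (!is.null(cl) && cl %in% c("density_profile", "fluctuation_profile",
                                "lambda_eff_profile"))
    class(df) <- c(cl, class(df))
  for (a in c("H", "dz", "n"))
    if (!is.null(meta[[a]])) attr(df, a) <- as.numeric(meta[[a]])
  df
}

#' Write / read a trajectory as extended-XYZ-style TSV
#'
#' Columns `id, t, x, y, z, ex, ey, ez`; `#`-header metadata as in
#' [write_profile_tsv()]. Round trips are exact to the printed 17
#' significant digits.
#'
#' @param traj Trajectory tibble.
#' @inheritParams write_profile_tsv
#' @export
write_trajectory_tsv <- function(traj, path, meta = list()) {
  cols <- intersect(c("id", "t", "x", "y", "z", "ex", "ey", "ez"), names(traj))
  write_tsv_with_header(traj[, cols], path,
                        c(list(format = "activesed-trajectory"), meta))
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) read_tsv_with_header(path)

#' Run manifest
#'
#' Records the provenance of a set of output files: configuration snapshot,
#' master seed, unit system, package version, and an md5 checksum per
#' artifact. Written as a JSON sidecar next to the outputs.
#'
#' @param out_dir Directory holding the artifacts.
#' @param config Named list echoed verbatim into the manifest.
#' @param seed The master seed used for the run.
#' @param units `"lattice"` or `"SI"`; a run never mixes unit systems.
#' @param files Artifact file names (relative to `out_dir`).
#' @return The manifest list, invisibly; side effect: writes
#'   `manifest.json` in `out_dir`.
#' @export
write_manifest <- function(out_dir, config, seed, units = c("lattice", "SI"),
                           files = character(0)) {
  units <- match.arg(units)
  paths <- file.path(out_dir, files)
  checks <- if (length(paths)) as.list(tools::md5sum(paths)) else list()
  names(checks) <- files
  manifest <- list(
    package = "activesed",
    version = as.character(utils::packageVersion("activesed")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    units = units,
    config = config,
    checksums = checks
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
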