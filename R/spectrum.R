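# Stick spectra, linear frequency scaling, Lorentzian broadening, ZPVE and
# scaling-factor derivation.

#' Create a stick IR spectrum
#'
#' @param wavenumbers stick positions in 1/cm.
#' @param intensities integral absorption coefficients in km/mol (same
#'   length).
#' @param dmudq2 optional raw squared normal-mode dipole derivatives, stored
#'   alongside so any intensity-unit convention can be recovered.
#' @return Object of class `"ir_spectrum"`: list with `sticks` (data frame,
#'   ascending wavenumber), `grid` (`NULL` until [broaden()]), `lineshape`,
#'   `fwhm` and `scale_factor` metadata.
#' @examples
#' ir_spectrum(c(1600, 3650), c(60, 10))
#' @export
ir_spectrum <- function(wavenumbers, intensities, dmudq2 = NULL) {
  stopifnot(length(wavenumbers) == length(intensities))
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  ord <- order(wavenumbers)
  sticks <- data.frame(wavenumber = as.numeric(wavenumbers[ord]),
                       intensity = as.numeric(intensities[ord]))
  if (!is.null(dmudq2)) sticks$dmudq2 <- as.numeric(dmudq2[ord])
  structure(list(sticks = sticks, grid = NULL, lineshape = NA_character_,
                 fwhm = NA_real_, scale_factor = 1),
            class = "ir_spectrum")
}

#' Assemble the spectrum of a molecule from modes and a dipole gradient
#'
#' Combines a [normal_modes()] result with a Cartesian dipole gradient: the
#' dipole gradient is projected onto the internal modes (rigid/near-zero
#' modes excluded) and converted to km/mol.
#'
#' @param modes a [normal_modes()] result.
#' @param D 3N x 3 Cartesian dipole gradient (atomic units).
#' @param mol the [molecule()].
#' @return An [ir_spectrum()] over the internal modes; negative (imaginary)
#'   wavenumbers, if any, are retained and flagged by [normal_modes()].
#' @export
mode_spectrum <- function(modes, D, mol) {
  md <- project_dipole_gradient(D, modes, mol)
  A <- intensities(md)
  idx <- modes$internal
  ir_spectrum(modes$wavenumbers[idx], A$intensities[idx], A$dmudq2[idx])
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d sticks, scale factor %.6g%s\n",
              nrow(x$sticks), x$scale_factor,
              if (is.null(x$grid)) "" else
                sprintf(", %s-broadened (fwhm %g 1/cm, grid %g..%g by %g)",
                        x$lineshape, x$fwhm, min(x$grid$wavenumber),
                        max(x$grid$wavenumber),
                        x$grid$wavenumber[2] - x$grid$wavenumber[1])))
  invisible(x)
}

#' Apply a uniform linear frequency scaling factor
#'
#' Multiplies every stick wavenumber by `factor`; intensities are untouched
#' and the cumulative factor is recorded in the spectrum metadata. Any
#' existing broadened grid is dropped (it would no longer match the sticks).
#'
#' @param spec an [ir_spectrum()].
#' @param factor positive dimensionless scale.
#' @return Scaled [ir_spectrum()].
#' @export
scale_frequencies <- function(spec, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("factor must be a positive scalar", call. = FALSE)
  }
  spec$sticks$wavenumber <- spec$sticks$wavenumber * factor
  spec$scale_factor <- spec$scale_factor * factor
  spec$grid <- NULL
  spec
}

#' Apply externally supplied per-mode scale factors
#'
#' Hook for nonlinear (e.g. mass-dependent) scaling schemes parameterized
#' elsewhere: each stick wavenumber is multiplied by its own factor.
#'
#' @param spec an [ir_spectrum()].
#' @param factors positive numeric vector, one entry per stick.
#' @return Scaled [ir_spectrum()] (`scale_factor` metadata is set to `NA`
#'   since no single factor applies).
#' @export
scale_frequencies_per_mode <- function(spec, factors) {
  if (length(factors) != nrow(spec$sticks) || any(factors <= 0)) {
    stop("factors must be positive, one per stick", call. = FALSE)
  }
  spec$sticks$wavenumber <- spec$sticks$wavenumber * factors
  ord <- order(spec$sticks$wavenumber)
  spec$sticks <- spec$sticks[ord, , drop = FALSE]
  spec$scale_factor <- NA_real_
  spec$grid <- NULL
  spec
}

#' Broaden a stick spectrum onto a uniform grid
#'
#' Each stick contributes an area-normalized Lorentzian,
#' `A_p (gamma/pi) / ((nu - nu_p)^2 + gamma^2)` with `gamma = fwhm/2`, so the
#' integrated area of each line equals its stick intensity. The default
#' full width at half-maximum is 30 1/cm and the default grid is 0..4000 1/cm
#' at 1 1/cm spacing.
#'
#' @param spec an [ir_spectrum()].
#' @param fwhm full width at half-maximum in 1/cm (> 0).
#' @param from,to,by grid range and spacing in 1/cm; the grid must cover all
#'   sticks.
#' @return The spectrum with a `grid` component (`wavenumber`, `absorbance`)
#'   and line-shape metadata filled in.
#' @export
broaden <- function(spec, fwhm = 30, from = 0, to = 4000, by = 1) {
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (to <= from || by <= 0) stop("empty or invalid grid", call. = FALSE)
  nu <- seq(from, to, by = by)
  if (length(nu) < 2) stop("empty or invalid grid", call. = FALSE)
  st <- spec$sticks
  if (nrow(st) && (min(st$wavenumber) < from || max(st$wavenumber) > to)) {
    stop("grid does not cover all sticks (", round(min(st$wavenumber), 2), "..",
         round(max(st$wavenumber), 2), " 1/cm)", call. = FALSE)
  }
  g <- fwhm / 2
  y <- numeric(length(nu))
  for (p in seq_len(nrow(st))) {
    y <- y + st$intensity[p] * (g / pi) / ((nu - st$wavenumber[p])^2 + g^2)
  }
  spec$grid <- list(wavenumber = nu, absorbance = y)
  spec$lineshape <- "lorentzian"
  spec$fwhm <- fwhm
  spec
}

#' Harmonic zero-point vibrational energy
#'
#' `ZPVE = 1/2 sum_p nu_p`, converted from 1/cm to kcal/mol. Only real
#' (positive) internal-mode frequencies are admissible; imaginary modes must
#' be excluded upstream.
#'
#' @param wavenumbers numeric vector of internal-mode wavenumbers (1/cm,
#'   all > 0; an empty vector gives 0).
#' @return ZPVE in kcal/mol.
#' @export
zpve <- function(wavenumbers) {
  if (length(wavenumbers) && any(wavenumbers < 0)) {
    stop("negative (imaginary) frequencies must be excluded before ZPVE",
         call. = FALSE)
  }
  0.5 * sum(wavenumbers) * .const$rcm_to_kcalmol
}

#' Derive a linear frequency scaling factor from paired ZPVEs
#'
#' The per-molecule ZPVE ratio reference/method is averaged over the set:
#' `factor = mean(zpve_ref / zpve_method)`. Because the ZPVE is linear in the
#' frequencies, a method whose frequencies are uniformly `1/f` times the
#' reference recovers exactly `f`.
#'
#' @param zpve_ref,zpve_method equal-length vectors of positive ZPVEs (any
#'   common energy unit).
#' @return The scaling factor with attribute `"se"` (standard error of the
#'   mean ratio).
#' @export
derive_scaling_factor <- function(zpve_ref, zpve_method) {
  if (length(zpve_ref) != length(zpve_method)) {
    stop("ZPVE lists must have equal length", call. = FALSE)
  }
  if (!length(zpve_ref)) stop("empty ZPVE lists", call. = FALSE)
  if (any(zpve_ref <= 0) || any(zpve_method <= 0)) {
    stop("ZPVEs must be positive", call. = FALSE)
  }
  r <- zpve_ref / zpve_method
  f <- mean(r)
  attr(f, "se") <- if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_
  f
}

# ---------------------------------------------------------------------------
# Spectrum file I/O: two-column text with a '#'-prefixed metadata header.
# Stick and broadened files share the layout, distinguished by 'type'.

#' Write a spectrum to a two-column text file
#'
#' @param spec an [ir_spectrum()].
#' @param path output path.
#' @param what `"sticks"` or `"grid"` (requires a broadened spectrum).
#' @param metadata extra named entries for the `# key value` header.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, what = c("sticks", "grid"),
                           metadata = NULL) {
  what <- match.arg(what)
  meta <- c(type = if (what == "sticks") "stick" else "broadened",
            if (!is.na(spec$lineshape)) c(lineshape = spec$lineshape),
            if (!is.na(spec$fwhm)) c(fwhm = sprintf("%.10g", spec$fwhm)),
            if (!is.na(spec$scale_factor))
              c(scale_factor = sprintf("%.12g", spec$scale_factor)),
            metadata)
  if (what == "grid") {
    if (is.null(spec$grid)) stop("spectrum has no broadened grid", call. = FALSE)
    x <- spec$grid$wavenumber; y <- spec$grid$absorbance
    rows <- sprintf("%14.6f %20.12e", x, y)
  } else {
    rows <- if ("dmudq2" %in% names(spec$sticks)) {
      sprintf("%14.6f %20.12e %20.12e",
              spec$sticks$wavenumber, spec$sticks$intensity, spec$sticks$dmudq2)
    } else {
      sprintf("%14.6f %20.12e", spec$sticks$wavenumber, spec$sticks$intensity)
    }
  }
  writeLines(c(.format_hash_metadata(meta), rows), path)
  invisible(path)
}

#' Read a spectrum file written by [write_spectrum()]
#'
#' @param path file path.
#' @return An [ir_spectrum()]; for broadened files the grid is reconstructed
#'   and the sticks table is empty. The raw metadata is kept in attribute
#'   `"metadata"`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- .parse_hash_metadata(lines)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  ncols <- unique(vapply(vals, length, integer(1)))
  if (length(body) && (length(ncols) != 1 || anyNA(unlist(vals)))) {
    stop("malformed spectrum file (", path, ")", call. = FALSE)
  }
  m <- if (length(body)) do.call(rbind, vals) else matrix(numeric(0), 0, 2)
  type <- if (!is.na(meta["type"])) meta[["type"]] else "stick"
  if (type == "broadened") {
    spec <- ir_spectrum(numeric(0), numeric(0))
    spec$grid <- list(wavenumber = m[, 1], absorbance = m[, 2])
  } else {
    spec <- ir_spectrum(m[, 1], m[, 2],
                        dmudq2 = if (ncol(m) >= 3) m[, 3] else NULL)
  }
  num_meta <- function(key) suppressWarnings(as.numeric(meta[[key]]))
  if (!is.na(meta["lineshape"]) && meta[["lineshape"]] != "NA") {
    spec$lineshape <- meta[["lineshape"]]
  }
  if (!is.na(meta["fwhm"])) spec$fwhm <- num_meta("fwhm")
  if (!is.na(meta["scale_factor"])) spec$scale_factor <- num_meta("scale_factor")
  attr(spec, "metadata") <- meta
  spec
}
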