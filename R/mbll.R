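#' Modified Beer-Lambert law coefficients
#'
#' The MBLL relates the optical-density change at wavelength lambda to the
#' chromophore concentration changes:
#' `dOD(lambda) = d * DPF(lambda) * (eps_HbO(lambda) * dHbO +
#' eps_HbR(lambda) * dHbR)`.
#' Inverting the stacked system over >= 2 wavelengths recovers
#' `(dHbO, dHbR)` per channel and time point.
#'
#' Default extinction coefficients (1/(mM.cm)) are a standard literature
#' compilation for 780/805/830 nm; they are configuration, not ground
#' truth, and should be overridden to match the instrument in use.  The
#' differential path length factor defaults to 6 at every wavelength and
#' the source-detector distance to 3 cm.
#'
#' @param wavelengths_nm Wavelengths, length >= 2.
#' @param extinction Matrix (wavelength x 2) of extinction coefficients,
#'   columns HbO then HbR, in 1/(mM.cm).
#' @param d_cm Source-detector distance in cm.
#' @param dpf Differential path length factor, scalar or one per
#'   wavelength.
#' @return An `mbll_coefficients`.
#' @export
mbll_coefficients <- function(wavelengths_nm = c(780, 805, 830),
                              extinction = default_extinction(wavelengths_nm),
                              d_cm = 3.0,
                              dpf = 6.0) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  extinction <- as.matrix(extinction)
  if (length(wavelengths_nm) < 2L) {
    stop("at least two wavelengths are required", call. = FALSE)
  }
  if (nrow(extinction) != length(wavelengths_nm) || ncol(extinction) != 2L) {
    stop("extinction must be a (wavelength x 2) matrix [HbO, HbR]",
         call. = FALSE)
  }
  if (any(!is.finite(extinction))) {
    stop("extinction coefficients must be finite", call. = FALSE)
  }
  if (qr(extinction)$rank < 2L) {
    stop("extinction rows are collinear; HbO and HbR cannot be separated",
         call. = FALSE)
  }
  if (d_cm <= 0) stop("d_cm must be positive", call. = FALSE)
  dpf <- rep_len(as.numeric(dpf), length(wavelengths_nm))
  if (any(dpf <= 0)) stop("dpf must be positive", call. = FALSE)
  colnames(extinction) <- c("HbO", "HbR")
  structure(list(wavelengths_nm = wavelengths_nm, extinction = extinction,
                 d_cm = d_cm, dpf = dpf),
            class = "mbll_coefficients")
}

#' Literature extinction coefficients for common NIRS wavelengths
#'
#' Approximate hemoglobin extinction coefficients in 1/(mM.cm) near the
#' isosbestic point; intended as overridable defaults only.
#'
#' @param wavelengths_nm Subset of 780, 805, 830 nm.
#' @return Matrix (wavelength x 2), columns HbO, HbR.
#' @export
default_extinction <- function(wavelengths_nm = c(780, 805, 830)) {
  tab <- rbind(`780` = c(0.710, 1.075),
               `805` = c(0.830, 0.793),
               `830` = c(0.974, 0.693))
  key <- as.character(wavelengths_nm)
  if (!all(key %in% rownames(tab))) {
    stop("no default extinction value for wavelength(s) ",
         paste(setdiff(key, rownames(tab)), collapse = ", "),
         "; supply an extinction matrix explicitly", call. = FALSE)
  }
  m <- tab[key, , drop = FALSE]
  colnames(m) <- c("HbO", "HbR")
  m
}

# Effective (wavelength x 2) design matrix with distance and DPF folded in.
.mbll_design <- function(coeffs) {
  coeffs$d_cm * coeffs$dpf * coeffs$extinction
}

#' Convert optical density to concentration changes
#'
#' For exactly two wavelengths solves the 2x2 MBLL system; for three or
#' more, solves the stacked system in the least-squares sense.  The two
#' paths agree when given the same two wavelengths.
#'
#' @param od An [optical_density_record()].
#' @param coeffs An [mbll_coefficients()] covering all wavelengths in
#'   `od`.
#' @param max_condition Reject designs whose condition number exceeds
#'   this; default 1e8.
#' @return A [hemodynamic_record()].
#' @export
od_to_concentration <- function(od, coeffs = mbll_coefficients(
                                  od$wavelengths_nm),
                                max_condition = 1e8) {
  stopifnot(inherits(od, "optical_density_record"),
            inherits(coeffs, "mbll_coefficients"))
  wl <- od$wavelengths_nm
  idx <- match(wl, coeffs$wavelengths_nm)
  if (anyNA(idx)) {
    stop("coefficients do not cover wavelength(s) ",
         paste(wl[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  A <- .mbll_design(coeffs)[idx, , drop = FALSE]
  cond <- kappa(A, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition) {
    stop(sprintf("MBLL system is ill-conditioned (condition number %.3g > %.3g)",
                 cond, max_condition), call. = FALSE)
  }
  n_ch <- length(od$layout$channel_ids)
  W <- length(wl)
  n_t <- nrow(od$od)
  hbo <- matrix(0, n_t, n_ch)
  hbr <- matrix(0, n_t, n_ch)
  # Precompute the (2 x W) solver once; same for every channel/time.
  solver <- if (W == 2L) solve(A) else solve(crossprod(A), t(A))
  for (ch in seq_len(n_ch)) {
    cols <- (ch - 1L) * W + seq_len(W)
    conc <- od$od[, cols, drop = FALSE] %*% t(solver)
    hbo[, ch] <- conc[, 1L]
    hbr[, ch] <- conc[, 2L]
  }
  hemodynamic_record(hbo, hbr, od$fs_hz, od$layout)
}

#' Forward MBLL: concentrations to optical density
#'
#' Applies the MBLL in the forward direction, producing the per-wavelength
#' optical-density changes a continuous-wave instrument would report for
#' the given concentration changes.  `od_to_concentration()` inverts it.
#'
#' @param record A [hemodynamic_record()].
#' @param coeffs An [mbll_coefficients()].
#' @return An [optical_density_record()].
#' @export
forward_mbll <- function(record, coeffs = mbll_coefficients()) {
  stopifnot(inherits(record, "hemodynamic_record"),
            inherits(coeffs, "mbll_coefficients"))
  A <- .mbll_design(coeffs)
  if (qr(A)$rank < 2L) stop("singular extinction design", call. = FALSE)
  W <- length(coeffs$wavelengths_nm)
  n_ch <- ncol(record$hbo)
  od <- matrix(0, nrow(record$hbo), n_ch * W)
  for (ch in seq_len(n_ch)) {
    conc <- cbind(record$hbo[, ch], record$hbr[, ch])
    od[, (ch - 1L) * W + seq_len(W)] <- conc %*% t(A)
  }
  optical_density_record(od, coeffs$wavelengths_nm, record$fs_hz,
                         record$layout)
}
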