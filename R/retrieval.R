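#' Radiometric calibration of digital numbers
#'
#' Converts raw sensor digital numbers to apparent radiance:
#' `Rad = gain * DN / tdi_stage + offset`, where `tdi_stage` is the
#' time-delay-integration stage count of the instrument.
#'
#' @param dn_raster numeric matrix (or vector) of digital numbers.
#' @param gain,offset absolute radiometric calibration coefficients.
#' @param tdi_stage positive integer TDI stage.
#' @return Radiance raster of the same shape; `NA` propagates.
#' @examples
#' dn_to_radiance(100, gain = 0.1, offset = 1, tdi_stage = 2)  # 6
#' @export
dn_to_radiance <- function(dn_raster, gain, offset, tdi_stage = 1L) {
  if (tdi_stage < 1) stop("tdi_stage must be >= 1")
  gain * dn_raster / tdi_stage + offset
}

#' Per-pixel maximum reflectance over a wavelength window
#'
#' Selects all bands whose center wavelength lies in `[lo_nm, hi_nm]`
#' (inclusive) and returns the per-pixel maximum over them. The default
#' window, 510--560 nm, is the green region used by the empirical biomass
#' retrieval line. A pixel that is `NA` in any selected band is `NA` in the
#' result (nodata propagates).
#'
#' @param cube 3-D array (rows x cols x bands) of surface reflectance with
#'   band-center wavelengths in nm as attribute `wavelengths` (or supplied
#'   via `wavelengths`).
#' @param lo_nm,hi_nm window bounds in nm.
#' @param wavelengths optional explicit band centers, overriding the
#'   attribute.
#' @return Matrix of per-pixel window maxima.
#' @export
band_window_max <- function(cube, lo_nm = 510, hi_nm = 560,
                            wavelengths = NULL) {
  wl <- wavelengths %||% attr(cube, "wavelengths")
  if (is.null(wl)) stop("cube has no 'wavelengths' attribute")
  stopifnot(length(dim(cube)) == 3, dim(cube)[3] == length(wl))
  if (is.unsorted(wl, strictly = TRUE)) {
    stop("band wavelengths must be strictly increasing")
  }
  sel <- which(wl >= lo_nm & wl <= hi_nm)
  if (!length(sel)) {
    stop("no band center in [", lo_nm, ", ", hi_nm, "] nm; available: ",
         paste(round(wl, 1), collapse = ", "))
  }
  out <- cube[, , sel[1]]
  for (b in sel[-1]) out <- pmax(out, cube[, , b], na.rm = FALSE)
  out
}

#' Empirical above-ground biomass retrieval
#'
#' Applies the site's empirical retrieval line `AGB = -15.859 x + 4.8574`,
#' where `x` is the per-pixel maximum surface reflectance in the 510--560 nm
#' window. The line was fitted with biomass expressed in 10^3 g m-2 (its
#' values over vegetation reflectance, roughly 2.5--4.9, only match observed
#' reed biomass on that scale), so the returned `agb` raster is the equation
#' value multiplied by 1000 to give g m-2; the raw equation value is also
#' returned. Negative retrievals (bright pixels) are clamped to zero and
#' counted.
#'
#' @param x_raster matrix (or vector) of window-maximum reflectance,
#'   dimensionless in [0, 1].
#' @return A list with `agb` (g m-2, clamped at 0), `equation_value`
#'   (the unscaled line value, 10^3 g m-2) and `n_clamped`.
#' @examples
#' retrieve_agb(0)$equation_value    # 4.8574
#' retrieve_agb(0.1)$agb             # 3271.5
#' @export
retrieve_agb <- function(x_raster) {
  if (any(!is.finite(x_raster) & !is.na(x_raster))) {
    stop("x must be finite (or NA for nodata)")
  }
  eqv <- -15.859 * x_raster + 4.8574
  agb <- eqv * 1000
  n_clamped <- sum(agb < 0, na.rm = TRUE)
  agb[!is.na(agb) & agb < 0] <- 0
  list(agb = agb, equation_value = eqv, n_clamped = n_clamped)
}

#' Zonal statistics of a raster within one class
#'
#' Mean, sample standard deviation (n - 1) and linear-interpolation
#' quartiles of the unmasked pixels of one class. The interquartile interval
#' `[q25, q75]` is the "concentrated range" used to summarize retrieved
#' biomass maps.
#'
#' @param raster numeric matrix (e.g. retrieved AGB, g m-2).
#' @param class_mask integer matrix of class labels, same shape.
#' @param class_id the class to summarize.
#' @return A list with `mean`, `sd`, `q25`, `q75`, `n`.
#' @export
zonal_stats <- function(raster, class_mask, class_id) {
  stopifnot(identical(dim(raster), dim(class_mask)))
  v <- raster[class_mask == class_id]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no unmasked pixel of class ", class_id)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  list(mean = mean(v), sd = stats::sd(v), q25 = q[1], q75 = q[2],
       n = length(v))
}

#' Jeffries--Matusita distance and transformed divergence of two classes
#'
#' Gaussian-assumption separability of two sets of per-band reflectance
#' samples. With Bhattacharyya distance `B`, `JM = 2 (1 - exp(-B))`; with
#' divergence `D`, `TD = 2 (1 - exp(-D/8))`. Both lie in [0, 2]; values
#' above 1.9 conventionally indicate good separability. Class covariances
#' are ridge-regularized by a small diagonal when near-singular.
#'
#' @param samples_a,samples_b numeric matrices, one row per sample, one
#'   column per band (>= 2 rows each).
#' @param ridge diagonal regularization added when a covariance matrix is
#'   not positive definite.
#' @return A list with `jm`, `td` and `bhattacharyya`.
#' @export
sample_separability <- function(samples_a, samples_b, ridge = 1e-8) {
  samples_a <- as.matrix(samples_a)
  samples_b <- as.matrix(samples_b)
  if (nrow(samples_a) < 2 || nrow(samples_b) < 2) {
    stop("need at least 2 samples per class")
  }
  stopifnot(ncol(samples_a) == ncol(samples_b))
  mu_a <- colMeans(samples_a)
  mu_b <- colMeans(samples_b)
  S_a <- regularize_cov(stats::cov(samples_a), ridge)
  S_b <- regularize_cov(stats::cov(samples_b), ridge)
  S_m <- (S_a + S_b) / 2
  d <- mu_a - mu_b
  B <- 0.125 * drop(t(d) %*% solve(S_m, d)) +
    0.5 * (logdet(S_m) - 0.5 * (logdet(S_a) + logdet(S_b)))
  inv_a <- solve(S_a)
  inv_b <- solve(S_b)
  D <- 0.5 * sum(diag((S_a - S_b) %*% (inv_b - inv_a))) +
    0.5 * drop(t(d) %*% (inv_a + inv_b) %*% d)
  list(jm = 2 * (1 - exp(-B)), td = 2 * (1 - exp(-D / 8)), bhattacharyya = B)
}

regularize_cov <- function(S, ridge) {
  k <- 0
  repeat {
    ok <- tryCatch({
      chol(S)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(S)
    S <- S + diag(ridge * 10^k, nrow(S))
    k <- k + 1
    if (k > 12) stop("covariance matrix could not be regularized")
  }
}

logdet <- function(S) 2 * sum(log(diag(chol(S))))

#' Accuracy metrics of a classification confusion matrix
#'
#' Overall accuracy (`trace / total`), the chance-corrected Kappa
#' coefficient, and per-class producer's and user's accuracy. The matrix is
#' oriented with reference classes in columns and mapped classes in rows
#' (the standard remote-sensing convention): producer's accuracy is the
#' diagonal over the reference (column) sum, user's accuracy the diagonal
#' over the mapped (row) sum.
#'
#' @param mat square numeric matrix of pixel counts, mapped class in rows,
#'   reference class in columns.
#' @return A list with `oa`, `kappa`, `pa` and `ua` (named by class when the
#'   matrix has dimnames).
#' @examples
#' confusion_metrics(matrix(c(40, 10, 10, 40), 2, byrow = TRUE))
#' @export
confusion_metrics <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("confusion matrix must be square")
  if (any(mat < 0)) stop("confusion matrix counts must be >= 0")
  n <- sum(mat)
  if (n == 0) stop("confusion matrix has no observations")
  oa <- sum(diag(mat)) / n
  col_marg <- colSums(mat) / n
  row_marg <- rowSums(mat) / n
  pe <- sum(col_marg * row_marg)
  kappa <- if (pe < 1) (oa - pe) / (1 - pe) else 1
  pa <- diag(mat) / colSums(mat)
  ua <- diag(mat) / rowSums(mat)
  nms <- colnames(mat) %||% rownames(mat)
  if (!is.null(nms)) {
    names(pa) <- nms
    names(ua) <- nms
  }
  list(oa = oa, kappa = kappa, pa = pa, ua = ua)
}
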