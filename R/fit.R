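#' Assemble a CPMG dispersion curve table
#'
#' Canonical long-format container for relaxation dispersion data: one row
#' per (residue, field, nu_cpmg) point.
#'
#' @param residue residue numbers.
#' @param nucleus `"N"` or `"C"` per point (recycled).
#' @param field_mhz proton frequency per point, MHz.
#' @param nu_cpmg CPMG frequency, Hz.
#' @param r2eff effective transverse rate, s^-1.
#' @param r2eff_err one-sigma uncertainty, s^-1 (>= 0).
#' @return `dispersion_curves` data.frame.
#' @export
dispersion_curves <- function(residue, nucleus = "N", field_mhz, nu_cpmg,
                              r2eff, r2eff_err = 0) {
  n <- length(nu_cpmg)
  df <- data.frame(residue = as.integer(rep_len(residue, n)),
                   nucleus = rep_len(nucleus, n),
                   field_mhz = rep_len(field_mhz, n),
                   nu_cpmg = nu_cpmg, r2eff = r2eff,
                   r2eff_err = rep_len(r2eff_err, n))
  if (any(df$nu_cpmg <= 0)) stop("nu_cpmg must be positive")
  if (any(df$r2eff_err < 0)) stop("r2eff_err must be non-negative")
  class(df) <- c("dispersion_curves", "data.frame")
  df
}

#' @rdname dispersion_curves
#' @param path TSV path with columns residue, nucleus, field_mhz,
#'   nu_cpmg_hz, r2eff, r2eff_err.
#' @export
read_dispersion <- function(path) {
  df <- utils::read.delim(path)
  need <- c("residue", "nucleus", "field_mhz", "nu_cpmg_hz", "r2eff",
            "r2eff_err")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  dispersion_curves(df$residue, df$nucleus, df$field_mhz, df$nu_cpmg_hz,
                    df$r2eff, df$r2eff_err)
}

#' @rdname dispersion_curves
#' @param curves a `dispersion_curves` table to write.
#' @export
write_dispersion <- function(curves, path) {
  out <- data.frame(residue = curves$residue, nucleus = curves$nucleus,
                    field_mhz = curves$field_mhz,
                    nu_cpmg_hz = curves$nu_cpmg,
                    r2eff = curves$r2eff, r2eff_err = curves$r2eff_err)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# residuals of the two-state Carver-Richards model on a curve table;
# theta = c(pA, kex, dw_ppm, r20 at each field)
cr_residuals <- function(theta, curves, fields) {
  pA <- theta[1]; kex <- theta[2]; dw <- theta[3]
  r20 <- theta[-(1:3)]
  sig <- ifelse(curves$r2eff_err > 0, curves$r2eff_err, 1)
  calc <- numeric(nrow(curves))
  for (i in seq_along(fields)) {
    sel <- curves$field_mhz == fields[i]
    calc[sel] <- cr_r2eff(pA, kex, dw, r20[i], fields[i],
                          curves$nu_cpmg[sel],
                          nucleus = curves$nucleus[sel][1])
  }
  (curves$r2eff - calc) / sig
}

#' Fit the Carver-Richards model to one residue's dispersion curves
#'
#' Weighted least squares over all fields simultaneously: `pA`, `kex` and
#' `dw_ppm` are shared across fields, the intrinsic `R2_0` is fitted per
#' field. A grid of multistarts (log-spaced `kex`, several `pA` and `dw`
#' levels) guards against local minima; parameter uncertainties come from a
#' seeded point-resampling bootstrap restarted at the best fit.
#'
#' A flat (no-exchange) model with one `R2_0` per field is fitted alongside,
#' and the two are compared by AICc (ties favour no-exchange).
#'
#' @param curves `dispersion_curves` rows for a single residue (both fields).
#' @param n_starts number of multistarts over the seeding grid.
#' @param n_boot bootstrap resamples (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @param rex_threshold flagging threshold on Rex, s^-1.
#' @return object of class `dispersion_fit`: list with `model`
#'   (`"exchange"` or `"no-exchange"`), `pA`, `kex`, `dw_ppm`, `r2_0`
#'   (named by field), `chi2`, `aicc`, `aicc_flat`, `boot_se`,
#'   `rex_by_field`, `residuals`, `converged`.
#' @export
fit_dispersion <- function(curves, n_starts = 20, n_boot = 200,
                           seed = 20250101, rex_threshold = 5) {
  stopifnot(nrow(curves) >= 4)
  if (length(unique(curves$residue)) != 1L)
    stop("fit_dispersion expects curves for a single residue")
  if (length(unique(curves$nucleus)) != 1L)
    stop("curves mix nuclei")
  fields <- sort(unique(curves$field_mhz))
  nf <- length(fields)
  sig <- ifelse(curves$r2eff_err > 0, curves$r2eff_err, 1)

  # flat model: weighted mean R2_0 per field
  r20_flat <- vapply(fields, function(fm) {
    sel <- curves$field_mhz == fm
    stats::weighted.mean(curves$r2eff[sel], 1 / sig[sel]^2)
  }, numeric(1))
  res_flat <- (curves$r2eff - r20_flat[match(curves$field_mhz, fields)]) / sig
  chi2_flat <- sum(res_flat^2)

  # multistart grid
  grid <- expand.grid(kex = exp(seq(log(100), log(6000), length.out = 5)),
                      pA = c(0.7, 0.9, 0.98),
                      dw = c(0.5, 1.5, 3))
  grid <- grid[seq_len(min(n_starts, nrow(grid))), , drop = FALSE]
  r20_start <- vapply(fields, function(fm)
    min(curves$r2eff[curves$field_mhz == fm]), numeric(1))
  lower <- c(0.5, 1, 0, rep(0, nf))
  upper <- c(1 - 1e-9, 1e6, 30, rep(500, nf))

  run_fit <- function(theta0) {
    tryCatch(
      minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                         fn = cr_residuals, curves = curves, fields = fields,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  }

  best <- NULL
  for (i in seq_len(nrow(grid))) {
    f0 <- run_fit(c(grid$pA[i], grid$kex[i], grid$dw[i], r20_start))
    if (is.null(f0)) next
    if (is.null(best) || f0$deviance < best$deviance) best <- f0
  }
  if (is.null(best)) {
    return(structure(list(model = "no-exchange", converged = FALSE,
                          pA = NA, kex = NA, dw_ppm = NA, r2_0 = r20_flat,
                          chi2 = chi2_flat, aicc = NA, aicc_flat = NA,
                          boot_se = NULL, rex_by_field = NULL,
                          residuals = res_flat),
                     class = "dispersion_fit"))
  }
  th <- best$par
  names(th) <- c("pA", "kex", "dw_ppm", paste0("r2_0_", fields))
  chi2 <- best$deviance
  n <- nrow(curves)
  aicc_of <- function(chi2, k) {
    pen <- if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
    chi2 + 2 * k + pen
  }
  aicc_ex <- aicc_of(chi2, 3 + nf)
  aicc_flat <- aicc_of(chi2_flat, nf)
  model <- if (aicc_ex < aicc_flat) "exchange" else "no-exchange"

  boot_se <- NULL
  if (n_boot > 0) {
    bpars <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- unlist(lapply(fields, function(fm) {
          w <- which(curves$field_mhz == fm)
          sample(w, length(w), replace = TRUE)
        }))
        cb <- curves[idx, , drop = FALSE]
        fb <- tryCatch(
          minpack.lm::nls.lm(par = th, lower = lower, upper = upper,
                             fn = cr_residuals, curves = cb, fields = fields,
                             control = minpack.lm::nls.lm.control(maxiter = 100)),
          error = function(e) NULL)
        if (is.null(fb)) rep(NA_real_, length(th)) else fb$par
      }, numeric(length(th)))
    })
    boot_se <- apply(bpars, 1, stats::sd, na.rm = TRUE)
    names(boot_se) <- names(th)
    attr(boot_se, "quantiles") <- apply(bpars, 1, stats::quantile,
                                        probs = c(0.025, 0.975), na.rm = TRUE)
  }

  rex_by_field <- stats::setNames(vapply(seq_along(fields), function(i)
    rex(list(pA = th[1], kex = th[2], dw_ppm = th[3], r2_0 = th[3 + i]),
        fields[i], threshold = rex_threshold,
        nucleus = curves$nucleus[1])$rex, numeric(1)),
    as.character(fields))

  structure(list(model = model, converged = TRUE,
                 pA = unname(th[1]), kex = unname(th[2]),
                 dw_ppm = unname(th[3]),
                 r2_0 = stats::setNames(unname(th[-(1:3)]),
                                        as.character(fields)),
                 chi2 = chi2, chi2_flat = chi2_flat,
                 aicc = aicc_ex, aicc_flat = aicc_flat,
                 boot_se = boot_se, rex_by_field = rex_by_field,
                 rex_threshold = rex_threshold,
                 residuals = cr_residuals(best$par, curves, fields)),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat("<dispersion_fit>", x$model, "\n")
  if (x$model == "exchange" || isTRUE(x$converged))
    cat(sprintf("  pA = %.4f  kex = %.1f rad/s  dw = %.3f ppm  chi2 = %.2f\n",
                x$pA, x$kex, x$dw_ppm, x$chi2))
  invisible(x)
}

#' Model selection between exchange and no-exchange fits
#'
#' Minimum-AICc selection; an exact tie is resolved in favour of the simpler
#' no-exchange model.
#'
#' @param fit a `dispersion_fit` (which carries both models' AICc), or two
#'   AICc values via `aicc_exchange`, `aicc_flat`.
#' @param aicc_exchange,aicc_flat optional explicit AICc values.
#' @return `"exchange"` or `"no-exchange"`.
#' @export
select_model <- function(fit = NULL, aicc_exchange = fit$aicc,
                         aicc_flat = fit$aicc_flat) {
  if (is.na(aicc_exchange)) return("no-exchange")
  if (aicc_exchange < aicc_flat) "exchange" else "no-exchange"
}

#' Fit every residue in a dispersion table
#'
#' @param curves full `dispersion_curves` table (many residues).
#' @param ... passed to [fit_dispersion()].
#' @return named list of `dispersion_fit` objects keyed by residue.
#' @export
fit_all_residues <- function(curves, ...) {
  resids <- sort(unique(curves$residue))
  fits <- lapply(resids, function(r)
    fit_dispersion(curves[curves$residue == r, , drop = FALSE], ...))
  stats::setNames(fits, as.character(resids))
}

#' Serialise fit results to JSON records
#'
#' @param fits named list from [fit_all_residues()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  recs <- lapply(names(fits), function(r) {
    f <- fits[[r]]
    list(residue = as.integer(r), model = f$model, pA = f$pA,
         kex_rad_s = f$kex, dw_ppm = f$dw_ppm,
         r2_0_by_field = as.list(f$r2_0),
         rex_by_field = as.list(f$rex_by_field),
         chi2 = f$chi2, aicc = f$aicc)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
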