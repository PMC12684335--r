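#' Lipari-Szabo spectral density
#'
#' Model-free spectral density for an N-H bond vector undergoing overall
#' isotropic tumbling (correlation time `tau_c`) plus fast internal motion of
#' amplitude `1 - S2` and correlation time `tau_e`:
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2} +
#'   \frac{(1-S^2)\tau'}{1+(\omega\tau')^2}\right],\quad
#'   1/\tau' = 1/\tau_c + 1/\tau_e.}
#' With `S2 = 1` (or `tau_e = 0`) this reduces to the rigid-rotor form.
#'
#' @param omega angular frequency, rad/s (vectorised).
#' @param tau_c overall rotational correlation time, seconds.
#' @param S2 generalised order parameter in `[0, 1]`.
#' @param tau_e internal correlation time, seconds (0 = infinitely fast).
#' @return J(omega) in s/rad.
#' @export
spectral_density <- function(omega, tau_c, S2 = 1, tau_e = 0) {
  stopifnot(is.finite(omega), is.finite(tau_c), tau_c > 0,
            S2 >= 0, S2 <= 1, tau_e >= 0)
  j <- S2 * tau_c / (1 + (omega * tau_c)^2)
  if (S2 < 1 && tau_e > 0) {
    tau_p <- 1 / (1 / tau_c + 1 / tau_e)
    j <- j + (1 - S2) * tau_p / (1 + (omega * tau_p)^2)
  }
  0.4 * j
}

# dipolar coupling constant d = (mu0/4pi) hbar gammaH gammaN / rNH^3  [rad/s]
.dip_const <- function(r_nh) {
  (.mu0 / (4 * pi)) * .hbar * .gamma_H * .gamma_N / (r_nh * 1e-10)^3
}

#' Predict 15N R1, R2 and hetNOE from motional parameters
#'
#' Standard dipolar + CSA expressions for amide 15N relaxation, built on
#' [spectral_density()] evaluated at `{0, wN, wH - wN, wH, wH + wN}`.
#' Defaults use the community-standard bond length (1.02 A) and 15N CSA
#' (-172 ppm).
#'
#' @param tau_c rotational correlation time, seconds.
#' @param field a [field_context()] or proton frequency in MHz.
#' @param S2,tau_e internal-motion parameters, see [spectral_density()].
#' @param r_nh N-H bond length, Angstrom.
#' @param csa 15N chemical shift anisotropy, ppm.
#' @return list with elements `R1` (s^-1), `R2` (s^-1), `hetNOE`.
#' @examples
#' predict_rates(13.24e-9, 950)
#' @export
predict_rates <- function(tau_c, field, S2 = 1, tau_e = 0,
                          r_nh = 1.02, csa = -172) {
  f <- as_field(field)
  d2 <- .dip_const(r_nh)^2 / 4
  c2 <- (abs(f$omega_N) * csa * 1e-6)^2 / 3
  J <- function(w) spectral_density(w, tau_c, S2, tau_e)
  wN <- abs(f$omega_N); wH <- f$omega_H
  r1 <- d2 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  r2 <- (d2 / 2) * (4 * J(0) + J(wH - wN) + 3 * J(wN) +
                      6 * J(wH) + 6 * J(wH + wN)) +
        (c2 / 6) * (4 * J(0) + 3 * J(wN))
  noe <- 1 + d2 * (f$gamma_ratio) * (6 * J(wH + wN) - J(wH - wN)) / r1
  list(R1 = r1, R2 = r2, hetNOE = noe)
}

#' Build a per-residue relaxation-rate table
#'
#' Canonical container for backbone 15N relaxation data at one static field:
#' a `data.frame` with columns `residue`, `R1`, `R1_err`, `R2`, `R2_err`,
#' `hetNOE`, `hetNOE_err`, carrying the field as an attribute.
#'
#' @param residue integer residue numbers.
#' @param R1,R2 longitudinal / transverse rates, s^-1.
#' @param hetNOE heteronuclear NOE values (sanity bound: <= 1.2).
#' @param R1_err,R2_err,hetNOE_err one-sigma uncertainties (>= 0).
#' @param field a [field_context()] or MHz value.
#' @return `residue_rates` data.frame.
#' @export
residue_rates <- function(residue, R1, R2, hetNOE,
                          R1_err = 0, R2_err = 0, hetNOE_err = 0, field) {
  n <- length(residue)
  df <- data.frame(residue = as.integer(residue),
                   R1 = R1, R1_err = rep_len(R1_err, n),
                   R2 = R2, R2_err = rep_len(R2_err, n),
                   hetNOE = hetNOE, hetNOE_err = rep_len(hetNOE_err, n))
  if (any(df$R1 <= 0) || any(df$R2 <= 0))
    stop("R1 and R2 must be positive")
  if (any(df$hetNOE > 1.2))
    stop("hetNOE > 1.2: not physical for amide 15N")
  if (any(df$R1_err < 0) || any(df$R2_err < 0) || any(df$hetNOE_err < 0))
    stop("uncertainties must be non-negative")
  attr(df, "field") <- as_field(field)
  class(df) <- c("residue_rates", "data.frame")
  df
}

#' Read a relaxation table from TSV
#'
#' Expects header columns `residue, R1, R1_err, R2, R2_err, hetNOE,
#' hetNOE_err`. The field is taken from a sidecar key-value config file
#' (`<path>.cfg` with a `proton_frequency_mhz` line) unless given explicitly.
#'
#' @param path TSV file path.
#' @param field optional [field_context()] or MHz; overrides the sidecar.
#' @return `residue_rates` data.frame.
#' @export
read_rates <- function(path, field = NULL) {
  df <- utils::read.delim(path, sep = "\t", check.names = TRUE)
  need <- c("residue", "R1", "R1_err", "R2", "R2_err", "hetNOE", "hetNOE_err")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(field)) {
    cfg <- paste0(path, ".cfg")
    if (!file.exists(cfg))
      stop("no field given and no sidecar config at ", cfg)
    kv <- read_keyvals(cfg)
    field <- as.numeric(kv[["proton_frequency_mhz"]])
  }
  residue_rates(df$residue, df$R1, df$R2, df$hetNOE,
                df$R1_err, df$R2_err, df$hetNOE_err, field = field)
}

#' Write a relaxation table (+ sidecar field config) to TSV
#' @param rates `residue_rates` object.
#' @param path output TSV path; the sidecar goes to `<path>.cfg`.
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path) {
  utils::write.table(as.data.frame(rates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  f <- attr(rates, "field")
  writeLines(sprintf("proton_frequency_mhz\t%g", f$proton_mhz),
             paste0(path, ".cfg"))
  invisible(path)
}

read_keyvals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t=]")
  stats::setNames(lapply(parts, function(p) trimws(p[2])),
                  vapply(parts, function(p) trimws(p[1]), ""))
}

#' Estimate the rotational correlation time from R2/R1
#'
#' Residues with fast internal motion (hetNOE below `noe_cutoff`) are
#' excluded; the remaining per-residue R2/R1 ratios are inverted numerically
#' (rigid rotor, S2 = 1) to per-residue correlation times; values outside
#' median +/- 1.5 IQR are trimmed (robust to residual exchange); the result
#' is the trimmed mean. Uncertainty is by Monte-Carlo resampling of the rates
#' within their quoted errors.
#'
#' @param rates `residue_rates` table.
#' @param noe_cutoff hetNOE exclusion threshold (strict `<`), default 0.7.
#' @param n_mc Monte-Carlo resamples for the error bar.
#' @param seed RNG seed for the resampling.
#' @return list: `tau_c_ns`, `tau_c_err_ns`, `n_used`, `per_residue`
#'   (data.frame of residue, tau_c_ns, used flag).
#' @export
estimate_tau_c <- function(rates, noe_cutoff = 0.7, n_mc = 1000,
                           seed = 20250101) {
  f <- attr(rates, "field")
  keep <- rates$hetNOE >= noe_cutoff
  if (sum(keep) < 5)
    stop("fewer than 5 residues survive the hetNOE filter")
  est <- function(r1, r2) {
    vapply(seq_along(r1), function(i)
      invert_r2r1(r2[i] / r1[i], f), numeric(1))
  }
  tc <- est(rates$R1[keep], rates$R2[keep])
  qs <- stats::quantile(tc, c(0.25, 0.5, 0.75), na.rm = TRUE)
  iqr <- qs[3] - qs[1]
  inlier <- !is.na(tc) & abs(tc - qs[2]) <= 1.5 * iqr
  if (!any(inlier)) stop("no residues survive trimming")
  tau_ns <- mean(tc[inlier]) * 1e9

  err_ns <- NA_real_
  if (n_mc > 0 && any(rates$R1_err[keep] > 0 | rates$R2_err[keep] > 0)) {
    r1 <- rates$R1[keep][inlier]; r2 <- rates$R2[keep][inlier]
    s1 <- rates$R1_err[keep][inlier]; s2 <- rates$R2_err[keep][inlier]
    sims <- with_seed(seed, vapply(seq_len(n_mc), function(b) {
      tcb <- est(stats::rnorm(length(r1), r1, s1),
                 stats::rnorm(length(r2), r2, s2))
      mean(tcb, na.rm = TRUE)
    }, numeric(1)))
    err_ns <- stats::sd(sims) * 1e9
  }
  per <- data.frame(residue = rates$residue[keep],
                    tau_c_ns = tc * 1e9, used = inlier)
  list(tau_c_ns = tau_ns, tau_c_err_ns = err_ns,
       n_used = sum(inlier), per_residue = per)
}

# invert R2/R1 -> tau_c (seconds) by bisection on [0.1, 100] ns; R2/R1 is
# strictly increasing in tau_c so the root is unique when bracketed.
invert_r2r1 <- function(ratio, field, lower = 0.1e-9, upper = 100e-9) {
  g <- function(tc) {
    r <- predict_rates(tc, field)
    r$R2 / r$R1 - ratio
  }
  if (g(lower) > 0 || g(upper) < 0) return(NA_real_)
  stats::uniroot(g, c(lower, upper), tol = 1e-15)$root
}

#' Flag residues with elevated R1*R2 (slow us-ms exchange)
#'
#' The R1*R2 product removes the tumbling-anisotropy dependence that inflates
#' R2 alone, so values strictly above the threshold point to chemical
#' exchange.
#'
#' @param rates `residue_rates` table.
#' @param threshold flagging threshold in s^-2, default 20.
#' @return data.frame: residue, r1r2, flagged.
#' @export
r1r2_flags <- function(rates, threshold = 20) {
  prod <- rates$R1 * rates$R2
  data.frame(residue = rates$residue, r1r2 = prod,
             flagged = prod > threshold)
}

#' Flag residues with low hetNOE (fast ps-ns motion)
#'
#' @param rates `residue_rates` table.
#' @param threshold flagging threshold (strict `<`), default 0.7.
#' @return data.frame: residue, hetNOE, flagged.
#' @export
hetnoe_flags <- function(rates, threshold = 0.7) {
  data.frame(residue = rates$residue, hetNOE = rates$hetNOE,
             flagged = rates$hetNOE < threshold)
}

#' Combined amide chemical shift perturbation
#'
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_N)^2}}
#' with the standard nitrogen weighting `w = 0.14`. Residues with a missing
#' shift in either state are skipped with a message.
#'
#' @param apo,bound data.frames with columns `residue`, `dH`, `dN` (ppm).
#' @param weight nitrogen scaling factor, default 0.14.
#' @return data.frame: residue, csp (ppm), for residues present and complete
#'   in both states.
#' @export
csp <- function(apo, bound, weight = 0.14) {
  stopifnot(weight > 0)
  m <- merge(apo, bound, by = "residue", suffixes = c("_apo", "_bound"))
  ok <- stats::complete.cases(m[, c("dH_apo", "dN_apo", "dH_bound", "dN_bound")])
  if (any(!ok))
    message("csp: skipping ", sum(!ok), " residue(s) with missing shifts")
  m <- m[ok, , drop = FALSE]
  data.frame(residue = m$residue,
             csp = sqrt((m$dH_bound - m$dH_apo)^2 +
                          (weight * (m$dN_bound - m$dN_apo))^2))
}

#' Read a chemical-shift table (TSV: residue, dH, dN)
#' @param path TSV file.
#' @return data.frame with columns residue, dH, dN.
#' @export
read_shifts <- function(path) {
  df <- utils::read.delim(path)
  need <- c("residue", "dH", "dN")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df[need]
}

# evaluate expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
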