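# One-set-of-sites isothermal titration calorimetry model: forward
# simulation of per-injection heats under the Wiseman formalism with
# displacement-dilution bookkeeping, and nonlinear least-squares fitting of
# (n, K_d, dH, heat offset).  The default design mirrors a standard
# small-cell titration: 18 x 2 uL injections of 1.25 mM ligand into a
# 0.280 mL cell containing 0.05 mM macromolecule at 298 K.

#' ITC experimental design
#'
#' @param cell_volume_ml active cell volume, mL.
#' @param cell_conc_mm starting macromolecule concentration, mM.
#' @param syringe_conc_mm ligand (syringe) concentration, mM.
#' @param injection_volumes_ul per-injection volumes, uL (>= 2 injections).
#' @param temperature_k temperature, K.
#' @return list of class `itc_design`.
#' @export
itc_design <- function(cell_volume_ml = 0.280, cell_conc_mm = 0.05,
                       syringe_conc_mm = 1.25,
                       injection_volumes_ul = rep(2, 18),
                       temperature_k = 298) {
  stopifnot(cell_volume_ml > 0, cell_conc_mm > 0, syringe_conc_mm > 0,
            all(injection_volumes_ul > 0),
            length(injection_volumes_ul) >= 2, temperature_k > 0)
  structure(list(cell_volume_ml = cell_volume_ml,
                 cell_conc_mm = cell_conc_mm,
                 syringe_conc_mm = syringe_conc_mm,
                 injection_volumes_ul = injection_volumes_ul,
                 temperature_k = temperature_k),
            class = "itc_design")
}

#' One-set-of-sites binding parameters
#'
#' @param n sites per macromolecule (> 0).
#' @param k_d dissociation constant, molar (> 0).
#' @param dh binding enthalpy, kcal/mol of sites.
#' @param q_offset constant per-injection heat (dilution), ucal.
#' @return list of class `one_site_params`.
#' @export
one_site_params <- function(n = 1, k_d = 1.3e-9, dh = -10, q_offset = 0) {
  stopifnot(n > 0, k_d > 0)
  structure(list(n = n, k_d = k_d, dh = dh, q_offset = q_offset),
            class = "one_site_params")
}

# in-cell total concentrations (molar) after each injection
itc_concentrations <- function(design, dilution = c("exponential", "linear")) {
  dilution <- match.arg(dilution)
  v0 <- design$cell_volume_ml * 1e-3            # L
  dv <- design$injection_volumes_ul * 1e-6      # L
  cumv <- cumsum(dv)
  M0 <- design$cell_conc_mm * 1e-3              # M
  X0 <- design$syringe_conc_mm * 1e-3
  if (dilution == "exponential") {
    f <- exp(-cumv / v0)
    M_t <- M0 * f
    X_t <- X0 * (1 - f)
  } else {
    M_t <- M0 * (1 - cumv / (2 * v0)) / (1 + cumv / (2 * v0))
    X_t <- X0 * (cumv / v0) / (1 + cumv / (2 * v0))
  }
  list(M_t = M_t, X_t = X_t, v0 = v0,
       ratio = (X0 * cumv) / (M0 * v0))   # delivered ligand / initial protein
}

# bound fraction Theta from the one-site quadratic
one_site_theta <- function(X_t, M_t, n, k_a) {
  b <- 1 + X_t / (n * M_t) + 1 / (n * k_a * M_t)
  disc <- pmax(0, b^2 - 4 * X_t / (n * M_t))
  (b - sqrt(disc)) / 2
}

itc_model_heats <- function(design, n, k_d, dh, q_offset,
                            dilution = "exponential") {
  conc <- itc_concentrations(design, dilution)
  theta <- one_site_theta(conc$X_t, conc$M_t, n, 1 / k_d)
  # q_i = n M_t(i) dH V0 (Theta_i - Theta_{i-1}): complexes carried out of
  # the cell by the displaced volume generate no heat
  dq <- dh * n * conc$M_t * diff(c(0, theta)) * conc$v0 * 1e9  # kcal -> ucal
  dq + q_offset
}

#' Simulate a one-set-of-sites binding isotherm
#'
#' Per injection, total concentrations are updated with the perfusion-cell
#' displacement convention (concentrations scaled by `exp(-sum(V_inj)/V0)`;
#' a linear convention is available), the bound fraction is solved from the
#' one-site quadratic, and the injection heat is the enthalpy of the change
#' in occupied sites plus the constant offset and optional Gaussian noise.
#'
#' @param design an [itc_design].
#' @param params a [one_site_params].
#' @param noise_sd Gaussian noise per injection, ucal (default 0).
#' @param seed integer seed for the noise (deterministic per seed).
#' @param dilution "exponential" (default) or "linear".
#' @return list of class `itc_isotherm`: `heats_ucal`, `molar_ratio`
#'   (cumulative injected ligand over initial cell macromolecule moles),
#'   `design`, `params_true`.
#' @export
simulate_isotherm <- function(design, params, noise_sd = 0, seed = 1,
                              dilution = "exponential") {
  stopifnot(inherits(design, "itc_design"), inherits(params, "one_site_params"),
            noise_sd >= 0)
  q <- itc_model_heats(design, params$n, params$k_d, params$dh,
                       params$q_offset, dilution)
  if (noise_sd > 0)
    q <- q + with_seed(seed, stats::rnorm(length(q), 0, noise_sd))
  conc <- itc_concentrations(design, dilution)
  structure(list(heats_ucal = q, molar_ratio = conc$ratio,
                 design = design, params_true = params),
            class = "itc_isotherm")
}

#' Write / read an isotherm as a two-column TSV
#' @param iso an `itc_isotherm` (or list with `heats_ucal`).
#' @param path file path.
#' @return `write_isotherm_tsv` the path; `read_isotherm_heats` a numeric
#'   vector of heats (ucal) ordered by injection index.
#' @export
write_isotherm_tsv <- function(iso, path) {
  utils::write.table(
    data.frame(injection = seq_along(iso$heats_ucal),
               heat_ucal = iso$heats_ucal),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_isotherm_tsv
#' @export
read_isotherm_heats <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  d$heat_ucal[order(d$injection)]
}

#' Fit the one-set-of-sites model to an isotherm
#'
#' Nonlinear least squares over (n, log10 K_d, dH, q_offset), K_d bounded in
#' [1e-12, 1e-2] M.  Starting values come from a coarse deterministic grid
#' over (n, log10 K_d) with (dH, q_offset) profiled out by linear least
#' squares, then the fit is polished with Levenberg-Marquardt
#' (\pkg{minpack.lm}).  A flat isotherm (no heat structure above noise) is
#' flagged `no_binding` instead of being reported as a spurious tight fit.
#'
#' @param heats per-injection heats, ucal (or an `itc_isotherm`).
#' @param design the [itc_design] of the titration.
#' @param init optional [one_site_params] starting point (skips the grid).
#' @param dilution bookkeeping convention, as in [simulate_isotherm].
#' @return list of class `one_site_fit`: `params` ([one_site_params]),
#'   `se` (named vector: n, log10_kd, dh, q_offset), `converged`,
#'   `no_binding`, `residuals`, `fitted`, `rss`.
#' @export
fit_one_site <- function(heats, design, init = NULL,
                         dilution = "exponential") {
  if (inherits(heats, "itc_isotherm")) heats <- heats$heats_ucal
  stopifnot(length(heats) == length(design$injection_volumes_ul))
  informative <- sum(abs(heats - stats::median(heats)) > 1e-12)
  if (length(heats) < 4) stop("need at least 4 injections")
  scale_q <- max(abs(heats), 1e-12)
  spread <- stats::mad(heats, constant = 1)
  no_binding <- max(abs(heats - stats::median(heats))) <
    max(6 * spread, 1e-9) || informative < 4
  model_fun <- function(n, lkd, dh, q0)
    itc_model_heats(design, n, 10^lkd, dh, q0, dilution)
  if (is.null(init)) {
    best <- NULL
    for (n0 in c(0.5, 0.8, 1, 1.25, 1.6, 2)) {
      for (lkd in seq(-12, -3, by = 0.5)) {
        a_col <- model_fun(n0, lkd, 1, 0)
        X <- cbind(a_col, 1)
        cf <- tryCatch(stats::lm.fit(X, heats)$coefficients,
                       error = function(e) NULL)
        if (is.null(cf) || any(!is.finite(cf))) next
        rss <- sum((heats - X %*% cf)^2)
        if (is.null(best) || rss < best$rss)
          best <- list(rss = rss, n = n0, lkd = lkd, dh = cf[1], q0 = cf[2])
      }
    }
    if (is.null(best))
      stop("grid initialization failed")
    start <- list(n = best$n, lkd = best$lkd, dh = best$dh, q0 = best$q0)
  } else {
    start <- list(n = init$n, lkd = log10(init$k_d), dh = init$dh,
                  q0 = init$q_offset)
  }
  resid_fun <- function(p)
    heats - model_fun(p[1], p[2], p[3], p[4])
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(n = start$n, lkd = start$lkd, dh = unname(start$dh),
              q0 = unname(start$q0)),
      fn = resid_fun,
      lower = c(0.05, -12, -1e4, -1e6), upper = c(20, -2, 1e4, 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(params = NULL, se = NULL, converged = FALSE,
                          no_binding = no_binding, residuals = NULL,
                          fitted = NULL, rss = NA_real_),
                     class = "one_site_fit"))
  }
  cf <- fit$par
  se <- tryCatch({
    s <- summary(fit)
    s$coefficients[, "Std. Error"]
  }, error = function(e) rep(NA_real_, 4))
  names(se) <- c("n", "log10_kd", "dh", "q_offset")
  fitted_q <- model_fun(cf["n"], cf["lkd"], cf["dh"], cf["q0"])
  converged <- fit$info %in% 1:4
  structure(list(
    params = one_site_params(n = unname(cf["n"]), k_d = 10^unname(cf["lkd"]),
                             dh = unname(cf["dh"]),
                             q_offset = unname(cf["q0"])),
    se = se, converged = converged, no_binding = no_binding,
    residuals = heats - fitted_q, fitted = fitted_q,
    rss = sum((heats - fitted_q)^2)),
    class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("one-site fit: did not converge\n")
  } else {
    cat(sprintf(
      "one-site fit: n = %.3f, K_d = %.3g M, dH = %.2f kcal/mol, offset = %.3g ucal%s%s\n",
      x$params$n, x$params$k_d, x$params$dh, x$params$q_offset,
      if (!x$converged) " [NOT CONVERGED]" else "",
      if (x$no_binding) " [flagged: no binding detected]" else ""))
  }
  invisible(x)
}
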