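#' Worm-like-chain mean squared end-to-end distance
#'
#' Evaluates the Kratky-Porod relation for a worm-like chain in 3D,
#'
#' \deqn{\langle R^2 \rangle = 2 P L \left(1 - \frac{P}{L}
#'   \left(1 - e^{-L/P}\right)\right)}
#'
#' with persistence length `p_um` and contour length `l_um`, both in
#' micrometres. For `l_um / p_um < 1e-4` a series expansion
#' `L^2 (1 - x/3 + x^2/12)` with `x = L/P` is used to avoid catastrophic
#' cancellation; the limits are `L^2` for a rigid rod and `2 P L` for a
#' long flexible chain.
#'
#' @param p_um Persistence length P in um (> 0); vectorized.
#' @param l_um Contour length L in um (> 0); vectorized.
#' @return Expected squared end-to-end distance in um^2.
#' @examples
#' wlc_expected_r2(0.74, 1.48) # ~ 1.2435 um^2
#' @export
wlc_expected_r2 <- function(p_um, l_um) {
  if (any(!is.finite(p_um)) || any(p_um <= 0)) {
    stop("`p_um` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(l_um)) || any(l_um <= 0)) {
    stop("`l_um` must be positive and finite", call. = FALSE)
  }
  n <- max(length(p_um), length(l_um))
  p <- rep_len(p_um, n)
  l <- rep_len(l_um, n)
  x <- l / p
  out <- 2 * p * l * (1 - (1 - exp(-x)) / x)
  small <- x < 1e-4
  if (any(small)) {
    xs <- x[small]
    out[small] <- l[small]^2 * (1 - xs / 3 + xs^2 / 12)
  }
  out
}

#' Fit the persistence length to fibril geometry data
#'
#' Estimates the persistence length P by unweighted nonlinear least
#' squares of the squared end-to-end distance on contour length under the
#' worm-like-chain relation (see [wlc_expected_r2()]). The default
#' starting value is the flexible-limit moment estimate
#' `mean(R^2) / (2 * mean(L))`, clipped to the optimization bounds
#' \[1e-3, 1e3\] um. Confidence intervals are either linearized (t
#' quantile on the Jacobian-based standard error, emulating standard
#' curve-fitting output) or case-resampling bootstrap percentiles.
#'
#' @param geometry A data frame with columns `contour_length_um` and
#'   `r2_um2`, e.g. from [measure_all()].
#' @param ci_method `"linearized"` (default) or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param init Optional starting value for P in um.
#' @param bounds Length-2 positivity bounds for P in um.
#' @param bootstrap_B Number of bootstrap resamples.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `wlc_fit`: list with `p_hat_um`, `se_um`,
#'   `ci95_lo_um`, `ci95_hi_um`, `n_fibrils`, `rss_um4`, `converged`,
#'   `ci_method`, `level`, `at_boundary`.
#' @examples
#' l <- seq(0.1, 2, length.out = 50)
#' geom <- data.frame(contour_length_um = l, r2_um2 = wlc_expected_r2(0.5, l))
#' fit_persistence_length(geom)$p_hat_um # 0.5 exactly (noiseless)
#' @export
fit_persistence_length <- function(geometry,
                                   ci_method = c("linearized", "bootstrap"),
                                   level = 0.95, init = NULL,
                                   bounds = c(1e-3, 1e3),
                                   bootstrap_B = 1000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(is.data.frame(geometry),
            all(c("contour_length_um", "r2_um2") %in% names(geometry)))
  l <- geometry$contour_length_um
  r2 <- geometry$r2_um2
  n <- length(l)
  if (n < 3L) stop("need >= 3 fibrils to fit the persistence length",
                   call. = FALSE)
  if (any(sqrt(r2) > l * (1 + 1e-9))) {
    stop("rows with end-to-end distance exceeding contour length",
         call. = FALSE)
  }
  fit1 <- wlc_nls(l, r2, init, bounds)
  p_hat <- fit1$p_hat
  # a flat objective above p_hat means P is unbounded upward (e.g. all
  # chains collinear, R^2 = L^2 for every L): doubling P barely moves RSS
  rss_double <- sum((r2 - wlc_expected_r2(min(2 * p_hat, bounds[2]), l))^2)
  flat_above <- rss_double <= fit1$rss * (1 + 1e-6) + 1e-12
  at_boundary <- p_hat <= bounds[1] * (1 + 1e-6) ||
    p_hat >= bounds[2] * (1 - 1e-6) || flat_above
  if (at_boundary) {
    warning("fitted persistence length is at an optimization bound; ",
            "the data do not constrain P (e.g. perfectly straight chains)",
            call. = FALSE)
  }
  alpha <- 1 - level
  if (ci_method == "linearized") {
    se <- fit1$se
    tq <- stats::qt(1 - alpha / 2, df = n - 1L)
    ci <- p_hat + c(-1, 1) * tq * se
  } else {
    old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    boot <- vapply(seq_len(bootstrap_B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(wlc_nls(l[idx], r2[idx], p_hat, bounds)$p_hat,
               error = function(e) NA_real_)
    }, numeric(1))
    boot <- boot[is.finite(boot)]
    if (length(boot) < bootstrap_B * 0.5) {
      warning("more than half of the bootstrap refits failed",
              call. = FALSE)
    }
    se <- stats::sd(boot)
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  }
  structure(list(
    p_hat_um = p_hat, se_um = se,
    ci95_lo_um = ci[1], ci95_hi_um = ci[2],
    n_fibrils = n, rss_um4 = fit1$rss,
    converged = fit1$converged, at_boundary = at_boundary,
    ci_method = ci_method, level = level
  ), class = "wlc_fit")
}

# single bounded nls fit of the Kratky-Porod relation; internal
wlc_nls <- function(l, r2, init, bounds) {
  if (is.null(init)) init <- mean(r2) / (2 * mean(l))
  init <- min(max(init, bounds[1]), bounds[2])
  dat <- data.frame(l = l, r2 = r2)
  fit <- tryCatch(
    stats::nls(r2 ~ wlc_expected_r2(P, l), data = dat,
               start = list(P = init), algorithm = "port",
               lower = bounds[1], upper = bounds[2],
               control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) stop("nonlinear fit failed: no convergence from init ",
                         signif(init, 4), call. = FALSE)
  p_hat <- unname(stats::coef(fit)[["P"]])
  se <- tryCatch(unname(summary(fit)$coefficients["P", "Std. Error"]),
                 error = function(e) NA_real_)
  conv <- fit$convInfo$isConv %||% TRUE
  list(p_hat = p_hat, se = se,
       rss = sum(stats::resid(fit)^2), converged = isTRUE(conv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf(
    "Worm-like-chain fit: P = %.2f um (SE %.3f), %d%% CI [%.2f, %.2f] (%s), n = %d\n",
    x$p_hat_um, x$se_um, round(100 * x$level), x$ci95_lo_um, x$ci95_hi_um,
    x$ci_method, x$n_fibrils))
  invisible(x)
}

#' Bending rigidity from the persistence length
#'
#' Converts a persistence length to a bending rigidity through
#' `B = k_B * T * P`, with the Boltzmann constant fixed at its exact SI
#' value 1.380649e-23 J/K and P converted from um to m. An optional
#' standard error on P propagates linearly: `SE(B) = k_B * T * SE(P)`.
#'
#' @param p_um Persistence length in um (>= 0).
#' @param temperature_K Absolute temperature in K (default 300).
#' @param se_um Optional standard error of P in um.
#' @return A list of class `rigidity_result` with `b_Nm2`, `se_Nm2`
#'   (NA if no `se_um`), `temperature_K`, `boltzmann_JperK`, `p_um`.
#' @examples
#' bending_rigidity(0.74)$b_Nm2 # 3.065e-27 N m^2 -> 3.1e-27 at 2 s.f.
#' @export
bending_rigidity <- function(p_um, temperature_K = 300, se_um = NULL) {
  if (!is.numeric(p_um) || length(p_um) != 1L || !is.finite(p_um) ||
      p_um < 0) {
    stop("`p_um` must be a single non-negative number", call. = FALSE)
  }
  stopifnot(temperature_K > 0)
  kb <- 1.380649e-23
  b <- kb * temperature_K * (p_um * 1e-6)
  se_b <- if (is.null(se_um)) NA_real_ else {
    stopifnot(se_um >= 0)
    kb * temperature_K * (se_um * 1e-6)
  }
  structure(list(b_Nm2 = b, se_Nm2 = se_b, temperature_K = temperature_K,
                 boltzmann_JperK = kb, p_um = p_um),
            class = "rigidity_result")
}

#' @export
print.rigidity_result <- function(x, ...) {
  cat(sprintf("Bending rigidity B = %.2g N m^2 (P = %.2f um, T = %g K)\n",
              signif(x$b_Nm2, 2), x$p_um, x$temperature_K))
  if (is.finite(x$se_Nm2)) cat(sprintf("  propagated SE = %.1g N m^2\n",
                                       signif(x$se_Nm2, 1)))
  invisible(x)
}
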