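#' Sample bending-angle cosines for a discrete worm-like chain
#'
#' Draws `n` values of cos(theta) from the equilibrium bending density of a
#' discrete worm-like chain with stiffness `a = P / l` (persistence length
#' over segment length, dimensionless): density proportional to
#' exp(a * cos(theta)) on \[-1, 1\]. Sampling uses the closed-form inverse
#' CDF, so no rejection step is needed. The expectation is the Langevin
#' form coth(a) - 1/a, which approximates exp(-l/P) with relative error
#' O((l/P)^2).
#'
#' Draws consume the session RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param a Positive dimensionless stiffness P/l.
#' @param n Number of draws.
#' @return Numeric vector of cosines in \[-1, 1\].
#' @examples
#' set.seed(1)
#' mean(sample_bend_cosine(74, 1e4)) # ~ coth(74) - 1/74 = 0.98649
#' @export
sample_bend_cosine <- function(a, n = 1L) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop("`a` must be a single positive finite number", call. = FALSE)
  }
  u <- stats::runif(n)
  # cos = 1 + log(1 - u * (1 - exp(-2a))) / a, with 1 - exp(-2a) = -expm1(-2a)
  pmax(-1, pmin(1, 1 + log1p(u * expm1(-2 * a)) / a))
}

#' Mean bend cosine of the discrete worm-like chain
#'
#' Closed form coth(a) - 1/a for the expectation of [sample_bend_cosine()];
#' useful as an analytic oracle. Evaluated stably for large `a`.
#'
#' @param a Positive stiffness P/l.
#' @return The Langevin function coth(a) - 1/a.
#' @export
mean_bend_cosine <- function(a) {
  stopifnot(is.numeric(a), all(a > 0))
  # coth(a) = 1 + 2/(exp(2a) - 1); second term underflows safely for large a
  1 + 2 / expm1(2 * a) - 1 / a
}

# unit vector uniform on the sphere (2 RNG draws)
runif_sphere <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(phi), s * sin(phi), z)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate one discrete worm-like chain
#'
#' Builds a 3D polygonal chain of `round(l_um * 1000 / seg_nm)` segments of
#' exact length `seg_nm`. The first tangent is uniform on the unit sphere;
#' each subsequent tangent bends the previous one by a polar angle drawn
#' via [sample_bend_cosine()] with stiffness `a = (p_um * 1000) / seg_nm`
#' and a uniform azimuth in the plane normal to the previous tangent.
#' Points are the cumulative sum of tangent * seg_nm from the origin, so
#' the realized contour length is exactly `n_seg * seg_nm` (within
#' `seg_nm / 2` of the requested length).
#'
#' Consumes the session RNG; seed with [set.seed()].
#'
#' @param p_um True persistence length in micrometres (> 0).
#' @param l_um Requested contour length in micrometres (> 0).
#' @param seg_nm Discretization segment length in nanometres (> 0).
#' @param fibril_id Identifier for the resulting trace.
#' @return A [fibril_trace()] with provenance `"simulated"`.
#' @examples
#' set.seed(7)
#' tr <- generate_wlc_trace(0.74, 1.0, 10)
#' contour_length(tr) # exactly 1.000 um
#' @export
generate_wlc_trace <- function(p_um, l_um, seg_nm, fibril_id = "sim_1") {
  stopifnot(p_um > 0, l_um > 0, seg_nm > 0)
  n_seg <- round(l_um * 1000 / seg_nm)
  if (n_seg < 1L) {
    stop("requested contour length ", l_um, " um is too short for ",
         seg_nm, " nm segments", call. = FALSE)
  }
  a <- (p_um * 1000) / seg_nm
  t_cur <- runif_sphere()
  cosines <- if (n_seg > 1L) sample_bend_cosine(a, n_seg - 1L) else numeric(0)
  azim <- if (n_seg > 1L) stats::runif(n_seg - 1L, 0, 2 * pi) else numeric(0)
  tangents <- matrix(0, nrow = n_seg, ncol = 3L)
  tangents[1L, ] <- t_cur
  for (i in seq_len(n_seg - 1L)) {
    # orthonormal frame normal to the current tangent
    helper <- if (abs(t_cur[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- cross3(helper, t_cur)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(t_cur, e1)
    ct <- cosines[i]
    st <- sqrt(max(0, 1 - ct^2))
    t_new <- ct * t_cur + st * (cos(azim[i]) * e1 + sin(azim[i]) * e2)
    t_cur <- t_new / sqrt(sum(t_new^2))
    tangents[i + 1L, ] <- t_cur
  }
  pts <- rbind(c(0, 0, 0), apply(tangents * seg_nm, 2L, cumsum))
  if (n_seg == 1L) pts <- rbind(c(0, 0, 0), tangents * seg_nm)
  fibril_trace(fibril_id, pts, provenance = "simulated")
}

#' Specify a simulated tracing study
#'
#' Defaults reproduce the study design this package targets: a cohort of
#' 195 traced fibrils with persistence length 0.74 um, contour lengths
#' uniform on 0.3--2.0 um, 10-nm discretization and no tracing noise.
#'
#' @param n_fibrils Number of chains (>= 1).
#' @param p_um True persistence length in um (> 0).
#' @param length_dist Contour-length sampler: `list(kind = "uniform",
#'   lo_um =, hi_um =)` or `list(kind = "fixed", l_um =)`.
#' @param seg_nm Segment length in nm; must satisfy
#'   `seg_nm <= 0.2 * p_um * 1000` for discretization validity.
#' @param noise_sd_nm SD of isotropic Gaussian point jitter in nm (0 = none).
#' @param seed Integer root seed; per-fibril streams are derived from it by
#'   fibril index, so each chain is reproducible independent of generation
#'   order.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_fibrils = 195L, p_um = 0.74,
                            length_dist = list(kind = "uniform",
                                               lo_um = 0.3, hi_um = 2.0),
                            seg_nm = 10, noise_sd_nm = 0, seed = 1L) {
  stopifnot(n_fibrils >= 1L, p_um > 0, seg_nm > 0, noise_sd_nm >= 0,
            is.numeric(seed), length(seed) == 1L)
  if (seg_nm > 0.2 * p_um * 1000) {
    stop("seg_nm = ", seg_nm, " nm violates discretization validity ",
         "(must be <= 0.2 * P = ", 0.2 * p_um * 1000, " nm)", call. = FALSE)
  }
  kind <- length_dist$kind
  if (identical(kind, "uniform")) {
    lo <- length_dist$lo_um; hi <- length_dist$hi_um
    if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || lo >= hi) {
      stop("uniform length_dist needs 0 < lo_um < hi_um", call. = FALSE)
    }
  } else if (identical(kind, "fixed")) {
    if (!is.numeric(length_dist$l_um) || length_dist$l_um <= 0) {
      stop("fixed length_dist needs l_um > 0", call. = FALSE)
    }
  } else {
    stop("length_dist$kind must be 'uniform' or 'fixed'", call. = FALSE)
  }
  structure(list(n_fibrils = as.integer(n_fibrils), p_um = p_um,
                 length_dist = length_dist, seg_nm = seg_nm,
                 noise_sd_nm = noise_sd_nm, seed = as.integer(seed)),
            class = "simulation_spec")
}

# deterministic per-fibril seed derived from the root seed and index
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 48271 * as.double(index)) %% 2147483647)
}

#' Simulate a cohort of traced fibrils
#'
#' Generates `spec$n_fibrils` worm-like chains at the spec's persistence
#' length, drawing each chain's contour length from `spec$length_dist` and
#' optionally adding iid Gaussian jitter to every point after chain
#' construction. Each fibril uses an RNG stream derived deterministically
#' from the root seed and the fibril index, so output is bit-reproducible
#' for a fixed seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `traces` (list of [fibril_trace()]) and `manifest`
#'   (spec, seed, per-fibril requested and realized contour lengths in um).
#' @examples
#' sim <- simulate_study(simulation_spec(n_fibrils = 5, seed = 42))
#' length(sim$traces)
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  n <- spec$n_fibrils
  traces <- vector("list", n)
  req_len <- numeric(n)
  real_len <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed, i))
    l_um <- switch(spec$length_dist$kind,
      uniform = stats::runif(1, spec$length_dist$lo_um,
                             spec$length_dist$hi_um),
      fixed = spec$length_dist$l_um)
    id <- sprintf("sim_%03d", i)
    tr <- generate_wlc_trace(spec$p_um, l_um, spec$seg_nm, fibril_id = id)
    if (spec$noise_sd_nm > 0) {
      jitter <- matrix(stats::rnorm(length(tr$points), 0, spec$noise_sd_nm),
                       ncol = 3L)
      tr <- fibril_trace(id, tr$points + jitter, provenance = "simulated")
    }
    req_len[i] <- l_um
    real_len[i] <- contour_length(tr)
    traces[[i]] <- tr
  }
  manifest <- list(
    spec = unclass(spec), seed = spec$seed,
    fibril_ids = vapply(traces, function(t) t$fibril_id, character(1)),
    requested_length_um = req_len,
    realized_length_um = real_len
  )
  list(traces = traces, manifest = manifest)
}
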