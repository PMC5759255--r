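#' Distribution specifications for uncertain parameters
#'
#' Every uncertain quantity in a scenario -- a participation proportion, an
#' illness probability, a unit cost -- is described by a `dist_spec`: a
#' distribution family, its parameters, and optional clamping bounds.
#' Supported families are `point`, `uniform`, `normal`, `truncated_normal`,
#' `triangular`, `pert`, `lognormal` and `empirical`.
#'
#' Draws that fall outside `[lower, upper]` are moved to the nearest bound
#' (clamping). Clamping, rather than rejection sampling, keeps the number of
#' random deviates consumed per parameter fixed, so a seeded simulation is
#' reproducible draw-for-draw regardless of how often a bound is hit.
#' Bounds are only accepted for families with unbounded support (`normal`,
#' `truncated_normal`, `lognormal`, `empirical`); for the bounded-support
#' families the natural support is the bound.
#'
#' A `dist_spec` may also carry `source_year` and `series`, marking a cost
#' parameter quoted in another year's dollars; the simulation engine then
#' applies the scenario's consumer-price-index factor (see
#' [inflation_adjust()]).
#'
#' @param family One of `"point"`, `"uniform"`, `"normal"`,
#'   `"truncated_normal"`, `"triangular"`, `"pert"`, `"lognormal"`,
#'   `"empirical"`.
#' @param ... Family parameters: `value` (point); `min`, `max` (uniform);
#'   `mean`, `sd` (normal, truncated_normal); `min`, `mode`, `max`
#'   (triangular, pert); `meanlog`, `sdlog` (lognormal); `values` (empirical).
#' @param lower,upper Optional clamping bounds.
#' @param source_year,series Optional consumer-price-index tag (calendar year
#'   and series name) for cost parameters quoted in non-reference-year dollars.
#'
#' @return A `dist_spec` object.
#' @examples
#' dist_spec("normal", mean = 10, sd = 2, lower = 0)
#' dist_spec("pert", min = 1, mode = 3, max = 9)
#' @export
dist_spec <- function(family, ..., lower = -Inf, upper = Inf,
                      source_year = NULL, series = NULL) {
  params <- list(...)
  spec <- structure(
    list(family = family, params = params,
         lower = lower %||% -Inf, upper = upper %||% Inf,
         source_year = source_year, series = series),
    class = "dist_spec"
  )
  validate_dist_spec(spec)
}

dist_families <- c("point", "uniform", "normal", "truncated_normal",
                   "triangular", "pert", "lognormal", "empirical")

bad_param <- function(field, why) {
  abort(paste0("invalid parameter: ", field, " (", why, ")"),
        class = "aquaburden_invalid_parameter")
}

validate_dist_spec <- function(spec, field = "dist_spec") {
  if (!spec$family %in% dist_families) {
    bad_param(field, paste0("unknown family '", spec$family, "'"))
  }
  p <- spec$params
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  need <- function(nms) {
    if (!setequal(names(p), nms)) {
      bad_param(field, paste0(spec$family, " needs parameters {",
                              paste(nms, collapse = ", "), "}"))
    }
    for (nm in setdiff(nms, "values")) if (!num1(p[[nm]])) {
      bad_param(field, paste0(nm, " must be a finite number"))
    }
  }
  if (spec$lower > spec$upper) bad_param(field, "lower bound exceeds upper bound")
  bounded_support <- spec$family %in% c("point", "uniform", "triangular", "pert")
  if (bounded_support && (is.finite(spec$lower) || is.finite(spec$upper))) {
    bad_param(field, "clamping bounds are not accepted for bounded-support families")
  }
  switch(spec$family,
    point = need("value"),
    uniform = {
      need(c("min", "max"))
      if (p$min > p$max) bad_param(field, "min must not exceed max")
    },
    normal = ,
    truncated_normal = {
      need(c("mean", "sd"))
      if (p$sd <= 0) bad_param(field, "sd must be strictly positive")
      if (spec$family == "truncated_normal" &&
          !is.finite(spec$lower) && !is.finite(spec$upper)) {
        bad_param(field, "truncated_normal needs at least one finite bound")
      }
    },
    triangular = ,
    pert = {
      need(c("min", "mode", "max"))
      if (!(p$min <= p$mode && p$mode <= p$max)) {
        bad_param(field, "min <= mode <= max required")
      }
    },
    lognormal = {
      need(c("meanlog", "sdlog"))
      if (p$sdlog <= 0) bad_param(field, "sdlog must be strictly positive")
      if (spec$lower > 0 || is.finite(spec$upper)) {
        # allowed, clamped-lognormal mean has a closed form
      }
    },
    empirical = {
      need("values")
      if (!is.numeric(p$values) || length(p$values) == 0 || anyNA(p$values)) {
        bad_param(field, "values must be a non-empty numeric vector")
      }
    }
  )
  spec
}

#' @export
print.dist_spec <- function(x, ...) {
  ps <- paste(names(x$params),
              vapply(x$params, function(v) paste(signif(v, 6), collapse = ","),
                     character(1)),
              sep = "=", collapse = ", ")
  b <- if (is.finite(x$lower) || is.finite(x$upper)) {
    paste0(" clamped to [", x$lower, ", ", x$upper, "]")
  } else ""
  cat("<dist_spec> ", x$family, "(", ps, ")", b, "\n", sep = "")
  invisible(x)
}

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# inverse-CDF triangular deviates
qtri <- function(u, a, m, b) {
  if (a == b) return(rep(a, length(u)))
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Draw from a distribution specification
#'
#' Draws `n` values using the current R random-number stream (seed the stream
#' with [set.seed()]; [run_simulation()] does this for you). Exactly one
#' vectorized deviate call is consumed per invocation, so draw counts -- and
#' hence seeded reproducibility -- do not depend on parameter values. Values
#' outside the spec's bounds are clamped to the nearest bound.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`; a `point` spec returns its value
#'   unconditionally.
#' @examples
#' set.seed(1)
#' sample_dist(dist_spec("normal", mean = 0.015, sd = 0.003, lower = 0), 5)
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), is.numeric(n), n >= 0)
  p <- spec$params
  x <- switch(spec$family,
    point = rep(p$value, n),
    uniform = runif(n, p$min, p$max),
    normal = rnorm(n, p$mean, p$sd),
    truncated_normal = rnorm(n, p$mean, p$sd),
    triangular = qtri(runif(n), p$min, p$mode, p$max),
    pert = {
      if (p$min == p$max) rep(p$min, n) else {
        alpha <- 1 + 4 * (p$mode - p$min) / (p$max - p$min)
        beta <- 1 + 4 * (p$max - p$mode) / (p$max - p$min)
        p$min + (p$max - p$min) * rbeta(n, alpha, beta)
      }
    },
    lognormal = rlnorm(n, p$meanlog, p$sdlog),
    empirical = p$values[sample.int(length(p$values), n, replace = TRUE)]
  )
  clamp(x, spec$lower, spec$upper)
}

# mean of a normal clamped to [l, u]
clamped_normal_mean <- function(mu, s, l, u) {
  a <- (l - mu) / s
  b <- (u - mu) / s
  lo <- if (is.finite(l)) l * pnorm(a) else 0
  hi <- if (is.finite(u)) u * pnorm(b, lower.tail = FALSE) else 0
  mid <- mu * (pnorm(b) - pnorm(a)) +
    s * ((if (is.finite(l)) dnorm(a) else 0) - (if (is.finite(u)) dnorm(b) else 0))
  lo + hi + mid
}

# mean of a lognormal clamped to [l, u]; partial expectation of the lognormal
clamped_lognormal_mean <- function(mu, s, l, u) {
  l <- max(l, 0)
  zl <- if (l > 0) (log(l) - mu) / s else -Inf
  zu <- if (is.finite(u)) (log(u) - mu) / s else Inf
  lo <- if (l > 0) l * pnorm(zl) else 0
  hi <- if (is.finite(u)) u * pnorm(zu, lower.tail = FALSE) else 0
  lo + hi + exp(mu + s^2 / 2) * (pnorm(zu - s) - pnorm(zl - s))
}

#' Analytic mean of a distribution specification
#'
#' Closed-form expectation of the draws produced by [sample_dist()],
#' including the effect of clamping bounds. Used by the deterministic
#' point-mass pipeline ([point_estimate()]) and by the synthetic-scenario
#' truth tables ([analytic_expectation()]).
#'
#' @param spec A [dist_spec()].
#' @return The expected value of one draw.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    point = p$value,
    uniform = (p$min + p$max) / 2,
    normal = ,
    truncated_normal = clamped_normal_mean(p$mean, p$sd, spec$lower, spec$upper),
    triangular = (p$min + p$mode + p$max) / 3,
    pert = (p$min + 4 * p$mode + p$max) / 6,
    lognormal = clamped_lognormal_mean(p$meanlog, p$sdlog, spec$lower, spec$upper),
    empirical = mean(clamp(p$values, spec$lower, spec$upper))
  )
}

#' Build a distribution from a reported mean and central-90% interval
#'
#' Inverts the reporting convention used throughout the pipeline's outputs: a
#' quantity quoted as mean with 5th and 95th percentiles becomes a normal
#' spec centred at the mean with `sd = (p95 - p5) / (2 * 1.6449)`. When the
#' interval has zero width the result is a point mass. For an untruncated
#' symmetric input the analytic 5th/95th percentiles of the result reproduce
#' `p5` and `p95`.
#'
#' @param mean Reported mean.
#' @param p5,p95 Reported 5th and 95th percentiles (`p5 <= mean <= p95`).
#' @param lower,upper Optional clamping bounds for the resulting spec.
#' @return A [dist_spec()].
#' @examples
#' spec_from_c90(9.50, 8.62, 10.34)
#' @export
spec_from_c90 <- function(mean, p5, p95, lower = -Inf, upper = Inf) {
  if (!(p5 <= mean && mean <= p95)) {
    abort("invalid C90: need p5 <= mean <= p95", class = "aquaburden_invalid_c90")
  }
  if (p95 == p5) {
    return(dist_spec("point", value = mean))
  }
  dist_spec("normal", mean = mean, sd = (p95 - p5) / (2 * qnorm(0.95)),
            lower = lower, upper = upper)
}
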