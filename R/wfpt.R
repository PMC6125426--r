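#' Wiener first-passage-time density
#'
#' Density of the decision-time component of the drift-diffusion process at
#' the chosen boundary. The non-decision time is excluded: `t` is the time
#' since accumulation onset (shift observed response times by `tr` before
#' calling, or use [ddm_loglik()] which does so internally). Inter-trial
#' drift variability (`sv`) is marginalized analytically (the Gaussian drift
#' mixture has a closed form); starting-point (`sz`) and non-decision-time
#' (`st`) variability are marginalized by 7-point Gauss-Legendre quadrature.
#' The series expansion is truncated for absolute error below `err`,
#' switching between the small- and large-time representations by the
#' standard bound comparison.
#'
#' @param t Vector of decision times in seconds (> 0).
#' @param boundary `"upper"` (face) or `"lower"` (house).
#' @param params A [ddm_params()] object.
#' @param err Absolute series truncation error (default 1e-7).
#' @return Vector of densities (1/s), nonnegative and finite.
#' @examples
#' p <- ddm_params(a = 1.2, z = 0.66, v = 1)
#' wfpt_density(c(0.3, 0.6, 1.2), "upper", p)
#' @export
wfpt_density <- function(t, boundary = c("upper", "lower"), params,
                         err = 1e-7) {
  boundary <- match.arg(boundary)
  params <- as_ddm_params(params)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("decision times 't' must be finite and > 0", call. = FALSE)
  wfpt_density_cpp(as.numeric(t), as.integer(boundary == "upper"),
                   params$a, params$z, params$v,
                   params$sv, params$sz, params$st, err)
}

#' Closed-form absorption probability
#'
#' Exact probability that the diffusion terminates at the given boundary,
#' available when there is no inter-trial drift or starting-point
#' variability: `P(upper) = (1 - exp(-2 v a z)) / (1 - exp(-2 v a))` for
#' unit diffusion coefficient, with the limit `P(upper) = z` as `v -> 0`.
#' Non-decision-time variability does not affect choice and is allowed.
#'
#' @inheritParams wfpt_density
#' @return A probability; `P(upper) + P(lower) = 1`.
#' @examples
#' choice_probability("upper", ddm_params(a = 1, z = 0.66, v = 0))
#' @export
choice_probability <- function(boundary = c("upper", "lower"), params) {
  boundary <- match.arg(boundary)
  params <- as_ddm_params(params)
  if (params$sv != 0 || params$sz != 0)
    stop("closed-form choice probability requires sv = 0 and sz = 0",
         call. = FALSE)
  a <- params$a; z <- params$z; v <- params$v
  p_up <- if (abs(v) < 1e-10) {
    z
  } else {
    expm1(-2 * v * a * z) / expm1(-2 * v * a)
  }
  if (boundary == "upper") p_up else 1 - p_up
}

#' Drift-diffusion log-likelihood of a set of trials
#'
#' Sum of per-trial log Wiener first-passage densities for trials sharing a
#' single parameter configuration. Response times are observed times; the
#' non-decision time is subtracted internally (and its inter-trial range
#' handled by quadrature). Trials whose density underflows to zero
#' contribute a large finite penalty rather than `-Inf`, keeping MCMC
#' samplers alive; the penalty constant is documented and adjustable.
#'
#' @param rt Vector of observed response times in seconds.
#' @param response Vector (same length) coding the boundary reached:
#'   logical/0-1 (TRUE/1 = upper/face) or character `"upper"`/`"lower"` /
#'   `"face"`/`"house"`.
#' @param params A [ddm_params()] object.
#' @param err Series truncation error.
#' @param penalty Log-density contribution of a zero-density trial
#'   (default -1e6).
#' @return Scalar log-likelihood.
#' @export
ddm_loglik <- function(rt, response, params, err = 1e-7, penalty = -1e6) {
  params <- as_ddm_params(params)
  up <- response_to_upper(response)
  if (length(rt) == 0) stop("empty data", call. = FALSE)
  if (length(up) != length(rt))
    stop("'rt' and 'response' lengths differ", call. = FALSE)
  ddm_loglik_cpp(as.numeric(rt), up, params$a, params$z, params$v, params$tr,
                 params$sv, params$sz, params$st, err, penalty)
}

response_to_upper <- function(response) {
  if (is.character(response) || is.factor(response)) {
    response <- as.character(response)
    up <- response %in% c("upper", "face")
    lo <- response %in% c("lower", "house")
    if (!all(up | lo)) stop("unrecognized response codes", call. = FALSE)
    as.integer(up)
  } else {
    r <- as.integer(response)
    if (!all(r %in% c(0L, 1L))) stop("responses must be 0/1", call. = FALSE)
    r
  }
}
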