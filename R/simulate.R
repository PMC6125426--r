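#' Simulate drift-diffusion trials
#'
#' Forward-simulates the diffusion process by Euler-Maruyama integration.
#' Per trial, the drift is drawn from `Normal(v, sv)`, the starting point
#' from `Uniform(z - sz/2, z + sz/2)` and the non-decision time from
#' `Uniform(tr - st/2, tr + st/2)`; the process is integrated to absorption
#' with step `dt`, and the response time is the absorption time plus the
#' trial's non-decision time. Trials whose response time would exceed
#' `deadline` are censored as `no_response`. The default step `dt = 1e-4` s
#' is accurate enough for oracle comparisons; bulk posterior-predictive runs
#' may use a coarser step (e.g. `1e-3`).
#'
#' @param params A [ddm_params()] object.
#' @param n Number of trials (>= 1).
#' @param deadline Response deadline in seconds (the task window; default 6).
#' @param seed Integer seed; fixes the simulation stream.
#' @param dt Integration step in seconds.
#' @return A data.frame with columns `choice` (`"upper"`, `"lower"` or
#'   `"no_response"`) and `rt` (seconds; `NA` for `no_response`).
#' @examples
#' simulate_ddm(ddm_params(a = 1.2, z = 0.55, v = 1.5, tr = 0.3),
#'              n = 5, seed = 1)
#' @export
simulate_ddm <- function(params, n, deadline = 6, seed = 1L, dt = 1e-4) {
  params <- as_ddm_params(params)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (deadline <= 0) stop("'deadline' must be > 0", call. = FALSE)
  out <- simulate_ddm_cpp(as.integer(n), params$a, params$z, params$v,
                          params$tr, params$sv, params$sz, params$st,
                          dt, deadline, as.integer(seed))
  choice <- ifelse(is.na(out$choice), "no_response",
                   ifelse(out$choice == 1L, "upper", "lower"))
  data.frame(choice = choice, rt = out$rt, stringsAsFactors = FALSE)
}
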