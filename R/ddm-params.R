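#' Drift-diffusion model parameter set
#'
#' Bundles one subject-condition parameter configuration of the
#' drift-diffusion model, with the boundary coding used throughout the
#' package: the *upper* boundary is the face response, the *lower* boundary
#' the house response, and a positive drift rate drifts towards the face
#' boundary. The starting point `z` is relative: a fraction of the boundary
#' separation measured from the lower (house) boundary, so `z = 0.5` is
#' unbiased. The diffusion coefficient is fixed at `s = 1`, so all
#' parameters are expressed on that scale.
#'
#' @param a Boundary separation (evidence units, > 0).
#' @param z Relative starting point in (0, 1).
#' @param v Drift rate (evidence units per second, signed towards the
#'   upper/face boundary).
#' @param tr Non-decision time in seconds (>= 0).
#' @param sv Inter-trial standard deviation of the drift rate (>= 0).
#' @param sz Inter-trial range of the starting point (uniform width, as a
#'   fraction of `a`; >= 0). The support `z +/- sz/2` must stay inside (0, 1).
#' @param st Inter-trial range of the non-decision time in seconds (uniform
#'   width, >= 0). `tr - st/2` must be >= 0.
#'
#' @return An object of class `"ddm_params"` (a named list).
#' @examples
#' p <- ddm_params(a = 1.5, z = 0.66, v = 1, tr = 0.4)
#' p
#' @export
ddm_params <- function(a, z, v, tr, sv = 0, sz = 0, st = 0) {
  stopifnot(length(a) == 1, length(z) == 1, length(v) == 1, length(tr) == 1,
            length(sv) == 1, length(sz) == 1, length(st) == 1)
  vals <- c(a = a, z = z, v = v, tr = tr, sv = sv, sz = sz, st = st)
  if (any(!is.finite(vals)))
    stop("all DDM parameters must be finite", call. = FALSE)
  if (a <= 0) stop("boundary separation 'a' must be > 0", call. = FALSE)
  if (z <= 0 || z >= 1)
    stop("relative starting point 'z' must lie in (0, 1)", call. = FALSE)
  if (sv < 0 || sz < 0 || st < 0)
    stop("variability parameters sv, sz, st must be >= 0", call. = FALSE)
  if (z - sz / 2 <= 0 || z + sz / 2 >= 1)
    stop("starting-point range z +/- sz/2 must stay inside (0, 1)",
         call. = FALSE)
  if (tr < 0) stop("non-decision time 'tr' must be >= 0", call. = FALSE)
  if (tr - st / 2 < 0)
    stop("non-decision-time range requires tr - st/2 >= 0", call. = FALSE)
  structure(as.list(vals), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("DDM parameters (s = 1; upper boundary = face):\n")
  print(unlist(x))
  invisible(x)
}

as_ddm_params <- function(x) {
  if (inherits(x, "ddm_params")) return(x)
  x <- as.list(x)
  do.call(ddm_params, x[c("a", "z", "v", "tr",
                          intersect(names(x), c("sv", "sz", "st")))])
}
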