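# Iterative projection algorithms for holographic phase retrieval.
#
# The two building blocks are the magnitude (data) projector P_M and the
# object-constraint projector P_O; AP, RAAR and mHIO combine them in
# different ways. All operate on the object-plane complex wavefield, with
# the empty beam psi = 1 as the natural background.

#' Object constraints for iterative phase retrieval
#'
#' Bundles the prior knowledge imposed in object space: an optional binary
#' support mask (outside which the field is the empty beam), a phase range,
#' and an amplitude rule: `"free"` leaves the amplitude untouched,
#' `"pure_phase"` forces unit amplitude, `"single_material"` couples the
#' amplitude to the phase via `mu = -2 * beta_delta * phi` (meaningful for
#' the non-positive phases of the package sign convention).
#'
#' @param support logical matrix (TRUE inside the object region) or `NULL`.
#' @param phase_min,phase_max phase range in radians (defaults unbounded).
#' @param amplitude amplitude rule.
#' @param beta_delta `beta/delta` ratio for `amplitude = "single_material"`.
#' @return an object of class `"constraint_set"`.
#' @export
constraint_set <- function(support = NULL, phase_min = -Inf, phase_max = Inf,
                           amplitude = c("free", "pure_phase", "single_material"),
                           beta_delta = 0) {
  amplitude <- match.arg(amplitude)
  if (!is.null(support)) {
    if (!is.matrix(support)) stop("support must be a matrix or NULL")
    support <- support != 0
  }
  if (!(phase_min <= phase_max)) stop("phase_min must be <= phase_max")
  if (amplitude == "single_material" && beta_delta <= 0)
    stop("single_material amplitude rule needs beta_delta > 0")
  structure(list(support = support, phase_min = phase_min,
                 phase_max = phase_max, amplitude = amplitude,
                 beta_delta = beta_delta),
            class = "constraint_set")
}

#' Iteration schedule for the projection algorithms
#'
#' @param n_iter number of iterations (>= 1).
#' @param beta_start,beta_max RAAR relaxation start/end values in `[0, 1]`.
#' @param beta_switch iteration index around which the relaxation ramps
#'   from `beta_start` to `beta_max` (default `n_iter / 2`).
#' @param feedback mHIO feedback strength in `(0, 1]`.
#' @param init `"flat"` (empty beam), `"ctf"` (seed from [phaserec_ctf()]),
#'   or a complex matrix used as the starting field.
#' @return an object of class `"iteration_schedule"`.
#' @export
iteration_schedule <- function(n_iter = 300L, beta_start = 1.0, beta_max = 0.5,
                               beta_switch = NULL, feedback = 0.5,
                               init = "flat") {
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (is.null(beta_switch)) beta_switch <- max(1, n_iter / 2)
  if (beta_switch < 1 || beta_switch > n_iter)
    stop("beta_switch must lie within 1..n_iter")
  if (any(c(beta_start, beta_max) < 0) || any(c(beta_start, beta_max) > 1))
    stop("beta_start and beta_max must lie in [0, 1]")
  if (!(feedback > 0 && feedback <= 1)) stop("feedback must lie in (0, 1]")
  if (!(is.character(init) && init %in% c("flat", "ctf")) && !is.matrix(init))
    stop("init must be 'flat', 'ctf' or a matrix")
  structure(list(n_iter = n_iter, beta_start = beta_start,
                 beta_max = beta_max, beta_switch = beta_switch,
                 feedback = feedback, init = init),
            class = "iteration_schedule")
}

# RAAR relaxation ramp: beta_n decays smoothly from beta_start to beta_max
# around beta_switch.
raar_beta <- function(n, sched) {
  sched$beta_max + (sched$beta_start - sched$beta_max) *
    exp(-(n / sched$beta_switch)^3)
}

#' Magnitude (data) projector
#'
#' Projects an object-plane field onto the measured hologram magnitudes:
#' for each distance the field is propagated forward, its modulus replaced
#' by `sqrt(I_j)` (phase kept; zero-modulus pixels get phase 0), and
#' propagated back; the J single-distance projections are averaged. For
#' `J = 1` this is an exact (idempotent) projector; for `J > 1` the average
#' of projectors is not itself a projector but remains non-expansive.
#'
#' @param psi complex object-plane field.
#' @param stack an aligned [hologram_stack()] (non-negative intensities).
#' @param pad padding policy for the internal propagation.
#' @return projected complex field of the same shape.
#' @export
project_data <- function(psi, stack, pad = c("replicate", "none")) {
  pad <- match.arg(pad)
  stopifnot(inherits(stack, "hologram_stack"))
  assert_image(psi)
  if (any(vapply(stack$images, function(im) any(im < 0), logical(1))))
    stop("negative intensities in stack")
  acc <- matrix(0i, nrow(psi), ncol(psi))
  for (j in seq_along(stack$images)) {
    d <- fresnel_propagate(psi, stack$fresnel_numbers[j], "forward", pad)
    a <- Mod(d)
    ph <- d
    ph[a > 0] <- ph[a > 0] / a[a > 0]
    ph[a == 0] <- 1 + 0i          # tie-break: impose measured amplitude at phase 0
    acc <- acc + fresnel_propagate(sqrt(stack$images[[j]]) * ph,
                                   stack$fresnel_numbers[j], "backward", pad)
  }
  acc / length(stack$images)
}

#' Object-constraint projector
#'
#' Applies a [constraint_set()] to a complex field: the amplitude rule
#' first, then clamping of the (principal-value) phase to the allowed
#' range, then replacement by the empty beam (`psi = 1`) outside the
#' support. Exactly idempotent.
#'
#' @param psi complex field.
#' @param constraints a [constraint_set()].
#' @return constrained complex field.
#' @export
project_object <- function(psi, constraints) {
  stopifnot(inherits(constraints, "constraint_set"))
  assert_image(psi)
  phi <- Arg(psi)
  phi <- pmin(pmax(phi, constraints$phase_min), constraints$phase_max)
  amp <- switch(constraints$amplitude,
    free = Mod(psi),
    pure_phase = 1,
    single_material = exp(constraints$beta_delta * phi))
  out <- amp * exp(1i * phi)
  if (!is.null(constraints$support)) out[!constraints$support] <- 1 + 0i
  out
}

# RMS mismatch between propagated amplitudes and measured ones,
# normalized by the total measured energy.
data_residual <- function(psi, stack, pad) {
  num <- 0; den <- 0
  for (j in seq_along(stack$images)) {
    a <- Mod(fresnel_propagate(psi, stack$fresnel_numbers[j], "forward", pad))
    num <- num + sum((a - sqrt(stack$images[[j]]))^2)
    den <- den + sum(stack$images[[j]])
  }
  sqrt(num / den)
}

init_field <- function(stack, schedule, constraints) {
  sh <- dim(stack$images[[1]])
  if (is.matrix(schedule$init)) {
    if (!all(dim(schedule$init) == sh)) stop("init field shape mismatch")
    return(schedule$init + 0i)
  }
  if (identical(schedule$init, "ctf")) {
    bd <- if (!is.null(constraints) && constraints$amplitude == "single_material")
      constraints$beta_delta else 0
    phi0 <- phaserec_ctf(stack, beta_delta = bd)
    return(exp(bd * pmin(phi0, 0) + 1i * phi0))
  }
  matrix(1 + 0i, sh[1], sh[2])
}

iterate_engine <- function(stack, constraints, schedule, pad, update) {
  stopifnot(inherits(stack, "hologram_stack"),
            inherits(schedule, "iteration_schedule"))
  if (!is.null(constraints)) stopifnot(inherits(constraints, "constraint_set"))
  psi <- init_field(stack, schedule, constraints)
  res <- numeric(schedule$n_iter)
  for (n in seq_len(schedule$n_iter)) {
    psi <- update(psi, n)
    res[n] <- data_residual(psi, stack, pad)
    if (n > 1L && res[n] > 10 * max(res[1], 1e-12)) {
      warning(sprintf("divergence guard triggered at iteration %d", n))
      res <- res[seq_len(n)]
      break
    }
  }
  phi <- Arg(psi)
  amp <- Mod(psi)
  mu <- -2 * log(pmax(amp, 1e-12))
  list(phi = phi, mu = mu, residuals = res, psi = psi)
}

#' Iterative holographic phase retrieval
#'
#' Three projection algorithms built from the magnitude projector `P_M`
#' ([project_data()]) and the object projector `P_O` ([project_object()]):
#'
#' * `iterate_ap()`: alternating projections, `psi <- P_O P_M psi`.
#' * `iterate_raar()`: relaxed averaged alternating reflections,
#'   `psi <- (beta_n/2) (R_O R_M + Id) psi + (1 - beta_n) P_M psi` with
#'   reflectors `R = 2 P - Id`; the relaxation `beta_n` ramps from
#'   `beta_start` to `beta_max` around `beta_switch`. With `beta = 1` this
#'   is averaged alternating reflections, with `beta = 0` pure `P_M`.
#' * `iterate_mhio()`: a near-field modified hybrid input-output; inside
#'   the support the constrained magnitude projection is accepted,
#'   `psi <- P_O' P_M psi` (amplitude/phase-range rules of the constraint
#'   set), while outside the support negative feedback drives the field
#'   towards the empty beam, `psi <- psi - feedback * (P_M psi - 1)`.
#'   A support mask is required.
#'
#' All three record the normalized RMS amplitude mismatch per iteration and
#' abort (with a warning) if it exceeds 10 times its initial value.
#'
#' @param stack an aligned [hologram_stack()].
#' @param constraints a [constraint_set()]; `iterate_ap` and `iterate_raar`
#'   accept `NULL` (data projection only), `iterate_mhio` requires a
#'   support.
#' @param schedule an [iteration_schedule()].
#' @param pad padding policy for the internal propagations.
#' @return list with `phi` (principal-value phase, radians), `mu`
#'   (`-2 log |psi|`), `residuals` (one per executed iteration) and the
#'   final complex field `psi`. No phase unwrapping is performed: objects
#'   with `|phi| > pi` need range constraints to resolve the ambiguity.
#' @export
iterate_ap <- function(stack, constraints = NULL, schedule = iteration_schedule(),
                       pad = c("replicate", "none")) {
  pad <- match.arg(pad)
  po <- if (is.null(constraints)) identity else
    function(x) project_object(x, constraints)
  iterate_engine(stack, constraints, schedule, pad,
                 function(psi, n) po(project_data(psi, stack, pad)))
}

#' @rdname iterate_ap
#' @export
iterate_raar <- function(stack, constraints = NULL,
                         schedule = iteration_schedule(),
                         pad = c("replicate", "none")) {
  pad <- match.arg(pad)
  po <- if (is.null(constraints)) identity else
    function(x) project_object(x, constraints)
  iterate_engine(stack, constraints, schedule, pad, function(psi, n) {
    beta <- raar_beta(n, schedule)
    pm <- project_data(psi, stack, pad)
    rm_ <- 2 * pm - psi
    ro <- 2 * po(rm_) - rm_
    (beta / 2) * (ro + psi) + (1 - beta) * pm
  })
}

#' @rdname iterate_ap
#' @export
iterate_mhio <- function(stack, constraints, schedule = iteration_schedule(),
                         pad = c("replicate", "none")) {
  pad <- match.arg(pad)
  if (is.null(constraints) || is.null(constraints$support))
    stop("mHIO requires a support constraint")
  inside <- constraints$support
  # amplitude/phase rules applied inside the support only
  cs_in <- constraint_set(support = NULL, phase_min = constraints$phase_min,
                          phase_max = constraints$phase_max,
                          amplitude = constraints$amplitude,
                          beta_delta = max(constraints$beta_delta,
                                           if (constraints$amplitude == "single_material") 1e-12 else 0))
  iterate_engine(stack, constraints, schedule, pad, function(psi, n) {
    pm <- project_data(psi, stack, pad)
    out <- psi - schedule$feedback * (pm - 1)
    pin <- project_object(pm, cs_in)
    out[inside] <- pin[inside]
    out
  })
}
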