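#' @useDynLib localsampler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Candidate generative models
#'
#' The eight sequence generators compared by the package: independent
#' sampling (\code{iid}), a schema-based generator (\code{schema}), and six
#' local samplers built by adding three qualitative features to a
#' Metropolis-Hastings base in a semi-factorial design: multiple tempered
#' chains (\code{MC3}), gradient-based Hamiltonian proposals (\code{HMC}),
#' and partial momentum recycling (\code{REC}); \code{MCHMC} and
#' \code{MCREC} are the multi-chain versions of \code{HMC} and \code{REC}.
#' @export
MODELS <- c("iid", "schema", "MH", "MC3", "HMC", "REC", "MCHMC", "MCREC")

#' @rdname MODELS
#' @export
LOCAL_MODELS <- c("MH", "MC3", "HMC", "REC", "MCHMC", "MCREC")

model_features <- function(model_id) {
  switch(model_id,
    MH    = list(gradient = FALSE, chains = FALSE, recycle = FALSE),
    MC3   = list(gradient = FALSE, chains = TRUE,  recycle = FALSE),
    HMC   = list(gradient = TRUE,  chains = FALSE, recycle = FALSE),
    REC   = list(gradient = TRUE,  chains = FALSE, recycle = TRUE),
    MCHMC = list(gradient = TRUE,  chains = TRUE,  recycle = FALSE),
    MCREC = list(gradient = TRUE,  chains = TRUE,  recycle = TRUE),
    stop("unknown model_id: ", model_id, call. = FALSE))
}

# Number of leapfrog steps per Hamiltonian proposal (fixed, not inferred).
HMC_LEAPFROG_STEPS <- 10L

#' Uniform parameter priors
#'
#' Each sampler parameter has an independent uniform prior. Scale parameters
#' are expressed relative to the domain width W (six standard deviations for
#' the unbounded Gaussian family): proposal noise \code{sigma} ~ U(0.005 W,
#' 0.5 W); leapfrog step size \code{eps} ~ U(0.005 W, 0.3 W) with 10 leapfrog
#' steps; momentum scale \code{psd} ~ U(0.5, 2); recycling coefficient
#' \code{alpha} ~ U(0, 0.99); chain count \code{C} uniform on \{2,...,6\};
#' temperature spacing \code{Delta} ~ U(0.1, 5); swap probability \code{s} ~
#' U(0, 1). The schema generator has six selection weights (a uniform draw
#' on the simplex) and a persistence probability \code{rho} ~ U(0, 1).
#'
#' @param model_id one of \code{MODELS}.
#' @param domain the target \code{rg_domain} (sets the width scale).
#' @return named list of parameter ranges; discrete parameters give their
#'   value set.
#' @export
param_prior <- function(model_id, domain) {
  W <- domain_width(domain)
  f <- if (model_id %in% LOCAL_MODELS) model_features(model_id) else NULL
  pr <- list()
  if (model_id == "schema") {
    pr$weights <- "uniform simplex (6 schemas)"
    pr$rho <- c(0, 1)
    return(pr)
  }
  if (model_id == "iid") return(pr)
  if (!f$gradient) pr$sigma <- c(0.005 * W, 0.5 * W)
  if (f$gradient) {
    pr$eps <- c(0.005 * W, 0.3 * W)
    pr$psd <- c(0.5, 2)
  }
  if (f$recycle) pr$alpha <- c(0, 0.99)
  if (f$chains) {
    pr$C <- 2:6
    pr$Delta <- c(0.1, 5)
    pr$s <- c(0, 1)
  }
  pr
}

#' Draw model parameters from their prior
#'
#' Independent uniform draw for every parameter of \code{model_id} (see
#' \code{\link{param_prior}} for the ranges).
#'
#' @inheritParams param_prior
#' @return named list of parameter values (empty for \code{iid}).
#' @export
draw_params_from_prior <- function(model_id, domain) {
  pr <- param_prior(model_id, domain)
  if (model_id == "iid") return(list())
  if (model_id == "schema") {
    w <- stats::runif(6)
    return(list(weights = w / sum(w), rho = stats::runif(1, 0, 1)))
  }
  out <- list()
  for (nm in names(pr)) {
    out[[nm]] <- if (nm == "C") sample(pr$C, 1L)
                 else stats::runif(1, pr[[nm]][1], pr[[nm]][2])
  }
  out
}

# Parameters at the middle of their prior range (used for diagnostics).
midrange_params <- function(model_id, domain) {
  pr <- param_prior(model_id, domain)
  if (model_id %in% c("iid", "schema")) return(list())
  out <- list()
  for (nm in names(pr))
    out[[nm]] <- if (nm == "C") 3L else mean(pr[[nm]])
  out
}

domain_cspec <- function(domain) {
  switch(domain$family,
    gaussian = list(family = 0L, p1 = domain$params$mean,
                    p2 = domain$params$sd, lo = -Inf, hi = Inf, dim = 1L),
    scaled_beta = list(family = 1L, p1 = domain$params$alpha,
                       p2 = domain$params$beta, lo = domain$params$lo,
                       hi = domain$params$hi, dim = 1L),
    discrete_uniform = {
      if (domain$dim == 2L)
        list(family = 3L, p1 = 0, p2 = 0, lo = 0, hi = 0, dim = 2L,
             poly = hex7_hull())
      else
        list(family = 2L, p1 = 0, p2 = 0, lo = domain$support[1],
             hi = domain$support[2], dim = 1L)
    })
}

#' One leapfrog trajectory
#'
#' Exposes the integrator used by the Hamiltonian samplers: half-step
#' momentum, full-step position, half-step momentum, repeated \code{L}
#' times, with reflection (and momentum negation along the boundary normal)
#' at finite support boundaries. The Hamiltonian is
#' \eqn{-\log p(x)/T + |p|^2/(2 m)}.
#'
#' @param domain an \code{rg_domain}.
#' @param x,p starting position and momentum.
#' @param eps step size (> 0).
#' @param L number of leapfrog steps (>= 1).
#' @param temp chain temperature (1 = the target itself).
#' @param mass particle mass (momentum scale squared).
#' @return list with elements \code{position} and \code{momentum}.
#' @export
leapfrog <- function(domain, x, p, eps, L = 1L, temp = 1, mass = 1) {
  stopifnot(eps > 0, L >= 1)
  leapfrog_cpp(domain_cspec(domain), as.numeric(x), as.numeric(p),
               eps, as.integer(L), temp, mass)
}

# Schema generator: applies one of six transformation rules to the previous
# item -- +1, -1, +2, -2 grid steps, repeat, or a uniform random jump --
# keeping the active rule with persistence probability rho, otherwise
# redrawing it by weight. Results beyond the response range reflect back in.
run_schema <- function(domain, params, n_emit, burnin) {
  if (domain$dim == 2L)
    stop("the schema model cannot sample in two-dimensional domains",
         call. = FALSE)
  grid <- domain_grid(domain)
  n <- length(grid)
  w <- params$weights
  rho <- params$rho
  reflect_idx <- function(i) {
    while (i < 1L || i > n) i <- if (i < 1L) 2L - i else 2L * n - i
    i
  }
  i <- (n + 1L) %/% 2L
  sch <- sample.int(6L, 1L, prob = w)
  total <- burnin + n_emit
  out <- integer(total)
  for (t in seq_len(total)) {
    if (stats::runif(1) >= rho) sch <- sample.int(6L, 1L, prob = w)
    i <- switch(sch,
      reflect_idx(i + 1L),  # +1
      reflect_idx(i - 1L),  # -1
      reflect_idx(i + 2L),  # +2
      reflect_idx(i - 2L),  # -2
      i,                    # repeat
      sample.int(n, 1L))    # random jump
    out[t] <- i
  }
  grid[out[(burnin + 1L):total]]
}

run_iid <- function(domain, n) {
  u <- stats::runif(n)
  switch(domain$family,
    gaussian = stats::qnorm(u, domain$params$mean, domain$params$sd),
    scaled_beta = {
      p <- domain$params
      p$lo + (p$hi - p$lo) * stats::qbeta(u, p$alpha, p$beta)
    },
    discrete_uniform = pmin(floor(u * domain$params$K) + 1L, domain$params$K))
}

#' Generate a response sequence from a candidate model
#'
#' Runs the generator for 50 unemitted burn-in iterations, then emits one
#' rounded response per iteration; rejected MCMC proposals therefore emit
#' repetitions, as a participant who stays put utters the same item again.
#'
#' @param model_id one of \code{MODELS}.
#' @param domain the target \code{rg_domain}.
#' @param length number of emitted responses (>= 2; the model-comparison
#'   simulations use 400).
#' @param params named parameter list; drawn from the prior when \code{NULL}.
#' @param seed integer seed; when given, the sequence is reproducible
#'   byte-for-byte.
#' @param burnin unemitted initial iterations.
#' @param keep_states also keep the continuous pre-rounding chain states
#'   (MCMC and iid models; used by stationarity diagnostics).
#' @param negate_on_reject negate the momentum when a Hamiltonian proposal is
#'   rejected (the textbook partial-refreshment convention). The default
#'   \code{FALSE} keeps the momentum, so movement direction is maintained
#'   across rejected proposals.
#' @return an \code{rg_sequence}: responses, domain, model, parameters, seed.
#' @export
generate_sequence <- function(model_id, domain, length = 400L, params = NULL,
                              seed = NULL, burnin = 50L, keep_states = FALSE,
                              negate_on_reject = FALSE) {
  if (!model_id %in% MODELS)
    stop("unknown model_id: ", model_id, call. = FALSE)
  stopifnot(length >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- draw_params_from_prior(model_id, domain)
  states <- NULL
  if (model_id == "iid") {
    x <- run_iid(domain, burnin + length)
    x <- x[(burnin + 1L):(burnin + length)]
    responses <- if (domain$family == "discrete_uniform") as.integer(x)
                 else round_to_grid(domain, x)
    states <- x
  } else if (model_id == "schema") {
    responses <- run_schema(domain, params, length, burnin)
  } else {
    f <- model_features(model_id)
    st <- run_chain_cpp(domain_cspec(domain),
                        start = as.numeric(domain_start(domain)),
                        use_gradient = f$gradient,
                        sigma = if (is.null(params$sigma)) 0 else params$sigma,
                        eps = if (is.null(params$eps)) 0 else params$eps,
                        L = HMC_LEAPFROG_STEPS,
                        psd = if (is.null(params$psd)) 1 else params$psd,
                        alpha = if (f$recycle) params$alpha else 0,
                        C = if (f$chains) as.integer(params$C) else 1L,
                        Delta = if (is.null(params$Delta)) 0 else params$Delta,
                        s = if (is.null(params$s)) 0 else params$s,
                        n_emit = as.integer(length),
                        burnin = as.integer(burnin),
                        negate_on_reject = negate_on_reject)
    responses <- round_to_grid(domain, if (domain$dim == 2L) st else st[, 1])
    states <- if (domain$dim == 2L) st else st[, 1]
  }
  structure(list(responses = responses, domain = domain, model = model_id,
                 params = params, seed = seed,
                 states = if (keep_states) states else NULL,
                 meta = list()),
            class = "rg_sequence")
}

#' @export
print.rg_sequence <- function(x, ...) {
  cat("<rg_sequence>", x$model, "n =", length(x$responses),
      "on", x$domain$family, "\n")
  invisible(x)
}

# Response coordinates as an n x d matrix (layout items mapped to their
# spatial positions).
seq_coords <- function(seq) {
  d <- seq$domain
  if (d$family == "discrete_uniform") {
    pos <- d$layout$positions
    if (d$dim == 2L) pos[seq$responses, , drop = FALSE]
    else matrix(pos[seq$responses, 1], ncol = 1)
  } else {
    matrix(seq$responses, ncol = 1)
  }
}

#' Small-transitions independent sampler
#'
#' An independent sampler modified to never move more than \code{max_sd}
#' target standard deviations from the previous item: each draw is resampled
#' from the target until it lies within that distance. Used to show that
#' small steps alone depress the global turning-point rate while leaving
#' turns at the centre of the distribution near 50\%.
#'
#' @param domain a continuous \code{rg_domain}.
#' @param length emitted responses.
#' @param max_sd maximum allowed jump, in target standard deviations.
#' @param seed optional integer seed.
#' @return an \code{rg_sequence} with model \code{"iid_small"}.
#' @export
small_transition_sequence <- function(domain, length = 150L, max_sd = 1,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd_target <- switch(domain$family,
    gaussian = domain$params$sd,
    scaled_beta = {
      p <- domain$params
      (p$hi - p$lo) * sqrt(p$alpha * p$beta /
        ((p$alpha + p$beta)^2 * (p$alpha + p$beta + 1)))
    },
    stop("small-transitions sampler needs a continuous domain", call. = FALSE))
  lim <- max_sd * sd_target
  x <- numeric(length)
  x[1] <- run_iid(domain, 1L)
  for (i in 2:length) {
    repeat {
      cand <- run_iid(domain, 1L)
      if (abs(cand - x[i - 1]) <= lim) break
    }
    x[i] <- cand
  }
  structure(list(responses = round_to_grid(domain, x), domain = domain,
                 model = "iid_small", params = list(max_sd = max_sd),
                 seed = seed, states = x, meta = list()),
            class = "rg_sequence")
}
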