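#' Target distributions and response layouts
#'
#' A domain bundles the density a generator must reproduce with the grid on
#' which responses are uttered. Three families are supported:
#' \describe{
#'   \item{\code{gaussian}}{heights in cm, \code{mean} and \code{sd}; responses
#'     on an integer-cm grid.}
#'   \item{\code{scaled_beta}}{a Beta(\code{alpha}, \code{beta}) density
#'     rescaled to the closed interval \code{[lo, hi]} (cm); integer-cm grid.}
#'   \item{\code{discrete_uniform}}{\code{K} equally likely items arranged on a
#'     spatial layout (\code{"line7"} or \code{"hex7"}). Continuous samplers
#'     move on the convex hull of the item coordinates under a flat density and
#'     responses are produced by nearest-item rounding.}
#' }
#'
#' @param family one of \code{"gaussian"}, \code{"scaled_beta"},
#'   \code{"discrete_uniform"}.
#' @param mean,sd Gaussian parameters (cm).
#' @param alpha,beta,lo,hi scaled-Beta shape parameters and support ends (cm).
#' @param layout layout name for \code{discrete_uniform}: \code{"line7"} or
#'   \code{"hex7"}.
#' @param grid_step response resolution; 1 cm for heights, 1 item for layouts.
#' @return an object of class \code{rg_domain}.
#' @examples
#' d <- make_domain("gaussian", mean = 176.4, sd = 12)
#' log_density(d, 176.4)
#' @export
make_domain <- function(family = c("gaussian", "scaled_beta", "discrete_uniform"),
                        mean = NULL, sd = NULL,
                        alpha = NULL, beta = NULL, lo = NULL, hi = NULL,
                        layout = NULL, grid_step = 1) {
  family <- match.arg(family)
  dom <- switch(family,
    gaussian = {
      if (is.null(mean) || !is.finite(mean))
        stop("invalid parameter 'mean' for gaussian domain", call. = FALSE)
      if (is.null(sd) || !is.finite(sd) || sd <= 0)
        stop("invalid parameter 'sd' for gaussian domain: must be > 0", call. = FALSE)
      list(family = family, params = list(mean = mean, sd = sd),
           support = c(-Inf, Inf), dim = 1L, grid_step = grid_step,
           layout = NULL)
    },
    scaled_beta = {
      if (is.null(alpha) || !is.finite(alpha) || alpha <= 0)
        stop("invalid parameter 'alpha' for scaled_beta domain: must be > 0", call. = FALSE)
      if (is.null(beta) || !is.finite(beta) || beta <= 0)
        stop("invalid parameter 'beta' for scaled_beta domain: must be > 0", call. = FALSE)
      if (is.null(lo) || is.null(hi) || !is.finite(lo) || !is.finite(hi) || lo >= hi)
        stop("invalid parameters 'lo'/'hi' for scaled_beta domain: need lo < hi", call. = FALSE)
      list(family = family,
           params = list(alpha = alpha, beta = beta, lo = lo, hi = hi),
           support = c(lo, hi), dim = 1L, grid_step = grid_step,
           layout = NULL)
    },
    discrete_uniform = {
      if (is.null(layout)) layout <- "line7"
      lay <- if (inherits(layout, "rg_layout")) layout else make_layout(layout)
      K <- nrow(lay$positions)
      if (K < 2L)
        stop("invalid parameter 'layout': need K >= 2 items", call. = FALSE)
      list(family = family, params = list(K = K),
           support = if (lay$kind == "line7") range(lay$positions[, 1]) else NULL,
           dim = if (lay$kind == "hex7") 2L else 1L, grid_step = 1,
           layout = lay)
    })
  class(dom) <- "rg_domain"
  dom
}

#' @export
print.rg_domain <- function(x, ...) {
  cat("<rg_domain>", x$family,
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      if (!is.null(x$layout)) paste0("layout=", x$layout$kind), "\n")
  invisible(x)
}

#' Spatial response layouts
#'
#' \code{line7} places seven items at (1,0)...(7,0). \code{hex7} places seven
#' hexagons in rows of two, three and two (vertex-up hexes), with every pair
#' of touching hexes exactly one unit apart; the middle item of the middle
#' row is the centre and has six unit-distance neighbours, the corner items
#' three each.
#'
#' @param kind \code{"line7"} or \code{"hex7"}.
#' @return an \code{rg_layout}: item positions, unit-distance adjacency pairs,
#'   and the central item set used by the turns-at-centre analysis
#'   (\{3,4,5\} for the line, the centre hex for the grid).
#' @export
make_layout <- function(kind = c("line7", "hex7")) {
  kind <- match.arg(kind)
  if (kind == "line7") {
    pos <- cbind(x = 1:7, y = rep(0, 7))
    center <- 3:5
  } else {
    h <- sqrt(3) / 2
    pos <- cbind(x = c(-0.5, 0.5, -1, 0, 1, -0.5, 0.5),
                 y = c(h, h, 0, 0, 0, -h, -h))
    center <- 4L
  }
  rownames(pos) <- as.character(1:7)
  d <- as.matrix(stats::dist(pos))
  adj <- which(abs(d - 1) < 1e-9 & upper.tri(d), arr.ind = TRUE)
  structure(list(kind = kind, positions = pos,
                 adjacency = unname(adj), center_items = center),
            class = "rg_layout")
}

# Convex hull vertices of the hex7 item centres, counter-clockwise.
hex7_hull <- function() {
  h <- sqrt(3) / 2
  cbind(x = c(1, 0.5, -0.5, -1, -0.5, 0.5),
        y = c(0, h, h, 0, -h, -h))
}

point_in_hull <- function(xy, poly) {
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (xy[2] - a[2]) - (b[2] - a[2]) * (xy[1] - a[1])
    if (cr < -1e-12) return(FALSE)
  }
  TRUE
}

hull_area <- function(poly) {
  n <- nrow(poly); j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Log density of a target distribution
#'
#' Returns the (normalised) log density at \code{x}; positions outside the
#' support return \code{-Inf} rather than raising an error. For discrete
#' layouts this is the flat density over the continuous convex hull of the
#' item coordinates on which the samplers move.
#'
#' @param domain an \code{rg_domain}.
#' @param x a position: scalar for 1-D families, length-2 vector for
#'   \code{hex7}.
#' @return finite log density inside the support, \code{-Inf} outside.
#' @export
log_density <- function(domain, x) {
  switch(domain$family,
    gaussian = stats::dnorm(x, domain$params$mean, domain$params$sd, log = TRUE),
    scaled_beta = {
      p <- domain$params
      if (x <= p$lo || x >= p$hi) return(-Inf)
      z <- (x - p$lo) / (p$hi - p$lo)
      stats::dbeta(z, p$alpha, p$beta, log = TRUE) - log(p$hi - p$lo)
    },
    discrete_uniform = {
      if (domain$dim == 2L) {
        if (point_in_hull(x, hex7_hull())) -log(hull_area(hex7_hull())) else -Inf
      } else {
        s <- domain$support
        if (x < s[1] || x > s[2]) -Inf else -log(s[2] - s[1])
      }
    })
}

#' Gradient of the log density
#'
#' Analytic gradient inside the open support; the flat families (uniform
#' hulls, Beta(1,1)) have an identically zero gradient. Evaluation at or
#' beyond a finite boundary is an error: samplers reflect before calling.
#'
#' @inheritParams log_density
#' @return gradient vector (length = domain dimension).
#' @export
grad_log_density <- function(domain, x) {
  switch(domain$family,
    gaussian = (domain$params$mean - x) / domain$params$sd^2,
    scaled_beta = {
      p <- domain$params
      if (x <= p$lo || x >= p$hi)
        stop("gradient requested at or beyond the support boundary", call. = FALSE)
      z <- (x - p$lo) / (p$hi - p$lo)
      ((p$alpha - 1) / z - (p$beta - 1) / (1 - z)) / (p$hi - p$lo)
    },
    discrete_uniform = {
      if (domain$dim == 2L) {
        if (!point_in_hull(x, hex7_hull()))
          stop("gradient requested at or beyond the support boundary", call. = FALSE)
        c(0, 0)
      } else {
        s <- domain$support
        if (x <= s[1] || x >= s[2])
          stop("gradient requested at or beyond the support boundary", call. = FALSE)
        0
      }
    })
}

#' Round continuous positions to the response grid
#'
#' Heights are rounded to the nearest integer cm; layout positions to the
#' nearest item (Euclidean distance). Exact ties break toward the smaller
#' value (smaller item index), deterministically.
#'
#' @param domain an \code{rg_domain}.
#' @param x numeric vector of positions (or an n-by-2 matrix for
#'   \code{hex7}).
#' @return response values: integers (cm) or item indices.
#' @export
round_to_grid <- function(domain, x) {
  if (domain$family == "discrete_uniform") {
    pos <- domain$layout$positions
    if (domain$dim == 2L) {
      x <- matrix(x, ncol = 2)
      apply(x, 1, function(p) {
        d2 <- (pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2
        which.min(d2 + seq_len(nrow(pos)) * 1e-12) # tie -> smaller index
      })
    } else {
      pmin(pmax(ceiling(x - 0.5), 1L), nrow(pos))
    }
  } else {
    # nearest integer cm, ties toward the smaller value
    ceiling(x - 0.5)
  }
}

#' Central region membership
#'
#' The turns-at-centre analysis restricts turning points to transitions whose
#' origin lies in the centre of the domain: the 37.5--62.5 percentile window
#' of the target distribution for continuous families (25\% of the mass),
#' items \{3,4,5\} for \code{line7}, and the centre hex for \code{hex7}.
#'
#' @param domain an \code{rg_domain}.
#' @param responses response values (integer cm or item indices).
#' @param percentiles window bounds for continuous families; the default is
#'   the central quarter of the mass.
#' @param empirical if \code{TRUE}, compute the percentile window from the
#'   responses themselves instead of from the target distribution.
#' @return logical vector, \code{TRUE} where the response is central.
#' @export
central_region <- function(domain, responses, percentiles = c(0.375, 0.625),
                           empirical = FALSE) {
  if (domain$family == "discrete_uniform") {
    responses %in% domain$layout$center_items
  } else {
    q <- if (empirical) {
      stats::quantile(responses, percentiles, names = FALSE, type = 7)
    } else if (domain$family == "gaussian") {
      stats::qnorm(percentiles, domain$params$mean, domain$params$sd)
    } else {
      p <- domain$params
      p$lo + (p$hi - p$lo) * stats::qbeta(percentiles, p$alpha, p$beta)
    }
    responses >= q[1] & responses <= q[2]
  }
}

#' Serialize / deserialize domain specifications
#'
#' Domains round-trip through a small JSON object, e.g.
#' \code{{"family":"gaussian","mean":176.4,"sd":12,"grid":1}}.
#'
#' @param domain an \code{rg_domain}.
#' @return \code{domain_to_json}: a JSON string; \code{domain_from_json}: an
#'   \code{rg_domain}.
#' @export
domain_to_json <- function(domain) {
  spec <- switch(domain$family,
    gaussian = list(family = "gaussian", mean = domain$params$mean,
                    sd = domain$params$sd, grid = domain$grid_step),
    scaled_beta = list(family = "scaled_beta", alpha = domain$params$alpha,
                       beta = domain$params$beta, lo = domain$params$lo,
                       hi = domain$params$hi, grid = domain$grid_step),
    discrete_uniform = list(family = "discrete_uniform",
                            layout = domain$layout$kind))
  jsonlite::toJSON(spec, auto_unbox = TRUE)
}

#' @rdname domain_to_json
#' @param json a JSON string produced by \code{domain_to_json}.
#' @export
domain_from_json <- function(json) {
  s <- jsonlite::fromJSON(json)
  switch(s$family,
    gaussian = make_domain("gaussian", mean = s$mean, sd = s$sd,
                           grid_step = s$grid),
    scaled_beta = make_domain("scaled_beta", alpha = s$alpha, beta = s$beta,
                              lo = s$lo, hi = s$hi, grid_step = s$grid),
    discrete_uniform = make_domain("discrete_uniform", layout = s$layout),
    stop("unknown domain family in JSON: ", s$family, call. = FALSE))
}

# Effective support width used to scale proposal/step-size priors.
# Gaussian support is unbounded; six standard deviations cover essentially
# all its mass and play the role of the width.
domain_width <- function(domain) {
  switch(domain$family,
    gaussian = 6 * domain$params$sd,
    scaled_beta = diff(domain$support),
    discrete_uniform = if (domain$dim == 2L) 2 else diff(domain$support))
}

# Starting position for chains: the centre of the domain.
domain_start <- function(domain) {
  switch(domain$family,
    gaussian = domain$params$mean,
    scaled_beta = mean(domain$support),
    discrete_uniform = if (domain$dim == 2L) c(0, 0) else mean(domain$support))
}

# Integer response grid of a 1-D domain (used by the schema generator and
# file validation). The gaussian family has unbounded support; the grid is
# truncated to the central 99.98% of the mass, mirroring the finite range
# of responses people actually produce.
domain_grid <- function(domain) {
  switch(domain$family,
    gaussian = {
      lo <- round(stats::qnorm(1e-4, domain$params$mean, domain$params$sd))
      hi <- round(stats::qnorm(1 - 1e-4, domain$params$mean, domain$params$sd))
      seq.int(lo, hi)
    },
    scaled_beta = seq.int(ceiling(domain$support[1]), floor(domain$support[2])),
    discrete_uniform = seq_len(domain$params$K))
}
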