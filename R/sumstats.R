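#' Randomness indices for response sequences
#'
#' The measurement layer shared by recorded-format data and simulations:
#' proportions of repetitions, adjacencies and turning points, mean step
#' distance, turns restricted to the centre of the domain, the Shape
#' statistic, and permutation ("reshuffle") null expectations.
#'
#' @name sumstats
NULL

resp_values <- function(seq) {
  if (inherits(seq, "rg_sequence")) seq$responses else seq
}

#' Proportion of repeated transitions
#'
#' The fraction of transitions in which the new item repeats the previous
#' one, over the full (unstripped) sequence.
#'
#' @param seq an \code{rg_sequence} or a response vector.
#' @return proportion in [0, 1].
#' @export
repetitions <- function(seq) {
  x <- resp_values(seq)
  stopifnot(length(x) >= 2)
  mean(x[-1] == x[-length(x)])
}

#' Collapse runs of consecutive repeats
#'
#' Removes every response that repeats the one immediately before it, so
#' that runs of identical items collapse to a single occurrence. The
#' direction-based indices are computed on the stripped sequence.
#'
#' @param seq an \code{rg_sequence} or a response vector.
#' @return same type as the input, with consecutive repeats collapsed.
#' @export
strip_repeats <- function(seq) {
  x <- resp_values(seq)
  keep <- c(TRUE, x[-1] != x[-length(x)])
  if (inherits(seq, "rg_sequence")) {
    seq$responses <- x[keep]
    seq$states <- NULL
    seq
  } else {
    x[keep]
  }
}

seq_or_coords <- function(seq, domain = NULL) {
  if (inherits(seq, "rg_sequence")) seq_coords(seq)
  else if (is.matrix(seq)) seq
  else matrix(seq, ncol = 1)
}

#' Proportion of unit-distance transitions
#'
#' The fraction of transitions (after repeat stripping) whose Euclidean step
#' length equals one grid unit: 1 cm for heights, 1 layout unit for item
#' displays.
#'
#' @param seq a repeat-stripped \code{rg_sequence}, response vector, or
#'   coordinate matrix.
#' @param unit the adjacency distance (default 1).
#' @return proportion in [0, 1], or \code{NA} if fewer than 2 responses.
#' @export
adjacencies <- function(seq, unit = 1) {
  xy <- seq_or_coords(seq)
  n <- nrow(xy)
  if (n < 2) return(NA_real_)
  d <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-n, , drop = FALSE])^2))
  mean(abs(d - unit) < 1e-9)
}

#' Mean Euclidean step length
#'
#' @inheritParams adjacencies
#' @return mean transition distance (domain units), or \code{NA} if fewer
#'   than 2 responses.
#' @export
distances <- function(seq) {
  xy <- seq_or_coords(seq)
  n <- nrow(xy)
  if (n < 2) return(NA_real_)
  mean(sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-n, , drop = FALSE])^2)))
}

turn_indicator <- function(xy) {
  n <- nrow(xy)
  d <- xy[-1, , drop = FALSE] - xy[-n, , drop = FALSE]
  # turn iff the angle between consecutive displacements exceeds 90 degrees;
  # in one dimension this is exactly a sign change of the step
  rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE]) < 0
}

#' Proportion of turning points
#'
#' A transition is a turn when it does not follow the previous direction: a
#' sign change of the step in one dimension, an absolute direction change
#' greater than 90 degrees in two. Computed on the repeat-stripped sequence;
#' the denominator is the number of transitions with a defined previous
#' direction.
#'
#' @inheritParams adjacencies
#' @return proportion in [0, 1], or \code{NA} if fewer than 3 responses.
#' @export
turning_points <- function(seq) {
  xy <- seq_or_coords(seq)
  if (nrow(xy) < 3) return(NA_real_)
  mean(turn_indicator(xy))
}

#' Turning points at the centre of the domain
#'
#' As \code{\link{turning_points}}, but counting only transitions whose
#' origin (the middle item of the triple) lies in the central region of the
#' domain -- see \code{\link{central_region}}. At the centre, boundaries and
#' uneven mass exert no pull, so independent sampling and standard local
#' samplers both predict about 50\% turns there.
#'
#' @param seq a repeat-stripped \code{rg_sequence}, response vector, or
#'   coordinate matrix.
#' @param domain the target \code{rg_domain} (taken from the sequence when
#'   available).
#' @param empirical compute the percentile window from the sequence itself
#'   rather than from the target distribution (continuous domains only).
#' @return proportion in [0, 1]; \code{NA} when no transition qualifies.
#' @export
central_turning_points <- function(seq, domain = NULL, empirical = FALSE) {
  if (inherits(seq, "rg_sequence") && is.null(domain)) domain <- seq$domain
  if (is.null(domain)) stop("a domain is required", call. = FALSE)
  xy <- seq_or_coords(seq, domain)
  if (nrow(xy) < 3) return(NA_real_)
  x <- resp_values(seq)
  central <- central_region(domain, x, empirical = empirical)
  origin_central <- central[2:(nrow(xy) - 1)]
  if (!any(origin_central)) return(NA_real_)
  mean(turn_indicator(xy)[origin_central])
}

#' Shape statistic
#'
#' The mean difference between the log densities of the best-fitting
#' Gaussian and the best-fitting uniform distribution over the sequence:
#' \deqn{S = \frac{1}{N} \sum_{n=1}^{N} [lpdf_G(x_n) - lpdf_U(x_n)].}
#' The Gaussian fit is the maximum-likelihood one (sample mean, population
#' standard deviation); the uniform fit spans the observed range
#' [min(x), max(x)]. Positive values mean the sequence is better described
#' by a Gaussian than by a uniform distribution. Repeats are \emph{not}
#' removed first, and the statistic is invariant to reordering.
#'
#' @param seq an \code{rg_sequence} or a 1-D response vector (at least two
#'   distinct values).
#' @return the Shape value S.
#' @export
shape_stat <- function(seq) {
  x <- resp_values(seq)
  stopifnot(length(x) >= 2)
  if (length(unique(x)) < 2)
    stop("shape is undefined for a constant sequence (degenerate fits)",
         call. = FALSE)
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  lpdf_g <- stats::dnorm(x, mu, sdev, log = TRUE)
  lpdf_u <- -log(max(x) - min(x))
  mean(lpdf_g - lpdf_u)
}

#' Bundle all indices for one sequence
#'
#' Computes repetitions on the full sequence; adjacencies, turning points,
#' central turning points and distances after repeat stripping; and Shape on
#' the full sequence. Indices that are undefined for the input (too short, no
#' central transition, 2-D Shape) are \code{NA}, never silently zero.
#'
#' @param seq an \code{rg_sequence}.
#' @param domain optional domain override.
#' @return named numeric vector with elements \code{repetitions},
#'   \code{adjacencies}, \code{turning_points},
#'   \code{central_turning_points}, \code{distances}, \code{shape}.
#' @export
summarize_sequence <- function(seq, domain = NULL) {
  if (is.null(domain)) domain <- seq$domain
  stripped <- strip_repeats(seq)
  shp <- if (domain$dim == 2L || length(unique(resp_values(seq))) < 2)
    NA_real_ else shape_stat(seq)
  c(repetitions = repetitions(seq),
    adjacencies = adjacencies(stripped),
    turning_points = turning_points(stripped),
    central_turning_points = central_turning_points(stripped, domain),
    distances = distances(stripped),
    shape = shp)
}

#' Reshuffle null expectations
#'
#' The expected value of each index under uniform random permutations of the
#' observed sequence -- the reference against which serial structure is
#' judged. Repetitions are computed on each permuted sequence; the
#' repeat-stripped indices are computed after stripping the permuted
#' sequence. Shape is permutation-invariant and therefore omitted.
#'
#' @param seq an \code{rg_sequence}.
#' @param n number of reshuffles (default 10^4).
#' @param seed optional integer seed.
#' @param domain optional domain override.
#' @return list with \code{expected} (named means across reshuffles),
#'   \code{se} (Monte-Carlo standard errors of those means),
#'   \code{n_reshuffles}, and \code{seed}.
#' @export
reshuffle_null <- function(seq, n = 10000L, seed = NULL, domain = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(domain)) domain <- seq$domain
  x <- resp_values(seq)
  acc <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, c("repetitions", "adjacencies",
                                        "turning_points",
                                        "central_turning_points",
                                        "distances")))
  template <- seq
  for (i in seq_len(n)) {
    template$responses <- x[sample.int(length(x))]
    s <- strip_repeats(template)
    acc[i, ] <- c(repetitions(template),
                  adjacencies(s),
                  turning_points(s),
                  central_turning_points(s, domain),
                  distances(s))
  }
  nn <- colSums(!is.na(acc))
  list(expected = colMeans(acc, na.rm = TRUE),
       se = apply(acc, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nn, 1)),
       n_reshuffles = n, seed = seed)
}

#' Exact central-turn expectation on the 7-item line
#'
#' Under independent uniform sampling with repeats stripped, a transition
#' triple (a, b, c) has a, c uniform over the six items different from b.
#' Enumerating all triples whose origin b is one of the three central items
#' gives the exact probability that the step b to c reverses the step a to
#' b. The result is 58/108.
#'
#' @param center_items origin items to restrict to (default 3:5).
#' @param n_items number of line items (default 7).
#' @return exact expected turning proportion.
#' @export
central_turn_enumeration <- function(center_items = 3:5, n_items = 7L) {
  total <- 0L
  turns <- 0L
  for (b in center_items) {
    others <- setdiff(seq_len(n_items), b)
    for (a in others) for (cc in others) {
      total <- total + 1L
      if ((b - a) * (cc - b) < 0) turns <- turns + 1L
    }
  }
  turns / total
}
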