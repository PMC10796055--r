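#' Study-condition domains
#'
#' The canonical target distributions of the two experiment designs the
#' synthetic cohorts emulate: height production (a Gaussian with mean
#' 176.4 cm and SD 12 cm, and a scaled Beta(1.27, 1.43) on 122--219 cm for
#' the uniform-target condition, on an integer-cm grid), and spatial
#' syllable layouts (seven equally likely items on a line or hex grid).
#'
#' @param condition for \code{heights_domain}: \code{"gaussian"} or
#'   \code{"uniform"}; for \code{syllables_domain}: \code{"line7"} or
#'   \code{"hex7"}.
#' @return an \code{rg_domain}.
#' @export
heights_domain <- function(condition = c("gaussian", "uniform")) {
  condition <- match.arg(condition)
  if (condition == "gaussian")
    make_domain("gaussian", mean = 176.4, sd = 12)
  else
    make_domain("scaled_beta", alpha = 1.27, beta = 1.43, lo = 122, hi = 219)
}

#' @rdname heights_domain
#' @export
syllables_domain <- function(condition = c("line7", "hex7")) {
  make_domain("discrete_uniform", layout = match.arg(condition))
}

experiment_conditions <- function(experiment) {
  switch(experiment,
    heights = list(gaussian = heights_domain("gaussian"),
                   uniform = heights_domain("uniform")),
    syllables = list(line7 = syllables_domain("line7"),
                     hex7 = syllables_domain("hex7")),
    stop("unknown experiment: ", experiment, call. = FALSE))
}

# Default sequence lengths per condition: five minutes of production at the
# observed paces -- 30 heights/min and ~71 syllables/min.
default_lengths <- function(experiment) {
  if (experiment == "heights") c(150L, 150L) else c(355L, 355L)
}

#' Generate one synthetic participant
#'
#' Produces one response sequence per condition of the chosen experiment
#' from a known generating model, recording the ground truth. Heights
#' participants produce a Gaussian-target and a uniform-target sequence;
#' syllables participants produce either two line or two hex sequences
#' (\code{layout}).
#'
#' @param model_id generating model (one of \code{MODELS}).
#' @param params named parameter list, or \code{NULL} to draw fresh
#'   parameters from the prior (one draw, shared across conditions).
#' @param experiment \code{"heights"} or \code{"syllables"}.
#' @param lengths integer vector of per-condition sequence lengths.
#' @param seed integer seed.
#' @param layout for syllables, which display the participant learned.
#' @return list with \code{sequences} (named by condition) and
#'   \code{truth} (model, params, seed).
#' @export
generate_participant <- function(model_id, params = NULL,
                                 experiment = c("heights", "syllables"),
                                 lengths = NULL, seed = 1L,
                                 layout = c("line7", "hex7")) {
  experiment <- match.arg(experiment)
  layout <- match.arg(layout)
  conds <- experiment_conditions(experiment)
  if (experiment == "syllables") conds <- conds[layout]
  if (is.null(lengths)) lengths <- default_lengths(experiment)[seq_along(conds)]
  stopifnot(all(lengths >= 50))
  if (model_id == "schema" && any(vapply(conds, function(d) d$dim, 0L) == 2L))
    stop("the schema model cannot sample in two-dimensional domains",
         call. = FALSE)
  set.seed(seed)
  if (is.null(params)) params <- draw_params_from_prior(model_id, conds[[1]])
  seqs <- vector("list", length(conds))
  names(seqs) <- names(conds)
  for (i in seq_along(conds)) {
    seqs[[i]] <- generate_sequence(model_id, conds[[i]],
                                   length = lengths[i], params = params)
    seqs[[i]]$meta$condition <- names(conds)[i]
  }
  list(sequences = seqs,
       truth = list(model = model_id, params = params, seed = seed,
                    experiment = experiment, layout = layout))
}

#' Generate a synthetic cohort on disk
#'
#' Writes \code{sequences.csv} and \code{manifest.json} for a cohort of
#' synthetic participants, each generated from the requested model with its
#' own prior parameter draw and recorded ground truth. Deterministic per
#' seed.
#'
#' @param n_participants cohort size.
#' @param model_id generating model for every participant, or
#'   \code{"prior"} to draw a random model per participant.
#' @param experiment \code{"heights"} or \code{"syllables"}.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param lengths per-condition lengths (defaults to the experiment's).
#' @param layout syllable display (\code{"line7"} or \code{"hex7"}).
#' @return invisibly, the manifest list.
#' @export
generate_cohort <- function(n_participants, model_id, experiment = "heights",
                            out_dir, seed = 1L, lengths = NULL,
                            layout = "line7") {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  set.seed(seed)
  pick <- if (model_id == "prior") {
    avail <- if (experiment == "syllables" && layout == "hex7")
      setdiff(MODELS, "schema") else MODELS
    sample(avail, n_participants, replace = TRUE)
  } else rep(model_id, n_participants)
  part_seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  all_seqs <- list()
  manifest <- list(experiment = experiment, seed = seed,
                   participants = vector("list", n_participants))
  conds <- experiment_conditions(experiment)
  if (experiment == "syllables") conds <- conds[layout]
  for (i in seq_len(n_participants)) {
    pp <- generate_participant(pick[i], params = NULL,
                               experiment = experiment, lengths = lengths,
                               seed = part_seeds[i], layout = layout)
    for (cn in names(pp$sequences)) {
      s <- pp$sequences[[cn]]
      s$meta$participant <- sprintf("P%03d", i)
      all_seqs[[length(all_seqs) + 1L]] <- s
    }
    manifest$participants[[i]] <-
      list(participant = sprintf("P%03d", i), model = pick[i],
           params = pp$truth$params, seed = part_seeds[i])
  }
  manifest$domains <- lapply(conds, function(d)
    jsonlite::fromJSON(domain_to_json(d)))
  write_sequences(all_seqs, file.path(out_dir, "sequences.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read and write sequence files
#'
#' Sequences are stored as plain CSV with columns \code{participant},
#' \code{condition}, \code{trial}, \code{response} and, for hex layouts,
#' \code{x} and \code{y} item coordinates. \code{read_sequences} validates
#' every row against the condition's domain and reports offending row
#' numbers.
#'
#' @param seqs list of \code{rg_sequence} objects.
#' @param path CSV file path.
#' @return \code{write_sequences}: the path, invisibly;
#'   \code{read_sequences}: a list of \code{rg_sequence} objects.
#' @export
write_sequences <- function(seqs, path) {
  rows <- lapply(seqs, function(s) {
    n <- length(s$responses)
    hex <- s$domain$family == "discrete_uniform" && s$domain$dim == 2L
    data.frame(
      participant = if (is.null(s$meta$participant)) "P001" else s$meta$participant,
      condition = if (is.null(s$meta$condition)) s$domain$family else s$meta$condition,
      trial = seq_len(n),
      response = s$responses,
      x = if (hex) s$domain$layout$positions[s$responses, 1] else NA_real_,
      y = if (hex) s$domain$layout$positions[s$responses, 2] else NA_real_)
  })
  df <- do.call(rbind, rows)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write sequences to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

condition_domain <- function(condition, domains = NULL) {
  if (!is.null(domains) && condition %in% names(domains))
    return(domains[[condition]])
  switch(condition,
    gaussian = heights_domain("gaussian"),
    uniform = heights_domain("uniform"),
    line7 = syllables_domain("line7"),
    hex7 = syllables_domain("hex7"),
    stop("unknown condition: ", condition, call. = FALSE))
}

#' @rdname write_sequences
#' @param domains optional named list mapping condition names to
#'   \code{rg_domain} objects; the built-in study conditions are recognised
#'   automatically.
#' @export
read_sequences <- function(path, domains = NULL) {
  if (!file.exists(path))
    stop("sequence file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("participant", "condition", "trial", "response")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing columns in '", path, "': ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$.row <- seq_len(nrow(df)) + 1L # header is line 1
  out <- list()
  for (key in unique(paste(df$participant, df$condition, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- df[df$participant == parts[1] & df$condition == parts[2], ]
    sub <- sub[order(sub$trial), ]
    dom <- condition_domain(parts[2], domains)
    bad <- if (dom$family == "gaussian") {
      # unbounded support: integer cm within eight SDs of the mean
      lim <- dom$params$mean + c(-8, 8) * dom$params$sd
      which(sub$response != round(sub$response) |
              sub$response < lim[1] | sub$response > lim[2])
    } else {
      which(!(sub$response %in% domain_grid(dom)))
    }
    if (length(bad) > 0)
      stop("off-grid response for condition '", parts[2], "' at row ",
           sub$.row[bad[1]], " of '", path, "'", call. = FALSE)
    if (dom$dim == 2L && all(c("x", "y") %in% names(df))) {
      pos <- dom$layout$positions[sub$response, , drop = FALSE]
      mism <- which(abs(pos[, 1] - sub$x) > 1e-6 | abs(pos[, 2] - sub$y) > 1e-6)
      if (length(mism) > 0)
        stop("x,y coordinates inconsistent with item id at row ",
             sub$.row[mism[1]], " of '", path, "'", call. = FALSE)
    }
    s <- structure(list(responses = sub$response, domain = dom,
                        model = NA_character_, params = NULL, seed = NULL,
                        states = NULL,
                        meta = list(participant = parts[1],
                                    condition = parts[2])),
                   class = "rg_sequence")
    out[[length(out) + 1L]] <- s
  }
  out
}
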