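#' Configuration of the synthetic bee-choice generator
#'
#' Describes a two-by-two choice experiment (cue type: social bee model vs.
#' non-social foam model; prior reward distribution: high-variance vs.
#' no-variance) with bees nested in colonies. Defaults emulate the
#' reference design: 57 bees from 3 colonies, group sizes 16
#' (social/high-variance), 17 (social/no-variance) and 12/12 for the two
#' non-social cells (only the non-social total of 24 is fixed by the
#' design; the even split is a choice).
#'
#' Each bee's per-landing probability of choosing a cued flower is
#' `plogis(baseline_logit + linear predictor + colony intercept)`, with
#' colony intercepts drawn from `Normal(0, colony_sd^2)`. The baseline is
#' the chance landing level `logit(1/3)` for the reference cell
#' (non-social cue, no-variance experience), so the configured effects act
#' relative to chance. Effects are expressed on the logit scale with
#' indicators social = 1 and high-variance = 1 (see the methods vignette):
#'
#' * `parameterization = "split"`: one reward-distribution effect per cue
#'   type — `dist_effect_social` (default 3.125) applies to the
#'   social/high-variance cell, `dist_effect_nonsocial` (default 0.696) to
#'   the non-social/high-variance cell.
#' * `parameterization = "full"`: `cue_effect` (default -1.138),
#'   `dist_effect` (0.733) and `interaction_effect` (2.593) combine as
#'   `cue*social + dist*high + interaction*social*high`.
#'
#' The default effect magnitudes are plausible values of the size reported
#' for this kind of experiment; they are generator defaults for testing the
#' analysis pipeline, not ground truth to be matched.
#'
#' @param group_sizes Named integer vector with entries `social_high`,
#'   `social_none`, `nonsocial_high`, `nonsocial_none`.
#' @param n_colonies Number of colonies; bees are assigned round-robin.
#' @param colony_sd SD of the colony random intercept on the logit scale.
#' @param baseline_logit Logit of the reference-cell landing probability.
#' @param parameterization `"split"` or `"full"` (see above).
#' @param dist_effect_social,dist_effect_nonsocial Split-parameterization
#'   effects of high-variance experience within each cue type.
#' @param cue_effect,dist_effect,interaction_effect Full-parameterization
#'   effects.
#' @param n_landings_per_bee Landings recorded per bee (independent
#'   Bernoulli draws; the first is the first-choice outcome).
#' @param seed Default seed used by [generate_choice_dataset()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(group_sizes = c(social_high = 16L, social_none = 17L,
                                             nonsocial_high = 12L, nonsocial_none = 12L),
                             n_colonies = 3L,
                             colony_sd = 0.3,
                             baseline_logit = stats::qlogis(1 / 3),
                             parameterization = c("split", "full"),
                             dist_effect_social = 3.125,
                             dist_effect_nonsocial = 0.696,
                             cue_effect = -1.138,
                             dist_effect = 0.733,
                             interaction_effect = 2.593,
                             n_landings_per_bee = 10L,
                             seed = 1L) {
  parameterization <- match.arg(parameterization)
  need <- c("social_high", "social_none", "nonsocial_high", "nonsocial_none")
  if (!all(need %in% names(group_sizes)))
    stop("group_sizes must name all of: ", paste(need, collapse = ", "))
  group_sizes <- as.integer(group_sizes[need])
  names(group_sizes) <- need
  if (any(group_sizes < 1L)) stop("all group sizes must be positive")
  if (n_colonies < 1L) stop("n_colonies must be >= 1")
  if (colony_sd < 0) stop("colony_sd must be non-negative")
  if (n_landings_per_bee < 1L) stop("n_landings_per_bee must be >= 1")
  structure(list(
    group_sizes = group_sizes,
    n_colonies = as.integer(n_colonies),
    colony_sd = as.numeric(colony_sd),
    baseline_logit = as.numeric(baseline_logit),
    parameterization = parameterization,
    dist_effect_social = as.numeric(dist_effect_social),
    dist_effect_nonsocial = as.numeric(dist_effect_nonsocial),
    cue_effect = as.numeric(cue_effect),
    dist_effect = as.numeric(dist_effect),
    interaction_effect = as.numeric(interaction_effect),
    n_landings_per_bee = as.integer(n_landings_per_bee),
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Read a generator configuration from JSON
#'
#' Field names mirror [generator_config()]; unknown keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(generator_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown generator configuration key(s): ", paste(extra, collapse = ", "))
  if (!is.null(raw$group_sizes)) raw$group_sizes <- unlist(raw$group_sizes)
  do.call(generator_config, raw)
}

# Linear predictor contribution of a cell, excluding baseline and colony.
cell_effect <- function(config, social, high) {
  if (config$parameterization == "split") {
    high * ifelse(social, config$dist_effect_social, config$dist_effect_nonsocial)
  } else {
    config$cue_effect * social + config$dist_effect * high +
      config$interaction_effect * social * high
  }
}

#' Generate a synthetic bee-choice dataset
#'
#' Assigns bees round-robin to colonies in a fixed cell order
#' (social/high-variance, social/no-variance, non-social/high-variance,
#' non-social/no-variance), draws one colony intercept per colony, and for
#' every bee draws `n_landings_per_bee` independent Bernoulli landings with
#' the cell- and colony-specific probability of choosing a cued flower.
#' The first landing is the bee's first-choice outcome. Deterministic for
#' a fixed config and seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `bee_choices` data frame: `bee_id`, `colony`, `cue_type`,
#'   `distribution`, `first_choice_cued`, and a `landings` list column of
#'   0/1 integer vectors.
#' @examples
#' bees <- generate_choice_dataset(generator_config(), seed = 42)
#' table(bees$cue_type, bees$distribution)
#' @export
generate_choice_dataset <- function(config = generator_config(),
                                    seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))
  gs <- config$group_sizes
  cells <- data.frame(
    cell = names(gs),
    cue_type = c("social", "social", "nonsocial", "nonsocial"),
    distribution = c("high_variance", "no_variance",
                     "high_variance", "no_variance"),
    n = as.integer(gs)
  )
  n_bees <- sum(cells$n)
  cue_type <- rep(cells$cue_type, cells$n)
  distribution <- rep(cells$distribution, cells$n)
  colony_idx <- ((seq_len(n_bees) - 1L) %% config$n_colonies) + 1L
  colony_int <- stats::rnorm(config$n_colonies, 0, config$colony_sd)
  eta <- config$baseline_logit +
    cell_effect(config, cue_type == "social", distribution == "high_variance") +
    colony_int[colony_idx]
  prob <- stats::plogis(eta)
  landings <- lapply(seq_len(n_bees), function(i) {
    as.integer(stats::rbinom(config$n_landings_per_bee, 1L, prob[i]))
  })
  out <- data.frame(
    bee_id = sprintf("bee_%03d", seq_len(n_bees)),
    colony = sprintf("colony_%d", colony_idx),
    cue_type = cue_type,
    distribution = distribution,
    first_choice_cued = vapply(landings, `[`, integer(1), 1L),
    stringsAsFactors = FALSE
  )
  out$landings <- landings
  class(out) <- c("bee_choices", "data.frame")
  out
}

#' Write / read bee-choice data as long-format CSV
#'
#' `write_choice_csv()` writes one row per landing with columns `bee_id`,
#' `colony`, `cue_type`, `distribution`, `landing_index` (1-based) and
#' `landed_on_cued` (0/1). `read_choice_csv()` reads that format back —
#' the round trip is the identity on `bee_choices` collections — and also
#' accepts a wide one-row-per-bee variant with a `first_choice_cued`
#' column instead of landing rows (each bee then has a single landing).
#' Malformed rows are rejected with the offending row number and column.
#'
#' @param records A `bee_choices` data frame.
#' @param path CSV file path.
#' @return `write_choice_csv()` the path invisibly; `read_choice_csv()` a
#'   `bee_choices` data frame.
#' @export
write_choice_csv <- function(records, path) {
  n_land <- vapply(records$landings, length, integer(1))
  long <- data.frame(
    bee_id = rep(records$bee_id, n_land),
    colony = rep(records$colony, n_land),
    cue_type = rep(records$cue_type, n_land),
    distribution = rep(records$distribution, n_land),
    landing_index = as.integer(unlist(lapply(n_land, seq_len), use.names = FALSE)),
    landed_on_cued = as.integer(unlist(records$landings, use.names = FALSE))
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_choice_csv
#' @export
read_choice_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  base_cols <- c("bee_id", "colony", "cue_type", "distribution")
  wide <- "first_choice_cued" %in% names(long) &&
    !"landing_index" %in% names(long)
  need <- c(base_cols,
            if (wide) "first_choice_cued" else c("landing_index", "landed_on_cued"))
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  value_col <- if (wide) "first_choice_cued" else "landed_on_cued"
  bad <- which(!(long[[value_col]] %in% c(0L, 1L)))
  if (length(bad))
    stop(sprintf("row %d, column %s: value must be 0 or 1 (got %s)",
                 bad[1], value_col, long[[value_col]][bad[1]]))
  bad_cue <- which(!(long$cue_type %in% c("social", "nonsocial")))
  if (length(bad_cue))
    stop(sprintf("row %d, column cue_type: unknown level '%s'",
                 bad_cue[1], long$cue_type[bad_cue[1]]))
  bad_dist <- which(!(long$distribution %in% c("high_variance", "no_variance")))
  if (length(bad_dist))
    stop(sprintf("row %d, column distribution: unknown level '%s'",
                 bad_dist[1], long$distribution[bad_dist[1]]))
  bees <- unique(long$bee_id)  # preserve file order
  if (wide) {
    first <- long[match(bees, long$bee_id), , drop = FALSE]
    landings <- lapply(as.integer(first$first_choice_cued), function(v) v)
    meta <- first
  } else {
    if (any(long$landing_index != as.integer(long$landing_index)) ||
        any(long$landing_index < 1L))
      stop("landing_index must be a positive integer")
    landings <- lapply(bees, function(b) {
      rows <- long[long$bee_id == b, , drop = FALSE]
      rows <- rows[order(rows$landing_index), , drop = FALSE]
      if (!identical(as.integer(rows$landing_index), seq_len(nrow(rows))))
        stop(sprintf("bee %s: landing_index must run 1..%d without gaps",
                     b, nrow(rows)))
      as.integer(rows$landed_on_cued)
    })
    meta <- long[match(bees, long$bee_id), , drop = FALSE]
  }
  out <- data.frame(
    bee_id = as.character(meta$bee_id),
    colony = as.character(meta$colony),
    cue_type = meta$cue_type,
    distribution = meta$distribution,
    first_choice_cued = vapply(landings, `[`, integer(1), 1L),
    stringsAsFactors = FALSE
  )
  out$landings <- landings
  rownames(out) <- NULL
  class(out) <- c("bee_choices", "data.frame")
  out
}
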