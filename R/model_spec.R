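#' Model specification for the time-evolving ex-Gaussian model
#'
#' Declares, per target parameter (`start`, `rate`, `asym`,
#' `gauss_mean`), the fixed covariate terms of its log-scale linear
#' predictor, and per grouping factor the subset of terms allowed to
#' vary randomly. All four targets use a log link (exponential inverse
#' link), so coefficients are multiplicative on the ms scale. The
#' Gaussian SD is a single trial-constant scale parameter.
#'
#' Recognised terms:
#' * `intercept` — required for every target.
#' * `incomp` — incompatible-block indicator (0 = compatible), so the
#'   coefficient is the log-scale incompatibility (IAT) effect.
#' * `incomp_c` — the same contrast as a zero-centered code (+1/2
#'   incompatible), for designs where the intercept should sit at the
#'   midpoint of the two pairings.
#' * `run2` — second-run indicator (carry-over / order-within-session).
#' * `incomp:run2` — their interaction.
#' * `iat_type` — zero-centered dichotomous IAT-type code (+1/2 for
#'   the alphabetically second type); needs exactly two types.
#' * `iat_type:incomp` — type-by-incompatibility interaction.
#' * `word_vs_face` — centered stimulus-class code (+1/2 word);
#'   `gauss_mean` only.
#' * `gender`, `age` — participant covariates, centered at the sample
#'   mean (requires a participants table).
#' * `condition`, `condition:incomp` — between-participant learning
#'   condition; expands to treatment contrasts against the reference
#'   level (first level, or `"control"` when present).
#'
#' @param start,rate,asym,gauss_mean character vectors of fixed terms
#'   per target.
#' @param random named list of grouping factors (`participant`,
#'   `experiment`), each a named list giving the random terms per
#'   target, e.g. `list(participant = list(start = c("intercept",
#'   "incomp")))`. Random terms must be a subset of the fixed terms of
#'   the same target.
#' @param time_varying `FALSE` builds the static null: the exponential
#'   component is constant over trials at the `asym` predictor, and
#'   `start`/`rate` must carry no terms.
#' @return a list of class `iat_model_spec`.
#' @export
iat_model_spec <- function(start = c("intercept", "incomp"),
                           rate = c("intercept", "incomp"),
                           asym = c("intercept", "incomp"),
                           gauss_mean = "intercept",
                           random = list(
                             participant = list(
                               start = "intercept",
                               rate = "intercept",
                               asym = "intercept",
                               gauss_mean = "intercept")),
                           time_varying = TRUE) {
  fixed <- list(start = start, rate = rate, asym = asym,
                gauss_mean = gauss_mean)
  if (!time_varying) {
    if (length(start) > 0 || length(rate) > 0) {
      stop("the static null forbids `start` and `rate` terms ",
           "(start is equated with asym)", call. = FALSE)
    }
  } else {
    for (tg in c("start", "rate", "asym")) {
      if (!"intercept" %in% fixed[[tg]]) {
        stop("`", tg, "` must include an intercept", call. = FALSE)
      }
    }
  }
  if (!"intercept" %in% gauss_mean) {
    stop("`gauss_mean` must include an intercept", call. = FALSE)
  }
  for (g in names(random)) {
    if (!g %in% c("participant", "experiment")) {
      stop("unknown grouping factor: ", g, call. = FALSE)
    }
    for (tg in names(random[[g]])) {
      extra <- setdiff(random[[g]][[tg]], fixed[[tg]])
      if (length(extra) > 0) {
        stop("random terms must be a subset of fixed terms; `", tg,
             "` lacks: ", paste(extra, collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(list(fixed = fixed, random = random,
                 time_varying = time_varying),
            class = "iat_model_spec")
}

#' Preset model specifications
#'
#' * `spec_two_run()` — single-IAT session: trajectory parameters vary
#'   by compatibility and run position, with participant random
#'   intercepts and compatibility slopes (and a run-2 shift on the
#'   asymptote as the fixed carry-over term).
#' * `spec_two_iat()` — joint two-IAT model: a zero-centered IAT-type
#'   predictor in fixed and random effects, order/run terms removed.
#' * `spec_condition()` — between-group learning-condition design with
#'   condition-by-incompatibility interactions, centered gender/age
#'   covariates, participant intercept + compatibility slope, and
#'   experiment-level random intercepts.
#' * `spec_static(spec)` — the static null matching any of the above:
#'   the asym predictor keeps the union of the start/asym terms, rate
#'   and start are emptied, random structure collapses accordingly.
#'
#' @return an [iat_model_spec()].
#' @export
spec_two_run <- function() {
  iat_model_spec(
    start = c("intercept", "incomp", "run2"),
    rate = c("intercept", "incomp", "run2"),
    asym = c("intercept", "incomp", "run2"),
    gauss_mean = c("intercept", "word_vs_face"),
    random = list(participant = list(
      start = c("intercept", "incomp"),
      rate = c("intercept", "incomp"),
      asym = c("intercept", "incomp"),
      gauss_mean = "intercept")))
}

#' @rdname spec_two_run
#' @export
spec_two_iat <- function() {
  iat_model_spec(
    start = c("intercept", "iat_type", "incomp", "iat_type:incomp"),
    rate = c("intercept", "iat_type", "incomp"),
    asym = c("intercept", "iat_type", "incomp", "iat_type:incomp"),
    gauss_mean = c("intercept", "word_vs_face"),
    random = list(participant = list(
      start = c("intercept", "iat_type", "incomp"),
      rate = c("intercept", "incomp"),
      asym = c("intercept", "iat_type", "incomp"),
      gauss_mean = "intercept")))
}

#' @rdname spec_two_run
#' @export
spec_condition <- function() {
  iat_model_spec(
    start = c("intercept", "condition", "incomp", "gender", "age",
              "condition:incomp"),
    rate = c("intercept", "condition", "incomp", "gender", "age",
             "condition:incomp"),
    asym = c("intercept", "condition", "incomp", "gender", "age",
             "condition:incomp"),
    gauss_mean = "intercept",
    random = list(
      participant = list(start = c("intercept", "incomp"),
                         rate = c("intercept", "incomp"),
                         asym = c("intercept", "incomp"),
                         gauss_mean = "intercept"),
      experiment = list(start = "intercept",
                        rate = "intercept",
                        asym = "intercept")))
}

#' @rdname spec_two_run
#' @param spec a time-varying [iat_model_spec()].
#' @export
spec_static <- function(spec) {
  level_terms <- unique(c(spec$fixed$asym, spec$fixed$start))
  random <- lapply(spec$random, function(rg) {
    out <- list()
    lvl <- unique(c(rg$asym, rg$start))
    if (length(lvl) > 0) out$asym <- lvl
    if (length(rg$gauss_mean) > 0) out$gauss_mean <- rg$gauss_mean
    out
  })
  random <- random[lengths(random) > 0]
  iat_model_spec(start = character(0), rate = character(0),
                 asym = level_terms, gauss_mean = spec$fixed$gauss_mean,
                 random = random, time_varying = FALSE)
}

# -- design construction -----------------------------------------------

expand_term <- function(term, df, pinfo) {
  one <- function(nm) {
    switch(nm,
      intercept = rep(1, nrow(df)),
      incomp = as.numeric(df$compatibility == "incompatible"),
      incomp_c = ifelse(df$compatibility == "incompatible", 0.5, -0.5),
      run2 = as.numeric(df$run_index == 2L),
      iat_type = {
        types <- sort(unique(df$iat_type))
        if (length(types) != 2) {
          stop("`iat_type` term needs exactly two IAT types, found ",
               length(types), call. = FALSE)
        }
        ifelse(df$iat_type == types[2], 0.5, -0.5)
      },
      word_vs_face = {
        if (!"stimulus_class" %in% names(df)) {
          stop("`word_vs_face` term requires a `stimulus_class` column",
               call. = FALSE)
        }
        ifelse(df$stimulus_class == "word", 0.5, -0.5)
      },
      gender = pinfo$covariate(df, "gender"),
      age = pinfo$covariate(df, "age"),
      stop("model spec names a covariate the dataset lacks: ", nm,
           call. = FALSE)
    )
  }
  if (grepl("condition", term, fixed = TRUE)) {
    cond <- pinfo$condition(df)
    parts <- setdiff(strsplit(term, ":", fixed = TRUE)[[1]],
                     "condition")
    rest <- if (length(parts) > 0) {
      Reduce(`*`, lapply(parts, one))
    } else rep(1, nrow(df))
    cols <- lapply(cond$contrast_levels, function(lv) {
      as.numeric(cond$value == lv) * rest
    })
    names(cols) <- paste0(
      "condition_", cond$contrast_levels,
      if (length(parts) > 0) paste0(":", paste(parts, collapse = ":"))
      else "")
    return(cols)
  }
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  col <- Reduce(`*`, lapply(parts, one))
  stats::setNames(list(col), term)
}

make_pinfo <- function(participants) {
  covariate <- function(df, nm) {
    if (is.null(participants) || !nm %in% names(participants)) {
      stop("term `", nm, "` requires a participants table with a `",
           nm, "` column", call. = FALSE)
    }
    v <- participants[[nm]][match(df$participant_id,
                                  participants$participant_id)]
    if (anyNA(v)) {
      stop("participants table is missing `", nm,
           "` for some participants", call. = FALSE)
    }
    v - mean(participants[[nm]], na.rm = TRUE)
  }
  condition <- function(df) {
    if (is.null(participants) ||
        !"condition" %in% names(participants)) {
      stop("`condition` terms require a participants table with a ",
           "`condition` column", call. = FALSE)
    }
    value <- participants$condition[match(df$participant_id,
                                          participants$participant_id)]
    lev <- unique(participants$condition)
    ref <- if ("control" %in% lev) "control" else sort(lev)[1]
    list(value = value,
         contrast_levels = setdiff(sort(lev), ref),
         reference = ref)
  }
  list(covariate = covariate, condition = condition,
       participants = participants)
}

#' Build the per-parameter design structure
#'
#' Expands an [iat_model_spec()] against a trial dataset into, per
#' target, a fixed-effects design matrix with deterministic column
#' ordering (spec order, condition contrasts in level order), plus the
#' random-effects bookkeeping (group index per trial and the design
#' column of every random term). Centered codings are centered against
#' the participants table; condition contrasts use the reference level
#' `"control"` when present, otherwise the alphabetically first level.
#'
#' @param spec an [iat_model_spec()].
#' @param data an [iat_trials()] dataset (dual-stimulus rows; rows with
#'   `NA` compatibility are refused).
#' @param participants optional participant-level table
#'   (`participant_id` plus any of `gender`, `age`, `condition`,
#'   `experiment`) for covariate terms and experiment grouping.
#' @return an internal design list used by [fit_trajectory()] and
#'   [model_loglik()].
#' @export
build_design <- function(spec, data, participants = NULL) {
  df <- tibble::as_tibble(data)
  if (anyNA(df$compatibility)) {
    stop("design requires dual-stimulus rows only ",
         "(found NA compatibility)", call. = FALSE)
  }
  pinfo <- make_pinfo(participants)
  targets <- list()
  for (tg in names(spec$fixed)) {
    terms <- spec$fixed[[tg]]
    if (length(terms) == 0) {
      targets[[tg]] <- list(X = matrix(0, nrow(df), 0), terms = list())
      next
    }
    cols <- list()
    term_cols <- list()  # original term name -> expanded column indices
    i <- 1L
    for (term in terms) {
      expanded <- expand_term(term, df, pinfo)
      cols <- c(cols, expanded)
      term_cols[[term]] <- seq.int(i, length.out = length(expanded))
      i <- i + length(expanded)
    }
    X <- do.call(cbind, cols)
    colnames(X) <- names(cols)
    targets[[tg]] <- list(X = X, terms = term_cols)
  }

  random <- list()
  for (g in names(spec$random)) {
    gid <- if (g == "participant") {
      factor(df$participant_id)
    } else {
      if (is.null(participants) ||
          !"experiment" %in% names(participants)) {
        stop("experiment random effects require a participants table ",
             "with an `experiment` column", call. = FALSE)
      }
      factor(participants$experiment[match(df$participant_id,
                                           participants$participant_id)])
    }
    if (g == "participant" && nlevels(gid) < 2) {
      stop("participant random effects need at least 2 participants",
           call. = FALSE)
    }
    random[[g]] <- list(index = as.integer(gid),
                        levels = levels(gid),
                        n_groups = nlevels(gid),
                        terms = spec$random[[g]])
  }

  structure(list(targets = targets, random = random,
                 t = df$trial_index, rt = df$rt_ms, n = nrow(df),
                 spec = spec, participant_id = df$participant_id,
                 participants = participants),
            class = "iat_design")
}
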