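#' Pipeline orchestration
#'
#' Runs one stage of the analysis pipeline from an argument vector, so
#' the whole workflow is scriptable (`inst/scripts/iat-pipeline` is a
#' thin Rscript wrapper around this function). Every stochastic stage
#' requires an explicit `--seed`; outputs are the package's documented
#' CSV/JSON formats, and a plain-text run log records seeds and
#' stage-level counts.
#'
#' Subcommands:
#' * `simulate --config cfg.json --out trials.csv [--truth t.json]
#'   [--externals ext.csv]` — generate a synthetic dataset; the JSON
#'   config holds [iat_sim_config()] fields (`seed` mandatory).
#' * `score --in trials.csv --out scores.csv [--preset trialwise]` —
#'   per-participant D-scores.
#' * `study1 --in trials.csv --out contrasts.csv --seed S` —
#'   block-level paired contrasts, the order effect and the blockwise
#'   between-subjects d table.
#' * `fit --in trials.csv --out fit.csv [--spec basic|two_run|two_iat]
#'   [--null] [--seed S]` — fit the trajectory model (or static null)
#'   and write the tidy coefficient table.
#' * `compare --in trials.csv --out loo.json [--spec ...] [--seed S]`
#'   — fit the time-varying model and its static null and write the
#'   cross-validated comparison.
#' * `indices --in trials.csv --out indices.csv [--spec ...]` —
#'   participant-level trajectory indices (plus D-scores).
#' * `link --indices indices.csv --externals ext.csv --out link.csv
#'   --seed S [--n-boot B] [--models a,b]` — bootstrapped robust
#'   linkage models (comma-separated subset of `seeming_racist`,
#'   `seating_distance`, `seating_black_interviewer`).
#' * `report --fit fit.csv --out report.txt` — plain-text rendering
#'   of a fit table.
#'
#' @param args character vector of command-line style arguments.
#' @return invisibly, the primary artifact path written.
#' @export
iat_pipeline <- function(args = character()) {
  if (length(args) == 0) {
    stop("usage: iat_pipeline(c('<subcommand>', ...)); subcommands: ",
         "simulate score study1 fit compare indices link report",
         call. = FALSE)
  }
  cmd <- args[1]
  opts <- parse_flags(args[-1])
  log_line <- function(...) {
    msg <- sprintf(...)
    message(msg)
    if (!is.null(opts$log)) cat(msg, "\n", file = opts$log,
                                append = TRUE)
  }
  need <- function(nm) {
    if (is.null(opts[[nm]])) {
      stop(sprintf("subcommand `%s` requires --%s", cmd, nm),
           call. = FALSE)
    }
    opts[[nm]]
  }
  need_file <- function(nm) {
    path <- need(nm)
    if (!file.exists(path)) {
      stop(sprintf("input file not found: %s", path), call. = FALSE)
    }
    path
  }
  get_spec <- function() {
    switch(opts$spec %||% "basic",
           basic = iat_model_spec(),
           two_run = spec_two_run(),
           two_iat = spec_two_iat(),
           condition = spec_condition(),
           stop("unknown --spec: ", opts$spec, call. = FALSE))
  }
  out <- switch(cmd,
    simulate = {
      cfg <- jsonlite::read_json(need_file("config"),
                                 simplifyVector = TRUE)
      config <- do.call(iat_sim_config, cfg)
      sim <- simulate_iat(config)
      write_iat_trials(sim$trials, need("out"))
      log_line("simulate: %d trials, %d participants, seed %d",
               nrow(sim$trials), config$n_participants, config$seed)
      if (!is.null(opts$truth)) {
        jsonlite::write_json(list(fixed = as.list(sim$truth$fixed),
                                  indices = true_indices(sim$truth)),
                             opts$truth, auto_unbox = TRUE, digits = NA)
      }
      if (!is.null(opts$externals)) {
        write_external_measures(simulate_externals(sim$truth, config),
                                opts$externals)
      }
      need("out")
    },
    score = {
      trials <- read_iat_trials(need_file("in"))
      rules <- if ((opts$preset %||% "none") == "none") NULL
               else filter_preset(opts$preset)
      scores <- d_score_all(trials, rules)
      utils::write.csv(scores, need("out"), row.names = FALSE)
      log_line("score: %d participants scored", nrow(scores))
      need("out")
    },
    study1 = {
      seed <- as.integer(need("seed"))
      trials <- read_iat_trials(need_file("in"))
      df <- tibble::as_tibble(trials)
      key <- interaction(df$participant_id, df$iat_type, drop = TRUE)
      bm <- function(b) {
        tapply(df$rt_ms[df$block_index == b],
               key[df$block_index == b], mean)
      }
      rows <- list()
      add <- function(label, eff) {
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          contrast = label, kind = eff$kind,
          statistic = eff$statistic, effect_d = eff$effect_d,
          ci_low = eff$ci_low, ci_high = eff$ci_high,
          p_value = eff$p_value)
      }
      add("block4_vs_block3", paired_contrast(bm(3), bm(4)))
      add("block7_vs_block6", paired_contrast(bm(6), bm(7)))
      scores <- d_score_all(trials)
      add("order_effect_on_D", order_effect(scores, seed = seed))
      for (b in c(3, 4, 6, 7)) {
        add(sprintf("blockwise_d_block%d", b),
            blockwise_d(trials, b, seed = seed + b))
      }
      res <- do.call(rbind, rows)
      utils::write.csv(res, need("out"), row.names = FALSE)
      log_line("study1: %d contrasts written (seed %d)", nrow(res),
               seed)
      need("out")
    },
    fit = {
      trials <- read_iat_trials(need_file("in"))
      spec <- get_spec()
      seed <- as.integer(opts$seed %||% 1L)
      f <- if (isTRUE(opts$null)) {
        fit_static(trials, spec, seed = seed)
      } else {
        fit_trajectory(trials, spec, seed = seed,
                       method = opts$method %||% "map")
      }
      utils::write.csv(fit_summary_table(f), need("out"),
                       row.names = FALSE)
      log_line("fit: %d parameters, convergence code %d",
               f$layout$n_par, f$diagnostics$convergence)
      need("out")
    },
    compare = {
      trials <- read_iat_trials(need_file("in"))
      spec <- get_spec()
      seed <- as.integer(opts$seed %||% 1L)
      fa <- fit_trajectory(trials, spec, seed = seed)
      fb <- fit_static(trials, spec, seed = seed)
      cmp <- compare_loo(fa, fb,
                         K = as.integer(opts$kfold %||% 10L))
      jsonlite::write_json(
        list(looic_diff = cmp$looic_diff, se_diff = cmp$se_diff,
             elpd_diff = cmp$elpd_diff, reliable = cmp$reliable,
             method = cmp$method, n = cmp$n),
        need("out"), auto_unbox = TRUE, digits = NA)
      log_line("compare: looic_diff = %.1f (SE %.1f), reliable = %s",
               cmp$looic_diff, cmp$se_diff, cmp$reliable)
      need("out")
    },
    indices = {
      trials <- read_iat_trials(need_file("in"))
      spec <- get_spec()
      f <- fit_trajectory(trials, spec,
                          seed = as.integer(opts$seed %||% 1L))
      idx <- extract_indices(f)
      scores <- d_score_all(trials)
      agg <- stats::aggregate(d_overall ~ participant_id, scores, mean)
      idx <- merge(idx, agg, by = "participant_id")
      utils::write.csv(idx, need("out"), row.names = FALSE)
      log_line("indices: %d participants", nrow(idx))
      need("out")
    },
    link = {
      idx <- utils::read.csv(need_file("indices"),
                             colClasses = c(participant_id = "character"))
      ext <- read_external_measures(need_file("externals"))
      seed <- as.integer(need("seed"))
      models <- if (is.null(opts$models)) {
        c("seeming_racist", "seating_distance",
          "seating_black_interviewer")
      } else {
        strsplit(opts$models, ",", fixed = TRUE)[[1]]
      }
      res <- linkage_suite(idx, ext, models = models, seed = seed,
                           n_boot = as.integer(opts$`n-boot` %||% 5000))
      utils::write.csv(linkage_table(res), need("out"),
                       row.names = FALSE)
      log_line("link: %d models (seed %d)", length(res$models), seed)
      need("out")
    },
    report = {
      tab <- utils::read.csv(need_file("fit"))
      txt <- utils::capture.output(print(tab, row.names = FALSE))
      writeLines(txt, need("out"))
      log_line("report: written to %s", need("out"))
      need("out")
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(out)
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument: ", a, call. = FALSE)
    }
    key <- substring(a, 3)
    if (key == "null") {
      opts$null <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) {
        stop("flag --", key, " needs a value", call. = FALSE)
      }
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}
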